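test_that("lognormal moment matching has the closed form and round-trips", {
  p <- fit_lognormal_moments(0.23, 0.0575)
  expect_equal(round(unname(p["meanlog"]), 4), -1.5000)
  expect_equal(round(unname(p["sdlog"]), 4), 0.2462)
  # degenerate limit: sd 0 -> point mass
  p0 <- fit_lognormal_moments(70, 0)
  expect_equal(unname(p0), c(log(70), 0))
  expect_error(fit_lognormal_moments(-1, 1), "mean")
  expect_error(fit_lognormal_moments(1, -1), "sd")

  # sampled moments recover the inputs (law of large numbers at n = 1e6)
  p <- fit_lognormal_moments(70, 7)
  set.seed(1)
  x <- rlnorm(1e6, p["meanlog"], p["sdlog"])
  expect_lt(abs(mean(x) / 70 - 1), 0.005)
  expect_lt(abs(sd(x) / 7 - 1), 0.005)
})

test_that("dist_spec validates family parameters", {
  expect_error(dist_spec("lognormal", mean = -1, sd = 1), "mean > 0")
  expect_error(dist_spec("normal", mean = 0, sd = -1), "non-negative")
  expect_error(dist_spec("uniform", low = 10, high = 5), "high >= low")
  expect_error(dist_spec("gamma"), "arg")
})

test_that("input sampling honours specs, seeds and truncation", {
  cfg <- mc_config(iterations = 1000, seed = 42)
  specs <- list(A = dist_spec("point", value = 3),
                B = dist_spec("uniform", low = 365, high = 365))
  m <- sample_inputs(specs, cfg)
  expect_true(all(m[, "A"] == 3))
  expect_true(all(m[, "B"] == 365))

  big <- mc_config(iterations = 1e5, seed = 42)
  m2 <- sample_inputs(list(BW = dist_spec("normal", mean = 70, sd = 7)), big)
  expect_lt(abs(mean(m2[, "BW"]) / 70 - 1), 0.01)
  expect_true(all(m2[, "BW"] >= 0))

  # truncation by resampling keeps the stream deterministic
  tr <- sample_inputs(list(X = dist_spec("normal", mean = 1, sd = 2)), cfg)
  expect_true(all(tr[, "X"] >= 0))
  expect_identical(tr, sample_inputs(
    list(X = dist_spec("normal", mean = 1, sd = 2)), cfg))
})

test_that("per-variable streams are independent of the variable set", {
  cfg <- mc_config(iterations = 100, seed = 7)
  a <- sample_inputs(list(A = dist_spec("normal", mean = 0, sd = 1,
                                        truncate_low = -Inf)), cfg)
  ab <- sample_inputs(list(A = dist_spec("normal", mean = 0, sd = 1,
                                         truncate_low = -Inf),
                           B = dist_spec("uniform", low = 0, high = 1)), cfg)
  expect_identical(a[, "A"], ab[, "A"])
})

test_that("probabilistic propagation is reproducible end to end", {
  specs <- concentration_specs(zone_mean_table())
  cfg <- mc_config(iterations = 500, seed = 9)
  r1 <- run_probabilistic_risk(specs, config = cfg)
  r2 <- run_probabilistic_risk(specs, config = cfg)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$summary, r2$summary)
  # summaries recomputable from stored samples
  expect_equal(r1$summary$mean, unname(sapply(r1$samples, mean)))
  expect_equal(nrow(r1$samples), 500)
})

test_that("all-point specs collapse the MC to the deterministic pipeline", {
  tab <- apply_censoring(zone_mean_table(), "zero")
  gm <- colMeans(concentration_matrix(tab))
  specs <- lapply(gm, function(v) dist_spec("point", value = v))
  res <- run_probabilistic_risk(specs, default_exposure_specs(point = TRUE),
                                mode = "paper_compat",
                                config = mc_config(iterations = 50, seed = 2))
  expect_equal(unique(res$samples$teq), compute_teq(gm))
  expect_equal(unique(res$samples$ilcr),
               compute_ilcr(compute_teq(gm), exposure_params("paper_compat")))
  expect_equal(res$summary$sd, c(0, 0))
})

test_that("moment-matched lognormal specs preserve the mean TEQ", {
  det <- compute_teq(grand_mean_vector("zero"))
  specs <- concentration_specs(apply_censoring(zone_mean_table(), "zero"),
                               cv = 0.5)
  res <- run_probabilistic_risk(specs, default_exposure_specs(point = TRUE),
                                config = mc_config(iterations = 1e5,
                                                   seed = 3))
  expect_lt(abs(res$summary$mean[res$summary$output == "teq"] / det - 1),
            0.02)
})

test_that("ILCR percentiles are TEQ percentiles times the constant factor", {
  specs <- concentration_specs(zone_mean_table(), cv = 0.4)
  res <- run_probabilistic_risk(specs, default_exposure_specs(point = TRUE),
                                config = mc_config(iterations = 2e4,
                                                   seed = 7))
  s <- res$summary
  qcols <- grep("^p", names(s), value = TRUE)
  expect_equal(as.numeric(s[s$output == "ilcr", qcols]),
               as.numeric(s[s$output == "teq", qcols]) * paper_compat_factor)
})

test_that("missing specs are rejected", {
  specs <- concentration_specs(zone_mean_table())
  expect_error(run_probabilistic_risk(specs[-1]), "NAP")
  expect_error(run_probabilistic_risk(specs, exposure_specs = list()), "IR")
})

test_that("contribution to variance follows the Crystal Ball convention", {
  n <- 5000
  set.seed(10)
  only <- cbind(X = rnorm(n, 10, 2), K = rep(1, n))
  out <- only[, "X"]
  s <- contribution_to_variance(only, out)
  expect_equal(s$contribution_pct[s$input == "X"], 100)
  expect_equal(s$contribution_pct[s$input == "K"], 0)
  expect_true(s$constant[s$input == "K"])

  # analytic shares 1:4 for independent additive normals
  set.seed(11)
  m <- cbind(A = rnorm(1e5, sd = 1), B = rnorm(1e5, sd = 2))
  s2 <- contribution_to_variance(m, m[, "A"] + m[, "B"])
  expect_equal(s2$contribution_pct[s2$input == "A"], 20, tolerance = 3 / 20)
  expect_equal(s2$contribution_pct[s2$input == "B"], 80, tolerance = 3 / 80)
  expect_equal(sum(abs(s2$contribution_pct)), 100)

  # negative driver gets a signed share
  s3 <- contribution_to_variance(m, m[, "A"] - m[, "B"])
  expect_lt(s3$contribution_pct[s3$input == "B"], 0)
  expect_equal(sum(abs(s3$contribution_pct)), 100)

  expect_error(contribution_to_variance(m, rep(1, 1e5)), "constant")
  expect_error(contribution_to_variance(m[1:2, ], 1:2), "3 rows")
})

test_that("contribution shares are invariant under monotone input maps", {
  set.seed(12)
  m <- cbind(A = rlnorm(2e4), B = rlnorm(2e4, sdlog = 1.5))
  out <- m[, "A"] + m[, "B"]
  s1 <- contribution_to_variance(m, out)
  warped <- cbind(A = log(m[, "A"]), B = m[, "B"]^3)
  s2 <- contribution_to_variance(warped, out)
  expect_equal(s1$contribution_pct, s2$contribution_pct)
})

test_that("synthetic-study sensitivity ranks BaP first and BaA second", {
  tab <- generate_synthetic_study(study_design(), default_paper_model(),
                                  seed = 11)
  specs <- concentration_specs(tab)  # moments of the drawn concentrations
  res <- run_probabilistic_risk(specs, default_exposure_specs(point = TRUE),
                                config = mc_config(iterations = 2e4,
                                                   seed = 11))
  sens <- contribution_to_variance(res$inputs, res$samples$teq)
  sens <- sens[!sens$constant, ]
  expect_equal(sens$input[1:2], c("BaP", "BaA"))
})
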