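#' Default exposure-parameter distributions
#'
#' Uncertainty model for the exposure constants: intake rate IR lognormal
#' with mean 0.23 kg/day and 25% CV, body weight BW normal(70, 7) kg
#' truncated at zero by resampling, exposure frequency EF uniform(350, 365)
#' days/year, exposure duration ED uniform(60, 70) years, averaging time AT
#' fixed at 25550 days. The survey reports the distribution families but no
#' dispersion parameters, so these spreads are this package's defaults
#' (documented in the methods vignette) and freely overridable.
#'
#' @param point If `TRUE`, return all parameters as point masses at their
#'   central values (a degenerate, fully deterministic exposure model).
#' @return Named list of [dist_spec] objects for IR, EF, ED, BW, AT.
#' @export
default_exposure_specs <- function(point = FALSE) {
  if (point)
    return(list(IR = dist_spec("point", value = 0.23),
                EF = dist_spec("point", value = 365),
                ED = dist_spec("point", value = 70),
                BW = dist_spec("point", value = 70),
                AT = dist_spec("point", value = 25550)))
  list(IR = dist_spec("lognormal", mean = 0.23, sd = 0.25 * 0.23),
       EF = dist_spec("uniform", low = 350, high = 365),
       ED = dist_spec("uniform", low = 60, high = 70),
       BW = dist_spec("normal", mean = 70, sd = 7),
       AT = dist_spec("point", value = 25550))
}

#' Lognormal concentration specs from a concentration table
#'
#' Builds one moment-matched lognormal spec per congener from the per-sample
#' values of a table (mean and SD over samples). Congeners whose mean or SD
#' is zero (e.g. all-censored non-detects) become point masses. By default
#' moments are taken from the values as stored (`policy = "raw"`): fitting a
#' lognormal to zero-substituted data biases congeners that sit near their
#' detection limit, so ND substitution is better left to the deterministic
#' summaries.
#'
#' @param table A [concentration_table].
#' @param policy `"raw"` (use stored values) or a censoring policy applied
#'   before computing moments, see [apply_censoring()].
#' @param cv Optional fixed coefficient of variation overriding the
#'   empirical SDs.
#' @return Named list of [dist_spec] objects, one per registry congener.
#' @export
concentration_specs <- function(table, policy = "raw", cv = NULL) {
  if (!identical(policy, "raw")) table <- apply_censoring(table, policy)
  m <- concentration_matrix(table)
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  if (!is.null(cv)) sd <- cv * mu
  specs <- lapply(seq_along(mu), function(i) {
    if (mu[i] <= 0) dist_spec("point", value = 0)
    else if (is.na(sd[i]) || sd[i] <= 0) dist_spec("point", value = mu[i])
    else dist_spec("lognormal", mean = mu[i], sd = sd[i])
  })
  names(specs) <- names(mu)
  specs
}

#' Probabilistic TEQ and cancer-risk propagation
#'
#' Runs the full risk model per Monte Carlo iteration: sampled congener
#' concentrations are TEF-weighted into a TEQ, then pushed through the ILCR
#' dose equation with the sampled exposure parameters and the chosen
#' constant set. With all-point specs the sampled outputs equal the
#' deterministic pipeline values exactly.
#'
#' @param conc_specs Named list of [dist_spec], one per registry congener
#'   (point 0 allowed for non-detects).
#' @param exposure_specs Named list of [dist_spec] for `IR`, `EF`, `ED`,
#'   `BW`, `AT`.
#' @param registry Congener registry.
#' @param mode Constant set for CSF/CF, see [exposure_params()].
#' @param config An [mc_config].
#' @return An object of class `mc_result`: list with `samples` (data.frame
#'   of per-iteration `teq` and `ilcr`), `summary` (mean, sd, percentiles
#'   per output), `inputs` (the sampled input matrix), `config` and `mode`.
#' @examples
#' specs <- concentration_specs(zone_mean_table())
#' res <- run_probabilistic_risk(specs, default_exposure_specs(point = TRUE),
#'                               config = mc_config(iterations = 1000))
#' res$summary
#' @export
run_probabilistic_risk <- function(conc_specs,
                                   exposure_specs = default_exposure_specs(),
                                   registry = pah_registry(),
                                   mode = "paper_compat",
                                   config = mc_config()) {
  missing <- setdiff(registry$id, names(conc_specs))
  if (length(missing))
    stop("missing concentration spec(s): ", paste(missing, collapse = ", "))
  missing_e <- setdiff(c("IR", "EF", "ED", "BW", "AT"), names(exposure_specs))
  if (length(missing_e))
    stop("missing exposure spec(s): ", paste(missing_e, collapse = ", "))
  conc_specs <- conc_specs[registry$id]

  inputs <- sample_inputs(c(conc_specs, exposure_specs), config)
  consts <- exposure_params(mode)
  conc <- inputs[, registry$id, drop = FALSE]
  teq <- compute_teq(conc, registry)
  ilcr <- teq * inputs[, "IR"] * inputs[, "EF"] * inputs[, "ED"] *
    consts$csf * consts$cf / (inputs[, "BW"] * inputs[, "AT"])

  samples <- data.frame(teq = teq, ilcr = ilcr)
  summ <- do.call(rbind, lapply(names(samples), function(v) {
    x <- samples[[v]]
    q <- stats::quantile(x, probs = config$percentiles / 100, names = FALSE)
    row <- data.frame(output = v, mean = mean(x), sd = stats::sd(x))
    for (i in seq_along(config$percentiles))
      row[[sprintf("p%.4g", config$percentiles[i])]] <- q[i]
    row
  }))
  structure(list(samples = samples, summary = summ, inputs = inputs,
                 config = config, mode = mode),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %d iterations, seed %d, mode %s\n",
              x$config$iterations, x$config$seed, x$mode))
  print.data.frame(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Contribution-to-variance sensitivity analysis
#'
#' Ranks model inputs by their signed share of output uncertainty: for each
#' input, the Spearman rank correlation r_i with the output is computed and
#' the contribution is sign(r_i) * 100 * r_i^2 / sum_j r_j^2, so absolute
#' contributions sum to 100%. Shares are invariant under any strictly
#' increasing transform of an input (rank-based). Constant inputs get
#' contribution 0 and are flagged.
#'
#' @param inputs Numeric matrix (iterations x inputs) with column names.
#' @param output Numeric vector, one value per row of `inputs`.
#' @return A data.frame of class `sensitivity_result` with columns `input`,
#'   `rank_correlation`, `contribution_pct`, `constant`, sorted by
#'   decreasing absolute contribution.
#' @examples
#' set.seed(1)
#' a <- rnorm(5000); b <- rnorm(5000, sd = 2)
#' contribution_to_variance(cbind(A = a, B = b), a + b)
#' @export
contribution_to_variance <- function(inputs, output) {
  stopifnot(is.matrix(inputs), !is.null(colnames(inputs)))
  if (nrow(inputs) != length(output))
    stop("inputs and output must have the same number of rows")
  if (nrow(inputs) < 3) stop("need at least 3 rows")
  if (stats::sd(output) == 0) stop("output is constant; nothing to attribute")
  constant <- apply(inputs, 2, function(x) stats::sd(x) == 0)
  r <- rep(0, ncol(inputs))
  r[!constant] <- suppressWarnings(
    apply(inputs[, !constant, drop = FALSE], 2, stats::cor, y = output,
          method = "spearman"))
  denom <- sum(r^2)
  contrib <- if (denom > 0) sign(r) * 100 * r^2 / denom else r * 0
  out <- data.frame(input = colnames(inputs), rank_correlation = r,
                    contribution_pct = contrib, constant = constant,
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$contribution_pct)), ]
  rownames(out) <- NULL
  class(out) <- c("sensitivity_result", class(out))
  out
}
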