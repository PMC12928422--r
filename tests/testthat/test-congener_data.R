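test_that("registry carries the study's TEF groups and QC limit structure", {
  reg <- pah_registry()
  expect_equal(nrow(reg), 16)
  expect_setequal(unique(reg$tef), c(0.001, 0.01, 0.1, 1))
  expect_equal(reg$loq, 3 * reg$lod)
  expect_true(all(reg$rings >= 2 & reg$rings <= 6))
  expect_true(all(reg$lod > 0))
  # light/heavy partition: 7 congeners with 2-3 rings, 9 with 4-6
  expect_equal(sum(reg$rings <= 3), 7)
  # the two reference carcinogens carry TEF 1
  expect_equal(reg$id[reg$tef == 1], c("BaP", "DhA"))
})

test_that("registry round-trips through CSV and YAML", {
  reg <- pah_registry()
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write.csv(reg, csv, row.names = FALSE)
  yaml::write_yaml(setNames(lapply(seq_len(nrow(reg)), function(i)
    list(name = reg$name[i], rings = reg$rings[i], tef = reg$tef[i],
         lod = reg$lod[i], loq = reg$loq[i])), reg$id), yml)
  expect_equal(read_registry(csv), reg)
  expect_equal(read_registry(yml), reg)
})

test_that("shipped fixtures agree with the built-in tables", {
  ext <- function(f) system.file("extdata", f, package = "pahrisk")
  expect_equal(read_registry(ext("pah_registry.csv")), pah_registry())
  expect_equal(read_registry(ext("pah_registry.yaml")), pah_registry())
  qc <- read.csv(ext("method_qc.csv"))
  expect_equal(qc, method_qc_table())
  tab <- read_concentration_table(ext("zone_means_long.csv"))
  expect_equal(concentration_matrix(apply_censoring(tab, "zero")),
               concentration_matrix(apply_censoring(zone_mean_table(),
                                                    "zero")))
})

test_that("long-format loading flags ND and below-LOD values as censored", {
  path <- write_long_csv(tiny_long(), withr::local_tempfile(fileext = ".csv"))
  tab <- read_concentration_table(path)
  d <- tab$data
  # explicit ND rows load as censored with raw 0
  expect_true(all(d$censored[d$congener == "DhA"]))
  expect_equal(d$value[d$congener == "DhA"], c(0, 0))
  # 0.01 < BaP LOD 0.063 -> censored even without a flag
  expect_true(d$censored[d$sample_id == "b" & d$congener == "BaP"])
  expect_false(d$censored[d$sample_id == "a" & d$congener == "BaP"])
  # congeners absent from the file are filled in as censored
  expect_equal(sum(d$sample_id == "a"), 16)
  expect_true(all(d$censored[!d$congener %in% c("NAP", "BaP")]))
})

test_that("zone-mean fixture has 8 samples and 24 censored entries", {
  tab <- zone_mean_table()
  expect_equal(length(unique(tab$data$sample_id)), 8)
  expect_equal(sum(tab$data$censored), 24)
  expect_setequal(unique(tab$data$congener[tab$data$censored]),
                  c("IP", "DhA", "BghiP"))
})

test_that("an empty file with a valid header loads as an empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("sample_id,zone,method,bread_type,replicate,congener,",
                   "value,censored", sep = ""), path)
  tab <- read_concentration_table(path)
  expect_equal(nrow(tab$data), 0)
})

test_that("values exactly at the LOD are detections (strict censoring)", {
  reg <- pah_registry()
  df <- data.frame(sample_id = "s1", zone = 1L, method = "traditional",
                   bread_type = "Lavash", replicate = 1L,
                   congener = reg$id, value = as.character(reg$lod),
                   censored = "", stringsAsFactors = FALSE)
  # wide format: one row per sample, one column per congener
  wide <- cbind(df[1, 1:5],
                as.data.frame(as.list(setNames(reg$lod, reg$id))))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, path, row.names = FALSE, quote = FALSE)
  tab <- read_concentration_table(path, format = "wide")
  expect_equal(sum(tab$data$censored), 0)
})

test_that("malformed inputs are rejected with informative errors", {
  df <- tiny_long()
  bad <- df; bad$congener[1] <- "XYZ"
  expect_error(concentration_table(bad), "XYZ")
  neg <- df; neg$value[1] <- -1
  expect_error(concentration_table(neg), "negative")
  dup <- rbind(df, df[1, ])
  expect_error(concentration_table(dup), "duplicate")
  vocab <- df; vocab$method[1] <- "microwave"
  expect_error(concentration_table(vocab), "method")
})

test_that("censoring substitution follows the policy and is idempotent", {
  path <- write_long_csv(tiny_long(), withr::local_tempfile(fileext = ".csv"))
  tab <- read_concentration_table(path)
  val <- function(t, sid, cong)
    t$data$value[t$data$sample_id == sid & t$data$congener == cong]

  half <- apply_censoring(tab, "half_lod")
  expect_equal(val(half, "a", "DhA"), 0.093 / 2)
  # NAP filled-in censored entry in neither sample: half of NAP LOD 0.055
  expect_equal(val(half, "a", "ACY"), 0.055 / 2)
  expect_equal(val(apply_censoring(tab, "lod"), "a", "DhA"), 0.093)
  expect_equal(val(apply_censoring(tab, "zero"), "a", "DhA"), 0)
  # uncensored values unchanged
  expect_equal(val(half, "a", "NAP"), 30)
  # idempotent
  expect_equal(apply_censoring(half, "half_lod"), half)
  # monotone: zero <= half_lod <= lod entry-wise
  expect_true(all(apply_censoring(tab, "zero")$data$value <=
                    half$data$value))
  expect_true(all(half$data$value <=
                    apply_censoring(tab, "lod")$data$value))
})

test_that("tables round-trip through write/read exactly", {
  tab <- generate_synthetic_study(study_design(zones = 2, replicates = 1),
                                  default_paper_model(), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_concentration_table(tab, path)
  back <- read_concentration_table(path)
  expect_equal(back$data$value, tab$data$value)
  expect_equal(back$data$censored, tab$data$censored)
  expect_equal(back$data[1:6], tab$data[1:6])
})

test_that("method QC validation checks ratios, recovery, RSD and R2", {
  rep <- validate_method_table(method_qc_table(), pah_registry(),
                               recovery_limits = c(70, 120), rsd_max = 15,
                               r2_floor = 0.98)
  expect_true(attr(rep, "overall_pass"))
  expect_true(all(abs(rep$loq_lod_ratio - 3) < 1e-6))

  # oracle: direct per-row scan of the QC fixture at a stricter floor
  qc <- method_qc_table()
  n_fail <- sum(qc$r_squared < 0.99)
  strict <- validate_method_table(qc, r2_floor = 0.99)
  expect_equal(sum(!strict$r2_ok), n_fail)
  expect_equal(sum(!strict$pass), n_fail)

  zero_rec <- qc; zero_rec$recovery_pct[1] <- 0
  bad <- validate_method_table(zero_rec)
  expect_false(bad$recovery_ok[1])
  expect_false(attr(bad, "overall_pass"))

  unknown <- qc; unknown$id[1] <- "XXX"
  expect_error(validate_method_table(unknown), "XXX")
})

test_that("QC report serialises to JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_report(validate_method_table(method_qc_table()), path)
  parsed <- jsonlite::read_json(path)
  expect_true(parsed$overall_pass)
  expect_equal(length(parsed$congeners), 16)
})
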