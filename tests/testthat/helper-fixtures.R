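# Small in-code fixtures shared across test files.

# A minimal 2-sample long-format data.frame covering detections, an explicit
# ND and a value below the LOD.
tiny_long <- function() {
  data.frame(
    sample_id = rep(c("a", "b"), each = 3),
    zone = 1L,
    method = rep(c("traditional", "industrial"), each = 3),
    bread_type = "Lavash",
    replicate = 1L,
    congener = rep(c("NAP", "BaP", "DhA"), 2),
    value = c(30, 0.08, 0, 25, 0.01, 0),
    censored = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Write a long-format CSV for read tests; ND encoded as the literal token.
write_long_csv <- function(df, path) {
  df$value <- ifelse(df$censored & df$value == 0, "ND",
                     as.character(df$value))
  df$censored <- NULL
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Independent scalar-loop TEQ oracle (kept free of the package's vectorised
# path on purpose).
teq_loop_oracle <- function(values, registry) {
  total <- 0
  for (id in names(values)) {
    total <- total + values[[id]] * registry$tef[registry$id == id]
  }
  total
}

paper_compat_factor <- 0.23 * 1 * 0.1 / 70  # IR * CSF * CF / BW, EF*ED/AT = 1

grand_mean_vector <- function(policy = "zero") {
  colMeans(concentration_matrix(apply_censoring(zone_mean_table(), policy)))
}
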