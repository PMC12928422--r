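#' Per-sample, per-congener concentration tables
#'
#' A `concentration_table` bundles a long-format data.frame of measured
#' concentrations (ug/kg) with censoring flags, the congener registry they
#' refer to, and free-text provenance. Required data columns: `sample_id`,
#' `zone`, `method`, `bread_type`, `replicate`, `congener`, `value`,
#' `censored`. Every registry congener is present for every sample; congeners
#' missing from the input are added as censored (non-detect) entries.
#'
#' @param data Long-format data.frame (see Details).
#' @param registry Congener registry data.frame, see [pah_registry()].
#' @param provenance Free-text origin of the data.
#' @return An object of class `concentration_table`: a list with elements
#'   `data`, `registry`, `provenance` and a `policy` attribute recording any
#'   censoring substitution already applied (`"raw"` before any).
#' @export
concentration_table <- function(data, registry = pah_registry(),
                                provenance = "") {
  req <- c("sample_id", "zone", "method", "bread_type", "replicate",
           "congener", "value", "censored")
  missing <- setdiff(req, names(data))
  if (length(missing))
    stop("concentration data is missing columns: ",
         paste(missing, collapse = ", "))
  data <- as.data.frame(data)[req]

  unknown <- setdiff(unique(data$congener), registry$id)
  if (length(unknown))
    stop("unknown congener code(s): ", paste(unknown, collapse = ", "))
  if (any(data$value < 0, na.rm = TRUE))
    stop("negative concentration encountered")
  key <- paste(data$sample_id, data$congener, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, congener) entries: ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  check_vocabulary(data)

  # fill congeners absent from a sample as censored non-detects
  samples <- unique(data$sample_id)
  if (length(samples)) {
    full <- expand.grid(sample_id = samples, congener = registry$id,
                        stringsAsFactors = FALSE)
    miss <- !paste(full$sample_id, full$congener) %in%
      paste(data$sample_id, data$congener)
    if (any(miss)) {
      meta <- data[!duplicated(data$sample_id),
                   c("sample_id", "zone", "method", "bread_type", "replicate")]
      add <- merge(full[miss, ], meta, by = "sample_id", sort = FALSE)
      add$value <- 0
      add$censored <- TRUE
      data <- rbind(data, add[req])
    }
  }
  data <- data[order(data$sample_id, match(data$congener, registry$id)), ]
  rownames(data) <- NULL

  structure(list(data = data, registry = registry, provenance = provenance),
            policy = "raw", class = "concentration_table")
}

study_methods <- c("traditional", "industrial", "mixed")
study_bread_types <- c("Lavash", "Sangak", "Barbari", "mixed")

check_vocabulary <- function(data) {
  bad_m <- setdiff(unique(data$method), study_methods)
  if (length(bad_m))
    stop("unknown baking method(s): ", paste(bad_m, collapse = ", "))
  bad_b <- setdiff(unique(data$bread_type), study_bread_types)
  if (length(bad_b))
    stop("unknown bread type(s): ", paste(bad_b, collapse = ", "))
  if (any(!data$zone %in% 1:8))
    stop("zone must be an integer in 1..8")
  invisible(TRUE)
}

#' @export
print.concentration_table <- function(x, ...) {
  cat(sprintf("<concentration_table> %d samples x %d congeners, %d censored entries (policy: %s)\n",
              length(unique(x$data$sample_id)), nrow(x$registry),
              sum(x$data$censored), attr(x, "policy")))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Read a concentration table from CSV
#'
#' Long format: columns `sample_id`, `zone`, `method`, `bread_type`,
#' `replicate`, `congener`, `value`, `censored`; `value` may be empty or the
#' token `"ND"` for a non-detect (loaded as censored with raw value 0). Wide
#' format: one row per sample with the same metadata columns followed by one
#' column per congener code. Any value strictly below the congener's LOD is
#' flagged censored (a value exactly at the LOD is a detection).
#'
#' @param path CSV file path.
#' @param registry Congener registry.
#' @param format `"long"` or `"wide"`.
#' @return A validated [concentration_table].
#' @export
read_concentration_table <- function(path, registry = pah_registry(),
                                     format = c("long", "wide")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  meta_cols <- c("sample_id", "zone", "method", "bread_type", "replicate")
  if (format == "wide" && nrow(raw)) {
    cong_cols <- setdiff(names(raw), meta_cols)
    raw <- stats::reshape(
      raw, direction = "long", varying = cong_cols, v.names = "value",
      times = cong_cols, timevar = "congener", idvar = "sample_id")
    raw$censored <- ""
  } else if (format == "wide") {
    raw <- data.frame(sample_id = character(), zone = character(),
                      method = character(), bread_type = character(),
                      replicate = character(), congener = character(),
                      value = character(), censored = character())
  }
  missing <- setdiff(c(meta_cols, "congener", "value"), names(raw))
  if (length(missing))
    stop("input file is missing columns: ", paste(missing, collapse = ", "))
  if (is.null(raw$censored)) raw$censored <- ""

  nd <- trimws(raw$value) %in% c("", "ND", "nd")
  val <- suppressWarnings(as.numeric(raw$value))
  if (any(is.na(val) & !nd))
    stop("non-numeric concentration value(s): ",
         paste(unique(raw$value[is.na(val) & !nd]), collapse = ", "))
  val[nd] <- 0
  cens_txt <- tolower(trimws(raw$censored))
  explicit <- cens_txt %in% c("true", "t", "1", "yes", "false", "f", "0",
                              "no")
  flagged <- cens_txt %in% c("true", "t", "1", "yes")
  lod <- registry$lod[match(raw$congener, registry$id)]
  # an explicit censored flag is authoritative (summary rows may legitimately
  # average below the LOD); otherwise ND tokens and values strictly below
  # the congener's LOD are non-detects
  censored <- ifelse(explicit, flagged | nd,
                     nd | (!is.na(lod) & val < lod))

  out <- data.frame(
    sample_id = raw$sample_id,
    zone = as.integer(raw$zone),
    method = raw$method,
    bread_type = raw$bread_type,
    replicate = as.integer(raw$replicate),
    congener = raw$congener,
    value = val,
    censored = censored,
    stringsAsFactors = FALSE
  )
  concentration_table(out, registry, provenance = path)
}

#' Write a concentration table as long-format CSV
#'
#' @param table A [concentration_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(table, path) {
  stopifnot(inherits(table, "concentration_table"))
  out <- table$data
  out$value <- vapply(out$value, format_num, "")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_num <- function(x) {
  # shortest decimal representation that round-trips exactly
  for (d in 1:17) {
    s <- formatC(x, digits = d, format = "g")
    if (as.numeric(s) == x) return(s)
  }
  s
}

#' Substitute below-LOD values under a censoring policy
#'
#' Replaces the working value of every censored entry with the policy
#' substitute: 0 (`zero`), half the congener's detection limit (`half_lod`),
#' or the detection limit itself (`lod`). Detected values are untouched. The
#' operation is idempotent and entry-wise, and the substitute depends only on
#' the registry LOD, so policies can be switched freely on the same table.
#'
#' @param table A [concentration_table].
#' @param policy One of `"zero"`, `"half_lod"`, `"lod"`. The default `zero`
#'   is the convention under which the survey's summary TEQ statistics are
#'   reproduced; `half_lod` is the conventional substitution in dietary
#'   exposure work and remains available.
#' @return A new `concentration_table` with substituted working values; the
#'   applied policy is recorded in the `policy` attribute.
#' @examples
#' tab <- apply_censoring(zone_mean_table(), "half_lod")
#' @export
apply_censoring <- function(table, policy = c("zero", "half_lod", "lod")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "concentration_table"))
  lod <- table$registry$lod[match(table$data$congener, table$registry$id)]
  sub <- switch(policy, zero = rep(0, length(lod)), half_lod = lod / 2,
                lod = lod)
  table$data$value[table$data$censored] <- sub[table$data$censored]
  attr(table, "policy") <- policy
  table
}

#' Concentration matrix view of a table
#'
#' @param table A [concentration_table].
#' @return A numeric samples x congeners matrix of working values, rows named
#'   by `sample_id`, columns ordered as the registry.
#' @export
concentration_matrix <- function(table) {
  stopifnot(inherits(table, "concentration_table"))
  d <- table$data
  ids <- unique(d$sample_id)
  m <- matrix(0, length(ids), nrow(table$registry),
              dimnames = list(ids, table$registry$id))
  m[cbind(match(d$sample_id, ids), match(d$congener, table$registry$id))] <-
    d$value
  m
}

sample_metadata <- function(table) {
  d <- table$data[!duplicated(table$data$sample_id),
                  c("sample_id", "zone", "method", "bread_type", "replicate")]
  rownames(d) <- NULL
  d
}
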