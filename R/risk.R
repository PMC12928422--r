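#' Exposure and dose-equation constants
#'
#' Parameter set for the dietary dose and lifetime cancer risk equations:
#' intake rate IR (kg/day), exposure frequency EF (days/year), exposure
#' duration ED (years), body weight BW (kg), averaging time AT (days), the
#' oral cancer slope factor CSF ((mg/kg/day)^-1) and a unit conversion
#' factor CF. Two named constant sets are provided:
#'
#' * `paper_compat` — CSF = 1, CF = 0.1: the constants under which the
#'   survey's printed TEQ-to-risk pairs are reproduced.
#' * `usepa_standard` — CSF = 7.3 (USEPA oral slope factor for
#'   benzo\[a\]pyrene), CF = 1e-3 (ug to mg).
#'
#' With the default Iranian-adult values (IR 0.23, EF 365, ED 70, BW 70,
#' AT 25550) the time ratio EF*ED/AT equals exactly 1.
#'
#' @param mode Constant-set name, `"paper_compat"` or `"usepa_standard"`.
#' @param ir,ef,ed_years,bw,at_days Exposure constants (see above).
#' @param csf,cf Override the mode's slope factor / conversion factor.
#' @return An object of class `exposure_params`.
#' @export
exposure_params <- function(mode = c("paper_compat", "usepa_standard"),
                            ir = 0.23, ef = 365, ed_years = 70,
                            bw = 70, at_days = 25550,
                            csf = NULL, cf = NULL) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    paper_compat = list(csf = 1, cf = 0.1),
    usepa_standard = list(csf = 7.3, cf = 1e-3))
  if (is.null(csf)) csf <- defaults$csf
  if (is.null(cf)) cf <- defaults$cf
  p <- list(ir = ir, ef = ef, ed_years = ed_years, bw = bw,
            at_days = at_days, csf = csf, cf = cf, mode = mode)
  num <- unlist(p[c("ir", "ef", "ed_years", "bw", "at_days", "csf", "cf")])
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all exposure parameters must be strictly positive")
  structure(p, class = "exposure_params")
}

#' @export
print.exposure_params <- function(x, ...) {
  cat(sprintf(
    "<exposure_params> mode=%s IR=%g kg/d EF=%g d/y ED=%g y BW=%g kg AT=%g d CSF=%g CF=%g\n",
    x$mode, x$ir, x$ef, x$ed_years, x$bw, x$at_days, x$csf, x$cf))
  invisible(x)
}

tef_for <- function(ids, registry) {
  tef <- registry$tef[match(ids, registry$id)]
  if (anyNA(tef))
    stop("congener(s) without a TEF in the registry: ",
         paste(ids[is.na(tef)], collapse = ", "))
  tef
}

#' Toxic equivalent concentration (TEQ) of a congener mixture
#'
#' TEQ = sum_i C_i x TEF_i, expressing a PAH mixture as the equivalent
#' concentration of benzo\[a\]pyrene (ug BaPeq/kg). Linear and additive over
#' congeners.
#'
#' @param values Named non-negative numeric vector of working concentrations
#'   (ug/kg), names = congener ids; or a samples x congeners matrix with
#'   column names, in which case a per-sample TEQ vector is returned.
#' @param registry Congener registry supplying TEFs.
#' @return TEQ in ug BaPeq/kg (scalar, or vector for a matrix input).
#' @examples
#' compute_teq(c(BaP = 0.06, BaA = 0.34), pah_registry())
#' @export
compute_teq <- function(values, registry = pah_registry()) {
  if (is.matrix(values)) {
    if (is.null(colnames(values))) stop("matrix input needs column names")
    if (any(values < 0)) stop("concentrations must be non-negative")
    tef <- tef_for(colnames(values), registry)
    # row-wise weighted sum; fixed summation order keeps identical rows
    # bit-identical (BLAS gemv kernels do not guarantee that)
    return(unname(rowSums(values * rep(tef, each = nrow(values)))))
  }
  if (is.null(names(values)) || !length(values))
    stop("values must be a named numeric vector")
  if (any(values < 0)) stop("concentrations must be non-negative")
  sum(values * tef_for(names(values), registry))
}

#' Daily dietary exposure to BaP-equivalents
#'
#' ED = sum_i TEQ_i x IR_i over food items (ug BaPeq/day). With a single
#' item this is just TEQ x IR.
#'
#' @param teq TEQ concentration(s), ug BaPeq/kg, one per food item.
#' @param ir Matching intake rate(s), kg/day.
#' @return Daily exposure, ug BaPeq/day (scalar).
#' @examples
#' compute_dietary_exposure(0.18, 0.23)
#' @export
compute_dietary_exposure <- function(teq, ir) {
  if (length(teq) != length(ir))
    stop("teq and ir must have matching lengths (one entry per food item)")
  if (any(teq < 0) || any(ir < 0)) stop("teq and ir must be non-negative")
  sum(teq * ir)
}

#' Incremental lifetime cancer risk from a TEQ concentration
#'
#' ILCR = TEQ x IR x EF x ED x CSF x CF / (BW x AT): the probability of an
#' individual developing cancer over a lifetime from the modelled dietary
#' exposure. Linear in TEQ; with the default adult constants the time ratio
#' EF*ED/AT is exactly 1, so ILCR = TEQ x IR x CSF x CF / BW.
#'
#' @param teq TEQ concentration, ug BaPeq/kg (vectorised).
#' @param params An [exposure_params] object.
#' @return Dimensionless lifetime risk, same length as `teq`.
#' @examples
#' compute_ilcr(0.21, exposure_params("paper_compat"))
#' @export
compute_ilcr <- function(teq, params = exposure_params()) {
  stopifnot(inherits(params, "exposure_params"))
  if (any(teq < 0)) stop("teq must be non-negative")
  teq * params$ir * params$ef * params$ed_years * params$csf * params$cf /
    (params$bw * params$at_days)
}

#' Classify a lifetime cancer risk into regulatory bands
#'
#' Below 1e-6: negligible (no action needed); 1e-6 to 1e-4 inclusive:
#' acceptable (monitoring recommended); above 1e-4: high (intervention
#' warranted).
#'
#' @param ilcr Non-negative lifetime risk(s).
#' @return Character vector in `{"negligible", "acceptable", "high"}`.
#' @export
classify_risk <- function(ilcr) {
  if (any(ilcr < 0)) stop("ilcr must be non-negative")
  ifelse(ilcr < 1e-6, "negligible",
         ifelse(ilcr <= 1e-4, "acceptable", "high"))
}

#' Light/heavy congener sums
#'
#' Light PAHs are the 2-3-ring congeners, heavy PAHs the 4-6-ring ones;
#' their sums partition the total mixture concentration.
#'
#' @param values Named working-concentration vector (ug/kg).
#' @param registry Congener registry supplying ring counts.
#' @return Named numeric `c(l_pahs, h_pahs, total)`.
#' @export
light_heavy_sums <- function(values, registry = pah_registry()) {
  rings <- registry$rings[match(names(values), registry$id)]
  if (anyNA(rings))
    stop("congener(s) without ring counts: ",
         paste(names(values)[is.na(rings)], collapse = ", "))
  l <- sum(values[rings <= 3])
  h <- sum(values[rings >= 4])
  c(l_pahs = l, h_pahs = h, total = l + h)
}

#' Group-level summary statistics of a concentration table
#'
#' For each group (level of a metadata field, or the whole table): the
#' per-congener mean and SD of working values, the total / light / heavy
#' sums of the group-mean vector, the TEQ of the group-mean vector (equal,
#' by linearity, to the mean of per-sample TEQs), and the sample SD of
#' per-sample TEQs.
#'
#' @param table A [concentration_table].
#' @param by Grouping key: `"zone"`, `"method"`, `"bread_type"`, or
#'   `"overall"`.
#' @param policy Censoring policy applied before summarising.
#' @return A list of class `group_summary` with `groups` (one row per group:
#'   `group`, `n`, `total_pahs`, `l_pahs`, `h_pahs`, `teq`, `teq_sd`) and
#'   `congeners` (group x congener `mean` and `sd`).
#' @examples
#' group_summary(zone_mean_table(), by = "zone")$groups
#' @export
group_summary <- function(table, by = c("overall", "zone", "method",
                                        "bread_type"),
                          policy = "zero") {
  by <- match.arg(by)
  table <- apply_censoring(table, policy)
  m <- concentration_matrix(table)
  meta <- sample_metadata(table)
  key <- if (by == "overall") rep("overall", nrow(meta)) else
    as.character(meta[[by]][match(rownames(m), meta$sample_id)])
  groups <- split(seq_len(nrow(m)), key)
  empty <- lengths(groups) == 0
  if (any(empty)) {
    warning("dropping empty group(s): ",
            paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }

  cong <- do.call(rbind, lapply(names(groups), function(g) {
    sub <- m[groups[[g]], , drop = FALSE]
    data.frame(group = g, congener = colnames(sub),
               mean = colMeans(sub), sd = apply(sub, 2, stats::sd),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  cong$sd[is.na(cong$sd)] <- 0

  rows <- lapply(names(groups), function(g) {
    sub <- m[groups[[g]], , drop = FALSE]
    mu <- colMeans(sub)
    lh <- light_heavy_sums(mu, table$registry)
    teqs <- compute_teq(sub, table$registry)
    data.frame(group = g, n = nrow(sub),
               total_pahs = lh[["total"]], l_pahs = lh[["l_pahs"]],
               h_pahs = lh[["h_pahs"]],
               teq = compute_teq(mu, table$registry),
               teq_sd = if (nrow(sub) > 1) stats::sd(teqs) else 0,
               stringsAsFactors = FALSE)
  })
  out <- list(groups = do.call(rbind, rows), congeners = cong,
              by = by, policy = policy)
  class(out) <- "group_summary"
  out
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> by %s (policy %s)\n", x$by, x$policy))
  print.data.frame(x$groups, row.names = FALSE, digits = 4)
  invisible(x)
}
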