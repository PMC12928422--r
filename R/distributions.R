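#' Declarative input distributions for Monte Carlo propagation
#'
#' A `dist_spec` describes one model input: concentrations are typically
#' lognormal (right-skewed environmental data), body weight normal, exposure
#' frequency/duration uniform, and fixed constants point masses. Lognormal
#' and normal specs are parameterised by their *arithmetic* mean and SD;
#' lognormal draws are moment-matched via [fit_lognormal_moments()].
#'
#' @param family `"lognormal"`, `"normal"`, `"uniform"` or `"point"`.
#' @param mean,sd Arithmetic mean and SD (lognormal/normal families).
#' @param low,high Bounds (uniform family).
#' @param value Fixed value (point family).
#' @param truncate_low Lower truncation floor applied by resampling
#'   (default 0: physical quantities cannot go negative).
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("lognormal", mean = 0.23, sd = 0.0575)
#' dist_spec("uniform", low = 350, high = 365)
#' @export
dist_spec <- function(family = c("lognormal", "normal", "uniform", "point"),
                      mean = NULL, sd = NULL, low = NULL, high = NULL,
                      value = NULL, truncate_low = 0) {
  family <- match.arg(family)
  spec <- switch(family,
    lognormal = {
      stopifnot(is.numeric(mean), is.numeric(sd))
      if (mean <= 0) stop("lognormal requires mean > 0")
      if (sd < 0) stop("sd must be non-negative")
      list(mean = mean, sd = sd)
    },
    normal = {
      stopifnot(is.numeric(mean), is.numeric(sd))
      if (sd < 0) stop("sd must be non-negative")
      list(mean = mean, sd = sd)
    },
    uniform = {
      stopifnot(is.numeric(low), is.numeric(high))
      if (high < low) stop("uniform requires high >= low")
      list(low = low, high = high)
    },
    point = {
      stopifnot(is.numeric(value))
      list(value = value)
    })
  structure(c(list(family = family, truncate_low = truncate_low), spec),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  pars <- x[setdiff(names(x), c("family", "truncate_low"))]
  cat(sprintf("<dist_spec> %s(%s)\n", x$family,
              paste(names(pars), unlist(pars), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Moment-matched lognormal parameters
#'
#' Returns the log-scale parameters of the lognormal distribution whose
#' arithmetic mean and SD equal the inputs: sigma^2 = log(1 + sd^2/mean^2),
#' mu = log(mean) - sigma^2/2. With sd = 0 the fit degenerates to a point
#' mass at `mean` (sigma = 0).
#'
#' @param mean Arithmetic mean (> 0).
#' @param sd Arithmetic standard deviation (>= 0).
#' @return Named numeric `c(meanlog, sdlog)`.
#' @examples
#' fit_lognormal_moments(0.23, 0.0575)
#' @export
fit_lognormal_moments <- function(mean, sd) {
  if (!is.numeric(mean) || mean <= 0) stop("mean must be > 0")
  if (!is.numeric(sd) || sd < 0) stop("sd must be non-negative")
  mean <- unname(mean)
  sd <- unname(sd)
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Monte Carlo run settings
#'
#' @param iterations Number of iterations (default 1e5, the scale at which
#'   the probabilistic results stabilise to well under a percent).
#' @param seed Master seed; every variable's stream is derived from it
#'   deterministically.
#' @param percentiles Summary percentiles (default the empirical 95% interval
#'   plus the median).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(iterations = 1e5, seed = 1,
                      percentiles = c(2.5, 50, 97.5)) {
  stopifnot(iterations >= 1, all(percentiles > 0 & percentiles < 100))
  structure(list(iterations = as.integer(iterations), seed = as.integer(seed),
                 percentiles = percentiles), class = "mc_config")
}

# Deterministic per-variable sub-seed: one master seed, independent streams,
# so adding a variable does not perturb the draws of the others.
variable_seed <- function(seed, name) {
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 1000003
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 7919) %% 2147483629)
}

draw_one <- function(spec, n, seed, name) {
  set.seed(variable_seed(seed, name))
  gen <- switch(spec$family,
    point = function(k) rep(spec$value, k),
    uniform = function(k) if (spec$high == spec$low)
      rep(spec$low, k) else stats::runif(k, spec$low, spec$high),
    normal = function(k) if (spec$sd == 0) rep(spec$mean, k) else
      stats::rnorm(k, spec$mean, spec$sd),
    lognormal = {
      p <- fit_lognormal_moments(spec$mean, spec$sd)
      function(k) if (spec$sd == 0) rep(spec$mean, k) else
        stats::rlnorm(k, p[["meanlog"]], p[["sdlog"]])
    })
  x <- gen(n)
  floor_ <- spec$truncate_low
  if (!is.null(floor_) && !is.na(floor_)) {
    # truncation by resampling, not clipping (clipping distorts moments)
    for (i in 1:1000) {
      bad <- which(x < floor_)
      if (!length(bad)) break
      x[bad] <- gen(length(bad))
    }
    if (any(x < floor_))
      stop("truncation floor unattainable for variable ", name)
  }
  x
}

#' Draw the Monte Carlo input sample matrix
#'
#' Each variable gets its own random stream derived from the master seed, so
#' the draws for a given variable depend only on (seed, name, iterations).
#' Truncation below `truncate_low` is applied by resampling.
#'
#' @param specs Named list of [dist_spec] objects.
#' @param config An [mc_config].
#' @return An iterations x variables numeric matrix with `colnames` =
#'   variable names.
#' @export
sample_inputs <- function(specs, config = mc_config()) {
  stopifnot(length(specs) > 0, !is.null(names(specs)),
            !anyDuplicated(names(specs)))
  ok <- vapply(specs, inherits, TRUE, "dist_spec")
  if (!all(ok))
    stop("not dist_spec objects: ", paste(names(specs)[!ok], collapse = ", "))
  n <- config$iterations
  m <- vapply(names(specs),
              function(nm) draw_one(specs[[nm]], n, config$seed, nm),
              numeric(n))
  if (n == 1) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(specs)))
  m
}

spec_mean <- function(spec) {
  switch(spec$family,
    point = spec$value,
    uniform = (spec$low + spec$high) / 2,
    normal = spec$mean,
    lognormal = spec$mean)
}
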