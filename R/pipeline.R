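#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration for [run_pipeline()]:
#' input table, registry, censoring policy, exposure constant set, grouping
#' keys, and the Monte Carlo section.
#'
#' @param input Path to a long-format concentration CSV, or an existing
#'   [concentration_table] (e.g. from [generate_synthetic_study()]).
#' @param registry Path to a registry file, or a registry data.frame
#'   (default the built-in 16-congener registry).
#' @param policy Censoring policy, see [apply_censoring()].
#' @param mode Exposure constant set, see [exposure_params()].
#' @param group_by Metadata keys to summarise by (besides "overall").
#' @param iterations,seed,percentiles Monte Carlo settings.
#' @param concentration_cv Optional fixed CV for the concentration specs
#'   (default: empirical per-congener SDs of the input table).
#' @param exposure `"stochastic"` (default uncertainty model) or `"point"`.
#' @param out_dir Output directory, or `NULL` for no files.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, registry = NULL,
                            policy = "zero", mode = "paper_compat",
                            group_by = c("zone", "method", "bread_type"),
                            iterations = 1e5, seed = 1,
                            percentiles = c(2.5, 50, 97.5),
                            concentration_cv = NULL,
                            exposure = c("stochastic", "point"),
                            out_dir = NULL) {
  exposure <- match.arg(exposure)
  structure(list(input = input, registry = registry, policy = policy,
                 mode = mode, group_by = group_by, iterations = iterations,
                 seed = seed, percentiles = percentiles,
                 concentration_cv = concentration_cv, exposure = exposure,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [pipeline_config()]; the `mc`
#' sub-map may carry `iterations`, `seed`, `percentiles`,
#' `concentration_cv` and `exposure`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  stopifnot(file.exists(path))
  y <- yaml::read_yaml(path)
  # bare filenames fall back to the package's shipped data
  resolve <- function(p) {
    if (is.character(p) && !file.exists(p)) {
      shipped <- system.file("extdata", p, package = "pahrisk")
      if (nzchar(shipped)) return(shipped)
    }
    p
  }
  y$input <- resolve(y$input)
  y$registry <- resolve(y$registry)
  mc <- if (is.null(y$mc)) list() else y$mc
  args <- list(
    input = y$input,
    registry = y$registry,
    policy = if (is.null(y$policy)) "zero" else y$policy,
    mode = if (is.null(y$mode)) "paper_compat" else y$mode,
    iterations = if (is.null(mc$iterations)) 1e5 else mc$iterations,
    seed = if (is.null(mc$seed)) 1 else mc$seed,
    concentration_cv = mc$concentration_cv,
    exposure = if (is.null(mc$exposure)) "stochastic" else mc$exposure,
    out_dir = y$out_dir)
  if (!is.null(y$group_by)) args$group_by <- unlist(y$group_by)
  if (!is.null(mc$percentiles)) args$percentiles <- unlist(mc$percentiles)
  do.call(pipeline_config, args)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s: %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the end-to-end risk-assessment pipeline
#'
#' Executes load -> censoring -> group summaries -> deterministic TEQ/ILCR
#' per group -> Monte Carlo propagation -> sensitivity analysis, and (when
#' an output directory is configured) writes `results.json`, Table-style
#' CSVs (`group_*.csv`, `congener_means.csv`), `sensitivity.csv` and
#' `run_log.txt`. Fully reproducible for a given configuration; a failure in
#' any stage aborts with a stage-labelled error and removes partial outputs.
#'
#' @param config A [pipeline_config] or path to a YAML config file.
#' @return The results bundle (list of class `risk_bundle`), invisibly when
#'   files are written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  registry <- with_stage("registry", {
    if (is.null(config$registry)) pah_registry()
    else if (is.character(config$registry)) read_registry(config$registry)
    else validate_registry(config$registry)
  })
  table <- with_stage("load", {
    if (inherits(config$input, "concentration_table")) config$input
    else read_concentration_table(config$input, registry)
  })
  table <- with_stage("censor", apply_censoring(table, config$policy))

  params <- exposure_params(config$mode)
  groupings <- unique(c("overall", intersect(config$group_by,
                                             c("zone", "method", "bread_type"))))
  summaries <- with_stage("summaries", {
    out <- lapply(groupings, function(g)
      group_summary(table, by = g, policy = config$policy))
    names(out) <- groupings
    out
  })
  deterministic <- with_stage("deterministic", {
    do.call(rbind, lapply(groupings, function(g) {
      s <- summaries[[g]]$groups
      data.frame(grouping = g, group = s$group, n = s$n, teq = s$teq,
                 teq_sd = s$teq_sd,
                 ilcr = compute_ilcr(s$teq, params),
                 band = classify_risk(compute_ilcr(s$teq, params)),
                 stringsAsFactors = FALSE)
    }))
  })

  mc <- with_stage("montecarlo", {
    run_probabilistic_risk(
      conc_specs = concentration_specs(table, config$policy,
                                       cv = config$concentration_cv),
      exposure_specs = default_exposure_specs(
        point = identical(config$exposure, "point")),
      registry = registry, mode = config$mode,
      config = mc_config(config$iterations, config$seed,
                         config$percentiles))
  })
  sensitivity <- with_stage("sensitivity", {
    # degenerate runs (all-point inputs, or too few iterations) have no
    # variance to attribute; the report marks the section "not computed"
    if (nrow(mc$inputs) < 3 || stats::sd(mc$samples$ilcr) == 0) NULL
    else contribution_to_variance(mc$inputs, mc$samples$ilcr)
  })

  overall <- summaries$overall$congeners
  bap <- overall$mean[overall$congener == "BaP"]
  pah4 <- sum(overall$mean[overall$congener %in% c("BaA", "CHR", "BbF", "BaP")])
  eu <- list(bap_mean = bap, bap_limit = 1, bap_compliant = bap <= 1,
             pah4_sum = pah4, pah4_limit = 1, pah4_compliant = pah4 <= 1)

  bundle <- structure(list(
    deterministic = deterministic, summaries = summaries,
    mc_summary = mc$summary, sensitivity = sensitivity, eu_limits = eu,
    settings = list(policy = config$policy, mode = config$mode,
                    iterations = config$iterations, seed = config$seed,
                    exposure = config$exposure,
                    version = as.character(utils::packageVersion("pahrisk"))),
    mc = mc), class = "risk_bundle")

  if (!is.null(config$out_dir))
    write_bundle(bundle, config$out_dir)
  invisible(bundle)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  on_fail <- function(e) {
    unlink(written)
    stop(sprintf("stage write: %s", conditionMessage(e)), call. = FALSE)
  }
  tryCatch({
    emit <- function(name, fun) {
      path <- file.path(out_dir, name)
      written <<- c(written, path)
      fun(path)
      path
    }
    sens_df <- if (is.null(bundle$sensitivity)) NULL else
      as.data.frame(unclass(bundle$sensitivity))
    emit("results.json", function(p) jsonlite::write_json(
      list(settings = bundle$settings,
           deterministic = bundle$deterministic,
           mc_summary = bundle$mc_summary,
           sensitivity = sens_df,
           eu_limits = bundle$eu_limits),
      p, auto_unbox = TRUE, digits = NA, dataframe = "rows"))
    for (g in names(bundle$summaries)) {
      s <- bundle$summaries[[g]]
      emit(sprintf("group_%s.csv", g), function(p)
        utils::write.csv(s$groups, p, row.names = FALSE))
    }
    emit("congener_means.csv", function(p)
      utils::write.csv(bundle$summaries$overall$congeners, p,
                       row.names = FALSE))
    if (!is.null(sens_df))
      emit("sensitivity.csv", function(p)
        utils::write.csv(sens_df, p, row.names = FALSE))
    emit("run_log.txt", function(p) writeLines(c(
      sprintf("pahrisk %s", bundle$settings$version),
      sprintf("censoring policy: %s", bundle$settings$policy),
      sprintf("exposure mode: %s", bundle$settings$mode),
      sprintf("exposure uncertainty: %s", bundle$settings$exposure),
      sprintf("mc iterations: %d", as.integer(bundle$settings$iterations)),
      sprintf("mc seed: %d", as.integer(bundle$settings$seed))), p))
  }, error = on_fail)
  invisible(out_dir)
}

fmt_sig1 <- function(x) formatC(signif(x, 1), format = "g")

#' Render a results bundle as a human-readable report
#'
#' Markdown summary of the deterministic group results (display rounding:
#' concentrations and TEQ to 2 decimals, risks to one significant figure —
#' the bundle retains full precision), the probabilistic section, EU-limit
#' compliance flags (benzo\[a\]pyrene and the PAH4 sum against 1 ug/kg), and
#' the sensitivity ranking. Sections absent from the bundle are rendered
#' with an explicit "not computed" marker.
#'
#' @param bundle A `risk_bundle` from [run_pipeline()] (possibly partial).
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  lines <- c("# PAH dietary risk report", "")
  lines <- c(lines, "## Deterministic risk by group", "")
  if (is.null(bundle$deterministic)) {
    lines <- c(lines, "not computed", "")
  } else {
    d <- bundle$deterministic
    lines <- c(lines,
      "| grouping | group | n | TEQ (ug BaPeq/kg) | ILCR | band |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %s | %d | %.2f | %s | %s |",
              d$grouping, d$group, d$n, d$teq, fmt_sig1(d$ilcr), d$band),
      "")
  }
  lines <- c(lines, "## Probabilistic (Monte Carlo) summary", "")
  if (is.null(bundle$mc_summary)) {
    lines <- c(lines, "not computed", "")
  } else {
    s <- bundle$mc_summary
    qcols <- grep("^p", names(s), value = TRUE)
    lines <- c(lines, sprintf(
      "- %s: mean %s, sd %s, percentiles (%s) = %s",
      s$output, fmt_sig1(s$mean), fmt_sig1(s$sd),
      paste(sub("^p", "", qcols), collapse = "/"),
      apply(s[qcols], 1, function(r)
        paste(fmt_sig1(as.numeric(r)), collapse = " / "))), "")
  }
  lines <- c(lines, "## EU regulatory limits", "")
  if (is.null(bundle$eu_limits)) {
    lines <- c(lines, "not computed", "")
  } else {
    eu <- bundle$eu_limits
    lines <- c(lines,
      sprintf("- BaP mean %.2f ug/kg vs limit %g ug/kg: %s", eu$bap_mean,
              eu$bap_limit,
              if (eu$bap_compliant) "compliant" else "EXCEEDS LIMIT"),
      sprintf("- PAH4 sum %.2f ug/kg vs limit %g ug/kg: %s", eu$pah4_sum,
              eu$pah4_limit,
              if (eu$pah4_compliant) "compliant" else "EXCEEDS LIMIT"),
      "")
  }
  lines <- c(lines, "## Sensitivity (contribution to variance)", "")
  if (is.null(bundle$sensitivity)) {
    lines <- c(lines, "not computed", "")
  } else {
    s <- utils::head(bundle$sensitivity, 10)
    lines <- c(lines, sprintf("- %s: %+.1f%%", s$input, s$contribution_pct),
               "")
  }
  lines
}
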