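#' Run the analysis pipeline end to end
#'
#' Orchestrates one pass of the pipeline: acquire a trace (simulate one
#' from a molecule specification, or read an existing file), convert FDC to
#' FEC with the trap correction, reduce to the analysis bandwidth, fit the
#' requested elasticity model over the force window, optionally run the
#' secondary-structure analysis, and write all artifacts. All randomness
#' flows from the single config seed; identical configs yield identical
#' artifacts. Progress is logged to stderr; results go to files.
#'
#' The config is a named list (or a path to a JSON/YAML file with the same
#' structure). Recognised fields, with defaults in parentheses:
#'
#' * `outdir` - output directory (required)
#' * `seed` (1), `model` ("wlc"), `fmin` (10), `fmax` (40),
#'   `stiffness` (0.07), `bandwidth` (2)
#' * `salt_type` ("monovalent"), `concentration` (1000)
#' * `input` - path of a trace to analyse; if absent, a trace is simulated
#'   from `simulate`: a list with `elastic` (list: `model` plus its
#'   parameters), optional `ss` (`fc`, `delta`, `x0`), `noise_sd` (0.5),
#'   `n_bases` (13650), `speed` (30), `rate` (200)
#' * `fixed` - named list of parameters to hold fixed in the fit
#' * `ss_analyze` (TRUE when the model is "wlc") - run the
#'   effective-contour-length / unpaired-fraction analysis
#'
#' @param config Named list or path to a JSON/YAML config file.
#' @return Invisibly, a list with `status` (0 on success), the fit, the
#'   secondary-structure fit (or NULL) and the artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- .load_config(config)
  for (field in c("outdir"))
    if (is.null(cfg[[field]]))
      stop("config error: missing field '", field, "'")
  cfg <- utils::modifyList(
    list(seed = 1L, model = "wlc", fmin = 10, fmax = 40, stiffness = 0.07,
         bandwidth = 2, salt_type = "monovalent", concentration = 1000,
         fixed = list(), ss_analyze = NULL),
    cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  cond <- conditions(cfg$salt_type, cfg$concentration)
  trap <- trap_model(cfg$stiffness)
  log_msg <- function(stage, ...) message("[saltfec:", stage, "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  artifacts <- list()

  curve <- stage("acquire", {
    if (!is.null(cfg$input)) {
      log_msg("acquire", "reading ", cfg$input)
      read_curve(cfg$input)
    } else {
      if (is.null(cfg$simulate))
        stop("config error: need either 'input' or 'simulate'")
      sim <- utils::modifyList(
        list(noise_sd = 0.5, n_bases = 13650, speed = 30, rate = 200,
             fmin = 0.5, fmax = 40),
        cfg$simulate)
      el <- sim$elastic
      params <- .make_elastic_params(el$model,
                                     el[setdiff(names(el), "model")])
      spec <- molecule_spec(params, n_bases = sim$n_bases, ss = sim$ss,
                            trap = trap)
      log_msg("simulate", "model ", el$model, ", seed ", cfg$seed)
      generate_fec(spec,
                   pulling_protocol(sim$speed, sim$rate, sim$fmin, sim$fmax),
                   noise_model(sim$noise_sd, cfg$seed), cond)
    }
  })

  curve <- stage("convert", {
    if (curve_kind(curve) == "FDC") {
      log_msg("convert", "applying trap correction, k = ", trap$stiffness,
              " pN/nm")
      fdc_to_fec(curve, trap)
    } else curve
  })

  filtered <- stage("filter", {
    log_msg("filter", "boxcar to ", cfg$bandwidth, " Hz")
    bandwidth_filter(curve, cfg$bandwidth)
  })
  artifacts$trace <- file.path(cfg$outdir, "trace.csv")
  write_curve(filtered, artifacts$trace,
              metadata = list(seed = cfg$seed, model = cfg$model,
                              salt_type = cfg$salt_type,
                              concentration_mM = cfg$concentration))

  fit <- stage("fit", {
    log_msg("fit", cfg$model, " over [", cfg$fmin, ", ", cfg$fmax, "] pN")
    fit_model(filtered, cfg$model, fit_window(cfg$fmin, cfg$fmax),
              cond = cond, fixed = cfg$fixed)
  })
  artifacts$fit <- file.path(cfg$outdir, "fit.csv")
  write_report(stats::setNames(list(fit), cfg$model), artifacts$fit)

  ss_fit <- NULL
  do_ss <- cfg$ss_analyze %||% identical(cfg$model, "wlc")
  if (isTRUE(do_ss) && cfg$model == "wlc") {
    ssres <- stage("ss-analyze", {
      log_msg("ss-analyze", "effective contour length and unpaired fraction")
      lce <- suppressWarnings(
        effective_contour_length(filtered, fit$estimate["Lp"], cond = cond))
      frac <- unpaired_fraction(lce, fit$estimate["Lc"], fit$estimate["Lp"])
      sfit <- tryCatch(fit_ss_model(frac), error = function(e) {
        log_msg("ss-analyze", "sigmoid fit skipped: ", conditionMessage(e))
        NULL
      })
      list(frac = frac, sfit = sfit)
    })
    artifacts$fraction <- file.path(cfg$outdir, "fraction.csv")
    utils::write.csv(as.data.frame(ssres$frac), artifacts$fraction,
                     row.names = FALSE, quote = FALSE)
    ss_fit <- ssres$sfit
    if (!is.null(ss_fit)) {
      artifacts$ss <- file.path(cfg$outdir, "ss.json")
      jsonlite::write_json(
        list(estimate = as.list(ss_fit$estimate),
             std_error = as.list(ss_fit$se),
             units = list(fc = "pN", delta = "pN", x0 = "")),
        artifacts$ss, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  log_msg("done", "artifacts in ", cfg$outdir)
  invisible(list(status = 0L, fit = fit, ss_fit = ss_fit,
                 artifacts = artifacts))
}

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config error: no such file: ", config)
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("config error: yaml package required for YAML configs")
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  } else if (is.list(config)) {
    config
  } else stop("config error: config must be a list or a file path")
}
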