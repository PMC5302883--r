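#' Default analysis configuration
#'
#' Hierarchical list of every tunable analysis default: thermal-model
#' parameters, event-detection criteria, spectral-density settings and
#' unmixing ranges. A YAML document with the same structure can override
#' any subset of values; unknown keys are rejected so typos fail loudly.
#'
#' @param overrides Named nested list (or path to a YAML file) of values
#'   overriding the defaults.
#' @return A validated nested list of class `analysis_config`.
#' @export
analysis_config <- function(overrides = NULL) {
  defaults <- list(
    thermal = list(lambda_max = 481, T = 310.5, m = 45,
                   pocket = "closed", A = NULL, constants = "precise"),
    events = list(amplitude_fraction = 0.30, ti_low = 0.5, ti_high = 2.0,
                  counting_filter_hz = 3, epoch_s = 100),
    psd = list(segment_s = 8.192, overlap = 0.5, quiet_s = 60,
               band_low = 0.1, band_high = 5),
    msp = list(baseline_low = 650, baseline_high = 700,
               unmix_low = 510, unmix_high = 750, template_degree = 10),
    n_pigments = 6.5e7,
    seed = 1L
  )
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  cfg <- .merge_config(defaults, overrides, path = "")
  structure(cfg, class = "analysis_config")
}

.merge_config <- function(base, over, path) {
  if (is.null(over)) return(base)
  if (!is.list(over)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(over), names(base))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  for (k in names(over)) {
    if (is.list(base[[k]]) && !is.null(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], over[[k]], paste0(path, ".", k))
    else base[k] <- over[k]
  }
  base
}

#' Run the dark-noise analysis pipeline
#'
#' Executes the requested analysis stages against supplied inputs and
#' returns a machine-readable report. Stages: `"predict"` (thermal-rate
#' prediction from the config's pigment parameters), `"count"` (event
#' detection, counting rate and Poisson epoch fit on a dark trace),
#' `"psd"` (power-spectrum difference rate on the same trace), `"unmix"`
#' (9-cis fraction of a spectrum against a template pair) and
#' `"exchange"` (saturating-exponential fit of a time course).
#'
#' @param config An [analysis_config()] (or overrides accepted by it).
#' @param stages Character vector of stages to run.
#' @param trace A [current_trace()] (for `count` / `psd`).
#' @param spr A [single_photon_response()] (for `count` / `psd`).
#' @param spectrum An [absorbance_spectrum()] (for `unmix`).
#' @param templates A [template_pair()] (for `unmix`).
#' @param timecourse An [exchange_timecourse()] (for `exchange`).
#' @return A list of class `analysis_report` with one entry per stage,
#'   plus `config`, `package_version` and `seed`.
#' @export
run_pipeline <- function(config = analysis_config(),
                         stages = c("predict"),
                         trace = NULL, spr = NULL, spectrum = NULL,
                         templates = NULL, timecourse = NULL) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  known <- c("predict", "count", "psd", "unmix", "exchange")
  if (length(stages) == 0) stop("no stages requested")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  report <- list()
  for (st in stages) {
    message("running stage: ", st)
    report[[st]] <- switch(st,
      predict = {
        th <- config$thermal
        pp <- pigment_params(th$lambda_max, T = th$T, m = th$m,
                             pocket = th$pocket, A = th$A)
        pred <- predict_rate_constant(pp, physical_constants(th$constants))
        list(k_molecular = pred$k_molecular, x = pred$x,
             sum_value = pred$sum_value,
             k_cellular = cellular_rate_from_molecular(
               pred$k_molecular, config$n_pigments))
      },
      count = {
        if (is.null(trace) || is.null(spr))
          stop("stage 'count' needs `trace` and `spr`")
        ec <- event_criteria(config$events$amplitude_fraction,
                             c(config$events$ti_low, config$events$ti_high),
                             config$events$counting_filter_hz)
        ev <- detect_events(trace, spr, ec)
        cr <- counting_rate(ev)
        pf <- poisson_fit(epoch_counts(ev, epoch_length = config$events$epoch_s))
        list(n_events = nrow(ev), counting_rate = cr$rate,
             poisson_w = pf$w, poisson_rate = pf$rate$rate,
             n_epochs = pf$n_epochs)
      },
      psd = {
        if (is.null(trace) || is.null(spr))
          stop("stage 'psd' needs `trace` and `spr`")
        pc <- config$psd
        full <- welch_psd(trace, pc$segment_s, pc$overlap)
        quiet <- welch_psd(select_quiet_segment(trace, pc$quiet_s),
                           pc$segment_s, pc$overlap)
        est <- fit_rate_from_psd(difference_spectrum(full, quiet), spr,
                                 acquisition_s = pc$segment_s,
                                 band = c(pc$band_low, pc$band_high))
        list(psd_rate = est$rate, scale = as.numeric(attr(est, "scale")),
             n_segments = attr(full, "n_segments"))
      },
      unmix = {
        if (is.null(spectrum) || is.null(templates))
          stop("stage 'unmix' needs `spectrum` and `templates`")
        fr <- unmix_fraction(spectrum, templates,
                             range = c(config$msp$unmix_low,
                                       config$msp$unmix_high))
        list(fraction_9cis = as.numeric(fr),
             coefficients = as.list(attr(fr, "coefficients")))
      },
      exchange = {
        if (is.null(timecourse)) stop("stage 'exchange' needs `timecourse`")
        kin <- fit_exchange_kinetics(timecourse)
        list(asymptote = kin$asymptote, tau_min = kin$tau,
             asymptote_se = kin$asymptote_se, tau_se = kin$tau_se)
      }
    )
  }
  structure(
    c(report,
      list(config = unclass(config),
           package_version = as.character(utils::packageVersion("pigmentnoise")),
           seed = config$seed)),
    class = "analysis_report"
  )
}

#' Write an analysis report as JSON
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
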