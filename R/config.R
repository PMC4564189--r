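# Configuration objects for the synthetic flow-stretch experiment and for
# trace analysis.

#' Simulation configuration for a synthetic flow-stretch experiment
#'
#' Parameterizes the tethered-bead primer-extension generator: a primed
#' ssDNA template (default 7,249 nt, the M13mp18 genome) held at ~3 pN,
#' observed at 0.5 s frames with 70 bp positional noise, on which a fast
#' replicative polymerase (Pol III) and a slow translesion polymerase
#' (Pol IV) alternate.  Each molecule alternates pauses (exponential
#' duration, total exit rate = sum of per-species binding rates) and
#' processive synthesis events (log-normal per-event rate; exponential
#' nucleotide extent set by a per-nt termination hazard).  An optional
#' displacement hazard adds a competing per-nt termination risk to active
#' Pol III events, modeling disruption of Pol III synthesis by the Pol IV
#' catalytic domain; setting it to 0 models the inactive T120P variant.
#'
#' Per-event rate medians/geometric SDs and the hazards are not published
#' quantities; the defaults are placeholders chosen well-separated around
#' the 45 bp/s classification cutoff (see the methods vignette).
#'
#' @param template_len template length, nt.
#' @param frame_interval camera frame interval, s.
#' @param noise_sd per-frame positional noise SD, bp.
#' @param force stretching force, pN (metadata unless polymer calibration
#'   is used).
#' @param pol3_rate_median,pol3_rate_gsd log-normal per-event synthesis rate
#'   of the fast polymerase: median (bp/s) and geometric SD (>= 1).
#' @param pol4_rate_median,pol4_rate_gsd same for the slow polymerase.
#' @param pol3_term_hazard,pol4_term_hazard intrinsic per-nt termination
#'   hazard; mean event extent = 1/hazard.
#' @param displacement_hazard additional per-nt hazard on active Pol III
#'   events (0 = no displacement).
#' @param pause_exit_rates named numeric `c(pol3 =, pol4 =)`: per-second
#'   binding rate of each species during a pause; the next event's species
#'   is chosen proportional to these.
#' @param concentrations named numeric, nM; metadata recorded with the run.
#' @param duration observation length, s.
#' @param n_molecules molecules per condition.
#' @param seed integer RNG seed; mandatory for simulation.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(template_len = 7249,
                       frame_interval = 0.5,
                       noise_sd = 70,
                       force = 3.0,
                       pol3_rate_median = 150, pol3_rate_gsd = 1.4,
                       pol4_rate_median = 10, pol4_rate_gsd = 1.4,
                       pol3_term_hazard = 1 / 1200,
                       pol4_term_hazard = 1 / 350,
                       displacement_hazard = 0,
                       pause_exit_rates = c(pol3 = 0.05, pol4 = 0),
                       concentrations = c(pol3 = 5, beta = 30,
                                          clamp_loader = 15, pol4 = 0),
                       duration = 100,
                       n_molecules = 50,
                       seed = NULL) {
  cfg <- list(template_len = template_len, frame_interval = frame_interval,
              noise_sd = noise_sd, force = force,
              pol3_rate_median = pol3_rate_median, pol3_rate_gsd = pol3_rate_gsd,
              pol4_rate_median = pol4_rate_median, pol4_rate_gsd = pol4_rate_gsd,
              pol3_term_hazard = pol3_term_hazard,
              pol4_term_hazard = pol4_term_hazard,
              displacement_hazard = displacement_hazard,
              pause_exit_rates = pause_exit_rates,
              concentrations = concentrations,
              duration = duration, n_molecules = n_molecules, seed = seed)
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  num1 <- function(nm, min = 0, strict = FALSE) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("sim_config: '", nm, "' must be a single finite number")
    if (strict && v <= min) stop("sim_config: '", nm, "' must be > ", min)
    if (!strict && v < min) stop("sim_config: '", nm, "' must be >= ", min)
    v
  }
  num1("template_len", 0, strict = TRUE)
  num1("frame_interval", 0, strict = TRUE)
  num1("noise_sd"); num1("force")
  num1("pol3_rate_median", 0, strict = TRUE)
  num1("pol4_rate_median", 0, strict = TRUE)
  num1("pol3_rate_gsd", 1); num1("pol4_rate_gsd", 1)
  num1("pol3_term_hazard"); num1("pol4_term_hazard")
  num1("displacement_hazard")
  num1("duration", 0, strict = TRUE)
  num1("n_molecules", 0, strict = TRUE)
  if (cfg$pol3_rate_median <= cfg$pol4_rate_median)
    stop("sim_config: pol3_rate_median must exceed pol4_rate_median ",
         "(fast/slow identity is meaningful)")
  per <- cfg$pause_exit_rates
  if (!is.numeric(per) || is.null(names(per)) ||
      !all(names(per) %in% c("pol3", "pol4")))
    stop("sim_config: pause_exit_rates must be a named numeric vector ",
         "with names in c('pol3','pol4')")
  if (any(per < 0) || any(!is.finite(per) & !is.infinite(per)))
    stop("sim_config: pause_exit_rates must be non-negative")
  if (sum(per) <= 0) stop("sim_config: total pause exit rate must be > 0")
  if (any(cfg$concentrations < 0))
    stop("sim_config: concentrations must be non-negative")
  if (!is.null(cfg$seed)) {
    if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
      stop("sim_config: seed must be a single integer")
    cfg$seed <- as.integer(cfg$seed)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:",
      sprintf("%d nt template, %d molecules x %.0f s at %.2g s frames",
              as.integer(x$template_len), as.integer(x$n_molecules),
              x$duration, x$frame_interval), "\n")
  cat(sprintf("  noise %.3g bp; pol3 %.3g bp/s (gsd %.3g, hazard %.3g/nt)\n",
              x$noise_sd, x$pol3_rate_median, x$pol3_rate_gsd,
              x$pol3_term_hazard))
  cat(sprintf("  pol4 %.3g bp/s (gsd %.3g, hazard %.3g/nt); displacement %.3g/nt\n",
              x$pol4_rate_median, x$pol4_rate_gsd, x$pol4_term_hazard,
              x$displacement_hazard))
  cat("  pause exit rates:",
      paste(sprintf("%s=%.3g/s", names(x$pause_exit_rates),
                    x$pause_exit_rates), collapse = ", "), "\n")
  invisible(x)
}

#' Analysis configuration for trace segmentation and classification
#'
#' @param rate_cutoff bp/s; segment rates at or above the cutoff are assigned
#'   to the fast polymerase (Pol III), below it to the slow one (Pol IV).
#'   Default 45 bp/s.
#' @param pause_rate_max bp/s; segments with |slope| at or below this are
#'   pauses.
#' @param min_event_bases bp; detected events smaller than this are merged
#'   into neighboring pauses (default 210 = 3 x the 70 bp noise floor).
#' @param min_event_frames minimum frames per event (>= 2).
#' @param changepoint_penalty multiplier on the per-changepoint penalty
#'   `penalty * sigma^2 * log(n)` in the piecewise-linear least-squares
#'   objective; default 3 (one extra segment costs slope + intercept +
#'   breakpoint location, BIC-style).
#' @param noise_method noise SD estimator used for the penalty:
#'   `"diff2"` (MAD of second differences / sqrt(6); trend-free, default) or
#'   `"diff1"` (MAD of first differences / sqrt(2)).
#' @param local_refine after the global changepoint search, re-run the same
#'   penalized search recursively inside each segment with the penalty's
#'   log(n) taken from the window length (off by default; increases
#'   sensitivity to short events at the cost of edge fragments).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(rate_cutoff = 45,
                            pause_rate_max = 2,
                            min_event_bases = 210,
                            min_event_frames = 3,
                            changepoint_penalty = 3,
                            noise_method = c("diff2", "diff1"),
                            local_refine = FALSE) {
  noise_method <- match.arg(noise_method)
  if (!(pause_rate_max >= 0 && pause_rate_max < rate_cutoff))
    stop("analysis_config: need 0 <= pause_rate_max < rate_cutoff")
  if (min_event_frames < 2) stop("analysis_config: min_event_frames must be >= 2")
  if (min_event_bases < 0) stop("analysis_config: min_event_bases must be >= 0")
  if (changepoint_penalty <= 0) stop("analysis_config: changepoint_penalty must be > 0")
  structure(list(rate_cutoff = rate_cutoff, pause_rate_max = pause_rate_max,
                 min_event_bases = min_event_bases,
                 min_event_frames = min_event_frames,
                 changepoint_penalty = changepoint_penalty,
                 noise_method = noise_method,
                 local_refine = isTRUE(local_refine)),
            class = "analysis_config")
}

#' Read / write a simulation or analysis configuration as YAML
#'
#' Every default of [sim_config()] / [analysis_config()] is overridable from
#' the file; unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return `read_sim_config`/`read_analysis_config` return the validated
#'   config object.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("read_sim_config: unknown keys: ",
                        paste(bad, collapse = ", "))
  for (nm in c("pause_exit_rates", "concentrations"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @export
read_analysis_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("read_analysis_config: unknown keys: ",
                        paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @rdname read_sim_config
#' @param cfg config object to serialize.
#' @export
write_config_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x <- lapply(x, function(v) if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}
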