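# Synthetic-data generator for the tethered-bead flow-stretch experiment:
# single-molecule synthesis trajectories with full ground truth, and
# pre-steady-state kinetic time courses.

# Run expr under a given seed, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for simulation")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(expr)
}

# One molecule; assumes the RNG is already seeded by the caller.
.sim_molecule <- function(cfg, molecule_id) {
  per <- cfg$pause_exit_rates
  per <- c(pol3 = unname(per["pol3"]), pol4 = unname(per["pol4"]))
  per[is.na(per)] <- 0
  total_exit <- sum(per)

  t_now <- 0
  pos <- 0
  ev <- list()
  repeat {
    # pause until the next polymerase binds
    pause_dur <- if (is.infinite(total_exit)) 0 else stats::rexp(1, total_exit)
    t_now <- t_now + pause_dur
    if (t_now >= cfg$duration || pos >= cfg$template_len) break
    pol <- if (all(is.infinite(per[per > 0]))) {
      sample(names(per)[per > 0], 1L)
    } else {
      sample(names(per), 1L, prob = per)
    }
    if (pol == "pol3") {
      rate <- cfg$pol3_rate_median * exp(log(cfg$pol3_rate_gsd) * stats::rnorm(1))
      hazard <- cfg$pol3_term_hazard + cfg$displacement_hazard
      p_displaced <- if (hazard > 0) cfg$displacement_hazard / hazard else 0
    } else {
      rate <- cfg$pol4_rate_median * exp(log(cfg$pol4_rate_gsd) * stats::rnorm(1))
      hazard <- cfg$pol4_term_hazard
      p_displaced <- 0
    }
    extent <- if (hazard > 0) stats::rexp(1, hazard) else Inf
    ended <- if (p_displaced > 0 && stats::runif(1) < p_displaced)
      "displaced" else "intrinsic"
    if (pos + extent >= cfg$template_len) {
      extent <- cfg$template_len - pos
      ended <- "template_end"
    }
    dur <- extent / rate
    if (t_now + dur > cfg$duration) {
      dur <- cfg$duration - t_now
      extent <- rate * dur
      ended <- "run_end"
    }
    if (extent > 0) {
      ev[[length(ev) + 1L]] <- data.frame(
        molecule_id = molecule_id,
        pol_id = if (pol == "pol3") "POL3" else "POL4",
        t_start = t_now, t_end = t_now + dur,
        nt_start = pos, nt_end = pos + extent,
        true_rate = rate, ended_by = ended,
        stringsAsFactors = FALSE)
    }
    t_now <- t_now + dur
    pos <- pos + extent
    if (t_now >= cfg$duration || pos >= cfg$template_len) break
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(molecule_id = integer(0), pol_id = character(0),
               t_start = numeric(0), t_end = numeric(0),
               nt_start = numeric(0), nt_end = numeric(0),
               true_rate = numeric(0), ended_by = character(0),
               stringsAsFactors = FALSE)

  times <- seq(0, cfg$duration, by = cfg$frame_interval)
  if (nrow(events)) {
    kt <- c(0, rbind(events$t_start, events$t_end), cfg$duration)
    kx <- c(0, rbind(events$nt_start, events$nt_end), pos)
    keep <- !duplicated(kt)
    truth <- stats::approx(kt[keep], kx[keep], xout = times, rule = 2)$y
  } else {
    truth <- rep(0, length(times))
  }
  observed <- truth + stats::rnorm(length(times), 0, cfg$noise_sd)

  structure(list(molecule_id = molecule_id, time = times,
                 position = observed, truth_position = truth,
                 events = events, frame_interval = cfg$frame_interval,
                 template_len = cfg$template_len),
            class = "fs_trajectory")
}

#' Simulate one single-molecule synthesis trajectory
#'
#' Generates the alternating pause/event structure of a flow-stretch
#' primer-extension trace: pause durations are exponential with total rate
#' equal to the sum of the per-species binding rates, the binding species is
#' chosen proportional to its rate, each processive event draws a log-normal
#' per-event rate and an exponential nucleotide extent from its per-nt
#' termination hazard (plus the displacement hazard for Pol III), truncated
#' at the template end and at the end of the observation.  Observed positions
#' are the true cumulative synthesis plus i.i.d. Gaussian noise.  The same
#' seed and config always produce an identical trajectory.
#'
#' @param config a [sim_config()].
#' @param molecule_id identifier stored in the outputs.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return `fs_trajectory`: list with `time` (s), `position` (bp, noisy),
#'   `truth_position` (bp), and ground-truth `events` data frame
#'   (`pol_id`, `t_start`, `t_end`, `nt_start`, `nt_end`, `true_rate`,
#'   `ended_by` in intrinsic/displaced/template_end/run_end).
#' @export
simulate_trajectory <- function(config, molecule_id = 1L, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, .sim_molecule(config, molecule_id))
}

#' Simulate all molecules of one condition
#'
#' @param config a [sim_config()] with a seed; `config$n_molecules`
#'   trajectories are drawn from one seeded RNG stream.
#' @return `fs_trajectory_set`: list with `$trajectories` (list of
#'   [simulate_trajectory()] results) and `$config`.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  trajs <- .with_seed(config$seed,
                      lapply(seq_len(config$n_molecules),
                             function(i) .sim_molecule(config, i)))
  structure(list(trajectories = trajs, config = config),
            class = "fs_trajectory_set")
}

#' Simulate a multi-condition experiment
#'
#' Wraps [simulate_trajectories()] over a named list of conditions (e.g.
#' Pol III alone; + Pol IV; + Pol IV catalytic domain).  Each condition `i`
#' gets the deterministic seed `(master_seed + 100003 * (i - 1)) mod 2^31-1`,
#' so the whole experiment is reproducible from the master seed alone.
#'
#' @param conditions named list of [sim_config()] objects; names are the
#'   condition labels and must be unique.
#' @param seed master seed.
#' @return named list of `fs_trajectory_set`, one per condition.
#' @export
simulate_experiment <- function(conditions, seed) {
  if (is.null(names(conditions)) || any(names(conditions) == "") ||
      anyDuplicated(names(conditions)))
    stop("simulate_experiment: conditions must have unique non-empty labels")
  out <- vector("list", length(conditions))
  names(out) <- names(conditions)
  for (i in seq_along(conditions)) {
    cfg <- conditions[[i]]
    stopifnot(inherits(cfg, "sim_config"))
    cfg$seed <- as.integer((as.numeric(seed) + 100003 * (i - 1)) %%
                             (.Machine$integer.max - 1)) + 1L
    out[[i]] <- simulate_trajectories(cfg)
  }
  out
}

#' Flatten trajectories / truth events to data frames
#'
#' @param x an `fs_trajectory_set` (or a named list of them, in which case a
#'   `condition` column is added).
#' @return data frame: `molecule_id`, `t_s`, `x_bp`, `truth_x_bp` for
#'   `trajectories_df`; the truth-event schema for `truth_events_df`.
#' @export
trajectories_df <- function(x) {
  if (inherits(x, "fs_trajectory_set")) {
    do.call(rbind, lapply(x$trajectories, function(tr)
      data.frame(molecule_id = tr$molecule_id, t_s = tr$time,
                 x_bp = tr$position, truth_x_bp = tr$truth_position)))
  } else {
    do.call(rbind, lapply(names(x), function(lab) {
      d <- trajectories_df(x[[lab]])
      cbind(condition = lab, d, stringsAsFactors = FALSE)
    }))
  }
}

#' @rdname trajectories_df
#' @export
truth_events_df <- function(x) {
  if (inherits(x, "fs_trajectory_set")) {
    do.call(rbind, lapply(x$trajectories, function(tr) tr$events))
  } else {
    do.call(rbind, lapply(names(x), function(lab) {
      d <- truth_events_df(x[[lab]])
      if (is.null(d) || !nrow(d)) return(NULL)
      cbind(condition = lab, d, stringsAsFactors = FALSE)
    }))
  }
}

#' Simulate a pre-steady-state kinetic time course
#'
#' Product formation follows the single-exponential burst equation
#' \deqn{y(t) = A (1 - e^{-k_{obs} t}) + C}
#' plus optional Gaussian noise, clipped at 0 (and at the template
#' concentration when given).
#'
#' @param A burst amplitude, nM (>= 0).
#' @param kobs observed rate constant, 1/s (>= 0).
#' @param C product offset at t = 0, nM.
#' @param times sampling times, s (non-negative, increasing).
#' @param noise_sd Gaussian noise SD, nM.
#' @param dNTP_conc nucleotide concentration metadata, uM.
#' @param template_conc primer/template concentration, nM (upper clip).
#' @param seed RNG seed (required when `noise_sd > 0`).
#' @return data frame `time_s`, `product_nM`, with attributes `true_params`
#'   and `dNTP_conc`.
#' @export
simulate_timecourse <- function(A, kobs, C, times, noise_sd = 0,
                                dNTP_conc = NA_real_, template_conc = NULL,
                                seed = NULL) {
  if (A < 0 || kobs < 0) stop("simulate_timecourse: A and kobs must be >= 0")
  if (any(times < 0)) stop("simulate_timecourse: negative times rejected")
  if (is.unsorted(times, strictly = FALSE))
    stop("simulate_timecourse: times must be increasing")
  y <- A * (1 - exp(-kobs * times)) + C
  if (noise_sd > 0) {
    y <- y + .with_seed(seed, stats::rnorm(length(times), 0, noise_sd))
  }
  y <- pmax(y, 0)
  if (!is.null(template_conc)) y <- pmin(y, template_conc)
  structure(data.frame(time_s = times, product_nM = y),
            true_params = c(A = A, kobs = kobs, C = C),
            dNTP_conc = dNTP_conc)
}
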