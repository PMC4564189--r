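# Piecewise-linear segmentation of synthesis traces into processive events
# and pauses, by penalized least squares with an exact dynamic-programming
# changepoint search.

#' Estimate per-frame positional noise SD from a trace
#'
#' Robust noise estimate used both for the changepoint penalty and for
#' noise self-consistency checks.  `"diff2"` (default) uses the MAD of
#' second differences divided by sqrt(6), which is exactly trend-free on
#' piecewise-linear signal; `"diff1"` uses the MAD of first differences
#' divided by sqrt(2).
#'
#' @param x numeric positions (bp), one trace or pooled frames.
#' @param method `"diff2"` or `"diff1"`.
#' @return estimated SD (bp).
#' @export
estimate_noise_sd <- function(x, method = c("diff2", "diff1")) {
  method <- match.arg(method)
  if (length(x) < 3) stop("estimate_noise_sd: need at least 3 frames")
  if (method == "diff2") stats::mad(diff(x, differences = 2)) / sqrt(6)
  else stats::mad(diff(x)) / sqrt(2)
}

# Per-segment OLS line cost (SSE) machinery on prefix sums; returns a
# vectorized cost(is, j) over segment start indices for a fixed end.
.seg_cost_fun <- function(t, x) {
  t0 <- t - t[1]
  x0 <- x - mean(x)
  c1t <- c(0, cumsum(t0)); c1x <- c(0, cumsum(x0))
  c2t <- c(0, cumsum(t0^2)); c2x <- c(0, cumsum(x0^2))
  ctx <- c(0, cumsum(t0 * x0))
  function(is, j) {
    nn <- j - is + 1
    St <- c1t[j + 1] - c1t[is]; Sx <- c1x[j + 1] - c1x[is]
    Stt <- c2t[j + 1] - c2t[is]; Sxx <- c2x[j + 1] - c2x[is]
    Stx <- ctx[j + 1] - ctx[is]
    stt <- Stt - St^2 / nn
    sxx <- Sxx - Sx^2 / nn
    stx <- Stx - St * Sx / nn
    sse <- sxx - ifelse(stt > 0, stx^2 / stt, 0)
    pmax(sse, 0)
  }
}

# Exact optimal partitioning: minimize sum of per-segment OLS SSE +
# beta * (#changepoints).  Returns integer vector of segment start indices.
.segment_dp <- function(t, x, beta, minseg = 2L) {
  n <- length(t)
  cost <- .seg_cost_fun(t, x)
  Fp <- rep(Inf, n + 1)   # Fp[k+1]: optimal cost of frames 1..k
  Fp[1] <- -beta          # first segment's +beta cancels: penalty per changepoint
  Kp <- integer(n + 1)
  prev <- integer(n + 1)
  tie <- 1e-9 * (1 + cost(1L, n))  # prefer fewer segments among near-ties
  for (j in seq(minseg, n)) {
    is <- seq_len(j - minseg + 1L)
    cand <- Fp[is] + cost(is, j) + beta
    b <- which.min(cand + tie * Kp[is])
    Fp[j + 1] <- cand[b]
    Kp[j + 1] <- Kp[is[b]] + 1L
    prev[j + 1] <- is[b]
  }
  if (!is.finite(Fp[n + 1])) stop("segmentation failed: trajectory too short")
  starts <- integer(0)
  j <- n
  while (j >= 1) {
    i <- prev[j + 1]
    starts <- c(i, starts)
    j <- i - 1L
  }
  starts
}

.ols_slope <- function(t, x) {
  tm <- t - mean(t); xm <- x - mean(x)
  stt <- sum(tm^2)
  if (stt == 0) return(0)
  sum(tm * xm) / stt
}

#' Segment a synthesis trace into processive events and pauses
#'
#' Fits a penalized piecewise-linear least-squares model: changepoints are
#' chosen to minimize `SSE + penalty * (#changepoints) * sigma^2 * log(n)`
#' (exact dynamic-programming search over all placements with segments of at
#' least 2 frames), with `sigma` the robust noise estimate of
#' [estimate_noise_sd()].  Segments with |slope| at most `pause_rate_max`
#' are labeled pauses; the rest are events.  Events smaller than
#' `min_event_bases` (absolute fitted extent) or shorter than
#' `min_event_frames` are merged into neighboring pauses, and adjacent
#' same-label segments are merged (the merge is idempotent).  Event rates at
#' or above `rate_cutoff` are classified as the fast polymerase (`POL3`),
#' below it as the slow one (`POL4`); retrograde events (negative rate) are
#' classified `POL4` and flagged.
#'
#' @param traj an `fs_trajectory`, or a data frame with columns `t_s` and
#'   `x_bp` (optionally `molecule_id`).
#' @param cfg an [analysis_config()].
#' @return data frame of segments in time order: `molecule_id`, `label`
#'   (event/pause), `t_start`, `t_end`, `n_frames`, `rate` (bp/s), `bases`
#'   (fitted extent, bp), `pol_class` (`POL3`/`POL4`, `NA` for pauses),
#'   `retrograde`, `boundary` (touches the first or last frame).  Attributes:
#'   `noise_sd_est`, `penalty`.
#' @export
segment_trajectory <- function(traj, cfg = analysis_config()) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (inherits(traj, "fs_trajectory")) {
    t <- traj$time; x <- traj$position; mol <- traj$molecule_id
  } else {
    d <- as.data.frame(traj)
    if (!all(c("t_s", "x_bp") %in% names(d)))
      stop("segment_trajectory: need columns t_s and x_bp")
    t <- d$t_s; x <- d$x_bp
    mol <- if ("molecule_id" %in% names(d)) d$molecule_id[1] else NA
  }
  n <- length(t)
  if (n < 2 * cfg$min_event_frames)
    stop("segment_trajectory: trajectory too short (", n, " frames)")
  if (any(diff(t) <= 0)) stop("segment_trajectory: times must be increasing")

  sigma <- estimate_noise_sd(x, cfg$noise_method)
  beta <- cfg$changepoint_penalty * sigma^2 * log(n)
  starts <- .segment_dp(t, x, beta)
  ends <- c(starts[-1] - 1L, n)
  if (isTRUE(cfg$local_refine)) {
    # recursive local refinement: re-run the same penalized search inside
    # each segment with log(n) taken from the window length, so short events
    # that a whole-trace penalty leaves merged with their flanking pauses
    # are still resolved; recursion stops when a window no longer splits
    refine <- function(i, j) {
      if (j - i + 1L < 4L) return(i)
      bloc <- cfg$changepoint_penalty * sigma^2 * log(j - i + 1L)
      st <- .segment_dp(t[i:j], x[i:j], bloc)
      if (length(st) == 1L) return(i)
      abs_st <- i + st - 1L
      unlist(Map(refine, abs_st, c(abs_st[-1] - 1L, j)))
    }
    starts <- sort(unique(unlist(Map(refine, starts, ends))))
    ends <- c(starts[-1] - 1L, n)
  }

  seg_fit <- function(i, j) {
    slope <- .ols_slope(t[i:j], x[i:j])
    list(i = i, j = j, rate = slope, bases = slope * (t[j] - t[i]),
         frames = j - i + 1L)
  }
  segs <- Map(seg_fit, starts, ends)
  lab <- vapply(segs, function(s)
    if (abs(s$rate) <= cfg$pause_rate_max) "pause" else "event", "")

  # merge key: adjacent same-label segments coalesce.  Merging by label
  # (rather than by polymerase class) heals oversplit events whose tail
  # fragment alone would classify differently; truly adjacent fast/slow
  # events are almost always separated by a pause at this frame rate.
  seg_key <- function(s, l) l
  iter <- 0L
  repeat {
    changed <- FALSE
    # demote sub-threshold events to pauses
    for (k in seq_along(segs)) {
      s <- segs[[k]]
      if (lab[k] == "event" &&
          (abs(s$bases) < cfg$min_event_bases ||
           s$frames < cfg$min_event_frames)) {
        lab[k] <- "pause"
        changed <- TRUE
      }
    }
    # merge adjacent same-key segments
    if (length(segs) > 1) {
      keys <- mapply(seg_key, segs, lab)
      keep_segs <- list(); keep_lab <- character(0)
      cur <- segs[[1]]; curlab <- lab[1]; curkey <- keys[1]
      for (k in seq_along(segs)[-1]) {
        if (keys[k] == curkey) {
          cur <- seg_fit(cur$i, segs[[k]]$j)
          curkey <- seg_key(cur, curlab)
          changed <- TRUE
        } else {
          keep_segs[[length(keep_segs) + 1L]] <- cur
          keep_lab <- c(keep_lab, curlab)
          cur <- segs[[k]]; curlab <- lab[k]; curkey <- keys[k]
        }
      }
      keep_segs[[length(keep_segs) + 1L]] <- cur
      keep_lab <- c(keep_lab, curlab)
      segs <- keep_segs; lab <- keep_lab
    }
    iter <- iter + 1L
    if (!changed || iter > 50L) break
  }

  out <- data.frame(
    molecule_id = mol,
    label = lab,
    t_start = vapply(segs, function(s) t[s$i], 0),
    t_end = vapply(segs, function(s) t[s$j], 0),
    n_frames = vapply(segs, function(s) s$frames, 0L),
    rate = vapply(segs, function(s) s$rate, 0),
    bases = vapply(segs, function(s) s$bases, 0),
    stringsAsFactors = FALSE)
  out$pol_class <- ifelse(out$label == "event",
                          classify_event(out$rate, cfg), NA_character_)
  out$retrograde <- out$label == "event" & out$rate < 0
  out$boundary <- seq_len(nrow(out)) == 1L | seq_len(nrow(out)) == nrow(out)
  attr(out, "noise_sd_est") <- sigma
  attr(out, "penalty") <- beta
  out
}

#' Classify event rates by polymerase
#'
#' Rates at or above the cutoff (default 45 bp/s) are assigned to the fast
#' replicative polymerase (`POL3`), rates below it to the slow translesion
#' polymerase (`POL4`); the boundary value belongs to the fast class.
#' Negative (retrograde) rates are classified `POL4`.
#'
#' @param rate numeric vector of segment rates, bp/s.
#' @param cfg an [analysis_config()].
#' @return character vector, `"POL3"` or `"POL4"`.
#' @export
classify_event <- function(rate, cfg = analysis_config()) {
  if (any(!is.finite(rate))) stop("classify_event: rates must be finite")
  ifelse(rate >= cfg$rate_cutoff, "POL3", "POL4")
}

#' Segment every trajectory of a condition (or experiment)
#'
#' @param x an `fs_trajectory_set`, or a named list of them (condition
#'   labels are carried into a `condition` column).
#' @param cfg an [analysis_config()].
#' @return combined segment data frame (see [segment_trajectory()]).
#' @export
segment_experiment <- function(x, cfg = analysis_config()) {
  if (inherits(x, "fs_trajectory_set")) {
    do.call(rbind, lapply(x$trajectories, segment_trajectory, cfg = cfg))
  } else {
    do.call(rbind, lapply(names(x), function(lab) {
      d <- segment_experiment(x[[lab]], cfg)
      cbind(condition = lab, d, stringsAsFactors = FALSE)
    }))
  }
}
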