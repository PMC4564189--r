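# Per-condition processivity statistics and nonparametric comparisons.

#' Summarize processivity of a set of events
#'
#' Mean and SEM of event extents (bp), plus a truncation-corrected
#' processivity estimate: with exponential event extents, the extents above
#' any threshold `c` are distributed as `c + Exp(hazard)` (memorylessness),
#' so restricting to events of at least `detection_floor` bases and
#' subtracting the floor from their mean estimates the underlying mean
#' processivity `1/hazard` without detection bias — provided the floor is
#' set where detection is complete (see the methods vignette).
#'
#' @param bases numeric vector of event extents, bp.
#' @param label condition label carried into the summary.
#' @param detection_floor completeness threshold, bp: events below it are
#'   dropped and the floor is subtracted from the mean of the rest; 0
#'   disables the correction.
#' @return `condition_summary`: list with `label`, `n_events`, `mean`, `sem`
#'   (0 with `single_event = TRUE` when n = 1), `mean_corrected`.
#' @export
summarize_condition <- function(bases, label = "", detection_floor = 0) {
  bases <- bases[is.finite(bases)]
  n_all <- length(bases)
  if (n_all < 1) stop("summarize_condition: no events")
  kept <- bases[bases >= detection_floor]
  if (!length(kept)) stop("summarize_condition: no events above the floor")
  n <- length(kept)
  m <- mean(kept)
  sem <- if (n == 1) 0 else stats::sd(kept) / sqrt(n)
  structure(list(label = label, n_events = n, n_total = n_all,
                 mean = m, sem = sem,
                 single_event = n == 1,
                 detection_floor = detection_floor,
                 mean_corrected = m - detection_floor),
            class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d events, mean = %.1f +/- %.1f bp (SEM)",
              if (nzchar(x$label)) x$label else "condition",
              x$n_events, x$mean, x$sem))
  if (x$detection_floor > 0)
    cat(sprintf("; floor-corrected mean = %.1f bp", x$mean_corrected))
  cat("\n")
  invisible(x)
}

#' Summarize events of one class from a segment table
#'
#' Filters a [segment_trajectory()] / [segment_experiment()] table to events
#' (optionally one polymerase class), drops boundary-censored events (those
#' touching the first or last frame of their trace, whose extents are
#' truncated by the observation window), and summarizes extents.
#'
#' @param segments segment data frame.
#' @param label condition label for the summary.
#' @param class_filter `"POL3"`, `"POL4"`, or `NULL` for all events.
#' @param detection_floor see [summarize_condition()].
#' @param drop_censored exclude boundary-touching events (default TRUE).
#' @return `condition_summary`.
#' @export
summarize_events <- function(segments, label = "", class_filter = NULL,
                             detection_floor = 0, drop_censored = TRUE) {
  ev <- segments[segments$label == "event", , drop = FALSE]
  if (!is.null(class_filter))
    ev <- ev[ev$pol_class %in% class_filter, , drop = FALSE]
  if (drop_censored && "boundary" %in% names(ev))
    ev <- ev[!ev$boundary, , drop = FALSE]
  if (!nrow(ev)) stop("summarize_events: no events after filtering")
  summarize_condition(ev$bases, label, detection_floor)
}

#' Fraction of detected events assigned to the correct polymerase
#'
#' Each detected event is matched to the ground-truth event of the same
#' molecule with the largest time overlap; the match is correct when the
#' rate-cutoff class equals the generating polymerase.  Detected events that
#' overlap no true event count as incorrect.
#'
#' @param events detected segment table (with `condition` optional) -- only
#'   `label == "event"` rows are used.
#' @param truth ground-truth event table ([truth_events_df()]).
#' @return list: `percent` correctly classified, `n_events`, `n_correct`,
#'   `n_unmatched`.
#' @export
capture_fraction <- function(events, truth) {
  if (is.null(truth) || !nrow(truth)) stop("capture_fraction: no truth events")
  ev <- events[events$label == "event", , drop = FALSE]
  if (!nrow(ev)) stop("capture_fraction: no detected events")
  correct <- logical(nrow(ev))
  unmatched <- logical(nrow(ev))
  for (k in seq_len(nrow(ev))) {
    tr <- truth[truth$molecule_id == ev$molecule_id[k], , drop = FALSE]
    if ("condition" %in% names(ev) && "condition" %in% names(tr))
      tr <- tr[tr$condition == ev$condition[k], , drop = FALSE]
    if (!nrow(tr)) { unmatched[k] <- TRUE; next }
    ov <- pmax(0, pmin(ev$t_end[k], tr$t_end) - pmax(ev$t_start[k], tr$t_start))
    if (max(ov) <= 0) { unmatched[k] <- TRUE; next }
    correct[k] <- tr$pol_id[which.max(ov)] == ev$pol_class[k]
  }
  list(percent = 100 * sum(correct) / nrow(ev),
       n_events = nrow(ev), n_correct = sum(correct),
       n_unmatched = sum(unmatched))
}

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' The statistic is the rank sum (midranks) of the smaller sample.  When the
#' combined size is at most 20 the null distribution is obtained by full
#' enumeration of all assignments of the observed (mid)ranks, i.e. the exact
#' conditional permutation null; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.  Two-sided p is
#' twice the smaller tail, capped at 1.
#'
#' @param a,b numeric samples (non-empty).
#' @return `ranksum_result`: `statistic`, `p_two_sided`, `method`
#'   (`"exact"`/`"normal_approx"`), sample sizes.
#' @export
ranksum_test <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n_a <- length(a); n_b <- length(b)
  if (n_a < 1 || n_b < 1) stop("ranksum_test: both samples must be non-empty")
  N <- n_a + n_b
  r <- rank(c(a, b))
  # statistic on the smaller sample
  if (n_a <= n_b) { ns <- n_a; w <- sum(r[seq_len(n_a)]) }
  else { ns <- n_b; w <- sum(r[n_a + seq_len(n_b)]) }
  if (N <= 20) {
    sums <- utils::combn(N, ns, FUN = function(idx) sum(r[idx]))
    eps <- 1e-9
    p_lo <- mean(sums <= w + eps)
    p_hi <- mean(sums >= w - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    no <- N - ns
    mu <- ns * (N + 1) / 2
    ties <- table(r)
    v <- ns * no * (N + 1) / 12 -
      ns * no * sum(ties^3 - ties) / (12 * N * (N - 1))
    if (v <= 0) { # all observations identical
      p <- 1; method <- "normal_approx"
    } else {
      z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(v)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
      method <- "normal_approx"
    }
  }
  structure(list(statistic = w, p_two_sided = p, method = method,
                 n_a = n_a, n_b = n_b),
            class = "ranksum_result")
}

#' @export
print.ranksum_result <- function(x, ...) {
  cat(sprintf("rank-sum test (%s): W = %g, n = (%d, %d), two-sided p = %.4g\n",
              x$method, x$statistic, x$n_a, x$n_b, x$p_two_sided))
  invisible(x)
}

#' Ratio of mean processivities with bootstrap confidence interval
#'
#' Ratio of (detection-floor-corrected) mean event extents between two
#' conditions, with a seeded percentile bootstrap CI over events.
#'
#' @param bases_num,bases_den event extents (bp) of the numerator and
#'   denominator condition (numerator = perturbed, denominator = alone).
#' @param detection_floor completeness threshold, bp: events below it are
#'   dropped and it is subtracted from each mean before the ratio (see
#'   [summarize_condition()]).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list: `ratio`, `ci` (length 2), `n_boot`, `conf`.
#' @export
processivity_ratio <- function(bases_num, bases_den, detection_floor = 0,
                               n_boot = 2000, seed = 1, conf = 0.95) {
  bases_num <- bases_num[is.finite(bases_num)]
  bases_den <- bases_den[is.finite(bases_den)]
  if (!length(bases_num) || !length(bases_den))
    stop("processivity_ratio: empty event set")
  bases_num <- bases_num[bases_num >= detection_floor]
  bases_den <- bases_den[bases_den >= detection_floor]
  if (!length(bases_num) || !length(bases_den))
    stop("processivity_ratio: no events above the floor")
  den <- mean(bases_den) - detection_floor
  if (den <= 0) stop("processivity_ratio: non-positive denominator mean")
  ratio <- (mean(bases_num) - detection_floor) / den
  boots <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bn <- mean(sample(bases_num, replace = TRUE)) - detection_floor
      bd <- mean(sample(bases_den, replace = TRUE)) - detection_floor
      if (bd <= 0) NA_real_ else bn / bd
    }, 0)
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(ratio = ratio, ci = ci, n_boot = n_boot, conf = conf)
}

#' Molar excess of one species over another
#'
#' @param conc_a,conc_b concentrations in the same units (`conc_b > 0`).
#' @return fold excess `conc_a / conc_b`.
#' @export
fold_excess <- function(conc_a, conc_b) {
  if (conc_b <= 0) stop("fold_excess: reference concentration must be > 0")
  conc_a / conc_b
}
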