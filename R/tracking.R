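# Sub-pixel bead localization by 2D Gaussian fitting, and frame-by-frame
# tracking of an image stack into a position-vs-time trace.

#' Localize a bead in one frame by symmetric 2D Gaussian fitting
#'
#' Least-squares fit of `B + A * gx(x0, sd) * gy(y0, sd)` (per-pixel
#' integrated Gaussian plus constant background) over a square region of
#' interest, initialized from the background-subtracted intensity centroid.
#'
#' @param frame numeric matrix (rows = y, columns = x).
#' @param roi_center length-2 vector `c(x, y)` in pixels.
#' @param roi_halfwidth half-width of the ROI in pixels; the ROI must lie
#'   fully inside the frame.
#' @return `localization`: `x`, `y` (sub-pixel, px), `sd`, `amplitude`,
#'   `background`, `fit_rmse`, `ok`.
#' @export
localize_bead <- function(frame, roi_center, roi_halfwidth = 7) {
  cx <- round(roi_center[1]); cy <- round(roi_center[2])
  xr <- (cx - roi_halfwidth):(cx + roi_halfwidth)
  yr <- (cy - roi_halfwidth):(cy + roi_halfwidth)
  if (min(xr) < 1 || min(yr) < 1 ||
      max(xr) > ncol(frame) || max(yr) > nrow(frame))
    stop("localize_bead: ROI extends outside the frame")
  roi <- frame[yr, xr, drop = FALSE]
  if (stats::var(as.vector(roi)) == 0)
    stop("localize_bead: no bead (flat ROI)")

  I <- as.vector(roi)
  px <- rep(xr, each = length(yr))
  py <- rep(yr, times = length(xr))
  B0 <- min(I)
  w <- pmax(I - B0, 0)
  x0 <- sum(w * px) / sum(w)
  y0 <- sum(w * py) / sum(w)
  A0 <- max(sum(w), 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ B + A * (stats::pnorm(px + 0.5, x0f, s) - stats::pnorm(px - 0.5, x0f, s)) *
        (stats::pnorm(py + 0.5, y0f, s) - stats::pnorm(py - 0.5, y0f, s)),
      start = list(B = B0, A = A0, x0f = x0, y0f = y0, s = 1.5),
      lower = c(B = -Inf, A = 0, x0f = min(xr) - 1, y0f = min(yr) - 1,
                s = 0.3),
      upper = c(B = Inf, A = Inf, x0f = max(xr) + 1, y0f = max(yr) + 1,
                s = 4 * roi_halfwidth),
      control = minpack.lm::nls.lm.control(maxiter = 200,
                                           ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(x = x0, y = y0, sd = NA_real_, amplitude = NA_real_,
                          background = B0, fit_rmse = NA_real_, ok = FALSE),
                     class = "localization"))
  }
  p <- stats::coef(fit)
  structure(list(x = unname(p["x0f"]), y = unname(p["y0f"]),
                 sd = unname(p["s"]), amplitude = unname(p["A"]),
                 background = unname(p["B"]),
                 fit_rmse = sqrt(mean(stats::resid(fit)^2)),
                 ok = isTRUE(fit$convInfo$isConv)),
            class = "localization")
}

#' Track a bead through an image stack
#'
#' Localizes the bead frame by frame with the region of interest re-centered
#' on the previous successful fit.  Failed frames are marked and bridged by
#' linear interpolation when at most `max_gap` consecutive frames fail;
#' longer gaps split the trace (`segment_id` increments).  The x-coordinate
#' (flow axis) is converted to nucleotides synthesized through the pixel
#' size and the calibration, relative to the first localized frame.
#'
#' @param stack an `fs_bead_stack` (or a list with `frames`,
#'   `pixel_size_nm`, `cal`, `time`).
#' @param initial_roi length-2 `c(x, y)` start ROI center; defaults to the
#'   brightest pixel of the first frame.
#' @param roi_halfwidth ROI half-width, px.
#' @param max_gap longest failed-frame run bridged by interpolation.
#' @param cal,pixel_size_nm override the stack's calibration / pixel size.
#' @return data frame: `frame`, `t_s`, `x_px`, `y_px`, `ok`, `bridged`,
#'   `segment_id`, `x_bp`.
#' @export
track_stack <- function(stack, initial_roi = NULL, roi_halfwidth = 7,
                        max_gap = 2, cal = stack$cal,
                        pixel_size_nm = stack$pixel_size_nm) {
  frames <- stack$frames
  nf <- length(frames)
  if (nf < 1) stop("track_stack: empty stack")
  times <- stack$time %||% seq_len(nf)
  if (is.null(initial_roi)) {
    f1 <- frames[[1]]
    idx <- which(f1 == max(f1), arr.ind = TRUE)[1, ]
    initial_roi <- c(idx[["col"]], idx[["row"]])
  }
  x <- y <- rep(NA_real_, nf)
  ok <- rep(FALSE, nf)
  roi <- initial_roi
  for (i in seq_len(nf)) {
    loc <- tryCatch(localize_bead(frames[[i]], roi, roi_halfwidth),
                    error = function(e) NULL)
    if (!is.null(loc) && loc$ok) {
      x[i] <- loc$x; y[i] <- loc$y; ok[i] <- TRUE
      roi <- c(loc$x, loc$y)
    }
  }
  if (!ok[1]) stop("track_stack: first-frame localization failed")
  if (mean(!ok) > 0.5) stop("track_stack: more than 50% of frames failed")

  bridged <- rep(FALSE, nf)
  segment_id <- rep(1L, nf)
  seg <- 1L
  r <- rle(ok)
  pos <- cumsum(r$lengths)
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    i0 <- pos[k] - r$lengths[k] + 1L
    i1 <- pos[k]
    if (r$lengths[k] <= max_gap && i1 < nf) {
      a <- i0 - 1L; b <- i1 + 1L
      frac <- (seq(i0, i1) - a) / (b - a)
      x[i0:i1] <- x[a] + frac * (x[b] - x[a])
      y[i0:i1] <- y[a] + frac * (y[b] - y[a])
      bridged[i0:i1] <- TRUE
    } else {
      seg <- seg + 1L
    }
    if (i1 < nf) segment_id[(i1 + 1L):nf] <- seg
  }

  out <- data.frame(frame = seq_len(nf), t_s = times, x_px = x, y_px = y,
                    ok = ok, bridged = bridged, segment_id = segment_id)
  if (!is.null(cal)) {
    ref <- out$x_px[which(ok)[1]]
    out$x_bp <- displacement_to_bases((out$x_px - ref) * pixel_size_nm, cal)
  }
  out
}
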