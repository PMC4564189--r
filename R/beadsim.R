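# Synthetic dark-field bead image stacks rendered from a trajectory, with
# true sub-pixel centers recorded for localization benchmarking.

# integrated symmetric Gaussian over unit pixels centered at integer coords
.pixel_profile <- function(coords, center, sd) {
  stats::pnorm(coords + 0.5, center, sd) - stats::pnorm(coords - 0.5, center, sd)
}

#' Render a bead image stack from a trajectory
#'
#' One frame per time point: the bead is drawn as a symmetric 2D Gaussian
#' intensity profile (integrated per pixel) whose x-position follows the
#' trajectory's synthesis signal projected along the flow axis, plus a
#' constant background, with Poisson shot noise.  True sub-pixel centers are
#' recorded per frame.
#'
#' @param trajectory an `fs_trajectory`, or a numeric vector of positions
#'   (bp) per frame.
#' @param cal a [calibration()] (nm per nt synthesized).
#' @param pixel_size_nm physical pixel size, nm.
#' @param psf_sd_px Gaussian PSF SD in pixels (must be >= 0.5; narrower is
#'   unresolvable on the pixel grid).
#' @param photon_budget expected photons collected from the bead per frame.
#' @param background expected background photons per pixel per frame.
#' @param ny,margin_px frame height and lateral margin; the frame width is
#'   sized to keep the bead inside.
#' @param seed RNG seed for the shot noise.
#' @return `fs_bead_stack`: list with `frames` (list of matrices, photons),
#'   `centers` (data frame `frame`, `x_px`, `y_px`), `pixel_size_nm`, `cal`,
#'   `time`.
#' @export
simulate_bead_stack <- function(trajectory, cal, pixel_size_nm = 100,
                                psf_sd_px = 1.3, photon_budget = 5000,
                                background = 10, ny = 15, margin_px = 8,
                                seed = 1) {
  stopifnot(inherits(cal, "calibration"))
  if (psf_sd_px < 0.5)
    stop("simulate_bead_stack: PSF narrower than 0.5 px is unresolvable")
  if (inherits(trajectory, "fs_trajectory")) {
    pos_bp <- trajectory$position
    times <- trajectory$time
  } else {
    pos_bp <- as.numeric(trajectory)
    times <- seq_along(pos_bp)
  }
  x_px <- bases_to_displacement(pos_bp - pos_bp[1], cal) / pixel_size_nm
  x0 <- margin_px + 1
  xs <- x0 + x_px
  nx <- ceiling(max(xs)) + margin_px
  y0 <- (ny + 1) / 2
  frames <- .with_seed(seed, lapply(seq_along(xs), function(i) {
    gx <- .pixel_profile(seq_len(nx), xs[i], psf_sd_px)
    gy <- .pixel_profile(seq_len(ny), y0, psf_sd_px)
    lambda <- photon_budget * outer(gy, gx) + background
    matrix(stats::rpois(length(lambda), lambda), nrow = ny)
  }))
  structure(list(frames = frames,
                 centers = data.frame(frame = seq_along(xs),
                                      x_px = xs, y_px = y0),
                 pixel_size_nm = pixel_size_nm, cal = cal, time = times),
            class = "fs_bead_stack")
}

#' Write / read a bead stack as multi-page 16-bit TIFF with a sidecar CSV
#' of true centers
#'
#' Photon counts are stored clipped to the 16-bit range.
#'
#' @param stack an `fs_bead_stack`.
#' @param tiff_path output TIFF path.
#' @param centers_path optional sidecar CSV path for the true centers.
#' @return `write_bead_stack`: the TIFF path, invisibly.  `read_bead_stack`:
#'   a list with `frames` (matrices of photon counts) and `centers` (or NULL).
#' @export
write_bead_stack <- function(stack, tiff_path, centers_path = NULL) {
  stopifnot(inherits(stack, "fs_bead_stack"))
  imgs <- lapply(stack$frames, function(f) pmin(f, 65535) / 65535)
  tiff::writeTIFF(imgs, tiff_path, bits.per.sample = 16)
  if (!is.null(centers_path))
    utils::write.csv(stack$centers, centers_path, row.names = FALSE)
  invisible(tiff_path)
}

#' @rdname write_bead_stack
#' @export
read_bead_stack <- function(tiff_path, centers_path = NULL) {
  imgs <- tiff::readTIFF(tiff_path, all = TRUE)
  frames <- lapply(imgs, function(m) round(m * 65535))
  centers <- if (!is.null(centers_path))
    utils::read.csv(centers_path, stringsAsFactors = FALSE) else NULL
  list(frames = frames, centers = centers)
}
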