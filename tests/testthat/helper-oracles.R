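# Independent oracles used by the tests.  These deliberately re-derive
# results by brute force (bisection, exhaustive enumeration, grid search)
# and never share code paths with the package implementation beyond the
# declared objective functions.

# Evaluate expr under a fixed seed without disturbing the test RNG stream.
.with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Worm-like-chain fractional extension by plain bisection on (0, 1).
oracle_wlc_fraction <- function(force, persistence = 50, temperature = 298) {
  kT <- 1.380649e-2 * temperature
  f <- function(z) (kT / persistence) * (1 / (4 * (1 - z)^2) - 0.25 + z) - force
  lo <- 0; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Freely-jointed-chain extension per nt via an independent arrangement of
# the Langevin function (explicit exponentials instead of tanh).
oracle_fjc_per_nt <- function(force, contour = 0.56, kuhn = 1.5,
                              temperature = 298) {
  if (force == 0) return(0)
  kT <- 1.380649e-2 * temperature
  x <- force * kuhn / kT
  coth <- (exp(x) + exp(-x)) / (exp(x) - exp(-x))
  contour * (coth - 1 / x)
}

# Exhaustive penalized-SSE segmentation oracle: tries every placement of up
# to max_cp changepoints (segments of >= minseg frames) and returns the best
# objective value and segment starts.  Ties resolved toward fewer segments
# (candidate sets are visited in order of increasing changepoint count).
oracle_segment <- function(t, x, beta, max_cp = 3, minseg = 2) {
  n <- length(t)
  cost <- flowstretch:::.seg_cost_fun(t, x)
  # full cost matrix so candidate evaluation is table lookup
  CM <- matrix(Inf, n, n)
  for (j in minseg:n) {
    is <- seq_len(j - minseg + 1L)
    CM[cbind(is, j)] <- cost(is, j)
  }
  best_val <- CM[1, n]
  best_starts <- 1L
  for (k in seq_len(max_cp)) {
    cand <- utils::combn((minseg + 1L):(n - minseg + 1L), k)
    m <- ncol(cand)
    starts <- rbind(rep(1L, m), cand)        # (k+1) x m
    ends <- rbind(cand - 1L, rep(n, m))
    ok <- colSums((ends - starts + 1L) >= minseg) == k + 1L
    if (!any(ok)) next
    starts <- starts[, ok, drop = FALSE]
    ends <- ends[, ok, drop = FALSE]
    vals <- matrix(CM[cbind(as.vector(starts), as.vector(ends))],
                   nrow = k + 1L)
    tot <- colSums(vals) + beta * k
    b <- which.min(tot)
    if (tot[b] < best_val - 1e-9) {
      best_val <- tot[b]
      best_starts <- starts[, b]
    }
  }
  list(value = best_val, starts = as.integer(best_starts))
}

# Zooming grid-search least-squares oracle for the burst equation.
oracle_burst_grid <- function(t, y, A_range, k_range, C_range,
                              steps = 15, zooms = 6) {
  sse <- function(A, k, C) sum((y - (A * (1 - exp(-k * t)) + C))^2)
  best <- c(A = mean(A_range), k = mean(k_range), C = mean(C_range))
  for (z in seq_len(zooms)) {
    As <- seq(A_range[1], A_range[2], length.out = steps)
    ks <- seq(k_range[1], k_range[2], length.out = steps)
    Cs <- seq(C_range[1], C_range[2], length.out = steps)
    vals <- expand.grid(A = As, k = ks, C = Cs)
    s <- mapply(sse, vals$A, vals$k, vals$C)
    b <- vals[which.min(s), ]
    best <- c(A = b$A, k = b$k, C = b$C)
    shrink <- function(r, center) {
      w <- (r[2] - r[1]) / 4
      c(max(center - w, 0), center + w)
    }
    A_range <- shrink(A_range, b$A)
    k_range <- shrink(k_range, b$k)
    C_range <- c(b$C - (C_range[2] - C_range[1]) / 4,
                 b$C + (C_range[2] - C_range[1]) / 4)
  }
  c(best, sse = sse(best["A"], best["k"], best["C"]))
}

# Zooming 2-D grid oracle for the hyperbolic kobs-[dNTP] fit.
oracle_mm_grid <- function(conc, kobs, kpol_range, Kd_range,
                           steps = 40, zooms = 6) {
  sse <- function(kpol, Kd) sum((kobs - kpol * conc / (Kd + conc))^2)
  best <- c(kpol = mean(kpol_range), Kd = mean(Kd_range))
  for (z in seq_len(zooms)) {
    kps <- seq(kpol_range[1], kpol_range[2], length.out = steps)
    kds <- seq(Kd_range[1], Kd_range[2], length.out = steps)
    vals <- expand.grid(kpol = kps, Kd = kds)
    s <- mapply(sse, vals$kpol, vals$Kd)
    b <- vals[which.min(s), ]
    best <- c(kpol = b$kpol, Kd = b$Kd)
    shrink <- function(r, center) {
      w <- (r[2] - r[1]) / 4
      c(max(center - w, 1e-9), center + w)
    }
    kpol_range <- shrink(kpol_range, b$kpol)
    Kd_range <- shrink(Kd_range, b$Kd)
  }
  c(best, sse = sse(best["kpol"], best["Kd"]))
}

# Piecewise-linear noiseless trace builder: segments given as (frames, slope).
build_trace <- function(segments, dt = 0.5, x0 = 0) {
  t <- numeric(0); x <- numeric(0)
  cur_t <- 0; cur_x <- x0
  for (s in segments) {
    tt <- cur_t + dt * seq(0, s$frames - 1)
    xx <- cur_x + s$slope * (tt - cur_t)
    t <- c(t, tt); x <- c(x, xx)
    cur_t <- tt[length(tt)] + dt
    cur_x <- xx[length(xx)] + s$slope * dt
  }
  data.frame(t_s = t, x_bp = x)
}
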