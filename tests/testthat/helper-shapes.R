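# shared fixtures, all generated in code

# smooth random closed contour: unit-ish ellipse plus decaying random
# harmonics, sampled at n points
random_smooth_contour <- function(n = 240L, H = 6L) {
  co <- matrix(stats::rnorm(4L * H, 0, 0.4), H, 4L) / (seq_len(H)^2)
  co[1L, ] <- c(1.2, 0, 0, 0.8)
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  xs <- numeric(n); ys <- numeric(n)
  for (k in seq_len(H)) {
    xs <- xs + co[k, 1L] * cos(k * t) + co[k, 2L] * sin(k * t)
    ys <- ys + co[k, 3L] * cos(k * t) + co[k, 4L] * sin(k * t)
  }
  enforce_orientation(contour(cbind(xs, ys)))
}

# independent quadrature oracle for the first-harmonic coefficients of a
# parametric curve under arc-length parametrization (trapezoid-free simple
# midpoint sums at high resolution; deliberately not the Kuhl path)
arc_length_first_harmonic <- function(fx, fy, n = 100000L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- fx(th); y <- fy(th)
  dx <- diff(c(x, x[1L])); dy <- diff(c(y, y[1L]))
  ds <- sqrt(dx^2 + dy^2)
  s <- c(0, cumsum(ds))[seq_len(n)]
  L <- sum(ds)
  w <- 2 * pi * s / L
  c(a1 = 2 / L * sum(x * cos(w) * ds), b1 = 2 / L * sum(x * sin(w) * ds),
    c1 = 2 / L * sum(y * cos(w) * ds), d1 = 2 / L * sum(y * sin(w) * ds))
}

# three well-separated Gaussian blobs in 2-D
separable_blobs <- function(n_per = 15L, sd = 0.1, gap = 5) {
  centers <- rbind(c(0, 0), c(gap, 0), c(0, gap))
  X <- do.call(rbind, lapply(1:3, function(k)
    cbind(stats::rnorm(n_per, centers[k, 1L], sd),
          stats::rnorm(n_per, centers[k, 2L], sd))))
  list(X = X, labels = rep(c("a", "b", "c"), each = n_per))
}

# quick measurements table with plausible pronotum proportions
random_measurements <- function(n = 20L) {
  base <- exp(stats::rnorm(n, 0, 0.1))
  data.frame(id = sprintf("s%02d", seq_len(n)),
             pw = 1500 * base * exp(stats::rnorm(n, 0, 0.03)),
             pm = 700 * base * exp(stats::rnorm(n, 0, 0.03)),
             pc = 150 * base * exp(stats::rnorm(n, 0, 0.06)))
}
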