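#' Elliptic Fourier analysis of a closed contour
#'
#' Decomposes the x(t), y(t) traversal of a closed pseudolandmark contour
#' into `H` harmonics using the classical closed-form sums for a
#' piecewise-linear, chord-length parametrized curve. Each harmonic `n`
#' contributes four coefficients (a_n, b_n, c_n, d_n) describing an ellipse;
#' the constant terms (a0, c0) are the parametrization-weighted centroid.
#'
#' The `parametrization` choice sets the weight each polygon segment gets in
#' the Fourier sums. `"chord"` (default) is the classical convention: the
#' parameter advances with chord length, approximating arc length.
#' `"uniform"` advances the parameter by one unit per point regardless of
#' spacing (equal point weighting); for contours digitized at equal angular
#' or index spacing this reproduces closed-form series exactly (e.g. an
#' equal-angle-sampled ellipse collapses onto its first harmonic), and some
#' digitization software weights points this way. The two agree when points
#' are equally spaced along the outline.
#'
#' @param x a counterclockwise [contour()].
#' @param H number of harmonics, `1 <= H <= floor(P/2)` for `P` contour
#'   points.
#' @param parametrization `"chord"` (chord-length weighting, the classical
#'   closed-form sums) or `"uniform"` (equal point weighting).
#' @return An object of class `efa_coefficients`: list with `a0`, `c0`,
#'   `H` and an `H x 4` matrix `coef` with columns `a`, `b`, `c`, `d`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 201)[-201]
#' circ <- contour(cbind(cos(th), sin(th)))
#' ef <- fit_efa(circ, H = 3)   # (a1, d1) ~ (1, 1), the rest ~ 0
#' @export
fit_efa <- function(x, H = 7L, parametrization = c("chord", "uniform")) {
  stopifnot(inherits(x, "pronotum_contour"))
  parametrization <- match.arg(parametrization)
  if (attr(x, "orientation") != "ccw")
    stop("contour must be counterclockwise; see enforce_orientation()")
  pts <- unclass(x)
  P <- nrow(pts)
  H <- as.integer(H)
  if (H < 1L || H > P %/% 2L)
    stop("H must be in 1..floor(P/2) = 1..", P %/% 2L, ", got ", H)
  nxt <- c(2:P, 1L)
  dxy <- pts[nxt, , drop = FALSE] - pts
  dt <- if (parametrization == "chord") sqrt(rowSums(dxy^2))
        else rep(1, P)
  T_ <- sum(dt)
  t1 <- cumsum(dt)           # t at segment ends
  t0 <- c(0, t1[-P])         # t at segment starts
  a0 <- sum(dt * (pts[, 1L] + pts[nxt, 1L])) / (2 * T_)
  c0 <- sum(dt * (pts[, 2L] + pts[nxt, 2L])) / (2 * T_)
  vx <- dxy[, 1L] / dt
  vy <- dxy[, 2L] / dt
  co <- matrix(0, H, 4L, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(H)) {
    w <- 2 * pi * n / T_
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    k <- T_ / (2 * pi^2 * n^2)
    co[n, ] <- k * c(sum(vx * dcos), sum(vx * dsin),
                     sum(vy * dcos), sum(vy * dsin))
  }
  structure(list(a0 = a0, c0 = c0, H = H, coef = co),
            class = "efa_coefficients")
}

#' @export
print.efa_coefficients <- function(x, ...) {
  cat(sprintf("EFA coefficients: H = %d, centroid (%.4g, %.4g)\n",
              x$H, x$a0, x$c0))
  print(round(x$coef, 6))
  invisible(x)
}

## starting-point rotation angle of the first harmonic
.efa_theta1 <- function(co) {
  a1 <- co[1L, 1L]; b1 <- co[1L, 2L]; c1 <- co[1L, 3L]; d1 <- co[1L, 4L]
  0.5 * atan2(2 * (a1 * b1 + c1 * d1), a1^2 + c1^2 - b1^2 - d1^2)
}

## apply start-point rotation theta (right) and orientation rotation psi
## (left) to all harmonics
.efa_rotate <- function(co, theta, psi) {
  H <- nrow(co)
  out <- co
  L <- matrix(c(cos(psi), -sin(psi), sin(psi), cos(psi)), 2L) # [cos sin; -sin cos]
  for (n in seq_len(H)) {
    M <- matrix(co[n, ], 2L, byrow = TRUE)   # [a b; c d]
    R <- matrix(c(cos(n * theta), sin(n * theta),
                  -sin(n * theta), cos(n * theta)), 2L)
    out[n, ] <- as.numeric(t(L %*% M %*% R))
  }
  out
}

#' Semi-major axis of the first harmonic ellipse
#'
#' The outline-based global size estimate: half the length of the major axis
#' of the ellipse traced by the first Fourier harmonic. Scales exactly
#' linearly with isotropic contour scaling and is invariant to rotation,
#' translation and starting point.
#'
#' @param x an `efa_coefficients` object from [fit_efa()].
#' @return positive scalar, in the contour's units.
#' @export
semi_major_axis <- function(x) {
  stopifnot(inherits(x, "efa_coefficients"))
  co <- x$coef
  if (all(co[1L, ] == 0))
    stop("degenerate first harmonic: all coefficients zero")
  th <- .efa_theta1(co)
  axis_at <- function(t) {
    xa <- co[1L, 1L] * cos(t) + co[1L, 2L] * sin(t)
    ya <- co[1L, 3L] * cos(t) + co[1L, 4L] * sin(t)
    sqrt(xa^2 + ya^2)
  }
  max(axis_at(th), axis_at(th + pi / 2))
}

#' Normalized elliptic Fourier (NEF) coefficients
#'
#' Removes position, starting point, rotation and size from raw EFA
#' coefficients by the standard three-step normalization: (i) rotate the
#' parameter origin onto the major axis of the first harmonic ellipse,
#' (ii) rotate the frame so the major axis lies on x, (iii) divide by the
#' semi-major axis. By construction `a*_1 = 1`, `b*_1 = c*_1 = 0`, leaving
#' `4H - 3` free shape variables.
#'
#' Two residual ambiguities are fixed deterministically: the 180-degree
#' starting-point ambiguity by requiring the first non-negligible
#' even-harmonic coefficient to be positive, and the reflection ambiguity by
#' requiring `d*_1 >= 0` (automatic for counterclockwise contours).
#'
#' @param x an `efa_coefficients` object from [fit_efa()].
#' @return An object of class `nef_coefficients`: list with `H`, the `H x 4`
#'   normalized `coef` matrix, and `size`, the semi-major axis removed in
#'   step (iii).
#' @export
normalize_efa <- function(x) {
  stopifnot(inherits(x, "efa_coefficients"))
  co <- x$coef
  if (sum(co[1L, ]^2) == 0)
    stop("degenerate first harmonic: all coefficients zero")
  th <- .efa_theta1(co)
  ax <- function(t) {
    c(co[1L, 1L] * cos(t) + co[1L, 2L] * sin(t),
      co[1L, 3L] * cos(t) + co[1L, 4L] * sin(t))
  }
  if (sum(ax(th)^2) < sum(ax(th + pi / 2)^2)) th <- th + pi / 2

  norm_for <- function(theta) {
    v <- ax(theta)
    psi <- atan2(v[2L], v[1L])
    out <- .efa_rotate(co, theta, psi)
    out / sqrt(sum(v^2))
  }
  cand <- list(norm_for(th), norm_for(th + pi))
  pick <- 1L
  if (nrow(co) >= 2L) {
    even <- seq(2L, nrow(co), by = 2L)
    v1 <- as.numeric(t(cand[[1L]][even, , drop = FALSE]))
    j <- which(abs(v1) > 1e-8)
    if (length(j) && v1[j[1L]] < 0) pick <- 2L
  }
  nf <- cand[[pick]]
  if (nf[1L, 4L] < 0) {      # reflection fix: flip y
    nf[, 3L] <- -nf[, 3L]
    nf[, 4L] <- -nf[, 4L]
  }
  # snap the constrained entries to their exact values
  nf[1L, 1L] <- 1
  nf[1L, 2L] <- 0
  nf[1L, 3L] <- 0
  structure(list(H = x$H, coef = nf, size = semi_major_axis(x)),
            class = "nef_coefficients")
}

#' @export
print.nef_coefficients <- function(x, ...) {
  cat(sprintf("NEF coefficients: H = %d, size (semi-major axis) = %.6g\n",
              x$H, x$size))
  print(round(x$coef, 6))
  invisible(x)
}

#' Reconstruct a contour from Fourier coefficients
#'
#' Evaluates the truncated Fourier series at `n_points` equally spaced
#' parameter values. Works on raw (`efa_coefficients`) and normalized
#' (`nef_coefficients`) descriptors; the latter reconstruct the pure shape
#' at unit semi-major axis around the origin.
#'
#' @param x `efa_coefficients` or `nef_coefficients`.
#' @param n_points number of points to evaluate, `>= 8`.
#' @return a [contour()].
#' @export
inverse_efa <- function(x, n_points = 200L) {
  n_points <- as.integer(n_points)
  if (n_points < 8L) stop("n_points must be >= 8")
  if (inherits(x, "nef_coefficients")) {
    a0 <- 0; c0 <- 0; co <- x$coef
  } else if (inherits(x, "efa_coefficients")) {
    a0 <- x$a0; c0 <- x$c0; co <- x$coef
  } else stop("x must be efa_coefficients or nef_coefficients")
  t <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  xs <- rep(a0, n_points)
  ys <- rep(c0, n_points)
  for (n in seq_len(nrow(co))) {
    cn <- cos(n * t); sn <- sin(n * t)
    xs <- xs + co[n, 1L] * cn + co[n, 2L] * sn
    ys <- ys + co[n, 3L] * cn + co[n, 4L] * sn
  }
  tryCatch(contour(cbind(xs, ys)), error = function(e) {
    warning("degenerate reconstruction (", conditionMessage(e),
            "); returning bare coordinates")
    cbind(x = xs, y = ys)
  })
}

#' Coefficient-wise mean shape
#'
#' Arithmetic mean of a set of NEF coefficient objects sharing the same
#' harmonic count. The normalization constraints (`a*_1 = 1`,
#' `b*_1 = c*_1 = 0`) are preserved exactly.
#'
#' @param nefs list of `nef_coefficients` with identical `H`.
#' @return a `nef_coefficients` object; its `size` is the mean of the input
#'   sizes.
#' @export
mean_shape <- function(nefs) {
  if (!length(nefs)) stop("empty collection")
  if (!all(vapply(nefs, inherits, TRUE, "nef_coefficients")))
    stop("all elements must be nef_coefficients")
  Hs <- vapply(nefs, `[[`, 1L, "H")
  if (length(unique(Hs)) != 1L)
    stop("mixed harmonic counts: ", paste(unique(Hs), collapse = ", "))
  co <- Reduce(`+`, lapply(nefs, `[[`, "coef")) / length(nefs)
  structure(list(H = Hs[1L], coef = co,
                 size = mean(vapply(nefs, `[[`, 1, "size"))),
            class = "nef_coefficients")
}

#' NEF feature matrix
#'
#' Stacks the free NEF shape variables of a set of specimens into a numeric
#' matrix suitable for classification and clustering. The constant entries
#' `a*_1`, `b*_1`, `c*_1` are dropped; the remaining `4H - 3` columns are
#' ordered `d1, a2, b2, c2, d2, ..., aH, bH, cH, dH`.
#'
#' @param nefs named list of `nef_coefficients` sharing `H`.
#' @return numeric matrix, one row per specimen (rownames from `nefs`
#'   names), `4H - 3` columns.
#' @export
nef_feature_matrix <- function(nefs) {
  if (!length(nefs)) stop("empty collection")
  Hs <- vapply(nefs, `[[`, 1L, "H")
  if (length(unique(Hs)) != 1L)
    stop("mixed harmonic counts: ", paste(unique(Hs), collapse = ", "))
  H <- Hs[1L]
  cols <- "d1"
  if (H > 1L)
    cols <- c(cols, as.vector(t(outer(2:H, c("a", "b", "c", "d"),
                                      function(n, l) paste0(l, n)))))
  feat <- t(vapply(nefs, function(nf) {
    v <- as.numeric(t(nf$coef))   # a1 b1 c1 d1 a2 b2 ...
    v[-(1:3)]
  }, numeric(4L * H - 3L)))
  if (H == 1L) feat <- matrix(feat, ncol = 1L,
                              dimnames = list(names(nefs), NULL))
  colnames(feat) <- cols
  feat
}

#' Cumulative harmonic power
#'
#' Diagnostic for choosing the harmonic count: the power of harmonic `n` is
#' `(a_n^2 + b_n^2 + c_n^2 + d_n^2) / 2`; the cumulative proportion shows
#' how much outline signal the first `n` harmonics capture.
#'
#' @param x `efa_coefficients` or `nef_coefficients`.
#' @return data frame with columns `harmonic`, `power`,
#'   `cumulative_proportion`.
#' @export
harmonic_power <- function(x) {
  co <- if (inherits(x, c("efa_coefficients", "nef_coefficients"))) x$coef
        else stop("x must be efa_coefficients or nef_coefficients")
  p <- rowSums(co^2) / 2
  data.frame(harmonic = seq_len(nrow(co)), power = p,
             cumulative_proportion = cumsum(p) / sum(p))
}
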