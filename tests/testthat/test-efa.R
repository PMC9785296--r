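test_that("a circle collapses onto its first harmonic", {
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- contour(cbind(cos(th), sin(th)))
  ef <- fit_efa(circ, H = 3)
  expect_equal(unname(ef$coef[1L, ]), c(1, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(ef$coef[2:3, ])), 1e-3)
  expect_equal(semi_major_axis(ef), 1, tolerance = 1e-3)
  nf <- normalize_efa(ef)
  expect_equal(unname(nf$coef[1L, 4L]), 1, tolerance = 1e-3)
  expect_lt(max(abs(nf$coef[2:3, ])), 1e-3)
})

test_that("ellipse coefficients match the analytic series per parametrization", {
  te <- seq(0, 2 * pi, length.out = 401)[-401]
  ell <- contour(cbind(2 * cos(te), sin(te)))
  # equal point weighting reproduces the closed-form theta-series: the
  # equal-angle-sampled ellipse is a pure first harmonic (2, 1)
  ef_u <- fit_efa(ell, H = 5, parametrization = "uniform")
  expect_equal(unname(ef_u$coef[1L, ]), c(2, 0, 0, 1), tolerance = 1e-3)
  expect_lt(max(abs(ef_u$coef[2:5, ])), 1e-3)
  expect_equal(semi_major_axis(ef_u), 2, tolerance = 1e-2)
  # chord-length weighting matches the independent arc-length quadrature
  # oracle instead (the ellipse is not a single harmonic in arc length)
  oracle <- arc_length_first_harmonic(function(t) 2 * cos(t), sin)
  ef_c <- fit_efa(ell, H = 5, parametrization = "chord")
  expect_equal(unname(ef_c$coef[1L, ]), unname(oracle), tolerance = 2e-3)
  expect_equal(semi_major_axis(ef_c), unname(oracle["a1"]),
               tolerance = 1e-2)
  expect_equal(semi_major_axis(ef_c), 1.8284, tolerance = 1e-2)
})

test_that("translation moves only the DC terms", {
  set.seed(11)
  ct <- random_smooth_contour(160)
  ef <- fit_efa(ct, H = 5)
  ef2 <- fit_efa(transform_contour(ct, shift = c(5, 7)), H = 5)
  expect_equal(ef2$coef, ef$coef, tolerance = 1e-12)
  expect_equal(ef2$a0 - ef$a0, 5, tolerance = 1e-9)
  expect_equal(ef2$c0 - ef$c0, 7, tolerance = 1e-9)
})

test_that("semi-major axis scales exactly and ignores rigid motions", {
  set.seed(12)
  ct <- random_smooth_contour(200)
  s0 <- semi_major_axis(fit_efa(ct, H = 6))
  # powers of two scale the whole computation exactly
  expect_identical(semi_major_axis(fit_efa(transform_contour(ct, scale = 2),
                                           H = 6)), 2 * s0)
  expect_equal(semi_major_axis(fit_efa(transform_contour(ct, scale = 1.7),
                                       H = 6)), 1.7 * s0,
               tolerance = 1e-12)
  expect_equal(semi_major_axis(fit_efa(transform_contour(ct, angle = 1.1,
                                                         shift = c(3, -4)),
                                       H = 6)), s0, tolerance = 1e-9)
})

test_that("NEF coefficients are invariant to pose, size and starting point", {
  set.seed(13)
  for (rep in 1:10) {
    ct <- random_smooth_contour(180)
    n0 <- normalize_efa(fit_efa(ct, H = 6))
    expect_equal(n0$coef[1L, 1:3], c(a = 1, b = 0, c = 0),
                 ignore_attr = TRUE)
    expect_gte(n0$coef[1L, 4L], 0)
    tr <- transform_contour(ct, angle = stats::runif(1, 0, 2 * pi),
                            scale = stats::runif(1, 0.2, 5),
                            shift = stats::rnorm(2, 0, 10),
                            start = sample.int(180, 1))
    n1 <- normalize_efa(fit_efa(tr, H = 6))
    expect_lt(max(abs(n1$coef - n0$coef)), 1e-6)
  }
})

test_that("inverse reconstruction converges and is idempotent", {
  te <- seq(0, 2 * pi, length.out = 401)[-401]
  ell <- contour(cbind(2 * cos(te), sin(te)))
  # uniform H=1 fit of an equal-angle ellipse reconstructs it analytically
  rec <- inverse_efa(fit_efa(ell, H = 1, parametrization = "uniform"),
                     n_points = 400)
  expect_lt(max(abs(unclass(rec) - unclass(ell))), 1e-2)
  # fit -> inverse -> fit is the identity once the reconstruction is dense
  set.seed(14)
  ct <- random_smooth_contour(220)
  ef <- fit_efa(ct, H = 6, parametrization = "uniform")
  dense <- inverse_efa(ef, n_points = 32768)
  ef2 <- fit_efa(dense, H = 6, parametrization = "uniform")
  expect_lt(max(abs(ef2$coef - ef$coef)), 1e-6)
  expect_lt(abs(ef2$a0 - ef$a0) + abs(ef2$c0 - ef$c0), 1e-6)
  # DC-only coefficients degenerate to the centroid
  flat <- structure(list(a0 = 3, c0 = -2, H = 1L,
                         coef = matrix(0, 1, 4)),
                    class = "efa_coefficients")
  expect_warning(pts <- inverse_efa(flat, 20), "degenerate")
  expect_equal(unique(round(as.matrix(pts), 12)),
               matrix(c(3, -2), 1), ignore_attr = TRUE)
})

test_that("reconstruction error decreases as harmonics are added", {
  set.seed(15)
  ct <- random_smooth_contour(240, H = 6)
  pts <- unclass(ct)
  errs <- vapply(1:6, function(h) {
    rec <- unclass(inverse_efa(fit_efa(ct, H = h), n_points = 720))
    # mean distance from each original vertex to the reconstruction
    mean(vapply(seq_len(nrow(pts)), function(i) {
      sqrt(min((rec[, 1L] - pts[i, 1L])^2 + (rec[, 2L] - pts[i, 2L])^2))
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(errs) <= 1e-9))
  hp <- harmonic_power(fit_efa(ct, H = 6))
  expect_true(all(diff(hp$cumulative_proportion) >= 0))
})

test_that("mean shapes average coefficient-wise and keep the constraints", {
  set.seed(16)
  n1 <- normalize_efa(fit_efa(random_smooth_contour(100), H = 4))
  expect_equal(mean_shape(list(n1))$coef, n1$coef)
  n2 <- n1; n2$coef[2L, 4L] <- n1$coef[2L, 4L] + 0.1
  n3 <- n1; n3$coef[2L, 4L] <- n1$coef[2L, 4L] - 0.1
  ms <- mean_shape(list(n2, n3))
  expect_equal(ms$coef, n1$coef)
  many <- mean_shape(rep(list(n1), 7))
  expect_equal(many$coef, n1$coef)
  expect_equal(unname(ms$coef[1L, ]),
               c(1, 0, 0, unname(n1$coef[1L, 4L])))
  n_h3 <- normalize_efa(fit_efa(random_smooth_contour(100), H = 3))
  expect_error(mean_shape(list(n1, n_h3)), "mixed")
})

test_that("the NEF feature matrix drops the constrained entries", {
  set.seed(17)
  cts <- replicate(3, random_smooth_contour(120), simplify = FALSE)
  nefs1 <- lapply(cts, function(ct) normalize_efa(fit_efa(ct, H = 1)))
  expect_equal(ncol(nef_feature_matrix(nefs1)), 1L)
  nefs7 <- lapply(cts, function(ct) normalize_efa(fit_efa(ct, H = 7)))
  fm <- nef_feature_matrix(nefs7)
  expect_equal(ncol(fm), 25L)
  expect_equal(colnames(fm)[1:5], c("d1", "a2", "b2", "c2", "d2"))
  twin <- nef_feature_matrix(list(x = nefs7[[1]], y = nefs7[[1]]))
  expect_equal(twin["x", ], twin["y", ])
})

test_that("H beyond the point budget and degenerate harmonics are errors", {
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  ct <- contour(cbind(cos(th), sin(th)))
  expect_error(fit_efa(ct, H = 11), "floor")
  degen <- structure(list(a0 = 0, c0 = 0, H = 1L, coef = matrix(0, 1, 4)),
                     class = "efa_coefficients")
  expect_error(semi_major_axis(degen), "degenerate")
  expect_error(normalize_efa(degen), "degenerate")
})
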