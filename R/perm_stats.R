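#' Permutation ANOVA on a size variable
#'
#' One-way analysis of variance whose p-value is obtained by permuting group
#' labels rather than from the F distribution. The observed statistic is the
#' classical F-ratio; labels are permuted uniformly `n_perm` times and the
#' p-value is `(b + 1) / (n_perm + 1)` with `b` the number of permuted
#' statistics at least as large as the observed one — a valid test whose
#' smallest attainable p is `1 / (n_perm + 1)`.
#'
#' @param values numeric vector of per-specimen sizes.
#' @param labels group labels, same length; at least 2 groups with at least
#'   2 members each.
#' @param n_perm number of permutations, `>= 99`; 1000 cycles is the
#'   conventional choice here.
#' @param seed integer seed fixing the permutation stream; the global RNG
#'   state is left untouched.
#' @param statistic optional replacement statistic,
#'   `function(values, group_index, k)` returning a scalar to be compared
#'   upper-tail; the default is the F-ratio.
#' @return An object of class `perm_test`: list with `statistic` (observed
#'   F), `p_value`, `n_perm`, `df` (total degrees of freedom, N - 1),
#'   `df_between`, `df_within`, `seed` and `perm_stats` (the permuted
#'   statistics).
#' @examples
#' set.seed(1)
#' permutation_anova(c(rnorm(10), rnorm(10, 2)), rep(c("A", "B"), each = 10),
#'                   n_perm = 999, seed = 42)
#' @export
permutation_anova <- function(values, labels, n_perm = 1000L, seed = 1L,
                              statistic = NULL) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) stop("values must be finite")
  g <- factor(labels)
  if (length(g) != length(values)) stop("values and labels lengths differ")
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  sizes <- tabulate(g, k)
  if (any(sizes < 2L))
    stop("every group needs >= 2 members; sizes: ",
         paste(sizes, collapse = ", "))
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("n_perm must be >= 99")
  N <- length(values)
  gi <- as.integer(g)
  stat_fun <- if (is.null(statistic)) .f_ratio else statistic
  obs <- stat_fun(values, gi, k)
  perm <- with_seed(as.integer(seed), {
    vapply(seq_len(n_perm),
           function(i) stat_fun(values, gi[sample.int(N)], k),
           numeric(1L))
  })
  b <- sum(perm >= obs)
  structure(list(statistic = obs, p_value = (b + 1) / (n_perm + 1),
                 n_perm = n_perm, df = N - 1L,
                 df_between = k - 1L, df_within = N - k,
                 seed = as.integer(seed), perm_stats = perm),
            class = "perm_test")
}

## classical one-way F-ratio; returns 0 for zero between-group variance and
## +Inf for zero within-group variance with nonzero between
.f_ratio <- function(v, gi, k) {
  N <- length(v)
  gs <- rowsum_int(v, gi, k)
  ns <- tabulate(gi, k)
  grand <- sum(v) / N
  ssb <- sum(gs^2 / ns) - N * grand^2
  sst <- sum(v^2) - N * grand^2
  ssw <- sst - ssb
  if (ssb <= 0) return(0)
  if (ssw <= .Machine$double.eps * sst) return(Inf)
  (ssb / (k - 1)) / (ssw / (N - k))
}

## group sums without factor overhead
rowsum_int <- function(v, gi, k) {
  out <- numeric(k)
  for (i in seq_along(v)) out[gi[i]] <- out[gi[i]] + v[i]
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation ANOVA: F = %.4g, df = %d, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$df, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Total ANOVA degrees of freedom
#'
#' The degrees-of-freedom convention used when reporting the permutation
#' tests: the total for the stratum, `N - 1` over all groups entering the
#' test.
#'
#' @param group_sizes vector of group sizes, all `>= 1`.
#' @return integer, `sum(group_sizes) - 1`.
#' @examples
#' anova_df(c(14, 7, 12))  # 32
#' @export
anova_df <- function(group_sizes) {
  if (!length(group_sizes)) stop("empty group sizes")
  gs <- as.integer(group_sizes)
  if (anyNA(gs) || any(gs < 1L)) stop("group sizes must be integers >= 1")
  sum(gs) - 1L
}

#' Allometric determination coefficients
#'
#' Quantifies the influence of size on shape by regressing each shape
#' variable (LSR1/LSR2 or the first two PCs of the NEF coefficients) onto
#' the size estimate by ordinary least squares, and reporting the
#' determination coefficient R-squared per column.
#'
#' @param shape_vars numeric matrix or data frame of shape scores, typically
#'   2 columns.
#' @param size numeric vector of per-specimen size estimates, same length.
#' @return named numeric vector of R-squared values in `[0, 1]`, one per
#'   shape column.
#' @export
allometry_r2 <- function(shape_vars, size) {
  sv <- as.matrix(shape_vars)
  size <- as.numeric(size)
  if (nrow(sv) != length(size)) stop("shape_vars and size lengths differ")
  if (stats::var(size) <= 0) stop("size has zero variance")
  r2 <- apply(sv, 2L, function(y) {
    vy <- stats::var(y)
    if (vy <= 0) return(0)
    stats::cor(y, size)^2
  })
  names(r2) <- if (!is.null(colnames(sv))) colnames(sv)
               else paste0("shape", seq_len(ncol(sv)))
  r2
}

#' First two principal components of a shape feature matrix
#'
#' Covariance-matrix PCA of a (within-sex) shape feature matrix, used to
#' obtain the two leading shape axes for the allometry analysis of the
#' outline branch. Components are oriented so their largest-magnitude
#' loading is positive.
#'
#' @param features numeric matrix, specimens in rows.
#' @param k number of components (default 2).
#' @return matrix of PC scores, `k` columns named `PC1`, `PC2`, ...
#' @export
shape_pc_scores <- function(features, k = 2L) {
  features <- as.matrix(features)
  k <- min(as.integer(k), ncol(features), nrow(features) - 1L)
  if (k < 1L) stop("not enough data for PCA")
  pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) sc[, j] <- -sc[, j]
  }
  colnames(sc) <- paste0("PC", seq_len(k))
  rownames(sc) <- rownames(features)
  sc
}
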