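#' Darroch-Mosimann log-size
#'
#' The per-specimen mean of the natural-log-transformed linear measurements
#' (pw, pm, pc): the isometric size estimate of linear morphometry. Under a
#' global unit change by factor `k`, log-size shifts by `log(k)` while the
#' log-shape ratios are unchanged.
#'
#' @param m data frame (or matrix) with columns `pw`, `pm`, `pc`, all
#'   strictly positive.
#' @return numeric vector of log-sizes, one per row.
#' @examples
#' log_size(data.frame(pw = 2, pm = 4, pc = 8))  # log 4
#' @export
log_size <- function(m) {
  v <- .lsr_values(m)
  rowMeans(log(v))
}

.lsr_values <- function(m) {
  m <- as.data.frame(m)
  if (!all(c("pw", "pm", "pc") %in% names(m)))
    stop("need columns pw, pm, pc")
  v <- as.matrix(m[, c("pw", "pm", "pc")])
  if (anyNA(v) || any(v <= 0))
    stop("all measurements must be strictly positive")
  v
}

#' Log-shape ratios (LSR1, LSR2)
#'
#' Size-free shape variables from the three linear measurements, following
#' Darroch and Mosimann: each specimen's log measurements are centered by its
#' own log-size (row-centering), and the resulting n x 3 table is submitted
#' to a covariance-matrix PCA. Row-centering costs one degree of freedom, so
#' the last principal component is null and dropped; the scores on the two
#' remaining components are LSR1 and LSR2.
#'
#' Each component is oriented so its loading on `pw` is non-negative, making
#' score signs reproducible. `centering = "column"` replaces the
#' Darroch-Mosimann row-centering by plain column-centering of the logs (in
#' which case size is *not* removed and all three PCs carry variance; the
#' last is still dropped for comparability).
#'
#' @param m data frame with columns `pw`, `pm`, `pc` (and optionally `id`
#'   used for rownames); at least 3 rows.
#' @param centering `"row"` (default, Darroch-Mosimann) or `"column"`.
#' @return An object of class `lsr_scores`: list with `log_size` (numeric
#'   vector), `scores` (n x 2 matrix, columns `LSR1`, `LSR2`), `loadings`,
#'   `dropped_pc_variance` and `centering`.
#' @export
log_shape_ratios <- function(m, centering = c("row", "column")) {
  centering <- match.arg(centering)
  v <- .lsr_values(m)
  if (nrow(v) < 3L) stop("need at least 3 specimens, got ", nrow(v))
  ids <- if (!is.null(as.data.frame(m)$id)) as.character(as.data.frame(m)$id)
         else rownames(v)
  lv <- log(v)
  ls <- rowMeans(lv)
  ctr <- if (centering == "row") lv - ls else lv
  tot_var <- sum(apply(ctr, 2L, stats::var))
  if (tot_var < 1e-24) {
    warning("zero shape variance: all specimens share one shape; scores set to 0")
    scores <- matrix(0, nrow(v), 2L, dimnames = list(ids, c("LSR1", "LSR2")))
    return(structure(list(log_size = ls, scores = scores,
                          loadings = NULL, dropped_pc_variance = 0,
                          centering = centering),
                     class = "lsr_scores"))
  }
  pc <- stats::prcomp(ctr, center = TRUE, scale. = FALSE)
  rot <- pc$rotation
  flip <- ifelse(rot["pw", ] < 0, -1, 1)
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)[, 1:2, drop = FALSE]
  dimnames(scores) <- list(ids, c("LSR1", "LSR2"))
  structure(list(log_size = stats::setNames(ls, ids), scores = scores,
                 loadings = rot[, 1:2, drop = FALSE],
                 dropped_pc_variance = pc$sdev[3L]^2,
                 centering = centering),
            class = "lsr_scores")
}

#' @export
print.lsr_scores <- function(x, ...) {
  cat(sprintf("Log-shape ratios (%s-centered): %d specimens\n",
              x$centering, nrow(x$scores)))
  cat(sprintf("  dropped-PC variance: %.3g\n", x$dropped_pc_variance))
  print(utils::head(cbind(log_size = x$log_size, x$scores)))
  if (nrow(x$scores) > 6L) cat("  ...\n")
  invisible(x)
}
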