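#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so package functions never perturb the user's random
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## deterministic 31-bit substream seed derived from a master seed and a
## character key; additive-multiplicative string hash, stable across
## platforms
derive_seed <- function(master, key) {
  h <- as.double(master %% 2147483647L)
  for (b in utf8ToInt(as.character(key))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

#' Compact significance letters from pairwise p-values
#'
#' Assigns letter codes to groups such that two groups share a letter if and
#' only if their pairwise test is non-significant at `alpha` (insertion
#' order: groups sorted by `means` decreasing). This mirrors the usual
#' compact-letter-display convention of size-comparison tables.
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames
#'   (diagonal ignored).
#' @param means named vector of group means used to order the letters.
#' @param alpha significance level, default 0.05.
#' @return named character vector of letter codes.
#' @export
significance_letters <- function(pmat, means, alpha = 0.05) {
  groups <- names(means)[order(-means)]
  nsd <- function(g1, g2) pmat[g1, g2] >= alpha   # not significantly different
  sets <- list()   # each set: character vector of mutually-nsd groups
  for (g in groups) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (all(vapply(sets[[s]], nsd, TRUE, g2 = g))) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  out <- stats::setNames(rep("", length(means)), names(means))
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) out[g] <- paste0(out[g], letters[s])
  }
  out
}

## format "94% (31/33)" style concordance strings
fraction_label <- function(n_correct, n_total) {
  sprintf("%d%% (%d/%d)", round(100 * n_correct / n_total), n_correct,
          n_total)
}
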