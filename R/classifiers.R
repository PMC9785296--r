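#' Leave-one-out maximum-likelihood classification on size
#'
#' Validated reclassification from a single size variable: for each held-out
#' specimen, per-group normal densities are estimated (mean and unbiased
#' variance) from all *other* specimens, and the specimen is assigned to the
#' group maximizing the likelihood of its size. Priors are equal; the
#' procedure is deterministic. A group whose leave-one-out variance is zero
#' is handled by falling back to distance-to-mean for that fold (logged).
#'
#' @param sizes numeric vector of per-specimen sizes (or log-sizes).
#' @param labels group labels, same length; at least 2 groups with at least
#'   3 members each.
#' @return a `classification_report`: list with `mean_accuracy` and
#'   `sd_accuracy` (percent; SD is 0 for this deterministic method),
#'   `per_repeat_accuracy`, `confusion` (true x predicted counts),
#'   `n_correct`, `n_total`, `predicted`.
#' @export
ml_size_classify_loo <- function(sizes, labels) {
  x <- as.numeric(sizes)
  g <- factor(labels)
  if (length(x) != length(g)) stop("sizes and labels lengths differ")
  if (anyNA(x) || any(!is.finite(x))) stop("sizes must be finite")
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 groups")
  if (any(tabulate(g, k) < 3L))
    stop("every group needs >= 3 members for leave-one-out variance")
  n <- length(x)
  pred <- integer(n)
  for (i in seq_len(n)) {
    best <- -Inf; best_g <- 1L; fallback <- FALSE
    for (j in seq_len(k)) {
      xs <- x[-i][g[-i] == levels(g)[j]]
      mu <- mean(xs); s2 <- stats::var(xs)
      if (!is.finite(s2) || s2 <= 0) { fallback <- TRUE; break }
      ll <- stats::dnorm(x[i], mu, sqrt(s2), log = TRUE)
      if (ll > best) { best <- ll; best_g <- j }
    }
    if (fallback) {
      message("zero leave-one-out variance at fold ", i,
              "; assigning by distance to group mean")
      d <- vapply(seq_len(k), function(j)
        abs(x[i] - mean(x[-i][g[-i] == levels(g)[j]])), numeric(1L))
      best_g <- which.min(d)
    }
    pred[i] <- best_g
  }
  predicted <- factor(levels(g)[pred], levels = levels(g))
  .classification_report(truth = g, predicted = predicted,
                         per_repeat = mean(predicted == g),
                         method = "ml_size_loo")
}

.classification_report <- function(truth, predicted, per_repeat, method) {
  conf <- table(truth = truth, predicted = predicted)
  acc <- 100 * per_repeat
  structure(list(per_repeat_accuracy = per_repeat,
                 mean_accuracy = mean(acc),
                 sd_accuracy = if (length(acc) > 1L) stats::sd(acc) else 0,
                 se_accuracy = if (length(acc) > 1L)
                   stats::sd(acc) / sqrt(length(acc)) else 0,
                 confusion = conf,
                 n_correct = sum(predicted == truth),
                 n_total = length(truth),
                 predicted = predicted,
                 method = method),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Validated reclassification (%s): %.1f%% +/- %.1f%% (%d/%d)\n",
              x$method, x$mean_accuracy, x$sd_accuracy, x$n_correct,
              x$n_total))
  print(x$confusion)
  invisible(x)
}

## ---- multilayer perceptron ------------------------------------------------

## Xavier-uniform weight initialization
.mlp_init <- function(n_in, n_hidden, n_out) {
  lim1 <- sqrt(6 / (n_in + n_hidden))
  lim2 <- sqrt(6 / (n_hidden + n_out))
  list(W1 = matrix(stats::runif(n_in * n_hidden, -lim1, lim1), n_in),
       b1 = numeric(n_hidden),
       W2 = matrix(stats::runif(n_hidden * n_out, -lim2, lim2), n_hidden),
       b2 = numeric(n_out))
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

## full-batch gradient descent on cross-entropy, sigmoid hidden and output
.mlp_train <- function(X, Y, n_hidden, lr, epochs) {
  w <- .mlp_init(ncol(X), n_hidden, ncol(Y))
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    Hh <- .sigmoid(sweep(X %*% w$W1, 2L, w$b1, `+`))
    O <- .sigmoid(sweep(Hh %*% w$W2, 2L, w$b2, `+`))
    dO <- (O - Y) / n
    dH <- (dO %*% t(w$W2)) * Hh * (1 - Hh)
    w$W2 <- w$W2 - lr * crossprod(Hh, dO)
    w$b2 <- w$b2 - lr * colSums(dO)
    w$W1 <- w$W1 - lr * crossprod(X, dH)
    w$b1 <- w$b1 - lr * colSums(dH)
  }
  w
}

.mlp_predict <- function(w, X) {
  Hh <- .sigmoid(sweep(X %*% w$W1, 2L, w$b1, `+`))
  O <- .sigmoid(sweep(Hh %*% w$W2, 2L, w$b2, `+`))
  max.col(O, ties.method = "first")
}

#' Leave-one-out validated MLP shape classification
#'
#' Supervised reclassification from shape variables with a small multilayer
#' perceptron: one hidden layer of `hidden` sigmoid units, one-hot sigmoid
#' outputs trained by full-batch backpropagation on cross-entropy loss. Each
#' specimen is predicted by a network trained on all other specimens
#' (leave-one-out), so the reclassified case never contributes to the model;
#' feature standardization uses training-fold statistics only. The whole
#' leave-one-out cycle is repeated `repeats` times with fresh weight
#' initializations, and the mean, SD and standard error of the per-repeat
#' accuracies are reported.
#'
#' @param features numeric matrix of shape variables (specimens x
#'   variables), all finite.
#' @param labels class labels, at least 2 classes. Classes with a single
#'   member have their fold skipped with a warning.
#' @param hidden hidden-layer width, default 3.
#' @param repeats number of full leave-one-out cycles, default 10.
#' @param seed integer seed; each repeat draws its initializations from a
#'   derived substream, so results are reproducible and independent of the
#'   caller's RNG.
#' @param lr learning rate of the full-batch gradient descent, default 0.1.
#' @param epochs training epochs per fold, default 500.
#' @param standardize center/scale features with training-fold statistics
#'   (default TRUE).
#' @return a `classification_report`; `per_repeat_accuracy` holds the
#'   `repeats` accuracies, the confusion matrix is built from per-specimen
#'   majority votes across repeats.
#' @export
mlp_loo_classify <- function(features, labels, hidden = 3L, repeats = 10L,
                             seed = 1L, lr = 0.1, epochs = 500L,
                             standardize = TRUE) {
  X0 <- as.matrix(features)
  if (anyNA(X0) || any(!is.finite(X0))) stop("features must be finite")
  g <- factor(labels)
  if (nrow(X0) != length(g)) stop("features and labels sizes differ")
  k <- nlevels(g)
  if (k < 2L) stop("need at least 2 classes")
  repeats <- as.integer(repeats)
  if (repeats < 1L) stop("repeats must be >= 1")
  n <- nrow(X0)
  singleton <- tabulate(g, k)[as.integer(g)] == 1L
  if (any(singleton))
    warning("skipping leave-one-out folds for single-member classes: ",
            paste(unique(g[singleton]), collapse = ", "))
  folds <- which(!singleton)
  Y <- diag(k)[as.integer(g), , drop = FALSE]
  votes <- matrix(0L, n, k)
  acc <- numeric(repeats)
  for (r in seq_len(repeats)) {
    pred_r <- rep(NA_integer_, n)
    with_seed(derive_seed(seed, paste0("mlp_repeat_", r)), {
      for (i in folds) {
        Xtr <- X0[-i, , drop = FALSE]
        if (standardize) {
          mu <- colMeans(Xtr)
          sdv <- apply(Xtr, 2L, stats::sd)
          sdv[sdv == 0] <- 1
          Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, `/`)
          Xte <- matrix((X0[i, ] - mu) / sdv, 1L)
        } else Xte <- X0[i, , drop = FALSE]
        w <- .mlp_train(Xtr, Y[-i, , drop = FALSE], hidden, lr, epochs)
        pred_r[i] <- .mlp_predict(w, Xte)
      }
    })
    acc[r] <- mean(pred_r[folds] == as.integer(g)[folds])
    ok <- !is.na(pred_r)
    votes[cbind(which(ok), pred_r[ok])] <-
      votes[cbind(which(ok), pred_r[ok])] + 1L
  }
  maj <- max.col(votes[folds, , drop = FALSE], ties.method = "first")
  predicted <- factor(levels(g)[maj], levels = levels(g))
  rep_out <- .classification_report(truth = factor(g[folds],
                                                   levels = levels(g)),
                                    predicted = predicted,
                                    per_repeat = acc, method = "mlp_loo")
  rep_out$n_correct <- NA_integer_  # headline numbers are repeat averages
  rep_out$n_correct <- sum(predicted == g[folds])
  rep_out
}

## ---- clustering -----------------------------------------------------------

#' UPGMA clustering of shape variables
#'
#' Average-linkage hierarchical agglomeration of the Euclidean distance
#' matrix between specimens' shape variables (unweighted pair-group method
#' with arithmetic mean). Merge heights are non-decreasing (ultrametric).
#' Ties are broken deterministically by the agglomeration order of
#' [stats::hclust()].
#'
#' @param features numeric matrix (specimens x shape variables) with
#'   rownames as specimen ids, or a [stats::dist] object.
#' @return an object of classes `upgma` and `hclust`.
#' @export
upgma <- function(features) {
  d <- if (inherits(features, "dist")) features
       else stats::dist(as.matrix(features), method = "euclidean")
  if (attr(d, "Size") < 2L) stop("need at least 2 specimens")
  hc <- stats::hclust(d, method = "average")
  class(hc) <- c("upgma", "hclust")
  hc
}

#' Write a dendrogram to Newick
#'
#' Branch lengths are differences between successive merge heights, so
#' root-to-leaf path lengths reproduce the UPGMA heights.
#'
#' @param x an `upgma`/`hclust` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "hclust"))
  ape::write.tree(ape::as.phylo(x), file = path)
  invisible(path)
}

#' Concordance between a dendrogram cut and species labels
#'
#' Cuts the tree into `k` clusters and matches clusters to species one-to-one
#' so that total agreement is maximal (exhaustive optimal matching over the
#' smaller of the two sides). Concordance is the fraction of specimens whose
#' cluster maps to their species, reported with the raw counts, plus the full
#' cluster x species composition table for eyeball verification of split
#' clusters.
#'
#' @param dendrogram an `upgma`/`hclust` object.
#' @param labels species labels in the order of the clustered specimens.
#' @param k number of clusters to cut; defaults to the number of distinct
#'   labels.
#' @return list with `concordance_pct` (rounded percent), `n_matched`,
#'   `n_total`, `label` (e.g. `"94% (31/33)"`), `assignment` (cluster ->
#'   species map) and `composition` (cluster x species table).
#' @export
cluster_concordance <- function(dendrogram, labels,
                                k = length(unique(labels))) {
  stopifnot(inherits(dendrogram, "hclust"))
  g <- factor(labels)
  n <- length(dendrogram$order)
  if (length(g) != n) stop("labels length must equal leaf count")
  if (k > n) stop("k exceeds leaf count")
  cl <- stats::cutree(dendrogram, k = k)
  tab <- table(cluster = cl, species = g)
  assignment <- .optimal_matching(tab)
  matched <- sum(vapply(seq_along(assignment), function(i) {
    sp <- assignment[i]
    if (is.na(sp)) 0L else tab[names(assignment)[i], sp]
  }, integer(1L)))
  list(concordance_pct = round(100 * matched / n),
       n_matched = as.integer(matched), n_total = n,
       label = fraction_label(matched, n),
       assignment = assignment,
       composition = tab)
}

## optimal one-to-one matching cluster -> species maximizing total
## agreement; exhaustive search enumerating over the smaller dimension, each
## element of which picks a distinct partner from the larger dimension (fine
## for a handful of species)
.optimal_matching <- function(tab) {
  nr <- nrow(tab); nc <- ncol(tab)
  if (min(nr, nc) > 6L)
    stop("optimal matching implemented for up to 6 on the smaller side")
  by_col <- nc <= nr   # enumerate species (columns) if they are fewer
  small <- if (by_col) nc else nr
  large <- if (by_col) nr else nc
  val_at <- function(i_large, j_small)
    if (by_col) tab[i_large, j_small] else tab[j_small, i_large]
  best_map <- NULL; best_val <- -1
  rec <- function(j, used, val, pick) {
    if (j > small) {
      if (val > best_val) { best_val <<- val; best_map <<- pick }
      return()
    }
    for (i in seq_len(large)) {
      if (used[i]) next
      used[i] <- TRUE
      pick[j] <- i
      rec(j + 1L, used, val + val_at(i, j), pick)
      used[i] <- FALSE
    }
  }
  rec(1L, logical(large), 0, integer(small))
  # express as cluster -> species map
  out <- stats::setNames(rep(NA_character_, nr), rownames(tab))
  for (j in seq_len(small)) {
    if (by_col) out[best_map[j]] <- colnames(tab)[j]
    else out[j] <- colnames(tab)[best_map[j]]
  }
  out
}
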