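test_that("size-based ML reclassification separates, chances, and rescales", {
  set.seed(41)
  # complete separation
  sizes <- c(rnorm(10, 0, 0.1), rnorm(10, 100, 0.1))
  labs <- rep(c("small", "big"), each = 10)
  rep1 <- ml_size_classify_loo(sizes, labs)
  expect_equal(rep1$mean_accuracy, 100)
  expect_equal(rep1$sd_accuracy, 0)
  expect_equal(unname(diag(rep1$confusion)), c(10, 10))
  # affine rescaling never changes assignments
  rep2 <- ml_size_classify_loo(sizes * 0.042 - 7, labs)
  expect_identical(rep2$predicted, rep1$predicted)
  # identical distributions: accuracy hovers at chance over many datasets
  accs <- vapply(1:50, function(i) {
    v <- rnorm(400)
    ml_size_classify_loo(v, rep(c("A", "B"), each = 200))$mean_accuracy
  }, numeric(1L))
  expect_gt(mean(accs), 47)
  expect_lt(mean(accs), 53)
})

test_that("confusion matrix bookkeeping is consistent", {
  set.seed(42)
  sizes <- c(rnorm(8, 0, 1), rnorm(9, 2, 1), rnorm(7, 4, 1))
  labs <- rep(c("a", "b", "c"), c(8, 9, 7))
  rp <- ml_size_classify_loo(sizes, labs)
  expect_equal(unname(rowSums(rp$confusion)), c(8, 9, 7))
  expect_equal(sum(diag(rp$confusion)), rp$n_correct)
  expect_equal(rp$n_total, 24L)
})

test_that("the MLP is deterministic given a seed and aces separable blobs", {
  set.seed(43)
  bl <- separable_blobs(n_per = 10)
  r1 <- mlp_loo_classify(bl$X, bl$labels, repeats = 3, seed = 5)
  r2 <- mlp_loo_classify(bl$X, bl$labels, repeats = 3, seed = 5)
  expect_identical(r1$per_repeat_accuracy, r2$per_repeat_accuracy)
  expect_equal(r1$mean_accuracy, 100)
  expect_equal(r1$sd_accuracy, 0)
})

test_that("an independent neural-net implementation agrees on separable data", {
  skip_if_not_installed("nnet")
  set.seed(50)
  bl <- separable_blobs(n_per = 8)
  ours <- mlp_loo_classify(bl$X, bl$labels, repeats = 2, seed = 3)
  # nnet trains by quasi-Newton rather than plain backpropagation, so it is
  # a genuinely independent route to the same leave-one-out predictions
  y <- factor(bl$labels)
  preds <- vapply(seq_len(nrow(bl$X)), function(i) {
    mu <- colMeans(bl$X[-i, ]); sdv <- apply(bl$X[-i, ], 2, sd)
    # best of three random starts: single nnet runs can stall in a local
    # optimum on perfectly separable data
    fits <- lapply(1:3, function(k)
      nnet::nnet(x = scale(bl$X[-i, ], mu, sdv),
                 y = stats::model.matrix(~ y[-i] - 1),
                 size = 3, trace = FALSE, maxit = 300, decay = 1e-4))
    fit <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
    which.max(predict(fit, matrix((bl$X[i, ] - mu) / sdv, 1)))
  }, integer(1L))
  expect_equal(mean(levels(y)[preds] == bl$labels) * 100, 100)
  expect_equal(ours$mean_accuracy, 100)
})

test_that("MLP validation never leaks the held-out case", {
  set.seed(44)
  bl <- separable_blobs(n_per = 6)
  base <- mlp_loo_classify(bl$X, bl$labels, repeats = 2, seed = 9)
  # corrupt one specimen's label: its own prediction cannot change, because
  # neither its features nor its label enter the fold that predicts it
  labs2 <- bl$labels
  labs2[4] <- "c"
  mod <- mlp_loo_classify(bl$X, labs2, repeats = 2, seed = 9)
  expect_identical(as.character(mod$predicted[4]),
                   as.character(base$predicted[4]))
})

test_that("single-member classes are skipped with a warning", {
  set.seed(45)
  X <- rbind(separable_blobs(n_per = 5)$X[1:10, ], c(50, 50))
  labs <- c(rep(c("a", "b"), each = 5), "lonely")
  expect_warning(rp <- mlp_loo_classify(X, labs, repeats = 1, seed = 1),
                 "lonely")
  expect_equal(rp$n_total, 10L)
})

test_that("UPGMA reproduces the hand-computed merge history", {
  x <- matrix(c(0, 1, 10, 12), ncol = 1,
              dimnames = list(c("p", "q", "r", "s"), NULL))
  hc <- upgma(x)
  expect_equal(sort(hc$height), c(1, 2, 10.5))
  # ultrametric: heights never decrease
  expect_true(all(diff(hc$height) >= 0))
  # duplicate specimens merge first at height zero
  hc0 <- upgma(matrix(c(0, 0, 5, 9, 9.5, 20, 21, 22), ncol = 1))
  expect_equal(min(hc0$height), 0)
  # row order does not change the merge heights (distances are tie-free)
  set.seed(46)
  X <- matrix(rnorm(30), 15, 2)
  perm <- sample.int(15)
  expect_equal(sort(upgma(X)$height), sort(upgma(X[perm, ])$height),
               tolerance = 1e-12)
})

test_that("newick export preserves leaves and ultrametric depths", {
  set.seed(47)
  X <- matrix(rnorm(20), 10, 2,
              dimnames = list(sprintf("s%02d", 1:10), NULL))
  hc <- upgma(X)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, tf)
  tr <- ape::read.tree(tf)
  expect_setequal(tr$tip.label, rownames(X))
  expect_true(ape::is.ultrametric(tr, tol = 1e-6))
})

test_that("cluster concordance counts agreement like the study reports", {
  set.seed(48)
  # three tight clusters of 11: perfect recovery
  feats <- rbind(matrix(rnorm(22, 0, 0.05), ncol = 2),
                 matrix(rnorm(22, 10, 0.05), ncol = 2),
                 matrix(rnorm(22, 20, 0.05), ncol = 2))
  labs <- rep(c("P", "C", "S"), each = 11)
  cc <- cluster_concordance(upgma(feats), labs)
  expect_equal(cc$concordance_pct, 100)
  expect_equal(cc$label, "100% (33/33)")
  # move two specimens of species P into C's region: 31/33 = 94%
  feats2 <- feats
  feats2[1:2, ] <- matrix(rnorm(4, 10, 0.05), ncol = 2)
  cc2 <- cluster_concordance(upgma(feats2), labs)
  expect_equal(cc2$n_matched, 31L)
  expect_equal(cc2$label, "94% (31/33)")
  expect_equal(unname(cc2$composition[cc2$assignment == "C",  "P"]), 2)
  # degenerate cut: every leaf its own cluster, all clusters pure
  cc3 <- cluster_concordance(upgma(feats), labs, k = 33)
  expect_lte(cc3$concordance_pct, 100)
  expect_true(all(apply(cc3$composition, 1, function(r) sum(r > 0)) == 1))
  expect_error(cluster_concordance(upgma(feats), labs, k = 34), "exceeds")
})
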