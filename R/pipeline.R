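#' Pipeline configuration
#'
#' Collects the tunable parameters of the end-to-end comparison: harmonic
#' count for the elliptic Fourier analysis, permutation count and seeds for
#' the permutation ANOVAs, and the MLP settings.
#'
#' @param H harmonics for the outline branch (default 7, capturing well
#'   over 99 percent of harmonic power on synthetic pronota; check with
#'   [harmonic_power()]).
#' @param n_perm permutations for the size ANOVAs (default 1000).
#' @param mlp_repeats leave-one-out cycles for the MLP (default 10).
#' @param mlp_hidden hidden units (default 3).
#' @param mlp_epochs training epochs per fold (default 500).
#' @param mlp_lr learning rate (default 0.1).
#' @param alpha significance level for the letter display (default 0.05).
#' @param seed master seed; every stochastic stage derives its own
#'   substream.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(H = 7L, n_perm = 1000L, mlp_repeats = 10L,
                            mlp_hidden = 3L, mlp_epochs = 500L,
                            mlp_lr = 0.1, alpha = 0.05, seed = 1L) {
  structure(list(H = as.integer(H), n_perm = as.integer(n_perm),
                 mlp_repeats = as.integer(mlp_repeats),
                 mlp_hidden = as.integer(mlp_hidden),
                 mlp_epochs = as.integer(mlp_epochs), mlp_lr = mlp_lr,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

## pairwise two-group permutation ANOVAs between species within one sex;
## returns the p-value matrix plus a tidy table carrying both the
## stratum-wide df (as reported) and the subset df
.pairwise_species_tests <- function(sizes, species, n_perm, seed, sex,
                                    method) {
  sp <- sort(unique(species))
  pmat <- matrix(NA_real_, length(sp), length(sp), dimnames = list(sp, sp))
  rows <- list()
  df_stratum <- length(sizes) - 1L
  for (i in seq_along(sp)) for (j in seq_along(sp)) {
    if (j <= i) next
    sel <- species %in% c(sp[i], sp[j])
    pt <- permutation_anova(sizes[sel], species[sel], n_perm = n_perm,
                            seed = derive_seed(seed,
                                               paste(sex, method, sp[i],
                                                     sp[j], sep = "|")))
    pmat[sp[i], sp[j]] <- pmat[sp[j], sp[i]] <- pt$p_value
    rows[[length(rows) + 1L]] <-
      data.frame(comparison = paste(sp[i], "vs", sp[j]), sex = sex,
                 method = method, statistic = pt$statistic,
                 df = df_stratum, df_subset = pt$df, p = pt$p_value,
                 n_perm = n_perm, seed = pt$seed)
  }
  list(pmat = pmat, table = do.call(rbind, rows))
}

## male-vs-female tests within species on a size variable available for
## both sexes
.dimorphism_tests <- function(sizes, species, sex, n_perm, seed, method) {
  rows <- list()
  for (sp in sort(unique(species))) {
    sel <- species == sp
    if (length(unique(sex[sel])) < 2L) next
    if (min(table(sex[sel])) < 2L) next
    pt <- permutation_anova(sizes[sel], sex[sel], n_perm = n_perm,
                            seed = derive_seed(seed,
                                               paste("dimorphism", method,
                                                     sp, sep = "|")))
    rows[[length(rows) + 1L]] <-
      data.frame(comparison = paste(sp, "male vs female"), sex = "both",
                 method = method, statistic = pt$statistic, df = pt$df,
                 df_subset = pt$df, p = pt$p_value, n_perm = n_perm,
                 seed = pt$seed)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

## shared per-sex analysis once a size vector and a shape feature matrix
## exist
.branch_stratum <- function(sizes, shape_feats, shape_scores, species, sex,
                            method, cfg) {
  pw_tests <- .pairwise_species_tests(sizes, species, cfg$n_perm, cfg$seed,
                                      sex, method)
  ml <- ml_size_classify_loo(sizes, species)
  mlp <- mlp_loo_classify(shape_feats, species, hidden = cfg$mlp_hidden,
                          repeats = cfg$mlp_repeats,
                          seed = derive_seed(cfg$seed,
                                             paste("mlp", method, sex,
                                                   sep = "|")),
                          lr = cfg$mlp_lr, epochs = cfg$mlp_epochs)
  dend <- upgma(shape_feats)
  conc <- cluster_concordance(dend, species)
  allo <- allometry_r2(shape_scores, sizes)
  mu <- tapply(sizes, species, mean)
  size_table <- data.frame(
    species = names(mu), sex = sex, method = method, n = as.integer(table(species)[names(mu)]),
    mean_size = as.numeric(mu),
    sd_size = as.numeric(tapply(sizes, species, stats::sd)),
    letters = significance_letters(pw_tests$pmat, mu, cfg$alpha))
  list(size_table = size_table, size_tests = pw_tests$table,
       pmat = pw_tests$pmat, ml_size = ml, mlp_shape = mlp,
       dendrogram = dend, concordance = conc, allometry = allo,
       sizes = sizes, species = species)
}

#' Run the linear-morphometry branch
#'
#' Per sex: Darroch-Mosimann log-size and log-shape ratios from pw/pm/pc,
#' pairwise species permutation ANOVAs on log-size plus male-vs-female tests
#' within species, leave-one-out maximum-likelihood reclassification on
#' log-size, leave-one-out MLP reclassification on (LSR1, LSR2), UPGMA
#' clustering with concordance, and allometric R-squared of the LSRs on
#' log-size.
#'
#' @param ds a [dataset()] with linear measurements.
#' @param config a [pipeline_config()].
#' @return a `branch_report` list with one entry per sex plus the
#'   dimorphism tests.
#' @export
run_linear_branch <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "cimicid_dataset"))
  if (is.null(ds$measurements)) stop("dataset has no linear measurements")
  strata <- list()
  all_sizes <- c(); all_species <- c(); all_sex <- c()
  for (sx in intersect(c("male", "female"), unique(ds$meta$sex))) {
    sub <- suppressWarnings(subset_sex(ds, sx))
    m <- measurements_for(sub, sub$meta$id)
    lsr <- log_shape_ratios(m)
    strata[[sx]] <- .branch_stratum(
      sizes = lsr$log_size, shape_feats = lsr$scores,
      shape_scores = lsr$scores, species = sub$meta$species, sex = sx,
      method = "linear", cfg = config)
    strata[[sx]]$lsr <- lsr
    all_sizes <- c(all_sizes, lsr$log_size)
    all_species <- c(all_species, sub$meta$species)
    all_sex <- c(all_sex, rep(sx, nrow(sub$meta)))
  }
  if (!length(strata)) stop("no sexed specimens to analyze")
  dim_tests <- .dimorphism_tests(all_sizes, all_species, all_sex,
                                 config$n_perm, config$seed, "linear")
  structure(list(method = "linear", strata = strata,
                 dimorphism_tests = dim_tests, config = config),
            class = "branch_report")
}

#' Run the outline-morphometry branch
#'
#' Per sex: elliptic Fourier analysis of each contour at `config$H`
#' harmonics, size as the semi-major axis of the first harmonic ellipse,
#' NEF shape coefficients, then the same battery as the linear branch:
#' pairwise species permutation ANOVAs on size plus dimorphism tests,
#' leave-one-out ML reclassification on size, leave-one-out MLP
#' reclassification on the full NEF feature matrix, UPGMA with concordance,
#' allometric R-squared of the first two NEF principal components on size,
#' and per-species mean shapes with reconstructed coordinates.
#'
#' @param ds a [dataset()] with contours.
#' @param config a [pipeline_config()].
#' @return a `branch_report` list with one entry per sex plus the
#'   dimorphism tests and mean shapes.
#' @export
run_outline_branch <- function(ds, config = pipeline_config()) {
  stopifnot(inherits(ds, "cimicid_dataset"))
  if (is.null(ds$contours)) stop("dataset has no contours")
  strata <- list()
  all_sizes <- c(); all_species <- c(); all_sex <- c()
  for (sx in intersect(c("male", "female"), unique(ds$meta$sex))) {
    sub <- suppressWarnings(subset_sex(ds, sx))
    ids <- sub$meta$id[sub$meta$id %in% names(sub$contours)]
    if (length(ids) < nrow(sub$meta))
      warning("specimens without contours excluded: ",
              paste(setdiff(sub$meta$id, ids), collapse = ", "))
    efas <- lapply(sub$contours[ids], fit_efa, H = config$H)
    sizes <- vapply(efas, semi_major_axis, numeric(1L))
    nefs <- lapply(efas, normalize_efa)
    feats <- nef_feature_matrix(nefs)
    species <- sub$meta$species[match(ids, sub$meta$id)]
    pcs <- shape_pc_scores(feats, k = 2L)
    strata[[sx]] <- .branch_stratum(
      sizes = sizes, shape_feats = feats, shape_scores = pcs,
      species = species, sex = sx, method = "outline", cfg = config)
    strata[[sx]]$nefs <- nefs
    strata[[sx]]$mean_shapes <- lapply(
      split(seq_along(ids), species),
      function(ii) inverse_efa(mean_shape(nefs[ii]), n_points = 200L))
    all_sizes <- c(all_sizes, sizes)
    all_species <- c(all_species, species)
    all_sex <- c(all_sex, rep(sx, length(ids)))
  }
  if (!length(strata)) stop("no sexed specimens to analyze")
  dim_tests <- .dimorphism_tests(all_sizes, all_species, all_sex,
                                 config$n_perm, config$seed, "outline")
  structure(list(method = "outline", strata = strata,
                 dimorphism_tests = dim_tests, config = config),
            class = "branch_report")
}

#' @export
print.branch_report <- function(x, ...) {
  cat(sprintf("Morphometric branch report: %s method, strata: %s\n",
              x$method, paste(names(x$strata), collapse = ", ")))
  for (sx in names(x$strata)) {
    st <- x$strata[[sx]]
    cat(sprintf("-- %s: size ML %.0f%%, shape MLP %.1f%% +/- %.1f%%, HAC %s\n",
                sx, st$ml_size$mean_accuracy, st$mlp_shape$mean_accuracy,
                st$mlp_shape$sd_accuracy, st$concordance$label))
  }
  invisible(x)
}

#' Juxtapose the linear and outline branches
#'
#' Merges two [run_linear_branch()] / [run_outline_branch()] reports built
#' on the same dataset into the study's result surfaces: a size panel
#' (group means with significance letters per method), a classification
#' panel (validated size-based and shape-based scores per method and sex), a
#' clustering panel (HAC concordance per method and sex) and an allometry
#' panel (R-squared of the first two shape variables on size).
#'
#' @param linear_report a linear `branch_report`.
#' @param outline_report an outline `branch_report`.
#' @return an `analysis_report` list with `size_table`, `size_tests`,
#'   `classification_table`, `clustering_table`, `allometry_table` and the
#'   two branch reports.
#' @export
compare_methods <- function(linear_report, outline_report) {
  stopifnot(inherits(linear_report, "branch_report"),
            inherits(outline_report, "branch_report"),
            identical(linear_report$method, "linear"),
            identical(outline_report$method, "outline"))
  sexes <- intersect(names(linear_report$strata),
                     names(outline_report$strata))
  if (!length(sexes)) stop("the two branches share no sex stratum")
  for (sx in sexes) {
    nl <- sort(names(linear_report$strata[[sx]]$sizes))
    no <- sort(names(outline_report$strata[[sx]]$sizes))
    if (!is.null(nl) && !is.null(no) && !identical(nl, no))
      stop("branches were run on different specimen sets (", sx, ")")
  }
  size_table <- do.call(rbind, c(
    lapply(sexes, function(sx) linear_report$strata[[sx]]$size_table),
    lapply(sexes, function(sx) outline_report$strata[[sx]]$size_table)))
  rownames(size_table) <- NULL
  size_tests <- rbind(
    do.call(rbind, lapply(sexes,
                          function(sx) linear_report$strata[[sx]]$size_tests)),
    do.call(rbind, lapply(sexes,
                          function(sx) outline_report$strata[[sx]]$size_tests)),
    linear_report$dimorphism_tests, outline_report$dimorphism_tests)
  rownames(size_tests) <- NULL
  cls <- list(); clu <- list(); allo <- list()
  for (method in c("linear", "outline")) {
    rep_ <- if (method == "linear") linear_report else outline_report
    for (sx in sexes) {
      st <- rep_$strata[[sx]]
      cls[[paste(method, sx)]] <- data.frame(
        method = method, sex = sx,
        size_ml_pct = st$ml_size$mean_accuracy,
        size_ml_label = fraction_label(st$ml_size$n_correct,
                                       st$ml_size$n_total),
        shape_mlp_pct = st$mlp_shape$mean_accuracy,
        shape_mlp_sd = st$mlp_shape$sd_accuracy,
        shape_mlp_se = st$mlp_shape$se_accuracy)
      clu[[paste(method, sx)]] <- data.frame(
        method = method, sex = sx,
        concordance_pct = st$concordance$concordance_pct,
        concordance_label = st$concordance$label)
      allo[[paste(method, sx)]] <- data.frame(
        method = method, sex = sx,
        shape_var = names(st$allometry),
        r2_pct = 100 * as.numeric(st$allometry))
    }
  }
  structure(list(size_table = size_table, size_tests = size_tests,
                 classification_table = do.call(rbind, c(cls,
                                                         make.row.names = FALSE)),
                 clustering_table = do.call(rbind, c(clu,
                                                     make.row.names = FALSE)),
                 allometry_table = do.call(rbind, c(allo,
                                                    make.row.names = FALSE)),
                 linear = linear_report, outline = outline_report),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Size panel ==\n"); print(x$size_table)
  cat("\n== Validated reclassification ==\n"); print(x$classification_table)
  cat("\n== HAC concordance ==\n"); print(x$clustering_table)
  cat("\n== Allometry (R2, %) ==\n"); print(x$allometry_table)
  invisible(x)
}

#' Export mean shapes as CSV coordinates and an SVG overlay
#'
#' @param outline_report an outline `branch_report` carrying mean shapes.
#' @param dir output directory, created if needed.
#' @return paths of the written files, invisibly.
#' @export
export_mean_shapes <- function(outline_report, dir) {
  stopifnot(inherits(outline_report, "branch_report"),
            identical(outline_report$method, "outline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (sx in names(outline_report$strata)) {
    ms <- outline_report$strata[[sx]]$mean_shapes
    for (sp in names(ms)) {
      p <- file.path(dir, sprintf("mean_shape_%s_%s.csv", sp, sx))
      utils::write.csv(as.data.frame(unclass(ms[[sp]])), p,
                       row.names = FALSE)
      paths <- c(paths, p)
    }
    svg_path <- file.path(dir, sprintf("mean_shapes_%s.svg", sx))
    grDevices::svg(svg_path, width = 6, height = 6)
    xr <- range(unlist(lapply(ms, function(m) unclass(m)[, 1L])))
    yr <- range(unlist(lapply(ms, function(m) unclass(m)[, 2L])))
    graphics::plot(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x",
                   ylab = "y",
                   main = sprintf("Mean pronotum shapes (%s)", sx))
    for (i in seq_along(ms)) {
      xy <- unclass(ms[[i]])
      graphics::lines(rbind(xy, xy[1L, ]), col = i, lwd = 2)
    }
    graphics::legend("topright", legend = names(ms), col = seq_along(ms),
                     lwd = 2, bty = "n")
    grDevices::dev.off()
    paths <- c(paths, svg_path)
  }
  invisible(paths)
}
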