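#' Specimen dataset
#'
#' A dataset bundles specimen metadata (id, species, sex), optional linear
#' pronotum measurements (pw, pm, pc) and optional digitized contours under a
#' single length-unit tag. All analyses stratify by sex; specimens with
#' missing sex or species are kept in the container but dropped (with a
#' warning) from stratified computations.
#'
#' @param meta data frame with columns `id`, `species`, `sex`. `sex` must be
#'   `"male"`, `"female"` or `NA`.
#' @param measurements optional data frame with columns `id`, `pw`, `pm`,
#'   `pc` (micrometres): pronotum width, medial pronotum length, anterior
#'   pronotal concavity depth. All strictly positive.
#' @param contours optional named list of [contour()] objects, names matching
#'   ids.
#' @param units single length-unit tag, default `"um"`.
#' @return An object of class `cimicid_dataset`.
#' @export
dataset <- function(meta, measurements = NULL, contours = NULL,
                    units = "um") {
  meta <- as.data.frame(meta)
  need <- c("id", "species", "sex")
  if (!all(need %in% names(meta)))
    stop("meta must have columns id, species, sex")
  meta$id <- as.character(meta$id)
  meta$species <- as.character(meta$species)
  meta$sex <- as.character(meta$sex)
  if (anyDuplicated(meta$id))
    stop("duplicate specimen ids: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  bad_sex <- !is.na(meta$sex) & !meta$sex %in% c("male", "female")
  if (any(bad_sex))
    stop("sex must be 'male' or 'female' (or NA), offending ids: ",
         paste(meta$id[bad_sex], collapse = ", "))
  if (!is.null(measurements)) {
    measurements <- as.data.frame(measurements)
    if (!all(c("id", "pw", "pm", "pc") %in% names(measurements)))
      stop("measurements must have columns id, pw, pm, pc")
    measurements$id <- as.character(measurements$id)
    if (!all(measurements$id %in% meta$id))
      stop("measurement ids missing from meta")
    vals <- as.matrix(measurements[, c("pw", "pm", "pc")])
    if (anyNA(vals) || any(vals <= 0)) {
      bad <- measurements$id[apply(vals, 1L, function(r) anyNA(r) || any(r <= 0))]
      stop("non-positive or missing measurement for ids: ",
           paste(bad, collapse = ", "))
    }
    if (any(measurements$pw < measurements$pm))
      warning("pw < pm for ids: ",
              paste(measurements$id[measurements$pw < measurements$pm],
                    collapse = ", "))
  }
  if (!is.null(contours)) {
    if (is.null(names(contours)) || !all(names(contours) %in% meta$id))
      stop("contours must be a named list keyed by specimen id")
    if (!all(vapply(contours, inherits, TRUE, "pronotum_contour")))
      stop("all contours must be pronotum_contour objects")
  }
  has_any <- meta$id %in% c(if (!is.null(measurements)) measurements$id,
                            if (!is.null(contours)) names(contours))
  if (!all(has_any))
    stop("specimens with neither contour nor measurements: ",
         paste(meta$id[!has_any], collapse = ", "))
  structure(list(meta = meta, measurements = measurements,
                 contours = contours, units = units),
            class = "cimicid_dataset")
}

#' @export
print.cimicid_dataset <- function(x, ...) {
  cat(sprintf("Cimicid dataset: %d specimens [%s]\n", nrow(x$meta), x$units))
  cat(sprintf("  measurements: %d, contours: %d\n",
              if (is.null(x$measurements)) 0L else nrow(x$measurements),
              length(x$contours)))
  print(group_sizes(x))
  invisible(x)
}

#' Group sizes per species and sex
#'
#' @param x a [dataset()].
#' @return a species x sex contingency table of specimen counts.
#' @export
group_sizes <- function(x) {
  stopifnot(inherits(x, "cimicid_dataset"))
  table(species = x$meta$species, sex = x$meta$sex, useNA = "no")
}

#' Restrict a dataset to one sex
#'
#' Specimens with missing sex or species are excluded with a warning, in
#' keeping with the fully sex-stratified design of every analysis.
#'
#' @param x a [dataset()].
#' @param sex `"male"` or `"female"`.
#' @return a [dataset()] restricted to that sex.
#' @export
subset_sex <- function(x, sex) {
  stopifnot(inherits(x, "cimicid_dataset"))
  sex <- match.arg(sex, c("male", "female"))
  incomplete <- is.na(x$meta$sex) | is.na(x$meta$species)
  if (any(incomplete))
    warning(sum(incomplete),
            " specimen(s) without sex/species excluded from stratified analysis")
  keep <- !incomplete & x$meta$sex == sex
  ids <- x$meta$id[keep]
  if (!length(ids)) stop("no specimens of sex '", sex, "'")
  meas <- x$measurements
  if (!is.null(meas)) {
    meas <- meas[meas$id %in% ids, , drop = FALSE]
    if (!nrow(meas)) meas <- NULL
  }
  ctr <- x$contours
  if (!is.null(ctr)) {
    ctr <- ctr[names(ctr) %in% ids]
    if (!length(ctr)) ctr <- NULL
  }
  dataset(x$meta[keep, , drop = FALSE], meas, ctr, x$units)
}

## measurements aligned to meta row order for the given ids
measurements_for <- function(x, ids) {
  m <- x$measurements
  if (is.null(m)) stop("dataset has no linear measurements")
  missing <- setdiff(ids, m$id)
  if (length(missing))
    stop("no measurements for ids: ", paste(missing, collapse = ", "))
  m[match(ids, m$id), , drop = FALSE]
}
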