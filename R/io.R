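#' Read pseudolandmark outlines from a TPS file
#'
#' Supports the two common TPS dialects for outline data: records whose
#' pseudolandmarks are stored directly under `LM=n`, and records using
#' `OUTLINES=1` / `POINTS=n`. `SCALE=` factors are applied to the
#' coordinates; `ID=` names the specimen (falling back to `IMAGE=`, then to a
#' running index). Each record yields one specimen.
#'
#' Coordinates digitized on micrographs usually live in an image frame with
#' the y-axis pointing down; set `image_frame = TRUE` to flip them into the
#' y-up mathematical frame used throughout. All imported contours are forced
#' counterclockwise.
#'
#' @param path TPS file path.
#' @param image_frame logical; flip the y-axis on import.
#' @param meta optional data frame with columns `id`, `species`, `sex` to
#'   attach metadata by id; unmatched ids get `NA` species/sex.
#' @param units unit tag for the resulting dataset.
#' @return a [dataset()] with one contour per record.
#' @export
read_tps <- function(path, image_frame = FALSE, meta = NULL, units = "um") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  is_key <- grepl("^[A-Za-z]+=", lines)
  key_of <- function(i) toupper(sub("=.*$", "", lines[i]))
  val_of <- function(i) sub("^[A-Za-z]+=", "", lines[i])

  parse_count <- function(i) {
    v <- suppressWarnings(as.integer(val_of(i)))
    if (is.na(v) || v < 0)
      stop(sprintf("TPS parse error at line %d: bad count '%s'", i, lines[i]))
    v
  }
  parse_coords <- function(from, n) {
    if (from + n - 1L > length(lines))
      stop(sprintf(
        "TPS parse error at line %d: expected %d coordinate lines, file ends",
        from, n))
    block <- lines[seq.int(from, length.out = n)]
    mats <- lapply(seq_along(block), function(j) {
      toks <- strsplit(trimws(block[j]), "[,;[:space:]]+")[[1]]
      xy <- suppressWarnings(as.numeric(toks))
      if (length(xy) != 2L || anyNA(xy))
        stop(sprintf("TPS parse error at line %d: expected 'x y', got '%s'",
                     from + j - 1L, block[j]))
      xy
    })
    do.call(rbind, mats)
  }

  specs <- list()
  i <- 1L
  rec <- 0L
  n_lines <- length(lines)
  while (i <= n_lines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!is_key[i] || key_of(i) != "LM")
      stop(sprintf("TPS parse error at line %d: expected LM= record, got '%s'",
                   i, lines[i]))
    rec <- rec + 1L
    n_lm <- parse_count(i)
    i <- i + 1L
    pts <- NULL
    if (n_lm > 0L) {
      pts <- parse_coords(i, n_lm)
      i <- i + n_lm
    }
    id <- NULL; img <- NULL; scale <- 1
    while (i <= n_lines && nzchar(trimws(lines[i])) &&
           (!is_key[i] || key_of(i) != "LM")) {
      if (!is_key[i])
        stop(sprintf("TPS parse error at line %d: unexpected '%s'",
                     i, lines[i]))
      k <- key_of(i)
      if (k == "OUTLINES") {
        n_out <- parse_count(i)
        if (n_out != 1L)
          stop(sprintf("line %d: only single-outline records supported (OUTLINES=%d)",
                       i, n_out))
        i <- i + 1L
        if (i > n_lines || !is_key[i] || key_of(i) != "POINTS")
          stop(sprintf("TPS parse error at line %d: expected POINTS= after OUTLINES=", i))
        n_pt <- parse_count(i)
        if (n_pt == 0L)
          stop(sprintf("rejected record %d (line %d): zero-point outline", rec, i))
        i <- i + 1L
        pts <- parse_coords(i, n_pt)
        i <- i + n_pt
      } else {
        switch(k,
               ID = { id <- trimws(val_of(i)) },
               IMAGE = { img <- trimws(val_of(i)) },
               SCALE = {
                 scale <- suppressWarnings(as.numeric(val_of(i)))
                 if (is.na(scale) || scale <= 0)
                   stop(sprintf("TPS parse error at line %d: bad SCALE", i))
               },
               NULL) # COMMENT= etc: ignored
        i <- i + 1L
      }
    }
    if (is.null(pts))
      stop(sprintf("rejected record %d: zero-point outline", rec))
    if (is.null(id)) id <- if (!is.null(img)) img else sprintf("tps_%03d", rec)
    pts <- pts * scale
    if (image_frame) pts[, 2L] <- -pts[, 2L]
    specs[[id]] <- enforce_orientation(contour(pts))
  }
  if (!length(specs)) stop("no records found in ", path)
  ids <- names(specs)
  md <- data.frame(id = ids, species = NA_character_, sex = NA_character_,
                   stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    j <- match(ids, as.character(meta$id))
    md$species <- as.character(meta$species)[j]
    md$sex <- as.character(meta$sex)[j]
  }
  dataset(md, contours = specs, units = units)
}

#' Write dataset contours to a TPS file
#'
#' Emits one `LM=` record per contour with coordinates at 6 decimals,
#' followed by `ID=`. Round-trips through [read_tps()] reproduce the
#' coordinates to that precision.
#'
#' @param x a [dataset()] with contours.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(x, path) {
  stopifnot(inherits(x, "cimicid_dataset"))
  if (is.null(x$contours)) stop("dataset has no contours")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (id in names(x$contours)) {
    pts <- unclass(x$contours[[id]])
    writeLines(sprintf("LM=%d", nrow(pts)), con)
    writeLines(sprintf("%.6f %.6f", pts[, 1L], pts[, 2L]), con)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}

#' Read linear pronotum measurements from CSV
#'
#' Expects the exact header `id,species,sex,pw,pm,pc` with measurements in
#' the dataset unit (micrometres by default). All three measurements must be
#' strictly positive; `pw < pm` is flagged as a warning on real imports (it
#' never occurs in generated data).
#'
#' @param path CSV file path.
#' @param units unit tag for the resulting dataset.
#' @return a [dataset()] with measurements only.
#' @export
read_measurements_csv <- function(path, units = "um") {
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  expected <- c("id", "species", "sex", "pw", "pm", "pc")
  if (!identical(trimws(header), expected))
    stop("CSV header must be exactly 'id,species,sex,pw,pm,pc', got '",
         paste(header, collapse = ","), "'")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character",
                                       species = "character",
                                       sex = "character"))
  df$sex[df$sex == ""] <- NA_character_
  df$species[df$species == ""] <- NA_character_
  dataset(df[, c("id", "species", "sex")],
          measurements = df[, c("id", "pw", "pm", "pc")],
          units = units)
}

#' Write linear measurements to CSV
#'
#' @param x a [dataset()] with measurements.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(x, path) {
  stopifnot(inherits(x, "cimicid_dataset"))
  if (is.null(x$measurements)) stop("dataset has no measurements")
  m <- measurements_for(x, x$meta$id[x$meta$id %in% x$measurements$id])
  j <- match(m$id, x$meta$id)
  out <- data.frame(id = m$id, species = x$meta$species[j],
                    sex = x$meta$sex[j], pw = m$pw, pm = m$pm, pc = m$pc)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
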