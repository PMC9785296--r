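test_that("contour construction enforces its invariants", {
  expect_error(contour(cbind(1:4, 1:4)), "at least 8")
  pts <- cbind(c(0, 1, 2, 3, 3, 2, 1, 0), c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_s3_class(contour(pts), "pronotum_contour")
  dup <- pts; dup[2L, ] <- dup[1L, ]
  expect_error(contour(dup), "duplicate")
  # explicit closing point is dropped
  closed <- rbind(pts, pts[1L, ])
  expect_equal(nrow(contour(closed)), 8L)
})

test_that("orientation is detected and can be enforced, keeping the start", {
  th <- seq(0, 2 * pi, length.out = 17)[-17]
  ccw <- contour(cbind(cos(th), sin(th)))
  cw <- contour(cbind(cos(-th), sin(-th)))
  expect_identical(attr(ccw, "orientation"), "ccw")
  expect_identical(attr(cw, "orientation"), "cw")
  fixed <- enforce_orientation(cw)
  expect_identical(attr(fixed, "orientation"), "ccw")
  expect_equal(unclass(fixed)[1L, ], unclass(cw)[1L, ])
  expect_gt(signed_area(fixed), 0)
  expect_identical(enforce_orientation(ccw), ccw)
  # collinear points enclose no area
  line <- contour(cbind(seq(0, 1, length.out = 10), seq(0, 2, length.out = 10)))
  expect_error(enforce_orientation(line), "degenerate")
})

test_that("TPS import applies SCALE, flips image-frame y, and round-trips", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c(sprintf("LM=%d", 12L),
               sprintf("%.4f %.4f", cos(th), sin(th)),
               "ID=spec1", "SCALE=2.0"), tf)
  ds <- read_tps(tf)
  expect_equal(nrow(ds$meta), 1L)
  expect_equal(max(unclass(ds$contours$spec1)[, 1L]), 2, tolerance = 1e-9)

  # image-frame digitization: y flipped, orientation still ccw
  ds_img <- read_tps(tf, image_frame = TRUE)
  expect_identical(attr(ds_img$contours$spec1, "orientation"), "ccw")
  expect_equal(min(unclass(ds_img$contours$spec1)[, 2L]), -2,
               tolerance = 1e-9)

  # OUTLINES/POINTS dialect reads the same outline
  tf2 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=0", "OUTLINES=1", sprintf("POINTS=%d", 12L),
               sprintf("%.4f %.4f", cos(th), sin(th)), "ID=o1"), tf2)
  ds2 <- read_tps(tf2)
  expect_equal(unclass(ds2$contours$o1), unclass(ds$contours$spec1) / 2,
               tolerance = 1e-9, ignore_attr = TRUE)

  # round-trip at 6 decimals
  set.seed(42)
  ds_rand <- dataset(data.frame(id = c("r1", "r2"), species = "x",
                                sex = "male"),
                     contours = list(r1 = random_smooth_contour(60),
                                     r2 = random_smooth_contour(60)))
  tf3 <- withr::local_tempfile(fileext = ".tps")
  write_tps(ds_rand, tf3)
  back <- read_tps(tf3)
  for (id in c("r1", "r2"))
    expect_equal(unclass(back$contours[[id]]),
                 unclass(ds_rand$contours[[id]]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("malformed TPS records are rejected with a line number", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=0", "OUTLINES=1", "POINTS=5",
               "0 0", "1 0", "1 1", "0 1", "ID=bad"), tf)
  expect_error(read_tps(tf), "line 8")
  tf2 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=0", "OUTLINES=1", "POINTS=0", "ID=empty"), tf2)
  expect_error(read_tps(tf2), "zero-point")
  tf3 <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=abc", "ID=x"), tf3)
  expect_error(read_tps(tf3), "line 1")
})

test_that("measurement CSV reading validates and reports group sizes", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,species,sex,pw,pm,pc",
               "s1,A,male,100,80,10"), tf)
  ds <- read_measurements_csv(tf)
  expect_equal(ds$measurements$pw, 100)
  expect_equal(ds$meta$sex, "male")

  writeLines(c("id,species,sex,pw,pm,pc",
               "s1,A,male,100,80,0"), tf)
  expect_error(read_measurements_csv(tf), "s1")

  writeLines(c("id,species,sex,pw,pm,pc",
               "s1,A,male,100,80,10",
               "s1,A,male,100,80,10"), tf)
  expect_error(read_measurements_csv(tf), "duplicate")

  writeLines(c("pw,pm,pc,id,species,sex", "100,80,10,s1,A,male"), tf)
  expect_error(read_measurements_csv(tf), "header")

  # a study-sized file: 33 males, 45 females across 3 species
  n_m <- c(14, 7, 12); n_f <- c(12, 19, 14)
  rows <- character()
  for (i in 1:3) {
    sp <- LETTERS[i]
    rows <- c(rows,
              sprintf("%s_m%02d,%s,male,100,80,10", sp, seq_len(n_m[i]), sp),
              sprintf("%s_f%02d,%s,female,100,80,10", sp, seq_len(n_f[i]), sp))
  }
  writeLines(c("id,species,sex,pw,pm,pc", rows), tf)
  big <- read_measurements_csv(tf)
  gs <- group_sizes(big)
  expect_equal(sum(gs[, "male"]), 33)
  expect_equal(sum(gs[, "female"]), 45)
  expect_equal(unname(gs[c("A", "B", "C"), "male"]), n_m)

  # round-trip
  out <- withr::local_tempfile(fileext = ".csv")
  write_measurements_csv(big, out)
  again <- read_measurements_csv(out)
  expect_equal(again$measurements, big$measurements, ignore_attr = TRUE)
})

test_that("sex stratification partitions the dataset without overlap", {
  meta <- data.frame(id = sprintf("s%d", 1:7),
                     species = "A",
                     sex = c("male", "female", "male", NA, "female",
                             "male", "female"))
  meas <- data.frame(id = meta$id, pw = 100, pm = 80, pc = 10)
  ds <- dataset(meta, meas)
  expect_warning(males <- subset_sex(ds, "male"), "excluded")
  expect_warning(females <- subset_sex(ds, "female"), "excluded")
  expect_length(intersect(males$meta$id, females$meta$id), 0L)
  expect_setequal(c(males$meta$id, females$meta$id),
                  meta$id[!is.na(meta$sex)])
})

test_that("dataset constructor validates ids, membership and pw >= pm", {
  meta <- data.frame(id = c("a", "a"), species = "A", sex = "male")
  meas <- data.frame(id = c("a", "a"), pw = 1, pm = 1, pc = 1)
  expect_error(dataset(meta, meas), "duplicate")
  meta2 <- data.frame(id = "a", species = "A", sex = "male")
  expect_error(dataset(meta2), "neither contour nor measurements")
  expect_warning(
    dataset(meta2, data.frame(id = "a", pw = 70, pm = 80, pc = 10)),
    "pw < pm")
})
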