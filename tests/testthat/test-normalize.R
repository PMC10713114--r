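test_that("KDE peak detection recovers bimodal and unimodal positions", {
  set.seed(31)
  x <- c(rnorm(2000, 1.0, 0.15), rnorm(2000, 3.0, 0.15))
  s <- make_sample(matrix(x, ncol = 1))
  pk <- detect_peaks(s, "FL1", 2)
  expect_length(pk, 2)
  expect_lt(abs(pk[1] - 1.0), 0.1)
  expect_lt(abs(pk[2] - 3.0), 0.1)

  u <- make_sample(matrix(rnorm(2000, 2.0, 0.2), ncol = 1))
  pk1 <- detect_peaks(u, "FL1", 1)
  expect_lt(abs(pk1 - 2.0), 0.05)

  # unimodal data asked for two peaks -> flagged for manual override
  pk2 <- detect_peaks(u, "FL1", 2)
  expect_true(isTRUE(attr(pk2, "needs_override")))
  expect_lt(length(pk2), 2)

  expect_error(detect_peaks(make_sample(matrix(rnorm(100), ncol = 1)), "FL1", 1),
               class = "cp_estimation_error")
})

test_that("landmark targets are per-rank medians with overrides taking precedence", {
  set.seed(32)
  mk <- function(id, lo, hi) {
    make_sample(matrix(c(rnorm(1500, lo, 0.1), rnorm(1500, hi, 0.1)), ncol = 1),
                id = id)
  }
  ds <- new_dataset(list(mk("a", 1.0, 3.0), mk("b", 1.4, 3.6)))
  map <- build_landmark_map(ds, landmark_spec(c(FL1 = 2)))
  expect_equal(map$targets$FL1, c(1.2, 3.3), tolerance = 0.05)

  ov <- landmark_spec(c(FL1 = 2), overrides = list("b::FL1" = c(1.5, 3.5)))
  map2 <- build_landmark_map(ds, ov)
  expect_equal(map2$detected[["b::FL1"]], c(1.5, 3.5))
  expect_equal(map2$targets$FL1[1], median(c(map2$detected[["a::FL1"]][1], 1.5)))

  # single sample: targets equal its own peaks
  ds1 <- new_dataset(list(mk("solo", 1.1, 2.9)))
  map3 <- build_landmark_map(ds1, landmark_spec(c(FL1 = 2)))
  expect_equal(map3$targets$FL1, map3$detected[["solo::FL1"]])
})

test_that("piecewise-linear warp matches hand-computed values and edge rules", {
  # peaks {1, 3} -> targets {1.2, 3.3}: interior interpolation, shift outside
  expect_equal(cytopipe:::warp_values(c(1, 2, 3, 4, 0.5), c(1, 3), c(1.2, 3.3)),
               c(1.2, 2.25, 3.3, 4.3, 0.7))
  # single landmark degenerates to a global shift
  expect_equal(cytopipe:::warp_values(c(0, 2, 5), 2, 2.4), c(0.4, 2.4, 5.4))
  # identity when peaks equal targets
  x <- seq(-1, 5, by = 0.25)
  expect_equal(cytopipe:::warp_values(x, c(1, 3), c(1, 3)), x)
})

test_that("warp is strictly increasing and preserves within-sample rank order", {
  set.seed(33)
  for (i in 1:20) {
    peaks <- sort(runif(3, 0, 4) + c(0, 1, 2))
    targets <- sort(runif(3, 0, 4) + c(0, 1, 2))
    x <- sort(runif(200, -2, 8))
    y <- cytopipe:::warp_values(x, peaks, targets)
    expect_true(all(diff(y) > 0))
  }
})

test_that("normalization aligns two-batch peaks and conserves events", {
  set.seed(34)
  mk <- function(id, shift) {
    make_sample(matrix(c(rnorm(1500, 1 + shift, 0.12),
                         rnorm(1500, 3 + shift, 0.12)), ncol = 1), id = id)
  }
  ds <- new_dataset(list(mk("b1a", 0), mk("b1b", 0.02),
                         mk("b2a", 0.5), mk("b2b", 0.48)))
  map <- build_landmark_map(ds, landmark_spec(c(FL1 = 2)))
  norm <- normalize_dataset(ds, map)
  redetected <- sapply(norm$samples, function(s) detect_peaks(s, "FL1", 2))
  expect_lt(sd(redetected[1, ]), 0.05)
  expect_lt(sd(redetected[2, ]), 0.05)
  expect_true(all(abs(redetected - map$targets$FL1) < 0.05))
  expect_equal(sapply(norm$samples, function(s) nrow(s$events)),
               sapply(ds$samples, function(s) nrow(s$events)))
  # rank preservation
  ord0 <- order(ds$samples$b2a$events[, 1])
  ord1 <- order(norm$samples$b2a$events[, 1])
  expect_identical(ord0, ord1)
  # QC density curves exported for plotting
  qc <- attr(norm, "qc")
  expect_named(qc, "FL1")
  dir <- withr::local_tempdir()
  paths <- export_normalization_qc(norm, dir)
  expect_true(all(file.exists(paths)))
})

test_that("non-monotone landmark configurations raise warp errors", {
  set.seed(35)
  mk <- function(id) {
    make_sample(matrix(c(rnorm(1000, 1, 0.1), rnorm(1000, 3, 0.1)), ncol = 1),
                id = id)
  }
  ds <- new_dataset(list(mk("a")))
  map <- build_landmark_map(ds, landmark_spec(c(FL1 = 2)))
  map$targets$FL1 <- c(3, 1)  # out of order
  expect_error(normalize_dataset(ds, map), class = "cp_warp_error")

  map2 <- build_landmark_map(ds, landmark_spec(c(FL1 = 2)))
  map2$detected[["a::FL1"]] <- c(2.5)  # wrong landmark count
  expect_error(normalize_dataset(ds, map2), class = "cp_warp_error")
})

test_that("peak override files round into landmark specs", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(
    data.frame(sample_id = c("a", "a"), channel = c("FL1", "FL1"),
               rank = c(2, 1), position = c(3.5, 1.5)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  ov <- read_peak_overrides(path)
  expect_equal(ov[["a::FL1"]], c(1.5, 3.5))
})
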