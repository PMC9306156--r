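test_that("window counts follow floor((L - W)/H) + 1 with 50% overlap", {
  fs <- 2048
  w4 <- extract_windows(4 * fs, fs)          # 4-s segment
  expect_length(w4, 31L)
  expect_equal(attr(w4, "window"), 512L)
  expect_equal(attr(w4, "hop"), 256L)
  expect_length(extract_windows(512L, fs), 1L)  # exactly one window
  # consecutive windows share exactly 256 samples
  expect_equal(unique(diff(w4)), 256L)
  expect_error(extract_windows(100L, fs), "shorter than one window")
  # formula exact for assorted (L, W, H)
  for (L in c(512L, 700L, 2048L, 5000L)) {
    s <- extract_windows(L, fs)
    expect_length(s, (L - 512L) %/% 256L + 1L)
    expect_lte(s[length(s)] + 511L, L)
  }
})

test_that("time-domain features match hand-computed values", {
  f <- td_features(c(1, -1, 1, -1), eps = 0)
  expect_equal(f[["MAV"]], 1)
  expect_equal(f[["WL"]], 6)
  expect_equal(f[["ZC"]], 3)
  const <- td_features(rep(2.5, 10), eps = 0)
  expect_equal(const[["MAV"]], 2.5)
  expect_equal(const[["WL"]], 0)
  expect_equal(const[["ZC"]], 0)
  expect_equal(const[["SSC"]], 0)
  expect_equal(const[["LogVar"]], log(1e-12))
})

test_that("feature homogeneity: amplitude scaling acts as expected", {
  set.seed(8)
  x <- rnorm(512)
  k <- 3.7
  f1 <- td_features(x, eps = 0)
  f2 <- td_features(k * x, eps = 0)
  expect_equal(f2[["MAV"]], k * f1[["MAV"]])
  expect_equal(f2[["WL"]], k * f1[["WL"]])
  expect_equal(f2[["ZC"]], f1[["ZC"]])
  expect_equal(f2[["SSC"]], f1[["SSC"]])
  expect_equal(f2[["LogVar"]], f1[["LogVar"]] + 2 * log(k), tolerance = 1e-9)
})

test_that("vectorised and scalar feature paths agree", {
  set.seed(9)
  X <- matrix(rnorm(512 * 7), nrow = 512)
  M <- hdemg:::td_features_mat(X)           # default 1%-RMS deadband
  for (j in seq_len(ncol(X)))
    expect_equal(M[, j], td_features(X[, j]), tolerance = 1e-12)
  M0 <- hdemg:::td_features_mat(X, eps = 0)
  for (j in seq_len(ncol(X)))
    expect_equal(M0[, j], td_features(X[, j], eps = 0), tolerance = 1e-12)
})

make_segment <- function(gesture, wrist, level, n = 1024L, fs = 2048,
                         seed = 1) {
  set.seed(seed)
  lab <- task_label(gesture, wrist)
  lab$level <- level
  structure(list(signal = matrix(rnorm(256L * n), nrow = 256L), fs = fs,
                 label = lab, contraction = 1L, range = c(1L, n)),
            class = "emg_segment")
}

test_that("feature matrices have (channels x 5) columns and merged labels", {
  lay <- build_default_layout()
  segs <- list(make_segment("PG", "neutral", "low", seed = 1),
               make_segment("PG", "pronation", "moderate", seed = 2),
               make_segment("HO", "neutral", "low", seed = 3))
  fm <- build_feature_matrix(segs, lay)
  expect_equal(ncol(fm$X), 1280L)  # 256 channels x 5 features
  expect_equal(nrow(fm$X), 3L * 3L)  # 1024 samples -> 3 windows each
  expect_equal(levels(droplevels(fm$y)), c("PG", "HO"))
  expect_equal(sum(fm$y == "PG"), 6L)  # wrists/levels merged into one class
  lay4 <- build_default_layout(corrupted = c(0, 10, 200, 255))
  fm4 <- build_feature_matrix(segs, lay4)
  expect_equal(ncol(fm4$X), 1260L)  # (256 - 4) x 5
  expect_false(any(fm4$columns$channel %in% c(0, 10, 200, 255)))
  expect_error(build_feature_matrix(segs, lay, mode = "single_wrist",
                                    wrist = "supination"), "supination")
  fm_n <- build_feature_matrix(segs, lay, mode = "single_wrist",
                               wrist = "neutral")
  expect_equal(nrow(fm_n$X), 6L)
})

test_that("feature extraction commutes with channel sub-selection", {
  lay <- build_default_layout()
  seg <- make_segment("LG", "neutral", "low", seed = 4)
  fm <- build_feature_matrix(list(seg), lay)
  cs <- channel_set(c(12L, 100L), "SFS")
  sel <- features_for_channels(fm, cs)
  # independent oracle: features computed directly from those channels' rows
  starts <- extract_windows(seg, window_s = 0.25, overlap = 0.5)
  W <- attr(starts, "window")
  for (ci in seq_along(cs$channels)) {
    direct <- t(vapply(starts, function(s)
      td_features(seg$signal[cs$channels[ci] + 1L, s:(s + W - 1L)]),
      numeric(5)))
    expect_equal(unname(sel$X[, (ci - 1L) * 5L + 1:5]), unname(direct),
                 tolerance = 1e-12)
  }
})

test_that("stratified split preserves per-stratum proportions", {
  lay <- build_default_layout()
  segs <- unlist(lapply(hdemg_gestures[1:3], function(g) {
    lapply(c("low", "moderate"), function(lv)
      make_segment(g, "neutral", lv, n = 512L + 255L * 256L,
                   seed = match(g, hdemg_gestures) * 10 + (lv == "low")))
  }), recursive = FALSE)
  fm <- build_feature_matrix(segs, lay)   # 256 windows per (gesture, level)
  sp <- stratified_split(fm, train_frac = 0.70, seed = 2)
  expect_equal(nrow(sp$train$X) + nrow(sp$test$X), nrow(fm$X))
  for (g in hdemg_gestures[1:3]) for (lv in c("low", "moderate")) {
    n_tr <- sum(sp$train$y == g & sp$train$meta$level == lv)
    expect_equal(n_tr, round(0.7 * 256))
  }
  sp2 <- stratified_split(fm, train_frac = 0.70, seed = 2)
  expect_identical(sp$train$X, sp2$train$X)
  # disjoint and exhaustive in feature space
  expect_equal(sort(c(sp$train$X[, 1], sp$test$X[, 1])), sort(fm$X[, 1]))
})

test_that("stratified split rejects singleton strata", {
  X <- matrix(rnorm(3 * 10), nrow = 3)
  fm <- fm_from_matrix(X, c("A", "A", "B"), channels = 0:1)
  expect_error(stratified_split(fm), "fewer than 2")
})

test_that("feature matrices round-trip through CSV + JSON sidecar", {
  fm <- informative_channel_fm(n_per_class = 5L)
  path <- file.path(tempdir(), "fm.csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$X, fm$X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(back$columns$channel, fm$columns$channel)
  expect_equal(back$columns$name, fm$columns$name)
  expect_equal(as.character(back$y), as.character(fm$y))
  expect_equal(back$meta$wrist, fm$meta$wrist)
  unlink(c(path, paste0(path, ".json")))
})
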