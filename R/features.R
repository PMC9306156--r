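# Windowing, Hudgins-style time-domain features, labelled feature matrices
# and stratified splitting.
#
# Feature definitions (per 250-ms window x, deadband eps):
#   MAV    = mean(|x|)
#   ZC     = #{i : x_i * x_{i+1} < 0 and |x_i| > eps and |x_{i+1}| > eps}
#   SSC    = #{i : (x_i - x_{i-1})(x_i - x_{i+1}) > 0 and
#                  (|x_i - x_{i-1}| > eps or |x_i - x_{i+1}| > eps)}
#   WL     = sum(|diff(x)|)
#   LogVar = log(var(x) + eps_var)

FEATURE_NAMES <- c("MAV", "ZC", "SSC", "WL", "LogVar")

#' Sliding-window start indices
#'
#' Windows of `window_s` seconds with fractional `overlap` (hop =
#' `window_s * (1 - overlap)`); the number of windows is
#' `floor((L - W) / H) + 1`.
#'
#' @param x an `emg_segment`, a matrix (channels x samples) or a sample count.
#' @param fs sampling rate (Hz); taken from the segment when applicable.
#' @param window_s window length (s).
#' @param overlap fractional overlap between consecutive windows.
#' @return integer vector of 1-based start indices, with attributes
#'   `window` and `hop` (samples).
#' @export
extract_windows <- function(x, fs = NULL, window_s = 0.25, overlap = 0.5) {
  if (inherits(x, "emg_segment")) {
    fs <- x$fs
    L <- ncol(x$signal)
  } else if (is.matrix(x)) {
    L <- ncol(x)
  } else {
    L <- as.integer(x)
  }
  if (is.null(fs)) stop("fs is required")
  W <- round(window_s * fs)
  H <- max(1L, round(W * (1 - overlap)))
  if (L < W)
    stop("segment (", L, " samples) is shorter than one window (", W, ")")
  starts <- seq.int(1L, by = H, length.out = (L - W) %/% H + 1L)
  attr(starts, "window") <- W
  attr(starts, "hop") <- H
  starts
}

#' Time-domain features of one analysis window
#'
#' @param x numeric vector (single-channel window, length >= 3).
#' @param eps amplitude deadband for the ZC and SSC counts; `NULL` uses the
#'   default 1% of the window RMS (a noise deadband); pass 0 for the plain
#'   analytic definitions.
#' @param eps_var variance floor keeping `LogVar` finite on constant windows.
#' @return named numeric vector `MAV`, `ZC`, `SSC`, `WL`, `LogVar`.
#' @export
td_features <- function(x, eps = NULL, eps_var = 1e-12) {
  n <- length(x)
  if (n < 3L) stop("window must have at least 3 samples")
  if (is.null(eps)) eps <- 0.01 * sqrt(mean(x^2))
  d <- diff(x)
  mid <- (x[2:(n - 1)] - x[1:(n - 2)]) * (x[2:(n - 1)] - x[3:n])
  c(MAV = mean(abs(x)),
    ZC = sum(x[-n] * x[-1] < 0 & abs(x[-n]) > eps & abs(x[-1]) > eps),
    SSC = sum(mid > 0 & (abs(d[-(n - 1)]) > eps | abs(d[-1]) > eps)),
    WL = sum(abs(d)),
    LogVar = log(var(x) + eps_var))
}

# Vectorised variant: X is samples x windows for one channel; eps is NULL
# (1% window RMS) or a scalar applied to every window. Returns 5 x windows.
td_features_mat <- function(X, eps = NULL, eps_var = 1e-12) {
  n <- nrow(X)
  m <- ncol(X)
  if (is.null(eps)) eps <- 0.01 * sqrt(colMeans(X^2))
  epsm <- matrix(eps, nrow = n - 1L, ncol = m, byrow = TRUE)
  D <- X[-1L, , drop = FALSE] - X[-n, , drop = FALSE]
  zc <- colSums(X[-n, , drop = FALSE] * X[-1L, , drop = FALSE] < 0 &
                  abs(X[-n, , drop = FALSE]) > epsm &
                  abs(X[-1L, , drop = FALSE]) > epsm)
  epsd <- epsm[-1L, , drop = FALSE]
  mid <- -D[-1L, , drop = FALSE] * D[-(n - 1L), , drop = FALSE]
  ssc <- colSums(mid > 0 & (abs(D[-(n - 1L), , drop = FALSE]) > epsd |
                              abs(D[-1L, , drop = FALSE]) > epsd))
  mu <- colMeans(X)
  v <- (colSums(X^2) - n * mu^2) / (n - 1L)
  rbind(MAV = colMeans(abs(X)), ZC = zc, SSC = ssc,
        WL = colSums(abs(D)), LogVar = log(pmax(v, 0) + eps_var))
}

#' Build a labelled feature matrix from contraction segments
#'
#' Extracts the five time-domain features in sliding windows for every
#' non-corrupted channel of every segment. Class labels are the gesture
#' only: the same gesture at different contraction levels (and, in combined
#' mode, different wrist positions) shares one class; wrist and level remain
#' available per window in `meta`.
#'
#' @param segments list of `emg_segment` objects.
#' @param layout an `emg_layout` (defines the corrupted channels excluded
#'   from the columns).
#' @param mode `"combined"` keeps all segments; `"single_wrist"` restricts
#'   to segments recorded at `wrist`.
#' @param wrist wrist position for `mode = "single_wrist"`.
#' @param window_s,overlap windowing parameters, see [extract_windows()].
#' @param eps ZC/SSC deadband, see [td_features()].
#' @param task_id optional task identifier stored per window.
#' @return an object of class `feature_matrix`: list with `X` (windows x
#'   features), `columns` (data frame `channel`, `name`), `y` (gesture
#'   factor), `meta` (data frame `wrist`, `level`, `task_id`,
#'   `contraction`), and the windowing parameters.
#' @export
build_feature_matrix <- function(segments, layout,
                                 mode = c("combined", "single_wrist"),
                                 wrist = NULL, window_s = 0.25, overlap = 0.5,
                                 eps = NULL, task_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "emg_layout"), length(segments) > 0L)
  if (mode == "single_wrist") {
    if (is.null(wrist)) stop("single_wrist mode requires a wrist")
    segments <- Filter(function(s) s$label$wrist == wrist, segments)
    if (length(segments) == 0L)
      stop("no segments recorded at wrist position '", wrist, "'")
  }
  keep <- setdiff(layout$channels$index, layout$corrupted)
  columns <- data.frame(channel = rep(keep, each = length(FEATURE_NAMES)),
                        name = rep.int(FEATURE_NAMES, length(keep)))
  rows <- match(keep, layout$channels$index)
  parts <- vector("list", length(segments))
  meta <- vector("list", length(segments))
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    starts <- extract_windows(seg, window_s = window_s, overlap = overlap)
    W <- attr(starts, "window")
    idx <- outer(0:(W - 1L), starts, "+")
    nwin <- length(starts)
    Xs <- matrix(0, nwin, nrow(columns))
    for (ci in seq_along(rows)) {
      F5 <- td_features_mat(matrix(seg$signal[rows[ci], ][idx], nrow = W),
                            eps = eps)
      Xs[, (ci - 1L) * 5L + 1:5] <- t(F5)
    }
    parts[[si]] <- Xs
    meta[[si]] <- data.frame(wrist = seg$label$wrist,
                             level = seg$label$level %||% "rest",
                             gesture = seg$label$gesture,
                             task_id = task_id,
                             contraction = as.character(seg$contraction))[
                               rep(1L, nwin), , drop = FALSE]
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  structure(list(X = do.call(rbind, parts), columns = columns,
                 y = factor(meta$gesture, levels = hdemg_gestures),
                 meta = meta[, c("wrist", "level", "task_id", "contraction")],
                 window_s = window_s, overlap = overlap),
            class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature matrix:", nrow(x$X), "windows x", ncol(x$X), "features (",
      length(unique(x$columns$channel)), "channels x 5 ),",
      nlevels(droplevels(x$y)), "gesture classes\n")
  invisible(x)
}

#' Row/column subsets of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @param idx row (window) or column indices.
#' @return a `feature_matrix`.
#' @export
fm_rows <- function(fm, idx) {
  fm$X <- fm$X[idx, , drop = FALSE]
  fm$y <- fm$y[idx]
  fm$meta <- fm$meta[idx, , drop = FALSE]
  rownames(fm$meta) <- NULL
  fm
}

#' @rdname fm_rows
#' @export
fm_cols <- function(fm, idx) {
  fm$X <- fm$X[, idx, drop = FALSE]
  fm$columns <- fm$columns[idx, , drop = FALSE]
  rownames(fm$columns) <- NULL
  fm
}

# Concatenate feature matrices with identical columns.
rbind_feature_matrix <- function(...) {
  fms <- list(...)
  fms <- Filter(Negate(is.null), fms)
  stopifnot(length(fms) > 0L)
  base <- fms[[1L]]
  for (f in fms[-1L])
    stopifnot(identical(f$columns, base$columns))
  base$X <- do.call(rbind, lapply(fms, `[[`, "X"))
  base$y <- factor(unlist(lapply(fms, function(f) as.character(f$y))),
                   levels = hdemg_gestures)
  base$meta <- do.call(rbind, lapply(fms, `[[`, "meta"))
  rownames(base$meta) <- NULL
  base
}

#' Stratified train/test split
#'
#' Random 70/30 (by default) holdout split, stratified on the composite
#' (gesture x wrist x level) stratum so that every sub-condition of each
#' merged gesture class is covered proportionally in both parts.
#'
#' @param fm a `feature_matrix`.
#' @param train_frac fraction of each stratum assigned to training.
#' @param seed integer seed.
#' @return list with elements `train` and `test` (both `feature_matrix`),
#'   disjoint and exhaustive.
#' @export
stratified_split <- function(fm, train_frac = 0.70, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"), train_frac > 0, train_frac < 1)
  strata <- interaction(fm$y, fm$meta$wrist, fm$meta$level, drop = TRUE)
  sizes <- table(strata)
  if (any(sizes < 2L))
    stop("stratum with fewer than 2 windows: ",
         names(sizes)[which(sizes < 2L)[1L]])
  set.seed(seed)
  train_idx <- integer(0)
  for (s in levels(strata)) {
    idx <- which(strata == s)
    ntr <- min(max(round(train_frac * length(idx)), 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, ntr))
  }
  train_idx <- sort(train_idx)
  list(train = fm_rows(fm, train_idx),
       test = fm_rows(fm, setdiff(seq_len(nrow(fm$X)), train_idx)))
}

#' Write / read a feature matrix as CSV with a JSON label sidecar
#'
#' The CSV has one column per feature, named `ch<index>_<feature>`; window
#' labels and metadata go to `<path>.json`.
#'
#' @param fm a `feature_matrix`.
#' @param path CSV file path.
#' @return `read_feature_matrix` returns the reconstructed `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$X)
  names(df) <- sprintf("ch%d_%s", fm$columns$channel, fm$columns$name)
  write.csv(df, path, row.names = FALSE)
  side <- list(y = as.character(fm$y), meta = fm$meta,
               window_s = fm$window_s, overlap = fm$overlap)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  parts <- regmatches(names(df), regexec("^ch([0-9]+)_(.+)$", names(df)))
  lv <- if (all(side$y %in% hdemg_gestures)) hdemg_gestures else unique(side$y)
  structure(list(X = as.matrix(df),
                 columns = data.frame(
                   channel = as.integer(vapply(parts, `[`, "", 2L)),
                   name = vapply(parts, `[`, "", 3L)),
                 y = factor(side$y, levels = lv),
                 meta = as.data.frame(side$meta),
                 window_s = side$window_s, overlap = side$overlap),
            class = "feature_matrix")
}
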