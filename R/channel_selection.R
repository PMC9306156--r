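# Sequential forward selection (SFS) over feature columns with
# parent-channel mapping, and accuracy-vs-channel-count curves.

# Stratified fold assignment (by gesture class), seeded. Returns 1..nfold
# per row.
make_folds <- function(y, nfold = 10, seed = 1) {
  y <- factor(y)
  if (any(table(y) < nfold))
    stop("every class needs at least ", nfold, " windows for ", nfold,
         "-fold cross-validation")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(nfold), length(idx)))
  }
  fold
}

#' Sequential forward feature selection with parent-channel mapping
#'
#' Greedy wrapper selection: starting from an empty set, each step adds the
#' single feature column that maximises the mean 10-fold cross-validated
#' LDA accuracy of the selected set plus that candidate (ties broken toward
#' the lowest (channel, feature) column index). Each selected feature is
#' mapped back to its parent channel; because several features can share a
#' channel, steps continue until the set of distinct parent channels reaches
#' `n_channels`. Folds are assigned once per run, stratified by gesture
#' class and seeded.
#'
#' @param fm_train training `feature_matrix`.
#' @param n_channels desired number of distinct parent channels.
#' @param seed integer seed for the fold assignment.
#' @param folds number of cross-validation folds.
#' @param lambda LDA shrinkage used during selection.
#' @param verbose print one line per step.
#' @return an object of class `sfs_trace`: data frame `steps` (column index,
#'   channel, feature name, cross-validated accuracy per step), `channels`
#'   (distinct parents in first-appearance order), `features` (selected
#'   column indices), plus `folds`, `seed`, `lambda`.
#' @export
sfs_select <- function(fm_train, n_channels, seed = 1, folds = 10,
                       lambda = 1e-3, verbose = FALSE) {
  stopifnot(inherits(fm_train, "feature_matrix"))
  avail <- unique(fm_train$columns$channel)
  if (n_channels < 1L || n_channels > length(avail))
    stop("n_channels must be in 1..", length(avail),
         " (distinct channels in the training matrix)")
  y <- droplevels(fm_train$y)
  fold <- make_folds(y, nfold = folds, seed = seed)
  y0 <- as.integer(y) - 1L
  X <- fm_train$X
  p <- ncol(X)
  selected <- integer(0)
  channels <- integer(0)
  steps <- list()
  while (length(channels) < n_channels) {
    cand <- setdiff(seq_len(p), selected)
    sc <- sfs_cv_scores(X, y0, as.integer(selected - 1L),
                        as.integer(cand - 1L), as.integer(fold - 1L),
                        as.integer(folds), nlevels(y), lambda)
    best <- cand[which.max(sc)]
    selected <- c(selected, best)
    ch <- fm_train$columns$channel[best]
    if (!ch %in% channels) channels <- c(channels, ch)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, column = best, channel = ch,
      name = fm_train$columns$name[best], cv_accuracy = max(sc))
    if (verbose)
      message(sprintf("step %d: ch %d %s (cv %.4f, %d channels)",
                      length(steps), ch, fm_train$columns$name[best],
                      max(sc), length(channels)))
  }
  structure(list(steps = do.call(rbind, steps), channels = channels,
                 features = selected, folds = folds, seed = seed,
                 lambda = lambda),
            class = "sfs_trace")
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat("SFS trace:", nrow(x$steps), "features ->", length(x$channels),
      "channels; final CV accuracy",
      round(x$steps$cv_accuracy[nrow(x$steps)], 4), "\n")
  invisible(x)
}

#' Channel set from an SFS trace
#'
#' @param trace an `sfs_trace`.
#' @param n optionally keep only the first `n` distinct channels (a prefix
#'   of the trace, by the greedy nesting property).
#' @return a `channel_set` with method `"SFS"`.
#' @export
sfs_channel_set <- function(trace, n = NULL) {
  ch <- trace$channels
  if (!is.null(n)) {
    if (n > length(ch)) stop("trace has only ", length(ch), " channels")
    ch <- ch[seq_len(n)]
  }
  channel_set(ch, "SFS")
}

#' Expand a channel set to all five features per channel
#'
#' After channel selection, all five time-domain features of each selected
#' channel are used downstream, regardless of which individual features the
#' selection picked.
#'
#' @param fm a `feature_matrix`.
#' @param cs a `channel_set` (its channels must all be present in `fm`).
#' @return a `feature_matrix` with `5 * length(cs$channels)` columns.
#' @export
features_for_channels <- function(fm, cs) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(cs, "channel_set"))
  missing <- setdiff(cs$channels, unique(fm$columns$channel))
  if (length(missing))
    stop("channels not present in the feature matrix: ",
         paste(missing, collapse = ", "))
  fm_cols(fm, which(fm$columns$channel %in% cs$channels))
}

#' Export an SFS trace as CSV
#'
#' @param trace an `sfs_trace`.
#' @param path CSV file path.
#' @export
write_sfs_trace <- function(trace, path) {
  write.csv(trace$steps, path, row.names = FALSE)
  invisible(path)
}

#' Test accuracy across channel counts
#'
#' For every channel count `n` in `n_grid`: select channels on the training
#' data (SFS trace prefix, or the fixed circumferential set for CIRC), take
#' all five features per selected channel, fit shrinkage LDA on the training
#' windows and score on the test windows. In `"single"` wrist mode the whole
#' procedure runs per wrist position on that wrist's windows and the
#' reported accuracy is the mean over the three wrist positions; in
#' `"combined"` mode one classifier covers all wrists.
#'
#' @param fm_train,fm_test training and test `feature_matrix` objects.
#' @param method `"SFS"` or `"CIRC"`.
#' @param n_grid ascending channel counts. CIRC is defined at n = 8 only
#'   unless `circ_generalized` enables the equidistant generalisation.
#' @param layout `emg_layout`, required for CIRC.
#' @param seed seed for the SFS fold assignment.
#' @param folds,lambda selection and classifier parameters.
#' @param wrist_mode `"combined"` or `"single"`.
#' @param circ_generalized allow CIRC at n other than 8 by selecting n
#'   equidistant ring columns.
#' @return data frame with columns `method`, `mode`, `n`, `accuracy`.
#' @export
accuracy_vs_channels <- function(fm_train, fm_test, method = c("SFS", "CIRC"),
                                 n_grid, layout = NULL, seed = 1, folds = 10,
                                 lambda = 1e-3,
                                 wrist_mode = c("combined", "single"),
                                 circ_generalized = FALSE) {
  method <- match.arg(method)
  wrist_mode <- match.arg(wrist_mode)
  if (is.unsorted(n_grid)) stop("n_grid must be sorted ascending")
  if (method == "CIRC") {
    if (is.null(layout)) stop("CIRC selection requires the layout")
    if (any(n_grid != 8L) && !circ_generalized)
      stop("CIRC is defined for 8 channels; set circ_generalized = TRUE ",
           "for the equidistant generalisation")
  }
  eval_pair <- function(tr, te) {
    if (method == "SFS")
      trace <- sfs_select(tr, max(n_grid), seed = seed, folds = folds,
                          lambda = lambda)
    vapply(n_grid, function(n) {
      cs <- if (method == "SFS") sfs_channel_set(trace, n)
            else if (n == 8L) circ_select(layout)
            else circ_select_n(layout, n)
      m <- fit_lda(features_for_channels(tr, cs)$X, tr$y, lambda = lambda)
      classification_accuracy(m, features_for_channels(te, cs)$X, te$y)
    }, numeric(1))
  }
  if (wrist_mode == "combined") {
    acc <- eval_pair(fm_train, fm_test)
  } else {
    per <- vapply(hdemg_wrists, function(w) {
      tr <- fm_rows(fm_train, fm_train$meta$wrist == w)
      te <- fm_rows(fm_test, fm_test$meta$wrist == w)
      eval_pair(tr, te)
    }, numeric(length(n_grid)))
    acc <- rowMeans(matrix(per, nrow = length(n_grid)))
  }
  data.frame(method = method, mode = wrist_mode, n = n_grid, accuracy = acc)
}
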