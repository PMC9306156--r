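# Shared fixtures, computed lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# One simulated PG/neutral task recording plus its measured MVC (a few
# seconds to build; shared by the preprocessing and synthetic tests).
task_fixture <- function() {
  if (is.null(.fixture_env$task)) {
    lay <- build_default_layout()
    cfg <- simulation_config()
    mvc_rec <- hdemg:::simulate_mvc_task(cfg, "PG", "neutral", lay, seed = 11)
    rec <- simulate_task(cfg, task_label("PG", "neutral"), lay, seed = 12)
    .fixture_env$task <- list(lay = lay, cfg = cfg, rec = rec,
                              mvc = compute_mvc(mvc_rec))
  }
  .fixture_env$task
}

# Build a feature_matrix object directly from a plain matrix: columns are
# (channel x the 5 feature names) in channel-major order; used by the
# classifier/selection tests that construct feature values analytically.
fm_from_matrix <- function(X, y, channels, wrist = "neutral", level = "low") {
  stopifnot(ncol(X) == 5 * length(channels))
  n <- nrow(X)
  meta <- data.frame(wrist = rep_len(wrist, n), level = rep_len(level, n),
                     task_id = NA_character_, contraction = "1")
  structure(list(
    X = X,
    columns = data.frame(channel = rep(channels, each = 5L),
                         name = rep.int(c("MAV", "ZC", "SSC", "WL", "LogVar"),
                                        length(channels))),
    y = factor(y),
    meta = meta, window_s = 0.25, overlap = 0.5),
    class = "feature_matrix")
}

# Two-class data where exactly one column (channel `informative`, MAV) is
# informative and everything else is standard noise.
informative_channel_fm <- function(informative = 7L,
                                   channels = c(3L, 7L, 9L),
                                   n_per_class = 60L, delta = 3, seed = 99) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(rnorm(n * 5L * length(channels)), nrow = n)
  y <- rep(c("A", "B"), each = n_per_class)
  col <- (match(informative, channels) - 1L) * 5L + 1L  # that channel's MAV
  X[, col] <- X[, col] + ifelse(y == "A", -delta, delta)
  fm_from_matrix(X, y, channels)
}

# Small Gaussian-class feature matrix with per-channel class separation
# given by `sep` (one value per channel, applied to that channel's MAV).
gauss_channels_fm <- function(sep, n_per_class = 40L, classes = c("A", "B"),
                              seed = 5) {
  set.seed(seed)
  channels <- seq_along(sep) - 1L
  n <- length(classes) * n_per_class
  X <- matrix(rnorm(n * 5L * length(channels)), nrow = n)
  y <- rep(classes, each = n_per_class)
  for (i in seq_along(sep)) {
    col <- (i - 1L) * 5L + 1L
    X[, col] <- X[, col] + sep[i] * (as.integer(factor(y)) - 1.5)
  }
  fm_from_matrix(X, y, channels)
}

# Tiny synthetic session with short random signals, for container I/O tests.
tiny_session <- function(seed = 3, n_tasks = 2L, n_samples = 120L) {
  set.seed(seed)
  lay <- build_default_layout()
  cfg <- simulation_config()
  protocol <- session_protocol(seed)[seq_len(n_tasks), , drop = FALSE]
  mvc <- expand.grid(gesture = hdemg_gestures, wrist = hdemg_wrists,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mvc$value <- runif(nrow(mvc), 40, 60)
  recordings <- lapply(seq_len(n_tasks), function(i) {
    lab <- task_label(protocol$gesture[i], protocol$wrist[i])
    structure(list(signal = matrix(rnorm(256 * n_samples), nrow = 256),
                   fs = cfg$fs, label = lab,
                   mvc = mvc$value[mvc$gesture == lab$gesture &
                                     mvc$wrist == lab$wrist],
                   corrupted = integer()),
              class = "emg_recording")
  })
  names(recordings) <- protocol$task_id
  structure(list(protocol = protocol, mvc = mvc, recordings = recordings,
                 mvc_recordings = NULL, layout = lay, config = cfg,
                 seed = seed),
            class = "emg_session")
}
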