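# Session container I/O: a directory with `session.json` (sampling rate,
# layout, labels, MVC values, seed, configuration echo) plus one binary
# signal block per task, `signals_<task_id>.f32` (little-endian 32-bit
# float, channel-major: all samples of channel 1, then channel 2, ...).
# CSV import/export is available as an interoperability escape hatch.

#' Write a session bundle to a directory
#'
#' @param session an `emg_session` from [simulate_session()].
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "emg_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lay <- session$layout
  cfg <- session$config
  meta <- list(
    fs = cfg$fs,
    seed = session$seed,
    layout = list(ied_mm = lay$ied_mm, corrupted = lay$corrupted,
                  channels = lay$channels[, c("index", "grid", "row", "col")]),
    mvc = session$mvc[, c("gesture", "wrist", "value")],
    config = cfg[setdiff(names(cfg), "model")],
    model = cfg$model,
    tasks = data.frame(
      task_id = session$protocol$task_id,
      gesture = session$protocol$gesture,
      wrist = session$protocol$wrist,
      n_channels = vapply(session$recordings, function(r) nrow(r$signal), 0L),
      n_samples = vapply(session$recordings, function(r) ncol(r$signal), 0L))
  )
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  for (id in session$protocol$task_id) {
    con <- file(file.path(dir, paste0("signals_", id, ".f32")), "wb")
    # t() makes channel-major order: channel 1's samples first
    writeBin(as.vector(t(session$recordings[[id]]$signal)), con,
             size = 4L, endian = "little")
    close(con)
  }
  invisible(dir)
}

#' Read a session bundle from a directory
#'
#' Signals round-trip losslessly at 32-bit float precision.
#'
#' @param dir directory written by [write_session()].
#' @return an `emg_session` (without the raw MVC recordings).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  layout <- build_default_layout(corrupted = meta$layout$corrupted %||% integer(),
                                 ied_mm = meta$layout$ied_mm)
  cfg_args <- meta$config[setdiff(names(meta$config), "corrupted")]
  config <- do.call(simulation_config,
                    c(cfg_args, list(corrupted = meta$config$corrupted %||% integer(),
                                     model = as.data.frame(meta$model))))
  tasks <- as.data.frame(meta$tasks)
  mvc <- as.data.frame(meta$mvc)
  recordings <- vector("list", nrow(tasks))
  for (i in seq_len(nrow(tasks))) {
    path <- file.path(dir, paste0("signals_", tasks$task_id[i], ".f32"))
    if (!file.exists(path))
      stop("missing signal file for task '", tasks$task_id[i], "'")
    n_expect <- tasks$n_channels[i] * tasks$n_samples[i]
    con <- file(path, "rb")
    vals <- readBin(con, "numeric", n = n_expect + 1L, size = 4L,
                    endian = "little")
    close(con)
    if (length(vals) != n_expect)
      stop("signal file for task '", tasks$task_id[i], "' has ",
           length(vals), " values, expected ", n_expect)
    lab <- task_label(tasks$gesture[i], tasks$wrist[i])
    recordings[[i]] <- structure(
      list(signal = t(matrix(vals, nrow = tasks$n_samples[i])),
           fs = meta$fs, label = lab,
           mvc = mvc$value[mvc$gesture == lab$gesture & mvc$wrist == lab$wrist],
           corrupted = layout$corrupted),
      class = "emg_recording")
  }
  names(recordings) <- tasks$task_id
  protocol <- tasks[, c("task_id", "gesture", "wrist")]
  structure(list(protocol = protocol, mvc = mvc, recordings = recordings,
                 mvc_recordings = NULL, layout = layout, config = config,
                 seed = meta$seed),
            class = "emg_session")
}

#' Export / import task signals as CSV
#'
#' One CSV per task with one column per channel (header `ch<index>`); a
#' plain-text interoperability format, lossy only to printed precision.
#'
#' @param session an `emg_session`.
#' @param dir target directory.
#' @param digits signif digits written.
#' @export
export_session_csv <- function(session, dir, digits = 7) {
  stopifnot(inherits(session, "emg_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in session$protocol$task_id) {
    sig <- session$recordings[[id]]$signal
    df <- as.data.frame(signif(t(sig), digits))
    names(df) <- sprintf("ch%d", seq_len(nrow(sig)) - 1L)
    write.csv(df, file.path(dir, paste0("signals_", id, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname export_session_csv
#' @param task_id task identifier of the CSV to read back.
#' @return `read_task_csv` returns the channels x samples signal matrix.
#' @export
read_task_csv <- function(dir, task_id) {
  df <- read.csv(file.path(dir, paste0("signals_", task_id, ".csv")),
                 check.names = FALSE)
  t(as.matrix(df))
}
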