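# Synthetic HD-EMG generator.
#
# The simulator reproduces the statistical structure the downstream analysis
# relies on, not motor-unit physiology: each active gesture drives a small
# number of spatial "hot spots" on the forearm cylinder; every hot spot is an
# independent band-limited (10-500 Hz) Gaussian source mixed into the channels
# with Gaussian spatial weights, so that neighbouring channels are correlated
# as in real surface recordings; the wrist position rigidly shifts the spots
# around/along the cylinder; the contraction level scales the sources through
# a trapezoidal activation profile; baseline instrumentation noise is added
# everywhere and corrupted channels carry large-variance noise instead of
# signal.

#' Default gesture hot-spot table
#'
#' Fixed table of spatial hot spots for the seven active gestures (rest has
#' none): circumferential position in ring-column units (1..24, may be
#' fractional), proximo-distal position in mm (negative values lie on the
#' distal ventral grid), and relative source amplitude (1 corresponds to
#' `snr` times the baseline noise RMS at full activation). Every gesture pair
#' differs in at least one spot, ventral columns (ring 1-8) carry the
#' flexor-driven grasps and dorso-lateral columns (9-24) the extension
#' gestures, and a few spots sit on the distal grid.
#'
#' @return data frame with columns `gesture`, `theta_col`, `z_mm`, `rel_amp`.
#' @export
default_gesture_model <- function() {
  tab <- rbind(
    c("PG",  3, 20, 1.4), c("PG",  6, 40, 1.2), c("PG",  4, -30, 1.0),
    c("OP",  2, 40, 1.0), c("OP",  8, 20, 0.9), c("OP",  6, -50, 0.8),
    c("TP2", 4, 50, 1.1), c("TP2", 10, 20, 0.8), c("TP2", 2, -20, 0.9),
    c("LG",  7, 10, 1.2), c("LG", 16, 40, 0.9), c("LG",  1, 50, 0.8),
    c("TP3", 5, 30, 1.0), c("TP3", 12, 50, 0.9), c("TP3", 22, 20, 0.7),
    c("IP", 13, 20, 1.2), c("IP", 18, 10, 1.0), c("IP", 15, 50, 0.8),
    c("HO", 17, 30, 1.3), c("HO", 21, 50, 1.0), c("HO", 11, 10, 0.9)
  )
  data.frame(gesture = tab[, 1],
             theta_col = as.numeric(tab[, 2]),
             z_mm = as.numeric(tab[, 3]),
             rel_amp = as.numeric(tab[, 4]))
}

#' Simulation configuration
#'
#' Bundles the generator parameters. Defaults define the package's reference
#' synthetic benchmark; see the methods vignette for the rationale behind
#' each value.
#'
#' @param fs sampling rate in Hz.
#' @param baseline_noise baseline (rest) noise RMS in microvolt.
#' @param snr ratio of hot-spot source RMS at full activation (MVC) to the
#'   baseline noise RMS.
#' @param spatial_sigma spatial spread (mm) of the Gaussian mixing weights.
#' @param wrist_dcol circumferential hot-spot shift for pronation, in ring
#'   columns (supination shifts by the opposite amount; neutral is zero).
#' @param wrist_dz_mm proximo-distal hot-spot shift for pronation, in mm
#'   (supination mirrored).
#' @param jitter_col_sd,jitter_z_sd standard deviation of per-session
#'   ("subject") jitter applied once to hot-spot positions, in ring columns
#'   and mm.
#' @param corrupted_gain multiple of the baseline noise RMS carried by
#'   corrupted channels.
#' @param corrupted integer vector of corrupted channel indices (0-based).
#' @param model gesture hot-spot table, see [default_gesture_model()].
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(fs = 2048, baseline_noise = 2, snr = 150,
                              spatial_sigma = 15, wrist_dcol = 2,
                              wrist_dz_mm = -10, jitter_col_sd = 0,
                              jitter_z_sd = 0, corrupted_gain = 20,
                              corrupted = integer(),
                              model = default_gesture_model()) {
  stopifnot(fs > 0, baseline_noise > 0, snr > 0, spatial_sigma > 0,
            corrupted_gain > 0)
  stopifnot(all(c("gesture", "theta_col", "z_mm", "rel_amp") %in% names(model)))
  if (any(model$rel_amp <= 0)) stop("hot-spot amplitudes must be positive")
  if ("RE" %in% model$gesture) stop("rest has no hot spots")
  structure(list(fs = fs, baseline_noise = baseline_noise, snr = snr,
                 spatial_sigma = spatial_sigma, wrist_dcol = wrist_dcol,
                 wrist_dz_mm = wrist_dz_mm, jitter_col_sd = jitter_col_sd,
                 jitter_z_sd = jitter_z_sd, corrupted_gain = corrupted_gain,
                 corrupted = as.integer(corrupted), model = model),
            class = "sim_config")
}

# Hot-spot displacement for a wrist position: c(dtheta [rad], dz [mm]).
wrist_offset <- function(config, wrist) {
  wrist <- match.arg(wrist, hdemg_wrists)
  s <- switch(wrist, pronation = 1, neutral = 0, supination = -1)
  c(dtheta = s * config$wrist_dcol * 2 * pi / RING_COLS,
    dz = s * config$wrist_dz_mm)
}

# Apply per-session ("subject") jitter to the hot-spot table, seeded.
jitter_model <- function(config, seed) {
  if (config$jitter_col_sd == 0 && config$jitter_z_sd == 0) return(config)
  set.seed(seed)
  m <- config$model
  m$theta_col <- m$theta_col + rnorm(nrow(m), 0, config$jitter_col_sd)
  m$z_mm <- m$z_mm + rnorm(nrow(m), 0, config$jitter_z_sd)
  config$model <- m
  config
}

#' Trapezoidal activation profile of a data-collection task
#'
#' The reference profile tracked during recording: two trapezoids with 1-s
#' ascending and descending ramps and a 4-s plateau, separated by 5 s of
#' rest; the first plateau at 30% and the second at 60% of the MVC. Total
#' duration 17 s.
#'
#' @param fs sampling rate in Hz.
#' @return an object of class `activation_profile`: list with `fs`, `samples`
#'   (per-sample target activation as a fraction of MVC) and the segment
#'   parameters.
#' @export
make_activation_profile <- function(fs) {
  stopifnot(fs > 0)
  breaks <- c(0, 1, 5, 6, 11, 12, 16, 17)
  values <- c(0, 0.30, 0.30, 0, 0, 0.60, 0.60, 0)
  n <- round(17 * fs)
  t <- (seq_len(n) - 1) / fs
  structure(list(fs = fs,
                 samples = approx(breaks, values, xout = t, rule = 2)$y,
                 ramp_s = 1, plateau_s = 4, separation_s = 5,
                 plateau_levels = c(0.30, 0.60)),
            class = "activation_profile")
}

# Hot spots of a gesture after the wrist shift, with absolute amplitudes (uV).
gesture_spots <- function(config, gesture, wrist) {
  spots <- config$model[config$model$gesture == gesture, , drop = FALSE]
  if (nrow(spots) == 0L) return(spots)
  off <- wrist_offset(config, wrist)
  spots$theta <- ((spots$theta_col - 1) * 2 * pi / RING_COLS + off["dtheta"]) %% (2 * pi)
  spots$z <- spots$z_mm + off["dz"]
  spots$amp <- config$snr * config$baseline_noise * spots$rel_amp
  spots
}

#' Expected per-channel RMS map at full activation
#'
#' Deterministic spatial map of the per-channel RMS amplitude (microvolt) a
#' task would show at full (MVC-level) activation:
#' `baseline + sum_k amp_k * exp(-d(c, spot_k)^2 / (2 sigma^2))`, with `d`
#' the geodesic distance on the forearm cylinder and the spots shifted
#' according to the wrist position. Rest maps are flat at the baseline.
#'
#' @param config a `sim_config`.
#' @param label a [task_label()] (the level is irrelevant for the map).
#' @param layout an `emg_layout`.
#' @return numeric vector of length 256 (microvolt RMS), in channel order.
#' @export
channel_rms_map <- function(config, label, layout) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "emg_layout"))
  rms <- rep(config$baseline_noise, nrow(layout$channels))
  spots <- gesture_spots(config, label$gesture, label$wrist)
  s2 <- 2 * config$spatial_sigma^2
  for (k in seq_len(nrow(spots))) {
    d <- cyl_distance(layout, spots$theta[k], spots$z[k])
    rms <- rms + spots$amp[k] * exp(-d^2 / s2)
  }
  rms
}

# Band-limited (10-500 Hz) unit-RMS Gaussian noise, one row per trace.
bandlimited_noise <- function(nrow, nsamp, fs) {
  bf <- signal::butter(2, c(10, 500) / (fs / 2), type = "pass")
  out <- matrix(rnorm(nrow * nsamp), nrow = nrow)
  for (i in seq_len(nrow)) {
    v <- signal::filter(bf, out[i, ])
    out[i, ] <- v / sqrt(mean(v^2))
  }
  out
}

# Gaussian mixing weights (channels x spots), in uV at full activation.
mixing_weights <- function(config, layout, spots) {
  s2 <- 2 * config$spatial_sigma^2
  W <- matrix(0, nrow(layout$channels), nrow(spots))
  for (k in seq_len(nrow(spots)))
    W[, k] <- spots$amp[k] * exp(-cyl_distance(layout, spots$theta[k], spots$z[k])^2 / s2)
  W
}

#' Simulate one task recording
#'
#' Generates a 256-channel recording of one (gesture, wrist) task following
#' the two-trapezoid activation profile (or an arbitrary activation vector).
#' Each hot spot drives an independent band-limited Gaussian source; channel
#' signals are the spatially weighted source mixture scaled by the activation
#' profile, plus baseline noise. Corrupted channels carry high-variance noise
#' only. Reproducible for a fixed seed.
#'
#' @param config a `sim_config`.
#' @param label a [task_label()].
#' @param layout an `emg_layout`.
#' @param seed integer seed.
#' @param activation optional per-sample activation vector (fraction of MVC)
#'   overriding the default 17-s profile; used e.g. for MVC recordings.
#' @return an object of class `emg_recording`: list with `signal`
#'   (channels x samples, microvolt), `fs`, `label`, `mvc` (filled by the
#'   session generator) and `corrupted`.
#' @export
simulate_task <- function(config, label, layout, seed,
                          activation = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "emg_layout"))
  set.seed(seed)
  fs <- config$fs
  if (is.null(activation))
    activation <- make_activation_profile(fs)$samples
  n <- length(activation)
  nch <- nrow(layout$channels)
  sig <- config$baseline_noise * bandlimited_noise(nch, n, fs)
  spots <- gesture_spots(config, label$gesture, label$wrist)
  if (nrow(spots) > 0L) {
    S <- bandlimited_noise(nrow(spots), n, fs)
    S <- S * rep(activation, each = nrow(spots))
    sig <- sig + mixing_weights(config, layout, spots) %*% S
  }
  corr <- intersect(union(config$corrupted, layout$corrupted),
                    layout$channels$index)
  if (length(corr)) {
    rows <- match(corr, layout$channels$index)
    sig[rows, ] <- config$corrupted_gain * config$baseline_noise *
      bandlimited_noise(length(rows), n, fs)
  }
  structure(list(signal = sig, fs = fs, label = label, mvc = NA_real_,
                 corrupted = sort(corr)),
            class = "emg_recording")
}

# MVC recording: 3 s of sustained full activation.
simulate_mvc_task <- function(config, gesture, wrist, layout, seed) {
  simulate_task(config, task_label(gesture, wrist), layout, seed,
                activation = rep(1, round(3 * config$fs)))
}

#' Pseudorandom data-collection protocol
#'
#' The 24-task sequence of one session: each combination of the 8 gestures
#' and 3 wrist positions exactly once, in seeded pseudorandom order.
#'
#' @param seed integer seed.
#' @return data frame with columns `task_id`, `gesture`, `wrist`.
#' @export
session_protocol <- function(seed) {
  tasks <- expand.grid(gesture = hdemg_gestures, wrist = hdemg_wrists,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  set.seed(seed)
  tasks <- tasks[sample.int(nrow(tasks)), , drop = FALSE]
  tasks$task_id <- sprintf("%02d_%s_%s", seq_len(nrow(tasks)),
                           tasks$gesture, tasks$wrist)
  rownames(tasks) <- NULL
  tasks[, c("task_id", "gesture", "wrist")]
}

# Deterministic seed plan for one session: protocol order, per-(gesture,wrist)
# MVC seeds and per-task seeds, all derived from the session seed.
session_seed_plan <- function(seed) {
  protocol <- session_protocol(seed)
  # session_protocol() consumed the RNG stream from `seed`; continue it.
  mvc <- expand.grid(gesture = hdemg_gestures, wrist = hdemg_wrists,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- sample.int(.Machine$integer.max - 1L, nrow(mvc) + nrow(protocol) + 1L)
  mvc$seed <- s[seq_len(nrow(mvc))]
  protocol$seed <- s[nrow(mvc) + seq_len(nrow(protocol))]
  list(protocol = protocol, mvc = mvc, jitter_seed = s[length(s)])
}

#' Simulate a full recording session
#'
#' Generates the MVC recordings (3-s sustained full activation per gesture
#' and wrist position) and the 24 task recordings of one session in seeded
#' pseudorandom order. Session MVC values are measured from the simulated
#' MVC recordings with [compute_mvc()] (not taken from the configuration)
#' and stamped onto each task recording.
#'
#' @param config a `sim_config`.
#' @param layout an `emg_layout`.
#' @param seed integer session seed.
#' @param tasks optional integer vector of protocol positions to simulate
#'   (default all 24); MVC values are always computed for the gestures the
#'   selected tasks need.
#' @param keep_mvc_recordings keep the raw MVC recordings in the returned
#'   object (large); by default only the measured MVC values are retained.
#' @return an object of class `emg_session`: list with `protocol`, `mvc`
#'   (data frame gesture x wrist x value), `recordings` (list of
#'   `emg_recording`), `layout`, `config`, `seed`.
#' @export
simulate_session <- function(config, layout, seed, tasks = NULL,
                             keep_mvc_recordings = FALSE) {
  plan <- session_seed_plan(seed)
  config <- jitter_model(config, plan$jitter_seed)
  if (is.null(tasks)) tasks <- seq_len(nrow(plan$protocol))
  protocol <- plan$protocol[tasks, , drop = FALSE]
  need <- unique(protocol[, c("gesture", "wrist")])
  mvc <- plan$mvc
  mvc$value <- NA_real_
  mvc_recs <- list()
  for (i in seq_len(nrow(mvc))) {
    if (!any(need$gesture == mvc$gesture[i] & need$wrist == mvc$wrist[i]))
      next
    rec <- simulate_mvc_task(config, mvc$gesture[i], mvc$wrist[i], layout,
                             mvc$seed[i])
    mvc$value[i] <- compute_mvc(rec)
    if (keep_mvc_recordings)
      mvc_recs[[paste(mvc$gesture[i], mvc$wrist[i], sep = "_")]] <- rec
  }
  recordings <- vector("list", nrow(protocol))
  for (j in seq_len(nrow(protocol))) {
    lab <- task_label(protocol$gesture[j], protocol$wrist[j])
    rec <- simulate_task(config, lab, layout, protocol$seed[j])
    rec$mvc <- mvc$value[mvc$gesture == lab$gesture & mvc$wrist == lab$wrist]
    recordings[[j]] <- rec
  }
  names(recordings) <- protocol$task_id
  structure(list(protocol = protocol, mvc = mvc, recordings = recordings,
                 mvc_recordings = if (keep_mvc_recordings) mvc_recs,
                 layout = layout, config = config, seed = seed),
            class = "emg_session")
}

#' Feature matrix of a full synthetic session (streaming)
#'
#' Convenience pipeline that simulates one session task by task and runs the
#' offline preprocessing chain on each recording before discarding its
#' signal: band-pass filtering, MVC-referenced contraction segmentation and
#' time-domain feature extraction. Memory stays bounded by a single task.
#'
#' @inheritParams simulate_session
#' @param window_s,overlap analysis window length (s) and fractional overlap.
#' @param eps amplitude deadband for the ZC/SSC features; `NULL` for the
#'   default 1% of the window RMS.
#' @param filter apply the zero-phase 10-500 Hz band-pass before analysis.
#' @return a `feature_matrix` (see [build_feature_matrix()]) covering the
#'   whole session.
#' @export
session_feature_matrix <- function(config, layout, seed,
                                   window_s = 0.25, overlap = 0.5,
                                   eps = NULL, filter = TRUE, tasks = NULL) {
  plan <- session_seed_plan(seed)
  config <- jitter_model(config, plan$jitter_seed)
  if (is.null(tasks)) tasks <- seq_len(nrow(plan$protocol))
  protocol <- plan$protocol[tasks, , drop = FALSE]
  need <- unique(protocol[, c("gesture", "wrist")])
  mvc <- plan$mvc
  mvc$value <- NA_real_
  for (i in seq_len(nrow(mvc))) {
    if (!any(need$gesture == mvc$gesture[i] & need$wrist == mvc$wrist[i]))
      next
    rec <- simulate_mvc_task(config, mvc$gesture[i], mvc$wrist[i], layout,
                             mvc$seed[i])
    if (filter) rec <- bandpass(rec, config$fs)
    mvc$value[i] <- compute_mvc(rec)
  }
  parts <- vector("list", nrow(protocol))
  for (j in seq_len(nrow(protocol))) {
    lab <- task_label(protocol$gesture[j], protocol$wrist[j])
    rec <- simulate_task(config, lab, layout, protocol$seed[j])
    if (filter) rec <- bandpass(rec, config$fs)
    rec$mvc <- mvc$value[mvc$gesture == lab$gesture & mvc$wrist == lab$wrist]
    segs <- segment_contractions(rec, rec$mvc)
    parts[[j]] <- build_feature_matrix(segs, layout, window_s = window_s,
                                       overlap = overlap, eps = eps,
                                       task_id = protocol$task_id[j])
  }
  do.call(rbind_feature_matrix, parts)
}
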