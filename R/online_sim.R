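# Closed-loop simulation of the online gesture-control task: a synthetic
# subject produces EMG for a target (gesture, wrist) at a commanded
# activation level; every 125 ms a 250-ms analysis segment (the new 125 ms
# plus the previous 125 ms) is featurised on the active channel set and
# classified. Predictions count toward the dwell only while the activation
# lies inside the target gating window; the trial succeeds when the target
# class is held for 2 s of consecutive valid ticks and fails at the 10-s
# timeout.

#' Specification of one online trial
#'
#' Gating windows: low force 10-35% MVC, moderate force 45-75% MVC. A rest
#' target uses the window (0, 10%] MVC - relaxing below the low-force bound
#' is what "performing" rest means, so rest trials are gated on inactivity.
#'
#' @param gesture,wrist the target task.
#' @param level `"low"` or `"moderate"` target contraction level.
#' @param dwell_s required continuous match duration (s).
#' @param timeout_s trial timeout (s).
#' @param tick_s prediction period (s).
#' @return an object of class `trial_spec` with the gating `window`
#'   (fractions of MVC) included.
#' @export
trial_spec <- function(gesture, wrist, level = c("low", "moderate"),
                       dwell_s = 2, timeout_s = 10, tick_s = 0.125) {
  level <- match.arg(level)
  gesture <- match.arg(gesture, hdemg_gestures)
  wrist <- match.arg(wrist, hdemg_wrists)
  window <- if (gesture == "RE") c(0, 0.10)
            else if (level == "low") c(0.10, 0.35)
            else c(0.45, 0.75)
  stopifnot(window[1] < window[2], dwell_s < timeout_s)
  structure(list(gesture = gesture, wrist = wrist, level = level,
                 window = window, dwell_s = dwell_s, timeout_s = timeout_s,
                 tick_s = tick_s),
            class = "trial_spec")
}

#' Synthetic subject policy
#'
#' Open-loop stand-in for the human participant: after a reaction delay the
#' subject holds the middle of the gating window with multiplicative
#' activation noise, and occasionally produces an off-target spatial
#' pattern (a wrong gesture) for one analysis window. The policy does not
#' react to feedback; adaptive corrective behaviour is the main fidelity
#' gap relative to a human subject.
#'
#' @param reaction_delay_s delay before the subject starts the task (s).
#' @param activation_sd multiplicative noise on the produced activation.
#' @param off_target_prob probability per tick of producing a wrong
#'   gesture's spatial pattern.
#' @param activation_target produced activation as a fraction of MVC;
#'   `NULL` targets the gating-window midpoint.
#' @param rest_activation residual activation while at rest.
#' @return an object of class `subject_policy`.
#' @export
subject_policy <- function(reaction_delay_s = 0.25, activation_sd = 0.08,
                           off_target_prob = 0.03, activation_target = NULL,
                           rest_activation = 0.02) {
  stopifnot(reaction_delay_s >= 0, activation_sd >= 0,
            off_target_prob >= 0, off_target_prob <= 1)
  structure(list(reaction_delay_s = reaction_delay_s,
                 activation_sd = activation_sd,
                 off_target_prob = off_target_prob,
                 activation_target = activation_target,
                 rest_activation = rest_activation),
            class = "subject_policy")
}

#' Run one simulated online trial
#'
#' @param model either a fitted `emg_lda` trained on the
#'   all-five-features-per-channel expansion of `cs` (see
#'   [features_for_channels()]), or - for protocol-level tests - a stub
#'   function `function(tick)` returning a gesture label directly, in which
#'   case no signal is generated.
#' @param cs the active `channel_set`; only these channels are generated
#'   and featurised.
#' @param spec a [trial_spec()].
#' @param policy a [subject_policy()].
#' @param config a `sim_config` (required for model-based trials).
#' @param layout an `emg_layout` (required for model-based trials).
#' @param seed integer seed.
#' @param eps ZC/SSC deadband passed to feature extraction.
#' @return an object of class `trial_result`: `success`, `time_s` (`NA` on
#'   failure; measured from target display to the tick completing the
#'   dwell, inclusive of the dwell), `dwellings` (prediction changes between
#'   consecutive in-window ticks), and the per-tick `predictions`, `valid`
#'   and `activation` traces.
#' @export
run_trial <- function(model, cs, spec, policy, config = NULL, layout = NULL,
                      seed = 1, eps = NULL) {
  stopifnot(inherits(spec, "trial_spec"), inherits(policy, "subject_policy"))
  set.seed(seed)
  nticks <- round(spec$timeout_s / spec$tick_s)
  dwell_need <- round(spec$dwell_s / spec$tick_s)
  target_a <- policy$activation_target %||%
    (if (spec$gesture == "RE") policy$rest_activation else mean(spec$window))
  active_pool <- setdiff(hdemg_gestures, "RE")
  t_k <- seq_len(nticks) * spec$tick_s
  started <- t_k > policy$reaction_delay_s
  activation <- ifelse(started,
                       pmin(pmax(target_a * (1 + rnorm(nticks) * policy$activation_sd), 0), 1),
                       policy$rest_activation)
  gest <- ifelse(started, spec$gesture, "RE")
  flip <- started & runif(nticks) < policy$off_target_prob
  if (any(flip))
    gest[flip] <- vapply(gest[flip], function(g)
      sample(setdiff(active_pool, g), 1L), "")
  if (is.function(model)) {
    predictions <- vapply(seq_len(nticks), function(k) as.character(model(k)), "")
  } else {
    stopifnot(inherits(model, "emg_lda"), inherits(config, "sim_config"),
              inherits(layout, "emg_layout"))
    block <- round(spec$tick_s * config$fs)
    total <- (nticks + 1L) * block
    ch <- sort(cs$channels)
    rows <- match(ch, layout$channels$index)
    X <- config$baseline_noise * bandlimited_noise(length(ch), total, config$fs)
    for (g in intersect(unique(gest), active_pool)) {
      spots <- gesture_spots(config, g, spec$wrist)
      W <- mixing_weights(config, layout, spots)[rows, , drop = FALSE]
      S <- bandlimited_noise(nrow(spots), total, config$fs)
      for (k in which(gest == g)) {
        cols <- k * block + seq_len(block)
        X[, cols] <- X[, cols] + W %*% S[, cols, drop = FALSE] * activation[k]
      }
    }
    predictions <- character(nticks)
    for (k in seq_len(nticks)) {
      seg <- X[, (k - 1L) * block + seq_len(2L * block), drop = FALSE]
      f <- as.vector(td_features_mat(t(seg), eps = eps))
      predictions[k] <- as.character(predict(model, matrix(f, nrow = 1)))
    }
  }
  valid <- activation >= spec$window[1] & activation <= spec$window[2]
  streak <- 0L
  success <- FALSE
  end_tick <- nticks
  for (k in seq_len(nticks)) {
    streak <- if (valid[k] && predictions[k] == spec$gesture) streak + 1L else 0L
    if (streak >= dwell_need) {
      success <- TRUE
      end_tick <- k
      break
    }
  }
  vseq <- predictions[seq_len(end_tick)][valid[seq_len(end_tick)]]
  dwellings <- if (length(vseq) > 1L) sum(vseq[-1L] != vseq[-length(vseq)]) else 0L
  structure(list(success = success,
                 time_s = if (success) end_tick * spec$tick_s else NA_real_,
                 dwellings = dwellings,
                 predictions = predictions[seq_len(end_tick)],
                 valid = valid[seq_len(end_tick)],
                 activation = activation[seq_len(end_tick)],
                 spec = spec),
            class = "trial_result")
}

#' Run one block of online trials
#'
#' One repetition of every combination of the 8 gestures, 3 wrist positions
#' and the selected channel-set methods, in seeded random order, all at the
#' given target contraction level.
#'
#' @param models named list of fitted `emg_lda` models (or stub functions),
#'   one per method.
#' @param channel_sets named list of `channel_set` objects matching
#'   `models`.
#' @param config a `sim_config`.
#' @param layout an `emg_layout`.
#' @param level `"low"` or `"moderate"`.
#' @param seed integer seed (trial order and per-trial seeds).
#' @param policy a [subject_policy()].
#' @param methods which methods to run (default all in `models`).
#' @return data frame of class `trial_results`, one row per trial:
#'   `method`, `gesture`, `wrist`, `level`, `success`, `time_s`,
#'   `dwellings`.
#' @export
run_block <- function(models, channel_sets, config, layout,
                      level = c("low", "moderate"), seed = 1,
                      policy = subject_policy(), methods = names(models)) {
  level <- match.arg(level)
  stopifnot(all(methods %in% names(models)),
            all(methods %in% names(channel_sets)))
  grid <- expand.grid(gesture = hdemg_gestures, wrist = hdemg_wrists,
                      method = methods, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  set.seed(seed)
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  grid$trial_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    spec <- trial_spec(grid$gesture[i], grid$wrist[i], level)
    run_trial(models[[grid$method[i]]], channel_sets[[grid$method[i]]],
              spec, policy, config, layout, seed = grid$trial_seed[i])
  })
  out <- data.frame(method = grid$method, gesture = grid$gesture,
                    wrist = grid$wrist, level = level,
                    success = vapply(res, `[[`, logical(1), "success"),
                    time_s = vapply(res, `[[`, numeric(1), "time_s"),
                    dwellings = vapply(res, `[[`, numeric(1), "dwellings"))
  rownames(out) <- NULL
  attr(out, "trials") <- res
  class(out) <- c("trial_results", class(out))
  out
}

#' Outcome measures of online trials
#'
#' Completion rate over all trials; completion time and number of dwellings
#' summarised (median) over the successful trials only.
#'
#' @param results a `trial_results` data frame (or any data frame with
#'   `success`, `time_s`, `dwellings` columns).
#' @param by optional character vector of grouping columns (e.g.
#'   `c("method", "level")`).
#' @return data frame with `n`, `completion_rate` (percent),
#'   `median_time_s` and `median_dwellings` (`NA` when a group has no
#'   successes).
#' @export
outcome_measures <- function(results, by = NULL) {
  if (nrow(results) == 0L) stop("no trials to summarise")
  summarise <- function(df) {
    succ <- df[df$success, , drop = FALSE]
    data.frame(n = nrow(df),
               completion_rate = 100 * mean(df$success),
               median_time_s = if (nrow(succ)) median(succ$time_s) else NA_real_,
               median_dwellings = if (nrow(succ)) median(succ$dwellings) else NA_real_)
  }
  if (is.null(by)) return(summarise(results))
  groups <- split(seq_len(nrow(results)),
                  interaction(results[by], drop = TRUE, sep = "/"))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    cbind(results[groups[[g]][1L], by, drop = FALSE],
          summarise(results[groups[[g]], , drop = FALSE]))
  }))
  rownames(out) <- NULL
  out
}

#' Write trial results as CSV
#'
#' @param results a `trial_results` data frame.
#' @param path CSV file path.
#' @export
write_trial_results <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}
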