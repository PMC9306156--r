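# Run configuration: one structured-text (YAML) document collecting every
# tunable parameter of the pipeline, with documented defaults. All
# randomness of a run derives from the single `seed`, split
# deterministically per stage.

#' Default run configuration
#'
#' @param seed master seed of the run.
#' @return nested list of class `run_config` with components `sim`
#'   (simulator parameters, see [simulation_config()]), `features`
#'   (`window_s`, `overlap`, `eps`), `split` (`train_frac`), `sfs`
#'   (`folds`, `n_channels`), `lda` (`lambda`), `online`
#'   ([subject_policy()] parameters) and `seed`.
#' @export
run_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    sim = list(fs = 2048, baseline_noise = 2, snr = 150, spatial_sigma = 15,
               wrist_dcol = 2, wrist_dz_mm = -10, jitter_col_sd = 0,
               jitter_z_sd = 0, corrupted_gain = 20, corrupted = integer()),
    features = list(window_s = 0.25, overlap = 0.5, eps = NULL),
    split = list(train_frac = 0.70),
    sfs = list(folds = 10, n_channels = 8),
    lda = list(lambda = 1e-3),
    online = list(reaction_delay_s = 0.25, activation_sd = 0.08,
                  off_target_prob = 0.03)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- unclass(run_config())
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (is.list(base[[sec]])) {
      badk <- setdiff(names(user[[sec]]), names(base[[sec]]))
      if (length(badk))
        stop("unknown key(s) in '", sec, "': ", paste(badk, collapse = ", "))
      base[[sec]] <- modifyList(base[[sec]], user[[sec]])
    } else {
      base[[sec]] <- user[[sec]]
    }
  }
  structure(base, class = "run_config")
}

# Materialise the sim_config of a run.
as_sim_config <- function(rc) do.call(simulation_config, rc$sim)
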