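#' Motility-state presets
#'
#' Axonal organelles move, to a good approximation, in one of two discrete
#' trafficking states: a mobile state with processive runs and an immobile
#' state dominated by pausing and non-processive jitter. Each
#' (state, organelle) pair is described by a small set of run-and-pause
#' kinetic parameters that were calibrated once, by grid search, so that
#' simulated tracks reproduce the published state-level statistics
#' (mobile: ~0.7/1.1 um/s mean speed and ~9/14 um net displacement for
#' mitochondria/lysosomes; immobile: ~0.4 um/s and ~5 um for both). The
#' frozen values ship in `inst/extdata/motility_presets.yaml`.
#'
#' @param state `"mobile"` or `"immobile"`.
#' @param organelle `"mito"` or `"lyso"`.
#' @param file Optional path to an alternative preset YAML file.
#'
#' @return An object of class `motility_state`: a list with fields `name`,
#'   `organelle`, `run_speed_mean` (um/s), `run_speed_sd` (um/s),
#'   `pause_fraction`, `reversal_prob_per_step`, `jitter_sd` (um per step),
#'   `diameter_meanlog`, `diameter_sdlog` (log-um, per-track diameters).
#' @examples
#' motility_preset("mobile", "mito")$run_speed_mean
#' @export
motility_preset <- function(state = c("mobile", "immobile"),
                            organelle = c("mito", "lyso"),
                            file = NULL) {
  state <- match.arg(state)
  organelle <- match.arg(organelle)
  tab <- load_presets(file)
  key <- paste(state, organelle, sep = "_")
  if (!key %in% names(tab)) {
    stop("no preset for state '", state, "' and organelle '", organelle, "'")
  }
  p <- tab[[key]]
  motility_state(name = state, organelle = organelle,
                 run_speed_mean = p$run_speed_mean,
                 run_speed_sd = p$run_speed_sd,
                 pause_fraction = p$pause_fraction,
                 reversal_prob_per_step = p$reversal_prob_per_step,
                 jitter_sd = p$jitter_sd,
                 diameter_meanlog = p$diameter_meanlog,
                 diameter_sdlog = p$diameter_sdlog)
}

#' Construct a motility state from explicit kinetic parameters
#'
#' @param name State label, `"mobile"` or `"immobile"`.
#' @param organelle Channel label, `"mito"` or `"lyso"`.
#' @param run_speed_mean,run_speed_sd Per-step run speed law (um/s); draws
#'   are truncated at zero.
#' @param pause_fraction Probability that a step is a pause (no directed
#'   motion), in `[0, 1]`.
#' @param reversal_prob_per_step Probability per step of reversing the run
#'   direction, in `[0, 1]`.
#' @param jitter_sd Isotropic positional jitter added per step (um).
#' @param diameter_meanlog,diameter_sdlog Log-normal law for per-track
#'   apparent diameters (um).
#' @return A `motility_state` object.
#' @export
motility_state <- function(name, organelle, run_speed_mean, run_speed_sd,
                           pause_fraction, reversal_prob_per_step,
                           jitter_sd, diameter_meanlog = log(0.8),
                           diameter_sdlog = 0.2) {
  stopifnot(run_speed_mean >= 0, run_speed_sd >= 0, jitter_sd >= 0)
  if (pause_fraction < 0 || pause_fraction > 1) {
    stop("pause_fraction must be in [0, 1]")
  }
  if (reversal_prob_per_step < 0 || reversal_prob_per_step > 1) {
    stop("reversal_prob_per_step must be in [0, 1]")
  }
  structure(
    list(name = name, organelle = organelle,
         run_speed_mean = run_speed_mean, run_speed_sd = run_speed_sd,
         pause_fraction = pause_fraction,
         reversal_prob_per_step = reversal_prob_per_step,
         jitter_sd = jitter_sd,
         diameter_meanlog = diameter_meanlog,
         diameter_sdlog = diameter_sdlog),
    class = "motility_state")
}

load_presets <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "motility_presets.yaml",
                        package = "axotrace", mustWork = TRUE)
  }
  yaml::read_yaml(file)
}
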