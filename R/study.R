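#' Reference conditions of the in-silico TEP experiment
#'
#' The whole-brain TEP simulations are run at a fixed operating point
#' chosen so that the network reproduces the qualitative physiology of
#' a TMS-evoked potential: regions rest at a stable fixed point (the
#' constant background drive `qcon = 45` /s lies below the oscillatory
#' range of the Jansen-Rit model), while long-range input (saturation
#' `gmax = 90` /s) places strongly connected hub regions close to the
#' oscillation onset. The TMS pulse (focal amplitude 4000 /s for 1 ms)
#' and the EIN noise (std 45 /s) then evoke damped, propagating
#' responses whose size is sensitive to the inhibitory parameters `b`
#' and `C4` — decreasing either pushes part of the network across the
#' large-amplitude oscillation threshold, increasing the global mean
#' field amplitude, which is the phenomenon under study.
#'
#' Everything is overridable per call; these values define the default
#' study conditions used by the pipeline, the sweep drivers and the
#' acceptance analyses.
#'
#' @param seed Integer seed stored in the simulation configuration.
#' @return List with elements `params` ([jr_params()]), `coupling`
#'   ([coupling_params()]), `noise` ([noise_spec()]), `config`
#'   ([sim_config()]) and `stimulus_amplitude` (focal amplitude, 1/s).
#' @export
study_conditions <- function(seed = 42L) {
  list(params = jr_params(qcon = 45),
       coupling = coupling_params(gmax = 90),
       noise = noise_spec(std = 45),
       config = sim_config(seed = seed),
       stimulus_amplitude = 4000)
}
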