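#' Jansen-Rit neural mass parameters
#'
#' Parameter set for the three-population Jansen-Rit model (pyramidal
#' cells PC, excitatory interneurons EIN, inhibitory interneurons IIN).
#' Defaults are the classical Jansen & Rit (1995) values. The two
#' inhibitory parameters central to the GABA-deficit experiments are `b`
#' (inhibitory synaptic decay rate, default 50 /s) and `C4` (number of
#' inhibitory synapses from IIN onto PC, default 33.75).
#'
#' @param A Maximum excitatory PSP (mV).
#' @param B Maximum inhibitory PSP (mV).
#' @param a Excitatory synaptic decay rate (1/s), reciprocal of the
#'   excitatory synaptic time constant.
#' @param b Inhibitory synaptic decay rate (1/s).
#' @param C1,C2,C3,C4 Synapse-count constants: PC->EIN, EIN->PC, PC->IIN,
#'   IIN->PC.
#' @param vmax Half of the maximum population firing rate (1/s).
#' @param v0 Firing threshold (mV) at which half the maximum rate is
#'   reached.
#' @param r Sigmoid steepness (1/mV).
#' @param qcon Constant external input to the EIN population (1/s),
#'   representing unspecific background drive.
#' @return A `jr_params` object (named list).
#' @export
jr_params <- function(A = 3.25, B = 22, a = 100, b = 50,
                      C1 = 135, C2 = 0.8 * 135, C3 = 0.25 * 135,
                      C4 = 0.25 * 135,
                      vmax = 2.5, v0 = 6, r = 0.56, qcon = 220) {
  p <- list(A = A, B = B, a = a, b = b, C1 = C1, C2 = C2, C3 = C3,
            C4 = C4, vmax = vmax, v0 = v0, r = r, qcon = qcon)
  for (nm in c("A", "B", "a", "b", "vmax", "r"))
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("jr_params: ", nm, " must be strictly positive", call. = FALSE)
  for (nm in c("C1", "C2", "C3", "C4"))
    if (p[[nm]] < 0)
      stop("jr_params: ", nm, " must be non-negative", call. = FALSE)
  structure(p, class = "jr_params")
}

#' Long-range coupling sigmoid parameters
#'
#' The summed delayed PSP input from other regions is transformed by a
#' sigmoid before entering the EIN equation. `gmin`/`gmax` are the lower
#' and upper saturation values (1/s), `gmid` the midpoint (mV), `gsigma`
#' a steepness factor multiplying the exponential and `ga` the scaling
#' factor inside the exponent.
#'
#' @param gmin,gmax Saturation firing-rate contributions (1/s).
#' @param gmid Midpoint (mV).
#' @param gsigma Steepness multiplier (dimensionless).
#' @param ga Exponent scaling factor (1/mV).
#' @return A `coupling_params` object.
#' @export
coupling_params <- function(gmin = 0, gmax = 5, gmid = 6,
                            gsigma = 1, ga = 0.56) {
  if (gmax <= gmin) stop("coupling_params: gmax must exceed gmin",
                         call. = FALSE)
  if (gsigma <= 0) stop("coupling_params: gsigma must be positive",
                        call. = FALSE)
  structure(list(gmin = gmin, gmax = gmax, gmid = gmid,
                 gsigma = gsigma, ga = ga),
            class = "coupling_params")
}

#' Virtual TMS stimulus
#'
#' Per-region stimulus amplitudes in model-input units (1/s), typically
#' a gain times the regional electric-field magnitude. Exactly the
#' stimulated regions carry nonzero amplitude. Onset is expressed
#' relative to the stimulus time origin of the simulation (t = 0).
#'
#' @param region_amplitudes Numeric vector, one non-negative amplitude
#'   per region.
#' @param onset Onset in s relative to the epoch time origin (default 0).
#' @param duration Pulse duration in s (default 1 ms).
#' @param waveform `"rect"` (rectangular pulse) or `"biexponential"`
#'   (fast-rise, slow-decay pulse of comparable integral).
#' @return A `stimulus_spec` object.
#' @export
stimulus_spec <- function(region_amplitudes, onset = 0, duration = 1e-3,
                          waveform = c("rect", "biexponential")) {
  waveform <- match.arg(waveform)
  if (any(region_amplitudes < 0))
    stop("stimulus amplitudes must be non-negative", call. = FALSE)
  if (duration <= 0) stop("stimulus duration must be positive",
                          call. = FALSE)
  structure(list(region_amplitudes = as.numeric(region_amplitudes),
                 onset = onset, duration = duration, waveform = waveform),
            class = "stimulus_spec")
}

#' Additive noise specification
#'
#' White noise added to the EIN input (alongside coupling, constant
#' drive and stimulus). The noise process is generated per integration
#' step as independent N(0, std) draws, held constant over the step.
#'
#' @param std Standard deviation (1/s).
#' @param seed Optional integer seed; when `NULL` the simulation seed in
#'   [sim_config()] governs the draw.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(std = 22, seed = NULL) {
  if (std < 0) stop("noise std must be non-negative", call. = FALSE)
  structure(list(std = std, seed = seed), class = "noise_spec")
}

#' Simulation configuration
#'
#' @param dt Integration step (ms); the stochastic Heun scheme requires
#'   `max(a, b) * dt` small (a warning is issued above 0.01).
#' @param duration Total simulated time (s), including the transient;
#'   the default leaves a -0.1 to 0.4 s stimulus-locked epoch.
#' @param transient Initial segment (s) discarded before the epoch; the
#'   stimulus time origin lies at `transient + pre_stimulus`.
#' @param pre_stimulus Pre-stimulus baseline retained in the output (s).
#' @param sampling_rate Output sampling rate (Hz).
#' @param seed Integer seed for the noise process.
#' @param initial_state `"zeros"` (all state variables at 0) is the only
#'   implemented mode; the transient removes initial-condition
#'   artefacts.
#' @return A `sim_config` object.
#' @export
sim_config <- function(dt = 0.1, duration = 1.5, transient = 1,
                       pre_stimulus = 0.1, sampling_rate = 1000,
                       seed = 42L, initial_state = "zeros") {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration <= transient)
    stop("duration must exceed the transient", call. = FALSE)
  if (1000 / sampling_rate < dt - 1e-12)
    stop("sampling interval must be >= dt", call. = FALSE)
  if (pre_stimulus < 0 || transient + pre_stimulus >= duration)
    stop("pre_stimulus must fit between transient and duration",
         call. = FALSE)
  initial_state <- match.arg(initial_state, "zeros")
  structure(list(dt = dt, duration = duration, transient = transient,
                 pre_stimulus = pre_stimulus,
                 sampling_rate = sampling_rate, seed = as.integer(seed),
                 initial_state = initial_state),
            class = "sim_config")
}

#' Postsynaptic-potential impulse response
#'
#' The rate-to-potential kernel `H * (t/tau) * exp(-t/tau)` for t >= 0
#' and 0 for t < 0; maximal at `t = tau` with value `H/e`.
#'
#' @param t Time (s), vectorised.
#' @param H Maximum PSP (mV).
#' @param tau Synaptic time constant (s), reciprocal of the decay rate.
#' @return PSP values (mV).
#' @export
psp_kernel <- function(t, H, tau) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  ifelse(t >= 0, H * (t / tau) * exp(-t / tau), 0)
}

#' Potential-to-rate sigmoid
#'
#' Population firing rate `2 * vmax / (1 + exp(r * (v0 - v)))`: strictly
#' increasing in the mean PSP `v`, equal to `vmax` at `v = v0`, bounded
#' in (0, 2 * vmax).
#'
#' @param v Mean PSP (mV), vectorised.
#' @param vmax Half-maximum firing rate (1/s).
#' @param v0 Firing threshold (mV).
#' @param r Steepness (1/mV).
#' @return Firing rate (1/s).
#' @export
sigmoid_rate <- function(v, vmax = 2.5, v0 = 6, r = 0.56) {
  2 * vmax / (1 + exp(r * (v0 - v)))
}

#' Long-range coupling sigmoid
#'
#' Transforms the summed delayed PSP input `x` (mV) from other regions
#' into a firing-rate contribution:
#' `gmin + (gmax - gmin) / (1 + exp(-ga * (x - gmid)) * gsigma)`.
#'
#' @param x Summed delayed input (mV), vectorised.
#' @param cp A [coupling_params()] object.
#' @return Firing-rate contribution (1/s).
#' @export
coupling_sigmoid <- function(x, cp = coupling_params()) {
  cp$gmin + (cp$gmax - cp$gmin) /
    (1 + exp(-cp$ga * (x - cp$gmid)) * cp$gsigma)
}

#' Delayed network input to one region
#'
#' Reference implementation of the summed long-range input
#' `x_k(t) = sum_l M_kl * (y1_l(t - d_kl) - y2_l(t - d_kl))`, reading
#' PSP differences from a history matrix. The production integrator
#' computes the same quantity in compiled code; this function exists for
#' direct inspection and testing.
#'
#' @param psp_history Regions x time matrix of `y1 - y2` values, column
#'   `t` holding time step `t` (1-based).
#' @param conn A `connectome`.
#' @param delays A `delay_table` from [compute_delays()].
#' @param k Receiving region index.
#' @param t Current time step (1-based column into `psp_history`).
#' @return Summed delayed input (mV).
#' @export
delayed_input <- function(psp_history, conn, delays, k, t) {
  d <- delays$delays_steps[k, ]
  idx <- t - d
  if (any(idx < 1))
    stop("insufficient history: need ", max(d), " steps before t = ", t,
         call. = FALSE)
  psp <- psp_history[cbind(seq_len(conn$n_regions), idx)]
  sum(conn$weights[k, ] * psp)
}

#' Jansen-Rit right-hand side (reference implementation)
#'
#' Time derivatives of the six state variables of one or more Jansen-Rit
#' regions. `y0`, `y1`, `y2` are the mean PSPs of PC, EIN and IIN (mV);
#' `y3`-`y5` their derivatives. External inputs (coupling `qcou`,
#' constant drive `qcon`, stimulus, noise) enter only the EIN equation;
#' `b` and `C4` appear only in the IIN equation. The compiled integrator
#' implements the same equations; this R version serves as the oracle in
#' tests.
#'
#' @param state Named list of numeric vectors `y0`..`y5` (one entry per
#'   region).
#' @param qcou Transformed coupling input per region (1/s).
#' @param stimulus_now Stimulus input per region (1/s).
#' @param noise_now Noise input per region (1/s).
#' @param p A [jr_params()] object.
#' @return Named list of derivatives `dy0`..`dy5`.
#' @export
jr_rhs <- function(state, qcou = 0, stimulus_now = 0, noise_now = 0,
                   p = jr_params()) {
  S <- function(v) sigmoid_rate(v, p$vmax, p$v0, p$r)
  with(state, list(
    dy0 = y3,
    dy1 = y4,
    dy2 = y5,
    dy3 = p$A * p$a * S(y1 - y2) - 2 * p$a * y3 - p$a^2 * y0,
    dy4 = p$A * p$a * (p$C2 * S(p$C1 * y0) + qcou + p$qcon +
                         stimulus_now + noise_now) -
      2 * p$a * y4 - p$a^2 * y1,
    dy5 = p$B * p$b * p$C4 * S(p$C3 * y0) - 2 * p$b * y5 - p$b^2 * y2))
}

#' Scale one inhibitory parameter by a percentage
#'
#' Returns a copy of the parameter set with the named parameter scaled
#' by `(1 + percent/100)`; all other parameters are untouched, so a
#' sweep alters exactly one knob at a time.
#'
#' @param p A [jr_params()] object.
#' @param name One of `"b"`, `"C4"`, `"C3"`.
#' @param percent Percent change; a warning is issued outside
#'   \[-50, 50\], the range of the sweep design.
#' @return A modified `jr_params` object.
#' @export
#' @examples
#' alter_parameter(jr_params(), "b", -50)$b  # 25
alter_parameter <- function(p, name, percent) {
  if (!name %in% c("b", "C4", "C3"))
    stop("unknown parameter '", name,
         "'; alterable parameters are b, C4, C3", call. = FALSE)
  if (percent < -50 || percent > 50)
    warning("percent ", percent, " lies outside the designed [-50, 50] ",
            "alteration range")
  p[[name]] <- p[[name]] * (1 + percent / 100)
  class(p) <- "jr_params"
  p
}

#' Simulate the delay-coupled Jansen-Rit network
#'
#' Integrates one Jansen-Rit model per region, coupled through the
#' connectome with conduction delays, using a stochastic Heun scheme
#' with a ring-buffer delay history. A virtual TMS pulse perturbs the
#' EIN input of the stimulated regions at the stimulus time origin.
#' After discarding the transient, the per-region PSP (`y1 - y2`) is
#' decimated to the output sampling rate; the returned time axis has 0
#' at stimulus onset.
#'
#' @param conn A `connectome`.
#' @param params A [jr_params()] object.
#' @param coupling A [coupling_params()] object.
#' @param stimulus A [stimulus_spec()] with one amplitude per region, or
#'   `NULL` for an unperturbed run.
#' @param noise A [noise_spec()].
#' @param config A [sim_config()].
#' @param speed Conduction speed (m/s) used for the delay table.
#' @return A `source_activity` object: list with `time` (s, 0 at
#'   stimulus onset), `psp` (regions x time, mV) and `labels`.
#' @export
simulate_network <- function(conn, params = jr_params(),
                             coupling = coupling_params(),
                             stimulus = NULL,
                             noise = noise_spec(),
                             config = sim_config(),
                             speed = 2.5) {
  validate_connectome(conn)
  n <- conn$n_regions
  if (is.null(stimulus)) stimulus <- stimulus_spec(rep(0, n))
  if (length(stimulus$region_amplitudes) != n)
    stop("stimulus has ", length(stimulus$region_amplitudes),
         " amplitudes for ", n, " regions", call. = FALSE)
  if (max(params$a, params$b) * config$dt / 1000 > 0.01)
    warning("dt = ", config$dt, " ms is coarse for decay rates a = ",
            params$a, ", b = ", params$b,
            "; integration may be inaccurate")

  dt_s <- config$dt / 1000
  n_steps <- round(config$duration / dt_s)
  transient_steps <- round(config$transient / dt_s)
  onset_step <- transient_steps +
    round((config$pre_stimulus + stimulus$onset) / dt_s)
  dur_steps <- max(1L, round(stimulus$duration / dt_s))
  decim <- max(1L, round(1000 / config$sampling_rate / config$dt))

  w <- conn$weights
  diag(w) <- 0  # no self-coupling through the long-range term
  delays <- compute_delays(conn, speed = speed, dt = config$dt)

  seed <- if (!is.null(noise$seed)) noise$seed else config$seed
  set.seed(as.integer(seed))
  res <- jr_integrate_cpp(
    w, delays$delays_steps,
    unlist(params[c("A", "B", "a", "b", "C1", "C2", "C3", "C4",
                    "vmax", "v0", "r", "qcon")]),
    unlist(coupling),
    stimulus$region_amplitudes,
    as.integer(onset_step), as.integer(dur_steps),
    match(stimulus$waveform, c("rect", "biexponential")),
    noise$std, dt_s, as.integer(n_steps), as.integer(transient_steps),
    as.integer(decim), 1e6)
  if (!res$ok)
    stop("simulation diverged (|state| > 1e6 mV) at step ", res$fail_step,
         " with b = ", params$b, ", C4 = ", params$C4,
         "; reduce coupling or stimulus strength", call. = FALSE)

  rec_start <- transient_steps  # first recorded step
  time <- (rec_start + (seq_len(ncol(res$psp)) - 1L) * decim -
             (transient_steps + round(config$pre_stimulus / dt_s))) * dt_s
  structure(list(time = time, psp = res$psp, labels = conn$labels,
                 final_state = res$final_state),
            class = "source_activity")
}

#' @export
print.source_activity <- function(x, ...) {
  cat("source_activity:", nrow(x$psp), "regions x", ncol(x$psp),
      "samples,", sprintf("t in [%.3f, %.3f] s\n", min(x$time),
                          max(x$time)))
  invisible(x)
}
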