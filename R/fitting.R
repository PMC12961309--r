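#' Pearson correlation between two EEG epochs
#'
#' Correlation over all channel x time samples, flattened. Used to
#' score how well a simulated TEP reproduces a target TEP.
#'
#' @param sim,target [eeg_timeseries()] objects of identical shape and
#'   time axis.
#' @return Correlation in \[-1, 1\].
#' @export
pcc <- function(sim, target) {
  if (!identical(dim(sim$data), dim(target$data)))
    stop("sim and target epochs differ in shape", call. = FALSE)
  if (max(abs(sim$time - target$time)) > 1e-9)
    stop("sim and target epochs differ in time axis", call. = FALSE)
  a <- as.vector(sim$data)
  b <- as.vector(target$data)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined: zero variance input", call. = FALSE)
  stats::cor(a, b)
}

#' Configuration for structural-connectivity fitting
#'
#' @param loss `"mse"`, `"neg_pcc"` or `"mse_plus_prior"` (MSE plus
#'   `prior_weight * ||M - M0||^2`, regularising toward the initial
#'   matrix).
#' @param learning_rate Initial SPSA/gradient step size.
#' @param iterations Number of gradient iterations.
#' @param reps Number of independent repetitions.
#' @param seeds Optional integer vector of per-repetition seeds
#'   (length `reps`); derived from `master_seed` when `NULL`.
#' @param gradient `"spsa"` (simultaneous perturbation, two simulations
#'   per iteration) or `"finite_difference"` (one simulation per free
#'   weight — only sensible for very small networks).
#' @param prior_weight Weight of the prior term.
#' @param clip_nonnegative Clip weights at zero after each update.
#' @param epoch_window Fitting window `c(start, end)` in s
#'   post-stimulus.
#' @param perturbation SPSA perturbation magnitude (fraction of the
#'   current weight scale).
#' @return A `fit_config` object.
#' @export
fit_config <- function(loss = c("mse_plus_prior", "mse", "neg_pcc"),
                       learning_rate = 0.1, iterations = 50, reps = 3,
                       seeds = NULL,
                       gradient = c("spsa", "finite_difference"),
                       prior_weight = 0.01, clip_nonnegative = TRUE,
                       epoch_window = c(0, 0.3), perturbation = 0.05) {
  loss <- match.arg(loss)
  gradient <- match.arg(gradient)
  if (learning_rate <= 0) stop("learning_rate must be positive",
                               call. = FALSE)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (!is.null(seeds) && length(seeds) != reps)
    stop("seeds must have one entry per repetition", call. = FALSE)
  structure(list(loss = loss, learning_rate = learning_rate,
                 iterations = iterations, reps = reps, seeds = seeds,
                 gradient = gradient, prior_weight = prior_weight,
                 clip_nonnegative = clip_nonnegative,
                 epoch_window = epoch_window,
                 perturbation = perturbation),
            class = "fit_config")
}

# maximum per-entry step at iteration `it`, annealed
learning_rate_step <- function(lr, it, scale0) {
  lr * 0.2 * scale0 * (11 / (it + 10))^0.602
}

sc_loss <- function(sim_epoch, target_epoch, w, w0, fitcfg) {
  mse <- mean((sim_epoch$data - target_epoch$data)^2)
  switch(fitcfg$loss,
         mse = mse,
         neg_pcc = -pcc(sim_epoch, target_epoch),
         mse_plus_prior = mse + fitcfg$prior_weight * sum((w - w0)^2))
}

#' Optimize structural connectivity against a target TEP
#'
#' Gradient descent on the connectome weights so that the simulated,
#' lead-field-projected TEP matches the target epoch. Gradients are
#' estimated stochastically (SPSA by default): each iteration perturbs
#' all free (off-diagonal, symmetric) weights simultaneously with a
#' Rademacher direction, evaluates the loss at both perturbed points
#' with a frozen noise seed, and steps along the estimated descent
#' direction with standard decaying SPSA gains. Weights are clipped at
#' zero when requested. The returned weights are the best-loss iterate;
#' the final PCC is computed on a noise-free evaluation.
#'
#' @param conn0 Initial `connectome` (the common template M0).
#' @param target Target epoch ([eeg_timeseries()]).
#' @param lf [lead_field()].
#' @param params,coupling,stimulus,config Simulation settings.
#' @param noise [noise_spec()] used during fitting; its seed is
#'   overridden per repetition.
#' @param fitcfg A [fit_config()].
#' @param seed Seed for this run (perturbation directions + noise).
#' @return A `fit_result`: list with `weights`, `loss_trace`, `pcc`,
#'   `initial_pcc`, `seed`.
#' @export
optimize_sc <- function(conn0, target, lf, params = jr_params(),
                        coupling = coupling_params(), stimulus,
                        noise = noise_spec(), config = sim_config(),
                        fitcfg = fit_config(), seed = 1L) {
  validate_connectome(conn0)
  n <- conn0$n_regions
  w0 <- conn0$weights
  diag(w0) <- 0
  free <- upper.tri(w0)  # symmetric: optimize upper triangle, mirror

  eval_loss <- function(w, noise_seed, noise_std = noise$std) {
    conn <- conn0
    conn$weights <- w
    src <- simulate_network(conn, params, coupling, stimulus,
                            noise_spec(std = noise_std,
                                       seed = noise_seed), config)
    eeg <- project(src, lf, reference = "average")
    epoch <- extract_epoch(eeg, fitcfg$epoch_window)
    list(loss = sc_loss(epoch, target_epoch, w, w0, fitcfg),
         epoch = epoch)
  }

  target_epoch <- extract_epoch(target, fitcfg$epoch_window)
  scale0 <- max(w0[free], 1e-12)

  set.seed(as.integer(seed))
  # independent sub-seeds: noise frozen within an iteration so both
  # SPSA probes see the same realisation
  iter_seeds <- sample.int(.Machine$integer.max, fitcfg$iterations)

  w <- w0
  best_w <- w0
  init <- eval_loss(w0, iter_seeds[1L])
  best_loss <- init$loss
  loss_trace <- numeric(fitcfg$iterations)
  a_gain <- fitcfg$learning_rate
  c_gain <- fitcfg$perturbation * scale0

  for (it in seq_len(fitcfg$iterations)) {
    ak <- a_gain / (it + 10)^0.602
    ck <- c_gain / it^0.101
    if (fitcfg$gradient == "spsa") {
      delta <- matrix(0, n, n)
      delta[free] <- sample(c(-1, 1), sum(free), replace = TRUE)
      delta <- delta + t(delta)
      wp <- w + ck * delta
      wm <- w - ck * delta
      if (fitcfg$clip_nonnegative) {
        wp[wp < 0] <- 0
        wm[wm < 0] <- 0
      }
      lp <- eval_loss(wp, iter_seeds[it])$loss
      lm_ <- eval_loss(wm, iter_seeds[it])$loss
      if (!is.finite(lp) || !is.finite(lm_))
        stop("loss not finite during SC optimization", call. = FALSE)
      ghat <- matrix(0, n, n)
      ghat[delta != 0] <- (lp - lm_) / (2 * ck * delta[delta != 0])
      # elementwise step clip: SPSA gradient magnitudes depend on the
      # loss scale, which is not known a priori; cap the step at a
      # fraction of the weight scale so updates stay in-range
      step <- ak * ghat
      cap <- 0.1 * scale0
      step[step > cap] <- cap
      step[step < -cap] <- -cap
      w <- w - step
      cur <- min(lp, lm_)
    } else {
      base <- eval_loss(w, iter_seeds[it])$loss
      ghat <- matrix(0, n, n)
      idx <- which(free, arr.ind = TRUE)
      for (j in seq_len(nrow(idx))) {
        wj <- w
        wj[idx[j, 1], idx[j, 2]] <- wj[idx[j, 1], idx[j, 2]] + ck
        wj[idx[j, 2], idx[j, 1]] <- wj[idx[j, 1], idx[j, 2]]
        g <- (eval_loss(wj, iter_seeds[it])$loss - base) / ck
        ghat[idx[j, 1], idx[j, 2]] <- g
        ghat[idx[j, 2], idx[j, 1]] <- g
      }
      # normalised annealed step: the loss scale is problem-dependent,
      # so scale the largest gradient component to a fraction of the
      # weight scale and anneal with the usual 0.602 exponent
      gmaxabs <- max(abs(ghat))
      if (gmaxabs > 0)
        w <- w - learning_rate_step(fitcfg$learning_rate, it, scale0) *
          ghat / gmaxabs
      cur <- base
    }
    if (fitcfg$clip_nonnegative) w[w < 0] <- 0
    ev <- eval_loss(w, iter_seeds[it])
    loss_trace[it] <- ev$loss
    if (ev$loss < best_loss) {
      best_loss <- ev$loss
      best_w <- w
    }
  }

  # contract check: the smoothed loss should be non-increasing
  if (fitcfg$iterations >= 10) {
    sm <- stats::filter(c(init$loss, loss_trace), rep(1 / 5, 5),
                        sides = 1)
    sm <- sm[!is.na(sm)]
    if (utils::tail(sm, 1) > utils::head(sm, 1) * (1 + 1e-6))
      warning("smoothed loss increased over the optimization run; ",
              "consider lowering the learning rate")
  }

  # noise-free final evaluation for the reported PCC
  final <- eval_loss(best_w, iter_seeds[1L], noise_std = 0)
  init_free <- eval_loss(w0, iter_seeds[1L], noise_std = 0)
  structure(list(weights = best_w, loss_trace = loss_trace,
                 initial_loss = init$loss, best_loss = best_loss,
                 pcc = pcc(final$epoch, target_epoch),
                 initial_pcc = pcc(init_free$epoch, target_epoch),
                 seed = as.integer(seed)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "fit_result: loss %.4g -> %.4g (%d iters), PCC %.3f -> %.3f\n",
    x$initial_loss, x$best_loss, length(x$loss_trace), x$initial_pcc,
    x$pcc))
  invisible(x)
}

#' Run independent SC-fitting repetitions
#'
#' Calls [optimize_sc()] `reps` times with distinct, reproducible
#' seeds; results are returned in seed order.
#'
#' @inheritParams optimize_sc
#' @param master_seed Seed from which per-repetition seeds are derived
#'   when `fitcfg$seeds` is `NULL`.
#' @return List of `fit_result` objects, one per repetition.
#' @export
run_repetitions <- function(conn0, target, lf, params = jr_params(),
                            coupling = coupling_params(), stimulus,
                            noise = noise_spec(),
                            config = sim_config(),
                            fitcfg = fit_config(), master_seed = 1L) {
  seeds <- fitcfg$seeds
  if (is.null(seeds))
    seeds <- vapply(seq_len(fitcfg$reps), function(i)
      derive_seed(master_seed, paste0("fit_rep_", i)), integer(1))
  lapply(seeds, function(s)
    optimize_sc(conn0, target, lf, params, coupling, stimulus, noise,
                config, fitcfg, seed = s))
}
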