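#' Global mean field power
#'
#' At each time point, the standard deviation of the voltage across
#' channels (population formula, divisor K):
#' `sqrt(mean((V_k - mean(V))^2))`.
#'
#' @param epoch An [eeg_timeseries()] with at least two channels.
#' @return Numeric vector of GMFP values (uV), one per time point.
#' @export
gmfp <- function(epoch) {
  if (nrow(epoch$data) < 2)
    stop("GMFP requires >= 2 channels", call. = FALSE)
  v <- epoch$data
  m <- colMeans(v)
  sqrt(colMeans(sweep(v, 2L, m)^2))
}

#' Global mean field amplitude
#'
#' Area under the GMFP curve over a window (ms post-stimulus),
#' integrated with the trapezoidal rule. This is the scalar used to
#' quantify TEP amplitude.
#'
#' @param epoch An [eeg_timeseries()].
#' @param window `c(start, end)` in ms post-stimulus; default 15-300 ms
#'   (the first 15 ms are excluded, mirroring the empirical exclusion of
#'   the early stimulation artifact).
#' @return GMFA in uV*s (non-negative).
#' @export
gmfa <- function(epoch, window = c(15, 300)) {
  g <- gmfp(epoch)
  t_ms <- epoch$time * 1000
  sel <- t_ms >= window[1] - 1e-9 & t_ms <= window[2] + 1e-9
  if (sum(sel) < 2)
    stop("GMFA window [", window[1], ", ", window[2],
         "] ms contains fewer than 2 samples", call. = FALSE)
  tt <- epoch$time[sel]
  gg <- g[sel]
  sum(diff(tt) * (utils::head(gg, -1) + utils::tail(gg, -1)) / 2)
}

#' Relative GMFA
#'
#' Expresses a GMFA value as a percentage of the GMFA obtained with
#' default parameters for the same repetition:
#' `100 * value / default_value`.
#'
#' @param value GMFA at the altered parameter value (uV*s).
#' @param default_value GMFA at the default parameter value (uV*s),
#'   must be positive.
#' @return Percentage (100 at the default).
#' @export
relative_gmfa <- function(value, default_value) {
  if (any(default_value <= 0))
    stop("default GMFA must be positive for normalization",
         call. = FALSE)
  100 * value / default_value
}

#' Default TEP peak windows
#'
#' Integration windows (ms post-stimulus) for the four canonical TEP
#' deflections. The window edges are configuration, not physiology:
#' adjacent windows abut and jointly cover 30-250 ms.
#'
#' @param N45,P60,N100,P185 `c(start, end)` in ms.
#' @return Named list of windows.
#' @export
peak_windows <- function(N45 = c(30, 57), P60 = c(58, 80),
                         N100 = c(81, 144), P185 = c(145, 250)) {
  w <- list(N45 = N45, P60 = P60, N100 = N100, P185 = P185)
  starts <- vapply(w, `[`, numeric(1), 1L)
  ends <- vapply(w, `[`, numeric(1), 2L)
  if (any(diff(starts) <= 0) || any(ends <= starts) ||
      any(utils::head(ends, -1) >= utils::tail(starts, -1)))
    stop("peak windows must be disjoint and increasing", call. = FALSE)
  w
}

#' Build a parameter sweep grid
#'
#' Symmetric percentage grid around a default value:
#' `default * (1 + k * step / 100)` for
#' `k = -span/step, ..., +span/step`. With the design defaults (span 50,
#' step 2) this yields 51 values including the default.
#'
#' @param default Default parameter value.
#' @param span_percent Half-range in percent (default 50).
#' @param step_percent Step in percent (default 2); must divide the
#'   span.
#' @return Data frame with columns `percent` and `value`.
#' @export
#' @examples
#' g <- make_sweep_grid(50)
#' range(g$value)  # 25 75
make_sweep_grid <- function(default, span_percent = 50,
                            step_percent = 2) {
  if (step_percent <= 0)
    stop("step_percent must be positive", call. = FALSE)
  k <- span_percent / step_percent
  if (abs(k - round(k)) > 1e-9)
    stop("span_percent must be divisible by step_percent",
         call. = FALSE)
  k <- round(k)
  percent <- seq(-k, k) * step_percent
  data.frame(percent = percent, value = default * (1 + percent / 100))
}

#' Plan a multi-parameter sweep
#'
#' Enumerates the distinct simulations required to sweep several
#' parameters one at a time: altered values for each parameter plus a
#' single shared default simulation. For the design grid (span 50, step
#' 2) over `b` and `C4` this is 50 + 50 + 1 = 101 simulations per
#' weight set.
#'
#' @param parameters Character vector of parameter names.
#' @param defaults Named numeric vector/list of default values; by
#'   default taken from [jr_params()].
#' @param span_percent,step_percent Grid geometry, see
#'   [make_sweep_grid()].
#' @return Data frame with columns `parameter`, `percent`, `value`; the
#'   shared default row has `parameter = "default"`, `percent = 0`.
#' @export
plan_sweep <- function(parameters = c("b", "C4"),
                       defaults = jr_params(),
                       span_percent = 50, step_percent = 2) {
  rows <- lapply(parameters, function(par) {
    g <- make_sweep_grid(defaults[[par]], span_percent, step_percent)
    g <- g[g$percent != 0, , drop = FALSE]
    data.frame(parameter = par, percent = g$percent, value = g$value)
  })
  out <- rbind(data.frame(parameter = "default", percent = 0,
                          value = NA_real_),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Plan the repetition structure of the scaled-up experiment
#'
#' Manifest of independent structural-connectivity optimizations:
#' one row per (subject, repetition) with a derived seed. The
#' full-scale design (20 subjects x 100 repetitions) yields 2,000
#' optimized parameter sets.
#'
#' @param n_subjects Number of subjects.
#' @param n_reps Repetitions per subject.
#' @param master_seed Seed from which per-run seeds are derived.
#' @return Data frame with columns `subject`, `rep`, `seed`.
#' @export
plan_repetitions <- function(n_subjects = 20, n_reps = 100,
                             master_seed = 1L) {
  df <- expand.grid(rep = seq_len(n_reps), subject = seq_len(n_subjects),
                    KEEP.OUT.ATTRS = FALSE)[, c("subject", "rep")]
  df$seed <- vapply(seq_len(nrow(df)), function(i)
    derive_seed(master_seed, paste0("fit_s", df$subject[i],
                                    "_r", df$rep[i])),
    integer(1))
  rownames(df) <- NULL
  df
}

#' Sweep an inhibitory parameter and quantify TEP amplitude
#'
#' For every grid value of the chosen parameter and every repetition
#' (weight set x noise seed), simulates the TMS-perturbed network with
#' [alter_parameter()] applied, projects to EEG, and computes the
#' overall and per-peak GMFA. Each repetition's values are normalised
#' to the same repetition's default-parameter run (relative GMFA, %).
#' Means are taken per value over repetitions within subject, then over
#' subjects.
#'
#' In `"joint"` mode `b` and `C4` are altered simultaneously over the
#' full percent x percent grid.
#'
#' @param parameter `"b"`, `"C4"`, `"C3"` or `"joint"`.
#' @param weight_sets List of `connectome` objects (the per-subject
#'   optimized weight sets); a single `connectome` is promoted to a
#'   one-element list.
#' @param lf A [lead_field()].
#' @param params,coupling,stimulus,config Model, coupling, stimulus and
#'   integration settings shared across the sweep.
#' @param noise_std Noise standard deviation (1/s).
#' @param n_reps Noise repetitions per weight set.
#' @param seed Master seed; per-run noise seeds are derived from it.
#' @param windows Peak windows, see [peak_windows()].
#' @param gmfa_window Overall GMFA window (ms).
#' @param span_percent,step_percent Grid geometry.
#' @param progress Print one line per simulation.
#' @return A `sweep_result`: list with `parameter`, `grid`, `records`
#'   (long data frame: parameter, percent, value, subject, rep, window,
#'   gmfa_abs, gmfa_rel) and `mean_rel` (per grid value, overall
#'   window).
#' @export
run_sweep <- function(parameter, weight_sets, lf,
                      params = jr_params(),
                      coupling = coupling_params(),
                      stimulus, config = sim_config(),
                      noise_std = noise_spec()$std,
                      n_reps = 1, seed = 1L,
                      windows = peak_windows(),
                      gmfa_window = c(15, 300),
                      span_percent = 50, step_percent = 2,
                      progress = FALSE) {
  stopifnot(parameter %in% c("b", "C4", "C3", "joint"))
  if (inherits(weight_sets, "connectome"))
    weight_sets <- list(weight_sets)
  if (length(weight_sets) == 0)
    stop("weight_sets must be non-empty", call. = FALSE)

  if (parameter == "joint") {
    gb <- make_sweep_grid(params$b, span_percent, step_percent)
    gc <- make_sweep_grid(params$C4, span_percent, step_percent)
    grid <- expand.grid(percent_b = gb$percent, percent_C4 = gc$percent,
                        KEEP.OUT.ATTRS = FALSE)
    grid$value_b <- params$b * (1 + grid$percent_b / 100)
    grid$value_C4 <- params$C4 * (1 + grid$percent_C4 / 100)
  } else {
    grid <- make_sweep_grid(params[[parameter]], span_percent,
                            step_percent)
  }

  all_windows <- c(list(overall = gmfa_window), windows)
  records <- list()
  for (s in seq_along(weight_sets)) {
    conn <- weight_sets[[s]]
    for (rep_i in seq_len(n_reps)) {
      rep_seed <- derive_seed(seed, paste0("sweep_", parameter,
                                           "_s", s, "_r", rep_i))
      run_one <- function(p_alt) {
        src <- simulate_network(conn, p_alt, coupling, stimulus,
                                noise_spec(std = noise_std,
                                           seed = rep_seed),
                                config)
        epoch <- project(src, lf, reference = "average")
        vapply(all_windows, function(w) gmfa(epoch, w), numeric(1))
      }
      abs_mat <- matrix(NA_real_, nrow = nrow(grid),
                        ncol = length(all_windows),
                        dimnames = list(NULL, names(all_windows)))
      for (i in seq_len(nrow(grid))) {
        p_alt <- if (parameter == "joint") {
          alter_parameter(alter_parameter(params, "b",
                                          grid$percent_b[i]),
                          "C4", grid$percent_C4[i])
        } else {
          alter_parameter(params, parameter, grid$percent[i])
        }
        val <- tryCatch(run_one(p_alt), error = function(e) {
          warning("simulation failed at grid row ", i, " (",
                  conditionMessage(e), "); recorded as missing")
          rep(NA_real_, length(all_windows))
        })
        abs_mat[i, ] <- val
        if (progress)
          message(sprintf("sweep %s subj %d rep %d value %d/%d",
                          parameter, s, rep_i, i, nrow(grid)))
      }
      default_row <- if (parameter == "joint") {
        which(grid$percent_b == 0 & grid$percent_C4 == 0)
      } else {
        which(grid$percent == 0)
      }
      rel_mat <- relative_gmfa(abs_mat,
                               matrix(abs_mat[default_row, ],
                                      nrow = nrow(abs_mat),
                                      ncol = ncol(abs_mat),
                                      byrow = TRUE))
      for (w in names(all_windows)) {
        rec <- data.frame(parameter = parameter, subject = s,
                          rep = rep_i, window = w,
                          gmfa_abs = abs_mat[, w],
                          gmfa_rel = rel_mat[, w])
        records[[length(records) + 1L]] <- cbind(grid, rec)
      }
    }
  }
  records <- do.call(rbind, records)
  rownames(records) <- NULL

  overall <- records[records$window == "overall", , drop = FALSE]
  if (parameter == "joint") {
    key <- interaction(overall$percent_b, overall$percent_C4,
                       drop = TRUE)
    subj_mean <- stats::aggregate(
      gmfa_rel ~ percent_b + percent_C4 + subject, data = overall,
      FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
    mean_rel <- stats::aggregate(
      gmfa_rel ~ percent_b + percent_C4, data = subj_mean, FUN = mean,
      na.rm = TRUE, na.action = stats::na.pass)
  } else {
    subj_mean <- stats::aggregate(
      gmfa_rel ~ percent + value + subject, data = overall, FUN = mean,
      na.rm = TRUE, na.action = stats::na.pass)
    mean_rel <- stats::aggregate(
      gmfa_rel ~ percent + value, data = subj_mean, FUN = mean,
      na.rm = TRUE, na.action = stats::na.pass)
    mean_rel <- mean_rel[order(mean_rel$percent), ]
    rownames(mean_rel) <- NULL
  }
  structure(list(parameter = parameter, grid = grid, records = records,
                 mean_rel = mean_rel),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", x$parameter, "-", nrow(x$grid), "grid values,",
      length(unique(paste(x$records$subject, x$records$rep))),
      "repetitions\n")
  invisible(x)
}

#' Write sweep records to CSV / summary to JSON
#'
#' @param sweep A `sweep_result`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @param fits Optional result of [fit_models()] to embed in the JSON
#'   summary.
#' @return `sweep`, invisibly.
#' @export
write_sweep <- function(sweep, csv_path = NULL, json_path = NULL,
                        fits = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(sweep$records, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    out <- list(parameter = sweep$parameter, mean_rel = sweep$mean_rel)
    if (!is.null(fits)) out$regression <- regression_table(fits)
    jsonlite::write_json(out, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }
  invisible(sweep)
}
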