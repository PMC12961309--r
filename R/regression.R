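#' Fit and compare linear, quadratic and exponential response models
#'
#' Characterises the relation between a swept parameter value `x` and
#' the mean relative GMFA `y` by three candidate regressions:
#' * linear `y = b0 + b1 x`, ordinary least squares, slope significance
#'   by Wald test;
#' * quadratic `y = b0 + b1 x + b2 x^2`, ordinary least squares, overall
#'   F-test;
#' * exponential `y = c + alpha * exp(beta * x)`, nonlinear least
#'   squares (Levenberg-Marquardt), standard errors from the covariance
#'   matrix, p-value from the t-statistic of the rate `beta`.
#'
#' Each model reports its sum of squared errors (SSE) and goodness of
#' fit \eqn{r = \sqrt{1 - SSE/SST}} (the multiple correlation of the fitted
#' model). The model with minimum SSE is selected; SSE ties (relative
#' difference < 1e-9) are broken toward fewer parameters. Missing `y`
#' values (failed simulations) are dropped listwise.
#'
#' @param x Numeric predictor (parameter values).
#' @param y Numeric response (mean relative GMFA, %).
#' @return A `model_comparison`: list of `regression_fit` objects
#'   (`linear`, `quadratic`, `exponential`), each with fields `model`,
#'   `coefficients`, `sse`, `r`, `p`, `n_par`, `converged`, `selected`,
#'   plus `selected` naming the winner.
#' @export
fit_models <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 5)
    stop("model comparison requires >= 5 finite points", call. = FALSE)
  sst <- sum((y - mean(y))^2)
  gof <- function(sse) sqrt(max(0, 1 - sse / sst))

  fits <- list()

  lin <- stats::lm(y ~ x)
  sse_lin <- sum(stats::resid(lin)^2)
  p_lin <- suppressWarnings(
    stats::coef(summary(lin))["x", "Pr(>|t|)"])
  fits$linear <- list(model = "linear", coefficients = stats::coef(lin),
                      sse = sse_lin, r = gof(sse_lin), p = p_lin,
                      n_par = 2L, converged = TRUE, selected = FALSE)

  quad <- stats::lm(y ~ x + I(x^2))
  sse_quad <- sum(stats::resid(quad)^2)
  fs <- suppressWarnings(summary(quad))$fstatistic
  p_quad <- stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE)
  fits$quadratic <- list(model = "quadratic",
                         coefficients = stats::coef(quad),
                         sse = sse_quad, r = gof(sse_quad),
                         p = unname(p_quad), n_par = 3L,
                         converged = TRUE, selected = FALSE)

  expf <- fit_exponential(x, y)
  fits$exponential <- expf

  for (nm in names(fits)) class(fits[[nm]]) <- "regression_fit"
  candidates <- Filter(function(f) f$converged, fits)
  sses <- vapply(candidates, `[[`, numeric(1), "sse")
  npars <- vapply(candidates, `[[`, integer(1), "n_par")
  best_sse <- min(sses)
  # ties are judged on the scale of the data (SST), so that two
  # numerically perfect fits count as tied
  tied <- (sses - best_sse) <= 1e-9 * max(sst, .Machine$double.xmin)
  sel_pool <- names(candidates)[tied]
  sel <- sel_pool[order(npars[tied],
                        match(sel_pool,
                              c("linear", "quadratic", "exponential")))][1L]
  fits[[sel]]$selected <- TRUE
  structure(c(fits, list(selected = sel)), class = "model_comparison")
}

# Exponential model y = c + alpha * exp(beta * x), fitted by
# Levenberg-Marquardt NLS. Initialisation: log-linear regression of
# (y - min(y) + eps) on x gives a starting slope; both orientations
# (growth anchored at left or right end) are tried and the better
# converged fit kept.
fit_exponential <- function(x, y) {
  sst <- sum((y - mean(y))^2)
  eps <- max(1e-8, 1e-3 * diff(range(y)))
  starts <- list()
  ll <- stats::lm(log(y - min(y) + eps) ~ x)
  beta0 <- unname(stats::coef(ll)[2L])
  alpha0 <- exp(unname(stats::coef(ll)[1L]))
  starts[[1]] <- c(c = min(y), alpha = alpha0, beta = beta0)
  # mirrored orientation for decaying relations
  starts[[2]] <- c(c = min(y), alpha = max(y) - min(y), beta = -beta0)
  rng <- diff(range(x))
  starts[[3]] <- c(c = min(y), alpha = max(y) - min(y),
                   beta = -5 / rng)
  starts[[4]] <- c(c = min(y), alpha = max(y) - min(y), beta = 5 / rng)

  best <- NULL
  for (st in starts) {
    if (!all(is.finite(st))) next
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c + alpha * exp(beta * x),
                        start = as.list(st),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500),
                        lower = c(-Inf, -Inf, -700 / max(abs(x))),
                        upper = c(Inf, Inf, 700 / max(abs(x)))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit,
                                                     sse = sse)
  }
  if (is.null(best)) {
    return(list(model = "exponential", coefficients = NULL, sse = Inf,
                r = NA_real_, p = NA_real_, n_par = 3L,
                converged = FALSE, selected = FALSE))
  }
  co <- suppressWarnings(summary(best$fit))$coefficients
  p_beta <- co["beta", "Pr(>|t|)"]
  list(model = "exponential",
       coefficients = stats::coef(best$fit), sse = best$sse,
       r = sqrt(max(0, 1 - best$sse / sst)), p = unname(p_beta),
       n_par = 3L, converged = TRUE, selected = FALSE)
}

#' Tabulate a model comparison
#'
#' @param fits A `model_comparison` from [fit_models()].
#' @return Data frame with one row per model: model, coefficients
#'   (collapsed), SSE, r, p, selected.
#' @export
regression_table <- function(fits) {
  rows <- lapply(c("linear", "quadratic", "exponential"), function(nm) {
    f <- fits[[nm]]
    data.frame(
      model = nm,
      coefficients = if (is.null(f$coefficients)) NA_character_ else
        paste(sprintf("%.6g", f$coefficients), collapse = ", "),
      sse = f$sse, r = f$r, p = f$p, converged = f$converged,
      selected = f$selected)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  print(regression_table(x), digits = 4)
  cat("selected:", x$selected, "\n")
  invisible(x)
}
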