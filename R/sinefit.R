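## Bounded sum-of-sines model for daily-rhythm detection.
##
## y(t) = d + sum_k a_k * sin(b_k * t + c_k),  with period 2*pi/b_k
## constrained to a user-given interval per component (e.g. 23-25 h for the
## daily component, 10-12 h for a half-day harmonic). An offset d is always
## included: percent-of-maximum profiles are not zero-mean.
##
## For fixed periods the model is linear in (d, a_k sin c_k, a_k cos c_k),
## so the fit uses variable projection: the profiled sum of squares over
## the period vector is minimized by box-bounded quasi-Newton refinement
## from a deterministic multi-start grid, and the linear coefficients come
## from an exact least-squares solve at the optimum. This keeps the search
## space tiny (one dimension per component) and makes the fit deterministic.

sines_design <- function(t, periods) {
  X <- matrix(1, length(t), 1 + 2 * length(periods))
  for (k in seq_along(periods)) {
    w <- 2 * pi / periods[k]
    X[, 2 * k] <- sin(w * t)
    X[, 2 * k + 1] <- cos(w * t)
  }
  X
}

profiled_sse <- function(periods, t, y) {
  X <- sines_design(t, periods)
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Fit a bounded sum-of-sines rhythm model
#'
#' Fits `y(t) = d + sum_k a_k sin(b_k t + c_k)` by nonlinear least squares
#' with each component's period `2*pi/b_k` constrained to `period_bounds[[k]]`.
#' Amplitudes and phases are profiled out exactly (they enter linearly), and
#' the periods are optimized within their bounds from a deterministic grid
#' of starting values, so repeated fits of the same data are identical.
#'
#' @param time sampling times in hours (or a formula `value ~ time` with
#'   `data`).
#' @param value observed values (e.g. percent of within-day maximum).
#' @param period_bounds list of `c(low, high)` period intervals in hours,
#'   one per component; default a single daily component bounded to 23-25 h.
#'   Use `list(c(10, 12), c(23, 25))` for the aggregate-profile fit.
#' @param data optional data.frame when `time` is a formula.
#' @param n_starts number of starting periods per component spread evenly
#'   across each bound (default 5).
#' @return An object of class `sinefit` with components `coefficients`
#'   (offset, and per component amplitude / period / phase), `periods`,
#'   `amplitudes`, `phases`, `offset`, `fitted.values`, `residuals`, `sse`,
#'   `rmse`, `r.squared`, `adj.r.squared` (penalized for `p = 3K + 1`
#'   parameters), `sigma`, `n`, `p`, `degenerate` and the call. Supports
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `confint`, `plot` and `simulate`.
#' @examples
#' t <- 0:23
#' y <- 80 + 20 * sin(2 * pi * t / 24 + 1)
#' fit <- sinefit(t, y, period_bounds = list(c(23, 25)))
#' coef(fit)
#' @export
sinefit <- function(time, value = NULL, period_bounds = list(c(23, 25)),
                    data = NULL, n_starts = 5L) {
  cl <- match.call()
  if (inherits(time, "formula")) {
    mf <- stats::model.frame(time, data = data)
    value <- mf[[1L]]
    time <- mf[[2L]]
  }
  stopifnot(is.numeric(time), is.numeric(value),
            length(time) == length(value))
  ok <- is.finite(time) & is.finite(value)
  t <- time[ok]; y <- value[ok]
  K <- length(period_bounds)
  for (b in period_bounds)
    if (length(b) != 2L || b[1] <= 0 || b[2] < b[1])
      stop("each period bound must be c(low, high) with 0 < low <= high")
  p <- 3L * K + 1L
  n <- length(y)
  if (n <= p)
    stop(sprintf("need more than %d points to fit %d component(s); got %d",
                 p, K, n))

  sstot <- sum((y - mean(y))^2)
  lower <- vapply(period_bounds, `[`, numeric(1), 1L)
  upper <- vapply(period_bounds, `[`, numeric(1), 2L)

  if (sstot < 1e-10) {
    ## constant input: flat model, zero amplitudes, flagged degenerate
    periods <- (lower + upper) / 2
    fit <- structure(list(
      coefficients = sine_coef_vector(mean(y), numeric(K), periods,
                                      numeric(K)),
      offset = mean(y), amplitudes = numeric(K), phases = numeric(K),
      periods = periods, period_bounds = period_bounds,
      fitted.values = rep(mean(y), n), residuals = y - mean(y),
      sse = sum((y - mean(y))^2), rmse = sqrt(mean((y - mean(y))^2)),
      r.squared = NA_real_, adj.r.squared = NA_real_,
      sigma = NA_real_, n = n, p = p, degenerate = TRUE,
      time = t, value = y, call = cl), class = "sinefit")
    return(fit)
  }

  ## deterministic multi-start: evenly spaced periods within each bound,
  ## full factorial across components
  start_1d <- lapply(seq_len(K), function(k)
    seq(lower[k], upper[k], length.out = max(2L, n_starts)))
  starts <- as.matrix(expand.grid(start_1d))

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::nlminb(start = as.numeric(starts[i, ]),
                         objective = profiled_sse, t = t, y = y,
                         lower = lower, upper = upper,
                         control = list(iter.max = 200))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  periods <- as.numeric(best$par)

  X <- sines_design(t, periods)
  lsq <- stats::lm.fit(X, y)
  beta <- lsq$coefficients
  beta[is.na(beta)] <- 0
  offset <- beta[1]
  amplitudes <- phases <- numeric(K)
  for (k in seq_len(K)) {
    al <- beta[2 * k]; be <- beta[2 * k + 1]
    amplitudes[k] <- sqrt(al^2 + be^2)
    phases[k] <- if (amplitudes[k] > 0) atan2(be, al) else 0
  }
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sse <- sum(res^2)
  r2 <- 1 - sse / sstot
  adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  sigma <- sqrt(sse / max(n - p, 1))

  structure(list(
    coefficients = sine_coef_vector(offset, amplitudes, periods, phases),
    offset = unname(offset), amplitudes = amplitudes, phases = phases,
    periods = periods, period_bounds = period_bounds,
    fitted.values = fitted, residuals = res,
    sse = sse, rmse = sqrt(sse / n),
    r.squared = r2, adj.r.squared = adj, sigma = sigma,
    n = n, p = p, degenerate = FALSE,
    convergence = best$convergence, time = t, value = y, call = cl),
    class = "sinefit")
}

sine_coef_vector <- function(offset, amplitudes, periods, phases) {
  K <- length(periods)
  out <- c(offset = unname(offset))
  for (k in seq_len(K)) {
    v <- c(amplitudes[k], periods[k], phases[k])
    names(v) <- paste0(c("amplitude", "period", "phase"), k)
    out <- c(out, v)
  }
  out
}

sine_eval <- function(object, t) {
  y <- rep(object$offset, length(t))
  for (k in seq_along(object$periods))
    y <- y + object$amplitudes[k] *
      sin(2 * pi / object$periods[k] * t + object$phases[k])
  y
}

#' @export
predict.sinefit <- function(object, newtime = NULL, ...) {
  if (is.null(newtime)) return(object$fitted.values)
  sine_eval(object, newtime)
}

#' @export
fitted.sinefit <- function(object, ...) object$fitted.values

#' @export
residuals.sinefit <- function(object, ...) object$residuals

#' @export
coef.sinefit <- function(object, ...) object$coefficients

#' @export
print.sinefit <- function(x, digits = 4, ...) {
  K <- length(x$periods)
  cat(sprintf("Sum-of-sines fit: %d component(s), n = %d\n", K, x$n))
  if (x$degenerate) {
    cat("  degenerate (constant input); amplitudes 0, R^2 undefined\n")
    return(invisible(x))
  }
  for (k in seq_len(K))
    cat(sprintf(
      "  component %d: period %.*f h (bounds %g-%g), amplitude %.*f, phase %.*f rad\n",
      k, digits, x$periods[k], x$period_bounds[[k]][1],
      x$period_bounds[[k]][2], digits, x$amplitudes[k], digits, x$phases[k]))
  cat(sprintf("  offset %.*f | RMSE %.*f | R^2 %.4f | adj R^2 %.4f\n",
              digits, x$offset, digits, x$rmse, x$r.squared,
              x$adj.r.squared))
  invisible(x)
}

## Jacobian of the model surface wrt theta = (d, {a_k, b_k, c_k}) at the fit
sine_jacobian <- function(object) {
  t <- object$time
  K <- length(object$periods)
  J <- matrix(0, length(t), 3 * K + 1)
  J[, 1] <- 1
  for (k in seq_len(K)) {
    b <- 2 * pi / object$periods[k]
    a <- object$amplitudes[k]
    ph <- b * t + object$phases[k]
    J[, 3 * k - 1] <- sin(ph)            # d/da
    J[, 3 * k] <- a * t * cos(ph)        # d/db (angular frequency)
    J[, 3 * k + 1] <- a * cos(ph)        # d/dc
  }
  colnames(J) <- c("offset", as.vector(vapply(seq_len(K), function(k)
    paste0(c("amplitude", "angfreq", "phase"), k), character(3))))
  J
}

#' @export
vcov.sinefit <- function(object, ...) {
  if (object$degenerate) stop("no covariance for a degenerate fit")
  J <- sine_jacobian(object)
  JtJ <- crossprod(J)
  V <- tryCatch(object$sigma^2 * solve(JtJ), error = function(e) {
    JtJ * NA_real_
  })
  dimnames(V) <- list(colnames(J), colnames(J))
  V
}

#' @export
confint.sinefit <- function(object, parm, level = 0.95, ...) {
  V <- vcov.sinefit(object)
  se <- sqrt(diag(V))
  est <- c(object$offset, as.vector(rbind(object$amplitudes,
                                          2 * pi / object$periods,
                                          object$phases)))
  q <- stats::qt(1 - (1 - level) / 2, df = max(object$n - object$p, 1))
  out <- cbind(est - q * se, est + q * se)
  dimnames(out) <- list(names(se),
                        paste0(format(100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2)), " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
summary.sinefit <- function(object, ...) {
  tab <- NULL
  if (!object$degenerate) {
    V <- vcov.sinefit(object)
    se <- sqrt(diag(V))
    est <- c(object$offset, as.vector(rbind(object$amplitudes,
                                            2 * pi / object$periods,
                                            object$phases)))
    tab <- cbind(Estimate = est, `Std. Error` = se,
                 `t value` = est / se)
    rownames(tab) <- names(se)
  }
  structure(list(fit = object, coef_table = tab),
            class = "summary.sinefit")
}

#' @export
print.summary.sinefit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$coef_table)) {
    cat("\nAsymptotic parameter table (angfreq = 2*pi/period, rad/h):\n")
    stats::printCoefmat(x$coef_table, has.Pvalue = FALSE)
  }
  invisible(x)
}

#' @export
plot.sinefit <- function(x, n_grid = 500, ...) {
  graphics::plot(x$time, x$value, xlab = "time (h)", ylab = "value",
                 main = "sum-of-sines fit", ...)
  tg <- seq(min(x$time), max(x$time), length.out = n_grid)
  graphics::lines(tg, sine_eval(x, tg), col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
simulate.sinefit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- if (is.finite(object$sigma)) object$sigma else 0
  out <- matrix(object$fitted.values, object$n, nsim) +
    matrix(stats::rnorm(object$n * nsim, 0, s), object$n, nsim)
  as.data.frame(out)
}

#' Period of a fit's dominant component
#'
#' @param object a [sinefit()] object.
#' @return The period (hours) of the component with the largest amplitude.
#' @export
dominant_period <- function(object) {
  stopifnot(inherits(object, "sinefit"))
  object$periods[which.max(object$amplitudes)]
}

#' Clock time of the fitted curve's daily peak
#'
#' Evaluates the fitted curve on a one-minute grid across the observed time
#' span and returns the clock hour (0-24) at which it is maximal.
#'
#' @param object a [sinefit()] object.
#' @return Acrophase as a clock hour in `[0, 24)`.
#' @export
acrophase <- function(object) {
  stopifnot(inherits(object, "sinefit"))
  tg <- seq(min(object$time), max(object$time), by = 1 / 60)
  tg[which.max(sine_eval(object, tg))] %% 24
}
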