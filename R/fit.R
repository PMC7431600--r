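#' Fit the exponential spatial-decay model
#'
#' Fits \eqn{y = a e^{bx}} to pooled (distance, constriction) points by
#' nonlinear least squares, minimising \eqn{\sum_i (y_i - a e^{b x_i})^2}
#' over all points with no per-distance averaging -- so distances with more
#' measurements weigh in more heavily, exactly as pooling implies. `a` is
#' the local constriction at the stimulation site, `b` (per um, usually
#' negative) the spatial decay rate, and `-1/b` the length constant of the
#' conducted response.
#'
#' Starting values are `a0 =` mean constriction at the shortest distance
#' and `b0` from a linear regression of `log(y)` on `x` over strictly
#' positive `y` (fallback `-5e-3`/um when fewer than two such points span
#' two distances). Optimisation is Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]) with an analytic Jacobian, unconstrained in
#' `b`; standard errors come from the curvature of the objective at the
#' optimum (`sigma^2 (J'J)^{-1}`). Zero-truncated points are
#' kept in the fit. A fit that does not converge is returned with
#' `converged = FALSE`, never silently.
#'
#' @param object A formula like `constriction ~ distance`, a data frame
#'   with columns `distance` and `constriction`, a [pool_group()] result,
#'   or (default method) a numeric vector of distances.
#' @param data Data frame in which a formula is evaluated.
#' @param constriction Numeric response for the default method.
#' @param maxiter,tol Optimiser control: maximum Levenberg-Marquardt
#'   iterations and relative convergence tolerance.
#' @param ... Passed between methods.
#'
#' @return An object of class `"decay_fit"` with components
#'   `coefficients` (`a`, `b`), `se`, `vcov`, `length_constant` (um; `NA`
#'   when `b >= 0`), `residual_sum_squares`, `n_points`, `n_distances`,
#'   `converged`, `fitted.values`, `residuals` and `data`. Methods:
#'   `print`, `summary`, `coef`, `vcov`, `confint`, `predict`, `fitted`,
#'   `residuals`, `simulate`, `plot`.
#' @seealso [length_constant()], [bootstrap_fit()]
#' @examples
#' x <- rep(seq(0, 300, 50), each = 4)
#' y <- 0.25 * exp(-x / 300) + rnorm(length(x), 0, 0.02)
#' fit <- decay_fit(constriction ~ distance,
#'                  data.frame(distance = x, constriction = y))
#' coef(fit)
#' length_constant(coef(fit)[["b"]])
#' predict(fit, newdata = c(0, 100, 200))
#' @export
decay_fit <- function(object, ...) UseMethod("decay_fit")

#' @rdname decay_fit
#' @export
decay_fit.formula <- function(object, data, ...) {
  mf <- stats::model.frame(object, data)
  if (ncol(mf) != 2L)
    stop("formula must have one response and one covariate, e.g. ",
         "constriction ~ distance", call. = FALSE)
  fit <- decay_fit.default(mf[[2L]], mf[[1L]], ...)
  fit$call <- match.call()
  fit
}

#' @rdname decay_fit
#' @export
decay_fit.data.frame <- function(object, ...) {
  if (!all(c("distance", "constriction") %in% names(object)))
    stop("data frame must have columns 'distance' and 'constriction'",
         call. = FALSE)
  decay_fit.default(object$distance, object$constriction, ...)
}

#' @rdname decay_fit
#' @export
decay_fit.pooled_group <- function(object, ...) {
  fit <- decay_fit.default(object$points$distance,
                           object$points$constriction, ...)
  fit$group_label <- object$group_label
  fit
}

#' @rdname decay_fit
#' @export
decay_fit.default <- function(object, constriction, maxiter = 1000,
                              tol = 1e-12, ...) {
  x <- as.numeric(object)
  y <- as.numeric(constriction)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2L)
    stop("need at least 2 points to fit the decay model", call. = FALSE)
  if (length(unique(x)) < 2L)
    stop("need at least 2 distinct distances to fit the decay model",
         call. = FALSE)

  a0 <- mean(y[x == min(x)])
  pos <- y > 0
  b0 <- if (sum(pos) >= 2L && length(unique(x[pos])) >= 2L) {
    unname(stats::coef(stats::lm(log(y[pos]) ~ x[pos]))[2L])
  } else -5e-3
  if (!is.finite(b0)) b0 <- -5e-3

  resid_fn <- function(p) y - p[1] * exp(p[2] * x)
  jac_fn <- function(p) {
    e <- exp(p[2] * x)
    -cbind(e, p[1] * x * e) # Jacobian of the residuals
  }
  lm_fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a = a0, b = b0), fn = resid_fn, jac = jac_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = maxiter, ftol = tol, ptol = tol,
                         gtol = 0)),
    error = function(e) NULL)

  if (is.null(lm_fit)) {
    cf <- c(a = a0, b = b0)
    conv <- FALSE
  } else {
    cf <- c(a = unname(lm_fit$par[["a"]]), b = unname(lm_fit$par[["b"]]))
    conv <- lm_fit$info %in% 1:4 # minpack convergence codes
  }
  fitted <- cf[["a"]] * exp(cf[["b"]] * x)
  # curvature-based covariance: sigma^2 * (J'J)^-1 at the optimum
  df <- length(x) - 2L
  sigma2 <- sum((y - fitted)^2) / max(df, 1L)
  J <- jac_fn(cf)
  V <- tryCatch(sigma2 * solve(crossprod(J)),
                error = function(e) matrix(NA_real_, 2, 2))
  dimnames(V) <- list(c("a", "b"), c("a", "b"))
  out <- list(coefficients = cf,
              se = c(a = sqrt(V["a", "a"]), b = sqrt(V["b", "b"])),
              vcov = V,
              converged = conv)
  res <- y - fitted
  out$residual_sum_squares <- sum(res^2)
  out$n_points <- length(x)
  out$n_distances <- length(unique(x))
  b <- out$coefficients[["b"]]
  out$length_constant <- if (is.finite(b) && b < 0) -1 / b else NA_real_
  out$fitted.values <- fitted
  out$residuals <- res
  out$data <- data.frame(distance = x, constriction = y)
  out$start <- c(a = a0, b = b0)
  out$call <- match.call()
  structure(out, class = "decay_fit")
}

#' Length constant of an exponential decay
#'
#' Converts a (negative) spatial decay rate `b` (per um) into the length
#' constant `-1/b` (um): the distance over which the conducted response
#' falls to `1/e` of its local amplitude.
#'
#' @param b Decay rate in 1/um; must be negative (a non-negative rate means
#'   no spatial decay and has no length constant).
#' @return Length constant in um.
#' @examples
#' length_constant(-5.6e-3) # 178.6 um
#' length_constant(-2.2e-3) # 454.5 um
#' @export
length_constant <- function(b) {
  if (any(!is.finite(b))) stop("b must be finite", call. = FALSE)
  if (any(b >= 0))
    stop("b must be negative: a non-negative decay rate implies no spatial ",
         "decay, so the length constant is undefined", call. = FALSE)
  -1 / b
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
vcov.decay_fit <- function(object, ...) object$vcov

#' @export
fitted.decay_fit <- function(object, ...) object$fitted.values

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' Predict conducted constriction at given distances
#'
#' Evaluates the fitted curve `a * exp(b * x)`; at `x = 0` this is the
#' fitted local constriction `a`.
#'
#' @param object A `decay_fit`.
#' @param newdata Numeric vector of distances (um), or a data frame with a
#'   `distance` column. Defaults to the fitted distances.
#' @param ... Unused.
#' @return Numeric vector of predicted constriction fractions.
#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$distance
  else if (is.data.frame(newdata)) newdata$distance
  else as.numeric(newdata)
  cf <- object$coefficients
  cf[["a"]] * exp(cf[["b"]] * x)
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential decay fit: y = a * exp(b * x)\n")
  if (!is.null(x$group_label)) cat("Group:", x$group_label, "\n")
  cat(sprintf("  a = %.*g   b = %.*g /um\n", digits,
              x$coefficients[["a"]], digits, x$coefficients[["b"]]))
  if (is.finite(x$length_constant))
    cat(sprintf("  length constant -1/b = %.1f um\n", x$length_constant))
  else
    cat("  length constant undefined (b >= 0)\n")
  cat(sprintf("  %d points over %d distances; RSS = %.3g%s\n", x$n_points,
              x$n_distances, x$residual_sum_squares,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, level = 0.95, ...) {
  cf <- object$coefficients
  se <- object$se
  df <- object$n_points - 2L
  z <- stats::qt(1 - (1 - level) / 2, df)
  tab <- cbind(Estimate = cf, `Std. Error` = se,
               Lower = cf - z * se, Upper = cf + z * se)
  lc <- object$length_constant
  # monotone transform of the b interval; defined only when both ends < 0
  lc_ci <- c(NA_real_, NA_real_)
  if (is.finite(lc) && all(is.finite(tab["b", c("Lower", "Upper")])) &&
      tab["b", "Upper"] < 0)
    lc_ci <- c(-1 / tab["b", "Lower"], -1 / tab["b", "Upper"])
  structure(list(coefficients = tab, length_constant = lc,
                 length_constant_ci = lc_ci, level = level,
                 residual_sum_squares = object$residual_sum_squares,
                 sigma = sqrt(object$residual_sum_squares / max(df, 1L)),
                 n_points = object$n_points, df = df,
                 converged = object$converged,
                 group_label = object$group_label),
            class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, digits = 4, ...) {
  cat("Exponential decay fit: y = a * exp(b * x)\n")
  if (!is.null(x$group_label)) cat("Group:", x$group_label, "\n")
  stats::printCoefmat(x$coefficients, digits = digits, cs.ind = 1:2,
                      tst.ind = integer())
  if (is.finite(x$length_constant)) {
    cat(sprintf("\nLength constant -1/b: %.1f um", x$length_constant))
    if (all(is.finite(x$length_constant_ci)))
      cat(sprintf("  (%g%% curvature CI %.1f-%.1f um)", 100 * x$level,
                  x$length_constant_ci[1], x$length_constant_ci[2]))
    cat("\n")
  }
  cat(sprintf("Residual sd %.4g on %d degrees of freedom (%d points)\n",
              x$sigma, x$df, x$n_points))
  if (!x$converged) cat("Warning: fit did not converge\n")
  invisible(x)
}

#' @export
confint.decay_fit <- function(object, parm = c("a", "b"), level = 0.95, ...) {
  s <- summary(object, level = level)
  s$coefficients[parm, c("Lower", "Upper"), drop = FALSE]
}

#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sqrt(object$residual_sum_squares / max(object$n_points - 2L, 1L))
  n <- object$n_points
  out <- as.data.frame(replicate(nsim, object$fitted.values +
                                   stats::rnorm(n, 0, sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a decay fit
#'
#' Base-graphics plot of the pooled points, per-distance means (if the fit
#' came from a [pool_group()] object via `pooled`), and the fitted curve.
#'
#' @param x A `decay_fit`.
#' @param pooled Optional `pooled_group` for per-distance mean +/- SEM
#'   overlays.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.decay_fit <- function(x, pooled = NULL, ...) {
  d <- x$data
  graphics::plot(d$distance, d$constriction, pch = 1, col = "grey50",
                 xlab = "Distance from stimulation site (um)",
                 ylab = "Relative constriction",
                 main = if (!is.null(x$group_label)) x$group_label else
                   "Exponential decay fit", ...)
  xx <- seq(0, max(d$distance), length.out = 200)
  graphics::lines(xx, predict(x, xx), lwd = 2)
  if (!is.null(pooled)) {
    pd <- pooled$per_distance
    graphics::points(pd$distance, pd$mean, pch = 18, cex = 1.3)
    has_sem <- is.finite(pd$sem)
    graphics::arrows(pd$distance[has_sem], pd$mean[has_sem] - pd$sem[has_sem],
                     pd$distance[has_sem], pd$mean[has_sem] + pd$sem[has_sem],
                     angle = 90, code = 3, length = 0.03)
  }
  invisible(x)
}
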