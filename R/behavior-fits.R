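# Learning-curve model fits.
#
# Two candidate time-course models for task-goal achievement P(t) over
# training day t, compared by R^2:
#   sigmoid:               P(t) = d + a / (1 + exp(-c (t - b)))
#     with 0 <= a <= 10, 0 <= b <= 12, 0 <= c <= 1, 0 <= d <= 1
#   stretched exponential: P(t) = a + b exp(c t^d)
#     with c < 0, 0 < d < 1, a and b unconstrained.
# Fits use bounded nonlinear least squares (Levenberg-Marquardt with box
# constraints) from a deterministic multi-start grid, so results are
# reproducible without any random initialization.

sigmoid_fn <- function(t, a, b, c, d) d + a / (1 + exp(-c * (t - b)))
stretch_exp_fn <- function(t, a, b, c, d) a + b * exp(c * t^d)

new_learning_fit <- function(model, params, r_squared, sse, converged,
                             degenerate, data, t10 = NA_real_) {
  structure(
    list(model = model, params = params, r_squared = r_squared, sse = sse,
         converged = converged, degenerate = degenerate, data = data,
         t10_max = t10),
    class = "learning_fit"
  )
}

multistart_nls <- function(df, fn, starts, lower, upper) {
  best <- NULL
  form <- value ~ fn(day, a, b, c, d)
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        form, data = df, start = as.list(starts[i, ]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
      )),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(fit = fit, sse = sse)
  }
  best
}

finish_fit <- function(model, df, best) {
  sst <- sum((df$value - mean(df$value))^2)
  if (is.null(best)) {
    return(new_learning_fit(model, c(a = NA, b = NA, c = NA, d = NA),
                            NA_real_, NA_real_, FALSE, FALSE, df))
  }
  params <- coef(best$fit)
  degen <- sst == 0
  r2 <- if (degen) 0 else 1 - best$sse / sst
  new_learning_fit(model, params, r2, best$sse, TRUE, degen, df)
}

#' Fit a sigmoid learning curve
#'
#' Bounded nonlinear least squares of
#' `P(t) = d + a / (1 + exp(-c (t - b)))` with box constraints
#' `a <= 10`, `b <= 12`, `c <= 1`, `d <= 1` (all non-negative), started
#' from a deterministic grid over the box; the lowest-SSE solution is
#' returned along with its R^2 and the t10%-max onset day.
#'
#' @param curve Tibble with `day` and `value` columns; at least 5
#'   non-missing days. Missing values are dropped.
#' @return A `learning_fit` object (see [tidy.learning_fit()],
#'   [glance.learning_fit()]).
#' @export
#' @examples
#' days <- 1:12
#' curve <- tibble::tibble(day = days,
#'                         value = 0.02 + 0.3 / (1 + exp(-0.9 * (days - 6))))
#' fit <- fit_sigmoid(curve)
#' glance(fit)
fit_sigmoid <- function(curve) {
  df <- curve[!is.na(curve$value), c("day", "value")]
  if (nrow(df) < 5) stop_input("need at least 5 non-missing days")
  if (sd(df$value) == 0) {
    # flat curve: the a -> 0 solution family; report the exact member d = value
    params <- c(a = 0, b = mean(df$day), c = 0.5, d = df$value[1])
    return(new_learning_fit("sigmoid", params, 0, 0, TRUE, TRUE, df))
  }
  lower <- c(a = 0, b = 0, c = 0, d = 0)
  upper <- c(a = 10, b = 12, c = 1, d = 1)
  ry <- diff(range(df$value))
  grid <- expand.grid(
    a = c(ry, 2 * ry, 5),
    b = quantile(df$day, c(0.25, 0.5, 0.75), names = FALSE),
    c = c(0.1, 0.5, 0.9),
    d = c(0, max(0, min(df$value)), 0.5)
  )
  grid$a <- pmin(pmax(grid$a, lower["a"]), upper["a"])
  fit <- finish_fit("sigmoid", df, multistart_nls(df, sigmoid_fn, grid, lower, upper))
  if (fit$converged && !fit$degenerate) fit$t10_max <- t10_max(fit)
  fit
}

#' Fit a stretched-exponential learning curve
#'
#' Bounded nonlinear least squares of `P(t) = a + b exp(c t^d)` with
#' `c < 0` and `0 < d < 1` (`a`, `b` unconstrained), with the same
#' deterministic multi-start and R^2 contract as [fit_sigmoid()].
#'
#' @inheritParams fit_sigmoid
#' @return A `learning_fit` object.
#' @export
fit_exponential <- function(curve) {
  df <- curve[!is.na(curve$value), c("day", "value")]
  if (nrow(df) < 5) stop_input("need at least 5 non-missing days")
  if (sd(df$value) == 0) {
    params <- c(a = df$value[1], b = 0, c = -0.5, d = 0.5)
    return(new_learning_fit("exponential", params, 0, 0, TRUE, TRUE, df))
  }
  lower <- c(a = -100, b = -100, c = -50, d = 1e-4)
  upper <- c(a = 100, b = 100, c = -1e-6, d = 1 - 1e-4)
  ry <- diff(range(df$value))
  grid <- expand.grid(
    a = quantile(df$value, c(0.1, 0.5, 0.9), names = FALSE),
    b = c(-(ry + 0.05), -(ry + 0.05) / 2, ry + 0.05),
    c = c(-1, -0.3, -0.05),
    d = c(0.3, 0.6, 0.9)
  )
  finish_fit("exponential", df, multistart_nls(df, stretch_exp_fn, grid, lower, upper))
}

#' Onset of performance improvement (t10%-max)
#'
#' The day at which the fitted sigmoid reaches 10% of its asymptotic
#' amplitude `a`, in closed form `t = b - ln(9) / c`. With
#' `include_baseline = TRUE` the 10% level is instead taken on the full
#' peak `a + d` (so the baseline counts toward "maximum performance");
#' that variant is undefined when `d >= a/9`.
#'
#' @param fit A converged sigmoid `learning_fit` with `c > 0`.
#' @param include_baseline Use the baseline-inclusive definition.
#' @return Onset day (possibly outside the training window), or `NA`
#'   when undefined (`c = 0`, or infeasible baseline-inclusive level).
#' @export
t10_max <- function(fit, include_baseline = FALSE) {
  stopifnot(inherits(fit, "learning_fit"), fit$model == "sigmoid")
  p <- fit$params
  if (!fit$converged || is.na(p["c"]) || p["c"] <= 0) return(NA_real_)
  if (!include_baseline) {
    return(unname(p["b"] - log(9) / p["c"]))
  }
  level <- 0.1 * (p["a"] + p["d"]) - p["d"]
  if (level <= 0 || level >= p["a"]) return(NA_real_)
  unname(p["b"] - log(p["a"] / level - 1) / p["c"])
}

#' @export
print.learning_fit <- function(x, ...) {
  cat(sprintf("<learning_fit: %s>\n", x$model))
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4f, converged = %s%s\n", x$r_squared, x$converged,
              if (x$degenerate) " (degenerate)" else ""))
  if (!is.na(x$t10_max)) cat(sprintf("  t10%%-max = %.2f days\n", x$t10_max))
  invisible(x)
}

#' Tidy a learning-curve fit
#'
#' @param x A `learning_fit`.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`.
#' @export
tidy.learning_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' One-row summary of a learning-curve fit
#'
#' @param x A `learning_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `r_squared`, `sse`, `t10_max`,
#'   `converged`, `degenerate`, `n`.
#' @export
glance.learning_fit <- function(x, ...) {
  tibble(model = x$model, r_squared = x$r_squared, sse = x$sse,
         t10_max = x$t10_max, converged = x$converged,
         degenerate = x$degenerate, n = nrow(x$data))
}

#' @export
predict.learning_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$day else newdata$day
  p <- as.list(object$params)
  fn <- if (object$model == "sigmoid") sigmoid_fn else stretch_exp_fn
  fn(t, p$a, p$b, p$c, p$d)
}

#' Plot a learning-curve fit over the daily data
#'
#' @param object A `learning_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.learning_fit <- function(object, ...) {
  grid <- tibble(day = seq(min(object$data$day), max(object$data$day),
                           length.out = 200))
  grid$value <- predict(object, grid)
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Training day", y = "Successes per reach",
                  title = sprintf("%s fit (R² = %.3f)", object$model,
                                  object$r_squared))
  if (!is.na(object$t10_max)) {
    p <- p + ggplot2::geom_vline(xintercept = object$t10_max, linetype = "dotted")
  }
  p
}
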