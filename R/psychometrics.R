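## Psychometric-function regression. Per-condition percent-correct scores
## are fitted with the four-parameter logistic
##
##   Ps(x) = p_chance + p_range / (1 + exp(-s (x - x_o)))
##
## with the chance level fixed by the task (50% for the two-alternative
## spectral task, 10% for the ten-alternative word task), and the
## threshold is read off at a task criterion by closed-form inversion.

#' Fit a psychometric function to per-condition scores
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with `p_chance`
#' fixed and `p_range` in `[0, 100 - p_chance]`, `s > 0` free. A
#' multi-start over slope initializations (0.2, 0.5, 1, 2) with `x_o`
#' started at the empirical half-range crossing guards against local
#' minima; the best converged fit by residual sum of squares is kept.
#'
#' @param scores percent correct per condition (0..100).
#' @param conditions condition values (dB), same length, at least 4.
#' @param p_chance fixed chance level (percent).
#' @return object of class `psychfit` with components `coefficients`
#'   (`p_range`, `s`, `x_o`), `p_chance`, `p_max`, `r_squared`, `data`.
#' @export
fit_psychometric <- function(scores, conditions, p_chance) {
  if (length(scores) != length(conditions)) stop("length mismatch")
  if (length(scores) < 4) stop("need at least 4 conditions")
  if (any(scores < 0 | scores > 100)) stop("scores must be in [0, 100]")
  df <- data.frame(x = as.numeric(conditions), y = as.numeric(scores))
  df <- df[order(df$x), ]
  ## degenerate case: no usable range above chance; the logistic collapses
  ## to its lower asymptote and the threshold is undefined downstream
  if (diff(range(df$y)) < 1e-8 || max(df$y) <= p_chance + 1e-8) {
    return(structure(list(
      coefficients = c(p_range = max(0, max(df$y) - p_chance), s = 1,
                       x_o = stats::median(df$x)),
      p_chance = p_chance,
      p_max = max(p_chance, max(df$y)),
      r_squared = NA_real_, data = df, fit = NULL),
      class = "psychfit"))
  }
  ## empirical inflection guess: first crossing of the half range
  half <- p_chance + (max(df$y) - p_chance) / 2
  above <- which(df$y >= half)
  x0_guess <- if (length(above)) df$x[above[1]] else stats::median(df$x)
  pr_guess <- min(max(max(df$y) - p_chance, 1), 100 - p_chance)
  best <- NULL; best_ss <- Inf
  for (s0 in c(0.2, 0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ p_chance + p_range / (1 + exp(-s * (x - x_o))),
        data = df,
        start = list(p_range = pr_guess, s = s0, x_o = x0_guess),
        lower = c(p_range = 0, s = 1e-4, x_o = min(df$x) - 30),
        upper = c(p_range = 100 - p_chance, s = 50, x_o = max(df$x) + 30),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(residuals(fit)^2)
    if (ss < best_ss) { best <- fit; best_ss <- ss }
  }
  if (is.null(best))
    stop("psychometric fit failed to converge from all starts; ",
         "conditions: ", paste(df$x, collapse = ", "))
  cf <- coef(best)
  ss_tot <- sum((df$y - mean(df$y))^2)
  r2 <- if (ss_tot > 0) 1 - best_ss / ss_tot else NA_real_
  structure(list(coefficients = cf, p_chance = p_chance,
                 p_max = p_chance + unname(cf["p_range"]),
                 r_squared = r2, data = df, fit = best),
            class = "psychfit")
}

#' Evaluate the fitted psychometric function
#'
#' @param object a `psychfit`.
#' @param newdata optional numeric vector of condition values (dB) or a
#'   data frame with column `x`.
#' @param ... unused.
#' @return predicted percent correct.
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x else as.numeric(newdata)
  cf <- object$coefficients
  object$p_chance + cf["p_range"] / (1 + exp(-cf["s"] * (x - cf["x_o"])))
}

#' @export
coef.psychfit <- function(object, ...) object$coefficients

#' @export
residuals.psychfit <- function(object, ...) {
  object$data$y - unname(predict(object))
}

#' @export
print.psychfit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "psychometric fit: p_chance = %g%%, p_max = %.1f%%, s = %.3f /dB, x_o = %.2f dB, R^2 = %.4f\n",
    x$p_chance, x$p_max, cf["s"], cf["x_o"], x$r_squared))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  cat("Psychometric function fit\n")
  print(object)
  cat(sprintf("  p_range = %.2f%% (upper bound %g%%)\n",
              object$coefficients["p_range"], 100 - object$p_chance))
  cat(sprintf("  conditions: %s dB\n", paste(object$data$x, collapse = ", ")))
  cat(sprintf("  scores:     %s %%\n", paste(round(object$data$y, 1), collapse = ", ")))
  invisible(object)
}

#' @export
plot.psychfit <- function(x, criterion = NULL, ...) {
  xs <- seq(min(x$data$x) - 1, max(x$data$x) + 1, length.out = 200)
  graphics::plot(x$data$x, x$data$y, pch = 4,
                 xlab = "condition (dB)", ylab = "correct (%)",
                 ylim = c(0, 100), ...)
  graphics::lines(xs, predict(x, xs), col = "red")
  graphics::abline(h = x$p_chance, lty = 3)
  if (!is.null(criterion)) {
    graphics::abline(h = criterion, lty = 2)
    th <- tryCatch(threshold(x, criterion), error = function(e) NULL)
    if (!is.null(th)) graphics::abline(v = th, lty = 2)
  }
  invisible(x)
}

#' Threshold at a performance criterion
#'
#' Closed-form inversion of the fitted logistic:
#' `x = x_o - log(p_range / (criterion - p_chance) - 1) / s`. The
#' threshold is defined only for criteria strictly between the chance
#' level and the fitted upper asymptote.
#'
#' @param fit a `psychfit`.
#' @param criterion percent-correct criterion (79.4 for the spectral
#'   modulation task, 50 for the speech reception task).
#' @return threshold in dB.
#' @export
threshold <- function(fit, criterion) {
  stopifnot(inherits(fit, "psychfit"))
  cf <- fit$coefficients
  if (criterion <= fit$p_chance)
    stop("criterion at or below the chance level")
  if (criterion >= fit$p_max)
    stop(sprintf("threshold undefined: criterion %.1f%% >= fitted p_max %.1f%%",
                 criterion, fit$p_max))
  unname(cf["x_o"] - log(cf["p_range"] / (criterion - fit$p_chance) - 1) / cf["s"])
}
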