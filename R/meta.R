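# Internal computational kernel shared by meta_fit(), cherry_pick() and the
# Monte Carlo machinery. All take bare numeric vectors; no validation here.

# pooled one-sided / two-sided p from effects y and weights w
.pool_z <- function(y, w) sum(w * y) / sqrt(sum(w))

.p_from_z <- function(z, sided) {
  switch(sided,
         right = stats::pnorm(-z),
         left  = stats::pnorm(z),
         two   = 2 * stats::pnorm(-abs(z)))
}

# DerSimonian-Laird moment estimator, truncated at zero; 0 when k = 1
.dl_tau2 <- function(y, v) {
  k <- length(y)
  if (k < 2L) return(0)
  w0 <- 1 / v
  y0 <- sum(w0 * y) / sum(w0)
  q <- sum(w0 * (y - y0)^2)
  den <- sum(w0) - sum(w0^2) / sum(w0)
  max(0, (q - (k - 1)) / den)
}

#' Inverse-variance meta-analysis
#'
#' Fits the standard inverse-variance pooled model to a set of studies. Under
#' the fixed-effect model every study estimates one common effect
#' \eqn{\theta} and the study weight is \eqn{w_i = 1/\sigma_i^2}; under the
#' random-effects model the true study effects vary with between-study
#' variance \eqn{\tau^2} and the weights become
#' \eqn{w_i = 1/(\sigma_i^2 + \tau^2)}, with \eqn{\tau^2} estimated by the
#' DerSimonian-Laird moment estimator unless supplied. The pooled estimate is
#' the weighted mean \eqn{\hat\theta = \sum w_i y_i / \sum w_i}, its standard
#' error \eqn{(\sum w_i)^{-1/2}}, the confidence interval
#' \eqn{\hat\theta \mp z_{\alpha}(\sum w_i)^{-1/2}} with
#' \eqn{z_\alpha = \Phi^{-1}(1-\alpha/2)}, and the default decision p-value is
#' the one-sided right-tailed \eqn{p = \Phi(-\hat\theta\sqrt{\sum w_i})} for
#' the hypotheses \eqn{H_0: \theta = 0} versus \eqn{H_1: \theta > 0}.
#'
#' Within-study variances are treated as known constants; no estimation of
#' \eqn{\sigma_i^2} is attempted.
#'
#' @param x A [studies] object or a data frame with columns `label`, `effect`
#'   and `variance` (or `se`). Alternatively `effect`/`variance`/`se` may be
#'   supplied directly together with optional `label`.
#' @param effect,variance,se,label Used when `x` is missing: numeric vectors
#'   as in [studies()].
#' @param model `"fixed"` or `"random"`.
#' @param alpha Significance level in (0,1); also sets the CI coverage
#'   \eqn{1-\alpha}. Default 0.05.
#' @param tau2 Optional between-study variance override. Ignored (forced to
#'   0) under `model = "fixed"`; if supplied under `model = "random"` it is
#'   used instead of the DerSimonian-Laird estimate (this is how a full-set
#'   estimate is held fixed when re-analysing subsets).
#' @param sided Tail of the decision p-value: `"right"` (default;
#'   \eqn{H_1:\theta>0}), `"left"` or `"two"`.
#' @return An object of class `"meta_fit"`: a list with components
#'   `estimate`, `se`, `ci` (length 2), `p` (the decision p-value),
#'   `p_one_sided` (right-tailed, always reported), `tau2`, `weights`
#'   (named), `model`, `alpha`, `sided`, `k`, `q` (Cochran's heterogeneity
#'   statistic) and `studies`.
#' @examples
#' fit <- meta_fit(effect = c(1, 0, -0.5), variance = c(0.1, 0.2, 0.4))
#' fit
#' coef(fit)
#' confint(fit)
#' @seealso [dl_tau2()], [cherry_pick()], [forest_table()]
#' @export
meta_fit <- function(x, effect = NULL, variance = NULL, se = NULL,
                     label = NULL, model = c("fixed", "random"),
                     alpha = 0.05, tau2 = NULL,
                     sided = c("right", "left", "two")) {
  model <- match.arg(model)
  sided <- match.arg(sided)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0,1)", call. = FALSE)
  if (missing(x)) {
    if (is.null(label)) label <- paste0("study_", seq_along(effect))
    x <- studies(label, effect, variance = variance, se = se)
  } else {
    x <- as_studies(x)
  }
  y <- x$effect
  v <- x$variance
  if (model == "fixed") {
    t2 <- 0
  } else if (is.null(tau2)) {
    if (nrow(x) < 2L)
      warning("single study: between-study variance set to 0", call. = FALSE)
    t2 <- .dl_tau2(y, v)
  } else {
    if (tau2 < 0) stop("'tau2' must be nonnegative", call. = FALSE)
    t2 <- tau2
  }
  w <- 1 / (v + t2)
  sw <- sum(w)
  est <- sum(w * y) / sw
  se_p <- 1 / sqrt(sw)
  zcrit <- stats::qnorm(1 - alpha / 2)
  z <- est / se_p
  w0 <- 1 / v
  y0 <- sum(w0 * y) / sum(w0)
  out <- list(
    estimate = est,
    se = se_p,
    ci = c(est - zcrit * se_p, est + zcrit * se_p),
    p = .p_from_z(z, sided),
    p_one_sided = .p_from_z(z, "right"),
    statistic = z,
    tau2 = t2,
    weights = stats::setNames(w, x$label),
    model = model,
    alpha = alpha,
    sided = sided,
    k = nrow(x),
    q = sum(w0 * (y - y0)^2),
    studies = x
  )
  class(out) <- "meta_fit"
  out
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator
#' \eqn{\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i^0 - \sum (w_i^0)^2/\sum w_i^0)\}}
#' where \eqn{w_i^0 = 1/\sigma_i^2} and
#' \eqn{Q = \sum w_i^0 (y_i - \bar y^0)^2} is Cochran's statistic around the
#' fixed-effect pooled mean \eqn{\bar y^0}. For a single study the
#' denominator is degenerate and the estimate is defined as 0 (one study
#' carries no between-study information); a warning is issued.
#'
#' @inheritParams meta_fit
#' @return Nonnegative scalar \eqn{\hat\tau^2}.
#' @examples
#' dl_tau2(effect = c(0, 2), variance = c(1, 1)) # Q = 2, denominator 1 -> 1
#' @export
dl_tau2 <- function(x, effect = NULL, variance = NULL, se = NULL,
                    label = NULL) {
  if (missing(x)) {
    if (is.null(label)) label <- paste0("study_", seq_along(effect))
    x <- studies(label, effect, variance = variance, se = se)
  } else {
    x <- as_studies(x)
  }
  if (nrow(x) < 2L) {
    warning("single study: between-study variance set to 0", call. = FALSE)
    return(0)
  }
  .dl_tau2(x$effect, x$variance)
}

#' Inverse-variance study weights
#'
#' Weights \eqn{w_i = 1/(\sigma_i^2 + \tau^2)}; `tau2 = 0` gives the
#' fixed-effect weights \eqn{1/\sigma_i^2}.
#'
#' @inheritParams meta_fit
#' @param tau2 Nonnegative between-study variance.
#' @return Named numeric vector of positive weights.
#' @export
study_weights <- function(x, tau2 = 0) {
  x <- as_studies(x)
  if (!is.numeric(tau2) || length(tau2) != 1L || tau2 < 0 || !is.finite(tau2))
    stop("'tau2' must be a single nonnegative number", call. = FALSE)
  stats::setNames(1 / (x$variance + tau2), x$label)
}

#' One-sided per-study p-value
#'
#' \eqn{p_i = \Phi(-\sqrt{w_i}\, y_i)}: the right-tailed p-value of a single
#' study under \eqn{H_0:\theta=0}, using its inverse-variance weight. This is
#' the ranking key of the top-S selection rule.
#'
#' @param effect Study effect \eqn{y_i}.
#' @param weight Positive weight \eqn{w_i}.
#' @return p-value in (0,1), strictly decreasing in `effect`.
#' @export
study_p_value <- function(effect, weight) {
  if (any(weight <= 0)) stop("'weight' must be positive", call. = FALSE)
  stats::pnorm(-sqrt(weight) * effect)
}

#' Pooled one-sided p-value of a fit
#'
#' \eqn{p_{meta} = \Phi(-\hat\theta\sqrt{\sum w_i})}. For a single study this
#' reduces exactly to [study_p_value()].
#'
#' @param fit A [meta_fit] object.
#' @return p-value in (0,1).
#' @export
pooled_p_value <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  fit$p_one_sided
}

#' Heterogeneity fraction from a typical within-study variance
#'
#' \eqn{I^2 = \tau^2 / (\tau^2 + s^2)} where \eqn{s^2} is a typical
#' within-study variance: the fraction of total variance attributable to
#' between-study heterogeneity. With \eqn{s^2 = 0.17} (the mean of the
#' truncated within-variance model used in the simulations),
#' \eqn{\tau^2 = 0.70} gives about 80%.
#'
#' @param tau2 Nonnegative between-study variance.
#' @param typical_within_var Positive typical within-study variance
#'   \eqn{s^2}.
#' @return Value in \[0, 1).
#' @export
i_squared_typical <- function(tau2, typical_within_var) {
  if (any(typical_within_var <= 0))
    stop("'typical_within_var' must be positive", call. = FALSE)
  if (any(tau2 < 0)) stop("'tau2' must be nonnegative", call. = FALSE)
  tau2 / (tau2 + typical_within_var)
}

#' Forest-plot table
#'
#' Per-study effects, confidence intervals and percentage weights, plus a
#' pooled row — the data behind a forest plot, as a plain data frame.
#'
#' @param fit A [meta_fit] object.
#' @return Data frame with columns `label`, `effect`, `ci_low`, `ci_high`,
#'   `weight_pct` (summing to 100 over the studies; `NA` for the pooled row)
#'   and `pooled` (logical).
#' @export
forest_table <- function(fit) {
  stopifnot(inherits(fit, "meta_fit"))
  s <- fit$studies
  zcrit <- stats::qnorm(1 - fit$alpha / 2)
  se_i <- sqrt(s$variance + fit$tau2)
  wpct <- 100 * fit$weights / sum(fit$weights)
  out <- data.frame(
    label = c(s$label, "(pooled)"),
    effect = c(s$effect, fit$estimate),
    ci_low = c(s$effect - zcrit * se_i, fit$ci[1L]),
    ci_high = c(s$effect + zcrit * se_i, fit$ci[2L]),
    weight_pct = c(unname(wpct), NA_real_),
    pooled = c(rep(FALSE, nrow(s)), TRUE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# ---- methods ---------------------------------------------------------------

#' @export
print.meta_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s-effect%s meta-analysis of %d studies\n",
              if (x$model == "fixed") "Fixed" else "Random",
              if (x$model == "random") "s" else "", x$k))
  if (x$model == "random")
    cat(sprintf("  tau^2 (DerSimonian-Laird unless supplied): %.*g\n",
                digits, x$tau2))
  cat(sprintf("  pooled estimate: %.*g  (se %.*g)\n",
              digits, x$estimate, digits, x$se))
  cat(sprintf("  %g%% CI: [%.*g, %.*g]\n", 100 * (1 - x$alpha),
              digits, x$ci[1L], digits, x$ci[2L]))
  cat(sprintf("  %s-tailed p: %.*g\n", x$sided, digits, x$p))
  invisible(x)
}

#' @export
summary.meta_fit <- function(object, ...) {
  s2_typ <- mean(object$studies$variance)
  out <- list(fit = object,
              i2 = i_squared_typical(object$tau2, s2_typ),
              typical_within_var = s2_typ)
  class(out) <- "summary.meta_fit"
  out
}

#' @export
print.summary.meta_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  Cochran Q: %.*g on %d df\n", digits, x$fit$q, x$fit$k - 1L))
  cat(sprintf("  I^2 (typical within-variance %.3g): %.1f%%\n",
              x$typical_within_var, 100 * x$i2))
  cat("\nStudies:\n")
  print(forest_table(x$fit), digits = digits)
  invisible(x)
}

#' @export
coef.meta_fit <- function(object, ...) {
  c(estimate = object$estimate)
}

#' @export
vcov.meta_fit <- function(object, ...) {
  matrix(object$se^2, 1L, 1L, dimnames = list("estimate", "estimate"))
}

#' @export
confint.meta_fit <- function(object, parm, level, ...) {
  alpha <- if (missing(level)) object$alpha else 1 - level
  zcrit <- stats::qnorm(1 - alpha / 2)
  out <- matrix(object$estimate + c(-1, 1) * zcrit * object$se, 1L, 2L)
  dimnames(out) <- list("estimate",
                        sprintf("%.1f %%", 100 * c(alpha / 2, 1 - alpha / 2)))
  out
}

#' @export
weights.meta_fit <- function(object, ...) object$weights

#' @export
fitted.meta_fit <- function(object, ...) {
  stats::setNames(rep(object$estimate, object$k), object$studies$label)
}

#' @export
residuals.meta_fit <- function(object, type = c("raw", "standardized"), ...) {
  type <- match.arg(type)
  r <- object$studies$effect - object$estimate
  if (type == "standardized")
    r <- r / sqrt(object$studies$variance + object$tau2)
  stats::setNames(r, object$studies$label)
}

#' @export
simulate.meta_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- object$studies
  sd_i <- sqrt(s$variance + object$tau2)
  lapply(seq_len(nsim), function(i) {
    studies(s$label, stats::rnorm(object$k, object$estimate, sd_i),
            variance = s$variance)
  })
}

#' Forest plot of a fitted meta-analysis
#'
#' Base-graphics forest display: per-study effects with confidence
#' intervals, point sizes proportional to weight, and the pooled estimate.
#'
#' @param x A [meta_fit] object.
#' @param xlab Axis label.
#' @param ... Passed to [graphics::plot.default()].
#' @return `x`, invisibly.
#' @export
plot.meta_fit <- function(x, xlab = "effect", ...) {
  ft <- forest_table(x)
  n <- nrow(ft)
  ys <- rev(seq_len(n))
  graphics::plot(ft$effect, ys, yaxt = "n", ylab = "", xlab = xlab,
                 xlim = range(ft$ci_low, ft$ci_high, 0),
                 pch = ifelse(ft$pooled, 18, 15),
                 cex = c(0.6 + 1.5 * ft$weight_pct[-n] / max(ft$weight_pct[-n]), 2),
                 ...)
  graphics::segments(ft$ci_low, ys, ft$ci_high, ys)
  graphics::abline(v = 0, lty = 3)
  graphics::abline(v = x$estimate, lty = 2, col = "grey40")
  graphics::axis(2, at = ys, labels = ft$label, las = 1, cex.axis = 0.8)
  invisible(x)
}
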