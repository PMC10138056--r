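#' Weight ratio of a study set
#'
#' \eqn{\eta = w_{max}/w_{min}} among the studies, with
#' \eqn{w_i = 1/(\sigma_i^2+\tau^2)}. Equals 1 for homoscedastic studies and
#' tends to 1 as \eqn{\tau^2} dominates the within-study variances. Computed
#' over all supplied studies, it is a conservative bound on any subset's
#' ratio.
#'
#' @param x A [studies] object (or data frame), or a numeric vector of
#'   within-study variances.
#' @param tau2 Nonnegative between-study variance.
#' @return Scalar \eqn{\eta \ge 1}.
#' @export
weight_ratio <- function(x, tau2 = 0) {
  v <- if (is.numeric(x)) x else as_studies(x)$variance
  if (length(v) < 1L) stop("empty study set", call. = FALSE)
  if (any(v <= 0)) stop("variances must be positive", call. = FALSE)
  if (tau2 < 0) stop("'tau2' must be nonnegative", call. = FALSE)
  w <- 1 / (v + tau2)
  max(w) / min(w)
}

.check_bound_inputs <- function(alpha, delta, epsilon, eta, case) {
  if (alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must be in (0, 1/2)", call. = FALSE)
  if (delta <= 0 || delta >= 1)
    stop("'delta' must be in (0, 1)", call. = FALSE)
  emax <- if (case == "overstate") 1 / 3 else 1
  if (epsilon <= 0 || epsilon >= emax)
    stop(sprintf("'epsilon' must be in (0, %s) for the %s bound",
                 if (case == "overstate") "1/3" else "1", case),
         call. = FALSE)
  if (eta < 1) stop("'eta' must be >= 1", call. = FALSE)
  invisible(TRUE)
}

#' Minimum subset size for guaranteed overstatement
#'
#' Lower bound on the number of picked studies `s` such that, when
#' additionally \eqn{s/k \le \epsilon}, a meta-analyst picking the top-S
#' smallest per-study p-values from `k` null studies
#' (\eqn{\theta = 0}) attains \eqn{p_{meta}(D_S) \le \alpha} with
#' probability at least \eqn{1-\delta}. The bound is the larger of a
#' weight-ratio/quantile term and a concentration term:
#' \deqn{\max\left\{\frac{\eta\,\Phi^{-1}(\alpha)}{\Phi^{-1}(1/2-\epsilon^2/2)},\;
#'   \frac{\epsilon\log(1/\delta)}{2}\Big(\frac{1}{2}-\frac{3\epsilon^2}{2}\Big)^{-2}\right\}.}
#' It is nondecreasing in \eqn{\eta} and diverges as \eqn{\epsilon \to 0^+}
#' (the quantile in the first term tends to 0 from below).
#'
#' @param alpha Significance level, in (0, 1/2).
#' @param delta Failure probability budget, in (0, 1).
#' @param epsilon Picking-fraction bound \eqn{s/k \le \epsilon}, in (0, 1/3).
#' @param eta Weight ratio \eqn{w_{max}/w_{min} \ge 1}; see [weight_ratio()].
#' @return Real-valued lower bound on `s` (use `ceiling()` for the integer
#'   gate).
#' @export
min_studies_overstate <- function(alpha, delta, epsilon, eta = 1) {
  .check_bound_inputs(alpha, delta, epsilon, eta, "overstate")
  term_quant <- eta * stats::qnorm(alpha) / stats::qnorm(0.5 - epsilon^2 / 2)
  term_conc <- (epsilon * log(1 / delta) / 2) *
    (0.5 - 1.5 * epsilon^2)^(-2)
  max(term_quant, term_conc)
}

#' Subset-size window for guaranteed understatement
#'
#' Two-sided condition on the number of picked studies `s` such that, when
#' additionally \eqn{1-\epsilon \le s/k \le 1}, a meta-analyst picking the
#' top-S largest per-study p-values from `k` studies with a real effect
#' (\eqn{\theta > 0}) attains \eqn{p_{meta}(D_S) \ge \alpha} with
#' probability at least \eqn{\delta} (note the asymmetry: at least
#' \eqn{\delta}, not \eqn{1-\delta} — the guarantee is a chance, not a near
#' certainty):
#' \deqn{\frac{\eta\,\Phi^{-1}(\alpha)}{\Phi^{-1}(1-\epsilon^2/2)} \le s <
#'   \frac{(1-\epsilon)\log(1/\delta)}{2(1-\epsilon/2)^2} - 2.}
#' The window may be empty (`s_low >= s_high`), which is reported rather
#' than raised: as \eqn{\delta \to 1^-} the upper expression tends to the
#' negative constant \eqn{-2}. The lower expression is nonpositive for
#' \eqn{\alpha < 1/2} and moves away from zero as \eqn{\eta} grows.
#'
#' @inheritParams min_studies_overstate
#' @param epsilon Dropped-fraction bound, in (0, 1).
#' @return Named numeric vector `c(s_low, s_high)`.
#' @export
studies_range_understate <- function(alpha, delta, epsilon, eta = 1) {
  .check_bound_inputs(alpha, delta, epsilon, eta, "understate")
  s_low <- eta * stats::qnorm(alpha) / stats::qnorm(1 - epsilon^2 / 2)
  s_high <- (1 - epsilon) * log(1 / delta) / (2 * (1 - epsilon / 2)^2) - 2
  c(s_low = s_low, s_high = s_high)
}

#' Is a meta-analysis cherry-pickable under the stated guarantees?
#'
#' Evaluates the overstatement or understatement vulnerability condition for
#' a concrete subset size `s` out of `k` studies. Overstate is satisfied
#' when \eqn{s/k \le \epsilon} and \eqn{s \ge} [min_studies_overstate()];
#' understate when \eqn{1-\epsilon \le s/k \le 1} and `s` lies in
#' [studies_range_understate()] (integer gate:
#' \eqn{\lceil s_{low}\rceil \le s < s_{high}}). When satisfied, readers of a
#' meta-analysis with these characteristics can flag the possibility of
#' cherry-picking.
#'
#' @inheritParams min_studies_overstate
#' @param s Number of picked studies.
#' @param k Total number of available studies, `s <= k`.
#' @param case `"overstate"` (force significance of a null effect, with
#'   probability at least `1 - delta`) or `"understate"` (mask a real
#'   effect, with probability at least `delta`).
#' @param epsilon Picking-fraction parameter; in (0, 1/3) for overstate,
#'   (0, 1) for understate.
#' @return Object of class `"cherry_bound"`: list echoing all inputs plus
#'   `satisfied`, `ratio_ok`, `s_min` (overstate) or `s_low`/`s_high`
#'   (understate), `guarantee_prob` and `notes`.
#' @examples
#' pickable(s = 132, k = 1320, case = "overstate",
#'          alpha = 0.05, delta = 0.1, epsilon = 0.1, eta = 1)
#' @export
pickable <- function(s, k, case = c("overstate", "understate"),
                     alpha = 0.05, delta = 0.1, epsilon = 0.1, eta = 1) {
  case <- match.arg(case)
  if (s < 1 || s != round(s) || k < 1 || k != round(k) || s > k)
    stop("need integers 1 <= s <= k", call. = FALSE)
  inputs <- list(alpha = alpha, delta = delta, epsilon = epsilon, eta = eta)
  if (case == "overstate") {
    s_min <- min_studies_overstate(alpha, delta, epsilon, eta)
    ratio_ok <- s / k <= epsilon
    satisfied <- ratio_ok && s >= ceiling(s_min)
    out <- list(case = case, s = s, k = k, inputs = inputs,
                ratio_ok = ratio_ok, satisfied = satisfied, s_min = s_min,
                guarantee_prob = 1 - delta,
                notes = paste0("satisfied iff s/k <= epsilon and s >= ",
                               "ceiling(s_min); guarantee: forced ",
                               "significance with probability >= 1-delta"))
  } else {
    rng <- studies_range_understate(alpha, delta, epsilon, eta)
    ratio_ok <- s / k >= 1 - epsilon && s <= k
    satisfied <- ratio_ok && s >= ceiling(rng[["s_low"]]) &&
      s < rng[["s_high"]]
    out <- list(case = case, s = s, k = k, inputs = inputs,
                ratio_ok = ratio_ok, satisfied = satisfied,
                s_low = rng[["s_low"]], s_high = rng[["s_high"]],
                guarantee_prob = delta,
                notes = paste0("satisfied iff 1-epsilon <= s/k <= 1 and ",
                               "ceiling(s_low) <= s < s_high; the window ",
                               "may be empty; guarantee: forced ",
                               "non-significance with probability >= delta ",
                               "(note: delta, not 1-delta)"))
  }
  class(out) <- "cherry_bound"
  out
}

#' @export
print.cherry_bound <- function(x, digits = 4, ...) {
  cat(sprintf("Cherry-pickability (%s): s = %d of k = %d\n", x$case, x$s,
              x$k))
  with(x$inputs, cat(sprintf(
    "  alpha = %g, delta = %g, epsilon = %g, eta = %.*g\n",
    alpha, delta, epsilon, digits, eta)))
  if (x$case == "overstate") {
    cat(sprintf("  required: s/k <= %g (%s) and s >= %.*g (%s)\n",
                x$inputs$epsilon, if (x$ratio_ok) "yes" else "NO",
                digits, x$s_min,
                if (x$s >= ceiling(x$s_min)) "yes" else "NO"))
  } else {
    cat(sprintf("  required: s/k >= %g (%s) and s in [%.*g, %.*g) (%s)\n",
                1 - x$inputs$epsilon, if (x$ratio_ok) "yes" else "NO",
                digits, x$s_low, digits, x$s_high,
                if (x$satisfied || x$ratio_ok &&
                    x$s >= ceiling(x$s_low) && x$s < x$s_high)
                  "yes" else "NO"))
  }
  cat(sprintf("  satisfied: %s (guarantee probability >= %g)\n",
              if (x$satisfied) "YES" else "no", x$guarantee_prob))
  invisible(x)
}

#' Monte Carlo check of a cherry-pickability guarantee
#'
#' Simulates `reps` ensembles of `k` studies, applies the greedy top-S
#' selection in the stated direction, and returns the frequency with which
#' the significance target is achieved (\eqn{p_{meta}(D_S) \le \alpha} for
#' overstate, \eqn{\ge \alpha} for understate). For a configuration flagged
#' satisfied by [pickable()], the overstate frequency should be at least
#' \eqn{1-\delta} and the understate frequency at least \eqn{\delta}, up to
#' binomial noise.
#'
#' @inheritParams pickable
#' @param theta True effect used in simulation (0 for overstate, > 0 for
#'   understate).
#' @param tau2 True between-study variance (analysis uses the fixed-effect
#'   model when 0).
#' @param reps Number of simulated ensembles (at least 100).
#' @param seed Seed; results are deterministic given `seed`.
#' @param variance Optional vector of known within-study variances, recycled
#'   to length `k` (for example equal variances give \eqn{\eta = 1}
#'   exactly). Default: draws from [rvariance_trunc()] per ensemble.
#' @param model,tau2_policy Analysis model for selection and pooling, as in
#'   [cherry_pick()].
#' @return Achieved frequency in \[0, 1\].
#' @export
guarantee_frequency <- function(case = c("overstate", "understate"), s, k,
                                alpha = 0.05, theta = 0, tau2 = 0,
                                reps = 1000, seed = 1L, variance = NULL,
                                model = c("fixed", "random"),
                                tau2_policy = c("full_set", "subset")) {
  case <- match.arg(case)
  model <- match.arg(model)
  tau2_policy <- match.arg(tau2_policy)
  if (reps < 100) stop("'reps' must be at least 100", call. = FALSE)
  if (s < 1 || s > k) stop("need 1 <= s <= k", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fixed_v <- !is.null(variance)
  if (fixed_v) v <- rep_len(variance, k)
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    if (!fixed_v) v <- rvariance_trunc(k)
    y <- stats::rnorm(k, mean = theta, sd = sqrt(v + tau2))
    ev <- .pick_eval(y, v, s, case, model, tau2_policy)
    hits[r] <- if (case == "overstate") ev$p_sel <= alpha
               else ev$p_sel >= alpha
  }
  mean(hits)
}
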