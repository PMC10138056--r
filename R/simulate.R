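#' Sample within-study variances from the truncated chi-square model
#'
#' Draws i.i.d. within-study variances \eqn{\sigma_i^2 \sim 0.25\,\chi^2_1}
#' conditioned on the interval (0.009, 0.600), by exact rejection sampling
#' (never by clamping, which would pile mass on the boundaries). The
#' truncated distribution has mean about 0.17, a realistic typical
#' within-study variance for log odds-ratio trials.
#'
#' @param n Number of draws.
#' @return Numeric vector of `n` values strictly inside (0.009, 0.600).
#' @examples
#' set.seed(1)
#' mean(rvariance_trunc(1e4))
#' @export
rvariance_trunc <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) / 0.7) + 8L
    x <- 0.25 * stats::rchisq(m, df = 1)
    out <- c(out, x[x > 0.009 & x < 0.600])
  }
  out[seq_len(n)]
}

#' Simulate a study ensemble
#'
#' Generates `k` independent studies with
#' \eqn{\sigma_i^2} drawn from [rvariance_trunc()] and
#' \eqn{y_i \mid \sigma_i \sim N(\theta, \sigma_i^2 + \tau^2)}. Each study
#' records \eqn{\sigma_i^2} (not \eqn{\sigma_i^2+\tau^2}) as its reported
#' within-study variance, as a real trial would.
#'
#' @param k Number of studies.
#' @param theta True treatment effect.
#' @param tau2 True between-study variance.
#' @return A [studies] object with labels `s1 ... sk`.
#' @export
simulate_studies <- function(k, theta = 0, tau2 = 0) {
  if (tau2 < 0) stop("'tau2' must be nonnegative", call. = FALSE)
  v <- rvariance_trunc(k)
  y <- stats::rnorm(k, mean = theta, sd = sqrt(v + tau2))
  studies(paste0("s", seq_len(k)), y, variance = v)
}

#' Define a cherry-picking simulation scenario
#'
#' One cell of the Monte Carlo grid: `s` studies are cherry-picked out of
#' `k = round(s / ratio)` (rounded to nearest, ties up), with true effect
#' `theta` and between-study variance `tau2`. `theta = 0` is the
#' overstatement case (type-I error: forcing significance out of a null
#' effect); `theta > 0` is the understatement case (type-II error: masking a
#' real effect).
#'
#' @param s Number of cherry-picked studies.
#' @param ratio Proportion `s / k` of picked studies, in (0, 1].
#' @param theta True effect (nonnegative; 0 = overstate, > 0 = understate).
#' @param tau2 True between-study variance.
#' @param alpha Significance level.
#' @param model `"fixed"` or `"random"`; default is fixed when `tau2 = 0`
#'   and random otherwise.
#' @param tau2_policy Passed to the selection rule under the random model;
#'   see [cherry_pick()].
#' @param reps Monte Carlo replicates.
#' @param seed Base seed for this scenario.
#' @param conditional For `theta > 0` only: count a false conclusion only
#'   when the full-set analysis was itself significant (default `FALSE`:
#'   unconditional counting of nonsignificant selections).
#' @return A list of class `"cherry_scenario"`.
#' @seealso [run_scenario()], [run_grid()], [default_scenarios()]
#' @export
scenario <- function(s, ratio, theta = 0, tau2 = 0, alpha = 0.05,
                     model = NULL, tau2_policy = c("full_set", "subset"),
                     reps = 200, seed = 1L, conditional = FALSE) {
  if (s < 1 || s != round(s)) stop("'s' must be a positive integer",
                                   call. = FALSE)
  if (ratio <= 0 || ratio > 1) stop("'ratio' must be in (0, 1]",
                                    call. = FALSE)
  if (theta < 0) stop("'theta' must be nonnegative", call. = FALSE)
  if (tau2 < 0) stop("'tau2' must be nonnegative", call. = FALSE)
  if (reps < 1) stop("'reps' must be a positive integer", call. = FALSE)
  if (is.null(model)) model <- if (tau2 > 0) "random" else "fixed"
  model <- match.arg(model, c("fixed", "random"))
  k <- floor(s / ratio + 0.5)  # nearest integer, ties rounded up
  if (k < s) k <- s
  structure(list(s = as.integer(s), k = as.integer(k), ratio = ratio,
                 theta = theta, tau2 = tau2, alpha = alpha, model = model,
                 tau2_policy = match.arg(tau2_policy),
                 reps = as.integer(reps), seed = as.integer(seed),
                 conditional = isTRUE(conditional),
                 case = if (theta == 0) "overstate" else "understate"),
            class = "cherry_scenario")
}

# deterministic per-scenario substream seed: a polynomial hash of the
# scenario parameters folded with the master seed, so results do not depend
# on the position of a scenario within a grid
.scenario_seed <- function(sc, master) {
  key <- paste(sc$case, sc$theta, sc$tau2, sc$s, sc$ratio, sc$model,
               sc$tau2_policy, sc$alpha, sc$reps, sep = "|")
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Run one simulation scenario
#'
#' For each replicate, simulates `k` studies via [simulate_studies()],
#' applies the greedy top-S selection of [cherry_pick()] in the scenario's
#' direction, and records a false conclusion when the selected subset's
#' pooled one-sided p crosses `alpha` the wrong way: \eqn{p \le \alpha}
#' under `theta = 0`, \eqn{p > \alpha} under `theta > 0`.
#'
#' @param sc A [scenario()] object.
#' @param seed Overrides the scenario's seed when supplied.
#' @return One-row data frame with columns `case`, `theta`, `tau2`, `s`,
#'   `k`, `ratio`, `model`, `reps`, `prop_false`, `mc_se` (binomial standard
#'   error \eqn{\sqrt{p(1-p)/reps}}) and `seed`.
#' @export
run_scenario <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "cherry_scenario"))
  if (is.null(seed)) seed <- sc$seed
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- sc$reps
  k <- sc$k
  vmat <- matrix(rvariance_trunc(reps * k), nrow = reps)
  ymat <- matrix(stats::rnorm(reps * k, mean = sc$theta,
                              sd = sqrt(vmat + sc$tau2)), nrow = reps)
  hits <- logical(reps)
  for (r in seq_len(reps)) {
    ev <- .pick_eval(ymat[r, ], vmat[r, ], sc$s, sc$case, sc$model,
                     sc$tau2_policy)
    hits[r] <- if (sc$case == "overstate") {
      ev$p_sel <= sc$alpha
    } else if (sc$conditional) {
      ev$p_sel > sc$alpha && ev$p_full <= sc$alpha
    } else {
      ev$p_sel > sc$alpha
    }
  }
  p <- mean(hits)
  data.frame(case = sc$case, theta = sc$theta, tau2 = sc$tau2, s = sc$s,
             k = k, ratio = sc$ratio, model = sc$model, reps = reps,
             prop_false = p, mc_se = sqrt(p * (1 - p) / reps),
             seed = seed, stringsAsFactors = FALSE)
}

#' Run a grid of scenarios
#'
#' Runs [run_scenario()] for every scenario, seeding each from an
#' independent substream derived from `seed` and the scenario's own
#' parameters, so that results are reproducible and unchanged under
#' permutation of the grid.
#'
#' @param scenarios List of [scenario()] objects.
#' @param seed Master seed.
#' @return Tidy data frame, one row per scenario (see [run_scenario()]).
#' @export
run_grid <- function(scenarios, seed = 1L) {
  if (inherits(scenarios, "cherry_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) == 0L) stop("no scenarios supplied", call. = FALSE)
  out <- lapply(scenarios, function(sc)
    run_scenario(sc, seed = .scenario_seed(sc, seed)))
  do.call(rbind, out)
}

#' The default simulation grid
#'
#' The full factorial grid of the cherry-picking study:
#' `s = 2:30`, `ratio` in {1/3, 1/5, 1/10}, `theta` in {0, 0.5, 1.0} and
#' `tau2` in {0, 0.01, 0.10, 0.50, 0.70} (fixed-effect model at
#' \eqn{\tau^2=0}, random-effects otherwise), at `alpha = 0.05`.
#'
#' @param reps Replicates per cell (200 by default, giving a Monte Carlo CI
#'   of about ±0.03 at p = 0.5; 1000 reproduces the full-precision study).
#' @param s,ratio,theta,tau2 Grid values, overridable to subset the grid.
#' @return List of [scenario()] objects.
#' @export
default_scenarios <- function(reps = 200, s = 2:30,
                              ratio = c(1 / 3, 1 / 5, 1 / 10),
                              theta = c(0, 0.5, 1.0),
                              tau2 = c(0, 0.01, 0.10, 0.50, 0.70)) {
  g <- expand.grid(s = s, ratio = ratio, theta = theta, tau2 = tau2,
                   KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i)
    scenario(s = g$s[i], ratio = g$ratio[i], theta = g$theta[i],
             tau2 = g$tau2[i], reps = reps))
}

#' Line plot of false-conclusion proportions
#'
#' Base-graphics companion to [run_grid()]: proportion of false conclusions
#' against the number of picked studies, one line per `ratio`.
#'
#' @param results Data frame from [run_grid()] (a single `theta`/`tau2`
#'   combination is plotted; filter first if needed).
#' @param ... Passed to [graphics::matplot()].
#' @return `results`, invisibly.
#' @export
plot_false_conclusions <- function(results, ...) {
  stopifnot(all(c("s", "ratio", "prop_false") %in% names(results)))
  ratios <- sort(unique(results$ratio), decreasing = TRUE)
  svals <- sort(unique(results$s))
  m <- sapply(ratios, function(r) {
    sub <- results[results$ratio == r, ]
    sub$prop_false[match(svals, sub$s)]
  })
  graphics::matplot(svals, m, type = "b", pch = 19, lty = 1,
                    xlab = "number of picked studies S",
                    ylab = "proportion of false conclusions",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", bty = "n", col = seq_along(ratios), lty = 1,
                   pch = 19, legend = sprintf("S/K = %.3g", ratios))
  invisible(results)
}
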