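# Internal selection/evaluation kernel. Shared verbatim by cherry_pick(),
# run_scenario() and guarantee_frequency() so the Monte Carlo machinery
# measures exactly the public selection rule.

# stable greedy top-s indices by per-study one-sided p
# overstate: s smallest p (largest sqrt(w)*y); understate: s largest p
.greedy_idx <- function(y, w, s, direction) {
  z <- sqrt(w) * y
  key <- if (direction == "overstate") -z else z
  utils::head(order(key, seq_along(key)), s)
}

# full-set + selected-subset pooled p under a tau2 policy; tau2_full is the
# DL estimate on all studies (0 under the fixed model)
.pick_eval <- function(y, v, s, direction, model, tau2_policy) {
  tau2_full <- if (model == "random") .dl_tau2(y, v) else 0
  w_full <- 1 / (v + tau2_full)
  idx <- .greedy_idx(y, w_full, s, direction)
  if (model == "random" && tau2_policy == "subset") {
    tau2_sel <- .dl_tau2(y[idx], v[idx])
  } else {
    tau2_sel <- tau2_full
  }
  w_sel <- 1 / (v[idx] + tau2_sel)
  list(idx = idx,
       p_full = stats::pnorm(-.pool_z(y, w_full)),
       p_sel = stats::pnorm(-.pool_z(y[idx], w_sel)),
       tau2_full = tau2_full, tau2_sel = tau2_sel)
}

# exhaustive enumeration of all size-s subsets (vectorised); returns the
# subset minimising (overstate) / maximising (understate) the pooled p,
# ties broken by lexicographic order of the sorted label vector
.exhaustive_eval <- function(y, v, labels, s, direction, model, tau2_policy) {
  k <- length(y)
  tau2_full <- if (model == "random") .dl_tau2(y, v) else 0
  m <- utils::combn(k, s)
  ym <- matrix(y[m], nrow = s)
  vm <- matrix(v[m], nrow = s)
  if (model == "random" && tau2_policy == "subset") {
    w0 <- 1 / vm
    sw0 <- colSums(w0)
    yb <- colSums(w0 * ym) / sw0
    q <- colSums(w0 * ym^2) - sw0 * yb^2
    den <- sw0 - colSums(w0^2) / sw0
    t2 <- if (s < 2L) rep(0, ncol(m)) else pmax(0, (q - (s - 1)) / den)
    wm <- 1 / (vm + rep(t2, each = s))
  } else {
    t2 <- rep(tau2_full, ncol(m))
    wm <- 1 / (vm + tau2_full)
  }
  z <- colSums(wm * ym) / sqrt(colSums(wm))
  p <- stats::pnorm(-z)
  best <- if (direction == "overstate") p == min(p) else p == max(p)
  cand <- which(best)
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(j)
      paste(sort(labels[m[, j]]), collapse = "\r"), character(1))
    cand <- cand[order(keys)][1L]
  }
  j <- cand[1L]
  list(idx = sort(m[, j]),
       p_full = stats::pnorm(-.pool_z(y, 1 / (v + tau2_full))),
       p_sel = p[j], tau2_full = tau2_full, tau2_sel = t2[j])
}

#' Cherry-pick a subset of studies toward a desired conclusion
#'
#' Selects `s` of the `k` available studies so as to push the pooled
#' one-sided p-value across the significance level `alpha`:
#' `direction = "overstate"` seeks \eqn{p_{meta}(D_S) \le \alpha} (making a
#' null treatment look effective), `direction = "understate"` seeks
#' \eqn{p_{meta}(D_S) \ge \alpha} (masking a real effect).
#'
#' The default `"greedy"` method keeps the studies with the top-S smallest
#' (overstate) or largest (understate) per-study one-sided p-values
#' \eqn{\Phi(-\sqrt{w_i} y_i)}, ties broken by input order. The
#' `"exhaustive"` method enumerates every size-`s` subset and returns the one
#' with the extreme pooled p — an optimality oracle for the greedy rule, ties
#' broken by lexicographic label order.
#'
#' Under `model = "random"` the between-study variance enters via
#' `tau2_policy`: `"full_set"` (default) estimates \eqn{\tau^2} once on all
#' `k` studies by DerSimonian-Laird and holds it fixed, so that subset
#' weights stay comparable; `"subset"` re-estimates \eqn{\tau^2} on the
#' selected subset (for greedy ranking, which precedes selection, the
#' full-set estimate is still used as the only one available).
#'
#' @inheritParams meta_fit
#' @param s Number of studies to keep, `1 <= s <= k`.
#' @param direction `"overstate"` or `"understate"`.
#' @param tau2_policy `"full_set"` or `"subset"`.
#' @param method `"greedy"` (the top-S rule) or `"exhaustive"`.
#' @param budget Maximum number of subsets the exhaustive method will
#'   enumerate; `choose(k, s)` above this is refused.
#' @return An object of class `"cherry_pick"`: list with `selected` (labels,
#'   in input order), `s`, `direction`, `method`, `tau2_policy`, `p_selected`
#'   and `p_full` (pooled one-sided p-values), `flipped` (did significance at
#'   `alpha` change), `alpha`, `fit_full` and `fit_selected` ([meta_fit]
#'   objects).
#' @examples
#' x <- studies(letters[1:4], effect = c(-1, 0, 1, 2), variance = rep(1, 4))
#' cherry_pick(x, s = 2, direction = "overstate")
#' @export
cherry_pick <- function(x, s, direction = c("overstate", "understate"),
                        model = c("fixed", "random"), alpha = 0.05,
                        tau2_policy = c("full_set", "subset"),
                        method = c("greedy", "exhaustive"), budget = 2e5) {
  direction <- match.arg(direction)
  model <- match.arg(model)
  tau2_policy <- match.arg(tau2_policy)
  method <- match.arg(method)
  x <- as_studies(x)
  k <- nrow(x)
  if (!is.numeric(s) || length(s) != 1L || s < 1 || s != round(s))
    stop("'s' must be a positive integer", call. = FALSE)
  if (s > k)
    stop("'s' (", s, ") exceeds the number of studies (", k, ")",
         call. = FALSE)
  if (method == "exhaustive" && choose(k, s) > budget)
    stop("exhaustive enumeration refused: choose(", k, ", ", s, ") = ",
         format(choose(k, s), big.mark = ","), " subsets exceeds budget ",
         budget, call. = FALSE)
  ev <- if (method == "greedy") {
    .pick_eval(x$effect, x$variance, s, direction, model, tau2_policy)
  } else {
    .exhaustive_eval(x$effect, x$variance, x$label, s, direction, model,
                     tau2_policy)
  }
  idx <- sort(ev$idx)
  tau2_arg <- if (model == "random") ev$tau2_sel else NULL
  fit_full <- meta_fit(x, model = model, alpha = alpha,
                       tau2 = if (model == "random") ev$tau2_full else NULL)
  fit_sel <- meta_fit(x[idx, , drop = FALSE], model = model, alpha = alpha,
                      tau2 = tau2_arg)
  out <- list(selected = x$label[idx], s = as.integer(s), k = k,
              direction = direction, method = method,
              tau2_policy = tau2_policy, alpha = alpha,
              p_selected = ev$p_sel, p_full = ev$p_full,
              flipped = (ev$p_sel <= alpha) != (ev$p_full <= alpha),
              fit_full = fit_full, fit_selected = fit_sel)
  class(out) <- "cherry_pick"
  out
}

#' Can cherry-picking flip this meta-analysis?
#'
#' Decision wrapper around [cherry_pick()]: `TRUE` when the selected size-`s`
#' subset achieves the direction's significance target while the full set
#' does not (overstate: \eqn{p_{sel} \le \alpha < p_{full}}; understate:
#' \eqn{p_{sel} \ge \alpha \ge p_{full}}).
#'
#' @inheritParams cherry_pick
#' @param exhaustive Use the exhaustive optimality oracle instead of the
#'   greedy top-S rule.
#' @return List with elements `flip` (logical) and `result` (the
#'   [cherry_pick] object).
#' @export
can_flip <- function(x, s, alpha = 0.05,
                     direction = c("overstate", "understate"),
                     model = c("fixed", "random"),
                     tau2_policy = c("full_set", "subset"),
                     exhaustive = FALSE, budget = 2e5) {
  direction <- match.arg(direction)
  res <- cherry_pick(x, s, direction = direction, model = match.arg(model),
                     alpha = alpha, tau2_policy = match.arg(tau2_policy),
                     method = if (exhaustive) "exhaustive" else "greedy",
                     budget = budget)
  flip <- if (direction == "overstate") {
    res$p_selected <= alpha && res$p_full > alpha
  } else {
    res$p_selected >= alpha && res$p_full <= alpha
  }
  list(flip = flip, result = res)
}

#' @export
print.cherry_pick <- function(x, digits = 4, ...) {
  cat(sprintf("Cherry-picked %d of %d studies (%s, %s, tau2 policy: %s)\n",
              x$s, x$k, x$direction, x$method, x$tau2_policy))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  pooled one-sided p, full set: %.*g%s\n", digits, x$p_full,
              if (x$p_full <= x$alpha) "  (significant)" else ""))
  cat(sprintf("  pooled one-sided p, selection: %.*g%s\n", digits,
              x$p_selected,
              if (x$p_selected <= x$alpha) "  (significant)" else ""))
  cat(sprintf("  conclusion at alpha = %g flipped: %s\n", x$alpha,
              if (x$flipped) "YES" else "no"))
  invisible(x)
}
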