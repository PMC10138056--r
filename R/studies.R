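#' Construct a set of studies for meta-analysis
#'
#' A study set holds, for each trial, its reported effect estimate on the
#' pooling scale (for example a log odds ratio) and its within-study variance,
#' which is treated as known throughout the package. Exactly one of
#' `variance` or `se` must be supplied; a standard error is squared on entry.
#'
#' @param label Character vector of unique, nonempty study identifiers.
#' @param effect Numeric vector of effect estimates on the pooling scale.
#' @param variance Numeric vector of within-study variances (strictly
#'   positive), in squared effect units.
#' @param se Numeric vector of within-study standard errors; an alternative
#'   to `variance`.
#' @return A `data.frame` of class `"studies"` with columns `label`, `effect`
#'   and `variance`, in input order. Input order is significant: it is the
#'   documented tie-break for study selection.
#' @examples
#' studies(c("A", "B"), effect = c(0.2, 0.4), variance = c(1, 1))
#' @seealso [read_study_csv()], [studies_from_2x2()], [meta_fit()]
#' @export
studies <- function(label, effect, variance = NULL, se = NULL) {
  if (is.null(variance) == is.null(se))
    stop("supply exactly one of 'variance' or 'se'", call. = FALSE)
  if (!is.null(se)) variance <- se^2
  label <- as.character(label)
  x <- data.frame(label = label, effect = as.numeric(effect),
                  variance = as.numeric(variance),
                  stringsAsFactors = FALSE)
  validate_studies(x)
}

#' @rdname studies
#' @param x Object to convert or validate.
#' @export
as_studies <- function(x) {
  if (inherits(x, "studies")) return(x)
  if (!is.data.frame(x))
    stop("cannot interpret object of class '", class(x)[1L],
         "' as a study set", call. = FALSE)
  nm <- names(x)
  if (!("label" %in% nm)) x$label <- paste0("study_", seq_len(nrow(x)))
  if (!("variance" %in% nm) && "se" %in% nm) x$variance <- x$se^2
  if (!all(c("effect", "variance") %in% names(x)))
    stop("need columns 'effect' and one of 'variance'/'se'", call. = FALSE)
  validate_studies(x[, c("label", "effect", "variance")])
}

validate_studies <- function(x) {
  if (nrow(x) < 1L) stop("study set is empty", call. = FALSE)
  if (anyNA(x$label) || any(!nzchar(x$label)))
    stop("study labels must be nonempty", call. = FALSE)
  if (anyDuplicated(x$label)) {
    dup <- unique(x$label[duplicated(x$label)])
    stop("duplicate study label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(x$effect)))
    stop("non-finite effect for study: ",
         paste(x$label[!is.finite(x$effect)], collapse = ", "), call. = FALSE)
  bad <- !is.finite(x$variance) | x$variance <= 0
  if (any(bad))
    stop("within-study variance must be positive and finite; offending ",
         "study: ", paste(x$label[bad], collapse = ", "), call. = FALSE)
  rownames(x) <- NULL
  class(x) <- c("studies", "data.frame")
  x
}

#' Read a study table from CSV
#'
#' The file must be comma-separated with a header containing `label`,
#' `effect` and exactly one of `se` or `variance`. Malformed rows are
#' rejected with their line number (header = line 1).
#'
#' @param path Path to a CSV file.
#' @return A [studies] object in file order.
#' @export
read_study_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(x)
  has_se <- "se" %in% nm
  has_var <- "variance" %in% nm
  if (has_se == has_var)
    stop("CSV header must contain exactly one of 'se' or 'variance'",
         call. = FALSE)
  if (!all(c("label", "effect") %in% nm))
    stop("CSV header must contain 'label' and 'effect'", call. = FALSE)
  line <- seq_len(nrow(x)) + 1L
  val <- if (has_se) x$se else x$variance
  bad <- !is.finite(x$effect) | !is.finite(val) | val <= 0
  if (any(bad))
    stop("malformed study row(s) at line(s): ",
         paste(line[bad], collapse = ", "),
         " (effect and se/variance must be finite, se/variance > 0)",
         call. = FALSE)
  if (has_se) studies(x$label, x$effect, se = x$se)
  else studies(x$label, x$effect, variance = x$variance)
}

#' Write a study table to CSV
#'
#' Inverse of [read_study_csv()]: writes columns `label`, `effect`,
#' `variance` so that a read/write/read round-trip reproduces the study set
#' exactly.
#'
#' @param x A [studies] object (or coercible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(x, path) {
  x <- as_studies(x)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert 2x2 contingency tables to log odds-ratio studies
#'
#' Each record gives event counts and totals for a treatment and a control
#' arm. The effect is the log odds ratio
#' \eqn{\log(ad/(bc))} with \eqn{a} = treatment events, \eqn{b} = treatment
#' non-events, \eqn{c} = control events, \eqn{d} = control non-events, and
#' variance \eqn{1/a + 1/b + 1/c + 1/d}. If any cell of a table is zero, 0.5
#' is added to all four cells of that table before computing (Gart
#' continuity correction).
#'
#' With `orientation = "benefit_positive"` the log odds ratio is negated, so
#' that a protective treatment (fewer events, e.g. deaths, under treatment)
#' maps to a positive pooled effect and the one-sided alternative
#' "treatment is beneficial" is a right-tailed test.
#'
#' @param x Data frame with columns `label`, `events_trt`, `total_trt`,
#'   `events_ctl`, `total_ctl`.
#' @param orientation `"as_given"` (log OR of events under treatment vs
#'   control) or `"benefit_positive"` (negated).
#' @return A [studies] object on the log odds-ratio scale.
#' @examples
#' tab <- data.frame(label = "X", events_trt = 10, total_trt = 20,
#'                   events_ctl = 5, total_ctl = 25)
#' studies_from_2x2(tab)
#' @export
studies_from_2x2 <- function(x, orientation = c("as_given", "benefit_positive")) {
  orientation <- match.arg(orientation)
  need <- c("label", "events_trt", "total_trt", "events_ctl", "total_ctl")
  if (!all(need %in% names(x)))
    stop("2x2 table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(x$total_trt <= 0 | x$total_ctl <= 0))
    stop("arm totals must be positive", call. = FALSE)
  if (any(x$events_trt < 0 | x$events_ctl < 0 |
          x$events_trt > x$total_trt | x$events_ctl > x$total_ctl))
    stop("event counts must lie in [0, total]", call. = FALSE)
  a <- x$events_trt
  b <- x$total_trt - x$events_trt
  c_ <- x$events_ctl
  d <- x$total_ctl - x$events_ctl
  zero <- a == 0 | b == 0 | c_ == 0 | d == 0
  a[zero] <- a[zero] + 0.5
  b[zero] <- b[zero] + 0.5
  c_[zero] <- c_[zero] + 0.5
  d[zero] <- d[zero] + 0.5
  eff <- log(a * d / (b * c_))
  v <- 1 / a + 1 / b + 1 / c_ + 1 / d
  if (orientation == "benefit_positive") eff <- -eff
  studies(x$label, eff, variance = v)
}

#' Read 2x2 contingency tables from CSV
#'
#' @param path CSV with header `label,events_trt,total_trt,events_ctl,total_ctl`.
#' @inheritParams studies_from_2x2
#' @return A [studies] object (see [studies_from_2x2()]).
#' @export
read_2x2_csv <- function(path, orientation = c("as_given", "benefit_positive")) {
  studies_from_2x2(utils::read.csv(path, stringsAsFactors = FALSE),
                   orientation = match.arg(orientation))
}

#' @export
print.studies <- function(x, ...) {
  cat("Study set:", nrow(x), "studies\n")
  print.data.frame(x, ...)
  invisible(x)
}
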