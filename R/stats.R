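# Arm-level summaries and hypothesis machinery for the Delta-lambda
# treatment-effect parameters, combination-vs-single-agent comparison, and
# ROC analysis linking volume changes to qualitative scores.

#' Arm-level summary of PID treatment effects
#'
#' Mean, sample SD and a two-sided one-sample test against 0 for each
#' `delta_lambda` column of a per-subject estimate table (see
#' [cohort_delta_pid()]), or for a bare numeric vector. The default test is
#' the one-sample t-test; `test = "permutation"` uses a sign-flip
#' permutation of the mean as a distribution-free alternative. A degenerate
#' sample (SD exactly 0) is flagged via `exactly_determined` and given
#' p = 0 for a nonzero mean, p = 1 otherwise.
#'
#' @param deltas Data frame with `delta_lambda1/2/3` columns (and optionally
#'   `arm`), or a numeric vector.
#' @param arm Optional arm label to filter on when `deltas` has an `arm`
#'   column.
#' @param test `"t"` or `"permutation"`.
#' @param n_perm Sign-flip draws for the permutation test.
#' @param seed Seed for the permutation test.
#' @return Data frame of class `arm_summary`: one row per parameter with
#'   `n`, `mean`, `sd`, `statistic`, `p_value`, `exactly_determined`.
#' @examples
#' summarize_arm(c(-1, 0, 1)) # mean 0, t 0, p 1
#' @export
summarize_arm <- function(deltas, arm = NULL, test = c("t", "permutation"),
                          n_perm = 2000L, seed = 1L) {
  test <- match.arg(test)
  if (is.numeric(deltas)) {
    cols <- list(delta = deltas)
  } else {
    if (!is.null(arm) && "arm" %in% names(deltas)) {
      deltas <- deltas[deltas$arm == arm, , drop = FALSE]
    }
    nm <- intersect(c("delta_lambda1", "delta_lambda2", "delta_lambda3"),
                    names(deltas))
    if (!length(nm)) stop("no delta_lambda columns found", call. = FALSE)
    cols <- as.list(deltas[, nm, drop = FALSE])
  }
  one <- function(x, label) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) {
      stop("arm summary needs n >= 2 (", label, " has ", n, ")",
           call. = FALSE)
    }
    m <- mean(x)
    s <- stats::sd(x)
    if (s == 0) {
      return(data.frame(parameter = label, n = n, mean = m, sd = s,
                        statistic = NA_real_,
                        p_value = if (m == 0) 1 else 0,
                        exactly_determined = TRUE))
    }
    if (test == "t") {
      stat <- m / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(stat), df = n - 1)
    } else {
      stat <- m
      p <- with_rng_seed(seed, {
        flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE),
                        nrow = n_perm)
        perm_means <- drop(flips %*% x) / n
        (1 + sum(abs(perm_means) >= abs(m))) / (n_perm + 1)
      })
    }
    data.frame(parameter = label, n = n, mean = m, sd = s, statistic = stat,
               p_value = p, exactly_determined = FALSE)
  }
  out <- do.call(rbind, Map(one, cols, names(cols)))
  rownames(out) <- NULL
  class(out) <- c("arm_summary", "data.frame")
  out
}

#' Probability of a lower (better) parameter under combination therapy
#'
#' All-pairs empirical estimate of `P(combination < single)`: the fraction
#' of (combination, single-agent) subject pairs in which the combination
#' value is lower, ties counted one half. This is the Mann-Whitney
#' probability of superiority.
#'
#' @param deltas_combination,deltas_single Numeric vectors of per-subject
#'   `delta_lambda` values.
#' @return Probability in `[0, 1]`.
#' @examples
#' prob_lower(c(0, 1.5), c(1, 2, 3)) # 5/6
#' @export
prob_lower <- function(deltas_combination, deltas_single) {
  a <- deltas_combination[!is.na(deltas_combination)]
  b <- deltas_single[!is.na(deltas_single)]
  if (!length(a) || !length(b)) {
    stop("prob_lower needs non-empty samples on both sides", call. = FALSE)
  }
  cmp <- outer(a, b, "<") + 0.5 * outer(a, b, "==")
  sum(cmp) / (length(a) * length(b))
}

#' Welch comparison of two arms
#'
#' Arm-vs-arm comparison of a `delta_lambda` parameter by Welch's t-test.
#' The working hypothesis for an effective therapy is that its parameter is
#' *lower* than the control's, so `alternative = "less"` is available as a
#' documented one-sided orientation; the default is two-sided.
#'
#' @param deltas_treated,deltas_control Numeric vectors.
#' @param alternative Passed to [stats::t.test()].
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_arms <- function(deltas_treated, deltas_control,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stats::t.test(deltas_treated, deltas_control, alternative = alternative)
}

#' ROC analysis of percent volume change against a binary outcome
#'
#' Sweeps every observed percent-change value as a cutoff for the rule
#' "positive when value >= cutoff", computes sensitivity and specificity at
#' each, the trapezoidal area under the ROC curve, and the cutoff
#' maximizing Youden's J (largest cutoff on ties). Cutoffs are taken at
#' observed values (not midpoints) so a deterministic threshold rule is
#' recovered exactly.
#'
#' @param labels Binary outcome per comparison (logical or 0/1; 1 = the
#'   condition to detect, e.g. progression).
#' @param percent_changes Percent volume change per comparison; larger
#'   values indicate the positive condition.
#' @return Object of class `roc_result`: data frame `curve` (`cutoff`,
#'   `sensitivity`, `specificity`), `auc`, `youden_cutoff`, `youden_j`.
#' @examples
#' roc_analysis(c(0, 0, 1, 1), c(-10, 5, 20, 40))
#' @export
roc_analysis <- function(labels, percent_changes) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(percent_changes))
  keep <- !is.na(labels) & !is.na(percent_changes)
  labels <- labels[keep]
  v <- percent_changes[keep]
  if (!any(labels) || all(labels)) {
    stop("ROC needs both classes present", call. = FALSE)
  }
  cutoffs <- sort(unique(v), decreasing = TRUE)
  sens <- vapply(cutoffs, function(c) mean(v[labels] >= c), numeric(1))
  spec <- vapply(cutoffs, function(c) mean(v[!labels] < c), numeric(1))
  # trapezoid over (FPR, TPR), anchored at (0,0) and (1,1)
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))[1L] # cutoffs descending: first = largest
  out <- list(
    curve = data.frame(cutoff = cutoffs, sensitivity = sens,
                       specificity = spec),
    auc = auc,
    youden_cutoff = cutoffs[best],
    youden_j = j[best]
  )
  class(out) <- "roc_result"
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d cutoffs: AUC = %.4f\n", nrow(x$curve), x$auc))
  cat(sprintf("  Youden cutoff %+.4g%% (J = %.3f, sens %.3f, spec %.3f)\n",
              x$youden_cutoff, x$youden_j,
              x$curve$sensitivity[x$curve$cutoff == x$youden_cutoff][1L],
              x$curve$specificity[x$curve$cutoff == x$youden_cutoff][1L]))
  invisible(x)
}
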