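# Diagnostic evaluation of the score against the hsPDA label: empirical
# ROC curves with midpoint thresholds, Youden-optimal cut-offs, exact
# binomial CIs, and DeLong (structural-component) AUC inference.

.delong_components <- function(cases, controls) {
  # psi(x, y) = 1 if x > y, 1/2 if tied, 0 otherwise
  ps <- outer(cases, controls, function(x, y) (x > y) + 0.5 * (x == y))
  list(v10 = rowMeans(ps), v01 = colMeans(ps), auc = mean(ps))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta-distribution quantiles; the lower
#' bound is exactly 0 when `successes = 0` and the upper exactly 1 when
#' `successes = trials`.
#'
#' @param successes Number of successes (0..trials).
#' @param trials Number of trials (> 0).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector `c(lower, upper)` on the proportion scale.
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (length(successes) != 1 || length(trials) != 1 ||
      !is.finite(successes) || !is.finite(trials) ||
      successes != round(successes) || trials != round(trials) ||
      successes < 0 || trials <= 0 || successes > trials) {
    .stop_invalid("need integer counts with 0 <= successes <= trials")
  }
  if (!is.finite(level) || level <= 0 || level >= 1) .stop_invalid("level must be in (0, 1)")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower, upper = upper)
}

.split_by_label <- function(scores, labels) {
  if (length(scores) != length(labels)) .stop_invalid("scores and labels differ in length")
  if (any(!is.finite(scores))) .stop_invalid("scores must be finite")
  labels <- as.logical(labels)
  if (any(is.na(labels))) .stop_invalid("labels must be TRUE/FALSE")
  cases <- scores[labels]
  controls <- scores[!labels]
  if (length(cases) == 0 || length(controls) == 0) {
    .stop_invalid("need at least one case and one control")
  }
  list(cases = cases, controls = controls)
}

#' Empirical ROC evaluation of a score against a binary label
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' observed scores, plus -Inf and +Inf sentinels; the classification rule
#' is "predict case if score > threshold". The AUC is the trapezoid area
#' under the empirical curve, which for this construction equals the
#' normalised Mann-Whitney statistic (ties counted 1/2). Per-threshold
#' sensitivity and specificity carry exact Clopper-Pearson CIs.
#'
#' @param scores Numeric score per subject.
#' @param labels Logical (or 0/1) case indicator per subject.
#' @param level Confidence level for the per-threshold CIs.
#' @param hour Optional assessment hour carried into the result.
#' @return Object of class `roc_eval`: thresholds, per-threshold
#'   sensitivity/specificity with CIs, `auc`, `optimal_cutoff` (Youden),
#'   `n_cases`, `n_controls`, and the group score vectors.
#' @export
empirical_roc <- function(scores, labels, level = 0.95, hour = NA) {
  g <- .split_by_label(scores, labels)
  uniq <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(uniq) > 1) (uniq[-1] + uniq[-length(uniq)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(g$cases > t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(g$controls <= t), numeric(1))
  m <- length(g$cases); n <- length(g$controls)
  sens_ci <- t(vapply(sens, function(s) clopper_pearson(round(s * m), m, level), numeric(2)))
  spec_ci <- t(vapply(spec, function(s) clopper_pearson(round(s * n), n, level), numeric(2)))
  # trapezoid over the empirical curve, swept from high to low threshold
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(sens)]) / 2)
  out <- structure(list(hour = hour, thresholds = thresholds,
                        sensitivity = sens, specificity = spec,
                        sens_ci = sens_ci, spec_ci = spec_ci,
                        auc = auc, n_cases = m, n_controls = n,
                        level = level, cases = g$cases, controls = g$controls),
                   class = "roc_eval")
  out$optimal_cutoff <- youden_optimal(out)
  out
}

#' @export
print.roc_eval <- function(x, ...) {
  cat(sprintf("Empirical ROC (%d cases, %d controls)%s\n", x$n_cases, x$n_controls,
              if (is.na(x$hour)) "" else sprintf(" at %s h", x$hour)))
  cat(sprintf("  AUC = %.3f; Youden-optimal cut-off: score > %s\n",
              x$auc, format(x$optimal_cutoff)))
  invisible(x)
}

#' Youden-optimal cut-off of an ROC evaluation
#'
#' Returns the candidate threshold maximising Youden's J
#' (sensitivity + specificity - 1); ties are broken toward the higher
#' threshold (higher specificity).
#'
#' @param roc An object from [empirical_roc()].
#' @return The optimal threshold (possibly `Inf` for degenerate input).
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "roc_eval"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  roc$thresholds[max(best)]
}

#' Sensitivity and specificity at a fixed cut-off, with exact CIs
#'
#' Applies the rule "score > cutoff predicts case" and reports both
#' proportions with exact Clopper-Pearson intervals.
#'
#' @param scores,labels As in [empirical_roc()].
#' @param cutoff Decision threshold.
#' @param level Confidence level.
#' @return Data frame with one row each for sensitivity and specificity:
#'   `measure`, `successes`, `trials`, `estimate`, `lower`, `upper`.
#' @export
sens_spec_at <- function(scores, labels, cutoff, level = 0.95) {
  g <- .split_by_label(scores, labels)
  tp <- sum(g$cases > cutoff)
  tn <- sum(g$controls <= cutoff)
  ci_se <- clopper_pearson(tp, length(g$cases), level)
  ci_sp <- clopper_pearson(tn, length(g$controls), level)
  data.frame(measure = c("sensitivity", "specificity"),
             successes = c(tp, tn),
             trials = c(length(g$cases), length(g$controls)),
             estimate = c(tp / length(g$cases), tn / length(g$controls)),
             lower = c(ci_se[1], ci_sp[1]),
             upper = c(ci_se[2], ci_sp[2]),
             stringsAsFactors = FALSE)
}

#' Significance of an AUC against the no-discrimination value 0.5
#'
#' Two-sided p-value from the asymptotic normal distribution of the AUC
#' with the DeLong structural-component variance estimate.
#'
#' @param roc An object from [empirical_roc()].
#' @return List with `auc`, `se`, `z` and `p_value`.
#' @export
auc_significance <- function(roc) {
  stopifnot(inherits(roc, "roc_eval"))
  comp <- .delong_components(roc$cases, roc$controls)
  v <- stats::var(comp$v10) / roc$n_cases + stats::var(comp$v01) / roc$n_controls
  if (v <= 0) {
    p <- if (abs(comp$auc - 0.5) < 1e-12) 1 else 0
    return(list(auc = comp$auc, se = 0, z = if (p == 1) 0 else Inf, p_value = p))
  }
  z <- (comp$auc - 0.5) / sqrt(v)
  list(auc = comp$auc, se = sqrt(v), z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' DeLong paired comparison of two AUCs on the same subjects
#'
#' Compares the AUCs of two scores measured on the same infants with the
#' same labels, using the covariance of the DeLong structural components.
#'
#' @param scores_a,scores_b Numeric score vectors on the same subjects.
#' @param labels Logical case indicator.
#' @return List with `auc_a`, `auc_b`, `difference` (a - b), `se`, `z`
#'   and `p_value` (two-sided).
#' @export
delong_paired_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) .stop_invalid("score vectors differ in length")
  ga <- .split_by_label(scores_a, labels)
  gb <- .split_by_label(scores_b, labels)
  ca <- .delong_components(ga$cases, ga$controls)
  cb <- .delong_components(gb$cases, gb$controls)
  m <- length(ga$cases); n <- length(ga$controls)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (v <= 1e-14) {
    p <- if (abs(d) < 1e-12) 1 else 0
    return(list(auc_a = ca$auc, auc_b = cb$auc, difference = d,
                se = sqrt(max(v, 0)), z = if (p == 1) 0 else Inf, p_value = p))
  }
  z <- d / sqrt(v)
  list(auc_a = ca$auc, auc_b = cb$auc, difference = d, se = sqrt(v),
       z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
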