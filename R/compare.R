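# Group-comparison layer: Mann-Whitney U (exact by enumeration on small
# samples, ties included), Fisher exact and Pearson chi-square on 2x2
# tables, and median (range) / n (%) group summaries.

#' Mann-Whitney U test
#'
#' The U statistic counts, over all case-control pairs, pairs where the
#' first sample's value exceeds the second's (ties count 1/2). The
#' two-sided p-value is exact — computed by full enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments, valid under ties — whenever
#' the enumeration is tractable; otherwise the normal approximation with
#' tie correction (via [stats::wilcox.test()]) is used. The method
#' actually applied is reported.
#'
#' @param a,b Numeric samples (non-empty).
#' @param max_enum Enumeration budget: exact enumeration is used when
#'   `choose(n_a + n_b, n_a) <= max_enum`.
#' @return List with `u` (U statistic for `a`), `p_value` (two-sided) and
#'   `method` (`"exact enumeration"` or `"normal approximation"`).
#' @export
mann_whitney <- function(a, b, max_enum = 2e5) {
  if (length(a) == 0 || length(b) == 0) .stop_invalid("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) .stop_invalid("samples must be finite")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (choose(na + nb, na) <= max_enum) {
    idx <- utils::combn(na + nb, na)
    ranksum <- colSums(matrix(r[idx], nrow = na))
    u_all <- ranksum - na * (na + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    list(u = u_obs, p_value = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    list(u = u_obs, p_value = wt$p.value, method = "normal approximation")
  }
}

.check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) .stop_invalid("need a 2x2 table")
  if (any(!is.finite(tab) | tab < 0 | tab != round(tab))) {
    .stop_invalid("table entries must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    .stop_invalid("degenerate table: zero row or column margin")
  }
  tab
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- .check_2x2(tab)
  stats::fisher.test(tab)$p.value
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param tab 2x2 matrix of counts with positive margins.
#' @param correct Apply Yates continuity correction (default `FALSE`).
#' @return List with `statistic` (df = 1) and `p_value`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- .check_2x2(tab)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Per-variable group summaries with the matching nonparametric test
#'
#' Continuous variables are summarised as median (min-max) per group and
#' compared by Mann-Whitney U; binary variables as n (%) and compared by
#' Fisher's exact test when any expected cell count is below 5, otherwise
#' by Pearson chi-square. The test used is recorded per row.
#'
#' @param data Per-infant data frame containing `variables`.
#' @param case Logical vector: `TRUE` = case group, `FALSE` = control.
#' @param variables Character vector of columns to summarise; defaults to
#'   every column except `infant_id`.
#' @return Data frame: `variable`, `type`, `case_summary`,
#'   `control_summary`, `test`, `p_value`.
#' @export
summarize_groups <- function(data, case, variables = NULL) {
  case <- as.logical(case)
  if (length(case) != nrow(data) || any(is.na(case))) {
    .stop_invalid("`case` must be a complete logical vector matching `data` rows")
  }
  if (is.null(variables)) variables <- setdiff(names(data), "infant_id")
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    .stop_invalid("unknown variable(s): %s", paste(missing_vars, collapse = ", "))
  }
  rows <- lapply(variables, function(v) {
    x <- data[[v]]
    binary <- is.logical(x) || all(x %in% c(0, 1, NA))
    if (binary) {
      x <- as.integer(as.logical(x))
      k <- c(sum(x[case]), sum(x[!case]))
      n <- c(sum(case), sum(!case))
      tab <- rbind(k, n - k)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(rowSums(tab) == 0)) {
        # constant in both groups: proportions identical by construction
        test <- "degenerate (constant)"; p <- 1
      } else if (any(expected < 5)) {
        test <- "fisher"; p <- fisher_exact(tab)
      } else {
        test <- "chi-square"; p <- chi_square_2x2(tab)$p_value
      }
      data.frame(variable = v, type = "binary",
                 case_summary = sprintf("%d (%.0f%%)", k[1], 100 * k[1] / n[1]),
                 control_summary = sprintf("%d (%.0f%%)", k[2], 100 * k[2] / n[2]),
                 test = test, p_value = p, stringsAsFactors = FALSE)
    } else {
      xa <- x[case]; xb <- x[!case]
      mw <- mann_whitney(xa, xb)
      fmt <- function(z) sprintf("%.3g (%.3g-%.3g)", stats::median(z), min(z), max(z))
      data.frame(variable = v, type = "continuous",
                 case_summary = fmt(xa), control_summary = fmt(xb),
                 test = paste("mann-whitney", mw$method, sep = ", "),
                 p_value = mw$p_value, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
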