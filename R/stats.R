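#' Statistical battery for region-wise hemodynamic comparisons
#'
#' The tests follow the conventions of the major commercial statistics
#' packages so that results are directly comparable with the clinical
#' literature: the Wilcoxon signed-rank test uses the smaller rank sum with a
#' tie-corrected normal approximation and no continuity correction (applied at
#' any sample size); the Fisher exact test sums hypergeometric probabilities
#' of all tables at the fixed margins that are no more probable than the
#' observed one; the chi-square test is Pearson's without continuity
#' correction.
#'
#' @name stats-battery
NULL

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Zero differences are dropped; absolute differences are ranked with
#' mid-ranks for ties; `T` is the smaller of the positive/negative rank sums;
#' `Z = (T - n(n+1)/4) / sigma_T` with the tie-corrected
#' `sigma_T = sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48)`; the two-sided p-value
#' is `2 * (1 - Phi(|Z|))`. By construction `Z <= 0`.
#'
#' @param x,y Paired numeric vectors, or `y = NULL` to test differences `x`.
#' @return List of class `vaa_test`: `method`, `n` (non-zero pairs), `statistic`
#'   (Z), `p`, and internals `t_plus`, `t_minus`, `mu_t`, `sd_t`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) vaa_abort("non-finite differences", "vaaflow_data_error")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) vaa_abort("all paired differences are zero: test undefined",
                        "vaaflow_undefined_test")
  r <- rank(abs(d))
  t_plus <- sum(r[d > 0])
  t_minus <- sum(r[d < 0])
  T_stat <- min(t_plus, t_minus)
  mu_t <- n * (n + 1) / 4
  ties <- table(r)
  tie_sizes <- as.numeric(ties[ties > 1]) # mid-ranked groups
  tie_corr <- if (length(tie_sizes)) sum(tie_sizes^3 - tie_sizes) / 48 else 0
  sd_t <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_corr)
  z <- if (sd_t > 0) (T_stat - mu_t) / sd_t else 0
  p <- if (sd_t > 0) 2 * stats::pnorm(-abs(z)) else 1
  structure(list(method = "wilcoxon_signed_rank_normal_approx", n = n,
                 statistic = z, p = min(p, 1),
                 t_plus = t_plus, t_minus = t_minus, mu_t = mu_t, sd_t = sd_t),
            class = "vaa_test")
}

#' Two-sample Student / Welch t-test
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param welch Use the Welch-Satterthwaite unequal-variance form (default
#'   FALSE: pooled-variance Student test).
#' @return A `vaa_test` with `statistic` (t), `df`, `p`.
#' @export
student_t_two_sample <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    vaa_abort("each group needs at least two values", "vaaflow_invalid_parameter")
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(method = "student_t_two_sample", n = length(a) + length(b),
                            statistic = 0, df = length(a) + length(b) - 2, p = 1),
                       class = "vaa_test"))
    }
    vaa_abort("zero variance in both groups with unequal means (infinite t)",
              "vaaflow_infinite_t")
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  structure(list(method = if (welch) "welch_t_two_sample" else "student_t_two_sample",
                 n = length(a) + length(b),
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value),
            class = "vaa_test")
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-sum rule: the sum of hypergeometric
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's probability (relative tolerance 1e-7 on the
#' comparison).
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return A `vaa_test` with `p` and the observed table probability in
#'   `statistic`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    vaa_abort("need a 2x2 table of non-negative integers", "vaaflow_invalid_table")
  }
  if (sum(tab) == 0) vaa_abort("empty table", "vaaflow_invalid_table")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n)
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  structure(list(method = "fisher_exact_2x2", n = n, statistic = p_obs,
                 p = min(p, 1)),
            class = "vaa_test")
}

#' Pearson chi-square test on a 2x2 table
#'
#' Uncorrected Pearson chi-square with one degree of freedom. When any
#' expected cell count is below 5 a warning recommends the Fisher exact test.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return A `vaa_test` with `statistic` (chi-square), `df = 1`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0)) {
    vaa_abort("need a 2x2 table of non-negative counts", "vaaflow_invalid_table")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    vaa_abort("a zero margin makes the chi-square test undefined", "vaaflow_undefined_test")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warning("expected cell count below 5: the Fisher exact test is recommended")
  }
  stat <- sum((tab - expected)^2 / expected)
  structure(list(method = "chi_square_2x2", n = sum(tab), statistic = stat,
                 df = 1, p = stats::pchisq(stat, 1, lower.tail = FALSE)),
            class = "vaa_test")
}

#' @export
print.vaa_test <- function(x, ...) {
  cat(sprintf("<vaa_test> %s: n=%d, statistic=%.4g, p=%.4g\n",
              x$method, x$n, x$statistic, x$p))
  invisible(x)
}

#' Region-comparison Wilcoxon battery
#'
#' For every stratum (`all`, `high`, `low`), metric (peak wall shear maximum,
#' TAWSS, WSSG, OSI, AFI) and comparison (aneurysm vs para mean, vs upstream,
#' vs downstream), runs the signed-rank test across models and tabulates Z
#' and the two-sided p.
#'
#' @param summaries Named list of `vaa_region_summary`, one per model.
#' @param groups List of `vaa_group` assignments in the same order.
#' @return Tidy data.frame: `stratum, metric, comparison, n, Z, p` (cells with
#'   no usable pair are `NA`).
#' @export
run_table3_battery <- function(summaries, groups) {
  stopifnot(length(summaries) == length(groups))
  tags <- vapply(groups, function(g) g$group, character(1))
  metrics <- c("wssmax_pa", "tawss_pa", "wssg_nm3", "osi", "afi")
  comparisons <- c("para", "upstream", "downstream")
  strata <- list(all = rep(TRUE, length(summaries)),
                 high = tags == "high",
                 low = tags == "low")
  rows <- list()
  for (st in names(strata)) {
    sel <- which(strata[[st]])
    for (m in metrics) {
      for (cmp in comparisons) {
        a <- vapply(summaries[sel], function(s) s$metrics["aneurysm", m], numeric(1))
        b <- vapply(summaries[sel], function(s) {
          if (cmp == "para") s$para[m] else s$metrics[cmp, m]
        }, numeric(1))
        ok <- is.finite(a) & is.finite(b)
        res <- if (sum(ok) >= 1 && any(a[ok] != b[ok])) {
          tryCatch(wilcoxon_signed_rank(a[ok], b[ok]),
                   vaaflow_undefined_test = function(e) NULL)
        } else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = st, metric = m, comparison = cmp,
          n = if (is.null(res)) sum(ok) else res$n,
          Z = if (is.null(res)) NA_real_ else res$statistic,
          p = if (is.null(res)) NA_real_ else res$p)
      }
    }
  }
  do.call(rbind, rows)
}
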