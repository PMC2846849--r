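# Per-gene case-control burden statistics on carrier-collapsed 2x2
# tables: exact Fisher test by full hypergeometric enumeration, Pearson
# chi-square without continuity correction, and cohort relative risks
# with Katz log-method confidence intervals.

#' Construct a carrier 2x2 table
#'
#' Layout: rows carrier / non-carrier, columns case / control.
#'
#' @param a Case carriers.
#' @param b Control carriers.
#' @param c Case non-carriers.
#' @param d Control non-carriers.
#' @return List of class `two_by_two` with fields `a`, `b`, `c`, `d`,
#'   `n_cases`, `n_controls`.
#' @export
two_by_two <- function(a, b, c, d) {
  v <- as.integer(c(a, b, c, d))
  if (anyNA(v) || any(v < 0L)) stop("2x2 cells must be non-negative integers")
  structure(list(a = v[1], b = v[2], c = v[3], d = v[4],
                 n_cases = v[1] + v[3], n_controls = v[2] + v[4]),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("carrier", "non-carrier"),
                              c("case", "control")))
  print(m)
  invisible(x)
}

#' Per-gene carrier collapse
#'
#' Builds the carrier 2x2 for one gene: a subject counts as a carrier if
#' it harbours at least one qualifying variant in the gene, regardless of
#' multiplicity.
#'
#' @param gene Gene symbol.
#' @param case_cohort,control_cohort Lists of per-subject
#'   `annotated_variant` data frames (or data frames with `gene` and
#'   `effect` columns).
#' @param effect_filter Effects that qualify (default non-synonymous, the
#'   usual burden definition).
#' @return A [two_by_two()].
#' @export
carrier_table <- function(gene, case_cohort, control_cohort,
                          effect_filter = "non-synonymous") {
  if (length(case_cohort) == 0L || length(control_cohort) == 0L)
    stop("cohorts must be non-empty")
  is_carrier <- function(ann)
    any(!is.na(ann$gene) & ann$gene == gene & ann$effect %in% effect_filter)
  a <- sum(vapply(case_cohort, is_carrier, logical(1)))
  b <- sum(vapply(control_cohort, is_carrier, logical(1)))
  two_by_two(a, b, length(case_cohort) - a, length(control_cohort) - b)
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Enumerates every 2x2 table with the observed margins and sums the
#' point probabilities of all tables whose probability does not exceed
#' that of the observed table, with a `1e-7` relative tolerance on the
#' comparison to absorb floating-point ties.  The degenerate case with no
#' carriers (or no non-carriers) anywhere returns 1.
#'
#' @param t A [two_by_two()].
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_two_sided(two_by_two(4, 0, 31, 40))  # ~0.043
#' @export
fisher_exact_two_sided <- function(t) {
  r <- t$a + t$b            # carriers
  m <- t$n_cases; n <- t$n_controls
  if (r == 0L || r == m + n) return(1)
  support <- max(0L, r - n):min(r, m)
  p <- stats::dhyper(support, m, n, r)
  p_obs <- stats::dhyper(t$a, m, n, r)
  sum(p[p <= p_obs * (1 + 1e-7)])
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected (no Yates continuity correction):
#' `X2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, compared to the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param t A [two_by_two()].
#' @return List with `statistic` and `p_value`.
#' @export
pearson_chi2 <- function(t) {
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  N <- a + b + c + d
  denom <- as.numeric(a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) stop("chi-square requires all margins positive")
  stat <- N * (as.numeric(a) * d - as.numeric(b) * c)^2 / denom
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Cohort relative risk with Katz confidence interval
#'
#' Three orientations of the risk ratio on a carrier 2x2:
#' * `"case-cohort"` (default): risk of being a case among carriers vs
#'   non-carriers, `RR = (a/(a+b)) / (c/(c+d))`;
#' * `"control-cohort"`: risk of being a control among carriers vs
#'   non-carriers, `RR = (b/(a+b)) / (d/(c+d))`;
#' * `"exposure"`: carrier-rate ratio cases vs controls,
#'   `RR = (a/(a+c)) / (b/(b+d))`.
#'
#' The confidence interval is the Katz log method,
#' `exp(log RR +/- z * SE)` with `SE` the usual delta-method standard
#' error of `log RR`; `z = 1.959964` at the default 95% level.  No
#' continuity correction is applied: a zero cell in either numerator is
#' an error (add a correction upstream or choose another orientation).
#'
#' @param t A [two_by_two()].
#' @param orientation `"case-cohort"`, `"control-cohort"` or
#'   `"exposure"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `rr`, `ci_low`, `ci_high`, `orientation`.
#' @examples
#' cohort_rr(two_by_two(21, 4, 14, 36))  # RR 3.00, CI (1.86, 4.83)
#' @export
cohort_rr <- function(t, orientation = c("case-cohort", "control-cohort",
                                         "exposure"),
                      conf_level = 0.95) {
  orientation <- match.arg(orientation)
  cells <- switch(orientation,
    # x1/n1 over x2/n2
    "case-cohort"    = list(x1 = t$a, n1 = t$a + t$b, x2 = t$c, n2 = t$c + t$d),
    "control-cohort" = list(x1 = t$b, n1 = t$a + t$b, x2 = t$d, n2 = t$c + t$d),
    "exposure"       = list(x1 = t$a, n1 = t$a + t$c, x2 = t$b, n2 = t$b + t$d))
  if (cells$n1 == 0L || cells$n2 == 0L)
    stop("relative risk undefined: empty comparison group")
  if (cells$x1 == 0L || cells$x2 == 0L)
    stop("relative risk numerator cell is zero; no continuity correction is ",
         "applied -- consider another orientation or an exact method")
  rr <- (cells$x1 / cells$n1) / (cells$x2 / cells$n2)
  se <- sqrt(1 / cells$x1 - 1 / cells$n1 + 1 / cells$x2 - 1 / cells$n2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(rr = rr, ci_low = rr * exp(-z * se), ci_high = rr * exp(z * se),
       orientation = orientation)
}

#' Per-gene burden table
#'
#' One row per gene: carrier 2x2, test p-value under the chosen policy,
#' and relative risk with CI.  Policy `"auto"` uses the Pearson
#' chi-square when every expected cell count is at least 5 and the exact
#' Fisher test otherwise.  Genes whose chosen RR orientation is undefined
#' (zero numerator cell) get `NA` RR fields rather than an error.
#'
#' @param case_cohort,control_cohort Lists of per-subject annotated
#'   variant data frames (see [carrier_table()]).
#' @param genes Character vector of gene symbols to test.
#' @param policy `"fisher"` (default), `"chi2"` or `"auto"`.
#' @param orientation RR orientation passed to [cohort_rr()].
#' @param effect_filter Qualifying effects for carrier status.
#' @param others_genes Optional character vector: genes pooled into a
#'   final `"Others"` row (carrier = any qualifying variant in any of
#'   them).  RNA-gene variants qualify via effect `rna_gene` here.
#' @return Data frame of class `burden_result` with columns `gene`, `a`,
#'   `b`, `c`, `d`, `test_used`, `p_value`, `rr`, `ci_low`, `ci_high`,
#'   `orientation`.
#' @export
burden_table <- function(case_cohort, control_cohort, genes,
                         policy = c("fisher", "chi2", "auto"),
                         orientation = "case-cohort",
                         effect_filter = "non-synonymous",
                         others_genes = NULL) {
  policy <- match.arg(policy)
  one <- function(gene, tab) {
    test_used <- policy
    if (policy == "auto") {
      N <- tab$a + tab$b + tab$c + tab$d
      expected <- outer(c(tab$a + tab$b, tab$c + tab$d),
                        c(tab$n_cases, tab$n_controls)) / N
      test_used <- if (all(expected >= 5)) "chi2" else "fisher"
    }
    p <- if (test_used == "chi2") pearson_chi2(tab)$p_value
         else fisher_exact_two_sided(tab)
    rr <- tryCatch(cohort_rr(tab, orientation),
                   error = function(e) list(rr = NA_real_, ci_low = NA_real_,
                                            ci_high = NA_real_,
                                            orientation = orientation))
    data.frame(gene = gene, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               test_used = test_used, p_value = p, rr = rr$rr,
               ci_low = rr$ci_low, ci_high = rr$ci_high,
               orientation = rr$orientation, stringsAsFactors = FALSE)
  }
  rows <- lapply(genes, function(g)
    one(g, carrier_table(g, case_cohort, control_cohort, effect_filter)))
  if (!is.null(others_genes)) {
    is_other_carrier <- function(ann)
      any(!is.na(ann$gene) & ann$gene %in% others_genes &
            ann$effect %in% c(effect_filter, "rna_gene"))
    a <- sum(vapply(case_cohort, is_other_carrier, logical(1)))
    b <- sum(vapply(control_cohort, is_other_carrier, logical(1)))
    tab <- two_by_two(a, b, length(case_cohort) - a, length(control_cohort) - b)
    rows <- c(rows, list(one("Others", tab)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("burden_result", "data.frame")
  out
}

#' Burden statistics from pre-tabulated carrier counts
#'
#' Recomputes the test and RR columns of a published per-gene carrier
#' table from its printed counts.
#'
#' @param counts Data frame with columns `gene`, `a` (case carriers),
#'   `b` (control carriers).
#' @param n_cases,n_controls Cohort sizes.
#' @inheritParams burden_table
#' @return A `burden_result` data frame.
#' @export
burden_from_counts <- function(counts, n_cases, n_controls,
                               policy = "fisher",
                               orientation = "case-cohort") {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    tab <- two_by_two(counts$a[i], counts$b[i],
                      n_cases - counts$a[i], n_controls - counts$b[i])
    p <- if (policy == "chi2") pearson_chi2(tab)$p_value
         else fisher_exact_two_sided(tab)
    rr <- tryCatch(cohort_rr(tab, orientation),
                   error = function(e) list(rr = NA_real_, ci_low = NA_real_,
                                            ci_high = NA_real_,
                                            orientation = orientation))
    data.frame(gene = counts$gene[i], a = tab$a, b = tab$b, c = tab$c,
               d = tab$d, test_used = policy, p_value = p, rr = rr$rr,
               ci_low = rr$ci_low, ci_high = rr$ci_high,
               orientation = rr$orientation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("burden_result", "data.frame")
  out
}
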