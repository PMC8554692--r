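# Tumor-pattern tabulation and two-group 2x2 comparisons: uncorrected
# Pearson chi-square, or the two-sided Fisher exact test (point-probability
# method) when any expected cell count is below 5. No continuity correction
# and no multiple-testing adjustment; significance is declared at p < .01.

#' Uncorrected Pearson chi-square test for a 2x2 table
#'
#' Statistic `N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, identical to the
#' observed-vs-expected sum over the four cells; p-value from the
#' chi-square distribution with one degree of freedom. No continuity
#' correction.
#'
#' @param a,b,c,d Non-negative cell counts (group 1 with/without the trait;
#'   group 2 with/without).
#' @return List with `statistic` and `p_value`.
#' @export
pearson_chi2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    stop("zero margin: the chi-square test is undefined; use fisher_exact",
         call. = FALSE)
  }
  n <- sum(cells)
  statistic <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every table at most as probable as the observed one (point-probability
#' method; a relative tolerance of 1e-7 guards against floating-point ties).
#' A table with a zero row or column margin has a single attainable
#' configuration and p = 1.
#'
#' @inheritParams pearson_chi2
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be non-negative", call. = FALSE)
  m <- a + b          # row 1 (group 1 size)
  n2 <- c + d         # row 2
  k <- a + c          # column 1
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Tabulate case sets by organ or histology
#'
#' At the `organ` level every case counts and the per-group denominator is
#' the total number of cases in that group. At the histology levels
#' (`soft_tissue_histology`, `brain_histology`) only cases of the relevant
#' organ with morphological information available are counted, and the
#' per-group denominator is that subset's size. Percentages are reported to
#' 2 decimals (organ) or 1 decimal (histology) and are `NA` when a
#' denominator is zero.
#'
#' @param strata Result of [stratify_for_analysis()] (or any list with
#'   `met_cases` / `not_met_cases` diagnosis data frames).
#' @param level `"organ"`, `"soft_tissue_histology"` or
#'   `"brain_histology"`.
#' @return Data frame of class `lfs_tabulation` with columns `label`, `n1`,
#'   `pct1`, `n2`, `pct2` and attributes `den1`, `den2`, `level`.
#' @export
tabulate_cases <- function(strata, level = c("organ",
                                             "soft_tissue_histology",
                                             "brain_histology")) {
  level <- match.arg(level)
  g1 <- strata$met_cases
  g2 <- strata$not_met_cases
  if (level == "organ") {
    if (nrow(g1) + nrow(g2) == 0) {
      stop("organ-level tabulation needs at least one case", call. = FALSE)
    }
    labels <- lfs_sites()
    n1 <- vapply(labels, function(s) sum(g1$site == s), integer(1))
    n2 <- vapply(labels, function(s) sum(g2$site == s), integer(1))
    den1 <- nrow(g1); den2 <- nrow(g2)
    digits <- 2
  } else {
    org <- if (level == "soft_tissue_histology") "soft_tissues" else "brain"
    labels <- if (level == "soft_tissue_histology") {
      c("fibrosarcoma", "leiomyosarcoma", "liposarcoma", "rhabdomyosarcoma",
        "malignant_fibrous_histiocytoma", "sarcoma_other", "sarcoma_nos")
    } else {
      c("astrocytoma", "choroid_plexus_carcinoma", "ependymoma",
        "glioblastoma_glioma", "medulloblastoma", "pnet", "brain_other",
        "cancer_nos")
    }
    s1 <- g1[g1$site == org & !is.na(g1$morphology), , drop = FALSE]
    s2 <- g2[g2$site == org & !is.na(g2$morphology), , drop = FALSE]
    n1 <- vapply(labels, function(m) sum(s1$morphology == m), integer(1))
    n2 <- vapply(labels, function(m) sum(s2$morphology == m), integer(1))
    den1 <- nrow(s1); den2 <- nrow(s2)
    digits <- 1
  }
  pct <- function(n, den) if (den == 0) rep(NA_real_, length(n)) else
    round(100 * n / den, digits)
  out <- data.frame(label = labels, n1 = unname(n1), pct1 = pct(n1, den1),
                    n2 = unname(n2), pct2 = pct(n2, den2),
                    stringsAsFactors = FALSE)
  attr(out, "den1") <- den1
  attr(out, "den2") <- den2
  attr(out, "level") <- level
  class(out) <- c("lfs_tabulation", class(out))
  out
}

#' Compare the two groups label by label
#'
#' For each tabulated label builds the 2x2 table (label vs all other cases
#' within each group's denominator), applies the uncorrected Pearson
#' chi-square test unless any expected cell count is below 5, in which case
#' the two-sided Fisher exact test is used, and flags significance at
#' p < .01.
#'
#' @param tab An `lfs_tabulation`.
#' @param alpha Significance threshold (default 0.01).
#' @return Data frame with one row per label: cell counts `a`,`b`,`c`,`d`,
#'   percentages, `test_used`, `statistic`, `p_value`, `p_formatted`,
#'   `significant`.
#' @export
compare_groups <- function(tab, alpha = 0.01) {
  den1 <- attr(tab, "den1"); den2 <- attr(tab, "den2")
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    a <- tab$n1[i]; b <- den1 - a
    c_ <- tab$n2[i]; d <- den2 - c_
    n <- a + b + c_ + d
    expected <- outer(c(a + b, c_ + d), c(a + c_, b + d)) / n
    use_fisher <- any(expected < 5) || any(c(a + b, c_ + d) == 0)
    if (use_fisher) {
      p <- fisher_exact(a, b, c_, d)
      statistic <- NA_real_
      test <- "fisher_exact"
    } else {
      res <- pearson_chi2(a, b, c_, d)
      p <- res$p_value
      statistic <- res$statistic
      test <- "pearson_chi2"
    }
    data.frame(label = tab$label[i], a = a, b = b, c = c_, d = d,
               pct1 = tab$pct1[i], pct2 = tab$pct2[i], test_used = test,
               statistic = statistic, p_value = p,
               p_formatted = format_p(p), significant = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a p-value in tabular style
#'
#' `"<.001"` below 0.001, three decimals below 0.01, `">.99"` above 0.99,
#' two decimals otherwise, with no leading zero.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 0.001) return("<.001")
    if (x > 0.99) return(">.99")
    digits <- if (x < 0.0095) 3 else 2
    sub("^0", "", sprintf(paste0("%.", digits, "f"), x))
  }, character(1))
}

#' Age summary per group
#'
#' Median, minimum and maximum of each individual's age at first diagnosis.
#' Cancer-free individuals contribute nothing; groups with no ages yield
#' `NA` summaries.
#'
#' @param cohort An `lfs_cohort`.
#' @param groups Named list of character vectors of individual ids.
#' @return Data frame with one row per group: `group`, `n`, `median_age`,
#'   `min_age`, `max_age`.
#' @export
summarize_ages <- function(cohort, groups) {
  rows <- lapply(names(groups), function(g) {
    ages <- vapply(groups[[g]], function(id) {
      dx <- diagnoses_of(cohort, id)
      if (nrow(dx) == 0) NA_real_ else min(dx$age_at_dx)
    }, numeric(1))
    ages <- ages[!is.na(ages)]
    data.frame(group = g, n = length(ages),
               median_age = if (length(ages)) stats::median(ages) else NA_real_,
               min_age = if (length(ages)) min(ages) else NA_real_,
               max_age = if (length(ages)) max(ages) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Tumor-pattern report table
#'
#' Builds the organ-level and both histology-level tabulations with group
#' comparisons and stacks them into one publication-style table
#' (`label, group1 "n (pct)", group2 "n (pct)", p, test`).
#'
#' @param strata Result of [stratify_for_analysis()].
#' @param alpha Significance threshold.
#' @return Data frame with a `section` column
#'   (`organ`/`soft_tissue_histology`/`brain_histology`).
#' @export
tumor_pattern_table <- function(strata, alpha = 0.01) {
  sections <- c("organ", "soft_tissue_histology", "brain_histology")
  out <- lapply(sections, function(lv) {
    tab <- tabulate_cases(strata, lv)
    cmp <- compare_groups(tab, alpha)
    digits <- if (lv == "organ") 2 else 1
    data.frame(section = lv, label = cmp$label,
               met = sprintf(paste0("%d (%.", digits, "f)"), cmp$a, cmp$pct1),
               not_met = sprintf(paste0("%d (%.", digits, "f)"), cmp$c,
                                 cmp$pct2),
               p = cmp$p_formatted, test = cmp$test_used,
               significant = cmp$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
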