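# Clinical genetic-testing criteria for Li-Fraumeni syndrome: the classic
# family-history criteria (young sarcoma proband plus affected first- and
# second-degree relatives), the 2015-revision Chompret criteria split into
# category A (familial presentation or multiple primary tumors) and
# category B (specific tumor types irrespective of family history), and the
# age-18 childhood-cancer rule. All age cut-offs and tumor lists live in a
# config object so criteria variants can be swapped without code changes.

#' Criteria configuration
#'
#' Ages are exclusive upper bounds in years ("before age N" means
#' `age_at_dx < N`). The core tumor spectrum (premenopausal breast cancer,
#' soft tissue sarcoma, osteosarcoma, CNS tumor, adrenocortical carcinoma)
#' drives the Chompret category A rules. When the premenopausal flag is
#' missing on a breast cancer, diagnosis before `premenopausal_fallback_age`
#' is used as a proxy.
#'
#' @param classic_proband_age Proband sarcoma age cut-off (classic), 45.
#' @param classic_relative_age Relative cancer age cut-off (classic), 45.
#' @param chompret_proband_age Proband age cut-off (Chompret A), 46.
#' @param chompret_relative_age Relative age cut-off (Chompret A), 56.
#' @param chompret_breast_age Breast-cancer age cut-off (Chompret B), 31.
#' @param premenopausal_fallback_age Age proxy for premenopausal status, 50.
#' @param require_rms_subtype If `TRUE`, rhabdomyosarcoma only satisfies
#'   category B when the embryonal anaplastic subtype is recorded; the
#'   shipped morphology vocabulary carries no subtype, so the default
#'   (`FALSE`) lets any rhabdomyosarcoma qualify.
#' @return A list of class `lfs_criteria_config`.
#' @export
criteria_config <- function(classic_proband_age = 45,
                            classic_relative_age = 45,
                            chompret_proband_age = 46,
                            chompret_relative_age = 56,
                            chompret_breast_age = 31,
                            premenopausal_fallback_age = 50,
                            require_rms_subtype = FALSE) {
  cfg <- list(classic_proband_age = classic_proband_age,
              classic_relative_age = classic_relative_age,
              chompret_proband_age = chompret_proband_age,
              chompret_relative_age = chompret_relative_age,
              chompret_breast_age = chompret_breast_age,
              premenopausal_fallback_age = premenopausal_fallback_age,
              require_rms_subtype = require_rms_subtype)
  if (any(vapply(cfg[1:6], function(a) !is.numeric(a) || a <= 0,
                 logical(1)))) {
    stop("all criteria ages must be positive numbers", call. = FALSE)
  }
  structure(cfg, class = "lfs_criteria_config")
}

#' Write / read a criteria configuration
#'
#' JSON serialization of [criteria_config()]; the shipped default
#' reproduces the published criteria.
#'
#' @param cfg An `lfs_criteria_config`.
#' @param path File path.
#' @return `read_criteria_config` returns an `lfs_criteria_config`.
#' @export
write_criteria_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_criteria_config
#' @export
read_criteria_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(criteria_config, x)
}

new_criteria_result <- function(criterion, trace) {
  structure(list(met = length(trace) > 0, criterion = criterion,
                 trace = as.character(trace)),
            class = "lfs_criteria_result")
}

#' @export
print.lfs_criteria_result <- function(x, ...) {
  cat("<", x$criterion, "> ", if (x$met) "MET" else "not met", "\n", sep = "")
  for (t in x$trace) cat("  - ", t, "\n", sep = "")
  invisible(x)
}

# breast cancer counted as premenopausal: explicit flag, else age fallback
is_premenopausal_breast <- function(dx, cfg) {
  dx$site == "breast" &
    ifelse(is.na(dx$premenopausal),
           dx$age_at_dx < cfg$premenopausal_fallback_age,
           dx$premenopausal)
}

# sarcoma: any soft-tissue tumor, or a bone tumor that is (or may be) a
# bone sarcoma; bone tumors without morphology are counted
is_sarcoma <- function(dx) {
  dx$site == "soft_tissues" |
    (dx$site == "bones" &
       (is.na(dx$morphology) |
          dx$morphology %in% c("osteosarcoma", "sarcoma_other",
                               "sarcoma_nos")))
}

# LFS core tumor spectrum: premenopausal breast cancer, soft tissue
# sarcoma, osteosarcoma, CNS tumor, adrenocortical carcinoma
is_core_tumor <- function(dx, cfg) {
  is_premenopausal_breast(dx, cfg) |
    dx$site == "soft_tissues" |
    (dx$site == "bones" &
       (is.na(dx$morphology) | dx$morphology == "osteosarcoma")) |
    dx$site == "brain" |
    dx$site == "adrenal_gland"
}

#' Classic Li-Fraumeni criteria
#'
#' Met when the proband has a sarcoma before age 45, a first-degree
#' relative has any cancer before 45, and an additional (distinct) first-
#' or second-degree relative has any cancer before 45 or a sarcoma at any
#' age. Individuals without diagnosis rows are treated as cancer-free.
#'
#' @param pedigree An `lfs_pedigree` for the proband's family.
#' @param cohort An `lfs_cohort`.
#' @param proband Individual id.
#' @param cfg An [criteria_config()].
#' @return An `lfs_criteria_result` with a trace naming the qualifying
#'   relatives and diagnoses.
#' @export
meets_classic <- function(pedigree, cohort, proband, cfg = criteria_config()) {
  check_member(pedigree, proband)
  trace <- character()
  pdx <- diagnoses_of(cohort, proband)
  psarc <- pdx[is_sarcoma(pdx) & pdx$age_at_dx < cfg$classic_proband_age, ,
               drop = FALSE]
  if (nrow(psarc) > 0) {
    fdr <- relatives_within_degree(pedigree, proband, 1)
    sdr <- relatives_within_degree(pedigree, proband, 2)
    q1 <- fdr[vapply(fdr, function(r) {
      any(diagnoses_of(cohort, r)$age_at_dx < cfg$classic_relative_age)
    }, logical(1))]
    q2 <- sdr[vapply(sdr, function(r) {
      rdx <- diagnoses_of(cohort, r)
      any(rdx$age_at_dx < cfg$classic_relative_age) || any(is_sarcoma(rdx))
    }, logical(1))]
    # a distinct pair (one from q1, one from q2) must exist
    ok <- length(q1) > 0 && length(setdiff(q2, q1[1])) > 0 ||
      length(q1) > 1 && length(q2) > 0
    if (ok) {
      r1 <- q1[1]
      r2 <- setdiff(q2, r1)[1]
      if (is.na(r2)) { r1 <- q1[2]; r2 <- setdiff(q2, r1)[1] }
      trace <- c(
        sprintf("proband %s: %s at age %g (sarcoma < %g)", proband,
                psarc$site[1], psarc$age_at_dx[1], cfg$classic_proband_age),
        sprintf("first-degree relative %s with cancer < %g", r1,
                cfg$classic_relative_age),
        sprintf("additional first/second-degree relative %s qualifies", r2))
    }
  }
  new_criteria_result("classic", trace)
}

#' Chompret criteria, category A (familial presentation / multiple tumors)
#'
#' Met when either (i) the proband has a core-spectrum tumor before age 46
#' and at least one first- or second-degree relative has a core tumor
#' before 56 or multiple primary tumors; or (ii) the proband has multiple
#' primaries (multiple breast tumors counted once), at least two of them
#' core-spectrum, the first before age 46.
#'
#' @inheritParams meets_classic
#' @return An `lfs_criteria_result`.
#' @export
meets_chompret_A <- function(pedigree, cohort, proband,
                             cfg = criteria_config()) {
  check_member(pedigree, proband)
  trace <- character()
  pdx <- diagnoses_of(cohort, proband)
  # (i) familial presentation
  pcore <- pdx[is_core_tumor(pdx, cfg) &
                 pdx$age_at_dx < cfg$chompret_proband_age, , drop = FALSE]
  if (nrow(pcore) > 0) {
    rels <- relatives_within_degree(pedigree, proband, 2)
    for (r in rels) {
      rdx <- diagnoses_of(cohort, r)
      if (nrow(rdx) == 0) next
      if (any(is_core_tumor(rdx, cfg) &
                rdx$age_at_dx < cfg$chompret_relative_age)) {
        trace <- c(sprintf("proband %s: core tumor (%s) at age %g < %g",
                           proband, pcore$site[1], pcore$age_at_dx[1],
                           cfg$chompret_proband_age),
                   sprintf("relative %s: core tumor < %g", r,
                           cfg$chompret_relative_age))
        break
      }
      if (nrow(rdx) >= 2) {
        trace <- c(sprintf("proband %s: core tumor (%s) at age %g < %g",
                           proband, pcore$site[1], pcore$age_at_dx[1],
                           cfg$chompret_proband_age),
                   sprintf("relative %s: multiple primary tumors", r))
        break
      }
    }
  }
  # (ii) multiple primary tumors in the proband
  if (length(trace) == 0 && nrow(pdx) >= 2) {
    breast <- which(pdx$site == "breast")
    keep <- if (length(breast) > 1) {
      setdiff(seq_len(nrow(pdx)), breast[-which.min(pdx$age_at_dx[breast])])
    } else seq_len(nrow(pdx))
    mdx <- pdx[keep, , drop = FALSE]
    if (nrow(mdx) >= 2 && sum(is_core_tumor(mdx, cfg)) >= 2 &&
          min(mdx$age_at_dx) < cfg$chompret_proband_age) {
      trace <- c(sprintf(
        "proband %s: %d primary tumors (>= 2 core), first at age %g < %g",
        proband, nrow(mdx), min(mdx$age_at_dx), cfg$chompret_proband_age))
    }
  }
  new_criteria_result("chompret_A", trace)
}

#' Chompret criteria, category B (specific tumor types)
#'
#' Met, irrespective of family history, for adrenocortical carcinoma or
#' choroid plexus carcinoma at any age, rhabdomyosarcoma at any age (see
#' `require_rms_subtype` in [criteria_config()]), or breast cancer before
#' age 31.
#'
#' @param cohort An `lfs_cohort`.
#' @param proband Individual id.
#' @param cfg An [criteria_config()].
#' @return An `lfs_criteria_result`.
#' @export
meets_chompret_B <- function(cohort, proband, cfg = criteria_config()) {
  pdx <- diagnoses_of(cohort, proband)
  trace <- character()
  if (nrow(pdx) > 0) {
    hit <- pdx$site == "adrenal_gland"
    hit <- hit | (!is.na(pdx$morphology) &
                    pdx$morphology == "choroid_plexus_carcinoma")
    if (!isTRUE(cfg$require_rms_subtype)) {
      hit <- hit | (!is.na(pdx$morphology) &
                      pdx$morphology == "rhabdomyosarcoma")
    }
    hit <- hit | (pdx$site == "breast" &
                    pdx$age_at_dx < cfg$chompret_breast_age)
    if (any(hit)) {
      i <- which(hit)[1]
      trace <- sprintf("proband %s: %s%s at age %g qualifies (category B)",
                       proband, pdx$site[i],
                       ifelse(is.na(pdx$morphology[i]), "",
                              paste0("/", pdx$morphology[i])),
                       pdx$age_at_dx[i])
    }
  }
  new_criteria_result("chompret_B", trace)
}

#' Combined LFS genetic-testing criteria
#'
#' Classic, Chompret A and Chompret B evaluated in that order; met when any
#' fires. The trace lists every criterion that fired, the first one first.
#'
#' @inheritParams meets_classic
#' @return An `lfs_criteria_result` with `criterion = "any_testing"`.
#' @export
meets_testing_criteria <- function(pedigree, cohort, proband,
                                   cfg = criteria_config()) {
  parts <- list(meets_classic(pedigree, cohort, proband, cfg),
                meets_chompret_A(pedigree, cohort, proband, cfg),
                meets_chompret_B(cohort, proband, cfg))
  fired <- Filter(function(p) p$met, parts)
  trace <- unlist(lapply(fired, function(p) {
    c(paste0("criterion met: ", p$criterion), p$trace)
  }))
  new_criteria_result("any_testing", trace)
}

#' Childhood cancer rule
#'
#' `TRUE` iff the individual has any cancer diagnosed strictly before age
#' 18 years.
#'
#' @param cohort An `lfs_cohort`.
#' @param individual Individual id.
#' @return Logical scalar.
#' @export
childhood_cancer <- function(cohort, individual) {
  any(diagnoses_of(cohort, individual)$age_at_dx < 18)
}
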