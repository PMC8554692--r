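# The Li-Fraumeni spectrum classifier. Carriers of a pathogenic / likely
# pathogenic (P/LP) germline or germline-mosaic TP53 variant are assigned
# LFS, attenuated LFS, incidental LFS or a cancer-free-carrier state;
# non-carriers meeting classic or Chompret-A criteria are phenotypic LFS.
# The carrier categories (LFS, attenuated, incidental and the cancer-free
# carrier states) together form the heritable TP53-related cancer
# syndromes.

spectrum_categories <- c("LFS", "attenuated_LFS", "incidental_LFS",
                         "phenotypic_LFS", "carrier_cancer_free_LFS_family",
                         "carrier_cancer_free_attenuated_family",
                         "not_in_spectrum")

# severity used for the per-family summary (most severe category present)
category_severity <- c(LFS = 7, attenuated_LFS = 6,
                       carrier_cancer_free_LFS_family = 5,
                       carrier_cancer_free_attenuated_family = 4,
                       incidental_LFS = 3, phenotypic_LFS = 2,
                       not_in_spectrum = 1)

heritable_categories <- c("LFS", "attenuated_LFS", "incidental_LFS",
                          "carrier_cancer_free_LFS_family",
                          "carrier_cancer_free_attenuated_family")

# carrier for classification purposes: P/LP (including mosaic P/LP) and no
# suspicion of clonal hematopoiesis; VUS/conflicting/LB/B/unknown calls are
# treated as non-carriers for category assignment but retained in analyses
is_plp_carrier <- function(ind_row) {
  !is.na(ind_row$clinsig) & ind_row$clinsig == "P_LP" &
    !(ind_row$clonal_hematopoiesis %in% TRUE)
}

# tumor types that qualify a carrier for LFS beyond the testing criteria:
# osteosarcoma, childhood hypodiploid ALL, SHH-medulloblastoma
has_additional_qualifying_tumor <- function(pdx) {
  if (nrow(pdx) == 0) return(FALSE)
  m <- pdx$morphology
  any(!is.na(m) & (m == "osteosarcoma" | m == "shh_medulloblastoma" |
                     (m == "hypodiploid_all" & pdx$age_at_dx < 18)))
}

#' Classify one individual on the Li-Fraumeni spectrum
#'
#' Decision procedure: a P/LP (or mosaic P/LP) carrier with any cancer
#' before age 18, or meeting the genetic-testing criteria, or with an
#' additional qualifying tumor type (osteosarcoma, childhood hypodiploid
#' ALL, SHH-medulloblastoma) is `LFS`; a carrier with cancer but none of
#' these is `attenuated_LFS`; a cancer-free carrier is assigned by their
#' blood relatives' categories (`carrier_cancer_free_LFS_family`,
#' `carrier_cancer_free_attenuated_family`, else `incidental_LFS`). A
#' non-carrier meeting classic or Chompret-A criteria is `phenotypic_LFS`;
#' all other non-carriers — including those meeting only the
#' tumor-type-specific Chompret category B — are `not_in_spectrum`.
#'
#' @param pedigree An `lfs_pedigree` for the individual's family.
#' @param cohort An `lfs_cohort`.
#' @param individual Individual id.
#' @param cfg A [criteria_config()].
#' @param family_categories Optional named vector of already-resolved
#'   categories of family members, used to place cancer-free carriers;
#'   when `NULL` the relatives are classified on the fly.
#' @return A list of class `lfs_spectrum_assignment` with fields
#'   `individual_id`, `category`, `heritable_tp53_related`, `rationale`.
#' @export
classify_individual <- function(pedigree, cohort, individual,
                                cfg = criteria_config(),
                                family_categories = NULL) {
  ind <- cohort$individuals[cohort$individuals$individual_id == individual, ,
                            drop = FALSE]
  if (nrow(ind) != 1) stop("unknown individual: ", individual, call. = FALSE)
  pdx <- diagnoses_of(cohort, individual)
  rationale <- character()

  if (is_plp_carrier(ind)) {
    if (nrow(pdx) > 0) {
      child <- childhood_cancer(cohort, individual)
      crit <- meets_testing_criteria(pedigree, cohort, individual, cfg)
      extra <- has_additional_qualifying_tumor(pdx)
      if (child || crit$met || extra) {
        category <- "LFS"
        rationale <- c("P/LP carrier with cancer",
                       if (child) "cancer before age 18",
                       if (crit$met) paste0("meets testing criteria (",
                                            crit$trace[1], ")"),
                       if (extra) "additional qualifying tumor type")
      } else {
        category <- "attenuated_LFS"
        rationale <- c("P/LP carrier with cancer",
                       "no cancer before age 18",
                       "does not meet testing criteria")
      }
    } else {
      if (is.null(family_categories)) {
        rels <- blood_relatives(pedigree, individual)
        family_categories <- vapply(rels, function(r) {
          classify_affected_only(pedigree, cohort, r, cfg)
        }, character(1))
      } else {
        rels <- intersect(blood_relatives(pedigree, individual),
                          names(family_categories))
        family_categories <- family_categories[rels]
      }
      if (any(family_categories == "LFS")) {
        category <- "carrier_cancer_free_LFS_family"
        rationale <- "cancer-free P/LP carrier; LFS in blood relatives"
      } else if (any(family_categories == "attenuated_LFS")) {
        category <- "carrier_cancer_free_attenuated_family"
        rationale <- "cancer-free P/LP carrier; attenuated LFS in blood relatives"
      } else {
        category <- "incidental_LFS"
        rationale <- "cancer-free P/LP carrier; no LFS or attenuated LFS in family"
      }
    }
  } else {
    cls <- meets_classic(pedigree, cohort, individual, cfg)
    cha <- meets_chompret_A(pedigree, cohort, individual, cfg)
    if (cls$met || cha$met) {
      category <- "phenotypic_LFS"
      rationale <- c("no P/LP variant",
                     if (cls$met) "meets classic criteria",
                     if (cha$met) "meets Chompret category A")
    } else {
      category <- "not_in_spectrum"
      rationale <- "no P/LP variant; classic and Chompret A not met"
    }
  }
  structure(list(individual_id = individual, category = category,
                 heritable_tp53_related = category %in% heritable_categories,
                 rationale = rationale),
            class = "lfs_spectrum_assignment")
}

# category ignoring the cancer-free-carrier resolution (first pass)
classify_affected_only <- function(pedigree, cohort, individual, cfg) {
  ind <- cohort$individuals[cohort$individuals$individual_id == individual, ,
                            drop = FALSE]
  pdx <- diagnoses_of(cohort, individual)
  if (!is_plp_carrier(ind) || nrow(pdx) == 0) return("unresolved")
  if (childhood_cancer(cohort, individual) ||
        meets_testing_criteria(pedigree, cohort, individual, cfg)$met ||
        has_additional_qualifying_tumor(pdx)) "LFS" else "attenuated_LFS"
}

#' Classify a whole cohort
#'
#' Two-pass evaluation: affected individuals and non-carriers are
#' classified first, then cancer-free carriers are placed using their blood
#' relatives' resolved categories, so the result is a fixed point of
#' re-classification. Also returns a per-family summary holding the most
#' severe category present (LFS > attenuated > cancer-free carrier states >
#' incidental > phenotypic > none).
#'
#' @param cohort An `lfs_cohort`.
#' @param cfg A [criteria_config()].
#' @return A list with `assignments` (data frame: `individual_id`,
#'   `family_id`, `category`, `heritable_tp53_related`, `rationale`) and
#'   `families` (data frame: `family_id`, `category`).
#' @export
classify_cohort <- function(cohort, cfg = criteria_config()) {
  ind <- cohort$individuals
  rows <- vector("list", nrow(ind))
  peds <- lapply(stats::setNames(nm = unique(ind$family_id)),
                 function(f) build_pedigree(cohort, f))
  # pass 1: categories that do not depend on relatives' final categories
  first_pass <- stats::setNames(rep("unresolved", nrow(ind)),
                                ind$individual_id)
  for (i in seq_len(nrow(ind))) {
    first_pass[i] <- classify_affected_only(peds[[ind$family_id[i]]], cohort,
                                            ind$individual_id[i], cfg)
  }
  # pass 2: full assignment, cancer-free carriers resolved against pass 1
  for (i in seq_len(nrow(ind))) {
    rows[[i]] <- classify_individual(peds[[ind$family_id[i]]], cohort,
                                     ind$individual_id[i], cfg,
                                     family_categories = first_pass)
  }
  assignments <- data.frame(
    individual_id = ind$individual_id,
    family_id = ind$family_id,
    category = vapply(rows, `[[`, character(1), "category"),
    heritable_tp53_related = vapply(rows, `[[`, logical(1),
                                    "heritable_tp53_related"),
    rationale = vapply(rows, function(r) paste(r$rationale, collapse = "; "),
                       character(1)),
    stringsAsFactors = FALSE)
  fam_cat <- tapply(assignments$category, assignments$family_id, function(cats) {
    names(which.max(category_severity[unique(cats)]))
  })
  families <- data.frame(family_id = names(fam_cat),
                         category = unname(as.character(fam_cat)),
                         stringsAsFactors = FALSE)
  list(assignments = assignments, families = families)
}

#' Stratify a classified cohort for tumor-pattern analysis
#'
#' Splits individuals into the group fulfilling genetic-testing criteria or
#' with any cancer before age 18 ("met") and the group with cancer meeting
#' neither condition ("not met"); their diagnoses form the two case sets
#' (one case per tumor, so a patient with two primaries contributes two
#' cases). Cancer-free individuals are reported as strata counts only:
#' unaffected members of families containing a met individual, unaffected
#' members of families whose affected members all missed the criteria, and
#' unaffected members of cancer-free families (the incidental stratum).
#'
#' @param cohort An `lfs_cohort`.
#' @param cfg A [criteria_config()].
#' @return A list with `met_cases` / `not_met_cases` (diagnosis data
#'   frames), `met_ids` / `not_met_ids`, and `strata` (named integer
#'   vector: `met`, `unaffected_met_family`, `not_met`,
#'   `unaffected_not_met_family`, `unaffected_cancer_free_family`).
#' @export
stratify_for_analysis <- function(cohort, cfg = criteria_config()) {
  ind <- cohort$individuals
  peds <- lapply(stats::setNames(nm = unique(ind$family_id)),
                 function(f) build_pedigree(cohort, f))
  has_cancer <- ind$individual_id %in% cohort$diagnoses$individual_id
  met <- vapply(seq_len(nrow(ind)), function(i) {
    id <- ind$individual_id[i]
    has_cancer[i] && (childhood_cancer(cohort, id) ||
      meets_testing_criteria(peds[[ind$family_id[i]]], cohort, id, cfg)$met)
  }, logical(1))
  not_met <- has_cancer & !met
  fam_has_met <- tapply(met, ind$family_id, any)
  fam_has_notmet <- tapply(not_met, ind$family_id, any)
  unaffected <- !has_cancer
  strata <- c(
    met = sum(met),
    unaffected_met_family = sum(unaffected & fam_has_met[ind$family_id]),
    not_met = sum(not_met),
    unaffected_not_met_family = sum(unaffected &
      !fam_has_met[ind$family_id] & fam_has_notmet[ind$family_id]),
    unaffected_cancer_free_family = sum(unaffected &
      !fam_has_met[ind$family_id] & !fam_has_notmet[ind$family_id]))
  met_ids <- ind$individual_id[met]
  not_met_ids <- ind$individual_id[not_met]
  dx <- cohort$diagnoses
  list(met_cases = dx[dx$individual_id %in% met_ids, , drop = FALSE],
       not_met_cases = dx[dx$individual_id %in% not_met_ids, , drop = FALSE],
       met_ids = met_ids, not_met_ids = not_met_ids, strata = strata)
}

#' Write an assignments table
#'
#' One CSV row per person: `individual_id`, `category`,
#' `heritable_tp53_related`, `rationale` (semicolon-joined).
#'
#' @param assignments The `assignments` element of [classify_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(assignments[c("individual_id", "category",
                                 "heritable_tp53_related", "rationale")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}
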