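# Controlled vocabularies shared by the cohort tables, the criteria engine
# and the tabulation code. The site list is the organ/tissue stratification
# used throughout; the morphology list covers the sarcoma and brain-tumor
# histologies plus the special tumor types that carry classification weight
# (osteosarcoma, childhood hypodiploid ALL, SHH-medulloblastoma).

#' Tumor site vocabulary
#'
#' The closed set of organ/tissue labels accepted in the `site` column of a
#' diagnoses table. Unknown labels are coerced to `"not_specified"` on read.
#'
#' @return Character vector of valid site labels.
#' @export
lfs_sites <- function() {
  c("breast", "soft_tissues", "adrenal_gland", "brain", "bones",
    "hematopoietic", "lung", "colon_rectum", "ovary", "liver", "prostate",
    "skin", "stomach", "kidney", "pancreas", "not_specified")
}

#' Tumor morphology vocabulary
#'
#' Histology labels accepted in the `morphology` column. Unknown labels are
#' coerced to `"other"` on read; a missing morphology is permitted and means
#' no detailed morphological information was available.
#'
#' @return Character vector of valid morphology labels.
#' @export
lfs_morphologies <- function() {
  c("fibrosarcoma", "leiomyosarcoma", "liposarcoma", "rhabdomyosarcoma",
    "malignant_fibrous_histiocytoma", "sarcoma_other", "sarcoma_nos",
    "astrocytoma", "choroid_plexus_carcinoma", "ependymoma",
    "glioblastoma_glioma", "medulloblastoma", "pnet", "brain_other",
    "cancer_nos", "osteosarcoma", "hypodiploid_all", "shh_medulloblastoma",
    "breast_carcinoma", "other")
}

#' Clinical-significance classes
#'
#' Variant pathogenicity classes accepted in the `clinsig` column. `P_LP`
#' groups pathogenic and likely pathogenic; `LB_B` groups likely benign and
#' benign.
#'
#' @return Character vector of valid classes.
#' @export
lfs_clinsig_classes <- function() {
  c("P_LP", "VUS", "conflicting", "LB_B", "unknown")
}

# morphology -> sites where it may occur; NULL entry means any site
morphology_site_map <- function() {
  list(
    fibrosarcoma = "soft_tissues",
    leiomyosarcoma = "soft_tissues",
    liposarcoma = "soft_tissues",
    rhabdomyosarcoma = "soft_tissues",
    malignant_fibrous_histiocytoma = "soft_tissues",
    sarcoma_other = c("soft_tissues", "bones"),
    sarcoma_nos = c("soft_tissues", "bones"),
    astrocytoma = "brain",
    choroid_plexus_carcinoma = "brain",
    ependymoma = "brain",
    glioblastoma_glioma = "brain",
    medulloblastoma = "brain",
    pnet = "brain",
    brain_other = "brain",
    osteosarcoma = "bones",
    hypodiploid_all = "hematopoietic",
    shh_medulloblastoma = "brain",
    breast_carcinoma = "breast",
    cancer_nos = NULL,
    other = NULL
  )
}
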