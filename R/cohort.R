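# Cohort container: an individuals table (one row per person, with pedigree
# links and germline TP53 variant call) and a long-format diagnoses table
# (one row per tumor). Both are plain data.frames wrapped in an S3 class so
# validation travels with the object.

individuals_columns <- c("family_id", "individual_id", "father_id",
                         "mother_id", "sex", "hgvs_p", "clinsig", "mosaic",
                         "clonal_hematopoiesis", "proband")
diagnoses_columns <- c("individual_id", "site", "morphology", "age_at_dx",
                       "premenopausal")

#' Construct a cohort
#'
#' Bundles an individuals table and a diagnoses table into a validated
#' `lfs_cohort`. The individuals table has one row per person with columns
#' `family_id`, `individual_id`, `father_id`, `mother_id`, `sex`
#' (`male`/`female`/`unknown`), `hgvs_p` (protein-level TP53 variant, `NA`
#' when untested or variant-negative), `clinsig` (see
#' [lfs_clinsig_classes()]), `mosaic`, `clonal_hematopoiesis` and `proband`
#' (logicals). The diagnoses table has one row per tumor with columns
#' `individual_id`, `site`, `morphology`, `age_at_dx` (years) and
#' `premenopausal` (logical, breast cancers only, `NA` when unknown).
#'
#' @param individuals Data frame of individuals.
#' @param diagnoses Data frame of diagnoses; may have zero rows.
#' @return An object of class `lfs_cohort`: a list with elements
#'   `individuals` and `diagnoses`.
#' @export
new_cohort <- function(individuals, diagnoses) {
  individuals <- normalize_individuals(individuals)
  diagnoses <- normalize_diagnoses(diagnoses)
  cohort <- structure(list(individuals = individuals, diagnoses = diagnoses),
                      class = "lfs_cohort")
  validate_cohort(cohort)
  cohort
}

empty_diagnoses <- function() {
  data.frame(individual_id = character(), site = character(),
             morphology = character(), age_at_dx = numeric(),
             premenopausal = logical(), stringsAsFactors = FALSE)
}

normalize_individuals <- function(df) {
  missing_cols <- setdiff(individuals_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("individuals table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[individuals_columns]
  for (col in c("family_id", "individual_id", "father_id", "mother_id",
                "sex", "hgvs_p", "clinsig")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][!is.na(df[[col]]) & df[[col]] == ""] <- NA_character_
  }
  for (col in c("mosaic", "clonal_hematopoiesis", "proband")) {
    df[[col]] <- parse_logical(df[[col]], col)
    df[[col]][is.na(df[[col]])] <- FALSE
  }
  df$sex[is.na(df$sex)] <- "unknown"
  bad_sex <- setdiff(unique(df$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  bad_cs <- setdiff(unique(df$clinsig[!is.na(df$clinsig)]),
                    lfs_clinsig_classes())
  if (length(bad_cs) > 0) {
    warning("unknown clinsig value(s) coerced to 'unknown': ",
            paste(bad_cs, collapse = ", "), call. = FALSE)
    df$clinsig[df$clinsig %in% bad_cs] <- "unknown"
  }
  rownames(df) <- NULL
  df
}

normalize_diagnoses <- function(df) {
  if (is.null(df) || nrow(df) == 0) return(empty_diagnoses())
  missing_cols <- setdiff(diagnoses_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("diagnoses table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[diagnoses_columns]
  df$individual_id <- as.character(df$individual_id)
  df$site <- as.character(df$site)
  df$morphology <- as.character(df$morphology)
  df$morphology[!is.na(df$morphology) & df$morphology == ""] <- NA_character_
  df$age_at_dx <- as.numeric(df$age_at_dx)
  df$premenopausal <- parse_logical(df$premenopausal, "premenopausal")

  unknown_sites <- setdiff(unique(df$site), lfs_sites())
  if (length(unknown_sites) > 0) {
    warning("unknown site value(s) mapped to 'not_specified': ",
            paste(unknown_sites, collapse = ", "), call. = FALSE)
    df$site[df$site %in% unknown_sites | is.na(df$site)] <- "not_specified"
  }
  df$site[is.na(df$site)] <- "not_specified"
  unknown_morph <- setdiff(unique(df$morphology[!is.na(df$morphology)]),
                           lfs_morphologies())
  if (length(unknown_morph) > 0) {
    warning("unknown morphology value(s) mapped to 'other': ",
            paste(unknown_morph, collapse = ", "), call. = FALSE)
    df$morphology[df$morphology %in% unknown_morph] <- "other"
  }
  rownames(df) <- NULL
  df
}

parse_logical <- function(x, col) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- !is.na(x) & x != "" & x != "NA" & is.na(out)
  if (any(bad)) {
    stop("column '", col, "' contains non-logical value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Validate a cohort
#'
#' Checks uniqueness of individual ids, referential integrity of parent and
#' diagnosis links (parents must belong to the same family), non-negative
#' diagnosis ages and site/morphology consistency (e.g. rhabdomyosarcoma
#' implies soft tissues).
#'
#' @param cohort An `lfs_cohort`.
#' @return The cohort, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_cohort <- function(cohort) {
  ind <- cohort$individuals
  dx <- cohort$diagnoses
  dup <- ind$individual_id[duplicated(ind$individual_id)]
  if (length(dup) > 0) {
    stop("duplicated individual_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  fam_of <- stats::setNames(ind$family_id, ind$individual_id)
  for (col in c("father_id", "mother_id")) {
    ref <- ind[[col]]
    present <- !is.na(ref)
    dangling <- ref[present & !(ref %in% ind$individual_id)]
    if (length(dangling) > 0) {
      stop("referential-integrity error: ", col,
           " references unknown individual(s): ",
           paste(unique(dangling), collapse = ", "), call. = FALSE)
    }
    cross <- present & fam_of[ref] != ind$family_id
    if (any(cross, na.rm = TRUE)) {
      stop("referential-integrity error: ", col,
           " crosses family boundaries for individual(s): ",
           paste(ind$individual_id[which(cross)], collapse = ", "),
           call. = FALSE)
    }
  }
  if (nrow(dx) > 0) {
    dangling <- dx$individual_id[!(dx$individual_id %in% ind$individual_id)]
    if (length(dangling) > 0) {
      stop("referential-integrity error: diagnoses reference unknown ",
           "individual(s): ", paste(unique(dangling), collapse = ", "),
           call. = FALSE)
    }
    if (any(is.na(dx$age_at_dx)) || any(dx$age_at_dx < 0)) {
      stop("age_at_dx must be a non-negative number", call. = FALSE)
    }
    msm <- morphology_site_map()
    has_m <- !is.na(dx$morphology)
    for (i in which(has_m)) {
      allowed <- msm[[dx$morphology[i]]]
      if (!is.null(allowed) && !(dx$site[i] %in% allowed)) {
        stop("morphology '", dx$morphology[i], "' is inconsistent with site '",
             dx$site[i], "' for individual ", dx$individual_id[i],
             call. = FALSE)
      }
    }
  }
  # pedigree edges must be acyclic within each family
  for (fam in unique(ind$family_id)) {
    build_pedigree(cohort, fam) # errors on cycles
  }
  invisible(cohort)
}

#' Read a cohort from delimited tables
#'
#' Reads the comma-delimited individuals and diagnoses tables (UTF-8, header
#' row; see [new_cohort()] for the column schemas) and returns a validated
#' cohort. Unknown site or morphology strings are mapped to
#' `"not_specified"` / `"other"` with a warning.
#'
#' @param individuals_path Path to the individuals CSV.
#' @param diagnoses_path Path to the diagnoses CSV.
#' @return An `lfs_cohort`.
#' @export
read_cohort <- function(individuals_path, diagnoses_path) {
  for (p in c(individuals_path, diagnoses_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  ind <- utils::read.csv(individuals_path, colClasses = "character",
                         na.strings = c("", "NA"), encoding = "UTF-8")
  dx <- utils::read.csv(diagnoses_path, colClasses = "character",
                        na.strings = c("", "NA"), encoding = "UTF-8")
  new_cohort(ind, dx)
}

#' Write a cohort to delimited tables
#'
#' Emits `individuals.csv` and `diagnoses.csv` in the same schema
#' [read_cohort()] accepts, so that writing and re-reading reproduces the
#' cohort.
#'
#' @param cohort An `lfs_cohort`.
#' @param out_dir Output directory (created if absent).
#' @return Named character vector with the two file paths, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "lfs_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(individuals = file.path(out_dir, "individuals.csv"),
             diagnoses = file.path(out_dir, "diagnoses.csv"))
  utils::write.csv(cohort$individuals, paths[["individuals"]],
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$diagnoses, paths[["diagnoses"]],
                   row.names = FALSE, na = "")
  invisible(paths)
}

#' Export a cohort in PED dialect
#'
#' Writes one row per individual with columns family id, individual id,
#' father (0 when unknown), mother (0), sex (1 = male, 2 = female,
#' 0 = unknown) and affection status (2 = any cancer diagnosis, 1 = none),
#' tab-delimited without header, for interoperability with pedigree tools.
#'
#' @param cohort An `lfs_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(cohort, path) {
  ind <- cohort$individuals
  affected <- ind$individual_id %in% cohort$diagnoses$individual_id
  ped <- data.frame(
    fid = ind$family_id,
    iid = ind$individual_id,
    father = ifelse(is.na(ind$father_id), "0", ind$father_id),
    mother = ifelse(is.na(ind$mother_id), "0", ind$mother_id),
    sex = c(male = 1L, female = 2L, unknown = 0L)[ind$sex],
    affection = ifelse(affected, 2L, 1L),
    stringsAsFactors = FALSE)
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.lfs_cohort <- function(x, ...) {
  cat("<lfs_cohort> ", nrow(x$individuals), " individuals in ",
      length(unique(x$individuals$family_id)), " families; ",
      nrow(x$diagnoses), " diagnoses\n", sep = "")
  invisible(x)
}

#' Diagnoses of one individual
#'
#' @param cohort An `lfs_cohort`.
#' @param individual_id Individual id.
#' @return Data frame of that individual's diagnoses, sorted by age.
#' @export
diagnoses_of <- function(cohort, individual_id) {
  dx <- cohort$diagnoses[cohort$diagnoses$individual_id == individual_id, ,
                         drop = FALSE]
  dx[order(dx$age_at_dx), , drop = FALSE]
}
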