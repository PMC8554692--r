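# Synthetic family-history generator. Families are built from templates
# that force a known clinical presentation by construction (classic
# pattern, Chompret-A familial pattern, category-B-only tumor without a
# variant, attenuated adult-onset cancer, incidental cancer-free carriage,
# Brazilian p.R337H founder carriage with childhood adrenocortical
# carcinoma, and a variant-negative classic-pattern family), so the
# intended spectrum category of every family is known ground truth.
# Tumor types follow the age-related phases of the syndrome: childhood
# (0-15 y) adrenocortical carcinoma, choroid plexus carcinoma,
# rhabdomyosarcoma and medulloblastoma; a childhood-to-young-adulthood
# transition with osteosarcoma, leukemia and gliomas; early adulthood
# (16-50 y) breast, gastrointestinal and lung cancers and sarcomas; and
# late adulthood (51-80 y) pancreatic and prostate cancer.

sim_templates <- c("classic_LFS", "chompret_A", "chompret_B_only",
                   "attenuated", "incidental", "founder_r337h",
                   "phenotypic_no_variant")

template_intent <- c(classic_LFS = "LFS", chompret_A = "LFS",
                     chompret_B_only = "not_in_spectrum",
                     attenuated = "attenuated_LFS",
                     incidental = "incidental_LFS",
                     founder_r337h = "LFS",
                     phenotypic_no_variant = "phenotypic_LFS")

#' Simulation configuration
#'
#' The default template mixture loosely mirrors a criteria-ascertained
#' germline TP53 registry: most families present with criteria-meeting
#' disease, founder-variant families make up about 8 percent, and
#' incidental cancer-free carriage is uncommon. Ages are drawn uniformly
#' within the age-phase windows (the phases are stated as windows, not
#' hazards) and rounded to 0.1 years; the transition phase, whose numeric
#' bounds are not standardized, defaults to 10-25 years.
#'
#' @param n_families Number of families to simulate.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param template_mix Named probabilities over the seven family templates
#'   (must sum to 1).
#' @param penetrance_by_phase Named per-phase probabilities that a proband
#'   of a criteria-meeting carrier family develops an additional tumor in
#'   that phase.
#' @param phase_windows Named list of `c(min, max)` age windows per phase.
#' @param plp_pool Pathogenic/likely pathogenic variant pool (HGVS protein
#'   shorthand): hotspot-codon missense changes plus variants reported in
#'   criteria-meeting or attenuated presentations; sampled uniformly.
#' @param vus_pool Variants sampled for non-carrier presentations that
#'   carry a VUS rather than no variant.
#' @return A list of class `lfs_sim_config`.
#' @export
sim_config <- function(n_families = 100,
                       seed = 1L,
                       template_mix = c(classic_LFS = 0.15,
                                        chompret_A = 0.22,
                                        chompret_B_only = 0.18,
                                        attenuated = 0.22,
                                        incidental = 0.05,
                                        founder_r337h = 0.08,
                                        phenotypic_no_variant = 0.10),
                       penetrance_by_phase = c(childhood = 0.20,
                                               transition = 0.15,
                                               early_adult = 0.40,
                                               late_adult = 0.15),
                       phase_windows = list(childhood = c(0, 15),
                                            transition = c(10, 25),
                                            early_adult = c(16, 50),
                                            late_adult = c(51, 80)),
                       plp_pool = c("p.R175H", "p.G245S", "p.R248Q",
                                    "p.R248W", "p.R273H", "p.R282W",
                                    "p.M133T", "p.P152L", "p.C275Y",
                                    "p.C275*", "p.R342*", "p.R342P",
                                    "p.R337C", "p.R110L"),
                       vus_pool = c("p.P72R", "p.N235S", "p.V31I")) {
  if (!setequal(names(template_mix), sim_templates)) {
    stop("template_mix must name exactly the templates: ",
         paste(sim_templates, collapse = ", "), call. = FALSE)
  }
  if (abs(sum(template_mix) - 1) > 1e-8 || any(template_mix < 0)) {
    stop("template_mix probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  structure(list(n_families = as.integer(n_families), seed = as.integer(seed),
                 template_mix = template_mix[sim_templates],
                 penetrance_by_phase = penetrance_by_phase,
                 phase_windows = phase_windows,
                 plp_pool = plp_pool, vus_pool = vus_pool),
            class = "lfs_sim_config")
}

# per-phase (site, morphology, weight) spectra
phase_tumor_spectrum <- function(phase) {
  switch(phase,
    childhood = data.frame(
      site = c("adrenal_gland", "brain", "soft_tissues", "brain"),
      morphology = c(NA, "choroid_plexus_carcinoma", "rhabdomyosarcoma",
                     "medulloblastoma"),
      w = c(0.3, 0.2, 0.3, 0.2), stringsAsFactors = FALSE),
    transition = data.frame(
      site = c("bones", "hematopoietic", "brain"),
      morphology = c("osteosarcoma", NA, "glioblastoma_glioma"),
      w = c(0.4, 0.3, 0.3), stringsAsFactors = FALSE),
    early_adult = data.frame(
      site = c("breast", "colon_rectum", "stomach", "lung", "soft_tissues",
               "soft_tissues", "soft_tissues", "brain"),
      morphology = c("breast_carcinoma", NA, NA, NA, "leiomyosarcoma",
                     "liposarcoma", "sarcoma_nos", "astrocytoma"),
      w = c(0.35, 0.10, 0.05, 0.10, 0.12, 0.08, 0.10, 0.10),
      stringsAsFactors = FALSE),
    late_adult = data.frame(
      site = c("pancreas", "prostate"),
      morphology = c(NA, NA),
      w = c(0.5, 0.5), stringsAsFactors = FALSE),
    stop("unknown phase: ", phase, call. = FALSE))
}

runif1 <- function(window) round(stats::runif(1, window[1], window[2]), 1)

#' Generate a synthetic cohort
#'
#' Deterministic given `cfg$seed` (the caller's RNG state is left
#' untouched). Each family is a three-generation pedigree of seven members
#' (paternal grandparents, father, paternal uncle, married-in mother,
#' proband, sibling) whose variants and diagnoses are constructed so the
#' family realizes its template's intended spectrum category.
#'
#' @param cfg An [sim_config()].
#' @return A list of class `lfs_simulation` with `cohort` (an
#'   `lfs_cohort`) and `truth` (data frame: `family_id`, `template`,
#'   `intended_category`).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "lfs_sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  templates <- sample(sim_templates, cfg$n_families, replace = TRUE,
                      prob = cfg$template_mix)
  fams <- lapply(seq_len(cfg$n_families), function(i) {
    make_family(sprintf("F%04d", i), templates[i], cfg)
  })
  individuals <- do.call(rbind, lapply(fams, `[[`, "individuals"))
  diagnoses <- do.call(rbind, lapply(fams, `[[`, "diagnoses"))
  truth <- data.frame(family_id = sprintf("F%04d", seq_len(cfg$n_families)),
                      template = templates,
                      intended_category = unname(template_intent[templates]),
                      stringsAsFactors = FALSE)
  structure(list(cohort = new_cohort(individuals, diagnoses), truth = truth),
            class = "lfs_simulation")
}

# seven-member, three-generation skeleton; proband is female so breast
# presentations are realizable
family_skeleton <- function(fid) {
  id <- function(role) paste0(fid, "_", role)
  data.frame(
    family_id = fid,
    individual_id = id(c("GF", "GM", "F", "U", "M", "P", "S")),
    father_id = c(NA, NA, id("GF"), id("GF"), NA, id("F"), id("F")),
    mother_id = c(NA, NA, id("GM"), id("GM"), NA, id("M"), id("M")),
    sex = c("male", "female", "male", "male", "female", "female", "male"),
    hgvs_p = NA_character_, clinsig = NA_character_,
    mosaic = FALSE, clonal_hematopoiesis = FALSE,
    proband = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

add_dx <- function(dx, id, site, morphology, age, premenopausal = NA) {
  rbind(dx, data.frame(individual_id = id, site = site,
                       morphology = morphology, age_at_dx = age,
                       premenopausal = premenopausal,
                       stringsAsFactors = FALSE))
}

sample_phase_tumor <- function(phase) {
  spec <- phase_tumor_spectrum(phase)
  spec[sample.int(nrow(spec), 1, prob = spec$w), , drop = FALSE]
}

make_family <- function(fid, template, cfg) {
  ind <- family_skeleton(fid)
  dx <- empty_diagnoses()
  id <- function(role) paste0(fid, "_", role)
  set_variant <- function(role, hgvs, clinsig = "P_LP", mosaic = FALSE) {
    i <- ind$individual_id == id(role)
    ind$hgvs_p[i] <<- hgvs
    ind$clinsig[i] <<- clinsig
    ind$mosaic[i] <<- mosaic
  }
  plp <- function() sample(cfg$plp_pool, 1)
  maybe_vus <- function(role) {
    if (stats::runif(1) < 0.5) set_variant(role, sample(cfg$vus_pool, 1),
                                           "VUS")
  }
  win <- cfg$phase_windows

  if (template == "classic_LFS" || template == "phenotypic_no_variant") {
    # proband sarcoma < 45; father any cancer < 45; uncle sarcoma any age
    dx <- add_dx(dx, id("P"), "soft_tissues", "rhabdomyosarcoma",
                 round(stats::runif(1, 2, 40), 1))
    dx <- add_dx(dx, id("F"), "colon_rectum", NA,
                 round(stats::runif(1, 25, 44.5), 1))
    dx <- add_dx(dx, id("U"), "bones", "osteosarcoma",
                 round(stats::runif(1, 15, 60), 1))
    if (template == "classic_LFS") {
      set_variant("P", plp(), mosaic = stats::runif(1) < 0.03)
    } else {
      maybe_vus("P")
    }
  } else if (template == "chompret_A") {
    # proband core tumor < 46 plus one relative with a core tumor < 56;
    # only one affected relative, so the classic criteria cannot fire
    dx <- add_dx(dx, id("P"), "soft_tissues", "leiomyosarcoma",
                 round(stats::runif(1, 18, 45.5), 1))
    age_m <- round(stats::runif(1, 35, 49), 1)
    dx <- add_dx(dx, id("M"), "breast", "breast_carcinoma", age_m,
                 premenopausal = TRUE)
    set_variant("P", plp())
  } else if (template == "chompret_B_only") {
    # category-B tumor, no family history, no P/LP variant
    dx <- add_dx(dx, id("P"), "adrenal_gland", NA,
                 round(stats::runif(1, 0.5, 10), 1))
    maybe_vus("P")
  } else if (template == "attenuated") {
    # carrier with a single adult-onset, non-core tumor and silent family
    pick <- sample(3, 1)
    if (pick == 1) {
      dx <- add_dx(dx, id("P"), "lung", NA, runif1(c(46, 60)))
    } else if (pick == 2) {
      dx <- add_dx(dx, id("P"), "colon_rectum", NA, runif1(c(46, 60)))
    } else {
      dx <- add_dx(dx, id("P"), "breast", "breast_carcinoma",
                   runif1(c(50, 65)), premenopausal = FALSE)
    }
    set_variant("P", plp())
  } else if (template == "incidental") {
    # cancer-free carrier in a cancer-free family
    set_variant("P", plp())
    if (stats::runif(1) < 0.5) set_variant("M", ind$hgvs_p[ind$individual_id == id("P")])
  } else if (template == "founder_r337h") {
    # Brazilian founder carrier ascertained through childhood
    # adrenocortical carcinoma; cascade testing finds a carrier sibling
    dx <- add_dx(dx, id("P"), "adrenal_gland", NA,
                 round(stats::runif(1, 1, 8), 1))
    set_variant("P", "p.R337H")
    set_variant("S", "p.R337H")
  } else {
    stop("unknown template: ", template, call. = FALSE)
  }

  # additional phase-driven primaries for criteria-meeting carrier
  # probands; monotone with respect to the intended category
  if (template %in% c("classic_LFS", "chompret_A", "founder_r337h")) {
    for (phase in names(cfg$penetrance_by_phase)) {
      if (stats::runif(1) < cfg$penetrance_by_phase[[phase]]) {
        tum <- sample_phase_tumor(phase)
        # proband is female: redirect sex-inappropriate sites
        if (tum$site == "prostate") {
          tum$site <- "pancreas"; tum$morphology <- NA_character_
        }
        age <- runif1(win[[phase]])
        dx <- add_dx(dx, id("P"), tum$site, tum$morphology, age,
                     premenopausal = if (tum$site == "breast") age < 50 else NA)
      }
    }
  }
  list(individuals = ind, diagnoses = dx)
}

#' Read / write a simulation configuration
#'
#' JSON serialization of [sim_config()]; absent fields take the defaults.
#'
#' @param path File path.
#' @param cfg An `lfs_sim_config`.
#' @return `read_sim_config` returns an `lfs_sim_config`.
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$template_mix)) x$template_mix <- unlist(x$template_mix)
  if (!is.null(x$penetrance_by_phase)) {
    x$penetrance_by_phase <- unlist(x$penetrance_by_phase)
  }
  if (!is.null(x$phase_windows)) {
    x$phase_windows <- lapply(x$phase_windows, as.numeric)
  }
  do.call(sim_config, x)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  x <- lapply(unclass(cfg), function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Template-recovery confusion report
#'
#' Cross-tabulates each simulated family's intended spectrum category
#' against the category assigned by [classify_cohort()] (the per-family
#' summary), and reports per-template recovery rates.
#'
#' @param sim An `lfs_simulation` from [generate_cohort()].
#' @param classified Result of [classify_cohort()] on `sim$cohort`.
#' @return List with `confusion` (template x assigned-category table) and
#'   `recovery` (named per-template fraction of families whose assigned
#'   category equals the intended one).
#' @export
recovery_report <- function(sim, classified) {
  merged <- merge(sim$truth, classified$families, by = "family_id")
  confusion <- table(template = merged$template, assigned = merged$category)
  recovery <- tapply(merged$category == merged$intended_category,
                     merged$template, mean)
  list(confusion = confusion, recovery = recovery)
}
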