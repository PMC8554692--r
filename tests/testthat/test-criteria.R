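three_gen_ped <- build_pedigree(do.call(rbind, h_three_gen()), "FAM1")

classic_dx <- function(proband_age = 30, father_age = 40, uncle_age = 60) {
  list(h_dx("P", "soft_tissues", proband_age, "rhabdomyosarcoma"),
       h_dx("F", "colon_rectum", father_age),
       h_dx("U", "bones", uncle_age, "osteosarcoma"))
}

test_that("classic criteria: textbook pattern, age gates, lone proband", {
  cohort <- h_cohort(h_three_gen(), classic_dx())
  res <- meets_classic(three_gen_ped, cohort, "P")
  expect_true(res$met)
  expect_true(any(grepl("F", res$trace)))

  # proband sarcoma at 50 fails the age gate
  cohort <- h_cohort(h_three_gen(), classic_dx(proband_age = 50))
  expect_false(meets_classic(three_gen_ped, cohort, "P")$met)

  # no affected relatives
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "soft_tissues", 30, "rhabdomyosarcoma")))
  expect_false(meets_classic(three_gen_ped, cohort, "P")$met)

  # the two qualifying relatives must be distinct: father alone (young
  # cancer, also a sarcoma) cannot serve twice
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "soft_tissues", 30, "rhabdomyosarcoma"),
                          h_dx("F", "soft_tissues", 40, "leiomyosarcoma")))
  expect_false(meets_classic(three_gen_ped, cohort, "P")$met)
})

test_that("chompret A: familial route, multiple-primary route, breast exception", {
  # premenopausal breast at 30 plus mother sarcoma at 40
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "breast", 30, premeno = TRUE),
                          h_dx("M", "soft_tissues", 40, "leiomyosarcoma")))
  expect_true(meets_chompret_A(three_gen_ped, cohort, "P")$met)

  # multiple primaries, two core, first before 46, no family history
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "soft_tissues", 20, "sarcoma_nos"),
                          h_dx("P", "brain", 35, "glioblastoma_glioma")))
  expect_true(meets_chompret_A(three_gen_ped, cohort, "P")$met)

  # two breast primaries only count once
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "breast", 35, premeno = TRUE),
                          h_dx("P", "breast", 40, premeno = TRUE)))
  expect_false(meets_chompret_A(three_gen_ped, cohort, "P")$met)

  # relative qualifies through multiple primaries at any ages
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "brain", 10, "medulloblastoma"),
                          h_dx("GM", "lung", 70), h_dx("GM", "skin", 75)))
  expect_true(meets_chompret_A(three_gen_ped, cohort, "P")$met)

  # age gates: proband at 46 or relative at 56 fail
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "soft_tissues", 46, "sarcoma_nos"),
                          h_dx("M", "soft_tissues", 40, "sarcoma_nos")))
  expect_false(meets_chompret_A(three_gen_ped, cohort, "P")$met)
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "soft_tissues", 40, "sarcoma_nos"),
                          h_dx("M", "breast", 56, premeno = TRUE)))
  expect_false(meets_chompret_A(three_gen_ped, cohort, "P")$met)
})

test_that("chompret B: tumor-type rules and the strict before-31 boundary", {
  acc <- h_cohort(h_three_gen(), list(h_dx("P", "adrenal_gland", 2)))
  expect_true(meets_chompret_B(acc, "P")$met)
  cpc <- h_cohort(h_three_gen(),
                  list(h_dx("P", "brain", 55, "choroid_plexus_carcinoma")))
  expect_true(meets_chompret_B(cpc, "P")$met)
  rms <- h_cohort(h_three_gen(),
                  list(h_dx("P", "soft_tissues", 50, "rhabdomyosarcoma")))
  expect_true(meets_chompret_B(rms, "P")$met)
  expect_false(meets_chompret_B(rms, "P",
                                criteria_config(require_rms_subtype = TRUE))$met)
  b30 <- h_cohort(h_three_gen(), list(h_dx("P", "breast", 30)))
  expect_true(meets_chompret_B(b30, "P")$met)
  b31 <- h_cohort(h_three_gen(), list(h_dx("P", "breast", 31)))
  expect_false(meets_chompret_B(b31, "P")$met)
  gbm <- h_cohort(h_three_gen(),
                  list(h_dx("P", "brain", 40, "glioblastoma_glioma")))
  expect_false(meets_chompret_B(gbm, "P")$met)
})

test_that("combined testing criteria are the disjunction, in order", {
  cohort <- h_cohort(h_three_gen(), classic_dx())
  res <- meets_testing_criteria(three_gen_ped, cohort, "P")
  expect_true(res$met)
  expect_match(res$trace[1], "classic")

  acc <- h_cohort(h_three_gen(), list(h_dx("P", "adrenal_gland", 2)))
  res <- meets_testing_criteria(three_gen_ped, acc, "P")
  expect_true(res$met)
  expect_match(res$trace[1], "chompret_B")

  # adult breast cancer, no family history
  late <- h_cohort(h_three_gen(), list(h_dx("P", "breast", 45)))
  expect_false(meets_testing_criteria(three_gen_ped, late, "P")$met)
})

test_that("disjunction identity holds on random synthetic probands (property)", {
  sim <- generate_cohort(sim_config(n_families = 40, seed = 12))
  cohort <- sim$cohort
  ind <- cohort$individuals
  for (fam in unique(ind$family_id)) {
    ped <- build_pedigree(cohort, fam)
    for (id in ped$members) {
      any_fired <- meets_classic(ped, cohort, id)$met ||
        meets_chompret_A(ped, cohort, id)$met ||
        meets_chompret_B(cohort, id)$met
      expect_identical(meets_testing_criteria(ped, cohort, id)$met, any_fired)
    }
  }
})

test_that("criteria are monotone in added diagnoses (property)", {
  set.seed(31)
  extra_pool <- list(h_dx("X", "adrenal_gland", 3),
                     h_dx("X", "soft_tissues", 25, "rhabdomyosarcoma"),
                     h_dx("X", "breast", 29, premeno = TRUE),
                     h_dx("X", "lung", 60),
                     h_dx("X", "brain", 33, "glioblastoma_glioma"))
  sim <- generate_cohort(sim_config(n_families = 12, seed = 5))
  cohort <- sim$cohort
  fams <- unique(cohort$individuals$family_id)
  for (fam in fams) {
    ped <- build_pedigree(cohort, fam)
    proband <- cohort$individuals$individual_id[
      cohort$individuals$family_id == fam & cohort$individuals$proband]
    before <- vapply(list(meets_classic(ped, cohort, proband),
                          meets_chompret_A(ped, cohort, proband),
                          meets_chompret_B(cohort, proband)),
                     `[[`, logical(1), "met")
    target <- sample(ped$members, 1)
    extra <- extra_pool[[sample(length(extra_pool), 1)]]
    extra$individual_id <- target
    aug <- new_cohort(cohort$individuals, rbind(cohort$diagnoses, extra))
    after <- vapply(list(meets_classic(ped, aug, proband),
                         meets_chompret_A(ped, aug, proband),
                         meets_chompret_B(aug, proband)),
                    `[[`, logical(1), "met")
    expect_true(all(after >= before))
  }
})

test_that("chompret B ignores family structure (property)", {
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "adrenal_gland", 2),
                          h_dx("F", "lung", 50), h_dx("M", "breast", 28)))
  base <- meets_chompret_B(cohort, "P")$met
  # permute the relatives' diagnoses among relatives
  permuted <- h_cohort(h_three_gen(),
                       list(h_dx("P", "adrenal_gland", 2),
                            h_dx("GM", "lung", 50), h_dx("S", "breast", 28)))
  expect_identical(meets_chompret_B(permuted, "P")$met, base)
})

test_that("childhood cancer rule is strict at 18", {
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "soft_tissues", 4, "rhabdomyosarcoma"),
                          h_dx("S", "breast", 18)))
  expect_true(childhood_cancer(cohort, "P"))
  expect_false(childhood_cancer(cohort, "S"))
  expect_false(childhood_cancer(cohort, "F"))
})

test_that("criteria config serializes and validates", {
  d <- withr::local_tempdir()
  cfg <- criteria_config(chompret_breast_age = 36)
  p <- file.path(d, "cfg.json")
  write_criteria_config(cfg, p)
  expect_equal(read_criteria_config(p), cfg)
  expect_error(criteria_config(classic_proband_age = -1), "positive")
  shipped <- read_criteria_config(system.file("extdata",
                                              "criteria_default.json",
                                              package = "lfspectrum"))
  expect_equal(shipped, criteria_config())
})
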