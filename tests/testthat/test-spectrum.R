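# carrier helper: three-generation family whose proband carries a P/LP
# variant, with optional diagnosis rows
carrier_family <- function(dx = NULL, proband_variant = "p.R248Q",
                           extra = identity) {
  ind <- h_three_gen()
  ind[[6]]$hgvs_p <- proband_variant
  ind[[6]]$clinsig <- "P_LP"
  h_cohort(extra(ind), dx)
}

ped_of <- function(cohort, fam = "FAM1") build_pedigree(cohort, fam)

test_that("carrier decision rules reproduce the definitional examples", {
  # P/LP carrier with childhood rhabdomyosarcoma -> LFS
  cohort <- carrier_family(list(h_dx("P", "soft_tissues", 4,
                                     "rhabdomyosarcoma")))
  a <- classify_individual(ped_of(cohort), cohort, "P")
  expect_equal(a$category, "LFS")
  expect_true(a$heritable_tp53_related)

  # carrier, adult breast cancer, no family history, no criteria
  cohort <- carrier_family(list(h_dx("P", "breast", 45)))
  expect_equal(classify_individual(ped_of(cohort), cohort, "P")$category,
               "attenuated_LFS")

  # carrier, cancer-free, silent family -> incidental
  cohort <- carrier_family()
  a <- classify_individual(ped_of(cohort), cohort, "P")
  expect_equal(a$category, "incidental_LFS")

  # non-carrier in a classic-pattern family -> phenotypic
  cohort <- h_cohort(h_three_gen(),
                     list(h_dx("P", "soft_tissues", 30, "rhabdomyosarcoma"),
                          h_dx("F", "colon_rectum", 40),
                          h_dx("U", "bones", 60, "osteosarcoma")))
  a <- classify_individual(ped_of(cohort), cohort, "P")
  expect_equal(a$category, "phenotypic_LFS")
  expect_false(a$heritable_tp53_related)

  # non-carrier with category-B-only presentation is outside the spectrum
  cohort <- h_cohort(h_three_gen(), list(h_dx("P", "adrenal_gland", 2)))
  expect_equal(classify_individual(ped_of(cohort), cohort, "P")$category,
               "not_in_spectrum")
})

test_that("additional qualifying tumor types upgrade carriers to LFS", {
  # adult osteosarcoma meets no testing criterion but qualifies
  cohort <- carrier_family(list(h_dx("P", "bones", 50, "osteosarcoma")))
  expect_equal(classify_individual(ped_of(cohort), cohort, "P")$category,
               "LFS")
  # hypodiploid ALL counts only in childhood
  cohort <- carrier_family(list(h_dx("P", "hematopoietic", 30,
                                     "hypodiploid_all")))
  expect_equal(classify_individual(ped_of(cohort), cohort, "P")$category,
               "attenuated_LFS")
})

test_that("mosaic P/LP carriers classify as carriers; VUS and clonal
           hematopoiesis do not", {
  dx <- list(h_dx("P", "soft_tissues", 4, "rhabdomyosarcoma"))
  mosaic <- carrier_family(dx, extra = function(ind) {
    ind[[6]]$mosaic <- TRUE; ind
  })
  expect_equal(classify_individual(ped_of(mosaic), mosaic, "P")$category,
               "LFS")
  vus <- h_cohort(local({i <- h_three_gen(); i[[6]]$hgvs_p <- "p.N235S";
                         i[[6]]$clinsig <- "VUS"; i}), dx)
  expect_false(classify_individual(ped_of(vus), vus, "P")$category %in%
                 c("LFS", "attenuated_LFS", "incidental_LFS"))
  ch <- carrier_family(dx, extra = function(ind) {
    ind[[6]]$clonal_hematopoiesis <- TRUE; ind
  })
  expect_false(classify_individual(ped_of(ch), ch, "P")$heritable_tp53_related)
})

test_that("cascade-tested cancer-free carriers inherit the family context", {
  # carrier parent with criteria-meeting sarcoma, cancer-free carrier child
  ind <- h_three_gen()
  ind[[3]]$hgvs_p <- "p.R273H"; ind[[3]]$clinsig <- "P_LP"  # father
  ind[[6]]$hgvs_p <- "p.R273H"; ind[[6]]$clinsig <- "P_LP"  # proband child
  cohort <- h_cohort(ind, list(h_dx("F", "soft_tissues", 4,
                                    "rhabdomyosarcoma")))
  cls <- classify_cohort(cohort)
  cat_of <- with(cls$assignments, setNames(category, individual_id))
  expect_equal(cat_of[["F"]], "LFS")
  expect_equal(cat_of[["P"]], "carrier_cancer_free_LFS_family")

  # attenuated relative instead
  cohort <- h_cohort(ind, list(h_dx("F", "lung", 50)))
  cls <- classify_cohort(cohort)
  cat_of <- with(cls$assignments, setNames(category, individual_id))
  expect_equal(cat_of[["F"]], "attenuated_LFS")
  expect_equal(cat_of[["P"]], "carrier_cancer_free_attenuated_family")

  # a married-in cancer-free carrier is not a blood relative
  ind2 <- h_three_gen()
  ind2[[5]]$hgvs_p <- "p.R273H"; ind2[[5]]$clinsig <- "P_LP"  # mother
  ind2[[3]]$hgvs_p <- "p.R273H"; ind2[[3]]$clinsig <- "P_LP"
  cohort <- h_cohort(ind2, list(h_dx("F", "soft_tissues", 4,
                                     "rhabdomyosarcoma")))
  cls <- classify_cohort(cohort)
  cat_of <- with(cls$assignments, setNames(category, individual_id))
  expect_equal(cat_of[["M"]], "incidental_LFS")
})

test_that("classification is a partition, a fixed point, and respects
           carrier/non-carrier boundaries (property)", {
  sim <- generate_cohort(sim_config(n_families = 50, seed = 23))
  cls1 <- classify_cohort(sim$cohort)
  expect_equal(nrow(cls1$assignments), nrow(sim$cohort$individuals))
  expect_true(all(table(cls1$assignments$individual_id) == 1))
  cls2 <- classify_cohort(sim$cohort)
  expect_identical(cls1$assignments, cls2$assignments)

  ind <- sim$cohort$individuals
  plp <- !is.na(ind$clinsig) & ind$clinsig == "P_LP"
  carrier_cats <- c("LFS", "attenuated_LFS", "incidental_LFS",
                    "carrier_cancer_free_LFS_family",
                    "carrier_cancer_free_attenuated_family")
  expect_true(all(cls1$assignments$category[!plp] %in%
                    c("phenotypic_LFS", "not_in_spectrum")))
  expect_true(all(cls1$assignments$category[plp] %in% carrier_cats))
  expect_identical(cls1$assignments$heritable_tp53_related,
                   cls1$assignments$category %in% carrier_cats)
})

test_that("adding a childhood cancer reclassifies attenuated to LFS", {
  cohort <- carrier_family(list(h_dx("P", "breast", 45)))
  expect_equal(classify_individual(ped_of(cohort), cohort, "P")$category,
               "attenuated_LFS")
  aug <- new_cohort(cohort$individuals,
                    rbind(cohort$diagnoses, h_dx("P", "brain", 10,
                                                 "medulloblastoma")))
  expect_equal(classify_individual(ped_of(aug), aug, "P")$category, "LFS")
})

test_that("stratification partitions individuals and counts cases per tumor", {
  sim <- generate_cohort(sim_config(n_families = 20, seed = 77))
  strata <- stratify_for_analysis(sim$cohort)
  expect_equal(sum(strata$strata), nrow(sim$cohort$individuals))
  expect_equal(nrow(strata$met_cases) + nrow(strata$not_met_cases),
               nrow(sim$cohort$diagnoses))

  # a met individual with two tumors contributes two cases to one group
  cohort <- carrier_family(list(h_dx("P", "soft_tissues", 4,
                                     "rhabdomyosarcoma"),
                                h_dx("P", "brain", 30,
                                     "glioblastoma_glioma")))
  st <- stratify_for_analysis(cohort)
  expect_equal(nrow(st$met_cases), 2)
  expect_equal(nrow(st$not_met_cases), 0)

  # carrier with only late cancer and no criteria lands in not-met
  cohort <- carrier_family(list(h_dx("P", "breast", 45)))
  st <- stratify_for_analysis(cohort)
  expect_equal(st$not_met_ids, "P")
  expect_equal(unname(st$strata[c("met", "not_met")]), c(0L, 1L))
})

test_that("family summary takes the most severe category", {
  ind <- h_three_gen()
  ind[[3]]$hgvs_p <- "p.R273H"; ind[[3]]$clinsig <- "P_LP"
  ind[[6]]$hgvs_p <- "p.R273H"; ind[[6]]$clinsig <- "P_LP"
  cohort <- h_cohort(ind, list(h_dx("F", "soft_tissues", 4,
                                    "rhabdomyosarcoma")))
  cls <- classify_cohort(cohort)
  expect_equal(cls$families$category, "LFS")
})
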