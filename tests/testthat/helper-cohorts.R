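# Builders for small in-code fixtures.

h_individual <- function(id, fid = "FAM1", father = NA, mother = NA,
                         sex = "unknown", hgvs = NA, clinsig = NA,
                         mosaic = FALSE, ch = FALSE, proband = FALSE) {
  data.frame(family_id = fid, individual_id = id,
             father_id = as.character(father), mother_id = as.character(mother),
             sex = sex, hgvs_p = as.character(hgvs),
             clinsig = as.character(clinsig), mosaic = mosaic,
             clonal_hematopoiesis = ch, proband = proband,
             stringsAsFactors = FALSE)
}

h_dx <- function(id, site, age, morphology = NA, premeno = NA) {
  data.frame(individual_id = id, site = site,
             morphology = as.character(morphology), age_at_dx = age,
             premenopausal = premeno, stringsAsFactors = FALSE)
}

h_cohort <- function(ind, dx = NULL) {
  new_cohort(do.call(rbind, ind),
             if (is.null(dx)) NULL else do.call(rbind, dx))
}

# three-generation family: paternal grandparents GF+GM, father F and
# uncle U, married-in mother M, proband P and sibling S
h_three_gen <- function(fid = "FAM1") {
  list(h_individual("GF", fid, sex = "male"),
       h_individual("GM", fid, sex = "female"),
       h_individual("F", fid, "GF", "GM", "male"),
       h_individual("U", fid, "GF", "GM", "male"),
       h_individual("M", fid, sex = "female"),
       h_individual("P", fid, "F", "M", "female", proband = TRUE),
       h_individual("S", fid, "F", "M", "male"))
}

# random multi-generation pedigree without consanguinity: layered founders
# and married-in spouses, up to `n` members
h_random_pedigree <- function(n, fid = "R1") {
  stopifnot(n >= 2)
  rows <- list(h_individual("I1", fid, sex = "male"),
               h_individual("I2", fid, sex = "female"))
  couples <- list(c("I1", "I2"))
  k <- 2
  while (k < n) {
    k <- k + 1
    id <- paste0("I", k)
    if (stats::runif(1) < 0.45 || length(couples) == 0) {
      # child of an existing couple
      cp <- couples[[sample.int(length(couples), 1)]]
      rows[[k]] <- h_individual(id, fid, cp[1], cp[2],
                                sample(c("male", "female"), 1))
    } else {
      # married-in founder paired with a random non-founder-spouse member
      mate <- paste0("I", sample.int(k - 1, 1))
      rows[[k]] <- h_individual(id, fid, sex = sample(c("male", "female"), 1))
      couples[[length(couples) + 1]] <- c(mate, id)
    }
  }
  build_pedigree(do.call(rbind, rows), fid)
}
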