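# Family graph and kinship-degree queries. Degree follows clinical-genetics
# convention (expected genome sharing), not raw graph distance: parents,
# children and full siblings are first degree; grandparents, avuncular pairs
# and half-siblings are second degree. Internally the degree is derived from
# the kinship coefficient phi computed by the standard recursion on parent
# links: for non-inbred relatives the relatedness r = 2*phi halves with each
# degree, so degree = -log2(r).

#' Build a family pedigree
#'
#' Extracts one family from a cohort (or from a raw individuals data frame)
#' as a pedigree graph supporting kinship queries. Parent links must be
#' acyclic.
#'
#' @param x An `lfs_cohort` or an individuals data frame.
#' @param family_id Family to extract.
#' @return An object of class `lfs_pedigree` with elements `family_id`,
#'   `members` (character vector of ids), and named parent vectors `father`
#'   and `mother` (`NA` for founders).
#' @export
build_pedigree <- function(x, family_id) {
  ind <- if (inherits(x, "lfs_cohort")) x$individuals else x
  fam <- ind[ind$family_id == family_id, , drop = FALSE]
  if (nrow(fam) == 0) stop("no such family: ", family_id, call. = FALSE)
  ped <- structure(list(
    family_id = family_id,
    members = fam$individual_id,
    father = stats::setNames(fam$father_id, fam$individual_id),
    mother = stats::setNames(fam$mother_id, fam$individual_id)
  ), class = "lfs_pedigree")
  assert_acyclic(ped)
  ped
}

assert_acyclic <- function(ped) {
  state <- stats::setNames(rep(0L, length(ped$members)), ped$members) # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (is.na(id) || !(id %in% ped$members)) return(invisible())
    if (state[[id]] == 1L) {
      stop("pedigree parent links contain a cycle involving ", id,
           call. = FALSE)
    }
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    visit(ped$father[[id]])
    visit(ped$mother[[id]])
    state[[id]] <<- 2L
    invisible()
  }
  for (m in ped$members) visit(m)
  invisible(ped)
}

check_member <- function(ped, id) {
  if (!(id %in% ped$members)) {
    stop("individual ", id, " is not in family ", ped$family_id,
         call. = FALSE)
  }
}

# generation depth: founders 0, child = 1 + max(parent depths)
ped_depths <- function(ped) {
  depth <- stats::setNames(rep(NA_real_, length(ped$members)), ped$members)
  get_depth <- function(id) {
    if (!is.na(depth[[id]])) return(depth[[id]])
    f <- ped$father[[id]]; m <- ped$mother[[id]]
    d <- 0
    if (!is.na(f)) d <- max(d, get_depth(f) + 1)
    if (!is.na(m)) d <- max(d, get_depth(m) + 1)
    depth[[id]] <<- d
    d
  }
  for (id in ped$members) get_depth(id)
  depth
}

# kinship coefficient phi(a, b) by the classic recursion on parent links
kinship_phi <- function(ped, a, b, depth = NULL, memo = new.env(parent = emptyenv())) {
  if (is.null(depth)) depth <- ped_depths(ped)
  phi <- function(a, b) {
    if (is.na(a) || is.na(b)) return(0)
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      0.5 * (1 + phi(ped$father[[a]], ped$mother[[a]]))
    } else {
      # recurse on the member further from the founders
      if (depth[[a]] >= depth[[b]]) {
        0.5 * (phi(ped$father[[a]], b) + phi(ped$mother[[a]], b))
      } else {
        0.5 * (phi(a, ped$father[[b]]) + phi(a, ped$mother[[b]]))
      }
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Kinship degree between two family members
#'
#' Returns 1 for parent-child and full siblings, 2 for grandparent-
#' grandchild, avuncular pairs and half-siblings, 3 for first cousins, and
#' so on; `NA` for pairs with no genealogical connection (e.g. two
#' married-in founders). The degree is `round(-log2(r))` with `r` the
#' relatedness coefficient, so in consanguineous pedigrees the closest
#' (combined) relationship governs.
#'
#' @param pedigree An `lfs_pedigree`.
#' @param a,b Distinct individual ids in the pedigree.
#' @return Positive integer degree, or `NA` if unrelated.
#' @export
kinship_degree <- function(pedigree, a, b) {
  check_member(pedigree, a)
  check_member(pedigree, b)
  if (a == b) stop("kinship_degree requires two distinct individuals",
                   call. = FALSE)
  r <- 2 * kinship_phi(pedigree, a, b)
  if (r <= 0) return(NA_integer_)
  as.integer(round(-log2(r)))
}

#' Relatives within a kinship degree
#'
#' All family members whose kinship degree with `a` is at most `max_degree`
#' (excluding `a` itself and genealogically unconnected members).
#'
#' @param pedigree An `lfs_pedigree`.
#' @param a Individual id.
#' @param max_degree Maximum degree, typically 1 or 2.
#' @return Character vector of individual ids (possibly empty).
#' @export
relatives_within_degree <- function(pedigree, a, max_degree) {
  check_member(pedigree, a)
  others <- setdiff(pedigree$members, a)
  if (length(others) == 0) return(character())
  depth <- ped_depths(pedigree)
  memo <- new.env(parent = emptyenv())
  deg <- vapply(others, function(b) {
    r <- 2 * kinship_phi(pedigree, a, b, depth, memo)
    if (r <= 0) NA_real_ else round(-log2(r))
  }, numeric(1))
  others[!is.na(deg) & deg <= max_degree]
}

#' Blood relatives of an individual
#'
#' All family members genealogically connected to `a` at any degree.
#'
#' @inheritParams relatives_within_degree
#' @return Character vector of individual ids.
#' @export
blood_relatives <- function(pedigree, a) {
  relatives_within_degree(pedigree, a, Inf)
}

#' @export
print.lfs_pedigree <- function(x, ...) {
  cat("<lfs_pedigree> family ", x$family_id, ": ", length(x$members),
      " members\n", sep = "")
  invisible(x)
}
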