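# TP53 protein-variant shorthand: parsing, hotspot and domain annotation,
# and the cohort-level exclusion filters (p.R337H Brazilian founder
# carriers; suspected clonal hematopoiesis).

aa3_to_1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
              Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
              Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
              Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
              Ter = "*")

#' Parse protein-level HGVS shorthand
#'
#' Accepts the forms `p.R337H` (missense), `p.C275*` (nonsense) and
#' `p.R175` (codon-only mention), with one- or three-letter amino-acid
#' codes (`p.Arg337His`, `p.Cys275Ter`) and a case-tolerant `p.` prefix.
#'
#' @param text Variant string.
#' @param max_codon Highest valid codon; 393 for full-length p53.
#' @return A list of class `lfs_variant` with fields `ref_aa`, `codon`,
#'   `alt` (`NA` for codon-only) and `kind`
#'   (`missense`/`nonsense`/`codon_only`).
#' @export
parse_hgvs_p <- function(text, max_codon = 393) {
  if (length(text) != 1 || is.na(text) || !nzchar(trimws(text))) {
    stop("cannot parse empty variant string", call. = FALSE)
  }
  raw <- trimws(text)
  s <- sub("^[pP]\\.", "", raw)
  one <- "[ACDEFGHIKLMNPQRSTVWY]"
  three <- paste0("(", paste(names(aa3_to_1), collapse = "|"), ")")
  norm_aa <- function(x) {
    if (nchar(x) == 1) return(toupper(x))
    key <- paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, 3)))
    unname(aa3_to_1[key])
  }
  m <- regmatches(s, regexec(paste0(
    "^(", one, "|", three, ")([0-9]+)(\\*|", one, "|", three, ")?$"), s,
    ignore.case = TRUE))[[1]]
  if (length(m) == 0) {
    stop("cannot parse protein variant: '", raw, "'", call. = FALSE)
  }
  ref <- norm_aa(m[2])
  codon <- as.integer(m[4])
  alt_raw <- m[5]
  if (is.na(ref)) stop("cannot parse protein variant: '", raw, "'",
                       call. = FALSE)
  if (is.na(codon) || codon < 1 || codon > max_codon) {
    stop("codon out of range [1, ", max_codon, "]: '", raw, "'",
         call. = FALSE)
  }
  if (is.na(alt_raw) || alt_raw == "") {
    alt <- NA_character_; kind <- "codon_only"
  } else if (alt_raw == "*" || tolower(alt_raw) == "ter") {
    alt <- "*"; kind <- "nonsense"
  } else {
    alt <- norm_aa(alt_raw)
    if (is.na(alt)) stop("cannot parse protein variant: '", raw, "'",
                         call. = FALSE)
    kind <- "missense"
  }
  structure(list(ref_aa = ref, codon = codon, alt = alt, kind = kind),
            class = "lfs_variant")
}

#' Format a parsed variant back to canonical shorthand
#'
#' Inverse of [parse_hgvs_p()]: one-letter codes with `p.` prefix.
#'
#' @param v An `lfs_variant`.
#' @return Canonical string such as `"p.R337H"`.
#' @export
format_hgvs_p <- function(v) {
  stopifnot(inherits(v, "lfs_variant"))
  paste0("p.", v$ref_aa, v$codon,
         if (v$kind == "codon_only") "" else v$alt)
}

#' Hotspot codons of TP53
#'
#' @return Integer vector of the recurrently mutated DNA-binding-domain
#'   codons: 175, 245, 248, 273, 282.
#' @export
hotspot_codons <- function() c(175L, 245L, 248L, 273L, 282L)

#' Is a variant at a hotspot codon?
#'
#' @param v An `lfs_variant` (or a string, parsed on the fly).
#' @return `TRUE` iff the codon is one of [hotspot_codons()]. The p.R337H
#'   founder variant is not a hotspot.
#' @export
is_hotspot <- function(v) {
  if (is.character(v)) v <- parse_hgvs_p(v)
  v$codon %in% hotspot_codons()
}

#' Default p53 protein-domain map
#'
#' Canonical domain boundaries (UniProt P04637 numbering): transactivation
#' domain (TAD) 1-61, proline-rich region (PR) 64-92, DNA-binding domain
#' (DNAB) 94-312, oligomerization domain (OD) 323-356, C-terminal
#' regulatory domain (CT) 364-393. Codons between intervals are "linker".
#'
#' @return Data frame with columns `domain`, `start`, `end`.
#' @export
default_domain_map <- function() {
  data.frame(domain = c("TAD", "PR", "DNAB", "OD", "CT"),
             start = c(1L, 64L, 94L, 323L, 364L),
             end = c(61L, 92L, 312L, 356L, 393L),
             stringsAsFactors = FALSE)
}

#' Read a domain map from a config file
#'
#' CSV with columns `domain,start,end`; intervals must be ascending and
#' non-overlapping.
#'
#' @param path Config file path.
#' @return Validated domain-map data frame.
#' @export
read_domain_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_domain_map(map)
}

validate_domain_map <- function(map) {
  stopifnot(all(c("domain", "start", "end") %in% names(map)))
  map <- map[order(map$start), , drop = FALSE]
  if (any(map$end < map$start) ||
      any(utils::head(map$end, -1) >= utils::tail(map$start, -1))) {
    stop("domain intervals must be ascending and non-overlapping",
         call. = FALSE)
  }
  map
}

#' Assign a variant to a protein domain
#'
#' @param v An `lfs_variant` (or string).
#' @param map Domain map, by default [default_domain_map()].
#' @return Domain label, or `"linker"` when the codon falls between
#'   intervals.
#' @export
assign_domain <- function(v, map = default_domain_map()) {
  if (is.character(v)) v <- parse_hgvs_p(v)
  map <- validate_domain_map(map)
  hit <- which(map$start <= v$codon & v$codon <= map$end)
  if (length(hit) == 0) "linker" else map$domain[hit[1]]
}

# canonical founder spelling after parse/format normalization
is_r337h <- function(hgvs) {
  if (is.na(hgvs)) return(FALSE)
  v <- tryCatch(parse_hgvs_p(hgvs), error = function(e) NULL)
  !is.null(v) && v$codon == 337L && identical(v$ref_aa, "R") &&
    identical(v$alt, "H")
}

#' Apply the study exclusion filters
#'
#' Removes (by individual) carriers of the Brazilian p.R337H founder
#' variant and/or individuals whose variant call is flagged as suspected
#' clonal hematopoiesis, which mimics a germline result and falls outside
#' the Li-Fraumeni spectrum. Parent links pointing at removed individuals
#' are blanked so the filtered cohort remains valid. If the individuals
#' table carries a `population` column and `r337h_populations` is given,
#' only founder carriers from those populations are removed; by default the
#' filter keys on the variant alone since ancestry is often absent.
#'
#' @param cohort An `lfs_cohort`.
#' @param exclude_r337h Remove p.R337H carriers?
#' @param exclude_clonal_hematopoiesis Remove flagged individuals?
#' @param r337h_populations Optional character vector restricting the
#'   founder exclusion to given `population` labels (case-insensitive).
#' @return List with `cohort` (filtered) and `report` (named counts
#'   `r337h`, `clonal_hematopoiesis`).
#' @export
apply_exclusions <- function(cohort, exclude_r337h = TRUE,
                             exclude_clonal_hematopoiesis = TRUE,
                             r337h_populations = NULL) {
  ind <- cohort$individuals
  drop_r337h <- rep(FALSE, nrow(ind))
  if (exclude_r337h) {
    drop_r337h <- vapply(ind$hgvs_p, is_r337h, logical(1), USE.NAMES = FALSE)
    if (!is.null(r337h_populations) && "population" %in% names(ind)) {
      drop_r337h <- drop_r337h &
        tolower(ind$population) %in% tolower(r337h_populations)
    }
  }
  drop_ch <- if (exclude_clonal_hematopoiesis) {
    ind$clonal_hematopoiesis %in% TRUE
  } else rep(FALSE, nrow(ind))
  report <- c(r337h = sum(drop_r337h, na.rm = TRUE),
              clonal_hematopoiesis = sum(drop_ch & !drop_r337h, na.rm = TRUE))
  drop <- drop_r337h | drop_ch
  dropped_ids <- ind$individual_id[drop]
  ind <- ind[!drop, , drop = FALSE]
  ind$father_id[ind$father_id %in% dropped_ids] <- NA_character_
  ind$mother_id[ind$mother_id %in% dropped_ids] <- NA_character_
  dx <- cohort$diagnoses
  dx <- dx[!(dx$individual_id %in% dropped_ids), , drop = FALSE]
  list(cohort = new_cohort(ind, dx), report = report)
}
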