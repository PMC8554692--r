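---
title: "Methods: classifying cohorts on the Li-Fraumeni spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying cohorts on the Li-Fraumeni spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfspectrum)
```

## The classification problem

Germline pathogenic variants of *TP53* cause Li-Fraumeni syndrome (LFS),
but sequencing of patients ascertained for other reasons increasingly
finds carriers whose personal and family histories do not resemble the
classical syndrome. The Li-Fraumeni *spectrum* resolves this by assigning
each person one of several categories that jointly cover all observed
combinations of variant status and phenotype. `lfspectrum` implements
that assignment as a deterministic rule engine with a full rationale
trace, so cohort-scale analyses are reproducible and auditable.

The decision procedure for an individual is, in order:

1. **Carrier test.** A carrier is a person whose variant call is
   pathogenic/likely pathogenic (P/LP), including germline-mosaic P/LP.
   Calls classified VUS, conflicting, likely benign/benign or unknown are
   treated as non-carriers for category purposes (they remain in all
   analysis tables). A P/LP call flagged as suspected clonal
   hematopoiesis is excluded from the spectrum: the recommended path is
   the `apply_exclusions()` filter; if the flag survives into
   classification, the classifier treats the person as a non-carrier,
   which is the only reading under which the flag has one consistent
   meaning.
2. **Carriers with cancer.** Cancer before age 18 (strictly `< 18`
   years), OR meeting any genetic-testing criterion (classic, Chompret A,
   Chompret B), OR an additional qualifying tumor type — osteosarcoma,
   childhood (`< 18`) hypodiploid acute lymphoblastic leukemia,
   SHH-activated medulloblastoma — gives **LFS**; otherwise
   **attenuated LFS**.
3. **Carriers without cancer.** Placed by their *blood relatives'*
   resolved categories: any LFS relative →
   `carrier_cancer_free_LFS_family`; else any attenuated relative →
   `carrier_cancer_free_attenuated_family`; else **incidental LFS**.
   "Blood relative" means genealogically connected at any degree within
   the family graph, because the defining condition is on the
   person/family, not on a fixed kinship radius.
4. **Non-carriers.** Classic criteria or Chompret category A (the
   familial-presentation / multiple-tumor items) give **phenotypic LFS**;
   everything else — including non-carriers meeting only the
   tumor-type-specific category B — is `not_in_spectrum`.

`classify_cohort()` runs two passes: pass one resolves everyone whose
category does not depend on relatives (steps 2 and 4); pass two places
cancer-free carriers against those results. Because the
cancer-free-carrier states are themselves never inputs to step 3, the
two-pass result is a fixed point — re-running the classifier on its own
output changes nothing, which the test suite asserts.

The per-family summary is the most severe category present, with severity
ordered LFS > attenuated > cancer-free-carrier states > incidental >
phenotypic > none.

## Clinical criteria and their parameters

All cut-offs live in `criteria_config()` so criteria revisions can be
swapped without code changes. Ages are years; "before age N" is strict
(`age_at_dx < N`), so a breast cancer at exactly 31.0 does **not** meet
the Chompret breast item.

| parameter | default | role |
|---|---|---|
| `classic_proband_age` | 45 | proband sarcoma age gate (classic) |
| `classic_relative_age` | 45 | relative any-cancer age gate (classic) |
| `chompret_proband_age` | 46 | proband core-tumor gate (Chompret A) |
| `chompret_relative_age` | 56 | relative core-tumor gate (Chompret A) |
| `chompret_breast_age` | 31 | breast-cancer gate (Chompret B) |
| `premenopausal_fallback_age` | 50 | age proxy when the premenopausal flag is missing |
| `require_rms_subtype` | FALSE | restrict category B to subtype-confirmed rhabdomyosarcoma |

**Classic criteria**: proband sarcoma (soft-tissue, or bone tumor that is
or may be a sarcoma) before 45, AND a first-degree relative with any
cancer before 45, AND a *distinct* first- or second-degree relative with
any cancer before 45 or a sarcoma at any age. The engine searches for an
explicit distinct pair, so one young-sarcoma parent cannot satisfy both
relative slots.

**Chompret A**: (i) proband with a core-spectrum tumor (premenopausal
breast cancer, soft-tissue sarcoma, osteosarcoma, CNS tumor,
adrenocortical carcinoma) before 46 plus a first-/second-degree relative
with a core tumor before 56 or with multiple primaries (≥ 2 at any ages);
or (ii) proband with multiple primaries — multiple breast tumors counted
once (the earliest is kept) — of which ≥ 2 are core, the first before 46.

**Chompret B**: adrenocortical carcinoma or choroid plexus carcinoma at
any age, rhabdomyosarcoma at any age, or breast cancer before 31,
irrespective of family history.

Design choices where the published wording leaves room:

* *Premenopausal breast cancer.* The `premenopausal` flag is used when
  present; otherwise diagnosis before 50 (the typical age at menopause)
  is the proxy, because registry data frequently lack the flag.
* *Bone tumors.* A bone tumor with missing morphology counts as a
  (potential) sarcoma for the classic criterion and as
  osteosarcoma-eligible for the core spectrum; explicitly non-sarcoma
  bone morphologies do not. This is the inclusive reading registry coding
  forces.
* *Rhabdomyosarcoma subtype.* The category-B item nominally requires the
  embryonal anaplastic subtype, which the morphology vocabulary cannot
  express; by default any rhabdomyosarcoma qualifies. Setting
  `require_rms_subtype = TRUE` disables the item instead (only
  subtype-confirmed cases would qualify, and none can be confirmed in
  this schema).
* *Non-carriers meeting classic criteria in variant-positive families*
  are still phenotypic LFS: classification is strictly by the
  individual's own variant status.

## Kinship degree

The criteria speak of first- and second-degree relatives. Degree here is
the clinical-genetics notion — relatives of degree $d$ share on
expectation $(1/2)^d$ of their genome — not graph distance: full siblings
are first degree although the path through the parents has length two,
and avuncular pairs are second degree although the path has length three.
`kinship_degree()` computes the kinship coefficient $\varphi$ by the
standard recursion on parent links (memoized, recursing on the member
further from the founders) and returns
$\mathrm{round}(-\log_2 2\varphi)$, with `NA` for genealogically
unconnected pairs such as married-in founders. Half-siblings come out as
degree 2, first cousins as 3. In consanguineous pedigrees $2\varphi$ sums
over connections, so the *combined* (closest effective) relationship
governs; the random pedigrees used in testing are consanguinity-free, and
there the result provably equals the independent ancestor-path-enumeration
oracle.

## Two-group statistics

`stratify_for_analysis()` splits individuals into the group meeting
testing criteria or with cancer before 18 ("met") versus those with
cancer meeting neither condition ("not met"); *cases* are tumors, so a
patient with two primaries contributes two cases to their group's case
set. Cancer-free individuals contribute no cases and are reported as
three structural strata (unaffected in a met family, in a not-met family,
in a cancer-free family).

For each tumor label the 2×2 table is (label vs all other cases) ×
(met vs not met). The test is the **uncorrected Pearson χ²**
$$X^2 = \frac{N(ad-bc)^2}{(a+b)(c+d)(a+c)(b+d)},\qquad
p = P(\chi^2_1 \ge X^2),$$
switching to the **two-sided Fisher exact test** when any expected cell
count is below 5 (the standard "when appropriate" convention; with it,
the lung, kidney and prostate rows of the published table reproduce under
Pearson, which pins the convention down). Fisher is the
point-probability method: conditioning on both margins, sum the
hypergeometric probabilities of all tables at most as probable as the
observed one. Numerical choices:

* a relative tolerance of `1e-7` on the point-probability comparison
  guards against floating-point ties (same guard as the reference
  implementations);
* a table with a zero row or column margin admits exactly one
  configuration, so p = 1;
* Pearson with a zero margin is an error directing the caller to Fisher;
* percentages use the group case total as denominator at organ level,
  and the morphology-known subset of the organ's cases at histology
  level; empty denominators yield `NA`, never 0;
* p-values are formatted in table style: `<.001` below 0.001, three
  decimals below .01, two decimals otherwise, `>.99` above 0.99. No
  continuity correction, no multiple-testing adjustment; the significance
  guard is p < .01.

When the published tumor-pattern table is reconstructed from its printed
cell counts (the acceptance tests do this), recomputation reproduces the
bounded rows and the `.003`/`.98` rows exactly, while a few printed
values (hematopoietic `.55`, colon-rectum `.05`, "not specified" `.16`,
glioblastoma "38.6") disagree slightly with any test on the printed
counts; the package always recomputes from counts and does not attempt to
match misprints. The printed organ rows also sum to less than the
footnoted case totals (rarer sites are not itemized), so the
reconstruction carries the remainder as `not_specified` cases.

## The synthetic-data generator

`generate_cohort()` emulates the *structure* of a literature-compiled
germline *TP53* registry: families ascertained through a proband,
variants given as protein HGVS with a clinical-significance class, and
age-phase-dependent tumor spectra — childhood (0–15 y: adrenocortical
carcinoma, choroid plexus carcinoma, rhabdomyosarcoma, medulloblastoma),
a childhood-to-young-adulthood transition (osteosarcoma, leukemia,
glioma; numeric bounds are not standardized, we use 10–25 y), early
adulthood (16–50 y: breast, gastrointestinal, lung, sarcomas) and late
adulthood (51–80 y: pancreas, prostate). Ages are uniform within the
phase window (the phases are stated as windows, not hazards) and rounded
to 0.1 y so CSV round-trips are exact.

Each family is drawn from one of seven templates that force a known
presentation by construction — classic pattern, Chompret-A familial
pattern, category-B-only tumor without a P/LP variant, attenuated
adult-onset cancer, incidental cancer-free carriage, p.R337H founder
carriage ascertained through childhood adrenocortical carcinoma (with a
cascade-tested carrier sibling), and a variant-negative classic-pattern
family. The default mixture (0.15, 0.22, 0.18, 0.22, 0.05, 0.08, 0.10)
was set once to loosely mirror a criteria-ascertained registry — founder
families at ~8% matching the reported founder share, criteria-meeting
presentations dominating, incidental carriage uncommon (kept above its
real ~1% so small simulations still contain the category). The P/LP pool
combines hotspot-codon missense changes with variants reported in
criteria-meeting or attenuated presentations; per-phase penetrance
defaults (0.20, 0.15, 0.40, 0.15) add extra primaries to criteria-meeting
probands at roughly the multiple-primary frequency seen in such cohorts.

What the generator deliberately does **not** emulate: real penetrance and
hazard functions, ascertainment bias beyond the template mixture,
untested family members with silent disease, recombination-scale pedigree
variety (every family is the same seven-member, three-generation shape),
and the real registry's absolute composition. A green template-recovery
test therefore establishes that the classifier implements the definitions
(templates force their categories *by construction*, so recovery must be
exact), and that proportions propagate binomially — it does **not**
validate the classifier against real-world coding noise, nor calibrate
any rate to the real database.

Determinism: generation seeds a local RNG and restores the caller's
`.Random.seed`, so the same `sim_config()` always yields byte-identical
cohorts and the generator cannot perturb downstream randomness.

## Degenerate inputs and edge policies

* Unknown site/morphology strings map to `not_specified`/`other` with a
  warning; missing parents are empty fields, and exclusion filters blank
  parent links that would dangle.
* Morphology–site consistency is enforced at validation (e.g.
  rhabdomyosarcoma ⇒ soft tissues); `cancer_nos`/`other` are
  site-agnostic.
* Individuals without diagnosis rows are cancer-free by definition;
  missing-diagnosis lookups never error inside criteria.
* `summarize_ages()` uses age at first diagnosis and excludes cancer-free
  individuals (age at testing is not modeled); empty groups give `NA`.
* Codon bounds: protein positions are validated against full-length p53
  (1–393); the domain map (TAD 1–61, PR 64–92, DNAB 94–312, OD 323–356,
  CT 364–393, canonical UniProt P04637 boundaries) is configurable, with
  inter-domain codons labelled `linker`.

## Known limitations

* The spectrum is defined on P/LP calls taken as input; the package does
  not re-classify variant pathogenicity, and carriers of VUS remain
  outside the carrier categories even though some will be reannotated.
* Longitudinal movement between categories is handled only by re-running
  the classifier on updated data.
* The strata counts approximate the published person-level strata
  structurally; the cancer-free-family stratum includes untested
  unaffected members, which a carriers-only registry would not contain.
* Chompret B's rhabdomyosarcoma item cannot be subtype-restricted with
  the shipped vocabulary (see above).
* Monozygotic twins are treated as ordinary siblings; kinship
  coefficients, inbreeding coefficients and loop-aware degree reporting
  beyond the combined-relationship rule are out of scope.
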