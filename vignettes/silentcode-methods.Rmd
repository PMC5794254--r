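---
title: "Methods: screening isoform families for divergent ribosome densities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening isoform families for divergent ribosome densities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silentcode)
```

## The model

Gene families that encode nearly identical proteins — actins, tubulins,
histones — are the natural place to look for regulation carried by the
*nucleotide* sequence rather than the protein: within such a family the
proteins are almost interchangeable, so any large, reproducible difference in
how heavily each member's mRNA is translated must be driven by features of
the coding sequence itself (or its surrounding gene), not by the protein
product. The screen implemented here formalizes that intuition:

1. pick one representative protein per gene (the longest annotated at the
   locus, ties broken by smallest protein id);
2. connect two genes when their proteins are ≥ 90% identical and within 90%
   of each other's length; families are the connected components of this
   graph (single linkage), and singletons are discarded because the
   divergence statistic needs at least two members;
3. give every member gene a *characteristic ribosome density* — the mean
   per-base ribosome-profiling coverage over the first 150 codons of its
   CDS — and summarize each family by the *normalized standard deviation*
   (coefficient of variation, CV) of member densities;
4. discard families whose best-translated member has density < 1 (they are
   negligibly represented in the polysome fraction), rank the rest by CV
   descending, and select those with CV ≥ 1.4 within the top 100.

The screen is a *ranking*, not a hypothesis test: no p-values or
multiple-testing machinery are attached, faithfully to its origin as a
data-mining step whose top hits were then followed up experimentally.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| identity threshold | 90 | % of longer sequence | the family definition; inclusive `>=` by default (`strict = TRUE` gives `>`), because the phrase "over 90%" does not determine the boundary and the boundary genuinely matters for proteins of length ≤ 10·k |
| length ratio | 0.9 | fraction | "identical in length" gate; applied before aligning, so hopeless pairs are never aligned |
| density window | 150 | codons | the first 150 codons (450 nt) of the CDS, start codon included; shorter CDSs truncate the window rather than being padded |
| density floor | 1.0 | mean reads/base | a family must have one member at or above this; inclusive boundary |
| CV threshold | 1.4 | — | for a two-member family CV is bounded by √2 ≈ 1.414 and approaches it as one member dominates, so 1.4 marks "essentially one-sided translation"; with more members CV can exceed √2 |
| top N | 100 | families | the published cut for follow-up classification |
| aggregation | `sum_tracks` | — | multiple profiling studies are summed base-wise into one composite track before the density is taken; `mean_tracks` (mean of per-track densities) is exposed for robustness checks. The two differ when studies have very different depths; the source analysis used a pre-composited browser track, which `sum_tracks` emulates |

### The "normalized SD"

The divergence statistic is the *sample* coefficient of variation on raw
densities: `sd(d, n-1 denominator) / mean(d)`. Two alternatives were
considered and rejected as the default:

- population SD (n denominator): caps the two-member statistic at 1 and
  makes the 1.4 threshold unreachable for pairs — inconsistent with pairs
  appearing among selected families;
- CV of log densities: ill-defined when the mean log is ≤ 0. Instead the SD
  of log10 densities over strictly positive members is reported alongside
  (`log_sd` in every report) for users who prefer a geometric dispersion
  measure; it never participates in selection.

Scale invariance holds for the statistic and the ranking: multiplying all
densities by c > 0 changes no CV and no rank. The min-density *filter* is
deliberately not scale invariant — it is an absolute depth floor.

## Alignment

Identity is computed from a global Needleman–Wunsch alignment with match +1,
mismatch −1, linear gap −2 — identity screening needs identity fractions,
not homology-search sensitivity, and the simple scoring keeps the test
suite's brute-force enumeration oracle exact. Percent identity divides
matches by the *longer* input length by default (the alignment-length
denominator is available); combined with the 0.9 length-ratio gate this is a
conservative reading of "90% identity over 90% of length" — the original
clustering tool's normalization is not recoverable, so the choice is
documented and configurable rather than guessed.

Two determinism guarantees: traceback ties break diagonal > up > left, and
the DP is bicriteria (optimal score, then maximum matches among co-optimal
alignments), so the reported match count is a property of the input pair
alone and percent identity is exactly symmetric under swapping inputs.

## Codon-level divergence

`codon_align()` pairs codons through the *proteins*: both CDSs are
translated (terminal stop trimmed; "codons affected" plainly refers to sense
codons), the proteins are globally aligned, and gaps map back onto codons;
gapped columns are excluded and counted. Each gapless pair is classified
identical / silent-only / replacement, with "amino acid differs" winning
when a codon carries both kinds of change, so the three classes partition
the compared codons. Codons containing non-ACGT bases are excluded with a
warning. Only the standard genetic code is built in.

## Recoding design

`minimal_recode()` answers: what is the smallest set of point substitutions
that makes gene A's CDS encode protein B? Per codon whose residue must
change, the synonymous codon of the target residue at minimum Hamming
distance is chosen (ties: lexicographically smallest — determinism over
biology, since the tie is genuinely arbitrary). Because the per-codon choices
are independent, the per-codon minimum is the global minimum.

The published knock-in that motivates this tool used *five* edits in the
first ten codons where four suffice for the protein swap: its codon-10 edit
is a two-base change (GTC→ATT) where one base (GTC→ATC) would do. The extra
edit plausibly hardens the design against guide re-cutting, but the minimal
four-edit plan already breaks the protospacer match, so no simple minimality
criterion reproduces the realized design; the package reports the minimum
and exposes a `disrupt:<motif>` constraint (edited CDS must no longer match
the motif where the source did, at minimum added cost) rather than
pretending the five-edit plan is an optimum. The five-edit count itself is
verified directly from the published donor sequence with
`count_substitutions()`.

The wild-type reference for those checks (`actb_wt_5prime()`) is
*reconstructed*, not downloaded: the donor template is published verbatim,
and the five reverted positions are pinned by the published guide
protospacer, the EcoRV recognition site, and the canonical β-actin
N-terminal decapeptide MDDDIAALVV. The two third-position choices this does
not pin (codons 2 and 3) cannot change any substitution count, because both
synonymous options sit one base from the donor codon.

## The synthetic data generator

`generate_dataset()` emulates exactly the statistical structure the screen
consumes: families of near-identical proteins on multi-exon genes (2–5
exons, both strands), with controlled within-family identity (85–100%;
member 1 *is* the ancestor so planted pairwise identity is exact) and
controlled density ratios. Member mean densities are geometrically spaced
from `base_density` (default 2 reads/base, a modestly expressed gene) up to
`base_density × ratio`; default ratios are log-spaced 1–1000, the magnitude
range observed across real isoform families. Per-base counts are negative
binomial (size 0.5 by default — strongly overdispersed, as ribosome
profiling coverage is), drawn per track; three tracks by default, summed by
the screen. Reverse-translation randomizes synonymous codons per member, so
members planted at 100% protein identity still carry silent divergence.

What the generator does *not* emulate — and hence what a green test does not
establish: triplet periodicity and P-site geometry of real footprints
(inputs are already per-base densities), 5′ ramps or pause sites (coverage
is flat in expectation along the CDS), UTRs and promoters, mapping artifacts
between paralogs (reads are never "mapped"; coverage is assigned to the true
gene), and the composition biases of real proteomes. In particular the
published genome-wide counts (741 mouse families, ~4000 ORFs) depend on a
specific genome snapshot and clustering tool and are out of the package's
verification scope.

Under the default world, a three-member family at ratio 100 has true CV
1.480 with sampling noise σ ≈ 0.012 over the 450-base window, so
selection at 1.4 is recovered essentially always, while ratio-2 families sit
at CV ≈ 0.34 and are never selected — these are analytic properties of the
chosen defaults, verified by the property suite over 50 seeded datasets.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally everywhere; GFF3 (1-based
  inclusive) and bedGraph (already half-open) convert at the file boundary.
- Sequences are stored uppercase; input case ignored (published guides are
  printed lowercase, donors uppercase).
- bedGraph intervals must not overlap (densities are pre-aggregated;
  `aggregate_tracks()` builds composites); negative values are errors.
- A CDS whose length is not divisible by 3 is flagged (`frame_ok = FALSE`),
  scored anyway, and can be excluded via
  `screen_config(exclude_frame_flagged = TRUE)`.
- A family with all-zero densities cannot be scored (`normalized_sd()`
  errors: "all-silent family"); inside the screen such families get `NA` and
  never rank. Members missing from the annotation leave their family
  `incomplete`: scored on available members, excluded from selection unless
  `include_incomplete = TRUE`.
- Ranking ties break by family id; family ids are the sorted member gene ids
  joined with `+` — deterministic by construction.

## Known limitations

- Identity semantics differ across clustering tools; at the 90% boundary the
  same proteome can cluster differently. Both the denominator and the
  strictness of the inequality are exposed, and reports record them.
- The density statistic inherits whatever units the coverage tracks carry
  (raw vs normalized reads); the screen is unit-agnostic but the density
  floor of 1 is not, so mixing differently normalized tracks shifts the
  filter, not the ranking.
- Restriction enzymes are exact-motif with fixed cut offsets (EcoRV built
  in); degenerate recognition sites are out of scope.
- The full published screen (browser-scale composite coverage over a complete
  genome) is not desk-reproducible; the package verifies the definitions,
  statistics and behavior of every step on published per-family numbers and
  on synthetic data with known truth.
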