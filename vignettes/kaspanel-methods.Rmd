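---
title: "Methods: from SNP screening to fingerprints and core germplasm"
author: "kaspanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from SNP screening to fingerprints and core germplasm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspanel)
```

`kaspanel` implements the computational workflow behind a KASP-based SNP
fingerprinting system for crop germplasm: screen a large resequencing-derived
SNP set down to a few hundred assay-worthy candidates, design KASP primer
triples, quality-control the genotyped marker panel, quantify its diversity,
resolve population structure, select a minimal set of discriminating markers,
build a core germplasm collection, and encode every accession as a fingerprint
barcode. This vignette explains each model and procedure, its assumptions,
the tunable parameters, and the numerical choices made where the design was
genuinely open.

## The synthetic panel generator

Every stage is exercised on synthetic data, so the generator defines the
study conditions. A panel is described by a `population_model`: `K` ancestral
populations, `L` biallelic markers, `N` samples. Ancestral allele frequencies
are drawn i.i.d. per population and locus from a Beta(`a`, `b`) prior
(optionally truncated to a frequency interval via the inverse CDF); sample
ancestry vectors come from a symmetric Dirichlet with concentration
`admix_alpha`; the genotype of sample *i* at locus *j* is Binomial(2,
*f~ij~*) with *f~ij~* = Σ~k~ Q~ik~ P~kj~; missingness is i.i.d. per call.
Defaults are the study scale: N = 280, L = 32, K = 8, Beta(0.2, 0.2)
frequencies (strongly diverged populations), `admix_alpha` = 0.05 (near-pure
ancestry, the regime in which a germplasm bank's accessions mostly belong to
one subgroup each), 2% missing calls. Ref/alt base pairs are drawn uniformly
from the 12 ordered substitution categories — deliberately without
transition/transversion bias, since the variant-type census should be
exercised over all categories; a biased census can be simulated by
post-hoc relabelling if needed.

What the generator does *not* emulate: linkage disequilibrium between
markers (loci are independent), genotyping error (only missingness, not
miscalls), and systematic assay failure of whole samples. Tests passing on
these panels therefore certify the algorithms under idealized independence
assumptions, not robustness to correlated or adversarial noise in real KASP
plates.

Duplicated accessions — the same cultivar deposited under several names —
are emulated by `plant_duplicates()`, which copies the pre-missingness call
vector of a group's first member to the others and then re-applies the
original missingness mask, so duplicates remain identical wherever both are
observed.

Seeding: one master seed; every sub-stage (frequencies, ancestries,
genotypes, base pairs, missingness) derives its own seed deterministically,
so any stage can be reproduced in isolation and two runs are byte-identical.

## Candidate-SNP screening

The funnel mirrors the standard GATK + vcftools recipe and applies, in
order:

1. restriction to SNP records;
2. **hard filters** on site annotations — fail iff any *present* annotation
   violates QD < 2.0, MQ < 40.0, MQRankSum < −12.5 or ReadPosRankSum <
   −8.0 (strict inequalities, so QD = 2.0 passes; an absent annotation
   never fails its clause);
3. **site filters** — biallelic only, minor-allele count ≥ 3, minor-allele
   frequency ≥ 0.05 over non-missing calls, mean per-sample depth ≥ 4,
   QUAL ≥ 30, and non-missing genotype fraction ≥ 0.5 (the vcftools
   `--max-missing` convention: the threshold is a minimum non-missing
   fraction, boundary inclusive);
4. **flank isolation** — a candidate is kept only if no other variant of
   any type lies within `flank_bp` of it on the same chromosome; "within"
   is violating, i.e. keeping requires distance strictly greater than
   `flank_bp`. The default is 100 bp (the assay-design window extracts
   100 bp each side); 200 bp is available by configuration since both
   figures circulate for this step. Isolation is tested against the full
   input variant set, not only the survivors, because a primer-binding
   window must be clean regardless of whether the neighbouring variant
   itself survived filtering;
5. **mid-frequency window** — alternate-allele frequency within
   [0.30, 0.70] inclusive. A *minor*-allele frequency cannot exceed 0.5,
   so a published 30–70% "MAF" window is implementable only on the
   alternate (or major) frequency; the intent — mid-frequency, maximally
   informative sites — is preserved;
6. **even genome-wide selection** down to a target count: per-chromosome
   quotas by largest-remainder apportionment proportional to candidate
   counts (minimum one where candidates exist), then greedy farthest-point
   selection on position within each chromosome, maximizing the minimum
   pairwise distance. Ties break toward the lower position; a quota of one
   takes the candidate nearest the chromosome span's midpoint. The whole
   step is deterministic.

The funnel report records counts after every stage (they are provably
non-increasing) and per-stage removal reasons, and the final candidate set
is censused over the 12 ordered substitution categories.

## KASP assay design

A KASP assay is two allele-specific primers — identical except for the
3'-terminal base, which is the respective allele — carrying the universal
FAM (`GAAGGTGACCAAGTTCATGCT`) and HEX (`GAAGGTCGGAGTCAACGGATT`) tails, plus
one common primer on the opposite strand. `design_assay()` scans
allele-specific candidates of length 18–30 bp ending exactly at the SNP and
common-primer windows downstream such that the amplicon does not exceed 120
bp, and returns the first triple — ordered by smallest product, then longest
primers — whose gene-specific portions (tails excluded) all satisfy GC <
60% and Tm within 55–62 °C. The forward strand is tried first; if no
forward triple passes, the reverse complement is scanned, which keeps the
choice deterministic while allowing AT- or GC-skewed flanks a second
chance. On failure the report counts which constraint excluded the
candidates.

Melting temperatures use the two-state nearest-neighbor model with the
unified duplex parameter set, terminal A/T / G·C initiation corrections, an
entropic salt correction proportional to ln[Na⁺], and the CT/4 factor for
non-self-complementary duplexes. The declared conditions
(`kasp_tm_conditions()`: 50 mM monovalent cation, 200 nM primer) are
centralized so the thermodynamic assumptions are auditable; no simple
length rule is used because tail-adjacent 18–30-mers span exactly the range
where such rules diverge most from duplex thermodynamics.

Marker-level QC classifies each marker as retained, dropped for a missing
rate above 20%, dropped as monomorphic (one genotype class among
non-missing calls), or both; samples whose own missing rate exceeds 50%
are excluded first. The two thresholds are configuration-exposed defaults:
"high missing rate" is not quantified in common practice, and 20%/50% are
ordinary plate-QC choices.

## Diversity statistics

All statistics are computed from genotype counts without assuming
Hardy–Weinberg equilibrium (observed heterozygosity is reported separately
from gene diversity, which would be redundant under HWE). For allele
frequencies *p~i~*:

* gene diversity GD = 1 − Σ *p~i~*²  (≤ 0.5 for biallelic markers);
* observed heterozygosity He = fraction of non-missing calls that are
  heterozygous;
* PIC = 1 − Σ *p~i~*² − Σ~i<j~ 2 *p~i~*² *p~j~*²  (≤ 0.375 for biallelic
  markers; PIC ≤ GD is an algebraic identity asserted in the tests);
* minor- and major-allele frequencies.

The panel summary emits `maf`, `major_freq` and `alt_freq` as separate
labelled columns. A published "MAF" panel ranging above 0.5 cannot be a
minor frequency; emitting all three candidate quantities avoids guessing
which one a given figure shows.

## Distances and trees

Between single accessions, per-locus "allele frequencies" are 1/0 for
homozygotes and 0.5/0.5 for heterozygotes — the only frequencies computable
from one diploid genotype, and the convention PowerMarker uses for
individual-level distances. With pairwise deletion (loci missing in either
sample are skipped; L′ = shared non-missing loci):

* Nei (1983) DA = 1 − (1/L′) Σ~l~ Σ~a~ √(*p~x,a~ p~y,a~*);
* modified Rogers MR = √((1/2L′) Σ~l~ Σ~a~ (*p~x~* − *p~y~*)²);
* Cavalli-Sforza–Edwards CE, the same form on square-root frequencies.

All three are symmetric, zero on identical inputs, bounded by [0, 1] and
invariant to locus order; pairwise computation is vectorized through
cross-products of masked matrices, so the 280 × 280 matrix is immediate.
Neighbor-joining uses the Saitou–Nei Q-criterion (via `ape::nj`), which
exactly recovers additive matrices; negative branch-length estimates are
clamped to zero with the clamped deficit recorded on the tree, preserving
Newick validity.

## Population structure

`fit_admixture()` maximizes the standard admixture likelihood for diploid
dosages *g~ij~* ∈ {0, 1, 2}:

LL = Σ~ij~ [ *g~ij~* ln *f~ij~* + (2 − *g~ij~*) ln(1 − *f~ij~*) ],
*f~ij~* = Σ~k~ Q~ik~ P~kj~,

by EM block updates of Q (ancestry, rows on the simplex) and P (ancestral
frequencies, clipped to [10⁻⁶, 1 − 10⁻⁶]) from random initialization
(Dirichlet(1, …, 1) rows for Q; Uniform(0.2, 0.8) for P). Missing dosages
are excluded from every sum. The Bayesian MCMC machinery of the classical
structure programs is deliberately replaced by this maximum-likelihood EM:
same likelihood family, deterministic under a seed, no external binary, and
fast enough to test at desk scale.

Plain EM on this likelihood is correct but slow — thousands of iterations
near convergence. Each iteration therefore applies a SQUAREM extrapolation
(two EM maps, a squared step with the step length capped at −1, one
stabilizing EM map) with a monotone safeguard: the accelerated candidate is
accepted only if it improves on the plain double-EM step, so the
log-likelihood is non-decreasing at every iteration — an invariant the code
asserts at run time. Convergence is declared when an iteration improves the
log-likelihood by less than `tol` (default 10⁻⁶) within `max_iter` (default
2000) accelerated iterations.

### Choosing K: the Evanno table

`structure_scan()` fits K over a range (default 2–10) with `n_replicates`
(default 10) replicate fits per K and computes L′(K), |L″(K)| and
ΔK = |L″(K)| / sd(L(K)) over the replicate log-likelihoods; `best_K` is the
interior argmax of ΔK, ties broken toward smaller K (preferring the
smallest K with comparable support). K values with zero replicate standard
deviation are flagged and excluded.

Two numerical choices matter here. First, each Evanno *replicate* is
itself the best of `inner_restarts` (default 3) EM starts, so a replicate
log-likelihood estimates the maximized likelihood at that K rather than
the depth of one arbitrary local optimum; replicate spread then reflects
genuine optimization variability, the analogue of run-to-run spread among
replicate MCMC runs. Second, a converged optimizer can return replicate
log-likelihoods that agree to within its convergence tolerance; their
sample standard deviation then measures numerical noise (~10⁻⁴), not
variability, and dividing a curvature of hundreds of log-likelihood units
by it would let rounding noise choose K. The ΔK denominator is therefore
floored at `sd_floor` = 1 log-likelihood unit — roughly one genotype call's
contribution, the resolution below which two fits are numerically the same
— while the table always reports the raw sd. On panels from eight strongly
diverged populations this selects K = 8; the full ΔK table is always
reported so secondary local peaks remain visible.

### PCA

Genotype PCA mean-imputes missing dosages per marker, centers columns, and
scales by √(*p*(1 − *p*)) — the variance of a binomial allele draw, the
standard SNP scaling — then decomposes by SVD. Monomorphic columns are
dropped with a warning; scores are deterministic up to sign.

## Minimal discriminating markers

A marker *resolves* a sample pair iff both calls are non-missing and the
genotype classes differ — a missing well is never evidence of difference.
`greedy_min_marker_set()` is maximum-coverage greedy set cover over the
N(N−1)/2 pairs: repeatedly add the marker resolving the most unresolved
pairs (ties: higher PIC, then genome order) until no marker adds a pair.
The greedy choice is the natural reading of "fewest markers distinguishing
the most samples" when the selecting software itself is unpublished; an
exhaustive oracle (`brute_force_min_set`, guarded to ≤ 20 markers)
enumerates subsets by increasing size, and the tests assert that greedy
always attains the oracle's maximum achievable resolution, with its size
within the classical set-cover logarithmic bound. Samples identical over
the chosen markers are reported as unresolved groups: strict equality
(missing as its own symbol) for duplicate reporting, conservative-missing
closure for resolution accounting.

## Core collection

`select_core()` picks round(fraction · N) entries (round half away from
zero, so 20% of 280 is 56) maximizing one of three objectives on the
modified-Rogers (or CE) matrix: mean entry-to-nearest-entry distance
("EN", the default — it spreads the core across the diversity space),
or mean pairwise MR/CE. The optimizer is greedy seeding from the farthest
pair followed by steepest-ascent swap local search, with random restarts;
ascent is monotone by construction and the best restart wins. This
replaces the mixed-replica search of dedicated core-selection software
with a simpler, seeded, auditable optimizer; the quality bar in the tests
is dominance of the selected core's mean MR over 1,000 random same-size
subsets. With `enforce_coverage`, any allele present in the collection but
absent from the core triggers a repair swap that inserts a carrier while
removing the least costly non-essential entry, so allele coverage (CV)
reaches 100% whenever carriers exist.

`evaluate_core()` reports the standard indices with frequencies computed
within the core: mean pairwise MR and CE, Shannon index (per-locus mean of
−Σ *p~a~* ln *p~a~*; biallelic loci cap it at ln 2 ≈ 0.693, so the
across-locus *sum* is also emitted because published Shannon values for
marker panels are sometimes sums over loci), expected heterozygosity (mean
GD), effective allele number (mean 1/Σ *p*²), mean PIC, and CV. Note that
under these standard definitions a biallelic panel cannot produce PIC >
0.375 or NE = 1 alongside HE > 0; the indices are implemented by their
definitions and not adjusted toward any particular published table.

## Fingerprints

A fingerprint is the ordered string of genotype classes over a marker set,
markers fixed in (chromosome, position) order so codes are comparable
across runs; heterozygotes are canonicalized alphabetically and missing
calls rendered `NN`. Encoding is injective on genotype vectors. The barcode
figure colours homozygotes AA yellow, CC green, GG blue, TT purple, any
heterozygote gray and NN white; the plot collapses heterozygotes to one
colour but the sidecar TSV retains the full two-base symbols, so no
information is lost. `compare_fingerprints()` splits positions into
matches, mismatches and incomparable (either side NN) — three disjoint
counts summing to the code length.

## Problem sizes used in the tests

The test suite and the acceptance script run entirely on synthetic panels
at the study scale (280 samples × 32 markers) for the headline checks —
core sizing and coverage, Evanno recovery of K = 8 with ten replicate fits
per K over K = 2–10, ancestry recovery — and on smaller panels (≤ 80
samples, ≤ 25 markers) for property checks such as oracle comparisons,
random-subset dominance, and round-trips, sizes at which the exhaustive
oracles remain exact. The end-to-end demo used in the tests runs a reduced
configuration (40 samples, 16 markers, K 2–5); `run_demo()`'s defaults are
the full study conditions.

## Known limitations

* The admixture EM finds local maxima; multi-start plus acceleration makes
  the global optimum overwhelmingly likely at these sizes but offers no
  guarantee, and the ΔK statistic inherits the brittleness of dividing a
  curvature by a replicate spread.
* Individual-level DA/MR/CE distances on 32 markers quantize (each locus
  contributes one of a few values), so ties in trees and cores are common;
  deterministic tie-breaking makes results reproducible rather than unique.
* The greedy marker set can exceed the true minimum size (within the
  set-cover bound); the exact oracle is exponential and gated to small
  instances.
* KASP design checks composition and thermodynamics only — no
  secondary-structure, dimer, or genome-specificity screening.
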