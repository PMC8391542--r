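---
title: "Read-depth CNV calling and prioritization in family exome cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-depth CNV calling and prioritization in family exome cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcnv)
```

# The problem

Congenital scoliosis (CS) arises from congenital vertebral malformations,
most commonly hemivertebrae. Beyond the established *TBX6*-containing
16p11.2 microdeletion, which explains roughly 5–10% of cases, the
contribution of other copy number variants (CNVs) is largely unknown. The
study design this package implements is a family-based whole-exome survey:
patients and their unaffected parents and siblings are exome-sequenced, CNVs
are called per sample from exon read depth against a fixed reference set of
healthy controls, and candidates are prioritized three ways — a
candidate-gene screen against genes with prior evidence in scoliosis or
somitogenesis, a screen for patient-unique homozygous (recessive) losses,
and a recurrence-based screen for novel CNVs enriched in patients but absent
or very rare in family controls and population databases.

Because no cohort data are deposited, the package ships a first-class
synthetic-cohort generator so that every downstream stage is testable
without any download, plus re-encodings of the published result tables as
fixtures for exact reproduction of the downstream counts.

# The calling model

## Emission

For a test sample at exon $i$, let $x_i$ be its read count and $r_i$ the
summed count of the reference samples. Conditional on the total $n_i = x_i +
r_i$, the test count is modelled as beta-binomial:

$$ x_i \mid n_i \sim \mathrm{BetaBin}(n_i, \phi'_c, \rho), $$

where $\phi$ is the expected diploid fraction of test reads among test +
reference reads, and the copy-number adjustment for copy state $c$ is

$$ \phi'_c = \frac{(c/2)\,\phi}{(c/2)\,\phi + (1 - \phi)}. $$

Diploid ($c = 2$) gives $\phi'_2 = \phi$; a heterozygous deletion halves the
odds; a single-copy gain multiplies them by $3/2$. The overdispersion $\rho$
is the beta-binomial intra-class correlation; $\rho \to 0$ recovers the
binomial.

Two estimation choices matter:

* **$\phi$ is a single per-sample value** computed from the sample's count
  totals over unmasked exons, $\hat\phi = \sum_i x_i / \sum_i (x_i + r_i)$.
  Exon-to-exon capture efficiency affects $x_i$ and $r_i$ proportionally and
  cancels in the conditional fraction, while a per-exon estimate pooled over
  the other test samples would absorb any carrier's CNV at exactly the exons
  under test and dilute the evidence — in a ten-sample cohort a shared
  heterozygous deletion moves the pooled per-exon fraction by several
  percent, which halves the per-exon log likelihood ratio. Count totals, by
  contrast, are perturbed only by the few CNV exons.
* **$\rho$ is fitted on a reference-versus-reference split** by method of
  moments: the reference samples are split in half, and the excess variance
  of the per-exon fraction over its binomial expectation gives $\rho$,
  floored at $10^{-4}$. Real copy-number signal in test samples can never
  inflate this estimate because no test sample participates.

Exons whose summed reference count is zero carry no relative-depth
information and are masked before decoding.

## Segmentation

Hidden copy states {deletion, diploid, duplication} evolve along the ordered
exons of each chromosome as a first-order chain: the diploid state is left
with probability $t$ per exon boundary (default $10^{-4}$, split equally
between deletion and duplication), and a CNV state returns to diploid with
probability $q$ (default 0.2, i.e. a mean CNV length of five exons). The
maximum-probability state path is decoded by dynamic programming (Viterbi);
each maximal non-diploid run becomes one call whose boundaries are the first
exon's start and the last exon's end. The test suite proves the decoder
against exhaustive enumeration over all $3^n$ paths on small instances.

A deliberate simplification is the **post-hoc zygosity refinement**: the
chain has three states, not five, and a called deletion is labelled
homozygous (copy 0) only afterwards, when the segment's observed/expected
ratio falls below 0.1 — the same discriminator the downstream recessive
screen uses. This keeps the decoder minimal and avoids a second threshold.

## Per-call statistics

Each call carries:

* the **Bayes factor**, $\mathrm{BF} = \log_{10} \prod_i L(x_i \mid c) /
  \prod_i L(x_i \mid 2)$, summed in log space over the segment's exons
  against the refined copy state (it is additive over exons and may be
  negative);
* the **observed/expected reads ratio**, $\sum_i x_i / \sum_i \phi_i (x_i +
  r_i)$ — approximately 0.5 for heterozygous loss, below 0.1 for homozygous
  loss, 1.5 for a single-copy gain;
* the **exon annotation**, `GENE_a-b` for the first and last overlapped exon
  of each gene (computed via GenomicRanges overlaps).

For copy state 0 the adjustment uses an effective copy number of 0.02
rather than 0, so that stray mis-mapped reads in a homozygous deletion never
produce an infinite penalty; published homozygous calls show ratios of both
0 and 0.04, i.e. genuinely nonzero observed reads.

# The filter cascade and screens

The filtering criteria are implemented with **boundaries kept**, reading the
exclusion rules literally: only BF *smaller than* 1, size *smaller than*
100 bp and population frequency *greater than* 0.01 are excluded. Frequency
filtering is gene-based: records from database cohorts smaller than 100
samples are ignored; per gene the maximum over all remaining frequencies is
taken, with East-Asian values participating in the maximum alongside overall
values when present (the alternative — letting the ancestry-matched value
override — is not stated anywhere; taking the max is the more conservative
exclusion rule). Genes without any eligible record are retained.

Two documented irregularities are handled explicitly:

* the **size filter applies only on the genome-wide path**; the
  candidate-gene screen bypasses it, because the published candidate table
  retains a 71 bp single-exon call that criterion (ii) would remove. A
  single-exon hit in a strong candidate gene is worth manual review.
* the duplication reported by the novel screen is filtered against the same
  heterozygous-loss frequency fields as deletions, since that is how the
  published gene table lists it.

Inheritance is classified on calls, not raw depth: a parent carries a
patient's variant when the parent has a call of the same type sharing an
annotated gene (default) or reciprocally overlapping by at least 50%
(interval mode). Gene-level matching is the default because inherited calls
may legitimately differ in boundaries between family members. Both parents
assayed and neither carrying gives "De novo"; a missing parent gives
"N.D.". When the patient's relatives were filtered before classification,
carrier lookup still runs against the unfiltered call set, so a parent call
that itself failed a filter still counts as carriage.

The recessive screen composes homozygosity detection (ratio strictly below
0.1, deletions only), removal of genes that also carry a control homozygous
call, and inheritance annotation. Sibling absence is reported as an
annotation, never as a requirement for the de novo label.

The novel screen counts, per gene, the distinct patient and control
carriers; a gene is reported when more than three patients carry it
(implemented as $\ge 4$, matching the minimum published count), the control
fraction is strictly below 1% (with 125 controls this means at most 1
carrier: $1/125 = 0.8\%$, $2/125 = 1.6\%$), and the maximum eligible
population frequency is at most 0.01. Discovery follows the published
two-pass design — genes are first found among patients from complete
families (both parents assayed), then counts are updated with the remaining
patients — although for pure thresholding the two passes select the same
genes as one.

# The qPCR calculator

Validation uses relative quantification against a reference locus and a
calibrator sample: $\Delta C_t = C_t^{target} - C_t^{ref}$, $\Delta\Delta
C_t = \Delta C_t^{sample} - \Delta C_t^{calibrator}$, relative quantity
$= 2^{-\Delta\Delta C_t}$. The copy estimate doubles the relative quantity
(diploid autosomal calibrator); this scaling is a package convenience, not
part of the published method, and the raw $2^{-\Delta\Delta C_t}$ is always
reported alongside.

# The synthetic world

The generator emulates the study design at its published scale: 2 quintets,
14 quartets, 33 trios, 9 duos and 9 singleton patients — 67 patients and
125 relatives. Families have exactly one affected child; quintets and
quartets are filled with both parents first, then unaffected siblings (the
published per-family splits are not stated; this choice is flagged, not
inferred). Duos pair the patient with the mother, again an arbitrary fixed
choice. Implanted CNVs span 1–30 whole exons of a single gene, heterozygous
events may be de novo or inherited (in which case the identical event enters
one parent's truth set), and homozygous deletions are always de novo and
patient-only, matching the published recessive findings.

Counts are negative-binomial with expectation $\bar d \cdot (c/2) \cdot
\ell_i / \bar\ell$ for mean depth $\bar d$ and exon length $\ell_i$
(capture yield is proportional to target length), plus an optional
mis-mapping term $\bar d \cdot m \cdot \ell_i/\bar\ell$ that gives
homozygous deletions small nonzero ratios when $m > 0$ (default $m = 0$).

**Dispersion default.** The per-exon negative-binomial dispersion defaults
to 0.01 — variance twice Poisson at 100× depth. This is the residual
sample-to-sample noise regime read-depth callers are designed for: the large
exon-to-exon differences in capture efficiency seen in real data are shared
across samples and cancel in the test/reference fraction, so they are
deliberately not simulated. At substantially higher dispersion (e.g. 0.05)
the conditional fraction becomes so overdispersed that no three-state
decoder with a realistic transition prior can recover short heterozygous
deletions reliably — the per-segment evidence (≈ 1 nat/exon) cannot clear
the state-entry cost — which contradicts the operating characteristics this
model class is meant to have at 100× with four reference samples. At the
default, measured recovery of 4-exon heterozygous deletions is ~96% over 50
replicates, with ratios concentrated near 0.5.

What a green synthetic test does **not** establish: performance under GC
bias, batch effects, reference-sample mismatch, segmental duplications,
sex-chromosome calling, or the boundary uncertainty of real capture designs
— none of which are simulated. The published cohort-level discovery numbers
(15,671 raw calls, ~234 CNVs per patient, 6,084 distinct CNVs) depend on the
real capture and are out of reach of any desk-scale simulation; the package
reproduces the downstream table counts from re-encoded fixtures instead.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; size $=$ end $-$ start,
  which reproduces every published size from its printed endpoints exactly
  (e.g. $30{,}199{,}897 - 29{,}674{,}601 = 525{,}296$).
* Beta-binomial likelihoods use the `lbeta` closed form; the test oracle
  evaluates the rising-factorial product term by term instead.
* Exons with zero combined count are masked before decoding; a segment whose
  expected total is zero raises an error rather than returning NaN.
* $\rho$ fitting falls back to the $10^{-4}$ floor with fewer than two
  reference samples or a degenerate pooled fraction.
* Viterbi ties (log-probability equal) resolve to the first state in
  (deletion, diploid, duplication) order via `which.max`; with continuous
  emissions ties have measure zero.
* A test sample that is also in the reference set is called anyway with a
  warning (self-comparison halves sensitivity; the published design keeps
  reference and test samples disjoint).
* An empty frequency table is the identity on calls; unannotated calls pass
  gene-based filters unchanged and are simply invisible to gene-based
  screens.

# Known limitations

* Duplications beyond copy 3 are not genotyped, and short duplications are
  recovered much less reliably than deletions (a 3/2 odds shift is weaker
  evidence than 1/2).
* The "optimized reference set" selection of the cited tool family is not
  reimplemented; the reference is a fixed, configured sample list, as in the
  published analysis (four named healthy relatives).
* Parental mosaicism, compound heterozygosity with SNVs, and
  pathogenicity scoring are out of scope.
* The abstract-level discrepancies in the source tables (15 vs 14 novel
  genes; 64 CNVs vs counts summing to 63) are surfaced in the package's
  reports as computed, not reconciled.
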