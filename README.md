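# famcnv

Family-based exon read-depth CNV calling and prioritization in R.

`famcnv` implements the analysis design used in family-based whole-exome
studies of congenital scoliosis (CS): patients with congenital vertebral
malformations and their unaffected parents and siblings are exome-sequenced,
copy number variants (CNVs) are called per sample from exon read counts
against a fixed reference set of healthy controls, and candidates are
prioritized by a candidate-gene screen, a patient-unique recessive
(homozygous) screen, and a recurrence-based novel-CNV enrichment screen,
with a 2^−ΔΔCt qPCR calculator for validating individual calls. Because
cohorts of this kind are not publicly deposited, the package also ships a
first-class synthetic-cohort generator (pedigrees, exon targets,
overdispersed read counts with implanted CNVs, companion DGV/gnomAD-SV-style
frequency tables) so the entire pipeline is testable offline.

## The model

For a test sample at exon *i* with count *x_i* and summed reference count
*r_i*, the count is modelled conditional on the total as beta-binomial,

> x_i | n_i ~ BetaBin(n_i, φ′_c, ρ),  n_i = x_i + r_i,

where φ is the sample's expected diploid fraction of test reads
(estimated from count totals) and the copy-number-adjusted fraction for
copy state *c* is φ′_c = (c/2)φ / ((c/2)φ + 1 − φ). Hidden copy states
{deletion, diploid, duplication} are decoded along each chromosome by a
first-order chain (Viterbi; default transition probability 10⁻⁴ per exon
boundary), and each non-diploid run becomes a call carrying:

- **BF** — log₁₀ likelihood ratio of the called copy state over diploid,
  summed over the segment's exons;
- **reads ratio** — Σx_i / Σφ_i(x_i+r_i): ≈0.5 for heterozygous loss,
  <0.1 for homozygous loss, ≈1.5 for a gain;
- **exon annotation** — `GENE_a-b` per overlapped gene.

Downstream filtering follows the study criteria: exclude BF < 1, size
< 100 bp (genome-wide path only), and genes whose maximum eligible
population heterozygous-loss frequency (database cohort ≥ 100 samples)
exceeds 0.01; classify inheritance against assayed parents (De novo /
Paternal / Maternal / N.D.); detect recessive CNVs as deletions with reads
ratio < 0.1 unique to patients; and report genes recurrent in > 3 patients
but < 1% of family controls.

## Worked example

The package bundles the call tables of a 67-patient / 125-control
congenital hemivertebrae cohort re-encoded as fixtures (see
`inst/extdata/README.md`; synthetic reconstructions are flagged there).
The candidate-gene screen on the bundled calls:

```r
library(famcnv)
ext <- function(f) system.file("extdata", f, package = "famcnv")
ped    <- read_ped(ext("cohort.ped"))
calls  <- read_calls(ext("candidate_calls.tsv"))
pf     <- read_popfreq(ext("candidate_popfreq.tsv"))
screen <- candidate_gene_screen(calls, ped, popfreq = pf)
screen[, c("gene", "sample_id", "type", "size", "bayes_factor",
           "reads_ratio", "inheritance")]
```

```
   gene sample_id     type   size bayes_factor reads_ratio inheritance
  DSCAM     CS018 deletion    187         4.65       0.429     De novo
  DSCAM     CS036 deletion    187         6.02       0.415     De novo
  DSCAM     CS050 deletion    187         5.80       0.468    Paternal
  DSCAM     CS053 deletion    187         5.45       0.494        N.D.
  DSCAM     CS064 deletion    187         6.10       0.463        N.D.
 NOTCH2     CS033 deletion     71         4.62       0.657        N.D.
 NOTCH2     CS043 deletion  72399         8.46       0.722     De novo
  SNTG1     CS048 deletion  67783         6.37       0.430     De novo
   TBX6     CS059 deletion 525296       644.00       0.555        N.D.
   TBX6     CS071 deletion 723210       754.00       0.572     De novo
   TBX6     CS078 deletion 701381       690.00       0.578        N.D.
   TBX6     CS081 deletion 701381       645.00       0.558        N.D.
```

Twelve rare CNVs in four candidate genes across twelve patients, four of
them carrying the TBX6-containing 16p11.2 deletion. Each row shows the
calling statistics (BF > 1 supports a real CNV; reads ratio near 0.5 means
one copy lost) and the inheritance pattern against the assayed relatives —
"De novo" when both parents were tested and neither carries the variant,
"Paternal" when the father does, "N.D." when parents were unavailable.

The same fixtures drive the recessive screen (`recessive_screen()`: 8
patients, 3 genes, all ratios < 0.1) and the novel-CNV enrichment
(`novel_enrichment()`: 14 genes). An end-to-end synthetic run goes through
`run_pipeline()` with a YAML or list config; see the vignette
(`vignettes/cnv-family-cohorts.Rmd`) for the model, parameter and design
discussion.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates the full family cohort (2 quintets, 14 quartets, 33 trios, 9
duos, 9 singletons; 67 patients + 125 relatives) at 100× mean depth with
implanted CNVs under the given seed, builds the reference profile, calls
CNVs for every non-reference sample, applies the filter cascade and
inheritance classification, and produces the three report surfaces, writing
its result object to the given path:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
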