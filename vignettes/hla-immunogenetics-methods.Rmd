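---
title: "Methods: cohort-scale HLA immunogenetics with hlacohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-scale HLA immunogenetics with hlacohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlacohort)
library(dplyr)
```

## Scope and model

`hlacohort` implements the computational core of a cohort-scale HLA
immunogenetics analysis: establishing high-confidence HLA genotypes from
heterogeneous sequencing-based typing calls, inferring multilocus
haplotypes and their population frequencies, screening allele
frequencies and homozygosity against control populations, classifying
somatic loss-of-heterozygosity (LOH) from allele-specific copy number,
filtering tumor/normal variant calls over antigen processing and
presentation (APP) genes, and quantifying transcript levels from qPCR.
Patient-level sequencing data in this field are access-controlled, so
the package ships a seeded synthetic-cohort generator with known ground
truth; every rule is validated against that truth or against independent
brute-force oracles.

## Nomenclature

All comparisons run at two-field ("4-digit") resolution — the protein
level at which sequencing-based typing algorithms report. Higher
resolution fields are truncated on parsing (with a notice), expression
suffixes (N, L, S, Q) are preserved in storage but ignored during
consensus and haplotype matching: typing tools cannot distinguish, for
instance, a null DRB4 allele carrying a splice-site mutation from its
expressed counterpart. G groups — alleles identical over the exons
encoding the peptide-binding domains — are supplied as a small editable
TSV; an allele missing from the table forms its own singleton group, so
the mapping is always a partition. G-group equivalence is applied during
haplotype classification (where it flags variants), not during consensus
calling; the typing algorithms themselves report specific alleles, and
collapsing them earlier would discard information the consensus rule can
use.

## Consensus genotyping

A consensus genotype for one patient and locus is an unordered allele
pair whose supporters span **at least two distinct algorithms and two
distinct sequencing samples**. Stage 1 admits only the two primary
typing algorithms (HLA-HD, HLAProfiler, configurable); when stage 1
yields no single qualifying candidate, stage 2 opens the supporter set
to the fallback algorithms (Optitype, xHLA, HISAT-genotype). Candidates
are whole genotypes, not per-allele votes; a tool reporting a single
allele is treated as a putative homozygote and supports only the
homozygous candidate. Several qualifying candidates at the deciding
stage yield `unresolved` with all candidates listed — frequency-based
tie-breaking is deliberately absent.

One subtlety surfaced by property testing: support for a given genotype
only shrinks when calls are removed, so a consensus re-established *at
the same stage* is always the same genotype; but because the two stages
are sequential and stage 2 sees a wider algorithm set, removing a
stage-1 supporting call can, in adversarial configurations, surface a
different stage-2 candidate. The package keeps the sequential procedure
(it mirrors how typing consensus is established in practice: fallback
algorithms are only consulted when the primary pair disagrees), and the
tests assert the per-stage form of the
monotonicity property.

## Haplotype inference

Compatible diplotypes of a genotype over L loci with H heterozygous loci
are enumerated exhaustively (2^(H−1) unordered pairs). Population
haplotype frequencies are estimated by gene-counting EM over
phase-ambiguous genotypes: the E-step weights each compatible pair
(h1, h2) of an individual by f(h1)·f(h2), doubled when h1 ≠ h2 and
normalized within the individual; the M-step sets f(h) to the expected
chromosome count over 2N. Initialization is uniform over the haplotypes
compatible with at least one individual — deterministic, no seed — and
the log-likelihood is asserted non-decreasing at every iteration.
Defaults: convergence at 1e-8 maximum frequency change, 10,000 iteration
cap (a non-converged fit is flagged, not hidden), frequencies below
1e-12 pruned and the rest renormalized.

Diplotype assignment against a reference frequency table scores each
compatible pair by f(h1)·f(h2) (doubled for heterozygous pairs).
Reference tables are truncated, so haplotypes absent from the table
receive a pseudo-frequency of 1e-9 — far below any listed entry, making
every pair scoreable while guaranteeing listed pairs dominate. Score
ties are flagged ambiguous and broken lexicographically for determinism.

A haplotype identical to a reference entry is **known**; one diverging
at exactly one locus is a **variant**, labeled by the closest reference
haplotype number plus a letter suffix (b, c, d, ...) assigned in
discovery order within the analysis run; two or more divergent loci from
every reference is **unknown**. Divergence only by G-group membership
still classifies as variant, with a flag. When several references sit at
divergence one, the most frequent is chosen — a deterministic reading of
"closest" where several candidates are equally near. DRB1–DRB3/4/5
combinations are resolved through the serological linkage groups (DR1,
DR8: no paralogue; DR51: DRB5; DR52: DRB3; DR53: DRB4), shipped as an
editable TSV.

## Cohort statistics

Allele frequency is occurrences over chromosomes (2N), homozygotes
counting twice; individuals without a consensus genotype at a locus are
excluded from that locus (never imputed) and the exclusion is reported.
An individual is homozygous at a locus when the consensus pair is
identical at two-field resolution ignoring suffixes — a single detected
allele counts as homozygous, an operational definition that conflates
true homozygosity with allele dropout and is stated as such.

The over/under-representation screen fires the first of three criteria,
evaluated in order: (i) frequency ≥ 0.1 in either group and frequency
ratio (patients/controls) ≤ 0.5 or ≥ 2; (ii) frequency ≥ 0.1 in both
groups and ratio ≤ 0.67 or ≥ 1.5; (iii) allele undetected in patients
with control frequency ≥ 0.07. An allele present only in patients has an
undefined ratio and is flagged `patient-only`. No significance testing
is attached — cohort sizes in this setting do not support it, and the
screen is explicitly a candidate generator. Control tables are inputs;
when several published sources report the same allele the unweighted
mean is taken by default (weights are configurable, since the sources'
sample sizes differ by orders of magnitude and the field has no fixed
convention).

Ancestry assignment takes precomputed superpopulation fractions (EUR,
AFR, AMR, EAS, SAS) and assigns the unique population with fraction
≥ 0.70 (inclusive), otherwise `admixed`. The threshold exceeds 0.5 by
construction, so uniqueness is guaranteed on valid input and violations
are treated as data errors.

## LOH from allele-specific copy number

Segments carry total (CNt), major-allele (A) and minor-allele (B) copy
numbers; "CNA" in the category definitions is the retained major allele,
so every LOH category requires B = 0. Classification: CNt = 0 →
biallelic loss; A = CNt = 1 → LOH; A = CNt = 2 → copy-neutral LOH
(deliberately defined relative to a diploid germline, independent of
aneuploidy); A = CNt ≥ 3 → LOH with gain, upgraded to amplification when
CNt ≥ 7 at ploidy 2 or CNt ≥ 1 + 2·ploidy at ploidy 3–9. The rule is
stated on integer ploidy, so fractional ploidy is rounded half-up first;
above ploidy 9 no amplification call is made (gain instead, logged).
Retention gates before classification: segment ≥ 50 kb, sample
cellularity ≥ 0.2, at least one overlapping annotated target gene; every
rejection is logged with its reason.

Gene events use any-overlap (≥ 1 base) attribution; co-occurring
categories at one gene resolve by severity (biallelic loss > LOH >
CN-LOH > LOH+amplification > LOH+gain > none), an ordering the source
procedure leaves unstated and which is therefore logged with the result;
the full overlap table is kept as an audit attribute. Coordinates are
1-based inclusive internally; BED input is converted on read. Prevalence
counts, for HLA genes, any LOH-bearing category in the numerator and
removes germline-homozygous patients from the denominator (without
germline heterozygosity, reference-based analysis cannot see LOH); for
B2M and CIITA only LOH and biallelic loss count. The denominator
universe is an explicit argument, never inferred, because the evaluable
set differs between cohorts and genes. Arm-level calls require ≥ 90% arm
coverage.

## Somatic filtering

A variant passes when the normal sample shows fewer than 4 mutated reads
*and* VAF < 0.06, and the tumor more than 3 mutated reads *and*
VAF ≥ 0.15 — four conjunctive conditions with the stated mix of strict
and inclusive bounds, applied after an upstream quality flag and a
sample-level cellularity ≥ 0.2 gate. Records with missing counts fail
with reason `missing-data` rather than being dropped silently. Summaries
restrict to a configurable gene set (the bundled fixture reconstructs
the KEGG antigen processing and presentation pathway membership, 78
genes, as an editable TSV); silent variants are excluded unless
requested, and splice-site consequences count as non-silent.

## qPCR quantification

Relative quantity is 2^(mean(reference Cts) − target Ct). Averaging
reference Cts on the cycle scale is mathematically identical to the
geometric mean of per-reference 2^ΔCt quantities (asserted to 1e-12 in
tests) and numerically more robust. Undetermined wells are missing, not
zero — a meaningful distinction when transcripts are silenced.
Amplification efficiency comes from a least-squares fit of Ct on log10
input quantity over a dilution series (≥ 3 points): efficiency =
10^(−1/slope) − 1, i.e. 100% at the perfect-doubling slope of
−1/log10(2) ≈ −3.32 cycles per decade. Reference-gene stability
selection is out of scope; the reference set is configuration.

## Synthetic cohorts and what they do (not) show

The generator draws pool haplotype frequencies from a Dirichlet
distribution, forms individuals by two independent haplotype draws
(random mating — which is what makes the Σf² homozygosity check exact in
expectation), and corrupts per-algorithm calls with three failure modes
the consensus rule addresses: miscalls (one allele replaced by another
pool allele), dropout (single-allele reporting), and RNA transcript
silencing (RNA-based algorithms see one chromosome only, configurable
per locus). Default noise rates (1% miscall, 1% dropout, 2% silencing)
reflect the >99% per-tool accuracy regime of modern typing algorithms on
high-coverage data. Segment, variant and expression generators plant
events with known labels, deliberately straddling every filter boundary
(sub-50 kb segments, cellularity 0.15, tumor VAF 0.149/0.150, normal
reads 3/4).

What passing these tests shows: the rules are implemented exactly, the
EM recovers planted frequencies to sampling accuracy, and the pipeline
is deterministic under a seed. What they do not show: performance on
real sequencing data, where typing errors are correlated between
algorithms sharing references, linkage disequilibrium extends beyond the
simulated haplotype pool, and segmentation boundaries are noisy. The
generator makes no attempt to simulate reads.

Problem sizes in the shipped tests and acceptance script (2000
individuals for EM recovery, 1000 genotypes for the assignment oracle,
10,000 variant records, 500 individuals for the homozygosity check) were
chosen so each check's sampling error sits well below its assertion
tolerance while the whole suite runs in a couple of minutes.

## Worked example

```{r example}
cfg <- sim_config(n_individuals = 100, loci = c("A", "B", "C"),
                  pool_size = 8, miscall = 0.01, dropout = 0.01)
sim <- simulate_cohort(cfg, seed = 1)
consensus <- patient_consensus(sim$calls)
table(consensus$status)

fit <- em_frequencies(consensus |> filter(status == "consensus") |>
                        select(patient, locus, allele1, allele2))
glance(fit)
head(tidy(fit), 4)

homozygosity_rates(consensus)
```

## Known limitations

Which parental allele is lost in an LOH event is not identified
(reference-based copy-number analysis cannot tell). Full IMGT/HLA
nomenclature (fields 3–4, renamed alleles, serological equivalents) is
out of scope, as are read-level simulation, association testing, and
liftover between genome assemblies — segment and gene annotations must
share one assembly. Variant suffix letters are assigned per analysis
run, so labels are stable within a run but not across cohorts analyzed
separately.
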