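---
title: "Trio variant prioritization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio variant prioritization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triofunnel)
library(data.table)
```

## The problem

When a single affected individual with healthy parents is sequenced as a
trio (proband, mother, father), the millions of called variants can be
narrowed to a handful of candidates by combining pedigree logic with
population-frequency, consequence, network and pathogenicity evidence.
`triofunnel` implements that funnel as composable, individually testable
stages:

1. a relatedness sanity check (pairwise SNP concordance);
2. site-quality hard filters on the standard caller metrics;
3. an inheritance-mode partition (X-linked, autosomal recessive, de novo);
4. consequence-impact selection (high/moderate Sequence Ontology classes);
5. common-variant exclusion against population panels;
6. two parallel prioritization workflows — rare-allele + network
   propagation, and predictor-based pathogenicity ranking;
7. a merge, a user-curated exclusion list, and finalization against
   orthogonal zygosity genotyping.

Because autosomal dominant inheritance is excluded by the unaffected
parents, only the three modes above are modeled.

## Genotype and pedigree model

Genotype calls are normalized VCF `GT` strings restricted to allele
indices 0/1 after multi-allelic splitting. "Present" always means a
non-missing call carrying at least one alt allele. The mode rules are:

* **X-linked**: chrX variant present in proband and mother but absent in
  the father. For a male proband an alt call on X is hemizygous; diploid
  `0/1` calls on male X are accepted as present but tagged `XHET_MALE`,
  because callers disagree on X ploidy encoding.
* **De novo**: present only in the proband. Only this presence rule is
  implemented; external de novo callers are out of scope.
* **Autosomal recessive**: proband homozygous-alt with both parents
  heterozygous (the strict, consanguinity-free trio model, and the only
  one consistent with two healthy carrier parents). A relaxed variant —
  each parent carries at least one alt, neither homozygous-alt — is
  available via `recessive_model = "relaxed"`.

Any missing genotype in the trio removes the variant from all modes with
a `MISSING_GENOTYPE` tag: a pedigree rule should not fire on evidence it
cannot see. Pseudoautosomal X regions are by default treated like the
rest of chrX; `par_exclude = TRUE` removes the GRCh37 PAR intervals from
the X-linked rule, documenting rather than hiding the simplification.

## Hard filters and frequency exclusions

The five site-quality thresholds (`QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
`MQRankSum < -12.5`, `ReadPosRankSum < -8.0`) are applied per variant
record with *strict* comparisons: equality at a threshold survives, and
an absent metric can never fail a variant. The occasionally quoted extra
condition `FS > 200` is subsumed by `FS > 60` and is therefore not a
separate parameter.

Common-variant exclusion drops a variant iff any *present* panel
frequency strictly exceeds its maximum (dbSNP global 5%, 1000 Genomes
global 2%, ExAC 5%, gnomAD Ashkenazi Jewish 5%); absent frequencies are
treated as not exceeding, so novel alleles survive. The rare-allele
workflow additionally requires the population-matched (AJ) frequency to
be absent or strictly below 0.1%. The split matters: a variant that is
*not rare* in the matched population (e.g. an AJ frequency of 0.01991)
passes the 5% exclusions yet is excluded from the rare-allele workflow —
it can then only be rescued by the pathogenicity branch. This dual
routing is exactly what the shipped demo exercises.

Minor-allele frequencies are consumed as given; no folding to ≤ 0.5 is
attempted, since panel annotations in the wild are already alt-allele or
folded depending on the annotator.

## Network propagation

The gene network is a weighted undirected graph (weights in (0, 1],
STRING-style 0–1000 integer scores auto-rescaled) with edges retained
only above a strict confidence threshold (default 0.7). A seed-gene set
carries the disease label.

Two scorers are provided:

* **Direct neighbor**: `direct(g) = sum over seed neighbors s of w(g, s)`
  — one-hop evidence, exact and assumption-free.
* **Gaussian smoothing** (network diffusion): the unique minimizer of

  $$\sum_i \frac{1-\alpha}{\alpha}(f_i - y_i)^2 +
    \sum_{(i,j)\in E} w'_{ij} (f_i - f_j)^2,$$

  with seed labels $y_i = 1$, solved in closed form as
  $f = (1-\alpha)(I - \alpha S)^{-1} y$ where
  $S = D^{-1/2} W D^{-1/2}$. This is the textbook realization of a
  label-propagation objective that keeps labeled genes near their labels
  and neighbors near each other. It is computed by the fixed-point
  iteration $f \leftarrow \alpha S f + (1-\alpha) y$ to a max-norm
  residual of `tol` (default 1e-10, default cap 10,000 iterations;
  non-convergence is an error, not a silent result). With `alpha`
  strictly inside (0, 1) and symmetric degree normalization the spectral
  radius of $\alpha S$ is below 1, so the iteration converges
  geometrically; in the test suite it agrees with a dense direct solve to
  below 1e-8 on random graphs.

Numerical notes, chosen deliberately:

* `alpha = 0.8` retains most mass in the network, the common default in
  diffusion-based gene prioritization; it is exposed in configuration.
* Under symmetric normalization diffusion scores are nonnegative but are
  *not* guaranteed to stay ≤ 1 for degree-skewed seed configurations (a
  hub surrounded by seeded leaves can exceed 1); the row-stochastic
  variant would bound them by 1. We keep the symmetric form because it
  matches the stated objective; ranks, not absolute values, drive
  selection.
* On trees with a single seed, scores never increase along any
  root-to-leaf path (asserted in the suite); across-branch comparisons at
  equal depth can still be reordered by degree, which is a property of
  the normalization, not a bug.
* Ranks use competition ranking (ties share the best rank) with a
  deterministic secondary sort on gene symbol, so reports are
  reproducible byte for byte.

The rule that turns scores into a selection ("located in a functional
gene network") is not uniquely recoverable from score lists alone, so it
is a configurable predicate. The default — selected iff `direct > 0` or
the diffusion rank falls in the top `q = 0.10` of non-seed genes — is
deliberately simple, and both scores with ranks are always emitted so
users can apply their own cutoff.

## Pathogenicity workflow and finalization

A variant is a *possibly damaging SNV* (PDS) iff both predictor scores
are present and both cross their canonical published thresholds: SIFT
≤ 0.05 (low = damaging) and PolyPhen-2 ≥ 0.447 (the "possibly damaging"
lower bound). The combined score `polyphen + (1 - sift)` (range 0–2) is a
monotone, scale-free merge of the two evidence directions; the top `k`
(default 2) PDS variants form workflow 2. Ties break by lower SIFT, then
gene symbol.

The two workflows merge as a set union with provenance
(`NETWORK`/`PATHOGENICITY`/`BOTH`). Manual disease-relevance review is
modeled as *data* — a gene→reason exclusion list — keeping an honest
boundary between computation and curation.

Finalization resolves each candidate against optional orthogonal
genotyping: wild-type observations are false positives (dropped);
heterozygous observations contradict autosomal-recessive or male-X
candidates (dropped as zygosity-inconsistent); alt-bearing observations
consistent with the mode confirm; candidates without an observation stay
ranked but flagged `UNTESTED` — absence of genotyping is not evidence
against. An observed homozygous-alt on a male-X candidate confirms, since
Sanger traces cannot distinguish hemizygous from homozygous there.
Confirmed candidates rank above untested; within groups dual-workflow
candidates rank first, then score (combined when present, else diffusion,
else direct — the scales differ, but the ordering is only used within a
provenance group and is dominated by the 0–2 combined score when both
kinds are present), then gene symbol.

## The synthetic generator

The generator exists so every stage — and the end-to-end funnel — can be
tested against known truth without any external download. Its defaults
define the study conditions and are not tuned per test:

* 2,000 autosomal and 300 chrX sites; true alt-allele frequencies from
  Beta(0.7, 4) (median ≈ 0.10, a realistic skew toward rare), parents
  drawn under Hardy–Weinberg, proband by Mendelian transmission with a
  haploid maternal X for the male proband.
* Exactly 5 injected autosomal de novos (parents forced `0/0`, proband
  `0/1`) — everything else is transmission-consistent by construction.
* Exactly 10% of sites receive at least one quality-metric violation;
  violating and passing values are drawn from disjoint open intervals so
  rounding can never cross a threshold, and 5% of passing metrics are
  left absent to exercise the absent-never-fails contract.
* Panel frequencies are correlated noisy copies (log-normal factor,
  sd 0.25) of the latent truth, each panel independently missing at 10% —
  independent draws per panel would make multi-panel exclusion
  unrealistically leaky.
* A 300-node preferential-attachment network (one edge per new node,
  giving tree-like sparsity and hub structure) with weights in
  (0.705, 1], 25 seed genes, the planted gene chosen among direct seed
  neighbors, and 10 distractor genes at hop distance ≥ 3 from every seed.
* The planted variant: X-linked, carrier mother, hemizygous proband,
  missense, AJ frequency 0.01991 with rare frequencies elsewhere, SIFT
  0.001 / PolyPhen-2 0.999. The 10 distractor variants are X-linked and
  rare but benign-scored, so they reach the network branch and must be
  rejected there.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: linkage disequilibrium between
sites, genotyping error and allelic dropout, indels and multi-nucleotide
variants, realistic gene symbol vocabularies, annotation disagreement
between transcripts, and the actual degree distribution of curated
interactomes. The planted-recovery criterion demonstrates that the
pipeline's logic composes correctly, not that its thresholds are optimal
for any particular cohort.

All randomness flows through a single seeded generator per simulation
call (the network stream is offset by +1 from the trio stream so the two
files are independent but jointly reproducible); global RNG state is
saved and restored, and identical configurations yield byte-identical
files.

## Problem sizes in the shipped checks

The test suite exercises 10,000-variant quality partitions, 10,000-site
Mendelian consistency, 100-graph propagation oracles (≤ 50 nodes against
a dense solver, ≤ 30 nodes against brute force), and 100 seeded
end-to-end replicates of the demo, asserting recovery of the planted gene
as the top confirmed candidate in at least 95 of them. These sizes were
chosen as the smallest that make the binomial and numerical margins
comfortable; they are the package's own test design, and all inputs are
regenerated programmatically at test time.

## Known limitations

* Compound heterozygotes, mitochondrial and imprinting models are out of
  scope; the mode partition is exactly the three rules above.
* SIFT/PolyPhen-2 scores are consumed as annotations, never recomputed;
  variants missing either score can never be PDS, which is conservative
  for workflow 2.
* Multi-allelic splitting maps "other alt" alleles to the reference in
  the per-allele genotype view; sites where two alts segregate in the
  same trio are rare but lose information under this convention.
* The funnel is deliberately sequential: a variant dropped by an early
  stage is never revisited, so provenance tags record exactly one drop
  point per branch.
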