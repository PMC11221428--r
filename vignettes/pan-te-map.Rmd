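---
title: "Building and analyzing a pan-TE map: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analyzing a pan-TE map: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panTE)
```

## The problem

Transposable elements (TEs) are a major source of structural variation in
plant genomes, and TE insertion polymorphisms are increasingly implicated in
domestication and agronomic traits. With chromosome-level assemblies for
hundreds of accessions it becomes possible to call TE presence/absence
variants (PAVs) directly from whole-genome alignments instead of inferring
them from short reads, to genotype the resulting loci across a population,
and — given outgroup genomes — to say for each locus which allele is
*ancestral* and which is *derived*.

panTE implements that workflow as a set of composable stages:

1. **PAV calling** (`extract_pavs`): every insertion (I) or deletion (D)
   operation longer than 50 bp in a query-vs-reference alignment CIGAR
   becomes a candidate PAV. The ">50 bp" rule is read as a strict
   inequality (a 51 bp gap passes, a 50 bp gap does not); the threshold is
   the `min_len` argument.
2. **TE classification** (`classify_te_variations`): a PAV whose sequence
   is more than 90% covered by annotated TE intervals (union semantics —
   overlapping annotations never count a base twice) is a *TE variation*.
   ">90%" is again strict and configurable (`min_te_frac`). A PAV may span
   several TE units; the locus-level family label is the unit covering the
   most bases, ties broken by the earliest position.
3. **Non-redundant merging** (`merge_loci`): single-linkage clustering.
   Deletions cluster at reciprocal overlap ≥ 0.8; insertions cluster when
   their insertion points are within ±25 bp *and* their min/max length
   ratio is ≥ 0.8. No published merging rule exists for this step, so the
   tolerances are package defaults, exposed in the configuration. Single
   linkage means transitive merges are intentional.
4. **Genotyping** (`genotype_matrix`): an accession is `1/1` at a locus if
   it contributed a member PAV, `0/0` if its alignment covers the
   breakpoint region `[start − 25, end + 25]` without one, and `NA`
   otherwise. Assembly-to-assembly alignment cannot observe
   heterozygosity, so `0/1` enters only through an optional external het
   table (in the simulator, the known truth). `NA` genotypes are never
   imputed.
5. **Polarization** (`polarize_loci`): the ancestral allele is the strict
   majority allele among non-`NA` outgroup genotypes; a het outgroup votes
   for neither allele, and a tie leaves the locus *unpolarized* (excluded
   from dTE analyses, counted and logged). An ingroup accession whose
   genotype differs from the ancestral homozygote — the opposite homozygote
   or a het — is a derived-state carrier. A locus segregating in both
   states among the ingroup is a *derived TE variation* (dTE). Polarity
   follows from the ancestral allele and the PAV orientation: the derived
   allele either gained the TE (INS) or lost it (DEL).

Downstream analyses operate on the polarized matrix: carrier-frequency
spectra and INS/DEL ratios, Hudson FST scans, permutation enrichment
against SNP-based selective windows, TE-family enrichment, presence/absence
diversity, LD with nearby small variants, genic context, structure
(PCA/neighbor joining), LTR insertion-age dating, cis-eQTL and GWAS.

## Statistical choices

**FST estimator.** No estimator is canonical for presence/absence loci, so
the package uses the sample-size-corrected Hudson estimator
(`hudson_fst`), the standard recommendation for two-population scans:

$$F_{ST} = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}}
               {p_1(1-p_2) + p_2(1-p_1)}$$

with allele counts on the derived allele (a het contributes one of two).
Negative values are reported, not clamped — they carry information about
sampling noise and do not affect ranking. Outliers are loci at or above
the empirical 95th percentile; each locus also carries a rank percentile
(fraction of loci with strictly greater FST). Window-level SNP FST uses
the ratio-of-averages rule (summed numerators over summed denominators per
100 kb window), which is robust to low-information SNPs.

**Permutation enrichment.** The observed statistic is the mean dTE count
over the selective windows; the null redraws the same number of windows
uniformly without replacement, 500 times by default. The empirical p-value
uses the add-one correction \(p = (1 + \#\{null \ge obs\})/(n_{perm}+1)\)
so that p is never zero.

**Diversity.** Per-locus π treats each accession as one sampled
presence/absence state: \( \pi = 2\hat p(1-\hat p)\,m/(m-1) \) with
\(\hat p\) the carrier frequency over the \(m\) non-`NA` accessions. This
equals the mean pairwise difference over all accession pairs exactly (the
package tests it against a brute-force pair loop). An allele-based mode
would double the sample size and count hets as half-differences; the
carrier-based convention matches how the genotypes are observed
(assemblies, one haplotype each).

**Variability summaries.** Cross-accession copy-number CV and SD use the
population (divide-by-n) convention.

**Association models.** Expression and trait associations are ordinary
least squares on dosage (0/1/2): no covariates for the cis scan (±50 kb),
and the leading principal components (3 by default) of the tested variant
class for GWAS. Mixed-model kinship correction is intentionally out of
scope. Multiplicity: per-gene Bonferroni over that gene's cis variants,
then Benjamini–Hochberg at 5% across genes on the per-gene minima, for
eGene calling; genome-wide Bonferroni 0.05/M for GWAS. These conventions
are printed in every report header because no single convention is
canonical.

**Insertion dating.** `ltr_insertion_time` applies the Jukes–Cantor
correction \(d = -\tfrac34\ln(1-\tfrac{4p}{3})\) to the mismatch
proportion of a pre-aligned terminal-repeat pair (gap columns dropped) and
converts with \(T = d/(2\mu)\), with \(\mu = 1.3\times10^{-8}\)
substitutions/site/year by default (the common rice rate; configurable).
Saturated pairs (\(p \ge 0.75\)) are flagged undefined rather than
extrapolated. The same function accepts any paralogous pre-aligned pair,
which covers elements without paired LTRs when a suitable pair is
supplied.

## What the simulator emulates — and what it does not

`simulate_population()` generates an ancestral backbone, plants
non-overlapping TE events (placement keeps ≥100 bp between events and from
chromosome ends so truth↔call matching is unambiguous), draws genotypes
from per-subpopulation derived-allele frequencies, and emits every file the
pipeline consumes: per-accession FASTA, truth PAF alignments with `cg:Z`
CIGARs, per-genome TE annotations, gene models, a SNP/InDel VCF with
Balding–Nichols differentiation (F = 0.15), a recombination track,
expression and phenotype tables, and the full truth set.

Key design choices, fixed once:

- **The reference is a sampled ingroup accession**, not the ancestor. The
  map therefore contains both reference-present loci (deletion-type PAVs
  in carriers) and reference-absent loci (insertion-type PAVs), and
  polarization must disentangle PAV orientation from ancestral state —
  exactly the situation with a domesticated reference like Nipponbare.
- **Frequency model.** INS events draw carrier frequencies from
  Beta(0.35, 1.4) (skewed rare) and DEL events from Beta(1.2, 0.9)
  (flatter), reflecting the empirical pattern that young insertions
  dominate the rare end of the spectrum; this is what makes the INS/DEL
  count ratio fall with frequency. A configurable fraction of events
  (`fraction_selected`) instead receives strongly differentiated
  frequencies (low in one subpopulation, at least `selected_margin`
  higher in another), providing FST-scan truth.
- **Every planted event is visible against the reference**: if the
  reference carries the ancestral allele and no ingroup carrier was drawn,
  the genotype vector is redrawn (frequency model intact). This slightly
  conditions the realized frequency of very rare events; the calibration
  tests therefore check the frequency law at the population level rather
  than per rare locus.
- **`NA` genotypes are mechanistic**, not label noise: the truth alignment
  is broken around the locus (a 40 bp coverage gap on each side), and the
  caller must rediscover the missing coverage and emit `NA`. At
  `na_rate > 0` a locus whose every carrier happens to be masked is
  legitimately absent from the map; exact end-to-end recovery is therefore
  asserted at `na_rate = 0`.
- **Heterozygotes** are injected directly (carriers are het with
  probability `het_rate`) and exposed through the het table, because
  assembly alignment cannot observe them; the haplotype sequence carries
  the derived allele.

What the simulator does *not* model: coalescent genealogies, recombination
during simulation (the ρ track is an exogenous covariate), nested or
overlapping TE events, sequence divergence inside aligned segments
(alignments are exact `=` runs plus indels), alignment artifacts, and
read-level errors. Passing tests therefore demonstrate the correctness of
the calling/merging/polarizing logic and the calibration of the
statistics, not robustness to noisy real-world alignments — the latter
depends on the upstream aligner.

Simulation is on the + strand throughout; the PAF reader's minus-strand
contract (target-forward CIGAR, query as reverse complement, coordinates
on the original strand) is exercised by dedicated fixtures instead.

## Numerical and degeneracy conventions

- Coordinates are 0-based half-open in memory; GFF3 is 1-based inclusive
  and VCF POS 1-based on disk. `M` CIGAR ops are accepted and treated as
  aligned for span accounting; PAV extraction uses only I/D ops.
- Adjacent I and D ops are not merged into substitutions; each op is an
  independent PAV.
- Zero-variance vectors: correlation and regression return `NA` with a
  degenerate flag instead of erroring; monomorphic variants are skipped in
  scans and recorded.
- Genic context ties are broken CDS > 5'UTR > 3'UTR > intron > promoter >
  downstream; insertion points use the containing feature; a locus
  overlapping two genes counts for both genes.
- eGene leading variants break p-value ties by larger r², then smaller
  coordinate.
- All stochastic steps (simulation, permutation) take explicit seeds, and
  an identical configuration reproduces byte-identical outputs.

## Problem sizes used in the test-suite and acceptance runs

The bundled checks run a demo simulation of 1 Mb across 2 chromosomes with
30 ingroup accessions (two subpopulations of 15), 2 outgroups and 300
planted events for end-to-end truth recovery; genotype-level simulations
with 100–200 accessions per subpopulation and 40–1000 loci for the FST,
eQTL and GWAS power studies; 200 simulated data sets for each calibration
study; and 1000 random instances per statistical kernel for oracle
equivalence. These sizes give stable pass/fail behavior on a single CPU
while exercising every code path; all of them scale up through the same
configuration objects.

## Known limitations

- Genotyping from assembly alignment is haploid in nature; heterozygous
  calls require external evidence (long-read re-genotyping is out of
  scope).
- The merger assumes breakpoint-stable calls; highly fragmented alignments
  around nested TEs would need a graph representation, which is a
  non-goal.
- The eQTL/GWAS models are OLS; population structure beyond a few PCs
  (kinship, admixture) is not corrected.
- Fine-mapping, GO enrichment and climate-data joins are intentionally
  outside the package surface.
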