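---
title: "Models and design choices in the MAPK family evolution pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in the MAPK family evolution pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mapkevol)
```

This vignette is the package's own account of its science: the models
implemented, the parameters that matter, what the synthetic-data world
does and does not emulate, and the choices made where the design was
genuinely open. It states no empirical result that the test suite or the
acceptance script does not itself compute.

## 1. The analysis in one paragraph

A plant kinase family (the MAPKs, defined by the TxY activation-loop
motif) is identified in a proteome by profile scoring, paired with
orthologs in a sister species to estimate between-species divergence
(Ka/Ks), and profiled within a population of resequenced accessions for
nucleotide diversity partitioned by site class (π_a/π_s). Sliding windows
localize divergence/polymorphism spikes along each gene; distance
phylogenies and coexpression dendrograms are compared topologically; and
the family's statistics are tested against a genome-wide background with
Wilcoxon rank-sum tests. Every input is synthetic with recorded ground
truth, so each method is validated by planted-truth recovery rather than
by re-downloading genomes.

## 2. Codon counting and divergence

`count_sites()` and `count_differences()` implement Nei–Gojobori-style
counting. Site counts use stop-excluded denominators: at each codon
position the synonymous fraction is (synonymous changes)/(changes not
creating a stop), so S + N = 3 exactly for every sense codon. Differences
are averaged over all k! orderings of the single-base steps between two
codons, discarding orderings that pass through a stop; if every ordering
does, the average is taken over all of them and flagged. These
3721-codon-pair tables are precomputed once per session.

`ka_ks()` drops gap/ambiguous/stop codon columns whole (common practice;
the source analyses are silent on this), averages site counts over the two
rows, and applies the Jukes–Cantor correction d = −(3/4)ln(1 − 4p/3) to
each class. Two numerical regimes matter:

* **Low divergence** (pS ≲ 0.05): the estimator is consistent; mean
  recovery of the simulated ω is verified to Monte-Carlo precision
  (3 SE over 50 × 10,000-codon replicates) in the acceptance suite.
* **Appreciable divergence** (the *A. thaliana*/*A. lyrata* scale,
  Ks ≈ 0.13): JC assumes every site can saturate to 3/4 difference, but
  two-fold degenerate synonymous sites saturate at 1/2, so Ks is slightly
  under-corrected and Ka/Ks overestimated by a few percent. The suite
  asserts only the coarse band [0.17, 0.23] for a true ω of 0.2 there.
  Users comparing families to backgrounds are unaffected (both carry the
  same bias), which is also why the paper-level conclusions are
  estimator-robust.

A maximum-likelihood codon model (YN00-style iteration) is deliberately
out of scope; the kappa-weighted refinement of site counting is not
implemented because the recovery experiments run at κ = 1, where NG86's
unweighted sites are exact (see §4).

## 3. Diversity and pseudochromosomes

Variant tables (4-column TSV dialect: chrom, pos, ref, alt with "−" as
the deletion allele) are substituted into the reference per accession.
Deletions become runs of "-" of the reference length — the
length-preserving convention is what makes a single GFF3 coordinate
system valid for all accessions, and is the only coherent reading of
"extract the CDS positions from the 80 pseudochromosomes".

π, π_a, π_s are mean pairwise difference proportions over all accession
pairs (Tajima's pairwise estimator without the n/(n−1) correction,
matching the pairwise-average form of polydNdS-style tools), with the
site-class partition from the same NG86 tables as divergence — but with
no multiple-hit correction, standard for within-species data. Codons
containing a premature stop in either row of a pair are dropped like
gapped codons, so genes carrying large-effect alleles remain computable
before the exclusion policy runs.

Large-effect detection flags premature stops (gap-free in-frame stops
before the final codon), lost start/terminal-stop codons, and any "-"
run whose length is not divisible by 3 (frameshift). The exclusion policy
offers the two modes used in practice: drop the gene (background sets) or
drop only the affected accessions (the family-specific rescue that keeps
a gene analysable with 78–79 of 80 rows).

## 4. The synthetic world

All generators are pure functions of (parameters, seed). Defaults state
the emulated world; none were revisited after seeing test outcomes.

* **Genes**: ATG + uniform sense codons + stop; 400 codons by default
  (a typical Arabidopsis CDS length).
* **Ortholog evolution**: proposal/acceptance codon model. Single-base
  changes are proposed (transitions weighted κ over transversions) and
  accepted with relative rate 1 (synonymous), ω (nonsynonymous), 0
  (stop-creating). The branch length t is the expected number of
  *proposed* changes per codon; realized substitutions are fewer under
  constraint. All recovery checks concern ratios, which are invariant to
  this time scaling. Default t = 0.4 gives Ks ≈ 0.13, the
  *thaliana*/*lyrata* scale. Default κ = 2 (a realistic plant
  transition bias) for bundle realism; the estimator-recovery experiments
  run at κ = 1 because NG86's unweighted site counting assumes an
  unbiased mutation process — they test estimator correctness under its
  own model, not robustness to κ.
* **Population samples**: infinite-sites heuristic. Mutation count ~
  Poisson(θ·L·a_n), derived-allele counts from the neutral frequency
  spectrum (P(i) ∝ 1/i), random accession subsets, nonsynonymous
  mutations thinned by ω. E[π] = θ at ω = 1 (exactly, by construction);
  there is no genealogy, recombination or demography, so the sampling
  variance is *smaller* than a coalescent's — the acceptance band uses
  the (larger) coalescent variance and is therefore conservative.
  Stop-creating mutations are redrawn; premature stops and in-CDS
  deletions enter only through explicit injection interfaces, because
  they are the "large-effect" class handled separately downstream.
* **Genome bundles**: 2–4 exons per gene, both strands, two chromosomes,
  intergenic SNPs/deletions; CDS-local mutations are mapped to genomic
  coordinates with allele complementation on the minus strand. Deletions
  whose footprint would cross an exon junction are dropped (keeping every
  record genomically contiguous).
* **Proteomes**: members are mutated copies of a 350-residue consensus
  with the requested TDY/TEY/MEY loop implanted and protected.
  Substitutions are drawn from a conservative 3-residue set per column
  (families substitute within a narrow residue repertoire, not uniformly
  over 20). The seed alignment is drawn at 8% divergence, members at 5%:
  the seed collection stands in for published family members across
  studies, whose spread exceeds the single proteome actually scanned —
  the situation in which a seed-derived threshold is applied.
* **Expression**: gene g in cluster c is √ρ·z_c + √(1−ρ)·σ·η_g per
  sample; ρ = 0.9, σ = 1 by default.

What a green planted-truth test establishes: the method implementations
recover parameters under their own model assumptions. What it does not
establish: robustness to real-data violations — alignment error, indel
realism, recombination, demography, expression normalization artifacts.

## 5. Family scan

The profile is an ungapped position-specific scoring matrix
(log natural-odds with pseudocount 0.5 by default; columns > 50% gaps
dropped; background = seed residue composition, smoothed). A full profile
HMM adds insert/delete states that the discriminative signal here — a
highly conserved kinase core plus a decisive motif filter — does not
need at this scale; this is a deliberate simplification of the
hmmbuild/hmmsearch route.

The reporting threshold is the mean seed self-score minus 3 SD, with
self-scores computed **leave-one-out** (each seed scored against the
profile of the remaining seeds). In-sample self-scores are inflated by
roughly +30 log-odds units on the default world — each sequence's own
residues contribute to the frequencies it is scored against — and a
threshold derived from them misses genuine out-of-sample members.
Decoy scores sit hundreds of log-odds units below members, so the
threshold's exact placement is uncritical within a wide band.

Proteins shorter than the profile are scored over all full-protein
placements inside the profile (never an error). Refinement rebuilds the
profile from the current candidates' best-window segments, rescans, and
adds motif-positive new hits until the set is stable; oscillation beyond
`max_iter` returns the last set with a warning. MAPK vs MAPK-like
separation is phylogenetic, not scan-level: the scan reports one
candidate pool.

## 6. Windows

The nucleotide grid is width 51 / step 9 (truncated final window; windows
shorter than one codon dropped). 51 is not divisible by 3, so each window
is codon-trimmed inward rather than re-phased — the published window grid
is preserved while site-class arithmetic stays codon-coherent. Per-window
divergence is the mean over (ingroup row, outgroup) pairs; per-window
ratios carry NA flags when the denominator class has zero sites or
differences, which is frequent at 51 nt and is information, not error.
With width = step, per-window difference counts tile the whole-gene count
exactly (asserted in the acceptance suite).

## 7. Trees and comparison

NJ follows the Saitou–Nei Q-criterion; ties are broken by the
lexicographically smallest pair of subtree representative labels, and a
negative branch length is clamped to zero with the deficit moved to its
sister so the joined distance is preserved. UPGMA uses size-weighted
average linkage with merge height d/2 (output ultrametric by
construction). Bootstrap support is the plain percentage of column-resample
replicates containing the same leaf bipartition — a simplification of
multiscale bootstrap probabilities (pvclust), documented as such.
Topology overlap counts shared non-trivial bipartitions normalized by
n − 3; for n ≤ 3 the overlap is undefined (NA).

Wilcoxon "significance" is the two-sample rank-sum test (pairing is
meaningless between a family and a background); exact p-values enumerate
all label assignments and take the two-sided tail as distance of U from
its mean (the convention R's `wilcox.test` also uses), with midranks for
ties; the approximation uses continuity and tie-corrected variance.
Regression is OLS with intercept on the (Ks, Ka) or (π_s, π_a) axes.
No multiple-testing correction is applied across the three statistics —
they are reported individually — and the output metadata says so.

## 8. Known limitations

* NG86 + JC bias at moderate divergence (§2); no YN00/ML estimator.
* The population generator has no genealogical correlation structure:
  variance-sensitive statistics (e.g. Tajima's D, which is out of scope)
  could not be validated against it.
* Smith–Waterman best-hit search is O(query × target) exact alignment —
  appropriate at desk scale, not for genome-wide ortholog mapping.
* Bootstrap supports on very short alignments are granular (multiples of
  100/n_reps).
* The expression dendrogram reports topology only; no AU/BP-style
  per-cluster significance.
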