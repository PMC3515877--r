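# mapkevol

Molecular-evolution analysis of a plant gene family — the mitogen-activated
protein kinases (MAPKs) — built as a fully testable pipeline over synthetic
data with recorded ground truth.

## The scientific problem

MAPKs are the last tier of the MAP3K → MAP2K → MAPK phosphorylation cascade
and are defined by a conserved activation-loop motif (TxY: the TDY and TEY
classes, plus a rare atypical MEY). Two population-genetic questions frame
the analysis of such a family:

1. **Between species** — has purifying selection constrained the family
   since the split of *Arabidopsis thaliana* and *A. lyrata*? Measured by
   the ratio of nonsynonymous to synonymous divergence,
   Ka/Ks (dN/dS), with Ka/Ks ≪ 1 indicating purifying selection.
2. **Within a population** — is the same constraint visible among
   resequenced accessions? Measured by nucleotide diversity π partitioned
   into nonsynonymous and synonymous sites (π_a/π_s).

Around these sit the supporting analyses: profile-based identification of
family members in a proteome and classification of their activation loop;
construction of per-accession *pseudochromosomes* from variant tables so
that one reference coordinate system serves all accessions; sliding-window
scans (width 51 nt, step 9 nt) that localize divergence/polymorphism spikes
along a gene; distance phylogenies (neighbor joining with bootstrap,
UPGMA) and coexpression dendrograms (distance = 1 − Pearson r) whose
topological discordance is the signature of transcriptional
subfunctionalization.

Reproducing the original numbers requires downloading 13 proteomes and an
80-accession variant release; instead, every input here is generated by the
package's synthetic-data module under stated parameters (mutation model,
ω, θ, branch lengths, planted family members, planted expression clusters),
and the tests check that each method recovers the planted truth.

## Methods at the core

* **Sites and differences (NG86 counting).** Per codon, the synonymous
  site count is `S = Σ_pos (#synonymous single-base changes) /
  (#changes not creating a stop)` and `N = 3 − S`. Differences between two
  codons are averaged over all stop-free orderings of the single-base
  steps (pathway averaging), so `Sd + Nd` equals the number of differing
  positions.
* **Divergence.** `pN = Nd/N`, `pS = Sd/S`, each corrected for multiple
  hits with Jukes–Cantor `d = −(3/4)·ln(1 − (4/3)p)`; `Ka/Ks = d(pN)/d(pS)`.
* **Diversity.** π, π_a, π_s are mean pairwise difference proportions over
  all n(n−1)/2 accession pairs (Tajima's pairwise estimator, uncorrected —
  standard for within-species polymorphism), with codon columns containing
  gaps, ambiguity or stops dropped per pair.
* **Family scan.** A position-specific log-odds profile (pseudocount
  smoothing, majority-gap columns dropped) built from a seed alignment;
  best ungapped-window scores; reporting threshold = mean leave-one-out
  seed self-score − 3 SD; activation-loop classes from the literal motif
  patterns `T?YV??RWYRAPE` / `MEY??RWYRAPE`; iterative species-specific
  profile refinement to a fixed point.
* **Trees.** Saitou–Nei neighbor joining (exact on additive matrices) and
  size-weighted UPGMA, ordinary bootstrap over alignment columns,
  Robinson–Foulds-style bipartition overlap.
* **Statistics.** Two-sample Wilcoxon rank-sum with exact enumeration for
  small samples (normal approximation with tie/continuity corrections
  otherwise), OLS regressions, and 1.5×IQR box summaries.

## Worked example

```r
library(mapkevol)

# a 2000-codon gene, an ortholog diverged at t = 0.4 under omega = 0.2
cds      <- simulate_coding_gene(2000, seed = 1)
ortholog <- evolve_ortholog(cds, 0.4, omega = 0.2, kappa = 1, seed = 2)
ka_ks(c(cds, ortholog))
#>   n_codons    N    S    Nd    Sd      pN     pS      Ka     Ks  ratio
#> 1     1999 4448 1549 136.5 184.5 0.03069 0.1191 0.03133 0.1297 0.2416

# a 10-accession population sample at theta = 0.005 under the same omega
pop  <- simulate_population_sample(cds, n_accessions = 10,
                                   theta_site = 0.005, omega = 0.2, seed = 3)
rows <- vapply(pop$accession_ids, function(acc) {
  v <- pop$variants[pop$variants$accession_id == acc, , drop = FALSE]
  apply_variants(cds, v)
}, "")
nucleotide_diversity(rows)
#>    n    L     pi     pi_a    pi_s ratio ratio_undefined n_pairs
#> 1 10 5997 0.0016 0.000899 0.00363 0.247           FALSE      45
```

Both estimators recover the simulated constraint: the divergence ratio
(0.24) and the polymorphism ratio (0.25) sit near the planted ω = 0.2,
and π (0.0016) reflects θ = 0.005 thinned by selection against
nonsynonymous changes.

The `analysis/` directory holds the numbered stage drivers
(`01_simulate_bundle.R` … `07_family_vs_background.R`); run them in order
from the repository root to produce the full study under `results/`:
simulation bundle, family scan table, Ka/Ks and π tables, window tracks,
trees, and the family-vs-background comparison (which prints the
purifying-selection signature: Ka and Ka/Ks significantly reduced,
Ks not).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete pipeline end to end on a small synthetic bundle
(simulate → scan → orthologs → Ka/Ks → diversity → windows →
trees/expression → comparison), checking that every stage executes against
the installed package, and writes the JSON target report to `--out`.
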