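---
title: "Methods: phylogenomic profiling of UFMylation and C53 sAIM evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenomic profiling of UFMylation and C53 sAIM evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

UFMylation — conjugation of the ubiquitin-fold modifier UFM1 to substrate
lysines via the UBA5 (E1) → UFC1 (E2) → UFL1/DDRGK1 (E3) cascade — regulates
ER homeostasis, and the ER-phagy receptor C53 (CDK5RAP3) couples it to
selective autophagy. C53's intrinsically disordered region (IDR) binds both
UFM1 and ATG8 through *shuffled* ATG8-interacting motifs (sAIMs, consensus
`I[DS]W[GD]`) alongside a canonical AIM/LIR (`[WFY]xx[LIV]`). Three linked
comparative questions drive the package:

1. Which eukaryotic lineages retain or have lost the UFMylation machinery,
   and does C53 co-evolve with it? (ortholog presence/absence profiling,
   Dollo loss mapping, phi-coefficient co-evolution)
2. Are the sAIMs conserved specifically in UFM1-retaining species?
   (two-group column conservation, motif scanning)
3. What are the quantitative binding and modification signatures?
   (anisotropy isotherm fitting, NMR CSP analysis, remnant masses)

The real study ran on 153 eukaryotic proteomes; that input is not
redistributable or desk-scale, so the package ships a first-class synthetic
generator whose statistical structure matches what the downstream analysis
assumes, plus the peptide strings and printed constants that *are* in the
text.

# Pipeline model and assumptions

## Homology search

Round 1 is affine-gap Smith–Waterman (gap cost `11 + (L-1)·1`, BLOSUM62
with `X` scored 0) with Karlin–Altschul E-values `E = K·m·n·e^(−λS)` using
the standard gapped constants (λ = 0.267, K = 0.041); `n` is the searched
proteome's total residue count. Round 2 builds a position-specific log-odds
profile (PSSM) from the Henikoff-weighted, 10%-gap-trimmed alignment of
round-1 orthologs:

```
score(c, a) = log2( ((w_c(a) + pc·bg(a)) / (W_c + pc)) / bg(a) )
```

with pseudocount mass `pc = 1` and Robinson–Robinson background. Profiles
are *not* full HMMs — no insert/delete states. Placement against a target
is local affine-gap alignment of the PSSM; we deliberately allow
unrestricted affine gaps rather than the bounded two-gap extension
originally sketched, since it is a strict superset covered by the same
null calibration and keeps one alignment kernel for the whole package.

Because PSSM scores have no analytic E-value, each profile is calibrated
once per run: 200 seeded background sequences are scored, a Gumbel is fit
by maximum likelihood, and `λ̂ = 1/β`, `K̂ = e^(μ/β)/(L·n0)` convert tail
probabilities to E-values. The calibration is part of the seeded state, so
identical configs give identical hit lists.

The rescue stage emulates translated search of unannotated genomes:
six-frame translation, ORFs ≥ 30 residues (all-`X` ORFs discarded, which
also makes an all-`N` genome yield zero ORFs), profile search over the
ORFs. Spliced genes are out of scope; the generator plants single-exon
orthologs only.

## Alignment processing

Progressive alignment with an NJ guide tree (identity distances from
pairwise global alignments) and profile–profile merging. Trimming follows
the trimAl `-gt` convention: *retain* columns whose non-gap fraction is at
least the threshold (0.3 for analysis alignments, 0.1 before profile
building). The fragment rule drops rows with under 50% residues over the
retained columns; it runs after trimming, matching the order the source
protocol lists. Both operations are idempotent and never alter retained
characters.

## Gene trees and the paralog screen

Gene trees are NJ on Poisson-corrected p-distances (`d = −ln(1−p)`,
saturated pairs clamped at 5). NJ replaces ML inference: topology-accuracy
claims are made only on synthetic data, where NJ is exact for additive
distances. The paralog screen takes the smallest clade containing a
reference set. Midpoint rooting is the default, but the pipeline roots on
the search query: during implementation we found that with a paralog clade
duplicating near the family root, the midpoint falls *inside* the paralog
clade, splitting it across the root so the reference clade necessarily
captures half the paralogs. The query is a genuine outgroup to the
ortholog crown radiation and gives a deterministic, correct rooting. The
reference set is the query plus each taxon's best round-1 hit — the
observable stand-in for the original study's manual tree curation (a
stand-in, not asserted as equivalent).

## Dollo loss mapping

Gain is fixed at the root (the study's conclusion is ancestral presence
with secondary losses; `gain = "mrca"` is available). Losses are the
maximal all-absent subtrees, which is provably the minimum-cardinality
loss set under single-gain semantics — the test suite checks this against
brute-force enumeration on all presence vectors over trees of up to 8
leaves. No attempt is made to distinguish loss from dataset
incompleteness; the matrix records provenance instead.

## Co-evolution

Phi coefficients on the assembled presence/absence columns (equal to the
Pearson correlation of the binary vectors); any zero marginal flags the
pair undefined. Clustering is Ward-D2 on Euclidean distances between rows
of the phi matrix (each family's correlation profile) — the feature space
is stated here because heatmap practice varies. Undefined entries are
mean-imputed with a warning before clustering only.

## Conservation scoring

The single-group track is the expected pair score
`Σ_a Σ_b f(a) f(b) S(a,b)` with Henikoff-weighted, gap-excluded
frequencies, binned 1–9 by equal-frequency ranks within one alignment
(9 = most conserved; ties share the minimum rank, so a degenerate
alignment collapses into one class). This is a declared proxy — no
Bayesian rate model, no cross-alignment calibration. The two-group track
is the cross-group expected pair score `Σ_a Σ_b f_A(a) f_B(b) S(a,b)`;
negative values mark signature columns where the groups carry dissimilar
residues. Henikoff weights substitute for the original tool's Voronoi
weighting. BLOSUM62 is the default matrix (integer values make examples
exactly checkable); an LG-derived log-odds table can be loaded from file.

# The synthetic world

Defaults state one fixed world (12 taxa, 7 families, exponential branch
lengths with mean 0.12 subs/site) and are not revisited per test:

* **Families.** ufm1 (per-branch loss probability 0.12, constrained to an
  informative pattern), uba5/ufc1/ufl1 (0.05), ufsp2 (0.08), ddrgk1 with
  losses *copied* from ufm1 (the planted co-evolution partner), and c53
  present everywhere.
* **Substitution process.** Per-site counts ~ Poisson(branch length ×
  length); replacements drawn ∝ exp(BLOSUM62 row / 2) — conservative
  substitution structure without matrix exponentiation.
* **Paralogs** duplicate on a 0.5-subs/site stem below the family root and
  then evolve at 3× branch rates. The stems matter: without them the
  gene-tree root is a degree-4 node (query, paralog clade, two ortholog
  lineages) and "the ortholog clade" is topologically undefined, so no
  screen could separate paralogs even in principle. The ortholog crown
  gets a 0.1 stem for the same reason.
* **Decoys** are random sequences matching the family's residue
  composition, so presence calls cannot succeed on composition alone.
* **Fragments.** Exactly two orthologs (in ufc1 and ufsp2) are truncated
  to 40% — below the 50%-data rule — providing the two expected mismatches
  (2/84 ≈ 2.4%) inside the ≥95% matrix-accuracy criterion.
* **Hidden ortholog.** One uba5 ortholog is removed from its proteome and
  reverse-translated onto the reverse strand of that taxon's genome; only
  the rescue stage can recover it, which exercises the provenance record.
* **C53.** Conserved 80-residue helical flanks (rate 0.05) around a
  140-residue IDR (rate 0.3). Motifs (three `IDWD` sAIMs and one `WEIV`
  cAIM) sit between 7-residue conserved anchors drawn from an alphabet
  without I/W/D/S (so anchors can never take part in a sAIM match).
  UFM1-retaining taxa keep exact motifs (purifying selection); UFM1-less
  taxa get motif 4-mers ablated with residues whose BLOSUM62 scores
  against the IDWD consensus are strictly negative, a 30-residue tail
  deletion (the "shorter IDR"), a retained cAIM, and a scrub of any
  accidental sAIM. The anchors are what pin the ablated residues to the
  motif columns during alignment — without them the aligner prefers to
  gap the dissimilar residues and the signature columns become all-gap
  flags instead of negative scores.

What a green end-to-end test does **not** establish: performance on real
proteomes (alignment ambiguity, fragmented gene models, contamination,
rate heterogeneity across sites and lineages are all absent or idealized),
nor equivalence with the original HMMER/tree-curation toolchain.

A note on the single-group conservation check: the fixture asserts the
"conserved motif islands in a divergent IDR" pattern *within the
UFM1-retaining group*. Across all rows the planted UFM1-less residues at
motif columns are dissimilar by design (that is what makes the two-group
score strictly negative there), which depresses the all-rows single-group
score; conservation driven by purifying selection is a within-group
statement in this world.

# Biophysics

* `fraction_bound` uses the ligand-depletion quadratic in the
  cancellation-safe form `2L / (s + sqrt(s² − 4PL))`, `s = P + L + K_d`,
  with the `L/(L+K_d)` limit at `P = 0`.
* `fit_kd` minimizes RSS over `(log K_d, r_free, r_bound)` (BFGS then
  Nelder–Mead polish; positivity via the log parameterisation).
  Initialisation: `r_free` = min response, `r_bound` = max response,
  `K_d` = concentration nearest half-response. Flat curves return a
  non-convergence flag rather than an error. Fits with maximal model
  fraction bound < 0.8 are flagged non-saturating (the printed
  148.2 μM affinity does not saturate at 320 μM, and the flag reproduces
  that diagnosis). Whether the original fits floated the plateaus is
  unstated; they are floated here.
* CSP uses `sqrt(ΔδH² + (0.2·ΔδN)²)` — the common ¹⁵N scaling, stated
  because the source does not print its factor — and the three-class
  thresholds are applied with boundary values assigned to the lower class.
* Remnant masses are sums of water-free monoisotopic residue masses at
  six decimals; the two printed adduct masses (VG, DRVG) anchor the table
  as regression values.

# Numerical choices and tie-breaks

* Alignment traceback prefers diagonal > up > left; the best local cell is
  the first maximum in row-major order; an origin score of zero always
  restarts a local alignment (keeps spans minimal).
* NJ input rows are sorted lexicographically before agglomeration and
  negative NJ branch lengths are clamped to 0.
* Conservation bins use `ceiling(rank·9/L)` with minimum-rank ties.
* Every stochastic step (generation, calibration, titration noise) flows
  from an integer seed through `withr::with_seed`; identical configs give
  byte-identical outputs.

# Known limitations

No spliced-gene modeling; PSSMs rather than profile HMMs; NJ rather than
ML trees; rank-based conservation bins are not comparable across
alignments; phi co-evolution is not phylogenetically corrected (by
design — the source analysis used raw phi); the anisotropy model ignores
fluorescence-intensity changes on binding; competition (K_i) models are
out of scope.
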