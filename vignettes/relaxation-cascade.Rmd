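---
title: "Detecting clade-specific relaxation of purifying selection with branch-model Ka/Ks cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting clade-specific relaxation of purifying selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Obligate bacterial endosymbionts lose genes in stages: a gene first escapes
purifying selection (neutralization, Ka/Ks drifting toward 1 while the reading
frame is still intact), then acquires inactivating mutations
(pseudogenization), and finally erodes away. Neutralization is the transient,
hard-to-catch stage: detecting it requires many closely related strains and a
statistical procedure that can attribute a relaxed Ka/Ks to one clade while
the same gene remains constrained elsewhere. `omegarelax` implements such a
procedure for sets of in-frame, codon-aligned genes from clades of closely
related endosymbiont strains (the motivating system is the DNA-repair
/ homologous-recombination pathway of arthropod *Wolbachia*), together with
the alignment-preparation filters, tree-resampling robustness machinery,
and descriptive substitution scans that surround it.

## The codon model

All likelihoods use a Goldman–Yang-style codon substitution model on the 61
sense codons of translation table 11 (bacterial; configurable). The
instantaneous rate from codon $i$ to $j$ is

$$
q_{ij} =
\begin{cases}
0 & \text{more than one nucleotide differs} \\
\mu\,\pi_j & \text{synonymous transversion} \\
\mu\,\kappa\,\pi_j & \text{synonymous transition} \\
\mu\,\omega\,\pi_j & \text{nonsynonymous transversion} \\
\mu\,\omega\,\kappa\,\pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

where $\kappa$ is the transition/transversion rate ratio, $\omega =$ Ka/Ks,
$\pi$ the equilibrium codon frequencies, and $\mu$ fixes the mean
substitution rate at equilibrium to 1, so branch lengths are expected
substitutions per codon. The generator is time-reversible; transition
probabilities come from the eigendecomposition of the symmetrized generator,
with a scaling-and-squaring fallback for numerically degenerate inputs. Codon
frequencies default to F3x4 (position-specific nucleotide frequencies,
stop-codon mass renormalized, zero frequencies floored at 1e-8 with a
warning); `F1x4` and `equal` are available. Gaps, ambiguity codes and any
codon containing a non-ACGT character are treated as missing data
(partial likelihood 1 over all codons) — in particular a partially ambiguous
codon is treated as fully missing, a simplification with negligible effect at
the divergences this package targets. In-frame stop codons in the data are
reported, then treated as missing.

Log-likelihoods are computed by Felsenstein pruning over compressed site
patterns in compiled code, with per-node rescaling against underflow.
Correctness is pinned by an exhaustive-enumeration oracle (summing over all
internal-node codon states on 4-taxon alignments), by a truncated-series
matrix-exponential oracle, and by the semigroup identity
$P(s{+}t) = P(s)P(t)$.

## Branch classes and the model ladder

Strain clades are declared as groups; `label_clades()` tags every branch
whose descendant leaves all belong to one group with that group's class, and
everything else (the backbone, the root side, the outgroup) with the
background class. Selection models are declared as `model_spec`s mapping
branch classes to free, shared or fixed $\omega$ parameters:

* **neutral** — $\omega = 1$ on all branches (0 free $\omega$);
* **single ratio** — one shared free $\omega$;
* **clade model** — one free $\omega$ per clade, with the background/backbone
  branches sharing the first clade's $\omega$. This mirrors a branch-model
  setup in which all clades but one are marked foreground, keeps the model at
  exactly $k$ free ratios for $k$ clades, and gives the single-vs-clade test
  $k-1$ degrees of freedom (2 for the three-clade design);
* **forced-neutral foreground** — the clade model with one clade's $\omega$
  fixed at 1;
* **branch-site Model A** and its null — the standard four-class site
  mixture on a designated foreground clade: proportions
  $(p_0, p_1, p_{2a}, p_{2b})$ with $p_{2a} = (1-p_0-p_1)\,p_0/(p_0+p_1)$,
  $\omega_0 \in (0,1]$ free, $\omega_1 = 1$, and $\omega_2 \ge 1$ free in the
  alternative, fixed at 1 in the null.

For branch (clade) models, each class's generator is normalized to mean rate
1, so a branch length is the expected number of substitutions per codon on
that branch and $\omega$ governs their synonymous/nonsynonymous composition.
For the branch-site mixture that convention would cancel the signal —
per-class normalization gives every site class the same total rate — so
there all site classes share one synonymous clock: each class matrix is
calibrated against the neutral ($\omega = 1$) generator, branch lengths mean
expected substitutions per codon for a neutral site, and sites with
$\omega_2 > 1$ genuinely evolve faster on the foreground. The branch-site
simulator uses the same convention.

Sharing the backbone with the first clade is a genuine design choice: a
four-ratio alternative (separate background class) is expressible with
`model_spec()` directly, but the three-ratio form is what a two-foreground
codeml labeling produces and keeps the published degrees of freedom
(step 1: df 1; step 2: df 2; step 3: df 1; branch-site: df 1, plain
chi-square, which is conservative relative to the 50:50 mixture refinement).

## Fitting

Free parameters are optimized in log space by bound-constrained L-BFGS-B
($\omega \in [10^{-4}, 99]$, $\kappa \in [0.1, 99]$) from three seeded starts
by default, with a coordinate-wise line-search polish whenever the
quasi-Newton search reports an abnormal termination; estimates at the
$\omega$ upper bound are flagged. Branch lengths ($\le 50$) are optimized by
per-edge golden-section line searches on cached directional partials
(an eigen-space factorization makes each 1-D evaluation O(61 × patterns)),
swept in preorder and alternated with the parameter search.

Per gene and per tree hypothesis, branch lengths are optimized once under
the single-ratio model and then held fixed for every other model on that
gene/tree (the reference-fit convention). This stabilizes the cascade and
cuts runtime by an order of magnitude; because every comparison evaluates
both models at the same branch lengths — the null's maximum-likelihood
ones — the resulting statistic is bounded above by the fully profiled LRT
and the chi-square reference stays valid. Full joint optimization remains
available through `fit_model(..., branch_lengths = "optimize")`. Inside the
cascade, each model is warm-started from its parent model's estimates (and
the branch-site alternative from its null), which both speeds convergence
and enforces the nesting contract that an alternative's fitted likelihood
never falls below its null's. The branch-site alternative additionally always
tries an exploratory start with elevated $\omega_2$: the null solution is a
local optimum with a flat $\omega_2$ direction, and a search started only at
$\omega_2 = 1$ can silently stay there.

## The decision cascade

For each gene and each tree hypothesis, `run_cascade()` performs up to four
nested comparisons at the 5% level (strict inequality; a p-value exactly
equal to alpha selects the simpler model):

1. neutral vs single ratio — is the gene under selection at all;
2. single vs clade model (only if the single-ratio model won step 1) — is
   selection heterogeneous among clades;
3. clade model vs forced-neutral foreground, forcing $\omega = 1$ in the
   clade with the highest estimate (chosen per tree; per-tree disagreement on
   that clade is flagged, not resolved) — failing to reject the forced model
   is the neutralization signal, verdict "neutral foreground";
4. for a gene whose consensus verdict is neutral foreground, a branch-site
   check on the foreground clade, run once on the first usable tree
   hypothesis (the published analysis reports a single branch-site p-value
   per gene, not a per-tree range) — a significant result warns that
   positive selection, not relaxation, may have inflated the ratio.

`neutrality_scan_other_clades()` repeats the step-3 forcing for every clade
in turn, localizing the relaxation signal.

Robustness comes from gene-jackknife tree hypotheses: each gene is dropped
in turn from the concatenated supermatrix and a tree rebuilt from the rest,
giving one hypothesis per gene. The consensus rule across hypotheses is
deliberately conservative: a more complex verdict (heterogeneity, and a
fortiori neutralization) stands only when every usable tree supports it;
any disagreement falls back to the simplest verdict among the trees.
Unconverged fits mark a tree unusable; the consensus is computed over the
rest with a warning. Reported ranges (p-values, per-clade $\omega$) are
min–max across usable trees. No multiple-testing correction is applied
across genes, matching the published procedure; a Bonferroni adjustment can
be imposed by passing a corrected alpha.

Tree building itself is deliberately simple: neighbor joining on
Jukes–Cantor-corrected p-distances after an 85% partial-deletion site
filter, with saturated pairs falling back to uncorrected distances and
negative branch lengths clamped at zero. A maximum-likelihood tree search is
not reimplemented — tree hypotheses are inputs to the cascade, not its
contribution — and user-supplied newick trees are accepted everywhere trees
are consumed. With NJ instead of ML search, the number of distinct jackknife
topologies on real data need not match a published count; it is reported,
not asserted.

## Alignment preparation

All preparation filters operate in 1-based inclusive nucleotide coordinates
("np") relative to the gene. Coordinate masks delete whole codon columns
(all-strain scope) or gap out named strains only; intervals not aligned to
codon boundaries are expanded outward to whole codons and the expansion
logged. The seven palindromic (WPE-like) insertion regions of the motivating
data set ship as a default mask table. Genes interrupted by a premature stop
are split into two partitions around the stop codon column. Strains closer
than 0.2% pairwise nucleotide divergence (uncorrected p-distance, pairwise
deletion) are collapsed to one representative per single-linkage cluster —
the lexicographically smallest strain id, a deterministic rule chosen here
because the published choice is not documented.

Intragenic recombination is scanned with a MaxChi-style statistic: for each
strain pair, a two-half window (default 80 variable sites per half, a width
chosen for sensitivity on sub-kilobase genes at moderate divergence) slides
over the variable sites and the 2x2 chi-square contrasts pairwise
differences left vs right of the midpoint. The per-pair maximum is
calibrated by a seeded permutation test (999 site-order permutations) with a
Bonferroni correction across pairs; this keeps the family-wise false-positive
rate at or below alpha without the extreme conservatism of a Bonferroni
correction over all midpoints. The published analysis required agreement of
4 of 7 detection algorithms; only MaxChi is implemented here, so the
consensus filter clamps its threshold to the available detector count with a
warning and the 4-of-7 rule becomes expressible only when users supply
further detectors' results.

## The substitution scan

For a neutralized gene, `clade_exclusive_substitutions()` lists nucleotide
sites where all background strains share one state and (up to
`max_exceptions`) all foreground strains share a different one; records are
classified synonymous/nonsynonymous by translating the background consensus
codon against the substituted codon (a foreground stop is flagged
"inactivating"), annotated with charge / hydrophobicity / aliphatic property
changes, mapped to structural domains, and cross-referenced against a
functional-site list with a configurable numbering offset (the offset
between alignment numbering and the reference protein numbering is data-set
specific and defaults to 0). The amino-acid property table follows standard
groupings (charged D,E negative and K,R,H positive; hydrophobic side chains
A,V,L,I,M,F,W,C,P; aliphatic A,V,L,I) under which the canonical RuvA
replacements annotate as printed: L118P aliphatic-to-nonaliphatic, D165N
negative-to-neutral, T166M nonhydrophobic-to-hydrophobic, P175Q
hydrophobic-to-nonhydrophobic, K180R conservative. The shipped RuvA
functional-site list and domain map are synthetic stand-ins (see their help
page): position 118 and the domain roles are real, the remainder are
placeholders, and real analyses should substitute a curated list.
Pseudogenization checks flag premature stops, frameshift-indicative gap
runs, and poly(A) homopolymer tracts strictly longer than 9 bp.

## The synthetic study design

`scenario_paper_like()` generates the data structure the pipeline assumes:
three monophyletic clades of six strains (supergroup A, supergroup B from
insects, supergroup B from isopods) plus one distant outgroup; twelve gene
partitions named after the homologous-recombination pathway genes; eleven
genes under a single Ka/Ks drawn uniformly from [0.05, 0.35] (the range of
the purifying estimates in the motivating study) and one gene, ruvA, with
clade ratios (0.3, 0.2, 1.0) — neutralized in the isopod clade. Branch
lengths are calibrated by bisection on the model's expected p-distance so
realized divergences hit the study's printed values: intragroup 1.5% / 1.0%
/ 1.2% (inside the reported 1–2% band) and intergroup 10.2%, 9.3% and 5.9%.
Codon frequencies are AT-rich (A/T 0.35 each), kappa is 2, and genes default
to 300 codons — the scale of the shorter genes in the motivating pathway,
chosen so the full design remains analyzable on a desktop. Simulation is
forward along the tree from an equilibrium root draw, with per-gene seed
substreams so adding genes never reshuffles existing ones and identical
seeds give byte-identical FASTA.

What the generator does *not* emulate: indels (gaps arise only from masks),
base-composition drift across lineages, within-gene rate variation beyond
the branch-site classes, and real recombination mosaics (the recombinant
generator splices exactly once). Passing tests on this design therefore
demonstrate the statistical machinery under the model's own assumptions, not
robustness to alignment error or model violation on real data.

## Calibration and scale choices

Simulation-backed checks in the test suite and acceptance script run at
deliberate desk scales, stated here as the package's own choices: parameter
recovery for the clade model uses 20 seeds at 500 codons on the 18-strain
ingroup; the type-I error of the single-vs-clade LRT uses 200 replicates at
300 codons; end-to-end neutralization detection uses a handful of full
cascade replicates over all 12 jackknife hypotheses for the neutralized gene
plus a specificity pass over the other genes on a subset of hypotheses;
MaxChi power uses 30 planted-breakpoint replicates at 600 sites. The
branch-site test with plain df=1 is conservative (its empirical type-I rate
in our checks is well below nominal), which is the standard trade-off.

## Known limitations

* The clade model's backbone-sharing convention means "forcing clade 1
  neutral" also forces the backbone; interpret the per-clade neutrality scan
  for clade 1 accordingly.
* Branch lengths fixed from the single-ratio reference fit make each LRT
  slightly conservative relative to full per-model re-optimization.
* MaxChi localization degrades for breakpoints close to the alignment ends
  (no full window fits) and the scan reports pairwise evidence, not
  recombination events reconciled across strains.
* The likelihood treats any ambiguous codon as missing rather than summing
  over compatible states.
* NJ tree hypotheses are adequate for the shallow divergences this pipeline
  targets but are not a substitute for ML search on difficult data; supply
  your own trees in that case.
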