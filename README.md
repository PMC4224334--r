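# omegarelax

Branch-model Ka/Ks cascades for detecting clade-specific relaxation of
purifying selection in bacterial endosymbiont genes.

## The problem

Endosymbiont genomes shed genes in stages: relaxation of selection first
*neutralizes* a gene (Ka/Ks drifts to 1 while the reading frame is still
intact), inactivating mutations then pseudogenize it, and erosion removes it.
The neutralization stage is transient and easy to miss; catching it requires
many closely related strains and a test that can attribute a relaxed Ka/Ks to
one clade while the same gene stays constrained in its sister clades — the
situation of the DNA-repair (homologous recombination) pathway in arthropod
*Wolbachia*, where the branch-migration gene *ruvA* is redundant with the
*recG* helicase and can drift while *recG* remains under strong purifying
selection.

`omegarelax` implements the full analysis as a tested R package:

* a Goldman–Yang-style codon substitution model
  (`q_ij ∝ π_j · κ^[ts] · ω^[nonsyn]`, mean rate 1, 61 sense codons of
  translation table 11) with Felsenstein-pruning likelihoods in compiled code;
* branch-class models on clade-labeled trees and the nested LRT cascade:
  neutral (ω=1) → single ω → one ω per clade → forced-neutral foreground
  (the neutralization test), plus a branch-site Model A check that the
  elevated ratio is not positive selection;
* gene-jackknife tree resampling (leave one gene out, rebuild the tree) with
  a conservative all-trees consensus rule and min–max reporting of p and ω;
* the alignment preparation filters applied before such analyses: np-coordinate
  masking (the seven WPE-like palindromic regions ship as a default table),
  premature-stop gene splitting, 0.2%-divergence strain deduplication, and a
  permutation-calibrated MaxChi recombination scan;
* a clade-exclusive substitution scanner with synonymous/nonsynonymous
  classification, physicochemical property annotation, functional-site
  cross-referencing and poly(A)/frameshift/premature-stop pseudogenization
  checks;
* seeded synthetic-data generators reproducing the study design (three
  clades of six strains plus outgroup, 12 gene partitions, one gene
  neutralized in one clade, intragroup divergence 1–2%, intergroup 6–10%),
  so every stage is testable without downloads.

## Worked example

```r
library(omegarelax)

sc <- scenario_paper_like(seed = 11)        # synthetic 19-strain, 12-gene design
group_divergence_summary(sc$supermatrix, sc$groups[1:3])$intra
#>        A B_insect B_isopod
#>   0.0164   0.0095   0.0121

jk <- jackknife_trees(sc$supermatrix)       # 12 leave-one-gene-out NJ trees
length(jk)
#> [1] 12

rep <- run_cascade(sc$alignments$ruvA, jk[1:3], sc$groups, seed = 5)
rep
#> cascade_report 'ruvA': consensus best fit = neutral foreground (3/3 trees usable)
#>   neutralized clade: class 3 (B_isopod)
#>   Ka/Ks ranges: 0: 0.39-0.39; 1: 0.39-0.39; 2: 0.13-0.13; 3: 1.1-1.1
rep$branch_site$lrt$p
#> [1] 1
```

The cascade walks neutral → single ω → clade ω → forced-neutral foreground
on each tree hypothesis: here the clade model beats the single-ratio model,
forcing ω=1 in the isopod clade is *not* rejected (the neutralization
signal), and the branch-site check finds no positive selection behind it
(p = 1: the positive-selection class adds nothing), so the gene is reported
as neutrally evolving in the isopod clade with purifying estimates
(ω ≈ 0.1–0.4) elsewhere.

The numbered drivers under `analysis/` run the same workflow as a pipeline
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1    # simulate the study design
Rscript analysis/02_prep.R 1       # masks, splits, dedup, MaxChi scan
Rscript analysis/03_trees.R 1      # 12 jackknife tree hypotheses
Rscript analysis/04_cascade.R 1    # LRT cascade -> results/cascade/cascade.tsv
Rscript analysis/05_subscan.R 1    # substitution scan on the flagged gene
```

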