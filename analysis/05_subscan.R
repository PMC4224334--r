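#!/usr/bin/env Rscript
# Stage 5: clade-exclusive substitution scan on the neutralized gene. Finds
# substitutions exclusively shared by the isopod clade, classifies them
# synonymous/nonsynonymous, annotates physicochemical property changes and
# structural domains, cross-references the curated functional-site list, and
# runs the pseudogenization feature checks. Writes the Table-3-style report
# under results/subscan/.

suppressPackageStartupMessages(library(omegarelax))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
gene <- if (length(args) > 1) args[[2]] else "ruvA"
out <- "results/subscan"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- scenario_paper_like(seed = seed)
aln <- sc$alignments[[gene]]
fg <- sc$groups[[3]]$members                      # B isopod clade
bg <- c(sc$groups[[1]]$members, sc$groups[[2]]$members)

rec <- clade_exclusive_substitutions(aln, fg, bg, max_exceptions = 1)
rec <- classify_syn_nonsyn(rec, aln, bg)
rec <- annotate_domains(rec)
ns <- rec[rec$type == "nonsynonymous", ]
if (nrow(ns)) {
  props <- lapply(seq_len(nrow(ns)), function(k) {
    ch <- ns$aa_change[k]
    annotate_property_change(substr(ch, 1, 1), substr(ch, nchar(ch), nchar(ch)))
  })
  ns$property_change <- vapply(props, function(p)
    paste(attr(p, "description"), collapse = "; "), character(1))
  rec$property_change <- ""
  rec$property_change[rec$type == "nonsynonymous"] <- ns$property_change
}
hits <- crossref_functional_sites(rec, ruva_functional_sites())

write.table(rec, file.path(out, paste0(gene, "_substitutions.tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%s: %d clade-exclusive substitutions (%d nonsynonymous, %d synonymous)\n",
            gene, nrow(rec), sum(rec$type == "nonsynonymous"),
            sum(rec$type == "synonymous")))
if (nrow(ns)) {
  changed <- sum(ns$property_change != "")
  cat(sprintf("%d replacement(s) change a physicochemical property\n", changed))
}
cat(sprintf("%d substitution(s) hit curated functional sites\n", nrow(hits)))

# pseudogenization feature checks on the foreground strains
feat_n <- 0L
for (s in fg) {
  f <- detect_inactivating_features(paste(aln$seq[s, ], collapse = ""),
                                    polyA_threshold = 9)
  feat_n <- feat_n + nrow(f)
  if (nrow(f)) {
    f$strain <- s
    write.table(f, file.path(out, paste0(gene, "_features_", s, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
cat(sprintf("inactivating features in foreground strains: %d\n", feat_n))
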