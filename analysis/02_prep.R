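#!/usr/bin/env Rscript
# Stage 2: alignment preparation on the simulated data set. Exercises the
# filters the real study applies before selection analyses: coordinate
# masking, premature-stop gene splitting, near-duplicate strain removal and
# the MaxChi recombination scan. Writes reports under results/prep/.

suppressPackageStartupMessages(library(omegarelax))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/prep"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- scenario_paper_like(seed = seed)

# deduplication: plant ten sub-threshold near-duplicates and recover them
aug <- scenario_near_duplicates(sc$supermatrix, n_dupes = 10,
                                divergence = 0.001, seed = seed)
dd <- dedup_strains(aug$alignment, threshold = 0.002)
cat(sprintf("dedup: %d strains in, %d removed (planted %d), %d kept\n",
            length(aug$alignment$strains), length(dd$removed), 10,
            length(dd$kept)))
write.table(data.frame(removed = dd$removed), file.path(out, "dedup_removed.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# recombination scan on a planted recombinant gene
t1 <- parse_newick(paste0("(((A:0.01,B:0.01):0.2,C:0.2):0.1,",
                          "(D:0.25,E:0.25):0.1,F:0.3);"))
t2 <- parse_newick(paste0("(((A:0.01,C:0.2):0.2,(B:0.05,D:0.25):0.05):0.1,",
                          "E:0.3,F:0.3);"))
rec <- scenario_recombinant(t1, t2, splice_np = 301, n_codons = 200,
                            kappa = 2, omega = 1, seed = seed)
det <- suppressWarnings(maxchi_scan(rec$alignment, alpha = 0.05, seed = seed))
cat(sprintf("MaxChi: %d detection(s); true splice at np %d\n",
            nrow(det), rec$truth$splice_np))
if (nrow(det)) {
  cat(sprintf("  closest breakpoint estimate: np %d\n",
              det$breakpoint_np[which.min(abs(det$breakpoint_np - 301))]))
  det$strains <- paste(det$strain1, det$strain2, sep = ";")
  masks <- consensus_recombination_filter(list(det), min_detectors = 1)
  write.table(det, file.path(out, "recombination.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(masks, file.path(out, "recombination_masks.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

# masking and splitting worked example (the addA geometry)
addA <- codon_alignment(
  stats::setNames(rep(strrep("CTG", 1279), 2), c("s1", "s2")),
  partitions = data.frame(gene = "addA", start_np = 1L, end_np = 3837L),
  check_stops = FALSE)
masked <- mask_regions(addA, palindromic_mask_regions()[1:3, ])
cat(sprintf("palindromic masking: addA %d -> %d codons\n",
            n_codons(addA), n_codons(masked)))
s2 <- strrep("CTG", 1279); substr(s2, 3100, 3102) <- "TAA"
addA2 <- codon_alignment(c(s1 = strrep("CTG", 1279), s2 = s2),
                         partitions = data.frame(gene = "addA", start_np = 1L,
                                                 end_np = 3837L),
                         check_stops = FALSE)
sp <- split_gene_at_stop(addA2, "addA", 3100)
lens <- (sp$partitions$end_np - sp$partitions$start_np + 1) / 3
cat(sprintf("premature-stop split: addA_1 %d codons, addA_2 %d codons\n",
            lens[1], lens[2]))
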