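test_that("all-strain masking removes whole codon columns with remapping", {
  # synthetic addA-length gene: 3837 np = 1279 codons of a harmless codon
  aln <- codon_alignment(c(s1 = strrep("CTG", 1279), s2 = strrep("CTG", 1279)),
                         partitions = data.frame(gene = "addA", start_np = 1L,
                                                 end_np = 3837L),
                         check_stops = FALSE)
  masked <- mask_regions(aln, mask_region("addA", 289, 459,
                                          reason = "palindrome"))
  # 171 nucleotides = 57 codon columns removed
  expect_equal(ncol(aln$seq) - ncol(masked$seq), 171L)
  expect_equal(n_codons(aln) - n_codons(masked), 57L)
  expect_equal(masked$partitions$end_np, 3837L - 171L)
  # empty list: identity
  expect_identical(mask_regions(aln, NULL)$seq, aln$seq)
  # region outside gene errors
  expect_error(mask_regions(aln, mask_region("addA", 3800, 4000)), "outside")
  expect_error(mask_regions(aln, mask_region("nope", 1, 3)), "unknown gene")
  # overlapping all-strain regions merge with a warning
  expect_warning(
    m2 <- mask_regions(aln, rbind(mask_region("addA", 1, 30),
                                  mask_region("addA", 25, 60))),
    "merged")
  expect_equal(n_codons(m2), 1279L - 20L)
})

test_that("strain-scoped masks expand to codon boundaries and gap one strain", {
  aln <- codon_alignment(c(wNo = strrep("ATT", 200), other = strrep("ATT", 200)),
                         partitions = data.frame(gene = "ruvC", start_np = 1L,
                                                 end_np = 600L),
                         check_stops = FALSE)
  expect_message(
    masked <- mask_regions(aln, mask_region("ruvC", 1, 346, strains = "wNo",
                                            reason = "recombination")),
    "expanded to codon boundaries 1-348")
  expect_true(all(masked$seq["wNo", 1:348] == "-"))
  expect_identical(masked$seq["wNo", 349:600], aln$seq["wNo", 349:600])
  expect_true(all(masked$seq["other", ] != "-"))
  expect_equal(ncol(masked$seq), 600L)  # no columns deleted
})

test_that("gene splitting at a premature stop yields the documented parts", {
  # addA-like: 3837 np, stop codon TAA at np 3100-3102 in one strain
  s1 <- strrep("CTG", 1279)
  s2 <- s1
  substr(s2, 3100, 3102) <- "TAA"
  aln <- codon_alignment(c(a = s1, b = s2),
                         partitions = data.frame(gene = "addA", start_np = 1L,
                                                 end_np = 3837L),
                         check_stops = FALSE)
  out <- split_gene_at_stop(aln, "addA", 3100)
  p <- out$partitions
  expect_equal(p$gene, c("addA_1", "addA_2"))
  n1 <- (p$end_np[1] - p$start_np[1] + 1L) / 3L
  n2 <- (p$end_np[2] - p$start_np[2] + 1L) / 3L
  expect_equal(n1, 1033)
  expect_equal(n2, 245)
  expect_equal(ncol(out$seq), 3837L - 3L)
  # toy: stop at np 4 of a 9-nt gene -> two 1-codon parts
  toy <- codon_alignment(c(x = "ATGTAAGGG", y = "ATGTAAGGG"),
                         check_stops = FALSE)
  toy$partitions$gene <- "g"
  out2 <- split_gene_at_stop(toy, "g", 4)
  expect_equal((out2$partitions$end_np - out2$partitions$start_np + 1L) / 3L,
               c(1, 1))
  # error cases
  expect_error(split_gene_at_stop(toy, "g", 5), "codon boundary")
  clean <- codon_alignment(c(x = "ATGAAAGGG"), check_stops = FALSE)
  clean$partitions$gene <- "g"
  expect_error(split_gene_at_stop(clean, "g", 4), "no stop codon")
})

test_that("pairwise divergence uses pairwise deletion", {
  expect_equal(pairwise_divergence("AAAAAA", "AAAAAT"), 1/6)
  expect_equal(pairwise_divergence("ACGTAC", "ACGTAC"), 0)
  expect_equal(pairwise_divergence("AA-AAA", "AATAAC"), 1/5)
  expect_error(pairwise_divergence("---", "AAA"), "no overlap")
  expect_error(pairwise_divergence("AA", "AAA"), "equal length")
})

test_that("strain deduplication keeps one representative per cluster", {
  # three strains: A identical to B, C at ~1%
  base <- strrep("ATGCTG", 100)
  cseq <- base
  for (k in seq(1, 600, by = 100)) substr(cseq, k, k) <- "T"
  aln <- codon_alignment(c(A = base, B = base, C = cseq), check_stops = FALSE)
  dd <- dedup_strains(aln, 0.002)
  expect_setequal(dd$kept, c("A", "C"))
  expect_equal(dd$removed, "B")
  # all strains apart: nothing removed
  dd2 <- dedup_strains(codon_alignment(c(A = base, C = cseq),
                                       check_stops = FALSE), 0.002)
  expect_length(dd2$removed, 0)
  # idempotence
  dd3 <- dedup_strains(dd$alignment, 0.002)
  expect_length(dd3$removed, 0)
})

test_that("planted near-duplicates are removed at the documented threshold", {
  sc <- fixture_scenario()
  base <- sc$supermatrix
  aug <- scenario_near_duplicates(base, n_dupes = 10, divergence = 0.001,
                                  seed = 3)
  dd <- dedup_strains(aug$alignment, 0.002)
  # all 10 planted sub-threshold copies fall in their source's cluster
  expect_length(dd$removed, 10)
  expect_true(all(vapply(seq_len(nrow(aug$truth)), function(k) {
    pair <- c(aug$truth$dup[k], aug$truth$source[k])
    any(vapply(dd$groups, function(g) all(pair %in% g), logical(1)))
  }, logical(1))))
  # far-above-threshold copies survive
  aug2 <- scenario_near_duplicates(base, n_dupes = 3, divergence = 0.01,
                                   seed = 4)
  dd2 <- dedup_strains(aug2$alignment, 0.002)
  expect_length(dd2$removed, 0)
  # exact copies are removed
  aug3 <- scenario_near_duplicates(base, n_dupes = 3, divergence = 0,
                                   seed = 5)
  expect_length(dedup_strains(aug3$alignment, 0.002)$removed, 3)
})

test_that("group divergence summary reports intra and inter means", {
  a <- strrep("ACGTGG", 50)
  b <- a; for (k in seq(3, 300, by = 100)) substr(b, k, k) <- "T"  # 3 diffs = 1%
  aln <- codon_alignment(c(g1a = a, g1b = a, g2a = b, g2b = b),
                         check_stops = FALSE)
  groups <- list(strain_group("g1", c("g1a", "g1b")),
                 strain_group("g2", c("g2a", "g2b")))
  gs <- group_divergence_summary(aln, groups)
  expect_equal(unname(gs$intra), c(0, 0))
  expect_equal(gs$inter$divergence, 0.01)
  # singleton group -> NA intra
  gs2 <- group_divergence_summary(aln, list(strain_group("s", "g1a"),
                                            strain_group("r", c("g2a", "g2b"))))
  expect_true(is.na(gs2$intra[["s"]]))
  # two strains at exactly 2%
  c2 <- a; for (k in seq(1, 31, by = 6)) substr(c2, k, k) <- "T"  # 6 diffs = 2%
  aln2 <- codon_alignment(c(x = a, y = c2), check_stops = FALSE)
  gs3 <- group_divergence_summary(aln2, list(strain_group("p", c("x", "y"))))
  expect_equal(unname(gs3$intra), 0.02)
})

test_that("masking commutes with manual column excision for divergence", {
  aln <- codon_alignment(c(u = "ATGAAACCCGGGTTTAAG", v = "ATGAATCCAGGCTTCAAA"),
                         check_stops = FALSE)
  aln$partitions$gene <- "g"
  masked <- mask_regions(aln, mask_region("g", 7, 12))
  manual <- c(u = paste0(substr("ATGAAACCCGGGTTTAAG", 1, 6),
                         substr("ATGAAACCCGGGTTTAAG", 13, 18)),
              v = paste0(substr("ATGAATCCAGGCTTCAAA", 1, 6),
                         substr("ATGAATCCAGGCTTCAAA", 13, 18)))
  expect_equal(
    pairwise_divergence(paste(masked$seq["u", ], collapse = ""),
                        paste(masked$seq["v", ], collapse = "")),
    pairwise_divergence(manual[["u"]], manual[["v"]]))
})
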