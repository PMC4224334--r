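test_that("a shared exclusive substitution is found with correct coordinates", {
  aln <- make_planted_alignment(5, c("b1", "b2"), c("f1", "f2"),
                                base_codon = "AAA",
                                edits = list(list(np = 3, fg = "G")))
  rec <- clade_exclusive_substitutions(aln, c("f1", "f2"), c("b1", "b2"))
  expect_equal(nrow(rec), 1)
  expect_equal(rec$np, 3)
  expect_equal(rec$codon_index, 1)
  expect_equal(rec$codon_position, 3)
  expect_equal(rec$background_state, "A")
  expect_equal(rec$foreground_state, "G")
  expect_equal(rec$exceptions, "")
  # coordinate invariants hold by construction
  expect_equal(rec$codon_index, (rec$np + 2) %/% 3)
  expect_equal(rec$codon_position, (rec$np - 1) %% 3 + 1)
  expect_error(clade_exclusive_substitutions(aln, c("f1", "b1"), c("b1", "b2")),
               "overlap")
})

test_that("exceptions are honored via max_exceptions", {
  fg <- paste0("f", 1:6)
  aln <- make_planted_alignment(5, c("b1", "b2", "b3"), fg,
                                base_codon = "AAA",
                                edits = list(list(np = 6, fg = "C",
                                                  strains = fg[1:5])))
  # f6 matches the background: excluded at 0 exceptions
  r0 <- clade_exclusive_substitutions(aln, fg, c("b1", "b2", "b3"),
                                      max_exceptions = 0)
  expect_equal(nrow(r0), 0)
  r1 <- clade_exclusive_substitutions(aln, fg, c("b1", "b2", "b3"),
                                      max_exceptions = 1)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$exceptions, "f6")
  # gap-bearing sites are skipped
  aln$seq["f1", 9] <- "-"
  aln$seq["f2", 9] <- "G"
  expect_equal(nrow(clade_exclusive_substitutions(aln, fg, c("b1", "b2", "b3"),
                                                  max_exceptions = 1)), 1)
})

test_that("published replacements classify with the printed notation", {
  # codon 118: background CTA (Leu), T353C -> CCA (Pro)
  bg <- c("wA1", "wA2"); fg <- c("wP1", "wP2")
  aln <- make_planted_alignment(170, bg, fg, base_codon = "CTA",
                                edits = list(list(np = 353, fg = "C"),
                                             list(np = 493, bg = "G", fg = "A")))
  # np 493 sits at codon 165 position 1; make that codon GAT -> AAT (D165N)
  aln$seq[, 494] <- "A"; aln$seq[, 495] <- "T"
  aln$seq[bg, 493] <- "G"; aln$seq[fg, 493] <- "A"
  rec <- clade_exclusive_substitutions(aln, fg, bg)
  rec <- classify_syn_nonsyn(rec, aln, bg)
  expect_equal(nrow(rec), 2)
  r353 <- rec[rec$np == 353, ]
  expect_equal(r353$codon_index, 118)
  expect_equal(r353$codon_position, 2)
  expect_equal(r353$type, "nonsynonymous")
  expect_equal(r353$aa_change, "L118P")
  r493 <- rec[rec$np == 493, ]
  expect_equal(r493$codon_index, 165)
  expect_equal(r493$aa_change, "D165N")
  # property annotations match the printed table conventions
  expect_setequal(annotate_property_change("L", "P"), "aliphatic")
  expect_setequal(annotate_property_change("D", "N"), "charge")
  expect_length(annotate_property_change("K", "R"), 0)
})

test_that("classification agrees with direct translation for every single-base change", {
  code <- genetic_code()
  cases <- list()
  for (cod in code$sense_codons) {
    for (pos in 1:3) {
      for (nt in setdiff(c("A", "C", "G", "T"), substr(cod, pos, pos))) {
        mut <- cod
        substr(mut, pos, pos) <- nt
        cases[[length(cases) + 1L]] <- c(cod, mut, pos)
      }
    }
  }
  # one long alignment: one codon column per case
  bg_seq <- paste(vapply(cases, `[[`, character(1), 1), collapse = "")
  fg_seq <- paste(vapply(cases, `[[`, character(1), 2), collapse = "")
  aln <- codon_alignment(c(b1 = bg_seq, b2 = bg_seq, f1 = fg_seq, f2 = fg_seq),
                         check_stops = FALSE)
  rec <- clade_exclusive_substitutions(aln, c("f1", "f2"), c("b1", "b2"))
  expect_equal(nrow(rec), length(cases))
  rec <- classify_syn_nonsyn(rec, aln, c("b1", "b2"))
  for (k in seq_len(nrow(rec))) {
    aa_from <- translate_codons(cases[[rec$codon_index[k]]][1])
    aa_to <- translate_codons(cases[[rec$codon_index[k]]][2])
    if (aa_to == "*") {
      expect_equal(rec$type[k], "inactivating")
    } else if (aa_from == aa_to) {
      expect_equal(rec$type[k], "synonymous")
      expect_true(is.na(rec$aa_change[k]))
    } else {
      expect_equal(rec$type[k], "nonsynonymous")
      expect_equal(rec$aa_change[k],
                   paste0(aa_from, rec$codon_index[k], aa_to))
    }
  }
})

test_that("a planted 14-substitution scenario is recovered exactly", {
  # 8 nonsynonymous + 6 synonymous exclusive substitutions in a 203-codon gene
  bg <- paste0("b", 1:8); fg <- paste0("f", 1:6)
  nonsyn_edits <- list(
    list(np = 70, bg = "G", fg = "A"),   # GTG V -> ATG M (codon 24 pos 1)
    list(np = 353, fg = "C"),            # CTA L118 -> CCA P
    list(np = 493, bg = "G", fg = "A"))  # see below: GAT D -> AAT N
  syn_edits <- lapply(c(30, 60, 90, 120, 150, 600), function(np)
    list(np = np, bg = "A", fg = "G"))   # CTA -> CTG (Leu, synonymous, pos 3)
  more_nonsyn <- lapply(c(200, 260, 320, 380, 440), function(np) {
    # position ((np-1) %% 3) + 1 == 2 for these: CTA -> CAA (L -> Q)
    list(np = np, bg = "T", fg = "A")
  })
  aln <- make_planted_alignment(203, bg, fg, base_codon = "CTA",
                                edits = c(nonsyn_edits, syn_edits, more_nonsyn))
  # make codon 165 GAT in background so np 493 G->A is D165N
  aln$seq[, 494] <- "A"; aln$seq[, 495] <- "T"
  aln$seq[bg, 493] <- "G"; aln$seq[fg, 493] <- "A"
  # make codon 24 GTG
  aln$seq[, 71] <- "T"; aln$seq[, 72] <- "G"
  aln$seq[bg, 70] <- "G"; aln$seq[fg, 70] <- "A"
  rec <- clade_exclusive_substitutions(aln, fg, bg)
  rec <- classify_syn_nonsyn(rec, aln, bg)
  expect_equal(nrow(rec), 14)
  expect_equal(sum(rec$type == "nonsynonymous"), 8)
  expect_equal(sum(rec$type == "synonymous"), 6)
  # domain annotation via the synthetic coordinate map
  rec <- annotate_domains(rec)
  expect_true(all(!is.na(rec$functional_domain)))
  # the L118P record hits the curated DNA-binding site list
  hits <- crossref_functional_sites(rec, ruva_functional_sites())
  expect_true(118 %in% hits$site_position)
  expect_true(any(grepl("DNA-binding", hits$role[hits$site_position == 118])))
})

test_that("property table covers all amino acids and annotation is symmetric", {
  tab <- aa_property_table()
  expect_equal(nrow(tab), 20)
  expect_setequal(tab$charge, c("negative", "neutral", "positive"))
  expect_error(annotate_property_change("B", "A"), "nonstandard")
  for (i in 1:20) {
    for (j in 1:20) {
      expect_setequal(annotate_property_change(tab$aa[i], tab$aa[j]),
                      annotate_property_change(tab$aa[j], tab$aa[i]))
    }
  }
})

test_that("functional-site crossref honors numbering offsets", {
  rec <- data.frame(gene = "g", np = 352, codon_index = 118,
                    codon_position = 1, background_state = "C",
                    foreground_state = "T", exceptions = "",
                    type = "nonsynonymous", aa_change = "L118P",
                    stringsAsFactors = FALSE)
  sites <- data.frame(position = 116, role = "DNA-binding", source = "x")
  expect_equal(nrow(crossref_functional_sites(rec, sites, offset = 0)), 0)
  hit <- crossref_functional_sites(rec, sites, offset = -2)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$site_position, 116)
  empty <- crossref_functional_sites(rec, sites[0, ])
  expect_equal(nrow(empty), 0)
  # shipped fixture: 51 entries, position 118 among them
  fs <- ruva_functional_sites()
  expect_equal(nrow(fs), 51)
  expect_true(118 %in% fs$position)
  dm <- ruva_domains()
  expect_equal(dm$domain, c("I", "II", "III"))
})

test_that("pseudogenization features fire at the documented thresholds", {
  # poly(A) of 10 is a feature, 9 is not
  base <- strrep("CTG", 20)
  seq10 <- paste0(base, strrep("A", 10), "CTG", "TGG")
  seq9 <- paste0(base, strrep("A", 9), "CTGTGGCTG")
  f10 <- detect_inactivating_features(seq10)
  expect_equal(sum(f10$feature == "polyA"), 1)
  expect_equal(f10$length[f10$feature == "polyA"], 10)
  expect_equal(sum(detect_inactivating_features(seq9)$feature == "polyA"), 0)
  # threshold is configurable
  expect_equal(sum(detect_inactivating_features(seq9, polyA_threshold = 8)$feature == "polyA"), 1)
  # in-frame TAA at codon 5 of 100
  s <- strrep("CTG", 100)
  substr(s, 13, 15) <- "TAA"
  f <- detect_inactivating_features(s)
  expect_equal(f$feature, "premature_stop")
  expect_equal(f$position, 13)
  # frameshift-indicative gap run (not a multiple of 3)
  g <- paste0(strrep("CTG", 5), "--", strrep("CTG", 5))
  fg <- detect_inactivating_features(g)
  expect_true("frameshift" %in% fg$feature)
  # clean sequence: nothing
  expect_equal(nrow(detect_inactivating_features(strrep("CTG", 50))), 0)
})
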