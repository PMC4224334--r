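test_that("newick parsing validates and round trips", {
  tr <- parse_newick("(A:0.1,B:0.2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_equal(sort(tr$edge.length), c(0.1, 0.2))
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate leaf label")
  expect_error(parse_newick("((A,B),(C,D);"), "unbalanced parentheses")
  expect_error(parse_newick("(A,B));"), "unbalanced parentheses at position 6")
  # round trip a random 19-leaf tree: identical topology and lengths
  set.seed(5)
  big <- ape::rtree(19)
  rt <- parse_newick(write_newick(big))
  expect_equal(phangorn::RF.dist(big, rt), 0)
  expect_equal(sort(rt$edge.length), sort(big$edge.length), tolerance = 1e-9)
})

test_that("NJ tree building recovers simulated topologies", {
  sc <- fixture_scenario()
  # high-signal check: the full supermatrix recovers the generating topology
  tr <- build_nj_tree(sc$supermatrix)
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(sc$tree)), 0)
  # replicated recovery on fresh simulations
  ok <- vapply(1:5, function(s) {
    a <- simulate_codon_alignment(sc$tree, 1200, kappa = 2, omega = 0.3,
                                  pi = sc$pi, seed = 400 + s)
    phangorn::RF.dist(ape::unroot(build_nj_tree(a)),
                      ape::unroot(sc$tree)) == 0
  }, logical(1))
  expect_gte(sum(ok), 4)
  # all-identical sequences: star tree with zero lengths, warning
  same <- codon_alignment(setNames(rep(strrep("ATG", 50), 5),
                                   paste0("s", 1:5)), check_stops = FALSE)
  expect_warning(star <- build_nj_tree(same), "star tree")
  expect_equal(sum(star$edge.length), 0)
  expect_error(build_nj_tree(subset_alignment(same, strains = c("s1", "s2"))),
               "at least 4")
})

test_that("site filter removes low-coverage columns before distances", {
  base <- strrep("ATGCTGAAA", 40)
  gappy <- base
  # make the first 90 np gap-rich in one strain pair out of four
  seqs <- c(a = base, b = base, c = base, d = base)
  substr(seqs[["a"]], 1, 90) <- strrep("-", 90)
  substr(seqs[["b"]], 1, 90) <- strrep("-", 90)
  aln <- codon_alignment(seqs, check_stops = FALSE)
  expect_warning(tr <- build_nj_tree(aln, site_filter = 0.85), "star|negative")
  expect_s3_class(tr, "phylo")
})

test_that("gene jackknife yields one tree per partition and counts topologies", {
  jk <- fixture_jackknife()
  expect_length(jk, 12)
  expect_setequal(names(jk), fixture_scenario()$supermatrix$partitions$gene)
  expect_true(all(vapply(jk, function(t) !is.null(t$left_out), logical(1))))
  expect_gte(attr(jk, "n_topologies"), 1)
  # two identical-content partitions: identical topologies, count 1
  sc <- fixture_scenario()
  g <- sc$alignments$recA
  two <- concat_alignments(list(p1 = g, p2 = g))
  jk2 <- jackknife_trees(two)
  expect_length(jk2, 2)
  expect_equal(attr(jk2, "n_topologies"), 1)
  expect_equal(phangorn::RF.dist(jk2[[1]], jk2[[2]]), 0)
})

test_that("a gene with conflicting signal changes the jackknife topology", {
  t1 <- parse_newick("((A:0.02,B:0.02):0.15,(C:0.02,D:0.02):0.15,(E:0.02,F:0.02):0.15);")
  t2 <- parse_newick("((A:0.02,D:0.02):0.15,(C:0.02,B:0.02):0.15,(E:0.02,F:0.02):0.15);")
  g1 <- simulate_codon_alignment(t1, 400, kappa = 2, omega = 0.5, seed = 21)
  g2 <- simulate_codon_alignment(t1, 400, kappa = 2, omega = 0.5, seed = 22)
  conflict <- simulate_codon_alignment(t2, 2500, kappa = 2, omega = 0.5, seed = 23)
  sm <- concat_alignments(list(g1 = g1, g2 = g2, conflict = conflict))
  jk <- jackknife_trees(sm)
  expect_length(jk, 3)
  # dropping the conflicting gene flips the topology
  expect_gt(phangorn::RF.dist(jk[["conflict"]], jk[["g1"]]), 0)
  expect_equal(attr(jk, "n_topologies"), 2)
})

test_that("clade labeling assigns classes by descent and checks monophyly", {
  tr <- parse_newick("((A1:0.1,A2:0.1):0.1,(B1:0.1,B2:0.1):0.1);")
  groups <- list(strain_group("A", c("A1", "A2")),
                 strain_group("B", c("B1", "B2")))
  lab <- label_clades(tr, groups)
  expect_length(lab$edge_class, nrow(lab$edge))
  # each clade gets its terminal branches plus its stem; with a degree-2 root
  # every edge belongs to one of the two clades
  expect_setequal(unique(lab$edge_class), c(1L, 2L))
  expect_equal(sum(lab$edge_class == 1), 3)  # 2 terminal + stem
  expect_equal(sum(lab$edge_class == 2), 3)
  # with an outgroup, the outgroup branch stays in the background class
  og <- parse_newick("((A1:0.1,A2:0.1):0.1,(B1:0.1,B2:0.1):0.1,OUT:0.3);")
  lab_og <- label_clades(og, c(groups, list(strain_group("out", "OUT",
                                                         "outgroup"))))
  expect_setequal(unique(lab_og$edge_class), c(0L, 1L, 2L))
  # full-size tree: every branch tagged
  sc <- fixture_scenario()
  big <- label_clades(fixture_jackknife()[[1]], sc$groups)
  expect_length(big$edge_class, nrow(big$edge))
  expect_setequal(unique(big$edge_class), 0:3)
  # non-monophyletic group errors and names intruders
  bad <- list(strain_group("X", c("A1", "B1")),
              strain_group("Y", c("A2", "B2")))
  expect_error(label_clades(tr, bad), "not monophyletic")
  # labeling is invariant to leaf rotation of the newick input
  rot <- parse_newick("((B2:0.1,B1:0.1):0.1,(A2:0.1,A1:0.1):0.1);")
  lab2 <- label_clades(rot, groups)
  expect_equal(sort(table(lab2$edge_class)), sort(table(lab$edge_class)))
  # incomplete group assignment errors
  expect_error(label_clades(tr, groups[1]), "not assigned")
})
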