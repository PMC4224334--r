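# Shared fixtures and independent oracles for the test suite. Expensive
# objects (the study-design scenario, its jackknife trees) are built once per
# test run and memoized here.

.fixture_env <- new.env(parent = emptyenv())

fixture_scenario <- function(seed = 1L) {
  key <- paste0("scenario_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- scenario_paper_like(seed = seed)
  }
  .fixture_env[[key]]
}

fixture_jackknife <- function(seed = 1L) {
  key <- paste0("jk_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- jackknife_trees(fixture_scenario(seed)$supermatrix)
  }
  .fixture_env[[key]]
}

# 18-taxon labeled tree (scenario tree without the outgroup)
fixture_ingroup_tree <- function(seed = 1L) {
  key <- paste0("ingroup_", seed)
  if (is.null(.fixture_env[[key]])) {
    sc <- fixture_scenario(seed)
    tr <- ape::drop.tip(sc$tree, "wOut")
    tr$edge_class <- NULL
    .fixture_env[[key]] <- label_clades(tr, sc$groups[1:3])
  }
  .fixture_env[[key]]
}

# independent matrix exponential: truncated Taylor series
series_expm <- function(M, kmax = 50L) {
  P <- diag(nrow(M))
  term <- P
  for (k in seq_len(kmax)) {
    term <- term %*% M / k
    P <- P + term
  }
  P
}

# independent pruning oracle: exhaustive enumeration over internal-node
# states for a rooted binary 4-taxon tree ((t1,t2),(t3,t4)) with the given
# branch lengths; aln strains must match tip names
brute_force_lnl_4tax <- function(aln, tips, bl, kappa, omega, pi,
                                 code = genetic_code()) {
  rm <- codon_rate_matrix(kappa, omega, pi, code)
  P <- lapply(bl, function(t) transition_probabilities(rm, t))
  st <- codon_states(aln, code)
  total <- 0
  for (s in seq_len(n_codons(aln))) {
    v1 <- P$inner1 %*% (P$t1[, st[tips[1], s]] * P$t2[, st[tips[2], s]])
    v2 <- P$inner2 %*% (P$t3[, st[tips[3], s]] * P$t4[, st[tips[4], s]])
    total <- total + log(sum(pi * v1 * v2))
  }
  total
}

# small alignment of constant codons with targeted foreground edits
make_planted_alignment <- function(n_codons, bg_strains, fg_strains,
                                   base_codon = "CTG",
                                   edits = list()) {
  base <- strrep(base_codon, n_codons)
  seqs <- stats::setNames(rep(base, length(bg_strains) + length(fg_strains)),
                          c(bg_strains, fg_strains))
  for (ed in edits) {
    # ed: list(np, bg = base at np (optional), fg = foreground base,
    #          strains = fg strains carrying it (default all fg))
    who <- ed$strains %||% fg_strains
    if (!is.null(ed$bg)) {
      for (s in names(seqs)) substr(seqs[[s]], ed$np, ed$np) <- ed$bg
    }
    for (s in who) substr(seqs[[s]], ed$np, ed$np) <- ed$fg
  }
  codon_alignment(seqs, check_stops = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
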