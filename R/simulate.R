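# Seeded forward simulators under the codon model. All generators restore the
# global RNG state on exit and derive per-gene substreams from the master
# seed, so adding genes does not reshuffle existing ones.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% 2147483647L)
  force(expr)
}

.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 7919) %% 2147483629)
}

#' Simulate a codon alignment along a tree
#'
#' Forward simulation under the codon substitution model: root codons are
#' drawn from the equilibrium frequencies, then evolved along each branch by
#' sampling from the branch's transition probability matrix, with the
#' branch's omega taken from its class tag (see [label_clades()]). An
#' optional branch-site mixture assigns each codon one of the four Model A
#' site classes. Deterministic under `seed`.
#'
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   codon); optional `edge_class` tags.
#' @param n_codons Number of codon sites (>= 1).
#' @param kappa Transition/transversion ratio.
#' @param omega Single value, or named vector mapping class tags to omega.
#' @param pi Codon frequencies (default uniform over sense codons).
#' @param site_classes Optional list `(p0, p1, omega0, omega2, foreground)`
#'   for branch-site simulation; `foreground` is a class tag.
#' @param seed Integer seed.
#' @param code A [genetic_code()].
#' @return A [codon_alignment()]; attribute `"site_class"` holds the per-codon
#'   class when `site_classes` is used.
#' @export
simulate_codon_alignment <- function(tree, n_codons, kappa = 2, omega = 0.3,
                                     pi = NULL, site_classes = NULL,
                                     seed = 1L, code = genetic_code()) {
  if (n_codons < 1L) stop("n_codons must be >= 1")
  n61 <- length(code$sense_codons)
  if (is.null(pi)) pi <- rep(1 / n61, n61)
  po <- ape::reorder.phylo(tree, "postorder")
  eclass <- if (!is.null(tree$edge_class)) {
    okey <- paste(tree$edge[, 1], tree$edge[, 2])
    tree$edge_class[match(paste(po$edge[, 1], po$edge[, 2]), okey)]
  } else integer(nrow(po$edge))
  if (length(omega) == 1L && is.null(names(omega))) {
    omega <- stats::setNames(rep(omega, length(unique(eclass))),
                             as.character(sort(unique(eclass))))
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  .with_seed(seed, {
    if (is.null(site_classes)) {
      class_of <- rep(1L, n_codons)
      omega_maps <- list(omega)
    } else {
      sc <- site_classes
      p2 <- 1 - sc$p0 - sc$p1
      props <- c(sc$p0, sc$p1, p2 * sc$p0 / (sc$p0 + sc$p1),
                 p2 * sc$p1 / (sc$p0 + sc$p1))
      class_of <- sample.int(4L, n_codons, replace = TRUE, prob = props)
      tags <- names(omega)
      fg <- as.character(sc$foreground)
      omega_maps <- list(
        stats::setNames(rep(sc$omega0, length(tags)), tags),
        stats::setNames(rep(1, length(tags)), tags),
        stats::setNames(ifelse(tags == fg, sc$omega2, sc$omega0), tags),
        stats::setNames(ifelse(tags == fg, sc$omega2, 1), tags))
    }
    # per (site-class, omega value) transition matrices are built lazily
    states <- matrix(NA_integer_, nrow = ntip + tree$Nnode, ncol = n_codons)
    states[root, ] <- sample.int(n61, n_codons, replace = TRUE, prob = pi)
    Qcache <- new.env(parent = emptyenv())
    get_rm <- function(om) {
      key <- sprintf("%.12g", om)
      if (is.null(Qcache[[key]])) {
        Qcache[[key]] <- codon_rate_matrix(kappa, om, pi, code)
      }
      Qcache[[key]]
    }
    # with site classes, all classes share one synonymous clock calibrated
    # against the neutral generator (see fit_branch_site)
    sconst <- .rate_scale_constants(pi, code)
    s1 <- .rate_scale(kappa, 1, sconst)
    for (e in rev(seq_len(nrow(po$edge)))) {  # preorder
      par <- po$edge[e, 1]; ch <- po$edge[e, 2]
      t <- po$edge.length[e]
      tag <- as.character(eclass[e])
      for (cl in unique(class_of)) {
        om <- omega_maps[[cl]][[tag]]
        t_eff <- if (is.null(site_classes)) t else
          t * .rate_scale(kappa, om, sconst) / s1
        P <- transition_probabilities(get_rm(om), t_eff)
        idx <- which(class_of == cl)
        pstates <- states[par, idx]
        for (s in unique(pstates)) {
          sel <- idx[pstates == s]
          states[ch, sel] <- sample.int(n61, length(sel), replace = TRUE,
                                        prob = P[s, ])
        }
      }
    }
    seqs <- vapply(seq_len(ntip), function(v)
      paste(code$sense_codons[states[v, ]], collapse = ""), character(1))
    names(seqs) <- tree$tip.label
    aln <- codon_alignment(seqs, check_stops = FALSE)
    attr(aln, "site_class") <- class_of
    aln
  })
}

# expected nucleotide p-distance between two tips separated by path length T
.expected_pdist <- function(T, kappa, pi, omega, code = genetic_code()) {
  rm <- codon_rate_matrix(kappa, omega, pi, code)
  P <- transition_probabilities(rm, T)
  cd <- do.call(rbind, strsplit(code$sense_codons, ""))
  ndiff <- matrix(0L, nrow(cd), nrow(cd))
  for (p in 1:3) ndiff <- ndiff + outer(cd[, p], cd[, p], "!=")
  sum(pi * rowSums(P * ndiff)) / 3
}

# invert .expected_pdist by bisection (monotone in T)
.time_for_pdist <- function(p, kappa, pi, omega, code = genetic_code()) {
  stats::uniroot(function(T) .expected_pdist(T, kappa, pi, omega, code) - p,
                 lower = 1e-6, upper = 20, tol = 1e-8)$root
}

# ultrametric 6-tip clade template with unit tip depth; mean pairwise tip
# distance = 1.626667 (pairs: 3 x 0.8 + 4 x 1.5 + 8 x 2, over 15 pairs)
.clade_newick <- function(tips, h) {
  f <- function(x) sprintf("%.10f", x)
  sprintf("(((%s:%s,%s:%s):%s,(%s:%s,%s:%s):%s):%s,(%s:%s,%s:%s):%s)",
          tips[1], f(0.4 * h), tips[2], f(0.4 * h), f(0.35 * h),
          tips[3], f(0.4 * h), tips[4], f(0.4 * h), f(0.35 * h), f(0.25 * h),
          tips[5], f(0.4 * h), tips[6], f(0.4 * h), f(0.6 * h))
}
.CLADE_MEAN_FACTOR <- 24.4 / 15

#' Study-design scenario: three clades, one neutralized gene
#'
#' Generates the full synthetic study design on which the pipeline is
#' exercised: three monophyletic clades of six strains each (supergroup A,
#' supergroup B from insects, supergroup B from isopods) plus one outgroup;
#' twelve gene partitions named after the homologous-recombination pathway
#' genes; eleven genes evolve under a single Ka/Ks drawn uniformly from
#' `[0.05, 0.35]` and the `ruvA` partition evolves with clade-specific
#' Ka/Ks (background/clade A 0.3, B-insect 0.2, B-isopod 1.0: the
#' neutralized clade). Branch lengths are calibrated by bisection on the
#' model's expected p-distance so the realized divergences hit the design
#' targets: intragroup 1.5% / 1.0% / 1.2%, intergroup 10.2% (A vs B-insect),
#' 9.3% (A vs B-isopod) and 5.9% (B-insect vs B-isopod).
#'
#' @param seed Integer seed.
#' @param n_codons Codons per gene (default 300).
#' @param kappa Transition/transversion ratio (default 2).
#' @return List: `supermatrix` (12-partition [codon_alignment()]),
#'   `alignments` (per gene), `tree` (the generating tree, branch lengths in
#'   expected substitutions per codon), `groups` (list of [strain_group()]s
#'   incl. outgroup), `truth` (per-gene omega map, neutralized gene/clade,
#'   divergence targets), `pi`, `kappa`.
#' @export
scenario_paper_like <- function(seed = 1L, n_codons = 300L, kappa = 2) {
  code <- genetic_code()
  ntf <- c(A = 0.35, C = 0.13, G = 0.17, T = 0.35)
  cd <- do.call(rbind, strsplit(code$sense_codons, ""))
  pi <- ntf[cd[, 1]] * ntf[cd[, 2]] * ntf[cd[, 3]]
  pi <- stats::setNames(pi / sum(pi), code$sense_codons)

  targets <- list(intra = c(A = 0.015, B_insect = 0.010, B_isopod = 0.012),
                  inter = c(A_Binsect = 0.102, A_Bisopod = 0.093,
                            Binsect_Bisopod = 0.059))
  om_cal <- 0.2  # calibration omega (mid-range of the purifying genes)
  Tt <- function(p) .time_for_pdist(p, kappa, pi, om_cal, code)
  T_ABi <- Tt(targets$inter[["A_Binsect"]])
  T_ABp <- Tt(targets$inter[["A_Bisopod"]])
  T_BiBp <- Tt(targets$inter[["Binsect_Bisopod"]])
  bi <- (T_BiBp + T_ABi - T_ABp) / 2
  bp <- T_BiBp - bi
  ax <- T_ABi - bi
  h <- vapply(targets$intra, Tt, numeric(1)) / .CLADE_MEAN_FACTOR
  names(h) <- c("A", "B_insect", "B_isopod")
  stem <- c(A = 0.7 * ax - h[["A"]], B_insect = bi - h[["B_insect"]],
            B_isopod = bp - h[["B_isopod"]])
  if (any(stem <= 0)) stop("infeasible divergence targets (negative stem)")
  x <- 0.3 * ax
  t_out <- Tt(0.20) / 2

  tipsA <- paste0("wA", 1:6)
  tipsBi <- paste0("wBi", 1:6)
  tipsBp <- paste0("wBp", 1:6)
  nwk <- sprintf("(%s:%.10f,(%s:%.10f,%s:%.10f):%.10f,%s:%.10f);",
                 .clade_newick(tipsA, h[["A"]]), stem[["A"]],
                 .clade_newick(tipsBi, h[["B_insect"]]), stem[["B_insect"]],
                 .clade_newick(tipsBp, h[["B_isopod"]]), stem[["B_isopod"]],
                 x, "wOut", t_out)
  tree <- parse_newick(nwk)
  groups <- list(
    strain_group("A", tipsA, "clade_A"),
    strain_group("B_insect", tipsBi, "clade_B_insect"),
    strain_group("B_isopod", tipsBp, "clade_B_isopod"),
    strain_group("outgroup", "wOut", "outgroup"))
  labeled <- label_clades(tree, groups)

  genes <- c("recJ", "recF", "recO", "recR", "addA", "addB", "recA",
             "ruvB", "ruvC", "recG", "priA", "ruvA")
  omegas <- .with_seed(.substream(seed, 999L),
                       stats::runif(length(genes) - 1L, 0.05, 0.35))
  truth_omega <- stats::setNames(vector("list", length(genes)), genes)
  for (g in seq_len(length(genes) - 1L)) {
    truth_omega[[genes[g]]] <- c("0" = omegas[g], "1" = omegas[g],
                                 "2" = omegas[g], "3" = omegas[g])
  }
  truth_omega[["ruvA"]] <- c("0" = 0.3, "1" = 0.3, "2" = 0.2, "3" = 1.0)

  alns <- lapply(seq_along(genes), function(g) {
    a <- simulate_codon_alignment(labeled, n_codons, kappa = kappa,
                                  omega = truth_omega[[genes[g]]], pi = pi,
                                  seed = .substream(seed, g))
    a$partitions$gene <- genes[g]
    a
  })
  names(alns) <- genes
  supermatrix <- concat_alignments(alns)
  list(supermatrix = supermatrix, alignments = alns, tree = labeled,
       groups = groups,
       truth = list(omega = truth_omega, neutralized_gene = "ruvA",
                    neutralized_clade = "3", targets = targets,
                    seed = seed),
       pi = pi, kappa = kappa)
}

#' Recombinant alignment with a planted breakpoint
#'
#' Simulates the left of the splice point on `tree1` and the right on
#' `tree2` (same leaves, discordant topologies) and records the truth.
#'
#' @param tree1,tree2 Trees over the same leaf set.
#' @param splice_np 1-based nucleotide position at which `tree2` takes over.
#' @param n_codons Total codons.
#' @param kappa,omega,pi,seed,code As in [simulate_codon_alignment()].
#' @return List `alignment`, `truth` (splice_np).
#' @export
scenario_recombinant <- function(tree1, tree2, splice_np, n_codons,
                                 kappa = 2, omega = 0.3, pi = NULL,
                                 seed = 1L, code = genetic_code()) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees must share the same leaf set")
  }
  rf <- tryCatch(ape::dist.topo(ape::unroot(tree1), ape::unroot(tree2),
                                method = "PH85"), error = function(e) NA)
  if (!is.na(rf) && rf == 0) {
    warning("concordant topologies: planted breakpoint is undetectable by design",
            call. = FALSE)
  }
  a1 <- simulate_codon_alignment(tree1, n_codons, kappa, omega, pi,
                                 seed = .substream(seed, 1L), code = code)
  a2 <- simulate_codon_alignment(tree2, n_codons, kappa, omega, pi,
                                 seed = .substream(seed, 2L), code = code)
  strains <- a1$strains
  nsites <- ncol(a1$seq)
  splice_np <- max(1L, min(as.integer(splice_np), nsites + 1L))
  mat <- a1$seq[strains, , drop = FALSE]
  if (splice_np <= nsites) {
    mat[, splice_np:nsites] <- a2$seq[strains, splice_np:nsites]
  }
  list(alignment = codon_alignment(mat, check_stops = FALSE),
       truth = list(splice_np = splice_np))
}

#' Plant near-duplicate strains
#'
#' Adds `n_dupes` copies of randomly chosen strains, each mutated by
#' independent substitutions at per-site rate `divergence` (0 = exact
#' copies), to exercise the deduplication filter.
#'
#' @param aln Base [codon_alignment()].
#' @param n_dupes Number of duplicates to add.
#' @param divergence Per-site substitution probability for each copy.
#' @param seed Integer seed.
#' @return List `alignment` (augmented), `truth` (data frame `dup`, `source`).
#' @export
scenario_near_duplicates <- function(aln, n_dupes, divergence = 0,
                                     seed = 1L) {
  if (divergence < 0) stop("divergence must be >= 0")
  .with_seed(.substream(seed, 3L), {
    src <- sample(aln$strains, n_dupes, replace = n_dupes > length(aln$strains))
    mat <- aln$seq
    bases <- c("A", "C", "G", "T")
    newrows <- list()
    for (k in seq_len(n_dupes)) {
      row <- mat[src[k], ]
      if (divergence > 0) {
        hit <- which(stats::runif(length(row)) < divergence & row %in% bases)
        for (i in hit) row[i] <- sample(setdiff(bases, row[i]), 1L)
      }
      newrows[[paste0(src[k], "_dup", k)]] <- row
    }
    aug <- rbind(mat, do.call(rbind, newrows))
    rownames(aug) <- c(rownames(mat), names(newrows))
    list(alignment = codon_alignment(aug, partitions = aln$partitions,
                                     check_stops = FALSE),
         truth = data.frame(dup = names(newrows), source = src,
                            stringsAsFactors = FALSE))
  })
}
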