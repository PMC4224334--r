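# Likelihood plumbing: site-pattern compression, tip-state encoding, and the
# R-facing pruning log-likelihood over the compiled core.

# Prepare pattern-compressed data + postorder tree encoding for the core.
# Returns NULL-free list understood by cpp_loglik / cpp_optimize_bl.
.lik_prep <- function(aln, tree, code = genetic_code()) {
  if (!setequal(tree$tip.label, aln$strains)) {
    stop("tree leaves do not match alignment strains")
  }
  st <- codon_states(aln, code)
  if (any(st[!is.na(st)] < 0)) {
    warning("in-frame stop codon(s) treated as missing data", call. = FALSE)
    st[st < 0 & !is.na(st)] <- NA_integer_
  }
  st <- st[tree$tip.label, , drop = FALSE]
  st[is.na(st)] <- 0L
  key <- apply(st, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  tipstate <- st[, first, drop = FALSE]

  po <- ape::reorder.phylo(tree, "postorder")
  eclass <- if (!is.null(tree$edge_class)) {
    okey <- paste(tree$edge[, 1], tree$edge[, 2])
    nkey <- paste(po$edge[, 1], po$edge[, 2])
    tree$edge_class[match(nkey, okey)]
  } else {
    integer(nrow(po$edge))
  }
  ntip <- length(tree$tip.label)
  list(tipstate = tipstate, weights = weights, edge = po$edge,
       lengths = po$edge.length, eclass = eclass,
       nnode = ntip + tree$Nnode, root = ntip + 1L,
       pattern_of = match(key, key[first]))
}

# mean-rate constants: the pre-scaling mean rate of the generator is linear
# in omega and kappa, s(kappa, omega) = A0 + kappa A1 + omega (B0 + kappa B1)
# (A: synonymous, B: nonsynonymous; 0: transversion, 1: transition terms).
# Used to put several omega classes on a common synonymous clock.
.rate_scale_constants <- function(pi, code) {
  pr <- code$pairs
  term <- pi[pr$i] * pi[pr$j]
  c(A0 = sum(term[pr$synonymous & !pr$transition]),
    A1 = sum(term[pr$synonymous & pr$transition]),
    B0 = sum(term[!pr$synonymous & !pr$transition]),
    B1 = sum(term[!pr$synonymous & pr$transition]))
}

.rate_scale <- function(kappa, omega, const) {
  unname(const["A0"] + kappa * const["A1"] +
           omega * (const["B0"] + kappa * const["B1"]))
}

# eigens for a named omega map; returns list(eigens, eidx) where eidx maps
# each edge-class tag to an eigen index
.class_eigens <- function(kappa, omega_by_class, pi, code) {
  vals <- unname(omega_by_class)
  uniq <- unique(vals)
  eigens <- lapply(uniq, function(om)
    codon_rate_matrix(kappa, om, pi, code)$eigen)
  list(eigens = eigens,
       eidx = stats::setNames(match(vals, uniq), names(omega_by_class)))
}

# map per-edge class tags (0-based tags) to 1-based eigen indices
.edge_eidx <- function(eclass, eidx) {
  tag <- as.character(eclass)
  if (!all(tag %in% names(eidx))) {
    stop("edge class(es) without an omega assignment: ",
         paste(setdiff(unique(tag), names(eidx)), collapse = ", "))
  }
  unname(eidx[tag])
}

#' Codon-model log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of a codon alignment on a tree under the
#' codon substitution model of [codon_rate_matrix()], with a possibly
#' branch-class-specific omega. Site patterns are compressed before
#' computation; gaps, ambiguous codons and (with a warning) unmasked stop
#' codons contribute partial likelihood 1; underflow is handled by per-node
#' likelihood scaling.
#'
#' @param aln A [codon_alignment()].
#' @param tree `ape::phylo` with branch lengths (expected substitutions per
#'   codon); optional `edge_class` tags from [label_clades()].
#' @param kappa Transition/transversion ratio.
#' @param omega Single Ka/Ks value applied to all branches, or a named vector
#'   mapping edge-class tags (as character; `"0"` = background) to omega.
#' @param pi Codon frequencies (default: F3x4 estimated from `aln`).
#' @param code A [genetic_code()].
#' @param site_loglik Also return per-codon-site log-likelihoods.
#' @return Log-likelihood (numeric scalar), or if `site_loglik` a list with
#'   `loglik` and `site_loglik` (per original codon column).
#' @export
codon_log_likelihood <- function(aln, tree, kappa, omega, pi = NULL,
                                 code = genetic_code(), site_loglik = FALSE) {
  if (is.null(pi)) pi <- estimate_codon_frequencies(aln, "F3x4", code)
  prep <- .lik_prep(aln, tree, code)
  if (length(omega) == 1L && is.null(names(omega))) {
    omega <- stats::setNames(rep(omega, length(unique(prep$eclass))),
                             as.character(sort(unique(prep$eclass))))
  }
  ce <- .class_eigens(kappa, omega, pi, code)
  res <- cpp_loglik(prep$tipstate, prep$edge, prep$nnode, prep$root,
                    prep$lengths, .edge_eidx(prep$eclass, ce$eidx),
                    ce$eigens, pi, prep$weights, site_loglik)
  if (!site_loglik) return(res$loglik)
  list(loglik = res$loglik,
       site_loglik = res$site_loglik[prep$pattern_of])
}
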