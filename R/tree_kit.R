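#' Newick tree I/O
#'
#' Thin, validating wrappers over ape's newick parser/writer. `parse_newick`
#' rejects unbalanced parentheses (reporting the character position of the
#' first imbalance) and duplicate leaf labels; `write_newick` emits branch
#' lengths to 10 significant digits so a write/parse round trip preserves the
#' tree.
#'
#' @param text Newick string (trailing semicolon optional).
#' @return `parse_newick`: an `ape::phylo`; `write_newick`: a newick string.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses at position ", k)
  }
  if (depth != 0L) stop("unbalanced parentheses at position ", length(chars))
  if (!grepl(";$", text)) text <- paste0(text, ";")
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse error")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  tr
}

#' @rdname parse_newick
#' @param tree An `ape::phylo`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

#' Pairwise nucleotide p-distance with pairwise deletion
#'
#' Proportion of differing sites among sites where neither sequence carries a
#' gap or ambiguity character (uncorrected p-distance, pairwise deletion).
#'
#' @param a,b Nucleotide strings or character vectors of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_divergence <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no overlap: no comparable sites")
  mean(a[ok] != b[ok])
}

#' Pairwise divergence matrix
#'
#' Uncorrected p-distances ([pairwise_divergence()]) between all strain pairs.
#'
#' @param aln A [codon_alignment()].
#' @return Symmetric numeric matrix with strain ids as dimnames.
#' @export
divergence_matrix <- function(aln) {
  .pdist_matrix(aln)
}

# strains x strains p-distance matrix (pairwise deletion)
.pdist_matrix <- function(aln) {
  mat <- aln$seq
  n <- nrow(mat)
  valid <- matrix(mat %in% c("A", "C", "G", "T"), n, ncol(mat))
  d <- matrix(0, n, n, dimnames = list(aln$strains, aln$strains))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- valid[i, ] & valid[j, ]
      if (!any(ok)) stop("no overlap between ", aln$strains[i], " and ",
                         aln$strains[j])
      d[i, j] <- d[j, i] <- mean(mat[i, ok] != mat[j, ok])
    }
  }
  d
}

#' Neighbor-joining tree from a codon alignment
#'
#' Builds a tree hypothesis by neighbor joining on Jukes-Cantor-corrected
#' p-distances. Alignment columns with less than `site_filter` fraction of
#' unambiguous bases are removed first (the partial-deletion site filter).
#' Pairs too divergent for the JC correction fall back to the uncorrected
#' distance with a warning; negative NJ branch lengths are clamped to zero
#' with a warning.
#'
#' @param aln A [codon_alignment()] with at least 4 strains.
#' @param site_filter Minimum fraction of unambiguous bases per column
#'   (default 0.85).
#' @return An unrooted `ape::phylo`.
#' @export
build_nj_tree <- function(aln, site_filter = 0.85) {
  if (length(aln$strains) < 4L) stop("need at least 4 strains")
  mat <- aln$seq
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow(mat), ncol(mat))
  keep <- colMeans(good) >= site_filter
  sub <- aln
  sub$seq <- mat[, keep, drop = FALSE]
  if (ncol(sub$seq) == 0L) stop("site filter removed all columns")
  p <- .pdist_matrix(sub)
  if (all(p == 0)) {
    warning("all sequences identical: returning star tree with zero lengths",
            call. = FALSE)
    txt <- paste0("(", paste0(aln$strains, ":0", collapse = ","), ");")
    return(ape::read.tree(text = txt))
  }
  d <- p
  sat <- p >= 0.7499
  if (any(sat[upper.tri(sat)])) {
    warning("saturated pair(s): uncorrected distance used", call. = FALSE)
  }
  d[!sat] <- -0.75 * log(1 - 4 * p[!sat] / 3)
  tr <- ape::nj(as.dist(d))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0", call. = FALSE)
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Gene-jackknife tree hypotheses
#'
#' Leave-one-gene-out resampling of a concatenated multigene alignment:
#' removes each gene partition in turn and rebuilds a tree from the remaining
#' genes, yielding one tree hypothesis per gene. Used to attach robustness
#' ranges to every downstream likelihood-ratio test.
#'
#' @param supermatrix A [codon_alignment()] with `G >= 2` gene partitions.
#' @param site_filter Passed to [build_nj_tree()].
#' @return Named list of `G` trees (name = left-out gene; each tree carries a
#'   `left_out` element), with attribute `n_topologies` = number of distinct
#'   topologies (Robinson-Foulds distance 0 means same topology).
#' @export
jackknife_trees <- function(supermatrix, site_filter = 0.85) {
  part <- supermatrix$partitions
  if (nrow(part) < 2L) stop("need at least 2 gene partitions")
  trees <- vector("list", nrow(part))
  names(trees) <- part$gene
  for (g in seq_len(nrow(part))) {
    keep_cod <- integer(0)
    for (h in seq_len(nrow(part))[-g]) {
      keep_cod <- c(keep_cod,
                    seq.int((part$start_np[h] + 2L) %/% 3L, part$end_np[h] %/% 3L))
    }
    sub <- subset_alignment(supermatrix, codon_cols = keep_cod)
    if (ncol(sub$seq) < 100L) {
      warning("fewer than 100 sites after removing ", part$gene[g], call. = FALSE)
    }
    tr <- build_nj_tree(sub, site_filter = site_filter)
    tr$left_out <- part$gene[g]
    trees[[g]] <- tr
  }
  # distinct topology count via pairwise RF distance
  G <- length(trees)
  topo_id <- seq_len(G)
  for (i in seq_len(G - 1)) {
    for (j in (i + 1):G) {
      if (topo_id[j] != j) next
      rf <- tryCatch(ape::dist.topo(trees[[i]], trees[[j]], method = "PH85"),
                     error = function(e) NA)
      if (!is.na(rf) && rf == 0) topo_id[j] <- topo_id[i]
    }
  }
  attr(trees, "n_topologies") <- length(unique(topo_id))
  trees
}

#' Strain groups (clades) for branch-class models
#'
#' @param name Group name.
#' @param members Character vector of strain ids.
#' @param role One of `"clade_A"`, `"clade_B_insect"`, `"clade_B_isopod"`,
#'   `"outgroup"`, `"custom"`.
#' @return An object of class `strain_group`.
#' @export
strain_group <- function(name, members,
                         role = c("custom", "clade_A", "clade_B_insect",
                                  "clade_B_isopod", "outgroup")) {
  role <- match.arg(role)
  structure(list(name = name, members = unique(members), role = role),
            class = "strain_group")
}

.check_groups <- function(groups, strains) {
  all_members <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(all_members)) {
    stop("strain groups must be disjoint: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  missing <- setdiff(strains, all_members)
  if (length(missing)) {
    stop("strain(s) not assigned to any group: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Label tree branches with omega classes by clade
#'
#' Assigns each branch an integer omega-class tag: a branch gets a group's
#' class iff every leaf descending from it belongs to that group; all other
#' branches (the backbone and the root side) get the background class 0.
#' Groups with role `"outgroup"` are used to root the tree and their branches
#' stay in the background class. Every non-outgroup group must be
#' monophyletic on the tree.
#'
#' @param tree `ape::phylo`; leaf set must equal the union of group members.
#' @param groups List of [strain_group()] objects covering every leaf.
#' @return The tree with added elements `edge_class` (integer per edge row,
#'   0 = background) and `class_labels` (names for classes 1..k, in `groups`
#'   order, outgroup excluded).
#' @export
label_clades <- function(tree, groups) {
  .check_groups(groups, tree$tip.label)
  og <- Filter(function(g) g$role == "outgroup", groups)
  fg <- Filter(function(g) g$role != "outgroup", groups)
  if (length(og) > 0) {
    out_tips <- og[[1]]$members
    if (!all(out_tips %in% tree$tip.label)) stop("outgroup tips not in tree")
    tree <- ape::root(tree, outgroup = out_tips, resolve.root = TRUE)
  }
  ntip <- length(tree$tip.label)
  below <- .tips_below(tree)
  edge_class <- integer(nrow(tree$edge))
  for (k in seq_along(fg)) {
    grp <- fg[[k]]
    stem_found <- FALSE
    for (e in seq_len(nrow(tree$edge))) {
      tb <- tree$tip.label[below[[tree$edge[e, 2]]]]
      if (all(tb %in% grp$members)) {
        edge_class[e] <- k
        if (setequal(tb, grp$members)) stem_found <- TRUE
      }
    }
    if (!stem_found) {
      # identify leaves breaking monophyly: tips inside the smallest clade
      # containing the group that are not group members
      mrca_tips <- .mrca_tips(tree, grp$members, below)
      stop("group '", grp$name, "' is not monophyletic; intruding leaves: ",
           paste(setdiff(mrca_tips, grp$members), collapse = ", "))
    }
  }
  tree$edge_class <- edge_class
  tree$class_labels <- vapply(fg, `[[`, character(1), "name")
  tree
}

# list over nodes of tip indices below each node (tree direction)
.tips_below <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  below <- vector("list", nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  eo <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(eo$edge))) {
    p <- eo$edge[e, 1]; ch <- eo$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  below
}

# tips of the smallest clade containing all given members
.mrca_tips <- function(tree, members, below) {
  sizes <- vapply(below, length, integer(1))
  cand <- which(vapply(seq_along(below), function(v)
    all(members %in% tree$tip.label[below[[v]]]), logical(1)))
  best <- cand[which.min(sizes[cand])]
  tree$tip.label[below[[best]]]
}
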