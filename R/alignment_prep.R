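#' Mask regions
#'
#' A mask region names a gene-relative nucleotide interval (1-based inclusive
#' "np" coordinates) to be removed before selection analyses, either in all
#' strains (whole codon columns are deleted) or in a named subset of strains
#' (the interval is replaced by gaps in those strains only). Intervals not
#' aligned to codon boundaries are expanded outward to whole codons and the
#' expansion is logged.
#'
#' @param gene Gene (partition) name.
#' @param np_start,np_end 1-based inclusive nucleotide positions within the
#'   gene.
#' @param strains `NA` for all strains, else a character vector of strain ids.
#' @param reason One of `"palindrome"`, `"recombination"`, `"user"`.
#' @return One-row data frame; rbind rows to form a mask table.
#' @export
mask_region <- function(gene, np_start, np_end, strains = NA,
                        reason = c("user", "palindrome", "recombination")) {
  reason <- match.arg(reason)
  if (np_start > np_end) stop("np_start > np_end")
  if (np_start < 1) stop("np_start must be >= 1")
  data.frame(gene = gene, np_start = as.integer(np_start),
             np_end = as.integer(np_end),
             strains = if (all(is.na(strains))) NA_character_ else
               paste(strains, collapse = ";"),
             reason = reason, stringsAsFactors = FALSE)
}

#' The seven palindromic (WPE-like) regions masked before analysis
#'
#' Regions resembling Wolbachia palindromic elements that are hard to align
#' with confidence, in gene-relative np coordinates: addA 289-459, 907-1146,
#' 3076-3387; addB 778-1023, 2452-2655; priA 523-1365, 2587-2790.
#'
#' @return Mask table (see [mask_region()]).
#' @export
palindromic_mask_regions <- function() {
  rbind(
    mask_region("addA", 289, 459, reason = "palindrome"),
    mask_region("addA", 907, 1146, reason = "palindrome"),
    mask_region("addA", 3076, 3387, reason = "palindrome"),
    mask_region("addB", 778, 1023, reason = "palindrome"),
    mask_region("addB", 2452, 2655, reason = "palindrome"),
    mask_region("priA", 523, 1365, reason = "palindrome"),
    mask_region("priA", 2587, 2790, reason = "palindrome"))
}

# expand a gene-relative np interval to whole codons; returns c(start, end)
.expand_to_codons <- function(np_start, np_end) {
  s <- np_start - (np_start - 1L) %% 3L
  e <- np_end + (3L - (np_end - 1L) %% 3L - 1L)
  c(s, e)
}

#' Apply mask regions to a codon alignment
#'
#' All-strain regions delete whole codon columns (partition coordinates are
#' remapped); strain-scoped regions are replaced by gaps in the named strains
#' only. Overlapping all-strain regions within a gene are merged with a
#' warning. The applied-mask log (with any codon-boundary expansion) is
#' attached as attribute `"mask_log"`.
#'
#' @param aln A [codon_alignment()].
#' @param regions Mask table (rbind of [mask_region()] rows).
#' @return Masked [codon_alignment()] with attribute `mask_log`.
#' @export
mask_regions <- function(aln, regions) {
  if (is.null(regions) || nrow(regions) == 0L) return(aln)
  part <- aln$partitions
  log <- list()
  mat <- aln$seq
  drop_codons <- integer(0)
  # validate + expand
  reg <- regions
  reg$exp_start <- NA_integer_; reg$exp_end <- NA_integer_
  for (r in seq_len(nrow(reg))) {
    p <- part[part$gene == reg$gene[r], , drop = FALSE]
    if (nrow(p) != 1L) stop("mask region names unknown gene: ", reg$gene[r])
    glen <- p$end_np - p$start_np + 1L
    if (reg$np_end[r] > glen) {
      stop(sprintf("mask region %s np %d-%d outside gene (length %d)",
                   reg$gene[r], reg$np_start[r], reg$np_end[r], glen))
    }
    ex <- .expand_to_codons(reg$np_start[r], reg$np_end[r])
    if (ex[1] != reg$np_start[r] || ex[2] != reg$np_end[r]) {
      message(sprintf("mask %s np %d-%d expanded to codon boundaries %d-%d",
                      reg$gene[r], reg$np_start[r], reg$np_end[r], ex[1], ex[2]))
    }
    reg$exp_start[r] <- ex[1]; reg$exp_end[r] <- min(ex[2], glen)
  }
  all_strain <- is.na(reg$strains)
  # merge overlapping all-strain regions per gene
  if (any(all_strain)) {
    for (g in unique(reg$gene[all_strain])) {
      rows <- which(all_strain & reg$gene == g)
      if (length(rows) > 1L) {
        o <- rows[order(reg$exp_start[rows])]
        for (k in seq_along(o)[-1]) {
          if (reg$exp_start[o[k]] <= reg$exp_end[o[k - 1]]) {
            warning("overlapping all-strain mask regions in ", g, " merged",
                    call. = FALSE)
          }
        }
      }
      p <- part[part$gene == g, ]
      for (r in rows) {
        cods <- seq.int((p$start_np + reg$exp_start[r] - 1L + 2L) %/% 3L,
                        (p$start_np + reg$exp_end[r] - 1L) %/% 3L)
        drop_codons <- union(drop_codons, cods)
      }
    }
  }
  # strain-scoped: gap out in named strains (alignment coordinates)
  for (r in which(!all_strain)) {
    p <- part[part$gene == reg$gene[r], ]
    cols <- seq.int(p$start_np + reg$exp_start[r] - 1L,
                    p$start_np + reg$exp_end[r] - 1L)
    ss <- strsplit(reg$strains[r], ";")[[1]]
    missing <- setdiff(ss, aln$strains)
    if (length(missing)) stop("mask names unknown strain(s): ",
                              paste(missing, collapse = ", "))
    mat[ss, cols] <- "-"
  }
  out <- codon_alignment(mat, partitions = part, check_stops = FALSE)
  if (length(drop_codons)) {
    keep <- setdiff(seq_len(n_codons(out)), drop_codons)
    out <- subset_alignment(out, codon_cols = keep)
  }
  attr(out, "mask_log") <- reg
  out
}

#' Split a gene partition at a premature stop codon
#'
#' Splits gene `gene` into `<gene>_1` (np 1 .. stop_np - 1) and `<gene>_2`
#' (np stop_np + 3 .. gene end); the stop codon column itself is excluded
#' from both parts. `stop_np` is the gene-relative position of the stop
#' codon's first base and must sit on a codon boundary; at least one strain
#' must actually carry a stop codon there.
#'
#' @param aln A [codon_alignment()].
#' @param gene Partition to split.
#' @param stop_np Gene-relative np of the stop codon's first base.
#' @param code A [genetic_code()].
#' @return A [codon_alignment()] with the gene replaced by two partitions.
#' @export
split_gene_at_stop <- function(aln, gene, stop_np, code = genetic_code()) {
  part <- aln$partitions
  p <- part[part$gene == gene, , drop = FALSE]
  if (nrow(p) != 1L) stop("gene not found: ", gene)
  if ((stop_np - 1L) %% 3L != 0L) stop("stop_np not at a codon boundary")
  glen <- p$end_np - p$start_np + 1L
  if (stop_np + 2L > glen) stop("stop_np outside gene")
  stop_codon_idx <- (p$start_np + stop_np - 1L + 2L) %/% 3L
  trip <- vapply(aln$strains, function(s)
    .codon_strings(aln$seq[s, ], stop_codon_idx), character(1))
  if (!any(trip %in% code$stop_codons)) {
    stop("no stop codon present at ", gene, " np ", stop_np,
         " in any strain (found: ", paste(unique(trip), collapse = ","), ")")
  }
  # rebuild partitions: replace the gene row by two rows, drop the stop codon
  first_cod <- (p$start_np + 2L) %/% 3L
  last_cod <- p$end_np %/% 3L
  keep <- setdiff(seq_len(n_codons(aln)), stop_codon_idx)
  new_part <- list()
  for (g in seq_len(nrow(part))) {
    if (part$gene[g] != gene) {
      new_part[[g]] <- part[g, ]
    } else {
      new_part[[g]] <- data.frame(
        gene = paste0(gene, c("_1", "_2")),
        start_np = c(p$start_np, p$start_np + stop_np + 2L),
        end_np = c(p$start_np + stop_np - 2L, p$end_np),
        stringsAsFactors = FALSE)
    }
  }
  tmp <- aln
  tmp$partitions <- do.call(rbind, new_part)
  subset_alignment(tmp, codon_cols = keep)
}

#' Remove near-duplicate strains
#'
#' Clusters strains by single linkage at pairwise nucleotide divergence below
#' `threshold` (uncorrected p-distance, pairwise deletion) and keeps exactly
#' one representative per cluster: the lexicographically smallest strain id,
#' a deterministic, input-order-independent choice.
#'
#' @param aln A [codon_alignment()] (typically the concatenated supermatrix).
#' @param threshold Divergence below which strains are considered redundant
#'   (default 0.002, i.e. 0.2%).
#' @return List with `kept`, `removed` (character vectors), `groups` (list of
#'   clusters), and `alignment` (the deduplicated [codon_alignment()]).
#' @export
dedup_strains <- function(aln, threshold = 0.002) {
  n <- length(aln$strains)
  if (n < 2L) stop("need at least 2 strains")
  d <- .pdist_matrix(aln)
  # single-linkage connected components under d < threshold
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] < threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(aln$strains, comp)
  names(groups) <- NULL
  kept <- vapply(groups, function(g) sort(g)[1], character(1))
  removed <- setdiff(aln$strains, kept)
  list(kept = sort(kept), removed = sort(removed), groups = groups,
       alignment = subset_alignment(aln, strains = intersect(aln$strains, kept)))
}

#' Intra- and inter-group mean divergence summary
#'
#' Mean pairwise nucleotide divergence ([pairwise_divergence()]) within each
#' strain group and between each group pair. A singleton group has no
#' intra-group value and is reported as `NA`.
#'
#' @param aln A [codon_alignment()].
#' @param groups List of [strain_group()]s.
#' @return List with `intra` (named vector) and `inter` (data frame with
#'   `group1`, `group2`, `divergence`).
#' @export
group_divergence_summary <- function(aln, groups) {
  d <- .pdist_matrix(aln)
  gnames <- vapply(groups, `[[`, character(1), "name")
  intra <- stats::setNames(rep(NA_real_, length(groups)), gnames)
  for (k in seq_along(groups)) {
    m <- intersect(groups[[k]]$members, aln$strains)
    if (length(m) >= 2L) {
      sub <- d[m, m]
      intra[k] <- mean(sub[upper.tri(sub)])
    }
  }
  inter <- list()
  if (length(groups) >= 2L) {
    for (i in seq_len(length(groups) - 1L)) {
      for (j in (i + 1L):length(groups)) {
        mi <- intersect(groups[[i]]$members, aln$strains)
        mj <- intersect(groups[[j]]$members, aln$strains)
        inter[[length(inter) + 1L]] <- data.frame(
          group1 = gnames[i], group2 = gnames[j],
          divergence = mean(d[mi, mj, drop = FALSE]),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(intra = intra, inter = do.call(rbind, inter))
}
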