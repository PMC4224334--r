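#' In-frame codon alignments
#'
#' The substrate of every analysis stage: an in-frame multi-strain nucleotide
#' alignment stored as a character matrix (rows = strains, columns =
#' nucleotide sites), with optional named gene partitions in 1-based inclusive
#' nucleotide ("np") coordinates. Codon column k covers np 3k-2 .. 3k.
#'
#' Gaps (`-`) and IUPAC ambiguity characters are permitted and are treated as
#' missing data by the likelihood machinery. On construction, any in-frame
#' stop codon at a non-terminal position is reported with a warning (such
#' stops are biologically meaningful -- they flag pseudogenization or the need
#' to split the gene -- and must not pass silently).
#'
#' @param seqs Named character vector of equal-length nucleotide strings, or a
#'   character matrix of single characters with row names = strain ids.
#' @param partitions Optional data frame with columns `gene`, `start_np`,
#'   `end_np` (1-based inclusive, codon-aligned). Defaults to a single
#'   partition spanning the alignment.
#' @param check_stops Report in-frame premature stop codons (default TRUE).
#' @param code A [genetic_code()] object.
#' @return An object of class `codon_alignment`: list with `strains`, `seq`
#'   (character matrix), `partitions`.
#' @export
codon_alignment <- function(seqs, partitions = NULL, check_stops = TRUE,
                            code = genetic_code()) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    if (is.null(rownames(mat))) stop("sequence matrix must have row names")
  } else {
    if (is.null(names(seqs))) stop("sequences must be named by strain")
    if (length(unique(nchar(seqs))) != 1L) {
      stop("all sequences must have equal length")
    }
    mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
    rownames(mat) <- names(seqs)
  }
  if (anyDuplicated(rownames(mat))) stop("duplicate strain ids")
  nsites <- ncol(mat)
  if (nsites %% 3L != 0L) stop("alignment length not divisible by 3")
  if (is.null(partitions)) {
    partitions <- data.frame(gene = "gene1", start_np = 1L,
                             end_np = nsites, stringsAsFactors = FALSE)
  }
  .validate_partitions(partitions, nsites)
  aln <- structure(list(strains = rownames(mat), seq = mat,
                        partitions = partitions),
                   class = "codon_alignment")
  if (check_stops) {
    ps <- premature_stops(aln, code)
    if (nrow(ps) > 0) {
      warning(sprintf(
        "in-frame premature stop codon(s) found: %s",
        paste(utils::head(sprintf("%s codon %d (%s)", ps$strain,
                                  ps$codon_index, ps$codon), 5),
              collapse = "; ")), call. = FALSE)
    }
  }
  aln
}

.validate_partitions <- function(p, nsites) {
  stopifnot(all(c("gene", "start_np", "end_np") %in% names(p)))
  if (any(p$start_np > p$end_np)) stop("partition start_np > end_np")
  if (any(p$start_np < 1L) || any(p$end_np > nsites)) {
    stop("partition out of alignment bounds")
  }
  if (any((p$start_np - 1L) %% 3L != 0L) || any(p$end_np %% 3L != 0L)) {
    stop("partitions must be codon-aligned")
  }
  o <- order(p$start_np)
  if (any(p$start_np[o][-1] <= p$end_np[o][-nrow(p)])) {
    stop("partitions overlap")
  }
  invisible(TRUE)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d strains x %d np (%d codons), %d partition(s)\n",
              length(x$strains), ncol(x$seq), ncol(x$seq) %/% 3L,
              nrow(x$partitions)))
  invisible(x)
}

#' Number of codon columns in an alignment
#' @param aln A [codon_alignment()].
#' @return Integer codon count.
#' @export
n_codons <- function(aln) ncol(aln$seq) %/% 3L

#' Report in-frame premature stop codons
#'
#' Scans every strain for stop codons at non-terminal codon positions
#' (the final codon of each partition is excluded, as a terminal stop is
#' ordinary). Codons containing gaps or ambiguities are skipped.
#'
#' @param aln A [codon_alignment()].
#' @param code A [genetic_code()] object.
#' @return Data frame with columns `strain`, `gene`, `codon_index`
#'   (alignment-wide, 1-based), `np_start`, `codon`.
#' @export
premature_stops <- function(aln, code = genetic_code()) {
  out <- list()
  for (g in seq_len(nrow(aln$partitions))) {
    p <- aln$partitions[g, ]
    cods <- seq.int((p$start_np + 2L) %/% 3L, p$end_np %/% 3L)
    cods <- cods[-length(cods)]  # terminal codon of the partition is fine
    if (length(cods) == 0) next
    for (s in aln$strains) {
      trip <- .codon_strings(aln$seq[s, , drop = TRUE], cods)
      hit <- which(trip %in% code$stop_codons)
      if (length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          strain = s, gene = p$gene, codon_index = cods[hit],
          np_start = 3L * cods[hit] - 2L, codon = trip[hit],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(strain = character(), gene = character(),
                      codon_index = integer(), np_start = integer(),
                      codon = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

.codon_strings <- function(chars, codon_idx) {
  paste0(chars[3L * codon_idx - 2L], chars[3L * codon_idx - 1L],
         chars[3L * codon_idx])
}

#' Extract one gene partition as its own alignment
#' @param aln A [codon_alignment()].
#' @param gene Partition name.
#' @return A [codon_alignment()] restricted to that gene, single partition.
#' @export
extract_gene <- function(aln, gene) {
  p <- aln$partitions[aln$partitions$gene == gene, , drop = FALSE]
  if (nrow(p) != 1L) stop("gene not found (or duplicated): ", gene)
  cols <- seq.int(p$start_np, p$end_np)
  codon_alignment(aln$seq[, cols, drop = FALSE],
                  partitions = data.frame(gene = gene, start_np = 1L,
                                          end_np = length(cols),
                                          stringsAsFactors = FALSE),
                  check_stops = FALSE)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alns Named list of [codon_alignment()] objects over the same strain
#'   set (order may differ); names become partition genes.
#' @return A [codon_alignment()] with one partition per input gene.
#' @export
concat_alignments <- function(alns) {
  if (is.null(names(alns)) || any(names(alns) == "")) {
    stop("alignments must be named by gene")
  }
  strains <- alns[[1]]$strains
  for (a in alns) {
    if (!setequal(a$strains, strains)) stop("strain sets differ across genes")
  }
  mats <- lapply(alns, function(a) a$seq[strains, , drop = FALSE])
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  part <- data.frame(gene = names(alns), start_np = starts, end_np = ends,
                     stringsAsFactors = FALSE, row.names = NULL)
  codon_alignment(do.call(cbind, mats), partitions = part, check_stops = FALSE)
}

#' Drop strains or whole codon columns
#' @param aln A [codon_alignment()].
#' @param strains Strain ids to keep (default all).
#' @param codon_cols Codon column indices (1-based) to keep (default all);
#'   partitions are remapped (a partition losing all its codons is dropped).
#' @return A [codon_alignment()].
#' @export
subset_alignment <- function(aln, strains = aln$strains, codon_cols = NULL) {
  mat <- aln$seq[strains, , drop = FALSE]
  if (is.null(codon_cols)) {
    return(codon_alignment(mat, partitions = aln$partitions,
                           check_stops = FALSE))
  }
  codon_cols <- sort(unique(codon_cols))
  keep_np <- as.vector(rbind(3L * codon_cols - 2L, 3L * codon_cols - 1L,
                             3L * codon_cols))
  # remap partitions: count surviving codons per gene
  p <- aln$partitions
  new_parts <- list()
  offset <- 0L
  for (g in seq_len(nrow(p))) {
    gc_idx <- seq.int((p$start_np[g] + 2L) %/% 3L, p$end_np[g] %/% 3L)
    nkeep <- sum(codon_cols %in% gc_idx)
    if (nkeep == 0L) next
    new_parts[[length(new_parts) + 1L]] <- data.frame(
      gene = p$gene[g], start_np = offset * 3L + 1L,
      end_np = (offset + nkeep) * 3L, stringsAsFactors = FALSE)
    offset <- offset + nkeep
  }
  codon_alignment(mat[, keep_np, drop = FALSE],
                  partitions = do.call(rbind, new_parts), check_stops = FALSE)
}

#' Read / write in-frame FASTA alignments
#'
#' Thin wrappers over ape's FASTA reader/writer. `read_codon_alignment`
#' accepts gap characters and IUPAC ambiguity codes; the alignment must be
#' in frame (length divisible by 3).
#'
#' @param file Path to a FASTA file.
#' @param ... Passed to [codon_alignment()].
#' @return `read_codon_alignment`: a [codon_alignment()].
#' @export
read_codon_alignment <- function(file, ...) {
  dna <- ape::read.FASTA(file)
  mat <- toupper(as.character(as.matrix(dna)))
  codon_alignment(mat, ...)
}

#' @rdname read_codon_alignment
#' @param aln A [codon_alignment()].
#' @export
write_codon_alignment <- function(aln, file) {
  seqs <- apply(aln$seq, 1L, paste0, collapse = "")
  con <- file(file, "w")
  on.exit(close(con))
  for (s in names(seqs)) {
    writeLines(c(paste0(">", s), seqs[[s]]), con)
  }
  invisible(file)
}

#' Map alignment columns to codon states
#'
#' Encodes each strain x codon-column cell as a 1-based index into the sense
#' codons of `code`; codons containing gaps or ambiguity characters map to
#' `NA`, and stop codons map to `-2` so callers can decide how to treat them
#' (the likelihood machinery treats them as missing, with a warning).
#'
#' @param aln A [codon_alignment()].
#' @param code A [genetic_code()].
#' @return Integer matrix (strains x codons); `NA` = missing, negative = stop.
#' @export
codon_states <- function(aln, code = genetic_code()) {
  nc <- n_codons(aln)
  idx <- seq_len(nc)
  out <- matrix(NA_integer_, nrow = length(aln$strains), ncol = nc,
                dimnames = list(aln$strains, NULL))
  lookup <- stats::setNames(seq_along(code$sense_codons), code$sense_codons)
  for (s in seq_along(aln$strains)) {
    trip <- .codon_strings(aln$seq[s, , drop = TRUE], idx)
    v <- lookup[trip]
    v[trip %in% code$stop_codons] <- -2L
    out[s, ] <- v
  }
  out
}
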