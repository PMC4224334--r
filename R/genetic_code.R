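#' Genetic code tables for codon models
#'
#' Builds the genetic code used throughout the package: the codon-to-amino-acid
#' map, the ordered list of sense (non-stop) codons that index every rate
#' matrix and likelihood vector, and precomputed single-nucleotide-change
#' relations between sense codons (transition vs transversion, synonymous vs
#' nonsynonymous).
#'
#' The default is NCBI translation table 11 (bacterial, archaeal and plant
#' plastid code), which shares all codon assignments with the standard code
#' (table 1); the two tables differ only in permitted start codons, which play
#' no role in substitution models. Table 11 has 61 sense codons and the three
#' stops TAA, TAG and TGA.
#'
#' @param table_id Integer translation table id. Tables 1 and 11 are
#'   supported (identical codon-to-amino-acid maps).
#' @return An object of class `genetic_code`: a list with elements
#'   `table_id`, `codons` (all 64 triplets), `codon_to_aa` (named character
#'   vector, `"*"` for stops), `sense_codons` (ordered, length 61),
#'   `stop_codons`, and `pairs`, a data frame of ordered sense-codon pairs
#'   differing at exactly one nucleotide position with columns `i`, `j`
#'   (1-based indices into `sense_codons`), `pos` (1-3), `transition`
#'   (logical) and `synonymous` (logical).
#' @examples
#' gc <- genetic_code()
#' length(gc$sense_codons)  # 61
#' gc$codon_to_aa[["ATG"]]  # "M"
#' @export
genetic_code <- function(table_id = 11L) {
  table_id <- as.integer(table_id)
  if (!table_id %in% c(1L, 11L)) {
    stop("unsupported translation table: ", table_id)
  }
  key <- as.character(table_id)
  cached <- .code_cache[[key]]
  if (!is.null(cached)) return(cached)
  bases <- c("T", "C", "A", "G")
  # standard code, codons enumerated with first base slowest over T,C,A,G
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  codons_tcag <- as.vector(vapply(bases, function(b1)
    vapply(bases, function(b2)
      paste0(b1, b2, bases), character(4)), character(16)))
  codon_to_aa <- stats::setNames(aa, codons_tcag)
  # reorder alphabetically (A,C,G,T) for a stable, documented codon order
  ord <- order(names(codon_to_aa))
  codon_to_aa <- codon_to_aa[ord]
  codons <- names(codon_to_aa)
  sense <- codons[codon_to_aa != "*"]
  stops <- codons[codon_to_aa == "*"]

  pairs <- .codon_pairs(sense, codon_to_aa)
  out <- structure(
    list(table_id = table_id, codons = codons, codon_to_aa = codon_to_aa,
         sense_codons = sense, stop_codons = stops, pairs = pairs),
    class = "genetic_code"
  )
  .code_cache[[key]] <- out
  out
}

# built genetic codes are immutable; cache them per table id
.code_cache <- new.env(parent = emptyenv())

# ordered pairs of sense codons differing at exactly one position
.codon_pairs <- function(sense, codon_to_aa) {
  n <- length(sense)
  mat <- do.call(rbind, strsplit(sense, ""))
  out_i <- integer(0); out_j <- integer(0); out_pos <- integer(0)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  is_ts <- logical(0); is_syn <- logical(0)
  for (pos in 1:3) {
    other <- setdiff(1:3, pos)
    key <- paste0(mat[, other[1]], mat[, other[2]])
    for (k in unique(key)) {
      idx <- which(key == k)
      if (length(idx) < 2) next
      cmb <- expand.grid(a = idx, b = idx)
      cmb <- cmb[cmb$a != cmb$b, , drop = FALSE]
      out_i <- c(out_i, cmb$a)
      out_j <- c(out_j, cmb$b)
      out_pos <- c(out_pos, rep.int(pos, nrow(cmb)))
      chg <- paste0(mat[cmb$a, pos], mat[cmb$b, pos])
      is_ts <- c(is_ts, chg %in% ts_pairs)
      is_syn <- c(is_syn, codon_to_aa[sense[cmb$a]] == codon_to_aa[sense[cmb$b]])
    }
  }
  data.frame(i = out_i, j = out_j, pos = out_pos,
             transition = is_ts, synonymous = is_syn)
}

#' Translate an in-frame nucleotide sequence
#'
#' @param seq Character scalar (nucleotides) or character vector of codons.
#' @param code A [genetic_code()] object.
#' @return Character vector of amino acids (`"*"` for stops, `NA` for codons
#'   containing gaps or ambiguity characters).
#' @export
translate_codons <- function(seq, code = genetic_code()) {
  if (length(seq) == 1L && nchar(seq[1]) > 3L) {
    if (nchar(seq) %% 3L != 0L) stop("sequence length not a multiple of 3")
    seq <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  }
  seq <- toupper(seq)
  out <- unname(code$codon_to_aa[seq])
  out
}
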