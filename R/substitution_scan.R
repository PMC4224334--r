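#' Amino acid physicochemical property table
#'
#' Charge class (negative / neutral / positive), hydrophobicity class
#' (hydrophobic / nonhydrophobic) and aliphatic flag for the 20 standard
#' amino acids, following standard biochemical groupings: charged residues
#' D,E (negative) and K,R,H (positive); hydrophobic side chains
#' A,V,L,I,M,F,W,C,P; aliphatic A,V,L,I. Proline is classed hydrophobic and
#' nonaliphatic (its ring is nonlinear), so L -> P changes the aliphatic
#' property only and P -> Q changes hydrophobicity only; D -> N is a pure
#' charge change and K -> R no change -- the annotation conventions used in
#' clade-exclusive substitution tables for RuvA.
#'
#' @return Data frame with columns `aa`, `charge`, `hydrophobicity`,
#'   `aliphatic` covering all 20 amino acids.
#' @export
aa_property_table <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  charge <- rep("neutral", 20)
  charge[aa %in% c("D", "E")] <- "negative"
  charge[aa %in% c("K", "R", "H")] <- "positive"
  hydro <- ifelse(aa %in% c("A", "V", "L", "I", "M", "F", "W", "C", "P"),
                  "hydrophobic", "nonhydrophobic")
  aliph <- aa %in% c("A", "V", "L", "I")
  data.frame(aa = aa, charge = charge, hydrophobicity = hydro,
             aliphatic = aliph, stringsAsFactors = FALSE)
}

#' Annotate the physicochemical change of an amino acid replacement
#'
#' @param aa_from,aa_to Single-letter amino acids.
#' @param table Property table (default [aa_property_table()]).
#' @return Character vector: the subset of
#'   `c("charge", "hydrophobicity", "aliphatic")` whose class differs between
#'   the two residues; empty = conservative replacement. Attribute
#'   `"description"` holds printable `from > to` class strings.
#' @export
annotate_property_change <- function(aa_from, aa_to,
                                     table = aa_property_table()) {
  for (a in c(aa_from, aa_to)) {
    if (!a %in% table$aa) stop("nonstandard amino acid: ", a)
  }
  f <- table[table$aa == aa_from, ]
  t <- table[table$aa == aa_to, ]
  out <- character(0)
  desc <- character(0)
  if (f$charge != t$charge) {
    out <- c(out, "charge")
    desc <- c(desc, paste0(f$charge, " > ", t$charge))
  }
  if (f$hydrophobicity != t$hydrophobicity) {
    out <- c(out, "hydrophobicity")
    desc <- c(desc, paste0(f$hydrophobicity, " > ", t$hydrophobicity))
  }
  if (f$aliphatic != t$aliphatic) {
    out <- c(out, "aliphatic")
    desc <- c(desc, paste0(ifelse(f$aliphatic, "aliphatic", "nonaliphatic"),
                           " > ",
                           ifelse(t$aliphatic, "aliphatic", "nonaliphatic")))
  }
  attr(out, "description") <- desc
  out
}

#' Find substitutions exclusively shared by a foreground clade
#'
#' A nucleotide site qualifies when (i) all background strains share one
#' state, (ii) at least `|foreground| - max_exceptions` foreground strains
#' share a single different state, and (iii) no background strain carries the
#' foreground state. Sites where any involved strain has a gap or ambiguity
#' are skipped. Foreground strains not carrying the foreground state are
#' listed as exceptions per record (`max_exceptions = 1` supports
#' "except for one strain" style footnotes).
#'
#' @param aln Single-gene [codon_alignment()].
#' @param foreground A [strain_group()] or character vector of strain ids.
#' @param background Character vector of strain ids (disjoint from
#'   foreground); defaults to all other strains.
#' @param max_exceptions Number of foreground strains allowed to deviate
#'   (default 0).
#' @return Data frame of substitution records: `gene`, `np`, `codon_index`,
#'   `codon_position`, `background_state`, `foreground_state`, `exceptions`
#'   (`;`-separated), plus empty classification columns filled by
#'   [classify_syn_nonsyn()].
#' @export
clade_exclusive_substitutions <- function(aln, foreground, background = NULL,
                                          max_exceptions = 0L) {
  if (inherits(foreground, "strain_group")) foreground <- foreground$members
  if (is.null(background)) background <- setdiff(aln$strains, foreground)
  if (length(foreground) == 0L || length(background) == 0L) {
    stop("foreground and background must be non-empty")
  }
  if (length(intersect(foreground, background))) {
    stop("foreground and background overlap")
  }
  stopifnot(all(c(foreground, background) %in% aln$strains))
  gene <- aln$partitions$gene[1]
  fg <- aln$seq[foreground, , drop = FALSE]
  bg <- aln$seq[background, , drop = FALSE]
  acgt <- c("A", "C", "G", "T")
  rows <- list()
  for (np in seq_len(ncol(aln$seq))) {
    bcol <- bg[, np]; fcol <- fg[, np]
    if (!all(c(bcol, fcol) %in% acgt)) next
    if (length(unique(bcol)) != 1L) next
    b <- bcol[1]
    tab <- table(fcol[fcol != b])
    if (length(tab) == 0L) next
    f <- names(tab)[which.max(tab)]
    if (max(tab) < length(foreground) - max_exceptions) next
    exc <- foreground[fcol != f]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, np = np, codon_index = (np + 2L) %/% 3L,
      codon_position = (np - 1L) %% 3L + 1L,
      background_state = b, foreground_state = f,
      exceptions = paste(exc, collapse = ";"),
      type = NA_character_, aa_change = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), np = integer(),
                      codon_index = integer(), codon_position = integer(),
                      background_state = character(),
                      foreground_state = character(), exceptions = character(),
                      type = character(), aa_change = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify substitution records as synonymous or nonsynonymous
#'
#' Translates the background codon and the background codon with the
#' substituted base: identical amino acids give a synonymous record;
#' otherwise the record is nonsynonymous with an `aa_change` in compact
#' notation (background amino acid, codon index, foreground amino acid, e.g.
#' `L118P`). A foreground codon that is a stop is flagged `"inactivating"`.
#' The background codon is the consensus codon over background strains and
#' must be unambiguous.
#'
#' @param records Data frame from [clade_exclusive_substitutions()].
#' @param aln The same single-gene [codon_alignment()].
#' @param background Background strain ids (default: all strains not listed
#'   as carrying the foreground state -- pass the same vector used for the
#'   scan).
#' @param code A [genetic_code()].
#' @return `records` with `type` and `aa_change` filled.
#' @export
classify_syn_nonsyn <- function(records, aln, background, code = genetic_code()) {
  if (nrow(records) == 0L) return(records)
  acgt <- c("A", "C", "G", "T")
  for (r in seq_len(nrow(records))) {
    ci <- records$codon_index[r]
    cp <- records$codon_position[r]
    cods <- vapply(background, function(s)
      .codon_strings(aln$seq[s, ], ci), character(1))
    cods <- cods[vapply(strsplit(cods, ""), function(ch)
      all(ch %in% acgt), logical(1))]
    if (length(cods) == 0L) stop("background codon ambiguous at codon ", ci)
    bg_codon <- names(sort(table(cods), decreasing = TRUE))[1]
    if (substr(bg_codon, cp, cp) != records$background_state[r]) {
      stop("background codon inconsistent with record at codon ", ci)
    }
    fg_codon <- bg_codon
    substr(fg_codon, cp, cp) <- records$foreground_state[r]
    aa_from <- code$codon_to_aa[[bg_codon]]
    aa_to <- code$codon_to_aa[[fg_codon]]
    if (aa_to == "*") {
      records$type[r] <- "inactivating"
      records$aa_change[r] <- paste0(aa_from, ci, "*")
    } else if (aa_from == aa_to) {
      records$type[r] <- "synonymous"
      records$aa_change[r] <- NA_character_
    } else {
      records$type[r] <- "nonsynonymous"
      records$aa_change[r] <- paste0(aa_from, ci, aa_to)
    }
  }
  records
}

#' Cross-reference substitutions against a functional-site list
#'
#' @param records Classified substitution records.
#' @param sites Data frame with columns `position` (reference protein
#'   numbering), `role`, `source` (see [ruva_functional_sites()]).
#' @param offset Integer added to the alignment codon index to obtain the
#'   reference protein position (default 0).
#' @return The subset of `records` hitting a listed site, with added columns
#'   `site_position` and `role`.
#' @export
crossref_functional_sites <- function(records, sites, offset = 0L) {
  if (nrow(records) == 0L || nrow(sites) == 0L) {
    out <- records[0, , drop = FALSE]
    out$site_position <- integer(0); out$role <- character(0)
    return(out)
  }
  ref_pos <- records$codon_index + offset
  hit <- ref_pos %in% sites$position
  out <- records[hit, , drop = FALSE]
  out$site_position <- ref_pos[hit]
  out$role <- vapply(out$site_position, function(p)
    paste(sites$role[sites$position == p], collapse = ";"), character(1))
  out
}

#' Curated RuvA functional-site and domain fixtures (synthetic stand-ins)
#'
#' The published literature synthesis lists 51 amino acid sites of the
#' roughly 200-residue RuvA protein considered important for folding,
#' multimerization or DNA binding (crystallography and mutagenesis studies),
#' and three structural domains (I and II: tetramerization and junction-DNA
#' binding; III: branch migration through heteroduplex contact with RuvB).
#' The exact site list and domain coordinates are not reproduced in the text
#' available to this package, so the shipped fixtures are SYNTHETIC
#' stand-ins: position 118 (DNA binding, the E. coli Lys-118 contact) and the
#' domain roles are real; the remaining 50 positions and the domain
#' boundaries are constructed placeholders consistent with the published
#' domain assignments. Replace them with a curated list for real analyses.
#'
#' @return `ruva_functional_sites()`: data frame `position`, `role`,
#'   `source`; `ruva_domains()`: data frame `domain`, `aa_start`, `aa_end`,
#'   `role`.
#' @export
ruva_functional_sites <- function() {
  path <- system.file("extdata", "ruva_functional_sites_synthetic.tsv",
                      package = "omegarelax", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' @rdname ruva_functional_sites
#' @export
ruva_domains <- function() {
  path <- system.file("extdata", "ruva_domains_synthetic.tsv",
                      package = "omegarelax", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Annotate records with their structural domain
#'
#' @param records Substitution records.
#' @param domains Domain map (default [ruva_domains()]).
#' @return `records` with a `functional_domain` column (`NA` outside all
#'   domains).
#' @export
annotate_domains <- function(records, domains = ruva_domains()) {
  records$functional_domain <- vapply(records$codon_index, function(ci) {
    hit <- domains$domain[domains$aa_start <= ci & domains$aa_end >= ci]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  records
}

#' Pseudogenization feature checks
#'
#' Scans a nucleotide sequence for inactivating features: premature stop
#' codons (in frame, before the final codon), frameshift indicators (gapless
#' length not a multiple of 3, or gap runs whose length is not a multiple of
#' 3), and homopolymeric poly(A) tracts strictly longer than
#' `polyA_threshold` (default 9, i.e. > 9 bp) which can induce RNA-polymerase
#' slippage.
#'
#' @param seq Nucleotide string (gaps allowed).
#' @param polyA_threshold Poly(A) run length that must be exceeded (default 9).
#' @param code A [genetic_code()].
#' @return Data frame with columns `feature`
#'   (`premature_stop` / `frameshift` / `polyA`), `position` (np in the
#'   gapless sequence; codon start for stops), `length`, `detail`.
#' @export
detect_inactivating_features <- function(seq, polyA_threshold = 9L,
                                         code = genetic_code()) {
  chars <- strsplit(toupper(seq), "")[[1]]
  rows <- list()
  add <- function(feature, position, len, detail) {
    rows[[length(rows) + 1L]] <<- data.frame(
      feature = feature, position = position, length = len,
      detail = detail, stringsAsFactors = FALSE)
  }
  # gap runs not a multiple of 3
  r <- rle(chars == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths %% 3L != 0L)) {
    add("frameshift", starts[k], r$lengths[k],
        sprintf("gap run of %d bp (not a multiple of 3)", r$lengths[k]))
  }
  gapless <- chars[chars != "-"]
  if (length(gapless) %% 3L != 0L) {
    add("frameshift", length(gapless), length(gapless) %% 3L,
        "gapless length not a multiple of 3")
  }
  nc <- length(gapless) %/% 3L
  if (nc >= 2L) {
    trip <- paste0(gapless[3 * seq_len(nc) - 2], gapless[3 * seq_len(nc) - 1],
                   gapless[3 * seq_len(nc)])
    stops <- which(trip[-nc] %in% code$stop_codons)
    for (s in stops) {
      add("premature_stop", 3L * s - 2L, 3L,
          sprintf("stop codon %s at codon %d of %d", trip[s], s, nc))
    }
  }
  ra <- rle(gapless)
  endsA <- cumsum(ra$lengths); startsA <- endsA - ra$lengths + 1L
  for (k in which(ra$values == "A" & ra$lengths > polyA_threshold)) {
    add("polyA", startsA[k], ra$lengths[k],
        sprintf("poly(A) tract of %d bp (> %d bp)", ra$lengths[k],
                polyA_threshold))
  }
  if (length(rows) == 0L) {
    return(data.frame(feature = character(), position = integer(),
                      length = integer(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
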