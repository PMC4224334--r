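#' MaxChi intragenic recombination scan
#'
#' Sliding-window breakpoint detection in the style of maximum chi-square
#' (MaxChi): for each sequence pair, alignment sites that are variable are
#' scanned with a two-half window of `window` variable sites on each side of
#' a candidate midpoint; the 2x2 chi-square contrasts the number of pairwise
#' differences left vs right of the midpoint, and the per-pair maximum over
#' midpoints locates the candidate breakpoint.
#'
#' Significance of a per-pair maximum is assessed by a seeded permutation
#' test (site order is permuted `n_perm` times and the maximum recomputed;
#' default), which calibrates the maximum statistic exactly, with a
#' Bonferroni correction across pairs; `correction = "bonferroni"` instead
#' Bonferroni-corrects the plain chi-square p over all midpoints and pairs
#' (very conservative), and `"none"` reports raw per-pair maxima. Under a
#' recombination-free alignment the family-wise false-positive rate is at
#' most `alpha`.
#'
#' @param aln A [codon_alignment()] with at least 3 strains.
#' @param window Number of variable sites per half-window (>= 10; default 80).
#' @param alpha Family-wise significance level (default 0.05).
#' @param correction `"permutation"` (default), `"bonferroni"`, or `"none"`.
#' @param n_perm Permutations for the default calibration (default 999).
#' @param seed Seed for the permutation test.
#' @return Data frame with one row per detected breakpoint: `strain1`,
#'   `strain2`, `breakpoint_np`, `np_start`, `np_end` (the window span at the
#'   maximum), `chi2`, `p`, `p_adj`. Empty (with a warning) when there are
#'   too few variable sites.
#' @export
maxchi_scan <- function(aln, window = 80L, alpha = 0.05,
                        correction = c("permutation", "bonferroni", "none"),
                        n_perm = 999L, seed = 1L) {
  correction <- match.arg(correction)
  if (length(aln$strains) < 3L) stop("need at least 3 strains")
  if (window < 10L) stop("window must cover at least 10 variable sites")
  empty <- data.frame(strain1 = character(), strain2 = character(),
                      breakpoint_np = integer(), np_start = integer(),
                      np_end = integer(), chi2 = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE)
  mat <- aln$seq
  good <- matrix(mat %in% c("A", "C", "G", "T"), nrow(mat), ncol(mat))
  nvar_states <- apply(mat, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")]))
  })
  var_sites <- which(nvar_states >= 2L)
  if (length(var_sites) < 2L * window + 1L) {
    warning("too few variable sites for a MaxChi scan (",
            length(var_sites), ")", call. = FALSE)
    return(empty)
  }
  strains <- aln$strains
  n <- length(strains)
  pairs <- utils::combn(n, 2)
  n_mid_total <- 0L
  scan_results <- vector("list", ncol(pairs))
  # windowed max chi-square over midpoints for a 0/1 difference vector
  max_scan <- function(diffs) {
    csum <- c(0L, cumsum(diffs))
    nm <- length(diffs) - 2L * window + 1L
    mids <- seq_len(nm) + window - 1L
    a <- csum[mids + 1L] - csum[mids + 1L - window]
    cc <- csum[mids + 1L + window] - csum[mids + 1L]
    b <- window - a; dd <- window - cc
    num <- 2 * window * (a * dd - b * cc)^2
    den <- (a + b) * (cc + dd) * (a + cc) * (b + dd)
    chi <- ifelse(den == 0, 0, num / den)
    k <- which.max(chi)
    list(chi = chi[k], mid = mids[k], n_mid = nm)
  }
  for (pp in seq_len(ncol(pairs))) {
    i <- pairs[1, pp]; j <- pairs[2, pp]
    ok <- good[i, var_sites] & good[j, var_sites]
    vs <- var_sites[ok]
    if (length(vs) < 2L * window + 1L) next
    diffs <- as.integer(mat[i, vs] != mat[j, vs])
    sc <- max_scan(diffs)
    n_mid_total <- n_mid_total + sc$n_mid
    scan_results[[pp]] <- list(i = i, j = j, vs = vs, diffs = diffs, sc = sc)
  }
  n_pairs_used <- sum(!vapply(scan_results, is.null, logical(1)))
  if (n_pairs_used == 0L) {
    warning("no strain pair has enough comparable variable sites", call. = FALSE)
    return(empty)
  }
  rows <- list()
  .with_seed(seed, {
    for (sr in scan_results) {
      if (is.null(sr)) next
      if (correction == "permutation") {
        exceed <- 0L
        for (b in seq_len(n_perm)) {
          pm <- max_scan(sr$diffs[sample.int(length(sr$diffs))])
          if (pm$chi >= sr$sc$chi) exceed <- exceed + 1L
        }
        p <- (1 + exceed) / (n_perm + 1)
        p_adj <- min(1, p * n_pairs_used)
      } else {
        p <- stats::pchisq(sr$sc$chi, df = 1, lower.tail = FALSE)
        p_adj <- if (correction == "bonferroni") {
          min(1, p * n_mid_total)
        } else p
      }
      if (p_adj < alpha) {
        vs <- sr$vs; mid <- sr$sc$mid
        bp <- as.integer(round((vs[mid] + vs[mid + 1L]) / 2))
        rows[[length(rows) + 1L]] <- data.frame(
          strain1 = strains[sr$i], strain2 = strains[sr$j],
          breakpoint_np = bp,
          np_start = vs[mid - window + 1L], np_end = vs[mid + window],
          chi2 = sr$sc$chi, p = p, p_adj = p_adj, stringsAsFactors = FALSE)
      }
    }
  })
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$p_adj), , drop = FALSE]
}

#' Consensus filter over recombination detectors
#'
#' Accepts candidate recombination regions supported by at least
#' `min_detectors` of the supplied detector result sets (interval
#' intersection over np coordinates). With fewer detector sets than
#' `min_detectors` the threshold is clamped with a warning (the full
#' multi-detector consensus rule is expressible when users add detectors).
#'
#' @param detections List of data frames, one per detector, each with columns
#'   `np_start`, `np_end` and optionally `strains` (`;`-separated, `NA` =
#'   all strains) and `gene`.
#' @param min_detectors Minimum number of supporting detectors.
#' @return Mask table (see [mask_region()]) with `reason = "recombination"`;
#'   strain scope is the union of the involved strains of the supporting
#'   detections (all strains if any detection is unscoped).
#' @export
consensus_recombination_filter <- function(detections, min_detectors = 4L) {
  if (length(detections) == 0L) stop("need at least one detector result set")
  if (min_detectors > length(detections)) {
    warning("min_detectors clamped from ", min_detectors, " to ",
            length(detections), " (only ", length(detections),
            " detector(s) supplied; the 4-of-7 consensus rule needs more ",
            "detectors)", call. = FALSE)
    min_detectors <- length(detections)
  }
  nonempty <- Filter(function(d) !is.null(d) && nrow(d) > 0, detections)
  if (length(nonempty) == 0L) {
    return(mask_region("none", 1, 1)[0, ])
  }
  max_np <- max(vapply(nonempty, function(d) max(d$np_end), numeric(1)))
  support <- matrix(FALSE, length(detections), max_np)
  for (k in seq_along(detections)) {
    d <- detections[[k]]
    if (is.null(d) || nrow(d) == 0) next
    for (r in seq_len(nrow(d))) {
      support[k, d$np_start[r]:d$np_end[r]] <- TRUE
    }
  }
  cov <- colSums(support)
  inside <- cov >= min_detectors
  if (!any(inside)) return(mask_region("none", 1, 1)[0, ])
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values)) {
    s <- starts[r]; e <- ends[r]
    strains <- character(0); all_strains <- FALSE; gene <- NA_character_
    for (d in nonempty) {
      hit <- d$np_start <= e & d$np_end >= s
      if (!any(hit)) next
      if (!is.null(d$gene)) gene <- d$gene[which(hit)[1]]
      if (is.null(d$strains)) { all_strains <- TRUE; next }
      ss <- as.character(d$strains[hit])
      if (any(is.na(ss))) all_strains <- TRUE
      ss <- ss[!is.na(ss)]
      if (length(ss)) {
        strains <- union(strains, unlist(strsplit(ss, "[;,]")))
      }
    }
    # a pairwise detector implicates both strains; keep the union as scope
    out[[length(out) + 1L]] <- mask_region(
      if (is.na(gene)) "gene1" else gene, s, e,
      strains = if (all_strains || length(strains) == 0) NA else strains,
      reason = "recombination")
  }
  do.call(rbind, out)
}
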