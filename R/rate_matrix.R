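#' Goldman-Yang style codon substitution rate matrix
#'
#' Builds the 61x61 instantaneous rate matrix Q of the codon model used for
#' all likelihood computations. Off-diagonal rates between sense codons i and
#' j are zero unless the codons differ at exactly one nucleotide position;
#' for single-nucleotide changes the rate is proportional to the target codon
#' frequency pi_j, multiplied by kappa for transitions and by omega (= Ka/Ks)
#' for nonsynonymous changes:
#'
#' \deqn{q_{ij} \propto \pi_j \cdot \kappa^{[transition]} \cdot \omega^{[nonsynonymous]}}
#'
#' Q is scaled so that the expected number of substitutions per codon per unit
#' time at equilibrium is 1 (branch lengths are then expected substitutions
#' per codon). The model is time-reversible: pi_i q_ij = pi_j q_ji.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Ka/Ks ratio (>= 0); 0 forbids nonsynonymous change.
#' @param pi Equilibrium frequencies over the 61 sense codons (sum 1).
#' @param code A [genetic_code()].
#' @return Object of class `codon_rate_matrix`: list with `Q` (scaled),
#'   `kappa`, `omega`, `pi`, `scale` (the pre-scaling mean rate) and `eigen`
#'   (spectral decomposition of the symmetrized generator, used to form
#'   transition probabilities).
#' @export
codon_rate_matrix <- function(kappa, omega, pi, code = genetic_code()) {
  if (length(pi) != length(code$sense_codons)) {
    stop("pi must have one entry per sense codon")
  }
  if (abs(sum(pi) - 1) > 1e-9) stop("frequencies not normalized")
  if (any(pi < 0)) stop("frequencies must be nonnegative")
  if (kappa <= 0) stop("kappa must be positive")
  if (omega < 0) stop("omega must be nonnegative")
  n <- length(pi)
  Q <- matrix(0, n, n, dimnames = list(code$sense_codons, code$sense_codons))
  pr <- code$pairs
  rate <- pi[pr$j] * ifelse(pr$transition, kappa, 1) *
    ifelse(pr$synonymous, 1, omega)
  Q[cbind(pr$i, pr$j)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero mean rate)")
  Q <- Q / scale
  structure(list(Q = Q, kappa = kappa, omega = omega, pi = pi, scale = scale,
                 eigen = .rev_eigen(Q, pi)),
            class = "codon_rate_matrix")
}

# spectral decomposition of a reversible generator via symmetrization:
# B = D^{1/2} Q D^{-1/2} is symmetric; P(t) = A exp(Lambda t) Ainv with
# A = D^{-1/2} V, Ainv = V' D^{1/2}
.rev_eigen <- function(Q, pi) {
  d <- sqrt(pmax(pi, 1e-300))
  B <- sweep(Q * d, 2L, d, "/")  # d_i q_ij / d_j
  B <- (B + t(B)) / 2            # enforce exact symmetry
  e <- eigen(B, symmetric = TRUE)
  list(A = e$vectors / d, Ainv = t(e$vectors) * rep(d, each = length(d)),
       lambda = e$values)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the cached spectral decomposition of the reversible
#' generator; falls back to scaling-and-squaring if the decomposition is
#' numerically unusable. Tiny negative entries from round-off are clamped to
#' zero and rows renormalized.
#'
#' @param Q A [codon_rate_matrix()].
#' @param t Branch length (>= 0), expected substitutions per codon.
#' @return 61x61 row-stochastic matrix.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("branch length must be nonnegative")
  e <- Q$eigen
  P <- e$A %*% (exp(e$lambda * t) * e$Ainv)
  if (!all(is.finite(P))) P <- .expm_ss(Q$Q * t)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q$Q)
  P
}

# scaling-and-squaring Taylor fallback; used only if eigen path degenerates
.expm_ss <- function(M) {
  k <- max(0L, ceiling(log2(max(1e-12, max(abs(M))))) + 4L)
  A <- M / 2^k
  P <- diag(nrow(M))
  term <- P
  for (i in 1:24) {
    term <- term %*% A / i
    P <- P + term
  }
  for (i in seq_len(k)) P <- P %*% P
  P
}

#' Equilibrium codon frequencies from an alignment
#'
#' `equal` gives 1/61 per sense codon. `F1x4` builds codon frequencies from
#' overall nucleotide frequencies, `F3x4` from position-specific nucleotide
#' frequencies (the common codeml defaults); in both, stop-codon target
#' frequencies are excluded and the remaining mass renormalized. Frequencies
#' that come out exactly zero (degenerate composition) are floored at a small
#' pseudo-frequency (1e-8 before renormalization) with a warning, so
#' downstream matrices stay irreducible.
#'
#' @param aln A [codon_alignment()].
#' @param method One of `"F3x4"`, `"F1x4"`, `"equal"`.
#' @param code A [genetic_code()].
#' @return Named numeric vector over the 61 sense codons, summing to 1.
#' @export
estimate_codon_frequencies <- function(aln, method = c("F3x4", "F1x4", "equal"),
                                       code = genetic_code()) {
  method <- match.arg(method)
  n61 <- length(code$sense_codons)
  if (method == "equal") {
    return(stats::setNames(rep(1 / n61, n61), code$sense_codons))
  }
  if (ncol(aln$seq) == 0 || length(aln$strains) == 0) stop("empty alignment")
  bases <- c("A", "C", "G", "T")
  nc <- n_codons(aln)
  pos_of <- rep(1:3, nc)
  f <- matrix(0, 3, 4, dimnames = list(NULL, bases))
  for (p in 1:3) {
    chars <- as.vector(aln$seq[, pos_of == p, drop = FALSE])
    cnt <- table(factor(chars, levels = bases))
    f[p, ] <- as.numeric(cnt)
  }
  if (method == "F1x4") {
    tot <- colSums(f)
    if (sum(tot) == 0) stop("empty alignment")
    f <- matrix(rep(tot / sum(tot), each = 3), 3, 4, dimnames = list(NULL, bases))
  } else {
    rs <- rowSums(f)
    if (any(rs == 0)) stop("empty alignment")
    f <- f / rs
  }
  mat <- do.call(rbind, strsplit(code$sense_codons, ""))
  pi <- f[1, mat[, 1]] * f[2, mat[, 2]] * f[3, mat[, 3]]
  if (any(pi == 0)) {
    warning("degenerate nucleotide composition: pseudo-frequency floor applied",
            call. = FALSE)
    pi[pi == 0] <- 1e-8
  }
  pi <- pi / sum(pi)
  stats::setNames(pi, code$sense_codons)
}
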