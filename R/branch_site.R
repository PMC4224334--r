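#' Branch-site positive-selection model (Model A) and its null
#'
#' Fits the standard branch-site mixture over four site classes on a tree
#' with one foreground branch set (an omega-class tag from [label_clades()]):
#'
#' * class 0 (proportion p0): omega0 in (0, 1] on all branches;
#' * class 1 (proportion p1): omega = 1 on all branches;
#' * class 2a (proportion `(1-p0-p1) p0/(p0+p1)`): omega0 on background,
#'   omega2 on foreground;
#' * class 2b (proportion `(1-p0-p1) p1/(p0+p1)`): 1 on background, omega2 on
#'   foreground.
#'
#' The alternative frees omega2 >= 1; the null fixes omega2 = 1. Their LRT
#' (one degree of freedom) tests for codons under positive selection on the
#' foreground lineage; a significant result on a gene otherwise flagged as
#' neutrally evolving indicates the elevated Ka/Ks was driven by positive
#' selection rather than relaxation.
#'
#' Branch lengths are taken from the tree as given (fix them from the
#' single-omega reference fit). Kappa is free.
#'
#' @param aln A [codon_alignment()].
#' @param tree Labeled tree with branch lengths.
#' @param foreground Class tag (integer or character) marking the foreground
#'   branch set.
#' @param variant `"alt"` (omega2 free, >= 1) or `"null"` (omega2 = 1).
#' @param pi Codon frequencies (default F3x4).
#' @param n_starts Seeded initial points (default 2).
#' @param init Optional warm start: named list with any of `kappa`, `p0`,
#'   `p1`, `omega0`, `omega2` (used as the first start; an alt fit seeded
#'   from its null's solution is guaranteed to reach at least the null lnL).
#' @param seed Seed for start jitter.
#' @param code A [genetic_code()].
#' @return A `fit_result` with extra elements `mixture` (proportions and
#'   omegas) and `variant`.
#' @export
fit_branch_site <- function(aln, tree, foreground, variant = c("alt", "null"),
                            pi = NULL, n_starts = 2L, init = NULL, seed = 1L,
                            code = genetic_code()) {
  variant <- match.arg(variant)
  if (is.null(pi)) pi <- estimate_codon_frequencies(aln, "F3x4", code)
  prep <- .lik_prep(aln, tree, code)
  fg <- as.character(foreground)
  tags <- as.character(sort(unique(prep$eclass)))
  if (!fg %in% tags) stop("foreground class ", fg, " not present on tree")
  bg <- setdiff(tags, fg)

  # per-site-class omega maps (bg omega, fg omega)
  class_maps <- function(w0, w2) {
    list(
      c0 = stats::setNames(rep(w0, length(tags)), tags),
      c1 = stats::setNames(rep(1, length(tags)), tags),
      c2a = stats::setNames(ifelse(tags == fg, w2, w0), tags),
      c2b = stats::setNames(ifelse(tags == fg, w2, 1), tags))
  }

  # all site classes share one synonymous clock: every class matrix is
  # calibrated against the neutral (omega = 1) generator, so branch lengths
  # mean expected substitutions per codon for a neutral site and a class with
  # elevated omega genuinely evolves faster (per-class mean-1 normalization
  # would cancel the signal)
  sconst <- .rate_scale_constants(pi, code)
  sl_cache <- new.env(parent = emptyenv())
  site_logliks <- function(kappa, w0, w2) {
    key <- sprintf("%.14g,%.14g,%.14g", kappa, w0, w2)
    hit <- sl_cache[[key]]
    if (!is.null(hit)) return(hit)
    maps <- class_maps(w0, w2)
    s1 <- .rate_scale(kappa, 1, sconst)
    out <- vapply(maps, function(om) {
      ce <- .class_eigens(kappa, om, pi, code)
      mult <- vapply(om, function(o) .rate_scale(kappa, o, sconst) / s1,
                     numeric(1))
      eff <- prep$lengths * unname(mult[as.character(prep$eclass)])
      cpp_loglik(prep$tipstate, prep$edge, prep$nnode, prep$root, eff,
                 .edge_eidx(prep$eclass, ce$eidx), ce$eigens, pi, prep$weights,
                 TRUE)$site_loglik
    }, numeric(length(prep$weights)))
    sl_cache[[key]] <- out
    out
  }

  # par = (log kappa, a, b, logit-ish w0 [, log(w2 - 1)])
  mixture_props <- function(a, b) {
    ea <- exp(a); eb <- exp(b)
    z <- ea + eb + 1
    p0 <- ea / z; p1 <- eb / z; p2 <- 1 / z
    c(p0 = p0, p1 = p1,
      p2a = p2 * p0 / (p0 + p1), p2b = p2 * p1 / (p0 + p1))
  }
  unpack <- function(par) {
    list(kappa = exp(par[1]), a = par[2], b = par[3],
         w0 = stats::plogis(par[4]),
         w2 = if (variant == "alt") 1 + exp(par[5]) else 1)
  }
  objective <- function(par) {
    u <- unpack(par)
    sl <- site_logliks(u$kappa, u$w0, u$w2)  # npat x 4
    p <- mixture_props(u$a, u$b)
    m <- apply(sl, 1L, max)
    mix <- log(exp(sl - m) %*% p) + m
    sum(prep$weights * mix)
  }
  npar <- if (variant == "alt") 5L else 4L
  lower <- c(log(.KAPPA_BOUNDS[1]), -8, -8, stats::qlogis(1e-4),
             if (variant == "alt") log(1e-9))
  upper <- c(log(.KAPPA_BOUNDS[2]), 8, 8, stats::qlogis(1 - 1e-9),
             if (variant == "alt") log(98))
  base <- c(log(2), log(0.7 / 0.1), log(0.2 / 0.1), stats::qlogis(0.2),
            if (variant == "alt") log(0.5))
  if (!is.null(init)) {
    p0 <- init$p0 %||% 0.7; p1 <- init$p1 %||% 0.2
    p2 <- max(1e-6, 1 - p0 - p1)
    base <- c(log(init$kappa %||% 2), log(p0 / p2), log(p1 / p2),
              stats::qlogis(min(1 - 1e-9, max(1e-4, init$omega0 %||% 0.2))),
              if (variant == "alt") log(max(1e-9, (init$omega2 %||% 1.5) - 1)))
    base <- pmin(pmax(base, lower), upper)
  }
  rng <- .seeded_rng(seed + 17L)
  starts <- list(base)
  if (variant == "alt") {
    # an exploratory start with elevated omega2: the null solution is a local
    # optimum with a flat omega2 direction, so a start at omega2 = 1 can trap
    # the search there
    explore <- c(base[1:3], stats::qlogis(0.3), log(4 - 1))
    starts[[2]] <- pmin(pmax(explore, lower), upper)
  }
  while (length(starts) < max(n_starts, length(starts))) {
    starts[[length(starts) + 1L]] <-
      pmin(pmax(base + rng$norm(npar) * 0.5, lower), upper)
  }
  best <- NULL
  for (s in starts) {
    res <- .optimize_params(objective, s, lower, upper)
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (variant == "alt") {
    # probe the omega2 -> 1 boundary: the alternative must never fall below
    # its null, and the boundary direction is numerically flat
    for (pb in list(best$par, starts[[1]])) {
      probe <- pb
      probe[5] <- log(1e-9)
      vp <- objective(probe)
      if (vp > best$value) best <- list(par = probe, value = vp,
                                        converged = best$converged)
    }
  }
  u <- unpack(best$par)
  props <- mixture_props(u$a, u$b)
  nm <- if (variant == "alt") "branch-site A" else "branch-site A null"
  sp <- model_spec(nm,
                   stats::setNames(rep("mix", length(tags)), tags),
                   nests = if (variant == "alt") "branch-site A null")
  structure(list(
    spec = sp, lnL = best$value, kappa_hat = u$kappa,
    omega_hat = c(omega0 = u$w0, omega1 = 1, omega2 = u$w2),
    mixture = list(proportions = props, omega0 = u$w0, omega2 = u$w2,
                   foreground = fg),
    variant = variant, tree = tree,
    n_free_params = npar, converged = isTRUE(best$converged),
    n_restarts_used = length(starts)),
    class = "fit_result")
}
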