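#' Declarative codon model specifications
#'
#' A `model_spec` names one codon model variant by saying, for every
#' branch-class tag of the labeled tree, whether its omega is free or fixed
#' and which free omegas are shared. Free entries are parameter labels
#' (equal labels share one parameter); numeric entries are fixed values.
#' Nesting between specs is declared explicitly (`nests`) so likelihood-ratio
#' degrees of freedom are computable and non-nested comparisons are refused.
#'
#' Convenience constructors build the cascade's standard specs for a tree
#' labeled with background class `0` and clade classes `1..k`:
#' * `spec_neutral()`: omega fixed to 1 on all branches.
#' * `spec_single_omega()`: one shared free omega on all branches.
#' * `spec_clade_omega()`: one free omega per clade; background/backbone
#'   branches share the first clade's omega (so the model has exactly k free
#'   omegas, mirroring a branch-model setup in which k-1 clades are marked
#'   foreground).
#' * `spec_forced_neutral(forced_class)`: the clade model with one clade's
#'   omega fixed to 1.
#'
#' @param name Model name.
#' @param omega Named vector over class tags (`"0"` = background); entries are
#'   parameter labels (character, free/shared) or numbers (fixed).
#' @param kappa `"free"` or a fixed numeric value.
#' @param nests Name of the null spec this spec nests (or NULL).
#' @param class_tags Character vector of class tags present on the tree.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, omega, kappa = "free", nests = NULL,
                       nested_in = NULL) {
  if (is.null(names(omega))) stop("omega entries must be named by class tag")
  ov <- suppressWarnings(as.numeric(omega))
  fixed <- !is.na(ov)
  if (any(fixed & ov < 0)) stop("fixed omega values must be >= 0")
  free_labels <- unique(as.character(omega[!fixed]))
  structure(list(name = name, omega = omega, fixed = fixed,
                 free_labels = free_labels, kappa = kappa, nests = nests,
                 nested_in = nested_in),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
spec_neutral <- function(class_tags = c("0", "1", "2", "3")) {
  model_spec("neutral", stats::setNames(rep(1, length(class_tags)), class_tags),
             nests = NULL)
}

#' @rdname model_spec
#' @export
spec_single_omega <- function(class_tags = c("0", "1", "2", "3")) {
  model_spec("1 Ka/Ks", stats::setNames(rep("w", length(class_tags)), class_tags),
             nests = "neutral")
}

#' @rdname model_spec
#' @export
spec_clade_omega <- function(class_tags = c("0", "1", "2", "3")) {
  clades <- setdiff(class_tags, "0")
  om <- stats::setNames(paste0("w", clades), clades)
  om <- c(stats::setNames(paste0("w", clades[1]), "0"), om)
  model_spec("3 Ka/Ks", om[class_tags], nests = "1 Ka/Ks")
}

#' @rdname model_spec
#' @param forced_class Clade class tag whose omega is fixed to 1.
#' @export
spec_forced_neutral <- function(forced_class, class_tags = c("0", "1", "2", "3")) {
  sp <- spec_clade_omega(class_tags)
  om <- sp$omega
  # force every class sharing the forced clade's parameter (the first clade
  # shares its omega with the background/backbone branches)
  shared <- names(om)[om == om[[as.character(forced_class)]]]
  om[shared] <- 1
  # this spec is the NULL of the step-3 LRT; the clade model nests it
  model_spec(paste0("neutral foreground (class ", forced_class, ")"), om,
             nested_in = "3 Ka/Ks")
}

# number of substantive free parameters (omegas + kappa; branch lengths are
# counted only when the fit optimizes them)
.n_free_params <- function(spec, n_branch = 0L) {
  length(spec$free_labels) + as.integer(identical(spec$kappa, "free")) + n_branch
}

# omega values per class tag given free-parameter values
.omega_by_class <- function(spec, free_values) {
  out <- numeric(length(spec$omega))
  names(out) <- names(spec$omega)
  out[spec$fixed] <- as.numeric(spec$omega[spec$fixed])
  if (any(!spec$fixed)) {
    out[!spec$fixed] <- free_values[as.character(spec$omega[!spec$fixed])]
  }
  out
}

.OMEGA_BOUNDS <- c(1e-4, 99)
.KAPPA_BOUNDS <- c(0.1, 99)

#' Fit a codon model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the spec's free parameters with
#' a bound-constrained quasi-Newton search in log space (coordinate-wise
#' golden/Brent fallback if it fails), from `n_starts` seeded initial points.
#' Branch lengths are either taken from the tree as-is (`"fixed"`, the
#' default for all cascade fits after the reference fit) or jointly optimized
#' by per-edge line searches alternated with the parameter search
#' (`"optimize"`).
#'
#' @param aln A [codon_alignment()].
#' @param tree Labeled tree (see [label_clades()]); must carry branch lengths
#'   unless `branch_lengths = "optimize"`.
#' @param spec A [model_spec()].
#' @param branch_lengths `"fixed"` or `"optimize"`.
#' @param pi Codon frequencies (default F3x4 from the alignment).
#' @param n_starts Number of seeded initial points (>= 1; default 3).
#' @param init Optional named list of warm-start values (`kappa`, and free
#'   omega labels); used as the first start.
#' @param seed Integer seed for start jitter.
#' @param code A [genetic_code()].
#' @return Object of class `fit_result`: `spec`, `lnL`, `kappa_hat`,
#'   `omega_hat` (per class tag), `free_omega` (per label), `tree` (with
#'   fitted lengths if optimized), `n_free_params`, `converged`,
#'   `n_restarts_used`.
#' @export
fit_model <- function(aln, tree, spec, branch_lengths = c("fixed", "optimize"),
                      pi = NULL, n_starts = 3L, init = NULL, seed = 1L,
                      code = genetic_code()) {
  branch_lengths <- match.arg(branch_lengths)
  if (is.null(pi)) pi <- estimate_codon_frequencies(aln, "F3x4", code)
  prep <- .lik_prep(aln, tree, code)
  tags_present <- as.character(sort(unique(prep$eclass)))
  if (!all(tags_present %in% names(spec$omega))) {
    stop("spec does not cover class tag(s): ",
         paste(setdiff(tags_present, names(spec$omega)), collapse = ", "))
  }
  if (is.null(prep$lengths) && branch_lengths == "fixed") {
    stop("tree has no branch lengths and branch_lengths = 'fixed'")
  }
  if (is.null(prep$lengths)) prep$lengths <- rep(0.1, nrow(prep$edge))

  kfree <- identical(spec$kappa, "free")
  labels <- spec$free_labels
  npar <- length(labels) + as.integer(kfree)

  lik_fun <- function(kappa, free_values, lengths) {
    om <- .omega_by_class(spec, free_values)
    ce <- .class_eigens(kappa, om, pi, code)
    cpp_loglik(prep$tipstate, prep$edge, prep$nnode, prep$root, lengths,
               .edge_eidx(prep$eclass, ce$eidx), ce$eigens, pi, prep$weights,
               FALSE)$loglik
  }
  unpack <- function(par) {
    kappa <- if (kfree) exp(par[1]) else spec$kappa
    fv <- stats::setNames(exp(par[(1 + kfree):npar])[seq_along(labels)], labels)
    if (length(labels) == 0) fv <- stats::setNames(numeric(0), character(0))
    list(kappa = kappa, free = fv)
  }
  lower <- c(if (kfree) log(.KAPPA_BOUNDS[1]),
             rep(log(.OMEGA_BOUNDS[1]), length(labels)))
  upper <- c(if (kfree) log(.KAPPA_BOUNDS[2]),
             rep(log(.OMEGA_BOUNDS[2]), length(labels)))

  # seeded starts
  rng <- .seeded_rng(seed)
  starts <- list()
  base <- c(if (kfree) log(2), rep(log(0.3), length(labels)))
  if (!is.null(init)) {
    v <- c(if (kfree) log(init$kappa %||% 2),
           log(vapply(labels, function(l) init[[l]] %||% 0.3, numeric(1))))
    starts[[1]] <- v
  } else starts[[1]] <- base
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1L]] <- base + rng$norm(npar) * 0.7
  }
  starts <- lapply(starts, function(s) pmin(pmax(s, lower), upper))

  lengths <- prep$lengths
  best <- NULL
  n_used <- 0L
  if (npar == 0L) {
    starts <- list(numeric(0))
  }
  for (s in starts) {
    if (npar == 0L) {
      best <- list(par = numeric(0), value = lik_fun(spec$kappa,
                   stats::setNames(numeric(0), character(0)), lengths),
                   converged = TRUE)
      n_used <- 1L
      break
    }
    n_used <- n_used + 1L
    res <- .optimize_params(function(par) {
      u <- unpack(par)
      lik_fun(u$kappa, u$free, lengths)
    }, s, lower, upper)
    if (is.null(best) || res$value > best$value) best <- res
  }
  if (branch_lengths == "optimize" && npar > 0) {
    for (round in 1:2) {
      u <- unpack(best$par)
      om <- .omega_by_class(spec, u$free)
      ce <- .class_eigens(u$kappa, om, pi, code)
      bl <- cpp_optimize_bl(prep$tipstate, prep$edge, prep$nnode, prep$root,
                            lengths, .edge_eidx(prep$eclass, ce$eidx),
                            ce$eigens, pi, prep$weights,
                            nsweeps = 4L, tol = 1e-6)
      lengths <- bl$lengths
      res <- .optimize_params(function(par) {
        u <- unpack(par)
        lik_fun(u$kappa, u$free, lengths)
      }, best$par, lower, upper)
      if (res$value >= best$value) best <- res else break
    }
  } else if (branch_lengths == "optimize") {
    u <- unpack(best$par)
    om <- .omega_by_class(spec, u$free)
    ce <- .class_eigens(u$kappa, om, pi, code)
    bl <- cpp_optimize_bl(prep$tipstate, prep$edge, prep$nnode, prep$root,
                          lengths, .edge_eidx(prep$eclass, ce$eidx),
                          ce$eigens, pi, prep$weights, nsweeps = 5L)
    lengths <- bl$lengths
    best <- list(par = starts[[1]], value = bl$loglik, converged = TRUE)
  }

  u <- unpack(best$par)
  omega_hat <- .omega_by_class(spec, u$free)
  fitted_tree <- tree
  if (branch_lengths == "optimize") {
    # map postorder lengths back to the tree's original edge order
    okey <- paste(tree$edge[, 1], tree$edge[, 2])
    nkey <- paste(prep$edge[, 1], prep$edge[, 2])
    fitted_tree$edge.length <- lengths[match(okey, nkey)]
  }
  at_bound <- any(abs(omega_hat[!spec$fixed] - .OMEGA_BOUNDS[2]) < 1e-6)
  if (at_bound) warning("omega estimate at upper bound", call. = FALSE)
  structure(list(
    spec = spec, lnL = best$value, kappa_hat = u$kappa,
    omega_hat = omega_hat, free_omega = u$free,
    tree = fitted_tree,
    n_free_params = .n_free_params(
      spec, if (branch_lengths == "optimize") nrow(prep$edge) else 0L),
    converged = isTRUE(best$converged), n_restarts_used = n_used),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result '%s': lnL = %.4f, kappa = %.3f\n",
              x$spec$name, x$lnL, x$kappa_hat))
  cat("  omega by class:",
      paste(sprintf("%s=%.4g", names(x$omega_hat), x$omega_hat),
            collapse = ", "), "\n")
  invisible(x)
}

# bound-constrained quasi-Newton with coordinate-wise golden-section fallback
.optimize_params <- function(fn, start, lower, upper) {
  neg <- function(p) {
    v <- fn(p)
    if (!is.finite(v)) 1e12 else -v
  }
  res <- tryCatch(
    stats::optim(start, neg, method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e6, maxit = 300)),
    error = function(e) NULL)
  coord_polish <- function(par, nsweep) {
    for (sweep in seq_len(nsweep)) {
      for (k in seq_along(par)) {
        o <- stats::optimize(function(x) {
          p <- par; p[k] <- x; neg(p)
        }, lower = lower[k], upper = upper[k], tol = 1e-7)
        if (o$objective < neg(par)) par[k] <- o$minimum
      }
    }
    par
  }
  if (is.null(res)) {
    par <- coord_polish(start, 4L)
    return(list(par = par, value = -neg(par), converged = TRUE))
  }
  if (res$convergence != 0) {
    # line-search hiccup: polish coordinate-wise and accept if at an optimum
    par <- coord_polish(res$par, 2L)
    v <- -neg(par)
    return(list(par = par, value = v,
                converged = v - (-res$value) < 1e-3))
  }
  list(par = res$par, value = -res$value, converged = res$convergence == 0)
}

# tiny deterministic normal generator independent of the global RNG state
.seeded_rng <- function(seed) {
  state <- as.numeric(seed) %% 2147483647
  if (state <= 0) state <- state + 2147483646
  nxt <- function() {
    state <<- (16807 * state) %% 2147483647  # Park-Miller
    state / 2147483647
  }
  list(norm = function(n) {
    u1 <- vapply(seq_len(n), function(i) nxt(), numeric(1))
    u2 <- vapply(seq_len(n), function(i) nxt(), numeric(1))
    sqrt(-2 * log(pmax(u1, 1e-12))) * cos(2 * pi * u2)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
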