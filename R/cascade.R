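#' Likelihood ratio test between nested codon model fits
#'
#' `stat = max(0, 2 (lnL_alt - lnL_null))` compared to a chi-square with
#' `df` = difference in free parameter counts. Negative 2-delta-lnL from
#' numerical noise is clamped to 0 with a warning. Refuses non-nested specs
#' (nesting must be declared on the specs) and unconverged fits.
#'
#' @param null_fit,alt_fit `fit_result` objects with declared nesting.
#' @param alpha Significance level recorded on the result (default 0.05).
#' @return Object of class `lrt_result`: `stat`, `df`, `p`, `alpha`,
#'   `null`, `alt` (model names).
#' @export
lrt <- function(null_fit, alt_fit, alpha = 0.05) {
  if (!isTRUE(null_fit$converged) || !isTRUE(alt_fit$converged)) {
    stop("cannot LRT on unconverged fit(s)")
  }
  nested <- (null_fit$spec$name %in% alt_fit$spec$nests) ||
    (alt_fit$spec$name %in% null_fit$spec$nested_in)
  if (!nested) {
    stop("specs are not declared nested: '", null_fit$spec$name, "' vs '",
         alt_fit$spec$name, "'")
  }
  df <- alt_fit$n_free_params - null_fit$n_free_params
  if (df <= 0) stop("alternative must have more free parameters than null")
  stat <- 2 * (alt_fit$lnL - null_fit$lnL)
  if (stat < 0) {
    if (stat < -1e-3) {
      warning(sprintf("alternative lnL below null by %.3g: optimizer artifact",
                      -stat / 2), call. = FALSE)
    }
    stat <- 0
  }
  structure(list(stat = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE),
                 alpha = alpha, null = null_fit$spec$name,
                 alt = alt_fit$spec$name),
            class = "lrt_result")
}

#' Best-fit model decision rule
#'
#' When the LRT p-value is significant at level `alpha` (strictly
#' `p < alpha`; a boundary p equal to alpha is read as not significant), the
#' higher-likelihood (alternative) model is the best fit; otherwise the
#' simpler (null) model is.
#'
#' @inheritParams lrt
#' @param alpha Significance level (default 0.05).
#' @return Name of the selected model.
#' @export
best_fit_decision <- function(null_fit, alt_fit, alpha = 0.05) {
  l <- lrt(null_fit, alt_fit, alpha)
  if (l$p < alpha) alt_fit$spec$name else null_fit$spec$name
}

# run the four-step comparison chain on one gene and one labeled tree;
# returns the per-tree decision record
.cascade_one_tree <- function(aln, labeled_tree, alpha, pi, seed, code) {
  tags <- as.character(sort(unique(c(0L, seq_along(labeled_tree$class_labels)))))
  out <- list(usable = TRUE, verdict = NA_character_, lrts = list(),
              omega = NULL, kappa = NA_real_, foreground = NA_character_)
  res <- tryCatch({
    ref <- fit_model(aln, labeled_tree, spec_single_omega(tags),
                     branch_lengths = "optimize", pi = pi, n_starts = 3L,
                     seed = seed, code = code)
    fixed_tree <- ref$tree
    single <- fit_model(aln, fixed_tree, spec_single_omega(tags),
                        branch_lengths = "fixed", pi = pi, n_starts = 1L,
                        init = c(list(kappa = ref$kappa_hat),
                                 as.list(ref$free_omega)),
                        seed = seed, code = code)
    neutral <- fit_model(aln, fixed_tree, spec_neutral(tags),
                         branch_lengths = "fixed", pi = pi, n_starts = 1L,
                         init = list(kappa = ref$kappa_hat),
                         seed = seed, code = code)
    out$lrts$step1 <- lrt(neutral, single, alpha)
    out$kappa <- single$kappa_hat
    if (best_fit_decision(neutral, single, alpha) == "neutral") {
      out$verdict <- "neutral"
      out$omega <- single$omega_hat
      return(out)
    }
    clade_init <- c(list(kappa = single$kappa_hat),
                    stats::setNames(as.list(rep(unname(single$free_omega["w"]),
                                                length(tags) - 1L)),
                                    paste0("w", setdiff(tags, "0"))))
    clade <- fit_model(aln, fixed_tree, spec_clade_omega(tags),
                       branch_lengths = "fixed", pi = pi, n_starts = 2L,
                       init = clade_init, seed = seed, code = code)
    out$lrts$step2 <- lrt(single, clade, alpha)
    if (best_fit_decision(single, clade, alpha) == "1 Ka/Ks") {
      out$verdict <- "1 Ka/Ks"
      out$omega <- single$omega_hat
      return(out)
    }
    out$omega <- clade$omega_hat
    out$kappa <- clade$kappa_hat
    clade_tags <- setdiff(tags, "0")
    om_clades <- clade$omega_hat[clade_tags]
    hi <- clade_tags[which.max(om_clades)]
    out$foreground <- hi
    forced_init <- c(list(kappa = clade$kappa_hat),
                     as.list(clade$free_omega[setdiff(names(clade$free_omega),
                                                      paste0("w", hi))]))
    forced <- fit_model(aln, fixed_tree, spec_forced_neutral(hi, tags),
                        branch_lengths = "fixed", pi = pi, n_starts = 2L,
                        init = forced_init, seed = seed, code = code)
    out$lrts$step3 <- lrt(forced, clade, alpha)
    if (out$lrts$step3$p < alpha) {
      out$verdict <- "3 Ka/Ks"
    } else {
      out$verdict <- "neutral foreground"
    }
    out$fixed_tree <- fixed_tree
    out
  }, error = function(e) {
    out$usable <- FALSE
    out$error <- conditionMessage(e)
    out
  })
  res
}

.VERDICT_RANK <- c("neutral" = 0L, "1 Ka/Ks" = 1L, "3 Ka/Ks" = 2L,
                   "neutral foreground" = 3L)

#' Run the four-step model-comparison cascade on one gene
#'
#' For each tree hypothesis: (1) neutral (omega = 1 everywhere) vs single
#' free omega; (2) if the single-omega model won, single omega vs one omega
#' per clade; (3) if the clade model won, the clade model vs the same model
#' with omega forced to 1 in the clade with the highest estimate -- failure
#' to reject the forced model is the neutralization signal ("neutral
#' foreground"); (4) for a gene whose consensus verdict is neutral
#' foreground, a branch-site positive-selection check (Model A alt vs null)
#' on the foreground clade, to exclude positive selection as the cause of
#' the elevated ratio.
#'
#' Branch lengths are optimized once per tree under the single-omega model
#' and held fixed for all other fits on that tree. The consensus across tree
#' hypotheses is conservative: a more complex verdict (heterogeneity, and a
#' fortiori neutralization) is accepted only when supported under all usable
#' trees; otherwise the simplest verdict among them stands. Per-tree
#' disagreement on which clade has the highest ratio is flagged, not
#' resolved.
#'
#' @param aln Single-gene [codon_alignment()].
#' @param trees List of trees (or a single tree), each covering the
#'   alignment's strains.
#' @param groups List of [strain_group()]s (clades + optional outgroup).
#' @param alpha Significance level (default 0.05, strict inequality).
#' @param branch_site Run the step-4 branch-site check when the consensus is
#'   neutral foreground (default TRUE; run once, on the first usable tree).
#' @param pi Codon frequencies (default F3x4 from `aln`).
#' @param seed Seed for optimizer starts.
#' @param code A [genetic_code()].
#' @return Object of class `cascade_report`: per-tree decisions, consensus
#'   verdict, foreground clade, p and omega ranges, branch-site result.
#' @export
run_cascade <- function(aln, trees, groups, alpha = 0.05, branch_site = TRUE,
                        pi = NULL, seed = 1L, code = genetic_code()) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) < 1L) stop("need at least one tree")
  if (is.null(pi)) pi <- estimate_codon_frequencies(aln, "F3x4", code)
  gene <- aln$partitions$gene[1]
  decisions <- vector("list", length(trees))
  tree_ids <- names(trees) %||% as.character(seq_along(trees))
  if (is.null(names(trees))) names(trees) <- tree_ids
  for (k in seq_along(trees)) {
    labeled <- label_clades(trees[[k]], groups)
    decisions[[k]] <- .cascade_one_tree(aln, labeled, alpha, pi,
                                        seed + k, code)
    decisions[[k]]$tree <- tree_ids[k]
  }
  usable <- vapply(decisions, function(d) isTRUE(d$usable), logical(1))
  if (!all(usable)) {
    warning(sum(!usable), " tree(s) unusable (unconverged or failed fits); ",
            "consensus computed on the rest", call. = FALSE)
  }
  if (!any(usable)) stop("no usable tree hypothesis for gene ", gene)
  verdicts <- vapply(decisions[usable], `[[`, character(1), "verdict")
  consensus <- names(.VERDICT_RANK)[min(.VERDICT_RANK[verdicts]) + 1L]
  fg <- NA_character_
  fg_disagreement <- FALSE
  if (consensus == "neutral foreground") {
    fgs <- vapply(decisions[usable], `[[`, character(1), "foreground")
    fg <- names(sort(table(fgs), decreasing = TRUE))[1]
    fg_disagreement <- length(unique(fgs)) > 1L
    if (fg_disagreement) {
      warning("trees disagree on the highest-Ka/Ks clade", call. = FALSE)
    }
  }
  # ranges
  p_range <- function(step) {
    ps <- unlist(lapply(decisions[usable], function(d)
      if (!is.null(d$lrts[[step]])) d$lrts[[step]]$p else NULL))
    if (length(ps)) range(ps) else c(NA_real_, NA_real_)
  }
  om_all <- do.call(rbind, lapply(decisions[usable], function(d) d$omega))
  omega_range <- if (!is.null(om_all)) {
    apply(om_all, 2L, range)
  } else NULL

  bs <- NULL
  if (branch_site && consensus == "neutral foreground") {
    first <- which(usable)[1]
    ft <- decisions[[first]]$fixed_tree
    if (!is.null(ft)) {
      bs_null <- fit_branch_site(aln, ft, fg, "null", pi = pi, seed = seed,
                                 code = code)
      # seed the alternative from the null solution: guarantees nesting
      bs_alt <- fit_branch_site(
        aln, ft, fg, "alt", pi = pi, seed = seed, code = code,
        init = list(kappa = bs_null$kappa_hat,
                    p0 = unname(bs_null$mixture$proportions["p0"]),
                    p1 = unname(bs_null$mixture$proportions["p1"]),
                    omega0 = bs_null$mixture$omega0, omega2 = 1 + 1e-4))
      bs <- list(alt = bs_alt, null = bs_null,
                 lrt = lrt(bs_null, bs_alt, alpha))
      if (bs$lrt$p < alpha) {
        warning("branch-site test significant: elevated Ka/Ks may reflect ",
                "positive selection, not relaxation", call. = FALSE)
      }
    }
  }
  structure(list(gene = gene, decisions = decisions, consensus = consensus,
                 foreground = fg, foreground_disagreement = fg_disagreement,
                 class_labels = label_clades(trees[[1]], groups)$class_labels,
                 p_range = list(step1 = p_range("step1"),
                                step2 = p_range("step2"),
                                step3 = p_range("step3")),
                 omega_range = omega_range, branch_site = bs,
                 alpha = alpha, n_usable = sum(usable)),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat(sprintf("cascade_report '%s': consensus best fit = %s (%d/%d trees usable)\n",
              x$gene, x$consensus, x$n_usable, length(x$decisions)))
  if (!is.na(x$foreground)) {
    cat(sprintf("  neutralized clade: class %s (%s)%s\n", x$foreground,
                x$class_labels[as.integer(x$foreground)],
                if (x$foreground_disagreement) " [trees disagree]" else ""))
  }
  if (!is.null(x$omega_range)) {
    cat("  Ka/Ks ranges:",
        paste(sprintf("%s: %.2g-%.2g", colnames(x$omega_range),
                      x$omega_range[1, ], x$omega_range[2, ]),
              collapse = "; "), "\n")
  }
  invisible(x)
}

#' Test each clade in turn for neutral evolution
#'
#' For a gene where the clade (3-Ka/Ks) model is selected, fits the clade
#' model with each clade's omega forced to 1 in turn and LRTs it against the
#' free clade model, per tree: the clades for which neutrality is rejected
#' localize the relaxation signal. Note the background/backbone branches
#' share the first clade's omega, so forcing that clade also forces the
#' backbone.
#'
#' @inheritParams run_cascade
#' @return Data frame with columns `clade` (class tag), `tree`, `p`,
#'   `reject` (neutral evolution rejected at `alpha`).
#' @export
neutrality_scan_other_clades <- function(aln, trees, groups, alpha = 0.05,
                                         pi = NULL, seed = 1L,
                                         code = genetic_code()) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (is.null(pi)) pi <- estimate_codon_frequencies(aln, "F3x4", code)
  tree_ids <- names(trees) %||% as.character(seq_along(trees))
  rows <- list()
  for (k in seq_along(trees)) {
    labeled <- label_clades(trees[[k]], groups)
    tags <- as.character(sort(unique(c(0L, seq_along(labeled$class_labels)))))
    ref <- fit_model(aln, labeled, spec_single_omega(tags),
                     branch_lengths = "optimize", pi = pi, seed = seed + k,
                     code = code)
    fixed_tree <- ref$tree
    clade <- fit_model(aln, fixed_tree, spec_clade_omega(tags),
                       branch_lengths = "fixed", pi = pi, n_starts = 2L,
                       init = c(list(kappa = ref$kappa_hat),
                                stats::setNames(
                                  as.list(rep(unname(ref$free_omega["w"]),
                                              length(tags) - 1L)),
                                  paste0("w", setdiff(tags, "0")))),
                       seed = seed + k, code = code)
    for (cl in setdiff(tags, "0")) {
      forced <- fit_model(aln, fixed_tree, spec_forced_neutral(cl, tags),
                          branch_lengths = "fixed", pi = pi, n_starts = 2L,
                          init = c(list(kappa = clade$kappa_hat),
                                   as.list(clade$free_omega[
                                     setdiff(names(clade$free_omega),
                                             paste0("w", cl))])),
                          seed = seed + k, code = code)
      l <- lrt(forced, clade, alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl, tree = tree_ids[k], p = l$p, reject = l$p < alpha,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Tabulate cascade reports in the style of a selection-analysis summary
#'
#' One row per gene: consensus best-fit model, p-value range of the decisive
#' LRT step, and Ka/Ks ranges per clade across tree hypotheses.
#'
#' @param reports List of `cascade_report` objects.
#' @return Data frame.
#' @export
cascade_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    decisive <- switch(r$consensus,
                       "neutral" = "step1", "1 Ka/Ks" = "step1",
                       "3 Ka/Ks" = "step2", "neutral foreground" = "step3")
    pr <- r$p_range[[decisive]]
    om <- r$omega_range
    om_txt <- if (!is.null(om)) {
      paste(vapply(colnames(om), function(cl) {
        lab <- if (cl == "0") "background" else
          r$class_labels[as.integer(cl)]
        sprintf("%s: %.3g-%.3g", lab, om[1, cl], om[2, cl])
      }, character(1)), collapse = "; ")
    } else NA_character_
    data.frame(gene = r$gene, best_fit = r$consensus,
               p_min = pr[1], p_max = pr[2], omega = om_txt,
               foreground = r$foreground, n_trees = length(r$decisions),
               n_usable = r$n_usable, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
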