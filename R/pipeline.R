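#' Pipeline configuration
#'
#' Validates and fills a pipeline configuration. Unknown keys are rejected;
#' defaults are the study's printed thresholds: deduplication at 0.2%
#' divergence, LRTs at the 5% level, 85% partial-deletion site filter,
#' poly(A) tracts flagged above 9 bp.
#'
#' @param alignments Named list of single-gene [codon_alignment()]s, or
#'   `genes_dir`, a directory of per-gene FASTA files (`<gene>.fasta`).
#' @param groups List of [strain_group()]s (clades + optional outgroup).
#' @param genes_dir See `alignments`.
#' @param trees Optional list of `ape::phylo` tree hypotheses; when absent,
#'   gene-jackknife NJ trees are built from the concatenated supermatrix.
#' @param masks Optional mask table ([mask_region()] rows).
#' @param splits Optional data frame `gene`, `stop_np` of premature-stop
#'   splits to apply.
#' @param dedup_threshold,alpha,partial_deletion,polyA_threshold,
#'   recomb_min_detectors,maxchi_window Thresholds.
#' @param run_recombination_scan Run the MaxChi scan (default TRUE).
#' @param branch_site Run the step-4 branch-site check (default TRUE).
#' @param seed Integer seed.
#' @param out_dir Output directory (created if needed); `NULL` = no files.
#' @return Validated config (class `pipeline_config`).
#' @export
pipeline_config <- function(alignments = NULL, groups = NULL, genes_dir = NULL,
                            trees = NULL, masks = NULL, splits = NULL,
                            dedup_threshold = 0.002, alpha = 0.05,
                            partial_deletion = 0.85, polyA_threshold = 9L,
                            recomb_min_detectors = 1L, maxchi_window = 80L,
                            run_recombination_scan = TRUE, branch_site = TRUE,
                            seed = 1L, out_dir = NULL) {
  if (is.null(alignments) && is.null(genes_dir)) {
    stop("config must provide alignments or genes_dir")
  }
  if (is.null(groups)) stop("config must provide strain groups")
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full relaxation-detection pipeline
#'
#' Sequences the whole workflow: alignment preparation (masking, premature
#' stop splitting, recombination scan + masking, strain deduplication),
#' supermatrix concatenation, gene-jackknife tree hypotheses, the per-gene
#' LRT cascade across all trees, and -- for genes with a neutral-foreground
#' consensus -- the clade-exclusive substitution scan with physicochemical
#' annotation and pseudogenization feature checks. All stages are
#' deterministic given the config and seed.
#'
#' @param config A [pipeline_config()].
#' @return List of artifacts: `supermatrix`, `dedup`, `recombination`,
#'   `trees`, `cascade` (named list of `cascade_report`), `cascade_table`,
#'   `substitutions`, `features`, `log`. Reports are written under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  alns <- config$alignments
  if (is.null(alns)) {
    files <- list.files(config$genes_dir, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    if (length(files) == 0L) {
      stop("no FASTA files found in ", config$genes_dir)
    }
    alns <- lapply(files, read_codon_alignment, check_stops = FALSE)
    names(alns) <- sub("\\.fa(sta)?$", "", basename(files))
  }
  for (g in names(alns)) alns[[g]]$partitions$gene <- g

  # 1. masks + splits
  if (!is.null(config$masks) && nrow(config$masks) > 0) {
    for (g in names(alns)) {
      reg <- config$masks[config$masks$gene == g, , drop = FALSE]
      if (nrow(reg)) alns[[g]] <- mask_regions(alns[[g]], reg)
    }
  }
  if (!is.null(config$splits) && nrow(config$splits) > 0) {
    for (r in seq_len(nrow(config$splits))) {
      g <- config$splits$gene[r]
      split_aln <- split_gene_at_stop(alns[[g]], g, config$splits$stop_np[r])
      parts <- split_aln$partitions$gene
      for (pg in parts) {
        sub <- extract_gene(split_aln, pg)
        alns[[pg]] <- sub
      }
      alns[[g]] <- NULL
    }
  }

  # 2. recombination scan per gene + masking
  recomb <- NULL
  if (isTRUE(config$run_recombination_scan)) {
    rec_rows <- list()
    for (g in names(alns)) {
      det <- tryCatch(
        maxchi_scan(alns[[g]], window = config$maxchi_window,
                    alpha = config$alpha),
        warning = function(w) NULL)
      if (is.null(det) || nrow(det) == 0L) next
      det$gene <- g
      det$strains <- paste(det$strain1, det$strain2, sep = ";")
      masks <- consensus_recombination_filter(list(det),
                                              config$recomb_min_detectors)
      if (nrow(masks)) {
        masks$gene <- g
        alns[[g]] <- mask_regions(alns[[g]], masks)
        rec_rows[[g]] <- cbind(det, data.frame(masked = TRUE))
      }
    }
    recomb <- if (length(rec_rows)) do.call(rbind, rec_rows) else NULL
  }

  # 3. concatenate + dedup
  supermatrix <- concat_alignments(alns)
  dd <- dedup_strains(supermatrix, config$dedup_threshold)
  supermatrix <- dd$alignment
  groups <- lapply(config$groups, function(g) {
    g$members <- intersect(g$members, supermatrix$strains)
    g
  })
  groups <- Filter(function(g) length(g$members) > 0, groups)
  alns <- lapply(alns, function(a)
    subset_alignment(a, strains = supermatrix$strains))

  # 4. tree hypotheses
  trees <- config$trees
  if (is.null(trees)) {
    trees <- jackknife_trees(supermatrix, site_filter = config$partial_deletion)
  }

  # 5. cascade per gene
  reports <- list()
  for (g in names(alns)) {
    reports[[g]] <- run_cascade(alns[[g]], trees, groups,
                                alpha = config$alpha,
                                branch_site = config$branch_site,
                                seed = config$seed)
  }
  tab <- cascade_table(reports)

  # 6. substitution scan + pseudogenization checks on neutralized genes
  subs <- list()
  feats <- list()
  og <- Filter(function(g) g$role == "outgroup", groups)
  out_strains <- if (length(og)) og[[1]]$members else character(0)
  for (g in names(reports)) {
    r <- reports[[g]]
    if (r$consensus != "neutral foreground") next
    fg_group <- groups[[which(vapply(groups, function(x)
      x$role != "outgroup", logical(1)))[as.integer(r$foreground)]]]
    bg <- setdiff(supermatrix$strains, c(fg_group$members, out_strains))
    rec <- clade_exclusive_substitutions(alns[[g]], fg_group$members, bg)
    if (nrow(rec)) rec <- classify_syn_nonsyn(rec, alns[[g]], bg)
    subs[[g]] <- rec
    for (s in fg_group$members) {
      f <- detect_inactivating_features(
        paste(alns[[g]]$seq[s, ], collapse = ""),
        polyA_threshold = config$polyA_threshold)
      if (nrow(f)) {
        f$gene <- g; f$strain <- s
        feats[[paste(g, s)]] <- f
      }
    }
  }
  substitutions <- if (length(subs)) do.call(rbind, subs) else NULL
  features <- if (length(feats)) do.call(rbind, feats) else NULL

  log <- list(seed = config$seed, alpha = config$alpha,
              dedup_threshold = config$dedup_threshold,
              n_genes = length(alns), n_trees = length(trees),
              n_strains = length(supermatrix$strains),
              removed_strains = dd$removed,
              package_version = as.character(utils::packageVersion("omegarelax")),
              timestamp = format(Sys.time(), tz = "UTC"))

  out <- list(supermatrix = supermatrix, dedup = dd, recombination = recomb,
              trees = trees, cascade = reports, cascade_table = tab,
              substitutions = substitutions, features = features, log = log)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_codon_alignment(supermatrix, file.path(od, "supermatrix.fasta"))
    .write_tsv(supermatrix$partitions, file.path(od, "partitions.tsv"))
    .write_tsv(data.frame(strain = dd$removed), file.path(od, "dedup_removed.tsv"))
    if (!is.null(recomb)) .write_tsv(recomb, file.path(od, "recombination.tsv"))
    .write_tsv(tab, file.path(od, "cascade.tsv"))
    jsonlite::write_json(
      lapply(reports, function(r) list(
        gene = r$gene, consensus = r$consensus, foreground = r$foreground,
        p_range = r$p_range,
        omega_range = if (!is.null(r$omega_range)) as.list(as.data.frame(r$omega_range)) else NULL,
        verdicts = lapply(r$decisions, function(d)
          list(tree = d$tree, usable = d$usable, verdict = d$verdict)))),
      file.path(od, "cascade.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    if (!is.null(substitutions)) {
      .write_tsv(substitutions, file.path(od, "substitutions.tsv"))
    }
    if (!is.null(features)) .write_tsv(features, file.path(od, "features.tsv"))
    writeLines(vapply(trees, write_newick, character(1)),
               file.path(od, "jackknife_trees.nwk"))
    jsonlite::write_json(log, file.path(od, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
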