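#' Example trinucleotide signatures
#'
#' Two synthetic mutational processes used by the simulator and the
#' worked examples: a CpG-deamination-like signature (C>T concentrated
#' at NpCpG contexts, the dominant in vivo process in normal somatic
#' lineages) and an oxidative-damage-like signature (C>A spread over all
#' contexts, the process that comes to dominate in culture). These are
#' synthetic stand-ins shaped like the corresponding processes, not
#' fitted reference signatures.
#'
#' @return 2 x 96 matrix, rows `deamination` and `transversion`, each
#'   summing to 1.
#' @export
example_signatures <- function() {
  labs <- channel_labels()
  deam <- numeric(96)
  cpg <- grepl("\\[C>T\\]G$", labs)          # NpCpG C>T
  other_ct <- grepl("\\[C>T\\]", labs) & !cpg
  deam[cpg] <- 0.80 / sum(cpg)
  deam[other_ct] <- 0.15 / sum(other_ct)
  tcn <- grepl("\\[T>C\\]", labs)
  deam[tcn] <- 0.05 / sum(tcn)
  tv <- numeric(96)
  ca <- grepl("\\[C>A\\]", labs)
  tv[ca] <- 0.85 / sum(ca)
  cg <- grepl("\\[C>G\\]", labs)
  tv[cg] <- 0.15 / sum(cg)
  out <- rbind(deamination = deam, transversion = tv)
  colnames(out) <- labs
  out
}

#' Default pipeline configuration
#'
#' All tunable parameters of the synthetic end-to-end analysis with the
#' defaults of the motivating experimental design: a monoclonal
#' expansion of ~24 binary divisions assayed with 1,500 template
#' molecules per site, three derived clone lines, ~40% of in vitro
#' candidate variants covered by deep sequencing.
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @return nested named list; see the fields themselves. Pass a modified
#'   copy to [run_pipeline()] -- unknown keys are rejected there.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    expansion = list(
      mu = 14,               # mutations per daughter cell per division
      generations = 24L,     # divisions of the monoclonal expansion
      n_molecules = 1500     # template molecules per amplicon assay
    ),
    assay = list(
      n_lines = 3L,          # derived clone lines deep-sequenced
      depth = 50000L,        # reads per site
      error_rate = 2e-4,     # post-consensus per-base error
      assay_fraction = 0.40, # share of candidate variants amplified
      n_null_sites = 50L     # truly absent sites tested alongside
    ),
    calling = list(alpha = 0.05, correct = FALSE, maf_threshold = 0.30),
    rate = list(genome_size = 6.6e9),
    lineage = list(
      generations = 3L,      # exact-tree depth for the genealogy stage
      mu = 12,               # mutations per daughter for the genealogy
      wgs_depth = 1000L      # simulated depth for MAF clustering
    ),
    spectra = list(
      k = 2L, restarts = 20L, n_mutations = 3000L,
      exposures = list(in_vivo = c(0.9, 0.1), in_vitro = c(0.35, 0.65))
    )
  )
}

check_config <- function(config, template = default_config()) {
  walk <- function(cfg, tmpl, path) {
    unknown <- setdiff(names(cfg), names(tmpl))
    if (length(unknown) > 0)
      stop("unknown config key(s): ",
           paste(paste0(path, unknown), collapse = ", "))
    missing_keys <- setdiff(names(tmpl), names(cfg))
    if (length(missing_keys) > 0)
      stop("missing config key(s): ",
           paste(paste0(path, missing_keys), collapse = ", "))
    for (k in names(tmpl))
      if (is.list(tmpl[[k]]) && !is.null(names(tmpl[[k]])))
        walk(cfg[[k]], tmpl[[k]], paste0(path, k, "$"))
  }
  walk(config, template, "")
  invisible(TRUE)
}

#' Run the full synthetic reconstruction pipeline
#'
#' Chains the stages in dependency order: simulate a clonal expansion
#' and its deep amplicon assay; call sub-clonal variants against the
#' matched control; convert detected counts into a per-cell
#' per-generation mutation rate; reconstruct the lineage tree and the
#' MAF sub-populations from an exactly simulated genealogy; draw
#' signature-mixture catalogs and re-extract the signatures by NNMF.
#' Every stage's outputs, a structured log and the effective
#' configuration (with an md5 hash for provenance) are written into
#' `out_dir`. Re-running with the same config is byte-identical.
#'
#' @param config configuration list ([default_config()]); unknown or
#'   missing keys are rejected before any stage runs.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results:
#'   `rate` (a `rate_estimate`), `calls` (per line), `tree`
#'   (a `clone_tree`), `clusters` (a `maf_clusters`), `signatures`
#'   (a `signature_set`), `out_dir`.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  check_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  seed <- config$seed
  exp_cfg <- config$expansion
  assay <- config$assay
  factor_f <- detection_factor(exp_cfg$n_molecules, exp_cfg$generations)

  ## stage 1+2: simulate each line's lineage truth and its deep assay,
  ## then call sub-clonal variants against the error-only control
  calls <- list(); counts <- integer(assay$n_lines)
  fractions <- numeric(assay$n_lines)
  for (l in seq_len(assay$n_lines)) {
    asy <- simulate_deep_assay(exp_cfg$mu, exp_cfg$generations,
                               n_molecules = exp_cfg$n_molecules,
                               depth = assay$depth,
                               error_rate = assay$error_rate,
                               assay_fraction = assay$assay_fraction,
                               n_null_sites = assay$n_null_sites,
                               seed = seed + 1000L * l)
    fractions[l] <- asy$realized_fraction
    cl <- call_subclonal(asy$sites, "sample", "control",
                         alpha = config$calling$alpha,
                         correct = config$calling$correct,
                         maf_threshold = config$calling$maf_threshold)
    calls[[l]] <- cl
    counts[l] <- sum(cl$detected)
    utils::write.table(cl, file.path(out_dir, sprintf("calls_line%d.tsv", l)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    note("line %d: %d truth variants, %d assayed, %d detected (m = %d)",
         l, nrow(asy$truth), asy$n_assayed, counts[l], attr(cl, "m"))
  }

  ## stage 3: mutation rate
  rate <- estimate_rate(counts, fractions, factor_f)
  rate_df <- data.frame(line = names(rate$per_line), detected = counts,
                        assay_fraction = fractions,
                        rate = unname(rate$per_line))
  utils::write.table(rate_df, file.path(out_dir, "rate_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(utils::capture.output(print(rate)),
               sprintf("per-nucleotide rate: %.3g per nucleotide per generation",
                       per_nucleotide_rate(rate$mean, config$rate$genome_size)),
               sprintf("assumed genome size: %.3g", config$rate$genome_size)),
             file.path(out_dir, "rate_report.txt"))
  note("rate: mean %.2f +- %.2f SNVs per cell per generation (factor %.4f)",
       rate$mean, rate$sd, factor_f)

  ## stage 4: lineage reconstruction from an exact genealogy
  lin <- config$lineage
  tree <- simulate_expansion(lin$mu, lin$generations, founder_mutations = 20,
                             seed = seed + 77L)
  leaves <- tree_leaves(tree)
  sampled <- leaves[c(1L, ceiling(length(leaves) / 2), length(leaves))]
  truth_tab <- truth_variants(tree)
  presence <- vapply(sampled, function(leaf) {
    anc <- c("", substring(leaf, 1, seq_len(nchar(leaf))))
    truth_tab$id %in% c(tree$founder_mutations,
                        unlist(tree$branch_mutations[anc]))
  }, logical(nrow(truth_tab)))
  rownames(presence) <- truth_tab$id
  colnames(presence) <- paste0("line_", sampled)
  presence <- presence[rowSums(presence) > 0, , drop = FALSE]
  ctree <- build_tree(presence)
  writeLines(ctree$newick, file.path(out_dir, "tree.newick"))
  utils::write.table(ctree$conflicts, file.path(out_dir, "tree_conflicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("lineage: %d variants on %d sampled lines, %d conflicts",
       nrow(presence), ncol(presence), nrow(ctree$conflicts))

  ## MAF sub-populations at bulk WGS depth
  keep <- truth_tab$origin <= 2L
  set.seed(seed + 78L)
  wgs_maf <- stats::rbinom(sum(keep), lin$wgs_depth,
                           truth_tab$molecule_fraction[keep]) / lin$wgs_depth
  clusters <- cluster_mafs(wgs_maf, rep(lin$wgs_depth, sum(keep)),
                           method = "em")
  utils::write.table(clusters$clusters, file.path(out_dir, "maf_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("MAF clustering: %d clusters at centers %s",
       nrow(clusters$clusters),
       paste(sprintf("%.3f", clusters$clusters$center), collapse = ", "))

  ## stage 5: spectra and signature extraction
  sp <- config$spectra
  sigs <- example_signatures()
  catalog <- rbind(
    in_vivo = simulate_catalog(sigs, sp$exposures$in_vivo, sp$n_mutations,
                               seed = seed + 101L),
    in_vitro = simulate_catalog(sigs, sp$exposures$in_vitro, sp$n_mutations,
                                seed = seed + 102L))
  write_catalog_tsv(catalog, file.path(out_dir, "catalog.tsv"))
  sigset <- nnmf_extract(catalog, k = sp$k, restarts = sp$restarts,
                         seed = seed + 103L)
  utils::write.table(
    data.frame(channel = channel_labels(), t(sigset$signatures),
               check.names = FALSE),
    file.path(out_dir, "signatures.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = rownames(sigset$exposure_proportions),
               sigset$exposure_proportions, check.names = FALSE),
    file.path(out_dir, "exposures.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("spectra: k = %d signatures, stability %s",
       sp$k, paste(sprintf("%.3f", sigset$stability), collapse = ", "))

  ## provenance
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  prov <- list(tool = "clonaltrace",
               version = as.character(utils::packageVersion("clonaltrace")),
               config_md5 = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(rate = rate, calls = calls, tree = ctree,
                 clusters = clusters, signatures = sigset,
                 out_dir = out_dir))
}
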