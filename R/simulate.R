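#' Simulate a binary clonal expansion with per-division mutation accrual
#'
#' Grows a pure binary genealogy from one founder cell for a fixed number
#' of divisions. Every daughter cell born at every division acquires
#' `Poisson(mu)` new heterozygous mutations, which are then inherited by
#' its whole descendant clade; no cell death or selection is simulated.
#' A mutation that arose at generation `n >= 1` is therefore carried by
#' exactly `2^(generations - n)` of the `2^generations` leaf cells, i.e.
#' at cell fraction `2^-n` and (being heterozygous in a diploid genome)
#' molecule fraction `2^-(n+1)`.
#'
#' The genealogy is materialized cell by cell, so the number of divisions
#' is capped (default 16, ~65k leaves). Deeper expansions -- the motivating
#' experiment ran ~24 divisions, 1.35e7 cells -- do not need an explicit
#' tree for site-level analyses; use [simulate_population_mutations()] or
#' [simulate_lineage_mutations()] instead, which draw the same per-
#' generation mutation counts and assign molecule fractions analytically.
#'
#' @param mu expected new mutations per daughter cell per division.
#' @param generations number of binary divisions (0 gives just the founder).
#' @param founder_mutations number of clonal mutations present in the
#'   founder (origin generation 0).
#' @param seed integer seed; all randomness in the simulation flows from it.
#' @param max_generations cap on the exact simulation.
#' @return an object of class `division_tree`: list with `generations`,
#'   `founder_mutations` (character ids), `branch_mutations` (named list,
#'   one entry per non-root node keyed by its binary path label, e.g.
#'   `"0"`, `"01"`), `mutation_origin` (named integer, id -> generation),
#'   `cell_count`.
#' @examples
#' tr <- simulate_expansion(mu = 2, generations = 4, founder_mutations = 3,
#'                          seed = 1)
#' tr$cell_count
#' table(tr$mutation_origin)
#' @export
simulate_expansion <- function(mu, generations, founder_mutations = 0,
                               seed = 1, max_generations = 16L) {
  if (!is.numeric(mu) || length(mu) != 1L || mu < 0)
    stop("mu must be a non-negative scalar")
  if (generations < 0) stop("generations must be non-negative")
  if (generations > max_generations)
    stop("generations exceeds the exact-simulation cap (", max_generations,
         "); use simulate_population_mutations() or ",
         "simulate_lineage_mutations() for deep expansions")
  set.seed(seed)
  founder <- if (founder_mutations > 0) {
    sprintf("m0_%d", seq_len(founder_mutations))
  } else character(0)
  origin <- stats::setNames(rep(0L, length(founder)), founder)
  branch <- list()
  if (generations >= 1) {
    for (n in seq_len(generations)) {
      daughters <- apply(expand.grid(rep(list(c("0", "1")), n))[, rev(seq_len(n)),
                                                                drop = FALSE],
                         1, paste0, collapse = "")
      counts <- stats::rpois(length(daughters), mu)
      for (i in seq_along(daughters)) {
        if (counts[i] > 0) {
          ids <- sprintf("m%d_%s_%d", n, daughters[i], seq_len(counts[i]))
          branch[[daughters[i]]] <- ids
          origin[ids] <- n
        } else {
          branch[[daughters[i]]] <- character(0)
        }
      }
    }
  }
  structure(list(generations = as.integer(generations),
                 founder_mutations = founder,
                 branch_mutations = branch,
                 mutation_origin = origin,
                 cell_count = 2L^as.integer(generations)),
            class = "division_tree")
}

#' @export
print.division_tree <- function(x, ...) {
  cat(sprintf("division_tree: %d generations, %d cells, %d founder + %d acquired mutations\n",
              x$generations, x$cell_count, length(x$founder_mutations),
              length(x$mutation_origin) - length(x$founder_mutations)))
  invisible(x)
}

#' Leaf carrier sets of a simulated genealogy
#'
#' @param tree a `division_tree`.
#' @param node a node label (binary path string, `""` = founder).
#' @return character vector of leaf labels descending from `node`.
#' @export
tree_leaves <- function(tree, node = "") {
  stopifnot(inherits(tree, "division_tree"))
  pad <- tree$generations - nchar(node)
  if (pad < 0) stop("node deeper than the tree")
  if (pad == 0) return(node)
  suff <- apply(expand.grid(rep(list(c("0", "1")), pad))[, rev(seq_len(pad)),
                                                         drop = FALSE],
                1, paste0, collapse = "")
  paste0(node, suff)
}

#' Truth table of simulated mutations
#'
#' Flattens a `division_tree` (or draws mutations directly, see the two
#' generator variants) into one row per mutation with its origin
#' generation, cell fraction `2^-n`, heterozygous molecule fraction
#' `2^-(n+1)`, and the expected number of mutant template molecules
#' `lambda = n_molecules * molecule_fraction` for a given assay input.
#'
#' @param tree a `division_tree` from [simulate_expansion()].
#' @param n_molecules template molecules per assay (default 1500).
#' @return data.frame with columns `id`, `origin`, `cell_fraction`,
#'   `molecule_fraction`, `lambda`.
#' @export
truth_variants <- function(tree, n_molecules = 1500) {
  stopifnot(inherits(tree, "division_tree"))
  org <- tree$mutation_origin
  truth_table(names(org), unname(org), n_molecules)
}

truth_table <- function(ids, origin, n_molecules) {
  cf <- 2^-origin
  mf <- cf / 2
  data.frame(id = ids, origin = as.integer(origin), cell_fraction = cf,
             molecule_fraction = mf, lambda = n_molecules * mf,
             stringsAsFactors = FALSE)
}

#' @rdname truth_variants
#' @details `simulate_population_mutations()` draws, for each division
#'   generation `n = 1..generations`, `Poisson(mu * 2^n)` new mutations
#'   (the `2^n` daughters born at that division each contribute
#'   `Poisson(mu)`), without materializing cells. This is the population-
#'   wide catalog: identical in distribution to flattening an exact tree.
#' @param mu expected new mutations per daughter per division.
#' @param generations number of divisions.
#' @param seed integer seed.
#' @export
simulate_population_mutations <- function(mu, generations, seed = 1,
                                          n_molecules = 1500) {
  if (mu < 0 || generations < 0) stop("mu and generations must be non-negative")
  set.seed(seed)
  if (generations == 0)
    return(truth_table(character(0), integer(0), n_molecules))
  counts <- stats::rpois(generations, mu * 2^(seq_len(generations)))
  origin <- rep.int(seq_len(generations), counts)
  ids <- sprintf("p%d_%d", origin, sequence(counts))
  truth_table(ids, origin, n_molecules)
}

#' @rdname truth_variants
#' @details `simulate_lineage_mutations()` instead follows the ancestry of
#'   one sampled cell (e.g. the founder of a derived clonal line): that
#'   single lineage acquires `Poisson(mu)` mutations at each of its
#'   `generations` divisions, each at population molecule fraction
#'   `2^-(n+1)`. This is the truth set a deep-sequencing assay of that
#'   line's variants interrogates.
#' @export
simulate_lineage_mutations <- function(mu, generations, seed = 1,
                                       n_molecules = 1500) {
  if (mu < 0 || generations < 0) stop("mu and generations must be non-negative")
  set.seed(seed)
  counts <- if (generations >= 1) stats::rpois(generations, mu) else integer(0)
  origin <- rep.int(seq_len(generations), counts)
  ids <- sprintf("l%d_%d", origin, sequence(counts))
  truth_table(ids, origin, n_molecules)
}

#' Simulate deep amplicon sequencing of one site
#'
#' Models the two-stage sampling of an amplicon assay. First the PCR input
#' samples template molecules: the number of mutant templates `k` is drawn
#' `Poisson(lambda)` with `lambda = n_molecules * molecule_fraction` --
#' the site is detectable at all only if `k > 0`. Then `depth` reads are
#' drawn from the templates proportionally (each read is mutant with
#' probability `k / n_molecules`), and sequencing errors are injected
#' independently per base, uniformly over the three non-truth bases.
#'
#' @param molecule_fraction fraction of template molecules carrying the
#'   variant (0 for a truly absent site, 1/2 for clonal heterozygous).
#' @param n_molecules template molecules in the PCR input.
#' @param depth number of reads.
#' @param error_rate per-base substitution error probability in [0, 1).
#' @param seed integer seed.
#' @return list with `ref_reads`, `alt_reads`, `other_reads` (errors to the
#'   two remaining bases), `k` (mutant templates sampled), `depth`.
#' @examples
#' simulate_amplicon(1/8, depth = 5000, error_rate = 2e-4, seed = 7)
#' @export
simulate_amplicon <- function(molecule_fraction, n_molecules = 1500,
                              depth = 10000, error_rate = 0, seed = 1) {
  if (n_molecules <= 0) stop("n_molecules must be positive")
  if (depth < 0) stop("depth must be non-negative")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (molecule_fraction < 0 || molecule_fraction > 0.5)
    stop("molecule_fraction must be in [0, 1/2]")
  lambda <- n_molecules * molecule_fraction
  if (!is.finite(lambda)) stop("lambda is not finite")
  set.seed(seed)
  k <- stats::rpois(1L, lambda)
  k <- min(k, n_molecules)
  true_alt <- stats::rbinom(1L, depth, k / n_molecules)
  true_ref <- depth - true_alt
  # errors: each base miscalled with prob error_rate, 1/3 to each other base
  ref_err <- stats::rbinom(1L, true_ref, error_rate)
  alt_err <- stats::rbinom(1L, true_alt, error_rate)
  ref_to_alt <- stats::rbinom(1L, ref_err, 1 / 3)
  alt_to_ref <- stats::rbinom(1L, alt_err, 1 / 3)
  alt_reads <- true_alt - alt_err + ref_to_alt
  ref_reads <- true_ref - ref_err + alt_to_ref
  list(ref_reads = ref_reads, alt_reads = alt_reads,
       other_reads = depth - ref_reads - alt_reads, k = k, depth = depth)
}

#' Simulate the deep amplicon assay of one clone line
#'
#' End-to-end generator for the rate-recovery experiment: draws the
#' mutations acquired along one sampled cell lineage
#' ([simulate_lineage_mutations()]), selects each independently with
#' probability `assay_fraction` for the amplicon panel, and simulates the
#' two-stage molecule/read sampling with sequencing error for every
#' assayed site ([simulate_amplicon()]) in both the clonal population and
#' an error-only matched control. Truly absent sites are tested alongside
#' as negative controls.
#'
#' @inheritParams simulate_lineage_mutations
#' @param depth reads per site.
#' @param error_rate per-base substitution error probability.
#' @param assay_fraction probability that a candidate variant is covered
#'   by the panel.
#' @param n_null_sites number of truly absent sites tested alongside.
#' @return list with `sites` (data.frame ready for [call_subclonal()]
#'   with columns `site`, `sample_ref`, `sample_alt`, `control_ref`,
#'   `control_alt`), `truth` (the lineage truth table), `n_assayed`,
#'   `realized_fraction` (assayed / total candidates).
#' @export
simulate_deep_assay <- function(mu, generations, n_molecules = 1500,
                                depth = 50000, error_rate = 2e-4,
                                assay_fraction = 0.40, n_null_sites = 50L,
                                seed = 1) {
  truth <- simulate_lineage_mutations(mu, generations, seed = seed,
                                      n_molecules = n_molecules)
  set.seed(seed + 1L)
  assayed <- truth[stats::runif(nrow(truth)) < assay_fraction, ,
                   drop = FALSE]
  mf <- c(assayed$molecule_fraction, rep(0, n_null_sites))
  ids <- c(assayed$id,
           if (n_null_sites > 0) sprintf("null_%d", seq_len(n_null_sites)))
  n <- length(mf)
  sr <- sa <- cr <- ca <- integer(n)
  for (i in seq_len(n)) {
    s <- simulate_amplicon(mf[i], n_molecules, depth, error_rate,
                           seed = seed + 2L * i)
    ctrl <- simulate_amplicon(0, n_molecules, depth, error_rate,
                              seed = seed + 2L * i + 1L)
    sr[i] <- s$ref_reads; sa[i] <- s$alt_reads
    cr[i] <- ctrl$ref_reads; ca[i] <- ctrl$alt_reads
  }
  list(sites = data.frame(site = ids, sample_ref = sr, sample_alt = sa,
                          control_ref = cr, control_alt = ca,
                          stringsAsFactors = FALSE),
       truth = truth, n_assayed = nrow(assayed),
       realized_fraction = if (nrow(truth) > 0) nrow(assayed) / nrow(truth)
                           else NA_real_)
}

#' Simulate overlapping read pairs from an amplicon template
#'
#' Generates `n_pairs` read pairs from a single template, the two reads
#' entering from opposite ends and overlapping by `overlap` bases in the
#' middle (the amplicon design guarantees the overlap). Each base of each
#' read is miscalled independently with probability `error_rate`, uniform
#' over the three other bases; quality scores are drawn from
#' `quality_profile`. Alignment offsets are 0-based template coordinates.
#'
#' @param template base string (A/C/G/T) for the amplicon.
#' @param overlap overlap length; read length is
#'   `(nchar(template) + overlap) / 2`, which must be an integer.
#' @param error_rate per-base substitution error probability.
#' @param n_pairs number of pairs.
#' @param quality_profile function(n) returning n integer Phred scores in
#'   [2, 41]; default constant Q30.
#' @param seed integer seed.
#' @param pair_prefix id prefix for the pairs.
#' @return list of `read_pair` objects, each a list with `id`, `seq1`,
#'   `qual1`, `offset1`, `seq2`, `qual2`, `offset2`, `truth` (the
#'   template).
#' @export
simulate_read_pairs <- function(template, overlap, error_rate = 0,
                                n_pairs = 1,
                                quality_profile = function(n) rep(30L, n),
                                seed = 1, pair_prefix = "pair",
                                amplicon = "amplicon") {
  bases <- c("A", "C", "G", "T")
  tchars <- strsplit(toupper(template), "")[[1]]
  tlen <- length(tchars)
  if (!all(tchars %in% bases)) stop("template must contain only A/C/G/T")
  if (overlap < 0) stop("overlap must be non-negative")
  rlen <- (tlen + overlap) / 2
  if (rlen != floor(rlen))
    stop("template length + overlap must be even")
  rlen <- as.integer(rlen)
  if (overlap > rlen) stop("overlap exceeds read length")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  set.seed(seed)
  off2 <- tlen - rlen
  sequence_read <- function(truth) {
    n <- length(truth)
    err <- stats::runif(n) < error_rate
    out <- truth
    if (any(err)) {
      out[err] <- vapply(truth[err],
                         function(b) sample(setdiff(bases, b), 1L), "")
    }
    out
  }
  lapply(seq_len(n_pairs), function(i) {
    r1 <- sequence_read(tchars[seq_len(rlen)])
    r2 <- sequence_read(tchars[(off2 + 1L):tlen])
    q1 <- pmin(41L, pmax(2L, as.integer(quality_profile(rlen))))
    q2 <- pmin(41L, pmax(2L, as.integer(quality_profile(rlen))))
    structure(list(id = sprintf("%s_%d", pair_prefix, i), amplicon = amplicon,
                   seq1 = paste0(r1, collapse = ""), qual1 = q1, offset1 = 0L,
                   seq2 = paste0(r2, collapse = ""), qual2 = q2,
                   offset2 = as.integer(off2),
                   truth = paste0(tchars, collapse = "")),
              class = "read_pair")
  })
}

#' Draw a mutation catalog from a mixture of trinucleotide signatures
#'
#' Each mutation's 96-channel class is drawn from the mixture
#' `sum_j exposures[j] * signatures[j, ]`; the catalog row is the
#' resulting multinomial count vector. Signatures are probability vectors
#' over the 96 channels in [channel_labels()] order.
#'
#' @param signatures matrix (k x 96), rows non-negative and summing to 1
#'   (renormalized if within 1e-6).
#' @param exposures length-k non-negative mixing weights summing to 1.
#' @param n_mutations number of mutations to draw.
#' @param seed integer seed.
#' @return named integer vector of 96 channel counts.
#' @export
simulate_catalog <- function(signatures, exposures, n_mutations, seed = 1) {
  signatures <- rbind(signatures)
  if (ncol(signatures) != 96L) stop("signatures must have 96 channels")
  if (any(signatures < 0)) stop("signatures must be non-negative")
  rs <- rowSums(signatures)
  if (any(abs(rs - 1) > 1e-6)) stop("signature rows must sum to 1")
  signatures <- signatures / rs
  if (length(exposures) != nrow(signatures))
    stop("one exposure weight per signature required")
  if (any(exposures < 0) || abs(sum(exposures) - 1) > 1e-6)
    stop("exposures must be non-negative and sum to 1")
  set.seed(seed)
  p <- as.numeric(exposures %*% signatures)
  counts <- as.integer(stats::rmultinom(1L, n_mutations, p))
  stats::setNames(counts, channel_labels())
}

#' Write a simulated truth table to TSV
#'
#' @param truth data.frame from [truth_variants()] or the generator
#'   variants.
#' @param path output path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write simulated read pairs as paired FASTQ (phred+33)
#'
#' @param pairs list of `read_pair` objects.
#' @param path1,path2 output paths for read 1 and read 2.
#' @export
write_pairs_fastq <- function(pairs, path1, path2) {
  enc <- function(q) paste(intToUtf8(q + 33L, multiple = TRUE), collapse = "")
  w <- function(path, which_seq, which_qual) {
    con <- file(path, "w")
    on.exit(close(con))
    for (p in pairs)
      writeLines(c(paste0("@", p$id), p[[which_seq]], "+",
                   enc(p[[which_qual]])), con)
  }
  w(path1, "seq1", "qual1")
  w(path2, "seq2", "qual2")
  invisible(c(path1, path2))
}
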