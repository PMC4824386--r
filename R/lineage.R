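#' Partition variants by their sharing pattern across clone lines
#'
#' Variants found in clonal lines derived from one monoclonal population
#' fall into three historical classes. Variants carried by *all* derived
#' lines and sitting at clonal MAF in the bulk population were present in
#' the founder cell, i.e. acquired in vivo. Variants shared by a proper
#' subset of lines (or by all lines but only at sub-clonal bulk MAF) arose
#' during the in vitro expansion before the lines diverged. Variants
#' private to a single line arose in that line's own history
#' (late expansion and/or derivation).
#'
#' @param presence logical matrix or data.frame, variants (rows, named) x
#'   clone lines (columns); every variant must be present somewhere.
#' @param bulk_maf optional numeric vector (one per variant) of MAFs
#'   measured in the bulk population; `NA` where not assayed.
#' @param clonal_band length-2 numeric: bulk-MAF interval regarded as
#'   clonal (default `c(0.4, 0.6)`, i.e. approximately 50%).
#' @return list with character vectors `in_vivo_clonal`, `culture_shared`,
#'   `private`, and a data.frame `classification` (`variant`, `n_lines`,
#'   `bulk_maf`, `class`).
#' @export
partition_variants <- function(presence, bulk_maf = NULL,
                               clonal_band = c(0.4, 0.6)) {
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  if (ncol(presence) < 2) stop("need at least two clone lines")
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("v", seq_len(nrow(presence)))
  n_lines <- rowSums(presence)
  if (any(n_lines == 0))
    stop("variant(s) absent from every line: ",
         paste(utils::head(rownames(presence)[n_lines == 0]), collapse = ", "))
  if (is.null(bulk_maf)) bulk_maf <- rep(NA_real_, nrow(presence))
  if (length(bulk_maf) != nrow(presence))
    stop("bulk_maf must have one value per variant")
  in_all <- n_lines == ncol(presence)
  clonal_bulk <- !is.na(bulk_maf) & bulk_maf >= clonal_band[1] &
    bulk_maf <= clonal_band[2]
  cls <- ifelse(in_all & clonal_bulk, "in_vivo_clonal",
                ifelse(n_lines == 1L, "private", "culture_shared"))
  out <- data.frame(variant = rownames(presence), n_lines = n_lines,
                    bulk_maf = bulk_maf, class = cls,
                    stringsAsFactors = FALSE, row.names = NULL)
  list(in_vivo_clonal = out$variant[cls == "in_vivo_clonal"],
       culture_shared = out$variant[cls == "culture_shared"],
       private = out$variant[cls == "private"],
       classification = out)
}

halving_center <- function(g) 2^-(g + 1)

generation_label <- function(center) {
  pmax(0L, as.integer(round(-log2(pmax(center, 1e-12)) - 1)))
}

#' Cluster mutant allele frequencies into division-generation groups
#'
#' In a binary clonal expansion, MAFs of heterozygous mutations
#' concentrate on the halving series 1/2 (clonal), 1/4 (fixed at the
#' first division), 1/8 (second division), ... Each variant's MAF is a
#' binomial proportion with its read depth as denominator.
#'
#' Two routes are provided. `method = "dp"` fits a Dirichlet-process
#' mixture of binomials (Beta(1,1) base measure, concentration
#' `concentration`) by collapsed Gibbs sampling and reports the
#' maximum-posterior partition over `sweeps` sweeps, so the summary is
#' deterministic under a fixed seed. `method = "em"` fits a finite
#' mixture whose component success probabilities are *fixed* at the
#' halving series and estimates only the mixing weights by EM -- a fully
#' deterministic fallback.
#'
#' @param maf mutant allele frequencies in [0, 1].
#' @param depth read depth per variant (binomial denominator, > 0).
#' @param method `"dp"` or `"em"`.
#' @param seed integer seed (Gibbs sampling).
#' @param sweeps number of Gibbs sweeps (>= 200 recommended).
#' @param concentration Dirichlet-process concentration parameter.
#' @param max_components number of halving-series components for the EM
#'   route.
#' @return object of class `maf_clusters`: list with `assignments`
#'   (integer cluster id per variant), `clusters` (data.frame: `cluster`,
#'   `n`, `center`, `generation` where 0 = clonal), `method`.
#' @examples
#' set.seed(1)
#' d <- rep(1000L, 90)
#' maf <- rbinom(90, d, rep(c(0.5, 0.25, 0.125), each = 30)) / d
#' cluster_mafs(maf, d, method = "em")$clusters
#' @export
cluster_mafs <- function(maf, depth, method = c("dp", "em"), seed = 1,
                         sweeps = 200, concentration = 1.0,
                         max_components = 6L) {
  method <- match.arg(method)
  if (length(maf) != length(depth)) stop("maf and depth lengths differ")
  if (length(maf) == 0) stop("no variants supplied")
  if (all(depth == 0)) stop("all depths are zero")
  if (any(depth <= 0)) stop("depths must be positive")
  if (any(maf < 0 | maf > 1)) stop("maf must be in [0, 1]")
  alt <- round(maf * depth)
  res <- if (method == "dp") {
    dp_binom_gibbs(alt, depth, seed, sweeps, concentration)
  } else {
    em_halving(alt, depth, max_components)
  }
  z <- res$assignments
  ids <- sort(unique(z))
  summ <- do.call(rbind, lapply(seq_along(ids), function(j) {
    m <- z == ids[j]
    center <- sum(alt[m]) / sum(depth[m])
    data.frame(cluster = j, n = sum(m), center = center,
               generation = generation_label(center))
  }))
  z <- match(z, ids)
  structure(list(assignments = z, clusters = summ, method = method),
            class = "maf_clusters")
}

# Collapsed Gibbs sampler for a DP mixture of binomials with Beta(a, b)
# base measure; returns the max-posterior partition visited.
dp_binom_gibbs <- function(alt, depth, seed, sweeps, concentration,
                           a = 1, b = 1) {
  set.seed(seed)
  n <- length(alt)
  z <- rep(1L, n)
  A <- c(sum(alt))           # per-cluster alt sums
  D <- c(sum(depth))         # per-cluster depth sums
  N <- c(n)                  # per-cluster sizes
  log_pred <- function(k, d, As, Ds) {
    # Beta-binomial predictive (binomial coefficient omitted: constant per i)
    lbeta(a + As + k, b + (Ds - As) + (d - k)) - lbeta(a + As, b + Ds - As)
  }
  log_joint <- function(z) {
    K <- 0; lj <- 0
    for (c in unique(z)) {
      m <- z == c
      lj <- lj + lgamma(sum(m)) +
        lbeta(a + sum(alt[m]), b + sum(depth[m]) - sum(alt[m])) - lbeta(a, b)
      K <- K + 1
    }
    lj + K * log(concentration)
  }
  best <- list(score = -Inf, z = z)
  for (s in seq_len(sweeps)) {
    for (i in seq_len(n)) {
      c_i <- z[i]
      A[c_i] <- A[c_i] - alt[i]; D[c_i] <- D[c_i] - depth[i]
      N[c_i] <- N[c_i] - 1L
      if (N[c_i] == 0L) {            # remove emptied cluster
        A <- A[-c_i]; D <- D[-c_i]; N <- N[-c_i]
        z[z > c_i] <- z[z > c_i] - 1L
      }
      lw <- c(log(N) + log_pred(alt[i], depth[i], A, D),
              log(concentration) + log_pred(alt[i], depth[i], 0, 0))
      w <- exp(lw - max(lw))
      pick <- sample.int(length(w), 1L, prob = w)
      if (pick > length(N)) {        # open a new cluster
        A <- c(A, alt[i]); D <- c(D, depth[i]); N <- c(N, 1L)
        z[i] <- length(N)
      } else {
        A[pick] <- A[pick] + alt[i]; D[pick] <- D[pick] + depth[i]
        N[pick] <- N[pick] + 1L
        z[i] <- pick
      }
    }
    sc <- log_joint(z)
    if (sc > best$score) best <- list(score = sc, z = z)
  }
  list(assignments = best$z, score = best$score)
}

# EM for a binomial mixture with success probabilities fixed at the
# halving series 2^-(g+1); only mixing weights are free.
em_halving <- function(alt, depth, max_components, max_iter = 500,
                       tol = 1e-10) {
  p <- halving_center(0:(max_components - 1L))
  w <- rep(1 / length(p), length(p))
  ll_mat <- sapply(p, function(pc) stats::dbinom(alt, depth, pc, log = TRUE))
  ll_mat <- rbind(ll_mat)  # n x K even for n = 1
  old <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- sweep(ll_mat, 2, log(w), "+")
    mx <- apply(lw, 1, max)
    post <- exp(lw - mx)
    post <- post / rowSums(post)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    w <- colMeans(post)
    if (abs(ll - old) < tol) break
    old <- ll
  }
  z <- max.col(post, ties.method = "first")
  list(assignments = z, weights = w)
}

set_key <- function(members) paste(sort(members), collapse = "|")

is_compatible <- function(set_a, set_b) {
  inter <- length(intersect(set_a, set_b))
  inter == 0L || inter == length(set_a) || inter == length(set_b)
}

#' Build a cellular lineage tree from variant sharing patterns
#'
#' Each variant's carrier set (the clone lines that carry it) marks one
#' branch of the cell genealogy: all variants whose carrier set equals a
#' clade were acquired by that clade's ancestral cell. Carrier sets of a
#' true genealogy form a nested (laminar) family; sets incompatible with
#' it (e.g. from detection errors) are conflicts. Conflicts are resolved
#' greedily for maximum compatibility -- carrier sets are admitted in
#' decreasing order of supporting variant count (ties broken toward
#' larger sets, then lexicographically) and a set is rejected if it
#' overlaps an admitted set without nesting. Rejected variants are
#' reported, never silently dropped.
#'
#' Edge counts are *minimum* mutation numbers: detection of sub-clonal
#' variants is incomplete, so a branch can only gain mutations as
#' sensitivity improves.
#'
#' @param presence logical matrix, variants (rows, named) x clone lines
#'   (columns, named).
#' @param conflict_threshold maximum tolerated fraction of conflicting
#'   variants before a structured error is raised.
#' @return object of class `clone_tree`: list with `line_ids`, `nodes`
#'   (list: `members`, `parent` key, `count`, `variants`), `conflicts`
#'   (data.frame `variant`, `carriers`), `newick` (edge counts as branch
#'   lengths), `n_variants`.
#' @export
build_tree <- function(presence, conflict_threshold = 0.5) {
  presence <- as.matrix(presence)
  mode(presence) <- "logical"
  lines <- colnames(presence)
  if (is.null(lines)) stop("presence matrix must have line names as columns")
  if (is.null(rownames(presence)))
    rownames(presence) <- paste0("v", seq_len(nrow(presence)))
  if (any(rowSums(presence) == 0))
    stop("variant(s) with empty carrier set")
  carrier <- apply(presence, 1, function(r) set_key(lines[r]))
  tab <- sort(table(carrier), decreasing = TRUE)
  keys <- names(tab)
  sizes <- lengths(strsplit(keys, "|", fixed = TRUE))
  ord <- order(-as.integer(tab), -sizes, keys)
  keys <- keys[ord]
  accepted <- list()
  rejected <- character(0)
  for (k in keys) {
    members <- strsplit(k, "|", fixed = TRUE)[[1]]
    ok <- all(vapply(accepted, function(s) is_compatible(members, s), TRUE))
    if (ok) accepted[[k]] <- members else rejected <- c(rejected, k)
  }
  conflict_variants <- rownames(presence)[carrier %in% rejected]
  if (length(conflict_variants) / nrow(presence) > conflict_threshold)
    stop("irreconcilable sharing patterns: ",
         length(conflict_variants), "/", nrow(presence),
         " variants conflict (patterns: ",
         paste(rejected, collapse = "; "), ")")
  # complete the laminar family with the root and all leaves
  for (k in c(set_key(lines), lines))
    if (is.null(accepted[[k]]))
      accepted[[k]] <- strsplit(k, "|", fixed = TRUE)[[1]]
  node_keys <- names(accepted)
  node_sizes <- lengths(accepted)
  parent_of <- function(k) {
    members <- accepted[[k]]
    sup <- node_keys[node_sizes > length(members) &
                       vapply(node_keys, function(o)
                         all(members %in% accepted[[o]]), TRUE)]
    if (length(sup) == 0) return(NA_character_)
    sup[which.min(node_sizes[match(sup, node_keys)])]
  }
  nodes <- lapply(node_keys, function(k) {
    vars <- rownames(presence)[carrier == k]
    list(members = accepted[[k]], parent = parent_of(k),
         count = length(vars), variants = vars)
  })
  names(nodes) <- node_keys
  tree <- structure(list(
    line_ids = lines, nodes = nodes,
    conflicts = data.frame(variant = conflict_variants,
                           carriers = carrier[conflict_variants],
                           stringsAsFactors = FALSE, row.names = NULL),
    n_variants = nrow(presence)), class = "clone_tree")
  tree$newick <- tree_newick(tree)
  tree
}

# newick with edge counts as branch lengths; root labelled "founder"
tree_newick <- function(tree) {
  root <- set_key(tree$line_ids)
  children_of <- function(k)
    names(Filter(function(n) identical(n$parent, k), tree$nodes))
  rec <- function(k) {
    kids <- children_of(k)
    node <- tree$nodes[[k]]
    label <- if (length(node$members) == 1L) node$members else ""
    inner <- if (length(kids) > 0)
      paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")")
    else ""
    paste0(inner, label, ":", node$count)
  }
  kids <- children_of(root)
  paste0("(", paste(vapply(kids, rec, ""), collapse = ","),
         ")founder:", tree$nodes[[root]]$count, ";")
}

#' @export
print.clone_tree <- function(x, ...) {
  cat(sprintf("clone_tree over %d lines, %d variants (%d conflicting)\n",
              length(x$line_ids), x$n_variants, nrow(x$conflicts)))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Convert a clone tree to an ape `phylo` object
#'
#' Branch lengths are the per-edge minimum mutation counts.
#'
#' @param tree a `clone_tree`.
#' @return an object of class `phylo`.
#' @export
clone_tree_phylo <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  ape::read.tree(text = tree$newick)
}

#' Internal clades of a clone tree
#'
#' @param tree a `clone_tree`.
#' @return list of character vectors: the member sets of all internal
#'   nodes other than the root (the clades the tree resolves).
#' @export
tree_clades <- function(tree) {
  stopifnot(inherits(tree, "clone_tree"))
  ms <- lapply(tree$nodes, `[[`, "members")
  ms <- ms[lengths(ms) > 1L & lengths(ms) < length(tree$line_ids)]
  unname(lapply(ms, sort))
}
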