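#' Trinucleotide channel labels
#'
#' The 96 single-base-substitution channels in fixed order: the six
#' pyrimidine-strand substitution classes C>A, C>G, C>T, T>A, T>C, T>G,
#' each crossed with the 16 combinations of 5' and 3' flanking bases in
#' alphabetical order, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ...
#'
#' @return character vector of length 96.
#' @export
channel_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    as.vector(t(outer(bases, bases, function(f, t)
      paste0(f, "[", s, "]", t))))))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, ""), function(ch)
    paste(rev(unname(COMPLEMENT[ch])), collapse = ""), "")
}

#' Classify a single-base substitution into its 96-channel class
#'
#' Labels follow the pyrimidine-strand convention: when the reference
#' base is a purine (A or G), the variant and its trinucleotide context
#' are reverse-complemented before labelling, so each substitution has a
#' unique class regardless of the strand it was reported on.
#'
#' @param contig,position 1-based locus of the variant.
#' @param ref,alt reference and alternate bases (single characters,
#'   different).
#' @param reference a named character vector of contig sequences or a
#'   `Biostrings::DNAStringSet` ([Biostrings::readDNAStringSet()]).
#' @return channel label such as `"A[C>T]G"`, or `NA_character_` (with a
#'   warning) when the context contains an ambiguous base or the variant
#'   sits at a contig edge.
#' @examples
#' ref <- c(chr1 = "TTACGTT")
#' classify_96("chr1", 4, "C", "T", ref)  # "A[C>T]G"
#' classify_96("chr1", 4, "G", "A", c(chr1 = "TTAGCTT"))  # revcomp branch
#' @export
classify_96 <- function(contig, position, ref, alt, reference) {
  if (inherits(reference, "DNAStringSet"))
    reference <- stats::setNames(as.character(reference), names(reference))
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1L || nchar(alt) != 1L || ref == alt)
    stop("ref and alt must be distinct single bases")
  if (!contig %in% names(reference))
    stop("contig not found in reference: ", contig)
  seqs <- reference[[contig]]
  seqs <- toupper(seqs)
  at <- substr(seqs, position, position)
  if (at != ref)
    stop(sprintf("reference mismatch at %s:%d: reference has %s, variant says %s",
                 contig, position, at, ref))
  if (position < 2L || position >= nchar(seqs)) {
    warning(sprintf("variant at %s:%d lacks trinucleotide context; skipped",
                    contig, position))
    return(NA_character_)
  }
  ctx <- substr(seqs, position - 1L, position + 1L)
  if (grepl("[^ACGT]", ctx)) {
    warning(sprintf("ambiguous base in context at %s:%d; skipped",
                    contig, position))
    return(NA_character_)
  }
  if (ref %in% c("A", "G")) {
    ctx <- revcomp(ctx)
    ref <- unname(COMPLEMENT[ref])
    alt <- unname(COMPLEMENT[alt])
  }
  lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  if (!lab %in% channel_labels()) stop("internal: bad channel label ", lab)
  lab
}

#' Build a 96-channel catalog from a variant table
#'
#' @param variants data.frame with columns `contig`, `position`, `ref`,
#'   `alt` and optionally `sample`.
#' @param reference as in [classify_96()].
#' @return samples x 96 integer matrix (one row named `"all"` when no
#'   `sample` column is given) with `channel_labels()` as columns;
#'   attribute `n_skipped` counts variants without usable context.
#' @export
catalog_96 <- function(variants, reference) {
  samples <- if ("sample" %in% names(variants)) variants$sample
             else rep("all", nrow(variants))
  labs <- channel_labels()
  ids <- unique(samples)
  mat <- matrix(0L, nrow = length(ids), ncol = 96L,
                dimnames = list(ids, labs))
  skipped <- 0L
  for (i in seq_len(nrow(variants))) {
    ch <- classify_96(variants$contig[i], variants$position[i],
                      variants$ref[i], variants$alt[i], reference)
    if (is.na(ch)) { skipped <- skipped + 1L; next }
    mat[samples[i], ch] <- mat[samples[i], ch] + 1L
  }
  attr(mat, "n_skipped") <- skipped
  mat
}

#' Normalized mutational spectrum and its 6-class collapse
#'
#' @param counts named 96-vector of channel counts, or a samples x 96
#'   matrix (each row is treated separately).
#' @return for a vector: list with `spectrum` (96 proportions summing to
#'   1), `collapsed` (6 substitution-class proportions), `n`. For a
#'   matrix: list of such lists, one per row. A row with zero mutations
#'   yields `n = 0` and `NULL` spectra (explicit empty status).
#' @export
spectrum <- function(counts) {
  if (is.matrix(counts))
    return(lapply(stats::setNames(seq_len(nrow(counts)), rownames(counts)),
                  function(i) spectrum(counts[i, ])))
  if (length(counts) != 96L) stop("expected 96 channel counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) return(list(spectrum = NULL, collapsed = NULL, n = 0L))
  sp <- counts / n
  cls <- sub("^.\\[(.>.)\\].$", "\\1", channel_labels())
  collapsed <- tapply(sp, cls, sum)[c("C>A", "C>G", "C>T",
                                      "T>A", "T>C", "T>G")]
  list(spectrum = stats::setNames(as.numeric(sp), channel_labels()),
       collapsed = stats::setNames(as.numeric(collapsed),
                                   c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")),
       n = as.integer(n))
}

kl_divergence <- function(V, WH) {
  keep <- V > 0
  sum(V[keep] * log(V[keep] / WH[keep])) - sum(V) + sum(WH)
}

nmf_once <- function(V, k, max_iter, tol, divergence) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  eps <- .Machine$double.eps
  obj <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    if (divergence == "kl") {
      WH <- W %*% H + eps
      H <- H * (t(W) %*% (V / WH)) / (colSums(W) + eps)
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H), n, k, byrow = TRUE)
      new_obj <- kl_divergence(V, W %*% H + eps)
    } else {
      H <- H * (t(W) %*% V) / (t(W) %*% W %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
      new_obj <- sum((V - W %*% H)^2)
    }
    trace <- c(trace, new_obj)
    if (is.finite(obj) && abs(obj - new_obj) < tol * max(1, obj)) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  list(W = W, H = H, objective = obj, trace = trace)
}

cosine_sim <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# match rows of H to rows of H_ref maximizing total cosine similarity;
# exhaustive over permutations (k is small in signature analysis)
match_signatures <- function(H, H_ref) {
  k <- nrow(H_ref)
  S <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) cosine_sim(H_ref[i, ], H[j, ])))
  if (k <= 7L) {
    perms <- permutations_of(k)
    scores <- apply(perms, 1, function(p) sum(S[cbind(seq_len(k), p)]))
    p <- perms[which.max(scores), ]
  } else {
    p <- integer(k)
    taken <- logical(k)
    for (i in order(-apply(S, 1, max))) {
      j <- which.max(ifelse(taken, -Inf, S[i, ]))
      p[i] <- j; taken[j] <- TRUE
    }
  }
  list(perm = p, sims = S[cbind(seq_len(k), p)])
}

permutations_of <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Extract mutational signatures by non-negative matrix factorization
#'
#' Factorizes a samples x 96 count catalog `V` into non-negative
#' exposures `W` (samples x k) and signatures `H` (k x 96) by
#' multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence (the natural choice for count data; squared Frobenius
#' error is available via `divergence = "frobenius"`). The objective is
#' non-increasing across iterations. The factorization is restarted
#' `restarts` times from random initializations; the best-objective run
#' is kept and each kept signature's stability is the mean cosine
#' similarity of its matched counterpart across all restarts (matching
#' by exhaustive assignment on cosine similarity). Signature rows are
#' normalized to sum to 1, with exposures rescaled to compensate.
#'
#' @param catalog samples x 96 non-negative matrix.
#' @param k number of signatures, `1 <= k <= min(samples, 96)`.
#' @param restarts random restarts (default 50).
#' @param max_iter,tol update iteration cap and relative-change
#'   convergence tolerance.
#' @param seed integer seed.
#' @param divergence `"kl"` or `"frobenius"`.
#' @return object of class `signature_set`: list with `signatures`
#'   (k x 96, rows sum to 1), `exposures` (samples x k),
#'   `exposure_proportions`, `objective`, `objective_trace` (best run),
#'   `stability` (length k), `divergence`, `k`.
#' @export
nnmf_extract <- function(catalog, k, restarts = 50, max_iter = 500,
                         tol = 1e-8, seed = 1,
                         divergence = c("kl", "frobenius")) {
  divergence <- match.arg(divergence)
  V <- rbind(catalog)
  if (any(V < 0)) stop("catalog must be non-negative")
  if (sum(V) == 0) stop("catalog is all zero")
  if (k < 1 || k > min(nrow(V), ncol(V)))
    stop("k must be between 1 and min(samples, channels)")
  set.seed(seed)
  runs <- lapply(seq_len(restarts), function(r)
    nmf_once(V, k, max_iter, tol, divergence))
  objs <- vapply(runs, `[[`, 0, "objective")
  best <- runs[[which.min(objs)]]
  # normalize signatures to probability vectors
  s <- rowSums(best$H)
  H <- best$H / s
  W <- sweep(best$W, 2, s, "*")
  stability <- rowMeans(matrix(vapply(runs, function(r) {
    Hr <- r$H / rowSums(r$H)
    match_signatures(Hr, H)$sims
  }, numeric(k)), nrow = k))
  props <- W / pmax(rowSums(W), .Machine$double.eps)
  rownames(H) <- paste0("signature", seq_len(k))
  colnames(H) <- channel_labels()
  colnames(W) <- colnames(props) <- rownames(H)
  rownames(W) <- rownames(props) <- rownames(V)
  structure(list(signatures = H, exposures = W,
                 exposure_proportions = props,
                 objective = best$objective,
                 objective_trace = best$trace,
                 stability = stability, divergence = divergence, k = k),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: k = %d (%s divergence), objective %.4g\n",
              x$k, x$divergence, x$objective))
  cat("  stability:", paste(sprintf("%.3f", x$stability), collapse = ", "),
      "\n")
  invisible(x)
}

#' Attribute a spectrum to fixed signatures
#'
#' Non-negative least-squares decomposition of an observed spectrum over
#' a fixed set of signatures, reported as exposure proportions.
#'
#' @param spec numeric 96-vector (counts or proportions).
#' @param signatures k x 96 matrix, rows summing to 1.
#' @return list with `exposures` (NNLS coefficients) and `proportions`
#'   (normalized to sum to 1; all zero for an all-zero spectrum).
#' @export
attribute <- function(spec, signatures) {
  signatures <- rbind(signatures)
  if (ncol(signatures) != 96L || length(spec) != 96L)
    stop("expected 96 channels")
  if (any(abs(rowSums(signatures) - 1) > 1e-6))
    stop("signature rows must sum to 1")
  if (nrow(signatures) > 1) {
    cs <- stats::cor(t(signatures))
    if (any(cs[upper.tri(cs)] > 1 - 1e-9))
      warning("duplicate (collinear) signatures: exposure split is not unique")
  }
  if (sum(spec) == 0)
    return(list(exposures = rep(0, nrow(signatures)),
                proportions = rep(0, nrow(signatures))))
  fit <- pracma::lsqnonneg(t(signatures), as.numeric(spec))
  e <- fit$x
  list(exposures = e,
       proportions = if (sum(e) > 0) e / sum(e) else e)
}
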