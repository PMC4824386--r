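#' Merge an overlapping read pair into a consensus read
#'
#' Error suppression for deep amplicon sequencing: within the region where
#' the two reads of a pair overlap, a base call is accepted only when both
#' reads report the same base and the sum of their Phred quality scores
#' exceeds `min_qual_sum` (strictly). Positions failing either condition
#' are masked with `N`, never replaced by a guess. A pair whose overlap
#' shows more than `max_mismatch` mismatches (as a fraction of the
#' double-called overlap positions, strictly greater) is discarded
#' entirely. Bases called `N` or with zero quality in either read are
#' masked and do not count as mismatches.
#'
#' By default only the doubly-read overlap enters the consensus; the
#' single-read flanks can be appended with `include_flanks = TRUE` for
#' coverage studies (they do not benefit from error suppression).
#'
#' @param pair a `read_pair` (see [simulate_read_pairs()]) or any list
#'   with `seq1`, `qual1`, `offset1`, `seq2`, `qual2`, `offset2` and
#'   optionally `id` and `amplicon`; offsets are 0-based coordinates of
#'   each read's first base on the amplicon reference.
#' @param min_qual_sum quality-sum threshold; accepted iff
#'   `q1 + q2 > min_qual_sum` (default 40, i.e. >= 41).
#' @param max_mismatch overlap mismatch fraction above which the pair is
#'   discarded (default 0.10).
#' @param include_flanks include non-overlap flanks as single-read calls.
#' @return an object of class `consensus_read`: list with `id`,
#'   `amplicon`, `offset` (0-based start of the consensus on the
#'   reference), `bases` (character vector, `"N"` where masked),
#'   `accepted` (logical vector), `status = "merged"` -- or a rejection:
#'   list with `id`, `status` one of `"rejected_mismatch"`,
#'   `"rejected_no_overlap"`, and `mismatch_fraction` where applicable.
#' @examples
#' p <- simulate_read_pairs("ACGTACGTACGTACGTACGT", overlap = 8, seed = 1)[[1]]
#' merge_pair(p)
#' @export
merge_pair <- function(pair, min_qual_sum = 40, max_mismatch = 0.10,
                       include_flanks = FALSE) {
  s1 <- strsplit(toupper(pair$seq1), "")[[1]]
  s2 <- strsplit(toupper(pair$seq2), "")[[1]]
  q1 <- as.integer(pair$qual1)
  q2 <- as.integer(pair$qual2)
  if (length(s1) != length(q1) || length(s2) != length(q2))
    stop("sequence and quality lengths differ")
  o1 <- as.integer(pair$offset1)
  o2 <- as.integer(pair$offset2)
  if (is.na(o1) || is.na(o2)) stop("alignment offsets required")
  id <- if (!is.null(pair$id)) pair$id else NA_character_
  amplicon <- if (!is.null(pair$amplicon)) pair$amplicon else "amplicon"
  # overlap in reference coordinates [lo, hi), 0-based half-open
  lo <- max(o1, o2)
  hi <- min(o1 + length(s1), o2 + length(s2))
  if (hi <= lo)
    return(structure(list(id = id, status = "rejected_no_overlap"),
                     class = "consensus_read"))
  i1 <- (lo - o1 + 1L):(hi - o1)
  i2 <- (lo - o2 + 1L):(hi - o2)
  b1 <- s1[i1]; b2 <- s2[i2]
  called <- b1 != "N" & b2 != "N" & q1[i1] > 0L & q2[i2] > 0L
  mism <- called & (b1 != b2)
  n_called <- sum(called)
  mismatch_fraction <- if (n_called > 0) sum(mism) / n_called else 0
  if (mismatch_fraction > max_mismatch)
    return(structure(list(id = id, status = "rejected_mismatch",
                          mismatch_fraction = mismatch_fraction),
                     class = "consensus_read"))
  accepted <- called & (b1 == b2) & (q1[i1] + q2[i2] > min_qual_sum)
  bases <- ifelse(accepted, b1, "N")
  offset <- lo
  if (include_flanks) {
    left <- if (o1 < lo) list(b = s1[seq_len(lo - o1)], o = o1)
            else if (o2 < lo) list(b = s2[seq_len(lo - o2)], o = o2)
            else NULL
    right <- if (o1 + length(s1) > hi) list(b = s1[(hi - o1 + 1L):length(s1)])
             else if (o2 + length(s2) > hi) list(b = s2[(hi - o2 + 1L):length(s2)])
             else NULL
    if (!is.null(left)) {
      bases <- c(left$b, bases)
      accepted <- c(left$b != "N", accepted)
      offset <- left$o
    }
    if (!is.null(right)) {
      bases <- c(bases, right$b)
      accepted <- c(accepted, right$b != "N")
    }
    bases[!accepted] <- "N"
  }
  structure(list(id = id, amplicon = amplicon, offset = offset,
                 bases = bases, accepted = accepted, status = "merged",
                 mismatch_fraction = mismatch_fraction),
            class = "consensus_read")
}

#' Merge many pairs and summarize the outcome
#'
#' @param pairs list of read pairs.
#' @param ... passed to [merge_pair()].
#' @return list with `reads` (merged `consensus_read`s) and `qc` (counts
#'   of merged / rejected pairs by reason).
#' @export
merge_pairs <- function(pairs, ...) {
  merged <- lapply(pairs, merge_pair, ...)
  status <- vapply(merged, function(x) x$status, "")
  list(reads = merged[status == "merged"],
       qc = list(n_pairs = length(pairs),
                 n_merged = sum(status == "merged"),
                 n_rejected_mismatch = sum(status == "rejected_mismatch"),
                 n_rejected_no_overlap = sum(status == "rejected_no_overlap")))
}

#' Count accepted bases per site
#'
#' Tallies A/C/G/T among accepted consensus bases at every covered
#' position of each amplicon; masked (`N`) positions contribute nothing.
#' Reads assigned to an amplicon not present in `references` are skipped
#' and reported in the QC attribute.
#'
#' @param reads list of merged `consensus_read`s (or the `reads` element
#'   of [merge_pairs()] output).
#' @param references named character vector of amplicon reference
#'   sequences.
#' @return data.frame of class `site_counts` with columns `amplicon`,
#'   `offset` (0-based), `ref`, `A`, `C`, `G`, `T`, `total`,
#'   `error_fraction` (non-reference / total). Attribute `qc` holds
#'   `n_skipped_unknown_amplicon`.
#' @export
count_bases <- function(reads, references) {
  if (is.null(names(references)) || any(names(references) == ""))
    stop("references must be a named character vector")
  tabs <- list()
  skipped <- 0L
  for (amp in names(references)) {
    rlen <- nchar(references[[amp]])
    tabs[[amp]] <- matrix(0L, nrow = rlen, ncol = 4L,
                          dimnames = list(NULL, c("A", "C", "G", "T")))
  }
  for (r in reads) {
    if (!identical(r$status, "merged")) next
    if (is.null(r$amplicon) || is.null(tabs[[r$amplicon]])) {
      skipped <- skipped + 1L
      next
    }
    pos <- r$offset + seq_along(r$bases)   # 1-based row index
    keep <- r$accepted & r$bases %in% c("A", "C", "G", "T") &
      pos >= 1L & pos <= nrow(tabs[[r$amplicon]])
    if (!any(keep)) next
    idx <- cbind(pos[keep], match(r$bases[keep], c("A", "C", "G", "T")))
    tabs[[r$amplicon]][idx] <- tabs[[r$amplicon]][idx] + 1L
  }
  out <- do.call(rbind, lapply(names(tabs), function(amp) {
    m <- tabs[[amp]]
    covered <- rowSums(m) > 0L
    if (!any(covered)) return(NULL)
    off <- which(covered) - 1L
    refb <- strsplit(toupper(references[[amp]]), "")[[1]][off + 1L]
    tot <- rowSums(m)[covered]
    refc <- m[cbind(which(covered), match(refb, c("A", "C", "G", "T")))]
    data.frame(amplicon = amp, offset = off, ref = refb,
               A = m[covered, "A"], C = m[covered, "C"],
               G = m[covered, "G"], T = m[covered, "T"],
               total = tot, error_fraction = (tot - refc) / tot,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (is.null(out))
    out <- data.frame(amplicon = character(0), offset = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), total = integer(0),
                      error_fraction = numeric(0))
  attr(out, "qc") <- list(n_skipped_unknown_amplicon = skipped)
  class(out) <- c("site_counts", class(out))
  out
}

#' Per-region error-rate summary
#'
#' Summarizes per-site non-reference fractions region by region as the
#' median with 5th/25th/75th/95th percentiles, after excluding known
#' variant positions so that only sequencing error contributes.
#'
#' @param site_counts a `site_counts` data.frame ([count_bases()]).
#' @param exclude_sites optional data.frame with columns `amplicon`,
#'   `offset` of known variant sites to drop.
#' @return data.frame with one row per amplicon: `n_sites`, `median`,
#'   `p5`, `p25`, `p75`, `p95`.
#' @export
error_rate_summary <- function(site_counts, exclude_sites = NULL) {
  sc <- site_counts
  if (!is.null(exclude_sites) && nrow(exclude_sites) > 0) {
    drop <- paste(sc$amplicon, sc$offset) %in%
      paste(exclude_sites$amplicon, exclude_sites$offset)
    sc <- sc[!drop, , drop = FALSE]
  }
  if (nrow(sc) == 0) stop("no covered sites after exclusion")
  out <- do.call(rbind, lapply(split(sc$error_fraction, sc$amplicon),
    function(e) {
      q <- stats::quantile(e, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
      data.frame(n_sites = length(e), median = q[3], p5 = q[1], p25 = q[2],
                 p75 = q[4], p95 = q[5])
    }))
  out <- cbind(amplicon = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Compare two error-rate distributions by rank-sum test
#'
#' Two-sided Mann-Whitney U test on per-site error fractions from two
#' conditions (e.g. single reads vs consensus reads); ties are handled by
#' midranks.
#'
#' @param rates_a,rates_b non-empty numeric vectors of per-site error
#'   fractions.
#' @return list with `U` (statistic for `rates_a` relative to `rates_b`),
#'   `p` (two-sided), `n_a`, `n_b`.
#' @export
compare_error_distributions <- function(rates_a, rates_b) {
  if (length(rates_a) == 0 || length(rates_b) == 0)
    stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(rates_a, rates_b,
                                            alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(rates_a), n_b = length(rates_b))
}
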