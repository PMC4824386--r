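#' Chi-square test of one site against the matched control
#'
#' Pearson chi-square on the 2x2 contingency table of reference vs mutant
#' read counts in the test population against its matched control genome
#' (e.g. monoclonal progenitor cells vs the donor's fibroblasts). No
#' continuity correction is applied by default. Tables with a zero margin
#' (e.g. no mutant read in either sample) carry no evidence either way and
#' are returned as degenerate with statistic 0 and p = 1 rather than
#' raising.
#'
#' @param sample_counts,control_counts length-2 numeric vectors
#'   `c(ref_count, alt_count)`.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p`, `degenerate` (logical),
#'   `sample_maf`, `control_maf`.
#' @examples
#' test_site(c(9990, 10), c(10000, 0))
#' @export
test_site <- function(sample_counts, control_counts, correct = FALSE) {
  if (length(sample_counts) != 2L || length(control_counts) != 2L)
    stop("counts must be length-2 (ref, alt) vectors")
  if (any(c(sample_counts, control_counts) < 0))
    stop("counts must be non-negative")
  if (sum(sample_counts) == 0 || sum(control_counts) == 0)
    stop("each sample needs at least one read")
  tab <- rbind(sample_counts, control_counts)
  maf <- tab[, 2] / rowSums(tab)
  if (any(colSums(tab) == 0)) {
    return(list(statistic = 0, p = 1, degenerate = TRUE,
                sample_maf = maf[1], control_maf = maf[2]))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value, degenerate = FALSE,
       sample_maf = unname(maf[1]), control_maf = unname(maf[2]))
}

#' Bonferroni correction
#'
#' Family-wise multiple-testing control: each p-value is multiplied by the
#' number of tests and capped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param alpha family-wise significance level.
#' @return list with `adjusted` (numeric) and `significant` (logical,
#'   `adjusted < alpha`); both empty for empty input.
#' @export
bonferroni <- function(p, alpha = 0.05) {
  if (length(p) == 0) return(list(adjusted = numeric(0),
                                  significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adjusted <- stats::p.adjust(p, method = "bonferroni")
  list(adjusted = adjusted, significant = !is.na(adjusted) & adjusted < alpha)
}

#' Classify a variant as clonal or sub-clonal by MAF
#'
#' In a clonally expanded diploid population, heterozygous mutations
#' carried by every cell sit near 50% mutant allele frequency; mutations
#' that arose after the founder's first divisions sit at or below 25%.
#' The conventional boundary is MAF < 30% for sub-clonal.
#'
#' @param maf mutant allele frequency; `NA` (zero depth) is unclassified.
#' @param threshold sub-clonal boundary (strict `<`), default 0.30.
#' @return character vector: `"clonal"`, `"subclonal"` or
#'   `"unclassified"`.
#' @examples
#' classify_clonality(c(0.5, 0.05, 0.30, NA))
#' @export
classify_clonality <- function(maf, threshold = 0.30) {
  if (any(maf < 0 | maf > 1, na.rm = TRUE)) stop("maf must be in [0, 1]")
  ifelse(is.na(maf), "unclassified",
         ifelse(maf < threshold, "subclonal", "clonal"))
}

#' Call sub-clonal variants against a matched control
#'
#' For each candidate site, tests the ref/alt read counts of the test
#' population against the matched control with [test_site()], applies the
#' Bonferroni correction over all sites tested in this invocation, and
#' calls a variant detected when the adjusted p-value is below `alpha`
#' *and* the test population's mutant fraction exceeds the control's
#' (one-sided semantics as a directional post-filter on the two-sided
#' test). Sites with zero depth in either sample are skipped and logged.
#'
#' @param sites data.frame with columns `site` (identifier) plus
#'   `<sample_id>_ref`, `<sample_id>_alt`, `<control_id>_ref`,
#'   `<control_id>_alt`.
#' @param sample_id,control_id column prefixes of the test and control
#'   samples.
#' @param alpha family-wise significance level.
#' @param correct Yates continuity correction for the site tests.
#' @param maf_threshold clonal/sub-clonal boundary for the reported class.
#' @return data.frame of class `subclonal_calls` with one row per tested
#'   site: `site`, `sample_maf`, `control_maf`, `statistic`, `p`,
#'   `p_adjusted`, `detected`, `clonality`, `degenerate`. Attributes:
#'   `m` (number of tests), `skipped` (data.frame of skipped sites with
#'   reasons), `alpha`, `correct`.
#' @export
call_subclonal <- function(sites, sample_id, control_id, alpha = 0.05,
                           correct = FALSE, maf_threshold = 0.30) {
  need <- c("site", paste0(sample_id, c("_ref", "_alt")),
            paste0(control_id, c("_ref", "_alt")))
  missing_cols <- setdiff(need, names(sites))
  if (length(missing_cols) > 0)
    stop("sites is missing columns: ", paste(missing_cols, collapse = ", "))
  sr <- sites[[paste0(sample_id, "_ref")]]
  sa <- sites[[paste0(sample_id, "_alt")]]
  cr <- sites[[paste0(control_id, "_ref")]]
  ca <- sites[[paste0(control_id, "_alt")]]
  depth_ok <- (sr + sa) > 0 & (cr + ca) > 0 &
    !is.na(sr + sa) & !is.na(cr + ca)
  skipped <- data.frame(site = sites$site[!depth_ok],
                        reason = rep("zero depth or missing counts",
                                     sum(!depth_ok)),
                        stringsAsFactors = FALSE)
  keep <- which(depth_ok)
  res <- lapply(keep, function(i)
    test_site(c(sr[i], sa[i]), c(cr[i], ca[i]), correct = correct))
  p <- vapply(res, `[[`, 0, "p")
  bf <- bonferroni(p, alpha)
  sample_maf <- vapply(res, `[[`, 0, "sample_maf")
  control_maf <- vapply(res, `[[`, 0, "control_maf")
  out <- data.frame(
    site = sites$site[keep],
    sample_maf = sample_maf,
    control_maf = control_maf,
    statistic = vapply(res, `[[`, 0, "statistic"),
    p = p,
    p_adjusted = bf$adjusted,
    detected = bf$significant & sample_maf > control_maf,
    clonality = classify_clonality(sample_maf, maf_threshold),
    degenerate = vapply(res, `[[`, TRUE, "degenerate"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "m") <- length(keep)
  attr(out, "skipped") <- skipped
  attr(out, "alpha") <- alpha
  attr(out, "correct") <- correct
  class(out) <- c("subclonal_calls", class(out))
  out
}
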