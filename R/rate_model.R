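#' Poisson molecule-sampling detection model
#'
#' A deep amplicon assay of a clonally expanded population starts from a
#' fixed number of template molecules `N` (5 ng of human genomic DNA is
#' roughly 750 diploid genomes, i.e. 1,500 molecules per locus). A
#' heterozygous mutation that arose at division generation `n` of a pure
#' binary expansion is carried by a fraction 2^-(n+1) of the molecules, so
#' the number of mutant templates sampled into the PCR is Poisson with mean
#' \deqn{\lambda_n = N / 2^{n+1}.}
#' The mutation is detectable iff at least one mutant molecule is sampled,
#' which happens with probability 1 - exp(-lambda_n). Summing that
#' detection probability over the division generations gives the expected
#' number of detectable sub-clonal mutations per unit per-generation
#' mutation rate: the *detection factor*.
#'
#' @param n_molecules number of template molecules per assay (default 1500).
#' @param generation division generation `n` at which the mutation arose
#'   (0 = present in the founder, i.e. clonal).
#' @return `molecule_lambda()` returns the Poisson mean lambda_n.
#' @examples
#' molecule_lambda(1500, 0)   # clonal heterozygous: half of all molecules
#' molecule_lambda(1500, 24)
#' @export
molecule_lambda <- function(n_molecules, generation) {
  stopifnot(is.numeric(n_molecules), is.numeric(generation))
  if (any(n_molecules <= 0)) stop("n_molecules must be positive")
  if (any(generation < 0)) stop("generation must be non-negative")
  n_molecules / 2^(generation + 1)
}

#' @rdname molecule_lambda
#' @param lambda non-negative Poisson mean (expected mutant molecules).
#' @return `detection_probability()` returns P(X > 0) = 1 - exp(-lambda).
#' @export
detection_probability <- function(lambda) {
  stopifnot(is.numeric(lambda))
  if (any(lambda < 0)) stop("lambda must be non-negative")
  -expm1(-lambda)
}

#' @rdname molecule_lambda
#' @param generations number of division generations of the expansion
#'   (default 24).
#' @param include_clonal if `TRUE`, add the clonal `n = 0` term to the sum.
#'   The default (`FALSE`) sums over the post-founder generations
#'   `n = 1..generations` only: clonal mutations are identified as the set
#'   shared by all derived lines and are counted separately, and only this
#'   form reproduces the factor 9.88 for `N = 1500`, `G = 24` (the
#'   `n = 0` term adds 1, giving 10.88).
#' @return `detection_factor()` returns the scalar factor `F`; the expected
#'   number of detectable sub-clonal mutations is `F * M`, where `M` is the
#'   per-cell per-generation mutation rate.
#' @examples
#' detection_factor(1500, 24)                       # 9.88
#' detection_factor(1500, 24, include_clonal = TRUE) # 10.88
#' @export
detection_factor <- function(n_molecules = 1500, generations = 24,
                             include_clonal = FALSE) {
  stopifnot(generations >= 1)
  from <- if (include_clonal) 0L else 1L
  sum(detection_probability(molecule_lambda(n_molecules, from:generations)))
}

#' Estimate the per-cell per-generation mutation rate
#'
#' Converts the counts of sub-clonal variants detected by deep sequencing
#' into a mutation rate. For each clone line the rate is
#' `count / (assay_fraction * factor)`: the detected count is scaled up by
#' the fraction of that line's candidate variants actually assayed, then
#' divided by the detection factor (expected detectable variants per unit
#' rate, see [detection_factor()]).
#'
#' @param counts integer vector, sub-clonal variants detected per line.
#' @param assay_fractions fraction of each line's candidate variants that
#'   was covered by the deep-sequencing assay, in (0, 1].
#' @param factor detection factor, e.g. from [detection_factor()].
#' @param line_ids optional names for the lines.
#' @return an object of class `rate_estimate`: a list with `per_line`
#'   (named numeric), `mean`, `sd` (sample SD across lines, `NA` for a
#'   single line) and the inputs.
#' @examples
#' estimate_rate(c(60, 51, 58), c(0.421, 0.438, 0.372),
#'               factor = detection_factor())
#' @export
estimate_rate <- function(counts, assay_fractions, factor,
                          line_ids = names(counts)) {
  stopifnot(length(counts) == length(assay_fractions), length(counts) >= 1)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(assay_fractions <= 0 | assay_fractions > 1))
    stop("assay_fractions must be in (0, 1]")
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("factor must be a positive scalar")
  per_line <- counts / (assay_fractions * factor)
  if (is.null(line_ids)) line_ids <- paste0("line", seq_along(counts))
  names(per_line) <- line_ids
  structure(list(
    per_line = per_line,
    mean = mean(per_line),
    sd = if (length(per_line) > 1L) stats::sd(per_line) else NA_real_,
    counts = counts, assay_fractions = assay_fractions, factor = factor
  ), class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Mutation rate estimate (SNVs per cell per generation)\n")
  cat(sprintf("  detection factor: %.4f\n", x$factor))
  for (i in seq_along(x$per_line))
    cat(sprintf("  %s: %d detected / assay fraction %.3f -> %.2f\n",
                names(x$per_line)[i], x$counts[i], x$assay_fractions[i],
                x$per_line[i]))
  cat(sprintf("  mean +- SD: %.1f +- %s\n", x$mean,
              if (is.na(x$sd)) "NA (single line)" else sprintf("%.1f", x$sd)))
  invisible(x)
}

#' @rdname estimate_rate
#' @param rate_per_cell per-cell per-generation SNV rate.
#' @param genome_size nucleotides per cell; defaults to a diploid human
#'   genome, 6.6e9.
#' @return `per_nucleotide_rate()` returns the rate per nucleotide per
#'   generation.
#' @export
per_nucleotide_rate <- function(rate_per_cell, genome_size = 6.6e9) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (any(rate_per_cell < 0)) stop("rate_per_cell must be non-negative")
  rate_per_cell / genome_size
}

#' @rdname estimate_rate
#' @param final_cells cell count at the end of a clonal expansion.
#' @return `divisions_from_cell_count()` returns `round(log2(final_cells))`,
#'   the number of binary divisions a single founder needs to reach that
#'   population size.
#' @examples
#' divisions_from_cell_count(13.5e6)  # 24
#' @export
divisions_from_cell_count <- function(final_cells) {
  if (any(final_cells < 1)) stop("final_cells must be >= 1")
  as.integer(round(log2(final_cells)))
}

#' Per-division mutation rate of sub-cloned lines
#'
#' For cell lines grown continuously for a known number of divisions and
#' then sub-cloned and sequenced, the rate is simply the SNV count divided
#' by the division count. Replicate sub-clones of one line are summarized
#' as mean +- sample SD.
#'
#' @param snv_counts SNVs accumulated by each replicate sub-clone.
#' @param divisions number of divisions of the expansion (default 60).
#' @return list with `per_replicate`, `mean`, `sd` (NA for one replicate),
#'   `divisions`.
#' @examples
#' subclone_division_rate(c(48, 60, 102), divisions = 60)
#' @export
subclone_division_rate <- function(snv_counts, divisions = 60) {
  if (divisions <= 0) stop("divisions must be positive")
  if (any(snv_counts < 0)) stop("snv_counts must be non-negative")
  per <- snv_counts / divisions
  list(per_replicate = per, mean = mean(per),
       sd = if (length(per) > 1L) stats::sd(per) else NA_real_,
       divisions = divisions)
}

#' In vitro variant count and assay fraction for one clone line
#'
#' Bookkeeping for the deep-sequencing design: variants found in a derived
#' clone line but shared by all lines are in vivo (pre-expansion); the
#' remainder arose in vitro. The assay fraction is the share of those in
#' vitro candidates covered by the amplicon panel.
#'
#' @param n_total total SNVs detected in the line.
#' @param n_shared SNVs shared by all lines (in vivo, clonal).
#' @param n_assayed in vitro SNVs covered by the deep-sequencing assay.
#' @return list with `in_vitro = n_total - n_shared` and
#'   `fraction = n_assayed / in_vitro`.
#' @examples
#' assay_fraction(933, 391, 228)  # 542 in vitro, fraction 0.421
#' @export
assay_fraction <- function(n_total, n_shared, n_assayed) {
  if (any(n_shared > n_total)) stop("n_shared cannot exceed n_total")
  in_vitro <- n_total - n_shared
  if (any(n_assayed > in_vitro)) stop("n_assayed cannot exceed in vitro count")
  list(in_vitro = in_vitro, fraction = n_assayed / in_vitro)
}
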