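#' Read per-sample allele counts
#'
#' Two input routes carry the same data model: one genomic site per
#' variant with reference and mutant read counts per sample.
#'
#' * `format = "tsv"`: long-format tab-separated table with header
#'   `contig  position  ref  alt  sample  ref_count  alt_count`
#'   (1-based positions).
#' * `format = "vcf"`: any VCF with a per-sample `AD` (allele depths)
#'   FORMAT field; multi-allelic records are split into one row per
#'   alternate allele with a warning.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"` (default guessed from the
#'   extension).
#' @return data.frame with columns `contig`, `position` (1-based),
#'   `ref`, `alt`, `sample`, `ref_count`, `alt_count`, `maf`
#'   (`NA` at zero depth).
#' @export
read_allele_counts <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  out <- if (format == "tsv") read_counts_tsv(path) else read_counts_vcf(path)
  out$maf <- ifelse(out$ref_count + out$alt_count > 0,
                    out$alt_count / (out$ref_count + out$alt_count),
                    NA_real_)
  out
}

read_counts_tsv <- function(path) {
  need <- c("contig", "position", "ref", "alt", "sample",
            "ref_count", "alt_count")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("allele-count TSV lacks columns: ",
         paste(missing_cols, collapse = ", "))
  df$contig <- as.character(df$contig)
  df$sample <- as.character(df$sample)
  bad <- which(is.na(df$position) | is.na(df$ref_count) | is.na(df$alt_count))
  if (length(bad) > 0)
    stop("malformed allele-count record at line ", bad[1] + 1L)
  df[need]
}

read_counts_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad) || all(is.na(ad)))
    stop("VCF has no per-sample AD (allele depths) field")
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    if (length(alts) > 1)
      warning(sprintf("multi-allelic record at %s:%s split into %d rows",
                      fix[i, "CHROM"], fix[i, "POS"], length(alts)))
    for (s in colnames(ad)) {
      if (is.na(ad[i, s]))
        stop("missing AD for sample ", s, " at ",
             fix[i, "CHROM"], ":", fix[i, "POS"])
      depths <- as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]])
      for (j in seq_along(alts)) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig = fix[i, "CHROM"],
          position = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[j], sample = s,
          ref_count = depths[1], alt_count = depths[j + 1L],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname read_allele_counts
#' @param counts data.frame as returned by `read_allele_counts()` (the
#'   `maf` column, if present, is recomputed on read).
#' @export
write_allele_counts <- function(counts, path) {
  cols <- c("contig", "position", "ref", "alt", "sample",
            "ref_count", "alt_count")
  utils::write.table(counts[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a FASTA reference into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of sequences (suitable for
#'   [classify_96()]).
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Read paired FASTQ files into read pairs
#'
#' Phred+33 qualities. Pairs are matched by file order; offsets must be
#' supplied by the amplicon design (`offset2` is typically
#' `amplicon_length - read_length`).
#'
#' @param path1,path2 FASTQ files for read 1 and read 2.
#' @param offset1,offset2 0-based alignment offsets of each read on the
#'   amplicon reference.
#' @param amplicon amplicon identifier attached to each pair.
#' @return list of `read_pair` objects (see [simulate_read_pairs()]).
#' @export
read_pairs_fastq <- function(path1, path2, offset1 = 0L, offset2 = 0L,
                             amplicon = "amplicon") {
  parse_fq <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
    idx <- seq(1L, length(lines), by = 4L)
    list(id = sub("^@", "", sub("\\s.*$", "", lines[idx])),
         seq = toupper(lines[idx + 1L]),
         qual = lapply(lines[idx + 3L],
                       function(q) utf8ToInt(q) - 33L))
  }
  f1 <- parse_fq(path1); f2 <- parse_fq(path2)
  if (length(f1$id) != length(f2$id))
    stop("paired FASTQ files differ in read count")
  lapply(seq_along(f1$id), function(i)
    structure(list(id = f1$id[i], amplicon = amplicon,
                   seq1 = f1$seq[i], qual1 = f1$qual[[i]],
                   offset1 = as.integer(offset1),
                   seq2 = f2$seq[i], qual2 = f2$qual[[i]],
                   offset2 = as.integer(offset2)),
              class = "read_pair"))
}

#' Write site counts / calls tables
#'
#' Positions in all user-facing tables are 1-based; internal consensus
#' offsets are 0-based half-open and are converted on write.
#'
#' @param site_counts a `site_counts` data.frame ([count_bases()]).
#' @param path output TSV path.
#' @export
write_site_counts <- function(site_counts, path) {
  out <- as.data.frame(site_counts)
  out$position <- out$offset + 1L
  out$offset <- NULL
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sub-clonal calls as a minimal VCF
#'
#' One record per detected variant with the Bonferroni-adjusted p-value
#' in INFO (`ADJP`), 1-based positions.
#'
#' @param calls a `subclonal_calls` data.frame; `site` entries must be
#'   `"contig:position:ref:alt"` strings.
#' @param path output path.
#' @param all_sites write all tested sites rather than detected ones only.
#' @export
write_calls_vcf <- function(calls, path, all_sites = FALSE) {
  rows <- if (all_sites) calls else calls[calls$detected, , drop = FALSE]
  parts <- strsplit(rows$site, ":", fixed = TRUE)
  ok <- lengths(parts) == 4L
  if (any(!ok)) stop("site ids must be contig:position:ref:alt")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##source=clonaltrace %s",
                   as.character(utils::packageVersion("clonaltrace"))),
           "##INFO=<ID=ADJP,Number=1,Type=Float,Description=\"Bonferroni-adjusted chi-square p-value\">",
           "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Mutant allele frequency in the test sample\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    sprintf("%s\t%s\t.\t%s\t%s\t.\t%s\tADJP=%.6g;MAF=%.6g",
            p[1], p[2], p[3], p[4],
            if (rows$detected[i]) "PASS" else "not_detected",
            rows$p_adjusted[i], rows$sample_maf[i])
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a 96-channel catalog as TSV
#'
#' @param catalog samples x 96 matrix ([catalog_96()] or
#'   [simulate_catalog()]).
#' @param path output path; rows are channels keyed by standard labels,
#'   columns are samples.
#' @export
write_catalog_tsv <- function(catalog, path) {
  m <- rbind(catalog)
  if (ncol(m) != 96L) stop("expected 96 channels")
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  out <- data.frame(channel = channel_labels(), t(m), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @return `read_catalog_tsv()` returns the samples x 96 matrix.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(df$channel, channel_labels()))
    stop("catalog TSV channels do not match the standard 96 labels")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- channel_labels()
  m
}
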