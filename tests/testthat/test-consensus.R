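test_that("overlap bases are accepted only on agreement above the quality sum", {
  # both reads agree at Q30+30: accepted; at Q20+20 = 40: masked (strict >40)
  p <- make_pair("AAAA", "AAAA", c(30, 30, 20, 21), c(30, 20, 20, 20))
  cr <- merge_pair(p)
  expect_equal(cr$status, "merged")
  expect_equal(cr$accepted, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(cr$bases, c("A", "A", "N", "A"))
  # an isolated disagreement is masked even at high quality
  s1 <- paste(rep("A", 20), collapse = "")
  s2 <- paste(c(rep("A", 10), "C", rep("A", 9)), collapse = "")
  cr2 <- merge_pair(make_pair(s1, s2, rep(40, 20), rep(40, 20)))
  expect_equal(cr2$status, "merged")
  expect_equal(cr2$bases[11], "N")
  expect_equal(sum(cr2$bases == "N"), 1L)
})

test_that("pairs with more than 10% overlap mismatches are discarded", {
  s1 <- paste(rep("A", 20), collapse = "")
  s2 <- paste(c(rep("C", 3), rep("A", 17)), collapse = "")  # 15% mismatch
  cr <- merge_pair(make_pair(s1, s2, rep(35, 20), rep(35, 20)))
  expect_equal(cr$status, "rejected_mismatch")
  expect_equal(cr$mismatch_fraction, 0.15)
  # exactly 10% (2/20) is kept: the rule is strictly greater
  s3 <- paste(c(rep("C", 2), rep("A", 18)), collapse = "")
  cr2 <- merge_pair(make_pair(s1, s3, rep(35, 20), rep(35, 20)))
  expect_equal(cr2$status, "merged")
  # disjoint reads cannot be merged at all
  cr3 <- merge_pair(make_pair("AAAA", "CCCC", rep(30, 4), rep(30, 4),
                              offset1 = 0L, offset2 = 10L))
  expect_equal(cr3$status, "rejected_no_overlap")
})

test_that("N or zero-quality bases are masked and never counted as mismatches", {
  p <- make_pair("ANAA", "AAAA", c(30, 30, 0, 30), c(30, 30, 30, 30))
  cr <- merge_pair(p)
  expect_equal(cr$accepted, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(cr$mismatch_fraction, 0)
})

test_that("error-free input merges losslessly and order-independently", {
  tmpl <- paste(rep("ACGT", 10), collapse = "")
  pairs <- simulate_read_pairs(tmpl, overlap = 20, error_rate = 0,
                               n_pairs = 20, seed = 1)
  merged <- merge_pairs(pairs)
  expect_equal(merged$qc$n_merged, 20)
  for (cr in merged$reads) {
    expect_true(all(cr$accepted))
    expect_equal(paste(cr$bases, collapse = ""),
                 substr(tmpl, cr$offset + 1, cr$offset + length(cr$bases)))
  }
  refs <- c(amplicon = tmpl)
  fwd <- count_bases(merged$reads, refs)
  rev_ <- count_bases(rev(merged$reads), refs)
  expect_equal(fwd, rev_)
  expect_true(all(fwd$error_fraction == 0))
})

test_that("count_bases tallies accepted bases and skips unknown amplicons", {
  mk <- function(bases, amp = "a1") {
    structure(list(id = "x", amplicon = amp, offset = 0L,
                   bases = bases, accepted = bases != "N",
                   status = "merged"), class = "consensus_read")
  }
  reads <- c(replicate(100, mk(c("C")), simplify = FALSE))
  sc <- count_bases(reads, c(a1 = "C"))
  expect_equal(sc$C, 100L)
  expect_equal(sc$error_fraction, 0)
  # 9999 C + 1 T at one site: non-reference fraction 0.01%
  reads2 <- c(replicate(9999, mk("C"), simplify = FALSE), list(mk("T")))
  sc2 <- count_bases(reads2, c(a1 = "C"))
  expect_equal(sc2$total, 10000L)
  expect_equal(sc2$error_fraction, 1e-4)
  # unknown amplicon: skipped and reported
  sc3 <- count_bases(list(mk("C"), mk("C", amp = "nope")), c(a1 = "C"))
  expect_equal(attr(sc3, "qc")$n_skipped_unknown_amplicon, 1L)
  expect_equal(sc3$total, 1L)
})

test_that("error summary reports median and box-plot percentiles per region", {
  sc <- data.frame(amplicon = "r1", offset = 0:2, ref = "C",
                   A = 0L, C = 10L, G = 0L, T = 0L, total = 10L,
                   error_fraction = c(1e-4, 2e-4, 9e-4))
  s <- error_rate_summary(sc)
  expect_equal(s$median, 2e-4)
  expect_equal(s$n_sites, 3L)
  # excluding true variant sites removes them from the error estimate
  s2 <- error_rate_summary(sc, exclude_sites = data.frame(amplicon = "r1",
                                                          offset = 2L))
  expect_equal(s2$median, 1.5e-4)
  expect_error(error_rate_summary(sc[0, ]), "no covered sites")
})

test_that("consensus merging lowers the error rate below single reads", {
  set.seed(20)
  tmpl <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
  pairs <- simulate_read_pairs(tmpl, overlap = 60, error_rate = 1e-3,
                               n_pairs = 4000, seed = 21)
  refs <- c(amplicon = tmpl)
  merged <- merge_pairs(pairs)
  cons <- count_bases(merged$reads, refs)
  raw <- count_bases(lapply(pairs, raw_read_as_consensus), refs)
  cons_med <- error_rate_summary(cons)$median
  raw_med <- error_rate_summary(raw)$median
  expect_lt(cons_med, raw_med)
  expect_gt(raw_med, 1e-4)   # single reads sit near the injected error rate
})

test_that("rank-sum comparison matches symmetry and detects shifts", {
  x <- c(1, 2, 3, 7, 9)
  same <- compare_error_distributions(x, x)
  expect_equal(same$U, length(x)^2 / 2)
  expect_gt(same$p, 0.99)
  sep <- compare_error_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 0.1)
  # power: shifted distributions at n = 200 are detected nearly always
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    a <- rgamma(200, 2, 2); b <- rgamma(200, 2, 2) + 0.5
    compare_error_distributions(a, b)$p < 0.001
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  expect_error(compare_error_distributions(numeric(0), 1), "non-empty")
})
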