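test_that("the 96 channel labels are unique and well-formed", {
  labs <- channel_labels()
  expect_length(labs, 96)
  expect_false(any(duplicated(labs)))
  expect_true(all(grepl("^[ACGT]\\[[CT]>[ACGT]\\][ACGT]$", labs)))
  expect_equal(labs[1], "A[C>A]A")
})

test_that("variants are classified on the pyrimidine strand", {
  expect_equal(classify_96("chr1", 4, "C", "T", c(chr1 = "TTACGTT")),
               "A[C>T]G")
  # purine reference: variant and context are reverse-complemented.
  # plus-strand context T G A around a G>T is TCA around C>A when flipped
  expect_equal(classify_96("chr1", 4, "G", "T", c(chr1 = "TTTGATT")),
               "T[C>A]A")
  # strand idempotence: the same physical change described from the
  # reverse-complemented reference yields the same label
  fwd <- c(chr1 = "TTACGTT")
  rev_ <- c(chr1 = "AACGTAA")  # reverse complement of fwd
  expect_equal(classify_96("chr1", 4, "C", "T", fwd),
               classify_96("chr1", 4, "G", "A", rev_))
  expect_error(classify_96("chr1", 4, "A", "T", c(chr1 = "TTACGTT")),
               "reference mismatch")
  expect_error(classify_96("chr2", 1, "C", "T", c(chr1 = "ACGT")),
               "contig not found")
  expect_warning(out <- classify_96("chr1", 3, "C", "T", c(chr1 = "TNCGT")),
                 "ambiguous")
  expect_true(is.na(out))
  expect_warning(classify_96("chr1", 1, "C", "T", c(chr1 = "CTACG")),
                 "context")
})

test_that("catalogs conserve the classified variant count", {
  ref <- c(chr1 = "TTACGTTACGTAACGT")
  vars <- data.frame(contig = "chr1",
                     position = c(4, 9, 14, 2),
                     ref = c("C", "C", "C", "T"),
                     alt = c("T", "A", "G", "G"),
                     sample = c("a", "a", "b", "b"))
  cat1 <- catalog_96(vars, ref)
  expect_equal(sum(cat1), 4L)
  expect_equal(unname(rowSums(cat1)), c(2L, 2L))
  # a variant losing its context is skipped, not silently dropped
  vars2 <- rbind(vars, data.frame(contig = "chr1", position = 1,
                                  ref = "T", alt = "C", sample = "b"))
  expect_warning(cat2 <- catalog_96(vars2, ref), "context")
  expect_equal(sum(cat2), 4L)
  expect_equal(attr(cat2, "n_skipped"), 1L)
})

test_that("spectra normalize and collapse consistently", {
  counts <- setNames(integer(96), channel_labels())
  counts["A[C>T]G"] <- 1L
  sp <- spectrum(counts)
  expect_equal(sum(sp$spectrum), 1)
  expect_equal(unname(sp$spectrum["A[C>T]G"]), 1)
  expect_equal(unname(sp$collapsed["C>T"]), 1)
  # collapse preserves mass for an arbitrary catalog
  set.seed(61)
  counts2 <- setNames(rpois(96, 5), channel_labels())
  sp2 <- spectrum(counts2)
  expect_equal(sum(sp2$collapsed), 1)
  expect_equal(sum(sp2$spectrum), 1)
  # deamination-dominated catalog has C>T as its largest class
  deam <- simulate_catalog(example_signatures()[1, , drop = FALSE], 1,
                           5000, seed = 62)
  expect_equal(names(which.max(spectrum(deam)$collapsed)), "C>T")
  empty <- spectrum(setNames(integer(96), channel_labels()))
  expect_equal(empty$n, 0L)
  expect_null(empty$spectrum)
})

test_that("rank-1 catalogs factorize exactly", {
  set.seed(63)
  sig <- example_signatures()[1, ]
  loading <- c(200, 1000, 5000)
  V <- outer(loading, sig)
  fit <- nnmf_extract(V, k = 1, restarts = 5, seed = 64)
  expect_gt(cosine(fit$signatures[1, ], sig), 0.999)
  expect_lt(fit$objective / sum(V), 1e-6)
  expect_equal(sum(fit$signatures), 1, tolerance = 1e-9)
})

test_that("two mixed signatures are recovered across 20 samples", {
  sigs <- example_signatures()
  set.seed(65)
  w <- runif(20, 0.1, 0.9)
  V <- t(vapply(seq_along(w), function(i)
    as.numeric(simulate_catalog(sigs, c(w[i], 1 - w[i]), 5000,
                                seed = 65 + i)), numeric(96)))
  fit <- nnmf_extract(V, k = 2, restarts = 10, seed = 66)
  sims <- vapply(1:2, function(i)
    max(cosine(fit$signatures[i, ], sigs[1, ]),
        cosine(fit$signatures[i, ], sigs[2, ])), 0)
  expect_true(all(sims > 0.95))
  expect_true(all(fit$stability > 0.9))
  # each signature matched a *different* truth signature
  who <- vapply(1:2, function(i)
    which.max(c(cosine(fit$signatures[i, ], sigs[1, ]),
                cosine(fit$signatures[i, ], sigs[2, ]))), 0L)
  expect_setequal(who, 1:2)
  # exposures sum to the sample totals after row normalization
  expect_equal(rowSums(fit$exposure_proportions), rep(1, 20))
  # model-order sanity: k = 2 fits strictly better than k = 1
  fit1 <- nnmf_extract(V, k = 1, restarts = 5, seed = 67)
  expect_lt(fit$objective, fit1$objective)
})

test_that("the factorization objective is non-increasing per iteration", {
  sigs <- example_signatures()
  V <- rbind(simulate_catalog(sigs, c(0.8, 0.2), 2000, seed = 70),
             simulate_catalog(sigs, c(0.2, 0.8), 2000, seed = 71))
  for (div in c("kl", "frobenius")) {
    fit <- nnmf_extract(V, k = 2, restarts = 3, seed = 72, divergence = div)
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
  }
  expect_error(nnmf_extract(V, k = 5), "k must be")
  expect_error(nnmf_extract(matrix(0, 2, 96), k = 1), "all zero")
})

test_that("exposure attribution solves the non-negative decomposition", {
  sigs <- example_signatures()
  pure <- attribute(sigs[1, ], sigs)
  expect_equal(pure$proportions, c(1, 0), tolerance = 1e-8)
  blend <- attribute(as.numeric(0.7 * sigs[1, ] + 0.3 * sigs[2, ]), sigs)
  expect_equal(blend$proportions, c(0.7, 0.3), tolerance = 1e-8)
  # multinomial noise at n = 10,000: within +-0.05
  noisy <- simulate_catalog(sigs, c(0.7, 0.3), 10000, seed = 73)
  est <- attribute(as.numeric(noisy), sigs)
  expect_lt(max(abs(est$proportions - c(0.7, 0.3))), 0.05)
  zero <- attribute(rep(0, 96), sigs)
  expect_equal(zero$proportions, c(0, 0))
  expect_warning(attribute(sigs[1, ], sigs[c(1, 1), ]), "duplicate")
})
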