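test_that("an expansion without mutagenesis carries only founder mutations", {
  tr <- simulate_expansion(mu = 0, generations = 5, founder_mutations = 3,
                           seed = 11)
  expect_equal(tr$cell_count, 32L)
  expect_length(tr$founder_mutations, 3L)
  expect_equal(sum(lengths(tr$branch_mutations)), 0L)
  tv <- truth_variants(tr)
  expect_equal(tv$molecule_fraction, rep(1 / 2, 3))
})

test_that("carrier counts and molecule fractions follow binary inheritance", {
  tr <- simulate_expansion(mu = 3, generations = 6, founder_mutations = 2,
                           seed = 3)
  tv <- truth_variants(tr)
  # every mutation at generation n is carried by 2^(G - n) leaves
  for (i in sample(nrow(tv), 25)) {
    id <- tv$id[i]
    n <- tv$origin[i]
    if (n == 0) {
      carriers <- length(tree_leaves(tr))
    } else {
      node <- names(Filter(function(v) id %in% v, tr$branch_mutations))
      carriers <- length(tree_leaves(tr, node))
    }
    expect_equal(carriers, 2^(tr$generations - n))
    expect_equal(tv$molecule_fraction[i], 2^-(n + 1))
    expect_equal(tv$cell_fraction[i], 2 * tv$molecule_fraction[i])
  }
  # conservation: founder + per-branch new mutations = truth table size
  expect_equal(length(tr$founder_mutations) +
                 sum(lengths(tr$branch_mutations)), nrow(tv))
  expect_false(any(duplicated(tv$id)))
})

test_that("expansion is deterministic under a seed and validates inputs", {
  a <- simulate_expansion(2, 4, 1, seed = 9)
  b <- simulate_expansion(2, 4, 1, seed = 9)
  expect_identical(a, b)
  expect_error(simulate_expansion(-1, 4), "non-negative")
  expect_error(simulate_expansion(1, -1), "non-negative")
  expect_error(simulate_expansion(1, 20), "cap")
})

test_that("mutation accrual matches the Poisson expectation mu * (2^(G+1) - 2)", {
  # closed form: sum over generations of mu * 2^n daughters
  mu <- 14; G <- 8
  expected <- mu * (2^(G + 1) - 2)   # 7140
  totals <- vapply(1:150, function(s) {
    tr <- simulate_expansion(mu, G, seed = s)
    length(tr$mutation_origin)
  }, 0)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se + 1e-9)
  # the per-generation approximation path has the same expectation
  totals2 <- vapply(1:300, function(s)
    nrow(simulate_population_mutations(mu, G, seed = 1000 + s)), 0)
  se2 <- sd(totals2) / sqrt(length(totals2))
  expect_lt(abs(mean(totals2) - expected), 3 * se2 + 1e-9)
})

test_that("a single lineage accrues Poisson(mu) mutations per generation", {
  tv <- simulate_lineage_mutations(5, 24, seed = 2)
  expect_true(all(tv$origin >= 1 & tv$origin <= 24))
  expect_equal(tv$lambda, 1500 * 2^-(tv$origin + 1))
  totals <- vapply(1:400, function(s)
    nrow(simulate_lineage_mutations(5, 24, seed = s)), 0)
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - 5 * 24), 3 * se + 1e-9)
})

test_that("amplicon sampling is Poisson in molecules and error-free when asked", {
  # absent truth, no error: never any mutant read
  for (s in 1:5) {
    r <- simulate_amplicon(0, depth = 5000, error_rate = 0, seed = s)
    expect_equal(r$alt_reads, 0L)
    expect_equal(r$k, 0L)
  }
  # clonal heterozygous truth converges to MAF 0.5; residual spread comes
  # from the Poisson molecule-sampling stage (SD ~ sqrt(750)/1500 = 0.018)
  r <- simulate_amplicon(1 / 2, depth = 2e5, error_rate = 0, seed = 1)
  expect_lt(abs(r$alt_reads / r$depth - 0.5), 4 * sqrt(750) / 1500)
  expect_error(simulate_amplicon(0.7), "molecule_fraction")
  expect_error(simulate_amplicon(0.1, error_rate = 1), "error_rate")
})

test_that("detection frequency over seeds matches 1 - exp(-lambda)", {
  n_mol <- 1500
  for (lambda in c(0.1, 0.5, 1, 2)) {
    mf <- lambda / n_mol
    hits <- vapply(1:2000, function(s)
      simulate_amplicon(mf, n_mol, depth = 1, seed = s)$k > 0, TRUE)
    p <- -expm1(-lambda)
    se <- sqrt(p * (1 - p) / length(hits))
    expect_lt(abs(mean(hits) - p), 3 * se + 1e-9)
  }
  # the spec'd worked value: lambda = 0.732 detects ~51.9% of the time
  hits <- vapply(1:4000, function(s)
    simulate_amplicon(0.732 / 1500, 1500, depth = 1, seed = s)$k > 0, TRUE)
  expect_lt(abs(mean(hits) - 0.519), 3 * sqrt(0.25 / 4000) + 0.001)
})

test_that("read pairs reproduce the template and the error rate", {
  tmpl <- paste(rep("ACGT", 10), collapse = "")  # 40 bp
  p <- simulate_read_pairs(tmpl, overlap = 20, error_rate = 0, n_pairs = 3,
                           seed = 4)
  for (pr in p) {
    expect_equal(pr$seq1, substr(tmpl, 1, 30))
    expect_equal(pr$seq2, substr(tmpl, 11, 40))
    expect_equal(pr$offset2, 10L)
    expect_true(all(pr$qual1 == 30L))
  }
  # per-read mismatch fraction ~ error rate
  p <- simulate_read_pairs(tmpl, overlap = 20, error_rate = 0.01,
                           n_pairs = 4000, seed = 5)
  mm <- vapply(p, function(pr)
    sum(strsplit(pr$seq1, "")[[1]] != strsplit(tmpl, "")[[1]][1:30]), 0)
  rate <- sum(mm) / (4000 * 30)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / (4000 * 30)))
  expect_error(simulate_read_pairs(tmpl, overlap = 41), "overlap")
  expect_error(simulate_read_pairs("ACGTN", overlap = 1), "A/C/G/T")
})

test_that("coincident same-base errors in both reads are quadratically rare", {
  # both reads wrong with the same base at an overlap position:
  # 3 * (e/3)^2 = e^2/3 per site, far below the single-read rate e
  e <- 0.02
  tmpl <- paste(rep("A", 40), collapse = "")
  p <- simulate_read_pairs(tmpl, overlap = 40, error_rate = e,
                           n_pairs = 30000, seed = 6)
  both_same <- vapply(p, function(pr) {
    s1 <- strsplit(pr$seq1, "")[[1]]
    s2 <- strsplit(pr$seq2, "")[[1]]
    sum(s1 != "A" & s1 == s2)
  }, 0)
  n_pos <- 30000 * 40
  p_expected <- e^2 / 3
  se <- sqrt(p_expected / n_pos)
  expect_lt(abs(sum(both_same) / n_pos - p_expected), 4 * se)
  expect_lt(p_expected, e / 10)
})

test_that("catalog draws follow the signature mixture", {
  sig <- example_signatures()
  big <- simulate_catalog(sig[1, , drop = FALSE], 1, 2e5, seed = 7)
  expect_equal(sum(big), 2e5)
  expect_gt(cosine(big / sum(big), sig[1, ]), 0.999)
  # two orthogonal single-channel signatures at weights 0.7 / 0.3
  s <- matrix(0, 2, 96)
  s[1, 1] <- 1; s[2, 96] <- 1
  cat2 <- simulate_catalog(s, c(0.7, 0.3), 10000, seed = 8)
  expect_lt(abs(cat2[1] - 7000), 4 * sqrt(10000 * 0.7 * 0.3))
  expect_equal(sum(cat2[c(1, 96)]), 10000)
  expect_error(simulate_catalog(matrix(1, 1, 95), 1, 10), "96")
  expect_error(simulate_catalog(sig, c(0.7, 0.7), 10), "sum to 1")
})

test_that("truth tables and read pairs round-trip through their text formats", {
  tr <- simulate_expansion(2, 4, 2, seed = 12)
  tv <- truth_variants(tr)
  tsv <- tempfile(fileext = ".tsv")
  write_truth_tsv(tv, tsv)
  back <- read.table(tsv, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  expect_equal(back$id, tv$id)
  expect_equal(back$molecule_fraction, tv$molecule_fraction)

  tmpl <- paste(rep("GATC", 10), collapse = "")
  pairs <- simulate_read_pairs(tmpl, overlap = 10, error_rate = 0.01,
                               n_pairs = 5, seed = 13)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  write_pairs_fastq(pairs, f1, f2)
  rp <- read_pairs_fastq(f1, f2, offset1 = 0, offset2 = 15)
  expect_length(rp, 5)
  expect_equal(rp[[1]]$seq1, pairs[[1]]$seq1)
  expect_equal(rp[[3]]$qual2, pairs[[3]]$qual2)
})
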