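test_that("read_vcf parses phased biallelic records into a haplotype panel", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, list(c("0|1", "1|0", "0|0", "0|1"),
                           c("0|0", "0|1", "1|1", "0|0"),
                           c("1|0", "0|0", "0|1", "0|0")))
  p <- read_vcf(path, maf_min = 0.001)
  expect_s3_class(p, "haplotype_panel")
  expect_equal(dim(p$hap), c(8L, 3L))
  expect_equal(n_individuals(p), 4L)
  # columns ordered by position
  expect_equal(p$variants$pos, sort(p$variants$pos))
  # haplotype entries reproduce the GT fields of the first record
  expect_equal(unname(p$hap[1:2, 1L]), c(0L, 1L))
})

test_that("read_vcf excludes variants at or below the MAF threshold", {
  path <- withr::local_tempfile(fileext = ".vcf")
  # site 2 has MAF 0 .. below any positive threshold after one carrier flips
  write_toy_vcf(path, list(c("0|1", "1|0", "0|0", "0|1"),
                           c("0|1", "0|0", "0|0", "0|0"),
                           c("1|0", "0|0", "0|1", "0|0")))
  expect_message(p <- read_vcf(path, maf_min = 0.2), "excluded")
  expect_equal(n_variants(p), 2L)
})

test_that("read_vcf rejects unphased and missing genotypes, naming the record", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, list(c("0|1", "1|0", "0|0", "0|1"),
                           c("0/1", "0|0", "0|0", "0|1")),
                pos = c(101L, 202L))
  expect_error(read_vcf(path), "unphased.*19:202", ignore.case = TRUE)
  write_toy_vcf(path, list(c("0|1", ".", "0|0", "0|1")), pos = 303L)
  expect_error(read_vcf(path), "missing genotype.*19:303")
})

test_that("read_vcf codes the minor allele as 1", {
  path <- withr::local_tempfile(fileext = ".vcf")
  # ALT frequency 6/8 > 0.5: coding must flip so that 1 is the minor allele
  write_toy_vcf(path, list(c("1|1", "1|0", "1|1", "0|1"),
                           c("0|1", "0|0", "0|0", "0|1")))
  p <- read_vcf(path)
  expect_lt(p$variants$freq[1L], 0.5)
  expect_equal(p$variants$coded[1L], "A")
})

test_that("haplotype-matrix round-trip is bit-exact", {
  p <- random_small_panel(6, 4, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_hapmatrix(p, path)
  q <- read_hapmatrix(path)
  expect_identical(q$hap, p$hap)
  expect_identical(q$variants$id, p$variants$id)
})

test_that("genotypes are the sum of the two haplotype rows of each individual", {
  for (seed in c(1, 2)) {
    p <- random_small_panel(7, 5, seed = seed)
    g <- genotypes(p)
    for (i in seq_len(n_individuals(p))) {
      expect_identical(g[i, ], p$hap[2L * i - 1L, ] + p$hap[2L * i, ])
    }
  }
})

test_that("panel construction enforces its invariants", {
  h <- matrix(c(0, 1, 1, 0, 0, 0, 0, 0), nrow = 4)
  expect_error(haplotype_panel(h), "monomorphic")
  expect_s3_class(haplotype_panel(h, allow_monomorphic = TRUE),
                  "haplotype_panel")
  expect_error(haplotype_panel(matrix(0:1, nrow = 3, ncol = 2)), "even")
  expect_error(haplotype_panel(matrix(2, nrow = 4, ncol = 2)), "0 or 1")
  p <- random_small_panel(8, 3, seed = 3)
  expect_equal(p$variants$maf,
               unname(pmin(colMeans(p$hap), 1 - colMeans(p$hap))),
               tolerance = 1e-12)
})

test_that("ld_stats matches brute-force haplotype counting", {
  # perfect LD: identical columns
  p <- panel_from_strings(c("11", "00", "11", "00"))
  s <- ld_stats(p, 1, 2)
  expect_equal(s$r2, 1)
  expect_equal(s$D_prime, 1)

  # independence by construction: all four haplotype combinations equally
  p <- panel_from_strings(c("00", "01", "10", "11"))
  s <- ld_stats(p, 1, 2)
  expect_equal(s$D, 0)
  expect_equal(s$r2, 0)

  # worked 10-haplotype panel: r2 equals squared Pearson correlation of the
  # 0/1 columns (independent oracle)
  p <- panel_from_strings(c("10", "11", "01", "00", "10",
                            "11", "00", "01", "11", "00"))
  s <- ld_stats(p, 1, 2)
  expect_equal(s$r2, cor(p$hap[, 1L], p$hap[, 2L])^2, tolerance = 1e-12)

  # brute-force 2x2 oracle on random small panels
  for (seed in 1:5) {
    p <- random_small_panel(6, 2, seed = 100 + seed)
    x <- p$hap[, 1L]; y <- p$hap[, 2L]
    n11 <- sum(x == 1 & y == 1); n <- length(x)
    D <- n11 / n - mean(x) * mean(y)
    s <- ld_stats(p, 1, 2)
    expect_equal(s$D, D, tolerance = 1e-12)
    expect_equal(s$r2, D^2 / (mean(x) * (1 - mean(x)) *
                                mean(y) * (1 - mean(y))), tolerance = 1e-12)
    expect_lte(abs(s$D_prime), 1 + 1e-12)
    # identity r2 = D^2 / (p_i(1-p_i) p_j(1-p_j)) is the definition used
  }
})

test_that("ld_stats refuses monomorphic columns and i == j", {
  p <- panel_from_strings(c("10", "10", "00", "01"), allow_monomorphic = FALSE)
  expect_error(ld_stats(p, 1, 1), "different")
  q <- haplotype_panel(cbind(v1 = c(1L, 1L, 1L, 1L), v2 = c(0L, 1L, 0L, 1L)),
                       allow_monomorphic = TRUE)
  expect_error(ld_stats(q, 1, 2), "monomorphic")
})

test_that("joint_genotype_freq tallies the empirical 3x3 table", {
  g <- c(0, 1, 2, 1, 0)
  j <- joint_genotype_freq(g, g)
  expect_equal(unname(diag(j$table)), sapply(0:2, function(k) mean(g == k)))
  expect_equal(sum(j$table) - sum(diag(j$table)), 0)

  # 10-individual toy table vs exhaustive hand tally
  gi <- c(0, 0, 1, 2, 1, 0, 1, 2, 0, 1)
  dj <- c(0, 1, 1, 2, 0, 0, 2, 2, 1, 1)
  j <- joint_genotype_freq(gi, dj)
  oracle <- matrix(0, 3, 3)
  for (r in seq_along(gi)) {
    oracle[gi[r] + 1, dj[r] + 1] <- oracle[gi[r] + 1, dj[r] + 1] + 1 / 10
  }
  expect_equal(unname(j$table), oracle, tolerance = 1e-12)
  expect_equal(sum(j$table), 1, tolerance = 1e-12)
  expect_equal(unname(j$margin_g), rowSums(oracle), tolerance = 1e-12)
  expect_equal(unname(j$margin_d), colSums(oracle), tolerance = 1e-12)

  expect_error(joint_genotype_freq(integer(0), integer(0)), "empty")
  expect_error(joint_genotype_freq(c(0, 1), c(0, 1, 2)), "length")
})

test_that("independent columns give a near-product joint table", {
  set.seed(42)
  n <- 4000
  gi <- rbinom(n, 2, 0.3)
  dj <- rbinom(n, 2, 0.4)
  j <- joint_genotype_freq(gi, dj)
  expect_lt(max(abs(j$table - outer(j$margin_g, j$margin_d))), 0.02)
})

test_that("freq and LD summaries tabulate every variant and pair", {
  p <- random_small_panel(10, 4, seed = 9)
  fs <- freq_summary(p)
  expect_equal(nrow(fs), 4L)
  expect_equal(fs$f_g0 + fs$f_g1 + fs$f_g2, rep(1, 4), tolerance = 1e-12)
  path <- withr::local_tempfile(fileext = ".tsv")
  ls <- ld_summary(p, path = path)
  expect_equal(nrow(ls), choose(4, 2))
  expect_true(file.exists(path))
})
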