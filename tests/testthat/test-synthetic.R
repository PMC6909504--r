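spec_small <- list(chrom = "chrSim", chrom_length = 1.5e6,
                   tad = gintervals("chrSim", 2e5, 1.3e6),
                   partition = gintervals("chrSim", c(2e5, 7e5),
                                          c(7e5, 1.3e6),
                                          name = c("p1", "p2")))

test_that("simulators are bit-stable under a fixed seed", {
  a <- simulate_contact_matrix(spec_small, seed = 5)
  b <- simulate_contact_matrix(spec_small, seed = 5)
  expect_identical(a$maternal$values, b$maternal$values)

  fm <- simulate_fragment_map(1e5, seed = 5)
  expect_identical(fm$boundaries, simulate_fragment_map(1e5, seed = 5)$boundaries)

  snps <- snp_table(c(10, 60, 110), c("A", "C", "G"), c("T", "G", "A"))
  r1 <- simulate_snp_reads(snps, 50, 30, 0.5, 0.01, 1000, seed = 5)
  r2 <- simulate_snp_reads(snps, 50, 30, 0.5, 0.01, 1000, seed = 5)
  expect_identical(r1, r2)

  e1 <- simulate_expression(100, seed = 5)
  expect_identical(e1, simulate_expression(100, seed = 5))

  f1 <- simulate_fish_nuclei(5, "p", 1e6, seed = 5)
  expect_identical(f1, simulate_fish_nuclei(5, "p", 1e6, seed = 5))
})

test_that("contact matrices have the planted block structure", {
  sim <- simulate_contact_matrix(spec_small, tad_boost = 1,
                                 noise_dispersion = 0, seed = 6,
                                 decay_exponent = -1)
  m <- sim$maternal$values
  # pure power-law Toeplitz away from the planted structure
  d <- abs(outer(seq_len(nrow(m)), seq_len(nrow(m)), "-"))
  ref <- 100 * pmax(d, 1)^-1
  diag(ref) <- 0
  expect_equal(m, ref, ignore_attr = TRUE)

  sim2 <- simulate_contact_matrix(spec_small, noise_dispersion = 0, seed = 6,
                                  subtad_boost = list(maternal = c(p2 = 2),
                                                      paternal = NULL))
  Em <- attr(sim2$maternal, "expected")
  Ep <- attr(sim2$paternal, "expected")
  bins_p2 <- 71:129  # strictly inside p2 (0.7-1.3 Mb at 10-kb bins)
  off <- upper.tri(Em[bins_p2, bins_p2])   # diagonal is structurally zero
  expect_equal(mean((Em[bins_p2, bins_p2] / Ep[bins_p2, bins_p2])[off]), 2)
  out <- 1:20
  expect_equal(Em[out, out], Ep[out, out])
})

test_that("negative-binomial noise is centred on the expectation", {
  ratios <- sapply(1:100, function(s) {
    sim <- simulate_contact_matrix(spec_small, noise_dispersion = 0.1,
                                   seed = 300 + s)
    E <- attr(sim$maternal, "expected")
    inb <- 21:129
    mean(sim$maternal$values[inb, inb]) / mean(E[inb, inb])
  })
  expect_true(mean(ratios) > 0.9 && mean(ratios) < 1.1)
})

test_that("4C sampling conserves reads and matches expected frequencies", {
  fm <- simulate_fragment_map(3e5, 600, seed = 7)
  spec <- list(chrom = "chrSim", chrom_length = 3e5,
               tad = gintervals("chrSim", 0, 3e5),
               partition = gintervals("chrSim", 0, 3e5, name = "all"))
  sim <- simulate_contact_matrix(spec, bin_width = 10000,
                                 noise_dispersion = 0, seed = 7)
  tr <- simulate_4c_counts(sim$maternal, 15, 1000, fm, seed = 8)
  expect_equal(sum(tr$values), 1000)

  # point-mass row: all reads land in that bin's fragments
  row <- rep(0, 30); row[4] <- 1
  attr(row, "bin_width") <- 10000; attr(row, "origin") <- 0
  tr2 <- simulate_4c_counts(viewpoint_bin = 4, n_reads = 500,
                            fragment_map = fm, seed = 9, row_probs = row)
  mids <- fragment_midpoints(fm)
  expect_equal(sum(tr2$values[mids >= 30000 & mids < 40000]), 500)
  expect_equal(sum(tr2$values[mids < 30000 | mids >= 40000]), 0)

  # pooled empirical frequencies against exact multinomial expectation
  row3 <- sim$maternal$values[15, ]
  fbin <- floor(mids / 10000) + 1
  per_bin <- tabulate(fbin, 30)
  probs <- row3[fbin] / per_bin[fbin]
  probs <- probs / sum(probs)
  tot <- Reduce(`+`, lapply(1:50, function(s)
    simulate_4c_counts(sim$maternal, 15, 1e4, fm, seed = 400 + s)$values))
  N <- 50 * 1e4
  inside <- abs(tot / N - probs) <= 3 * sqrt(probs * (1 - probs) / N) + 1e-9
  expect_gte(mean(inside), 0.98)

  expect_error(simulate_4c_counts(viewpoint_bin = 1, n_reads = 10,
                                  fragment_map = fm, seed = 1,
                                  row_probs = structure(rep(0, 30),
                                                        bin_width = 1e4,
                                                        origin = 0)),
               "all-zero")
})

test_that("ChIP bins are Poisson around background plus planted peaks", {
  pk <- data.frame(center = 5000, width = 500, height = 4, allele_fold = 8)
  sim <- simulate_chip_bins(pk, background_rate = 1, n_bins = 400, seed = 10)
  expect_equal(max(sim$expected$maternal), 1 + 32)
  expect_equal(max(sim$expected$paternal), 1 + 4)

  pk1 <- data.frame(center = 5000, width = 500, height = 30, allele_fold = 1)
  sim1 <- simulate_chip_bins(pk1, background_rate = 1, n_bins = 400, seed = 10)
  expect_equal(sim1$expected$maternal, sim1$expected$paternal)

  peak_bins <- which(sim1$expected$maternal > 1)
  means <- sapply(1:200, function(s) {
    mean(simulate_chip_bins(pk1, background_rate = 1, n_bins = 400,
                            seed = 500 + s)$maternal$values[peak_bins])
  })
  expect_equal(mean(means), 31, tolerance = 0.05)
})

test_that("input artifacts and zero regions feed the blacklist", {
  pk <- data.frame(center = 5000, width = 500, height = 30, allele_fold = 1)
  sim <- simulate_chip_bins(pk, n_bins = 400, seed = 11,
                            artifact_regions = gintervals("chrSim", 1000, 1500),
                            zero_regions = gintervals("chrSim", 8000, 8500))
  bl <- blacklist_from_input(sim$input)
  expect_true(any(bl$start <= 1000 & bl$end >= 1500))
  expect_true(any(bl$start <= 8000 & bl$end >= 8500))
})

test_that("SNP reads carry the true allele's bases", {
  pos <- seq(50, 9950, by = 150)
  snps <- snp_table(pos, rep(c("A", "C"), length.out = length(pos)),
                    rep(c("G", "T"), length.out = length(pos)))
  rd <- simulate_snp_reads(snps, 500, 100, 0.5, error_rate = 0,
                           chrom_length = 10000, seed = 12)
  calls <- assign_alleles(rd, snps)
  informative <- calls$label %in% c("maternal", "paternal")
  expect_gt(mean(informative), 0.5)   # 100-bp reads on 150-bp SNP spacing
  # with zero error every informative call is the hidden truth
  expect_equal(calls$label[informative], rd$true_allele[informative])

  # maternal fraction within 3 binomial SD
  rd2 <- simulate_snp_reads(snps, 10000, 100, 0.5, 0, 10000, seed = 13)
  expect_lt(abs(mean(rd2$true_allele == "maternal") - 0.5),
            3 * sqrt(0.25 / 10000))
})

test_that("half-error reads are right 3/4 of the time when informative", {
  # single SNP per read, error_rate 0.5: the SNP base stays correct w.p. 1/2,
  # flips to the other allele w.p. 1/6, else mismatch -> uninformative.
  # Among informative reads accuracy is (1/2)/(1/2 + 1/6) = 3/4 and the
  # uninformative fraction is 1/3.
  snps <- snp_table(c(500), "A", "G")
  rd <- simulate_snp_reads(snps, 30000, 20, 1, error_rate = 0.5,
                           chrom_length = 1000, seed = 14)
  rd <- rd[rd$start <= 500 & rd$start + 20 > 500, ]
  calls <- assign_alleles(rd, snps)
  inf <- calls$label %in% c("maternal", "paternal")
  expect_lt(abs(mean(calls$label[inf] == "maternal") - 0.75), 0.07)
  expect_lt(abs(mean(!inf) - 1 / 3), 0.07)
})

test_that("TPM columns sum to one million and planted folds survive", {
  ds <- data.frame(transcript = c(5, 10), tpm = c(50, 10),
                   fold = c(5, 5), up_in = c("PR8", "AK2"))
  tab <- simulate_expression(300, ds, cv = 0.05, seed = 15)
  for (col in names(tab)[-1]) expect_equal(sum(tab[[col]]), 1e6)
  comb <- combine_replicates(tab, list(PR8 = paste0("PR8_", 1:3),
                                       AK2 = paste0("AK2_", 1:3)))
  calls <- call_differential_expression(comb)
  expect_true(all(calls$differential[c(5, 10)]))
  expect_equal(calls$direction[c(5, 10)], c("PR8", "AK2"))
  expect_error(simulate_expression(10, cv = 0, seed = 1), "degenerate")
})

test_that("FISH distances follow the scale model", {
  sp <- simulate_fish_nuclei(20, "p", 1e6, noise_sd = 0, seed = 16)
  d <- sapply(split(sp, sp$nucleus), function(n)
    sqrt(sum((n[n$channel == "A", c("x", "y", "z")] -
                n[n$channel == "B", c("x", "y", "z")])^2)))
  expect_equal(unname(d), rep(0.9, 20), tolerance = 1e-12)

  sp2 <- simulate_fish_nuclei(500, "p", 1e6, noise_sd = 0.03, seed = 17)
  d2 <- sapply(split(sp2, sp2$nucleus), function(n)
    sqrt(sum((n[n$channel == "A", c("x", "y", "z")] -
                n[n$channel == "B", c("x", "y", "z")])^2)))
  expect_lt(abs(mean(d2) - 0.9), 2 * stats::sd(d2) / sqrt(500) + 0.03^2 / 0.9)
  r2 <- with(sp2, x^2 + y^2 + z^2)
  expect_true(all(r2 <= 4^2 + 1e-9))
})
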