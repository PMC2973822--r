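regAB <- locus_registry(c("A", "B"))

test_that("pairing frequency matches hand computation and identities", {
  # {A+B+: 0.6, A-B-: 0.4} -> observed 1.0, expected 0.6^2 + 0.4^2 = 0.52
  t1 <- haplotype_table(rbind(c(1, 1), c(0, 0)), c(0.6, 0.4), regAB)
  pr <- pairing_frequency(t1, "A", "B")
  expect_equal(pr$observed, 1.0)
  expect_equal(pr$expected, 0.52)

  # a gene paired with itself is always observed together
  expect_equal(pairing_frequency(t1, "A", "A")$observed, 1.0)

  # independence: observed == expected on a product-form table
  t2 <- haplotype_table(rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)),
                        c(0.3 * 0.7, 0.3 * 0.3, 0.7 * 0.7, 0.7 * 0.3), regAB)
  pi <- pairing_frequency(t2, "A", "B")
  expect_equal(pi$observed, pi$expected, tolerance = 1e-12)

  expect_error(pairing_frequency(t1, "A", "Z"), "unknown locus")
})

test_that("pairing frequency is symmetric and matches brute-force summation", {
  for (seed in 1:5) {
    tab <- random_haplotype_table(L = 4, k = 6, seed = seed)
    loci <- tab$registry$loci
    for (i in 1:3) for (j in (i + 1):4) {
      a <- loci[i]; b <- loci[j]
      pr <- pairing_frequency(tab, a, b)
      pr_rev <- pairing_frequency(tab, b, a)
      expect_equal(pr$observed, pr_rev$observed)
      expect_equal(pr$expected, pr_rev$expected)
      # brute force over haplotypes
      ha <- tab$haplotypes[, a]; hb <- tab$haplotypes[, b]; f <- tab$frequency
      obs <- sum(f[ha == 1 & hb == 1]) + sum(f[ha == 0 & hb == 0])
      pA <- sum(f[ha == 1]); pB <- sum(f[hb == 1])
      expect_equal(pr$observed, obs, tolerance = 1e-12)
      expect_equal(pr$expected, pA * pB + (1 - pA) * (1 - pB), tolerance = 1e-12)
    }
  }
})

test_that("Fisher two-tailed p matches enumeration on canonical tables", {
  expect_equal(fisher_two_tailed(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisher_two_tailed(matrix(c(10, 0, 0, 10), 2)),
               2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(fisher_two_tailed(matrix(c(1, 0, 0, 1), 2)), 1.0)
  expect_warning(p0 <- fisher_two_tailed(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero marginal")
  expect_equal(p0, 1.0)
})

test_that("Fisher p agrees with the hypergeometric oracle on random tables", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    cell <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    m <- matrix(cell, 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_two_tailed(m), oracle_fisher_two_tailed(m),
                 tolerance = 1e-9)
  }
})

test_that("fisher_ld reconstructs integer counts from frequencies", {
  # frequencies that are exact multiples of 1/20 reconstruct exactly
  t1 <- haplotype_table(rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)),
                        c(10, 0, 0, 10) / 20, regAB)
  expect_equal(fisher_ld(t1, "A", "B", 20), 2 / choose(20, 10),
               tolerance = 1e-10)
  # rounding keeps the total equal to hap_count
  t2 <- haplotype_table(rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)),
                        c(0.301, 0.199, 0.249, 0.251), regAB)
  expect_silent(p <- fisher_ld(t2, "A", "B", 26))
  expect_true(p > 0 && p <= 1)
})

test_that("association ratios: conditional-frequency normalization and AL", {
  # ref+g+: 0.35, ref+g-: 0.15, ref-g+: 0.05, ref-g-: 0.45 -> ratio 7
  t7 <- haplotype_table(rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0)),
                        c(0.35, 0.15, 0.05, 0.45), regAB)
  ar <- association_ratios(t7, "A")
  expect_equal(ar$ratio[ar$gene == "B"], 7.0)
  expect_equal(attr(ar, "n_ref_pos"), 0.50)

  # a gene on every haplotype has ratio 1
  reg3 <- locus_registry(c("R", "G", "F"))
  tfix <- haplotype_table(rbind(c(1, 1, 1), c(0, 0, 1)), c(0.4, 0.6), reg3)
  arf <- association_ratios(tfix, "R")
  expect_equal(arf$ratio[arf$gene == "F"], 1.0)

  # absolute linkage: gene present only with the reference
  expect_equal(arf$label[arf$gene == "G"], "AL")
  expect_equal(arf$ratio[arf$gene == "G"], Inf)

  # gene absent everywhere is undefined
  tz <- haplotype_table(rbind(c(1, 0, 0), c(0, 0, 1)), c(0.5, 0.5), reg3)
  arz <- association_ratios(tz, "R")
  expect_equal(arz$label[arz$gene == "G"], "undefined")

  # fixed reference is rejected
  expect_error(association_ratios(
    haplotype_table(rbind(c(1, 1), c(1, 0)), c(0.5, 0.5), regAB), "A"),
    "fixed")
})

test_that("declared absolute-linkage constraints co-segregate and are flagged", {
  reg3 <- locus_registry(c("R", "X", "Y"))
  tab <- haplotype_table(rbind(c(1, 1, 0), c(1, 0, 0), c(0, 0, 1)),
                        c(0.3, 0.3, 0.4), reg3)
  ar <- association_ratios(tab, "R", constraints = list(c("X", "Y")))
  expect_true(all(ar$constrained[ar$gene %in% c("X", "Y")]))
  # after forcing, X and Y have identical presence, hence identical ratios
  expect_equal(ar$ratio[ar$gene == "X"], ar$ratio[ar$gene == "Y"])
})

test_that("ratios are invariant under uniform frequency rescaling", {
  tab <- random_haplotype_table(L = 3, k = 5, seed = 77)
  ref <- tab$registry$loci[1]
  # renormalized copy (same ratios by construction)
  f2 <- tab$frequency * 5
  tab2 <- haplotype_table(tab$haplotypes, f2 / sum(f2), tab$registry)
  expect_equal(association_ratios(tab, ref)$ratio,
               association_ratios(tab2, ref)$ratio, tolerance = 1e-12)
})
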