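test_that("haplotype pool generation: degenerate, product and constraint cases", {
  regAB <- locus_registry(c("A", "B"))

  # one unit, presence probability 1 -> a single haplotype at frequency 1
  sp1 <- pool_spec("chimp", regAB,
                   units = list(u = list(loci = c("A", "B"), prob = 1)))
  ht1 <- simulate_haplotype_pool(sp1)
  expect_equal(nrow(ht1$haplotypes), 1L)
  expect_equal(unname(ht1$frequency), 1)

  # human-like cross product: (0.6, 0.4) x (0.5, 0.5) -> 0.30/0.30/0.20/0.20
  reg4 <- locus_registry(c("c1", "c2", "t1", "t2"),
                         region = c(c1 = "centromeric", c2 = "centromeric",
                                    t1 = "telomeric", t2 = "telomeric"))
  sph <- pool_spec("human", reg4,
                   cen_motifs = list(m1 = list(loci = "c1", freq = 0.6),
                                     m2 = list(loci = "c2", freq = 0.4)),
                   tel_motifs = list(m1 = list(loci = "t1", freq = 0.5),
                                     m2 = list(loci = "t2", freq = 0.5)))
  hth <- simulate_haplotype_pool(sph)
  expect_equal(sort(unname(hth$frequency)), c(0.2, 0.2, 0.3, 0.3))
  expect_equal(nrow(hth$haplotypes), 4L)

  # chimp-like pair constraint: constrained loci jointly present or absent
  spc <- pool_spec("chimp", regAB,
                   units = list(a = list(loci = "A", prob = 0.5),
                                b = list(loci = "B", prob = 0.3)),
                   pair_constraints = list(c("A", "B")))
  htc <- simulate_haplotype_pool(spc)
  expect_true(all(htc$haplotypes[, "A"] == htc$haplotypes[, "B"]))
  expect_equal(sum(htc$frequency), 1)

  expect_error(pool_spec("chimp", regAB, units = list()), "non-empty")
  expect_error(pool_spec("chimp", regAB,
                         units = list(u = list(loci = "Z", prob = 0.5))),
               "unknown locus")
})

test_that("default pool specs satisfy their structural claims", {
  for (ht in list(simulate_haplotype_pool(chimp_pool_spec()),
                  simulate_haplotype_pool(human_pool_spec()))) {
    expect_equal(sum(ht$frequency), 1, tolerance = 1e-12)
    expect_false(anyDuplicated(apply(ht$haplotypes, 1, paste, collapse = "")) > 0)
  }
  cht <- simulate_haplotype_pool(chimp_pool_spec())
  # absolute linkage between 2DL8 and 2DL5 is built in
  expect_true(all(cht$haplotypes[, "2DL8"] == cht$haplotypes[, "2DL5"]))
  # framework loci ride on every haplotype
  expect_true(all(cht$haplotypes[, "3DL3"] == 1))
})

test_that("genotype simulation pairs haplotypes under Hardy-Weinberg", {
  regAB <- locus_registry(c("A", "B"))
  one <- haplotype_table(rbind(c(1, 0)), 1, regAB)
  pan1 <- simulate_genotypes(one, 10, seed = 5)
  expect_true(all(pan1$matrix[, "A"] == 1) && all(pan1$matrix[, "B"] == 0))

  # two disjoint haplotypes at 0.5/0.5: P(carry both) = 2pq = 0.5
  two <- haplotype_table(rbind(c(1, 0), c(0, 1)), c(0.5, 0.5), regAB)
  pan2 <- simulate_genotypes(two, 4000, seed = 9)
  both <- mean(pan2$matrix[, "A"] == 1 & pan2$matrix[, "B"] == 1)
  expect_lt(abs(both - 0.5), 3 * sqrt(0.25 / 4000))

  # determinism and seed sensitivity
  expect_identical(simulate_genotypes(two, 50, seed = 3)$matrix,
                   simulate_genotypes(two, 50, seed = 3)$matrix)
  expect_false(identical(simulate_genotypes(two, 50, seed = 3)$matrix,
                         simulate_genotypes(two, 50, seed = 4)$matrix))
})

test_that("per-locus presence frequency converges to 1-(1-p)^2", {
  ht <- random_haplotype_table(L = 5, k = 4, seed = 21)
  pan <- simulate_genotypes(ht, 10000, seed = 22)
  p_hap <- colSums(ht$haplotypes * ht$frequency)
  expected <- 1 - (1 - p_hap)^2
  se <- sqrt(expected * (1 - expected) / 10000)
  observed <- colMeans(pan$matrix)
  expect_true(all(abs(observed - expected) <= pmax(3 * se, 1e-12)))
})

test_that("frequency-table simulation honours ranges, B46 flags and seeds", {
  pt <- list(KIR2DL1 = c(0.9, 0.9), KIR2DL2 = c(0.4, 0.4),
             KIR2DL3 = c(0.8, 0.8), C1 = c(0.6, 0.6), C2 = c(0.5, 0.5),
             B46 = c(0.1, 0.1))
  ft <- simulate_frequency_table(n_pops = 6, ranges = pt, seed = 1,
                                 b46_pops = "pop01")
  expect_true(all(ft$KIR2DL1 == 0.9) && all(ft$C2 == 0.5))
  expect_equal(ft$B46, c(0.1, rep(0, 5)))
  expect_equal(ft$b46_flagged, c(TRUE, rep(FALSE, 5)))

  ft0 <- simulate_frequency_table(n_pops = 4, b46_pops = character(0), seed = 2)
  expect_true(all(ft0$B46 == 0))

  expect_identical(simulate_frequency_table(seed = 7),
                   simulate_frequency_table(seed = 7))
  bad <- pt; bad$C1 <- c(0.9, 0.2)
  expect_error(simulate_frequency_table(n_pops = 3, ranges = bad, seed = 1),
               "inverted range")
})

test_that("tip-state simulation propagates the root state and placed events", {
  nwk <- "((A,B),(C,D));"

  st0 <- simulate_tip_states(nwk, list(), root_state = "E")
  expect_true(all(st0$states == "E"))

  st1 <- simulate_tip_states(
    nwk, list(list(edge = c("A", "B"), from = "E", to = "V")),
    root_state = "E")
  expect_equal(unname(st1$states[c("A", "B", "C", "D")]),
               c("V", "V", "E", "E"))

  # terminal-edge event on one tip
  st2 <- simulate_tip_states(
    nwk, list(list(edge = "C", from = "E", to = "V")), root_state = "E")
  expect_equal(sum(st2$states == "V"), 1L)

  expect_error(simulate_tip_states(
    nwk, list(list(edge = c("A", "C"), from = "E", to = "V")),
    root_state = "E"), "unknown edge")
  expect_error(simulate_tip_states(
    nwk, list(list(edge = "A", from = "E", to = "V"),
              list(edge = "A", from = "E", to = "K")),
    root_state = "E"), "contradictory")
  expect_error(simulate_tip_states(
    nwk, list(list(edge = "A", from = "V", to = "E")),
    root_state = "E"), "flows in")
})
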