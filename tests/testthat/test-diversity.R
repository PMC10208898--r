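test_that("per-site pi follows the unbiased heterozygosity formula", {
  # one SNP with j = 2 alt copies among m = 4 in a 1000-bp window:
  # per-site pi = 2 j (m - j) / (m (m - 1)) = 8/12 = 2/3 -> window 6.667e-4
  g <- matrix(c(1L, 1L), 2, 1)
  vm <- toy_vm(g, pos = 500L)
  pw <- windowPi(vm, c("s1", "s2"), windowSpec(1000, 1000),
                 chrom_lengths = c(chr1 = 1000))
  expect_equal(pw$pi, (2 / 3) / 1000)
  # monomorphic -> 0
  g0 <- matrix(c(2L, 2L), 2, 1)
  pw0 <- windowPi(toy_vm(g0, pos = 500L), c("s1", "s2"),
                  windowSpec(1000, 1000), chrom_lengths = c(chr1 = 1000))
  expect_equal(pw0$pi, 0)
  expect_error(windowPi(vm, "s1"), ">= 2 samples")
})

test_that("genome-wide pi matches the coalescent expectation E[pi] = theta", {
  sim <- simulateGenotypes(constantSizeModel(), c(P = 10), L = 1e6,
                           theta_site = 0.001, seed = 7)
  pw <- windowPi(sim$vm, sampleIds(sim$vm), windowSpec(1e6, 1e6),
                 chrom_lengths = c(chr1 = 1e6))
  expect_lt(abs(pw$pi / 0.001 - 1), 0.10)
})

test_that("window pi composes over non-overlapping tilings", {
  set.seed(3)
  g <- matrix(sample(c(0L, 1L, 2L), 8 * 60, TRUE), 8, 60)
  vm <- toy_vm(g, pos = sort(sample(1:4000, 60)))
  big <- windowPi(vm, sampleIds(vm), windowSpec(4000, 4000),
                  chrom_lengths = c(chr1 = 4000))
  small <- windowPi(vm, sampleIds(vm), windowSpec(1000, 1000),
                    chrom_lengths = c(chr1 = 4000))
  expect_equal(big$pi * 4000, sum(small$pi * 1000), tolerance = 1e-12)
})

test_that("sample heterozygosity is the het count over genome length", {
  g <- rbind(c(1L, 1L, 0L, 2L, 1L), c(0L, 0L, 0L, 0L, 0L),
             c(1L, NA, 2L, 1L, 0L))
  vm <- toy_vm(g)
  h <- sampleHeterozygosity(vm, 1000)
  expect_equal(unname(h), c(3, 0, 2) / 1000)
  expect_error(sampleHeterozygosity(vm, 0))
})

test_that("Weir-Cockerham FST matches a literal transcription of the 1984 formulas", {
  gA <- rbind(c(0L, 1L, 2L), c(0L, 2L, 2L), c(1L, 1L, 0L), c(0L, 0L, 1L))
  gB <- rbind(c(2L, 1L, 0L), c(2L, 2L, 1L), c(1L, 0L, 0L), c(2L, 1L, 1L))
  vm <- toy_vm(rbind(gA, gB))
  comp <- wcFstComponents(vm, paste0("s", 1:4), paste0("s", 5:8))
  oracle <- t(sapply(1:3, function(j) wc_oracle_site(gA[, j], gB[, j])))
  expect_equal(unname(comp), unname(oracle), tolerance = 1e-10)
  fst <- wcFstOverall(vm, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(fst, sum(oracle[, "a"]) / sum(oracle), tolerance = 1e-10)
})

test_that("FST endpoints: complete fixation gives 1, identical sets give ~0", {
  g <- rbind(matrix(0L, 4, 6), matrix(2L, 4, 6))
  vm <- toy_vm(g)
  expect_equal(wcFstOverall(vm, paste0("s", 1:4), paste0("s", 5:8)), 1)
  set.seed(9)
  g2 <- matrix(sample(0:2, 8 * 250, TRUE, prob = c(.5, .3, .2)), 8, 250)
  vm2 <- toy_vm(g2)
  # the two "populations" are overlapping draws from one pool
  expect_lt(abs(wcFstOverall(vm2, paste0("s", 1:4), paste0("s", 5:8))), 0.02)
})

test_that("FST is symmetric and invariant to sample order within pops", {
  set.seed(4)
  g <- matrix(sample(0:2, 10 * 40, TRUE), 10, 40)
  vm <- toy_vm(g)
  A <- paste0("s", 1:5); B <- paste0("s", 6:10)
  expect_identical(wcFstOverall(vm, A, B), wcFstOverall(vm, B, A))
  expect_identical(wcFstOverall(vm, sample(A), sample(B)),
                   wcFstOverall(vm, A, B))
  pwA <- windowPi(vm, A)
  pwA2 <- windowPi(vm, sample(A))
  expect_identical(pwA$pi, pwA2$pi)
})

test_that("windowed WC FST agrees with an allele-frequency oracle on an island model", {
  sim <- simulateGenotypes(twoPopModel(T = 5, m = 2), c(A = 8, B = 8),
                           L = 1e6, theta_site = 0.002, seed = 13)
  A <- popSamples(sim$pops, "A"); B <- popSamples(sim$pops, "B")
  wc <- wcFstOverall(sim$vm, A, B)
  hud <- hudson_fst(sim$vm, A, B)
  expect_lt(abs(wc - hud) / hud, 0.20)
})

test_that("ln pi-ratio handles identities, zeros and grid mismatches", {
  w <- data.frame(chrom = "c", start = c(1, 11), end = c(10, 20))
  a <- data.frame(w, n_sites = 1, pi = c(0.02, 0.01))
  b <- data.frame(w, n_sites = 1, pi = c(0.02, 0.01 / exp(1)))
  lr <- lnPiRatio(a, b)
  expect_equal(lr$ln_pi_ratio, c(0, 1))
  bz <- data.frame(w, n_sites = 1, pi = c(0, NA))
  expect_true(all(is.na(lnPiRatio(a, bz)$ln_pi_ratio)))
  w2 <- data.frame(chrom = "c", start = c(1, 21), end = c(10, 30))
  expect_error(lnPiRatio(a, data.frame(w2, n_sites = 1, pi = 1:2)), "grid")
})

test_that("half-decay distance is read off the smoothed binned curve", {
  # constructed curve: max 0.8 at distance 0, crosses 0.4 exactly at 12 kb
  d <- seq(0, 30000, by = 1000)
  r2 <- ifelse(d <= 12000, 0.8 - 0.4 * d / 12000, 0.25)
  r2[d == 12000] <- 0.4
  hd <- halfDecayDistance(d, r2)
  expect_equal(hd$max_r2, 0.8, tolerance = 1e-9)
  expect_equal(hd$half_decay_distance, 12000)
})

test_that("LD decay: duplicated sites give r2 = 1 in their distance bin", {
  set.seed(21)
  base <- sample(0:2, 40, TRUE)
  other <- replicate(10, sample(0:2, 40, TRUE))
  g <- cbind(base, other[, 1:5], base, other[, 6:10])
  # the duplicate pair sits at a distance (6300) no other pair shares
  vm <- toy_vm(g, pos = c(1000L, 2:6 * 1000L, 7300L, 8:12 * 1000L))
  curve <- ldDecay(vm, sampleIds(vm), max_dist = 50000, bin_width = 100)
  bin_dup <- curve$bins[abs(curve$bins$distance - 6250) < 50, ]
  expect_gte(max(bin_dup$mean_r2), 0.999)
})

test_that("LD decays with distance on a tiled-locus simulation", {
  sim <- simulateGenotypes(constantSizeModel(), c(P = 12), L = 4e5,
                           theta_site = 0.002, locus_len = 2000, seed = 31)
  curve <- ldDecay(sim$vm, sampleIds(sim$vm), max_dist = 20000,
                   bin_width = 1000)
  sm <- halfDecayDistance(curve$bins$distance, curve$bins$mean_r2)$smoothed
  expect_true(all(diff(sm$r2) <= 1e-12))
  # linked (within-locus) pairs are more correlated than distant pairs
  expect_gt(curve$bins$mean_r2[1], curve$bins$mean_r2[nrow(curve$bins)])
  expect_error(ldDecay(vm <- toy_vm(matrix(c(0L, 1L, 1L, 2L), 2)),
                       c("s1", "s2"), max_dist = 10), "no SNP pair")
})
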