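# manual FoldedSFS over one population of n allele copies
sfs1d <- function(counts_by_minor, n) {
  cells <- n + 1
  cnt <- rep(0, cells)
  cnt[seq_along(counts_by_minor) + 1] <- counts_by_minor
  msk <- sapply(0:n, function(d) d == 0 || d > n - d)
  cnt[msk] <- 0
  new("FoldedSFS", counts = array(cnt, cells), mask = array(msk, cells),
      dims = as.integer(n))
}

test_that("folded SFS construction places counts in the right cells", {
  # 2 + 2 diploids (4 + 4 copies); one singleton private to pop1 -> cell (1,0)
  g <- rbind(a1 = 1L, a2 = 0L, b1 = 0L, b2 = 0L)
  pops <- PopulationMap(c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  sfs <- buildFoldedSfs(toy_vm(g), pops, c("A", "B"))
  expect_equal(sfs@dims, c(4L, 4L))
  expect_equal(sfsCounts(sfs)[2, 1], 1)
  expect_equal(nSnps(sfs), 1)
  # a site with one missing call is excluded (complete-case rule)
  g2 <- cbind(c(1L, 0L, 0L, 0L), c(NA, 1L, 0L, 0L))
  rownames(g2) <- names(pops@assignments)
  sfs2 <- buildFoldedSfs(toy_vm(g2), pops, c("A", "B"))
  expect_equal(nSnps(sfs2), 1)
})

test_that("a 12-site toy panel folds to the hand tally", {
  # 3 + 3 diploids; alt counts per (pop1, pop2) chosen by hand
  d1 <- c(1, 2, 3, 6, 5, 0, 0, 3, 4, 1, 2, 6)
  d2 <- c(0, 1, 3, 6, 6, 2, 1, 4, 3, 0, 1, 5)
  # expected folded cells (total <= 6 keeps, else conjugate):
  fold <- function(a, b) if (a + b > 6 || (a + b == 6 && a > 6 - a)) {
    c(6 - a, 6 - b) } else c(a, b)
  spread <- function(d) {
    v <- c(rep(2L, d %/% 2), rep(1L, d %% 2))
    c(v, rep(0L, 3 - length(v)))
  }
  g <- mapply(function(a, b) c(spread(a), spread(b)), d1, d2)
  rownames(g) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  pops <- PopulationMap(structure(rep(c("A", "B"), each = 3),
                                  names = rownames(g)))
  sfs <- buildFoldedSfs(toy_vm(g), pops, c("A", "B"))
  poly <- which(d1 + d2 > 0 & d1 + d2 < 12)
  tallied <- table(vapply(poly, function(i)
    paste(fold(d1[i], d2[i]), collapse = ","), character(1)))
  for (k in names(tallied)) {
    ij <- as.integer(strsplit(k, ",")[[1]])
    expect_equal(sfsCounts(sfs)[ij[1] + 1, ij[2] + 1],
                 as.numeric(tallied[[k]]), label = k)
  }
  expect_equal(nSnps(sfs), sum(d1 + d2 > 0 & d1 + d2 < 12))
})

test_that("expected SFS matches the analytic constant-size spectrum", {
  e <- expectedSfs(constantSizeModel(), 4L, n_reps = 30000, seed = 42)
  v <- as.numeric(sfsCounts(e)[!sfsMask(e)])
  expect_equal(v / sum(v), c(8, 3) / 11, tolerance = 0.03)
  # unfolded: per-unit-theta expectation is 1/i
  eu <- expectedSfs(constantSizeModel(), 4L, n_reps = 30000, seed = 42,
                    fold = FALSE)
  expect_equal(as.numeric(sfsCounts(eu)[2:4]), c(1, 1 / 2, 1 / 3), tolerance = 0.05)
})

test_that("folding the unfolded expectation reproduces the folded one", {
  eu <- expectedSfs(constantSizeModel(), 6L, n_reps = 20000, seed = 9,
                    fold = FALSE)
  ef <- expectedSfs(constantSizeModel(), 6L, n_reps = 20000, seed = 9)
  f <- PopGenFlow:::.fold_array(sfsCounts(eu), 6L)
  expect_equal(f$counts, sfsCounts(ef))
  expect_equal(f$mask, sfsMask(ef))
})

test_that("a vanishing split time collapses to the single-population spectrum", {
  e2 <- expectedSfs(twoPopModel(T = 1e-5), c(4L, 4L), n_reps = 40000,
                    seed = 3, fold = FALSE)
  e1 <- expectedSfs(constantSizeModel(), 8L, n_reps = 40000, seed = 4,
                    fold = FALSE)
  diag_sum <- vapply(1:7, function(k) {
    cells <- PopGenFlow:::.sfs_cells(c(4L, 4L))
    sum(sfsCounts(e2)[rowSums(cells) == k])
  }, numeric(1))
  expect_equal(diag_sum, as.numeric(sfsCounts(e1)[2:8]), tolerance = 0.06)
})

test_that("a symmetric island model yields an exchange-symmetric expectation", {
  e <- expectedSfs(twoPopModel(T = 5, m = 2), c(4L, 4L), n_reps = 60000,
                   seed = 8, fold = FALSE)
  m <- sfsCounts(e)
  expect_equal(m, t(m), tolerance = 0.08)
})

test_that("composite log-likelihood follows the Poisson formula", {
  # 3 informative cells: obs (2,1,1), exp (0.5,0.25,0.25), theta 4
  obs <- sfs1d(c(2, 1, 1), 6)
  ex <- sfs1d(c(0.5, 0.25, 0.25), 6)
  hand <- sum(c(2, 1, 1) * log(4 * c(.5, .25, .25)) - 4 * c(.5, .25, .25) -
                lfactorial(c(2, 1, 1)))
  expect_equal(compositeLoglik(obs, ex, 4), hand)
  # saturated case: obs = theta * exp maximizes over theta
  o <- c(8, 4, 2)
  obs2 <- sfs1d(o, 6); ex2 <- sfs1d(o / 2, 6)
  expect_equal(thetaHat(obs2, ex2), 2)
  expect_equal(compositeLoglik(obs2, ex2, 2), sum(o * log(o) - o - lfactorial(o)))
  expect_lt(compositeLoglik(obs2, ex2, 4), compositeLoglik(obs2, ex2, 2))
  expect_lt(compositeLoglik(obs2, ex2, 1), compositeLoglik(obs2, ex2, 2))
  # empty expectation cell with positive observation is floored with warning
  ex3 <- sfs1d(c(0.5, 0, 0.5), 6)
  expect_warning(compositeLoglik(obs, ex3, 4), "floored")
})

test_that("profiled theta matches a numeric 1-D optimization", {
  set.seed(2)
  obs <- sfs1d(rpois(3, c(50, 30, 10)), 6)
  ex <- sfs1d(c(1, 0.5, 0.33), 6)
  th <- thetaHat(obs, ex)
  num <- optimize(function(t) -compositeLoglik(obs, ex, t),
                  interval = c(1, 200))$minimum
  expect_equal(th, num, tolerance = 1e-6)
})

test_that("AIC is 2k - 2 loglik, bit-stable on stored fits", {
  expect_identical(aic(-418444, 8), 836904)
  expect_identical(aic(0, 1), 2)
  expect_equal(aic(-10.5, 3), 27)
  f <- new("FitResult", model = "x", family = "y",
           params = c(nu = 1), theta = 2, loglik = -10.5, k = 3L,
           aic = aic(-10.5, 3), converted = list())
  expect_identical(f@aic, 2 * f@k - 2 * f@loglik)
  expect_error(aic(0, 0))
})

test_that("fitModel is self-consistent on the constant-size model", {
  mod <- constantSizeModel()
  e <- expectedSfs(mod, 8L, n_reps = 40000, seed = 17)
  theta_true <- 5000
  obs_cnt <- theta_true * sfsCounts(e)
  obs <- new("FoldedSFS", counts = obs_cnt, mask = sfsMask(e), dims = 8L)
  fit <- fitModel(mod, obs, n_starts = 8, maxiter = 40, seed = 5,
                  n_reps = 40000)
  # nu and theta are jointly identified only through their product
  expect_lt(abs(fit@theta * fit@params[["nu"]] / theta_true - 1), 0.01)
  expect_equal(fit@k, 2L)
  expect_identical(fit@aic, aic(fit@loglik, fit@k))
})

test_that("best-of-starts never loses to a single start", {
  mod <- constantSizeModel()
  e <- expectedSfs(mod, 6L, n_reps = 5000, seed = 17)
  obs <- new("FoldedSFS", counts = round(1000 * sfsCounts(e)),
             mask = sfsMask(e), dims = 6L)
  f1 <- fitModel(mod, obs, n_starts = 1, maxiter = 10, seed = 3, n_reps = 5000)
  f5 <- fitModel(mod, obs, n_starts = 5, maxiter = 10, seed = 3, n_reps = 5000)
  expect_gte(f5@loglik, f1@loglik - 1e-9)
})

test_that("unit conversion follows Ne = theta / (4 mu L)", {
  const <- unitConstants(mu = 3.75e-8, gen_time = 15, L = 370.75e6)
  expect_equal(4 * const$mu * const$L, 55.6125)
  f <- new("FitResult", model = "m", family = "f",
           params = c(nu1 = 2, T2 = 0.5), theta = 55.6125, loglik = -1,
           k = 3L, aic = aic(-1, 3), converted = list())
  fc <- convertUnits(f, const)
  expect_equal(fc@converted$N_ref, 1)
  f2 <- initialize(f, theta = 55.6125 * 1e4)
  fc2 <- convertUnits(f2, const)
  expect_equal(fc2@converted$N_ref, 1e4)
  expect_equal(fc2@converted$Ne_nu1, 2e4)
  expect_equal(fc2@converted$T2_years, 2 * 1e4 * 0.5 * 15)
})

test_that("model ranking sorts by AIC with documented tie-breaking", {
  mk <- function(id, ll, k) new("FitResult", model = id, family = "f",
                                params = c(nu = 1), theta = 1, loglik = ll,
                                k = as.integer(k), aic = aic(ll, k),
                                converted = list())
  rk <- selectModel(list(mk("a", -45, 5), mk("b", -45, 10)))
  expect_equal(rk$model, c("a", "b"))
  expect_equal(rk$delta_aic, c(0, 10))
  # equal AIC: fewer parameters wins, then id
  rk2 <- selectModel(list(mk("z", -51, 4), mk("y", -50, 5)))
  expect_equal(rk2$model[1], "z")
  rk3 <- selectModel(list(mk("z", -50, 5), mk("y", -50, 5)))
  expect_equal(rk3$model[1], "y")
})

test_that("the model registry ships 17 buildable configurations in 5 families", {
  reg <- modelRegistry()
  expect_length(reg, 17)
  expect_setequal(unique(vapply(reg, function(m) m@family, character(1))),
                  c("divergence_with_gene_flow", "ancient_migration",
                    "secondary_contact", "simultaneous_split",
                    "hybrid_origin"))
  for (m in reg) {
    ep <- modelEpochs(m)
    ends <- vapply(ep, function(e) e$end, numeric(1))
    expect_true(all(diff(ends) >= 0) && is.infinite(ends[length(ends)]),
                label = m@id)
  }
  # k = 8 for the flagship secondary-contact configuration (7 + theta)
  expect_length(reg$m09_sc_adjacent_sym@params, 7)
})

test_that("SFS text serialization round-trips", {
  e <- expectedSfs(twoPopModel(), c(4L, 4L), n_reps = 2000, seed = 1)
  p <- tempfile(fileext = ".fs")
  writeSfs(e, p)
  e2 <- readSfs(p)
  expect_equal(sfsCounts(e2), sfsCounts(e))
  expect_equal(sfsMask(e2), sfsMask(e))
  expect_equal(e2@dims, e@dims)
})

test_that("non-nested epoch times are rejected", {
  bad <- demographicModel("bad", "x", c(T2 = 0.2, dT = -0.1, nu3 = 1),
                          c(T2 = 1e-4, dT = -1, nu3 = 1e-3),
                          c(T2 = 10, dT = 10, nu3 = 50),
                          function(p) PopGenFlow:::.nested_epochs(
                            p, list(PopGenFlow:::.epoch(p[["T2"]], c(1, 1, 1),
                                                        PopGenFlow:::.mig3(),
                                    move = PopGenFlow:::.join(2, 1))),
                            PopGenFlow:::.mig3()))
  expect_error(expectedSfs(bad, c(2L, 2L, 2L), 100, 1), "nested")
})

test_that("parametric bootstrap intervals cover the generating parameters", {
  mod <- constantSizeModel()
  e <- expectedSfs(mod, 6L, n_reps = 30000, seed = 19)
  obs <- new("FoldedSFS", counts = round(3000 * sfsCounts(e)),
             mask = sfsMask(e), dims = 6L)
  fit <- fitModel(mod, obs, n_starts = 4, maxiter = 30, seed = 3,
                  n_reps = 20000)
  ci <- bootstrapFit(mod, fit, obs, n_boot = 4, seed = 5, n_starts = 2,
                     maxiter = 20, n_reps = 20000)
  expect_equal(dim(ci), c(1L, 3L))
  expect_lte(ci["nu", "lower"], ci["nu", "estimate"])
  expect_gte(ci["nu", "upper"], ci["nu", "estimate"])
})
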