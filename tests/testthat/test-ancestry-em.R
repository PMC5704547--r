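test_that("log-likelihood matches closed-form hand evaluations", {
  # K=1, M=1, f=0.5, g=1: ln(0.5) + ln(0.5)
  expect_equal(ancestryLogLik(1, 1L, matrix(0.5, 1, 1)), 2 * log(0.5))
  # K=2, q=(.5,.5), f column (0.9, 0.1): mixture p = 0.5, g=2 -> 2 ln(0.5)
  expect_equal(ancestryLogLik(c(0.5, 0.5), 2L, matrix(c(0.9, 0.1), 2, 1)),
               2 * log(0.5))
  # all markers missing: empty sum is 0
  expect_equal(ancestryLogLik(c(0.5, 0.5), c(NA_integer_, NA_integer_),
                              matrix(0.3, 2, 2)), 0)
  expect_error(ancestryLogLik(c(0.5, 0.5), c(1L, 1L), matrix(0.3, 2, 3)),
               "dimension mismatch")
})

test_that("EM update solves fully-informative cases and preserves fixed points", {
  # fixed-different panel, individual homozygous for pop-1 allele
  f <- matrix(rep(c(1, 0), 5), nrow = 2)
  g <- rep(2L, 5)
  q1 <- emStep(c(0.5, 0.5), g, f)
  expect_equal(q1, c(1, 0), tolerance = 1e-4)  # within the 1e-6 clamp
  # stationary point stays put
  f2 <- matrix(runif(2 * 6), 2, 6)
  set.seed(5)
  q <- c(0.3, 0.7)
  g2 <- rbinom(6, 2, as.vector(q %*% f2))
  qstar <- q
  for (i in 1:2000) qstar <- emStep(qstar, g2, f2)
  expect_equal(emStep(qstar, g2, f2), qstar, tolerance = 1e-12)
})

test_that("E-step responsibilities normalize over populations", {
  set.seed(9)
  f <- matrix(runif(3 * 8), 3, 8)
  r <- admixscreen:::emResponsibilities(c(0.2, 0.3, 0.5), rbinom(8, 2, 0.5), f)
  expect_equal(colSums(r$a), rep(1, 8))
  expect_equal(colSums(r$b), rep(1, 8))
})

test_that("log-likelihood is non-decreasing and q stays on the simplex (100 seeded instances)", {
  for (seed in 1:100) {
    inst <- randomInstance(K = sample(2:4, 1), M = sample(5:30, 1), seed = seed)
    K <- nrow(inst$f)
    q <- rep(1 / K, K)
    ll <- ancestryLogLik(q, inst$g, inst$f)
    for (it in 1:25) {
      q <- emStep(q, inst$g, inst$f)
      expect_equal(sum(q), 1, tolerance = 1e-9)
      expect_true(all(q >= 0))
      llnew <- ancestryLogLik(q, inst$g, inst$f)
      expect_gte(llnew, ll - 1e-10)
      ll <- llnew
    }
  }
})

test_that("missing dosages are skipped with adjusted normalization", {
  set.seed(13)
  f <- matrix(runif(2 * 10), 2, 10)
  g <- rbinom(10, 2, 0.5)
  gmiss <- as.integer(g); gmiss[c(3, 7)] <- NA
  q1 <- emStep(c(0.5, 0.5), gmiss, f)
  expect_equal(sum(q1), 1, tolerance = 1e-12)
  # equals the update computed on the observed subset alone
  q2 <- emStep(c(0.5, 0.5), as.integer(g[-c(3, 7)]), f[, -c(3, 7)])
  expect_equal(q1, q2)
})

test_that("EM optimum agrees with direct simplex-constrained maximization", {
  for (seed in 1:20) {
    inst <- randomInstance(K = sample(2:3, 1), M = sample(5:20, 1), seed = 400 + seed)
    K <- nrow(inst$f)
    q <- rep(1 / K, K)
    ll <- ancestryLogLik(q, inst$g, inst$f)
    repeat {
      q <- emStep(q, inst$g, inst$f)
      llnew <- ancestryLogLik(q, inst$g, inst$f)
      if (llnew - ll < 1e-13) break
      ll <- llnew
    }
    ll_em <- ancestryLogLik(q, inst$g, inst$f)
    ll_direct <- oracleMaxLoglik(inst$g, inst$f)
    expect_lt(abs(ll_em - ll_direct), 1e-4)
  }
})

test_that("estimateAncestry recovers pure and symmetric ancestries", {
  M <- 60
  f <- matrix(rep(c(0.999, 0.001), M), nrow = 2,
              dimnames = list(c("P1", "P2"), sprintf("m%03d", 1:M)))
  fp <- FrequencyPanel(f, allele1 = rep("A", M),
                       continentalGroup = c("P1", "P2"))
  pure <- matrix(2L, M, 1, dimnames = list(colnames(f), "pureS"))
  gm <- GenotypeMatrix(pure, allele1 = rep("A", M))
  est <- estimateAncestry(gm, fp, epsilon = 1e-8)
  expect_equal(unname(ancestryProportions(est)[1, ]), c(1, 0), tolerance = 1e-3)
  expect_identical(as.character(maxAncestralGroup(est)), "P1")

  # half pop-1-homozygous, half pop-2-homozygous -> (0.5, 0.5)
  half <- matrix(c(rep(2L, M / 2), rep(0L, M / 2)), M, 1,
                 dimnames = list(colnames(f), "mix"))
  gm2 <- GenotypeMatrix(half, allele1 = rep("A", M))
  est2 <- estimateAncestry(gm2, fp, epsilon = 1e-10, maxIter = 5000)
  expect_equal(unname(ancestryProportions(est2)[1, ]), c(0.5, 0.5),
               tolerance = 1e-3)
})

test_that("K=1 returns q = 1 immediately; unusable samples are flagged", {
  fp <- FrequencyPanel(matrix(0.4, 1, 3, dimnames = list("P1", paste0("m", 1:3))),
                       allele1 = rep("A", 3))
  d <- matrix(c(1L, 2L, 0L, NA, NA, NA), 3, 2,
              dimnames = list(paste0("m", 1:3), c("ok", "empty")))
  gm <- GenotypeMatrix(d, allele1 = rep("A", 3))
  expect_warning(est <- estimateAncestry(gm, fp), "zero non-missing")
  expect_equal(unname(ancestryProportions(est)["ok", ]), 1)
  expect_identical(unname(emIterations(est)["ok"]), 1L)
  expect_true(is.na(emConverged(est)["empty"]))
  expect_true(all(is.na(ancestryProportions(est)["empty", ])))
})

test_that("ties in maxAncestralGroup break to the first group and are flagged", {
  x <- c(A = 0.5, B = 0.5)
  mg <- maxAncestralGroup(x)
  expect_identical(as.character(mg), "A")
  expect_true(attr(mg, "tied"))
  y <- c(A = 0.79, B = 0.12, C = 0.09)
  expect_identical(as.character(maxAncestralGroup(y)), "A")
  expect_false(attr(maxAncestralGroup(y), "tied"))
})

test_that("recovery error shrinks as the marker panel grows", {
  mae <- vapply(c(100, 400), function(M) {
    panel <- simulatePanel(K = 4, M = M, seed = 500 + M)
    sim <- simulateCohort(panel, n = 60, dirichletAlpha = 1, seed = 600 + M)
    est <- estimateAncestry(sim$genotypes, panel)
    mean(abs(ancestryProportions(est) - sim$Q))
  }, 0)
  expect_lt(mae[2], mae[1])
})

test_that("cohort-scope convergence matches per-sample estimates closely", {
  panel <- simulatePanel(K = 3, M = 150, seed = 71)
  sim <- simulateCohort(panel, n = 15, seed = 72)
  e1 <- estimateAncestry(sim$genotypes, panel, epsilon = 1e-6)
  e2 <- estimateAncestry(sim$genotypes, panel, epsilon = 1e-6,
                         convergenceScope = "cohort")
  expect_equal(ancestryProportions(e1), ancestryProportions(e2),
               tolerance = 1e-2)
  expect_true(all(emConverged(e2)))
})
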