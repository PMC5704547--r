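test_that("qcFilter drops low-coverage populations and low-call-rate markers", {
  set.seed(42)
  M <- 20
  f <- matrix(runif(3 * M), 3, M,
              dimnames = list(c("P1", "P2", "P3"), sprintf("m%02d", 1:M)))
  f["P3", 1:15] <- NA                    # 25% coverage -> dropped
  f["P1", 1] <- NA                       # m01 still missing after drop
  d <- matrix(1L, M, 100, dimnames = list(colnames(f), sprintf("s%03d", 1:100)))
  d[2, 1] <- NA                          # m02 call rate 0.99 < 0.999 -> dropped
  gm <- GenotypeMatrix(d, allele1 = rep("A", M))
  fp <- FrequencyPanel(f, allele1 = rep("A", M))
  qc <- qcFilter(fp, gm)
  expect_identical(populationIds(qc$panel), c("P1", "P2"))
  expect_false(any(c("m01", "m02") %in% markerIds(qc$panel)))
  expect_identical(markerIds(qc$panel), markerIds(qc$genotypes))
  expect_false(anyNA(freq(qc$panel)))

  # fully complete inputs pass through unchanged
  f2 <- matrix(runif(2 * 4), 2, 4, dimnames = list(c("A", "B"), paste0("x", 1:4)))
  gm2 <- GenotypeMatrix(matrix(1L, 4, 5, dimnames = list(colnames(f2), paste0("s", 1:5))),
                        allele1 = rep("A", 4))
  fp2 <- FrequencyPanel(f2, allele1 = rep("A", 4))
  qc2 <- qcFilter(fp2, gm2)
  expect_equal(freq(qc2$panel), f2)
  expect_identical(dosage(qc2$genotypes), dosage(gm2))

  # everything below coverage -> error
  fp3 <- FrequencyPanel(matrix(NA_real_, 1, 4,
                               dimnames = list("P", colnames(f2))),
                        allele1 = rep("A", 4))
  expect_error(qcFilter(fp3, gm2), "all populations dropped")
})

test_that("continental frequencies are unweighted means of member populations", {
  f <- matrix(c(0.2, 0.8, 0.6), 3, 1, dimnames = list(c("a", "b", "c"), "m1"))
  fp <- FrequencyPanel(f, allele1 = "A",
                       continentalGroup = c("G1", "G2", "G2"))
  out <- continentalFrequencies(fp)
  expect_equal(unname(freq(out)[, "m1"]), c(0.2, 0.7))
  expect_identical(populationIds(out), c("G1", "G2"))

  # single population per group is the identity
  fp1 <- FrequencyPanel(f, allele1 = "A",
                        continentalGroup = c("G1", "G2", "G3"))
  expect_equal(unname(freq(continentalFrequencies(fp1))), unname(f))

  fp2 <- FrequencyPanel(f, allele1 = "A")
  expect_error(continentalFrequencies(fp2), "continental group label")
})

test_that("Wright's Fst matches hand values and its invariances", {
  expect_equal(wrightFst(c(1, 0)), 1)             # fixed difference
  expect_equal(wrightFst(c(0.3, 0.3, 0.3)), 0)    # no differentiation
  expect_equal(wrightFst(c(0.2, 0.8)), 0.36)      # H_T=0.5, H_S=0.32
  expect_equal(wrightFst(c(0, 0)), 0)             # monomorphic: H_T=0
  set.seed(7)
  for (rep in 1:25) {
    p <- runif(sample(2:6, 1))
    fst <- wrightFst(p)
    expect_gte(fst, 0); expect_lte(fst, 1)
    # allele relabeling invariance
    expect_equal(wrightFst(1 - p), fst)
    # zero iff all frequencies equal
    expect_identical(fst == 0, isTRUE(all.equal(max(p), min(p))))
  }
})

test_that("LD pruning removes duplicated markers and matches the all-pairs oracle", {
  set.seed(11)
  # two identical markers: the later one is removed
  d <- rbind(m1 = rbinom(30, 2, 0.5), m2 = 0L)
  d["m2", ] <- d["m1", ]
  gm <- GenotypeMatrix(matrix(as.integer(d), 2, 30,
                              dimnames = list(c("m1", "m2"), paste0("s", 1:30))),
                       allele1 = c("A", "A"))
  expect_identical(ldPrune(gm, windowSize = 10), "m1")

  # hand-built correlated block vs exhaustive greedy oracle
  for (seed in c(1, 2, 3)) {
    set.seed(seed)
    M <- 40; n <- 60
    base <- matrix(rbinom(M * n, 2, 0.5), M, n)
    # induce LD: every 4th marker copies its predecessor with noise
    for (m in seq(4, M, by = 4))
      base[m, ] <- ifelse(runif(n) < 0.9, base[m - 1, ], rbinom(n, 2, 0.5))
    dn <- list(sprintf("m%02d", 1:M), sprintf("s%02d", 1:n))
    gm <- GenotypeMatrix(matrix(as.integer(base), M, n, dimnames = dn),
                         allele1 = rep("A", M))
    kept <- ldPrune(gm, r2Threshold = 0.5, windowSize = 8, step = 1)
    expect_identical(kept, oracleLdPrune(dosage(gm), 0.5, 8))
    # no retained within-window pair exceeds the threshold
    idx <- match(kept, dn[[1]])
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a || idx[b] - idx[a] >= 8) next
      r <- cor(base[idx[a], ], base[idx[b], ])
      expect_lte(if (is.na(r)) 0 else r^2, 0.5)
    }
  }
})

test_that("independent markers survive pruning; missing-heavy pairs are kept", {
  set.seed(21)
  M <- 60; n <- 400
  d <- matrix(rbinom(M * n, 2, runif(M, 0.2, 0.8)), M, n)
  gm <- GenotypeMatrix(matrix(as.integer(d), M, n,
                              dimnames = list(sprintf("m%02d", 1:M),
                                              sprintf("s%03d", 1:n))),
                       allele1 = rep("A", M))
  expect_gte(length(ldPrune(gm, windowSize = 20)), M - 2)

  # <2 complete observations -> r2 treated as 0, both markers kept
  d2 <- matrix(NA_integer_, 2, 4, dimnames = list(c("m1", "m2"), paste0("s", 1:4)))
  d2[1, 1:2] <- c(0L, 2L); d2[2, 3:4] <- c(0L, 2L)
  gm2 <- GenotypeMatrix(d2, allele1 = c("A", "A"))
  expect_identical(ldPrune(gm2, windowSize = 10), c("m1", "m2"))
})

test_that("two-stage AIM selection equals the brute-force full-sort oracle", {
  set.seed(31)
  G <- 8; M <- 5000
  f <- matrix(rbeta(G * M, 0.5, 0.5), G, M,
              dimnames = list(paste0("GRP", 1:G), sprintf("mk%05d", 1:M)))
  fp <- FrequencyPanel(f, allele1 = rep("A", M),
                       continentalGroup = paste0("GRP", 1:G))
  sel <- selectAims(fp, nGlobal = 600, nPerPair = 20)
  expect_identical(sort(sel$markers), sort(oracleSelectAims(f, 600, 20)))
  # contains the stage-1 set exactly
  gl <- sel$fst$global_fst
  stage1 <- sel$fst$marker_id[order(-gl, sel$fst$marker_id)][1:600]
  expect_true(all(stage1 %in% sel$markers))
  # size bound after dedup
  expect_lte(length(sel$markers), 600 + 20 * choose(G, 2))
  # output order: descending global Fst, ties by id
  got <- gl[match(sel$markers, sel$fst$marker_id)]
  expect_true(all(diff(got) <= 1e-12))
})

test_that("AIM selection handles degenerate configurations", {
  # m3 is fixed-different between exactly the pair A|B; m0 dominates the
  # global ranking so m3 can only enter through stage 2
  f <- matrix(0.5, 3, 4, dimnames = list(c("A", "B", "C"),
                                         c("m0", "m1", "m2", "m3")))
  f[, "m0"] <- c(0, 1, 1)                     # global Fst = 1
  f[, "m3"] <- c(1, 0, 0.5)                   # A|B separator
  f[, "m1"] <- c(0.4, 0.5, 0.6)
  fp <- FrequencyPanel(f, allele1 = rep("A", 4),
                       continentalGroup = c("A", "B", "C"))
  sel <- selectAims(fp, nGlobal = 1, nPerPair = 1)
  expect_true("m3" %in% sel$markers)
  expect_gt(sel$fst[sel$fst$marker_id == "m3", "A|B"], 0.99)
  # n_global = all markers returns everything
  sel_all <- selectAims(fp, nGlobal = 4, nPerPair = 0)
  expect_setequal(sel_all$markers, c("m0", "m1", "m2", "m3"))
  expect_error(selectAims(fp, nGlobal = 10, nPerPair = 0), "exceeds")
})
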