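# Shared fixtures and independent oracles. Fixtures are built in code at
# test time; oracles are brute-force reimplementations kept deliberately
# separate from the package's own code paths.

writeTempLines <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# 2-marker, 3-sample VCF (GT only), rs2 has a missing call
fixtureVcf <- function() {
  writeTempLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1\t0/0",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/1\t1/1"
  ), ".vcf")
}

fixtureVcfMultiallelic <- function() {
  writeTempLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1",
    "1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT\t1/2"
  ), ".vcf")
}

# 3-sample x 2-marker genotype TSV with stated entries
fixtureGenotypeTsv <- function() {
  writeTempLines(c(
    "marker_id\tallele1\tallele2\ts1\ts2\ts3",
    "rs1\tA\tG\t0\t1\t2",
    "rs2\tC\tT\t2\tNA\t1"
  ), ".tsv")
}

smallGenotypeMatrix <- function() {
  GenotypeMatrix(matrix(c(0L, 2L, 1L, NA, 2L, 1L), nrow = 2,
                        dimnames = list(c("rs1", "rs2"), c("s1", "s2", "s3"))),
                 allele1 = c("A", "C"), allele2 = c("G", "T"))
}

smallFrequencyPanel <- function() {
  FrequencyPanel(matrix(c(0.1, 0.9, 0.5, 0.2), nrow = 2,
                        dimnames = list(c("P1", "P2"), c("rs1", "rs2"))),
                 allele1 = c("A", "C"),
                 continentalGroup = c("G1", "G2"))
}

metadataRow <- function(id, form, consult, has_consult = TRUE,
                        excluded = FALSE, disease = list()) {
  out <- data.frame(sample_id = id, stringsAsFactors = FALSE)
  out$form <- list(form)
  out$consult <- list(consult)
  out$has_consult <- has_consult
  out$excluded <- excluded
  for (d in names(disease))
    out[[d]] <- factor(disease[[d]], levels = c("carrier", "non-carrier", "untested"))
  out
}

bindMetadata <- function(..., diseases = character()) {
  out <- do.call(rbind, list(...))
  attr(out, "diseases") <- diseases
  out
}

## ---- independent oracles ----

# exact McNemar by exhaustive enumeration of all 2^n discordant outcomes
oracleMcnemar <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  lo <- min(b, c)
  outcomes <- 0:n
  counts <- choose(n, outcomes)
  min(1, 2 * sum(counts[outcomes <= lo]) / 2^n)
}

# two-sided Fisher p by full hypergeometric enumeration (point-prob rule)
oracleFisher <- function(a, b, c, d) {
  m <- a + c; n2 <- b + d; k <- a + b
  xs <- max(0, k - n2):min(k, m)
  probs <- dhyper(xs, m, n2, k)
  pobs <- dhyper(a, m, n2, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# two-sided exact Mann-Whitney by complete enumeration of group
# assignments (no ties assumed)
oracleMannWhitney <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  Uobs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  Us <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (n - n1) / 2
  mean(abs(Us - mu) >= abs(Uobs - mu) - 1e-9)
}

# quadratic-time LD pruning oracle: greedy left-to-right over all pairs
# within `windowSize` of each other (step 1)
oracleLdPrune <- function(d, r2Threshold, windowSize) {
  M <- nrow(d)
  keep <- rep(TRUE, M)
  for (j in seq_len(M)[-1]) {
    for (i in seq_len(j - 1)) {
      if (!keep[i] || !keep[j] || (j - i) >= windowSize) next
      r <- suppressWarnings(stats::cor(d[i, ], d[j, ],
                                       use = "pairwise.complete.obs"))
      r2 <- if (is.na(r)) 0 else r^2
      if (r2 > r2Threshold) keep[j] <- FALSE
    }
  }
  rownames(d)[keep]
}

# full-sort AIM selection oracle
oracleSelectAims <- function(f, nGlobal, nPerPair) {
  fstv <- function(ff) {
    pbar <- colMeans(ff); ht <- 2 * pbar * (1 - pbar)
    hs <- colMeans(2 * ff * (1 - ff))
    ifelse(ht == 0, 0, (ht - hs) / ht)
  }
  ids <- colnames(f)
  gl <- fstv(f)
  sel <- ids[order(-gl, ids)][seq_len(nGlobal)]
  for (pr in utils::combn(rownames(f), 2, simplify = FALSE)) {
    pw <- fstv(f[pr, , drop = FALSE])
    cand <- setdiff(ids[order(-pw, ids)], sel)
    sel <- c(sel, cand[seq_len(nPerPair)])
  }
  sel[order(-gl[match(sel, ids)], sel)]
}

# direct maximization of the admixture log-likelihood over the simplex
# via softmax reparameterization (independent of the EM path)
oracleMaxLoglik <- function(g, f, clamp = 1e-6) {
  K <- nrow(f)
  fc <- pmin(pmax(f, clamp), 1 - clamp)
  nll <- function(theta) {
    q <- exp(c(theta, 0)); q <- q / sum(q)
    s <- as.vector(q %*% fc); t <- as.vector(q %*% (1 - fc))
    obs <- !is.na(g)
    -sum(g[obs] * log(s[obs]) + (2 - g[obs]) * log(t[obs]))
  }
  # multistart, including boundary-biased starts: optima with some q_k = 0
  # sit at theta_k -> -Inf under the softmax map
  starts <- as.matrix(expand.grid(rep(list(c(-12, 0, 12)), K - 1)))
  best <- Inf
  for (r in seq_len(nrow(starts))) {
    o <- stats::optim(starts[r, ], nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
    o2 <- suppressWarnings(  # Nelder-Mead grumbles in one dimension
      stats::optim(o$par, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-14)))
    best <- min(best, o$value, o2$value)
  }
  -best
}

randomInstance <- function(K, M, seed) {
  set.seed(seed)
  f <- matrix(runif(K * M), K, M)
  q <- rgamma(K, 1); q <- q / sum(q)
  g <- rbinom(M, 2, as.vector(q %*% f))
  list(f = f, g = as.integer(g))
}
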