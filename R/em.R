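#' Admixture log-likelihood of one sample
#'
#' For ancestry vector q on the K-simplex, dosage vector g (allele-1
#' copies) and a K x M matrix F of population allele frequencies, the
#' log-likelihood treats the 2M alleles as independent draws from the
#' mixture frequency sum_k q_k f_km:
#'
#'   L(q) = sum_m \{ g_m ln(sum_k q_k f_km) +
#'                   (2 - g_m) ln(sum_k q_k (1 - f_km)) \}
#'
#' Markers with missing dosage are excluded from the sum; with no usable
#' markers the (empty) sum is 0. Frequencies are clamped to
#' \[clamp, 1 - clamp\] so monomorphic markers keep the logs finite.
#'
#' @param q numeric length-K ancestry vector (non-negative, sums to 1).
#' @param g integer length-M dosage vector in \{0,1,2,NA\}.
#' @param f numeric K x M frequency matrix.
#' @param clamp frequency clamp delta (default 1e-6).
#' @return finite numeric scalar.
#' @examples
#' ancestryLogLik(1, 1L, matrix(0.5, 1, 1))  # 2 * ln(0.5)
#' @export
ancestryLogLik <- function(q, g, f, clamp = 1e-6) {
  f <- matrix(pmin(pmax(f, clamp), 1 - clamp), nrow = length(q))
  if (ncol(f) != length(g)) stop("dimension mismatch between g and f")
  obs <- !is.na(g)
  if (!any(obs)) return(0)
  g <- g[obs]; f <- f[, obs, drop = FALSE]
  s <- as.vector(q %*% f)
  t <- as.vector(q %*% (1 - f))
  sum(g * log(s) + (2 - g) * log(t))
}

#' One EM update of an ancestry vector
#'
#' The E-step attributes each observed allele copy to source populations
#' by responsibility a_mk = q_k f_km / sum_p q_p f_pm (allele 1) and
#' b_mk = q_k (1-f_km) / sum_p q_p (1-f_pm) (allele 2); the M-step then
#' averages: q_k' = (1 / 2M_obs) sum_m \[ g_m a_mk + (2 - g_m) b_mk \],
#' where M_obs counts non-missing markers so that q' stays on the
#' simplex under missingness. The log-likelihood never decreases across
#' this update.
#'
#' @inheritParams ancestryLogLik
#' @return updated length-K ancestry vector.
#' @export
emStep <- function(q, g, f, clamp = 1e-6) {
  f <- matrix(pmin(pmax(f, clamp), 1 - clamp), nrow = length(q))
  if (ncol(f) != length(g)) stop("dimension mismatch between g and f")
  obs <- !is.na(g)
  if (!any(obs)) return(q)
  g <- g[obs]; f <- f[, obs, drop = FALSE]
  s <- as.vector(q %*% f)        # mixture freq of allele 1 per marker
  t <- as.vector(q %*% (1 - f))  # and of allele 2
  qnew <- q * (as.vector(f %*% (g / s)) + as.vector((1 - f) %*% ((2 - g) / t)))
  qnew / (2 * length(g))
}

# responsibilities a (allele 1) and b (allele 2), K x M, for tests of the
# E-step normalization
emResponsibilities <- function(q, g, f, clamp = 1e-6) {
  f <- matrix(pmin(pmax(f, clamp), 1 - clamp), nrow = length(q))
  a <- q * f
  a <- sweep(a, 2, colSums(a), "/")
  b <- q * (1 - f)
  b <- sweep(b, 2, colSums(b), "/")
  list(a = a, b = b)
}

#' Supervised ancestry estimation by EM
#'
#' Estimates, independently for every sample, the ancestry proportion
#' vector Q on the K-simplex against the fixed population allele
#' frequencies of `fp`, by EM from a uniform start (1/K, ..., 1/K). The
#' likelihood is concave in Q for fixed frequencies, so the uniform start
#' affects only the iteration count, not the optimum. Iteration stops
#' once the log-likelihood improvement drops below `epsilon` or
#' `maxIter` is reached.
#'
#' `convergenceScope = "per_sample"` applies the epsilon rule to each
#' sample's own likelihood (the per-sample likelihoods are independent);
#' `"cohort"` applies it to the cohort total, stopping all samples
#' together.
#'
#' @param gm a [GenotypeMatrix], harmonized with `fp` and restricted to
#'   the ancestry-informative marker set.
#' @param fp a [FrequencyPanel] with one row per ancestral population
#'   (K rows).
#' @param epsilon log-likelihood improvement tolerance (default 0.01).
#' @param maxIter iteration cap (default 1000).
#' @param freqClamp frequency clamp delta (default 1e-6).
#' @param convergenceScope `"per_sample"` (default) or `"cohort"`.
#' @return an [AncestryEstimate]. Samples with zero non-missing markers
#'   get an all-`NA` row and `converged = NA`, with a warning.
#' @export
estimateAncestry <- function(gm, fp, epsilon = 0.01, maxIter = 1000,
                             freqClamp = 1e-6,
                             convergenceScope = c("per_sample", "cohort")) {
  stopifnot(is(gm, "GenotypeMatrix"), is(fp, "FrequencyPanel"),
            epsilon > 0, maxIter >= 1, freqClamp > 0, freqClamp < 0.5)
  convergenceScope <- match.arg(convergenceScope)
  if (!identical(markerIds(gm), markerIds(fp)))
    stop("genotypes and panel must be harmonized (identical marker order)")
  f <- pmin(pmax(freq(fp), freqClamp), 1 - freqClamp)
  if (anyNA(f)) stop("panel has missing frequencies; run qcFilter first")
  K <- nrow(f)
  d <- dosage(gm)
  n <- ncol(d)
  P <- matrix(NA_real_, n, K, dimnames = list(colnames(d), rownames(f)))
  ll <- rep(NA_real_, n); it <- rep(0L, n); cv <- rep(NA, n)
  usable <- colSums(!is.na(d)) > 0
  if (any(!usable))
    warning(sum(!usable), " sample(s) with zero non-missing markers; no estimate")
  if (convergenceScope == "per_sample") {
    for (i in which(usable)) {
      g <- d[, i]
      q <- rep(1 / K, K)
      lcur <- ancestryLogLik(q, g, f, freqClamp)
      conv <- FALSE
      iter <- 0L
      while (iter < maxIter) {
        iter <- iter + 1L
        q <- emStep(q, g, f, freqClamp)
        lnew <- ancestryLogLik(q, g, f, freqClamp)
        if (lnew - lcur < epsilon) { lcur <- lnew; conv <- TRUE; break }
        lcur <- lnew
      }
      P[i, ] <- q; ll[i] <- lcur; it[i] <- iter; cv[i] <- conv
    }
  } else {
    act <- which(usable)
    Q <- matrix(1 / K, length(act), K)
    lcur <- sum(vapply(seq_along(act), function(j)
      ancestryLogLik(Q[j, ], d[, act[j]], f, freqClamp), 0))
    conv <- FALSE; iter <- 0L
    while (iter < maxIter) {
      iter <- iter + 1L
      for (j in seq_along(act)) Q[j, ] <- emStep(Q[j, ], d[, act[j]], f, freqClamp)
      lnew <- sum(vapply(seq_along(act), function(j)
        ancestryLogLik(Q[j, ], d[, act[j]], f, freqClamp), 0))
      if (lnew - lcur < epsilon) { lcur <- lnew; conv <- TRUE; break }
      lcur <- lnew
    }
    P[act, ] <- Q
    ll[act] <- vapply(seq_along(act), function(j)
      ancestryLogLik(Q[j, ], d[, act[j]], f, freqClamp), 0)
    it[act] <- iter; cv[act] <- conv
  }
  AncestryEstimate(P, ll, it, cv)
}
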