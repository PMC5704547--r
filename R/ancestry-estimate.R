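AncestryEstimate <- function(proportions, loglik, iterations, converged) {
  new("AncestryEstimate",
      proportions = proportions,
      loglik = as.numeric(loglik),
      iterations = as.integer(iterations),
      converged = as.logical(converged))
}

#' @rdname AncestryEstimate-class
#' @aliases ancestryProportions,AncestryEstimate-method
setMethod("ancestryProportions", "AncestryEstimate", function(x) x@proportions)

#' @rdname AncestryEstimate-class
setMethod("sampleIds", "AncestryEstimate", function(x) rownames(x@proportions))

#' @rdname AncestryEstimate-class
setMethod("populationIds", "AncestryEstimate", function(x) colnames(x@proportions))

#' Final log-likelihood per sample
#' @param x an [AncestryEstimate].
#' @return named numeric vector.
#' @export
emLogLik <- function(x) {
  stopifnot(is(x, "AncestryEstimate"))
  stats::setNames(x@loglik, rownames(x@proportions))
}

#' EM iteration counts per sample
#' @param x an [AncestryEstimate].
#' @return named integer vector.
#' @export
emIterations <- function(x) {
  stopifnot(is(x, "AncestryEstimate"))
  stats::setNames(x@iterations, rownames(x@proportions))
}

#' Convergence flags per sample
#' @param x an [AncestryEstimate].
#' @return named logical vector (NA for samples with no usable markers).
#' @export
emConverged <- function(x) {
  stopifnot(is(x, "AncestryEstimate"))
  stats::setNames(x@converged, rownames(x@proportions))
}

setMethod("show", "AncestryEstimate", function(object) {
  p <- object@proportions
  cat(sprintf("AncestryEstimate: %d samples, K = %d populations\n",
              nrow(p), ncol(p)))
  cat("  populations:", paste(colnames(p), collapse = ", "), "\n")
  conv <- object@converged
  cat(sprintf("  converged: %d/%d (median %d iterations)\n",
              sum(conv, na.rm = TRUE), length(conv),
              as.integer(stats::median(object@iterations[!is.na(conv)]))))
  if (anyNA(conv))
    cat(sprintf("  %d sample(s) had no usable markers\n", sum(is.na(conv))))
})

#' @rdname maxAncestralGroup
setMethod("maxAncestralGroup", "AncestryEstimate", function(x, ...) {
  p <- x@proportions
  labs <- colnames(p)
  out <- rep(NA_character_, nrow(p))
  tied <- rep(NA, nrow(p))
  for (i in seq_len(nrow(p))) {
    if (anyNA(p[i, ])) next
    mx <- max(p[i, ])
    hit <- which(p[i, ] == mx)
    out[i] <- labs[hit[1L]]
    tied[i] <- length(hit) > 1L
  }
  names(out) <- rownames(p)
  attr(out, "tied") <- stats::setNames(tied, rownames(p))
  out
})

#' @rdname maxAncestralGroup
setMethod("maxAncestralGroup", "numeric", function(x, ...) {
  labs <- names(x)
  if (is.null(labs)) labs <- as.character(seq_along(x))
  mx <- max(x)
  hit <- which(x == mx)
  out <- labs[hit[1L]]
  attr(out, "tied") <- length(hit) > 1L
  out
})

#' Ancestry estimates as a data.frame
#'
#' One row per sample: the ancestry proportions, final log-likelihood,
#' iteration count, convergence flag and the maximum ancestral group.
#' This is the layout written by the `estimate` command-line subcommand.
#'
#' @param x an [AncestryEstimate].
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.AncestryEstimate <- function(x, ...) {
  mg <- maxAncestralGroup(x)
  data.frame(
    sample_id = rownames(x@proportions),
    as.data.frame(x@proportions),
    loglik = x@loglik,
    iterations = x@iterations,
    converged = x@converged,
    max_group = unname(mg),
    row.names = NULL,
    check.names = FALSE
  )
}
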