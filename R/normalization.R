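#' Median-of-ratios size factors
#'
#' For every feature with strictly positive counts in all samples, the ratio
#' of each sample's count to the feature's geometric mean is formed; a
#' sample's size factor is the median of those ratios, and the vector is then
#' rescaled to geometric mean 1 so factors are comparable across runs.
#'
#' When no feature is positive in every sample (common for sparse matrices)
#' the default is to stop; `fallback = "poscounts"` switches to a
#' pseudo-reference computed over positive counts only.
#'
#' @param cm Count matrix.
#' @param fallback `"error"` (default) or `"poscounts"`.
#' @return Named numeric vector of per-sample size factors, geometric mean 1.
#' @export
estimate_size_factors <- function(cm, fallback = c("error", "poscounts")) {
  fallback <- match.arg(fallback)
  validate_count_matrix(cm)
  logm <- log(cm)
  loggeo <- rowMeans(logm)
  ok <- is.finite(loggeo)
  if (any(ok)) {
    sf <- apply(cm[ok, , drop = FALSE], 2L, function(col) {
      stats::median(col / exp(loggeo[ok]))
    })
  } else if (fallback == "poscounts") {
    # pseudo-reference over positive counts only, zeros excluded from ratios
    loggeo <- apply(logm, 1L, function(r) sum(r[is.finite(r)]) / ncol(cm))
    sf <- vapply(seq_len(ncol(cm)), function(j) {
      r <- cm[, j] / exp(loggeo)
      stats::median(r[cm[, j] > 0])
    }, numeric(1L))
    names(sf) <- colnames(cm)
  } else {
    stop("no feature has positive counts in every sample; ",
         "consider fallback = \"poscounts\"")
  }
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("size factor estimation failed (non-positive factor)")
  sf / exp(mean(log(sf)))
}

#' Normalized fragments per million (FPM)
#'
#' Counts are divided by their sample's size factor, then rescaled to a
#' per-million library using the mean normalized library size:
#' `FPM_ij = 1e6 * (K_ij / s_j) / m` with `m = mean_j sum_i K_ij / s_j`.
#' The mean over samples of per-sample FPM totals is therefore exactly 1e6.
#'
#' @param cm Count matrix.
#' @param sf Size factors from [estimate_size_factors()]; recomputed if NULL.
#' @return Numeric matrix of FPM values, same dimnames as `cm`.
#' @export
fpm <- function(cm, sf = NULL) {
  validate_count_matrix(cm)
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  stopifnot(length(sf) == ncol(cm), all(sf > 0))
  zero <- colSums(cm) == 0
  if (any(zero)) stop("sample(s) with zero total count: ",
                      paste(colnames(cm)[zero], collapse = ", "))
  norm <- sweep(cm, 2L, sf, "/")
  1e6 * norm / mean(colSums(norm))
}

#' Log-transformed FPM
#'
#' Element-wise `log(FPM + pseudocount)` in the requested base (default
#' log2 with pseudocount 1, the convention used for the risk score).
#'
#' @param f FPM matrix from [fpm()].
#' @param pseudocount Non-negative offset added before the log; with 0, every
#'   FPM value must be strictly positive.
#' @param base Logarithm base, default 2.
#' @return Matrix of the same shape.
#' @export
log_fpm <- function(f, pseudocount = 1, base = 2) {
  stopifnot(is.numeric(f), is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount >= 0, base > 1)
  if (pseudocount == 0 && any(f <= 0)) {
    stop("log of non-positive FPM; use a positive pseudocount")
  }
  out <- log(f + pseudocount, base = base)
  attr(out, "log_base") <- base
  attr(out, "pseudocount") <- pseudocount
  out
}
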