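#' Build the group + age design matrix
#'
#' Columns: intercept, a case indicator (0 = control, 1 = case) and the age
#' covariate, optionally standardized. The matrix must be full column rank
#' and the group column non-constant.
#'
#' @param samples Sample metadata data.frame ([read_sample_metadata()]):
#'   `group` a factor with the control level first, `age` numeric.
#' @param covariates Character vector of extra covariate columns; default
#'   `"age"`. Use `character(0)` for a group-only design.
#' @param standardize Standardize covariates to mean 0, sd 1? Default FALSE
#'   (age enters in years).
#' @return Numeric design matrix, one row per sample.
#' @export
design_matrix <- function(samples, covariates = "age", standardize = FALSE) {
  stopifnot(is.data.frame(samples), is.factor(samples$group))
  x <- as.integer(samples$group == levels(samples$group)[2L])
  if (length(unique(x)) < 2L) stop("group column is constant; both groups required")
  X <- cbind(intercept = 1, group = x)
  for (cv in covariates) {
    v <- samples[[cv]]
    if (is.null(v) || !is.numeric(v)) stop("covariate '", cv, "' missing or non-numeric")
    if (standardize) v <- as.numeric(scale(v))
    X <- cbind(X, v)
    colnames(X)[ncol(X)] <- cv
  }
  rownames(X) <- samples$sample
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

# IRLS for a negative-binomial GLM with log link and log size-factor offset.
# Natural-log scale internally; dispersion alpha fixed. Returns coefficients,
# the weighted information matrix and fitted means.
#' @noRd
nb_irls <- function(y, X, offset, alpha, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  beta <- tryCatch(
    stats::lm.fit(X, log((y + 0.5) / exp(offset)))$coefficients,
    error = function(e) rep(0, p)
  )
  beta[!is.finite(beta)] <- 0
  converged <- FALSE
  XtWX <- NULL
  mu <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)          # guard against overflow
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtWX <- crossprod(X, X * w)
    beta_new <- tryCatch(drop(solve(XtWX, crossprod(X, w * z))),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      return(list(beta = beta, XtWX = XtWX, mu = mu, converged = FALSE, iter = it))
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  XtWX <- crossprod(X, X * w)
  if (max(abs(beta)) > 25) converged <- FALSE   # practical separation guard
  list(beta = beta, XtWX = XtWX, mu = mu, converged = converged, iter = it)
}

# Cox-Reid adjusted NB profile log-likelihood at a given dispersion.
#' @noRd
cr_profile_loglik <- function(alpha, y, X, offset) {
  fit <- nb_irls(y, X, offset, alpha)
  if (!all(is.finite(fit$beta))) return(-Inf)
  ll <- sum(stats::dnbinom(y, size = 1 / alpha, mu = fit$mu, log = TRUE))
  adj <- 0.5 * as.numeric(determinant(fit$XtWX, logarithm = TRUE)$modulus)
  if (!is.finite(ll) || !is.finite(adj)) return(-Inf)
  ll - adj
}

#' Per-gene negative-binomial dispersion
#'
#' Maximizes the Cox-Reid adjusted profile likelihood of the NB dispersion
#' given the design (the adjustment corrects the downward bias of plain ML
#' when coefficients are estimated from few samples). The estimate is clamped
#' to `[1e-8, 10]`. No shrinkage toward a mean-dispersion trend is applied.
#' If the profile likelihood cannot be evaluated, a method-of-moments
#' estimate on normalized counts is used and flagged.
#'
#' @param counts_row Integer vector of per-sample counts for one feature.
#' @param design Design matrix from [design_matrix()].
#' @param sf Size factors.
#' @param method `"CR"` (Cox-Reid adjusted ML, default) or `"mom"`.
#' @return List: `alpha`, `method` ("CR" or "mom").
#' @export
estimate_dispersion <- function(counts_row, design, sf, method = c("CR", "mom")) {
  method <- match.arg(method)
  stopifnot(length(counts_row) == nrow(design), length(sf) == nrow(design))
  if (nrow(design) < ncol(design) + 1L) stop("need more samples than coefficients")
  lo <- 1e-8; hi <- 10
  mom <- function() {
    ynorm <- counts_row / sf
    m <- mean(ynorm); v <- stats::var(ynorm)
    list(alpha = min(max((v - m) / m^2, lo), hi), method = "mom")
  }
  if (method == "mom") return(mom())
  offset <- log(sf)
  res <- tryCatch(
    stats::optimize(function(la) -cr_profile_loglik(exp(la), counts_row, design, offset),
                    interval = c(log(lo), log(hi)), tol = 1e-4),
    error = function(e) NULL
  )
  if (is.null(res) || !is.finite(res$objective)) return(mom())
  list(alpha = min(max(exp(res$minimum), lo), hi), method = "CR")
}

#' Fit a negative-binomial GLM for one feature
#'
#' Log-link NB regression of counts on the design with `log(sf)` offset,
#' fitted by iteratively reweighted least squares at fixed dispersion.
#' Coefficients and standard errors (inverse Fisher information) are
#' reported in log2 units, so the group coefficient is the log2 fold change
#' of case vs control.
#'
#' @inheritParams estimate_dispersion
#' @param alpha Dispersion (NB variance `mu + alpha * mu^2`).
#' @return List of class `gene_fit`: `lfc` (log2), `se` (log2),
#'   `coefficients` / `se_all` (all terms, log2), `dispersion`, `converged`,
#'   `mu` (fitted means), `base_mean` (mean normalized count).
#' @export
fit_nb_glm <- function(counts_row, design, sf, alpha) {
  stopifnot(length(counts_row) == nrow(design), all(sf > 0), alpha >= 0)
  if (qr(design)$rank < ncol(design)) stop("design matrix is rank deficient")
  alpha <- max(alpha, 1e-12)
  fit <- nb_irls(counts_row, design, log(sf), alpha)
  cov_nat <- tryCatch(solve(fit$XtWX), error = function(e) NULL)
  ok <- fit$converged && !is.null(cov_nat) && all(diag(cov_nat) > 0)
  se_nat <- if (!is.null(cov_nat)) sqrt(pmax(diag(cov_nat), 0)) else rep(NA_real_, ncol(design))
  ln2 <- log(2)
  g <- match("group", colnames(design))
  structure(list(
    coefficients = fit$beta / ln2,
    se_all = se_nat / ln2,
    lfc = unname(fit$beta[g] / ln2),
    se = unname(se_nat[g] / ln2),
    dispersion = alpha,
    converged = ok,
    iter = fit$iter,
    mu = fit$mu,
    base_mean = mean(counts_row / sf)
  ), class = "gene_fit")
}

#' Two-sided Wald test
#'
#' `z = lfc / se`, referred to the standard normal: `p = 2 * (1 - Phi(|z|))`.
#' Vectorized.
#'
#' @param lfc Coefficient(s), log2 units.
#' @param se Standard error(s), log2 units; must be positive.
#' @return data.frame with columns `z`, `p`.
#' @export
wald_test <- function(lfc, se) {
  stopifnot(is.numeric(lfc), is.numeric(se), length(lfc) == length(se))
  if (any(se <= 0, na.rm = TRUE)) stop("standard errors must be positive")
  z <- lfc / se
  data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; a thin validated front end to
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed features
#'
#' A feature is DE when its raw p-value is at most `p_thresh` and its |LFC|
#' at least `lfc_thresh`. The raw p-value is used deliberately: in small
#' extreme case-control designs the BH-adjusted values may clear no
#' threshold while large, consistent fold changes are still reportable.
#'
#' @param results data.frame with columns `pvalue` and `lfc` (and optionally
#'   `converged`, which must be TRUE to qualify).
#' @param p_thresh Raw p-value threshold, default 0.01.
#' @param lfc_thresh Absolute log2-fold-change threshold, default 2.
#' @return The DE subset of `results` (possibly empty), original order.
#' @export
call_de <- function(results, p_thresh = 0.01, lfc_thresh = 2) {
  stopifnot(is.data.frame(results), all(c("pvalue", "lfc") %in% colnames(results)))
  ok <- is.finite(results$pvalue) & is.finite(results$lfc)
  if (!is.null(results$converged)) ok <- ok & results$converged
  sel <- ok & results$pvalue <= p_thresh & abs(results$lfc) >= lfc_thresh
  results[sel, , drop = FALSE]
}

#' Linear fold change from a log2 fold change
#'
#' `2^|lfc|`, the magnitude of the between-group ratio regardless of
#' direction; always at least 1.
#'
#' @param lfc Finite log2 fold change(s).
#' @return Numeric vector of linear fold changes.
#' @export
lfc_to_fold_change <- function(lfc) {
  stopifnot(is.numeric(lfc), all(is.finite(lfc)))
  2^abs(lfc)
}

#' Negative-binomial Wald differential expression, all features
#'
#' The per-feature pipeline: Cox-Reid dispersion, NB GLM fit with group +
#' covariates, Wald test on the group coefficient, BH correction computed
#' over converged fits only (non-converged features get NA statistics and do
#' not enter the multiple-testing denominator), and DE calling on raw p and
#' |LFC| thresholds.
#'
#' @param cm Count matrix (filtered, mature-level).
#' @param samples Sample metadata; rows matched to `colnames(cm)` by the
#'   `sample` column.
#' @param sf Size factors; estimated from `cm` when NULL.
#' @param covariates Covariates beyond group; default `"age"`.
#' @param standardize Standardize covariates? Default FALSE.
#' @param p_thresh,lfc_thresh DE thresholds, see [call_de()].
#' @return data.frame, one row per feature: `mirna`, `base_mean`, `lfc`,
#'   `se`, `z`, `pvalue`, `padj`, `dispersion`, `dispersion_method`,
#'   `converged`, `de`.
#' @export
nb_de <- function(cm, samples, sf = NULL, covariates = "age",
                  standardize = FALSE, p_thresh = 0.01, lfc_thresh = 2) {
  validate_count_matrix(cm)
  idx <- match(colnames(cm), samples$sample)
  if (anyNA(idx)) stop("samples missing from metadata: ",
                       paste(colnames(cm)[is.na(idx)], collapse = ", "))
  samples <- samples[idx, , drop = FALSE]
  if (is.null(sf)) sf <- estimate_size_factors(cm)
  X <- design_matrix(samples, covariates = covariates, standardize = standardize)

  n <- nrow(cm)
  out <- data.frame(
    mirna = rownames(cm), base_mean = NA_real_, lfc = NA_real_, se = NA_real_,
    z = NA_real_, pvalue = NA_real_, padj = NA_real_, dispersion = NA_real_,
    dispersion_method = NA_character_, converged = FALSE, de = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    y <- cm[i, ]
    disp <- estimate_dispersion(y, X, sf)
    fit <- fit_nb_glm(y, X, sf, disp$alpha)
    out$base_mean[i] <- fit$base_mean
    out$dispersion[i] <- disp$alpha
    out$dispersion_method[i] <- disp$method
    out$converged[i] <- fit$converged
    if (fit$converged && is.finite(fit$se) && fit$se > 0) {
      w <- wald_test(fit$lfc, fit$se)
      out$lfc[i] <- fit$lfc
      out$se[i] <- fit$se
      out$z[i] <- w$z
      out$pvalue[i] <- w$p
    } else {
      out$converged[i] <- FALSE
    }
  }
  tested <- out$converged & is.finite(out$pvalue)
  out$padj[tested] <- bh_adjust(out$pvalue[tested])
  n_skip <- sum(!tested)
  if (n_skip) message("nb_de: ", n_skip, " feature(s) excluded from testing (non-converged)")
  de_rows <- call_de(out, p_thresh = p_thresh, lfc_thresh = lfc_thresh)
  out$de <- out$mirna %in% de_rows$mirna
  out
}
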