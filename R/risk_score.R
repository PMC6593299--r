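#' LFC-weighted polygenic expression risk score
#'
#' For each sample, the log-FPM values of the panel miRNAs are summed,
#' weighted by their log2 fold changes:
#' `score_j = sum_i w_i * L_ij`. With a single-miRNA panel and weight 1 the
#' score reduces to that miRNA's log-FPM. The weights are plug-in LFC
#' estimates from the same samples; when evaluated in-sample the AUC is
#' optimistically biased, which downstream reporting flags.
#'
#' @param logfpm Log-FPM matrix ([log_fpm()]), features x samples.
#' @param weights Named numeric vector: names are the panel miRNA IDs,
#'   values their weights (typically LFCs). All finite.
#' @return Object of class `polygenic_score`: `score` (named per-sample
#'   vector), `weights`, `panel`, and the log base/pseudocount of the input
#'   when recorded there.
#' @export
polygenic_score <- function(logfpm, weights) {
  stopifnot(is.matrix(logfpm), is.numeric(weights), length(weights) >= 1L,
            !is.null(names(weights)), all(is.finite(weights)))
  missing <- setdiff(names(weights), rownames(logfpm))
  if (length(missing)) {
    stop("panel miRNA(s) absent from the matrix: ", paste(missing, collapse = ", "))
  }
  L <- logfpm[names(weights), , drop = FALSE]
  score <- drop(crossprod(L, weights))
  names(score) <- colnames(logfpm)
  structure(list(score = score, weights = weights, panel = names(weights),
                 log_base = attr(logfpm, "log_base"),
                 pseudocount = attr(logfpm, "pseudocount")),
            class = "polygenic_score")
}

#' @export
print.polygenic_score <- function(x, ...) {
  cat("polygenic_score:", length(x$panel), "miRNA panel,",
      length(x$score), "samples\n")
  invisible(x)
}

#' @noRd
split_scores <- function(scores, labels, case) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  is_case <- labels == case
  if (!any(is_case) || all(is_case)) stop("both classes must be present")
  list(case = scores[is_case], control = scores[!is_case])
}

#' Midrank Mann-Whitney AUC
#'
#' The probability that a random case outscores a random control, ties
#' counted half: `AUC = [#(case > control) + 0.5 #(ties)] / (n1 * n2)`,
#' computed via midranks. Cases are taken to score high; no automatic
#' orientation flip is applied here (see [roc_curve()] for recorded
#' orientation), so `AUC(labels) + AUC(flipped labels) = 1` holds exactly.
#'
#' @param scores Numeric per-sample scores.
#' @param labels Class labels, same length.
#' @param case Label value identifying cases.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, case) {
  g <- split_scores(scores, labels, case)
  n1 <- length(g$case); n2 <- length(g$control)
  r <- rank(c(g$case, g$control))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Empirical ROC curve
#'
#' Operating points at every threshold between consecutive distinct scores
#' (plus the two infinite ends). Under the `"case_high"` orientation a sample
#' is called a case when its score is at least the cutoff; `"case_low"`
#' mirrors this on negated scores and records the flip. `"auto"` picks the
#' orientation whose AUC is at least 0.5 and reports it, mimicking how ROC
#' software auto-detects direction, but without hiding the choice.
#' The trapezoidal area of the stored points equals the midrank
#' Mann-Whitney [auc()] of the oriented scores exactly, ties included.
#'
#' @inheritParams auc
#' @param direction `"case_high"` (default), `"case_low"`, or `"auto"`.
#' @return Object of class `roc_result`: `points` (data.frame `cutoff`,
#'   `sensitivity`, `specificity`, decreasing threshold order), `auc`,
#'   `direction`, `n_case`, `n_control`.
#' @export
roc_curve <- function(scores, labels, case,
                      direction = c("case_high", "case_low", "auto")) {
  direction <- match.arg(direction)
  if (direction == "auto") {
    direction <- if (auc(scores, labels, case) >= 0.5) "case_high" else "case_low"
  }
  s <- if (direction == "case_low") -scores else scores
  g <- split_scores(s, labels, case)
  d <- sort(unique(s))
  cut <- c(-Inf, d[-length(d)] + diff(d) / 2, Inf)
  sens <- vapply(cut, function(t) mean(g$case >= t), numeric(1L))
  spec <- vapply(cut, function(t) mean(g$control < t), numeric(1L))
  ord <- order(cut, decreasing = TRUE)           # sens, 1-spec non-decreasing
  pts <- data.frame(cutoff = if (direction == "case_low") -cut[ord] else cut[ord],
                    sensitivity = sens[ord], specificity = spec[ord])
  fpr <- 1 - pts$specificity
  area <- sum(diff(fpr) * (utils::head(pts$sensitivity, -1) + utils::tail(pts$sensitivity, -1)) / 2)
  structure(list(points = pts, auc = area, direction = direction,
                 n_case = length(g$case), n_control = length(g$control)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d cases vs %d controls, direction %s)\n",
              x$auc, x$n_case, x$n_control, x$direction))
  invisible(x)
}

#' Youden-optimal operating point
#'
#' Maximizes the Youden index `J = sensitivity + specificity - 1` over the
#' ROC operating points. Ties are broken in favour of higher sensitivity
#' (screening-oriented), then the lower cutoff.
#'
#' @param roc A `roc_result` from [roc_curve()], or a data.frame of
#'   operating points with columns `cutoff`, `sensitivity`, `specificity`.
#' @return List: `cutoff`, `sensitivity`, `specificity`, `J`.
#' @export
youden_cutoff <- function(roc) {
  pts <- if (inherits(roc, "roc_result")) roc$points else roc
  stopifnot(is.data.frame(pts),
            all(c("cutoff", "sensitivity", "specificity") %in% colnames(pts)))
  J <- pts$sensitivity + pts$specificity - 1
  best <- which(J == max(J))
  best <- best[pts$sensitivity[best] == max(pts$sensitivity[best])]
  best <- best[which.min(pts$cutoff[best])]
  list(cutoff = pts$cutoff[best], sensitivity = pts$sensitivity[best],
       specificity = pts$specificity[best], J = J[best])
}

#' Confidence interval for the AUC
#'
#' Default: DeLong's structural-components variance with a normal
#' approximation, truncated to `[0, 1]`. When the empirical AUC is exactly 0
#' or 1 the DeLong variance degenerates to zero; the interval is then
#' returned with `widened = TRUE` to flag that it understates uncertainty.
#' A stratified bootstrap (percentile interval) is available as an
#' alternative.
#'
#' @inheritParams auc
#' @param level Coverage, default 0.95.
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap resamples, default 2000.
#' @param seed Optional seed for the bootstrap (local RNG state).
#' @return List: `auc`, `lower`, `upper`, `se`, `method`, `widened`.
#' @export
auc_confidence_interval <- function(scores, labels, case, level = 0.95,
                                    method = c("delong", "bootstrap"),
                                    n_boot = 2000, seed = NULL) {
  method <- match.arg(method)
  g <- split_scores(scores, labels, case)
  if (length(g$case) < 2L || length(g$control) < 2L)
    stop("need at least 2 members per class")
  theta <- auc(scores, labels, case)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "delong") {
    psi <- outer(g$case, g$control,
                 function(x, y) (x > y) + 0.5 * (x == y))
    v10 <- rowMeans(psi)                 # per-case structural components
    v01 <- colMeans(psi)                 # per-control
    v <- stats::var(v10) / length(v10) + stats::var(v01) / length(v01)
    se <- sqrt(v)
    widened <- se == 0
    lo <- max(0, theta - z * se); hi <- min(1, theta + z * se)
  } else {
    boot_one <- function() {
      bs <- c(sample(g$case, replace = TRUE), sample(g$control, replace = TRUE))
      bl <- rep(c(TRUE, FALSE), c(length(g$case), length(g$control)))
      auc(bs, bl, TRUE)
    }
    stats_boot <- if (is.null(seed)) {
      replicate(n_boot, boot_one())
    } else {
      local_seed(seed, replicate(n_boot, boot_one()))
    }
    q <- stats::quantile(stats_boot, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    se <- stats::sd(stats_boot)
    widened <- FALSE
    lo <- max(0, q[1L]); hi <- min(1, q[2L])
  }
  list(auc = theta, lower = lo, upper = hi, se = se, method = method,
       widened = widened)
}

# Evaluate an expression under a temporary RNG state.
#' @noRd
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
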