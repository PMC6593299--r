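#' Simulation parameters for a serum miRNA case-control study
#'
#' Defaults emulate a small extreme case-control serum miRNA design: 10
#' cases (DR) vs 11 controls (NDR); 756 abundant mature miRNAs; log-normal
#' baseline abundance and per-feature NB dispersion; log-normal library size
#' factors; a small planted group effect on a subset of miRNAs with |LFC|
#' spanning 2 to 4.26 and mostly negative sign; and ages drawn from
#' Normal(47.10, 6.45^2) for cases and Normal(63.45, 4.25^2) for controls,
#' truncated to [18, 90] — so group and age are strongly confounded and the
#' age-adjustment code path is genuinely exercised. The per-gene age effect
#' is 0 by default (`age_effect` switches on a confounded alternative).
#'
#' @param n_case,n_control Group sizes.
#' @param n_features Number of miRNAs.
#' @param frac_de Fraction of features with a planted group effect.
#' @param lfc_range Magnitude range of planted log2 fold changes.
#' @param prob_down Probability a planted effect is negative (lower in cases).
#' @param dispersion_meanlog,dispersion_sdlog Log-normal dispersion
#'   distribution; the default median is 0.3.
#' @param abundance_meanlog,abundance_sdlog Log-normal distribution of
#'   baseline mean counts per sample (right-skewed).
#' @param abundance_min Lower truncation of baseline means, keeping the
#'   default feature set abundant.
#' @param sf_sdlog Log-normal spread of library size factors (rescaled to
#'   geometric mean 1).
#' @param age_case_mean,age_case_sd,age_control_mean,age_control_sd Group
#'   age distributions (years).
#' @param age_range Truncation bounds for ages.
#' @param age_effect Per-gene log2 change per year of (centred) age; 0
#'   disables the age effect.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_case = 10, n_control = 11, n_features = 756,
                       frac_de = 5 / 756, lfc_range = c(2, 4.26),
                       prob_down = 0.8,
                       dispersion_meanlog = log(0.3), dispersion_sdlog = 0.6,
                       abundance_meanlog = log(50), abundance_sdlog = 1.5,
                       abundance_min = 15, sf_sdlog = 0.3,
                       age_case_mean = 47.10, age_case_sd = 6.45,
                       age_control_mean = 63.45, age_control_sd = 4.25,
                       age_range = c(18, 90), age_effect = 0) {
  p <- as.list(environment())
  stopifnot(n_case >= 2, n_control >= 2, n_features >= 1,
            frac_de >= 0, frac_de <= 1, lfc_range[1] <= lfc_range[2],
            prob_down >= 0, prob_down <= 1, dispersion_sdlog >= 0,
            abundance_sdlog >= 0, abundance_min > 0, sf_sdlog >= 0,
            age_case_sd > 0, age_control_sd > 0, age_range[1] < age_range[2])
  structure(p, class = "sim_params")
}

#' @noRd
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

# Pin the RNG so identical seeds give identical matrices across platforms.
#' @noRd
with_pinned_rng <- function(seed, expr) {
  old <- RNGkind("Mersenne-Twister", "Inversion", "Rejection")
  on.exit(RNGkind(old[1L], old[2L], old[3L]), add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a serum miRNA count matrix with planted effects
#'
#' Counts are negative binomial with mean
#' `s_j * q_i * 2^(beta_i * x_j + gamma_i * (age_j - mean(age)))` and
#' per-feature dispersion `alpha_i`, where `x_j` is the case indicator. Age
#' is centred inside the mean model so `q_i` remains the baseline abundance
#' when an age effect is switched on. The planted truth (`beta`, `gamma`,
#' `alpha`, `q` per feature; `s`, `age`, `group` per sample) is returned
#' alongside the data. Identical seeds give identical output.
#'
#' @param params A [sim_params()] list.
#' @param seed Integer seed.
#' @return List: `counts` (integer matrix), `samples` (metadata data.frame),
#'   `truth` (per-feature data.frame), `sample_truth` (per-sample
#'   data.frame).
#' @export
simulate_dataset <- function(params = sim_params(), seed = 1) {
  stopifnot(inherits(params, "sim_params"))
  with_pinned_rng(seed, {
    n1 <- params$n_case; n2 <- params$n_control
    ns <- n1 + n2; nf <- params$n_features
    sample_id <- sprintf("S%02d", seq_len(ns))
    group <- factor(rep(c("DR", "NDR"), c(n1, n2)), levels = c("NDR", "DR"))
    age <- c(rnorm_trunc(n1, params$age_case_mean, params$age_case_sd,
                         params$age_range[1], params$age_range[2]),
             rnorm_trunc(n2, params$age_control_mean, params$age_control_sd,
                         params$age_range[1], params$age_range[2]))
    s <- exp(stats::rnorm(ns, 0, params$sf_sdlog))
    s <- s / exp(mean(log(s)))

    feature_id <- sprintf("sim-miR-%04d", seq_len(nf))
    q <- pmax(stats::rlnorm(nf, params$abundance_meanlog, params$abundance_sdlog),
              params$abundance_min)
    alpha <- stats::rlnorm(nf, params$dispersion_meanlog, params$dispersion_sdlog)
    n_de <- round(params$frac_de * nf)
    de_idx <- if (n_de > 0) sort(sample.int(nf, n_de)) else integer(0)
    beta <- numeric(nf)
    if (n_de > 0) {
      mag <- stats::runif(n_de, params$lfc_range[1], params$lfc_range[2])
      sign <- ifelse(stats::runif(n_de) < params$prob_down, -1, 1)
      beta[de_idx] <- sign * mag
    }
    gamma <- rep(params$age_effect, nf)

    x <- as.integer(group == "DR")
    age_c <- age - mean(age)
    log2mu <- outer(beta, x) + outer(gamma, age_c) + log2(q)
    mu <- sweep(2^log2mu, 2L, s, "*")
    counts <- matrix(stats::rnbinom(nf * ns, mu = mu, size = rep(1 / alpha, ns)),
                     nrow = nf, dimnames = list(feature_id, sample_id))
    storage.mode(counts) <- "integer"

    list(
      counts = counts,
      samples = data.frame(sample = sample_id, group = group, age = age,
                           stringsAsFactors = FALSE),
      truth = data.frame(mirna = feature_id, q = q, beta = beta, gamma = gamma,
                         alpha = alpha, de = beta != 0, stringsAsFactors = FALSE),
      sample_truth = data.frame(sample = sample_id, size_factor = s, age = age,
                                group = group, stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a mixture of abundant and low-abundance miRNAs
#'
#' A stated fraction of features is generated at low abundance (expected
#' totals well under `min_total`) so that [filter_low_abundance()] removes
#' approximately that fraction; the remaining features follow the abundant
#' defaults. Low-abundance rows whose sampled total crosses the threshold
#' are proportionally thinned back below it, so the low stratum is
#' guaranteed to be filtered; the realized kept set is recorded in the
#' truth table.
#'
#' @param params A [sim_params()] list (used for the abundant stratum).
#' @param seed Integer seed.
#' @param fraction Fraction of features in the low-abundance stratum.
#' @param min_total Abundance threshold the mixture is built around.
#' @return As [simulate_dataset()], with logical truth columns `low` and
#'   `kept` (realized row total at least `min_total`).
#' @export
simulate_low_abundance_mix <- function(params = sim_params(), seed = 1,
                                       fraction = 0.7, min_total = 200) {
  stopifnot(fraction >= 0, fraction <= 1)
  sim <- simulate_dataset(params, seed)
  nf <- nrow(sim$counts)
  ns <- ncol(sim$counts)
  n_low <- round(fraction * nf)
  low_idx <- if (n_low > 0) {
    with_pinned_rng(seed + 1L, sort(sample.int(nf, n_low)))
  } else integer(0)
  if (n_low > 0) {
    with_pinned_rng(seed + 2L, {
      target_total <- stats::runif(n_low, 5, 0.6 * min_total)
      alpha <- sim$truth$alpha[low_idx]
      mu_row <- target_total / ns
      low <- matrix(stats::rnbinom(n_low * ns, mu = mu_row,
                                   size = rep(1 / alpha, ns)),
                    nrow = n_low)
      over <- which(rowSums(low) >= min_total)
      for (i in over) {   # thin back under the threshold; see generator docs
        low[i, ] <- floor(low[i, ] * 0.75 * min_total / sum(low[i, ]))
      }
      sim$counts[low_idx, ] <- low
      sim$truth$q[low_idx] <- mu_row
      sim$truth$beta[low_idx] <- 0
      sim$truth$de[low_idx] <- FALSE
    })
  }
  storage.mode(sim$counts) <- "integer"
  sim$truth$low <- seq_len(nf) %in% low_idx
  sim$truth$kept <- rowSums(sim$counts) >= min_total
  sim
}

#' Synthetic miRNA-target and pathway fixture with a prescribed overlap
#'
#' Builds a validated-target table and a gene-set collection whose overlap
#' structure is exact by construction: the union of targets over the panel
#' has `n_union` genes, `n_unique_top` of them are targeted only by the
#' first panel miRNA, and exactly `pathway_overlap` of the union fall inside
#' a `pathway_size`-gene pathway. The collection is padded with decoy sets
#' drawn from a synthetic background universe disjoint from the union, so
#' multiplicity correction is exercised. All gene symbols are synthetic.
#'
#' @param panel Character vector of miRNA IDs; the first is the
#'   high-connectivity miRNA.
#' @param n_union Size of the target-gene union.
#' @param n_unique_top Genes targeted by the first panel miRNA only.
#' @param pathway_overlap Union genes inside the focal pathway.
#' @param pathway_size Focal pathway size.
#' @param n_decoy_sets Decoy gene sets in the collection.
#' @param universe_size Declared background gene universe size N.
#' @param seed Seed for decoy-set construction.
#' @return List: `targets` (target table), `collection`
#'   ([gene_set_collection()]), `pathway` (focal set name).
#' @export
make_target_fixture <- function(panel, n_union = 55, n_unique_top = 41,
                                pathway_overlap = 4, pathway_size = 11,
                                n_decoy_sets = 404, universe_size = 20000,
                                seed = 1) {
  stopifnot(is.character(panel), length(panel) >= 1L,
            n_unique_top <= n_union, pathway_overlap <= pathway_size,
            pathway_overlap <= n_unique_top,
            universe_size >= n_union + pathway_size)
  if (length(panel) > 1L && n_unique_top >= n_union)
    stop("with more than one panel miRNA, n_unique_top must be below n_union")
  genes <- sprintf("TGT%03d", seq_len(n_union))
  top <- panel[1L]
  n_shared <- if (length(panel) > 1L) min(4L, n_union - n_unique_top) else 0L
  top_genes <- genes[seq_len(n_unique_top + n_shared)]
  rows <- data.frame(mirna = top, gene = top_genes,
                     evidence = "synthetic_luciferase", stringsAsFactors = FALSE)
  if (length(panel) > 1L) {
    others <- panel[-1L]
    rest <- genes[seq(n_unique_top + 1L, n_union)]  # shared + others-only
    assign_to <- rep(others, length.out = length(rest))
    rows <- rbind(rows, data.frame(mirna = assign_to, gene = rest,
                                   evidence = "synthetic_luciferase",
                                   stringsAsFactors = FALSE))
  }
  rows <- rows[!duplicated(rows[, c("mirna", "gene")]), , drop = FALSE]

  pathway_genes <- c(genes[seq_len(pathway_overlap)],
                     sprintf("PWY%03d", seq_len(pathway_size - pathway_overlap)))
  sets <- list(SYNTHETIC_FOCAL_PATHWAY = pathway_genes)
  if (n_decoy_sets > 0) {
    bg <- sprintf("BG%05d", seq_len(universe_size - n_union - (pathway_size - pathway_overlap)))
    with_pinned_rng(seed, {
      for (i in seq_len(n_decoy_sets)) {
        sz <- sample(10:200, 1L)
        sets[[sprintf("SYNTHETIC_DECOY_%03d", i)]] <- sample(bg, sz)
      }
    })
  }
  list(targets = rows,
       collection = gene_set_collection(sets, universe_size = universe_size),
       pathway = "SYNTHETIC_FOCAL_PATHWAY")
}
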