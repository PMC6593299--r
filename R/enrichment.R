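#' Collect validated target genes of a miRNA panel
#'
#' Union of the validated target genes over the DE miRNA panel,
#' deduplicated. A panel miRNA with no row in the target table triggers a
#' warning (not an error). Per-miRNA target counts are attached as the
#' `per_mirna` attribute and reported.
#'
#' @param de_mirnas Character vector of miRNA IDs (the DE panel).
#' @param targets Target table from [read_target_table()] (columns `mirna`,
#'   `gene`).
#' @return Character vector of gene symbols (the query set), with attribute
#'   `per_mirna` (named integer vector of per-miRNA target counts).
#' @export
collect_target_genes <- function(de_mirnas, targets) {
  stopifnot(is.character(de_mirnas), is.data.frame(targets),
            all(c("mirna", "gene") %in% colnames(targets)))
  if (length(de_mirnas) == 0L) {
    return(structure(character(0), per_mirna = integer(0)))
  }
  absent <- setdiff(de_mirnas, unique(targets$mirna))
  if (length(absent)) {
    warning("no validated targets recorded for: ", paste(absent, collapse = ", "))
  }
  hit <- targets[targets$mirna %in% de_mirnas, , drop = FALSE]
  per <- vapply(de_mirnas, function(m) sum(hit$mirna == m), integer(1L))
  genes <- unique(hit$gene)
  message("target genes: ", length(genes), " unique over ", length(de_mirnas),
          " miRNAs (", paste(sprintf("%s=%d", de_mirnas, per), collapse = ", "), ")")
  structure(genes, per_mirna = per)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` query hits in a `K`-gene set when `n` genes are drawn without
#' replacement from an `N`-gene background.
#'
#' @param k Observed overlap.
#' @param K Gene-set size.
#' @param n Query size.
#' @param N Background universe size.
#' @return Upper-tail probability in `(0, 1]`.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) != round(c(k, K, n, N))) || any(c(k, K, n, N) < 0))
    stop("k, K, n, N must be non-negative integers")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (k > min(K, n)) stop("k must not exceed min(K, n)")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of gene sets
#'
#' Tests every set in the collection for over-representation of the query
#' genes: `k = |query & set|`, `K = |set|`, `n = |query|`, against a
#' background of `N` genes. Both Bonferroni and BH corrections are reported;
#' results are sorted by raw p. Query genes outside a declared universe are
#' counted, logged and excluded from `n` when `restrict_to_universe` is set
#' (the default when the collection carries a universe).
#'
#' @param query Character vector of gene symbols.
#' @param collection A [gene_set_collection()].
#' @param N Background universe size; defaults to the collection's declared
#'   size, else 20000 (approximate protein-coding gene count).
#' @param restrict_to_universe Drop query genes absent from the collection's
#'   universe before testing? Only meaningful when a universe is declared.
#' @return data.frame, one row per set, sorted by raw p: `set`, `k`, `K`,
#'   `n`, `N`, `pvalue`, `bonferroni`, `bh`, `genes` (overlap, comma-joined).
#' @export
enrich_gene_sets <- function(query, collection, N = NULL,
                             restrict_to_universe = !is.null(collection$universe)) {
  stopifnot(inherits(collection, "gene_set_collection"), is.character(query))
  query <- unique(toupper(trimws(query)))
  if (is.null(N)) N <- if (!is.null(collection$universe_size)) collection$universe_size else 20000L
  if (restrict_to_universe && !is.null(collection$universe)) {
    outside <- setdiff(query, collection$universe)
    if (length(outside)) {
      message("enrichment: ", length(outside),
              " query gene(s) outside the declared universe, excluded")
      query <- intersect(query, collection$universe)
    }
  }
  n <- length(query)
  max_K <- max(lengths(collection$sets))
  if (N < n || N < max_K) stop("background N must be at least the query and set sizes")
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    ov <- intersect(query, set)
    data.frame(set = nm, k = length(ov), K = length(set), n = n, N = N,
               pvalue = hypergeom_upper_tail(length(ov), length(set), n, N),
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
    })
  res <- do.call(rbind, rows)
  m <- nrow(res)
  res$bonferroni <- pmin(1, res$pvalue * m)
  res$bh <- bh_adjust(res$pvalue)
  res <- res[order(res$pvalue, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("set", "k", "K", "n", "N", "pvalue", "bonferroni", "bh", "genes")]
}
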