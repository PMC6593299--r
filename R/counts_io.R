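#' Read a miRNA count matrix from TSV
#'
#' Reads a tab-separated count table (header row; first column = feature IDs,
#' remaining columns = one sample each) into a validated integer matrix.
#' Malformed cells are rejected, never coerced: every count must be a
#' non-negative integer and every cell must be present.
#'
#' @param path Path to a TSV file.
#' @param precursor_column Optional name of a column holding precursor
#'   (hairpin) IDs. When given, that column supplies the feature IDs and the
#'   matrix is precursor-level; merge to mature IDs with
#'   [merge_mature_counts()].
#' @return Integer matrix, features x samples, with unique dimnames.
#' @seealso [merge_mature_counts()], [filter_low_abundance()]
#' @export
read_count_matrix <- function(path, precursor_column = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("count matrix file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("count matrix needs a feature-ID column plus at least one sample column")
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  id_col <- 1L
  if (!is.null(precursor_column)) {
    id_col <- match(precursor_column, header)
    if (is.na(id_col)) stop("precursor column '", precursor_column, "' not found in ", path)
  }
  dup_s <- header[-id_col][duplicated(header[-id_col])]
  if (length(dup_s)) stop("duplicate sample columns: ", paste(unique(dup_s), collapse = ", "))
  features <- trimws(tab[[id_col]])
  num <- tab[, -id_col, drop = FALSE]
  samples <- header[-id_col]
  dup_f <- features[duplicated(features)]
  if (length(dup_f)) stop("duplicate feature IDs: ", paste(unique(dup_f), collapse = ", "))

  counts <- matrix(NA_real_, nrow = nrow(tab), ncol = ncol(num),
                   dimnames = list(features, samples))
  for (j in seq_along(samples)) {
    cell <- trimws(num[[j]])
    bad <- which(is.na(cell) | cell == "" | cell == "NA")
    if (length(bad)) {
      stop("missing count at row '", features[bad[1L]], "', column '", samples[j], "'")
    }
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val))
    if (length(bad)) {
      stop("non-numeric count '", cell[bad[1L]], "' at row '", features[bad[1L]],
           "', column '", samples[j], "'")
    }
    counts[, j] <- val
  }
  validate_count_matrix(counts, where = path)
  storage.mode(counts) <- "integer"
  counts
}

#' @noRd
validate_count_matrix <- function(counts, where = "count matrix") {
  if (!is.matrix(counts) || !is.numeric(counts)) stop("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature and sample names")
  if (anyDuplicated(rownames(counts))) stop("duplicate feature IDs in ", where)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample IDs in ", where)
  if (anyNA(counts)) stop("missing counts in ", where)
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative count at row '", rownames(counts)[neg[1L, 1L]],
         "', column '", colnames(counts)[neg[1L, 2L]], "' in ", where)
  }
  frac <- which(counts != round(counts), arr.ind = TRUE)
  if (nrow(frac)) {
    stop("non-integer count at row '", rownames(counts)[frac[1L, 1L]],
         "', column '", colnames(counts)[frac[1L, 2L]], "' in ", where)
  }
  invisible(counts)
}

#' Write a count matrix (or any matrix) to TSV
#'
#' Inverse of [read_count_matrix()]: first column `feature`, one column per
#' sample.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param feature_column Name for the ID column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path, feature_column = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- feature_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge precursor-level counts to mature miRNAs
#'
#' Read counts mapped to the same mature miRNA but derived from different
#' genomic precursors are summed per sample. Per-sample totals are conserved
#' exactly. Output features follow the first-appearance order of the mature
#' IDs in the precursor ordering.
#'
#' @param cm Precursor-level count matrix (rows = precursor IDs).
#' @param mapping Named character vector, `names` = precursor IDs,
#'   values = mature IDs; or a two-column data.frame (precursor, mature).
#' @return Mature-level integer count matrix.
#' @export
merge_mature_counts <- function(cm, mapping) {
  validate_count_matrix(cm)
  if (is.data.frame(mapping)) {
    mapping <- stats::setNames(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  }
  missing <- setdiff(rownames(cm), names(mapping))
  if (length(missing)) {
    stop("precursors missing from mapping: ", paste(missing, collapse = ", "))
  }
  mature <- unname(mapping[rownames(cm)])
  order_first <- unique(mature)
  out <- rowsum(cm, group = factor(mature, levels = order_first), reorder = FALSE)
  storage.mode(out) <- "integer"
  out[order_first, , drop = FALSE]
}

#' Filter miRNAs of insufficient abundance
#'
#' Keeps features whose total read count across all samples is at least
#' `min_total`; the boundary is retained (a feature totalling exactly
#' `min_total` stays in). Row order of the survivors is preserved, the sample
#' set is unchanged, and the operation is idempotent.
#'
#' @param cm Count matrix (mature-level).
#' @param min_total Minimum total count across samples; default 200.
#' @return Filtered count matrix.
#' @export
filter_low_abundance <- function(cm, min_total = 200) {
  validate_count_matrix(cm)
  stopifnot(is.numeric(min_total), length(min_total) == 1L, min_total >= 0)
  keep <- rowSums(cm) >= min_total
  if (!any(keep)) {
    stop("all ", nrow(cm), " features fall below total count ", min_total,
         "; review the abundance threshold")
  }
  cm[keep, , drop = FALSE]
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample`, `group`, `age` (years) and, optionally, `sex`
#' and `bmi`. Group labels must come from `{case, control}` (default
#' "DR"/"NDR"); anything else is rejected. Group sizes are reported via
#' [message()].
#'
#' @param path TSV path.
#' @param case,control Group labels for cases and controls.
#' @return data.frame with `group` as a factor, levels `(control, case)`.
#' @export
read_sample_metadata <- function(path, case = "DR", control = "NDR") {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("sample", "group", "age")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$group), c(case, control))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "),
                        " (expected '", case, "' or '", control, "')")
  if (anyDuplicated(tab$sample)) stop("duplicate sample IDs in metadata")
  if (!is.numeric(tab$age) || anyNA(tab$age)) stop("age must be numeric and complete")
  tab$group <- factor(tab$group, levels = c(control, case))
  if (any(table(tab$group) == 0L)) stop("both groups must be non-empty")
  n <- table(tab$group)
  message("sample metadata: ", n[[case]], " ", case, " vs ", n[[control]], " ", control)
  tab
}

#' Read a miRNA -> validated target gene table
#'
#' Expects columns `mirna`, `gene` and optionally `evidence`. Whitespace is
#' trimmed and gene symbols upper-cased before deduplicating (miRNA, gene)
#' pairs; the number of dropped duplicates is reported.
#'
#' @param path TSV path.
#' @return data.frame with columns `mirna`, `gene`, `evidence`.
#' @export
read_target_table <- function(path) {
  if (!file.exists(path)) stop("target table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("mirna", "gene")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("target table missing columns: ", paste(miss, collapse = ", "))
  tab$mirna <- trimws(tab$mirna)
  tab$gene <- toupper(trimws(tab$gene))
  if (is.null(tab$evidence)) tab$evidence <- NA_character_
  dup <- duplicated(tab[, c("mirna", "gene")])
  if (any(dup)) {
    message("target table: dropped ", sum(dup), " duplicate (miRNA, gene) pairs")
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab[, c("mirna", "gene", "evidence")]
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors (gene symbols).
#' @param universe Optional character vector: the background gene universe.
#'   When supplied, every set must be a subset of it.
#' @param universe_size Declared background size N; defaults to
#'   `length(universe)` when a universe is given, else must be supplied at
#'   enrichment time.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL, universe_size = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  if (any(lengths(sets) == 0L)) stop("empty gene set(s): ",
                                     paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, function(g) unique(toupper(trimws(g))))
  if (!is.null(universe)) {
    universe <- unique(toupper(trimws(universe)))
    outside <- vapply(sets, function(g) length(setdiff(g, universe)), integer(1L))
    if (any(outside > 0L)) {
      stop("gene set(s) contain genes outside the declared universe: ",
           paste(names(sets)[outside > 0L], collapse = ", "))
    }
    if (is.null(universe_size)) universe_size <- length(universe)
  }
  structure(list(sets = sets, universe = universe, universe_size = universe_size),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT path.
#' @inheritParams gene_set_collection
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL, universe_size = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    sets[[fields[[1L]]]] <- unique(fields[-(1:2)])
  }
  gene_set_collection(sets, universe = universe, universe_size = universe_size)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$sets), "sets")
  if (!is.null(x$universe_size)) cat(", background N =", x$universe_size)
  cat("\n")
  invisible(x)
}
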