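#' Construct a perturbation rank matrix
#'
#' The compendium is stored as an integer matrix with one row per gene in
#' the shared universe and one column per instance (one treatment-vs-control
#' experiment for some compound). Each column is a full permutation of
#' `1..N`; rank 1 is the gene most up-regulated by the treatment relative to
#' control. Instance metadata (compound, dose, cell line) rides alongside.
#'
#' @param ranks Integer matrix, genes x instances, with rownames (gene
#'   universe) and colnames (instance ids); every column a permutation of
#'   `1..nrow(ranks)`.
#' @param meta `data.frame` with columns instance_id, compound, dose,
#'   cell_line; one row per column of `ranks`.
#' @return An object of class `rank_matrix` with elements `ranks`, `meta`,
#'   `universe`.
#' @export
rank_matrix <- function(ranks, meta) {
  ranks <- as.matrix(ranks)
  storage.mode(ranks) <- "integer"
  if (is.null(rownames(ranks)) || is.null(colnames(ranks))) {
    stop("rank matrix needs gene rownames and instance colnames")
  }
  if (nrow(ranks) < 2L) stop("gene universe must have N >= 2")
  if (anyDuplicated(rownames(ranks))) stop("duplicate gene in universe")
  if (anyDuplicated(colnames(ranks))) stop("duplicate instance_id")
  need <- c("instance_id", "compound", "dose", "cell_line")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns ", paste(need, collapse = ", "))
  }
  meta <- as.data.frame(meta)[, need]
  meta[] <- lapply(meta, as.character)
  extra_meta <- setdiff(meta$instance_id, colnames(ranks))
  if (length(extra_meta) > 0L) {
    warning(length(extra_meta),
            " metadata rows without a matrix column; dropped", call. = FALSE)
    meta <- meta[!meta$instance_id %in% extra_meta, , drop = FALSE]
  }
  missing_meta <- setdiff(colnames(ranks), meta$instance_id)
  if (length(missing_meta) > 0L) {
    stop("instance without metadata: ", missing_meta[1L])
  }
  if (any(!nzchar(meta$compound))) {
    stop("empty compound name for instance ",
         meta$instance_id[!nzchar(meta$compound)][1L])
  }
  meta <- meta[match(colnames(ranks), meta$instance_id), , drop = FALSE]
  rownames(meta) <- NULL
  check_permutation_columns(ranks)
  structure(list(ranks = ranks, meta = meta, universe = rownames(ranks)),
            class = "rank_matrix")
}

check_permutation_columns <- function(ranks) {
  n <- nrow(ranks)
  want <- sum(seq_len(n))
  for (j in seq_len(ncol(ranks))) {
    col <- ranks[, j]
    # fast reject by sum, then exact check
    if (sum(col) != want || anyDuplicated(col) || min(col) < 1L || max(col) > n) {
      stop("column '", colnames(ranks)[j], "' is not a permutation of 1..", n)
    }
  }
  invisible(ranks)
}

#' @export
print.rank_matrix <- function(x, ...) {
  cat(sprintf("<rank_matrix> %d genes x %d instances, %d compounds\n",
              nrow(x$ranks), ncol(x$ranks), length(unique(x$meta$compound))))
  invisible(x)
}

#' Number of instances in a rank matrix
#' @param x A `rank_matrix`.
#' @return Integer instance count.
#' @export
n_instances <- function(x) ncol(x$ranks)

#' Read a perturbation compendium
#'
#' Accepts either GCT 1.2 (first line `#1.2`, then `N M`, then a header row
#' `NAME  Description  <instance ids...>` and one row per gene) or a plain
#' headered TSV whose first column holds gene identifiers. Every column is
#' validated as a permutation of `1..N`; every column must have a metadata
#' row (CSV with header `instance_id,compound,dose,cell_line`).
#'
#' @param matrix_path Path to the GCT/TSV rank matrix.
#' @param meta_path Path to the metadata CSV.
#' @param invert_ranks If `TRUE`, flip rank orientation (`r -> N+1-r`) for
#'   compendia stored with rank 1 = most down-regulated.
#' @return A `rank_matrix`.
#' @export
read_rank_matrix <- function(matrix_path, meta_path, invert_ranks = FALSE) {
  if (!file.exists(matrix_path)) stop("rank matrix not found: ", matrix_path)
  if (!file.exists(meta_path)) stop("metadata not found: ", meta_path)
  first <- readLines(matrix_path, n = 1L, warn = FALSE)
  if (startsWith(first, "#")) {
    if (trimws(first) != "#1.2") {
      stop("unrecognized dialect: '#' first line but not GCT 1.2 (#1.2): ",
           matrix_path)
    }
    dims <- scan(matrix_path, what = integer(), skip = 1L, nlines = 1L,
                 quiet = TRUE)
    tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                             skip = 2L, check.names = FALSE,
                             stringsAsFactors = FALSE, quote = "")
    if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L]) {
      stop("GCT dimension line disagrees with table: ", matrix_path)
    }
    ranks <- as.matrix(tab[, -c(1L, 2L), drop = FALSE])
    rownames(ranks) <- tab[[1L]]
  } else {
    tab <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE,
                             quote = "")
    ranks <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(ranks) <- tab[[1L]]
  }
  storage.mode(ranks) <- "integer"
  if (invert_ranks) ranks <- nrow(ranks) + 1L - ranks
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  rm <- rank_matrix(ranks, meta)
  message(sprintf("read_rank_matrix: %d genes x %d instances from %s",
                  nrow(rm$ranks), ncol(rm$ranks), matrix_path))
  rm
}

#' Write a perturbation compendium
#'
#' @param x A `rank_matrix`.
#' @param matrix_path Output path for the rank matrix.
#' @param meta_path Output path for the metadata CSV.
#' @param format `"tsv"` (headered, first column `gene`) or `"gct"`
#'   (GCT 1.2).
#' @export
write_rank_matrix <- function(x, matrix_path, meta_path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "rank_matrix"))
  tab <- data.frame(gene = rownames(x$ranks), x$ranks,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (format == "tsv") {
    utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(matrix_path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(x$ranks), ncol(x$ranks), sep = "\t")), con)
    gct <- data.frame(NAME = rownames(x$ranks), Description = "na", x$ranks,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(gct, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(x$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(matrix_path)
}

#' Convert a treatment/control expression pair to a rank vector
#'
#' Genes are ordered by descending `log2(treatment/control)` and assigned
#' ranks `1..N` in that order (rank 1 = most up-regulated); ties are broken
#' by universe order, so the result is stable.
#'
#' @param treatment Named numeric vector of expression values (> 0).
#' @param control Named numeric vector over the same genes.
#' @return Named integer rank vector over the shared universe, in
#'   `names(treatment)` order.
#' @export
ranks_from_expression <- function(treatment, control) {
  if (is.null(names(treatment)) || is.null(names(control))) {
    stop("expression vectors must be named by gene")
  }
  if (!setequal(names(treatment), names(control)) ||
      length(treatment) != length(control)) {
    stop("treatment and control gene sets differ")
  }
  control <- control[names(treatment)]
  if (any(!is.finite(treatment)) || any(!is.finite(control)) ||
      any(treatment <= 0) || any(control <= 0)) {
    stop("expression values must be finite and > 0")
  }
  lr <- log2(treatment / control)
  ord <- order(-lr, seq_along(lr))   # stable: ties keep universe order
  ranks <- integer(length(lr))
  ranks[ord] <- seq_along(lr)
  names(ranks) <- names(treatment)
  ranks
}
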