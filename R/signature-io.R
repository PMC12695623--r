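#' Construct a signed query signature
#'
#' A signed signature is the pair of gene tag lists that defines a
#' connectivity query: `up_tags` are the genes up-regulated in the state of
#' interest (here, the regenerating-neuron transcriptional state the screen
#' was built around), `down_tags` the down-regulated ones. A compound
#' "mimics" the query when its instances rank the up-tags near the top and
#' the down-tags near the bottom of the perturbation ranking.
#'
#' @param name Query identifier.
#' @param up_tags Character vector of up-regulated gene identifiers.
#' @param down_tags Character vector of down-regulated gene identifiers.
#' @param provenance Free-text note on where the signature came from.
#' @return An object of class `signed_signature`.
#' @export
signed_signature <- function(name, up_tags, down_tags, provenance = "") {
  up_tags <- as.character(up_tags)
  down_tags <- as.character(down_tags)
  if (anyDuplicated(up_tags)) stop("up_tags contains duplicates")
  if (anyDuplicated(down_tags)) stop("down_tags contains duplicates")
  if (length(intersect(up_tags, down_tags)) > 0L) {
    stop("up_tags and down_tags must be disjoint; shared: ",
         paste(utils::head(intersect(up_tags, down_tags), 5L), collapse = ", "))
  }
  structure(
    list(name = as.character(name)[1L], up_tags = up_tags,
         down_tags = down_tags, provenance = as.character(provenance)[1L]),
    class = "signed_signature"
  )
}

#' @export
print.signed_signature <- function(x, ...) {
  cat(sprintf("<signed_signature> %s: %d up tags, %d down tags\n",
              x$name, length(x$up_tags), length(x$down_tags)))
  invisible(x)
}

#' Read a GRP gene list
#'
#' GRP is the one-gene-per-line list format; lines starting with `#` are
#' comments. Duplicates are removed keeping the first occurrence.
#'
#' @param path Path to a GRP file.
#' @return Character vector of gene identifiers in file order.
#' @export
read_grp <- function(path) {
  if (!file.exists(path)) stop("GRP file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(lines)
  if (length(genes) == 0L) stop("no gene identifiers in GRP file: ", path)
  message(sprintf("read_grp: %d identifiers from %s", length(genes), path))
  genes
}

#' Write a GRP gene list
#'
#' @param genes Character vector of gene identifiers.
#' @param path Output path.
#' @export
write_grp <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT is the tab-separated MSigDB carrier: each line holds a set name, a
#' description (discarded), then one or more gene identifiers. Within-set
#' duplicates are removed; duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return An object of class `gene_set_collection`: a named list of
#'   duplicate-free gene identifier vectors, with attribute `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) {
      stop(sprintf("GMT line %d has %d fields (need name, description, >=1 gene): %s",
                   i, length(fields), path))
    }
    nms[i] <- fields[1L]
    sets[[i]] <- unique(fields[-c(1L, 2L)])
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set name in GMT: ", nms[duplicated(nms)][1L])
  }
  names(sets) <- nms
  gene_set_collection(sets, source = path)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of gene identifier vectors.
#' @param source Label or path recording where the sets came from.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, source = "") {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) stop("gene-set names must be unique")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop("empty gene set: ",
                                     names(sets)[lengths(sets) == 0L][1L])
  structure(sets, source = source, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Write a gene-set collection to GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects a delimited file with header columns `gene`, `log2fc`, `adj_p`
#' (extra columns are ignored). Delimiter is inferred from the extension
#' (`.csv` comma, otherwise tab).
#'
#' @param path Path to the table.
#' @return A `data.frame` with columns gene, log2fc, adj_p.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  de <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene", "log2fc", "adj_p")
  if (!all(need %in% names(de))) {
    stop("DE table must have header columns gene, log2fc, adj_p; found: ",
         paste(names(de), collapse = ", "))
  }
  de <- de[, need]
  validate_de_table(de)
  de
}

validate_de_table <- function(de) {
  if (nrow(de) == 0L) stop("DE table is empty")
  if (anyDuplicated(de$gene)) {
    stop("duplicate gene_id in DE table: ", de$gene[duplicated(de$gene)][1L])
  }
  if (any(!is.finite(de$log2fc))) stop("non-finite log2fc in DE table")
  if (any(de$adj_p < 0 | de$adj_p > 1 | !is.finite(de$adj_p))) {
    stop("adj_p outside [0,1] in DE table")
  }
  invisible(de)
}

#' Build a signed signature from a differential-expression table
#'
#' Genes with `log2fc >= lfc_threshold` and `adj_p < p_threshold` become
#' up-tags (sorted by descending log2fc); genes with
#' `log2fc <= -lfc_threshold` and `adj_p < p_threshold` become down-tags
#' (ascending log2fc). Each list is truncated to `max_tags`; ties in log2fc
#' keep input row order so results are reproducible.
#'
#' The default fold-change cutoff of 1.5 on the log2 scale mirrors the
#' threshold used when the screen's downstream expression comparisons were
#' made; it is deliberately conservative for a rank-based statistic.
#'
#' @param de `data.frame` with columns gene, log2fc, adj_p.
#' @param lfc_threshold Non-negative log2 fold-change cutoff (default 1.5).
#' @param p_threshold Adjusted-p cutoff in (0, 1] (default 0.05).
#' @param max_tags Maximum tags kept per side (default 250).
#' @param name Signature name.
#' @return A `signed_signature`.
#' @export
build_signature <- function(de, lfc_threshold = 1.5, p_threshold = 0.05,
                            max_tags = 250L, name = "query") {
  stopifnot(lfc_threshold >= 0, p_threshold > 0, p_threshold <= 1,
            max_tags >= 1)
  validate_de_table(de)
  sig_rows <- de$adj_p < p_threshold
  up <- which(sig_rows & de$log2fc >= lfc_threshold)
  dn <- which(sig_rows & de$log2fc <= -lfc_threshold)
  if (length(up) == 0L) {
    stop("no genes pass the up-regulation thresholds (log2fc >= ",
         lfc_threshold, ", adj_p < ", p_threshold,
         "); relax lfc_threshold or p_threshold")
  }
  if (length(dn) == 0L) {
    stop("no genes pass the down-regulation thresholds (log2fc <= -",
         lfc_threshold, ", adj_p < ", p_threshold,
         "); relax lfc_threshold or p_threshold")
  }
  # stable sorts: ties in log2fc keep input row order
  up <- up[order(-de$log2fc[up], up)]
  dn <- dn[order(de$log2fc[dn], dn)]
  up <- utils::head(up, max_tags)
  dn <- utils::head(dn, max_tags)
  signed_signature(name, de$gene[up], de$gene[dn],
                   provenance = sprintf(
                     "build_signature(lfc>=%.3g, adj_p<%.3g, max_tags=%d)",
                     lfc_threshold, p_threshold, as.integer(max_tags)))
}

#' Match a signature to a compendium gene universe
#'
#' Matching is exact string equality after whitespace trimming and
#' case-folding. Unmatched tags are dropped with a warning, not an error:
#' compendium probe/symbol vocabularies rarely cover a query exactly.
#' Matched tags are returned in the universe's spelling.
#'
#' @param sig A `signed_signature`.
#' @param universe Character vector: the compendium's gene identifiers.
#' @return A `signed_signature` whose tags all exist in `universe`.
#' @export
match_signature <- function(sig, universe) {
  stopifnot(inherits(sig, "signed_signature"))
  key <- function(x) toupper(trimws(x))
  uni_key <- key(universe)
  match_side <- function(tags, side) {
    idx <- match(key(tags), uni_key)
    dropped <- sum(is.na(idx))
    if (dropped > 0L) {
      warning(sprintf("%d of %d %s tags not in compendium universe; dropped",
                      dropped, length(tags), side), call. = FALSE)
    }
    unique(universe[idx[!is.na(idx)]])
  }
  up <- match_side(sig$up_tags, "up")
  dn <- match_side(sig$down_tags, "down")
  if (length(up) == 0L) stop("no up tags match the compendium universe")
  if (length(dn) == 0L) stop("no down tags match the compendium universe")
  signed_signature(sig$name, up, dn, provenance = sig$provenance)
}
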