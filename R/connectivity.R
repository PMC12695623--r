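#' Two-sided KS enrichment of a tag list in one ranking
#'
#' The classic Connectivity Map statistic. With `t` tags whose ascending
#' rank positions in the instance are `V(1) < ... < V(t)` and a universe of
#' `N` genes, compute
#' \deqn{a = \max_j\left(\frac{j}{t} - \frac{V(j)}{N}\right), \qquad
#'       b = \max_j\left(\frac{V(j)}{N} - \frac{j-1}{t}\right)}
#' and return `a` if `a > b`, else `-b`. A positive score means the tags
#' concentrate near the top of the ranking (up-regulated by the
#' perturbation), a negative score near the bottom. The tie `a == b`
#' resolves to `-b`; on integer ranks both maxima are exact rational
#' quantities represented in double precision.
#'
#' @param tags Character vector of gene identifiers (all present in the
#'   instance universe) or an integer vector of rank positions.
#' @param ranks Named integer rank vector for one instance (a permutation
#'   of `1..N`). Ignored when `tags` is already positions and `n_genes`
#'   given.
#' @param n_genes Universe size `N` when `tags` is given as positions.
#' @return Enrichment score in `[-1, 1]`.
#' @export
ks_enrichment <- function(tags, ranks = NULL, n_genes = NULL) {
  if (is.numeric(tags)) {
    v <- as.integer(tags)
    n <- as.integer(n_genes)
    if (is.null(n_genes)) stop("n_genes required when tags are positions")
  } else {
    if (length(tags) == 0L) stop("empty tag list")
    v <- ranks[tags]
    if (any(is.na(v))) {
      stop("tag absent from instance universe: ",
           tags[is.na(v)][1L])
    }
    n <- length(ranks)
  }
  if (length(v) == 0L) stop("empty tag list")
  if (length(v) > n) stop("more tags than genes")
  ks_stat(sort(v), n)
}

# core statistic on sorted positions; no validation
ks_stat <- function(v_sorted, n) {
  t <- length(v_sorted)
  j <- seq_len(t)
  a <- max(j / t - v_sorted / n)
  b <- max(v_sorted / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Score one instance against a signed signature
#'
#' `ks_up` and `ks_down` are the KS enrichment of the up- and down-tag
#' lists. When they share a sign the instance carries no consistent
#' directional information about the query and is declared null
#' (`raw_score = 0`); otherwise `raw_score = ks_up - ks_down`, positive for
#' a mimic (up-tags high, down-tags low) and negative for an anti-mimic.
#'
#' @param sig A `signed_signature` already matched to the universe.
#' @param ranks Named integer rank vector for one instance.
#' @return List with `ks_up`, `ks_down`, `raw_score`, `is_null`.
#' @export
instance_score <- function(sig, ranks) {
  ks_up <- ks_enrichment(sig$up_tags, ranks)
  ks_down <- ks_enrichment(sig$down_tags, ranks)
  if (sign(ks_up) == sign(ks_down)) {
    list(ks_up = ks_up, ks_down = ks_down, raw_score = 0, is_null = TRUE)
  } else {
    list(ks_up = ks_up, ks_down = ks_down,
         raw_score = ks_up - ks_down, is_null = FALSE)
  }
}

#' Score every instance of a compendium against a signed signature
#'
#' Vectorised driver for [instance_score()]: the signature is matched to
#' the compendium universe once (unmatched tags dropped with a warning),
#' each instance is scored, and raw scores are scaled onto `[-1, +1]` with
#' [scale_scores()] across all instances of the run.
#'
#' @param sig A `signed_signature`.
#' @param rmat A `rank_matrix`.
#' @param match_universe Match/drop tags against the universe first
#'   (default `TRUE`; set `FALSE` when tags are known to be in-universe).
#' @return `data.frame` with one row per instance: instance_id, compound,
#'   ks_up, ks_down, raw_score, scaled_score, is_null.
#' @export
score_instances <- function(sig, rmat, match_universe = TRUE) {
  stopifnot(inherits(sig, "signed_signature"), inherits(rmat, "rank_matrix"))
  if (match_universe) sig <- match_signature(sig, rmat$universe)
  up_idx <- match(sig$up_tags, rmat$universe)
  dn_idx <- match(sig$down_tags, rmat$universe)
  n <- nrow(rmat$ranks)
  m <- ncol(rmat$ranks)
  up_pos <- rmat$ranks[up_idx, , drop = FALSE]
  dn_pos <- rmat$ranks[dn_idx, , drop = FALSE]
  ks_up <- vapply(seq_len(m), function(i) ks_stat(sort.int(up_pos[, i]), n),
                  numeric(1L))
  ks_down <- vapply(seq_len(m), function(i) ks_stat(sort.int(dn_pos[, i]), n),
                    numeric(1L))
  is_null <- sign(ks_up) == sign(ks_down)
  raw <- ifelse(is_null, 0, ks_up - ks_down)
  res <- data.frame(
    instance_id = colnames(rmat$ranks),
    compound = rmat$meta$compound,
    ks_up = ks_up, ks_down = ks_down,
    raw_score = raw, scaled_score = NA_real_, is_null = is_null,
    stringsAsFactors = FALSE
  )
  scale_scores(res)
}

#' Scale raw connectivity scores onto the interval -1..+1
#'
#' With `p` the maximum positive and `q` the minimum negative raw score
#' across all instances of the run, each positive raw score maps to
#' `raw / p` and each negative one to `-raw / q`; nulls stay 0. After
#' scaling, the best mimic instance in the run sits at +1 and the strongest
#' anti-mimic at -1, matching the conventional presentation of a
#' connectivity screen. Scaling is per query across the whole run, not per
#' compound.
#'
#' @param results `data.frame` with a `raw_score` column (as produced by
#'   [score_instances()]), or a bare numeric vector of raw scores.
#' @return The same object with `scaled_score` filled (or the scaled
#'   vector).
#' @export
scale_scores <- function(results) {
  raw <- if (is.data.frame(results)) results$raw_score else results
  if (length(raw) == 0L) stop("no scores to scale")
  scaled <- numeric(length(raw))
  pos <- raw > 0
  neg <- raw < 0
  if (any(pos)) scaled[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) scaled[neg] <- -raw[neg] / min(raw[neg])
  if (is.data.frame(results)) {
    results$scaled_score <- scaled
    results
  } else {
    scaled
  }
}

#' Write a per-instance score table
#'
#' @param results Instance-score `data.frame` from [score_instances()].
#' @param path Output TSV path.
#' @export
write_instance_scores <- function(results, path) {
  cols <- c("instance_id", "compound", "ks_up", "ks_down", "raw_score",
            "scaled_score", "is_null")
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
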