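#' Aggregate one compound's instance scores
#'
#' The compound-level connectivity is the arithmetic mean of its instances'
#' scaled scores; null instances contribute 0 (they are retained, not
#' discarded, so they dilute inconsistent compounds). Spread is the sample
#' standard deviation (0 for a single instance).
#'
#' @param scaled Numeric vector of scaled instance scores for one compound.
#' @return List with `mean_score`, `sd_score`, `instance_count`,
#'   `direction` (sign of the mean).
#' @export
summarize_compound <- function(scaled) {
  if (length(scaled) == 0L) stop("no instances for compound")
  m <- mean(scaled)
  list(mean_score = m,
       sd_score = if (length(scaled) > 1L) stats::sd(scaled) else 0,
       instance_count = length(scaled),
       direction = sign(m))
}

#' Replicate-consistency (non-null) ratio
#'
#' The fraction of a compound's instances that score non-null with the
#' majority direction. The majority direction is the sign of the sum of
#' non-null scaled scores (a tied sum falls back to the sign of the mean;
#' all-null compounds return 0). The denominator is all instances, nulls
#' included, so a compound whose replicates mostly fail the null rule is
#' penalised.
#'
#' @param scaled Numeric vector of scaled instance scores for one compound.
#' @param is_null Logical vector marking null instances.
#' @return Ratio in `[0, 1]`.
#' @export
non_null_ratio <- function(scaled, is_null) {
  stopifnot(length(scaled) == length(is_null), length(scaled) > 0L)
  nn <- scaled[!is_null]
  if (length(nn) == 0L) return(0)
  maj <- sign(sum(nn))
  if (maj == 0) maj <- sign(mean(scaled))
  if (maj == 0) return(0)
  sum(sign(nn) == maj) / length(scaled)
}

#' Permutation p-value for a compound's mean score
#'
#' The null asks: is this compound's mean scaled score larger in magnitude
#' than expected for an arbitrary set of `n` instances drawn from this run?
#' `B` resamples of size `n_instances` are drawn without replacement from
#' the pool of all instances' scaled scores; the two-sided, pseudo-counted
#' p-value is `(1 + #{|mean_b| >= |observed|}) / (B + 1)`. Resampling
#' instance scores (rather than re-labelling genes) keeps the null anchored
#' to the empirical score distribution of the compendium.
#'
#' @param observed_mean Observed mean scaled score.
#' @param n_instances Number of instances behind the observed mean.
#' @param pool Numeric vector: all instances' scaled scores in the run.
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed; the draw is deterministic given it.
#' @return p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(observed_mean, n_instances, pool, B = 1000L,
                               seed) {
  stopifnot(B >= 100L, n_instances >= 1L)
  if (length(pool) < n_instances) {
    stop("pool smaller than n_instances (", length(pool), " < ",
         n_instances, ")")
  }
  means <- with_local_seed(seed, {
    vapply(seq_len(B),
           function(b) mean(pool[sample.int(length(pool), n_instances)]),
           numeric(1L))
  })
  (1 + sum(abs(means) >= abs(observed_mean))) / (B + 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment in input order, values clipped to at most 1.
#'
#' @param p_values Numeric vector of raw p-values in `(0, 1]`.
#' @return Adjusted values, same order as input.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Build surrogate signed queries from unsigned background gene sets
#'
#' Background collections (MSigDB-style) are unsigned gene lists, but the
#' connectivity statistic needs a signed query. Each background set is
#' matched to the universe (sets left with fewer than 5 genes are dropped
#' with a warning), randomly halved into pseudo-up / pseudo-down tags, and
#' size-matched to the real query's `(t_up, t_down)` by seeded subsampling
#' when larger. At least 20 usable sets are required.
#'
#' @param background A `gene_set_collection`.
#' @param sig_sizes Integer pair `c(t_up, t_down)` of the real query.
#' @param universe Compendium gene universe.
#' @param seed Integer seed for halving/subsampling.
#' @return Named list of `signed_signature` surrogates.
#' @export
make_surrogate_signatures <- function(background, sig_sizes, universe, seed) {
  stopifnot(length(sig_sizes) == 2L, all(sig_sizes >= 1L))
  key <- toupper(trimws(universe))
  matched <- lapply(background, function(s) {
    unique(universe[stats::na.omit(match(toupper(trimws(s)), key))])
  })
  small <- lengths(matched) < 5L
  if (any(small)) {
    warning(sum(small), " background sets with < 5 matched genes dropped",
            call. = FALSE)
    matched <- matched[!small]
  }
  if (length(matched) < 20L) {
    stop("need >= 20 usable background sets after universe matching; have ",
         length(matched))
  }
  with_local_seed(seed, {
    out <- lapply(names(matched), function(nm) {
      genes <- sample(matched[[nm]])       # seeded shuffle, then halve
      half <- length(genes) %/% 2L
      up <- genes[seq_len(half)]
      dn <- genes[(half + 1L):length(genes)]
      if (length(up) > sig_sizes[1L]) up <- up[seq_len(sig_sizes[1L])]
      if (length(dn) > sig_sizes[2L]) dn <- dn[seq_len(sig_sizes[2L])]
      signed_signature(nm, up, dn, provenance = "surrogate background query")
    })
    names(out) <- names(matched)
    out
  })
}

#' Per-compound mean connectivity of surrogate background queries
#'
#' Each surrogate query is scored over all instances of the run (scaled per
#' query, exactly as the real query is) and averaged within each compound.
#'
#' @param background A `gene_set_collection`.
#' @param sig_sizes Integer pair `c(t_up, t_down)`.
#' @param rmat A `rank_matrix`.
#' @param seed Integer seed for surrogate construction.
#' @return Numeric matrix, compounds x background sets, of mean scaled
#'   scores.
#' @export
background_connectivity <- function(background, sig_sizes, rmat, seed) {
  surrogates <- make_surrogate_signatures(background, sig_sizes,
                                          rmat$universe, seed)
  compounds <- unique(rmat$meta$compound)
  grp <- factor(rmat$meta$compound, levels = compounds)
  bg <- vapply(surrogates, function(s) {
    sc <- score_instances(s, rmat, match_universe = FALSE)
    as.numeric(tapply(sc$scaled_score, grp, mean))
  }, numeric(length(compounds)))
  bg <- matrix(bg, nrow = length(compounds),
               dimnames = list(compounds, names(surrogates)))
  bg
}

#' Specificity of a compound's connectivity to the query
#'
#' How unusual is this compound's connectivity to the real query, relative
#' to its connectivity to arbitrary background gene sets? With `K`
#' background mean scores for the compound, specificity is
#' `1 - #{|background mean| >= |compound mean|} / K`: 1 means no background
#' set connects this compound as strongly as the query does (maximally
#' specific), 0 means every background set does.
#'
#' @param compound_mean The compound's mean scaled score for the real
#'   query.
#' @param bg_means Numeric vector: the compound's mean scaled scores for
#'   each surrogate background query (one row of
#'   [background_connectivity()]).
#' @return Specificity in `[0, 1]`.
#' @export
specificity_score <- function(compound_mean, bg_means) {
  if (length(bg_means) == 0L) stop("no background scores")
  1 - sum(abs(bg_means) >= abs(compound_mean)) / length(bg_means)
}

#' Composite reliability score
#'
#' A convex combination of six rescaled components, each oriented so larger
#' is better and bounded in `[0, 1]`:
#' `|mean_score|`, `1 - p_value`, `1 - fdr`,
#' `min(instance_count / n_cap, 1)`, `non_null_ratio`, `specificity`.
#' Default weights are equal; the instance-count saturation cap defaults to
#' `n_cap = 4` (replicates beyond 4 add little evidence). Both are
#' configurable, so an alternative composite can be swapped in without code
#' change.
#'
#' @param mean_score,p_value,fdr,instance_count,non_null,specificity The
#'   six components (vectors recycle together).
#' @param weights Six non-negative weights summing to 1, in the component
#'   order above.
#' @param n_cap Instance-count saturation cap.
#' @return Reliability in `[0, 1]`.
#' @export
reliability_score <- function(mean_score, p_value, fdr, instance_count,
                              non_null, specificity,
                              weights = rep(1 / 6, 6L), n_cap = 4L) {
  if (length(weights) != 6L || any(weights < 0)) {
    stop("weights must be 6 non-negative reals")
  }
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  comp <- cbind(abs(mean_score), 1 - p_value, 1 - fdr,
                pmin(instance_count / n_cap, 1), non_null, specificity)
  if (any(comp < -1e-12 | comp > 1 + 1e-12)) {
    stop("reliability components must lie in [0, 1]")
  }
  as.numeric(comp %*% weights)
}

#' Rank compounds into a screen report
#'
#' Sorts by descending reliability; ties break by descending
#' `|mean_score|`, then ascending compound name, so the order is total and
#' deterministic.
#'
#' @param summaries `data.frame` of compound summaries (one row per
#'   compound) with at least `reliability` and `mean_score` columns.
#' @return The same `data.frame`, sorted, with a `rank` column prepended.
#' @export
rank_compounds <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no compounds to rank")
  ord <- order(-summaries$reliability, -abs(summaries$mean_score),
               summaries$compound)
  out <- summaries[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Full compound table for a screen
#'
#' Drives the per-compound layer: aggregation, permutation p-values, BH
#' FDR, non-null ratios, background specificity and the composite
#' reliability, returning the ranked report.
#'
#' @param instance_scores Output of [score_instances()].
#' @param rmat The `rank_matrix` that was scored.
#' @param background A `gene_set_collection` for specificity.
#' @param sig_sizes Integer pair `c(t_up, t_down)` of the matched query.
#' @param B Permutation resamples per compound.
#' @param seed Integer seed (child seeds derived per stage).
#' @param weights Reliability weights (see [reliability_score()]).
#' @param n_cap Instance-count cap.
#' @return Ranked compound `data.frame` with columns rank, compound,
#'   mean_score, sd_score, instance_count, p_value, fdr, non_null_ratio,
#'   specificity, reliability, direction.
#' @export
summarize_screen <- function(instance_scores, rmat, background, sig_sizes,
                             B = 1000L, seed, weights = rep(1 / 6, 6L),
                             n_cap = 4L) {
  compounds <- unique(instance_scores$compound)
  pool <- instance_scores$scaled_score
  by_cmpd <- split(seq_len(nrow(instance_scores)), instance_scores$compound)
  perm_seeds <- derive_seed(seed, "perm", seq_along(compounds))
  rows <- lapply(seq_along(compounds), function(i) {
    idx <- by_cmpd[[compounds[i]]]
    s <- summarize_compound(instance_scores$scaled_score[idx])
    s$compound <- compounds[i]
    s$non_null_ratio <- non_null_ratio(instance_scores$scaled_score[idx],
                                       instance_scores$is_null[idx])
    s$p_value <- permutation_pvalue(s$mean_score, s$instance_count, pool,
                                    B = B, seed = perm_seeds[i])
    s
  })
  tab <- data.frame(
    compound = vapply(rows, `[[`, character(1L), "compound"),
    mean_score = vapply(rows, `[[`, numeric(1L), "mean_score"),
    sd_score = vapply(rows, `[[`, numeric(1L), "sd_score"),
    instance_count = vapply(rows, `[[`, integer(1L), "instance_count"),
    p_value = vapply(rows, `[[`, numeric(1L), "p_value"),
    stringsAsFactors = FALSE
  )
  tab$fdr <- bh_fdr(tab$p_value)
  tab$non_null_ratio <- vapply(rows, `[[`, numeric(1L), "non_null_ratio")
  bg <- background_connectivity(background, sig_sizes, rmat,
                                seed = derive_seed(seed, "specificity"))
  tab$specificity <- vapply(seq_len(nrow(tab)), function(i) {
    specificity_score(tab$mean_score[i], bg[tab$compound[i], ])
  }, numeric(1L))
  tab$reliability <- reliability_score(tab$mean_score, tab$p_value, tab$fdr,
                                       tab$instance_count, tab$non_null_ratio,
                                       tab$specificity, weights = weights,
                                       n_cap = n_cap)
  tab$direction <- sign(tab$mean_score)
  rank_compounds(tab)
}

#' Write the compound screen report
#'
#' @param report Ranked compound table from [summarize_screen()].
#' @param path Output TSV path.
#' @export
write_screen_report <- function(report, path) {
  cols <- c("compound", "mean_score", "sd_score", "instance_count",
            "p_value", "fdr", "non_null_ratio", "specificity",
            "reliability", "direction")
  utils::write.table(report[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
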