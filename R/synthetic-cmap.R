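#' Configuration for a synthetic perturbation compendium
#'
#' The generator emulates the geometry of a CMap-style compendium: a
#' shared gene universe of 10^3-10^4 genes, a few hundred compounds with a
#' handful of replicate instances each, most of them null (uniform random
#' rankings), plus planted mimics and anti-mimics of a planted signed
#' signature at a tunable effect size.
#'
#' @param n_genes Universe size (>= 100). Default 1000.
#' @param n_compounds Number of compounds (>= 10). Default 200.
#' @param instances_per_compound Replicates per compound: a single count or
#'   a `c(min, max)` range sampled per compound. Default 3.
#' @param effect_size Additive shift `lambda` applied to planted tags'
#'   latent gene scores, in latent-noise standard deviations. Default 3.
#' @param mimic_fraction Fraction of compounds planted as mimics.
#'   Default 0.10.
#' @param antimimic_fraction Fraction planted as anti-mimics. Default 0.05.
#' @param signature_sizes `c(t_up, t_down)` planted tag-list sizes.
#'   Default `c(50, 50)`.
#' @param n_background_sets Background gene sets generated. Default 50.
#' @param background_set_size Genes per background set. Default 100.
#' @param mode `"latent"` (graded latent-score shift) or `"hard"` (rank
#'   surgery: tags forced into the extreme rank blocks), for extreme-case
#'   tests.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000L, n_compounds = 200L,
                             instances_per_compound = 3L, effect_size = 3,
                             mimic_fraction = 0.10, antimimic_fraction = 0.05,
                             signature_sizes = c(50L, 50L),
                             n_background_sets = 50L,
                             background_set_size = 100L,
                             mode = c("latent", "hard"), seed = 1L) {
  mode <- match.arg(mode)
  cfg <- list(n_genes = as.integer(n_genes),
              n_compounds = as.integer(n_compounds),
              instances_per_compound = as.integer(instances_per_compound),
              effect_size = as.numeric(effect_size),
              mimic_fraction = as.numeric(mimic_fraction),
              antimimic_fraction = as.numeric(antimimic_fraction),
              signature_sizes = as.integer(signature_sizes),
              n_background_sets = as.integer(n_background_sets),
              background_set_size = as.integer(background_set_size),
              mode = mode, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_genes < 100L) stop("n_genes must be >= 100")
  if (cfg$n_compounds < 10L) stop("n_compounds must be >= 10")
  if (!length(cfg$instances_per_compound) %in% c(1L, 2L) ||
      any(cfg$instances_per_compound < 1L)) {
    stop("instances_per_compound must be a count >= 1 or a c(min, max) range")
  }
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  if (cfg$mimic_fraction < 0 || cfg$antimimic_fraction < 0 ||
      cfg$mimic_fraction + cfg$antimimic_fraction > 1) {
    stop("mimic_fraction + antimimic_fraction must lie in [0, 1]")
  }
  if (length(cfg$signature_sizes) != 2L || any(cfg$signature_sizes < 1L)) {
    stop("signature_sizes must be c(t_up, t_down) with both >= 1")
  }
  if (sum(cfg$signature_sizes) > cfg$n_genes) {
    stop("t_up + t_down exceeds n_genes")
  }
  if (cfg$background_set_size > cfg$n_genes) {
    stop("background_set_size exceeds n_genes")
  }
  invisible(cfg)
}

#' Simulate a compendium with planted ground truth
#'
#' Every instance draws i.i.d. standard-normal latent gene scores; a mimic
#' instance adds `+lambda` to the planted up-tags and `-lambda` to the
#' planted down-tags (anti-mimics reversed); genes are then ranked by
#' descending latent score into a permutation of `1..N` (rank 1 = most
#' up-regulated). Null compounds are untouched, so their rankings are
#' uniform random permutations. In `"hard"` mode the tags are instead
#' forced into the extreme rank blocks. Background sets are uniform draws
#' from the universe and may overlap the planted signature, as real
#' MSigDB sets would.
#'
#' @param config A `synthetic_config`.
#' @return List with elements `rank_matrix` (a [rank_matrix()]),
#'   `signature` (the planted [signed_signature()]), `background`
#'   (a [gene_set_collection()]), and `truth` (class `synthetic_truth`:
#'   per-compound labels in mimic/antimimic/null, the planted signature,
#'   and the config).
#' @export
simulate_compendium <- function(config) {
  validate_synthetic_config(config)
  n <- config$n_genes
  universe <- sprintf("g%05d", seq_len(n))
  compounds <- sprintf("cmpd_%03d", seq_len(config$n_compounds))

  with_local_seed(config$seed, {
    tags <- sample(universe, sum(config$signature_sizes))
    up <- tags[seq_len(config$signature_sizes[1L])]
    dn <- tags[config$signature_sizes[1L] + seq_len(config$signature_sizes[2L])]
    sig <- signed_signature("planted_query", up, dn,
                            provenance = "simulate_compendium")
    up_idx <- match(up, universe)
    dn_idx <- match(dn, universe)

    n_mimic <- round(config$mimic_fraction * config$n_compounds)
    n_anti <- round(config$antimimic_fraction * config$n_compounds)
    labels <- rep("null", config$n_compounds)
    planted <- sample.int(config$n_compounds, n_mimic + n_anti)
    labels[planted[seq_len(n_mimic)]] <- "mimic"
    if (n_anti > 0L) labels[planted[n_mimic + seq_len(n_anti)]] <- "antimimic"
    names(labels) <- compounds

    ipc <- config$instances_per_compound
    counts <- if (length(ipc) == 1L) rep(ipc, config$n_compounds) else {
      sample(seq.int(ipc[1L], ipc[2L]), config$n_compounds, replace = TRUE)
    }

    total <- sum(counts)
    ranks <- matrix(0L, nrow = n, ncol = total)
    rownames(ranks) <- universe
    inst_id <- character(total)
    inst_cmpd <- character(total)
    col <- 0L
    for (i in seq_len(config$n_compounds)) {
      dir <- switch(labels[i], mimic = 1, antimimic = -1, null = 0)
      for (r in seq_len(counts[i])) {
        col <- col + 1L
        g <- stats::rnorm(n)
        if (dir != 0) {
          if (config$mode == "latent") {
            g[up_idx] <- g[up_idx] + dir * config$effect_size
            g[dn_idx] <- g[dn_idx] - dir * config$effect_size
          } else {
            # rank surgery: force tags into the extreme blocks
            top <- if (dir > 0) up_idx else dn_idx
            bot <- if (dir > 0) dn_idx else up_idx
            g[top] <- Inf
            g[bot] <- -Inf
          }
        }
        ord <- order(-g, seq_len(n))
        rk <- integer(n)
        rk[ord] <- seq_len(n)
        ranks[, col] <- rk
        inst_id[col] <- sprintf("%s_r%d", compounds[i], r)
        inst_cmpd[col] <- compounds[i]
      }
    }
    colnames(ranks) <- inst_id
    meta <- data.frame(instance_id = inst_id, compound = inst_cmpd,
                       dose = "10uM", cell_line = "SYN1",
                       stringsAsFactors = FALSE)

    bg <- lapply(seq_len(config$n_background_sets), function(k) {
      sample(universe, config$background_set_size)
    })
    names(bg) <- sprintf("bg_%03d", seq_len(config$n_background_sets))

    truth <- structure(list(labels = labels, signature = sig,
                            config = config),
                       class = "synthetic_truth")
    list(rank_matrix = rank_matrix(ranks, meta),
         signature = sig,
         background = gene_set_collection(bg, source = "synthetic"),
         truth = truth)
  })
}

#' Recovery metrics for a screen of a synthetic compendium
#'
#' Measures how well the ranked report recovers the planted truth:
#' `recall@k` = planted mimics found in the top `k` reliability ranks over
#' all planted mimics; `precision@k` = the same count over `k`; direction
#' accuracy = fraction of planted compounds (mimics and anti-mimics) whose
#' reported direction matches their label.
#'
#' @param report Ranked compound table from [summarize_screen()].
#' @param truth A `synthetic_truth`.
#' @param k Depth of the ranking to inspect (`<=` report rows).
#' @return List with `recall_at_k`, `precision_at_k`,
#'   `direction_accuracy`, `k`.
#' @export
truth_recovery_report <- function(report, truth, k) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (k > nrow(report)) {
    stop("k (", k, ") exceeds report size (", nrow(report), ")")
  }
  if (!setequal(report$compound, names(truth$labels))) {
    stop("report and truth cover different compounds; mismatched run?")
  }
  mimics <- names(truth$labels)[truth$labels == "mimic"]
  top_k <- report$compound[seq_len(k)]
  hit <- length(intersect(top_k, mimics))
  planted <- names(truth$labels)[truth$labels != "null"]
  expected_dir <- ifelse(truth$labels[planted] == "mimic", 1, -1)
  got_dir <- report$direction[match(planted, report$compound)]
  list(recall_at_k = if (length(mimics)) hit / length(mimics) else NA_real_,
       precision_at_k = hit / k,
       direction_accuracy = if (length(planted)) {
         mean(got_dir == expected_dir)
       } else NA_real_,
       k = k)
}
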