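#' Run a full connectivity screen in memory
#'
#' Signature -> per-instance connectivity scores -> compound summaries with
#' permutation p, FDR, non-null ratio, specificity and reliability ->
#' ranked report.
#'
#' @param sig A `signed_signature`.
#' @param rmat A `rank_matrix` compendium.
#' @param background A `gene_set_collection` for specificity.
#' @param B Permutation resamples per compound (default 1000).
#' @param seed Integer run seed (mandatory; all child seeds derive from
#'   it).
#' @param weights Reliability weights (see [reliability_score()]).
#' @param n_cap Instance-count saturation cap.
#' @return List with `instances` (per-instance score table), `report`
#'   (ranked compound table) and `meta` (run parameters).
#' @export
run_screen <- function(sig, rmat, background, B = 1000L, seed,
                       weights = rep(1 / 6, 6L), n_cap = 4L) {
  if (missing(seed)) stop("seed is mandatory: screens must be reproducible")
  matched <- match_signature(sig, rmat$universe)
  message(sprintf("screen: query '%s' matched %d up / %d down tags to %d genes",
                  matched$name, length(matched$up_tags),
                  length(matched$down_tags), length(rmat$universe)))
  inst <- score_instances(matched, rmat, match_universe = FALSE)
  message(sprintf("screen: scored %d instances (%d null) for %d compounds",
                  nrow(inst), sum(inst$is_null),
                  length(unique(inst$compound))))
  sig_sizes <- c(length(matched$up_tags), length(matched$down_tags))
  report <- summarize_screen(inst, rmat, background, sig_sizes,
                             B = B, seed = seed, weights = weights,
                             n_cap = n_cap)
  meta <- list(query = matched$name,
               n_genes = nrow(rmat$ranks),
               n_instances = ncol(rmat$ranks),
               n_compounds = length(unique(rmat$meta$compound)),
               t_up = sig_sizes[1L], t_down = sig_sizes[2L],
               B = as.integer(B), seed = as.integer(seed),
               weights = as.numeric(weights), n_cap = as.integer(n_cap))
  list(instances = inst, report = report, meta = meta)
}

#' Screen a compendium from files and write the report
#'
#' File-level entry point behind the `screen` subcommand. Reads the signed
#' query (either a pair of GRP tag lists or a differential-expression table
#' plus thresholds), the rank-matrix compendium with its metadata, and the
#' background GMT; runs [run_screen()]; writes the per-instance score TSV,
#' the ranked compound report TSV, and a run-metadata JSON (including an
#' md5 checksum of the compendium file) into `out_dir`.
#'
#' @param up_grp,down_grp Paths to GRP tag lists (used when both given).
#' @param de_table Path to a DE table (used when GRPs are not given).
#' @param matrix_path,meta_path Compendium rank matrix and metadata paths.
#' @param background_gmt Background gene-set GMT path.
#' @param out_dir Output directory (created if missing).
#' @param query_name Name recorded for the query.
#' @param lfc_threshold,p_threshold,max_tags Signature-construction
#'   thresholds for the DE-table route.
#' @param B,seed,weights,n_cap Screen parameters (see [run_screen()]).
#' @param invert_ranks Passed to [read_rank_matrix()].
#' @return Invisibly, the [run_screen()] result; files are written as a
#'   side effect.
#' @export
cmd_screen <- function(up_grp = NULL, down_grp = NULL, de_table = NULL,
                       matrix_path, meta_path, background_gmt, out_dir,
                       query_name = "query", lfc_threshold = 1.5,
                       p_threshold = 0.05, max_tags = 250L, B = 1000L,
                       seed, weights = rep(1 / 6, 6L), n_cap = 4L,
                       invert_ranks = FALSE) {
  if (missing(seed)) stop("seed is mandatory")
  # fail fast: validate every input before any compute
  if (!is.null(up_grp) && !is.null(down_grp)) {
    sig <- signed_signature(query_name, read_grp(up_grp), read_grp(down_grp),
                            provenance = paste(up_grp, down_grp, sep = " + "))
  } else if (!is.null(de_table)) {
    sig <- build_signature(read_de_table(de_table), lfc_threshold,
                           p_threshold, max_tags, name = query_name)
  } else {
    stop("signature stage: provide either up_grp + down_grp or de_table")
  }
  if (!file.exists(background_gmt)) {
    stop("specificity stage: background GMT not found: ", background_gmt)
  }
  background <- read_gmt(background_gmt)
  rmat <- read_rank_matrix(matrix_path, meta_path,
                           invert_ranks = invert_ranks)
  res <- run_screen(sig, rmat, background, B = B, seed = seed,
                    weights = weights, n_cap = n_cap)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_instance_scores(res$instances,
                        file.path(out_dir, "instance_scores.tsv"))
  write_screen_report(res$report, file.path(out_dir, "screen_report.tsv"))
  res$meta$compendium_md5 <- unname(tools::md5sum(matrix_path))
  res$meta$lfc_threshold <- lfc_threshold
  res$meta$p_threshold <- p_threshold
  jsonlite::write_json(res$meta, file.path(out_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("screen: report written to ", file.path(out_dir, "screen_report.tsv"))
  invisible(res)
}

#' Generate a synthetic compendium on disk
#'
#' File-level entry point behind the `simulate` subcommand: runs
#' [simulate_compendium()] and writes the rank matrix (TSV), instance
#' metadata (CSV), planted signature (two GRP files), background collection
#' (GMT), truth labels (CSV) and the generating config (JSON) into
#' `out_dir`.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the [simulate_compendium()] result.
#' @export
cmd_simulate <- function(config, out_dir) {
  validate_synthetic_config(config)
  sim <- simulate_compendium(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_rank_matrix(sim$rank_matrix, file.path(out_dir, "ranks.tsv"),
                    file.path(out_dir, "instances.csv"))
  write_grp(sim$signature$up_tags, file.path(out_dir, "signature_up.grp"))
  write_grp(sim$signature$down_tags, file.path(out_dir, "signature_down.grp"))
  write_gmt(sim$background, file.path(out_dir, "background.gmt"))
  utils::write.csv(data.frame(compound = names(sim$truth$labels),
                              label = unname(sim$truth$labels),
                              stringsAsFactors = FALSE),
                   file.path(out_dir, "truth.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("simulate: dataset written to ", out_dir)
  invisible(sim)
}

#' Compute recovery metrics from screen and truth files
#'
#' File-level entry point behind the `recover` subcommand: reads a screen
#' report TSV and a truth CSV (columns compound, label) from the same run
#' and writes recall@k, precision@k and direction accuracy as JSON.
#'
#' @param report_path Screen report TSV from [cmd_screen()].
#' @param truth_path Truth CSV from [cmd_simulate()].
#' @param k Ranking depth.
#' @param out_path Output JSON path (optional).
#' @return The [truth_recovery_report()] metrics list.
#' @export
cmd_recover <- function(report_path, truth_path, k, out_path = NULL) {
  report <- utils::read.delim(report_path, stringsAsFactors = FALSE)
  tr <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
  if (!all(c("compound", "label") %in% names(tr))) {
    stop("truth file must have columns compound, label")
  }
  labels <- tr$label
  names(labels) <- tr$compound
  truth <- structure(list(labels = labels, signature = NULL, config = NULL),
                     class = "synthetic_truth")
  metrics <- truth_recovery_report(report, truth, k)
  if (!is.null(out_path)) {
    jsonlite::write_json(metrics, out_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  metrics
}
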