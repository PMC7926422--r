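# Orchestration and reporting: run the simulation -> table building ->
# scoring/ranking -> differential calling -> orthologue comparison chain in
# dependency order, writing tabular outputs plus a reproducibility manifest.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline on synthetic or user-supplied inputs
#'
#' Executes the requested stages in dependency order: `simulate` (generate
#' all inputs with known truth), `build-tables`, `rank` (score the planted
#' protein and decoys at the target site), `diff-edit` and
#' `compare-orthologues`, then `report`. Every output is written under
#' `outdir` together with a `manifest.json` recording the resolved
#' parameters, the package version, the seed and an md5 digest of each
#' output file; re-running with the same configuration reproduces identical
#' digests. Inputs are never mutated.
#'
#' @param config a [generator_config()] (or arguments for one).
#' @param outdir output directory, created if needed.
#' @param stages subset of
#'   `c("simulate", "build-tables", "rank", "diff-edit",
#'   "compare-orthologues", "report")`; stages always run in this order.
#' @param alpha,min_total,delta_min passed to [call_differential_sites()].
#' @return (invisibly) list with the in-memory results of each stage and the
#'   manifest.
#' @export
run_pipeline <- function(config = generator_config(), outdir,
                         stages = c("simulate", "build-tables", "rank",
                                    "diff-edit", "compare-orthologues",
                                    "report"),
                         alpha = 0.05, min_total = 10, delta_min = 0.10) {
  all_stages <- c("simulate", "build-tables", "rank", "diff-edit",
                  "compare-orthologues", "report")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  outputs <- character(0)

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  # generation is needed by every downstream stage, in memory even when the
  # 'simulate' stage (file output) was not requested
  gen <- run_stage("simulate", {
    training <- simulate_training_observations(config)
    planted <- simulate_protein_with_target(config, training)
    counts <- simulate_count_matrices(config)
    panel <- simulate_orthologue_panel(config, planted)
    list(training = training, planted = planted, counts = counts,
         panel = panel)
  })

  if ("simulate" %in% stages) {
    outputs <- c(outputs,
      write_tsv(gen$training$observations,
                file.path(outdir, "training_observations.tsv")),
      write_tsv(write_ppr_annotation(c(list(gen$planted$protein),
                                       gen$planted$decoys)),
                file.path(outdir, "proteins.tsv")),
      write_tsv(data.frame(site_id = gen$planted$site$site_id,
                           position = gen$planted$site$genome_position,
                           strand = gen$planted$site$strand,
                           window = gen$planted$site$window),
                file.path(outdir, "sites.tsv")),
      write_tsv(gen$counts$matrix_a, file.path(outdir, "counts_a.tsv")),
      write_tsv(gen$counts$matrix_b, file.path(outdir, "counts_b.tsv")),
      write_tsv(gen$counts$truth, file.path(outdir, "counts_truth.tsv")))
    res$simulate <- gen
  }

  code <- run_stage("build-tables",
                    build_scoring_tables(gen$training$observations))
  if ("build-tables" %in% stages) {
    tdir <- file.path(outdir, "scoring_tables")
    write_scoring_tables(code, tdir)
    outputs <- c(outputs, list.files(tdir, full.names = TRUE))
    res$code <- code
  }

  if ("rank" %in% stages) {
    ranking <- run_stage("rank",
      rank_candidates(gen$planted$site,
                      c(list(gen$planted$protein), gen$planted$decoys), code))
    outputs <- c(outputs, write_tsv(ranking, file.path(outdir, "ranking.tsv")))
    res$ranking <- ranking
  }

  if ("diff-edit" %in% stages) {
    diff <- run_stage("diff-edit",
      call_differential_sites(gen$counts$matrix_a, gen$counts$matrix_b,
                              alpha = alpha, min_total = min_total,
                              delta_min = delta_min))
    outputs <- c(outputs,
                 write_tsv(as.data.frame(diff),
                           file.path(outdir, "differential_sites.tsv")))
    res$differential <- diff
  }

  if ("compare-orthologues" %in% stages) {
    ortho <- run_stage("compare-orthologues", {
      sc <- score_orthologue_set(gen$panel$records, code)
      list(scores = sc, test = editable_vs_noneditable_test(sc))
    })
    outputs <- c(outputs,
                 write_tsv(ortho$scores, file.path(outdir, "ortho_scores.tsv")),
                 write_tsv(as.data.frame(ortho$test),
                           file.path(outdir, "ortho_test.tsv")))
    res$ortho <- ortho
  }

  if ("report" %in% stages) {
    rep <- run_stage("report",
      render_report(diff = res$differential, ranking = res$ranking,
                    outdir = outdir))
    outputs <- c(outputs, attr(rep, "files"))
    res$report <- rep
  }

  manifest <- list(
    stages = stages,
    parameters = c(unclass(config),
                   list(alpha = alpha, min_total = min_total,
                        delta_min = delta_min)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ppredit")),
    outputs = as.list(tools::md5sum(sort(unique(outputs)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Render summary tables from pipeline results
#'
#' Produces the numeric content of the standard result displays: a per-site
#' table of editing-extent differences with the significant sites
#' highlighted, and a summary of the candidate-ranking score distribution.
#' Plotting is deliberately left to the caller; the tables are
#' side-effect-free unless `outdir` is given.
#'
#' @param diff a `differential_editing` result (or `NULL`).
#' @param ranking a [rank_candidates()] data frame (or `NULL`).
#' @param outdir optional directory to write `report_*.tsv` files into.
#' @return list with `extent_diff` (all tested sites: position, extents,
#'   `delta_extent`, call), `highlights` (significant sites only) and
#'   `score_summary`; written file paths in `attr(, "files")`.
#' @export
render_report <- function(diff = NULL, ranking = NULL, outdir = NULL) {
  out <- list()
  files <- character(0)
  if (!is.null(diff)) {
    ed <- data.frame(position = diff$position,
                     extent_a = diff$extent_a, extent_b = diff$extent_b,
                     delta_extent = diff$extent_b - diff$extent_a,
                     p_adj = diff$p_adj, call = diff$call,
                     stringsAsFactors = FALSE)
    out$extent_diff <- ed
    out$highlights <- ed[diff$significant, , drop = FALSE]
  } else {
    out$extent_diff <- out$highlights <- data.frame()
  }
  if (!is.null(ranking)) {
    out$score_summary <- data.frame(
      n = nrow(ranking), min = min(ranking$total),
      median = stats::median(ranking$total), max = max(ranking$total),
      top_protein = ranking$protein_id[ranking$rank == 1][1])
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (is.data.frame(out[[nm]]) && nrow(out[[nm]]) >= 0)
        files <- c(files, write_tsv(out[[nm]],
                                    file.path(outdir, paste0("report_", nm, ".tsv"))))
    }
  }
  attr(out, "files") <- files
  out
}
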