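# End-to-end orchestration: simulate -> QC -> call -> filter -> downstream.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one validated object. One
#' global `seed` fans out deterministically to per-stage child seeds, so
#' stages are individually reproducible and a run is bit-reproducible.
#'
#' @param seed Global integer seed.
#' @param n_by_type Cells per type (default 15 neurons + 15 non-neurons,
#'   the 30-cell demo scale).
#' @param noise A [noise_spec()].
#' @param thresholds A [qc_thresholds()].
#' @param two_tailed Mixture cutoff tail (default 0.01).
#' @param alpha,min_bins,n_perm Segmentation parameters.
#' @param clone_spec Optional clone specification (see [simulate_cohort()]).
#' @param enrich_n,enrich_width Random-region count and boundary-window
#'   width for enrichment (defaults 3000 and 1 Mb).
#' @param clone_tolerance Clone boundary tolerance (default 1 Mb).
#' @param filter_params Overrides for [filter_calls()].
#' @param cohort_args Extra arguments passed to [simulate_cohort()].
#' @param genome_args Extra arguments passed to [simulate_genome()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_by_type = c(neuron = 15,
                                                    non_neuron = 15),
                            noise = noise_spec(),
                            thresholds = qc_thresholds(),
                            two_tailed = 0.01, alpha = 0.01, min_bins = 2,
                            n_perm = 1000, clone_spec = NULL,
                            enrich_n = 3000, enrich_width = 1e6,
                            clone_tolerance = 1e6, filter_params = list(),
                            cohort_args = list(), genome_args = list()) {
  if (two_tailed <= 0 || two_tailed >= 0.5) {
    abort("`two_tailed` must be in (0, 0.5)")
  }
  structure(
    list(seed = as.integer(seed), n_by_type = n_by_type, noise = noise,
         thresholds = thresholds, two_tailed = two_tailed, alpha = alpha,
         min_bins = min_bins, n_perm = n_perm, clone_spec = clone_spec,
         enrich_n = enrich_n, enrich_width = enrich_width,
         clone_tolerance = clone_tolerance, filter_params = filter_params,
         cohort_args = cohort_args, genome_args = genome_args),
    class = "pipeline_config"
  )
}

#' Run the full pipeline on simulated data
#'
#' Stage order: genome simulation, cohort simulation, per-cell QC +
#' segmentation, batch mixture-model calling and filtering, then downstream
#' analytics (clone detection, composition, inclusion association,
#' boundary-feature enrichment). When `outdir` is given, every stage's
#' tabular output is persisted (TSV) together with a key-value summary and a
#' run manifest; a stage failure halts the run with the failing stage named,
#' retaining outputs already written.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory (created if missing).
#' @return A list of class `pipeline_run`: `sim`, `cohort`, `batch`
#'   (a `cnv_batch`), `clones`, `composition`, `association`, `enrichment`,
#'   `summary` (named list of headline numbers).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  sim <- stage("simulate_genome", do.call(simulate_genome, c(
    list(seed = child_seed(config$seed, "genome")), config$genome_args
  )))
  cohort <- stage("simulate_cohort", do.call(simulate_cohort, c(
    list(sim = sim, n_by_type = config$n_by_type, noise = config$noise,
         clone_spec = config$clone_spec,
         seed = child_seed(config$seed, "cohort")),
    config$cohort_args
  )))
  batch <- stage("call_cells", call_cells(
    cohort, sim, alpha = config$alpha, min_bins = config$min_bins,
    n_perm = config$n_perm, thresholds = config$thresholds,
    two_tailed = config$two_tailed, filter_params = config$filter_params,
    seed = child_seed(config$seed, "calling")
  ))

  kept <- filter(batch$calls, .data$kept,
                 .data$event_class == "sub_chromosomal")
  meta <- cohort[, c("cell_id", "cell_type", "inclusion")]
  clones <- stage("detect_clones",
                  detect_clones(kept, config$clone_tolerance))
  composition <- stage("summarize_composition",
                       summarize_composition(batch$calls, meta))
  assoc_cells <- cohort |>
    filter(.data$cell_id %in% batch$qc$cell_id[batch$qc$pass]) |>
    mutate(
      has_cnv = purrr::map_lgl(.data$cell_id, function(id) {
        any(kept$cell_id == id)
      }),
      has_inclusion = .data$inclusion,
      disease = "simulated"
    )
  association <- if (nrow(assoc_cells) == 0L) {
    tibble(disease = character(), cell_type = character(), a = integer(),
           b = integer(), c = integer(), d = integer())
  } else {
    stage("inclusion_association", inclusion_association(assoc_cells))
  }
  enrichment <- stage("enrichment_summary", enrichment_summary(
    kept, sim$tracks, meta, sim$genome, n_null = config$enrich_n,
    width = config$enrich_width, seed = child_seed(config$seed, "enrich")
  ))

  summary <- list(
    n_cells = nrow(cohort),
    n_pass_qc = sum(batch$qc$pass),
    n_calls_raw = nrow(batch$calls),
    n_calls_kept = sum(batch$calls$kept),
    n_cnvs = nrow(kept),
    n_gains = sum(kept$kind == "gain"),
    n_losses = sum(kept$kind == "loss"),
    n_clone_groups = nrow(clones),
    loss_cutoff = unname(batch$cutoffs[["loss"]]),
    gain_cutoff = unname(batch$cutoffs[["gain"]]),
    seed = config$seed
  )

  run <- structure(
    list(sim = sim, cohort = cohort, batch = batch, clones = clones,
         composition = composition, association = association,
         enrichment = enrichment, summary = summary),
    class = "pipeline_run"
  )
  if (!is.null(outdir)) {
    write_pipeline_run(run, outdir, config)
  }
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<pipeline_run> %d cells, %d pass QC; %d CNVs kept ",
           "(%d gains / %d losses), %d clone group(s)\n"),
    s$n_cells, s$n_pass_qc, s$n_cnvs, s$n_gains, s$n_losses,
    s$n_clone_groups
  ))
  invisible(x)
}

write_pipeline_run <- function(run, outdir, config) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, file) {
    readr::write_tsv(df, file.path(outdir, file), progress = FALSE)
  }
  w(run$batch$qc, "qc.tsv")
  w(run$batch$segments, "segments.tsv")
  write_calls(run$batch$calls, file.path(outdir, "calls.tsv"))
  w(run$clones |> select(-"members", -"cell_ids"), "clones.tsv")
  w(run$composition, "composition.tsv")
  w(run$association |> select(-dplyr::any_of("assoc")), "association.tsv")
  w(run$enrichment$boundaries, "enrichment_boundaries.tsv")
  w(run$enrichment$fractions, "enrichment_fractions.tsv")
  summary_df <- tibble(
    key = names(run$summary),
    value = vapply(run$summary, function(v) format(v, digits = 15), "")
  )
  w(summary_df, "summary.tsv")
  manifest <- c(
    sprintf("mosaicnv %s", as.character(utils::packageVersion("mosaicnv"))),
    sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed %d", config$seed),
    sprintf("config sha %s",
            paste0(format(sum(utf8ToInt(paste(deparse(config),
                                              collapse = ""))), trim = TRUE))),
    deparse(config)
  )
  writeLines(manifest, file.path(outdir, "run_manifest.txt"))
  invisible(outdir)
}
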