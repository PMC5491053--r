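#' Run the full profiling pipeline
#'
#' Composes every stage: preprocessing (filter, orient, standardize, clip,
#' impute), coupled measure/entity co-organization, reference-profile
#' extraction, expert-score consolidation (loaded from files or
#' auto-generated for synthetic runs), kernel propagation of scores, the
#' neural-feature heat-kernel diffusion map, heat-source neighborhoods, and
#' the neighborhood report. Idempotent for a fixed config and seed.
#'
#' @param m A raw [quality_matrix()] (e.g. from [load_matrix()] or
#'   [generate_synthetic()]).
#' @param cfg A [pipeline_config()].
#' @param expert_score_paths Character vector of expert-score JSON files, or
#'   `NULL`.
#' @param auto_scores If `TRUE`, expert scores are simulated with
#'   [auto_expert_scores()] when no files are supplied; with `FALSE` and no
#'   files, the propagation stage aborts.
#' @param output_dir Optional directory; when given, assignment, profile,
#'   embedding, and report files plus a JSON run manifest are written there.
#' @return A `pipeline_result` with elements `matrix` (preprocessed),
#'   `coupled`, `references`, `consolidated_scores`, `propagated`,
#'   `features`, `embedding`, `neighborhoods`, `report`, and `manifest`.
#' @export
run_pipeline <- function(m, cfg = pipeline_config(),
                         expert_score_paths = NULL, auto_scores = TRUE,
                         output_dir = NULL) {
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  pre <- stage("preprocess", preprocess(m, cfg))
  coupled <- stage("coupled_geometry", run_coupled_iterations(pre, cfg))
  refs <- stage("reference_profiles",
                extract_reference_profiles(coupled$entity_tree, pre, cfg))

  scores_raw <- stage("expert_scores", {
    if (!is.null(expert_score_paths)) {
      read_expert_scores(expert_score_paths)
    } else if (auto_scores) {
      auto_expert_scores(refs, pre$meta, seed = cfg$rng_seed)
    } else {
      stop("no expert-score files supplied and auto_scores = FALSE")
    }
  })
  consolidated <- stage("consolidate",
                        consolidate_scores(scores_raw,
                                           leaf_ids = refs$profiles$leaf_id))
  refs <- score_reference_profiles(refs, consolidated)
  propagated <- stage("propagate",
                      propagate_scores(refs, coupled$entity_geometry, pre))
  features <- stage("train_ensemble", train_ensemble(pre, propagated, cfg))
  embedding <- stage("diffusion_map", diffusion_map(
    connect_kernel(feature_heat_kernel(features, cfg)), cfg))
  sources <- stage("place_sources",
                   place_sources(embedding, cfg$n_neighborhoods,
                                 seed = cfg$rng_seed))
  nb <- stage("neighborhoods",
              assign_neighborhoods(embedding, sources, m = pre, cfg = cfg))
  report <- stage("report", report_neighborhoods(nb, pre$meta,
                                                 margin = cfg$domain_margin))

  manifest <- list(
    config = unclass(cfg),
    seed = cfg$rng_seed,
    n_entities_in = nrow(m$values), n_measures_in = ncol(m$values),
    n_entities = nrow(pre$values), n_measures = ncol(pre$values),
    n_reference_profiles = nrow(refs$profiles),
    n_neighborhoods = nrow(nb$sizes),
    stage_seconds = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    outputs = character()
  )

  res <- structure(
    list(matrix = pre, coupled = coupled, references = refs,
         consolidated_scores = consolidated, propagated = propagated,
         features = features, embedding = embedding, neighborhoods = nb,
         report = report, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) res <- write_pipeline_outputs(res, output_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    assignment = file.path(dir, "assignment.csv"),
    profiles = file.path(dir, "neighborhood_profiles.csv"),
    embedding = file.path(dir, "embedding.csv"),
    scores = file.path(dir, "propagated_scores.csv"),
    report_csv = file.path(dir, "neighborhood_report.csv"),
    report_md = file.path(dir, "neighborhood_report.md"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_csv(tidy(res$neighborhoods), paths[["assignment"]])
  readr::write_csv(tibble::as_tibble(res$neighborhoods$profiles,
                                     rownames = "label"),
                   paths[["profiles"]])
  write_embedding_csv(res$embedding, paths[["embedding"]])
  readr::write_csv(res$propagated, paths[["scores"]])
  readr::write_csv(res$report, paths[["report_csv"]])
  writeLines(format_report_markdown(res$report), paths[["report_md"]])
  res$manifest$outputs <- unname(paths)
  jsonlite::write_json(res$manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d entities x %d measures after preprocessing\n",
              nrow(x$matrix$values), ncol(x$matrix$values)))
  cat(sprintf("  %d reference profiles, %d neighborhoods\n",
              nrow(x$references$profiles), nrow(x$neighborhoods$sizes)))
  cat(sprintf("  total %.1f s\n", x$manifest$total_seconds))
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n_entities = nrow(x$matrix$values),
                   n_measures = ncol(x$matrix$values),
                   n_reference_profiles = nrow(x$references$profiles)),
    glance(x$neighborhoods)[, c("n_neighborhoods", "cover_radius",
                                "median_size")]
  )
}

#' Per-neighborhood domain classification report
#'
#' One row per neighborhood and domain: the good/poor/mixed/average
#' classification of the central profile, with counts of measures flagged
#' beyond +/-1 SD.
#'
#' @param nb A `neighborhood_assignment` with profiles.
#' @param meta Measure metadata tibble.
#' @param margin Near-average band half-width in SD units.
#' @return A tibble `label`, `n`, `domain`, `classification`, `n_measures`,
#'   `n_particularly_good`, `n_particularly_poor`.
#' @export
report_neighborhoods <- function(nb, meta, margin = 0.1) {
  if (is.null(nb$profiles)) {
    stop("assignment has no profiles; rerun assign_neighborhoods with the ",
         "quality matrix", call. = FALSE)
  }
  purrr::map_dfr(rownames(nb$profiles), function(lab) {
    cls <- classify_domain_performance(nb$profiles[lab, ], meta,
                                       margin = margin)
    flags <- attr(cls, "flags")
    flag_counts <- flags |>
      dplyr::count(.data$domain, .data$flag) |>
      tidyr::pivot_wider(names_from = "flag", values_from = "n",
                         values_fill = 0L)
    out <- dplyr::left_join(cls, flag_counts, by = "domain")
    for (col in c("particularly_good", "particularly_poor")) {
      if (!col %in% names(out)) out[[col]] <- 0L
      out[[col]][is.na(out[[col]])] <- 0L
    }
    tibble::tibble(label = lab,
                   n = nb$sizes$n[match(lab, nb$sizes$label)]) |>
      dplyr::bind_cols(out) |>
      dplyr::rename(n_particularly_good = "particularly_good",
                    n_particularly_poor = "particularly_poor")
  })
}

format_report_markdown <- function(report) {
  wide <- report |>
    dplyr::mutate(cell = .data$classification) |>
    dplyr::select("label", "n", "domain", "cell") |>
    tidyr::pivot_wider(names_from = "domain", values_from = "cell")
  header <- paste0("| ", paste(names(wide), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(wide)), collapse = "|"), "|")
  rows <- apply(wide, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
  c("# Neighborhood performance report", "", header, sep, rows)
}
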