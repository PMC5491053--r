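# Internal: tree-EMD distance for a plain points-x-items matrix, where the
# tree partitions the items. Shared by the entity pass (items = measures) and
# the transposed measure pass (items = entities).
tree_emd_distances_mat <- function(values, item_ids, tree, alpha) {
  nodes <- tree_nodes(tree)
  all_members <- sort(unique(unlist(lapply(nodes, `[[`, "members"))))
  if (!setequal(all_members, item_ids)) {
    stop("partition tree members do not match the item ids", call. = FALSE)
  }
  n_items <- length(item_ids)
  scaled <- vapply(nodes, function(node) {
    cols <- match(node$members, item_ids)
    w <- 2^(-alpha * node$level) * length(cols) / n_items
    rowMeans(values[, cols, drop = FALSE]) * w
  }, numeric(nrow(values)))
  as.matrix(stats::dist(scaled, method = "manhattan"))
}

#' Coupled co-organization of measures and entities
#'
#' Alternating organization of the matrix's two axes. The first round builds a
#' diffusion metric on the measures from cosine affinity, cuts a binary
#' partition tree on its low-frequency eigenvectors, and uses that tree to
#' define a tree-approximate earth mover's distance between entities, from
#' which the entity diffusion geometry and entity tree follow. Later rounds
#' rebuild the measure metric with the tree-EMD over the current entity tree
#' (on the transposed matrix), so each axis's metric is informed by the
#' other's organization. Iteration stops after `cfg$n_coupled_iterations`
#' rounds or as soon as consecutive entity leaf partitions agree at adjusted
#' Rand index >= 0.99.
#'
#' @param m A preprocessed (imputed) [quality_matrix()].
#' @param cfg A [pipeline_config()].
#' @return A `coupled_geometry` object: `entity_geometry`, `measure_geometry`
#'   (diffusion geometries), `entity_tree` (depth
#'   `log2(n_reference_profiles)`), `measure_tree`, and an `iterations` tibble
#'   logging the adjusted Rand index between consecutive entity partitions.
#' @export
run_coupled_iterations <- function(m, cfg = pipeline_config()) {
  if (!m$imputed) stop("run_coupled_iterations expects an imputed matrix",
                       call. = FALSE)
  entity_depth <- as.integer(log2(cfg$n_reference_profiles))
  measure_depth <- max(1L, min(floor(log2(length(m$measure_ids))), 6L))
  seed <- cfg$rng_seed

  measure_kernel <- cosine_affinity(m, "measures")
  prev_leaf_labels <- NULL
  log <- list()
  measure_geom <- entity_geom <- measure_tree <- entity_tree <- NULL

  for (iter in seq_len(cfg$n_coupled_iterations)) {
    if (iter > 1) {
      dm <- tree_emd_distances_mat(t(m$values), m$entity_ids, entity_tree,
                                   cfg$emd_level_decay)
      measure_kernel <- heat_kernel(dm, m$measure_ids, cfg)
    }
    measure_geom <- diffusion_embed(connect_kernel(measure_kernel), cfg)
    measure_tree <- build_partition_tree(measure_geom, measure_depth,
                                         seed = seed + iter, strict = FALSE)
    entity_kernel <- tree_emd_affinity(m, measure_tree, cfg)
    entity_geom <- diffusion_embed(connect_kernel(entity_kernel), cfg)
    entity_tree <- build_partition_tree(entity_geom, entity_depth,
                                        seed = seed + 100L + iter,
                                        strict = TRUE)
    leaf_labels <- tidy(entity_tree)$leaf_id[order(tidy(entity_tree)$id)]
    ari <- if (is.null(prev_leaf_labels)) NA_real_ else
      adjusted_rand_index(prev_leaf_labels, leaf_labels)
    log[[iter]] <- tibble::tibble(iteration = iter, entity_ari = ari)
    prev_leaf_labels <- leaf_labels
    if (!is.na(ari) && ari >= 0.99) break
  }

  structure(
    list(entity_geometry = entity_geom, measure_geometry = measure_geom,
         entity_tree = entity_tree, measure_tree = measure_tree,
         iterations = dplyr::bind_rows(log)),
    class = "coupled_geometry"
  )
}

#' @export
print.coupled_geometry <- function(x, ...) {
  cat(sprintf(
    "<coupled_geometry> %d entities, %d measures, %d iteration(s)\n",
    length(x$entity_geometry$ids), length(x$measure_geometry$ids),
    nrow(x$iterations)))
  if (nrow(x$iterations) > 1) {
    cat("  entity-partition ARI by round:",
        paste(signif(x$iterations$entity_ari[-1], 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.coupled_geometry <- function(x, ...) {
  tibble::tibble(
    n_entities = length(x$entity_geometry$ids),
    n_measures = length(x$measure_geometry$ids),
    n_iterations = nrow(x$iterations),
    n_entity_leaves = length(tree_leaves(x$entity_tree)),
    final_entity_ari = dplyr::last(x$iterations$entity_ari)
  )
}
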