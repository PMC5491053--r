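#' Tree-approximate earth mover's distances between entity profiles
#'
#' A multiscale surrogate for the earth mover's distance: for every node of a
#' partition tree over the measures, the two profiles' means on the node's
#' measures are compared, and the absolute differences are combined with
#' weights `2^(-alpha * level) * (|node| / n_measures)`. Coarse (low-level)
#' nodes carry more weight, so profiles that agree on broad measure groups but
#' differ measure-by-measure are closer than profiles that differ wholesale.
#'
#' @param m An imputed [quality_matrix()].
#' @param tree A `partition_tree` whose members are exactly `m`'s measure ids.
#' @param cfg A [pipeline_config()]; `emd_level_decay` is alpha.
#' @return Symmetric entity-by-entity distance matrix.
#' @export
tree_emd_distances <- function(m, tree, cfg = pipeline_config()) {
  nodes <- tree_nodes(tree)
  all_members <- sort(unique(unlist(lapply(nodes, `[[`, "members"))))
  if (!setequal(all_members, m$measure_ids)) {
    stop("partition tree members do not match the matrix's measure ids",
         call. = FALSE)
  }
  n_measures <- length(m$measure_ids)
  # entities x nodes matrix of node means, columns scaled by node weight
  scaled <- vapply(nodes, function(node) {
    cols <- match(node$members, m$measure_ids)
    w <- 2^(-cfg$emd_level_decay * node$level) * length(cols) / n_measures
    rowMeans(m$values[, cols, drop = FALSE]) * w
  }, numeric(nrow(m$values)))
  dm <- as.matrix(stats::dist(scaled, method = "manhattan"))
  dimnames(dm) <- list(m$entity_ids, m$entity_ids)
  dm
}

#' Tree-EMD affinity kernel over entities
#'
#' [tree_emd_distances()] passed through the heat kernel
#' `exp(-d^2 / eps)`, with the bandwidth set by `cfg$kernel_bandwidth_rule`.
#'
#' @inheritParams tree_emd_distances
#' @return An [affinity_kernel()] over entities.
#' @export
tree_emd_affinity <- function(m, tree, cfg = pipeline_config()) {
  dm <- tree_emd_distances(m, tree, cfg)
  heat_kernel(dm, m$entity_ids, cfg)
}
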