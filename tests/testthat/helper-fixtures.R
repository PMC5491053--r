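# Fixture builders shared across test files. Everything is generated in code;
# no data files.

make_meta <- function(measure_ids, domain = "process",
                      direction = "higher_better") {
  tibble::tibble(measure_id = measure_ids,
                 domain = rep_len(domain, length(measure_ids)),
                 direction = rep_len(direction, length(measure_ids)))
}

make_qm <- function(values, domain = "process", direction = "higher_better",
                    ...) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("e%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("m%02d", seq_len(ncol(values)))
  }
  quality_matrix(values, make_meta(colnames(values), domain, direction), ...)
}

# A quality_matrix already marked as fully preprocessed.
make_processed_qm <- function(values, ...) {
  make_qm(values, ..., standardized = TRUE, clipped = TRUE, imputed = TRUE)
}

# Fully processed matrix with explicit measure ids.
make_named_qm <- function(values, entity_ids, measure_ids) {
  dimnames(values) <- list(entity_ids, measure_ids)
  quality_matrix(values, make_meta(measure_ids),
                 standardized = TRUE, clipped = TRUE, imputed = TRUE)
}

# Minimal embedding_result around given coordinates.
make_embedding <- function(coords, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("e%02d", seq_len(nrow(coords)))
  rownames(coords) <- ids
  colnames(coords) <- paste0("dc", seq_len(ncol(coords)))
  structure(list(entity_ids = ids, coordinates = coords,
                 eigenvalues = rep(0.9, ncol(coords))),
            class = "embedding_result")
}

# Hand-built partition tree node / tree (for tree-EMD closed-form checks).
mk_node <- function(id, level, members, children = NULL) {
  list(id = id, level = level, members = members, children = children)
}
mk_tree <- function(root, depth) {
  collect <- function(node) {
    if (is.null(node$children)) node$members else
      unlist(lapply(node$children, collect))
  }
  structure(list(root = root, depth = depth, ids = sort(collect(root))),
            class = "partition_tree")
}

# Balanced depth-2 tree over 6 measures: {m1}{m2,m3} | {m4}{m5,m6}.
six_measure_tree <- function() {
  mk_tree(mk_node("r", 0, paste0("m", 1:6), list(
    mk_node("r0", 1, c("m1", "m2", "m3"), list(
      mk_node("r00", 2, "m1"), mk_node("r01", 2, c("m2", "m3")))),
    mk_node("r1", 1, c("m4", "m5", "m6"), list(
      mk_node("r10", 2, "m4"), mk_node("r11", 2, c("m5", "m6")))))), 2)
}

# Hierarchically structured 4-block bicluster: measure blocks A~B, C~D.
bicluster_qm <- function(n_e = 80, n_m = 24, noise_sd = 0.5, seed = 3) {
  withr::with_seed(seed, {
    ec <- rep(1:4, each = n_e / 4)
    mc <- rep(1:4, each = n_m / 4)
    B <- matrix(c(2, 1, -1, -2,
                  1, 2, -2, -1,
                  -1, -2, 2, 1,
                  -2, -1, 1, 2), 4, 4, byrow = TRUE)
    vals <- B[ec, mc] + matrix(stats::rnorm(n_e * n_m, 0, noise_sd), n_e, n_m)
    dimnames(vals) <- list(sprintf("e%02d", seq_len(n_e)),
                           sprintf("m%02d", seq_len(n_m)))
    qm <- make_qm(vals, domain = paste0("d", mc))
    list(qm = qm, entity_block = ec, measure_block = mc)
  })
}

# Cached heavy runs so several test files can share one computation.
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

default_synthetic_run <- function() {
  cached("default_run", {
    syn <- generate_synthetic(synthetic_spec(seed = 1))
    res <- run_pipeline(syn$matrix, pipeline_config(rng_seed = 1))
    list(syn = syn, res = res)
  })
}

spearman <- function(x, y) stats::cor(x, y, method = "spearman")
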