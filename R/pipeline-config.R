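#' Pipeline configuration
#'
#' Collects every tunable of the profiling pipeline in one validated object.
#' Defaults mirror the pre-specified analysis constants: 90% row/column
#' completeness filters, winsorization at 4 standard deviations, 32 reference
#' profiles (a depth-5 dyadic partition tree), 16 neighborhoods, profile
#' averaging over a center and its 10 nearest neighbors, and a 3-D embedding.
#'
#' @param row_completeness_min Minimum fraction of measures an entity must
#'   report to be retained (default 0.90).
#' @param col_completeness_min Minimum fraction of surviving entities a measure
#'   must be reported by (default 0.90).
#' @param clip_sd Winsorization bound on the standardized scale, in SD units
#'   (default 4).
#' @param n_reference_profiles Number of partition-tree leaf profiles; must be
#'   a power of two (default 32).
#' @param n_neighborhoods Number of heat sources / neighborhoods (default 16).
#' @param n_profile_neighbors Neighbors averaged with each source when
#'   characterizing a neighborhood profile (default 10).
#' @param embed_dims Dimension of the diffusion-map embedding (default 3).
#' @param n_coupled_iterations Rounds of measure/entity co-organization
#'   (default 3).
#' @param n_eigenvectors Non-trivial eigenpairs retained in each diffusion
#'   geometry (default 8).
#' @param diffusion_time Diffusion time t used in diffusion distances and
#'   embedding coordinates (default 1).
#' @param emd_level_decay Per-level decay exponent alpha in the tree
#'   earth-mover's weights 2^(-alpha * level) (default 0.5).
#' @param ensemble_size Number of networks in the feature ensemble (default 10).
#' @param hidden_widths Integer vector of hidden-layer widths (default
#'   c(32, 16)).
#' @param kernel_bandwidth_rule Either "median_sq_dist" (self-tuning: epsilon =
#'   median squared pairwise distance) or "fixed".
#' @param kernel_bandwidth Bandwidth used when `kernel_bandwidth_rule` is
#'   "fixed".
#' @param standardize_method "zscore" (default) or "normal_scores" for a
#'   rank-based inverse-normal transform.
#' @param domain_margin Margin, in SD units, around 0 used when classifying
#'   domain performance as good/poor/average (default 0.1).
#' @param rng_seed Integer seed from which all randomness derives (default 1).
#'
#' @return A `pipeline_config` object (a named list).
#' @export
#' @examples
#' cfg <- pipeline_config(rng_seed = 7)
#' cfg$n_reference_profiles
pipeline_config <- function(row_completeness_min = 0.90,
                            col_completeness_min = 0.90,
                            clip_sd = 4,
                            n_reference_profiles = 32L,
                            n_neighborhoods = 16L,
                            n_profile_neighbors = 10L,
                            embed_dims = 3L,
                            n_coupled_iterations = 3L,
                            n_eigenvectors = 8L,
                            diffusion_time = 1,
                            emd_level_decay = 0.5,
                            ensemble_size = 10L,
                            hidden_widths = c(32L, 16L),
                            kernel_bandwidth_rule = c("median_sq_dist", "fixed"),
                            kernel_bandwidth = 1,
                            standardize_method = c("zscore", "normal_scores"),
                            domain_margin = 0.1,
                            rng_seed = 1L) {
  kernel_bandwidth_rule <- match.arg(kernel_bandwidth_rule)
  standardize_method <- match.arg(standardize_method)
  stopifnot(
    row_completeness_min > 0, row_completeness_min <= 1,
    col_completeness_min > 0, col_completeness_min <= 1,
    clip_sd > 0,
    n_neighborhoods >= 1, n_profile_neighbors >= 1,
    embed_dims >= 1, n_coupled_iterations >= 1, n_eigenvectors >= 1,
    diffusion_time > 0, ensemble_size >= 1, all(hidden_widths >= 1),
    kernel_bandwidth > 0
  )
  d <- log2(n_reference_profiles)
  if (n_reference_profiles < 2 || abs(d - round(d)) > 1e-12) {
    stop("`n_reference_profiles` must be a power of two >= 2, got ",
         n_reference_profiles, call. = FALSE)
  }
  structure(
    list(
      row_completeness_min = row_completeness_min,
      col_completeness_min = col_completeness_min,
      clip_sd = clip_sd,
      n_reference_profiles = as.integer(n_reference_profiles),
      n_neighborhoods = as.integer(n_neighborhoods),
      n_profile_neighbors = as.integer(n_profile_neighbors),
      embed_dims = as.integer(embed_dims),
      n_coupled_iterations = as.integer(n_coupled_iterations),
      n_eigenvectors = as.integer(n_eigenvectors),
      diffusion_time = diffusion_time,
      emd_level_decay = emd_level_decay,
      ensemble_size = as.integer(ensemble_size),
      hidden_widths = as.integer(hidden_widths),
      kernel_bandwidth_rule = kernel_bandwidth_rule,
      kernel_bandwidth = kernel_bandwidth,
      standardize_method = standardize_method,
      domain_margin = domain_margin,
      rng_seed = as.integer(rng_seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file holds any subset of [pipeline_config()]'s arguments by name;
#' unset fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
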