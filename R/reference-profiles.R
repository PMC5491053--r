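#' Extract reference profiles from an entity partition tree
#'
#' One profile per leaf of the entity tree: the arithmetic mean of the leaf
#' members' standardized performance profiles. These centroids are the
#' reference points that experts score on the 1-10 scale.
#'
#' @param tree A depth `log2(n_reference_profiles)` `partition_tree` over
#'   entities.
#' @param m The preprocessed [quality_matrix()].
#' @param cfg A [pipeline_config()].
#' @return A `reference_profile_set`: a tibble with columns `leaf_id`,
#'   `members` (list of entity ids), `n`, `centroid` (list of named numeric
#'   vectors over measures), and `expert_score` (NA until scored).
#' @export
extract_reference_profiles <- function(tree, m, cfg = pipeline_config()) {
  lv <- tree_leaves(tree)
  if (length(lv) < cfg$n_reference_profiles) {
    stop("partition tree has ", length(lv), " leaves; ",
         cfg$n_reference_profiles, " reference profiles configured",
         call. = FALSE)
  }
  profiles <- purrr::imap_dfr(lv, function(members, leaf_id) {
    rows <- match(members, m$entity_ids)
    centroid <- colMeans(m$values[rows, , drop = FALSE])
    tibble::tibble(leaf_id = leaf_id, members = list(members),
                   n = length(members), centroid = list(centroid),
                   expert_score = NA_real_)
  })
  structure(list(profiles = profiles, measure_ids = m$measure_ids),
            class = "reference_profile_set")
}

#' @export
print.reference_profile_set <- function(x, ...) {
  cat(sprintf("<reference_profile_set> %d profiles over %d measures\n",
              nrow(x$profiles), length(x$measure_ids)))
  if (!all(is.na(x$profiles$expert_score))) {
    cat("  expert scores:",
        paste(x$profiles$expert_score, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.reference_profile_set <- function(x, ...) {
  x$profiles |>
    dplyr::mutate(centroid_df = purrr::map(.data$centroid, function(v) {
      tibble::tibble(measure_id = names(v), value = unname(v))
    })) |>
    dplyr::select("leaf_id", "n", "expert_score", "centroid_df") |>
    tidyr::unnest("centroid_df")
}

#' Read expert score files
#'
#' Each JSON file maps rater id to a `leaf_id -> score` map, scores on the
#' 1-10 scale (10 = top performance).
#'
#' @param paths Character vector of JSON file paths.
#' @return A tibble with columns `rater`, `leaf_id`, `score`.
#' @export
read_expert_scores <- function(paths) {
  purrr::map_dfr(paths, function(p) {
    raw <- jsonlite::read_json(p)
    purrr::imap_dfr(raw, function(scores, rater) {
      tibble::tibble(rater = rater, leaf_id = names(scores),
                     score = as.numeric(unlist(scores)))
    })
  })
}

#' Consolidate expert scores across raters
#'
#' Per-leaf median across raters, replacing the iterative expert
#' re-reconciliation with a deterministic consolidation. Leaves where the
#' rater range exceeds 2 points are flagged in the attached discrepancy
#' report so a human reviewer can revisit them.
#'
#' @param scores A tibble with columns `rater`, `leaf_id`, `score` (e.g. from
#'   [read_expert_scores()]), or a list of such tibbles.
#' @param leaf_ids Optional character vector of leaf ids that must all be
#'   scored.
#' @return A tibble `leaf_id`, `score`, `n_raters`, `range`, `flagged`, with
#'   the flagged subset also in `attr(, "discrepancies")`.
#' @export
consolidate_scores <- function(scores, leaf_ids = NULL) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- dplyr::bind_rows(scores)
  }
  stopifnot(all(c("rater", "leaf_id", "score") %in% names(scores)))
  bad <- scores$score < 1 | scores$score > 10 | !is.finite(scores$score)
  if (any(bad)) {
    stop("score outside [1, 10] for leaf ",
         paste(unique(scores$leaf_id[bad]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(leaf_ids)) {
    unscored <- setdiff(leaf_ids, scores$leaf_id)
    if (length(unscored) > 0) {
      stop("unscored leaf/leaves: ", paste(unscored, collapse = ", "),
           call. = FALSE)
    }
  }
  out <- scores |>
    dplyr::group_by(.data$leaf_id) |>
    dplyr::summarise(n_raters = dplyr::n(),
                     range = max(.data$score) - min(.data$score),
                     score = stats::median(.data$score),
                     .groups = "drop")
  out$flagged <- out$range > 2
  attr(out, "discrepancies") <- out[out$flagged, , drop = FALSE]
  out
}

#' Attach consolidated expert scores to a reference profile set
#'
#' @param refs A `reference_profile_set`.
#' @param consolidated A tibble `leaf_id`, `score` (from
#'   [consolidate_scores()]).
#' @return The scored `reference_profile_set`.
#' @export
score_reference_profiles <- function(refs, consolidated) {
  idx <- match(refs$profiles$leaf_id, consolidated$leaf_id)
  if (anyNA(idx)) {
    stop("unscored leaf/leaves: ",
         paste(refs$profiles$leaf_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  refs$profiles$expert_score <- consolidated$score[idx]
  refs
}

#' Propagate expert scores to every entity
#'
#' Nadaraya-Watson kernel regression on diffusion distance: each leaf is
#' embodied by its representative (the member nearest the centroid in
#' Euclidean profile distance), and an entity's rough quality score is the
#' kernel-weighted average of the leaf scores,
#' `w_j = exp(-d(entity, rep_j)^2 / bandwidth)`. Scores are convex
#' combinations of the expert scores, hence bounded by their range.
#'
#' @param refs A scored `reference_profile_set`.
#' @param g The entity `diffusion_geometry`.
#' @param m The preprocessed [quality_matrix()] (for locating
#'   representatives).
#' @param bandwidth Positive kernel bandwidth on squared diffusion distance;
#'   default is the median over entities of the squared diffusion distance to
#'   the nearest representative, which keeps the smoothing local (the median
#'   over all entity-representative pairs is dominated by distant pairs and
#'   shrinks every score toward the grand mean).
#' @return A tibble `entity_id`, `score`.
#' @export
propagate_scores <- function(refs, g, m, bandwidth = NULL) {
  if (anyNA(refs$profiles$expert_score)) {
    stop("all reference profiles must be scored before propagation",
         call. = FALSE)
  }
  reps <- purrr::map_chr(seq_len(nrow(refs$profiles)), function(i) {
    members <- refs$profiles$members[[i]]
    centroid <- refs$profiles$centroid[[i]]
    rows <- match(members, m$entity_ids)
    d2 <- rowSums((m$values[rows, , drop = FALSE] -
                     matrix(centroid, length(rows), length(centroid),
                            byrow = TRUE))^2)
    members[which.min(d2)]
  })
  coords <- diffusion_coords(g)
  rep_rows <- match(reps, g$ids)
  # entities x representatives squared diffusion distances
  d2 <- outer(rowSums(coords^2), rowSums(coords[rep_rows, , drop = FALSE]^2),
              `+`) - 2 * tcrossprod(coords, coords[rep_rows, , drop = FALSE])
  d2 <- pmax(d2, 0)
  if (is.null(bandwidth)) {
    nearest <- apply(d2, 1, function(r) min(r[r > 0]))
    bandwidth <- stats::median(nearest)
  }
  stopifnot(bandwidth > 0)
  w <- exp(-d2 / bandwidth)
  tot <- rowSums(w)
  if (any(tot == 0)) {
    stop("kernel weights underflow to 0 for entity ",
         paste(g$ids[tot == 0], collapse = ", "),
         "; increase the bandwidth", call. = FALSE)
  }
  score <- as.vector(w %*% refs$profiles$expert_score) / tot
  tibble::tibble(entity_id = g$ids, score = score)
}
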