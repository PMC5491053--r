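#' Place heat sources on the embedding
#'
#' Finds the configuration of `k` sources whose simultaneous diffusion covers
#' the map fastest. Since heat cover time on a point cloud is monotone in the
#' distance to the nearest source, the objective is the k-center (minimax
#' cover) criterion on Euclidean embedding distances: minimize the maximum,
#' over entities, of the distance to the nearest source. Greedy farthest-point
#' seeding followed by single-swap local search until no swap improves the
#' objective; instances small enough to enumerate (`choose(n, k) <= 5000`)
#' are solved exactly. Deterministic given `seed`.
#'
#' @param e An `embedding_result`.
#' @param k Number of sources.
#' @param seed Integer seed (chooses the farthest-point start).
#' @param exact_limit Largest `choose(n, k)` for which exhaustive enumeration
#'   is used instead of the heuristic (set 0 to force the heuristic).
#' @return Character vector of `k` source entity ids, with the achieved cover
#'   radius in `attr(, "objective")`.
#' @export
place_sources <- function(e, k, seed = 1L, exact_limit = 5000) {
  n <- nrow(e$coordinates)
  if (k > n) stop("k = ", k, " exceeds the number of entities (", n, ")",
                  call. = FALSE)
  ids <- e$entity_ids
  if (k == n) {
    out <- ids
    attr(out, "objective") <- 0
    return(out)
  }
  dmat <- as.matrix(stats::dist(e$coordinates))

  # tiny instances: exact enumeration of all source sets
  if (choose(n, k) <= exact_limit) {
    combos <- utils::combn(n, k)
    objs <- apply(combos, 2, function(src) {
      max(apply(dmat[, src, drop = FALSE], 1, min))
    })
    best <- combos[, which.min(objs)]
    out <- ids[best]
    attr(out, "objective") <- min(objs)
    return(out)
  }

  objective <- function(src) max(apply(dmat[, src, drop = FALSE], 1, min))

  # one greedy farthest-point seeding + single-swap local search
  solve_from <- function(start) {
    sources <- start
    nearest <- dmat[, start]
    while (length(sources) < k) {
      cand <- which.max(nearest)  # ties: lowest index
      sources <- c(sources, cand)
      nearest <- pmin(nearest, dmat[, cand])
    }
    obj <- objective(sources)
    for (pass in seq_len(100)) {
      improved <- FALSE
      dsrc <- dmat[, sources, drop = FALSE]
      ord <- t(apply(dsrc, 1, order))
      near1 <- dsrc[cbind(seq_len(n), ord[, 1])]
      near2 <- if (k >= 2) dsrc[cbind(seq_len(n), ord[, 2])] else
        rep(Inf, n)
      nearest_src <- ord[, 1]
      for (si in seq_len(k)) {
        base <- ifelse(nearest_src == si, near2, near1)
        cand_obj <- apply(pmin(matrix(base, n, n), dmat), 2, max)
        cand_obj[sources] <- Inf
        best_v <- which.min(cand_obj)
        if (cand_obj[best_v] < obj - 1e-12) {
          sources[si] <- best_v
          obj <- cand_obj[best_v]
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    list(sources = sources, obj = obj)
  }

  starts <- if (n <= 50) seq_len(n) else with_seed(seed, sample.int(n, 5L))
  best <- NULL
  for (st in starts) {
    sol <- solve_from(st)
    if (is.null(best) || sol$obj < best$obj - 1e-12) best <- sol
  }

  out <- ids[best$sources]
  attr(out, "objective") <- best$obj
  out
}

#' Assign entities to heat-source neighborhoods
#'
#' Each entity joins the nearest source's neighborhood (Euclidean embedding
#' distance; ties go to the earliest source in the given order). Letters A,
#' B, ... are assigned in descending neighborhood size, ties broken by source
#' id, giving A..P under the 16-source default.
#'
#' @param e An `embedding_result`.
#' @param sources Character vector of distinct source entity ids.
#' @param m Optional preprocessed [quality_matrix()]; when supplied,
#'   neighborhood profiles (source + `n_profile_neighbors` nearest entities)
#'   are attached.
#' @param cfg A [pipeline_config()].
#' @return A `neighborhood_assignment`: `assignment` tibble (`entity_id`,
#'   `label`, `source_id`, `is_source`, `distance_to_source`), `sources`,
#'   `objective`, `sizes`, and (with `m`) `profiles` (label x measure
#'   matrix).
#' @export
assign_neighborhoods <- function(e, sources, m = NULL,
                                 cfg = pipeline_config()) {
  if (anyDuplicated(sources)) stop("duplicate sources", call. = FALSE)
  src_rows <- match(sources, e$entity_ids)
  if (anyNA(src_rows)) stop("unknown source id(s): ",
                            paste(sources[is.na(src_rows)], collapse = ", "),
                            call. = FALSE)
  dmat <- as.matrix(stats::dist(e$coordinates))
  dsrc <- dmat[, src_rows, drop = FALSE]
  nearest <- apply(dsrc, 1, which.min)  # ties: earliest source
  dist_to <- dsrc[cbind(seq_len(nrow(dsrc)), nearest)]

  sizes <- tabulate(nearest, length(sources))
  lab_order <- order(-sizes, sources)
  label_of_source <- character(length(sources))
  label_of_source[lab_order] <- make_labels(length(sources))

  assignment <- tibble::tibble(
    entity_id = e$entity_ids,
    label = label_of_source[nearest],
    source_id = sources[nearest],
    is_source = e$entity_ids %in% sources,
    distance_to_source = dist_to
  )
  sizes_tbl <- assignment |>
    dplyr::count(.data$label, name = "n") |>
    dplyr::arrange(.data$label)

  profiles <- NULL
  if (!is.null(m)) {
    prof <- purrr::map(seq_along(sources), function(si) {
      neighborhood_profile(m, e, sources[si], cfg$n_profile_neighbors)
    })
    profiles <- do.call(rbind, prof)
    rownames(profiles) <- label_of_source
    profiles <- profiles[order(rownames(profiles)), , drop = FALSE]
  }

  structure(
    list(assignment = assignment, sources = sources,
         source_labels = stats::setNames(label_of_source, sources),
         objective = max(dist_to), sizes = sizes_tbl, profiles = profiles),
    class = "neighborhood_assignment"
  )
}

make_labels <- function(k) {
  if (k <= 26) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS, paste0)))[seq_len(k)]
}

#' @export
print.neighborhood_assignment <- function(x, ...) {
  cat(sprintf("<neighborhood_assignment> %d entities in %d neighborhoods\n",
              nrow(x$assignment), length(x$sources)))
  cat("  sizes:", paste(sprintf("%s=%d", x$sizes$label, x$sizes$n),
                        collapse = ", "), "\n")
  cat(sprintf("  cover radius: %.4g\n", x$objective))
  invisible(x)
}

#' @export
tidy.neighborhood_assignment <- function(x, ...) x$assignment

#' @export
glance.neighborhood_assignment <- function(x, ...) {
  tibble::tibble(
    n_entities = nrow(x$assignment),
    n_neighborhoods = length(x$sources),
    cover_radius = x$objective,
    min_size = min(x$sizes$n),
    median_size = stats::median(x$sizes$n),
    max_size = max(x$sizes$n)
  )
}

#' Characterize a neighborhood by its central profile
#'
#' Mean standardized profile of a source entity and its `n_neighbors` nearest
#' entities in embedding distance (11 entities under the default of 10
#' neighbors).
#'
#' @param m The preprocessed [quality_matrix()].
#' @param e The `embedding_result`.
#' @param source A source entity id.
#' @param n_neighbors Number of nearest neighbors to average with the source.
#' @return Named numeric profile vector over measures.
#' @export
neighborhood_profile <- function(m, e, source, n_neighbors = 10L) {
  n <- nrow(e$coordinates)
  if (n_neighbors + 1 > n) {
    stop("requested ", n_neighbors, " neighbors but only ", n - 1,
         " other entities are available", call. = FALSE)
  }
  s_row <- match(source, e$entity_ids)
  if (is.na(s_row)) stop("unknown source id: ", source, call. = FALSE)
  d <- sqrt(colSums((t(e$coordinates) - e$coordinates[s_row, ])^2))
  ord <- order(d, e$entity_ids)  # source itself first (distance 0)
  chosen <- e$entity_ids[ord[seq_len(n_neighbors + 1)]]
  rows <- match(chosen, m$entity_ids)
  colMeans(m$values[rows, , drop = FALSE])
}

#' Classify a profile's performance by measurement domain
#'
#' Per domain: `good` if most (> 50%) of its measures are above `+margin`,
#' `poor` if most are below `-margin`, `average` if most lie within the
#' margin, otherwise `mixed`. Measures more than 1 SD above or below the mean
#' are additionally flagged as particularly good / particularly poor.
#'
#' @param profile Named numeric vector over measures (standardized scale).
#' @param meta Measure metadata tibble (`measure_id`, `domain`).
#' @param margin Half-width of the "near average" band in SD units (default
#'   0.1).
#' @return A tibble `domain`, `classification`, `n_measures`,
#'   `frac_above`, `frac_below`, plus a `flags` attribute listing measures
#'   beyond +/-1 SD.
#' @export
classify_domain_performance <- function(profile, meta, margin = 0.1) {
  stopifnot(!is.null(names(profile)))
  df <- tibble::tibble(measure_id = names(profile), value = unname(profile)) |>
    dplyr::left_join(meta[, c("measure_id", "domain")], by = "measure_id")
  if (anyNA(df$domain)) {
    stop("measure(s) without a domain tag: ",
         paste(df$measure_id[is.na(df$domain)], collapse = ", "),
         call. = FALSE)
  }
  out <- df |>
    dplyr::group_by(.data$domain) |>
    dplyr::summarise(
      n_measures = dplyr::n(),
      frac_above = mean(.data$value > margin),
      frac_below = mean(.data$value < -margin),
      frac_near = mean(abs(.data$value) <= margin),
      .groups = "drop"
    ) |>
    dplyr::mutate(classification = dplyr::case_when(
      .data$frac_above > 0.5 ~ "good",
      .data$frac_below > 0.5 ~ "poor",
      .data$frac_near > 0.5 ~ "average",
      TRUE ~ "mixed"
    )) |>
    dplyr::select("domain", "classification", "n_measures",
                  "frac_above", "frac_below")
  flags <- df |>
    dplyr::filter(abs(.data$value) > 1) |>
    dplyr::mutate(flag = ifelse(.data$value > 1, "particularly_good",
                                "particularly_poor")) |>
    dplyr::select("measure_id", "domain", "value", "flag")
  attr(out, "flags") <- flags
  out
}

#' Plot neighborhood profiles
#'
#' Bar chart of each neighborhood's central profile across measures, grouped
#' and colored by domain, on the standardized (SD-unit) scale.
#'
#' @param object A `neighborhood_assignment` with profiles attached.
#' @param meta Measure metadata tibble (`measure_id`, `domain`).
#' @param labels Optional subset of neighborhood labels to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.neighborhood_assignment <- function(object, meta, labels = NULL,
                                             ...) {
  if (is.null(object$profiles)) {
    stop("assignment has no profiles; pass the quality matrix to ",
         "assign_neighborhoods()", call. = FALSE)
  }
  df <- tibble::as_tibble(object$profiles, rownames = "label") |>
    tidyr::pivot_longer(-"label", names_to = "measure_id",
                        values_to = "value") |>
    dplyr::left_join(meta[, c("measure_id", "domain")], by = "measure_id")
  if (!is.null(labels)) df <- dplyr::filter(df, .data$label %in% labels)
  df$measure_id <- factor(df$measure_id,
                          levels = unique(df$measure_id[order(df$domain)]))
  ggplot2::ggplot(df, ggplot2::aes(.data$measure_id, .data$value,
                                   fill = .data$domain)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = NULL, y = "standardized score (SD)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
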