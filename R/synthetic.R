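#' Specification of a synthetic quality-measure dataset
#'
#' The generator emulates the structure of a public hospital quality-measure
#' release: ~7 measurement domains with within-domain correlation, planted
#' entity clusters with distinct domain-level signatures, Gaussian
#' measurement noise, adverse ("lower is better") measures reported on a
#' flipped scale, missing-completely-at-random cells, and a block of
#' low-completeness entities that exercises the 90% row filter.
#'
#' @param n_entities Number of entities (default 600).
#' @param n_measures Number of measures (default 84).
#' @param n_domains Number of measurement domains (default 7).
#' @param measures_per_domain Optional integer vector summing to
#'   `n_measures`; defaults to an even split with the remainder spread over
#'   the first domains.
#' @param n_clusters Number of planted entity clusters (default 16).
#' @param domain_effect_scale SD of the per-cluster, per-domain mean shifts
#'   (default 1.5).
#' @param noise_sd SD of the measure-level Gaussian noise (default 0.7).
#' @param missing_rate MCAR missingness rate (default 0.03).
#' @param n_low_completeness_entities Entities given >10% missing cells so
#'   the row filter has something to drop (default 20).
#' @param seed Integer seed (default 1).
#' @return A `synthetic_spec` object (named list).
#' @export
synthetic_spec <- function(n_entities = 600L, n_measures = 84L,
                           n_domains = 7L, measures_per_domain = NULL,
                           n_clusters = 16L, domain_effect_scale = 1.5,
                           noise_sd = 0.7, missing_rate = 0.03,
                           n_low_completeness_entities = 20L, seed = 1L) {
  if (is.null(measures_per_domain)) {
    base <- n_measures %/% n_domains
    measures_per_domain <- rep(base, n_domains)
    extra <- n_measures - base * n_domains
    if (extra > 0) {
      measures_per_domain[seq_len(extra)] <-
        measures_per_domain[seq_len(extra)] + 1L
    }
  }
  if (n_clusters > n_entities) {
    stop("more clusters than entities is infeasible", call. = FALSE)
  }
  stopifnot(sum(measures_per_domain) == n_measures,
            missing_rate >= 0, missing_rate < 1,
            n_low_completeness_entities >= 0,
            n_low_completeness_entities <= n_entities)
  structure(
    list(n_entities = as.integer(n_entities),
         n_measures = as.integer(n_measures),
         n_domains = as.integer(n_domains),
         measures_per_domain = as.integer(measures_per_domain),
         n_clusters = as.integer(n_clusters),
         domain_effect_scale = domain_effect_scale,
         noise_sd = noise_sd, missing_rate = missing_rate,
         n_low_completeness_entities = as.integer(n_low_completeness_entities),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Canonical domain names in the spirit of a hospital quality release; domains
# beyond the first seven are numbered. Direction tags follow the field:
# outcome/safety/value-style domains are adverse rates (lower is better).
synthetic_domain_names <- function(n_domains) {
  base <- c("process", "experience", "value", "safety", "surgery",
            "readmission", "mortality")
  if (n_domains <= length(base)) return(base[seq_len(n_domains)])
  c(base, paste0("domain", seq_len(n_domains - length(base))))
}

synthetic_domain_directions <- function(domains) {
  lower <- c("value", "safety", "surgery", "readmission", "mortality")
  ifelse(domains %in% lower, "lower_better", "higher_better")
}

# Value-based-purchasing-style domain weights: outcomes (mortality,
# readmission) heaviest, then experience, then process, then the rest.
vbp_domain_weights <- function(domains) {
  w <- c(process = 0.10, experience = 0.20, value = 0.05, safety = 0.10,
         surgery = 0.05, readmission = 0.25, mortality = 0.25)
  out <- ifelse(domains %in% names(w), w[domains], 0.05)
  stats::setNames(out / sum(out), domains)
}

#' Generate a synthetic entity-by-measure dataset
#'
#' Cluster `c`'s signature in domain `d` is `mu[c, d] ~ N(0,
#' domain_effect_scale^2)`. Measure `j` in domain `d` for entity `i` of
#' cluster `c` is `mu[c, d] + loading_j * u_i + N(0, noise_sd^2)`, where
#' `u_i ~ N(0, 0.5^2)` is an entity-level general-quality wobble and
#' `loading_j ~ Uniform(0.5, 1)` induces within-domain correlation.
#' Lower-better measures are sign-flipped in the raw file (so a good hospital
#' shows a low raw rate), MCAR missingness is applied at `missing_rate`, and
#' `n_low_completeness_entities` entities additionally lose >10% of their
#' cells so the completeness filter is exercised. Fully reproducible from the
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional directory; when given, `matrix.csv`, `meta.csv`, and
#'   `ground_truth.json` are written there.
#' @return A list with `matrix` (a raw [quality_matrix()]), `meta` (tibble),
#'   `truth` (list: `cluster` labels, `mu` cluster-by-domain effect matrix,
#'   `u` entity quality wobble, `domain_of_measure`, `directions`,
#'   `cluster_quality` — the VBP-weighted oriented domain mean per cluster),
#'   and file `paths` when `dir` is given.
#' @export
generate_synthetic <- function(spec = synthetic_spec(), dir = NULL) {
  out <- with_seed(spec$seed, {
    n <- spec$n_entities
    p <- spec$n_measures
    domains <- synthetic_domain_names(spec$n_domains)
    domain_of_measure <- rep(domains, times = spec$measures_per_domain)
    directions <- synthetic_domain_directions(domain_of_measure)

    entity_ids <- sprintf("H%04d", seq_len(n))
    measure_ids <- sprintf("%s_m%02d", domain_of_measure,
                           unlist(lapply(spec$measures_per_domain, seq_len)))

    cluster <- sort(rep_len(seq_len(spec$n_clusters), n))
    mu <- matrix(stats::rnorm(spec$n_clusters * spec$n_domains,
                              sd = spec$domain_effect_scale),
                 spec$n_clusters, spec$n_domains,
                 dimnames = list(NULL, domains))
    u <- stats::rnorm(n, sd = 0.5)
    loading <- stats::runif(p, 0.5, 1)

    d_idx <- match(domain_of_measure, domains)
    vals <- mu[cluster, d_idx, drop = FALSE] +
      outer(u, loading) +
      matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    # adverse measures are reported on a flipped scale in the raw file
    flip <- directions == "lower_better"
    vals[, flip] <- -vals[, flip]
    dimnames(vals) <- list(entity_ids, measure_ids)

    if (spec$missing_rate > 0) {
      drop <- matrix(stats::runif(n * p) < spec$missing_rate, n, p)
      vals[drop] <- NA_real_
    }
    if (spec$n_low_completeness_entities > 0) {
      low <- sample.int(n, spec$n_low_completeness_entities)
      for (i in low) {
        n_del <- ceiling(0.10 * p) + sample.int(max(1, p %/% 4), 1)
        vals[i, sample.int(p, min(n_del, p))] <- NA_real_
      }
    }

    meta <- tibble::tibble(measure_id = measure_ids,
                           domain = domain_of_measure,
                           direction = directions)
    w <- vbp_domain_weights(domains)
    cluster_quality <- as.vector(mu %*% w)
    list(vals = vals, meta = meta, cluster = cluster, mu = mu, u = u,
         domain_of_measure = domain_of_measure, directions = directions,
         cluster_quality = cluster_quality, entity_ids = entity_ids)
  })

  qm <- quality_matrix(out$vals, out$meta)
  truth <- list(cluster = stats::setNames(out$cluster, out$entity_ids),
                mu = out$mu, u = out$u,
                domain_of_measure = out$domain_of_measure,
                directions = out$directions,
                cluster_quality = out$cluster_quality)
  res <- list(matrix = qm, meta = out$meta, truth = truth)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    mat_path <- file.path(dir, "matrix.csv")
    meta_path <- file.path(dir, "meta.csv")
    truth_path <- file.path(dir, "ground_truth.json")
    df <- data.frame(entity_id = rownames(out$vals), out$vals,
                     check.names = FALSE)
    utils::write.csv(df, mat_path, row.names = FALSE, na = "")
    readr::write_csv(out$meta, meta_path)
    jsonlite::write_json(
      list(cluster = truth$cluster, cluster_quality = truth$cluster_quality,
           mu = truth$mu),
      truth_path, auto_unbox = TRUE, digits = NA)
    res$paths <- list(matrix = mat_path, meta = meta_path,
                      ground_truth = truth_path)
  }
  res
}

#' Auto-generate expert score files for synthetic reference profiles
#'
#' Stands in for the human 1-10 ranking: each reference centroid's
#' value-based-purchasing-weighted domain mean (outcomes weighted more
#' heavily than experience, which outweighs process and the remaining
#' domains) is mapped affinely onto [1, 10] and rounded to the nearest
#' integer; three simulated raters add independent -1/0/+1 jitter, clamped to
#' the scale.
#'
#' @param refs A `reference_profile_set` (from
#'   [extract_reference_profiles()]).
#' @param meta Measure metadata tibble (`measure_id`, `domain`).
#' @param n_raters Number of simulated raters (default 3).
#' @param seed Integer seed.
#' @return A tibble `rater`, `leaf_id`, `score` (the [read_expert_scores()]
#'   shape).
#' @export
auto_expert_scores <- function(refs, meta, n_raters = 3L, seed = 1L) {
  domains <- unique(meta$domain)
  w <- vbp_domain_weights(domains)
  d_of <- meta$domain[match(refs$measure_ids, meta$measure_id)]
  quality <- purrr::map_dbl(refs$profiles$centroid, function(v) {
    dm <- tapply(v, d_of, mean)
    sum(w[names(dm)] * dm)
  })
  rng <- range(quality)
  base <- if (diff(rng) == 0) rep(5.5, length(quality)) else
    1 + 9 * (quality - rng[1]) / diff(rng)
  base <- round(base)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_raters), function(r) {
      jitter <- sample(c(-1L, 0L, 1L), length(base), replace = TRUE)
      tibble::tibble(rater = paste0("rater", r),
                     leaf_id = refs$profiles$leaf_id,
                     score = pmin(pmax(base + jitter, 1), 10))
    })
  })
}

#' Write expert scores as per-rater JSON files
#'
#' @param scores Tibble `rater`, `leaf_id`, `score`.
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
write_expert_scores <- function(scores, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- purrr::map_chr(unique(scores$rater), function(r) {
    sub <- scores[scores$rater == r, ]
    path <- file.path(dir, paste0(r, ".json"))
    jsonlite::write_json(
      stats::setNames(list(as.list(stats::setNames(sub$score, sub$leaf_id))),
                      r),
      path, auto_unbox = TRUE, digits = NA)
    path
  })
  invisible(paths)
}

#' Emit a ranking template for human experts
#'
#' Writes a skeleton expert-score JSON (scores null) and a per-leaf centroid
#' CSV — the ranking sheet an expert fills in on the 1-10 scale.
#'
#' @param refs A `reference_profile_set`.
#' @param dir Output directory.
#' @return Paths of the two files, invisibly.
#' @export
rank_template <- function(refs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "expert_scores_template.json")
  csv_path <- file.path(dir, "reference_centroids.csv")
  skeleton <- stats::setNames(
    list(as.list(stats::setNames(rep(list(NULL), nrow(refs$profiles)),
                                 refs$profiles$leaf_id))),
    "rater1")
  jsonlite::write_json(skeleton, json_path, auto_unbox = TRUE, null = "null")
  readr::write_csv(
    tidy(refs) |>
      tidyr::pivot_wider(names_from = "measure_id", values_from = "value"),
    csv_path)
  invisible(c(json = json_path, csv = csv_path))
}
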