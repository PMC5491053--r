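# A small fully-connected regression network trained by full-batch gradient
# descent with momentum. Deliberately plain: determinism from the seed
# matters more than training speed at the scale of a few hundred profiles.

mlp_init <- function(n_in, hidden_widths, seed) {
  with_seed(seed, {
    dims <- c(n_in, hidden_widths, 1L)
    lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]
      list(W = matrix(stats::rnorm(dims[l] * dims[l + 1], sd = 1 / sqrt(fan_in)),
                      dims[l], dims[l + 1]),
           b = rep(0, dims[l + 1]))
    })
  })
}

# Forward pass; returns activations per layer (tanh hidden, linear output).
mlp_forward <- function(layers, x) {
  acts <- vector("list", length(layers) + 1)
  acts[[1]] <- x
  for (l in seq_along(layers)) {
    z <- acts[[l]] %*% layers[[l]]$W +
      matrix(layers[[l]]$b, nrow(x), length(layers[[l]]$b), byrow = TRUE)
    acts[[l + 1]] <- if (l < length(layers)) tanh(z) else z
  }
  acts
}

mlp_train <- function(layers, x, y, epochs = 300L, lr = 0.05, momentum = 0.9,
                      weight_decay = 1e-4, plateau_tol = 1e-8,
                      plateau_patience = 25L) {
  n <- nrow(x)
  vel <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  best <- Inf
  best_layers <- layers
  stall <- 0L
  for (ep in seq_len(epochs)) {
    acts <- mlp_forward(layers, x)
    pred <- acts[[length(acts)]]
    err <- pred - y
    loss <- mean(err^2)
    if (!is.finite(loss)) break
    if (loss < best - plateau_tol) {
      best <- loss
      best_layers <- layers
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= plateau_patience) break
    }
    delta <- 2 * err / n
    for (l in rev(seq_along(layers))) {
      gW <- crossprod(acts[[l]], delta) + weight_decay * layers[[l]]$W
      gb <- colSums(delta)
      if (l > 1) {
        delta <- (delta %*% t(layers[[l]]$W)) * (1 - acts[[l]]^2)
      }
      vel[[l]]$W <- momentum * vel[[l]]$W - lr * gW
      vel[[l]]$b <- momentum * vel[[l]]$b - lr * gb
      layers[[l]]$W <- layers[[l]]$W + vel[[l]]$W
      layers[[l]]$b <- layers[[l]]$b + vel[[l]]$b
    }
  }
  list(layers = best_layers, loss = best)
}

#' Train the neural feature ensemble
#'
#' Trains `cfg$ensemble_size` small feedforward networks (tanh hidden layers
#' of widths `cfg$hidden_widths`, linear output) to regress the propagated
#' quality score from the standardized profile, each on its own bootstrap
#' resample with its own seeded initialization. The concatenated last-hidden-
#' layer activations of all members, evaluated on every entity, form a
#' high-dimensional feature set in which distance reflects the
#' quality-oriented, non-Euclidean metric the networks learned.
#'
#' @param m A preprocessed [quality_matrix()].
#' @param scores A tibble `entity_id`, `score` (from [propagate_scores()]),
#'   covering every entity.
#' @param cfg A [pipeline_config()].
#' @return A `feature_set`: `entity_ids`, `features` (entities x
#'   last-width * ensemble_size), and a `training` tibble (member, seed,
#'   initial and final mean squared error).
#' @export
train_ensemble <- function(m, scores, cfg = pipeline_config()) {
  idx <- match(m$entity_ids, scores$entity_id)
  if (anyNA(idx)) {
    stop("scores missing for entity ",
         paste(m$entity_ids[is.na(idx)][1], collapse = ", "), call. = FALSE)
  }
  x <- m$values
  y_raw <- scores$score[idx]
  y_center <- mean(y_raw)
  y_scale <- stats::sd(y_raw)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  y <- matrix((y_raw - y_center) / y_scale, ncol = 1)
  n <- nrow(x)
  last_width <- cfg$hidden_widths[length(cfg$hidden_widths)]

  members <- purrr::map(seq_len(cfg$ensemble_size), function(b) {
    seed <- cfg$rng_seed * 1000L + b
    boot <- with_seed(seed, sample.int(n, n, replace = TRUE))
    layers <- mlp_init(ncol(x), cfg$hidden_widths, seed + 1L)
    init_loss <- mean((mlp_forward(layers, x[boot, , drop = FALSE])[[
      length(cfg$hidden_widths) + 2]] - y[boot, , drop = FALSE])^2)
    fit <- mlp_train(layers, x[boot, , drop = FALSE],
                     y[boot, , drop = FALSE])
    if (!is.finite(fit$loss)) {
      stop("non-finite training loss in ensemble member ", b,
           " (seed ", seed, ")", call. = FALSE)
    }
    acts <- mlp_forward(fit$layers, x)
    list(features = acts[[length(cfg$hidden_widths) + 1]],
         prediction = acts[[length(cfg$hidden_widths) + 2]][, 1] *
           y_scale + y_center,
         log = tibble::tibble(member = b, seed = seed,
                              initial_mse = init_loss, final_mse = fit$loss))
  })

  features <- do.call(cbind, purrr::map(members, "features"))
  rownames(features) <- m$entity_ids
  colnames(features) <- paste0("f", seq_len(ncol(features)))
  predictions <- rowMeans(do.call(cbind, purrr::map(members, "prediction")))
  structure(
    list(entity_ids = m$entity_ids, features = features,
         predictions = tibble::tibble(entity_id = m$entity_ids,
                                      predicted_score = predictions),
         training = dplyr::bind_rows(purrr::map(members, "log")),
         last_width = last_width),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d entities x %d features (%d members)\n",
              nrow(x$features), ncol(x$features), nrow(x$training)))
  cat(sprintf("  final MSE: median %.4f (range %.4f-%.4f)\n",
              stats::median(x$training$final_mse),
              min(x$training$final_mse), max(x$training$final_mse)))
  invisible(x)
}

#' @export
glance.feature_set <- function(x, ...) {
  tibble::tibble(
    n_entities = nrow(x$features),
    n_features = ncol(x$features),
    ensemble_size = nrow(x$training),
    median_final_mse = stats::median(x$training$final_mse)
  )
}

#' Heat kernel on ensemble features
#'
#' `k(x, y) = exp(-||feat(x) - feat(y)||^2 / eps)` on the concatenated
#' hidden-layer features, with the self-tuning (median squared distance)
#' bandwidth by default.
#'
#' @param f A `feature_set` from [train_ensemble()].
#' @param cfg A [pipeline_config()].
#' @return An [affinity_kernel()] over entities.
#' @export
feature_heat_kernel <- function(f, cfg = pipeline_config()) {
  dm <- as.matrix(stats::dist(f$features))
  heat_kernel(dm, f$entity_ids, cfg)
}

#' Low-dimensional diffusion map
#'
#' Embeds the kernel's points with the top `cfg$embed_dims` non-trivial
#' diffusion coordinates `lambda_l^t psi_l`. Eigenvector signs are fixed
#' (largest-magnitude entry positive) and coordinates are centered, so the
#' map is reproducible and translation-free; centering does not alter any
#' pairwise distance.
#'
#' @param k A connected [affinity_kernel()].
#' @param cfg A [pipeline_config()].
#' @return An `embedding_result`: `entity_ids`, `coordinates` (entities x
#'   embed_dims), `eigenvalues` used.
#' @export
diffusion_map <- function(k, cfg = pipeline_config()) {
  g <- diffusion_embed(k, cfg)
  coords <- diffusion_coords(g, n_coords = cfg$embed_dims)
  coords <- sweep(coords, 2, colMeans(coords))
  colnames(coords) <- paste0("dc", seq_len(ncol(coords)))
  structure(
    list(entity_ids = g$ids, coordinates = coords,
         eigenvalues = g$eigenvalues[seq_len(ncol(coords)) + 1],
         geometry = g),
    class = "embedding_result"
  )
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d entities in %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.embedding_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(entity_id = x$entity_ids),
                   tibble::as_tibble(x$coordinates))
}

#' Write embedding coordinates to CSV
#'
#' @param x An `embedding_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding_csv <- function(x, path) {
  readr::write_csv(tidy(x), path)
  invisible(path)
}

#' Plot a diffusion map
#'
#' First two diffusion coordinates, optionally colored by a per-entity value
#' (e.g. propagated score or neighborhood label).
#'
#' @param object An `embedding_result`.
#' @param color Optional named vector or tibble `entity_id`, `value` used for
#'   the color aesthetic.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding_result <- function(object, color = NULL, ...) {
  df <- tidy(object)
  if (!is.null(color)) {
    if (is.data.frame(color)) {
      df$value <- color[[2]][match(df$entity_id, color[[1]])]
    } else {
      df$value <- unname(color[df$entity_id])
    }
    ggplot2::ggplot(df, ggplot2::aes(.data$dc1, .data$dc2,
                                     color = .data$value)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "diffusion coordinate 1",
                    y = "diffusion coordinate 2") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$dc1, .data$dc2)) +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "diffusion coordinate 1",
                    y = "diffusion coordinate 2") +
      ggplot2::theme_minimal()
  }
}
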