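#' Affinity kernel
#'
#' A symmetric nonnegative similarity matrix with unit diagonal over a set of
#' identified points (measures or entities).
#'
#' @param ids Character vector of point identifiers.
#' @param weights Symmetric numeric matrix in \[0, 1\] with unit diagonal.
#' @return An `affinity_kernel` object.
#' @export
affinity_kernel <- function(ids, weights) {
  stopifnot(is.matrix(weights), nrow(weights) == length(ids),
            ncol(weights) == length(ids))
  if (max(abs(weights - t(weights))) > 1e-12) {
    stop("affinity weights must be symmetric", call. = FALSE)
  }
  if (any(weights < -1e-12) || any(weights > 1 + 1e-12)) {
    stop("affinity weights must lie in [0, 1]", call. = FALSE)
  }
  weights <- pmin(pmax(weights, 0), 1)
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 1
  dimnames(weights) <- list(ids, ids)
  structure(list(ids = ids, weights = weights), class = "affinity_kernel")
}

#' @export
print.affinity_kernel <- function(x, ...) {
  cat(sprintf("<affinity_kernel> %d points, mean off-diagonal weight %.3f\n",
              length(x$ids), mean(x$weights[upper.tri(x$weights)])))
  invisible(x)
}

#' Cosine affinity between profiles
#'
#' Pairwise cosine similarity between measure profiles (columns) or entity
#' profiles (rows), with negative cosines clipped to 0 so the kernel admits a
#' Markov normalization; orthogonal profiles therefore sit at affinity 0.
#'
#' @param m An imputed [quality_matrix()].
#' @param axis `"measures"` (columns) or `"entities"` (rows).
#' @return An [affinity_kernel()].
#' @export
cosine_affinity <- function(m, axis = c("measures", "entities")) {
  axis <- match.arg(axis)
  x <- if (axis == "measures") t(m$values) else m$values
  ids <- if (axis == "measures") m$measure_ids else m$entity_ids
  norms <- sqrt(rowSums(x^2))
  zero <- which(norms == 0)
  if (length(zero) > 0) {
    stop("zero-norm profile(s): ", paste(ids[zero], collapse = ", "),
         call. = FALSE)
  }
  u <- x / norms
  w <- tcrossprod(u)
  w <- pmax(w, 0)
  affinity_kernel(ids, w)
}

#' Heat kernel from squared distances
#'
#' `k(x, y) = exp(-d(x, y)^2 / eps)` with the bandwidth chosen by
#' `cfg$kernel_bandwidth_rule` (median squared pairwise distance by default).
#'
#' @param dist_mat Symmetric matrix of pairwise distances.
#' @param ids Point identifiers.
#' @param cfg A [pipeline_config()].
#' @return An [affinity_kernel()].
#' @export
heat_kernel <- function(dist_mat, ids, cfg = pipeline_config()) {
  eps <- kernel_bandwidth_for(dist_mat, cfg)
  w <- exp(-dist_mat^2 / eps)
  affinity_kernel(ids, w)
}
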