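#' Diffusion geometry of an affinity kernel
#'
#' Row-stochastic (Markov) normalization of the kernel, eigendecomposed
#' through its symmetric conjugate `S = D^{-1/2} W D^{-1/2}`. Right
#' eigenvectors of the Markov matrix are recovered as
#' `psi = sqrt(sum(d)) * D^{-1/2} phi`, a normalization under which the
#' trivial eigenvector is the constant 1 vector and the spectral diffusion
#' distance equals the distance between Markov transition rows weighted by
#' the inverse stationary distribution.
#'
#' @param k An [affinity_kernel()]; must be connected under positive weights.
#' @param cfg A [pipeline_config()]; `n_eigenvectors` non-trivial pairs are
#'   retained and `diffusion_time` sets t.
#' @return A `diffusion_geometry` object with fields `ids`, `eigenvalues`
#'   (descending, leading value 1), `eigenvectors` (points x pairs, trivial
#'   pair first), and `diffusion_time`.
#' @export
diffusion_embed <- function(k, cfg = pipeline_config()) {
  w <- k$weights
  comp <- affinity_components(w)
  if (max(comp) > 1) {
    sizes <- table(comp)
    stop("affinity kernel is disconnected; component sizes: ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  d <- rowSums(w)
  inv_sqrt_d <- 1 / sqrt(d)
  s <- w * tcrossprod(inv_sqrt_d)
  es <- eigen(s, symmetric = TRUE)
  ord <- order(es$values, decreasing = TRUE)
  lambda <- es$values[ord]
  phi <- es$vectors[, ord, drop = FALSE]
  n_keep <- min(cfg$n_eigenvectors + 1L, length(lambda))
  lambda <- lambda[seq_len(n_keep)]
  psi <- sqrt(sum(d)) * (inv_sqrt_d * phi[, seq_len(n_keep), drop = FALSE])
  # fix signs: largest-magnitude entry of each eigenvector is positive
  for (l in seq_len(n_keep)) {
    i_max <- which.max(abs(psi[, l]))
    if (psi[i_max, l] < 0) psi[, l] <- -psi[, l]
  }
  lambda[1] <- 1
  rownames(psi) <- k$ids
  structure(
    list(ids = k$ids, eigenvalues = lambda, eigenvectors = psi,
         diffusion_time = cfg$diffusion_time),
    class = "diffusion_geometry"
  )
}

#' @export
print.diffusion_geometry <- function(x, ...) {
  cat(sprintf(
    "<diffusion_geometry> %d points, %d non-trivial eigenpairs, t = %g\n",
    length(x$ids), length(x$eigenvalues) - 1, x$diffusion_time))
  cat("  eigenvalues:",
      paste(signif(x$eigenvalues[seq_len(min(6, length(x$eigenvalues)))], 3),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Diffusion coordinates
#'
#' Non-trivial eigenvectors scaled by `lambda^t`; Euclidean distance between
#' rows is the diffusion distance restricted to the retained spectrum.
#'
#' @param g A `diffusion_geometry`.
#' @param n_coords Number of coordinates (default: all retained non-trivial
#'   pairs).
#' @return Numeric matrix (points x n_coords) with ids as rownames.
#' @export
diffusion_coords <- function(g, n_coords = NULL) {
  nt <- length(g$eigenvalues) - 1L
  if (is.null(n_coords)) n_coords <- nt
  n_coords <- min(n_coords, nt)
  idx <- seq_len(n_coords) + 1L
  coords <- sweep(g$eigenvectors[, idx, drop = FALSE], 2,
                  g$eigenvalues[idx]^g$diffusion_time, `*`)
  rownames(coords) <- g$ids
  coords
}

#' Pairwise diffusion distances
#'
#' `d(i, j) = sqrt(sum_l lambda_l^{2t} (psi_l(i) - psi_l(j))^2)` over the
#' retained non-trivial eigenpairs.
#'
#' @param g A `diffusion_geometry`.
#' @return Symmetric distance matrix with ids as dimnames.
#' @export
diffusion_distances <- function(g) {
  coords <- diffusion_coords(g)
  dm <- as.matrix(stats::dist(coords))
  dimnames(dm) <- list(g$ids, g$ids)
  dm
}

#' @export
tidy.diffusion_geometry <- function(x, ...) {
  coords <- diffusion_coords(x)
  out <- tibble::as_tibble(coords, .name_repair = ~ paste0("dc", seq_along(.x)))
  dplyr::bind_cols(tibble::tibble(id = x$ids), out)
}
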