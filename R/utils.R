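# Internal helpers shared across modules.

# Evaluate `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Small deterministic string hash onto [0, 2^28), for per-node subseeds.
str_hash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 268435456
  as.integer(h)
}

# Adjusted Rand index between two label vectors (Hubert & Arabie).
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_i <- sum(choose2(rowSums(tab)))
  sum_j <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Median of squared off-diagonal entries of a distance matrix; the
# self-tuning heat-kernel bandwidth.
median_sq_bandwidth <- function(dist_mat) {
  off <- dist_mat[upper.tri(dist_mat)]
  eps <- stats::median(off^2)
  if (!is.finite(eps) || eps <= 0) {
    stop("degenerate bandwidth: all pairwise distances are zero",
         call. = FALSE)
  }
  eps
}

kernel_bandwidth_for <- function(dist_mat, cfg) {
  switch(cfg$kernel_bandwidth_rule,
    median_sq_dist = median_sq_bandwidth(dist_mat),
    fixed = cfg$kernel_bandwidth
  )
}

# Ensure an affinity kernel is connected: if hard zeros (clipped cosines or
# underflowed heat weights) split the graph, blend in a uniform floor just
# large enough to bridge the components. Leaves connected kernels untouched.
connect_kernel <- function(k, floor = 1e-6) {
  if (max(affinity_components(k$weights)) == 1) return(k)
  w <- pmax(k$weights, floor)
  diag(w) <- 1
  affinity_kernel(k$ids, w)
}

# Connected components of a nonnegative affinity matrix (edges where w > 0).
affinity_components <- function(w) {
  n <- nrow(w)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(w[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
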