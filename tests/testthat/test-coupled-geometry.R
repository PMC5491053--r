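test_that("cosine affinity matches hand-computed values and clips negatives", {
  m <- make_processed_qm(rbind(c(1, 0, 1), c(1, 1, -1), c(2, 0, 2)))
  k <- cosine_affinity(m, "entities")
  expect_equal(unname(k$weights["e01", "e03"]), 1)          # parallel
  expect_equal(unname(diag(k$weights)), rep(1, 3))
  v <- make_processed_qm(rbind(c(1, 0), c(1, 1), c(0, 1)))
  kv <- cosine_affinity(v, "entities")
  expect_equal(unname(kv$weights["e01", "e02"]), 0.7071, tolerance = 1e-4)
  expect_equal(unname(kv$weights["e01", "e03"]), 0)         # orthogonal

  # anti-parallel profiles are clipped to 0, not negative
  a <- make_processed_qm(rbind(c(1, 1), c(-1, -1)))
  expect_equal(unname(cosine_affinity(a, "entities")$weights[1, 2]), 0)

  z <- make_processed_qm(rbind(c(0, 0), c(1, 1)))
  expect_error(cosine_affinity(z, "entities"), "e01")
})

test_that("diffusion geometry has the Markov structure", {
  withr::with_seed(2, {
    x <- matrix(rnorm(12), 6, 2)
    w <- exp(-as.matrix(dist(x))^2)
    diag(w) <- 1
    k <- affinity_kernel(sprintf("p%d", 1:6), w)
    g <- diffusion_embed(k, pipeline_config(n_eigenvectors = 5))
    expect_equal(g$eigenvalues[1], 1)
    expect_lt(max(abs(g$eigenvectors[, 1] - g$eigenvectors[1, 1])), 1e-9)
    expect_equal(unname(diag(diffusion_distances(g))), rep(0, 6))
    dm <- diffusion_distances(g)
    expect_equal(dm, t(dm))
  })
})

test_that("first non-trivial eigenvector separates a two-block kernel", {
  w <- matrix(0.01, 6, 6)
  w[1:3, 1:3] <- 1
  w[4:6, 4:6] <- 1
  diag(w) <- 1
  k <- affinity_kernel(sprintf("p%d", 1:6), w)
  g <- diffusion_embed(k, pipeline_config(n_eigenvectors = 5))
  s <- sign(g$eigenvectors[, 2])
  expect_true(all(s[1:3] == s[1]) && all(s[4:6] == s[4]) && s[1] != s[4])
  # cross-check against base eigen() on the Markov matrix directly
  p <- w / rowSums(w)
  ev <- eigen(p)
  expect_equal(sort(Re(ev$values), decreasing = TRUE)[2], g$eigenvalues[2],
               tolerance = 1e-9)
})

test_that("disconnected kernels are rejected with component sizes", {
  w <- diag(5)
  w[1:2, 1:2] <- 1
  k <- affinity_kernel(sprintf("p%d", 1:5), w)
  expect_error(diffusion_embed(k), "component sizes: 2, 1, 1, 1")
})

test_that("eigen diffusion distances equal explicit Markov-power distances", {
  withr::with_seed(11, {
    x <- matrix(rnorm(16), 8, 2)
    dm <- as.matrix(dist(x))
    w <- exp(-dm^2 / median(dm^2))
    diag(w) <- 1
    k <- affinity_kernel(sprintf("p%d", 1:8), w)
    g <- diffusion_embed(k, pipeline_config(n_eigenvectors = 7,
                                            diffusion_time = 1))
    # independent oracle: rows of the Markov matrix, weighted by 1/stationary
    p1 <- w / rowSums(w)
    pi_st <- rowSums(w) / sum(w)
    brute <- matrix(0, 8, 8)
    for (i in 1:8) for (j in 1:8) {
      brute[i, j] <- sqrt(sum((p1[i, ] - p1[j, ])^2 / pi_st))
    }
    expect_lt(max(abs(unname(diffusion_distances(g)) - brute)), 1e-6)
  })
})

test_that("partition tree recovers a planted bipartition and obeys structure", {
  withr::with_seed(8, {
    x <- rbind(matrix(rnorm(8, mean = 0, sd = 0.1), 4, 2),
               matrix(rnorm(8, mean = 5, sd = 0.1), 4, 2))
    w <- exp(-as.matrix(dist(x))^2 / 4)
    diag(w) <- 1
    k <- affinity_kernel(sprintf("p%d", 1:8), w)
    g <- diffusion_embed(k)
    tree <- build_partition_tree(g, depth = 1, seed = 1)
    lv <- tree_leaves(tree)
    expect_length(lv, 2)
    expect_setequal(lv[[1]], sprintf("p%d", 1:4))
    expect_setequal(lv[[2]], sprintf("p%d", 5:8))
  })
})

test_that("depth-5 tree on 512 points yields 32 leaves that partition ids", {
  withr::with_seed(21, {
    x <- matrix(rnorm(1024), 512, 2)
    w <- exp(-as.matrix(dist(x))^2 / 8)
    diag(w) <- 1
    k <- affinity_kernel(sprintf("p%03d", 1:512), w)
    g <- diffusion_embed(k)
    tree <- build_partition_tree(g, depth = 5, seed = 1)
    lv <- tree_leaves(tree)
    expect_length(lv, 32)
    expect_setequal(unlist(lv), sprintf("p%03d", 1:512))
    expect_equal(sum(lengths(lv)), 512)
    # every level's nodes partition the set
    for (level in 0:5) {
      expect_setequal(names(tree_cut(tree, level)), sprintf("p%03d", 1:512))
    }
    # determinism
    tree2 <- build_partition_tree(g, depth = 5, seed = 1)
    expect_identical(tree_leaves(tree2), lv)
  })
})

test_that("a node too small to split at the requested depth errors in strict mode", {
  w <- matrix(0.5, 3, 3)
  diag(w) <- 1
  k <- affinity_kernel(sprintf("p%d", 1:3), w)
  g <- diffusion_embed(k)
  expect_error(build_partition_tree(g, depth = 2, seed = 1),
               "insufficient entities")
  loose <- build_partition_tree(g, depth = 2, seed = 1, strict = FALSE)
  expect_lte(length(tree_leaves(loose)), 4)
})

test_that("tree-EMD distances follow the multiscale node formula", {
  tree <- six_measure_tree()
  cfg <- pipeline_config()
  base <- rep(1, 6)
  delta <- 0.6
  bumped <- base
  bumped[2] <- base[2] + delta  # m2 sits in leaf r01 under r0 under r
  m <- make_named_qm(rbind(base, bumped, base),
                     c("e01", "e02", "e03"), paste0("m", 1:6))
  dm <- tree_emd_distances(m, tree, cfg)

  expect_equal(unname(dm["e01", "e03"]), 0)
  expect_equal(dm, t(dm))
  # ancestors of m2's leaf: r01 (level 2, 2 members), r0 (level 1, 3), r (0, 6)
  expected <- delta / 2 * 2^(-0.5 * 2) * (2 / 6) +
    delta / 3 * 2^(-0.5 * 1) * (3 / 6) +
    delta / 6 * 2^(-0.5 * 0) * (6 / 6)
  expect_equal(unname(dm["e01", "e02"]), expected, tolerance = 1e-12)

  k <- tree_emd_affinity(m, tree, cfg)
  expect_equal(unname(k$weights["e01", "e03"]), 1)
})

test_that("tree-EMD with a root-only tree reduces to grand-mean differences", {
  tree <- mk_tree(mk_node("r", 0, paste0("m", 1:4)), 0)
  vals <- rbind(c(1, 2, 3, 4), c(2, 3, 4, 5), c(1, 2, 3, 4))
  m <- make_named_qm(vals, c("e01", "e02", "e03"), paste0("m", 1:4))
  dm <- tree_emd_distances(m, tree, pipeline_config())
  expect_equal(unname(dm["e01", "e02"]), abs(mean(vals[1, ]) - mean(vals[2, ])))
  expect_equal(unname(dm["e01", "e03"]), 0)
})

test_that("tree-EMD is a pseudometric on random instances", {
  withr::with_seed(13, {
    vals <- matrix(rnorm(80), 10, 8)
    m <- make_processed_qm(vals)
    g <- diffusion_embed(cosine_affinity(m, "measures"))
    tree <- build_partition_tree(g, 2, seed = 1, strict = FALSE)
    dm <- tree_emd_distances(m, tree, pipeline_config())
    expect_true(all(dm >= 0))
    expect_equal(dm, t(dm))
    for (i in 1:10) for (j in 1:10) for (l in 1:10) {
      expect_lte(dm[i, j], dm[i, l] + dm[l, j] + 1e-9)
    }
  })
})

test_that("coupled iterations recover planted hierarchical biclusters", {
  fx <- bicluster_qm()
  pre <- impute_missing(clip_extremes(standardize_measures(fx$qm)))
  cg <- run_coupled_iterations(pre, pipeline_config(rng_seed = 1))
  expect_gte(adjusted_rand_index(fx$measure_block,
                                 tree_cut(cg$measure_tree, 2)), 0.9)
  expect_gte(adjusted_rand_index(fx$entity_block,
                                 tree_cut(cg$entity_tree, 2)), 0.9)
  expect_true(is.na(cg$iterations$entity_ari[1]))
  expect_true(all(cg$iterations$entity_ari[-1] >= -1, na.rm = TRUE))
})

test_that("one coupled iteration equals the single-pass composition", {
  fx <- bicluster_qm(n_e = 40, n_m = 16, seed = 6)
  pre <- impute_missing(clip_extremes(standardize_measures(fx$qm)))
  cfg1 <- pipeline_config(rng_seed = 3, n_coupled_iterations = 1)
  cg <- run_coupled_iterations(pre, cfg1)

  mk <- hospmap:::connect_kernel(cosine_affinity(pre, "measures"))
  mg <- diffusion_embed(mk, cfg1)
  mt <- build_partition_tree(mg, max(1L, min(floor(log2(16)), 6L)),
                             seed = cfg1$rng_seed + 1L, strict = FALSE)
  ek <- tree_emd_affinity(pre, mt, cfg1)
  eg <- diffusion_embed(ek, cfg1)
  expect_identical(tree_leaves(cg$measure_tree), tree_leaves(mt))
  expect_equal(cg$entity_geometry$eigenvalues, eg$eigenvalues)

  # determinism of the whole loop
  cg2 <- run_coupled_iterations(pre, cfg1)
  expect_identical(tree_leaves(cg$entity_tree), tree_leaves(cg2$entity_tree))
})
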