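test_that("source placement solves tiny instances exactly", {
  # k = 1 on a line {0, 1, 10}: the minimax center is the middle point
  e <- make_embedding(cbind(c(0, 1, 10)))
  src <- place_sources(e, 1, seed = 1)
  expect_equal(as.character(src), "e02")
  expect_equal(attr(src, "objective"), 9)

  # k = n: every point is a source, objective 0
  src_all <- place_sources(e, 3, seed = 1)
  expect_setequal(as.character(src_all), e$entity_ids)
  expect_equal(attr(src_all, "objective"), 0)

  expect_error(place_sources(e, 4, seed = 1), "exceeds")
})

test_that("placement matches exhaustive search exactly; heuristic stays near-optimal", {
  brute_kcenter <- function(coords, k) {
    dmat <- as.matrix(dist(coords))
    combos <- utils::combn(nrow(coords), k)
    objs <- apply(combos, 2, function(s) {
      max(apply(dmat[, s, drop = FALSE], 1, min))
    })
    min(objs)
  }
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- sample(8:12, 1)
      k <- sample(2:3, 1)
      coords <- matrix(rnorm(n * 2), n, 2)
      e <- make_embedding(coords)
      best <- brute_kcenter(coords, k)
      # default path enumerates these instances exactly
      src <- place_sources(e, k, seed = rep)
      expect_equal(attr(src, "objective"), best, tolerance = 1e-9)
      # forced greedy + swap path: optimal <= heuristic <= 2x optimal
      heur <- place_sources(e, k, seed = rep, exact_limit = 0)
      expect_gte(attr(heur, "objective"), best - 1e-9)
      expect_lte(attr(heur, "objective"), 2 * best + 1e-9)
    }
  })

  # 12 points in 3 well-separated clusters: one source per cluster
  withr::with_seed(2, {
    coords <- rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
                    matrix(rnorm(8, 10, 0.1), 4, 2),
                    matrix(rnorm(8, -10, 0.1), 4, 2))
  })
  e <- make_embedding(coords)
  src <- place_sources(e, 3, seed = 1, exact_limit = 0)
  grp <- rep(1:3, each = 4)
  expect_setequal(grp[match(as.character(src), e$entity_ids)], 1:3)
})

test_that("neighborhood assignment partitions entities with size-ordered labels", {
  withr::with_seed(9, {
    coords <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
                    matrix(rnorm(8, 6, 0.3), 4, 2))
  })
  e <- make_embedding(coords)
  src <- place_sources(e, 2, seed = 1)
  nb <- assign_neighborhoods(e, src)
  td <- tidy(nb)
  expect_setequal(td$entity_id, e$entity_ids)
  expect_equal(sum(nb$sizes$n), 14)
  # A is the larger neighborhood
  expect_equal(nb$sizes$label[which.max(nb$sizes$n)], "A")
  # sources belong to their own neighborhood at distance 0
  expect_true(all(td$distance_to_source[td$is_source] == 0))
  expect_error(assign_neighborhoods(e, c(src[1], src[1])), "duplicate")
})

test_that("distance ties are broken toward the earlier source deterministically", {
  e <- make_embedding(cbind(c(-1, 0, 1)))
  nb1 <- assign_neighborhoods(e, c("e01", "e03"))
  nb2 <- assign_neighborhoods(e, c("e01", "e03"))
  lab_mid1 <- tidy(nb1)$source_id[tidy(nb1)$entity_id == "e02"]
  expect_equal(lab_mid1, "e01")
  expect_identical(tidy(nb1), tidy(nb2))
})

test_that("neighborhood profiles average the source and nearest neighbors", {
  vals <- rbind(c(0, 0), c(2, 2), c(50, 50), c(60, 60))
  m <- make_processed_qm(vals)
  e <- make_embedding(vals, ids = m$entity_ids)
  prof <- neighborhood_profile(m, e, "e01", n_neighbors = 1)
  expect_equal(unname(prof), c(1, 1))
  expect_length(prof, 2)

  ident <- make_processed_qm(matrix(3, 11, 4))
  ei <- make_embedding(matrix(rnorm(22), 11, 2), ids = ident$entity_ids)
  expect_equal(unname(neighborhood_profile(ident, ei, ident$entity_ids[1],
                                           10)), rep(3, 4))
  expect_error(neighborhood_profile(m, e, "e01", n_neighbors = 5),
               "3 other entities")
})

test_that("domain performance classification follows the majority rule", {
  meta <- make_meta(paste0("m", 1:6),
                    domain = rep(c("process", "experience", "safety"),
                                 each = 2))
  prof <- c(m1 = 0.5, m2 = 0.4, m3 = 0.5, m4 = -0.5, m5 = 0.02, m6 = -0.03)
  out <- classify_domain_performance(prof, meta)
  expect_equal(out$classification[out$domain == "process"], "good")
  expect_equal(out$classification[out$domain == "experience"], "mixed")
  expect_equal(out$classification[out$domain == "safety"], "average")

  poor <- classify_domain_performance(c(m1 = -0.3, m2 = -0.4), make_meta(paste0("m", 1:2)))
  expect_equal(poor$classification, "poor")

  flagged <- classify_domain_performance(c(m1 = 1.3, m2 = -1.2, m3 = 0),
                                         make_meta(paste0("m", 1:3)))
  flags <- attr(flagged, "flags")
  expect_equal(flags$flag[flags$measure_id == "m1"], "particularly_good")
  expect_equal(flags$flag[flags$measure_id == "m2"], "particularly_poor")
  expect_false("m3" %in% flags$measure_id)

  expect_error(classify_domain_performance(c(mx = 1), make_meta("m1")),
               "without a domain")
})
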