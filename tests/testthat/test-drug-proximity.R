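path_graph <- function(nodes) {
  as_interactome(tibble::tibble(
    from = nodes[-length(nodes)], to = nodes[-1]
  ))
}

test_that("closest distance matches forced path lengths", {
  g <- path_graph(c("A", "B", "C", "D"))
  expect_equal(closest_distance(g, S = c("A", "B"), T_set = c("A", "B")), 0)
  expect_equal(closest_distance(g, S = "A", T_set = c("C", "D")), 2.5)

  # unscorable pair: no exception, NA with a reason
  d <- closest_distance(g, S = "ZZZ", T_set = "A")
  expect_true(is.na(d))
  expect_match(attr(d, "reason"), "empty")
})

test_that("closest distance equals a Floyd-Warshall oracle on random graphs", {
  for (seed in 1:10) {
    g <- random_connected_interactome(15, 0.25, seed)
    D <- oracle_floyd_warshall(g)
    sets <- withr::with_seed(seed + 50, list(
      S = sample(g$nodes, 4), T_set = sample(g$nodes, 3)
    ))
    expect_equal(
      closest_distance(g, sets$S, sets$T_set),
      oracle_closest_distance(D, sets$S, sets$T_set)
    )
  }
})

test_that("distance is monotone non-increasing as the disease set grows", {
  g <- random_connected_interactome(20, 0.2, 31)
  sets <- withr::with_seed(32, list(
    S = sample(g$nodes, 3), T_set = sample(g$nodes, 4),
    extra = sample(g$nodes, 6)
  ))
  d1 <- closest_distance(g, sets$S, sets$T_set)
  d2 <- closest_distance(g, union(sets$S, sets$extra), sets$T_set)
  expect_lte(d2, d1)
  # zero iff every target is a disease protein
  expect_equal(closest_distance(g, g$nodes, sets$T_set), 0)
  expect_gt(closest_distance(g, setdiff(g$nodes, sets$T_set)[1:3],
    sets$T_set), 0)
})

test_that("degree-matched sampling preserves size and mean degree", {
  g <- random_connected_interactome(250, 0.05, 41)
  node_set <- withr::with_seed(42, sample(g$nodes, 12))
  draws <- withr::with_seed(43, {
    replicate(2000, sample_degree_matched(g, node_set, min_bin = 20L),
      simplify = FALSE)
  })
  expect_true(all(vapply(draws, length, integer(1)) == length(node_set)))
  deg <- node_degrees(g)
  target <- mean(deg[node_set])
  got <- mean(vapply(draws, function(d) mean(deg[d]), numeric(1)))
  expect_lt(abs(got - target) / target, 0.05)
})

test_that("degree-matched sampling degenerates gracefully on tiny graphs", {
  # star: unique max-degree hub; min_bin larger than the graph means one
  # bin, so any same-size subset can be drawn
  star <- as_interactome(tibble::tibble(
    from = rep("HUB", 4), to = paste0("L", 1:4)
  ))
  s <- withr::with_seed(1, sample_degree_matched(star, c("HUB", "L1")))
  expect_equal(length(s), 2L)
  expect_true(all(s %in% star$nodes))
  expect_equal(length(unique(s)), 2L) # without replacement
})

test_that("proximity permutation statistics are reproducible and sane", {
  g <- random_connected_interactome(60, 0.1, 51)
  sets <- withr::with_seed(52, list(
    S = sample(g$nodes, 8), T_set = sample(g$nodes, 4)
  ))
  r1 <- proximity_z(g, sets$S, sets$T_set, n_perm = 200, seed = 99)
  r2 <- proximity_z(g, sets$S, sets$T_set, n_perm = 200, seed = 99)
  expect_identical(tidy(r1), tidy(r2))
  expect_identical(r1$perm_distances, r2$perm_distances)

  expect_equal(r1$z, (r1$distance - r1$mu) / r1$sigma)
  expect_gte(r1$p_empirical, 1 / 201)
  expect_lte(r1$p_empirical, 1)
})

test_that("zero permutation variance flags the result", {
  # disease set = whole graph: every permuted distance is exactly zero
  nodes <- paste0("K", 1:6)
  p <- t(combn(nodes, 2))
  g <- as_interactome(tibble::tibble(from = p[, 1], to = p[, 2]))
  r <- proximity_z(g, S = nodes, T_set = c("K3", "K4"),
    n_perm = 50, seed = 1)
  expect_true(r$flagged)
  expect_true(is.na(r$z))
  expect_false(is.na(r$p_empirical))
})

test_that("screening keeps approved, strongly proximal drugs only", {
  res <- tibble::tibble(
    drug_id = sprintf("D%d", 1:4),
    z = c(-5, -3.5, -3.5, -2),
    p_normal = c(1e-4, 0.01, 0.01, 0.01),
    approved = c(TRUE, FALSE, TRUE, TRUE)
  )
  kept <- screen_drugs(res)
  expect_equal(kept$drug_id, c("D1", "D3"))

  sim <- withr::with_seed(61, tibble::tibble(
    drug_id = sprintf("D%03d", 1:100),
    z = rnorm(100, -2, 2),
    p_normal = runif(100),
    approved = runif(100) < 0.5
  ))
  kept2 <- screen_drugs(sim)
  oracle <- sim[sim$z < -3 & sim$p_normal < 0.05 & sim$approved, ]
  expect_setequal(kept2$drug_id, oracle$drug_id)
  expect_equal(kept2$z, sort(kept2$z))
})

test_that("a drug screen runs per-drug substreams reproducibly", {
  g <- random_connected_interactome(50, 0.12, 71)
  targets <- withr::with_seed(72, tibble::tibble(
    drug_id = rep(c("DA", "DB"), each = 3),
    target = sample(g$nodes, 6),
    approved = TRUE
  ))
  S <- withr::with_seed(73, sample(g$nodes, 10))
  scr1 <- proximity_screen(g, S, targets, n_perm = 100, seed = 5)
  scr2 <- proximity_screen(g, S, targets, n_perm = 100, seed = 5)
  expect_identical(as.data.frame(scr1), as.data.frame(scr2))
  # reordering the drug table does not change per-drug results
  scr3 <- proximity_screen(g, S, targets[6:1, ], n_perm = 100, seed = 5)
  expect_equal(
    dplyr::arrange(as.data.frame(scr1), drug_id),
    dplyr::arrange(as.data.frame(scr3), drug_id)
  )
})
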