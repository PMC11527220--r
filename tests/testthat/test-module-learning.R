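eye <- function(n) diag(n)

test_that("propagation matches forced linear algebra on a single edge", {
  g <- as_interactome(tibble::tibble(from = "A", to = "B"))
  Ahat <- symmetric_normalize(g)
  W <- list(eye(1), eye(1), eye(1))
  H <- matrix(c(1, 0), 2, 1)
  # Ahat^2 = I for one edge, so (I + Ahat + I) H = [[2],[1]]
  expect_equal(unname(propagate_layer(H, Ahat, W)), matrix(c(2, 1), 2, 1))

  zeroW <- list(matrix(0, 1, 3), matrix(0, 1, 3), matrix(0, 1, 3))
  expect_equal(unname(propagate_layer(H, Ahat, zeroW)), matrix(0, 2, 3))
})

test_that("propagation equals a dense matrix-power oracle on random graphs", {
  for (seed in 1:5) {
    g <- random_connected_interactome(12, 0.3, seed)
    Ahat <- symmetric_normalize(g)
    n <- length(g$nodes)
    H <- withr::with_seed(seed + 100, matrix(rnorm(n * 4), n, 4))
    W <- withr::with_seed(seed + 200, lapply(1:3, function(j) {
      matrix(rnorm(4 * 3), 4, 3)
    }))
    Ad <- as.matrix(Ahat)
    oracle <- pmax(
      diag(n) %*% H %*% W[[1]] + Ad %*% H %*% W[[2]] +
        (Ad %*% Ad) %*% H %*% W[[3]],
      0
    )
    expect_equal(propagate_layer(H, Ahat, W), oracle, tolerance = 1e-10)
  }
})

test_that("propagation is permutation-equivariant", {
  g <- random_connected_interactome(10, 0.35, 77)
  Ahat <- symmetric_normalize(g)
  n <- length(g$nodes)
  H <- withr::with_seed(1, matrix(rnorm(n * 3), n, 3))
  W <- withr::with_seed(2, lapply(1:3, function(j) matrix(rnorm(9), 3, 3)))
  out <- propagate_layer(H, Ahat, W)

  perm <- withr::with_seed(3, sample.int(n))
  P <- eye(n)[perm, ]
  out_perm <- propagate_layer(
    H[perm, , drop = FALSE],
    as.matrix(Ahat)[perm, perm],
    W
  )
  expect_equal(out_perm, out[perm, , drop = FALSE])
})

test_that("propagation preserves constant features on regular graphs", {
  # 5-cycle is 2-regular
  cyc <- as_interactome(tibble::tibble(
    from = c("A", "B", "C", "D", "A"), to = c("B", "C", "D", "E", "E")
  ))
  Ahat <- symmetric_normalize(cyc)
  H <- matrix(1, 5, 2)
  out <- propagate_layer(H, Ahat, list(eye(2), eye(2), eye(2)))
  expect_equal(unname(out), matrix(3, 5, 2)) # each order contributes the constant
})

test_that("propagation validates dimensions with informative errors", {
  g <- as_interactome(tibble::tibble(from = "A", to = "B"))
  Ahat <- symmetric_normalize(g)
  expect_error(
    propagate_layer(matrix(0, 3, 1), Ahat, list(eye(1), eye(1), eye(1))),
    "rows"
  )
  expect_error(
    propagate_layer(matrix(0, 2, 2), Ahat, list(eye(1), eye(1), eye(1))),
    "W\\[\\[1\\]\\]"
  )
  expect_error(propagate_layer(matrix(0, 2, 1), Ahat, list(eye(1))), "three")
})

test_that("jumping-knowledge concatenation stacks layer widths in order", {
  layers <- list(matrix(1, 5, 4), matrix(2, 5, 4), matrix(3, 5, 2))
  out <- jk_concat(layers)
  expect_equal(dim(out), c(5L, 10L))
  expect_equal(out[, 1:4], layers[[1]])
  expect_equal(out[, 9:10], layers[[3]])
  expect_equal(jk_concat(layers[1]), layers[[1]])
  expect_error(jk_concat(list(matrix(0, 5, 2), matrix(0, 4, 2))), "row")
})

test_that("module training recovers planted partitions", {
  spec <- fixture_spec(seed = 1)
  net <- generate_interactome(spec)
  lcc <- extract_lcc(net$graph)
  fit <- train_modules(lcc, K = 2, seed = 1)
  truth <- setNames(net$labels$module, net$labels$gene)
  expect_gte(adjusted_rand_index(fit$labels, truth), 0.9)
  expect_equal(unname(rowSums(fit$membership)), rep(1, length(lcc$nodes)),
    tolerance = 1e-9)
})

test_that("two cliques joined by one edge are separated at K = 2", {
  clique <- function(nodes) {
    p <- t(combn(nodes, 2))
    tibble::tibble(from = p[, 1], to = p[, 2])
  }
  g <- as_interactome(dplyr::bind_rows(
    clique(sprintf("A%02d", 1:8)),
    clique(sprintf("B%02d", 1:8)),
    tibble::tibble(from = "A01", to = "B01")
  ))
  fit <- train_modules(g, K = 2, seed = 3)
  labs <- fit$labels
  expect_equal(length(unique(labs[startsWith(names(labs), "A")])), 1L)
  expect_equal(length(unique(labs[startsWith(names(labs), "B")])), 1L)
  expect_false(labs[["A01"]] == labs[["B01"]])
})

test_that("training is deterministic for a fixed seed and validates K", {
  g <- random_connected_interactome(20, 0.25, 5)
  f1 <- train_modules(g, K = 3, seed = 9, epochs = 40)
  f2 <- train_modules(g, K = 3, seed = 9, epochs = 40)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$loss_trace, f2$loss_trace)

  expect_error(train_modules(g, K = 1, seed = 1), "at least 2")
  expect_error(train_modules(g, K = 1000, seed = 1), "exceeds")
  two <- as_interactome(tibble::tibble(from = c("A", "C"), to = c("B", "D")))
  expect_error(train_modules(two, K = 2, seed = 1), "connected")
})

test_that("tidy and glance summarize a module fit", {
  g <- random_connected_interactome(15, 0.3, 8)
  fit <- train_modules(g, K = 2, seed = 2, epochs = 30)
  td <- tidy(fit)
  expect_equal(nrow(td), length(g$nodes))
  expect_true(all(td$probability >= 1 / fit$K))
  gl <- glance(fit)
  expect_equal(gl$n_nodes, length(g$nodes))
  expect_equal(gl$k, 2L)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_lt(abs(adjusted_rand_index(
    rep(1:2, 50),
    withr::with_seed(1, sample(rep(1:2, 50)))
  )), 0.2)
})
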