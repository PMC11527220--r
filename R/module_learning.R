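# Self-supervised graph module learning.
#
# The model propagates node features through 0th-, 1st- and 2nd-order
# neighborhoods of the symmetrically normalized adjacency,
#
#   H^(i+1) = ReLU( sum_{j=0..2} Ahat^j H^(i) W_j^(i) ),    Ahat^0 = I,
#
# concatenates all layer representations (jumping knowledge), and reads a
# soft module assignment off a softmax head. Training maximizes the soft
# modularity of the assignment plus an adjacency-reconstruction term, so the
# whole procedure is supervised by the graph alone. Backpropagation is
# implemented directly on the dense linear algebra; graphs at this scale do
# not need an autodiff framework.

#' One multi-order propagation layer
#'
#' Computes \eqn{H' = \mathrm{ReLU}(\sum_{j=0}^{2} \hat A^j H W_j)} where
#' \eqn{\hat A^0} is the identity, so every node aggregates its own features
#' together with those of its first- and second-order neighborhoods.
#'
#' @param H Numeric matrix of node representations (nodes x d_in).
#' @param A_norm Symmetrically normalized adjacency from
#'   [symmetric_normalize()].
#' @param W List of exactly three weight matrices (d_in x d_out), one per
#'   neighbor order 0, 1, 2.
#' @return Numeric matrix (nodes x d_out), entrywise nonnegative.
#' @export
propagate_layer <- function(H, A_norm, W) {
  H <- as.matrix(H)
  if (!is.list(W) || length(W) != 3L) {
    abort("W must be a list of three weight matrices (orders 0, 1, 2)")
  }
  if (nrow(H) != nrow(A_norm)) {
    abort(sprintf(
      "H has %d rows but A_norm has %d: node dimensions do not match",
      nrow(H), nrow(A_norm)
    ))
  }
  for (j in 1:3) {
    if (ncol(H) != nrow(W[[j]])) {
      abort(sprintf(
        "W[[%d]] has %d rows but H has %d columns", j, nrow(W[[j]]), ncol(H)
      ))
    }
  }
  S1 <- as.matrix(A_norm %*% H)
  S2 <- as.matrix(A_norm %*% S1)
  Z <- H %*% W[[1]] + S1 %*% W[[2]] + S2 %*% W[[3]]
  pmax(Z, 0)
}

#' Jumping-knowledge concatenation
#'
#' Concatenates per-layer node representations column-wise,
#' \eqn{\bar H^{(L)} = H^{(1)} \| \cdots \| H^{(L)}}, so each node's final
#' representation draws on all neighborhood radii reached during propagation.
#'
#' @param layers List of numeric matrices with identical row counts.
#' @return A single matrix whose width is the sum of the layer widths.
#' @export
jk_concat <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1L)
  n <- vapply(layers, nrow, integer(1))
  if (length(unique(n)) != 1L) {
    abort(sprintf(
      "layer row counts differ: %s", paste(unique(n), collapse = " vs ")
    ))
  }
  do.call(cbind, lapply(layers, as.matrix))
}

row_softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Soft modularity of assignment P on adjacency A:
#   Q = (1/2m) * [ tr(P' A P) - |d' P|^2 / 2m ]
soft_modularity <- function(P, A, d = Matrix::rowSums(A),
                            two_m = sum(d)) {
  AP <- as.matrix(A %*% P)
  dp <- as.vector(crossprod(P, d))
  (sum(P * AP) - sum(dp^2) / two_m) / two_m
}

glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -s, s), n_in, n_out)
}

adam_step <- function(state, grad, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  mh <- state$m / (1 - b1^state$t)
  vh <- state$v / (1 - b2^state$t)
  state$value <- state$value - lr * mh / (sqrt(vh) + eps)
  state
}

new_adam <- function(W) list(value = W, m = W * 0, v = W * 0, t = 0)

#' Learn functional network modules by self-supervision
#'
#' Trains the two-layer multi-order propagation model with jumping knowledge
#' on a connected interactome and returns a soft partition of its nodes into
#' `K` modules. The objective is
#' \deqn{\mathcal{L} = -Q_{soft}(P, A) + \lambda\,\mathrm{BCE}(\sigma(ZZ^T), A)
#'   + \gamma\,\left(\frac{\sqrt K}{n}\bigl\lVert\textstyle\sum_i P_i\bigr\rVert_2 - 1\right)}
#' where \eqn{P} is the softmax module assignment, \eqn{Q_{soft}} the soft
#' modularity, the second term scores reconstruction of sampled edges and
#' non-edges from a linear embedding head \eqn{Z}, and the third is a
#' collapse regularizer (zero for perfectly balanced assignments, maximal
#' when all mass lands in one module) that keeps the head from merging
#' separable modules -- plain modularity objectives have degenerate optima
#' in which pairs of blocks fuse. All terms are computable
#' from the graph alone. All randomness (weight initialization, input feature
#' projection, non-edge sampling) is consumed from the single `seed`, so a
#' fixed seed gives bit-identical results.
#'
#' @param g A connected `interactome` (run [extract_lcc()] first).
#' @param K Number of modules (at least 2, at most the node count).
#' @param seed Integer RNG seed.
#' @param epochs Number of full-batch training epochs.
#' @param lr Adam learning rate.
#' @param lambda Weight of the reconstruction term.
#' @param gamma Weight of the collapse regularizer.
#' @param dims Hidden widths of the two propagation layers.
#' @param embed_dim Width of the reconstruction embedding head.
#' @param feature_width Width of the Gaussian random projection used as input
#'   features when the graph has more than `max_onehot` nodes; smaller graphs
#'   use one-hot node identity.
#' @param max_onehot Node-count threshold below which one-hot features are
#'   used.
#' @param max_edge_sample Per-epoch cap on sampled edges (an equal number of
#'   non-edges is drawn).
#' @return An object of class `module_fit` with elements `membership` (nodes
#'   x K soft assignment, rows summing to 1), `labels` (named hard
#'   assignment), `modularity` (soft modularity of the final assignment),
#'   `loss_trace`, and the fitted weights.
#' @export
train_modules <- function(g, K, seed = 1L, epochs = 200L, lr = 1e-3,
                          lambda = 1, gamma = 1, dims = c(32L, 16L),
                          embed_dim = 16L,
                          feature_width = 128L, max_onehot = 256L,
                          max_edge_sample = 2000L) {
  stopifnot(inherits(g, "interactome"))
  n <- length(g$nodes)
  if (K < 2) abort("K must be at least 2")
  if (K > n) abort(sprintf("K = %d exceeds the node count %d", K, n))
  if (igraph::components(g$graph)$no != 1L) {
    abort("graph must be connected; extract the LCC first")
  }

  A <- adjacency(g)
  Ahat <- symmetric_normalize(g)
  d <- Matrix::rowSums(A)
  two_m <- sum(d)
  edge_idx <- cbind(
    match(g$edges$from, g$nodes),
    match(g$edges$to, g$nodes)
  )

  with_seed(seed, {
    X <- if (n <= max_onehot) {
      diag(n)
    } else {
      matrix(rnorm(n * feature_width) / sqrt(feature_width), n, feature_width)
    }
    d0 <- ncol(X)
    d1 <- dims[1]
    d2 <- dims[2]
    dj <- d1 + d2

    params <- list(
      W1 = lapply(1:3, function(j) glorot(d0, d1)),
      W2 = lapply(1:3, function(j) glorot(d1, d2)),
      Wp = glorot(dj, K),
      bp = matrix(0, 1, K),
      Wz = glorot(dj, embed_dim)
    )
    opt <- rapply(params, new_adam, how = "replace", classes = "matrix")

    get_par <- function() rapply(opt, function(s) s$value,
      how = "replace", classes = "ANY"
    )

    relu_fwd <- function(Xin, W) {
      S1 <- as.matrix(Ahat %*% Xin)
      S2 <- as.matrix(Ahat %*% S1)
      U <- Xin %*% W[[1]] + S1 %*% W[[2]] + S2 %*% W[[3]]
      list(H = pmax(U, 0), mask = U > 0, S = list(Xin, S1, S2))
    }

    loss_trace <- numeric(epochs)
    n_e <- nrow(edge_idx)

    for (ep in seq_len(epochs)) {
      W1 <- lapply(opt$W1, function(s) s$value)
      W2 <- lapply(opt$W2, function(s) s$value)
      Wp <- opt$Wp$value
      bp <- opt$bp$value
      Wz <- opt$Wz$value

      f1 <- relu_fwd(X, W1)
      f2 <- relu_fwd(f1$H, W2)
      HJ <- cbind(f1$H, f2$H)
      logits <- sweep(HJ %*% Wp, 2, -as.vector(bp))
      P <- row_softmax(logits)
      Z <- HJ %*% Wz

      # --- modularity term ---
      AP <- as.matrix(A %*% P)
      dp <- as.vector(crossprod(P, d))
      Q <- (sum(P * AP) - sum(dp^2) / two_m) / two_m
      GP <- -(2 * AP - 2 * outer(d, dp) / two_m) / two_m # d(-Q)/dP

      # --- collapse regularizer ---
      csum <- colSums(P)
      cnorm <- sqrt(sum(csum^2))
      col_loss <- sqrt(K) / n * cnorm - 1
      GP <- GP + gamma * sqrt(K) / n *
        matrix(csum / cnorm, n, K, byrow = TRUE)

      # --- reconstruction term on sampled edges / non-edges ---
      if (n_e > max_edge_sample) {
        take <- sample.int(n_e, max_edge_sample)
      } else {
        take <- seq_len(n_e)
      }
      pos <- edge_idx[take, , drop = FALSE]
      neg <- cbind(
        sample.int(n, length(take), replace = TRUE),
        sample.int(n, length(take), replace = TRUE)
      )
      keep <- neg[, 1] != neg[, 2] & A[neg] == 0
      neg <- neg[keep, , drop = FALSE]
      pairs <- rbind(pos, neg)
      y <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
      s <- rowSums(Z[pairs[, 1], , drop = FALSE] *
        Z[pairs[, 2], , drop = FALSE])
      pr <- 1 / (1 + exp(-s))
      eps <- 1e-12
      bce <- -mean(y * log(pr + eps) + (1 - y) * log(1 - pr + eps))
      gpair <- lambda * (pr - y) / length(y)
      Gmat <- sparseMatrix(
        i = pairs[, 1], j = pairs[, 2], x = gpair, dims = c(n, n)
      )
      GZ <- as.matrix(Gmat %*% Z + Matrix::t(Gmat) %*% Z)

      loss_trace[ep] <- -Q + lambda * bce + gamma * col_loss

      # --- backward ---
      Glogit <- P * (GP - rowSums(GP * P))
      gWp <- crossprod(HJ, Glogit)
      gbp <- matrix(colSums(Glogit), 1, K)
      gWz <- crossprod(HJ, GZ)
      GHJ <- Glogit %*% t(Wp) + GZ %*% t(Wz)

      GH2 <- GHJ[, (d1 + 1):dj, drop = FALSE]
      D2 <- GH2 * f2$mask
      gW2 <- lapply(1:3, function(j) crossprod(f2$S[[j]], D2))
      GH1 <- GHJ[, 1:d1, drop = FALSE] +
        D2 %*% t(W2[[1]]) +
        as.matrix(Ahat %*% (D2 %*% t(W2[[2]]))) +
        as.matrix(Ahat %*% as.matrix(Ahat %*% (D2 %*% t(W2[[3]]))))
      D1 <- GH1 * f1$mask
      gW1 <- lapply(1:3, function(j) crossprod(f1$S[[j]], D1))

      for (j in 1:3) {
        opt$W1[[j]] <- adam_step(opt$W1[[j]], gW1[[j]], lr)
        opt$W2[[j]] <- adam_step(opt$W2[[j]], gW2[[j]], lr)
      }
      opt$Wp <- adam_step(opt$Wp, gWp, lr)
      opt$bp <- adam_step(opt$bp, gbp, lr)
      opt$Wz <- adam_step(opt$Wz, gWz, lr)
    }

    # final forward pass with trained weights
    W1 <- lapply(opt$W1, function(s) s$value)
    W2 <- lapply(opt$W2, function(s) s$value)
    f1 <- relu_fwd(X, W1)
    f2 <- relu_fwd(f1$H, W2)
    HJ <- cbind(f1$H, f2$H)
    logits <- sweep(HJ %*% opt$Wp$value, 2, -as.vector(opt$bp$value))
    P <- row_softmax(logits)
    rownames(P) <- g$nodes

    structure(
      list(
        membership = P,
        labels = setNames(max.col(P, ties.method = "first"), g$nodes),
        K = K,
        seed = seed,
        modularity = soft_modularity(P, A, d, two_m),
        loss_trace = loss_trace,
        weights = list(
          W1 = W1, W2 = W2,
          Wp = opt$Wp$value, bp = opt$bp$value, Wz = opt$Wz$value
        ),
        nodes = g$nodes
      ),
      class = "module_fit"
    )
  })
}

#' @export
print.module_fit <- function(x, ...) {
  cat(sprintf(
    "<module_fit> %d nodes, K = %d, soft modularity = %.4f (seed %d)\n",
    length(x$nodes), x$K, x$modularity, x$seed
  ))
  occ <- table(x$labels)
  cat(sprintf(
    "  occupied modules: %d; largest module: %d nodes\n",
    length(occ), max(occ)
  ))
  invisible(x)
}

#' @describeIn train_modules Tidy the soft module assignment into one row per
#'   node with its hard label and membership probability.
#' @param x A `module_fit`.
#' @param ... Unused.
#' @method tidy module_fit
#' @export
tidy.module_fit <- function(x, ...) {
  tibble(
    gene = x$nodes,
    module = unname(x$labels),
    probability = x$membership[cbind(seq_along(x$nodes), x$labels)]
  )
}

#' @describeIn train_modules One-row model summary.
#' @method glance module_fit
#' @export
glance.module_fit <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    k = x$K,
    n_occupied = length(unique(x$labels)),
    soft_modularity = x$modularity,
    final_loss = x$loss_trace[length(x$loss_trace)],
    seed = x$seed
  )
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-invariant agreement between a predicted partition and a
#' reference partition; 1 for identical partitions, about 0 for independent
#' ones.
#'
#' @param a,b Vectors of cluster labels of equal length (matched by names
#'   when both are named).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    b <- b[names(a)]
  }
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) {
    return(ifelse(sum_ij == maxi, 1, 0))
  }
  (sum_ij - expected) / (maxi - expected)
}
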