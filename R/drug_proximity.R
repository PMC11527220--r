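# Network-proximity drug screening with a degree-preserving permutation null.
#
# The closest distance between a disease protein set S and a drug target set
# T is d(S,T) = (1/|T|) * sum_{t in T} min_{s in S} sp(s,t) on the unweighted
# interactome. Significance is a Z score against distances of degree-matched
# random (S', T') pairs, which discounts the literature bias of well-studied
# hub proteins.

#' Closest network distance between disease proteins and drug targets
#'
#' \eqn{d(S,T) = \frac{1}{|T|}\sum_{t\in T}\min_{s\in S} sp(s,t)} with
#' `sp` the unweighted shortest-path length; a target that is itself a
#' disease protein contributes 0. Both sets are intersected with the graph
#' first; if either becomes empty the pair is unscorable and `NA` is
#' returned (with a `reason` attribute) rather than an error, so drug screens
#' can skip such drugs gracefully.
#'
#' @param g An `interactome` (use the LCC so all pairs are reachable).
#' @param S Character vector of disease protein symbols.
#' @param T_set Character vector of drug target symbols.
#' @param dist_matrix Optional precomputed all-pairs distance matrix (rows
#'   and columns named by gene); supplying one makes repeated calls on the
#'   same graph much faster.
#' @return The mean closest distance, or `NA_real_` if unscorable.
#' @export
closest_distance <- function(g, S, T_set, dist_matrix = NULL) {
  S <- intersect(normalize_symbols(S), g$nodes)
  T_set <- intersect(normalize_symbols(T_set), g$nodes)
  if (length(S) == 0 || length(T_set) == 0) {
    return(structure(NA_real_, reason = "empty set after network intersection"))
  }
  if (!is.null(dist_matrix)) {
    D <- dist_matrix[T_set, S, drop = FALSE]
  } else {
    D <- igraph::distances(g$graph, v = T_set, to = S)
  }
  mean(apply(D, 1, min))
}

# Degree bins with at least min_bin members each: walk the nodes in degree
# order and close a bin as soon as it holds min_bin nodes (the final bin is
# merged backwards if short). On graphs with fewer than 2*min_bin nodes this
# degenerates to a single bin, i.e. uniform sampling.
degree_bins <- function(degrees, min_bin = 20L) {
  ord <- order(degrees, names(degrees), method = "radix")
  n <- length(degrees)
  bin <- integer(n)
  current <- 1L
  count <- 0L
  for (i in seq_len(n)) {
    bin[ord[i]] <- current
    count <- count + 1L
    at_degree_boundary <- i == n || degrees[ord[i + 1]] != degrees[ord[i]]
    if (count >= min_bin && at_degree_boundary && i < n) {
      current <- current + 1L
      count <- 0L
    }
  }
  # merge a short trailing bin into its predecessor
  if (count < min_bin && current > 1L) {
    bin[bin == current] <- current - 1L
  }
  setNames(bin, names(degrees))
}

#' Sample a degree-matched random node set
#'
#' Returns a node set of the same size as `node_set`, drawn uniformly
#' without replacement within degree bins: for each bin, as many random
#' nodes are drawn from it as `node_set` has members there. Bins are
#' contiguous degree ranges guaranteed to hold at least `min_bin` nodes
#' (short bins are widened to neighboring degrees), so matching is always
#' feasible; on small graphs this collapses to uniform sampling.
#'
#' Consumes the current RNG stream; seed upstream for reproducibility.
#'
#' @param g An `interactome`.
#' @param node_set Character vector of node names, subset of the graph.
#' @param min_bin Minimum bin occupancy (default 20).
#' @return Character vector of sampled node names, same length as
#'   `node_set`.
#' @export
sample_degree_matched <- function(g, node_set, min_bin = 20L) {
  node_set <- intersect(normalize_symbols(node_set), g$nodes)
  stopifnot(length(node_set) > 0)
  make_degree_sampler(g, min_bin)(node_set)
}

# Precompute the degree-bin structure once and return a fast sampling
# closure; proximity_z draws hundreds of thousands of sets from it.
make_degree_sampler <- function(g, min_bin = 20L) {
  bins <- degree_bins(node_degrees(g), min_bin)
  members <- split(names(bins), bins)
  function(node_set) {
    need <- table(bins[node_set])
    unlist(
      lapply(names(need), function(b) sample(members[[b]], need[[b]])),
      use.names = FALSE
    )
  }
}

# min over rows of a small dense matrix, column-wise pmin
row_mins <- function(M) {
  do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
}

#' Permutation Z score of network proximity
#'
#' Recomputes [closest_distance()] for `n_perm` degree-matched random
#' replacements of both the disease set and the target set;
#' \eqn{Z = (d_{obs} - \mu)/\sigma} with \eqn{\mu,\sigma} the permutation
#' mean and standard deviation. Both the normal-theory one-sided p (from Z)
#' and the empirical p \eqn{(1 + \#\{d_{perm} \le d_{obs}\})/(n_{perm}+1)}
#' are reported. A fixed seed gives bit-identical results.
#'
#' @inheritParams closest_distance
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed.
#' @param min_bin Degree-bin occupancy for the matched sampler.
#' @param cache_threshold Precompute the full all-pairs distance matrix when
#'   the graph has at most this many nodes (a large speedup for repeated
#'   permutation distances).
#' @return A `proximity_result` list: `distance`, `mu`, `sigma`, `z`,
#'   `p_normal`, `p_empirical`, `n_perm`, `flagged` (TRUE when Z is
#'   undefined or the pair unscorable) and the permuted distances.
#' @export
proximity_z <- function(g, S, T_set, n_perm = 1000L, seed = 1L,
                        min_bin = 20L, cache_threshold = 2000L,
                        dist_matrix = NULL) {
  if (is.null(dist_matrix) && length(g$nodes) <= cache_threshold) {
    dist_matrix <- igraph::distances(g$graph)
  }
  d_obs <- closest_distance(g, S, T_set, dist_matrix)
  if (is.na(d_obs)) {
    return(structure(
      list(
        distance = NA_real_, mu = NA_real_, sigma = NA_real_, z = NA_real_,
        p_normal = NA_real_, p_empirical = NA_real_, n_perm = n_perm,
        flagged = TRUE, reason = attr(d_obs, "reason"),
        perm_distances = numeric(0)
      ),
      class = "proximity_result"
    ))
  }
  S_in <- intersect(normalize_symbols(S), g$nodes)
  T_in <- intersect(normalize_symbols(T_set), g$nodes)
  sampler <- make_degree_sampler(g, min_bin)
  perm_dist <- if (!is.null(dist_matrix)) {
    function(Sp, Tp) mean(row_mins(dist_matrix[Tp, Sp, drop = FALSE]))
  } else {
    function(Sp, Tp) {
      mean(row_mins(igraph::distances(g$graph, v = Tp, to = Sp)))
    }
  }
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      perm_dist(sampler(S_in), sampler(T_in))
    }, numeric(1))
  })
  mu <- mean(perm)
  sigma <- sd(perm)
  z <- if (sigma > 0) (d_obs - mu) / sigma else NA_real_
  structure(
    list(
      distance = d_obs,
      mu = mu,
      sigma = sigma,
      z = z,
      p_normal = if (is.na(z)) NA_real_ else pnorm(z),
      p_empirical = (1 + sum(perm <= d_obs)) / (n_perm + 1),
      n_perm = n_perm,
      flagged = is.na(z),
      reason = if (is.na(z)) "zero permutation variance" else NA_character_,
      perm_distances = perm
    ),
    class = "proximity_result"
  )
}

#' @export
print.proximity_result <- function(x, ...) {
  if (is.na(x$distance)) {
    cat(sprintf("<proximity_result> unscorable (%s)\n", x$reason))
  } else {
    cat(sprintf(
      "<proximity_result> d = %.3f, null %.3f +/- %.3f, Z = %.2f, p = %.3g (%d perms)\n",
      x$distance, x$mu, x$sigma, x$z, x$p_normal, x$n_perm
    ))
  }
  invisible(x)
}

#' @describeIn proximity_z One-row tibble of the proximity statistics.
#' @param x A `proximity_result`.
#' @param ... Unused.
#' @method tidy proximity_result
#' @export
tidy.proximity_result <- function(x, ...) {
  tibble(
    distance = x$distance, mu = x$mu, sigma = x$sigma, z = x$z,
    p_normal = x$p_normal, p_empirical = x$p_empirical,
    n_perm = x$n_perm, flagged = x$flagged
  )
}

#' Proximity screen of a drug-target table against a disease module
#'
#' Runs [proximity_z()] for every drug in the table. Each drug consumes an
#' RNG substream derived from the master seed and the drug id by stable
#' hashing, so results are reproducible drug-by-drug and independent of
#' screening order.
#'
#' @param g An `interactome` (the LCC).
#' @param disease_genes Character vector of disease proteins.
#' @param drug_targets Tibble with columns `drug_id`, `target` and
#'   optionally `drug_name`, `atc_codes`, `approved`.
#' @param n_perm Permutations per drug.
#' @param seed Master seed.
#' @param min_bin Degree-bin occupancy.
#' @return A `proximity_screen` tibble: one row per drug with distance,
#'   permutation null, `z`, both p-values and pass-through metadata.
#' @export
proximity_screen <- function(g, disease_genes, drug_targets, n_perm = 1000L,
                             seed = 1L, min_bin = 20L) {
  assert_cols(drug_targets, c("drug_id", "target"), "drug-target table")
  dist_matrix <- if (length(g$nodes) <= 2000L) {
    igraph::distances(g$graph)
  } else {
    NULL
  }
  meta_cols <- intersect(
    c("drug_name", "atc_codes", "approved"), names(drug_targets)
  )
  drugs <- drug_targets |>
    group_by(.data$drug_id) |>
    summarise(
      targets = list(unique(.data$target)),
      across(all_of(meta_cols), ~ .x[1]),
      .groups = "drop"
    )
  rows <- purrr::pmap(drugs, function(drug_id, targets, ...) {
    res <- proximity_z(
      g, disease_genes, targets,
      n_perm = n_perm,
      seed = derive_seed(seed, drug_id),
      min_bin = min_bin,
      dist_matrix = dist_matrix
    )
    bind_cols(
      tibble(drug_id = drug_id, n_targets = length(
        intersect(normalize_symbols(targets), g$nodes)
      )),
      tidy(res),
      tibble(...)[meta_cols]
    )
  })
  out <- bind_rows(rows) |> arrange(.data$z)
  class(out) <- c("proximity_screen", class(out))
  out
}

#' Screen proximity results for repurposing candidates
#'
#' Keeps approved drugs with a strongly significant proximity signal
#' (default Z < -3 and one-sided p < 0.05), ranked by ascending Z.
#'
#' @param results A `proximity_screen` tibble (needs `z`, `p_normal` and
#'   `approved` columns).
#' @param z_max Strict upper bound on Z (default -3).
#' @param p_max Strict upper bound on the one-sided normal p (default 0.05).
#' @param approved_only Keep only approved drugs (default TRUE).
#' @return Filtered tibble ordered by ascending Z.
#' @export
screen_drugs <- function(results, z_max = -3, p_max = 0.05,
                         approved_only = TRUE) {
  assert_cols(results, c("z", "p_normal"), "proximity results")
  out <- results |>
    filter(!is.na(.data$z), .data$z < z_max, .data$p_normal < p_max)
  if (approved_only) {
    assert_cols(results, "approved", "proximity results")
    out <- out |> filter(as.logical(.data$approved))
  }
  out |> arrange(.data$z)
}
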