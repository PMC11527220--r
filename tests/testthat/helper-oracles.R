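# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive (flood fill, Floyd-Warshall, nested loops,
# explicit enumeration) and share no code with the package internals.

write_edge_file <- function(rows, header = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  lines <- vapply(rows, paste, character(1), collapse = "\t")
  if (!is.null(header)) lines <- c(paste(header, collapse = "\t"), lines)
  writeLines(lines, path)
  path
}

random_edge_rows <- function(n_rows, n_nodes, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n_rows), function(i) {
      sample(sprintf("N%03d", seq_len(n_nodes)), 2)
    })
  })
}

# Hash-set recount of nodes and canonical undirected edges.
oracle_edge_count <- function(rows) {
  seen <- new.env(hash = TRUE)
  nodes <- new.env(hash = TRUE)
  for (r in rows) {
    a <- toupper(trimws(r[1]))
    b <- toupper(trimws(r[2]))
    if (a == b) next
    key <- paste(min(a, b), max(a, b), sep = "|")
    assign(key, TRUE, envir = seen)
    assign(a, TRUE, envir = nodes)
    assign(b, TRUE, envir = nodes)
  }
  list(n_nodes = length(ls(nodes)), n_edges = length(ls(seen)))
}

# BFS flood fill over an edge tibble; returns list of components (sorted).
oracle_components <- function(edges) {
  adj <- list()
  add <- function(a, b) adj[[a]] <<- c(adj[[a]], b)
  for (i in seq_len(nrow(edges))) {
    add(edges$from[i], edges$to[i])
    add(edges$to[i], edges$from[i])
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  seen <- character(0)
  comps <- list()
  for (start in nodes) {
    if (start %in% seen) next
    queue <- start
    comp <- character(0)
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (v %in% comp) next
      comp <- c(comp, v)
      queue <- c(queue, setdiff(adj[[v]], comp))
    }
    seen <- c(seen, comp)
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# Floyd-Warshall all-pairs shortest paths on an interactome (small n only).
oracle_floyd_warshall <- function(g) {
  n <- length(g$nodes)
  D <- matrix(Inf, n, n, dimnames = list(g$nodes, g$nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(g$edges))) {
    a <- g$edges$from[i]
    b <- g$edges$to[i]
    D[a, b] <- 1
    D[b, a] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_closest_distance <- function(D, S, T_set) {
  mean(vapply(T_set, function(t) min(D[t, S]), numeric(1)))
}

# Exhaustive one-sided hypergeometric tail by explicit choose() sums.
oracle_hyper_tail <- function(overlap, n_hits, n_anno, n_bg) {
  ks <- overlap:min(n_hits, n_anno)
  sum(choose(n_anno, ks) * choose(n_bg - n_anno, n_hits - ks)) /
    choose(n_bg, n_hits)
}

# Pairwise AUROC with half-credit ties.
oracle_auroc <- function(pos, neg) {
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Independent greedy clumping on plain vectors.
oracle_clump <- function(snp, chrom, pos, p, ld_pairs, r2_cutoff, window) {
  r2_of <- function(a, b) {
    hit <- (ld_pairs$snp_a == a & ld_pairs$snp_b == b) |
      (ld_pairs$snp_a == b & ld_pairs$snp_b == a)
    if (any(hit)) ld_pairs$r2[hit][1] else 0
  }
  leads <- character(0)
  alive <- rep(TRUE, length(snp))
  repeat {
    if (!any(alive)) break
    cand <- which(alive)
    best <- cand[order(p[cand], chrom[cand], pos[cand])][1]
    leads <- c(leads, snp[best])
    alive[best] <- FALSE
    for (i in which(alive)) {
      if (chrom[i] == chrom[best] && abs(pos[i] - pos[best]) <= window &&
        r2_of(snp[i], snp[best]) > r2_cutoff) {
        alive[i] <- FALSE
      }
    }
  }
  leads
}

random_connected_interactome <- function(n, p, seed) {
  withr::with_seed(seed, {
    repeat {
      pairs <- t(combn(n, 2))
      keep <- runif(nrow(pairs)) < p
      if (sum(keep) == 0) next
      nm <- sprintf("V%02d", seq_len(n))
      g <- as_interactome(tibble::tibble(
        from = nm[pairs[keep, 1]], to = nm[pairs[keep, 2]]
      ))
      lcc <- extract_lcc(g)
      if (length(lcc$nodes) >= max(4, n * 0.6)) {
        return(lcc)
      }
    }
  })
}
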