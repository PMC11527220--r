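# From network modules plus regulatory evidence genes to per-gene risk
# scores, seed ensembling, benchmark AUROC and risk-gene calls.

#' Score genes by module-level concentration of regulatory evidence
#'
#' For soft module assignment \eqn{P} and an evidence gene set \eqn{E}, each
#' module's evidence concentration is
#' \eqn{e(m) = \sum_{v \in E} P(v \in m) / \sum_{v} P(v \in m)}, the fraction
#' of the module's total membership mass carried by evidence genes. A gene's
#' raw score is its membership-weighted average concentration,
#' \eqn{s(g) = \sum_m P(g \in m)\,e(m)}; genes sharing modules with many
#' evidence genes score high regardless of whether they carry direct evidence
#' themselves.
#'
#' @param fit A `module_fit` from [train_modules()], or a soft membership
#'   matrix with gene rownames.
#' @param evidence Character vector of evidence (e.g. QTL-regulated) gene
#'   symbols.
#' @return A tibble with columns `gene` and `score` (nonnegative).
#' @export
score_genes <- function(fit, evidence) {
  P <- if (inherits(fit, "module_fit")) fit$membership else as.matrix(fit)
  if (is.null(rownames(P))) abort("membership matrix must have gene rownames")
  evidence <- normalize_symbols(evidence)
  hit <- rownames(P) %in% evidence
  if (!any(hit)) {
    warn("no evidence genes present in the graph; all scores are zero")
    return(tibble(gene = rownames(P), score = 0))
  }
  mass <- colSums(P)
  e_m <- colSums(P[hit, , drop = FALSE]) / mass
  tibble(gene = rownames(P), score = as.vector(P %*% e_m))
}

#' Ensemble per-seed gene scores into a standardized score table
#'
#' Raw scores from each seed are min-max scaled to `[0, 1]` (so no single
#' seed dominates the average), averaged per gene, and the ensemble score is
#' standardized to a Z score across genes.
#'
#' @param tables List of per-seed score tibbles from [score_genes()], all
#'   over the identical gene universe.
#' @return A `gene_score_table` tibble with columns `gene`,
#'   `score_s1..score_sN`, `ensemble`, `z` and `rank` (1 = highest Z).
#' @export
ensemble_scores <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  universes <- lapply(tables, function(t) sort(t$gene))
  ref <- universes[[1]]
  for (i in seq_along(universes)) {
    if (!identical(universes[[i]], ref)) {
      extra <- union(
        setdiff(universes[[i]], ref),
        setdiff(ref, universes[[i]])
      )
      abort(sprintf(
        "gene universes differ between seed tables; symmetric difference: %s",
        paste(head(extra, 10), collapse = ", ")
      ))
    }
  }
  minmax <- function(x) {
    r <- range(x)
    if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else rep(0, length(x))
  }
  mat <- vapply(
    tables,
    function(t) minmax(t$score[match(ref, t$gene)]),
    numeric(length(ref))
  )
  mat <- matrix(mat, nrow = length(ref))
  colnames(mat) <- paste0("score_s", seq_along(tables))
  ens <- rowMeans(mat)
  # population-sd standardization so that e.g. two genes map exactly to +/-1
  sd_pop <- sqrt(mean((ens - mean(ens))^2))
  z <- if (sd_pop > 0) (ens - mean(ens)) / sd_pop else rep(0, length(ens))
  out <- bind_cols(
    tibble(gene = ref),
    as_tibble(mat),
    tibble(
      ensemble = ens,
      z = z,
      rank = rank(-z, ties.method = "min")
    )
  ) |>
    arrange(.data$rank)
  class(out) <- c("gene_score_table", class(out))
  out
}

#' Area under the ROC curve of gene scores against a benchmark set
#'
#' The AUROC is computed as the probability that a randomly chosen benchmark
#' (positive) gene outscores a randomly chosen non-benchmark gene, with ties
#' counted one half -- the Mann-Whitney formulation over all
#' positive-negative pairs. The benchmark is intersected with the scored
#' universe first; genes missing from it are dropped with a message.
#'
#' @param scores A `gene_score_table`, or any tibble with `gene` and a score
#'   column, or a named numeric vector.
#' @param bench Character vector of benchmark positive gene symbols.
#' @param score_col Which column to rank by (default the ensemble Z).
#' @return AUROC in `[0, 1]`.
#' @export
evaluate_auroc <- function(scores, bench, score_col = "z") {
  if (is.numeric(scores) && !is.null(names(scores))) {
    s <- scores
  } else {
    assert_cols(scores, c("gene", score_col), "score table")
    s <- setNames(scores[[score_col]], scores$gene)
  }
  bench <- normalize_symbols(bench)
  dropped <- setdiff(bench, names(s))
  if (length(dropped) > 0) {
    inform(sprintf(
      "%d benchmark gene(s) absent from the scored universe were dropped",
      length(dropped)
    ))
  }
  pos <- names(s) %in% bench
  if (!any(pos)) abort("no benchmark genes in the scored universe")
  if (all(pos)) abort("every scored gene is a benchmark positive; AUROC undefined")
  r <- rank(s, ties.method = "average")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Call risk genes from the standardized ensemble score
#'
#' @param scores A `gene_score_table`.
#' @param z_cutoff Minimum Z score (default 1.645, the one-sided 5% point of
#'   the normal).
#' @param top_n If given, ignore `z_cutoff` and take the `top_n` highest-Z
#'   genes instead.
#' @return Tibble of selected genes sorted by descending Z.
#' @export
select_risk_genes <- function(scores, z_cutoff = 1.645, top_n = NULL) {
  assert_cols(scores, c("gene", "z"), "score table")
  out <- scores |> arrange(desc(.data$z))
  if (!is.null(top_n)) {
    out <- out |> slice_head(n = top_n)
  } else {
    out <- out |> filter(.data$z >= z_cutoff)
  }
  out |> select("gene", "z")
}

#' Disease module induced by a risk-gene set
#'
#' Induced subgraph of the interactome on the given genes, with self-loops
#' and isolated nodes removed -- the connected interaction core of the
#' prioritized genes.
#'
#' @param g An `interactome`.
#' @param genes Character vector of gene symbols.
#' @return An `interactome` containing only risk genes that interact with at
#'   least one other risk gene.
#' @export
disease_module <- function(g, genes) {
  stopifnot(inherits(g, "interactome"))
  genes <- normalize_symbols(genes)
  edges <- g$edges |>
    filter(.data$from %in% genes & .data$to %in% genes) |>
    filter(.data$from != .data$to)
  if (nrow(edges) == 0) {
    abort("no interactions among the supplied genes; disease module is empty")
  }
  # isolated nodes disappear automatically: the interactome is edge-defined
  new_interactome(edges)
}
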