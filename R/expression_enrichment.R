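# Tissue-specificity z-scores on a gene x tissue expression matrix, and
# Fisher-test enrichment of gene sets against the interactome background.

#' Tissue-specificity z-scores of an expression matrix
#'
#' For gene \eqn{i} and tissue \eqn{t}, specificity is
#' \eqn{z_{it} = (E_{it} - \bar E_i) / \sigma_i}, with \eqn{\bar E_i} and
#' \eqn{\sigma_i} the mean and standard deviation of gene \eqn{i}'s
#' expression across all tissues. Negative values are clamped to zero (a
#' gene is either specifically high in a tissue or it is not), while the
#' pre-clamp value is retained for diagnostics. Genes with zero variance
#' across tissues get z = 0 everywhere.
#'
#' @param expr Wide tibble/data frame with a `gene` column (or rownames) and
#'   one numeric TPM column per tissue, assumed already collapsed to
#'   per-tissue means.
#' @param ddof Degrees-of-freedom correction for the standard deviation:
#'   1 (default) for the sample sd, 0 for the population sd.
#' @return A tibble with columns `gene`, `tissue`, `z_raw` (pre-clamp) and
#'   `z` (clamped at zero).
#' @export
tissue_specificity <- function(expr, ddof = 1) {
  stopifnot(ddof %in% c(0, 1))
  expr <- as.data.frame(expr)
  if ("gene" %in% names(expr)) {
    genes <- normalize_symbols(expr$gene)
    mat <- as.matrix(expr[setdiff(names(expr), "gene")])
  } else {
    genes <- normalize_symbols(rownames(expr))
    mat <- as.matrix(expr)
  }
  if (ncol(mat) < 2) abort("at least two tissues are required")
  if (any(mat < 0)) abort("TPM values must be nonnegative")
  storage.mode(mat) <- "double"

  mu <- rowMeans(mat)
  centered <- mat - mu
  n_t <- ncol(mat)
  denom <- if (ddof == 1) n_t - 1 else n_t
  sigma <- sqrt(rowSums(centered^2) / denom)
  constant <- sigma == 0
  if (any(constant)) {
    inform(sprintf(
      "%d gene(s) constant across tissues; their z set to 0", sum(constant)
    ))
  }
  z_raw <- centered / ifelse(constant, 1, sigma)
  z_raw[constant, ] <- 0

  tibble(
    gene = rep(genes, times = n_t),
    tissue = rep(colnames(mat), each = length(genes)),
    z_raw = as.vector(z_raw),
    z = pmax(as.vector(z_raw), 0)
  )
}

#' Fisher exact enrichment of a hit set in an annotation set
#'
#' One-sided (greater) Fisher exact test on the 2x2 table of hit membership
#' versus annotation membership over a fixed background universe (typically
#' the full interactome gene set). The returned odds ratio is the sample
#' (cross-product) odds ratio of the table.
#'
#' @param hits Character vector, the prioritized gene set.
#' @param annotation Character vector, the evidence gene set tested for
#'   overlap.
#' @param background Character vector, the universe both sets live in.
#' @return One-row tibble: `overlap`, `n_hits`, `n_annotation`,
#'   `n_background`, `odds_ratio`, `p_value`.
#' @export
fisher_enrichment <- function(hits, annotation, background) {
  background <- unique(normalize_symbols(background))
  if (length(background) == 0) abort("background universe is empty")
  hits <- unique(normalize_symbols(hits))
  annotation <- unique(normalize_symbols(annotation))
  if (!all(hits %in% background) || !all(annotation %in% background)) {
    abort("hits and annotation must be subsets of the background")
  }
  a <- length(intersect(hits, annotation))
  fisher_table(
    overlap = a, n_hits = length(hits),
    n_annotation = length(annotation), n_background = length(background)
  )
}

#' One-sided Fisher enrichment from table counts
#'
#' Count-level, vectorized core of [fisher_enrichment()]: the one-sided
#' (greater) Fisher exact p-value of a 2x2 membership table is the
#' hypergeometric tail
#' \eqn{P(X \ge a)} with \eqn{X \sim \mathrm{Hypergeom}} drawing `n_hits`
#' from `n_background` of which `n_annotation` are marked, evaluated with
#' [stats::phyper()]. The odds ratio is the sample (cross-product) odds
#' ratio.
#'
#' @param overlap,n_hits,n_annotation,n_background Integer vectors
#'   (recycled) of table margins; `overlap` must not exceed either set.
#' @return Tibble with one row per table: the four counts, `odds_ratio`
#'   and `p_value`.
#' @export
fisher_table <- function(overlap, n_hits, n_annotation, n_background) {
  a <- as.numeric(overlap)
  b <- as.numeric(n_hits) - a
  cc <- as.numeric(n_annotation) - a
  dd <- as.numeric(n_background) - a - b - cc
  if (any(b < 0 | cc < 0 | dd < 0)) {
    abort("inconsistent table counts (negative implied cell)")
  }
  p <- stats::phyper(a - 1, n_annotation, n_background - n_annotation,
    n_hits,
    lower.tail = FALSE
  )
  or <- ifelse(
    b * cc == 0,
    ifelse(a * dd == 0, NaN, Inf),
    (a * dd) / (b * cc)
  )
  tibble(
    overlap = as.integer(overlap),
    n_hits = as.integer(n_hits),
    n_annotation = as.integer(n_annotation),
    n_background = as.integer(n_background),
    odds_ratio = or,
    p_value = p
  )
}

#' Enrichment of one hit set across many annotation sets
#'
#' Runs [fisher_enrichment()] for each annotation set and adds
#' Benjamini-Hochberg q-values across the battery of tests.
#'
#' @param hits Character vector of prioritized genes.
#' @param gene_sets Named list of annotation gene-symbol vectors.
#' @param background Character vector, the shared universe.
#' @return A tibble with one row per gene set, ordered by p-value, including
#'   a `q_value` column.
#' @export
enrich_gene_sets <- function(hits, gene_sets, background) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  background <- unique(normalize_symbols(background))
  res <- purrr::imap(gene_sets, function(set, name) {
    fisher_enrichment(
      hits,
      intersect(normalize_symbols(set), background),
      background
    ) |>
      mutate(gene_set = name, .before = 1)
  }) |>
    bind_rows()
  res |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    arrange(.data$p_value)
}
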