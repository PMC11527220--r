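# GWAS summary statistics x molecular QTLs -> regulatory connections.
#
# SNP-linked QTL classes (eQTL/pQTL/sQTL) are joined to GWAS variants by
# rsID; interval classes (meQTL/haQTL) are assigned to the nearest
# protein-coding gene. LD handling (clumping to lead SNPs, proxy lookup)
# operates on a supplied pairwise r-squared table rather than genotypes.
#
# Coordinate conventions: GWAS and QTL positions are 1-based inclusive; BED
# input is 0-based half-open and converted at read time.

#' Read GWAS summary statistics
#'
#' Reads one or more TSVs with columns `snp`, `chr`, `pos`, `p`. Multiple
#' studies are concatenated; a SNP appearing in several keeps its minimum
#' p-value. Rows with a non-numeric p-value are rejected with a warning.
#'
#' @param paths Character vector of file paths.
#' @return Tibble with columns `snp_id`, `chrom`, `pos`, `pvalue`.
#' @export
read_gwas <- function(paths) {
  raw <- purrr::map(paths, function(p) {
    readr::read_tsv(p,
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE
    )
  }) |>
    bind_rows()
  assert_cols(raw, c("snp", "chr", "pos", "p"), "GWAS table")
  pv <- suppressWarnings(as.numeric(raw$p))
  bad <- is.na(pv) | pv <= 0 | pv > 1
  if (any(bad)) {
    warn(sprintf("%d GWAS row(s) with invalid p-value rejected", sum(bad)))
  }
  tibble(
    snp_id = as.character(raw$snp),
    chrom = as.character(raw$chr),
    pos = as.integer(raw$pos),
    pvalue = pv
  ) |>
    filter(!bad) |>
    group_by(.data$snp_id) |>
    slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$chrom, .data$pos)
}

#' Filter GWAS variants at a significance threshold
#'
#' Keeps variants with `pvalue` strictly below the threshold (default
#' 1e-5, the conventional "suggestive" level), in stable (chrom, pos) order.
#'
#' @param variants Tibble with `snp_id`, `chrom`, `pos`, `pvalue`.
#' @param p_threshold Significance threshold in (0, 1].
#' @return Filtered tibble, ordered by chromosome then position.
#' @export
filter_gwas_snps <- function(variants, p_threshold = 1e-5) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  assert_cols(variants, c("snp_id", "chrom", "pos", "pvalue"), "variant table")
  variants |>
    filter(.data$pvalue < p_threshold) |>
    arrange(.data$chrom, .data$pos)
}

# Symmetric r2 lookup environment keyed "a|b" with a < b.
ld_lookup <- function(ld) {
  assert_cols(ld, c("snp_a", "snp_b", "r2"), "LD table")
  key <- paste(pmin(ld$snp_a, ld$snp_b), pmax(ld$snp_a, ld$snp_b), sep = "|")
  env <- new.env(hash = TRUE, size = max(nrow(ld), 16L))
  for (i in seq_len(nrow(ld))) assign(key[i], ld$r2[i], envir = env)
  env
}

ld_r2 <- function(env, a, b) {
  if (a == b) {
    return(1)
  }
  key <- paste(min(a, b), max(a, b), sep = "|")
  v <- get0(key, envir = env, ifnotfound = NA_real_)
  if (is.na(v)) 0 else v # missing pair treated as independent
}

#' Greedy LD clumping to lead SNPs
#'
#' Repeatedly promotes the most significant remaining variant to a lead and
#' removes all variants on the same chromosome within `window_bp` of it whose
#' r-squared with the lead exceeds `r2_cutoff`, until no variant remains.
#' Pairs absent from the LD table are treated as independent (r2 = 0).
#'
#' @param variants Pre-filtered tibble (`snp_id`, `chrom`, `pos`, `pvalue`).
#' @param ld LD tibble with columns `snp_a`, `snp_b`, `r2`.
#' @param r2_cutoff Clumping r-squared cutoff (default 0.1).
#' @param window_bp Clumping window in base pairs (default 1 Mb).
#' @return Tibble of lead variants with an added `clumped_n` column counting
#'   the variants each lead absorbed.
#' @export
ld_clump <- function(variants, ld, r2_cutoff = 0.1, window_bp = 1e6) {
  assert_cols(variants, c("snp_id", "chrom", "pos", "pvalue"), "variant table")
  env <- ld_lookup(ld)
  pool <- variants |> arrange(.data$pvalue, .data$chrom, .data$pos)
  leads <- list()
  while (nrow(pool) > 0) {
    lead <- pool[1, ]
    rest <- pool[-1, , drop = FALSE]
    in_window <- rest$chrom == lead$chrom &
      abs(rest$pos - lead$pos) <= window_bp
    linked <- in_window & vapply(
      rest$snp_id,
      function(s) ld_r2(env, s, lead$snp_id) > r2_cutoff,
      logical(1),
      USE.NAMES = FALSE
    )
    lead$clumped_n <- sum(linked)
    leads[[length(leads) + 1]] <- lead
    pool <- rest[!linked, , drop = FALSE]
  }
  bind_rows(leads) |> arrange(.data$chrom, .data$pos)
}

#' Proxy variants in strong LD with lead SNPs
#'
#' A candidate is a proxy of a lead iff their r-squared strictly exceeds
#' `r2_proxy`; a candidate may proxy several leads. Self pairs are excluded.
#'
#' @param leads Tibble of lead variants (or character vector of ids).
#' @param candidates Tibble of candidate variants (or character vector).
#' @param ld LD tibble (`snp_a`, `snp_b`, `r2`).
#' @param r2_proxy Strict lower bound on r-squared (default 0.8).
#' @return Tibble with columns `lead`, `proxy`, `r2`.
#' @export
find_proxy_snps <- function(leads, candidates, ld, r2_proxy = 0.8) {
  lead_ids <- if (is.data.frame(leads)) leads$snp_id else as.character(leads)
  cand_ids <- if (is.data.frame(candidates)) {
    candidates$snp_id
  } else {
    as.character(candidates)
  }
  env <- ld_lookup(ld)
  grid <- tidyr::expand_grid(lead = unique(lead_ids), proxy = unique(cand_ids)) |>
    filter(.data$lead != .data$proxy)
  grid$r2 <- purrr::map2_dbl(grid$lead, grid$proxy, function(a, b) {
    ld_r2(env, a, b)
  })
  grid |> filter(.data$r2 > r2_proxy)
}

#' Join GWAS variants to SNP-linked QTL records
#'
#' Emits one regulatory connection per distinct (SNP, QTL type, gene) triple
#' whose SNP id occurs in both the GWAS variant set and the QTL table.
#'
#' @param gwas_snps Tibble with `snp_id` (typically significant variants).
#' @param qtls Tibble with `snp_id`, `qtl_type` (eQTL/pQTL/sQTL) and `gene`.
#' @param annotation Optional protein-coding gene annotation (tibble with a
#'   `gene` column); when supplied, connections to genes outside it are
#'   dropped.
#' @return Tibble with columns `snp_id`, `qtl_type`, `gene`.
#' @export
map_snp_qtl_genes <- function(gwas_snps, qtls, annotation = NULL) {
  assert_cols(gwas_snps, "snp_id", "GWAS table")
  assert_cols(qtls, c("snp_id", "qtl_type", "gene"), "QTL table")
  out <- qtls |>
    mutate(gene = normalize_symbols(.data$gene)) |>
    semi_join(gwas_snps, by = "snp_id") |>
    distinct(.data$snp_id, .data$qtl_type, .data$gene)
  if (!is.null(annotation)) {
    out <- out |> filter(.data$gene %in% normalize_symbols(annotation$gene))
  }
  out
}

#' Assign interval QTLs (meQTL/haQTL peaks) to the nearest gene
#'
#' Each regulatory interval is assigned the protein-coding gene on the same
#' chromosome minimizing the genomic distance to the gene body (0 when they
#' overlap; otherwise the difference between the facing interval endpoints).
#' Equidistant candidates are tie-broken lexicographically by symbol and both
#' are reported in a message. Intervals on chromosomes absent from the
#' annotation are skipped with a warning.
#'
#' @param regions Tibble with `chrom`, `start`, `end` (1-based inclusive),
#'   `snp_id` (associated GWAS variant) and `qtl_type`.
#' @param annotation Tibble with `chrom`, `start`, `end`, `gene`, restricted
#'   to protein-coding genes.
#' @return Tibble with `snp_id`, `qtl_type`, `gene`, `distance`.
#' @export
map_region_nearest_gene <- function(regions, annotation) {
  assert_cols(regions, c("chrom", "start", "end", "snp_id", "qtl_type"),
    "region table")
  assert_cols(annotation, c("chrom", "start", "end", "gene"), "annotation")
  annotation <- annotation |> mutate(gene = normalize_symbols(.data$gene))

  missing_chrom <- setdiff(unique(regions$chrom), unique(annotation$chrom))
  if (length(missing_chrom) > 0) {
    warn(sprintf(
      "skipping %d region(s) on chromosome(s) absent from the annotation: %s",
      sum(regions$chrom %in% missing_chrom),
      paste(missing_chrom, collapse = ", ")
    ))
    regions <- regions |> filter(!.data$chrom %in% missing_chrom)
  }
  if (nrow(regions) == 0) {
    return(tibble(
      snp_id = character(), qtl_type = character(),
      gene = character(), distance = double()
    ))
  }

  out <- purrr::pmap(regions, function(chrom, start, end, snp_id, qtl_type,
                                       ...) {
    cand <- annotation[annotation$chrom == chrom, , drop = FALSE]
    gap <- pmax(0, pmax(cand$start - end, start - cand$end))
    best <- which(gap == min(gap))
    if (length(best) > 1) {
      syms <- sort(cand$gene[best])
      inform(sprintf(
        "region %s:%d-%d equidistant from genes {%s}; keeping %s",
        chrom, start, end, paste(syms, collapse = ", "), syms[1]
      ))
      best <- best[order(cand$gene[best])][1]
    }
    tibble(
      snp_id = snp_id, qtl_type = qtl_type,
      gene = cand$gene[best], distance = gap[best]
    )
  }) |>
    bind_rows()
  distinct(out)
}

#' Read interval QTLs from a BED file
#'
#' BED coordinates are 0-based half-open; they are converted to 1-based
#' inclusive on read. The 4th column is taken as the associated GWAS SNP id.
#'
#' @param path BED path (chrom, start, end, snp_id).
#' @param qtl_type Label to attach, e.g. `"meQTL"` or `"haQTL"`.
#' @return Tibble with `chrom`, `start`, `end`, `snp_id`, `qtl_type`.
#' @export
read_bed_regions <- function(path, qtl_type) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "snp_id"),
    col_types = "ciic", progress = FALSE
  )
  raw |>
    mutate(
      start = .data$start + 1L, # 0-based half-open -> 1-based inclusive
      qtl_type = qtl_type
    )
}

#' Read a protein-coding gene annotation
#'
#' Accepts a 6-column BED (`chrom start end gene score strand`; 0-based
#' half-open, converted on read) or, when the filename ends in `.gtf`, a GTF
#' whose `gene` features with `gene_biotype == "protein_coding"` are kept
#' (parsed with `rtracklayer`).
#'
#' @param path Annotation file path.
#' @return Tibble with `chrom`, `start`, `end`, `gene` (1-based inclusive).
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE)) {
      abort("reading GTF requires the rtracklayer package")
    }
    df <- as.data.frame(rtracklayer::import(path))
    df <- df[df$type == "gene", , drop = FALSE]
    if ("gene_biotype" %in% names(df)) {
      df <- df[df$gene_biotype == "protein_coding", , drop = FALSE]
    }
    return(tibble(
      chrom = as.character(df$seqnames),
      start = df$start,
      end = df$end,
      gene = normalize_symbols(df$gene_name)
    ))
  }
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene", "score", "strand"),
    col_types = "ciiccc", progress = FALSE
  )
  raw |>
    transmute(
      chrom = .data$chrom,
      start = .data$start + 1L,
      end = .data$end,
      gene = normalize_symbols(.data$gene)
    )
}

#' Annotate connections with lead and proxy status
#'
#' @param connections Connection tibble (`snp_id`, `qtl_type`, `gene`).
#' @param leads Lead tibble from [ld_clump()] (or character ids).
#' @param proxies Proxy tibble from [find_proxy_snps()] (optional).
#' @return The connections with `lead_flag` (logical) and `proxy_of`
#'   (lead id or `NA`) columns.
#' @export
flag_lead_connections <- function(connections, leads, proxies = NULL) {
  lead_ids <- if (is.data.frame(leads)) leads$snp_id else as.character(leads)
  out <- connections |> mutate(lead_flag = .data$snp_id %in% lead_ids)
  if (!is.null(proxies) && nrow(proxies) > 0) {
    first_lead <- proxies |>
      group_by(.data$proxy) |>
      slice_max(.data$r2, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select(snp_id = "proxy", proxy_of = "lead")
    out <- out |> left_join(first_lead, by = "snp_id")
  } else {
    out$proxy_of <- NA_character_
  }
  out
}

#' Summarize a regulatory-connection table
#'
#' @param connections Tibble with `snp_id`, `qtl_type`, `gene`.
#' @return A `regulatory_summary` list: `type_counts` (per-QTL-type counts
#'   and percentages), `gene_types` (per-gene supporting QTL types), and
#'   `genes`, the regulated-gene universe.
#' @export
build_regulatory_table <- function(connections) {
  if (nrow(connections) == 0) {
    return(structure(
      list(
        type_counts = tibble(
          qtl_type = character(), n = integer(), pct = double()
        ),
        gene_types = tibble(
          gene = character(), types = character(), n_types = integer()
        ),
        genes = character(),
        n_connections = 0L
      ),
      class = "regulatory_summary"
    ))
  }
  type_counts <- connections |>
    count(.data$qtl_type, name = "n") |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
  gene_types <- connections |>
    distinct(.data$gene, .data$qtl_type) |>
    group_by(.data$gene) |>
    summarise(
      types = paste(sort(.data$qtl_type), collapse = ","),
      n_types = n_distinct(.data$qtl_type),
      .groups = "drop"
    ) |>
    arrange(desc(.data$n_types), .data$gene)
  structure(
    list(
      type_counts = type_counts,
      gene_types = gene_types,
      genes = sort(unique(connections$gene)),
      n_connections = nrow(connections)
    ),
    class = "regulatory_summary"
  )
}

#' @export
print.regulatory_summary <- function(x, ...) {
  cat(sprintf(
    "<regulatory_summary> %d connections, %d regulated genes\n",
    x$n_connections, length(x$genes)
  ))
  print(x$type_counts)
  invisible(x)
}
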