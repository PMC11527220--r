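# End-to-end pipeline on synthetic fixtures: interactome -> QTL mapping ->
# module learning -> risk scoring -> proximity screen -> trial emulation.
# Primarily a reproducibility harness: the same spec and master seed must
# give bit-identical results.

#' Run the full prioritization pipeline on synthetic fixtures
#'
#' Generates every input from the fixture spec, then runs each stage with
#' seeds derived from the master seed: LCC extraction and normalization,
#' GWAS filtering, LD clumping, proxy lookup, QTL joins and nearest-gene
#' assignment, module learning over `n_seeds` model seeds, evidence scoring
#' and ensembling, benchmark AUROC against positives drawn from the planted
#' module, risk-gene calls, tissue specificity, enrichment of the risk set
#' in the evidence set, drug proximity screening, and emulated trials of the
#' planted tested drug.
#'
#' @param spec A [fixture_spec()].
#' @param n_seeds Model seeds ensembled for gene scoring.
#' @param k_modules Module count for the learner (defaults to the planted
#'   count).
#' @param n_perm Permutations per drug in the proximity screen.
#' @param n_emulations,n_boot,min_balanced,min_users Trial-emulation sizes.
#' @param epochs,lr Module-learner settings.
#' @param risk_frac Fraction of the network called as risk genes (the
#'   fixture-scale counterpart of a fixed Z cutoff: with a handful of
#'   planted modules the standardized ensemble score is strongly bimodal,
#'   so a rank-based call is the stable choice).
#' @return A named list with each stage's outputs (see the elements of the
#'   returned object).
#' @export
run_pipeline <- function(spec,
                         n_seeds = 3L,
                         k_modules = NULL,
                         n_perm = 200L,
                         n_emulations = 10L,
                         n_boot = 100L,
                         min_balanced = 5L,
                         min_users = 20L,
                         epochs = 200L,
                         lr = 1e-3,
                         risk_frac = 0.25) {
  net <- generate_interactome(spec)
  qtl <- generate_gwas_qtl(spec, net)
  drugs <- generate_drug_targets(spec, net)
  expr <- generate_expression(
    spec, net$graph$nodes, qtl$truth$evidence_genes
  )
  ehr <- generate_ehr_cohort(spec)

  lcc <- extract_lcc(net$graph)

  # --- GWAS x QTL mapping ---
  sig <- filter_gwas_snps(qtl$gwas)
  leads <- ld_clump(sig, qtl$ld)
  proxies <- find_proxy_snps(leads, qtl$gwas, qtl$ld)
  snp_conn <- map_snp_qtl_genes(
    sig |>
      bind_rows(qtl$gwas |> filter(.data$snp_id %in% proxies$proxy)),
    bind_rows(qtl$eqtl, qtl$pqtl, qtl$sqtl),
    annotation = qtl$annotation
  )
  region_conn <- map_region_nearest_gene(
    bind_rows(qtl$meqtl, qtl$haqtl), qtl$annotation
  ) |>
    select(-"distance")
  connections <- flag_lead_connections(
    bind_rows(snp_conn, region_conn), leads, proxies
  )
  regulatory <- build_regulatory_table(connections)
  evidence <- intersect(regulatory$genes, lcc$nodes)

  # --- module learning and risk scoring ---
  K <- k_modules %||% spec$graph$k_modules
  fits <- purrr::map(seq_len(n_seeds), function(i) {
    train_modules(lcc, K = K,
      seed = derive_seed(spec$seed, paste0("model", i)),
      epochs = epochs, lr = lr)
  })
  tables <- purrr::map(fits, score_genes, evidence = evidence)
  scores <- ensemble_scores(tables)

  # benchmark positives: the planted module's genes beyond the evidence set;
  # evidence genes are model inputs, so they are excluded from the
  # evaluation universe entirely rather than counted as negatives
  bench <- setdiff(
    net$labels$gene[net$labels$module == spec$evidence$module],
    evidence
  )
  auroc <- evaluate_auroc(
    scores |> filter(!.data$gene %in% evidence),
    bench
  )
  risk_genes <- select_risk_genes(
    scores,
    top_n = ceiling(risk_frac * length(lcc$nodes))
  )
  dis_mod <- tryCatch(
    disease_module(lcc, risk_genes$gene),
    error = function(e) NULL
  )

  # --- expression specificity + enrichment ---
  spec_tbl <- tissue_specificity(expr)
  enrich <- fisher_enrichment(
    risk_genes$gene,
    evidence,
    lcc$nodes
  )

  # --- drug proximity ---
  prox <- proximity_screen(
    lcc,
    disease_genes = if (!is.null(dis_mod)) dis_mod$nodes else risk_genes$gene,
    drug_targets = drugs,
    n_perm = n_perm,
    seed = derive_seed(spec$seed, "proximity"),
    min_bin = 20L
  )
  hits <- screen_drugs(prox)

  # --- trial emulation ---
  trials <- emulate_trials(
    ehr$patients, ehr$diagnoses, ehr$prescriptions,
    drug = ehr$drug, codes = ehr$codes,
    covariate_spec = ehr$covariate_spec,
    n_emulations = n_emulations, n_boot = n_boot,
    min_balanced = min_balanced, min_users = min_users,
    seed = derive_seed(spec$seed, "trials")
  )

  list(
    lcc = lcc,
    regulatory = regulatory,
    connections = connections,
    evidence = evidence,
    leads = leads,
    proxies = proxies,
    module_fits = fits,
    scores = scores,
    benchmark = bench,
    auroc = auroc,
    risk_genes = risk_genes,
    disease_module = dis_mod,
    specificity = spec_tbl,
    enrichment = enrich,
    proximity = prox,
    screened_drugs = hits,
    trials = trials
  )
}
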