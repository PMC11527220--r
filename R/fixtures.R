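# Synthetic data with planted ground truth for every input the pipeline
# consumes: a planted-partition interactome, GWAS + QTL + LD + annotation
# tables with QTL-linked risk genes, a tissue expression matrix with an
# elevated target tissue, a drug-target table with one drug planted near the
# evidence genes, and a confounded longitudinal patient cohort with a known
# treatment hazard ratio.
#
# Every generator is a pure function of (spec, master seed): each component
# consumes a substream seed derived by stable hashing of its name, so
# regenerating one fixture never perturbs the others.

#' Fixture specification
#'
#' Bundles the generating parameters of all synthetic inputs. Defaults give
#' a small two-module planted-partition graph with clearly separated blocks
#' and a protective tested drug, sized so the full pipeline runs in seconds.
#'
#' @param seed Master seed; all component streams derive from it.
#' @param graph List: `n_nodes`, `k_modules`, `p_in`, `p_out`
#'   (within/between-block edge probabilities, `p_in > p_out`).
#' @param evidence List: `n_evidence` genes planted in module
#'   `module`.
#' @param expression List: `n_tissues` exchangeable tissues plus one target
#'   tissue (`target`), where planted genes are elevated by `effect_size`
#'   standard deviations on the log scale.
#' @param drugs List: `n_drugs`, `targets_per_drug`; one extra "close" drug
#'   is planted with all targets inside the evidence module.
#' @param cohort List: `n_patients`, `true_hr`, `confounder_prev`,
#'   `treat_intercept` (baseline log-odds of receiving the tested drug;
#'   kept negative so the comparator pool outnumbers the treated arm),
#'   `conf_treat_effect` (log-odds shift of treatment given the
#'   confounder), `conf_hazard` (hazard multiplier of the confounder),
#'   `base_hazard` (events/day), `censor_days`, `n_ineligible` planted
#'   violations.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         graph = list(),
                         evidence = list(),
                         expression = list(),
                         drugs = list(),
                         cohort = list()) {
  spec <- list(
    seed = as.integer(seed),
    graph = utils::modifyList(
      list(n_nodes = 60L, k_modules = 2L, p_in = 0.3, p_out = 0.01),
      graph
    ),
    evidence = utils::modifyList(
      list(n_evidence = 10L, module = 1L),
      evidence
    ),
    expression = utils::modifyList(
      list(n_tissues = 8L, target = "SN", effect_size = 3),
      expression
    ),
    drugs = utils::modifyList(
      list(n_drugs = 12L, targets_per_drug = 4L),
      drugs
    ),
    cohort = utils::modifyList(
      list(
        n_patients = 1500L, true_hr = 0.5, confounder_prev = 0.4,
        treat_intercept = -1.0, conf_treat_effect = 1.2, conf_hazard = 2,
        base_hazard = 0.0015, censor_days = 1460L, n_ineligible = 30L
      ),
      cohort
    )
  )
  stopifnot(spec$graph$p_in > spec$graph$p_out)
  structure(spec, class = "fixture_spec")
}

#' Generate a planted-partition interactome
#'
#' Nodes are split into `k_modules` equal blocks; within-block pairs are
#' edges with probability `p_in` and between-block pairs with probability
#' `p_out`. If the sampled graph is disconnected, bridging edges between the
#' lexicographically smallest members of separate components are added (and
#' counted in the `n_patched` attribute) so downstream LCC-based stages see
#' the whole graph.
#'
#' @param spec A `fixture_spec`.
#' @param connect Patch the graph to a single component (default TRUE).
#' @return List with `graph` (an `interactome`), `labels` (tibble
#'   `gene`, `module`) and `edges`.
#' @export
generate_interactome <- function(spec, connect = TRUE) {
  g <- spec$graph
  n <- g$n_nodes
  k <- g$k_modules
  block <- rep(seq_len(k), each = ceiling(n / k))[seq_len(n)]
  nodes <- sprintf("G%04d", seq_len(n))
  labels <- tibble(gene = nodes, module = block)

  edges <- with_seed(derive_seed(spec$seed, "interactome"), {
    pairs <- t(combn(n, 2))
    same <- block[pairs[, 1]] == block[pairs[, 2]]
    p <- ifelse(same, g$p_in, g$p_out)
    keep <- runif(nrow(pairs)) < p
    tibble(
      from = nodes[pairs[keep, 1]],
      to = nodes[pairs[keep, 2]]
    )
  })
  expected_in <- g$p_in * (n / k - 1)
  if (expected_in < 1) {
    warn("expected within-block degree below 1; blocks may be undetectable")
  }

  n_patched <- 0L
  if (connect && nrow(edges) > 0) {
    ig <- as_interactome(edges)
    comps <- igraph::components(ig$graph)
    isolated <- setdiff(nodes, ig$nodes)
    while (comps$no > 1 || length(isolated) > 0) {
      reps <- vapply(
        seq_len(comps$no),
        function(cc) min(ig$nodes[comps$membership == cc]),
        character(1)
      )
      anchors <- sort(unique(c(reps, isolated)))
      new_edges <- tibble(
        from = anchors[-length(anchors)],
        to = anchors[-1]
      )
      edges <- bind_rows(edges, new_edges) |> distinct()
      n_patched <- n_patched + nrow(new_edges)
      ig <- as_interactome(edges)
      comps <- igraph::components(ig$graph)
      isolated <- setdiff(nodes, ig$nodes)
    }
    inform_patch <- n_patched > 0
    if (inform_patch) {
      inform(sprintf("added %d bridging edge(s) to connect the graph",
        n_patched))
    }
  }
  graph <- as_interactome(edges)
  structure(
    list(graph = graph, labels = labels, edges = as_edge_tibble(graph)),
    class = "interactome_fixture", n_patched = n_patched
  )
}

#' Generate GWAS, QTL, LD and annotation fixtures
#'
#' Evidence genes drawn from the planted module receive eQTL (and a few
#' pQTL/sQTL) links to genome-wide significant SNPs; each lead SNP comes
#' with linked satellite SNPs in high LD inside the clumping window (so
#' clumping has work to do) and one strong-LD proxy outside the significant
#' set. Decoy SNPs with non-significant p-values and decoy genes are added.
#' meQTL/haQTL intervals are placed overlapping a subset of evidence genes.
#'
#' @param spec A `fixture_spec`.
#' @param interactome Output of [generate_interactome()].
#' @return List with `gwas`, `eqtl`, `pqtl`, `sqtl`, `meqtl`, `haqtl`,
#'   `ld`, `annotation` tibbles and `truth` (evidence genes, lead SNPs,
#'   proxy pairs).
#' @export
generate_gwas_qtl <- function(spec, interactome) {
  nodes <- interactome$graph$nodes
  labels <- interactome$labels |> filter(.data$gene %in% nodes)
  ev_spec <- spec$evidence

  with_seed(derive_seed(spec$seed, "gwas_qtl"), {
    pool <- labels$gene[labels$module == ev_spec$module]
    evidence <- sort(sample(pool, min(ev_spec$n_evidence, length(pool))))

    # gene bodies laid out on two chromosomes, 1 kb genes / 50 kb spacing
    ann <- tibble(
      gene = sort(nodes),
      chrom = ifelse(seq_along(nodes) %% 2 == 1, "1", "2"),
    ) |>
      group_by(.data$chrom) |>
      mutate(
        start = 100000L + (row_number() - 1L) * 50000L,
        end = .data$start + 999L
      ) |>
      ungroup() |>
      select("chrom", "start", "end", "gene")

    gene_pos <- ann |> mutate(mid = (.data$start + .data$end) %/% 2L)

    # one lead SNP per evidence gene + 2 clumpable satellites + 1 proxy
    rows <- purrr::map(seq_along(evidence), function(i) {
      gpos <- gene_pos |> filter(.data$gene == evidence[i])
      lead <- sprintf("rs%d01", 1000 + i)
      sats <- sprintf("rs%d0%d", 1000 + i, 2:3)
      proxy <- sprintf("rs%d09", 1000 + i)
      tibble(
        snp = c(lead, sats, proxy),
        chr = gpos$chrom,
        pos = gpos$mid + c(0L, 2000L, -2000L, 4000L),
        p = c(
          10^runif(1, -12, -8),
          10^runif(2, -7, -6),
          0.2 # proxy itself not significant
        ),
        gene = evidence[i],
        role = c("lead", "sat", "sat", "proxy")
      )
    }) |>
      bind_rows()

    # decoys: significant SNPs without QTL links, and QTL-linked SNPs
    # without significance
    decoy_genes <- setdiff(nodes, evidence)
    n_decoy <- min(10L, length(decoy_genes))
    decoy_sig <- tibble(
      snp = sprintf("rs9%03d", seq_len(5)),
      chr = "1",
      pos = 4000000L + seq_len(5) * 123457L,
      p = 10^runif(5, -9, -6),
      gene = NA_character_, role = "decoy_sig"
    )
    decoy_qtl <- tibble(
      snp = sprintf("rs8%03d", seq_len(n_decoy)),
      chr = "2",
      pos = 5000000L + seq_len(n_decoy) * 98765L,
      p = runif(n_decoy, 0.05, 0.9),
      gene = sample(decoy_genes, n_decoy),
      role = "decoy_qtl"
    )
    all_snps <- bind_rows(rows, decoy_sig, decoy_qtl)

    gwas <- all_snps |>
      transmute(
        snp_id = .data$snp, chrom = .data$chr, pos = .data$pos,
        pvalue = .data$p
      ) |>
      arrange(.data$chrom, .data$pos)

    # LD: satellites and proxies in high LD with their lead; everything else
    # effectively independent
    ld <- purrr::map(seq_along(evidence), function(i) {
      lead <- sprintf("rs%d01", 1000 + i)
      tibble(
        snp_a = lead,
        snp_b = c(
          sprintf("rs%d0%d", 1000 + i, 2:3),
          sprintf("rs%d09", 1000 + i)
        ),
        r2 = c(0.92, 0.85, 0.9)
      )
    }) |>
      bind_rows()

    # SNP-linked QTLs: evidence genes via eQTL; first two evidence genes also
    # get pQTL/sQTL support through the proxy SNP (proxy transfers evidence)
    eqtl <- bind_rows(
      rows |>
        filter(.data$role %in% c("lead", "sat")) |>
        transmute(snp_id = .data$snp, qtl_type = "eQTL", gene = .data$gene),
      decoy_qtl |>
        transmute(snp_id = .data$snp, qtl_type = "eQTL", gene = .data$gene)
    )
    pqtl <- rows |>
      filter(.data$role == "proxy") |>
      slice_head(n = 2) |>
      transmute(snp_id = .data$snp, qtl_type = "pQTL", gene = .data$gene)
    sqtl <- rows |>
      filter(.data$role == "lead") |>
      slice_head(n = 2) |>
      transmute(snp_id = .data$snp, qtl_type = "sQTL", gene = .data$gene)

    # interval QTLs overlapping a subset of evidence genes, associated with
    # the gene's lead SNP
    peak_genes <- head(evidence, max(2L, length(evidence) %/% 2L))
    peaks <- gene_pos |>
      filter(.data$gene %in% peak_genes) |>
      mutate(lead = sprintf(
        "rs%d01", 1000 + match(.data$gene, evidence)
      ))
    meqtl <- peaks |>
      transmute(
        chrom = .data$chrom,
        start = .data$start - 200L,
        end = .data$start + 200L,
        snp_id = .data$lead,
        qtl_type = "meQTL"
      )
    haqtl <- peaks |>
      slice_head(n = max(1L, nrow(peaks) %/% 2L)) |>
      transmute(
        chrom = .data$chrom,
        start = .data$end + 300L, # nearby but non-overlapping
        end = .data$end + 600L,
        snp_id = .data$lead,
        qtl_type = "haQTL"
      )

    list(
      gwas = gwas,
      eqtl = eqtl, pqtl = pqtl, sqtl = sqtl,
      meqtl = meqtl, haqtl = haqtl,
      ld = ld,
      annotation = ann,
      truth = list(
        evidence_genes = evidence,
        lead_snps = sprintf("rs%d01", 1000 + seq_along(evidence)),
        satellite_snps = rows$snp[rows$role == "sat"],
        proxy_snps = rows$snp[rows$role == "proxy"],
        decoy_qtl_snps = decoy_qtl$snp
      )
    )
  })
}

#' Generate a gene x tissue expression matrix with a planted target tissue
#'
#' Baseline log-normal TPM per gene with exchangeable tissue noise; in the
#' target tissue the planted genes are shifted upward by `effect_size`
#' noise standard deviations on the log scale, so their specificity z-scores
#' are positive there.
#'
#' @param spec A `fixture_spec`.
#' @param genes Character vector of genes (rows).
#' @param planted Character vector of genes elevated in the target tissue.
#' @return Wide tibble: `gene` plus one TPM column per tissue (target
#'   tissue named per `spec$expression$target`).
#' @export
generate_expression <- function(spec, genes, planted) {
  e <- spec$expression
  tissues <- c(paste0("T", seq_len(e$n_tissues - 1)), e$target)
  with_seed(derive_seed(spec$seed, "expression"), {
    base <- exp(rnorm(length(genes), mean = 2, sd = 1))
    noise_sd <- 0.2
    mat <- vapply(tissues, function(tt) {
      x <- base * exp(rnorm(length(genes), 0, noise_sd))
      if (tt == e$target) {
        up <- genes %in% planted
        x[up] <- x[up] * exp(e$effect_size * noise_sd)
      }
      x
    }, numeric(length(genes)))
    bind_cols(tibble(gene = genes), as_tibble(mat))
  })
}

#' Generate a drug-target table with a planted proximal drug
#'
#' Background drugs draw targets uniformly from the graph; one additional
#' planted drug (`drug_id = "D_CLOSE"`, approved) draws all its targets from
#' the evidence-module genes, so it sits significantly closer to the planted
#' disease module than degree-matched chance.
#'
#' @param spec A `fixture_spec`.
#' @param interactome Output of [generate_interactome()].
#' @return Tibble `drug_id`, `drug_name`, `target`, `atc_codes`,
#'   `approved`.
#' @export
generate_drug_targets <- function(spec, interactome) {
  d <- spec$drugs
  nodes <- interactome$graph$nodes
  labels <- interactome$labels |> filter(.data$gene %in% nodes)
  module_genes <- labels$gene[labels$module == spec$evidence$module]
  with_seed(derive_seed(spec$seed, "drugs"), {
    bg <- purrr::map(seq_len(d$n_drugs), function(i) {
      tibble(
        drug_id = sprintf("D%03d", i),
        drug_name = sprintf("drug%03d", i),
        target = sample(nodes, d$targets_per_drug),
        atc_codes = sprintf("N0%dAA%02d", 1 + i %% 5, i),
        approved = i %% 3 != 0
      )
    }) |>
      bind_rows()
    planted <- tibble(
      drug_id = "D_CLOSE",
      drug_name = "planted_close",
      target = sample(module_genes, min(d$targets_per_drug,
        length(module_genes))),
      atc_codes = "C10AA01",
      approved = TRUE
    )
    bind_rows(bg, planted)
  })
}

#' Generate a confounded longitudinal patient cohort
#'
#' Emulates EHR extracts for one tested drug and its ATC-L3 comparators. A
#' binary baseline confounder raises both the odds of receiving the tested
#' drug and the outcome hazard; event times are exponential with the
#' treated-arm hazard multiplied by `true_hr`. Censoring is administrative
#' at `censor_days` after the index date, and every patient gets a terminal
#' encounter record so censoring dates are recoverable from the tables.
#' Eligibility violations (too young; prior exclusion diagnosis) are planted
#' and reported in the truth block.
#'
#' @param spec A `fixture_spec`.
#' @return List with `patients`, `diagnoses`, `prescriptions`, `codes`
#'   (condition/exclusion/outcome ICD prefixes), `covariate_spec`, `drug`
#'   (tested ingredient code) and `truth` (true HR, confounder assignment,
#'   planted ineligible ids).
#' @export
generate_ehr_cohort <- function(spec) {
  cs <- spec$cohort
  with_seed(derive_seed(spec$seed, "ehr"), {
    n <- cs$n_patients
    ids <- sprintf("P%05d", seq_len(n))
    conf <- rbinom(n, 1, cs$confounder_prev)
    p_treat <- stats::plogis(cs$treat_intercept + cs$conf_treat_effect * conf)
    treated <- rbinom(n, 1, p_treat)

    first_pd <- as.Date("2010-01-01") + floor(runif(n, 0, 2000))
    age_at_pd <- runif(n, 55, 85)
    birth <- first_pd - round(age_at_pd * 365.25)
    initiation <- lubridate::add_with_rollback(
      first_pd, -lubridate::period(6, "months")
    )
    index <- initiation + floor(runif(n, 200, 360)) # after first_pd or not
    sex <- ifelse(runif(n) < 0.5, "F", "M")
    race <- sample(c("white", "black", "asian", "other"), n,
      replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)
    )

    rate <- cs$base_hazard * cs$conf_hazard^conf *
      ifelse(treated == 1, cs$true_hr, 1)
    t_event <- rexp(n, rate)
    censor_t <- cs$censor_days
    event <- t_event < censor_t
    outcome_date <- index + ceiling(t_event)
    censor_date <- index + ifelse(event, ceiling(t_event), censor_t)

    patients <- tibble(
      id = ids, birth_date = birth, sex = sex, race = race
    )
    diagnoses <- bind_rows(
      tibble(id = ids, icd = "G20", date = first_pd),
      tibble(id = ids[conf == 1], icd = "I10",
        date = initiation[conf == 1] + 10),
      tibble(id = ids[event], icd = "F03", date = outcome_date[event]),
      tibble(id = ids, icd = "Z00", date = censor_date) # terminal encounter
    )
    # noise comorbidity unrelated to treatment or outcome
    noisy <- runif(n) < 0.3
    diagnoses <- bind_rows(
      diagnoses,
      tibble(id = ids[noisy], icd = "E11", date = initiation[noisy] + 20)
    )

    comparators <- c("compA", "compB")
    comp_atc <- c(compA = "C10AA02", compB = "C10AA03")
    ingredient <- ifelse(treated == 1, "simva",
      sample(comparators, n, replace = TRUE))
    prescriptions <- tibble(
      id = ids,
      ingredient = ingredient,
      atc = ifelse(ingredient == "simva", "C10AA01",
        comp_atc[ingredient]),
      date = index
    )
    # background medication noise in the baseline window
    med_noise <- runif(n) < 0.25
    prescriptions <- bind_rows(
      prescriptions,
      tibble(
        id = ids[med_noise], ingredient = "aspirin", atc = "B01AC06",
        date = initiation[med_noise] + 30
      )
    )

    # planted ineligible patients: half too young, half with a prior
    # neurodegenerative exclusion diagnosis
    n_bad <- cs$n_ineligible
    bad_ids <- sprintf("X%05d", seq_len(n_bad))
    young <- seq_len(n_bad) <= n_bad %/% 2
    bad_first_pd <- as.Date("2012-06-01") + seq_len(n_bad)
    bad_birth <- bad_first_pd - round(ifelse(young, 40, 70) * 365.25)
    patients <- bind_rows(
      patients,
      tibble(
        id = bad_ids, birth_date = bad_birth,
        sex = "F", race = "white"
      )
    )
    diagnoses <- bind_rows(
      diagnoses,
      tibble(id = bad_ids, icd = "G20", date = bad_first_pd),
      tibble(
        id = bad_ids[!young], icd = "G30",
        date = bad_first_pd[!young] - 400
      )
    )
    prescriptions <- bind_rows(
      prescriptions,
      tibble(
        id = bad_ids, ingredient = "simva", atc = "C10AA01",
        date = bad_first_pd + 100
      )
    )

    list(
      patients = patients,
      diagnoses = diagnoses,
      prescriptions = prescriptions,
      codes = list(
        condition = "G20",
        exclusion = c("G30", "331"),
        outcome = "F03"
      ),
      covariate_spec = list(
        comorbidities = list(
          hypertension = "I10",
          diabetes = "E11"
        ),
        medications = "aspirin"
      ),
      drug = "simva",
      truth = list(
        true_hr = cs$true_hr,
        confounder = tibble(id = ids, confounder = conf,
          treated = treated),
        ineligible_ids = bad_ids
      )
    )
  })
}

#' Write all fixtures of a spec to a directory
#'
#' Materializes every synthetic input in the on-disk formats the package
#' readers consume (edge-list TSV, GWAS/QTL TSVs, BED intervals with 0-based
#' half-open coordinates, annotation BED, expression TSV, drug-target TSV,
#' patient CSVs).
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- generate_interactome(spec)
  qtl <- generate_gwas_qtl(spec, net)
  expr <- generate_expression(
    spec, net$graph$nodes, qtl$truth$evidence_genes
  )
  drugs <- generate_drug_targets(spec, net)
  ehr <- generate_ehr_cohort(spec)

  path <- function(f) file.path(dir, f)
  readr::write_tsv(net$edges, path("ppi_edges.tsv"))
  readr::write_tsv(net$labels, path("planted_modules.tsv"))
  readr::write_tsv(
    qtl$gwas |> rename(snp = "snp_id", chr = "chrom", p = "pvalue"),
    path("gwas.tsv")
  )
  for (ty in c("eqtl", "pqtl", "sqtl")) {
    readr::write_tsv(qtl[[ty]], path(paste0(ty, ".tsv")))
  }
  for (ty in c("meqtl", "haqtl")) {
    bed <- qtl[[ty]] |>
      transmute(
        chrom = .data$chrom, start = .data$start - 1L, end = .data$end,
        snp_id = .data$snp_id
      )
    readr::write_tsv(bed, path(paste0(ty, ".bed")), col_names = FALSE)
  }
  readr::write_tsv(qtl$ld, path("ld.tsv"))
  ann_bed <- qtl$annotation |>
    transmute(
      chrom = .data$chrom, start = .data$start - 1L, end = .data$end,
      gene = .data$gene, score = 0L, strand = "+"
    )
  readr::write_tsv(ann_bed, path("genes.bed"), col_names = FALSE)
  readr::write_tsv(expr, path("expression.tsv"))
  readr::write_tsv(drugs, path("drug_targets.tsv"))
  readr::write_csv(ehr$patients, path("patients.csv"))
  readr::write_csv(ehr$diagnoses, path("diagnoses.csv"))
  readr::write_csv(ehr$prescriptions, path("prescriptions.csv"))

  invisible(list(
    ppi = path("ppi_edges.tsv"),
    labels = path("planted_modules.tsv"),
    gwas = path("gwas.tsv"),
    eqtl = path("eqtl.tsv"), pqtl = path("pqtl.tsv"),
    sqtl = path("sqtl.tsv"),
    meqtl = path("meqtl.bed"), haqtl = path("haqtl.bed"),
    ld = path("ld.tsv"),
    genes = path("genes.bed"),
    expression = path("expression.tsv"),
    drug_targets = path("drug_targets.tsv"),
    patients = path("patients.csv"),
    diagnoses = path("diagnoses.csv"),
    prescriptions = path("prescriptions.csv")
  ))
}
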