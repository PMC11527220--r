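variants_tbl <- function(snp, chrom, pos, p) {
  tibble::tibble(snp_id = snp, chrom = chrom, pos = pos, pvalue = p)
}

test_that("GWAS p-value filter is strict and order-stable", {
  v <- variants_tbl(
    c("rs1", "rs2"), c("1", "1"), c(100L, 200L), c(1e-6, 1e-4)
  )
  kept <- filter_gwas_snps(v, 1e-5)
  expect_equal(kept$snp_id, "rs1")

  all_half <- variants_tbl(paste0("rs", 1:4), "1", 1:4 * 100L, rep(0.5, 4))
  expect_equal(nrow(filter_gwas_snps(all_half, 1e-5)), 0L)

  sim <- withr::with_seed(5, variants_tbl(
    sprintf("rs%04d", 1:1000), sample(c("1", "2"), 1000, TRUE),
    sample.int(1e6, 1000), runif(1000)
  ))
  expect_equal(
    nrow(filter_gwas_snps(sim, 0.01)),
    sum(sim$pvalue < 0.01)
  )
})

test_that("read_gwas rejects invalid p and keeps the minimum across studies", {
  f1 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    snp = c("rs1", "rs2", "rs3"), chr = "1", pos = c(10L, 20L, 30L),
    p = c("1e-6", "oops", "0.2")
  ), f1)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    snp = "rs1", chr = "1", pos = 10L, p = "1e-8"
  ), f2)
  expect_warning(g <- read_gwas(c(f1, f2)), "rejected")
  expect_equal(g$pvalue[g$snp_id == "rs1"], 1e-8)
  expect_false("rs2" %in% g$snp_id)
})

test_that("LD clumping follows the greedy window rule", {
  v <- variants_tbl(
    c("S1", "S2", "S3"), "1", c(100000L, 150000L, 2000000L),
    c(1e-9, 1e-7, 1e-6)
  )
  ld <- tibble::tibble(
    snp_a = c("S1", "S1"), snp_b = c("S2", "S3"), r2 = c(0.5, 0.9)
  )
  leads <- ld_clump(v, ld, r2_cutoff = 0.1, window_bp = 1e6)
  # S2 clumped under S1; S3 correlated but outside the 1 Mb window
  expect_setequal(leads$snp_id, c("S1", "S3"))

  single <- ld_clump(v[1, ], ld)
  expect_equal(single$snp_id, "S1")

  indep <- ld_clump(
    variants_tbl(c("A", "B"), "1", c(100L, 200L), c(1e-8, 1e-7)),
    tibble::tibble(snp_a = "A", snp_b = "B", r2 = 0.05)
  )
  expect_equal(nrow(indep), 2L)
})

test_that("clumping matches an independent greedy oracle and its invariants", {
  sim <- withr::with_seed(11, {
    n <- 40
    v <- variants_tbl(
      sprintf("rs%02d", 1:n),
      sample(c("1", "2"), n, TRUE),
      sample.int(3e6, n),
      runif(n)^3
    )
    pairs <- t(combn(v$snp_id, 2))
    take <- sample.int(nrow(pairs), 120)
    list(v = v, ld = tibble::tibble(
      snp_a = pairs[take, 1], snp_b = pairs[take, 2],
      r2 = runif(120)
    ))
  })
  leads <- ld_clump(sim$v, sim$ld, r2_cutoff = 0.2, window_bp = 5e5)
  oracle <- oracle_clump(
    sim$v$snp_id, sim$v$chrom, sim$v$pos, sim$v$pvalue,
    sim$ld, 0.2, 5e5
  )
  expect_setequal(leads$snp_id, oracle)
  # every removed variant is accounted for by some lead
  expect_equal(nrow(sim$v), nrow(leads) + sum(leads$clumped_n))
  # no two leads on the same chromosome within the window are correlated
  env_pairs <- merge(leads, leads, by = NULL)
  for (i in seq_len(nrow(env_pairs))) {
    a <- env_pairs[i, ]
    if (a$snp_id.x >= a$snp_id.y || a$chrom.x != a$chrom.y) next
    if (abs(a$pos.x - a$pos.y) > 5e5) next
    r2 <- sim$ld$r2[(sim$ld$snp_a == a$snp_id.x & sim$ld$snp_b == a$snp_id.y) |
      (sim$ld$snp_a == a$snp_id.y & sim$ld$snp_b == a$snp_id.x)]
    expect_true(length(r2) == 0 || r2 <= 0.2)
  }
})

test_that("proxy lookup uses a strict r2 bound", {
  ld <- tibble::tibble(
    snp_a = c("L", "L"), snp_b = c("C1", "C2"), r2 = c(0.85, 0.8)
  )
  px <- find_proxy_snps("L", c("C1", "C2"), ld, 0.8)
  expect_equal(px$proxy, "C1") # 0.8 exactly is not a proxy

  sim <- withr::with_seed(3, {
    leads <- sprintf("L%02d", 1:5)
    cands <- sprintf("C%02d", 1:10)
    grid <- expand.grid(a = leads, b = cands, stringsAsFactors = FALSE)
    take <- sample.int(nrow(grid), 50)
    tibble::tibble(
      snp_a = grid$a[take], snp_b = grid$b[take], r2 = runif(50)
    )
  })
  px2 <- find_proxy_snps(sprintf("L%02d", 1:5), sprintf("C%02d", 1:10),
    sim, 0.8)
  # exhaustive oracle
  expected <- sim[sim$r2 > 0.8, ]
  expect_equal(nrow(px2), nrow(expected))
  expect_setequal(
    paste(px2$lead, px2$proxy),
    paste(expected$snp_a, expected$snp_b)
  )
})

test_that("SNP-QTL join emits distinct triples present in both sources", {
  gwas <- tibble::tibble(snp_id = "rs1")
  qtls <- tibble::tibble(
    snp_id = c("rs1", "rs2"), qtl_type = "eQTL", gene = c("G1", "G2")
  )
  out <- map_snp_qtl_genes(gwas, qtls)
  expect_equal(out, tibble::tibble(
    snp_id = "rs1", qtl_type = "eQTL", gene = "G1"
  ))

  expect_equal(nrow(map_snp_qtl_genes(
    tibble::tibble(snp_id = "rsX"), qtls
  )), 0L)

  sim <- withr::with_seed(9, list(
    gwas = tibble::tibble(snp_id = sample(sprintf("rs%02d", 1:30), 15)),
    qtls = tibble::tibble(
      snp_id = sample(sprintf("rs%02d", 1:30), 100, TRUE),
      qtl_type = sample(c("eQTL", "pQTL", "sQTL"), 100, TRUE),
      gene = sample(sprintf("G%02d", 1:20), 100, TRUE)
    )
  ))
  out2 <- map_snp_qtl_genes(sim$gwas, sim$qtls)
  # nested-loop join oracle
  expected <- unique(do.call(rbind, lapply(seq_len(nrow(sim$qtls)),
    function(i) {
      q <- sim$qtls[i, ]
      if (q$snp_id %in% sim$gwas$snp_id) q else NULL
    })))
  expect_equal(nrow(out2), nrow(expected))
  expect_setequal(
    paste(out2$snp_id, out2$qtl_type, out2$gene),
    paste(expected$snp_id, expected$qtl_type, expected$gene)
  )
})

test_that("nearest-gene assignment handles overlap, gaps and ties", {
  ann <- tibble::tibble(
    chrom = "1", start = c(150L, 500L), end = c(300L, 600L),
    gene = c("G1", "G2")
  )
  reg <- tibble::tibble(
    chrom = "1", start = 100L, end = 200L, snp_id = "rs1",
    qtl_type = "meQTL"
  )
  out <- map_region_nearest_gene(reg, ann)
  expect_equal(out$gene, "G1")
  expect_equal(out$distance, 0)

  ann2 <- tibble::tibble(
    chrom = "1", start = c(50L, 205L), end = c(90L, 260L),
    gene = c("G1", "G2")
  )
  out2 <- map_region_nearest_gene(reg, ann2)
  expect_equal(out2$gene, "G2") # distance 5 beats 10
  expect_equal(out2$distance, 5)

  ann3 <- tibble::tibble(
    chrom = "1", start = c(50L, 205L), end = c(95L, 260L),
    gene = c("GB", "GA")
  )
  expect_message(out3 <- map_region_nearest_gene(reg, ann3), "equidistant")
  expect_equal(out3$gene, "GA") # lexicographic tie-break

  expect_warning(
    none <- map_region_nearest_gene(
      reg |> dplyr::mutate(chrom = "7"), ann
    ),
    "absent"
  )
  expect_equal(nrow(none), 0L)
})

test_that("BED readers convert half-open coordinates on the way in", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t99\t200\trs1", bed)
  r <- read_bed_regions(bed, "haQTL")
  expect_equal(r$start, 100L)
  expect_equal(r$end, 200L)

  gbed <- withr::local_tempfile(fileext = ".bed")
  writeLines("1\t149\t300\tg1\t0\t+", gbed)
  a <- read_gene_annotation(gbed)
  expect_equal(a$start, 150L)
  expect_equal(a$gene, "G1")
})

test_that("regulatory summary counts types, genes and percentages", {
  conn <- tibble::tibble(
    snp_id = c("rs1", "rs1", "rs2"),
    qtl_type = c("eQTL", "meQTL", "eQTL"),
    gene = c("G1", "G1", "G2")
  )
  s <- build_regulatory_table(conn)
  expect_equal(length(s$genes), 2L)
  expect_equal(s$n_connections, 3L)
  expect_equal(s$gene_types$n_types[s$gene_types$gene == "G1"], 2L)

  s0 <- build_regulatory_table(conn[0, ])
  expect_equal(s0$n_connections, 0L)
  expect_equal(length(s0$genes), 0L)

  sim <- withr::with_seed(2, tibble::tibble(
    snp_id = sample(sprintf("rs%02d", 1:40), 200, TRUE),
    qtl_type = sample(c("eQTL", "pQTL", "sQTL", "meQTL", "haQTL"), 200, TRUE),
    gene = sample(sprintf("G%02d", 1:30), 200, TRUE)
  )) |> dplyr::distinct()
  s2 <- build_regulatory_table(sim)
  expect_equal(sum(s2$type_counts$pct), 100, tolerance = 1e-9)
  expect_equal(sum(s2$type_counts$n), nrow(sim))
})
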