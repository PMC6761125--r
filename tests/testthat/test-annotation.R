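test_that("GFF3 and BED coordinates convert to the 0-based half-open convention", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t101\t200\t.\t+\t.\tID=g1",
    "chr1\tsrc\tgene\t301\t400\t.\t-\t.\tID=g2"
  ), gff)
  g <- load_annotation(gff)
  expect_equal(g$start[g$gene_id == "g1"], 100)
  expect_equal(g$end[g$gene_id == "g1"], 200)
  expect_equal(g$tss[g$gene_id == "g1"], 100)
  expect_equal(g$tes[g$gene_id == "g1"], 199)
  # minus strand: TSS at the right edge
  expect_equal(g$tss[g$gene_id == "g2"], 399)
  expect_equal(g$tes[g$gene_id == "g2"], 300)

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200\tg1\t0\t-", bed)
  b <- load_annotation(bed)
  expect_equal(b$tss, 199)
  expect_equal(b$tes, 100)
})

test_that("annotation write -> load round-trips a generated fixture", {
  sim <- gen_annotation(small_cfg(seed = 1, n_genes = 30))
  path <- tempfile(fileext = ".gff3")
  write_gff3(sim$genes, path)
  back <- load_annotation(path)
  cols <- c("gene_id", "chrom", "start", "end", "strand", "tss", "tes", "biotype")
  expect_equal(as.data.frame(back[cols]), as.data.frame(sim$genes[cols]),
               ignore_attr = TRUE)
  expect_setequal(gene_features(back)$kind, gene_features(sim$genes)$kind)
  # byte-identical rewrite
  path2 <- tempfile(fileext = ".gff3")
  write_gff3(gen_annotation(small_cfg(seed = 1, n_genes = 30))$genes, path2)
  expect_identical(readLines(path), readLines(path2))

  bed <- tempfile(fileext = ".bed")
  write_bed(sim$genes, bed)
  back_bed <- load_annotation(bed)
  cols_bed <- c("gene_id", "chrom", "start", "end", "strand", "tss", "tes")
  expect_equal(as.data.frame(back_bed[cols_bed]),
               as.data.frame(sim$genes[cols_bed]), ignore_attr = TRUE)
})

test_that("invalid annotations are rejected", {
  expect_error(as_gene_model(tibble::tibble(
    gene_id = "g", chrom = "c", start = 10L, end = 10L, strand = "+"
  )), "end <= start")
  expect_error(as_gene_model(tibble::tibble(
    gene_id = c("g", "g"), chrom = "c", start = c(1L, 5L), end = c(4L, 9L),
    strand = "+"
  )), "duplicate")
})

test_that("neighbor contexts classify orientation and measure the 244 bp gap", {
  ctx <- neighbor_contexts(tiny_genes())
  # tandem pair gA -> gB: upstream gene ends at 3000, downstream TSS at 3244
  up_b <- ctx[ctx$gene_id == "gB" & ctx$side == "upstream", ]
  expect_equal(up_b$neighbor_id, "gA")
  expect_equal(up_b$pair_class, "tandem")
  expect_equal(up_b$intergenic_distance, 244L)
  expect_equal(up_b$tss_to_border, 244L)
  # gC(-) with left neighbor gB(+): tail-to-tail = convergent, and it is gC's
  # DOWNSTREAM side; gD(+) with left neighbor gC(-): head-to-head = divergent
  expect_equal(ctx$pair_class[ctx$gene_id == "gC" & ctx$side == "downstream"], "convergent")
  expect_equal(ctx$pair_class[ctx$gene_id == "gD" & ctx$side == "upstream"], "divergent")
  # symmetry: gA downstream-tandem of gB's upstream, equal distance
  down_a <- ctx[ctx$gene_id == "gA" & ctx$side == "downstream", ]
  expect_equal(down_a$neighbor_id, "gB")
  expect_equal(down_a$pair_class, "tandem")
  expect_equal(down_a$intergenic_distance, 244L)
  # max_distance drops far neighbors
  ctx2 <- neighbor_contexts(tiny_genes(), max_distance = 100)
  expect_true(is.na(ctx2$neighbor_id[ctx2$gene_id == "gB" & ctx2$side == "upstream"]))
})

test_that("neighbor contexts are symmetric for tandem pairs on generated genomes", {
  sim <- gen_annotation(small_cfg(seed = 4, n_genes = 80))
  ctx <- neighbor_contexts(sim$genes)
  up <- ctx[ctx$side == "upstream" & !is.na(ctx$neighbor_id) & ctx$pair_class == "tandem", ]
  for (i in seq_len(nrow(up))) {
    mirror <- ctx[ctx$gene_id == up$neighbor_id[i] & ctx$side == "downstream", ]
    expect_equal(mirror$neighbor_id, up$gene_id[i])
    expect_equal(mirror$intergenic_distance, up$intergenic_distance[i])
    expect_equal(mirror$pair_class, "tandem")
  }
})

test_that("planted tandem structure is recovered from generator bookkeeping", {
  cfg <- sim_config(seed = 8, n_genes = 200, fraction_tandem = 1,
                    protected = list(fraction = 0, tandem_prob = 0.74,
                                     intergenic_meanlog = log(244),
                                     intergenic_sdlog = 0.5,
                                     upstream_expression_boost = 1.32,
                                     lfc = -1.5))
  sim <- gen_annotation(cfg)
  ctx <- neighbor_contexts(sim$genes)
  with_nb <- ctx[!is.na(ctx$neighbor_id), ]
  expect_true(all(with_nb$pair_class == "tandem"))

  # planted upstream same-strand flags match the contexts exactly
  sim2 <- gen_annotation(small_cfg(seed = 2))
  ctx2 <- neighbor_contexts(sim2$genes)
  up2 <- ctx2[ctx2$side == "upstream", ]
  up2 <- up2[match(sim2$truth$gene_id, up2$gene_id), ]
  has_nb <- !is.na(up2$neighbor_id)
  expect_equal(up2$orientation[has_nb] == "same_strand",
               sim2$truth$up_same_strand[has_nb])
  expect_equal(up2$intergenic_distance[has_nb], as.integer(sim2$truth$up_gap[has_nb]))
})

test_that("peak annotation follows the category precedence exactly", {
  genes <- tiny_genes()
  # explicit sub-features for gA: 5'UTR 1000-1100, exons 1000-1900/2100-3000,
  # intron 1900-2100, 3'UTR 2900-3000
  feats <- tibble::tibble(
    gene_id = "gA",
    kind = c("five_prime_UTR", "exon", "exon", "three_prime_UTR"),
    start = c(1000L, 1000L, 2100L, 2900L),
    end = c(1100L, 1900L, 3000L, 3000L)
  )
  genes2 <- as_gene_model(genes, feats)
  # 10 summits walking every category; gB's promoter window is 2944..3243,
  # which also lies < 300 bp downstream of gA's TES (2999): promoter wins
  peaks <- tibble::tibble(
    chrom = "chr1",
    summit = c(
      3100L,  # promoter of gB (also immediate downstream of gA) -> promoter
      900L,   # 100 bp upstream of gA TSS -> promoter
      5400L,  # 156 bp downstream of gB TES (5243) -> immediate_downstream
      8100L,  # gC is minus: downstream of its TES (6000) is left; 8100 is
              # 101 bp upstream of gC TSS (7999) -> promoter
      5900L,  # 100 bp left of gC start: downstream of gC TES -> immediate_downstream
      1050L,  # inside gA 5'UTR -> five_prime_UTR
      2905L,  # inside gA 3'UTR (and clear of gB's promoter window) -> three_prime_UTR
      1500L,  # inside gA exon -> exon
      2000L,  # inside gA intron -> intron
      15000L  # far from everything -> intergenic
    ),
    name = paste0("p", 1:10), score = 1
  )
  peaks$start <- peaks$summit - 10L; peaks$end <- peaks$summit + 10L
  ann <- annotate_peaks(peaks, genes2, chrom_sizes = tiny_sizes)
  expect_equal(ann$category, c(
    "promoter", "promoter", "immediate_downstream", "promoter",
    "immediate_downstream", "five_prime_UTR", "three_prime_UTR",
    "exon", "intron", "intergenic"
  ))
  expect_equal(ann$assigned_gene[1:5], c("gB", "gA", "gB", "gC", "gC"))
  # genes without exon features: whole body is exon
  ann_plain <- annotate_peaks(
    tibble::tibble(chrom = "chr1", summit = 10000L, name = "p", score = 1,
                   start = 9990L, end = 10010L),
    genes, chrom_sizes = tiny_sizes
  )
  expect_equal(ann_plain$category, "exon")
  expect_equal(ann_plain$assigned_gene, "gD")
  # out-of-bounds summit rejected
  expect_error(annotate_peaks(
    tibble::tibble(chrom = "chr1", summit = 30000L, name = "x", score = 1,
                   start = 29990L, end = 30010L),
    genes, chrom_sizes = tiny_sizes
  ), "bounds")
})

test_that("peak annotation partitions peaks and breaks ties deterministically", {
  sim <- gen_annotation(small_cfg(seed = 6))
  sizes <- attr(sim$genes, "chrom_sizes")
  set.seed(1)
  pos <- sort(sample.int(sizes[["chr1"]], 400) - 1L)
  peaks <- tibble::tibble(chrom = "chr1", summit = pos,
                          start = pmax(0L, pos - 5L), end = pos + 5L,
                          name = paste0("p", seq_along(pos)), score = 1)
  ann <- annotate_peaks(peaks, sim$genes, chrom_sizes = sizes)
  expect_false(anyNA(ann$category))
  expect_equal(nrow(ann), 400)
  expect_true(all(ann$category %in% c("promoter", "immediate_downstream",
                                      "five_prime_UTR", "three_prime_UTR",
                                      "exon", "intron", "intergenic")))
  # a summit equidistant between two gene TSSs goes to the lexicographically
  # smaller gene id
  two <- as_gene_model(tibble::tibble(
    gene_id = c("gx", "gy"), chrom = "chr1",
    start = c(1000L, 1400L), end = c(1201L, 1600L), strand = c("-", "+")
  ))
  # summit 1300: 100 bp upstream of gy TSS (1400) and 100 bp upstream of gx
  # TSS (1200, minus strand, upstream is to the right)
  tie <- annotate_peaks(tibble::tibble(chrom = "chr1", summit = 1300L,
                                       start = 1290L, end = 1310L,
                                       name = "t", score = 1), two)
  expect_equal(tie$category, "promoter")
  expect_equal(tie$assigned_gene, "gx")
})

test_that("random-position enrichment is calibrated and flags extremes", {
  genes <- tiny_genes()
  expect_error(random_position_enrichment(
    tibble::tibble(chrom = "chr1", summit = 1L, start = 0L, end = 2L,
                   name = "p", score = 1),
    genes, tiny_sizes, n_samples = 0
  ), "n_samples")

  # all peaks in promoters of a dense genome: one-sided p at the floor
  sim <- gen_annotation(small_cfg(seed = 3))
  sizes <- attr(sim$genes, "chrom_sizes")
  plus <- sim$genes[sim$genes$strand == "+", ][1:40, ]
  peaks <- tibble::tibble(chrom = "chr1", summit = plus$tss - 50L,
                          start = plus$tss - 60L, end = plus$tss - 40L,
                          name = paste0("p", 1:40), score = 1)
  res <- random_position_enrichment(peaks, sim$genes, sizes,
                                    n_samples = 400, seed = 2)
  expect_equal(res$observed_fraction[res$category == "promoter"], 1)
  expect_lte(res$p_greater[res$category == "promoter"], 1 / (400 + 1))

  # uniformly random peaks: no category significant in most repetitions
  set.seed(99)
  n_sig <- sum(replicate(15, {
    pos <- sample.int(sizes[["chr1"]], 60) - 1L
    pk <- tibble::tibble(chrom = "chr1", summit = pos, start = pmax(0L, pos - 5L),
                         end = pos + 5L, name = paste0("r", 1:60), score = 1)
    r <- random_position_enrichment(pk, sim$genes, sizes, n_samples = 300,
                                    seed = sample.int(1e6, 1))
    any(r$empirical_p < 0.01)
  }))
  expect_lte(n_sig, 2)
})

test_that("expression groups are quantile-balanced with ties kept together", {
  expr <- tibble::tibble(gene_id = paste0("g", 1:18),
                         mean_expression = stats::rnorm(18))
  g <- expression_groups(expr, 9)
  expect_equal(as.integer(table(g$expression_group)), rep(2L, 9))
  expect_equal(sort(unique(g$expression_group)), 1:9)
  # every gene in exactly one group
  expect_equal(nrow(g), 18)

  # degenerate: all equal -> single populated group with a warning
  same <- tibble::tibble(gene_id = paste0("g", 1:10), mean_expression = 1)
  expect_warning(gs <- expression_groups(same, 3), "ties")
  expect_equal(unique(gs$expression_group), 1L)

  # tied boundary values share a group
  tied <- tibble::tibble(gene_id = paste0("g", 1:6),
                         mean_expression = c(1, 2, 2, 2, 3, 4))
  suppressWarnings(gt <- expression_groups(tied, 3))
  expect_equal(length(unique(gt$expression_group[tied$mean_expression == 2])), 1)

  expect_error(expression_groups(expr[1:3, ], 9), "groups")
})

test_that("not-DE control selection equals a brute-force row filter", {
  de <- tidyr::expand_grid(gene_id = paste0("g", 1:200),
                           contrast = paste0("c", 1:4))
  set.seed(5)
  de$log2fc <- stats::rnorm(nrow(de), 0, 0.3)
  de$pvalue <- stats::runif(nrow(de))
  de$padj <- bh_adjust(de$pvalue)
  de$basemean <- stats::rlnorm(nrow(de), 4, 2)
  sel <- select_not_de_controls(de)
  # independent brute-force filter
  brute <- vapply(unique(de$gene_id), function(g) {
    rows <- de[de$gene_id == g, ]
    nrow(rows) == 4 && all(rows$pvalue > 0.45) && all(abs(rows$log2fc) < 0.25) &&
      all(rows$basemean > 3) && all(rows$basemean < 1e5)
  }, logical(1))
  expect_setequal(sel, unique(de$gene_id)[brute])
  # single failing contrast excludes
  de2 <- de
  g1_first <- which(de2$gene_id == sel[1])[1]
  de2$pvalue[g1_first] <- 0.44
  expect_false(sel[1] %in% select_not_de_controls(de2))
  expect_error(select_not_de_controls(de, contrasts = "missing"), "missing")
})

test_that("expression-matched control selection matches the reference distribution", {
  set.seed(21)
  expr <- tibble::tibble(gene_id = paste0("g", 1:4000),
                         mean_expression = c(stats::rnorm(2000, 2, 1),
                                             stats::rnorm(2000, 4, 1)))
  reference <- expr$gene_id[1:2000]
  candidates <- expr$gene_id[2001:4000]
  # shifted candidates: matching beats raw candidates in KS distance
  expect_warning(
    matched <- select_expression_matched_controls(candidates, reference, expr,
                                                  n = 500, seed = 3),
    "exhausted"
  )
  ex <- stats::setNames(expr$mean_expression, expr$gene_id)
  d_matched <- ks_two_sample(ex[matched], ex[reference])$statistic
  d_raw <- ks_two_sample(ex[candidates], ex[reference])$statistic
  expect_lt(d_matched, d_raw)
  # determinism
  expect_identical(matched, suppressWarnings(
    select_expression_matched_controls(candidates, reference, expr,
                                       n = 500, seed = 3)
  ))
  # self-matching: per-bin counts follow reference proportions (+/- 1)
  ref2 <- expr$gene_id[1:1000]
  cand2 <- expr$gene_id[1:2000]
  m2 <- select_expression_matched_controls(cand2, ref2, expr, n = 200,
                                           n_bins = 10, seed = 5)
  brk <- stats::quantile(ex[ref2], seq(0, 1, 0.1))
  brk[1] <- -Inf; brk[11] <- Inf
  counts <- table(cut(ex[m2], brk))
  expect_true(all(abs(as.numeric(counts) - 20) <= 1))
  expect_error(select_expression_matched_controls(candidates[1:10], reference,
                                                  expr, n = 50), "candidates")
})

test_that("vectorized and general neighbor scans agree on disjoint genomes", {
  sim <- gen_annotation(small_cfg(seed = 16, n_genes = 60))
  key <- function(d) as.data.frame(
    d[order(d$gene_id, d$side),
      c("gene_id", "side", "neighbor_id", "pair_class",
        "intergenic_distance", "overlap", "tss_to_border")]
  )
  fast <- neighbor_contexts(sim$genes, use_fast_path = TRUE)
  general <- neighbor_contexts(sim$genes, use_fast_path = FALSE)
  expect_equal(key(fast), key(general), ignore_attr = TRUE)

  # overlapping fixture exercises the general scan: overlap flagged, distance 0
  ov <- as_gene_model(tibble::tibble(
    gene_id = c("o1", "o2"), chrom = "chr1",
    start = c(100L, 500L), end = c(700L, 1200L), strand = "+"
  ))
  ctx_ov <- neighbor_contexts(ov)
  row <- ctx_ov[ctx_ov$gene_id == "o2" & ctx_ov$side == "upstream", ]
  expect_true(row$overlap)
  expect_equal(row$intergenic_distance, 0L)
})
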