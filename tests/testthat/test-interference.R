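test_that("orientation fractions report planted context structure exactly", {
  ctx <- neighbor_contexts(tiny_genes())
  sets <- list(focal = "gB", other = "gD")
  fr <- orientation_fractions(sets, ctx, distance_cutoffs = c(300, Inf))
  # gB has a same-strand upstream neighbor at 244 bp
  expect_equal(fr$fraction[fr$set == "focal" & fr$side == "upstream" &
                             fr$orientation == "same_strand" &
                             fr$max_distance == 300], 1)
  # gD's upstream neighbor is divergent: same-strand fraction 0
  expect_equal(fr$fraction[fr$set == "other" & fr$side == "upstream" &
                             fr$orientation == "same_strand" &
                             fr$max_distance == Inf], 0)
  # distance cutoff below every intergenic distance empties the fractions
  fr0 <- orientation_fractions(sets, ctx, distance_cutoffs = 10)
  expect_true(all(fr0$fraction[fr0$set == "focal"] == 0))
  # empty set comes back NA
  fr_empty <- orientation_fractions(list(none = character(0)), ctx, Inf)
  expect_true(all(is.na(fr_empty$fraction[fr_empty$set == "none"])))

  # planted genome: protected-set same-strand-upstream fraction matches the
  # generator bookkeeping exactly
  sim <- gen_annotation(small_cfg(seed = 27, n_genes = 200))
  ctx2 <- neighbor_contexts(sim$genes)
  prot <- sim$truth$gene_id[sim$truth$role == "protected"]
  fr2 <- orientation_fractions(list(protected = prot), ctx2, Inf)
  planted <- mean(sim$truth$planted_up_same_strand[sim$truth$role == "protected"])
  got <- fr2$fraction[fr2$set == "protected" & fr2$side == "upstream" &
                        fr2$orientation == "same_strand"]
  expect_equal(got, planted)
})

test_that("distance distributions: planted medians recovered, KS against background", {
  cfg <- small_cfg(seed = 29, n_genes = 300)
  sim <- gen_annotation(cfg)
  ctx <- neighbor_contexts(sim$genes)
  prot <- sim$truth$gene_id[sim$truth$role == "protected"]
  res <- distance_distribution_tests(list(protected = prot), ctx)
  # planted truth: the median gap of protected genes from the bookkeeping
  planted_median <- stats::median(sim$truth$gap_before[sim$truth$role == "protected" &
                                                         sim$truth$up_same_strand])
  expect_equal(res$median_bp[res$set == "protected"], planted_median)
  # short-distance planting is detected against the background
  expect_lt(res$median_bp, attr(res, "background_median"))
  expect_lt(res$padj[res$set == "protected"], 0.05)
  # a set drawn from the background is not significant (calibration)
  set.seed(4)
  bg_ids <- sample(sim$truth$gene_id[sim$truth$role == "normal"], 60)
  res_bg <- distance_distribution_tests(list(bg = bg_ids), ctx)
  expect_gt(res_bg$p_value, 0.01)
  # too-small sets come back NA
  res_na <- distance_distribution_tests(list(tiny = prot[1:2]), ctx)
  expect_true(is.na(res_na$p_value))
})

test_that("upstream expression tests detect the planted boost", {
  cfg <- small_cfg(seed = 31, n_genes = 400)
  sim <- gen_annotation(cfg)
  ctx <- neighbor_contexts(sim$genes)
  expr <- tibble::tibble(gene_id = sim$truth$gene_id,
                         mean_expression = sim$truth$expression)
  prot <- sim$truth$gene_id[sim$truth$role == "protected"]
  normal <- sim$truth$gene_id[sim$truth$role == "normal" &
                                !sim$truth$is_upstream_of_protected]
  res <- upstream_expression_test(list(protected = prot, normal = normal),
                                  ctx, expr)
  # upstream neighbors of protected genes are boosted by +1.32 log2
  expect_gt(res$median_ref - res$median_set, 0.6)
  expect_lt(res$p_value, 0.01)
  # identical sets are not significant
  res_same <- upstream_expression_test(list(a = normal, b = normal), ctx, expr)
  expect_equal(res_same$p_value, 1, tolerance = 1e-6)
})

test_that("loop enrichment finds the planted context", {
  cfg <- sim_config(seed = 37, n_genes = 600,
                    loops = list(base_rate = 0.1, protected_upstream_rate = 1))
  sim <- gen_annotation(cfg)
  ctx <- neighbor_contexts(sim$genes)
  loops <- gen_loops(cfg, sim$truth)
  prot <- sim$truth$gene_id[sim$truth$role == "protected"]
  rep_ <- sim$truth$gene_id[sim$truth$role == "repressed"]
  res <- loop_enrichment(list(protected = prot, repressed = rep_), ctx, loops,
                         alternative = "greater")
  # rate-1 planting in the upstream-tandem context makes it the top context
  expect_equal(res$context[which.min(res$padj)], "protected.upstream.same_strand")
  # loop set = all genes: odds ratio degenerate, p = 1
  all_loop <- suppressWarnings(
    loop_enrichment(list(p = prot), ctx, unique(ctx$gene_id))
  )
  expect_true(all(all_loop$p_value == 1))
})

test_that("TI-up selection walks every threshold with strict inequalities", {
  # 6 handcrafted pairs: 2 qualify for the up arm, 2 for the not-DE arm,
  # 1 fails the distance cutoff, 1 fails the pre-existing-TI filter
  pairs <- tibble::tibble(
    up_gene = paste0("u", 1:6), down_gene = paste0("d", 1:6),
    intergenic_distance = c(100L, 200L, 300L, 400L, 700L, 150L)
  )
  light_cts <- c("wt_light2_vs_dark", "wt_light4_vs_dark",
                 "mut_light2_vs_dark", "mut_light4_vs_dark")
  mk_de <- function(gene, lfc, padj, p = padj) {
    tidyr::expand_grid(gene_id = gene, contrast = light_cts) |>
      dplyr::mutate(log2fc = lfc, pvalue = p, padj = padj, basemean = 100)
  }
  de <- dplyr::bind_rows(
    mk_de("u1", 1.5, 0.01),          # up arm (FC ~2.8)
    mk_de("u2", 1.2, 0.001),         # up arm (FC ~2.3)
    mk_de("u3", 0.1, 0.9),           # not-DE arm
    mk_de("u4", -0.2, 0.5),          # not-DE arm
    mk_de("u5", 2.0, 0.01),          # would be up arm but distance 700 >= 600
    mk_de("u6", 1.5, 0.01),          # up arm thresholds met, but pre-existing TI
    mk_de(paste0("d", 1:6), 0, 0.9),
    # mutant/wt ratios: d6 is already down in the dark (pre-existing TI)
    tidyr::expand_grid(gene_id = paste0("d", 1:6),
                       contrast = c("mut_vs_wt_dark", "mut_vs_wt_light2",
                                    "mut_vs_wt_light4")) |>
      dplyr::mutate(log2fc = ifelse(gene_id == "d6", -1, 0),
                    pvalue = ifelse(gene_id == "d6", 0.001, 0.8),
                    padj = pvalue, basemean = 100)
  )
  sel <- select_ti_up(pairs, de)
  expect_setequal(sel$up_gene[sel$arm == "up_regulated"], c("u1", "u2"))
  expect_setequal(sel$up_gene[sel$arm == "up_not_de"], c("u3", "u4"))
  expect_false("u5" %in% sel$up_gene)
  expect_false("u6" %in% sel$up_gene)
  expect_true(all(c("ratio_mut_vs_wt_dark", "ratio_mut_vs_wt_light2") %in% names(sel)))

  # boundary audit: FC exactly 2 is excluded by the strict > 2
  de_b <- dplyr::bind_rows(mk_de("u1", 1, 0.01), mk_de("d1", 0, 0.9),
                           tidyr::expand_grid(gene_id = "d1",
                                              contrast = c("mut_vs_wt_dark",
                                                           "mut_vs_wt_light2",
                                                           "mut_vs_wt_light4")) |>
                             dplyr::mutate(log2fc = 0, pvalue = 0.8,
                                           padj = 0.8, basemean = 100))
  sel_b <- select_ti_up(pairs[1, ], de_b)
  expect_false("up_regulated" %in% sel_b$arm)
  # padj exactly 0.05 excluded by the strict < 0.05
  de_p <- de_b; de_p$log2fc[de_p$gene_id == "u1"] <- 1.5
  de_p$padj[de_p$gene_id == "u1"] <- 0.05
  expect_false("up_regulated" %in% select_ti_up(pairs[1, ], de_p)$arm)
  # not-DE: padj exactly 0.2 excluded by the strict > 0.2
  de_n <- de_b; de_n$log2fc[de_n$gene_id == "u1"] <- 0
  de_n$padj[de_n$gene_id == "u1"] <- 0.2
  expect_false("up_not_de" %in% select_ti_up(pairs[1, ], de_n)$arm)
  expect_error(select_ti_up(pairs, de[de$contrast != "mut_vs_wt_dark", ]),
               "missing")
})

test_that("TI-relief selection requires dark TI evidence and the relief arm", {
  pairs <- tibble::tibble(up_gene = c("u1", "u2"), down_gene = c("d1", "d2"),
                          intergenic_distance = c(100L, 100L))
  light_cts <- c("wt_light2_vs_dark", "wt_light4_vs_dark",
                 "mut_light2_vs_dark", "mut_light4_vs_dark")
  mk <- function(gene, lfc, padj) {
    tidyr::expand_grid(gene_id = gene, contrast = light_cts) |>
      dplyr::mutate(log2fc = lfc, pvalue = padj, padj = padj, basemean = 100)
  }
  ratios <- function(gene, dark_lfc, dark_p) {
    tidyr::expand_grid(gene_id = gene,
                       contrast = c("mut_vs_wt_dark", "mut_vs_wt_light2",
                                    "mut_vs_wt_light4")) |>
      dplyr::mutate(log2fc = dark_lfc, pvalue = dark_p, padj = dark_p,
                    basemean = 100)
  }
  de <- dplyr::bind_rows(
    mk("u1", -1, 0.01),             # downregulated upstream (FC 2 > 1.5)
    mk("u2", -1, 0.01),
    ratios("d1", -0.8, 0.01),       # dark TI evidence
    ratios("d2", -0.8, 0.05)        # p exactly 0.05: excluded by strict <
  )
  sel <- select_ti_relief(pairs, de)
  expect_equal(sel$down_gene, "d1")
  expect_equal(sel$arm, "up_downregulated")
})

test_that("TI ratio tests match sign-pattern enumeration", {
  sel <- tibble::tibble(
    up_gene = paste0("u", 1:3), down_gene = paste0("d", 1:3),
    intergenic_distance = 100L, arm = "up_regulated",
    passes_preexisting_TI_filter = TRUE,
    ratio_mut_vs_wt_dark = c(0, 0, 0),
    ratio_mut_vs_wt_light2 = c(-1, -2, -3),
    ratio_mut_vs_wt_light4 = c(0, 0, 0)
  )
  res <- suppressWarnings(ti_ratio_tests(sel, alternative = "less"))
  # paired deltas [-1,-2,-3]: one-sided exact p = 1/8
  expect_equal(res$p_value[res$comparison == "ratio_mut_vs_wt_light2"], 1 / 8)
  # identical conditions: one-sided p >= 0.5 (all-zero convention p = 1)
  expect_gte(suppressWarnings(
    res$p_value[res$comparison == "ratio_mut_vs_wt_light4"]
  ), 0.5)
})

test_that("light-induced distance analysis separates only the planted bin", {
  cfg <- sim_config(seed = 47, n_genes = 600)
  sim <- gen_annotation(cfg)
  ctx <- neighbor_contexts(sim$genes)
  det <- gen_de_tables(cfg, sim$truth, seed = 48)
  lu <- select_light_upregulated(det$de)
  res <- light_induced_distance_analysis(lu, ctx, det$de)
  light_rows <- res[res$condition != "mut_vs_wt_dark" & res$distance_bin == "<600", ]
  # planted TI pulls same-strand medians below opposite-strand medians in light
  expect_true(all(light_rows$median_same < light_rows$median_opposite,
                  na.rm = TRUE))
  # sides below min_n are NA
  res_small <- light_induced_distance_analysis(lu[1:3], ctx, det$de)
  expect_true(all(is.na(res_small$p_value)))
})

test_that("planted light-dependent TI moves the up-regulated arm only", {
  res <- purrr::map_dfr(1:10, function(s) {
    cfg <- sim_config(seed = 900 + s, n_genes = 800,
                      light = list(up_fraction = 0.25, down_fraction = 0.10,
                                   lfc = 2, ti_effect = -1, relief_effect = 1,
                                   d_max = 600, ti_scope = "upstream_induced"))
    sim <- gen_annotation(cfg)
    ctx <- neighbor_contexts(sim$genes)
    det <- gen_de_tables(cfg, sim$truth, seed = 90000 + s)
    sel <- select_ti_up(tandem_pairs(ctx), det$de)
    suppressWarnings(ti_ratio_tests(sel, alternative = "less"))
  })
  up <- res[res$arm == "up_regulated", ]
  ctrl <- res[res$arm == "up_not_de", ]
  # both arms populated and the effect confined to the up-regulated arm
  expect_true(all(up$n >= 5))
  expect_true(all(ctrl$n >= 20))
  expect_gte(mean(up$p_value < 0.05), 0.9)
  expect_gte(mean(ctrl$p_value > 0.1), 0.8)
  expect_lt(median(up$median_delta), -0.5)

  # relief planting: downregulating the upstream gene raises the downstream
  # mutant/wt ratio under light
  relief <- purrr::map_dfr(1:5, function(s) {
    cfg <- sim_config(seed = 950 + s, n_genes = 800)
    sim <- gen_annotation(cfg)
    ctx <- neighbor_contexts(sim$genes)
    det <- gen_de_tables(cfg, sim$truth, seed = 95000 + s)
    sel <- select_ti_relief(tandem_pairs(ctx), det$de)
    sel[sel$arm == "up_downregulated", ]
  })
  delta <- relief$ratio_mut_vs_wt_light2 - relief$ratio_mut_vs_wt_dark
  expect_gt(median(delta, na.rm = TRUE), 0.25)
})
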