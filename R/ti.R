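#' @title Light-modulated transcriptional interference procedures
#'
#' @description Selection and testing procedures for detecting
#' transcriptional interference (TI) at closely spaced tandem gene pairs when
#' the upstream gene's expression is re-leveled by light. The expected
#' differential-expression contrast names are:
#'
#' * `wt_light2_vs_dark`, `wt_light4_vs_dark`, `mut_light2_vs_dark`,
#'   `mut_light4_vs_dark` - light response per genotype and time point;
#' * `mut_vs_wt_dark`, `mut_vs_wt_light2`, `mut_vs_wt_light4` - mutant/wild-type
#'   ratio per condition.
#'
#' All thresholds are strict inequalities exactly as stated (fold-changes on
#' the linear scale, i.e. "fold-change > 2" means |log2FC| > 1 in the stated
#' direction).
#'
#' @name ti
NULL

de_lookup <- function(de, contrasts) {
  missing <- setdiff(contrasts, unique(de$contrast))
  if (length(missing) > 0) stop("missing contrast(s): ", paste(missing, collapse = ", "))
  de |>
    dplyr::filter(.data$contrast %in% contrasts) |>
    dplyr::select("gene_id", "contrast", "log2fc", "pvalue", "padj") |>
    tidyr::pivot_wider(names_from = "contrast",
                       values_from = c("log2fc", "pvalue", "padj"))
}

ratio_columns <- function(de, genes, ratio_contrasts) {
  wide <- de_lookup(de, ratio_contrasts)
  out <- tibble::tibble(gene_id = genes)
  for (ct in ratio_contrasts) {
    out[[paste0("ratio_", ct)]] <- wide[[paste0("log2fc_", ct)]][match(genes, wide$gene_id)]
  }
  out
}

#' Select tandem pairs with light-upregulated (or unchanged) upstream genes
#'
#' From tandem pairs closer than `d_max` bp, selects two arms by the behavior
#' of the upstream gene under light in both genotypes and at both time points:
#'
#' * `up_regulated`: log2FC > log2(`up_fc_min`) and padj < `up_padj_max` in
#'   all four light contrasts;
#' * `up_not_de`: |log2FC| < log2(`nde_fc_max`) and padj > `nde_p_min` in all
#'   four light contrasts.
#'
#' Pairs whose downstream gene already shows evidence of TI in darkness
#' (mutant-vs-wt dark raw p < `preexist_p` with negative log2FC) are removed
#' from both arms. The per-condition log2(mutant/wt) of the downstream gene is
#' attached.
#'
#' @param pairs tibble from [tandem_pairs()].
#' @param de long DE tibble (`gene_id`, `contrast`, `log2fc`, `pvalue`,
#'   `padj`).
#' @param d_max maximum intergenic distance (strict <).
#' @param up_fc_min,up_padj_max upregulated-arm thresholds (linear FC, padj).
#' @param nde_fc_max,nde_p_min not-DE-arm thresholds (linear FC, padj).
#' @param preexist_p raw-p threshold of the pre-existing-TI filter.
#' @param light_contrasts the four light-response contrast names.
#' @param dark_ratio_contrast,ratio_contrasts mutant/wt contrast names.
#' @return tibble `up_gene`, `down_gene`, `intergenic_distance`, `arm`,
#'   `passes_preexisting_TI_filter`, and one `ratio_*` column per condition.
#' @export
select_ti_up <- function(pairs, de, d_max = 600, up_fc_min = 2,
                         up_padj_max = 0.05, nde_fc_max = 1.5, nde_p_min = 0.2,
                         preexist_p = 0.05,
                         light_contrasts = c("wt_light2_vs_dark", "wt_light4_vs_dark",
                                             "mut_light2_vs_dark", "mut_light4_vs_dark"),
                         dark_ratio_contrast = "mut_vs_wt_dark",
                         ratio_contrasts = c("mut_vs_wt_dark", "mut_vs_wt_light2",
                                             "mut_vs_wt_light4")) {
  sel <- pairs[pairs$intergenic_distance < d_max, ]
  wide <- de_lookup(de, light_contrasts)
  w <- wide[match(sel$up_gene, wide$gene_id), ]
  lfc <- as.matrix(w[, paste0("log2fc_", light_contrasts)])
  padj <- as.matrix(w[, paste0("padj_", light_contrasts)])
  up_arm <- rowSums(lfc > log2(up_fc_min) & padj < up_padj_max) == length(light_contrasts)
  nde_arm <- rowSums(abs(lfc) < log2(nde_fc_max) & padj > nde_p_min) == length(light_contrasts)
  up_arm[is.na(up_arm)] <- FALSE; nde_arm[is.na(nde_arm)] <- FALSE
  dark <- de_lookup(de, dark_ratio_contrast)
  di <- match(sel$down_gene, dark$gene_id)
  preexisting <- dark[[paste0("pvalue_", dark_ratio_contrast)]][di] < preexist_p &
    dark[[paste0("log2fc_", dark_ratio_contrast)]][di] < 0
  preexisting[is.na(preexisting)] <- FALSE
  out <- sel |>
    dplyr::mutate(
      arm = dplyr::case_when(up_arm ~ "up_regulated", nde_arm ~ "up_not_de",
                             TRUE ~ NA_character_),
      passes_preexisting_TI_filter = !preexisting
    ) |>
    dplyr::filter(!is.na(.data$arm), .data$passes_preexisting_TI_filter)
  dplyr::left_join(out, ratio_columns(de, out$down_gene, ratio_contrasts),
                   by = c(down_gene = "gene_id"))
}

#' Select tandem pairs probing TI relief
#'
#' From tandem pairs closer than `d_max` bp whose downstream gene shows
#' evidence of TI in darkness (mutant-vs-wt dark raw p < `ti_evidence_p` and
#' negative log2FC), selects pairs whose upstream gene is either downregulated
#' by light (log2FC < -log2(`down_fc_min`), padj < `down_padj_max`, in both
#' genotypes at 2 or at 4 h) or not differentially expressed (|log2FC| <
#' log2(`nde_fc_max`) and padj > `nde_p_min` in all four light contrasts).
#'
#' @inheritParams select_ti_up
#' @param down_fc_min,down_padj_max downregulated-arm thresholds.
#' @param ti_evidence_p raw-p threshold for dark TI evidence on the
#'   downstream gene.
#' @return tibble as in [select_ti_up()] with arms `up_downregulated` /
#'   `up_not_de`.
#' @export
select_ti_relief <- function(pairs, de, d_max = 600, down_fc_min = 1.5,
                             down_padj_max = 0.05, nde_fc_max = 1.5,
                             nde_p_min = 0.1, ti_evidence_p = 0.05,
                             light_contrasts = c("wt_light2_vs_dark", "wt_light4_vs_dark",
                                                 "mut_light2_vs_dark", "mut_light4_vs_dark"),
                             dark_ratio_contrast = "mut_vs_wt_dark",
                             ratio_contrasts = c("mut_vs_wt_dark", "mut_vs_wt_light2",
                                                 "mut_vs_wt_light4")) {
  sel <- pairs[pairs$intergenic_distance < d_max, ]
  dark <- de_lookup(de, dark_ratio_contrast)
  di <- match(sel$down_gene, dark$gene_id)
  ti_evidence <- dark[[paste0("pvalue_", dark_ratio_contrast)]][di] < ti_evidence_p &
    dark[[paste0("log2fc_", dark_ratio_contrast)]][di] < 0
  ti_evidence[is.na(ti_evidence)] <- FALSE
  sel <- sel[ti_evidence, ]
  wide <- de_lookup(de, light_contrasts)
  w <- wide[match(sel$up_gene, wide$gene_id), ]
  lfc <- as.matrix(w[, paste0("log2fc_", light_contrasts)])
  padj <- as.matrix(w[, paste0("padj_", light_contrasts)])
  # "at 2 or 4 h": both genotypes must pass at the same time point
  wt2 <- grep("wt_light2", light_contrasts); mut2 <- grep("mut_light2", light_contrasts)
  wt4 <- grep("wt_light4", light_contrasts); mut4 <- grep("mut_light4", light_contrasts)
  down_ok <- function(cols) {
    rowSums(lfc[, cols, drop = FALSE] < -log2(down_fc_min) &
              padj[, cols, drop = FALSE] < down_padj_max) == length(cols)
  }
  down_arm <- down_ok(c(wt2, mut2)) | down_ok(c(wt4, mut4))
  nde_arm <- rowSums(abs(lfc) < log2(nde_fc_max) & padj > nde_p_min) == length(light_contrasts)
  down_arm[is.na(down_arm)] <- FALSE; nde_arm[is.na(nde_arm)] <- FALSE
  out <- sel |>
    dplyr::mutate(arm = dplyr::case_when(down_arm ~ "up_downregulated",
                                         nde_arm ~ "up_not_de",
                                         TRUE ~ NA_character_),
                  passes_preexisting_TI_filter = TRUE) |>
    dplyr::filter(!is.na(.data$arm))
  dplyr::left_join(out, ratio_columns(de, out$down_gene, ratio_contrasts),
                   by = c(down_gene = "gene_id"))
}

#' Test the change of the mutant/wt ratio between dark and light
#'
#' Per selection arm, a Wilcoxon signed-rank test of the paired downstream-gene
#' log2(mutant/wt) values between darkness and each light time point.
#'
#' @param selection output of [select_ti_up()] or [select_ti_relief()].
#' @param dark_col,light_cols ratio column names.
#' @param alternative sidedness of light minus dark (default two-sided; use
#'   `"less"` for aggravated TI under light, `"greater"` for relief).
#' @return tibble per arm x comparison: `n`, `median_delta`, `statistic`,
#'   `p_value`.
#' @export
ti_ratio_tests <- function(selection, dark_col = "ratio_mut_vs_wt_dark",
                           light_cols = c("ratio_mut_vs_wt_light2",
                                          "ratio_mut_vs_wt_light4"),
                           alternative = "two_sided") {
  purrr::map_dfr(unique(selection$arm), function(a) {
    sub <- selection[selection$arm == a, ]
    purrr::map_dfr(light_cols, function(lc) {
      delta <- sub[[lc]] - sub[[dark_col]]
      delta <- delta[!is.na(delta)]
      if (length(delta) < 2) {
        return(tibble::tibble(arm = a, comparison = lc, n = length(delta),
                              median_delta = NA_real_, statistic = NA_real_,
                              p_value = NA_real_))
      }
      w <- wilcoxon_signed_rank(delta, alternative = alternative)
      tibble::tibble(arm = a, comparison = lc, n = length(delta),
                     median_delta = stats::median(delta),
                     statistic = w$statistic, p_value = w$p_value)
    })
  })
}

#' Select light-upregulated genes
#'
#' Genes upregulated by light in wild type at 2 or 4 h (log2FC >
#' log2(`fc_min`) and padj < `padj_max` in either contrast).
#'
#' @param de long DE tibble.
#' @param fc_min,padj_max thresholds (linear FC).
#' @param contrasts wild-type light-response contrasts.
#' @return character vector of gene ids.
#' @export
select_light_upregulated <- function(de, fc_min = 1.5, padj_max = 0.05,
                                     contrasts = c("wt_light2_vs_dark",
                                                   "wt_light4_vs_dark")) {
  wide <- de_lookup(de, contrasts)
  lfc <- as.matrix(wide[, paste0("log2fc_", contrasts)])
  padj <- as.matrix(wide[, paste0("padj_", contrasts)])
  hit <- rowSums(lfc > log2(fc_min) & padj < padj_max, na.rm = TRUE) > 0
  wide$gene_id[hit]
}

#' Orientation x distance analysis of light-induced genes
#'
#' Splits light-upregulated genes by the orientation of their upstream
#' neighbor (S = same strand, O = opposite strand) and by the distance from
#' their TSS to the upstream gene border, then compares the downstream
#' log2(mutant/wt) of S vs O genes per condition and distance bin with a
#' Mann-Whitney U test, BH adjusted across all comparisons.
#'
#' @param light_up_genes character vector from [select_light_upregulated()].
#' @param contexts tibble from [neighbor_contexts()].
#' @param de long DE tibble holding the mutant/wt ratio contrasts.
#' @param distance_breaks interior bin edges in bp (default bins: <600,
#'   600-1200, >1200).
#' @param ratio_contrasts mutant/wt contrast per condition.
#' @param min_n minimum genes per side of a comparison.
#' @return tibble per condition x bin: `n_same`, `n_opposite`,
#'   `median_same`, `median_opposite`, `statistic`, `p_value`, `padj`.
#' @export
light_induced_distance_analysis <- function(light_up_genes, contexts, de,
                                            distance_breaks = c(600, 1200),
                                            ratio_contrasts = c("mut_vs_wt_dark",
                                                                "mut_vs_wt_light2",
                                                                "mut_vs_wt_light4"),
                                            min_n = 5) {
  up <- contexts |>
    dplyr::filter(.data$gene_id %in% light_up_genes, .data$side == "upstream",
                  !is.na(.data$neighbor_id))
  brk <- c(-Inf, distance_breaks, Inf)
  labels <- c(paste0("<", distance_breaks[1]),
              paste0(distance_breaks[1], "-", distance_breaks[2]),
              paste0(">", distance_breaks[2]))
  up$distance_bin <- cut(up$tss_to_border, brk, labels = labels, right = FALSE)
  ratios <- ratio_columns(de, up$gene_id, ratio_contrasts)
  up <- dplyr::bind_cols(up, ratios[, -1])
  grid <- tidyr::expand_grid(condition = ratio_contrasts, bin = labels)
  res <- purrr::pmap_dfr(grid, function(condition, bin) {
    sub <- up[!is.na(up$distance_bin) & up$distance_bin == bin, ]
    s <- sub[[paste0("ratio_", condition)]][sub$orientation == "same_strand"]
    o <- sub[[paste0("ratio_", condition)]][sub$orientation == "opposite_strand"]
    s <- s[!is.na(s)]; o <- o[!is.na(o)]
    if (length(s) < min_n || length(o) < min_n) {
      return(tibble::tibble(condition = condition, distance_bin = bin,
                            n_same = length(s), n_opposite = length(o),
                            median_same = NA_real_, median_opposite = NA_real_,
                            statistic = NA_real_, p_value = NA_real_))
    }
    mw <- mann_whitney_u(s, o)
    tibble::tibble(condition = condition, distance_bin = bin,
                   n_same = length(s), n_opposite = length(o),
                   median_same = stats::median(s), median_opposite = stats::median(o),
                   statistic = mw$statistic, p_value = mw$p_value)
  })
  dplyr::mutate(res, padj = bh_adjust(.data$p_value))
}
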