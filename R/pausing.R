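#' @title 3' pausing index
#'
#' @description The 3' pausing index of a gene is the ratio of the read
#' density in the window immediately downstream of the TES to the read
#' density of the gene body (read density = signal summed over a region
#' divided by its length in bp). An index above 1 indicates accumulation of
#' polymerase just past the termination site - 3' pausing. Because it is a
#' ratio of densities from the same track, the index is invariant to
#' library-size scaling.
#'
#' @name pausing
NULL

#' Per-gene 3' pausing indexes
#'
#' For each gene longer than `min_gene_len`, computes body density over
#' `[TSS + body_trim[1], TES - body_trim[2])` (in the direction of
#' transcription) and TES density over the `tes_window_bp` bases immediately
#' downstream of the TES, both strand-aware. Genes are kept with a `status`
#' flag rather than silently dropped: `"ok"`, `"short"` (gene too short),
#' `"zero_body"` / `"zero_tes"` (undefined index). TES windows running off
#' the chromosome are truncated (`tes_truncated`), and windows intruding into
#' another gene's body are flagged (`tes_in_gene`) but still computed, since
#' read-through into a downstream neighbor is exactly the phenomenon of
#' interest.
#'
#' @param track a [coverage_track()].
#' @param genes gene tibble.
#' @param tes_window_bp width of the downstream window in bp.
#' @param body_trim `c(from_tss_bp, from_tes_bp)` trimmed off the body ends.
#' @param min_gene_len genes at or below this length (bp) are skipped.
#' @param condition,antibody labels carried into the output.
#' @return tibble: `gene_id`, `condition`, `antibody`, `body_density`,
#'   `tes_density`, `pausing_index`, `log2_pi`, `status`, `tes_truncated`,
#'   `tes_in_gene`.
#' @export
pausing_index <- function(track, genes, tes_window_bp = 200,
                          body_trim = c(0, 0), min_gene_len = 1000,
                          condition = "wt", antibody = "PolII") {
  sizes <- track_chrom_sizes(track)
  n <- nrow(genes)
  body_d <- tes_d <- rep(NA_real_, n)
  status <- rep("ok", n)
  trunc <- in_gene <- rep(FALSE, n)
  for (i in seq_len(n)) {
    len <- genes$end[i] - genes$start[i]
    if (len <= min_gene_len) { status[i] <- "short"; next }
    plus <- genes$strand[i] == "+"
    if (plus) {
      b_start <- genes$start[i] + body_trim[1]
      b_end <- genes$end[i] - body_trim[2]
      t_start <- genes$end[i]
      t_end <- genes$end[i] + tes_window_bp
    } else {
      b_start <- genes$start[i] + body_trim[2]
      b_end <- genes$end[i] - body_trim[1]
      t_start <- genes$start[i] - tes_window_bp
      t_end <- genes$start[i]
    }
    chrom_len <- sizes[[genes$chrom[i]]]
    t_start_c <- max(0L, t_start); t_end_c <- min(chrom_len, t_end)
    if (t_start_c > t_start || t_end_c < t_end) trunc[i] <- TRUE
    if (t_end_c <= t_start_c || b_end <= b_start) { status[i] <- "zero_body"; next }
    body_d[i] <- region_density(track, genes$chrom[i], b_start, b_end)
    tes_d[i] <- region_density(track, genes$chrom[i], t_start_c, t_end_c)
    in_gene[i] <- any(genes$chrom == genes$chrom[i] &
                        genes$gene_id != genes$gene_id[i] &
                        genes$start < t_end_c & genes$end > t_start_c)
    if (body_d[i] == 0) status[i] <- "zero_body"
    else if (tes_d[i] == 0) status[i] <- "zero_tes"
  }
  pi_val <- ifelse(status == "ok", tes_d / body_d, NA_real_)
  tibble::tibble(
    gene_id = genes$gene_id, condition = condition, antibody = antibody,
    body_density = body_d, tes_density = tes_d,
    pausing_index = pi_val, log2_pi = log2(pi_val),
    status = status, tes_truncated = trunc, tes_in_gene = in_gene
  )
}

#' Compare pausing indexes between two conditions
#'
#' Pairs records by gene (and antibody), drops genes whose index is undefined
#' in either condition, and tests the difference in mean log2 pausing index
#' per expression group with a paired Student's t test. p-values are BH
#' adjusted across all (group x antibody) tests of the run. Groups with fewer
#' than 3 complete pairs are reported as NA.
#'
#' @param records_a,records_b [pausing_index()] outputs for the two
#'   conditions (a = reference, e.g. wild type).
#' @param groups tibble `gene_id`, `expression_group` (see
#'   [expression_groups()]).
#' @return tibble per group x antibody: `n`, `mean_log2_pi_a`,
#'   `mean_log2_pi_b`, `delta` (b - a), `direction`, `statistic`, `p_value`,
#'   `padj`, plus `n_dropped` pairs lost to undefined indexes.
#' @export
compare_pausing <- function(records_a, records_b, groups) {
  paired <- dplyr::inner_join(
    records_a |> dplyr::select("gene_id", "antibody", log2_a = "log2_pi", status_a = "status"),
    records_b |> dplyr::select("gene_id", "antibody", log2_b = "log2_pi", status_b = "status"),
    by = c("gene_id", "antibody")
  ) |>
    dplyr::inner_join(groups, by = "gene_id")
  n_dropped <- sum(paired$status_a != "ok" | paired$status_b != "ok")
  paired <- paired |> dplyr::filter(.data$status_a == "ok", .data$status_b == "ok")
  res <- paired |>
    dplyr::group_by(.data$antibody, .data$expression_group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3) {
        return(tibble::tibble(n = nrow(d), mean_log2_pi_a = NA_real_,
                              mean_log2_pi_b = NA_real_, delta = NA_real_,
                              direction = NA_character_, statistic = NA_real_,
                              p_value = NA_real_))
      }
      tt <- paired_t(d$log2_b, d$log2_a)
      delta <- mean(d$log2_b) - mean(d$log2_a)
      tibble::tibble(
        n = nrow(d), mean_log2_pi_a = mean(d$log2_a),
        mean_log2_pi_b = mean(d$log2_b), delta = delta,
        direction = dplyr::case_when(delta < 0 ~ "reduced in b",
                                     delta > 0 ~ "increased in b",
                                     TRUE ~ "no change"),
        statistic = tt$statistic, p_value = tt$p_value
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(padj = bh_adjust(.data$p_value))
  attr(res, "n_dropped") <- n_dropped
  res
}
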