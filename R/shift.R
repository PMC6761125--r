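#' @title TES-shift estimation
#'
#' @description Quantifies how far the 3' pausing peak moves between two
#' conditions, either at the population level (distance between the maxima of
#' the two TES-anchored average profiles) or per gene (difference of per-gene
#' coverage argmax positions within a TES window). Positive shifts point
#' downstream, in the direction of transcription.
#'
#' @name shift
NULL

#' Population-level TES shift between two tracks
#'
#' Builds a TES-anchored winsorized metagene for each condition over the same
#' gene set and reports the offset difference of the profile maxima within the
#' search window (argmax of b minus argmax of a), with the same tie rules as
#' [profile_argmax()].
#'
#' @param track_a,track_b [coverage_track()]s (a = reference condition).
#' @param genes gene tibble (warns below 20 genes).
#' @param window `c(lo, hi)` search window in bp around the TES.
#' @param winsor_pct,ci_level passed to [metagene_anchor()].
#' @return one-row tibble `offset_a`, `offset_b`, `shift` (bp), `n_genes`,
#'   with both profiles attached as attributes.
#' @export
population_shift <- function(track_a, track_b, genes, window = c(-1000, 1000),
                             winsor_pct = 0.01, ci_level = 0.95) {
  if (nrow(genes) < 20) warning("fewer than 20 genes; population shift will be noisy")
  flank <- max(abs(window))
  prof_a <- metagene_anchor(track_a, genes, "TES", flank, winsor_pct, ci_level)
  prof_b <- metagene_anchor(track_b, genes, "TES", flank, winsor_pct, ci_level)
  if (!any(prof_a$offset >= window[1] & prof_a$offset <= window[2])) {
    stop("empty window overlap")
  }
  off_a <- profile_argmax(prof_a, window)
  off_b <- profile_argmax(prof_b, window)
  out <- tibble::tibble(offset_a = off_a, offset_b = off_b,
                        shift = off_b - off_a, n_genes = nrow(genes))
  attr(out, "profile_a") <- prof_a
  attr(out, "profile_b") <- prof_b
  out
}

#' Per-gene TES shifts between two tracks
#'
#' For each gene, takes the raw (unwinsorized) coverage in the TES window of
#' both tracks and reports the difference of the argmax offsets. Genes whose
#' maximum window coverage does not exceed `min_signal` in both tracks are
#' dropped (counted in the `n_dropped` attribute), never zero-imputed.
#'
#' @inheritParams population_shift
#' @param min_signal per-gene maximum window coverage must exceed this in both
#'   tracks.
#' @param smooth_bp optional boxcar half-width (bp) applied to the window
#'   coverage before the argmax; 0 disables smoothing.
#' @return tibble `gene_id`, `offset_a`, `offset_b`, `shift`.
#' @export
per_gene_shifts <- function(track_a, track_b, genes, window = c(-1000, 1000),
                            min_signal = 0, smooth_bp = 0) {
  flank <- max(abs(window))
  win_a <- extract_windows(track_a, genes, "TES", flank)
  win_b <- extract_windows(track_b, genes, "TES", flank)
  offs <- -flank:flank
  sel <- offs >= window[1] & offs <= window[2]
  win_a <- win_a[, sel, drop = FALSE]
  win_b <- win_b[, sel, drop = FALSE]
  offs <- offs[sel]
  if (smooth_bp > 0) {
    k <- rep(1 / (2 * smooth_bp + 1), 2 * smooth_bp + 1)
    smooth_row <- function(r) as.numeric(stats::filter(r, k, sides = 2))
    win_a <- t(apply(win_a, 1, smooth_row))
    win_b <- t(apply(win_b, 1, smooth_row))
  }
  max_a <- apply(win_a, 1, max, na.rm = TRUE)
  max_b <- apply(win_b, 1, max, na.rm = TRUE)
  keep <- which(max_a > min_signal & max_b > min_signal)
  if (length(keep) == 0) {
    stop("all genes dropped: no gene exceeds min_signal = ", min_signal,
         " in both tracks")
  }
  shifts <- purrr::map_dfr(keep, function(i) {
    va <- win_a[i, ]; vb <- win_b[i, ]
    ok <- !is.na(va) & !is.na(vb)
    oa <- argmax_with_ties(va[ok], offs[ok])
    ob <- argmax_with_ties(vb[ok], offs[ok])
    tibble::tibble(gene_id = genes$gene_id[i], offset_a = oa, offset_b = ob,
                   shift = ob - oa)
  })
  attr(shifts, "n_dropped") <- nrow(genes) - length(keep)
  shifts
}

#' Test whether gene groups shift more than the expressed-gene baseline
#'
#' One-sided Wilcoxon signed-rank test of `shift - baseline > 0` per group,
#' where the baseline is the mean shift over all expressed genes. p-values are
#' BH adjusted across the groups of the run. Groups with fewer than `min_n`
#' genes are reported as NA.
#'
#' @param shifts [per_gene_shifts()] output.
#' @param groups tibble `gene_id`, `group` (character labels).
#' @param baseline_shifts shift vector of the all-expressed-genes reference
#'   set (defaults to all shifts in `shifts`).
#' @param min_n minimum group size.
#' @param alternative test sidedness (default `"greater"`: larger shift than
#'   baseline).
#' @return tibble per group: `n`, `median_shift`, `baseline`, `statistic`,
#'   `p_value`, `padj`.
#' @export
test_shift_groups <- function(shifts, groups,
                              baseline_shifts = shifts$shift, min_n = 5,
                              alternative = "greater") {
  baseline <- mean(baseline_shifts)
  res <- shifts |>
    dplyr::inner_join(groups, by = "gene_id") |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < min_n) {
        return(tibble::tibble(n = nrow(d), median_shift = NA_real_,
                              baseline = baseline, statistic = NA_real_,
                              p_value = NA_real_))
      }
      w <- wilcoxon_signed_rank(d$shift - baseline, alternative = alternative)
      tibble::tibble(n = nrow(d), median_shift = stats::median(d$shift),
                     baseline = baseline, statistic = w$statistic,
                     p_value = w$p_value)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(padj = bh_adjust(.data$p_value))
  res
}
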