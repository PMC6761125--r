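#' @title Gene-set selection
#'
#' @description Helpers that carve gene sets out of expression tables: equal-size
#' expression groups, "Not DE" control genes, and expression-matched control
#' sets for comparisons where expression level is a confounder.
#'
#' @name annotation-sets
NULL

#' Split genes into expression groups
#'
#' Quantile-based grouping by increasing expression. Target group sizes differ
#' by at most one; tied expression values always land in the same group, which
#' is what makes observed group sizes unequal.
#'
#' @param expr tibble with `gene_id` and `mean_expression` (e.g., log2 RPKM).
#' @param n_groups number of groups.
#' @return tibble `gene_id`, `expression_group` (1 = lowest expression).
#' @export
expression_groups <- function(expr, n_groups = 9) {
  expr <- expr[!is.na(expr$mean_expression), ]
  n <- nrow(expr)
  if (n_groups > n) stop("more groups than genes")
  o <- order(expr$mean_expression, expr$gene_id)
  base <- rep(seq_len(n_groups), diff(floor(seq(0, n, length.out = n_groups + 1))))
  g <- integer(n)
  g[o] <- base
  # ties share the group of their first (lowest-rank) member
  g <- stats::ave(g, expr$mean_expression, FUN = min)
  if (length(unique(g)) < n_groups) {
    warning("ties collapsed ", n_groups - length(unique(g)), " group boundary(ies)")
  }
  tibble::tibble(gene_id = expr$gene_id, expression_group = as.integer(g))
}

#' Select non-differentially-expressed control genes
#'
#' A gene qualifies only if, in every listed contrast, its raw p-value exceeds
#' `p_min`, its |log2 fold-change| is below `abs_lfc_max`, and its base mean
#' lies strictly between `basemean_min` and `basemean_max`.
#'
#' @param de long differential-expression tibble with `gene_id`, `contrast`,
#'   `log2fc`, `pvalue`, `basemean`.
#' @param contrasts contrasts that must all pass (default: all present).
#' @param p_min,abs_lfc_max,basemean_min,basemean_max thresholds.
#' @return character vector of selected gene ids.
#' @export
select_not_de_controls <- function(de, contrasts = unique(de$contrast),
                                   p_min = 0.45, abs_lfc_max = 0.25,
                                   basemean_min = 3, basemean_max = 1e5) {
  missing <- setdiff(contrasts, unique(de$contrast))
  if (length(missing) > 0) stop("missing contrast(s): ", paste(missing, collapse = ", "))
  de |>
    dplyr::filter(.data$contrast %in% contrasts) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_contrasts = dplyr::n(),
      ok = all(.data$pvalue > p_min & abs(.data$log2fc) < abs_lfc_max &
                 .data$basemean > basemean_min & .data$basemean < basemean_max),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_contrasts == length(contrasts), .data$ok) |>
    dplyr::pull("gene_id")
}

#' Select expression-matched control genes
#'
#' Stratified sampling: the reference set's expression distribution is split
#' into `n_bins` quantile bins, target counts are allocated to bins in
#' proportion to the reference mass (largest-remainder rounding), and
#' candidates are drawn per bin without replacement. Deficits in exhausted
#' bins are redistributed to bins with spare candidates, with a warning.
#'
#' @param candidates,reference character vectors of gene ids.
#' @param expr tibble with `gene_id`, `mean_expression`.
#' @param n number of controls to select.
#' @param n_bins quantile bins over the reference expression.
#' @param seed integer seed.
#' @return character vector of `n` selected gene ids.
#' @export
select_expression_matched_controls <- function(candidates, reference, expr,
                                               n = 1500, n_bins = 20, seed = 1L) {
  if (n > length(candidates)) stop("n exceeds the number of candidates")
  ex <- stats::setNames(expr$mean_expression, expr$gene_id)
  ref_e <- ex[reference]; cand_e <- ex[candidates]
  if (any(is.na(ref_e)) || any(is.na(cand_e))) stop("expression missing for some genes")
  brk <- unique(stats::quantile(ref_e, probs = seq(0, 1, length.out = n_bins + 1)))
  brk[1] <- -Inf; brk[length(brk)] <- Inf
  ref_bin <- cut(ref_e, brk, labels = FALSE)
  cand_bin <- cut(cand_e, brk, labels = FALSE)
  n_eff <- length(brk) - 1
  mass <- tabulate(ref_bin, n_eff) / length(ref_e)
  # largest-remainder allocation of n across bins
  raw <- mass * n
  alloc <- floor(raw)
  rem <- n - sum(alloc)
  if (rem > 0) {
    extra <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  avail <- tabulate(cand_bin, n_eff)
  short <- alloc > avail
  if (any(short)) {
    warning("candidates exhausted in ", sum(short),
            " bin(s); redistributing to neighboring bins")
    deficit <- sum(pmax(alloc - avail, 0))
    alloc <- pmin(alloc, avail)
    spare_order <- order(avail - alloc, decreasing = TRUE)
    for (b in spare_order) {
      if (deficit == 0) break
      add <- min(deficit, avail[b] - alloc[b])
      alloc[b] <- alloc[b] + add
      deficit <- deficit - add
    }
  }
  withr::with_seed(seed, {
    unlist(lapply(seq_len(n_eff), function(b) {
      pool <- candidates[which(cand_bin == b)]
      if (alloc[b] == 0) return(character(0))
      pool[sample.int(length(pool), alloc[b])]
    }), use.names = FALSE)
  })
}
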