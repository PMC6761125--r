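#' @title Genomic-context statistics for regulated gene sets
#'
#' @description Compares the neighborhoods of regulated gene sets (protected =
#' down in the mutant, repressed = up in the mutant, plus a non-DE control
#' set) against the all-genes background: neighbor orientation fractions,
#' intergenic-distance distributions, upstream-neighbor expression, and
#' gene-loop enrichment.
#'
#' @name interference
NULL

#' Neighbor orientation fractions per gene set
#'
#' For each gene set (plus the `all` background), the fraction of genes having
#' an upstream / downstream neighbor of each orientation within each distance
#' cutoff.
#'
#' @param sets named list of gene-id character vectors.
#' @param contexts tibble from [neighbor_contexts()].
#' @param distance_cutoffs numeric vector of inclusive distance cutoffs (bp);
#'   `Inf` means any distance.
#' @return tibble `set`, `side`, `orientation`, `max_distance`, `n_set`,
#'   `n_with_neighbor`, `fraction`.
#' @export
orientation_fractions <- function(sets, contexts,
                                  distance_cutoffs = c(600, 1200, Inf)) {
  all_ids <- unique(contexts$gene_id)
  sets <- c(sets, list(all = all_ids))
  grid <- tidyr::expand_grid(
    set = names(sets), side = c("upstream", "downstream"),
    orientation = c("same_strand", "opposite_strand"),
    max_distance = distance_cutoffs
  )
  purrr::pmap_dfr(grid, function(set, side, orientation, max_distance) {
    ids <- sets[[set]]
    if (length(ids) == 0) {
      return(tibble::tibble(set = set, side = side, orientation = orientation,
                            max_distance = max_distance, n_set = 0L,
                            n_with_neighbor = NA_integer_, fraction = NA_real_))
    }
    sub <- contexts[contexts$gene_id %in% ids & contexts$side == side &
                      !is.na(contexts$neighbor_id) &
                      contexts$orientation == orientation &
                      contexts$intergenic_distance <= max_distance, ]
    tibble::tibble(set = set, side = side, orientation = orientation,
                   max_distance = max_distance, n_set = length(ids),
                   n_with_neighbor = length(unique(sub$gene_id)),
                   fraction = length(unique(sub$gene_id)) / length(ids))
  })
}

#' Intergenic-distance distribution tests
#'
#' Per gene set, the median tandem (upstream same-strand) intergenic distance
#' and a two-sample Kolmogorov-Smirnov test against the all-genes tandem
#' distance distribution, BH adjusted across sets. Overlapping pairs are
#' excluded from the distributions.
#'
#' @inheritParams orientation_fractions
#' @param min_n sets with fewer tandem pairs are reported NA.
#' @return tibble `set`, `n`, `median_bp`, `statistic` (KS D), `p_value`,
#'   `padj`, plus the background median as an attribute.
#' @export
distance_distribution_tests <- function(sets, contexts, min_n = 5) {
  tandem_up <- contexts |>
    dplyr::filter(.data$side == "upstream", !is.na(.data$neighbor_id),
                  .data$pair_class == "tandem", !.data$overlap)
  background <- tandem_up$intergenic_distance
  res <- purrr::imap_dfr(sets, function(ids, set) {
    d <- tandem_up$intergenic_distance[tandem_up$gene_id %in% ids]
    if (length(d) < min_n) {
      return(tibble::tibble(set = set, n = length(d), median_bp = NA_real_,
                            statistic = NA_real_, p_value = NA_real_))
    }
    ks <- ks_two_sample(d, background)
    tibble::tibble(set = set, n = length(d), median_bp = stats::median(d),
                   statistic = ks$statistic, p_value = ks$p_value)
  }) |>
    dplyr::mutate(padj = bh_adjust(.data$p_value))
  attr(res, "background_median") <- stats::median(background)
  attr(res, "background_n") <- length(background)
  res
}

#' Upstream tandem neighbor expression tests
#'
#' Compares the expression of upstream same-strand neighbors of a reference
#' gene set (e.g. the protected set) against those of each other set, with a
#' Mann-Whitney U test. Neighbors without expression (or with zero counts,
#' encoded as NA) are excluded.
#'
#' @inheritParams orientation_fractions
#' @param expr tibble `gene_id`, `mean_expression`.
#' @param reference name of the reference set (default the first).
#' @param alternative sidedness (default two-sided).
#' @return tibble per comparison: `set`, `n_ref`, `n_set`,
#'   `median_ref`, `median_set`, `statistic` (U), `p_value`.
#' @export
upstream_expression_test <- function(sets, contexts, expr,
                                     reference = names(sets)[1],
                                     alternative = "two_sided") {
  ex <- stats::setNames(expr$mean_expression, expr$gene_id)
  up_expr <- function(ids) {
    nb <- contexts$neighbor_id[contexts$gene_id %in% ids &
                                 contexts$side == "upstream" &
                                 !is.na(contexts$neighbor_id) &
                                 contexts$orientation == "same_strand"]
    v <- ex[nb]
    v[!is.na(v)]
  }
  ref_e <- up_expr(sets[[reference]])
  purrr::imap_dfr(sets[setdiff(names(sets), reference)], function(ids, nm) {
    e <- up_expr(ids)
    if (length(e) == 0 || length(ref_e) == 0) {
      return(tibble::tibble(set = nm, n_ref = length(ref_e), n_set = length(e),
                            median_ref = NA_real_, median_set = NA_real_,
                            statistic = NA_real_, p_value = NA_real_))
    }
    mw <- mann_whitney_u(ref_e, e, alternative = alternative)
    tibble::tibble(set = nm, n_ref = length(ref_e), n_set = length(e),
                   median_ref = stats::median(ref_e), median_set = stats::median(e),
                   statistic = mw$statistic, p_value = mw$p_value)
  })
}

#' Gene-loop enrichment by genomic context
#'
#' For each focal gene set and each neighbor context (the set itself, its
#' upstream/downstream neighbors on the same/opposite strand), tests with a
#' Fisher exact test whether genes in that context carry gene loops more often
#' than the remaining genes, BH adjusted across all contexts of the run.
#'
#' @inheritParams orientation_fractions
#' @param loops character vector of loop-forming gene ids.
#' @param alternative Fisher sidedness (default two-sided).
#' @return tibble `context`, `n_with_loops`, `n_total`, `pct_with_loops`,
#'   `odds_ratio`, `p_value`, `padj`.
#' @export
loop_enrichment <- function(sets, contexts, loops, alternative = "two_sided") {
  universe <- unique(contexts$gene_id)
  context_genes <- list()
  for (nm in names(sets)) {
    ids <- sets[[nm]]
    context_genes[[nm]] <- ids
    for (side in c("upstream", "downstream")) {
      for (orient in c("same_strand", "opposite_strand")) {
        nb <- contexts$neighbor_id[contexts$gene_id %in% ids &
                                     contexts$side == side &
                                     !is.na(contexts$neighbor_id) &
                                     contexts$orientation == orient]
        context_genes[[paste(nm, side, orient, sep = ".")]] <- unique(nb)
      }
    }
  }
  res <- purrr::imap_dfr(context_genes, function(ids, nm) {
    in_ctx <- universe %in% ids
    in_loop <- universe %in% loops
    tab <- matrix(c(sum(in_ctx & in_loop), sum(!in_ctx & in_loop),
                    sum(in_ctx & !in_loop), sum(!in_ctx & !in_loop)), 2, 2)
    fe <- suppressWarnings(fisher_exact_2x2(tab, alternative = alternative))
    tibble::tibble(context = nm, n_with_loops = tab[1, 1],
                   n_total = sum(in_ctx),
                   pct_with_loops = if (sum(in_ctx) > 0) 100 * tab[1, 1] / sum(in_ctx) else NA_real_,
                   odds_ratio = fe$statistic, p_value = fe$p_value)
  })
  dplyr::mutate(res, padj = bh_adjust(.data$p_value))
}
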