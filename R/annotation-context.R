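#' Neighbor contexts of genes
#'
#' For each focal gene, finds the nearest gene on each side along the genome
#' axis (genes fully nested inside another gene are skipped as candidates),
#' relabels the two sides as upstream/downstream relative to the focal
#' strand, and classifies each pair:
#'
#' * `tandem` - both genes on the same strand, so the upstream gene's 3' end
#'   faces the downstream gene's promoter;
#' * `divergent` - head-to-head (the physically left gene on `-`, the right
#'   gene on `+`);
#' * `convergent` - tail-to-tail.
#'
#' `intergenic_distance` is the gap between the gene bodies in bp; for tandem
#' pairs this equals the distance from the upstream gene's TES to the
#' downstream gene's TSS. Overlapping pairs get distance 0 and `overlap =
#' TRUE`. `tss_to_border` (upstream side only) is the distance from the focal
#' TSS to the nearest border of the upstream gene, used for distance binning
#' of light-induced genes.
#'
#' @param genes gene tibble from [as_gene_model()], sorted by (chrom, start).
#' @param max_distance drop neighbors farther than this (bp); `NULL` keeps all.
#' @param use_fast_path use the vectorized scan on sorted non-overlapping
#'   chromosomes (results are identical to the general scan; exposed for
#'   verification).
#' @return tibble with one row per gene x side: `gene_id`, `side`,
#'   `neighbor_id`, `orientation`, `pair_class`, `intergenic_distance`,
#'   `overlap`, `tss_to_border`.
#' @export
neighbor_contexts <- function(genes, max_distance = NULL, use_fast_path = TRUE) {
  if (is.unsorted(order(genes$chrom, genes$start))) stop("genes must be sorted by (chrom, start)")
  res <- genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(~ chrom_contexts(.x, use_fast_path)) |>
    dplyr::ungroup() |>
    dplyr::select(-"chrom")
  if (!is.null(max_distance)) {
    far <- !is.na(res$neighbor_id) & res$intergenic_distance > max_distance
    res$neighbor_id[far] <- NA_character_
    res$orientation[far] <- NA_character_
    res$pair_class[far] <- NA_character_
    res$intergenic_distance[far] <- NA_integer_
    res$overlap[far] <- NA
    res$tss_to_border[far] <- NA_integer_
  }
  res
}

chrom_contexts <- function(g, use_fast_path = TRUE) {
  n <- nrow(g)
  if (use_fast_path && n > 1 && all(g$start[-1] >= g$end[-n])) {
    return(chrom_contexts_disjoint(g))
  }
  # candidates: genes not fully nested inside another gene
  nested <- vapply(seq_len(n), function(i) {
    any(g$start <= g$start[i] & g$end >= g$end[i] & seq_len(n) != i &
          (g$start < g$start[i] | g$end > g$end[i]))
  }, logical(1))
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    cand <- which(!nested & seq_len(n) != i)
    left <- cand[g$start[cand] < g$start[i] |
                   (g$start[cand] == g$start[i] & g$end[cand] < g$end[i])]
    right <- cand[g$start[cand] > g$start[i] |
                    (g$start[cand] == g$start[i] & g$end[cand] > g$end[i])]
    j_left <- if (length(left) > 0) left[which.max(g$end[left])] else NA_integer_
    j_right <- if (length(right) > 0) right[which.min(g$start[right])] else NA_integer_
    side_of <- function(j, physical) {
      if (is.na(j)) {
        return(tibble::tibble(
          gene_id = g$gene_id[i], side = NA_character_, neighbor_id = NA_character_,
          orientation = NA_character_, pair_class = NA_character_,
          intergenic_distance = NA_integer_, overlap = NA, tss_to_border = NA_integer_,
          physical = physical
        ))
      }
      gap <- if (physical == "left") g$start[i] - g$end[j] else g$start[j] - g$end[i]
      ov <- gap < 0
      dist <- max(0L, as.integer(gap))
      same <- g$strand[j] == g$strand[i]
      left_strand <- if (physical == "left") g$strand[j] else g$strand[i]
      right_strand <- if (physical == "left") g$strand[i] else g$strand[j]
      pair_class <- if (same) "tandem"
        else if (left_strand == "-" && right_strand == "+") "divergent"
        else "convergent"
      # upstream/downstream per focal strand
      side <- if (g$strand[i] == "+") {
        if (physical == "left") "upstream" else "downstream"
      } else {
        if (physical == "left") "downstream" else "upstream"
      }
      ttb <- NA_integer_
      if (side == "upstream") {
        # genomic gap between the focal TSS and the upstream gene body; equals
        # intergenic_distance when the TSS is the boundary facing the neighbor
        tss <- g$tss[i]
        ttb <- if (tss >= g$start[j] && tss < g$end[j]) 0L
          else if (tss >= g$end[j]) as.integer(tss - g$end[j])
          else as.integer(g$start[j] - tss - 1L)
      }
      tibble::tibble(
        gene_id = g$gene_id[i], side = side, neighbor_id = g$gene_id[j],
        orientation = if (same) "same_strand" else "opposite_strand",
        pair_class = pair_class, intergenic_distance = dist, overlap = ov,
        tss_to_border = ttb, physical = physical
      )
    }
    dplyr::bind_rows(side_of(j_left, "left"), side_of(j_right, "right"))
  })
  # fix side labels for rows without neighbor: report both sides explicitly
  miss <- is.na(rows$side)
  if (any(miss)) {
    st <- g$strand[match(rows$gene_id[miss], g$gene_id)]
    rows$side[miss] <- ifelse(
      (st == "+") == (rows$physical[miss] == "left"), "upstream", "downstream"
    )
  }
  rows$physical <- NULL
  rows
}

# vectorized fast path: sorted, non-overlapping genes, so the physical left
# and right neighbors are simply the previous and next rows
chrom_contexts_disjoint <- function(g) {
  n <- nrow(g)
  one_side <- function(j, physical) {
    valid <- !is.na(j) & j >= 1 & j <= n
    js <- ifelse(valid, j, 1L)
    gap <- if (physical == "left") g$start - g$end[js] else g$start[js] - g$end
    same <- g$strand[js] == g$strand
    left_strand <- if (physical == "left") g$strand[js] else g$strand
    right_strand <- if (physical == "left") g$strand else g$strand[js]
    pair_class <- ifelse(same, "tandem",
                         ifelse(left_strand == "-" & right_strand == "+",
                                "divergent", "convergent"))
    side <- ifelse((g$strand == "+") == (physical == "left"),
                   "upstream", "downstream")
    tss <- g$tss
    ttb <- ifelse(tss >= g$start[js] & tss < g$end[js], 0L,
                  ifelse(tss >= g$end[js], tss - g$end[js],
                         g$start[js] - tss - 1L))
    out <- tibble::tibble(
      gene_id = g$gene_id, side = side,
      neighbor_id = ifelse(valid, g$gene_id[js], NA_character_),
      orientation = ifelse(valid, ifelse(same, "same_strand", "opposite_strand"),
                           NA_character_),
      pair_class = ifelse(valid, pair_class, NA_character_),
      intergenic_distance = ifelse(valid, as.integer(pmax(0, gap)), NA_integer_),
      overlap = ifelse(valid, gap < 0, NA),
      tss_to_border = ifelse(valid & side == "upstream", as.integer(ttb),
                             NA_integer_)
    )
    out
  }
  idx <- seq_len(n)
  dplyr::bind_rows(one_side(idx - 1L, "left"), one_side(idx + 1L, "right")) |>
    dplyr::arrange(match(.data$gene_id, g$gene_id))
}

#' Tandem gene pairs from neighbor contexts
#'
#' One row per (upstream gene, downstream gene) same-strand pair, derived from
#' the upstream side of the contexts. Overlapping pairs are excluded.
#'
#' @param contexts tibble from [neighbor_contexts()].
#' @return tibble `up_gene`, `down_gene`, `intergenic_distance`.
#' @export
tandem_pairs <- function(contexts) {
  contexts |>
    dplyr::filter(.data$side == "upstream", !is.na(.data$neighbor_id),
                  .data$pair_class == "tandem", !.data$overlap) |>
    dplyr::transmute(up_gene = .data$neighbor_id, down_gene = .data$gene_id,
                     intergenic_distance = .data$intergenic_distance)
}
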