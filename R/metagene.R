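#' @title Metagene profiles
#'
#' @description Average coverage across a gene set, aligned on a common anchor
#' (TSS or TES, strand-aware) or on a length-scaled gene body (100 bins of 1%
#' of gene length). Before averaging, the most extreme `winsor_pct`% of the
#' pooled window values are replaced by the upper `(100 - winsor_pct/100)`th
#' percentile value (one-sided winsorization), so a single very high locus
#' cannot dominate the mean. The confidence band is the normal approximation
#' `mean +/- z * sd / sqrt(n)` per bin.
#'
#' @name metagene
NULL

z_from_level <- function(ci_level) stats::qnorm(1 - (1 - ci_level) / 2)

# genes x offsets matrix of per-bp coverage, strand-aware; NA outside chromosome
extract_windows <- function(track, genes, anchor = c("TSS", "TES"), flank_bp) {
  anchor <- match.arg(anchor)
  if (nrow(genes) == 0) stop("empty gene set")
  anchors <- if (anchor == "TSS") genes$tss else genes$tes
  offs <- -flank_bp:flank_bp
  mat <- matrix(NA_real_, nrow(genes), length(offs))
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    v <- track$values[[ch]]
    if (is.null(v)) stop("unknown chromosome: ", ch)
    idx <- outer(anchors[gi], offs, "+")  # genomic positions, 0-based
    bad <- idx < 0 | idx >= length(v)
    idx[bad] <- 0L
    vals <- matrix(v[idx + 1L], nrow = length(gi))
    vals[bad] <- NA_real_
    mat[gi, ] <- vals
  }
  minus <- genes$strand == "-"
  if (any(minus)) mat[minus, ] <- mat[minus, ncol(mat):1, drop = FALSE]
  dimnames(mat) <- list(genes$gene_id, offs)
  mat
}

winsorize_upper <- function(mat, winsor_pct) {
  if (winsor_pct <= 0) return(mat)
  pool <- mat[!is.na(mat)]
  cap <- stats::quantile(pool, 1 - winsor_pct / 100, names = FALSE)
  mat[!is.na(mat) & mat > cap] <- cap
  attr(mat, "winsor_cap") <- cap
  mat
}

profile_from_matrix <- function(mat, offsets, ci_level, anchor, bin_bp,
                                winsor_pct, segment = NULL) {
  z <- z_from_level(ci_level)
  n <- unname(colSums(!is.na(mat)))
  mu <- unname(colMeans(mat, na.rm = TRUE))
  sdv <- unname(apply(mat, 2, stats::sd, na.rm = TRUE))
  ci <- ifelse(n > 1, z * sdv / sqrt(n), 0)
  ci[n <= 1 | is.na(ci)] <- 0
  out <- tibble::tibble(offset = offsets, mean = mu, ci_half_width = ci,
                        ci_lo = mu - ci, ci_hi = mu + ci, n = as.integer(n))
  if (!is.null(segment)) out <- tibble::add_column(out, segment = segment, .before = 1)
  out <- out[out$n > 0, ]
  structure(out, class = c("metagene_profile", class(out)),
            anchor = anchor, bin_bp = bin_bp, ci_level = ci_level,
            winsor_pct = winsor_pct, n_genes = nrow(mat),
            winsor_cap = attr(mat, "winsor_cap"))
}

bin_columns <- function(mat, bin_bp) {
  if (bin_bp <= 1) return(mat)
  grp <- (seq_len(ncol(mat)) - 1) %/% bin_bp
  t(apply(mat, 1, function(row) as.numeric(tapply(row, grp, mean))))
}

#' Anchored metagene profile
#'
#' Per-gene windows of `+/- flank_bp` around the TSS or TES, extracted
#' strand-aware (minus-strand windows are reversed so offsets always increase
#' in the direction of transcription), winsorized across the pooled window
#' values, then averaged per offset. Windows truncated at chromosome edges
#' contribute only to the offsets they cover.
#'
#' @param track a [coverage_track()].
#' @param genes gene tibble.
#' @param anchor `"TSS"` or `"TES"`.
#' @param flank_bp half-window size in bp.
#' @param winsor_pct percentage of pooled values to cap (0.01 = cap at the
#'   99.99th percentile); 0 disables winsorization.
#' @param ci_level confidence level of the normal-approximation band.
#' @param bin_bp average offsets into bins of this many bp (1 = unbinned).
#' @return `metagene_profile` tibble: `offset` (bp, transcription direction),
#'   `mean`, `ci_half_width`, `ci_lo`, `ci_hi`, `n`.
#' @export
metagene_anchor <- function(track, genes, anchor = c("TSS", "TES"),
                            flank_bp = 1000, winsor_pct = 0.01,
                            ci_level = 0.95, bin_bp = 1) {
  anchor <- match.arg(anchor)
  mat <- extract_windows(track, genes, anchor, flank_bp)
  mat <- winsorize_upper(mat, winsor_pct)
  offs <- -flank_bp:flank_bp
  if (bin_bp > 1) {
    cap <- attr(mat, "winsor_cap")
    mat <- bin_columns(mat, bin_bp)
    attr(mat, "winsor_cap") <- cap
    grp <- (seq_along(offs) - 1) %/% bin_bp
    offs <- as.numeric(tapply(offs, grp, mean))
  }
  profile_from_matrix(mat, offs, ci_level, anchor, bin_bp, winsor_pct)
}

# per-gene gene-body bin means: position j (0-based) of an L-bp body falls in
# bin floor(j * n_bins / L) + 1, so genes whose values are constant within
# each 1%-of-length segment yield identical bin vectors regardless of length
genebody_bins <- function(track, genes, n_bins) {
  t(vapply(seq_len(nrow(genes)), function(i) {
    v <- track_values(track, genes$chrom[i], genes$start[i], genes$end[i])
    if (genes$strand[i] == "-") v <- rev(v)
    L <- length(v)
    bin <- pmin(n_bins, (seq_len(L) - 1L) %/% (L / n_bins) + 1L)
    means <- rep(NA_real_, n_bins)
    agg <- tapply(v, bin, mean)
    means[as.integer(names(agg))] <- agg
    if (anyNA(means)) {
      # genes shorter than n_bins: empty bins borrow the nearest base
      means <- stats::approx(which(!is.na(means)), means[!is.na(means)],
                             xout = seq_len(n_bins), method = "constant",
                             rule = 2)$y
    }
    means
  }, numeric(n_bins)))
}

#' Gene-body-scaled metagene profile
#'
#' Each gene body is mapped onto `n_bins` equal-fraction bins (per-gene,
#' per-bin means), optionally flanked by fixed-width windows upstream of the
#' TSS and downstream of the TES at `flank_bin_bp` resolution. Winsorization
#' and the confidence band are applied across the combined value set exactly
#' as in [metagene_anchor()].
#'
#' @inheritParams metagene_anchor
#' @param n_bins gene-body bins (100 = 1% of gene length each).
#' @param flank_bp flank extent in bp (0 = body only).
#' @param flank_bin_bp flank resolution (1 for profiles, 20 for heatmap grids).
#' @return `metagene_profile` tibble with a `segment` column
#'   (`upstream`/`body`/`downstream`); `offset` is bp relative to TSS/TES in
#'   the flanks and the bin index 1..n_bins in the body.
#' @export
metagene_genebody <- function(track, genes, n_bins = 100, flank_bp = 0,
                              winsor_pct = 0.01, ci_level = 0.95,
                              flank_bin_bp = 1) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (nrow(genes) == 0) stop("empty gene set")
  body <- genebody_bins(track, genes, n_bins)
  mats <- list(body = body)
  if (flank_bp > 0) {
    up <- extract_windows(track, genes, "TSS", flank_bp)[, seq_len(flank_bp), drop = FALSE]
    down <- extract_windows(track, genes, "TES", flank_bp)[, flank_bp + 1 + seq_len(flank_bp), drop = FALSE]
    mats <- list(upstream = bin_columns(up, flank_bin_bp), body = body,
                 downstream = bin_columns(down, flank_bin_bp))
  }
  all_mat <- do.call(cbind, mats)
  all_mat <- winsorize_upper(all_mat, winsor_pct)
  seg <- rep(names(mats), vapply(mats, ncol, integer(1)))
  offsets <- unlist(lapply(names(mats), function(nm) {
    k <- ncol(mats[[nm]])
    switch(nm,
      upstream = {
        grp_means <- tapply(-flank_bp:-1, ((seq_len(flank_bp)) - 1) %/% flank_bin_bp, mean)
        as.numeric(grp_means)
      },
      body = seq_len(n_bins),
      downstream = {
        grp_means <- tapply(1:flank_bp, ((seq_len(flank_bp)) - 1) %/% flank_bin_bp, mean)
        as.numeric(grp_means)
      }
    )
  }), use.names = FALSE)
  profile_from_matrix(all_mat, offsets, ci_level, "gene_body",
                      bin_bp = flank_bin_bp, winsor_pct = winsor_pct,
                      segment = seg)
}

#' Offset of the profile maximum
#'
#' Position of the maximum mean within a search window. Ties are broken
#' toward the anchor (smallest absolute offset), then toward the lower
#' offset. A completely flat window triggers a warning and returns the
#' anchor-proximal position.
#'
#' @param profile anchored `metagene_profile`.
#' @param search_window `c(lo, hi)` in bp; `NULL` uses the whole profile.
#' @return offset (bp) of the maximum.
#' @export
profile_argmax <- function(profile, search_window = NULL) {
  df <- profile
  if ("segment" %in% names(df)) stop("profile_argmax needs an anchored profile")
  if (!is.null(search_window)) {
    df <- df[df$offset >= search_window[1] & df$offset <= search_window[2], ]
  }
  if (nrow(df) == 0) stop("search window outside profile extent")
  if (max(df$mean) - min(df$mean) == 0) {
    warning("flat profile in search window; returning anchor-proximal offset")
  }
  cand <- df$offset[df$mean == max(df$mean)]
  cand[order(abs(cand), cand)][1]
}

argmax_with_ties <- function(values, offsets) {
  m <- max(values)
  cand <- offsets[values == m]
  cand[order(abs(cand), cand)][1]
}

#' Per-gene occupancy heatmap matrix
#'
#' Builds a genes-by-bins matrix of binned coverage (TSS flank, scaled gene
#' body, TES flank) and orders rows by decreasing occupancy score, defined as
#' the summed signal in the `score_bins` bins around the TSS plus those around
#' the TES. Tied scores keep a stable order by gene id.
#'
#' @inheritParams metagene_genebody
#' @param flank_bp flank extent around TSS and TES in bp.
#' @param bin_bp flank bin width (20 bp grids are typical for heatmaps).
#' @param score_bins number of bins on each side of the anchor summed into the
#'   occupancy score (TSS +/- `score_bins` bins and TES +/- `score_bins` bins).
#' @param top_n keep only the highest-scoring genes (all if larger than the
#'   gene count, with a warning).
#' @return numeric matrix with gene ids as row names and an `occupancy_score`
#'   attribute; columns are upstream flank bins, body bins, downstream flank
#'   bins.
#' @export
heatmap_matrix <- function(track, genes, n_bins = 100, flank_bp = 1000,
                           bin_bp = 20, score_bins = 10, top_n = Inf) {
  tss_win <- extract_windows(track, genes, "TSS", flank_bp)
  tes_win <- extract_windows(track, genes, "TES", flank_bp)
  tss_b <- bin_columns(tss_win, bin_bp)
  tes_b <- bin_columns(tes_win, bin_bp)
  body <- genebody_bins(track, genes, n_bins)
  center <- (ncol(tss_b) + 1) / 2
  pick <- function(m) {
    cols <- max(1, floor(center - score_bins)):min(ncol(m), ceiling(center + score_bins))
    rowSums(m[, cols, drop = FALSE], na.rm = TRUE)
  }
  score <- pick(tss_b) + pick(tes_b)
  mat <- cbind(tss_b[, seq_len(floor(center)), drop = FALSE], body,
               tes_b[, ceiling(center):ncol(tes_b), drop = FALSE])
  rownames(mat) <- genes$gene_id
  o <- order(-score, genes$gene_id)
  mat <- mat[o, , drop = FALSE]
  score <- score[o]
  if (is.finite(top_n)) {
    if (top_n > nrow(mat)) {
      warning("top_n exceeds gene count; using all genes")
      top_n <- nrow(mat)
    }
    mat <- mat[seq_len(top_n), , drop = FALSE]
    score <- score[seq_len(top_n)]
  }
  attr(mat, "occupancy_score") <- stats::setNames(score, rownames(mat))
  mat
}

#' @export
glance.metagene_profile <- function(x, ...) {
  tibble::tibble(
    anchor = attr(x, "anchor"), n_genes = attr(x, "n_genes"),
    bin_bp = attr(x, "bin_bp"), winsor_pct = attr(x, "winsor_pct"),
    winsor_cap = attr(x, "winsor_cap") %||% NA_real_,
    ci_level = attr(x, "ci_level"), n_bins = nrow(x)
  )
}
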