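#' @title Peak-to-feature annotation
#'
#' @description Peak summits are assigned to exactly one genomic category
#' following a fixed precedence list: promoter (within `promoter_bp` upstream
#' of a TSS), immediate downstream (within `downstream_bp` downstream of a
#' TES), 5' UTR, 3' UTR, exon, intron, and intergenic (farther than
#' `intergenic_bp` from any gene). Once a summit matches a category it is
#' never reassigned to a later one. Ties among several genes within the
#' winning category are broken by the smallest summit-to-anchor distance,
#' then lexicographic gene id.
#'
#' @name annotation-peaks
NULL

#' Read a narrowPeak-like BED file
#'
#' 10-column narrowPeak (summit offset in column 10) or BED with at least 3
#' columns (summit defaults to the interval midpoint).
#'
#' @param path input file.
#' @return tibble `chrom`, `start`, `end`, `name`, `score`, `summit`.
#' @export
read_peaks <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  out <- tibble::tibble(
    chrom = as.character(df[[1]]),
    start = as.integer(df[[2]]), end = as.integer(df[[3]]),
    name = if (ncol(df) >= 4) as.character(df[[4]]) else paste0("peak_", seq_len(nrow(df))),
    score = if (ncol(df) >= 5) as.numeric(df[[5]]) else 0
  )
  out$summit <- if (ncol(df) >= 10 && all(df[[10]] >= 0)) {
    out$start + as.integer(df[[10]])
  } else {
    out$start + (out$end - out$start) %/% 2L
  }
  if (any(out$summit < out$start | out$summit >= out$end)) stop("summit outside peak interval")
  out
}

# category interval table used by both annotate_peaks and position annotation.
# Intervals are 0-based half-open; anchor is the position used for tie-breaks.
category_intervals <- function(genes, features, promoter_bp, downstream_bp) {
  plus <- genes$strand == "+"
  promoter <- tibble::tibble(
    category = "promoter", gene_id = genes$gene_id, chrom = genes$chrom,
    start = ifelse(plus, genes$tss - promoter_bp, genes$tss + 1L),
    end = ifelse(plus, genes$tss, genes$tss + promoter_bp + 1L),
    anchor = genes$tss
  )
  downstream <- tibble::tibble(
    category = "immediate_downstream", gene_id = genes$gene_id, chrom = genes$chrom,
    start = ifelse(plus, genes$tes + 1L, genes$tes - downstream_bp),
    end = ifelse(plus, genes$tes + downstream_bp + 1L, genes$tes),
    anchor = genes$tes
  )
  # exon set: explicit exons, or the whole gene span for genes without any
  exon_feats <- features[features$kind == "exon", , drop = FALSE]
  no_exon <- setdiff(genes$gene_id, exon_feats$gene_id)
  if (length(no_exon) > 0) {
    gi <- match(no_exon, genes$gene_id)
    exon_feats <- dplyr::bind_rows(exon_feats, tibble::tibble(
      gene_id = no_exon, kind = "exon", start = genes$start[gi], end = genes$end[gi]
    ))
  }
  feat_rows <- function(kind_in, category) {
    f <- if (identical(category, "exon")) exon_feats else
      features[features$kind %in% kind_in, , drop = FALSE]
    if (nrow(f) == 0) return(NULL)
    gi <- match(f$gene_id, genes$gene_id)
    tibble::tibble(
      category = category, gene_id = f$gene_id, chrom = genes$chrom[gi],
      start = f$start, end = f$end,
      anchor = dplyr::case_when(
        category %in% c("five_prime_UTR") ~ genes$tss[gi],
        category %in% c("three_prime_UTR") ~ genes$tes[gi],
        TRUE ~ NA_integer_
      )
    )
  }
  # introns: gene span minus exon set, per gene
  introns <- exon_feats |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(ex, key) {
      gi <- match(key$gene_id, genes$gene_id)
      ex <- ex[order(ex$start), ]
      gaps_start <- c(genes$start[gi], ex$end)
      gaps_end <- c(ex$start, genes$end[gi])
      keep <- gaps_end > gaps_start
      tibble::tibble(start = gaps_start[keep], end = gaps_end[keep])
    }) |>
    dplyr::ungroup()
  intron_rows <- NULL
  if (nrow(introns) > 0) {
    gi <- match(introns$gene_id, genes$gene_id)
    intron_rows <- tibble::tibble(
      category = "intron", gene_id = introns$gene_id, chrom = genes$chrom[gi],
      start = introns$start, end = introns$end, anchor = NA_integer_
    )
  }
  dplyr::bind_rows(
    promoter, downstream,
    feat_rows("five_prime_UTR", "five_prime_UTR"),
    feat_rows("three_prime_UTR", "three_prime_UTR"),
    feat_rows("exon", "exon"),
    intron_rows
  )
}

peak_categories <- c("promoter", "immediate_downstream", "five_prime_UTR",
                     "three_prime_UTR", "exon", "intron", "intergenic")

# assign each position (chrom, pos) to a category + gene; vectorized via IRanges
annotate_positions <- function(chrom, pos, genes, features, promoter_bp,
                               downstream_bp, intergenic_bp) {
  ints <- category_intervals(genes, features, promoter_bp, downstream_bp)
  n <- length(pos)
  category <- rep(NA_character_, n)
  assigned <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    pi <- which(chrom == ch)
    q <- IRanges::IRanges(start = pos[pi] + 1L, width = 1L)
    remaining <- seq_along(pi)
    for (cat in setdiff(peak_categories, "intergenic")) {
      if (length(remaining) == 0) break
      sub <- ints[ints$category == cat & ints$chrom == ch, ]
      if (nrow(sub) == 0) next
      s <- IRanges::IRanges(start = sub$start + 1L, end = sub$end)
      hits <- IRanges::findOverlaps(q[remaining], s)
      if (length(hits) == 0) next
      qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
      p_here <- pos[pi[remaining[qh]]]
      gi <- match(sub$gene_id[sh], genes$gene_id)
      anchor <- sub$anchor[sh]
      # exon/intron anchor: nearer of the gene's TSS/TES
      na_a <- is.na(anchor)
      if (any(na_a)) {
        anchor[na_a] <- ifelse(
          abs(p_here[na_a] - genes$tss[gi[na_a]]) <= abs(p_here[na_a] - genes$tes[gi[na_a]]),
          genes$tss[gi[na_a]], genes$tes[gi[na_a]]
        )
      }
      cand <- tibble::tibble(q = qh, gene_id = sub$gene_id[sh],
                             d = abs(p_here - anchor)) |>
        dplyr::arrange(.data$q, .data$d, .data$gene_id) |>
        dplyr::distinct(.data$q, .keep_all = TRUE)
      idx <- pi[remaining[cand$q]]
      category[idx] <- cat
      assigned[idx] <- cand$gene_id
      remaining <- remaining[-cand$q]
    }
    if (length(remaining) > 0) {
      # everything within intergenic_bp of a gene is caught by the flank or
      # body categories above, so leftovers are intergenic by construction
      category[pi[remaining]] <- "intergenic"
    }
  }
  tibble::tibble(category = category, assigned_gene = assigned)
}

#' Annotate peak summits relative to genomic features
#'
#' @param peaks tibble from [read_peaks()] (needs `chrom`, `summit`, `name`).
#' @param genes gene tibble; sub-features are taken from its `features`
#'   attribute unless supplied.
#' @param features optional feature tibble (`gene_id`, `kind`, `start`, `end`).
#' @param promoter_bp,downstream_bp flank widths for the promoter and
#'   immediate-downstream categories (distance 1..N bp from TSS/TES).
#' @param intergenic_bp minimum distance from any gene for the intergenic
#'   category.
#' @param chrom_sizes optional named vector to validate summit bounds.
#' @return tibble `peak_name`, `category`, `assigned_gene`.
#' @export
annotate_peaks <- function(peaks, genes, features = gene_features(genes),
                           promoter_bp = 300, downstream_bp = 300,
                           intergenic_bp = 300, chrom_sizes = NULL) {
  if (!is.null(chrom_sizes)) {
    if (any(peaks$summit < 0 | peaks$summit >= chrom_sizes[peaks$chrom])) {
      stop("summit outside chromosome bounds")
    }
  }
  ann <- annotate_positions(peaks$chrom, peaks$summit, genes, features,
                            promoter_bp, downstream_bp, intergenic_bp)
  tibble::tibble(peak_name = peaks$name, category = ann$category,
                 assigned_gene = ann$assigned_gene)
}

#' Category enrichment of peaks against random genomic positions
#'
#' Compares the observed fraction of peak summits in each category with the
#' null distribution obtained from `n_samples` replicate sets of random
#' single-bp positions drawn uniformly over the non-blacklisted genome (each
#' replicate the size of the peak set), annotated with the same precedence
#' rules. Empirical two-sided p-values use the add-one correction
#' `(1 + #as-or-more-extreme) / (n_samples + 1)`.
#'
#' @inheritParams annotate_peaks
#' @param chrom_sizes named vector of chromosome lengths (required).
#' @param n_samples number of random replicate sets.
#' @param seed integer seed.
#' @param blacklist optional tibble `chrom`, `start`, `end` of positions to
#'   avoid.
#' @return tibble per category: `observed_fraction`, `null_mean`,
#'   `empirical_p`.
#' @export
random_position_enrichment <- function(peaks, genes, chrom_sizes,
                                       n_samples = 10000, seed = 1L,
                                       blacklist = NULL,
                                       features = gene_features(genes),
                                       promoter_bp = 300, downstream_bp = 300,
                                       intergenic_bp = 300) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (n_samples < 100) warning("n_samples < 100 gives coarse empirical p-values")
  if (sum(chrom_sizes) == 0) stop("zero-length genome")
  obs <- annotate_peaks(peaks, genes, features, promoter_bp, downstream_bp,
                        intergenic_bp, chrom_sizes)
  n_peaks <- nrow(peaks)
  obs_frac <- vapply(peak_categories, function(cat) mean(obs$category == cat), numeric(1))
  # flatten genome into a single coordinate axis for uniform sampling
  offsets <- c(0, cumsum(as.numeric(chrom_sizes)))[seq_along(chrom_sizes)]
  names(offsets) <- names(chrom_sizes)
  total <- sum(as.numeric(chrom_sizes))
  draw_positions <- function(k) {
    repeat {
      flat <- floor(stats::runif(k, 0, total))
      ci <- findInterval(flat, c(offsets, total), rightmost.closed = TRUE)
      ch <- names(chrom_sizes)[ci]
      p <- as.integer(flat - offsets[ci])
      if (is.null(blacklist) || nrow(blacklist) == 0) return(list(chrom = ch, pos = p))
      bad <- vapply(seq_len(k), function(i) {
        any(blacklist$chrom == ch[i] & blacklist$start <= p[i] & blacklist$end > p[i])
      }, logical(1))
      if (!any(bad)) return(list(chrom = ch, pos = p))
      keep <- list(chrom = ch[!bad], pos = p[!bad])
      extra <- draw_positions(sum(bad))
      return(list(chrom = c(keep$chrom, extra$chrom), pos = c(keep$pos, extra$pos)))
    }
  }
  null_frac <- withr::with_seed(seed, {
    rp <- draw_positions(n_samples * n_peaks)
    ann <- annotate_positions(rp$chrom, rp$pos, genes, features,
                              promoter_bp, downstream_bp, intergenic_bp)
    rep_id <- rep(seq_len(n_samples), each = n_peaks)
    vapply(peak_categories, function(cat) {
      as.numeric(tapply(ann$category == cat, rep_id, mean))
    }, numeric(n_samples))
  })
  null_frac <- matrix(null_frac, nrow = n_samples)
  colnames(null_frac) <- peak_categories
  purrr::map_dfr(peak_categories, function(cat) {
    nf <- null_frac[, cat]
    p_hi <- (1 + sum(nf >= obs_frac[[cat]])) / (n_samples + 1)
    p_lo <- (1 + sum(nf <= obs_frac[[cat]])) / (n_samples + 1)
    tibble::tibble(category = cat, observed_fraction = obs_frac[[cat]],
                   null_mean = mean(nf), p_greater = p_hi, p_less = p_lo,
                   empirical_p = min(1, 2 * min(p_hi, p_lo)))
  })
}
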