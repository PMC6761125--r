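#' @title Coverage tracks
#'
#' @description A `coverage_track` holds dense per-base signal, one numeric
#' vector per chromosome, together with its units (raw fragment counts, FP10M,
#' RPM, or arbitrary score), strandedness and the raw library size. FP10M
#' (fragments per 10 million aligned fragments) is the linear library-size
#' normalization used for all ChIP-seq coverage in this package.
#'
#' @name coverage
NULL

#' Construct a coverage track
#'
#' @param values named list of per-chromosome numeric vectors (one value per
#'   bp, 0-based positions `0..len-1` stored at indexes `1..len`).
#' @param units one of `"raw"`, `"FP10M"`, `"RPM"`, `"score"`.
#' @param strand `"+"`, `"-"` or `"unstranded"`.
#' @param total_fragments raw library size before any normalization.
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, units = "raw", strand = "unstranded",
                           total_fragments = NA_real_) {
  stopifnot(is.list(values), !is.null(names(values)))
  units <- match.arg(units, c("raw", "FP10M", "RPM", "score"))
  strand <- match.arg(strand, c("+", "-", "unstranded"))
  if (units != "score") {
    bad <- vapply(values, function(v) any(!is.finite(v)) || any(v < 0), logical(1))
    if (any(bad)) stop("fragment coverage values must be finite and >= 0")
  }
  structure(
    list(values = values, units = units, strand = strand,
         total_fragments = total_fragments),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  lens <- vapply(x$values, length, integer(1))
  cat("<coverage_track> ", length(lens), " chromosome(s), ",
      format(sum(lens), big.mark = ","), " bp, units=", x$units,
      ", strand=", x$strand,
      if (!is.na(x$total_fragments)) paste0(", fragments=", x$total_fragments),
      "\n", sep = "")
  invisible(x)
}

track_chrom_sizes <- function(track) {
  vapply(track$values, length, integer(1))
}

# raw per-bp values of [start, end) on one chromosome; errors out of bounds
track_values <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  if (start < 0 || end > length(v)) {
    stop("region [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", length(v), ")")
  }
  v[(start + 1):end]
}

#' Read a chrom.sizes file
#'
#' Two-column whitespace-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("chrom", "size"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$size, df$chrom)
}

#' Load a coverage track from bedGraph or fragment BED
#'
#' bedGraph input (4 columns: chrom, start, end, value) is expanded to
#' per-base signal; overlapping bedGraph intervals are an error. Fragment BED
#' input (3+ columns) is converted to per-base coverage by counting
#' overlapping fragments, with optional fragment-length filtering (e.g.,
#' 70-250 bp for MNase/histone data).
#'
#' @param path input file.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param format `"auto"` (by extension), `"bedgraph"` or `"bed"`.
#' @param normalize `"none"`, `"FP10M"` (1e7 / total fragments) or `"RPM"`.
#' @param total_fragments library size; required to normalize bedGraph input
#'   (inferred as the fragment count for BED input).
#' @param min_frag,max_frag inclusive fragment-length bounds for BED input.
#' @param strand strandedness label for the track.
#' @return a [coverage_track()].
#' @export
load_coverage <- function(path, chrom_sizes, format = "auto",
                          normalize = "none", total_fragments = NULL,
                          min_frag = NULL, max_frag = NULL,
                          strand = "unstranded") {
  format <- match.arg(format, c("auto", "bedgraph", "bed"))
  normalize <- match.arg(normalize, c("none", "FP10M", "RPM"))
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bdg)$", path, ignore.case = TRUE)) "bedgraph" else "bed"
  }
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         if (format == "bedgraph") "numeric"),
                          col.names = c("chrom", "start", "end",
                                        if (format == "bedgraph") "value"))
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown) > 0) stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (any(df$end <= df$start)) stop("intervals with end <= start")
  if (any(df$start < 0) || any(df$end > chrom_sizes[df$chrom])) {
    stop("intervals outside chromosome bounds")
  }
  values <- lapply(names(chrom_sizes), function(ch) numeric(chrom_sizes[[ch]]))
  names(values) <- names(chrom_sizes)
  if (format == "bedgraph") {
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, ]
      sub <- sub[order(sub$start), ]
      if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
        stop("overlapping bedGraph intervals on ", ch)
      }
      v <- values[[ch]]
      idx <- sequence(sub$end - sub$start, from = sub$start + 1)
      v[idx] <- rep(sub$value, sub$end - sub$start)
      values[[ch]] <- v
    }
    tf <- if (is.null(total_fragments)) NA_real_ else total_fragments
  } else {
    len <- df$end - df$start
    if (!is.null(min_frag)) df <- df[len >= min_frag, , drop = FALSE]
    len <- df$end - df$start
    if (!is.null(max_frag)) df <- df[len <= max_frag, , drop = FALSE]
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, ]
      delta <- numeric(chrom_sizes[[ch]] + 1)
      tab_s <- tabulate(sub$start + 1, nbins = chrom_sizes[[ch]] + 1)
      tab_e <- tabulate(sub$end + 1, nbins = chrom_sizes[[ch]] + 1)
      delta <- tab_s - tab_e
      values[[ch]] <- cumsum(delta)[seq_len(chrom_sizes[[ch]])]
    }
    tf <- nrow(df)
  }
  track <- coverage_track(values, units = "raw", strand = strand,
                          total_fragments = tf)
  if (normalize != "none") track <- normalize_coverage(track, normalize, tf)
  track
}

#' Library-size normalize a raw coverage track
#'
#' @param track raw-count [coverage_track()].
#' @param method `"FP10M"` (x 1e7 / total fragments) or `"RPM"` (x 1e6 / total).
#' @param total_fragments library size; defaults to the track's own.
#' @return normalized track.
#' @export
normalize_coverage <- function(track, method = "FP10M", total_fragments = NULL) {
  method <- match.arg(method, c("FP10M", "RPM"))
  tf <- if (is.null(total_fragments)) track$total_fragments else total_fragments
  if (is.null(tf) || is.na(tf)) stop("total_fragments required for ", method, " normalization")
  if (tf <= 0) stop("total_fragments must be > 0 for ", method, " normalization")
  fac <- if (method == "FP10M") 1e7 / tf else 1e6 / tf
  track$values <- lapply(track$values, function(v) v * fac)
  track$units <- method
  track$total_fragments <- tf
  track
}

#' Mean signal per bp over a region
#'
#' Read density of a region: total signal divided by region length in bp.
#'
#' @param track a [coverage_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open region.
#' @return mean per-bp signal (double).
#' @export
region_density <- function(track, chrom, start, end) {
  if (end <= start) stop("zero- or negative-length region")
  mean(track_values(track, chrom, start, end))
}

#' Write a coverage track as bedGraph
#'
#' Run-length encodes each chromosome; zero runs are omitted.
#'
#' @param track a [coverage_track()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  lines <- character(0)
  for (ch in names(track$values)) {
    r <- rle(track$values[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                                format(r$values[keep], trim = TRUE, scientific = FALSE)))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Build a greylist of artifact regions from control tracks
#'
#' Flags genome bins with systematically high signal across control samples
#' (input DNA / IgG ChIP). Per control, the per-bin count threshold is the
#' median, over `n_random` random samples of `sample_size` bins, of the
#' `quantile`-th percentile of a negative-binomial distribution fitted to each
#' sample by the method of moments (Poisson fallback when variance <= mean).
#' Bins exceeding their control's threshold in more than `majority` of the
#' controls are flagged, and adjacent flagged bins are merged.
#'
#' The same random bin samples are evaluated in every control, so the result
#' is invariant to control ordering.
#'
#' @param controls list of at least two raw-count [coverage_track()]s on the
#'   same genome.
#' @param bin_bp bin width in bp.
#' @param n_random number of random bin samples per control.
#' @param sample_size bins per random sample (capped at the bin count with a
#'   warning).
#' @param quantile percentile of the fitted distribution used as threshold.
#' @param majority fraction of controls that must exceed threshold.
#' @param seed integer seed for the random bin samples.
#' @return tibble with `chrom`, `start`, `end`, `n_supporting_controls`.
#' @export
build_blacklist <- function(controls, bin_bp = 1000, n_random = 100,
                            sample_size = 30000, quantile = 0.95,
                            majority = 0.5, seed = 1L) {
  if (length(controls) < 2) stop("need at least 2 control tracks")
  sizes <- track_chrom_sizes(controls[[1]])
  for (tr in controls[-1]) {
    if (!identical(track_chrom_sizes(tr), sizes)) stop("controls are on different genomes")
  }
  bin_counts <- function(track) {
    unlist(lapply(names(sizes), function(ch) {
      v <- track$values[[ch]]
      g <- (seq_along(v) - 1) %/% bin_bp
      as.numeric(rowsum(v, g))
    }), use.names = FALSE)
  }
  bins_tbl <- dplyr::bind_rows(lapply(names(sizes), function(ch) {
    n_bins <- ceiling(sizes[[ch]] / bin_bp)
    tibble::tibble(chrom = ch,
                   start = (seq_len(n_bins) - 1) * bin_bp,
                   end = pmin(seq_len(n_bins) * bin_bp, sizes[[ch]]))
  }))
  counts <- vapply(controls, bin_counts, numeric(nrow(bins_tbl)))
  n_bins <- nrow(bins_tbl)
  ss <- sample_size
  if (ss > n_bins) {
    warning("sample_size exceeds bin count; sampling all bins")
    ss <- n_bins
  }
  sample_sets <- withr::with_seed(seed, {
    replicate(n_random, sample.int(n_bins, ss), simplify = FALSE)
  })
  nb_q <- function(x) {
    m <- mean(x); v <- stats::var(x)
    if (is.na(v) || v <= m || m == 0) {
      stats::qpois(quantile, lambda = m)
    } else {
      stats::qnbinom(quantile, size = m^2 / (v - m), mu = m)
    }
  }
  flagged <- vapply(seq_along(controls), function(j) {
    thr <- stats::median(vapply(sample_sets, function(s) nb_q(counts[s, j]), numeric(1)))
    counts[, j] > thr
  }, logical(n_bins))
  support <- rowSums(flagged)
  hit <- support > majority * length(controls)
  if (!any(hit)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_supporting_controls = integer()))
  }
  hits <- bins_tbl[hit, ]
  hits$support <- support[hit]
  # merge adjacent flagged bins per chromosome
  hits |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1, diff(.data$start) > bin_bp))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_supporting_controls = as.integer(max(.data$support)),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "n_supporting_controls") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Call nucleosome-free regions
#'
#' Maximal runs of more than `min_len` consecutive bp where both the MNase-seq
#' and the H3 ChIP-seq coverage are below their respective genome-wide first
#' quartiles (computed over all bases, zeros included). Runs overlapping any
#' `exclude` region (peaks, blacklist) are removed.
#'
#' @param mnase,h3 [coverage_track()]s on the same genome.
#' @param min_len minimum run length in bp (strictly greater than).
#' @param exclude optional tibble with `chrom`, `start`, `end` to mask.
#' @return tibble `chrom`, `start`, `end` of the retained regions.
#' @export
call_nfr <- function(mnase, h3, min_len = 500, exclude = NULL) {
  sizes <- track_chrom_sizes(mnase)
  if (!identical(sizes, track_chrom_sizes(h3))) stop("tracks are on different genomes")
  q1_m <- stats::quantile(unlist(mnase$values, use.names = FALSE), 0.25, names = FALSE)
  q1_h <- stats::quantile(unlist(h3$values, use.names = FALSE), 0.25, names = FALSE)
  if (q1_m <= 0 || q1_h <= 0) {
    warning("first quartile is zero in at least one track; no regions callable")
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  out <- list()
  for (ch in names(sizes)) {
    low <- mnase$values[[ch]] < q1_m & h3$values[[ch]] < q1_h
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values & r$lengths > min_len
    if (any(keep)) {
      out[[ch]] <- tibble::tibble(chrom = ch, start = starts[keep], end = ends[keep])
    }
  }
  res <- if (length(out) > 0) dplyr::bind_rows(out) else {
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  }
  if (!is.null(exclude) && nrow(res) > 0 && nrow(exclude) > 0) {
    bad <- vapply(seq_len(nrow(res)), function(i) {
      any(exclude$chrom == res$chrom[i] &
            exclude$start < res$end[i] & exclude$end > res$start[i])
    }, logical(1))
    res <- res[!bad, ]
  }
  res
}
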