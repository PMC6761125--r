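#' @title Gene annotation input/output
#'
#' @description Gene models are plain tibbles with one row per gene and
#' columns `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#' `tss`, `tes`, `biotype`. The TSS is `start` on the plus strand and
#' `end - 1` on the minus strand; the TES is the opposite boundary. Optional
#' sub-features (UTRs, exons) travel in a `features` attribute tibble
#' (`gene_id`, `kind`, `start`, `end`).
#'
#' @name annotation-io
NULL

#' Derive TSS/TES and validate a gene table
#'
#' @param genes tibble with `gene_id`, `chrom`, `start`, `end`, `strand` and
#'   optionally `biotype`.
#' @param features optional feature tibble to attach.
#' @return validated gene tibble sorted by (chrom, start), with `tss`/`tes`.
#' @export
as_gene_model <- function(genes, features = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(genes$end <= genes$start)) {
    bad <- genes$gene_id[genes$end <= genes$start][1]
    stop("gene with end <= start: ", bad)
  }
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1])
  }
  genes <- genes |>
    dplyr::mutate(
      tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
      tes = ifelse(.data$strand == "+", .data$end - 1L, .data$start),
      biotype = if ("biotype" %in% names(genes)) .data$biotype else "protein_coding"
    ) |>
    dplyr::arrange(.data$chrom, .data$start, .data$gene_id) |>
    dplyr::select("gene_id", "chrom", "start", "end", "strand", "tss", "tes",
                  "biotype", dplyr::any_of(setdiff(names(genes),
                    c("gene_id", "chrom", "start", "end", "strand", "tss", "tes", "biotype"))))
  if (!is.null(features)) {
    stopifnot(all(c("gene_id", "kind", "start", "end") %in% names(features)))
    span <- genes[match(features$gene_id, genes$gene_id), ]
    if (any(is.na(span$gene_id))) stop("feature refers to unknown gene")
    if (any(features$start < span$start | features$end > span$end)) {
      stop("features must lie within their gene span")
    }
    attr(genes, "features") <- tibble::as_tibble(features)
  }
  genes
}

#' Sub-feature table of a gene model
#'
#' @param genes gene tibble from [as_gene_model()] or [load_annotation()].
#' @return feature tibble, or an empty tibble when none attached.
#' @export
gene_features <- function(genes) {
  f <- attr(genes, "features")
  if (is.null(f)) {
    tibble::tibble(gene_id = character(), kind = character(),
                   start = integer(), end = integer())
  } else f
}

#' Load a gene annotation from GFF3 or BED
#'
#' GFF3 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. `type == "gene"` records become gene models;
#' `five_prime_UTR`, `three_prime_UTR` and `exon` records are attached as
#' sub-features, resolving `Parent` through one mRNA level if needed.
#' BED6/BED12 files are taken as one gene per line.
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param biotype_filter optional biotype to keep (GFF3 `biotype`/`gene_biotype`
#'   attribute).
#' @return gene tibble (see [as_gene_model()]).
#' @export
load_annotation <- function(path, biotype_filter = NULL) {
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  if (is_gff) {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- tibble::as_tibble(as.data.frame(gr))
    df$start0 <- df$start - 1L   # GFF3 1-based closed -> 0-based half-open
    df$end0 <- df$end
    bio_col <- intersect(c("biotype", "gene_biotype"), names(df))
    genes <- df[df$type == "gene", ]
    if (nrow(genes) == 0) stop("no gene records in ", path)
    gt <- tibble::tibble(
      gene_id = as.character(genes$ID),
      chrom = as.character(genes$seqnames),
      start = genes$start0, end = genes$end0,
      strand = as.character(genes$strand),
      biotype = if (length(bio_col) > 0) as.character(genes[[bio_col[1]]]) else "protein_coding"
    )
    gt$biotype[is.na(gt$biotype)] <- "protein_coding"
    if (!is.null(biotype_filter)) gt <- gt[gt$biotype == biotype_filter, ]
    # map transcript-level parents back to genes (one level)
    has_parents <- all(c("Parent", "ID") %in% names(df))
    tx_parent <- if (has_parents) {
      stats::setNames(
        vapply(df$Parent, function(p) if (length(p) > 0) p[[1]] else NA_character_, character(1)),
        as.character(df$ID)
      )
    } else character(0)
    resolve_gene <- function(parent) {
      ifelse(parent %in% gt$gene_id, parent,
             unname(tx_parent[parent]))
    }
    fk <- df[df$type %in% c("five_prime_UTR", "three_prime_UTR", "exon", "intron"), ]
    features <- NULL
    if (nrow(fk) > 0 && has_parents) {
      par <- vapply(fk$Parent, function(p) if (length(p) > 0) p[[1]] else NA_character_, character(1))
      features <- tibble::tibble(
        gene_id = resolve_gene(par),
        kind = as.character(fk$type),
        start = fk$start0, end = fk$end0
      )
      features <- features[!is.na(features$gene_id) & features$gene_id %in% gt$gene_id, ]
      if (nrow(features) == 0) features <- NULL
    }
    as_gene_model(gt, features)
  } else {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED file needs at least 6 columns (strand required)")
    gt <- tibble::tibble(
      gene_id = as.character(df[[4]]),
      chrom = as.character(df[[1]]),
      start = as.integer(df[[2]]), end = as.integer(df[[3]]),
      strand = as.character(df[[6]])
    )
    as_gene_model(gt)
  }
}

#' Write a gene annotation as GFF3
#'
#' Converts the internal 0-based half-open coordinates back to GFF3 1-based
#' closed. Attached sub-features are written with `Parent` pointing at the
#' gene.
#'
#' @param genes gene tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  gene_lines <- sprintf(
    "%s\tpausepoint\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
    genes$chrom, genes$start + 1L, genes$end, genes$strand,
    genes$gene_id, genes$biotype
  )
  feats <- gene_features(genes)
  feat_lines <- character(0)
  if (nrow(feats) > 0) {
    st <- genes$strand[match(feats$gene_id, genes$gene_id)]
    feat_lines <- sprintf(
      "%s\tpausepoint\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
      genes$chrom[match(feats$gene_id, genes$gene_id)], feats$kind,
      feats$start + 1L, feats$end, st,
      paste0(feats$gene_id, ":", feats$kind, ":", seq_len(nrow(feats))),
      feats$gene_id
    )
  }
  readr::write_lines(c("##gff-version 3", gene_lines, feat_lines), path)
  invisible(path)
}

#' Write a gene annotation as BED6
#'
#' @param genes gene tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(genes, path) {
  readr::write_lines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                             genes$end, genes$gene_id, genes$strand), path)
  invisible(path)
}
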