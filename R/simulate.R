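#' @title Synthetic experiment generator
#'
#' @description Generates a compact synthetic genome with controlled gene-pair
#' structure, strand-aware polymerase coverage with a parameterized 3' pausing
#' bump, negative-binomial RNA-seq differential-expression tables with planted
#' effects, control-ChIP tracks with artifact hot regions, and gene-loop
#' labels - together with complete ground-truth bookkeeping, so every analysis
#' stage of the package can be checked against a planted truth.
#'
#' The defaults emulate the structural features reported for the biological
#' system the package targets: tandem upstream neighbors of protected genes at
#' short intergenic distances (median 244 bp vs a genome-wide 859 bp), a
#' same-strand upstream-neighbor rate of 74% for protected genes vs 50%
#' genome-wide, upstream neighbors expressed ~2.5-fold above background, a 3'
#' pausing bump ~100 bp past the TES whose amplitude halves and whose position
#' shifts 96 bp downstream in the mutant.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' @param seed default integer seed for all generator calls.
#' @param n_genes number of genes on the single synthetic chromosome.
#' @param gene_len log-normal gene-length law (bp) with a floor.
#' @param intergenic log-normal background intergenic-distance law with floor.
#' @param fraction_tandem probability that a gene shares its predecessor's
#'   strand (0.5 = independent strands, 50% tandem background).
#' @param protected protected-gene planting: fraction of genes, probability of
#'   a same-strand upstream neighbor, short intergenic law, upstream
#'   expression boost (log2) and planted mutant/wt log2FC.
#' @param repressed repressed-gene fraction and planted log2FC.
#' @param expression normal law of log2 expression.
#' @param pausing TES bump: center (bp downstream of TES), sd (bp), amplitude
#'   (multiple of the gene's body plateau).
#' @param mutant mutant effects: bump amplitude ratio (applied to all genes),
#'   downstream shift in bp, and shift scope (`"upstream_of_protected"`,
#'   `"all"`, `"none"`).
#' @param tss_bump TSS-proximal bump for initiation-phosphorylated profiles.
#' @param s2p_ramp body-plateau multiplier from TSS to TES for the
#'   elongation-phosphorylated profile.
#' @param depth expected body coverage per bp per unit linear expression.
#' @param noise Poisson-sample the expected coverage (FALSE = noiseless).
#' @param light light experiment planting: fractions of light-up/down genes,
#'   their log2FC, the TI effect (log2, applied in light to genes downstream
#'   of / near light-re-leveled same-strand upstream genes), the relief
#'   effect, the distance cutoff, and `ti_scope` selecting which planted TI
#'   route is active (`"both"`, `"upstream_induced"`, `"focal_induced"`).
#' @param loops Bernoulli loop rates: baseline and for upstream-tandem
#'   neighbors of protected genes.
#' @param hot_regions artifact regions planted into control tracks.
#' @param nb_size negative-binomial size (1/dispersion) of simulated counts.
#' @param n_reps RNA-seq replicates per genotype x condition.
#' @param count_depth expected counts per unit linear expression.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 600,
                       gene_len = list(meanlog = log(2000), sdlog = 0.3, min = 1100),
                       intergenic = list(meanlog = log(859), sdlog = 0.8, min = 40),
                       fraction_tandem = 0.5,
                       protected = list(fraction = 0.15, tandem_prob = 0.74,
                                        intergenic_meanlog = log(244),
                                        intergenic_sdlog = 0.5,
                                        upstream_expression_boost = 1.32,
                                        lfc = -1.5),
                       repressed = list(fraction = 0.10, lfc = 1.5),
                       expression = list(mean = 3, sd = 1.25),
                       pausing = list(bump_center = 100, bump_sd = 50, amplitude = 4),
                       mutant = list(amplitude_ratio = 0.5, shift_bp = 96,
                                     shift_scope = "upstream_of_protected"),
                       tss_bump = list(center = 0, sd = 75, amplitude = 2),
                       s2p_ramp = c(0.5, 1.5),
                       depth = 1.0, noise = TRUE,
                       light = list(up_fraction = 0.25, down_fraction = 0.10,
                                    lfc = 2, ti_effect = -1, relief_effect = 1,
                                    d_max = 600, ti_scope = "both"),
                       loops = list(base_rate = 0.10, protected_upstream_rate = 0.20),
                       hot_regions = list(n = 10, width = 3000, fold = 20,
                                          background = 2),
                       nb_size = 100, n_reps = 3, count_depth = 25) {
  stopifnot(fraction_tandem >= 0, fraction_tandem <= 1,
            mutant$amplitude_ratio > 0, mutant$shift_bp >= 0,
            protected$fraction >= 0, protected$fraction <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic gene annotation with planted pair structure
#'
#' Genes are laid head-to-tail on one chromosome with drawn lengths, strands
#' and intergenic gaps. A designated protected subset (never adjacent to each
#' other, never the first gene) is placed on the plus strand with its
#' immediate left (= upstream) neighbor forced to the same strand with
#' probability `protected$tandem_prob`, at a short intergenic distance, and
#' with a boosted upstream expression. Each gene receives a 5' UTR, two exons
#' flanking one intron, and a 3' UTR.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return list with `genes` (gene tibble, chromosome length in the
#'   `chrom_sizes` attribute) and `truth` (per-gene tibble of planted
#'   quantities plus planted hot regions in the `hot_regions` attribute).
#' @export
gen_annotation <- function(cfg, seed = cfg$seed) {
  withr::with_seed(seed, {
    n <- cfg$n_genes
    lens <- pmax(cfg$gene_len$min, round(stats::rlnorm(n, cfg$gene_len$meanlog,
                                                       cfg$gene_len$sdlog)))
    strand <- character(n)
    strand[1] <- sample(c("+", "-"), 1)
    for (i in 2:n) {
      strand[i] <- if (stats::runif(1) < cfg$fraction_tandem) strand[i - 1] else
        setdiff(c("+", "-"), strand[i - 1])
    }
    n_prot <- round(cfg$protected$fraction * n)
    prot_pool <- seq(3, n - 1, by = 2)  # keeps protected genes non-adjacent
    prot_idx <- sort(sample(prot_pool, min(n_prot, length(prot_pool))))
    n_prot <- length(prot_idx)
    up_same <- stats::runif(n_prot) < cfg$protected$tandem_prob
    strand[prot_idx] <- "+"
    strand[prot_idx - 1] <- ifelse(up_same, "+", "-")
    gaps <- pmax(cfg$intergenic$min,
                 round(stats::rlnorm(n, cfg$intergenic$meanlog, cfg$intergenic$sdlog)))
    gaps[prot_idx] <- pmax(cfg$intergenic$min,
                           round(stats::rlnorm(n_prot, cfg$protected$intergenic_meanlog,
                                               cfg$protected$intergenic_sdlog)))
    gaps[1] <- 2000
    starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
    ends <- starts + lens
    chrom_len <- ends[n] + 2000
    gene_id <- sprintf("G%04d", seq_len(n))
    expression <- stats::rnorm(n, cfg$expression$mean, cfg$expression$sd)
    is_up_of_prot <- seq_len(n) %in% (prot_idx - 1)
    expression[prot_idx - 1] <- expression[prot_idx - 1] +
      cfg$protected$upstream_expression_boost
    role <- rep("normal", n)
    role[prot_idx] <- "protected"
    rep_pool <- setdiff(seq_len(n), c(prot_idx, prot_idx - 1))
    rep_idx <- sort(sample(rep_pool, round(cfg$repressed$fraction * n)))
    role[rep_idx] <- "repressed"
    # light experiment planting
    light_class <- rep("none", n)
    light_class[stats::runif(n) < cfg$light$up_fraction] <- "up"
    pool_down <- which(light_class == "none")
    light_class[pool_down[stats::runif(length(pool_down)) <
                            cfg$light$down_fraction / (1 - cfg$light$up_fraction)]] <- "down"
    r_dark <- dplyr::case_when(role == "protected" ~ cfg$protected$lfc,
                               role == "repressed" ~ cfg$repressed$lfc,
                               TRUE ~ 0)
    # realized upstream neighbor (sequential layout: previous gene for +,
    # next gene for -)
    up_idx <- ifelse(strand == "+", seq_len(n) - 1L, seq_len(n) + 1L)
    up_idx[up_idx < 1 | up_idx > n] <- NA_integer_
    up_same_strand <- !is.na(up_idx) & strand[pmax(up_idx, 1L)] == strand
    up_gap <- ifelse(is.na(up_idx), NA_integer_,
                     ifelse(strand == "+", gaps, gaps[pmin(up_idx, n)]))
    up_light <- ifelse(is.na(up_idx), "none", light_class[pmax(up_idx, 1L)])
    close_tandem <- up_same_strand & !is.na(up_gap) & up_gap < cfg$light$d_max
    # interference aggravated under light, two planted routes (selectable via
    # light$ti_scope): the downstream partner of a light-induced upstream gene
    # ("upstream_induced"), and a light-induced gene close downstream of any
    # same-strand neighbor, whose induction the mutant cannot protect
    # ("focal_induced"); default "both"
    scope <- cfg$light$ti_scope %||% "both"
    ti_light <- close_tandem & up_light == "up" & scope != "focal_induced"
    ti_focal <- close_tandem & light_class == "up" & scope != "upstream_induced"
    relief <- close_tandem & up_light == "down" & r_dark < 0
    ti_eff <- ifelse(ti_light | ti_focal, cfg$light$ti_effect, 0) +
      ifelse(relief, cfg$light$relief_effect, 0)
    r_light <- r_dark + ti_eff
    truth <- tibble::tibble(
      gene_id = gene_id, idx = seq_len(n), strand = strand, length = lens,
      gap_before = gaps, role = role,
      is_upstream_of_protected = is_up_of_prot,
      planted_up_same_strand = FALSE,
      expression = expression, r_dark = r_dark,
      light_class = light_class, up_same_strand = up_same_strand,
      up_gap = up_gap, ti_light = ti_light, ti_focal = ti_focal,
      relief = relief,
      r_light2 = r_light, r_light4 = r_light
    )
    truth$planted_up_same_strand <- FALSE
    truth$planted_up_same_strand[prot_idx] <- up_same
    genes <- as_gene_model(
      tibble::tibble(gene_id = gene_id, chrom = "chr1", start = starts,
                     end = ends, strand = strand,
                     biotype = "protein_coding"),
      features = gene_structure_features(gene_id, starts, ends, strand)
    )
    attr(genes, "chrom_sizes") <- c(chr1 = chrom_len)
    hot <- NULL
    if (cfg$hot_regions$n > 0) {
      hs <- sort(sample.int(chrom_len - cfg$hot_regions$width, cfg$hot_regions$n))
      hot <- tibble::tibble(chrom = "chr1", start = hs,
                            end = hs + cfg$hot_regions$width)
    }
    attr(truth, "hot_regions") <- hot
    list(genes = genes, truth = truth)
  })
}

# 5'UTR (first 10%), exon/intron/exon (45/10/45), 3'UTR (last 10%),
# in transcription direction
gene_structure_features <- function(gene_id, starts, ends, strand) {
  n <- length(gene_id)
  lens <- ends - starts
  cut1 <- starts + pmax(1L, round(0.45 * lens))
  cut2 <- starts + pmin(lens - 1L, round(0.55 * lens))
  utr_len <- pmax(1L, round(0.10 * lens))
  plus <- strand == "+"
  dplyr::bind_rows(
    tibble::tibble(gene_id = gene_id, kind = "exon", start = starts, end = cut1),
    tibble::tibble(gene_id = gene_id, kind = "exon", start = cut2, end = ends),
    tibble::tibble(gene_id = gene_id, kind = "five_prime_UTR",
                   start = ifelse(plus, starts, ends - utr_len),
                   end = ifelse(plus, starts + utr_len, ends)),
    tibble::tibble(gene_id = gene_id, kind = "three_prime_UTR",
                   start = ifelse(plus, ends - utr_len, starts),
                   end = ifelse(plus, ends, starts + utr_len))
  )
}

#' Generate a synthetic coverage track
#'
#' Expected per-bp signal per gene: a body plateau proportional to linear
#' expression (with a 5'-to-3' ramp for the elongation-mark profile), plus a
#' Gaussian 3' pausing bump centered `pausing$bump_center` bp downstream of
#' the TES (amplitude x `mutant$amplitude_ratio`, center + `mutant$shift_bp`
#' for in-scope genes, in the mutant condition), plus a TSS bump for the
#' initiation-mark profile. Control tracks are flat background with planted
#' hot regions; nucleosome-like tracks are flat background. Per-bp values are
#' Poisson-sampled unless `cfg$noise` is FALSE.
#'
#' @param cfg a [sim_config()].
#' @param genes,truth output of [gen_annotation()].
#' @param condition `"wt"` or `"mutant"`.
#' @param profile `"polii"`, `"s5p"`, `"s2p"`, `"mnase_like"` or `"control"`.
#' @param seed integer seed.
#' @return raw-count [coverage_track()].
#' @export
gen_coverage <- function(cfg, genes, truth, condition = c("wt", "mutant"),
                         profile = c("polii", "s5p", "s2p", "mnase_like", "control"),
                         seed = cfg$seed) {
  condition <- match.arg(condition)
  profile <- match.arg(profile)
  chrom_len <- attr(genes, "chrom_sizes")[["chr1"]]
  lambda <- numeric(chrom_len)
  if (profile %in% c("polii", "s5p", "s2p")) {
    tr <- truth[match(genes$gene_id, truth$gene_id), ]
    plateau <- cfg$depth * 2^tr$expression
    shifted <- switch(cfg$mutant$shift_scope,
      all = rep(TRUE, nrow(genes)),
      none = rep(FALSE, nrow(genes)),
      upstream_of_protected = tr$is_upstream_of_protected
    )
    amp_ratio <- if (condition == "mutant") cfg$mutant$amplitude_ratio else 1
    for (i in seq_len(nrow(genes))) {
      span <- (genes$start[i] + 1):genes$end[i]
      body <- plateau[i]
      if (profile == "s2p") {
        ramp <- seq(cfg$s2p_ramp[1], cfg$s2p_ramp[2], length.out = length(span))
        if (genes$strand[i] == "-") ramp <- rev(ramp)
        lambda[span] <- lambda[span] + body * ramp
      } else {
        lambda[span] <- lambda[span] + body
      }
      dir <- if (genes$strand[i] == "+") 1 else -1
      center <- genes$tes[i] + dir * (cfg$pausing$bump_center +
        if (condition == "mutant" && shifted[i]) cfg$mutant$shift_bp else 0)
      # gaussian bump, added in place (a helper call would copy the genome
      # vector on every gene)
      sd_b <- cfg$pausing$bump_sd
      lo <- max(0L, floor(center - 4 * sd_b))
      hi <- min(chrom_len - 1L, ceiling(center + 4 * sd_b))
      if (hi >= lo) {
        x <- lo:hi
        lambda[x + 1L] <- lambda[x + 1L] + cfg$pausing$amplitude * amp_ratio *
          body * exp(-(x - center)^2 / (2 * sd_b^2))
      }
      if (profile == "s5p") {
        c5 <- genes$tss[i] + dir * cfg$tss_bump$center
        sd5 <- cfg$tss_bump$sd
        lo <- max(0L, floor(c5 - 4 * sd5))
        hi <- min(chrom_len - 1L, ceiling(c5 + 4 * sd5))
        if (hi >= lo) {
          x <- lo:hi
          lambda[x + 1L] <- lambda[x + 1L] + cfg$tss_bump$amplitude * body *
            exp(-(x - c5)^2 / (2 * sd5^2))
        }
      }
    }
  } else if (profile == "control") {
    lambda[] <- cfg$hot_regions$background
    hot <- attr(truth, "hot_regions")
    if (!is.null(hot)) {
      for (i in seq_len(nrow(hot))) {
        span <- (hot$start[i] + 1):hot$end[i]
        lambda[span] <- lambda[span] * cfg$hot_regions$fold
      }
    }
  } else {
    lambda[] <- 10
  }
  values <- if (cfg$noise) {
    withr::with_seed(seed, stats::rpois(chrom_len, lambda))
  } else lambda
  coverage_track(list(chr1 = as.numeric(values)), units = "raw",
                 strand = "unstranded",
                 total_fragments = round(sum(lambda)))
}


#' Generate differential-expression tables from planted effects
#'
#' Simulates negative-binomial counts per replicate for two genotypes (wt,
#' mutant) under three conditions (dark, light 2 h, light 4 h) from the
#' planted expression, light responses and mutant/wt ratios, then derives each
#' contrast's log2 fold-change, a per-gene Welch t-test p-value on log2
#' counts, and BH-adjusted p-values (per contrast).
#'
#' @param cfg a [sim_config()].
#' @param truth truth tibble from [gen_annotation()].
#' @param seed integer seed.
#' @return list: `de` (long tibble `gene_id`, `contrast`, `basemean`,
#'   `log2fc`, `pvalue`, `padj`) and `expr` (`gene_id`, `mean_expression`,
#'   `basemean`).
#' @export
gen_de_tables <- function(cfg, truth, seed = cfg$seed) {
  n <- nrow(truth)
  base <- cfg$count_depth * 2^truth$expression
  L <- dplyr::case_when(truth$light_class == "up" ~ cfg$light$lfc,
                        truth$light_class == "down" ~ -cfg$light$lfc,
                        TRUE ~ 0)
  mu <- list(
    wt_dark = base,
    wt_light2 = base * 2^L,
    wt_light4 = base * 2^L,
    mut_dark = base * 2^truth$r_dark,
    mut_light2 = base * 2^(L + truth$r_light2),
    mut_light4 = base * 2^(L + truth$r_light4)
  )
  counts <- withr::with_seed(seed, {
    lapply(mu, function(m) {
      matrix(stats::rnbinom(n * cfg$n_reps, mu = rep(m, cfg$n_reps),
                            size = cfg$nb_size), nrow = n)
    })
  })
  contrast_def <- list(
    wt_light2_vs_dark = c("wt_light2", "wt_dark"),
    wt_light4_vs_dark = c("wt_light4", "wt_dark"),
    mut_light2_vs_dark = c("mut_light2", "mut_dark"),
    mut_light4_vs_dark = c("mut_light4", "mut_dark"),
    mut_vs_wt_dark = c("mut_dark", "wt_dark"),
    mut_vs_wt_light2 = c("mut_light2", "wt_light2"),
    mut_vs_wt_light4 = c("mut_light4", "wt_light4")
  )
  welch_p <- function(a, b) {
    va <- stats::var(a); vb <- stats::var(b)
    if (va + vb == 0) return(1)
    se2 <- va / length(a) + vb / length(b)
    t_stat <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                     vb^2 / (length(b)^2 * (length(b) - 1)))
    2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  }
  de <- purrr::imap_dfr(contrast_def, function(pair, nm) {
    ca <- counts[[pair[1]]]; cb <- counts[[pair[2]]]
    la <- log2(ca + 0.5); lb <- log2(cb + 0.5)
    p <- vapply(seq_len(n), function(i) welch_p(la[i, ], lb[i, ]), numeric(1))
    tibble::tibble(
      gene_id = truth$gene_id, contrast = nm,
      basemean = rowMeans(cbind(ca, cb)),
      log2fc = log2((rowMeans(ca) + 0.5) / (rowMeans(cb) + 0.5)),
      pvalue = p, padj = bh_adjust(p)
    )
  })
  expr <- tibble::tibble(
    gene_id = truth$gene_id,
    mean_expression = log2(rowMeans(counts$wt_dark) + 0.5),
    basemean = rowMeans(do.call(cbind, counts))
  )
  list(de = de, expr = expr)
}

#' Generate gene-loop membership labels
#'
#' Bernoulli loop membership with a context-dependent rate: upstream-tandem
#' neighbors of protected genes loop at `loops$protected_upstream_rate`,
#' everything else at `loops$base_rate`.
#'
#' @param cfg a [sim_config()].
#' @param truth truth tibble from [gen_annotation()].
#' @param seed integer seed.
#' @return character vector of loop-forming gene ids, planted rates in the
#'   `rates` attribute.
#' @export
gen_loops <- function(cfg, truth, seed = cfg$seed) {
  enriched <- truth$is_upstream_of_protected &
    truth$strand == truth$strand[pmin(truth$idx + 1, nrow(truth))]
  rate <- ifelse(enriched, cfg$loops$protected_upstream_rate, cfg$loops$base_rate)
  hit <- withr::with_seed(seed, stats::runif(nrow(truth)) < rate)
  structure(truth$gene_id[hit], rates = rate)
}
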