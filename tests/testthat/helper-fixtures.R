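# Shared in-code fixtures for the test suite.

# hand-laid 4-gene annotation on one 20 kb chromosome:
#   gA + [1000,3000)   gB + [3244,5244)   gC - [6000,8000)   gD + [9000,12000)
# gA->gB is a tandem pair with a 244 bp gap; gB/gC are convergent; gC/gD divergent.
tiny_genes <- function() {
  as_gene_model(tibble::tibble(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = "chr1",
    start = c(1000L, 3244L, 6000L, 9000L),
    end = c(3000L, 5244L, 8000L, 12000L),
    strand = c("+", "+", "-", "+")
  ))
}

tiny_sizes <- c(chr1 = 20000L)

# constant-value track on the tiny genome
const_track <- function(value = 2, len = 20000L) {
  coverage_track(list(chr1 = rep(as.numeric(value), len)))
}

small_cfg <- function(seed = 1L, n_genes = 120, ...) {
  sim_config(seed = seed, n_genes = n_genes, ...)
}
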