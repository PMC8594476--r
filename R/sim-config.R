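#' Simulation configuration for synthetic single-nucleus editing data
#'
#' Builds and validates the parameter set used by the synthetic-data
#' generators. Defaults describe a desk-scale cortical sNuc-seq experiment:
#' two gross neuronal phenotypes mixed roughly 1 inhibitory : 3 excitatory,
#' six cortical regions, sites concentrated in Alu repeats, a bimodal
#' per-cell edited-allele-fraction mixture, and sparse negative-binomial
#' read coverage in which any given site is transcribed in only a few
#' percent of cells.
#'
#' @param n_cells number of nuclei to simulate.
#' @param n_sites number of candidate editing-site positions.
#' @param n_genes number of genes in the toy genome.
#' @param phenotype_proportions named numeric vector of phenotype mixing
#'   fractions; must sum to 1.
#' @param region_labels character vector of cortical region labels.
#' @param alu_fraction fraction of sites placed inside Alu repeats.
#' @param rep_nonalu_fraction fraction of sites inside non-Alu repeats.
#' @param intergenic_fraction fraction of sites placed outside any gene
#'   (these exercise the annotation-based drop rule).
#' @param overlap_fraction fraction of genes laid down overlapping the
#'   previous gene on the opposite strand.
#' @param decoy_fraction fraction of sites given a non-cognate variant
#'   class (A>G inside a minus-strand gene or vice versa); these are
#'   artifact decoys, not true editing.
#' @param catalog_fraction fraction of true editing sites present in the
#'   simulated known-site catalog.
#' @param snp_fraction fraction of sites that are genomic SNPs rather than
#'   editing (edited-allele fraction ~ allele dosage / 2 in all cells).
#' @param bimodal_mix numeric vector `c(low, high, weight)`: means of the
#'   low and high modes of the per-cell editing-probability mixture and
#'   the weight of the high mode.
#' @param mix_concentration beta concentration of the per-cell draw around
#'   each mode mean.
#' @param site_weight_concentration beta concentration of the per-site
#'   high-mode weight around `bimodal_mix["weight"]`; values near 1 give
#'   the positively skewed cross-site mean editing the analysis assumes.
#' @param celltype_effect list with `shift` (log-odds added to affected
#'   sites in the target phenotype), `fraction` (fraction of true sites
#'   affected) and `phenotype` (label receiving the shift).
#' @param cell_sd standard deviation of the per-cell log-odds random
#'   effect (drives cell-to-cell variation in overall editing level).
#' @param coverage_nb numeric vector `c(mean, size)` of the
#'   negative-binomial read depth at transcribed site/cell pairs.
#' @param expressed_fraction probability that a site is transcribed in a
#'   given cell (zero-inflation of depth).
#' @param mito_fail_fraction fraction of cells planted with mitochondrial
#'   read fraction above 0.15.
#' @param complexity_fail_fraction fraction of cells planted with low
#'   library complexity.
#' @param assoc_genes data.frame with columns `gene` (index) and `beta`
#'   (planted change in editing index per unit log10 TPM) for genes whose
#'   abundance is constructed to covary with per-cell editing.
#' @param assoc_noise_sd residual standard deviation (log10 units) of the
#'   abundance of association genes.
#' @param seed master integer seed; every sub-generator derives its own
#'   stream from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells = 500L,
                       n_sites = 5000L,
                       n_genes = 200L,
                       phenotype_proportions = c(Ex = 0.75, In = 0.25),
                       region_labels = c("BA8", "BA10", "BA17", "BA21",
                                         "BA22", "BA41"),
                       alu_fraction = 0.60,
                       rep_nonalu_fraction = 0.10,
                       intergenic_fraction = 0.02,
                       overlap_fraction = 0.10,
                       decoy_fraction = 0.05,
                       catalog_fraction = 0.80,
                       snp_fraction = 0.05,
                       bimodal_mix = c(low = 0.05, high = 0.90,
                                       weight = 0.40),
                       mix_concentration = 30,
                       site_weight_concentration = 1,
                       celltype_effect = list(shift = 0.5, fraction = 0.2,
                                              phenotype = "In"),
                       cell_sd = 0.4,
                       coverage_nb = c(mean = 20, size = 2),
                       expressed_fraction = 0.045,
                       mito_fail_fraction = 0.02,
                       complexity_fail_fraction = 0.01,
                       assoc_genes = data.frame(gene = c(1L, 2L),
                                                beta = c(0.05, -0.05)),
                       assoc_noise_sd = 0.15,
                       seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), n_sites = as.integer(n_sites),
              n_genes = as.integer(n_genes),
              phenotype_proportions = phenotype_proportions,
              region_labels = as.character(region_labels),
              alu_fraction = alu_fraction,
              rep_nonalu_fraction = rep_nonalu_fraction,
              intergenic_fraction = intergenic_fraction,
              overlap_fraction = overlap_fraction,
              decoy_fraction = decoy_fraction,
              catalog_fraction = catalog_fraction,
              snp_fraction = snp_fraction,
              bimodal_mix = bimodal_mix,
              mix_concentration = mix_concentration,
              site_weight_concentration = site_weight_concentration,
              celltype_effect = celltype_effect,
              cell_sd = cell_sd,
              coverage_nb = coverage_nb,
              expressed_fraction = expressed_fraction,
              mito_fail_fraction = mito_fail_fraction,
              complexity_fail_fraction = complexity_fail_fraction,
              assoc_genes = assoc_genes,
              assoc_noise_sd = assoc_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_cells < 1L) stop_cfg("n_cells", "must be >= 1")
  if (cfg$n_sites < 1L) stop_cfg("n_sites", "must be >= 1")
  if (cfg$n_genes < 1L) stop_cfg("n_genes", "must be >= 1")
  pp <- cfg$phenotype_proportions
  if (is.null(names(pp)) || any(!nzchar(names(pp))))
    stop_cfg("phenotype_proportions", "must be a named vector")
  if (any(pp < 0) || abs(sum(pp) - 1) > 1e-9)
    stop_cfg("phenotype_proportions", "must be nonnegative and sum to 1")
  fracs <- c(alu_fraction = cfg$alu_fraction,
             rep_nonalu_fraction = cfg$rep_nonalu_fraction,
             intergenic_fraction = cfg$intergenic_fraction,
             overlap_fraction = cfg$overlap_fraction,
             decoy_fraction = cfg$decoy_fraction,
             catalog_fraction = cfg$catalog_fraction,
             snp_fraction = cfg$snp_fraction,
             expressed_fraction = cfg$expressed_fraction,
             mito_fail_fraction = cfg$mito_fail_fraction,
             complexity_fail_fraction = cfg$complexity_fail_fraction)
  bad <- which(fracs < 0 | fracs > 1)
  if (length(bad))
    stop_cfg(names(fracs)[bad[1]], "must lie in [0, 1]")
  if (cfg$alu_fraction + cfg$rep_nonalu_fraction + cfg$intergenic_fraction > 1)
    stop_cfg("alu_fraction", paste("+ rep_nonalu_fraction +",
             "intergenic_fraction must not exceed 1"))
  bm <- cfg$bimodal_mix
  if (length(bm) != 3L || any(bm < 0) || any(bm[1:2] > 1) || bm[3] > 1)
    stop_cfg("bimodal_mix", "must be c(low, high, weight) in [0, 1]")
  if (cfg$coverage_nb[1] <= 0)
    stop_cfg("coverage_nb", "mean must be > 0")
  if (cfg$coverage_nb[2] <= 0)
    stop_cfg("coverage_nb", "size must be > 0")
  if (!is.null(cfg$assoc_genes) && nrow(cfg$assoc_genes) > 0) {
    if (!all(c("gene", "beta") %in% names(cfg$assoc_genes)))
      stop_cfg("assoc_genes", "must have columns 'gene' and 'beta'")
    if (any(cfg$assoc_genes$gene < 1 | cfg$assoc_genes$gene > cfg$n_genes))
      stop_cfg("assoc_genes", "gene indices must be in 1..n_genes")
  }
  invisible(cfg)
}

# Derive a deterministic sub-stream seed from the master seed. Offsets keep
# the four generator stages reproducible independently of one another.
sub_seed <- function(seed, stage) {
  offs <- c(annotation = 101L, cells = 211L, counts = 307L,
            expression = 401L)
  (as.integer(seed) %% 1000000000L) * 2L + offs[[stage]]
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_cells, "cells,", x$n_sites, "sites,",
      x$n_genes, "genes\n")
  cat("  phenotypes:",
      paste(sprintf("%s=%.2f", names(x$phenotype_proportions),
                    x$phenotype_proportions), collapse = ", "), "\n")
  cat("  contexts: Alu", x$alu_fraction, "| rep non-Alu",
      x$rep_nonalu_fraction, "| SNP", x$snp_fraction, "\n")
  cat("  mixture: low", x$bimodal_mix[[1]], "high", x$bimodal_mix[[2]],
      "weight", x$bimodal_mix[[3]], "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
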