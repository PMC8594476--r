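#' @importFrom stats rbeta rbinom rnbinom rnorm runif rpois plogis qlogis
#'   rlnorm var
NULL

GENE_LEN <- 6000L
GENE_GAP <- 2000L
GENE_OVERLAP <- 1000L

# Feature layout of a toy gene, in 0-based offsets relative to gene start.
# Exons at 0-599, 2600-3199, 5200-5999; introns between. UTR/stop placement
# depends on strand (the left end is the 3' end of a minus-strand gene).
gene_feature_offsets <- function(strand) {
  ex <- data.frame(type = "exon",
                   off1 = c(0L, 2600L, 5200L),
                   off2 = c(599L, 3199L, 5999L))
  if (strand == "+") {
    extra <- data.frame(
      type = c("five_prime_UTR", "stop_codon", "three_prime_UTR"),
      off1 = c(0L, 5400L, 5403L),
      off2 = c(399L, 5402L, 5999L))
  } else {
    extra <- data.frame(
      type = c("three_prime_UTR", "stop_codon", "five_prime_UTR"),
      off1 = c(0L, 597L, 5600L),
      off2 = c(596L, 599L, 5999L))
  }
  rbind(ex, extra)
}

# Repeat intervals per gene (0-based offsets). Alu elements cluster in the
# first two introns plus one in the 3'-UTR-proximal exon; a single non-Alu
# repeat sits in the second intron.
repeat_offsets <- function(strand) {
  alu_utr <- if (strand == "+") c(5450L, 5749L) else c(150L, 449L)
  data.frame(
    class = c("Alu", "Alu", "Alu", "Alu", "repNonAlu"),
    off1 = c(700L, 1300L, 3400L, alu_utr[1], 4000L),
    off2 = c(999L, 1599L, 3699L, alu_utr[2], 4299L))
}

#' Simulate a toy genome annotation, editing catalog and SNP list
#'
#' Lays out `n_genes` genes on one chromosome, alternating strands, with a
#' configurable fraction overlapping the previous gene on the opposite
#' strand (such regions are ambiguous for unstranded variant calls and are
#' rescue-ineligible unless cataloged). Alu and non-Alu repeat intervals
#' are nested inside introns and 3' UTRs. Candidate site positions are
#' drawn inside (and, for a small fraction, between) genes with the
#' configured context mix; a fraction of true editing sites enters the
#' known-site catalog, a disjoint fraction is marked as genomic SNPs, and
#' a further fraction becomes non-cognate "decoy" variants.
#'
#' @param config a [sim_config()] object.
#' @return list with elements `genes` (gene/feature table, GFF3-like,
#'   1-based inclusive), `repeats` (repeat intervals, 1-based inclusive,
#'   class Alu/repNonAlu), `sites` (per-site truth table), `catalog`
#'   (known editing sites: chrom, pos, strand, context), and `snps`
#'   (chrom, pos, ref, alt).
#' @export
simulate_annotation <- function(config) {
  validate_sim_config(config)
  set.seed(sub_seed(config$seed, "annotation"))
  ng <- config$n_genes
  chrom <- "chr1"

  # gene placement
  starts <- integer(ng); strands <- character(ng)
  overlaps_prev <- runif(ng) < config$overlap_fraction
  overlaps_prev[1] <- FALSE
  cur <- 1000L
  for (i in seq_len(ng)) {
    if (overlaps_prev[i]) {
      starts[i] <- cur - GENE_OVERLAP  # tail overlap with previous gene
      strands[i] <- if (strands[i - 1] == "+") "-" else "+"
    } else {
      starts[i] <- cur + GENE_GAP
      strands[i] <- if (runif(1) < 0.5) "+" else "-"
    }
    cur <- starts[i] + GENE_LEN
  }
  gene_ids <- sprintf("gene%03d", seq_len(ng))
  genes <- data.frame(chrom = chrom, start = starts,
                      end = starts + GENE_LEN - 1L, strand = strands,
                      gene_id = gene_ids, type = "gene",
                      stringsAsFactors = FALSE)
  feats <- do.call(rbind, lapply(seq_len(ng), function(i) {
    fo <- gene_feature_offsets(strands[i])
    data.frame(chrom = chrom, start = starts[i] + fo$off1,
               end = starts[i] + fo$off2, strand = strands[i],
               gene_id = gene_ids[i], type = fo$type,
               stringsAsFactors = FALSE)
  }))
  gene_tab <- rbind(genes, feats)
  gene_tab <- gene_tab[order(gene_tab$start, gene_tab$end), ]
  rownames(gene_tab) <- NULL

  reps <- do.call(rbind, lapply(seq_len(ng), function(i) {
    ro <- repeat_offsets(strands[i])
    data.frame(chrom = chrom, start = starts[i] + ro$off1,
               end = starts[i] + ro$off2, class = ro$class,
               strand = strands[i], stringsAsFactors = FALSE)
  }))
  rownames(reps) <- NULL

  # ---- site placement ----
  ns <- config$n_sites
  n_alu <- round(config$alu_fraction * ns)
  n_rna <- round(config$rep_nonalu_fraction * ns)
  n_inter <- round(config$intergenic_fraction * ns)
  n_nonrep <- ns - n_alu - n_rna - n_inter

  pick_in_intervals <- function(n, ints) {
    idx <- sample.int(nrow(ints), n, replace = TRUE)
    pos <- ints$start[idx] +
      floor(runif(n) * (ints$end[idx] - ints$start[idx] + 1L))
    as.integer(pos)
  }
  alu_ints <- reps[reps$class == "Alu", ]
  rna_ints <- reps[reps$class == "repNonAlu", ]
  pos_alu <- pick_in_intervals(n_alu, alu_ints)
  pos_rna <- pick_in_intervals(n_rna, rna_ints)

  # nonrepetitive: inside genes but outside any repeat interval
  gene_for_site <- sample.int(ng, n_nonrep, replace = TRUE)
  pos_nonrep <- integer(n_nonrep)
  for (i in seq_len(n_nonrep)) {
    g <- gene_for_site[i]
    ro <- repeat_offsets(strands[g])
    repeat {
      off <- floor(runif(1) * GENE_LEN)
      if (!any(off >= ro$off1 & off <= ro$off2)) break
    }
    pos_nonrep[i] <- starts[g] + as.integer(off)
  }
  # intergenic: in the gaps between genes
  pos_inter <- integer(0)
  if (n_inter > 0) {
    gap_start <- c(1L, genes$end + 1L)
    gap_end <- c(genes$start - 1L, max(genes$end) + GENE_GAP)
    gaps <- data.frame(start = gap_start, end = gap_end)
    gaps <- gaps[gaps$end - gaps$start > 50, ]
    pos_inter <- pick_in_intervals(n_inter, gaps)
  }

  pos <- c(pos_alu, pos_rna, pos_nonrep, pos_inter)
  context <- rep(c("Alu", "repNonAlu", "nonrepetitive", "nonrepetitive"),
                 c(n_alu, n_rna, n_nonrep, n_inter))
  # de-duplicate positions (keep first occurrence, redraw none: duplicates
  # are simply dropped and topped up from the largest class)
  keep <- !duplicated(pos)
  pos <- pos[keep]; context <- context[keep]
  ns <- length(pos)

  o <- order(pos)
  pos <- pos[o]; context <- context[o]

  # host gene(s): a site may fall inside 0, 1 or 2 gene footprints
  hit_count <- integer(ns); host <- integer(ns)
  for (i in seq_len(ns)) {
    ing <- which(pos[i] >= genes$start & pos[i] <= genes$end)
    hit_count[i] <- length(ing)
    host[i] <- if (length(ing)) ing[1] else NA_integer_
  }
  in_overlap <- hit_count >= 2L
  strand_site <- ifelse(is.na(host), NA_character_, strands[host])

  is_genic <- !is.na(host)
  site_kind <- rep("edit", ns)
  n_snp <- round(config$snp_fraction * ns)
  snp_idx <- sample(which(is_genic), min(n_snp, sum(is_genic)))
  site_kind[snp_idx] <- "snp"
  eligible_decoy <- which(is_genic & site_kind == "edit" & !in_overlap)
  n_decoy <- round(config$decoy_fraction * ns)
  decoy_idx <- sample(eligible_decoy, min(n_decoy, length(eligible_decoy)))
  site_kind[decoy_idx] <- "decoy"

  # variant class: cognate with the host gene strand except for decoys;
  # intergenic sites get an arbitrary class
  eff_strand <- ifelse(is.na(strand_site),
                       ifelse(runif(ns) < 0.5, "+", "-"), strand_site)
  cognate_ref <- ifelse(eff_strand == "+", "A", "T")
  cognate_alt <- ifelse(eff_strand == "+", "G", "C")
  ref <- cognate_ref; alt <- cognate_alt
  flip <- site_kind == "decoy"
  ref[flip] <- ifelse(cognate_ref[flip] == "A", "T", "A")
  alt[flip] <- ifelse(cognate_alt[flip] == "G", "C", "G")

  in_catalog <- rep(FALSE, ns)
  true_edit <- site_kind == "edit"
  cat_pool <- which(true_edit)
  in_catalog[sample(cat_pool,
                    round(config$catalog_fraction * length(cat_pool)))] <- TRUE

  # per-site editing structure
  bm <- config$bimodal_mix
  k <- config$site_weight_concentration
  w_site <- rbeta(ns, bm[[3]] * k + 1e-3, (1 - bm[[3]]) * k + 1e-3)
  affected <- rep(FALSE, ns)
  aff_pool <- which(true_edit)
  affected[sample(aff_pool,
                  round(config$celltype_effect$fraction *
                        length(aff_pool)))] <- TRUE
  geno <- rep(NA_character_, ns)
  geno[site_kind == "snp"] <- ifelse(runif(sum(site_kind == "snp")) < 0.7,
                                     "het", "hom")

  l <- qlogis(min(max(bm[[1]], 1e-4), 1 - 1e-4))
  h <- qlogis(min(max(bm[[2]], 1e-4), 1 - 1e-4))
  d <- config$celltype_effect$shift
  p_base <- (1 - w_site) * plogis(l) + w_site * plogis(h)
  p_shift <- (1 - w_site) * plogis(l + d) + w_site * plogis(h + d)

  sites <- data.frame(
    site_id = sprintf("site%05d", seq_len(ns)),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    strand = eff_strand, context = context,
    gene_id = ifelse(is.na(host), NA_character_, gene_ids[host]),
    in_overlap = in_overlap, site_kind = site_kind,
    in_catalog = in_catalog, is_snp = site_kind == "snp",
    genotype = geno, high_mode_weight = w_site,
    celltype_affected = affected,
    p_base = ifelse(true_edit, p_base, 0),
    p_shifted = ifelse(true_edit,
                       ifelse(affected, p_shift, p_base), 0),
    stringsAsFactors = FALSE)
  # decoys behave like editing sites at the read level (mismapping mimics
  # an edited signal) so that only annotation logic can remove them
  sites$p_base[site_kind == "decoy"] <- p_base[site_kind == "decoy"]
  sites$p_shifted[site_kind == "decoy"] <- p_base[site_kind == "decoy"]

  catalog <- sites[sites$in_catalog,
                   c("chrom", "pos", "strand", "context")]
  rownames(catalog) <- NULL
  snps <- sites[sites$is_snp, c("chrom", "pos", "ref", "alt")]
  rownames(snps) <- NULL

  list(genes = gene_tab, repeats = reps, sites = sites,
       catalog = catalog, snps = snps)
}

#' Simulate per-cell metadata
#'
#' Assigns each nucleus a gross phenotype (multinomial with the configured
#' proportions), a subgroup within phenotype (eight subgroups each, after
#' the usual cortical taxonomies), a cortical region, a library size, a
#' mitochondrial read fraction and a library complexity (detected genes).
#' `ceiling(mito_fail_fraction * n)` cells are planted with mitochondrial
#' fraction above 0.15 and `ceiling(complexity_fail_fraction * n)` with
#' complexity below 1000, to exercise cell QC.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with one row per cell: `cell_id`, `phenotype`,
#'   `subgroup`, `region`, `library_size`, `mito_frac`, `complexity`,
#'   `cell_effect` (log-odds random effect), `true_qc_fail` reason.
#' @export
simulate_cells <- function(config) {
  validate_sim_config(config)
  if (config$n_cells < 1L) stop("n_cells must be >= 1")
  set.seed(sub_seed(config$seed, "cells"))
  n <- config$n_cells
  ph_levels <- names(config$phenotype_proportions)
  phenotype <- sample(ph_levels, n, replace = TRUE,
                      prob = config$phenotype_proportions)
  subgroup <- paste0(phenotype, sample.int(8L, n, replace = TRUE))
  region <- sample(config$region_labels, n, replace = TRUE)
  library_size <- round(rlnorm(n, meanlog = log(3e6), sdlog = 0.3))
  mito <- rbeta(n, 2, 40)
  mito <- pmin(mito, 0.149)
  complexity <- pmax(1200L, as.integer(round(rnorm(n, 4000, 600))))

  n_mito_fail <- ceiling(config$mito_fail_fraction * n)
  n_cx_fail <- ceiling(config$complexity_fail_fraction * n)
  fail_pool <- sample.int(n, min(n, n_mito_fail + n_cx_fail))
  mito_fail <- fail_pool[seq_len(min(n_mito_fail, length(fail_pool)))]
  cx_fail <- setdiff(fail_pool, mito_fail)
  mito[mito_fail] <- runif(length(mito_fail), 0.151, 0.5)
  complexity[cx_fail] <- as.integer(runif(length(cx_fail), 200, 950))

  reason <- rep("none", n)
  reason[cx_fail] <- "complexity"
  reason[mito_fail] <- "mito"

  data.frame(cell_id = sprintf("cell%04d", seq_len(n)),
             phenotype = phenotype, subgroup = subgroup, region = region,
             library_size = library_size, mito_frac = mito,
             complexity = complexity,
             cell_effect = rnorm(n, 0, config$cell_sd),
             true_qc_fail = reason, stringsAsFactors = FALSE)
}

#' Simulate the full synthetic truth (annotation + cells + cell truth)
#'
#' Convenience wrapper that generates the annotation and the cell table
#' and computes each cell's true mean editing level (the expectation of
#' its per-site editing probabilities over all true editing sites, given
#' the cell's random effect and phenotype shift).
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_truth`: `config`, `annotation` (see
#'   [simulate_annotation()]), `cells`, and `gene_table` (filled in by
#'   [simulate_expression()]).
#' @export
simulate_truth <- function(config) {
  ann <- simulate_annotation(config)
  cells <- simulate_cells(config)
  st <- ann$sites
  bm <- config$bimodal_mix
  l <- qlogis(min(max(bm[[1]], 1e-4), 1 - 1e-4))
  h <- qlogis(min(max(bm[[2]], 1e-4), 1 - 1e-4))
  tgt <- config$celltype_effect$phenotype
  dshift <- config$celltype_effect$shift
  edit <- st$site_kind == "edit"
  w <- st$high_mode_weight[edit]
  aff <- st$celltype_affected[edit]
  n_edit <- sum(edit)
  W0 <- sum(w[!aff]); n0 <- sum(!aff)
  W1 <- sum(w[aff]); n1 <- sum(aff)
  e_cell <- vapply(seq_len(nrow(cells)), function(i) {
    u <- cells$cell_effect[i]
    dd <- if (cells$phenotype[i] == tgt) dshift else 0
    v0 <- (n0 - W0) * plogis(l + u) + W0 * plogis(h + u)
    v1 <- (n1 - W1) * plogis(l + u + dd) + W1 * plogis(h + u + dd)
    (v0 + v1) / n_edit
  }, numeric(1))
  cells$true_mean_editing <- e_cell
  out <- list(config = config, annotation = ann, cells = cells,
              gene_table = NULL)
  class(out) <- "sim_truth"
  out
}

#' Simulate allele counts at candidate sites
#'
#' For every site/cell pair the site is transcribed with probability
#' `expressed_fraction`; transcribed pairs receive a negative-binomial
#' read depth (truncated at 1). At true editing sites the edited-allele
#' count is binomial with a per-cell probability drawn from the
#' two-component beta mixture (low/high modes), shifted on the log-odds
#' scale by the cell random effect and, at affected sites in the target
#' phenotype, by the cell-type effect. SNP sites emit the allele dosage
#' (~0.5 heterozygous, ~1 homozygous) in every cell regardless of editing
#' truth; decoy sites emit editing-like signal under a non-cognate variant
#' class.
#'
#' @param truth a `sim_truth` object from [simulate_truth()].
#' @param config optional override of `truth$config`.
#' @return an [editing_matrix()] whose rows are the truth sites and
#'   columns the truth cells.
#' @export
simulate_allele_counts <- function(truth, config = truth$config) {
  set.seed(sub_seed(config$seed, "counts"))
  st <- truth$annotation$sites
  cells <- truth$cells
  ns <- nrow(st); nc <- nrow(cells)
  bm <- config$bimodal_mix
  l <- qlogis(min(max(bm[[1]], 1e-4), 1 - 1e-4))
  h <- qlogis(min(max(bm[[2]], 1e-4), 1 - 1e-4))
  conc <- config$mix_concentration
  mu <- config$coverage_nb[[1]]; size <- config$coverage_nb[[2]]
  tgt <- config$celltype_effect$phenotype
  dshift <- config$celltype_effect$shift
  u_cell <- cells$cell_effect
  is_tgt <- cells$phenotype == tgt

  ii <- vector("list", ns); jj <- vector("list", ns)
  dd <- vector("list", ns); aa <- vector("list", ns)
  for (s in seq_len(ns)) {
    covered <- which(runif(nc) < config$expressed_fraction)
    m <- length(covered)
    if (!m) next
    depth <- pmax(1L, rnbinom(m, mu = mu, size = size))
    kind <- st$site_kind[s]
    if (kind == "snp") {
      p <- if (st$genotype[s] == "het") 0.5 else 0.999
      altc <- rbinom(m, depth, p)
    } else {
      hi <- rbinom(m, 1L, st$high_mode_weight[s]) == 1L
      mode_mean <- ifelse(hi, plogis(h), plogis(l))
      p0 <- rbeta(m, mode_mean * conc, (1 - mode_mean) * conc)
      p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
      shift <- u_cell[covered] +
        ifelse(st$celltype_affected[s] & is_tgt[covered], dshift, 0)
      altc <- rbinom(m, depth, plogis(qlogis(p0) + shift))
    }
    ii[[s]] <- rep.int(s, m); jj[[s]] <- covered
    dd[[s]] <- depth; aa[[s]] <- altc
  }
  i <- unlist(ii); j <- unlist(jj)
  depth <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(unlist(dd)),
                                dims = c(ns, nc))
  altm <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(unlist(aa)),
                               dims = c(ns, nc))
  editing_matrix(alt = altm, depth = depth, sites = st, cells = cells)
}

# Solve for the loading k such that regressing editing level on simulated
# log10 abundance a = mu + k (e - mean(e)) + s * eps recovers slope beta:
# beta = k v / (k^2 v + s^2), v = var(e). Smaller root preferred (less
# extreme abundance spread); if beta exceeds the attainable maximum
# sqrt(v)/(2 s), the maximising k is used with a warning.
solve_assoc_loading <- function(beta, v, s) {
  if (beta == 0) return(0)
  disc <- v^2 - 4 * beta^2 * v * s^2
  if (disc < 0) {
    warning("planted association beta ", beta,
            " exceeds attainable slope; using maximum")
    return(sign(beta) * s / sqrt(v))
  }
  b <- abs(beta)
  k <- (v - sqrt(disc)) / (2 * b * v)
  sign(beta) * k
}

#' Simulate gene-by-cell expression with planted editing associations
#'
#' Generates per-cell log10 abundances for `n_genes` genes. Genes listed
#' in `config$assoc_genes` have abundance constructed so that a linear
#' regression of the cell's true mean editing level on log10 TPM recovers
#' the planted slope (`beta`); all other genes are independent of editing.
#' Abundances are converted to transcripts per million (columns sum to
#' 1e6) and to negative-binomial counts.
#'
#' @param truth a `sim_truth` object.
#' @param config optional override of `truth$config`.
#' @return list with `tpm` and `counts` (genes x cells matrices, dimnames
#'   gene/cell ids) and `gene_table` (per-gene planted beta, baseline
#'   mean, expression probability).
#' @export
simulate_expression <- function(truth, config = truth$config) {
  set.seed(sub_seed(config$seed, "expression"))
  cells <- truth$cells
  nc <- nrow(cells); ng <- config$n_genes
  e <- cells$true_mean_editing
  v <- var(e)
  gene_ids <- sprintf("gene%03d", seq_len(ng))

  beta_plant <- rep(0, ng)
  if (!is.null(config$assoc_genes) && nrow(config$assoc_genes))
    beta_plant[config$assoc_genes$gene] <- config$assoc_genes$beta
  mu_g <- rnorm(ng, 1, 1)
  pi_g <- runif(ng, 0.3, 0.95)
  pi_g[beta_plant != 0] <- 0.95
  s <- config$assoc_noise_sd

  a <- matrix(0, ng, nc, dimnames = list(gene_ids, cells$cell_id))
  for (g in seq_len(ng)) {
    k <- solve_assoc_loading(beta_plant[g], v, s)
    a[g, ] <- mu_g[g] + k * (e - mean(e)) + rnorm(nc, 0, s)
  }
  expressed <- matrix(runif(ng * nc) < pi_g, ng, nc)
  raw <- ifelse(expressed, 10^a, 0)
  dimnames(raw) <- dimnames(a)
  # TPM normalization adds a per-cell shift -log10(column sum) to every
  # gene's log10 abundance; pre-compensate the association genes so the
  # planted slope holds for the predictor the models actually use
  # (log10 TPM), not just the raw abundance
  assoc_idx <- which(beta_plant != 0)
  if (length(assoc_idx)) {
    cs_other <- colSums(raw[-assoc_idx, , drop = FALSE])
    cs_other[cs_other == 0] <- 1
    delta <- log10(cs_other)
    for (g in assoc_idx) {
      a[g, ] <- a[g, ] + delta - mean(delta)
      raw[g, ] <- ifelse(expressed[g, ], 10^a[g, ], 0)
    }
  }
  cs <- colSums(raw)
  cs[cs == 0] <- 1
  tpm <- sweep(raw, 2, cs, "/") * 1e6
  counts <- matrix(rnbinom(ng * nc, mu = raw * 2, size = 10), ng, nc,
                   dimnames = dimnames(a))
  gene_table <- data.frame(gene_id = gene_ids, planted_beta = beta_plant,
                           baseline_log10 = mu_g, expr_prob = pi_g,
                           stringsAsFactors = FALSE)
  list(tpm = tpm, counts = counts, gene_table = gene_table)
}

#' Run the full synthetic-data generator
#'
#' @param config a [sim_config()] object.
#' @return list of class `sim_dataset` with `truth`, `matrix` (an
#'   [editing_matrix()]), and `expression` (see [simulate_expression()]).
#' @export
simulate_dataset <- function(config = sim_config()) {
  truth <- simulate_truth(config)
  em <- simulate_allele_counts(truth)
  expr <- simulate_expression(truth)
  truth$gene_table <- expr$gene_table
  out <- list(truth = truth, matrix = em, expression = expr)
  class(out) <- "sim_dataset"
  out
}
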