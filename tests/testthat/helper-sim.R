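# Shared fixture builders and independent oracles for the test suite.
# Everything here is deliberately naive (dense loops, direct likelihoods)
# so it can serve as an independent check on the package's vectorised
# implementations.

# small simulated data set used by several module tests
small_sim <- function(seed = 42, n_cells = 120, n_sites = 400,
                      n_genes = 30) {
  simulate_dataset(sim_config(n_cells = n_cells, n_sites = n_sites,
                              n_genes = n_genes, seed = seed))
}

# hand-built editing matrix from dense matrices
em_from_dense <- function(alt, depth, sites = NULL, cells = NULL) {
  ns <- nrow(alt); nc <- ncol(alt)
  if (is.null(sites))
    sites <- data.frame(chrom = "chr1", pos = seq_len(ns) * 10L,
                        ref = "A", alt = "G")
  if (is.null(cells))
    cells <- data.frame(cell_id = sprintf("c%02d", seq_len(nc)))
  editing_matrix(alt = Matrix::Matrix(alt, sparse = TRUE),
                 depth = Matrix::Matrix(depth, sparse = TRUE),
                 sites = sites, cells = cells)
}

# brute-force candidate scan: per-site loop over cells
brute_candidates <- function(alt, depth, ref, altb, min_depth, min_alt,
                             min_cells) {
  keep <- logical(nrow(alt))
  for (s in seq_len(nrow(alt))) {
    n <- 0L
    for (c in seq_len(ncol(alt)))
      if (depth[s, c] >= min_depth && alt[s, c] >= min_alt) n <- n + 1L
    cls_ok <- (ref[s] == "A" && altb[s] == "G") ||
      (ref[s] == "T" && altb[s] == "C")
    keep[s] <- n >= min_cells && cls_ok
  }
  keep
}

# brute-force per-cell editing index: explicit loop over cells
brute_gei <- function(alt, depth) {
  nc <- ncol(alt)
  out <- rep(NA_real_, nc)
  for (c in seq_len(nc)) {
    tr <- which(depth[, c] > 0)
    if (length(tr)) out[c] <- mean(alt[tr, c] / depth[tr, c])
  }
  out
}

# brute-force full filter cascade on a simulated data set, working only
# from the truth tables and dense matrices (no GenomicRanges, no package
# filter functions)
brute_filter <- function(sim, min_depth = 5, min_alt = 2,
                         min_cells = 10, mito_max = 0.15,
                         min_complexity = 1000) {
  st <- sim$truth$annotation$sites
  genes <- sim$truth$annotation$genes
  genes <- genes[genes$type == "gene", ]
  cat_key <- paste(sim$truth$annotation$catalog$chrom,
                   sim$truth$annotation$catalog$pos)
  snp_key <- paste(sim$truth$annotation$snps$chrom,
                   sim$truth$annotation$snps$pos,
                   sim$truth$annotation$snps$ref,
                   sim$truth$annotation$snps$alt)
  cells <- sim$truth$cells
  pass <- !(cells$mito_frac > mito_max |
              cells$complexity < min_complexity)
  alt <- as.matrix(sim$matrix$alt[, pass, drop = FALSE])
  depth <- as.matrix(sim$matrix$depth[, pass, drop = FALSE])

  keep <- logical(nrow(st))
  for (s in seq_len(nrow(st))) {
    nq <- sum(depth[s, ] >= min_depth & alt[s, ] >= min_alt)
    if (nq < min_cells) next
    cls <- paste0(st$ref[s], ">", st$alt[s])
    if (!cls %in% c("A>G", "T>C")) next
    if (paste(st$chrom[s], st$pos[s], st$ref[s], st$alt[s]) %in%
          snp_key) next
    hits <- which(st$pos[s] >= genes$start & st$pos[s] <= genes$end)
    in_cat <- paste(st$chrom[s], st$pos[s]) %in% cat_key
    cognate <- length(hits) == 1 &&
      ((cls == "A>G" && genes$strand[hits] == "+") ||
         (cls == "T>C" && genes$strand[hits] == "-"))
    keep[s] <- in_cat || cognate
  }
  keep
}

# direct pseudobulk count simulator: S exchangeable pseudoreplicates in
# two phenotype groups (optionally crossed with regions), beta-binomial
# edited counts given negative-binomial totals
sim_pb_counts <- function(seed, n_sites, S = 8, mu_tot = 200,
                          rho = 0.05, shift = 0, regions = TRUE,
                          gene_id = NULL) {
  set.seed(seed)
  samples <- data.frame(sample = paste0("s", seq_len(S)),
                        phenotype = rep(c("Ex", "In"), each = S / 2))
  if (regions)
    samples$region <- rep(paste0("BA", seq_len(S / 2)), 2)
  tot <- matrix(pmax(1, stats::rnbinom(n_sites * S, mu = mu_tot,
                                       size = 5)), n_sites, S)
  p_site <- stats::plogis(stats::rnorm(n_sites, stats::qlogis(0.3),
                                       0.8))
  ed <- matrix(0L, n_sites, S)
  is_in <- samples$phenotype == "In"
  for (s in seq_len(n_sites)) {
    lp <- stats::qlogis(p_site[s]) + ifelse(is_in, shift, 0)
    pj <- if (rho > 0) {
      a <- (1 - rho) / rho
      stats::rbeta(S, stats::plogis(lp) * a,
                   (1 - stats::plogis(lp)) * a)
    } else stats::plogis(lp)
    ed[s, ] <- stats::rbinom(S, tot[s, ], pj)
  }
  sites <- data.frame(chrom = "chr1", pos = seq_len(n_sites))
  if (!is.null(gene_id)) sites$gene_id <- gene_id
  structure(list(edited = ed, unedited = tot - ed, samples = samples,
                 sites = sites), class = "pseudobulk")
}

# cell-level simulator for the gene-level power study: sites at
# intermediate editing levels (the dynamic range where a cell-type
# log-odds shift can manifest), per-cell depth ~ NB(20, 2), aggregated
# into 8 single-subgroup pseudoreplicates
sim_cells_gene_pb <- function(seed, shift = 0.5, cells_per_group = 40,
                              cover = 0.5, n_bg_genes = 40,
                              sites_per_bg = 5, planted_sites = 10) {
  set.seed(seed)
  S <- 8
  groups <- data.frame(subgroup = c(paste0("Ex", 1:4),
                                    paste0("In", 1:4)),
                       phenotype = rep(c("Ex", "In"), each = 4))
  nc <- S * cells_per_group
  cell_grp <- rep(seq_len(S), each = cells_per_group)
  is_in <- groups$phenotype[cell_grp] == "In"
  genes <- c(rep("planted", planted_sites),
             rep(paste0("g", seq_len(n_bg_genes)), each = sites_per_bg))
  ns <- length(genes)
  u <- stats::rnorm(nc, 0, 0.4)
  m_site <- stats::runif(ns, 0.2, 0.5)
  ii <- jj <- dd <- aa <- vector("list", ns)
  for (s in seq_len(ns)) {
    cov_cells <- which(stats::runif(nc) < cover)
    m <- length(cov_cells)
    depth <- pmax(1L, stats::rnbinom(m, mu = 20, size = 2))
    p0 <- pmin(pmax(stats::rbeta(m, m_site[s] * 30,
                                 (1 - m_site[s]) * 30), 1e-4), 1 - 1e-4)
    lp <- stats::qlogis(p0) + u[cov_cells] +
      ifelse(genes[s] == "planted" & is_in[cov_cells], shift, 0)
    ii[[s]] <- rep(s, m); jj[[s]] <- cov_cells; dd[[s]] <- depth
    aa[[s]] <- stats::rbinom(m, depth, stats::plogis(lp))
  }
  em <- editing_matrix(
    alt = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = as.numeric(unlist(aa)),
                               dims = c(ns, nc)),
    depth = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                 x = as.numeric(unlist(dd)),
                                 dims = c(ns, nc)),
    sites = data.frame(chrom = "chr1", pos = seq_len(ns), ref = "A",
                       alt = "G", gene_id = genes),
    cells = data.frame(cell_id = sprintf("c%03d", seq_len(nc)),
                       subgroup = groups$subgroup[cell_grp],
                       phenotype = groups$phenotype[cell_grp]))
  suppressWarnings(build_pseudobulk(em, group_by = "subgroup"))
}

# exact beta-binomial likelihood-ratio oracle for two-group differential
# editing on one site (common intra-class correlation, ML by Nelder-Mead)
bb_lrt_p <- function(ed, tot, grp) {
  nll <- function(par, grp_idx) {
    rho <- stats::plogis(par[length(par)])
    a <- (1 - rho) / rho
    p <- stats::plogis(par[-length(par)][grp_idx])
    -sum(lchoose(tot, ed) + lbeta(ed + p * a, tot - ed + (1 - p) * a) -
           lbeta(p * a, (1 - p) * a))
  }
  g2 <- as.integer(factor(grp))
  p0 <- stats::qlogis(pmin(pmax(sum(ed) / sum(tot), 0.01), 0.99))
  f0 <- stats::optim(c(p0, 0), nll, grp_idx = rep(1L, length(ed)),
                     method = "Nelder-Mead")
  f1 <- stats::optim(c(p0, p0, 0), nll, grp_idx = g2,
                     method = "Nelder-Mead")
  stat <- 2 * (f0$value - f1$value)
  stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE)
}

# sample skewness
skewness <- function(x) {
  x <- x[!is.na(x)]
  mean((x - mean(x))^3) / stats::sd(x)^3
}

# count well-separated modes of a kernel density estimate
count_modes <- function(x, bw = 0.05, min_height = 0.1) {
  d <- stats::density(x, bw = bw, from = -0.05, to = 1.05, n = 512)
  y <- d$y / max(d$y)
  peaks <- which(diff(sign(diff(y))) == -2) + 1L
  sum(y[peaks] >= min_height)
}
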