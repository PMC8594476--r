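#' Model per-cell editing index as a function of gene abundance
#'
#' For each gene, fits an ordinary linear model of the per-cell editing
#' index on log10 transcripts-per-million, controlling for gross
#' phenotype and log10 library size, over the cells expressing the gene
#' (TPM > 0). P-values are two-sided t-tests on the abundance
#' coefficient, corrected by Benjamini-Hochberg across all fitted genes.
#' A gene is declared significant when FDR < `fdr` and |beta| >
#' `beta_min` (tiny effects are excluded as biologically negligible).
#'
#' @param summaries per-cell index table from [per_cell_indices()].
#' @param tpm genes x cells TPM matrix (dimnames required).
#' @param cells cell metadata with `cell_id`, `phenotype`,
#'   `library_size`.
#' @param min_cells_expr minimum expressing cells to fit a gene
#'   (default 300, i.e. the background-expression rule).
#' @param fdr FDR threshold for significance (default 0.05).
#' @param beta_min minimum absolute effect size (default 0.01, in index
#'   units per unit log10 TPM).
#' @return data.frame per fitted gene: `gene_id`, `beta`, `se`, `p`,
#'   `fdr`, `n_cells_expr`, `significant`; skipped genes (too few
#'   expressing cells or no abundance variance) are listed in the
#'   `skipped` attribute.
#' @export
fit_gene_associations <- function(summaries, tpm, cells,
                                  min_cells_expr = 300, fdr = 0.05,
                                  beta_min = 0.01) {
  d <- merge(summaries, cells, by = "cell_id")
  d <- d[!is.na(d$index), ]
  ci <- match(d$cell_id, colnames(tpm))
  if (anyNA(ci))
    stop("TPM matrix lacks columns for some cells")
  skipped <- character(0)
  rows <- vector("list", nrow(tpm))
  ph <- factor(d$phenotype)
  log_lib <- log10(d$library_size)
  for (g in seq_len(nrow(tpm))) {
    x_all <- tpm[g, ci]
    expr <- x_all > 0
    n_expr <- sum(expr)
    gid <- rownames(tpm)[g]
    if (n_expr < min_cells_expr) {
      skipped <- c(skipped, gid); next
    }
    x <- log10(x_all[expr])
    if (stats::sd(x) == 0) { skipped <- c(skipped, gid); next }
    dat <- data.frame(y = d$index[expr], x = x,
                      ph = droplevels(ph[expr]),
                      log_lib = log_lib[expr])
    form <- if (nlevels(dat$ph) > 1) y ~ x + ph + log_lib else
      y ~ x + log_lib
    fit <- stats::lm(form, data = dat)
    cf <- summary(fit)$coefficients
    rows[[g]] <- data.frame(gene_id = gid, beta = cf["x", 1],
                            se = cf["x", 2], p = cf["x", 4],
                            n_cells_expr = n_expr,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), beta = numeric(),
                      se = numeric(), p = numeric(),
                      n_cells_expr = integer())
  out$fdr <- stats::p.adjust(out$p, "BH")
  out$significant <- out$fdr < fdr & abs(out$beta) > beta_min
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "thresholds") <- c(fdr = fdr, beta_min = beta_min)
  out
}

#' Downsampling robustness check for abundance-editing associations
#'
#' Significant associations tend to come from widely expressed genes; to
#' verify they are not artifacts of sheer cell number, genes expressed
#' in more than `cap` cells are refitted on a seeded random subsample of
#' `cap` expressing cells, and sign concordance / retained significance
#' are reported.
#'
#' @param assoc result of [fit_gene_associations()].
#' @param summaries,tpm,cells as in [fit_gene_associations()].
#' @param cap maximum cells per gene (default 1500).
#' @param seed integer seed for the subsampling.
#' @param genes genes to check (default: significant genes).
#' @param fdr,beta_min thresholds applied to the refit (defaults taken
#'   from `assoc`).
#' @return data.frame: `gene_id`, `downsampled`, `beta_full`,
#'   `beta_capped`, `p_capped`, `sign_concordant`, `still_significant`.
#' @export
downsample_check <- function(assoc, summaries, tpm, cells, cap = 1500,
                             seed = 1, genes = NULL, fdr = NULL,
                             beta_min = NULL) {
  th <- attr(assoc, "thresholds")
  if (is.null(fdr)) fdr <- unname(th["fdr"])
  if (is.null(beta_min)) beta_min <- unname(th["beta_min"])
  if (is.null(genes)) genes <- assoc$gene_id[assoc$significant]
  d <- merge(summaries, cells, by = "cell_id")
  d <- d[!is.na(d$index), ]
  ci <- match(d$cell_id, colnames(tpm))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rows <- lapply(genes, function(gid) {
    a <- assoc[assoc$gene_id == gid, ]
    x_all <- tpm[gid, ci]
    expr_idx <- which(x_all > 0)
    down <- length(expr_idx) > cap
    use <- if (down) sort(sample(expr_idx, cap)) else expr_idx
    dat <- data.frame(y = d$index[use], x = log10(x_all[use]),
                      ph = factor(d$phenotype[use]),
                      log_lib = log10(d$library_size[use]))
    form <- if (nlevels(dat$ph) > 1) y ~ x + ph + log_lib else
      y ~ x + log_lib
    cf <- summary(stats::lm(form, data = dat))$coefficients
    data.frame(gene_id = gid, downsampled = down,
               beta_full = a$beta, beta_capped = cf["x", 1],
               p_capped = cf["x", 4],
               sign_concordant = sign(cf["x", 1]) == sign(a$beta),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_id = character(), downsampled = logical(),
                      beta_full = numeric(), beta_capped = numeric(),
                      p_capped = numeric(), sign_concordant = logical(),
                      still_significant = logical()))
  # re-assess significance of the capped fits within the checked family
  out$fdr_capped <- stats::p.adjust(out$p_capped, "BH")
  out$still_significant <- out$fdr_capped < fdr &
    abs(out$beta_capped) > beta_min
  rownames(out) <- NULL
  out
}

#' Correlate abundance-editing association profiles across data sets
#'
#' Computes the Pearson correlation of per-gene association betas over
#' genes shared by two result tables. When a labelled gene subset is
#' supplied (e.g. genes with known positive/negative editing
#' associations from an external study), the correlation is also
#' computed within the subset and a two-sample Mann-Whitney test checks
#' that the two labels separate on the betas of each data set.
#'
#' @param res_a,res_b results of [fit_gene_associations()] on two data
#'   sets.
#' @param subset optional data.frame with `gene_id` and `label` (two
#'   levels, e.g. "positive"/"negative").
#' @return list: `n_shared`, `r`, `p`, and when `subset` is given
#'   `r_subset`, `p_subset`, `separation_p_a`, `separation_p_b`.
#' @export
cross_dataset_beta_correlation <- function(res_a, res_b,
                                           subset = NULL) {
  m <- merge(res_a[c("gene_id", "beta")], res_b[c("gene_id", "beta")],
             by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(m) < 3)
    stop("need at least 3 shared genes; got ", nrow(m))
  ct <- stats::cor.test(m$beta_a, m$beta_b)
  out <- list(n_shared = nrow(m), r = unname(ct$estimate),
              p = ct$p.value)
  if (!is.null(subset)) {
    ms <- merge(m, subset, by = "gene_id")
    if (nrow(ms) >= 3) {
      cts <- stats::cor.test(ms$beta_a, ms$beta_b)
      out$r_subset <- unname(cts$estimate)
      out$p_subset <- cts$p.value
      labs <- unique(ms$label)
      if (length(labs) == 2 && all(table(ms$label) >= 1)) {
        out$separation_p_a <- stats::wilcox.test(
          beta_a ~ label, data = ms, exact = FALSE)$p.value
        out$separation_p_b <- stats::wilcox.test(
          beta_b ~ label, data = ms, exact = FALSE)$p.value
      }
    }
  }
  out
}
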