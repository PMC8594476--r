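#' Aggregate single-cell editing counts into pseudobulk replicates
#'
#' Sums edited (alt) and unedited (depth - alt) allele counts per site
#' within each cell group (by default subgroup x region), forming
#' bulk-like pseudoreplicates for count-based testing. Sites whose
#' count variance across pseudoreplicates does not exceed `var_min`
#' carry no usable signal and are removed.
#'
#' @param em an [editing_matrix()] of filtered candidate sites.
#' @param cells optional cell metadata (defaults to `em$cells`); only
#'   `qc_pass` cells are used when that column exists.
#' @param group_by character vector of cell columns defining
#'   pseudoreplicates (default `c("subgroup", "region")`).
#' @param var_min variance threshold (strict >; default 0.2).
#' @param var_on `"counts"` applies the threshold to the edited-allele
#'   counts across pseudoreplicates; `"fraction"` to the editing
#'   fraction edited/(edited+unedited).
#' @return list of class `pseudobulk`: `edited` and `unedited`
#'   (site x sample matrices), `samples` (sample covariates incl.
#'   phenotype and the grouping columns, n_cells), `sites`, and a
#'   `removed` attribute with the variance-filtered site count.
#' @export
build_pseudobulk <- function(em, cells = NULL,
                             group_by = c("subgroup", "region"),
                             var_min = 0.2,
                             var_on = c("counts", "fraction")) {
  var_on <- match.arg(var_on)
  if (is.null(cells)) cells <- em$cells
  if (!is.null(cells$qc_pass)) {
    keep <- cells$qc_pass
    em <- em[, keep]; cells <- cells[keep, ]
  }
  miss <- setdiff(group_by, names(cells))
  if (length(miss))
    stop("cell table lacks grouping columns: ",
         paste(miss, collapse = ", "))
  grp <- interaction(cells[group_by], sep = ":", drop = FALSE)
  tab <- table(grp)
  if (any(tab == 0))
    warning(sum(tab == 0), " group(s) with 0 cells dropped")
  grp <- factor(as.character(grp), levels = names(tab)[tab > 0])
  # cells x groups indicator (built directly: works for 1 group too)
  G <- vapply(levels(grp), function(l) as.numeric(grp == l),
              numeric(length(grp)))
  if (is.null(dim(G))) G <- matrix(G, nrow = length(grp))
  edited <- as.matrix(em$alt %*% G)
  total <- as.matrix(em$depth %*% G)
  unedited <- total - edited
  colnames(edited) <- colnames(unedited) <- levels(grp)

  first <- match(levels(grp), as.character(interaction(cells[group_by],
                                                       sep = ":")))
  samples <- data.frame(sample = levels(grp),
                        cells[first, group_by, drop = FALSE],
                        n_cells = as.integer(tab[tab > 0]),
                        row.names = NULL, stringsAsFactors = FALSE)
  if (!"phenotype" %in% names(samples) && "phenotype" %in% names(cells))
    samples$phenotype <- cells$phenotype[first]

  if (ncol(edited) < 2) {
    # variance across pseudoreplicates is undefined for a single group
    keep_site <- rep(TRUE, nrow(edited))
  } else {
    v <- if (var_on == "counts") apply(edited, 1, stats::var) else {
      fr <- edited / pmax(edited + unedited, 1)
      apply(fr, 1, stats::var)
    }
    keep_site <- !is.na(v) & v > var_min
  }
  out <- list(edited = edited[keep_site, , drop = FALSE],
              unedited = unedited[keep_site, , drop = FALSE],
              samples = samples,
              sites = em$sites[keep_site, , drop = FALSE])
  attr(out, "removed") <- sum(!keep_site)
  class(out) <- "pseudobulk"
  out
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("pseudobulk:", nrow(x$edited), "sites x", nrow(x$samples),
      "samples (", attr(x, "removed"), "sites variance-filtered )\n")
  invisible(x)
}

# Design matrix for the paired-count editing model: one row per
# (sample, allele-status) observation. Sample blocking absorbs total
# coverage; 'status' is the editing indicator; status:adjust terms allow
# the editing odds to differ by the adjustment factor; status:contrast is
# the coefficient of interest (log odds-ratio of editing between contrast
# levels). This mirrors count-based differential-methylation designs.
paired_design <- function(samples, contrast, adjust) {
  S <- nrow(samples)
  d <- data.frame(sample = factor(rep(samples$sample, 2)),
                  status = rep(c(0, 1), each = S))
  f <- "~ sample + status"
  if (!is.null(adjust)) {
    d$adj <- factor(rep(samples[[adjust]], 2))
    if (nlevels(d$adj) > 1) f <- paste(f, "+ status:adj")
  }
  d$con <- factor(rep(samples[[contrast]], 2))
  if (nlevels(d$con) != 2L)
    stop("contrast must have exactly two levels; got ",
         nlevels(d$con))
  f <- paste(f, "+ status:con")
  X <- stats::model.matrix(stats::as.formula(f), d)
  list(X = X, coef = ncol(X),
       contrast_levels = levels(d$con))
}

# Pearson-matching estimate of the NB dispersion phi: the value at which
# the Pearson statistic sum (y-mu)^2 / (mu (1 + phi mu)) equals the
# residual degrees of freedom. Accounts for the fitted parameters (unlike
# the naive moment estimator, which is badly downward-biased when the
# design is large relative to the observation count). mu is held at the
# Poisson fit; X2 is monotone decreasing in phi so the root is unique.
pearson_dispersion <- function(y, mu, df) {
  mu <- pmax(mu, 1e-8)
  x2 <- function(phi) sum((y - mu)^2 / (mu * (1 + phi * mu)))
  if (df <= 0 || x2(0) <= df) return(0)
  upper <- 1
  while (x2(upper) > df && upper < 1e6) upper <- upper * 10
  stats::uniroot(function(phi) x2(phi) - df, c(0, upper),
                 tol = 1e-8)$root
}

#' Site-level differential editing on pseudobulk paired counts
#'
#' For each site, edited and unedited counts across pseudoreplicates are
#' modelled jointly with a negative-binomial generalized linear model:
#' sample blocking terms, an editing-status indicator, status-by-
#' adjustment interactions, and the status-by-contrast interaction whose
#' coefficient is the log odds-ratio of editing between the two contrast
#' levels. Each site's NB dispersion is estimated by matching the
#' Pearson statistic to the residual degrees of freedom and shrunk
#' towards the common (median) dispersion with `prior_df` prior degrees
#' of freedom; the shrunken dispersion is treated as known, and Wald
#' statistics for the interaction are referred to the standard normal,
#' giving two-sided p-values corrected by Benjamini-Hochberg.
#'
#' When all counts of one arm (edited or unedited within one contrast
#' level) are zero the site is refitted with 0.5 added to both arms and
#' flagged.
#'
#' @param pb a [build_pseudobulk()] object.
#' @param contrast sample column with exactly two levels (default
#'   `"phenotype"`).
#' @param adjust sample column to correct for (default `"region"`; NULL
#'   for none).
#' @param prior_df prior degrees of freedom for dispersion shrinkage
#'   (default 10).
#' @return data.frame (one row per site): `logFC` (log2 odds-ratio of
#'   editing, second contrast level vs first), `z`, `p`, `fdr`,
#'   `dispersion`, `flagged`.
#' @export
fit_site_models <- function(pb, contrast = "phenotype",
                            adjust = "region", prior_df = 10) {
  samples <- pb$samples
  if (!is.null(adjust) && !adjust %in% names(samples)) adjust <- NULL
  des <- paired_design(samples, contrast, adjust)
  X <- des$X
  ns <- nrow(pb$edited)
  if (ns == 0)
    return(data.frame(logFC = numeric(), z = numeric(), p = numeric(),
                      fdr = numeric(), dispersion = numeric(),
                      flagged = logical()))
  lev <- des$contrast_levels
  arm2 <- samples[[contrast]] == lev[2]
  n <- nrow(X); pcol <- ncol(X)
  df_res <- n - pcol

  ys <- lapply(seq_len(ns), function(s)
    c(pb$unedited[s, ], pb$edited[s, ]))
  flagged <- vapply(seq_len(ns), function(s) {
    all(pb$edited[s, !arm2] == 0) || all(pb$edited[s, arm2] == 0) ||
      all(pb$unedited[s, !arm2] == 0) || all(pb$unedited[s, arm2] == 0)
  }, logical(1))
  ys[flagged] <- lapply(ys[flagged], function(y) y + 0.5)

  pois <- stats::poisson()
  phi_site <- numeric(ns)
  fits <- vector("list", ns)
  for (s in seq_len(ns)) {
    f <- suppressWarnings(stats::glm.fit(X, ys[[s]], family = pois))
    fits[[s]] <- f
    phi_site[s] <- pearson_dispersion(ys[[s]], f$fitted.values, df_res)
  }
  phi_common <- stats::median(phi_site)
  phi <- (prior_df * phi_common + df_res * phi_site) /
    (prior_df + df_res)
  phi <- pmin(phi, 100)  # guard against degenerate blow-ups

  est <- se <- numeric(ns)
  for (s in seq_len(ns)) {
    theta <- if (phi[s] > 1e-8) 1 / phi[s] else 1e8
    fam <- MASS::negative.binomial(theta = theta, link = "log")
    st_coef <- fits[[s]]$coefficients
    if (anyNA(st_coef)) st_coef <- NULL
    f <- tryCatch(
      suppressWarnings(stats::glm.fit(X, ys[[s]], family = fam,
                                      start = st_coef)),
      error = function(e)
        suppressWarnings(stats::glm.fit(X, ys[[s]], family = fam)))
    R <- f$qr$qr[seq_len(pcol), , drop = FALSE]
    R[lower.tri(R)] <- 0
    V <- chol2inv(R)
    j <- which(f$qr$pivot == pcol)  # position of the contrast column
    est[s] <- f$coefficients[pcol]
    se[s] <- sqrt(V[j, j])
  }
  z <- est / se
  # with dispersion strongly moderated across sites it is treated as
  # known, so the Wald statistic is referred to the standard normal
  # (the usual convention for NB GLMs with shared dispersion)
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(logFC = est / log(2), z = z, p = p,
                    fdr = stats::p.adjust(p, "BH"),
                    dispersion = phi, flagged = flagged,
                    stringsAsFactors = FALSE)
  if (!is.null(pb$sites$site_id)) out <- cbind(site_id = pb$sites$site_id,
                                               out)
  if (!is.null(pb$sites$gene_id)) out$gene_id <- pb$sites$gene_id
  attr(out, "contrast_levels") <- lev
  attr(out, "phi_common") <- phi_common
  out
}

# Per-site effect/residual vectors for the rotation test. Each site's
# per-sample editing log-odds is modelled by a weighted linear model
# y ~ nuisance + contrast (contrast last). Returns e = Q'y restricted to
# the contrast + residual subspace (first element = adjusted contrast
# effect) so that random rotations of e generate the exact Gaussian null.
rotation_effects <- function(pb, contrast, adjust) {
  samples <- pb$samples
  if (!is.null(adjust) && !adjust %in% names(samples)) adjust <- NULL
  d <- data.frame(con = factor(samples[[contrast]]))
  f <- "~ con"
  if (!is.null(adjust)) {
    d$adj <- factor(samples[[adjust]])
    if (nlevels(d$adj) > 1) f <- "~ adj + con"
  }
  if (nlevels(d$con) != 2L)
    stop("contrast must have exactly two levels")
  Z <- stats::model.matrix(stats::as.formula(f), d)
  # put the contrast column last
  ccol <- grep("^con", colnames(Z))
  Z <- Z[, c(setdiff(seq_len(ncol(Z)), ccol), ccol), drop = FALSE]
  p <- ncol(Z); S <- nrow(Z)
  if (S - p < 1L)
    stop("not enough pseudoreplicates for the rotation test")
  y <- log((pb$edited + 0.5) / (pb$unedited + 0.5))
  w <- 1 / (1 / (pb$edited + 0.5) + 1 / (pb$unedited + 0.5))
  ns <- nrow(y)
  d_dim <- S - p + 1L
  E <- matrix(0, ns, d_dim)
  for (s in seq_len(ns)) {
    sw <- sqrt(w[s, ])
    qr_s <- qr(Z * sw)
    qty <- qr.qty(qr_s, y[s, ] * sw)
    e <- qty[p:S]
    # Householder QR leaves the sign of each effect coordinate
    # arbitrary; align the contrast coordinate with the sign of the
    # fitted coefficient so 'direction' is meaningful
    rpp <- qr.R(qr_s)[p, p]
    if (rpp < 0) e[1] <- -e[1]
    E[s, ] <- e
  }
  list(E = E, d = d_dim,
       contrast_levels = levels(d$con))
}

# Empirical-Bayes prior for residual variances: assume s2 ~ s0 * F(df1,
# d0) across sites and estimate (s0, d0) by matching the mean and
# variance of log s2 (the scaled-F moments involve di-/tri-gamma
# functions). Returns d0 = Inf when the observed spread is no larger
# than expected under a common variance.
fit_var_prior <- function(s2, df1) {
  s2 <- s2[s2 > 1e-12]
  if (length(s2) < 3) return(list(s0 = stats::median(s2), d0 = Inf))
  z <- log(s2)
  excess <- stats::var(z) - trigamma(df1 / 2)
  if (!is.finite(excess) || excess <= 0)
    return(list(s0 = exp(mean(z) - digamma(df1 / 2) + log(df1 / 2)),
                d0 = Inf))
  d0 <- 2 * stats::uniroot(function(x) trigamma(x) - excess,
                           c(1e-3, 1e6), extendInt = "downX")$root
  ls0 <- mean(z) - digamma(df1 / 2) + digamma(d0 / 2) -
    log(d0 / df1)
  list(s0 = exp(ls0), d0 = min(d0, 1e6))
}

rotation_t <- function(E, u, d, s0 = 0, d0 = 0) {
  # u: unit vector in R^d; per-site moderated t statistics for the
  # projected effect (residual variances squeezed towards the prior
  # s0 with d0 prior df), converted to standard-normal equivalents so
  # the gene-level mean is not dominated by heavy t tails
  proj <- as.vector(E %*% u)
  ss <- rowSums(E^2)
  df1 <- d - 1
  s2 <- (ss - proj^2) / df1
  if (is.finite(d0)) {
    s2post <- (d0 * s0 + df1 * s2) / (d0 + df1)
    dft <- df1 + d0
  } else {
    s2post <- rep(s0, length(s2))
    dft <- 1e6
  }
  tt <- proj / sqrt(pmax(s2post, 1e-12))
  z <- stats::qnorm(stats::pt(tt, df = dft))
  pmin(pmax(z, -8), 8)
}

#' Directional gene-level editing enrichment by rotation
#'
#' Tests, per gene, whether its editing sites shift consistently in one
#' direction between the contrast groups. The gene statistic is the mean
#' of per-site moderated t-statistics for the contrast effect (computed
#' from a weighted linear model of per-sample editing log-odds,
#' adjusting for the nuisance factor, with residual variances squeezed
#' towards an empirical-Bayes prior shared across all sites and the
#' resulting t statistics mapped to normal equivalents). The null
#' distribution is
#' generated by random rotation of each site's combined effect/residual
#' vector, applied identically to all sites of a gene so that
#' inter-site correlation is preserved. Two one-sided rotation p-values
#' are combined into a direction and a two-sided p, with
#' Benjamini-Hochberg correction across genes.
#'
#' @param pb a [build_pseudobulk()] object.
#' @param gene_map site-to-gene assignment: character vector along
#'   `pb$sites` rows, or NULL to use `pb$sites$gene_id`.
#' @param contrast,adjust as in [fit_site_models()].
#' @param min_sites minimum sites per tested gene (default 2).
#' @param n_perm number of rotations (default 10000; must be >= 100).
#' @param seed integer seed for the rotations.
#' @return data.frame per gene: `gene_id`, `n_sites`, `stat` (mean site
#'   t), `direction` (second contrast level if positive), `p`, `fdr`.
#' @export
gene_directional_test <- function(pb, gene_map = NULL,
                                  contrast = "phenotype",
                                  adjust = "region", min_sites = 2,
                                  n_perm = 10000, seed = 1) {
  if (n_perm < 100)
    stop("n_perm must be at least 100 for a stable rotation null")
  if (is.null(gene_map)) gene_map <- pb$sites$gene_id
  if (length(gene_map) != nrow(pb$edited))
    stop("gene_map must assign a gene to every site")
  ro <- rotation_effects(pb, contrast, adjust)
  E <- ro$E; d <- ro$d
  # variance prior shared across all sites (fixed over rotations)
  s2_obs <- (rowSums(E^2) - E[, 1]^2) / (d - 1)
  vp <- fit_var_prior(s2_obs, d - 1)
  t_obs <- rotation_t(E, c(1, rep(0, d - 1)), d, vp$s0, vp$d0)

  genes <- split(seq_along(gene_map), gene_map)
  genes <- genes[vapply(genes, length, integer(1)) >= min_sites &
                   !is.na(names(genes)) & names(genes) != "NA"]
  if (!length(genes))
    return(data.frame(gene_id = character(), n_sites = integer(),
                      stat = numeric(), direction = character(),
                      p = numeric(), fdr = numeric()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  res <- lapply(names(genes), function(g) {
    idx <- genes[[g]]
    Tg <- mean(t_obs[idx])
    Eg <- E[idx, , drop = FALSE]
    U <- matrix(stats::rnorm(n_perm * d), n_perm, d)
    U <- U / sqrt(rowSums(U^2))
    Tnull <- vapply(seq_len(n_perm), function(b)
      mean(rotation_t(Eg, U[b, ], d, vp$s0, vp$d0)), numeric(1))
    p_up <- (1 + sum(Tnull >= Tg)) / (n_perm + 1)
    p_dn <- (1 + sum(Tnull <= Tg)) / (n_perm + 1)
    data.frame(gene_id = g, n_sites = length(idx), stat = Tg,
               direction = if (Tg >= 0) ro$contrast_levels[2] else
                 ro$contrast_levels[1],
               p = min(1, 2 * min(p_up, p_dn)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, "BH")
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for disease-site overlap with gene sets
#'
#' Cross-tabulates sites in a universe by membership in a disease-site
#' list and membership in a set of differentially edited genes, and
#' applies Fisher's exact test. The reported odds ratio is the sample
#' odds ratio (ad/bc).
#'
#' @param universe data.frame of all candidate sites (chrom, pos) with a
#'   `gene_id` column, or a precomputed 2x2 matrix (rows: in/out disease
#'   list; cols: in/out gene set).
#' @param disease_sites data.frame (chrom, pos) of disease-associated
#'   sites; ignored when `universe` is a matrix.
#' @param de_genes character vector of differentially edited gene ids;
#'   ignored when `universe` is a matrix.
#' @return list: `table`, `odds_ratio`, `p`, `flagged` (TRUE when a
#'   margin is empty, in which case `p` is 1 and the OR undefined).
#' @export
disease_overlap_test <- function(universe, disease_sites = NULL,
                                 de_genes = NULL) {
  if (is.matrix(universe)) {
    tab <- universe
  } else {
    in_dis <- paste(universe$chrom, universe$pos) %in%
      paste(disease_sites$chrom, disease_sites$pos)
    in_set <- !is.na(universe$gene_id) & universe$gene_id %in% de_genes
    tab <- matrix(c(sum(in_dis & in_set), sum(!in_dis & in_set),
                    sum(in_dis & !in_set), sum(!in_dis & !in_set)),
                  2, 2,
                  dimnames = list(disease = c("yes", "no"),
                                  gene_set = c("yes", "no")))
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, odds_ratio = NA_real_, p = 1,
                flagged = TRUE))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, p = p, flagged = FALSE)
}
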