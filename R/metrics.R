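#' Per-cell editing indices (GEI / AEI / stringent AEI)
#'
#' The global editing index (GEI) of a cell is the unweighted mean of the
#' edited-allele fraction alt/depth over all candidate sites transcribed
#' (depth > 0) in that cell. The Alu editing index (AEI) restricts the
#' site set to Alu-context sites, and the stringent variant (`AEI100`)
#' further to Alu sites transcribed in at least `min_prevalence` cells.
#' A cell transcribing no eligible site has an undefined index (NA).
#'
#' @param em an [editing_matrix()]; `AEI` modes require a `context` site
#'   column (see [annotate_context()]).
#' @param mode one of `"GEI"`, `"AEI"`, `"AEI100"`.
#' @param min_prevalence transcription prevalence (cells with depth > 0)
#'   required of a site for the stringent AEI (default 100).
#' @param edited_min_alt alt count at which a transcribed site counts as
#'   edited in a cell (default 1).
#' @return data.frame with one row per cell: `cell_id`, `n_transcribed`,
#'   `n_edited`, `index`, `mode`.
#' @export
per_cell_indices <- function(em, mode = c("GEI", "AEI", "AEI100"),
                             min_prevalence = 100, edited_min_alt = 1) {
  mode <- match.arg(mode)
  site_set <- rep(TRUE, nrow(em$sites))
  if (mode %in% c("AEI", "AEI100")) {
    if (is.null(em$sites$context))
      stop("AEI modes require a 'context' site column")
    site_set <- em$sites$context == "Alu"
  }
  if (mode == "AEI100") {
    prev <- Matrix::rowSums(em$depth > 0)
    site_set <- site_set & prev >= min_prevalence
  }
  tr <- em_triplets(em)
  tr <- tr[site_set[tr$site], ]
  nc <- nrow(em$cells)
  n_tr <- tabulate(tr$cell, nbins = nc)
  n_ed <- tabulate(tr$cell[tr$alt >= edited_min_alt], nbins = nc)
  frac <- tr$alt / tr$depth
  ssum <- rep(0, nc)
  agg <- tapply(frac, tr$cell, sum)
  ssum[as.integer(names(agg))] <- agg
  idx <- ifelse(n_tr > 0, ssum / n_tr, NA_real_)
  data.frame(cell_id = em$cells$cell_id, n_transcribed = n_tr,
             n_edited = n_ed, index = idx, mode = mode,
             stringsAsFactors = FALSE)
}

#' Per-site editing summaries
#'
#' For each site: the number of cells transcribing it, the number of
#' cells in which it is edited (alt >= `edited_min_alt`), and the mean
#' edited-allele fraction over transcribed cells. Sites transcribed
#' nowhere have an undefined mean (NA).
#'
#' @param em an [editing_matrix()].
#' @param edited_min_alt per-cell edited threshold (default 1).
#' @return data.frame with `site_id` (when available), `chrom`, `pos`,
#'   `n_transcribed`, `n_edited`, `mean_maf`.
#' @export
per_site_summaries <- function(em, edited_min_alt = 1) {
  tr <- em_triplets(em)
  ns <- nrow(em$sites)
  n_tr <- tabulate(tr$site, nbins = ns)
  n_ed <- tabulate(tr$site[tr$alt >= edited_min_alt], nbins = ns)
  ssum <- rep(0, ns)
  agg <- tapply(tr$alt / tr$depth, tr$site, sum)
  ssum[as.integer(names(agg))] <- agg
  out <- data.frame(chrom = em$sites$chrom, pos = em$sites$pos,
                    n_transcribed = n_tr, n_edited = n_ed,
                    mean_maf = ifelse(n_tr > 0, ssum / n_tr, NA_real_),
                    stringsAsFactors = FALSE)
  if (!is.null(em$sites$site_id)) out <- cbind(site_id = em$sites$site_id,
                                               out)
  out
}

#' Per-cell edited-allele fractions (long form)
#'
#' All alt/depth fractions at transcribed site/cell pairs, for
#' distributional checks (bimodality of per-cell fractions, skew of
#' cross-cell means).
#'
#' @param em an [editing_matrix()].
#' @return data.frame with `site`, `cell`, `depth`, `alt`, `frac`.
#' @export
per_cell_fractions <- function(em) {
  tr <- em_triplets(em)
  tr$frac <- tr$alt / tr$depth
  tr
}

#' Compare editing indices between cell groups
#'
#' Fits an ordinary linear model of the per-cell index on group
#' indicators plus log10 library size (editing indices show a modest
#' library-size effect, which is controlled for here).
#'
#' @param summaries output of [per_cell_indices()].
#' @param cells cell metadata with `cell_id`, grouping columns and
#'   `library_size`.
#' @param grouping `"phenotype"`, `"subgroup"`, or
#'   `"region_phenotype"` (the interaction of region and phenotype).
#' @return data.frame of model coefficients (term, estimate, se,
#'   statistic, p); the fitted model is attached as attribute `model`.
#' @export
compare_indices <- function(summaries, cells,
                            grouping = c("phenotype", "subgroup",
                                         "region_phenotype")) {
  grouping <- match.arg(grouping)
  d <- merge(summaries, cells, by = "cell_id")
  d <- d[!is.na(d$index), ]
  d$group <- switch(grouping,
                    phenotype = d$phenotype,
                    subgroup = d$subgroup,
                    region_phenotype = paste(d$region, d$phenotype,
                                             sep = ":"))
  tab <- table(d$group)
  if (length(tab) < 2L)
    stop("need at least two groups with defined indices")
  if (any(tab < 2L))
    stop("every group must contain at least two cells; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  d$log_lib <- log10(d$library_size)
  fit <- stats::lm(index ~ group + log_lib, data = d)
  if (any(is.na(stats::coef(fit))))
    stop("singular design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  cf <- summary(fit)$coefficients
  out <- data.frame(term = rownames(cf), estimate = cf[, 1],
                    se = cf[, 2], statistic = cf[, 3], p = cf[, 4],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "model") <- fit
  out
}
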