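#' Flag cells failing quality control
#'
#' A nucleus fails QC when its mitochondrial read fraction exceeds
#' `mito_max` (strictly — "more than 15%" mitochondrial RNA) or its
#' library complexity (detected genes) falls below `min_complexity`.
#'
#' @param cells cell metadata with `mito_frac` and `complexity` columns.
#' @param mito_max maximum tolerated mitochondrial fraction (default
#'   0.15; a cell at exactly 0.15 passes).
#' @param min_complexity minimum detected-gene count (default 1000; the
#'   threshold is a free parameter of the pipeline).
#' @return `cells` with logical `qc_pass` and character `qc_reason`
#'   columns; failure counts by reason are attached as attribute
#'   `qc_counts`.
#' @export
cell_qc <- function(cells, mito_max = 0.15, min_complexity = 1000) {
  fail_mito <- cells$mito_frac > mito_max
  fail_cx <- cells$complexity < min_complexity
  cells$qc_pass <- !(fail_mito | fail_cx)
  cells$qc_reason <- ifelse(fail_mito & fail_cx, "mito+complexity",
                     ifelse(fail_mito, "mito",
                     ifelse(fail_cx, "complexity", "none")))
  attr(cells, "qc_counts") <- c(mito = sum(fail_mito & !fail_cx),
                                complexity = sum(fail_cx & !fail_mito),
                                both = sum(fail_mito & fail_cx),
                                total_failed = sum(!cells$qc_pass))
  cells
}

variant_class <- function(sites) {
  ifelse(sites$ref == "A" & sites$alt == "G", "A>G",
  ifelse(sites$ref == "T" & sites$alt == "C", "T>C", "other"))
}

#' Select candidate editing sites by coverage and prevalence
#'
#' Retains A>G and T>C sites that, in at least `min_cells` cells, are
#' covered by at least `min_depth` reads with an alternate-allele count
#' of at least `min_alt`. Every threshold is inclusive ("at least"). Each
#' cell must individually satisfy both the depth and the alt-count
#' threshold to count towards prevalence.
#'
#' @param em an [editing_matrix()]; cells should already be QC-filtered.
#' @param min_depth minimum per-cell read depth (default 5).
#' @param min_alt minimum per-cell alternate count (default 2).
#' @param min_cells minimum number of qualifying cells (default 10; the
#'   replication-data configuration uses 3).
#' @return the site-subset `editing_matrix`; per-site qualifying-cell
#'   counts are stored in the `n_qualifying` site column.
#' @export
select_candidates <- function(em, min_depth = 5, min_alt = 2,
                              min_cells = 10) {
  if (min_cells < 1) stop("min_cells must be >= 1")
  tr <- em_triplets(em)
  qual <- tr$depth >= min_depth & tr$alt >= min_alt
  nq <- tabulate(tr$site[qual], nbins = nrow(em$sites))
  cls <- variant_class(em$sites)
  keep <- nq >= min_cells & cls %in% c("A>G", "T>C")
  em$sites$n_qualifying <- nq
  out <- em[keep, ]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Remove known common genomic SNPs
#'
#' Drops sites matching a SNP list exactly on (chrom, pos, ref, alt).
#'
#' @param em an [editing_matrix()].
#' @param snps data.frame with chrom, pos, ref, alt.
#' @return the filtered `editing_matrix`; the number removed is attached
#'   as attribute `n_snps_removed`.
#' @export
remove_common_snps <- function(em, snps) {
  key <- paste(em$sites$chrom, em$sites$pos, em$sites$ref, em$sites$alt,
               sep = ":")
  snp_key <- paste(snps$chrom, snps$pos, snps$ref, snps$alt, sep = ":")
  hit <- key %in% snp_key
  out <- em[!hit, ]
  attr(out, "n_snps_removed") <- sum(hit)
  out
}

#' Strand-consistency and overlap filter with catalog rescue
#'
#' In unstranded data the edited strand cannot be observed directly, so a
#' site is kept only if (i) it is present in a known editing-site
#' catalog, or (ii) it lies within exactly one gene footprint (no
#' overlapping gene on either strand) and its variant class is cognate
#' with that gene's strand: A>G inside plus-strand genes, T>C inside
#' minus-strand genes. Retained sites are reported canonically as A>G on
#' the gene (or catalog) strand.
#'
#' @param em an [editing_matrix()].
#' @param catalog data.frame of known sites (chrom, pos, strand).
#' @param genes GRanges of gene annotation (rows with `type == "gene"`
#'   are used) or the generator's gene data.frame.
#' @return the filtered `editing_matrix` with site columns
#'   `gene_strand`, `variant_class`, `rescued` (kept by catalog
#'   membership only) and `gene_id`.
#' @export
strand_filter <- function(em, catalog, genes) {
  if (is.data.frame(genes)) genes <- genes_to_granges(genes)
  if (!all(as.character(GenomicRanges::strand(genes)) %in% c("+", "-")))
    stop("gene annotation is missing strand information", call. = FALSE)
  g <- genes[genes$type == "gene"]
  sgr <- sites_to_granges(em$sites)
  ov <- GenomicRanges::findOverlaps(sgr, g, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  n_hit <- tabulate(qh, nbins = length(sgr))
  first_gene <- rep(NA_integer_, length(sgr))
  first_gene[qh[!duplicated(qh)]] <- sh[!duplicated(qh)]
  gstrand <- as.character(GenomicRanges::strand(g))[first_gene]
  cls <- variant_class(em$sites)
  cognate <- (cls == "A>G" & gstrand == "+") |
             (cls == "T>C" & gstrand == "-")
  cognate[is.na(cognate)] <- FALSE
  in_cat <- paste(em$sites$chrom, em$sites$pos) %in%
    paste(catalog$chrom, catalog$pos)
  keep <- in_cat | (n_hit == 1L & cognate)

  st <- em$sites
  st$gene_id <- ifelse(is.na(first_gene), NA_character_,
                       g$gene_id[first_gene])
  cat_strand <- catalog$strand[match(paste(st$chrom, st$pos),
                                     paste(catalog$chrom, catalog$pos))]
  st$variant_class <- cls
  # canonical strand: gene strand where available, else catalog strand,
  # else inferred from the variant class itself
  st$gene_strand <- ifelse(!is.na(gstrand), gstrand,
                    ifelse(!is.na(cat_strand), cat_strand,
                           ifelse(cls == "A>G", "+", "-")))
  st$rescued <- in_cat & !(n_hit == 1L & cognate)
  em$sites <- st
  out <- em[keep, ]
  attr(out, "n_dropped_strand") <- sum(!keep)
  out
}

#' Annotate sites with repeat context
#'
#' Labels each site `Alu` if it overlaps an Alu interval, otherwise
#' `repNonAlu` if it overlaps any other repeat, otherwise
#' `nonrepetitive`. Alu takes precedence when intervals nest.
#'
#' @param em an [editing_matrix()] (or a site data.frame).
#' @param repeats GRanges with a `class` column (`Alu`/`repNonAlu`), or
#'   the generator's repeat data.frame.
#' @return input with a `context` site column.
#' @export
annotate_context <- function(em, repeats) {
  if (is.data.frame(repeats)) repeats <- repeats_to_granges(repeats)
  sites <- if (inherits(em, "editing_matrix")) em$sites else em
  sgr <- sites_to_granges(sites)
  alu <- GenomicRanges::countOverlaps(
    sgr, repeats[repeats$class == "Alu"], ignore.strand = TRUE) > 0
  anyrep <- GenomicRanges::countOverlaps(sgr, repeats,
                                         ignore.strand = TRUE) > 0
  sites$context <- ifelse(alu, "Alu",
                   ifelse(anyrep, "repNonAlu", "nonrepetitive"))
  if (inherits(em, "editing_matrix")) {
    em$sites <- sites
    em
  } else sites
}

FEATURE_PRECEDENCE <- c("stop_codon", "three_prime_UTR",
                        "five_prime_UTR", "exon")

#' Annotate sites with gene feature
#'
#' Assigns the most specific overlapping feature, with precedence
#' stop codon > UTR > exon; sites inside a gene but outside any exon are
#' intronic; sites outside all genes are `other`.
#'
#' @param em an [editing_matrix()] (or a site data.frame).
#' @param genes GRanges of gene annotation (GFF3 feature types) or the
#'   generator's gene data.frame.
#' @return input with a `feature` site column (`stop_codon`, `3'UTR`,
#'   `5'UTR`, `exon`, `intron`, `noncoding`, `other`).
#' @export
annotate_feature <- function(em, genes) {
  if (is.data.frame(genes)) genes <- genes_to_granges(genes)
  sites <- if (inherits(em, "editing_matrix")) em$sites else em
  sgr <- sites_to_granges(sites)
  lab <- rep("other", length(sgr))
  in_gene <- GenomicRanges::countOverlaps(
    sgr, genes[genes$type == "gene"], ignore.strand = TRUE) > 0
  lab[in_gene] <- "intron"
  hit <- function(type) GenomicRanges::countOverlaps(
    sgr, genes[genes$type == type], ignore.strand = TRUE) > 0
  lab[hit("exon")] <- "exon"
  lab[hit("five_prime_UTR")] <- "5'UTR"
  lab[hit("three_prime_UTR")] <- "3'UTR"
  lab[hit("stop_codon")] <- "stop_codon"
  if (any(genes$type == "noncoding_gene"))
    lab[GenomicRanges::countOverlaps(
      sgr, genes[genes$type == "noncoding_gene"],
      ignore.strand = TRUE) > 0] <- "noncoding"
  sites$feature <- lab
  if (inherits(em, "editing_matrix")) {
    em$sites <- sites
    em
  } else sites
}

#' Classify sites as cataloged or novel
#'
#' A site is novel iff it is absent from every supplied catalog.
#' Per-catalog membership flags are retained for intersection reporting.
#'
#' @param em an [editing_matrix()] (or a site data.frame).
#' @param catalogs a named list of data.frames with chrom and pos
#'   columns (a single data.frame is treated as one catalog).
#' @return input with logical `in_<name>` columns and a
#'   `catalog_status` column (`cataloged`/`novel`).
#' @export
classify_novelty <- function(em, catalogs) {
  if (is.data.frame(catalogs)) catalogs <- list(catalog = catalogs)
  if (!length(catalogs)) stop("at least one catalog is required")
  if (is.null(names(catalogs)) || any(!nzchar(names(catalogs))))
    names(catalogs) <- paste0("catalog", seq_along(catalogs))
  sites <- if (inherits(em, "editing_matrix")) em$sites else em
  key <- paste(sites$chrom, sites$pos)
  any_hit <- rep(FALSE, nrow(sites))
  for (nm in names(catalogs)) {
    hit <- key %in% paste(catalogs[[nm]]$chrom, catalogs[[nm]]$pos)
    sites[[paste0("in_", nm)]] <- hit
    any_hit <- any_hit | hit
  }
  sites$catalog_status <- ifelse(any_hit, "cataloged", "novel")
  if (inherits(em, "editing_matrix")) {
    em$sites <- sites
    em
  } else sites
}

#' Nearest-neighbor distances between editing sites, per context
#'
#' For each site, the distance to the nearest other site of the same
#' context class on the same chromosome. Sites that are the only member
#' of their context/chromosome class have no defined distance and are
#' excluded (and counted in the `n_excluded` attribute).
#'
#' @param sites site data.frame with chrom, pos and `context` columns
#'   (or an [editing_matrix()]).
#' @return list with `distances` (data.frame site row, context, dist)
#'   and `medians` (named per-context medians).
#' @export
neighbor_distances <- function(sites) {
  if (inherits(sites, "editing_matrix")) sites <- sites$sites
  if (is.null(sites$context))
    stop("sites must carry a 'context' column (run annotate_context)")
  res <- list(); excluded <- 0L
  for (ctx in unique(sites$context)) {
    for (ch in unique(sites$chrom[sites$context == ctx])) {
      idx <- which(sites$context == ctx & sites$chrom == ch)
      if (length(idx) < 2L) { excluded <- excluded + length(idx); next }
      o <- idx[order(sites$pos[idx])]
      p <- sites$pos[o]
      gap <- diff(p)
      d <- pmin(c(Inf, gap), c(gap, Inf))
      res[[length(res) + 1L]] <- data.frame(row = o, context = ctx,
                                            chrom = ch, pos = p,
                                            dist = d)
    }
  }
  distances <- if (length(res)) do.call(rbind, res) else
    data.frame(row = integer(), context = character(),
               chrom = character(), pos = integer(), dist = numeric())
  medians <- vapply(split(distances$dist, distances$context),
                    stats::median, numeric(1))
  out <- list(distances = distances, medians = medians)
  attr(out, "n_excluded") <- excluded
  out
}

#' Run the full editing-site filter cascade
#'
#' Applies, in order: cell QC subsetting; coverage/prevalence candidate
#' selection; common-SNP removal; the strand/overlap filter with catalog
#' rescue; repeat-context, gene-feature and novelty annotation.
#'
#' @param em an [editing_matrix()] over all called sites and cells.
#' @param genes gene annotation (GRanges or generator data.frame).
#' @param repeats repeat annotation (GRanges or generator data.frame).
#' @param catalog known editing-site catalog (chrom, pos, strand).
#' @param snps common-SNP list (chrom, pos, ref, alt).
#' @param min_depth,min_alt,min_cells see [select_candidates()].
#' @param mito_max,min_complexity see [cell_qc()].
#' @return the filtered, annotated `editing_matrix`; a per-step count
#'   log is attached as attribute `filter_log`.
#' @export
filter_editing_sites <- function(em, genes, repeats, catalog, snps,
                                 min_depth = 5, min_alt = 2,
                                 min_cells = 10, mito_max = 0.15,
                                 min_complexity = 1000) {
  log <- c(input_sites = nrow(em$sites), input_cells = nrow(em$cells))
  cells <- em$cells
  if (!is.null(cells$mito_frac) && !is.null(cells$complexity)) {
    cells <- cell_qc(cells, mito_max, min_complexity)
    em <- em[, cells$qc_pass]
  }
  log["cells_pass_qc"] <- nrow(em$cells)
  em <- select_candidates(em, min_depth, min_alt, min_cells)
  log["candidate_sites"] <- nrow(em$sites)
  em <- remove_common_snps(em, snps)
  log["after_snp_removal"] <- nrow(em$sites)
  em <- strand_filter(em, catalog, genes)
  log["after_strand_filter"] <- nrow(em$sites)
  em <- annotate_context(em, repeats)
  em <- annotate_feature(em, genes)
  em <- classify_novelty(em, list(catalog = catalog))
  attr(em, "filter_log") <- log
  em
}
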