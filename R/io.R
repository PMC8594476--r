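#' @importFrom utils read.delim write.table
NULL

# ---- writers ------------------------------------------------------------

#' Write the editing matrix as a multi-sample VCF v4.2
#'
#' Sites with at least one cell carrying the alternate allele are emitted
#' as biallelic SNV records with per-sample GT:AD:DP fields; cells in
#' which the site is not transcribed are encoded as missing.
#'
#' @param em an [editing_matrix()].
#' @param path output file path.
#' @return invisibly, the number of records written.
#' @export
write_editing_vcf <- function(em, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=scredit-simulator",
           "##contig=<ID=chr1>",
           paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                  "Description=\"Genotype\">"),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                  "Description=\"Read depth\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", em$cells$cell_id), collapse = "\t"))
  has_alt <- Matrix::rowSums(em$alt) > 0
  idx <- which(has_alt)
  lines <- character(length(idx))
  altm <- as.matrix(em$alt[idx, , drop = FALSE])
  depm <- as.matrix(em$depth[idx, , drop = FALSE])
  for (k in seq_along(idx)) {
    s <- idx[k]
    dp <- depm[k, ]; ac <- altm[k, ]
    gt <- ifelse(dp == 0, "./.:.:.",
                 paste0(ifelse(ac > 0, "0/1", "0/0"), ":",
                        dp - ac, ",", ac, ":", dp))
    lines[k] <- paste(c(em$sites$chrom[s], em$sites$pos[s], ".",
                        em$sites$ref[s], em$sites$alt[s], ".", "PASS",
                        ".", "GT:AD:DP", gt), collapse = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(length(lines))
}

#' Write per-site per-cell total depths as a long-format TSV
#'
#' Columns: chrom, pos, cell_id, depth — one row per transcribed
#' site/cell pair. This is the companion input that distinguishes
#' "transcribed, unedited" from "not transcribed" downstream.
#'
#' @param em an [editing_matrix()].
#' @param path output file path.
#' @export
write_depth_tsv <- function(em, path) {
  tr <- em_triplets(em)
  out <- data.frame(chrom = em$sites$chrom[tr$site],
                    pos = em$sites$pos[tr$site],
                    cell_id = em$cells$cell_id[tr$cell],
                    depth = as.integer(tr$depth))
  out <- out[order(out$pos, out$cell_id), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(out))
}

#' Write repeat intervals as BED6
#'
#' The name field carries the repeat class (`Alu` or `repNonAlu`);
#' coordinates follow the BED convention (0-based, half-open).
#'
#' @param repeats data.frame with chrom, start, end (1-based inclusive),
#'   class, strand.
#' @param path output file path.
#' @export
write_repeats_bed <- function(repeats, path) {
  bed <- data.frame(chrom = repeats$chrom,
                    start = repeats$start - 1L,
                    end = repeats$end,
                    name = repeats$class,
                    score = 0L,
                    strand = repeats$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(nrow(bed))
}

#' Write the gene/feature table as GFF3
#'
#' @param genes data.frame with chrom, start, end, strand, gene_id, type
#'   (1-based inclusive coordinates).
#' @param path output file path.
#' @export
write_genes_gff3 <- function(genes, path) {
  attr_col <- ifelse(genes$type == "gene",
                     paste0("ID=", genes$gene_id),
                     paste0("Parent=", genes$gene_id))
  gff <- data.frame(seqid = genes$chrom, source = "scredit",
                    type = genes$type, start = genes$start,
                    end = genes$end, score = ".", strand = genes$strand,
                    phase = ".", attributes = attr_col)
  con <- file(path, "w")
  writeLines("##gff-version 3", con)
  write.table(gff, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  close(con)
  invisible(nrow(gff))
}

#' Write a complete synthetic fixture directory
#'
#' Emits every file the ingest side of the pipeline consumes: a
#' multi-sample VCF, a depth TSV, gene GFF3, repeat BED6, editing-site
#' catalog TSV, SNP TSV, cell metadata TSV, TPM and count matrices, and
#' the truth tables.
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory path.
#' @export
write_fixture_dir <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_editing_vcf(sim$matrix, fp("variants.vcf"))
  write_depth_tsv(sim$matrix, fp("depths.tsv"))
  write_genes_gff3(sim$truth$annotation$genes, fp("genes.gff3"))
  write_repeats_bed(sim$truth$annotation$repeats, fp("repeats.bed"))
  wt <- function(x, f) write.table(x, fp(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(sim$truth$annotation$catalog, "catalog.tsv")
  wt(sim$truth$annotation$snps, "snps.tsv")
  wt(sim$truth$cells, "cells.tsv")
  wt(sim$truth$annotation$sites, "site_truth.tsv")
  wt(sim$truth$gene_table, "gene_truth.tsv")
  tpm <- data.frame(gene_id = rownames(sim$expression$tpm),
                    sim$expression$tpm, check.names = FALSE)
  wt(tpm, "tpm.tsv")
  cnt <- data.frame(gene_id = rownames(sim$expression$counts),
                    sim$expression$counts, check.names = FALSE)
  wt(cnt, "counts.tsv")
  invisible(dir)
}

# ---- readers ------------------------------------------------------------

#' Load per-cell variant calls from VCF files
#'
#' Reads one or more VCF v4.2 files with per-sample allelic depths (AD),
#' splits multi-allelic records into biallelic ones, drops indels and
#' spanning-deletion alleles, and returns one record per cell x site x
#' alternate allele.
#'
#' @param paths character vector of VCF paths.
#' @param cells optional cell metadata; when given, samples absent from
#'   `cells$cell_id` are dropped.
#' @return data.frame with columns chrom, pos, ref, alt, cell_id,
#'   ref_depth, alt_depth.
#' @export
load_variants <- function(paths, cells = NULL) {
  out <- lapply(paths, function(p) {
    v <- vcfR::read.vcfR(p, verbose = FALSE)
    if (nrow(v@fix) == 0) return(NULL)
    fmt <- v@gt[, "FORMAT"]
    if (!all(grepl("(^|:)AD(:|$)", fmt)))
      stop("VCF file lacks per-sample AD field: ", p, call. = FALSE)
    ad <- vcfR::extract.gt(v, element = "AD")
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    samples <- colnames(ad)
    recs <- vector("list", nrow(fix))
    for (r in seq_len(nrow(fix))) {
      alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
      ref <- fix$REF[r]
      adr <- strsplit(ad[r, ], ",", fixed = TRUE)
      ok_cell <- !is.na(ad[r, ]) & ad[r, ] != "."
      sub <- vector("list", length(alts))
      for (a in seq_along(alts)) {
        if (nchar(ref) != 1L || nchar(alts[a]) != 1L ||
            alts[a] == "*") next  # indel or spanning deletion
        refd <- vapply(adr, function(x)
          if (length(x) >= 1) suppressWarnings(as.integer(x[1]))
          else NA_integer_, integer(1))
        altd <- vapply(adr, function(x)
          if (length(x) >= a + 1) suppressWarnings(as.integer(x[a + 1]))
          else NA_integer_, integer(1))
        keep <- ok_cell & !is.na(refd) & !is.na(altd)
        if (!any(keep)) next
        sub[[a]] <- data.frame(chrom = fix$CHROM[r],
                               pos = as.integer(fix$POS[r]),
                               ref = ref, alt = alts[a],
                               cell_id = samples[keep],
                               ref_depth = refd[keep],
                               alt_depth = altd[keep],
                               stringsAsFactors = FALSE)
      }
      recs[[r]] <- do.call(rbind, sub)
    }
    do.call(rbind, recs)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      cell_id = character(), ref_depth = integer(),
                      alt_depth = integer(), stringsAsFactors = FALSE)
  if (!is.null(cells)) out <- out[out$cell_id %in% cells$cell_id, ]
  rownames(out) <- NULL
  out
}

#' Assemble an editing matrix from variant calls and a depth table
#'
#' Sites are keyed by (chrom, pos, ref, alt). The alt matrix is filled
#' from the calls; the depth matrix from `ref_depth + alt_depth`,
#' overridden/augmented by the long-format depth table when supplied, so
#' that cells transcribing a site without the variant are represented.
#'
#' @param calls data.frame from [load_variants()].
#' @param cells cell metadata data.frame with `cell_id`.
#' @param depths optional data.frame with chrom, pos, cell_id, depth.
#' @return an [editing_matrix()].
#' @export
build_editing_matrix <- function(calls, cells, depths = NULL) {
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
  ukey <- unique(key)
  site_idx <- match(key, ukey)
  first <- !duplicated(key)
  sites <- data.frame(chrom = calls$chrom[first],
                      pos = calls$pos[first],
                      ref = calls$ref[first], alt = calls$alt[first],
                      stringsAsFactors = FALSE)
  o <- order(sites$chrom, sites$pos, sites$alt)
  rank <- integer(nrow(sites)); rank[o] <- seq_len(nrow(sites))
  sites <- sites[o, ]; rownames(sites) <- NULL
  site_idx <- rank[site_idx]
  cell_idx <- match(calls$cell_id, cells$cell_id)
  if (anyNA(cell_idx))
    stop("calls contain cell ids absent from the cell table")
  ns <- nrow(sites); nc <- nrow(cells)
  altm <- Matrix::sparseMatrix(i = site_idx, j = cell_idx,
                               x = as.numeric(calls$alt_depth),
                               dims = c(ns, nc))
  depm <- Matrix::sparseMatrix(
    i = site_idx, j = cell_idx,
    x = as.numeric(calls$ref_depth + calls$alt_depth),
    dims = c(ns, nc))
  if (!is.null(depths)) {
    ds <- match(paste(depths$chrom, depths$pos, sep = ":"),
                paste(sites$chrom, sites$pos, sep = ":"))
    dc <- match(depths$cell_id, cells$cell_id)
    keep <- !is.na(ds) & !is.na(dc)
    if (any(keep)) {
      # depth table wins where both present
      tab <- rbind(data.frame(i = ds[keep], j = dc[keep],
                              x = as.numeric(depths$depth[keep])),
                   data.frame(i = site_idx, j = cell_idx,
                              x = as.numeric(calls$ref_depth +
                                             calls$alt_depth)))
      tab <- tab[!duplicated(tab[c("i", "j")]), ]
      depm <- Matrix::sparseMatrix(i = tab$i, j = tab$j, x = tab$x,
                                   dims = c(ns, nc))
    }
  }
  editing_matrix(alt = altm, depth = depm, sites = sites, cells = cells)
}

#' Read gene annotation (GFF3) as a GRanges
#'
#' @param path GFF3 file path.
#' @return GRanges with `type` and `gene_id` metadata columns.
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gid <- gr$ID
  if (!is.null(gr$Parent)) {
    par <- vapply(gr$Parent, function(x)
      if (length(x)) as.character(x[1]) else NA_character_, character(1))
    gid <- ifelse(is.na(gid) | !nzchar(gid), par, gid)
  }
  gr$gene_id <- gid
  if (any(GenomicRanges::strand(gr) == "*"))
    stop("gene annotation is missing strand information: ", path,
         call. = FALSE)
  gr
}

#' Read repeat annotation (BED6) as a GRanges
#'
#' @param path BED file path; the name field must label each interval
#'   `Alu` or `repNonAlu`.
#' @return GRanges with a `class` metadata column.
#' @export
read_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  gr$class <- gr$name
  gr
}

#' Read a tab-separated table (catalog, SNP list, cells, depths, truth)
#'
#' @param path TSV path with a header row.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

# convert in-memory annotation data.frames to GRanges
genes_to_granges <- function(genes) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  gr$type <- genes$type
  gr$gene_id <- genes$gene_id
  gr
}

repeats_to_granges <- function(repeats) {
  gr <- GenomicRanges::GRanges(
    seqnames = repeats$chrom,
    ranges = IRanges::IRanges(start = repeats$start, end = repeats$end),
    strand = repeats$strand)
  gr$class <- repeats$class
  gr
}

sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L))
}
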