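#' Sparse site-by-cell editing matrix
#'
#' Container pairing an edited-allele (alt) count matrix with a total read
#' depth matrix over the same sites and cells, plus site and cell
#' metadata. A depth of 0 means the site was not transcribed in that cell;
#' depth > 0 with alt = 0 means transcribed but unedited — the two are
#' deliberately distinct states throughout the package.
#'
#' @param alt sparse (or dense) numeric matrix of edited-allele counts,
#'   sites x cells.
#' @param depth matrix of total read depths, same shape as `alt`.
#' @param sites data.frame of site metadata, one row per matrix row; must
#'   contain at least `chrom`, `pos`, `ref`, `alt`.
#' @param cells data.frame of cell metadata, one row per matrix column;
#'   must contain `cell_id`.
#' @return an object of class `editing_matrix`.
#' @export
editing_matrix <- function(alt, depth, sites, cells) {
  alt <- methods::as(methods::as(alt, "CsparseMatrix"), "generalMatrix")
  depth <- methods::as(methods::as(depth, "CsparseMatrix"),
                       "generalMatrix")
  if (!all(dim(alt) == dim(depth)))
    stop("alt and depth matrices must share dimensions")
  if (nrow(alt) != nrow(sites))
    stop("sites table must have one row per matrix row")
  if (ncol(alt) != nrow(cells))
    stop("cells table must have one row per matrix column")
  if (any((alt - depth)@x > 0))
    stop("alt counts must not exceed depth anywhere")
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stop("sites table must contain columns: ",
         paste(need, collapse = ", "))
  if (!"cell_id" %in% names(cells))
    stop("cells table must contain a cell_id column")
  structure(list(alt = alt, depth = depth, sites = sites, cells = cells),
            class = "editing_matrix")
}

#' @export
print.editing_matrix <- function(x, ...) {
  nt <- Matrix::nnzero(x$depth)
  cat("editing_matrix:", nrow(x$sites), "sites x", nrow(x$cells),
      "cells;", nt, "transcribed site/cell pairs (",
      sprintf("%.1f%%", 100 * nt / prod(dim(x$depth))), ")\n")
  invisible(x)
}

#' @export
dim.editing_matrix <- function(x) dim(x$alt)

#' Subset an editing matrix by sites and/or cells
#'
#' @param x an `editing_matrix`.
#' @param i site (row) index, logical or integer.
#' @param j cell (column) index, logical or integer.
#' @param ... ignored.
#' @return the subset `editing_matrix`.
#' @export
`[.editing_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$alt))
  if (missing(j)) j <- seq_len(ncol(x$alt))
  editing_matrix(alt = x$alt[i, j, drop = FALSE],
                 depth = x$depth[i, j, drop = FALSE],
                 sites = x$sites[i, , drop = FALSE],
                 cells = x$cells[j, , drop = FALSE])
}

# triplet view of transcribed entries: data.frame(site, cell, depth, alt)
em_triplets <- function(x) {
  tr <- Matrix::summary(x$depth)
  a <- x$alt[cbind(tr$i, tr$j)]
  data.frame(site = tr$i, cell = tr$j, depth = tr$x, alt = a)
}
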