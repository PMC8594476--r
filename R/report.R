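#' Exact percentage with half-up rounding
#'
#' Computes 100 * numerator / denominator rounded half-up at the
#' requested number of decimals (the convention used when reporting
#' site-census percentages). The numerator and denominator are stored as
#' attributes so every printed percentage can be recomputed.
#'
#' @param numerator,denominator nonnegative counts; the denominator must
#'   be positive.
#' @param decimals decimal places (default 1).
#' @return the rounded percentage, with `numerator`, `denominator` and
#'   `decimals` attributes.
#' @export
percent_of <- function(numerator, denominator, decimals = 1) {
  if (any(denominator <= 0))
    stop("denominator must be > 0")
  scale <- 10^decimals
  raw <- 100 * numerator / denominator
  out <- floor(raw * scale + 0.5) / scale
  attr(out, "numerator") <- numerator
  attr(out, "denominator") <- denominator
  attr(out, "decimals") <- decimals
  out
}

#' Set-intersection census over site membership flags
#'
#' Counts sites in every combination of the requested membership sets
#' (upset-plot style), together with per-set sizes and the union. Counts
#' satisfy inclusion-exclusion by construction and each percentage keeps
#' its numerator and denominator.
#'
#' @param membership data.frame (or site table) whose columns named in
#'   `sets` are logical membership flags.
#' @param sets character vector of membership column names.
#' @return list of class `editing_census`: `combinations` (one row per
#'   observed combination, with flag columns, `count` and `percent` of
#'   the universe), `set_sizes`, `union_size`, `n_universe`.
#' @export
editing_census <- function(membership, sets) {
  missing_sets <- setdiff(sets, names(membership))
  if (length(missing_sets))
    stop("unknown set name(s): ", paste(missing_sets, collapse = ", "))
  flags <- membership[sets]
  for (s in sets) {
    if (!is.logical(flags[[s]]))
      stop("set column must be logical: ", s)
  }
  n <- nrow(flags)
  key <- do.call(paste, c(lapply(flags, as.integer), sep = ""))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  names(combos) <- sets
  ckey <- do.call(paste, c(lapply(combos, as.integer), sep = ""))
  counts <- as.integer(table(factor(key, levels = ckey)))
  combos$count <- counts
  combos$percent <- vapply(counts, function(k)
    as.numeric(percent_of(k, max(n, 1), 1)), numeric(1))
  set_sizes <- vapply(flags, sum, numeric(1))
  out <- list(combinations = combos,
              set_sizes = set_sizes,
              union_size = sum(Reduce(`|`, flags)),
              n_universe = n)
  class(out) <- "editing_census"
  out
}

#' @export
print.editing_census <- function(x, ...) {
  cat("editing site census over", x$n_universe, "sites\n")
  cat("set sizes:\n")
  for (nm in names(x$set_sizes))
    cat(sprintf("  %-24s %d\n", nm, x$set_sizes[[nm]]))
  cat("union:", x$union_size, "\n")
  nonzero <- x$combinations[x$combinations$count > 0, ]
  nonzero <- nonzero[order(-nonzero$count), ]
  print(utils::head(nonzero, 10), row.names = FALSE)
  invisible(x)
}
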