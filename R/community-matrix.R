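#' Site-by-species presence/absence matrix
#'
#' Constructs and validates a binary community matrix: rows are sites
#' (assemblages), columns are species, entries are 1 (present) / 0 (absent).
#' All pairwise dissimilarities in the package are computed from this object.
#'
#' @param x numeric matrix with row names (site ids) and column names
#'   (species ids); entries must be 0 or 1.
#' @return an object of class `community_matrix` (a classed binary matrix).
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("low", "high"), c("sp1", "sp2", "sp3")))
#' cm <- community_matrix(m)
#' sites(cm)
#' species(cm)
#' @export
community_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("`x` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("`x` must carry site row names and species column names", call. = FALSE)
  rownames(x) <- trim_ids(rownames(x))
  colnames(x) <- trim_ids(colnames(x))
  stop_if_duplicated(rownames(x), "site")
  stop_if_duplicated(colnames(x), "species")
  if (nrow(x) < 2L) stop("a community matrix needs at least 2 sites", call. = FALSE)
  if (ncol(x) < 1L) stop("a community matrix needs at least 1 species", call. = FALSE)
  if (anyNA(x)) stop("community matrix contains missing values", call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop("community matrix entries must be 0 or 1 (use read_community_matrix() to coerce)",
         call. = FALSE)
  storage.mode(x) <- "double"
  class(x) <- c("community_matrix", class(x))
  x
}

#' @rdname community_matrix
#' @param cm a `community_matrix`.
#' @export
sites <- function(cm) UseMethod("sites")

#' @export
sites.community_matrix <- function(cm) rownames(cm)

#' @rdname community_matrix
#' @export
species <- function(cm) UseMethod("species")

#' @export
species.community_matrix <- function(cm) colnames(cm)

#' @export
print.community_matrix <- function(x, ...) {
  r <- rowSums(x)
  cat(sprintf("community_matrix: %d sites x %d species\n", nrow(x), ncol(x)))
  cat(sprintf("  richness %d-%d (median %g); %d species never recorded\n",
              min(r), max(r), stats::median(r), sum(colSums(x) == 0)))
  invisible(x)
}

#' Read a community matrix from CSV
#'
#' The file must have a header row of species names and a first column of
#' site ids; remaining cells are incidences. Any nonzero numeric cell is
#' coerced to 1 with a warning, matching how raw occurrence counts are usually
#' collapsed to presence/absence.
#'
#' @param path CSV file path.
#' @param transpose set `TRUE` if the file stores species in rows and sites in
#'   columns; the matrix is transposed after reading (never silently).
#' @return a [community_matrix].
#' @export
read_community_matrix <- function(path, transpose = FALSE) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(raw) < 2L)
    stop("community CSV needs a site id column plus at least one species column",
         call. = FALSE)
  ids <- trim_ids(raw[[1L]])
  sp <- trim_ids(colnames(raw)[-1L])
  m <- matrix(NA_real_, nrow(raw), length(sp), dimnames = list(ids, sp))
  for (j in seq_along(sp)) {
    cell <- trim_ids(raw[[j + 1L]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric cell at row '%s', column '%s': '%s'",
                   ids[bad[1L]], sp[j], cell[bad[1L]]), call. = FALSE)
    m[, j] <- val
  }
  nonbinary <- m != 0 & m != 1
  if (any(nonbinary)) {
    warning(sprintf("%d nonzero cell(s) coerced to presence (1)", sum(nonbinary)),
            call. = FALSE)
    m[nonbinary] <- 1
  }
  if (transpose) m <- t(m)
  community_matrix(m)
}

#' @rdname read_community_matrix
#' @param cm a `community_matrix` to write.
#' @export
write_community_matrix <- function(cm, path) {
  df <- data.frame(site = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Drop species from the matrix that are absent from a reference id set.
# Hard error by default; with drop_unmatched = TRUE the offenders are pruned
# and listed in a message (we refuse to prune silently).
match_species_pool <- function(cm, reference_ids, what, drop_unmatched = FALSE) {
  pool <- species(cm)[colSums(cm) > 0]
  missing <- setdiff(pool, reference_ids)
  if (!length(missing)) return(cm)
  if (!drop_unmatched)
    stop(sprintf("%d species in the community matrix have no %s entry: %s",
                 length(missing), what, paste(missing, collapse = ", ")),
         call. = FALSE)
  message(sprintf("dropping %d species without %s entry: %s",
                  length(missing), what, paste(missing, collapse = ", ")))
  keep <- setdiff(species(cm), missing)
  community_matrix(unclass(cm)[, keep, drop = FALSE])
}
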