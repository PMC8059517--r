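#' Read a rooted phylogeny with branch lengths from a newick file
#'
#' Wraps [ape::read.tree()] with the validation the dissimilarity engines
#' rely on: every edge must carry a non-negative branch length, tip labels
#' must be unique, and the tree must be rooted. An unrooted tree whose only
#' departure from rootedness is a basal polytomy (e.g. a star tree) can be
#' accepted as rooted at that polytomy via `allow_basal_polytomy = TRUE`;
#' any other unrooted input is refused rather than rooted arbitrarily.
#'
#' @param path newick file path (single tree, or several trees one per line
#'   when `multi = TRUE`).
#' @param allow_basal_polytomy interpret a basal polytomy as the root.
#' @param multi return a list of trees (`ape::multiPhylo` input).
#' @return an `ape::phylo` object (or list of them).
#' @export
read_newick <- function(path, allow_basal_polytomy = FALSE, multi = FALSE) {
  tr <- ape::read.tree(path)
  if (inherits(tr, "multiPhylo")) {
    if (!multi)
      stop("file contains several trees; use multi = TRUE", call. = FALSE)
    return(lapply(tr, validate_tree, allow_basal_polytomy = allow_basal_polytomy))
  }
  if (multi) return(list(validate_tree(tr, allow_basal_polytomy)))
  validate_tree(tr, allow_basal_polytomy)
}

validate_tree <- function(tr, allow_basal_polytomy = FALSE) {
  if (!inherits(tr, "phylo")) stop("not a parseable newick tree", call. = FALSE)
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge) ||
      anyNA(tr$edge.length))
    stop("tree has missing branch lengths; lengths are required on every edge",
         call. = FALSE)
  if (any(tr$edge.length < 0))
    stop("tree has negative branch lengths", call. = FALSE)
  stop_if_duplicated(tr$tip.label, "tip")
  if (!ape::is.rooted(tr)) {
    if (!allow_basal_polytomy)
      stop(paste0("tree is unrooted; a basal polytomy can be accepted as the ",
                  "root with allow_basal_polytomy = TRUE"), call. = FALSE)
    # accepted as-is: the basal polytomy acts as the root node
  }
  tr
}

#' Read a species trait table from CSV
#'
#' First column: species id; remaining columns: positive size measurements
#' (e.g. body weight in g, head-body length in mm). Values must be strictly
#' positive because the trait-space construction log-transforms them.
#'
#' @param path CSV file path.
#' @return numeric matrix, rows named by species.
#' @export
read_trait_table <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("trait CSV needs a species id column plus at least 2 trait columns",
         call. = FALSE)
  ids <- stop_if_duplicated(trim_ids(raw[[1L]]), "species")
  m <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- trim_ids(colnames(m))
  if (anyNA(m)) stop("trait table contains missing values", call. = FALSE)
  if (any(m <= 0)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive trait value for species '%s', trait '%s' (log transform undefined)",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  m
}

#' Read a site table (elevation and optional environmental columns) from CSV
#'
#' First column: site id; an `elevation` column (metres) is required.
#' Recognised optional environmental columns: `AMT` (annual mean temperature,
#' deg C), `AP` (annual precipitation, mm), `AMH` (annual mean humidity, %),
#' `NPP` (net primary production), `PET` (potential evapotranspiration).
#'
#' @param path CSV file path.
#' @param cm optional [community_matrix]; when given, every matrix site must
#'   appear in the table (cross-validation error otherwise).
#' @return data.frame with a `site` character column.
#' @export
read_site_table <- function(path, cm = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(raw)[1L] <- "site"
  raw$site <- stop_if_duplicated(trim_ids(raw$site), "site")
  if (!"elevation" %in% colnames(raw))
    stop("site table needs an 'elevation' column (metres)", call. = FALSE)
  if (!all(is.finite(raw$elevation)))
    stop("site elevations must be finite", call. = FALSE)
  if (!is.null(cm)) {
    missing <- setdiff(sites(cm), raw$site)
    if (length(missing))
      stop(sprintf("site table is missing community-matrix site(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  raw
}

#' Read weather-station annual climate records from CSV
#'
#' Columns: station id, station `elevation` (m), and annual summaries `AMT`,
#' `AP`, `AMH`. Used by [interpolate_station_climate()].
#'
#' @param path CSV file path.
#' @return data.frame with a `station` character column.
#' @export
read_station_records <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(raw)[1L] <- "station"
  raw$station <- stop_if_duplicated(trim_ids(raw$station), "station")
  need <- c("elevation", "AMT", "AP", "AMH")
  missing <- setdiff(need, colnames(raw))
  if (length(missing))
    stop(sprintf("station records missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(raw) < 2L) stop("need at least 2 stations", call. = FALSE)
  if (anyDuplicated(raw$elevation))
    stop("station elevations must be distinct", call. = FALSE)
  raw
}

# Column documentation emitted alongside result CSVs.
result_dictionary <- c(
  site_i = "first site of the unordered pair (matrix order)",
  site_j = "second site of the unordered pair (matrix order)",
  a = "shared species count",
  b = "species unique to site_i",
  c = "species unique to site_j",
  a_bl = "summed branch length shared by both communities' root-to-tip paths",
  b_bl = "branch length on site_i's paths only",
  c_bl = "branch length on site_j's paths only",
  a_area = "area of the two communities' convex-hull intersection (squared PCA units)",
  b_area = "hull area unique to site_i",
  c_area = "hull area unique to site_j",
  beta_sim = "turnover (replacement) dissimilarity, min(b,c)/(a+min(b,c))",
  beta_sne = "nestedness-resultant dissimilarity, beta_sor - beta_sim",
  beta_sor = "total Sorensen dissimilarity, (b+c)/(2a+b+c)",
  excluded = "TRUE when the pair carries no dissimilarity (see reason)",
  reason = "why the pair was excluded, empty otherwise",
  dimension = "beta-diversity dimension: taxonomic, phylogenetic or functional",
  index = "which member of the decomposition: sim, sne or sor",
  observed = "observed dissimilarity for the pair",
  null_mean = "mean of the null distribution",
  null_sd = "standard deviation of the null distribution",
  ses = "(observed - null_mean)/null_sd",
  n_rand = "number of null randomizations",
  scheme = "randomization scheme id",
  seed = "seed of the randomization stream"
)

#' Write result tables as tidy CSVs with a data dictionary
#'
#' Each table becomes `<name>.csv` (one row per site pair for pairwise
#' tables, deterministic pair order), plus a `data_dictionary.txt`
#' documenting every column that appears.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  cols <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
    cols <- union(cols, colnames(df))
  }
  dict <- vapply(cols, function(cl) {
    d <- if (cl %in% names(result_dictionary)) result_dictionary[[cl]]
         else "(no description)"
    sprintf("%-12s %s", cl, d)
  }, character(1))
  dp <- file.path(out_dir, "data_dictionary.txt")
  writeLines(c("Column dictionary for result CSVs", "", dict), dp)
  invisible(c(paths, dp))
}
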