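# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Polygon area by the shoelace formula
#'
#' @param pts two-column numeric matrix of vertices in traversal order
#'   (either orientation; the absolute area is returned).
#' @return non-negative scalar area.
#' @keywords internal
#' @noRd
shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1L]
  y <- pts[, 2L]
  nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

# Derive a bounded sub-seed from a master seed (R integers are 32-bit).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483587)
}

trim_ids <- function(x) trimws(as.character(x))

stop_if_duplicated <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicated %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}
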