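#' Two-sided Wilcoxon rank-sum comparison reported as a z statistic
#'
#' Rank-sum test with average ranks for ties; the statistic is the
#' normal-approximation `z = (W - mu_W) / sigma_W` with tie-corrected
#' `sigma_W` and no continuity correction, and the two-sided p comes from
#' the standard normal. An exact-enumeration p over all C(n1+n2, n1) group
#' assignments of the pooled values is available as a cross-check for small
#' samples (`exact = TRUE`); it uses the symmetric-tail convention
#' `P(|W - mu_W| >= |w_obs - mu_W|)`.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param exact also compute the exact enumeration p (pooled n <= 16).
#' @return list of class `wilcoxon_z`: `z`, `abs_z`, `p`, `n1`, `n2`,
#'   `tie_correction_applied`, and `p_exact` when requested.
#' @examples
#' wilcoxon_z(c(1, 2, 3), c(4, 5, 6))  # |z| ~ 1.964
#' @export
wilcoxon_z <- function(x, y, exact = FALSE) {
  x <- as.numeric(x[is.finite(x)])
  y <- as.numeric(y[is.finite(y)])
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("each sample needs >= 2 values", call. = FALSE)
  N <- n1 + n2
  pooled <- c(x, y)
  r <- rank(pooled) # average ranks for ties
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_corr / (N * (N - 1)))
  if (sigma2 <= 0)
    stop("all values tied across both samples: rank-sum degenerate",
         call. = FALSE)
  z <- (W - mu) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  out <- list(z = z, abs_z = abs(z), p = p, n1 = n1, n2 = n2,
              tie_correction_applied = tie_corr > 0)
  if (exact) {
    if (N > 16L)
      stop("exact enumeration limited to pooled n <= 16", call. = FALSE)
    combs <- utils::combn(N, n1)
    Ws <- colSums(matrix(r[combs], nrow = n1))
    out$p_exact <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-12)
  }
  structure(out, class = "wilcoxon_z")
}

#' @export
print.wilcoxon_z <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: |z| = %.3f, p = %.4g (n1 = %d, n2 = %d%s)\n",
              x$abs_z, x$p, x$n1, x$n2,
              if (x$tie_correction_applied) ", tie-corrected" else ""))
  if (!is.null(x$p_exact)) cat(sprintf("  exact enumeration p = %.4g\n", x$p_exact))
  invisible(x)
}

# Decision label at alpha with the "nearly significant" band above it.
significance_label <- function(p, alpha = 0.05, near = 0.1) {
  ifelse(p <= alpha, "significant",
         ifelse(p <= near, "nearly significant", "not significant"))
}

#' Distance-decay regression of dissimilarity on elevational distance
#'
#' Ordinary least squares of a chosen pairwise index on the absolute
#' elevation difference of the site pair (metres). Excluded pairs and pairs
#' with missing values are dropped. The slope `S` (dissimilarity per metre)
#' is the currency for cross-group comparison.
#'
#' @param beta a `pairwise_beta` table (observed indices) or `ses_table`
#'   (standardized indices).
#' @param sites site table with `site` and `elevation` columns covering all
#'   sites in `beta`.
#' @param index column to regress for a `pairwise_beta` input
#'   (`"beta_sor"`, `"beta_sim"`, `"beta_sne"`); for an `ses_table` input,
#'   the index id (`"sor"`, `"sim"`, `"sne"`) whose `ses` values are used.
#' @return list of class `decay_fit`: `slope`, `intercept`, `p_slope`
#'   (two-sided t-test), `r_squared`, `n_pairs`, `index`, and the `lm`
#'   object as `model`.
#' @export
distance_decay <- function(beta, sites, index = "beta_sor") {
  stopifnot(is.data.frame(beta), is.data.frame(sites),
            all(c("site", "elevation") %in% colnames(sites)))
  if (inherits(beta, "ses_table")) {
    sub <- beta[beta$index == sub("^beta_", "", index), , drop = FALSE]
    y <- sub$ses
    si <- sub$site_i
    sj <- sub$site_j
  } else {
    if (!index %in% colnames(beta))
      stop(sprintf("no column '%s' in the pairwise table", index), call. = FALSE)
    keep <- if ("excluded" %in% colnames(beta)) !beta$excluded else TRUE
    sub <- beta[keep, , drop = FALSE]
    y <- sub[[index]]
    si <- sub$site_i
    sj <- sub$site_j
  }
  elev <- stats::setNames(sites$elevation, sites$site)
  missing <- setdiff(unique(c(si, sj)), names(elev))
  if (length(missing))
    stop(sprintf("sites missing from the site table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  d <- abs(elev[si] - elev[sj])
  ok <- is.finite(y) & is.finite(d)
  y <- y[ok]
  d <- d[ok]
  if (length(y) < 3L) stop("need >= 3 computable pairs", call. = FALSE)
  if (stats::sd(d) == 0)
    stop("zero variance in elevational distances", call. = FALSE)
  fit <- stats::lm(y ~ d)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 p_slope = unname(sm$coefficients[2L, 4L]),
                 r_squared = sm$r.squared,
                 n_pairs = length(y), index = index, model = fit),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("distance decay of %s: S = %.3e per m, p = %.4g, r2 = %.3f (%d pairs)\n",
              x$index, x$slope, x$p_slope, x$r_squared, x$n_pairs))
  invisible(x)
}

#' Rank groups by their distance-decay slopes
#'
#' Groups whose slope is not significant at `alpha` are excluded from the
#' ranking and listed separately; the remainder are ranked by slope,
#' steepest first. Exact slope ties share a rank and keep input order.
#'
#' @param fits named list of [distance_decay()] fits, one per group.
#' @param alpha significance threshold for entering the ranking.
#' @return data.frame of class `slope_ranking`: `group`, `slope`,
#'   `slope_sci` (scientific notation, as conventionally reported),
#'   `p_slope`, `significant`, `rank` (NA for non-significant groups).
#' @export
compare_slopes <- function(fits, alpha = 0.05) {
  stopifnot(is.list(fits), length(fits) >= 2L, !is.null(names(fits)))
  df <- data.frame(
    group = names(fits),
    slope = vapply(fits, function(f) f$slope, numeric(1)),
    p_slope = vapply(fits, function(f) f$p_slope, numeric(1)),
    stringsAsFactors = FALSE)
  df$slope_sci <- formatC(df$slope, format = "e", digits = 2)
  df$significant <- df$p_slope <= alpha
  df$rank <- NA_integer_
  sig <- which(df$significant)
  if (length(sig)) {
    # rank by descending slope; ties share the smallest rank, stable order
    s <- df$slope[sig]
    df$rank[sig] <- as.integer(rank(-s, ties.method = "min"))
  }
  df <- df[, c("group", "slope", "slope_sci", "p_slope", "significant", "rank")]
  rownames(df) <- NULL
  attr(df, "alpha") <- alpha
  class(df) <- c("slope_ranking", "data.frame")
  df
}

#' @export
print.slope_ranking <- function(x, ...) {
  cat(sprintf("slope ranking (alpha = %g):\n", attr(x, "alpha")))
  ord <- order(is.na(x$rank), x$rank)
  print.data.frame(as.data.frame(x)[ord, ], digits = 4, row.names = FALSE)
  invisible(x)
}

#' Forward model selection by AIC
#'
#' Starting from the intercept-only model, greedily adds the candidate
#' predictor that most lowers `AIC = n log(RSS/n) + 2k` (k counts the
#' intercept and slopes), stopping when no addition lowers it. Exact AIC
#' ties are broken by input column order. Perfectly collinear candidates
#' (|r| = 1) are detected up front and the later column is dropped with a
#' warning.
#'
#' @param response numeric vector (e.g. a pairwise dissimilarity index).
#' @param predictors data.frame or matrix of candidate predictors, typically
#'   pairwise absolute differences of site-level environmental variables.
#' @return list of class `selected_model`: `predictors` (in selection
#'   order), `aic` (trajectory starting at the intercept-only model),
#'   `coefficients` of the final fit, `n`.
#' @export
forward_aic <- function(response, predictors) {
  y <- as.numeric(response)
  X <- as.data.frame(predictors)
  if (ncol(X) < 1L) stop("need at least one candidate predictor", call. = FALSE)
  ok <- is.finite(y) & Reduce(`&`, lapply(X, is.finite))
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  if (n < 3L) stop("need >= 3 complete observations", call. = FALSE)

  if (ncol(X) > 1L) {
    cm <- suppressWarnings(stats::cor(X))
    drop <- logical(ncol(X))
    for (j in 2:ncol(X)) for (i in 1:(j - 1L)) {
      if (!drop[i] && !drop[j] && is.finite(cm[i, j]) &&
          abs(cm[i, j]) >= 1 - 1e-12) {
        drop[j] <- TRUE
        warning(sprintf("dropping '%s': perfectly collinear with '%s'",
                        colnames(X)[j], colnames(X)[i]), call. = FALSE)
      }
    }
    X <- X[, !drop, drop = FALSE]
  }

  aic_of <- function(rss, k) n * log(rss / n) + 2 * k
  selected <- character(0)
  rss0 <- sum((y - mean(y))^2)
  trajectory <- aic_of(rss0, 1L)
  current <- trajectory
  remaining <- colnames(X)
  dat <- cbind(.y = y, X)
  while (length(remaining)) {
    cand_aic <- vapply(remaining, function(v) {
      f <- stats::as.formula(paste(".y ~",
                                   paste(c(selected, v), collapse = " + ")))
      fit <- stats::lm(f, data = dat)
      aic_of(sum(stats::residuals(fit)^2), length(stats::coef(fit)))
    }, numeric(1))
    best <- which.min(cand_aic) # ties: first in input order
    if (cand_aic[best] >= current) break
    selected <- c(selected, remaining[best])
    remaining <- setdiff(remaining, remaining[best])
    current <- cand_aic[best]
    trajectory <- c(trajectory, current)
  }
  coefs <- if (length(selected)) {
    stats::coef(stats::lm(stats::as.formula(
      paste(".y ~", paste(selected, collapse = " + "))), data = dat))
  } else c(`(Intercept)` = mean(y))
  structure(list(predictors = selected, aic = trajectory,
                 coefficients = coefs, n = n),
            class = "selected_model")
}

#' @export
print.selected_model <- function(x, ...) {
  if (length(x$predictors))
    cat(sprintf("forward AIC selected: %s (AIC %s)\n",
                paste(x$predictors, collapse = " + "),
                paste(sprintf("%.2f", x$aic), collapse = " -> ")))
  else cat(sprintf("forward AIC: intercept-only model retained (AIC %.2f)\n",
                   x$aic[1L]))
  invisible(x)
}

#' Interpolate site climate from the two elevation-nearest stations
#'
#' For each site elevation, finds the two weather stations nearest in
#' absolute elevation difference and linearly interpolates (or, outside
#' their span, extrapolates, flagged) each of AMT, AP and AMH along
#' elevation.
#'
#' @param stations station records as from [read_station_records()].
#' @param site_elevation numeric vector of site elevations (m).
#' @return data.frame with one row per site: `elevation`, `AMT`, `AP`,
#'   `AMH`, `extrapolated`.
#' @examples
#' st <- data.frame(station = c("low", "high"), elevation = c(2000, 3000),
#'                  AMT = c(10, 4), AP = c(900, 700), AMH = c(70, 60))
#' interpolate_station_climate(st, 2500)  # AMT 7, midway
#' @export
interpolate_station_climate <- function(stations, site_elevation) {
  stopifnot(is.data.frame(stations),
            all(c("elevation", "AMT", "AP", "AMH") %in% colnames(stations)))
  if (nrow(stations) < 2L) stop("need >= 2 stations", call. = FALSE)
  vars <- c("AMT", "AP", "AMH")
  out <- lapply(site_elevation, function(e) {
    d <- abs(stations$elevation - e)
    ord <- order(d, stations$elevation)
    s1 <- stations[ord[1L], ]
    s2 <- stations[ord[2L], ]
    if (s1$elevation == s2$elevation)
      stop("two nearest stations at identical elevation", call. = FALSE)
    w <- (e - s1$elevation) / (s2$elevation - s1$elevation)
    vals <- vapply(vars, function(v) s1[[v]] + w * (s2[[v]] - s1[[v]]),
                   numeric(1))
    c(elevation = e, vals,
      extrapolated = as.numeric(e < min(s1$elevation, s2$elevation) |
                                  e > max(s1$elevation, s2$elevation)))
  })
  df <- as.data.frame(do.call(rbind, out))
  df$extrapolated <- df$extrapolated > 0
  df
}
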