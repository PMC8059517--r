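# Pairwise absolute differences of site-level environmental variables,
# aligned with a pairwise table's (site_i, site_j) rows.
env_distance_columns <- function(beta, sites,
                                 vars = c("AMT", "AP", "AMH", "NPP", "PET")) {
  vars <- intersect(vars, colnames(sites))
  if (!length(vars)) return(NULL)
  out <- lapply(vars, function(v) {
    val <- stats::setNames(sites[[v]], sites$site)
    abs(val[beta$site_i] - val[beta$site_j])
  })
  df <- as.data.frame(stats::setNames(out, paste0("d", vars)))
  rownames(df) <- NULL
  df
}

# Wilcoxon comparison of two index columns, with the shared-pair subset rule.
compare_indices <- function(vals1, vals2, label, alpha = 0.05) {
  ok <- is.finite(vals1) & is.finite(vals2)
  w <- wilcoxon_z(vals1[ok], vals2[ok])
  data.frame(comparison = label, abs_z = w$abs_z, z = w$z, p = w$p,
             n1 = w$n1, n2 = w$n2,
             higher = if (w$z > 0) "first" else if (w$z < 0) "second" else "tie",
             decision = significance_label(w$p, alpha),
             stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' The file maps group names to either input file paths
#' (`matrix`, `sites`, `tree`, `traits`) or a `simulate:` block of
#' [simulation_config()] fields, plus optional top-level `dimensions`,
#' `n_rand`, `min_richness`, `alpha`, `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return list of arguments suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$groups) || !length(cfg$groups))
    stop("config must define at least one group under `groups:`", call. = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  groups <- lapply(cfg$groups, function(g) {
    if (!is.null(g$simulate)) {
      sim <- g$simulate
      if (is.null(sim$seed)) sim$seed <- cfg$seed
      ds <- simulate_metacommunity(do.call(simulation_config, sim))
      list(community = ds$community, sites = ds$sites, tree = ds$tree,
           traits = ds$traits)
    } else {
      list(community = read_community_matrix(resolve(g$matrix)),
           sites = if (!is.null(g$sites)) read_site_table(resolve(g$sites)),
           tree = if (!is.null(g$tree))
             read_newick(resolve(g$tree), multi = isTRUE(g$multi_tree)),
           traits = if (!is.null(g$traits)) read_trait_table(resolve(g$traits)))
    }
  })
  c(list(groups = groups),
    cfg[intersect(names(cfg), c("dimensions", "n_rand", "min_richness",
                                "alpha", "seed", "out_dir", "shared_subset"))])
}

#' Run the full comparative beta-diversity workflow
#'
#' For each species group: observed pairwise tables in up to three
#' dimensions; null-model standardized effect sizes; within-dimension
#' turnover-vs-nestedness rank-sum comparisons; cross-dimension comparisons
#' of each component; distance-decay fits of observed and standardized
#' indices; and forward-AIC selection of environmental-distance predictors.
#' Across groups, distance-decay slopes of the significant fits are ranked.
#' Cross-dimension comparisons involving the functional dimension are
#' restricted to pairs computable in both compared dimensions (the
#' >= `min_richness` subset), applied to both sides for fairness; set
#' `shared_subset = FALSE` to compare each dimension on its own full subset.
#'
#' @param groups named list; each element a list with `community`
#'   (a [community_matrix]), `sites` (site table), and optionally `tree`
#'   (`phylo`, or list of `phylo` for a tree distribution) and `traits`
#'   (trait matrix). Alternatively pass `config =` a YAML path.
#' @param config optional YAML config path; overrides `groups`.
#' @param dimensions which dimensions to compute; dimensions lacking inputs
#'   in any group cause an upfront validation error.
#' @param min_richness functional minimum community size.
#' @param n_rand null randomizations per SES table.
#' @param seed mandatory master seed; per-group/dimension sub-seeds are
#'   derived from it.
#' @param alpha significance threshold; p in (alpha, 0.1] is labelled
#'   "nearly significant".
#' @param shared_subset use the shared computable-pair subset in
#'   cross-dimension comparisons.
#' @param out_dir when given, all tables, a human-readable `summary.txt`
#'   and a run `manifest.yaml` are written there.
#' @param burnin,thin swap-null tuning (see [randomize()]).
#' @return list of class `report_bundle`: per-group results (`beta`, `ses`,
#'   `component_tests`, `dimension_tests`, `decay`, `aic`), cross-group
#'   `slope_rankings`, `summary` (character lines) and `manifest`.
#' @export
run_pipeline <- function(groups = NULL, config = NULL,
                         dimensions = c("taxonomic", "phylogenetic", "functional"),
                         min_richness = 3, n_rand = 199, seed,
                         alpha = 0.05, shared_subset = TRUE, out_dir = NULL,
                         burnin = 10000, thin = 1000) {
  if (!is.null(config)) {
    args <- read_pipeline_config(config)
    args$config <- NULL
    return(do.call(run_pipeline, utils::modifyList(
      args, Filter(Negate(is.null),
                   list(out_dir = out_dir,
                        seed = if (!missing(seed)) seed)))))
  }
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  dimensions <- match.arg(dimensions, several.ok = TRUE)

  # validate every group's inputs before any computation
  for (g in names(groups)) {
    gr <- groups[[g]]
    if (!inherits(gr$community, "community_matrix"))
      stop(sprintf("group '%s': `community` must be a community_matrix", g),
           call. = FALSE)
    if ("phylogenetic" %in% dimensions && is.null(gr$tree))
      stop(sprintf("group '%s': phylogenetic dimension enabled but no tree", g),
           call. = FALSE)
    if ("functional" %in% dimensions && is.null(gr$traits))
      stop(sprintf("group '%s': functional dimension enabled but no traits", g),
           call. = FALSE)
    if (!is.null(gr$sites) &&
        length(setdiff(sites(gr$community), gr$sites$site)))
      stop(sprintf("group '%s': site table does not cover the matrix sites", g),
           call. = FALSE)
  }

  summary_lines <- character(0)
  say <- function(fmt, ...) summary_lines <<- c(summary_lines, sprintf(fmt, ...))
  results <- list()
  failures <- character(0)

  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    gr <- groups[[g]]
    res <- tryCatch({
      say("== group %s ==", g)
      beta <- list()
      ses <- list()
      tspace <- NULL
      if ("taxonomic" %in% dimensions)
        beta$taxonomic <- beta_matrix_taxonomic(gr$community)
      if ("phylogenetic" %in% dimensions)
        beta$phylogenetic <- if (is.list(gr$tree) && !inherits(gr$tree, "phylo"))
          multi_tree_summary(gr$community, gr$tree)
        else beta_matrix_phylo(gr$community, gr$tree)
      if ("functional" %in% dimensions) {
        tspace <- build_trait_space(gr$traits)
        beta$functional <- beta_matrix_functional(gr$community, tspace,
                                                  min_richness = min_richness)
      }

      # SES per dimension (sub-seed derived per group x dimension)
      for (di in seq_along(dimensions)) {
        dm <- dimensions[di]
        one_tree <- if (is.list(gr$tree) && !inherits(gr$tree, "phylo"))
          gr$tree[[1L]] else gr$tree
        ses[[dm]] <- ses_beta(gr$community, dimension = dm, n_rand = n_rand,
                              seed = derive_seed(seed, gi * 10 + di),
                              tree = one_tree, trait_space = tspace,
                              min_richness = min_richness,
                              burnin = burnin, thin = thin)
      }

      # level 1: turnover vs nestedness within each dimension
      comp <- do.call(rbind, lapply(names(beta), function(dm) {
        b <- beta[[dm]]
        r <- compare_indices(b$beta_sim, b$beta_sne,
                             sprintf("%s: sim vs sne", dm), alpha)
        r$level <- "component"; r$dimension <- dm; r
      }))
      for (k in seq_len(nrow(comp)))
        say("  %s: |z| = %.3f, p = %.4g (%s; higher: %s)", comp$comparison[k],
            comp$abs_z[k], comp$p[k], comp$decision[k], comp$higher[k])

      # level 2: each component across dimension pairs
      dim_tests <- NULL
      if (length(beta) >= 2L) {
        pairs <- utils::combn(names(beta), 2L, simplify = FALSE)
        dim_tests <- do.call(rbind, lapply(pairs, function(pr) {
          b1 <- beta[[pr[1L]]]; b2 <- beta[[pr[2L]]]
          keep <- if (shared_subset) !b1$excluded & !b2$excluded
                  else rep(TRUE, nrow(b1))
          do.call(rbind, lapply(c("beta_sim", "beta_sne", "beta_sor"),
            function(ix) {
              r <- compare_indices(b1[[ix]][keep], b2[[ix]][keep],
                                   sprintf("%s: %s vs %s", ix, pr[1L], pr[2L]),
                                   alpha)
              r$level <- "dimension"; r$dimension <- paste(pr, collapse = "/")
              r
            }))
        }))
      }

      # level 3 inputs: distance-decay fits (observed + SES)
      decay <- NULL
      aic <- list()
      if (!is.null(gr$sites)) {
        fits <- list()
        for (dm in names(beta)) for (ix in c("beta_sim", "beta_sne", "beta_sor")) {
          f <- tryCatch(distance_decay(beta[[dm]], gr$sites, ix),
                        error = function(e) NULL)
          if (!is.null(f))
            fits[[paste(dm, ix, sep = ".")]] <-
              data.frame(dimension = dm, index = ix, kind = "observed",
                         slope = f$slope, p_slope = f$p_slope,
                         r_squared = f$r_squared, n_pairs = f$n_pairs)
        }
        for (dm in names(ses)) for (ix in c("sim", "sne", "sor")) {
          f <- tryCatch(distance_decay(ses[[dm]], gr$sites, ix),
                        error = function(e) NULL)
          if (!is.null(f))
            fits[[paste("ses", dm, ix, sep = ".")]] <-
              data.frame(dimension = dm, index = ix, kind = "ses",
                         slope = f$slope, p_slope = f$p_slope,
                         r_squared = f$r_squared, n_pairs = f$n_pairs)
        }
        decay <- do.call(rbind, fits)
        if (!is.null(decay)) rownames(decay) <- NULL

        # forward AIC on environmental distances, per observed index
        for (dm in names(beta)) {
          env <- env_distance_columns(beta[[dm]], gr$sites)
          if (!is.null(env)) {
            keep <- !beta[[dm]]$excluded
            for (ix in c("beta_sim", "beta_sne", "beta_sor")) {
              sel <- tryCatch(
                forward_aic(beta[[dm]][[ix]][keep], env[keep, , drop = FALSE]),
                error = function(e) NULL)
              if (!is.null(sel)) aic[[paste(dm, ix, sep = ".")]] <- sel
            }
          }
        }
      }

      list(beta = beta, ses = ses, trait_space = tspace,
           component_tests = comp, dimension_tests = dim_tests,
           decay = decay, aic = aic)
    }, error = function(e) {
      failures <<- c(failures, sprintf("group '%s' failed: %s", g,
                                       conditionMessage(e)))
      NULL
    })
    results[[g]] <- res
  }

  ok_groups <- names(results)[!vapply(results, is.null, logical(1))]
  if (!length(ok_groups))
    stop(paste(c("every group failed:", failures), collapse = "\n"),
         call. = FALSE)
  for (f in failures) say("WARNING: %s", f)

  # cross-group slope rankings for each dimension x observed index
  slope_rankings <- list()
  if (length(ok_groups) >= 2L) {
    for (dm in dimensions) for (ix in c("beta_sim", "beta_sor")) {
      fits <- list()
      for (g in ok_groups) {
        gr <- groups[[g]]
        b <- results[[g]]$beta[[dm]]
        if (is.null(b) || is.null(gr$sites)) next
        f <- tryCatch(distance_decay(b, gr$sites, ix), error = function(e) NULL)
        if (!is.null(f)) fits[[g]] <- f
      }
      if (length(fits) >= 2L) {
        rk <- compare_slopes(fits, alpha)
        slope_rankings[[paste(dm, ix, sep = ".")]] <- rk
        top <- rk[!is.na(rk$rank) & rk$rank == 1L, ]
        if (nrow(top))
          say("  steepest %s %s decay: %s (S = %s)", dm, ix,
              paste(top$group, collapse = ", "),
              paste(top$slope_sci, collapse = ", "))
      }
    }
  }

  settings <- list(dimensions = dimensions, min_richness = min_richness,
                   n_rand = n_rand, seed = as.integer(seed), alpha = alpha,
                   shared_subset = shared_subset,
                   groups = lapply(groups, function(gr)
                     list(sites = sites(gr$community),
                          species = species(gr$community))))
  tf <- tempfile(fileext = ".yaml")
  yaml::write_yaml(settings, tf)
  manifest <- list(package = "elevbeta",
                   version = as.character(utils::packageVersion("elevbeta")),
                   seed = as.integer(seed),
                   config_hash = unname(tools::md5sum(tf)))
  unlink(tf)

  bundle <- structure(list(groups = results,
                           slope_rankings = slope_rankings,
                           summary = summary_lines,
                           manifest = manifest),
                      class = "report_bundle")
  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle\n")
  cat(paste0("  ", x$summary, collapse = "\n"), "\n")
  invisible(x)
}

# Flatten a bundle into tidy CSVs + summary + manifest.
write_report_bundle <- function(bundle, out_dir) {
  tables <- list()
  for (g in names(bundle$groups)) {
    res <- bundle$groups[[g]]
    if (is.null(res)) next
    for (dm in names(res$beta))
      tables[[sprintf("%s_beta_%s", g, dm)]] <- res$beta[[dm]]
    for (dm in names(res$ses))
      tables[[sprintf("%s_ses_%s", g, dm)]] <- res$ses[[dm]]
    if (!is.null(res$component_tests))
      tables[[sprintf("%s_component_tests", g)]] <- res$component_tests
    if (!is.null(res$dimension_tests))
      tables[[sprintf("%s_dimension_tests", g)]] <- res$dimension_tests
    if (!is.null(res$decay))
      tables[[sprintf("%s_distance_decay", g)]] <- res$decay
  }
  for (nm in names(bundle$slope_rankings))
    tables[[paste0("slope_ranking_", gsub("\\.", "_", nm))]] <-
      bundle$slope_rankings[[nm]]
  write_results(tables, out_dir)
  writeLines(bundle$summary, file.path(out_dir, "summary.txt"))
  yaml::write_yaml(bundle$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
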