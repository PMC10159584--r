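# Full-study orchestration: diversity -> assembly -> phylogenetic signal ->
# contrast correlations -> slopes -> GMYC substructure control -> rerun.

#' Run the full analysis on a study directory
#'
#' The directory must contain `alignments/` (one FASTA per species),
#' `traits.csv` (or `.tsv`) and `species_tree.nwk`; `gene_trees/` is
#' optional and, when present, triggers the substructure-controlled rerun:
#' each species' ultrametric gene tree is fitted with the single-threshold
#' GMYC model, species splitting into multiple clusters have their diversity
#' re-estimated from the largest cluster, and the correlation battery is
#' rerun on the revised estimates.
#'
#' @param study_dir Study directory.
#' @param out_dir Where to write report CSV/JSON (default
#'   `study_dir/results`; `NULL` to skip writing).
#' @param n_perm Tip-label permutations for the lambda tests (0 = LRT only).
#' @inheritParams genetic_code
#' @param log_base Log base for the assembly stage.
#' @param seed Seed for the (optional) lambda permutations.
#' @param verbose Emit per-stage messages?
#' @return A `study_report` object: list with `descriptives`, `table1`
#'   (lambda fits), `table2` (contrast correlations), `slopes`,
#'   `multiple_regression`, `gmyc_summary`, `rerun_table2`, `exclusions`.
#' @export
run_study <- function(study_dir, out_dir = file.path(study_dir, "results"),
                      n_perm = 0L, code = "vertebrate_mito", log_base = 10,
                      seed = 1L, verbose = TRUE) {
  say <- function(...) if (verbose) message("[mitodiv] ", ...)
  aln_dir <- file.path(study_dir, "alignments")
  tree_file <- file.path(study_dir, "species_tree.nwk")
  trait_file <- file.path(study_dir, "traits.csv")
  if (!file.exists(trait_file)) {
    trait_file <- file.path(study_dir, "traits.tsv")
  }
  if (!dir.exists(aln_dir) || !file.exists(tree_file) ||
    !file.exists(trait_file)) {
    stop_format(paste0(
      "study directory must contain alignments/, species_tree.nwk and ",
      "traits.csv"
    ))
  }
  gt_dir <- file.path(study_dir, "gene_trees")
  has_gmyc <- dir.exists(gt_dir) &&
    length(list.files(gt_dir, "\\.nwk$")) > 0

  say("stage diversity: estimating piS/piN per species")
  div <- diversity_table(aln_dir, code = code)

  say("stage assemble: joining traits and tree")
  traits <- read_trait_table(trait_file)
  sp_tree <- read_tree(tree_file)
  dataset <- assemble_dataset(div, traits, sp_tree, log_base = log_base)
  desc <- report_descriptives(dataset)

  say("stage lambda: phylogenetic signal (", nrow(dataset$data),
      " species)")
  table1 <- lambda_table(dataset, n_perm = n_perm, seed = seed)

  say("stage contrasts: correlation battery")
  table2 <- contrast_correlations(dataset)

  say("stage slopes: through-origin regressions on range")
  slopes <- slope_report(dataset)
  multi <- tryCatch(
    multiple_regression(dataset),
    mitodiv_error = function(e) NULL
  )

  gmyc_summary <- tibble()
  rerun_table2 <- tibble()
  if (has_gmyc) {
    say("stage gmyc: substructure control")
    gm <- gmyc_stage(study_dir, div, code = code)
    gmyc_summary <- gm$summary
    rerun <- tryCatch(
      assemble_dataset(gm$revised, traits, sp_tree, log_base = log_base),
      mitodiv_insufficient_data = function(e) NULL
    )
    if (!is.null(rerun)) {
      rerun_table2 <- contrast_correlations(rerun)
    }
  }

  report <- structure(
    list(
      descriptives = desc, table1 = table1, table2 = table2,
      slopes = slopes, multiple_regression = multi,
      gmyc_summary = gmyc_summary, rerun_table2 = rerun_table2,
      exclusions = dataset$exclusions, dataset = dataset
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Descriptive summary of an assembled dataset
#'
#' @param dataset A `species_dataset`.
#' @return One-row tibble: species counts, min/median/max individuals,
#'   exclusion tallies.
#' @export
report_descriptives <- function(dataset) {
  d <- dataset$data
  excl <- dataset$exclusions
  tibble(
    n_species = nrow(d),
    n_excluded = nrow(excl),
    n_excluded_zero_diversity = sum(excl$reason == "zero-diversity"),
    n_excluded_no_tree = sum(excl$reason == "no-tree"),
    n_excluded_no_traits = sum(excl$reason == "no-traits"),
    min_individuals = min(d$n_individuals),
    median_individuals = median(d$n_individuals),
    max_individuals = max(d$n_individuals),
    median_pi_s = median(d$pi_s),
    median_ratio = median(d$ratio, na.rm = TRUE)
  )
}

#' Through-origin slopes of the diversity responses on log range
#'
#' @param dataset A `species_dataset`.
#' @param predictor Predictor log-variable (default `log_range_km2`).
#' @return Tibble: response, slope, se, p, n, pct_per_doubling.
#' @export
slope_report <- function(dataset, predictor = "log_range_km2") {
  purrr::map_dfr(c("log_pi_s", "log_ratio"), function(resp) {
    cp <- tryCatch(contrast_pair(dataset, predictor, resp),
                   mitodiv_insufficient_data = function(e) NULL)
    if (is.null(cp)) {
      return(tibble(
        response = resp, predictor = predictor, slope = NA_real_,
        se = NA_real_, p = NA_real_, n = NA_integer_,
        pct_per_doubling = NA_real_
      ))
    }
    fit <- origin_regression(cp$y, cp$x, y_name = resp)
    tibble(
      response = resp, predictor = predictor, slope = fit$slopes[1],
      se = fit$slope_se[1], p = fit$p_values[1], n = fit$n,
      pct_per_doubling = percent_change_per_doubling(fit$slopes[1])
    )
  })
}

#' Multiple through-origin regression of piS contrasts
#'
#' Default predictors are range and clutch size.
#'
#' @param dataset A `species_dataset`.
#' @param response Response log-variable.
#' @param predictors Predictor log-variables.
#' @return An `origin_regression`.
#' @export
multiple_regression <- function(dataset, response = "log_pi_s",
                                predictors = c("log_range_km2",
                                               "log_clutch_size")) {
  d <- dataset$data
  need <- c(response, predictors)
  keep <- d$species_id[rowSums(is.na(d[, need, drop = FALSE])) == 0]
  if (length(keep) < length(predictors) + 3L) {
    stop_insufficient("too few complete species for multiple regression")
  }
  tree <- resolve_tree(ape::keep.tip(dataset$tree, keep))
  dd <- d[match(tree$tip.label, d$species_id), ]
  getc <- function(v) {
    compute_contrasts(setNames(dd[[v]], dd$species_id), tree,
                      trait_name = v)
  }
  origin_regression(
    getc(response), setNames(purrr::map(predictors, getc), predictors),
    y_name = response
  )
}

# GMYC stage over all species with gene trees; returns the per-species
# digest and the revised diversity table (largest-cluster re-estimates for
# species splitting into > 1 cluster, originals otherwise).
gmyc_stage <- function(study_dir, div, code = "vertebrate_mito",
                       alpha = 0.05) {
  gt_dir <- file.path(study_dir, "gene_trees")
  aln_dir <- file.path(study_dir, "alignments")
  files <- sort(list.files(gt_dir, "\\.nwk$", full.names = TRUE))
  revised <- div
  rows <- purrr::map_dfr(files, function(f) {
    sp <- sub("\\.nwk$", "", basename(f))
    tr <- tryCatch(read_tree(f), mitodiv_error = function(e) NULL)
    if (is.null(tr) || ape::Ntip(tr) < 4L || !is_ultrametric(tr)) {
      return(tibble(
        species_id = sp, n_tips = if (is.null(tr)) NA_integer_ else
          ape::Ntip(tr),
        n_clusters = NA_integer_, threshold_time = NA_real_,
        lrt = NA_real_, p = NA_real_, largest_cluster_size = NA_integer_,
        reestimated = FALSE, reason = "tree-unusable"
      ))
    }
    fit <- tryCatch(fit_gmyc(tr, tree_id = sp),
                    mitodiv_error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(
        species_id = sp, n_tips = ape::Ntip(tr), n_clusters = NA_integer_,
        threshold_time = NA_real_, lrt = NA_real_, p = NA_real_,
        largest_cluster_size = NA_integer_, reestimated = FALSE,
        reason = "fit-failed"
      ))
    }
    keep <- largest_cluster(fit)
    split_up <- fit$n_clusters > 1L && (is.null(alpha) || fit$p < alpha)
    reest <- FALSE
    reason <- "single-cluster"
    if (split_up) {
      aln_file <- file.path(aln_dir, paste0(sp, ".fasta"))
      if (length(keep) >= 2L && file.exists(aln_file)) {
        aln <- read_alignment(aln_file)
        new_est <- tryCatch(
          reestimate_diversity(aln, keep, code = code),
          mitodiv_error = function(e) NULL
        )
        if (!is.null(new_est)) {
          revised[revised$species_id == sp, ] <<- new_est
          reest <- TRUE
          reason <- "largest-cluster"
        } else {
          reason <- "reestimate-failed"
        }
      } else {
        reason <- "cluster-too-small"
      }
    }
    tibble(
      species_id = sp, n_tips = ape::Ntip(tr),
      n_clusters = fit$n_clusters, threshold_time = fit$threshold_time,
      lrt = fit$lrt_stat, p = fit$p,
      largest_cluster_size = length(keep), reestimated = reest,
      reason = reason
    )
  })
  list(summary = rows, revised = revised)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$table1, file.path(out_dir, "table1_lambda.csv"))
  readr::write_csv(report$table2,
                   file.path(out_dir, "table2_correlations.csv"))
  readr::write_csv(report$slopes, file.path(out_dir, "slopes.csv"))
  readr::write_csv(report$descriptives,
                   file.path(out_dir, "descriptives.csv"))
  readr::write_csv(report$exclusions, file.path(out_dir, "exclusions.csv"))
  if (nrow(report$gmyc_summary)) {
    readr::write_csv(report$gmyc_summary, file.path(out_dir, "gmyc.csv"))
    readr::write_csv(report$rerun_table2,
                     file.path(out_dir, "table2_largest_cluster.csv"))
  }
  js <- list(
    descriptives = report$descriptives,
    slopes = report$slopes,
    multiple_regression = if (!is.null(report$multiple_regression)) {
      tidy(report$multiple_regression)
    }
  )
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  species: ", x$descriptives$n_species, " retained (",
      x$descriptives$n_excluded, " excluded); individuals ",
      x$descriptives$min_individuals, "/",
      x$descriptives$median_individuals, "/",
      x$descriptives$max_individuals, " (min/median/max)\n", sep = "")
  sl <- x$slopes
  for (i in seq_len(nrow(sl))) {
    cat(sprintf(
      "  %s ~ %s: slope %.3f (%.3f), %+.1f%% per doubling, n = %d\n",
      sl$response[i], sl$predictor[i], sl$slope[i], sl$se[i],
      sl$pct_per_doubling[i], sl$n[i]
    ))
  }
  if (nrow(x$gmyc_summary)) {
    cat("  gmyc: ", sum(x$gmyc_summary$reestimated),
        " of ", nrow(x$gmyc_summary),
        " species re-estimated from their largest cluster\n", sep = "")
  }
  invisible(x)
}
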