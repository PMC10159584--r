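# broom-style tidiers for the fitted objects.

#' Tidy a Pagel's lambda fit
#' @param x A `lambda_fit`.
#' @param ... Unused.
#' @return One-row tibble of estimates and test results.
#' @method tidy lambda_fit
#' @export
tidy.lambda_fit <- function(x, ...) {
  tibble(
    trait = x$trait_name, lambda = x$lambda_hat,
    loglik = x$loglik_hat, loglik_lambda0 = x$loglik_lambda0,
    lrt = x$lrt_stat, p_lrt = x$p_lrt, p_perm = x$p_perm
  )
}

#' @rdname tidy.lambda_fit
#' @method glance lambda_fit
#' @export
glance.lambda_fit <- function(x, ...) {
  tibble(n_species = x$n_species, n_perm = x$n_perm)
}

#' Tidy a through-origin regression
#' @param x An `origin_regression`.
#' @param ... Unused.
#' @return Tibble with one row per predictor: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy origin_regression
#' @export
tidy.origin_regression <- function(x, ...) {
  tibble(
    term = x$predictor_names, estimate = x$slopes,
    std.error = x$slope_se, statistic = x$t_values, p.value = x$p_values
  )
}

#' @rdname tidy.origin_regression
#' @method glance origin_regression
#' @export
glance.origin_regression <- function(x, ...) {
  tibble(
    r.squared = x$r_squared, sigma = x$sigma, n = x$n,
    df.residual = x$df_residual
  )
}

#' Tidy a GMYC fit
#' @param x A `gmyc_fit`.
#' @param ... Unused.
#' @return One-row tibble with the threshold, cluster count and test.
#' @method tidy gmyc_fit
#' @export
tidy.gmyc_fit <- function(x, ...) {
  tibble(
    tree_id = x$tree_id, threshold_time = x$threshold_time,
    n_clusters = x$n_clusters, n_singletons = x$n_singletons,
    loglik_mixed = x$loglik_mixed, loglik_null = x$loglik_null,
    lrt = x$lrt_stat, p = x$p,
    rate_yule = x$rate_yule, rate_coal = x$rate_coal
  )
}

#' @rdname tidy.gmyc_fit
#' @method glance gmyc_fit
#' @export
glance.gmyc_fit <- function(x, ...) {
  tibble(n_tips = x$n_tips, root_age = x$root_age)
}

#' Tidy a study report
#'
#' Returns the correlation battery (the Table-2-style block), with the
#' substructure-controlled rerun stacked underneath when present.
#'
#' @param x A `study_report`.
#' @param ... Unused.
#' @method tidy study_report
#' @export
tidy.study_report <- function(x, ...) {
  out <- mutate(x$table2, analysis = "all-individuals")
  if (nrow(x$rerun_table2)) {
    out <- bind_rows(
      out, mutate(x$rerun_table2, analysis = "largest-cluster")
    )
  }
  out
}

#' @rdname tidy.study_report
#' @method glance study_report
#' @export
glance.study_report <- function(x, ...) {
  x$descriptives
}
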