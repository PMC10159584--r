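# Phylogenetic signal (Pagel's lambda), Felsenstein independent contrasts,
# and through-origin correlation/regression of contrasts. Contrast
# regressions are forced through the origin (the Garland convention: a
# contrast's sign is arbitrary, so an intercept has no meaning).

# Brownian covariance of tips with off-diagonals scaled by lambda.
.lambda_cov <- function(V, lam) {
  C <- lam * V
  diag(C) <- diag(V)
  C
}

# Profiled BM log-likelihood given a tip covariance matrix.
.bm_loglik_C <- function(x, C) {
  n <- length(x)
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) {
    stop_mitodiv(
      paste0(
        "singular tip covariance (duplicate zero-distance tips at ",
        "lambda = 1?); add epsilon branch lengths"
      ),
      "mitodiv_singular_cov"
    )
  }
  logdet <- 2 * sum(log(diag(R)))
  one <- rep(1, n)
  Ci_x <- backsolve(R, forwardsolve(t(R), x))
  Ci_1 <- backsolve(R, forwardsolve(t(R), one))
  mu <- sum(Ci_x) / sum(Ci_1)
  r <- x - mu
  q <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  sig2 <- q / n
  -0.5 * (n * log(2 * pi * sig2) + logdet + n)
}

#' Brownian-motion log-likelihood under a Pagel's-lambda transform
#'
#' Log-likelihood of tip values under Brownian motion whose tip covariance
#' is the shared-path-length matrix with all off-diagonal entries multiplied
#' by `lam`; the ancestral mean and the rate sigma^2 are profiled out at
#' their conditional maximum-likelihood values.
#'
#' @param values Named numeric vector of tip values (names = tip labels).
#' @param tree `ape::phylo` with branch lengths.
#' @param lam Pagel's lambda in \[0, 1\].
#' @return Log-likelihood (numeric scalar).
#' @export
bm_loglik <- function(values, tree, lam) {
  stopifnot(lam >= 0, lam <= 1)
  tree <- validate_tree(tree)
  if (!all(tree$tip.label %in% names(values)) ||
    length(values) != ape::Ntip(tree)) {
    stop_format("tip labels of tree and names of values must coincide")
  }
  V <- ape::vcv(tree)
  x <- values[rownames(V)]
  .bm_loglik_C(x, .lambda_cov(V, lam))
}

#' Fit Pagel's lambda by maximum likelihood
#'
#' Bounded scalar optimization of [bm_loglik()] over \[0, 1\] (three starts
#' at 0.05/0.5/0.95, tolerance 1e-6). The likelihood-ratio test against
#' lambda = 0 uses the boundary-corrected p-value 0.5 P(chi2_1 >= LRT);
#' optionally a permutation p-value from `n_perm` random tip-label shuffles
#' is computed, whose smallest attainable value is 1 / (1 + n_perm).
#'
#' @inheritParams bm_loglik
#' @param n_perm Number of tip-label permutations (0 = skip).
#' @param trait_name Label carried into the result.
#' @param seed Seed for the permutations.
#' @return A `lambda_fit` object; see [tidy.lambda_fit()].
#' @export
fit_lambda <- function(values, tree, n_perm = 0L, trait_name = "trait",
                       seed = NULL) {
  tree <- validate_tree(tree)
  keep <- names(values)[!is.na(values)]
  keep <- intersect(tree$tip.label, keep)
  if (length(keep) < 4L) {
    stop_insufficient("need at least 4 non-missing tips to fit lambda")
  }
  if (length(keep) < 10L) {
    warn("fewer than 10 tips: lambda estimates will be unstable")
  }
  tree <- ape::keep.tip(tree, keep)
  V <- ape::vcv(tree)
  x <- values[rownames(V)]

  profile <- function(x) {
    nll <- function(l) -.bm_loglik_C(x, .lambda_cov(V, l))
    fits <- purrr::map(c(0.05, 0.5, 0.95), function(s) {
      nlminb(s, nll, lower = 0, upper = 1,
             control = list(abs.tol = 1e-10, rel.tol = 1e-8))
    })
    best <- fits[[which.min(purrr::map_dbl(fits, "objective"))]]
    list(lambda = min(max(best$par, 0), 1), loglik = -best$objective)
  }

  fit <- profile(x)
  ll0 <- .bm_loglik_C(x, .lambda_cov(V, 0))
  lrt <- max(2 * (fit$loglik - ll0), 0)
  p_lrt <- min(0.5 * pchisq(lrt, df = 1, lower.tail = FALSE) + 0, 1)
  if (lrt == 0) p_lrt <- 1

  p_perm <- NA_real_
  if (n_perm > 0L) {
    gain_obs <- fit$loglik - ll0
    gains <- withr::with_seed(seed %||% 1L, {
      purrr::map_dbl(seq_len(n_perm), function(i) {
        xp <- setNames(sample(x), names(x))
        fp <- profile(xp)
        fp$loglik - .bm_loglik_C(xp, .lambda_cov(V, 0))
      })
    })
    p_perm <- (1 + sum(gains >= gain_obs)) / (1 + n_perm)
  }

  structure(
    list(
      trait_name = trait_name, lambda_hat = fit$lambda,
      loglik_hat = fit$loglik, loglik_lambda0 = ll0, lrt_stat = lrt,
      p_lrt = p_lrt, p_perm = p_perm, n_perm = as.integer(n_perm),
      n_species = length(x)
    ),
    class = "lambda_fit"
  )
}

#' @export
print.lambda_fit <- function(x, ...) {
  cat(
    "<lambda_fit> ", x$trait_name, ": lambda = ",
    formatC(x$lambda_hat, digits = 3, format = "fg"),
    ", LRT = ", formatC(x$lrt_stat, digits = 3, format = "fg"),
    ", p(LRT) = ", format.pval(x$p_lrt, digits = 3),
    if (!is.na(x$p_perm)) paste0(", p(perm) = ", x$p_perm) else "",
    ", n = ", x$n_species, "\n",
    sep = ""
  )
  invisible(x)
}

# Resolve polytomies deterministically (tip-label order) and pad zero branch
# lengths with a relative epsilon so contrast variances stay positive.
resolve_tree <- function(tree, eps_rel = 1e-8) {
  tree <- ape::multi2di(tree, random = FALSE)
  depth <- max(ape::node.depth.edgelength(tree))
  if (depth <= 0) stop_format("tree has zero depth")
  tree$edge.length[tree$edge.length <= 0] <- eps_rel * depth
  tree
}

#' Phylogenetically independent contrasts
#'
#' Standardized Felsenstein contrasts of one trait. Polytomies are resolved
#' deterministically (by tip-label order) with zero-length branches padded by
#' 1e-8 x tree depth; a binary n-tip tree yields exactly n - 1 contrasts.
#'
#' @inheritParams bm_loglik
#' @param trait_name Label carried into the result.
#' @return Tibble with columns `node` (internal node id) and `contrast`;
#'   attribute `trait_name`.
#' @export
compute_contrasts <- function(values, tree, trait_name = "trait") {
  tree <- validate_tree(tree)
  keep <- intersect(tree$tip.label, names(values)[!is.na(values)])
  if (length(keep) < 3L) {
    stop_insufficient("need at least 3 tips for contrasts")
  }
  tree <- resolve_tree(ape::keep.tip(tree, keep))
  pic <- ape::pic(values[tree$tip.label], tree, scaled = TRUE)
  out <- tibble(node = as.integer(names(pic)), contrast = unname(pic))
  attr(out, "trait_name") <- trait_name
  out
}

.contrast_pair <- function(x, y) {
  if (is.data.frame(x) && is.data.frame(y)) {
    j <- dplyr::inner_join(x, y, by = "node",
                           suffix = c("_x", "_y"))
    if (nrow(j) != nrow(x) || nrow(j) != nrow(y)) {
      stop_format("contrast sets must share the same node set")
    }
    list(x = j$contrast_x, y = j$contrast_y)
  } else {
    if (length(x) != length(y)) stop_format("contrast lengths differ")
    list(x = as.numeric(x), y = as.numeric(y))
  }
}

#' Through-origin correlation of two contrast sets
#'
#' r = sum(xy) / sqrt(sum(x^2) sum(y^2)), the Pearson correlation
#' constrained through the origin; p from t = r sqrt((n-1)/(1-r^2)) on n - 1
#' degrees of freedom. The Spearman correlation is computed on positivized
#' pairs (each pair jointly sign-flipped so the x contrast is non-negative),
#' since ranks are not invariant to the arbitrary sign of a contrast.
#'
#' @param x,y Contrast tibbles from [compute_contrasts()] (joined on node)
#'   or plain numeric vectors.
#' @param spearman Also compute Spearman's rank correlation?
#' @param x_name,y_name Labels (default from attributes).
#' @return One-row tibble: `x_name`, `y_name`, `n`, `r`, `p`, `r_spearman`,
#'   `p_spearman`.
#' @export
origin_correlation <- function(x, y, spearman = TRUE,
                               x_name = NULL, y_name = NULL) {
  x_name <- x_name %||% attr(x, "trait_name") %||% "x"
  y_name <- y_name %||% attr(y, "trait_name") %||% "y"
  p <- .contrast_pair(x, y)
  n <- length(p$x)
  if (n < 3L) stop_insufficient("need at least 3 contrast pairs")
  sxx <- sum(p$x^2)
  syy <- sum(p$y^2)
  if (sxx == 0 || syy == 0) {
    stop_mitodiv("zero variance in a contrast set", "mitodiv_degenerate")
  }
  r <- sum(p$x * p$y) / sqrt(sxx * syy)
  r <- min(max(r, -1), 1)
  tstat <- r * sqrt((n - 1) / max(1 - r^2, .Machine$double.eps))
  pval <- 2 * pt(-abs(tstat), df = n - 1)

  r_s <- NA_real_
  p_s <- NA_real_
  if (spearman) {
    flip <- ifelse(p$x < 0, -1, 1)
    ct <- suppressWarnings(
      cor.test(flip * p$x, flip * p$y, method = "spearman", exact = FALSE)
    )
    r_s <- unname(ct$estimate)
    p_s <- ct$p.value
  }
  tibble(
    x_name = x_name, y_name = y_name, n = as.integer(n),
    r = r, p = pval, r_spearman = r_s, p_spearman = p_s
  )
}

#' Through-origin regression of contrasts
#'
#' No-intercept least squares of a response contrast set on one or more
#' predictor contrast sets; slope standard errors and t-tests use
#' n - k degrees of freedom (no intercept degree of freedom is spent).
#'
#' @param y Response contrasts ([compute_contrasts()] tibble or numeric).
#' @param xs A single contrast set or a (possibly named) list of them.
#' @param y_name Response label.
#' @return An `origin_regression` object; see [tidy.origin_regression()].
#' @export
origin_regression <- function(y, xs, y_name = NULL) {
  y_name <- y_name %||% attr(y, "trait_name") %||% "y"
  if (is.data.frame(xs) || is.numeric(xs)) xs <- list(xs)
  nm <- names(xs) %||% rep("", length(xs))
  nm[nm == ""] <- purrr::map_chr(seq_along(xs), function(i) {
    attr(xs[[i]], "trait_name") %||% paste0("x", i)
  })[nm == ""]
  cols <- purrr::map(xs, function(x) .contrast_pair(x, y)$x)
  yv <- .contrast_pair(xs[[1]], y)$y
  X <- do.call(cbind, cols)
  colnames(X) <- nm
  n <- length(yv)
  k <- ncol(X)
  if (n < k + 2L) {
    stop_insufficient("need at least 2 more contrast pairs than predictors")
  }
  if (k > 1L) {
    sv <- svd(X, nu = 0, nv = 0)$d
    if (sv[1] / max(sv[k], .Machine$double.xmin) > 1e8) {
      stop_mitodiv("collinear predictors", "mitodiv_degenerate")
    }
  }
  fit <- lm(yv ~ X - 1)
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(
    list(
      y_name = y_name, predictor_names = nm,
      slopes = unname(ct[, 1]), slope_se = unname(ct[, 2]),
      t_values = unname(ct[, 3]), p_values = unname(ct[, 4]),
      n = as.integer(n), df_residual = fit$df.residual,
      r_squared = sm$r.squared, sigma = sm$sigma
    ),
    class = "origin_regression"
  )
}

#' @export
print.origin_regression <- function(x, ...) {
  cat("<origin_regression> ", x$y_name, " ~ ",
      paste(x$predictor_names, collapse = " + "),
      " (through origin, n = ", x$n, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' Percent change in diversity per doubling of a predictor
#'
#' For a log-log slope b, a doubling of the predictor multiplies the
#' response by 2^b: the percent change is 100 (2^b - 1). A slope of 0.20
#' gives ~15%.
#'
#' @param b Slope on the log-log scale (any log base).
#' @return Percent change (numeric).
#' @examples
#' percent_change_per_doubling(0.20)
#' @export
percent_change_per_doubling <- function(b) {
  100 * (2^b - 1)
}

#' Phylogenetic-signal table for an assembled dataset
#'
#' Fits Pagel's lambda to every log-scale variable.
#'
#' @param dataset A `species_dataset` from [assemble_dataset()].
#' @param vars Log-variable names (default all).
#' @param n_perm Permutations per variable (see [fit_lambda()]).
#' @param seed Seed for permutations.
#' @return Tibble: `trait`, `n`, `lambda`, `lrt`, `p_lrt`, `p_perm`.
#' @export
lambda_table <- function(dataset, vars = dataset_log_vars(dataset),
                         n_perm = 0L, seed = 1L) {
  purrr::map_dfr(vars, function(v) {
    vals <- setNames(dataset$data[[v]], dataset$data$species_id)
    fit <- tryCatch(
      fit_lambda(vals, dataset$tree, n_perm = n_perm, trait_name = v,
                 seed = seed),
      mitodiv_insufficient_data = function(e) NULL
    )
    if (is.null(fit)) {
      return(tibble(
        trait = v, n = sum(!is.na(vals)), lambda = NA_real_,
        lrt = NA_real_, p_lrt = NA_real_, p_perm = NA_real_
      ))
    }
    tibble(
      trait = v, n = fit$n_species, lambda = fit$lambda_hat,
      lrt = fit$lrt_stat, p_lrt = fit$p_lrt, p_perm = fit$p_perm
    )
  })
}

#' Contrast correlations of responses against predictors
#'
#' For each response x predictor pair, species missing either variable are
#' dropped (pairwise deletion, so n varies across rows), the tree is
#' re-pruned, contrasts recomputed, and the through-origin correlation
#' taken.
#'
#' @param dataset A `species_dataset`.
#' @param predictors Log-variable names of predictors.
#' @param responses Log-variable names of responses
#'   (default `log_pi_s` and `log_ratio`).
#' @return Tibble with one row per response x predictor:
#'   `response`, `predictor`, `n`, `r`, `p`, `r_spearman`, `p_spearman`.
#' @export
contrast_correlations <- function(dataset,
                                  predictors = setdiff(
                                    dataset_log_vars(dataset),
                                    c("log_pi_s", "log_ratio")
                                  ),
                                  responses = c("log_pi_s", "log_ratio")) {
  grid <- tidyr::expand_grid(predictor = predictors, response = responses)
  purrr::pmap_dfr(grid, function(predictor, response) {
    cp <- tryCatch(
      contrast_pair(dataset, predictor, response),
      mitodiv_insufficient_data = function(e) NULL
    )
    if (is.null(cp)) {
      return(tibble(
        response = response, predictor = predictor, n = NA_integer_,
        r = NA_real_, p = NA_real_, r_spearman = NA_real_,
        p_spearman = NA_real_
      ))
    }
    res <- origin_correlation(cp$x, cp$y,
                              x_name = predictor, y_name = response)
    tibble(
      response = response, predictor = predictor, n = res$n, r = res$r,
      p = res$p, r_spearman = res$r_spearman, p_spearman = res$p_spearman
    )
  })
}

#' Contrasts of two dataset variables on their shared species
#'
#' @param dataset A `species_dataset`.
#' @param x_var,y_var Log-variable names.
#' @return List with contrast tibbles `x` and `y` (same node set) and the
#'   pruned tree.
#' @export
contrast_pair <- function(dataset, x_var, y_var) {
  d <- dataset$data
  keep <- d$species_id[!is.na(d[[x_var]]) & !is.na(d[[y_var]])]
  if (length(keep) < 4L) {
    stop_insufficient(paste0(
      "fewer than 4 species share ", x_var, " and ", y_var
    ))
  }
  tree <- resolve_tree(ape::keep.tip(dataset$tree, keep))
  dd <- d[match(tree$tip.label, d$species_id), ]
  xv <- setNames(dd[[x_var]], dd$species_id)
  yv <- setNames(dd[[y_var]], dd$species_id)
  list(
    x = compute_contrasts(xv, tree, trait_name = x_var),
    y = compute_contrasts(yv, tree, trait_name = y_var),
    tree = tree
  )
}
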