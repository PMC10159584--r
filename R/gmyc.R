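# Single-threshold generalized mixed Yule-coalescent (GMYC) model on an
# ultrametric gene tree. Node ages before the threshold are treated as
# branching events of a Yule process over "species" lineages; ages after it
# as coalescences inside the clusters seeded where lineages cross the
# threshold. The likelihood is the classic waiting-interval form: between
# successive branching events (conditioning on the root), the waiting time
# is exponential with the total rate
#   b_i = rate_yule * n_yule_i^p_yule +
#         rate_coal * sum_clusters n_j (n_j - 1)^p_coal
# and each event contributes log b_i. The null model (threshold at or older
# than the root) is a single coalescent over the whole tree.

# Ages (time before present) of all nodes/tips; tips forced to exactly 0.
.node_ages <- function(tree, tol = 1e-6) {
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth) - depth
  ntip <- ape::Ntip(tree)
  if (!is_ultrametric(tree, tol)) {
    stop_format("GMYC requires an ultrametric tree")
  }
  age[seq_len(ntip)] <- 0
  age
}

# Decompose an ultrametric binary tree at a threshold age: cluster
# membership of every node/tip and the tip count of each threshold-crossing
# lineage.
.gmyc_decompose <- function(tree, threshold_time) {
  ntip <- ape::Ntip(tree)
  age <- .node_ages(tree)
  node_age <- age[ntip + seq_len(tree$Nnode)]
  root_age <- age[ntip + 1L]
  thr <- threshold_time

  if (thr >= root_age) {
    cluster_of <- rep(1L, ntip + tree$Nnode)
    crossing <- tibble(lineage = 1L, n_tips = ntip)
  } else {
    parent_age <- age[tree$edge[, 1]]
    child_age <- age[tree$edge[, 2]]
    cross_edge <- which(parent_age > thr & child_age <= thr)
    seeds <- tree$edge[cross_edge, 2]
    cluster_of <- rep(NA_integer_, ntip + tree$Nnode)
    for (k in seq_along(seeds)) {
      s <- seeds[k]
      if (s <= ntip) {
        cluster_of[s] <- k
      } else {
        cluster_of[c(s, tree_descendants(tree, s))] <- k
      }
    }
    n_tips_cl <- tabulate(cluster_of[seq_len(ntip)], length(seeds))
    crossing <- tibble(lineage = seq_along(seeds), n_tips = n_tips_cl)
  }

  list(
    ntip = ntip, age = age, node_age = node_age, root_age = root_age,
    thr = thr, cluster_of = cluster_of, crossing = crossing
  )
}

# All descendant node/tip ids of an internal node (iterative).
tree_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    ch <- tree$edge[tree$edge[, 1] == cur, 2]
    out <- c(out, ch)
    stack <- c(stack, ch[ch > ape::Ntip(tree)])
  }
  out
}

# Band table for a threshold: one row per waiting interval between
# successive branching events (root conditioned on), with the interval
# length x, the Yule lineage count n_y, and the per-cluster coalescent sum
# sum_j n_j (n_j - 1)^p_coal evaluated lazily via the raw counts.
.gmyc_bands <- function(tree, threshold_time) {
  dec <- .gmyc_decompose(tree, threshold_time)
  ntip <- dec$ntip
  thr <- dec$thr
  nage <- sort(dec$node_age, decreasing = TRUE) # a_1 = root .. a_M
  M <- length(nage)
  if (M < 2L) stop_insufficient("need >= 3 tips")
  k <- nrow(dec$crossing)
  cl_nodes <- dec$cluster_of[ntip + seq_len(tree$Nnode)]
  cl_ages <- purrr::map(seq_len(k), function(j) {
    if (thr >= dec$root_age) {
      dec$node_age
    } else {
      dec$node_age[!is.na(cl_nodes) & cl_nodes == j & dec$node_age <= thr]
    }
  })
  x <- nage[-M] - nage[-1]
  n_y <- numeric(M - 1L)
  counts <- vector("list", M - 1L)
  for (i in seq_len(M - 1L)) {
    mid <- (nage[i] + nage[i + 1]) / 2
    if (mid > thr) {
      n_y[i] <- 1 + sum(nage > mid)
      counts[[i]] <- integer(0)
    } else {
      # species lineages persist below the threshold; none exist in the
      # degenerate single-coalescent model
      n_y[i] <- if (thr >= dec$root_age) 0 else k
      nj <- vapply(cl_ages, function(a) 1L + sum(a > mid), integer(1))
      counts[[i]] <- nj[nj > 1L]
    }
  }
  list(
    x = x, n_y = n_y, counts = counts, crossing = dec$crossing,
    cluster_of_tip = dec$cluster_of[seq_len(ntip)],
    root_age = dec$root_age
  )
}

.gmyc_band_loglik <- function(bands, rate_yule, rate_coal,
                              p_yule = 1, p_coal = 1) {
  csum <- vapply(bands$counts, function(nj) {
    if (!length(nj)) 0 else sum(nj * (nj - 1)^p_coal)
  }, numeric(1))
  b <- rate_yule * bands$n_y^p_yule + rate_coal * csum
  if (any(b <= 0)) {
    return(-Inf)
  }
  sum(log(b) - b * bands$x)
}

#' GMYC log-likelihood at a fixed threshold
#'
#' Waiting intervals between successive branching events (the root is
#' conditioned on) are modeled as exponential with total rate
#' `rate_yule x n_Yule^p_yule + rate_coal x sum_clusters n_j (n_j-1)^p_coal`:
#' lineages older than the threshold are Yule lineages, younger lineages
#' belong to the clusters seeded where lineages cross the threshold (the
#' Yule count stays at the number of crossing lineages below the
#' threshold). A threshold at or older than the root gives the degenerate
#' single-coalescent null; a threshold younger than every node gives a pure
#' Yule process.
#'
#' @param tree Ultrametric binary `ape::phylo` with >= 3 tips.
#' @param threshold_time Age (before present) separating the two processes.
#' @param rate_yule,rate_coal Positive rates.
#' @param p_yule,p_coal Scaling exponents (1 = pure Yule + Kingman).
#' @return Log-likelihood.
#' @export
gmyc_loglik <- function(tree, threshold_time, rate_yule, rate_coal,
                        p_yule = 1, p_coal = 1) {
  stopifnot(rate_yule >= 0, rate_coal >= 0)
  tree <- validate_tree(tree)
  if (!ape::is.binary(tree)) stop_format("GMYC requires a binary tree")
  if (ape::Ntip(tree) < 3L) stop_insufficient("need >= 3 tips")
  bands <- .gmyc_bands(tree, threshold_time)
  .gmyc_band_loglik(bands, rate_yule, rate_coal, p_yule, p_coal)
}

# Maximize the two rates for a fixed band table. Closed form when only one
# process is active; otherwise Nelder-Mead on the log scale from
# method-of-moments starts.
.gmyc_fit_rates <- function(bands, p_yule = 1, p_coal = 1) {
  csum <- vapply(bands$counts, function(nj) {
    if (!length(nj)) 0 else sum(nj * (nj - 1)^p_coal)
  }, numeric(1))
  ny <- bands$n_y^p_yule
  x <- bands$x
  n_ev <- length(x)
  pure <- function(mult) {
    # single-process exponential: lambda-hat = events / sum(mult * x)
    X <- sum(mult * x)
    if (X <= 0 || any(mult <= 0)) {
      return(NULL)
    }
    lam <- n_ev / X
    list(ll = sum(log(lam * mult)) - n_ev, rates = c(lam, lam))
  }
  if (all(csum == 0)) {
    f <- pure(ny)
    if (is.null(f)) {
      return(NULL)
    }
    return(list(
      loglik = f$ll, rate_yule = f$rates[1], rate_coal = 0
    ))
  }
  if (all(bands$n_y == 0)) {
    f <- pure(csum)
    if (is.null(f)) {
      return(NULL)
    }
    return(list(loglik = f$ll, rate_yule = 0, rate_coal = f$rates[1]))
  }
  ev_y <- sum(csum == 0)
  ev_c <- n_ev - ev_y
  l_y0 <- max(ev_y, 0.5) / max(sum(ny * x), 1e-12)
  l_c0 <- max(ev_c, 0.5) / max(sum(csum * x), 1e-12)
  nll <- function(p) {
    b <- exp(p[1]) * ny + exp(p[2]) * csum
    -sum(log(b) - b * x)
  }
  op <- stats::optim(log(c(l_y0, l_c0)), nll,
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-10)
  )
  list(
    loglik = -op$value, rate_yule = exp(op$par[1]),
    rate_coal = exp(op$par[2])
  )
}

#' Fit the single-threshold GMYC model
#'
#' Threshold candidates are the root age, the midpoints between consecutive
#' distinct node ages, and the midpoint between the youngest node and the
#' present. At each candidate the two rates are maximized (scaling
#' exponents fixed at 1: pure Yule + Kingman); the best candidate is kept
#' and compared with the null single-coalescent model by a likelihood-ratio
#' test on 3 df, the convention of the original method (the mixed model
#' spends the second rate plus the scanned threshold).
#'
#' Clusters are threshold-crossing lineages with >= 2 sampled tips;
#' single-tip crossers are reported as singletons.
#'
#' @param tree Ultrametric binary (or polytomous; resolved deterministically)
#'   `ape::phylo` with >= 4 tips.
#' @param tree_id Identifier carried into the fit.
#' @return A `gmyc_fit` object; see [tidy.gmyc_fit()].
#' @export
fit_gmyc <- function(tree, tree_id = "tree") {
  tree <- validate_tree(tree)
  if (!ape::is.binary(tree)) tree <- resolve_tree(tree)
  if (ape::Ntip(tree) < 4L) stop_insufficient("need >= 4 tips for GMYC")
  age <- .node_ages(tree)
  node_age <- sort(unique(age[-seq_len(ape::Ntip(tree))]),
    decreasing = TRUE
  )
  root_age <- node_age[1]
  mids <- if (length(node_age) > 1L) {
    (node_age[-1] + node_age[-length(node_age)]) / 2
  } else {
    numeric(0)
  }
  cand <- unique(c(root_age, mids, min(node_age) / 2))

  fits <- purrr::map(cand, function(thr) {
    bands <- .gmyc_bands(tree, thr)
    f <- .gmyc_fit_rates(bands)
    if (is.null(f)) {
      return(NULL)
    }
    c(f, list(thr = thr, bands = bands))
  })
  fits <- purrr::compact(fits)
  if (!length(fits)) {
    stop_mitodiv(
      "all threshold candidates degenerate",
      "mitodiv_optim_failure"
    )
  }
  lls <- purrr::map_dbl(fits, "loglik")
  best <- fits[[which.max(lls)]]
  null <- fits[[1]] # root-age candidate evaluated first
  lrt <- max(2 * (best$loglik - null$loglik), 0)
  p <- pchisq(lrt, df = 3, lower.tail = FALSE)

  sizes <- best$bands$crossing$n_tips
  assignments <- tibble(
    tip = tree$tip.label,
    cluster = best$bands$cluster_of_tip,
    singleton = sizes[best$bands$cluster_of_tip] < 2L
  )

  structure(
    list(
      tree_id = tree_id, threshold_time = best$thr,
      loglik_mixed = best$loglik, loglik_null = null$loglik,
      lrt_stat = lrt, p = p,
      n_clusters = max(sum(sizes >= 2L), 1L),
      n_singletons = sum(sizes == 1L),
      cluster_sizes = sizes,
      cluster_assignments = assignments,
      rate_yule = best$rate_yule, rate_coal = best$rate_coal,
      scaling_p_yule = 1, scaling_p_coal = 1,
      root_age = best$bands$root_age, n_tips = ape::Ntip(tree)
    ),
    class = "gmyc_fit"
  )
}

#' @export
print.gmyc_fit <- function(x, ...) {
  cat(
    "<gmyc_fit> ", x$tree_id, ": ", x$n_clusters, " cluster(s), ",
    x$n_singletons, " singleton(s); threshold age ",
    formatC(x$threshold_time, digits = 4, format = "g"),
    ", LRT = ", formatC(x$lrt_stat, digits = 3, format = "fg"),
    ", p = ", format.pval(x$p, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Tips of the largest GMYC cluster
#'
#' Returns the tip set of the cluster with the most individuals; ties are
#' broken by the lexicographically smallest member id. Singleton crossers
#' are only eligible when no multi-tip cluster exists.
#'
#' @param fit A `gmyc_fit`.
#' @return Character vector of tip ids.
#' @export
largest_cluster <- function(fit) {
  stopifnot(inherits(fit, "gmyc_fit"))
  a <- fit$cluster_assignments
  sizes <- fit$cluster_sizes
  eligible <- if (any(sizes >= 2L)) which(sizes >= 2L) else seq_along(sizes)
  best_size <- max(sizes[eligible])
  cand <- eligible[sizes[eligible] == best_size]
  if (length(cand) > 1L) {
    firsts <- vapply(cand, function(k) min(a$tip[a$cluster == k]),
      character(1)
    )
    cand <- cand[order(firsts)][1]
  }
  sort(a$tip[a$cluster == cand])
}

#' Re-estimate diversity from a subset of individuals
#'
#' Restricts the alignment to the kept individuals (typically the largest
#' GMYC cluster, the subsample consistent with a single panmictic
#' population) and reruns [pairwise_pi()].
#'
#' @param alignment A [species_alignment()].
#' @param keep Individual ids to retain (>= 2).
#' @inheritParams genetic_code
#' @return One-row tibble as from [pairwise_pi()].
#' @export
reestimate_diversity <- function(alignment, keep, code = "vertebrate_mito") {
  stopifnot(inherits(alignment, "species_alignment"))
  missing <- setdiff(keep, names(alignment$sequences))
  if (length(missing)) {
    stop_format(paste0(
      "individuals not in alignment: ", paste(missing, collapse = ", ")
    ))
  }
  if (length(keep) < 2L) {
    stop_insufficient("need >= 2 retained individuals to re-estimate")
  }
  sub <- species_alignment(
    alignment$species_id, alignment$sequences[keep],
    gene_ids = alignment$gene_ids, frame_offset = alignment$frame_offset
  )
  pairwise_pi(sub, code = code)
}
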