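# Synthetic studies with the statistical structure the analysis assumes:
# Yule species trees, Kingman within-species genealogies (optionally with
# injected two-cluster substructure), codon sequences evolved under the
# vertebrate mitochondrial code with purifying selection on nonsynonymous
# changes, and correlated Brownian-motion traits on a lambda-transformed
# tree. Everything is reproducible from (config, seed) alone.

#' Configuration of a synthetic study
#'
#' Defaults emulate a compiled avian mitochondrial polymorphism dataset:
#' ~300 species; sample sizes 2-420 individuals with a median of 21 (drawn
#' from a truncated log-normal); per-synonymous-site diversity in a
#' realistic mitochondrial band; piS >> piN (a small fraction of
#' nonsynonymous mutations is effectively neutral); a weak log-log
#' dependence of piS on geographic range with slope 0.20 and noise tuned to
#' a contrast correlation of r ~ 0.4; an opposite dependence of piN/piS on
#' range (slope -0.16, r ~ -0.35); and log population size tracking log
#' range with r ~ 0.79.
#'
#' @param n_species Number of species.
#' @param ind_range Min/max individuals per species.
#' @param ind_median Target median individuals per species.
#' @param ind_sdlog Log-sd of the (truncated) log-normal sample-size draw.
#' @param yule_birth_rate Species-tree birth rate.
#' @param coal_depth_ratio Species-tree depth over within-species coalescent
#'   depth for substructured species (the deep split between clusters).
#' @param theta_s_range Bounds on per-synonymous-site diversity.
#' @param theta_s_log10_mean Mean of log10 theta_s before the range effect.
#' @param neutral_nonsyn_fraction Baseline fraction of nonsynonymous
#'   mutations that is neutral (controls piN/piS).
#' @param n_codons Codons per alignment.
#' @param trait_lambda Pagel's lambda used for trait evolution.
#' @param slope_pis_range True log-log slope of piS on range.
#' @param slope_ratio_range True log-log slope of piN/piS on range.
#' @param noise_sd_pis Independent BM noise sd on log10 piS (per unit
#'   depth); the default gives a contrast correlation r ~ 0.4 with the
#'   default range BM sd.
#' @param noise_sd_ratio Noise sd on log10 ratio (default: r ~ -0.35).
#' @param range_sd BM sd of log10 range per unit tree depth.
#' @param substructure_fraction Fraction of species given a two-cluster
#'   genealogy.
#' @param seed Master seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_species = 300L,
                             ind_range = c(2L, 420L),
                             ind_median = 21,
                             ind_sdlog = 1.1,
                             yule_birth_rate = 1,
                             coal_depth_ratio = 50,
                             theta_s_range = c(3e-4, 0.2),
                             theta_s_log10_mean = -1.7,
                             neutral_nonsyn_fraction = 0.08,
                             n_codons = 500L,
                             trait_lambda = 1,
                             slope_pis_range = 0.20,
                             slope_ratio_range = -0.16,
                             noise_sd_pis = 0.35,
                             noise_sd_ratio = 0.30,
                             range_sd = 1.3,
                             substructure_fraction = 0.2,
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_species >= 2L, yule_birth_rate > 0, coal_depth_ratio > 0,
    all(theta_s_range > 0), neutral_nonsyn_fraction >= 0,
    neutral_nonsyn_fraction <= 1, n_codons >= 1L,
    trait_lambda >= 0, trait_lambda <= 1,
    substructure_fraction >= 0, substructure_fraction <= 1
  )
  structure(cfg, class = "synthetic_config")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Waiting time to the next speciation while k lineages exist is
#' exponential with rate `birth_rate * k`; after the n-th lineage appears
#' one further exponential stretch is added so the youngest node has
#' positive age. The tree is ultrametric by construction.
#'
#' @param n_species Number of tips (>= 2).
#' @param birth_rate Per-lineage speciation rate.
#' @param seed Seed (reproducible; `NULL` uses the current RNG state).
#' @return Ultrametric binary `ape::phylo` with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = NULL) {
  stopifnot(n_species >= 2L, birth_rate > 0)
  sim <- function() {
    # node records: parent, birth time; tips assigned at the end
    parent <- integer(0)
    btime <- numeric(0)
    new_node <- function(p, t) {
      parent[length(parent) + 1L] <<- p
      btime[length(btime) + 1L] <<- t
      length(parent)
    }
    root <- new_node(0L, 0)
    active <- c(root)
    t <- 0
    while (length(active) < n_species) {
      k <- length(active)
      t <- t + rexp(1L, rate = birth_rate * k)
      i <- if (k == 1L) 1L else sample.int(k, 1L)
      split <- active[i]
      c1 <- new_node(split, t)
      c2 <- new_node(split, t)
      active <- c(active[-i], c1, c2)
    }
    t_end <- t + rexp(1L, rate = birth_rate * n_species)
    # assemble newick bottom-up (children have larger indices than parents)
    n_nodes <- length(parent)
    lab <- character(n_nodes)
    children <- split(seq_len(n_nodes)[-1], parent[-1])
    tip_id <- 0L
    for (v in n_nodes:1) {
      ch <- children[[as.character(v)]]
      end_t <- if (is.null(ch)) t_end else btime[ch[1]]
      len <- end_t - btime[v]
      if (is.null(ch)) {
        tip_id <- tip_id + 1L
        lab[v] <- paste0("tip", v, ":", format(len, digits = 15))
      } else {
        lab[v] <- paste0(
          "(", lab[ch[1]], ",", lab[ch[2]], "):", format(len, digits = 15)
        )
      }
    }
    tr <- ape::read.tree(text = paste0(lab[root], ";"))
    tr$tip.label <- paste0("t", seq_len(ape::Ntip(tr)))
    tr
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate a Kingman coalescent genealogy
#'
#' While k lineages remain, the waiting time to the next coalescence is
#' exponential with rate k(k-1)/2 (coalescent units); a random pair merges.
#' Branch lengths are then scaled by `theta_scale / 2`, so the expected
#' pairwise path length between two tips equals `theta_scale` - i.e. time is
#' measured in units of expected pairwise diversity, and a mutation rate of
#' 1 per site per unit branch length yields E\[piS\] = `theta_scale`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param theta_scale Target expected pairwise path length.
#' @param seed Seed.
#' @param tip_labels Optional tip labels (default `i1..in`).
#' @return Ultrametric binary `ape::phylo`.
#' @export
simulate_coalescent_genealogy <- function(n_tips, theta_scale = 0.02,
                                          seed = NULL, tip_labels = NULL) {
  stopifnot(n_tips >= 2L, theta_scale > 0)
  sim <- function() {
    labs <- tip_labels %||% paste0("i", seq_len(n_tips))
    frag <- labs
    height <- rep(0, n_tips)
    t <- 0
    while (length(frag) > 1L) {
      k <- length(frag)
      t <- t + rexp(1L, rate = k * (k - 1) / 2)
      pr <- sample.int(k, 2L)
      i <- pr[1]
      j <- pr[2]
      sc <- theta_scale / 2
      merged <- paste0(
        "(", frag[i], ":", format((t - height[i]) * sc, digits = 15), ",",
        frag[j], ":", format((t - height[j]) * sc, digits = 15), ")"
      )
      frag <- c(frag[-c(i, j)], merged)
      height <- c(height[-c(i, j)], t)
    }
    ape::read.tree(text = paste0(frag, ";"))
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

#' Simulate codon sequences along a genealogy
#'
#' The root sequence is drawn uniformly from sense codons. Candidate
#' mutations are placed as a Poisson process on branches at rate `mu` per
#' nucleotide site per unit branch length; each picks a random site and a
#' random alternative base. Changes creating a stop codon are always
#' rejected; nonsynonymous changes are retained with probability
#' `neutral_nonsyn_fraction`; synonymous changes are always retained. With
#' `mu = 1` and branch lengths in expected-diversity units (see
#' [simulate_coalescent_genealogy()]), E\[piS\] ~ theta_scale and
#' E\[piN/piS\] ~ `neutral_nonsyn_fraction`.
#'
#' Proposal-rate calibration factor for NG86-counted diversity
#'
#' The mutation simulator proposes each of a codon's nine single-nucleotide
#' neighbours at rate `mu / 3` and silently discards proposals that hit a
#' stop codon, so the realized synonymous-change rate per codon is
#' `mu / 3 x (number of synonymous neighbours)`. Nei-Gojobori site counts,
#' however, exclude stops from the per-position denominators, which makes
#' the site denominator systematically larger than the mutational
#' opportunity. The ratio of the two (averaged over sense codons, the root
#' distribution) is the factor by which `mu` must be multiplied for the
#' expected NG86-counted piS per synonymous site to equal the genealogy's
#' branch-length scale; ~1.06 for the vertebrate mitochondrial code.
#'
#' @inheritParams genetic_code
#' @return Named numeric: `kappa_s`, `kappa_n`.
#' @export
ng86_calibration <- function(code = "vertebrate_mito") {
  tb <- codon_tables(code)
  sense <- which(!tb$is_stop)
  nb <- function(i, want_syn) {
    ch <- strsplit(tb$codons[i], "")[[1]]
    cnt <- 0L
    for (p in 1:3) {
      for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
        x <- ch
        x[p] <- b
        j <- match(paste(x, collapse = ""), tb$codons)
        if (!tb$is_stop[j] && (tb$aa[j] == tb$aa[i]) == want_syn) {
          cnt <- cnt + 1L
        }
      }
    }
    cnt
  }
  syn_nb <- vapply(sense, nb, integer(1), want_syn = TRUE)
  nonsyn_nb <- vapply(sense, nb, integer(1), want_syn = FALSE)
  c(
    kappa_s = sum(tb$syn_sites[sense]) / sum(syn_nb / 3),
    kappa_n = sum(tb$nonsyn_sites[sense]) / sum(nonsyn_nb / 3)
  )
}

#' @param genealogy `ape::phylo` whose tip labels become individual ids.
#' @param n_codons Number of codons.
#' @param mu Proposal rate per nucleotide site per unit branch length.
#' @param neutral_nonsyn_fraction Acceptance probability of a
#'   nonsynonymous change.
#' @inheritParams genetic_code
#' @param seed Seed.
#' @param species_id Species id for the returned alignment.
#' @return A [species_alignment()].
#' @export
simulate_codon_sequences <- function(genealogy, n_codons, mu = 1,
                                     neutral_nonsyn_fraction = 0.1,
                                     code = "vertebrate_mito", seed = NULL,
                                     species_id = "sim") {
  stopifnot(ape::Ntip(genealogy) >= 2L, n_codons >= 1L, mu >= 0)
  tb <- codon_tables(code)
  sense <- which(!tb$is_stop)
  bases <- c("A", "C", "G", "T")
  # position/base decomposition of every codon id for fast mutation
  codon_chars <- do.call(rbind, strsplit(tb$codons, ""))
  # id lookup from three base indices
  base_idx <- function(ch) match(ch, bases)
  id_of <- array(0L, c(4, 4, 4))
  for (i in seq_len(64)) {
    b <- base_idx(codon_chars[i, ])
    id_of[b[1], b[2], b[3]] <- i
  }
  codon_base <- matrix(0L, 64, 3)
  for (i in seq_len(64)) codon_base[i, ] <- base_idx(codon_chars[i, ])

  sim <- function() {
    ntip <- ape::Ntip(genealogy)
    nnode <- genealogy$Nnode
    root <- ntip + 1L
    seqs <- vector("list", ntip + nnode)
    seqs[[root]] <- sample(sense, n_codons, replace = TRUE)
    # preorder traversal
    ord <- ape::reorder.phylo(genealogy, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]
      chd <- ord$edge[e, 2]
      len <- ord$edge.length[e]
      s <- seqs[[par]]
      n_mut <- rpois(1L, mu * 3 * n_codons * len)
      if (n_mut > 0L) {
        sites <- sample.int(3L * n_codons, n_mut, replace = TRUE)
        shifts <- sample.int(3L, n_mut, replace = TRUE)
        us <- runif(n_mut)
        for (m in seq_len(n_mut)) {
          cod <- (sites[m] - 1L) %/% 3L + 1L
          pos <- (sites[m] - 1L) %% 3L + 1L
          old_id <- s[cod]
          b <- codon_base[old_id, ]
          b[pos] <- (b[pos] - 1L + shifts[m]) %% 4L + 1L
          new_id <- id_of[b[1], b[2], b[3]]
          if (tb$is_stop[new_id]) next
          syn <- tb$aa[new_id] == tb$aa[old_id]
          if (syn || us[m] < neutral_nonsyn_fraction) s[cod] <- new_id
        }
      }
      seqs[[chd]] <- s
    }
    tips <- setNames(
      vapply(seq_len(ntip), function(i) {
        paste(tb$codons[seqs[[i]]], collapse = "")
      }, character(1)),
      genealogy$tip.label
    )
    species_alignment(species_id, tips, gene_ids = species_id,
                      frame_offset = 0L)
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

# Draw one multivariate normal sample with covariance C (chol-based).
.rmvn1 <- function(mean, C) {
  n <- length(mean)
  R <- chol(C + diag(1e-10 * max(diag(C)), n))
  as.vector(mean + t(R) %*% rnorm(n))
}

#' Simulate correlated log-scale traits on a tree
#'
#' Base traits evolve by Brownian motion on the lambda-transformed tree
#' (tip covariance with off-diagonals scaled by `lam`); dependent traits are
#' `slope x partner log-trait + independent BM noise` on the same
#' lambda-transformed tree. All traits are exponentiated (base 10) to the
#' natural scale for the returned table.
#'
#' @param tree Ultrametric `ape::phylo`.
#' @param lam Pagel's lambda for trait evolution.
#' @param base_traits Named list: trait -> list(mean, sd) of the log10-scale
#'   BM (sd per unit tree depth).
#' @param slope_structure Named list: trait -> list(partner, slope,
#'   noise_sd, mean); the dependent log-trait is
#'   `mean + slope * (partner - partner_mean) + noise`.
#' @param seed Seed.
#' @return Tibble: `species_id` plus one column per trait (natural scale).
#' @export
simulate_traits <- function(tree, lam,
                            base_traits = list(
                              range_km2 = list(mean = 5.5, sd = 0.7)
                            ),
                            slope_structure = list(),
                            seed = NULL) {
  stopifnot(lam >= 0, lam <= 1)
  tree <- validate_tree(tree)
  depth <- max(ape::node.depth.edgelength(tree))
  V <- ape::vcv(tree) / depth # unit-depth scaling: sds are per unit depth
  C <- .lambda_cov(V, lam)
  tips <- rownames(V)

  sim <- function() {
    logs <- list()
    for (nm in names(base_traits)) {
      bt <- base_traits[[nm]]
      logs[[nm]] <- .rmvn1(rep(bt$mean, length(tips)), bt$sd^2 * C)
    }
    for (nm in names(slope_structure)) {
      ss <- slope_structure[[nm]]
      partner <- logs[[ss$partner]]
      if (is.null(partner)) {
        stop_format(paste0("partner trait '", ss$partner, "' not simulated"))
      }
      pmean <- base_traits[[ss$partner]]$mean
      noise <- if (ss$noise_sd > 0) {
        .rmvn1(rep(0, length(tips)), ss$noise_sd^2 * C)
      } else {
        rep(0, length(tips))
      }
      logs[[nm]] <- ss$mean + ss$slope * (partner - pmean) + noise
    }
    out <- tibble(species_id = tips)
    for (nm in names(logs)) out[[nm]] <- 10^logs[[nm]]
    out
  }
  if (is.null(seed)) sim() else withr::with_seed(seed, sim())
}

# Truncated log-normal sample sizes with a target median.
.sample_sizes <- function(n, median, sdlog, lo, hi, seed = NULL) {
  draw <- function() {
    x <- round(rlnorm(n, meanlog = log(median), sdlog = sdlog))
    pmin(pmax(x, lo), hi)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a complete synthetic study on disk
#'
#' Writes, under `out_dir`: `alignments/<species>.fasta`,
#' `species_tree.nwk`, `gene_trees/<species>.nwk` (the true genealogies; a
#' configured fraction of species get a two-cluster genealogy whose
#' between-cluster split is `coal_depth_ratio` times deeper than the
#' within-cluster coalescent), `traits.csv`, and `truth.json` recording all
#' generative parameters (true lambda, slopes, theta values, cluster
#' counts, substructured species).
#'
#' Trait columns mirror a bird life-history compilation: range (km^2),
#' population size, absolute breeding/nonbreeding latitude, body mass (g),
#' longevity (months), mass-specific metabolic rate, egg mass (g), clutch
#' size. Missingness is injected per trait at rates mimicking such
#' compilations (population size and metabolic rate are the sparsest), so
#' pairwise deletion is exercised downstream.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, the truth list.
#' @export
make_study <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(file.path(out_dir, "alignments"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "gene_trees"), showWarnings = FALSE)
  cfg <- config
  kappa <- ng86_calibration()
  n <- cfg$n_species
  sp_ids <- sprintf("sp%03d", seq_len(n))

  withr::with_seed(cfg$seed, {
    # species tree, rescaled to unit depth for trait evolution
    tree <- simulate_yule_tree(n, cfg$yule_birth_rate)
    tree$edge.length <- tree$edge.length /
      max(ape::node.depth.edgelength(tree))
    tree$tip.label <- sp_ids

    base_traits <- list(
      range_km2 = list(mean = 5.2, sd = cfg$range_sd),
      abs_latitude_breeding = list(mean = 1.25, sd = 0.25),
      abs_latitude_nonbreeding = list(mean = 1.2, sd = 0.25),
      mass_g = list(mean = 1.7, sd = 0.5),
      longevity_months = list(mean = 2.1, sd = 0.25),
      msmr = list(mean = 0.3, sd = 0.25),
      egg_mass_g = list(mean = 0.8, sd = 0.4),
      clutch_size = list(mean = 0.55, sd = 0.2)
    )
    slope_structure <- list(
      population_size = list(
        partner = "range_km2", slope = 1,
        noise_sd = cfg$range_sd * sqrt(1 / 0.79^2 - 1), mean = 6
      ),
      .theta_s = list(
        partner = "range_km2", slope = cfg$slope_pis_range,
        noise_sd = cfg$noise_sd_pis, mean = cfg$theta_s_log10_mean
      ),
      .neutral = list(
        partner = "range_km2", slope = cfg$slope_ratio_range,
        noise_sd = cfg$noise_sd_ratio,
        mean = log10(cfg$neutral_nonsyn_fraction)
      )
    )
    # simulate_traits returns natural scale, so .theta_s / .neutral are the
    # per-species theta and neutral fractions themselves
    traits_full <- simulate_traits(
      tree, cfg$trait_lambda,
      base_traits = base_traits, slope_structure = slope_structure
    )
    theta <- pmin(pmax(traits_full$.theta_s, cfg$theta_s_range[1]),
                  cfg$theta_s_range[2])
    neutral <- pmin(traits_full$.neutral, 1)
    traits <- traits_full |>
      select(-".theta_s", -".neutral") |>
      select("species_id", dplyr::everything())

    # inject missingness
    miss_rate <- c(
      range_km2 = 0.0, population_size = 0.70,
      abs_latitude_breeding = 0.35, abs_latitude_nonbreeding = 0.35,
      mass_g = 0.01, longevity_months = 0.55, msmr = 0.75,
      egg_mass_g = 0.25, clutch_size = 0.03
    )
    for (nm in names(miss_rate)) {
      if (miss_rate[[nm]] > 0) {
        drop <- runif(n) < miss_rate[[nm]]
        traits[[nm]][drop] <- NA_real_
      }
    }

    sizes <- .sample_sizes(n, cfg$ind_median, cfg$ind_sdlog,
                           cfg$ind_range[1], cfg$ind_range[2])
    n_sub <- ceiling(cfg$substructure_fraction * n)
    sub_ids <- if (n_sub > 0) sort(sample(sp_ids, n_sub)) else character(0)

    n_clusters_true <- setNames(rep(1L, n), sp_ids)
    for (i in seq_len(n)) {
      sp <- sp_ids[i]
      m <- sizes[i]
      labs <- sprintf("%s_i%03d", sp, seq_len(m))
      th <- theta[i]
      if (sp %in% sub_ids && m >= 4L) {
        m1 <- max(2L, rbinom_mid(m))
        m2 <- m - m1
        g1 <- simulate_coalescent_genealogy(m1, th, tip_labels = labs[1:m1])
        g2 <- simulate_coalescent_genealogy(
          m2, th, tip_labels = labs[(m1 + 1):m]
        )
        join_age <- cfg$coal_depth_ratio * th / 2
        gen <- bind_at_age(g1, g2, join_age)
        n_clusters_true[sp] <- 2L
      } else {
        gen <- simulate_coalescent_genealogy(m, th, tip_labels = labs)
      }
      aln <- simulate_codon_sequences(
        gen, cfg$n_codons, mu = kappa[["kappa_s"]],
        neutral_nonsyn_fraction = neutral[i], species_id = sp
      )
      write_alignment(aln, file.path(out_dir, "alignments",
                                     paste0(sp, ".fasta")))
      write_tree(gen, file.path(out_dir, "gene_trees",
                                paste0(sp, ".nwk")))
    }

    write_tree(tree, file.path(out_dir, "species_tree.nwk"))
    write_trait_table(traits, file.path(out_dir, "traits.csv"))

    truth <- list(
      seed = cfg$seed, n_species = n,
      trait_lambda = cfg$trait_lambda,
      slope_pis_range = cfg$slope_pis_range,
      slope_ratio_range = cfg$slope_ratio_range,
      neutral_nonsyn_fraction = cfg$neutral_nonsyn_fraction,
      theta_s = setNames(as.list(theta), sp_ids),
      neutral_fraction = setNames(as.list(neutral), sp_ids),
      individuals = setNames(as.list(as.integer(sizes)), sp_ids),
      substructured_species = as.list(sub_ids),
      n_clusters = as.list(n_clusters_true),
      coal_depth_ratio = cfg$coal_depth_ratio,
      n_codons = cfg$n_codons
    )
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(truth)
  })
}

# Split m individuals into two clusters of at least 2 (binomial around m/2).
rbinom_mid <- function(m) {
  k <- stats::rbinom(1L, m, 0.5)
  min(max(k, 2L), m - 2L)
}

# Join two ultrametric trees as sister clades at a given age.
bind_at_age <- function(t1, t2, join_age) {
  h1 <- max(ape::node.depth.edgelength(t1))
  h2 <- max(ape::node.depth.edgelength(t2))
  join_age <- max(join_age, 1.05 * max(h1, h2))
  n1 <- ape::write.tree(t1)
  n2 <- ape::write.tree(t2)
  strip <- function(s) sub(";$", "", s)
  txt <- paste0(
    "(", strip(n1), ":", format(join_age - h1, digits = 15), ",",
    strip(n2), ":", format(join_age - h2, digits = 15), ");"
  )
  ape::read.tree(text = txt)
}
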