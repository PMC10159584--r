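# Independent oracles used to check the package's own implementations.
# These deliberately re-derive everything from first principles (and from
# Biostrings' genetic-code table only), sharing no code with the package
# internals they check.

oracle_code <- function() Biostrings::getGeneticCode("2")

# Exhaustive-enumeration NG86 site counts: per position, fraction of
# non-stop single-base changes that preserve the amino acid.
oracle_sites <- function(codon) {
  gc <- oracle_code()
  ch <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    alts <- setdiff(c("A", "C", "G", "T"), ch[p])
    aas <- sapply(alts, function(b) {
      x <- ch
      x[p] <- b
      gc[[paste(x, collapse = "")]]
    })
    ok <- aas != "*"
    if (any(ok)) syn <- syn + mean(aas[ok] == gc[[codon]]) * 1
  }
  c(syn, 3 - syn)
}

# Pathway enumeration by explicit recursion over all step orders.
oracle_pair <- function(a, b) {
  gc <- oracle_code()
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) {
    return(c(0, 0))
  }
  paths <- function(cur, remaining) {
    if (!length(remaining)) {
      return(list(list()))
    }
    out <- list()
    for (p in remaining) {
      nxt <- strsplit(cur, "")[[1]]
      nxt[p] <- strsplit(b, "")[[1]][p]
      nxt <- paste(nxt, collapse = "")
      for (rest in paths(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1]] <- c(list(c(from = cur, to = nxt)), rest)
      }
    }
    out
  }
  all_paths <- paths(a, pos)
  score <- function(path, drop_stops) {
    s <- 0
    n <- 0
    for (st in path) {
      if (gc[[st["from"]]] == "*" || gc[[st["to"]]] == "*") {
        if (!drop_stops) {
          return(NULL)
        }
      } else if (gc[[st["from"]]] == gc[[st["to"]]]) {
        s <- s + 1
      } else {
        n <- n + 1
      }
    }
    c(s, n)
  }
  ok <- Filter(Negate(is.null), lapply(all_paths, score, drop_stops = FALSE))
  if (!length(ok)) ok <- lapply(all_paths, score, drop_stops = TRUE)
  colMeans(do.call(rbind, ok))
}

# Brute-force pairwise piS/piN on raw sequences via the oracles above.
oracle_pi <- function(seqs) {
  gc <- oracle_code()
  n <- length(seqs)
  ncod <- nchar(seqs[1]) %/% 3
  codons <- function(s) substring(s, 3 * (1:ncod) - 2, 3 * (1:ncod))
  valid <- function(cod) !grepl("[^ACGT]", cod) & gc[cod] != "*"
  ps <- c()
  pn <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ca <- codons(seqs[i])
      cb <- codons(seqs[j])
      keep <- valid(ca) & valid(cb)
      sd <- 0
      nd <- 0
      ss <- 0
      ns <- 0
      for (k in which(keep)) {
        d <- oracle_pair(ca[k], cb[k])
        sd <- sd + d[1]
        nd <- nd + d[2]
        sa <- oracle_sites(ca[k])
        sb <- oracle_sites(cb[k])
        ss <- ss + (sa[1] + sb[1]) / 2
        ns <- ns + (sa[2] + sb[2]) / 2
      }
      ps <- c(ps, sd / ss)
      pn <- c(pn, nd / ns)
    }
  }
  c(pi_s = mean(ps), pi_n = mean(pn))
}

# Direct multivariate-normal BM machinery on the tip covariance matrix.
oracle_bm_loglik <- function(x, V, lam) {
  C <- lam * V
  diag(C) <- diag(V)
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(one %*% Ci %*% x) / as.numeric(one %*% Ci %*% one)
  r <- x - mu
  s2 <- as.numeric(r %*% Ci %*% r) / n
  ld <- as.numeric(determinant(C, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi * s2) + ld + n)
}

# GLS correlation with BM covariance; equals the through-origin Pearson
# correlation of independent contrasts.
oracle_gls_corr <- function(x, y, V) {
  Ci <- solve(V)
  one <- rep(1, length(x))
  mu <- function(z) as.numeric(one %*% Ci %*% z) / as.numeric(one %*% Ci %*% one)
  rx <- x - mu(x)
  ry <- y - mu(y)
  as.numeric(rx %*% Ci %*% ry) /
    sqrt(as.numeric(rx %*% Ci %*% rx) * as.numeric(ry %*% Ci %*% ry))
}

# Hand-rolled Felsenstein pruning on a binary ape tree.
oracle_pic <- function(x, tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  val <- c(x[tree$tip.label], rep(NA, tree$Nnode))
  elen <- numeric(nn)
  elen[tree$edge[, 2]] <- tree$edge.length
  contrasts <- c()
  ord <- ape::reorder.phylo(tree, "postorder")$edge[, 1]
  for (node in unique(ord)) {
    ch <- tree$edge[tree$edge[, 1] == node, 2]
    v1 <- elen[ch[1]]
    v2 <- elen[ch[2]]
    contrasts <- c(contrasts, (val[ch[1]] - val[ch[2]]) / sqrt(v1 + v2))
    val[node] <- (val[ch[1]] / v1 + val[ch[2]] / v2) / (1 / v1 + 1 / v2)
    elen[node] <- elen[node] + v1 * v2 / (v1 + v2)
  }
  contrasts
}

# Random alignment of sense codons with occasional N/gap codons.
random_alignment <- function(n_seq, n_codons, p_mut = 0.3, p_bad = 0.05,
                             species = "sim") {
  gc <- oracle_code()
  sense <- names(gc)[gc != "*"]
  base <- sample(sense, n_codons, replace = TRUE)
  seqs <- sapply(seq_len(n_seq), function(i) {
    cods <- base
    mut <- runif(n_codons) < p_mut
    cods[mut] <- sample(sense, sum(mut), replace = TRUE)
    bad <- runif(n_codons) < p_bad
    cods[bad] <- sample(c("NNN", "A-T", "NAT"), sum(bad), replace = TRUE)
    paste(cods, collapse = "")
  })
  names(seqs) <- paste0("i", seq_len(n_seq))
  species_alignment(species, seqs)
}

# Species tree whose tips each carry a within-species coalescent cluster:
# every species divergence (i.e. the shallowest split) is `ratio` x the
# expected cluster TMRCA.
make_two_scale_tree <- function(n_species, tips_per, theta, ratio) {
  sp <- simulate_yule_tree(n_species, 1)
  dep <- ape::node.depth.edgelength(sp)
  youngest <- min(max(dep) - dep[-seq_len(n_species)])
  target <- ratio * theta * (1 - 1 / tips_per) # E[cluster TMRCA]
  sp$edge.length <- sp$edge.length * target / youngest
  clusters <- lapply(seq_len(n_species), function(k) {
    simulate_coalescent_genealogy(
      tips_per, theta,
      tip_labels = sprintf("s%d_%d", k, seq_len(tips_per))
    )
  })
  hts <- sapply(clusters, function(cl) max(ape::node.depth.edgelength(cl)))
  hmax <- max(hts)
  # graft each cluster onto its species tip, extending the stem so every
  # tip ends at the same present
  txt <- ape::write.tree(sp)
  for (k in seq_len(n_species)) {
    m <- regmatches(txt, regexec(paste0("t", k, ":([0-9.eE+-]+)"), txt))[[1]]
    len <- as.numeric(m[2]) + (hmax - hts[k])
    sub <- sub(";$", "", ape::write.tree(clusters[[k]]))
    txt <- sub(m[1], paste0(sub, ":", format(len, digits = 15)), txt,
      fixed = TRUE
    )
  }
  ape::read.tree(text = txt)
}
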