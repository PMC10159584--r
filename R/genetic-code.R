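# Genetic-code tables and Nei-Gojobori (1986) codon machinery.
#
# The per-codon synonymous/nonsynonymous site fractions and the
# pathway-averaged difference counts for every ordered codon pair are
# precomputed once per genetic code and cached: pairwise_pi() then reduces to
# table lookups, which keeps large alignments (hundreds of haplotypes)
# tractable.

.mitodiv_code_cache <- new.env(parent = emptyenv())

#' Resolve a genetic code by name
#'
#' @param code `"vertebrate_mito"` (NCBI translation table 2, the default:
#'   ATA = Met, TGA = Trp, AGA/AGG = stop, leaving 60 sense codons) or
#'   `"standard"` (table 1).
#' @return Named character vector mapping the 64 codons to amino-acid
#'   one-letter codes, `"*"` for stops.
#' @export
genetic_code <- function(code = "vertebrate_mito") {
  id <- switch(code,
    vertebrate_mito = "2",
    standard = "1",
    stop_format(paste0("unknown genetic code: '", code, "'"))
  )
  Biostrings::getGeneticCode(id)
}

# All permutations of 1..d for d <= 3 (mutational pathway orders).
.perms <- function(d) {
  switch(d,
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(
      c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)
    )
  )
}

.check_codon <- function(codon, what = "codon") {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
    grepl("[^ACGT]", codon)) {
    stop_format(paste0(
      what, " must be a 3-mer over {A,C,G,T}, got '", codon, "'"
    ))
  }
  invisible(codon)
}

#' Count synonymous and nonsynonymous sites of a sense codon
#'
#' Nei-Gojobori site counting: each of the three positions contributes the
#' fraction of its single-nucleotide changes that are synonymous, with
#' changes to stop codons excluded from that position's denominator.
#' For a fully resolved sense codon the two counts sum to 3.
#'
#' @param codon A sense codon (3-mer over A/C/G/T).
#' @inheritParams genetic_code
#' @return Named numeric: `syn_sites`, `nonsyn_sites`.
#' @examples
#' count_codon_sites("TTT") # 1/3 synonymous site
#' count_codon_sites("CTT") # fully degenerate third position
#' @export
count_codon_sites <- function(codon, code = "vertebrate_mito") {
  gc <- genetic_code(code)
  .check_codon(codon)
  if (gc[[codon]] == "*") {
    stop_format(paste0("'", codon, "' is a stop codon under ", code))
  }
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    alts <- setdiff(bases, chars[p])
    tgt <- vapply(alts, function(b) {
      x <- chars
      x[p] <- b
      paste(x, collapse = "")
    }, character(1))
    aa <- gc[tgt]
    keep <- aa != "*"
    if (any(keep)) {
      syn <- syn + sum(aa[keep] == gc[[codon]]) / sum(keep)
    }
  }
  c(syn_sites = syn, nonsyn_sites = 3 - syn)
}

#' Classify the differences between two sense codons
#'
#' Zero differences give (0, 0); one difference is classified directly;
#' two or three differences are averaged over all mutational pathways,
#' equally weighted, with pathways passing through a stop codon excluded.
#' If every pathway hits a stop (possible only for triple differences),
#' all pathways are used with their stop steps dropped.
#'
#' @param codon_a,codon_b Sense codons.
#' @inheritParams genetic_code
#' @return Named numeric: `syn_diffs`, `nonsyn_diffs`.
#' @examples
#' classify_codon_pair("TTT", "TTC") # synonymous Phe change
#' classify_codon_pair("TTA", "CTG") # two steps, Leu throughout
#' @export
classify_codon_pair <- function(codon_a, codon_b, code = "vertebrate_mito") {
  gc <- genetic_code(code)
  .check_codon(codon_a, "codon_a")
  .check_codon(codon_b, "codon_b")
  if (gc[[codon_a]] == "*" || gc[[codon_b]] == "*") {
    stop_format("both codons must be sense codons")
  }
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  d <- length(pos)
  if (d == 0L) {
    return(c(syn_diffs = 0, nonsyn_diffs = 0))
  }

  walk_path <- function(ord, drop_stop_steps = FALSE) {
    cur <- a
    s <- 0
    n <- 0
    for (p in pos[ord]) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- gc[[paste(cur, collapse = "")]]
      aa_nxt <- gc[[paste(nxt, collapse = "")]]
      if (aa_nxt == "*" || aa_cur == "*") {
        if (!drop_stop_steps) {
          return(NULL)
        } # pathway invalid
      } else if (aa_cur == aa_nxt) {
        s <- s + 1
      } else {
        n <- n + 1
      }
      cur <- nxt
    }
    c(s, n)
  }

  orders <- .perms(d)
  tallies <- purrr::compact(purrr::map(orders, walk_path))
  if (length(tallies) == 0L) {
    # Every pathway is stop-blocked (e.g. AAA <-> TGA under the vertebrate
    # mitochondrial code, whose two intermediates TAA and AGA are both
    # stops): fall back to all pathways with their stop steps dropped.
    tallies <- purrr::map(orders, walk_path, drop_stop_steps = TRUE)
  }
  m <- rowMeans(do.call(cbind, tallies))
  c(syn_diffs = m[1], nonsyn_diffs = m[2])
}

# Cached lookup tables for a genetic code:
#   codons      the 64 codon strings
#   aa          translation
#   is_stop     logical(64)
#   syn_sites / nonsyn_sites  per-codon site counts (NA for stops)
#   syn_diff / nonsyn_diff    64 x 64 pathway-averaged difference counts
codon_tables <- function(code = "vertebrate_mito") {
  if (!is.null(.mitodiv_code_cache[[code]])) {
    return(.mitodiv_code_cache[[code]])
  }
  gc <- genetic_code(code)
  codons <- names(gc)
  is_stop <- unname(gc == "*")
  syn_sites <- rep(NA_real_, 64)
  nonsyn_sites <- rep(NA_real_, 64)
  for (i in which(!is_stop)) {
    sc <- count_codon_sites(codons[i], code)
    syn_sites[i] <- sc[["syn_sites"]]
    nonsyn_sites[i] <- sc[["nonsyn_sites"]]
  }
  syn_diff <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nonsyn_diff <- syn_diff
  sense <- which(!is_stop)
  for (i in sense) {
    for (j in sense) {
      if (j < i) {
        syn_diff[i, j] <- syn_diff[j, i]
        nonsyn_diff[i, j] <- nonsyn_diff[j, i]
      } else {
        cl <- classify_codon_pair(codons[i], codons[j], code)
        syn_diff[i, j] <- cl[["syn_diffs"]]
        nonsyn_diff[i, j] <- cl[["nonsyn_diffs"]]
      }
    }
  }
  tb <- list(
    code = code, codons = codons, aa = unname(gc), is_stop = is_stop,
    syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
    syn_diff = syn_diff, nonsyn_diff = nonsyn_diff
  )
  assign(code, tb, envir = .mitodiv_code_cache)
  tb
}
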