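# Per-species synonymous and nonsynonymous nucleotide diversity from codon
# alignments: Nei-Gojobori unweighted pathway counting with uncorrected
# proportions. Within-species mitochondrial diversity is small (<< 0.1), so a
# multiple-hit correction would change nothing material; uncorrected
# proportions keep pair-level estimates exactly interpretable.

# Integer codon ids (1..64, NA for codons containing N/gap or stops) for each
# sequence of an alignment, after trimming the frame offset and any trailing
# incomplete codon.
.codon_ids <- function(alignment, tb) {
  seqs <- alignment$sequences
  off <- alignment$frame_offset
  len <- nchar(seqs[1])
  n_codons <- (len - off) %/% 3L
  if (n_codons < 1L) stop_format("no complete codons after frame offset")
  starts <- off + 1L + 3L * (seq_len(n_codons) - 1L)
  ids <- matrix(NA_integer_, nrow = length(seqs), ncol = n_codons)
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], starts, starts + 2L)
    id <- match(cods, tb$codons) # NA for anything with N or '-'
    id[!is.na(id) & tb$is_stop[id]] <- NA_integer_
    ids[i, ] <- id
  }
  rownames(ids) <- names(seqs)
  ids
}

# Difference/site sums for one pair of codon-id vectors. Returns NULL when no
# codon column is retained.
.pair_counts <- function(ia, ib, tb) {
  keep <- !is.na(ia) & !is.na(ib)
  if (!any(keep)) {
    return(NULL)
  }
  ia <- ia[keep]
  ib <- ib[keep]
  idx <- cbind(ia, ib)
  syn_sites <- sum((tb$syn_sites[ia] + tb$syn_sites[ib]) / 2)
  nonsyn_sites <- sum((tb$nonsyn_sites[ia] + tb$nonsyn_sites[ib]) / 2)
  list(
    syn_diffs = sum(tb$syn_diff[idx]),
    nonsyn_diffs = sum(tb$nonsyn_diff[idx]),
    syn_sites = syn_sites, nonsyn_sites = nonsyn_sites
  )
}

#' Pairwise synonymous and nonsynonymous diversity of a species alignment
#'
#' For every unordered pair of sequences, codon columns where either codon
#' contains N or a gap, or is a stop codon, are skipped (pairwise deletion at
#' codon granularity). Synonymous/nonsynonymous differences are summed with
#' Nei-Gojobori pathway averaging, site counts are the average of the two
#' sequences' counts over the retained codons, and the pair-level proportions
#' pS and pN are averaged (unweighted) over all pairs to give piS and piN.
#'
#' Identical haplotypes are collapsed internally, so alignments with
#' hundreds of individuals remain fast.
#'
#' @param alignment A [species_alignment()].
#' @inheritParams genetic_code
#' @return One-row tibble: `species_id`, `n_individuals`, `pi_s`, `pi_n`,
#'   `ratio` (piN/piS, `NA` when piS = 0), `syn_sites_total`,
#'   `nonsyn_sites_total` (mean per-pair site counts), `n_pairs`.
#' @examples
#' aln <- species_alignment("sp", c(a = "TTTTTC", b = "TTTTTT"))
#' pairwise_pi(aln)
#' @export
pairwise_pi <- function(alignment, code = "vertebrate_mito") {
  stopifnot(inherits(alignment, "species_alignment"))
  tb <- codon_tables(code)
  ids <- .codon_ids(alignment, tb)
  n <- nrow(ids)

  # collapse identical haplotype rows
  key <- apply(ids, 1L, paste, collapse = ",")
  uk <- unique(key)
  first <- match(uk, key)
  mult <- as.vector(table(factor(key, levels = uk)))
  u <- ids[first, , drop = FALSE]
  nu <- length(uk)

  sum_ps <- 0
  sum_pn <- 0
  sum_ss <- 0
  sum_ns <- 0
  n_pairs <- 0L
  n_dropped <- 0L

  # within-haplotype pairs: zero differences, own site counts
  for (i in seq_len(nu)) {
    w <- choose(mult[i], 2)
    if (w > 0) {
      pc <- .pair_counts(u[i, ], u[i, ], tb)
      if (is.null(pc)) {
        n_dropped <- n_dropped + w
      } else {
        n_pairs <- n_pairs + w
        sum_ss <- sum_ss + w * pc$syn_sites
        sum_ns <- sum_ns + w * pc$nonsyn_sites
      }
    }
  }
  # between-haplotype pairs
  if (nu > 1L) {
    for (i in seq_len(nu - 1L)) {
      for (j in (i + 1L):nu) {
        w <- mult[i] * mult[j]
        pc <- .pair_counts(u[i, ], u[j, ], tb)
        if (is.null(pc)) {
          n_dropped <- n_dropped + w
          next
        }
        if (pc$syn_sites <= 0 || pc$nonsyn_sites <= 0) {
          n_dropped <- n_dropped + w
          next
        }
        n_pairs <- n_pairs + w
        sum_ps <- sum_ps + w * pc$syn_diffs / pc$syn_sites
        sum_pn <- sum_pn + w * pc$nonsyn_diffs / pc$nonsyn_sites
        sum_ss <- sum_ss + w * pc$syn_sites
        sum_ns <- sum_ns + w * pc$nonsyn_sites
      }
    }
  }

  if (n_dropped > 0L) {
    warn(paste0(
      alignment$species_id, ": ", n_dropped,
      " sequence pair(s) dropped (no retained codons)"
    ))
  }
  if (n_pairs == 0L) {
    stop_insufficient(paste0(
      alignment$species_id, ": no sequence pair retains any codon"
    ))
  }

  pi_s <- sum_ps / n_pairs
  pi_n <- sum_pn / n_pairs
  tibble(
    species_id = alignment$species_id,
    n_individuals = n,
    pi_s = pi_s,
    pi_n = pi_n,
    ratio = if (pi_s > 0) pi_n / pi_s else NA_real_,
    syn_sites_total = sum_ss / n_pairs,
    nonsyn_sites_total = sum_ns / n_pairs,
    n_pairs = as.integer(n_pairs)
  )
}

#' Concatenate multi-gene alignments sequenced from the same individuals
#'
#' Individuals present in every gene are kept; their per-gene sequences are
#' pasted in the order given. Each gene is first trimmed to complete codons
#' so the concatenation stays in frame.
#'
#' @param alignments List of [species_alignment()] objects for one species.
#' @return A single [species_alignment()].
#' @export
concatenate_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  if (length(alignments) == 1L) {
    return(alignments[[1]])
  }
  ids <- Reduce(intersect, purrr::map(alignments, ~ names(.x$sequences)))
  if (length(ids) < 2L) {
    stop_insufficient("fewer than 2 individuals shared across genes")
  }
  trim <- function(a) {
    len <- nchar(a$sequences[1])
    nc <- (len - a$frame_offset) %/% 3L
    substr(a$sequences[ids], a$frame_offset + 1L, a$frame_offset + 3L * nc)
  }
  species_alignment(
    species_id = alignments[[1]]$species_id,
    sequences = setNames(
      do.call(paste0, purrr::map(alignments, trim)), ids
    ),
    gene_ids = unlist(purrr::map(alignments, "gene_ids")),
    frame_offset = 0L
  )
}

#' Aggregate per-gene diversity estimates into one species estimate
#'
#' When the genes were sequenced from the same individuals the caller must
#' concatenate the alignments first ([concatenate_alignments()]) and estimate
#' once; this function then simply passes the single estimate through. When
#' genes come from different individuals, piS is the unweighted mean of the
#' gene piS values and piN/piS the unweighted mean of the gene ratios over
#' genes with piS > 0 (the ratio is undefined for the rest); piN is reported
#' as piS x ratio for consistency.
#'
#' @param gene_estimates Tibble of [pairwise_pi()] rows (one per gene).
#' @param same_individuals Were all genes sequenced from the same
#'   individuals?
#' @return One-row tibble in the [pairwise_pi()] format.
#' @export
aggregate_species <- function(gene_estimates, same_individuals = FALSE) {
  stopifnot(is.data.frame(gene_estimates), nrow(gene_estimates) >= 1L)
  if (nrow(gene_estimates) == 1L) {
    return(as_tibble(gene_estimates))
  }
  if (same_individuals) {
    stop_format(paste0(
      "multiple estimates with same_individuals = TRUE: concatenate the ",
      "alignments with concatenate_alignments() and estimate once"
    ))
  }
  g <- gene_estimates
  pos <- g$pi_s > 0 & !is.na(g$ratio)
  pi_s <- mean(g$pi_s)
  ratio <- if (any(pos)) mean(g$ratio[pos]) else NA_real_
  tibble(
    species_id = g$species_id[1],
    n_individuals = max(g$n_individuals),
    pi_s = pi_s,
    pi_n = pi_s * ratio,
    ratio = ratio,
    syn_sites_total = sum(g$syn_sites_total),
    nonsyn_sites_total = sum(g$nonsyn_sites_total),
    n_pairs = as.integer(sum(g$n_pairs))
  )
}

#' Diversity estimates for a directory of FASTA alignments
#'
#' @param dir Directory of `.fa`/`.fasta` files, one species per file.
#' @inheritParams genetic_code
#' @param frame_offset Shared frame offset.
#' @return Tibble of [pairwise_pi()] rows, one per species.
#' @export
diversity_table <- function(dir, code = "vertebrate_mito", frame_offset = 0L) {
  files <- sort(list.files(dir, "\\.(fa|fasta)$", full.names = TRUE))
  if (!length(files)) stop_format(paste0("no FASTA files in ", dir))
  purrr::map_dfr(files, function(f) {
    pairwise_pi(read_alignment(f, frame_offset = frame_offset), code = code)
  })
}
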