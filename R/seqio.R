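# Reading and writing the formats the pipeline touches: FASTA codon
# alignments, newick trees, and delimited trait tables; plus assembly of the
# joined species-level dataset with the inclusion rules (zero-diversity
# species dropped, species absent from the tree dropped, everything logged).

#' Construct a species alignment
#'
#' An in-frame codon alignment of conspecific haplotypes: equal-length
#' sequences over A/C/G/T/N/-, at least two individuals, and at least one
#' complete codon after the frame offset. A trailing incomplete codon is
#' trimmed silently downstream.
#'
#' @param species_id Species identifier.
#' @param sequences Named character vector (names are individual ids).
#' @param gene_ids Character vector of gene names covered by the alignment.
#' @param frame_offset 0-based offset of the first complete codon.
#' @return A `species_alignment` object.
#' @export
species_alignment <- function(species_id, sequences, gene_ids = "gene1",
                              frame_offset = 0L) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    stop_format("sequences must be uniquely named by individual id")
  }
  sequences <- toupper(sequences)
  sequences <- gsub("U", "T", sequences, fixed = TRUE)
  if (any(grepl("[^ACGTN-]", sequences))) {
    stop_format("sequences may only contain A, C, G, T, N or '-'")
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop_format(paste0(
      "alignment '", species_id, "': sequences have unequal lengths (",
      paste(sort(unique(lens)), collapse = ", "), ")"
    ))
  }
  if (length(sequences) < 2L) {
    stop_insufficient(paste0(
      "alignment '", species_id, "' has fewer than 2 sequences"
    ))
  }
  if (lens[1] - frame_offset < 3L) {
    stop_format("alignment too short: need at least one codon after offset")
  }
  structure(
    list(
      species_id = species_id, sequences = sequences,
      gene_ids = gene_ids, frame_offset = as.integer(frame_offset)
    ),
    class = "species_alignment"
  )
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(
    "<species_alignment> ", x$species_id, ": ", length(x$sequences),
    " sequences x ", nchar(x$sequences[1]), " nt (frame offset ",
    x$frame_offset, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Read a FASTA codon alignment
#'
#' Sequences are case-folded to upper case and U is mapped to T. All records
#' must have equal length and there must be at least two of them.
#'
#' @param path FASTA file.
#' @param frame_offset 0-based offset of the first complete codon.
#' @param species_id Defaults to the file name without extension.
#' @param gene_ids Gene names, defaults to the species id.
#' @return A [species_alignment()].
#' @export
read_alignment <- function(path, frame_offset = 0L, species_id = NULL,
                           gene_ids = NULL) {
  species_id <- species_id %||% sub("\\.[^.]*$", "", basename(path))
  dss <- Biostrings::readBStringSet(path)
  species_alignment(
    species_id = species_id,
    sequences = setNames(as.character(dss), names(dss)),
    gene_ids = gene_ids %||% species_id,
    frame_offset = frame_offset
  )
}

#' Write a species alignment to FASTA
#'
#' @param alignment A [species_alignment()].
#' @param path Output file.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(alignment$sequences), path
  )
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Branch lengths are required, negative branch lengths and missing tip
#' labels are errors. Polytomies are preserved.
#'
#' @param path Newick file.
#' @return An `ape::phylo` tree.
#' @seealso [is_ultrametric()]
#' @export
read_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop_format(paste0("could not parse newick in ", path))
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length)) stop_format("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop_format("tree has negative branch lengths")
  if (is.null(tr$tip.label) || any(!nzchar(tr$tip.label))) {
    stop_format("tree has unlabeled tips")
  }
  if (anyDuplicated(tr$tip.label)) stop_format("tip labels must be unique")
  tr
}

#' Write a tree to newick
#' @param tree An `ape::phylo`.
#' @param path Output file.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Is a tree ultrametric?
#'
#' Relative criterion: the spread of root-to-tip depths divided by the
#' maximum depth must not exceed `tol`.
#'
#' @param tree An `ape::phylo`.
#' @param tol Relative tolerance (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  if (max(depths) <= 0) {
    return(FALSE)
  }
  (max(depths) - min(depths)) / max(depths) <= tol
}

#' Read a species trait table
#'
#' Delimited text (comma for `.csv`, tab for `.tsv`/`.txt`) with a header
#' containing `species_id`. Zero or negative trait values are invalid on a
#' log scale: they are flagged and treated as missing. Duplicated species are
#' an error.
#'
#' @param path File path.
#' @return A tibble, one row per species; invalid (non-positive) cells are
#'   recorded in the `"invalid_values"` attribute.
#' @export
read_trait_table <- function(path) {
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  tb <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!"species_id" %in% names(tb)) {
    stop_format("trait table must have a 'species_id' column")
  }
  if (anyDuplicated(tb$species_id)) {
    stop_format("duplicate species_id in trait table")
  }
  num_cols <- setdiff(names(tb), "species_id")
  invalid <- tibble(species_id = character(), trait = character(),
                    value = numeric())
  for (cl in num_cols) {
    bad <- which(!is.na(tb[[cl]]) & tb[[cl]] <= 0)
    if (length(bad)) {
      invalid <- bind_rows(invalid, tibble(
        species_id = tb$species_id[bad], trait = cl, value = tb[[cl]][bad]
      ))
      tb[[cl]][bad] <- NA_real_
    }
  }
  if (nrow(invalid)) {
    warn(paste0(
      nrow(invalid), " non-positive trait value(s) treated as missing ",
      "(log undefined)"
    ))
  }
  attr(tb, "invalid_values") <- invalid
  tb
}

#' Write a trait table
#' @param traits Tibble with `species_id`.
#' @param path Output `.csv` or `.tsv`.
#' @export
write_trait_table <- function(traits, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(traits, path)
  } else {
    readr::write_tsv(traits, path)
  }
  invisible(path)
}

#' Assemble the joined species-level dataset
#'
#' Applies the inclusion rules and log-transforms diversity and traits:
#' species with zero synonymous or nonsynonymous diversity are excluded
#' (their logs are undefined), as are species absent from the species tree or
#' without any trait value. The tree is pruned to the retained tips.
#'
#' @param diversity Tibble of per-species diversity estimates
#'   ([pairwise_pi()] rows bound together).
#' @param traits Trait tibble from [read_trait_table()].
#' @param tree Species tree (`ape::phylo`).
#' @param log_base Base for all log transforms (default 10; log-log slopes
#'   are base-invariant).
#' @return A `species_dataset`: list with `data` (tibble of log-scale
#'   diversity + traits), `tree` (pruned), `exclusions` (species_id, reason),
#'   `log_base`.
#' @export
assemble_dataset <- function(diversity, traits, tree, log_base = 10) {
  stopifnot(is.data.frame(diversity), "species_id" %in% names(diversity))
  tree <- validate_tree(tree)
  trait_cols <- setdiff(names(traits), "species_id")

  d <- as_tibble(diversity)
  excl <- tibble(species_id = character(), reason = character())
  # log piS is undefined without synonymous diversity; species without
  # nonsynonymous diversity stay in the piS analyses but their ratio is
  # missing (it drops out pairwise downstream)
  zero <- is.na(d$pi_s) | d$pi_s <= 0
  excl <- bind_rows(excl, tibble(
    species_id = d$species_id[zero], reason = "zero-diversity"
  ))
  d <- d[!zero, , drop = FALSE]

  in_tree <- d$species_id %in% tree$tip.label
  excl <- bind_rows(excl, tibble(
    species_id = d$species_id[!in_tree], reason = "no-tree"
  ))
  d <- d[in_tree, , drop = FALSE]

  tr_rows <- traits[match(d$species_id, traits$species_id), , drop = FALSE]
  has_trait <- rowSums(!is.na(tr_rows[, trait_cols, drop = FALSE])) > 0
  has_trait[is.na(has_trait)] <- FALSE
  excl <- bind_rows(excl, tibble(
    species_id = d$species_id[!has_trait], reason = "no-traits"
  ))
  d <- d[has_trait, , drop = FALSE]

  if (nrow(d) < 4L) {
    stop_insufficient(paste0(
      "only ", nrow(d), " species retained; need at least 4 ",
      "(contrasts need >= 3 tips, correlation >= 3 contrasts)"
    ))
  }

  lg <- function(x) log(x, base = log_base)
  tr_rows <- traits[match(d$species_id, traits$species_id), , drop = FALSE]
  logt <- purrr::map_dfc(
    setNames(trait_cols, paste0("log_", trait_cols)),
    function(cl) lg(tr_rows[[cl]])
  )
  ratio <- ifelse(!is.na(d$ratio) & d$ratio > 0, d$ratio, NA_real_)
  data <- dplyr::bind_cols(
    d,
    tibble(log_pi_s = lg(d$pi_s), log_ratio = lg(ratio)),
    logt
  )
  pruned <- ape::keep.tip(tree, data$species_id)

  structure(
    list(
      data = data, tree = pruned, exclusions = excl, log_base = log_base
    ),
    class = "species_dataset"
  )
}

#' @export
print.species_dataset <- function(x, ...) {
  cat(
    "<species_dataset> ", nrow(x$data), " species retained, ",
    nrow(x$exclusions), " excluded (log base ", x$log_base, ")\n",
    sep = ""
  )
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Log-scale variables available in an assembled dataset
#' @param dataset A `species_dataset`.
#' @return Character vector of `log_*` column names.
#' @export
dataset_log_vars <- function(dataset) {
  grep("^log_", names(dataset$data), value = TRUE)
}
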