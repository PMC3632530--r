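#' Construct an abundance table
#'
#' The abundance (OTU) table is the one mandatory component of an experiment:
#' a non-negative numeric matrix of taxa by samples. Input may be oriented
#' either way; the `taxa_are_rows` flag records the source orientation, and
#' the table is stored internally in the canonical taxa-by-samples
#' orientation so that all downstream computation uses a single code path.
#'
#' @param values numeric matrix with unique row and column names.
#' @param taxa_are_rows logical; `TRUE` if rows of `values` are taxa.
#' @return An object of class `abundance_table`: a list with `values`
#'   (taxa x samples matrix) and `taxa_are_rows` (the source orientation).
#' @export
abundance_table <- function(values, taxa_are_rows = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    otk_stop("abundance values must be a numeric matrix")
  }
  if (anyNA(values)) otk_stop("abundance values must not contain NA")
  if (any(values < 0)) otk_stop("abundance values must be non-negative")
  if (!taxa_are_rows) values <- t(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    otk_stop("abundance matrix must have taxon and sample names")
  }
  if (anyDuplicated(rownames(values))) otk_stop("duplicate taxon IDs in abundance table")
  if (anyDuplicated(colnames(values))) otk_stop("duplicate sample IDs in abundance table")
  structure(list(values = values, taxa_are_rows = taxa_are_rows),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d taxa x %d samples (source orientation: taxa are %s)\n",
              nrow(x$values), ncol(x$values),
              if (x$taxa_are_rows) "rows" else "columns"))
  invisible(x)
}

#' Construct a sample covariate table
#'
#' @param df data.frame of per-sample variables; sample IDs taken from
#'   row names (or a `sample_id` column, which is removed).
#' @return data.frame with class `c("sample_table","data.frame")`, one row
#'   per sample, row names = sample IDs.
#' @export
sample_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if ("sample_id" %in% names(df)) {
    rownames(df) <- as.character(df$sample_id)
    df$sample_id <- NULL
  }
  if (anyDuplicated(rownames(df))) otk_stop("duplicate sample IDs in sample table")
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Default taxonomic rank names (domain convention: Kingdom through Species)
#' @export
default_ranks <- function() {
  c("Kingdom", "Phylum", "Class", "Order", "Family", "Genus", "Species")
}

# Canonical missing representation for taxonomy entries: NA. Empty strings and
# whitespace-only entries are treated as the same missing value.
normalize_taxonomy_missing <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  x
}

#' Construct a taxonomy table
#'
#' @param assignments character matrix (taxa x ranks) with taxon IDs as row
#'   names; empty strings are normalized to `NA`.
#' @param ranks rank names in fixed coarse-to-fine order; defaults to the
#'   matrix column names, or [default_ranks()] prefixes when unnamed.
#' @return character matrix of class `taxonomy_table`.
#' @export
taxonomy_table <- function(assignments, ranks = NULL) {
  assignments <- as.matrix(assignments)
  storage.mode(assignments) <- "character"
  if (is.null(rownames(assignments))) otk_stop("taxonomy table must have taxon IDs as row names")
  if (anyDuplicated(rownames(assignments))) otk_stop("duplicate taxon IDs in taxonomy table")
  if (is.null(ranks)) {
    ranks <- colnames(assignments) %||% default_ranks()[seq_len(ncol(assignments))]
  }
  if (length(ranks) != ncol(assignments)) otk_stop("rank names do not match taxonomy columns")
  colnames(assignments) <- ranks
  assignments[] <- normalize_taxonomy_missing(assignments)
  class(assignments) <- c("taxonomy_table", class(assignments))
  assignments
}

#' Construct a reference sequence set
#'
#' @param seqs named character vector of nucleotide sequences (IUPAC
#'   alphabet), or a `Biostrings::DNAStringSet`.
#' @return named character vector of class `ref_seqs`.
#' @export
ref_seqs <- function(seqs) {
  if (methods::is(seqs, "XStringSet")) {
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    otk_stop("reference sequences must have unique taxon IDs as names")
  }
  # Validation through the IUPAC-aware DNA container.
  tryCatch(Biostrings::DNAStringSet(unname(seqs)),
           error = function(e) otk_stop("reference sequences are not valid IUPAC DNA: %s",
                                        conditionMessage(e)))
  structure(seqs, class = "ref_seqs")
}

# --- phylogenetic tree normalization ------------------------------------

#' Normalize a phylogenetic tree for use in an experiment
#'
#' Missing branch lengths are resolved to 0 and tip labels are checked for
#' uniqueness. An attribute `rooted` records rootedness at read time.
#'
#' @param tree an `ape::phylo` object.
#' @return the normalized `phylo` object.
#' @export
normalize_tree <- function(tree) {
  if (!inherits(tree, "phylo")) otk_stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label)) otk_stop("duplicate tip labels in tree")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (any(tree$edge.length < 0)) otk_stop("negative branch lengths in tree")
  attr(tree, "rooted") <- ape::is.rooted(tree)
  tree
}

# Degenerate single-tip tree (ape cannot prune down to one tip directly).
single_tip_tree <- function(label, length = 0) {
  tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                       tip.label = label,
                       edge.length = length,
                       Nnode = 1L),
                  class = "phylo")
  attr(tr, "rooted") <- TRUE
  tr
}

# Restrict a tree to keep_ids, contracting degree-2 nodes by summing the
# adjacent branch lengths so patristic distances among kept tips are invariant.
prune_tree_to <- function(tree, keep_ids) {
  if (length(keep_ids) == length(tree$tip.label) &&
      setequal(keep_ids, tree$tip.label)) {
    return(tree)
  }
  if (length(keep_ids) == 1L) {
    # root-to-tip length is retained on the single remaining edge
    depths <- ape::node.depth.edgelength(tree)
    tip_idx <- match(keep_ids, tree$tip.label)
    return(single_tip_tree(keep_ids, depths[tip_idx]))
  }
  out <- ape::keep.tip(tree, keep_ids)
  out <- normalize_tree(out)
  attr(out, "rooted") <- ape::is.rooted(out)
  out
}
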