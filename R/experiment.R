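#' Build an integrated microbiome experiment
#'
#' Assembles the multi-component experiment container from an abundance table
#' (mandatory) and optional sample covariates, taxonomy, phylogenetic tree and
#' reference sequences. Component ID sets are intersected rather than required
#' to match: taxa or samples absent from any supplied component are dropped
#' from all components (with the counts logged), and everything is reordered
#' to the canonical order of the abundance table. All validity checks are
#' consolidated here, so downstream functions can assume a consistent object.
#'
#' @param abundance an [abundance_table()].
#' @param samples optional [sample_table()] (data.frame, sample IDs as row names).
#' @param taxonomy optional [taxonomy_table()].
#' @param tree optional `ape::phylo` tree whose tip labels are taxon IDs.
#' @param refseq optional [ref_seqs()].
#' @return An object of class `mb_experiment`: a list with elements
#'   `abundance`, `samples`, `taxonomy`, `tree`, `refseq` (absent components
#'   are `NULL`).
#' @export
build_experiment <- function(abundance, samples = NULL, taxonomy = NULL,
                             tree = NULL, refseq = NULL) {
  if (missing(abundance) || is.null(abundance)) {
    otk_stop("an experiment without an abundance (OTU) table is invalid")
  }
  if (!inherits(abundance, "abundance_table")) {
    otk_stop("'abundance' must be an abundance_table")
  }
  if (!is.null(samples)) {
    if (!inherits(samples, "sample_table")) samples <- sample_table(samples)
    if (nrow(samples) == 0L) otk_stop("supplied sample table is empty")
  }
  if (!is.null(taxonomy)) {
    if (!inherits(taxonomy, "taxonomy_table")) taxonomy <- taxonomy_table(taxonomy)
    if (nrow(taxonomy) == 0L) otk_stop("supplied taxonomy table is empty")
  }
  if (!is.null(tree)) tree <- normalize_tree(tree)
  if (!is.null(refseq)) {
    if (!inherits(refseq, "ref_seqs")) refseq <- ref_seqs(refseq)
  }

  taxa <- rownames(abundance$values)
  intersect_ids <- function(current, other, what, component) {
    kept <- current[current %in% other]
    dropped <- length(current) - length(kept)
    if (dropped > 0L) {
      otk_log(sprintf("dropping %d %s absent from %s", dropped, what, component))
    }
    if (length(kept) == 0L) {
      otk_stop("empty %s intersection between abundance table and %s", what, component)
    }
    kept
  }
  if (!is.null(taxonomy)) taxa <- intersect_ids(taxa, rownames(taxonomy), "taxa", "taxonomy table")
  if (!is.null(tree))     taxa <- intersect_ids(taxa, tree$tip.label, "taxa", "tree")
  if (!is.null(refseq))   taxa <- intersect_ids(taxa, names(refseq), "taxa", "reference sequences")

  smp <- colnames(abundance$values)
  if (!is.null(samples)) smp <- intersect_ids(smp, rownames(samples), "samples", "sample table")

  n_drop_t <- nrow(abundance$values) - length(taxa)
  n_drop_s <- ncol(abundance$values) - length(smp)
  if (n_drop_t > 0L) otk_log(sprintf("abundance table: %d taxa dropped during assembly", n_drop_t))
  if (n_drop_s > 0L) otk_log(sprintf("abundance table: %d samples dropped during assembly", n_drop_s))

  values <- abundance$values[taxa, smp, drop = FALSE]
  abundance$values <- values
  if (!is.null(samples)) {
    samples <- samples[smp, , drop = FALSE]
    class(samples) <- c("sample_table", "data.frame")
  }
  if (!is.null(taxonomy)) {
    cls <- class(taxonomy)
    taxonomy <- taxonomy[taxa, , drop = FALSE]
    class(taxonomy) <- cls
  }
  if (!is.null(tree)) tree <- prune_tree_to(tree, taxa)
  if (!is.null(refseq)) refseq <- structure(refseq[taxa], class = "ref_seqs")

  exp <- structure(list(abundance = abundance, samples = samples,
                        taxonomy = taxonomy, tree = tree, refseq = refseq),
                   class = "mb_experiment")
  validate_experiment(exp)
  exp
}

validate_experiment <- function(exp) {
  stopifnot(inherits(exp, "mb_experiment"))
  taxa <- rownames(exp$abundance$values)
  smp <- colnames(exp$abundance$values)
  if (any(exp$abundance$values < 0)) otk_stop("negative abundance values")
  if (!is.null(exp$taxonomy) && !identical(rownames(exp$taxonomy), taxa)) {
    otk_stop("taxonomy taxon IDs do not match abundance order")
  }
  if (!is.null(exp$tree) && !setequal(exp$tree$tip.label, taxa)) {
    otk_stop("tree tips do not match abundance taxa")
  }
  if (!is.null(exp$refseq) && !identical(names(exp$refseq), taxa)) {
    otk_stop("reference sequence IDs do not match abundance order")
  }
  if (!is.null(exp$samples) && !identical(rownames(exp$samples), smp)) {
    otk_stop("sample table IDs do not match abundance order")
  }
  invisible(exp)
}

#' @export
print.mb_experiment <- function(x, ...) {
  cat(sprintf("mb_experiment: %d taxa x %d samples\n",
              nrow(x$abundance$values), ncol(x$abundance$values)))
  comp <- c(samples = !is.null(x$samples), taxonomy = !is.null(x$taxonomy),
            tree = !is.null(x$tree), refseq = !is.null(x$refseq))
  cat("components:", paste(names(comp)[comp], collapse = ", ") %||% "", "\n")
  invisible(x)
}

#' Accessors for experiment components
#'
#' @param exp an `mb_experiment`.
#' @return `taxon_ids`/`sample_ids`: character vectors in canonical order;
#'   `abundances`: the taxa x samples numeric matrix.
#' @export
taxon_ids <- function(exp) rownames(exp$abundance$values)

#' @rdname taxon_ids
#' @export
sample_ids <- function(exp) colnames(exp$abundance$values)

#' @rdname taxon_ids
#' @export
abundances <- function(exp) exp$abundance$values

#' @rdname taxon_ids
#' @export
n_taxa <- function(exp) nrow(exp$abundance$values)

#' @rdname taxon_ids
#' @export
n_samples <- function(exp) ncol(exp$abundance$values)

# Replace the abundance matrix, keeping orientation metadata.
set_abundances <- function(exp, values) {
  exp$abundance$values <- values
  exp
}

#' Restrict an experiment to a set of taxa
#'
#' The restriction propagates across all components: abundance rows, taxonomy
#' rows and reference sequences are subset, and the tree is pruned with
#' degree-2 nodes contracted by branch-length addition (patristic distances
#' among kept tips are unchanged). Relative order is preserved.
#'
#' @param keep_ids taxon IDs to keep; must be a subset of `taxon_ids(exp)`.
#' @param exp an `mb_experiment`.
#' @return the pruned `mb_experiment`.
#' @export
prune_taxa <- function(keep_ids, exp) {
  keep_ids <- as.character(keep_ids)
  if (length(keep_ids) == 0L) otk_stop("prune_taxa: empty set of taxa to keep")
  unknown <- setdiff(keep_ids, taxon_ids(exp))
  if (length(unknown) > 0L) {
    otk_stop("prune_taxa: unknown taxon IDs: %s", paste(unknown, collapse = ", "))
  }
  keep <- taxon_ids(exp)[taxon_ids(exp) %in% keep_ids]  # preserve canonical order
  exp$abundance$values <- exp$abundance$values[keep, , drop = FALSE]
  if (!is.null(exp$taxonomy)) {
    cls <- class(exp$taxonomy)
    exp$taxonomy <- exp$taxonomy[keep, , drop = FALSE]
    class(exp$taxonomy) <- cls
  }
  if (!is.null(exp$refseq)) exp$refseq <- structure(exp$refseq[keep], class = "ref_seqs")
  if (!is.null(exp$tree)) exp$tree <- prune_tree_to(exp$tree, keep)
  validate_experiment(exp)
}

#' Restrict an experiment to a set of samples
#'
#' Mirror of [prune_taxa()] for the sample dimension: abundance columns and
#' sample-table rows are subset, other components are untouched.
#'
#' @inheritParams prune_taxa
#' @param keep_ids sample IDs to keep.
#' @return the pruned `mb_experiment`.
#' @export
prune_samples <- function(keep_ids, exp) {
  keep_ids <- as.character(keep_ids)
  if (length(keep_ids) == 0L) otk_stop("prune_samples: empty set of samples to keep")
  unknown <- setdiff(keep_ids, sample_ids(exp))
  if (length(unknown) > 0L) {
    otk_stop("prune_samples: unknown sample IDs: %s", paste(unknown, collapse = ", "))
  }
  keep <- sample_ids(exp)[sample_ids(exp) %in% keep_ids]
  exp$abundance$values <- exp$abundance$values[, keep, drop = FALSE]
  if (!is.null(exp$samples)) {
    exp$samples <- exp$samples[keep, , drop = FALSE]
    class(exp$samples) <- c("sample_table", "data.frame")
  }
  validate_experiment(exp)
}

#' Merge a set of taxa into one archetype taxon
#'
#' Abundance rows of `ids` are summed into the row of `archetype`; the other
#' components keep only the archetype entry. Per-sample totals are conserved
#' exactly. This is the shared primitive behind taxonomic and tree-based
#' agglomeration.
#'
#' @param exp an `mb_experiment`.
#' @param ids taxon IDs to merge (subset of `taxon_ids(exp)`).
#' @param archetype the ID (must be in `ids`) that represents the merged taxon.
#' @return the merged `mb_experiment`.
#' @export
merge_taxa <- function(exp, ids, archetype = ids[[1]]) {
  ids <- as.character(ids)
  unknown <- setdiff(ids, taxon_ids(exp))
  if (length(unknown) > 0L) {
    otk_stop("merge_taxa: unknown taxon IDs: %s", paste(unknown, collapse = ", "))
  }
  if (!archetype %in% ids) otk_stop("merge_taxa: archetype must be one of the merged IDs")
  if (length(ids) == 1L) return(exp)
  merged <- colSums(exp$abundance$values[ids, , drop = FALSE])
  exp$abundance$values[archetype, ] <- merged
  drop_ids <- setdiff(ids, archetype)
  keep <- setdiff(taxon_ids(exp), drop_ids)
  prune_taxa(keep, exp)
}
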