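# Filtering, transformation, subsampling and agglomeration.

#' Transform abundance values
#'
#' * `relative`: each sample column divided by its column sum.
#' * `log1p_base`: `x -> log(1 + x) / log(param)` (param = logarithm base).
#' * `rank`: within-sample ranks (average ties).
#' * `even_depth_scale`: each column rescaled to sum to `param` (real-valued
#'   scaling, not subsampling; see [rarefy_even_depth()] for subsampling).
#'
#' @param exp an `mb_experiment`.
#' @param kind one of `"relative"`, `"log1p_base"`, `"rank"`,
#'   `"even_depth_scale"`.
#' @param param the base for `log1p_base`, the target depth for
#'   `even_depth_scale`.
#' @return the transformed `mb_experiment`.
#' @export
transform_counts <- function(exp, kind = c("relative", "log1p_base", "rank", "even_depth_scale"),
                             param = NULL) {
  kind <- match.arg(kind)
  x <- abundances(exp)
  if (length(x) == 0L) otk_stop("abundance table is empty")
  if (kind %in% c("relative", "even_depth_scale")) {
    cs <- colSums(x)
    zero <- colnames(x)[cs == 0]
    if (length(zero) > 0L) {
      otk_stop("sample(s) with zero total abundance cannot be %s-transformed: %s",
               kind, paste(zero, collapse = ", "))
    }
  }
  out <- switch(kind,
    relative = sweep(x, 2, colSums(x), "/"),
    log1p_base = {
      if (is.null(param) || param <= 1) otk_stop("log1p_base requires a base > 1 via 'param'")
      log1p(x) / log(param)
    },
    rank = apply(x, 2, rank, ties.method = "average"),
    even_depth_scale = {
      if (is.null(param) || param <= 0) otk_stop("even_depth_scale requires a positive target depth via 'param'")
      sweep(x, 2, colSums(x) / param, "/")
    })
  dimnames(out) <- dimnames(x)
  set_abundances(exp, out)
}

#' Rarefy all samples to an even sequencing depth
#'
#' Each sample is randomly subsampled (without replacement by default) to
#' exactly `depth` reads. Samples whose total is below `depth` are dropped
#' with a logged warning; taxa left with all-zero rows are removed. The result
#' is a deterministic function of `(exp, depth, seed, replace)` — a seed is
#' required, never defaulted.
#'
#' @param exp an `mb_experiment` with integer counts.
#' @param depth target depth (positive integer).
#' @param seed integer random seed (required).
#' @param replace sample with replacement instead of without.
#' @return the rarefied `mb_experiment`.
#' @export
rarefy_even_depth <- function(exp, depth, seed, replace = FALSE) {
  if (missing(seed)) otk_stop("rarefy_even_depth requires an explicit 'seed'")
  x <- abundances(exp)
  if (!is_wholenumber(x)) otk_stop("rarefaction requires integer counts")
  depth <- as.integer(depth)
  if (depth < 1L) otk_stop("depth must be a positive integer")
  totals <- colSums(x)
  keep <- colnames(x)[totals >= depth]
  dropped <- setdiff(colnames(x), keep)
  if (length(keep) == 0L) otk_stop("no sample reaches depth %d", depth)
  if (length(dropped) > 0L) {
    otk_log(sprintf("rarefy_even_depth: dropping %d sample(s) below depth %d: %s",
                    length(dropped), depth, paste(dropped, collapse = ", ")), "warn")
    exp <- prune_samples(keep, exp)
    x <- abundances(exp)
  }
  set.seed(as.integer(seed))
  out <- apply(x, 2, function(col) {
    if (replace) {
      draws <- sample.int(length(col), size = depth, replace = TRUE,
                          prob = col / sum(col))
    } else {
      pool <- rep.int(seq_along(col), times = round(col))
      draws <- pool[sample.int(length(pool), size = depth, replace = FALSE)]
    }
    tabulate(draws, nbins = length(col))
  })
  dimnames(out) <- dimnames(x)
  exp <- set_abundances(exp, out)
  nonzero <- taxon_ids(exp)[rowSums(out) > 0]
  if (length(nonzero) < n_taxa(exp)) exp <- prune_taxa(nonzero, exp)
  exp
}

#' Keep taxa exceeding a count threshold in enough samples
#'
#' Keeps taxa whose count exceeds `a` in at least
#' `ceiling(k_fraction * n_samples)` samples. The conventional "observed at
#' least 3 times in 20% of samples" trim is `k_fraction = 0.2, a = 2`
#' (count > 2 is count >= 3).
#'
#' @param exp an `mb_experiment`.
#' @param k_fraction fraction of samples, in (0, 1].
#' @param a strict count threshold (keep requires count > a).
#' @return the filtered `mb_experiment`.
#' @export
filter_taxa_k_over_a <- function(exp, k_fraction, a) {
  if (k_fraction <= 0 || k_fraction > 1) otk_stop("k_fraction must be in (0, 1]")
  k <- ceiling(k_fraction * n_samples(exp))
  x <- abundances(exp)
  keep <- taxon_ids(exp)[rowSums(x > a) >= k]
  if (length(keep) == 0L) {
    otk_stop("filter_taxa_k_over_a(k_fraction=%g, a=%g) removes every taxon", k_fraction, a)
  }
  prune_taxa(keep, exp)
}

#' Keep taxa with coefficient of variation above a threshold
#'
#' The coefficient of variation is sd/mean per taxon across samples, with the
#' sample (n-1) standard deviation. Taxa with CV strictly greater than
#' `cv_min` are kept; all-zero taxa are removed unconditionally.
#'
#' @param exp an `mb_experiment` with at least 2 samples.
#' @param cv_min CV threshold (keep requires CV > cv_min).
#' @return the filtered `mb_experiment`.
#' @export
filter_taxa_cv <- function(exp, cv_min) {
  if (n_samples(exp) < 2L) otk_stop("CV filter needs at least 2 samples")
  x <- abundances(exp)
  m <- rowMeans(x)
  s <- apply(x, 1, stats::sd)
  cv <- ifelse(m > 0, s / m, 0)
  keep <- taxon_ids(exp)[m > 0 & cv > cv_min]
  if (length(keep) == 0L) otk_stop("filter_taxa_cv(cv_min=%g) removes every taxon", cv_min)
  prune_taxa(keep, exp)
}

# Most-abundant archetype, ties broken by lexicographically smallest ID.
pick_archetype <- function(exp, ids) {
  totals <- rowSums(abundances(exp)[ids, , drop = FALSE])
  cand <- ids[totals == max(totals)]
  sort(cand)[1]
}

#' Agglomerate taxa sharing a taxonomic assignment
#'
#' Taxa with identical assignments from the coarsest rank down to `rank` are
#' merged via [merge_taxa()]; the archetype is the most abundant member (ties
#' broken by lexicographically smallest ID). Taxa missing an assignment at
#' `rank` are dropped when `na_rm = TRUE`, otherwise grouped by their exact
#' shared prefix.
#'
#' @param exp an `mb_experiment` with a taxonomy table.
#' @param rank a rank name of the taxonomy table.
#' @param na_rm drop taxa unassigned at `rank`.
#' @return the agglomerated `mb_experiment`.
#' @export
tax_glom <- function(exp, rank, na_rm = TRUE) {
  if (is.null(exp$taxonomy)) otk_stop("tax_glom requires a taxonomy table")
  ranks <- colnames(exp$taxonomy)
  if (!rank %in% ranks) otk_stop("unknown rank '%s' (available: %s)", rank,
                                 paste(ranks, collapse = ", "))
  upto <- seq_len(match(rank, ranks))
  asn <- exp$taxonomy[, upto, drop = FALSE]
  if (na_rm) {
    assigned <- taxon_ids(exp)[!is.na(asn[, length(upto)])]
    if (length(assigned) == 0L) otk_stop("no taxon is assigned at rank '%s'", rank)
    if (length(assigned) < n_taxa(exp)) {
      otk_log(sprintf("tax_glom: dropping %d taxa unassigned at %s",
                      n_taxa(exp) - length(assigned), rank))
      exp <- prune_taxa(assigned, exp)
      asn <- exp$taxonomy[, upto, drop = FALSE]
    }
  }
  key <- apply(asn, 1, function(r) paste(ifelse(is.na(r), "\r<NA>", r), collapse = "\r"))
  groups <- split(taxon_ids(exp), key)
  for (ids in groups) {
    if (length(ids) > 1L) exp <- merge_taxa(exp, ids, pick_archetype(exp, ids))
  }
  exp
}

#' Agglomerate taxa by phylogenetic proximity
#'
#' Complete-linkage agglomerative clustering of taxa on cophenetic (patristic)
#' distances, cut at height `h`; every pair of merged tips is therefore within
#' `h` of each other. Clusters are merged via [merge_taxa()] with the
#' most-abundant archetype.
#'
#' @param exp an `mb_experiment` with a tree.
#' @param h cut height (> 0) on the patristic distance scale.
#' @return the agglomerated `mb_experiment`.
#' @export
tip_glom <- function(exp, h) {
  if (is.null(exp$tree)) otk_stop("tip_glom requires a phylogenetic tree")
  if (h <= 0) otk_stop("h must be > 0")
  if (n_taxa(exp) < 2L) return(exp)
  d <- stats::as.dist(ape::cophenetic.phylo(exp$tree))
  hc <- stats::hclust(d, method = "complete")
  cl <- stats::cutree(hc, h = h)
  groups <- split(names(cl), cl)
  for (ids in groups) {
    if (length(ids) > 1L) exp <- merge_taxa(exp, ids, pick_archetype(exp, ids))
  }
  exp
}
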