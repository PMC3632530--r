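# Synthetic experiment generation: random trees plus group-structured
# multinomial counts, so every part of the toolkit is testable without
# external data. Not a realistic microbiome simulator (no zero-inflation or
# overdispersion model) — a controlled null/alternative generator.

#' Random coalescent-style tree
#'
#' Coalescent topology with independent exponential branch lengths
#' (mean 0.1), tips labeled `OTU1..OTUn`. Deterministic given `seed`.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed (required).
#' @return a rooted `ape::phylo`.
#' @export
random_tree <- function(n_tips, seed) {
  if (missing(seed)) otk_stop("random_tree requires an explicit 'seed'")
  if (n_tips < 2L) otk_stop("n_tips must be >= 2")
  set.seed(as.integer(seed))
  tree <- ape::rcoal(n_tips, tip.label = paste0("OTU", seq_len(n_tips)))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 10)
  normalize_tree(tree)
}

# Hierarchically consistent taxonomy: each rank refines the previous one.
random_taxonomy <- function(taxon_ids) {
  n <- length(taxon_ids)
  ranks <- default_ranks()[1:6]  # Kingdom..Genus
  n_groups <- c(1, 3, 5, 8, 12, 20)
  asn <- matrix(NA_character_, n, length(ranks), dimnames = list(taxon_ids, ranks))
  parent <- rep("Bacteria", n)
  asn[, 1] <- parent
  for (j in 2:length(ranks)) {
    g <- sample.int(n_groups[j], n, replace = TRUE)
    parent <- paste0(parent, ".", substr(ranks[j], 1, 1), g)
    asn[, j] <- parent
  }
  taxonomy_table(asn, ranks = ranks)
}

#' Simulate a group-structured experiment
#'
#' Per-sample counts are multinomial draws of size `depth` from group-specific
#' proportion vectors: a single Dirichlet(1) draw provides the base
#' proportions, and in every second group the first `effect_taxa` components
#' are multiplied by `effect_size` and renormalized. `effect_size = 1` makes
#' the groups exchangeable (the null configuration for error-rate
#' calibration). A random tree, a hierarchically consistent taxonomy and a
#' sample table with the group label are attached.
#'
#' @param n_taxa,n_samples,n_groups dimensions (samples are assigned to groups
#'   round-robin).
#' @param effect_taxa number of taxa carrying the group effect.
#' @param effect_size multiplicative effect (1 = null).
#' @param depth per-sample total count.
#' @param seed integer seed (required).
#' @return an `mb_experiment` with all components.
#' @export
simulate_experiment <- function(n_taxa = 50, n_samples = 20, n_groups = 2,
                                effect_taxa = 5, effect_size = 1,
                                depth = 1000, seed) {
  if (missing(seed)) otk_stop("simulate_experiment requires an explicit 'seed'")
  if (effect_taxa > n_taxa) otk_stop("effect_taxa must be <= n_taxa")
  if (n_groups > n_samples) otk_stop("n_groups must be <= n_samples")
  if (n_taxa < 2L || n_samples < 1L) otk_stop("invalid sizes")
  tree <- random_tree(n_taxa, seed = derive_seed(seed, 7))
  set.seed(as.integer(seed))
  base <- stats::rgamma(n_taxa, shape = 1)
  base <- base / sum(base)
  props <- lapply(seq_len(n_groups), function(g) {
    p <- base
    if (g %% 2 == 0 && effect_taxa > 0) {
      p[seq_len(effect_taxa)] <- p[seq_len(effect_taxa)] * effect_size
    }
    p / sum(p)
  })
  group <- rep(seq_len(n_groups), length.out = n_samples)
  counts <- vapply(seq_len(n_samples), function(s) {
    drop(stats::rmultinom(1, size = depth, prob = props[[group[s]]]))
  }, numeric(n_taxa))
  taxa <- paste0("OTU", seq_len(n_taxa))
  smp <- sprintf("S%02d", seq_len(n_samples))
  dimnames(counts) <- list(taxa, smp)
  samples <- sample_table(data.frame(Group = paste0("G", group),
                                     row.names = smp, stringsAsFactors = FALSE))
  taxonomy <- random_taxonomy(taxa)
  build_experiment(abundance_table(counts, taxa_are_rows = TRUE),
                   samples = samples, taxonomy = taxonomy, tree = tree)
}
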