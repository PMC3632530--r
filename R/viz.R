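# Deterministic data/layout computations behind the six standard microbiome
# plots. These return plain labeled tables; rendering (ggplot2 or otherwise)
# is the caller's concern.

#' Coordinate tables for plotting an ordination
#'
#' Joins ordination coordinates with sample variables (samples) or taxonomy
#' ranks (taxa). `display = "biplot"` concatenates both with a `type` column,
#' `"split"` returns them separately. Scree proportions are computed over the
#' positive eigenvalues.
#'
#' @param exp the ordinated `mb_experiment`.
#' @param ord an `ordination_result`.
#' @param display `"samples"`, `"taxa"`, `"biplot"` or `"split"`.
#' @param axes pair of axis indices to extract.
#' @return list with `data` (for samples/taxa/biplot) or `samples` + `taxa`
#'   (for split), and `scree` (proportion of total positive inertia per axis,
#'   `NULL` when the method carries no eigenvalues).
#' @export
ordination_plot_data <- function(exp, ord, display = c("samples", "taxa", "biplot", "split"),
                                 axes = c(1, 2)) {
  display <- match.arg(display)
  if (length(axes) != 2L) otk_stop("axes must be a pair of axis indices")
  if (max(axes) > ncol(ord$sample_coords)) {
    otk_stop("requested axis %d but the ordination has only %d axes",
             max(axes), ncol(ord$sample_coords))
  }
  sample_df <- function() {
    df <- data.frame(id = rownames(ord$sample_coords),
                     ord$sample_coords[, axes, drop = FALSE],
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(exp$samples)) {
      df <- cbind(df, as.data.frame(exp$samples)[df$id, , drop = FALSE])
    }
    rownames(df) <- NULL
    df
  }
  taxa_df <- function() {
    if (is.null(ord$taxa_coords)) {
      otk_stop(paste0("this ordination carries no taxa coordinates (distance-based ",
                      "methods place only samples); use a table-based method for taxa displays"))
    }
    df <- data.frame(id = rownames(ord$taxa_coords),
                     ord$taxa_coords[, axes, drop = FALSE],
                     stringsAsFactors = FALSE, check.names = FALSE)
    if (!is.null(exp$taxonomy)) {
      df <- cbind(df, as.data.frame(unclass(exp$taxonomy)[df$id, , drop = FALSE]))
    }
    rownames(df) <- NULL
    df
  }
  scree <- NULL
  if (!is.null(ord$eigenvalues)) {
    pos <- ord$eigenvalues[ord$eigenvalues > 0]
    scree <- pos / sum(pos)
  }
  out <- switch(display,
    samples = list(data = sample_df()),
    taxa = list(data = taxa_df()),
    biplot = {
      s <- sample_df(); t_ <- taxa_df()
      s$type <- "sample"; t_$type <- "taxon"
      common <- intersect(names(s), names(t_))
      list(data = rbind(s[common], t_[common]))
    },
    split = list(samples = sample_df(), taxa = taxa_df()))
  out$scree <- scree
  out
}

# Sort IDs by the angle of their first-two-axes coordinates, ascending within
# (-pi, pi], ties broken by ID (lexicographic) for determinism.
angle_order <- function(coords) {
  theta <- atan2(coords[, 2], coords[, 1])
  ids <- rownames(coords)
  ids[order(theta, ids)]
}

#' Sample (and taxa) orderings for an ordination-organized heatmap
#'
#' Objects are ordered by the radial coordinate angle of their position in the
#' first two axes of an ordination (NMDS of Bray-Curtis by default), which
#' places similar profiles next to one another without the arbitrary
#' adjacencies of dendrogram leaf orders. Taxa are ordered by the same
#' ordination applied in taxa space (distances among taxa over the transposed
#' table); tree-based distances have no taxa-space analogue and are rejected.
#'
#' @param exp an `mb_experiment` with >= 3 samples.
#' @param ord_method ordination method (`"NMDS"` or `"MDS"`/`"PCoA"`).
#' @param distance_method a [distance()] registry method.
#' @param order_taxa also compute the taxa ordering.
#' @param seed integer seed (NMDS restarts).
#' @return list with `sample_order`, `taxa_order` (or `NULL`) and the
#'   recommended abundance color transform recorded as metadata.
#' @export
heatmap_order <- function(exp, ord_method = "NMDS", distance_method = "bray",
                          order_taxa = TRUE, seed) {
  if (missing(seed)) otk_stop("heatmap_order requires an explicit 'seed'")
  if (n_samples(exp) < 3L) otk_stop("heatmap ordering needs at least 3 samples")
  if (order_taxa && distance_method %in% c("unifrac", "wunifrac", "dpcoa-dist")) {
    otk_stop("taxa ordering is not defined for tree-based distances; pick e.g. 'bray'")
  }
  ord <- ordinate(exp, ord_method, distance_method = distance_method,
                  seed = derive_seed(seed, 1))
  sample_order <- angle_order(ord$sample_coords[, 1:2, drop = FALSE])
  taxa_order <- NULL
  if (order_taxa) {
    flipped <- build_experiment(abundance_table(t(abundances(exp)), taxa_are_rows = TRUE))
    tord <- ordinate(flipped, ord_method, distance_method = distance_method,
                     seed = derive_seed(seed, 2))
    taxa_order <- angle_order(tord$sample_coords[, 1:2, drop = FALSE])
  }
  list(sample_order = sample_order, taxa_order = taxa_order,
       color_transform = "log(1 + x)/log(4)")
}

#' Threshold co-occurrence network
#'
#' Connects two samples (or taxa) whenever their ecological distance is
#' strictly below `max_dist`; isolated nodes are retained. Node attributes are
#' joined from the sample table (samples) or taxonomy (taxa).
#'
#' @param exp an `mb_experiment` with >= 2 units.
#' @param unit `"samples"` or `"taxa"`.
#' @param distance_method a [distance()] registry method.
#' @param max_dist edge threshold (edges satisfy d < max_dist).
#' @return An object of class `mb_graph`: list with `nodes` (data.frame of IDs
#'   + attributes) and `edges` (data.frame from/to/distance).
#' @export
make_network <- function(exp, unit = c("samples", "taxa"),
                         distance_method = "jaccard", max_dist = 0.4) {
  unit <- match.arg(unit)
  if (unit == "taxa") {
    work <- build_experiment(abundance_table(t(abundances(exp)), taxa_are_rows = TRUE))
    d <- distance(work, distance_method)
    attrs <- if (!is.null(exp$taxonomy)) as.data.frame(unclass(exp$taxonomy)) else NULL
  } else {
    d <- distance(exp, distance_method)
    attrs <- if (!is.null(exp$samples)) as.data.frame(exp$samples) else NULL
  }
  m <- as.matrix(d)
  if (nrow(m) < 2L) otk_stop("make_network needs at least 2 %s", unit)
  ids <- rownames(m)
  pair_idx <- which(upper.tri(m) & m < max_dist, arr.ind = TRUE)
  edges <- data.frame(from = ids[pair_idx[, 1]], to = ids[pair_idx[, 2]],
                      distance = m[pair_idx], stringsAsFactors = FALSE)
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(attrs)) nodes <- cbind(nodes, attrs[ids, , drop = FALSE])
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, unit = unit,
                 distance_method = distance_method, max_dist = max_dist),
            class = "mb_graph")
}

#' Force-directed layout for a threshold network
#'
#' Fruchterman-Reingold spring layout (via igraph), deterministic given
#' `seed`, with coordinates centered at the origin. The relative positions
#' optimise the display of network structure and are otherwise arbitrary.
#'
#' @param g an `mb_graph` from [make_network()].
#' @param seed integer seed (required).
#' @return data.frame with `id`, `x`, `y`.
#' @export
network_layout <- function(g, seed) {
  if (missing(seed)) otk_stop("network_layout requires an explicit 'seed'")
  n <- nrow(g$nodes)
  if (n == 1L) {
    return(data.frame(id = g$nodes$id, x = 0, y = 0, stringsAsFactors = FALSE))
  }
  ig <- igraph::graph_from_data_frame(g$edges[, c("from", "to")],
                                      directed = FALSE, vertices = g$nodes$id)
  set.seed(as.integer(seed))
  xy <- igraph::layout_with_fr(ig, dim = 2)
  xy <- scale(xy, center = TRUE, scale = FALSE)
  data.frame(id = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2],
             stringsAsFactors = FALSE)
}

#' Segment and marker tables for an annotated tree plot
#'
#' Tips receive integer vertical positions in the tree's (postorder) tip
#' order; internal nodes sit at the mean of their children; horizontal
#' positions are cumulative branch lengths from the root. One marker is
#' emitted per (tip, sample with count > 0), offset horizontally in successive
#' columns beside the tip, carrying the abundance and any mapped sample
#' variables. A warning is logged above 200 tips, where a tree display stops
#' being readable.
#'
#' @param exp an `mb_experiment` with a tree.
#' @param color_var,shape_var optional sample-variable names carried onto the
#'   markers.
#' @return list with `segments` (x, xend, y, yend), `tips` (tip label
#'   positions) and `markers`.
#' @export
tree_plot_data <- function(exp, color_var = NULL, shape_var = NULL) {
  if (is.null(exp$tree)) otk_stop("tree_plot_data requires a tree")
  tree <- exp$tree
  n_tip <- length(tree$tip.label)
  if (n_tip > 200L) {
    otk_log(sprintf("tree has %d tips; plots beyond ~200 tips are rarely readable — consider agglomerating or subsetting", n_tip), "warn")
  }
  for (v in c(color_var, shape_var)) {
    if (!is.null(exp$samples) && !v %in% colnames(exp$samples)) {
      otk_stop("unknown sample variable '%s'", v)
    }
  }
  xpos <- ape::node.depth.edgelength(tree)
  n_node <- n_tip + tree$Nnode
  ypos <- numeric(n_node)
  post <- ape::reorder.phylo(tree, "postorder")
  ypos[seq_len(n_tip)] <- order(order(match(seq_len(n_tip), post$edge[, 2])))
  # internal nodes at the mean of their children, resolved in postorder
  for (i in seq_len(nrow(post$edge))) {
    parent <- post$edge[i, 1]
    kids <- post$edge[post$edge[, 1] == parent, 2]
    ypos[parent] <- mean(ypos[kids])
  }
  seg_h <- data.frame(x = xpos[post$edge[, 1]], xend = xpos[post$edge[, 2]],
                      y = ypos[post$edge[, 2]], yend = ypos[post$edge[, 2]])
  seg_v <- do.call(rbind, lapply(unique(post$edge[, 1]), function(p) {
    kids <- post$edge[post$edge[, 1] == p, 2]
    data.frame(x = xpos[p], xend = xpos[p],
               y = min(ypos[kids]), yend = max(ypos[kids]))
  }))
  segments <- rbind(seg_h, seg_v)
  tips <- data.frame(taxon = tree$tip.label,
                     x = xpos[seq_len(n_tip)], y = ypos[seq_len(n_tip)],
                     stringsAsFactors = FALSE)
  x <- abundances(exp)
  offset_step <- max(xpos) * 0.02 + 1e-9
  base_x <- max(xpos)
  markers <- do.call(rbind, lapply(seq_len(n_tip), function(t_idx) {
    taxon <- tree$tip.label[t_idx]
    present <- which(x[taxon, ] > 0)
    if (length(present) == 0L) return(NULL)
    df <- data.frame(taxon = taxon,
                     sample = colnames(x)[present],
                     abundance = x[taxon, present],
                     x = base_x + offset_step * seq_along(present),
                     y = tips$y[tips$taxon == taxon],
                     stringsAsFactors = FALSE)
    for (v in c(color_var, shape_var)) df[[v]] <- exp$samples[df$sample, v]
    df
  }))
  rownames(markers) <- NULL
  list(segments = segments, tips = tips, markers = markers)
}

#' Stacked-segment table for abundance bar plots
#'
#' Abundances are aggregated per (x group, fill label) cell; within each x
#' position the segments are stacked in decreasing order of abundance, so the
#' aggregate bar height equals the group total.
#'
#' @param exp an `mb_experiment`.
#' @param x `"Sample"` or the name of a sample variable defining horizontal
#'   positions.
#' @param fill optional taxonomy rank whose labels colour the segments (taxa
#'   sharing the label are summed first); default one segment per taxon.
#' @param facet optional taxonomy rank or sample variable; stacking is within
#'   (x, facet) cells.
#' @return data.frame with columns `x`, `facet` (if requested), `fill`,
#'   `abundance`, `bottom`, `top`.
#' @export
bar_plot_data <- function(exp, x = "Sample", fill = NULL, facet = NULL) {
  mat <- abundances(exp)
  ranks <- if (!is.null(exp$taxonomy)) colnames(exp$taxonomy) else character(0)
  svars <- if (!is.null(exp$samples)) colnames(exp$samples) else character(0)
  group_of_sample <- function(var) {
    if (identical(var, "Sample")) return(stats::setNames(colnames(mat), colnames(mat)))
    if (!var %in% svars) otk_stop("unknown sample variable '%s'", var)
    stats::setNames(as.character(exp$samples[[var]]), colnames(mat))
  }
  label_of_taxon <- function(var) {
    if (!var %in% ranks) otk_stop("unknown taxonomy rank '%s'", var)
    lab <- exp$taxonomy[, var]
    ifelse(is.na(lab), "Unassigned", lab)
  }
  xg <- group_of_sample(x)
  fill_lab <- if (is.null(fill)) taxon_ids(exp) else label_of_taxon(fill)
  facet_lab <- NULL
  if (!is.null(facet)) {
    if (facet %in% ranks) {
      facet_lab <- list(kind = "taxa", lab = label_of_taxon(facet))
    } else {
      facet_lab <- list(kind = "samples", lab = group_of_sample(facet))
    }
  }
  long <- data.frame(taxon = rep(taxon_ids(exp), times = ncol(mat)),
                     sample = rep(colnames(mat), each = nrow(mat)),
                     abundance = as.vector(mat), stringsAsFactors = FALSE)
  long$x <- xg[long$sample]
  long$fill <- rep(fill_lab, times = ncol(mat))
  if (!is.null(facet_lab)) {
    long$facet <- if (facet_lab$kind == "taxa") rep(facet_lab$lab, times = ncol(mat))
                  else facet_lab$lab[long$sample]
  }
  keys <- c("x", if (!is.null(facet_lab)) "facet", "fill")
  agg <- stats::aggregate(long["abundance"], by = long[keys], FUN = sum)
  cell_keys <- c("x", if (!is.null(facet_lab)) "facet")
  split_key <- interaction(agg[cell_keys], drop = TRUE)
  pieces <- lapply(split(agg, split_key), function(df) {
    df <- df[order(-df$abundance, df$fill), , drop = FALSE]
    df$top <- cumsum(df$abundance)
    df$bottom <- df$top - df$abundance
    df
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[, c(keys, "abundance", "bottom", "top")]
}

#' Long table of richness estimates for plotting
#'
#' One row per (sample, measure), joined with the grouping variables;
#' standard errors are present only for the Chao1 and ACE rows.
#'
#' @param exp an `mb_experiment`.
#' @param x sample variable for horizontal grouping.
#' @param color optional sample variable for colour shading.
#' @param measures passed to [estimate_richness()].
#' @return data.frame with sample, x, color, measure, estimate, se.
#' @export
richness_plot_data <- function(exp, x, color = NULL,
                               measures = c("Observed", "Chao1", "Shannon")) {
  est <- estimate_richness(exp, measures)
  if (is.null(exp$samples) || !x %in% colnames(exp$samples)) {
    otk_stop("unknown sample variable '%s'", x)
  }
  se_col <- c(Chao1 = "se.chao1", ACE = "se.ACE")
  rows <- lapply(measures, function(m) {
    data.frame(sample = rownames(est),
               x = exp$samples[rownames(est), x],
               color = if (!is.null(color)) exp$samples[rownames(est), color] else NA,
               measure = m,
               estimate = est[[m]],
               se = if (m %in% names(se_col)) est[[se_col[[m]]]] else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
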