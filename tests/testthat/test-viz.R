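test_that("ordination plot data joins covariates and normalizes the scree", {
  e <- tiny_experiment()
  ord <- ordinate(e, "CA")
  s <- ordination_plot_data(e, ord, "samples")
  expect_equal(nrow(s$data), n_samples(e))
  expect_true(all(c("Group", "pH") %in% colnames(s$data)))
  t_ <- ordination_plot_data(e, ord, "taxa")
  expect_equal(nrow(t_$data), n_taxa(e))
  expect_true("Phylum" %in% colnames(t_$data))
  b <- ordination_plot_data(e, ord, "biplot")
  expect_equal(nrow(b$data), n_samples(e) + n_taxa(e))
  expect_setequal(unique(b$data$type), c("sample", "taxon"))
  sp <- ordination_plot_data(e, ord, "split")
  expect_named(sp, c("samples", "taxa", "scree"))
  expect_equal(sum(sp$scree), 1)
  # distance-based ordinations have no taxa scores for these displays
  ord_d <- ordinate(e, "PCoA", "bray")
  expect_error(ordination_plot_data(e, ord_d, "biplot"), "taxa")
  expect_error(ordination_plot_data(e, ord, axes = c(1, 50)), "axis")
})

test_that("heatmap ordering sorts by radial angle with deterministic ties", {
  # points at known angles: 10, 90, 200 degrees -> order S10, S90, S200
  coords <- rbind(S200 = c(cos(200 * pi / 180), sin(200 * pi / 180)),
                  S10 = c(cos(10 * pi / 180), sin(10 * pi / 180)),
                  S90 = c(cos(90 * pi / 180), sin(90 * pi / 180)))
  expect_identical(otukit:::angle_order(coords), c("S200", "S10", "S90"))
  # 200 deg maps to a negative angle, hence first in (-pi, pi]
  dup <- rbind(B = c(1, 1), A = c(1, 1))
  expect_identical(otukit:::angle_order(dup), c("A", "B"))  # tie -> ID order

  e <- simulate_experiment(n_taxa = 12, n_samples = 8, seed = 51)
  hm <- heatmap_order(e, seed = 3)
  expect_setequal(hm$sample_order, sample_ids(e))
  expect_setequal(hm$taxa_order, taxon_ids(e))
  hm2 <- heatmap_order(e, seed = 3)
  expect_identical(hm, hm2)
  expect_error(heatmap_order(e, distance_method = "unifrac", seed = 1), "taxa")
})

test_that("threshold networks connect exactly the close pairs", {
  # hand case: d(1,2) = 0.2, d(1,3) = 0.6, d(2,3) = 0.5 and threshold 0.4
  # give exactly the edge {1,2}; realised below on Bray-Curtis distances
  x <- matrix(c(10, 0,
                 9, 1,
                 2, 8), 2, 3, dimnames = list(c("A", "B"), c("S1", "S2", "S3")))
  e3 <- build_experiment(abundance_table(x))
  d3 <- as.matrix(distance(e3, "bray"))
  expect_equal(d3["S1", "S2"], 0.1)
  g3 <- make_network(e3, distance_method = "bray", max_dist = 0.4)
  expect_equal(nrow(g3$edges), 1L)
  expect_setequal(unlist(g3$edges[1, c("from", "to")]), c("S1", "S2"))

  e <- simulate_experiment(n_taxa = 10, n_samples = 6, seed = 53)
  g_all <- make_network(e, distance_method = "bray", max_dist = 2)
  expect_equal(nrow(g_all$edges), choose(6, 2))      # complete graph
  g_none <- make_network(e, distance_method = "bray", max_dist = 0)
  expect_equal(nrow(g_none$edges), 0L)
  expect_equal(nrow(g_none$nodes), 6L)               # isolated nodes retained
  d <- as.matrix(distance(e, "bray"))
  thr <- stats::median(d[upper.tri(d)])
  g_mid <- make_network(e, distance_method = "bray", max_dist = thr)
  expect_equal(nrow(g_mid$edges), sum(d[upper.tri(d)] < thr))
  expect_true(all(g_mid$edges$distance < thr))
  expect_true("Group" %in% colnames(g_mid$nodes))
})

test_that("network layouts are seeded, centered, and respect structure", {
  e <- simulate_experiment(n_taxa = 10, n_samples = 8, seed = 55)
  g <- make_network(e, distance_method = "bray", max_dist = 1)
  l1 <- network_layout(g, seed = 4)
  l2 <- network_layout(g, seed = 4)
  expect_identical(l1, l2)
  expect_equal(colMeans(as.matrix(l1[, c("x", "y")])), c(x = 0, y = 0),
               tolerance = 1e-9)
  expect_error(network_layout(g), "seed")
  # single node at the origin
  e1 <- prune_samples(sample_ids(e)[1:2], e)
  g1 <- make_network(e1, distance_method = "bray", max_dist = 0)
  g1$nodes <- g1$nodes[1, , drop = FALSE]
  expect_equal(network_layout(g1, seed = 1)[, c("x", "y")],
               data.frame(x = 0, y = 0))
  # connected nodes end up closer than disconnected ones in a path graph
  set.seed(0)
  ok <- 0
  for (s in 1:5) {
    gp <- list(nodes = data.frame(id = c("a", "b", "c", "d")),
               edges = data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                                  distance = 0.1))
    class(gp) <- "mb_graph"
    l <- network_layout(gp, seed = s)
    rownames(l) <- l$id
    dd <- as.matrix(stats::dist(l[, c("x", "y")]))
    if (dd["a", "b"] < dd["a", "d"]) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("tree plot layout emits one marker per nonzero tip/sample entry", {
  e <- tiny_experiment()
  tp <- tree_plot_data(e, color_var = "Group")
  expect_equal(nrow(tp$markers), sum(abundances(e) > 0))
  expect_true(all(tp$markers$abundance > 0))
  expect_true("Group" %in% colnames(tp$markers))
  # a taxon observed in 3 samples gets 3 successive markers
  n_A <- sum(abundances(e)["A", ] > 0)
  mk <- tp$markers[tp$markers$taxon == "A", ]
  expect_equal(nrow(mk), n_A)
  expect_equal(length(unique(mk$x)), n_A)           # successive offsets
  expect_equal(length(unique(mk$y)), 1L)
  # tips sit at integer heights, one per tip
  expect_setequal(tp$tips$y, seq_len(n_taxa(e)))
  # markers sit beyond the deepest tip
  expect_true(all(tp$markers$x > max(tp$tips$x)))
  e$tree <- NULL
  expect_error(tree_plot_data(e), "tree")
})

test_that("large trees trigger the readability warning", {
  e <- simulate_experiment(n_taxa = 201, n_samples = 3, depth = 2000, seed = 57)
  expect_message(tree_plot_data(e), "200")
})

test_that("bar plot stacking is cumulative, ordered, and conserves totals", {
  x <- matrix(c(5, 3, 2), 3, 1, dimnames = list(c("T1", "T2", "T3"), "S1"))
  e <- build_experiment(abundance_table(x))
  bp <- bar_plot_data(e)
  expect_equal(bp$bottom, c(0, 5, 8))
  expect_equal(bp$top, c(5, 8, 10))
  e2 <- tiny_experiment()
  bp2 <- bar_plot_data(e2, fill = "Phylum")
  tot <- tapply(bp2$top, bp2$x, max)
  expect_equal(as.vector(tot[sample_ids(e2)]), unname(colSums(abundances(e2))))
  # same-phylum taxa merge before stacking
  expect_equal(sum(bp2$x == "S1"), length(unique(e2$taxonomy[, "Phylum"])))
  agg <- tapply(bp2$abundance, bp2$fill, sum)
  expect_equal(unname(agg["Firmicutes"]),
               sum(abundances(e2)[c("A", "B"), ]))
  expect_error(bar_plot_data(e2, x = "nope"), "nope")
})

test_that("richness plot data is long, joined, and delegates estimates", {
  e <- simulate_experiment(n_taxa = 15, n_samples = 5, seed = 59)
  rp <- richness_plot_data(e, x = "Group", measures = c("Observed", "Chao1"))
  expect_equal(nrow(rp), 10L)                 # 5 samples x 2 measures
  est <- estimate_richness(e, c("Observed", "Chao1"))
  expect_equal(rp$estimate[rp$measure == "Chao1"], est$Chao1)
  expect_true(all(is.na(rp$se[rp$measure == "Observed"])))
  expect_true(all(!is.na(rp$se[rp$measure == "Chao1"])))
})

test_that("layout computations are pure functions of their inputs", {
  e <- simulate_experiment(n_taxa = 10, n_samples = 6, seed = 61)
  expect_identical(bar_plot_data(e, fill = "Phylum"), bar_plot_data(e, fill = "Phylum"))
  expect_identical(tree_plot_data(e), tree_plot_data(e))
  expect_identical(heatmap_order(e, seed = 2), heatmap_order(e, seed = 2))
})
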