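test_that("CA matches its chi-square inertia oracle and closed forms", {
  # diagonal 2x2: one nontrivial axis with eigenvalue 1
  x <- matrix(c(10, 0, 0, 10), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  res <- ca(x)
  expect_equal(length(res$eigenvalues), 1L)
  expect_equal(res$eigenvalues, 1)

  # a rank-1 (independence) table has zero inertia
  r1 <- outer(c(1, 2, 3), c(4, 5))
  dimnames(r1) <- list(paste0("T", 1:3), paste0("S", 1:2))
  expect_equal(length(ca(r1)$eigenvalues), 0L)

  # total inertia equals chi-square statistic / N on random tables
  set.seed(7)
  for (rep in 1:5) {
    tab <- matrix(stats::rpois(20, 8) + 1, 4, 5,
                  dimnames = list(paste0("T", 1:4), paste0("S", 1:5)))
    res <- ca(tab)
    chi <- suppressWarnings(stats::chisq.test(tab)$statistic)
    expect_equal(res$details$total_inertia, unname(chi) / sum(tab), tolerance = 1e-10)
    expect_equal(sum(res$eigenvalues), unname(chi) / sum(tab), tolerance = 1e-10)
  }
  # zero margins are named errors
  bad <- matrix(c(0, 0, 1, 2), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_error(ca(bad), "A")
})

test_that("CA eigenvalues agree with the independent vegan implementation", {
  set.seed(11)
  tab <- matrix(stats::rpois(30, 6) + 1, 5, 6,
                dimnames = list(paste0("T", 1:5), paste0("S", 1:6)))
  res <- ca(tab)
  ref <- vegan::cca(t(tab))
  expect_equal(unname(res$eigenvalues), unname(ref$CA$eig), tolerance = 1e-10)
})

test_that("PCoA recovers Euclidean configurations and splits two points evenly", {
  set.seed(3)
  pts <- matrix(stats::rnorm(24), 8, 3)
  rownames(pts) <- paste0("S", 1:8)
  d <- stats::dist(pts)
  res <- pcoa(d)
  expect_equal(as.matrix(stats::dist(res$sample_coords)), as.matrix(d),
               tolerance = 1e-8)
  # two points at distance 7 are placed at +/- 3.5 on one axis
  m2 <- matrix(c(0, 7, 7, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  r2 <- pcoa(stats::as.dist(m2))
  expect_equal(unname(sort(abs(r2$sample_coords[, 1]))), c(3.5, 3.5))
  # equilateral triangle: two equal positive eigenvalues
  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  r3 <- pcoa(stats::as.dist(m3))
  pos <- r3$eigenvalues[r3$eigenvalues > 1e-12]
  expect_equal(length(pos), 2L)
  expect_equal(pos[1], pos[2], tolerance = 1e-12)
  # collinear points: a single positive eigenvalue
  line <- stats::dist(matrix(c(0, 1, 3), 3, 1))
  rl <- pcoa(line)
  expect_equal(sum(rl$eigenvalues > 1e-12), 1L)
  expect_equal(as.vector(stats::dist(rl$sample_coords)), as.vector(line))
})

test_that("PCoA retains negative eigenvalues on non-Euclidean input", {
  e <- simulate_experiment(n_taxa = 12, n_samples = 8, seed = 13)
  d <- distance(e, "bray")
  suppressMessages(res <- pcoa(d))
  expect_true(any(res$eigenvalues < 0))
  expect_equal(ncol(res$sample_coords), sum(res$eigenvalues > max(res$eigenvalues) * 1e-9))
})

test_that("NMDS is seeded, near-zero on embeddable input, rotation-invariant", {
  set.seed(21)
  pts <- matrix(stats::rnorm(20), 10, 2, dimnames = list(paste0("S", 1:10), NULL))
  d <- stats::dist(pts)
  r1 <- nmds(d, k = 2, seed = 5)
  expect_lte(r1$stress, 1e-6)
  r2 <- nmds(d, k = 2, seed = 5)
  expect_identical(r1$sample_coords, r2$sample_coords)
  expect_identical(r1$stress, r2$stress)
  # stress evaluated independently is invariant under rotation/reflection
  s0 <- kruskal_stress1(r1$sample_coords, d)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(kruskal_stress1(r1$sample_coords %*% R, d), s0, tolerance = 1e-9)
  expect_equal(kruskal_stress1(r1$sample_coords %*% diag(c(-1, 1)), d), s0,
               tolerance = 1e-9)
  expect_error(nmds(d, k = 12, seed = 1), "smaller")
  zero <- stats::as.dist(matrix(0, 3, 3))
  expect_error(nmds(zero, seed = 1), "degenerate")
})

test_that("NMDS never ends above the stress of its metric initialization", {
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(6:10, 1)
    y <- matrix(stats::runif(n * 4), n, 4)
    d <- stats::dist(y) + stats::as.dist(matrix(stats::runif(n * n, 0, 0.2), n, n))
    suppressMessages(init <- pcoa(d)$sample_coords[, 1:2])
    res <- nmds(d, k = 2, n_starts = 3, seed = rep)
    expect_lte(res$stress, kruskal_stress1(init, d) + 1e-9)
  }
})

test_that("PCA carries full variance on a line and preserves the trace", {
  y <- cbind(x = 1:6, y = 2 * (1:6))
  res <- pca(y)
  expect_equal(res$eigenvalues[1] / sum(res$eigenvalues), 1)
  set.seed(4)
  z <- matrix(stats::rnorm(40), 8, 5)
  res2 <- pca(z)
  expect_equal(sum(res2$eigenvalues), sum(apply(z, 2, stats::var)), tolerance = 1e-12)
  # scaling makes the result invariant to per-column rescaling
  res_s <- pca(z, scale = TRUE)
  res_s2 <- pca(sweep(z, 2, c(1, 10, 100, 0.1, 5), "*"), scale = TRUE)
  expect_equal(abs(res_s$sample_coords), abs(res_s2$sample_coords), tolerance = 1e-8)
  expect_error(pca(cbind(z, const = rep(1, 8)), scale = TRUE), "zero-variance")
})

test_that("RDA decomposes inertia exactly and matches rank arguments", {
  e <- simulate_experiment(n_taxa = 15, n_samples = 12, n_groups = 2, seed = 17)
  res <- constrained_ordination(e, "RDA", "Group")
  expect_equal(res$details$constrained_inertia + res$details$unconstrained_inertia,
               res$details$total_inertia, tolerance = 1e-8)
  # one binary constraint: exactly one constrained axis
  expect_equal(res$details$n_constrained_axes, 1L)
  # intercept-only: zero constrained inertia
  res0 <- constrained_ordination(e, "RDA", character(0))
  expect_equal(res0$details$constrained_inertia, 0)
  # constraints spanning the whole sample space reproduce PCA
  full <- sample_table(data.frame(matrix(stats::rnorm(12 * 11), 12),
                                  row.names = sample_ids(e)))
  ef <- build_experiment(e$abundance, samples = full)
  resf <- constrained_ordination(ef, "RDA", colnames(full))
  refp <- pca(t(abundances(e)))
  expect_equal(sort(resf$details$constrained_eigenvalues, decreasing = TRUE),
               unname(refp$eigenvalues[refp$eigenvalues > 1e-9]), tolerance = 1e-8)
})

test_that("RDA and CCA inertias agree with the independent vegan engines", {
  e <- simulate_experiment(n_taxa = 15, n_samples = 12, n_groups = 3, seed = 19)
  Y <- t(abundances(e))
  grp <- factor(e$samples$Group)
  ours_r <- constrained_ordination(e, "RDA", "Group")
  ref_r <- vegan::rda(Y ~ grp)
  expect_equal(ours_r$details$constrained_inertia, unname(ref_r$CCA$tot.chi),
               tolerance = 1e-8)
  expect_equal(ours_r$details$total_inertia, unname(ref_r$tot.chi), tolerance = 1e-8)
  ours_c <- constrained_ordination(e, "CCA", "Group")
  ref_c <- vegan::cca(Y ~ grp)
  expect_equal(ours_c$details$constrained_inertia, unname(ref_c$CCA$tot.chi),
               tolerance = 1e-8)
  expect_equal(ours_c$details$total_inertia, unname(ref_c$tot.chi), tolerance = 1e-8)
})

test_that("DPCoA sample distances equal the Rao dissimilarity oracle", {
  e <- simulate_experiment(n_taxa = 10, n_samples = 6, seed = 23)
  res <- dpcoa(e)
  D <- ape::cophenetic.phylo(e$tree)[taxon_ids(e), taxon_ids(e)]
  p <- sweep(abundances(e), 2, colSums(abundances(e)), "/")
  got <- as.matrix(stats::dist(res$sample_coords))
  for (i in 1:5) for (j in (i + 1):6) {
    v <- p[, i] - p[, j]
    rao <- -0.5 * drop(v %*% D %*% v)
    expect_equal(got[i, j]^2, rao, tolerance = 1e-10)
  }
  # identical samples land on identical coordinates
  x2 <- cbind(abundances(e), DUP = abundances(e)[, 1])
  e2 <- build_experiment(abundance_table(x2), tree = e$tree)
  r2 <- dpcoa(e2)
  expect_equal(r2$sample_coords["DUP", ], r2$sample_coords[sample_ids(e)[1], ],
               tolerance = 1e-10)
})

test_that("DPCoA on a star tree is proportional to non-phylogenetic distances", {
  # equal branch lengths L: patristic distance is 2L between all pairs, so
  # Rao d^2 reduces to L * sum((p_i - q_i)^2) = L * euclidean^2 on profiles
  n <- 5
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(2, n)
  tr$tip.label <- paste0("OTU", 1:n)
  set.seed(31)
  x <- matrix(stats::rpois(n * 4, 5) + 1, n, 4,
              dimnames = list(tr$tip.label, paste0("S", 1:4)))
  e <- build_experiment(abundance_table(x), tree = tr)
  res <- dpcoa(e)
  p <- sweep(x, 2, colSums(x), "/")
  eu <- stats::dist(t(p))
  got <- stats::dist(res$sample_coords)
  expect_equal(as.vector(got)^2, 2 * as.vector(eu)^2, tolerance = 1e-10)
})

test_that("ordinate dispatches, requires seeds for NMDS, and refuses DCA", {
  e <- simulate_experiment(n_taxa = 12, n_samples = 8, seed = 29)
  e <- prune_taxa(taxon_ids(e)[rowSums(abundances(e)) > 0], e)  # CA needs positive rows
  o1 <- ordinate(e, "MDS", "unifrac")
  expect_equal(o1$method, "MDS")
  expect_equal(o1$details$distance_method, "unifrac")
  expect_equal(rownames(o1$sample_coords), sample_ids(e))
  o2 <- ordinate(e, "CA")
  expect_equal(o2$method, "CA")
  expect_false(is.null(o2$taxa_coords))
  o3a <- ordinate(e, "NMDS", "bray", seed = 1)
  o3b <- ordinate(e, "NMDS", "bray", seed = 1)
  expect_identical(o3a$sample_coords, o3b$sample_coords)
  expect_error(ordinate(e, "NMDS", "bray"), "seed")
  expect_error(ordinate(e, "DCA"), "not implemented")
  expect_error(ordinate(e, "UMAP"), "supported")
  # precomputed dist objects are accepted
  o4 <- ordinate(e, "PCoA", distance_method = distance(e, "bray"))
  expect_equal(o4$details$distance_method, "bray")
})
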