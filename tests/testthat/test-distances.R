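test_that("the distance registry is large, stable and duplicate-free", {
  methods <- list_distance_methods()
  expect_gt(length(methods), 40)
  expect_identical(anyDuplicated(methods), 0L)
  expect_true(all(c("unifrac", "wunifrac", "bray", "jaccard", "jsd") %in% methods))
  expect_identical(methods, list_distance_methods())  # stable order
})

test_that("quantitative distances match hand-evaluated formulas", {
  x <- t(matrix(c(1, 0, 3,
                  2, 1, 1), 2, byrow = TRUE,
                dimnames = list(c("S1", "S2"), c("A", "B", "C"))))
  e <- build_experiment(abundance_table(x))
  expect_equal(as.vector(distance(e, "bray")), 4 / 8)   # sum|x-y| / sum(x+y)
  # difference vector (3, 4) -> euclidean distance 5
  y <- matrix(c(1, 1, 4, 5), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  e2 <- build_experiment(abundance_table(y))
  expect_equal(as.vector(distance(e2, "euclidean")), 5)
  # a pair involving an all-zero sample is an error, not NaN
  z0 <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_error(distance(build_experiment(abundance_table(z0)), "bray"), "S2")
  # identical presence patterns have zero Jaccard dissimilarity
  z <- matrix(c(5, 1, 2, 8), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  ez <- build_experiment(abundance_table(z))
  expect_equal(as.vector(distance(ez, "jaccard", binary = TRUE)), 0)
  expect_error(distance(e, "nosuch"), "bray")  # error lists the registry
})

test_that("jsd is a symmetric bounded divergence with closed-form values", {
  x <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  e <- build_experiment(abundance_table(x))
  expect_equal(as.vector(distance(e, "jsd")), log(2))  # disjoint profiles
  x2 <- matrix(c(2, 2, 1, 1), 2, dimnames = list(c("A", "B"), c("S1", "S2")))
  expect_equal(as.vector(distance(build_experiment(abundance_table(x2)), "jsd")), 0)
})

test_that("betadiver incidence indices agree with their published formulas", {
  # a = shared, b,c = unique; Whittaker w = (b+c)/(2a+b+c)
  x <- matrix(c(1, 1, 1, 0,
                0, 1, 1, 1), 4, 2,
              dimnames = list(paste0("T", 1:4), c("S1", "S2")))
  e <- build_experiment(abundance_table(x))
  a <- 2; b <- 1; cc <- 1
  expect_equal(as.vector(distance(e, "w")), (b + cc) / (2 * a + b + cc))
  expect_equal(as.vector(distance(e, "j")), a / (a + b + cc))       # Jaccard similarity
  expect_equal(as.vector(distance(e, "sor")), 2 * a / (2 * a + b + cc))
})

test_that("branch_abundance fills descendant totals by a single traversal", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  x <- matrix(c(1, 0, 2,
                0, 1, 3,
                0, 0, 0), 3,
              dimnames = list(c("A", "B", "C"), c("S1", "S2", "S3")))
  e <- build_experiment(abundance_table(x), tree = tree)
  ba <- branch_abundance(tree, e$abundance)
  # the edge above the (A,B) cherry carries counts(A) + counts(B)
  post <- ba$tree
  cherry_edge <- which(post$edge[, 2] > length(post$tip.label))
  expect_equal(ba$descendant_totals[cherry_edge, ],
               x["A", ] + x["B", ])
  # an all-zero sample has all-zero descendant totals
  expect_true(all(ba$descendant_totals[, "S3"] == 0))
  expect_equal(unname(ba$tip_depths["A"]), 2)
  expect_equal(unname(ba$tip_depths["C"]), 2)
  # unrooted trees are refused with rooting advice
  tru <- ape::read.tree(text = "(A:1,B:1,C:1);")
  eu <- build_experiment(abundance_table(x), tree = tru)
  expect_error(branch_abundance(tru, eu$abundance), "midpoint")
})

test_that("unifrac reproduces hand-enumerated branch sums", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  x <- matrix(c(1, 0, 0,
                0, 1, 0,
                0, 0, 1), 3, dimnames = list(c("A", "B", "C"), c("SA", "SB", "SC")))
  e <- build_experiment(abundance_table(x), tree = tree)
  m <- as.matrix(unifrac(e, weighted = FALSE))
  expect_equal(m["SA", "SB"], 2 / 3)     # unique 1+1 over union 1+1+1
  expect_equal(m["SA", "SC"], 1)         # disjoint: all branches unique
  # identical samples at distance zero under every variant
  x2 <- cbind(x, SA2 = x[, "SA"])
  e2 <- build_experiment(abundance_table(x2), tree = tree)
  for (w in c(FALSE, TRUE)) for (nm in c(TRUE, FALSE)) {
    d <- as.matrix(unifrac(e2, weighted = w, normalized = nm))
    expect_equal(d["SA", "SA2"], 0)
  }
  # zero-total sample is an error naming the sample
  x3 <- x; x3[, "SB"] <- 0
  e3 <- build_experiment(abundance_table(x3), tree = tree)
  expect_error(unifrac(e3), "SB")
})

test_that("fast unifrac equals the brute-force oracle on random trees", {
  set.seed(42)
  for (s in 1:20) {
    nt <- sample(3:8, 1)
    tr <- random_tree(nt, seed = s)
    x <- matrix(stats::rpois(nt * 4, 3), nt, 4,
                dimnames = list(paste0("OTU", seq_len(nt)), paste0("S", 1:4)))
    x[sample(length(x), length(x) %/% 3)] <- 0
    x <- x[, colSums(x) > 0, drop = FALSE]
    if (ncol(x) < 2) next
    e <- build_experiment(abundance_table(x), tree = tr)
    for (w in c(FALSE, TRUE)) for (nm in c(TRUE, FALSE)) {
      d <- as.matrix(unifrac(e, weighted = w, normalized = nm))
      for (i in 1:(ncol(x) - 1)) for (j in (i + 1):ncol(x)) {
        expect_equal(d[i, j],
                     oracle_unifrac(tr, abundances(e), w, nm, i, j),
                     tolerance = 1e-12)
      }
      if (!w || nm) expect_true(all(d >= -1e-15 & d <= 1 + 1e-12))
    }
  }
})

test_that("chunked pair computation merges to the serial result bitwise", {
  e <- simulate_experiment(n_taxa = 15, n_samples = 12, seed = 3)
  serial <- unifrac(e, weighted = TRUE, normalized = TRUE, chunks = 1)
  for (ch in c(2, 5, 11)) {
    expect_identical(unclass(unifrac(e, weighted = TRUE, normalized = TRUE, chunks = ch))[],
                     unclass(serial)[])
  }
})

test_that("distances are symmetric with zero diagonal and euclidean is metric", {
  e <- simulate_experiment(n_taxa = 12, n_samples = 6, seed = 8)
  for (m in c("bray", "jaccard", "jsd", "manhattan", "unifrac", "wunifrac", "dpcoa-dist")) {
    dm <- as.matrix(distance(e, m))
    expect_equal(dm, t(dm))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm >= 0))
  }
  # triangle inequality for euclidean on random inputs
  set.seed(1)
  for (rep in 1:10) {
    y <- matrix(stats::runif(30, 0, 10), 5, 6,
                dimnames = list(paste0("T", 1:5), paste0("S", 1:6)))
    d <- as.matrix(distance(build_experiment(abundance_table(y)), "euclidean"))
    n <- ncol(y)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("tree-dependent methods demand a tree", {
  e <- tiny_experiment()
  e$tree <- NULL
  expect_error(distance(e, "unifrac"), "tree")
  expect_error(distance(e, "dpcoa-dist"), "tree")
})
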