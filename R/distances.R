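# The unified ecological distance dispatch. Quantitative indices are delegated
# to vegan::vegdist, the 24 presence/absence incidence indices to
# vegan::betadiver; UniFrac, Jensen-Shannon divergence and the DPCoA distance
# are computed natively.

.vegdist_methods <- c("manhattan", "euclidean", "canberra", "bray", "kulczynski",
                      "jaccard", "gower", "altGower", "morisita", "horn",
                      "mountford", "raup", "binomial", "chao", "cao", "chisq")

.betadiver_methods <- c("w", "-1", "c", "wb", "r", "I", "e", "t", "me", "j",
                        "sor", "m", "-2", "co", "cc", "g", "-3", "l", "19",
                        "hk", "rlb", "sim", "gl", "z")

.native_methods <- c("jsd", "unifrac", "wunifrac", "dpcoa-dist")

#' List the supported ecological distance methods
#'
#' The registry holds more than 40 named methods: 16 quantitative
#' dissimilarities, the Jensen-Shannon divergence, three phylogenetic
#' distances (unweighted UniFrac, weighted UniFrac, DPCoA distance), and the
#' 24 classical presence/absence incidence indices of the `betadiver` family,
#' each defined by its standard published formula.
#'
#' @return character vector of method names in stable registry order.
#' @export
list_distance_methods <- function() {
  c(.vegdist_methods, .native_methods, .betadiver_methods)
}

# Jensen-Shannon divergence between relative-abundance profiles (natural log,
# 0 log 0 = 0). Symmetric, bounded by log 2.
jsd_dist <- function(x) {
  # x: samples x taxa, rows are counts or abundances
  p <- sweep(x, 1, rowSums(x), "/")
  n <- nrow(p)
  m <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      mid <- (p[i, ] + p[j, ]) / 2
      m[i, j] <- m[j, i] <- 0.5 * kl(p[i, ], mid) + 0.5 * kl(p[j, ], mid)
    }
  }
  stats::as.dist(m)
}

# DPCoA distance between samples: the full-space sample distance of double
# principal coordinates analysis, sqrt(-1/2 (p_k - p_l)' D (p_k - p_l)) with
# D the patristic distance matrix and p the relative-abundance profiles.
dpcoa_dist <- function(exp) {
  if (is.null(exp$tree)) otk_stop("method 'dpcoa-dist' requires a phylogenetic tree")
  D <- ape::cophenetic.phylo(exp$tree)[taxon_ids(exp), taxon_ids(exp)]
  p <- sweep(abundances(exp), 2, colSums(abundances(exp)), "/")
  n <- ncol(p)
  m <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- p[, i] - p[, j]
      m[i, j] <- m[j, i] <- sqrt(max(0, -0.5 * drop(v %*% D %*% v)))
    }
  }
  stats::as.dist(m)
}

#' Pairwise ecological distances between samples
#'
#' Single dispatch over the method registry of [list_distance_methods()].
#' Phylogenetic methods (`unifrac`, `wunifrac`, `dpcoa-dist`) require a tree;
#' `wunifrac` here is the normalized weighted UniFrac (use [unifrac()]
#' directly for the raw variant).
#'
#' @param exp an `mb_experiment`.
#' @param method a registry method name.
#' @param binary reduce counts to presence/absence before computing
#'   (incidence indices do this by definition).
#' @return a `stats::dist` over samples with attribute `method`.
#' @export
distance <- function(exp, method, binary = FALSE) {
  if (!method %in% list_distance_methods()) {
    otk_stop("unknown distance method '%s'; supported methods: %s",
             method, paste(list_distance_methods(), collapse = ", "))
  }
  x <- abundances(exp)
  zero <- colnames(x)[colSums(x) == 0]
  if (length(zero) > 0L) {
    otk_stop("sample(s) with zero total abundance: %s", paste(zero, collapse = ", "))
  }
  if (binary) {
    x <- (x > 0) * 1
    exp <- set_abundances(exp, x)
  }
  xs <- t(x)  # samples as rows for vegan
  d <- if (method %in% .vegdist_methods) {
    vegan::vegdist(xs, method = method)
  } else if (method %in% .betadiver_methods) {
    vegan::betadiver(xs, method = method)
  } else if (method == "jsd") {
    jsd_dist(xs)
  } else if (method == "unifrac") {
    unifrac(exp, weighted = FALSE)
  } else if (method == "wunifrac") {
    unifrac(exp, weighted = TRUE, normalized = TRUE)
  } else if (method == "dpcoa-dist") {
    dpcoa_dist(exp)
  }
  attr(d, "method") <- method
  d
}

#' Write a distance matrix as a labeled square TSV
#' @param d a `stats::dist`.
#' @param path output path.
#' @export
write_distance_tsv <- function(d, path) {
  m <- as.matrix(d)
  out <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
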