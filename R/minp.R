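# Westfall-Young step-down minP permutation testing for taxon-wise group
# comparisons. Permutations act on sample labels jointly across taxa so the
# dependence structure among taxa is preserved, as minP requires. Statistics
# for all taxa and all permutations are computed from group sums via matrix
# products, so B permutations cost a handful of matrix multiplications.

# All permutations of 1..n (small n only), as an n! x n matrix.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# Group-wise statistics for every permutation at once.
# x: taxa x samples; perm: n_perm x n matrix of label orderings applied to the
# group vector. Returns taxa x n_perm matrix of statistics.
perm_statistics <- function(x, g, perm, stat) {
  n <- ncol(x)
  k <- nlevels(g)
  n_perm <- nrow(perm)
  gi <- as.integer(g)
  # indicator blocks: columns (perm-1)*k + level
  G <- matrix(0, n, n_perm * k)
  for (b in seq_len(n_perm)) {
    gb <- gi[perm[b, ]]
    G[cbind(seq_len(n), (b - 1L) * k + gb)] <- 1
  }
  ng <- as.vector(table(g))            # group sizes are permutation-invariant
  Sg <- x %*% G                         # taxa x (n_perm*k) group sums
  Ti <- rowSums(x)
  if (stat == "f") {
    sst <- rowSums(x^2) - Ti^2 / n
    # between-group SS per permutation: sum_g sum_g^2/n_g - T^2/n
    ssb <- matrix(0, nrow(x), n_perm)
    for (g_idx in seq_len(k)) {
      cols <- (seq_len(n_perm) - 1L) * k + g_idx
      ssb <- ssb + Sg[, cols, drop = FALSE]^2 / ng[g_idx]
    }
    ssb <- ssb - Ti^2 / n
    ssw <- pmax(sst - ssb, 0)
    stat_m <- (ssb / (k - 1)) / (ssw / (n - k))
    stat_m[ssw == 0 & ssb == 0] <- 0    # completely constant taxon
    stat_m[ssw == 0 & ssb > 0] <- Inf
    stat_m
  } else {
    if (k != 2L) otk_stop("t statistics require exactly 2 groups")
    Sq <- x^2 %*% G
    cols1 <- (seq_len(n_perm) - 1L) * k + 1L
    cols2 <- (seq_len(n_perm) - 1L) * k + 2L
    m1 <- Sg[, cols1, drop = FALSE] / ng[1]; m2 <- Sg[, cols2, drop = FALSE] / ng[2]
    v1 <- (Sq[, cols1, drop = FALSE] - ng[1] * m1^2) / (ng[1] - 1)
    v2 <- (Sq[, cols2, drop = FALSE] - ng[2] * m2^2) / (ng[2] - 1)
    v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
    if (stat == "t") {
      sp <- ((ng[1] - 1) * v1 + (ng[2] - 1) * v2) / (n - 2)
      se <- sqrt(sp * (1 / ng[1] + 1 / ng[2]))
    } else {
      se <- sqrt(v1 / ng[1] + v2 / ng[2])
    }
    stat_m <- (m1 - m2) / se
    stat_m[se == 0 & abs(m1 - m2) < .Machine$double.eps^0.5] <- 0
    stat_m[se == 0 & abs(m1 - m2) >= .Machine$double.eps^0.5] <- Inf
    stat_m
  }
}

#' Westfall-Young minP multiple testing over taxa
#'
#' Tests each taxon for association with a categorical sample variable using a
#' permutation null. Raw p-values use the `(1 + count)/(B + 1)` convention
#' (always positive). Adjusted p-values control the family-wise error rate via
#' the step-down minP procedure on the joint permutation distribution of
#' p-values (single permutation matrix, rank-based null p-values), with
#' step-down monotonicity enforced. Taxa whose statistic is undefined
#' (no variance anywhere) receive statistic 0 and p = 1.
#'
#' @param exp an `mb_experiment` with a sample table.
#' @param class_var name of a categorical sample variable with >= 2 levels.
#' @param stat `"f"` (one-way ANOVA F; any number of levels), `"t"` (pooled
#'   two-sample t) or `"welch_t"` (unequal-variance t); t variants need
#'   exactly 2 levels. Two-sided via `|stat|`.
#' @param B number of random label permutations (ignored when `exact = TRUE`).
#' @param seed integer seed (required unless `exact`).
#' @param exact enumerate all `n!` label permutations instead of sampling
#'   (feasible for small n); raw p-values are then exact.
#' @return data.frame of class `test_table`, one row per taxon, sorted by raw
#'   p then statistic descending, with columns `taxon`, `index` (original row
#'   position), `statistic`, `raw_p`, `adj_p`.
#' @export
mt_minp <- function(exp, class_var, stat = c("f", "t", "welch_t"),
                    B = 9999, seed = NULL, exact = FALSE) {
  stat <- match.arg(stat)
  if (is.null(exp$samples) || !class_var %in% colnames(exp$samples)) {
    otk_stop("class variable '%s' not found in the sample table", class_var)
  }
  g_raw <- exp$samples[[class_var]]
  keep <- !is.na(g_raw)
  if (!all(keep)) {
    otk_log(sprintf("mt_minp: dropping %d sample(s) with missing '%s'", sum(!keep), class_var))
    exp <- prune_samples(sample_ids(exp)[keep], exp)
    g_raw <- exp$samples[[class_var]]
  }
  g <- factor(g_raw)
  if (nlevels(g) < 2L) otk_stop("class variable '%s' has fewer than 2 levels", class_var)
  n <- n_samples(exp)
  if (n < 3L) otk_stop("at least 3 samples are required")
  x <- abundances(exp)

  if (exact) {
    perm <- all_permutations(n)
  } else {
    if (is.null(seed)) otk_stop("mt_minp requires an explicit 'seed' (or exact = TRUE)")
    if (B < 99) otk_log(sprintf("B = %d gives p-value resolution of only %.3g", B, 1 / (B + 1)), "warn")
    set.seed(as.integer(seed))
    perm <- t(replicate(B, sample.int(n)))
  }
  obs <- abs(perm_statistics(x, g, matrix(seq_len(n), 1), stat)[, 1])
  S <- abs(perm_statistics(x, g, perm, stat))
  if (!exact) {
    # the observed labelling counts as one of the B + 1 permutations, which
    # yields the (1 + count)/(B + 1) raw p-value convention and keeps the
    # joint null distribution on the same granularity as the raw p-values
    S <- cbind(S, obs)
  }
  n_perm <- ncol(S)
  raw_p <- rowMeans(S >= obs - 1e-12)
  # per-permutation null p-values from within-row ranks (ties share the count)
  P <- t(apply(S, 1, function(row) {
    (length(row) + 1 - rank(row, ties.method = "min")) / length(row)
  }))

  # step-down minP over the joint null: successive minima from the least
  # significant taxon upward
  ord <- order(raw_p, -obs)
  m <- length(ord)
  q <- rep(1, n_perm)
  adj <- numeric(m)
  for (i in rev(seq_len(m))) {
    q <- pmin(q, P[ord[i], ])
    adj[i] <- sum(q <= raw_p[ord[i]] + 1e-12) / n_perm
  }
  adj <- cummax(adj)                          # enforce step-down monotonicity
  adj_p <- numeric(m)
  adj_p[ord] <- pmin(adj, 1)
  adj_p <- pmax(adj_p, raw_p)

  out <- data.frame(taxon = taxon_ids(exp),
                    index = seq_len(m),
                    statistic = obs,
                    raw_p = raw_p,
                    adj_p = adj_p,
                    stringsAsFactors = FALSE)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("test_table", "data.frame")
  out
}
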