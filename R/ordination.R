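# Ordination engines and the single `ordinate` dispatch.

ordination_result <- function(method, sample_coords, taxa_coords = NULL,
                              eigenvalues = NULL, stress = NULL,
                              axis_labels = NULL, details = list()) {
  if (!is.null(eigenvalues) && is.unsorted(rev(eigenvalues), strictly = FALSE)) {
    # eigenvalues must be non-increasing
    ord <- order(eigenvalues, decreasing = TRUE)
    eigenvalues <- eigenvalues[ord]
  }
  if (is.null(axis_labels)) {
    axis_labels <- paste0("Axis", seq_len(ncol(sample_coords)))
  }
  colnames(sample_coords) <- axis_labels[seq_len(ncol(sample_coords))]
  if (!is.null(taxa_coords)) {
    colnames(taxa_coords) <- axis_labels[seq_len(ncol(taxa_coords))]
  }
  structure(list(method = method, sample_coords = sample_coords,
                 taxa_coords = taxa_coords, eigenvalues = eigenvalues,
                 stress = stress, axis_labels = axis_labels, details = details),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result: %s, %d samples x %d axes%s\n", x$method,
              nrow(x$sample_coords), ncol(x$sample_coords),
              if (!is.null(x$stress)) sprintf(", stress %.4g", x$stress) else ""))
  invisible(x)
}

#' Ordinate an experiment
#'
#' Single dispatch over the supported ordination methods. `"MDS"`/`"PCoA"` and
#' `"NMDS"` operate on a distance matrix: pass either a precomputed
#' `stats::dist` or the name of a method supported by [distance()] via
#' `distance_method`. The other methods operate on the abundance table
#' directly (DPCoA additionally uses the tree). Detrended correspondence
#' analysis is intentionally not implemented and raises an explanatory error.
#'
#' @param exp an `mb_experiment`.
#' @param method one of `"CA"`, `"CCA"`, `"RDA"`, `"PCA"`, `"DPCoA"`,
#'   `"MDS"`/`"PCoA"`, `"NMDS"`.
#' @param distance_method a [distance()] method name or a `dist` object
#'   (MDS/NMDS only). Default `"bray"`.
#' @param constraints character vector of sample-variable names (or a one-sided
#'   formula) for CCA/RDA.
#' @param seed integer seed, required for NMDS.
#' @param ... passed on to the engine (e.g. `k`, `n_starts` for NMDS).
#' @return an `ordination_result`.
#' @export
ordinate <- function(exp, method, distance_method = "bray", constraints = NULL,
                     seed = NULL, ...) {
  supported <- c("CA", "CCA", "RDA", "PCA", "DPCoA", "MDS", "PCoA", "NMDS")
  if (identical(method, "DCA")) {
    otk_stop(paste0("DCA (detrended correspondence analysis) is not implemented; ",
                    "see the package documentation for the supported set: %s"),
             paste(supported, collapse = ", "))
  }
  if (!method %in% supported) {
    otk_stop("unsupported ordination method '%s'; supported: %s",
             method, paste(supported, collapse = ", "))
  }
  get_dist <- function() {
    if (inherits(distance_method, "dist")) distance_method
    else distance(exp, distance_method)
  }
  res <- switch(method,
    CA = ca(exp$abundance),
    PCA = pca(t(abundances(exp))),
    CCA = constrained_ordination(exp, "CCA", constraints),
    RDA = constrained_ordination(exp, "RDA", constraints),
    DPCoA = dpcoa(exp),
    MDS = ,
    PCoA = pcoa(get_dist()),
    NMDS = {
      if (is.null(seed)) otk_stop("NMDS requires an explicit 'seed'")
      nmds(get_dist(), seed = seed, ...)
    })
  res$details$distance_method <-
    if (method %in% c("MDS", "PCoA", "NMDS")) {
      if (inherits(distance_method, "dist")) attr(distance_method, "method") %||% "precomputed"
      else distance_method
    } else NULL
  res$method <- method
  res
}

#' Correspondence analysis
#'
#' Singular value decomposition of the standardized residuals of the
#' correspondence matrix. Eigenvalues are the squared singular values and sum
#' to the total inertia, the chi-square statistic of the table divided by its
#' grand total. Scores are reported in symmetric scaling (both sides scaled by
#' the square root of the singular values).
#'
#' @param table an [abundance_table()] or taxa x samples matrix with all row
#'   and column sums positive.
#' @return an `ordination_result` with both sample and taxa coordinates.
#' @export
ca <- function(table) {
  x <- if (inherits(table, "abundance_table")) table$values else as.matrix(table)
  if (any(rowSums(x) <= 0)) {
    otk_stop("CA requires positive row sums; offending taxa: %s",
             paste(rownames(x)[rowSums(x) <= 0], collapse = ", "))
  }
  if (any(colSums(x) <= 0)) {
    otk_stop("CA requires positive column sums; offending samples: %s",
             paste(colnames(x)[colSums(x) <= 0], collapse = ", "))
  }
  N <- sum(x)
  P <- x / N
  r <- rowSums(P); c <- colSums(P)
  S <- (P - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(S)
  keep <- which(sv$d > 1e-12)
  d <- sv$d[keep]
  # symmetric scaling: principal coordinates shared between rows and columns
  taxa_coords <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/") %*% diag(sqrt(d), length(d))
  sample_coords <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(c), "/") %*% diag(sqrt(d), length(d))
  rownames(taxa_coords) <- rownames(x)
  rownames(sample_coords) <- colnames(x)
  ordination_result("CA", sample_coords, taxa_coords,
                    eigenvalues = d^2,
                    axis_labels = paste0("CA", seq_along(d)),
                    details = list(total_inertia = sum(sv$d^2), scaling = "symmetric"))
}

#' Principal coordinates analysis (metric MDS)
#'
#' Double centering of `-d^2/2` followed by eigendecomposition. Axes are
#' ordered by eigenvalue; negative eigenvalues (non-Euclidean input) are
#' retained in the `eigenvalues` field with a logged warning, but coordinates
#' are returned only for positive-eigenvalue axes.
#'
#' @param d a `stats::dist` or symmetric matrix of dissimilarities.
#' @return an `ordination_result`.
#' @export
pcoa <- function(d) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- rownames(m) %||% paste0("obj", seq_len(n))
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  if (any(eig$values < -tol)) {
    otk_log(sprintf("PCoA: %d negative eigenvalues retained (non-Euclidean distances)",
                    sum(eig$values < -tol)), "warn")
  }
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), length(pos))
  rownames(coords) <- labels
  ordination_result("PCoA", coords,
                    eigenvalues = eig$values,
                    axis_labels = paste0("PCo", seq_len(length(eig$values))))
}

#' Kruskal stress-1 of a configuration against dissimilarities
#'
#' Evaluates `sqrt(sum((dhat - delta)^2) / sum(delta^2))` where `delta` are the
#' configuration distances and `dhat` the monotone (isotonic) regression of
#' `delta` on the order of `d`. Useful as an independent check of NMDS output
#' (it is invariant under rotation, reflection and translation of the
#' configuration).
#'
#' @param coords configuration matrix (objects x dimensions).
#' @param d the input dissimilarities (`dist` or matrix).
#' @return the stress value.
#' @export
kruskal_stress1 <- function(coords, d) {
  delta <- as.vector(stats::dist(coords))
  dd <- as.vector(stats::as.dist(as.matrix(d)))
  ord <- order(dd, delta)
  fit <- stats::isoreg(delta[ord])$yf
  sqrt(sum((fit - delta[ord])^2) / sum(delta^2))
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 by monotone regression (via `vegan::monoMDS`,
#' global model), taking the best of one PCoA-initialized start plus
#' `n_starts` random starts. The final configuration is centered and rotated
#' to its principal axes. Deterministic given `seed`.
#'
#' @param d dissimilarities (`dist` or matrix).
#' @param k target dimensionality (must be < number of objects).
#' @param n_starts number of random restarts in addition to the PCoA start.
#' @param max_iter maximum iterations per start.
#' @param tol relative stress-change convergence tolerance.
#' @param seed integer seed (required).
#' @return an `ordination_result` with `stress` set.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 200, tol = 1e-7, seed) {
  if (missing(seed)) otk_stop("NMDS requires an explicit 'seed'")
  d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  if (k >= n) otk_stop("k must be smaller than the number of objects")
  if (all(d == 0)) otk_stop("degenerate input: all dissimilarities are zero")
  labels <- attr(d, "Labels") %||% paste0("obj", seq_len(n))
  run <- function(init) {
    vegan::monoMDS(d, y = init, k = k, model = "global",
                   maxit = max_iter, smin = 1e-9, sfgrmin = 1e-9,
                   sratmax = 1 - tol)
  }
  # PCoA initialization, padded with tiny jitter-free zeros if rank < k
  p <- pcoa(d)
  init0 <- matrix(0, n, k)
  take <- min(k, ncol(p$sample_coords))
  init0[, seq_len(take)] <- p$sample_coords[, seq_len(take)]
  set.seed(as.integer(seed))
  best <- run(init0)
  for (s in seq_len(n_starts)) {
    cand <- run(matrix(stats::runif(n * k, -1, 1), n, k))
    if (cand$stress < best$stress) best <- cand
  }
  coords <- best$points
  coords <- scale(coords, center = TRUE, scale = FALSE)
  if (k > 1) coords <- coords %*% svd(coords)$v  # principal-axis rotation
  rownames(coords) <- labels
  ordination_result("NMDS", coords, stress = best$stress,
                    axis_labels = paste0("NMDS", seq_len(k)),
                    details = list(n_starts = n_starts, converged = best$icause))
}

#' Principal components analysis
#'
#' @param x matrix with observations (samples) as rows.
#' @param center center columns (default TRUE).
#' @param scale scale columns to unit variance (default FALSE); zero-variance
#'   columns are an error when `scale = TRUE`.
#' @return an `ordination_result`; eigenvalues are the score variances.
#' @export
pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) otk_stop("PCA needs at least 2 rows")
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) {
      otk_stop("zero-variance column(s) cannot be scaled: %s",
               paste(colnames(x)[sds == 0], collapse = ", "))
    }
  }
  pc <- stats::prcomp(x, center = center, scale. = scale)
  coords <- pc$x
  ordination_result("PCA", coords,
                    taxa_coords = pc$rotation,
                    eigenvalues = pc$sdev^2,
                    axis_labels = colnames(pc$x))
}

# Build a numeric constraint matrix from sample variables (factors expanded
# to indicator columns, intercept excluded).
constraint_matrix <- function(exp, constraints) {
  if (inherits(constraints, "formula")) constraints <- all.vars(constraints)
  if (is.null(constraints) || length(constraints) == 0L) {
    return(matrix(0, n_samples(exp), 0))
  }
  if (is.null(exp$samples)) otk_stop("constrained ordination requires a sample table")
  missing_vars <- setdiff(constraints, colnames(exp$samples))
  if (length(missing_vars) > 0L) {
    otk_stop("unknown sample variable(s): %s", paste(missing_vars, collapse = ", "))
  }
  df <- as.data.frame(exp$samples)[, constraints, drop = FALSE]
  df[] <- lapply(df, function(v) if (is.character(v)) factor(v) else v)
  Z <- stats::model.matrix(~ ., data = df)
  Z[, -1, drop = FALSE]  # drop intercept; centering handles it
}

#' Constrained ordination (RDA and CCA)
#'
#' RDA: least-squares projection of the centered abundance profile matrix onto
#' the span of the constraint variables, followed by an eigen-analysis of the
#' fitted values; the residual part yields the unconstrained axes, and
#' constrained + residual inertia equals the total inertia exactly. CCA: the
#' same scheme applied to the chi-square standardized residual matrix under
#' CA's row weighting.
#'
#' @param exp an `mb_experiment` with a sample table.
#' @param method `"RDA"` or `"CCA"`.
#' @param constraints character vector of sample-variable names (or one-sided
#'   formula); categorical variables are expanded to indicators. An empty set
#'   (intercept only) yields zero constrained inertia.
#' @return an `ordination_result`; `details` carries the inertia decomposition.
#' @export
constrained_ordination <- function(exp, method = c("RDA", "CCA"), constraints) {
  method <- match.arg(method)
  x <- abundances(exp)
  n <- ncol(x)
  Z <- constraint_matrix(exp, constraints)

  if (method == "RDA") {
    Y <- scale(t(x), center = TRUE, scale = FALSE)      # samples x taxa
    w <- rep(1 / (n - 1), n)                             # variance normalization
    Zc <- if (ncol(Z) > 0) scale(Z, center = TRUE, scale = FALSE) else Z
    sw <- sqrt(rep(1, n))
    Yw <- Y; Zw <- Zc
    denom <- n - 1
  } else {
    N <- sum(x)
    P <- t(x) / N                                        # samples x taxa
    r <- rowSums(P); cc <- colSums(P)
    if (any(r <= 0) || any(cc <= 0)) otk_stop("CCA requires positive sample and taxon totals")
    Yw <- (P - outer(r, cc)) / sqrt(outer(r, cc))        # standardized residuals
    # weighted (by r) centering and scaling of constraints
    if (ncol(Z) > 0) {
      Zc <- sweep(Z, 2, colSums(Z * r) / sum(r))
      Zw <- Zc * sqrt(r)
    } else Zw <- Z
    denom <- 1
  }

  total <- sum(Yw^2) / denom
  if (ncol(Zw) > 0) {
    qr_z <- qr(Zw)
    if (qr_z$rank == 0) otk_stop("constraint matrix has rank 0")
    fitted <- qr.fitted(qr_z, Yw)
    resid <- Yw - fitted
  } else {
    fitted <- Yw * 0
    resid <- Yw
  }
  sv_f <- svd(fitted)
  sv_r <- svd(resid)
  keep_f <- which(sv_f$d^2 / denom > max(total, 1) * 1e-12)
  keep_r <- which(sv_r$d^2 / denom > max(total, 1) * 1e-12)
  eig_f <- sv_f$d[keep_f]^2 / denom
  eig_r <- sv_r$d[keep_r]^2 / denom
  n_axes_f <- length(keep_f)

  coords_f <- sv_f$u[, keep_f, drop = FALSE] %*% diag(sv_f$d[keep_f], n_axes_f)
  coords_r <- sv_r$u[, keep_r, drop = FALSE] %*% diag(sv_r$d[keep_r], length(keep_r))
  sample_coords <- cbind(coords_f, coords_r)
  taxa_coords <- cbind(sv_f$v[, keep_f, drop = FALSE], sv_r$v[, keep_r, drop = FALSE])
  rownames(sample_coords) <- colnames(x)
  rownames(taxa_coords) <- rownames(x)
  labels <- c(if (n_axes_f > 0) paste0(method, seq_len(n_axes_f)),
              if (length(keep_r) > 0) paste0(if (method == "RDA") "PC" else "CA", seq_along(keep_r)))
  ordination_result(method, sample_coords, taxa_coords,
                    eigenvalues = sort(c(eig_f, eig_r), decreasing = TRUE),
                    axis_labels = labels,
                    details = list(constrained_eigenvalues = eig_f,
                                   unconstrained_eigenvalues = eig_r,
                                   constrained_inertia = sum(eig_f),
                                   unconstrained_inertia = sum(eig_r),
                                   total_inertia = total,
                                   n_constrained_axes = n_axes_f))
}

#' Double principal coordinates analysis
#'
#' Taxa are embedded by PCoA of the square-root patristic distances (so that
#' squared taxon distances in the embedding equal patristic distances); each
#' sample is placed at the abundance-weighted centroid of its taxa; the sample
#' cloud is then analysed by a PCA weighted by the samples' relative totals.
#' Squared sample distances in the full space equal the Rao dissimilarity
#' computed directly from abundances and patristic distances.
#'
#' @param exp an `mb_experiment` with a tree.
#' @return an `ordination_result` with both sample and taxa coordinates.
#' @export
dpcoa <- function(exp) {
  if (is.null(exp$tree)) otk_stop("DPCoA requires a phylogenetic tree")
  x <- abundances(exp)
  if (any(colSums(x) == 0)) otk_stop("DPCoA requires positive sample totals")
  D <- ape::cophenetic.phylo(exp$tree)[rownames(x), rownames(x)]
  # PCoA of sqrt(patristic): Gower matrix of sqrt distances, i.e. -D/2 centered
  nt <- nrow(x)
  J <- diag(nt) - matrix(1 / nt, nt, nt)
  B <- J %*% (-0.5 * D) %*% J
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  if (any(eig$values < -tol)) {
    otk_stop(paste0("square-root patristic distances are not Euclidean-embeddable; ",
                    "check the tree for inconsistent branch lengths"))
  }
  pos <- which(eig$values > tol)
  Y <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(eig$values[pos]), length(pos))
  rownames(Y) <- rownames(x)
  p <- sweep(x, 2, colSums(x), "/")      # taxa profiles per sample
  C <- t(p) %*% Y                        # samples at weighted centroids
  w <- colSums(x) / sum(x)               # sample weights
  m <- drop(w %*% C)
  Cc <- sweep(C, 2, m)
  cov_w <- t(Cc) %*% (Cc * w)
  eg <- eigen((cov_w + t(cov_w)) / 2, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)
  rot <- eg$vectors[, keep, drop = FALSE]
  sample_coords <- Cc %*% rot
  taxa_coords <- sweep(Y, 2, m) %*% rot
  rownames(sample_coords) <- colnames(x)
  ordination_result("DPCoA", sample_coords, taxa_coords,
                    eigenvalues = eg$values[keep],
                    axis_labels = paste0("DPCoA", seq_along(keep)))
}
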