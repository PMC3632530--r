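# Alpha-diversity estimation and hypergeometric enrichment.

#' Per-sample richness and diversity estimates
#'
#' Supported measures: `Observed` (taxa with count > 0), `Chao1` (always in
#' the bias-corrected form `S_obs + F1(F1-1)/(2(F2+1))`, defined also when
#' there are no doubletons) with standard error, `ACE` (standard
#' rare/abundant partition at 10 with coverage estimate) with standard error,
#' `Shannon` (`-sum p log p`, natural log) and `Simpson` (`1 - sum p^2`).
#' Chao1 and ACE require integer counts.
#'
#' @param exp an `mb_experiment`.
#' @param measures subset of `c("Observed","Chao1","ACE","Shannon","Simpson")`.
#' @return data.frame, one row per sample; Chao1/ACE carry `se.chao1`/`se.ACE`
#'   columns.
#' @export
estimate_richness <- function(exp, measures = c("Observed", "Chao1", "ACE",
                                                "Shannon", "Simpson")) {
  all_measures <- c("Observed", "Chao1", "ACE", "Shannon", "Simpson")
  bad <- setdiff(measures, all_measures)
  if (length(bad) > 0L) otk_stop("unsupported measures: %s", paste(bad, collapse = ", "))
  x <- abundances(exp)
  out <- data.frame(row.names = colnames(x))
  if ("Observed" %in% measures) out$Observed <- colSums(x > 0)
  if (any(c("Chao1", "ACE") %in% measures)) {
    if (!is_wholenumber(x)) {
      otk_stop("Chao1 and ACE require integer counts; transform-free data needed")
    }
    # estimateR can emit NaN ACE standard errors for degenerate samples (no
    # rare taxa); those propagate as NA values rather than warnings here
    est <- suppressWarnings(apply(round(x), 2, vegan::estimateR))
    if ("Chao1" %in% measures) {
      out$Chao1 <- est["S.chao1", ]
      out$se.chao1 <- est["se.chao1", ]
    }
    if ("ACE" %in% measures) {
      out$ACE <- est["S.ACE", ]
      out$se.ACE <- est["se.ACE", ]
    }
  }
  if ("Shannon" %in% measures) out$Shannon <- vegan::diversity(t(x), index = "shannon")
  if ("Simpson" %in% measures) out$Simpson <- vegan::diversity(t(x), index = "simpson")
  out
}

#' Upper-tail hypergeometric enrichment test
#'
#' Probability of observing at least `category_in_selected` members of a
#' category in a selection of `selected` draws without replacement from a
#' universe of `universe_size` items of which `category_in_universe` belong to
#' the category — the classical one-sided Fisher / hypergeometric
#' overrepresentation test.
#'
#' @param universe_size total number of items.
#' @param category_in_universe category members in the universe.
#' @param selected size of the selection.
#' @param category_in_selected observed category members in the selection.
#' @return upper-tail p-value `P[X >= category_in_selected]`.
#' @export
hypergeom_enrichment <- function(universe_size, category_in_universe,
                                 selected, category_in_selected) {
  u <- as.integer(universe_size); m <- as.integer(category_in_universe)
  k <- as.integer(selected); q <- as.integer(category_in_selected)
  if (m > u || k > u || q > min(k, m) || any(c(u, m, k, q) < 0)) {
    otk_stop("inconsistent counts: need category <= universe, selected <= universe, overlap <= min(selected, category)")
  }
  stats::phyper(q - 1, m, u - m, k, lower.tail = FALSE)
}
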