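# BIOM v1 (JSON) reading and writing. The JSON layer is jsonlite; the mapping
# between BIOM fields and experiment components is defined here so that the
# dense/sparse contract and the error conditions are explicit.

greengenes_prefix_map <- c(k = "Kingdom", p = "Phylum", c = "Class",
                           o = "Order", f = "Family", g = "Genus", s = "Species")

# Parse a vector of lineage entries (one taxon) into a named rank vector.
# Entries with greengenes prefixes ("k__Bacteria") map to their rank; an empty
# suffix ("p__") is a missing value. Unprefixed entries fill ranks positionally.
parse_lineage <- function(entries, ranks = default_ranks()) {
  entries <- trimws(as.character(entries))
  entries <- entries[nzchar(entries)]
  out <- stats::setNames(rep(NA_character_, length(ranks)), ranks)
  pos <- 1L
  for (e in entries) {
    m <- regmatches(e, regexec("^([kpcofgs])__(.*)$", e))[[1]]
    if (length(m) == 3L) {
      rank <- greengenes_prefix_map[[m[2]]]
      val <- m[3]
      if (rank %in% names(out)) out[[rank]] <- if (nzchar(trimws(val))) trimws(val) else NA_character_
      pos <- match(rank, ranks) + 1L
    } else {
      if (pos <= length(ranks)) {
        out[[ranks[pos]]] <- e
        pos <- pos + 1L
      }
    }
  }
  out
}

lineage_matrix <- function(lineages, ids) {
  mat <- t(vapply(lineages, parse_lineage, character(length(default_ranks()))))
  rownames(mat) <- ids
  if (all(is.na(mat))) return(NULL)
  taxonomy_table(mat, ranks = default_ranks())
}

looks_like_hdf5 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4)
  length(magic) == 4 && identical(magic, as.raw(c(0x89, 0x48, 0x44, 0x46)))
}

#' Read a BIOM v1 (JSON) table into an experiment
#'
#' Supports both `"dense"` and `"sparse"` matrix types. Observation metadata
#' named `taxonomy` becomes the taxonomy table (greengenes rank prefixes are
#' mapped to Kingdom...Species); sample metadata becomes the sample table.
#' BIOM v2 (HDF5) files are rejected with an explicit message.
#'
#' @param path path to a BIOM v1 JSON file.
#' @return an `mb_experiment`.
#' @export
read_biom_json <- function(path) {
  if (!file.exists(path)) otk_stop("file not found: %s", path)
  if (looks_like_hdf5(path)) {
    otk_stop("'%s' is a BIOM v2 (HDF5) file; only the BIOM v1 JSON dialect is supported", path)
  }
  b <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) otk_stop("not a valid BIOM v1 JSON file: %s",
                                             conditionMessage(e)))
  for (f in c("rows", "columns", "shape", "data", "matrix_type")) {
    if (is.null(b[[f]])) otk_stop("BIOM file missing required field '%s'", f)
  }
  shape <- as.integer(unlist(b$shape))
  n_obs <- shape[1]; n_smp <- shape[2]
  obs_ids <- vapply(b$rows, function(r) as.character(r$id), character(1))
  smp_ids <- vapply(b$columns, function(cc) as.character(cc$id), character(1))
  if (length(obs_ids) != n_obs || length(smp_ids) != n_smp) {
    otk_stop("BIOM shape %dx%d does not match rows/columns lists", n_obs, n_smp)
  }
  mt <- tolower(b$matrix_type)
  mat <- matrix(0, n_obs, n_smp, dimnames = list(obs_ids, smp_ids))
  if (mt == "dense") {
    if (length(b$data) != n_obs) otk_stop("BIOM dense data does not match shape")
    for (i in seq_len(n_obs)) {
      row <- as.numeric(unlist(b$data[[i]]))
      if (length(row) != n_smp) otk_stop("BIOM dense data row %d does not match shape", i)
      mat[i, ] <- row
    }
  } else if (mt == "sparse") {
    for (trip in b$data) {
      trip <- as.numeric(unlist(trip))
      if (length(trip) != 3) otk_stop("BIOM sparse triplet of length %d", length(trip))
      i <- trip[1] + 1; j <- trip[2] + 1   # BIOM indices are 0-based
      if (i > n_obs || j > n_smp) otk_stop("BIOM sparse index (%d,%d) outside shape", i - 1, j - 1)
      mat[i, j] <- trip[3]
    }
  } else {
    otk_stop("unknown BIOM matrix_type '%s' (expected 'dense' or 'sparse')", b$matrix_type)
  }

  taxonomy <- NULL
  lineages <- lapply(b$rows, function(r) {
    md <- r$metadata
    if (is.null(md) || is.null(md$taxonomy)) NULL else unlist(md$taxonomy)
  })
  if (any(!vapply(lineages, is.null, logical(1)))) {
    lineages <- lapply(lineages, function(x) if (is.null(x)) character(0) else x)
    taxonomy <- lineage_matrix(lineages, obs_ids)
  }

  samples <- NULL
  smeta <- lapply(b$columns, function(cc) cc$metadata)
  if (any(!vapply(smeta, is.null, logical(1)))) {
    keys <- unique(unlist(lapply(smeta, names)))
    if (length(keys) > 0) {
      df <- as.data.frame(lapply(keys, function(k) {
        vals <- vapply(smeta, function(m) {
          v <- m[[k]]
          if (is.null(v)) NA_character_ else as.character(v)
        }, character(1))
        retype_column(vals)
      }), col.names = keys, stringsAsFactors = FALSE, check.names = FALSE)
      rownames(df) <- smp_ids
      samples <- sample_table(df)
    }
  }

  build_experiment(abundance_table(mat, taxa_are_rows = TRUE),
                   samples = samples, taxonomy = taxonomy)
}

#' Write an experiment's abundance table (and taxonomy) as BIOM v1 JSON
#'
#' Always writes a dense matrix; taxonomy (when present) is embedded as
#' per-observation `taxonomy` metadata with greengenes rank prefixes, and the
#' sample table (when present) as column metadata.
#'
#' @param exp an `mb_experiment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biom_json <- function(exp, path) {
  validate_experiment(exp)
  mat <- abundances(exp)
  prefixes <- stats::setNames(names(greengenes_prefix_map), greengenes_prefix_map)
  rows <- lapply(seq_len(nrow(mat)), function(i) {
    md <- NULL
    if (!is.null(exp$taxonomy)) {
      asn <- exp$taxonomy[i, ]
      ranks <- colnames(exp$taxonomy)
      lin <- ifelse(ranks %in% names(prefixes),
                    paste0(prefixes[ranks], "__", ifelse(is.na(asn), "", asn)),
                    ifelse(is.na(asn), "", asn))
      md <- list(taxonomy = as.list(unname(lin)))
    }
    list(id = rownames(mat)[i], metadata = md)
  })
  cols <- lapply(seq_len(ncol(mat)), function(j) {
    md <- NULL
    if (!is.null(exp$samples) && ncol(exp$samples) > 0) {
      md <- lapply(as.list(exp$samples[j, , drop = FALSE]), function(v) {
        if (is.na(v)) NA else unclass(v)
      })
    }
    list(id = colnames(mat)[j], metadata = md)
  })
  element_type <- if (is_wholenumber(mat)) "int" else "float"
  doc <- list(
    id = "otukit export",
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = "otukit",
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    rows = rows,
    columns = cols,
    matrix_type = "dense",
    matrix_element_type = element_type,
    shape = c(nrow(mat), ncol(mat)),
    data = lapply(seq_len(nrow(mat)), function(i) as.list(unname(mat[i, ])))
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}
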