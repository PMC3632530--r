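# Readers for OTU-clustering output formats: QIIME legacy tab-delimited OTU
# tables and mothur .shared/.cons.taxonomy pairs.

#' Read a QIIME legacy (tab-delimited) OTU table
#'
#' The header line begins with `#OTU ID`; an optional final column named
#' `Consensus Lineage` (or `taxonomy`) is split on `;` and mapped to ranks via
#' the greengenes prefix convention (`k__`, `p__`, ...), empty suffixes
#' becoming missing values.
#'
#' @param path path to the OTU table.
#' @return an `mb_experiment` (taxonomy present iff a lineage column exists).
#' @export
read_qiime_legacy <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#OTU ID", lines)
  if (length(hdr_idx) == 0L) {
    otk_stop("'%s' is not a QIIME legacy OTU table: no '#OTU ID' header line", path)
  }
  hdr_idx <- hdr_idx[[1]]
  header <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_idx)]
  body <- body[nzchar(body) & !startsWith(body, "#")]
  if (length(body) == 0L) otk_stop("QIIME table has no data rows")
  cells <- strsplit(body, "\t", fixed = TRUE)
  ncols <- length(header)
  bad <- which(lengths(cells) != ncols)
  if (length(bad) > 0L) otk_stop("QIIME table row %d has %d fields, expected %d",
                                 bad[1], lengths(cells)[bad[1]], ncols)
  tab <- do.call(rbind, cells)
  otu_ids <- tab[, 1]
  lineage_col <- which(tolower(header) %in% c("consensus lineage", "taxonomy"))
  smp_cols <- setdiff(seq_len(ncols)[-1], lineage_col)
  mat <- matrix(as.numeric(tab[, smp_cols, drop = FALSE]),
                nrow = length(otu_ids),
                dimnames = list(otu_ids, header[smp_cols]))
  taxonomy <- NULL
  if (length(lineage_col) > 0L) {
    lineages <- strsplit(tab[, lineage_col[1]], ";", fixed = TRUE)
    taxonomy <- lineage_matrix(lineages, otu_ids)
  }
  build_experiment(abundance_table(mat, taxa_are_rows = TRUE), taxonomy = taxonomy)
}

#' Read mothur `.shared` (and optional `.cons.taxonomy`) files
#'
#' The `.shared` file carries columns `label`, `Group`, `numOtus` followed by
#' per-OTU counts; samples come from the `Group` rows and taxa from the OTU
#' columns. The optional consensus taxonomy file has `OTU`, `Size`, `Taxonomy`
#' columns; taxonomy strings are split on `;` with bootstrap confidence
#' suffixes like `(97)` stripped.
#'
#' @param shared_path path to the `.shared` file.
#' @param taxonomy_path optional path to the `.cons.taxonomy` file.
#' @param label OTU-clustering distance label to select when the shared file
#'   contains more than one.
#' @return an `mb_experiment`.
#' @export
read_mothur <- function(shared_path, taxonomy_path = NULL, label = NULL) {
  df <- utils::read.table(shared_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("label", "Group", "numOtus")
  if (!all(tolower(need) %in% tolower(names(df)[1:3]))) {
    otk_stop("'%s' does not look like a mothur .shared file (expected label/Group/numOtus)",
             shared_path)
  }
  labels <- unique(as.character(df[[1]]))
  if (length(labels) > 1L) {
    if (is.null(label)) {
      otk_stop("shared file contains multiple distance labels (%s); select one with 'label'",
               paste(labels, collapse = ", "))
    }
    df <- df[as.character(df[[1]]) == as.character(label), , drop = FALSE]
    if (nrow(df) == 0L) otk_stop("label '%s' not present in shared file", label)
  }
  groups <- as.character(df[[2]])
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  storage.mode(counts) <- "numeric"
  mat <- t(counts)                      # taxa x samples
  colnames(mat) <- groups
  taxonomy <- NULL
  if (!is.null(taxonomy_path)) {
    tx <- utils::read.table(taxonomy_path, sep = "\t", header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            quote = "", comment.char = "")
    tax_col <- which(tolower(names(tx)) == "taxonomy")[1]
    otu_col <- which(tolower(names(tx)) == "otu")[1]
    if (is.na(tax_col) || is.na(otu_col)) {
      otk_stop("'%s' does not look like a mothur cons.taxonomy file", taxonomy_path)
    }
    strings <- gsub("\\(\\d+\\)", "", tx[[tax_col]])  # strip bootstrap confidences
    lineages <- strsplit(strings, ";", fixed = TRUE)
    taxonomy <- lineage_matrix(lineages, as.character(tx[[otu_col]]))
  }
  build_experiment(abundance_table(mat, taxa_are_rows = TRUE), taxonomy = taxonomy)
}

#' Unimplemented legacy import formats
#'
#' RDP-pipeline and Pyrotagger exports are recognised by name but not parsed;
#' requesting them raises an explanatory error.
#'
#' @param format format name.
#' @keywords internal
unimplemented_format <- function(format) {
  otk_stop(paste0("import format '%s' is recognised but not implemented; ",
                  "supported formats: biom, qiime, mothur"), format)
}
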