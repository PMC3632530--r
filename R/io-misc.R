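# Readers for Newick trees, FASTA reference sequences, sample tables, and the
# serialized experiment bundle.

#' Read a Newick tree
#'
#' Absent branch lengths are resolved to 0. Trees with a basal multifurcation
#' (unrooted in the Newick convention) are flagged via the `rooted` attribute.
#' Unbalanced parentheses are reported with their character position.
#'
#' @param path path to a Newick file (single tree).
#' @return an `ape::phylo` with attribute `rooted`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_newick_balance(txt)
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) otk_stop("Newick parse error: %s", conditionMessage(e)))
  if (is.null(tree)) otk_stop("Newick parse error: no tree found in '%s'", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  tree <- normalize_tree(tree)
  if (!attr(tree, "rooted")) {
    otk_log("tree has a basal multifurcation and is flagged unrooted", "warn")
  }
  tree
}

check_newick_balance <- function(txt) {
  depth <- 0L
  in_quote <- FALSE
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) otk_stop("unbalanced parenthesis at position %d in Newick string", i)
    }
  }
  if (depth != 0L) {
    otk_stop("unbalanced parentheses in Newick string: %d unclosed '(' at end of input", depth)
  }
  invisible(TRUE)
}

#' Write a tree in Newick format
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read reference sequences from a FASTA file
#' @param path path to a FASTA file.
#' @return a [ref_seqs()] object (named character vector).
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions after the ID token
  names(ss) <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1)
  ref_seqs(ss)
}

#' Write reference sequences to FASTA
#' @param seqs a [ref_seqs()] object.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

# Missing-value tokens for sample tables (case-insensitive).
missing_tokens <- c("", "na", "n/a")

# Type a character column: numeric when every non-missing value parses as a
# number, categorical (character) otherwise.
retype_column <- function(x) {
  x <- as.character(x)
  x[tolower(trimws(x)) %in% missing_tokens] <- NA_character_
  nonmiss <- x[!is.na(x)]
  num <- suppressWarnings(as.numeric(nonmiss))
  if (length(nonmiss) > 0 && !anyNA(num)) as.numeric(x) else x
}

#' Read a sample covariate table from TSV/CSV
#'
#' The first column holds sample IDs; a header row is required. Columns in
#' which every non-missing value parses as a number become numeric, all
#' others stay categorical. Missing-value tokens: empty cell, `NA`, `N/A`
#' (case-insensitive).
#'
#' @param path path to the file.
#' @param sep field separator; guessed from the extension by default
#'   (`.csv` is comma, anything else tab).
#' @return a [sample_table()].
#' @export
read_sample_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 1L) otk_stop("sample table has no columns")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    otk_stop("duplicate sample IDs in '%s': %s", path,
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vars <- df[, -1, drop = FALSE]
  vars[] <- lapply(vars, retype_column)
  rownames(vars) <- ids
  sample_table(vars)
}

#' Write a sample table as TSV
#' @param samples a [sample_table()].
#' @param path output path.
#' @export
write_sample_table <- function(samples, path) {
  out <- data.frame(sample_id = rownames(samples), samples,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_taxonomy_tsv <- function(taxonomy, path) {
  out <- data.frame(taxon_id = rownames(taxonomy),
                    unclass(taxonomy), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

read_taxonomy_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                          check.names = FALSE, quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  taxonomy_table(mat, ranks = colnames(mat))
}

# --- experiment bundle ----------------------------------------------------

bundle_members <- c(abundance = "otu_table.biom", samples = "sample_data.tsv",
                    taxonomy = "taxonomy.tsv", tree = "tree.nwk",
                    refseq = "refseq.fasta")

#' Serialize an experiment to a bundle archive
#'
#' The bundle is a tar archive containing `otu_table.biom` (BIOM v1 JSON),
#' and, when present, `sample_data.tsv`, `taxonomy.tsv`, `tree.nwk` and
#' `refseq.fasta`. It is the canonical on-disk form used by the command-line
#' interface. Note the abundance+taxonomy live inside the BIOM member; the
#' separate taxonomy.tsv is included for plain-text inspection.
#'
#' @param exp an `mb_experiment`.
#' @param path output path (conventionally `.tar`).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(exp, path) {
  validate_experiment(exp)
  tmp <- tempfile("bundle")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  write_biom_json(exp, file.path(tmp, bundle_members[["abundance"]]))
  if (!is.null(exp$samples)) write_sample_table(exp$samples, file.path(tmp, bundle_members[["samples"]]))
  if (!is.null(exp$taxonomy)) write_taxonomy_tsv(exp$taxonomy, file.path(tmp, bundle_members[["taxonomy"]]))
  if (!is.null(exp$tree)) write_newick(exp$tree, file.path(tmp, bundle_members[["tree"]]))
  if (!is.null(exp$refseq)) write_fasta(exp$refseq, file.path(tmp, bundle_members[["refseq"]]))
  tarfile <- file.path(normalizePath(dirname(path), mustWork = TRUE), basename(path))
  old <- setwd(tmp)
  on.exit(setwd(old), add = TRUE, after = FALSE)
  utils::tar(tarfile, files = list.files(tmp), tar = "internal")
  invisible(path)
}

#' Read an experiment bundle
#' @param path path to a bundle written by [write_bundle()].
#' @return an `mb_experiment`.
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) otk_stop("bundle not found: %s", path)
  tmp <- tempfile("bundle")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  utils::untar(path, exdir = tmp)
  biom_path <- file.path(tmp, bundle_members[["abundance"]])
  if (!file.exists(biom_path)) otk_stop("bundle is missing %s", bundle_members[["abundance"]])
  base <- read_biom_json(biom_path)
  samples <- NULL; tree <- NULL; refseq <- NULL; taxonomy <- base$taxonomy
  p <- file.path(tmp, bundle_members[["samples"]])
  if (file.exists(p)) samples <- read_sample_table(p)
  p <- file.path(tmp, bundle_members[["taxonomy"]])
  if (file.exists(p)) taxonomy <- read_taxonomy_tsv(p)
  p <- file.path(tmp, bundle_members[["tree"]])
  if (file.exists(p)) tree <- read_newick(p)
  p <- file.path(tmp, bundle_members[["refseq"]])
  if (file.exists(p)) refseq <- read_fasta(p)
  build_experiment(base$abundance, samples = samples %||% base$samples,
                   taxonomy = taxonomy, tree = tree, refseq = refseq)
}
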