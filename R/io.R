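#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased and RNA `U` is mapped to `T`. Records must have
#' unique, non-empty identifiers (the first whitespace-delimited token of the
#' header line).
#'
#' @param path path to a FASTA file.
#' @param allow_gap logical; accept `-` characters (aligned FASTA).
#' @return named character vector of sequences, names are record ids; the
#'   full header lines are kept in the `"description"` attribute.
#' @export
read_fasta <- function(path, allow_gap = FALSE) {
  stopifnot(file.exists(path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a valid FASTA file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  if (length(set) == 0) stop("FASTA file contains no records: ", path, call. = FALSE)
  desc <- names(set)
  ids <- sub("\\s.*$", "", desc)
  if (any(!nzchar(ids))) stop("FASTA record with empty id in ", path, call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  seqs <- normalize_dna(as.character(set))
  names(seqs) <- ids
  check_dna(seqs, allow_gap = allow_gap, what = paste("FASTA file", path))
  if (any(nchar(seqs) == 0)) stop("zero-length sequence in ", path, call. = FALSE)
  attr(seqs, "description") <- desc
  seqs
}

#' Write DNA sequences to FASTA
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70) {
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' All records must have identical aligned length; `-` is the gap character.
#'
#' @param path path to an aligned FASTA file.
#' @return named character vector with an `"alignment_length"` attribute.
#' @export
read_alignment <- function(path) {
  x <- read_fasta(path, allow_gap = TRUE)
  len <- unique(nchar(x))
  if (length(len) != 1)
    stop("aligned FASTA records differ in length: ", path, call. = FALSE)
  attr(x, "alignment_length") <- len
  x
}

#' Read a rooted tree from a newick file
#'
#' Polytomies are preserved; branch lengths, if present, are kept but all
#' parsimony operations in this package are topology-only.
#'
#' @param path path to a file holding a single newick string ending in `;`.
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced parentheses in newick at character ", i, call. = FALSE)
  }
  if (depth != 0L)
    stop("unbalanced parentheses in newick: ", depth,
         " unclosed '(' at end of input", call. = FALSE)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("could not parse newick in ", path, call. = FALSE)
  if (inherits(tr, "multiPhylo"))
    stop("expected a single newick tree in ", path, call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels in ", path, call. = FALSE)
  tr
}

#' Write a tree to newick
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

PRESENCE_STATES <- c("P", "A", "ND")

#' Construct a presence/absence matrix
#'
#' A presence/absence matrix is a data frame with metadata columns `gene`,
#' `species`, `clade` followed by one column per ancestral intron slot, each
#' holding states `P` (present), `A` (absent) or `ND` (not determined). `ND`
#' is a first-class state: it is never silently coerced to absent.
#'
#' @param df data frame with the columns described above.
#' @param slot_cols names of the slot columns; default: everything after the
#'   metadata columns.
#' @return a `presence_matrix` (data frame subclass).
#' @export
presence_matrix <- function(df, slot_cols = NULL) {
  need <- c("gene", "species", "clade")
  if (!all(need %in% names(df)))
    stop("presence matrix needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(slot_cols)) slot_cols <- setdiff(names(df), need)
  df$gene <- as.character(df$gene)
  df$species <- as.character(df$species)
  df$clade <- as.character(df$clade)
  if (anyDuplicated(df$gene))
    stop("duplicate gene ids in presence matrix", call. = FALSE)
  for (sc in slot_cols) {
    df[[sc]] <- as.character(df[[sc]])
    bad <- !(df[[sc]] %in% PRESENCE_STATES)
    if (any(bad))
      stop(sprintf("unknown state '%s' at row %d, column '%s' (expected P/A/ND)",
                   df[[sc]][which(bad)[1]], which(bad)[1], sc), call. = FALSE)
  }
  rownames(df) <- NULL  # normalized so file round trips compare identical
  structure(df, slot_cols = slot_cols,
            class = c("presence_matrix", "data.frame"))
}

#' Read a presence/absence matrix from delimited text
#'
#' Expects a header row; the first three columns are gene id, species and
#' clade label, the remaining columns are per-slot states in `{P, A, ND}`.
#' Tab- and comma-delimited files are supported (chosen by file extension,
#' or forced with `sep`).
#'
#' @param path path to the file.
#' @param sep field separator; default: `","` for `.csv`, otherwise tab.
#' @return a [presence_matrix].
#' @export
read_matrix <- function(path, sep = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 3) stop("presence matrix needs at least 3 columns", call. = FALSE)
  names(df)[1:3] <- c("gene", "species", "clade")
  presence_matrix(df)
}

#' Write a presence/absence matrix to delimited text
#' @param pm a [presence_matrix].
#' @param path output path.
#' @param sep field separator.
#' @return invisibly, `path`.
#' @export
write_matrix <- function(pm, path, sep = "\t") {
  utils::write.table(as.data.frame(pm), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence matrix: %d genes x %d slots (%d species)\n",
              nrow(x), length(attr(x, "slot_cols")),
              length(unique(x$species))))
  NextMethod()
}

#' Slot columns of a presence matrix
#' @param pm a [presence_matrix].
#' @return character vector of slot column names.
#' @export
slot_names <- function(pm) attr(pm, "slot_cols")

#' Per-leaf states for one intron slot
#' @param pm a [presence_matrix].
#' @param slot a slot column name or index.
#' @return named character vector (names = gene ids) of P/A/ND states.
#' @export
slot_states <- function(pm, slot) {
  sc <- slot_names(pm)
  if (is.numeric(slot)) slot <- sc[slot]
  if (!slot %in% sc) stop("unknown slot: ", slot, call. = FALSE)
  stats::setNames(pm[[slot]], pm$gene)
}

#' Packaged angiosperm ABCB1 intron presence/absence matrix
#'
#' A curated matrix of presence/absence states for the nine ancestral intron
#' slots of the angiosperm ABCB1 auxin-transporter gene, covering 100 gene
#' copies from 80 species (dicots, monocots and the basal angiosperm
#' *Amborella trichopoda*), assembled from published gene structures. States
#' determined by PCR fragment sizing without confirmatory sequencing are
#' recorded `ND`.
#'
#' @return a [presence_matrix].
#' @export
abcb1_presence <- function() {
  read_matrix(system.file("extdata", "abcb1_presence.tsv",
                          package = "intronevo", mustWork = TRUE))
}

#' Packaged angiosperm species/gene topology for the ABCB1 data set
#'
#' A composite rooted topology over the gene copies of [abcb1_presence()],
#' following accepted angiosperm relationships (APG family-level topology;
#' grass subfamily relationships per the Grass Phylogeny Working Group).
#' Within-species duplicate gene copies are attached as terminal cherries.
#' Topology only; no branch lengths.
#'
#' @return an [ape::phylo] object whose tip labels match the `gene` column
#'   of [abcb1_presence()].
#' @export
abcb1_tree <- function() {
  read_newick(system.file("extdata", "abcb1_tree.nwk",
                          package = "intronevo", mustWork = TRUE))
}
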