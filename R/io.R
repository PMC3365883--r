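#' Read a FASTA file of barcode sequences
#'
#' Wraps [seqinr::read.fasta()]. Sequences are uppercased and RNA `U` is
#' mapped to `T`; any letter outside the IUPAC DNA set
#' `A C G T R Y S W K M N` is rejected. The part of the header line after
#' the first whitespace is kept as a free-text description.
#'
#' @param path Path to a FASTA file (any line wrapping).
#' @return Data frame with columns `id`, `sequence`, `desc`, in file order.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  recs <- seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                             forceDNAtolower = FALSE, whole.header = TRUE)
  headers <- vapply(recs, function(x) attr(x, "name"), character(1))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(vapply(recs, function(x) as.character(x)[1], character(1)))
  seqs <- chartr("U", "T", seqs)
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": ", ids[duplicated(ids)][1])
  empty <- !nzchar(seqs) | is.na(seqs)
  if (any(empty))
    stop("empty sequence for id: ", ids[empty][1])
  bad <- grepl(paste0("[^", DNA_LETTERS, "]"), seqs)
  if (any(bad))
    stop("non-IUPAC DNA letter in sequence: ", ids[bad][1])
  data.frame(id = unname(ids), sequence = unname(seqs), desc = unname(desc),
             stringsAsFactors = FALSE)
}

DNA_LETTERS <- "ACGTRYSWKMN"

#' Write sequences to FASTA
#'
#' Lines are wrapped at 70 columns for interoperability.
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `desc`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  names_out <- records$id
  if (!is.null(records$desc)) {
    has <- nzchar(records$desc)
    names_out[has] <- paste(records$id[has], records$desc[has])
  }
  seqinr::write.fasta(lapply(records$sequence, seqinr::s2c),
                      names = names_out, file.out = path, nbchar = 70)
  invisible(path)
}

#' Read a regional species checklist
#'
#' One species per line; blank lines and `#` comments are ignored;
#' duplicates collapse.
#'
#' @param path Path to a plain-text checklist.
#' @return Sorted character vector of unique species labels.
#' @export
read_checklist <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  sort(unique(lines[nzchar(lines)]))
}

#' Write a table of results as TSV with header
#'
#' @param rows A data frame.
#' @param path Output path.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a phylogenetic tree as newick
#'
#' Leaf labels have whitespace replaced by underscores; labels containing
#' newick-reserved characters (parentheses, commas, colons, semicolons,
#' quotes) are single-quoted. Branch lengths are written at full precision
#' so that a round-trip read returns an isomorphic tree.
#'
#' @param tree An [ape::phylo] tree with at least one tip.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (is.null(tree) || !inherits(tree, "phylo") || is.null(tree$tip.label) ||
      length(tree$tip.label) == 0)
    stop("write_newick: empty or invalid tree")
  tree$tip.label <- sanitize_newick_label(tree$tip.label)
  if (!is.null(tree$node.label))
    tree$node.label <- sanitize_newick_label(tree$node.label)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

sanitize_newick_label <- function(x) {
  x <- gsub("\\s+", "_", x)
  reserved <- grepl("[(),:;'\\[\\]]", x)
  x[reserved] <- paste0("'", gsub("'", "''", x[reserved]), "'")
  x
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  stopifnot(file.exists(path))
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  tr
}
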