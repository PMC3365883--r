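#' Ranked taxonomy paths
#'
#' A taxon path records the four ranks reported in reef diet barcoding work
#' (order, family, genus, species), with partial resolution allowed: a query
#' matched only to genus carries an empty species label. The only structural
#' rule is that resolution is contiguous from the top: a non-empty rank
#' requires every coarser rank to be non-empty too.
#'
#' @param order,family,genus,species Character labels; `""` marks an
#'   unresolved rank. Labels must not contain tabs or newlines.
#' @return A one-row data frame of class `taxon_path` with columns
#'   `order`, `family`, `genus`, `species`.
#' @examples
#' taxon_path("Perciformes", "Labridae", "Halichoeres", "Halichoeres garnoti")
#' taxon_path("Decapoda", "Alpheidae", "Synalpheus")  # genus-level resolution
#' @export
taxon_path <- function(order = "", family = "", genus = "", species = "") {
  tp <- data.frame(order = as.character(order), family = as.character(family),
                   genus = as.character(genus), species = as.character(species),
                   stringsAsFactors = FALSE)
  validate_taxon_path(tp)
  class(tp) <- c("taxon_path", class(tp))
  tp
}

RANKS <- c("order", "family", "genus", "species")

validate_taxon_path <- function(tp) {
  for (r in RANKS) {
    lab <- tp[[r]]
    if (any(grepl("[\t\n]", lab)))
      stop("taxon label at rank '", r, "' contains a tab or newline")
  }
  # contiguity: a resolved rank implies all coarser ranks are resolved
  for (i in seq_len(nrow(tp))) {
    filled <- vapply(RANKS, function(r) nzchar(tp[[r]][i]), logical(1))
    if (any(filled) && any(diff(filled) > 0) && !all(filled[seq_len(max(which(filled)))]))
      stop("taxon path row ", i, ": rank '", RANKS[max(which(filled))],
           "' is resolved but a coarser rank is empty")
  }
  invisible(tp)
}

#' Finest resolved rank of a taxon path
#'
#' @param tp A taxon path (or any data frame with the four rank columns).
#' @return Character vector, one of `"order"`, `"family"`, `"genus"`,
#'   `"species"`, or `"none"` per row.
#' @export
resolution <- function(tp) {
  vapply(seq_len(nrow(tp)), function(i) {
    filled <- vapply(RANKS, function(r) nzchar(tp[[r]][i]), logical(1))
    if (!any(filled)) "none" else RANKS[max(which(filled))]
  }, character(1))
}

#' Read a four-rank taxonomy table
#'
#' The table is tab-separated with header columns `id`, `order`, `family`,
#' `genus`, `species`; empty cells mark unresolved ranks. Partial rows are
#' accepted as long as resolution is contiguous from order downwards.
#'
#' @param path Path to a TSV file.
#' @return Data frame with columns `id`, `order`, `family`, `genus`,
#'   `species`; one row per input row, ids unique.
#' @export
read_taxonomy <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE)
  expected <- c("id", RANKS)
  if (!identical(sort(names(tab)), sort(expected)))
    stop("taxonomy table must have exactly the columns ",
         paste(expected, collapse = ", "), "; got ",
         paste(names(tab), collapse = ", "))
  tab <- tab[, expected]
  tab[is.na(tab)] <- ""
  if (anyDuplicated(tab$id))
    stop("duplicate taxonomy id: ", tab$id[duplicated(tab$id)][1])
  validate_taxon_path(tab)
  tab
}

#' Write a four-rank taxonomy table
#'
#' @param tax Data frame with columns `id`, `order`, `family`, `genus`,
#'   `species`.
#' @param path Output path.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(all(c("id", RANKS) %in% names(tax)))
  utils::write.table(tax[, c("id", RANKS)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
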