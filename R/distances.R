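#' Semi-global (free end-gap) alignment of a fragment to a reference
#'
#' Optimal pairwise alignment under affine gap costs in which terminal
#' gaps are unpenalised, so a short fragment aligns to its containing
#' region of a full-length barcode at no cost (a Gotoh three-state
#' dynamic program, implemented in C++ for speed). The returned strings
#' cover the aligned overlap only; traceback ties are broken
#' deterministically (diagonal over up over left).
#'
#' @param query_seq,ref_seq Character DNA sequences (IUPAC letters).
#' @param match,mismatch Match score and mismatch penalty.
#' @param gap_open,gap_extend Gap opening/extension penalties (sign is
#'   ignored; the magnitudes are used as costs; a gap of length L costs
#'   `|gap_open| + L |gap_extend|`).
#' @return List with `query_aln` and `ref_aln`, equal-length gapped strings.
#' @export
align_overlap <- function(query_seq, ref_seq, match = 1, mismatch = -1,
                          gap_open = -10, gap_extend = -1) {
  stopifnot(nzchar(query_seq), nzchar(ref_seq))
  res <- .align_pair_cpp(toupper(query_seq), toupper(ref_seq),
                         match, mismatch, gap_open, gap_extend)
  list(query_aln = res$query_aln, ref_aln = res$ref_aln)
}

# Site counts over an aligned pair. Sites where either sequence carries a
# gap or an ambiguity code are excluded from all substitution counts
# (pairwise deletion); gap openings inside the overlap are counted
# separately as a diagnostic for indels/pseudogenes.
count_aligned_pair <- function(q_aln, r_aln) {
  qi <- utf8ToInt(q_aln)
  ri <- utf8ToInt(r_aln)
  if (length(qi) != length(ri))
    stop("aligned strings must have equal length")
  acgt <- utf8ToInt("ACGT")
  gap <- utf8ToInt("-")
  ok <- (qi %in% acgt) & (ri %in% acgt)
  overlap <- sum(ok)
  diff <- ok & (qi != ri)
  purine <- function(x) x %in% utf8ToInt("AG")
  transitions <- sum(diff & (purine(qi) == purine(ri)))
  transversions <- sum(diff) - transitions
  gap_any <- (qi == gap) | (ri == gap)
  internal_gaps <- sum(diff(c(FALSE, gap_any)) == 1L)
  list(overlap_sites = overlap, transitions = transitions,
       transversions = transversions, internal_gaps = internal_gaps)
}

#' Kimura two-parameter distance over an aligned overlap
#'
#' Computes the closed form `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))`,
#' where `P` and `Q` are the transition and transversion proportions over
#' the aligned sites where both sequences carry an unambiguous base
#' (pairwise deletion). When the logarithm's argument is non-positive the
#' distance is saturated and reported as `Inf`.
#'
#' @param query_aln,ref_aln Equal-length gapped aligned strings, e.g. from
#'   [align_overlap()].
#' @param query_id,ref_id Identifiers carried into the result.
#' @return One-row data frame: `query_id`, `ref_id`, `overlap_sites`,
#'   `transitions`, `transversions`, `internal_gaps`, `p_distance`,
#'   `similarity_pct` (= 100 (1 - p)), `k2p`, `saturated`.
#' @export
k2p_distance <- function(query_aln, ref_aln, query_id = "query",
                         ref_id = "ref") {
  cts <- count_aligned_pair(query_aln, ref_aln)
  if (cts$overlap_sites == 0L)
    stop("NO_OVERLAP: no aligned unambiguous sites between ", query_id,
         " and ", ref_id)
  k2p_from_counts(cts, query_id, ref_id)
}

k2p_from_counts <- function(cts, query_id, ref_id) {
  n <- cts$overlap_sites
  P <- cts$transitions / n
  Q <- cts$transversions / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  saturated <- a1 <= 0 || a2 <= 0
  d <- if (saturated) Inf else -0.5 * log(a1 * sqrt(a2)) + 0  # +0 kills -0
  p <- P + Q
  data.frame(query_id = query_id, ref_id = ref_id, overlap_sites = n,
             transitions = cts$transitions,
             transversions = cts$transversions,
             internal_gaps = cts$internal_gaps,
             p_distance = p, similarity_pct = 100 * (1 - p), k2p = d,
             saturated = saturated, stringsAsFactors = FALSE)
}

#' Compare one query against a set of references
#'
#' Aligns the query to every reference (semi-global) and computes the full
#' per-pair comparison. Alignments are dispatched in one vectorised call.
#'
#' @param query One-row data frame (or list) with `id` and `sequence`.
#' @param references Data frame with `id` and `sequence`.
#' @param ... Scoring parameters passed to the aligner, see
#'   [align_overlap()].
#' @return Data frame of comparisons, one row per reference, in reference
#'   order.
#' @export
compare_to_references <- function(query, references, ...) {
  if (is.null(references) || nrow(references) == 0L)
    stop("empty reference set")
  scoring <- list(...)
  match <- scoring$match %||% 1
  mismatch <- scoring$mismatch %||% -1
  gap_open <- scoring$gap_open %||% -10
  gap_extend <- scoring$gap_extend %||% -1
  cts <- .align_counts_cpp(toupper(query$sequence[1]),
                           toupper(references$sequence),
                           match, mismatch, gap_open, gap_extend)
  out <- lapply(seq_len(nrow(cts)), function(i) {
    row <- list(overlap_sites = cts[i, 1], transitions = cts[i, 2],
                transversions = cts[i, 3], internal_gaps = cts[i, 4])
    if (row$overlap_sites == 0L)
      stop("NO_OVERLAP: no aligned unambiguous sites between ",
           query$id[1], " and ", references$id[i])
    k2p_from_counts(row, query$id[1], references$id[i])
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' All-pairs K2P distance matrix
#'
#' Every pair is aligned semi-globally and its K2P distance computed with
#' pairwise deletion; saturated pairs are `Inf`. The diagonal is zero and
#' the matrix is exactly symmetric.
#'
#' @param records Data frame with `id` and `sequence`, at least two rows.
#' @param ... Scoring parameters, see [align_overlap()].
#' @return List with `matrix` (named square matrix of K2P distances) and
#'   `mean`, `min`, `max` over finite off-diagonal entries.
#' @export
distance_matrix <- function(records, ...) {
  n <- nrow(records)
  if (is.null(n) || n < 2L) stop("distance_matrix needs at least 2 records")
  if (anyDuplicated(records$id)) stop("duplicate record id")
  D <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    rest <- records[(i + 1L):n, , drop = FALSE]
    cmp <- compare_to_references(records[i, ], rest, ...)
    D[i, (i + 1L):n] <- cmp$k2p
    D[(i + 1L):n, i] <- cmp$k2p
  }
  off <- D[upper.tri(D)]
  fin <- off[is.finite(off)]
  list(matrix = D, mean = mean(fin), min = min(fin), max = max(fin))
}
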