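#' Ranked best matches of a query against the reference library
#'
#' References are ranked by percent similarity (identity over the aligned
#' overlap) descending, ties by K2P ascending, then by id, mirroring how a
#' barcode ID engine reports candidate matches.
#'
#' @param query One-row data frame with `id` and `sequence`.
#' @param references Data frame with `id` and `sequence`.
#' @param top_n Number of hits to return.
#' @param ... Scoring parameters, see [align_overlap()].
#' @return Data frame of the `top_n` best comparisons with an added
#'   `n_ties` column: the number of references within 0.01 similarity
#'   percentage points of the best hit.
#' @export
best_matches <- function(query, references, top_n = 10L, ...) {
  cmp <- compare_to_references(query, references, ...)
  ord <- order(-cmp$similarity_pct, cmp$k2p, cmp$ref_id)
  cmp <- cmp[ord, , drop = FALSE]
  n_ties <- sum(cmp$similarity_pct >= cmp$similarity_pct[1] - 0.01)
  out <- utils::head(cmp, top_n)
  out$n_ties <- n_ties
  rownames(out) <- NULL
  out
}

rank_path_columns <- function(taxonomy, ids) {
  taxonomy[match(ids, taxonomy$id), RANKS, drop = FALSE]
}

# Finest rank at which all paths carry one identical non-empty label.
finest_unanimous_rank <- function(paths) {
  for (r in rev(RANKS)) {
    labs <- paths[[r]]
    if (all(!is.na(labs)) && all(nzchar(labs)) &&
        length(unique(labs)) == 1L)
      return(list(rank = r, taxon = labs[1]))
  }
  list(rank = "none", taxon = "")
}

# Full four-rank path for an assignment, truncated below `rank`.
truncate_path <- function(path, rank) {
  out <- path
  if (rank == "none") {
    out[RANKS] <- ""
    return(out)
  }
  keep <- seq_len(match(rank, RANKS))
  out[RANKS[-keep]] <- ""
  out
}

#' Assign a taxon to one query from its hit table
#'
#' The species rule: if the best match diverges by less than
#' `species_threshold_pct` (K2P, in percent) the query is assigned at
#' species rank, capped at the finest rank unanimous among all in-band
#' hits (so a genus-only reference, or disagreeing in-band species, yields
#' a genus-level call). Queries without any in-band hit fall back to the
#' tree-based strict criterion on a neighbor-joining tree of the query
#' plus all references, capped at genus rank: a species-level claim
#' without a sub-threshold match would contradict the divergence rule.
#'
#' @param query One-row data frame with `id` and `sequence`.
#' @param hits Full comparison table for this query (all references), as
#'   from [compare_to_references()].
#' @param references Reference data frame (`id`, `sequence`).
#' @param taxonomy Reference taxonomy (`id` plus the four ranks).
#' @param ref_dist Optional pre-computed K2P matrix over the references
#'   (reused across queries); computed on demand if `NULL`.
#' @param species_threshold_pct Species-level divergence threshold,
#'   percent K2P.
#' @return One-row assignment data frame: `query_id`, `method`
#'   (`threshold`/`strict-tree`/`none`), `rank`, `taxon`, the four path
#'   columns, `best_ref_id`, `best_similarity_pct`, `best_k2p_pct`,
#'   `n_ties`.
#' @export
assign_query <- function(query, hits, references, taxonomy,
                         ref_dist = NULL, species_threshold_pct = 3.0) {
  stopifnot(nrow(hits) >= 1L)
  ord <- order(-hits$similarity_pct, hits$k2p, hits$ref_id)
  hits <- hits[ord, , drop = FALSE]
  best <- hits[1, ]
  n_ties <- sum(hits$similarity_pct >= best$similarity_pct - 0.01)
  base <- data.frame(query_id = query$id[1], method = "none", rank = "none",
                     taxon = "", order = "", family = "", genus = "",
                     species = "", best_ref_id = best$ref_id,
                     best_similarity_pct = best$similarity_pct,
                     best_k2p_pct = 100 * best$k2p, n_ties = n_ties,
                     stringsAsFactors = FALSE)

  in_band <- is.finite(hits$k2p) & (100 * hits$k2p < species_threshold_pct)
  if (any(in_band)) {
    paths <- rank_path_columns(taxonomy, hits$ref_id[in_band])
    un <- finest_unanimous_rank(paths)
    if (un$rank == "none") return(base)
    base$method <- "threshold"
    base$rank <- un$rank
    base$taxon <- un$taxon
    base[RANKS] <- truncate_path(paths[1, , drop = FALSE], un$rank)
    return(base)
  }

  # strict-tree fallback; saturated references are unusable for NJ
  usable <- hits$ref_id[is.finite(hits$k2p)]
  if (length(usable) < 2L) return(base)
  if (is.null(ref_dist))
    ref_dist <- distance_matrix(references[references$id %in% usable, ])$matrix
  refs_kept <- intersect(rownames(ref_dist), usable)
  if (any(!is.finite(ref_dist[refs_kept, refs_kept]))) {
    fin <- apply(is.finite(ref_dist[refs_kept, refs_kept]), 1, all)
    refs_kept <- refs_kept[fin]
  }
  if (length(refs_kept) < 2L) return(base)
  qid <- query$id[1]
  D <- rbind(cbind(ref_dist[refs_kept, refs_kept],
                   hits$k2p[match(refs_kept, hits$ref_id)]),
             c(hits$k2p[match(refs_kept, hits$ref_id)], 0))
  rownames(D) <- colnames(D) <- c(refs_kept, qid)
  tree <- nj_tree(D)
  strict <- strict_criterion(tree, qid, taxonomy, query_ids = qid,
                             finest_rank = "genus")
  if (strict$rank == "none") return(base)
  base$method <- "strict-tree"
  base$rank <- strict$rank
  base$taxon <- strict$taxon
  donor <- taxonomy[which(taxonomy[[strict$rank]] == strict$taxon)[1], RANKS]
  base[RANKS] <- truncate_path(donor, strict$rank)
  base
}

#' Identify a batch of queries against a reference library
#'
#' Runs [compare_to_references()] and [assign_query()] for every query,
#' sharing one reference-by-reference distance matrix across all
#' strict-tree fallbacks. Deterministic: the output depends only on the
#' inputs.
#'
#' @param queries Data frame of QC-passed queries (`id`, `sequence`).
#' @param references Data frame of reference sequences (`id`, `sequence`).
#' @param taxonomy Reference taxonomy (`id` plus the four ranks).
#' @param species_threshold_pct Species-level divergence threshold,
#'   percent K2P.
#' @param ... Scoring parameters, see [align_overlap()].
#' @return List with `assignments` (one row per query) and `report`
#'   (counts of assignments by method and by rank).
#' @export
identify_batch <- function(queries, references, taxonomy,
                           species_threshold_pct = 3.0, ...) {
  if (is.null(queries) || nrow(queries) == 0L) {
    return(list(assignments = data.frame(), report = list(
      by_method = table(character(0)), by_rank = table(character(0)))))
  }
  ref_dist <- NULL
  rows <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    q <- queries[i, , drop = FALSE]
    hits <- compare_to_references(q, references, ...)
    if (is.null(ref_dist) &&
        !any(is.finite(hits$k2p) &
               100 * hits$k2p < species_threshold_pct)) {
      ref_dist <- distance_matrix(references)$matrix
    }
    rows[[i]] <- assign_query(q, hits, references, taxonomy,
                              ref_dist = ref_dist,
                              species_threshold_pct = species_threshold_pct)
  }
  assignments <- do.call(rbind, rows)
  rownames(assignments) <- NULL
  list(assignments = assignments,
       report = list(by_method = table(assignments$method),
                     by_rank = table(assignments$rank)))
}
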