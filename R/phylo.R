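#' Neighbor-joining tree from a distance matrix
#'
#' Classic neighbor joining: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - R_i - R_j` is joined, with branch lengths from
#' the standard two-point formulas and the reduced matrix by
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Negative branch lengths are
#' clamped to zero. Ties in Q are broken by the lexicographically smallest
#' pair of cluster labels (a cluster is labelled by its smallest member
#' id), so the output is bit-reproducible under input permutation. The
#' result carries the usual NJ trifurcation at its (arbitrary) root.
#'
#' @param D Square symmetric numeric matrix of distances with row/column
#'   names, `n >= 3`, all entries finite.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (is.list(D) && !is.null(D$matrix)) D <- D$matrix
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("D must be a square matrix")
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) stop("D must have row/column names")
  if (any(!is.finite(D)))
    stop("distance matrix contains non-finite entries; ",
         "drop saturated taxa before tree building")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix must be symmetric")

  fmt <- function(x) sprintf("%.12g", max(x, 0))
  newick <- sanitize_newick_label(rownames(D))
  labels <- rownames(D)  # tie-break label = smallest member id
  m <- n
  while (m > 3L) {
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(labels[ij[1]], labels[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    d_ij <- D[i, j]
    vi <- d_ij / 2 + (R[i] - R[j]) / (2 * (m - 2))
    vj <- d_ij - vi
    merged <- paste0("(", newick[i], ":", fmt(vi), ",",
                     newick[j], ":", fmt(vj), ")")
    keep <- setdiff(seq_len(m), c(i, j))
    d_new <- (D[i, keep] + D[j, keep] - d_ij) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new),
               c(d_new, 0))
    lab_new <- min(labels[c(i, j)])
    labels <- c(labels[keep], lab_new)
    newick <- c(newick[keep], merged)
    rownames(D) <- colnames(D) <- labels
    m <- m - 1L
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- paste0("(", newick[1], ":", fmt(v1), ",", newick[2], ":", fmt(v2),
                ",", newick[3], ":", fmt(v3), ");")
  ape::read.tree(text = txt)
}

# Tips descending from `node` (which may itself be a tip).
descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    children <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- children[children <= ntip]
    out <- c(out, tips)
    stack <- c(stack, children[children > ntip])
  }
  out
}

#' Midpoint rooting on the longest path between non-excluded leaves
#'
#' The tree is rooted at the midpoint of the longest path between two
#' leaves, optionally ignoring a set of leaves (query sequences) when
#' searching for that path; query leaves stay in the tree but do not steer
#' the root. Ties are broken by the lexicographically smallest leaf pair.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param exclude Leaf labels ignored when locating the longest path.
#' @return A rooted [ape::phylo] tree.
#' @export
midpoint_root <- function(tree, exclude = character(0)) {
  tips <- tree$tip.label
  consider <- which(!(tips %in% exclude))
  if (length(consider) < 2L)
    stop("midpoint rooting needs at least two non-excluded leaves")
  dn <- ape::dist.nodes(tree)
  Dt <- dn[consider, consider, drop = FALSE]
  dmax <- max(Dt)
  cand <- which(Dt - dmax >= -1e-12 * max(1, dmax), arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  keys <- apply(cand, 1, function(ij) {
    paste(sort(tips[consider[ij]]), collapse = "\r")
  })
  pick <- cand[order(keys)[1], ]
  a_tip <- consider[pick[1]]; b_tip <- consider[pick[2]]
  path <- ape::nodepath(tree, a_tip, b_tip)
  target <- dn[a_tip, b_tip] / 2
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    seg <- dn[path[k], path[k + 1L]]
    if (cum + seg >= target - 1e-12) {
      x <- target - cum  # distance from path[k] along this edge
      a <- path[k]; b <- path[k + 1L]
      edge_ab <- which(tree$edge[, 1] == a & tree$edge[, 2] == b)
      if (length(edge_ab)) {       # a is the parent
        return(phytools::reroot(tree, node.number = b, position = x))
      }
      len <- tree$edge.length[which(tree$edge[, 1] == b &
                                      tree$edge[, 2] == a)]
      return(phytools::reroot(tree, node.number = a, position = len - x))
    }
    cum <- cum + seg
  }
  stop("midpoint not found on path")  # unreachable
}

#' Tree-based "strict criterion" taxon assignment
#'
#' Implements the clade-nesting rule used for queries without close
#' reference matches: root the joint tree at the midpoint of its longest
#' reference-to-reference path, locate the smallest clade containing the
#' query and at least one reference leaf, and assign the finest rank at
#' which every reference leaf in that clade carries one identical,
#' non-empty label. Other query leaves are transparent: they neither steer
#' the root nor count toward clade unanimity.
#'
#' @param tree Joint [ape::phylo] tree of references plus queries.
#' @param query_id Leaf label of the query to assign.
#' @param taxonomy Data frame with columns `id`, `order`, `family`,
#'   `genus`, `species` covering the reference leaves.
#' @param query_ids All leaf labels that are queries (defaults to
#'   `query_id`).
#' @param finest_rank Finest rank the criterion may assign
#'   (`"species"` by default; identification caps it at `"genus"` for
#'   out-of-band queries, since a species-level claim without a
#'   sub-threshold match would contradict the divergence rule).
#' @return One-row data frame: `query_id`, `rank` (or `"none"`), `taxon`,
#'   `clade_size` (reference leaves in the assigning clade).
#' @export
strict_criterion <- function(tree, query_id, taxonomy,
                             query_ids = query_id,
                             finest_rank = "species") {
  if (!(query_id %in% tree$tip.label))
    stop("query leaf not in tree: ", query_id)
  rooted <- midpoint_root(tree, exclude = query_ids)
  ranks_up <- rev(RANKS)  # species, genus, family, order
  start <- match(finest_rank, ranks_up)
  if (is.na(start)) stop("unknown rank: ", finest_rank)

  tips <- rooted$tip.label
  node <- which(tips == query_id)
  tax_at <- function(ids, rank) taxonomy[[rank]][match(ids, taxonomy$id)]

  next_rank <- start
  repeat {
    parent_edge <- which(rooted$edge[, 2] == node)
    if (!length(parent_edge)) break  # reached the root
    node <- rooted$edge[parent_edge, 1]
    ref_tips <- setdiff(tips[descendant_tips(rooted, node)], query_ids)
    if (!length(ref_tips)) next
    for (r in next_rank:length(ranks_up)) {
      labs <- tax_at(ref_tips, ranks_up[r])
      if (all(!is.na(labs)) && all(nzchar(labs)) &&
          length(unique(labs)) == 1L) {
        return(data.frame(query_id = query_id, rank = ranks_up[r],
                          taxon = labs[1], clade_size = length(ref_tips),
                          stringsAsFactors = FALSE))
      }
    }
    # every rank from finest to order tested in this clade; enclosing
    # clades are supersets, so only coarser ranks could newly succeed --
    # and none remain below order.
    next_rank <- length(ranks_up) + 1L
    if (next_rank > length(ranks_up)) break
  }
  data.frame(query_id = query_id, rank = "none", taxon = "",
             clade_size = 0L, stringsAsFactors = FALSE)
}
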