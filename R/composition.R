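#' Label prey assignments as fish or crustacean
#'
#' Diet tables are reported per coarse prey class; the class is derived
#' from the assigned order. Orders not listed in either set raise an
#' error so silent misclassification cannot occur.
#'
#' @param assignments Assignment data frame with an `order` column.
#' @param crustacean_orders Orders classed as crustaceans.
#' @param fish_orders Orders classed as fishes; by default every other
#'   non-empty order.
#' @return The input with an added `class` column (`"fish"`,
#'   `"crustacean"`, or `""` for unassigned rows).
#' @export
add_prey_class <- function(assignments,
                           crustacean_orders = c("Decapoda", "Stomatopoda",
                                                 "Euphausiacea"),
                           fish_orders = NULL) {
  cls <- ifelse(!nzchar(assignments$order), "",
                ifelse(assignments$order %in% crustacean_orders,
                       "crustacean", "fish"))
  if (!is.null(fish_orders)) {
    unknown <- nzchar(assignments$order) &
      !(assignments$order %in% c(crustacean_orders, fish_orders))
    if (any(unknown))
      stop("order not in either class: ",
           assignments$order[unknown][1])
  }
  assignments$class <- cls
  assignments
}

assignment_counts <- function(assignments) {
  if ("count" %in% names(assignments)) assignments$count else
    rep(1L, nrow(assignments))
}

#' Percent composition by number (%N)
#'
#' The share of each prey taxon in the total count of prey items, at a
#' chosen rank and denominator scope. Scopes reproduce the reporting
#' conventions of diet barcoding studies: class-level percentages over all
#' prey items, fish family/species percentages over fish items only, and
#' crustacean order percentages over crustacean items only.
#'
#' @param assignments Assignment data frame with the four rank columns
#'   (and a `class` column from [add_prey_class()] when `rank = "class"`
#'   or a restricted scope is requested). An optional `count` column
#'   weights rows; otherwise each row is one prey item.
#' @param rank One of `"class"`, `"order"`, `"family"`, `"genus"`,
#'   `"species"`.
#' @param scope Denominator scope: `"all"`, `"fish_only"` or
#'   `"crustacean_only"`.
#' @return Data frame with `rank`, `taxon`, `count`, `percent_n` (full
#'   precision) and `percent_n_display` (rounded to 1 decimal), sorted by
#'   descending count then taxon. Percentages sum to 100 within rounding.
#' @export
percent_n <- function(assignments, rank = "species", scope = "all") {
  if (!scope %in% c("all", "fish_only", "crustacean_only"))
    stop("unknown scope: ", scope)
  if (!rank %in% c("class", RANKS)) stop("unknown rank: ", rank)
  df <- assignments
  if (scope != "all" || rank == "class") {
    if (is.null(df$class))
      stop("assignments need a 'class' column; see add_prey_class()")
  }
  if (scope == "fish_only") df <- df[df$class == "fish", , drop = FALSE]
  if (scope == "crustacean_only")
    df <- df[df$class == "crustacean", , drop = FALSE]
  cnt <- assignment_counts(df)
  denom <- sum(cnt)
  if (denom == 0) return(data.frame(rank = character(0),
                                    taxon = character(0),
                                    count = numeric(0),
                                    percent_n = numeric(0),
                                    percent_n_display = numeric(0)))
  labels <- if (rank == "class") df$class else taxon_label_at(df, rank)
  agg <- stats::aggregate(cnt, by = list(taxon = labels), FUN = sum)
  pct <- 100 * agg$x / denom
  out <- data.frame(rank = rank, taxon = agg$taxon, count = agg$x,
                    percent_n = pct,
                    percent_n_display = round(pct, 1),
                    stringsAsFactors = FALSE)
  out[order(-out$count, out$taxon), , drop = FALSE]
}

# Display label of a row at `rank`: the label itself, or "<finest> sp."
# for rows resolved only to a coarser rank (a genus-only match becomes
# "Genus sp." in a species table), or "Unassigned".
taxon_label_at <- function(df, rank) {
  lab <- df[[rank]]
  need <- !nzchar(lab)
  if (any(need)) {
    finer_missing <- vapply(which(need), function(i) {
      filled <- vapply(RANKS, function(r) nzchar(df[[r]][i]), logical(1))
      if (!any(filled)) return("Unassigned")
      paste(df[[RANKS[max(which(filled))]]][i], "sp.")
    }, character(1))
    lab[need] <- finer_missing
  }
  lab
}

#' Distinct-taxon richness per rank
#'
#' Counts distinct taxa at each rank. At species rank, an assignment
#' resolved only to genus contributes one species-equivalent taxon
#' ("Genus sp."), distinct from any named congeners, matching how diet
#' studies count an unmatched genus-level record as an additional species.
#'
#' @param assignments Assignment data frame with the four rank columns.
#' @return Named integer vector with counts for `order`, `family`,
#'   `genus`, `species`.
#' @export
richness <- function(assignments) {
  if (is.null(assignments) || nrow(assignments) == 0L)
    return(c(order = 0L, family = 0L, genus = 0L, species = 0L))
  out <- vapply(RANKS, function(r) {
    if (r == "species") {
      labs <- taxon_label_at(assignments, "species")
      labs <- labs[labs != "Unassigned"]
    } else {
      labs <- assignments[[r]]
      labs <- labs[nzchar(labs)]
    }
    length(unique(labs))
  }, integer(1))
  stats::setNames(as.integer(out), RANKS)
}

#' Flag species absent from a regional checklist
#'
#' Only species-rank assignments are compared; genus-level records are
#' never flagged as new.
#'
#' @param assignments Assignment data frame with a `species` column.
#' @param checklist Character vector of species previously recorded in
#'   the region.
#' @return Sorted character vector of newly recorded species.
#' @export
flag_new_records <- function(assignments, checklist) {
  sp <- unique(assignments$species[nzchar(assignments$species)])
  sort(setdiff(sp, checklist))
}

#' Detect cannibalism in prey assignments
#'
#' @param assignments Assignment data frame with `species` (and optionally
#'   `query_id` and `count`).
#' @param predator_species Species label of the predator; must be
#'   non-empty.
#' @return List with `count` (number of prey items assigned to the
#'   predator species) and `ids` (their query ids, if present).
#' @export
flag_cannibalism <- function(assignments, predator_species) {
  if (is.null(predator_species) || !nzchar(predator_species))
    stop("predator_species must be a non-empty species label")
  hit <- assignments$species == predator_species
  cnt <- sum(assignment_counts(assignments)[hit])
  ids <- if (!is.null(assignments$query_id))
    assignments$query_id[hit] else character(0)
  list(count = cnt, ids = ids)
}

#' Base-composition statistics of a set of sequences
#'
#' Per-sequence percentages of each base and of GC overall and at the
#' three codon positions (codons indexed from `frame`), aggregated as
#' min, mean, max and standard error over sequences. Ambiguous bases are
#' excluded from the denominators, so %A + %C + %G + %T = 100 per
#' sequence.
#'
#' @param records Data frame with a `sequence` column; all sequences are
#'   assumed to share the reading frame.
#' @param frame Reading frame (1-3) from which codon positions are
#'   counted.
#' @return List with `per_sequence` (data frame of per-sequence
#'   percentages) and `stats` (data frame with rows `min`, `mean`, `max`,
#'   `se`). SE is the sample standard deviation (n - 1) over sqrt(n),
#'   zero for a single sequence.
#' @export
base_composition <- function(records, frame = 1L) {
  stopifnot(nrow(records) >= 1L, frame %in% 1:3)
  per <- do.call(rbind, lapply(records$sequence, function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    pos_in_codon <- ((seq_along(chars) - frame) %% 3L) + 1L
    pos_in_codon[seq_along(chars) < frame] <- NA_integer_
    base_pct <- function(sel) {
      sub <- chars[sel]
      sub <- sub[sub %in% BASES]
      if (!length(sub)) return(stats::setNames(rep(NA_real_, 4), BASES))
      100 * vapply(BASES, function(b) mean(sub == b), numeric(1))
    }
    all_pct <- base_pct(rep(TRUE, length(chars)))
    gc_pos <- vapply(1:3, function(p) {
      pp <- base_pct(!is.na(pos_in_codon) & pos_in_codon == p)
      pp[["G"]] + pp[["C"]]
    }, numeric(1))
    data.frame(pct_G = all_pct[["G"]], pct_C = all_pct[["C"]],
               pct_A = all_pct[["A"]], pct_T = all_pct[["T"]],
               pct_GC = all_pct[["G"]] + all_pct[["C"]],
               pct_GC_pos1 = gc_pos[1], pct_GC_pos2 = gc_pos[2],
               pct_GC_pos3 = gc_pos[3])
  }))
  n <- nrow(per)
  se <- function(x) if (n == 1L) 0 else stats::sd(x) / sqrt(n)
  stats_df <- data.frame(
    statistic = c("min", "mean", "max", "se"),
    rbind(vapply(per, min, numeric(1)), vapply(per, mean, numeric(1)),
          vapply(per, max, numeric(1)), vapply(per, se, numeric(1))),
    row.names = NULL, check.names = FALSE)
  list(per_sequence = per, stats = stats_df)
}
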