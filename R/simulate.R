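#' Configuration for the barcode library / query simulator
#'
#' The simulator emulates the statistical structure a barcode identification
#' pipeline relies on: a taxonomy-structured reference library whose
#' sequences diverge little within species and much more between species
#' (well separated around the 3 percent species rule), and query fragments
#' that are truncated, lightly mutated copies of library haplotypes.
#'
#' Divergences are expected substitutions per site between two tips:
#' `intraspecific_div` separates haplotypes of one species,
#' `interspecific_div` separates congeneric species, and each coarser rank
#' multiplies the interspecific divergence by `deeper_div`.
#'
#' @param seed Integer seed; the same config yields byte-identical output.
#' @param n_orders,families_per_order,genera_per_family,species_per_genus
#'   Cardinalities of the balanced taxonomy (all positive).
#' @param haplotypes_per_species Sequences per species in the library.
#' @param barcode_length Length of the simulated barcode in bp.
#' @param kappa Transition/transversion rate ratio of the K80 process.
#' @param intraspecific_div Expected substitutions/site within species.
#' @param interspecific_div Expected substitutions/site between congeners.
#' @param deeper_div Per-rank multiplier for genus/family/order splits
#'   (must exceed 1).
#' @param query_length_mix List of `c(prob, min_len, max_len)` triples;
#'   probabilities must sum to 1. The default reproduces the observed read
#'   length mixture of stomach-content amplicons: 85 percent at 600+ bp,
#'   most of the rest 300-500 bp, and a rare few below 200 bp.
#' @param query_error_rate Additional substitutions/site applied to queries
#'   (sequencing error plus template damage).
#' @param dark_taxon_fraction Fraction of queries drawn from species
#'   withheld from the reference library.
#' @param cannibal_fraction Fraction of queries drawn from the predator
#'   species itself.
#' @param code_table Genetic code used for stop-codon screening:
#'   `"vertebrate_mito"`, `"invertebrate_mito"` or `"standard"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_orders = 5L, families_per_order = 2L,
                       genera_per_family = 2L, species_per_genus = 2L,
                       haplotypes_per_species = 2L,
                       barcode_length = 658L,
                       kappa = 3,
                       intraspecific_div = 0.005,
                       interspecific_div = 0.05,
                       deeper_div = 2,
                       query_length_mix = list(c(0.85, 600, 658),
                                               c(0.13, 300, 500),
                                               c(0.02, 100, 199)),
                       query_error_rate = 0.005,
                       dark_taxon_fraction = 0.256,
                       cannibal_fraction = 0.095,
                       code_table = "vertebrate_mito") {
  cfg <- list(seed = as.integer(seed), n_orders = as.integer(n_orders),
              families_per_order = as.integer(families_per_order),
              genera_per_family = as.integer(genera_per_family),
              species_per_genus = as.integer(species_per_genus),
              haplotypes_per_species = as.integer(haplotypes_per_species),
              barcode_length = as.integer(barcode_length),
              kappa = kappa, intraspecific_div = intraspecific_div,
              interspecific_div = interspecific_div, deeper_div = deeper_div,
              query_length_mix = query_length_mix,
              query_error_rate = query_error_rate,
              dark_taxon_fraction = dark_taxon_fraction,
              cannibal_fraction = cannibal_fraction,
              code_table = code_table)
  counts <- c(cfg$n_orders, cfg$families_per_order, cfg$genera_per_family,
              cfg$species_per_genus, cfg$haplotypes_per_species)
  if (any(counts < 1L)) stop("all taxonomy cardinalities must be >= 1")
  if (cfg$barcode_length < 3L) stop("barcode_length must be >= 3")
  if (cfg$kappa <= 0) stop("kappa must be positive")
  if (cfg$intraspecific_div >= cfg$interspecific_div)
    stop("intraspecific_div must be smaller than interspecific_div")
  if (cfg$deeper_div <= 1) stop("deeper_div must exceed 1")
  probs <- vapply(cfg$query_length_mix, `[`, numeric(1), 1)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("query_length_mix probabilities must sum to 1")
  for (comp in cfg$query_length_mix) {
    if (comp[2] > comp[3]) stop("query_length_mix: min_len > max_len")
    if (comp[3] > cfg$barcode_length)
      stop("query_length_mix: requested length exceeds barcode_length")
  }
  if (cfg$dark_taxon_fraction < 0 || cfg$dark_taxon_fraction > 1 ||
      cfg$cannibal_fraction < 0 || cfg$cannibal_fraction > 1)
    stop("dark_taxon_fraction and cannibal_fraction must lie in [0, 1]")
  stop_codons(cfg$code_table)  # validates the code name
  class(cfg) <- "sim_config"
  cfg
}

GENETIC_CODE_IDS <- c(standard = "1", vertebrate_mito = "2",
                      invertebrate_mito = "5")

stop_codons <- function(code_table) {
  id <- GENETIC_CODE_IDS[[match.arg(code_table, names(GENETIC_CODE_IDS))]]
  gc <- Biostrings::getGeneticCode(id)
  names(gc)[gc == "*"]
}

BASES <- c("A", "C", "G", "T")

#' Generate a balanced four-rank taxonomy
#'
#' Labels encode their lineage (`Ord1_Fam2_Gen1_sp2`) so every label is
#' unique. Output is deterministic (the seed only matters for the sequence
#' stages).
#'
#' @param config A [sim_config()].
#' @return Data frame with columns `order`, `family`, `genus`, `species`,
#'   one row per species.
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- expand.grid(sp = seq_len(config$species_per_genus),
                      gen = seq_len(config$genera_per_family),
                      fam = seq_len(config$families_per_order),
                      ord = seq_len(config$n_orders))
  rows <- rows[order(rows$ord, rows$fam, rows$gen, rows$sp), ]
  ord <- paste0("Ord", rows$ord)
  fam <- paste0(ord, "_Fam", rows$fam)
  gen <- paste0(fam, "_Gen", rows$gen)
  sp <- paste0(gen, "_sp", rows$sp)
  out <- data.frame(order = ord, family = fam, genus = gen, species = sp,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# K80 transition probability matrix for branch length t (expected
# substitutions/site) and transition/transversion ratio kappa. Rates are
# normalised so alpha + 2 beta = 1.
k80_pmatrix <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv <- 0.25 - 0.25 * e1
  # base order A C G T; transitions are A<->G and C<->T
  m <- matrix(tv, 4, 4, dimnames = list(BASES, BASES))
  diag(m) <- same
  m["A", "G"] <- m["G", "A"] <- ts
  m["C", "T"] <- m["T", "C"] <- ts
  m
}

# Evolve an integer-coded sequence (1..4 = A,C,G,T) along one branch.
evolve_branch <- function(seq_int, t, kappa) {
  if (t <= 0) return(seq_int)
  P <- k80_pmatrix(t, kappa)
  cum <- t(apply(P, 1, cumsum))
  u <- stats::runif(length(seq_int))
  out <- integer(length(seq_int))
  for (b in 1:4) {
    idx <- which(seq_int == b)
    if (!length(idx)) next
    out[idx] <- findInterval(u[idx], cum[b, ], left.open = TRUE) + 1L
  }
  out
}

# Positions (1-based) of complete codons given the frame offset of the
# first base within its codon (0 = frame 1).
codon_starts <- function(len, phase = 0L) {
  first <- ((3L - phase) %% 3L) + 1L
  starts <- seq.int(first, len - 2L, by = 3L)
  starts[starts >= 1L]
}

codon_at <- function(seq_int, start) {
  paste(BASES[seq_int[start:(start + 2L)]], collapse = "")
}

# Replace child codons that became stops: redraw the codon from the parent
# under the same branch process; after max_try failures revert to parent.
enforce_no_stops <- function(child, parent, t, kappa, stops, phase = 0L,
                             max_try = 50L) {
  starts <- codon_starts(length(child), phase)
  for (s in starts) {
    tries <- 0L
    while (codon_at(child, s) %in% stops && tries < max_try) {
      child[s:(s + 2L)] <- evolve_branch(parent[s:(s + 2L)], t, kappa)
      tries <- tries + 1L
    }
    if (codon_at(child, s) %in% stops)
      child[s:(s + 2L)] <- parent[s:(s + 2L)]
  }
  child
}

# Random in-frame coding ancestor: uniform bases with stop codons redrawn.
random_coding_ancestor <- function(len, stops, max_try = 1000L) {
  seq_int <- sample.int(4L, len, replace = TRUE)
  for (s in codon_starts(len, 0L)) {
    tries <- 0L
    while (codon_at(seq_int, s) %in% stops) {
      if (tries >= max_try)
        stop("could not construct a stop-free ancestor in ", max_try,
             " attempts")
      seq_int[s:(s + 2L)] <- sample.int(4L, 3L, replace = TRUE)
      tries <- tries + 1L
    }
  }
  seq_int
}

int_to_seq <- function(x) paste(BASES[x], collapse = "")
seq_to_int <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]], BASES)

#' Simulate a taxonomy-structured reference barcode library
#'
#' One ancestral in-frame coding sequence is evolved down the balanced
#' taxonomy under a K80 substitution process with ultrametric per-rank
#' depths, so that the expected pairwise divergence between two conspecific
#' haplotypes equals `intraspecific_div`, between congeneric species
#' `interspecific_div`, and `deeper_div` times more per coarser rank.
#' Substitutions that would create an in-frame stop codon are redrawn;
#' no indels are introduced, mirroring clean COI barcodes.
#'
#' @param config A [sim_config()].
#' @param taxonomy Output of [simulate_taxonomy()] (or a compatible data
#'   frame of species paths).
#' @return Data frame with columns `id`, `sequence`, `order`, `family`,
#'   `genus`, `species`; `haplotypes_per_species` rows per species.
#' @export
simulate_reference_library <- function(config, taxonomy) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stops <- stop_codons(config$code_table)
  kappa <- config$kappa
  len <- config$barcode_length

  s <- config$interspecific_div; m <- config$deeper_div
  depth <- c(root = s * m^3 / 2, order = s * m^2 / 2, family = s * m / 2,
             genus = s / 2, species = config$intraspecific_div / 2)
  branch <- c(order = depth[["root"]] - depth[["order"]],
              family = depth[["order"]] - depth[["family"]],
              genus = depth[["family"]] - depth[["genus"]],
              species = depth[["genus"]] - depth[["species"]],
              tip = depth[["species"]])

  evolve <- function(parent, t) {
    child <- evolve_branch(parent, t, kappa)
    enforce_no_stops(child, parent, t, kappa, stops)
  }

  ancestor <- random_coding_ancestor(len, stops)
  out_id <- character(0); out_seq <- character(0); out_row <- integer(0)

  orders <- unique(taxonomy$order)
  for (o in orders) {
    seq_o <- evolve(ancestor, branch[["order"]])
    fams <- unique(taxonomy$family[taxonomy$order == o])
    for (f in fams) {
      seq_f <- evolve(seq_o, branch[["family"]])
      gens <- unique(taxonomy$genus[taxonomy$family == f])
      for (g in gens) {
        seq_g <- evolve(seq_f, branch[["genus"]])
        sp_rows <- which(taxonomy$genus == g)
        for (r in sp_rows) {
          seq_s <- evolve(seq_g, branch[["species"]])
          for (h in seq_len(config$haplotypes_per_species)) {
            seq_h <- evolve(seq_s, branch[["tip"]])
            out_id <- c(out_id, paste0(taxonomy$species[r], "_h", h))
            out_seq <- c(out_seq, int_to_seq(seq_h))
            out_row <- c(out_row, r)
          }
        }
      }
    }
  }
  data.frame(id = out_id, sequence = out_seq,
             order = taxonomy$order[out_row],
             family = taxonomy$family[out_row],
             genus = taxonomy$genus[out_row],
             species = taxonomy$species[out_row],
             stringsAsFactors = FALSE)
}

#' Choose species to withhold from the reference library
#'
#' Dark taxa in stomach-content surveys sit at very different depths from
#' the reference library: a few have a referenced congener (best matches
#' around 93-96 percent similarity), while most match nothing closer than
#' a confamilial or even just an ordinal relative (79-89 percent). To
#' reproduce that skew, species are withheld at three depths: lone species
#' from genera with at least two species (congener stays referenced),
#' whole genera from families with at least two genera, and whole families
#' from orders with at least two families. The predator species is never
#' withheld.
#'
#' @param taxonomy Species-level taxonomy data frame.
#' @param seed Integer seed.
#' @param predator_species Species label excluded from withholding.
#' @param n_lone_species Number of single species to withhold.
#' @param n_whole_genera Number of complete genera to withhold.
#' @param n_whole_families Number of complete families to withhold.
#' @return Character vector of withheld species labels.
#' @export
choose_withheld_species <- function(taxonomy, seed = 1L,
                                    predator_species = NULL,
                                    n_lone_species = 2L,
                                    n_whole_genera = 1L,
                                    n_whole_families = 1L) {
  set.seed(seed)
  withheld <- character(0)
  ok_rows <- function() !(taxonomy$species %in% c(withheld,
                                                  predator_species))
  # whole families, from orders keeping at least one other family
  fam_by_order <- unique(taxonomy[, c("order", "family")])
  cand_fam <- fam_by_order$family[
    fam_by_order$order %in% names(which(table(fam_by_order$order) >= 2))]
  cand_fam <- setdiff(cand_fam,
                      taxonomy$family[taxonomy$species %in% predator_species])
  if (n_whole_families > 0L && length(cand_fam)) {
    take <- cand_fam[sample.int(length(cand_fam),
                                min(n_whole_families, length(cand_fam)))]
    withheld <- c(withheld, taxonomy$species[taxonomy$family %in% take])
  }
  # whole genera, from untouched families keeping at least one other genus
  gen_by_fam <- unique(taxonomy[ok_rows(), c("family", "genus")])
  cand_gen <- gen_by_fam$genus[
    gen_by_fam$family %in% names(which(table(gen_by_fam$family) >= 2))]
  cand_gen <- setdiff(cand_gen,
                      taxonomy$genus[taxonomy$species %in% predator_species])
  if (n_whole_genera > 0L && length(cand_gen)) {
    take <- cand_gen[sample.int(length(cand_gen),
                                min(n_whole_genera, length(cand_gen)))]
    withheld <- c(withheld, taxonomy$species[taxonomy$genus %in% take])
  }
  # lone species whose genus keeps at least one referenced congener
  left <- taxonomy[ok_rows(), ]
  gsize <- table(left$genus)
  cand_sp <- left[gsize[left$genus] >= 2, ]
  cand_sp <- cand_sp[!duplicated(cand_sp$genus), ]
  if (n_lone_species > 0L && nrow(cand_sp)) {
    withheld <- c(withheld, cand_sp$species[
      sample.int(nrow(cand_sp), min(n_lone_species, nrow(cand_sp)))])
  }
  sort(unique(withheld))
}

#' Simulate degraded stomach-content query fragments
#'
#' Each query is a contiguous substring of a library haplotype with its
#' length drawn from `query_length_mix`, a uniform start position, and
#' additional point substitutions at `query_error_rate` (stop-codon
#' preserving in the source reading frame; no indels). Queries fall into
#' three categories: `cannibal` (drawn from the predator species), `dark`
#' (drawn from species withheld from the reference library), and `normal`
#' (any other referenced species).
#'
#' @param config A [sim_config()].
#' @param library Output of [simulate_reference_library()].
#' @param withheld_species Species labels absent from the reference set;
#'   sources for dark queries.
#' @param n_queries Number of queries to generate.
#' @param predator_species Predator species label; defaults to the first
#'   species in the library.
#' @return List with `queries` (data frame `id`, `sequence`, `desc`) and
#'   `truth` (data frame `id`, `source_id`, `species`, `genus`, `family`,
#'   `order`, `category`, `start`, `length`).
#' @export
simulate_queries <- function(config, library, withheld_species = character(0),
                             n_queries = 100L, predator_species = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  if (is.null(predator_species)) predator_species <- library$species[1]
  if (length(withheld_species) &&
      any(!withheld_species %in% library$species))
    stop("withheld_species must name species present in the full library")
  stops <- stop_codons(config$code_table)

  u <- stats::runif(n_queries)
  category <- ifelse(u < config$cannibal_fraction, "cannibal",
              ifelse(u < config$cannibal_fraction + config$dark_taxon_fraction,
                     "dark", "normal"))
  if (length(withheld_species) == 0L) category[category == "dark"] <- "normal"

  normal_pool <- which(!(library$species %in% withheld_species) &
                         library$species != predator_species)
  dark_pool <- which(library$species %in% withheld_species)
  cannibal_pool <- which(library$species == predator_species)
  if (!length(normal_pool)) stop("no referenced non-predator species to draw from")

  probs <- vapply(config$query_length_mix, `[`, numeric(1), 1)
  mins <- vapply(config$query_length_mix, `[`, numeric(1), 2)
  maxs <- vapply(config$query_length_mix, `[`, numeric(1), 3)

  ids <- sprintf("q%04d", seq_len(n_queries))
  seqs <- character(n_queries)
  src <- integer(n_queries); starts <- integer(n_queries)
  lens <- integer(n_queries)
  for (i in seq_len(n_queries)) {
    pool <- switch(category[i], cannibal = cannibal_pool, dark = dark_pool,
                   normal = normal_pool)
    src[i] <- pool[sample.int(length(pool), 1L)]
    comp <- sample.int(length(probs), 1L, prob = probs)
    lens[i] <- sample.int(maxs[comp] - mins[comp] + 1L, 1L) + mins[comp] - 1L
    starts[i] <- sample.int(config$barcode_length - lens[i] + 1L, 1L)
    frag <- seq_to_int(library$sequence[src[i]])[starts[i]:(starts[i] + lens[i] - 1L)]
    if (config$query_error_rate > 0) {
      mutated <- evolve_branch(frag, config$query_error_rate, config$kappa)
      phase <- (starts[i] - 1L) %% 3L
      frag <- enforce_no_stops(mutated, frag, config$query_error_rate,
                               config$kappa, stops, phase = phase)
    }
    seqs[i] <- int_to_seq(frag)
  }
  queries <- data.frame(id = ids, sequence = seqs,
                        desc = paste0("category=", category),
                        stringsAsFactors = FALSE)
  truth <- data.frame(id = ids, source_id = library$id[src],
                      species = library$species[src],
                      genus = library$genus[src],
                      family = library$family[src],
                      order = library$order[src],
                      category = category, start = starts, length = lens,
                      stringsAsFactors = FALSE)
  list(queries = queries, truth = truth)
}
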