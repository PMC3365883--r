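#' Run the full identification and diet-composition pipeline
#'
#' Orchestrates QC, identification and composition over files on disk and
#' writes every stage's table plus a JSON manifest (input checksums,
#' parameters, per-stage record counts) into `out_dir`. Reruns with the
#' same inputs and parameters produce byte-identical outputs.
#'
#' @param config A list (or path to a YAML file) with entries:
#'   `refs`, `taxonomy`, `queries`, `checklist` (input paths), `out_dir`,
#'   `predator_species`, and optionally `min_len`, `max_ambiguous`,
#'   `code_table`, `species_threshold_pct`, `crustacean_orders`.
#' @return Invisibly, a list with the manifest and the main result tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(min_len = 100L, max_ambiguous = 0.02,
                   code_table = "vertebrate_mito",
                   species_threshold_pct = 3.0,
                   crustacean_orders = character(0),
                   predator_species = "")
  config <- utils::modifyList(defaults, config)

  for (p in c("refs", "taxonomy", "queries", "checklist")) {
    if (is.null(config[[p]]))
      stop("validation: config entry '", p, "' is required")
    if (!file.exists(config[[p]]))
      stop("validation: missing input file for '", p, "': ", config[[p]])
  }
  if (is.null(config$out_dir)) stop("validation: out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$out_dir, name)

  refs <- read_fasta(config$refs)
  taxonomy <- read_taxonomy(config$taxonomy)
  if (any(!refs$id %in% taxonomy$id))
    stop("io: reference ids missing from taxonomy: ",
         refs$id[!refs$id %in% taxonomy$id][1])
  queries <- read_fasta(config$queries)
  checklist <- read_checklist(config$checklist)

  qc <- qc_batch(queries, min_len = config$min_len,
                 max_ambiguous = config$max_ambiguous,
                 code_table = config$code_table)
  write_table(qc$reports, out("qc.tsv"))

  idf <- identify_batch(qc$passing, refs, taxonomy,
                        species_threshold_pct = config$species_threshold_pct)
  asn <- idf$assignments
  asn_out <- data.frame(query_id = asn$query_id, method = asn$method,
                        rank = asn$rank, taxon = asn$taxon,
                        best_ref_id = asn$best_ref_id,
                        similarity_pct = sprintf("%.2f",
                                                 asn$best_similarity_pct),
                        k2p_pct = sprintf("%.4f", asn$best_k2p_pct),
                        n_ties = asn$n_ties, stringsAsFactors = FALSE)
  write_table(asn_out, out("assignments.tsv"))
  write_table(asn, out("assignments_full.tsv"))

  asn <- add_prey_class(asn, crustacean_orders = config$crustacean_orders)
  write_table(percent_n(asn, "class", "all"), out("composition_class.tsv"))
  write_table(percent_n(asn, "family", if (length(config$crustacean_orders))
    "fish_only" else "all"), out("composition_family.tsv"))
  write_table(percent_n(asn, "species", if (length(config$crustacean_orders))
    "fish_only" else "all"), out("composition_species.tsv"))
  rich <- richness(asn)
  write_table(data.frame(rank = names(rich), n_taxa = as.integer(rich)),
              out("richness.tsv"))
  newrec <- flag_new_records(asn, checklist)
  write_table(data.frame(species = newrec), out("new_records.tsv"))
  cann <- if (nzchar(config$predator_species))
    flag_cannibalism(asn, config$predator_species)
  else list(count = 0L, ids = character(0))
  write_table(data.frame(query_id = cann$ids), out("cannibalism.tsv"))

  pred_refs <- taxonomy$id[taxonomy$species == config$predator_species]
  basecomp_recs <- refs[refs$id %in% pred_refs, , drop = FALSE]
  if (nrow(basecomp_recs) == 0L) basecomp_recs <- refs
  bc <- base_composition(basecomp_recs)
  write_table(bc$stats, out("basecomp.tsv"))

  manifest <- list(
    tool = "barcodediet",
    version = as.character(utils::packageVersion("barcodediet")),
    parameters = config[c("min_len", "max_ambiguous", "code_table",
                          "species_threshold_pct", "predator_species")],
    inputs = as.list(tools::md5sum(unlist(config[c("refs", "taxonomy",
                                                   "queries",
                                                   "checklist")]))),
    counts = list(n_queries = nrow(queries),
                  n_pass_qc = as.integer(qc$summary[["n_pass"]]),
                  n_fail_qc = nrow(queries) -
                    as.integer(qc$summary[["n_pass"]]),
                  by_method = as.list(idf$report$by_method),
                  by_rank = as.list(idf$report$by_rank),
                  n_new_records = length(newrec),
                  n_cannibal = cann$count))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, qc = qc, assignments = asn,
                 new_records = newrec, cannibalism = cann))
}

#' Write a small demonstration fixture set
#'
#' Simulates a reference library (40 species, 2 haplotypes each) and 168
#' query fragments -- the number of readable stomach-content sequences the
#' pipeline's record bookkeeping mirrors -- together with their taxonomy,
#' an answer sheet, and a regional checklist that omits a few referenced
#' species so that new-record flagging has something to find.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed.
#' @param n_queries Number of query fragments.
#' @return Invisibly, a list with the file paths and the truth sheet.
#' @export
make_demo_fixture <- function(out_dir, seed = 1L, n_queries = 168L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed)
  taxonomy <- simulate_taxonomy(cfg)
  lib <- simulate_reference_library(cfg, taxonomy)
  predator <- taxonomy$species[1]
  withheld <- choose_withheld_species(taxonomy, seed = seed,
                                      predator_species = predator)
  sim <- simulate_queries(cfg, lib, withheld_species = withheld,
                          n_queries = n_queries,
                          predator_species = predator)
  refs <- lib[!(lib$species %in% withheld), , drop = FALSE]

  set.seed(seed + 2L)
  ref_species <- unique(refs$species)
  n_drop <- max(1L, round(0.08 * length(ref_species)))
  missing_from_checklist <-
    ref_species[sample.int(length(ref_species), n_drop)]
  checklist <- sort(setdiff(ref_species, missing_from_checklist))

  paths <- list(refs = file.path(out_dir, "reference.fasta"),
                taxonomy = file.path(out_dir, "reference_taxonomy.tsv"),
                queries = file.path(out_dir, "queries.fasta"),
                truth = file.path(out_dir, "truth.tsv"),
                checklist = file.path(out_dir, "checklist.txt"))
  write_fasta(refs, paths$refs)
  write_taxonomy(cbind(id = refs$id, refs[, RANKS]), paths$taxonomy)
  write_fasta(sim$queries, paths$queries)
  write_table(sim$truth, paths$truth)
  writeLines(checklist, paths$checklist)
  invisible(list(paths = paths, truth = sim$truth, config = cfg,
                 predator_species = predator, withheld = withheld))
}
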