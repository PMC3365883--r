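# Small hand-built reference set: two Halichoeres species (two haplotypes
# of one), one genus-only Synalpheus record, plus one distant outgroup.
make_tiny_refs <- function() {
  base <- random_dna(400, seed = 55)
  hg2 <- mutate_seq(base, c(30, 200), c("T", "C"))
  pos <- seq(5, 400, by = 10)
  orig <- strsplit(base, "")[[1]][pos]
  sib <- mutate_seq(base, pos, chartr("ACGT", "CATG", orig))  # 10% congener
  syn <- mutate_seq(random_dna(400, seed = 56), 1, "A")
  refs <- data.frame(id = c("hg_h1", "hg_h2", "hb_h1", "syn_h1"),
                     sequence = c(base, hg2, sib, syn))
  taxonomy <- data.frame(
    id = refs$id,
    order = c("Perciformes", "Perciformes", "Perciformes", "Decapoda"),
    family = c("Labridae", "Labridae", "Labridae", "Alpheidae"),
    genus = c("Halichoeres", "Halichoeres", "Halichoeres", "Synalpheus"),
    species = c("Halichoeres garnoti", "Halichoeres garnoti",
                "Halichoeres bivittatus", ""))
  list(refs = refs, taxonomy = taxonomy, base = base)
}

test_that("ranked matches put the identical reference first", {
  tiny <- make_tiny_refs()
  q <- data.frame(id = "q1", sequence = tiny$base)
  hits <- best_matches(q, tiny$refs)
  expect_identical(hits$ref_id[1], "hg_h1")
  expect_equal(hits$similarity_pct[1], 100)
  expect_error(best_matches(q, tiny$refs[0, ]), "empty")
})

test_that("ties within 0.01 similarity are counted and ordered by id", {
  base <- random_dna(300, seed = 77)
  refs <- data.frame(id = c("r_b", "r_a"), sequence = c(base, base))
  taxonomy <- data.frame(id = refs$id, order = "O", family = "F",
                         genus = "G", species = "G s")
  q <- data.frame(id = "q1", sequence = substr(base, 20, 280))
  hits <- best_matches(q, refs)
  expect_equal(hits$n_ties[1], 2)
  expect_identical(hits$ref_id, c("r_a", "r_b"))
})

test_that("sub-threshold matches give species; genus-only refs cap the rank", {
  tiny <- make_tiny_refs()
  # conspecific query: a fragment a few substitutions from hg_h1
  q <- data.frame(id = "q1",
                  sequence = mutate_seq(substr(tiny$base, 40, 380),
                                        c(17, 101), c("T", "T")))
  hits <- compare_to_references(q, tiny$refs)
  asn <- assign_query(q, hits, tiny$refs, tiny$taxonomy)
  expect_identical(asn$method, "threshold")
  expect_identical(asn$rank, "species")
  expect_identical(asn$taxon, "Halichoeres garnoti")
  expect_lt(asn$best_k2p_pct, 3)
  # near-identical match to a genus-only reference: genus-level call
  q2 <- data.frame(id = "q2",
                   sequence = mutate_seq(tiny$refs$sequence[4], 57, "T"))
  hits2 <- compare_to_references(q2, tiny$refs)
  asn2 <- assign_query(q2, hits2, tiny$refs, tiny$taxonomy)
  expect_identical(asn2$method, "threshold")
  expect_identical(asn2$rank, "genus")
  expect_identical(asn2$taxon, "Synalpheus")
})

test_that("in-band species disagreement resolves to the unanimous genus", {
  base <- random_dna(400, seed = 91)
  near <- mutate_seq(base, c(10, 50), c("T", "T"))
  refs <- data.frame(id = c("spA", "spB"), sequence = c(base, near))
  taxonomy <- data.frame(id = refs$id, order = "Perciformes",
                         family = "Gobiidae", genus = "Coryphopterus",
                         species = c("Coryphopterus eidolon",
                                     "Coryphopterus thrix"))
  q <- data.frame(id = "q1", sequence = mutate_seq(base, 200, "T"))
  asn <- assign_query(q, compare_to_references(q, refs), refs, taxonomy)
  expect_identical(asn$method, "threshold")
  expect_identical(asn$rank, "genus")
  expect_identical(asn$taxon, "Coryphopterus")
})

test_that("queries without in-band hits fall back to the strict tree", {
  s <- small_sim(seed = 121, interspecific_div = 0.08)
  predator <- s$tax$species[1]
  # withhold one species whose congener stays referenced
  withheld <- s$tax$species[2]
  stopifnot(s$tax$genus[2] == s$tax$genus[1] ||
            any(s$tax$genus[-2] == s$tax$genus[2]))
  cfg <- s$cfg
  cfg$query_length_mix <- list(c(1, 400, 400))
  sim <- simulate_queries(cfg, s$lib, withheld_species = withheld,
                          n_queries = 40, predator_species = predator)
  refs <- s$lib[!(s$lib$species %in% withheld), ]
  taxdf <- s$taxdf[s$taxdf$id %in% refs$id, ]
  res <- identify_batch(sim$queries, refs, taxdf)
  m <- merge(res$assignments, sim$truth, by.x = "query_id", by.y = "id")
  dark <- m[m$category == "dark", ]
  expect_gt(nrow(dark), 0)
  expect_true(all(dark$method == "strict-tree"))
  expect_true(all(dark$rank != "species"))
  expect_true(all(dark$genus.x == dark$genus.y))
  # non-dark full-length error-bearing queries resolve to the right species
  nd <- m[m$category != "dark", ]
  expect_true(all(nd$method == "threshold"))
  expect_true(all(nd$species.x == nd$species.y))
})

test_that("method bookkeeping and empty input behave", {
  empty <- identify_batch(data.frame(), NULL, NULL)
  expect_equal(nrow(empty$assignments), 0)
  s <- small_sim(seed = 121, interspecific_div = 0.08)
  sim <- simulate_queries(s$cfg, s$lib, n_queries = 12)
  res <- identify_batch(sim$queries, s$lib, s$taxdf)
  expect_equal(sum(res$report$by_method), 12)
  expect_equal(nrow(res$assignments), 12)
})

test_that("raising the threshold never demotes a species assignment", {
  s <- small_sim(seed = 131, interspecific_div = 0.1)
  sim <- simulate_queries(s$cfg, s$lib, n_queries = 30)
  res3 <- identify_batch(sim$queries, s$lib, s$taxdf,
                         species_threshold_pct = 3)
  res4 <- identify_batch(sim$queries, s$lib, s$taxdf,
                         species_threshold_pct = 4)
  was_species <- res3$assignments$rank == "species"
  expect_true(all(res4$assignments$rank[was_species] == "species"))
})

test_that("well-separated species are never misassigned at any rank", {
  # interspecific divergence above twice the threshold: wrong species
  # would need a threshold-violating simulation
  cfg <- sim_config(seed = 141, n_orders = 2, families_per_order = 1,
                    genera_per_family = 2, species_per_genus = 2,
                    barcode_length = 400, interspecific_div = 0.08,
                    query_length_mix = list(c(0.9, 300, 400),
                                            c(0.1, 150, 299)))
  tax <- simulate_taxonomy(cfg)
  lib <- simulate_reference_library(cfg, tax)
  taxdf <- cbind(id = lib$id,
                 lib[, c("order", "family", "genus", "species")])
  sim <- simulate_queries(cfg, lib, n_queries = 40)
  res <- identify_batch(sim$queries, lib, taxdf)
  m <- merge(res$assignments, sim$truth, by.x = "query_id", by.y = "id")
  thr <- m[m$method == "threshold", ]
  for (r in c("order", "family", "genus", "species")) {
    assigned <- nzchar(thr[[paste0(r, ".x")]])
    expect_true(all(thr[[paste0(r, ".x")]][assigned] ==
                      thr[[paste0(r, ".y")]][assigned]))
  }
})
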