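test_that("K2P closed form matches hand-counted examples", {
  # one transition among 8 sites: P = 0.125, Q = 0
  a <- k2p_distance("AAAAAAAA", "GAAAAAAA")
  expect_equal(a$transitions, 1)
  expect_equal(a$transversions, 0)
  expect_equal(a$p_distance, 0.125)
  expect_equal(a$k2p, 0.14384103622589, tolerance = 1e-12)
  # one transversion among 4 sites: P = 0, Q = 0.25
  b <- k2p_distance("AAAA", "ACAA")
  expect_equal(b$transversions, 1)
  expect_equal(b$k2p, 0.31712783136588, tolerance = 1e-12)
  # identical sequences
  c0 <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(c0$k2p, 0)
  expect_equal(c0$similarity_pct, 100)
})

test_that("pairwise deletion excludes ambiguous and gapped sites", {
  d <- k2p_distance("AC-GTN", "ACAGTA")
  expect_equal(d$overlap_sites, 4)   # N and gap columns dropped
  expect_equal(d$internal_gaps, 1)
  expect_equal(d$p_distance, 0)
  expect_error(k2p_distance("NNNN", "ACGT"), "NO_OVERLAP")
})

test_that("comparisons are symmetric and k2p dominates p-distance", {
  set.seed(21)
  for (i in 1:25) {
    x <- random_dna(60)
    y <- mutate_seq(x, sample(60, 8), sample(c("A", "C", "G", "T"), 8, TRUE))
    f <- k2p_distance(x, y)
    g <- k2p_distance(y, x)
    expect_equal(f[c("overlap_sites", "transitions", "transversions",
                     "p_distance", "k2p")],
                 g[c("overlap_sites", "transitions", "transversions",
                     "p_distance", "k2p")])
    if (is.finite(f$k2p)) expect_gte(f$k2p, f$p_distance)
    expect_equal(f$similarity_pct + 100 * f$p_distance, 100)
  }
})

test_that("saturated pairs report infinite distance", {
  d <- k2p_distance("AAAA", "CCCC")
  expect_true(d$saturated)
  expect_identical(d$k2p, Inf)
})

test_that("fragments align to their containing region without gaps", {
  ref <- random_dna(400, seed = 31)
  q <- substr(ref, 51, 350)
  aln <- align_overlap(q, ref)
  cmp <- k2p_distance(aln$query_aln, aln$ref_aln)
  expect_equal(cmp$overlap_sites, 300)
  expect_equal(cmp$p_distance, 0)
  expect_equal(cmp$internal_gaps, 0)
  # full-length self alignment
  aln2 <- align_overlap(ref, ref)
  expect_equal(nchar(aln2$query_aln), 400)
  # three substitutions stay three mismatches
  orig <- strsplit(q, "")[[1]][c(10, 150, 290)]
  q3 <- mutate_seq(q, c(10, 150, 290), ifelse(orig == "T", "G", "T"))
  aln3 <- align_overlap(q3, ref)
  cmp3 <- k2p_distance(aln3$query_aln, aln3$ref_aln)
  expect_equal(cmp3$overlap_sites, 300)
  expect_equal(cmp3$transitions + cmp3$transversions, 3)
})

test_that("alignment scores are optimal against a brute-force oracle", {
  set.seed(77)
  for (i in 1:40) {
    q <- random_dna(sample(3:12, 1))
    r <- random_dna(sample(3:12, 1))
    aln <- align_overlap(q, r)
    got <- score_of_alignment(aln$query_aln, aln$ref_aln)
    expect_equal(got, oracle_overlap_score(q, r),
                 info = paste(q, r))
  }
})

test_that("banded batch comparisons agree with the full dynamic program", {
  set.seed(99)
  for (i in 1:15) {
    r <- random_dna(658)
    st <- sample(1:350, 1)
    q <- substr(r, st, min(658, st + sample(c(99, 299, 500), 1)))
    nmut <- rbinom(1, nchar(q), sample(c(0.01, 0.15), 1))
    if (nmut > 0)
      q <- mutate_seq(q, sample(nchar(q), nmut),
                      sample(c("A", "C", "G", "T"), nmut, TRUE))
    full <- barcodediet:::.align_counts_cpp(q, r, 1, -1, 10, 1, 0L)
    banded <- barcodediet:::.align_counts_cpp(q, r, 1, -1, 10, 1, 24L)
    expect_identical(full, banded)
  }
})

test_that("distance matrices are symmetric with zero diagonal", {
  lib <- small_sim()$lib
  dm <- distance_matrix(lib[1:10, ])
  expect_identical(dm$matrix, t(dm$matrix))
  expect_true(all(diag(dm$matrix) == 0))
  same <- data.frame(id = c("a", "b", "c"), sequence = rep(lib$sequence[1], 3))
  expect_true(all(distance_matrix(same)$matrix == 0))
  expect_error(distance_matrix(lib[1, , drop = FALSE]), "at least 2")
})

test_that("K2P matrices agree with an independent implementation", {
  lib <- small_sim()$lib
  sub <- lib[lib$order == lib$order[1], ][1:6, ]  # moderate divergences
  mine <- distance_matrix(sub)$matrix
  bin <- ape::as.DNAbin(t(sapply(sub$sequence,
                                 function(s) strsplit(tolower(s), "")[[1]])))
  rownames(bin) <- sub$id
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(mine[sub$id, sub$id], ref[sub$id, sub$id], tolerance = 1e-10)
})

test_that("low intraspecific divergence reproduces sub-0.1% mean K2P", {
  # 30 conspecific barcodes at 0.054% expected divergence, as in a recent
  # single-source invasion
  cfg <- sim_config(seed = 606, n_orders = 1, families_per_order = 1,
                    genera_per_family = 1, species_per_genus = 2,
                    haplotypes_per_species = 30, barcode_length = 658,
                    intraspecific_div = 0.00054, interspecific_div = 0.05)
  lib <- simulate_reference_library(cfg, simulate_taxonomy(cfg))
  one_sp <- lib[lib$species == lib$species[1], ]
  dm <- distance_matrix(one_sp)
  offdiag <- dm$matrix[upper.tri(dm$matrix)]
  # pairwise distances share tip branches, so the effective sample size is
  # the 30 haplotypes, not the 435 pairs: use per-haplotype mean distances
  per_tip <- (rowSums(dm$matrix)) / (nrow(dm$matrix) - 1)
  se <- stats::sd(per_tip) / sqrt(length(per_tip))
  expect_lt(abs(mean(offdiag) - 0.00054), 3 * max(se, 1e-5))
})
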