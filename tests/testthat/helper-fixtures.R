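# Shared fixtures: a small simulated library (8 species x 2 haplotypes,
# 400 bp) built once per test file, plus an independent brute-force
# alignment-score oracle used to verify optimality of the aligner.

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function(seed = 101L, ...) {
  key <- paste0("sim", seed, paste(c(...), collapse = "_"))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  args <- list(seed = seed, n_orders = 2L, families_per_order = 1L,
               genera_per_family = 2L, species_per_genus = 2L,
               haplotypes_per_species = 2L, barcode_length = 400L)
  args <- utils::modifyList(args, list(...))
  if (is.null(args$query_length_mix) && args$barcode_length < 658L)
    args$query_length_mix <- list(c(0.85, 340, 400), c(0.13, 180, 300),
                                  c(0.02, 100, 179))
  cfg <- do.call(sim_config, args)
  tax <- simulate_taxonomy(cfg)
  lib <- simulate_reference_library(cfg, tax)
  out <- list(cfg = cfg, tax = tax, lib = lib,
              taxdf = cbind(id = lib$id,
                            lib[, c("order", "family", "genus", "species")]))
  .fixture_cache[[key]] <- out
  out
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, positions, bases) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[positions] <- bases
  paste(chars, collapse = "")
}

# Brute-force semi-global alignment score: plain dynamic program over the
# three affine states, written independently of the package's C++ kernel.
# Free end gaps; gap of length L costs open + L * extend; non-ACGT pairs
# score 0.
oracle_overlap_score <- function(q, r, match = 1, mismatch = -1,
                                 gap_open = 10, gap_extend = 1) {
  qs <- strsplit(q, "", fixed = TRUE)[[1]]
  rs <- strsplit(r, "", fixed = TRUE)[[1]]
  m <- length(qs); n <- length(rs)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  pair_score <- function(a, b) {
    if (!(a %in% c("A", "C", "G", "T")) || !(b %in% c("A", "C", "G", "T")))
      return(0)
    if (a == b) match else mismatch
  }
  for (i in 1:m) for (j in 1:n) {
    s <- pair_score(qs[i], rs[j])
    prev <- max(M[i, j], X[i, j], Y[i, j],
                if (i == 1 || j == 1) 0 else NEG)
    M[i + 1, j + 1] <- prev + s
    Y[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                           Y[i, j + 1] - gap_extend)
    X[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                           X[i + 1, j] - gap_extend)
  }
  max(M[m + 1, 2:(n + 1)], M[2:(m + 1), n + 1])
}

# Score implied by a gapped aligned pair under the same convention.
score_of_alignment <- function(qa, ra, match = 1, mismatch = -1,
                               gap_open = 10, gap_extend = 1) {
  qs <- strsplit(qa, "", fixed = TRUE)[[1]]
  rs <- strsplit(ra, "", fixed = TRUE)[[1]]
  s <- 0; in_gap <- FALSE
  for (k in seq_along(qs)) {
    if (qs[k] == "-" || rs[k] == "-") {
      s <- s - gap_extend - if (in_gap) 0 else gap_open
      in_gap <- TRUE
    } else {
      in_gap <- FALSE
      if (qs[k] %in% c("A", "C", "G", "T") &&
          rs[k] %in% c("A", "C", "G", "T"))
        s <- s + if (qs[k] == rs[k]) match else mismatch
    }
  }
  s
}

# Quartet split implied by a distance matrix under the four-point
# condition: returns 1 for ij|kl, 2 for ik|jl, 3 for il|jk.
four_point_split <- function(D, i, j, k, l) {
  sums <- c(D[i, j] + D[k, l], D[i, k] + D[j, l], D[i, l] + D[j, k])
  which.min(sums)
}
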