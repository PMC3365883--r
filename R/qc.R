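#' Quality control of a single query sequence
#'
#' Three gates are applied before identification: a minimum length (the
#' mini-barcode floor of 100 bp, below which identification efficiency
#' collapses), a cap on the fraction of ambiguous bases, and a reading-frame
#' check. The reading frame is chosen as the frame (1-3) minimising the
#' number of stop codons among complete codons under the chosen genetic
#' code; a stop codon surviving in the best frame flags a likely pseudogene
#' or spurious read. The trailing partial codon is ignored and codons
#' containing ambiguous bases are skipped in translation.
#'
#' @param record One-row data frame (or list) with `id` and `sequence`.
#' @param min_len Minimum acceptable length in bp.
#' @param max_ambiguous Maximum fraction of ambiguous (non-ACGT) bases.
#' @param code_table Genetic code name, see [sim_config()].
#' @return A one-row data frame: `id`, `length`, `ambiguous_fraction`,
#'   `best_frame`, `stops_in_best_frame`, `pass`, `reasons`
#'   (comma-separated failure codes among `TOO_SHORT`, `TOO_AMBIGUOUS`,
#'   `STOP_CODON`; empty iff `pass`).
#' @export
qc_sequence <- function(record, min_len = 100L, max_ambiguous = 0.02,
                        code_table = "vertebrate_mito") {
  seq <- toupper(record$sequence[1])
  id <- record$id[1]
  stopifnot(nzchar(seq))
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  amb_frac <- mean(!(chars %in% BASES))
  stops <- stop_codons(code_table)

  stops_by_frame <- vapply(1:3, function(f) {
    count_stops(chars, f, stops)
  }, integer(1))
  best_frame <- which.min(stops_by_frame)
  n_stops <- stops_by_frame[best_frame]

  reasons <- character(0)
  if (n < min_len) reasons <- c(reasons, "TOO_SHORT")
  if (amb_frac > max_ambiguous) reasons <- c(reasons, "TOO_AMBIGUOUS")
  if (n_stops > 0L) reasons <- c(reasons, "STOP_CODON")

  data.frame(id = id, length = n, ambiguous_fraction = amb_frac,
             best_frame = as.integer(best_frame),
             stops_in_best_frame = n_stops,
             pass = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ","),
             stringsAsFactors = FALSE)
}

# Count stop codons among complete, unambiguous codons starting at `frame`.
count_stops <- function(chars, frame, stops) {
  n <- length(chars)
  if (frame > n - 2L) return(0L)
  starts <- seq.int(frame, n - 2L, by = 3L)
  codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
  clean <- !grepl(paste0("[^", paste(BASES, collapse = ""), "]"), codons)
  sum(codons[clean] %in% stops)
}

#' Quality control of a batch of query sequences
#'
#' @param records Data frame with columns `id`, `sequence`.
#' @param min_len,max_ambiguous,code_table See [qc_sequence()].
#' @return List with `passing` (the subset of `records` that pass, input
#'   order preserved), `reports` (one QC row per input record) and
#'   `summary` (n_input, n_pass and per-reason failure counts).
#' @export
qc_batch <- function(records, min_len = 100L, max_ambiguous = 0.02,
                     code_table = "vertebrate_mito") {
  if (is.null(records) || nrow(records) == 0L) {
    empty <- qc_sequence(list(id = "x", sequence = "ACG"))[0, ]
    return(list(passing = records, reports = empty,
                summary = c(n_input = 0L, n_pass = 0L)))
  }
  reports <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    qc_sequence(records[i, ], min_len, max_ambiguous, code_table)))
  reasons <- unlist(strsplit(reports$reasons[!reports$pass], ","))
  summary <- c(n_input = nrow(records), n_pass = sum(reports$pass),
               table(factor(reasons,
                            levels = c("TOO_SHORT", "TOO_AMBIGUOUS",
                                       "STOP_CODON"))))
  list(passing = records[reports$pass, , drop = FALSE], reports = reports,
       summary = summary)
}
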