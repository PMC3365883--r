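#' Bundled lionfish diet survey tables
#'
#' The package ships, as plain text under `inst/extdata`, the prey tables
#' printed by a DNA-barcoding survey of invasive lionfish (*Pterois
#' volitans*) stomach contents on Mexican Caribbean reefs: the fish prey
#' roster with per-species specimen counts and best-match similarities,
#' the crustacean prey taxa (mostly resolved only to order), the
#' crustacean order-level sequence counts, and the prior regional
#' reef-fish checklist used for new-record flagging. These printed tables
#' are the inputs to the diet-composition stage and let its statistics be
#' recomputed without the deposited sequence data.
#'
#' @return `study_fish_prey()` and `study_crustacean_prey()` return data
#'   frames with the four rank columns (plus `count` and `similarity_pct`
#'   where reported); `study_crustacean_order_counts()` returns order-level
#'   sequence counts; `study_checklist()` returns a character vector of
#'   species.
#' @name study_tables
NULL

study_file <- function(name) {
  path <- system.file("extdata", name, package = "barcodediet")
  if (!nzchar(path)) stop("bundled file not found: ", name)
  path
}

read_study_tsv <- function(name) {
  tab <- utils::read.delim(study_file(name), sep = "\t",
                           colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE)
  tab[is.na(tab)] <- ""
  tab
}

#' @rdname study_tables
#' @export
study_fish_prey <- function() {
  tab <- read_study_tsv("lionfish_fish_prey.tsv")
  tab$count <- as.integer(tab$count)
  tab$similarity_pct <- suppressWarnings(as.numeric(tab$similarity_pct))
  tab
}

#' @rdname study_tables
#' @export
study_crustacean_prey <- function() {
  tab <- read_study_tsv("lionfish_crustacean_prey.tsv")
  tab$similarity_pct <- suppressWarnings(as.numeric(tab$similarity_pct))
  tab
}

#' @rdname study_tables
#' @export
study_crustacean_order_counts <- function() {
  tab <- read_study_tsv("lionfish_crustacean_order_counts.tsv")
  tab$count <- as.integer(tab$count)
  tab
}

#' @rdname study_tables
#' @export
study_checklist <- function() {
  read_checklist(study_file("mexican_caribbean_checklist.txt"))
}

#' Combined prey assignment table of the survey
#'
#' Joins the fish prey roster with the crustacean order-level counts into
#' one assignment-style table (four rank columns, `count`, `class`) whose
#' 168 prey items (125 fish + 43 crustaceans) feed the composition
#' statistics.
#'
#' @return Data frame with the four rank columns, `count` and `class`.
#' @export
study_prey_assignments <- function() {
  fish <- study_fish_prey()
  fish <- fish[, c(RANKS, "count")]
  cru <- study_crustacean_order_counts()
  cru <- data.frame(order = cru$order, family = "", genus = "",
                    species = "", count = cru$count,
                    stringsAsFactors = FALSE)
  add_prey_class(rbind(fish, cru))
}
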