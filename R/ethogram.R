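## Consolidation of the 12 observed behaviours into the 5 analysis
## categories. Rare behaviours (together roughly 2% of observations in
## the field data) are excluded from the thermal analysis.

CONSOLIDATION <- c(
  browsing = "browsing",
  grazing = "grazing",
  foraging = "walking",      # slow food-searching walk, pooled with walking
  walking = "walking",
  ruminating = "ruminating",
  "low-activity" = "resting",
  sleeping = "resting",
  drinking = "EXCLUDED",
  "salt-licking" = "EXCLUDED",
  grooming = "EXCLUDED",
  trotting = "EXCLUDED",
  running = "EXCLUDED"
)

#' Map ethogram behaviours to analysis categories
#'
#' Consolidates the 12 observable behaviours to 5 analysis categories:
#' browsing and grazing map to themselves, foraging is pooled with
#' walking, sleeping and low-activity become resting, and the rare
#' behaviours (drinking, salt-licking, grooming, trotting, running) map
#' to `"EXCLUDED"`. The map is total on the ethogram and idempotent on
#' the 5 categories.
#'
#' @param label Character vector of ethogram labels or analysis
#'   categories.
#' @return Character vector of analysis categories or `"EXCLUDED"`.
#' @export
#' @examples
#' consolidate(c("foraging", "sleeping", "trotting"))
consolidate <- function(label) {
  full <- c(CONSOLIDATION,
            setNames(analysis_categories(), analysis_categories()),
            EXCLUDED = "EXCLUDED")
  unknown <- setdiff(label, names(full))
  if (length(unknown) > 0L) {
    abort(paste0("unknown behaviour label(s): ", paste(unique(unknown), collapse = ", ")))
  }
  unname(full[label])
}

#' Consolidate predicted behaviour records and drop exclusions
#'
#' @param records Tibble with a `behaviour` column of ethogram labels.
#' @return The records with a `category` column added and EXCLUDED rows
#'   dropped; attribute `"excluded_fraction"` gives the dropped fraction.
#' @export
consolidate_records <- function(records) {
  cat_all <- consolidate(records$behaviour)
  keep <- cat_all != "EXCLUDED"
  out <- records[keep, ]
  out$category <- cat_all[keep]
  frac <- if (nrow(records) > 0) mean(!keep) else 0
  inform(sprintf("excluded %d of %d records (%.1f%%) in rare behaviours",
                 sum(!keep), nrow(records), 100 * frac))
  attr(out, "excluded_fraction") <- frac
  out
}

#' Write the consolidation map as a two-column audit table
#'
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consolidation_map <- function(path) {
  write.csv(data.frame(behaviour = names(CONSOLIDATION),
                       category = unname(CONSOLIDATION)),
            path, row.names = FALSE)
  invisible(path)
}
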