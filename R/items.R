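#' The HRSD-17 item catalog
#'
#' The 17 items of the Hamilton Rating Scale for Depression with their
#' clinician-rated score ranges: nine items are scored 0-4 and eight items
#' (the three insomnia items, gastrointestinal and general somatic symptoms,
#' genital symptoms, weight loss, and insight) are scored 0-2.  The sum
#' score therefore ranges from 0 to 52.
#'
#' @return A tibble with one row per item and columns `item` (integer 1-17),
#'   `code` (the `item_<n>` column name used in cohort tables), `label`,
#'   and `max_score` (2 or 4; the minimum is always 0).
#' @examples
#' hrsd_items()
#' sum(hrsd_items()$max_score)  # 52, the maximum possible sum score
#' @export
hrsd_items <- function() {
  labels <- c(
    "Depressed mood", "Feelings of guilt", "Suicide",
    "Early insomnia", "Middle insomnia", "Late insomnia",
    "Work and interests", "Retardation", "Agitation",
    "Psychic anxiety", "Somatic anxiety",
    "Gastrointestinal somatic symptoms", "General somatic symptoms",
    "Genital symptoms", "Hypochondriasis", "Weight loss", "Insight"
  )
  max_score <- rep(4L, 17L)
  max_score[c(4L, 5L, 6L, 12L, 13L, 14L, 16L, 17L)] <- 2L
  tibble::tibble(
    item = 1:17,
    code = paste0("item_", 1:17),
    label = labels,
    max_score = max_score
  )
}

item_cols <- function() paste0("item_", 1:17)

# Score-range vector indexed by item number.
item_max <- function() hrsd_items()$max_score
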