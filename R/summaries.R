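#' Taxonomic and survey-size summary
#'
#' Counts the units the descriptive results of a market inventory are
#' reported in:
#'
#' * `n_listings` — rows of the inventory: a binomial as filed under a
#'   family, with repeated listings kept distinct;
#' * `n_species` — distinct (family, binomial) pairs (a binomial filed under
#'   two families counts under each, repeated listings within one family
#'   count once);
#' * `n_genera` — distinct genus tokens;
#' * `n_families` — distinct family labels as filed (see
#'   [family_count_conventions()] for the alternative conventions);
#' * `n_markets` — markets in the registry;
#' * `n_medicinal_species` — listings with at least one medicinal use
#'   report. Counting listings rather than deduplicated pairs here follows
#'   the tabulation convention of printed inventories, where each listing
#'   line is classified medicinal or not.
#'
#' @param survey a `market_survey`.
#' @return A one-row tibble.
#' @export
count_taxa <- function(survey) {
  stopifnot(inherits(survey, "market_survey"))
  idx <- species_index(survey)
  med <- unique(survey$reports$listing_id[survey$reports$medicinal])
  tibble::tibble(
    n_listings = nrow(idx),
    n_species = nrow(dplyr::distinct(idx, .data$family, .data$species)),
    n_genera = length(unique(sub(" .*", "", idx$species))),
    n_families = length(unique(idx$family)),
    n_markets = length(survey$markets),
    n_medicinal_species = length(med)
  )
}

#' Family counts under alternative conventions
#'
#' Printed family totals depend on whether legume subfamilies are pooled
#' and whether non-plant catch-all labels (e.g. "Algae") are counted as
#' families. This reports the count under each combination.
#'
#' @param survey a `market_survey`.
#' @param merge_map family merge map (default: legume subfamilies to
#'   Fabaceae).
#' @param exclude labels not counted as families under the "excluding"
#'   conventions.
#' @return A tibble with columns `convention` and `n_families`.
#' @export
family_count_conventions <- function(survey,
                                     merge_map = default_family_merge(),
                                     exclude = "Algae") {
  fams <- unique(species_index(survey)$family)
  merged <- unique(ifelse(fams %in% names(merge_map),
                          merge_map[fams], fams))
  tibble::tibble(
    convention = c("as filed", "as filed, excluding",
                   "merged", "merged, excluding"),
    n_families = c(length(fams), length(setdiff(fams, exclude)),
                   length(merged), length(setdiff(merged, exclude)))
  )
}

ranked_table <- function(counts, base_n, base_label) {
  if (length(counts) == 0) {
    out <- tibble::tibble(label = character(), n_species = integer(),
                          pct = double())
    attr(out, "base") <- base_label
    attr(out, "base_n") <- base_n
    return(out)
  }
  out <- tibble::tibble(
    label = names(counts),
    n_species = as.integer(unname(counts)),
    pct = round_half_up(100 * unname(counts) / base_n, 1)
  )
  out <- out[order(-out$n_species, out$label), ]
  attr(out, "base") <- base_label
  attr(out, "base_n") <- base_n
  out
}

#' Ranked family table
#'
#' One row per family with the number of species listings filed under it
#' and the percentage of all species that represents. Counts are as filed:
#' a binomial listed under two families contributes to both rows, and a
#' repeated listing within one family counts each time — the convention of
#' printed inventory tables. The percentage base is the deduplicated
#' species total (`n_species` of [count_taxa()]). Apply
#' [merge_families()] first if subfamily pooling is wanted.
#'
#' @param survey a `market_survey`.
#' @return A tibble (`label`, `n_species`, `pct`), sorted by `n_species`
#'   descending with alphabetical tie-break; the percentage base is stored
#'   in attributes `base` / `base_n`. Percentages are rounded half-up to
#'   one decimal.
#' @export
family_table <- function(survey) {
  stopifnot(inherits(survey, "market_survey"))
  idx <- species_index(survey)
  counts <- table(idx$family)
  base_n <- count_taxa(survey)$n_species
  ranked_table(c(counts), base_n, "all species")
}

#' Ranked use-category table
#'
#' One row per medicinal use category with the number of distinct species
#' (family, binomial pairs) reported at least once for it; the percentage
#' base is the medicinal species count of [count_taxa()]. Non-medicinal
#' reports are ignored.
#'
#' @param survey a `market_survey`.
#' @return A ranked tibble as in [family_table()].
#' @export
category_table <- function(survey) {
  stopifnot(inherits(survey, "market_survey"))
  med <- dplyr::filter(survey$reports, .data$medicinal)
  base_n <- count_taxa(survey)$n_medicinal_species
  if (nrow(med) == 0) {
    return(ranked_table(integer(), base_n, "medicinal species"))
  }
  per <- dplyr::distinct(med, .data$category, .data$family, .data$species)
  counts <- table(per$category)
  ranked_table(c(counts), base_n, "medicinal species")
}

#' Ranked ailment table
#'
#' One row per normalized ailment label (whitespace-trimmed,
#' case-insensitive; the first-seen spelling is displayed) with the number
#' of distinct species reported for it; percentage base is the medicinal
#' species count. Non-medicinal reports are ignored.
#'
#' @param survey a `market_survey`.
#' @return A ranked tibble as in [family_table()].
#' @export
ailment_table <- function(survey) {
  stopifnot(inherits(survey, "market_survey"))
  med <- dplyr::filter(survey$reports, .data$medicinal)
  base_n <- count_taxa(survey)$n_medicinal_species
  if (nrow(med) == 0) {
    return(ranked_table(integer(), base_n, "medicinal species"))
  }
  med$ailment_key <- normalize_label(med$ailment)
  display <- med$ailment[!duplicated(med$ailment_key)]
  names(display) <- med$ailment_key[!duplicated(med$ailment_key)]
  per <- dplyr::distinct(med, .data$ailment_key, .data$family, .data$species)
  counts <- table(per$ailment_key)
  names(counts) <- unname(display[names(counts)])
  ranked_table(c(counts), base_n, "medicinal species")
}
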