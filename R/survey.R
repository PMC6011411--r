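#' Normalization rules for reading a market survey
#'
#' Bundles the controlled-vocabulary configuration used by [read_survey()]:
#' alias maps that send transcription variants (typos, legacy spellings) to
#' canonical labels, the set of use categories that are *not* medicinal, and
#' an optional closed category registry.
#'
#' @param category_aliases named character vector; names are as-recorded
#'   category labels, values the canonical label they map to.
#' @param family_aliases named character vector mapping as-recorded family
#'   labels to canonical ones.
#' @param nonmedicinal character vector of category labels whose reports are
#'   flagged `medicinal = FALSE`.
#' @param categories optional character vector closing the category
#'   vocabulary: after aliasing, any category outside this registry raises a
#'   vocabulary error. `NULL` (default) leaves the vocabulary open.
#' @return A list of class `survey_config`.
#' @export
survey_config <- function(category_aliases = character(),
                          family_aliases = character(),
                          nonmedicinal = c("Human food", "Animal food",
                                           "Toxic", "Cultural", "Cosmetic"),
                          categories = NULL) {
  structure(
    list(category_aliases = category_aliases,
         family_aliases = family_aliases,
         nonmedicinal = nonmedicinal,
         categories = categories),
    class = "survey_config"
  )
}

new_market_survey <- function(reports, markets, categories, provenance = "",
                              n_duplicates_dropped = 0L) {
  structure(
    list(reports = reports, markets = markets, categories = categories,
         provenance = provenance,
         n_duplicates_dropped = n_duplicates_dropped),
    class = "market_survey"
  )
}

#' Read a long-format market survey table
#'
#' Ingests one row per (species, market, use-category, ailment) observation
#' and returns a validated `market_survey`. Scientific names are
#' canonicalized with [canonicalize_binomial()], category labels are passed
#' through the configured alias map, the medicinal flag is derived from the
#' configured non-medicinal category set (unless a `medicinal` column
#' overrides it), and exact duplicate rows are collapsed (the number dropped
#' is kept on the survey).
#'
#' A "listing" is a species as filed under a family: the pair
#' (family, canonical binomial) plus an optional `listing_id` column that
#' keeps repeated listings of the same binomial distinct, as printed
#' inventories sometimes do. When absent, `listing_id` is derived from the
#' (family, species) pair.
#'
#' @param table_source a file path to a UTF-8 delimited text file (tab or
#'   comma, auto-detected from the header line) or a data frame, with
#'   columns `family`, `species`, `vernacular`, `category`, `ailment`,
#'   `market` and optionally `medicinal` and `listing_id`.
#' @param config a [survey_config()].
#' @return A `market_survey`: a list with `reports` (tibble of validated use
#'   reports), `markets` (ordered market registry), `categories` (tibble of
#'   category labels and medicinal flags), `provenance`, and
#'   `n_duplicates_dropped`.
#' @export
read_survey <- function(table_source, config = survey_config()) {
  if (is.character(table_source) && length(table_source) == 1) {
    header <- readLines(table_source, n = 1, encoding = "UTF-8")
    sep <- if (grepl("\t", header)) "\t" else ","
    df <- utils::read.delim(table_source, sep = sep, quote = "",
                            stringsAsFactors = FALSE, encoding = "UTF-8",
                            check.names = FALSE)
  } else if (is.data.frame(table_source)) {
    df <- as.data.frame(table_source)
  } else {
    abort_schema("table_source must be a file path or a data frame")
  }
  required <- c("family", "species", "vernacular", "category", "ailment",
                "market")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort_schema(paste0("missing required column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort_schema("survey table has no rows")

  # alias resolution
  cat_raw <- trimws(as.character(df$category))
  hit <- cat_raw %in% names(config$category_aliases)
  cat_canon <- cat_raw
  cat_canon[hit] <- unname(config$category_aliases[cat_raw[hit]])
  if (!is.null(config$categories)) {
    bad <- setdiff(unique(cat_canon), config$categories)
    if (length(bad) > 0) {
      abort_vocabulary(paste0("unknown use categories: ",
                              paste(sort(bad), collapse = "; ")))
    }
  }
  fam_raw <- trimws(as.character(df$family))
  fhit <- fam_raw %in% names(config$family_aliases)
  fam_raw[fhit] <- unname(config$family_aliases[fam_raw[fhit]])

  nm <- canonicalize_binomial(as.character(df$species))

  medicinal <- if ("medicinal" %in% names(df)) {
    as.logical(df$medicinal)
  } else {
    !(cat_canon %in% config$nonmedicinal)
  }

  listing_id <- if ("listing_id" %in% names(df)) {
    as.character(df$listing_id)
  } else {
    paste(fam_raw, nm$species, sep = "::")
  }

  reports <- tibble::tibble(
    listing_id = listing_id,
    family = fam_raw,
    species = nm$species,
    genus = nm$genus,
    qualifier = nm$qualifier,
    hybrid = nm$hybrid,
    vernacular = dplyr::coalesce(trimws(as.character(df$vernacular)), ""),
    category = cat_canon,
    ailment = trimws(as.character(df$ailment)),
    market = trimws(as.character(df$market)),
    medicinal = medicinal
  )

  before <- nrow(reports)
  reports <- dplyr::distinct(
    reports, .data$listing_id, .data$species, .data$market, .data$category,
    .data$ailment, .keep_all = TRUE
  )
  dropped <- before - nrow(reports)

  categories <- dplyr::distinct(reports, .data$category, .data$medicinal)
  categories <- dplyr::arrange(categories, .data$category)
  dup_cat <- categories$category[duplicated(categories$category)]
  if (length(dup_cat) > 0) {
    abort_vocabulary(paste0(
      "categories flagged both medicinal and non-medicinal: ",
      paste(unique(dup_cat), collapse = "; ")
    ))
  }

  new_market_survey(
    reports = reports,
    markets = sort(unique(reports$market)),
    categories = categories,
    provenance = if (is.character(table_source)) table_source else "in-memory",
    n_duplicates_dropped = as.integer(dropped)
  )
}

#' Write a market survey back to long-format delimited text
#'
#' Emits one row per use report with the same schema [read_survey()]
#' consumes, so that a read -> write -> read round trip reproduces the
#' survey field by field.
#'
#' @param survey a `market_survey`.
#' @param path output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_survey <- function(survey, path) {
  stopifnot(inherits(survey, "market_survey"))
  out <- survey$reports[, c("listing_id", "family", "species", "vernacular",
                            "category", "ailment", "market", "medicinal")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.market_survey <- function(x, ...) {
  idx <- species_index(x)
  cat("<market_survey> ", nrow(idx), " listings, ",
      length(unique(idx$species)), " binomials, ",
      length(x$markets), " markets, ",
      nrow(x$reports), " use reports\n", sep = "")
  cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Listing index of a survey
#'
#' One row per listing: a species as filed under a family. Repeated listings
#' of the same binomial (as printed inventories sometimes carry) keep
#' distinct `listing_id`s. When the same binomial is filed under two
#' families, the first-listed family wins in the `first_family` column of
#' the species-level index returned by `first_family = TRUE`.
#'
#' @param survey a `market_survey`.
#' @param first_family if `TRUE`, return one row per binomial with its
#'   first-listed family (conflicting filings are resolved by first
#'   appearance).
#' @return A tibble.
#' @export
species_index <- function(survey, first_family = FALSE) {
  stopifnot(inherits(survey, "market_survey"))
  idx <- dplyr::distinct(survey$reports, .data$listing_id, .data$family,
                         .data$species)
  if (first_family) {
    idx <- dplyr::distinct(idx, .data$species, .keep_all = TRUE)
    idx <- idx[, c("species", "family")]
    names(idx) <- c("species", "first_family")
  }
  idx
}

#' Keep only medicinal use reports
#'
#' Drops every report whose category is non-medicinal. Listings left with no
#' report disappear from the listing index; the market registry is kept
#' unchanged (a market can legitimately end up empty).
#'
#' @param survey a `market_survey`.
#' @return A `market_survey` with only `medicinal = TRUE` reports.
#' @export
filter_medicinal <- function(survey) {
  stopifnot(inherits(survey, "market_survey"))
  reports <- dplyr::filter(survey$reports, .data$medicinal)
  out <- survey
  out$reports <- reports
  out$categories <- dplyr::filter(survey$categories, .data$medicinal)
  out
}

#' Merge family labels through an idempotent map
#'
#' Rewrites the families of a survey through `merge_map` (as-recorded label
#' -> merged label). The map must be idempotent: no value may itself be a
#' key mapping elsewhere, so chained or cyclic merges are rejected.
#'
#' @param survey a `market_survey`.
#' @param merge_map named character vector (`c(old = "new", ...)`).
#' @return The survey with families rewritten.
#' @export
merge_families <- function(survey, merge_map = default_family_merge()) {
  stopifnot(inherits(survey, "market_survey"))
  if (length(merge_map) == 0) return(survey)
  chained <- intersect(unname(merge_map), names(merge_map))
  chained <- chained[merge_map[chained] != chained]
  if (length(chained) > 0) {
    abort_parameter(paste0("merge map is not idempotent; chained through: ",
                           paste(chained, collapse = ", ")))
  }
  fam <- survey$reports$family
  hit <- fam %in% names(merge_map)
  fam[hit] <- unname(merge_map[fam[hit]])
  out <- survey
  out$reports$family <- fam
  out
}

#' Default family merge for legume subfamilies
#'
#' Inventories often file legumes under the three classical Leguminosae
#' subfamilies; family-level statistics conventionally pool them into
#' Fabaceae.
#'
#' @return Named character vector suitable for [merge_families()].
#' @export
default_family_merge <- function() {
  c("Leguminosae-Caesalpinioideae" = "Fabaceae",
    "Leguminosae-Mimosoideae" = "Fabaceae",
    "Leguminosae-Papilionoideae" = "Fabaceae")
}
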