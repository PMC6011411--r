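#' The packaged Bogotá market inventory
#'
#' Loads the structured transcription of a 24-market medicinal-plant
#' inventory of the Bogotá metropolitan area (409 species-by-family
#' listings across 122+ plant families, 19 medicinal use categories plus
#' five non-medicinal ones) that ships with the package, and expands it to
#' long-format use reports.
#'
#' The source inventory records, per listing, its full set of uses and its
#' full set of markets, without linking individual uses to individual
#' markets. Expansion therefore crosses every use of a listing with every
#' market it occurs in. Statistics that only need species-by-market
#' incidence (taxon counts, family tables, species-level market comparison)
#' are unaffected by this convention; use-by-market statistics (the LIC
#' index, use-level incidence) are upper bounds under it, which is why the
#' package demonstrates those on synthetic surveys where the linkage is
#' known (see [generate_survey()]).
#'
#' By default the two category-label misspellings of the source
#' ("Respitarory system", "Muscular-skelettal system") are passed through
#' [bogota_category_aliases()]; set `alias_categories = FALSE` to keep the
#' transcription literal.
#'
#' @param alias_categories apply the shipped category alias map (default
#'   `TRUE`).
#' @return A `market_survey` (see [read_survey()]).
#' @examples
#' sv <- bogota_survey()
#' count_taxa(sv)
#' @export
bogota_survey <- function(alias_categories = TRUE) {
  ext <- function(f) system.file("extdata", f, package = "ethnomarket",
                                 mustWork = TRUE)
  taxa <- utils::read.delim(ext("bogota_taxa.tsv"), sep = "\t", quote = "",
                            stringsAsFactors = FALSE, encoding = "UTF-8")
  uses <- utils::read.delim(ext("bogota_uses.tsv"), sep = "\t", quote = "",
                            stringsAsFactors = FALSE, encoding = "UTF-8")
  cats <- utils::read.delim(ext("bogota_categories.tsv"), sep = "\t",
                            quote = "", stringsAsFactors = FALSE,
                            encoding = "UTF-8")
  uses$category <- cats$category[match(uses$category, cats$code)]

  taxa$listing_id <- as.character(taxa$listing_id)
  uses$listing_id <- as.character(uses$listing_id)

  # re-inject determination qualifiers so canonicalization re-derives them
  tok <- strsplit(taxa$species, " ", fixed = TRUE)
  taxa$species <- mapply(function(t, q) {
    if (q %in% c("aff", "cf")) paste(t[1], paste0(q, "."), t[2])
    else if (q == "hybrid") paste(t[1], "x", t[2])
    else paste(t, collapse = " ")
  }, tok, taxa$qualifier)

  # one row per (listing, market)
  mk <- strsplit(taxa$markets, ";", fixed = TRUE)
  occ <- data.frame(
    listing_id = rep(taxa$listing_id, lengths(mk)),
    market = trimws(unlist(mk)),
    stringsAsFactors = FALSE
  )
  long <- merge(merge(uses, occ, by = "listing_id"),
                taxa[, c("listing_id", "family", "species", "qualifier",
                         "vernacular")],
                by = "listing_id")

  cfg <- survey_config(
    category_aliases = if (alias_categories) bogota_category_aliases()
                       else character(),
    categories = NULL
  )
  sv <- read_survey(long[, c("listing_id", "family", "species", "vernacular",
                             "category", "ailment", "market")], cfg)
  sv$provenance <- "packaged Bogota market inventory transcription"
  sv
}

#' Category alias map shipped with the Bogotá transcription
#'
#' The source table spells two category labels inconsistently with standard
#' usage; the transcription keeps them literal and this map sends them to
#' canonical labels.
#'
#' @return Named character vector for [survey_config()].
#' @export
bogota_category_aliases <- function() {
  c("Respitarory system" = "Respiratory system",
    "Muscular-skelettal system" = "Musculoskeletal system")
}

#' Published LIC ranking accompanying the Bogotá inventory
#'
#' The source study's ranking of species whose logarithmic informant
#' consensus (LIC) exceeds the 95th percentile (threshold 3.0), as printed.
#' These values are not recomputable from the packaged inventory because the
#' source does not link individual uses to individual markets (see
#' [bogota_survey()]); the table is provided for reference and comparison.
#'
#' Note one internal inconsistency of the source, kept verbatim: the ranking
#' lists *Sambucus nigra*, while the inventory itself files only *Sambucus
#' peruviana*.
#'
#' @return A tibble with columns `species`, `lic` and `introduced`
#'   (logical; the source marks introduced species).
#' @export
bogota_lic_table <- function() {
  f <- system.file("extdata", "bogota_lic_table2.tsv",
                   package = "ethnomarket", mustWork = TRUE)
  df <- utils::read.delim(f, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  tibble::tibble(species = df$species, lic = df$lic,
                 introduced = df$introduced == 1)
}
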