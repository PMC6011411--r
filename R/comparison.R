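#' Market-by-item incidence matrix
#'
#' Builds the binary markets x items presence/absence matrix at one of the
#' three comparison levels used for market surveys:
#'
#' * `"species"` — items are canonical binomials;
#' * `"use"` — items are species::ailment pairs (a species used for an
#'   ailment), ailments normalized as in [ailment_table()];
#' * `"category"` — items are species::category pairs.
#'
#' Rows follow the survey's market registry; columns are sorted
#' lexicographically. Every column has at least one presence (items only
#' exist through reports). Apply [filter_medicinal()] first if only
#' medicinal items should be compared.
#'
#' @param survey a `market_survey`.
#' @param level `"species"`, `"use"` or `"category"`.
#' @return An integer 0/1 matrix with markets as rownames and items as
#'   colnames; attribute `level` records the level.
#' @export
incidence_matrix <- function(survey, level = c("species", "use", "category")) {
  stopifnot(inherits(survey, "market_survey"))
  level <- match.arg(level)
  rp <- survey$reports
  item <- switch(level,
    species = rp$species,
    use = paste(rp$species, normalize_label(rp$ailment), sep = "::"),
    category = paste(rp$species, rp$category, sep = "::")
  )
  items <- sort(unique(item))
  markets <- survey$markets
  m <- matrix(0L, nrow = length(markets), ncol = length(items),
              dimnames = list(markets, items))
  m[cbind(match(rp$market, markets), match(item, items))] <- 1L
  attr(m, "level") <- level
  m
}

#' Plant-space incidence: species and use columns side by side
#'
#' Concatenates the species-level and use-level incidence matrices
#' (unweighted), giving the "plant space" in which markets are ordinated:
#' two markets are close when they share both their plants and the uses of
#' those plants.
#'
#' @param survey a `market_survey`.
#' @return A binary matrix as in [incidence_matrix()], with column names
#'   prefixed `species|` and `use|`; attribute `level` is `"plantspace"`.
#' @export
plantspace_matrix <- function(survey) {
  sp <- incidence_matrix(survey, "species")
  us <- incidence_matrix(survey, "use")
  colnames(sp) <- paste0("species|", colnames(sp))
  colnames(us) <- paste0("use|", colnames(us))
  m <- cbind(sp, us)
  attr(m, "level") <- "plantspace"
  m
}

#' Shared and unique items per market
#'
#' Decomposes an incidence matrix into, per market, the items found in no
#' other market ("unique") and, per market pair, the number of co-present
#' items ("shared").
#'
#' @param matrix a binary incidence matrix (markets x items), e.g. from
#'   [incidence_matrix()].
#' @return A list with `per_market` (tibble: `market`, `n_present`,
#'   `n_unique`, `prop_unique`, and a list-column `unique_items`) and
#'   `shared` (symmetric market x market matrix of co-presence counts; the
#'   diagonal holds each market's item count).
#' @export
shared_unique <- function(matrix) {
  stopifnot(is.matrix(matrix))
  m <- matrix
  singleton <- colSums(m) == 1
  per_market <- tibble::tibble(
    market = rownames(m),
    n_present = as.integer(rowSums(m)),
    n_unique = as.integer(rowSums(m[, singleton, drop = FALSE])),
    unique_items = lapply(seq_len(nrow(m)), function(i) {
      colnames(m)[singleton & m[i, ] == 1]
    })
  )
  per_market$prop_unique <- ifelse(per_market$n_present > 0,
                                   per_market$n_unique / per_market$n_present,
                                   NA_real_)
  per_market <- per_market[, c("market", "n_present", "n_unique",
                               "prop_unique", "unique_items")]
  list(per_market = per_market, shared = m %*% t(m))
}

#' Percent of a plant's uses unique to each market
#'
#' For each plant occurring in at least two markets, the percentage of its
#' uses in a given market that are found in no other market. A use is
#' unique to market `m` when the (species, ailment) pair occurs in `m` and
#' nowhere else. Plants sold in a single market are excluded: uniqueness of
#' their uses is undefined without a second market to compare against.
#'
#' @param survey a `market_survey`.
#' @return A tibble with one row per (species, market): `species`,
#'   `market`, `n_uses_here`, `n_unique_here`, `pct_unique`.
#' @export
unique_use_percent <- function(survey) {
  stopifnot(inherits(survey, "market_survey"))
  rp <- survey$reports
  occ <- dplyr::distinct(
    tibble::tibble(species = rp$species,
                   use = normalize_label(rp$ailment),
                   market = rp$market)
  )
  n_mkt <- dplyr::summarise(dplyr::group_by(occ, .data$species),
                            n_markets = dplyr::n_distinct(.data$market),
                            .groups = "drop")
  keep <- n_mkt$species[n_mkt$n_markets >= 2]
  occ <- occ[occ$species %in% keep, ]
  if (nrow(occ) == 0) {
    return(tibble::tibble(species = character(), market = character(),
                          n_uses_here = integer(), n_unique_here = integer(),
                          pct_unique = double()))
  }
  spread <- dplyr::summarise(
    dplyr::group_by(occ, .data$species, .data$use),
    n_markets_use = dplyr::n_distinct(.data$market),
    .groups = "drop"
  )
  occ <- dplyr::left_join(occ, spread, by = c("species", "use"))
  out <- dplyr::summarise(
    dplyr::group_by(occ, .data$species, .data$market),
    n_uses_here = dplyr::n(),
    n_unique_here = sum(.data$n_markets_use == 1),
    .groups = "drop"
  )
  out$pct_unique <- 100 * out$n_unique_here / out$n_uses_here
  out
}

#' Euclidean distances among markets
#'
#' Computes the Euclidean distance between market rows of one incidence
#' matrix, or of several concatenated ones (e.g. species plus use columns
#' for the "plant space"). On binary data the squared Euclidean distance
#' between two markets equals the number of items found in exactly one of
#' them.
#'
#' @param matrix a markets x items matrix, or a list of such matrices with
#'   identical row sets to be concatenated column-wise.
#' @return A [stats::dist] object labelled with market names.
#' @export
euclidean_distances <- function(matrix) {
  if (is.list(matrix) && !is.data.frame(matrix) && !is.matrix(matrix)) {
    rows <- lapply(matrix, rownames)
    if (length(unique(vapply(rows, paste, "", collapse = "\r"))) != 1) {
      abort_dimension("matrices to concatenate must share the same markets")
    }
    matrix <- do.call(cbind, matrix)
  }
  stopifnot(is.matrix(matrix))
  if (nrow(matrix) < 2) {
    abort_dimension("at least two markets are required for distances")
  }
  stats::dist(matrix, method = "euclidean")
}
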