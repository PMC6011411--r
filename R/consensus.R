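#' Informant consensus per use, with markets as occurrences
#'
#' For every distinct use `u` (an ailment label by default, or a use
#' category), the informant consensus is
#' \deqn{IC_u = (FC_u - NS_u) / (FC_u - 1)}
#' where `FCu` is the total number of occurrence reports of the use and
#' `NSu` the number of distinct species reported for it. The counting unit
#' for `FCu` is the (species, market) pair: a species reported for a use in
#' a market counts once regardless of how many vendors in that market
#' reported it ("markets as occurrences").
#'
#' `ICu` is 1 when every report of the use converges on one species and 0
#' when every report names a different species. A use with a single report
#' (`FCu = 1`) makes the formula 0/0; by the degenerate-case convention of
#' the consensus-index literature a single report carries no consensus, so
#' `ICu = 0` there.
#'
#' Only medicinal reports enter the computation.
#'
#' @param survey a `market_survey`.
#' @param level `"ailment"` (default) or `"category"` — what counts as a
#'   use.
#' @return A tibble with one row per use: `use`, `FCu`, `NSu`, `ICu`.
#' @export
use_consensus <- function(survey, level = c("ailment", "category")) {
  stopifnot(inherits(survey, "market_survey"))
  level <- match.arg(level)
  occ <- consensus_occurrences(survey, level)
  if (nrow(occ) == 0) {
    return(tibble::tibble(use = character(), FCu = integer(),
                          NSu = integer(), ICu = double()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(occ, .data$use),
    FCu = dplyr::n(),
    NSu = dplyr::n_distinct(.data$species),
    .groups = "drop"
  )
  out$ICu <- ifelse(out$FCu > 1, (out$FCu - out$NSu) / (out$FCu - 1), 0)
  out
}

# deduplicated (species, market, use) occurrence tuples, medicinal only
consensus_occurrences <- function(survey, level) {
  med <- dplyr::filter(survey$reports, .data$medicinal)
  if (nrow(med) == 0) {
    return(tibble::tibble(species = character(), market = character(),
                          use = character()))
  }
  med$use <- if (level == "ailment") normalize_label(med$ailment)
             else med$category
  dplyr::distinct(med, .data$species, .data$market, .data$use)
}

#' Logarithmic informant consensus (LIC) score per species
#'
#' The LIC of species `s` sums, over the uses the species is reported for,
#' the use's consensus weighted by the natural log of the species'
#' occurrence frequency for that use:
#' \deqn{LIC_s = \sum_u IC_u \ln(FC_{us})}
#' where `FCus` is the number of markets in which species `s` is reported
#' for use `u` (markets as occurrences). A species reported once for one
#' use in one market scores 0 (`ln 1 = 0`); widely-agreed-on, widely-sold
#' species score highest.
#'
#' @inheritParams use_consensus
#' @return An object of class `consensus_table`: a list with `scores` (one
#'   row per species: `species`, `LIC`, `n_uses`, `n_markets`, sorted by
#'   LIC descending), `uses` (the [use_consensus()] table) and `level`.
#' @export
species_lic <- function(survey, level = c("ailment", "category")) {
  stopifnot(inherits(survey, "market_survey"))
  level <- match.arg(level)
  uses <- use_consensus(survey, level)
  occ <- consensus_occurrences(survey, level)
  if (nrow(occ) == 0) {
    scores <- tibble::tibble(species = character(), LIC = double(),
                             n_uses = integer(), n_markets = integer())
    return(structure(list(scores = scores, uses = uses, level = level),
                     class = "consensus_table"))
  }
  per_su <- dplyr::summarise(
    dplyr::group_by(occ, .data$species, .data$use),
    FCus = dplyr::n_distinct(.data$market),
    .groups = "drop"
  )
  per_su <- dplyr::left_join(per_su, uses[, c("use", "ICu")], by = "use")
  per_sp <- dplyr::summarise(
    dplyr::group_by(per_su, .data$species),
    LIC = sum(.data$ICu * log(.data$FCus)),
    n_uses = dplyr::n(),
    .groups = "drop"
  )
  n_mkt <- dplyr::summarise(
    dplyr::group_by(occ, .data$species),
    n_markets = dplyr::n_distinct(.data$market),
    .groups = "drop"
  )
  scores <- dplyr::left_join(per_sp, n_mkt, by = "species")
  scores <- scores[order(-scores$LIC, scores$species), ]
  structure(list(scores = scores, uses = uses, level = level),
            class = "consensus_table")
}

#' @export
print.consensus_table <- function(x, ...) {
  cat("<consensus_table> level =", x$level, "—", nrow(x$scores),
      "species,", nrow(x$uses), "uses\n")
  print(utils::head(x$scores, 10))
  invisible(x)
}

#' Species exceeding an LIC percentile threshold
#'
#' Returns the species whose LIC score strictly exceeds the empirical
#' `q`-quantile of all species' scores (linear interpolation between order
#' statistics), the way published rankings cut a consensus table at, e.g.,
#' the 95th percentile.
#'
#' @param table a `consensus_table` from [species_lic()].
#' @param q percentile in (0, 1).
#' @return A list: `species` (score rows above the threshold), `threshold`
#'   (the quantile value) and `q`.
#' @export
lic_threshold <- function(table, q = 0.95) {
  stopifnot(inherits(table, "consensus_table"))
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    abort_parameter("q must be a single number strictly between 0 and 1")
  }
  if (nrow(table$scores) == 0) {
    abort_parameter("consensus table is empty")
  }
  thr <- unname(stats::quantile(table$scores$LIC, probs = q, type = 7))
  list(species = table$scores[table$scores$LIC > thr, ],
       threshold = thr, q = q)
}
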