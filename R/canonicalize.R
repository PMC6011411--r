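#' Canonicalize a scientific plant name to a two-token binomial
#'
#' Market inventories file plants under names that carry author strings
#' ("Aloe vera (L.) Burm. f."), determination qualifiers ("Espeletia aff.
#' corymbosa"), hybrid markers ("Mentha x piperita") and occasional
#' genus-level determinations ("Caulerpa sp."). Downstream counts are only
#' well defined on a canonical "Genus epithet" key, so this function strips
#' authorities and infraspecific ranks, records qualifiers as flags, and
#' normalizes capitalization (genus capitalized, epithet lower case).
#'
#' A single-token name is treated as a genus-level determination: the epithet
#' is set to the placeholder `"sp."` and the qualifier flag records it.
#'
#' The function is idempotent: applying it to its own `species` output
#' returns the same result.
#'
#' @param raw_name character vector of raw scientific names.
#' @return A tibble with one row per input and columns `input`, `species`
#'   (canonical binomial), `genus`, `epithet`, `qualifier` (`""`, `"aff"`,
#'   `"cf"` or `"genus-only"`) and `hybrid` (logical).
#' @examples
#' canonicalize_binomial(c(
#'   "Aloe vera (L.) Burm. f.",
#'   "Espeletia aff. corymbosa Bonpl.",
#'   "Mentha x piperita L.",
#'   "Caulerpa sp."
#' ))
#' @export
canonicalize_binomial <- function(raw_name) {
  if (length(raw_name) == 0) {
    return(tibble::tibble(
      input = character(), species = character(), genus = character(),
      epithet = character(), qualifier = character(), hybrid = logical()
    ))
  }
  if (any(is.na(raw_name) | trimws(raw_name) == "")) {
    abort_schema("scientific names must be non-empty")
  }
  one <- function(nm) {
    toks <- strsplit(trimws(gsub("\\s+", " ", nm)), " ")[[1]]
    qualifier <- ""
    hybrid <- FALSE
    genus <- toks[1]
    genus <- paste0(toupper(substring(genus, 1, 1)),
                    tolower(substring(genus, 2)))
    epithet <- NA_character_
    for (t in toks[-1]) {
      if (t %in% c("aff.", "aff")) { qualifier <- "aff"; next }
      if (t %in% c("cf.", "cf"))   { qualifier <- "cf";  next }
      if (t %in% c("x", "×")) { hybrid <- TRUE;     next }
      # first lower-case token after the genus is the epithet; anything
      # after it (authorities, infraspecific ranks) is dropped
      if (grepl("^[a-z][a-z-]*$", t) || identical(t, "sp.")) {
        epithet <- t
        break
      }
      # an authority token ("(L.)", "Burm.", "DC.") ends the name part
      break
    }
    if (is.na(epithet) || identical(epithet, "sp.")) {
      epithet <- "sp."
      if (qualifier == "") qualifier <- "genus-only"
    } else {
      epithet <- tolower(epithet)
    }
    c(genus, epithet, qualifier, as.character(hybrid))
  }
  m <- vapply(raw_name, one, character(4), USE.NAMES = FALSE)
  tibble::tibble(
    input = raw_name,
    species = paste(m[1, ], m[2, ]),
    genus = m[1, ],
    epithet = m[2, ],
    qualifier = m[3, ],
    hybrid = as.logical(m[4, ])
  )
}
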