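#' Configuration for the synthetic market-survey generator
#'
#' Describes a market system with a species pool partitioned into a shared,
#' Zipf-weighted pool and market-private pools. Each market draws its
#' species as a mixture: with probability `overlap` from the shared pool
#' (weighted by rank^-`zipf_exponent`, so a few species are widespread and
#' many are rare), otherwise from its own private pool (species occurring
#' nowhere else). Every (species, market) occurrence then receives a
#' shifted-Poisson number of uses drawn from the species' use repertoire,
#' built over a category -> ailment hierarchy with category-prefixed
#' ailment tokens.
#'
#' @param n_markets number of markets.
#' @param n_species_pool total species pool size (shared + private).
#' @param n_families number of plant families species are filed under.
#' @param n_categories_medicinal number of medicinal use categories.
#' @param n_ailments size of the medicinal ailment vocabulary.
#' @param mean_species_per_market mean of the shifted-Poisson market size
#'   (every market holds at least one species).
#' @param overlap probability in `[0, 1]` that a species draw comes from
#'   the shared pool rather than the market's private pool. 0 makes all
#'   markets disjoint; 1 makes them draw from one common pool.
#' @param zipf_exponent skew of the shared-pool occurrence frequencies
#'   (0 = uniform).
#' @param p_nonmedicinal probability that a repertoire slot is a
#'   non-medicinal use.
#' @param uses_per_species_market mean of the shifted-Poisson number of
#'   uses per (species, market) occurrence.
#' @param group_structure optional list `list(n_groups =, divergence =)`
#'   for geographically grouped markets (see
#'   [generate_grouped_survey()]).
#' @param seed integer seed; the whole survey is a deterministic function
#'   of the configuration.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_markets = 24, n_species_pool = 400,
                             n_families = 120, n_categories_medicinal = 19,
                             n_ailments = 300,
                             mean_species_per_market = 12, overlap = 0.25,
                             zipf_exponent = 1, p_nonmedicinal = 0.05,
                             uses_per_species_market = 2.5,
                             group_structure = NULL, seed = 1L) {
  cfg <- structure(
    list(n_markets = as.integer(n_markets),
         n_species_pool = as.integer(n_species_pool),
         n_families = as.integer(n_families),
         n_categories_medicinal = as.integer(n_categories_medicinal),
         n_ailments = as.integer(n_ailments),
         mean_species_per_market = mean_species_per_market,
         overlap = overlap, zipf_exponent = zipf_exponent,
         p_nonmedicinal = p_nonmedicinal,
         uses_per_species_market = uses_per_species_market,
         group_structure = group_structure, seed = as.integer(seed)),
    class = "synthetic_config"
  )
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_markets, cfg$n_species_pool, cfg$n_families,
              cfg$n_categories_medicinal, cfg$n_ailments)
  if (any(counts < 1)) abort_parameter("all counts must be positive")
  probs <- c(cfg$overlap, cfg$p_nonmedicinal)
  if (any(probs < 0 | probs > 1)) {
    abort_parameter("overlap and p_nonmedicinal must lie in [0, 1]")
  }
  if (cfg$zipf_exponent < 0) abort_parameter("zipf_exponent must be >= 0")
  if (cfg$mean_species_per_market < 1 || cfg$uses_per_species_market < 1) {
    abort_parameter("mean market size and uses per occurrence must be >= 1")
  }
  if (cfg$n_ailments < cfg$n_categories_medicinal) {
    abort_parameter("need at least one ailment per medicinal category")
  }
  split <- pool_split(cfg)
  if (cfg$overlap < 1 &&
      cfg$mean_species_per_market * (1 - cfg$overlap) > split$private_size) {
    abort_sizing(paste0(
      "private pools too small: expected private draws per market (",
      format(cfg$mean_species_per_market * (1 - cfg$overlap), digits = 3),
      ") exceed the per-market private pool (", split$private_size, ")"
    ))
  }
  if (!is.null(cfg$group_structure)) {
    gs <- cfg$group_structure
    if (is.null(gs$n_groups) || gs$n_groups < 1 ||
        gs$n_groups > cfg$n_markets) {
      abort_parameter("group count must be between 1 and n_markets")
    }
    if (is.null(gs$divergence) || gs$divergence < 0 || gs$divergence > 1) {
      abort_parameter("divergence must lie in [0, 1]")
    }
  }
  invisible(cfg)
}

pool_split <- function(cfg) {
  private_size <- floor(cfg$n_species_pool * (1 - cfg$overlap) /
                          cfg$n_markets + 1e-9)
  shared_size <- cfg$n_species_pool - cfg$n_markets * private_size
  list(private_size = private_size, shared_size = shared_size)
}

#' Scale anchors of the Bogotá inventory as a generator preset
#'
#' A configuration anchored to the packaged inventory's scale: 24 markets,
#' a pool of ~400 species, 19 medicinal categories, strong occurrence skew
#' and low between-market overlap (so per-market uniqueness is high, as in
#' the real inventory). Market sizes are kept moderate so the partitioned
#' pool remains feasible; the preset is scale-anchored, not fitted.
#'
#' @param seed integer seed (default fixed).
#' @return A `synthetic_config`.
#' @export
bogota_preset <- function(seed = 2018L) {
  synthetic_config(
    n_markets = 24, n_species_pool = 400, n_families = 120,
    n_categories_medicinal = 19, n_ailments = 318,
    mean_species_per_market = 12, overlap = 0.25, zipf_exponent = 1.2,
    p_nonmedicinal = 0.05, uses_per_species_market = 2.5, seed = seed
  )
}

int2alpha <- function(i) {
  vapply(i, function(x) {
    s <- ""
    repeat {
      s <- paste0(letters[(x - 1) %% 26 + 1], s)
      x <- (x - 1) %/% 26
      if (x == 0) break
    }
    s
  }, character(1))
}

build_vocab <- function(cfg) {
  cat_med <- sprintf("Medicinal category %02d",
                     seq_len(cfg$n_categories_medicinal))
  ail_cat <- cat_med[(seq_len(cfg$n_ailments) - 1) %%
                       cfg$n_categories_medicinal + 1]
  ail_med <- sprintf("%s ailment %03d", ail_cat, seq_len(cfg$n_ailments))
  cat_nonmed <- c("Human food", "Animal food", "Toxic", "Cultural",
                  "Cosmetic")
  ail_nonmed <- as.vector(outer(cat_nonmed, 1:2, function(c, i) {
    sprintf("%s use %d", c, i)
  }))
  cat_of_nonmed <- rep(cat_nonmed, 2)
  list(ailment = c(ail_med, ail_nonmed),
       category = c(ail_cat, cat_of_nonmed),
       medicinal = c(rep(TRUE, length(ail_med)),
                     rep(FALSE, length(ail_nonmed))))
}

# core generator; group pools implement both plain and grouped surveys
generate_core <- function(cfg, n_groups, divergence) {
  set.seed(cfg$seed)
  split <- pool_split(cfg)
  n_pool <- cfg$n_species_pool
  m <- cfg$n_markets

  # taxonomy: species -> genus, family
  n_genera <- max(1L, ceiling(0.78 * n_pool))
  genus_of <- sample(n_genera, n_pool, replace = TRUE)
  species_names <- sprintf("Genus%03d sp%s", genus_of,
                           int2alpha(seq_len(n_pool)))
  family_of <- sprintf("Family%03d",
                       sample(cfg$n_families, n_pool, replace = TRUE))

  # pool partition: shared head, private blocks behind it
  shared_ids <- seq_len(split$shared_size)
  private_blocks <- if (split$private_size > 0) {
    lapply(seq_len(m), function(i) {
      split$shared_size + (i - 1) * split$private_size +
        seq_len(split$private_size)
    })
  } else {
    rep(list(integer()), m)
  }
  zipf_w <- if (length(shared_ids) > 0) {
    seq_along(shared_ids)^(-cfg$zipf_exponent)
  } else {
    numeric()
  }

  # group-specific shared pools: common core (the most frequent species)
  # plus group-exclusive tail chunks scaled by divergence
  groups <- sort(rep_len(seq_len(n_groups), m))
  s <- length(shared_ids)
  core_n <- round((1 - divergence) * s)
  tail_ids <- shared_ids[seq_len(s) > core_n]
  group_pool <- lapply(seq_len(n_groups), function(g) {
    chunk <- tail_ids[(seq_along(tail_ids) - 1) %% n_groups + 1 == g]
    c(shared_ids[seq_len(core_n)], chunk)
  })

  # species repertoires over the category -> ailment hierarchy
  vocab <- build_vocab(cfg)
  med_idx <- which(vocab$medicinal)
  nonmed_idx <- which(!vocab$medicinal)
  repertoire <- lapply(seq_len(n_pool), function(i) {
    r <- 1 + stats::rpois(1, 2 * (cfg$uses_per_species_market - 1) + 1)
    n_nm <- stats::rbinom(1, r, cfg$p_nonmedicinal)
    n_med <- min(r - n_nm, length(med_idx))
    c(med_idx[sample.int(length(med_idx), n_med)],
      if (n_nm > 0) {
        nonmed_idx[sample.int(length(nonmed_idx),
                              min(n_nm, length(nonmed_idx)))]
      })
  })

  rows <- vector("list", m)
  for (i in seq_len(m)) {
    pool_i <- group_pool[[groups[i]]]
    w_i <- zipf_w[match(pool_i, shared_ids)]
    k <- 1 + stats::rpois(1, cfg$mean_species_per_market - 1)
    k <- min(k, length(pool_i) + length(private_blocks[[i]]))
    n_priv <- stats::rbinom(1, k, 1 - cfg$overlap)
    n_priv <- min(n_priv, length(private_blocks[[i]]))
    n_shared <- min(k - n_priv, length(pool_i))
    blk <- private_blocks[[i]]
    sp <- c(
      if (n_priv > 0) blk[sample.int(length(blk), n_priv)],
      if (n_shared > 0) pool_i[sample.int(length(pool_i), n_shared,
                                          prob = w_i)]
    )
    per_sp <- lapply(sp, function(s_id) {
      rep_s <- repertoire[[s_id]]
      n_u <- min(1 + stats::rpois(1, cfg$uses_per_species_market - 1),
                 length(rep_s))
      ail <- rep_s[sample.int(length(rep_s), n_u)]
      data.frame(species_id = s_id, ailment_id = ail)
    })
    per_sp <- do.call(rbind, per_sp)
    per_sp$market <- sprintf("Market%02d", i)
    rows[[i]] <- per_sp
  }
  long <- do.call(rbind, rows)

  df <- data.frame(
    family = family_of[long$species_id],
    species = species_names[long$species_id],
    vernacular = sprintf("plant-%03d", long$species_id),
    category = vocab$category[long$ailment_id],
    ailment = vocab$ailment[long$ailment_id],
    market = long$market,
    stringsAsFactors = FALSE
  )
  sv <- read_survey(df, survey_config())
  # keep the full market registry even if a market ended up tiny
  sv$markets <- sort(sprintf("Market%02d", seq_len(m)))
  sv$provenance <- sprintf("synthetic survey (seed %d)", cfg$seed)
  names(groups) <- sprintf("Market%02d", seq_len(m))
  list(survey = sv, groups = sprintf("Group%d", groups),
       group_names = stats::setNames(sprintf("Group%d", groups),
                                     names(groups)))
}

#' Generate a synthetic market survey
#'
#' Draws a full survey (taxonomy, markets, occurrences, uses) from a
#' [synthetic_config()]. The result is a valid `market_survey` that the
#' whole analysis pipeline accepts, and is a deterministic function of the
#' configuration (same config, same survey).
#'
#' @param config a `synthetic_config`.
#' @return A `market_survey`.
#' @examples
#' sv <- generate_survey(synthetic_config(n_markets = 6,
#'                                        n_species_pool = 60, seed = 42))
#' count_taxa(sv)
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  generate_core(config, n_groups = 1, divergence = 0)$survey
}

#' Generate a synthetic survey with geographic market groups
#'
#' Markets are partitioned into `config$group_structure$n_groups` groups;
#' each group draws its shared species from a group-specific pool. With
#' `divergence = 0` all group pools are identical (the labels carry no
#' signal); with `divergence = 1` the group pools are disjoint, so market
#' composition separates maximally by group. The true labels are returned
#' for recovery and power studies with [permutation_group_test()].
#'
#' With one group this reduces exactly to [generate_survey()] (same seed,
#' same survey).
#'
#' @param config a `synthetic_config` with `group_structure` set.
#' @return A list: `survey` (a `market_survey`) and `groups` (named
#'   character vector, market -> group label).
#' @export
generate_grouped_survey <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  if (is.null(config$group_structure)) {
    abort_parameter("config$group_structure must be set")
  }
  out <- generate_core(config,
                       n_groups = config$group_structure$n_groups,
                       divergence = config$group_structure$divergence)
  list(survey = out$survey, groups = out$group_names)
}
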