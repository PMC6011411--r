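test_that("generated surveys validate and respect the configuration", {
  cfg <- synthetic_config(n_markets = 6, n_species_pool = 60,
                          n_families = 10, n_ailments = 40,
                          mean_species_per_market = 8, seed = 3)
  sv <- generate_survey(cfg)
  expect_s3_class(sv, "market_survey")
  expect_equal(length(sv$markets), 6)
  ct <- count_taxa(sv)
  expect_lte(ct$n_species, 60)
  expect_lte(ct$n_families, 10)
  expect_true(all(sv$reports$market %in% sv$markets))
  # the category -> ailment hierarchy is recoverable from the tokens
  med <- sv$reports[sv$reports$medicinal, ]
  expect_true(all(startsWith(med$ailment, med$category)))
})

test_that("the generator is deterministic: same seed, byte-identical", {
  cfg <- synthetic_config(n_markets = 5, n_species_pool = 50,
                          mean_species_per_market = 8, seed = 99)
  s1 <- generate_survey(cfg)
  s2 <- generate_survey(cfg)
  expect_identical(s1$reports, s2$reports)
  f1 <- tempfile(); f2 <- tempfile()
  write_survey(s1, f1); write_survey(s2, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- generate_survey(synthetic_config(n_markets = 5, n_species_pool = 50,
                                         mean_species_per_market = 8,
                                         seed = 100))
  expect_false(identical(s1$reports, s3$reports))
})

test_that("overlap 0 makes every market fully unique", {
  cfg <- synthetic_config(n_markets = 6, n_species_pool = 120,
                          mean_species_per_market = 8, overlap = 0, seed = 8)
  sv <- generate_survey(cfg)
  su <- shared_unique(incidence_matrix(sv, "species"))
  expect_true(all(su$per_market$prop_unique == 1))
  off <- su$shared[upper.tri(su$shared)]
  expect_true(all(off == 0))
})

test_that("full overlap with a big common pool leaves little uniqueness", {
  cfg <- synthetic_config(n_markets = 12, n_species_pool = 30,
                          mean_species_per_market = 20, overlap = 1,
                          zipf_exponent = 0, seed = 21)
  sv <- generate_survey(cfg)
  su <- shared_unique(incidence_matrix(sv, "species"))
  expect_lt(mean(su$per_market$prop_unique), 0.10)
})

test_that("p_nonmedicinal = 0 makes the medicinal filter the identity", {
  cfg <- synthetic_config(n_markets = 5, n_species_pool = 50,
                          mean_species_per_market = 8,
                          p_nonmedicinal = 0, seed = 13)
  sv <- generate_survey(cfg)
  expect_equal(filter_medicinal(sv)$reports, sv$reports)
})

test_that("occurrence frequency spectrum is monotone at large sample", {
  cfg <- synthetic_config(n_markets = 40, n_species_pool = 60,
                          mean_species_per_market = 25, overlap = 1,
                          zipf_exponent = 1.2, seed = 4)
  # pool id order is the Zipf rank order; average occupancy over
  # replicates must not increase with rank (checked on rank bins)
  occ <- numeric(60)
  for (seed in 1:15) {
    cfg$seed <- seed
    sv <- generate_survey(cfg)
    m <- incidence_matrix(sv, "species")
    counts <- colSums(m)
    # map binomials back to pool ids via the deterministic epithet code
    pool_id <- vapply(colnames(m), function(s) {
      code <- sub(".* sp", "", s)
      sum((match(strsplit(code, "")[[1]], letters)) *
            26^rev(seq_along(strsplit(code, "")[[1]]) - 1))
    }, numeric(1))
    occ[pool_id] <- occ[pool_id] + counts
  }
  bins <- split(occ, cut(seq_along(occ), 6))
  means <- vapply(bins, mean, numeric(1))
  expect_true(all(diff(means) <= 0))
})

test_that("sizing errors fire when private pools cannot hold the draws", {
  expect_error(
    synthetic_config(n_markets = 20, n_species_pool = 40,
                     mean_species_per_market = 30, overlap = 0),
    class = "ethnomarket_sizing_error"
  )
  expect_error(synthetic_config(overlap = 1.4),
               class = "ethnomarket_parameter_error")
  expect_error(
    synthetic_config(group_structure = list(n_groups = 50, divergence = 0.5)),
    class = "ethnomarket_parameter_error"
  )
})

test_that("the preset is anchored at 24 markets and 19 categories", {
  cfg <- bogota_preset()
  expect_equal(cfg$n_markets, 24L)
  expect_equal(cfg$n_categories_medicinal, 19L)
  sv <- generate_survey(cfg)
  expect_equal(count_taxa(sv)$n_markets, 24L)
  med_cats <- unique(sv$reports$category[sv$reports$medicinal])
  expect_lte(length(med_cats), 19)
  # category coverage approaches 19 as markets grow
  big <- synthetic_config(n_markets = 24, n_species_pool = 400,
                          mean_species_per_market = 16, overlap = 0.25,
                          uses_per_species_market = 4, seed = 2018)
  svb <- generate_survey(big)
  expect_gte(length(unique(svb$reports$category[svb$reports$medicinal])), 18)
})

test_that("one group reduces exactly to the ungrouped generator", {
  cfg <- synthetic_config(n_markets = 6, n_species_pool = 60, seed = 55,
                          mean_species_per_market = 6,
                          group_structure = list(n_groups = 1,
                                                 divergence = 0.7))
  grouped <- generate_grouped_survey(cfg)
  plain <- generate_survey(cfg)
  expect_identical(grouped$survey$reports, plain$reports)
  expect_equal(length(unique(grouped$groups)), 1)
})

test_that("grouped generation returns market-aligned labels", {
  cfg <- synthetic_config(n_markets = 9, n_species_pool = 90, seed = 6,
                          mean_species_per_market = 8,
                          group_structure = list(n_groups = 3,
                                                 divergence = 1))
  out <- generate_grouped_survey(cfg)
  expect_equal(sort(names(out$groups)), sort(out$survey$markets))
  expect_equal(unname(table(out$groups)), rep(3L, 3), ignore_attr = TRUE)
})

test_that("raising overlap increases expected pairwise sharing", {
  shared_at <- function(ov) {
    vals <- numeric(6)
    for (i in 1:6) {
      cfg <- synthetic_config(n_markets = 8, n_species_pool = 80,
                              mean_species_per_market = 8, overlap = ov,
                              seed = 100 + i)
      m <- incidence_matrix(generate_survey(cfg), "species")
      s <- shared_unique(m)$shared
      vals[i] <- mean(s[upper.tri(s)])
    }
    mean(vals)
  }
  lo <- shared_at(0.1)
  hi <- shared_at(0.9)
  expect_gt(hi, lo)
})
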