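# toy survey builders and independent oracles used across the suite

# build a survey from a compact row spec:
#   list(c(species, market, category, ailment), ...)
toy_survey <- function(rows, family = "Famtoy", nonmedicinal = character()) {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(family = family, species = r[1], vernacular = "",
               category = r[3], ailment = r[4], market = r[2],
               stringsAsFactors = FALSE)
  }))
  read_survey(df, survey_config(nonmedicinal = nonmedicinal))
}

# random small survey drawn directly (independent of the package generator)
random_toy <- function(seed, n_species = 5, n_markets = 4, n_uses = 5,
                       n_rows = 25) {
  set.seed(seed)
  df <- data.frame(
    family = "Famtoy",
    species = paste("Genus",
                    letters[sample.int(n_species, n_rows, replace = TRUE)]),
    vernacular = "",
    category = "Cattoy",
    ailment = paste0("use", sample.int(n_uses, n_rows, replace = TRUE)),
    market = paste0("M", sample.int(n_markets, n_rows, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  read_survey(df, survey_config())
}

# brute-force LIC oracle: enumerate (species, market, use) tuples and
# evaluate the consensus formula term by term with plain loops
lic_oracle <- function(survey, level = "ailment") {
  rp <- survey$reports[survey$reports$medicinal, ]
  if (nrow(rp) == 0) {
    return(data.frame(species = character(), LIC = numeric()))
  }
  use <- if (level == "ailment") tolower(trimws(rp$ailment)) else rp$category
  tup <- unique(data.frame(species = rp$species, market = rp$market,
                           use = use, stringsAsFactors = FALSE))
  species <- sort(unique(tup$species))
  lic <- numeric(length(species))
  for (i in seq_along(species)) {
    s <- species[i]
    uses_s <- unique(tup$use[tup$species == s])
    total <- 0
    for (u in uses_s) {
      rows_u <- tup[tup$use == u, ]
      FCu <- nrow(rows_u)
      NSu <- length(unique(rows_u$species))
      ICu <- if (FCu > 1) (FCu - NSu) / (FCu - 1) else 0
      FCus <- length(unique(rows_u$market[rows_u$species == s]))
      total <- total + ICu * log(FCus)
    }
    lic[i] <- total
  }
  data.frame(species = species, LIC = lic, stringsAsFactors = FALSE)
}

# exact permutation p-value for the grouping test by enumerating every
# distinct assignment of group sizes to markets
exact_group_p <- function(d, groups) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  f <- factor(groups)
  g <- nlevels(f)
  sst <- sum(d2) / (2 * n)
  pf <- function(fac) {
    ssw <- 0
    for (lv in unique(fac)) {
      i <- which(fac == lv)
      ssw <- ssw + sum(d2[i, i]) / (2 * length(i))
    }
    ((sst - ssw) / (g - 1)) / (ssw / (n - g))
  }
  obs <- pf(as.character(f))
  perms <- combinat_permutations(as.character(f))
  stats <- apply(perms, 1, pf)
  mean(stats >= obs - 1e-12)
}

# all distinct orderings of a label multiset (tiny n only)
combinat_permutations <- function(labels) {
  n <- length(labels)
  if (n == 1) return(matrix(labels, 1, 1))
  out <- NULL
  for (v in unique(labels)) {
    rest <- labels[-match(v, labels)]
    sub <- combinat_permutations(rest)
    out <- rbind(out, cbind(v, sub, deparse.level = 0))
  }
  unique(out)
}

# orthogonal-Procrustes residual after centering (rotation/reflection +
# translation; classical scaling preserves scale so none is fitted)
procrustes_residual <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(t(Yc) %*% Xc)
  sqrt(sum((Yc %*% (s$u %*% t(s$v)) - Xc)^2))
}
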