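#' Principal coordinates analysis of a market distance matrix
#'
#' Classical metric scaling: the squared distances are double-centered
#' (Gower), the resulting matrix eigendecomposed, and coordinates formed by
#' scaling eigenvectors by the square roots of the non-negative
#' eigenvalues. For a Euclidean-embeddable matrix the inter-point distances
#' of the full embedding reproduce the input exactly. Negative eigenvalues
#' (non-Euclidean input) are dropped and their absolute mass reported;
#' `correction = "lingoes"` instead applies the additive constant
#' correction before embedding.
#'
#' @param d a [stats::dist] object or symmetric distance matrix over at
#'   least 3 markets.
#' @param n_axes number of ordination axes requested; truncated with a
#'   warning if it exceeds the embedding rank.
#' @param correction `"none"` (drop negative eigenvalues) or `"lingoes"`
#'   (additive constant).
#' @return An object of class `ordination`: list with `markets`,
#'   `coordinates` (markets x axes, column-centered, axes by decreasing
#'   eigenvalue), `eigenvalues` (all of them, decreasing),
#'   `negative_eigenvalue_mass` (sum of |negative| over sum of |all|, 0 for
#'   a degenerate all-zero input) and `method`.
#' @export
pcoa <- function(d, n_axes = 2, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  if (!inherits(d, "dist")) {
    stopifnot(is.matrix(d), isSymmetric(unname(d)))
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (n < 3) abort_dimension("at least 3 markets are required for ordination")
  labs <- attr(d, "Labels")
  if (is.null(labs)) labs <- as.character(seq_len(n))

  if (all(d == 0)) {
    k <- min(n_axes, n - 1)
    coords <- matrix(0, n, k, dimnames = list(labs, paste0("Axis", seq_len(k))))
    return(structure(list(markets = labs, coordinates = coords,
                          eigenvalues = rep(0, n - 1),
                          negative_eigenvalue_mass = 0,
                          method = "PCoA (classical scaling)"),
                     class = "ordination"))
  }

  fit <- suppressWarnings(
    stats::cmdscale(d, k = n - 1, eig = TRUE, add = correction == "lingoes")
  )
  eig <- fit$eig
  pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  k <- min(n_axes, pos)
  if (n_axes > pos) {
    warning("n_axes (", n_axes, ") exceeds embedding rank (", pos,
            "); truncated", call. = FALSE)
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  rownames(coords) <- labs
  colnames(coords) <- paste0("Axis", seq_len(k))
  neg_mass <- if (sum(abs(eig)) > 0) sum(abs(eig[eig < 0])) / sum(abs(eig))
              else 0
  structure(
    list(markets = labs, coordinates = coords,
         eigenvalues = sort(eig, decreasing = TRUE),
         negative_eigenvalue_mass = neg_mass,
         method = if (correction == "lingoes")
           "PCoA (classical scaling, Lingoes correction)"
         else "PCoA (classical scaling)"),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", x$method, ": ", length(x$markets), " markets, ",
      ncol(x$coordinates), " axes kept\n", sep = "")
  ev <- x$eigenvalues
  rel <- ev[ev > 0] / sum(ev[ev > 0])
  cat("relative eigenvalues:",
      paste(sprintf("%.3f", utils::head(rel, 5)), collapse = " "), "\n")
  if (x$negative_eigenvalue_mass > 0) {
    cat(sprintf("negative eigenvalue mass: %.3f\n",
                x$negative_eigenvalue_mass))
  }
  invisible(x)
}

new_permutation_test <- function(statistic_name, observed, n_permutations,
                                 p_value, seed, grouping, permuted) {
  structure(
    list(statistic_name = statistic_name, observed = observed,
         n_permutations = n_permutations, p_value = p_value, seed = seed,
         grouping = grouping,
         permutation_quantiles = stats::quantile(permuted,
                                                 c(0.5, 0.9, 0.95, 0.99))),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, ...) {
  cat("<permutation_test> ", x$statistic_name, " = ",
      format(x$observed, digits = 4), ", p = ",
      format(x$p_value, digits = 4), " (", x$n_permutations,
      " permutations, seed ", x$seed, ")\n", sep = "")
  cat("grouping:", x$grouping, "\n")
  invisible(x)
}

group_ss <- function(d2, f) {
  # within-group sum of squared distances, each group scaled by its size
  s <- 0
  for (lv in levels(f)) {
    i <- which(f == lv)
    s <- s + sum(d2[i, i]) / (2 * length(i))
  }
  s
}

#' Permutation test of market grouping (pseudo-F on distances)
#'
#' Tests whether a grouping of markets (geographic zones, localities, ...)
#' explains their composition, via the distance-based pseudo-F
#' \deqn{F = \frac{(SS_T - SS_W)/(g-1)}{SS_W/(n-g)}}
#' with \eqn{SS_T = \sum_{i<j} d_{ij}^2 / n} and \eqn{SS_W} the analogous
#' within-group sums, each divided by its group size. Significance is
#' assessed by free permutation of the group labels, with the add-one
#' convention \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + B)}, so p is never 0
#' and never below \eqn{1/(B+1)}.
#'
#' @param d a [stats::dist] or symmetric matrix of market distances.
#' @param groups group label per market: a named vector (names matching the
#'   distance labels) or a vector in distance order.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed integer seed making the permutation stream reproducible.
#' @return A `permutation_test` object: observed statistic, permutation
#'   quantiles, `p_value`, `seed`.
#' @export
permutation_group_test <- function(d, groups, n_permutations = 9999, seed) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (!is.null(names(groups)) && !is.null(labs)) {
    if (!all(labs %in% names(groups))) {
      abort_parameter("groups must cover every market in d")
    }
    groups <- groups[labs]
  }
  if (length(groups) != n) {
    abort_parameter("groups must assign a label to each market")
  }
  f <- factor(groups)
  g <- nlevels(f)
  if (g < 2) abort_parameter("need at least 2 groups; one group equals the whole sample")
  if (n_permutations < 1) abort_parameter("n_permutations must be >= 1")
  if (missing(seed)) abort_parameter("seed is required for reproducibility")

  d2 <- as.matrix(d)^2
  ss_total <- sum(d2) / (2 * n)
  pseudo_f <- function(fac) {
    ssw <- group_ss(d2, fac)
    ((ss_total - ssw) / (g - 1)) / (ssw / (n - g))
  }
  observed <- pseudo_f(f)
  set.seed(seed)
  permuted <- vapply(seq_len(n_permutations), function(b) {
    pseudo_f(factor(sample(as.integer(f)), levels = seq_len(g),
                    labels = levels(f)))
  }, numeric(1))
  p <- (1 + sum(permuted >= observed)) / (1 + n_permutations)
  new_permutation_test(
    statistic_name = "pseudo-F",
    observed = observed, n_permutations = n_permutations, p_value = p,
    seed = seed,
    grouping = paste0(g, " groups (", paste(table(f), collapse = "/"),
                      " markets)"),
    permuted = permuted
  )
}

#' Permutation test of association between market distance and size
#'
#' Mantel-style test: the observed statistic is the Pearson correlation
#' between the off-diagonal market distances and the absolute differences
#' in market size (e.g. number of species reported). Significance is
#' assessed by jointly permuting market identities in the size matrix;
#' one-sided (positive association), add-one convention.
#'
#' @param d a [stats::dist] or symmetric matrix of market distances over at
#'   least 4 markets.
#' @param sizes positive numeric vector of market sizes, named by market or
#'   in distance order.
#' @param n_permutations number of permutations (default 9999).
#' @param seed integer seed.
#' @return A `permutation_test` object.
#' @export
size_association_test <- function(d, sizes, n_permutations = 9999, seed) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (n < 4) abort_dimension("at least 4 markets are required")
  if (!is.null(names(sizes)) && !is.null(labs)) {
    if (!all(labs %in% names(sizes))) {
      abort_parameter("sizes must cover every market in d")
    }
    sizes <- sizes[labs]
  }
  if (length(sizes) != n) abort_parameter("one size per market is required")
  if (stats::var(sizes) == 0) {
    abort_parameter("sizes have zero variance; the correlation is undefined")
  }
  if (missing(seed)) abort_parameter("seed is required for reproducibility")

  dm <- as.matrix(d)
  sm <- abs(outer(sizes, sizes, "-"))
  low <- lower.tri(dm)
  observed <- stats::cor(dm[low], sm[low])
  set.seed(seed)
  permuted <- vapply(seq_len(n_permutations), function(b) {
    p <- sample(n)
    stats::cor(dm[low], sm[p, p][low])
  }, numeric(1))
  p <- (1 + sum(permuted >= observed)) / (1 + n_permutations)
  new_permutation_test(
    statistic_name = "Mantel r (distance vs |size difference|)",
    observed = observed, n_permutations = n_permutations, p_value = p,
    seed = seed,
    grouping = paste0("sizes of ", n, " markets"),
    permuted = permuted
  )
}
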