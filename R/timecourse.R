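#' Per-timepoint mean profiles
#'
#' Collapses a genes x samples matrix to a genes x timepoints matrix of
#' arithmetic means, one column per timepoint in the order of the factor
#' levels (or first appearance).
#'
#' @param matrix genes x samples numeric matrix.
#' @param timepoint vector over columns giving each sample's timepoint, or a
#'   metadata data frame with columns `sample` and `timepoint`.
#' @return genes x timepoints matrix of means.
#' @export
profile_means <- function(matrix, timepoint) {
  if (is.data.frame(timepoint)) {
    stopifnot(all(c("sample", "timepoint") %in% names(timepoint)))
    timepoint <- timepoint$timepoint[match(colnames(matrix), timepoint$sample)]
  }
  stopifnot(length(timepoint) == ncol(matrix), !anyNA(timepoint))
  if (!is.factor(timepoint))
    timepoint <- factor(timepoint, levels = unique(timepoint))
  sums <- t(rowsum(t(matrix), group = timepoint))
  counts <- as.vector(table(timepoint)[colnames(sums)])
  out <- sweep(sums, 2L, counts, "/")
  out[, levels(timepoint), drop = FALSE]
}

#' Filter flat genes by profile standard deviation
#'
#' Keeps genes whose standard deviation across the timepoint means is at
#' least `min_sd` (inclusive). Genes with an almost-constant profile carry
#' no trend information and would otherwise be inflated to unit variance by
#' the subsequent standardization, so the filter runs on the raw (log2)
#' profiles. The SD uses divisor `n` (population form), treating the few
#' timepoint means as the complete profile.
#'
#' @param profiles genes x timepoints matrix (from [profile_means()]).
#' @param min_sd nonnegative threshold, default 0.05.
#' @return the filtered profile matrix.
#' @export
sd_filter <- function(profiles, min_sd = 0.05) {
  stopifnot(is.numeric(min_sd), min_sd >= 0)
  profiles[row_pop_sd(profiles) >= min_sd, , drop = FALSE]
}

#' Standardize expression profiles gene-wise
#'
#' Centers each gene's profile to mean 0 and scales it to unit (population)
#' standard deviation so that clustering compares trend shapes rather than
#' absolute expression levels.
#'
#' @param profiles genes x timepoints matrix.
#' @return matrix of the same shape with row mean 0 and row SD 1.
#' @export
standardize_profiles <- function(profiles) {
  s <- row_pop_sd(profiles)
  if (any(s == 0))
    stop("zero-SD profile(s) reached standardization; apply sd_filter() first",
         call. = FALSE)
  (profiles - rowMeans(profiles)) / s
}

#' Heuristic fuzzifier estimate for fuzzy c-means
#'
#' Implements the Schwaemmle-Jensen (2010) rule of thumb relating the
#' fuzzifier to the data dimensionality `D` and the number of profiles `G`:
#' `m = 1 + (1418/G + 22.05) * D^-2 +
#'      (12.33/G + 0.243) * D^(-0.0406 * ln(G) - 0.1134)`,
#' clamped to \[1.05, 4\]. Larger datasets get a smaller (harder) fuzzifier;
#' three-point profiles sit near the upper clamp.
#'
#' @param profiles genes x timepoints matrix, or `NULL` if `G`/`D` given.
#' @param G,D profile count and dimensionality, read from `profiles` when
#'   supplied.
#' @param m optional explicit override; returned unchanged (after range
#'   check) when not `NULL`.
#' @return the fuzzifier, a single number > 1.
#' @export
estimate_fuzzifier <- function(profiles = NULL, G = NULL, D = NULL, m = NULL) {
  if (!is.null(m)) {
    stopifnot(is.numeric(m), length(m) == 1L, m > 1)
    return(as.numeric(m))
  }
  if (!is.null(profiles)) {
    G <- nrow(profiles)
    D <- ncol(profiles)
  }
  stopifnot(is.numeric(G), is.numeric(D), G >= 2, D >= 1)
  est <- 1 + (1418 / G + 22.05) * D^(-2) +
    (12.33 / G + 0.243) * D^(-0.0406 * log(G) - 0.1134)
  min(max(est, 1.05), 4)
}

# Squared Euclidean distances from every row of x to every centroid row.
dist2_to_centroids <- function(x, centroids) {
  d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(x, centroids)
  pmax(d2, 0)
}

# Membership update u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)). Rows where a
# profile coincides with a centroid (or where the powers overflow) get full
# membership on the first closest centroid.
memberships_from_dist <- function(d2, m) {
  w <- d2^(-1 / (m - 1))
  u <- w / rowSums(w)
  bad <- which(!is.finite(rowSums(u)) | rowSums(d2 == 0) > 0)
  if (length(bad)) {
    u[bad, ] <- 0
    first_min <- max.col(-d2[bad, , drop = FALSE], ties.method = "first")
    u[cbind(bad, first_min)] <- 1
  }
  u
}

# k-means++-style seeding over the gene rows: the first centroid is a
# uniform draw, each further centroid a draw weighted by squared distance to
# the nearest centroid chosen so far. Spreads initial centroids over all
# planted structures; deterministic given the RNG state.
init_centroids <- function(x, centers) {
  G <- nrow(x)
  idx <- integer(centers)
  idx[1L] <- sample.int(G, 1L)
  d2 <- rowSums((x - x[rep(idx[1L], G), , drop = FALSE])^2)
  for (j in seq_len(centers)[-1L]) {
    prob <- if (sum(d2) > 0) d2 else rep(1, G)
    idx[j] <- sample.int(G, 1L, prob = prob)
    d2 <- pmin(d2, rowSums((x - x[rep(idx[j], G), , drop = FALSE])^2))
  }
  x[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Soft-clusters standardized profiles by alternating the classic fuzzy
#' c-means updates: memberships
#' `u_ij = 1 / sum_k (||x_i - c_j|| / ||x_i - c_k||)^(2/(m-1))` and
#' centroids `c_j = sum_i u_ij^m x_i / sum_i u_ij^m`, until the largest
#' membership change falls below `tol` or `max_iter` is reached. The
#' objective `J = sum_ij u_ij^m ||x_i - c_j||^2` is recorded after every
#' iteration and is non-increasing. Profiles coinciding exactly with a
#' centroid receive full membership on the first such centroid. Centroids
#' are initialized from seeded, distance-weighted draws of gene rows
#' (k-means++-style), so the result is deterministic given `seed`.
#'
#' @param x genes x timepoints numeric matrix (standardized profiles).
#' @param centers number of clusters `c >= 2` (default 10, the usual choice
#'   for a three-timepoint monocyte-to-macrophage series).
#' @param m fuzzifier > 1, or `"auto"` to use [estimate_fuzzifier()].
#' @param seed integer seed for the centroid initialization.
#' @param tol convergence tolerance on `max |u - u_prev|`.
#' @param max_iter iteration cap; on non-convergence the best state is
#'   returned with `converged = FALSE` and a warning.
#' @return object of class `fuzzy_clustering`: list with `membership`
#'   (genes x clusters, rows summing to 1), `centroids` (clusters x
#'   timepoints), `m`, `objective` (per-iteration trajectory),
#'   `rowsum_error` (per-iteration max deviation of membership row sums
#'   from 1), `iterations`, `converged`.
#' @export
fuzzy_cmeans <- function(x, centers = 10L, m = "auto", seed = 1L,
                         tol = 1e-6, max_iter = 200L) {
  x <- as.matrix(x)
  G <- nrow(x)
  centers <- assert_count(centers, "centers", min = 2L)
  if (identical(m, "auto")) m <- estimate_fuzzifier(x)
  stopifnot(is.numeric(m), m > 1, G > centers)

  cent <- with_seed(seed, init_centroids(x, centers))
  u <- NULL
  obj <- numeric(0)
  rs_err <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    d2 <- dist2_to_centroids(x, cent)
    u_new <- memberships_from_dist(d2, m)
    um <- u_new^m
    cent <- (t(um) %*% x) / colSums(um)
    obj[it] <- sum(um * dist2_to_centroids(x, cent))
    rs_err[it] <- max(abs(rowSums(u_new) - 1))
    if (!is.null(u) && max(abs(u_new - u)) < tol) {
      u <- u_new
      converged <- TRUE
      break
    }
    u <- u_new
  }
  if (!converged)
    warning(sprintf("fuzzy_cmeans did not converge in %d iterations", max_iter))
  dimnames(u) <- list(rownames(x), sprintf("C%d", seq_len(centers)))
  dimnames(cent) <- list(sprintf("C%d", seq_len(centers)), colnames(x))
  structure(list(membership = u, centroids = cent, m = m, objective = obj,
                 rowsum_error = rs_err, iterations = it,
                 converged = converged),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf(
    "Fuzzy c-means: %d profiles, %d clusters, m = %.3f, %d iterations (%s)\n",
    nrow(x$membership), ncol(x$membership), x$m, x$iterations,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Classify cluster centroids into qualitative trends
#'
#' Labels each three-timepoint centroid `(a, b, c)` by its shape:
#' `rise-fall` when the middle point dominates both ends, `fall-rise` when
#' it is below both, otherwise monotone `up` (`a < c`) or `down` (`a > c`);
#' an all-equal centroid is labeled `flat`.
#'
#' @param x a `fuzzy_clustering` or a clusters x timepoints centroid
#'   matrix (exactly 3 columns).
#' @return named character vector of trend labels, one per cluster.
#' @export
classify_trends <- function(x) {
  cent <- if (inherits(x, "fuzzy_clustering")) x$centroids else as.matrix(x)
  stopifnot(ncol(cent) == 3L)
  lab <- apply(cent, 1L, function(v) {
    a <- v[1L]; b <- v[2L]; c3 <- v[3L]
    if (b > a && b > c3) "rise-fall"
    else if (b < a && b < c3) "fall-rise"
    else if (a < c3) "up"
    else if (a > c3) "down"
    else "flat"
  })
  stats::setNames(lab, rownames(cent))
}

#' Hard gene lists per cluster and trend class
#'
#' Assigns each gene to its maximum-membership cluster when that membership
#' reaches `membership_threshold`; genes below the threshold stay
#' unassigned. Trend-class gene lists are the unions over clusters sharing a
#' trend label.
#'
#' @param clustering a `fuzzy_clustering`.
#' @param membership_threshold minimum membership for a hard assignment
#'   (default 0.5).
#' @return list with `assignments` (data frame `gene`, `cluster`,
#'   `membership`, `trend` for assigned genes) and `by_trend` (named list of
#'   gene vectors per trend class).
#' @export
cluster_gene_sets <- function(clustering, membership_threshold = 0.5) {
  stopifnot(inherits(clustering, "fuzzy_clustering"))
  u <- clustering$membership
  best <- max.col(u, ties.method = "first")
  best_m <- u[cbind(seq_len(nrow(u)), best)]
  keep <- best_m >= membership_threshold
  trends <- classify_trends(clustering)
  assignments <- data.frame(
    gene = rownames(u)[keep],
    cluster = colnames(u)[best[keep]],
    membership = unname(best_m[keep]),
    trend = unname(trends[colnames(u)[best[keep]]]),
    stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$gene), , drop = FALSE]
  rownames(assignments) <- NULL
  by_trend <- lapply(split(assignments$gene, assignments$trend), sort)
  list(assignments = assignments, by_trend = by_trend)
}
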