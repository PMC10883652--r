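#' Hellinger distance between two compositions
#'
#' `HD = sqrt(sum_i (sqrt(a_i) - sqrt(b_i))^2)`, computed over the union of
#' features (missing features enter as zeros). Under this (default)
#' convention the distance of two disjoint compositions is `sqrt(2)`; with
#' `scaled = TRUE` the value is divided by `sqrt(2)` so the range becomes
#' `[0, 1]`. Rank-based downstream analyses (ANOSIM) are invariant to the
#' choice.
#'
#' @param a,b numeric compositional vectors (non-negative, each summing to 1
#'   within `1e-9`).
#' @param scaled use the `[0, 1]`-ranged convention.
#' @return The Hellinger distance.
#' @export
#' @examples
#' hellinger_distance(c(1, 0), c(0, 1)) # sqrt(2)
hellinger_distance <- function(a, b, scaled = FALSE) {
  if (length(a) != length(b))
    stop2("'a' and 'b' must cover the same feature set")
  a <- check_composition(a)
  b <- check_composition(b)
  d <- sqrt(sum((sqrt(a) - sqrt(b))^2))
  if (scaled) d / sqrt(2) else d
}

#' Pairwise Hellinger distances between all samples
#'
#' @param composition numeric matrix (features x samples) with columns
#'   summing to 1.
#' @param scaled see [hellinger_distance()].
#' @return A `dist` object labeled by sample id.
#' @export
hellinger_dist <- function(composition, scaled = FALSE) {
  if (ncol(composition) < 2L) stop2("need at least 2 samples")
  for (j in seq_len(ncol(composition)))
    check_composition(composition[, j],
                      what = paste0("composition (sample ",
                                    colnames(composition)[j] %||% j, ")"))
  d <- dist(t(sqrt(composition)))
  if (scaled) d / sqrt(2) else d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: Gower double-centering of
#' `-D^2/2` followed by eigendecomposition; coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues. Axes with
#' non-positive eigenvalues are reported but dropped from the coordinates.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param n_axes number of coordinate axes requested (`<= n_samples - 1`).
#' @return A list of class `pcoa_result` with `coordinates`
#'   (samples x axes), `eigenvalues` (all, sorted descending),
#'   `proportion` (variance share of each positive eigenvalue) and
#'   `n_negative`.
#' @export
pcoa <- function(d, n_axes = 2L) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n_axes > n - 1L) stop2("'n_axes' must be <= n_samples - 1")
  # cmdscale warns whenever k exceeds the positive-eigenvalue count; we ask
  # for everything and do our own axis bookkeeping below
  fit <- suppressWarnings(cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig > max(eig) * 1e-9)
  if (n_axes > pos) {
    warning("only ", pos, " positive eigenvalue(s); returning ", pos,
            " axes", call. = FALSE)
    n_axes <- pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 proportion = pmax(eig, 0) / sum(pmax(eig, 0)),
                 n_negative = sum(eig < 0)),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " axes\n", sep = "")
  cat("  variance explained:",
      paste0(round(100 * x$proportion[seq_len(ncol(x$coordinates))], 1), "%",
             collapse = ", "), "\n")
  invisible(x)
}

anosim_statistic <- function(rank_matrix, grouping) {
  same <- outer(grouping, grouping, "==")
  ut <- upper.tri(rank_matrix)
  rw <- rank_matrix[ut & same]
  rb <- rank_matrix[ut & !same]
  n <- length(grouping)
  m_pairs <- n * (n - 1) / 2
  (mean(rb) - mean(rw)) / (m_pairs / 2)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group distances exceed
#' within-group distances. The statistic is
#' `R = (mean rank between - mean rank within) / (M/2)` with
#' `M = n(n-1)/2` pairwise distances ranked with mid-rank ties, so
#' `R` lies in `[-1, 1]`. The p-value uses the add-one permutation
#' estimator `p = (1 + #(R_perm >= R_obs)) / (1 + n_permutations)`, or exact
#' enumeration of all label assignments for two groups when `exact = TRUE`.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param grouping group label per sample (>= 2 groups, each of size >= 2).
#' @param n_permutations number of random label permutations (>= 99).
#' @param seed optional integer seed making the permutations reproducible.
#' @param exact enumerate all distinct two-group label assignments instead
#'   of sampling (only available for two groups).
#' @return A list of class `anosim_result` with `statistic`, `p_value`,
#'   `n_permutations` (or number of enumerated assignments), `exact` and
#'   `grouping`.
#' @export
anosim <- function(d, grouping, n_permutations = 999L, seed = NULL,
                   exact = FALSE) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  grouping <- as.character(grouping)
  if (length(grouping) != n)
    stop2("'grouping' must have one label per sample")
  sizes <- table(grouping)
  if (length(sizes) < 2L) stop2("need at least 2 groups")
  if (any(sizes < 2L))
    stop2("every group needs at least 2 samples (offending: ",
          paste(names(sizes)[sizes < 2], collapse = ", "), ")")
  dm <- as.matrix(d)
  rk <- matrix(0, n, n)
  # dist vectors are stored in lower-triangle column-major order
  rk[lower.tri(rk)] <- rank(as.vector(d)) # mid-rank ties
  rk <- rk + t(rk)
  r_obs <- anosim_statistic(rk, grouping)
  if (exact) {
    if (length(sizes) != 2L)
      stop2("exact enumeration is implemented for two groups only")
    g1 <- names(sizes)[1L]
    combos <- combn(n, sizes[[1L]])
    r_all <- apply(combos, 2L, function(idx) {
      g <- rep(names(sizes)[2L], n)
      g[idx] <- g1
      anosim_statistic(rk, g)
    })
    p <- mean(r_all >= r_obs - 1e-12) # identity assignment included: p > 0
    n_perm <- ncol(combos)
  } else {
    if (n_permutations < 99L) stop2("'n_permutations' must be >= 99")
    perm <- function() anosim_statistic(rk, sample(grouping))
    r_perm <- if (is.null(seed)) {
      replicate(n_permutations, perm())
    } else {
      with_seed(seed, replicate(n_permutations, perm()))
    }
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(statistic = r_obs, p_value = p, n_permutations = n_perm,
                 exact = exact, grouping = sizes),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat("<anosim_result> R = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4),
      if (x$exact) " (exact, " else " (",
      x$n_permutations,
      if (x$exact) " assignments)\n" else " permutations)\n", sep = "")
  invisible(x)
}
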