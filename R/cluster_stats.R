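#' Paired (dependent-sample) t statistics per feature
#'
#' @param cond_a,cond_b Numeric matrices `units x features` (units are
#'   participants or replicates, paired across conditions).
#' @return Numeric vector of t values per feature; features with zero
#'   difference variance are NA.
#' @export
dependent_t <- function(cond_a, cond_b) {
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  stopifnot(all(dim(cond_a) == dim(cond_b)), nrow(cond_a) >= 2)
  d <- cond_a - cond_b
  n <- nrow(d)
  m <- colMeans(d)
  v <- (colSums(d^2) - n * m^2) / (n - 1)
  t <- ifelse(v > 0, m / sqrt(v / n), NA_real_)
  t
}

#' k-nearest-neighbour sensor adjacency
#'
#' Symmetric adjacency list for cluster formation over sensors, built from
#' 2-D sensor positions (each sensor is a neighbour of its k nearest
#' sensors; the relation is symmetrised by union).
#'
#' @param positions Numeric `sensors x 2` matrix.
#' @param k Number of nearest neighbours (default 4).
#' @return List of integer neighbour vectors, one per sensor.
#' @export
knn_adjacency <- function(positions, k = 4) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  k <- min(k, n - 1)
  D <- as.matrix(dist(positions))
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    adj[[i]] <- order(D[i, ])[2:(k + 1)]
  }
  for (i in seq_len(n)) for (j in adj[[i]])
    if (!(i %in% adj[[j]])) adj[[j]] <- c(adj[[j]], i)
  lapply(adj, sort)
}

## connected components of suprathreshold features
find_clusters <- function(above, adjacency = NULL) {
  idx <- which(above)
  if (length(idx) == 0) return(list())
  if (is.null(adjacency)) {  # temporal contiguity: runs of TRUE
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    return(lapply(keep, function(i) starts[i]:ends[i]))
  }
  seen <- logical(length(above))
  clusters <- list()
  for (s in idx) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adjacency[[v]]
      nb <- nb[above[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    clusters[[length(clusters) + 1]] <- sort(comp)
  }
  clusters
}

cluster_masses <- function(t, thr, tail, adjacency) {
  t0 <- ifelse(is.na(t), 0, t)
  out <- list(clusters = list(), mass = numeric(0), sign = numeric(0))
  if (tail %in% c("pos", "two")) {
    cl <- find_clusters(t0 > thr, adjacency)
    out$clusters <- c(out$clusters, cl)
    out$mass <- c(out$mass, vapply(cl, function(m) sum(t0[m]), 0))
    out$sign <- c(out$sign, rep(1, length(cl)))
  }
  if (tail %in% c("neg", "two")) {
    cl <- find_clusters(t0 < -thr, adjacency)
    out$clusters <- c(out$clusters, cl)
    out$mass <- c(out$mass, vapply(cl, function(m) sum(t0[m]), 0))
    out$sign <- c(out$sign, rep(-1, length(cl)))
  }
  out
}

#' Cluster-based permutation test for paired conditions
#'
#' Nonparametric multiple-comparison control over sensors or time points:
#' per-feature dependent-sample t values are thresholded at the
#' `cluster_alpha` quantile of the t distribution (tail-appropriate),
#' contiguous suprathreshold features are grouped under the adjacency
#' relation (temporal contiguity when `adjacency` is NULL), and each
#' cluster's mass (sum of t) is compared with a Monte-Carlo null of maximal
#' cluster masses obtained by randomly swapping the two conditions within
#' units. Cluster p values use the `+1` convention
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param cond_a,cond_b Matrices `units x features`.
#' @param adjacency Neighbour list (e.g. [knn_adjacency()]) or NULL for
#'   temporal contiguity along the feature axis.
#' @param tail `"pos"`, `"neg"` (one-tailed) or `"two"`.
#' @param n_perm Number of permutations (>= 100).
#' @param cluster_alpha Cluster-forming threshold probability.
#' @param seed Optional integer seed.
#' @return List of class `cluster_result`: `t` (observed per-feature t),
#'   `threshold`, `clusters` (data frame: id, n_features, mass, p, sign),
#'   `members` (list of feature index vectors), `null` (the n_perm maximal
#'   masses), `tail`.
#' @export
cluster_permutation <- function(cond_a, cond_b, adjacency = NULL,
                                tail = c("pos", "neg", "two"),
                                n_perm = 1000, cluster_alpha = 0.05,
                                seed = NULL) {
  tail <- match.arg(tail)
  if (n_perm < 100) stop("n_perm must be at least 100", call. = FALSE)
  if (cluster_alpha <= 0 || cluster_alpha >= 0.5)
    stop("cluster_alpha must lie in (0, 0.5)", call. = FALSE)
  cond_a <- as.matrix(cond_a); cond_b <- as.matrix(cond_b)
  stopifnot(all(dim(cond_a) == dim(cond_b)))
  n <- nrow(cond_a); p <- ncol(cond_a)
  if (p == 0) stop("no features", call. = FALSE)
  d <- cond_a - cond_b
  dfree <- n - 1
  thr <- if (tail == "two") qt(1 - cluster_alpha / 2, dfree) else
    qt(1 - cluster_alpha, dfree)

  t_obs <- dependent_t(cond_a, cond_b)
  obs <- cluster_masses(t_obs, thr, tail, adjacency)

  if (!is.null(seed)) set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  M <- (S %*% d) / n
  ss <- colSums(d^2)
  V <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
  Tp <- M / sqrt(pmax(V, 0) / n)
  Tp[!is.finite(Tp)] <- 0

  null <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    pm <- cluster_masses(Tp[i, ], thr, tail, adjacency)
    null[i] <- if (length(pm$mass) == 0) 0 else switch(tail,
      pos = max(pm$mass), neg = min(pm$mass), two = max(abs(pm$mass)))
  }

  pvals <- vapply(seq_along(obs$mass), function(i) {
    m <- obs$mass[i]
    exceed <- switch(tail,
                     pos = sum(null >= m),
                     neg = sum(null <= m),
                     two = sum(abs(null) >= abs(m)))
    (1 + exceed) / (n_perm + 1)
  }, 0)

  clusters <- data.frame(id = seq_along(obs$mass),
                         n_features = vapply(obs$clusters, length, 0L),
                         mass = obs$mass, p = pvals, sign = obs$sign)
  structure(list(t = t_obs, threshold = thr, clusters = clusters,
                 members = obs$clusters, null = null, tail = tail,
                 n_perm = n_perm, cluster_alpha = cluster_alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> tail=%s, threshold |t|>%.3f, %d permutations\n",
              x$tail, x$threshold, x$n_perm))
  if (nrow(x$clusters) == 0) cat("  no suprathreshold clusters\n")
  else print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Temporal cluster test between condition coherence series
#'
#' Compares two sets of per-participant coherence time courses (e.g. the
#' guided target-colour series against the unguided reference series)
#' within a test window, using [cluster_permutation()] with temporal
#' contiguity.
#'
#' @param series_a,series_b Matrices `participants x time`.
#' @param times Time axis in seconds matching the columns.
#' @param window Two-element test window in seconds (default 0.1-0.5).
#' @param ... Passed to [cluster_permutation()].
#' @return A `cluster_result`; `members` index into the windowed time axis
#'   returned as the `times` element.
#' @export
compare_coherence_conditions <- function(series_a, series_b, times,
                                         window = c(0.1, 0.5), ...) {
  keep <- which(times >= window[1] & times <= window[2])
  out <- cluster_permutation(series_a[, keep, drop = FALSE],
                             series_b[, keep, drop = FALSE],
                             adjacency = NULL, ...)
  out$times <- times[keep]
  out
}
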