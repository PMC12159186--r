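#' Cross-spectral density matrix at one frequency
#'
#' Tapers each data segment, evaluates the Fourier coefficient at exactly
#' the requested frequency for every sensor and for the reference channel,
#' and averages the outer products over segments. The reference occupies
#' the last row/column. The result is Hermitian with a real non-negative
#' diagonal by construction.
#'
#' @param x Numeric array `sensors x segments x samples`.
#' @param ref Numeric matrix `segments x samples` of the reference signal.
#' @param fs Sampling rate in Hz.
#' @param freq Analysis frequency in Hz.
#' @param taper `"hanning"` (default) or `"none"`.
#' @return List of class `csd_matrix`: `C` (complex
#'   `(sensors+1) x (sensors+1)`), `freq`, `n_segments`, `ref_index`.
#' @export
estimate_csd <- function(x, ref, fs, freq, taper = c("hanning", "none")) {
  taper <- match.arg(taper)
  stopifnot(length(dim(x)) == 3)
  ns <- dim(x)[1]; nseg <- dim(x)[2]; nt <- dim(x)[3]
  ref <- as.matrix(ref)
  stopifnot(nrow(ref) == nseg, ncol(ref) == nt)
  if (nseg < 2)
    stop("cross-spectral density from a single segment is rank 1; need >= 2",
         call. = FALSE)
  w <- if (taper == "hanning") as.numeric(signal::hanning(nt)) else
    rep(1, nt)
  e <- w * exp(-2i * pi * freq * (seq_len(nt) - 1) / fs)
  C <- matrix(0 + 0i, ns + 1, ns + 1)
  for (k in seq_len(nseg)) {
    v <- c(x[, k, , drop = TRUE] %*% e, sum(ref[k, ] * e))
    C <- C + v %*% Conj(t(v))
  }
  C <- C / nseg
  C <- (C + Conj(t(C))) / 2  # enforce exact Hermitian symmetry
  structure(list(C = C, freq = freq, n_segments = nseg,
                 ref_index = ns + 1), class = "csd_matrix")
}

#' Truncated-SVD pseudoinverse
#'
#' Decomposes a (Hermitian) matrix by SVD, retains the singular values
#' above `rank_tol` times the largest (or an explicitly given rank), and
#' inverts on the retained subspace. The default tolerance is the
#' numerical-rank convention `max(singular values) * machine epsilon *
#' matrix dimension`.
#'
#' @param C Square numeric or complex matrix.
#' @param rank Optional explicit rank to retain.
#' @param rank_tol Relative singular-value cut-off (ignored when `rank` is
#'   given).
#' @return The pseudoinverse matrix, with attribute `rank` (retained
#'   subspace dimension).
#' @export
truncated_svd_pinv <- function(C, rank = NULL, rank_tol = NULL) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == ncol(C))
  s <- svd(C)
  if (is.null(rank_tol)) rank_tol <- .Machine$double.eps * nrow(C)
  k <- if (!is.null(rank)) min(rank, length(s$d)) else
    sum(s$d > rank_tol * s$d[1])
  if (k == 0) stop("all singular values below tolerance", call. = FALSE)
  inv <- s$v[, seq_len(k), drop = FALSE] %*%
    (t(Conj(s$u[, seq_len(k), drop = FALSE])) / s$d[seq_len(k)])
  attr(inv, "rank") <- k
  inv
}

#' DICS source-coherence map
#'
#' Unit-noise-gain minimum-variance beamforming on a cross-spectral
#' density matrix: for each source grid point the spatial filter is the
#' regularised inverse CSD applied to the lead-field column, normalised to
#' unit Euclidean norm; the map value is the magnitude-squared coherence
#' between the beamformed source signal and the reference channel,
#' `|w^H c_ref|^2 / ((w^H C w) C_refref)`.
#'
#' @param L Lead field, `sensors x grid-points` (scalar gain per
#'   fixed-orientation dipole).
#' @param csd A `csd_matrix` from [estimate_csd()] whose sensor block
#'   matches `L`.
#' @param rank,rank_tol Regularisation of the CSD inverse, passed to
#'   [truncated_svd_pinv()].
#' @param positions Optional `grid-points x d` coordinates carried through
#'   to the result.
#' @return List of class `source_map`: `coherence` (per grid point, in
#'   `[0, 1]`), `filters` (`grid-points x sensors`, unit-norm rows),
#'   `flagged` (grid points with an all-zero lead-field column), `freq`,
#'   `positions`.
#' @export
dics_map <- function(L, csd, rank = NULL, rank_tol = NULL,
                     positions = NULL) {
  L <- as.matrix(L)
  ns <- nrow(L)
  stopifnot(inherits(csd, "csd_matrix"), csd$ref_index == ns + 1)
  Cs <- csd$C[seq_len(ns), seq_len(ns)]
  cref <- csd$C[seq_len(ns), csd$ref_index]
  Crr <- Re(csd$C[csd$ref_index, csd$ref_index])
  Cinv <- truncated_svd_pinv(Cs, rank = rank, rank_tol = rank_tol)
  W <- Cinv %*% L
  norms <- sqrt(colSums(Mod(W)^2))
  flagged <- colSums(abs(L)) == 0 | norms == 0
  norms[flagged] <- 1
  W <- sweep(W, 2, norms, "/")
  Pss <- Re(colSums(Conj(W) * (Cs %*% W)))
  cross <- colSums(Conj(W) * cref)
  coh <- Mod(cross)^2 / (Pss * Crr)
  coh <- pmin(pmax(coh, 0), 1)
  coh[flagged] <- NA_real_
  structure(list(coherence = coh, filters = t(W), flagged = flagged,
                 freq = csd$freq, positions = positions),
            class = "source_map")
}

#' Mask the most strongly coherent grid points
#'
#' @param map A `source_map` or a numeric coherence vector.
#' @param percent Percentage of grid points to retain (default 1); the
#'   mask keeps `ceiling(percent/100 * n)` points. Ties are broken stably
#'   by grid index.
#' @return Logical mask over grid points.
#' @export
#' @examples
#' top_percent_mask(runif(100), 1)  # exactly one TRUE
top_percent_mask <- function(map, percent = 1) {
  coh <- if (inherits(map, "source_map")) map$coherence else as.numeric(map)
  n <- length(coh)
  if (n == 0) stop("empty map", call. = FALSE)
  k <- ceiling(percent / 100 * n)
  coh2 <- ifelse(is.na(coh), -Inf, coh)
  ord <- order(-coh2, seq_len(n))
  mask <- logical(n)
  mask[ord[seq_len(k)]] <- TRUE
  mask
}

#' Synthetic lead field on a lattice source grid
#'
#' Random smooth gain matrix standing in for an anatomical forward model:
#' sensors are placed on a ring above a 3-D lattice of unit-spaced grid
#' points and each gain falls off with sensor-source distance, with
#' multiplicative log-normal roughness. Intended for simulation and tests;
#' no head model is implied (synthetic fixture).
#'
#' @param n_sensors Number of sensors.
#' @param grid_dims Integer 3-vector of lattice dimensions.
#' @param spacing Grid spacing (arbitrary units; 1 by default).
#' @param roughness sd of multiplicative log-normal gain noise.
#' @param seed Optional integer seed.
#' @return List with `L` (`sensors x grid-points`), `positions`
#'   (`grid-points x 3`), `sensor_positions`.
#' @export
synthetic_leadfield <- function(n_sensors = 20, grid_dims = c(5, 5, 4),
                                spacing = 1, roughness = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                             y = seq_len(grid_dims[2]),
                             z = seq_len(grid_dims[3]))) * spacing
  centre <- colMeans(g)
  ang <- 2 * pi * seq_len(n_sensors) / n_sensors
  radius <- max(grid_dims) * spacing
  sens <- cbind(centre[1] + radius * cos(ang),
                centre[2] + radius * sin(ang),
                centre[3] + max(g[, 3]) + spacing)
  L <- matrix(0, n_sensors, nrow(g))
  for (s in seq_len(n_sensors)) {
    d <- sqrt(colSums((t(g) - sens[s, ])^2))
    L[s, ] <- exp(rnorm(nrow(g), 0, roughness)) / (d^2)
  }
  list(L = L, positions = g, sensor_positions = sens)
}
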