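#' Direction-selective tuning matrix
#'
#' Rows are all sign patterns in `{-1, 0, 1}^D` except the all-zero one,
#' each normalized to unit length and scaled by `beta`: `3^D - 1` equally
#' distributed, overlapping preferred directions covering the whole
#' directional space (26 rows for a 3D feature, 2 rows for a 1D angle
#' feature). The row set satisfies the isotropy identity
#' `t(W) %*% W = beta^2 * (3^D - 1) / D * I`, which is what makes the
#' population response norm direction-independent.
#'
#' @param D feature dimensionality (1, 2 or 3).
#' @param beta row scaling (default from [beta_for()] with unit budget).
#' @return `(3^D - 1) x D` tuning matrix.
#' @export
build_tuning_matrix <- function(D, beta = beta_for(D, 1)) {
  stopifnot(D %in% 1:3)
  g <- as.matrix(do.call(expand.grid, rep(list(c(-1, 0, 1)), D)))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g <- g / sqrt(rowSums(g^2))
  dimnames(g) <- NULL
  g * beta
}

#' Population scaling for a given length budget
#'
#' Returns the `beta` that makes the direction-selective population
#' response to any unit direction have norm exactly `L`:
#' `beta = L * sqrt(D / (3^D - 1))`, the unique choice under the tuning-set
#' isotropy `t(W) %*% W = beta^2 (3^D - 1) / D * I`.
#'
#' @param D feature dimensionality (1, 2 or 3).
#' @param L per-feature length budget (> 0).
#' @return scalar `beta`.
#' @export
beta_for <- function(D, L) {
  stopifnot(D %in% 1:3, L > 0)
  L * sqrt(D / (3^D - 1))
}

#' Population-coding configuration
#'
#' Fixes the per-feature populations of the common visuo-proprioceptive
#' space: each of the N visual features gets `3^3 - 1 = 26`
#' direction-selective neurons plus one no-motion (static) neuron, each of
#' the M angle features gets `2 + 1` neurons. Every available feature slice
#' carries norm exactly `L = 1 / sqrt(N + M)`, so the concatenation of all
#' populations has unit norm — with the default N = 12, M = 8 the space is
#' `12 * 27 + 8 * 3 = 348`-dimensional.
#'
#' @param n_visual number of 3D visual features N (default 12).
#' @param n_proprio number of 1D angle features M (default 8).
#' @return an object of class `population_config` with the tuning matrices,
#'   slice index maps and budgets.
#' @export
population_config <- function(n_visual = 12L, n_proprio = 8L) {
  N <- as.integer(n_visual); M <- as.integer(n_proprio)
  stopifnot(N >= 1L, M >= 0L)
  L <- 1 / sqrt(N + M)
  W3 <- build_tuning_matrix(3L, beta_for(3L, L))
  W1 <- build_tuning_matrix(1L, beta_for(1L, L))
  sizes <- c(rep(27L, N), rep(3L, M))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  slices <- Map(seq.int, starts, ends)
  structure(list(n_visual = N, n_proprio = M, L = L, W3 = W3, W1 = W1,
                 slices = slices, total = sum(sizes)),
            class = "population_config")
}

#' @export
print.population_config <- function(x, ...) {
  cat(sprintf("<population_config> %d visual + %d proprio features -> %d neurons, L = %.4f\n",
              x$n_visual, x$n_proprio, x$total, x$L))
  invisible(x)
}

#' Encode one feature direction as a population slice
#'
#' Direction-selective part `W %*% direction`, plus the static (no-motion)
#' neuron `o_s = sqrt(max(0, L^2 - l^2))` with `l` the norm of the
#' direction-selective part; the whole slice is multiplied by the
#' availability gain `g`. For any direction of magnitude at most 1 the
#' slice norm is exactly `L * g`.
#'
#' @param direction motion direction (length 3 for a visual feature, 1 for
#'   an angle feature), magnitude at most 1.
#' @param cfg a [population_config()].
#' @param n feature index in `1..(N + M)` (visual features first).
#' @param g availability gain, 0 or 1.
#' @return numeric population slice (27 or 3 values, static neuron last).
#' @export
encode_feature <- function(direction, cfg, n, g = 1) {
  stopifnot(inherits(cfg, "population_config"))
  visual <- n <= cfg$n_visual
  D <- if (visual) 3L else 1L
  if (length(direction) != D)
    stop(sprintf("feature %d expects a %dD direction", n, D))
  nrm <- sqrt(sum(direction^2))
  if (nrm > 1 + 1e-6)
    stop("direction magnitude exceeds 1: upstream normalization contract violated")
  W <- if (visual) cfg$W3 else cfg$W1
  u <- as.vector(W %*% direction)
  l2 <- sum(u^2)
  s <- sqrt(max(0, cfg$L^2 - l2))
  g * c(u, s)
}

#' Encode all feature directions into the common population space
#'
#' @param directions length `3N + M` direction vector (Stage I output,
#'   visual triples first), or a `T x (3N + M)` matrix of such rows.
#' @param cfg a [population_config()].
#' @param gains availability gains, length `N + M` in `{0, 1}` (visual
#'   features first), or a matching `T x (N + M)` matrix.
#' @return a numeric vector of length `cfg$total` (or a `T x total`
#'   matrix): the concatenated population activation. With all gains 1 and
#'   valid directions its norm is 1; dropping features scales the norm to
#'   `sqrt(available / (N + M))`.
#' @export
encode_all <- function(directions, cfg, gains = NULL) {
  stopifnot(inherits(cfg, "population_config"))
  one <- !is.matrix(directions)
  D <- if (one) matrix(directions, nrow = 1L) else directions
  N <- cfg$n_visual; M <- cfg$n_proprio
  stopifnot(ncol(D) == 3L * N + M)
  Tn <- nrow(D)
  if (is.null(gains)) gains <- rep(1, N + M)
  G <- if (is.matrix(gains)) gains else
    matrix(gains, Tn, N + M, byrow = TRUE)
  out <- matrix(0, Tn, cfg$total)
  L2 <- cfg$L^2
  for (n in seq_len(N)) {
    q <- D[, 3L * (n - 1L) + 1:3, drop = FALSE]
    U <- q %*% t(cfg$W3)                     # T x 26
    l2 <- rowSums(U^2)
    out[, cfg$slices[[n]]] <- G[, n] * cbind(U, sqrt(pmax(0, L2 - l2)))
  }
  for (m in seq_len(M)) {
    v <- D[, 3L * N + m]
    U <- outer(v, as.vector(cfg$W1))         # T x 2
    l2 <- rowSums(U^2)
    out[, cfg$slices[[N + m]]] <- G[, N + m] * cbind(U, sqrt(pmax(0, L2 - l2)))
  }
  if (one) as.vector(out) else out
}

# mask vector over the population space from per-feature gains
population_mask <- function(cfg, gains) {
  m <- numeric(cfg$total)
  for (n in seq_along(cfg$slices)) m[cfg$slices[[n]]] <- gains[n]
  m
}
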