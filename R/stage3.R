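#' Noise scale from recruitment remainder and breadth
#'
#' Calibrates the Cauchy noise scale of the pattern layer so that the
#' probability of recruiting a new pattern is `epsilon` when the best
#' trained pattern's net input sits `b` above the recruitment threshold
#' (and `1 - epsilon` when it sits `b` below): `gamma = tan(epsilon * pi) *
#' b / 2`. As `epsilon` approaches 0.5 the scale diverges (the threshold
#' becomes completely fuzzy).
#'
#' @param epsilon recruitment probability remainder, in `(0, 0.5]`
#'   (default 0.001).
#' @param b threshold breadth (> 0, default 0.034).
#' @return the Cauchy scale `gamma`.
#' @export
gamma_from <- function(epsilon = 0.001, b = 0.034) {
  if (!is.numeric(epsilon) || epsilon <= 0 || epsilon > 0.5)
    stop("epsilon must lie in (0, 0.5]")
  if (!is.numeric(b) || b <= 0) stop("b must be > 0")
  tan(epsilon * pi) * b / 2
}

#' Growing pattern layer
#'
#' The spatio-temporal clustering layer: motion-pattern neurons with
#' instar weight vectors over the population space, a Cauchy-noise
#' activation function, winner-take-all instar learning with on-demand
#' recruitment (exactly one free pattern exists at all times), and lateral
#' transition weights that learn winner-sequence statistics. The object is
#' environment-backed: update functions modify it in place and also return
#' it, so both mutating and pipe styles work.
#'
#' @param n_input population space dimension (default 348).
#' @param theta recruitment threshold on the net input (default
#'   `cos(pi / 3)`).
#' @param epsilon,b recruitment remainder and breadth calibrating the
#'   noise scale via [gamma_from()].
#' @param gamma Cauchy noise scale; default derived from `epsilon` and `b`.
#' @param eta instar learning rate (default 0.01).
#' @param eta_l lateral learning rate (default 0.6).
#' @param r free/trained threshold on the instar norm; must satisfy
#'   `0 < r < eta` so one update recruits a free pattern (default
#'   `eta / 2`).
#' @param seed integer seed of the layer-owned random generator.
#' @param compat_printed_inhibition use the uncorrected lateral inhibition form
#'   `tanh(-2 gamma tan(w pi))` (kept for comparison; see
#'   [lateral_inhibition_term()]).
#' @return an object of class `pattern_layer`.
#' @export
pattern_layer <- function(n_input = 348L, theta = cos(pi / 3),
                          epsilon = 0.001, b = 0.034,
                          gamma = gamma_from(epsilon, b),
                          eta = 0.01, eta_l = 0.6, r = eta / 2,
                          seed = 1L, compat_printed_inhibition = FALSE) {
  stopifnot(n_input >= 1L, gamma > 0, eta > 0, eta_l > 0, eta_l <= 1)
  if (r <= 0 || r >= eta)
    stop("r must satisfy 0 < r < eta (a single update must recruit)")
  ly <- new.env(parent = emptyenv())
  ly$n_input <- as.integer(n_input)
  ly$theta <- theta; ly$gamma <- gamma
  ly$eta <- eta; ly$eta_l <- eta_l; ly$r <- r
  ly$compat_printed_inhibition <- isTRUE(compat_printed_inhibition)
  cap <- 16L
  ly$capacity <- cap
  ly$P <- 1L                                   # pattern 1 is the free pattern
  ly$instar <- matrix(0, cap, n_input)
  ly$norms <- numeric(cap)
  ly$lateral <- matrix(0.5, cap, cap)
  ly$prev_winner <- NA_integer_
  ly$buf <- matrix(NA_real_, 0L, 0L)           # net-input window since last transition
  ly$winner_count <- 0L
  ly$rng <- NULL
  layer_rng_eval(ly, seed, NULL)               # initialize owned RNG stream
  class(ly) <- "pattern_layer"
  ly
}

#' @export
print.pattern_layer <- function(x, ...) {
  cat(sprintf(
    "<pattern_layer> %d patterns (%d trained + 1 free), %d inputs\n",
    x$P, x$P - 1L, x$n_input))
  cat(sprintf("  theta = %.4f, gamma = %.3g, eta = %.3g, eta_l = %.2g, r = %.3g\n",
              x$theta, x$gamma, x$eta, x$eta_l, x$r))
  invisible(x)
}

# evaluate expr under the layer-owned RNG stream; seed used only at init
layer_rng_eval <- function(ly, seed = NULL, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  if (is.null(ly$rng)) set.seed(seed) else
    assign(".Random.seed", ly$rng, envir = globalenv())
  res <- expr
  ly$rng <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  res
}

free_index <- function(ly) ly$P          # the free pattern is always last
n_trained <- function(ly) ly$P - 1L

grow_layer <- function(ly) {
  newcap <- ly$capacity * 2L
  instar <- matrix(0, newcap, ly$n_input)
  instar[seq_len(ly$P), ] <- ly$instar[seq_len(ly$P), ]
  norms <- numeric(newcap); norms[seq_len(ly$P)] <- ly$norms[seq_len(ly$P)]
  lateral <- matrix(0.5, newcap, newcap)
  lateral[seq_len(ly$P), seq_len(ly$P)] <- ly$lateral[seq_len(ly$P), seq_len(ly$P)]
  ly$instar <- instar; ly$norms <- norms; ly$lateral <- lateral
  ly$capacity <- newcap
  invisible(ly)
}

#' Closed-form recruitment probability
#'
#' Probability that the free pattern out-competes the best matching
#' trained pattern whose net input is `net_g`:
#' `1/2 + arctan((theta - net_g) / (2 gamma)) / pi`. Equals 0.5 at
#' `net_g = theta`, `epsilon` at `theta + b` and `1 - epsilon` at
#' `theta - b`.
#'
#' @param net_g net input(s) of the best matching trained pattern.
#' @param layer a [pattern_layer()], or a list with `theta` and `gamma`.
#' @return recruitment probability, vectorized over `net_g`.
#' @export
recruitment_probability <- function(net_g, layer) {
  0.5 + atan((layer$theta - net_g) / (2 * layer$gamma)) / pi
}

#' Lateral inhibition presynaptic term
#'
#' Maps a lateral transition weight `w` in `[0, 1]` to an inhibition in
#' `(-1, 0]`: `tanh(2 gamma tan((w - 1/2) pi))` for `w < 0.5` and 0
#' otherwise (no facilitation). Calibrated so that under noise-only drive
#' the probability that the inhibited pattern out-competes the previous
#' winner is approximately `w`; at the 0.5 initialization no inhibition
#' occurs. `compat_printed = TRUE` selects the uncorrected variant
#' `tanh(-2 gamma tan(w pi))`, which is maximally inhibiting at `w = 0.5`
#' and is retained only for comparison.
#'
#' @param w lateral weight(s) in `[0, 1]`.
#' @param gamma Cauchy noise scale of the layer.
#' @param compat_printed use the uncorrected form.
#' @return inhibition value(s) in `(-1, 0]`.
#' @export
lateral_inhibition_term <- function(w, gamma, compat_printed = FALSE) {
  if (any(w < 0 | w > 1)) stop("lateral weights must lie in [0, 1]")
  if (compat_printed) return(tanh(-2 * gamma * tan(w * pi)))
  out <- numeric(length(w))
  lo <- w < 0.5
  out[lo] <- tanh(2 * gamma * tan((w[lo] - 0.5) * pi))
  out
}

# stimulus net inputs for patterns 1..P (free slot carries theta), plus the
# lateral inhibition from the previous winner
layer_nets <- function(ly, activation) {
  P <- ly$P
  nets <- numeric(P)
  if (P > 1L) {
    idx <- seq_len(P - 1L)
    nets[idx] <- as.vector(ly$instar[idx, , drop = FALSE] %*% activation) /
      pmax(ly$norms[idx], ly$r)
    k <- ly$prev_winner
    if (!is.na(k) && k < P) {            # free pattern neither sends nor receives
      j <- idx[idx != k]
      if (length(j))
        nets[j] <- nets[j] + lateral_inhibition_term(ly$lateral[k, j], ly$gamma,
                                                     ly$compat_printed_inhibition)
    }
  }
  nets[P] <- ly$theta
  nets
}

#' Net input of pattern neurons
#'
#' The stimulus part is the cosine between the pattern's instar vector and
#' the activation (instar normalized by `max(norm, r)`, activation a unit
#' vector when all features are available), plus the lateral inhibition
#' term contributed by the previous winner. The free pattern's slot holds
#' the recruitment threshold `theta`, its nominal activation mean.
#'
#' @param layer a [pattern_layer()].
#' @param activation population activation vector.
#' @param j optional single pattern index; default all patterns.
#' @return net input(s).
#' @export
net_input <- function(layer, activation, j = NULL) {
  nets <- layer_nets(layer, activation)
  if (is.null(j)) nets else nets[j]
}

#' Noisy activation and winner selection
#'
#' Every trained pattern fires `Cauchy(gamma, net_j)`; the free pattern
#' fires `Cauchy(gamma, theta)`. The winner is the most active pattern
#' (ties, a measure-zero event, break to the lowest index). Draws come
#' from the layer-owned generator.
#'
#' @param layer a [pattern_layer()].
#' @param activation population activation vector.
#' @param include_free let the free pattern compete (it should whenever
#'   learning/recruitment is enabled).
#' @return list with `outputs` (noisy activations), `nets` (net inputs)
#'   and `winner` (index).
#' @export
activate <- function(layer, activation, include_free = TRUE) {
  nets <- layer_nets(layer, activation)
  P <- layer$P
  use <- if (include_free || P == 1L) seq_len(P) else seq_len(P - 1L)
  noise <- layer_rng_eval(layer, NULL, stats::rcauchy(length(use)))
  outputs <- rep(-Inf, P)
  outputs[use] <- nets[use] + layer$gamma * noise
  list(outputs = outputs, nets = nets, winner = which.max(outputs))
}

#' Winner-take-all instar update (and recruitment)
#'
#' Moves the winner's instar toward the activation:
#' `instar_k <- instar_k + eta * (activation - instar_k)`. If the winner
#' was the free pattern its instar norm rises above `r` (guaranteed by
#' `eta > r` for unit activations), it thereby becomes trained, and a
#' fresh zero-instar free pattern is appended.
#'
#' @param layer a [pattern_layer()].
#' @param activation population activation vector.
#' @param winner winner index from [activate()].
#' @return the layer, invisibly.
#' @export
train_winner <- function(layer, activation, winner) {
  k <- winner
  was_free <- k == free_index(layer)
  w <- layer$instar[k, ] + layer$eta * (activation - layer$instar[k, ])
  layer$instar[k, ] <- w
  layer$norms[k] <- sqrt(sum(w^2))
  if (was_free) {
    if (layer$P + 1L > layer$capacity) grow_layer(layer)
    layer$P <- layer$P + 1L                   # new free pattern, zero instar
    layer$instar[layer$P, ] <- 0
    layer$norms[layer$P] <- 0
    layer$lateral[layer$P, ] <- 0.5
    layer$lateral[, layer$P] <- 0.5
  }
  invisible(layer)
}

#' Batch update of lateral transition weights
#'
#' Called when a winner transition away from pattern `k` is detected: for
#' every other trained pattern `j`, the outgoing weight `w_kj` moves toward
#' the window-averaged closed-form probability that `j` out-competes `k`,
#' `1/2 + arctan((net_j - net_k) / (2 gamma)) / pi`, at rate `eta_l`. The
#' free pattern is excluded. The window holds the net inputs buffered since
#' the previous transition.
#'
#' @param layer a [pattern_layer()].
#' @param k the pattern being left (previous winner).
#' @return the layer, invisibly.
#' @export
update_lateral <- function(layer, k) {
  B <- layer$buf
  if (!nrow(B)) return(invisible(layer))
  Pb <- ncol(B) - 1L                          # trained patterns in the window
  if (Pb < 1L || k > Pb) { layer$buf <- matrix(NA_real_, 0L, 0L); return(invisible(layer)) }
  targets <- 0.5 + atan((B[, seq_len(Pb), drop = FALSE] - B[, k]) /
                          (2 * layer$gamma)) / pi
  tbar <- colMeans(targets)
  j <- setdiff(seq_len(Pb), k)
  w <- layer$lateral[k, j]
  layer$lateral[k, j] <- w + layer$eta_l * (tbar[j] - w)
  layer$buf <- matrix(NA_real_, 0L, 0L)
  invisible(layer)
}

#' Drive the pattern layer for one time step
#'
#' The per-frame driver used by training and observation: computes net
#' inputs, draws noisy activations, selects the winner, and — when
#' learning is enabled — buffers the net-input window, applies the lateral
#' batch update on winner transitions, and adapts (or recruits) the
#' winner's instar. With learning disabled the free pattern does not
#' compete (recruitment is part of learning) and no weight changes.
#'
#' @param layer a [pattern_layer()].
#' @param activation population activation vector.
#' @param learn enable instar/lateral learning and recruitment.
#' @return list with `winner`, `outputs`, `nets`.
#' @export
step_pattern_layer <- function(layer, activation, learn = TRUE) {
  act <- activate(layer, activation, include_free = learn)
  k_prev <- layer$prev_winner
  if (learn) {
    # buffer this step's nets (free slot included, carrying theta)
    if (ncol(layer$buf) != layer$P)
      layer$buf <- matrix(NA_real_, 0L, layer$P)
    layer$buf <- rbind(layer$buf, act$nets)
    if (!is.na(k_prev) && act$winner != k_prev && k_prev < free_index(layer))
      update_lateral(layer, k_prev)
    train_winner(layer, activation, act$winner)
  }
  layer$prev_winner <- act$winner
  layer$winner_count <- layer$winner_count + 1L
  act
}

#' Noise-driven free run of the pattern layer
#'
#' Simulates learned motion sequences without sensory input: all
#' population gains are zero, so trained patterns are driven purely by
#' Cauchy noise and the lateral inhibition from the previous winner. No
#' learning occurs and the free pattern does not compete.
#'
#' @param layer a trained [pattern_layer()].
#' @param steps number of time steps.
#' @return a `winner_record`: list with `winners` (integer sequence) and
#'   `histogram` (wins per trained pattern).
#' @export
free_run <- function(layer, steps) {
  if (n_trained(layer) < 1L) stop("free run requires at least one trained pattern")
  zero <- numeric(layer$n_input)
  winners <- integer(steps)
  for (s in seq_len(steps)) {
    act <- activate(layer, zero, include_free = FALSE)
    layer$prev_winner <- act$winner
    winners[s] <- act$winner
  }
  winner_record(winners, n_patterns = n_trained(layer))
}

#' Winner record
#' @param winners integer vector of winner indices per step.
#' @param conditions optional per-step condition labels.
#' @param n_patterns number of trained patterns (default max index).
#' @return an object of class `winner_record`.
#' @export
winner_record <- function(winners, conditions = NULL,
                          n_patterns = max(winners)) {
  structure(list(winners = as.integer(winners), conditions = conditions,
                 histogram = tabulate(winners, nbins = n_patterns)),
            class = "winner_record")
}

#' @export
print.winner_record <- function(x, ...) {
  cat(sprintf("<winner_record> %d steps, %d patterns seen\n",
              length(x$winners), sum(x$histogram > 0)))
  invisible(x)
}

## ----------------------------------------------------- serialization ------

#' Save / load a pattern layer snapshot
#'
#' Writes the full layer state (weights, counters, generator state) to a
#' single structured-text (JSON) file, for experiment checkpointing.
#'
#' @param layer a [pattern_layer()].
#' @param path file path.
#' @return `path` (save) or the restored `pattern_layer` (load).
#' @export
save_pattern_layer <- function(layer, path) {
  P <- layer$P
  obj <- list(
    n_input = layer$n_input, theta = layer$theta, gamma = layer$gamma,
    eta = layer$eta, eta_l = layer$eta_l, r = layer$r,
    compat_printed_inhibition = layer$compat_printed_inhibition,
    P = P, prev_winner = layer$prev_winner,
    winner_count = layer$winner_count,
    instar = layer$instar[seq_len(P), , drop = FALSE],
    lateral = layer$lateral[seq_len(P), seq_len(P), drop = FALSE],
    rng = layer$rng)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_pattern_layer
#' @export
load_pattern_layer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ly <- pattern_layer(n_input = obj$n_input, theta = obj$theta,
                      gamma = obj$gamma, eta = obj$eta, eta_l = obj$eta_l,
                      r = obj$r, seed = 0L,
                      compat_printed_inhibition = obj$compat_printed_inhibition)
  while (ly$capacity < obj$P) grow_layer(ly)
  ly$P <- as.integer(obj$P)
  ly$instar[seq_len(ly$P), ] <- as.matrix(obj$instar)
  ly$norms[seq_len(ly$P)] <- sqrt(rowSums(ly$instar[seq_len(ly$P), , drop = FALSE]^2))
  ly$lateral[seq_len(ly$P), seq_len(ly$P)] <- as.matrix(obj$lateral)
  ly$prev_winner <- if (is.null(obj$prev_winner)) NA_integer_ else
    as.integer(obj$prev_winner)
  ly$winner_count <- as.integer(obj$winner_count)
  ly$rng <- as.integer(obj$rng)
  ly
}
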