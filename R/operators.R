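# The spider-wasp variation operators: searching (two exploration moves),
# following/escaping, nesting, mating (uniform crossover), the linear
# population-reduction schedule and bound clipping.  All randomness goes
# through R's global RNG so a single set.seed() makes a run reproducible.

#' Operator parameters for the spider-wasp moves
#'
#' @param TR Hunting-vs-mating trade-off probability in \[0, 1\]: each
#'   individual mates with probability `TR`, otherwise hunts.
#' @param CR Crossover rate in \[0, 1\] for the mating operator.
#' @param C0 Initial value of the speed-controlling factor `C`, which decays
#'   linearly to 0 over the iteration budget.
#' @param escape_scale Scale of the follow/escape distance threshold
#'   `escape_scale * ||H - L|| * (1 - t / t_max)`: a chasing wasp switches
#'   to the escape move when its leader is further away than this.
#' @param k_vc_low,k_vc_high Bounds of the per-dimension contraction factor
#'   `vc` drawn by the escape move.
#' @return A list of class `swo_params`.
#' @export
swo_params <- function(TR = 0.3, CR = 0.3, C0 = 2,
                       escape_scale = 0.5, k_vc_low = -1, k_vc_high = 1) {
  stopifnot(TR >= 0, TR <= 1, CR >= 0, CR <= 1, C0 > 0,
            escape_scale >= 0, k_vc_low <= k_vc_high)
  structure(list(TR = TR, CR = CR, C0 = C0, escape_scale = escape_scale,
                 k_vc_low = k_vc_low, k_vc_high = k_vc_high),
            class = "swo_params")
}

#' Searching move: differential step between two population members
#'
#' `sw_i + mu1 * (sw_a - sw_b)` with `mu1 = rn * r1`, `rn ~ Normal(0, 1)`,
#' `r1 ~ Uniform(0, 1)` — a local search around a dropped prey position.
#' The caller is responsible for clipping the result to the bounds.
#'
#' @param sw_i,sw_a,sw_b Positions of equal dimension.
#' @param mu1 Step factor; drawn as above when `NULL` (tests may pin it).
#' @return The proposed position.
#' @export
explore_move <- function(sw_i, sw_a, sw_b, mu1 = NULL) {
  if (length(sw_a) != length(sw_i) || length(sw_b) != length(sw_i))
    stop("positions must have equal dimension")
  if (is.null(mu1)) mu1 <- stats::rnorm(1) * stats::runif(1)
  sw_i + mu1 * (sw_a - sw_b)
}

#' Searching move: bounded random jump
#'
#' `sw_c + mu2 * (L + r2 * (H - L))` with `mu2 = B * cos(2 * pi * l)`,
#' `B = 1 / (1 + exp(l))` and `l ~ Uniform(-2, -1)`; `r2 ~ Uniform(0, 1)` is
#' drawn fresh per call.
#'
#' @param sw_c Current position.
#' @param lower,upper Bound vectors (recycled to the position length).
#' @param l The auxiliary draw; `NULL` means sample it.
#' @return The proposed position.
#' @export
explore_jump <- function(sw_c, lower, upper, l = NULL) {
  if (is.null(l)) l <- stats::runif(1, -2, -1)
  mu2 <- cos(2 * pi * l) / (1 + exp(l))
  r2 <- stats::runif(1)
  sw_c + mu2 * (lower + r2 * (upper - lower))
}

#' Following move: chase the leader with a decaying speed factor
#'
#' `sw_i + C * (2 * r5 * (sw_a - sw_i))` with a per-dimension
#' `r5 ~ Uniform(0, 1)` vector and `C = C0 * (1 - t / t_max)`.
#'
#' @param sw_i Current position.
#' @param sw_a Leader position being chased.
#' @param t,t_max Current iteration (0-based) and iteration budget.
#' @param C0 Initial speed factor.
#' @param r5 Optional pinned uniform vector (tests).
#' @return The proposed position.
#' @export
follow_move <- function(sw_i, sw_a, t, t_max, C0 = 2, r5 = NULL) {
  stopifnot(t <= t_max)
  C <- C0 * (1 - t / t_max)
  if (is.null(r5)) r5 <- stats::runif(length(sw_i))
  sw_i + C * (2 * r5 * (sw_a - sw_i))
}

#' Escaping move: per-dimension random contraction
#'
#' `sw_i * vc` with `vc` drawn per dimension from
#' `Uniform(k_vc_low, k_vc_high)` — a bounded shrink/reflect of the position
#' relative to the origin, used when the prey is out of chasing range.
#'
#' @param sw_i Current position.
#' @param k_vc_low,k_vc_high Contraction interval bounds.
#' @param vc Optional pinned contraction vector (tests).
#' @return The proposed position.
#' @export
escape_move <- function(sw_i, k_vc_low = -1, k_vc_high = 1, vc = NULL) {
  if (is.null(vc)) vc <- stats::runif(length(sw_i), k_vc_low, k_vc_high)
  sw_i * vc
}

#' Nesting move: pull toward the best position found
#'
#' `sw_star + cos(2 * pi * l) * (sw_star - sw_i)` with a fresh
#' `l ~ Uniform(-2, -1)`; the result always lies on the line through `sw_i`
#' and `sw_star`, between the current position (`cos = -1`) and its
#' reflection through the leader (`cos = 1`).
#'
#' @param sw_star Leader (nest site) position.
#' @param sw_i Current position.
#' @param l Optional pinned draw (tests).
#' @return The proposed position.
#' @export
nest_move <- function(sw_star, sw_i, l = NULL) {
  if (length(sw_star) != length(sw_i))
    stop("positions must have equal dimension")
  if (is.null(l)) l <- stats::runif(1, -2, -1)
  sw_star + cos(2 * pi * l) * (sw_star - sw_i)
}

#' Mating operator: uniform crossover
#'
#' Each dimension of the offspring is taken from the partner `sw_m` with
#' probability `CR`, otherwise from `sw_i`.
#'
#' @param sw_i,sw_m Parent positions of equal dimension.
#' @param CR Crossover rate in \[0, 1\].
#' @return The offspring position.
#' @export
mate <- function(sw_i, sw_m, CR) {
  if (length(sw_i) != length(sw_m))
    stop("positions must have equal dimension")
  stopifnot(CR >= 0, CR <= 1)
  take <- stats::runif(length(sw_i)) < CR
  ifelse(take, sw_m, sw_i)
}

#' Linear population-reduction schedule
#'
#' Interpolates from the initial population size down to `N_min`:
#' `round(N_min + (N_init - N_min) * k)` with `k = (t_max - t) / t_max`,
#' rounded half away from zero and clamped to at least `N_min`.  The schedule
#' is non-increasing in `t` and deterministic (it interpolates from the
#' *initial* size, not the current one).
#'
#' @param N_init Initial population size.
#' @param N_min Minimum population size.
#' @param t,t_max Current iteration and iteration budget.
#' @return The target population size (integer).
#' @export
reduce_population <- function(N_init, N_min, t, t_max) {
  if (N_min > N_init) stop("N_min must not exceed the initial population size")
  stopifnot(t <= t_max, t_max > 0)
  k <- (t_max - t) / t_max
  x <- N_min + (N_init - N_min) * k
  max(N_min, as.integer(sign(x) * floor(abs(x) + 0.5)))  # round half away from 0
}

#' Project a position onto the search box
#'
#' @param position Numeric vector.
#' @param lower,upper Bound vectors.
#' @return The clipped position.
#' @export
clip_to_bounds <- function(position, lower, upper) {
  pmin(pmax(position, lower), upper)
}
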