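# Benchmark problem container plus the ZDT and DTLZ families in their
# canonical formulations (dimensions and forms from the standard benchmark
# literature), each with an analytic Pareto-front sampler.

#' Define a multiobjective minimization problem
#'
#' @param name Short identifier (used by [run_campaign()] and the CLI).
#' @param n_var Decision-space dimension D.
#' @param n_obj Number of objectives M (all minimized).
#' @param lower,upper Bound vectors of length `n_var` (scalars are recycled).
#' @param fn Evaluation function: numeric vector of length `n_var` ->
#'   numeric vector of length `n_obj`.  Must be deterministic.
#' @param fn_pop Optional vectorized evaluator: matrix (rows = individuals) ->
#'   matrix of objectives.  Defaults to row-wise application of `fn`.
#' @param true_front Optional sampler `function(n)` returning `n` points on
#'   the analytic Pareto front (objective space).
#' @param violation Optional constraint-violation function: position ->
#'   non-negative scalar (0 = feasible).
#' @return An object of class `moswo_problem`.
#' @export
moswo_problem <- function(name, n_var, n_obj, lower, upper, fn,
                          fn_pop = NULL, true_front = NULL, violation = NULL) {
  lower <- rep_len(as.numeric(lower), n_var)
  upper <- rep_len(as.numeric(upper), n_var)
  if (any(lower >= upper)) stop("lower bounds must be strictly below upper bounds")
  if (is.null(fn_pop))
    fn_pop <- function(X) t(apply(X, 1, fn))
  structure(list(name = name, n_var = as.integer(n_var),
                 n_obj = as.integer(n_obj), lower = lower, upper = upper,
                 fn = fn, fn_pop = fn_pop, true_front = true_front,
                 violation = violation),
            class = "moswo_problem")
}

#' @export
print.moswo_problem <- function(x, ...) {
  cat(sprintf("moswo_problem '%s': D = %d, M = %d%s%s\n", x$name, x$n_var,
              x$n_obj,
              if (is.null(x$true_front)) "" else ", analytic front available",
              if (is.null(x$violation)) "" else ", constrained"))
  invisible(x)
}

# row-wise sum of the tail variables, shared by the ZDT g functions
.tail_mean <- function(X, from) rowMeans(X[, from:ncol(X), drop = FALSE])

#' ZDT bi-objective benchmark problems
#'
#' Canonical formulations of ZDT1 (convex front), ZDT2 (concave), ZDT3
#' (disconnected), ZDT4 (multimodal) and ZDT6 (biased, concave).  Default
#' dimensions are 30 for ZDT1-3 and 10 for ZDT4 and ZDT6.
#'
#' @param which One of 1, 2, 3, 4, 6.
#' @param D Decision dimension (at least 2).
#' @return A `moswo_problem` with `M = 2` and an analytic front sampler.
#' @examples
#' p <- make_zdt(1)
#' p$fn(c(0.25, rep(0, 29)))  # on the true front: (0.25, 0.5)
#' @export
make_zdt <- function(which, D = if (which %in% c(4, 6)) 10L else 30L) {
  if (!which %in% c(1, 2, 3, 4, 6)) stop("unknown ZDT index: ", which)
  stopifnot(D >= 2)
  name <- paste0("zdt", which)
  lower <- rep(0, D); upper <- rep(1, D)
  if (which == 4) { lower[-1] <- -5; upper[-1] <- 5 }
  fn_pop <- switch(as.character(which),
    "1" = function(X) {
      f1 <- X[, 1]
      g <- 1 + 9 * .tail_mean(X, 2L)
      cbind(f1, g * (1 - sqrt(f1 / g)), deparse.level = 0)
    },
    "2" = function(X) {
      f1 <- X[, 1]
      g <- 1 + 9 * .tail_mean(X, 2L)
      cbind(f1, g * (1 - (f1 / g)^2), deparse.level = 0)
    },
    "3" = function(X) {
      f1 <- X[, 1]
      g <- 1 + 9 * .tail_mean(X, 2L)
      h <- 1 - sqrt(f1 / g) - (f1 / g) * sin(10 * pi * f1)
      cbind(f1, g * h, deparse.level = 0)
    },
    "4" = function(X) {
      f1 <- X[, 1]
      Z <- X[, -1, drop = FALSE]
      g <- 1 + 10 * (ncol(X) - 1) + rowSums(Z^2 - 10 * cos(4 * pi * Z))
      cbind(f1, g * (1 - sqrt(f1 / g)), deparse.level = 0)
    },
    "6" = function(X) {
      f1 <- 1 - exp(-4 * X[, 1]) * sin(6 * pi * X[, 1])^6
      g <- 1 + 9 * .tail_mean(X, 2L)^0.25
      cbind(f1, g * (1 - (f1 / g)^2), deparse.level = 0)
    })
  front <- switch(as.character(which),
    "1" = , "4" = function(n) {
      f1 <- seq(0, 1, length.out = n)
      cbind(f1, 1 - sqrt(f1), deparse.level = 0)
    },
    "2" = function(n) {
      f1 <- seq(0, 1, length.out = n)
      cbind(f1, 1 - f1^2, deparse.level = 0)
    },
    "3" = function(n) {
      # sample densely in f1, then keep the non-dominated segments
      f1 <- seq(0, 0.8518329, length.out = max(4L * n, 2000L))
      f2 <- 1 - sqrt(f1) - f1 * sin(10 * pi * f1)
      pts <- cbind(f1, f2, deparse.level = 0)
      pts <- pts[colSums(dominance_matrix(pts)) == 0, , drop = FALSE]
      pts[unique(round(seq(1, nrow(pts), length.out = n))), , drop = FALSE]
    },
    "6" = function(n) {
      f1min <- 1 - exp(-4 * 0.08145) * sin(6 * pi * 0.08145)^6  # ~0.2808
      f1 <- seq(f1min, 1, length.out = n)
      cbind(f1, 1 - f1^2, deparse.level = 0)
    })
  moswo_problem(name, D, 2L, lower, upper,
                fn = function(x) drop(fn_pop(matrix(x, nrow = 1))),
                fn_pop = fn_pop, true_front = front)
}

# evenly weighted lattice on the (M-1)-simplex with at least n points,
# thinned back to exactly n
.simplex_lattice <- function(n, M = 3L) {
  H <- 1L
  while (choose(H + M - 1L, M - 1L) < n) H <- H + 1L
  grid <- expand.grid(i = 0:H, j = 0:H)
  grid <- grid[grid$i + grid$j <= H, ]
  W <- cbind(grid$i, grid$j, H - grid$i - grid$j) / H
  W[unique(round(seq(1, nrow(W), length.out = n))), , drop = FALSE]
}

#' DTLZ three-objective benchmark problems
#'
#' Canonical formulations of DTLZ1-DTLZ7 with `M = 3` objectives and the
#' standard decision dimension `D = M - 1 + k` (k = 5 for DTLZ1, 10 for
#' DTLZ2-6, 20 for DTLZ7).  All decision variables are in \[0, 1\].
#'
#' @param which One of 1..7.
#' @param D Decision dimension; defaults to the standard value.
#' @return A `moswo_problem` with `M = 3` and an analytic front sampler.
#' @export
make_dtlz <- function(which,
                      D = 2L + switch(which, 5L, 10L, 10L, 10L, 10L, 10L, 20L)) {
  if (!which %in% 1:7) stop("unknown DTLZ index: ", which)
  M <- 3L
  stopifnot(D >= M)
  name <- paste0("dtlz", which)
  kidx <- M:D      # distance variables
  g1 <- function(Z)  # Rastrigin-style distance function (DTLZ1/3)
    100 * (ncol(Z) + rowSums((Z - 0.5)^2 - cos(20 * pi * (Z - 0.5))))
  g2 <- function(Z) rowSums((Z - 0.5)^2)
  sphere <- function(T1, T2, g)    # theta in [0, pi/2]
    cbind((1 + g) * cos(T1) * cos(T2),
          (1 + g) * cos(T1) * sin(T2),
          (1 + g) * sin(T1), deparse.level = 0)
  fn_pop <- switch(which,
    function(X) {  # DTLZ1: linear front f1+f2+f3 = 0.5
      g <- g1(X[, kidx, drop = FALSE])
      x1 <- X[, 1]; x2 <- X[, 2]
      0.5 * cbind(x1 * x2 * (1 + g), x1 * (1 - x2) * (1 + g),
                  (1 - x1) * (1 + g), deparse.level = 0)
    },
    function(X) {  # DTLZ2: unit-sphere front
      g <- g2(X[, kidx, drop = FALSE])
      sphere(X[, 1] * pi / 2, X[, 2] * pi / 2, g)
    },
    function(X) {  # DTLZ3: sphere front, multimodal g
      g <- g1(X[, kidx, drop = FALSE])
      sphere(X[, 1] * pi / 2, X[, 2] * pi / 2, g)
    },
    function(X) {  # DTLZ4: sphere front, biased density (alpha = 100)
      g <- g2(X[, kidx, drop = FALSE])
      sphere(X[, 1]^100 * pi / 2, X[, 2]^100 * pi / 2, g)
    },
    function(X) {  # DTLZ5: degenerate curve on the sphere
      g <- g2(X[, kidx, drop = FALSE])
      t2 <- pi / (4 * (1 + g)) * (1 + 2 * g * X[, 2])
      sphere(X[, 1] * pi / 2, t2, g)
    },
    function(X) {  # DTLZ6: degenerate curve, slow-converging g
      g <- rowSums(X[, kidx, drop = FALSE]^0.1)
      t2 <- pi / (4 * (1 + g)) * (1 + 2 * g * X[, 2])
      sphere(X[, 1] * pi / 2, t2, g)
    },
    function(X) {  # DTLZ7: 2^(M-1) disconnected patches
      g <- 1 + 9 * rowMeans(X[, kidx, drop = FALSE])
      f1 <- X[, 1]; f2 <- X[, 2]
      h <- M - f1 / (1 + g) * (1 + sin(3 * pi * f1)) -
               f2 / (1 + g) * (1 + sin(3 * pi * f2))
      cbind(f1, f2, (1 + g) * h, deparse.level = 0)
    })
  front <- switch(which,
    function(n) 0.5 * .simplex_lattice(n),                       # DTLZ1
    function(n) {                                                # DTLZ2-4
      W <- .simplex_lattice(n)
      W / sqrt(rowSums(W^2))
    },
    function(n) {
      W <- .simplex_lattice(n)
      W / sqrt(rowSums(W^2))
    },
    function(n) {
      W <- .simplex_lattice(n)
      W / sqrt(rowSums(W^2))
    },
    function(n) {                                                # DTLZ5/6 curve
      t1 <- seq(0, pi / 2, length.out = n)
      cbind(cos(t1) / sqrt(2), cos(t1) / sqrt(2), sin(t1), deparse.level = 0)
    },
    function(n) {
      t1 <- seq(0, pi / 2, length.out = n)
      cbind(cos(t1) / sqrt(2), cos(t1) / sqrt(2), sin(t1), deparse.level = 0)
    },
    function(n) {                                                # DTLZ7
      # f3 = 6 - q(f1) - q(f2) with q(t) = t * (1 + sin(3*pi*t)) is separable,
      # so the front is the product of the per-coordinate non-dominated sets
      # {t : q(t) > q(t') for all t' < t} (the four disconnected patches)
      tg <- seq(0, 1, length.out = 4000L)
      q <- tg * (1 + sin(3 * pi * tg))
      admissible <- q > cummax(c(-Inf, q[-length(q)]))
      ta <- tg[admissible]
      m <- max(2L, ceiling(sqrt(n)))
      t1 <- ta[unique(round(seq(1, length(ta), length.out = m)))]
      f1 <- rep(t1, each = length(t1))
      f2 <- rep(t1, times = length(t1))
      qf <- function(t) t * (1 + sin(3 * pi * t))
      pts <- cbind(f1, f2, 6 - qf(f1) - qf(f2), deparse.level = 0)
      pts[unique(round(seq(1, nrow(pts), length.out = min(n, nrow(pts))))), ,
          drop = FALSE]
    })
  moswo_problem(name, D, M, 0, 1,
                fn = function(x) drop(fn_pop(matrix(x, nrow = 1))),
                fn_pop = fn_pop, true_front = front)
}

#' One-dimensional bi-objective test problem with a closed-form front
#'
#' `f(x) = (x^2, (x - 2)^2)` on \[-5, 5\]: the Pareto set is `x` in \[0, 2\]
#' and the front the curve `{(t^2, (t - 2)^2)}`.  Used for engine sanity
#' checks.
#'
#' @return A `moswo_problem`.
#' @export
make_schaffer <- function() {
  fn_pop <- function(X) cbind(X[, 1]^2, (X[, 1] - 2)^2, deparse.level = 0)
  moswo_problem("schaffer", 1L, 2L, -5, 5,
                fn = function(x) c(x[1]^2, (x[1] - 2)^2),
                fn_pop = fn_pop,
                true_front = function(n) {
                  t <- seq(0, 2, length.out = n)
                  cbind(t^2, (t - 2)^2, deparse.level = 0)
                })
}

#' Resolve a benchmark problem by name
#'
#' @param name e.g. `"zdt1"`, `"dtlz7"`, `"schaffer"`.
#' @return A `moswo_problem`.
#' @export
get_problem <- function(name) {
  name <- tolower(name)
  if (grepl("^zdt[12346]$", name))
    return(make_zdt(as.integer(substring(name, 4))))
  if (grepl("^dtlz[1-7]$", name))
    return(make_dtlz(as.integer(substring(name, 5))))
  if (name == "schaffer") return(make_schaffer())
  stop("unknown problem: ", name)
}

#' Sample the analytic Pareto front of a benchmark problem
#'
#' Points are spread uniformly in the front's natural parameterization and
#' are mutually non-dominated.
#'
#' @param problem A `moswo_problem` with an analytic front.
#' @param n Number of points (at least 2).
#' @return A matrix of objective vectors.
#' @export
sample_true_front <- function(problem, n) {
  stopifnot(inherits(problem, "moswo_problem"), n >= 2)
  if (is.null(problem$true_front))
    stop("problem '", problem$name, "' has no analytic Pareto front")
  problem$true_front(as.integer(n))
}
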