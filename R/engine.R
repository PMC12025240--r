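# The main optimizer loop: initialize, branch among the spider-wasp
# behaviors per individual, evaluate, sort, update the external archive,
# shrink the population on schedule, stop when the evaluation budget is
# spent.

#' Control parameters for a MOSWO run
#'
#' @param pop_size Initial population size N (benchmark protocol default 100).
#' @param pop_min Minimum population size reached by the linear reduction
#'   schedule; set equal to `pop_size` to disable reduction.
#' @param budget Maximum number of objective-function evaluations.
#' @param archive_size External archive capacity.
#' @param reduction_period Apply the reduction schedule every k-th iteration.
#' @param params Operator parameters, see [swo_params()].
#' @param seed Optional integer seed; when non-`NULL`, [moswo()] calls
#'   `set.seed(seed)` so a run is bit-reproducible.
#' @param history Record a per-iteration trace (evaluations used, archive
#'   size, population size, ideal point)?
#' @return A list of class `moswo_control`.
#' @export
moswo_control <- function(pop_size = 100L, pop_min = 20L, budget = 10000L,
                          archive_size = 100L, reduction_period = 1L,
                          params = swo_params(), seed = NULL,
                          history = TRUE) {
  stopifnot(pop_size >= pop_min, pop_min >= 2, budget > 0,
            archive_size >= 1, reduction_period >= 1,
            inherits(params, "swo_params"))
  structure(list(pop_size = as.integer(pop_size),
                 pop_min = as.integer(pop_min),
                 budget = as.integer(budget),
                 archive_size = as.integer(archive_size),
                 reduction_period = as.integer(reduction_period),
                 params = params, seed = seed, history = isTRUE(history)),
            class = "moswo_control")
}

#' Select a leader from the archive
#'
#' Binary tournament on crowding distance: two members are drawn uniformly at
#' random and the one with the larger crowding distance (the less crowded,
#' hence more diversity-preserving leader) wins; exact ties are broken
#' uniformly at random.
#'
#' @param archive A non-empty `moswo_archive`.
#' @return The row index of the selected member.
#' @export
select_leader <- function(archive) {
  n <- NROW(archive$objectives)
  if (!n) stop("archive is empty")
  if (n == 1L) return(1L)
  ij <- sample.int(n, 2L)
  ci <- archive$crowding[ij[1L]]; cj <- archive$crowding[ij[2L]]
  if (ci > cj) ij[1L]
  else if (cj > ci) ij[2L]
  else ij[sample.int(2L, 1L)]
}

# violation of a whole population (0 when the problem is unconstrained)
.viol_pop <- function(problem, X) {
  if (is.null(problem$violation)) return(numeric(nrow(X)))
  vapply(seq_len(nrow(X)), function(i) problem$violation(X[i, ]), numeric(1))
}

# per-dimension gate: take each coordinate of the proposal with probability
# CR, but always at least one (an identity proposal would waste the
# evaluation)
.gate <- function(xi, y, CR) {
  z <- mate(xi, y, CR)
  if (all(z == xi)) {
    j <- sample.int(length(xi), 1L)
    z[j] <- y[j]
  }
  z
}

.eval_pop <- function(problem, X) {
  F <- problem$fn_pop(X)
  if (is.null(dim(F))) F <- matrix(F, nrow = nrow(X))
  if (anyNA(F) || any(!is.finite(F)))
    stop("objective function returned NaN/Inf at a candidate position; ",
         "run aborted (problem '", problem$name, "')")
  F
}

#' Run the multiobjective spider-wasp optimizer
#'
#' Initializes `pop_size` individuals uniformly within the bounds, then
#' iterates: each individual either mates (uniform crossover with a partner
#' from the archive or the population, probability `TR`) or hunts.  A
#' hunting wasp explores with probability `1 - t/t_max` (differential step
#' or bounded random jump) and otherwise exploits an archive leader chosen
#' by crowding-distance tournament: it follows the leader with the decaying
#' speed factor, escapes (a single-coordinate random contraction, chosen
#' with probability proportional to the coordinate magnitude) when the
#' follow/escape coin or the distance threshold says the prey is out of
#' range, or performs the nesting pull toward the leader.  Search and
#' exploitation proposals are recombined with the parent per dimension at
#' rate `CR` so selection can accept single-coordinate improvements.
#' Offspring are clipped to the bounds and evaluated; parents and offspring
#' are pooled and the best `N` survive by (rank, crowding) order with exact
#' clones demoted, while every evaluated candidate also feeds the external
#' non-dominated archive.  The population shrinks linearly to `pop_min`
#' and the run stops when the evaluation budget is exhausted.
#'
#' @param problem A [moswo_problem()].
#' @param control A [moswo_control()] (elements can also be overridden via
#'   `...`, e.g. `moswo(p, budget = 5000, seed = 1)`).
#' @param ... Named overrides for `moswo_control()` fields.
#' @return An object of class `moswo_result`: the final archive (the Pareto
#'   front estimate), the evaluation count, a per-iteration history, the
#'   control echo and the seed.
#' @examples
#' res <- moswo(make_schaffer(), budget = 2000, seed = 1)
#' head(pareto_front(res))
#' @export
moswo <- function(problem, control = moswo_control(), ...) {
  stopifnot(inherits(problem, "moswo_problem"))
  dots <- list(...)
  if (length(dots)) {
    ctl <- unclass(control)
    prm <- names(dots) %in% names(ctl$params)
    for (nm in names(dots)[prm]) ctl$params[[nm]] <- dots[[nm]]
    for (nm in names(dots)[!prm]) ctl[[nm]] <- dots[[nm]]
    control <- do.call(moswo_control,
                       ctl[intersect(names(formals(moswo_control)), names(ctl))])
  }
  if (!is.null(control$seed)) set.seed(control$seed)
  p <- control$params
  N0 <- control$pop_size
  budget <- control$budget
  if (budget < N0)
    stop("budget must cover at least one generation (pop_size evaluations)")
  L <- problem$lower; H <- problem$upper
  D <- problem$n_var
  diagLH <- sqrt(sum((H - L)^2))
  reduce <- control$pop_min < N0
  # iteration horizon: with the shrinking population the average generation
  # costs (N0 + pop_min)/2 evaluations, so this horizon lets the schedules
  # (speed factor, exploration probability, escape threshold, population
  # size) reach their endpoints as the budget runs out
  t_max <- if (reduce) max(1L, round(2 * budget / (N0 + control$pop_min)))
           else max(1L, budget %/% N0)

  X <- matrix(stats::runif(N0 * D), N0, D)
  X <- sweep(sweep(X, 2, H - L, "*"), 2, L, "+")
  F <- .eval_pop(problem, X)
  V <- .viol_pop(problem, X)
  evals <- N0
  archive <- new_archive(control$archive_size)
  archive <- update_archive(archive, X, F, V)

  hist_rows <- if (control$history) vector("list", t_max + 16L) else NULL
  t <- 0L
  while (evals < budget) {
    t <- t + 1L
    k_lin <- max(0, (t_max - t) / t_max)     # shared linear schedule
    thr <- p$escape_scale * diagLH * k_lin
    N <- nrow(X)
    n_new <- min(N, budget - evals)
    idx <- seq_len(n_new)
    Xoff <- X
    have_archive <- NROW(archive$objectives) > 0L
    for (i in idx) {
      xi <- X[i, ]
      if (stats::runif(1) < p$TR) {                       # mating
        # partner drawn from the archive when available: its members carry
        # the best-converged coordinates, so crossover transfers good
        # coordinate values across the population
        if (have_archive && stats::runif(1) < 0.5) {
          m <- sample.int(NROW(archive$objectives), 1L)
          y <- mate(xi, archive$positions[m, ], p$CR)
        } else {
          m <- sample.int(N, 1L)
          y <- mate(xi, X[m, ], p$CR)
        }
      } else if (stats::runif(1) < k_lin) {               # searching
        if (stats::runif(1) > stats::runif(1)) {
          ab <- sample.int(N, 2L)
          y <- explore_move(xi, X[ab[1L], ], X[ab[2L], ])
        } else {
          y <- explore_jump(xi, L, H)
        }
        # recombine the search step with the parent so that exploration can
        # advance one coordinate at a time (essential on separable
        # multimodal landscapes)
        y <- .gate(xi, y, p$CR)
      } else {                                            # hunting a leader
        star <- if (have_archive)
          archive$positions[select_leader(archive), ]
        else X[which.min(non_dominated_sort(F, V)$rank), ]
        if (stats::runif(1) < 0.75) {
          # chase the prey, or escape when the coin says so / the prey is
          # out of chasing range
          if (stats::runif(1) > stats::runif(1) &&
              sqrt(sum((xi - star)^2)) <= thr) {
            y <- .gate(xi, follow_move(xi, star, min(t, t_max), t_max, p$C0),
                       p$CR)
          } else {
            # coordinate-wise escape: contract one random dimension so that
            # a successful basin jump is not vetoed by simultaneous damage
            # in the remaining coordinates
            y <- xi
            w_esc <- abs(xi) + 1e-12
            j <- sample.int(D, 1L, prob = w_esc)
            y[j] <- escape_move(xi, p$k_vc_low, p$k_vc_high)[j]
          }
        } else {
          y <- .gate(xi, nest_move(star, xi), p$CR)
        }
      }
      Xoff[i, ] <- clip_to_bounds(y, L, H)
    }
    Foff <- .eval_pop(problem, Xoff[idx, , drop = FALSE])
    Voff <- .viol_pop(problem, Xoff[idx, , drop = FALSE])
    evals <- evals + n_new
    archive <- update_archive(archive, Xoff[idx, , drop = FALSE], Foff, Voff)
    # elitist environmental selection over parents and offspring: keep the
    # best N by (rank, crowding); N follows the linear reduction schedule
    Ntgt <- if (reduce && t %% control$reduction_period == 0L)
      reduce_population(N0, control$pop_min, min(t, t_max), t_max)
    else nrow(X)
    pool_X <- rbind(X, Xoff[idx, , drop = FALSE])
    pool_F <- rbind(F, Foff)
    pool_V <- c(V, Voff)
    s <- non_dominated_sort(pool_F, pool_V)
    cd <- numeric(nrow(pool_F))
    for (fr in s$fronts) cd[fr] <- crowding_distance(pool_F[fr, , drop = FALSE])
    # exact clones rank behind every distinct solution: without this a
    # rank-1 corner point can flood the population with copies of itself
    # on concave fronts and extinguish diversity
    dup <- duplicated(pool_F)
    keep <- order(dup, s$rank, -cd)[seq_len(Ntgt)]
    X <- pool_X[keep, , drop = FALSE]
    F <- pool_F[keep, , drop = FALSE]
    V <- pool_V[keep]
    if (control$history)
      hist_rows[[t]] <- c(iter = t, evals = evals,
                          pop_size = nrow(X),
                          archive_size = NROW(archive$objectives),
                          stats::setNames(apply(archive$objectives, 2, min),
                                          paste0("best_f", seq_len(problem$n_obj))))
  }

  history <- if (control$history)
    as.data.frame(do.call(rbind, hist_rows[!vapply(hist_rows, is.null, TRUE)]))
  else NULL
  structure(list(archive = archive, evals = evals, t = t, t_max = t_max,
                 history = history, control = control, seed = control$seed,
                 problem = problem$name,
                 n_var = problem$n_var, n_obj = problem$n_obj),
            class = "moswo_result")
}

#' Extract the Pareto-front estimate of a run
#'
#' @param x A `moswo_result`.
#' @return Matrix of the archive's objective vectors.
#' @export
pareto_front <- function(x) {
  stopifnot(inherits(x, "moswo_result"))
  x$archive$objectives
}

#' Extract the Pareto-set estimate (decision vectors) of a run
#'
#' @param x A `moswo_result`.
#' @return Matrix of the archive's decision vectors.
#' @export
pareto_set <- function(x) {
  stopifnot(inherits(x, "moswo_result"))
  x$archive$positions
}

#' @export
print.moswo_result <- function(x, ...) {
  cat(sprintf("MOSWO run on '%s' (D = %d, M = %d)\n", x$problem, x$n_var, x$n_obj))
  cat(sprintf("  evaluations: %d, iterations: %d, archive: %d member(s)\n",
              x$evals, x$t, NROW(x$archive$objectives)))
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
summary.moswo_result <- function(object, ...) {
  front <- pareto_front(object)
  cat(sprintf("MOSWO run on '%s': %d evaluations, %d archive member(s)\n",
              object$problem, object$evals, nrow(front)))
  cat("Objective summary of the archive:\n")
  colnames(front) <- paste0("f", seq_len(ncol(front)))
  print(summary(as.data.frame(front)))
  invisible(object)
}

#' @export
as.data.frame.moswo_result <- function(x, ...) {
  X <- pareto_set(x); F <- pareto_front(x)
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(F) <- paste0("f", seq_len(ncol(F)))
  cbind(as.data.frame(X), as.data.frame(F),
        crowding = x$archive$crowding)
}

#' Plot the archive of a run in objective space
#'
#' Scatter of the first two objectives (and, for three objectives, a second
#' panel of objectives 1 and 3), optionally with the analytic front overlaid.
#'
#' @param x A `moswo_result`.
#' @param true_front Optional matrix of analytic-front points to overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.moswo_result <- function(x, true_front = NULL, ...) {
  F <- pareto_front(x)
  op <- NULL
  if (ncol(F) >= 3L) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(F[, 1], F[, 2], xlab = "f1", ylab = "f2",
                 main = paste("Archive:", x$problem), pch = 19, cex = 0.6, ...)
  if (!is.null(true_front))
    graphics::points(true_front[, 1], true_front[, 2], col = "grey60",
                     pch = ".", cex = 2)
  if (ncol(F) >= 3L) {
    graphics::plot(F[, 1], F[, 3], xlab = "f1", ylab = "f3",
                   main = paste("Archive:", x$problem), pch = 19, cex = 0.6, ...)
    if (!is.null(true_front))
      graphics::points(true_front[, 1], true_front[, 3], col = "grey60",
                       pch = ".", cex = 2)
  }
  invisible(x)
}
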