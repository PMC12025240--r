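# Independent brute-force oracles used to validate the fast implementations.
# These deliberately use naive scalar loops so that they share no code path
# with the package internals.

# plain pairwise dominance check
oracle_dominates <- function(a, b) {
  no_worse <- TRUE
  better <- FALSE
  for (m in seq_along(a)) {
    if (a[m] > b[m]) no_worse <- FALSE
    if (a[m] < b[m]) better <- TRUE
  }
  no_worse && better
}

# front partition by repeated peeling of the non-dominated subset
oracle_fronts <- function(obj) {
  n <- nrow(obj)
  remaining <- seq_len(n)
  fronts <- list()
  while (length(remaining)) {
    nd <- logical(length(remaining))
    for (ii in seq_along(remaining)) {
      dominated <- FALSE
      for (jj in seq_along(remaining)) {
        if (ii != jj &&
            oracle_dominates(obj[remaining[jj], ], obj[remaining[ii], ])) {
          dominated <- TRUE
          break
        }
      }
      nd[ii] <- !dominated
    }
    fronts[[length(fronts) + 1L]] <- remaining[nd]
    remaining <- remaining[!nd]
  }
  fronts
}

# indices of the non-dominated rows
oracle_nondominated <- function(obj) oracle_fronts(obj)[[1L]]

# Monte-Carlo hypervolume estimate with binomial standard error
oracle_hv_mc <- function(pts, ref, n_samples = 1e5) {
  M <- length(ref)
  lo <- apply(pts, 2, min)
  U <- matrix(stats::runif(n_samples * M), n_samples, M)
  S <- sweep(sweep(U, 2, ref - lo, "*"), 2, lo, "+")
  covered <- logical(n_samples)
  for (i in seq_len(nrow(pts))) {
    dom <- rep(TRUE, n_samples)
    for (m in seq_len(M)) dom <- dom & pts[i, m] <= S[, m]
    covered <- covered | dom
  }
  box <- prod(ref - lo)
  p <- mean(covered)
  list(hv = box * p, se = box * sqrt(p * (1 - p) / n_samples))
}

# naive scalar evaluation of the canonical ZDT formulas
oracle_zdt <- function(which, x) {
  D <- length(x)
  if (which == 6) {
    f1 <- 1 - exp(-4 * x[1]) * (sin(6 * pi * x[1]))^6
  } else {
    f1 <- x[1]
  }
  if (which == 4) {
    g <- 1 + 10 * (D - 1)
    for (i in 2:D) g <- g + x[i]^2 - 10 * cos(4 * pi * x[i])
  } else if (which == 6) {
    g <- 1 + 9 * (sum(x[-1]) / (D - 1))^0.25
  } else {
    g <- 1 + 9 * sum(x[-1]) / (D - 1)
  }
  h <- switch(as.character(which),
              "1" = 1 - sqrt(f1 / g),
              "2" = 1 - (f1 / g)^2,
              "3" = 1 - sqrt(f1 / g) - (f1 / g) * sin(10 * pi * f1),
              "4" = 1 - sqrt(f1 / g),
              "6" = 1 - (f1 / g)^2)
  c(f1, g * h)
}

# naive scalar evaluation of the canonical DTLZ formulas (M = 3)
oracle_dtlz <- function(which, x) {
  M <- 3
  D <- length(x)
  xm <- x[M:D]
  g1 <- 100 * (length(xm) + sum((xm - 0.5)^2 - cos(20 * pi * (xm - 0.5))))
  g2 <- sum((xm - 0.5)^2)
  if (which == 1) {
    g <- g1
    return(0.5 * c(x[1] * x[2] * (1 + g),
                   x[1] * (1 - x[2]) * (1 + g),
                   (1 - x[1]) * (1 + g)))
  }
  if (which %in% c(2, 3)) {
    g <- if (which == 2) g2 else g1
    t1 <- x[1] * pi / 2; t2 <- x[2] * pi / 2
  } else if (which == 4) {
    g <- g2
    t1 <- x[1]^100 * pi / 2; t2 <- x[2]^100 * pi / 2
  } else if (which %in% c(5, 6)) {
    g <- if (which == 5) g2 else sum(xm^0.1)
    t1 <- x[1] * pi / 2
    t2 <- pi / (4 * (1 + g)) * (1 + 2 * g * x[2])
  } else {
    g <- 1 + 9 * mean(xm)
    h <- M - x[1] / (1 + g) * (1 + sin(3 * pi * x[1])) -
             x[2] / (1 + g) * (1 + sin(3 * pi * x[2]))
    return(c(x[1], x[2], (1 + g) * h))
  }
  (1 + g) * c(cos(t1) * cos(t2), cos(t1) * sin(t2), sin(t1))
}

# random-search baseline: evaluate `budget` uniform points, return the
# non-dominated subset (at most `cap` by random thinning)
random_search_front <- function(problem, budget, cap = 200L) {
  X <- matrix(stats::runif(budget * problem$n_var), budget, problem$n_var)
  X <- sweep(sweep(X, 2, problem$upper - problem$lower, "*"), 2,
             problem$lower, "+")
  F <- problem$fn_pop(X)
  keep <- rep(TRUE, nrow(F))
  o <- order(F[, 1])
  F <- F[o, , drop = FALSE]
  # quick staircase filter for 2-D; generic filter otherwise
  if (ncol(F) == 2L) {
    best <- cummin(F[, 2])
    nd <- F[, 2] <= best & !duplicated(best)
    F <- F[nd, , drop = FALSE]
  } else {
    nd <- vapply(seq_len(nrow(F)), function(i) {
      !any(vapply(seq_len(nrow(F)), function(j)
        j != i && all(F[j, ] <= F[i, ]) && any(F[j, ] < F[i, ]), logical(1)))
    }, logical(1))
    F <- F[nd, , drop = FALSE]
  }
  if (nrow(F) > cap) F <- F[sample.int(nrow(F), cap), , drop = FALSE]
  F
}
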