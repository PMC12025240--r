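# Pareto dominance, non-dominated sorting, crowding distance and the external
# archive.  Objectives are always minimized internally; populations are plain
# numeric matrices (one row per individual).

#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` (minimization convention) when `a` is no worse than `b`
#' in every objective and strictly better in at least one.
#'
#' @param a,b Numeric vectors of equal length with finite entries.
#' @return A single logical.
#' @examples
#' dominates(c(1, 2), c(2, 2))  # TRUE
#' dominates(c(1, 3), c(3, 1))  # FALSE (incomparable)
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b))
    stop("objective vectors must have equal length")
  all(a <= b) && any(a < b)
}

# Pairwise constrained-dominance matrix: dom[i, j] is TRUE when i dominates j.
# Constraint dominance: a feasible point dominates any infeasible one; among
# infeasible points the smaller violation wins; objective dominance applies
# only between feasible points.
dominance_matrix <- function(obj, violation = NULL) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (m in seq_len(ncol(obj))) {
    fm <- obj[, m]
    le <- le & outer(fm, fm, "<=")
    lt <- lt | outer(fm, fm, "<")
  }
  dom <- le & lt
  if (!is.null(violation) && any(violation > 0)) {
    feas <- violation <= 0
    dom <- (dom & outer(feas, feas, "&")) |
      outer(feas, !feas, "&") |
      (outer(!feas, !feas, "&") & outer(violation, violation, "<"))
  }
  diag(dom) <- FALSE
  dom
}

#' Non-dominated sorting
#'
#' Partitions a population into successive fronts F1, F2, ... by iteratively
#' peeling off the mutually non-dominated members (domination counting).
#' Feasibility is folded in through constraint dominance: feasible points
#' always rank ahead of infeasible ones, and infeasible points are ordered by
#' their violation.
#'
#' @param obj Numeric matrix of objectives, one row per individual.
#' @param violation Optional non-negative violation per row (0 = feasible).
#' @return A list with `fronts` (list of integer index vectors) and `rank`
#'   (integer vector, 1 = first front).
#' @export
non_dominated_sort <- function(obj, violation = NULL) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n == 0L) stop("population must be non-empty")
  dom <- dominance_matrix(obj, violation)
  n_dom <- colSums(dom)           # how many points dominate each column
  rank <- integer(n)
  fronts <- list()
  current <- which(n_dom == 0)
  k <- 0L
  while (length(current)) {
    k <- k + 1L
    rank[current] <- k
    fronts[[k]] <- current
    n_dom[current] <- NA_integer_ # assigned
    if (length(current) < n) {
      n_dom <- n_dom - colSums(dom[current, , drop = FALSE])
      current <- which(!is.na(n_dom) & n_dom == 0)
    } else current <- integer(0)
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance along a front
#'
#' Per-objective density estimate: for each objective the front is sorted
#' (stable, index as tie-break), the first and last points receive infinite
#' distance, and interior points accumulate the normalized gap between their
#' two neighbours, `(f[i+1] - f[i-1]) / (max - min)`.  A degenerate objective
#' (max equal to min) contributes nothing.  Fronts of size two or less are
#' all-boundary, hence all infinite.
#'
#' @param obj Numeric matrix of the objectives of one front (assumed mutually
#'   non-dominated; not enforced).
#' @return Numeric vector of crowding distances (may contain `Inf`).
#' @export
crowding_distance <- function(obj) {
  obj <- as.matrix(obj)
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  cd <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    fm <- obj[, m]
    o <- order(fm, seq_len(n))    # stable; ties broken by original index
    cd[o[c(1L, n)]] <- Inf
    rng <- fm[o[n]] - fm[o[1L]]
    if (rng > 0) {
      inner <- o[2:(n - 1L)]
      cd[inner] <- cd[inner] + (fm[o[3:n]] - fm[o[1:(n - 2L)]]) / rng
    }
  }
  cd
}

#' Create an empty external archive
#'
#' The archive is the evolving Pareto-front estimate: a bounded store of
#' mutually non-dominated solutions, truncated by crowding distance when it
#' overflows.
#'
#' @param capacity Maximum number of members retained after an update.
#' @return An object of class `moswo_archive`.
#' @export
new_archive <- function(capacity = 100L) {
  stopifnot(is.numeric(capacity), capacity >= 1)
  structure(
    list(positions = NULL, objectives = NULL, violation = numeric(0),
         crowding = numeric(0), capacity = as.integer(capacity)),
    class = "moswo_archive")
}

#' Update an archive with candidate solutions
#'
#' Merges the candidates with the current members, drops exact duplicate
#' objective vectors (first-inserted wins), keeps the non-dominated subset of
#' the union, and — if over capacity — removes the lowest-crowding member one
#' at a time, recomputing crowding after each removal.
#'
#' @param archive A `moswo_archive`.
#' @param positions Matrix of candidate decision vectors (rows).
#' @param objectives Matrix of the corresponding objective vectors.
#' @param violation Optional candidate constraint violations (default 0).
#' @return The updated `moswo_archive`.
#' @export
update_archive <- function(archive, positions, objectives, violation = NULL) {
  stopifnot(inherits(archive, "moswo_archive"))
  if (is.null(positions) || NROW(positions) == 0L) return(archive)
  positions <- as.matrix(positions)
  objectives <- as.matrix(objectives)
  if (is.null(violation)) violation <- numeric(nrow(objectives))
  X <- rbind(archive$positions, positions)
  F <- rbind(archive$objectives, objectives)
  V <- c(archive$violation, violation)
  keep <- !duplicated(F)
  X <- X[keep, , drop = FALSE]; F <- F[keep, , drop = FALSE]; V <- V[keep]
  nd <- which(colSums(dominance_matrix(F, V)) == 0)
  X <- X[nd, , drop = FALSE]; F <- F[nd, , drop = FALSE]; V <- V[nd]
  while (nrow(F) > archive$capacity) {
    cd <- crowding_distance(F)
    drop1 <- which.min(cd)        # deterministic: first minimum
    X <- X[-drop1, , drop = FALSE]; F <- F[-drop1, , drop = FALSE]; V <- V[-drop1]
  }
  archive$positions <- X
  archive$objectives <- F
  archive$violation <- V
  archive$crowding <- crowding_distance(F)
  archive
}

#' @export
print.moswo_archive <- function(x, ...) {
  n <- NROW(x$objectives)
  cat("External Pareto archive:", n, "member(s), capacity", x$capacity, "\n")
  if (n) {
    cat("Objective ranges:\n")
    print(apply(x$objectives, 2, range))
  }
  invisible(x)
}

#' Write an archive to a delimiter-separated file
#'
#' One row per member: run id, member id, the decision-vector columns, the
#' objective columns, the dominance rank (1 inside an archive) and the
#' crowding distance.  A header row is always written.
#'
#' @param archive A `moswo_archive` (or a `moswo_result`, whose archive is used).
#' @param path Output file path.
#' @param run_id Identifier recorded in the `run` column.
#' @param sep Field separator (default comma).
#' @return Invisibly, the data frame written.
#' @export
write_archive <- function(archive, path, run_id = 1L, sep = ",") {
  if (inherits(archive, "moswo_result")) archive <- archive$archive
  stopifnot(inherits(archive, "moswo_archive"))
  X <- archive$positions; F <- archive$objectives
  n <- NROW(F)
  df <- data.frame(run = rep(run_id, n), id = seq_len(n))
  if (n) {
    pos <- as.data.frame(X); names(pos) <- paste0("x", seq_len(ncol(X)))
    obj <- as.data.frame(F); names(obj) <- paste0("f", seq_len(ncol(F)))
    df <- cbind(df, pos, obj,
                rank = rep(1L, n),
                crowding = archive$crowding)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Read an archive written by [write_archive()]
#'
#' @param path File path.
#' @param sep Field separator.
#' @return A `moswo_archive` with capacity equal to the number of rows read.
#' @export
read_archive <- function(path, sep = ",") {
  df <- utils::read.table(path, sep = sep, header = TRUE)
  xc <- grep("^x[0-9]+$", names(df), value = TRUE)
  fc <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (!length(fc)) stop("no objective columns (f1, f2, ...) found in ", path)
  a <- new_archive(max(1L, nrow(df)))
  a$positions <- as.matrix(df[xc])
  a$objectives <- as.matrix(df[fc])
  a$violation <- numeric(nrow(df))
  a$crowding <- if ("crowding" %in% names(df)) df$crowding else crowding_distance(a$objectives)
  a
}
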