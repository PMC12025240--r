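# Quality indicators for Pareto-front approximations: inverted generational
# distance, exact hypervolume in two and three dimensions, the spread
# (Delta) diversity metric, and summaries over repeated runs.

# squared Euclidean cross-distances between the rows of A (n x M) and B (m x M)
.cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Inverted generational distance
#'
#' Mean, over the reference points, of the Euclidean distance to the nearest
#' point of the approximation set.  Lower is better; 0 means every reference
#' point is matched exactly.
#'
#' @param approx Matrix of objective vectors approximating the front.
#' @param reference Matrix of reference (true-front) objective vectors.
#' @return A non-negative scalar.
#' @examples
#' igd(rbind(c(0, 0)), rbind(c(0, 0), c(1, 1)))  # sqrt(2) / 2
#' @export
igd <- function(approx, reference) {
  approx <- as.matrix(approx); reference <- as.matrix(reference)
  if (!nrow(approx) || !nrow(reference)) stop("point sets must be non-empty")
  if (ncol(approx) != ncol(reference)) stop("objective counts differ")
  mean(sqrt(apply(.cross_dist2(reference, approx), 1, min)))
}

# exact 2-D hypervolume by a sweep over the points sorted by f1
.hv2 <- function(pts, ref) {
  keep <- pts[, 1] < ref[1] & pts[, 2] < ref[2]
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) return(0)
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  # non-dominated staircase: strictly decreasing f2
  best <- cummin(pts[, 2])
  keep <- pts[, 2] <= best & !duplicated(best)
  pts <- pts[keep, , drop = FALSE]
  x <- c(pts[, 1], ref[1])
  sum((x[-1] - x[-length(x)]) * (ref[2] - pts[, 2]))
}

# exact 3-D hypervolume by slicing along the third objective
.hv3 <- function(pts, ref) {
  keep <- pts[, 1] < ref[1] & pts[, 2] < ref[2] & pts[, 3] < ref[3]
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) return(0)
  o <- order(pts[, 3])
  pts <- pts[o, , drop = FALSE]
  z <- c(pts[, 3], ref[3])
  vol <- 0
  for (i in seq_len(nrow(pts))) {
    dz <- z[i + 1L] - z[i]
    if (dz > 0)
      vol <- vol + dz * .hv2(pts[seq_len(i), 1:2, drop = FALSE], ref[1:2])
  }
  vol
}

#' Exact hypervolume of an approximation set
#'
#' Lebesgue measure of the union of the axis-aligned boxes spanned by each
#' point and the reference point (minimization; only points that dominate the
#' reference point contribute).  Computed exactly: by a sweep for two
#' objectives, by slicing for three.
#'
#' @param approx Matrix of objective vectors.
#' @param ref_point Reference point (length 2 or 3).
#' @return A non-negative scalar; 0 if no point dominates `ref_point`.
#' @examples
#' hypervolume(rbind(c(0, 0)), c(1, 1))  # 1 (unit box)
#' @export
hypervolume <- function(approx, ref_point) {
  approx <- as.matrix(approx)
  M <- length(ref_point)
  if (ncol(approx) != M) stop("reference point dimension must match objectives")
  if (M == 2L) .hv2(approx, ref_point)
  else if (M == 3L) .hv3(approx, ref_point)
  else stop("exact hypervolume implemented for 2 or 3 objectives only")
}

#' Spread (Delta) diversity metric
#'
#' For two objectives, the classical Delta metric: with the approximation
#' sorted along the front, `d_i` the consecutive Euclidean gaps, and `d_f`,
#' `d_l` the gaps to the two true-front extreme points,
#' `Delta = (d_f + d_l + sum |d_i - dbar|) / (d_f + d_l + (n - 1) * dbar)`.
#' For three objectives the generalized variant is used: `d_i` become
#' nearest-neighbour distances and the extreme terms sum the distance from
#' each supplied extreme point to its nearest approximation point.
#' 0 indicates a perfectly uniform distribution that reaches the extremes;
#' larger is worse.
#'
#' @param approx Matrix of objective vectors (any order; sorted internally).
#' @param extremes Matrix of the true front's extreme points (2 rows for
#'   `M = 2`, typically `M` rows for `M = 3`).
#' @return A non-negative scalar; `Inf` (with a warning) for fewer than 3
#'   points.
#' @export
spread <- function(approx, extremes) {
  approx <- as.matrix(approx); extremes <- as.matrix(extremes)
  n <- nrow(approx)
  if (n < 3L) {
    warning("spread is undefined for fewer than 3 points")
    return(Inf)
  }
  if (ncol(approx) == 2L) {
    o <- order(approx[, 1], approx[, 2])
    A <- approx[o, , drop = FALSE]
    e <- extremes[order(extremes[, 1]), , drop = FALSE]
    d <- sqrt(rowSums((A[-1, , drop = FALSE] - A[-n, , drop = FALSE])^2))
    df <- sqrt(sum((e[1, ] - A[1, ])^2))
    dl <- sqrt(sum((e[2, ] - A[n, ])^2))
    dbar <- mean(d)
    (df + dl + sum(abs(d - dbar))) / (df + dl + (n - 1) * dbar)
  } else {
    D2 <- .cross_dist2(approx, approx)
    diag(D2) <- Inf
    d <- sqrt(apply(D2, 1, min))           # nearest-neighbour distances
    de <- sqrt(apply(.cross_dist2(extremes, approx), 1, min))
    dbar <- mean(d)
    (sum(de) + sum(abs(d - dbar))) / (sum(de) + n * dbar)
  }
}

#' Extreme points of a front sample
#'
#' For each objective, the point of the set attaining its maximum — the
#' corner points used by the spread metric.
#'
#' @param front Matrix of objective vectors.
#' @return A matrix with one row per objective.
#' @export
front_extremes <- function(front) {
  front <- as.matrix(front)
  front[apply(front, 2, which.max), , drop = FALSE]
}

#' Normalize objectives by ideal and nadir points
#'
#' Affine map sending the ideal point to 0 and the nadir to 1 per objective,
#' as used before hypervolume computation with the (1.1, ..., 1.1) reference
#' point.
#'
#' @param obj Matrix of objective vectors.
#' @param ideal,nadir Vectors of per-objective minima and maxima (typically
#'   of a dense analytic front sample).
#' @return The normalized matrix.
#' @export
normalize_objectives <- function(obj, ideal, nadir) {
  obj <- as.matrix(obj)
  rng <- nadir - ideal
  if (any(rng <= 0)) stop("nadir must exceed ideal in every objective")
  sweep(sweep(obj, 2, ideal), 2, rng, "/")
}

#' Indicator panel for one archive against an analytic front
#'
#' Computes IGD (raw objective scale), hypervolume (after ideal/nadir
#' normalization by the front sample, reference point 1.1 per objective) and
#' spread (raw scale, against the front's extreme points).
#'
#' @param objectives Matrix of archive objective vectors.
#' @param front Matrix sampled from the analytic front (see
#'   [sample_true_front()]).
#' @param hv_ref Normalized reference-point coordinate (default 1.1).
#' @return Named numeric vector with `igd`, `hv`, `spread`, `size`.
#' @export
benchmark_metrics <- function(objectives, front, hv_ref = 1.1) {
  objectives <- as.matrix(objectives)
  ideal <- apply(front, 2, min)
  nadir <- apply(front, 2, max)
  c(igd = igd(objectives, front),
    hv = hypervolume(normalize_objectives(objectives, ideal, nadir),
                     rep(hv_ref, ncol(objectives))),
    spread = spread(objectives, front_extremes(front)),
    size = nrow(objectives))
}

#' Summarize per-run metric values
#'
#' @param per_run A data frame (or matrix) with one row per run and one
#'   column per metric; an optional `seed` column is echoed, not summarized.
#' @return An object of class `moswo_metric_report`: the per-run table plus
#'   mean, standard deviation (sample), min and max per metric.
#' @export
summarize_runs <- function(per_run) {
  per_run <- as.data.frame(per_run)
  if (!nrow(per_run)) stop("at least one run is required")
  seeds <- per_run$seed
  vals <- per_run[setdiff(names(per_run), "seed")]
  summary <- data.frame(
    metric = names(vals),
    mean = vapply(vals, mean, numeric(1)),
    sd = vapply(vals, function(v) if (length(v) > 1) stats::sd(v) else 0,
                numeric(1)),
    min = vapply(vals, min, numeric(1)),
    max = vapply(vals, max, numeric(1)),
    row.names = NULL)
  structure(list(per_run = per_run, summary = summary, seeds = seeds),
            class = "moswo_metric_report")
}

#' @export
print.moswo_metric_report <- function(x, ...) {
  cat("Metric summary over", nrow(x$per_run), "run(s):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
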