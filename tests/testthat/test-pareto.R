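test_that("dominance follows the minimization convention", {
  expect_false(dominates(c(1, 1), c(1, 1)))        # identity never dominates
  expect_true(dominates(c(1, 2), c(2, 2)))
  expect_false(dominates(c(2, 2), c(1, 2)))
  expect_false(dominates(c(1, 3), c(3, 1)))        # incomparable both ways
  expect_false(dominates(c(3, 1), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("non-dominated sorting handles the elementary cases", {
  s <- non_dominated_sort(matrix(c(0.3, 0.7), 1))
  expect_equal(s$rank, 1L)
  expect_equal(s$fronts, list(1L))

  obj <- rbind(c(0, 1), c(1, 0), c(1, 1))
  s <- non_dominated_sort(obj)
  expect_equal(sort(s$fronts[[1]]), c(1L, 2L))
  expect_equal(s$fronts[[2]], 3L)
  expect_equal(s$rank, c(1L, 1L, 2L))

  expect_error(non_dominated_sort(matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("sorting matches the brute-force peeling oracle on random populations", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(3:60, 1)
    M <- sample(2:3, 1)
    obj <- matrix(round(runif(n * M), 2), n, M)  # rounding forces ties
    s <- non_dominated_sort(obj)
    o <- oracle_fronts(obj)
    expect_equal(length(s$fronts), length(o))
    for (k in seq_along(o))
      expect_equal(sort(s$fronts[[k]]), sort(o[[k]]))
  }
})

test_that("dominance implies strictly smaller rank", {
  set.seed(7)
  obj <- matrix(runif(80), 40, 2)
  s <- non_dominated_sort(obj)
  for (i in 1:40) for (j in 1:40) {
    if (dominates(obj[i, ], obj[j, ]))
      expect_lt(s$rank[i], s$rank[j])
  }
})

test_that("crowding distance matches the hand-computed bi-objective case", {
  front <- rbind(c(0, 1), c(0.5, 0.5), c(1, 0))
  cd <- crowding_distance(front)
  expect_equal(cd, c(Inf, 2, Inf))
})

test_that("crowding handles boundaries, tiny fronts and degenerate objectives", {
  expect_equal(crowding_distance(rbind(c(0, 1), c(1, 0))), c(Inf, Inf))
  expect_equal(crowding_distance(matrix(c(0.2, 0.8), 1)), Inf)
  # degenerate objective (constant column) contributes nothing
  front <- cbind(c(0, 0.25, 0.5, 1), 1)
  cd <- crowding_distance(front)
  expect_equal(cd[2:3], c(0.5, 0.75))
  expect_equal(cd[c(1, 4)], c(Inf, Inf))
})

test_that("crowding is permutation invariant and scale invariant", {
  set.seed(11)
  f1 <- sort(runif(12))
  front <- cbind(f1, 1 - sqrt(f1))
  cd <- crowding_distance(front)
  perm <- sample(12)
  expect_equal(crowding_distance(front[perm, ]), cd[perm])
  # affine rescaling of one objective leaves normalized gaps unchanged
  scaled <- front
  scaled[, 2] <- 100 + 7 * scaled[, 2]
  expect_equal(crowding_distance(scaled), cd)
})

test_that("archive updates keep exactly the non-dominated union", {
  a <- new_archive(100)
  a <- update_archive(a, matrix(0.5), matrix(c(0, 1), 1))
  expect_equal(nrow(a$objectives), 1L)

  # dominance replacement with an identical first objective
  a <- update_archive(a, matrix(0.6), matrix(c(0, 0.5), 1))
  expect_equal(unname(a$objectives[1, ]), c(0, 0.5))
  expect_equal(nrow(a$objectives), 1L)

  expect_identical(update_archive(a, NULL, NULL), a)  # empty candidate set
})

test_that("archive matches the brute-force oracle on a long candidate stream", {
  set.seed(99)
  all_F <- matrix(runif(1000), 500, 2)
  all_X <- matrix(runif(500), 500, 1)
  a <- new_archive(100)
  for (batch in split(1:500, rep(1:10, each = 50)))
    a <- update_archive(a, all_X[batch, , drop = FALSE],
                        all_F[batch, , drop = FALSE])
  # no member may dominate another
  n <- nrow(a$objectives)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j)
      expect_false(oracle_dominates(a$objectives[i, ], a$objectives[j, ]))
  }
  expect_lte(n, 100)
  # every oracle-non-dominated point of the whole stream that fits the
  # capacity must be in the archive when there was no truncation
  nd <- oracle_nondominated(all_F)
  if (length(nd) <= 100) {
    expect_equal(n, length(nd))
    expect_equal(sort(a$objectives[, 1]), sort(all_F[nd, 1]))
  }
})

test_that("archive truncation respects capacity and keeps boundary points", {
  set.seed(4)
  f1 <- runif(400)
  F <- cbind(f1, 1 - sqrt(f1))       # all mutually non-dominated
  a <- new_archive(50)
  a <- update_archive(a, matrix(runif(400), 400, 1), F)
  expect_equal(nrow(a$objectives), 50L)
  expect_equal(min(a$objectives[, 1]), min(f1))  # extremes survive truncation
  expect_equal(max(a$objectives[, 1]), max(f1))
})

test_that("exact duplicate objective vectors are not stored twice", {
  a <- new_archive(10)
  a <- update_archive(a, rbind(0.1, 0.9, 0.5), rbind(c(0, 1), c(0, 1), c(1, 0)))
  expect_equal(nrow(a$objectives), 2L)
  expect_equal(a$positions[1, 1], 0.1)           # first-inserted duplicate wins
})

test_that("constraint dominance: feasible beats infeasible, lower violation wins", {
  obj <- rbind(c(0, 0), c(5, 5), c(9, 9))
  viol <- c(2, 0, 1)
  s <- non_dominated_sort(obj, viol)
  expect_equal(s$rank, c(3L, 1L, 2L))            # feasible first despite objectives
  a <- new_archive(10)
  a <- update_archive(a, matrix(1:3, 3), obj, viol)
  expect_equal(nrow(a$objectives), 1L)
  expect_equal(unname(a$objectives[1, ]), c(5, 5))
})

test_that("archive serialization round-trips through the delimited format", {
  set.seed(21)
  res <- moswo(make_schaffer(), budget = 600, seed = 21, pop_size = 30,
               pop_min = 10, archive_size = 25)
  path <- withr::local_tempfile(fileext = ".csv")
  df <- write_archive(res, path, run_id = 7)
  expect_true(file.exists(path))
  expect_named(df, c("run", "id", "x1", "f1", "f2", "rank", "crowding"))
  back <- read_archive(path)
  expect_equal(back$objectives, unname(res$archive$objectives),
               ignore_attr = TRUE)
  expect_equal(back$positions, unname(res$archive$positions),
               ignore_attr = TRUE)
})
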