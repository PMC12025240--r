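# stub prediction model with pinned outputs, used to check the objective
# arithmetic independently of any fitted cohort
stub_fit <- function(effect = 85, grade = 1.5, auc = 1200, cmax_ratio = 0.135) {
  structure(list(
    predict_auc = function(dose_a, dose_b) rep(auc, length(dose_a)),
    predict_effect = function(a) rep(effect, length(a)),
    predict_grade = function(a) rep(grade, length(a)),
    cmax_ratio = cmax_ratio, n = 10), class = "pkpd_fit")
}

test_that("cohort generation is deterministic and schema-valid", {
  c1 <- generate_cohort(10, seed = 1)
  c2 <- generate_cohort(10, seed = 1)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  big <- generate_cohort(400, seed = 2)
  expect_true(all(big$effect >= 0 & big$effect <= 100))
  expect_true(all(big$toxicity %in% 1:3))
  expect_true(all(big$cmax > 0 & big$auc > 0 & big$tmax > 0 & big$ti > 0))
  expect_false(anyDuplicated(big$patient_id) > 0)
})

test_that("generated effect increases with exposure", {
  co <- generate_cohort(500, seed = 3)
  expect_gt(cor(co$auc, co$effect, method = "spearman"), 0.5)
})

test_that("a printed-style PK/PD row parses to a valid record", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("Patient ID","Drug A Dose (mg)","Drug B Dose (mg)","Cmax (ng/mL)",
          "Tmax (h)","AUC (ng.h/mL)","Therapeutic Effect (%)",
          "Toxicity Level (Grade)","Therapeutic Index (TI)", sep = ","),
    "001,100,50,150,2,1200,85,1,1200"), path)
  co <- read_cohort(path)
  expect_equal(co$dose_a, 100)
  expect_equal(co$dose_b, 50)
  expect_equal(co$auc, 1200)
  expect_equal(co$effect, 85)
  expect_equal(co$toxicity, 1L)
  expect_equal(co$ti, 1200)
})

test_that("cohort files round-trip and tolerate shuffled, case-mangled headers", {
  co <- generate_cohort(25, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  for (cc in names(back)) expect_equal(back[[cc]], co[[cc]], ignore_attr = TRUE)

  # shuffle and lower-case the columns
  raw <- utils::read.csv(path, check.names = FALSE)
  shuffled <- raw[, sample(ncol(raw))]
  names(shuffled) <- tolower(names(shuffled))
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(shuffled, path2, row.names = FALSE)
  back2 <- read_cohort(path2)
  expect_equal(back2$auc, co$auc, ignore_attr = TRUE)
})

test_that("malformed cohort files fail with row/column diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  co <- generate_cohort(5, seed = 5)
  write_cohort(co, path)
  txt <- readLines(path)
  writeLines(txt[-1], path)                      # drop the header line
  expect_error(read_cohort(path), "missing column")
  parts <- strsplit(txt[3], ",")[[1]]
  parts[2] <- "oops"
  txt[3] <- paste(parts, collapse = ",")
  writeLines(txt, path)
  expect_error(read_cohort(path), "row")
  expect_error(read_cohort("no/such/file.csv"), "not found")
})

test_that("objective arithmetic matches the scoring formulas", {
  w <- regimen_weights(e_max = 100, w1 = 1, duration_t50 = 0)
  # AE = 100 - effect: stubbed effect 85 -> AE 15 -> efficacy 85
  expect_equal(efficacy(regimen(100, 12, 50, 4), stub_fit(effect = 85), w), 85)
  # zero adverse effect recovers the ceiling
  expect_equal(efficacy(regimen(100, 12, 50, 4), stub_fit(effect = 100), w), 100)
  # safety: S_max = 10, w2 = 2, AR = 1.5 -> 7
  w2 <- regimen_weights(s_max = 10, w2 = 2)
  expect_equal(safety(regimen(100, 12, 50, 4), stub_fit(grade = 1.5), w2), 7)
  expect_equal(safety(regimen(100, 12, 50, 4), stub_fit(grade = 0),
                      regimen_weights(s_max = 10)), 10)
  # cost: unit prices 1, one dose total, no fixed cost
  wc <- regimen_weights(c_max = 1000, w3 = 1, price_a = 1, price_b = 1,
                        weekly_cost = 0)
  expect_equal(cost(regimen(100, 168, 50, 1), wc), 1000 - 150)
  expect_equal(cost(regimen(0, 24, 0, 1), wc), 1000)
  # cost deduction scales with w3 and grows with duration
  wc2 <- regimen_weights(c_max = 1000, w3 = 2, price_a = 1, price_b = 1,
                         weekly_cost = 0)
  expect_equal(1000 - cost(regimen(100, 168, 50, 1), wc2), 300)
  expect_lt(cost(regimen(100, 12, 50, 8), wc), cost(regimen(100, 12, 50, 2), wc))
})

test_that("efficacy decreases in adverse effect; safety deduction scales", {
  w <- regimen_weights(duration_t50 = 0)
  e <- vapply(c(95, 85, 60), function(eff)
    efficacy(regimen(100, 12, 50, 4), stub_fit(effect = eff), w), numeric(1))
  expect_true(all(diff(e) < 0))
})

test_that("regimen encoding round-trips through the unit cube", {
  b <- regimen_bounds()
  expect_equal(unname(encode_regimen(regimen(50, 6, 0, 1), b)), rep(0, 4))
  expect_equal(unname(encode_regimen(regimen(200, 24, 150, 12), b)), rep(1, 4))
  expect_equal(unname(encode_regimen(regimen(125, 15, 75, 6.5), b)), rep(0.5, 4))
  set.seed(31)
  for (i in 1:100) {
    u <- runif(4)
    reg <- decode_regimen(u, b)
    expect_lt(max(abs(encode_regimen(reg, b) - u)), 1e-12)
  }
  expect_warning(encode_regimen(regimen(300, 12, 50, 4), b), "clipping")
  expect_error(regimen_bounds(lower = c(10, 6, 0, 1), upper = c(5, 24, 150, 12)),
               "infeasible")
})

test_that("regimen problem is deterministic and constraint-aware", {
  co <- generate_cohort(200, seed = 6)
  w <- regimen_weights()
  prob <- regimen_problem(co, w)
  x <- c(150, 12, 75, 6)
  expect_identical(prob$fn(x), prob$fn(x))
  # a regimen pushed over the exposure ceiling is infeasible
  hot <- c(200, 6, 150, 12)
  cold <- c(50, 24, 0, 1)
  expect_gt(prob$violation(hot), 0)
  expect_equal(prob$violation(cold), 0)
  # constraint dominance: feasible regimens rank ahead of infeasible ones
  s <- non_dominated_sort(rbind(prob$fn(hot), prob$fn(cold)),
                          c(prob$violation(hot), prob$violation(cold)))
  expect_lt(s$rank[2], s$rank[1])
})

test_that("degenerate weights collapse the front onto the cost axis", {
  co <- generate_cohort(150, seed = 7)
  w0 <- regimen_weights(w1 = 0, w2 = 0)
  prob <- regimen_problem(co, w0)
  set.seed(7)
  X <- cbind(runif(50, 50, 200), runif(50, 6, 24), runif(50, 0, 150),
             runif(50, 1, 12))
  F <- prob$fn_pop(X)
  expect_true(all(F[, 1] == F[1, 1]))  # efficacy objective constant
  expect_true(all(F[, 2] == F[1, 2]))  # safety objective constant
  # the non-dominated subset is exactly the cost minimizer(s)
  nd <- oracle_nondominated(F)
  expect_equal(sort(nd), sort(which(F[, 3] == min(F[, 3]))))
})

test_that("fitted models recover the generating Emax parameters", {
  co <- generate_cohort(600, seed = 8)
  fit <- fit_pkpd(co)
  p <- attr(co, "provenance")
  # exposure slopes within 10% of the generator's
  cf <- coef(stats::lm(auc ~ dose_a + dose_b, data = co))
  expect_lt(abs(cf[["dose_a"]] - p$ka) / p$ka, 0.1)
  # fitted effect curve close to the generating curve over the data range
  aucs <- seq(900, 2000, by = 50)
  truth <- p$emax * aucs^p$hill / (p$ec50^p$hill + aucs^p$hill)
  expect_lt(max(abs(fit$predict_effect(aucs) - truth)), 3)
  # expected grade is monotone in exposure
  g <- fit$predict_grade(aucs)
  expect_true(all(diff(g) >= -1e-8))
  ti <- therapeutic_index(fit)
  expect_gt(ti, 1)
})

test_that("optimized best-efficacy regimen matches a grid-search oracle", {
  co <- generate_cohort(300, seed = 9)
  w <- regimen_weights()
  prob <- regimen_problem(co, w)
  res <- moswo(prob, budget = 3000, seed = 9, pop_size = 60, pop_min = 30,
               history = FALSE)
  rep <- regimen_report(res, w)
  best <- rep[which.max(rep$efficacy), ]
  # grid-search oracle over the feasible decision box
  grid <- expand.grid(dose_a = seq(50, 200, length.out = 16),
                      interval = seq(6, 24, length.out = 16),
                      dose_b = seq(0, 150, length.out = 16),
                      duration = seq(1, 12, length.out = 12))
  G <- as.matrix(grid)
  FG <- prob$fn_pop(G)
  feas <- vapply(seq_len(nrow(G)), function(i) prob$violation(G[i, ]) == 0,
                 logical(1))
  opt_eff <- w$e_max - min(FG[feas, 1])
  expect_lt(abs(best$efficacy - opt_eff) / abs(opt_eff), 0.05)
})

test_that("end-to-end regimen pipeline spans the cost range", {
  co <- generate_cohort(250, seed = 10)
  w <- regimen_weights()
  prob <- regimen_problem(co, w)
  res <- moswo(prob, budget = 4000, seed = 10, pop_size = 80, pop_min = 40,
               history = FALSE)
  F <- pareto_front(res)
  for (i in seq_len(nrow(F))) for (j in seq_len(nrow(F))) {
    if (i != j) expect_false(oracle_dominates(F[i, ], F[j, ]))
  }
  # archive spans at least 80% of the cost range between the cheapest
  # feasible corner and the most effective feasible corner (grid search)
  grid <- as.matrix(expand.grid(seq(50, 200, length.out = 12),
                                seq(6, 24, length.out = 12),
                                seq(0, 150, length.out = 12),
                                seq(1, 12, length.out = 8)))
  FG <- prob$fn_pop(grid)
  feas <- vapply(seq_len(nrow(grid)), function(i) prob$violation(grid[i, ]) == 0,
                 logical(1))
  cost_cheap <- min(FG[feas, 3])
  cost_rich <- FG[feas, 3][which.min(FG[feas, 1])]
  span <- diff(range(F[, 3])) / (cost_rich - cost_cheap)
  expect_gt(span, 0.8)
})
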