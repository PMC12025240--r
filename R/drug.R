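# Drug-regimen design layer: a synthetic PK/PD cohort generator with a
# dose -> exposure -> effect/toxicity structure, cohort file I/O, fitted
# exposure/response/toxicity models, the efficacy/safety/cost objectives and
# the 3-objective regimen optimization problem.
#
# A regimen decision vector has four slots: dose of drug A (mg per
# administration), dosing interval (h), dose of co-drug B (mg per
# administration) and treatment duration (weeks).

# canonical internal column names and their file header names
.cohort_cols <- c(patient_id = "Patient ID",
                  dose_a = "Drug A Dose (mg)",
                  dose_b = "Drug B Dose (mg)",
                  cmax = "Cmax (ng/mL)",
                  tmax = "Tmax (h)",
                  auc = "AUC (ng.h/mL)",
                  effect = "Therapeutic Effect (%)",
                  toxicity = "Toxicity Level (Grade)",
                  ti = "Therapeutic Index (TI)")

.norm_header <- function(x) gsub("[^a-z]", "", tolower(x))

#' Parameters of the synthetic PK/PD cohort generator
#'
#' Defaults are calibrated once to the magnitudes of a typical two-drug
#' antiviral PK/PD screening table: per-dose AUC is linear in the two doses
#' (`auc0 + ka * doseA + kb * doseB`) with lognormal inter-patient
#' variability, Cmax is proportional to AUC, the therapeutic effect follows
#' an Emax (Hill) model of AUC with additive Gaussian noise, and the
#' toxicity grade (1 = mild, 2 = moderate, 3 = severe) thresholds the
#' realized AUC.  The therapeutic index is reported as the exposure margin
#' per toxicity grade, `AUC / grade`.
#'
#' @param dose_a_levels Drug A dose grid (mg).
#' @param dose_b_levels Drug B dose grid (mg).
#' @param auc0,ka,kb Exposure model: mean AUC (ng*h/mL) intercept and
#'   per-mg slopes for drugs A and B.
#' @param auc_cv Lognormal coefficient of variation of AUC between patients.
#' @param cmax_ratio Mean Cmax/AUC ratio (1/h scale).
#' @param cmax_cv Lognormal CV of the Cmax ratio.
#' @param tmax_range Uniform range of Tmax (h).
#' @param emax,ec50,hill Emax response model: maximum effect (%), AUC giving
#'   half-maximal effect, Hill coefficient.
#' @param effect_sd Additive noise SD on the effect (%).
#' @param tox_thresholds Two increasing AUC cutoffs separating grades 1/2
#'   and 2/3.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(dose_a_levels = c(100, 150, 200),
                          dose_b_levels = seq(50, 150, by = 25),
                          auc0 = 770, ka = 3.75, kb = 1.5, auc_cv = 0.07,
                          cmax_ratio = 0.135, cmax_cv = 0.05,
                          tmax_range = c(1.5, 2.5),
                          emax = 100, ec50 = 550, hill = 2, effect_sd = 2.5,
                          tox_thresholds = c(1375, 1500)) {
  stopifnot(length(tox_thresholds) == 2, diff(tox_thresholds) > 0,
            emax > 0, emax <= 100, ec50 > 0, hill > 0, auc_cv >= 0)
  structure(as.list(environment()), class = "cohort_params")
}

#' Generate a synthetic PK/PD cohort
#'
#' Each patient receives a dose pair sampled from the configured grids; the
#' exposure, effect and toxicity columns are then built by the generative
#' model described in [cohort_params()].  All invariants of the schema hold
#' by construction: effect in \[0, 100\], grade in \{1, 2, 3\}, positive
#' concentrations, unique patient ids.
#'
#' @param n Number of patients (at least 1).
#' @param params A [cohort_params()].
#' @param seed Optional integer seed for reproducibility.
#' @return A data frame of class `pkpd_cohort` with columns `patient_id`,
#'   `dose_a`, `dose_b`, `cmax`, `tmax`, `auc`, `effect`, `toxicity`, `ti`;
#'   the generator parameters are attached as attribute `provenance`.
#' @export
generate_cohort <- function(n, params = cohort_params(), seed = NULL) {
  stopifnot(n >= 1, inherits(params, "cohort_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- params
  dose_a <- sample(p$dose_a_levels, n, replace = TRUE)
  dose_b <- sample(p$dose_b_levels, n, replace = TRUE)
  sdlog <- sqrt(log(1 + p$auc_cv^2))
  auc <- (p$auc0 + p$ka * dose_a + p$kb * dose_b) *
    stats::rlnorm(n, -sdlog^2 / 2, sdlog)
  sdlog_c <- sqrt(log(1 + p$cmax_cv^2))
  cmax <- auc * p$cmax_ratio * stats::rlnorm(n, -sdlog_c^2 / 2, sdlog_c)
  tmax <- stats::runif(n, p$tmax_range[1], p$tmax_range[2])
  effect <- p$emax * auc^p$hill / (p$ec50^p$hill + auc^p$hill) +
    stats::rnorm(n, 0, p$effect_sd)
  effect <- pmin(100, pmax(0, effect))
  toxicity <- 1L + (auc > p$tox_thresholds[1]) + (auc > p$tox_thresholds[2])
  cohort <- data.frame(
    patient_id = sprintf("%03d", seq_len(n)),
    dose_a = dose_a, dose_b = dose_b,
    cmax = round(cmax, 1), tmax = round(tmax, 2), auc = round(auc, 1),
    effect = round(effect, 1), toxicity = toxicity,
    ti = round(auc / toxicity))
  attr(cohort, "provenance") <- p
  class(cohort) <- c("pkpd_cohort", "data.frame")
  cohort
}

#' Write a cohort to a delimiter-separated file
#'
#' Uses the standard PK/PD table header names (patient ID, doses, Cmax,
#' Tmax, AUC, therapeutic effect, toxicity grade, therapeutic index).
#'
#' @param cohort A `pkpd_cohort` (or compatible data frame).
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `cohort`.
#' @export
write_cohort <- function(cohort, path, sep = ",") {
  df <- as.data.frame(cohort)[names(.cohort_cols)]
  names(df) <- unname(.cohort_cols)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(cohort)
}

#' Read a PK/PD cohort table
#'
#' Header-driven, order- and case-insensitive parsing of the standard
#' column set; malformed numeric cells are rejected with row-numbered
#' diagnostics and a missing column is a schema error.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A `pkpd_cohort` data frame.
#' @export
read_cohort <- function(path, sep = ",") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  have <- .norm_header(names(raw))
  want <- .norm_header(.cohort_cols)
  pos <- match(want, have)
  if (anyNA(pos))
    stop("cohort file is missing column(s): ",
         paste(.cohort_cols[is.na(pos)], collapse = ", "))
  df <- raw[pos]
  names(df) <- names(.cohort_cols)
  num_cols <- setdiff(names(.cohort_cols), "patient_id")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & nzchar(df[[cc]]))
    if (length(bad))
      stop("non-numeric value in column '", .cohort_cols[[cc]], "' at row(s) ",
           paste(bad, collapse = ", "))
    if (anyNA(v))
      stop("missing value in column '", .cohort_cols[[cc]], "' at row(s) ",
           paste(which(is.na(v)), collapse = ", "))
    df[[cc]] <- v
  }
  df$toxicity <- as.integer(df$toxicity)
  if (any(!df$toxicity %in% 1:3))
    stop("toxicity grade outside {1, 2, 3} at row(s) ",
         paste(which(!df$toxicity %in% 1:3), collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("duplicate patient ids in ", path)
  attr(df, "provenance") <- path
  class(df) <- c("pkpd_cohort", "data.frame")
  df
}

#' Fit the PK/PD prediction models to a cohort
#'
#' Three components back the regimen objectives: a linear exposure model
#' `AUC ~ doseA + doseB` (least squares), an Emax response model of effect
#' versus AUC (nonlinear least squares, Hill coefficient estimated), and an
#' ordinal toxicity model of grade versus AUC (proportional-odds logistic
#' regression, falling back to empirical thresholds when the cohort does not
#' support it).  Also estimates the Cmax/AUC ratio used by the exposure
#' ceiling constraint.
#'
#' @param cohort A `pkpd_cohort`.
#' @return A list of class `pkpd_fit` with prediction functions
#'   `predict_auc(dose_a, dose_b)`, `predict_effect(auc)`,
#'   `predict_grade(auc)` (expected grade on the 1-3 scale) and the scalar
#'   `cmax_ratio`.
#' @export
fit_pkpd <- function(cohort) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 8)
  exposure <- stats::lm(auc ~ dose_a + dose_b, data = cohort)
  est_start <- list(emax = min(100, max(cohort$effect) * 1.05),
                    ec50 = stats::median(cohort$auc) / 2, hill = 2)
  response <- tryCatch(
    stats::nls(effect ~ emax * auc^hill / (ec50^hill + auc^hill),
               data = cohort, start = est_start,
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  predict_effect <- if (!is.null(response)) {
    cf <- stats::coef(response)
    function(auc) pmin(100, pmax(0, cf[["emax"]] * auc^cf[["hill"]] /
                                   (cf[["ec50"]]^cf[["hill"]] + auc^cf[["hill"]])))
  } else {
    # monotone fallback: linear interpolation of the empirical dose-response
    o <- order(cohort$auc)
    fa <- stats::approxfun(cohort$auc[o], cummax(cohort$effect[o]), rule = 2)
    function(auc) pmin(100, pmax(0, fa(auc)))
  }
  grades <- sort(unique(cohort$toxicity))
  predict_grade <- NULL
  if (length(grades) >= 2) {
    # proportional-odds model; degenerates (perfect separation) fall back to
    # empirical AUC thresholds between consecutive grades with logistic
    # smoothing at the scale of the between-grade gap
    fit <- tryCatch(
      MASS::polr(factor(toxicity, levels = 1:3, ordered = TRUE) ~ auc,
                 data = cohort, Hess = FALSE),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      predict_grade <- function(auc) {
        pr <- stats::predict(fit, newdata = data.frame(auc = auc),
                             type = "probs")
        if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1)
        drop(pr %*% as.numeric(colnames(pr)))
      }
    } else {
      cuts <- vapply(seq_len(length(grades) - 1L), function(k) {
        lo <- max(cohort$auc[cohort$toxicity == grades[k]])
        hi <- min(cohort$auc[cohort$toxicity == grades[k + 1L]])
        mean(c(lo, hi))
      }, numeric(1))
      scale <- max(1, 0.02 * stats::median(cohort$auc))
      base <- grades[1]
      steps <- diff(grades)
      predict_grade <- function(auc) {
        g <- rep(base, length(auc))
        for (k in seq_along(cuts))
          g <- g + steps[k] * stats::plogis((auc - cuts[k]) / scale)
        g
      }
    }
  } else {
    g0 <- grades[1]
    predict_grade <- function(auc) rep(g0, length(auc))
  }
  structure(list(
    predict_auc = function(dose_a, dose_b)
      pmax(0, stats::predict(exposure,
                             newdata = data.frame(dose_a = dose_a,
                                                  dose_b = dose_b))),
    predict_effect = predict_effect,
    predict_grade = predict_grade,
    cmax_ratio = mean(cohort$cmax / cohort$auc),
    n = nrow(cohort)), class = "pkpd_fit")
}

#' Objective weights and scale constants for regimen design
#'
#' @param e_max Maximum achievable efficacy score (the efficacy objective is
#'   `e_max - w1 * AE`, with `AE` the predicted adverse-effect score, i.e.
#'   the cohort-model response shortfall `100 - predicted effect`).
#' @param s_max Maximum achievable safety score (`s_max - w2 * AR`, `AR`
#'   the expected toxicity grade).
#' @param c_max Maximum allowable course cost (`c_max - w3 * Cost`).
#' @param w1,w2,w3 Non-negative weighting factors.
#' @param price_a,price_b Unit drug prices per mg per administration.
#' @param weekly_cost Fixed care cost per treatment week.
#' @param ref_interval Dosing interval (h) at which the cohort exposures
#'   were observed; exposure scales as `ref_interval / interval`.
#' @param duration_t50 Half-saturation of the duration-response factor
#'   (weeks).
#' @param cmax_ceiling Toxicity ceiling on predicted Cmax (ng/mL) used as an
#'   inequality constraint by [regimen_problem()].
#' @return A list of class `regimen_weights`.
#' @export
regimen_weights <- function(e_max = 100, s_max = 10, c_max = 5000,
                            w1 = 1, w2 = 1, w3 = 1,
                            price_a = 0.10, price_b = 0.15, weekly_cost = 20,
                            ref_interval = 12, duration_t50 = 2,
                            cmax_ceiling = 300) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0, e_max > 0, s_max > 0, c_max > 0,
            price_a >= 0, price_b >= 0, weekly_cost >= 0,
            ref_interval > 0, cmax_ceiling > 0)
  structure(as.list(environment()), class = "regimen_weights")
}

#' Construct a regimen decision vector
#'
#' @param dose_a Drug A dose per administration (mg).
#' @param interval Dosing interval (h), positive.
#' @param dose_b Drug B dose per administration (mg).
#' @param duration Treatment duration (weeks), at least 1.
#' @return Named numeric vector of class `regimen`.
#' @export
regimen <- function(dose_a, interval, dose_b, duration) {
  stopifnot(interval > 0, duration >= 1, dose_a >= 0, dose_b >= 0)
  structure(c(dose_a = dose_a, interval = interval, dose_b = dose_b,
              duration = duration), class = "regimen")
}

#' Default decision-space bounds for a regimen
#'
#' @param lower,upper Named or positional length-4 vectors
#'   (dose_a mg, interval h, dose_b mg, duration weeks).
#' @return A list of class `regimen_bounds`.
#' @export
regimen_bounds <- function(lower = c(dose_a = 50, interval = 6,
                                     dose_b = 0, duration = 1),
                           upper = c(dose_a = 200, interval = 24,
                                     dose_b = 150, duration = 12)) {
  lower <- unname(as.numeric(lower)); upper <- unname(as.numeric(upper))
  stopifnot(length(lower) == 4, length(upper) == 4)
  if (any(lower >= upper)) stop("infeasible bounds: lower must be below upper")
  structure(list(lower = lower, upper = upper), class = "regimen_bounds")
}

.as_regimen <- function(x) {
  x <- as.numeric(x)
  stopifnot(length(x) == 4)
  names(x) <- c("dose_a", "interval", "dose_b", "duration")
  x
}

.regimen_fit <- function(cohort) {
  if (inherits(cohort, "pkpd_fit")) cohort else fit_pkpd(cohort)
}

# effective steady-state exposure of a regimen under the fitted model:
# per-administration AUC scaled by dosing frequency relative to the
# reference interval
.regimen_auc <- function(reg, fit, weights) {
  fit$predict_auc(reg[["dose_a"]], reg[["dose_b"]]) *
    weights$ref_interval / reg[["interval"]]
}

# adverse-effect score: response shortfall under the fitted Emax model,
# attenuated for short courses by a saturating duration factor
.regimen_ae <- function(reg, fit, weights) {
  auc <- .regimen_auc(reg, fit, weights)
  dur <- reg[["duration"]] / (reg[["duration"]] + weights$duration_t50)
  100 - fit$predict_effect(auc) * dur
}

# adverse-reaction burden: expected toxicity grade at the regimen exposure
.regimen_ar <- function(reg, fit, weights) {
  fit$predict_grade(.regimen_auc(reg, fit, weights))
}

# raw course cost in currency units
.regimen_cost <- function(reg, weights) {
  doses <- reg[["duration"]] * 7 * 24 / reg[["interval"]]
  reg[["dose_a"]] * weights$price_a * doses +
    reg[["dose_b"]] * weights$price_b * doses +
    weights$weekly_cost * reg[["duration"]]
}

#' Efficacy of a drug regimen against a cohort
#'
#' `E = e_max - w1 * AE`, where the adverse-effect score `AE` is the
#' cohort-model response shortfall (100 minus the predicted therapeutic
#' effect percentage at the regimen's steady-state exposure, attenuated for
#' short treatment courses).  Higher is better.
#'
#' @param reg A [regimen()] (or length-4 numeric vector).
#' @param cohort A `pkpd_cohort` or a prefitted [fit_pkpd()] object.
#' @param weights A [regimen_weights()].
#' @return A scalar efficacy score.
#' @export
efficacy <- function(reg, cohort, weights = regimen_weights()) {
  if (is.data.frame(cohort) && !nrow(cohort)) stop("empty cohort")
  weights$e_max - weights$w1 * .regimen_ae(.as_regimen(reg),
                                           .regimen_fit(cohort), weights)
}

#' Safety of a drug regimen against a cohort
#'
#' `S = s_max - w2 * AR`, where the adverse-reaction burden `AR` is the
#' expected toxicity grade (1-3) at the regimen exposure under the fitted
#' ordinal model.  Higher is better.
#'
#' @inheritParams efficacy
#' @return A scalar safety score.
#' @export
safety <- function(reg, cohort, weights = regimen_weights()) {
  if (is.data.frame(cohort) && !nrow(cohort)) stop("empty cohort")
  weights$s_max - weights$w2 * .regimen_ar(.as_regimen(reg),
                                           .regimen_fit(cohort), weights)
}

#' Cost score of a drug regimen
#'
#' `C = c_max - w3 * Cost`, with the raw course cost
#' `doseA * priceA * n_doses + doseB * priceB * n_doses + weekly care cost`,
#' and `n_doses = duration * 7 * 24 / interval`.  Higher is better (cheaper).
#'
#' @inheritParams efficacy
#' @return A scalar cost score.
#' @export
cost <- function(reg, weights = regimen_weights()) {
  weights$c_max - weights$w3 * .regimen_cost(.as_regimen(reg), weights)
}

#' Therapeutic index of a regimen under the fitted cohort models
#'
#' Ratio of the toxic exposure (the AUC at which the expected toxicity grade
#' crosses `grade_ceiling`) to the effective exposure (the AUC giving
#' half-maximal predicted effect) — a safety-margin report column, not an
#' optimization objective.
#'
#' @param cohort A `pkpd_cohort` or `pkpd_fit`.
#' @param grade_ceiling Expected-grade level treated as toxic (default 2.5).
#' @return A positive scalar (may be `Inf` when toxicity never crosses the
#'   ceiling on the explored exposure range).
#' @export
therapeutic_index <- function(cohort, grade_ceiling = 2.5) {
  fit <- .regimen_fit(cohort)
  aucs <- seq(1, 5000, by = 1)
  eff <- fit$predict_effect(aucs)
  ed <- aucs[which(eff >= max(eff) / 2)[1]]
  gr <- fit$predict_grade(aucs)
  td_i <- which(gr >= grade_ceiling)[1]
  if (is.na(td_i)) return(Inf)
  aucs[td_i] / ed
}

#' Wrap regimen design as a 3-objective minimization problem
#'
#' Internally minimizes `(w1 * AE, w2 * AR, w3 * Cost)` — adverse effect,
#' adverse reaction and raw cost — which is the minimization form of
#' maximizing the efficacy, safety and cost scores.  The predicted-Cmax
#' toxicity ceiling enters as an inequality constraint handled by constraint
#' dominance (feasible solutions dominate infeasible ones).
#'
#' @param cohort A `pkpd_cohort` (the models are fitted once up front) or a
#'   `pkpd_fit`.
#' @param weights A [regimen_weights()].
#' @param bounds A [regimen_bounds()].
#' @return A `moswo_problem` with `D = 4`, `M = 3`.
#' @export
regimen_problem <- function(cohort, weights = regimen_weights(),
                            bounds = regimen_bounds()) {
  stopifnot(inherits(weights, "regimen_weights"),
            inherits(bounds, "regimen_bounds"))
  fit <- .regimen_fit(cohort)
  w <- weights
  fn_pop <- function(X) {
    auc <- fit$predict_auc(X[, 1], X[, 3]) * w$ref_interval / X[, 2]
    dur <- X[, 4] / (X[, 4] + w$duration_t50)
    ae <- 100 - fit$predict_effect(auc) * dur
    ar <- fit$predict_grade(auc)
    doses <- X[, 4] * 7 * 24 / X[, 2]
    cost_raw <- X[, 1] * w$price_a * doses + X[, 3] * w$price_b * doses +
      w$weekly_cost * X[, 4]
    cbind(w$w1 * ae, w$w2 * ar, w$w3 * cost_raw, deparse.level = 0)
  }
  violation <- function(x) {
    cmax_hat <- fit$predict_auc(x[1], x[3]) * w$ref_interval / x[2] *
      fit$cmax_ratio
    max(0, (cmax_hat - w$cmax_ceiling) / w$cmax_ceiling)
  }
  moswo_problem("regimen", 4L, 3L, bounds$lower, bounds$upper,
                fn = function(x) drop(fn_pop(matrix(x, nrow = 1))),
                fn_pop = fn_pop, violation = violation)
}

#' Report a regimen archive in both sign conventions
#'
#' Converts the minimized objectives of a [regimen_problem()] archive back to
#' the reported efficacy/safety/cost scores.
#'
#' @param result A `moswo_result` from a regimen problem run.
#' @param weights The [regimen_weights()] used to build the problem.
#' @return A data frame with the decoded regimen variables, the minimized
#'   objectives (`ae`, `ar`, `cost_raw`) and the score-convention columns
#'   (`efficacy`, `safety`, `cost_score`).
#' @export
regimen_report <- function(result, weights = regimen_weights()) {
  X <- pareto_set(result); F <- pareto_front(result)
  data.frame(dose_a = X[, 1], interval = X[, 2], dose_b = X[, 3],
             duration = X[, 4],
             ae = F[, 1], ar = F[, 2], cost_raw = F[, 3],
             efficacy = weights$e_max - F[, 1],
             safety = weights$s_max - F[, 2],
             cost_score = weights$c_max - F[, 3])
}

#' Encode a regimen to the unit hypercube / decode it back
#'
#' Affine map of each variable onto \[0, 1\] given the bounds;
#' `decode_regimen(encode_regimen(x)) == x` to numerical precision.
#' Out-of-bounds inputs are clipped with a warning.
#'
#' @param reg A regimen (length-4 numeric).
#' @param bounds A [regimen_bounds()].
#' @return `encode_regimen`: a length-4 vector in \[0, 1\];
#'   `decode_regimen`: a [regimen()] in original units.
#' @export
encode_regimen <- function(reg, bounds = regimen_bounds()) {
  x <- .as_regimen(reg)
  if (any(x < bounds$lower) || any(x > bounds$upper)) {
    warning("regimen outside bounds; clipping")
    x <- clip_to_bounds(x, bounds$lower, bounds$upper)
  }
  (x - bounds$lower) / (bounds$upper - bounds$lower)
}

#' @param u A length-4 vector in \[0, 1\].
#' @rdname encode_regimen
#' @export
decode_regimen <- function(u, bounds = regimen_bounds()) {
  u <- as.numeric(u)
  stopifnot(length(u) == 4)
  if (any(u < 0) || any(u > 1)) {
    warning("encoded regimen outside [0, 1]; clipping")
    u <- clip_to_bounds(u, 0, 1)
  }
  x <- bounds$lower + u * (bounds$upper - bounds$lower)
  regimen(x[1], x[2], x[3], x[4])
}
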