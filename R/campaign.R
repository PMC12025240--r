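# Multi-run benchmark campaign: repeated seeded runs per problem with
# indicator summaries in a problem x metric layout.

#' Run a seeded benchmark campaign
#'
#' For each problem: `runs` independent optimizer runs with seeds
#' `base_seed + 1, ..., base_seed + runs`, each scored by IGD, normalized
#' hypervolume (reference 1.1 per objective) and spread against a dense
#' analytic-front sample, plus the final archive size.  The default budgets
#' follow the benchmark protocol: 10,000 evaluations for the bi-objective
#' ZDT problems and 20,000 for the three-objective DTLZ problems, with
#' population 100.  Reference-front densities default to 1,000 points for
#' two objectives and 5,000 for three.
#'
#' When `out_dir` is given, each run's archive and metric row are written to
#' per-run files (atomically, via rename) and a completed run found on disk
#' is reused, so an interrupted campaign resumes where it stopped.
#'
#' @param problems Character vector of problem names (see [get_problem()]).
#' @param runs Runs per problem (default 25).
#' @param budget Named or scalar evaluation budget override; by default
#'   10,000 for 2-objective problems and 20,000 for 3-objective ones.
#' @param base_seed Base integer seed.
#' @param pop_size,pop_min,archive_size Passed to [moswo_control()].
#' @param ref_size Reference-front sample size override (default by M).
#' @param out_dir Optional output directory for per-run CSVs, a summary CSV
#'   and a JSON digest.
#' @param verbose Print one line per completed run?
#' @return A list of class `moswo_campaign`: `per_run` (data frame with
#'   problem, run, seed and the metric columns), `summary` (problem x metric
#'   means and standard deviations) and the campaign configuration.
#' @export
run_campaign <- function(problems, runs = 25L, budget = NULL,
                         base_seed = 1L, pop_size = 100L, pop_min = 20L,
                         archive_size = 100L, ref_size = NULL,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(runs >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (pname in problems) {
    problem <- get_problem(pname)
    b <- if (is.null(budget)) {
      if (problem$n_obj >= 3L) 20000L else 10000L
    } else if (!is.null(names(budget)) && pname %in% names(budget)) {
      as.integer(budget[[pname]])
    } else as.integer(budget[[1]])
    nref <- if (is.null(ref_size)) {
      if (problem$n_obj >= 3L) 5000L else 1000L
    } else as.integer(ref_size)
    front <- sample_true_front(problem, nref)
    for (r in seq_len(runs)) {
      seed <- as.integer(base_seed + r)
      run_file <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("%s_run%02d.csv", pname, r)) else NULL
      if (!is.null(run_file) && file.exists(run_file)) {
        arch <- read_archive(run_file)
        m <- benchmark_metrics(arch$objectives, front)
      } else {
        res <- moswo(problem, moswo_control(pop_size = pop_size,
                                            pop_min = pop_min,
                                            budget = b,
                                            archive_size = archive_size,
                                            seed = seed, history = FALSE))
        m <- benchmark_metrics(pareto_front(res), front)
        if (!is.null(run_file)) {
          tmp <- paste0(run_file, ".tmp")
          write_archive(res, tmp, run_id = r)
          file.rename(tmp, run_file)
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(problem = pname, run = r, seed = seed, budget = b,
                   igd = m[["igd"]], hv = m[["hv"]],
                   spread = m[["spread"]], size = m[["size"]])
      if (verbose)
        message(sprintf("%s run %d/%d: igd %.4g hv %.4g spread %.4g",
                        pname, r, runs, m[["igd"]], m[["hv"]], m[["spread"]]))
    }
  }
  per_run <- do.call(rbind, rows)
  agg <- function(f) stats::aggregate(per_run[c("igd", "hv", "spread", "size")],
                                      by = per_run["problem"], FUN = f)
  mu <- agg(mean); sdv <- agg(function(v) if (length(v) > 1) stats::sd(v) else 0)
  names(mu)[-1] <- paste0(names(mu)[-1], "_mean")
  names(sdv)[-1] <- paste0(names(sdv)[-1], "_sd")
  summary <- merge(mu, sdv, by = "problem", sort = FALSE)
  out <- structure(list(per_run = per_run, summary = summary,
                        config = list(problems = problems, runs = runs,
                                      base_seed = base_seed,
                                      pop_size = pop_size, pop_min = pop_min,
                                      archive_size = archive_size),
                        seeds = unique(per_run$seed)),
                   class = "moswo_campaign")
  if (!is.null(out_dir)) {
    utils::write.csv(per_run, file.path(out_dir, "per_run.csv"),
                     row.names = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE))
      jsonlite::write_json(
        list(config = out$config, seeds = out$seeds, summary = summary),
        file.path(out_dir, "digest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.moswo_campaign <- function(x, ...) {
  cat("MOSWO benchmark campaign:", length(unique(x$per_run$problem)),
      "problem(s) x", x$config$runs, "run(s)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
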