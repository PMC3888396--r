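# Monte-Carlo robustness harness: scenario grid, per-scenario replication
# loop, exact binomial confidence intervals, result tables and figures.

#' Factorial grid of simulation scenarios
#'
#' Crosses per-group sample sizes, questionnaire lengths, group effects and
#' latent-trait shapes into one scenario per combination.  The defaults are
#' the canonical robustness grid: `ng` in 50/100/200/300/500, `j` in 5/10,
#' `gamma` in 0/0.2/0.5/0.8 and the three non-normal beta shapes, giving
#' 120 scenarios; restricting to `gamma = 0` gives the 30 type-I-error
#' cells.
#'
#' @param ng Per-group sample sizes (`n0 = n1 = ng`).
#' @param j Questionnaire lengths; each must have a difficulty set, see
#'   [canonical_difficulties()].
#' @param gamma Group effects.
#' @param shape Latent-trait shapes: `"U"`, `"L"`, `"J"` (standardised
#'   beta) or `"normal"`.
#'
#' @return A tibble with columns `scenario_id`, `j`, `ng`, `gamma`,
#'   `shape`.
#' @examples
#' nrow(scenario_grid())               # 120
#' nrow(scenario_grid(gamma = 0))      # 30
#' @export
scenario_grid <- function(ng = c(50, 100, 200, 300, 500), j = c(5, 10),
                          gamma = c(0, 0.2, 0.5, 0.8),
                          shape = c("U", "J", "L")) {
  grid <- tidyr::expand_grid(j = j, ng = ng, gamma = gamma, shape = shape)
  dplyr::mutate(grid, scenario_id = dplyr::row_number(),
                .before = dplyr::everything())
}

# deterministic per-replication child seeds from one master seed
child_seeds <- function(seed, n) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n)
}

#' Exact binomial confidence interval
#'
#' Two-sided Clopper-Pearson interval for a proportion, via
#' [stats::binom.test()].
#'
#' @param successes,trials Counts, `0 <= successes <= trials`, `trials > 0`.
#' @param level Confidence level, default 0.95.
#'
#' @return Named numeric `c(lower = , upper = )`.
#' @examples
#' round(binomial_ci(50, 1000), 3)  # 0.037, 0.065
#' @export
binomial_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1) abort("`trials` must be positive")
  if (successes < 0 || successes > trials) abort("`successes` must lie in 0..trials")
  ci <- stats::binom.test(successes, trials, conf.level = level)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Run one Monte-Carlo scenario
#'
#' Replicates simulate -> estimate -> Wald test: each replication draws a
#' two-group dataset from `dist` under the design, estimates the group
#' effect by marginal maximum likelihood with difficulties and variance
#' fixed (normality assumed), and records the rejection of the Wald test.
#' Summaries are taken over converged replications only; the run fails if
#' more than `max_dropped` of replications fail to converge, since silent
#' drops would bias the rejection rate.  The planning predictions
#' ([raschpower()]) for the same design are attached for comparison.
#'
#' @param items An [item_bank()].
#' @param design A [study_design()].
#' @param dist A [latent_distribution()].
#' @param reps Number of replications.
#' @param seed Master seed; spawns one child seed per replication through
#'   `sample.int()` so that replications are individually reproducible.
#'   `NULL` continues the current RNG stream.
#' @param quad_order Number of Gauss-Hermite nodes.
#' @param max_dropped Largest tolerated fraction of non-converged
#'   replications (default 0.01).
#'
#' @return A one-row tibble: design identifiers, `reps`, `n_converged`,
#'   `rejection_rate` with exact binomial `ci_lower`/`ci_upper`,
#'   `mean_gamma_hat`, `var_s` (mean of per-replication variance
#'   estimates), and the planning counterparts `var_cr`, `power_cr`.
#' @examples
#' run_scenario(canonical_difficulties(5), study_design(50, 50, gamma = 0),
#'              latent_distribution("beta", shape = "L"),
#'              reps = 20, seed = 1)
#' @export
run_scenario <- function(items, design, dist, reps = 1000, seed = NULL,
                         quad_order = 40, max_dropped = 0.01) {
  if (reps < 1) abort("`reps` must be at least 1")
  seeds <- child_seeds(seed, reps)
  z <- qnorm(1 - design$alpha / 2)
  gamma_hat <- var_hat <- rep(NA_real_, reps)
  reject <- rep(NA, reps)
  for (r in seq_len(reps)) {
    set.seed(seeds[r])
    dat <- simulate_dataset(items, design, dist)
    fit <- estimate_gamma(dat, items, design$sigma2, quad_order)
    if (fit$converged) {
      gamma_hat[r] <- fit$gamma_hat
      var_hat[r] <- fit$var_hat
      reject[r] <- abs(fit$wald_z) > z
    }
  }
  ok <- !is.na(reject)
  if (mean(!ok) > max_dropped) {
    abort(sprintf("%.1f%% of replications failed to converge (limit %.1f%%)",
                  100 * mean(!ok), 100 * max_dropped))
  }
  rp <- raschpower(items, design, quad_order)
  ci <- binomial_ci(sum(reject[ok]), sum(ok))
  tibble(
    j = length(items), n0 = design$n0, n1 = design$n1,
    gamma = design$gamma, sigma2 = design$sigma2,
    shape = if (dist$family == "normal") "normal" else
      if (!is.na(dist$shape)) dist$shape else
        sprintf("beta(%g,%g)", dist$omega, dist$tau),
    reps = reps, n_converged = sum(ok),
    rejection_rate = mean(reject[ok]),
    ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
    mean_gamma_hat = mean(gamma_hat[ok]), var_s = mean(var_hat[ok]),
    var_cr = rp$var_cr, power_cr = rp$power
  )
}

#' Run a grid of scenarios
#'
#' Executes [run_scenario()] for each row of a [scenario_grid()].  Each
#' scenario gets its own master seed, derived deterministically from `seed`
#' and the scenario id, so results are identical whatever the execution
#' order and a grid can be resumed: with `checkpoint_dir` set, each
#' finished scenario is written to `scenario_<id>.csv` and existing files
#' are reloaded instead of recomputed.  A scenario that errors is reported
#' in the `status` column and the grid continues.
#'
#' @param grid A tibble from [scenario_grid()].
#' @param reps Replications per scenario.
#' @param seed Master seed for the whole grid.
#' @param quad_order Number of Gauss-Hermite nodes.
#' @param checkpoint_dir Optional directory for per-scenario checkpoints.
#' @param alpha,sigma2 Design constants shared by all scenarios.
#'
#' @return A `raschpower_results` tibble: the grid columns joined to each
#'   scenario's [run_scenario()] summary plus a `status` column
#'   (`"ok"` or the error message).  Supports [autoplot()].
#' @export
run_grid <- function(grid, reps = 200, seed = 1, quad_order = 40,
                     checkpoint_dir = NULL, alpha = 0.05, sigma2 = 1) {
  if (nrow(grid) == 0) abort("`grid` must contain at least one scenario")
  scen_seeds <- child_seeds(seed, max(grid$scenario_id))
  if (!is.null(checkpoint_dir) && !dir.exists(checkpoint_dir)) {
    dir.create(checkpoint_dir, recursive = TRUE)
  }
  rows <- purrr::pmap(grid, function(scenario_id, j, ng, gamma, shape) {
    ckpt <- if (!is.null(checkpoint_dir)) {
      file.path(checkpoint_dir, sprintf("scenario_%03d.csv", scenario_id))
    }
    if (!is.null(ckpt) && file.exists(ckpt)) {
      return(readr::read_csv(ckpt, show_col_types = FALSE))
    }
    dist <- if (shape == "normal") latent_distribution("normal") else
      latent_distribution("beta", shape = shape)
    res <- tryCatch({
      out <- run_scenario(canonical_difficulties(j),
                          study_design(ng, ng, gamma, sigma2, alpha),
                          dist, reps = reps, seed = scen_seeds[scenario_id],
                          quad_order = quad_order)
      dplyr::mutate(out, scenario_id = scenario_id, shape = shape,
                    status = "ok", .before = 1)
    }, error = function(e) {
      tibble(scenario_id = scenario_id, shape = shape,
             status = conditionMessage(e), j = j, n0 = ng, n1 = ng,
             gamma = gamma)
    })
    if (!is.null(ckpt)) readr::write_csv(res, ckpt)
    res
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$scenario_id)
  class(out) <- c("raschpower_results", class(out))
  out
}

format_cell <- function(rate, lo, hi) {
  ifelse(is.na(rate), "NA",
         sprintf("%.3f [%.3f-%.3f]", rate, lo, hi))
}

#' Shape Monte-Carlo results into report tables
#'
#' Pivots a results tibble from [run_grid()] into the standard report
#' layouts: `"type1"` - empirical type-I error with exact binomial CIs,
#' cells formatted `"0.055 [0.042-0.071]"`, rows `j` by `ng`, one column
#' per shape (uses the `gamma = 0` scenarios); `"gamma"` - mean estimated
#' group effect, columns shape by `gamma`; `"variance"` - paired `var_s` /
#' `var_cr` columns per `gamma` (one shape at a time, rows `j` by `ng`);
#' `"power"` - long table of empirical power next to the planning
#' prediction.  Missing scenarios appear as explicit `"NA"` cells (or `NA`
#' values); an empty input yields a header-only table.
#'
#' @param results A tibble from [run_grid()].
#' @param table One of `"type1"`, `"gamma"`, `"variance"`, `"power"`.
#' @param shape For `table = "variance"`, which latent-trait shape to
#'   tabulate (default `"U"`).
#'
#' @return A tibble in the requested layout.
#' @export
make_tables <- function(results, table = c("type1", "gamma", "variance",
                                           "power"), shape = "U") {
  table <- match.arg(table)
  res <- results
  needed <- c("rejection_rate", "ci_lower", "ci_upper", "mean_gamma_hat",
              "var_s", "var_cr", "power_cr")
  for (col in setdiff(needed, names(res))) res[[col]] <- NA_real_
  if (table == "type1") {
    res |>
      dplyr::filter(.data$gamma == 0) |>
      dplyr::mutate(cell = format_cell(.data$rejection_rate, .data$ci_lower,
                                       .data$ci_upper)) |>
      dplyr::select("j", ng = "n0", "shape", "cell") |>
      tidyr::pivot_wider(names_from = "shape", values_from = "cell") |>
      dplyr::arrange(.data$j, .data$ng)
  } else if (table == "gamma") {
    res |>
      dplyr::mutate(col = sprintf("%s_gamma_%g", .data$shape, .data$gamma),
                    val = round(.data$mean_gamma_hat, 3)) |>
      dplyr::select("j", ng = "n0", "col", "val") |>
      tidyr::pivot_wider(names_from = "col", values_from = "val") |>
      dplyr::arrange(.data$j, .data$ng)
  } else if (table == "variance") {
    res |>
      dplyr::filter(.data$shape == !!shape) |>
      dplyr::mutate(var_s = round(.data$var_s, 4),
                    var_cr = round(.data$var_cr, 4)) |>
      dplyr::select("j", ng = "n0", "gamma", "var_s", "var_cr") |>
      tidyr::pivot_wider(names_from = "gamma",
                         values_from = c("var_s", "var_cr"),
                         names_glue = "{.value}_gamma_{gamma}",
                         names_vary = "slowest") |>
      dplyr::arrange(.data$j, .data$ng)
  } else {
    res |>
      dplyr::filter(.data$gamma > 0) |>
      dplyr::mutate(power_s = round(.data$rejection_rate, 3),
                    power_cr = round(.data$power_cr, 3)) |>
      dplyr::select("j", ng = "n0", "gamma", "shape", "power_s", "power_cr") |>
      dplyr::arrange(.data$j, .data$ng, .data$gamma)
  }
}

#' Write all report tables of a grid run to CSV
#'
#' @param results A tibble from [run_grid()].
#' @param dir Output directory (created if needed).
#'
#' @return Invisibly, the paths written.
#' @export
write_result_tables <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    type1 = file.path(dir, "table_type1_error.csv"),
    gamma = file.path(dir, "table_mean_gamma.csv"),
    variance = file.path(dir, "table_variances.csv"),
    power = file.path(dir, "table_power.csv")
  )
  readr::write_csv(make_tables(results, "type1"), paths["type1"])
  readr::write_csv(make_tables(results, "gamma"), paths["gamma"])
  readr::write_csv(make_tables(results, "variance"), paths["variance"])
  readr::write_csv(make_tables(results, "power"), paths["power"])
  readr::write_csv(results, file.path(dir, "results_all.csv"))
  invisible(paths)
}

#' Power versus sample size, simulation against planning prediction
#'
#' Plots the empirical power from the simulations (one line per
#' latent-trait shape) against the planning prediction (dashed), as a
#' function of the per-group sample size, at one effect size and
#' questionnaire length.
#'
#' @param object A `raschpower_results` tibble from [run_grid()].
#' @param gamma,j Which effect size and questionnaire length to display.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot raschpower_results
#' @export
autoplot.raschpower_results <- function(object, gamma = 0.5, j = 5, ...) {
  dat <- dplyr::filter(object, .data$gamma == !!gamma, .data$j == !!j,
                       .data$status == "ok")
  if (nrow(dat) == 0) abort("no completed scenarios at this (gamma, j)")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n0)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rejection_rate,
                                    colour = .data$shape)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$rejection_rate,
                                     colour = .data$shape)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$power_cr,
                                    linetype = "planning (Cramer-Rao)")) +
    ggplot2::scale_linetype_manual(NULL, values = c("planning (Cramer-Rao)" = 2)) +
    ggplot2::labs(x = "sample size per group", y = "power",
                  colour = "latent-trait shape",
                  title = sprintf("Power of the Wald test (gamma = %g, J = %d)",
                                  gamma, j)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.raschpower_results
#' @param results A `raschpower_results` tibble.
#' @export
plot_power_curve <- function(results, gamma = 0.5, j = 5) {
  autoplot.raschpower_results(results, gamma = gamma, j = j)
}
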