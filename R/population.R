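# Virtual-cell-population orchestration: sweep expansion over species
# initial values and parameter values, many-cell hybrid runs with
# reproducible per-cell seeds, and phenotype fractions with binomial
# standard errors.

#' Sweep specification
#'
#' @param species_values named list: species name -> vector of initial
#'   concentrations (nM) to sweep over.
#' @param ratelaw_values named list: global parameter name -> vector of
#'   values to sweep over.
#' @param num_cells cells per condition (>= 1).
#' @param base_config base [simulation_config()] for every run.
#' @param base_seed integer seed from which per-cell seeds are derived.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(species_values = list(), ratelaw_values = list(),
                       num_cells = 1L, base_config = simulation_config(),
                       base_seed = 1L) {
  stopifnot(num_cells >= 1L)
  structure(list(species_values = species_values,
                 ratelaw_values = ratelaw_values,
                 num_cells = as.integer(num_cells),
                 base_config = base_config,
                 base_seed = as.integer(base_seed)),
            class = "sweep_spec")
}

#' Expand a sweep into per-cell runs
#'
#' Forms the Cartesian product of all species-value and parameter-value
#' lists, replicates each condition `num_cells` times, and assigns every
#' run a distinct, reproducible seed
#' `base_seed + (condition - 1) * num_cells + cell`, kept within 32-bit
#' integer range.
#'
#' @param s a [sweep_spec()].
#' @return data frame with one row per run: `condition`, `cell`, `seed`,
#'   plus one column per swept name; attribute `overrides` holds the
#'   per-condition named lists.
#' @export
expand_sweep <- function(s) {
  lists <- c(s$species_values, s$ratelaw_values)
  conds <- if (length(lists)) expand.grid(lists, KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1L)
  n_cond <- max(nrow(conds), 1L)
  runs <- do.call(rbind, lapply(seq_len(n_cond), function(ci) {
    cells <- seq_len(s$num_cells)
    seed <- (s$base_seed + (ci - 1L) * s$num_cells + cells) %% 2147483647L
    base <- data.frame(condition = ci, cell = cells, seed = seed)
    if (ncol(conds)) cbind(base, conds[rep(ci, s$num_cells), , drop = FALSE],
                           row.names = NULL)
    else base
  }))
  attr(runs, "n_species_vals") <- length(s$species_values)
  attr(runs, "species_names") <- names(s$species_values)
  attr(runs, "param_names") <- names(s$ratelaw_values)
  runs
}

#' Run a virtual cell population
#'
#' Executes every run of the expanded sweep (optionally across a local
#' process pool; per-cell seeds make the results independent of worker
#' count and run order), then scores each condition: percentage of cells
#' entering S-phase (summed cyclins above the threshold at `t_eval_h`),
#' percentage dead, and Eq.-style binomial standard errors.  Dead cells are
#' not counted as being in S-phase.
#'
#' @param cm a `compiled_model`.
#' @param s a [sweep_spec()].
#' @param workers size of the process pool (forked; 1 = sequential).
#' @param t_eval_h time at which S-phase is scored (defaults to the run
#'   duration).
#' @param sphase_threshold summed-cyclin threshold in nM (default 20).
#' @param keep_trajectories return the per-cell trajectories (memory!).
#' @return an object of class `population_result`: list with `summary`
#'   (a `fate_summary` data frame), `fates` (per-run data frame), `runs`,
#'   and optionally `trajectories`.
#' @export
run_population <- function(cm, s, workers = 1L, t_eval_h = NULL,
                           sphase_threshold = 20, keep_trajectories = FALSE) {
  runs <- expand_sweep(s)
  sp_names <- attr(runs, "species_names")
  par_names <- attr(runs, "param_names")
  cfg0 <- s$base_config
  if (is.null(t_eval_h)) t_eval_h <- cfg0$duration_h

  one <- function(i) {
    row <- runs[i, ]
    m2 <- cm
    if (length(sp_names))
      m2$init[sp_names] <- as.numeric(row[1L, sp_names])
    if (length(par_names))
      m2 <- set_parameters(m2, stats::setNames(as.numeric(row[1L, par_names]),
                                               par_names))
    cfg <- cfg0
    cfg$seed <- row$seed
    cfg$output_label <- sprintf("c%03d_cell%04d", row$condition, row$cell)
    traj <- tryCatch(simulate_cell(m2, cfg), error = function(e) e)
    if (inherits(traj, "error"))
      return(list(ok = FALSE, error = conditionMessage(traj), traj = NULL,
                  dead = NA, sphase = NA))
    dead <- !is.na(traj$died_at)
    sphase <- if (dead) FALSE else
      tryCatch(classify_sphase(traj, cm$cyclin_roles, t_eval_h,
                               sphase_threshold),
               error = function(e) NA)
    list(ok = TRUE, error = NA_character_, traj = traj, dead = dead,
         sphase = sphase)
  }

  results <- if (workers > 1L)
    parallel::mclapply(seq_len(nrow(runs)), one, mc.cores = workers,
                       mc.preschedule = TRUE)
  else lapply(seq_len(nrow(runs)), one)

  fates <- data.frame(
    condition = runs$condition, cell = runs$cell, seed = runs$seed,
    ok = vapply(results, `[[`, logical(1L), "ok"),
    dead = vapply(results, function(r) isTRUE(r$dead), logical(1L)),
    sphase = vapply(results, function(r) isTRUE(r$sphase), logical(1L)))

  summ <- do.call(rbind, lapply(split(fates, fates$condition), function(f) {
    n <- sum(f$ok)
    p_dead <- if (n) 100 * sum(f$dead[f$ok]) / n else NA_real_
    p_sph <- if (n) 100 * sum(f$sphase[f$ok]) / n else NA_real_
    data.frame(condition = f$condition[1L], n_cells = n,
               n_failed = sum(!f$ok),
               fraction_sphase = p_sph, fraction_dead = p_dead,
               sem_sphase = if (n) sem_binomial(p_sph, n) else NA_real_,
               sem_dead = if (n) sem_binomial(p_dead, n) else NA_real_)
  }))
  rownames(summ) <- NULL
  class(summ) <- c("fate_summary", "data.frame")

  out <- list(summary = summ, fates = fates, runs = runs)
  if (keep_trajectories)
    out$trajectories <- lapply(results, `[[`, "traj")
  class(out) <- "population_result"
  out
}

#' @export
print.population_result <- function(x, ...) {
  cat("virtual cell population:", nrow(x$fates), "runs,",
      length(unique(x$fates$condition)), "condition(s)\n")
  print.data.frame(x$summary, digits = 4)
  invisible(x)
}

#' S-phase classification of one trajectory
#'
#' A cell counts as entering S-phase when the summed concentration of the
#' cyclin role species (Cyclin E, A and B in the full model) strictly
#' exceeds the threshold at the evaluation time.
#'
#' @param traj a `cell_trajectory`.
#' @param cyclin_roles character vector of species names; `NULL` raises an
#'   informative error (classification unavailable).
#' @param t_eval_h evaluation time in hours; must lie within the
#'   trajectory.
#' @param threshold threshold in nM (default 20, strict inequality).
#' @param any_time classify on the maximum over all recorded times up to
#'   `t_eval_h` instead of the single time point (off by default).
#' @return logical.
#' @export
classify_sphase <- function(traj, cyclin_roles, t_eval_h,
                            threshold = 20, any_time = FALSE) {
  if (is.null(cyclin_roles) || !length(cyclin_roles))
    stop("cyclin role species not configured; S-phase classification ",
         "unavailable", call. = FALSE)
  t_s <- t_eval_h * 3600
  if (t_s > max(traj$time) + 1e-9)
    stop("evaluation time ", t_eval_h, " h beyond trajectory end (",
         max(traj$time) / 3600, " h)", call. = FALSE)
  if (any_time) {
    upto <- traj$time <= t_s
    tot <- max(rowSums(traj$species[upto, cyclin_roles, drop = FALSE]))
  } else {
    tot <- sum(trajectory_at(traj, cyclin_roles, min(t_s, max(traj$time))))
  }
  tot > threshold
}

#' Binomial standard error of a phenotype percentage
#'
#' `sqrt(p * (100 - p) / n)` with `p` in percent and `n` the number of
#' starting single-cell simulations.
#'
#' @param percentage phenotype percentage in `[0, 100]`.
#' @param n_cells number of cells (>= 1).
#' @return standard error of the mean, in percentage points.
#' @export
sem_binomial <- function(percentage, n_cells) {
  if (any(is.na(percentage)) || any(percentage < 0) || any(percentage > 100))
    stop("percentage must be in [0, 100]", call. = FALSE)
  if (any(n_cells < 1))
    stop("n_cells must be >= 1", call. = FALSE)
  sqrt(percentage * (100 - percentage) / n_cells)
}
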