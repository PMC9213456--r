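# Single-cell simulation loop: stiff ODE integration of the signalling
# network interleaved with the stochastic gene-expression module at a fixed
# exchange interval (30 simulated seconds by default).  In deterministic
# mode the transcript species follow the expected-value window update
# m <- m + dt * (n_copies * f_active * rate_per_copy - k_deg * m) on the
# same grid, so a deterministic run is the average-cell limit of the hybrid
# scheme.

#' Simulation configuration
#'
#' @param flag_deterministic 1 for a fully deterministic run, 0 for hybrid
#'   (stochastic gene expression).
#' @param duration_h total simulated time in hours.
#' @param ligands named numeric vector of ligand concentrations (nM)
#'   overwriting the corresponding species at t = 0.
#' @param doses optional list of later dosing events, each a list with
#'   `time_h` and a named `ligands` vector (sequential protocols such as
#'   conditioning followed by treatment).
#' @param exchange_s exchange-interval length in seconds (default 30).
#' @param seed RNG seed for hybrid runs (ignored in deterministic mode).
#' @param record_stride record every this-many windows (1 = 30 s resolution).
#' @param rtol,atol relative/absolute integrator tolerances (nM).
#' @param clamp_tol concentrations in `(-clamp_tol, 0)` after a window are
#'   clamped to 0 (stiff-integration noise); larger negatives abort.
#' @param output_label free-text label carried into the trajectory.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(flag_deterministic = 1, duration_h = 1,
                              ligands = numeric(), doses = list(),
                              exchange_s = 30, seed = NULL,
                              record_stride = 1L, rtol = 1e-6, atol = 1e-9,
                              clamp_tol = 1e-6, output_label = "cell") {
  stopifnot(duration_h > 0, exchange_s > 0, record_stride >= 1L,
            flag_deterministic %in% c(0, 1))
  structure(list(flag_deterministic = flag_deterministic,
                 duration_h = duration_h, ligands = ligands, doses = doses,
                 exchange_s = exchange_s, seed = seed,
                 record_stride = as.integer(record_stride),
                 rtol = rtol, atol = atol, clamp_tol = clamp_tol,
                 output_label = output_label),
            class = "simulation_config")
}

#' Apply a ligand dose to a state vector
#'
#' Sets the listed species to the given concentrations (nM); all other
#' entries are untouched.
#'
#' @param state named numeric state vector (nM).
#' @param ligands named numeric vector of doses.
#' @return the updated state.
#' @export
apply_ligands <- function(state, ligands) {
  if (!length(ligands)) return(state)
  unknown <- setdiff(names(ligands), names(state))
  if (length(unknown))
    stop("unknown ligand species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  state[names(ligands)] <- ligands
  state
}

#' Death criterion: cleaved PARP exceeds PARP
#'
#' @param state named numeric state vector (nM).
#' @param cm a `compiled_model` whose `death_roles` maps `parp` and `cparp`
#'   to species names; with no mapping the check is disabled and returns
#'   `FALSE`.
#' @return logical.
#' @export
check_death <- function(state, cm) {
  roles <- cm$death_roles
  if (is.null(roles) || !all(c("parp", "cparp") %in% names(roles)))
    return(FALSE)
  unname(state[roles[["cparp"]]] > state[roles[["parp"]]])
}

#' Simulate one cell
#'
#' Runs the hybrid (or fully deterministic) single-cell simulation: ligand
#' doses overwrite the initial state at t = 0, then the signalling ODEs are
#' integrated over consecutive exchange windows with a stiff solver
#' (`deSolve::lsoda`); at each window boundary the gene-expression module
#' updates transcript species (stochastically in hybrid mode, by the
#' expected-value update in deterministic mode), scheduled later doses are
#' applied, and the death criterion is checked.  The run stops at the
#' requested duration or at the end of the window in which the cell dies.
#'
#' @param cm a `compiled_model`.
#' @param cfg a [simulation_config()].
#' @return an object of class `cell_trajectory` with elements `time`
#'   (seconds), `species` (time points x species, nM), `genes` (recorded
#'   windows x genes, active copies; expected copies in deterministic
#'   mode), `mrna` (recorded windows x genes, mpc) and `died_at` (seconds,
#'   or `NA`).
#' @export
simulate_cell <- function(cm, cfg) {
  stopifnot(inherits(cm, "compiled_model"), inherits(cfg, "simulation_config"))
  hybrid <- cfg$flag_deterministic == 0
  if (hybrid && !is.null(cfg$seed)) set.seed(cfg$seed)

  dt <- cfg$exchange_s
  n_windows <- floor(cfg$duration_h * 3600 / dt)
  state <- apply_ligands(cm$init, cfg$ligands)

  doses <- cfg$doses
  dose_windows <- if (length(doses))
    vapply(doses, function(d) as.integer(round(d$time_h * 3600 / dt)), integer(1L))
  else integer()

  genes <- cm$genes
  ng <- nrow(genes)
  has_tr <- !is.na(genes$transcript)
  tr_idx <- match(genes$transcript[has_tr], cm$species)
  tr_vol <- unname(cm$comp_vols[genes$transcript_comp[has_tr]])

  if (hybrid) {
    gs <- init_gene_state(genes)
    active <- gs$active; mrna <- as.numeric(gs$mrna)
  } else {
    active <- genes$gene_copy_number * genes$f_active
    mrna <- genes$mrna_mpc
  }
  # transcript species start from the gene-expression state
  if (any(has_tr))
    state[tr_idx] <- mpc_to_nM(mrna[has_tr], tr_vol)

  n_rec <- n_windows %/% cfg$record_stride
  times <- numeric(n_rec + 1L)
  spmat <- matrix(NA_real_, n_rec + 1L, length(cm$species),
                  dimnames = list(NULL, cm$species))
  gmat <- matrix(NA_real_, n_rec + 1L, ng, dimnames = list(NULL, genes$gene))
  mmat <- matrix(NA_real_, n_rec + 1L, ng, dimnames = list(NULL, genes$gene))
  times[1L] <- 0; spmat[1L, ] <- state; gmat[1L, ] <- active; mmat[1L, ] <- mrna
  rec <- 1L
  died_at <- NA_real_

  p <- cm$param_values
  odefun <- function(t, y, parms) list(cm$rhs(t, y, parms))

  for (w in seq_len(n_windows)) {
    sol <- deSolve::lsoda(y = unname(state), times = c(0, dt), func = odefun,
                          parms = p, rtol = cfg$rtol, atol = cfg$atol)
    if (attr(sol, "istate")[1L] < 0)
      stop("ODE integration failed at t = ", (w - 1L) * dt, " s", call. = FALSE)
    newstate <- sol[2L, -1L]
    neg <- newstate < 0
    if (any(neg)) {
      if (any(newstate < -cfg$clamp_tol))
        stop("negative concentration beyond tolerance at t = ", w * dt,
             " s (species ", cm$species[which.min(newstate)], " = ",
             min(newstate), " nM)", call. = FALSE)
      newstate[neg] <- 0
    }
    state <- stats::setNames(newstate, cm$species)

    # gene-expression update with rates frozen at the window start
    rate_per_copy <- transcription_rates(genes, cm$regulation, state)
    if (hybrid) {
      active <- step_gene_states(active, genes$gene_copy_number,
                                 genes$k_gene_activation,
                                 genes$k_gene_inactivation, dt)
      mrna <- step_mrna_counts(mrna, active, rate_per_copy,
                               genes$k_mrna_degradation, dt)
    } else {
      mrna <- mrna + dt * (active * rate_per_copy -
                             genes$k_mrna_degradation * mrna)
    }
    if (any(has_tr))
      state[tr_idx] <- mpc_to_nM(mrna[has_tr], tr_vol)

    hit <- which(dose_windows == w)
    for (d in hit) state <- apply_ligands(state, doses[[d]]$ligands)

    if (w %% cfg$record_stride == 0L) {
      rec <- rec + 1L
      times[rec] <- w * dt
      spmat[rec, ] <- state
      gmat[rec, ] <- active
      mmat[rec, ] <- mrna
    }

    if (check_death(state, cm)) { died_at <- w * dt; break }
  }

  structure(list(time = times[seq_len(rec)],
                 species = spmat[seq_len(rec), , drop = FALSE],
                 genes = gmat[seq_len(rec), , drop = FALSE],
                 mrna = mmat[seq_len(rec), , drop = FALSE],
                 died_at = died_at, label = cfg$output_label,
                 flag_deterministic = cfg$flag_deterministic,
                 seed = cfg$seed),
            class = "cell_trajectory")
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat("cell trajectory '", x$label, "': ", length(x$time), " time points over ",
      max(x$time), " s (", if (x$flag_deterministic == 1) "deterministic"
      else "hybrid", " mode), ",
      ncol(x$species), " species, ", ncol(x$genes), " genes\n", sep = "")
  cat("  fate:", if (is.na(x$died_at)) "alive at end"
      else paste0("died at ", x$died_at, " s"), "\n")
  invisible(x)
}

#' Interpolate species concentrations at a time point
#'
#' @param traj a `cell_trajectory`.
#' @param species species name(s).
#' @param t_s time in seconds; must lie within the trajectory.
#' @return named numeric vector.
#' @export
trajectory_at <- function(traj, species, t_s) {
  if (t_s < min(traj$time) || t_s > max(traj$time))
    stop("time ", t_s, " s outside trajectory [", min(traj$time), ", ",
         max(traj$time), "]", call. = FALSE)
  vapply(species, function(s)
    stats::approx(traj$time, traj$species[, s], xout = t_s)$y, numeric(1L))
}

#' Write a trajectory's three matrices as TSV files
#'
#' Emits `<label>_species.tsv` (time and species concentrations),
#' `<label>_genes.tsv` (active gene copies per window) and
#' `<label>_time.tsv` (time points in seconds).
#'
#' @param traj a `cell_trajectory`.
#' @param directory output directory.
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(directory, traj$label)
  p1 <- paste0(base, "_species.tsv")
  utils::write.table(data.frame(time_s = traj$time, traj$species,
                                check.names = FALSE),
                     p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- paste0(base, "_genes.tsv")
  utils::write.table(data.frame(time_s = traj$time, traj$genes,
                                check.names = FALSE),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  p3 <- paste0(base, "_time.tsv")
  utils::write.table(data.frame(time_s = traj$time), p3, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
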