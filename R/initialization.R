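# Initialization calibration: map omics abundances to model targets, fit
# translation rate constants by iterative proportional updates at the
# unstimulated steady state, check starved-cell phenotype criteria, and
# provide single-parameter scans and coordinate-wise trajectory fitting.

#' Derive per-gene total-protein calibration targets
#'
#' Measured genes use the proteomics copy number directly; genes without
#' proteomics are imputed from mRNA via a gene-level protein/mRNA ratio.
#' Counts are converted to reference-compartment nM.
#'
#' @param genes gene bundle data frame (from a `compiled_model` or parsed
#'   omics table).
#' @param ratios named numeric vector of protein/mRNA ratios for imputed
#'   genes (may be empty when all genes are measured).
#' @param volume reference-compartment volume in liters.
#' @return data frame with `gene`, `target_nM`, `source`
#'   (`"measured"`/`"imputed"`).
#' @export
derive_targets <- function(genes, ratios = numeric(), volume) {
  n <- nrow(genes)
  target <- numeric(n); source <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(genes$protein_mpc[i])) {
      target[i] <- mpc_to_nM(genes$protein_mpc[i], volume)
      source[i] <- "measured"
    } else if (!is.na(genes$mrna_mpc[i]) && genes$gene[i] %in% names(ratios)) {
      target[i] <- mpc_to_nM(genes$mrna_mpc[i] * ratios[[genes$gene[i]]], volume)
      source[i] <- "imputed"
    } else {
      stop("gene '", genes$gene[i],
           "' has neither protein abundance nor an mRNA ratio", call. = FALSE)
    }
  }
  data.frame(gene = genes$gene, target_nM = target, source = source,
             stringsAsFactors = FALSE)
}

#' Volume-corrected total abundance of each gene's protein products
#'
#' Sums, per gene, `state_i * V_home(i) / V_ref` over every non-transcript
#' species whose gene-id list contains the gene.
#'
#' @param cm a `compiled_model`.
#' @param state named species state (nM).
#' @return named numeric vector, one total per gene in the bundle.
#' @export
gene_protein_totals <- function(cm, state) {
  Vh <- unname(cm$comp_vols[cm$species_comp[cm$species]])
  Vref <- cm$comp_vols[[cm$observable_reference]]
  idlists <- lapply(strsplit(cm$species_gene_ids[cm$species], ","), trimws)
  out <- stats::setNames(numeric(nrow(cm$genes)), cm$genes$gene)
  for (g in cm$genes$gene) {
    member <- vapply(seq_along(idlists), function(i)
      !cm$is_transcript[[i]] && g %in% idlists[[i]], logical(1L))
    out[[g]] <- sum(as.numeric(state[member]) * Vh[member]) / Vref
  }
  out
}

#' Deterministic unstimulated steady state
#'
#' Pins each transcript species at its deterministic stationary level
#' (`n_copies * f_active * k_const / k_deg`, converted to nM) -- at the
#' unstimulated stationary point the expected mRNA is constant, so the
#' exchange grid collapses and the signalling ODEs can be integrated
#' directly over a long horizon.  Stationarity is assessed by the scaled
#' derivative norm at the final state.
#'
#' @param cm a `compiled_model`.
#' @param hours equilibration horizon in simulated hours (default 1000).
#' @param rtol,atol integrator tolerances.
#' @return list with `state` (named nM vector), `stationary` (logical) and
#'   `residual` (max |dy/dt| * hours*3600 / max(|y|, atol)).
#' @export
steady_state <- function(cm, hours = 1000, rtol = 1e-6, atol = 1e-9) {
  state <- cm$init
  genes <- cm$genes
  has_tr <- !is.na(genes$transcript)
  if (any(has_tr)) {
    m_star <- ifelse(genes$k_mrna_degradation[has_tr] > 0,
                     genes$gene_copy_number[has_tr] * genes$f_active[has_tr] *
                       genes$k_transcription_const[has_tr] /
                       genes$k_mrna_degradation[has_tr],
                     genes$mrna_mpc[has_tr])
    state[match(genes$transcript[has_tr], cm$species)] <-
      mpc_to_nM(m_star, unname(cm$comp_vols[genes$transcript_comp[has_tr]]))
  }
  odefun <- function(t, y, parms) list(cm$rhs(t, y, parms))
  tend <- hours * 3600
  sol <- deSolve::lsoda(unname(state), times = c(0, tend / 4, tend / 2, tend),
                        func = odefun, parms = cm$param_values,
                        rtol = rtol, atol = atol)
  final <- stats::setNames(pmax(sol[nrow(sol), -1L], 0), cm$species)
  dy <- evaluate_rhs(cm, final)
  resid <- max(abs(dy) * tend / pmax(abs(final), atol))
  list(state = final, stationary = resid < 1e-3, residual = resid)
}

#' Calibrate translation rate constants to protein targets
#'
#' Iterative proportional fitting: simulate to the unstimulated steady
#' state, compute each gene's volume-corrected total protein, multiply its
#' translation rate constant by `target/current`, and repeat until every
#' non-excluded gene total is within `tol` of its target or the iteration
#' cap is reached.  Exact in one step for linear production-decay chains;
#' geometric convergence otherwise.
#'
#' @param cm a `compiled_model` with resolvable translation parameters.
#' @param targets data frame from [derive_targets()] (or with columns
#'   `gene` and `target_nM`).
#' @param excluded genes (or equivalently their observables) skipped in the
#'   update but still reported.
#' @param tol relative tolerance on each gene total (default 1 percent).
#' @param max_iter iteration cap (default 25).
#' @param ss_hours steady-state horizon passed to [steady_state()].
#' @param translation_params optional named character vector (gene ->
#'   global parameter name) overriding the automatically discovered
#'   translation parameters.
#' @return list with `model` (updated `compiled_model`, initial state set
#'   to the reached steady state), `report` (per-gene data frame),
#'   `converged`, `iterations`.
#' @export
calibrate_translation <- function(cm, targets, excluded = character(),
                                  tol = 0.01, max_iter = 25, ss_hours = 1000,
                                  translation_params = NULL) {
  if (!is.null(translation_params)) {
    unknown <- setdiff(translation_params, names(cm$param_values))
    if (length(unknown))
      stop("unknown translation parameter(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    i <- match(names(translation_params), cm$genes$gene)
    if (anyNA(i))
      stop("unknown gene(s) in translation_params", call. = FALSE)
    cm$genes$translation_param[i] <- unname(translation_params)
  }
  tgt <- stats::setNames(targets$target_nM, targets$gene)
  fit_genes <- cm$genes$gene[!is.na(cm$genes$translation_param) &
                               cm$genes$gene %in% names(tgt) &
                               !cm$genes$gene %in% excluded]
  converged <- FALSE
  it <- 0L
  ss <- NULL
  while (it < max_iter) {
    it <- it + 1L
    ss <- steady_state(cm, hours = ss_hours)
    current <- gene_protein_totals(cm, ss$state)
    rel <- abs(current[fit_genes] - tgt[fit_genes]) /
      pmax(tgt[fit_genes], .Machine$double.eps)
    zero_tgt <- tgt[fit_genes] == 0
    ok <- (zero_tgt & current[fit_genes] == 0) | (!zero_tgt & rel <= tol)
    if (all(ok)) { converged <- TRUE; break }
    for (g in fit_genes[!ok]) {
      pn <- cm$genes$translation_param[cm$genes$gene == g]
      if (current[[g]] == 0 && tgt[[g]] > 0)
        stop("gene '", g, "': zero steady-state total with nonzero target; ",
             "cannot scale translation rate", call. = FALSE)
      factor <- tgt[[g]] / current[[g]]
      cm <- set_parameters(cm, stats::setNames(cm$param_values[[pn]] * factor, pn))
    }
  }
  ss <- steady_state(cm, hours = ss_hours)
  current <- gene_protein_totals(cm, ss$state)
  cm$init <- ss$state
  report <- data.frame(
    gene = cm$genes$gene,
    target_nM = unname(tgt[cm$genes$gene]),
    reached_nM = unname(current[cm$genes$gene]),
    translation_param = cm$genes$translation_param,
    k_translation = unname(cm$param_values[cm$genes$translation_param]),
    fitted = cm$genes$gene %in% fit_genes,
    stringsAsFactors = FALSE)
  if (!converged)
    warning("translation calibration did not converge for: ",
            paste(fit_genes[!((tgt[fit_genes] == 0 & current[fit_genes] == 0) |
                                (tgt[fit_genes] > 0 &
                                   abs(current[fit_genes] / tgt[fit_genes] - 1) <= tol))],
                  collapse = ", "), call. = FALSE)
  list(model = cm, report = report, converged = converged, iterations = it)
}

#' Starved-cell phenotype check
#'
#' Simulates the model deterministically with no ligands over the horizon
#' and reports whether the death criterion (cleaved PARP exceeding PARP)
#' or the S-phase criterion (summed cyclins above the threshold) is
#' violated, with the violation times.  Criteria whose role species are
#' not configured are reported as unavailable and pass vacuously.
#'
#' @param cm a `compiled_model`.
#' @param horizon_h horizon in hours (default 48).
#' @param forbid_death,forbid_sphase which behaviours are violations.
#' @param sphase_threshold summed-cyclin threshold in nM (default 20).
#' @param record_stride window stride for recording.
#' @return list with `pass`, `death` and `sphase` sub-reports and the
#'   trajectory.
#' @export
phenotype_check <- function(cm, horizon_h = 48, forbid_death = TRUE,
                            forbid_sphase = TRUE, sphase_threshold = 20,
                            record_stride = 10L) {
  stopifnot(horizon_h > 0)
  cfg <- simulation_config(flag_deterministic = 1, duration_h = horizon_h,
                           record_stride = record_stride,
                           output_label = "phenotype_check")
  traj <- simulate_cell(cm, cfg)

  death <- list(available = !is.null(cm$death_roles), violated = FALSE,
                time_s = NA_real_)
  if (death$available) {
    death$violated <- !is.na(traj$died_at)
    death$time_s <- traj$died_at
  }

  sphase <- list(available = !is.null(cm$cyclin_roles), violated = FALSE,
                 time_s = NA_real_)
  if (sphase$available) {
    tot <- rowSums(traj$species[, cm$cyclin_roles, drop = FALSE])
    hit <- which(tot > sphase_threshold)
    if (length(hit)) {
      sphase$violated <- TRUE
      sphase$time_s <- traj$time[hit[1L]]
    }
  }
  pass <- !(forbid_death && death$violated) && !(forbid_sphase && sphase$violated)
  notices <- c(
    if (!death$available) "death roles not configured; death check disabled",
    if (!sphase$available) "cyclin roles not configured; S-phase check disabled")
  list(pass = pass, death = death, sphase = sphase, notices = notices,
       trajectory = traj)
}

#' Single-parameter scan against a trajectory criterion
#'
#' Evaluates a predicate over deterministic simulations on a log-uniform
#' grid between `low` and `high` and selects the smallest passing value.
#'
#' @param cm a `compiled_model`.
#' @param name global parameter name.
#' @param low,high scan bounds (`low < high`, both > 0).
#' @param n_points grid size (default 25); `1` evaluates at `low` only.
#' @param criterion function of a `cell_trajectory` returning a logical.
#' @param cfg base [simulation_config()] for the evaluations.
#' @return list with `selected` (value or `NA` when nothing passes) and
#'   `table` (data frame of value, pass).
#' @export
scan_parameter <- function(cm, name, low, high, n_points = 25, criterion,
                           cfg = simulation_config()) {
  if (!name %in% names(cm$param_values))
    stop("unknown parameter: ", name, call. = FALSE)
  if (n_points == 1L) grid <- low
  else {
    stopifnot(low < high, low > 0)
    grid <- 10^seq(log10(low), log10(high), length.out = n_points)
  }
  pass <- vapply(grid, function(v) {
    m2 <- set_parameters(cm, stats::setNames(v, name))
    isTRUE(criterion(simulate_cell(m2, cfg)))
  }, logical(1L))
  sel <- if (any(pass)) grid[which(pass)[1L]] else NA_real_
  list(selected = sel, table = data.frame(value = grid, pass = pass))
}

#' Coordinate-wise trajectory fitting
#'
#' Fits parameters one at a time, in order, keeping the best value found at
#' each step: for each parameter a log grid spanning `value * 10^(+/-
#' log10_halfwidth)` is searched for the value minimizing the sum of
#' squared errors between the simulated observable and the reference
#' trajectory.  The current value always lies on the grid (odd `n_grid`),
#' so the SSE never increases across steps; ties are broken toward the
#' current value.
#'
#' @param cm a `compiled_model`.
#' @param param_names ordered character vector of global parameter names.
#' @param reference list with `time` (seconds) and `values` for one
#'   observable or species.
#' @param observable name of the observable column (or species, with
#'   `use_species = TRUE`) compared against the reference.
#' @param log10_halfwidth half-width of the search range in log10 units
#'   (default 2).
#' @param n_grid points per parameter (default 25; forced odd).
#' @param cfg base [simulation_config()].
#' @param use_species compare a raw species concentration instead of an
#'   observable.
#' @return list with `values` (named numeric, fitted), `sse` (final), and
#'   `path` (per-step data frame).
#' @export
coordinate_fit <- function(cm, param_names, reference, observable,
                           log10_halfwidth = 2, n_grid = 25,
                           cfg = simulation_config(), use_species = FALSE) {
  if (n_grid %% 2L == 0L) n_grid <- n_grid + 1L
  sse_of <- function(m2) {
    traj <- simulate_cell(m2, cfg)
    sim <- if (use_species)
      vapply(reference$time, function(tt)
        stats::approx(traj$time, traj$species[, observable], xout = tt)$y,
        numeric(1L))
    else
      vapply(reference$time, function(tt) {
        i <- findInterval(tt, traj$time, all.inside = TRUE)
        w <- (tt - traj$time[i]) / (traj$time[i + 1L] - traj$time[i])
        o1 <- observable_values(m2, traj$species[i, ])[[observable]]
        o2 <- observable_values(m2, traj$species[i + 1L, ])[[observable]]
        (1 - w) * o1 + w * o2
      }, numeric(1L))
    sum((sim - reference$values)^2)
  }
  path <- list()
  for (pn in param_names) {
    v0 <- cm$param_values[[pn]]
    grid <- v0 * 10^seq(-log10_halfwidth, log10_halfwidth, length.out = n_grid)
    sse <- vapply(grid, function(v)
      sse_of(set_parameters(cm, stats::setNames(v, pn))), numeric(1L))
    best <- which(sse <= min(sse) + 0)
    pick <- best[which.min(abs(log10(grid[best]) - log10(v0)))]
    cm <- set_parameters(cm, stats::setNames(grid[pick], pn))
    path[[length(path) + 1L]] <- data.frame(parameter = pn, value = grid[pick],
                                            sse = sse[pick],
                                            stringsAsFactors = FALSE)
  }
  path <- do.call(rbind, path)
  list(values = stats::setNames(path$value, path$parameter),
       sse = path$sse[nrow(path)], path = path, model = cm)
}
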