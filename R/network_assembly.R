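# Compile a validated model input set into an executable reaction network.
#
# Unit conventions: concentrations are nM relative to each species' home
# compartment; rate laws evaluate in the reaction's home compartment, so a
# reactant living elsewhere enters a mass-action law as c * V_home/V_rxn
# (the EGF/EGFR-style cross-compartment correction).  Each species'
# derivative contribution is S_ij * v_j * V_rxn/V_home(i), which keeps all
# state variables in home-compartment nM.  Formula rate laws are taken
# verbatim: any volume correction inside a user formula is the author's
# responsibility.

#' Compile a model input set into an executable reaction network
#'
#' Builds the rate-law expression list (mass-action laws assembled from the
#' stoichiometric matrix with cross-compartment volume corrections, formula
#' laws parsed verbatim), renames every local parameter to a unique global
#' name (`k<reaction index>` for a mass-action constant,
#' `k<reaction index>_<n>` for formula parameters, ascending in rate-law
#' order), and assembles the gene-expression rate bundle from the omics
#' table.
#'
#' @param m a validated `model_input_set`.
#' @param observable_reference compartment whose volume normalizes
#'   volume-corrected observables (default `"Cytoplasm"`).
#' @param death_roles named character vector `c(parp = , cparp = )` mapping
#'   the death-criterion roles to species names, or `NULL` to disable the
#'   death check.
#' @param cyclin_roles character vector of species names summed for the
#'   S-phase criterion, or `NULL`.
#' @param strict passed to [validate_input_set()]; compilation refuses
#'   inconsistent input.
#' @return an object of class `compiled_model`.
#' @export
compile_model <- function(m, observable_reference = "Cytoplasm",
                          death_roles = NULL, cyclin_roles = NULL,
                          strict = TRUE) {
  rep <- validate_input_set(m, strict = strict)
  if (!attr(rep, "pass"))
    stop("refusing to compile an inconsistent model input set", call. = FALSE)

  sp <- m$species$species
  comp_vols <- stats::setNames(m$compartments$volume_L, m$compartments$compartment)
  species_comp <- stats::setNames(m$species$compartment, sp)
  S <- m$stoich
  nr <- length(m$reactions)

  rate_exprs <- vector("list", nr)
  ptab <- list()
  rxn_names <- vapply(m$reactions, `[[`, character(1L), "reaction")
  rxn_comp <- vapply(m$reactions, `[[`, character(1L), "compartment")

  for (j in seq_len(nr)) {
    r <- m$reactions[[j]]
    if (r$type == "mass_action") {
      gname <- paste0("k", j)
      ptab[[length(ptab) + 1L]] <- data.frame(
        global = gname, reaction = r$reaction, local = "k",
        value = r$rate_constant, stringsAsFactors = FALSE)
      ex <- as.symbol(gname)
      reactants <- which(S[, j] < 0)
      Vr <- comp_vols[[r$compartment]]
      for (i in reactants) {
        ratio <- comp_vols[[species_comp[[sp[i]]]]] / Vr
        term <- if (ratio == 1) as.symbol(sp[i]) else
          call("*", as.symbol(sp[i]), ratio)
        pw <- abs(S[i, j])
        if (pw != 1) term <- call("^", term, pw)
        ex <- call("*", ex, term)
      }
      rate_exprs[[j]] <- ex
    } else {
      ex <- parse_ratelaw(r$formula, r$reaction)
      locals <- names(r$params)
      globals <- paste0("k", j, "_", seq_along(locals))
      map <- stats::setNames(lapply(globals, as.symbol), locals)
      rate_exprs[[j]] <- substitute_symbols(ex, map)
      for (q in seq_along(locals))
        ptab[[length(ptab) + 1L]] <- data.frame(
          global = globals[q], reaction = r$reaction, local = locals[q],
          value = unname(r$params[q]), stringsAsFactors = FALSE)
    }
  }
  params <- if (length(ptab)) do.call(rbind, ptab) else
    data.frame(global = character(), reaction = character(),
               local = character(), value = numeric(), stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(params$global))
  param_values <- stats::setNames(params$value, params$global)

  genes <- build_gene_bundle(m, rate_exprs, params, rxn_names, species_comp)

  cm <- structure(list(
    species = sp,
    init = stats::setNames(m$species$initial_nM, sp),
    stoich = S,
    reactions = rxn_names,
    rxn_compartment = rxn_comp,
    rate_exprs = rate_exprs,
    params = params,
    param_values = param_values,
    comp_vols = comp_vols,
    species_comp = species_comp,
    species_gene_ids = stats::setNames(m$species$gene_ids, sp),
    is_transcript = stats::setNames(m$species$is_transcript, sp),
    genes = genes,
    regulation = m$regulation$entries,
    observables = m$observables,
    observable_reference = observable_reference,
    compartments_go = stats::setNames(m$compartments$go_term,
                                      m$compartments$compartment),
    death_roles = death_roles,
    cyclin_roles = cyclin_roles), class = "compiled_model")
  cm$rhs <- build_rhs(cm)
  cm
}

build_gene_bundle <- function(m, rate_exprs, params, rxn_names, species_comp) {
  g <- m$genes
  tr <- m$species$species[m$species$is_transcript]
  names(tr) <- m$species$transcript_of[m$species$is_transcript]
  g$transcript <- unname(tr[g$gene])
  g$transcript_comp <- ifelse(is.na(g$transcript), NA_character_,
                              species_comp[g$transcript])
  g$f_active <- ifelse(g$k_gene_activation + g$k_gene_inactivation > 0,
                       g$k_gene_activation /
                         (g$k_gene_activation + g$k_gene_inactivation), 0)
  # translation parameter: first parameter of the formula reaction that
  # consumes this gene's transcript symbol and produces a species carrying
  # the gene id
  g$translation_param <- NA_character_
  for (i in seq_len(nrow(g))) {
    if (is.na(g$transcript[i])) next
    for (j in seq_along(rate_exprs)) {
      syms <- expr_symbols(rate_exprs[[j]])
      if (!g$transcript[i] %in% syms) next
      prods <- rownames(m$stoich)[m$stoich[, j] > 0]
      carries <- vapply(prods, function(spn) {
        ids <- strsplit(m$species$gene_ids[m$species$species == spn], ",")[[1L]]
        g$gene[i] %in% trimws(ids)
      }, logical(1L))
      if (!any(carries)) next
      cand <- params$global[params$reaction == rxn_names[j]]
      if (length(cand)) { g$translation_param[i] <- cand[1L]; break }
    }
  }
  g
}

build_rhs <- function(cm) {
  sp <- cm$species
  smap <- stats::setNames(
    lapply(seq_along(sp), function(i) call("[", quote(y), i)), sp)
  pmap <- stats::setNames(
    lapply(seq_along(cm$param_values), function(j) call("[", quote(p), j)),
    names(cm$param_values))
  vmap <- as.list(cm$comp_vols)
  exprs <- lapply(cm$rate_exprs, substitute_symbols, map = c(smap, pmap, vmap))
  vcall <- as.call(c(list(quote(c)), exprs))
  Vr <- unname(cm$comp_vols[cm$rxn_compartment])
  Vh_inv <- 1 / unname(cm$comp_vols[cm$species_comp[sp]])
  S <- unname(cm$stoich)
  f <- eval(call("function", as.pairlist(alist(t = , y = , p = )),
                 bquote({
                   v <- .(vcall)
                   drop(S %*% (v * Vr)) * Vh_inv
                 })))
  environment(f) <- list2env(list(S = S, Vr = Vr, Vh_inv = Vh_inv),
                             parent = baseenv())
  compiler::cmpfun(f)
}

#' Reaction fluxes at a state
#'
#' Evaluates every rate-law expression (nM/s in each reaction's home
#' compartment) at the given state.
#'
#' @param cm a `compiled_model`.
#' @param state named or ordered numeric vector of concentrations (nM).
#' @return numeric vector of fluxes, one per reaction.
#' @export
reaction_fluxes <- function(cm, state) {
  env <- list2env(c(as.list(stats::setNames(as.numeric(state), cm$species)),
                    as.list(cm$param_values), as.list(cm$comp_vols)),
                  parent = baseenv())
  vapply(cm$rate_exprs, eval, numeric(1L), envir = env)
}

#' Evaluate the ODE right-hand side
#'
#' Returns `d(state)/dt` for the deterministic module:
#' `S %*% v(state)` with each flux scaled by the ratio of the reaction's
#' compartment volume to the species' home-compartment volume.  The system
#' is autonomous; `t` is accepted for solver compatibility only.
#'
#' @param cm a `compiled_model`.
#' @param state numeric vector of concentrations (nM), in species order.
#' @param t time in seconds (unused).
#' @return numeric vector of derivatives (nM/s), in species order.
#' @export
evaluate_rhs <- function(cm, state, t = 0) {
  state <- as.numeric(state)
  if (length(state) != length(cm$species))
    stop("state length ", length(state), " != species count ",
         length(cm$species), call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite state entry at index ",
         which(!is.finite(state))[1L], call. = FALSE)
  cm$rhs(t, state, cm$param_values)
}

#' Set global parameter values on a compiled model
#'
#' @param cm a `compiled_model`.
#' @param values named numeric vector; names are global parameter names
#'   from the parameter table.
#' @return the updated `compiled_model`.
#' @export
set_parameters <- function(cm, values) {
  unknown <- setdiff(names(values), names(cm$param_values))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cm$param_values[names(values)] <- values
  cm$params$value <- unname(cm$param_values[cm$params$global])
  cm
}

#' Volume-corrected observable values
#'
#' For observable `j`: `sum_i O_ij * state_i * V_home(i) / V_ref`, with the
#' reference volume taken from the model's `observable_reference`
#' compartment (cytoplasm by default), so each observable is the total
#' abundance of a protein across compartments expressed in
#' reference-compartment nM.
#'
#' @param cm a `compiled_model`.
#' @param state numeric vector of concentrations (nM) in species order.
#' @return named numeric vector, one value per observable column.
#' @export
observable_values <- function(cm, state) {
  O <- cm$observables
  Vh <- unname(cm$comp_vols[cm$species_comp[cm$species]])
  Vref <- cm$comp_vols[[cm$observable_reference]]
  drop(crossprod(O, as.numeric(state) * Vh)) / Vref
}

#' Human-readable reaction-listing export
#'
#' Writes a plain-text listing of the compiled network -- compartments,
#' species with home compartments and initial values, global parameters
#' with their source reactions, and reactions with their rate laws -- in a
#' stable order, for inspection and fine-tuning in a text editor.
#'
#' @param cm a `compiled_model`.
#' @param file optional path; when given the text is also written there.
#' @return the text as a character vector of lines, invisibly when `file`
#'   is given.
#' @export
export_model_text <- function(cm, file = NULL) {
  lines <- c("# reaction-network model listing",
             "", "## compartments (name, volume_L)")
  lines <- c(lines, paste0(names(cm$comp_vols), "\t", fmt_num(unname(cm$comp_vols))))
  lines <- c(lines, "", "## species (name, compartment, initial_nM)")
  lines <- c(lines, paste0(cm$species, "\t", unname(cm$species_comp[cm$species]),
                           "\t", fmt_num(unname(cm$init))))
  lines <- c(lines, "", "## parameters (global, reaction, local, value)")
  p <- cm$params
  lines <- c(lines, paste(p$global, p$reaction, p$local, fmt_num(p$value), sep = "\t"))
  lines <- c(lines, "", "## reactions (name, compartment, rate_law)")
  lines <- c(lines, vapply(seq_along(cm$reactions), function(j)
    paste(cm$reactions[j], cm$rxn_compartment[j],
          deparse_one(cm$rate_exprs[[j]]), sep = "\t"), character(1L)))
  if (nrow(cm$regulation)) {
    e <- cm$regulation
    lines <- c(lines, "", "## regulation (gene, regulator, role, hill, halfmax_nM)")
    lines <- c(lines, paste(e$gene, e$regulator, e$role, fmt_num(e$hill),
                            fmt_num(e$halfmax), sep = "\t"))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Export the full parameter table (ParamsAll-style report)
#'
#' @param cm a `compiled_model`.
#' @param file path of the TSV to write.
#' @return invisibly, the parameter data frame.
#' @export
export_parameter_report <- function(cm, file) {
  p <- cm$params
  lines <- c("global\treaction\tlocal\tvalue",
             paste(p$global, p$reaction, p$local, fmt_num(p$value), sep = "\t"))
  writeLines(lines, file)
  invisible(p)
}

#' @export
print.compiled_model <- function(x, ...) {
  cat("compiled reaction network:", length(x$species), "species,",
      length(x$reactions), "reactions,", nrow(x$params), "parameters,",
      length(x$comp_vols), "compartments\n")
  cat("  gene-expression bundle:", nrow(x$genes), "genes (",
      sum(!is.na(x$genes$transcript)), "with transcript species )\n")
  cat("  death roles:", if (is.null(x$death_roles)) "unset" else
    paste(names(x$death_roles), x$death_roles, sep = "=", collapse = ", "),
    "; cyclin roles:", if (is.null(x$cyclin_roles)) "unset" else
      paste(x$cyclin_roles, collapse = "+"), "\n")
  invisible(x)
}

#' @export
summary.compiled_model <- function(object, ...) {
  print(object)
  cat("  mass-action laws:",
      sum(grepl("^k[0-9]+$", object$params$global) & object$params$local == "k"),
      " formula parameters:", sum(object$params$local != "k"), "\n")
  invisible(object)
}
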