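# Fixture generator: complete, valid toy model input sets in the exact TSV
# dialects, with analytically known behaviour (telegraph genes, linear
# translation/decay chains, an optional cross-compartment ligand-receptor
# binding step, Michaelis-Menten signal production, a tunable death pair
# and a tunable cyclin triple).  Everything is sampled deterministically
# from the spec seed, so the same spec yields byte-identical files.

#' Toy-model specification
#'
#' @param n_genes number of telegraph genes (each with a transcript and a
#'   protein species, translation and protein-decay reactions).
#' @param n_signal_species downstream species produced from the first
#'   gene's protein through a Michaelis-Menten law (ensures the formula
#'   compiler branch is exercised); may be 0.
#' @param include_ligand add an extracellular ligand, a cytoplasmic
#'   receptor and a binding/unbinding pair spanning compartments.
#' @param include_death_pair add PARP/cleaved-PARP species and a tunable
#'   cleavage reaction (death-criterion roles).
#' @param include_cyclin_triple add Cyclin E/A/B species with tunable
#'   zeroth-order induction (S-phase-criterion roles).
#' @param regulation optional data frame with columns `gene`, `regulator`,
#'   `hill` (signed: positive activates), `halfmax` (nM) describing
#'   GeneReg entries.
#' @param copies gene copy number before scaling (default 2).
#' @param copy_scale multiplies copy numbers and divides per-copy
#'   transcription rates, preserving mean expression while shrinking
#'   relative fluctuations (law-of-large-numbers studies).
#' @param k_cleave PARP cleavage rate constant (1/s).
#' @param k_cyclin_induction zeroth-order cyclin induction rate (nM/s).
#' @param rate_ranges named list of `c(low, high)` sampling intervals
#'   overriding the defaults for `k_act`, `k_inact`, `k_tc_const`,
#'   `k_deg_m`, `protein_mpc`, `half_life` (a degenerate interval pins the
#'   constant).
#' @param seed RNG seed; same seed, same files.
#' @return an object of class `toy_spec`.
#' @export
toy_spec <- function(n_genes = 2L, n_signal_species = 1L,
                     include_ligand = TRUE, include_death_pair = FALSE,
                     include_cyclin_triple = FALSE, regulation = NULL,
                     copies = 2L, copy_scale = 1L,
                     k_cleave = 1e-9, k_cyclin_induction = 1e-6,
                     rate_ranges = list(), seed = 1L) {
  stopifnot(n_genes >= 1L, n_signal_species >= 0L, copies >= 1L,
            copy_scale >= 1L)
  if (!is.null(regulation))
    stopifnot(all(c("gene", "regulator", "hill", "halfmax") %in%
                    names(regulation)))
  defaults <- list(k_act = c(1e-3, 5e-3), k_inact = c(1e-3, 5e-3),
                   k_tc_const = c(0.05, 0.2), k_deg_m = c(2e-4, 1e-3),
                   protein_mpc = c(1e4, 1e5), half_life = c(3600, 36000))
  stopifnot(all(names(rate_ranges) %in% names(defaults)))
  defaults[names(rate_ranges)] <- rate_ranges
  structure(list(n_genes = as.integer(n_genes),
                 n_signal_species = as.integer(n_signal_species),
                 include_ligand = include_ligand,
                 include_death_pair = include_death_pair,
                 include_cyclin_triple = include_cyclin_triple,
                 regulation = regulation, copies = as.integer(copies),
                 copy_scale = as.integer(copy_scale),
                 k_cleave = k_cleave,
                 k_cyclin_induction = k_cyclin_induction,
                 rate_ranges = defaults,
                 seed = as.integer(seed)),
            class = "toy_spec")
}

# compartment volumes (liters): same four compartments and orders of
# magnitude as a mammalian cell, so volume-correction code paths matter
.toy_compartments <- data.frame(
  compartment = c("Cytoplasm", "Mitochondria", "Nucleus", "Extracellular"),
  volume_L = c(5.25e-12, 3.68e-13, 1.75e-12, 1.0e-10),
  go_term = c("GO:0005737", "GO:0005739", "GO:0005634", "GO:0005576"),
  stringsAsFactors = FALSE)

# deterministic per-gene and network constants from the spec seed
toy_params <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(spec$seed)
  n <- spec$n_genes
  rr <- spec$rate_ranges
  ru <- function(range) stats::runif(n, range[1], range[2])
  g <- data.frame(
    gene = paste0("G", seq_len(n)),
    copies = rep(spec$copies * spec$copy_scale, n),
    k_act = ru(rr$k_act),
    k_inact = ru(rr$k_inact),
    k_tc_const = ru(rr$k_tc_const) / spec$copy_scale,
    k_deg_m = ru(rr$k_deg_m),
    protein_mpc = ru(rr$protein_mpc),
    half_life = ru(rr$half_life),
    stringsAsFactors = FALSE)
  g$k_tc_max <- 2 * g$k_tc_const
  g$f_active <- g$k_act / (g$k_act + g$k_inact)
  g$mean_mrna <- g$copies * g$f_active * g$k_tc_const / g$k_deg_m
  g$k_deg_p <- log(2) / g$half_life
  g$k_tl <- g$k_deg_p * g$protein_mpc / g$mean_mrna
  sig <- if (spec$n_signal_species > 0)
    data.frame(name = paste0("S", seq_len(spec$n_signal_species)),
               kc = stats::runif(spec$n_signal_species, 0.01, 0.1),
               kM = stats::runif(spec$n_signal_species, 50, 200),
               k_deg = stats::runif(spec$n_signal_species, 1e-4, 1e-3),
               stringsAsFactors = FALSE)
  else NULL
  lig <- if (spec$include_ligand)
    list(kon = stats::runif(1, 1e-4, 1e-3), koff = stats::runif(1, 1e-4, 1e-3),
         R0 = stats::runif(1, 50, 200))
  else NULL
  parp0 <- if (spec$include_death_pair) stats::runif(1, 50, 150) else NULL
  list(genes = g, signal = sig, ligand = lig, parp0 = parp0)
}

#' Generate a toy model input set
#'
#' Emits the seven mandatory TSV files encoding the spec's motifs into
#' `directory` (a temporary directory by default) and reads them back, so
#' the returned object is exactly what [read_input_set()] produces.  The
#' generated set always passes [validate_input_set()].
#'
#' @param spec a [toy_spec()].
#' @param directory where the files are written.
#' @return the `model_input_set`, with attribute `directory`.
#' @export
make_toy_model <- function(spec, directory = tempfile("toymodel")) {
  tp <- toy_params(spec)
  g <- tp$genes
  Vc <- .toy_compartments$volume_L[1L]

  species <- data.frame(species = character(), compartment = character(),
                        initial_nM = numeric(), gene_ids = character(),
                        stringsAsFactors = FALSE)
  add_sp <- function(name, comp, init, ids = "")
    species <<- rbind(species, data.frame(species = name, compartment = comp,
                                          initial_nM = init, gene_ids = ids,
                                          stringsAsFactors = FALSE))
  reactions <- list()
  add_rxn <- function(name, comp, law, params = numeric())
    reactions[[length(reactions) + 1L]] <<-
      list(reaction = name, compartment = comp, law = law, params = params)
  stoich_entries <- list()
  add_st <- function(rxn, sp, coef)
    stoich_entries[[length(stoich_entries) + 1L]] <<- list(rxn, sp, coef)

  for (i in seq_len(nrow(g))) {
    gn <- g$gene[i]
    add_sp(paste0("m_", gn), "Cytoplasm", mpc_to_nM(round(g$mean_mrna[i]), Vc), gn)
    add_sp(paste0("P_", gn), "Cytoplasm", mpc_to_nM(g$protein_mpc[i], Vc), gn)
    add_rxn(paste0("vTL_", gn), "Cytoplasm", paste0("kTL*m_", gn),
            c(kTL = g$k_tl[i]))
    add_st(paste0("vTL_", gn), paste0("P_", gn), 1)
    add_rxn(paste0("vdeg_P", gn), "Cytoplasm", g$k_deg_p[i])
    add_st(paste0("vdeg_P", gn), paste0("P_", gn), -1)
  }
  if (!is.null(tp$signal)) for (i in seq_len(nrow(tp$signal))) {
    sn <- tp$signal$name[i]
    add_sp(sn, "Cytoplasm", 0)
    add_rxn(paste0("vprod_", sn), "Cytoplasm",
            paste0("kc*P_G1/(kM + P_G1)"),
            c(kc = tp$signal$kc[i], kM = tp$signal$kM[i]))
    add_st(paste0("vprod_", sn), sn, 1)
    add_rxn(paste0("vdeg_", sn), "Cytoplasm", tp$signal$k_deg[i])
    add_st(paste0("vdeg_", sn), sn, -1)
  }
  if (spec$include_ligand) {
    add_sp("L", "Extracellular", 0)
    add_sp("R", "Cytoplasm", tp$ligand$R0)
    add_sp("LR", "Cytoplasm", 0)
    add_rxn("vbind", "Extracellular", tp$ligand$kon)
    add_st("vbind", "L", -1); add_st("vbind", "R", -1); add_st("vbind", "LR", 1)
    add_rxn("vunbind", "Cytoplasm", tp$ligand$koff)
    add_st("vunbind", "LR", -1); add_st("vunbind", "L", 1); add_st("vunbind", "R", 1)
  }
  if (spec$include_death_pair) {
    add_sp("PARP", "Cytoplasm", tp$parp0)
    add_sp("cPARP", "Cytoplasm", 0)
    add_rxn("vcleave", "Cytoplasm", spec$k_cleave)
    add_st("vcleave", "PARP", -1); add_st("vcleave", "cPARP", 1)
  }
  if (spec$include_cyclin_triple) {
    for (cy in c("CycE", "CycA", "CycB")) {
      add_sp(cy, "Cytoplasm", 0.1)
      add_rxn(paste0("vind_", cy), "Cytoplasm", spec$k_cyclin_induction)
      add_st(paste0("vind_", cy), cy, 1)
      add_rxn(paste0("vdeg_", cy), "Cytoplasm", 1e-4)
      add_st(paste0("vdeg_", cy), cy, -1)
    }
  }

  rxn_names <- vapply(reactions, `[[`, character(1L), "reaction")
  S <- matrix(0, nrow(species), length(reactions),
              dimnames = list(species$species, rxn_names))
  for (e in stoich_entries) S[e[[2L]], e[[1L]]] <- e[[3L]]

  # observables: per-gene protein totals; cyclin sum when present
  obs_cols <- paste0("tot_", g$gene)
  O <- matrix(0L, nrow(species), length(obs_cols),
              dimnames = list(species$species, obs_cols))
  for (i in seq_len(nrow(g))) O[paste0("P_", g$gene[i]), i] <- 1L
  if (spec$include_cyclin_triple) {
    O <- cbind(O, CyclinSum = 0L)
    O[c("CycE", "CycA", "CycB"), "CyclinSum"] <- 1L
  }

  regulators <- character()
  reg_entries <- data.frame(gene = character(), regulator = character(),
                            hill = numeric(), halfmax = numeric(),
                            role = character(), stringsAsFactors = FALSE)
  if (!is.null(spec$regulation)) {
    regulators <- unique(spec$regulation$regulator)
    reg_entries <- data.frame(
      gene = spec$regulation$gene, regulator = spec$regulation$regulator,
      hill = abs(spec$regulation$hill), halfmax = spec$regulation$halfmax,
      role = ifelse(spec$regulation$hill > 0, "activator", "repressor"),
      stringsAsFactors = FALSE)
  }

  m <- structure(list(
    genes = data.frame(gene = g$gene, gene_copy_number = g$copies,
                       mrna_mpc = round(g$mean_mrna),
                       k_gene_inactivation = g$k_inact,
                       k_gene_activation = g$k_act,
                       k_transcription_const = g$k_tc_const,
                       k_transcription_max = g$k_tc_max,
                       k_mrna_degradation = g$k_deg_m,
                       protein_mpc = g$protein_mpc,
                       protein_half_life = g$half_life,
                       k_translation = g$k_tl, stringsAsFactors = FALSE),
    species = species, reactions = reactions, stoich = S,
    regulation = list(genes = g$gene, regulators = regulators,
                      entries = reg_entries),
    compartments = .toy_compartments, observables = O, initializer = NULL,
    transcript_prefix = "m_"), class = "model_input_set")

  # normalize through the writer/reader so the returned object is exactly
  # the parsed representation of the files on disk
  m$reactions <- lapply(m$reactions, function(r) {
    if (is.character(r$law))
      list(reaction = r$reaction, compartment = r$compartment,
           type = "formula", rate_constant = NA_real_, formula = r$law,
           params = r$params)
    else
      list(reaction = r$reaction, compartment = r$compartment,
           type = "mass_action", rate_constant = r$law,
           formula = NA_character_, params = numeric())
  })
  m$species$is_transcript <- startsWith(m$species$species, "m_")
  m$species$transcript_of <- ifelse(m$species$is_transcript,
                                    substring(m$species$species, 3L),
                                    NA_character_)
  write_input_set(m, directory)
  out <- read_input_set(directory)
  attr(out, "directory") <- directory
  out
}

#' Compile a toy model with its phenotype roles attached
#'
#' Convenience wrapper: [make_toy_model()] then [compile_model()] with the
#' death pair and cyclin triple mapped to their role species when present.
#'
#' @param spec a [toy_spec()].
#' @param directory passed to [make_toy_model()].
#' @return a `compiled_model`.
#' @export
compile_toy_model <- function(spec, directory = tempfile("toymodel")) {
  m <- make_toy_model(spec, directory)
  compile_model(
    m,
    death_roles = if (spec$include_death_pair)
      c(parp = "PARP", cparp = "cPARP") else NULL,
    cyclin_roles = if (spec$include_cyclin_triple)
      c("CycE", "CycA", "CycB") else NULL)
}

#' Closed-form reference behaviour of a toy model
#'
#' For the linear production-decay motifs: telegraph stationary active
#' fraction `k_on/(k_on+k_off)`, stationary mean mRNA
#' `n_copies * f_active * k_tc / k_deg` (mpc), and steady-state protein
#' `k_TL * [mRNA*] / k_deg_P` (nM).  Genes targeted by regulation entries
#' fall outside the analytic family and are flagged unsupported.
#'
#' @param spec a [toy_spec()].
#' @return data frame with one row per gene: `gene`, `f_active`,
#'   `mean_mrna_mpc`, `protein_ss_nM`, `supported`.
#' @export
analytic_reference <- function(spec) {
  tp <- toy_params(spec)
  g <- tp$genes
  Vc <- .toy_compartments$volume_L[1L]
  mrna_ss_nM <- mpc_to_nM(g$mean_mrna, Vc)
  regulated <- if (!is.null(spec$regulation)) unique(spec$regulation$gene)
  else character()
  data.frame(gene = g$gene, f_active = g$f_active,
             mean_mrna_mpc = g$mean_mrna,
             protein_ss_nM = g$k_tl * mrna_ss_nM / g$k_deg_p,
             supported = !g$gene %in% regulated,
             stringsAsFactors = FALSE)
}
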