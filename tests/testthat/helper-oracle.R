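# Independent right-hand-side oracle: assembles d(state)/dt directly from a
# parsed model input set by looping over reactions, without touching the
# package's compiled expression machinery.  Mass-action laws multiply the
# rate constant by each reactant concentration corrected to the reaction
# compartment (c * V_home/V_rxn, exponent |coefficient|); formula laws are
# evaluated verbatim in an environment of species values and local
# parameters; each flux feeds species i as S[i,j] * v * V_rxn/V_home(i).
oracle_rhs <- function(m, state) {
  vols <- setNames(m$compartments$volume_L, m$compartments$compartment)
  sp <- m$species$species
  spc <- setNames(m$species$compartment, sp)
  state <- setNames(as.numeric(state), sp)
  dy <- setNames(numeric(length(sp)), sp)
  for (j in seq_along(m$reactions)) {
    r <- m$reactions[[j]]
    Vr <- vols[[r$compartment]]
    if (r$type == "mass_action") {
      v <- r$rate_constant
      col <- m$stoich[, j]
      for (i in which(col < 0))
        v <- v * (state[[sp[i]]] * vols[[spc[[sp[i]]]]] / Vr)^abs(col[i])
    } else {
      env <- list2env(c(as.list(state), as.list(r$params),
                        as.list(vols)), parent = baseenv())
      v <- eval(parse(text = r$formula)[[1]], envir = env)
    }
    for (i in which(m$stoich[, j] != 0))
      dy[[sp[i]]] <- dy[[sp[i]]] +
        m$stoich[i, j] * v * Vr / vols[[spc[[sp[i]]]]]
  }
  dy
}

# relative deviation between two derivative vectors
max_rel_dev <- function(a, b) {
  d <- abs(a - b)
  max(d / pmax(abs(a), abs(b), 1e-30))
}

# a pool of varied toy specs exercising all generator features
varied_specs <- function(n, seed_base = 100) {
  lapply(seq_len(n), function(i) {
    reg <- if (i %% 4 == 0)
      data.frame(gene = "G1", regulator = "P_G1",
                 hill = if (i %% 8 == 0) -1.5 else 2, halfmax = 50)
    else NULL
    toy_spec(n_genes = 1 + i %% 3,
             n_signal_species = i %% 3,
             include_ligand = i %% 2 == 0,
             include_death_pair = i %% 3 == 0,
             include_cyclin_triple = i %% 5 == 0,
             regulation = reg,
             seed = seed_base + i)
  })
}
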