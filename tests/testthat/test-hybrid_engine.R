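test_that("a one-hour run executes 120 exchange windows", {
  cm <- compile_model(make_toy_model(toy_spec(n_genes = 1, seed = 601)))
  tr <- simulate_cell(cm, simulation_config(flag_deterministic = 1,
                                            duration_h = 1))
  expect_equal(length(tr$time), 121)   # 120 windows + t = 0
  expect_equal(max(tr$time), 3600)
  expect_equal(diff(tr$time), rep(30, 120))
  # record_stride thins the recording
  tr2 <- simulate_cell(cm, simulation_config(duration_h = 1,
                                             record_stride = 4))
  expect_equal(length(tr2$time), 31)
  expect_equal(diff(tr2$time), rep(120, 30))
})

test_that("deterministic mode ignores the seed; hybrid mode is reproducible", {
  cm <- compile_model(make_toy_model(toy_spec(n_genes = 2, seed = 602)))
  t1 <- simulate_cell(cm, simulation_config(flag_deterministic = 1,
                                            duration_h = 0.1, seed = 1))
  t2 <- simulate_cell(cm, simulation_config(flag_deterministic = 1,
                                            duration_h = 0.1, seed = 999))
  expect_identical(t1$species, t2$species)

  h1 <- simulate_cell(cm, simulation_config(flag_deterministic = 0,
                                            duration_h = 0.1, seed = 5))
  h2 <- simulate_cell(cm, simulation_config(flag_deterministic = 0,
                                            duration_h = 0.1, seed = 5))
  h3 <- simulate_cell(cm, simulation_config(flag_deterministic = 0,
                                            duration_h = 0.1, seed = 6))
  expect_identical(h1$species, h2$species)
  expect_identical(h1$genes, h2$genes)
  expect_false(identical(h1$genes, h3$genes))
})

test_that("ligand dosing overwrites exactly the listed species", {
  cm <- compile_model(make_toy_model(toy_spec(n_genes = 1,
                                              include_ligand = TRUE,
                                              seed = 603)))
  st <- apply_ligands(cm$init, c(L = 10))
  expect_equal(unname(st[["L"]]), 10)
  expect_equal(st[names(st) != "L"], cm$init[names(st) != "L"])
  expect_identical(apply_ligands(cm$init, numeric()), cm$init)
  expect_error(apply_ligands(cm$init, c(nope = 1)), "unknown ligand")
})

test_that("two-phase dosing steps the ligand exactly at the second dose time", {
  cm <- compile_model(make_toy_model(toy_spec(n_genes = 1,
                                              include_ligand = TRUE,
                                              seed = 604)))
  cfg <- simulation_config(flag_deterministic = 1, duration_h = 0.2,
                           ligands = c(L = 2),
                           doses = list(list(time_h = 0.1,
                                             ligands = c(L = 50))))
  tr <- simulate_cell(cm, cfg)
  i_dose <- which(tr$time == 0.1 * 3600)
  expect_equal(unname(tr$species[1, "L"]), 2)
  expect_true(all(tr$species[2:(i_dose - 1), "L"] < 2 + 1e-9))
  expect_equal(unname(tr$species[i_dose, "L"]), 50)
})

test_that("the death criterion is a strict inequality and stops the run", {
  cm <- compile_model(make_toy_model(toy_spec(n_genes = 1,
                                              include_death_pair = TRUE,
                                              k_cleave = 1e-3, seed = 605)),
                      death_roles = c(parp = "PARP", cparp = "cPARP"))
  # with a fast cleavage rate the crossing happens well within an hour
  tr <- simulate_cell(cm, simulation_config(flag_deterministic = 1,
                                            duration_h = 2))
  expect_false(is.na(tr$died_at))
  expect_equal(max(tr$time), tr$died_at)
  final <- tr$species[nrow(tr$species), ]
  expect_gt(final[["cPARP"]], final[["PARP"]])

  st <- cm$init
  st[c("PARP", "cPARP")] <- c(50, 51)
  expect_true(check_death(st, cm))
  st[c("PARP", "cPARP")] <- c(50, 50)
  expect_false(check_death(st, cm))    # equality is still alive
  # unmapped roles: the check is disabled and the cell never dies
  cm_no <- cm; cm_no$death_roles <- NULL
  expect_false(check_death(st * 0 + c(1, 100), cm_no))
  tr2 <- simulate_cell(cm_no, simulation_config(duration_h = 0.1))
  expect_true(is.na(tr2$died_at))
})

test_that("compile_model wires death roles from the constructor", {
  cm <- compile_toy_model(toy_spec(n_genes = 1, include_death_pair = TRUE,
                                   include_cyclin_triple = TRUE, seed = 606))
  expect_equal(unname(cm$death_roles), c("PARP", "cPARP"))
  expect_equal(cm$cyclin_roles, c("CycE", "CycA", "CycB"))
})

test_that("deterministic runs converge to the closed-form steady state", {
  spec <- toy_spec(n_genes = 1, n_signal_species = 0, seed = 607)
  cm <- compile_toy_model(spec)
  ref <- analytic_reference(spec)
  ss <- steady_state(cm, hours = 1000)
  expect_true(ss$stationary)
  expect_equal(unname(ss$state[["P_G1"]]), ref$protein_ss_nM[1],
               tolerance = 1e-6)
  # transcripts sit at the stationary mean converted to nM
  expect_equal(unname(ss$state[["m_G1"]]),
               mpc_to_nM(ref$mean_mrna_mpc[1], cm$comp_vols[["Cytoplasm"]]),
               tolerance = 1e-9)
})

test_that("the windowed deterministic loop tracks the direct ODE solution", {
  spec <- toy_spec(n_genes = 1, n_signal_species = 1, seed = 608)
  cm <- compile_toy_model(spec)
  tr <- simulate_cell(cm, simulation_config(flag_deterministic = 1,
                                            duration_h = 2))
  # S1 relaxes toward its quasi-steady value kc*P/(kM+P)/kdeg
  p <- cm$params
  val <- function(rxn, loc) p$value[p$reaction == rxn & p$local == loc]
  P <- tr$species[nrow(tr$species), "P_G1"]
  s_qss <- val("vprod_S1", "kc") * P / (val("vprod_S1", "kM") + P) /
    val("vdeg_S1", "k")
  kdeg <- val("vdeg_S1", "k")
  expected <- unname(s_qss * (1 - exp(-kdeg * 7200)))
  expect_equal(unname(tr$species[nrow(tr$species), "S1"]), expected,
               tolerance = 0.02)
})

test_that("tightening integrator tolerances barely moves the final state", {
  cm <- compile_toy_model(toy_spec(n_genes = 1, n_signal_species = 1,
                                   seed = 609))
  f1 <- simulate_cell(cm, simulation_config(duration_h = 0.5))
  f2 <- simulate_cell(cm, simulation_config(duration_h = 0.5,
                                            rtol = 5e-7, atol = 5e-10))
  end1 <- f1$species[nrow(f1$species), ]
  end2 <- f2$species[nrow(f2$species), ]
  expect_lt(max(abs(end1 - end2) / pmax(abs(end2), 1e-6)), 1e-4)
})

test_that("trajectories interpolate and export to TSV", {
  cm <- compile_toy_model(toy_spec(n_genes = 1, seed = 610))
  tr <- simulate_cell(cm, simulation_config(duration_h = 0.1))
  v <- trajectory_at(tr, c("P_G1", "m_G1"), 45)
  expect_length(v, 2)
  expect_error(trajectory_at(tr, "P_G1", 1e6), "outside")
  d <- tempfile()
  paths <- write_trajectory(tr, d)
  expect_true(all(file.exists(paths)))
  tab <- read.delim(paths[1])
  expect_equal(nrow(tab), length(tr$time))
  unlink(d, recursive = TRUE)
})
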