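test_that("calibration targets come from proteomics or mRNA-ratio imputation", {
  cm <- compile_toy_model(toy_spec(n_genes = 2, seed = 701))
  Vc <- cm$comp_vols[["Cytoplasm"]]
  g <- cm$genes
  tg <- derive_targets(g, volume = Vc)
  expect_equal(tg$source, c("measured", "measured"))
  expect_equal(tg$target_nM, mpc_to_nM(g$protein_mpc, Vc))

  g2 <- g
  g2$protein_mpc[2] <- NA
  tg2 <- derive_targets(g2, ratios = c(G2 = 1000), volume = Vc)
  expect_equal(tg2$source[2], "imputed")
  expect_equal(tg2$target_nM[2], mpc_to_nM(g2$mrna_mpc[2] * 1000, Vc))
  # imputation is linear in mRNA
  g3 <- g2; g3$mrna_mpc[2] <- 2 * g2$mrna_mpc[2]
  expect_equal(derive_targets(g3, c(G2 = 1000), Vc)$target_nM[2],
               2 * tg2$target_nM[2])
  g4 <- g2; g4$mrna_mpc[2] <- 0
  expect_equal(derive_targets(g4, c(G2 = 1000), Vc)$target_nM[2], 0)
  # a gene with neither source is fatal and named
  g5 <- g; g5$protein_mpc[1] <- NA
  expect_error(derive_targets(g5, volume = Vc), "G1")
})

test_that("translation calibration recovers the steady-state balance", {
  spec <- toy_spec(n_genes = 1, n_signal_species = 0, include_ligand = FALSE,
                   seed = 702)
  cm <- compile_toy_model(spec)
  Vc <- cm$comp_vols[["Cytoplasm"]]
  targets <- derive_targets(cm$genes, volume = Vc)
  pn <- cm$genes$translation_param[1]
  k_true <- cm$param_values[[pn]]

  # perturb the translation rate fivefold and calibrate it back
  cm_pert <- set_parameters(cm, setNames(k_true * 5, pn))
  fit <- calibrate_translation(cm_pert, targets)
  expect_true(fit$converged)
  # closed form: k_TL = k_deg_P * P_target / m_star
  ref <- analytic_reference(spec)
  m_star_nM <- mpc_to_nM(ref$mean_mrna_mpc[1], Vc)
  k_deg_p <- log(2) / cm$genes$protein_half_life[1]
  k_closed <- k_deg_p * targets$target_nM[1] / m_star_nM
  expect_equal(fit$model$param_values[[pn]], k_closed, tolerance = 0.01)
  expect_equal(fit$report$reached_nM[1], targets$target_nM[1],
               tolerance = 0.01)

  # re-running calibration is a fixpoint: no rate moves beyond tolerance
  fit2 <- calibrate_translation(fit$model, targets)
  expect_equal(fit2$iterations, 1)
  expect_equal(fit2$model$param_values[[pn]], fit$model$param_values[[pn]],
               tolerance = 0.01)
})

test_that("a zero translation rate silences the gene (loss-of-function)", {
  cm <- compile_toy_model(toy_spec(n_genes = 1, n_signal_species = 0,
                                   include_ligand = FALSE, seed = 703))
  pn <- cm$genes$translation_param[1]
  cm0 <- set_parameters(cm, setNames(0, pn))
  ss <- steady_state(cm0, hours = 2000)
  expect_equal(unname(gene_protein_totals(cm0, ss$state)[["G1"]]), 0,
               tolerance = 1e-9)
})

test_that("gene totals are volume-corrected sums over product species", {
  cm <- compile_toy_model(toy_spec(n_genes = 2, seed = 704))
  st <- cm$init
  tot <- gene_protein_totals(cm, st)
  # toy proteins live in the reference compartment; transcripts are excluded
  expect_equal(unname(tot[["G1"]]), unname(st[["P_G1"]]))
  expect_equal(unname(tot[["G2"]]), unname(st[["P_G2"]]))
})

test_that("phenotype check reports violations with times, or passes vacuously", {
  # no roles configured: vacuous pass with notices
  cm <- compile_toy_model(toy_spec(n_genes = 1, seed = 705))
  rep <- phenotype_check(cm, horizon_h = 0.2)
  expect_true(rep$pass)
  expect_length(rep$notices, 2)

  # cyclin induction engineered to cross 20 nM within the horizon
  cm2 <- compile_toy_model(toy_spec(n_genes = 1, include_cyclin_triple = TRUE,
                                    k_cyclin_induction = 0.05, seed = 706))
  rep2 <- phenotype_check(cm2, horizon_h = 1, record_stride = 1L)
  expect_false(rep2$pass)
  expect_true(rep2$sphase$violated)
  expect_gt(rep2$sphase$time_s, 0)
  # the violation time is when the summed cyclins first exceed 20 nM
  tot <- rowSums(rep2$trajectory$species[, c("CycE", "CycA", "CycB")])
  expect_equal(rep2$sphase$time_s,
               rep2$trajectory$time[which(tot > 20)[1]])

  # death violation via a hot cleavage rate
  cm3 <- compile_toy_model(toy_spec(n_genes = 1, include_death_pair = TRUE,
                                    k_cleave = 1e-3, seed = 707))
  rep3 <- phenotype_check(cm3, horizon_h = 2)
  expect_false(rep3$pass)
  expect_true(rep3$death$violated)
})

test_that("parameter scans select the smallest passing value", {
  cm <- compile_toy_model(toy_spec(n_genes = 1, include_cyclin_triple = TRUE,
                                   seed = 708))
  pn <- cm$params$global[cm$params$reaction == "vind_CycE"]
  cfg <- simulation_config(flag_deterministic = 1, duration_h = 0.5,
                           record_stride = 5L)
  crit <- function(tr) max(tr$species[, "CycE"]) > 1
  sc <- scan_parameter(cm, pn, 1e-5, 1e-1, n_points = 9, criterion = crit,
                       cfg = cfg)
  expect_equal(nrow(sc$table), 9)
  expect_false(is.na(sc$selected))
  expect_equal(sc$selected, min(sc$table$value[sc$table$pass]))
  # the scan brackets the true threshold: bisection oracle on the same model
  lo <- max(sc$table$value[!sc$table$pass & sc$table$value < sc$selected], 0)
  f <- function(v) {
    m2 <- set_parameters(cm, setNames(v, pn))
    crit(simulate_cell(m2, cfg))
  }
  root <- uniroot(function(lv) {
    m2 <- set_parameters(cm, setNames(10^lv, pn))
    tr <- simulate_cell(m2, cfg)
    max(tr$species[, "CycE"]) - 1
  }, c(-5, -1), tol = 1e-3)$root
  expect_gte(log10(sc$selected) + 1e-9, root - (4 / 8))
  expect_lte(log10(sc$selected), root + (4 / 8) + 1e-9)

  # degenerate scans
  sc1 <- scan_parameter(cm, pn, 1e-3, 1e-1, n_points = 1, criterion = crit,
                        cfg = cfg)
  expect_equal(nrow(sc1$table), 1)
  always <- scan_parameter(cm, pn, 1e-3, 1e-1, n_points = 5,
                           criterion = function(tr) TRUE, cfg = cfg)
  expect_equal(always$selected, 1e-3)
  never <- scan_parameter(cm, pn, 1e-3, 1e-1, n_points = 3,
                          criterion = function(tr) FALSE, cfg = cfg)
  expect_true(is.na(never$selected))
})

test_that("coordinate fitting is an SSE-monotone fixpoint on a perfect reference", {
  cm <- compile_toy_model(toy_spec(n_genes = 1, n_signal_species = 1,
                                   include_ligand = FALSE, seed = 709))
  cfg <- simulation_config(flag_deterministic = 1, duration_h = 0.5,
                           record_stride = 5L)
  tr <- simulate_cell(cm, cfg)
  ref <- list(time = tr$time[seq(2, length(tr$time), by = 2)],
              values = tr$species[seq(2, length(tr$time), by = 2), "S1"])
  pns <- c(cm$params$global[cm$params$local == "kc"],
           cm$params$global[cm$params$local == "kM"])
  fit <- coordinate_fit(cm, pns, ref, "S1", n_grid = 9, cfg = cfg,
                        use_species = TRUE)
  # reference equals the initial simulation: parameters must not move
  expect_equal(unname(fit$values), unname(cm$param_values[pns]))
  expect_equal(fit$sse, 0, tolerance = 1e-12)
  # SSE never increases along the path
  expect_true(all(diff(fit$path$sse) <= 1e-12))
  # a single-parameter list gives the same answer regardless of "order"
  f1 <- coordinate_fit(cm, pns[1], ref, "S1", n_grid = 9, cfg = cfg,
                       use_species = TRUE)
  expect_equal(unname(f1$values), unname(cm$param_values[pns[1]]))
})
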