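test_that("compiled RHS matches the independent oracle on random states", {
  set.seed(1)
  for (spec in varied_specs(5, seed_base = 300)) {
    m <- make_toy_model(spec)
    cm <- compile_model(m)
    for (k in 1:20) {
      st <- runif(length(cm$species), 0, 100)
      expect_lt(max_rel_dev(evaluate_rhs(cm, st), unname(oracle_rhs(m, st))),
                1e-12)
    }
  }
})

test_that("a hand-written binding-chain ODE matches the compiled RHS", {
  # A + B <-> C, C -> 0, single compartment: oracle written from scratch
  m <- make_toy_model(toy_spec(n_genes = 1, n_signal_species = 0,
                               include_ligand = TRUE, seed = 61))
  cm <- compile_model(m)
  kon <- cm$param_values[[cm$params$global[cm$params$reaction == "vbind"]]]
  koff <- cm$param_values[[cm$params$global[cm$params$reaction == "vunbind"]]]
  Vc <- cm$comp_vols[["Cytoplasm"]]; Ve <- cm$comp_vols[["Extracellular"]]
  set.seed(2)
  for (k in 1:10) {
    st <- setNames(runif(length(cm$species), 0, 50), cm$species)
    vb <- kon * st[["L"]] * (st[["R"]] * Vc / Ve)   # extracellular law
    vu <- koff * st[["LR"]]                          # cytoplasmic law
    dy <- evaluate_rhs(cm, st)
    names(dy) <- cm$species
    expect_equal(dy[["L"]], -vb + vu * Vc / Ve, tolerance = 1e-12)
    expect_equal(dy[["R"]], -vb * Ve / Vc + vu, tolerance = 1e-12)
    expect_equal(dy[["LR"]], vb * Ve / Vc - vu, tolerance = 1e-12)
  }
})

test_that("closed sub-networks conserve mass at every state", {
  m <- make_toy_model(toy_spec(n_genes = 1, n_signal_species = 0,
                               include_ligand = TRUE, seed = 62))
  cm <- compile_model(m)
  Vc <- cm$comp_vols[["Cytoplasm"]]; Ve <- cm$comp_vols[["Extracellular"]]
  set.seed(3)
  for (k in 1:25) {
    st <- setNames(runif(length(cm$species), 0, 100), cm$species)
    dy <- setNames(evaluate_rhs(cm, st), cm$species)
    # total ligand molecules: L*Ve + LR*Vc conserved; receptor R*Vc + LR*Vc
    expect_equal(dy[["L"]] * Ve + dy[["LR"]] * Vc, 0, tolerance = 1e-12 * Ve)
    expect_equal(dy[["R"]] + dy[["LR"]], 0, tolerance = 1e-12)
  }
})

test_that("all-zero state with no zeroth-order reactions gives zero derivative", {
  m <- make_toy_model(toy_spec(n_genes = 2, n_signal_species = 1,
                               include_ligand = TRUE, seed = 63))
  cm <- compile_model(m)
  expect_equal(unname(evaluate_rhs(cm, numeric(length(cm$species)))),
               numeric(length(cm$species)))
  expect_error(evaluate_rhs(cm, c(NaN, rep(0, length(cm$species) - 1))),
               "non-finite")
  expect_error(evaluate_rhs(cm, numeric(2)), "species count")
})

test_that("parameter renaming is a stable bijection with per-formula suffixes", {
  spec <- toy_spec(n_genes = 2, n_signal_species = 1, seed = 64)
  m <- make_toy_model(spec)
  cm1 <- compile_model(m)
  cm2 <- compile_model(m)
  expect_identical(cm1$params, cm2$params)
  expect_false(anyDuplicated(cm1$params$global) > 0)
  # (reaction, local) -> global is one-to-one
  key <- paste(cm1$params$reaction, cm1$params$local)
  expect_false(anyDuplicated(key) > 0)
  # the Michaelis-Menten law contributes two distinct globals
  mm <- cm1$params[cm1$params$reaction == "vprod_S1", ]
  expect_equal(nrow(mm), 2)
  expect_equal(mm$local, c("kc", "kM"))
  expect_length(unique(mm$global), 2)
})

test_that("parameter report counts mass-action and formula parameters", {
  spec <- toy_spec(n_genes = 2, n_signal_species = 1, include_ligand = TRUE,
                   seed = 65)
  cm <- compile_model(make_toy_model(spec))
  f <- tempfile(fileext = ".tsv")
  p <- export_parameter_report(cm, f)
  tab <- read.delim(f)
  # 2 genes: (kTL formula) + (decay MA); 1 signal: (kc,kM formula) + MA;
  # ligand: 2 MA => total rows = 2*2 + 3 + 2 = 9
  expect_equal(nrow(tab), 9)
  expect_equal(tab$global, p$global)
  expect_equal(tab$value, p$value, tolerance = 0)
})

test_that("model text export lists every element and round-trips values", {
  cm <- compile_model(make_toy_model(toy_spec(n_genes = 2, seed = 66)))
  txt <- export_model_text(cm)
  for (s in cm$species)
    expect_true(any(startsWith(txt, paste0(s, "\t"))), label = s)
  for (r in cm$reactions)
    expect_true(any(startsWith(txt, paste0(r, "\t"))), label = r)
  # parse the parameter section back and compare values
  i0 <- which(txt == "## parameters (global, reaction, local, value)") + 1
  i1 <- which(txt == "") [which(txt == "") > i0][1] - 1
  got <- do.call(rbind, strsplit(txt[i0:i1], "\t"))
  expect_equal(as.numeric(got[, 4]), unname(cm$params$value))
  expect_equal(got[, 1], cm$params$global)
  # no regulation section for an unregulated model
  expect_false(any(grepl("^## regulation", txt)))
})

test_that("observable values apply the volume correction", {
  spec <- toy_spec(n_genes = 2, seed = 67)
  cm <- compile_model(make_toy_model(spec))
  st <- cm$init
  ov <- observable_values(cm, st)
  # single-member observables in the reference compartment: plain values
  expect_equal(ov[["tot_G1"]], unname(st[["P_G1"]]))
  # move the member species to the Nucleus: contribution scales by Vn/Vc
  cm2 <- cm
  cm2$species_comp[["P_G1"]] <- "Nucleus"
  ratio <- cm$comp_vols[["Nucleus"]] / cm$comp_vols[["Cytoplasm"]]
  expect_equal(observable_values(cm2, st)[["tot_G1"]],
               unname(st[["P_G1"]]) * ratio)
  # an all-zero membership column reads 0
  cm3 <- cm
  cm3$observables <- cbind(cm$observables, empty = 0L)
  expect_equal(observable_values(cm3, st)[["empty"]], 0)
})

test_that("zero mass-action constants contribute nothing", {
  m <- make_toy_model(toy_spec(n_genes = 1, seed = 68))
  i <- which(vapply(m$reactions, `[[`, character(1), "type") == "mass_action")[1]
  m$reactions[[i]]$rate_constant <- 0
  cm <- compile_model(m)
  st <- setNames(runif(length(cm$species), 1, 10), cm$species)
  expect_equal(unname(reaction_fluxes(cm, st)[i]), 0)
})

test_that("negative mass-action constants are rejected at parse time", {
  m <- make_toy_model(toy_spec(n_genes = 1, seed = 69))
  d <- attr(m, "directory")
  lines <- readLines(file.path(d, "Ratelaws.txt"))
  parts <- strsplit(lines[3], "\t")[[1]]
  parts[3] <- "-1"
  lines[3] <- paste(parts, collapse = "\t")
  writeLines(lines, file.path(d, "Ratelaws.txt"))
  expect_error(read_input_set(d), "negative mass-action")
})
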