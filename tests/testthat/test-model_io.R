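test_that("generator output parses back with matching record counts", {
  spec <- toy_spec(n_genes = 2, include_death_pair = TRUE, seed = 11)
  m <- make_toy_model(spec)
  expect_s3_class(m, "model_input_set")
  expect_equal(nrow(m$genes), 2)
  expect_equal(nrow(m$species), nrow(m$stoich))
  expect_equal(length(m$reactions), ncol(m$stoich))
  expect_equal(rownames(m$observables), m$species$species)
  expect_true(all(m$genes$gene_copy_number == 2))
  expect_equal(sum(m$species$is_transcript), 2)
})

test_that("regulation cells parse per the A; B convention", {
  expect_null(parse_regulation_cell("0"))
  act <- parse_regulation_cell("2; 50")
  expect_equal(act, list(hill = 2, halfmax = 50, role = "activator"))
  rep_ <- parse_regulation_cell("-1.5; 10")
  expect_equal(rep_, list(hill = 1.5, halfmax = 10, role = "repressor"))
  expect_error(parse_regulation_cell("2; 0"), "half-max")
  expect_error(parse_regulation_cell("a; 5"), "non-numeric")
  expect_error(parse_regulation_cell("2"), "expected")
})

test_that("write then read is the identity on randomized toy models", {
  for (spec in varied_specs(6, seed_base = 200)) {
    m <- make_toy_model(spec)
    d2 <- tempfile("roundtrip")
    write_input_set(m, d2)
    m2 <- read_input_set(d2)
    attr(m, "directory") <- NULL
    expect_identical(m2, m, label = sprintf("seed %d", spec$seed))
    unlink(d2, recursive = TRUE)
  }
})

test_that("extreme numeric values survive the TSV round trip exactly", {
  spec <- toy_spec(n_genes = 1, seed = 42)
  m <- make_toy_model(spec)
  m$reactions[[2]]$rate_constant <- 1e-7
  m$genes$k_gene_activation[1] <- 0.1 + 2e-17   # full double precision
  d <- tempfile()
  write_input_set(m, d)
  m2 <- read_input_set(d)
  expect_identical(m2$reactions[[2]]$rate_constant, 1e-7)
  expect_identical(m2$genes$k_gene_activation[1], 0.1 + 2e-17)
  unlink(d, recursive = TRUE)
})

test_that("validation passes consistent sets and pinpoints constructed violations", {
  spec <- toy_spec(n_genes = 2, seed = 13)
  m <- make_toy_model(spec)
  expect_true(attr(validate_input_set(m), "pass"))

  # delete one Species row without touching the matrix
  m_bad <- m
  m_bad$species <- m_bad$species[-1, ]
  rep <- validate_input_set(m_bad)
  expect_false(attr(rep, "pass"))
  expect_match(rep$detail[!rep$pass][1], "rows")

  # formula referencing an undeclared species
  m_bad2 <- m
  i <- which(vapply(m_bad2$reactions, `[[`, character(1), "type") == "formula")[1]
  m_bad2$reactions[[i]]$formula <- "kTL*no_such_species"
  rep2 <- validate_input_set(m_bad2)
  expect_false(attr(rep2, "pass"))
  bad <- rep2[!rep2$pass, ]
  expect_match(paste(bad$detail, collapse = " "), "no_such_species")
  expect_match(paste(bad$detail, collapse = " "),
               m_bad2$reactions[[i]]$reaction, fixed = TRUE)
  expect_error(validate_input_set(m_bad2, strict = TRUE), "validation")
})

test_that("validation is order-sensitive in species vs matrix rows", {
  for (seed in c(31, 32, 33)) {
    m <- make_toy_model(toy_spec(n_genes = 2, seed = seed))
    perm <- rev(seq_len(nrow(m$species)))
    m_bad <- m
    m_bad$species <- m_bad$species[perm, ]
    rownames(m_bad$species) <- NULL
    expect_false(attr(validate_input_set(m_bad), "pass"))
  }
})

test_that("malformed and missing cells fail with addressed errors", {
  spec <- toy_spec(n_genes = 1, seed = 77)
  m <- make_toy_model(spec)
  d <- attr(m, "directory")
  lines <- readLines(file.path(d, "OmicsData.txt"))
  parts <- strsplit(lines[2], "\t")[[1]]
  parts[3] <- "oops"
  writeLines(c(lines[1], paste(parts, collapse = "\t")),
             file.path(d, "OmicsData.txt"))
  expect_error(read_input_set(d), "row 2, column 3")

  unlink(file.path(d, "Species.txt"))
  expect_error(read_input_set(d), "Species.txt")
})

test_that("missing proteomics cells are NA, not zero", {
  m <- make_toy_model(toy_spec(n_genes = 2, seed = 5))
  m$genes$protein_mpc[2] <- NA
  m$genes$protein_half_life[2] <- NA
  d <- tempfile()
  write_input_set(m, d)
  m2 <- read_input_set(d)
  expect_true(is.na(m2$genes$protein_mpc[2]))
  expect_true(is.na(m2$genes$protein_half_life[2]))
  expect_false(is.na(m2$genes$k_mrna_degradation[2]))
  unlink(d, recursive = TRUE)
})

test_that("the optional Initializer file round-trips and is truly optional", {
  m <- make_toy_model(toy_spec(n_genes = 2, seed = 6))
  d0 <- tempfile()
  write_input_set(m, d0)
  expect_false(file.exists(file.path(d0, "Initializer.txt")))

  m$initializer <- list(
    species_overrides = data.frame(species = c("P_G1", "P_G2"),
                                   value_nM = c(12.5, 1e-7),
                                   stringsAsFactors = FALSE),
    mrna_adjustments = data.frame(gene = "G1", mrna_mpc = 40,
                                  stringsAsFactors = FALSE),
    parameter_overrides = data.frame(parameter = "k1_1", value = 2.5e-4,
                                     stringsAsFactors = FALSE),
    observables_excluded = c("tot_G2"),
    scan = list(parameter = "k2", low = 1e-6, high = 1e-2))
  d <- tempfile()
  write_input_set(m, d)
  expect_true(file.exists(file.path(d, "Initializer.txt")))
  m2 <- read_input_set(d)
  expect_identical(m2$initializer, m$initializer)
  # initializer references are validated against the other files
  expect_true(attr(validate_input_set(m2), "pass"))
  m_bad <- m2
  m_bad$initializer$species_overrides$species[1] <- "ghost"
  rep <- validate_input_set(m_bad)
  expect_false(attr(rep, "pass"))
  expect_match(rep$detail[!rep$pass], "ghost")
  unlink(c(d0, d), recursive = TRUE)
})
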