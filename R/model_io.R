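# Reading, validating and writing the tab-separated model-definition
# dialects.  Eight files describe one model:
#
#   OmicsData            per-gene copy numbers, mRNA/protein abundances (mpc)
#                        and the stochastic-module rate constants
#   Species              species name, home compartment, initial nM, gene ids
#   Ratelaws             one reaction per row: name, home compartment, then a
#                        number (mass-action constant) or a formula followed
#                        by its local parameter values
#   StoichiometricMatrix species x reactions signed integer coefficients
#   GeneReg              per-gene transcriptional regulators, cells "A; B"
#   Compartments         name, volume (liters), GO term
#   Observables          species x observables 0/1 membership
#   Initializer          (optional) overrides and scan ranges for calibration
#
# All files are strict TSV with one header row and "." decimals.  Missing
# numeric cells are empty strings, never zero.

.default_files <- c(
  omics        = "OmicsData.txt",
  species      = "Species.txt",
  ratelaws     = "Ratelaws.txt",
  stoichmatrix = "StoichiometricMatrix.txt",
  genereg      = "GeneReg.txt",
  compartments = "Compartments.txt",
  observables  = "Observables.txt",
  initializer  = "Initializer.txt")

.omics_cols <- c("gene", "gene_copy_number", "mrna_mpc",
                 "k_gene_inactivation", "k_gene_activation",
                 "k_transcription_const", "k_transcription_max",
                 "k_mrna_degradation", "protein_mpc", "protein_half_life",
                 "k_translation")

read_tsv_rows <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines, whitespace = "[\r\n]"))]
  lapply(lines, function(l) {
    cells <- strsplit(sub("\r$", "", l), "\t", fixed = TRUE)[[1L]]
    trimws(cells)
  })
}

num_cell <- function(x, file, row, col, allow_missing = FALSE) {
  if (is.na(x) || !nzchar(x)) {
    if (allow_missing) return(NA_real_)
    stop(sprintf("%s: missing numeric value at row %d, column %d",
                 file, row, col), call. = FALSE)
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v))
    stop(sprintf("%s: malformed numeric cell '%s' at row %d, column %d",
                 file, x, row, col), call. = FALSE)
  v
}

#' Read a complete model input set from a directory
#'
#' Parses the eight tab-separated model-definition files into a
#' `model_input_set`.  The `Initializer` file is optional; the other seven
#' are mandatory.  Transcript species are identified by a naming convention:
#' a species named `paste0(transcript_prefix, gene)` is the mRNA of that
#' gene (default prefix `"m_"`), configurable because the file formats
#' themselves carry no transcript flag.
#'
#' @param directory path containing the files.
#' @param filename_map named character vector overriding default file names;
#'   names among `omics`, `species`, `ratelaws`, `stoichmatrix`, `genereg`,
#'   `compartments`, `observables`, `initializer`.
#' @param transcript_prefix species-name prefix marking a gene's transcript.
#' @return an object of class `model_input_set` with elements `genes`,
#'   `species`, `reactions`, `stoich`, `regulation`, `compartments`,
#'   `observables`, `initializer` (or `NULL`) and the `transcript_prefix`.
#' @seealso [write_input_set()], [validate_input_set()], [compile_model()]
#' @export
read_input_set <- function(directory, filename_map = character(),
                           transcript_prefix = "m_") {
  files <- .default_files
  if (length(filename_map)) files[names(filename_map)] <- filename_map
  paths <- file.path(directory, files)
  names(paths) <- names(files)

  mandatory <- setdiff(names(files), "initializer")
  missing <- mandatory[!file.exists(paths[mandatory])]
  if (length(missing))
    stop("missing mandatory model input file(s): ",
         paste(files[missing], collapse = ", "), call. = FALSE)

  genes        <- parse_omics(paths[["omics"]], files[["omics"]])
  compartments <- parse_compartments(paths[["compartments"]], files[["compartments"]])
  species      <- parse_species(paths[["species"]], files[["species"]],
                                compartments, genes, transcript_prefix)
  reactions    <- parse_ratelaws(paths[["ratelaws"]], files[["ratelaws"]], compartments)
  stoich       <- parse_stoich(paths[["stoichmatrix"]], files[["stoichmatrix"]])
  regulation   <- parse_genereg(paths[["genereg"]], files[["genereg"]])
  observables  <- parse_observables(paths[["observables"]], files[["observables"]])
  initializer  <- if (file.exists(paths[["initializer"]]))
    parse_initializer(paths[["initializer"]], files[["initializer"]]) else NULL

  structure(list(genes = genes, species = species, reactions = reactions,
                 stoich = stoich, regulation = regulation,
                 compartments = compartments, observables = observables,
                 initializer = initializer,
                 transcript_prefix = transcript_prefix),
            class = "model_input_set")
}

parse_omics <- function(path, file) {
  rows <- read_tsv_rows(path)[-1L]
  n <- length(rows)
  out <- data.frame(gene = character(n), gene_copy_number = numeric(n),
                    mrna_mpc = numeric(n), k_gene_inactivation = numeric(n),
                    k_gene_activation = numeric(n),
                    k_transcription_const = numeric(n),
                    k_transcription_max = numeric(n),
                    k_mrna_degradation = numeric(n), protein_mpc = numeric(n),
                    protein_half_life = numeric(n), k_translation = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    cells <- rows[[i]]
    length(cells) <- 11L
    out$gene[i] <- cells[1L]
    for (j in 2:11) {
      allow <- j %in% c(9L, 10L, 11L)   # proteomics / half-life / k_TL may be absent
      out[[.omics_cols[j]]][i] <- num_cell(cells[j], file, i + 1L, j,
                                           allow_missing = allow)
    }
  }
  if (anyDuplicated(out$gene))
    stop(file, ": duplicated gene name(s): ",
         paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "),
         call. = FALSE)
  rates <- out[, c(4:8, 11)]
  if (any(rates < 0, na.rm = TRUE))
    stop(file, ": negative rate constant", call. = FALSE)
  if (any(out$gene_copy_number < 0 | out$gene_copy_number != floor(out$gene_copy_number)))
    stop(file, ": gene copy number must be a nonnegative integer", call. = FALSE)
  out
}

parse_compartments <- function(path, file) {
  rows <- read_tsv_rows(path)[-1L]
  out <- data.frame(
    compartment = vapply(rows, `[`, character(1L), 1L),
    volume_L = vapply(seq_along(rows), function(i)
      num_cell(rows[[i]][2L], file, i + 1L, 2L), numeric(1L)),
    go_term = vapply(rows, function(r) if (length(r) >= 3L) r[3L] else "", character(1L)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(out$compartment))
    stop(file, ": duplicated compartment name", call. = FALSE)
  if (any(out$volume_L <= 0))
    stop(file, ": compartment volumes must be > 0", call. = FALSE)
  out
}

parse_species <- function(path, file, compartments, genes, transcript_prefix) {
  rows <- read_tsv_rows(path)[-1L]
  n <- length(rows)
  name <- vapply(rows, `[`, character(1L), 1L)
  comp <- vapply(rows, `[`, character(1L), 2L)
  init <- vapply(seq_len(n), function(i)
    num_cell(rows[[i]][3L], file, i + 1L, 3L), numeric(1L))
  gene_ids <- vapply(rows, function(r)
    if (length(r) >= 4L && !is.na(r[4L])) r[4L] else "", character(1L))
  if (anyDuplicated(name))
    stop(file, ": duplicated species name", call. = FALSE)
  bad <- !comp %in% compartments$compartment
  if (any(bad))
    stop(file, ": unknown compartment reference '", comp[which(bad)[1L]],
         "' at row ", which(bad)[1L] + 1L, call. = FALSE)
  if (any(init < 0))
    stop(file, ": negative initial concentration", call. = FALSE)
  transcript_of <- rep(NA_character_, n)
  pref <- transcript_prefix
  is_t <- startsWith(name, pref) & substring(name, nchar(pref) + 1L) %in% genes$gene
  transcript_of[is_t] <- substring(name[is_t], nchar(pref) + 1L)
  data.frame(species = name, compartment = comp, initial_nM = init,
             gene_ids = gene_ids, is_transcript = is_t,
             transcript_of = transcript_of, stringsAsFactors = FALSE)
}

parse_ratelaws <- function(path, file, compartments) {
  rows <- read_tsv_rows(path)[-1L]
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    cells <- rows[[i]]
    name <- cells[1L]
    comp <- cells[2L]
    if (!comp %in% compartments$compartment)
      stop(file, ": unknown compartment '", comp, "' at row ", i + 1L,
           call. = FALSE)
    law <- cells[3L]
    vals <- cells[-(1:3)]
    vals <- vals[nzchar(vals)]
    num <- suppressWarnings(as.numeric(law))
    if (!is.na(num)) {
      if (num < 0)
        stop(file, ": negative mass-action rate constant at row ", i + 1L,
             call. = FALSE)
      out[[i]] <- list(reaction = name, compartment = comp,
                       type = "mass_action", rate_constant = num,
                       formula = NA_character_, params = numeric())
    } else {
      ex <- parse_ratelaw(law, paste0(file, " row ", i + 1L, " (", name, ")"))
      syms <- expr_symbols(ex)
      locals <- syms[startsWith(syms, "k")]
      if (length(locals) != length(vals))
        stop(file, ": reaction '", name, "': formula declares ",
             length(locals), " parameter(s) (", paste(locals, collapse = ", "),
             ") but ", length(vals), " value(s) given", call. = FALSE)
      pv <- vapply(seq_along(vals), function(j)
        num_cell(vals[j], file, i + 1L, j + 3L), numeric(1L))
      names(pv) <- locals
      out[[i]] <- list(reaction = name, compartment = comp, type = "formula",
                       rate_constant = NA_real_, formula = law, params = pv)
    }
  }
  nm <- vapply(out, `[[`, character(1L), "reaction")
  if (anyDuplicated(nm)) stop(file, ": duplicated reaction name", call. = FALSE)
  out
}

parse_stoich <- function(path, file) {
  rows <- read_tsv_rows(path)
  header <- rows[[1L]][-1L]
  body <- rows[-1L]
  n <- length(body); m <- length(header)
  M <- matrix(0, n, m, dimnames = list(vapply(body, `[`, character(1L), 1L), header))
  for (i in seq_len(n)) {
    cells <- body[[i]][-1L]
    length(cells) <- m
    for (j in seq_len(m)) {
      v <- num_cell(ifelse(is.na(cells[j]), "0", cells[j]), file, i + 1L, j + 1L)
      if (v != floor(v))
        stop(file, ": non-integer stoichiometric coefficient at row ", i + 1L,
             ", column ", j + 1L, call. = FALSE)
      M[i, j] <- v
    }
  }
  M
}

#' Parse one GeneReg grid cell
#'
#' A cell is either `"0"` (no effect) or `"A; B"` where `A` is a signed Hill
#' coefficient (positive: activation, negative: repression) and `B` the
#' half-maximal regulator concentration in nM.
#'
#' @param cell the text token.
#' @param where label for error messages (grid address).
#' @return `NULL` for no effect, otherwise a list with `hill` (unsigned),
#'   `halfmax` and `role` (`"activator"` or `"repressor"`).
#' @export
parse_regulation_cell <- function(cell, where = "GeneReg cell") {
  cell <- trimws(cell)
  if (identical(cell, "0") || !nzchar(cell)) return(NULL)
  parts <- strsplit(cell, ";", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop(where, ": expected 'A; B', got '", cell, "'", call. = FALSE)
  A <- suppressWarnings(as.numeric(trimws(parts[1L])))
  B <- suppressWarnings(as.numeric(trimws(parts[2L])))
  if (is.na(A) || is.na(B))
    stop(where, ": non-numeric entry '", cell, "'", call. = FALSE)
  if (B <= 0)
    stop(where, ": half-max concentration must be > 0, got ", B, call. = FALSE)
  list(hill = abs(A), halfmax = B,
       role = if (A > 0) "activator" else "repressor")
}

parse_genereg <- function(path, file) {
  rows <- read_tsv_rows(path)
  regulators <- rows[[1L]][-1L]
  body <- rows[-1L]
  entries <- list()
  genes <- character(length(body))
  for (i in seq_along(body)) {
    cells <- body[[i]]
    genes[i] <- cells[1L]
    vals <- cells[-1L]
    length(vals) <- length(regulators)
    for (j in seq_along(regulators)) {
      cell <- ifelse(is.na(vals[j]), "0", vals[j])
      p <- parse_regulation_cell(cell, sprintf("%s row %d column %d", file, i + 1L, j + 1L))
      if (!is.null(p))
        entries[[length(entries) + 1L]] <- data.frame(
          gene = genes[i], regulator = regulators[j],
          hill = p$hill, halfmax = p$halfmax, role = p$role,
          stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(gene = character(), regulator = character(), hill = numeric(),
               halfmax = numeric(), role = character(), stringsAsFactors = FALSE)
  list(genes = genes, regulators = regulators, entries = entries)
}

parse_observables <- function(path, file) {
  rows <- read_tsv_rows(path)
  header <- rows[[1L]][-1L]
  body <- rows[-1L]
  M <- matrix(0L, length(body), length(header),
              dimnames = list(vapply(body, `[`, character(1L), 1L), header))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    length(cells) <- length(header)
    for (j in seq_along(header)) {
      v <- num_cell(ifelse(is.na(cells[j]) | !nzchar(cells[j]), "0", cells[j]),
                    file, i + 1L, j + 1L)
      if (!v %in% c(0, 1))
        stop(file, ": observable membership must be 0 or 1 at row ", i + 1L,
             ", column ", j + 1L, call. = FALSE)
      M[i, j] <- as.integer(v)
    }
  }
  M
}

parse_initializer <- function(path, file) {
  rows <- read_tsv_rows(path)[-1L]
  get2 <- function(r, a, b) c(if (length(r) >= a) r[a] else "",
                              if (length(r) >= b) r[b] else "")
  sp <- list(); mr <- list(); pv <- list(); excl <- character(); scan <- NULL
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    x <- get2(r, 1L, 2L)
    if (nzchar(x[1L])) sp[[length(sp) + 1L]] <-
      data.frame(species = x[1L], value_nM = num_cell(x[2L], file, i + 1L, 2L),
                 stringsAsFactors = FALSE)
    x <- get2(r, 3L, 4L)
    if (nzchar(x[1L])) mr[[length(mr) + 1L]] <-
      data.frame(gene = x[1L], mrna_mpc = num_cell(x[2L], file, i + 1L, 4L),
                 stringsAsFactors = FALSE)
    x <- get2(r, 5L, 6L)
    if (nzchar(x[1L])) pv[[length(pv) + 1L]] <-
      data.frame(parameter = x[1L], value = num_cell(x[2L], file, i + 1L, 6L),
                 stringsAsFactors = FALSE)
    if (length(r) >= 8L && nzchar(r[8L])) excl <- c(excl, r[8L])
    if (length(r) >= 9L && nzchar(r[9L]) && is.null(scan))
      scan <- list(parameter = r[9L],
                   low = num_cell(r[10L], file, i + 1L, 10L),
                   high = num_cell(r[11L], file, i + 1L, 11L))
  }
  bindf <- function(l, proto) if (length(l)) do.call(rbind, l) else proto
  list(species_overrides = bindf(sp, data.frame(species = character(),
                                                value_nM = numeric(), stringsAsFactors = FALSE)),
       mrna_adjustments = bindf(mr, data.frame(gene = character(),
                                               mrna_mpc = numeric(), stringsAsFactors = FALSE)),
       parameter_overrides = bindf(pv, data.frame(parameter = character(),
                                                  value = numeric(), stringsAsFactors = FALSE)),
       observables_excluded = excl, scan = scan)
}

#' Validate cross-file consistency of a model input set
#'
#' Runs the order-sensitive consistency checks between the files: Species
#' rows against stoichiometric-matrix rows, Ratelaws rows against matrix
#' columns, formula symbols against declared species/parameters, GeneReg
#' rows against the gene list (same order), compartment references, and
#' observable rows against Species.
#'
#' @param m a `model_input_set`.
#' @param strict if `TRUE`, any failed check raises an error.
#' @return a `validation_report`: data frame of checks with `check`,
#'   `pass`, `detail`, plus attribute `pass` for the conjunction.
#' @export
validate_input_set <- function(m, strict = FALSE) {
  checks <- list()
  add <- function(check, pass, detail = "")
    checks[[length(checks) + 1L]] <<- data.frame(check = check, pass = pass,
                                                 detail = detail, stringsAsFactors = FALSE)

  sp <- m$species$species
  add("species rows match stoichiometry rows",
      identical(sp, rownames(m$stoich)),
      if (!identical(sp, rownames(m$stoich))) {
        if (length(sp) != nrow(m$stoich))
          sprintf("Species has %d rows, StoichiometricMatrix has %d",
                  length(sp), nrow(m$stoich))
        else sprintf("first mismatch at row %d: '%s' vs '%s'",
                     which(sp != rownames(m$stoich))[1L],
                     sp[which(sp != rownames(m$stoich))[1L]],
                     rownames(m$stoich)[which(sp != rownames(m$stoich))[1L]])
      } else "")

  rxn <- vapply(m$reactions, `[[`, character(1L), "reaction")
  add("reaction rows match stoichiometry columns",
      identical(rxn, colnames(m$stoich)),
      if (!identical(rxn, colnames(m$stoich)))
        sprintf("Ratelaws has %d rows, StoichiometricMatrix has %d columns",
                length(rxn), ncol(m$stoich)) else "")

  for (r in m$reactions) {
    if (r$type != "formula") next
    syms <- expr_symbols(parse_ratelaw(r$formula, r$reaction))
    unknown <- setdiff(syms, c(sp, names(r$params), m$compartments$compartment))
    if (length(unknown))
      add("formula symbols resolve", FALSE,
          sprintf("reaction '%s' references undeclared symbol(s): %s",
                  r$reaction, paste(unknown, collapse = ", ")))
  }
  if (!any(vapply(checks, function(x) x$check == "formula symbols resolve", logical(1L))))
    add("formula symbols resolve", TRUE)

  add("GeneReg genes match OmicsData order",
      identical(m$regulation$genes, m$genes$gene),
      if (!identical(m$regulation$genes, m$genes$gene))
        "GeneReg row genes differ from OmicsData first column (order-sensitive)" else "")

  reg_sp <- unique(m$regulation$entries$regulator)
  unknown <- setdiff(reg_sp, sp)
  add("GeneReg regulators exist in Species", length(unknown) == 0L,
      if (length(unknown)) paste("unknown regulator species:",
                                 paste(unknown, collapse = ", ")) else "")

  add("observable rows match Species",
      identical(rownames(m$observables), sp),
      if (!identical(rownames(m$observables), sp))
        "Observables row names differ from Species order" else "")

  comp_used <- unique(c(m$species$compartment,
                        vapply(m$reactions, `[[`, character(1L), "compartment")))
  unknown <- setdiff(comp_used, m$compartments$compartment)
  add("compartment references resolve", length(unknown) == 0L,
      if (length(unknown)) paste("unknown compartment:",
                                 paste(unknown, collapse = ", ")) else "")

  if (!is.null(m$initializer)) {
    bad <- setdiff(m$initializer$species_overrides$species, sp)
    bad2 <- setdiff(m$initializer$mrna_adjustments$gene, m$genes$gene)
    add("initializer references resolve", length(bad) + length(bad2) == 0L,
        paste(c(if (length(bad)) paste("unknown species:", paste(bad, collapse = ", ")),
                if (length(bad2)) paste("unknown gene:", paste(bad2, collapse = ", "))),
              collapse = "; "))
  }

  report <- do.call(rbind, checks)
  ok <- all(report$pass)
  if (strict && !ok)
    stop("model input set failed validation:\n",
         paste(sprintf("  [%s] %s", report$check[!report$pass],
                       report$detail[!report$pass]), collapse = "\n"),
         call. = FALSE)
  structure(report, pass = ok, class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  status <- ifelse(x$pass, "ok", "FAIL")
  cat("model input set validation:", if (attr(x, "pass")) "PASS" else "FAIL", "\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  [%4s] %s%s\n", status[i], x$check[i],
                if (nzchar(x$detail[i])) paste0(" -- ", x$detail[i]) else ""))
  invisible(x)
}

#' Write a model input set back to the TSV dialects
#'
#' Inverse of [read_input_set()]: numeric values are written at full
#' precision so that a write/read round trip reproduces the input set
#' field-for-field.  No `Initializer` file is written when the set has none.
#'
#' @param m a `model_input_set`.
#' @param directory output directory (created if needed).
#' @param filename_map optional file-name overrides as in [read_input_set()].
#' @return invisibly, the named vector of paths written.
#' @export
write_input_set <- function(m, directory, filename_map = character()) {
  files <- .default_files
  if (length(filename_map)) files[names(filename_map)] <- filename_map
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", directory, call. = FALSE)

  wl <- function(lines, key) {
    p <- file.path(directory, files[[key]])
    writeLines(lines, p)
    p
  }
  paths <- c()

  g <- m$genes
  lines <- c(paste(.omics_cols, collapse = "\t"),
             vapply(seq_len(nrow(g)), function(i)
               paste(c(g$gene[i], fmt_num(as.numeric(g[i, .omics_cols[-1L]]))),
                     collapse = "\t"), character(1L)))
  paths["omics"] <- wl(lines, "omics")

  s <- m$species
  lines <- c("species\tcompartment\tinitial_nM\tgene_ids",
             paste(s$species, s$compartment, fmt_num(s$initial_nM), s$gene_ids,
                   sep = "\t"))
  paths["species"] <- wl(lines, "species")

  lines <- "reaction\tcompartment\tratelaw\tparam_values"
  for (r in m$reactions) {
    if (r$type == "mass_action")
      lines <- c(lines, paste(r$reaction, r$compartment,
                              fmt_num(r$rate_constant), sep = "\t"))
    else
      lines <- c(lines, paste(c(r$reaction, r$compartment, r$formula,
                                fmt_num(unname(r$params))), collapse = "\t"))
  }
  paths["ratelaws"] <- wl(lines, "ratelaws")

  M <- m$stoich
  lines <- c(paste(c("species", colnames(M)), collapse = "\t"),
             vapply(seq_len(nrow(M)), function(i)
               paste(c(rownames(M)[i], fmt_num(M[i, ])), collapse = "\t"),
               character(1L)))
  paths["stoichmatrix"] <- wl(lines, "stoichmatrix")

  reg <- m$regulation
  grid <- matrix("0", length(reg$genes), length(reg$regulators),
                 dimnames = list(reg$genes, reg$regulators))
  e <- reg$entries
  if (nrow(e)) for (i in seq_len(nrow(e))) {
    A <- e$hill[i] * if (e$role[i] == "repressor") -1 else 1
    grid[e$gene[i], e$regulator[i]] <- paste0(fmt_num(A), "; ", fmt_num(e$halfmax[i]))
  }
  lines <- c(paste(c("gene", reg$regulators), collapse = "\t"),
             vapply(seq_along(reg$genes), function(i)
               paste(c(reg$genes[i], grid[i, ]), collapse = "\t"), character(1L)))
  paths["genereg"] <- wl(lines, "genereg")

  cp <- m$compartments
  lines <- c("compartment\tvolume_L\tgo_term",
             paste(cp$compartment, fmt_num(cp$volume_L), cp$go_term, sep = "\t"))
  paths["compartments"] <- wl(lines, "compartments")

  O <- m$observables
  lines <- c(paste(c("species", colnames(O)), collapse = "\t"),
             vapply(seq_len(nrow(O)), function(i)
               paste(c(rownames(O)[i], O[i, ]), collapse = "\t"), character(1L)))
  paths["observables"] <- wl(lines, "observables")

  if (!is.null(m$initializer)) {
    ini <- m$initializer
    nr <- max(nrow(ini$species_overrides), nrow(ini$mrna_adjustments),
              nrow(ini$parameter_overrides), length(ini$observables_excluded),
              if (is.null(ini$scan)) 0L else 1L)
    grid <- matrix("", nr, 11L)
    if (nrow(ini$species_overrides)) {
      grid[seq_len(nrow(ini$species_overrides)), 1L] <- ini$species_overrides$species
      grid[seq_len(nrow(ini$species_overrides)), 2L] <- fmt_num(ini$species_overrides$value_nM)
    }
    if (nrow(ini$mrna_adjustments)) {
      grid[seq_len(nrow(ini$mrna_adjustments)), 3L] <- ini$mrna_adjustments$gene
      grid[seq_len(nrow(ini$mrna_adjustments)), 4L] <- fmt_num(ini$mrna_adjustments$mrna_mpc)
    }
    if (nrow(ini$parameter_overrides)) {
      grid[seq_len(nrow(ini$parameter_overrides)), 5L] <- ini$parameter_overrides$parameter
      grid[seq_len(nrow(ini$parameter_overrides)), 6L] <- fmt_num(ini$parameter_overrides$value)
    }
    if (length(ini$observables_excluded))
      grid[seq_along(ini$observables_excluded), 8L] <- ini$observables_excluded
    if (!is.null(ini$scan)) {
      grid[1L, 9L] <- ini$scan$parameter
      grid[1L, 10L] <- fmt_num(ini$scan$low)
      grid[1L, 11L] <- fmt_num(ini$scan$high)
    }
    lines <- c(paste(c("species", "value_nM", "gene", "mrna_mpc", "parameter",
                       "value", "reserved", "exclude_observable",
                       "scan_parameter", "scan_low", "scan_high"), collapse = "\t"),
               apply(grid, 1L, paste, collapse = "\t"))
    paths["initializer"] <- wl(lines, "initializer")
  }
  invisible(paths)
}

#' @export
print.model_input_set <- function(x, ...) {
  cat("model input set:",
      nrow(x$genes), "genes,",
      nrow(x$species), "species,",
      length(x$reactions), "reactions,",
      nrow(x$compartments), "compartments,",
      ncol(x$observables), "observables\n")
  cat("  transcripts flagged:", sum(x$species$is_transcript),
      " regulation entries:", nrow(x$regulation$entries),
      " initializer:", if (is.null(x$initializer)) "absent" else "present", "\n")
  invisible(x)
}
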