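# SBML Level 3 Version 2 (core) export and import, built directly on xml2.
#
# Conventions: compartments carry their volume in liters as `size` and a
# Gene Ontology term as an RDF annotation; species carry home compartment,
# initial concentration in nM, and ENSEMBL-style gene identifiers as RDF
# annotations; every global parameter records its source reaction and the
# original local name in an annotation; each reaction stores its home
# compartment in the L3 `compartment` attribute and its full rate law
# (including any cross-compartment volume-correction factors already folded
# in at compile time) as MathML, so an import reproduces the compiled
# right-hand side exactly.

SBML_NS <- "http://www.sbml.org/sbml/level3/version2/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"
NETSIM_NS <- "https://netsim.invalid/sbml-annotations"

#' Sanitize identifiers to valid SBML SIds
#'
#' Maps every character outside `[A-Za-z0-9_]` to `_`, prefixes a leading
#' digit with `x`, and disambiguates collisions with a numeric suffix.
#'
#' @param ids character vector.
#' @return named character vector: sanitized ids named by the originals
#'   (the translation table).
#' @export
sanitize_sbml_ids <- function(ids) {
  out <- gsub("[^A-Za-z0-9_]", "_", ids)
  lead <- grepl("^[0-9]", out)
  out[lead] <- paste0("x", out[lead])
  while (anyDuplicated(out)) {
    d <- which(duplicated(out))
    out[d] <- paste0(out[d], "_", seq_along(d))
  }
  stats::setNames(out, ids)
}

expr_to_mathml <- function(ex, parent) {
  if (is.numeric(ex)) {
    xml2::xml_add_child(parent, "cn", shortest_roundtrip(ex))
  } else if (is.symbol(ex)) {
    xml2::xml_add_child(parent, "ci", as.character(ex))
  } else if (is.call(ex)) {
    op <- as.character(ex[[1L]])
    if (op == "(") return(expr_to_mathml(ex[[2L]], parent))
    tag <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                  "/" = "divide", "^" = "power",
                  stop("cannot encode operator '", op, "' as MathML"))
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, tag)
    for (i in seq_along(ex)[-1L]) expr_to_mathml(ex[[i]], ap)
  } else stop("cannot encode expression as MathML")
  invisible(parent)
}

mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
  if (nm == "ci") return(as.symbol(trimws(xml2::xml_text(node))))
  if (nm == "apply") {
    kids <- xml2::xml_children(node)
    op <- switch(xml2::xml_name(kids[[1L]]),
                 plus = "+", minus = "-", times = "*", divide = "/",
                 power = "^",
                 stop("unsupported MathML operator: ", xml2::xml_name(kids[[1L]])))
    args <- lapply(kids[-1L], mathml_to_expr)
    if (length(args) == 1L) return(as.call(c(as.symbol(op), args)))
    # fold n-ary plus/times left-associatively
    ex <- args[[1L]]
    for (i in seq_along(args)[-1L]) ex <- call(op, ex, args[[i]])
    return(ex)
  }
  if (nm == "math") return(mathml_to_expr(xml2::xml_child(node)))
  stop("unsupported MathML node: ", nm)
}

rdf_annotation <- function(parent, about, resources) {
  lis <- paste0(sprintf('<rdf:li rdf:resource="%s"/>', resources),
                collapse = "")
  txt <- sprintf(paste0(
    '<annotation><rdf:RDF xmlns:rdf="%s" xmlns:bqbiol="%s">',
    '<rdf:Description rdf:about="#%s"><bqbiol:is><rdf:Bag>%s</rdf:Bag>',
    '</bqbiol:is></rdf:Description></rdf:RDF></annotation>'),
    RDF_NS, BQBIOL_NS, about, lis)
  xml2::xml_add_child(parent, xml2::read_xml(txt))
  invisible(parent)
}

read_rdf_resources <- function(node) {
  lis <- xml2::xml_find_all(node, ".//rdf:li",
                            ns = c(rdf = RDF_NS))
  vapply(lis, function(x) xml2::xml_attr(x, "resource"), character(1L))
}

#' Export a compiled model as an annotated SBML Level 3 document
#'
#' @param cm a `compiled_model`.
#' @param file path of the `.xml` file to write.
#' @param model_id SBML model id.
#' @return invisibly, the id translation table (original -> sanitized)
#'   covering species, reactions, parameters and compartments.
#' @export
export_sbml <- function(cm, file, model_id = "model") {
  all_ids <- c(cm$species, cm$reactions, names(cm$param_values),
               names(cm$comp_vols))
  idmap <- sanitize_sbml_ids(all_ids)

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = model_id,
                               substanceUnits = "item", timeUnits = "second",
                               volumeUnits = "litre", extentUnits = "item")

  loc <- xml2::xml_add_child(model, "listOfCompartments")
  for (cn in names(cm$comp_vols)) {
    comp <- xml2::xml_add_child(loc, "compartment", id = idmap[[cn]],
                                name = cn, spatialDimensions = "3",
                                size = shortest_roundtrip(cm$comp_vols[[cn]]),
                                constant = "true")
    go <- cm$compartments_go[[cn]]
    if (!is.null(go) && nzchar(go))
      rdf_annotation(comp, idmap[[cn]],
                     paste0("https://identifiers.org/GO:", sub("^GO:", "", go)))
  }

  los <- xml2::xml_add_child(model, "listOfSpecies")
  for (sn in cm$species) {
    spn <- xml2::xml_add_child(
      los, "species", id = idmap[[sn]], name = sn,
      compartment = idmap[[cm$species_comp[[sn]]]],
      initialConcentration = shortest_roundtrip(cm$init[[sn]]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
    ids <- trimws(strsplit(cm$species_gene_ids[[sn]], ",")[[1L]])
    ids <- ids[nzchar(ids)]
    if (length(ids))
      rdf_annotation(spn, idmap[[sn]],
                     paste0("https://identifiers.org/ensembl/", ids))
  }

  lop <- xml2::xml_add_child(model, "listOfParameters")
  for (q in seq_len(nrow(cm$params))) {
    par <- xml2::xml_add_child(
      lop, "parameter", id = idmap[[cm$params$global[q]]],
      value = shortest_roundtrip(cm$params$value[q]), constant = "true")
    ann <- xml2::xml_add_child(par, "annotation")
    xml2::xml_add_child(ann, "origin", xmlns = NETSIM_NS,
                        reaction = cm$params$reaction[q],
                        localName = cm$params$local[q])
  }

  lor <- xml2::xml_add_child(model, "listOfReactions")
  for (j in seq_along(cm$reactions)) {
    rx <- xml2::xml_add_child(lor, "reaction", id = idmap[[cm$reactions[j]]],
                              name = cm$reactions[j], reversible = "false",
                              compartment = idmap[[cm$rxn_compartment[j]]])
    col <- cm$stoich[, j]
    reac <- which(col < 0); prod <- which(col > 0)
    if (length(reac)) {
      l <- xml2::xml_add_child(rx, "listOfReactants")
      for (i in reac)
        xml2::xml_add_child(l, "speciesReference",
                            species = idmap[[cm$species[i]]],
                            stoichiometry = shortest_roundtrip(abs(col[i])),
                            constant = "true")
    }
    if (length(prod)) {
      l <- xml2::xml_add_child(rx, "listOfProducts")
      for (i in prod)
        xml2::xml_add_child(l, "speciesReference",
                            species = idmap[[cm$species[i]]],
                            stoichiometry = shortest_roundtrip(col[i]),
                            constant = "true")
    }
    syms <- expr_symbols(cm$rate_exprs[[j]])
    mods <- setdiff(intersect(syms, cm$species),
                    cm$species[c(reac, prod)])
    if (length(mods)) {
      l <- xml2::xml_add_child(rx, "listOfModifiers")
      for (sn in mods)
        xml2::xml_add_child(l, "modifierSpeciesReference",
                            species = idmap[[sn]])
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math", xmlns = MATHML_NS)
    # rewrite symbols to sanitized ids
    ex <- substitute_symbols(cm$rate_exprs[[j]],
                             stats::setNames(lapply(idmap, as.symbol), names(idmap)))
    expr_to_mathml(ex, math)
  }

  xml2::write_xml(doc, file)
  invisible(idmap)
}

#' Import an SBML document written by [export_sbml()]
#'
#' Rebuilds a `compiled_model` (species order, initial state, stoichiometry,
#' rate-law expressions, parameter table with source reaction/local names,
#' compartments) from the document.  The gene-expression bundle and
#' observables are not part of SBML; they come back empty, so a re-imported
#' model supports deterministic signalling simulation and RHS evaluation.
#'
#' @param file path to the `.xml` document.
#' @return a `compiled_model`.
#' @export
import_sbml <- function(file) {
  doc <- xml2::read_xml(file)
  ns <- c(s = SBML_NS, m = MATHML_NS, n = NETSIM_NS)
  model <- xml2::xml_find_first(doc, "./s:model", ns)
  if (inherits(model, "xml_missing"))
    stop("not an SBML Level 3 document: ", file, call. = FALSE)

  cnodes <- xml2::xml_find_all(model, "./s:listOfCompartments/s:compartment", ns)
  comp_ids <- xml2::xml_attr(cnodes, "id")
  comp_names <- xml2::xml_attr(cnodes, "name")
  comp_names[is.na(comp_names)] <- comp_ids[is.na(comp_names)]
  comp_vols <- stats::setNames(as.numeric(xml2::xml_attr(cnodes, "size")), comp_names)
  comp_go <- stats::setNames(vapply(cnodes, function(x) {
    res <- read_rdf_resources(x)
    if (length(res)) sub("^.*/", "", res[1L]) else ""
  }, character(1L)), comp_names)
  id2comp <- stats::setNames(comp_names, comp_ids)

  snodes <- xml2::xml_find_all(model, "./s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(snodes, "id")
  sp_names <- xml2::xml_attr(snodes, "name")
  sp_names[is.na(sp_names)] <- sp_ids[is.na(sp_names)]
  init <- stats::setNames(as.numeric(xml2::xml_attr(snodes, "initialConcentration")),
                          sp_names)
  species_comp <- stats::setNames(
    unname(id2comp[xml2::xml_attr(snodes, "compartment")]), sp_names)
  gene_ids <- stats::setNames(vapply(snodes, function(x) {
    res <- read_rdf_resources(x)
    paste(sub("^.*/", "", res), collapse = ",")
  }, character(1L)), sp_names)
  id2sp <- stats::setNames(sp_names, sp_ids)

  pnodes <- xml2::xml_find_all(model, "./s:listOfParameters/s:parameter", ns)
  p_ids <- xml2::xml_attr(pnodes, "id")
  p_val <- as.numeric(xml2::xml_attr(pnodes, "value"))
  origin <- lapply(pnodes, function(x)
    xml2::xml_find_first(x, ".//n:origin", ns))
  p_rxn <- vapply(origin, function(o)
    if (inherits(o, "xml_missing")) NA_character_ else xml2::xml_attr(o, "reaction"),
    character(1L))
  p_loc <- vapply(origin, function(o)
    if (inherits(o, "xml_missing")) NA_character_ else xml2::xml_attr(o, "localName"),
    character(1L))
  params <- data.frame(global = p_ids, reaction = p_rxn, local = p_loc,
                       value = p_val, stringsAsFactors = FALSE)

  rnodes <- xml2::xml_find_all(model, "./s:listOfReactions/s:reaction", ns)
  rxn_ids <- xml2::xml_attr(rnodes, "id")
  rxn_names <- xml2::xml_attr(rnodes, "name")
  rxn_names[is.na(rxn_names)] <- rxn_ids[is.na(rxn_names)]
  rxn_comp <- unname(id2comp[xml2::xml_attr(rnodes, "compartment")])
  S <- matrix(0, length(sp_names), length(rxn_names),
              dimnames = list(sp_names, rxn_names))
  rate_exprs <- vector("list", length(rnodes))
  backmap <- stats::setNames(lapply(c(id2sp, stats::setNames(comp_names, comp_ids)),
                                    as.symbol),
                             c(names(id2sp), comp_ids))
  for (j in seq_along(rnodes)) {
    rn <- rnodes[[j]]
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns))
      S[id2sp[[xml2::xml_attr(sr, "species")]], j] <-
        S[id2sp[[xml2::xml_attr(sr, "species")]], j] -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns))
      S[id2sp[[xml2::xml_attr(sr, "species")]], j] <-
        S[id2sp[[xml2::xml_attr(sr, "species")]], j] +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    math <- xml2::xml_find_first(rn, "./s:kineticLaw/m:math", ns)
    if (inherits(math, "xml_missing"))
      stop("reaction '", rxn_names[j], "' has no kinetic law", call. = FALSE)
    ex <- mathml_to_expr(xml2::xml_child(math))
    rate_exprs[[j]] <- substitute_symbols(ex, backmap)
  }

  genes <- data.frame(gene = character(), gene_copy_number = numeric(),
                      mrna_mpc = numeric(), k_gene_inactivation = numeric(),
                      k_gene_activation = numeric(),
                      k_transcription_const = numeric(),
                      k_transcription_max = numeric(),
                      k_mrna_degradation = numeric(), protein_mpc = numeric(),
                      protein_half_life = numeric(), k_translation = numeric(),
                      transcript = character(), transcript_comp = character(),
                      f_active = numeric(), translation_param = character(),
                      stringsAsFactors = FALSE)

  cm <- structure(list(
    species = sp_names,
    init = init,
    stoich = S,
    reactions = rxn_names,
    rxn_compartment = rxn_comp,
    rate_exprs = rate_exprs,
    params = params,
    param_values = stats::setNames(p_val, p_ids),
    comp_vols = comp_vols,
    species_comp = species_comp,
    species_gene_ids = gene_ids,
    is_transcript = stats::setNames(rep(FALSE, length(sp_names)), sp_names),
    genes = genes,
    regulation = data.frame(gene = character(), regulator = character(),
                            hill = numeric(), halfmax = numeric(),
                            role = character(), stringsAsFactors = FALSE),
    observables = matrix(0L, length(sp_names), 0L,
                         dimnames = list(sp_names, character())),
    observable_reference = if ("Cytoplasm" %in% comp_names) "Cytoplasm"
    else comp_names[1L],
    compartments_go = comp_go,
    death_roles = NULL,
    cyclin_roles = NULL), class = "compiled_model")
  cm$rhs <- build_rhs(cm)
  cm
}
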