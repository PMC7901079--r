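#' Genome-scale model container
#'
#' A `gem` holds a stoichiometric metabolic network the way constraint-based
#' tools represent it: a metabolite table, a reaction table with flux bounds
#' and gene associations, a sparse stoichiometry in triplet form, and one
#' objective (biomass) reaction. It is the "library of metabolites and
#' reactions" that pathway reconstruction draws on, and the substrate for
#' [fba()], [max_production()] and [knockout_scan()].
#'
#' @param model_id Identifier for the model.
#' @param mets Tibble with columns `met_id`, `name`, `compartment`.
#' @param rxns Tibble with columns `rxn_id`, `name`, `lb`, `ub`, `genes`
#'   (list-column of character vectors), `objective_coef`.
#' @param stoich Tibble with columns `rxn_id`, `met_id`, `coef` (negative =
#'   consumed).
#' @return A `gem` object.
#' @export
gem <- function(model_id, mets, rxns, stoich) {
  mets <- tibble::as_tibble(mets)
  rxns <- tibble::as_tibble(rxns)
  stoich <- tibble::as_tibble(stoich)
  if (!"genes" %in% names(rxns)) rxns$genes <- rep(list(character(0)), nrow(rxns))
  if (!"objective_coef" %in% names(rxns)) rxns$objective_coef <- 0
  if (!"name" %in% names(rxns)) rxns$name <- rxns$rxn_id
  if (!"name" %in% names(mets)) mets$name <- mets$met_id
  x <- structure(list(model_id = model_id, mets = mets, rxns = rxns,
                      stoich = stoich, pathway_rxns = character(0)),
                 class = "gem")
  validate_gem(x)
  x
}

#' Structural validation of a model
#'
#' Checks that every stoichiometric entry refers to an existing reaction and
#' metabolite, ids are unique, bounds are ordered and finite or at the
#' default +/-1000, and that exactly one objective reaction exists.
#'
#' @param model A `gem`.
#' @return The model, invisibly; errors describe the first violation found.
#' @export
validate_gem <- function(model) {
  stopifnot(inherits(model, "gem"))
  if (anyDuplicated(model$rxns$rxn_id)) {
    stop("duplicate reaction ids: ",
         paste(unique(model$rxns$rxn_id[duplicated(model$rxns$rxn_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(model$mets$met_id)) {
    stop("duplicate metabolite ids", call. = FALSE)
  }
  bad_r <- setdiff(model$stoich$rxn_id, model$rxns$rxn_id)
  if (length(bad_r)) stop("stoichiometry refers to unknown reaction: ",
                          paste(bad_r, collapse = ", "), call. = FALSE)
  bad_m <- setdiff(model$stoich$met_id, model$mets$met_id)
  if (length(bad_m)) stop("stoichiometry refers to unknown metabolite: ",
                          paste(bad_m, collapse = ", "), call. = FALSE)
  if (any(model$rxns$lb > model$rxns$ub)) {
    stop("reaction with lb > ub", call. = FALSE)
  }
  if (any(!is.finite(model$rxns$lb) & model$rxns$lb != -Inf) ||
      any(!is.finite(model$rxns$ub) & model$rxns$ub != Inf)) {
    stop("non-finite bound that is not +/-Inf", call. = FALSE)
  }
  if (sum(model$rxns$objective_coef != 0) != 1) {
    stop("model must have exactly one objective reaction", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.gem <- function(x, ...) {
  cat(sprintf("<gem> %s: %d reactions, %d metabolites, objective %s\n",
              x$model_id, nrow(x$rxns), nrow(x$mets), objective_id(x)))
  invisible(x)
}

#' Identifier of the model objective (biomass) reaction
#' @param model A `gem`.
#' @return A reaction id.
#' @export
objective_id <- function(model) {
  model$rxns$rxn_id[model$rxns$objective_coef != 0][1]
}

#' Exchange (boundary) reactions of a model
#'
#' A reaction is a boundary reaction when it touches exactly one metabolite
#' (exchange, demand or sink).
#'
#' @param model A `gem`.
#' @return Tibble mapping `rxn_id` to the single `met_id` it exchanges.
#' @export
exchanges <- function(model) {
  cnt <- dplyr::count(model$stoich, .data$rxn_id)
  one <- cnt$rxn_id[cnt$n == 1]
  dplyr::select(dplyr::filter(model$stoich, .data$rxn_id %in% one),
                "rxn_id", "met_id")
}

#' @export
#' @method glance gem
glance.gem <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, n_reactions = nrow(x$rxns),
                 n_metabolites = nrow(x$mets),
                 n_exchanges = nrow(exchanges(x)),
                 objective = objective_id(x))
}

#' Tidy a model into its reaction table
#' @param x A `gem`.
#' @param ... Unused.
#' @return Tibble of reactions with bounds and gene associations.
#' @export
#' @method tidy gem
tidy.gem <- function(x, ...) x$rxns

# dense or sparse retrieval of the stoichiometric matrix (mets x rxns)
stoich_matrix <- function(model) {
  m <- matrix(0, nrow(model$mets), nrow(model$rxns),
              dimnames = list(model$mets$met_id, model$rxns$rxn_id))
  m[cbind(model$stoich$met_id, model$stoich$rxn_id)] <- model$stoich$coef
  m
}

# ---- SBML L3V1 + FBC v2 I/O ------------------------------------------------
# Hand-written against the FBC subset this package needs (no libSBML binding
# exists in this R stack). Bounds are stored as shared parameters; gene
# associations as fbc:geneProductRef lists under an OR/AND is not needed --
# plain conjunction-free gene lists are written and read.

.sbml_ns <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

#' Read a genome-scale model from SBML (Level 3 + FBC)
#'
#' Performs a lossless load of ids, names, compartments, stoichiometry, flux
#' bounds, gene associations and the FBC objective. SBML files without FBC
#' flux bounds are rejected, naming the deficiency.
#'
#' @param path Path to an SBML file.
#' @return A `gem`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("unreadable SBML: ", conditionMessage(e),
                                           call. = FALSE))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  model_node <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (is.na(xml2::xml_attr(model_node, "id"))) {
    model_id <- "model"
  } else {
    model_id <- xml2::xml_attr(model_node, "id")
  }

  params <- xml2::xml_find_all(doc, ".//sbml:listOfParameters/sbml:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  strip <- function(x, pre) sub(paste0("^", pre, "_"), "", x)
  species <- xml2::xml_find_all(doc, ".//sbml:listOfSpecies/sbml:species", ns)
  mets <- tibble::tibble(
    met_id = strip(xml2::xml_attr(species, "id"), "M"),
    name = dplyr::coalesce(xml2::xml_attr(species, "name"),
                           xml2::xml_attr(species, "id")),
    compartment = xml2::xml_attr(species, "compartment")
  )

  rxn_nodes <- xml2::xml_find_all(doc, ".//sbml:listOfReactions/sbml:reaction", ns)
  if (length(rxn_nodes) > 0) {
    has_fbc <- !is.na(xml2::xml_attr(rxn_nodes[[1]], "lowerFluxBound"))
    if (!has_fbc) {
      stop("SBML file lacks fbc flux bounds (fbc:lowerFluxBound/upperFluxBound); ",
           "only Level 3 + FBC models are supported", call. = FALSE)
    }
  }

  one_rxn <- function(node) {
    rid <- strip(xml2::xml_attr(node, "id"), "R")
    lb_ref <- xml2::xml_attr(node, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(node, "upperFluxBound")
    reac <- xml2::xml_find_all(node, "./sbml:listOfReactants/sbml:speciesReference", ns)
    prod <- xml2::xml_find_all(node, "./sbml:listOfProducts/sbml:speciesReference", ns)
    gpr <- xml2::xml_find_all(node, ".//fbc:geneProductRef", ns)
    list(
      rxn_id = rid,
      name = dplyr::coalesce(xml2::xml_attr(node, "name"), rid),
      lb = unname(pval[lb_ref]), ub = unname(pval[ub_ref]),
      genes = strip(xml2::xml_attr(gpr, "geneProduct"), "G"),
      stoich = tibble::tibble(
        rxn_id = rid,
        met_id = strip(c(xml2::xml_attr(reac, "species"),
                         xml2::xml_attr(prod, "species")), "M"),
        coef = c(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                 as.numeric(xml2::xml_attr(prod, "stoichiometry")))
      )
    )
  }
  parsed <- lapply(rxn_nodes, one_rxn)
  rxns <- tibble::tibble(
    rxn_id = purrr::map_chr(parsed, "rxn_id"),
    name = purrr::map_chr(parsed, "name"),
    lb = purrr::map_dbl(parsed, "lb"),
    ub = purrr::map_dbl(parsed, "ub"),
    genes = purrr::map(parsed, "genes"),
    objective_coef = 0
  )
  stoich <- dplyr::bind_rows(purrr::map(parsed, "stoich"))

  obj_ref <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj_ref, "xml_missing")) {
    stop("SBML model has no fbc objective", call. = FALSE)
  }
  obj_rxn <- strip(xml2::xml_attr(obj_ref, "reaction"), "R")
  rxns$objective_coef[rxns$rxn_id == obj_rxn] <-
    as.numeric(xml2::xml_attr(obj_ref, "coefficient"))

  gem(model_id, mets, rxns, stoich)
}

#' Write a genome-scale model to SBML (Level 3 + FBC)
#'
#' @param model A `gem`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, scientific = FALSE, trim = TRUE, digits = 15)

  # shared bound parameters
  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bid <- function(v) {
    s <- gsub("-", "minus_", gsub("\\.", "_", num(v)))
    paste0("fb_", s)
  }
  par_lines <- vapply(bounds, function(v) {
    sprintf('      <parameter id="%s" value="%s" constant="true"/>', bid(v), num(v))
  }, character(1))

  comps <- unique(model$mets$compartment)
  comp_lines <- sprintf('      <compartment id="%s" constant="true"/>', comps)

  sp_lines <- sprintf(
    '      <species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    esc(model$mets$met_id), esc(model$mets$name), model$mets$compartment)

  all_genes <- sort(unique(unlist(model$rxns$genes)))
  gp_lines <- if (length(all_genes)) {
    sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
            esc(all_genes), esc(all_genes))
  } else character(0)

  stoich_by_rxn <- split(model$stoich, model$stoich$rxn_id)
  rxn_lines <- unlist(lapply(seq_len(nrow(model$rxns)), function(i) {
    r <- model$rxns[i, ]
    st <- stoich_by_rxn[[r$rxn_id]]
    reac <- st[st$coef < 0, ]
    prod <- st[st$coef > 0, ]
    lines <- sprintf(
      '      <reaction id="R_%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(r$rxn_id), esc(r$name), tolower(r$lb < 0), bid(r$lb), bid(r$ub))
    genes <- r$genes[[1]]
    if (length(genes) > 0) {
      lines <- c(lines, "        <fbc:geneProductAssociation>")
      if (length(genes) == 1) {
        lines <- c(lines, sprintf('          <fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                                  esc(genes)))
      } else {
        lines <- c(lines, "          <fbc:and>",
                   sprintf('            <fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                           esc(genes)),
                   "          </fbc:and>")
      }
      lines <- c(lines, "        </fbc:geneProductAssociation>")
    }
    if (nrow(reac) > 0) {
      lines <- c(lines, "        <listOfReactants>",
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         esc(reac$met_id), num(-reac$coef)),
                 "        </listOfReactants>")
    }
    if (nrow(prod) > 0) {
      lines <- c(lines, "        <listOfProducts>",
                 sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                         esc(prod$met_id), num(prod$coef)),
                 "        </listOfProducts>")
    }
    c(lines, "      </reaction>")
  }))

  obj <- model$rxns[model$rxns$objective_coef != 0, ]
  obj_lines <- c(
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="%s"/>',
            esc(obj$rxn_id), num(obj$objective_coef)),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>')

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            .sbml_ns[["sbml"]], .sbml_ns[["fbc"]]),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$model_id)),
    "    <listOfCompartments>", comp_lines, "    </listOfCompartments>",
    "    <listOfSpecies>", sp_lines, "    </listOfSpecies>",
    "    <listOfParameters>", par_lines, "    </listOfParameters>",
    "    <listOfReactions>", rxn_lines, "    </listOfReactions>",
    obj_lines,
    if (length(gp_lines)) c("    <fbc:listOfGeneProducts>", gp_lines,
                            "    </fbc:listOfGeneProducts>") else character(0),
    "  </model>",
    "</sbml>")
  writeLines(out, path)
  invisible(path)
}
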