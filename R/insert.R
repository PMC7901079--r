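## Inserting reconstructed pathways into a reference model.

# curated synonym table: common names / aliases -> canonical metabolite ids
.met_synonyms <- c(
  "malonyl-coa" = "malcoa_c",
  "methylmalonyl-coa" = "mmcoa_c",
  "ethylmalonyl-coa" = "emcoa_c",
  "methoxymalonyl-acp" = "mxmal_c",
  "s-adenosyl-l-methionine" = "amet_c",
  "sam" = "amet_c",
  "s-adenosyl-l-homocysteine" = "ahcys_c",
  "sah" = "ahcys_c",
  "coenzyme a" = "coa_c",
  "1,3-bisphosphoglycerate" = "13dpg_c",
  "water" = "h2o_c",
  "atp" = "atp_c",
  "adp" = "adp_c",
  "amp" = "amp_c",
  "diphosphate" = "ppi_c",
  "phosphate" = "pi_c",
  "nadph" = "nadph_c",
  "nadp+" = "nadp_c",
  "l-alanine" = "ala__L_c",
  "glycine" = "gly_c",
  "l-serine" = "ser__L_c",
  "l-threonine" = "thr__L_c",
  "l-lysine" = "lys__L_c",
  "l-tyrosine" = "tyr__L_c"
)

#' Resolve a pathway metabolite against a reference model
#'
#' Resolution is total: an exact id match wins, then a curated synonym-table
#' match on the metabolite name, and otherwise the metabolite is declared
#' new (to be created in the extended model, cytosolic by default).
#' Cluster-specific species (chain intermediates, carriers, products) are
#' always new.
#'
#' @param met_id Metabolite id used by the pathway.
#' @param model A `gem`.
#' @param name Optional display name used for synonym matching.
#' @return List with `met_id` (resolved id) and `new` (logical).
#' @export
resolve_metabolite <- function(met_id, model, name = met_id) {
  if (met_id %in% model$mets$met_id) {
    return(list(met_id = met_id, new = FALSE))
  }
  key <- tolower(name)
  if (key %in% names(.met_synonyms)) {
    cand <- unname(.met_synonyms[key])
    if (cand %in% model$mets$met_id) return(list(met_id = cand, new = FALSE))
  }
  hit <- model$mets$met_id[tolower(model$mets$name) == key &
                             model$mets$compartment == "c"]
  if (length(hit) == 1) return(list(met_id = hit, new = FALSE))
  list(met_id = met_id, new = TRUE)
}

#' Insert a reconstructed pathway into a reference model
#'
#' Adds every pathway reaction to a copy of the model (the input model is
#' never modified), resolving metabolites through [resolve_metabolite()] and
#' creating the cluster-specific species, then appends one irreversible
#' demand reaction for the final product; that demand is the production
#' objective used by [max_production()] and [knockout_scan()]. The extended
#' model grows by exactly `nrow(pathway$reactions) + 1` reactions. Reaction
#' id collisions with the base model are an error, never a silent overwrite.
#'
#' @param model A `gem`.
#' @param pathway A `bgc_pathway`.
#' @return The extended `gem`, with `pathway_rxns` recording the inserted
#'   reaction ids and attribute-level bookkeeping of the product demand id.
#' @export
insert_pathway <- function(model, pathway) {
  stopifnot(inherits(model, "gem"), inherits(pathway, "bgc_pathway"))
  clash <- intersect(pathway$reactions$rxn_id, model$rxns$rxn_id)
  if (length(clash) > 0) {
    stop("reaction id collision with model: ", paste(clash, collapse = ", "),
         call. = FALSE)
  }

  # resolve every metabolite mentioned by the pathway
  all_mets <- unique(unlist(lapply(pathway$reactions$stoich, names)))
  name_of <- stats::setNames(pathway$metabolites$name, pathway$metabolites$met_id)
  mapping <- character(0)
  new_mets <- list()
  for (m in all_mets) {
    res <- resolve_metabolite(m, model, name = name_of[m] %||% m)
    mapping[m] <- res$met_id
    if (res$new) {
      new_mets[[length(new_mets) + 1]] <- tibble::tibble(
        met_id = res$met_id, name = unname(name_of[m] %||% m),
        compartment = "c")
    }
  }

  ext <- model
  if (length(new_mets) > 0) {
    ext$mets <- dplyr::bind_rows(ext$mets,
                                 dplyr::distinct(dplyr::bind_rows(new_mets),
                                                 .data$met_id, .keep_all = TRUE))
  }
  ext$rxns <- dplyr::bind_rows(ext$rxns, tibble::tibble(
    rxn_id = pathway$reactions$rxn_id,
    name = pathway$reactions$name,
    lb = pathway$reactions$lb, ub = pathway$reactions$ub,
    genes = pathway$reactions$genes,
    objective_coef = 0))
  ext$stoich <- dplyr::bind_rows(ext$stoich, dplyr::bind_rows(
    purrr::map2(pathway$reactions$rxn_id, pathway$reactions$stoich,
                function(rid, s) {
                  tibble::tibble(rxn_id = rid, met_id = unname(mapping[names(s)]),
                                 coef = unname(s))
                })))

  product <- unname(mapping[pathway$final_product])
  demand_id <- paste0("DM_", product)
  if (demand_id %in% ext$rxns$rxn_id) {
    stop("reaction id collision with model: ", demand_id, call. = FALSE)
  }
  ext$rxns <- dplyr::bind_rows(ext$rxns, tibble::tibble(
    rxn_id = demand_id, name = paste("demand:", product),
    lb = 0, ub = 1000, genes = list(character(0)), objective_coef = 0))
  ext$stoich <- dplyr::bind_rows(ext$stoich, tibble::tibble(
    rxn_id = demand_id, met_id = product, coef = -1))

  ext$pathway_rxns <- c(model$pathway_rxns, pathway$reactions$rxn_id, demand_id)
  ext$product_demand <- demand_id
  validate_gem(ext)
  ext
}

# ---- pathway JSON ----------------------------------------------------------

#' Serialize a pathway reconstruction to JSON
#'
#' Versioned schema (`bgcflux-pathway/1`): reaction list with id, name,
#' metabolite coefficient map, bounds, gene list and provenance, plus the
#' metabolite table, final product and warnings - a form that drops directly
#' into constraint-based modelling tools. Serialization is deterministic:
#' identical pathways yield byte-identical files.
#'
#' @param pathway A `bgc_pathway`.
#' @param path Optional output path; when `NULL`, the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
write_pathway_json <- function(pathway, path = NULL) {
  obj <- list(
    schema = "bgcflux-pathway/1",
    cluster_id = pathway$cluster_id,
    chain_length = pathway$chain_length,
    load_descriptor = pathway$load_descriptor,
    final_product = pathway$final_product,
    warnings = pathway$warnings,
    reactions = purrr::pmap(pathway$reactions, function(rxn_id, name, stoich,
                                                        lb, ub, genes, provenance) {
      list(id = rxn_id, name = name, metabolites = as.list(stoich),
           lower_bound = lb, upper_bound = ub, genes = genes,
           provenance = provenance)
    }),
    metabolites = purrr::pmap(pathway$metabolites, function(met_id, name, role) {
      list(id = met_id, name = name, role = role)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Read a pathway reconstruction from JSON
#'
#' @param path Path to a file written by [write_pathway_json()].
#' @return A `bgc_pathway`.
#' @export
read_pathway_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(obj$schema, "bgcflux-pathway/1")) {
    stop("not a bgcflux pathway JSON file (schema: ",
         obj$schema %||% "missing", ")", call. = FALSE)
  }
  rxns <- dplyr::bind_rows(purrr::map(obj$reactions, function(r) {
    .rx(r$id, r$name, unlist(r$metabolites), genes = unlist(r$genes) %||% character(0),
        provenance = r$provenance, lb = r$lower_bound, ub = r$upper_bound)
  }))
  mets <- dplyr::bind_rows(purrr::map(obj$metabolites, function(m) {
    tibble::tibble(met_id = m$id, name = m$name, role = m$role)
  }))
  structure(
    list(cluster_id = obj$cluster_id, reactions = rxns, metabolites = mets,
         final_product = obj$final_product, chain_length = obj$chain_length,
         load_descriptor = obj$load_descriptor,
         warnings = unlist(obj$warnings) %||% character(0)),
    class = "bgc_pathway")
}
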