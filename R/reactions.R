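## The domain -> reaction calculus.
##
## Every stoichiometry here follows the assembly-line reaction table:
## loading (A / AT / CAL / GNAT / FkbH), condensation (C / Cy / KS),
## in-module tailoring (MTs, KR / DH / ER, E / ECH no-ops) and release
## (TE / TD). Chain intermediates are lumped pseudo-metabolites: mass is
## tracked only for cofactors, carriers and small molecules.

.aa_codes <- c(
  ala = "ala__L_c", arg = "arg__L_c", asn = "asn__L_c", asp = "asp__L_c",
  cys = "cys__L_c", gln = "gln__L_c", glu = "glu__L_c", gly = "gly_c",
  his = "his__L_c", ile = "ile__L_c", leu = "leu__L_c", lys = "lys__L_c",
  met = "met__L_c", phe = "phe__L_c", pro = "pro__L_c", ser = "ser__L_c",
  thr = "thr__L_c", trp = "trp__L_c", tyr = "tyr__L_c", val = "val__L_c"
)
.rare_aa_codes <- c(
  hpg = "hpg_c", bht = "bht_c", abu = "abu_c", pip = "pip_c",
  dhpg = "dhpg_c", ahba = "ahba_c"
)
.pks_codes <- c(
  mal = "malcoa_c", mmal = "mmcoa_c", emal = "emcoa_c", mxmal = "mxmal_c"
)

# smCOG codes triggering post-release tailoring, and the methoxymalonyl-ACP
# biosynthesis gene signature. The exact smCOG -> stoichiometry mapping
# beyond the named transformation families is implementer-defined.
.tailoring_smcogs <- list(
  glycosylation = c("1256", "1062", "1002"),
  c5n = c("1084", "1109")
)
.mxmal_smcogs <- c("1028")

.generic_aa <- "gaa_c"
.generic_fa <- "gfa_c"
.generic_starter <- "gsu_c"

# one reaction as a one-row tibble
.rx <- function(rxn_id, name, stoich, genes = character(0), provenance = "",
                lb = 0, ub = 1000) {
  tibble::tibble(rxn_id = rxn_id, name = name, stoich = list(stoich),
                 lb = lb, ub = ub, genes = list(genes),
                 provenance = provenance)
}

#' Select the extender unit of a module
#'
#' Maps the adenylation / acyltransferase substrate specificity of a module
#' to a reference-library metabolite id. Recognized PKS codes are `mal`,
#' `mmal`, `emal` and `mxmal` (methoxymalonyl-ACP, accepted only when the
#' cluster carries its biosynthesis gene signature); recognized NRPS codes
#' are the 20 proteinogenic amino acids plus the six common rare monomers
#' (hydroxyphenylglycine, beta-hydroxytyrosine, 2-aminobutyric acid,
#' pipecolic acid, dihydroxyphenylglycine, 3-amino-5-hydroxybenzoate).
#' Anything unrecognized, non-specific (`"X"`) or absent falls back to the
#' conservative default: a generic amino acid for NRPS modules, malonyl-CoA
#' for PKS modules, with a warning recorded.
#'
#' @param module One-row slice of an `assembly_plan` modules tibble.
#' @param cluster_smcogs Character vector of smCOG codes present on the
#'   cluster's genes (gates the methoxymalonyl-ACP assignment).
#' @return List with `met_id`, `code` (the annotation string used), `rare`
#'   (logical: requires a precursor subpathway) and `warning` (`NULL` or
#'   message).
#' @export
select_extender_unit <- function(module, cluster_smcogs = character(0)) {
  kinds <- module$kinds[[1]]
  d <- module$domains[[1]]
  is_pks <- module$module_kind == "PKS"
  spec_dom <- if (is_pks) "AT" else c("A", "CAL")
  code <- unlist(d$specificity[d$kind %in% spec_dom])
  code <- code[nzchar(code)]
  code <- if (length(code) > 0) code[[1]] else ""

  fallback <- function(msg) {
    list(met_id = if (is_pks) "malcoa_c" else .generic_aa,
         code = code, rare = FALSE, warning = msg)
  }

  if (is_pks) {
    if (code == "") {
      return(list(met_id = "malcoa_c", code = code, rare = FALSE, warning = NULL))
    }
    if (code == "mxmal") {
      if (any(.mxmal_smcogs %in% cluster_smcogs)) {
        return(list(met_id = "mxmal_c", code = code, rare = TRUE, warning = NULL))
      }
      return(fallback(
        "mxmal specificity without its biosynthesis gene signature; using malonyl-CoA"))
    }
    if (code %in% names(.pks_codes)) {
      return(list(met_id = unname(.pks_codes[code]), code = code,
                  rare = FALSE, warning = NULL))
    }
    return(fallback(sprintf("unrecognized PKS extender code '%s'; using malonyl-CoA",
                            code)))
  }
  if (code %in% names(.aa_codes)) {
    return(list(met_id = unname(.aa_codes[code]), code = code,
                rare = FALSE, warning = NULL))
  }
  if (code %in% names(.rare_aa_codes)) {
    return(list(met_id = unname(.rare_aa_codes[code]), code = code,
                rare = TRUE, warning = NULL))
  }
  msg <- if (code %in% c("", "X", "x")) NULL
  else sprintf("unrecognized NRPS extender code '%s'; using generic amino acid",
               code)
  list(met_id = .generic_aa, code = code, rare = FALSE, warning = msg)
}

# loading step of one module: activate the monomer and attach it to the
# carrier. `target` is the id the loaded species gets (a per-module loaded
# intermediate, or chain_0 when the module initiates the chain).
.load_step <- function(cluster_id, mi, module, extender, target, carrier,
                       genes, trans_at = FALSE) {
  is_pks <- module$module_kind == "PKS"
  if (is_pks) {
    if (extender$met_id == "mxmal_c") {
      # methoxymalonyl is built ACP-bound; transacylation to the module carrier
      .rx(sprintf("%s_M%02d_AT", cluster_id, mi),
          sprintf("module %d methoxymalonyl transacylation", mi),
          stats::setNames(c(-1, -1, 1), c("mxmal_c", carrier, target)),
          genes, provenance = "AT")
    } else {
      .rx(sprintf("%s_M%02d_AT", cluster_id, mi),
          sprintf("module %d acyltransferase loading%s", mi,
                  if (trans_at) " (trans-AT)" else ""),
          stats::setNames(c(-1, -1, 1, 1),
                          c(extender$met_id, carrier, target, "coa_c")),
          genes, provenance = "AT")
    }
  } else {
    .rx(sprintf("%s_M%02d_A", cluster_id, mi),
        sprintf("module %d adenylation loading", mi),
        stats::setNames(c(-1, -1, -1, 1, 1, 1),
                        c("atp_c", extender$met_id, carrier, target,
                          "amp_c", "ppi_c")),
        genes, provenance = "A")
  }
}

#' Build the reactions of one extending module
#'
#' Emits the loading step (adenylation for NRPS: ATP + monomer + carrier ->
#' loaded monomer + AMP + PPi; acyltransfer for PKS: acyl-CoA + carrier ->
#' acyl-carrier + CoA), the condensation step (KS: acyl-carrier + chain_n ->
#' chain_n+1 + CO2 + carrier; C/Cy: aminoacyl-carrier + chain_n ->
#' chain_n+1 + H2O + carrier) and the in-module tailoring reactions on the
#' elongated chain: methyltransferases consume SAM and release SAH,
#' KR and ER each consume NADPH + H+, DH releases H2O, E and ECH change no
#' stoichiometry and emit nothing. Only reductive domains returned by
#' [resolve_reduction_activity()] fire.
#'
#' @param module One-row module slice (must be an active extender).
#' @param n Chain index before this elongation (the module produces
#'   intermediate `n + 1`).
#' @param cluster_id Cluster identifier (prefixes all ids).
#' @param chain_in Metabolite id of the incoming chain intermediate.
#' @param extender Result of [select_extender_unit()].
#' @param trans_at Is the cluster a trans-AT PKS (loading by the
#'   freestanding acyltransferase)?
#' @return List with `reactions` (tibble), `chain_out` (metabolite id of the
#'   module's final chain species) and `new_mets` (tibble).
#' @export
build_extension_reactions <- function(module, n, cluster_id, chain_in,
                                      extender, trans_at = FALSE) {
  if (!isTRUE(module$is_extending) || isTRUE(module$truncated)) {
    return(list(reactions = .empty_reactions(), chain_out = chain_in,
                new_mets = .empty_mets()))
  }
  mi <- module$module_index
  genes <- unique(module$domains[[1]]$gene_id)
  carrier <- sprintf("%s_carrier_c", cluster_id)
  loaded <- sprintf("%s_M%02d_loaded_c", cluster_id, mi)
  chain_next <- sprintf("%s_chain_%d_c", cluster_id, n + 1)
  is_pks <- module$module_kind == "PKS"

  rxns <- .load_step(cluster_id, mi, module, extender, loaded, carrier,
                     genes, trans_at)
  cond_kind <- if (is_pks) "KS" else if ("Cy" %in% module$kinds[[1]]) "Cy" else "C"
  cond_sto <- if (is_pks) {
    stats::setNames(c(-1, -1, 1, 1, 1),
                    c(loaded, chain_in, chain_next, "co2_c", carrier))
  } else {
    stats::setNames(c(-1, -1, 1, 1, 1),
                    c(loaded, chain_in, chain_next, "h2o_c", carrier))
  }
  rxns <- dplyr::bind_rows(rxns, .rx(
    sprintf("%s_M%02d_%s", cluster_id, mi, cond_kind),
    sprintf("module %d condensation (%s)", mi, cond_kind),
    cond_sto, genes, provenance = cond_kind))

  # in-module tailoring: methylations, then the reductive cascade KR->DH->ER
  new_mets <- list(
    tibble::tibble(met_id = loaded, name = sprintf("%s module %d loaded monomer",
                                                   cluster_id, mi),
                   role = "chain_intermediate"),
    tibble::tibble(met_id = chain_next,
                   name = sprintf("%s chain intermediate %d", cluster_id, n + 1),
                   role = "chain_intermediate"))
  cur <- chain_next
  t_i <- 0
  reds <- module$reductions[[1]]
  kinds <- module$kinds[[1]]
  steps <- c(intersect(kinds, c("cMT", "nMT", "oMT")),
             intersect(c("KR", "DH", "ER"), reds))
  for (dk in steps) {
    t_i <- t_i + 1
    nxt <- sprintf("%s_chain_%d_t%d_c", cluster_id, n + 1, t_i)
    sto <- switch(
      dk,
      cMT = , nMT = , oMT =
        stats::setNames(c(-1, -1, 1, 1), c("amet_c", cur, nxt, "ahcys_c")),
      KR = , ER =
        stats::setNames(c(-1, -1, -1, 1, 1),
                        c("nadph_c", "h_c", cur, nxt, "nadp_c")),
      DH = stats::setNames(c(-1, 1, 1), c(cur, nxt, "h2o_c"))
    )
    rxns <- dplyr::bind_rows(rxns, .rx(
      sprintf("%s_M%02d_%s", cluster_id, mi, dk),
      sprintf("module %d %s tailoring", mi, dk),
      sto, genes, provenance = dk))
    new_mets[[length(new_mets) + 1]] <-
      tibble::tibble(met_id = nxt,
                     name = sprintf("%s chain intermediate %d (step %d)",
                                    cluster_id, n + 1, t_i),
                     role = "chain_intermediate")
    cur <- nxt
  }
  list(reactions = rxns, chain_out = cur,
       new_mets = dplyr::bind_rows(new_mets))
}

#' Build the chain-initiation reactions
#'
#' Emits the reactions that produce chain intermediate 0 according to the
#' load descriptor from [resolve_load_module()]: the standard PKS
#' acyltransferase load, the standard NRPS adenylation load, the CAL starter
#' incorporation (starter + carrier -> loaded starter + H2O), the GNAT load
#' (malonyl-CoA + carrier -> acetyl-carrier + CoA + CO2), the FkbH load
#' (1,3-bisphosphoglycerate + carrier -> D-lactyl-carrier + 2 Pi) and the
#' C-acylated NRPS start (adenylation of the first amino acid followed by
#' condensation with a generic fatty acid). With descriptor `none` the chain
#' is initialized from the first extender's bare monomer with a warning.
#'
#' @param plan An `assembly_plan`.
#' @param descriptor Load descriptor string (defaults to the plan's).
#' @return List with `reactions`, `chain_met` (id of the initial chain
#'   species), `chain_n` (its index), `new_mets`, `uses` (character vector of
#'   generic pools used) and `warnings`.
#' @export
build_load_reactions <- function(plan, descriptor = plan$load_descriptor) {
  cid <- plan$cluster_id
  carrier <- sprintf("%s_carrier_c", cid)
  chain0 <- sprintf("%s_chain_0_c", cid)
  m1 <- plan$modules[1, ]
  genes <- unique(m1$domains[[1]]$gene_id)
  warnings <- character(0)
  uses <- character(0)
  new_mets <- tibble::tibble(
    met_id = c(carrier, chain0),
    name = c(sprintf("%s carrier protein (ACP/PCP)", cid),
             sprintf("%s chain intermediate 0", cid)),
    role = c("carrier", "chain_intermediate"))

  starter_spec <- function() {
    d <- m1$domains[[1]]
    code <- unlist(d$specificity[d$kind %in% c("AT", "A", "CAL")])
    code <- code[nzchar(code)][1]
    if (is.na(code)) "" else code
  }

  out <- switch(
    descriptor,
    standard_PKS = {
      code <- starter_spec()
      met <- if (code %in% names(.pks_codes) && code != "mxmal") {
        unname(.pks_codes[code])
      } else "malcoa_c"
      list(rx = .rx(sprintf("%s_M01_AT", cid), "load module acyltransferase",
                    stats::setNames(c(-1, -1, 1, 1),
                                    c(met, carrier, chain0, "coa_c")),
                    genes, provenance = "AT"),
           n = 0)
    },
    standard_NRPS = {
      ext <- select_extender_unit(m1, .cluster_smcogs(plan))
      if (!is.null(ext$warning)) warnings <- c(warnings, ext$warning)
      if (ext$met_id == .generic_aa) uses <- c(uses, .generic_aa)
      list(rx = .rx(sprintf("%s_M01_A", cid), "load module adenylation",
                    stats::setNames(c(-1, -1, -1, 1, 1, 1),
                                    c("atp_c", ext$met_id, carrier, chain0,
                                      "amp_c", "ppi_c")),
                    genes, provenance = "A"),
           n = 0, rare = if (ext$rare) ext$met_id else NULL)
    },
    C_acylated_NRPS = {
      ext <- select_extender_unit(m1, .cluster_smcogs(plan))
      if (!is.null(ext$warning)) warnings <- c(warnings, ext$warning)
      if (ext$met_id == .generic_aa) uses <- c(uses, .generic_aa)
      uses <- c(uses, .generic_fa)
      loaded <- sprintf("%s_M01_loaded_c", cid)
      chain1 <- sprintf("%s_chain_1_c", cid)
      new_mets <- rbind(new_mets, tibble::tibble(
        met_id = c(loaded, chain1),
        name = c(sprintf("%s module 1 loaded monomer", cid),
                 sprintf("%s chain intermediate 1", cid)),
        role = "chain_intermediate"))
      rxns <- dplyr::bind_rows(
        .rx(sprintf("%s_M01_A", cid), "initiating module adenylation",
            stats::setNames(c(-1, -1, -1, 1, 1, 1),
                            c("atp_c", ext$met_id, carrier, loaded,
                              "amp_c", "ppi_c")),
            genes, provenance = "A"),
        .rx(sprintf("%s_M01_C", cid),
            "initiating module C-domain acylation (generic fatty acid)",
            stats::setNames(c(-1, -1, 1, 1),
                            c(.generic_fa, loaded, chain1, "h2o_c")),
            genes, provenance = "C"))
      # chain0 placeholder not used in this descriptor
      new_mets <- new_mets[new_mets$met_id != chain0, ]
      list(rx = rxns, n = 1, chain = chain1, new_mets = new_mets,
           rare = if (ext$rare) ext$met_id else NULL)
    },
    CAL = {
      code <- starter_spec()
      met <- if (code %in% names(.aa_codes)) unname(.aa_codes[code])
      else if (code %in% names(.rare_aa_codes)) unname(.rare_aa_codes[code])
      else .generic_starter
      if (met == .generic_starter) uses <- c(uses, .generic_starter)
      list(rx = .rx(sprintf("%s_M01_CAL", cid), "CoA-ligase starter incorporation",
                    stats::setNames(c(-1, -1, 1, 1),
                                    c(met, carrier, chain0, "h2o_c")),
                    genes, provenance = "CAL"),
           n = 0)
    },
    GNAT = list(
      rx = .rx(sprintf("%s_M01_GNAT", cid),
               "GNAT load (decarboxylating acetyl transfer)",
               stats::setNames(c(-1, -1, 1, 1, 1),
                               c("malcoa_c", carrier, chain0, "coa_c", "co2_c")),
               genes, provenance = "GNAT"),
      n = 0),
    FkbH = list(
      rx = .rx(sprintf("%s_M01_FkbH", cid),
               "FkbH load (1,3-bisphosphoglycerate dephosphorylation)",
               stats::setNames(c(-1, -1, 1, 2),
                               c("13dpg_c", carrier, chain0, "pi_c")),
               genes, provenance = "FkbH"),
      n = 0),
    none = {
      first_ext <- which(plan$modules$is_extending & !plan$modules$truncated)[1]
      if (is.na(first_ext)) {
        rlang::abort(sprintf("cluster '%s' has no active extending module",
                             plan$cluster_id),
                     class = "bgcflux_no_modules")
      }
      warnings <- c(warnings,
                    "no load module; chain initialized from first extender's monomer")
      me <- plan$modules[first_ext, ]
      ext <- select_extender_unit(me, .cluster_smcogs(plan))
      if (!is.null(ext$warning)) warnings <- c(warnings, ext$warning)
      if (ext$met_id == .generic_aa) uses <- c(uses, .generic_aa)
      trans_at <- "transAT-PKS" %in% plan$classes
      list(rx = .load_step(cid, me$module_index, me, ext, chain0, carrier,
                           unique(me$domains[[1]]$gene_id), trans_at),
           n = 0, starter_module = first_ext,
           rare = if (ext$rare) ext$met_id else NULL)
    }
  )
  if (!is.null(out$new_mets)) new_mets <- out$new_mets
  list(reactions = out$rx,
       chain_met = out$chain %||% chain0,
       chain_n = out$n,
       starter_module = out$starter_module %||% NA_integer_,
       rare = out$rare %||% NULL,
       new_mets = new_mets, uses = uses, warnings = warnings)
}

#' Build the chain-release reaction
#'
#' Thioesterase release hydrolyses the final chain intermediate (H2O +
#' chain -> product), thioester-reductase release is reductive (NADPH + H+ +
#' chain -> product + NADP+); both regenerate the carrier. When the plan has
#' no terminating domain anywhere, release falls back to TE-style hydrolysis
#' with a warning so the pathway still reaches a product.
#'
#' @param plan An `assembly_plan`.
#' @param chain_met Id of the final chain intermediate.
#' @param product_met Id the released product gets.
#' @return List with `reactions`, `warnings`.
#' @export
build_release_reaction <- function(plan, chain_met, product_met) {
  cid <- plan$cluster_id
  carrier <- sprintf("%s_carrier_c", cid)
  term_idx <- which(plan$modules$is_terminating & !plan$modules$truncated)[1]
  warnings <- character(0)
  if (is.na(term_idx)) {
    kind <- "TE"
    genes <- character(0)
    warnings <- "no TE/TD domain; product released by thioesterase-style hydrolysis"
    rid <- sprintf("%s_TE_fallback", cid)
  } else {
    m <- plan$modules[term_idx, ]
    kind <- if ("TD" %in% m$kinds[[1]]) "TD" else "TE"
    genes <- unique(m$domains[[1]]$gene_id)
    rid <- sprintf("%s_M%02d_%s", cid, m$module_index, kind)
  }
  sto <- if (kind == "TE") {
    stats::setNames(c(-1, -1, 1, 1), c("h2o_c", chain_met, product_met, carrier))
  } else {
    stats::setNames(c(-1, -1, -1, 1, 1, 1),
                    c("nadph_c", "h_c", chain_met, product_met, "nadp_c", carrier))
  }
  list(reactions = .rx(rid, sprintf("chain release (%s)", kind), sto, genes,
                       provenance = kind),
       warnings = warnings)
}

#' Lumped biosynthesis of a rare extender unit
#'
#' Appends a one-reaction synthesis subpathway from common reference-library
#' precursors for the six named rare NRPS monomers and methoxymalonyl-ACP.
#' The stoichiometries are lumped (each hides a multi-step route) and are
#' implementer-defined beyond the identity of the monomer. Extenders already
#' present in the reference model need no subpathway and yield an empty
#' result; a rare monomer with no defined subpathway falls back to nothing
#' with a warning (the caller then uses a generic monomer).
#'
#' @param met_id Metabolite id of the rare extender.
#' @param model Optional `gem`; when given and the metabolite exists there,
#'   no subpathway is added.
#' @param cluster_id Prefix for the reaction id.
#' @return Tibble of reactions (possibly empty).
#' @export
add_rare_precursor_pathway <- function(met_id, model = NULL, cluster_id = "bgc") {
  if (!is.null(model) && met_id %in% model$mets$met_id) {
    return(.empty_reactions())
  }
  defs <- list(
    hpg_c = list(name = "4-hydroxyphenylglycine synthesis (lumped)",
                 sto = c(tyr__L_c = -1, o2_c = -1, hpg_c = 1, co2_c = 1,
                         h2o_c = 1)),
    bht_c = list(name = "beta-hydroxytyrosine synthesis (lumped)",
                 sto = c(tyr__L_c = -1, o2_c = -1, nadph_c = -1, h_c = -1,
                         bht_c = 1, h2o_c = 1, nadp_c = 1)),
    abu_c = list(name = "2-aminobutyrate synthesis (lumped)",
                 sto = c(thr__L_c = -1, nadph_c = -1, h_c = -1,
                         abu_c = 1, nadp_c = 1, h2o_c = 1)),
    pip_c = list(name = "pipecolate synthesis (lumped)",
                 sto = c(lys__L_c = -1, nadph_c = -1, h_c = -1,
                         pip_c = 1, nh4_c = 1, nadp_c = 1)),
    dhpg_c = list(name = "3,5-dihydroxyphenylglycine synthesis (lumped)",
                  sto = c(tyr__L_c = -1, o2_c = -1, nadph_c = -1, h_c = -1,
                          dhpg_c = 1, co2_c = 1, nadp_c = 1, h2o_c = 1)),
    ahba_c = list(name = "3-amino-5-hydroxybenzoate synthesis (lumped)",
                  sto = c(glc__D_c = -1, nh4_c = -1, atp_c = -1,
                          ahba_c = 1, adp_c = 1, pi_c = 1, h2o_c = 2)),
    mxmal_c = list(name = "methoxymalonyl-ACP synthesis (lumped)",
                   sto = c(`13dpg_c` = -1, amet_c = -1, nadp_c = -2,
                           mxmal_c = 1, ahcys_c = 1, nadph_c = 2, h_c = 2,
                           pi_c = 2))
  )
  if (!met_id %in% names(defs)) {
    warning(sprintf("no synthesis subpathway defined for rare monomer '%s'",
                    met_id))
    return(.empty_reactions())
  }
  d <- defs[[met_id]]
  .rx(sprintf("%s_syn_%s", cluster_id, sub("_c$", "", met_id)), d$name, d$sto,
      provenance = "rare_precursor")
}

#' Pseudo-reactions sourcing the generic monomer pools
#'
#' When a generic amino acid is used as an extender, 20 irreversible
#' conversion pseudo-reactions (one per proteinogenic amino acid) feed the
#' generic pool so the biosynthetic pathway is functional; amino acids
#' absent from the reference model simply remain dead ends there. The
#' generic fatty acid (C-domain acylation) and generic starter pools are
#' sourced analogously from the model's fatty-acid pool.
#'
#' @param uses Character vector of generic pools in use (subset of
#'   `gaa_c`, `gfa_c`, `gsu_c`).
#' @param cluster_id Prefix for reaction ids.
#' @return Tibble of reactions.
#' @export
add_generic_monomer_pseudoreactions <- function(uses, cluster_id = "bgc") {
  out <- list()
  if (.generic_aa %in% uses) {
    for (code in names(.aa_codes)) {
      met <- unname(.aa_codes[code])
      out[[length(out) + 1]] <- .rx(
        sprintf("%s_gaa_%s", cluster_id, code),
        sprintf("generic amino acid pool from %s", code),
        stats::setNames(c(-1, 1), c(met, .generic_aa)),
        provenance = "generic_aa")
    }
  }
  if (.generic_fa %in% uses) {
    out[[length(out) + 1]] <- .rx(
      sprintf("%s_gfa_src", cluster_id), "generic fatty acid pool",
      c(fa_c = -1, gfa_c = 1), provenance = "generic_fa")
  }
  if (.generic_starter %in% uses) {
    out[[length(out) + 1]] <- .rx(
      sprintf("%s_gsu_src", cluster_id), "generic starter unit pool",
      c(fa_c = -1, gsu_c = 1), provenance = "generic_starter")
  }
  if (length(out) == 0) .empty_reactions() else dplyr::bind_rows(out)
}

#' Post-release tailoring reactions from smCOG annotations
#'
#' For each cluster gene whose smCOG code maps to an implemented tailoring
#' family, one reaction transforms the released product sequentially
#' (product_k -> product_k+1, gene genomic order): glycosylation consumes an
#' NDP-hexose donor; 2-amino-3-hydroxycyclopent-2-enone (C5N) incorporation
#' consumes glycine, acetyl-CoA and ATP. The final product is re-pointed to
#' the last tailored species.
#'
#' @param cluster A `bgc_cluster`.
#' @param product_met Id of the released (untailored) product.
#' @param cluster_id Cluster id prefix.
#' @return List with `reactions`, `final_product`, `new_mets`.
#' @export
add_tailoring_reactions <- function(cluster, product_met, cluster_id) {
  genes <- cluster$genes
  hits <- genes[!is.na(genes$smcog) &
                  genes$smcog %in% unlist(.tailoring_smcogs), ]
  if (nrow(hits) == 0) {
    return(list(reactions = .empty_reactions(), final_product = product_met,
                new_mets = .empty_mets()))
  }
  rxns <- list()
  mets <- list()
  cur <- product_met
  for (i in seq_len(nrow(hits))) {
    g <- hits[i, ]
    family <- names(.tailoring_smcogs)[
      vapply(.tailoring_smcogs, function(v) g$smcog %in% v, logical(1))][1]
    nxt <- sprintf("%s_product_%d_c", cluster_id, i)
    sto <- switch(
      family,
      glycosylation = stats::setNames(
        c(-1, -1, 1, 1), c("ndphex_c", cur, nxt, "ndp_c")),
      c5n = stats::setNames(
        c(-1, -1, -1, -1, 1, 1, 1, 1),
        c("gly_c", "accoa_c", "atp_c", cur, nxt, "coa_c", "amp_c", "ppi_c")))
    rxns[[i]] <- .rx(
      sprintf("%s_tailor_%d_smcog%s", cluster_id, i, g$smcog),
      sprintf("tailoring (%s, smCOG %s, gene %s)", family, g$smcog, g$gene_id),
      sto, genes = g$gene_id, provenance = sprintf("smCOG%s", g$smcog))
    mets[[i]] <- tibble::tibble(
      met_id = nxt, name = sprintf("%s tailored product %d", cluster_id, i),
      role = "final_product")
    cur <- nxt
  }
  list(reactions = dplyr::bind_rows(rxns), final_product = cur,
       new_mets = dplyr::bind_rows(mets))
}

.empty_reactions <- function() {
  tibble::tibble(rxn_id = character(0), name = character(0), stoich = list(),
                 lb = numeric(0), ub = numeric(0), genes = list(),
                 provenance = character(0))
}
.empty_mets <- function() {
  tibble::tibble(met_id = character(0), name = character(0), role = character(0))
}

.cluster_smcogs <- function(plan) {
  sm <- plan$cluster$genes$smcog
  sm[!is.na(sm)]
}

#' Build the full metabolic pathway of an assembled cluster
#'
#' Orchestrates the domain calculus over the whole assembly plan:
#' chain initiation per the load descriptor, one elongation per active
#' extending module in collinear order, in-module tailoring, chain release,
#' smCOG-driven post-release tailoring, rare-precursor subpathways (added
#' once per distinct rare monomer) and the generic-monomer pseudo-reactions.
#' All biosynthetic reactions are irreversible with bounds (0, 1000).
#'
#' @param plan An `assembly_plan` (a `bgc_cluster` is accepted and assembled
#'   first).
#' @param model Optional reference `gem`: rare monomers already present in
#'   the model then get no subpathway.
#' @return A `bgc_pathway`: ordered reaction tibble, new-metabolite table,
#'   final product id, chain length and accumulated warnings.
#' @examples
#' spec <- bgc_spec("demo", classes = "NRPS",
#'   genes = list(gene_spec(modules = list(
#'     module_spec(c("A", "PCP"), specificity = c(A = "ala")),
#'     module_spec(c("C", "A", "PCP", "TE"), specificity = c(A = "gly"))))))
#' pw <- build_pathway(assemble_modules(parse_region(write_synthetic_region(spec))))
#' tidy(pw)
#' @export
build_pathway <- function(plan, model = NULL) {
  if (inherits(plan, "bgc_cluster")) plan <- assemble_modules(plan)
  stopifnot(inherits(plan, "assembly_plan"))
  cid <- plan$cluster_id
  warnings <- character(0)
  uses <- character(0)
  rare_needed <- character(0)

  load <- build_load_reactions(plan)
  warnings <- c(warnings, load$warnings)
  uses <- union(uses, load$uses)
  if (!is.null(load$rare)) rare_needed <- union(rare_needed, load$rare)
  rxns <- load$reactions
  mets <- load$new_mets
  chain <- load$chain_met
  n <- load$chain_n
  trans_at <- "transAT-PKS" %in% plan$classes
  smcogs <- .cluster_smcogs(plan)

  ext_idx <- which(plan$modules$is_extending & !plan$modules$truncated &
                     !plan$modules$is_load)
  if (!is.na(load$starter_module)) {
    ext_idx <- setdiff(ext_idx, load$starter_module)
  }
  for (i in ext_idx) {
    m <- plan$modules[i, ]
    ext <- select_extender_unit(m, smcogs)
    if (!is.null(ext$warning)) warnings <- c(warnings, ext$warning)
    if (ext$rare) rare_needed <- union(rare_needed, ext$met_id)
    if (ext$met_id == .generic_aa) uses <- union(uses, .generic_aa)
    step <- build_extension_reactions(m, n, cid, chain, ext, trans_at)
    rxns <- dplyr::bind_rows(rxns, step$reactions)
    mets <- dplyr::bind_rows(mets, step$new_mets)
    chain <- step$chain_out
    n <- n + 1
  }

  product0 <- sprintf("%s_product_0_c", cid)
  rel <- build_release_reaction(plan, chain, product0)
  warnings <- c(warnings, rel$warnings)
  rxns <- dplyr::bind_rows(rxns, rel$reactions)
  mets <- dplyr::bind_rows(mets, tibble::tibble(
    met_id = product0, name = sprintf("%s released product", cid),
    role = "final_product"))

  tail <- add_tailoring_reactions(plan$cluster, product0, cid)
  rxns <- dplyr::bind_rows(rxns, tail$reactions)
  mets <- dplyr::bind_rows(mets, tail$new_mets)
  final_product <- tail$final_product

  for (rmet in rare_needed) {
    sub <- add_rare_precursor_pathway(rmet, model, cid)
    if (nrow(sub) > 0) {
      rxns <- dplyr::bind_rows(rxns, sub)
      mets <- dplyr::bind_rows(mets, tibble::tibble(
        met_id = rmet, name = rmet, role = "precursor"))
    } else if (is.null(model) || !rmet %in% model$mets$met_id) {
      warnings <- c(warnings,
                    sprintf("rare monomer '%s' left unsourced", rmet))
    }
  }
  rxns <- dplyr::bind_rows(rxns, add_generic_monomer_pseudoreactions(uses, cid))
  if (.generic_aa %in% uses) {
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      met_id = .generic_aa, name = "generic amino acid", role = "extender"))
  }
  if (.generic_fa %in% uses) {
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      met_id = .generic_fa, name = "generic fatty acid", role = "starter"))
  }
  if (.generic_starter %in% uses) {
    mets <- dplyr::bind_rows(mets, tibble::tibble(
      met_id = .generic_starter, name = "generic starter unit", role = "starter"))
  }
  mets <- dplyr::distinct(mets, .data$met_id, .keep_all = TRUE)

  structure(
    list(cluster_id = cid, reactions = rxns, metabolites = mets,
         final_product = final_product, chain_length = plan$chain_length,
         load_descriptor = plan$load_descriptor, warnings = warnings),
    class = "bgc_pathway")
}

#' @export
print.bgc_pathway <- function(x, ...) {
  cat(sprintf("<bgc_pathway> %s: %d reactions, chain length %d, product %s\n",
              x$cluster_id, nrow(x$reactions), x$chain_length, x$final_product))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Tidy a pathway into its reaction table
#'
#' @param x A `bgc_pathway`.
#' @param ... Unused.
#' @return Tibble with one row per reaction and a readable equation column.
#' @export
#' @method tidy bgc_pathway
tidy.bgc_pathway <- function(x, ...) {
  eqn <- vapply(x$reactions$stoich, function(s) {
    lhs <- s[s < 0]; rhs <- s[s > 0]
    fmt <- function(v) paste(ifelse(abs(v) == 1, names(v),
                                    paste(abs(v), names(v))), collapse = " + ")
    paste(fmt(lhs), "-->", fmt(rhs))
  }, character(1))
  dplyr::mutate(dplyr::select(x$reactions, -"stoich"), equation = eqn)
}

#' @export
#' @method glance bgc_pathway
glance.bgc_pathway <- function(x, ...) {
  tally <- cofactor_tally(x)
  tibble::tibble(cluster_id = x$cluster_id, n_reactions = nrow(x$reactions),
                 chain_length = x$chain_length,
                 load_descriptor = x$load_descriptor,
                 atp_loading = tally$atp_loading, nadph = tally$nadph,
                 co2_released = tally$co2_released,
                 n_warnings = length(x$warnings))
}

#' Cofactor and carrier bookkeeping of a pathway
#'
#' Sums the stoichiometry maps of the core biosynthetic reactions (loading,
#' condensation, in-module tailoring, release; support subpathways excluded)
#' into the audit counts used by the conservation tests: ATP consumed by
#' adenylation loadings, SAM consumed / SAH produced by methyltransferases,
#' NADPH consumed by reductive domains and release, CO2 released by
#' ketosynthase condensations, and the net carrier balance over the whole
#' pathway (which must be zero).
#'
#' @param pathway A `bgc_pathway`.
#' @return List of counts.
#' @export
cofactor_tally <- function(pathway) {
  core_prov <- c("A", "AT", "C", "Cy", "KS", "cMT", "nMT", "oMT", "KR", "DH",
                 "ER", "TE", "TD", "CAL", "GNAT", "FkbH")
  core <- pathway$reactions[pathway$reactions$provenance %in% core_prov, ]
  # summed coefficient of `met` over core reactions restricted to provenance
  # set `prov` (NULL = all core) and coefficient sign `s`
  pull <- function(met, s, prov = NULL) {
    sel <- if (is.null(prov)) core else core[core$provenance %in% prov, ]
    sum(vapply(sel$stoich, function(st) {
      v <- unname(st[names(st) == met])
      if (length(v) == 0) return(0)
      sum(v[sign(v) == s])
    }, numeric(1)))
  }
  carrier <- sprintf("%s_carrier_c", pathway$cluster_id)
  list(
    atp_loading = -pull("atp_c", -1, "A"),
    sam = -pull("amet_c", -1, c("cMT", "nMT", "oMT")),
    sah = pull("ahcys_c", 1, c("cMT", "nMT", "oMT")),
    nadph = -pull("nadph_c", -1, c("KR", "ER", "TD")),
    co2_released = pull("co2_c", 1, "KS"),
    net_carrier = pull(carrier, 1) + pull(carrier, -1)
  )
}
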