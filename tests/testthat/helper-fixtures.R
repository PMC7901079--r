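# Shared fixtures and independent oracles.

# the two-amino-acid NRPS used for all flux fixtures: ala load, gly
# extension, thioesterase release. Per product unit it draws 2 pyruvate,
# 6 ATP-equivalents and 2 NADPH from the toy network, which makes every
# optimum below an exact rational.
nrps_fixture_spec <- function(id = "nrps1") {
  bgc_spec(id, classes = "NRPS",
           genes = list(gene_spec(modules = list(
             module_spec(c("A", "PCP"), specificity = c(A = "ala")),
             module_spec(c("C", "A", "PCP", "TE"), specificity = c(A = "gly"))))))
}

nrps_fixture_pathway <- function(id = "nrps1", model = NULL) {
  build_pathway(assemble_modules(parse_region(
    write_synthetic_region(nrps_fixture_spec(id)))), model)
}

# hand-derived exact optima of the toy model (glucose 0.8, respiration
# capacity 0.3) with the NRPS fixture product:
#   wild-type max growth           3/20
#   production at 90% growth       177/2600
#   production at 99.9% growth     177/260000
#   FER-knockout mutant growth     11/100
#   FER-knockout production        33/40000
#   relative production gain       25/118
toy_oracle <- list(
  wt_growth = 3 / 20,
  wt_growth_uncapped = 26.4 / 122,
  production_90 = 177 / 2600,
  production_999 = 177 / 260000,
  fer_ko_growth = 11 / 100,
  fer_ko_production = 33 / 40000,
  fer_gain = 25 / 118
)

extended_toy_model <- function() {
  m <- build_toy_reference_model()
  insert_pathway(m, nrps_fixture_pathway(model = m))
}

# ---- independent LP oracle ------------------------------------------------
# Second formulation solved by a genuinely independent code path: the model
# is serialized to SBML and solved with cobrapy/GLPK through the system
# python. Used to cross-check growth, production and the knockout scan.

python_available <- local({
  ok <- NULL
  function() {
    if (is.null(ok)) {
      ok <<- nzchar(Sys.which("python")) &&
        system2("python", c("-c", shQuote("import cobra")),
                stdout = FALSE, stderr = FALSE) == 0
    }
    ok
  }
})

oracle_scan_python <- function(model, product, growth_floor = 0.5,
                               ko_growth_fraction = 0.999, min_gain = 0.001) {
  sbml <- tempfile(fileext = ".xml")
  write_sbml(model, sbml)
  out <- tempfile(fileext = ".json")
  script <- sprintf('
import json, cobra
cobra_config = cobra.Configuration()
m = cobra.io.read_sbml_model(%s)
bio = [r.id for r in m.reactions if r.objective_coefficient != 0][0]
product = %s
exchanges = {r.id for r in m.reactions if len(r.metabolites) == 1}
pathway = set(json.load(open(%s)))

def prod_at(model, frac):
    g = model.slim_optimize()
    with model:
        model.reactions.get_by_id(bio).lower_bound = frac * g
        model.objective = product
        return model.slim_optimize()

mu_wt = m.slim_optimize()
wt_prod = prod_at(m, %f)
res = {"wt_growth": mu_wt, "wt_production": wt_prod, "candidates": []}
for r in m.reactions:
    if not r.genes or r.id in exchanges or r.id in pathway:
        continue
    with m:
        r.bounds = (0, 0)
        mu = m.slim_optimize()
        if mu != mu and True:
            continue
        if mu is None or mu != mu or mu < %f * mu_wt - 1e-9:
            continue
        p = prod_at(m, %f)
        if p is None or p != p:
            continue
        if wt_prod > 0 and p / wt_prod - 1 > %f:
            res["candidates"].append({"rxn_id": r.id, "mutant_growth": mu,
                                      "production": p,
                                      "gain": p / wt_prod - 1})
json.dump(res, open(%s, "w"))
', shQuote(sbml), shQuote(product), shQuote({
    pj <- tempfile(fileext = ".json")
    jsonlite::write_json(model$pathway_rxns, pj)
    pj
  }), ko_growth_fraction, growth_floor, ko_growth_fraction, min_gain,
  shQuote(out))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = FALSE, stderr = FALSE)
  if (status != 0) return(NULL)
  jsonlite::fromJSON(out, simplifyVector = FALSE)
}

# chain-connectivity audit used by the property tests: every chain
# intermediate is produced by exactly one reaction and consumed by exactly
# one, and the per-pathway carrier balance is zero
check_chain_connectivity <- function(pathway) {
  chain_ids <- grep(sprintf("^%s_chain_[0-9]+(_t[0-9]+)?_c$", pathway$cluster_id),
                    pathway$metabolites$met_id, value = TRUE)
  ok <- TRUE
  for (cm in chain_ids) {
    produced <- sum(vapply(pathway$reactions$stoich,
                           function(s) sum(s[names(s) == cm] > 0), numeric(1)))
    consumed <- sum(vapply(pathway$reactions$stoich,
                           function(s) sum(s[names(s) == cm] < 0), numeric(1)))
    ok <- ok && produced == 1 && consumed == 1
  }
  ok
}
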