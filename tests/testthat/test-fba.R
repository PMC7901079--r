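# Constraint-based layer against the hand-derived rational optima of the
# toy network and the independent cobrapy/GLPK oracle.

test_that("toy-model growth optima equal the hand-derived rationals", {
  m <- build_toy_reference_model()
  expect_equal(fba(m)$objective_value, toy_oracle$wt_growth, tolerance = 1e-9)
  # without the respiration cap the network is homogeneous
  mu <- fba(build_toy_reference_model(resp_cap = Inf))$objective_value
  expect_equal(mu, toy_oracle$wt_growth_uncapped, tolerance = 1e-9)
})

test_that("medium setup drives growth as designed", {
  m <- build_toy_reference_model(resp_cap = Inf)
  # doubling the glucose limit doubles growth in the homogeneous model
  m2 <- set_medium(m, medium_spec(uptake_limits = c(EX_glc__D_e = 1.6)))
  expect_equal(fba(m2)$objective_value, 2 * toy_oracle$wt_growth_uncapped,
               tolerance = 1e-9)
  # no glucose, no growth
  m0 <- set_medium(m, medium_spec(uptake_limits = c(EX_glc__D_e = 0)))
  expect_equal(fba(m0)$objective_value, 0, tolerance = 1e-7)
  # ammonium is the sole nitrogen source
  mn <- set_medium(m, medium_spec(unconstrained = setdiff(
    medium_spec()$unconstrained, "EX_nh4_e")))
  expect_equal(fba(mn)$objective_value, 0, tolerance = 1e-7)
  # naming a missing exchange errors
  expect_error(set_medium(m, medium_spec(uptake_limits = c(EX_nope_e = 1))),
               "absent from the model")
})

test_that("growth-coupled production matches the analytic optimum", {
  ext <- extended_toy_model()
  res <- max_production(ext)
  expect_equal(res$wt_max_growth, toy_oracle$wt_growth, tolerance = 1e-9)
  expect_equal(res$production_rate, toy_oracle$production_90, tolerance = 1e-9)
  # full growth leaves no slack for a strictly competing product
  expect_equal(max_production(ext, growth_fraction = 1)$production_rate, 0,
               tolerance = 1e-7)
  # production is non-increasing in the growth fraction
  fr <- c(0, 0.25, 0.5, 0.75, 0.9, 0.999, 1)
  rates <- vapply(fr, function(f) {
    max_production(ext, growth_fraction = f)$production_rate
  }, numeric(1))
  expect_true(all(diff(rates) <= 1e-9))
})

test_that("a product with no synthesis route yields zero production", {
  m <- build_toy_reference_model()
  # a pathway whose rare monomer stays unsourced (no tyrosine route removed):
  # block tyrosine synthesis, then demand an hpg-containing product
  spec <- bgc_spec("dead1", classes = "NRPS", genes = list(gene_spec(list(
    module_spec(c("A", "PCP"), specificity = c(A = "hpg")),
    module_spec(c("C", "A", "PCP", "TE"), specificity = c(A = "ala"))))))
  pw <- build_pathway(assemble_modules(parse_region(write_synthetic_region(spec))), m)
  ext <- insert_pathway(m, pw)
  sel <- ext$rxns$rxn_id == "TYRS"
  ext$rxns$lb[sel] <- 0
  ext$rxns$ub[sel] <- 0
  expect_equal(max_production(ext)$production_rate, 0, tolerance = 1e-7)
})

test_that("the knockout scan recovers the engineered overflow target exactly", {
  ext <- extended_toy_model()
  scan <- knockout_scan(ext)
  expect_equal(attr(scan, "wt_growth"), toy_oracle$wt_growth, tolerance = 1e-9)
  expect_equal(attr(scan, "wt_production"), toy_oracle$production_999,
               tolerance = 1e-9)
  # the acetate-overflow fermentation is the unique candidate
  expect_equal(scan$rxn_id, "FER")
  expect_equal(scan$mutant_max_growth, toy_oracle$fer_ko_growth,
               tolerance = 1e-9)
  expect_equal(scan$mutant_production, toy_oracle$fer_ko_production,
               tolerance = 1e-9)
  expect_equal(scan$relative_increase, toy_oracle$fer_gain, tolerance = 1e-9)
  # every reported candidate satisfies its own invariants
  expect_true(all(scan$mutant_max_growth >=
                    0.5 * attr(scan, "wt_growth") - 1e-9))
  expect_true(all(scan$relative_increase > 0.001))
  # essential reactions were skipped, not reported
  skipped <- attr(scan, "skipped")
  expect_true(all(c("GLCt", "NH4t", "GLYC", "PPP", "ALAS") %in% skipped$rxn_id))
  # the biomass reaction (not gene-annotated) was never attempted
  expect_false("BIOMASS" %in% c(scan$rxn_id, skipped$rxn_id))
  # pathway reactions are excluded from the candidate set
  expect_false(any(grepl("^nrps1_", c(scan$rxn_id, skipped$rxn_id))))
})

test_that("objective values are deterministic across repeated solves", {
  ext <- extended_toy_model()
  v1 <- replicate(3, fba(ext)$objective_value)
  expect_true(all(abs(v1 - v1[1]) < 1e-12))
  p <- replicate(2, max_production(ext)$production_rate)
  expect_true(all(abs(p - p[1]) < 1e-12))
})

test_that("the scan agrees with the independent cobrapy/GLPK oracle", {
  expect_true(python_available())
  ext <- extended_toy_model()
  oracle <- oracle_scan_python(ext, "DM_nrps1_product_0_c")
  expect_false(is.null(oracle))
  expect_equal(oracle$wt_growth, toy_oracle$wt_growth, tolerance = 1e-6)
  expect_equal(oracle$wt_production, toy_oracle$production_999,
               tolerance = 1e-6)
  scan <- knockout_scan(ext)
  expect_equal(length(oracle$candidates), nrow(scan))
  o <- oracle$candidates[[1]]
  expect_equal(o$rxn_id, scan$rxn_id[1])
  expect_equal(o$mutant_growth, scan$mutant_max_growth[1], tolerance = 1e-6)
  expect_equal(o$gain, scan$relative_increase[1], tolerance = 1e-6)
})
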