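# Module assembly heuristics: load/extend/terminate structure, bridging and
# DHD detection, activity resolution, truncation, idempotence.

plan_for <- function(spec) assemble_modules(parse_region(write_synthetic_region(spec)))

test_that("a standard PKS gene set yields load, extender, terminator", {
  spec <- bgc_spec("pks3", classes = "T1PKS", genes = list(
    gene_spec(modules = list(module_spec(c("AT", "ACP")))),
    gene_spec(modules = list(module_spec(c("KS", "AT", "KR", "ACP"),
                                         activity = c(KR = "active")))),
    gene_spec(modules = list(module_spec(c("KS", "AT", "ACP", "TE"))))))
  plan <- plan_for(spec)
  td <- tidy(plan)
  expect_equal(nrow(td), 3)
  expect_equal(td$is_load, c(TRUE, FALSE, FALSE))
  expect_equal(td$is_extending, c(FALSE, TRUE, TRUE))
  expect_equal(td$is_terminating, c(FALSE, FALSE, TRUE))
  expect_equal(plan$load_descriptor, "standard_PKS")
  expect_equal(plan$chain_length, 2)
})

test_that("free-standing domains across a gene boundary assemble as a bridging module", {
  spec <- bgc_spec("br1", classes = "transAT-PKS", genes = list(
    gene_spec(modules = list(module_spec(c("KS", "ACP")),
                             module_spec("KS", annotated = FALSE))),
    gene_spec(modules = list(module_spec(c("KR", "ACP"), annotated = FALSE),
                             module_spec(c("KS", "ACP", "TE"))))))
  plan <- plan_for(spec)
  td <- tidy(plan)
  expect_equal(nrow(td), 3)
  expect_true(td$is_bridging[2])
  expect_equal(td$domains[2], "KS-KR-ACP")
  expect_true(td$is_extending[2])       # KR bridging module stays active
})

test_that("DHD modules are detected and marked non-extending", {
  spec <- bgc_spec("dhd1", classes = "transAT-PKS", genes = list(
    gene_spec(modules = list(module_spec(c("KS", "ACP")),
                             module_spec("KS", annotated = FALSE))),
    gene_spec(modules = list(module_spec(c("DH", "ACP"), annotated = FALSE),
                             module_spec(c("KS", "ACP", "TE"))))))
  plan <- plan_for(spec)
  td <- tidy(plan)
  expect_true(td$is_bridging[2])
  expect_false(td$is_extending[2])
  expect_match(plan$decisions$rule, "dhd_module", all = FALSE)

  # direct predicate checks
  dhd <- tibble::tibble(kind = c("KS", "DH", "ACP"), gene_rank = c(1, 2, 2))
  expect_true(detect_dhd(dhd))
  not_dhd <- tibble::tibble(kind = c("KS", "KR", "ACP"), gene_rank = c(1, 2, 2))
  expect_false(detect_dhd(not_dhd))
  single_gene <- tibble::tibble(kind = c("KS", "DH", "ACP"), gene_rank = c(1, 1, 1))
  expect_false(detect_dhd(single_gene))
})

test_that("free-standing epimerase domains are logged non-modular", {
  spec <- bgc_spec("e1", classes = "NRPS", genes = list(
    gene_spec(modules = list(module_spec(c("C", "A", "PCP")),
                             module_spec("E", annotated = FALSE),
                             module_spec(c("C", "A", "PCP", "TE"))))))
  plan <- plan_for(spec)
  expect_equal(nrow(plan$modules), 2)
  expect_match(plan$decisions$rule, "non_modular_domains", all = FALSE)
})

test_that("extension-activity rules match the module chemistry", {
  mk <- function(kinds, kind = "PKS", activity = rep("unknown", length(kinds)),
                 dhd = FALSE) {
    dom_tab <- tibble::tibble(kind = kinds, activity = activity)
    tibble::tibble(
      module_kind = kind, is_dhd = dhd,
      kinds = list(kinds),
      domains = list(dom_tab))
  }
  # oMT in a PKS module deactivates it
  expect_false(resolve_extension_activity(mk(c("KS", "AT", "oMT", "ACP")), "T1PKS"))
  # trans-AT module without in-module AT extends (freestanding AT loads)
  expect_true(resolve_extension_activity(mk(c("KS", "ACP")), "transAT-PKS"))
  # the same module in a cis-AT cluster lacks the minimal set
  expect_false(resolve_extension_activity(mk(c("KS", "ACP")), "T1PKS"))
  # NRPS needs condensation + adenylation + carrier
  expect_true(resolve_extension_activity(mk(c("C", "A", "PCP"), "NRPS"), "NRPS"))
  expect_false(resolve_extension_activity(mk(c("A", "PCP"), "NRPS"), "NRPS"))
  # explicit inactive KS annotation wins
  expect_false(resolve_extension_activity(
    mk(c("KS", "AT", "ACP"), activity = c("inactive", "unknown", "unknown")),
    "T1PKS"))
})

test_that("KR activity cascades to DH and ER", {
  mk <- function(kinds, kr = "unknown") {
    act <- ifelse(kinds == "KR", kr, "unknown")
    dom_tab <- tibble::tibble(kind = kinds, activity = act)
    tibble::tibble(kinds = list(kinds), domains = list(dom_tab))
  }
  expect_setequal(resolve_reduction_activity(mk(c("KS", "KR", "DH", "ER", "ACP"),
                                                "active")),
                  c("KR", "DH", "ER"))
  expect_length(resolve_reduction_activity(mk(c("KS", "KR", "DH", "ACP"),
                                              "inactive")), 0)
  # unknown KR defaults to active
  expect_setequal(resolve_reduction_activity(mk(c("KS", "KR", "DH", "ACP"))),
                  c("KR", "DH"))
  # DH without KR has no substrate hydroxyl: nothing fires
  expect_length(resolve_reduction_activity(mk(c("KS", "DH", "ACP"))), 0)
})

test_that("load descriptors cover the alternative loading chemistries", {
  desc_of <- function(first_mod, classes = "T1PKS", rest = list(
    module_spec(c("KS", "AT", "ACP", "TE")))) {
    spec <- bgc_spec("ld", classes = classes,
                     genes = list(gene_spec(c(list(first_mod), rest))))
    plan_for(spec)$load_descriptor
  }
  expect_equal(desc_of(module_spec(c("GNAT", "ACP"))), "GNAT")
  expect_equal(desc_of(module_spec(c("FkbH", "ACP"))), "FkbH")
  expect_equal(desc_of(module_spec(c("CAL", "ACP"))), "CAL")
  expect_equal(desc_of(module_spec(c("AT", "ACP"))), "standard_PKS")
  expect_equal(desc_of(module_spec(c("A", "PCP")), classes = "NRPS",
                       rest = list(module_spec(c("C", "A", "PCP", "TE")))),
               "standard_NRPS")
  # C domain in the initiating NRPS module: acylated start, still extending
  spec <- bgc_spec("ca", classes = "NRPS", genes = list(gene_spec(list(
    module_spec(c("C", "A", "PCP")), module_spec(c("C", "A", "PCP", "TE"))))))
  plan <- plan_for(spec)
  expect_equal(plan$load_descriptor, "C_acylated_NRPS")
  expect_true(plan$modules$is_load[1])
  expect_true(plan$modules$is_extending[1])
  expect_equal(plan$chain_length, 2)
  # plain extender at the front: no load module
  spec2 <- bgc_spec("no_load", classes = "T1PKS", genes = list(gene_spec(list(
    module_spec(c("KS", "AT", "ACP")), module_spec(c("KS", "AT", "ACP", "TE"))))))
  expect_equal(plan_for(spec2)$load_descriptor, "none")
})

test_that("a mid-cluster terminator truncates everything downstream", {
  spec <- bgc_spec("tr1", classes = "NRPS", genes = list(gene_spec(list(
    module_spec(c("A", "PCP")),
    module_spec(c("C", "A", "PCP", "TE")),
    module_spec(c("C", "A", "PCP")),
    module_spec(c("C", "A", "PCP", "TE"))))))
  plan <- plan_for(spec)
  expect_equal(plan$modules$truncated, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(plan$chain_length, 1)
  # chain length is identical to the same cluster without the trailing modules
  spec_cut <- bgc_spec("tr2", classes = "NRPS", genes = list(gene_spec(list(
    module_spec(c("A", "PCP")),
    module_spec(c("C", "A", "PCP", "TE"))))))
  expect_equal(plan_for(spec_cut)$chain_length, plan$chain_length)
  # truncated modules contribute no reactions
  pw <- build_pathway(plan)
  expect_false(any(grepl("_M0[34]_", pw$reactions$rxn_id)))
})

test_that("assembly is idempotent and logs every module", {
  plan <- plan_for(nrps_fixture_spec())
  expect_identical(assemble_modules(plan), plan)
  logged <- unique(stats::na.omit(plan$decisions$module_index))
  expect_setequal(logged, plan$modules$module_index)
})

test_that("a cluster with no assemblable module signals its absence", {
  spec <- bgc_spec("none1", classes = "NRPS",
                   genes = list(gene_spec(modules = list(
                     module_spec("E", annotated = FALSE)))))
  lines <- write_synthetic_region(spec)
  lines <- lines[!grepl("aSDomain|aSModule|/domain|/specificity|/locus_tag=\"none1_g1\"$",
                        lines)]
  # remove all domain features entirely
  cl <- parse_region(write_synthetic_region(
    bgc_spec("none1", classes = "NRPS",
             genes = list(gene_spec(modules = list(module_spec("E")))))))
  cl$domains <- cl$domains[0, ]
  expect_error(assemble_modules(cl), class = "bgcflux_no_modules")
})
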