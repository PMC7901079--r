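# Region parsing: round-trip fidelity, coordinate conventions, dialect
# tolerance, classification.

test_that("a written fixture round-trips through the parser exactly", {
  spec <- bgc_spec("rt1", classes = "NRPS",
                   genes = list(gene_spec(
                     modules = list(module_spec(c("C", "A", "PCP"),
                                                specificity = c(A = "ser"))),
                     smcog = "1062", is_core = TRUE)))
  cl <- parse_region(write_synthetic_region(spec))
  expect_s3_class(cl, "bgc_cluster")
  expect_equal(cl$cluster_id, "rt1")
  expect_equal(cl$classes, "NRPS")
  expect_equal(nrow(cl$genes), 1)
  expect_true(cl$genes$is_core)
  expect_equal(cl$genes$smcog, "1062")
  expect_equal(cl$domains$kind, c("C", "A", "PCP"))
  expect_equal(cl$domains$specificity[[2]], "ser")
  expect_equal(nrow(cl$annotated_modules), 1)
  expect_length(cl$parse_report, 0)
})

test_that("minus-strand genes present domains in translation order", {
  spec <- bgc_spec("rt2", classes = "NRPS",
                   genes = list(gene_spec(
                     modules = list(module_spec(c("C", "A", "PCP"))),
                     strand = "-")))
  lines <- write_synthetic_region(spec)
  # genomically the domains are written reversed (PCP first)
  dom_lines <- grep("/aSDomain=", lines, value = TRUE)
  expect_match(dom_lines[1], "PCP")
  cl <- parse_region(lines)
  expect_equal(cl$domains$kind, c("C", "A", "PCP"))
  expect_equal(cl$domains$order_index, 1:3)
})

test_that("total domain count is preserved and nothing is dropped", {
  for (seed in c(3, 7, 21)) {
    sp <- random_bgc_spec(seed)
    n_spec <- sum(vapply(sp$genes, function(g) {
      sum(vapply(g$modules, function(m) length(m$domains), integer(1)))
    }, integer(1)))
    cl <- parse_region(write_synthetic_region(sp))
    expect_equal(nrow(cl$domains), n_spec)
  }
})

test_that("parsing is deterministic", {
  lines <- write_synthetic_region(random_bgc_spec(5))
  expect_identical(parse_region(lines), parse_region(lines))
  expect_identical(lines, write_synthetic_region(random_bgc_spec(5)))
})

test_that("unknown domain labels degrade to UNKNOWN with a report entry", {
  spec <- bgc_spec("u1", classes = "T1PKS",
                   genes = list(gene_spec(modules = list(
                     module_spec(c("KS", "AT", "ACP", "TE"))))))
  lines <- write_synthetic_region(spec)
  lines <- sub("/aSDomain=\"PKS_KS\"", "/aSDomain=\"Strange_domain\"", lines)
  cl <- parse_region(lines)
  expect_equal(cl$domains$kind[1], "UNKNOWN")
  expect_match(cl$parse_report, "Strange_domain", all = FALSE)
  expect_error(parse_region(lines, strict = TRUE), class = "bgcflux_parse_error")
})

test_that("module features are optional: domain-only files still parse", {
  spec <- bgc_spec("u2", classes = "NRPS",
                   genes = list(gene_spec(modules = list(
                     module_spec(c("C", "A", "PCP", "TE"), annotated = FALSE)))))
  cl <- parse_region(write_synthetic_region(spec))
  expect_equal(nrow(cl$annotated_modules), 0)
  expect_equal(nrow(cl$domains), 4)
  # assembly then builds the module from the free-standing domains
  plan <- assemble_modules(cl)
  expect_equal(nrow(plan$modules), 1)
  expect_equal(plan$modules$provenance, "assembled")
})

test_that("a document with no CDS is an empty-cluster error", {
  txt <- c("LOCUS       empty 100 bp",
           "FEATURES             Location/Qualifiers",
           "     region          1..100",
           "                     /product=\"NRPS\"", "//")
  expect_error(parse_region(txt), class = "bgcflux_empty_cluster")
})

test_that("classification returns supported classes and flags hybrids", {
  nrps <- parse_region(write_synthetic_region(nrps_fixture_spec()))
  expect_equal(classify_cluster(nrps), "NRPS")

  hybrid_spec <- bgc_spec("h1", classes = c("NRPS", "T1PKS"),
                          genes = list(gene_spec(modules = list(
                            module_spec(c("KS", "AT", "ACP", "TE"))))))
  hybrid <- parse_region(write_synthetic_region(hybrid_spec))
  expect_setequal(classify_cluster(hybrid), c("NRPS", "T1PKS"))

  terp_spec <- bgc_spec("t1", classes = "terpene",
                        genes = list(gene_spec(modules = list(
                          module_spec(c("TE"))))))
  terp <- parse_region(write_synthetic_region(terp_spec))
  expect_equal(terp$classes, "other")
  expect_error(classify_cluster(terp), class = "bgcflux_unsupported_class")
})
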