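#' Declarative specification of a synthetic BGC
#'
#' Constructors for the small declarative language from which
#' [write_synthetic_region()] emits antiSMASH-dialect GenBank files. A spec
#' lists genes in genomic order; each gene lists modules in translation
#' order; each module lists domain kinds with optional substrate
#' specificities and activity annotations. The writer and [parse_region()]
#' share one dialect table, so `spec -> file -> parse` is the identity on all
#' spec fields.
#'
#' @param domains Character vector of domain kinds in translation order (see
#'   [domain_kinds()]).
#' @param specificity Named character vector, names are domain kinds (e.g.
#'   `c(A = "gly")`, `c(AT = "mmal")`). Attached to the first domain of that
#'   kind in the module.
#' @param activity Named character vector (`active`/`inactive`) per domain
#'   kind, written as activity qualifiers (KR domains get the KR-specific
#'   qualifier form).
#' @param annotated Should the writer emit an `aSModule` feature for this
#'   module? Un-annotated modules leave their domains free-standing, the way
#'   antiSMASH leaves bridging-module halves unassigned.
#' @return A `module_spec` list.
#' @export
module_spec <- function(domains, specificity = character(0),
                        activity = character(0), annotated = TRUE) {
  stopifnot(length(domains) > 0)
  bad <- setdiff(domains, domain_kinds())
  if (length(bad)) stop("unknown domain kind(s): ", paste(bad, collapse = ", "))
  structure(list(domains = domains, specificity = specificity,
                 activity = activity, annotated = annotated),
            class = "module_spec")
}

#' @rdname module_spec
#' @param modules List of `module_spec`s in translation order.
#' @param strand `"+"` or `"-"`.
#' @param smcog Optional 4-digit smCOG code for the gene.
#' @param is_core Core biosynthetic gene flag.
#' @export
gene_spec <- function(modules, strand = "+", smcog = NULL, is_core = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  if (!is.null(smcog) && !grepl("^[0-9]{4}$", smcog)) {
    stop("smcog must be a 4-digit code")
  }
  structure(list(modules = modules, strand = strand, smcog = smcog,
                 is_core = is_core), class = "gene_spec")
}

#' @rdname module_spec
#' @param cluster_id Identifier used as the GenBank LOCUS and cluster id.
#' @param classes Cluster class labels; supported labels are `NRPS`, `T1PKS`,
#'   `transAT-PKS`, anything else is written as an unsupported product class.
#' @param genes List of `gene_spec`s in genomic order.
#' @export
bgc_spec <- function(cluster_id, classes, genes) {
  if (length(genes) == 0) stop("bgc_spec requires at least one gene")
  structure(list(cluster_id = cluster_id, classes = classes, genes = genes),
            class = "bgc_spec")
}

#' Write a synthetic antiSMASH-dialect region GenBank document
#'
#' Emits `region`, `CDS`, `aSDomain` and (for annotated modules) `aSModule`
#' features with the qualifier vocabulary that [parse_region()] consumes.
#' Deterministic: the same spec always yields byte-identical output. Domains
#' are laid out 300 bp each; minus-strand genes have their domains written in
#' reversed genomic order so that translation order round-trips.
#'
#' @param spec A [bgc_spec()].
#' @param path Optional output path; when `NULL` the document is returned as
#'   a character vector of lines.
#' @return The GenBank document (lines), invisibly when `path` is given.
#' @export
write_synthetic_region <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "bgc_spec"))
  dom_w <- 300L
  gene_gap <- 500L
  offset <- 1000L

  feature_lines <- character(0)
  gene_tables <- list()
  pos <- offset

  for (gi in seq_along(spec$genes)) {
    g <- spec$genes[[gi]]
    gene_id <- sprintf("%s_g%d", spec$cluster_id, gi)
    doms <- purrr::imap(g$modules, function(m, mi) {
      tibble::tibble(kind = m$domains, module = mi,
                     pos_in_module = seq_along(m$domains),
                     annotated = m$annotated)
    })
    doms <- dplyr::bind_rows(doms)
    doms$trans_order <- seq_len(nrow(doms))
    ndom <- nrow(doms)
    gene_start <- pos
    gene_end <- pos + ndom * dom_w
    # genomic slot: translation order on '+', reversed on '-'
    slot <- if (g$strand == "+") doms$trans_order else ndom + 1 - doms$trans_order
    doms$start <- gene_start + (slot - 1) * dom_w
    doms$end <- doms$start + dom_w
    # unique domain ids per gene
    doms <- dplyr::group_by(doms, .data$kind)
    doms <- dplyr::mutate(doms, nth = dplyr::row_number())
    doms <- dplyr::ungroup(doms)
    doms$domain_id <- sprintf("nrpspksdomains_%s_%s.%d", gene_id,
                              .label_from_kind(doms$kind), doms$nth)
    doms$gene_id <- gene_id
    doms$gene_index <- gi

    # CDS feature
    quals <- list(locus_tag = gene_id)
    if (g$is_core) quals$gene_kind <- "biosynthetic"
    if (!is.null(g$smcog)) {
      quals$gene_functions <- sprintf(
        "biosynthetic-additional (smcogs) SMCOG%s:annotated function (Score: 100.0; E-value: 1e-30)",
        g$smcog)
    }
    feature_lines <- c(feature_lines,
                       gb_format_feature("CDS", gene_start, gene_end, g$strand, quals))

    # aSDomain features in genomic order
    for (k in order(doms$start)) {
      d <- doms[k, ]
      mspec <- g$modules[[d$module]]
      spec_quals <- character(0)
      sp <- mspec$specificity
      if (d$kind %in% names(sp) && d$pos_in_module ==
          min(which(mspec$domains == d$kind))) {
        spec_quals <- c(spec_quals, sprintf("consensus: %s", sp[[d$kind]]))
      }
      act <- mspec$activity
      if (d$kind %in% names(act)) {
        form <- if (d$kind == "KR") "KR activity: %s" else "activity: %s"
        spec_quals <- c(spec_quals, sprintf(form, act[[d$kind]]))
      }
      dq <- list(aSDomain = .label_from_kind(d$kind),
                 domain_id = d$domain_id,
                 locus_tag = gene_id)
      if (length(spec_quals)) dq$specificity <- spec_quals
      feature_lines <- c(feature_lines,
                         gb_format_feature("aSDomain", d$start, d$end, g$strand, dq))
    }

    # aSModule features for annotated modules
    for (mi in seq_along(g$modules)) {
      m <- g$modules[[mi]]
      if (!isTRUE(m$annotated)) next
      md <- doms[doms$module == mi, ]
      mtype <- if (any(m$domains %in% c("KS", "AT"))) "pks" else "nrps"
      feature_lines <- c(feature_lines, gb_format_feature(
        "aSModule", min(md$start), max(md$end), g$strand,
        list(domains = md$domain_id[order(md$trans_order)],
             locus_tags = gene_id, type = mtype)))
    }

    gene_tables[[gi]] <- doms
    pos <- gene_end + gene_gap
  }

  total <- pos
  product_label <- function(cl) {
    if (cl %in% names(.dialect_class)) cl
    else if (cl %in% .dialect_class) cl
    else cl
  }
  region_quals <- list(region_number = "1",
                       product = vapply(spec$classes, product_label, character(1)))
  region_lines <- gb_format_feature("region", 0, total, "+", region_quals)

  lines <- gb_format_record(spec$cluster_id, total,
                            c(region_lines, feature_lines))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Random synthetic BGC specification
#'
#' Draws a structurally valid cluster: an optional dedicated load module,
#' one to four extender modules, a terminating TE/TD domain on the last
#' module, class-appropriate domain sets (cis-AT PKS, trans-AT PKS, NRPS or
#' NRPS/PKS hybrid), random substrate specificities from the recognized
#' vocabulary, random KR activity annotations, minus-strand genes, and
#' (for trans-AT clusters) occasional cross-gene bridging or DHD constructs.
#' The intended module structure is attached as attribute `expected`, a
#' tibble the round-trip tests compare against.
#'
#' @param seed Integer seed; the same seed always yields the same spec.
#' @return A [bgc_spec()] with attribute `expected`.
#' @export
random_bgc_spec <- function(seed) {
  set.seed(seed)
  cls <- sample(c("NRPS", "T1PKS", "transAT-PKS", "hybrid"), 1,
                prob = c(0.3, 0.3, 0.2, 0.2))
  classes <- switch(cls, hybrid = c("NRPS", "T1PKS"), cls)

  n_ext <- sample(1:4, 1)
  aa_codes <- c("ala", "gly", "ser", "thr", "leu", "val", "X")
  at_codes <- c("mal", "mmal", "emal", "")

  nrps_ext <- function() {
    code <- sample(aa_codes, 1)
    sp <- if (nzchar(code)) c(A = code) else character(0)
    extra <- sample(c("", "nMT", "E"), 1, prob = c(0.6, 0.2, 0.2))
    doms <- c("C", "A", if (nzchar(extra)) extra, "PCP")
    list(m = module_spec(doms, specificity = sp),
         kind = "NRPS", extending = TRUE)
  }
  pks_ext <- function(trans = FALSE) {
    code <- sample(at_codes, 1)
    sp <- if (nzchar(code)) c(AT = code) else character(0)
    red <- sample(0:3, 1)                 # 0 none, 1 KR, 2 KR+DH, 3 KR+DH+ER
    reds <- c("KR", "DH", "ER")[seq_len(red)]
    kr_act <- if (red > 0) sample(c("active", "inactive", NA), 1) else NA
    act <- if (!is.na(kr_act)) c(KR = kr_act) else character(0)
    doms <- if (trans) c("KS", reds, "ACP") else c("KS", "AT", reds, "ACP")
    list(m = module_spec(doms, specificity = if (trans) character(0) else sp,
                         activity = act),
         kind = "PKS", extending = TRUE)
  }

  make_ext <- function() {
    if (cls == "NRPS") nrps_ext()
    else if (cls == "transAT-PKS") pks_ext(trans = TRUE)
    else if (cls == "T1PKS") pks_ext(FALSE)
    else if (stats::runif(1) < 0.5) nrps_ext() else pks_ext(FALSE)
  }

  mods <- list()
  expected <- list()
  # load module
  if (cls %in% c("T1PKS", "transAT-PKS", "hybrid") && stats::runif(1) < 0.7) {
    mods[[1]] <- module_spec(c("AT", "ACP"), specificity = c(AT = "mal"))
    expected[[1]] <- list(is_load = TRUE, is_extending = FALSE,
                          is_terminating = FALSE, is_bridging = FALSE)
  } else if (cls == "NRPS" && stats::runif(1) < 0.7) {
    code <- sample(setdiff(aa_codes, "X"), 1)
    mods[[1]] <- module_spec(c("A", "PCP"), specificity = c(A = code))
    expected[[1]] <- list(is_load = TRUE, is_extending = FALSE,
                          is_terminating = FALSE, is_bridging = FALSE)
  }
  for (i in seq_len(n_ext)) {
    e <- make_ext()
    term <- i == n_ext
    doms <- c(e$m$domains, if (term) sample(c("TE", "TD"), 1, prob = c(0.8, 0.2)))
    mods[[length(mods) + 1]] <- module_spec(doms, e$m$specificity, e$m$activity)
    # an NRPS extender that opens the cluster is the C-acylated start: it both
    # initiates (generic fatty-acid acylation) and elongates
    first_and_acylated <- length(expected) == 0 && e$kind == "NRPS"
    expected[[length(expected) + 1]] <-
      list(is_load = first_and_acylated, is_extending = TRUE,
           is_terminating = term, is_bridging = FALSE)
  }

  # trans-AT clusters occasionally get a cross-gene construct the annotation
  # tool would not assign to a module: a trailing KS on one gene and DH+ACP
  # (a DHD, inactive) or KR+ACP (an active bridging module) opening the next
  bridge <- NULL
  if (cls == "transAT-PKS" && stats::runif(1) < 0.6 && length(mods) >= 2) {
    dhd <- stats::runif(1) < 0.5
    bridge <- list(
      at = sample(seq_len(length(mods) - 1), 1),
      head = module_spec("KS", annotated = FALSE),
      tail = module_spec(c(if (dhd) "DH" else "KR", "ACP"), annotated = FALSE),
      expected = list(is_load = FALSE, is_extending = !dhd,
                      is_terminating = FALSE, is_bridging = TRUE))
  }

  # distribute across genes
  if (is.null(bridge)) {
    n_genes <- sample(1:min(3, length(mods)), 1)
    cuts <- sort(sample(seq_len(max(1, length(mods) - 1)),
                        min(n_genes - 1, length(mods) - 1)))
    groups <- split(seq_along(mods), findInterval(seq_along(mods), cuts + 0.5))
    genes <- purrr::map(groups, function(idx) {
      gene_spec(mods[idx], strand = sample(c("+", "+", "-"), 1))
    })
  } else {
    k <- bridge$at
    genes <- list(
      gene_spec(c(mods[seq_len(k)], list(bridge$head)),
                strand = sample(c("+", "+", "-"), 1)),
      gene_spec(c(list(bridge$tail), mods[seq(k + 1, length(mods))]),
                strand = "+"))
    expected <- append(expected, list(bridge$expected), after = k)
  }

  sp <- bgc_spec(sprintf("RBGC%05d", seed), classes, unname(genes))
  attr(sp, "expected") <- dplyr::bind_rows(purrr::map(expected, tibble::as_tibble))
  sp
}

#' Build the toy reference genome-scale model
#'
#' A deliberately small network (about 40 reactions) standing in for a real
#' host model, designed so every flux optimum is an exact rational that can
#' be derived by hand: glucose / ammonium / phosphate / sulphate / oxygen
#' exchanges, lumped glycolysis and respiration (the latter with a finite
#' capacity `resp_cap`), an NADPH-producing pentose-phosphate lump, six amino
#' acids, malonyl-CoA and methylmalonyl-CoA synthesis, a SAM/SAH methyl
#' cycle, fatty-acid and NDP-hexose pools, a biomass reaction, and a
#' gene-annotated acetate-overflow fermentation that boosts growth at a
#' carbon cost - the engineered knockout target that [knockout_scan()]
#' recovers.
#'
#' With the default capacity and a glucose uptake of 0.8 mmol/gDW/h the
#' maximum growth rate is exactly 0.15 1/h; with `resp_cap = Inf` the model
#' is a homogeneous linear network (growth scales linearly in the glucose
#' bound).
#'
#' @param resp_cap Upper flux bound on the respiration lump
#'   (mmol/gDW/h). Default 0.3.
#' @return A `gem` with the standard minimal medium already applied
#'   (glucose uptake 0.8; ammonium, phosphate, sulphate, oxygen, water and
#'   protons unconstrained).
#' @export
build_toy_reference_model <- function(resp_cap = 0.3) {
  U <- 1000
  mets <- tibble::tribble(
    ~met_id, ~name, ~compartment,
    "glc__D_e", "D-glucose", "e",
    "glc__D_c", "D-glucose", "c",
    "nh4_e", "ammonium", "e",
    "nh4_c", "ammonium", "c",
    "pi_e", "phosphate", "e",
    "pi_c", "phosphate", "c",
    "so4_e", "sulphate", "e",
    "so4_c", "sulphate", "c",
    "o2_e", "oxygen", "e",
    "o2_c", "oxygen", "c",
    "co2_e", "carbon dioxide", "e",
    "co2_c", "carbon dioxide", "c",
    "ac_e", "acetate", "e",
    "h2o_e", "water", "e",
    "h2o_c", "water", "c",
    "h_e", "proton", "e",
    "h_c", "proton", "c",
    "atp_c", "ATP", "c",
    "adp_c", "ADP", "c",
    "amp_c", "AMP", "c",
    "ppi_c", "diphosphate", "c",
    "pyr_c", "pyruvate", "c",
    "accoa_c", "acetyl-CoA", "c",
    "coa_c", "coenzyme A", "c",
    "nadph_c", "NADPH", "c",
    "nadp_c", "NADP+", "c",
    "amet_c", "S-adenosyl-L-methionine", "c",
    "ahcys_c", "S-adenosyl-L-homocysteine", "c",
    "ala__L_c", "L-alanine", "c",
    "gly_c", "glycine", "c",
    "ser__L_c", "L-serine", "c",
    "thr__L_c", "L-threonine", "c",
    "lys__L_c", "L-lysine", "c",
    "tyr__L_c", "L-tyrosine", "c",
    "gaa_c", "generic amino acid", "c",
    "malcoa_c", "malonyl-CoA", "c",
    "mmcoa_c", "methylmalonyl-CoA", "c",
    "fa_c", "fatty acid pool", "c",
    "13dpg_c", "1,3-bisphosphoglycerate", "c",
    "ndphex_c", "NDP-hexose", "c",
    "ndp_c", "NDP", "c"
  )

  r <- function(rxn_id, name, stoich, lb = 0, ub = U, genes = character(0)) {
    list(rxn_id = rxn_id, name = name, stoich = stoich, lb = lb, ub = ub,
         genes = genes)
  }
  defs <- list(
    r("EX_glc__D_e", "glucose exchange", c(glc__D_e = -1), lb = -0.8),
    r("EX_nh4_e", "ammonium exchange", c(nh4_e = -1), lb = -U),
    r("EX_pi_e", "phosphate exchange", c(pi_e = -1), lb = -U),
    r("EX_so4_e", "sulphate exchange", c(so4_e = -1), lb = -U),
    r("EX_o2_e", "oxygen exchange", c(o2_e = -1), lb = -U),
    r("EX_co2_e", "CO2 exchange", c(co2_e = -1)),
    r("EX_ac_e", "acetate exchange", c(ac_e = -1)),
    r("EX_h2o_e", "water exchange", c(h2o_e = -1), lb = -U),
    r("EX_h_e", "proton exchange", c(h_e = -1), lb = -U),

    r("GLCt", "glucose transport", c(glc__D_e = -1, glc__D_c = 1), genes = "b0001"),
    r("NH4t", "ammonium transport", c(nh4_e = -1, nh4_c = 1), genes = "b0002"),
    r("PIt", "phosphate transport", c(pi_e = -1, pi_c = 1), lb = -U, genes = "b0003"),
    r("SO4t", "sulphate transport", c(so4_e = -1, so4_c = 1), genes = "b0004"),
    r("O2t", "oxygen transport", c(o2_e = -1, o2_c = 1), genes = "b0005"),
    r("CO2t", "CO2 transport", c(co2_c = -1, co2_e = 1), genes = "b0006"),
    r("H2Ot", "water transport", c(h2o_e = -1, h2o_c = 1), lb = -U),
    r("Ht", "proton transport", c(h_e = -1, h_c = 1), lb = -U),

    r("GLYC", "glycolysis lump",
      c(glc__D_c = -1, adp_c = -2, pi_c = -2, pyr_c = 2, atp_c = 2, h2o_c = 2),
      genes = "b0101"),
    r("PDH", "pyruvate dehydrogenase",
      c(pyr_c = -1, coa_c = -1, accoa_c = 1, co2_c = 1), genes = "b0102"),
    r("RESP", "respiration lump",
      c(accoa_c = -1, o2_c = -2, adp_c = -10, pi_c = -10,
        co2_c = 2, coa_c = 1, atp_c = 10, h2o_c = 10),
      ub = resp_cap, genes = "b0103"),
    r("PPP", "pentose phosphate lump",
      c(glc__D_c = -1, nadp_c = -12, nadph_c = 12, co2_c = 6), genes = "b0104"),
    r("FER", "acetate overflow fermentation",
      c(pyr_c = -1, adp_c = -1, pi_c = -1, ac_e = 1, atp_c = 1, co2_c = 1),
      genes = "b0108"),

    r("ALAS", "alanine synthesis",
      c(pyr_c = -1, nh4_c = -1, atp_c = -1, nadph_c = -1,
        ala__L_c = 1, adp_c = 1, pi_c = 1, nadp_c = 1), genes = "b0111"),
    r("GLYS", "glycine synthesis",
      c(pyr_c = -1, nh4_c = -1, atp_c = -1, nadph_c = -1,
        gly_c = 1, adp_c = 1, pi_c = 1, nadp_c = 1), genes = "b0112"),
    r("SERS", "serine synthesis",
      c(pyr_c = -1, nh4_c = -1, atp_c = -1, nadph_c = -1,
        ser__L_c = 1, adp_c = 1, pi_c = 1, nadp_c = 1), genes = "b0113"),
    r("THRS", "threonine synthesis",
      c(pyr_c = -1, nh4_c = -1, atp_c = -1, nadph_c = -1,
        thr__L_c = 1, adp_c = 1, pi_c = 1, nadp_c = 1), genes = "b0114"),
    r("LYSS", "lysine synthesis",
      c(pyr_c = -1, nh4_c = -1, atp_c = -1, nadph_c = -1,
        lys__L_c = 1, adp_c = 1, pi_c = 1, nadp_c = 1), genes = "b0115"),
    r("TYRS", "tyrosine synthesis",
      c(pyr_c = -1, nh4_c = -1, atp_c = -1, nadph_c = -1,
        tyr__L_c = 1, adp_c = 1, pi_c = 1, nadp_c = 1), genes = "b0116"),

    r("MALCOAS", "malonyl-CoA synthesis (acetyl-CoA carboxylase)",
      c(accoa_c = -1, co2_c = -1, atp_c = -1, h2o_c = -1,
        malcoa_c = 1, adp_c = 1, pi_c = 1), genes = "b0121"),
    r("MMCOAS", "methylmalonyl-CoA synthesis lump",
      c(accoa_c = -1, co2_c = -1, atp_c = -1, h2o_c = -1,
        mmcoa_c = 1, adp_c = 1, pi_c = 1), genes = "b0122"),
    r("SAMS", "methyl cycle lump (SAH -> SAM)",
      c(ahcys_c = -1, atp_c = -1, amet_c = 1, adp_c = 1, pi_c = 1),
      genes = "b0123"),
    r("FAS", "fatty acid synthesis lump",
      c(accoa_c = -4, nadph_c = -4, h_c = -4, atp_c = -1,
        fa_c = 1, coa_c = 4, nadp_c = 4, adp_c = 1, pi_c = 1), genes = "b0124"),
    r("ADK", "adenylate kinase", c(atp_c = -1, amp_c = -1, adp_c = 2),
      genes = "b0125"),
    r("PPA", "inorganic pyrophosphatase",
      c(ppi_c = -1, h2o_c = -1, pi_c = 2), genes = "b0126"),
    r("BPGS", "1,3-bisphosphoglycerate supply lump",
      c(glc__D_c = -1, pi_c = -2, `13dpg_c` = 2), genes = "b0127"),
    r("NDPHS", "NDP-hexose synthesis",
      c(glc__D_c = -1, atp_c = -1, ndp_c = -1, ndphex_c = 1, adp_c = 1, pi_c = 1),
      genes = "b0128"),

    r("BIOMASS", "biomass",
      c(ala__L_c = -1, gly_c = -1, ser__L_c = -1, thr__L_c = -1,
        atp_c = -30, h2o_c = -30, so4_c = -0.2, pi_c = -0.5,
        adp_c = 30, pi_c_prod = 30))
  )
  # biomass releases the hydrolysis phosphate; net phosphate demand is the 0.5
  for (i in seq_along(defs)) {
    s <- defs[[i]]$stoich
    if ("pi_c_prod" %in% names(s)) {
      net <- unname(s[["pi_c_prod"]]) + ifelse("pi_c" %in% names(s), s[["pi_c"]], 0)
      s <- s[names(s) != "pi_c_prod"]
      s[["pi_c"]] <- net
      defs[[i]]$stoich <- s
    }
  }

  rxns <- tibble::tibble(
    rxn_id = purrr::map_chr(defs, "rxn_id"),
    name = purrr::map_chr(defs, "name"),
    lb = purrr::map_dbl(defs, "lb"),
    ub = purrr::map_dbl(defs, "ub"),
    genes = purrr::map(defs, "genes"),
    objective_coef = 0
  )
  rxns$objective_coef[rxns$rxn_id == "BIOMASS"] <- 1
  stoich <- dplyr::bind_rows(purrr::map(defs, function(d) {
    tibble::tibble(rxn_id = d$rxn_id, met_id = names(d$stoich),
                   coef = unname(d$stoich))
  }))
  gem("toy_host", mets, rxns, stoich)
}
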