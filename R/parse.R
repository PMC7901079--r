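#' Parse an antiSMASH region GenBank file into a cluster record
#'
#' Reads one region-specific GenBank document as produced by antiSMASH 5.x and
#' returns an in-memory record of the biosynthetic gene cluster: genes (CDS
#' features with core-gene and smCOG annotation), functional domains
#' (`aSDomain` features with substrate specificity and activity qualifiers)
#' and, when present, the modules annotated by the tool (`aSModule` features).
#'
#' GenBank coordinates (1-based inclusive) are converted to 0-based half-open
#' at this boundary. Domain labels outside the known vocabulary are retained
#' with kind `UNKNOWN` and reported, never dropped. Files lacking `aSModule`
#' features parse with an empty `annotated_modules` table; module structure is
#' then synthesised entirely by [assemble_modules()].
#'
#' @param input Path to a GenBank file, or the document itself as a character
#'   vector (single string or lines).
#' @param strict If `TRUE`, parse-report warnings (unknown domain labels,
#'   collapsed compound locations) are promoted to errors.
#'
#' @return A `bgc_cluster` object: a list with elements `cluster_id`,
#'   `classes`, `genes` (tibble), `domains` (tibble, one row per functional
#'   domain, ordered by gene then translation order), `annotated_modules`
#'   (tibble) and `parse_report` (character).
#' @examples
#' spec <- bgc_spec("demo", classes = "NRPS",
#'   genes = list(gene_spec(modules = list(
#'     module_spec(c("A", "PCP"), specificity = c(A = "ala")),
#'     module_spec(c("C", "A", "PCP", "TE"), specificity = c(A = "gly"))))))
#' cl <- parse_region(write_synthetic_region(spec))
#' cl$domains
#' @seealso [classify_cluster()], [assemble_modules()], [write_synthetic_region()]
#' @export
parse_region <- function(input, strict = FALSE) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    input <- readLines(input, warn = FALSE)
  }
  parsed <- gb_read_features(input)
  feats <- parsed$features
  report <- parsed$notes

  locus <- "region"
  first <- if (is.character(input) && length(input) > 1) input[1] else
    strsplit(input, "\n", fixed = TRUE)[[1]][1]
  if (grepl("^LOCUS", first)) locus <- strsplit(trimws(first), "\\s+")[[1]][2]

  cds <- dplyr::filter(feats, .data$key == "CDS")
  if (nrow(cds) == 0) {
    rlang::abort("empty cluster: GenBank document contains no CDS feature",
                 class = "bgcflux_empty_cluster")
  }

  q1 <- function(qual, name) {
    v <- qual[[name]]
    if (is.null(v) || length(v) == 0) NA_character_ else v[1]
  }

  genes <- tibble::tibble(
    gene_id = purrr::map_chr(cds$qualifiers, function(q) {
      id <- q1(q, "locus_tag")
      if (is.na(id)) id <- q1(q, "gene")
      if (is.na(id)) id <- q1(q, "protein_id")
      id
    }),
    start = cds$start, end = cds$end, strand = cds$strand,
    is_core = purrr::map_lgl(cds$qualifiers, function(q) {
      identical(q1(q, "gene_kind"), "biosynthetic")
    }),
    smcog = purrr::map_chr(cds$qualifiers, function(q) {
      fun <- q[["gene_functions"]]
      if (is.null(fun)) fun <- q[["note"]]
      hit <- regmatches(fun, regexpr("SMCOG([0-9]{4})", fun))
      hit <- hit[!is.na(hit) & nzchar(hit)]
      if (length(hit) == 0) NA_character_ else sub("SMCOG", "", hit[1])
    })
  )
  if (anyNA(genes$gene_id)) {
    n_missing <- sum(is.na(genes$gene_id))
    genes$gene_id[is.na(genes$gene_id)] <-
      sprintf("cds_%d", which(is.na(genes$gene_id)))
    report <- c(report, sprintf("%d CDS feature(s) lacked an identifier", n_missing))
  }
  genes <- dplyr::arrange(genes, .data$start)

  # assign each aSDomain to the covering gene (antiSMASH also writes
  # /locus_tag on domains; prefer that when present)
  dom <- dplyr::filter(feats, .data$key == "aSDomain")
  domains <- tibble::tibble(
    domain_id = purrr::map_chr(dom$qualifiers, ~ q1(.x, "domain_id")),
    label = purrr::map_chr(dom$qualifiers, ~ q1(.x, "aSDomain")),
    gene_id = purrr::map_chr(dom$qualifiers, ~ q1(.x, "locus_tag")),
    start = dom$start, end = dom$end, strand = dom$strand,
    raw_specificity = purrr::map(dom$qualifiers, function(q) {
      v <- q[["specificity"]]
      if (is.null(v)) character(0) else v
    })
  )
  if (nrow(domains) > 0 && anyNA(domains$gene_id)) {
    for (i in which(is.na(domains$gene_id))) {
      hit <- which(genes$start <= domains$start[i] & genes$end >= domains$end[i])
      domains$gene_id[i] <- if (length(hit)) genes$gene_id[hit[1]] else NA_character_
    }
    if (anyNA(domains$gene_id)) {
      report <- c(report, "aSDomain feature(s) outside any CDS were dropped from genes")
    }
  }
  domains$kind <- .kind_from_label(domains$label)
  unknown <- unique(domains$label[domains$kind == "UNKNOWN"])
  if (length(unknown) > 0) {
    report <- c(report,
                sprintf("unknown domain label retained as UNKNOWN: %s", unknown))
  }

  # specificity / activity from the raw qualifier strings; raw strings are
  # kept so activity rules can be retuned without re-parsing
  domains$specificity <- purrr::map(domains$raw_specificity, function(v) {
    hits <- sub("^consensus:\\s*", "", v[grepl("^consensus:", v)])
    hits[nzchar(hits)]
  })
  domains$activity <- purrr::map_chr(domains$raw_specificity, function(v) {
    act <- sub("^(KR )?activity:\\s*", "", v[grepl("^(KR )?activity:", v)])
    if (length(act) == 0) "unknown"
    else if (any(act == "inactive")) "inactive"
    else if (any(act == "active")) "active"
    else "unknown"
  })

  # translation order within each gene: ascending genomic start on '+',
  # descending on '-'
  domains <- dplyr::left_join(domains,
                              dplyr::select(genes, "gene_id", gene_start = "start",
                                            gene_strand = "strand"),
                              by = "gene_id")
  domains <- dplyr::group_by(domains, .data$gene_id)
  domains <- dplyr::mutate(domains, order_index = ifelse(
    .data$gene_strand == "-",
    rank(-.data$start, ties.method = "first"),
    rank(.data$start, ties.method = "first")))
  domains <- dplyr::ungroup(domains)
  domains <- dplyr::arrange(domains, .data$gene_start, .data$order_index)
  domains <- dplyr::select(domains, "domain_id", "gene_id", "kind", "label",
                           "start", "end", "strand", "order_index",
                           "specificity", "activity", "raw_specificity")

  # antiSMASH-annotated modules (may be absent)
  mods <- dplyr::filter(feats, .data$key == "aSModule")
  annotated_modules <- tibble::tibble(
    module_id = purrr::map_chr(mods$qualifiers, ~ q1(.x, "module_number") %||%
                                 NA_character_),
    type = purrr::map_chr(mods$qualifiers, ~ q1(.x, "type")),
    domain_ids = purrr::map(mods$qualifiers, function(q) {
      v <- q[["domains"]]
      if (is.null(v)) character(0) else v
    })
  )
  if (nrow(annotated_modules) > 0 && anyNA(annotated_modules$module_id)) {
    annotated_modules$module_id <- sprintf("module_%d", seq_len(nrow(annotated_modules)))
  }

  region <- dplyr::filter(feats, .data$key %in% c("region", "cand_cluster", "protocluster"))
  products <- unique(unlist(purrr::map(region$qualifiers, "product")))
  classes <- unique(unname(.dialect_class[products]))
  classes <- classes[!is.na(classes)]
  if (length(products) == 0) {
    report <- c(report, "no region/product annotation found")
  } else if (length(classes) == 0) {
    classes <- "other"
  } else if (any(is.na(.dialect_class[products]))) {
    classes <- c(classes, "other")
  }
  if (length(classes) == 0) classes <- "other"

  if (strict && length(report) > 0) {
    rlang::abort(paste("strict parse failed:", paste(report, collapse = "; ")),
                 class = "bgcflux_parse_error")
  }

  structure(
    list(cluster_id = locus, classes = classes, genes = genes,
         domains = domains, annotated_modules = annotated_modules,
         parse_report = report),
    class = "bgc_cluster")
}

#' Classify a parsed cluster into supported biosynthetic classes
#'
#' Returns the set of supported class labels (`NRPS`, `T1PKS`, `transAT-PKS`)
#' attached to the region. A cluster annotated only with unsupported classes
#' (terpenes, RiPPs, type 2/3 PKS, ...) signals a typed condition of class
#' `bgcflux_unsupported_class`, which callers may catch to skip the cluster.
#'
#' @param cluster A `bgc_cluster` from [parse_region()].
#' @return Character vector of supported class labels.
#' @export
classify_cluster <- function(cluster) {
  stopifnot(inherits(cluster, "bgc_cluster"))
  supported <- intersect(cluster$classes, c("NRPS", "T1PKS", "transAT-PKS"))
  if (length(supported) == 0) {
    rlang::abort(
      sprintf("cluster '%s' has no supported class (found: %s)",
              cluster$cluster_id, paste(cluster$classes, collapse = ", ")),
      class = "bgcflux_unsupported_class")
  }
  supported
}

#' @export
print.bgc_cluster <- function(x, ...) {
  cat(sprintf("<bgc_cluster> %s [%s]\n", x$cluster_id,
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d gene(s), %d domain(s), %d annotated module(s)\n",
              nrow(x$genes), nrow(x$domains), nrow(x$annotated_modules)))
  if (length(x$parse_report)) {
    cat("  parse report:\n")
    for (w in x$parse_report) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Tidy a cluster record into its domain table
#'
#' @param x A `bgc_cluster`.
#' @param ... Unused.
#' @return A tibble with one row per annotated functional domain.
#' @export
#' @method tidy bgc_cluster
tidy.bgc_cluster <- function(x, ...) {
  dplyr::mutate(x$domains, cluster_id = x$cluster_id, .before = 1)
}

#' @export
#' @method glance bgc_cluster
glance.bgc_cluster <- function(x, ...) {
  tibble::tibble(
    cluster_id = x$cluster_id,
    classes = paste(x$classes, collapse = ";"),
    n_genes = nrow(x$genes),
    n_domains = nrow(x$domains),
    n_annotated_modules = nrow(x$annotated_modules),
    n_warnings = length(x$parse_report)
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
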