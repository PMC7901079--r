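#' Assemble functional modules from a parsed cluster
#'
#' Produces the final ordered module list that the pathway builder consumes.
#' Modules annotated by the upstream tool are taken as given; free-standing
#' domains are combined into additional modules where possible, including
#' bridging modules that span a gene boundary (a trans-AT PKS feature the
#' annotation tool does not emit). Module activity is then resolved: trailing
#' modules after a thioesterase/thioester-reductase are truncated,
#' dehydratase-docking (DHD) modules and O-methyltransferase-containing PKS
#' modules are marked non-extending, and explicit inactive-KS annotations are
#' honoured. Every decision is logged, one row per (module, rule, outcome).
#'
#' The collinearity assumption applies: modules are ordered by gene genomic
#' order and translation order within genes, and each module performs at most
#' one chain elongation.
#'
#' @param x A `bgc_cluster` from [parse_region()], or an existing
#'   `assembly_plan` (returned unchanged, so assembly is idempotent).
#' @return An `assembly_plan`: modules tibble (one row per module with nested
#'   domain table and resolved flags), the load descriptor, `chain_length`
#'   (number of active extending modules) and the decisions log.
#' @seealso [detect_dhd()], [resolve_extension_activity()],
#'   [resolve_reduction_activity()], [resolve_load_module()]
#' @export
assemble_modules <- function(x) {
  if (inherits(x, "assembly_plan")) return(x)
  stopifnot(inherits(x, "bgc_cluster"))
  cluster <- x
  classes <- cluster$classes
  doms <- cluster$domains
  if (nrow(doms) == 0) {
    rlang::abort(sprintf("cluster '%s' has no functional modules or domains",
                         cluster$cluster_id),
                 class = "bgcflux_no_modules")
  }
  doms$gidx <- seq_len(nrow(doms))       # global translation-order index

  # gene rank in genomic order
  gene_rank <- stats::setNames(seq_len(nrow(cluster$genes)), cluster$genes$gene_id)
  doms$gene_rank <- gene_rank[doms$gene_id]

  # 1. annotated modules claim their domains
  assigned <- rep(NA_integer_, nrow(doms))
  groups <- list()
  provenance <- character(0)
  if (nrow(cluster$annotated_modules) > 0) {
    for (i in seq_len(nrow(cluster$annotated_modules))) {
      idx <- which(doms$domain_id %in% cluster$annotated_modules$domain_ids[[i]])
      if (length(idx) == 0) next
      groups[[length(groups) + 1]] <- sort(idx)
      provenance <- c(provenance, "annotated")
      assigned[idx] <- length(groups)
    }
  }

  # 2. free-standing domains: greedy grouping in global order; a group breaks
  # before a module-start kind, before a second A/carrier pair, and at gene
  # boundaries except the bridging case (trailing KS + non-start continuation)
  start_kinds <- c("C", "Cy", "KS", "CAL", "GNAT", "FkbH")
  leftovers <- which(is.na(assigned))
  runs <- split(leftovers, cumsum(c(1, diff(leftovers) != 1)))
  non_modular <- integer(0)
  for (run in runs) {
    cur <- integer(0)
    for (i in run) {
      k <- doms$kind[i]
      new_gene <- length(cur) > 0 &&
        doms$gene_rank[i] != doms$gene_rank[cur[length(cur)]]
      bridging_ok <- new_gene &&
        doms$kind[cur[length(cur)]] == "KS" &&
        !(k %in% start_kinds) &&
        doms$gene_rank[i] == doms$gene_rank[cur[length(cur)]] + 1
      break_here <- length(cur) > 0 && (
        (k %in% start_kinds) ||
          (k == "A" && any(doms$kind[cur] %in% c("A", "CAL"))) ||
          (k %in% c("ACP", "PCP") && any(doms$kind[cur] %in% c("ACP", "PCP"))) ||
          (new_gene && !bridging_ok))
      if (break_here) {
        groups[[length(groups) + 1]] <- cur
        provenance <- c(provenance, "assembled")
        cur <- integer(0)
      }
      cur <- c(cur, i)
    }
    if (length(cur) > 0) {
      groups[[length(groups) + 1]] <- cur
      provenance <- c(provenance, "assembled")
    }
  }

  # single free-standing non-start domains are non-modular, not modules
  decisions <- list()
  log_rule <- function(mi, rule, outcome) {
    decisions[[length(decisions) + 1]] <<-
      tibble::tibble(module_index = mi, rule = rule, outcome = outcome)
  }
  keep <- vapply(seq_along(groups), function(gi) {
    idx <- groups[[gi]]
    kinds <- doms$kind[idx]
    has_core <- any(kinds %in% c(start_kinds, "A", "AT", "TE", "TD"))
    if (!has_core && provenance[gi] == "assembled") {
      non_modular <- c(non_modular, idx)
      log_rule(NA_integer_, "non_modular_domains",
               paste(kinds, collapse = "+"))
      FALSE
    } else TRUE
  }, logical(1))
  groups <- groups[keep]
  provenance <- provenance[keep]

  # order modules by first-domain position
  ord <- order(vapply(groups, min, numeric(1)))
  groups <- groups[ord]
  provenance <- provenance[ord]

  modules <- tibble::tibble(
    module_index = seq_along(groups),
    provenance = provenance,
    domains = purrr::map(groups, function(idx) {
      dplyr::select(doms[idx, ], "domain_id", "gene_id", "gene_rank", "kind",
                    "specificity", "activity", "order_index")
    })
  )
  modules$gene_ids <- purrr::map(modules$domains, ~ unique(.x$gene_id))
  modules$spans_genes <- purrr::map_lgl(modules$gene_ids, ~ length(.x) > 1)
  modules$kinds <- purrr::map(modules$domains, "kind")

  kind_of <- function(kinds) {
    if (any(kinds %in% c("KS", "AT"))) "PKS"          # tie (KS and C) -> PKS
    else if (any(kinds %in% c("C", "Cy", "A", "CAL"))) "NRPS"
    else "unknown"
  }
  modules$module_kind <- purrr::map_chr(modules$kinds, kind_of)
  modules$is_bridging <- modules$spans_genes & provenance == "assembled"
  modules$is_terminating <- purrr::map_lgl(modules$kinds,
                                           ~ any(.x %in% c("TE", "TD")))

  # DHD detection (trans-AT bridging modules, usually inactive)
  modules$is_dhd <- purrr::map_lgl(seq_len(nrow(modules)), function(i) {
    if (!modules$is_bridging[i] || !("transAT-PKS" %in% classes)) return(FALSE)
    detect_dhd(modules$domains[[i]])
  })
  for (i in which(modules$is_dhd)) log_rule(i, "dhd_module", "inactive")
  for (i in which(modules$is_bridging & !modules$is_dhd)) {
    log_rule(i, "bridging_module", "assembled across gene boundary")
  }

  # extension activity
  modules$is_extending <- purrr::map_lgl(seq_len(nrow(modules)), function(i) {
    res <- resolve_extension_activity(modules[i, ], classes)
    log_rule(i, "extension_activity", as.character(res))
    res
  })

  # truncation after the first terminating module
  first_term <- which(modules$is_terminating)[1]
  modules$truncated <- FALSE
  if (!is.na(first_term) && first_term < nrow(modules)) {
    post <- seq(first_term + 1, nrow(modules))
    modules$truncated[post] <- TRUE
    modules$is_extending[post] <- FALSE
    modules$is_terminating[post] <- FALSE
    for (i in post) log_rule(i, "post_termination_truncation", "inactive")
  }

  # active reductive domains per module (cascade from KR annotation)
  modules$reductions <- purrr::map(seq_len(nrow(modules)), function(i) {
    resolve_reduction_activity(modules[i, ])
  })

  plan <- structure(
    list(cluster_id = cluster$cluster_id, classes = classes,
         modules = modules, cluster = cluster,
         load_descriptor = NULL, chain_length = NA_integer_,
         decisions = dplyr::bind_rows(decisions)),
    class = "assembly_plan")

  plan <- resolve_load_module(plan)
  plan$chain_length <- sum(plan$modules$is_extending & !plan$modules$truncated)
  plan
}

#' Detect a dehydratase docking domain (DHD) module
#'
#' DHD modules are a trans-AT PKS arrangement in which the ketosynthase is
#' the last domain of one gene and a dehydratase immediately followed by a
#' carrier protein opens the next gene; such modules are usually
#' catalytically inactive and must not extend the chain.
#'
#' @param module_domains Tibble of the module's domains (columns `kind`,
#'   `gene_rank` in translation order), typically one element of an
#'   `assembly_plan`'s `domains` list-column.
#' @return `TRUE` iff the module matches the KS | DH, ACP cross-gene pattern.
#' @export
detect_dhd <- function(module_domains) {
  d <- module_domains
  if (length(unique(d$gene_rank)) < 2) return(FALSE)
  first_gene <- d$gene_rank == min(d$gene_rank)
  second <- d[!first_gene, ]
  tail_first <- d$kind[first_gene]
  tail_first[length(tail_first)] == "KS" &&
    nrow(second) >= 2 &&
    second$kind[1] == "DH" &&
    second$kind[2] == "ACP"
}

#' Resolve whether a module performs a chain elongation
#'
#' A candidate extender is non-extending when it contains an
#' O-methyltransferase in a PKS context (a known KS-deactivation signature),
#' when it is a DHD module, when its KS carries an explicit inactive
#' annotation, or when it lacks the minimal elongation domain set:
#' KS + AT + carrier for cis-AT PKS, KS + carrier for trans-AT PKS (the
#' freestanding acyltransferase loads the extender), and C/Cy + A + carrier
#' for NRPS.
#'
#' @param module One-row slice of an `assembly_plan` modules tibble.
#' @param cluster_classes Character vector of cluster class labels.
#' @return Logical.
#' @export
resolve_extension_activity <- function(module, cluster_classes) {
  kinds <- module$kinds[[1]]
  d <- module$domains[[1]]
  if (module$module_kind == "PKS" && "oMT" %in% kinds) return(FALSE)
  if (isTRUE(module$is_dhd)) return(FALSE)
  ks_act <- d$activity[d$kind == "KS"]
  if (any(ks_act == "inactive")) return(FALSE)
  carrier <- any(kinds %in% c("ACP", "PCP"))
  if (module$module_kind == "PKS") {
    if ("transAT-PKS" %in% cluster_classes) {
      "KS" %in% kinds && carrier
    } else {
      "KS" %in% kinds && "AT" %in% kinds && carrier
    }
  } else if (module$module_kind == "NRPS") {
    any(kinds %in% c("C", "Cy")) && any(kinds %in% c("A", "CAL")) && carrier
  } else {
    FALSE
  }
}

#' Resolve active reductive domains of a PKS module
#'
#' The activity of the reducing domains follows the ketoreductase
#' annotation: an inactive KR silences any DH and ER in the module, because
#' they act on the hydroxyl moiety the KR produces. A KR with unknown
#' activity defaults to active (inactive calls by the annotation tool are a
#' known error source, and KR domains are almost always active). A module
#' without a KR has no active reductive domains.
#'
#' @param module One-row slice of an `assembly_plan` modules tibble.
#' @return Character subset of `c("KR", "DH", "ER")`.
#' @export
resolve_reduction_activity <- function(module) {
  kinds <- module$kinds[[1]]
  d <- module$domains[[1]]
  present <- intersect(c("KR", "DH", "ER"), kinds)
  if (!"KR" %in% present) return(character(0))
  kr_act <- d$activity[d$kind == "KR"][1]
  if (identical(kr_act, "inactive")) return(character(0))
  present
}

#' Classify the initiating module of an assembled plan
#'
#' Sets the plan's load descriptor: `GNAT`, `FkbH` and `CAL` alternative
#' loaders, the standard PKS (AT+ACP) and NRPS (A+carrier) load modules, the
#' C-acylated NRPS start (a condensation domain in the initiating module
#' acylates the first amino acid with a generic fatty acid; the module both
#' initiates and elongates), or `none` when the first module is a plain
#' extender that doubles as the start with a bare starter unit.
#'
#' @param plan An `assembly_plan`.
#' @return The plan with `load_descriptor` set and first-module flags
#'   (`is_load`, `is_extending`) adjusted.
#' @export
resolve_load_module <- function(plan) {
  stopifnot(inherits(plan, "assembly_plan"))
  m <- plan$modules
  m$is_load <- FALSE
  if (nrow(m) == 0) {
    plan$load_descriptor <- "none"
    plan$modules <- m
    return(plan)
  }
  kinds <- m$kinds[[1]]
  desc <- if ("GNAT" %in% kinds) "GNAT"
  else if ("FkbH" %in% kinds) "FkbH"
  else if ("CAL" %in% kinds && !any(kinds %in% c("C", "Cy"))) "CAL"
  else if (m$module_kind[1] == "NRPS" && any(kinds %in% c("C", "Cy")) &&
           "A" %in% kinds && any(kinds %in% c("ACP", "PCP")) &&
           m$is_extending[1]) "C_acylated_NRPS"
  else if (m$module_kind[1] == "NRPS" && "A" %in% kinds &&
           !any(kinds %in% c("C", "Cy"))) "standard_NRPS"
  else if (m$module_kind[1] == "PKS" && "AT" %in% kinds && !"KS" %in% kinds)
    "standard_PKS"
  else "none"

  if (desc != "none") {
    m$is_load[1] <- TRUE
    if (desc != "C_acylated_NRPS") m$is_extending[1] <- FALSE
  }
  plan$decisions <- dplyr::bind_rows(
    plan$decisions,
    tibble::tibble(module_index = 1L, rule = "load_module", outcome = desc))
  plan$load_descriptor <- desc
  plan$modules <- m
  plan
}

#' @export
print.assembly_plan <- function(x, ...) {
  cat(sprintf("<assembly_plan> %s [%s]: %d module(s), chain length %d, load %s\n",
              x$cluster_id, paste(x$classes, collapse = ", "),
              nrow(x$modules), x$chain_length, x$load_descriptor))
  summ <- tidy.assembly_plan(x)
  print(summ, n = Inf)
  invisible(x)
}

#' Tidy an assembly plan into one row per module
#'
#' @param x An `assembly_plan`.
#' @param ... Unused.
#' @return Tibble with module flags and domain composition.
#' @export
#' @method tidy assembly_plan
tidy.assembly_plan <- function(x, ...) {
  m <- x$modules
  tibble::tibble(
    module_index = m$module_index,
    domains = purrr::map_chr(m$kinds, paste, collapse = "-"),
    module_kind = m$module_kind,
    provenance = m$provenance,
    is_load = m$is_load,
    is_extending = m$is_extending,
    is_terminating = m$is_terminating,
    is_bridging = m$is_bridging,
    truncated = m$truncated
  )
}

#' @export
#' @method glance assembly_plan
glance.assembly_plan <- function(x, ...) {
  tibble::tibble(cluster_id = x$cluster_id, n_modules = nrow(x$modules),
                 chain_length = x$chain_length,
                 load_descriptor = x$load_descriptor,
                 n_bridging = sum(x$modules$is_bridging),
                 n_truncated = sum(x$modules$truncated))
}

#' Write the assembly decisions log
#'
#' Serializes the per-module heuristic decisions (rule, outcome) to a
#' tab-separated audit file.
#'
#' @param plan An `assembly_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_decisions_log <- function(plan, path) {
  utils::write.table(plan$decisions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
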