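## Constraint-based analysis: FBA, growth-coupled production, knockout scan.
##
## LPs are solved by a dense two-phase primal simplex written for this
## package (no LP library is available in this stack, and the recommended
## packages' small-scale simplex routines proved unreliable at genome-scale
## toy sizes). Bland's anti-cycling rule guarantees termination; problems
## are normalized to standard form (A x = b, x >= 0, b >= 0) with variables
## shifted by their lower bounds and slack variables for upper bounds.

.LP_TOL <- 1e-9
.BIG <- 1000

# maximize c'x subject to A x = b, x >= 0, with b >= 0.
# Dense two-phase full-tableau simplex, Bland's rule. Returns
# list(status, x, value).
.simplex_std <- function(A, b, cc, eps = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(all(b >= -eps))
  b[b < 0] <- 0

  run <- function(tab, basis, ncols, iter0 = 0L) {
    # tab: constraint rows plus cost row appended as row m+1; RHS is the last
    # column; pricing scans the first `ncols` columns only (phase 2 excludes
    # the artificials this way). Minimizes until no reduced cost < -eps,
    # Bland's rule throughout.
    rhs <- ncol(tab)
    it <- iter0
    repeat {
      cost <- tab[m + 1L, 1:ncols]
      enter <- which(cost < -eps)[1L]
      if (is.na(enter)) return(list(tab = tab, basis = basis, status = "optimal",
                                    iter = it))
      col <- tab[1:m, enter]
      pos <- which(col > eps)
      if (length(pos) == 0) return(list(tab = tab, basis = basis,
                                        status = "unbounded", iter = it))
      ratios <- tab[pos, rhs] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + eps]
      leave <- cand[which.min(basis[cand])]       # Bland tie-break
      piv <- tab[leave, enter]
      tab[leave, ] <- tab[leave, ] / piv
      other <- setdiff(seq_len(m + 1L), leave)
      tab[other, ] <- tab[other, ] - outer(tab[other, enter], tab[leave, ])
      basis[leave] <- enter
      it <- it + 1L
      if (it > max_iter) return(list(tab = tab, basis = basis,
                                     status = "iteration_limit", iter = it))
    }
  }

  # phase 1: artificial variables
  ncols <- n + m
  tab <- matrix(0, m + 1L, ncols + 1L)
  tab[1:m, 1:n] <- A
  tab[1:m, n + (1:m)] <- diag(m)
  tab[1:m, ncols + 1L] <- b
  # phase-1 cost: sum of artificials; reduced costs after eliminating basics
  tab[m + 1L, 1:n] <- -colSums(A)
  tab[m + 1L, ncols + 1L] <- -sum(b)
  basis <- n + (1:m)
  r1 <- run(tab, basis, ncols)
  if (r1$status != "optimal") return(list(status = r1$status, x = NULL,
                                          value = NA_real_))
  if (-r1$tab[m + 1L, ncols + 1L] > 1e-7) {
    return(list(status = "infeasible", x = NULL, value = NA_real_))
  }
  tab <- r1$tab
  basis <- r1$basis
  # drive remaining artificials out of the basis (degenerate rows)
  for (i in which(basis > n)) {
    row <- tab[i, 1:n]
    j <- which(abs(row) > eps)[1L]
    if (is.na(j)) next                      # redundant row; harmless
    piv <- tab[i, j]
    tab[i, ] <- tab[i, ] / piv
    other <- setdiff(seq_len(m + 1L), i)
    tab[other, ] <- tab[other, ] - outer(tab[other, j], tab[i, ])
    basis[i] <- j
  }
  # phase 2: original objective (maximize cc => minimize -cc). Artificial
  # columns stay in the tableau (a redundant row can keep one basic at zero)
  # but can never re-enter: the pricing scan covers the first n columns only.
  tab[m + 1L, ] <- 0
  tab[m + 1L, 1:n] <- -cc
  for (i in seq_len(m)) {
    j <- basis[i]
    if (j <= n && abs(tab[m + 1L, j]) > eps) {
      tab[m + 1L, ] <- tab[m + 1L, ] - tab[m + 1L, j] * tab[i, ]
    }
  }
  r2 <- run(tab, basis, n)
  if (r2$status == "unbounded") return(list(status = "unbounded", x = NULL,
                                            value = NA_real_))
  x <- numeric(n)
  sel <- r2$basis <= n
  x[r2$basis[sel]] <- r2$tab[seq_len(m)[sel], n + m + 1L]
  list(status = r2$status, x = x, value = sum(cc * x))
}

# maximize obj'v s.t. S v = 0 (rows = mets), lb <= v <= ub.
# S given as dense matrix mets x rxns. Returns list(status, value, fluxes).
lp_solve_fba <- function(S, lb, ub, obj) {
  n <- ncol(S)
  lb <- pmax(lb, -.BIG)
  ub <- pmin(ub, .BIG)
  if (any(lb > ub + .LP_TOL)) {
    return(list(status = "infeasible", value = NA_real_,
                fluxes = rep(NA_real_, n)))
  }
  width <- ub - lb
  free <- which(width > .LP_TOL)
  fixed_contrib <- as.vector(S %*% lb)
  if (length(free) == 0) {
    ok <- all(abs(fixed_contrib) < 1e-7)
    return(list(status = if (ok) "optimal" else "infeasible",
                value = sum(obj * lb), fluxes = lb))
  }
  nf <- length(free)
  Sf <- S[, free, drop = FALSE]
  b_eq <- -fixed_contrib
  # drop rows entirely untouched by free variables
  touched <- rowSums(abs(Sf)) > 0
  if (any(!touched & abs(b_eq) > 1e-7)) {
    return(list(status = "infeasible", value = NA_real_,
                fluxes = rep(NA_real_, n)))
  }
  Sf <- Sf[touched, , drop = FALSE]
  b_eq <- b_eq[touched]
  neg <- b_eq < 0
  Sf[neg, ] <- -Sf[neg, , drop = FALSE]
  b_eq[neg] <- -b_eq[neg]
  m_eq <- nrow(Sf)

  # standard form: [Sf 0; I I] (x, s) = (b_eq, width), x,s >= 0
  A <- rbind(cbind(Sf, matrix(0, m_eq, nf)),
             cbind(diag(nf), diag(nf)))
  b <- c(b_eq, width[free])
  cc <- c(obj[free], numeric(nf))
  res <- .simplex_std(A, b, cc)
  if (res$status != "optimal") {
    return(list(status = res$status, value = NA_real_,
                fluxes = rep(NA_real_, n)))
  }
  v <- lb
  v[free] <- res$x[seq_len(nf)] + lb[free]
  list(status = "optimal", value = sum(obj * v), fluxes = v)
}

#' Flux balance analysis
#'
#' Maximizes the flux through an objective reaction over the steady-state
#' flux cone of the model. Only the objective value is contracted to be
#' reproducible; flux vectors may differ between equivalent optima.
#'
#' @param model A `gem`.
#' @param objective Reaction id to maximize; defaults to the model objective
#'   (biomass).
#' @return List with `status` (`optimal` / `infeasible` / ...),
#'   `objective_value`, and `fluxes` (tibble of reaction id and flux).
#' @export
fba <- function(model, objective = NULL) {
  objective <- objective %||% objective_id(model)
  if (!objective %in% model$rxns$rxn_id) {
    stop("unknown objective reaction: ", objective, call. = FALSE)
  }
  S <- stoich_matrix(model)
  obj <- as.numeric(model$rxns$rxn_id == objective)
  res <- lp_solve_fba(S, model$rxns$lb, model$rxns$ub, obj)
  list(status = res$status, objective_value = res$value,
       fluxes = tibble::tibble(rxn_id = model$rxns$rxn_id, flux = res$fluxes))
}

#' Medium specification
#'
#' Named uptake limits (positive numbers, mmol/gDW/h) per exchange reaction,
#' plus a set of exchanges whose uptake is left unconstrained (ions, oxygen,
#' water, protons). The defaults reproduce the evaluation medium: glucose
#' and ammonium as sole carbon and nitrogen sources, maximum glucose uptake
#' 0.8, unconstrained ammonium / sulphate / phosphate / oxygen and free
#' water, proton and CO2 exchange.
#'
#' @param uptake_limits Named numeric vector, exchange reaction id -> max
#'   uptake rate (non-negative).
#' @param unconstrained Character vector of exchange ids with unlimited
#'   uptake.
#' @return A `medium_spec`.
#' @export
medium_spec <- function(uptake_limits = c(EX_glc__D_e = 0.8),
                        unconstrained = c("EX_nh4_e", "EX_so4_e", "EX_pi_e",
                                          "EX_o2_e", "EX_h2o_e", "EX_h_e")) {
  stopifnot(all(uptake_limits >= 0))
  structure(list(uptake_limits = uptake_limits, unconstrained = unconstrained),
            class = "medium_spec")
}

#' Apply a growth medium to a model
#'
#' Closes the uptake of every exchange reaction, then opens the listed
#' uptakes: limited exchanges get lower bound `-limit` (negative flux is
#' uptake, the SBML-FBC convention), unconstrained exchanges get the default
#' large bound. Secretion stays open for all exchanges.
#'
#' @param model A `gem`.
#' @param medium A [medium_spec()].
#' @return The model with medium bounds applied.
#' @export
set_medium <- function(model, medium = medium_spec()) {
  stopifnot(inherits(model, "gem"), inherits(medium, "medium_spec"))
  ex <- exchanges(model)$rxn_id
  named <- c(names(medium$uptake_limits), medium$unconstrained)
  missing <- setdiff(named, model$rxns$rxn_id)
  if (length(missing) > 0) {
    stop("medium names exchange reactions absent from the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  model$rxns$lb[model$rxns$rxn_id %in% ex] <-
    pmax(model$rxns$lb[model$rxns$rxn_id %in% ex], 0)
  for (rid in names(medium$uptake_limits)) {
    model$rxns$lb[model$rxns$rxn_id == rid] <- -medium$uptake_limits[[rid]]
  }
  model$rxns$lb[model$rxns$rxn_id %in% medium$unconstrained] <- -.BIG
  model
}

#' Growth-coupled maximum production rate
#'
#' The two-step procedure used throughout: (1) maximize biomass to obtain
#' the wild-type maximum growth rate; (2) constrain growth to at least
#' `growth_fraction` of that maximum and maximize flux through the product
#' demand reaction.
#'
#' @param model A `gem` containing a demand reaction for the product.
#' @param product Demand reaction id (defaults to the demand recorded by
#'   [insert_pathway()]).
#' @param growth_fraction Minimum fraction of maximal growth retained
#'   (default 0.9).
#' @return A `production_result`: one-row tibble with `product`,
#'   `wt_max_growth`, `growth_fraction_used` and `production_rate`.
#' @export
max_production <- function(model, product = NULL, growth_fraction = 0.9) {
  product <- product %||% model$product_demand
  stopifnot(!is.null(product), growth_fraction >= 0, growth_fraction <= 1)
  if (!product %in% model$rxns$rxn_id) {
    stop("unknown product demand reaction: ", product, call. = FALSE)
  }
  growth <- fba(model)
  if (growth$status != "optimal") {
    rlang::abort(sprintf("model infeasible when maximizing growth (status %s)",
                         growth$status),
                 class = "bgcflux_infeasible")
  }
  mu <- growth$objective_value
  bio <- objective_id(model)
  m2 <- model
  m2$rxns$lb[m2$rxns$rxn_id == bio] <- growth_fraction * mu
  prod <- fba(m2, objective = product)
  if (prod$status != "optimal") {
    rlang::abort(sprintf("production LP not optimal (status %s)", prod$status),
                 class = "bgcflux_infeasible")
  }
  structure(
    tibble::tibble(product = product, wt_max_growth = mu,
                   growth_fraction_used = growth_fraction,
                   production_rate = max(0, prod$objective_value)),
    class = c("production_result", "tbl_df", "tbl", "data.frame"))
}

#' Brute-force single-reaction knockout scan
#'
#' Iterates over every candidate reaction - gene-annotated, not an exchange
#' or demand, not part of the inserted pathway - and for each: disables the
#' reaction (both bounds zero), predicts the mutant's maximum growth,
#' discards mutants growing below `growth_floor` of the wild-type maximum
#' (non-essentiality criterion) or infeasible ones (treated as essential,
#' logged), then fixes growth at `ko_growth_fraction` of the mutant maximum
#' and maximizes production. Knockouts whose production exceeds the
#' wild-type reference (computed by the same growth-fixation procedure on
#' the unperturbed model) by more than `min_gain` are reported.
#'
#' @param model Extended `gem` with a product demand.
#' @param product Demand reaction id (defaults to the recorded demand).
#' @param growth_floor Minimum mutant growth as a fraction of wild-type
#'   maximum (default 0.5).
#' @param ko_growth_fraction Growth fixation used for production scoring
#'   (default 0.999).
#' @param min_gain Minimum relative production increase over wild type for a
#'   candidate (default 0.001).
#' @return A `knockout_scan` tibble: `rxn_id`, `mutant_max_growth`,
#'   `mutant_production`, `relative_increase`, sorted by decreasing gain,
#'   with attributes `wt_growth`, `wt_production`, `skipped` (tibble of
#'   reactions skipped with the reason).
#' @export
knockout_scan <- function(model, product = NULL, growth_floor = 0.5,
                          ko_growth_fraction = 0.999, min_gain = 0.001) {
  product <- product %||% model$product_demand
  stopifnot(!is.null(product))
  ex <- exchanges(model)$rxn_id
  has_genes <- purrr::map_lgl(model$rxns$genes, ~ length(.x) > 0)
  candidates <- model$rxns$rxn_id[
    has_genes & !model$rxns$rxn_id %in% ex &
      !model$rxns$rxn_id %in% model$pathway_rxns]

  wt <- fba(model)
  if (wt$status != "optimal") {
    rlang::abort("wild-type model infeasible", class = "bgcflux_infeasible")
  }
  mu_wt <- wt$objective_value
  wt_prod <- max_production(model, product,
                            growth_fraction = ko_growth_fraction)$production_rate

  rows <- list()
  skipped <- list()
  for (rid in candidates) {
    m <- model
    sel <- m$rxns$rxn_id == rid
    m$rxns$lb[sel] <- 0
    m$rxns$ub[sel] <- 0
    g <- fba(m)
    if (g$status != "optimal") {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(rxn_id = rid, reason = "infeasible (treated as essential)")
      next
    }
    mu <- g$objective_value
    if (mu < growth_floor * mu_wt - .LP_TOL) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(rxn_id = rid,
                       reason = sprintf("growth %.4g below floor", mu))
      next
    }
    p <- tryCatch(
      max_production(m, product, growth_fraction = ko_growth_fraction),
      bgcflux_infeasible = function(e) NULL)
    if (is.null(p)) {
      skipped[[length(skipped) + 1]] <-
        tibble::tibble(rxn_id = rid, reason = "production LP infeasible")
      next
    }
    gain <- if (wt_prod > 0) p$production_rate / wt_prod - 1 else
      ifelse(p$production_rate > 0, Inf, 0)
    if (gain > min_gain) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        rxn_id = rid, mutant_max_growth = mu,
        mutant_production = p$production_rate, relative_increase = gain)
    }
  }
  out <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows),
                                          dplyr::desc(.data$relative_increase))
  else tibble::tibble(rxn_id = character(0), mutant_max_growth = numeric(0),
                      mutant_production = numeric(0),
                      relative_increase = numeric(0))
  structure(out,
            class = c("knockout_scan", class(out)),
            wt_growth = mu_wt, wt_production = wt_prod,
            growth_floor = growth_floor,
            ko_growth_fraction = ko_growth_fraction,
            skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
              tibble::tibble(rxn_id = character(0), reason = character(0)))
}

#' @export
#' @method tidy production_result
tidy.production_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
#' @method glance production_result
glance.production_result <- function(x, ...) tibble::as_tibble(unclass(x))

#' Tidy a knockout scan
#' @param x A `knockout_scan`.
#' @param ... Unused.
#' @return Plain tibble of candidates.
#' @export
#' @method tidy knockout_scan
tidy.knockout_scan <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("rxn_id", "mutant_max_growth",
                                 "mutant_production", "relative_increase")])
}

#' @export
#' @method glance knockout_scan
glance.knockout_scan <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x),
    wt_growth = attr(x, "wt_growth"),
    wt_production = attr(x, "wt_production"),
    best_gain = if (nrow(x)) max(x$relative_increase) else NA_real_,
    n_skipped = nrow(attr(x, "skipped"))
  )
}

#' Plot knockout-scan candidates
#'
#' Bar chart of the relative production increase per knockout candidate,
#' annotated with the mutant growth rate.
#'
#' @param object A `knockout_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot knockout_scan
autoplot.knockout_scan <- function(object, ...) {
  d <- tidy.knockout_scan(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$rxn_id, .data$relative_increase),
    y = 100 * .data$relative_increase)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "production increase over wild type (%)",
                  title = "single-reaction knockout candidates") +
    ggplot2::theme_minimal()
}

#' Plot a pathway's reaction chain
#'
#' Displays the ordered biosynthetic reactions coloured by the generating
#' domain kind (provenance).
#'
#' @param object A `bgc_pathway`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
#' @method autoplot bgc_pathway
autoplot.bgc_pathway <- function(object, ...) {
  d <- tidy.bgc_pathway(object)
  d$step <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = 1,
                                  fill = .data$provenance)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "reaction order", y = NULL, fill = "domain",
                  title = sprintf("pathway %s (%d reactions)",
                                  object$cluster_id, nrow(d))) +
    ggplot2::theme_minimal()
}
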