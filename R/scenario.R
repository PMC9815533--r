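#' Define a community growth scenario
#'
#' A scenario fixes the environmental operating point of the co-culture:
#' the species-A biomass fraction `r`, the shared steady-state growth rate
#' `mu`, the total community biomass `x_total`, and the feed bounds of the
#' substrate exchanges. All fluxes of the scenario-constrained model are
#' environmental fluxes (mmol/l/h): specific fluxes times the biomass
#' concentration of the species carrying them.
#'
#' @param r Species-A fraction of community biomass, strictly in (0, 1).
#' @param mu Growth rate (1/h), shared by both species, > 0.
#' @param x_total Community biomass (gDW/l); default 0.22, the value
#'   measured for a comparable syngas co-culture.
#' @param feeds Data frame with columns `exchange`, `max_uptake`,
#'   `min_uptake` (mmol/l/h, nonnegative; `min <= max`). Each feed exchange
#'   gets bounds `(-max_uptake, -min_uptake)`.
#' @param bound_scaling If `TRUE` (default), finite reaction bounds other
#'   than 0 and the +-1000 "unbounded" sentinels are multiplied by the
#'   owning species' biomass concentration, converting specific-flux bounds
#'   to environmental units.
#' @return A `scenario` object.
#' @export
scenario <- function(r, mu, x_total = 0.22, feeds = NULL,
                     bound_scaling = TRUE) {
  stopifnot(r > 0, r < 1, mu > 0, x_total > 0)
  feeds <- feeds %||% tibble::tibble(exchange = character(),
                                     max_uptake = numeric(),
                                     min_uptake = numeric())
  feeds <- tibble::as_tibble(feeds)
  stopifnot(all(c("exchange", "max_uptake", "min_uptake") %in% names(feeds)))
  if (any(feeds$min_uptake < 0) ||
      any(feeds$min_uptake > feeds$max_uptake)) {
    stop("feeds need 0 <= min_uptake <= max_uptake")
  }
  structure(list(r = r, mu = mu, x_total = x_total, feeds = feeds,
                 bound_scaling = bound_scaling), class = "scenario")
}

#' Constrain a community model to a scenario
#'
#' Fixes each species' biomass synthesis flux to `mu * X_i` with
#' `X_A = r * x_total` and `X_B = (1 - r) * x_total`, applies the feed
#' bounds `(-max_uptake, -min_uptake)` to the feed exchanges, optionally
#' rescales finite non-sentinel species bounds by `X_i`, and rebuilds the
#' community biomass reaction with fractions `(r, 1 - r)`.
#'
#' @param cm A `community_gem`.
#' @param s A [scenario()].
#' @return A [gem] ready for [fba()], [is_feasible()] or [sample_fluxes()].
#' @export
apply_scenario <- function(cm, s) {
  stopifnot(inherits(cm, "community_gem"), inherits(s, "scenario"))
  cm <- add_community_biomass(cm, c(s$r, 1 - s$r))
  m <- cm$model
  x <- c(a = s$r * s$x_total, b = (1 - s$r) * s$x_total)
  if (s$bound_scaling) {
    for (side in c("a", "b")) {
      ids <- setdiff(cm$species[[side]]$reactions,
                     m$reactions$id[m$reactions$is_exchange])
      ids <- intersect(ids, m$reactions$id)
      i <- match(ids, m$reactions$id)
      scale_lb <- is.finite(m$reactions$lb[i]) &
        !m$reactions$lb[i] %in% c(0, -1000, 1000)
      scale_ub <- is.finite(m$reactions$ub[i]) &
        !m$reactions$ub[i] %in% c(0, -1000, 1000)
      m$reactions$lb[i[scale_lb]] <- m$reactions$lb[i[scale_lb]] * x[[side]]
      m$reactions$ub[i[scale_ub]] <- m$reactions$ub[i[scale_ub]] * x[[side]]
    }
  }
  for (side in c("a", "b")) {
    bio <- cm$species[[side]]$biomass_reaction
    m <- set_bounds(m, bio, s$mu * x[[side]], s$mu * x[[side]])
  }
  for (k in seq_len(nrow(s$feeds))) {
    id <- s$feeds$exchange[k]
    i <- rxn_row(m, id)
    if (!m$reactions$is_exchange[i]) {
      stop("feed '", id, "' is not an exchange reaction")
    }
    m <- set_bounds(m, id, -s$feeds$max_uptake[k], -s$feeds$min_uptake[k])
  }
  m
}

#' Feasibility of a scenario
#'
#' FBA with the community biomass objective; since the species biomass
#' fluxes are fixed by the scenario the objective is degenerate and the
#' result of interest is feasibility itself.
#'
#' @inheritParams apply_scenario
#' @return `TRUE` or `FALSE`.
#' @export
assess_feasibility <- function(cm, s) {
  is_feasible(apply_scenario(cm, s))
}

#' Scan feasibility over species ratio and growth rate
#'
#' One [assess_feasibility()] per grid cell, reproducing the feasible
#' solution-space maps of the community analysis. Defaults cover species
#' ratios 0.1-0.9 (step 0.1) and growth rates 0.005-0.1 1/h (step 0.005).
#'
#' @param cm A `community_gem`.
#' @param feeds Feed table (see [scenario()]).
#' @param ratio_grid,mu_grid Strictly increasing grids.
#' @param x_total Community biomass (gDW/l).
#' @param bound_scaling See [scenario()].
#' @param label Optional condition label stored on the result.
#' @return A `feasibility_map`: tibble with columns `r`, `mu`, `feasible`.
#'   `autoplot()` draws the feasible region.
#' @export
feasibility_scan <- function(cm, feeds,
                             ratio_grid = seq(0.1, 0.9, by = 0.1),
                             mu_grid = seq(0.005, 0.1, by = 0.005),
                             x_total = 0.22, bound_scaling = TRUE,
                             label = NULL) {
  stopifnot(length(ratio_grid) > 0, length(mu_grid) > 0,
            !is.unsorted(ratio_grid, strictly = TRUE),
            !is.unsorted(mu_grid, strictly = TRUE))
  grid <- tidyr::expand_grid(r = ratio_grid, mu = mu_grid)
  grid$feasible <- purrr::map2_lgl(grid$r, grid$mu, function(r, mu) {
    assess_feasibility(cm, scenario(r, mu, x_total, feeds, bound_scaling))
  })
  structure(grid, label = label, feeds = feeds, x_total = x_total,
            class = c("feasibility_map", class(grid)))
}

#' @method autoplot feasibility_map
#' @export
autoplot.feasibility_map <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$mu, y = .data$r,
                                    fill = .data$feasible)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#31688e",
                                          `FALSE` = "white"),
                               name = "feasible") +
    ggplot2::labs(x = "growth rate (1/h)", y = "species-A biomass fraction",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
}

#' Maximal feasible growth rate
#'
#' The scenario constraints are linear in `mu` at fixed ratio and total
#' biomass, so the supremum feasible growth rate is a single LP: `mu`
#' enters as an extra variable coupled to the two biomass fluxes
#' (`v_bio,i = mu * X_i`) and is maximized.
#'
#' @param cm A `community_gem`.
#' @param r Species-A biomass fraction.
#' @param feeds Feed table (see [scenario()]).
#' @param x_total Community biomass (gDW/l).
#' @param bound_scaling See [scenario()].
#' @return The maximal growth rate (1/h); 0 when only `mu = 0` is
#'   feasible, `NA` (with a warning) when the feed constraints are
#'   infeasible at any growth rate.
#' @export
max_growth <- function(cm, r, feeds, x_total = 0.22, bound_scaling = TRUE) {
  # constrain with a placeholder mu, then free the biomass fluxes
  s <- scenario(r, mu = 1, x_total = x_total, feeds = feeds,
                bound_scaling = bound_scaling)
  m <- apply_scenario(cm, s)
  bio_a <- cm$species$a$biomass_reaction
  bio_b <- cm$species$b$biomass_reaction
  m <- set_bounds(m, bio_a, 0, 1000)
  m <- set_bounds(m, bio_b, 0, 1000)
  S <- stoich_matrix(m)
  n <- ncol(S)
  A <- cbind(S, 0)
  couple <- matrix(0, 2, n + 1)
  couple[1, match(bio_a, m$reactions$id)] <- 1
  couple[1, n + 1] <- -r * x_total
  couple[2, match(bio_b, m$reactions$id)] <- 1
  couple[2, n + 1] <- -(1 - r) * x_total
  A <- rbind(A, couple)
  obj <- c(numeric(n), 1)
  res <- solve_lp(obj, A, rep(0, nrow(A)),
                  lb = c(m$reactions$lb, 0), ub = c(m$reactions$ub, 1000))
  if (res$status == "infeasible") {
    warning("feed constraints infeasible at every growth rate")
    return(NA_real_)
  }
  if (res$status != "optimal") stop("LP solver failure in max_growth")
  res$value
}

#' Sampled per-species exchange summary of a scenario
#'
#' Constrains the community model to the scenario, samples the flux
#' polytope uniformly, and decomposes for each shared extracellular
#' metabolite the community net exchange rate into the two species'
#' contributions (positive = production into the broth, negative =
#' uptake). At steady state the two species' rates sum to the community
#' net rate in every sample; the largest observed deviation is stored in
#' the `max_conservation_residual` attribute.
#'
#' @param cm A `community_gem`.
#' @param s A feasible [scenario()].
#' @param n,seed,thin Passed to [sample_fluxes()].
#' @param metabolites Extracellular metabolite ids to report (default: all
#'   with an exchange reaction).
#' @return A `species_flux_summary`: tibble with columns `metabolite`,
#'   `species` (species labels plus `"community"`), `mean`, `sd`
#'   (mmol/l/h). Attributes: `n`, `seed`, `max_conservation_residual`,
#'   `samples` kept on the underlying `flux_sample` object in
#'   `attr(, "sample")`.
#' @export
summarize_scenario <- function(cm, s, n = 5000, seed = NULL,
                               metabolites = NULL, thin = 5) {
  m <- apply_scenario(cm, s)
  if (!is_feasible(m)) stop("scenario is infeasible; nothing to sample")
  fs <- sample_fluxes(m, n = n, seed = seed, thin = thin)
  ex <- m$reactions[m$reactions$is_exchange, ]
  ex_met <- vapply(ex$stoichiometry, function(x) names(x)[1], character(1))
  metabolites <- metabolites %||% ex_met
  sets <- list(a = intersect(cm$species$a$reactions, m$reactions$id),
               b = intersect(cm$species$b$reactions, m$reactions$id))
  S <- stoich_matrix(m)
  rows <- list()
  resid <- 0
  for (met in metabolites) {
    exch_id <- ex$id[match(met, ex_met)]
    if (is.na(exch_id)) stop("no exchange reaction for metabolite '", met, "'")
    net <- fs$samples[, exch_id]
    contrib <- list()
    for (side in c("a", "b")) {
      ids <- setdiff(sets[[side]], exch_id)
      w <- S[met, ids]
      contrib[[side]] <- as.vector(fs$samples[, ids, drop = FALSE] %*% w)
    }
    resid <- max(resid, max(abs(contrib$a + contrib$b - net)))
    lab <- c(cm$species$a$label, cm$species$b$label, "community")
    vals <- list(contrib$a, contrib$b, net)
    for (k in 1:3) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite = met, species = lab[k],
        mean = mean(vals[[k]]), sd = stats::sd(vals[[k]]))
    }
  }
  structure(dplyr::bind_rows(rows),
            n = n, seed = seed, max_conservation_residual = resid,
            sample = fs, scenario = s,
            class = c("species_flux_summary",
                      class(tibble::tibble())))
}

#' @method autoplot species_flux_summary
#' @export
autoplot.species_flux_summary <- function(object, ...) {
  tbl <- tibble::as_tibble(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$species, y = .data$mean,
                                    fill = .data$species)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::facet_wrap(~metabolite, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "rate (mmol/l/h; negative = uptake)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
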