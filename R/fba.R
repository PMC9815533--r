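#' Flux balance analysis
#'
#' Solves the steady-state linear program `max/min v_obj` subject to
#' `S v = 0` and `lb <= v <= ub`, the standard FBA formulation. The
#' solution reports a status (`optimal`, `infeasible` or `solver_error`),
#' the objective value and the full flux vector.
#'
#' @param model A [gem] (or community model, in which case its merged model
#'   is used).
#' @param objective Reaction id to optimize; defaults to the model
#'   objective.
#' @param direction `"max"` or `"min"`.
#' @return An object of class `fba_solution`; use [tidy()] for the flux
#'   table and [glance()] for the one-row summary.
#' @examples
#' m <- toy_solventogen()
#' sol <- fba(m)
#' glance(sol)
#' @export
fba <- function(model, objective = NULL, direction = c("max", "min")) {
  model <- as_gem(model)
  direction <- match.arg(direction)
  objective <- objective %||% model$objective
  if (is.na(objective)) stop("no objective reaction given or stored")
  j <- rxn_row(model, objective)
  S <- stoich_matrix(model)
  obj <- numeric(ncol(S))
  obj[j] <- 1
  res <- solve_lp(obj, S, rep(0, nrow(S)), model$reactions$lb,
                  model$reactions$ub, maximize = direction == "max")
  if (res$status == "solver_error") {
    stop("LP solver failure while optimizing '", objective, "'")
  }
  fluxes <- if (res$status == "optimal") {
    tibble::tibble(reaction = model$reactions$id, flux = res$x)
  } else {
    tibble::tibble(reaction = character(), flux = numeric())
  }
  structure(
    list(status = res$status,
         objective_value = if (res$status == "optimal") res$value else NA_real_,
         fluxes = fluxes, objective = objective, direction = direction,
         model_id = model$id),
    class = "fba_solution")
}

#' @export
print.fba_solution <- function(x, ...) {
  cat(sprintf("<fba_solution> %s %s on %s: %s", x$direction, x$objective,
              x$model_id, x$status))
  if (x$status == "optimal") cat(sprintf(", objective = %g", x$objective_value))
  cat("\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fba
#' @param x An `fba_solution`.
#' @param ... Unused.
#' @method tidy fba_solution
#' @export
tidy.fba_solution <- function(x, ...) x$fluxes

#' @rdname fba
#' @method glance fba_solution
#' @export
glance.fba_solution <- function(x, ...) {
  tibble::tibble(status = x$status, objective = x$objective,
                 direction = x$direction,
                 objective_value = x$objective_value)
}

#' Flux of a single reaction in an FBA solution
#' @param solution An `fba_solution`.
#' @param reaction_id Reaction id.
#' @return A single flux value.
#' @export
flux_of <- function(solution, reaction_id) {
  i <- match(reaction_id, solution$fluxes$reaction)
  if (is.na(i)) stop("no flux for reaction '", reaction_id, "'")
  solution$fluxes$flux[i]
}

#' Feasibility of the steady-state constraint set
#'
#' Solves a zero-objective LP: `TRUE` iff `{v : S v = 0, lb <= v <= ub}` is
#' nonempty. Solver failures raise an error rather than reporting
#' infeasibility.
#'
#' @param model A [gem] or community model.
#' @return `TRUE` or `FALSE`.
#' @export
is_feasible <- function(model) {
  model <- as_gem(model)
  S <- stoich_matrix(model)
  res <- solve_lp(numeric(ncol(S)), S, rep(0, nrow(S)),
                  model$reactions$lb, model$reactions$ub)
  if (res$status == "solver_error") stop("LP solver failure in feasibility probe")
  res$status == "optimal"
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux over the steady-state polytope;
#' the standard LP oracle for the reachable flux range of each reaction.
#'
#' @param model A [gem] or community model; must be feasible.
#' @param reaction_ids Reactions to analyse (default: all).
#' @return A tibble with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, reaction_ids = NULL) {
  model <- as_gem(model)
  reaction_ids <- reaction_ids %||% model$reactions$id
  S <- stoich_matrix(model)
  if (!is_feasible(model)) stop("model is infeasible; no flux ranges exist")
  out <- purrr::map(reaction_ids, function(id) {
    j <- rxn_row(model, id)
    obj <- numeric(ncol(S))
    obj[j] <- 1
    lo <- solve_lp(obj, S, rep(0, nrow(S)), model$reactions$lb,
                   model$reactions$ub, maximize = FALSE)
    hi <- solve_lp(obj, S, rep(0, nrow(S)), model$reactions$lb,
                   model$reactions$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA solve failed for '", id, "'")
    }
    tibble::tibble(reaction = id, min = lo$value, max = hi$value)
  })
  dplyr::bind_rows(out)
}

as_gem <- function(model) {
  if (inherits(model, "community_gem")) model$model
  else if (inherits(model, "gem")) model
  else stop("expected a 'gem' or 'community_gem' object")
}
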