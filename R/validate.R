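#' Structural validation of a model
#'
#' Checks the structural invariants of a [gem] and reports every violation:
#' duplicate reaction/metabolite ids, reactions referencing unregistered
#' metabolites, gene rules citing unregistered genes, metabolites in
#' unregistered compartments, exchange reactions touching more than one (or
#' a non-extracellular) metabolite, empty stoichiometries, and `lb > ub`
#' bound violations. An empty report means all invariants hold.
#'
#' @param model A [gem] or community model.
#' @return A tibble with columns `type`, `id`, `message`; zero rows if the
#'   model is clean.
#' @export
gem_validate <- function(model) {
  if (inherits(model, "community_gem")) model <- model$model
  issues <- list()
  add <- function(type, id, message) {
    issues[[length(issues) + 1L]] <<- tibble::tibble(
      type = type, id = id, message = message)
  }
  dup_m <- unique(model$metabolites$id[duplicated(model$metabolites$id)])
  for (d in dup_m) add("duplicate_id", d, "duplicate metabolite id")
  dup_r <- unique(model$reactions$id[duplicated(model$reactions$id)])
  for (d in dup_r) add("duplicate_id", d, "duplicate reaction id")

  bad_cmp <- setdiff(unique(model$metabolites$compartment),
                     model$compartments)
  for (cm in bad_cmp) {
    add("unregistered_compartment", cm,
        "metabolite compartment not registered in the model")
  }

  extracellular <- model$metabolites$id[
    model$metabolites$compartment == "extracellular"]
  for (i in seq_len(nrow(model$reactions))) {
    id <- model$reactions$id[i]
    s <- model$reactions$stoichiometry[[i]]
    if (length(s) == 0) add("empty_stoichiometry", id, "no metabolites")
    miss <- setdiff(names(s), model$metabolites$id)
    if (length(miss)) {
      add("dangling_metabolite", id,
          paste("references unknown metabolite(s):",
                paste(miss, collapse = ", ")))
    }
    if (model$reactions$lb[i] > model$reactions$ub[i]) {
      add("bound_violation", id,
          sprintf("lb (%g) > ub (%g)", model$reactions$lb[i],
                  model$reactions$ub[i]))
    }
    if (isTRUE(model$reactions$is_exchange[i])) {
      if (length(s) != 1L || !(names(s) %in% extracellular)) {
        add("exchange_shape", id,
            "exchange reaction must touch exactly one extracellular metabolite")
      }
    }
    orphan <- setdiff(rule_genes(model$reactions$gene_rule[i]), model$genes)
    if (length(orphan)) {
      add("dangling_gene", id,
          paste("gene rule cites unregistered gene(s):",
                paste(orphan, collapse = ", ")))
    }
  }
  if (!is.na(model$objective) && !model$objective %in% model$reactions$id) {
    add("missing_objective", model$objective,
        "objective reaction not in model")
  }
  if (length(issues)) dplyr::bind_rows(issues) else {
    tibble::tibble(type = character(), id = character(),
                   message = character())
  }
}

#' Carbon balance of a reaction
#'
#' Sums `coefficient x carbon_count` over the metabolites of a reaction;
#' zero means the reaction is carbon-balanced. Currency metabolites whose
#' carbon moves with a tracked carrier (CoA, NAD(P)(H), ferredoxin,
#' ATP/ADP/AMP, phosphate, protons, water, translocated ions) and biomass
#' pseudo-metabolites are skipped via `ignore`, which matches metabolite
#' ids after stripping a trailing compartment/species tag (so `nad_c`,
#' `nad_ca` and `nad` all match `"nad"`).
#'
#' Exchange reactions necessarily have a non-zero balance (they move carbon
#' across the system boundary); callers exempt them from the zero check.
#'
#' @param model A [gem].
#' @param reaction_id Reaction to balance.
#' @param ignore Character vector of base metabolite names to skip;
#'   defaults to [cofactor_ignore()].
#' @return The signed carbon balance (a single number).
#' @export
carbon_balance <- function(model, reaction_id, ignore = cofactor_ignore()) {
  i <- rxn_row(model, reaction_id)
  s <- model$reactions$stoichiometry[[i]]
  total <- 0
  for (met in names(s)) {
    if (met_base(met) %in% ignore) next
    k <- model$metabolites$carbon_count[met_row(model, met)]
    if (is.na(k)) {
      stop("unknown carbon count for metabolite '", met,
           "' (not on the ignore list) in reaction '", reaction_id, "'")
    }
    total <- total + s[[met]] * k
  }
  total
}

#' @rdname carbon_balance
#' @export
cofactor_ignore <- function() {
  c("coa", "nad", "nadh", "nadp", "nadph", "fdox", "fdred", "fdxox",
    "fdxrd", "atp", "adp", "amp", "pi", "ppi", "h", "h2o", "ion", "na1",
    "biomass")
}

# strip trailing compartment/species tags: "nad_c" -> "nad",
# "nad_c_ca" -> "nad", "biomass_c" -> "biomass"
met_base <- function(id) {
  gsub("(_(c|e|ca|cb|p|m))+$", "", id)
}
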