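#' Construct a genome-scale metabolic model
#'
#' A `gem` is the in-memory representation of a stoichiometric network:
#' a metabolite table, a reaction table (with stoichiometry stored as a
#' list-column of named coefficient vectors, negative = consumed), a gene
#' registry, a compartment registry and an objective reaction. It is the
#' container every other function in the package operates on.
#'
#' @param id Model identifier.
#' @param metabolites A data frame with columns `id`, `compartment` and
#'   optionally `name`, `carbon_count` (number of carbon atoms, `NA` if
#'   unknown) and `formula`.
#' @param reactions A data frame with columns `id`, `stoichiometry` (a list
#'   of named numeric vectors keyed by metabolite id), `lb`, `ub` and
#'   optionally `name`, `gene_rule` (a boolean expression over gene ids
#'   using `and`/`or` and parentheses, `""` if none) and `is_exchange`.
#'   When `is_exchange` is missing it is inferred: a reaction is an
#'   exchange if it touches a single metabolite and its id starts with
#'   `"EX_"`.
#' @param genes Character vector of gene ids. Genes referenced by
#'   `gene_rule`s are added automatically.
#' @param compartments Character vector of compartment ids; defaults to the
#'   compartments used by `metabolites`.
#' @param objective Reaction id of the objective (usually biomass
#'   synthesis), or `NA`.
#'
#' @return An object of class `gem`.
#' @seealso [read_sbml()], [read_gem_table()], [gem_validate()]
#' @export
gem <- function(id, metabolites, reactions, genes = character(),
                compartments = NULL, objective = NA_character_) {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  if (!all(c("id", "compartment") %in% names(metabolites))) {
    stop("`metabolites` needs at least columns 'id' and 'compartment'")
  }
  if (!all(c("id", "stoichiometry", "lb", "ub") %in% names(reactions))) {
    stop("`reactions` needs columns 'id', 'stoichiometry', 'lb', 'ub'")
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"carbon_count" %in% names(metabolites)) {
    metabolites$carbon_count <- NA_real_
  }
  if (!"formula" %in% names(metabolites)) metabolites$formula <- NA_character_
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"gene_rule" %in% names(reactions)) reactions$gene_rule <- ""
  reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
  if (!"is_exchange" %in% names(reactions)) {
    reactions$is_exchange <- purrr::map2_lgl(
      reactions$stoichiometry, reactions$id,
      function(s, i) length(s) == 1L && grepl("^EX_", i)
    )
  }
  metabolites <- metabolites[, c("id", "name", "compartment",
                                 "carbon_count", "formula")]
  metabolites$carbon_count <- as.numeric(metabolites$carbon_count)
  reactions <- reactions[, c("id", "name", "stoichiometry", "lb", "ub",
                             "gene_rule", "is_exchange")]
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]),
               collapse = ", "))
  }
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]),
               collapse = ", "))
  }
  if (any(!nzchar(metabolites$id))) stop("empty metabolite id")
  genes <- union(genes, unlist(lapply(reactions$gene_rule, rule_genes)))
  if (is.null(compartments)) {
    compartments <- unique(metabolites$compartment)
  }
  structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         genes = genes, compartments = compartments, objective = objective),
    class = "gem"
  )
}

#' @export
print.gem <- function(x, ...) {
  n_ex <- sum(x$reactions$is_exchange)
  cat(sprintf(
    "<gem> %s: %d metabolites, %d reactions (%d exchange), %d genes\n",
    x$id, nrow(x$metabolites), nrow(x$reactions), n_ex, length(x$genes)))
  cat(sprintf("  compartments: %s\n", paste(x$compartments, collapse = ", ")))
  cat(sprintf("  objective: %s\n", x$objective))
  invisible(x)
}

#' Reaction and metabolite tables of a model
#'
#' @param model A [gem] or community model.
#' @return A tibble (one row per reaction / metabolite).
#' @export
reactions <- function(model) UseMethod("reactions")

#' @export
reactions.gem <- function(model) model$reactions

#' @rdname reactions
#' @export
metabolites <- function(model) UseMethod("metabolites")

#' @export
metabolites.gem <- function(model) model$metabolites

rxn_row <- function(model, id) {
  i <- match(id, model$reactions$id)
  if (is.na(i)) stop("no reaction '", id, "' in model '", model$id, "'")
  i
}

met_row <- function(model, id) {
  i <- match(id, model$metabolites$id)
  if (is.na(i)) stop("no metabolite '", id, "' in model '", model$id, "'")
  i
}

#' Stoichiometric matrix
#'
#' @param model A [gem].
#' @return A dense numeric matrix, metabolites in rows and reactions in
#'   columns, consumption negative.
#' @export
stoich_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[j]]
    S[names(s), j] <- S[names(s), j] + s
  }
  S
}

#' Modify a model
#'
#' Small pure helpers: each returns an edited copy of the model.
#' `add_reaction()` registers any new metabolite it introduces (compartment
#' guessed from an `_e` suffix as extracellular, otherwise the first
#' non-extracellular compartment; carbon count unknown) so validation
#' stays clean.
#'
#' @param model A [gem].
#' @param id Reaction id.
#' @param stoich Named numeric vector of stoichiometric coefficients
#'   (negative = consumed).
#' @param lb,ub Flux bounds.
#' @param name Human-readable name.
#' @param gene_rule Boolean gene association, `""` for none.
#' @param is_exchange Flag; inferred from the id/stoichiometry if `NULL`.
#' @return The edited model.
#' @export
add_reaction <- function(model, id, stoich, lb = 0, ub = 1000,
                         name = id, gene_rule = "", is_exchange = NULL) {
  if (id %in% model$reactions$id) {
    stop("reaction '", id, "' already present")
  }
  if (length(stoich) == 0) stop("empty stoichiometry for '", id, "'")
  if (lb > ub) stop("lb > ub for '", id, "'")
  new_mets <- setdiff(names(stoich), model$metabolites$id)
  if (length(new_mets)) {
    intra <- setdiff(model$compartments, "extracellular")
    cmp <- ifelse(grepl("_e$", new_mets),
                  "extracellular",
                  if (length(intra)) intra[[1]] else "cytosol")
    model$metabolites <- dplyr::bind_rows(
      model$metabolites,
      tibble::tibble(id = new_mets, name = new_mets, compartment = cmp,
                     carbon_count = NA_real_, formula = NA_character_))
    model$compartments <- union(model$compartments, unique(cmp))
  }
  if (is.null(is_exchange)) {
    is_exchange <- length(stoich) == 1L && grepl("^EX_", id)
  }
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(id = id, name = name, stoichiometry = list(stoich),
                   lb = lb, ub = ub, gene_rule = gene_rule,
                   is_exchange = is_exchange))
  model$genes <- union(model$genes, rule_genes(gene_rule))
  model
}

#' @rdname add_reaction
#' @export
remove_reaction <- function(model, id) {
  i <- rxn_row(model, id)
  model$reactions <- model$reactions[-i, ]
  if (identical(model$objective, id)) model$objective <- NA_character_
  model
}

#' @rdname add_reaction
#' @export
set_bounds <- function(model, id, lb, ub) {
  i <- rxn_row(model, id)
  if (lb > ub) stop("lb > ub for '", id, "'")
  model$reactions$lb[i] <- lb
  model$reactions$ub[i] <- ub
  model
}

#' @rdname add_reaction
#' @export
set_objective <- function(model, id) {
  rxn_row(model, id)
  model$objective <- id
  model
}

bounds_of <- function(model, id) {
  i <- rxn_row(model, id)
  c(model$reactions$lb[i], model$reactions$ub[i])
}

# gene ids occurring in a boolean rule
rule_genes <- function(rule) {
  if (is.na(rule) || !nzchar(rule)) return(character())
  toks <- strsplit(gsub("[()]", " ", rule), "\\s+")[[1]]
  setdiff(toks[nzchar(toks)], c("and", "or", "AND", "OR"))
}
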