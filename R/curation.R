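#' Declarative model edits
#'
#' Model curation is expressed as data: an edit operation has a `kind`, a
#' `target` reaction and a kind-specific `payload`, and a recipe is an
#' ordered list of operations with provenance notes. Keeping the edits as
#' config files makes a curation inspectable and reusable on freshly
#' downloaded models. Supported kinds:
#'
#' * `add_reaction` — payload: `equation` (or `stoichiometry` map), and
#'   optionally `lb`, `ub`, `gene_rule`, `name`. Bounds default from the
#'   equation arrow (`<=>` reversible, `-->` irreversible).
#' * `remove_reaction` — drop the target.
#' * `replace_reaction` — remove the target and add the payload reaction,
#'   atomically.
#' * `set_reversibility` — payload `reversible`; `TRUE` sets the lower
#'   bound to the negative default (-1000), `FALSE` clips it to 0.
#' * `set_bounds` — payload `lb`, `ub`.
#' * `set_gene_rule` — payload `rule`.
#' * `rebalance_stoichiometry` — payload `stoichiometry`: a full
#'   replacement coefficient map.
#'
#' @param kind Operation kind (see above).
#' @param target Target reaction id (may be omitted for `add_reaction` when
#'   the payload carries an `id`).
#' @param payload Kind-specific named list.
#' @param note Free-text provenance note.
#' @return `edit_op()` returns an `edit_op` object; `recipe()` a
#'   `curation_recipe`.
#' @export
edit_op <- function(kind, target = NULL, payload = list(), note = "") {
  kinds <- c("add_reaction", "remove_reaction", "replace_reaction",
             "set_reversibility", "set_bounds", "set_gene_rule",
             "rebalance_stoichiometry")
  if (!kind %in% kinds) {
    stop("unknown edit kind '", kind, "' (known: ",
         paste(kinds, collapse = ", "), ")")
  }
  if (is.null(target) && kind != "add_reaction") {
    stop("edit kind '", kind, "' needs a target reaction id")
  }
  structure(list(kind = kind, target = target, payload = payload,
                 note = note), class = "edit_op")
}

#' @rdname edit_op
#' @param name Recipe name.
#' @param ops List of `edit_op`s.
#' @export
recipe <- function(name, ops) {
  stopifnot(all(vapply(ops, inherits, logical(1), "edit_op")))
  structure(list(name = name, ops = ops), class = "curation_recipe")
}

#' @export
print.curation_recipe <- function(x, ...) {
  cat(sprintf("<curation_recipe> %s: %d ops\n", x$name, length(x$ops)))
  for (op in x$ops) {
    cat(sprintf("  - %s %s\n", op$kind, op$target %||% op$payload$id %||% ""))
  }
  invisible(x)
}

#' Load a curation recipe from a YAML file
#'
#' The file holds `name` and an `ops` list of `{kind, target, payload,
#' note}` entries; `add_reaction`/`replace_reaction` payloads give the new
#' reaction as an equation string. Recipes encoding the published curations
#' of the *C. beijerinckii* and *C. acetobutylicum* models ship with the
#' package: `syncom_recipe("icm943")`, `syncom_recipe("icac803")`, plus
#' community-extension recipes (`"community_extras"`,
#' `"toy_community_extras"`).
#'
#' @param path Path to a recipe YAML file.
#' @return A `curation_recipe`.
#' @export
load_recipe <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(recipe(name = basename(path), ops = list()))
  ops <- lapply(seq_along(raw$ops %||% list()), function(i) {
    o <- raw$ops[[i]]
    tryCatch(
      edit_op(kind = o$kind %||% "", target = o$target,
              payload = o$payload %||% list(), note = o$note %||% ""),
      error = function(e) stop("recipe '", path, "', op ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  })
  recipe(name = raw$name %||% basename(path), ops = ops)
}

#' @rdname load_recipe
#' @param name Shipped recipe name (file stem under `inst/recipes`).
#' @export
syncom_recipe <- function(name) {
  path <- system.file("recipes", paste0(name, ".yaml"), package = "syncom")
  if (!nzchar(path)) stop("no shipped recipe '", name, "'")
  load_recipe(path)
}

payload_reaction <- function(op) {
  p <- op$payload
  id <- p$id %||% op$target
  if (is.null(id)) stop("add_reaction payload needs an id or target")
  if (!is.null(p$equation)) {
    eq <- parse_equation(p$equation)
    stoich <- eq$stoichiometry
    lb <- p$lb %||% if (eq$reversible) -1000 else 0
    ub <- p$ub %||% 1000
  } else if (!is.null(p$stoichiometry)) {
    stoich <- unlist(p$stoichiometry)
    lb <- p$lb %||% 0
    ub <- p$ub %||% 1000
  } else {
    stop("payload for '", id, "' needs an 'equation' or 'stoichiometry'")
  }
  list(id = id, stoich = stoich, lb = lb, ub = ub,
       gene_rule = p$gene_rule %||% "", name = p$name %||% id)
}

#' Apply a single edit operation
#'
#' @param model A [gem].
#' @param op An [edit_op()].
#' @return The edited model (the input is not modified).
#' @export
apply_edit <- function(model, op) {
  stopifnot(inherits(op, "edit_op"))
  need_target <- function() {
    if (!op$target %in% model$reactions$id) {
      stop(op$kind, ": no reaction '", op$target, "' in model '",
           model$id, "'")
    }
  }
  switch(op$kind,
    add_reaction = {
      p <- payload_reaction(op)
      add_reaction(model, p$id, p$stoich, p$lb, p$ub,
                   name = p$name, gene_rule = p$gene_rule)
    },
    remove_reaction = {
      need_target()
      remove_reaction(model, op$target)
    },
    replace_reaction = {
      need_target()
      p <- payload_reaction(op)
      m <- remove_reaction(model, op$target)
      add_reaction(m, p$id, p$stoich, p$lb, p$ub,
                   name = p$name, gene_rule = p$gene_rule)
    },
    set_reversibility = {
      need_target()
      i <- rxn_row(model, op$target)
      if (isTRUE(op$payload$reversible)) {
        model$reactions$lb[i] <- -1000
      } else {
        model$reactions$lb[i] <- max(model$reactions$lb[i], 0)
      }
      model
    },
    set_bounds = {
      need_target()
      set_bounds(model, op$target, op$payload$lb, op$payload$ub)
    },
    set_gene_rule = {
      need_target()
      i <- rxn_row(model, op$target)
      model$reactions$gene_rule[i] <- op$payload$rule %||% ""
      model$genes <- union(model$genes, rule_genes(op$payload$rule %||% ""))
      model
    },
    rebalance_stoichiometry = {
      need_target()
      i <- rxn_row(model, op$target)
      stoich <- unlist(op$payload$stoichiometry)
      if (length(stoich) == 0) stop("rebalance_stoichiometry: empty map")
      new_mets <- setdiff(names(stoich), model$metabolites$id)
      if (length(new_mets)) {
        # route through add_reaction to register metabolites, then move
        tmp <- add_reaction(model, ".tmp_rebalance", stoich)
        model$metabolites <- tmp$metabolites
        model$compartments <- tmp$compartments
      }
      model$reactions$stoichiometry[[i]] <- stoich
      model
    },
    stop("unhandled edit kind '", op$kind, "'")
  )
}

#' Apply a recipe
#'
#' Applies the operations in order. The first failing operation aborts the
#' whole application and the input model is returned unchanged (edits are
#' pure). Re-applying a recipe fails on its first already-applied edit
#' rather than silently doing nothing.
#'
#' @param model A [gem].
#' @param rec A `curation_recipe`.
#' @return A list with `model` (the edited [gem]) and `log`, a tibble with
#'   one row per operation (`step`, `kind`, `target`, `note`,
#'   `n_reactions_before`, `n_reactions_after`).
#' @export
apply_recipe <- function(model, rec) {
  stopifnot(inherits(rec, "curation_recipe"))
  log <- vector("list", length(rec$ops))
  m <- model
  for (i in seq_along(rec$ops)) {
    op <- rec$ops[[i]]
    before <- nrow(m$reactions)
    m <- tryCatch(apply_edit(m, op), error = function(e) {
      stop("recipe '", rec$name, "' failed at op ", i, " (", op$kind, " ",
           op$target %||% "", "): ", conditionMessage(e), call. = FALSE)
    })
    log[[i]] <- tibble::tibble(
      step = i, kind = op$kind,
      target = op$target %||% (op$payload$id %||% NA_character_),
      note = op$note, n_reactions_before = before,
      n_reactions_after = nrow(m$reactions))
  }
  list(model = m, log = dplyr::bind_rows(log) %||%
         tibble::tibble(step = integer(), kind = character(),
                        target = character(), note = character(),
                        n_reactions_before = integer(),
                        n_reactions_after = integer()))
}
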