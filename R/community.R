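#' Describe one species for community-model construction
#'
#' @param model The species [gem].
#' @param suffix Id tag appended to every intracellular metabolite,
#'   reaction and gene id of this species (e.g. `"_ca"`); may be `""` for
#'   the species whose namespace is kept as-is. The two species of a
#'   community must use different suffixes.
#' @param compartment Label for this species' cytosol compartment in the
#'   merged model (e.g. `"cytosol_ca"`).
#' @param biomass_reaction Id of the biomass synthesis reaction.
#' @param biomass_metabolite Id of the biomass metabolite it produces.
#' @param label Short display label (defaults to the model id).
#' @return A `species_spec`.
#' @export
species_spec <- function(model, suffix, compartment, biomass_reaction,
                         biomass_metabolite, label = model$id) {
  stopifnot(inherits(model, "gem"))
  rxn_row(model, biomass_reaction)
  i <- met_row(model, biomass_metabolite)
  s <- model$reactions$stoichiometry[[rxn_row(model, biomass_reaction)]]
  if (!(biomass_metabolite %in% names(s)) || s[[biomass_metabolite]] <= 0) {
    stop("biomass reaction '", biomass_reaction,
         "' does not produce metabolite '", biomass_metabolite, "'")
  }
  structure(list(model = model, suffix = suffix, compartment = compartment,
                 biomass_reaction = biomass_reaction,
                 biomass_metabolite = biomass_metabolite, label = label),
            class = "species_spec")
}

#' Rewrite one species into the community namespace
#'
#' Intracellular metabolite, reaction and gene ids get the species suffix
#' and the cytosol compartment is relabelled per the spec. Extracellular
#' metabolites are renamed through the namespace map into the shared
#' extracellular namespace; extracellular metabolites *not* covered by the
#' map are treated as species-private and suffixed, so two species can
#' never silently share an unmapped compound.
#'
#' @param spec A [species_spec()].
#' @param namespace_map A data frame with columns `id_a`, `id_b` pairing
#'   the extracellular metabolite ids of the two species; the shared id is
#'   `id_b` (falling back to `id_a` for species-B-absent compounds).
#' @param side `"a"` or `"b"`: which column of the map names this species.
#' @return A [gem] with rewritten ids; the attribute
#'   `"unmapped_extracellular"` lists the original ids of private
#'   extracellular metabolites.
#' @export
tag_species <- function(spec, namespace_map, side = c("a", "b")) {
  side <- match.arg(side)
  m <- spec$model
  map_from <- namespace_map[[paste0("id_", side)]]
  shared <- dplyr::coalesce(namespace_map$id_b, namespace_map$id_a)
  extr <- m$metabolites$compartment == "extracellular"
  old <- m$metabolites$id
  new <- old
  unmapped <- character()
  for (i in which(extr)) {
    j <- match(old[i], map_from)
    if (!is.na(j)) {
      new[i] <- shared[j]
    } else if (nzchar(spec$suffix)) {
      new[i] <- paste0(old[i], spec$suffix)
      unmapped <- c(unmapped, old[i])
    } else {
      unmapped <- c(unmapped, old[i])
    }
  }
  new[!extr] <- paste0(old[!extr], spec$suffix)
  if (anyDuplicated(new)) {
    stop("species tagging creates duplicate metabolite ids: ",
         paste(unique(new[duplicated(new)]), collapse = ", "))
  }
  ren <- stats::setNames(new, old)
  m$metabolites$id <- new
  m$metabolites$compartment[!extr] <- spec$compartment
  m$compartments <- unique(m$metabolites$compartment)
  m$reactions$stoichiometry <- lapply(m$reactions$stoichiometry, function(s) {
    stats::setNames(as.numeric(s), unname(ren[names(s)]))
  })
  new_rid <- paste0(m$reactions$id, spec$suffix)
  if (anyDuplicated(new_rid)) {
    stop("species tagging creates duplicate reaction ids")
  }
  m$reactions$id <- new_rid
  if (nzchar(spec$suffix) && length(m$genes)) {
    gmap <- stats::setNames(paste0(m$genes, spec$suffix), m$genes)
    m$genes <- unname(gmap)
    m$reactions$gene_rule <- vapply(m$reactions$gene_rule, function(r) {
      if (!nzchar(r)) return("")
      for (g in names(gmap)) {
        r <- gsub(paste0("\\b", g, "\\b"), gmap[[g]], r)
      }
      r
    }, character(1))
  }
  if (!is.na(m$objective)) m$objective <- paste0(m$objective, spec$suffix)
  m$id <- paste0(m$id, spec$suffix)
  structure(m, unmapped_extracellular = unmapped)
}

#' Merge two species models into a three-compartment community model
#'
#' Builds the community model: each species keeps its own cytosol
#' compartment, extracellular metabolites are shared through the namespace
#' map, duplicate exchange reactions for the same shared metabolite are
#' deduplicated to one (with the union of the bound intervals, since the
#' environment rather than either species owns exchange bounds), optional
#' cross-feeding reactions are added from a recipe, and a community biomass
#' reaction consuming both species' biomass metabolites is appended. Every
#' metabolite interchanged between the species travels through the
#' extracellular compartment; no cytosol-to-cytosol reaction is created.
#'
#' @param spec_a,spec_b [species_spec()]s for the two members. By
#'   convention species A carries the non-empty suffix.
#' @param namespace_map Data frame with columns `id_a`, `id_b` (see
#'   [tag_species()]); `NA` entries mark species-private compounds that
#'   keep a stable shared-namespace name.
#' @param extras Optional `curation_recipe` of cross-feeding reactions to
#'   add after the merge.
#' @param fractions Community biomass fractions (A, B), summing to 1.
#' @return A `community_gem`: list with `model` (the merged [gem]),
#'   `species` (per-species registry of rewritten reaction ids, biomass
#'   ids and labels), `namespace_map` and `community_biomass`.
#' @export
build_community <- function(spec_a, spec_b, namespace_map, extras = NULL,
                            fractions = c(0.5, 0.5)) {
  stopifnot(inherits(spec_a, "species_spec"), inherits(spec_b, "species_spec"))
  if (identical(spec_a$suffix, spec_b$suffix)) {
    stop("the two species must use different id suffixes")
  }
  namespace_map <- tibble::as_tibble(namespace_map)
  ta <- tag_species(spec_a, namespace_map, side = "a")
  tb <- tag_species(spec_b, namespace_map, side = "b")
  priv <- intersect(attr(ta, "unmapped_extracellular"),
                    attr(tb, "unmapped_extracellular"))
  if (length(priv)) {
    warning("extracellular metabolite(s) present in both species but not ",
            "in the namespace map; kept as two species-private copies: ",
            paste(priv, collapse = ", "))
  }

  dup_m <- intersect(ta$metabolites$id, tb$metabolites$id)
  mets_b_extra <- tb$metabolites[!tb$metabolites$id %in% dup_m, ]
  # shared metabolites: reconcile carbon counts
  for (d in dup_m) {
    ka <- ta$metabolites$carbon_count[met_row(ta, d)]
    kb <- tb$metabolites$carbon_count[met_row(tb, d)]
    if (!is.na(ka) && !is.na(kb) && ka != kb) {
      stop("shared metabolite '", d, "' has conflicting carbon counts (",
           ka, " vs ", kb, ")")
    }
  }
  metabolites <- dplyr::bind_rows(ta$metabolites, mets_b_extra)

  dup_r <- intersect(ta$reactions$id, tb$reactions$id)
  if (length(dup_r)) {
    stop("reaction id collision after tagging: ",
         paste(dup_r, collapse = ", "))
  }
  reactions <- dplyr::bind_rows(ta$reactions, tb$reactions)

  m <- gem(id = paste0(ta$id, "__", tb$id),
           metabolites = metabolites, reactions = reactions,
           genes = union(ta$genes, tb$genes),
           compartments = unique(c(spec_a$compartment, spec_b$compartment,
                                   "extracellular")))

  # deduplicate exchange reactions keyed on the shared extracellular
  # metabolite: one exchange per compound, widest bounds
  ex <- m$reactions[m$reactions$is_exchange, ]
  ex_met <- vapply(ex$stoichiometry, function(s) names(s)[1], character(1))
  shared_ex <- 0L
  for (met in unique(ex_met[duplicated(ex_met)])) {
    ids <- ex$id[ex_met == met]
    lb <- min(vapply(ids, function(i) bounds_of(m, i)[1], numeric(1)))
    ub <- max(vapply(ids, function(i) bounds_of(m, i)[2], numeric(1)))
    for (i in ids) m <- remove_reaction(m, i)
    m <- add_reaction(m, paste0("EX_", met), stats::setNames(-1, met),
                      lb = lb, ub = ub, is_exchange = TRUE)
    shared_ex <- shared_ex + length(ids) - 1L
  }

  tag_bm <- function(spec) {
    cmp <- spec$model$metabolites$compartment[
      met_row(spec$model, spec$biomass_metabolite)]
    if (cmp == "extracellular") spec$biomass_metabolite
    else paste0(spec$biomass_metabolite, spec$suffix)
  }
  species <- list(
    a = list(label = spec_a$label, suffix = spec_a$suffix,
             compartment = spec_a$compartment,
             biomass_reaction = paste0(spec_a$biomass_reaction, spec_a$suffix),
             biomass_metabolite = tag_bm(spec_a),
             reactions = ta$reactions$id, genes = ta$genes),
    b = list(label = spec_b$label, suffix = spec_b$suffix,
             compartment = spec_b$compartment,
             biomass_reaction = paste0(spec_b$biomass_reaction, spec_b$suffix),
             biomass_metabolite = tag_bm(spec_b),
             reactions = tb$reactions$id, genes = tb$genes))

  cm <- structure(list(model = m, species = species,
                       namespace_map = namespace_map,
                       community_biomass = "Community_biomass",
                       n_shared_exchanges = shared_ex),
                  class = "community_gem")

  if (!is.null(extras)) {
    res <- apply_recipe(cm$model, extras)
    cm$model <- res$model
    cm$extras_log <- res$log
  }
  add_community_biomass(cm, fractions)
}

#' Set the community biomass reaction
#'
#' Adds (or replaces) the `Community_biomass` reaction consuming the two
#' species' biomass metabolites with coefficients equal to the biomass
#' fractions, and makes it the model objective. With species biomass fluxes
#' fixed by a scenario the choice of coefficients only scales the reported
#' community objective, not feasibility.
#'
#' @param cm A `community_gem`.
#' @param fractions Numeric length-2 vector `(f_A, f_B)`, nonnegative,
#'   summing to 1.
#' @return The updated `community_gem`.
#' @export
add_community_biomass <- function(cm, fractions) {
  stopifnot(inherits(cm, "community_gem"), length(fractions) == 2)
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop("biomass fractions must be nonnegative and sum to 1")
  }
  m <- cm$model
  if ("Community_biomass" %in% m$reactions$id) {
    m <- remove_reaction(m, "Community_biomass")
  }
  stoich <- stats::setNames(
    -fractions, c(cm$species$a$biomass_metabolite,
                  cm$species$b$biomass_metabolite))
  stoich <- stoich[fractions > 0]
  m <- add_reaction(m, "Community_biomass", stoich, lb = 0, ub = 1000,
                    name = "community biomass synthesis",
                    is_exchange = FALSE)
  m <- set_objective(m, "Community_biomass")
  cm$model <- m
  cm$fractions <- fractions
  cm
}

#' @export
print.community_gem <- function(x, ...) {
  cat(sprintf("<community_gem> %s + %s\n", x$species$a$label,
              x$species$b$label))
  print(x$model)
  invisible(x)
}

#' @export
reactions.community_gem <- function(model) model$model$reactions

#' @export
metabolites.community_gem <- function(model) model$model$metabolites

#' Read a namespace map from a two-column TSV
#'
#' @param path TSV with columns `id_a`, `id_b` (empty cells = `NA`).
#' @return A tibble.
#' @export
read_namespace_map <- function(path) {
  readr::read_tsv(path, col_types = "cc", progress = FALSE)
}
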