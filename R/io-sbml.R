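SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- c("http://www.sbml.org/sbml/level3/version1/fbc/version2",
            "http://www.sbml.org/sbml/level3/version1/fbc/version1")

#' Read a model from SBML Level 3
#'
#' Parses an SBML Level 3 Version 1 file into a [gem]. Flux bounds are taken
#' from the flux-constraints (`fbc`) bound attributes with their referenced
#' parameters; for legacy files a fallback accepts `LOWER_BOUND` /
#' `UPPER_BOUND` kinetic-law parameters. The active `fbc` objective becomes
#' the model objective, and gene-product associations are flattened to
#' `and`/`or` rule strings. Carbon counts are recovered from chemical
#' formulas.
#'
#' @param path Path to an SBML file.
#' @param default_bounds If `TRUE`, reactions without retrievable bounds get
#'   `(-1000, 1000)` when declared reversible and `(0, 1000)` otherwise;
#'   if `FALSE` (default) such reactions raise an error listing their ids.
#' @return A [gem].
#' @export
read_sbml <- function(path, default_bounds = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("not parseable as XML: ", path, " (", conditionMessage(e), ")",
         call. = FALSE)
  })
  ns <- xml2::xml_ns(doc)
  core <- names(ns)[ns == SBML_CORE_NS]
  if (!length(core)) stop("not an SBML Level 3 Version 1 document: ", path)
  core <- core[[1]]
  fbc <- names(ns)[ns %in% FBC_NS]
  fbc <- if (length(fbc)) fbc[[1]] else NA_character_
  p <- function(tag, pre = core) paste0(pre, ":", tag)

  model_node <- xml2::xml_find_first(doc, paste0("./", p("model")), ns)
  if (inherits(model_node, "xml_missing")) stop("SBML file has no <model>")
  model_id <- xml2::xml_attr(model_node, "id") %||% "model"

  comp_nodes <- xml2::xml_find_all(
    model_node, paste0("./", p("listOfCompartments"), "/", p("compartment")), ns)
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp_nodes <- xml2::xml_find_all(
    model_node, paste0("./", p("listOfSpecies"), "/", p("species")), ns)
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_formula <- if (!is.na(fbc)) {
    vapply(sp_nodes, xml2::xml_attr, character(1),
           attr = paste0(fbc, ":chemicalFormula"), ns = ns)
  } else rep(NA_character_, length(sp_nodes))
  mets <- tibble::tibble(
    id = sp_id,
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"), sp_id),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    carbon_count = vapply(sp_formula, formula_carbon, numeric(1)),
    formula = sp_formula
  )

  par_nodes <- xml2::xml_find_all(
    model_node, paste0("./", p("listOfParameters"), "/", p("parameter")), ns)
  par_val <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))

  rx_nodes <- xml2::xml_find_all(
    model_node, paste0("./", p("listOfReactions"), "/", p("reaction")), ns)
  n <- length(rx_nodes)
  ids <- xml2::xml_attr(rx_nodes, "id")
  stoichs <- vector("list", n)
  lb <- ub <- rep(NA_real_, n)
  rules <- character(n)
  reversible <- xml2::xml_attr(rx_nodes, "reversible") %in% c("true", "1")

  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    s <- numeric()
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(node, paste0("./", p(side), "/",
                                              p("speciesReference")), ns)
      if (!length(refs)) next
      sp <- xml2::xml_attr(refs, "species")
      undeclared <- setdiff(sp, mets$id)
      if (length(undeclared)) {
        stop("SBML format error: reaction '", ids[i],
             "' references undeclared species '",
             paste(undeclared, collapse = "', '"), "'")
      }
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      sgn <- if (side == "listOfReactants") -1 else 1
      for (k in seq_along(sp)) s[sp[k]] <- (s[sp[k]] %||% 0) + sgn * coef[k]
    }
    stoichs[[i]] <- s
    # bounds: fbc attributes first, kinetic-law parameters as fallback
    if (!is.na(fbc)) {
      lb_ref <- xml2::xml_attr(node, paste0(fbc, ":lowerFluxBound"), ns)
      ub_ref <- xml2::xml_attr(node, paste0(fbc, ":upperFluxBound"), ns)
      if (!is.na(lb_ref)) lb[i] <- unname(par_val[lb_ref])
      if (!is.na(ub_ref)) ub[i] <- unname(par_val[ub_ref])
    }
    if (is.na(lb[i]) || is.na(ub[i])) {
      kl <- xml2::xml_find_all(
        node, paste0(".//", p("localParameter"), " | .//", p("parameter")), ns)
      if (length(kl)) {
        kid <- toupper(xml2::xml_attr(kl, "id"))
        kval <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(lb[i]) && "LOWER_BOUND" %in% kid) {
          lb[i] <- kval[match("LOWER_BOUND", kid)]
        }
        if (is.na(ub[i]) && "UPPER_BOUND" %in% kid) {
          ub[i] <- kval[match("UPPER_BOUND", kid)]
        }
      }
    }
    if (!is.na(fbc)) {
      gpa <- xml2::xml_find_first(
        node, paste0("./", fbc, ":geneProductAssociation"), ns)
      if (!inherits(gpa, "xml_missing")) {
        rules[i] <- gpa_to_rule(xml2::xml_child(gpa), fbc, ns)
      }
    }
  }

  missing_b <- ids[is.na(lb) | is.na(ub)]
  if (length(missing_b)) {
    if (default_bounds) {
      miss <- is.na(lb)
      lb[miss] <- ifelse(reversible[miss], -1000, 0)
      ub[is.na(ub)] <- 1000
    } else {
      stop("missing flux bounds for reactions: ",
           paste(missing_b, collapse = ", "))
    }
  }

  genes <- character()
  objective <- NA_character_
  if (!is.na(fbc)) {
    gp <- xml2::xml_find_all(
      model_node, paste0("./", fbc, ":listOfGeneProducts/", fbc,
                         ":geneProduct"), ns)
    genes <- dplyr::coalesce(
      vapply(gp, xml2::xml_attr, character(1),
             attr = paste0(fbc, ":label"), ns = ns),
      vapply(gp, xml2::xml_attr, character(1),
             attr = paste0(fbc, ":id"), ns = ns))
    fo <- xml2::xml_find_first(
      model_node, paste0("./", fbc, ":listOfObjectives/", fbc, ":objective/",
                         fbc, ":listOfFluxObjectives/", fbc,
                         ":fluxObjective"), ns)
    if (!inherits(fo, "xml_missing")) {
      objective <- xml2::xml_attr(fo, paste0(fbc, ":reaction"), ns)
    }
  }

  reactions <- tibble::tibble(
    id = ids,
    name = dplyr::coalesce(xml2::xml_attr(rx_nodes, "name"), ids),
    stoichiometry = stoichs, lb = lb, ub = ub, gene_rule = rules
  )
  m <- gem(model_id, mets, reactions, genes = genes,
           compartments = compartments, objective = objective)
  issues <- gem_validate(m)
  if (nrow(issues)) {
    stop("SBML model fails validation:\n",
         paste(utils::capture.output(print(issues)), collapse = "\n"))
  }
  m
}

#' Write a model to SBML Level 3 Version 1
#'
#' Emits SBML L3V1 with `fbc` version 2 flux bounds (one parameter pair per
#' reaction), the objective, gene products and gene-product associations,
#' and chemical formulas (a bare `C<k>` formula encodes a known carbon
#' count when no formula is stored). [read_sbml()] is an inverse.
#'
#' @param model A [gem].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_CORE_NS, "xmlns:fbc" = FBC_NS[1],
    level = "3", version = "1", "fbc:required" = "false")
  mn <- xml2::xml_add_child(doc, "model", id = model$id,
                            "fbc:strict" = "false")

  lc <- xml2::xml_add_child(mn, "listOfCompartments")
  for (cm in model$compartments) {
    xml2::xml_add_child(lc, "compartment", id = cm, constant = "true")
  }

  ls <- xml2::xml_add_child(mn, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    row <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(
      ls, "species", id = row$id, name = row$name,
      compartment = row$compartment, hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
    f <- row$formula
    if (is.na(f) && !is.na(row$carbon_count)) {
      f <- paste0("C", format(row$carbon_count))
    }
    if (!is.na(f)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", f)
  }

  lp <- xml2::xml_add_child(mn, "listOfParameters")
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    xml2::xml_add_child(lp, "parameter", id = paste0(rid, "_lower"),
                        value = num2chr(model$reactions$lb[i]),
                        constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(rid, "_upper"),
                        value = num2chr(model$reactions$ub[i]),
                        constant = "true")
  }

  lr <- xml2::xml_add_child(mn, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    row <- model$reactions[i, ]
    rn <- xml2::xml_add_child(
      lr, "reaction", id = row$id, name = row$name,
      reversible = if (row$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = paste0(row$id, "_lower"),
      "fbc:upperFluxBound" = paste0(row$id, "_upper"))
    s <- row$stoichiometry[[1]]
    for (side in c(-1, 1)) {
      part <- s[sign(s) == side]
      if (!length(part)) next
      ln <- xml2::xml_add_child(
        rn, if (side < 0) "listOfReactants" else "listOfProducts")
      for (k in seq_along(part)) {
        xml2::xml_add_child(ln, "speciesReference",
                            species = names(part)[k],
                            stoichiometry = num2chr(abs(part[[k]])),
                            constant = "true")
      }
    }
    if (nzchar(row$gene_rule)) {
      gpa <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      rule_to_gpa(gpa, parse_rule(row$gene_rule))
    }
  }

  if (!is.na(model$objective)) {
    lo <- xml2::xml_add_child(mn, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lf, "fbc:fluxObjective",
                        "fbc:reaction" = model$objective,
                        "fbc:coefficient" = "1")
  }

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mn, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
                          "fbc:id" = paste0("G_", gsub("\\W", "_", g)),
                          "fbc:label" = g)
    }
  }

  tryCatch(xml2::write_xml(doc, path),
           error = function(e) stop("cannot write '", path, "': ",
                                    conditionMessage(e), call. = FALSE))
  invisible(path)
}

formula_carbon <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NA_real_)
  m <- regmatches(formula, regexec("C([0-9]*)([A-Z]|$)", formula))[[1]]
  if (length(m) == 0) return(0)
  if (!nzchar(m[2])) 1 else as.numeric(m[2])
}

# ---- gene rule <-> fbc geneProductAssociation ------------------------------

# grammar: expr := term ("or" term)* ; term := factor ("and" factor)* ;
# factor := gene | "(" expr ")"
parse_rule <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()\\s]+", rule,
                                    perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  expr <- function() {
    parts <- list(term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); parts <- c(parts, list(term()))
    }
    if (length(parts) == 1) parts[[1]] else list(op = "or", args = parts)
  }
  term <- function() {
    parts <- list(factor_())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); parts <- c(parts, list(factor_()))
    }
    if (length(parts) == 1) parts[[1]] else list(op = "and", args = parts)
  }
  factor_ <- function() {
    t <- take()
    if (is.na(t)) stop("malformed gene rule: '", rule, "'")
    if (t == "(") {
      e <- expr()
      if (!identical(take(), ")")) stop("unbalanced parentheses in gene rule")
      return(e)
    }
    if (t %in% c(")", "and", "or")) stop("malformed gene rule: '", rule, "'")
    list(op = "gene", id = t)
  }
  out <- expr()
  if (!is.na(peek())) stop("trailing tokens in gene rule: '", rule, "'")
  out
}

rule_to_gpa <- function(parent, ast) {
  if (ast$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = paste0("G_", gsub("\\W", "_", ast$id)))
  } else {
    node <- xml2::xml_add_child(parent, paste0("fbc:", ast$op))
    for (a in ast$args) rule_to_gpa(node, a)
  }
  invisible(parent)
}

gpa_to_rule <- function(node, fbc, ns) {
  tag <- xml2::xml_name(node)
  if (tag == "geneProductRef") {
    g <- xml2::xml_attr(node, paste0(fbc, ":geneProduct"), ns)
    return(sub("^G_", "", g))
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, gpa_to_rule, character(1), fbc = fbc, ns = ns)
  wrap <- function(x) ifelse(grepl(" ", x), paste0("(", x, ")"), x)
  if (tag == "and") paste(wrap(parts), collapse = " and ")
  else paste(wrap(parts), collapse = " or ")
}
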