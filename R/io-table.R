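#' Read and write the tabular model dialect
#'
#' The tabular dialect stores a model as two tab-separated files: a reaction
#' table (`id`, `equation`, `lb`, `ub`, `gene_rule`, optionally `name`) and
#' a metabolite table (`id`, `compartment`, `carbon_count`, optionally
#' `name`, `formula`). Equations use `"1 A + 2 B <=> C"` syntax; `<=>`
#' marks a reversible reaction and `-->` an irreversible one. When `lb`/`ub`
#' columns are absent, defaults are `(-1000, 1000)` for reversible and
#' `(0, 1000)` for irreversible reactions.
#'
#' @param reactions_path,metabolites_path Paths to the two TSV files.
#' @param id Model id.
#' @param objective Objective reaction id. If `NULL`, the first reaction id
#'   matching `"biomass"` (case-insensitively) is used, when present.
#' @return A [gem].
#' @export
read_gem_table <- function(reactions_path, metabolites_path,
                           id = "model", objective = NULL) {
  rx <- readr::read_tsv(reactions_path, col_types = readr::cols(),
                        progress = FALSE)
  mets <- readr::read_tsv(metabolites_path, col_types = readr::cols(),
                          progress = FALSE)
  if (!all(c("id", "equation") %in% names(rx))) {
    stop("reaction table needs columns 'id' and 'equation'")
  }
  if (!all(c("id", "compartment") %in% names(mets))) {
    stop("metabolite table needs columns 'id' and 'compartment'")
  }
  parsed <- vector("list", nrow(rx))
  for (i in seq_len(nrow(rx))) {
    parsed[[i]] <- tryCatch(parse_equation(rx$equation[i]), error = function(e) {
      stop("reaction table line ", i + 1L, " (", rx$id[i], "): ",
           conditionMessage(e), call. = FALSE)
    })
  }
  rev <- vapply(parsed, `[[`, logical(1), "reversible")
  lb <- if ("lb" %in% names(rx)) rx$lb else ifelse(rev, -1000, 0)
  ub <- if ("ub" %in% names(rx)) rx$ub else 1000
  lb[is.na(lb)] <- ifelse(rev[is.na(lb)], -1000, 0)
  ub[is.na(ub)] <- 1000
  reactions <- tibble::tibble(
    id = rx$id,
    name = if ("name" %in% names(rx)) rx$name else rx$id,
    stoichiometry = lapply(parsed, `[[`, "stoichiometry"),
    lb = as.numeric(lb), ub = as.numeric(ub),
    gene_rule = if ("gene_rule" %in% names(rx)) {
      ifelse(is.na(rx$gene_rule), "", rx$gene_rule)
    } else ""
  )
  if (is.null(objective)) {
    hit <- grep("biomass", rx$id, ignore.case = TRUE, value = TRUE)
    objective <- if (length(hit)) hit[[1]] else NA_character_
  }
  m <- gem(id, mets, reactions, objective = objective)
  issues <- gem_validate(m)
  if (nrow(issues)) {
    stop("table model fails validation:\n",
         paste(utils::capture.output(print(issues)), collapse = "\n"))
  }
  m
}

#' @rdname read_gem_table
#' @param model A [gem].
#' @param dir Output directory; `<model id>_reactions.tsv` and
#'   `<model id>_metabolites.tsv` are written there.
#' @return `write_gem_table()` invisibly returns the two file paths.
#' @export
write_gem_table <- function(model, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rx <- model$reactions
  rx_out <- tibble::tibble(
    id = rx$id, name = rx$name,
    equation = purrr::map2_chr(rx$stoichiometry, rx$lb,
                               ~format_equation(.x, .y < 0)),
    lb = rx$lb, ub = rx$ub, gene_rule = rx$gene_rule
  )
  paths <- file.path(dir, paste0(model$id, c("_reactions.tsv",
                                             "_metabolites.tsv")))
  readr::write_tsv(rx_out, paths[1])
  readr::write_tsv(model$metabolites, paths[2])
  invisible(paths)
}
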