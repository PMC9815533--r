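#' Screening parameters
#'
#' Parameters of the carbon-source growth screen. Each assessed source is
#' *forced* into the cell: the exchange lower bound is set to
#' `-max_uptake` and the upper bound to `-min_uptake`, so at least
#' `min_uptake` must be taken up and secretion of the source is impossible.
#' Growth is called when the optimized biomass flux strictly exceeds
#' `growth_threshold`. Ion/small-metabolite exchanges are opened to
#' `-free_exchange_bound`.
#'
#' @param max_uptake Maximum forced uptake, mmol/gDW/h (default 20).
#' @param min_uptake Minimum forced uptake, mmol/gDW/h (default 0.1).
#' @param growth_threshold Growth call threshold, 1/h (default 1e-4;
#'   ties at the threshold are no-growth).
#' @param free_exchange_bound Uptake bound for ion exchanges (default 1000).
#' @param ion_exchanges Exchange reaction ids left freely open during the
#'   screen (ions, water, and non-carbon co-substrates such as H2).
#' @return A `screen_params` list.
#' @export
screen_params <- function(max_uptake = 20, min_uptake = 0.1,
                          growth_threshold = 1e-4,
                          free_exchange_bound = 1000,
                          ion_exchanges = character()) {
  stopifnot(min_uptake >= 0, min_uptake <= max_uptake,
            growth_threshold > 0, free_exchange_bound > 0)
  structure(list(max_uptake = max_uptake, min_uptake = min_uptake,
                 growth_threshold = growth_threshold,
                 free_exchange_bound = free_exchange_bound,
                 ion_exchanges = ion_exchanges),
            class = "screen_params")
}

#' Force uptake of one carbon source
#'
#' Sets the exchange bounds of a source to `(-max_uptake, -min_uptake)`:
#' net uptake between the minimum and the maximum, secretion impossible.
#'
#' @param model A [gem].
#' @param exchange_id An exchange reaction id.
#' @param params A [screen_params()].
#' @return The constrained model.
#' @export
set_source_uptake <- function(model, exchange_id, params = screen_params()) {
  i <- rxn_row(model, exchange_id)
  if (!model$reactions$is_exchange[i]) {
    stop("'", exchange_id, "' is not an exchange reaction")
  }
  set_bounds(model, exchange_id, -params$max_uptake, -params$min_uptake)
}

# close uptake through every exchange except the ion list
close_uptake <- function(model, params) {
  ex <- model$reactions$is_exchange
  free <- model$reactions$id %in% params$ion_exchanges
  model$reactions$lb[ex & !free] <- pmax(model$reactions$lb[ex & !free], 0)
  model$reactions$lb[ex & free] <- -params$free_exchange_bound
  model
}

screen_one <- function(base, sources, params) {
  m <- base
  for (s in sources) m <- set_source_uptake(m, s, params)
  sol <- fba(m)
  if (sol$status == "infeasible") {
    list(rate = NA_real_, status = "infeasible")
  } else if (sol$objective_value > params$growth_threshold) {
    list(rate = sol$objective_value, status = "growth")
  } else {
    list(rate = sol$objective_value, status = "no_growth")
  }
}

#' Carbon-source growth screening
#'
#' `screen_single()` assesses growth on each carbon source alone;
#' `screen_pairs()` on every unordered pair of distinct sources. For each
#' condition all non-ion exchanges are first closed to uptake, the
#' source(s) are forced per [set_source_uptake()], and biomass synthesis is
#' maximized. Because every source carries a forced minimum uptake, a pair
#' containing an unusable co-substrate can be infeasible; that is recorded
#' distinctly (`status = "infeasible"`) but counts as no growth.
#'
#' @param model A [gem] with a biomass objective.
#' @param sources Character vector of exchange ids to screen.
#' @param params A [screen_params()].
#' @return A `growth_matrix`: a tibble with columns `source_a`, `source_b`
#'   (`NA` for single-source rows), `rate` and `status`
#'   (`growth` / `no_growth` / `infeasible`). Query it with
#'   [growth_value()]; `autoplot()` draws the Figs-2/3-style lower-triangle
#'   heatmap in which no-growth and infeasible render identically (blank).
#' @export
screen_single <- function(model, sources, params = screen_params()) {
  if (is.na(model$objective)) stop("model has no biomass objective")
  base <- close_uptake(model, params)
  rows <- purrr::map(sources, function(s) {
    r <- screen_one(base, s, params)
    tibble::tibble(source_a = s, source_b = NA_character_,
                   rate = r$rate, status = r$status)
  })
  new_growth_matrix(dplyr::bind_rows(rows), sources, params)
}

#' @rdname screen_single
#' @export
screen_pairs <- function(model, sources, params = screen_params()) {
  if (is.na(model$objective)) stop("model has no biomass objective")
  base <- close_uptake(model, params)
  if (length(sources) < 2) {
    return(new_growth_matrix(
      tibble::tibble(source_a = character(), source_b = character(),
                     rate = numeric(), status = character()),
      sources, params))
  }
  pairs <- utils::combn(sources, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(p) {
    r <- screen_one(base, p, params)
    tibble::tibble(source_a = p[1], source_b = p[2],
                   rate = r$rate, status = r$status)
  })
  new_growth_matrix(dplyr::bind_rows(rows), sources, params)
}

new_growth_matrix <- function(tbl, sources, params) {
  structure(tbl, sources = sources, params = params,
            class = c("growth_matrix", class(tbl)))
}

#' Query a growth matrix
#'
#' Pairs are stored once but can be queried in either order.
#'
#' @param gm A `growth_matrix`.
#' @param a,b Source exchange ids (`b = NULL` for a single-source entry).
#' @return A one-row tibble with `rate` and `status`.
#' @export
growth_value <- function(gm, a, b = NULL) {
  tbl <- tibble::as_tibble(gm)
  hit <- if (is.null(b)) {
    tbl[tbl$source_a == a & is.na(tbl$source_b), ]
  } else {
    tbl[!is.na(tbl$source_b) &
          ((tbl$source_a == a & tbl$source_b == b) |
           (tbl$source_a == b & tbl$source_b == a)), ]
  }
  if (nrow(hit) == 0) stop("no screened condition (", a,
                           if (!is.null(b)) paste0(", ", b), ")")
  hit[, c("rate", "status")]
}

#' @method autoplot growth_matrix
#' @export
autoplot.growth_matrix <- function(object, ...) {
  sources <- attr(object, "sources")
  tbl <- tibble::as_tibble(object)
  tbl$source_b <- ifelse(is.na(tbl$source_b), tbl$source_a, tbl$source_b)
  tbl$fill <- ifelse(tbl$status == "growth", tbl$rate, NA_real_)
  tbl$x <- factor(tbl$source_a, levels = sources)
  tbl$y <- factor(tbl$source_b, levels = rev(sources))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$x, y = .data$y,
                                    fill = .data$fill)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = "growth rate (1/h)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
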