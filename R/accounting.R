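#' Assemble a fed-batch time series
#'
#' Bundles the measured concentration series of a (fed-)batch fermentation
#' with its feed schedule so the carbon bookkeeping operates on amounts
#' (mmol) rather than concentrations: the lactate feed adds volume, so
#' every concentration is multiplied by the reactor volume at its time
#' point.
#'
#' @param concentrations Long-format data frame with columns `time`,
#'   `variable`, `value` (mM). Variables of interest: `lactate`,
#'   `acetate`, `butyrate`, `isobutyrate`.
#' @param feed Data frame with columns `time`, `fed_mmol` (cumulative
#'   lactate fed) and `volume_l` (reactor volume), on the same time grid.
#' @param carbon Named vector of carbon counts per tracked metabolite.
#'   Isobutyrate counts like butyrate (C4).
#' @return A `fedbatch_ts` object.
#' @export
fedbatch_timeseries <- function(concentrations, feed,
                                carbon = c(lactate = 3, acetate = 2,
                                           butyrate = 4, isobutyrate = 4)) {
  conc <- tibble::as_tibble(concentrations)
  feed <- tibble::as_tibble(feed)
  stopifnot(all(c("time", "variable", "value") %in% names(conc)),
            all(c("time", "fed_mmol", "volume_l") %in% names(feed)))
  feed <- dplyr::arrange(feed, .data$time)
  if (any(duplicated(feed$time))) stop("duplicate feed time points")
  if (is.unsorted(feed$time, strictly = TRUE)) {
    stop("time points must be strictly increasing")
  }
  if (any(diff(feed$fed_mmol) < 0)) stop("cumulative fed amount decreases")
  if (any(conc$value < 0, na.rm = TRUE)) stop("negative concentrations")
  if (!all(conc$time %in% feed$time)) {
    stop("every concentration time point needs a feed/volume entry")
  }
  structure(list(conc = conc, feed = feed, carbon = carbon),
            class = "fedbatch_ts")
}

#' @export
print.fedbatch_ts <- function(x, ...) {
  cat(sprintf("<fedbatch_ts> %d time points, variables: %s\n",
              nrow(x$feed), paste(unique(x$conc$variable), collapse = ", ")))
  invisible(x)
}

ts_amount <- function(ts, variable, t) {
  i <- match(t, ts$feed$time)
  if (is.na(i)) stop("time ", t, " not in the series")
  v <- ts$conc$value[ts$conc$variable == variable & ts$conc$time == t]
  if (length(v) == 0) stop("no '", variable, "' measurement at time ", t)
  v[[1]] * ts$feed$volume_l[i]
}

ts_has <- function(ts, variable) variable %in% ts$conc$variable

#' Lactate converted up to a time point
#'
#' Cumulative lactate fed minus lactate remaining in the reactor
#' (concentration times current volume). Noise can push the remainder
#' above the fed amount; the difference is clipped at zero with a warning.
#'
#' @param ts A [fedbatch_timeseries()].
#' @param t Time point (must be on the series grid).
#' @return Converted lactate, mmol.
#' @export
lactate_converted <- function(ts, t) {
  i <- match(t, ts$feed$time)
  if (is.na(i)) stop("time ", t, " not in the series")
  if (is.na(ts$feed$volume_l[i])) stop("missing volume at time ", t)
  remaining <- ts_amount(ts, "lactate", t)
  conv <- ts$feed$fed_mmol[i] - remaining
  if (conv < 0) {
    warning("lactate remaining exceeds lactate fed at t = ", t,
            " (measurement noise?); clipping to 0")
    conv <- 0
  }
  conv
}

#' Theoretical acetate produced from CO2
#'
#' Implements the fed-batch carbon bookkeeping: lactate oxidation via
#' pyruvate yields acetyl-CoA and CO2 1:1, so of every 3 lactate carbons
#' only 2 can end up in products. Product carbon beyond that share must
#' come from another source, i.e. from co-assimilated acetate
#' (`acetate_converted`); adding it back to the acetate measured in the
#' broth gives the theoretical amount of acetate produced from CO2 by the
#' acetogen.
#'
#' @param ts A [fedbatch_timeseries()] with lactate, acetate, butyrate and
#'   isobutyrate series (a missing isobutyrate series raises an error; use
#'   zero values for none detected).
#' @param t Time point.
#' @param subtract_baseline If `TRUE`, the acetate amount already present
#'   at the first time point is removed from `acetate_from_co2`.
#' @return One-row tibble: `time`, `lactate_converted`,
#'   `butyrate_produced`, `isobutyrate_produced`, `acetate_converted`,
#'   `acetate_from_co2` (all mmol).
#' @export
theoretical_acetate <- function(ts, t, subtract_baseline = FALSE) {
  for (v in c("lactate", "acetate", "butyrate", "isobutyrate")) {
    if (!ts_has(ts, v)) stop("missing series: '", v, "'")
  }
  t0 <- ts$feed$time[1]
  lac_conv <- lactate_converted(ts, t)
  but <- ts_amount(ts, "butyrate", t) - ts_amount(ts, "butyrate", t0)
  iso <- ts_amount(ts, "isobutyrate", t) - ts_amount(ts, "isobutyrate", t0)
  clipped <- but < 0 || iso < 0
  but <- max(but, 0)
  iso <- max(iso, 0)
  lactate_c <- 2 * lac_conv           # one of three carbons leaves as CO2
  product_c <- 4 * (but + iso)
  ac_conv <- (product_c - lactate_c) / 2
  if (ac_conv < 0) {
    clipped <- TRUE
    ac_conv <- 0
  }
  if (clipped) {
    warning("negative intermediate quantity at t = ", t,
            " clipped to 0 (measurement noise?)")
  }
  ac_meas <- ts_amount(ts, "acetate", t)
  if (subtract_baseline) ac_meas <- ac_meas - ts_amount(ts, "acetate", t0)
  tibble::tibble(time = t, lactate_converted = lac_conv,
                 butyrate_produced = but, isobutyrate_produced = iso,
                 acetate_converted = ac_conv,
                 acetate_from_co2 = ac_meas + ac_conv)
}

#' Product stoichiometry normalized to lactate
#'
#' Scales the change in (iso)butyrate produced and theoretical acetate
#' converted over an interval to the change in lactate converted, giving
#' coefficients relative to lactate = -1 (positive = produced, negative =
#' consumed). `method = "endpoint"` uses the two interval endpoints (the
#' difference rule used for bioreactor runs); `method = "regression"` fits
#' an origin-constrained least-squares slope through all time points in
#' the interval, which averages measurement noise.
#'
#' @param ts A [fedbatch_timeseries()].
#' @param t_start,t_end Interval endpoints (on the series grid).
#' @param method `"endpoint"` or `"regression"`.
#' @return A `stoich_summary`: tibble with columns `metabolite`,
#'   `coefficient`, rows lactate (-1), acetate, butyrate, isobutyrate.
#' @export
fedbatch_stoichiometry <- function(ts, t_start, t_end,
                                   method = c("endpoint", "regression")) {
  method <- match.arg(method)
  base <- theoretical_acetate(ts, t_start)
  dlac_total <- lactate_converted(ts, t_end) - base$lactate_converted
  if (dlac_total <= 0) {
    stop("no lactate converted between t = ", t_start, " and t = ", t_end)
  }
  if (method == "endpoint") {
    tt <- c(t_end)
  } else {
    tt <- ts$feed$time[ts$feed$time > t_start & ts$feed$time <= t_end]
  }
  rows <- dplyr::bind_rows(lapply(tt, theoretical_acetate, ts = ts))
  dlac <- rows$lactate_converted - base$lactate_converted
  slope <- function(y) {
    if (method == "endpoint") y[length(y)] / dlac[length(dlac)]
    else sum(dlac * y) / sum(dlac * dlac)
  }
  coef_but <- slope(rows$butyrate_produced - base$butyrate_produced)
  coef_iso <- slope(rows$isobutyrate_produced - base$isobutyrate_produced)
  coef_ac <- slope(rows$acetate_converted - base$acetate_converted)
  out <- tibble::tibble(
    metabolite = c("lactate", "acetate", "butyrate", "isobutyrate"),
    coefficient = c(-1, -coef_ac, coef_but, coef_iso))
  structure(out, interval = c(t_start, t_end), method = method,
            class = c("stoich_summary", class(out)))
}

#' Acetate co-assimilation fraction
#'
#' Fraction of the total converted carbon coming from consumed acetate:
#' `2 * acetate / sum(carbon_m * consumed_m)` over all consumed substrates.
#'
#' @param consumed Named vector of consumed amounts (mmol), nonnegative;
#'   must include `acetate`.
#' @param carbon Named carbon counts covering every consumed substrate.
#' @return A fraction in `[0, 1]`.
#' @export
acetate_cofraction <- function(consumed,
                               carbon = c(acetate = 2, lactate = 3,
                                          glycerol = 3, glucose = 6,
                                          ethanol = 2)) {
  if (any(consumed < 0)) stop("consumed amounts must be nonnegative")
  miss <- setdiff(names(consumed), names(carbon))
  if (length(miss)) {
    stop("no carbon count for: ", paste(miss, collapse = ", "))
  }
  total_c <- sum(carbon[names(consumed)] * consumed)
  if (total_c <= 0) stop("zero total converted carbon")
  ac <- if ("acetate" %in% names(consumed)) consumed[["acetate"]] else 0
  2 * ac / total_c
}
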