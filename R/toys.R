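#' Toy solventogen model
#'
#' A desk-scale model of the lactate/acetate-to-butyrate fermentation of a
#' solventogenic *Clostridium*: NAD-independent lactate dehydrogenase,
#' pyruvate:ferredoxin oxidoreductase, ferredoxin hydrogenase, acetate
#' activation (ACK/PTA, run toward acetyl-CoA), the thiolase-to-butyrate
#' kinase chain with the electron-bifurcating butyryl-CoA dehydrogenase
#' (Bcd-EtfAB), the CoA-transferase alternative to Ptb/Buk, the
#' ion-translocating Rnf complex and the ATP synthase, an ATP-maintenance
#' sink, and a biomass reaction drawing acetyl-CoA and ATP. Water and
#' protons are not tracked; exchanged compounds (lactate, acetate,
#' butyrate, CO2, H2) sit in the extracellular compartment and are moved
#' by `EX_*` exchange reactions. Uptake of lactate and acetate is allowed
#' by default; butyrate, CO2 and H2 are secretion-only.
#'
#' Hand-balancing the network gives the two reference conversions used
#' throughout the test suite: at a fixed lactate uptake of 2 (no acetate)
#' the maximal butyrate flux is 1 with CO2 2 and H2 2; at lactate 1 +
#' acetate 1 it is butyrate 1, CO2 1, H2 0. ATP yield per lactate is
#' strictly higher with acetate co-assimilation, which is why the model
#' grows faster on the pair — the mechanistic core of the co-culture
#' design.
#'
#' @param atp_cost ATP consumed per unit biomass (default 2).
#' @param accoa_cost Acetyl-CoA consumed per unit biomass (default 1).
#' @param rnf_ions Ions translocated per ferredoxin oxidized by Rnf
#'   (default 2).
#' @param atpase_ions Ions imported per ATP synthesized (default 3).
#' @return A [gem].
#' @export
toy_solventogen <- function(atp_cost = 2, accoa_cost = 1, rnf_ions = 2,
                            atpase_ions = 3) {
  stopifnot(atp_cost > 0, accoa_cost > 0, rnf_ions > 0, atpase_ions > 0)
  # net ATP from lactate-only catabolism must stay positive:
  # per butyrate, BUK yields 1 ATP and Rnf/ATPase rnf_ions/atpase_ions more
  if (1 + rnf_ions / atpase_ions <= 0) stop("translocation stoichiometry yields no ATP")
  mets <- tibble::tribble(
    ~id, ~compartment, ~carbon_count, ~formula,
    "lac_e", "extracellular", 3, "C3H5O3",
    "ac_e", "extracellular", 2, "C2H3O2",
    "but_e", "extracellular", 4, "C4H7O2",
    "co2_e", "extracellular", 1, "CO2",
    "h2_e", "extracellular", 0, "H2",
    "pyr_c", "cytosol", 3, NA,
    "accoa_c", "cytosol", 2, NA,
    "aacoa_c", "cytosol", 4, NA,
    "hbcoa_c", "cytosol", 4, NA,
    "crtcoa_c", "cytosol", 4, NA,
    "butcoa_c", "cytosol", 4, NA,
    "acp_c", "cytosol", 2, NA,
    "butp_c", "cytosol", 4, NA,
    "nad_c", "cytosol", NA, NA,
    "nadh_c", "cytosol", NA, NA,
    "fdox_c", "cytosol", NA, NA,
    "fdred_c", "cytosol", NA, NA,
    "atp_c", "cytosol", NA, NA,
    "adp_c", "cytosol", NA, NA,
    "pi_c", "cytosol", 0, "HPO4",
    "coa_c", "cytosol", NA, NA,
    "ion_c", "cytosol", 0, "Na",
    "biomass_c", "cytosol", NA, NA)
  rx <- tibble::tribble(
    ~id, ~equation, ~gene_rule,
    "LDH", "lac_e + nad_c --> pyr_c + nadh_c", "ldhA",
    "PFOR", "pyr_c + coa_c + fdox_c --> accoa_c + co2_e + fdred_c", "pfor",
    "HYD", "fdred_c --> fdox_c + h2_e", "hydA",
    "ACK", "ac_e + atp_c --> acp_c + adp_c", "ackA",
    "PTA", "acp_c + coa_c --> accoa_c + pi_c", "pta",
    "THL", "2 accoa_c --> aacoa_c + coa_c", "thlA",
    "HBD", "aacoa_c + nadh_c --> hbcoa_c + nad_c", "hbd",
    "CRT", "hbcoa_c --> crtcoa_c", "crt",
    "BCD", "crtcoa_c + 2 nadh_c + fdox_c --> butcoa_c + 2 nad_c + fdred_c",
      "bcd and etfA and etfB",
    "PTB", "butcoa_c + pi_c --> butp_c + coa_c", "ptb",
    "BUK", "butp_c + adp_c --> but_e + atp_c", "buk",
    "COAT", "butcoa_c + ac_e --> but_e + accoa_c", "ctfA or ctfB",
    "RNF", sprintf("fdred_c + nad_c --> fdox_c + nadh_c + %s ion_c",
                   num2chr(rnf_ions)), "rnfA and rnfB",
    "ATPASE", sprintf("%s ion_c + adp_c + pi_c --> atp_c",
                      num2chr(atpase_ions)), "atpF",
    "ATPM", "atp_c --> adp_c + pi_c", "",
    "BIOMASS", sprintf(
      "%s accoa_c + %s atp_c --> biomass_c + %s coa_c + %s adp_c + %s pi_c",
      num2chr(accoa_cost), num2chr(atp_cost), num2chr(accoa_cost),
      num2chr(atp_cost), num2chr(atp_cost)), "",
    "DM_biomass", "biomass_c -->", "",
    "EX_lac_e", "lac_e <=>", "",
    "EX_ac_e", "ac_e <=>", "",
    "EX_but_e", "but_e -->", "",
    "EX_co2_e", "co2_e -->", "",
    "EX_h2_e", "h2_e -->", "")
  build_toy("toy_solventogen", mets, rx, objective = "BIOMASS")
}

#' Toy acetogen model
#'
#' A lumped Wood-Ljungdahl acetogen: one reaction converts 2 CO2 + 4 H2 +
#' CoA (plus one ATP invested in formate activation) into acetyl-CoA and
#' half a reduced ferredoxin; acetate production by PTA/ACK recovers one
#' ATP, and chemiosmotic energy conservation (Rnf + ATP synthase) turns
#' the ferredoxin into a further third of an ATP, for a net autotrophic
#' yield of 1/3 ATP per acetate — deliberately small, since acetogens at
#' the thermodynamic edge are energy-limited. An ethanol branch reduces
#' acetyl-CoA with 2 H2. CO2 and H2 can be taken up or produced; acetate
#' and ethanol are secretion-only.
#'
#' @inheritParams toy_solventogen
#' @param wlp_atp ATP invested per lumped Wood-Ljungdahl turn (default 1).
#' @param wlp_fdred Reduced ferredoxin released per turn (default 0.5).
#' @return A [gem].
#' @export
toy_acetogen <- function(atp_cost = 2, accoa_cost = 1, rnf_ions = 2,
                         atpase_ions = 3, wlp_atp = 1, wlp_fdred = 0.5) {
  stopifnot(atp_cost > 0, accoa_cost > 0)
  net_atp <- 1 - wlp_atp + wlp_fdred * rnf_ions / atpase_ions
  if (net_atp <= 0) {
    stop("acetate production would not conserve energy (net ATP ",
         num2chr(net_atp), " per acetate)")
  }
  mets <- tibble::tribble(
    ~id, ~compartment, ~carbon_count, ~formula,
    "co2_e", "extracellular", 1, "CO2",
    "h2_e", "extracellular", 0, "H2",
    "ac_e", "extracellular", 2, "C2H3O2",
    "etoh_e", "extracellular", 2, "C2H6O",
    "accoa_c", "cytosol", 2, NA,
    "fdox_c", "cytosol", NA, NA,
    "fdred_c", "cytosol", NA, NA,
    "atp_c", "cytosol", NA, NA,
    "adp_c", "cytosol", NA, NA,
    "pi_c", "cytosol", 0, "HPO4",
    "coa_c", "cytosol", NA, NA,
    "ion_c", "cytosol", 0, "Na",
    "biomass_c", "cytosol", NA, NA)
  rx <- tibble::tribble(
    ~id, ~equation, ~gene_rule,
    "WLP", sprintf(
      "2 co2_e + 4 h2_e + coa_c + %s atp_c + %s fdox_c --> accoa_c + %s adp_c + %s pi_c + %s fdred_c",
      num2chr(wlp_atp), num2chr(wlp_fdred), num2chr(wlp_atp),
      num2chr(wlp_atp), num2chr(wlp_fdred)), "acsA and fhs",
    "ACKPTA", "accoa_c + adp_c + pi_c --> ac_e + atp_c + coa_c", "pta and ackA",
    "ETOH", "accoa_c + 2 h2_e --> etoh_e + coa_c", "adhE",
    "RNF", sprintf("fdred_c --> fdox_c + %s ion_c", num2chr(rnf_ions)),
      "rnfA and rnfB",
    "ATPASE", sprintf("%s ion_c + adp_c + pi_c --> atp_c",
                      num2chr(atpase_ions)), "atpF",
    "ATPM", "atp_c --> adp_c + pi_c", "",
    "BIOMASS", sprintf(
      "%s accoa_c + %s atp_c --> biomass_c + %s coa_c + %s adp_c + %s pi_c",
      num2chr(accoa_cost), num2chr(atp_cost), num2chr(accoa_cost),
      num2chr(atp_cost), num2chr(atp_cost)), "",
    "DM_biomass", "biomass_c -->", "",
    "EX_co2_e", "co2_e <=>", "",
    "EX_h2_e", "h2_e <=>", "",
    "EX_ac_e", "ac_e -->", "",
    "EX_etoh_e", "etoh_e -->", "")
  build_toy("toy_acetogen", mets, rx, objective = "BIOMASS")
}

build_toy <- function(id, mets, rx, objective) {
  parsed <- lapply(rx$equation, parse_equation)
  reactions <- tibble::tibble(
    id = rx$id, name = rx$id,
    stoichiometry = lapply(parsed, `[[`, "stoichiometry"),
    lb = ifelse(vapply(parsed, `[[`, logical(1), "reversible"), -1000, 0),
    ub = 1000,
    gene_rule = rx$gene_rule)
  m <- gem(id, mets, reactions, objective = objective)
  stopifnot(nrow(gem_validate(m)) == 0)
  m
}

#' Namespace map of the toy community
#'
#' Pairs the extracellular metabolites of the toy acetogen (`id_a`) and toy
#' solventogen (`id_b`); shared compounds are acetate, CO2 and H2, while
#' ethanol (acetogen only) and lactate/butyrate (solventogen only) keep
#' stable single-owner names.
#'
#' @return A tibble with columns `id_a`, `id_b`.
#' @export
toy_namespace_map <- function() {
  tibble::tribble(
    ~id_a, ~id_b,
    "ac_e", "ac_e",
    "co2_e", "co2_e",
    "h2_e", "h2_e",
    "etoh_e", NA,
    NA, "lac_e",
    NA, "but_e")
}

#' Toy two-species community model
#'
#' Merges the toy acetogen (species A, suffix `"_ca"`, compartment
#' `cytosol_ca`) and toy solventogen (species B, no suffix, compartment
#' `cytosol`) through [build_community()], sharing acetate, CO2 and H2 in
#' the extracellular compartment. Lactate enters only through the shared
#' extracellular compartment. With `extended = TRUE` the shipped
#' cross-conversion extras recipe (lumped butyrate-to-butanol reduction by
#' the acetogen) is applied on top.
#'
#' @param extended Add the extras recipe (default `FALSE`).
#' @param fractions Community biomass fractions (A, B).
#' @return A `community_gem`.
#' @export
toy_community <- function(extended = FALSE, fractions = c(0.5, 0.5)) {
  a <- species_spec(toy_acetogen(), suffix = "_ca",
                    compartment = "cytosol_ca",
                    biomass_reaction = "BIOMASS",
                    biomass_metabolite = "biomass_c",
                    label = "acetogen")
  b <- species_spec(toy_solventogen(), suffix = "",
                    compartment = "cytosol",
                    biomass_reaction = "BIOMASS",
                    biomass_metabolite = "biomass_c",
                    label = "solventogen")
  extras <- if (extended) syncom_recipe("toy_community_extras") else NULL
  build_community(a, b, toy_namespace_map(), extras = extras,
                  fractions = fractions)
}

#' Synthetic fed-batch time series
#'
#' Generates a fed-batch concentration series from a known conversion
#' stoichiometry (lactate -1, acetate `-acetate_coef`, butyrate
#' `+butyrate_coef`, isobutyrate `+isobutyrate_coef`) under a continuous
#' lactate feed, with optional multiplicative measurement noise — the
#' ground-truth test bed for the carbon bookkeeping. Acetate in the broth
#' is produced continuously (emulating the acetogen) at
#' `acetate_production_factor` times its consumption rate, so it
#' accumulates as in the real runs. Carbon feasibility requires
#' `butyrate_coef + isobutyrate_coef <= (1 + acetate_coef) / 2`; the
#' bookkeeping recovers the acetate coefficient exactly when this holds
#' with equality (all transferable carbon in products), which the defaults
#' (0.4 acetate, 0.7 butyrate — the measured regime of the lactate/acetate
#' fermentation) do.
#'
#' @param acetate_coef,butyrate_coef,isobutyrate_coef True stoichiometric
#'   coefficients per lactate converted.
#' @param feed_rate_ml_d Lactate feed rate (default 3 ml/d).
#' @param feed_conc_mM Feed stock concentration (default 2500 mM).
#' @param volume0_l Initial reactor volume (default 2 l).
#' @param acetate0_mM Acetate present at feed start (default 34 mM).
#' @param duration_d,interval_d Duration and sampling interval in days
#'   (defaults 19 and 1: 20 time points).
#' @param residual_fraction Fraction of fed lactate left unconverted
#'   (default 0.02).
#' @param acetate_production_factor Acetate production/consumption ratio
#'   (default 1.5; must be >= 1 to avoid acetate depletion).
#' @param noise_sd Multiplicative measurement noise standard deviation
#'   (0 = noise-free).
#' @param seed Seed for the noise draws.
#' @return A [fedbatch_timeseries()] whose `"truth"` attribute records the
#'   generating coefficients.
#' @export
synthetic_fedbatch <- function(acetate_coef = 0.4, butyrate_coef = 0.7,
                               isobutyrate_coef = 0, feed_rate_ml_d = 3,
                               feed_conc_mM = 2500, volume0_l = 2,
                               acetate0_mM = 34, duration_d = 19,
                               interval_d = 1, residual_fraction = 0.02,
                               acetate_production_factor = 1.5,
                               noise_sd = 0, seed = NULL) {
  a <- acetate_coef; b <- butyrate_coef; i <- isobutyrate_coef
  stopifnot(a > 0, b > 0, i >= 0, noise_sd >= 0,
            residual_fraction >= 0, residual_fraction < 1,
            acetate_production_factor >= 1)
  if (b + i > (1 + a) / 2 + 1e-12) {
    stop("carbon-infeasible stoichiometry: butyrate + isobutyrate (",
         num2chr(b + i), ") exceeds (1 + acetate)/2 = ", num2chr((1 + a) / 2))
  }
  times <- seq(0, duration_d, by = interval_d)
  fed <- feed_rate_ml_d / 1000 * feed_conc_mM * times        # mmol
  vol <- volume0_l + feed_rate_ml_d / 1000 * times           # l
  lconv <- (1 - residual_fraction) * fed
  amounts <- list(
    lactate = residual_fraction * fed,
    acetate = acetate0_mM * volume0_l +
      (acetate_production_factor - 1) * a * lconv,
    butyrate = b * lconv,
    isobutyrate = i * lconv)
  noisy <- function(x) {
    if (noise_sd == 0) return(x)
    pmax(x * (1 + noise_sd * stats::rnorm(length(x))), 0)
  }
  gen <- function() {
    conc <- dplyr::bind_rows(lapply(names(amounts), function(v) {
      tibble::tibble(time = times, variable = v,
                     value = noisy(amounts[[v]] / vol))
    }))
    fedbatch_timeseries(conc,
                        tibble::tibble(time = times, fed_mmol = fed,
                                       volume_l = vol))
  }
  ts <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(ts, "truth") <- c(lactate = -1, acetate = -a, butyrate = b,
                         isobutyrate = i)
  ts
}
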