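# Shared fixtures, built in code.

# minimal linear chain: substrate in -> product out, one conversion
chain_gem <- function(lb_in = -10) {
  gem(
    id = "chain",
    metabolites = tibble::tibble(
      id = c("a_e", "b_e"), compartment = "extracellular",
      carbon_count = c(1, 1)),
    reactions = tibble::tibble(
      id = c("EX_a_e", "CONV", "EX_b_e"),
      stoichiometry = list(c(a_e = -1), c(a_e = -1, b_e = 1), c(b_e = -1)),
      lb = c(lb_in, 0, 0), ub = c(0, 1000, 1000)),
    objective = "EX_b_e")
}

# 1-D flux polytope: one free flux on [0, 1]
unit_interval_gem <- function() {
  gem(
    id = "interval",
    metabolites = tibble::tibble(id = "a_e", compartment = "extracellular",
                                 carbon_count = 1),
    reactions = tibble::tibble(
      id = c("EX_in", "EX_out"),
      stoichiometry = list(c(a_e = 1), c(a_e = -1)),
      lb = c(0, 0), ub = c(1, 1000),
      is_exchange = c(TRUE, TRUE)),
    objective = "EX_out")
}

# mock fragment of the pre-curation C. beijerinckii model: carries the
# reactions the iCM943 recipe removes/replaces plus their metabolites
mock_icm925 <- function() {
  mets <- tibble::tibble(
    id = c("fdxrd", "fdxox", "nad", "nadh", "nadp", "nadph", "na1",
           "atp", "adp", "pi", "h2", "h2o", "n2", "nh3",
           "na1_e", "h2_e"),
    compartment = c(rep("cytosol", 14), "extracellular", "extracellular"))
  rx <- tibble::tibble(
    id = c("FDXNRx", "FDXNRy", "Habc", "DNOR", "HYD", "EX_h2_e"),
    stoichiometry = list(
      c(fdxrd = -1, nad = -1, fdxox = 1, nadh = 1),
      c(fdxrd = -1, nadp = -1, fdxox = 1, nadph = 1),
      c(h2 = -1, atp = -1, h2o = -1, h2_e = 1, adp = 1, pi = 1),
      # deliberately unbalanced, as in the published model
      c(n2 = -1, fdxrd = -6, atp = -10, nh3 = 2, fdxox = 6, adp = 10,
        pi = 10),
      c(fdxrd = -1, fdxox = 1, h2 = 1),
      c(h2_e = -1)),
    lb = c(0, 0, 0, 0, 0, 0), ub = 1000)
  gem("mock_icm925", mets, rx)
}

# mock fragment of the pre-curation C. acetobutylicum model
mock_icac802 <- function() {
  mets <- tibble::tibble(
    id = c("dpg13", "pg3", "atp", "adp", "fdxrd", "fdxox", "h2", "for",
           "nad", "nadh", "co2", "etoh", "h", "glyc", "pyr",
           "etoh_e", "h_e"),
    compartment = c(rep("cytosol", 15), "extracellular", "extracellular"))
  rx <- tibble::tibble(
    id = c("R0239", "R1563", "R1562", "R1708", "EX_ETOH_e"),
    stoichiometry = list(
      c(pg3 = -1, atp = -1, dpg13 = 1, adp = 1),
      c(fdxrd = -1, fdxox = 1, h2 = 1),
      c(`for` = -1, nad = -1, co2 = 1, nadh = 1),
      c(etoh = -1, h_e = -1, etoh_e = 1, h = 1),
      c(etoh_e = -1)),
    lb = c(0, 0, 0, 0, 0), ub = 1000)
  gem("mock_icac802", mets, rx)
}

toy_feeds <- function(co2 = 5, h2 = 5, lac = 2.5,
                      min_gas = 0.5, min_lac = 0.1) {
  tibble::tibble(
    exchange = c("EX_co2_e", "EX_h2_e", "EX_lac_e"),
    max_uptake = c(co2, h2, lac),
    min_uptake = c(min_gas, min_gas, min_lac))
}

# feeds with zero minima and one limiting gas, giving an interior
# feasibility boundary on the default growth-rate grid
tight_feeds <- function(h2 = 0.08) {
  tibble::tibble(exchange = c("EX_co2_e", "EX_h2_e", "EX_lac_e"),
                 max_uptake = c(100, h2, 100), min_uptake = 0)
}

expect_no_issues <- function(model) {
  expect_equal(nrow(gem_validate(model)), 0)
}

# toy solventogen with lactate/acetate exchange pinned and biomass off
solv_fixed <- function(lac, ac) {
  m <- toy_solventogen()
  m <- set_bounds(m, "EX_lac_e", lac, lac)
  m <- set_bounds(m, "EX_ac_e", ac, ac)
  set_bounds(m, "DM_biomass", 0, 0)
}
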