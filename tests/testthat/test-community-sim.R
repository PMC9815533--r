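test_that("scenario constraints fix biomass fluxes to r * X_total * mu", {
  cm <- toy_community()
  s <- scenario(r = 0.5, mu = 0.02, x_total = 0.22, feeds = toy_feeds())
  m <- apply_scenario(cm, s)
  expect_equal(unname(syncom:::bounds_of(m, "BIOMASS_ca")),
               c(0.0022, 0.0022))
  expect_equal(unname(syncom:::bounds_of(m, "BIOMASS")), c(0.0022, 0.0022))
  # feed bounds in environmental units, negative = uptake
  expect_equal(unname(syncom:::bounds_of(m, "EX_co2_e")), c(-5, -0.5))
  expect_equal(unname(syncom:::bounds_of(m, "EX_lac_e")), c(-2.5, -0.1))
  # community biomass rebuilt with the scenario's fractions
  cb <- m$reactions$stoichiometry[[which(m$reactions$id == "Community_biomass")]]
  expect_equal(unname(cb[c("biomass_c_ca", "biomass_c")]), c(-0.5, -0.5))

  bad <- tibble::tibble(exchange = "LDH", max_uptake = 1, min_uptake = 0)
  expect_error(apply_scenario(cm, scenario(0.5, 0.02, feeds = bad)),
               "not an exchange")
  expect_error(scenario(r = 1, mu = 0.02), "r < 1")
})

test_that("feasibility responds to growth demand and feed supply", {
  cm <- toy_community()
  expect_true(assess_feasibility(cm, scenario(0.5, 0.001,
                                              feeds = toy_feeds())))
  # growth beyond what the limiting H2 feed supports is infeasible
  mu_star <- max_growth(cm, 0.5, tight_feeds())
  expect_true(assess_feasibility(cm, scenario(0.5, mu_star * 0.9,
                                              feeds = tight_feeds())))
  expect_false(assess_feasibility(cm, scenario(0.5, mu_star * 1.1,
                                               feeds = tight_feeds())))
})

test_that("the scan grid matches the oracle within one growth-rate step", {
  cm <- toy_community()
  fm <- feasibility_scan(cm, tight_feeds())
  expect_equal(nrow(fm), 9 * 20)
  expect_equal(sort(unique(fm$r)), seq(0.1, 0.9, by = 0.1))
  expect_equal(sort(unique(fm$mu)), seq(0.005, 0.1, by = 0.005))

  step <- 0.005
  for (r in unique(fm$r)) {
    mu_star <- max_growth(cm, r, tight_feeds())
    cells <- fm[fm$r == r, ]
    expect_true(all(cells$feasible[cells$mu <= mu_star - step]))
    expect_true(all(!cells$feasible[cells$mu >= mu_star + step]))
    # for each ratio the feasible growth rates form one interval from below
    runs <- rle(cells$feasible[order(cells$mu)])$values
    expect_lte(sum(runs), 1)
    if (any(runs)) expect_true(runs[1])
  }
})

test_that("halving the limiting feed halves the maximal growth rate", {
  cm <- toy_community()
  mu1 <- max_growth(cm, 0.5, tight_feeds(h2 = 0.08))
  mu2 <- max_growth(cm, 0.5, tight_feeds(h2 = 0.04))
  expect_equal(mu2 / mu1, 0.5, tolerance = 1e-6)
  # zero feeds with no forced minima support no growth at all
  zero <- tibble::tibble(exchange = c("EX_co2_e", "EX_h2_e", "EX_lac_e"),
                         max_uptake = 0, min_uptake = 0)
  expect_equal(max_growth(cm, 0.5, zero), 0, tolerance = 1e-9)
})

test_that("relaxing feeds never shrinks the feasible set", {
  cm <- toy_community()
  grid_r <- c(0.3, 0.5, 0.7)
  grid_mu <- seq(0.01, 0.1, by = 0.01)
  narrow <- feasibility_scan(cm, tight_feeds(h2 = 0.05),
                             ratio_grid = grid_r, mu_grid = grid_mu)
  wide <- feasibility_scan(cm, tight_feeds(h2 = 0.1),
                           ratio_grid = grid_r, mu_grid = grid_mu)
  expect_true(all(wide$feasible[narrow$feasible]))

  # reducing the lactate cap from 5 to 2.5 never enlarges the set
  lac5 <- toy_feeds(lac = 5)
  lac25 <- toy_feeds(lac = 2.5)
  f5 <- feasibility_scan(cm, lac5, ratio_grid = grid_r, mu_grid = grid_mu)
  f25 <- feasibility_scan(cm, lac25, ratio_grid = grid_r, mu_grid = grid_mu)
  expect_true(all(f5$feasible[f25$feasible]))
})

test_that("sampled summaries show cross-feeding and conserve every shared metabolite", {
  cm <- toy_community()
  s <- scenario(r = 0.5, mu = 0.02, feeds = toy_feeds())
  sm <- summarize_scenario(cm, s, n = 800, seed = 5)
  tbl <- tibble::as_tibble(sm)
  get <- function(met, who) tbl$mean[tbl$metabolite == met & tbl$species == who]

  # acetate flows from the acetogen to the solventogen
  expect_gt(get("ac_e", "acetogen"), 0)
  expect_lt(get("ac_e", "solventogen"), 0)
  expect_equal(get("ac_e", "community"),
               get("ac_e", "acetogen") + get("ac_e", "solventogen"),
               tolerance = 1e-9)

  # gas recycling: the acetogen consumes more CO2/H2 than the community
  # net uptake, because the solventogen produces both
  expect_lt(get("co2_e", "acetogen"), get("co2_e", "community"))
  expect_gt(get("co2_e", "solventogen"), 0)
  expect_lt(get("h2_e", "acetogen"), get("h2_e", "community"))

  # butyrate comes from the solventogen
  expect_gt(get("but_e", "solventogen"), 0)

  # steady-state conservation holds in every sample, not just on average
  expect_lt(attr(sm, "max_conservation_residual"), 1e-7)

  # biomass fluxes are pinned by the scenario: zero spread
  fs <- attr(sm, "sample")
  expect_equal(unname(fs$summary$sd[fs$summary$reaction %in%
                                      c("BIOMASS", "BIOMASS_ca")]), c(0, 0))

  expect_error(summarize_scenario(cm, scenario(0.5, 50, feeds = toy_feeds())),
               "infeasible")
})

test_that("community-level carbon is conserved in every sample", {
  cm <- toy_community()
  s <- scenario(r = 0.5, mu = 0.02, feeds = toy_feeds())
  sm <- summarize_scenario(cm, s, n = 400, seed = 9)
  fs <- attr(sm, "sample")
  v <- fs$samples
  m <- apply_scenario(cm, s)
  carbon <- c(EX_lac_e = 3, EX_ac_e = 2, EX_but_e = 4, EX_co2_e = 1,
              EX_etoh_e_ca = 2)
  # biomass draws 1 acetyl-CoA (2 C) per unit in both toys
  total <- as.vector(v[, names(carbon)] %*% carbon) +
    2 * (v[, "BIOMASS"] + v[, "BIOMASS_ca"])
  expect_lt(max(abs(total)), 1e-7)
})
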