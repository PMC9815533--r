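test_that("toy model composition matches the shipped network definitions", {
  m <- toy_solventogen()
  pathway <- c("LDH", "PFOR", "HYD", "ACK", "PTA", "THL", "HBD", "CRT",
               "BCD", "PTB", "BUK", "COAT", "RNF", "ATPASE")
  expect_true(all(pathway %in% m$reactions$id))
  expect_equal(sum(m$reactions$is_exchange), 5)
  expect_equal(nrow(m$reactions), 22)

  a <- toy_acetogen()
  expect_true(all(c("WLP", "ACKPTA", "ETOH", "RNF", "ATPASE") %in%
                    a$reactions$id))
  expect_equal(nrow(a$reactions), 12)
  expect_error(toy_acetogen(wlp_atp = 2), "conserve energy")
})

test_that("every internal toy reaction is carbon-balanced", {
  skiplist <- c("BIOMASS", "DM_biomass", "BIOMASS_ca", "DM_biomass_ca",
                "Community_biomass")
  for (m in list(toy_solventogen(), toy_acetogen(), toy_community()$model)) {
    ids <- m$reactions$id[!m$reactions$is_exchange]
    for (id in setdiff(ids, skiplist)) {
      expect_equal(carbon_balance(m, id), 0,
                   info = paste(m$id, id))
    }
  }
})

test_that("the acetogen is H2-limited at 4 H2 per acetate", {
  a <- toy_acetogen()
  a1 <- set_bounds(a, "EX_co2_e", -5, 1000)
  a1 <- set_bounds(a1, "EX_h2_e", -10, 1000)
  expect_equal(fba(a1, objective = "EX_ac_e")$objective_value, 2.5,
               tolerance = 1e-7)

  # no electron donor: no acetate and no growth
  a0 <- set_bounds(a, "EX_co2_e", -5, 1000)
  a0 <- set_bounds(a0, "EX_h2_e", 0, 0)
  expect_equal(fba(a0, objective = "EX_ac_e")$objective_value, 0,
               tolerance = 1e-9)
  expect_equal(fba(a0)$objective_value, 0, tolerance = 1e-9)

  # carbon bound: at most half an acetate per CO2, whatever the feeds
  for (feeds in list(c(5, 10), c(2, 100), c(10, 10))) {
    ai <- set_bounds(a, "EX_co2_e", -feeds[1], 1000)
    ai <- set_bounds(ai, "EX_h2_e", -feeds[2], 1000)
    ac <- fba(ai, objective = "EX_ac_e")$objective_value
    expect_lte(ac, 0.5 * feeds[1] + 1e-9)
  }
})

test_that("acetate co-assimilation raises the ATP yield per lactate", {
  m <- set_bounds(toy_solventogen(), "DM_biomass", 0, 0)
  atp_yield <- function(lac, ac) {
    mm <- set_bounds(m, "EX_lac_e", -lac, -lac)
    mm <- set_bounds(mm, "EX_ac_e", -ac, -ac)
    fba(mm, objective = "ATPM")$objective_value / lac
  }
  expect_gt(atp_yield(1, 1), atp_yield(1, 0))
  # hand values: 2 lactate alone yield 1 + 2/3 ATP; with acetate, per
  # lactate one BUK ATP minus one ACK ATP plus 4 ions = 4/3
  expect_equal(atp_yield(2, 0), 5 / 6, tolerance = 1e-7)
  expect_equal(atp_yield(1, 1), 4 / 3, tolerance = 1e-7)
})

test_that("butyrate is made through Ptb/Buk when ATP matters", {
  m <- set_bounds(toy_solventogen(), "EX_lac_e", -20, -0.1)
  m <- set_bounds(m, "EX_ac_e", -20, 0)
  sol <- fba(m)
  # the optimum routes butyrate through the ATP-yielding kinase, not the
  # CoA-transferase
  expect_gt(flux_of(sol, "BUK"), 0)
  expect_equal(flux_of(sol, "COAT"), 0, tolerance = 1e-9)
  # on lactate alone the kinase is the only butyrate (and net ATP) route:
  # knocking it out abolishes growth
  solo <- set_bounds(set_bounds(toy_solventogen(), "EX_lac_e", -20, 0),
                     "EX_ac_e", 0, 0)
  base <- fba(solo)$objective_value
  expect_gt(base, 1e-4)
  ko <- fba(set_bounds(solo, "BUK", 0, 0))$objective_value
  expect_lt(ko, base - 1e-6)
})

test_that("the community needs the acetogen to process the gas feed", {
  cm <- toy_community()
  # without any H2 feed the forced CO2 minimum cannot be fixed
  no_h2 <- tibble::tibble(exchange = c("EX_co2_e", "EX_h2_e", "EX_lac_e"),
                          max_uptake = c(5, 0, 2.5),
                          min_uptake = c(0.5, 0, 0.1))
  expect_false(assess_feasibility(cm, scenario(0.5, 0.01, feeds = no_h2)))
  expect_true(assess_feasibility(cm, scenario(0.5, 0.01,
                                              feeds = toy_feeds())))
})

test_that("synthetic fed-batch series encode their own ground truth", {
  ts <- synthetic_fedbatch()
  truth <- attr(ts, "truth")
  st <- fedbatch_stoichiometry(ts, 0, 19)
  expect_equal(stats::setNames(st$coefficient, st$metabolite),
               truth[c("lactate", "acetate", "butyrate", "isobutyrate")],
               tolerance = 1e-9)

  # schedule invariants
  expect_true(all(diff(ts$feed$fed_mmol) >= 0))
  expect_equal(ts$feed$volume_l, 2 + 3 / 1000 * ts$feed$time)

  # carbon-infeasible truths are rejected
  expect_error(synthetic_fedbatch(acetate_coef = 0.2, butyrate_coef = 0.9),
               "carbon-infeasible")

  # same seed, same noise draw
  a <- synthetic_fedbatch(noise_sd = 0.05, seed = 4)
  b <- synthetic_fedbatch(noise_sd = 0.05, seed = 4)
  expect_identical(a$conc$value, b$conc$value)
})

test_that("noisy recovery stays accurate across seeds", {
  errs <- vapply(1:20, function(seed) {
    ts <- synthetic_fedbatch(noise_sd = 0.05, seed = seed)
    st <- suppressWarnings(
      fedbatch_stoichiometry(ts, 0, 19, method = "regression"))
    truth <- attr(ts, "truth")
    co <- stats::setNames(st$coefficient, st$metabolite)
    mean(abs(co[c("acetate", "butyrate")] -
               truth[c("acetate", "butyrate")]) /
           abs(truth[c("acetate", "butyrate")]))
  }, numeric(1))
  expect_lt(mean(errs), 0.15)
})
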