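test_that("equation strings parse into signed stoichiometries", {
  p <- syncom:::parse_equation("lac_c + nad_c --> pyr_c + nadh_c")
  expect_false(p$reversible)
  expect_equal(p$stoichiometry[c("lac_c", "nad_c", "pyr_c", "nadh_c")],
               c(lac_c = -1, nad_c = -1, pyr_c = 1, nadh_c = 1))

  p2 <- syncom:::parse_equation("2 accoa_c <=> aacoa_c + coa_c")
  expect_true(p2$reversible)
  expect_equal(p2$stoichiometry[["accoa_c"]], -2)

  p3 <- syncom:::parse_equation("lac_e <=>")
  expect_equal(p3$stoichiometry, c(lac_e = -1))

  p4 <- syncom:::parse_equation("0.5 fdox_c + co2_e --> 0.5 fdred_c + x_c")
  expect_equal(p4$stoichiometry[["fdox_c"]], -0.5)

  expect_error(syncom:::parse_equation("a_c + b_c = c_c"), "arrow")
})

test_that("the tabular dialect reads, writes and reports parse errors by line", {
  m <- toy_solventogen()
  d <- withr::local_tempdir()
  paths <- write_gem_table(m, d)
  m2 <- read_gem_table(paths[1], paths[2], id = m$id)
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$ub, m$reactions$ub)
  expect_equal(m2$objective, m$objective)
  for (i in seq_len(nrow(m$reactions))) {
    s1 <- m$reactions$stoichiometry[[i]]
    s2 <- m2$reactions$stoichiometry[[i]]
    expect_equal(s2[sort(names(s2))], s1[sort(names(s1))])
  }

  # malformed equation -> error naming the line
  rx <- readr::read_tsv(paths[1], col_types = readr::cols(), progress = FALSE)
  rx$equation[3] <- "no arrow here"
  bad <- file.path(d, "bad.tsv")
  readr::write_tsv(rx, bad)
  expect_error(read_gem_table(bad, paths[2]), "line 4")
})

test_that("SBML round-trip preserves ids, bounds, coefficients and rules", {
  for (m in list(toy_solventogen(), toy_acetogen())) {
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml(m, f)
    m2 <- read_sbml(f)
    expect_equal(nrow(m2$reactions), nrow(m$reactions))
    expect_equal(nrow(m2$metabolites), nrow(m$metabolites))
    expect_equal(m2$reactions$lb, m$reactions$lb)
    expect_equal(m2$reactions$ub, m$reactions$ub)
    expect_equal(m2$reactions$gene_rule, m$reactions$gene_rule)
    expect_equal(m2$objective, m$objective)
    expect_equal(sort(m2$genes), sort(m$genes))
    for (i in seq_len(nrow(m$reactions))) {
      s1 <- m$reactions$stoichiometry[[i]]
      s2 <- m2$reactions$stoichiometry[[i]]
      expect_equal(s2[sort(names(s2))], s1[sort(names(s1))])
    }
    # carbon counts survive via chemical formulas (0 distinct from unknown)
    expect_equal(m2$metabolites$carbon_count, m$metabolites$carbon_count)
  }
})

test_that("SBML serializes rational coefficients as decimals", {
  m <- toy_acetogen()          # the lumped autotrophic reaction carries 0.5
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  expect_true(any(grepl('stoichiometry="0.5"', readLines(f), fixed = TRUE)))
  # community biomass fractions 0.3/0.7 survive a round-trip exactly
  cm <- toy_community(fractions = c(0.3, 0.7))
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(cm$model, f2)
  s <- read_sbml(f2)$reactions$stoichiometry[[
    which(read_sbml(f2)$reactions$id == "Community_biomass")]]
  expect_equal(unname(s[c("biomass_c_ca", "biomass_c")]), c(-0.3, -0.7))
})

test_that("SBML reader raises format errors naming the offending element", {
  m <- toy_solventogen()
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  txt <- readLines(f)
  # cite an undeclared species in a reaction
  broken <- sub('species="pyr_c"', 'species="ghost_c"', txt)
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(broken, f2)
  expect_error(read_sbml(f2), "ghost_c")

  # strip one reaction's bound references -> error listing the reaction id
  broken2 <- sub(' fbc:lowerFluxBound="LDH_lower" fbc:upperFluxBound="LDH_upper"',
                 "", txt)
  f3 <- withr::local_tempfile(fileext = ".xml")
  writeLines(broken2, f3)
  expect_error(read_sbml(f3), "LDH")
  m3 <- read_sbml(f3, default_bounds = TRUE)
  expect_equal(unname(syncom:::bounds_of(m3, "LDH")), c(0, 1000))

  expect_error(read_sbml(withr::local_tempfile(fileext = ".xml")),
               "no such file")
})

test_that("tabular and SBML round-trips agree with each other", {
  m <- toy_solventogen()
  fx <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, fx)
  d <- withr::local_tempdir()
  paths <- write_gem_table(m, d)
  a <- read_sbml(fx)
  b <- read_gem_table(paths[1], paths[2], id = m$id)
  expect_equal(a$reactions$id, b$reactions$id)
  expect_equal(a$reactions$lb, b$reactions$lb)
  expect_equal(a$reactions$ub, b$reactions$ub)
  for (i in seq_len(nrow(a$reactions))) {
    s1 <- a$reactions$stoichiometry[[i]]
    s2 <- b$reactions$stoichiometry[[i]]
    expect_equal(s2[sort(names(s2))], s1[sort(names(s1))])
  }
})

test_that("validate reports structural violations and is empty when clean", {
  expect_no_issues(toy_solventogen())
  expect_no_issues(toy_community())

  m <- toy_solventogen()
  m$reactions$lb[m$reactions$id == "LDH"] <- 5
  m$reactions$ub[m$reactions$id == "LDH"] <- -5
  rep1 <- gem_validate(m)
  expect_equal(rep1$type, "bound_violation")
  expect_equal(rep1$id, "LDH")

  m2 <- toy_solventogen()
  m2$genes <- setdiff(m2$genes, "buk")        # orphan the BUK rule
  rep2 <- gem_validate(m2)
  expect_equal(rep2$type, "dangling_gene")
  expect_equal(rep2$id, "BUK")

  m3 <- toy_solventogen()
  m3$reactions$is_exchange[m3$reactions$id == "LDH"] <- TRUE
  expect_equal(gem_validate(m3)$type, "exchange_shape")

  expect_error(gem("x",
                   tibble::tibble(id = c("a", "a"), compartment = "c"),
                   toy_solventogen()$reactions[1, ]),
               "duplicate metabolite")
})

test_that("carbon_balance counts carbons and honours the ignore list", {
  m <- toy_solventogen()
  # lactate C3 -> pyruvate C3 + CO2? no: PFOR pyr C3 -> accoa C2 + co2 C1
  expect_equal(carbon_balance(m, "PFOR"), 0)
  expect_equal(carbon_balance(m, "EX_co2_e"), -1)   # exchange, exempt by caller

  broken <- gem(
    "broken",
    tibble::tibble(id = c("lac_c", "ac_c"), compartment = "cytosol",
                   carbon_count = c(3, 2)),
    tibble::tibble(id = "LOSS", stoichiometry = list(c(lac_c = -1, ac_c = 1)),
                   lb = 0, ub = 1000))
  expect_equal(carbon_balance(broken, "LOSS"), -1)

  unk <- gem(
    "unk",
    tibble::tibble(id = c("x_c", "y_c"),
                   compartment = "cytosol", carbon_count = c(2, NA)),
    tibble::tibble(id = "R", stoichiometry = list(c(x_c = -1, y_c = 1)),
                   lb = 0, ub = 1000))
  expect_error(carbon_balance(unk, "R"), "y_c")
})
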