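test_that("species tagging rewrites intracellular ids and keeps shared ones", {
  a <- species_spec(toy_acetogen(), suffix = "_ca",
                    compartment = "cytosol_ca",
                    biomass_reaction = "BIOMASS",
                    biomass_metabolite = "biomass_c", label = "A")
  ta <- tag_species(a, toy_namespace_map(), side = "a")
  expect_true("accoa_c_ca" %in% ta$metabolites$id)
  expect_true("ac_e" %in% ta$metabolites$id)          # mapped: unchanged
  expect_true("BIOMASS_ca" %in% ta$reactions$id)
  expect_true(all(grepl("_ca$", ta$genes)))
  expect_true("cytosol_ca" %in% ta$compartments)

  b <- species_spec(toy_solventogen(), suffix = "",
                    compartment = "cytosol",
                    biomass_reaction = "BIOMASS",
                    biomass_metabolite = "biomass_c", label = "B")
  tb <- tag_species(b, toy_namespace_map(), side = "b")
  expect_equal(tb$reactions$id, toy_solventogen()$reactions$id)

  # a namespace mapping that lands on a tagged intracellular id is caught
  clash <- gem("clash",
               tibble::tibble(id = c("x_c", "ac_e"),
                              compartment = c("cytosol", "extracellular")),
               tibble::tibble(id = "R",
                              stoichiometry = list(c(x_c = -1, ac_e = 1)),
                              lb = 0, ub = 1000))
  cs <- species_spec(add_reaction(clash, "BIO",
                                  c(x_c = -1, biomass_c = 1)),
                     suffix = "_ca", compartment = "cytosol_ca",
                     biomass_reaction = "BIO",
                     biomass_metabolite = "biomass_c")
  bad_map <- tibble::tibble(id_a = "ac_e", id_b = "x_c_ca")
  expect_error(tag_species(cs, bad_map, side = "a"), "duplicate")
})

test_that("merging follows the reaction-count arithmetic and dedups exchanges", {
  n_a <- nrow(toy_acetogen()$reactions)        # 12
  n_b <- nrow(toy_solventogen()$reactions)     # 22
  cm <- toy_community()
  expect_equal(cm$n_shared_exchanges, 3)       # acetate, CO2, H2
  expect_equal(nrow(cm$model$reactions), n_a + n_b - 3 + 1)
  expect_no_issues(cm$model)
  # lactate enters only through the shared extracellular compartment:
  # exactly one lactate exchange, and LDH is the only consumer of lac_e
  expect_equal(sum(grepl("^EX_lac", cm$model$reactions$id)), 1)
  users <- vapply(cm$model$reactions$stoichiometry,
                  function(st) "lac_e" %in% names(st), logical(1))
  expect_setequal(cm$model$reactions$id[users], c("LDH", "EX_lac_e"))

  ext <- toy_community(extended = TRUE)
  expect_equal(nrow(ext$model$reactions), n_a + n_b - 3 + 2 + 1)
  expect_true(all(c("BUTOH_ca", "EX_buoh_e") %in% ext$model$reactions$id))
  expect_no_issues(ext$model)

  # no gene deduplication across species
  expect_equal(length(cm$model$genes),
               length(toy_acetogen()$genes) + length(toy_solventogen()$genes))
})

test_that("an empty namespace map keeps species-private copies and warns", {
  a <- species_spec(toy_acetogen(), "_ca", "cytosol_ca",
                    "BIOMASS", "biomass_c", label = "A")
  b <- species_spec(toy_solventogen(), "", "cytosol",
                    "BIOMASS", "biomass_c", label = "B")
  empty_map <- tibble::tibble(id_a = character(), id_b = character())
  expect_warning(cm <- build_community(a, b, empty_map), "ac_e")
  expect_true(all(c("ac_e", "ac_e_ca") %in% cm$model$metabolites$id))
  expect_equal(cm$n_shared_exchanges, 0)
  expect_no_issues(cm$model)
})

test_that("merge order does not change what the community can do", {
  cm_ab <- toy_community()
  b_first <- species_spec(toy_solventogen(), "_cb", "cytosol_cb",
                          "BIOMASS", "biomass_c", label = "solventogen")
  a_second <- species_spec(toy_acetogen(), "", "cytosol",
                           "BIOMASS", "biomass_c", label = "acetogen")
  map <- toy_namespace_map()
  swapped <- tibble::tibble(id_a = map$id_b, id_b = map$id_a)
  cm_ba <- build_community(b_first, a_second, swapped)
  # species A of cm_ba is the solventogen, so r maps to 1 - r; the
  # lactate exchange carries that species suffix after tagging
  feeds_ba <- toy_feeds()
  feeds_ba$exchange[feeds_ba$exchange == "EX_lac_e"] <- "EX_lac_e_cb"
  expect_equal(max_growth(cm_ab, 0.4, toy_feeds()),
               max_growth(cm_ba, 0.6, feeds_ba), tolerance = 1e-6)
})

test_that("species only exchange metabolites through the extracellular space", {
  cm <- toy_community()
  m <- cm$model
  cyt <- setdiff(m$compartments, "extracellular")
  for (i in seq_len(nrow(m$reactions))) {
    if (m$reactions$id[i] == "Community_biomass") next
    comps <- unique(m$metabolites$compartment[
      match(names(m$reactions$stoichiometry[[i]]), m$metabolites$id)])
    expect_lte(length(intersect(comps, cyt)), 1)
  }
  # the community biomass reaction is the one sanctioned bridge
  cb <- m$reactions$stoichiometry[[which(m$reactions$id == "Community_biomass")]]
  expect_setequal(names(cb), c("biomass_c_ca", "biomass_c"))
})

test_that("community biomass fractions are validated and encoded as coefficients", {
  cm <- toy_community()
  cm5 <- add_community_biomass(cm, c(0.5, 0.5))
  s <- cm5$model$reactions$stoichiometry[[
    which(cm5$model$reactions$id == "Community_biomass")]]
  expect_equal(unname(s[c("biomass_c_ca", "biomass_c")]), c(-0.5, -0.5))

  cm10 <- add_community_biomass(cm, c(1, 0))
  s10 <- cm10$model$reactions$stoichiometry[[
    which(cm10$model$reactions$id == "Community_biomass")]]
  expect_equal(s10, c(biomass_c_ca = -1))

  expect_error(add_community_biomass(cm, c(0.6, 0.6)), "sum to 1")
  expect_error(add_community_biomass(cm, c(-0.2, 1.2)), "nonnegative")
})
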