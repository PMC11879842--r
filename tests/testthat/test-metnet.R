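test_that("constructors enforce their invariants", {
  expect_error(metabolite(""), "nonempty")
  expect_error(reaction("r", c(a = 1), 5, 1), "lower_bound")
  expect_error(reaction("ex", c(a = -1, b = 1), is_exchange = TRUE),
               "exactly one")
  mets <- list(metabolite("a"), metabolite("b"))
  expect_error(stoichiometric_model(mets, list(reaction("r", c(zz = 1))),
                                    "r"), "unknown metabolites")
  expect_error(stoichiometric_model(list(metabolite("a"), metabolite("a")),
                                    list(reaction("r", c(a = 1))), "r"),
               "duplicated")
  expect_error(stoichiometric_model(mets, list(reaction("r", c(a = 1))),
                                    "nope"), "biomass")
})

test_that("formula parsing handles multi-letter elements and counts", {
  f <- parse_formula("C10H12N5O13P3")
  expect_equal(f[["C"]], 10)
  expect_equal(f[["P"]], 3)
  expect_equal(parse_formula("H2O")[["O"]], 1)
  expect_equal(parse_formula("CHO2")[["H"]], 1)
  expect_error(parse_formula("C10?"), "cannot parse")
})

test_that("check_balance tallies elements with the products-minus-reactants convention", {
  mets <- list(
    metabolite("atp", formula = "C10H12N5O13P3", charge = -4L),
    metabolite("adp", formula = "C10H12N5O10P2", charge = -3L),
    metabolite("pi", formula = "HO4P", charge = -2L),
    metabolite("h2o", formula = "H2O"),
    metabolite("h", formula = "H", charge = 1L),
    metabolite("x"))
  rxns <- list(
    reaction("hydrolysis", c(atp = -1, h2o = -1, adp = 1, pi = 1, h = 1)),
    reaction("no_water", c(atp = -1, adp = 1, pi = 1)),
    reaction("formless", c(x = -1, atp = 1)),
    reaction("EX_x", c(x = -1), is_exchange = TRUE))
  m <- stoichiometric_model(mets, rxns, "hydrolysis")

  rep1 <- check_balance(m, "hydrolysis")
  expect_true(rep1$balanced)
  expect_length(rep1$element_imbalance, 0)

  # dropping the water leaves a one-water deficit on the product side:
  # products minus reactants = H -1 ... plus the missing proton
  rep2 <- check_balance(m, "no_water")
  expect_false(isTRUE(rep2$balanced))
  expect_equal(rep2$element_imbalance[["O"]], 1)   # O: -13 +10+4 = +1
  expect_equal(rep2$element_imbalance[["H"]], 1)
  expect_equal(rep2$charge_imbalance, -1)

  rep3 <- check_balance(m, "formless")
  expect_true(rep3$indeterminate)
  expect_true(is.na(rep3$balanced))

  rep4 <- check_balance(m, "EX_x")
  expect_true(rep4$indeterminate)
  expect_match(rep4$reason, "by design")

  expect_error(check_balance(m, "ghost"), "unknown reaction")
})

test_that("balance_biomass_atp repairs the hydrolysis block at the GAM magnitude", {
  mets <- list(
    metabolite("pyr_c", formula = "C3H3O3", charge = -1L),
    metabolite("atp_c", formula = "C10H12N5O13P3", charge = -4L),
    metabolite("adp_c", formula = "C10H12N5O10P2", charge = -3L),
    metabolite("pi_c", formula = "HO4P", charge = -2L),
    metabolite("h2o_c", formula = "H2O"),
    metabolite("h_c", formula = "H", charge = 1L))
  # biomass missing water and proton on the hydrolysis part
  bad <- stoichiometric_model(
    mets, list(reaction("BIOMASS", c(pyr_c = -2, atp_c = -30, adp_c = 30,
                                     pi_c = 30))), "BIOMASS")
  fixed <- balance_biomass_atp(bad)
  st <- fixed$reactions[["BIOMASS"]]$stoichiometry
  expect_equal(st[["h2o_c"]], -30)   # water consumed in the GAM amount
  expect_equal(st[["h_c"]], 30)      # protons produced in the GAM amount
  expect_equal(st[["atp_c"]], -30)   # GAM magnitude unchanged
  # input untouched
  expect_false("h2o_c" %in% names(bad$reactions[["BIOMASS"]]$stoichiometry))

  # hydrolysis part of the repaired reaction is balanced on its own
  hyd <- stoichiometric_model(
    mets, list(reaction("HYD", st[c("atp_c", "h2o_c", "adp_c", "pi_c",
                                    "h_c")])), "HYD")
  expect_true(check_balance(hyd, "HYD")$balanced)

  # already-balanced reaction comes back unchanged
  again <- balance_biomass_atp(fixed)
  expect_equal(again$reactions[["BIOMASS"]]$stoichiometry,
               fixed$reactions[["BIOMASS"]]$stoichiometry)

  noatp <- stoichiometric_model(mets, list(reaction("BIOMASS",
                                                    c(pyr_c = -1))),
                                "BIOMASS")
  expect_error(balance_biomass_atp(noatp), "ATP/ADP")
})

test_that("every non-exchange core-model reaction is balanced in C/H/N/O/P and charge", {
  aud <- balance_audit(core_for_tests())
  internal <- aud[!aud$indeterminate, ]
  expect_gt(nrow(internal), 10)
  expect_true(all(internal$balanced))
  # exchanges indeterminate by design, never "balanced"
  exch <- aud[startsWith(aud$reaction_id, "EX_"), ]
  expect_true(all(exch$indeterminate))
})
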