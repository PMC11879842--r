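test_that("the rGlyP route nets 2 formate + 1 CO2 with 2 ATP, 2 NADPH, 1 NADH per pyruvate", {
  nc <- net_conversion(bundled_route("RGLYP"))
  t <- nc$tallies
  expect_equal(t$formate_assimilated, 2)
  expect_equal(t$co2_fixed, 1)
  expect_equal(t$atp_cost, 2)
  expect_equal(t$nadph_cost, 2)
  expect_equal(t$nadh_cost, 1)
  expect_equal(t$reaction_count, 6)
  # multipliers agree with the double-precision linear-algebra oracle
  y <- vapply(nc$flux_multipliers, rat_dbl, 0)
  expect_equal(unname(y), unname(oracle_route_multipliers(
    bundled_route("RGLYP"))), tolerance = 1e-10)
  # intermediates eliminated exactly (rational zero, not approximately)
  for (ic in c("thf", "f10thf", "methenylthf", "mlthf", "gly", "ser", "nh4"))
    expect_identical(rat_num(nc$net_stoichiometry[[ic]]), 0)
  expect_identical(rat_dbl(nc$net_stoichiometry[["pyr"]]), 1)
})

test_that("the Calvin route nets 3 CO2 with 7 ATP and 5 NADH per pyruvate", {
  nc <- net_conversion(bundled_route("CBB"))
  t <- nc$tallies
  expect_equal(t$formate_assimilated, 0)
  expect_equal(t$co2_fixed, 3)
  expect_equal(t$atp_cost, 7)
  expect_equal(t$nadh_cost, 5)
  expect_equal(t$nadph_cost, 0)
  expect_equal(t$reaction_count, 16)
  y <- vapply(nc$flux_multipliers, rat_dbl, 0)
  expect_equal(unname(y), unname(oracle_route_multipliers(
    bundled_route("CBB"))), tolerance = 1e-10)
  # the RuBisCO triplet: 3 carboxylations, 5 reductions, 3 kinase steps
  expect_identical(rat_dbl(nc$flux_multipliers[["RBPC"]]), 3)
  expect_identical(rat_dbl(nc$flux_multipliers[["PGK"]]), 5)
  expect_identical(rat_dbl(nc$flux_multipliers[["PRK"]]), 3)
})

test_that("carbon and electron balances close exactly for both routes", {
  for (route in c("RGLYP", "CBB")) {
    nc <- net_conversion(bundled_route(route))
    net <- vapply(nc$net_stoichiometry, rat_dbl, 0)
    db <- compound_db()
    carbon <- 0; electrons <- 0
    for (id in names(net)) {
      f <- parse_formula(db$formula[db$id == id])
      cC <- if ("C" %in% names(f)) f[["C"]] else 0
      carbon <- carbon + net[[id]] * cC
      electrons <- electrons + net[[id]] * electrons_of(id)
    }
    # all carbon entering (formate + CO2) ends in the one pyruvate
    expect_identical(carbon, 0)
    expect_equal(nc$tallies$formate_assimilated + nc$tallies$co2_fixed, 3)
    # degree-of-reduction balance: net electron change is zero
    expect_identical(electrons, 0)
  }
})

test_that("net_conversion matches the oracle on random feasible toy routes", {
  set.seed(11)
  for (k in 1:20) {
    # random linear chain s -> i1 -> ... -> i_L -> pyr with random integer
    # cofactor usage; multipliers must all be 1
    L <- sample(2:5, 1)
    ids <- c("s", paste0("i", seq_len(L)), "pyr")
    rxns <- list()
    for (j in seq_len(L + 1)) {
      st <- stats::setNames(c(-1, 1), ids[c(j, j + 1)])
      extra <- sample(c("atp", "nadh", "nadph"), sample(0:2, 1))
      for (e in extra) st[e] <- sample(c(-2, -1, 1), 1)
      rxns[[j]] <- reaction(paste0("r", j), st)
    }
    rt <- route_definition("toy", rxns, internal_compounds = ids[2:(L + 1)],
                           target = "pyr")
    nc <- net_conversion(rt)
    y <- vapply(nc$flux_multipliers, rat_dbl, 0)
    expect_equal(unname(y), unname(oracle_route_multipliers(rt)),
                 tolerance = 1e-10)
    expect_identical(rat_dbl(nc$net_stoichiometry[["pyr"]]), 1)
  }
})

test_that("total formate demand folds cofactor regeneration in correctly", {
  nc <- net_conversion(bundled_route("RGLYP"))
  # hand arithmetic: 2 assimilated + 1 NADH + 2 NADPH (overhead 1)
  #                  + 2 ATP / 2 ATP-per-NADH = 6
  tot <- total_formate_per_pyruvate(nc, atp_per_nadh = 2)
  expect_identical(rat_dbl(tot), 6)
  # exactness at a fractional P/O: 2/1.5 = 4/3 -> total 19/3
  tot2 <- total_formate_per_pyruvate(nc, atp_per_nadh = 1.5)
  expect_identical(rat_num(tot2), 19)
  expect_identical(rat_den(tot2), 3)
  # a cofactor-free net conversion costs only its assimilated formate
  chain <- route_definition("plain", list(
    reaction("r1", c(s = -1, m = 1)), reaction("r2", c(m = -1, pyr = 1))),
    internal_compounds = "m")
  expect_identical(rat_dbl(total_formate_per_pyruvate(
    net_conversion(chain), 2)), 0)
  # monotonicity: cheaper respiration -> less formate
  tots <- vapply(c(1, 1.5, 2, 3), function(e)
    rat_dbl(total_formate_per_pyruvate(nc, e)), 0)
  expect_true(all(diff(tots) <= 0))
  expect_error(total_formate_per_pyruvate(nc, 0), "> 0")
})

test_that("route comparison favours the rGlyP across realistic P/O ratios", {
  for (e in c(1, 1.5, 2, 3, 10)) {
    tab <- compare_routes(atp_per_nadh = e)
    expect_lt(tab$atp_cost[tab$route == "RGLYP"],
              tab$atp_cost[tab$route == "CBB"])
    expect_lt(tab$formate_total[tab$route == "RGLYP"],
              tab$formate_total[tab$route == "CBB"])
  }
  # a route compared with itself is all-equal
  same <- compare_routes(bundled_route("RGLYP"), bundled_route("RGLYP"))
  expect_equal(same[1, -1], same[2, -1], ignore_attr = TRUE)
  # MDF column merges in when provided
  withmdf <- compare_routes(mdf = route_mdf_comparison())
  expect_true("mdf_kj_mol" %in% names(withmdf))
})

test_that("degenerate routes are rejected", {
  expect_error(route_definition("empty", list(), character(0)),
               "no reactions")
  # an intermediate that is produced but never consumed
  expect_error(route_definition("dead", list(
    reaction("r1", c(s = -1, m = 1)),
    reaction("r2", c(s = -1, pyr = 1))), internal_compounds = "m"),
    "produced and consumed")
  # infeasible elimination: intermediates can only cancel at zero flux,
  # which contradicts making one mole of target
  bad <- route_definition("skew", list(
    reaction("r1", c(s = -1, m = 1, n = 1)),
    reaction("r2", c(m = -1, n = -2, pyr = 1))),
    internal_compounds = c("m", "n"))
  expect_error(net_conversion(bad), "cannot balance")
})
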