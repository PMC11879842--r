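test_that("fully fixed pathways reduce to the negated standard energy", {
  pw <- list(thermo_reaction("r1", c(a = -1, b = 1), -10))
  cons <- conc_constraints(fixed_concentrations = c(a = 1e-3, b = 1e-3))
  res <- compute_mdf(pw, cons)
  expect_equal(res$mdf, 10, tolerance = 1e-9)
  expect_equal(res$limiting_reactions, "r1")
})

test_that("a single dG'0 = 0 step attains the closed form RT*ln(1e4)", {
  pw <- list(thermo_reaction("r1", c(a = -1, b = 1), 0))
  res <- compute_mdf(pw, conc_constraints(fixed_concentrations = numeric(0),
                                          fixed_ratios = NULL))
  RT <- RGAS_KJ * 298.15
  expect_equal(res$mdf, RT * log(1e4), tolerance = 1e-9)
  expect_equal(res$mdf, 22.83, tolerance = 0.005)
  # substrate driven to the top of the box, product to the bottom
  expect_equal(unname(res$optimal_log_concentrations["a"]), log(1e-2),
               tolerance = 1e-7)
  expect_equal(unname(res$optimal_log_concentrations["b"]), log(1e-6),
               tolerance = 1e-7)
})

test_that("the LP optimum matches exhaustive grid search on short chains", {
  # route ends fixed so the exhaustive grid runs over the two shared
  # intermediates at full 0.01 resolution
  cons <- conc_constraints(fixed_concentrations = c(co2 = 3.4e-3,
                                                    c = 1e-4),
                           fixed_ratios = NULL)
  pw <- list(
    thermo_reaction("r1", c(co2 = -1, a = 1), 8),
    thermo_reaction("r2", c(a = -1, b = 1), -2),
    thermo_reaction("r3", c(b = -1, c = 1), 5))
  got <- compute_mdf(pw, cons)
  want <- oracle_mdf_grid(pw, cons, step = 0.01)
  expect_equal(got$mdf, want, tolerance = 0.03)
  # reported driving forces recomputed from the optimal concentrations
  expect_true(all(got$per_reaction_driving_force >= got$mdf - 1e-6))
  expect_true(any(abs(got$per_reaction_driving_force - got$mdf) <= 1e-6))

  # with a ratio constraint (4 reactions, shared cofactor couple); the
  # terminal product is fixed too so the grid stays two-dimensional
  cons2 <- conc_constraints(fixed_concentrations = c(co2 = 3.4e-3,
                                                     c = 1e-4, d = 1e-4),
                            fixed_ratios = data.frame(
                              numerator = "nadh", denominator = "nad",
                              ratio = 0.1))
  pw2 <- c(pw, list(thermo_reaction("r4", c(c = -1, nadh = -1, d = 1,
                                            nad = 1), 12)))
  got2 <- compute_mdf(pw2, cons2)
  # grid oracle with the ratio folded into dG'0: the -1 nadh / +1 nad pair
  # contributes -RT*ln(nadh/nad) = -RT*ln(0.1)
  pw2sub <- c(pw, list(thermo_reaction(
    "r4", c(c = -1, d = 1), 12 - RGAS_KJ * 298.15 * log(0.1))))
  want2 <- oracle_mdf_grid(pw2sub, cons2, step = 0.01)
  expect_equal(got2$mdf, want2, tolerance = 0.03)
})

test_that("relaxing concentration constraints never lowers the MDF", {
  base <- conc_constraints()
  wide <- conc_constraints(default_range = c(1e-7, 1e-1))
  no_ratio <- conc_constraints(fixed_ratios = NULL)
  for (route in c("rglyp", "cbb")) {
    pw <- read_dg0_table(system.file(
      "extdata", paste0("mdf_", route, "_dg0.tsv"), package = "formayield"))
    b0 <- compute_mdf(pw, base)$mdf
    expect_gte(compute_mdf(pw, wide)$mdf, b0 - 1e-9)
    expect_gte(compute_mdf(pw, no_ratio)$mdf, b0 - 1e-9)
  }
})

test_that("reversal symmetry of the driving-force program", {
  cons <- conc_constraints(fixed_concentrations = numeric(0),
                           fixed_ratios = NULL)
  # an isoenergetic uni-uni chain reads the same forwards and backwards,
  # so reversing every reaction (with its negated dG'0) preserves B
  pw0 <- list(thermo_reaction("r1", c(a = -1, b = 1), 0),
              thermo_reaction("r2", c(b = -1, c = 1), 0))
  mirror0 <- lapply(pw0, function(r)
    thermo_reaction(r$id, -r$stoichiometry, -r$dg0_prime))
  expect_equal(compute_mdf(pw0, cons)$mdf, compute_mdf(mirror0, cons)$mdf,
               tolerance = 1e-9)
  # with a nonzero dG'0 the forward and reverse optima instead pair up
  # around the concentration-window term: B_fwd + B_rev = 2 RT ln(hi/lo)
  RT <- RGAS_KJ * 298.15
  pw1 <- list(thermo_reaction("r1", c(a = -1, b = 1), -4))
  rev1 <- list(thermo_reaction("r1", c(a = 1, b = -1), 4))
  expect_equal(compute_mdf(pw1, cons)$mdf + compute_mdf(rev1, cons)$mdf,
               2 * RT * log(1e4), tolerance = 1e-9)
})

test_that("both bundled routes give finite MDF values and named bottlenecks", {
  res <- route_mdf_comparison()
  expect_true(is.finite(res$rglyp$mdf))
  expect_true(is.finite(res$cbb$mdf))
  expect_gt(length(res$rglyp$limiting_reactions), 0)
  expect_gt(length(res$cbb$limiting_reactions), 0)
  expect_equal(res$table$mdf_kj_mol, c(res$rglyp$mdf, res$cbb$mdf))
  # per-reaction driving forces respect the max-min property
  for (r in list(res$rglyp, res$cbb))
    expect_true(all(r$per_reaction_driving_force >= r$mdf - 1e-6))
})

test_that("degenerate inputs are rejected", {
  expect_error(compute_mdf(list()), "empty pathway")
  expect_error(conc_constraints(default_range = c(1e-2, 1e-6)), "lower")
  expect_error(conc_constraints(fixed_ratios = data.frame(
    numerator = "a", denominator = "b", ratio = -1)), "positive")
})

test_that("Henry's law gives the comparison CO2 concentration", {
  expect_equal(round(dissolved_co2(0.10, 298.15, 1) * 1000, 1), 3.4)
  expect_equal(dissolved_co2(0, 298.15, 1), 0)
  # pure CO2 at 25 C equals the tabulated solubility within 2 percent
  expect_equal(dissolved_co2(1, 298.15, 1), 0.034, tolerance = 0.02)
  # warmer water dissolves less
  expect_lt(dissolved_co2(0.1, 303.15, 1), dissolved_co2(0.1, 298.15, 1))
  expect_error(dissolved_co2(-0.1), "in \\[0, 1\\]")
})
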