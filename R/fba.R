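#' Define a flux balance analysis problem
#'
#' FBA optimises `c'v` subject to steady state `S v = 0` and flux bounds.
#' Maintenance energetics enter in two places: non-growth-associated
#' maintenance (NGAM, mmol ATP gCDW^-1 h^-1) is a fixed flux through the
#' ATP-maintenance reaction, and growth-associated maintenance (GAM,
#' mmol ATP gCDW^-1) lives inside the biomass reaction's ATP-hydrolysis
#' coefficient, rewritten here so sweeps over GAM are possible.
#'
#' @param model a [stoichiometric_model()].
#' @param objective_reaction_id reaction whose flux is optimised; defaults
#'   to the model's objective/biomass reaction.
#' @param objective_sense `"maximize"` or `"minimize"`.
#' @param fixed_fluxes named numeric vector of reaction fluxes to pin
#'   (lower = upper = value).
#' @param growth_rate optional growth rate mu (h^-1) to fix on the biomass
#'   reaction.
#' @param gam optional GAM to write into the biomass ATP-hydrolysis block
#'   (`NULL` keeps the model's value).
#' @param ngam optional NGAM fixed through `atpm_id` (`NULL` leaves bounds).
#' @param atpm_id id of the ATP maintenance reaction.
#' @param id_map canonical-name mapping for the ATP-hydrolysis species (see
#'   [balance_biomass_atp()]).
#' @return an `fba_problem`.
#' @export
fba_problem <- function(model, objective_reaction_id = NULL,
                        objective_sense = c("maximize", "minimize"),
                        fixed_fluxes = NULL, growth_rate = NULL,
                        gam = NULL, ngam = NULL, atpm_id = "ATPM",
                        id_map = default_id_map()) {
  objective_sense <- match.arg(objective_sense)
  if (is.null(objective_reaction_id))
    objective_reaction_id <- model$objective_reaction_id
  if (!objective_reaction_id %in% names(model$reactions))
    stop("objective reaction '", objective_reaction_id, "' not in model")
  if (!is.null(growth_rate) && growth_rate < 0) stop("growth_rate must be >= 0")
  if (!is.null(gam) && gam < 0) stop("gam must be >= 0")
  if (!is.null(ngam) && ngam < 0) stop("ngam must be >= 0")
  structure(list(model = model,
                 objective_reaction_id = objective_reaction_id,
                 objective_sense = objective_sense,
                 fixed_fluxes = fixed_fluxes, growth_rate = growth_rate,
                 gam = gam, ngam = ngam, atpm_id = atpm_id,
                 id_map = id_map),
            class = "fba_problem")
}

# rewrite the GAM-sized ATP hydrolysis block of the biomass reaction
.set_biomass_gam <- function(model, gam, id_map = default_id_map()) {
  bid <- model$biomass_reaction_id
  st <- model$reactions[[bid]]$stoichiometry
  m <- function(x) id_map[[x]]
  if (!m("atp") %in% names(st)) {
    if (gam == 0) return(model)   # maintenance-free toy models
    stop("biomass reaction has no ATP term (per id_map); cannot set GAM")
  }
  old <- -st[[m("atp")]]
  delta <- gam - old
  for (nm in c("atp", "h2o")) {
    id <- m(nm)
    st[id] <- (if (id %in% names(st)) st[[id]] else 0) - delta
  }
  for (nm in c("adp", "pi", "h")) {
    id <- m(nm)
    st[id] <- (if (id %in% names(st)) st[[id]] else 0) + delta
  }
  st <- st[abs(st) > 1e-12]
  model$reactions[[bid]]$stoichiometry <- st
  model
}

#' Solve a flux balance analysis problem
#'
#' @param problem an [fba_problem()].
#' @return a `flux_solution`: `status` (`"optimal"`, `"infeasible"`,
#'   `"unbounded"`), `objective_value`, `fluxes` (named vector). For optimal
#'   solutions `S v = 0` holds to 1e-6 and all bounds are respected; only
#'   the objective value is unique when alternative optima exist.
#' @export
solve_fba <- function(problem) {
  stopifnot(inherits(problem, "fba_problem"))
  model <- problem$model
  if (!is.null(problem$gam))
    model <- .set_biomass_gam(model, problem$gam, problem$id_map)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")
  rids <- names(model$reactions)
  pin <- function(id, v) {
    if (!id %in% rids) stop("reaction '", id, "' not in model")
    lb[id] <<- v; ub[id] <<- v
  }
  if (!is.null(problem$ngam)) {
    if (problem$atpm_id %in% rids) pin(problem$atpm_id, problem$ngam)
    else if (problem$ngam != 0)
      stop("no maintenance reaction '", problem$atpm_id,
           "' to carry NGAM = ", problem$ngam)
  }
  if (!is.null(problem$growth_rate))
    pin(model$biomass_reaction_id, problem$growth_rate)
  if (!is.null(problem$fixed_fluxes))
    for (id in names(problem$fixed_fluxes)) pin(id, problem$fixed_fluxes[[id]])
  S <- stoich_matrix(model)
  obj <- stats::setNames(rep(0, length(rids)), rids)
  obj[problem$objective_reaction_id] <- 1
  # clamp infinities for the bounded solver
  big <- 1e6
  lb2 <- pmax(lb, -big); ub2 <- pmin(ub, big)
  sol <- lp_solve(obj, S, rep(0, nrow(S)), "=", lb2, ub2,
                  maximize = problem$objective_sense == "maximize")
  if (sol$status != "optimal")
    return(structure(list(status = sol$status, objective_value = NA_real_,
                          fluxes = NULL), class = "flux_solution"))
  v <- stats::setNames(sol$x, rids)
  resid <- max(abs(S %*% v))
  if (resid > 1e-6)
    warning("steady-state residual ", signif(resid, 3), " exceeds 1e-6")
  structure(list(status = "optimal", objective_value = sol$objective,
                 fluxes = v, residual = resid), class = "flux_solution")
}

#' Predict biomass yield on formate for a pathway variant
#'
#' Implements the yield protocol: fix the biomass flux to
#' `mu = ln(2) / doubling_time`, set GAM/NGAM, then optimise the formate
#' exchange flux in the direction that minimises uptake magnitude (under
#' the uptake-negative sign convention this is maximisation of
#' `EX_formate_e`). The yield is `Y = 1000 * mu / q` in g CDW per mol
#' formate, with `q` the uptake magnitude in mmol gCDW^-1 h^-1.
#'
#' @param model a [stoichiometric_model()] (wild-type-like base model).
#' @param variant a [variant_spec()], or `"CBB"`/`"RGLYP"` to build one
#'   with default ids, or `NULL` to use the model as-is.
#' @param doubling_time doubling time Td in hours.
#' @param gam growth-associated maintenance, mmol ATP gCDW^-1.
#' @param ngam non-growth-associated maintenance, mmol ATP gCDW^-1 h^-1.
#' @param formate_exchange_id id of the formate exchange reaction.
#' @param atpm_id id of the ATP maintenance reaction.
#' @param id_map canonical-name mapping used for GAM rewriting and for
#'   variant reaction additions.
#' @return a `yield_prediction`: `variant`, `doubling_time`, `growth_rate`,
#'   `formate_uptake` (magnitude q), `yield` (Y).
#' @export
predict_yield <- function(model, variant = NULL, doubling_time = 14,
                          gam = 135, ngam = 3,
                          formate_exchange_id = "EX_formate_e",
                          atpm_id = "ATPM", id_map = default_id_map()) {
  if (doubling_time <= 0) stop("doubling_time must be > 0")
  vname <- "as-is"
  if (is.character(variant)) variant <- variant_spec(variant, id_map = id_map)
  if (!is.null(variant)) {
    model <- apply_variant(model, variant)
    vname <- variant$variant
  }
  if (!formate_exchange_id %in% names(model$reactions))
    stop("formate exchange '", formate_exchange_id, "' not in model")
  mu <- log(2) / doubling_time
  mk <- function(mu) fba_problem(model,
                                 objective_reaction_id = formate_exchange_id,
                                 objective_sense = "maximize",
                                 growth_rate = mu, gam = gam, ngam = ngam,
                                 atpm_id = atpm_id, id_map = id_map)
  sol <- solve_fba(mk(mu))
  if (sol$status != "optimal") {
    # bisection for the largest feasible growth rate, 8 steps
    lo <- 0; hi <- mu
    for (k in seq_len(8)) {
      mid <- (lo + hi) / 2
      if (solve_fba(mk(mid))$status == "optimal") lo <- mid else hi <- mid
    }
    stop("model infeasible at mu = ", signif(mu, 4),
         " h^-1; largest feasible mu found by bisection: ", signif(lo, 4))
  }
  q <- -sol$objective_value
  if (q <= 0) stop("optimal formate flux is non-negative (no uptake); ",
                   "yield undefined")
  structure(list(variant = vname, doubling_time = doubling_time,
                 growth_rate = mu, formate_uptake = q,
                 yield = 1000 * mu / q),
            class = "yield_prediction")
}

#' @export
print.yield_prediction <- function(x, ...) {
  cat(sprintf("yield_prediction [%s]: Td=%g h, mu=%.4f h^-1, q=%.4f mmol/gCDW/h, Y=%.3f g CDW/mol\n",
              x$variant, x$doubling_time, x$growth_rate, x$formate_uptake,
              x$yield))
  invisible(x)
}

#' Yield sensitivity to maintenance parameters
#'
#' One [predict_yield()] per (GAM, NGAM) grid point; failures are recorded
#' per point without aborting the sweep. Yield is non-increasing in either
#' maintenance parameter at fixed doubling time.
#'
#' @inheritParams predict_yield
#' @param gam_grid,ngam_grid numeric vectors of maintenance values.
#' @return data frame with columns `gam`, `ngam`, `variant`,
#'   `growth_rate`, `formate_uptake`, `yield`, `error`.
#' @export
yield_vs_maintenance <- function(model, variant = NULL, doubling_time = 14,
                                 gam_grid = c(0, 67.5, 135),
                                 ngam_grid = c(0, 3),
                                 formate_exchange_id = "EX_formate_e",
                                 atpm_id = "ATPM",
                                 id_map = default_id_map()) {
  if (!length(gam_grid) || !length(ngam_grid)) stop("grids must be nonempty")
  grid <- expand.grid(gam = gam_grid, ngam = ngam_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- tryCatch(
      predict_yield(model, variant, doubling_time, grid$gam[i], grid$ngam[i],
                    formate_exchange_id, atpm_id, id_map),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(gam = grid$gam[i], ngam = grid$ngam[i],
                 variant = NA_character_, growth_rate = NA_real_,
                 formate_uptake = NA_real_, yield = NA_real_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(gam = grid$gam[i], ngam = grid$ngam[i],
                 variant = res$variant, growth_rate = res$growth_rate,
                 formate_uptake = res$formate_uptake, yield = res$yield,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
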