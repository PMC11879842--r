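#' Gas constant, kJ mol^-1 K^-1
#' @export
RGAS_KJ <- 8.31446261815324e-3

#' A reaction with a transformed standard Gibbs energy
#'
#' @param id reaction id.
#' @param stoichiometry named numeric vector, compound id -> signed
#'   coefficient (negative consumed).
#' @param dg0_prime transformed standard reaction Gibbs energy, kJ mol^-1,
#'   at the constraint set's pH/ionic strength/Mg.
#' @return a `thermo_reaction`.
#' @export
thermo_reaction <- function(id, stoichiometry, dg0_prime) {
  if (!length(stoichiometry) || is.null(names(stoichiometry)))
    stop("stoichiometry must be a nonempty named vector")
  if (!is.finite(dg0_prime)) stop("dg0_prime must be finite")
  structure(list(id = id, stoichiometry = stoichiometry,
                 dg0_prime = dg0_prime), class = "thermo_reaction")
}

#' Concentration constraint set for MDF analysis
#'
#' Defaults follow the comparison conditions: metabolite and cofactor
#' concentrations in 1 uM--10 mM, pH 7.5, ionic strength 0.25 M, 1 mM Mg2+,
#' CO2 fixed at its 10 percent-headspace Henry's-law value (3.4 mM) and an
#' NADH/NAD+ ratio of 0.1. Water and protons are excluded from the
#' concentration variables (their contribution is inside dG'0).
#'
#' @param default_range length-2 numeric, molar concentration box applied
#'   to every free compound.
#' @param fixed_concentrations named numeric vector (molar); fixed
#'   compounds are exempt from the box.
#' @param fixed_ratios data frame with columns `numerator`, `denominator`,
#'   `ratio`; each becomes an exact equality on log-concentrations.
#' @param temperature K (RT uses this).
#' @param ph,ionic_strength,mg_conc conditions at which the dG'0 values are
#'   stated (metadata; they do not enter the LP).
#' @param exclude compound ids never given a concentration variable.
#' @return a `conc_constraints` object.
#' @export
conc_constraints <- function(default_range = c(1e-6, 1e-2),
                             fixed_concentrations = c(co2 = 3.4e-3),
                             fixed_ratios = data.frame(
                               numerator = "nadh", denominator = "nad",
                               ratio = 0.1),
                             temperature = 298.15, ph = 7.5,
                             ionic_strength = 0.25, mg_conc = 1e-3,
                             exclude = c("h2o", "h")) {
  if (any(default_range <= 0) || default_range[1] > default_range[2])
    stop("default_range must be positive with lower <= upper")
  if (length(fixed_concentrations) && any(fixed_concentrations <= 0))
    stop("fixed concentrations must be positive")
  if (!is.null(fixed_ratios) && nrow(fixed_ratios) &&
      any(fixed_ratios$ratio <= 0))
    stop("ratios must be positive")
  structure(list(default_range = default_range,
                 fixed_concentrations = fixed_concentrations,
                 fixed_ratios = fixed_ratios, temperature = temperature,
                 ph = ph, ionic_strength = ionic_strength,
                 mg_conc = mg_conc, exclude = exclude),
            class = "conc_constraints")
}

#' Max-min driving force of a pathway
#'
#' Solves `max B` subject to, for every reaction j,
#' `-(dG'0_j + RT * sum_i s_ij ln c_i) >= B`, with each free `ln c_i` boxed
#' by the constraint set, fixed compounds folded into the constants, and
#' each concentration ratio an exact linear equality on logs.
#'
#' @param pathway list of [thermo_reaction()] objects.
#' @param constraints a [conc_constraints()].
#' @return an `mdf_result`: `mdf` (B, kJ mol^-1),
#'   `optimal_log_concentrations` (ln M, fixed compounds included),
#'   `per_reaction_driving_force`, `limiting_reactions` (ids attaining B).
#' @export
compute_mdf <- function(pathway, constraints = conc_constraints()) {
  if (!length(pathway)) stop("empty pathway")
  stopifnot(inherits(constraints, "conc_constraints"))
  RT <- RGAS_KJ * constraints$temperature
  cpds <- sort(unique(unlist(lapply(pathway, function(r)
    names(r$stoichiometry)))))
  cpds <- setdiff(cpds, constraints$exclude)
  fixed <- constraints$fixed_concentrations
  fixed <- fixed[names(fixed) %in% cpds]
  rng <- constraints$default_range
  free <- setdiff(cpds, names(fixed))
  nf <- length(free)
  nr <- length(pathway)

  # variables: ln c (free compounds), then B
  nv <- nf + 1L
  lb <- c(rep(log(rng[1]), nf), -1e4)
  ub <- c(rep(log(rng[2]), nf), 1e4)
  obj <- c(rep(0, nf), 1)

  A <- NULL; rhs <- c(); dir <- c()
  for (r in pathway) {
    row <- numeric(nv)
    const <- r$dg0_prime
    for (cid in names(r$stoichiometry)) {
      s <- r$stoichiometry[[cid]]
      if (cid %in% constraints$exclude) next
      if (cid %in% names(fixed)) const <- const + RT * s * log(fixed[[cid]])
      else row[match(cid, free)] <- RT * s
    }
    row[nv] <- 1
    A <- rbind(A, row); rhs <- c(rhs, -const); dir <- c(dir, "<=")
  }
  fr <- constraints$fixed_ratios
  if (!is.null(fr) && nrow(fr)) for (k in seq_len(nrow(fr))) {
    num <- fr$numerator[k]; den <- fr$denominator[k]
    if (!(num %in% cpds) || !(den %in% cpds)) next  # ratio on absent compound
    # ln(num) - ln(den) = ln(ratio), fixed sides folded into the rhs
    row <- numeric(nv)
    rr <- log(fr$ratio[k])
    if (num %in% names(fixed)) rr <- rr - log(fixed[[num]]) else
      row[match(num, free)] <- 1
    if (den %in% names(fixed)) rr <- rr + log(fixed[[den]]) else
      row[match(den, free)] <- -1
    if (!any(row != 0) && abs(rr) > 1e-9)
      stop("fixed concentrations contradict the ", num, "/", den, " ratio")
    A <- rbind(A, row); rhs <- c(rhs, rr); dir <- c(dir, "=")
  }
  # fixed value outside its own (exempted) positivity is impossible; but a
  # fixed compound whose value violates a stated ratio surfaces as LP
  # infeasibility below.
  sol <- lp_solve(obj, A, rhs, dir, lb, ub, maximize = TRUE)
  if (sol$status != "optimal")
    stop("MDF constraint set infeasible (check fixed concentrations ",
         "and ratios)")
  lnc <- stats::setNames(sol$x[seq_len(nf)], free)
  lnc_all <- c(lnc, log(fixed))
  dfs <- vapply(pathway, function(r) {
    s <- r$stoichiometry[!(names(r$stoichiometry) %in% constraints$exclude)]
    -(r$dg0_prime + RT * sum(s * lnc_all[names(s)]))
  }, 0)
  names(dfs) <- vapply(pathway, `[[`, "", "id")
  B <- sol$objective
  structure(list(mdf = B, optimal_log_concentrations = lnc_all,
                 per_reaction_driving_force = dfs,
                 limiting_reactions = names(dfs)[dfs <= B + 1e-6]),
            class = "mdf_result")
}

#' @export
print.mdf_result <- function(x, ...) {
  cat(sprintf("mdf_result: B = %.3f kJ/mol; limiting: %s\n", x$mdf,
              paste(x$limiting_reactions, collapse = ", ")))
  invisible(x)
}

#' Parse a reaction equation string
#'
#' Accepts `"2 a + b = c + 3 d"` (also `"->"` or `"<=>"` as the separator);
#' coefficients may be integers or decimals.
#'
#' @param eq equation string.
#' @return named numeric vector of signed coefficients.
#' @export
parse_equation <- function(eq) {
  sides <- strsplit(eq, "\\s*(<=>|<->|->|=)\\s*")[[1]]
  if (length(sides) != 2) stop("cannot parse equation: ", eq)
  out <- numeric(0)
  for (k in 1:2) {
    sgn <- if (k == 1) -1 else 1
    terms <- strsplit(sides[k], "\\s*\\+\\s*")[[1]]
    for (tm in terms) {
      tm <- trimws(tm)
      if (!nzchar(tm)) next
      mm <- regmatches(tm, regexec("^([0-9.]+\\s+)?(\\S+)$", tm))[[1]]
      if (length(mm) != 3) stop("cannot parse term '", tm, "' in: ", eq)
      coef <- if (nzchar(trimws(mm[2]))) as.numeric(trimws(mm[2])) else 1
      cid <- mm[3]
      out[cid] <- (if (cid %in% names(out)) out[[cid]] else 0) + sgn * coef
    }
  }
  out[abs(out) > 0]
}

#' Load a dG'0 fixture table as a thermo pathway
#'
#' @param path delimited text with columns `reaction_id`, `equation`,
#'   `dg0_prime_kj_mol` (further columns such as `ph`, `ionic_strength_M`,
#'   `mg_M`, `provenance` are carried as attributes).
#' @return list of [thermo_reaction()] objects.
#' @export
read_dg0_table <- function(path) {
  if (!file.exists(path)) stop("no such dG'0 fixture: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("reaction_id", "equation", "dg0_prime_kj_mol")
  if (!all(need %in% names(tab)))
    stop("dG'0 table must have columns ", paste(need, collapse = ", "))
  pw <- lapply(seq_len(nrow(tab)), function(i)
    thermo_reaction(tab$reaction_id[i], parse_equation(tab$equation[i]),
                    tab$dg0_prime_kj_mol[i]))
  attr(pw, "table") <- tab
  pw
}

.route_dg0_path <- function(route) {
  system.file("extdata",
              paste0("mdf_", tolower(route), "_dg0.tsv"),
              package = "formayield", mustWork = TRUE)
}

#' Thermodynamic comparison of the two formate-to-pyruvate routes
#'
#' Loads the bundled (reconstructed) dG'0 tables for the reductive glycine
#' pathway and the Calvin cycle route and computes both MDF values under a
#' shared constraint set. The Calvin-route GAPDH step is NAD+-dependent in
#' the bundled table.
#'
#' @param constraints a [conc_constraints()]; the defaults encode the
#'   comparison conditions (CO2 3.4 mM, NADH/NAD+ = 0.1).
#' @param rglyp_path,cbb_path optional overrides for the fixture tables.
#' @return list with elements `rglyp` and `cbb` (each an `mdf_result`) and
#'   `table`, a per-route summary data frame.
#' @export
route_mdf_comparison <- function(constraints = conc_constraints(),
                                 rglyp_path = .route_dg0_path("rglyp"),
                                 cbb_path = .route_dg0_path("cbb")) {
  res <- list(rglyp = compute_mdf(read_dg0_table(rglyp_path), constraints),
              cbb = compute_mdf(read_dg0_table(cbb_path), constraints))
  res$table <- data.frame(
    route = c("rglyp", "cbb"),
    mdf_kj_mol = c(res$rglyp$mdf, res$cbb$mdf),
    limiting_reactions = c(paste(res$rglyp$limiting_reactions, collapse = ";"),
                           paste(res$cbb$limiting_reactions, collapse = ";")),
    stringsAsFactors = FALSE)
  res
}

#' Henry's-law dissolved CO2 concentration
#'
#' `K_H(T) * fraction * pressure` with a van 't Hoff temperature dependence
#' around the tabulated 25 C solubility of CO2 in water
#' (`K_H(298.15 K) = 0.0340 mol l^-1 atm^-1`, d(ln K_H)/d(1/T) = 2400 K).
#' At 10 percent headspace and 1 atm this gives 3.4 mM at the reference
#' temperature.
#'
#' @param co2_fraction volume fraction of CO2 in the gas phase, 0..1.
#' @param temperature K.
#' @param pressure total pressure, atm.
#' @return dissolved CO2, mol l^-1.
#' @export
dissolved_co2 <- function(co2_fraction, temperature = 298.15, pressure = 1) {
  if (co2_fraction < 0 || co2_fraction > 1)
    stop("co2_fraction must be in [0, 1]")
  if (temperature <= 0 || pressure < 0) stop("negative/zero inputs")
  kh <- 0.0340 * exp(2400 * (1 / temperature - 1 / 298.15))
  kh * co2_fraction * pressure
}
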