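#' Route definition for net-stoichiometry accounting
#'
#' A route is an ordered set of reactions with exact integer/rational
#' stoichiometries, a set of internal intermediates that must cancel, and a
#' target compound (pyruvate). Cofactors (ATP/ADP/Pi, NAD(P)H/NAD(P)+),
#' substrates (formate, CO2) and water/protons stay external so the net
#' conversion exposes their per-pyruvate tallies.
#'
#' @param name route name, `"RGLYP"` or `"CBB"` (free text allowed).
#' @param reactions list of [reaction()] objects (bounds are ignored here;
#'   only stoichiometries matter).
#' @param internal_compounds character vector of compound ids to eliminate.
#' @param target target compound id (default `"pyr"`).
#' @return a `route_definition`.
#' @export
route_definition <- function(name, reactions, internal_compounds,
                             target = "pyr") {
  if (!length(reactions)) stop("route has no reactions")
  if (target %in% internal_compounds) stop("target cannot be internal")
  allc <- unlist(lapply(reactions, function(r) names(r$stoichiometry)))
  for (ic in internal_compounds) {
    prod <- any(vapply(reactions, function(r)
      ic %in% names(r$stoichiometry) && r$stoichiometry[[ic]] > 0, TRUE))
    cons <- any(vapply(reactions, function(r)
      ic %in% names(r$stoichiometry) && r$stoichiometry[[ic]] < 0, TRUE))
    if (!prod || !cons)
      stop("internal compound '", ic,
           "' is not both produced and consumed by the route")
  }
  if (!target %in% allc) stop("target '", target, "' absent from route")
  structure(list(name = name, reactions = reactions,
                 internal_compounds = internal_compounds, target = target),
            class = "route_definition")
}

#' Load a route definition from a delimited reaction table
#'
#' @param path delimited text with columns `id`, `equation`, `label`;
#'   comment lines start with `#`.
#' @param name route name.
#' @param internal_compounds internal intermediate ids; when `NULL`, every
#'   compound except the target and the conventional externals (formate,
#'   CO2, O2, water, protons and the ATP/NAD(P) cofactor pool) is internal.
#' @param target target compound id.
#' @return a [route_definition()].
#' @export
read_route_table <- function(path, name = basename(path),
                             internal_compounds = NULL, target = "pyr") {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "equation") %in% names(tab)))
    stop("route table needs columns id, equation")
  rxns <- lapply(seq_len(nrow(tab)), function(i)
    reaction(tab$id[i], parse_equation(tab$equation[i]),
             lower_bound = 0, upper_bound = 1000,
             label = if ("label" %in% names(tab)) tab$label[i] else ""))
  if (is.null(internal_compounds)) {
    allc <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
    ext <- c("for", "co2", "o2", "h", "h2o", "pi", "atp", "adp",
             "nad", "nadh", "nadp", "nadph", target)
    internal_compounds <- setdiff(allc, ext)
  }
  route_definition(name, rxns, internal_compounds, target)
}

.bundled_route_path <- function(route)
  system.file("extdata", paste0("route_", tolower(route), ".tsv"),
              package = "formayield", mustWork = TRUE)

#' Bundled formate-to-pyruvate route definitions
#'
#' `"RGLYP"`: FtfL/FchA/MtdA C1 activation, reductive glycine cleavage,
#' serine hydroxymethyltransferase and serine deaminase. `"CBB"`: RuBisCO
#' plus phosphoribulokinase with the full reduction/regeneration pentose
#' phosphate scaffold and lower glycolysis to pyruvate.
#'
#' @param route `"RGLYP"` or `"CBB"`.
#' @return a [route_definition()].
#' @export
bundled_route <- function(route = c("RGLYP", "CBB")) {
  route <- match.arg(route)
  internal <- if (route == "RGLYP")
    c("thf", "f10thf", "methenylthf", "mlthf", "gly", "ser", "nh4")
  else
    c("rubp", "pg3", "bpg13", "g3p", "dhap", "fbp", "f6p", "e4p", "sbp",
      "s7p", "r5p", "xu5p", "ru5p", "pg2", "pep")
  read_route_table(.bundled_route_path(route), name = route,
                   internal_compounds = internal)
}

# integer-valued stoichiometry matrix rows = compounds of interest
.route_system <- function(route) {
  rxns <- route$reactions
  cpds <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  S <- matrix(0, length(cpds), length(rxns),
              dimnames = list(cpds, vapply(rxns, `[[`, "", "id")))
  for (j in seq_along(rxns))
    S[names(rxns[[j]]$stoichiometry), j] <- rxns[[j]]$stoichiometry
  S
}

#' Net conversion of a route by exact elimination of intermediates
#'
#' Finds non-negative rational flux multipliers, one per route reaction,
#' that zero every internal compound and produce exactly one mole of the
#' target, then reports the exact net stoichiometry and cofactor tallies.
#' When the elimination system is underdetermined the free multipliers are
#' fixed at zero (deterministic, lexicographic in reaction order), giving
#' the minimal-support solution.
#'
#' @param route a [route_definition()].
#' @return a `net_conversion`: `flux_multipliers` (rational, named),
#'   `net_stoichiometry` (rational, named), and `tallies` with numeric
#'   fields `atp_cost`, `nadph_cost`, `nadh_cost`, `formate_assimilated`,
#'   `co2_fixed`, `reaction_count`, all per mole target.
#' @export
net_conversion <- function(route) {
  stopifnot(inherits(route, "route_definition"))
  S <- .route_system(route)
  if (any(abs(S - round(S)) > 0))
    stop("route stoichiometries must be integer for exact elimination")
  rows <- c(route$internal_compounds, route$target)
  miss <- setdiff(route$internal_compounds, rownames(S))
  if (length(miss)) stop("internal compounds absent from route: ",
                         paste(miss, collapse = ", "))
  M <- S[rows, , drop = FALSE]
  rhs <- c(rep(0, length(route$internal_compounds)), 1)
  gj <- rat_solve_gj(M, matrix(1, nrow(M), ncol(M)),
                     rhs, rep(1, length(rhs)))
  if (!gj$consistent)
    stop("route '", route$name, "' cannot balance its intermediates: ",
         "no flux multipliers zero all internal compounds")
  y <- gj$solution
  if (any(rat_dbl(y) < 0))
    stop("route '", route$name,
         "' requires a negative multiplier; reorient its reactions")
  # verify exactly: M y = rhs in rationals
  for (i in seq_len(nrow(M))) {
    acc <- rational(0)
    for (j in seq_len(ncol(M)))
      acc <- rat_add(acc, rat_mul(rational(M[i, j]), rat_elt(y, j)))
    if (rat_dbl(acc) != rhs[i]) stop("internal error: elimination not exact")
  }
  # exact net stoichiometry over all compounds
  net_n <- numeric(nrow(S)); net_d <- rep(1, nrow(S))
  for (i in seq_len(nrow(S))) {
    acc <- rational(0)
    for (j in seq_len(ncol(S)))
      if (S[i, j] != 0)
        acc <- rat_add(acc, rat_mul(rational(S[i, j]), rat_elt(y, j)))
    net_n[i] <- rat_num(acc); net_d[i] <- rat_den(acc)
  }
  net <- rational(net_n, net_d)
  cn <- rownames(S)
  get <- function(id) {
    k <- match(id, cn)
    if (is.na(k)) 0 else rat_dbl(rat_elt(net, k))
  }
  tal <- list(atp_cost = -get("atp"), nadph_cost = -get("nadph"),
              nadh_cost = -get("nadh"), formate_assimilated = -get("for"),
              co2_fixed = -get("co2"),
              reaction_count = sum(rat_dbl(y) > 0))
  structure(list(route = route$name,
                 flux_multipliers = stats::setNames(
                   lapply(seq_len(ncol(S)), function(j) rat_elt(y, j)),
                   colnames(S)),
                 net_stoichiometry = stats::setNames(
                   lapply(seq_len(nrow(S)), function(i) rat_elt(net, i)), cn),
                 tallies = tal),
            class = "net_conversion")
}

#' @export
print.net_conversion <- function(x, ...) {
  t <- x$tallies
  cat(sprintf(paste0("net_conversion [%s]: per pyruvate %g formate + %g CO2;",
                     " ATP %g, NADPH %g, NADH %g; %d reactions\n"),
              x$route, t$formate_assimilated, t$co2_fixed, t$atp_cost,
              t$nadph_cost, t$nadh_cost, t$reaction_count))
  invisible(x)
}

# small rational from a numeric such as 1.5 or 2
.dbl_to_rat <- function(x, max_den = 1e6) {
  den <- 1
  while (abs(x * den - round(x * den)) > 1e-9) {
    den <- den * 10
    if (den > max_den) stop("parameter not representable as a small rational")
  }
  rational(round(x * den), den)
}

#' Total formate demand per mole pyruvate
#'
#' Adds, to the formate assimilated into carbon, the formate oxidised by
#' formate dehydrogenase to regenerate the route's cofactors: one formate
#' per NADH, `transhydrogenase_overhead` formate per NADPH when NADPH comes
#' from the membrane transhydrogenase (PntAB), and `1/atp_per_nadh` formate
#' per ATP with respiration producing `atp_per_nadh` ATP per NADH.
#'
#' @param net a [net_conversion()].
#' @param atp_per_nadh ATP per NADH from respiration (P/O-like), > 0.
#' @param nadph_source `"transhydrogenase"` (NADH -> NADPH at the stated
#'   overhead) or `"direct"` (an NADP+-coupled formate dehydrogenase, one
#'   formate per NADPH).
#' @param transhydrogenase_overhead formate per NADPH via PntAB (default 1).
#' @return exact rational total (also retrievable as numeric via
#'   [rat_dbl()]).
#' @export
total_formate_per_pyruvate <- function(net, atp_per_nadh = 2,
                                       nadph_source = c("transhydrogenase",
                                                        "direct"),
                                       transhydrogenase_overhead = 1) {
  nadph_source <- match.arg(nadph_source)
  if (atp_per_nadh <= 0) stop("atp_per_nadh must be > 0")
  if (transhydrogenase_overhead <= 0)
    stop("transhydrogenase_overhead must be > 0")
  t <- net$tallies
  ov <- if (nadph_source == "transhydrogenase")
    .dbl_to_rat(transhydrogenase_overhead) else rational(1)
  total <- rat_add(.dbl_to_rat(t$formate_assimilated),
                   .dbl_to_rat(t$nadh_cost))
  total <- rat_add(total, rat_mul(.dbl_to_rat(t$nadph_cost), ov))
  rat_add(total, rat_div(.dbl_to_rat(t$atp_cost),
                         .dbl_to_rat(atp_per_nadh)))
}

#' Side-by-side comparison of two routes
#'
#' @param rglyp,cbb [route_definition()] objects (any two routes).
#' @param atp_per_nadh respiration stoichiometry passed to
#'   [total_formate_per_pyruvate()].
#' @param nadph_source,transhydrogenase_overhead see
#'   [total_formate_per_pyruvate()].
#' @param mdf optional result of [route_mdf_comparison()] whose `mdf`
#'   values are merged into the table.
#' @return data frame with one row per route: `route`, `reaction_count`,
#'   `atp_cost`, `nadph_cost`, `nadh_cost`, `formate_assimilated`,
#'   `co2_fixed`, `formate_total` and (when `mdf` is given) `mdf_kj_mol`.
#' @export
compare_routes <- function(rglyp = bundled_route("RGLYP"),
                           cbb = bundled_route("CBB"),
                           atp_per_nadh = 2,
                           nadph_source = "transhydrogenase",
                           transhydrogenase_overhead = 1, mdf = NULL) {
  rows <- lapply(list(rglyp, cbb), function(rt) {
    nc <- net_conversion(rt)
    tot <- total_formate_per_pyruvate(nc, atp_per_nadh, nadph_source,
                                      transhydrogenase_overhead)
    data.frame(route = rt$name, reaction_count = nc$tallies$reaction_count,
               atp_cost = nc$tallies$atp_cost,
               nadph_cost = nc$tallies$nadph_cost,
               nadh_cost = nc$tallies$nadh_cost,
               formate_assimilated = nc$tallies$formate_assimilated,
               co2_fixed = nc$tallies$co2_fixed,
               formate_total = rat_dbl(tot), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(mdf))
    out$mdf_kj_mol <- c(mdf$rglyp$mdf, mdf$cbb$mdf)
  out
}
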