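#' Construct a metabolite
#'
#' Metabolites carry the elemental composition and charge used by the
#' balance auditor. Formulas follow Hill-style strings (`"C3H3O3"`); an
#' empty string marks an unknown composition, which makes any reaction
#' touching the species "indeterminate" rather than "balanced".
#'
#' @param id unique, nonempty identifier.
#' @param name human-readable name (defaults to `id`).
#' @param formula elemental formula string, `""` if unknown.
#' @param charge integer formal charge of the represented (major) species.
#' @param compartment compartment identifier.
#' @return a `metabolite` list.
#' @export
metabolite <- function(id, name = id, formula = "", charge = 0L,
                       compartment = "c") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("metabolite id must be a nonempty string")
  if (!is.na(formula) && nzchar(formula)) parse_formula(formula)  # validate
  structure(list(id = id, name = name, formula = formula,
                 charge = as.integer(charge), compartment = compartment),
            class = "metabolite")
}

#' Construct a reaction
#'
#' @param id unique, nonempty identifier.
#' @param stoichiometry named numeric vector, metabolite id -> signed
#'   coefficient; negative coefficients are consumed, positive produced.
#' @param lower_bound,upper_bound flux bounds, mmol gCDW^-1 h^-1.
#' @param is_exchange logical; exchange reactions touch exactly one
#'   metabolite and connect the model to the environment. Sign convention
#'   throughout the package: negative exchange flux = uptake, positive =
#'   secretion.
#' @param label free-text enzyme/gene annotation.
#' @return a `reaction` list.
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0,
                     upper_bound = 1000, is_exchange = FALSE, label = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("reaction id must be a nonempty string")
  if (!length(stoichiometry) || is.null(names(stoichiometry)) ||
      any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a nonempty named vector")
  if (lower_bound > upper_bound)
    stop("reaction ", id, ": lower_bound > upper_bound")
  if (is_exchange && length(stoichiometry) != 1L)
    stop("exchange reaction ", id, " must touch exactly one metabolite")
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 is_exchange = is_exchange, label = label),
            class = "reaction")
}

#' Assemble a stoichiometric model
#'
#' @param metabolites list of [metabolite()] objects.
#' @param reactions list of [reaction()] objects.
#' @param biomass_reaction_id id of the biomass pseudo-reaction.
#' @param objective_reaction_id id of the default objective (defaults to the
#'   biomass reaction).
#' @return a `stoichiometric_model`: the implied stoichiometric matrix S has
#'   one row per metabolite and one column per reaction (see
#'   [stoich_matrix()]).
#' @export
stoichiometric_model <- function(metabolites, reactions,
                                 biomass_reaction_id,
                                 objective_reaction_id = biomass_reaction_id) {
  mids <- vapply(metabolites, `[[`, "", "id")
  rids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(mids)) stop("duplicated metabolite ids: ",
                                paste(unique(mids[duplicated(mids)]), collapse = ", "))
  if (anyDuplicated(rids)) stop("duplicated reaction ids: ",
                                paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (r in reactions) {
    miss <- setdiff(names(r$stoichiometry), mids)
    if (length(miss)) stop("reaction ", r$id,
                           " references unknown metabolites: ",
                           paste(miss, collapse = ", "))
  }
  if (length(reactions) == 0L) {
    biomass_reaction_id <- NA_character_
    objective_reaction_id <- NA_character_
  } else {
    if (!biomass_reaction_id %in% rids)
      stop("biomass_reaction_id '", biomass_reaction_id, "' not in model")
    if (!is.null(objective_reaction_id) && !is.na(objective_reaction_id) &&
        !objective_reaction_id %in% rids)
      stop("objective_reaction_id '", objective_reaction_id, "' not in model")
  }
  names(metabolites) <- mids
  names(reactions) <- rids
  structure(list(metabolites = metabolites, reactions = reactions,
                 biomass_reaction_id = biomass_reaction_id,
                 objective_reaction_id = objective_reaction_id),
            class = "stoichiometric_model")
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat("stoichiometric_model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  biomass:", x$biomass_reaction_id, "\n")
  invisible(x)
}

#' Stoichiometric matrix of a model
#'
#' @param model a `stoichiometric_model`.
#' @return dense numeric matrix S, metabolites x reactions, with row and
#'   column names.
#' @export
stoich_matrix <- function(model) {
  mids <- names(model$metabolites)
  rids <- names(model$reactions)
  S <- matrix(0, length(mids), length(rids), dimnames = list(mids, rids))
  for (r in model$reactions)
    S[names(r$stoichiometry), r$id] <- r$stoichiometry
  S
}

#' Parse an elemental formula string
#'
#' @param formula Hill-style string such as `"C10H12N5O13P3"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(integer(0))
  mm <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, list(mm))[[1]]
  if (!length(parts) || sum(attr(mm, "match.length")) != nchar(formula))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]+$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  tapply(ct, el, sum)[unique(el)]
}

#' Check the elemental and charge balance of one reaction
#'
#' Imbalances use the products-minus-reactants convention: a missing water
#' on the product side shows up as `H = -2, O = -1`. Exchange reactions and
#' reactions involving any formula-less metabolite are reported
#' indeterminate, never "balanced".
#'
#' @param model a `stoichiometric_model`.
#' @param reaction_id reaction to audit.
#' @return a `balance_report` list: `reaction_id`, `element_imbalance`
#'   (named numeric), `charge_imbalance`, `balanced` (logical, `NA` when
#'   indeterminate), `indeterminate` and `reason`.
#' @export
check_balance <- function(model, reaction_id) {
  rxn <- model$reactions[[reaction_id]]
  if (is.null(rxn)) stop("unknown reaction id: ", reaction_id)
  rep0 <- function(balanced, indet, reason, imb = numeric(0), chg = 0) {
    structure(list(reaction_id = reaction_id, element_imbalance = imb,
                   charge_imbalance = chg, balanced = balanced,
                   indeterminate = indet, reason = reason),
              class = "balance_report")
  }
  if (rxn$is_exchange)
    return(rep0(NA, TRUE, "exchange reaction: indeterminate by design"))
  mets <- model$metabolites[names(rxn$stoichiometry)]
  if (any(vapply(mets, function(m) !nzchar(m$formula), TRUE)))
    return(rep0(NA, TRUE, "metabolite(s) without formula"))
  imb <- numeric(0)
  chg <- 0
  for (k in seq_along(rxn$stoichiometry)) {
    coef <- rxn$stoichiometry[[k]]
    m <- mets[[k]]
    f <- parse_formula(m$formula)
    for (e in names(f)) imb[e] <- (if (e %in% names(imb)) imb[[e]] else 0) +
        coef * f[[e]]
    chg <- chg + coef * m$charge
  }
  imb <- imb[abs(imb) > 1e-9 | FALSE]
  ok <- length(imb) == 0 && abs(chg) < 1e-9
  rep0(ok, FALSE, if (ok) "balanced" else "imbalanced",
       imb, chg)
}

#' Audit the balance of every reaction in a model
#'
#' @param model a `stoichiometric_model`.
#' @return data frame with one row per reaction: `reaction_id`, `balanced`,
#'   `indeterminate`, `detail`.
#' @export
balance_audit <- function(model) {
  reps <- lapply(names(model$reactions), check_balance, model = model)
  data.frame(
    reaction_id = vapply(reps, `[[`, "", "reaction_id"),
    balanced = vapply(reps, function(r) isTRUE(r$balanced), TRUE),
    indeterminate = vapply(reps, `[[`, TRUE, "indeterminate"),
    detail = vapply(reps, function(r) {
      if (r$indeterminate) return(r$reason)
      if (isTRUE(r$balanced)) return("balanced")
      paste0(paste0(names(r$element_imbalance), ":",
                    r$element_imbalance, collapse = " "),
             " charge:", r$charge_imbalance)
    }, ""),
    stringsAsFactors = FALSE)
}

#' Balance the ATP-hydrolysis part of the biomass reaction
#'
#' Growth-associated maintenance is written into biomass reactions as an
#' ATP-hydrolysis sub-stoichiometry (ATP + H2O -> ADP + Pi + H+). Source
#' models sometimes omit the water and proton; this repairs the
#' sub-stoichiometry so it is element- and charge-balanced while leaving
#' the GAM magnitude (the ATP coefficient) unchanged. Water/proton ids are
#' located in the biomass reaction's own compartment-sharing namespace via
#' `id_map`.
#'
#' @param model a `stoichiometric_model`.
#' @param id_map named character vector mapping the canonical names
#'   `atp`, `adp`, `pi`, `h2o`, `h` to model metabolite ids.
#' @return edited copy of the model; the input is not modified.
#' @export
balance_biomass_atp <- function(model,
                                id_map = c(atp = "atp_c", adp = "adp_c",
                                           pi = "pi_c", h2o = "h2o_c",
                                           h = "h_c")) {
  needed <- c("atp", "adp", "pi", "h2o", "h")
  if (!all(needed %in% names(id_map)))
    stop("id_map must name atp, adp, pi, h2o and h")
  bid <- model$biomass_reaction_id
  rxn <- model$reactions[[bid]]
  st <- rxn$stoichiometry
  if (!id_map[["atp"]] %in% names(st) || !id_map[["adp"]] %in% names(st))
    stop("biomass reaction lacks ATP/ADP species (per id_map); cannot ",
         "balance its hydrolysis part")
  gam <- -st[[id_map[["atp"]]]]           # ATP consumed: coefficient < 0
  if (gam <= 0) stop("biomass ATP coefficient is not a consumption term")
  # enforce ATP + H2O -> ADP + Pi + H+ at the GAM magnitude, leaving any
  # non-hydrolysis use of these species untouched is impossible to separate;
  # the hydrolysis part is defined as the GAM-sized block.
  for (nm in c("h2o", "h", "pi")) {
    mid <- id_map[[nm]]
    if (!mid %in% names(model$metabolites))
      stop("metabolite ", mid, " (", nm, ") not in model")
  }
  target <- c(-gam, gam, gam, -gam, gam)
  names(target) <- id_map[c("atp", "adp", "pi", "h2o", "h")]
  # replace the hydrolysis block: keep everything else as-is
  st[names(target)] <- ifelse(is.na(st[names(target)]), 0, st[names(target)])
  st[id_map[["atp"]]] <- -gam
  st[id_map[["adp"]]] <- gam
  # Pi/H2O/H adjusted so the block is exactly balanced
  st[id_map[["pi"]]]  <- gam
  st[id_map[["h2o"]]] <- -gam
  st[id_map[["h"]]]   <- gam
  st <- st[abs(st) > 0]
  model$reactions[[bid]]$stoichiometry <- st
  model
}
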