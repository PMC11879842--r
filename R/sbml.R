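# SBML Level 3 Version 1 I/O for stoichiometric models.
#
# Covers the subset of SBML that constraint-based models use: compartments,
# species (with fbc charge/formula), reactions with reactant/product
# stoichiometries, and flux bounds in any of the three encodings found in
# the wild: fbc-v2 parameter references, kinetic-law local parameters
# (LOWER_BOUND/UPPER_BOUND), or nothing at all, in which case bounds default
# to (-1000, 1000) for reversible reactions and (0, 1000) otherwise.

.sbml_num <- function(x) {
  if (is.infinite(x)) return(if (x > 0) "INF" else "-INF")
  sprintf("%.12g", x)
}

.sbml_parse_num <- function(s) {
  if (is.na(s)) return(NA_real_)
  if (s %in% c("INF", "inf", "Inf")) return(Inf)
  if (s %in% c("-INF", "-inf", "-Inf")) return(-Inf)
  suppressWarnings(as.numeric(s))
}

.xattr <- function(node, names) {
  at <- xml2::xml_attrs(node)
  for (nm in names) {
    hit <- which(names(at) == nm | grepl(paste0(":", nm, "$"), names(at)))
    if (length(hit)) return(at[[hit[1]]])
  }
  NA_character_
}

#' Read an SBML L3V1 model
#'
#' @param path path to an SBML Level 3 Version 1 file.
#' @param biomass_reaction_id optional explicit biomass reaction id; when
#'   `NULL` the fbc active objective is used if present, then any reaction
#'   whose id matches "biomass" case-insensitively, then the first reaction.
#' @return a [stoichiometric_model()].
#' @export
load_sbml <- function(path, biomass_reaction_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("SBML parse error in '", path, "': ", conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  # default namespace prefix as assigned by xml2 (usually d1)
  core <- names(ns)[ns == "http://www.sbml.org/sbml/level3/version1/core"][1]
  if (is.na(core)) stop("not an SBML Level 3 Version 1 file: ", path)
  q <- function(xp) xml2::xml_find_all(doc, gsub("s:", paste0(core, ":"), xp), ns)

  # global parameters (flux-bound values)
  pars <- new.env(parent = emptyenv())
  for (p in q(".//s:listOfParameters/s:parameter")) {
    pid <- xml2::xml_attr(p, "id")
    assign(pid, .sbml_parse_num(xml2::xml_attr(p, "value")), envir = pars)
  }

  mets <- list()
  for (sp in q(".//s:listOfSpecies/s:species")) {
    chg <- .xattr(sp, c("charge"))
    mets[[length(mets) + 1L]] <- metabolite(
      id = xml2::xml_attr(sp, "id"),
      name = { nm <- xml2::xml_attr(sp, "name"); if (is.na(nm)) xml2::xml_attr(sp, "id") else nm },
      formula = { f <- .xattr(sp, "chemicalFormula"); if (is.na(f)) "" else f },
      charge = if (is.na(chg)) 0L else as.integer(as.numeric(chg)),
      compartment = xml2::xml_attr(sp, "compartment"))
  }
  mids <- vapply(mets, `[[`, "", "id")
  if (anyDuplicated(mids))
    stop("duplicated species ids in ", path, ": ",
         paste(unique(mids[duplicated(mids)]), collapse = ", "))

  rxns <- list()
  for (rx in q(".//s:listOfReactions/s:reaction")) {
    rid <- xml2::xml_attr(rx, "id")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    st <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      for (sr in xml2::xml_find_all(
             rx, paste0("./", core, ":", side, "/", core, ":speciesReference"), ns)) {
        sid <- xml2::xml_attr(sr, "species")
        coef <- .sbml_parse_num(xml2::xml_attr(sr, "stoichiometry"))
        if (is.na(coef)) coef <- 1
        st[sid] <- (if (sid %in% names(st)) st[[sid]] else 0) + sgn * coef
      }
    }
    # bounds: fbc attributes -> kinetic law -> defaults from `reversible`
    lb <- ub <- NA_real_
    lbp <- .xattr(rx, "lowerFluxBound"); ubp <- .xattr(rx, "upperFluxBound")
    if (!is.na(lbp) && exists(lbp, envir = pars)) lb <- get(lbp, envir = pars)
    if (!is.na(ubp) && exists(ubp, envir = pars)) ub <- get(ubp, envir = pars)
    if (is.na(lb) || is.na(ub)) {
      for (lp in xml2::xml_find_all(
             rx, paste0("./", core, ":kineticLaw//", core, ":localParameter | ./",
                        core, ":kineticLaw//", core, ":parameter"), ns)) {
        pid <- xml2::xml_attr(lp, "id")
        val <- .sbml_parse_num(xml2::xml_attr(lp, "value"))
        if (identical(pid, "LOWER_BOUND") && is.na(lb)) lb <- val
        if (identical(pid, "UPPER_BOUND") && is.na(ub)) ub <- val
      }
    }
    if (is.na(lb)) lb <- if (rev) -1000 else 0
    if (is.na(ub)) ub <- 1000
    rxns[[length(rxns) + 1L]] <- reaction(
      id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub,
      is_exchange = length(st) == 1L,
      label = { nm <- xml2::xml_attr(rx, "name"); if (is.na(nm)) "" else nm })
  }
  rids <- vapply(rxns, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicated reaction ids in ", path, ": ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))

  if (is.null(biomass_reaction_id)) {
    obj <- q(".//*[local-name()='fluxObjective']")
    if (length(obj)) {
      cand <- .xattr(obj[[1]], "reaction")
      if (!is.na(cand) && cand %in% rids) biomass_reaction_id <- cand
    }
  }
  if (is.null(biomass_reaction_id)) {
    hit <- grep("biomass", rids, ignore.case = TRUE, value = TRUE)
    biomass_reaction_id <- if (length(hit)) hit[1] else rids[1]
  }
  stoichiometric_model(mets, rxns, biomass_reaction_id)
}

#' Write a model as SBML L3V1 (with fbc-v2 flux bounds)
#'
#' Round-trip guarantee: [load_sbml()] of the written file reproduces the
#' model's ids, stoichiometries (to 12 significant digits) and bounds.
#'
#' @param model a [stoichiometric_model()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_sbml <- function(model, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    s <- gsub(">", "&gt;", s, fixed = TRUE)
    gsub('"', "&quot;", s, fixed = TRUE)
  }
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
                  'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
                  'level="3" version="1" fbc:required="false">'),
           '  <model id="model" fbc:strict="false">')
  comps <- unique(vapply(model$metabolites, `[[`, "", "compartment"))
  if (length(comps)) {
    out <- c(out, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
             "    </listOfCompartments>")
  }
  if (length(model$metabolites)) {
    out <- c(out, "    <listOfSpecies>")
    for (m in model$metabolites) {
      extra <- sprintf(' fbc:charge="%d"', m$charge)
      if (nzchar(m$formula))
        extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', esc(m$formula)))
      out <- c(out, sprintf(
        paste0('      <species id="%s" name="%s" compartment="%s" ',
               'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
               'constant="false"%s/>'),
        esc(m$id), esc(m$name), esc(m$compartment), extra))
    }
    out <- c(out, "    </listOfSpecies>")
  }
  # one shared parameter per distinct bound value
  bounds <- unlist(lapply(model$reactions,
                          function(r) c(r$lower_bound, r$upper_bound)))
  uvals <- unique(bounds)
  pid_of <- function(v) sprintf("fb_%d", match(v, uvals))
  if (length(uvals)) {
    out <- c(out, "    <listOfParameters>",
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     vapply(uvals, pid_of, ""),
                     vapply(uvals, .sbml_num, "")),
             "    </listOfParameters>")
  }
  if (length(model$reactions)) out <- c(out, "    <listOfReactions>")
  for (r in model$reactions) {
    rev <- r$lower_bound < 0
    out <- c(out, sprintf(
      paste0('      <reaction id="%s" name="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      esc(r$id), esc(r$label), if (rev) "true" else "false",
      pid_of(r$lower_bound), pid_of(r$upper_bound)))
    neg <- r$stoichiometry[r$stoichiometry < 0]
    pos <- r$stoichiometry[r$stoichiometry > 0]
    if (length(neg)) {
      out <- c(out, "        <listOfReactants>",
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       esc(names(neg)), vapply(-neg, .sbml_num, "")),
               "        </listOfReactants>")
    }
    if (length(pos)) {
      out <- c(out, "        <listOfProducts>",
               sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                       esc(names(pos)), vapply(pos, .sbml_num, "")),
               "        </listOfProducts>")
    }
    out <- c(out, "      </reaction>")
  }
  if (length(model$reactions)) out <- c(out, "    </listOfReactions>")
  if (length(model$reactions) && !is.na(model$biomass_reaction_id)) out <- c(out,
           "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
           '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
           "        <fbc:listOfFluxObjectives>",
           sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
                   esc(model$biomass_reaction_id)),
           "        </fbc:listOfFluxObjectives>",
           "      </fbc:objective>",
           "    </fbc:listOfObjectives>")
  out <- c(out, "  </model>", "</sbml>")
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
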