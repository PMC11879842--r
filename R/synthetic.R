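# Generators for every input the pipeline needs: a balanced ~30-reaction
# C. necator core network supporting both formate-assimilation variants,
# closed-form toy yield models, and chemostat sample tables.

#' Elemental formulas and charges of the compounds used by the bundled
#' fixtures
#'
#' Anionic/major species at physiological pH, so reactions written with
#' explicit protons balance both elements and charge.
#'
#' @return data frame with columns `id`, `formula`, `charge`, `name`.
#' @export
compound_db <- function() {
  d <- rbind(
    c("for", "CHO2", -1, "formate"),
    c("co2", "CO2", 0, "carbon dioxide"),
    c("o2", "O2", 0, "oxygen"),
    c("nh4", "H4N", 1, "ammonium"),
    c("h", "H", 1, "proton"),
    c("h2o", "H2O", 0, "water"),
    c("pi", "HO4P", -2, "phosphate"),
    c("atp", "C10H12N5O13P3", -4, "ATP"),
    c("adp", "C10H12N5O10P2", -3, "ADP"),
    c("nad", "C21H26N7O14P2", -1, "NAD+"),
    c("nadh", "C21H27N7O14P2", -2, "NADH"),
    c("nadp", "C21H25N7O17P3", -3, "NADP+"),
    c("nadph", "C21H26N7O17P3", -4, "NADPH"),
    c("thf", "C19H21N7O6", -2, "tetrahydrofolate"),
    c("f10thf", "C20H21N7O7", -2, "10-formyl-THF"),
    c("methenylthf", "C20H20N7O6", -1, "5,10-methenyl-THF"),
    c("mlthf", "C20H21N7O6", -2, "5,10-methylene-THF"),
    c("gly", "C2H5NO2", 0, "glycine"),
    c("ser", "C3H7NO3", 0, "L-serine"),
    c("pyr", "C3H3O3", -1, "pyruvate"),
    c("g3p", "C3H5O6P", -2, "glyceraldehyde 3-phosphate"),
    c("dhap", "C3H5O6P", -2, "dihydroxyacetone phosphate"),
    c("bpg13", "C3H4O10P2", -4, "1,3-bisphosphoglycerate"),
    c("pg3", "C3H4O7P", -3, "3-phosphoglycerate"),
    c("pg2", "C3H4O7P", -3, "2-phosphoglycerate"),
    c("pep", "C3H2O6P", -3, "phosphoenolpyruvate"),
    c("fbp", "C6H10O12P2", -4, "fructose 1,6-bisphosphate"),
    c("f6p", "C6H11O9P", -2, "fructose 6-phosphate"),
    c("e4p", "C4H7O7P", -2, "erythrose 4-phosphate"),
    c("sbp", "C7H12O13P2", -4, "sedoheptulose 1,7-bisphosphate"),
    c("s7p", "C7H13O10P", -2, "sedoheptulose 7-phosphate"),
    c("r5p", "C5H9O8P", -2, "ribose 5-phosphate"),
    c("xu5p", "C5H9O8P", -2, "xylulose 5-phosphate"),
    c("ru5p", "C5H9O8P", -2, "ribulose 5-phosphate"),
    c("rubp", "C5H8O11P2", -4, "ribulose 1,5-bisphosphate"))
  data.frame(id = d[, 1], formula = d[, 2], charge = as.integer(d[, 3]),
             name = d[, 4], stringsAsFactors = FALSE)
}

#' Build the reduced C. necator core network
#'
#' A balanced (C/H/O/N/P/charge) ~30-reaction stand-in for the genome-scale
#' model: formate exchange and transport, formate dehydrogenase, the
#' reductive glycine pathway reactions MtdA/GLYAMT/GlyA/SdaA (the C1-entry
#' reactions Ftl and Fch are deliberately absent, so the RGLYP variant
#' recipe adds them exactly as it would on the genome-scale model), a
#' lumped Calvin module (RuBisCO `RBPC`, phosphoribulokinase `PRK`, lumped
#' reduction and regeneration), the PntAB transhydrogenase, lumped
#' respiration (`eta` ATP per NADH), ATP maintenance, and a single
#' pyruvate+ATP+NADPH biomass pseudo-reaction. Both [variant_spec()]
#' recipes apply cleanly and the model grows on formate under each.
#'
#' Core-model yields are not calibrated to the genome-scale predictions;
#' the model's contract is the yield ordering between variants plus exact
#' elemental balance.
#'
#' @param biomass_precursor_demand mmol pyruvate per gCDW (integer-valued
#'   so the derived biomass formula stays integral).
#' @param biomass_nadph,biomass_nh4 mmol per gCDW consumed by biosynthesis.
#' @param gam growth-associated maintenance written into the biomass
#'   reaction, mmol ATP gCDW^-1.
#' @param eta ATP per NADH from lumped respiration (P/O-like), > 0.
#' @return a [stoichiometric_model()].
#' @export
build_core_model <- function(biomass_precursor_demand = 13,
                             biomass_nadph = 10, biomass_nh4 = 10,
                             gam = 135, eta = 2) {
  if (biomass_precursor_demand <= 0 || biomass_nadph < 0 ||
      biomass_nh4 < 0 || gam < 0 || eta <= 0)
    stop("core-model parameters must be positive")
  db <- compound_db()
  frm <- function(id) db$formula[db$id == id]
  chg <- function(id) db$charge[db$id == id]
  ext <- c("for", "co2", "o2", "nh4", "h", "h2o")
  mets <- list()
  for (id in ext) {
    mets[[length(mets) + 1L]] <- metabolite(paste0(id, "_e"),
                                            name = db$name[db$id == id],
                                            formula = frm(id),
                                            charge = chg(id),
                                            compartment = "e")
  }
  core_ids <- c(ext, "pi", "atp", "adp", "nad", "nadh", "nadp", "nadph",
                "thf", "f10thf", "methenylthf", "mlthf", "gly", "ser",
                "pyr", "ru5p", "rubp", "pg3", "g3p")
  for (id in core_ids) {
    mets[[length(mets) + 1L]] <- metabolite(paste0(id, "_c"),
                                            name = db$name[db$id == id],
                                            formula = frm(id),
                                            charge = chg(id),
                                            compartment = "c")
  }

  st <- function(...) {
    v <- c(...)
    v
  }
  rx <- list()
  add <- function(id, stoich, lb = 0, ub = 1000, exch = FALSE, label = "")
    rx[[length(rx) + 1L]] <<- reaction(id, stoich, lb, ub, exch, label)

  # exchanges (uptake negative); the formate exchange carries the
  # conventional genome-scale id EX_formate_e
  for (id in ext)
    add(if (id == "for") "EX_formate_e" else paste0("EX_", id, "_e"),
        st(stats::setNames(-1, paste0(id, "_e"))),
        lb = -1000, ub = 1000, exch = TRUE,
        label = paste(id, "exchange"))
  # transport
  for (id in ext)
    add(paste0(toupper(substr(id, 1, 1)), substr(id, 2, 99), "t"),
        stats::setNames(c(-1, 1), paste0(id, c("_e", "_c"))),
        lb = -1000, ub = 1000, label = paste(id, "diffusion"))

  # energy metabolism
  add("FDH", c(for_c = -1, nad_c = -1, co2_c = 1, nadh_c = 1),
      label = "formate dehydrogenase")
  add("PNT", c(nadh_c = -1, nadp_c = -1, nad_c = 1, nadph_c = 1),
      lb = -1000, label = "membrane transhydrogenase (PntAB)")
  add("RESP", c(nadh_c = -1, o2_c = -0.5, adp_c = -eta, pi_c = -eta,
                h_c = -(1 + eta), nad_c = 1, atp_c = eta,
                h2o_c = 1 + eta),
      label = sprintf("lumped respiration, %g ATP/NADH", eta))
  add("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
      label = "ATP maintenance")

  # reductive glycine pathway (C1-entry Ftl/Fch added by the RGLYP variant)
  add("MTD", c(methenylthf_c = -1, nadph_c = -1, mlthf_c = 1, nadp_c = 1),
      label = "methylene-THF dehydrogenase (MtdA)")
  add("GLYAMT", c(gly_c = -1, thf_c = -1, nad_c = -1,
                  mlthf_c = 1, co2_c = 1, nh4_c = 1, nadh_c = 1),
      lb = -1000,
      label = "glycine cleavage system (written glycine-cleaving; reverse = rGlyP direction)")
  add("GLYA", c(ser_c = -1, thf_c = -1, gly_c = 1, mlthf_c = 1, h2o_c = 1),
      lb = -1000,
      label = "serine hydroxymethyltransferase (GlyA)")
  add("SDA", c(ser_c = -1, pyr_c = 1, nh4_c = 1),
      label = "serine deaminase (SdaA)")

  # lumped Calvin module
  add("PRK", c(ru5p_c = -1, atp_c = -1, rubp_c = 1, adp_c = 1, h_c = 1),
      label = "phosphoribulokinase (Prk)")
  add("RBPC", c(rubp_c = -1, co2_c = -1, h2o_c = -1, pg3_c = 2, h_c = 2),
      label = "ribulose-bisphosphate carboxylase (RuBisCO)")
  add("PGK_GAPDH", c(pg3_c = -1, atp_c = -1, nadh_c = -1, h_c = -1,
                     g3p_c = 1, adp_c = 1, nad_c = 1, pi_c = 1),
      label = "lumped 3PG reduction (Pgk + GapDH)")
  add("REGEN", c(g3p_c = -5, h2o_c = -2, ru5p_c = 3, pi_c = 2),
      label = "lumped pentose regeneration")
  add("GLYC", c(pg3_c = -1, adp_c = -1, h_c = -1, pyr_c = 1, atp_c = 1,
                h2o_c = 1),
      label = "lumped lower glycolysis (Pgm + Eno + Pyk)")

  # biomass: precursors in, hydrolysis products out, composition derived so
  # the pseudo-species closes the elemental/charge balance exactly
  d <- biomass_precursor_demand
  bm <- c(pyr_c = -d, nadph_c = -biomass_nadph, nh4_c = -biomass_nh4,
          h_c = -d, atp_c = -gam, h2o_c = -gam,
          nadp_c = biomass_nadph, adp_c = gam, pi_c = gam)
  bm["h_c"] <- bm[["h_c"]] + gam          # hydrolysis protons out
  elems <- c(C = 0, H = 0, N = 0, O = 0, P = 0)
  q <- 0
  for (id in names(bm)) {
    base <- sub("_c$", "", id)
    f <- parse_formula(frm(base))
    for (e in names(f)) elems[e] <- elems[[e]] + bm[[id]] * f[[e]]
    q <- q + bm[[id]] * chg(base)
  }
  elems <- -elems; q <- -q
  if (any(abs(elems - round(elems)) > 1e-9) || abs(q - round(q)) > 1e-9)
    stop("biomass composition is not integral; use integer demands")
  elems <- round(elems[elems > 0]); q <- round(q)
  bform <- paste0(names(elems), ifelse(elems == 1, "", elems), collapse = "")
  mets[[length(mets) + 1L]] <- metabolite("biomass_c", "biomass",
                                          formula = bform, charge = q,
                                          compartment = "c")
  bm <- c(bm, biomass_c = 1)
  add("BIOMASS", bm, label = sprintf("biomass, GAM = %g mmol/gCDW", gam))
  add("EX_biomass_e", c(biomass_c = -1), lb = 0, ub = 1000, exch = TRUE,
      label = "biomass sink")

  stoichiometric_model(mets, rx, biomass_reaction_id = "BIOMASS")
}

#' Build a toy chain model with a closed-form optimal yield
#'
#' Substrate exchange -> transport -> biomass consuming
#' `substrate_per_biomass` mmol substrate per gCDW. With zero maintenance
#' the unique optimal yield is exactly `1000 / substrate_per_biomass`
#' g CDW mol^-1 at any growth rate. With `atp_per_substrate > 0` the model
#' gains a substrate-burning ATP reaction plus an `ATPM` maintenance
#' reaction so NGAM > 0 lowers the yield below the closed form.
#'
#' @param substrate_per_biomass mmol substrate per gCDW, > 0.
#' @param atp_per_substrate ATP gained per substrate burned (0 = no energy
#'   machinery).
#' @return a [stoichiometric_model()] whose formate-yield entry point works
#'   with `formate_exchange_id = "EX_s_e"`.
#' @export
build_toy_yield_model <- function(substrate_per_biomass,
                                  atp_per_substrate = 0) {
  if (substrate_per_biomass <= 0) stop("substrate_per_biomass must be > 0")
  mets <- list(metabolite("s_e", "substrate (ext)", compartment = "e"),
               metabolite("s_c", "substrate", compartment = "c"),
               metabolite("biomass_c", "biomass", compartment = "c"))
  rx <- list(
    reaction("EX_s_e", c(s_e = -1), -1000, 1000, is_exchange = TRUE),
    reaction("St", c(s_e = -1, s_c = 1), -1000, 1000),
    reaction("BIOMASS", stats::setNames(c(-substrate_per_biomass, 1),
                                        c("s_c", "biomass_c")), 0, 1000),
    reaction("EX_biomass_e", c(biomass_c = -1), 0, 1000,
             is_exchange = TRUE))
  if (atp_per_substrate > 0) {
    mets <- c(mets, list(metabolite("atp_c", "ATP", compartment = "c"),
                         metabolite("adp_c", "ADP", compartment = "c")))
    rx <- c(rx, list(
      reaction("BURN", stats::setNames(
        c(-1, -atp_per_substrate, atp_per_substrate),
        c("s_c", "adp_c", "atp_c")), 0, 1000),
      reaction("ATPM", c(atp_c = -1, adp_c = 1), 0, 1000)))
  }
  stoichiometric_model(mets, rx, biomass_reaction_id = "BIOMASS")
}

#' Simulate a chemostat yield experiment
#'
#' Per-sample yields are drawn from a normal distribution truncated at
#' zero (per strain), and cell dry weight follows as yield times the
#' formate fed; consumed formate equals the feed (residual formate below
#' detection at steady state). Defaults reproduce the study conditions:
#' means 3.88 and 4.52 g CDW mol^-1, SDs 0.19 and 0.17, n = 9 per strain,
#' 80 mM formate, samples spread over 3 days.
#'
#' @param mean_cbb,sd_cbb CBB-strain yield mean and SD, g CDW mol^-1.
#' @param mean_rglyp,sd_rglyp rGlyP-strain yield mean and SD.
#' @param n samples per strain (>= 2).
#' @param formate_fed formate fed, mol l^-1 (default 0.08).
#' @param days number of sampling days the samples are spread over.
#' @param seed optional RNG seed for reproducible tables.
#' @return sample table data frame (see [read_sample_table()]).
#' @export
simulate_chemostat <- function(mean_cbb = 3.88, sd_cbb = 0.19,
                               mean_rglyp = 4.52, sd_rglyp = 0.17,
                               n = 9, formate_fed = 0.08, days = 3,
                               seed = NULL) {
  if (n < 2) stop("need n >= 2 per strain")
  if (any(c(sd_cbb, sd_rglyp) < 0)) stop("sds must be >= 0")
  if (formate_fed <= 0) stop("formate_fed must be > 0")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  rtnorm <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  y <- c(rtnorm(n, mean_cbb, sd_cbb), rtnorm(n, mean_rglyp, sd_rglyp))
  data.frame(
    strain = rep(c("CBB", "RGLYP"), each = n),
    sample_id = paste0(rep(c("cbb_", "rglyp_"), each = n),
                       rep(seq_len(n), 2)),
    cdw_g_per_l = y * formate_fed,
    formate_mol_per_l = formate_fed,
    day = rep(rep_len(seq_len(days), n), 2),
    stringsAsFactors = FALSE)
}
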