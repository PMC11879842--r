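#' Doubling time from dilution rate
#'
#' In a chemostat at steady state the growth rate equals the dilution rate
#' `D`, so the doubling time is `ln(2) / D`.
#'
#' @param d dilution rate, h^-1, > 0.
#' @return doubling time in hours.
#' @seealso [round_hours()] for the display convention.
#' @export
doubling_time_from_dilution <- function(d) {
  if (any(d <= 0)) stop("dilution rate must be > 0")
  log(2) / d
}

#' Round a duration to the nearest integer hour (display helper)
#' @param hours numeric hours.
#' @export
round_hours <- function(hours) as.integer(round(hours))

#' Time to flush n reactor turnovers
#' @param n number of turnovers, >= 0.
#' @param d dilution rate, h^-1, > 0.
#' @return hours, `n / d`.
#' @export
time_for_turnovers <- function(n, d) {
  if (any(n < 0)) stop("turnover count must be >= 0")
  if (any(d <= 0)) stop("dilution rate must be > 0")
  n / d
}

#' Biomass yield from a chemostat sample
#' @param cdw cell dry weight concentration, g l^-1 (>= 0).
#' @param formate_consumed formate consumed, mol l^-1 (> 0).
#' @return yield, g CDW mol^-1 formate.
#' @export
measured_yield <- function(cdw, formate_consumed) {
  if (any(cdw < 0)) stop("cdw must be >= 0")
  if (any(formate_consumed <= 0)) stop("formate consumed must be > 0")
  cdw / formate_consumed
}

#' Percent yield increase over a baseline
#' @param difference difference of means, g CDW mol^-1.
#' @param baseline_mean baseline (CBB) mean yield, > 0.
#' @param digits decimals to report (default 1).
#' @return percent increase, rounded to `digits`.
#' @export
percent_increase <- function(difference, baseline_mean, digits = 1) {
  if (any(baseline_mean <= 0)) stop("baseline mean must be > 0")
  round(100 * difference / baseline_mean, digits)
}

#' Plate-reader to cuvette OD600 conversion
#' @param od_plate plate-reader OD600, >= 0.
#' @param factor conversion factor (default 4.35).
#' @return cuvette-equivalent OD600.
#' @export
od_plate_to_cuvette <- function(od_plate, factor = 4.35) {
  if (any(od_plate < 0)) stop("OD must be >= 0")
  factor * od_plate
}

#' Read a chemostat sample table
#'
#' @param path delimited text with header columns `strain`, `sample_id`,
#'   `cdw_g_per_l`, `formate_mol_per_l`, `day`.
#' @return validated data frame.
#' @export
read_sample_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_table(tab)
}

#' @rdname read_sample_table
#' @param tab data frame to validate in place.
#' @export
validate_sample_table <- function(tab) {
  need <- c("strain", "sample_id", "cdw_g_per_l", "formate_mol_per_l", "day")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(tab$cdw_g_per_l < 0)) stop("cdw must be >= 0")
  if (any(tab$formate_mol_per_l <= 0)) stop("formate consumed must be > 0")
  tab
}

#' Write a chemostat sample table
#' @param tab sample table data frame.
#' @param path output path (tab-delimited, with header).
#' @export
write_sample_table <- function(tab, path) {
  utils::write.table(validate_sample_table(tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-sample comparison of chemostat biomass yields
#'
#' Computes per-sample yields (`cdw / formate_consumed`), then the standard
#' two-sample t machinery between the `RGLYP` and `CBB` strains: difference
#' of means (RGLYP minus CBB), its standard error, the t statistic, degrees
#' of freedom, the two-tailed p value and a 95 percent confidence interval.
#' Both the pooled and the Welch degrees of freedom are reported alongside
#' the chosen flavor: published legends sometimes print a df that matches
#' neither convention, so the ambiguity is surfaced rather than hidden.
#'
#' @param tab sample table (see [read_sample_table()]) with strains `CBB`
#'   and `RGLYP`.
#' @param flavor `"pooled"` (equal variances) or `"welch"`.
#' @param paired logical; paired test requires equal counts.
#' @param conf_level confidence level for the interval.
#' @return a `yield_comparison` list: `mean_yield`, `sd_yield`, `n` (per
#'   strain), `difference_of_means`, `sem_of_difference`, `t_statistic`,
#'   `degrees_of_freedom`, `df_pooled`, `df_welch`, `p_two_tailed`, `ci95`,
#'   `percent_increase`, `flavor`, `paired`.
#' @export
two_sample_t <- function(tab, flavor = c("pooled", "welch"),
                         paired = FALSE, conf_level = 0.95) {
  flavor <- match.arg(flavor)
  tab <- validate_sample_table(tab)
  y <- measured_yield(tab$cdw_g_per_l, tab$formate_mol_per_l)
  g1 <- y[tab$strain == "RGLYP"]
  g0 <- y[tab$strain == "CBB"]
  if (length(g0) < 2 || length(g1) < 2)
    stop("need >= 2 samples per strain")
  if (paired && length(g0) != length(g1))
    stop("paired test requires equal sample counts")
  tt <- stats::t.test(g1, g0, var.equal = flavor == "pooled",
                      paired = paired, conf.level = conf_level)
  n0 <- length(g0); n1 <- length(g1)
  sem <- if (paired) stats::sd(g1 - g0) / sqrt(n1)
  else if (flavor == "pooled") {
    sp2 <- ((n1 - 1) * stats::var(g1) + (n0 - 1) * stats::var(g0)) /
      (n1 + n0 - 2)
    sqrt(sp2 * (1 / n1 + 1 / n0))
  } else sqrt(stats::var(g1) / n1 + stats::var(g0) / n0)
  vr <- c(stats::var(g1) / n1, stats::var(g0) / n0)
  structure(list(
    mean_yield = c(CBB = mean(g0), RGLYP = mean(g1)),
    sd_yield = c(CBB = stats::sd(g0), RGLYP = stats::sd(g1)),
    n = c(CBB = n0, RGLYP = n1),
    difference_of_means = mean(g1) - mean(g0),
    sem_of_difference = sem,
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    df_pooled = n0 + n1 - 2,
    df_welch = sum(vr)^2 / (vr[1]^2 / (n1 - 1) + vr[2]^2 / (n0 - 1)),
    p_two_tailed = tt$p.value,
    ci95 = as.numeric(tt$conf.int),
    percent_increase = percent_increase(mean(g1) - mean(g0), mean(g0)),
    flavor = flavor, paired = paired), class = "yield_comparison")
}

#' @export
print.yield_comparison <- function(x, ...) {
  cat(sprintf("yield_comparison (%s%s):\n", x$flavor,
              if (x$paired) ", paired" else ""))
  cat(sprintf("  CBB   %0.2f +/- %0.2f (n=%d)\n", x$mean_yield["CBB"],
              x$sd_yield["CBB"], x$n["CBB"]))
  cat(sprintf("  RGLYP %0.2f +/- %0.2f (n=%d)\n", x$mean_yield["RGLYP"],
              x$sd_yield["RGLYP"], x$n["RGLYP"]))
  cat(sprintf("  diff %0.4f +/- %0.5f; t=%0.3f df=%0.2f p=%.3g\n",
              x$difference_of_means, x$sem_of_difference, x$t_statistic,
              x$degrees_of_freedom, x$p_two_tailed))
  cat(sprintf("  95%% CI [%0.4f, %0.4f]; +%0.1f%%\n",
              x$ci95[1], x$ci95[2], x$percent_increase))
  invisible(x)
}
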