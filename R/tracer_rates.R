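#' @title Stable-isotope tracer arithmetic
#' @description Conversions between isotope ratios, delta notation and atom
#'   percent, and the net carbon incorporation rate computed from a 13C
#'   labelling incubation.
#' @name tracer-rates
NULL

#' Atomic 13C/12C ratio of the VPDB reference standard
#'
#' Delta values are expressed relative to the Vienna Pee Dee Belemnite
#' standard; this is its conventional atomic ratio.
#' @export
VPDB_RATIO <- 0.0112372

#' Convert an isotope ratio to delta notation (per mille)
#'
#' `delta13c()` maps an atomic 13C/12C ratio to the per-mille deviation from a
#' reference standard; `ratio_from_delta()` is its exact inverse.
#'
#' @param r_sample Atomic 13C/12C ratio(s) of the sample; must be >= 0.
#' @param r_standard Atomic ratio of the reference standard (default VPDB).
#' @param delta Per-mille delta value(s); must be >= -1000.
#' @return `delta13c()`: per-mille values; `ratio_from_delta()`: atomic ratios.
#' @examples
#' delta13c(2 * VPDB_RATIO)            # +1000
#' ratio_from_delta(0)                 # the standard ratio itself
#' @export
delta13c <- function(r_sample, r_standard = VPDB_RATIO) {
  if (any(r_standard <= 0)) stop("r_standard must be > 0")
  if (any(r_sample < 0)) stop("isotope ratios must be >= 0")
  (r_sample / r_standard - 1) * 1000
}

#' @rdname delta13c
#' @export
ratio_from_delta <- function(delta, r_standard = VPDB_RATIO) {
  if (any(r_standard <= 0)) stop("r_standard must be > 0")
  r <- (delta / 1000 + 1) * r_standard
  if (any(r < 0)) stop("delta below -1000 per mille implies a negative ratio")
  r
}

#' Atom percent 13C from an isotope ratio
#'
#' A% = R / (R + 1) * 100, the percentage of carbon atoms that are 13C.
#' `ratio_from_atom_percent()` inverts it.
#'
#' @param r Atomic 13C/12C ratio(s), >= 0.
#' @param a Atom percent value(s) in [0, 100).
#' @export
atom_percent <- function(r) {
  if (any(r < 0)) stop("isotope ratios must be >= 0")
  r / (r + 1) * 100
}

#' @rdname atom_percent
#' @export
ratio_from_atom_percent <- function(a) {
  if (any(a < 0 | a >= 100)) stop("atom percent must lie in [0, 100)")
  a / (100 - a)
}

#' Fraction of tissue carbon replaced by labelled 13C
#'
#' The excess atom percent of the labelled tissue over the natural-abundance
#' reference, scaled by the excess of the incubation water DIC:
#' (A_lab - A_nat) / (A_wat - A_nat).
#'
#' @param a_lab Atom percent of the labelled tissue.
#' @param a_nat Natural-abundance atom percent of the same tissue type.
#' @param a_wat Atom percent of the dissolved inorganic carbon in the
#'   incubation water.
#' @export
fraction_incorporated <- function(a_lab, a_nat, a_wat) {
  if (any(a_wat == a_nat)) {
    stop("a_wat equals a_nat: zero label excess, fraction undefined")
  }
  (a_lab - a_nat) / (a_wat - a_nat)
}

#' Net carbon incorporation rate from isotope records
#'
#' Takes per-worm tissue delta-13C measurements from a labelling incubation
#' and returns the incorporated-label fraction, the weight of 13C
#' incorporated, and dry- and wet-weight incorporation rates.  The dry-weight
#' rate is ((W13C / MW) * 1000) / (DW * hours) with MW = 13 g/mol, as the
#' tracer protocol defines it; note that the tissue dry weight cancels
#' algebraically in this rate.  The wet-weight rate multiplies by the
#' dry-to-wet weight ratio.
#'
#' @param records Data frame with columns `worm_id`, `tissue`,
#'   `delta13c_lab`, `delta13c_nat`, `a_pct_water`, `dry_weight_g`, `hours`,
#'   `dw_ww_ratio`, and optionally `r_standard` (defaults to VPDB).
#' @param carbon_fraction Fraction of tissue dry weight that is carbon,
#'   applied to the incorporated weight; default 1.0 treats the printed
#'   formula verbatim (dry weight taken as all carbon).
#' @return Data frame with per-record `pct13c_inc` (fraction), `w13c_inc_g`,
#'   `dry_c_inc`, `wet_c_inc` and `mw`, plus provenance columns.
#' @export
incorporation_rate <- function(records, carbon_fraction = 1) {
  req <- c("worm_id", "delta13c_lab", "delta13c_nat", "a_pct_water",
           "dry_weight_g", "hours", "dw_ww_ratio")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("isotope records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(records$dry_weight_g <= 0)) stop("dry_weight_g must be > 0")
  if (any(records$hours <= 0)) stop("hours must be > 0")
  if (any(records$dw_ww_ratio <= 0 | records$dw_ww_ratio > 1)) {
    stop("dw_ww_ratio must lie in (0, 1]")
  }
  if (carbon_fraction <= 0 || carbon_fraction > 1) {
    stop("carbon_fraction must lie in (0, 1]")
  }
  r_std <- if ("r_standard" %in% names(records)) records$r_standard
           else VPDB_RATIO

  a_lab <- atom_percent(ratio_from_delta(records$delta13c_lab, r_std))
  a_nat <- atom_percent(ratio_from_delta(records$delta13c_nat, r_std))
  a_wat <- records$a_pct_water
  if (any(a_wat <= a_nat)) {
    stop("a_pct_water must exceed the natural-abundance atom percent")
  }

  mw <- 13
  frac <- fraction_incorporated(a_lab, a_nat, a_wat)
  w13c <- frac * records$dry_weight_g * carbon_fraction
  dry_c <- ((w13c / mw) * 1000) / (records$dry_weight_g * records$hours)
  wet_c <- dry_c * records$dw_ww_ratio

  data.frame(
    worm_id = records$worm_id,
    tissue = if ("tissue" %in% names(records)) records$tissue else NA_character_,
    pct13c_inc = frac,
    w13c_inc_g = w13c,
    dry_c_inc = dry_c,
    wet_c_inc = wet_c,
    mw = mw,
    r_standard = r_std,
    stringsAsFactors = FALSE
  )
}

#' Substrate uptake rates from flow-through chemistry
#'
#' rate = (c_in - c_out) * flow / biomass per timepoint; negative rates
#' (net production) are retained and flagged.  Records with a missing inlet
#' or outlet concentration are skipped with a warning.
#'
#' @param records Data frame with columns `substrate`, `c_in`, `c_out`
#'   (umol/l), `flow_l_h` (l/h) and `biomass_g` (g); optional `timepoint`.
#' @return List with `rates` (per-timepoint data frame including a
#'   `production` flag), `mean` and `se` of the retained rates.
#' @export
uptake_rate <- function(records) {
  req <- c("c_in", "c_out", "flow_l_h", "biomass_g")
  miss <- setdiff(req, names(records))
  if (length(miss)) stop("uptake records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(records$flow_l_h <= 0, na.rm = TRUE)) stop("flow_l_h must be > 0")
  if (any(records$biomass_g <= 0, na.rm = TRUE)) stop("biomass_g must be > 0")
  ok <- stats::complete.cases(records[, c("c_in", "c_out")])
  if (any(!ok)) {
    warning(sum(!ok), " record(s) skipped: missing inlet/outlet pair")
  }
  kept <- records[ok, , drop = FALSE]
  rate <- (kept$c_in - kept$c_out) * kept$flow_l_h / kept$biomass_g
  rates <- cbind(kept, rate = rate, production = rate < 0)
  n <- length(rate)
  list(
    rates = rates,
    mean = mean(rate),
    se = if (n > 1) stats::sd(rate) / sqrt(n) else NA_real_
  )
}
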