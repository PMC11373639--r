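#' Water loss percentage
#'
#' Percentage weight lost during postharvest storage,
#' `WL% = (Wi - Wf) / Wi * 100`, where `Wi` is the sample weight before
#' storage and `Wf` the weight at the end of the storage period.
#'
#' @param Wi Initial weight (g), strictly positive.
#' @param Wf Final weight (g), non-negative. Vectorized with `Wi`.
#' @return Water loss percentage; 0 means no loss, negative values indicate
#'   weight gain (possible with condensation).
#' @examples
#' water_loss_pct(100, 90) # 10
#' @export
water_loss_pct <- function(Wi, Wf) {
  if (any(is.na(Wi)) || any(is.na(Wf))) stopf("weights must not be missing")
  if (any(Wi <= 0)) stopf("initial weight Wi must be > 0")
  if (any(Wf < 0)) stopf("final weight Wf must be >= 0")
  (Wi - Wf) / Wi * 100
}

#' Pedicel scar size coefficient
#'
#' Weighted mean scar score over a berry subsample visually classed as small,
#' medium or large: `(1*Ns + 2*Nm + 3*Nl) / (Ns + Nm + Nl)`. Ranges from 1
#' (all small) to 3 (all large).
#'
#' @param Ns,Nm,Nl Non-negative integer counts of berries with small, medium
#'   and large scars. Vectorized.
#' @return Scar coefficient in `[1, 3]`.
#' @examples
#' scar_coefficient(4, 3, 3) # 1.9
#' @export
scar_coefficient <- function(Ns, Nm, Nl) {
  counts <- cbind(Ns, Nm, Nl)
  if (any(is.na(counts))) stopf("scar counts must not be missing")
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("scar counts must be non-negative integers")
  }
  tot <- Ns + Nm + Nl
  if (any(tot == 0)) stopf("at least one berry must be counted (all counts zero)")
  (1 * Ns + 2 * Nm + 3 * Nl) / tot
}

#' Specification of a baseline-difference derived trait
#'
#' Describes a delta trait: the difference between a base trait's value at a
#' storage time point and its value at a baseline time point (the 1-day
#' treatment by default), computed within genotype and year.
#'
#' @param base_trait Name of the source trait (e.g. `"firmness"`).
#' @param name Name for the derived trait (e.g. `"delta_firmness"`).
#' @param baseline_time Baseline time point label, default `"1D"`. Must
#'   precede all later time points.
#' @return An object of class `derived_trait_spec`.
#' @export
derived_trait_spec <- function(base_trait, name = paste0("delta_", base_trait),
                               baseline_time = "1D") {
  baseline_time <- as.character(baseline_time)
  if (!baseline_time %in% TIME_LEVELS) {
    stopf("baseline_time must be one of: %s", paste(TIME_LEVELS, collapse = ", "))
  }
  if (match(baseline_time, TIME_LEVELS) == length(TIME_LEVELS)) {
    stopf("baseline_time '%s' precedes no later time point", baseline_time)
  }
  structure(list(base_trait = as.character(base_trait), name = as.character(name),
                 baseline_time = baseline_time),
            class = "derived_trait_spec")
}

#' Compute a baseline-difference (delta) trait
#'
#' Adds rows for a derived trait equal to `value(t) - value(baseline)` at every
#' time point after the baseline, within each (genotype, year). Genotypes
#' lacking a baseline record in a year are skipped with a warning. Technical
#' reps are averaged before differencing.
#'
#' @param table A [phenotype_table()].
#' @param spec A [derived_trait_spec()].
#' @return A [phenotype_table()] containing the original records plus the new
#'   derived-trait rows (rep = 1).
#' @export
delta_trait <- function(table, spec) {
  stopifnot(inherits(spec, "derived_trait_spec"))
  base <- table[table$trait == spec$base_trait, , drop = FALSE]
  if (nrow(base) == 0) stopf("base trait '%s' not present in table", spec$base_trait)
  base <- average_reps(base)
  baseline_idx <- as.character(base$time_point) == spec$baseline_time
  baseline <- base[baseline_idx, , drop = FALSE]
  later <- base[as.character(base$time_point) %in%
                  TIME_LEVELS[seq_along(TIME_LEVELS) > match(spec$baseline_time, TIME_LEVELS)], ,
                drop = FALSE]
  key_b <- paste(baseline$genotype_id, baseline$year)
  key_l <- paste(later$genotype_id, later$year)
  hit <- match(key_l, key_b)
  skipped <- unique(later$genotype_id[is.na(hit)])
  if (length(skipped) > 0) {
    warnf("no %s baseline for %d genotype-year(s) (e.g. '%s'); their delta rows are skipped",
          spec$baseline_time, length(skipped), skipped[1])
  }
  keep <- !is.na(hit)
  new_rows <- later[keep, , drop = FALSE]
  if (nrow(new_rows) > 0) {
    new_rows$value <- new_rows$value - baseline$value[hit[keep]]
    new_rows$trait <- spec$name
    new_rows$rep <- 1L
  }
  out <- rbind(as.data.frame(table), as.data.frame(new_rows))
  phenotype_table(out)
}

#' Average technical reps
#'
#' Collapses technical repetitions to their arithmetic mean, one record per
#' (genotype, year, time point, trait). Fruit of all reps comes from the same
#' field experimental unit, so reps are not independent replicates and are
#' averaged before any mixed-model analysis. Idempotent.
#'
#' @param table A [phenotype_table()].
#' @return A [phenotype_table()] with `rep = 1` everywhere.
#' @export
average_reps <- function(table) {
  df <- as.data.frame(table)
  key <- paste(df$genotype_id, df$year, df$time_point, df$trait, sep = "\r")
  agg <- tapply(df$value, key, mean, na.rm = TRUE)
  first <- df[!duplicated(key), , drop = FALSE]
  first$value <- as.numeric(agg[paste(first$genotype_id, first$year,
                                      first$time_point, first$trait, sep = "\r")])
  first$rep <- 1L
  phenotype_table(first)
}
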