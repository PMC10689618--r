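#' Screen classification thresholds
#'
#' Container for the thresholds used in plate normalization and hit calling:
#' a well is toxic when its calcein (green) signal falls more than
#' `toxicity_fraction` below the plate median; a compound decreases or
#' increases phagocytosis when its normalized response crosses
#' `decrease_cut_pct` / `increase_cut_pct` at a concentration above
#' `dose_gate_um`; crossings confined to concentrations above `high_dose_um`
#' are reported as the "above 20 uM" subcategories.
#'
#' @param toxicity_fraction Fractional calcein loss vs plate median that
#'   flags a well toxic (default 0.30).
#' @param decrease_cut_pct Percent-of-median below which a response counts as
#'   decreasing (default 70).
#' @param increase_cut_pct Percent-of-median above which a response counts as
#'   increasing (default 130).
#' @param dose_gate_um Concentration gate in uM; only points strictly above
#'   it are considered for classification (default 5).
#' @param high_dose_um Concentration in uM above which crossings fall in the
#'   "_gt20" subcategories (default 20).
#' @return An object of class `screen_thresholds`.
#' @examples
#' screen_thresholds()
#' @export
screen_thresholds <- function(toxicity_fraction = 0.30,
                              decrease_cut_pct = 70,
                              increase_cut_pct = 130,
                              dose_gate_um = 5,
                              high_dose_um = 20) {
  if (!(toxicity_fraction > 0 && toxicity_fraction < 1)) {
    stop("toxicity_fraction must be in (0, 1)")
  }
  if (!(decrease_cut_pct > 0 && decrease_cut_pct < 100 &&
        increase_cut_pct > 100)) {
    stop("need 0 < decrease_cut_pct < 100 < increase_cut_pct")
  }
  if (dose_gate_um < 0 || high_dose_um <= dose_gate_um) {
    stop("need 0 <= dose_gate_um < high_dose_um")
  }
  structure(
    list(toxicity_fraction = toxicity_fraction,
         decrease_cut_pct = decrease_cut_pct,
         increase_cut_pct = increase_cut_pct,
         dose_gate_um = dose_gate_um,
         high_dose_um = high_dose_um),
    class = "screen_thresholds"
  )
}

#' Read screen thresholds from a YAML file
#'
#' Keys absent from the file keep their [screen_thresholds()] defaults.
#'
#' @param path Path to a YAML file whose top-level keys are threshold names.
#' @return A `screen_thresholds` object.
#' @export
read_thresholds_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(screen_thresholds))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) stop("unknown threshold keys: ", paste(bad, collapse = ", "))
  do.call(screen_thresholds, vals)
}
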