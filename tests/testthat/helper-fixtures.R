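# Shared fixture builders. Everything is generated in code; no binary data.

# A minimal single-plate well table. `green` / `red` vectors fill the data
# wells in order; controls get fixed sane values unless overridden.
make_plate <- function(red, green, plate_id = "P1",
                       compound = sprintf("C%03d", seq_along(red)),
                       conc = rep(10, length(red))) {
  n <- length(red)
  data.frame(
    plate_id = plate_id,
    well_row = rep(LETTERS[6:16], length.out = n),
    well_col = rep(seq_len(22), length.out = n),
    role = "data",
    compound_id = compound,
    concentration_um = conc,
    red_intensity = red,
    green_intensity = green,
    stringsAsFactors = FALSE)
}

add_controls <- function(plate, high_green = 1000, high_red = 400,
                         low_green = 20, low_red = 8) {
  ctrl <- data.frame(
    plate_id = plate$plate_id[1],
    well_row = c("A", "A", "F"),
    well_col = c(1L, 2L, 23L),
    role = c("high_control", "high_control", "low_control"),
    compound_id = NA_character_,
    concentration_um = NA_real_,
    red_intensity = c(high_red, high_red, low_red),
    green_intensity = c(high_green, high_green, low_green),
    stringsAsFactors = FALSE)
  rbind(plate, ctrl)
}

# Dose series data.frame for classify_compound / fit_dose_response.
make_series <- function(pct, toxic = rep(FALSE, length(pct)),
                        doses = c(1.39, 2.78, 5.56, 11.11, 22.22)) {
  data.frame(concentration_um = doses, pct_phagocytosis = pct, toxic = toxic)
}

screen_doses <- c(1.39, 2.78, 5.56, 11.11, 22.22)

# Evaluate the four-parameter logistic used throughout.
fpl <- function(conc, bottom, top, ec50, slope) {
  bottom + (top - bottom) / (1 + (conc / ec50)^slope)
}

# Patient-table fixture built from per-patient event lists.
# events: list(person_id = list(exp = ages, dx = ages, inpat = ages,
#                               dx_lagged = ages)) -- minimal rules fixture.
make_patients <- function(exposure_ages, diagnosis_ages, obs_end = 40,
                          visits = NULL, extra_dx = NULL) {
  ids <- union(names(exposure_ages), names(diagnosis_ages))
  persons <- data.frame(person_id = ids, obs_start_age = 0,
                        obs_end_age = obs_end, stringsAsFactors = FALSE)
  mk <- function(lst, concept) {
    if (!length(lst)) return(data.frame(person_id = character(0),
                                        concept_id = character(0),
                                        age = numeric(0)))
    data.frame(person_id = rep(names(lst), lengths(lst)),
               concept_id = concept, age = unlist(lst, use.names = FALSE),
               stringsAsFactors = FALSE)
  }
  exposures <- mk(exposure_ages, "RX")
  diagnoses <- mk(diagnosis_ages, "DX")
  if (!is.null(extra_dx)) diagnoses <- rbind(diagnoses, extra_dx)
  if (is.null(visits)) {
    visits <- data.frame(person_id = character(0), visit_type = character(0),
                         age = numeric(0), stringsAsFactors = FALSE)
  }
  list(persons = persons, exposures = exposures, diagnoses = diagnoses,
       visits = visits)
}

# Direction-level call (increase/decrease families collapsed) for
# sensitivity / false-discovery summaries.
call_direction <- function(call) {
  ifelse(call %in% c("increase", "increase_gt20"), "increase",
         ifelse(call %in% c("decrease", "decrease_gt20"), "decrease", call))
}
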