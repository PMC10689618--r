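# Plate-level normalization: red:green ratios as percent of the plate
# median, with calcein-based toxicity flags.

.well_cols <- c("plate_id", "well_row", "well_col", "role", "compound_id",
                "concentration_um", "red_intensity", "green_intensity")
.well_roles <- c("data", "high_control", "low_control", "positive_control")

#' Read a plate well table from CSV
#'
#' Expects the eight well columns (plate_id, well_row, well_col, role,
#' compound_id, concentration_um, red_intensity, green_intensity) with a
#' header row. Rows are returned grouped by plate (stable within plate).
#'
#' @param path CSV path.
#' @return A validated well data.frame.
#' @export
read_well_table <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(.well_cols, names(raw))
  if (length(missing)) {
    stop("well table is missing column(s): ", paste(missing, collapse = ", "))
  }
  raw <- raw[, .well_cols]
  num <- function(col) {
    x <- raw[[col]]
    x[x == ""] <- NA
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           ": '", x[bad[1]], "'")
    }
    v
  }
  raw$well_col <- as.integer(num("well_col"))
  raw$concentration_um <- num("concentration_um")
  raw$red_intensity <- num("red_intensity")
  raw$green_intensity <- num("green_intensity")
  raw$compound_id[raw$compound_id == ""] <- NA
  bad_role <- setdiff(unique(raw$role), .well_roles)
  if (length(bad_role)) {
    stop("unknown well role(s): ", paste(bad_role, collapse = ", "))
  }
  out <- raw[order(match(raw$plate_id, unique(raw$plate_id))), ]
  rownames(out) <- NULL
  out
}

#' Flag toxic wells on one plate
#'
#' A data well is toxic when its calcein (green) signal has dropped more than
#' `toxicity_fraction` below the plate's median green over data wells, i.e.
#' strictly `green < (1 - toxicity_fraction) * median(green_data)`. Control
#' wells get `NA` (the rule is defined for compound-treated wells).
#'
#' @param plate Well data.frame for a single plate.
#' @param thresholds A [screen_thresholds()].
#' @return Logical vector along the rows of `plate` (NA for control wells).
#' @export
flag_toxic_wells <- function(plate, thresholds = screen_thresholds()) {
  is_data <- plate$role == "data"
  if (!any(is_data)) stop("plate has no data wells")
  g <- plate$green_intensity[is_data]
  med <- stats::median(g)
  if (!is.finite(med) || med <= 0) {
    stop("degenerate plate: median data-well green signal is not positive")
  }
  toxic <- rep(NA, nrow(plate))
  toxic[is_data] <- plate$green_intensity[is_data] <
    (1 - thresholds$toxicity_fraction) * med
  toxic
}

#' Normalize one plate to percent of the plate median red:green ratio
#'
#' Computes `rg_ratio = red / green` per well and expresses data-well ratios
#' as percent of the reference ratio: by default the median `rg_ratio` over
#' non-toxic data wells ("plate_median"); with
#' `normalize_to = "high_control"` the median over high-control wells
#' (percent of non-treated controls). Toxic wells are excluded from the
#' plate median but still reported; zero-green wells get `NA` ratios.
#' Control wells carry `pct_phagocytosis` relative to the same reference for
#' QC display.
#'
#' @param plate Well data.frame for a single plate.
#' @param thresholds A [screen_thresholds()].
#' @param normalize_to `"plate_median"` (default) or `"high_control"`.
#' @return `plate` with added columns rg_ratio, pct_phagocytosis, toxic,
#'   plate_median_green, plate_median_rg.
#' @export
normalize_plate <- function(plate, thresholds = screen_thresholds(),
                            normalize_to = c("plate_median", "high_control")) {
  normalize_to <- match.arg(normalize_to)
  toxic <- flag_toxic_wells(plate, thresholds)
  rg <- ifelse(plate$green_intensity > 0,
               plate$red_intensity / plate$green_intensity, NA_real_)
  is_data <- plate$role == "data"
  ok <- is_data & !toxic & !is.na(rg)
  ref_rows <- if (normalize_to == "plate_median") ok
              else plate$role == "high_control" & !is.na(rg)
  if (!any(ref_rows)) {
    stop("degenerate plate: no usable wells for the ", normalize_to,
         " reference")
  }
  ref <- stats::median(rg[ref_rows])
  if (!is.finite(ref) || ref <= 0) {
    stop("degenerate plate: reference red:green ratio is not positive")
  }
  plate$rg_ratio <- rg
  plate$pct_phagocytosis <- 100 * rg / ref
  plate$toxic <- toxic
  plate$plate_median_green <-
    stats::median(plate$green_intensity[is_data])
  plate$plate_median_rg <- ref
  plate
}

#' Normalize a multi-plate screen
#'
#' Applies [normalize_plate()] per plate_id and re-assembles the table.
#'
#' @inheritParams normalize_plate
#' @param wells Well data.frame covering one or more plates.
#' @return Normalized well data.frame.
#' @export
normalize_screen <- function(wells, thresholds = screen_thresholds(),
                             normalize_to = c("plate_median", "high_control")) {
  normalize_to <- match.arg(normalize_to)
  parts <- split(wells, factor(wells$plate_id, levels = unique(wells$plate_id)))
  out <- do.call(rbind, lapply(parts, normalize_plate,
                               thresholds = thresholds,
                               normalize_to = normalize_to))
  rownames(out) <- NULL
  out
}

#' Per-plate control summary for QC
#'
#' Medians of raw red and green intensity per well role (high_control,
#' low_control, positive_control, data), with no toxicity filtering.
#' Missing roles produce a warning and NA medians.
#'
#' @param plate Well data.frame for a single plate.
#' @return data.frame with columns role, n_wells, median_red, median_green.
#' @export
plate_control_summary <- function(plate) {
  out <- do.call(rbind, lapply(.well_roles, function(r) {
    sel <- plate$role == r
    data.frame(role = r, n_wells = sum(sel),
               median_red = if (any(sel)) stats::median(plate$red_intensity[sel]) else NA_real_,
               median_green = if (any(sel)) stats::median(plate$green_intensity[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  absent <- setdiff(c("high_control", "low_control"), plate$role)
  if (length(absent)) {
    warning("plate lacks control role(s): ", paste(absent, collapse = ", "))
  }
  rownames(out) <- NULL
  out
}
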