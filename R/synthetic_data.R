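# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised against these planted-truth inputs; no external data needed.

#' Configuration for a synthetic phagocytosis screen
#'
#' Defaults reproduce the screen's study conditions: 3,280 library compounds
#' dosed at 1.39, 2.78, 5.56, 11.11 and 22.22 uM in singlicate on 384-well
#' plates with four high-control rows, one positive-control row and no-cell
#' low-control wells.
#'
#' @param n_compounds Number of library compounds.
#' @param doses_um Dose ladder in uM, strictly increasing, all > 0.
#' @param frac_increase,frac_decrease,frac_toxic Fractions of compounds
#'   planted as increasing, decreasing or toxic; the remainder are inert.
#'   Labels are assigned by count (first `floor(f * n)` compounds of a seeded
#'   shuffle), not by coin flips, so truth counts are exact.
#' @param effect_increase_pct,effect_decrease_pct Planted normalized response
#'   (percent of plate median) for increase/decrease hits at doses above the
#'   gate.
#' @param toxic_green_fraction Fraction of the typical calcein signal left in
#'   a toxic well at doses above the gate (default 0.5, i.e. a 50% loss).
#' @param cv_noise Coefficient of variation of independent multiplicative
#'   lognormal noise applied to the red and green channels.
#' @param plate_format Wells per plate; 384 (16 x 24) or 96 (8 x 12).
#' @param seed Integer seed.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_compounds = 3280,
                              doses_um = c(1.39, 2.78, 5.56, 11.11, 22.22),
                              frac_increase = 0.05,
                              frac_decrease = 0.05,
                              frac_toxic = 0.02,
                              effect_increase_pct = 140,
                              effect_decrease_pct = 50,
                              toxic_green_fraction = 0.5,
                              cv_noise = 0.05,
                              plate_format = 384,
                              seed = 1) {
  if (frac_increase + frac_decrease + frac_toxic > 1) {
    stop("planted fractions must sum to at most 1")
  }
  if (any(doses_um <= 0) || is.unsorted(doses_um, strictly = TRUE)) {
    stop("doses_um must be positive and strictly increasing")
  }
  if (cv_noise < 0) stop("cv_noise must be >= 0")
  if (!(toxic_green_fraction > 0 && toxic_green_fraction < 0.7)) {
    stop("toxic_green_fraction must be in (0, 0.7) to plant detectable toxicity")
  }
  structure(as.list(environment()), class = "screen_sim_config")
}

# Plate geometry: rows A-D high control, row E positive control, last two
# columns of the remaining rows low control (no cells), the rest data wells.
plate_layout <- function(plate_format) {
  dims <- switch(as.character(plate_format),
                 "384" = c(16L, 24L),
                 "96" = c(8L, 12L),
                 stop("unsupported plate_format: ", plate_format,
                      " (supported: 384, 96)"))
  nr <- dims[1]; nc <- dims[2]
  rows <- LETTERS[seq_len(nr)]
  grid <- expand.grid(well_row = rows, well_col = seq_len(nc),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ri <- match(grid$well_row, rows)
  grid$role <- "data"
  grid$role[ri <= 4L] <- "high_control"
  grid$role[ri == 5L] <- "positive_control"
  grid$role[ri > 5L & grid$well_col > nc - 2L] <- "low_control"
  n_data <- sum(grid$role == "data")
  if (n_data < 1L) stop("plate format leaves no data wells")
  grid[order(ri, grid$well_col), ]
}

#' Generate a synthetic phagocytosis screen with planted ground truth
#'
#' Lays compounds out across as many plates as the dose ladder requires and
#' draws raw red (pHrodo) and green (calcein) integrated intensities around a
#' common baseline. Planted `increase` / `decrease` compounds shift the
#' red:green ratio to the configured percent of the plate median at doses
#' above 5 uM; planted `toxic` compounds lose green signal (and red
#' proportionally: dead cells neither retain calcein nor phagocytose) at
#' those doses. Noise is independent multiplicative lognormal per channel.
#'
#' @param config A [screen_sim_config()].
#' @return A list with `wells` (data.frame with columns plate_id, well_row,
#'   well_col, role, compound_id, concentration_um, red_intensity,
#'   green_intensity), `truth` (data.frame compound_id, true_class) and the
#'   `config` used.
#' @examples
#' scr <- gen_screen(screen_sim_config(n_compounds = 100, seed = 7))
#' table(scr$truth$true_class)
#' @export
gen_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  layout <- plate_layout(config$plate_format)
  n_data <- sum(layout$role == "data")
  doses <- config$doses_um
  needed <- config$n_compounds * length(doses)
  n_plates <- ceiling(needed / n_data)

  with_seed(config$seed, {
    ids <- sprintf("CPD%05d", seq_len(config$n_compounds))
    shuffled <- sample(ids)
    n_inc <- floor(config$frac_increase * config$n_compounds)
    n_dec <- floor(config$frac_decrease * config$n_compounds)
    n_tox <- floor(config$frac_toxic * config$n_compounds)
    true_class <- rep("no_effect", config$n_compounds)
    true_class[seq_len(n_inc)] <- "increase"
    true_class[n_inc + seq_len(n_dec)] <- "decrease"
    true_class[n_inc + n_dec + seq_len(n_tox)] <- "toxic"
    truth <- data.frame(compound_id = shuffled, true_class = true_class,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$compound_id), ]
    rownames(truth) <- NULL

    wells <- do.call(rbind, lapply(seq_len(n_plates), function(p) {
      w <- layout
      w$plate_id <- sprintf("PLATE%03d", p)
      w
    }))
    wells$compound_id <- NA_character_
    wells$concentration_um <- NA_real_

    # plate in natural id order: the seeded label shuffle above scatters
    # planted classes across plates, keeping every plate median anchored by
    # inert compounds
    is_data <- wells$role == "data"
    slots <- which(is_data)[seq_len(needed)]
    wells$compound_id[slots] <- rep(ids, each = length(doses))
    wells$concentration_um[slots] <- rep(doses, times = config$n_compounds)
    # drop unfilled data wells on the last plate (not plated in practice)
    wells <- wells[!(is_data & is.na(wells$compound_id)), ]

    # baseline intensities (arbitrary fluorescence units)
    green0 <- 5e5
    red0 <- 2e5

    cls <- truth$true_class[match(wells$compound_id, truth$compound_id)]
    gated <- !is.na(wells$concentration_um) &
      wells$concentration_um > 5  # planted effects act above the screen gate
    red_mult <- rep(1, nrow(wells))
    green_mult <- rep(1, nrow(wells))
    sel <- gated & cls == "increase"
    red_mult[sel] <- config$effect_increase_pct / 100
    sel <- gated & cls == "decrease"
    red_mult[sel] <- config$effect_decrease_pct / 100
    sel <- gated & cls == "toxic"
    red_mult[sel] <- config$toxic_green_fraction
    green_mult[sel] <- config$toxic_green_fraction

    # controls
    pos <- wells$role == "positive_control"
    red_mult[pos] <- 0.3  # strong planted decrease control
    low <- wells$role == "low_control"
    red_mult[low] <- 0.02
    green_mult[low] <- 0.02

    n <- nrow(wells)
    wells$red_intensity <- red0 * red_mult * lognormal_factor(n, config$cv_noise)
    wells$green_intensity <- green0 * green_mult * lognormal_factor(n, config$cv_noise)

    wells <- wells[, c("plate_id", "well_row", "well_col", "role",
                       "compound_id", "concentration_um",
                       "red_intensity", "green_intensity")]
    rownames(wells) <- NULL
    list(wells = wells, truth = truth, config = config)
  })
}

#' Generate synthetic per-dose phagocytosis time courses
#'
#' Hourly engulfment signal following a saturating accumulation curve
#' `A(dose) * (1 - exp(-t / tau))`, where the plateau `A` follows a
#' four-parameter logistic in dose. A vehicle (dose 0) series is always
#' included; its plateau is the logistic `top`.
#'
#' @param doses_um Positive doses in uM (vehicle is added automatically).
#' @param hill List with `top`, `bottom` (plateau signals), `ec50_um`,
#'   `slope` (> 0 gives a decreasing dose-response).
#' @param hours Number of hourly frames (>= 2); times are 1..hours.
#' @param tau_h Accumulation time constant in hours.
#' @param cv_noise CV of multiplicative lognormal noise on the signal.
#' @param seed Integer seed.
#' @return data.frame with columns dose_um, hour, signal.
#' @export
gen_timecourses <- function(doses_um,
                            hill = list(top = 100, bottom = 40,
                                        ec50_um = 5, slope = 1),
                            hours = 24, tau_h = 6, cv_noise = 0, seed = 1) {
  if (hours < 2) stop("hours must be >= 2")
  if (any(doses_um <= 0)) stop("doses_um must be positive (vehicle is implicit)")
  doses <- c(0, sort(unique(doses_um)))
  plateau <- hill$bottom +
    (hill$top - hill$bottom) / (1 + (doses / hill$ec50_um)^hill$slope)
  tgrid <- seq_len(hours)
  out <- expand.grid(hour = tgrid, dose_um = doses,
                     KEEP.OUT.ATTRS = FALSE)
  out$signal <- rep(plateau, each = hours) * (1 - exp(-out$hour / tau_h))
  with_seed(seed, {
    out$signal <- out$signal * lognormal_factor(nrow(out), cv_noise)
  })
  out[, c("dose_um", "hour", "signal")]
}

#' Configuration for synthetic drug-network tables
#'
#' Defaults mirror the meta-analysis scale: 239 screened drugs with
#' protein-binding targets split 52 / 43 / 144 into increase / decrease /
#' no-effect groups, a 1,947-gene disease-gene universe, and 77
#' neuropsychiatric phenotypes partitioned into 10 clusters.
#'
#' @param n_drugs Named integer vector: drugs per effect group.
#' @param gene_universe_size Size of the disease-gene universe.
#' @param n_phenotypes,n_clusters Phenotype annotation scale.
#' @param planted data.frame with columns `gene` plus one per-group presence
#'   probability column per effect group (prob_increase, prob_decrease,
#'   prob_no_effect). Planted genes let effect groups share disease genes at
#'   controlled rates. `NULL` plants nothing.
#' @param mean_genes_per_drug Poisson mean of background network size.
#' @param genes_per_phenotype Genes annotated to each phenotype.
#' @param seed Integer seed.
#' @return A `network_sim_config` list.
#' @export
network_sim_config <- function(n_drugs = c(increase = 52, decrease = 43,
                                           no_effect = 144),
                               gene_universe_size = 1947,
                               n_phenotypes = 77,
                               n_clusters = 10,
                               planted = NULL,
                               mean_genes_per_drug = 30,
                               genes_per_phenotype = 25,
                               seed = 1) {
  stopifnot(all(n_drugs >= 0), gene_universe_size > 0,
            n_clusters <= n_phenotypes)
  if (!is.null(planted)) {
    probs <- planted[, setdiff(names(planted), "gene"), drop = FALSE]
    if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
      stop("planted presence probabilities must be in [0, 1]")
    }
    if (nrow(planted) > gene_universe_size) {
      stop("gene universe smaller than the planted gene list")
    }
  }
  structure(as.list(environment()), class = "network_sim_config")
}

#' Generate synthetic drug-network / phenotype / cluster tables
#'
#' Each drug's network is a uniform sample of universe genes (Poisson size)
#' plus planted genes included independently with the configured per-group
#' probabilities. Phenotypes are annotated to random gene subsets and
#' partitioned round-robin into clusters.
#'
#' @param config A [network_sim_config()].
#' @return A [drug_network_set()] with an extra `planted` element echoing the
#'   planted-gene table.
#' @export
gen_network_tables <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  with_seed(config$seed, {
    genes <- sprintf("G%04d", seq_len(config$gene_universe_size))
    planted <- config$planted
    if (!is.null(planted)) {
      bad <- setdiff(planted$gene, genes)
      if (length(bad)) stop("planted genes outside universe: ",
                            paste(bad, collapse = ", "))
    }
    groups <- rep(names(config$n_drugs), times = config$n_drugs)
    drugs <- sprintf("DRUG%04d", seq_along(groups))
    names(groups) <- drugs

    drug_genes <- lapply(seq_along(drugs), function(i) {
      size <- stats::rpois(1, config$mean_genes_per_drug)
      gs <- sample(genes, min(size, length(genes)))
      if (!is.null(planted)) {
        pcol <- paste0("prob_", groups[i])
        if (!pcol %in% names(planted)) {
          stop("planted table lacks column ", pcol)
        }
        keep <- stats::runif(nrow(planted)) < planted[[pcol]]
        gs <- union(gs, planted$gene[keep])
      }
      sort(gs)
    })
    names(drug_genes) <- drugs

    phen <- sprintf("CUI%04d", seq_len(config$n_phenotypes))
    gene_phenotypes <- do.call(rbind, lapply(phen, function(p) {
      data.frame(gene_id = sample(genes,
                                  min(config$genes_per_phenotype, length(genes))),
                 phenotype_id = p, stringsAsFactors = FALSE)
    }))
    clusters <- sprintf("cluster%02d",
                        rep_len(seq_len(config$n_clusters), config$n_phenotypes))
    names(clusters) <- phen

    nets <- drug_network_set(drug_genes = drug_genes,
                             gene_phenotypes = gene_phenotypes,
                             phenotype_clusters = clusters,
                             drug_groups = groups)
    nets$planted <- planted
    nets
  })
}

#' Configuration for a synthetic patient cohort
#'
#' Emulates the observational study design at desk scale: patients may
#' receive a pediatric beta-2-agonist exposure (ages drawn within
#' `exposure_age_range`), all carry an adult schizophrenia diagnosis (the
#' cohort index event, after age `diagnosis_age_min`), and inpatient
#' outcome visits occur at exponential times with hazard
#' `baseline_hazard * exp(log(true_hr) * exposed + sum(beta_outcome * z))`,
#' administratively censored at `max_followup_years`. Exposure is assigned by
#' a logistic model on the confounders, so the crude hazard ratio is
#' confounded whenever a confounder has nonzero effects on both exposure and
#' outcome.
#'
#' Default confounding (a binary "asthma" covariate, prevalence 0.3, +3
#' log-odds on exposure, +0.5 log-hazard on outcome) inflates the crude HR
#' roughly 30% above the true HR of 0.75.
#'
#' @param n_patients Number of patients.
#' @param true_hr Planted hazard ratio of exposure on the outcome (> 0).
#' @param confounders data.frame with columns name, type ("binary" or
#'   "normal"), par1, par2 (prob / mean, sd), beta_exposure (log-odds),
#'   beta_outcome (log-hazard); `NULL` for an unconfounded cohort.
#' @param exposure_intercept Logistic intercept for exposure assignment.
#' @param baseline_hazard Outcome events per person-year at covariates 0,
#'   unexposed.
#' @param max_followup_years Administrative censoring horizon after index.
#' @param exposure_age_range Closed age interval of pediatric exposure.
#' @param diagnosis_age_min Diagnoses are planted strictly after this age.
#' @param seed Integer seed.
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n_patients = 20000,
                              true_hr = 0.75,
                              confounders = data.frame(
                                name = "asthma", type = "binary",
                                par1 = 0.3, par2 = NA,
                                beta_exposure = 3, beta_outcome = 0.5,
                                stringsAsFactors = FALSE),
                              exposure_intercept = -2,
                              baseline_hazard = 0.05,
                              max_followup_years = 10,
                              exposure_age_range = c(6, 18),
                              diagnosis_age_min = 18,
                              seed = 1) {
  if (true_hr <= 0) stop("true_hr must be > 0")
  if (exposure_age_range[1] < 0 ||
      exposure_age_range[2] > diagnosis_age_min) {
    stop("exposure_age_range must lie within [0, diagnosis_age_min]")
  }
  if (baseline_hazard < 0 || max_followup_years < 0) {
    stop("baseline_hazard and max_followup_years must be >= 0")
  }
  structure(as.list(environment()), class = "cohort_sim_config")
}

# concept ids used by the generator (OMOP-like strings, not real vocabulary)
.concept <- list(exposure = "RX_ADRB2_AGONIST",
                 disease = "DX_SCHIZOPHRENIA",
                 distractor_rx = "RX_OTHER",
                 distractor_dx = "DX_ASTHMA")

#' Generate a synthetic patient table with planted survival truth
#'
#' @param config A [cohort_sim_config()].
#' @return List with `persons` (person_id, obs_start_age, obs_end_age,
#'   covariate columns), `exposures`, `diagnoses`, `visits` (long event
#'   tables keyed by person_id) and `truth` (person_id, true_exposure,
#'   true_event, true_event_time) where `true_event_time` is years from
#'   index to event or censoring.
#' @export
gen_patient_table <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("P%06d", seq_len(n))
    conf <- config$confounders
    Z <- NULL
    lin_exp <- rep(config$exposure_intercept, n)
    lin_out <- rep(0, n)
    if (!is.null(conf) && nrow(conf) > 0) {
      Z <- sapply(seq_len(nrow(conf)), function(j) {
        switch(conf$type[j],
               binary = stats::rbinom(n, 1, conf$par1[j]),
               normal = stats::rnorm(n, conf$par1[j], conf$par2[j]),
               stop("unknown confounder type: ", conf$type[j]))
      })
      Z <- matrix(Z, nrow = n)
      colnames(Z) <- conf$name
      lin_exp <- lin_exp + drop(Z %*% conf$beta_exposure)
      lin_out <- lin_out + drop(Z %*% conf$beta_outcome)
    }
    exposed <- stats::rbinom(n, 1, expit(lin_exp)) == 1

    exp_age <- stats::runif(n, config$exposure_age_range[1],
                            config$exposure_age_range[2])
    index_age <- stats::runif(n, config$diagnosis_age_min + 1,
                              config$diagnosis_age_min + 12)

    rate <- config$baseline_hazard *
      exp(log(config$true_hr) * exposed + lin_out)
    t_event <- stats::rexp(n, rate = pmax(rate, .Machine$double.xmin))
    event <- t_event < config$max_followup_years &
      config$max_followup_years > 0
    t_obs <- pmin(t_event, config$max_followup_years)
    obs_end <- index_age + t_obs

    persons <- data.frame(person_id = pid, obs_start_age = 0,
                          obs_end_age = obs_end, stringsAsFactors = FALSE)
    if (!is.null(Z)) persons <- cbind(persons, as.data.frame(Z))

    # pediatric exposure for exposed; a few adult-only distractor exposures
    # among the unexposed (must NOT qualify: age > 18)
    adult_rx <- !exposed & stats::runif(n) < 0.05
    exposures <- rbind(
      data.frame(person_id = pid[exposed],
                 concept_id = .concept$exposure,
                 age = exp_age[exposed], stringsAsFactors = FALSE),
      data.frame(person_id = pid[adult_rx],
                 concept_id = .concept$exposure,
                 age = index_age[adult_rx] + 0.5, stringsAsFactors = FALSE),
      data.frame(person_id = pid[stats::runif(n) < 0.10],
                 concept_id = .concept$distractor_rx,
                 age = 20, stringsAsFactors = FALSE)
    )

    diagnoses <- data.frame(person_id = pid,
                            concept_id = .concept$disease,
                            age = index_age, stringsAsFactors = FALSE)
    if (!is.null(Z) && "asthma" %in% colnames(Z)) {
      asthmatic <- Z[, "asthma"] == 1
      diagnoses <- rbind(diagnoses,
                         data.frame(person_id = pid[asthmatic],
                                    concept_id = .concept$distractor_dx,
                                    age = stats::runif(sum(asthmatic), 3, 12),
                                    stringsAsFactors = FALSE))
    }

    # outcome: inpatient visit at the event age with a disease diagnosis
    # logged 0-3 days after the visit (billing lag)
    ev <- which(event)
    lag <- stats::runif(length(ev), 0, 3) / 365.25
    visits <- data.frame(person_id = pid[ev],
                         visit_type = rep("inpatient", length(ev)),
                         age = index_age[ev] + t_event[ev],
                         stringsAsFactors = FALSE)
    diagnoses <- rbind(diagnoses,
                       data.frame(person_id = pid[ev],
                                  concept_id = rep(.concept$disease, length(ev)),
                                  age = index_age[ev] + t_event[ev] + lag,
                                  stringsAsFactors = FALSE))
    # outpatient noise visits (never qualify as outcomes)
    outp <- stats::runif(n) < 0.3
    visits <- rbind(visits,
                    data.frame(person_id = pid[outp], visit_type = "outpatient",
                               age = index_age[outp] + 0.25,
                               stringsAsFactors = FALSE))
    # keep visit/diagnosis records inside the observation window
    visits <- visits[visits$age <= obs_end[match(visits$person_id, pid)], ]

    truth <- data.frame(person_id = pid, true_exposure = exposed,
                        true_event = event, true_event_time = t_obs,
                        stringsAsFactors = FALSE)
    list(persons = persons, exposures = exposures, diagnoses = diagnoses,
         visits = visits, truth = truth, config = config)
  })
}

#' Write a well table (and optional truth sidecar) to CSV
#'
#' @param screen Output of [gen_screen()] or a well data.frame.
#' @param path Output CSV path for the well table.
#' @param truth_path Optional path for the compound_id,true_class sidecar.
#' @return `path`, invisibly.
#' @export
write_well_table <- function(screen, path, truth_path = NULL) {
  wells <- if (is.data.frame(screen)) screen else screen$wells
  utils::write.csv(wells, path, row.names = FALSE, na = "")
  if (!is.null(truth_path) && !is.data.frame(screen)) {
    utils::write.csv(screen$truth, truth_path, row.names = FALSE)
  }
  invisible(path)
}
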