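## Deterministic synthetic hospital source dataset. Emulates the relational
## schema of a hospital information system feeding every archetype
## pipeline: patients admitted to the emergency room or hospitalized over
## a fixed study window, with episodes, diagnoses, drug orders and
## administrations, unit movements, clinical and laboratory observations,
## procedures and limitation-of-life-sustaining-treatment flags. Event
## counts are Poisson per episode and event times uniform within the
## episode span: distributional realism is irrelevant to the
## transformation contract being exercised. Local codes are drawn from the
## packaged toy dictionary so every coded value is bindable offline.

#' Synthetic source generator configuration
#'
#' @param seed integer RNG seed; the same seed yields byte-identical files.
#' @param n_patients number of patients in the cohort.
#' @param episode_rate extra episodes per patient beyond the guaranteed
#'   first (Poisson mean).
#' @param diagnosis_rate,prescription_rate,administration_rate,movement_rate,clinical_obs_rate,lab_obs_rate,procedure_rate
#'   Poisson means per episode for each event entity.
#' @param llst_prob per-episode probability of a
#'   limitation-of-life-sustaining-treatment flag.
#' @param death_prob per-patient probability that the final episode ends in
#'   death.
#' @param window_start,window_end study window (dates, inclusive);
#'   defaults to the first-to-sixth pandemic-wave window the cohort
#'   emulates.
#' @param timezone source wall-clock timezone.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(seed = 20200217L, n_patients = 30L,
                         episode_rate = 0.8, diagnosis_rate = 2,
                         prescription_rate = 1.5, administration_rate = 1.5,
                         movement_rate = 1.2, clinical_obs_rate = 3,
                         lab_obs_rate = 3, procedure_rate = 0.6,
                         llst_prob = 0.05, death_prob = 0.1,
                         window_start = "2020-02-17",
                         window_end = "2022-02-15",
                         timezone = "Europe/Madrid") {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              episode_rate = episode_rate, diagnosis_rate = diagnosis_rate,
              prescription_rate = prescription_rate,
              administration_rate = administration_rate,
              movement_rate = movement_rate,
              clinical_obs_rate = clinical_obs_rate,
              lab_obs_rate = lab_obs_rate, procedure_rate = procedure_rate,
              llst_prob = llst_prob, death_prob = death_prob,
              window_start = window_start, window_end = window_end,
              timezone = timezone)
  rates <- cfg[c("episode_rate", "diagnosis_rate", "prescription_rate",
                 "administration_rate", "movement_rate", "clinical_obs_rate",
                 "lab_obs_rate", "procedure_rate")]
  if (cfg$n_patients < 1L || any(unlist(rates) < 0) ||
      cfg$llst_prob < 0 || cfg$llst_prob > 1 ||
      cfg$death_prob < 0 || cfg$death_prob > 1)
    abort2("invalid generator configuration: counts/rates must be non-negative",
           "ehr2omop_config_error")
  if (as.Date(cfg$window_start) >= as.Date(cfg$window_end))
    abort2("invalid generator configuration: window start must precede end",
           "ehr2omop_config_error")
  structure(cfg, class = "synth_config")
}

code_pool <- function(map, local_system) {
  map$table$local_code[map$table$local_system == local_system]
}

fmt_local <- function(epoch, tz)
  format(as.POSIXct(epoch, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%d %H:%M:%S", tz = tz)

#' Generate the synthetic hospital source dataset
#'
#' Writes one CSV per source entity (patients, episodes, diagnoses,
#' drug_prescriptions, drug_administrations, movements,
#' clinical_observations, laboratory_observations, procedures, llst) with
#' referentially consistent keys, plus `manifest.json` recording the seed
#' and exact per-entity row counts.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if needed); with `NULL`
#'   nothing is written and the tables are only returned.
#' @return Invisibly, a list with `tables` (named list of data frames) and
#'   `manifest`.
#' @examples
#' src <- generate_synthetic_source(synth_config(seed = 1, n_patients = 5))
#' src$manifest$counts$patients
#' @export
generate_synthetic_source <- function(config = synth_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tz <- config$timezone
  map <- concept_map()
  pool <- list(diag = code_pool(map, "HIS-DIAG"), clin = code_pool(map, "HIS-CLIN"),
               lab = code_pool(map, "HIS-LAB"), drug = code_pool(map, "HIS-DRUG"),
               proc = code_pool(map, "HIS-PROC"), unit = code_pool(map, "HIS-UNIT"),
               llst = code_pool(map, "HIS-LLST"), route = code_pool(map, "HIS-ROUTE"))
  w0 <- as.numeric(as.POSIXct(paste(config$window_start, "00:00:00"), tz = "UTC"))
  w1 <- as.numeric(as.POSIXct(paste(config$window_end, "00:00:00"), tz = "UTC"))
  src <- "SAP-HIS"

  n <- config$n_patients
  patients <- data.frame(
    patient_id = sprintf("PAT%05d", seq_len(n)),
    sex_code = sample(c("SEX-M", "SEX-F"), n, replace = TRUE),
    birth_date = format(as.Date("1935-01-01") +
                          floor(runif(n, 0, 75 * 365.25)), "%Y-%m-%d"),
    source = src)
  dies <- runif(n) < config$death_prob

  episodes <- list(); diagnoses <- list(); prescriptions <- list()
  administrations <- list(); movements <- list(); clin <- list()
  lab <- list(); procedures <- list(); llst <- list()
  ctr <- new.env(); for (k in c("ep", "dg", "rx", "ad", "mv", "co", "lb",
                                "pr", "ll")) assign(k, 0L, envir = ctr)
  nxt <- function(k, fmt) {
    assign(k, get(k, envir = ctr) + 1L, envir = ctr)
    sprintf(fmt, get(k, envir = ctr))
  }

  for (i in seq_len(n)) {
    pid <- patients$patient_id[i]
    n_ep <- 1L + rpois(1, config$episode_rate)
    adm_hi <- max(w0 + 0.5 * (w1 - w0), w1 - 30 * 86400)
    adm <- sort(runif(n_ep, w0, adm_hi))
    for (j in seq_len(n_ep)) {
      eid <- nxt("ep", "EP%06d")
      type <- sample(c("ER", "HOSP"), 1, prob = c(0.4, 0.6))
      dur <- if (type == "ER") runif(1, 2, 24) * 3600
             else runif(1, 1, 20) * 86400
      dis <- adm[j] + dur
      last <- j == n_ep
      dtyp <- if (dies[i] && last) "DEATH"
              else sample(c("HOME", "TRANSFER"), 1, prob = c(0.85, 0.15))
      episodes[[length(episodes) + 1L]] <- data.frame(
        episode_id = eid, patient_id = pid, episode_type = type,
        admitted_at = fmt_local(adm[j], tz), discharged_at = fmt_local(dis, tz),
        discharge_type = dtyp, source = src)
      at <- function(k) fmt_local(runif(k, adm[j], dis), tz)

      for (q in seq_len(rpois(1, config$diagnosis_rate)))
        diagnoses[[length(diagnoses) + 1L]] <- data.frame(
          diagnosis_id = nxt("dg", "DG%07d"), patient_id = pid,
          episode_id = eid, diagnosis_code = sample(pool$diag, 1),
          recorded_at = at(1), source = src)

      for (q in seq_len(rpois(1, config$prescription_rate))) {
        t0 <- runif(1, adm[j], dis)
        prescriptions[[length(prescriptions) + 1L]] <- data.frame(
          prescription_id = nxt("rx", "RX%07d"), patient_id = pid,
          episode_id = eid, drug_code = sample(pool$drug, 1),
          start_at = fmt_local(t0, tz),
          end_at = fmt_local(min(t0 + runif(1, 1, 10) * 86400, dis), tz),
          dose = as.character(sample(c(100, 250, 500, 1000), 1)),
          dose_units = "mg", route = sample(pool$route, 1), source = src)
      }

      for (q in seq_len(rpois(1, config$administration_rate)))
        administrations[[length(administrations) + 1L]] <- data.frame(
          administration_id = nxt("ad", "AD%07d"), patient_id = pid,
          episode_id = eid, drug_code = sample(pool$drug, 1),
          administered_at = at(1),
          dose = as.character(sample(c(100, 250, 500, 1000), 1)),
          dose_units = "mg", route = sample(pool$route, 1), source = src)

      for (q in seq_len(rpois(1, config$movement_rate)))
        movements[[length(movements) + 1L]] <- data.frame(
          movement_id = nxt("mv", "MV%07d"), patient_id = pid,
          episode_id = eid, unit_code = sample(pool$unit, 1),
          entered_at = at(1), exited_at = at(1), source = src)

      for (q in seq_len(rpois(1, config$clinical_obs_rate)))
        clin[[length(clin) + 1L]] <- data.frame(
          observation_id = nxt("co", "CO%07d"), patient_id = pid,
          episode_id = eid, observation_code = sample(pool$clin, 1),
          value = sprintf("%.1f", runif(1, 35, 180)), units = "1",
          observed_at = at(1), source = src)

      for (q in seq_len(rpois(1, config$lab_obs_rate)))
        lab[[length(lab) + 1L]] <- data.frame(
          lab_id = nxt("lb", "LB%07d"), patient_id = pid, episode_id = eid,
          analyte_code = sample(pool$lab, 1),
          value = sprintf("%.2f", runif(1, 0.1, 300)), units = "1",
          resulted_at = at(1), source = src)

      for (q in seq_len(rpois(1, config$procedure_rate)))
        procedures[[length(procedures) + 1L]] <- data.frame(
          procedure_id = nxt("pr", "PR%07d"), patient_id = pid,
          episode_id = eid, procedure_code = sample(pool$proc, 1),
          performed_at = at(1), source = src)

      if (runif(1) < config$llst_prob)
        llst[[length(llst) + 1L]] <- data.frame(
          llst_id = nxt("ll", "LL%05d"), patient_id = pid, episode_id = eid,
          llst_code = sample(pool$llst, 1), recorded_at = at(1), source = src)
    }
  }

  bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
  tables <- list(
    patients = patients,
    episodes = bind(episodes, data.frame(episode_id = character(0),
      patient_id = character(0), episode_type = character(0),
      admitted_at = character(0), discharged_at = character(0),
      discharge_type = character(0), source = character(0))),
    diagnoses = bind(diagnoses, data.frame(diagnosis_id = character(0),
      patient_id = character(0), episode_id = character(0),
      diagnosis_code = character(0), recorded_at = character(0),
      source = character(0))),
    drug_prescriptions = bind(prescriptions, data.frame(
      prescription_id = character(0), patient_id = character(0),
      episode_id = character(0), drug_code = character(0),
      start_at = character(0), end_at = character(0), dose = character(0),
      dose_units = character(0), route = character(0), source = character(0))),
    drug_administrations = bind(administrations, data.frame(
      administration_id = character(0), patient_id = character(0),
      episode_id = character(0), drug_code = character(0),
      administered_at = character(0), dose = character(0),
      dose_units = character(0), route = character(0), source = character(0))),
    movements = bind(movements, data.frame(movement_id = character(0),
      patient_id = character(0), episode_id = character(0),
      unit_code = character(0), entered_at = character(0),
      exited_at = character(0), source = character(0))),
    clinical_observations = bind(clin, data.frame(
      observation_id = character(0), patient_id = character(0),
      episode_id = character(0), observation_code = character(0),
      value = character(0), units = character(0), observed_at = character(0),
      source = character(0))),
    laboratory_observations = bind(lab, data.frame(lab_id = character(0),
      patient_id = character(0), episode_id = character(0),
      analyte_code = character(0), value = character(0),
      units = character(0), resulted_at = character(0),
      source = character(0))),
    procedures = bind(procedures, data.frame(procedure_id = character(0),
      patient_id = character(0), episode_id = character(0),
      procedure_code = character(0), performed_at = character(0),
      source = character(0))),
    llst = bind(llst, data.frame(llst_id = character(0),
      patient_id = character(0), episode_id = character(0),
      llst_code = character(0), recorded_at = character(0),
      source = character(0))))

  ## running per-(patient, drug) totals for the cumulative-dose archetype
  ad <- tables$drug_administrations
  if (nrow(ad)) {
    ord <- order(ad$patient_id, ad$drug_code, ad$administered_at,
                 ad$administration_id, method = "radix")
    cum <- ad[ord, , drop = FALSE]
    cum$cumulative_dose <- as.character(stats::ave(
      as.numeric(cum$dose), cum$patient_id, cum$drug_code, FUN = cumsum))
    tables$drug_administrations <-
      cum[order(cum$administration_id, method = "radix"), , drop = FALSE]
    rownames(tables$drug_administrations) <- NULL
  } else {
    tables$drug_administrations$cumulative_dose <- character(0)
  }

  manifest <- list(seed = config$seed,
                   window = c(config$window_start, config$window_end),
                   counts = lapply(tables, nrow),
                   deaths = sum(dies))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables))
      write_csv_rfc(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(list(tables = tables, manifest = manifest))
}
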