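#' @title Synthetic electronic-medical-record cohorts
#' @description Seeded generation of synthetic NSCLC patient records and their
#'   rendering as token sequences, so the staging pipeline is fully testable
#'   without hospital data.
#' @name synthetic_emr
NULL

#' NSCLC stage labels, ordered by severity
#' @export
stage_levels <- c("I", "II", "III", "IV")

#' Tumor-marker panel used throughout the package
#'
#' Three highly relevant markers (CYFRA21-1, CEA, CA-125) followed by six
#' lower-relevance markers.
#' @export
nsclc_markers <- c(
  "CYFRA21-1", "CEA", "CA-125",
  "NSE", "CA242", "PSA", "HGH", "Free-PSA", "FERRITIN"
)

# Markers whose elevation tracks stage most strongly.
key_markers <- c("CYFRA21-1", "CEA", "CA-125")

#' Normal reference ranges for the tumor-marker panel
#'
#' Closed intervals `[lo, hi]` per marker, in each marker's units:
#' CYFRA21-1 (ug/mL), CEA (ug/L), CA-125 (KU/L), NSE (ug/mL), CA242 (KU/L),
#' PSA (ug/mL), HGH (ug/mL), Free-PSA (ug/mL), FERRITIN (KU/L). FERRITIN has
#' no published range in the source panel; the default upper reference 400 is
#' a package addition so the full panel tokenizes.
#'
#' @param ... Named overrides, each a numeric `c(lo, hi)`.
#' @return A named list of length-2 numeric vectors, class `normal_ranges`.
#' @export
#' @examples
#' normal_ranges()$CEA
#' normal_ranges(`CEA` = c(0, 10))$CEA
normal_ranges <- function(...) {
  ranges <- list(
    `CYFRA21-1` = c(0, 1.80),
    `CEA`       = c(0, 5.00),
    `CA-125`    = c(0, 35.00),
    `NSE`       = c(0, 13.00),
    `CA242`     = c(0, 20.00),
    `PSA`       = c(0, 5.00),
    `HGH`       = c(0, 7.50),
    `Free-PSA`  = c(0, 1.00),
    `FERRITIN`  = c(0, 400)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    r <- as.numeric(overrides[[nm]])
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2]) {
      stop("range for ", nm, " must be a finite c(lo, hi) with lo <= hi")
    }
    ranges[[nm]] <- r
  }
  structure(ranges, class = "normal_ranges")
}

#' Configuration for a synthetic cohort
#'
#' @param n_patients Number of records to generate.
#' @param stage_proportions Named fractions per stage; must sum to at most 1.
#'   The remainder is generated as non-NSCLC (empty stage set). The default
#'   skews towards stages III/IV, matching the clinical imbalance that
#'   motivates dynamic sampling.
#' @param cooccurrence_rate Probability that a staged record carries a second,
#'   adjacent stage label (I-II, II-III, III-IV), emulating clinically
#'   ambiguous transitions.
#' @param severity_multipliers Per-stage factor by which an elevated marker's
#'   median exceeds its normal upper bound.
#' @param noise_cv Coefficient of variation of the log-normal marker noise.
#' @param age_range Integer years, inclusive; the study population is 45-60.
#' @param seed Integer seed; generation is fully deterministic in it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1000,
                          stage_proportions = c(I = 0.05, II = 0.10,
                                                III = 0.35, IV = 0.40),
                          cooccurrence_rate = 0.10,
                          severity_multipliers = c(I = 2, II = 5,
                                                   III = 10, IV = 20),
                          noise_cv = 0.35,
                          age_range = c(45L, 60L),
                          seed = 1L) {
  stopifnot(n_patients >= 1)
  props <- rep(0, 4)
  names(props) <- stage_levels
  if (length(stage_proportions)) {
    if (is.null(names(stage_proportions)) ||
        !all(names(stage_proportions) %in% stage_levels)) {
      stop("stage_proportions must be named with stages in ",
           paste(stage_levels, collapse = ", "))
    }
    props[names(stage_proportions)] <- stage_proportions
  }
  if (any(props < 0) || sum(props) > 1 + 1e-12) {
    stop("stage_proportions must be non-negative and sum to at most 1")
  }
  if (cooccurrence_rate < 0 || cooccurrence_rate > 1) {
    stop("cooccurrence_rate must lie in [0, 1]")
  }
  mult <- rep(1, 4)
  names(mult) <- stage_levels
  mult[names(severity_multipliers)] <- severity_multipliers
  structure(list(
    n_patients = as.integer(n_patients),
    stage_proportions = props,
    cooccurrence_rate = cooccurrence_rate,
    severity_multipliers = mult,
    noise_cv = noise_cv,
    age_range = as.integer(age_range),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Symptom vocabulary; staged records draw more, and more severe, symptoms.
symptom_pool <- c("cough", "hemoptysis", "chest_pain", "dyspnea",
                  "weight_loss", "fatigue", "hoarseness", "fever")

# Probability that a highly relevant marker is elevated, by stage index.
elevation_prob <- c(0.60, 0.75, 0.85, 0.95)

lnorm_draw <- function(n, median, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(median), sdlog = sdlog)
}

draw_markers <- function(stage_idx, config, ranges) {
  cv <- config$noise_cv
  vals <- numeric(length(nsclc_markers))
  names(vals) <- nsclc_markers
  for (mk in nsclc_markers) {
    hi <- ranges[[mk]][2]
    if (is.na(stage_idx)) {               # non-NSCLC: within normal range
      vals[mk] <- lnorm_draw(1, 0.35 * hi, cv)
      next
    }
    key <- mk %in% key_markers
    p_elev <- if (key) elevation_prob[stage_idx] else 0.10 + 0.05 * stage_idx
    mult <- config$severity_multipliers[stage_idx]
    if (!key) mult <- max(1.5, sqrt(mult))
    if (stats::runif(1) <= p_elev) {
      vals[mk] <- lnorm_draw(1, mult * hi, cv)
    } else {
      vals[mk] <- lnorm_draw(1, 0.45 * hi, cv)
    }
  }
  vals
}

new_patient_record <- function(patient_id, markers, age, gender,
                               smoking_years, family_history, symptoms,
                               stages, exam_index = 1L) {
  stopifnot(all(markers >= 0), all(stages %in% stage_levels))
  structure(list(
    patient_id = as.character(patient_id),
    markers = markers,
    age = as.integer(age),
    gender = gender,
    smoking_years = as.integer(smoking_years),
    family_history = isTRUE(family_history),
    symptoms = as.character(symptoms),
    stages = sort(unique(as.character(stages))),
    exam_index = as.integer(exam_index)
  ), class = "patient_record")
}

#' Generate a seeded synthetic cohort
#'
#' Stage labels are drawn from `stage_proportions` (remainder non-NSCLC).
#' For staged records each highly relevant marker is elevated above its normal
#' upper bound with a probability that increases with stage, drawn log-normal
#' around `severity_multiplier * hi`; non-elevated and non-NSCLC draws sit
#' log-normally within the normal range. With probability `cooccurrence_rate`
#' a staged record gains a second, adjacent stage label.
#'
#' @param config A [cohort_config()].
#' @param ranges Marker reference ranges, default [normal_ranges()].
#' @return A list of `patient_record` objects; deterministic in the seed.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 10, seed = 42))
#' cohort[[1]]$stages
generate_cohort <- function(config, ranges = normal_ranges()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "cohort"), {
    n <- config$n_patients
    probs <- c(config$stage_proportions, none = 1 - sum(config$stage_proportions))
    cats <- sample(names(probs), n, replace = TRUE, prob = probs)
    lapply(seq_len(n), function(i) {
      cat_i <- cats[i]
      if (cat_i == "none") {
        stages <- character(0)
        stage_idx <- NA_integer_
      } else {
        stages <- cat_i
        stage_idx <- match(cat_i, stage_levels)
        if (stats::runif(1) <= config$cooccurrence_rate) {
          nbr <- c(stage_idx - 1L, stage_idx + 1L)
          nbr <- nbr[nbr >= 1L & nbr <= 4L]
          stages <- c(stages, stage_levels[nbr[sample.int(length(nbr), 1L)]])
        }
      }
      markers <- draw_markers(stage_idx, config, ranges)
      age <- sample(seq(config$age_range[1], config$age_range[2]), 1L)
      gender <- sample(c("male", "female"), 1L)
      smoking <- if (stats::runif(1) < 0.3) 0L else sample.int(40L, 1L)
      famhist <- stats::runif(1) < 0.15
      n_sym <- if (is.na(stage_idx)) sample(0:1, 1L) else
        min(length(symptom_pool), 1L + stage_idx)
      symptoms <- if (n_sym > 0) sample(symptom_pool, n_sym) else character(0)
      new_patient_record(sprintf("P%05d", i), markers, age, gender,
                         smoking, famhist, symptoms, stages)
    })
  })
}

# "CYFRA21-1" -> "cyfra21_1"; "Free-PSA" -> "free_psa"
canonical_token <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_+|_+$", "", x)
}

#' Render a patient record as a token sequence
#'
#' Each marker value is discretized against its normal range into
#' `normal` (<= hi), `high` (hi, 10*hi], or `very_high` (> 10*hi) -- the
#' 10x cut reflecting the clinical reading that a marker more than ten times
#' over its critical value marks severe disease. Demographics and symptoms
#' contribute categorical tokens. The vocabulary is finite and closed.
#'
#' @param record A `patient_record`.
#' @param ranges Marker reference ranges; every marker present in the record
#'   must have a range, otherwise an error is raised.
#' @param raw_values If `TRUE`, append a rounded raw-value token per marker
#'   (off by default; opens the vocabulary).
#' @return Character vector of tokens, deterministic in the record.
#' @export
#' @examples
#' rec <- generate_cohort(cohort_config(n_patients = 1, seed = 1))[[1]]
#' render_text(rec)
render_text <- function(record, ranges = normal_ranges(), raw_values = FALSE) {
  stopifnot(inherits(record, "patient_record"))
  unknown <- setdiff(names(record$markers), names(ranges))
  if (length(unknown)) {
    stop("no normal range for marker(s): ", paste(unknown, collapse = ", "))
  }
  tokens <- c(
    paste0("age_", 5L * (record$age %/% 5L), "s"),
    paste0("gender=", record$gender),
    paste0("smoking=", if (record$smoking_years == 0) "none"
           else if (record$smoking_years <= 10) "short" else "long"),
    paste0("famhist=", if (record$family_history) "yes" else "no")
  )
  for (mk in names(record$markers)) {
    hi <- ranges[[mk]][2]
    v <- record$markers[[mk]]
    level <- if (v <= hi) "normal" else if (v <= 10 * hi) "high" else "very_high"
    tokens <- c(tokens, paste0(canonical_token(mk), "=", level))
    if (raw_values) {
      tokens <- c(tokens, paste0(canonical_token(mk), "_val_", signif(v, 2)))
    }
  }
  c(tokens, paste0("sym_", record$symptoms))
}

record_to_row <- function(record) {
  row <- data.frame(
    patient_id = record$patient_id,
    age = record$age,
    gender = record$gender,
    smoking_years = record$smoking_years,
    family_history = record$family_history,
    symptoms = paste(record$symptoms, collapse = ";"),
    stages = paste(record$stages, collapse = ";"),
    exam_index = record$exam_index,
    stringsAsFactors = FALSE
  )
  for (mk in names(record$markers)) row[[mk]] <- record$markers[[mk]]
  row
}

row_to_record <- function(row) {
  marker_cols <- intersect(nsclc_markers, names(row))
  markers <- as.numeric(row[marker_cols])
  names(markers) <- marker_cols
  split_field <- function(x) {
    if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";")[[1]]
  }
  new_patient_record(row$patient_id, markers, row$age, row$gender,
                     row$smoking_years, row$family_history,
                     split_field(row$symptoms), split_field(row$stages),
                     row$exam_index)
}

#' Convert a cohort to a data frame (one row per record)
#'
#' Symptoms and stages are `;`-separated in their columns.
#' @param cohort List of `patient_record` objects.
#' @return A data frame.
#' @export
cohort_to_df <- function(cohort) {
  do.call(rbind, lapply(cohort, record_to_row))
}

#' Read/write patient records
#'
#' Records round-trip either as JSON-lines (one record object per line) or as
#' CSV with one column per field; the format is chosen from the file
#' extension (`.jsonl`/`.json` vs `.csv`).
#'
#' @param cohort List of `patient_record` objects.
#' @param path Output (or input) file path.
#' @return `write_records()` returns `path` invisibly; `read_records()`
#'   returns a list of `patient_record` objects.
#' @export
write_records <- function(cohort, path) {
  if (grepl("\\.jsonl?$", path)) {
    lines <- vapply(cohort, function(r) {
      payload <- unclass(r)
      payload$markers <- as.list(payload$markers)  # keep marker names
      jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path)
  } else {
    utils::write.csv(cohort_to_df(cohort), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  if (grepl("\\.jsonl?$", path)) {
    lapply(readLines(path), function(line) {
      x <- jsonlite::fromJSON(line)
      new_patient_record(x$patient_id, unlist(x$markers), x$age, x$gender,
                         x$smoking_years, x$family_history,
                         as.character(unlist(x$symptoms)),
                         as.character(unlist(x$stages)),
                         x$exam_index)
    })
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, , drop = FALSE]))
  }
}

#' Packaged example marker data
#'
#' `marker_group_means()` returns mean tumor-marker panels for three patient
#' groups over five serial examinations (columns `group`, `exam`, then the
#' nine markers). `treatment_trajectory()` returns a single patient's full
#' diagnosis-treatment-follow-up marker trajectory over eight examinations
#' as a list of `patient_record` objects ordered by `exam_index`.
#'
#' @return A data frame (`marker_group_means`) or list of records
#'   (`treatment_trajectory`).
#' @export
marker_group_means <- function() {
  utils::read.csv(system.file("extdata", "marker_group_means.csv",
                              package = "nsclcstager"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname marker_group_means
#' @export
treatment_trajectory <- function() {
  df <- utils::read.csv(system.file("extdata", "treatment_trajectory.csv",
                                    package = "nsclcstager"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    markers <- as.numeric(df[i, nsclc_markers])
    names(markers) <- nsclc_markers
    new_patient_record(
      patient_id = "T0001", markers = markers, age = 52L, gender = "male",
      smoking_years = 20L, family_history = FALSE,
      symptoms = c("cough", "chest_pain"), stages = character(0),
      exam_index = df$exam_index[i]
    )
  })
}
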