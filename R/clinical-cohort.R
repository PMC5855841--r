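# Clinical stroke-like-episode (SLE) cohort: episode fixtures, the explicit
# SLE classification rule, episode summary statistics, and the SLE-positive
# vs SLE-negative cohort comparison.
#
# The packaged episode table mirrors the published per-episode records of
# the nine SLE plus the two excluded candidate episodes; the two excluded
# rows (patient_id X1/X2) are reconstructed stand-ins, as only their
# exclusion reasons were reported. Focal deficits are encoded as presence
# of paresis/hemiparesis, matching the reported count of 3/9.

#' Load the packaged SLE candidate-episode table
#'
#' Eleven candidate episodes: nine classified as SLE and two exclusions
#' (one radiologically confirmed ischemic stroke, one epileptic seizure at
#' the onset of a CNS infection; both reconstructed from the narrative and
#' marked by patient_id `X1`/`X2`).
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return data.frame of episodes; empty cells become `NA`.
#' @export
load_episodes <- function(path = system.file("extdata",
                                             "sle_episode_candidates.csv",
                                             package = "cavgate")) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA", "No data available"))
}

#' Parse an age string of the form "<y> yr [<m> mo]"
#'
#' @param age_text Character vector, e.g. `"3 yr 11 mo"`, `"15 yr"`.
#' @return Age in decimal years (`y + m/12`).
#' @export
parse_age <- function(age_text) {
  vapply(age_text, function(a) {
    if (is.na(a)) return(NA_real_)
    m <- regexec("^\\s*(\\d+)\\s*yr(?:\\s+(\\d+)\\s*mo)?\\s*$", a)
    g <- regmatches(a, m)[[1]]
    if (length(g) == 0)
      stop("unparseable age: '", a, "'", call. = FALSE)
    yr <- as.numeric(g[2])
    mo <- if (is.na(g[3]) || g[3] == "") 0 else as.numeric(g[3])
    yr + mo / 12
  }, 0, USE.NAMES = FALSE)
}

#' Classify a candidate episode under the SLE definition
#'
#' An episode is an SLE if it shows at least one core symptom (focal
#' neurological deficit, irritability, or decreased consciousness), no
#' alternative diagnosis explains the symptoms, MRI shows no true ischemic
#' stroke, and it is not an epileptic seizure at the onset of a CNS
#' infection. Exclusion reasons take precedence over `not_SLE`.
#'
#' @param episode One-row data.frame (or list) with the episode fields.
#' @return One of `"SLE"`, `"excluded_true_stroke"`,
#'   `"excluded_seizure_cns_infection"`, `"not_SLE"`.
#' @export
classify_episode <- function(episode) {
  e <- as.list(episode)
  if (identical(e$mri_finding, "ischemic_stroke"))
    return("excluded_true_stroke")
  if (isTRUE(e$seizures) && isTRUE(e$cns_infection_at_onset))
    return("excluded_seizure_cns_infection")
  core <- isTRUE(e$focal_deficit) || isTRUE(e$irritability) ||
    isTRUE(e$decreased_consciousness)
  if (core && !isTRUE(e$alternative_diagnosis)) "SLE" else "not_SLE"
}

#' Classify every row of an episode table
#'
#' @param episodes data.frame as returned by [load_episodes()].
#' @return Character vector of classifications, one per row.
#' @export
classify_episodes <- function(episodes) {
  vapply(seq_len(nrow(episodes)),
         function(i) classify_episode(episodes[i, ]), "")
}

#' Summary statistics of a set of SLE episodes
#'
#' Mean/SD/range for age, symptom-free interval, body temperature and
#' symptom duration (missing values excluded per variable, with the n used
#' reported), plus counts of triggers, abnormal EEG and hemispheric edema.
#'
#' @param episodes data.frame of episodes (typically the 9 SLE rows).
#' @return List with `numeric` (data.frame: variable, n, mean, sd, min,
#'   max) and `counts` (data.frame: variable, count, total).
#' @export
episode_summary <- function(episodes) {
  stopifnot(nrow(episodes) >= 1)
  num_block <- function(name, x) {
    x <- x[!is.na(x)]
    data.frame(variable = name, n = length(x), mean = mean(x),
               sd = stats::sd(x), min = min(x), max = max(x))
  }
  numeric_tab <- rbind(
    num_block("age_years", parse_age(episodes$age_text)),
    num_block("free_interval_h", episodes$free_interval_h),
    num_block("temperature_c", episodes$temperature_c),
    num_block("duration_h", episodes$duration_h))
  n <- nrow(episodes)
  trig <- table(episodes$trigger)
  counts_tab <- rbind(
    data.frame(variable = paste0("trigger_", names(trig)),
               count = as.integer(trig), total = n),
    data.frame(variable = "eeg_abnormal",
               count = sum(episodes$eeg_abnormal, na.rm = TRUE), total = n),
    data.frame(variable = "hemispheric_edema",
               count = sum(episodes$mri_finding == "hemispheric_edema",
                           na.rm = TRUE), total = n))
  list(numeric = numeric_tab, counts = counts_tab)
}

#' Load the packaged group-level cohort table
#'
#' Group means/SDs (numeric variables) and counts (categorical variables)
#' for the SLE-positive (n = 7) and SLE-negative (n = 32) groups, as
#' published. Raw per-patient values were not published.
#'
#' @param path CSV path; defaults to the packaged fixture.
#' @return data.frame of group-level summaries.
#' @export
load_cohort_summary <- function(path = system.file(
                                  "extdata", "cohort_table2_summary.csv",
                                  package = "cavgate")) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
}

#' Generate a synthetic patient-level cohort table
#'
#' Raw per-patient laboratory values for the cohort were never published
#' (only group means/SDs), so patient-level analyses are exercised on a
#' synthetic table: numeric variables are drawn normally from the published
#' group means/SDs (truncated at zero for lab values), and categorical
#' flags are assigned deterministically to match the published counts
#' exactly. Four additional `excluded_early_death` records mirror the four
#' patients excluded from the comparison, giving 43 patients in total.
#'
#' @param seed Integer seed.
#' @param summary_table Group-level table from [load_cohort_summary()].
#' @param mvrd_sd SD used for the midsagittal vermis relative diameter,
#'   whose dispersion was not published.
#' @return data.frame with one row per patient: `patient_id`, `group`, the
#'   numeric variables, and logical categorical flags.
#' @export
make_synthetic_patients <- function(seed,
                                    summary_table = load_cohort_summary(),
                                    mvrd_sd = 0.1) {
  n_pos <- 7L; n_neg <- 32L; n_dead <- 4L
  with_local_seed(seed, {
    draw <- function(n, mean, sd, floor0 = TRUE) {
      x <- stats::rnorm(n, mean, sd)
      if (floor0) pmax(x, 0) else x
    }
    mk_group <- function(n, group, prefix, which_col) {
      df <- data.frame(patient_id = sprintf("%s%02d", prefix, seq_len(n)),
                       group = group)
      num <- summary_table[summary_table$type == "numeric", ]
      for (i in seq_len(nrow(num))) {
        v <- num$variable[i]
        mu <- num[[paste0(which_col, "_mean")]][i]
        sd <- num[[paste0(which_col, "_sd")]][i]
        if (is.na(sd)) sd <- mvrd_sd
        df[[v]] <- draw(n, mu, sd, floor0 = !identical(v, "mvrd"))
      }
      cat_ <- summary_table[summary_table$type == "categorical", ]
      for (i in seq_len(nrow(cat_))) {
        k <- cat_[[paste0(which_col, "_count")]][i]
        df[[cat_$variable[i]]] <- seq_len(n) <= k
      }
      df
    }
    pos <- mk_group(n_pos, "sle_positive", "P", "sle_pos")
    neg <- mk_group(n_neg, "sle_negative", "C", "sle_neg")
    dead <- mk_group(n_dead, "excluded_early_death", "D", "sle_neg")
    rbind(pos, neg, dead)
  })
}

#' Compare SLE-positive and SLE-negative patients
#'
#' Early-death patients are excluded first. Numeric variables are compared
#' with [mann_whitney_u()], categorical flags with [fisher_exact()]; each
#' row reports group sizes (after per-variable missing-value removal),
#' means/SDs or counts, and the p value. Every patient belongs to exactly
#' one group.
#'
#' @param patients Patient table, e.g. from [make_synthetic_patients()].
#' @return List with `comparison` (data.frame), `n_sle`, `n_control`,
#'   `n_excluded_early_death` and `prevalence_pct`
#'   (= 100 * n_sle / (n_sle + n_control)).
#' @export
compare_cohort <- function(patients) {
  stopifnot(all(c("patient_id", "group") %in% names(patients)))
  dead <- sum(patients$group == "excluded_early_death")
  pts <- patients[patients$group != "excluded_early_death", ]
  pos <- pts[pts$group == "sle_positive", ]
  neg <- pts[pts$group == "sle_negative", ]
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stop("a group is empty after exclusions", call. = FALSE)
  vars <- setdiff(names(pts), c("patient_id", "group"))
  rows <- lapply(vars, function(v) {
    x <- pos[[v]]; y <- neg[[v]]
    if (is.logical(x)) {
      tab <- matrix(c(sum(x), sum(!x), sum(y), sum(!y)), nrow = 2)
      res <- fisher_exact(tab)
      data.frame(variable = v, type = "categorical",
                 n_sle = length(x), n_control = length(y),
                 sle_stat = sum(x), control_stat = sum(y),
                 sle_sd = NA_real_, control_sd = NA_real_,
                 p_value = res$p_value)
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      res <- mann_whitney_u(x, y)
      data.frame(variable = v, type = "numeric",
                 n_sle = length(x), n_control = length(y),
                 sle_stat = mean(x), control_stat = mean(y),
                 sle_sd = stats::sd(x), control_sd = stats::sd(y),
                 p_value = res$p_value)
    }
  })
  list(comparison = do.call(rbind, rows),
       n_sle = nrow(pos), n_control = nrow(neg),
       n_excluded_early_death = dead,
       prevalence_pct = 100 * nrow(pos) / (nrow(pos) + nrow(neg)))
}
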