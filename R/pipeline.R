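#' Load a cohort: metadata plus transcript-derived linguistics
#'
#' Reads the cohort metadata table and the transcript set, computes a
#' similarity profile for every transcript, aggregates per subject x
#' timepoint, and appends the computed cognitive scores (Stroop
#' interference by the Golden method, DSST total). Transcripts resolve by
#' the filename pattern `<subject>_<timepoint>_<picture>.txt`.
#'
#' @param metadata Path to the metadata CSV, or a data.frame. Must carry
#'   subject_id, group, timepoint; clinical/cognitive columns are optional
#'   but analyses that need them will say so.
#' @param transcripts Directory of transcript files, or a named character
#'   vector of raw texts (`<subject>_<timepoint>_<picture>`).
#' @param table An `embedding_table`.
#' @param stoplist Stop words (default: shipped list).
#' @param window,pair_mode,include_stops Similarity settings (see
#'   [profile_transcript()]).
#' @return A `cohort`: list with `measures` (metadata + NW_mean, ASW_F_mean,
#'   ASW_10_mean, n_pictures, IG, DSST_total), `profiles` (per-transcript
#'   rows), `oov_report` (subject, picture, timepoint, surface_form), and
#'   the similarity settings.
#' @export
load_cohort <- function(metadata, transcripts, table,
                        stoplist = default_stoplist(),
                        window = 10L, pair_mode = "all_pairs",
                        include_stops = FALSE) {
  meta <- if (is.character(metadata)) {
    utils::read.csv(metadata, stringsAsFactors = FALSE)
  } else {
    as.data.frame(metadata)
  }
  required <- c("subject_id", "group", "timepoint")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0L) {
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_group <- setdiff(unique(meta$group), c("FES", "HC"))
  if (length(bad_group) > 0L) {
    stop("unknown group value(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  if (is.character(transcripts)) {
    if (length(transcripts) == 1L && dir.exists(transcripts)) {
      files <- list.files(transcripts, pattern = "\\.txt$",
                          full.names = TRUE)
      texts <- vapply(files, read_transcript, character(1))
      names(texts) <- sub("\\.txt$", "", basename(files))
    } else {
      texts <- transcripts
    }
  } else {
    stop("transcripts must be a directory path or a named character vector",
         call. = FALSE)
  }
  keys <- names(texts)
  parsed <- regmatches(keys, regexec("^(.+)_(baseline|followup)_([^_]+)$",
                                     keys))
  ok <- lengths(parsed) == 4L
  if (any(!ok)) {
    stop("transcript name(s) not matching <subject>_<timepoint>_<picture>: ",
         paste(utils::head(keys[!ok], 3), collapse = ", "), call. = FALSE)
  }
  subj <- vapply(parsed, `[`, character(1), 2L)
  tp <- vapply(parsed, `[`, character(1), 3L)
  pic <- vapply(parsed, `[`, character(1), 4L)
  unknown <- setdiff(unique(subj), unique(meta$subject_id))
  if (length(unknown) > 0L) {
    stop("transcript(s) for subject(s) absent from metadata: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  profiles <- vector("list", length(texts))
  oov <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    ann <- annotate_tokens(tokenize(texts[[i]]), stoplist, table,
                           subject_id = subj[i], picture_id = pic[i],
                           timepoint = tp[i], warn_oov = FALSE)
    profiles[[i]] <- profile_transcript(ann, table, window = window,
                                        pair_mode = pair_mode,
                                        include_stops = include_stops)
    if (length(ann$oov_report) > 0L) {
      oov[[i]] <- data.frame(subject = subj[i], picture = pic[i],
                             timepoint = tp[i],
                             surface_form = ann$oov_report,
                             stringsAsFactors = FALSE)
    }
  }
  profiles <- do.call(rbind, profiles)
  oov_report <- if (any(!vapply(oov, is.null, logical(1)))) {
    do.call(rbind, oov[!vapply(oov, is.null, logical(1))])
  } else {
    data.frame(subject = character(0), picture = character(0),
               timepoint = character(0), surface_form = character(0))
  }

  agg <- do.call(rbind, lapply(
    split(profiles, list(profiles$subject_id, profiles$timepoint),
          drop = TRUE),
    function(d) suppressWarnings(aggregate_subject(d))
  ))
  measures <- merge(meta, agg, by = c("subject_id", "timepoint"),
                    all.x = TRUE, sort = FALSE)
  no_txt <- is.na(measures$n_pictures)
  if (any(no_txt)) {
    warning(sum(no_txt), " subject x timepoint row(s) have no transcripts; ",
            "linguistic fields left missing", call. = FALSE)
  }
  if (all(c("stroop_W", "stroop_C", "stroop_CW") %in% names(measures))) {
    ok <- !is.na(measures$stroop_W) & !is.na(measures$stroop_C) &
      !is.na(measures$stroop_CW) &
      (measures$stroop_W + measures$stroop_C) > 0
    measures$IG <- NA_real_
    measures$IG[ok] <- golden_interference(measures$stroop_W[ok],
                                           measures$stroop_C[ok],
                                           measures$stroop_CW[ok])
  }
  if (all(c("DSST_oral", "DSST_written") %in% names(measures))) {
    measures$DSST_total <- dsst_total(measures$DSST_oral,
                                      measures$DSST_written)
  }
  measures <- measures[order(measures$timepoint, measures$subject_id), ]
  rownames(measures) <- NULL
  structure(
    list(measures = measures, profiles = profiles, oov_report = oov_report,
         settings = list(window = window, pair_mode = pair_mode,
                         include_stops = include_stops)),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  m <- x$measures
  cat("<cohort> ", length(unique(m$subject_id)), " subjects, ",
      nrow(x$profiles), " transcripts (",
      sum(m$timepoint == "followup"), " follow-up rows)\n", sep = "")
  invisible(x)
}

# pull the reporting fields out of a bayes_result into one row
bayes_row <- function(res) {
  data.frame(BF10 = res$bf10, effect_size = res$effect_size,
             ci_lower = res$ci95[1], ci_upper = res$ci95[2],
             family = res$family,
             prior = paste(names(res$prior), unlist(res$prior),
                           sep = "=", collapse = ";"),
             stringsAsFactors = FALSE)
}

default_continuous_vars <- function(measures) {
  candidates <- c("age", "SOFAS", "TLI_total", "TLI_disorganization",
                  "TLI_impoverishment", "TLI_dysregulation", "DSST_total",
                  "fluency_count", "stroop_total_correct",
                  "stroop_total_time", "IG", "NW_mean", "ASW_F_mean",
                  "ASW_10_mean")
  intersect(candidates, names(measures))
}

default_categorical_vars <- function(measures) {
  intersect(c("gender", "education_band", "parental_SES_band", "immigrant",
              "first_language_english"), names(measures))
}

#' Baseline group-comparison table
#'
#' For each demographic, clinical, cognitive and linguistic variable at
#' baseline: group means +/- SD and the default Bayesian independent t test
#' (HC as group 1), or a Gunel-Dickey contingency test for categorical
#' variables. Every row records the test family, prior and per-group n.
#'
#' @param cohort A `cohort`.
#' @param variables Continuous variables to test (default: all standard
#'   columns present).
#' @param categorical Categorical variables (default: all standard ones
#'   present).
#' @param cauchy_width,concentration Prior settings passed through.
#' @return Data frame, one row per variable.
#' @export
baseline_tables <- function(cohort, variables = NULL, categorical = NULL,
                            cauchy_width = sqrt(2) / 2, concentration = 1) {
  m <- cohort$measures[cohort$measures$timepoint == "baseline", ]
  if (!all(c("HC", "FES") %in% m$group)) {
    stop("baseline rows must contain both groups", call. = FALSE)
  }
  if (is.null(variables)) variables <- default_continuous_vars(m)
  if (is.null(categorical)) categorical <- default_categorical_vars(m)
  rows <- list()
  for (v in variables) {
    hc <- m[[v]][m$group == "HC"]
    fes <- m[[v]][m$group == "FES"]
    hc <- hc[!is.na(hc)]; fes <- fes[!is.na(fes)]
    if (length(hc) < 2L || length(fes) < 2L) {
      warning("variable '", v, "' skipped: fewer than 2 values per group",
              call. = FALSE)
      next
    }
    res <- bf_ttest_independent(x = hc, y = fes,
                                cauchy_width = cauchy_width)
    rows[[v]] <- cbind(
      data.frame(variable = v, type = "continuous",
                 HC_mean = mean(hc), HC_sd = sd(hc), n_HC = length(hc),
                 FES_mean = mean(fes), FES_sd = sd(fes),
                 n_FES = length(fes), stringsAsFactors = FALSE),
      bayes_row(res))
  }
  for (v in categorical) {
    tab <- table(m$group[!is.na(m[[v]])], m[[v]][!is.na(m[[v]])])
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      warning("categorical variable '", v, "' skipped: degenerate table",
              call. = FALSE)
      next
    }
    res <- bf_contingency(unclass(tab), concentration = concentration)
    rows[[v]] <- cbind(
      data.frame(variable = v, type = "categorical",
                 HC_mean = NA_real_, HC_sd = NA_real_,
                 n_HC = sum(tab["HC", ]),
                 FES_mean = NA_real_, FES_sd = NA_real_,
                 n_FES = sum(tab["FES", ]), stringsAsFactors = FALSE),
      bayes_row(res))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Change scores for one variable
#'
#' Linear change (follow-up minus baseline) and standardized change (linear
#' change divided by baseline) per subject, for subjects with both
#' timepoints. A zero baseline makes the standardized change missing, with
#' a warning.
#'
#' @param cohort A `cohort`.
#' @param variable Column name in the measures table.
#' @return Data frame: subject_id, group, baseline, followup,
#'   linear_change, standardized_change.
#' @export
change_scores <- function(cohort, variable) {
  m <- cohort$measures
  if (!variable %in% names(m)) {
    stop("no such variable: ", variable, call. = FALSE)
  }
  base <- m[m$timepoint == "baseline", c("subject_id", "group", variable)]
  fu <- m[m$timepoint == "followup", c("subject_id", variable)]
  names(base)[3] <- "baseline"
  names(fu)[2] <- "followup"
  d <- merge(base, fu, by = "subject_id", sort = TRUE)
  d$linear_change <- d$followup - d$baseline
  zero <- !is.na(d$baseline) & d$baseline == 0
  if (any(zero)) {
    warning(sum(zero), " subject(s) with zero baseline for '", variable,
            "': standardized change left missing", call. = FALSE)
  }
  d$standardized_change <- ifelse(zero, NA_real_,
                                  d$linear_change / d$baseline)
  d
}

#' Longitudinal comparison table
#'
#' Per group and linguistic variable: baseline and follow-up summaries for
#' the subjects observed twice, the default Bayesian paired t test, the
#' linear change, and the between-group independent t test on the linear
#' change. Subjects lacking follow-up are excluded (count logged).
#'
#' @param cohort A `cohort`.
#' @param variables Variables to analyze (default NW_mean, ASW_F_mean,
#'   ASW_10_mean).
#' @param cauchy_width Cauchy prior width.
#' @return Data frame, one row per variable x group, plus the group-change
#'   comparison columns on each variable's rows.
#' @export
longitudinal_tables <- function(cohort,
                                variables = c("NW_mean", "ASW_F_mean",
                                              "ASW_10_mean"),
                                cauchy_width = sqrt(2) / 2) {
  m <- cohort$measures
  if (!"followup" %in% m$timepoint) {
    stop("no follow-up rows in cohort", call. = FALSE)
  }
  n_base <- length(unique(m$subject_id[m$timepoint == "baseline"]))
  n_fu <- length(unique(m$subject_id[m$timepoint == "followup"]))
  message(n_base - n_fu, " of ", n_base,
          " subjects lack follow-up and are excluded")
  rows <- list()
  for (v in variables) {
    cs <- change_scores(cohort, v)
    cs <- cs[!is.na(cs$linear_change), ]
    chg_bf <- bf_ttest_independent(
      x = cs$linear_change[cs$group == "HC"],
      y = cs$linear_change[cs$group == "FES"],
      cauchy_width = cauchy_width)
    for (grp in c("HC", "FES")) {
      g <- cs[cs$group == grp, ]
      paired <- bf_ttest_paired(x = g$followup, y = g$baseline,
                                cauchy_width = cauchy_width)
      rows[[paste(v, grp)]] <- cbind(
        data.frame(variable = v, group = grp, n = nrow(g),
                   baseline_mean = mean(g$baseline),
                   baseline_sd = sd(g$baseline),
                   followup_mean = mean(g$followup),
                   followup_sd = sd(g$followup),
                   change_mean = mean(g$linear_change),
                   change_sd = sd(g$linear_change),
                   stringsAsFactors = FALSE),
        paired_BF10 = paired$bf10,
        paired_ci_lower = paired$ci95[1],
        paired_ci_upper = paired$ci95[2],
        group_change_BF10 = chg_bf$bf10)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation table over variable pairs
#'
#' Pearson r with the default Bayesian correlation test per pair, within a
#' data scope. With `change = TRUE` the variables are first reduced to
#' per-subject change scores between timepoints (standardized by baseline
#' when `standardized = TRUE`).
#'
#' @param cohort A `cohort`.
#' @param pairs Data frame (or 2-column matrix) of variable name pairs.
#' @param scope `"all"`, `"FES"`, `"HC"` or `"followup_FES"` (FES subjects
#'   observed at both timepoints).
#' @param timepoint Timepoint for cross-sectional scopes (default baseline).
#' @param change Correlate change scores instead of raw values.
#' @param standardized Use standardized (baseline-relative) change scores.
#' @param beta_width,alternative Prior settings for [bf_correlation()].
#' @return Data frame, one row per pair; rows with n < 3 are marked not
#'   computable.
#' @export
correlation_tables <- function(cohort, pairs,
                               scope = c("all", "FES", "HC", "followup_FES"),
                               timepoint = "baseline", change = FALSE,
                               standardized = TRUE, beta_width = 1,
                               alternative = "two.sided") {
  scope <- match.arg(scope)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs)[1:2] <- c("var1", "var2")
  m <- cohort$measures
  get_values <- function(v) {
    if (change) {
      cs <- change_scores(cohort, v)
      if (scope %in% c("FES", "followup_FES")) cs <- cs[cs$group == "FES", ]
      if (scope == "HC") cs <- cs[cs$group == "HC", ]
      setNames(if (standardized) cs$standardized_change else
        cs$linear_change, cs$subject_id)
    } else {
      d <- m[m$timepoint == timepoint, ]
      if (scope %in% c("FES", "followup_FES")) d <- d[d$group == "FES", ]
      if (scope == "HC") d <- d[d$group == "HC", ]
      if (scope == "followup_FES") {
        fu <- unique(m$subject_id[m$timepoint == "followup"])
        d <- d[d$subject_id %in% fu, ]
      }
      setNames(d[[v]], d$subject_id)
    }
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    v1 <- pairs$var1[i]; v2 <- pairs$var2[i]
    x <- get_values(v1); y <- get_values(v2)
    common <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
    base <- data.frame(var1 = v1, var2 = v2, scope = scope,
                       change = change, n = length(common),
                       stringsAsFactors = FALSE)
    if (length(common) < 3L) {
      return(cbind(base, r = NA_real_, BF10 = NA_real_,
                   ci_lower = NA_real_, ci_upper = NA_real_,
                   note = "not computable: n < 3"))
    }
    res <- tryCatch(
      bf_correlation(x = x[common], y = y[common], beta_width = beta_width,
                     alternative = alternative),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      # e.g. perfectly collinear pairs: |r| = 1 is outside the test's domain
      return(cbind(base, r = suppressWarnings(
        stats::cor(x[common], y[common])), BF10 = NA_real_,
        ci_lower = NA_real_, ci_upper = NA_real_,
        note = paste("not computable:", res)))
    }
    cbind(base, r = res$detail$r, BF10 = res$bf10,
          ci_lower = res$ci95[1], ci_upper = res$ci95[2], note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stratified robustness checks
#'
#' (i) the baseline ASW-F group test after removing immigrant or
#' non-English-first-language subjects; (ii) within-FES comparisons of
#' ASW-F and word count across education and parental-SES bands; (iii) the
#' three-level medication-class one-way Bayesian ANOVA at baseline and the
#' two-level t test at follow-up. Strata that are empty or too small are
#' skipped with a warning.
#'
#' @param cohort A `cohort`.
#' @param variables Linguistic variables for the band comparisons.
#' @return Data frame: analysis, variable, BF10, family, n, note.
#' @export
stratified_checks <- function(cohort,
                              variables = c("ASW_F_mean", "NW_mean")) {
  m <- cohort$measures[cohort$measures$timepoint == "baseline", ]
  rows <- list()
  add <- function(analysis, variable, res, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      analysis = analysis, variable = variable, BF10 = res$bf10,
      family = res$family, n = n, stringsAsFactors = FALSE)
  }
  # (i) social-factor exclusion
  if (all(c("immigrant", "first_language_english") %in% names(m))) {
    keep <- !(m$immigrant | !m$first_language_english)
    d <- m[keep, ]
    hc <- d$ASW_F_mean[d$group == "HC"]
    fes <- d$ASW_F_mean[d$group == "FES"]
    if (sum(!is.na(hc)) >= 2 && sum(!is.na(fes)) >= 2) {
      add("group_excluding_social_factors", "ASW_F_mean",
          bf_ttest_independent(x = hc[!is.na(hc)], y = fes[!is.na(fes)]),
          sum(keep))
    } else {
      warning("social-factor stratum too small; skipped", call. = FALSE)
    }
  }
  # (ii) within-FES band comparisons
  fes <- m[m$group == "FES", ]
  for (band in intersect(c("education_band", "parental_SES_band"),
                         names(fes))) {
    lv <- unique(fes[[band]][!is.na(fes[[band]])])
    for (v in variables) {
      if (length(lv) != 2L) {
        warning(band, " does not have two levels; skipped", call. = FALSE)
        next
      }
      a <- fes[[v]][fes[[band]] == lv[1]]
      b <- fes[[v]][fes[[band]] == lv[2]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) {
        warning(band, " stratum too small for ", v, "; skipped",
                call. = FALSE)
        next
      }
      add(paste0("FES_", band), v, bf_ttest_independent(x = a, y = b),
          length(a) + length(b))
    }
  }
  # (iii) medication classes
  if ("medication_class" %in% names(fes)) {
    cls <- split(fes$ASW_F_mean, fes$medication_class)
    cls <- lapply(cls, function(v) v[!is.na(v)])
    cls <- cls[lengths(cls) >= 2L]
    if (length(cls) >= 2L) {
      add("medication_class_baseline", "ASW_F_mean", bf_anova_oneway(cls),
          sum(lengths(cls)))
    } else {
      warning("medication strata too small at baseline; skipped",
              call. = FALSE)
    }
    fu <- cohort$measures[cohort$measures$timepoint == "followup" &
                            cohort$measures$group == "FES", ]
    if ("medication_class" %in% names(fu)) {
      cls2 <- split(fu$ASW_F_mean, fu$medication_class)
      cls2 <- lapply(cls2, function(v) v[!is.na(v)])
      cls2 <- cls2[lengths(cls2) >= 2L]
      if (length(cls2) == 2L) {
        add("medication_class_followup", "ASW_F_mean",
            bf_ttest_independent(x = cls2[[1]], y = cls2[[2]]),
            sum(lengths(cls2)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the study's output tables
#'
#' Emits the baseline demographic/clinical table, the baseline linguistic
#' table, the longitudinal table, the dose-correlation table, the
#' per-transcript similarity profiles, the OOV report, and a JSON run
#' manifest. Reruns on identical inputs produce byte-identical files.
#'
#' @param cohort A `cohort`.
#' @param out_dir Output directory.
#' @param dose_pairs Variable pairs for the dose table (default: daily and
#'   total dose against NW and ASW-F changes).
#' @return `out_dir`, invisibly.
#' @export
write_study_tables <- function(cohort, out_dir,
                               dose_pairs = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                       row.names = FALSE)
  base <- baseline_tables(cohort)
  ling <- c("NW_mean", "ASW_F_mean", "ASW_10_mean")
  w(base[!base$variable %in% ling, ], "table1_baseline.csv")
  w(base[base$variable %in% ling, ], "table2_linguistic.csv")
  has_fu <- "followup" %in% cohort$measures$timepoint
  if (has_fu) {
    w(longitudinal_tables(cohort), "table3_longitudinal.csv")
    if (is.null(dose_pairs)) {
      dose_pairs <- data.frame(
        var1 = c("daily_dose_DDD", "daily_dose_DDD", "total_dose",
                 "total_dose"),
        var2 = c("NW_mean", "ASW_F_mean", "NW_mean", "ASW_F_mean"))
    }
    if (all(c("daily_dose_DDD", "total_dose") %in%
            names(cohort$measures))) {
      dose_vals <- lapply(seq_len(nrow(dose_pairs)), function(i) {
        # dose is cross-sectional; the linguistic variable enters as change
        dp <- dose_pairs[i, ]
        cs <- change_scores(cohort, dp$var2)
        cs <- cs[cs$group == "FES", ]
        dose <- cohort$measures[cohort$measures$timepoint == "baseline",
                                c("subject_id", dp$var1)]
        d <- merge(cs, dose, by = "subject_id")
        ok <- !is.na(d$linear_change) & !is.na(d[[dp$var1]])
        base_row <- data.frame(var1 = dp$var1, var2 = dp$var2,
                               n = sum(ok), stringsAsFactors = FALSE)
        if (sum(ok) < 3L) {
          return(cbind(base_row, r = NA_real_, BF10 = NA_real_,
                       ci_lower = NA_real_, ci_upper = NA_real_))
        }
        res <- bf_correlation(x = d[[dp$var1]][ok],
                              y = d$linear_change[ok])
        cbind(base_row, r = res$detail$r, BF10 = res$bf10,
              ci_lower = res$ci95[1], ci_upper = res$ci95[2])
      })
      w(do.call(rbind, dose_vals), "table4_dose.csv")
    }
  }
  w(cohort$profiles, "similarity_profiles.csv")
  w(cohort$oov_report, "oov_report.csv")
  manifest <- list(
    n_subjects = length(unique(cohort$measures$subject_id)),
    n_transcripts = nrow(cohort$profiles),
    settings = cohort$settings,
    package_version = as.character(utils::packageVersion("semsim"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
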