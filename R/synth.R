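#' Synthetic study configuration
#'
#' Returns the default configuration of the synthetic cohort generator. The
#' defaults emulate a two-group (FES/HC), two-timepoint picture-description
#' study: 46 patients and 36 controls describing 3 pictures for one minute
#' at baseline (~246 transcripts), with 20 patients and 13 controls
#' returning at follow-up (~99 transcripts); word counts follow the groups'
#' observed distributions (HC 70.6 +/- 14.9, FES 68.4 +/- 30.3, truncated at
#' 5); group mean ASW-F targets are 0.334 (HC) and 0.352 (FES) at baseline,
#' with patients drifting +0.016 by follow-up while controls stay flat.
#' Vocabulary structure: words live in K semantic clusters on the unit
#' sphere; a transcript is a Markov walk that stays in its current cluster
#' with probability `p_stay` (higher p_stay -> higher semantic similarity).
#'
#' @param ... Named overrides of any default.
#' @return A list of generator settings (class `synth_config`).
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_clusters = 20L,
    dim = 50L,
    within_cluster_noise = 0.22,
    base_similarity = 0.30,
    vocab_per_cluster = 30L,
    n_oov = 20L,
    stopword_rate = 0.45,
    oov_rate = 0.02,
    n_FES = 46L,
    n_HC = 36L,
    n_pictures = 3L,
    n_followup_FES = 20L,
    n_followup_HC = 13L,
    words_mean = c(HC = 70.6, FES = 68.4),
    words_sd = c(HC = 14.9, FES = 30.3),
    min_words = 5L,
    target_asw = list(
      HC = c(baseline = 0.334, followup = 0.334),
      FES = c(baseline = 0.352, followup = 0.368)
    ),
    # within-group covariate coupling to the subject's realized ASW-F
    asw_cor = list(
      FES = c(DSST = -0.41, stroop_total_correct = -0.22),
      HC = c(DSST = -0.03, stroop_total_correct = -0.29)
    ),
    # correlation of follow-up PANSS-8 negative change with ASW-F change
    panss_neg_change_cor = 0.592
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown synth_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "synth_config")
}

# deterministic 31-bit substream seed from a global seed and labels, so a
# subject's transcript does not depend on generation order
substream_seed <- function(seed, ...) {
  labels <- paste(c(...), collapse = "\r")
  h <- as.double(seed %% 2147483647L)
  for (cp in utf8ToInt(labels)) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

#' Generate a synthetic clustered embedding
#'
#' Draws `n_clusters` random unit-vector centers; each cluster's vocabulary
#' is center + isotropic Gaussian noise, renormalized to the unit sphere,
#' then blended with a common direction shared by all content words so that
#' two words from different clusters have expected cosine similarity
#' `base_similarity` — mirroring the positive similarity floor that
#' co-occurrence embeddings give arbitrary word pairs. Stop-list tokens get
#' their own unclustered random unit vectors (they are in the table, as
#' function words are in real embedding corpora); designated OOV surfaces
#' are part of the lexicon but withheld from the table.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @param stoplist Stop words to include in the lexicon (defaults to the
#'   shipped list).
#' @return A `synth_embedding`: list with `table` (an `embedding_table`),
#'   `content_tokens`, `cluster_of` (integer vector parallel to
#'   `content_tokens`), `stop_tokens`, `oov_tokens`.
#' @export
synth_embedding <- function(cfg = synth_config(), seed = 1L,
                            stoplist = default_stoplist()) {
  set.seed(substream_seed(seed, "embedding"))
  K <- cfg$n_clusters
  d <- cfg$dim
  if (d < 2L || K < 2L) stop("need dim >= 2 and n_clusters >= 2",
                             call. = FALSE)
  if (d < K) {
    warning("embedding dimension ", d, " is small for ", K,
            " clusters; cluster separation will be limited", call. = FALSE)
  }
  centers <- matrix(stats::rnorm(K * d), K, d)
  centers <- unit_rows(centers)
  common <- unit_rows(matrix(stats::rnorm(d), 1, d))
  b <- cfg$base_similarity
  stopifnot(b >= 0, b < 1)
  a <- sqrt(b / (1 - b))   # blend weight giving between-cluster cosine ~ b
  vocab <- cfg$vocab_per_cluster
  content <- matrix(0, K * vocab, d)
  for (k in seq_len(K)) {
    noise <- matrix(stats::rnorm(vocab * d, sd = cfg$within_cluster_noise),
                    vocab, d)
    raw <- unit_rows(noise + matrix(centers[k, ], vocab, d, byrow = TRUE))
    rows <- (k - 1L) * vocab + seq_len(vocab)
    content[rows, ] <- unit_rows(raw + matrix(a * common, vocab, d,
                                              byrow = TRUE))
  }
  content_tokens <- paste0("w", rep(seq_len(K), each = vocab), "x",
                           rep(seq_len(vocab), K))
  rownames(content) <- content_tokens
  stop_vecs <- unit_rows(matrix(stats::rnorm(length(stoplist) * d),
                                length(stoplist), d))
  rownames(stop_vecs) <- stoplist
  table <- embedding_table(rbind(content, stop_vecs), case = "lower",
                           source_label = sprintf(
                             "synthetic K=%d dim=%d noise=%g seed=%d",
                             K, d, cfg$within_cluster_noise, seed))
  cluster_of <- rep(seq_len(K), each = vocab)
  structure(
    list(table = table,
         content_tokens = content_tokens,
         cluster_of = cluster_of,
         cluster_index = split(seq_along(cluster_of), cluster_of),
         stop_tokens = stoplist,
         oov_tokens = sprintf("novelword%03d", seq_len(cfg$n_oov))),
    class = "synth_embedding"
  )
}

#' @export
print.synth_embedding <- function(x, ...) {
  cat("<synth_embedding> ", length(x$content_tokens), " content tokens in ",
      max(x$cluster_of), " clusters, ", length(x$stop_tokens),
      " stop tokens, ", length(x$oov_tokens), " OOV surfaces\n", sep = "")
  invisible(x)
}

#' Sample one synthetic 1-minute transcript
#'
#' Content words follow a Markov cluster walk: the first word's cluster is
#' uniform; each subsequent content word stays in the current cluster with
#' probability `p_stay`, otherwise jumps to a uniformly chosen different
#' cluster; the word is uniform within its cluster. Stop words are
#' interleaved at `stopword_rate` and OOV surfaces injected at `oov_rate`.
#' Transcript length is drawn from the group's word-count distribution,
#' truncated at `min_words`. Uses the current RNG state; seed externally
#' for reproducibility.
#'
#' @param gen A `synth_embedding`.
#' @param p_stay Cluster-stay probability in `[0, 1]`.
#' @param cfg A [synth_config()].
#' @param group `"HC"` or `"FES"` (selects the word-count distribution).
#' @return Character scalar: the raw transcript text.
#' @export
sample_transcript <- function(gen, p_stay, cfg = synth_config(),
                              group = c("HC", "FES")) {
  group <- match.arg(group)
  stopifnot(p_stay >= 0, p_stay <= 1)
  K <- max(gen$cluster_of)
  n_words <- max(cfg$min_words,
                 round(stats::rnorm(1, cfg$words_mean[[group]],
                                    cfg$words_sd[[group]])))
  kind <- sample(c("content", "stop", "oov"), n_words, replace = TRUE,
                 prob = c(1 - cfg$stopword_rate - cfg$oov_rate,
                          cfg$stopword_rate, cfg$oov_rate))
  n_content <- sum(kind == "content")
  words <- character(n_words)
  if (n_content > 0L) {
    clusters <- integer(n_content)
    clusters[1L] <- sample.int(K, 1L)
    if (n_content > 1L) {
      stay <- stats::runif(n_content - 1L) < p_stay
      for (i in 2:n_content) {
        clusters[i] <- if (stay[i - 1L]) {
          clusters[i - 1L]
        } else {
          # uniform over the other K - 1 clusters
          k <- sample.int(K - 1L, 1L)
          if (k >= clusters[i - 1L]) k + 1L else k
        }
      }
    }
    idx_list <- if (is.null(gen$cluster_index)) {
      split(seq_along(gen$cluster_of), gen$cluster_of)
    } else {
      gen$cluster_index
    }
    sizes <- lengths(idx_list)[clusters]
    within <- ceiling(stats::runif(n_content) * sizes)
    picks <- mapply(function(k, w) idx_list[[k]][w], clusters, within)
    words[kind == "content"] <- gen$content_tokens[picks]
  }
  n_stop <- sum(kind == "stop")
  if (n_stop > 0L) {
    words[kind == "stop"] <- sample(gen$stop_tokens, n_stop, replace = TRUE)
  }
  n_oov <- sum(kind == "oov")
  if (n_oov > 0L) {
    words[kind == "oov"] <- sample(gen$oov_tokens, n_oov, replace = TRUE)
  }
  paste(words, collapse = " ")
}

# mean ASW-F over n_sim simulated transcripts at a given p_stay; scores via
# direct vocabulary lookup, which is provably identical to the
# tokenize/annotate path on generated text (generated words carry no
# punctuation, OOV surfaces are absent from the table, stop tokens are
# excluded either way)
simulated_mean_asw <- function(gen, p_stay, cfg, group, n_sim,
                               stoplist = gen$stop_tokens) {
  vocab <- rownames(gen$table)
  vals <- vapply(seq_len(n_sim), function(i) {
    txt <- sample_transcript(gen, p_stay, cfg, group)
    toks <- strsplit(txt, " ", fixed = TRUE)[[1]]
    idx <- match(toks, vocab)
    idx <- idx[!is.na(idx) & !(toks %in% stoplist)]
    asw_full(gen$table[idx, , drop = FALSE])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Calibrate the cluster-stay probability to a target mean ASW-F
#'
#' Monotone bisection on `p_stay` so that the simulated mean ASW-F over
#' `n_sim` transcripts is within `tol` of `target_asw`. Errors if the
#' target lies outside the achievable range of the embedding (the simulated
#' ASW-F at p_stay 0 and 1), reporting that interval.
#'
#' @param gen A `synth_embedding`.
#' @param target_asw Target group-mean ASW-F.
#' @param cfg A [synth_config()].
#' @param group Group whose word-count distribution to use.
#' @param n_sim Transcripts per evaluation (default 500).
#' @param tol Calibration tolerance on the mean (default 0.005).
#' @param seed Integer seed (common random numbers across evaluations).
#' @return Calibrated `p_stay` in `[0, 1]`.
#' @export
calibrate_p_stay <- function(gen, target_asw, cfg = synth_config(),
                             group = "HC", n_sim = 500L, tol = 0.005,
                             seed = 1L) {
  # common random numbers across evaluations: the simulated mean is then a
  # smooth monotone function of p_stay and bisection cannot chase noise
  eval_at <- function(p) {
    set.seed(substream_seed(seed, "calibrate", group))
    simulated_mean_asw(gen, p, cfg, group, n_sim)
  }
  lo <- 0; hi <- 1
  f_lo <- eval_at(lo)
  f_hi <- eval_at(hi)
  if (target_asw < f_lo - tol || target_asw > f_hi + tol) {
    stop(sprintf(
      "target ASW-F %.3f outside achievable range [%.3f, %.3f] of this embedding",
      target_asw, f_lo, f_hi), call. = FALSE)
  }
  if (target_asw <= f_lo) return(0)
  if (target_asw >= f_hi) return(1)
  # run to convergence in p: under common random numbers the evaluated curve
  # is smooth and monotone, so the bracket homes in on the exact crossing;
  # tol is verified at the end, not used as an early exit
  for (iter in 1:18) {
    mid <- (lo + hi) / 2
    f_mid <- eval_at(mid)
    if (f_mid < target_asw) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  f_mid <- eval_at(mid)
  if (abs(f_mid - target_asw) > tol) {
    stop(sprintf(
      "calibration did not converge: simulated mean %.4f vs target %.4f",
      f_mid, target_asw), call. = FALSE)
  }
  mid
}

# draw a vector with given mean/sd, correlated at r with standardized z
correlated_draw <- function(z, r, mean, sd) {
  noise <- stats::rnorm(length(z))
  mean + sd * (r * z + sqrt(1 - r^2) * noise)
}

#' Generate a synthetic cohort in memory
#'
#' Produces transcripts and a metadata table with the structure the
#' analysis pipeline consumes: `n_FES + n_HC` subjects, `n_pictures`
#' transcripts each at baseline, a follow-up subset with transcripts at the
#' follow-up cluster-stay probability, and clinical/cognitive covariates
#' drawn per group (Gaussian margins at the configured means/SDs) with the
#' configured correlations to each subject's realized ASW-F via a Gaussian
#' copula on the within-group ASW-F ranks. All randomness fans out from
#' `seed` through per-subject substreams, so outputs are independent of
#' generation order.
#'
#' @param cfg A [synth_config()].
#' @param seed Integer seed.
#' @param gen Optional pre-built `synth_embedding` (rebuilt from `seed` if
#'   NULL).
#' @param p_stay Optional named list `list(HC = c(baseline=, followup=),
#'   FES = ...)`; when NULL, calibrated from `cfg$target_asw` (slower).
#' @param calibration_n_sim Transcripts per calibration evaluation.
#' @return A `synth_cohort`: list with `metadata` (one row per subject x
#'   timepoint), `transcripts` (named character vector,
#'   `<subject>_<timepoint>_<picture>`), `truth` (generating parameters).
#' @export
synth_cohort <- function(cfg = synth_config(), seed = 1L, gen = NULL,
                         p_stay = NULL, calibration_n_sim = 1000L) {
  if (is.null(gen)) gen <- synth_embedding(cfg, seed)
  if (is.null(p_stay)) {
    p_stay <- lapply(setNames(c("HC", "FES"), c("HC", "FES")), function(grp) {
      vapply(c(baseline = "baseline", followup = "followup"), function(tp) {
        calibrate_p_stay(gen, cfg$target_asw[[grp]][[tp]], cfg, grp,
                         n_sim = calibration_n_sim, seed = seed)
      }, numeric(1))
    })
  }
  groups <- c(rep("FES", cfg$n_FES), rep("HC", cfg$n_HC))
  ids <- c(sprintf("FES%03d", seq_len(cfg$n_FES)),
           sprintf("HC%03d", seq_len(cfg$n_HC)))
  followup <- c(seq_len(cfg$n_FES) <= cfg$n_followup_FES,
                seq_len(cfg$n_HC) <= cfg$n_followup_HC)

  transcripts <- character(0)
  asw_subject <- list()  # realized subject-level mean ASW-F per timepoint
  for (i in seq_along(ids)) {
    grp <- groups[i]
    tps <- if (followup[i]) c("baseline", "followup") else "baseline"
    for (tp in tps) {
      vals <- numeric(cfg$n_pictures)
      for (pic in seq_len(cfg$n_pictures)) {
        set.seed(substream_seed(seed, "transcript", ids[i], tp, pic))
        txt <- sample_transcript(gen, p_stay[[grp]][[tp]], cfg, grp)
        transcripts[[paste(ids[i], tp, pic, sep = "_")]] <- txt
        t <- annotate_tokens(tokenize(txt), gen$stop_tokens, gen$table,
                             warn_oov = FALSE)
        vals[pic] <- asw_full(eligible_vectors(t, gen$table))
      }
      asw_subject[[paste(ids[i], tp, sep = "_")]] <- mean(vals, na.rm = TRUE)
    }
  }

  meta <- synth_metadata(cfg, seed, ids, groups, followup, asw_subject)
  structure(
    list(metadata = meta, transcripts = transcripts,
         truth = list(seed = seed, p_stay = p_stay,
                      target_asw = cfg$target_asw,
                      config = unclass(cfg))),
    class = "synth_cohort"
  )
}

# clinical/cognitive covariates for one cohort; z-couplings use the
# realized subject ASW-F (standardized within group) as the copula latent
synth_metadata <- function(cfg, seed, ids, groups, followup, asw_subject) {
  set.seed(substream_seed(seed, "covariates"))
  n <- length(ids)
  asw_base <- vapply(paste(ids, "baseline", sep = "_"),
                     function(k) asw_subject[[k]], numeric(1))
  z_asw <- stats::ave(asw_base, groups,
                      FUN = function(v) as.numeric(scale(v)))
  is_fes <- groups == "FES"

  draw_grp <- function(means, sds, r_by_group = c(FES = 0, HC = 0)) {
    out <- numeric(n)
    for (grp in c("FES", "HC")) {
      sel <- groups == grp
      out[sel] <- correlated_draw(z_asw[sel], r_by_group[[grp]],
                                  means[[grp]], sds[[grp]])
    }
    out
  }

  age <- round(draw_grp(c(FES = 22.0, HC = 21.4), c(FES = 3.6, HC = 3.2)), 1)
  gender <- ifelse(stats::runif(n) < ifelse(is_fes, 0.77, 0.67),
                   "male", "female")
  education_band <- ifelse(stats::runif(n) < ifelse(is_fes, 0.37, 0.27),
                           "<=12", ">12")
  ses_band <- ifelse(stats::runif(n) < ifelse(is_fes, 0.33, 0.42),
                     "<3", ">3")
  immigrant <- stats::runif(n) < ifelse(is_fes, 0.20, 0.30)
  first_language_english <- stats::runif(n) < ifelse(is_fes, 0.82, 0.88)

  dsst_r <- vapply(cfg$asw_cor, function(v) v[["DSST"]], numeric(1))
  dsst <- draw_grp(c(FES = 52.8, HC = 68.6), c(FES = 13.9, HC = 11.3),
                   dsst_r)
  dsst_oral <- pmax(0, round(dsst + stats::rnorm(n, 0, 2)))
  dsst_written <- pmax(0, round(2 * dsst - dsst_oral))

  stroop_r <- vapply(cfg$asw_cor, function(v) v[["stroop_total_correct"]],
                     numeric(1))
  stroop_total_correct <- pmin(84, pmax(
    0, round(draw_grp(c(FES = 70.8, HC = 78.2), c(FES = 13.1, HC = 3.1),
                      stroop_r))))
  stroop_total_time <- round(draw_grp(c(FES = 84.8, HC = 74.6),
                                      c(FES = 17.0, HC = 11.3)), 1)
  stroop_incongruent_time <- round(stroop_total_time / 2 +
                                     stats::rnorm(n, 5, 3), 1)
  stroop_W <- pmax(20, round(stats::rnorm(n, 100, 9)))
  stroop_C <- pmax(15, round(stats::rnorm(n, 75, 7)))
  ig_target <- draw_grp(c(FES = 7.09, HC = 8.89), c(FES = 3.5, HC = 1.5))
  stroop_CW <- pmax(0, round(stroop_W * stroop_C / (stroop_W + stroop_C) +
                               ig_target))

  fluency <- pmax(0, round(draw_grp(c(FES = 19.8, HC = 26.6),
                                    c(FES = 6.2, HC = 6.9))))

  sofas <- pmin(100, pmax(0, round(draw_grp(c(FES = 39.3, HC = 80.2),
                                            c(FES = 13.3, HC = 10)))))
  panss_pos <- ifelse(is_fes, pmax(4, round(stats::rnorm(n, 12.1, 3.0))), NA)
  panss_neg <- ifelse(is_fes, pmax(3, round(stats::rnorm(n, 7.4, 4.3))), NA)
  panss_tot <- ifelse(is_fes,
                      pmax(panss_pos + panss_neg + 1,
                           round(stats::rnorm(n, 25.6, 6.8))), NA)
  tli_total <- pmax(0, draw_grp(c(FES = 1.60, HC = 0.28),
                                c(FES = 1.3, HC = 0.3)))
  tli_dis <- pmax(0, draw_grp(c(FES = 1.01, HC = 0.153),
                              c(FES = 1.16, HC = 0.2)))
  tli_imp <- pmax(0, draw_grp(c(FES = 0.58, HC = 0.13),
                              c(FES = 0.74, HC = 0.2)))
  tli_dys <- pmax(0, draw_grp(c(FES = 0.17, HC = 0.06),
                              c(FES = 0.29, HC = 0.16)))
  cds <- ifelse(is_fes, pmax(0, round(stats::rnorm(n, 3.5, 3.3))), NA)
  cgi <- ifelse(is_fes, pmin(7, pmax(1, round(stats::rnorm(n, 5.2, 0.9)))), NA)
  med_class <- ifelse(is_fes,
                      sample(c("naive", "low_D2_occupancy",
                               "high_D2_occupancy"),
                             n, replace = TRUE, prob = c(0.5, 0.25, 0.25)),
                      NA)
  daily_dose <- ifelse(is_fes & med_class != "naive",
                       pmax(0.05, stats::rnorm(n, 0.81, 0.49)), 0)
  total_dose <- ifelse(is_fes,
                       pmax(0, stats::rnorm(n, 160.7, 110)), NA)

  base <- data.frame(
    subject_id = ids, group = groups, timepoint = "baseline",
    age = age, gender = gender, education_band = education_band,
    parental_SES_band = ses_band, immigrant = immigrant,
    first_language_english = first_language_english,
    PANSS8_pos = panss_pos, PANSS8_neg = panss_neg, PANSS8_total = panss_tot,
    SOFAS = sofas, TLI_total = round(tli_total, 2),
    TLI_disorganization = round(tli_dis, 2),
    TLI_impoverishment = round(tli_imp, 2),
    TLI_dysregulation = round(tli_dys, 2),
    CDS = cds, CGI_S = cgi, medication_class = med_class,
    daily_dose_DDD = round(daily_dose, 2),
    total_dose = round(total_dose, 1),
    stroop_W = stroop_W, stroop_C = stroop_C, stroop_CW = stroop_CW,
    stroop_total_correct = stroop_total_correct,
    stroop_total_time = stroop_total_time,
    stroop_incongruent_time = stroop_incongruent_time,
    DSST_oral = dsst_oral, DSST_written = dsst_written,
    fluency_count = fluency,
    stringsAsFactors = FALSE
  )

  # follow-up rows: symptomatic improvement for patients, PANSS-8 negative
  # change coupled to the subject's realized ASW-F change
  fu_ids <- ids[followup]
  fu <- base[match(fu_ids, base$subject_id), ]
  fu$timepoint <- "followup"
  nf <- nrow(fu)
  fu_fes <- fu$group == "FES"
  asw_fu <- vapply(paste(fu_ids, "followup", sep = "_"),
                   function(k) asw_subject[[k]], numeric(1))
  asw_b <- vapply(paste(fu_ids, "baseline", sep = "_"),
                  function(k) asw_subject[[k]], numeric(1))
  d_asw <- asw_fu - asw_b
  z_d <- as.numeric(scale(d_asw))
  z_d[is.na(z_d)] <- 0
  panss_tot_change <- stats::rnorm(nf, -10.25, 4.9)
  panss_pos_change <- stats::rnorm(nf, -7.3, 2.0)
  rho_neg <- cfg$panss_neg_change_cor
  panss_neg_change <- 0.3 + 3.9 * (rho_neg * z_d +
                                     sqrt(1 - rho_neg^2) * stats::rnorm(nf))
  fu$PANSS8_pos <- ifelse(fu_fes,
                          pmax(4, round(fu$PANSS8_pos + panss_pos_change)), NA)
  fu$PANSS8_neg <- ifelse(fu_fes,
                          pmax(3, round(fu$PANSS8_neg + panss_neg_change)), NA)
  fu$PANSS8_total <- ifelse(fu_fes,
                            pmax(8, round(fu$PANSS8_total + panss_tot_change)),
                            NA)
  fu$SOFAS <- pmin(100, pmax(0, round(
    fu$SOFAS + ifelse(fu_fes, stats::rnorm(nf, 19.5, 14.3),
                      stats::rnorm(nf, 0, 5)))))
  fu$medication_class <- ifelse(
    fu_fes, sample(c("low_D2_occupancy", "high_D2_occupancy"), nf,
                   replace = TRUE), NA)

  rbind(base, fu)
}

#' Write a synthetic cohort to disk
#'
#' Emits one transcript file per subject x timepoint x picture
#' (`<subject>_<timepoint>_<picture>.txt`), the metadata CSV the pipeline
#' consumes (`metadata.csv`), and `truth.json` recording the generating
#' parameters for recovery tests.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tdir <- file.path(dir, "transcripts")
  dir.create(tdir, showWarnings = FALSE)
  for (nm in names(cohort$transcripts)) {
    writeLines(cohort$transcripts[[nm]], file.path(tdir, paste0(nm, ".txt")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.synth_cohort <- function(x, ...) {
  m <- x$metadata
  cat("<synth_cohort> ", length(unique(m$subject_id)), " subjects (",
      sum(m$group == "FES" & m$timepoint == "baseline"), " FES, ",
      sum(m$group == "HC" & m$timepoint == "baseline"), " HC); ",
      length(x$transcripts), " transcripts\n", sep = "")
  invisible(x)
}

#' End-to-end parameter-recovery simulation
#'
#' Repeatedly generates two-group cohorts of picture descriptions (3 per
#' subject) and runs the baseline group comparison on subject-mean ASW-F:
#' each replicate scores every transcript through the same preprocessing
#' and similarity path the study pipeline uses, aggregates to subject
#' means, and computes the default Bayesian independent t test. Under
#' `null = TRUE` the two groups are fully exchangeable (common cluster-stay
#' probability and a common word-count distribution), so any group
#' difference is a false positive.
#'
#' @param gen A `synth_embedding`.
#' @param p_stay_hc,p_stay_fes Cluster-stay probabilities (under
#'   `null = TRUE`, `p_stay_hc` is used for both groups).
#' @param cfg A [synth_config()] (supplies group sizes and word-count
#'   distributions).
#' @param n_rep Number of replicate cohorts.
#' @param seed Integer seed; each replicate uses its own substream.
#' @param null Generate exchangeable groups instead of the group effect.
#' @return Numeric vector of `n_rep` Bayes factors.
#' @export
recovery_simulation <- function(gen, p_stay_hc, p_stay_fes,
                                cfg = synth_config(), n_rep = 200L,
                                seed = 1L, null = FALSE) {
  subject_means <- function(p, grp, n_subj) {
    vapply(seq_len(n_subj), function(i) {
      mean(vapply(seq_len(cfg$n_pictures), function(pic) {
        txt <- sample_transcript(gen, p, cfg, grp)
        t <- annotate_tokens(tokenize(txt), gen$stop_tokens, gen$table,
                             warn_oov = FALSE)
        asw_full(eligible_vectors(t, gen$table))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  vapply(seq_len(n_rep), function(rep) {
    set.seed(substream_seed(seed, "recovery", if (null) "null" else "effect",
                            rep))
    hc <- subject_means(p_stay_hc, "HC", cfg$n_HC)
    fes <- if (null) {
      # exchangeable null: same process for both groups, labels only
      subject_means(p_stay_hc, "HC", cfg$n_FES)
    } else {
      subject_means(p_stay_fes, "FES", cfg$n_FES)
    }
    bf_ttest_independent(x = hc, y = fes)$bf10
  }, numeric(1))
}
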