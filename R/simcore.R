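#' Ordered eligible word vectors for a transcript
#'
#' Eligible tokens are those found in the embedding table, excluding stop
#' words unless `include_stops = TRUE`. Order of occurrence is preserved,
#' which matters for the moving-window metric.
#'
#' @param t A `tokenized_transcript`.
#' @param table An `embedding_table`.
#' @param include_stops Include stop words in the similarity computation.
#' @return Numeric matrix with one row per eligible token (0-row matrix if
#'   none).
#' @export
eligible_vectors <- function(t, table, include_stops = FALSE) {
  stopifnot(inherits(t, "tokenized_transcript"),
            inherits(table, "embedding_table"))
  keep <- t$tokens$in_vocab & (include_stops | !t$tokens$is_stop)
  toks <- t$tokens$normalized[keep]
  m <- table[match(toks, rownames(table)), , drop = FALSE]
  rownames(m) <- toks
  class(m) <- c("matrix", "array")
  m
}

#' Average similarity of words over the full frame (ASW-F)
#'
#' Mean cosine similarity over all C(n, 2) unordered pairs of word vectors
#' (`pair_mode = "all_pairs"`, the default), or over the n - 1 successive
#' pairs (`"adjacent"`). Undefined (NA) when fewer than two vectors are
#' available.
#'
#' @param seq Numeric matrix of word vectors, one row per token, in order.
#' @param pair_mode `"all_pairs"` or `"adjacent"`.
#' @return Mean similarity in `[-1, 1]`, or `NA_real_` if `nrow(seq) < 2`.
#' @export
asw_full <- function(seq, pair_mode = c("all_pairs", "adjacent")) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(is.matrix(seq), is.numeric(seq))
  n <- nrow(seq)
  if (n < 2L) return(NA_real_)
  u <- unit_rows(seq)
  if (pair_mode == "adjacent") {
    return(mean(rowSums(u[-n, , drop = FALSE] * u[-1, , drop = FALSE])))
  }
  s <- tcrossprod(u)
  # sum of strictly-upper-triangular cosines over the number of pairs
  (sum(s) - n) / (n * (n - 1))
}

#' Average similarity of words over a moving window (ASW-10)
#'
#' Slides a window of `window` eligible tokens, step 1, across the sequence;
#' computes [asw_full()] within each window and averages over all window
#' positions. Only full windows are used; when the sequence is no longer
#' than the window the whole sequence is the single frame, so the result
#' equals `asw_full(seq)` exactly. Undefined (NA) for fewer than two
#' vectors.
#'
#' @inheritParams asw_full
#' @param window Window size in eligible tokens (>= 2); default 10.
#' @return Mean within-window similarity, or `NA_real_`.
#' @export
asw_window <- function(seq, window = 10L,
                       pair_mode = c("all_pairs", "adjacent")) {
  pair_mode <- match.arg(pair_mode)
  stopifnot(is.matrix(seq), is.numeric(seq))
  if (!is.numeric(window) || length(window) != 1L || window < 2) {
    stop("window must be a single integer >= 2", call. = FALSE)
  }
  window <- as.integer(window)
  n <- nrow(seq)
  if (n < 2L) return(NA_real_)
  if (n <= window) return(asw_full(seq, pair_mode))
  u <- unit_rows(seq)
  n_win <- n - window + 1L
  if (pair_mode == "adjacent") {
    adj <- rowSums(u[-n, , drop = FALSE] * u[-1, , drop = FALSE])
    # each window averages its window-1 successive-pair cosines
    csum <- c(0, cumsum(adj))
    win_means <- (csum[(window:n)] - csum[window:n - window + 1L]) /
      (window - 1L)
    return(mean(win_means))
  }
  s <- tcrossprod(u)
  np <- window * (window - 1L) / 2
  # incremental update: sliding the window drops row i-1 and adds row i+window-1
  idx <- seq_len(window)
  cur <- (sum(s[idx, idx]) - window) / 2
  total <- cur / np
  for (start in seq_len(n_win - 1L)) {
    drop_i <- start
    add_i <- start + window
    inside <- (start + 1L):(start + window - 1L)
    cur <- cur - sum(s[drop_i, inside]) + sum(s[add_i, inside])
    total <- total + cur / np
  }
  total / n_win
}

#' Similarity profile of one transcript
#'
#' Bundles the word count and both similarity metrics for a single
#' annotated transcript into a one-row data frame.
#'
#' @param t A `tokenized_transcript`.
#' @param table An `embedding_table`.
#' @param window Moving-window size (default 10).
#' @param pair_mode `"all_pairs"` (default) or `"adjacent"`.
#' @param include_stops Include stop words in similarity (default FALSE).
#' @return Data frame with columns subject_id, picture_id, timepoint, NW,
#'   n_eligible, ASW_F, ASW_10, pair_mode, window. Metrics are NA when fewer
#'   than two eligible tokens exist; NA never silently becomes 0.
#' @export
profile_transcript <- function(t, table, window = 10L,
                               pair_mode = c("all_pairs", "adjacent"),
                               include_stops = FALSE) {
  pair_mode <- match.arg(pair_mode)
  seq <- eligible_vectors(t, table, include_stops = include_stops)
  data.frame(
    subject_id = t$subject_id,
    picture_id = t$picture_id,
    timepoint = t$timepoint,
    NW = word_count(t),
    n_eligible = nrow(seq),
    ASW_F = asw_full(seq, pair_mode),
    ASW_10 = asw_window(seq, window, pair_mode),
    pair_mode = pair_mode,
    window = as.integer(window),
    stringsAsFactors = FALSE
  )
}

#' Aggregate per-picture profiles to one subject x timepoint row
#'
#' Arithmetic means of NW, ASW-F and ASW-10 across a subject's picture
#' descriptions at one timepoint. Undefined per-picture values are excluded
#' from the mean with a warning; if no picture yields a defined value the
#' aggregate is NA.
#'
#' @param profiles Data frame of per-transcript rows (from
#'   [profile_transcript()]), all sharing subject_id and timepoint.
#' @return One-row data frame: subject_id, timepoint, n_pictures, NW_mean,
#'   ASW_F_mean, ASW_10_mean.
#' @export
aggregate_subject <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L)
  if (length(unique(profiles$subject_id)) != 1L ||
      length(unique(profiles$timepoint)) != 1L) {
    stop("profiles must share one subject_id and one timepoint",
         call. = FALSE)
  }
  mean_defined <- function(x, label) {
    ok <- !is.na(x)
    if (!all(ok)) {
      warning(sum(!ok), " undefined ", label, " value(s) for subject ",
              profiles$subject_id[1L], " excluded from the mean",
              call. = FALSE)
    }
    if (!any(ok)) return(NA_real_)
    mean(x[ok])
  }
  data.frame(
    subject_id = profiles$subject_id[1L],
    timepoint = profiles$timepoint[1L],
    n_pictures = nrow(profiles),
    NW_mean = mean_defined(profiles$NW, "NW"),
    ASW_F_mean = mean_defined(profiles$ASW_F, "ASW-F"),
    ASW_10_mean = mean_defined(profiles$ASW_10, "ASW-10"),
    stringsAsFactors = FALSE
  )
}
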