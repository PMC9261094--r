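#' Default English stop list
#'
#' A standard snowball-style English function-word list shipped with the
#' package (`inst/extdata/stopwords_en.txt`). Used to mark stop words during
#' transcript annotation; override with any character vector.
#'
#' @param case Case rule applied to the list (should match the embedding
#'   table's rule).
#' @return Character vector of stop words.
#' @export
default_stoplist <- function(case = c("lower", "preserve")) {
  case <- match.arg(case)
  path <- system.file("extdata", "stopwords_en.txt", package = "semsim")
  words <- readLines(path, encoding = "UTF-8", warn = FALSE)
  words <- words[nzchar(words)]
  normalize_token(words, case)
}

#' Tokenize a raw transcript
#'
#' Splits on whitespace (hyphens and slashes also split), strips leading and
#' trailing punctuation from each piece, and drops empties. Internal
#' apostrophes are preserved ("it's", "man's"); digits are kept; no case
#' folding happens here (annotation applies the case rule).
#'
#' @param raw_text Character scalar (UTF-8). Empty or whitespace-only input
#'   yields an empty token vector, not an error.
#' @return Character vector of surface tokens in order of occurrence.
#' @examples
#' tokenize("The cat, sat.")        # "The" "cat" "sat"
#' tokenize("it's a man's hat —")
#' @export
tokenize <- function(raw_text) {
  stopifnot(is.character(raw_text))
  raw_text <- paste(raw_text, collapse = " ")
  if (!nzchar(trimws(raw_text))) return(character(0))
  # hyphen/em-dash/slash act as separators; apostrophes survive inside words
  txt <- gsub("[-‐-―/]", " ", raw_text)
  pieces <- strsplit(trimws(txt), "[[:space:]]+")[[1]]
  # strip anything that is not a letter, digit or apostrophe at the edges
  pieces <- gsub("^[^[:alnum:]']+|[^[:alnum:]']+$", "", pieces)
  # normalize typographic apostrophes, then drop apostrophe-only leftovers
  pieces <- gsub("’", "'", pieces)
  pieces <- gsub("^'+|'+$", "", pieces)
  pieces[nzchar(pieces)]
}

#' Annotate tokens with stop-word and vocabulary flags
#'
#' Flags each token as a stop word iff its normalized form is in `stoplist`,
#' and as in-vocabulary iff it is present in the embedding table. Every
#' out-of-vocabulary surface form is collected in `oov_report` and emitted as
#' a warning, mirroring the behaviour of similarity tools that ignore
#' unknown words but tell you about them.
#'
#' @param tokens Character vector of surface tokens (from [tokenize()]).
#' @param stoplist Character vector of stop words, normalized under the same
#'   case rule as the table.
#' @param table An `embedding_table`.
#' @param subject_id,picture_id,timepoint Provenance carried on the result.
#' @param warn_oov Emit one warning listing the OOV surfaces (default TRUE).
#' @return A `tokenized_transcript`: list with `tokens` (data.frame with
#'   columns surface, is_stop, in_vocab), `oov_report`, and the provenance
#'   fields.
#' @export
annotate_tokens <- function(tokens, stoplist, table,
                            subject_id = NA_character_,
                            picture_id = NA_character_,
                            timepoint = NA_character_,
                            warn_oov = TRUE) {
  stopifnot(is.character(tokens), inherits(table, "embedding_table"))
  case <- attr(table, "case")
  norm <- normalize_token(tokens, case)
  is_stop <- norm %in% normalize_token(stoplist, case)
  in_vocab <- norm %in% rownames(table)
  oov <- unique(tokens[!in_vocab])
  if (warn_oov && length(oov) > 0L) {
    warning("words not found in the embedding table: ",
            paste(oov, collapse = ", "), call. = FALSE)
  }
  structure(
    list(
      subject_id = subject_id,
      picture_id = as.character(picture_id),
      timepoint = timepoint,
      tokens = data.frame(surface = tokens, normalized = norm,
                          is_stop = is_stop, in_vocab = in_vocab,
                          stringsAsFactors = FALSE),
      oov_report = oov
    ),
    class = "tokenized_transcript"
  )
}

#' @export
print.tokenized_transcript <- function(x, ...) {
  cat("<tokenized_transcript> subject ", x$subject_id, ", picture ",
      x$picture_id, ", ", x$timepoint, ": ", nrow(x$tokens), " tokens (",
      sum(x$tokens$is_stop), " stop, ", sum(!x$tokens$in_vocab),
      " OOV)\n", sep = "")
  invisible(x)
}

#' Number of words in a transcript
#'
#' Counts all tokens remaining after punctuation removal, including stop
#' words and out-of-vocabulary words. Counting function words is what makes
#' a 1-minute description land near the natural speech rate of ~70 words.
#'
#' @param t A `tokenized_transcript`.
#' @param include_stops,include_oov Set FALSE to restrict the count.
#' @return Nonnegative integer.
#' @export
word_count <- function(t, include_stops = TRUE, include_oov = TRUE) {
  stopifnot(inherits(t, "tokenized_transcript"))
  keep <- rep(TRUE, nrow(t$tokens))
  if (!include_stops) keep <- keep & !t$tokens$is_stop
  if (!include_oov) keep <- keep & t$tokens$in_vocab
  sum(keep)
}

#' Read a plain-text transcript file
#'
#' One file per subject x picture x timepoint; the text is assumed to be
#' pre-cleaned participant-only speech.
#'
#' @param path File path.
#' @return Character scalar.
#' @export
read_transcript <- function(path) {
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = " ")
}

#' Extract participant speech from a CHAT (.cha) file
#'
#' Keeps main-tier utterances of the target participant code and strips CHAT
#' markup: headers (`@...`), dependent tiers (`%...`), bracketed codes,
#' angle-bracket scoping, pause/timing marks, and `&`-prefixed fragment
#' codes. Retraced material (`<...> [/]`, `[//]`) keeps the spoken words.
#'
#' @param path Path to a .cha file.
#' @param participant Speaker code of the target participant (default "PAR").
#' @return Character scalar with the participant's speech.
#' @export
read_chat <- function(path, participant = "PAR") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # join continuation lines (tab-indented) onto their tier line
  joined <- character(0)
  for (ln in lines) {
    if (grepl("^\t", ln) && length(joined) > 0L) {
      joined[length(joined)] <- paste(joined[length(joined)], trimws(ln))
    } else {
      joined <- c(joined, ln)
    }
  }
  tier <- paste0("*", participant, ":")
  utts <- joined[startsWith(joined, tier)]
  utts <- sub("^\\*[A-Za-z0-9]+:\\s*", "", utts)
  txt <- paste(utts, collapse = " ")
  txt <- gsub("\x15[0-9_ ]*\x15", " ", txt)    # time alignment marks
  txt <- gsub("\\[[^]]*\\]", " ", txt)             # bracketed codes
  txt <- gsub("[<>]", " ", txt)                    # scoping markers
  txt <- gsub("&[-=+]?[[:alnum:]:]+", " ", txt)    # fragments/fillers coded with &
  txt <- gsub("\\+[.?!/^<,\"]*", " ", txt)         # utterance terminators like +...
  txt <- gsub("\\([0-9.]+\\)", " ", txt)           # timed pauses
  txt <- gsub("[()]", "", txt)                     # shortening parens: (be)cause
  txt <- gsub("xxx|yyy|www", " ", txt)             # unintelligible codes
  txt <- gsub("@[[:alnum:]:]+", "", txt)           # word-level @ markers
  txt <- gsub("[[:space:]]+", " ", txt)
  trimws(txt)
}
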