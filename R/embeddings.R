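#' Read a word-vector table in GloVe text format
#'
#' Parses a plain-text embedding file with one record per line: a token
#' followed by D whitespace-separated floats, no header. All rows must have
#' the same dimension; duplicate tokens and all-zero vectors are rejected,
#' since either usually signals a corrupted vector file.
#'
#' @param path Path to the vector file (UTF-8).
#' @param expected_dimension Optional positive integer; if given, the file's
#'   dimension must equal it.
#' @param case Token normalization rule: `"lower"` (default) folds tokens to
#'   lower case before storing, `"preserve"` keeps them as-is. The same rule
#'   must be used when normalizing transcript tokens and stop lists.
#' @return An `embedding_table`: a numeric matrix with one row per token
#'   (rownames are the normalized tokens) and attributes `case` and
#'   `source_label`.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("cat 1 0 0", "dog 0 1 0", "the 0 0 1"), tf)
#' tab <- read_glove(tf)
#' dim(tab)
#' @export
read_glove <- function(path, expected_dimension = NULL,
                       case = c("lower", "preserve")) {
  case <- match.arg(case)
  if (!file.exists(path)) {
    stop("embedding file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    stop("embedding file is empty: ", path, call. = FALSE)
  }
  parts <- strsplit(lines, "[ \t]+")
  tokens <- vapply(parts, `[[`, character(1), 1L)
  if (case == "lower") tokens <- tolower(tokens)
  dims <- lengths(parts) - 1L
  dimension <- dims[1L]
  if (dimension < 1L) {
    stop("malformed embedding file: line ", line_no[1L],
         " has a token but no vector", call. = FALSE)
  }
  bad <- which(dims != dimension)
  if (length(bad) > 0L) {
    stop("malformed embedding file: line ", line_no[bad[1L]], " has ",
         dims[bad[1L]], " values but line ", line_no[1L], " has ",
         dimension, call. = FALSE)
  }
  if (!is.null(expected_dimension) && dimension != expected_dimension) {
    stop("embedding dimension is ", dimension, ", expected ",
         expected_dimension, call. = FALSE)
  }
  dup <- which(duplicated(tokens))
  if (length(dup) > 0L) {
    stop("duplicate token in embedding file: '", tokens[dup[1L]],
         "' at line ", line_no[dup[1L]], call. = FALSE)
  }
  vals <- suppressWarnings(
    as.numeric(unlist(lapply(parts, `[`, -1L), use.names = FALSE))
  )
  if (anyNA(vals)) {
    first_bad <- ceiling(which(is.na(vals))[1L] / dimension)
    stop("malformed embedding file: non-numeric value at line ",
         line_no[first_bad], call. = FALSE)
  }
  mat <- matrix(vals, nrow = length(tokens), ncol = dimension, byrow = TRUE)
  rownames(mat) <- tokens
  zero <- which(rowSums(mat != 0) == 0L)
  if (length(zero) > 0L) {
    stop("all-zero vector for token '", tokens[zero[1L]], "' at line ",
         line_no[zero[1L]], call. = FALSE)
  }
  embedding_table(mat, case = case, source_label = basename(path))
}

#' Construct an embedding table from a numeric matrix
#'
#' @param vectors Numeric matrix, one row per token; rownames are tokens.
#' @param case Normalization rule that was (or will be) applied to tokens.
#' @param source_label Free-text provenance label.
#' @return An `embedding_table` object.
#' @export
embedding_table <- function(vectors, case = "lower", source_label = "matrix") {
  stopifnot(is.matrix(vectors), is.numeric(vectors))
  if (is.null(rownames(vectors))) {
    stop("embedding matrix must have token rownames", call. = FALSE)
  }
  if (anyDuplicated(rownames(vectors))) {
    stop("duplicate tokens in embedding matrix", call. = FALSE)
  }
  if (any(rowSums(vectors != 0) == 0L)) {
    stop("embedding matrix contains an all-zero vector", call. = FALSE)
  }
  structure(vectors, class = c("embedding_table", "matrix", "array"),
            case = case, source_label = source_label)
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x), " tokens x ", ncol(x), " dimensions",
      " (case = ", attr(x, "case"), ", source = ",
      attr(x, "source_label"), ")\n", sep = "")
  invisible(x)
}

#' Write an embedding table in GloVe text format
#'
#' One record per line, `token v1 v2 ... vD`, single-space separated,
#' no header. Reloading with [read_glove()] under the same case rule
#' round-trips all lookups.
#'
#' @param table An `embedding_table`.
#' @param path Output file path.
#' @param digits Significant digits used when formatting vector entries.
#' @return `path`, invisibly.
#' @export
write_glove <- function(table, path, digits = 17) {
  stopifnot(inherits(table, "embedding_table"))
  rows <- vapply(seq_len(nrow(table)), function(i) {
    paste(c(rownames(table)[i],
            format(table[i, ], digits = digits, scientific = FALSE,
                   trim = TRUE)),
          collapse = " ")
  }, character(1))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Normalize a token under a table's case rule
#' @noRd
normalize_token <- function(token, case) {
  if (identical(case, "lower")) tolower(token) else token
}

#' Look up the vector for a token
#'
#' Applies the table's case rule to `token` before lookup. A token absent
#' from the vocabulary returns `NULL` (a distinguishable missing value),
#' never a default vector.
#'
#' @param table An `embedding_table`.
#' @param token Character scalar.
#' @return Numeric vector of length `ncol(table)`, or `NULL` if the token
#'   is out of vocabulary.
#' @export
vector_for <- function(table, token) {
  stopifnot(inherits(table, "embedding_table"), is.character(token),
            length(token) == 1L)
  key <- normalize_token(token, attr(table, "case"))
  idx <- match(key, rownames(table))
  if (is.na(idx)) return(NULL)
  as.numeric(table[idx, ])
}

#' Test whether tokens are in the embedding vocabulary
#'
#' @param table An `embedding_table`.
#' @param tokens Character vector (normalized under the table's case rule).
#' @return Logical vector.
#' @export
has_token <- function(table, tokens) {
  normalize_token(tokens, attr(table, "case")) %in% rownames(table)
}

#' Cosine similarity of two vectors
#'
#' `dot(u, v) / (||u|| ||v||)`; symmetric and invariant to positive
#' rescaling of either argument.
#'
#' @param u,v Numeric vectors of equal length, neither all zeros.
#' @return A number in `[-1, 1]` (up to machine rounding).
#' @examples
#' cosine_similarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(is.numeric(u), is.numeric(v))
  if (length(u) != length(v)) {
    stop("vectors have different lengths (", length(u), " vs ", length(v),
         ")", call. = FALSE)
  }
  nu <- sqrt(sum(u * u))
  nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero-norm vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

# Row-normalize a vector matrix so that pairwise cosines are crossprods.
unit_rows <- function(m) {
  n <- sqrt(rowSums(m * m))
  m / n
}
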