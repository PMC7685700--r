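#' Tokenize free text
#'
#' Lowercases and splits on runs of non-alphanumeric characters, dropping
#' empty tokens. This is the single tokenization used by all lexicon and
#' keyword matching, so counts are comparable across features.
#'
#' @param text Character vector (may be empty or `NA`).
#' @return A list of character token vectors, one per input element.
#' @examples
#' tokenize("What not to do?")
#' @export
tokenize <- function(text) {
  text[is.na(text)] <- ""
  stringr::str_extract_all(tolower(text), "[a-z0-9]+")
}

#' Construct a stem lexicon
#'
#' A lexicon maps named psychological dimensions to lists of patterns. A
#' pattern is either a lowercase literal token or a stem ending in `*`
#' (prefix match), mirroring the dictionary format used by word-count text
#' scoring tools. A token may match several dimensions.
#'
#' @param dimensions Named list: dimension name -> character vector of
#'   patterns.
#' @param name Optional lexicon name.
#' @return An object of class `lexicon`.
#' @examples
#' lx <- lexicon(list(negemo = c("sad*", "angry"), work = c("work*", "job")))
#' @export
lexicon <- function(dimensions, name = "lexicon") {
  if (!is.list(dimensions) || is.null(names(dimensions)) ||
      any(!nzchar(names(dimensions)))) {
    abort("`dimensions` must be a named list of pattern vectors")
  }
  dimensions <- lapply(dimensions, as.character)
  if (any(lengths(dimensions) == 0)) abort("lexicon has an empty dimension")
  ok <- vapply(dimensions, function(p) all(nzchar(p)) && all(p == tolower(p)),
               logical(1))
  if (!all(ok)) abort("patterns must be nonempty and lowercase")
  structure(list(name = name, dimensions = dimensions), class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon>", x$name, "-", length(x$dimensions), "dimensions\n")
  for (d in names(x$dimensions)) {
    cat(sprintf("  %-12s %s\n", d, paste(head(x$dimensions[[d]], 8), collapse = " ")))
  }
  invisible(x)
}

#' Read a lexicon file
#'
#' Two dialects are supported. The `.dic` dialect follows the classic
#' word-count dictionary layout: a header block delimited by lines containing
#' only `%`, with `id<TAB>name` rows, followed by `stem<TAB>id [id ...]`
#' rows. The YAML dialect is simply a mapping from dimension names to pattern
#' lists.
#'
#' @param path Path to a `.dic` or `.yml`/`.yaml` file.
#' @return A [lexicon()] object.
#' @export
read_lexicon <- function(path) {
  if (grepl("\\.dic$", path, ignore.case = TRUE)) {
    lines <- trimws(readLines(path, warn = FALSE), which = "right")
    lines <- lines[nzchar(lines)]
    pct <- which(trimws(lines) == "%")
    if (length(pct) < 2) abort(".dic file needs a %-delimited header block")
    header <- lines[(pct[1] + 1):(pct[2] - 1)]
    body <- lines[-seq_len(pct[2])]
    ids <- list()
    for (h in header) {
      parts <- strsplit(h, "[ \t]+")[[1]]
      ids[[parts[1]]] <- parts[2]
    }
    dims <- setNames(vector("list", length(ids)), unlist(ids))
    for (b in body) {
      parts <- strsplit(b, "[ \t]+")[[1]]
      stem <- tolower(parts[1])
      for (id in parts[-1]) {
        nm <- ids[[id]]
        if (is.null(nm)) abort(paste("unknown dimension id in .dic body:", id))
        dims[[nm]] <- c(dims[[nm]], stem)
      }
    }
    lexicon(dims, name = basename(path))
  } else {
    lexicon(yaml::read_yaml(path), name = basename(path))
  }
}

# logical: does each unique token match any pattern of the dimension
match_tokens <- function(tokens, patterns) {
  stems <- patterns[endsWith(patterns, "*")]
  literals <- patterns[!endsWith(patterns, "*")]
  hit <- tokens %in% literals
  for (s in sub("\\*$", "", stems)) {
    hit <- hit | startsWith(tokens, s)
  }
  hit
}

#' Count lexicon-dimension words in a text stream
#'
#' Tokenizes all texts, then counts tokens matching each dimension (a token
#' may count toward several dimensions). Counting is additive over text
#' partitions and order-independent.
#'
#' @param texts Character vector of texts (one blob per event is typical).
#' @param lex A [lexicon()].
#' @return A tibble of class `dimension_counts` with `dimension`, `count`,
#'   `percent` (of total tokens; `NA` when there are no tokens), and a
#'   `total_tokens` attribute/column.
#' @examples
#' lexicon_counts("sad sad happy", lexicon(list(neg = "sad*")))
#' @export
lexicon_counts <- function(texts, lex) {
  stopifnot(inherits(lex, "lexicon"))
  tokens <- unlist(tokenize(texts), use.names = FALSE)
  total <- length(tokens)
  vocab <- table(tokens)
  uniq <- names(vocab)
  counts <- unname(vapply(lex$dimensions, function(p) {
    if (total == 0) return(0L)
    as.integer(sum(vocab[match_tokens(uniq, p)]))
  }, integer(1)))
  out <- tibble(
    dimension = names(lex$dimensions),
    count = counts,
    percent = if (total > 0) counts / total * 100 else NA_real_,
    total_tokens = total
  )
  structure(out, class = c("dimension_counts", class(out)))
}

#' Per-dimension relative change in lexicon counts
#'
#' Applies the relative-change rule to each dimension's word count (default)
#' or to its percent-of-total-tokens share (`measure = "percent"`), between
#' the before and after text streams. Search text and video-title streams
#' should be passed separately, as their language differs.
#'
#' @param before_texts,after_texts Character vectors of texts.
#' @param lex A [lexicon()].
#' @param measure `"count"` or `"percent"`.
#' @inheritParams relative_change
#' @return A tibble with `dimension`, `before`, `after`, `change_percent`.
#' @export
lexicon_relative_change <- function(before_texts, after_texts, lex,
                                    zero_policy = c("strict", "pseudo"),
                                    measure = c("count", "percent")) {
  zero_policy <- match.arg(zero_policy)
  measure <- match.arg(measure)
  b <- lexicon_counts(before_texts, lex)
  a <- lexicon_counts(after_texts, lex)
  bv <- b[[measure]]
  av <- a[[measure]]
  tibble(
    dimension = b$dimension,
    before = bv,
    after = av,
    change_percent = dplyr::if_else(
      is.na(bv) | is.na(av), NA_real_,
      relative_change(dplyr::coalesce(bv, 0), dplyr::coalesce(av, 0), zero_policy)
    )
  )
}

#' Weighted summary score over lexicon dimensions
#'
#' A generic hook for composite text scores built as weighted sums of
#' dimension percents (for example an "authenticity"-style or an emotional
#' "tone"-style composite). The weights are supplied by the caller; no
#' proprietary composite formula is shipped.
#'
#' @param texts Character vector of texts.
#' @param lex A [lexicon()].
#' @param weights Named numeric vector: dimension -> weight.
#' @param intercept Constant added to the weighted sum.
#' @return A single numeric score (`NA` when the stream has no tokens).
#' @export
lexicon_summary_score <- function(texts, lex, weights, intercept = 0) {
  counts <- lexicon_counts(texts, lex)
  miss <- setdiff(names(weights), counts$dimension)
  if (length(miss)) abort(paste("weights name unknown dimensions:", paste(miss, collapse = ", ")))
  p <- counts$percent[match(names(weights), counts$dimension)]
  if (anyNA(p)) return(NA_real_)
  intercept + sum(weights * p)
}

#' Default summary-score weight sets
#'
#' Two built-in composites for the bundled synthetic lexicon: `authentic`
#' (weight on first-person language) and `tone` (positive minus negative
#' emotion). These are illustrative weight choices for the generic
#' [lexicon_summary_score()] hook.
#'
#' @return Named list of named weight vectors.
#' @export
default_summary_weights <- function() {
  list(
    authentic = c(i = 1),
    tone = c(posemo = 1, negemo = -1)
  )
}

#' The bundled synthetic lexicon
#'
#' A small stem lexicon shipped with the package covering the personal
#' concern, negative emotion, social and summary-support dimensions used in
#' the default semantic features: `work`, `money`, `death`, `anxiety`,
#' `sadness`, `friends`, `posemo`, `negemo`, `i`. It is synthetic: hand-picked
#' common stems, not any proprietary dictionary.
#'
#' @return A [lexicon()].
#' @export
phenoshift_lexicon <- function() {
  read_lexicon(system.file("extdata", "synthetic_lexicon.dic", package = "phenoshift"))
}
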