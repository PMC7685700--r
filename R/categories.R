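#' Rule-based category annotator
#'
#' Labels events with content categories (at minimum `adult` and `news`)
#' using keyword patterns applied to the event text and a domain list applied
#' to the URL host. An event may match several categories (counts are
#' per-category volumes, not a partition). This is a transparent, rule-based
#' stand-in for commercial content-classification services.
#'
#' @param rules Named list: category -> list with `keywords` (patterns as in
#'   [lexicon()], literal or `stem*`) and `domains` (bare hostnames; a host
#'   matches if equal or a subdomain).
#' @return An object of class `category_rules`.
#' @examples
#' r <- category_rules(list(
#'   news = list(keywords = c("news", "election*"), domains = "cnn.com")
#' ))
#' @export
category_rules <- function(rules) {
  if (!is.list(rules) || is.null(names(rules))) abort("`rules` must be a named list")
  rules <- lapply(rules, function(r) {
    list(
      keywords = tolower(as.character(r$keywords %||% character())),
      domains = tolower(as.character(r$domains %||% character()))
    )
  })
  empty <- vapply(rules, function(r) length(r$keywords) + length(r$domains) == 0, logical(1))
  if (any(empty)) abort("every category needs at least one keyword or domain")
  structure(rules, class = "category_rules")
}

#' @rdname category_rules
#' @param path YAML file mapping categories to `keywords`/`domains` lists.
#' @export
read_category_rules <- function(path) {
  category_rules(yaml::read_yaml(path))
}

#' Built-in demonstration category rules
#'
#' Small keyword/domain lists for the `adult` and `news` categories, matched
#' to the token pools of the synthetic cohort generator. Real deployments
#' should supply their own rule file via [read_category_rules()].
#'
#' @return A [category_rules()] object.
#' @export
default_category_rules <- function() {
  read_category_rules(system.file("extdata", "categories.yml", package = "phenoshift"))
}

url_host <- function(url) {
  h <- sub("^[a-z][a-z0-9+.-]*://", "", tolower(url))
  h <- sub("^www\\.", "", h)
  sub("[/:?#].*$", "", h)
}

host_matches <- function(hosts, domains) {
  hit <- rep(FALSE, length(hosts))
  for (d in domains) {
    hit <- hit | hosts == d | endsWith(hosts, paste0(".", d))
  }
  hit
}

# logical matrix: events x categories
category_hits <- function(events, rules) {
  stopifnot(inherits(rules, "category_rules"))
  if (nrow(events) == 0) {
    return(matrix(logical(0), nrow = 0, ncol = length(rules),
                  dimnames = list(NULL, names(rules))))
  }
  tokens <- tokenize(events$text)
  hosts <- url_host(events$url)
  sapply(names(rules), function(cat) {
    kw <- rules[[cat]]$keywords
    by_text <- vapply(tokens, function(tk) length(tk) > 0 && any(match_tokens(tk, kw)),
                      logical(1))
    by_url <- host_matches(hosts, rules[[cat]]$domains)
    by_text | by_url
  }, simplify = TRUE)
}

#' Count events per category
#'
#' @param events Event tibble (one window).
#' @param rules A [category_rules()] object.
#' @return A tibble with `category` and `count`.
#' @export
categorize_events <- function(events, rules) {
  hits <- category_hits(events, rules)
  counts <- if (nrow(events) == 0) {
    setNames(rep(0L, length(rules)), names(rules))
  } else {
    colSums(matrix(hits, nrow = nrow(events), dimnames = list(NULL, names(rules))))
  }
  tibble(category = names(rules), count = as.integer(counts))
}

#' Per-category relative change in event volume
#'
#' @param before_events,after_events Event tibbles for the two windows.
#' @param rules A [category_rules()] object.
#' @inheritParams relative_change
#' @return A tibble with `category`, `before`, `after`, `change_percent`.
#' @export
category_relative_change <- function(before_events, after_events, rules,
                                     zero_policy = c("strict", "pseudo")) {
  zero_policy <- match.arg(zero_policy)
  b <- categorize_events(before_events, rules)
  a <- categorize_events(after_events, rules)
  tibble(
    category = b$category,
    before = b$count,
    after = a$count,
    change_percent = relative_change(b$count, a$count, zero_policy)
  )
}
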