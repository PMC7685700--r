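test_that("tokenization lowercases, splits on non-alphanumerics, drops empties", {
  expect_equal(tokenize("What not to do?")[[1]], c("what", "not", "to", "do"))
  expect_equal(tokenize("")[[1]], character(0))
  expect_equal(tokenize("a-b_c 42!")[[1]], c("a", "b", "c", "42"))
  expect_equal(tokenize(NA_character_)[[1]], character(0))
})

test_that("lexicon counting matches stems and literals, multi-dimension allowed", {
  lx <- lexicon(list(neg = "sad*", pron = c("i", "me")))
  out <- lexicon_counts("sad sad happy", lx)
  expect_equal(out$count[out$dimension == "neg"], 2)
  expect_equal(out$percent[out$dimension == "neg"], 200 / 3, tolerance = 1e-9)

  empty <- lexicon_counts(character(0), lx)
  expect_equal(empty$count, c(0L, 0L))
  expect_true(all(is.na(empty$percent)))

  # one token counting toward two dimensions
  lx2 <- lexicon(list(a = "cry*", b = "crying"))
  both <- lexicon_counts("crying", lx2)
  expect_equal(both$count, c(1L, 1L))
})

test_that("lexicon constructor and .dic reader enforce the format", {
  expect_error(lexicon(list(bad = character(0))), "empty dimension")
  expect_error(lexicon(list(bad = "Upper")), "lowercase")
  lx <- phenoshift_lexicon()
  expect_setequal(
    names(lx$dimensions),
    c("work", "money", "death", "anxiety", "sadness", "friends",
      "posemo", "negemo", "i")
  )
  # the shared stem 'sad*' feeds both sadness and negemo
  sad <- lexicon_counts("sad", lx)
  expect_equal(sad$count[sad$dimension %in% c("sadness", "negemo")], c(1L, 1L))
})

test_that("lexicon counts match a regex-based oracle on random corpora", {
  lx <- phenoshift_lexicon()
  pools <- unlist(phenoshift:::TOKEN_POOLS, use.names = FALSE)
  for (seed in 1:20) {
    withr::with_seed(seed, {
      texts <- vapply(1:40, function(i) {
        paste(sample(pools, sample(1:5, 1), replace = TRUE), collapse = " ")
      }, character(1))
    })
    got <- lexicon_counts(texts, lx)
    want <- oracle_lexicon(texts, lx)
    expect_equal(setNames(as.numeric(got$count), got$dimension), want)
  }
})

test_that("counting is additive over text partitions", {
  lx <- phenoshift_lexicon()
  withr::with_seed(8, {
    a <- c("sad homework deadline", "money rent happy")
    b <- c("friend party", "death grief worry")
  })
  ca <- lexicon_counts(a, lx)$count
  cb <- lexicon_counts(b, lx)$count
  cab <- lexicon_counts(c(a, b), lx)$count
  expect_equal(cab, ca + cb)
})

test_that("lexicon relative change applies the shared rule per dimension", {
  lx <- lexicon(list(neg = "sad*", fin = "money"))
  out <- lexicon_relative_change(
    before_texts = c(rep("sad", 10)), after_texts = c(rep("sad", 15)),
    lx, zero_policy = "strict"
  )
  expect_equal(out$change_percent[out$dimension == "neg"], 50)
  expect_true(is.na(out$change_percent[out$dimension == "fin"]))
  out2 <- lexicon_relative_change(rep("sad", 10), rep("sad", 15), lx, "pseudo")
  expect_equal(out2$change_percent[out2$dimension == "fin"], 0)
})

test_that("summary-score hook is a weighted sum of dimension percents", {
  lx <- phenoshift_lexicon()
  s <- lexicon_summary_score("i love my homework", lx, c(posemo = 1, negemo = -1))
  # 4 tokens: love->posemo (25%), none negemo
  expect_equal(s, 25)
  expect_error(lexicon_summary_score("x", lx, c(nope = 1)), "unknown dimensions")
  expect_true(is.na(lexicon_summary_score(character(0), lx, c(posemo = 1))))
})

test_that("category annotation matches keywords or URL hosts, multi-label", {
  rules <- default_category_rules()
  ev <- make_events(
    rep("2020-01-05 10:00:00", 3),
    action = c("url_visit", "search_query", "search_query"),
    text = c("", "porn news", "calculus"),
    url = c("https://www.pornhub.com/video/1", "", "")
  )
  out <- categorize_events(ev, rules)
  expect_equal(out$count[out$category == "adult"], 2L)  # URL hit + keyword hit
  expect_equal(out$count[out$category == "news"], 1L)   # same event multi-labels
  # subdomains match, lookalike hosts do not
  ev2 <- make_events(rep("2020-01-05 10:00:00", 2), action = "url_visit",
                     url = c("https://en.cnn.com/x", "https://notcnn.com.evil.io/x"))
  out2 <- categorize_events(ev2, rules)
  expect_equal(out2$count[out2$category == "news"], 1L)
})

test_that("category counts match brute-force rule application", {
  rules <- default_category_rules()
  pools <- phenoshift:::TOKEN_POOLS
  domains <- unlist(phenoshift:::CATEGORY_DOMAINS, use.names = FALSE)
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- 100
      ev <- make_events(
        as.POSIXct("2020-01-05 10:00:00", tz = "UTC") + seq_len(n) * 60,
        text = replicate(n, paste(sample(unlist(pools), 2), collapse = " ")),
        url = ifelse(runif(n) < 0.3,
                     paste0("https://", sample(domains, n, TRUE), "/p"), "")
      )
    })
    got <- categorize_events(ev, rules)
    # brute force: loop every event against every rule
    for (cat in names(rules)) {
      manual <- 0L
      for (i in seq_len(nrow(ev))) {
        tks <- tokenize(ev$text[i])[[1]]
        kw_hit <- any(vapply(rules[[cat]]$keywords, function(p) {
          if (endsWith(p, "*")) any(startsWith(tks, sub("\\*$", "", p)))
          else any(tks == p)
        }, logical(1)))
        host <- sub("[/:?#].*$", "", sub("^https?://(www\\.)?", "", tolower(ev$url[i])))
        dom_hit <- any(vapply(rules[[cat]]$domains, function(d) {
          host == d || endsWith(host, paste0(".", d))
        }, logical(1)))
        if (kw_hit || dom_hit) manual <- manual + 1L
      }
      expect_equal(got$count[got$category == cat], manual)
    }
  }
})

test_that("category relative change mirrors the shared rule", {
  rules <- category_rules(list(news = list(keywords = "news")))
  mk <- function(n) make_events(
    as.POSIXct("2020-01-05 10:00:00", tz = "UTC") + seq_len(n), text = "news"
  )
  out <- category_relative_change(mk(10), mk(15), rules)
  expect_equal(out$change_percent, 50)
  zero <- category_relative_change(mk(0), mk(7), rules, "pseudo")
  expect_equal(zero$change_percent, 700)
})
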