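test_that("default rubric computes s_max = 46 from its option scores", {
  r <- default_rubric()
  expect_s3_class(r, "rubric")
  expect_identical(r$s_max, 46L)
  # s_max must be derived: per-item maxima plus the derived-bin maximum
  expect_equal(r$s_max,
               sum(vapply(r$option_scores, max, numeric(1))) +
                 max(r$incorrect_bins$score))
  expect_identical(nrow(r$item_table), 12L)
})

test_that("single-group and reduced-action rubrics compute their own s_max", {
  p5_only <- load_rubric(list(groups = list(
    P5 = list(items = list("trust"),
              options = list(`0%` = 0, `25%` = 1, `50%` = 2, `75%` = 3,
                             `100%` = 4))
  )))
  expect_identical(p5_only$s_max, 4L)
  four <- load_rubric(misinfok_file("rubric_four_actions.yaml"))
  expect_identical(four$s_max, 43L)
})

test_that("rubric validation names the offending group", {
  cfg <- tiny_rubric_config()
  cfg$groups$B$options <- NULL
  expect_error(load_rubric(cfg), "B.*missing 'options'")
  cfg <- tiny_rubric_config()
  names(cfg$groups$A$options)[2] <- "low"
  expect_error(load_rubric(cfg), "A.*duplicate option label")
  cfg <- tiny_rubric_config()
  cfg$groups$C$options$x <- -1
  expect_error(load_rubric(cfg), "C.*non-negative")
  cfg <- tiny_rubric_config()
  cfg$groups$A$items <- NULL
  expect_error(load_rubric(cfg), "A.*missing 'items'")
})

test_that("incorrect-judgment counting follows the polarity rule", {
  bank <- default_message_bank()
  expect_identical(count_incorrect(judgments_for(bank, correct = TRUE), bank), 0L)
  expect_identical(count_incorrect(judgments_for(bank, correct = FALSE), bank), 10L)
  # exhaustive: every rating x truth-label combination
  one_msg <- load_message_bank(list(messages = list(
    list(message_id = "m", truth_label = "false", evidence_flag = "none"))))
  for (rating in rating_levels()) {
    for (truth in c("true", "false")) {
      one_msg$truth_label <- truth
      marked_true <- rating %in% c("definitely_true", "maybe_true")
      expected <- as.integer(marked_true != (truth == "true"))
      expect_identical(count_incorrect(c(m = rating), one_msg), expected,
                       label = paste(rating, "vs", truth))
    }
  }
})

test_that("judgment validation identifies the offending message", {
  bank <- default_message_bank()
  j <- judgments_for(bank)
  expect_error(count_incorrect(j[-3], bank), "missing rating.*m03")
  names(j)[1] <- "zz"
  expect_error(count_incorrect(j, bank), "unknown message_id: zz")
})

test_that("hand-summed scoring profiles reproduce the expected s_cal and K", {
  r <- default_rubric()
  bank <- default_message_bank()
  lo <- score_respondent(make_record(bank), r, bank)
  expect_identical(lo$s_cal, 6L)
  expect_equal(lo$k, 6 / 46)
  expect_identical(lo$incorrect_count, 0L)

  hi <- score_respondent(
    make_record(bank, maximal_answers(), judgments_for(bank, correct = FALSE)),
    r, bank)
  expect_identical(hi$s_cal, 46L)
  expect_equal(hi$k, 1)

  mid_answers <- minimal_answers()
  mid_answers[c("covid_source", "trust", "fact_check")] <-
    c("WhatsApp", "50%", "Never")
  mid <- score_respondent(make_record(bank, mid_answers), r, bank)
  expect_identical(mid$s_cal, 16L)
})

test_that("scoring errors name the respondent and item", {
  r <- default_rubric()
  bank <- default_message_bank()
  a <- minimal_answers()
  a["trust"] <- NA
  expect_error(score_respondent(make_record(bank, a, id = "r9"), r, bank),
               "r9.*unanswered scored item 'trust'")
  a["trust"] <- "55%"
  expect_error(score_respondent(make_record(bank, a, id = "r9"), r, bank),
               "r9.*option '55%' for item 'trust'")
})

test_that("incorrect-count binning matches the rubric bins", {
  r <- default_rubric()
  expect_identical(bin_incorrect(c(0, 2, 3, 5, 6, 8, 9, 10), r),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(bin_incorrect(-1, r), "negative")
})

test_that("K is bounded, maximal only at the top profile, and separable", {
  r <- default_rubric()
  bank <- default_message_bank()
  set.seed(11)
  for (i in 1:25) {
    a <- vapply(r$item_table$item_id, function(it)
      sample(names(r$option_scores[[it]]), 1), character(1))
    j <- stats::setNames(sample(rating_levels(), nrow(bank), replace = TRUE),
                         bank$message_id)
    s <- score_respondent(make_record(bank, a, j), r, bank)
    expect_gte(s$k, 6 / 46)
    expect_lte(s$k, 1)
    # separability: total equals the sum of its per-item scores
    expect_identical(s$s_cal, as.integer(sum(s$item_scores)))
    if (s$k == 1) {
      expect_true(all(vapply(r$item_table$item_id, function(it)
        s$item_scores[[it]] == max(r$option_scores[[it]]), logical(1))))
    }
  }
})

test_that("upgrading any single item never decreases K", {
  r <- default_rubric()
  bank <- default_message_bank()
  set.seed(12)
  for (i in 1:10) {
    a <- vapply(r$item_table$item_id, function(it)
      sample(names(r$option_scores[[it]]), 1), character(1))
    base <- score_respondent(make_record(bank, a), r, bank)
    for (it in r$item_table$item_id) {
      tab <- r$option_scores[[it]]
      higher <- names(tab)[tab > tab[[a[[it]]]]]
      for (opt in higher) {
        a2 <- a
        a2[it] <- opt
        upgraded <- score_respondent(make_record(bank, a2), r, bank)
        expect_gt(upgraded$k, base$k)  # strict: scores differ by >= 1
      }
    }
  }
})

test_that("scoring matches exhaustive enumeration on a reduced rubric", {
  r <- load_rubric(tiny_rubric_config())
  expect_identical(r$s_max, 10L)
  combos <- expand.grid(a1 = c("low", "mid", "high"), b1 = c("no", "yes"),
                        b2 = c("no", "yes"), c1 = c("x", "y"),
                        stringsAsFactors = FALSE)
  # independent oracle: plain table lookup, summed
  lookup <- list(a1 = c(low = 0, mid = 1, high = 2),
                 b1 = c(no = 0, yes = 3), b2 = c(no = 0, yes = 3),
                 c1 = c(x = 1, y = 2))
  for (i in seq_len(nrow(combos))) {
    a <- unlist(combos[i, ])
    expected <- sum(vapply(names(a), function(it) lookup[[it]][[a[[it]]]],
                           numeric(1)))
    s <- score_respondent(list(respondent_id = i, answers = a,
                               judgments = NULL), r)
    expect_identical(s$s_cal, as.integer(expected))
    expect_equal(s$k, expected / 10)
  }
})

test_that("vectorized survey scoring agrees with per-respondent scoring", {
  r <- default_rubric()
  bank <- default_message_bank()
  set.seed(13)
  rows <- lapply(1:8, function(i) {
    a <- vapply(r$item_table$item_id, function(it)
      sample(names(r$option_scores[[it]]), 1), character(1))
    j <- stats::setNames(sample(rating_levels(), nrow(bank), replace = TRUE),
                         bank$message_id)
    make_survey_df(bank, n = 1, answers = a, judgments = j, age_years = 20 + i)
  })
  df <- do.call(rbind, rows)
  df$respondent_id <- sprintf("r%03d", 1:8)
  scored <- score_survey(df, r, bank)
  for (i in 1:8) {
    single <- score_respondent(df[i, ], r, bank)
    expect_identical(scored$s_cal[i], single$s_cal)
    expect_identical(scored$incorrect_count[i], single$incorrect_count)
    expect_equal(scored$k[i], single$k)
  }
})

test_that("message bank validation enforces labels and flags", {
  expect_error(load_message_bank(list(messages = list(
    list(message_id = "a", truth_label = "bogus", evidence_flag = "none")))),
    "truth_label")
  expect_error(load_message_bank(list(messages = list(
    list(message_id = "a", truth_label = "false", evidence_flag = "url")))),
    "evidence_flag")
  bank <- default_message_bank()
  expect_identical(nrow(bank), 10L)
  expect_identical(sum(bank$truth_label == "false"), 8L)
})
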