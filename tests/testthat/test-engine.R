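bank <- default_item_bank()

test_that("classification follows the CAM rule and is monotone", {
  expect_true(classify_outcome(c(TRUE, TRUE, FALSE, TRUE))$delirium)
  expect_false(classify_outcome(c(FALSE, TRUE, TRUE, TRUE))$delirium)
  expect_false(classify_outcome(rep(FALSE, 4))$delirium)
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  for (i in seq_len(nrow(combos))) {
    expect_identical(cam_rule(combos[i, ]), oracle_delirium(combos[i, ]))
    # monotonicity: adding features never removes the diagnosis
    for (j in seq_len(nrow(combos))) {
      if (all(combos[i, ] <= combos[j, ]) && cam_rule(combos[i, ]))
        expect_true(cam_rule(combos[j, ]))
    }
  }
})

test_that("enumerate_outcomes yields 16 categories, 3 positive, 13 negative", {
  out <- enumerate_outcomes()
  expect_identical(nrow(out), 16L)
  expect_identical(sum(out$delirium), 3L)
  expect_identical(sum(!out$delirium), 13L)
  expect_false(anyDuplicated(out$label) > 0)
})

test_that("within-feature jumps: items of a present feature are never asked", {
  # positive on item 4 makes F2 present; 5, 6, 7, 18-20 must be skipped
  s <- start_session(bank, "P", "N", mode = "full")
  s <- submit_response(s, 1, "normal")
  s <- submit_response(s, 2, "normal")
  s <- submit_response(s, 3, "normal")
  s <- submit_response(s, 4, "positive")
  expect_identical(feature_states(s)[["F2"]], "present")
  expect_identical(next_item(s), 8L)   # jumps over 5, 6, 7
  s <- run_session(s, rep(FALSE, 21))
  tr <- session_trace(s)
  expect_setequal(tr$item_id[tr$source == "skipped"], c(5, 6, 7, 18, 19, 20))
  expect_false(any(c(5, 6, 7, 18, 19, 20) %in%
                     tr$item_id[tr$source == "entered"]))
})

test_that("fast mode stops as soon as the outcome is decidable", {
  # F4 present early, then everything normal: once the F2 items are
  # exhausted (after item 20) delirium is impossible; item 21 never asked
  ans <- rep(FALSE, 21); ans[11] <- TRUE
  s <- run_session(start_session(bank, "P", "N", mode = "fast"), ans)
  tr <- session_trace(s)
  expect_false(21 %in% tr$item_id[tr$source == "entered"])
  expect_false(s$outcome$delirium)
  # full mode with the same responses continues through the later pages
  sf <- run_session(start_session(bank, "P", "N", mode = "full"), ans)
  trf <- session_trace(sf)
  expect_true(21 %in% trf$item_id[trf$source == "entered"])
  expect_identical(sf$outcome$delirium, s$outcome$delirium)
})

test_that("submission order is enforced", {
  s <- start_session(bank, "P", "N", mode = "full")
  expect_error(submit_response(s, 2, "normal"), "out-of-order")
  s <- submit_response(s, 1, "normal")
  expect_error(submit_response(s, 1, "normal"), "duplicate")
  expect_error(submit_response(s, 99, "normal"), "duplicate|unknown")
  expect_error(submit_response(s, 2, "maybe"), "normal")
  s <- run_session(s, rep(FALSE, 21))
  expect_error(next_item(s), "terminal")
  expect_error(submit_response(s, 21, "normal"), "terminal")
})

test_that("hand-derived outcomes from partial positives", {
  # positives on items 8 (F1), 4 (F2), 1 (F3) only -> delirium positive
  ans <- rep(FALSE, 21); ans[c(8, 4, 1)] <- TRUE
  s <- run_session(start_session(bank, "P", "N", mode = "fast"), ans)
  expect_true(s$outcome$delirium)
  expect_identical(unname(s$outcome$combo),
                   c(TRUE, TRUE, TRUE, FALSE))
  # all normal everywhere -> all-absent category
  s0 <- run_session(start_session(bank, "P", "N", mode = "full"),
                    rep(FALSE, 21))
  expect_false(s0$outcome$delirium)
  expect_identical(unname(s0$outcome$combo), rep(FALSE, 4))
  m <- session_metrics(s0)
  expect_identical(m$items_administered, 21L)
  expect_identical(m$items_skipped, 0L)
})

test_that("metrics conservation and skip soundness over random sessions", {
  set.seed(42)
  for (i in 1:400) {
    ans <- runif(21) < runif(1, 0.05, 0.6)
    mode <- if (i %% 2) "fast" else "full"
    s <- run_session(start_session(bank, "P", "N", mode = mode), ans)
    m <- session_metrics(s)
    expect_identical(m$items_administered + m$items_skipped + m$items_auto,
                     22L)
    expect_true(skip_sound(s))
  }
})

test_that("fast and full mode agree (exhaustive feature classes + sampled)", {
  # one representative latent vector per feature-combination class
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 4)))
  for (i in seq_len(nrow(combos))) {
    ans <- vector_for_combo(bank, combos[i, ])
    r <- run_both_modes(bank, ans)
    expect_identical(r$fast$outcome$delirium, r$full$outcome$delirium)
    det <- r$fast$features != "undetermined"
    expect_identical(r$fast$features[det], r$full$features[det])
  }
  set.seed(7)
  for (i in 1:500) {
    ans <- runif(21) < runif(1, 0.05, 0.7)
    r <- run_both_modes(bank, ans)
    expect_identical(r$fast$outcome$delirium, r$full$outcome$delirium)
    m <- session_metrics(r$fast)
    expect_lte(m$items_administered,
               session_metrics(r$full)$items_administered)
  }
})

test_that("item 22 derives from the baseline record as a new-deficit flag", {
  # no prior session -> normal, flagged no-baseline
  s <- start_session(bank, "P1", "N", mode = "full")
  expect_true(s$no_baseline)
  expect_identical(s$value[22], "normal")

  t0 <- as.POSIXct("2026-01-01 08:00:00", tz = "UTC")
  t1 <- t0 + 86400

  # delirium-negative all-normal baseline; current fails item 5
  store <- store_with_session(bank, "P1", rep(FALSE, 21), time = t0)
  s <- start_session(bank, "P1", "N", mode = "full", history = store,
                     time = t1)
  expect_false(s$no_baseline)
  expect_identical(next_item(s), 1L)       # first item of page 1
  expect_identical(s$value[22], "normal")  # nothing new yet
  for (id in 1:4) s <- submit_response(s, id, "normal")
  s <- submit_response(s, 5, "positive")
  expect_identical(s$value[22], "positive")  # new cognitive deficit
  expect_identical(feature_states(s)[["F1"]], "present")

  # baseline already failing item 5; the same deficit now is not NEW
  ans5 <- rep(FALSE, 21); ans5[5] <- TRUE
  store2 <- store_with_session(bank, "P2", ans5, time = t0)
  s2 <- start_session(bank, "P2", "N", mode = "full", history = store2,
                      time = t1)
  for (id in 1:4) s2 <- submit_response(s2, id, "normal")
  s2 <- submit_response(s2, 5, "positive")
  expect_identical(s2$value[22], "normal")
  # but a feature absent at baseline that now has evidence is new
  s2 <- run_session(s2, ans5)   # remaining items normal ... none positive
  expect_identical(s2$value[22], "normal")

  # mode affects stepping only: identical initial state fast vs full
  sa <- start_session(bank, "P1", "N", mode = "fast", history = store,
                      time = t1)
  sb <- start_session(bank, "P1", "N", mode = "full", history = store,
                      time = t1)
  expect_identical(sa$value, sb$value)
  expect_identical(sa$status, sb$status)
})

test_that("a new feature relative to baseline also trips item 22", {
  t0 <- as.POSIXct("2026-01-01 08:00:00", tz = "UTC")
  store <- store_with_session(bank, "P3", rep(FALSE, 21), time = t0)
  s <- start_session(bank, "P3", "N", mode = "full", history = store,
                     time = t0 + 3600)
  ans <- rep(FALSE, 21); ans[11] <- TRUE   # F4 sign, not a cognitive item
  s <- run_session(s, ans)
  expect_identical(s$value[22], "positive")
  expect_identical(unname(s$outcome$combo[c("F1", "F4")]), c(TRUE, TRUE))
})
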