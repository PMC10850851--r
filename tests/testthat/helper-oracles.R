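# Independent oracles and fixture builders. Everything here is deliberately
# naive (enumeration / direct formulas), never sharing code with R/.

# CAM rule restated as a truth-table lookup over the 16 combinations,
# built from the clinical definition rather than the boolean expression.
oracle_delirium <- local({
  positive <- c("TTTF", "TTFT", "TTTT")   # the three diagnostic patterns
  function(combo) {
    key <- paste(ifelse(combo, "T", "F"), collapse = "")
    key %in% positive
  }
})

# Two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, with point probabilities from lchoose (not dhyper).
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(c1, r1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[support == tab[1, 1]]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Two-sided sign-flip permutation p for the signed-rank statistic, by brute
# force over the full 2^n sign matrix (expand.grid), n small.
oracle_wilcoxon_perm_p <- function(a, b) {
  d <- (a - b)[a != b]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Run one latent response vector through both engine modes.
run_both_modes <- function(bank, answers, history = NULL) {
  list(
    fast = run_session(start_session(bank, "P", "N", mode = "fast",
                                     history = history), answers),
    full = run_session(start_session(bank, "P", "N", mode = "full",
                                     history = history), answers))
}

# A response vector whose noiseless feature pattern equals `combo`
# (one positive item per present feature, chosen deterministically).
vector_for_combo <- function(bank, combo) {
  ans <- rep(FALSE, 21)
  for (f in FEATURES_T[combo]) {
    ids <- bank$items$id[bank$items$feature == f & !bank$items$auto_derived]
    ans[ids[1]] <- TRUE
  }
  ans
}
FEATURES_T <- c("F1", "F2", "F3", "F4")

# Replay a session trace and check that no entered item belonged to a
# feature already evidenced positive at the time it was administered.
skip_sound <- function(session) {
  tr <- session_trace(session)
  feat_of <- session$bank$items$feature[order(session$bank$items$id)]
  seen_pos <- character(0)
  for (i in seq_len(nrow(tr))) {
    if (tr$source[i] == "entered" && feat_of[tr$item_id[i]] %in% seen_pos)
      return(FALSE)
    if (!is.na(tr$value[i]) && tr$value[i] == "positive")
      seen_pos <- union(seen_pos, feat_of[tr$item_id[i]])
  }
  TRUE
}

# Build a terminal session for a patient from a latent vector, and a store
# containing it, for baseline-comparison tests.
store_with_session <- function(bank, patient_id, answers,
                               time = as.POSIXct("2026-01-01 08:00:00",
                                                 tz = "UTC")) {
  s <- start_session(bank, patient_id, "N0", mode = "full", time = time)
  s <- run_session(s, answers)
  append_session(record_store(), s)
}

# Cheap hand-built summary (no engine run) for store-level property tests.
make_fake_summary <- function(pid, ts, combo = rep(FALSE, 4)) {
  structure(list(
    patient_id = pid, nurse_id = "N", timestamp = as.numeric(ts),
    combo = stats::setNames(combo, FEATURES_T),
    delirium = FALSE, label = "synthetic",
    item_values = stats::setNames(rep("normal", 7), as.character(1:7))
  ), class = "ddst_session_summary")
}
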