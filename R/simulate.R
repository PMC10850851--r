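# Synthetic randomized-crossover usability trial: latent patient states,
# nurse recording behaviour per modality, completion success, timing, and
# Likert usability questionnaires. Defaults are fitted to the published
# summary statistics of the field study the design emulates (prevalence
# 26%, success 203/216 vs 212/216, time medians 4.4 vs 2.3 min, usability
# means 3.40 vs 4.35), since generative parameters are never printed.

LIKERT_DOMAINS <- c("usefulness", "ease_of_use", "learnability",
                    "trustworthiness", "intention_to_use", "satisfaction")

# E[discretized item] for a latent N(mu, sd) cut at 1.5, 2.5, 3.5, 4.5 into
# categories 1..5: E = 1 + sum_t P(latent > t).
likert_expected_mean <- function(mu, sd) {
  1 + sum(1 - stats::pnorm(c(1.5, 2.5, 3.5, 4.5), mean = mu, sd = sd))
}

default_likert_model <- function() {
  m <- list(
    domains = LIKERT_DOMAINS,
    # items per domain; totals 26 (paper) and 43 (dst) as in the source
    # questionnaire. The per-domain split is not published; see vignette.
    items = list(paper = c(5L, 5L, 4L, 4L, 4L, 4L),
                 dst = c(8L, 8L, 7L, 7L, 7L, 6L)),
    # latent domain means start at the published per-domain medians ...
    mean = list(paper = c(3.86, 2.83, 3.33, 3.33, 3.67, 3.60),
                dst = c(4.57, 4.33, 4.33, 4.33, 4.40, 4.33)),
    nurse_sd = c(paper = 0.40, dst = 0.28),
    item_sd = c(paper = 0.60, dst = 0.60),
    # ... and are shifted by a single per-modality constant so the expected
    # questionnaire total mean equals the published value exactly.
    target_total = c(paper = 3.40, dst = 4.35),
    shift = c(paper = 0, dst = 0)
  )
  for (mod in c("paper", "dst")) {
    sd_tot <- sqrt(m$nurse_sd[[mod]]^2 + m$item_sd[[mod]]^2)
    w <- m$items[[mod]] / sum(m$items[[mod]])
    f <- function(d) {
      sum(w * vapply(m$mean[[mod]] + d, likert_expected_mean, numeric(1),
                     sd = sd_tot)) - m$target_total[[mod]]
    }
    m$shift[[mod]] <- stats::uniroot(f, c(-2, 2), tol = 1e-10)$root
  }
  m
}

# lognormal dispersion matched to a printed IQR: q75/q25 = exp(2 z_.75 sdlog)
iqr_sdlog <- function(q25, q75) log(q75 / q25) / (2 * stats::qnorm(0.75))

#' Simulation configuration
#'
#' All default rates and distributions are fitted to the published trial
#' summaries: delirium prevalence 0.26; per-item mis-recording rates chosen
#' so the expected total human-error counts match the printed 15 (paper)
#' and 5 (app) over 216 assessments of 21 displayed items each; completion
#' failure 13/216 and 4/216; completion-time lognormals with medians 4.4
#' and 2.3 minutes and dispersions matched to the printed IQRs (2.5-5.4 and
#' 1.25-3.55); and a latent-normal Likert model calibrated so the expected
#' questionnaire total means equal 3.40 and 4.35.
#'
#' @param prevalence Probability a sampled patient is delirium-positive.
#' @param p_feature_given_nondelirium Per-feature probabilities (`F1..F4`)
#'   used, conditioned on not satisfying the diagnostic rule, for
#'   non-delirious patients.
#' @param p_item_positive Probability each evidence item of a present
#'   feature is latently positive (at least one is always forced positive).
#' @param nurse_error_rate Per-modality per-item probability of recording
#'   the opposite of the latent value.
#' @param completion_failure_rate Per-modality probability an assessment is
#'   not completed successfully.
#' @param time_model Per-modality `c(median, sdlog)` of the lognormal
#'   completion-time distribution, minutes.
#' @param likert_model Latent-normal usability model; see
#'   `default_likert_model` in the package source.
#' @return A list of class `ddst_sim_config`.
#' @export
sim_config <- function(prevalence = 0.26,
                       p_feature_given_nondelirium =
                         c(F1 = 0.12, F2 = 0.08, F3 = 0.10, F4 = 0.06),
                       p_item_positive = 0.6,
                       nurse_error_rate = c(paper = 15 / (216 * 21),
                                            dst = 5 / (216 * 21)),
                       completion_failure_rate = c(paper = 13 / 216,
                                                   dst = 4 / 216),
                       time_model = list(
                         paper = c(median = 4.4, sdlog = iqr_sdlog(2.5, 5.4)),
                         dst = c(median = 2.3, sdlog = iqr_sdlog(1.25, 3.55))),
                       likert_model = default_likert_model()) {
  stopifnot(prevalence >= 0, prevalence <= 1,
            all(p_feature_given_nondelirium >= 0),
            all(p_feature_given_nondelirium <= 1),
            all(nurse_error_rate >= 0), all(nurse_error_rate <= 1),
            all(completion_failure_rate >= 0),
            all(completion_failure_rate <= 1),
            time_model$paper[["median"]] > 0, time_model$dst[["median"]] > 0)
  structure(list(prevalence = prevalence,
                 p_feature_given_nondelirium = p_feature_given_nondelirium,
                 p_item_positive = p_item_positive,
                 nurse_error_rate = nurse_error_rate,
                 completion_failure_rate = completion_failure_rate,
                 time_model = time_model,
                 likert_model = likert_model),
            class = "ddst_sim_config")
}

#' Crossover trial design
#'
#' @param n_nurses Number of nurses, split equally into group A (paper
#'   instrument first) and group B (app first).
#' @param patients_per_nurse_per_modality Patients each nurse assesses with
#'   each modality.
#' @param n_patients Size of the patient pool the assessed patients are
#'   drawn from (with replacement; the published study reused 148 patients
#'   across 432 assessments without stating the reuse scheme).
#' @param washout_hours Washout between a nurse's two modality blocks.
#' @return A list of class `ddst_trial_design`.
#' @export
trial_design <- function(n_nurses = 72L, patients_per_nurse_per_modality = 3L,
                         n_patients = 148L, washout_hours = 24) {
  n_nurses <- as.integer(n_nurses)
  if (n_nurses < 2L || n_nurses %% 2L != 0L)
    stop("n_nurses must be even so the two groups balance", call. = FALSE)
  structure(list(n_nurses = n_nurses,
                 patients_per_nurse_per_modality =
                   as.integer(patients_per_nurse_per_modality),
                 n_patients = as.integer(n_patients),
                 washout_hours = washout_hours),
            class = "ddst_trial_design")
}

#' Sample a latent patient state
#'
#' Draws delirium status Bernoulli(prevalence). Delirious patients receive
#' one of the 3 feature combinations satisfying the diagnostic rule
#' (uniformly); non-delirious patients receive independent per-feature draws
#' conditioned on not satisfying it. Latent item values are then drawn
#' consistent with the features: every present feature gets at least one
#' positive evidence item, absent features get none.
#'
#' @param config A `ddst_sim_config`.
#' @param bank Item bank (default built-in).
#' @return List of class `ddst_patient` with `delirium`, `features` (named
#'   logical) and `item_truth` (logical, `TRUE` = positive, indexed by item
#'   id over the 21 displayed items; the auto item has no latent truth).
#' @export
sample_patient <- function(config, bank = default_item_bank()) {
  delirium <- stats::runif(1) < config$prevalence
  if (delirium) {
    # the 3 combos satisfying the diagnostic rule, uniformly
    pos <- rbind(c(TRUE, TRUE, TRUE, FALSE),
                 c(TRUE, TRUE, FALSE, TRUE),
                 c(TRUE, TRUE, TRUE, TRUE))
    combo <- stats::setNames(pos[sample.int(3L, 1L), ], FEATURES)
  } else {
    p <- config$p_feature_given_nondelirium[FEATURES]
    repeat {
      combo <- stats::runif(4) < p
      if (!cam_rule(combo)) break
    }
    names(combo) <- FEATURES
  }
  truth <- rep(FALSE, 22L)
  for (f in FEATURES[combo]) {
    ids <- setdiff(bank$index$feature_items[[f]], bank$index$auto_id)
    v <- stats::runif(length(ids)) < config$p_item_positive
    if (!any(v)) v[sample.int(length(v), 1L)] <- TRUE
    truth[ids] <- v
  }
  structure(list(delirium = delirium, features = combo,
                 item_truth = truth[1:21]),
            class = "ddst_patient")
}

#' Simulate one nurse assessment of a patient
#'
#' The nurse's recorded responses are the latent item values flipped
#' independently with the modality's per-item error rate; the engine is then
#' run on the recorded responses (`fast` mode for the app, `full` for
#' paper). Completion success and duration are drawn from the modality's
#' distributions; these processes are independent of the item-level errors,
#' as they are reported separately in the source study.
#'
#' @param patient A `ddst_patient`.
#' @param modality `"paper"` or `"dst"`.
#' @param config A `ddst_sim_config`.
#' @param bank Item bank.
#' @param nurse_id,patient_id Identifiers carried into the row.
#' @return One-row data.frame (an assessment record).
#' @export
simulate_assessment <- function(patient, modality, config,
                                bank = default_item_bank(),
                                nurse_id = "N01", patient_id = "P001") {
  stopifnot(inherits(patient, "ddst_patient"), modality %in% c("paper", "dst"))
  flip <- stats::runif(21) < config$nurse_error_rate[[modality]]
  recorded <- xor(patient$item_truth, flip)
  mode <- if (modality == "dst") "fast" else "full"
  s <- start_session(bank, patient_id, nurse_id, modality = modality,
                     mode = mode, history = NULL)
  s <- run_session(s, c(recorded, FALSE))
  success <- stats::runif(1) >= config$completion_failure_rate[[modality]]
  tm <- config$time_model[[modality]]
  duration <- stats::rlnorm(1, meanlog = log(tm[["median"]]),
                            sdlog = tm[["sdlog"]])
  m <- session_metrics(s)
  data.frame(nurse_id = nurse_id, patient_id = patient_id,
             modality = modality,
             truth_delirium = patient$delirium,
             outcome_delirium = s$outcome$delirium,
             outcome_label = s$outcome$label,
             success = success,
             human_errors = sum(flip),
             duration = duration,
             items_administered = m$items_administered,
             items_skipped = m$items_skipped,
             stringsAsFactors = FALSE)
}

#' Simulate one usability questionnaire
#'
#' Latent-normal model: each item response is a nurse effect plus item noise
#' around the domain's latent mean, discretized to the 1-5 Likert scale with
#' equal-width thresholds. Domain scores are item means; the total is the
#' mean over all items (26 paper / 43 app).
#'
#' @param nurse_id Identifier.
#' @param modality `"paper"` or `"dst"`.
#' @param config A `ddst_sim_config`.
#' @return List with `items` (integer responses in 1..5), `domain_scores`
#'   (named, length 6) and `total`.
#' @export
simulate_usability <- function(nurse_id, modality, config) {
  lm_ <- config$likert_model
  counts <- lm_$items[[modality]]
  mu <- lm_$mean[[modality]] + lm_$shift[[modality]]
  b <- stats::rnorm(1, 0, lm_$nurse_sd[[modality]])
  items <- integer(0)
  domain_scores <- numeric(length(counts))
  for (d in seq_along(counts)) {
    latent <- mu[d] + b + stats::rnorm(counts[d], 0, lm_$item_sd[[modality]])
    resp <- pmin(pmax(round(latent), 1L), 5L)
    items <- c(items, as.integer(resp))
    domain_scores[d] <- mean(resp)
  }
  names(domain_scores) <- lm_$domains
  list(nurse_id = nurse_id, modality = modality, items = items,
       domain_scores = domain_scores, total = mean(items))
}

#' Simulate the full randomized crossover usability trial
#'
#' Nurses are randomized 1:1 into group A (paper first) and group B (app
#' first); each nurse assesses `patients_per_nurse_per_modality` patients
#' per modality (drawn with replacement from a fixed pool of latent patient
#' states), with the two modality blocks separated by the washout. Each
#' nurse completes one usability questionnaire per modality. With the
#' default design this yields 432 assessment rows forming 216 nurse-paired
#' sets and a 36/36 group split.
#'
#' @param design A `ddst_trial_design`.
#' @param config A `ddst_sim_config`.
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @param bank Item bank.
#' @return A list of class `ddst_trial` with data.frames `assessments`,
#'   `usability` (nurse x modality domain scores), `usability_items`
#'   (item-level Likert responses) and `patients` (the latent pool).
#' @export
simulate_trial <- function(design = trial_design(), config = sim_config(),
                           seed = 1L, bank = default_item_bank()) {
  stopifnot(inherits(design, "ddst_trial_design"),
            inherits(config, "ddst_sim_config"))
  set.seed(as.integer(seed))
  n <- design$n_nurses
  k <- design$patients_per_nurse_per_modality
  nurse_ids <- sprintf("N%02d", seq_len(n))
  group <- rep("", n)
  group[sample.int(n, n / 2L)] <- "A"
  group[group == ""] <- "B"
  pool <- lapply(seq_len(design$n_patients), function(i)
    sample_patient(config, bank))
  pool_ids <- sprintf("P%03d", seq_len(design$n_patients))

  rows <- vector("list", n * 2L * k)
  usab <- vector("list", n * 2L)
  uitems <- vector("list", n * 2L)
  r <- 0L; u <- 0L
  for (i in seq_len(n)) {
    mods <- if (group[i] == "A") c("paper", "dst") else c("dst", "paper")
    for (ord in 1:2) {
      mod <- mods[ord]
      idx <- sample.int(design$n_patients, k, replace = TRUE)
      for (slot in seq_len(k)) {
        r <- r + 1L
        row <- simulate_assessment(pool[[idx[slot]]], mod, config, bank,
                                   nurse_id = nurse_ids[i],
                                   patient_id = pool_ids[idx[slot]])
        row$group <- group[i]
        row$order <- ord
        row$slot <- slot
        row$pair_id <- sprintf("%s-%d", nurse_ids[i], slot)
        rows[[r]] <- row
      }
      u <- u + 1L
      q <- simulate_usability(nurse_ids[i], mod, config)
      usab[[u]] <- data.frame(
        nurse_id = nurse_ids[i], group = group[i], modality = mod,
        order = ord, n_items = length(q$items),
        as.list(q$domain_scores), total = q$total,
        stringsAsFactors = FALSE)
      uitems[[u]] <- data.frame(
        nurse_id = nurse_ids[i], modality = mod,
        item = seq_along(q$items), response = q$items,
        stringsAsFactors = FALSE)
    }
  }
  assessments <- do.call(rbind, rows)
  truth <- data.frame(
    patient_id = pool_ids,
    delirium = vapply(pool, `[[`, logical(1), "delirium"),
    stringsAsFactors = FALSE)
  structure(list(design = design, config = config, seed = as.integer(seed),
                 assessments = assessments,
                 usability = do.call(rbind, usab),
                 usability_items = do.call(rbind, uitems),
                 patients = truth),
            class = "ddst_trial")
}

#' @export
print.ddst_trial <- function(x, ...) {
  a <- x$assessments
  cat("<ddst_trial>", nrow(a), "assessments,",
      length(unique(a$pair_id)), "pairs,",
      length(unique(a$nurse_id)), "nurses (",
      sum(x$usability$group == "A" & x$usability$order == 1), "A /",
      sum(x$usability$group == "B" & x$usability$order == 1), "B )\n")
  cat("  assessed patients:", length(unique(a$patient_id)),
      "of a pool of", nrow(x$patients), "\n")
  invisible(x)
}

#' Write a simulated trial to CSV files
#'
#' @param trial A `ddst_trial`.
#' @param assessments_path,usability_path Output CSVs.
#' @return Invisibly, the two paths.
#' @export
write_trial <- function(trial, assessments_path, usability_path) {
  utils::write.csv(trial$assessments, assessments_path, row.names = FALSE)
  utils::write.csv(trial$usability, usability_path, row.names = FALSE)
  invisible(c(assessments_path, usability_path))
}

#' Read a simulated trial back from CSV files
#'
#' @param assessments_path,usability_path CSVs written by [write_trial()].
#' @return A list of class `ddst_trial` (without the latent patient pool).
#' @export
read_trial <- function(assessments_path, usability_path = NULL) {
  for (p in c(assessments_path, usability_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  structure(list(
    assessments = utils::read.csv(assessments_path, stringsAsFactors = FALSE),
    usability = if (is.null(usability_path)) NULL else
      utils::read.csv(usability_path, stringsAsFactors = FALSE)),
    class = "ddst_trial")
}
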