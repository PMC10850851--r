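# Comparison battery for the crossover trial: completion-rate tests,
# paired nonparametric domain comparisons, order-effect ANOVA, descriptive
# report tables, and sample-size planning with attrition inflation.

new_comparison <- function(statistic, statistic_name, p_value, method) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic),
                 statistic_name = statistic_name,
                 p_value = unname(p_value), method = method),
            class = "ddst_comparison")
}

#' @export
print.ddst_comparison <- function(x, ...) {
  cat(sprintf("<ddst_comparison> %s: %s = %.4g, p = %.4g\n",
              x$method, x$statistic_name, x$statistic, x$p_value))
  invisible(x)
}

#' Compare completion rates between two modalities
#'
#' Two-sided test on a 2x2 table (rows = modality, columns =
#' success/failure). `"chi2_yates"` is the continuity-corrected chi-square;
#' `"fisher_exact"` sums hypergeometric point probabilities no larger than
#' that of the observed table (the standard two-sided exact test). The
#' default `"auto"` picks Fisher whenever any expected cell count is below
#' 10, and the corrected chi-square otherwise.
#'
#' @param table 2x2 integer matrix with non-negative entries and positive
#'   margins.
#' @param method `"auto"`, `"fisher_exact"` or `"chi2_yates"`.
#' @return A `ddst_comparison`.
#' @export
#' @examples
#' completion_rate_test(matrix(c(203, 13, 212, 4), 2, byrow = TRUE))
completion_rate_test <- function(table,
                                 method = c("auto", "fisher_exact",
                                            "chi2_yates")) {
  method <- match.arg(method)
  tab <- as.matrix(table)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0))
    stop("zero row margin in 2x2 table", call. = FALSE)
  # a zero column margin is degenerate, not an error: the conditional
  # distribution is a point mass, so the rows cannot differ (p = 1)
  if (any(colSums(tab) == 0))
    return(new_comparison(0, "X-squared", 1,
                          if (method == "chi2_yates") "chi2_yates"
                          else "fisher_exact"))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto")
    method <- if (any(expected < 10)) "fisher_exact" else "chi2_yates"
  if (method == "chi2_yates") {
    stat <- sum((pmax(abs(tab - expected) - 0.5, 0))^2 / expected)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    return(new_comparison(stat, "X-squared", p, "chi2_yates"))
  }
  # Fisher: condition on margins; enumerate the hypergeometric support of
  # the [1,1] cell and sum point probabilities <= the observed one.
  m <- rowSums(tab)[1]; n <- rowSums(tab)[2]; kk <- colSums(tab)[1]
  support <- max(0, kk - n):min(kk, m)
  dens <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n, kk)
  p <- min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
  new_comparison(NA_real_, "none", p, "fisher_exact")
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test with zero-difference dropping; two-sided. The signed
#' statistic Z (tie-corrected normal approximation) follows the direction
#' of the `a - b` differences (negative when `a` ranks below `b`),
#' matching how crossover usability comparisons are conventionally
#' reported. For small samples (`n <= 10` non-zero differences by
#' default) the p-value is computed exactly from the sign-flip
#' permutation distribution of the rank sum; otherwise from the normal
#' approximation.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact permutation
#'   p-value; default `NULL` uses it when at most 10 non-zero differences
#'   remain.
#' @return A `ddst_comparison` with `statistic_name = "Z"`.
#' @export
#' @examples
#' paired_wilcoxon(c(3, 3.4, 2.8, 3.1), c(4.4, 4.2, 4.5, 4.0))
paired_wilcoxon <- function(a, b, exact = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all paired differences are zero")
    return(new_comparison(0, "Z", 1, "wilcoxon_signed_rank"))
  }
  if (is.null(exact)) exact <- n <= 10
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- if (sigma2 > 0) (w_pos - mu) / sqrt(sigma2) else 0
  if (exact) {
    if (n > 20) stop("exact permutation p is limited to n <= 20 pairs",
                     call. = FALSE)
    # distribution of the positive-rank sum over all 2^n sign assignments
    sums <- 0
    for (rk in r) sums <- c(sums, sums + rk)
    p <- mean(abs(sums - mu) >= abs(w_pos - mu) - 1e-9)
  } else {
    if (sigma2 <= 0) {
      warning("degenerate signed-rank distribution")
      return(new_comparison(0, "Z", 1, "wilcoxon_signed_rank"))
    }
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_comparison(z, "Z", p, "wilcoxon_signed_rank")
}

#' Order-effect test (one-way ANOVA)
#'
#' Tests whether nurses' questionnaire totals differ by administration
#' order (paper-first vs app-first), i.e. whether the crossover sequence
#' affected the usability outcome.
#'
#' @param totals Numeric outcome per nurse.
#' @param groups Group labels (2+ levels), one per nurse.
#' @return A `ddst_comparison` with the F statistic.
#' @export
order_effect_test <- function(totals, groups) {
  stopifnot(length(totals) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2))
    stop("each group needs at least 2 observations", call. = FALSE)
  fit <- stats::anova(stats::lm(totals ~ g))
  new_comparison(fit$`F value`[1], "F", fit$`Pr(>F)`[1], "anova")
}

# Percentage formatting used throughout the report tables: 1 decimal,
# with a trailing ".0" dropped at integers ("94" not "94.0"); demographic /
# prevalence style rounds to whole percents.
format_pct <- function(num, den, digits = 1) {
  p <- round(100 * num / den, digits)
  ifelse(p == round(p), sprintf("%d", as.integer(round(p))),
         sprintf(paste0("%.", digits, "f"), p))
}

median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  sprintf("%.2g (%.3g-%.3g)", q[2], q[1], q[3])
}

median_range <- function(x) {
  sprintf("%.3g (%.3g-%.3g)", stats::median(x), min(x), max(x))
}

#' Descriptive report tables for a trial dataset
#'
#' Produces the study-style summary: successful-completion n/N (%) per
#' modality (overall and by group) with the completion-rate test; human
#' error counts by modality and group; completion-time median (IQR) over
#' successful assessments; usability domain scores median (range) with
#' paired signed-rank comparisons and the order-effect ANOVA; and the
#' delirium prevalence among assessed pool patients.
#'
#' @param trial A `ddst_trial` (from [simulate_trial()] or [read_trial()]).
#' @return A list of class `ddst_trial_summary`; see its print method.
#' @export
summarize_trial <- function(trial) {
  a <- trial$assessments
  if (is.null(a) || nrow(a) == 0) stop("empty dataset", call. = FALSE)
  mods <- c("paper", "dst")

  success <- do.call(rbind, lapply(mods, function(m) {
    x <- a[a$modality == m, ]
    by_group <- vapply(c("A", "B"), function(g) {
      xg <- x[x$group == g, ]
      sprintf("%d/%d (%s)", sum(xg$success), nrow(xg),
              format_pct(sum(xg$success), nrow(xg)))
    }, character(1))
    data.frame(modality = m, n = sum(x$success), N = nrow(x),
               pct = format_pct(sum(x$success), nrow(x)),
               group_A = by_group[["A"]], group_B = by_group[["B"]],
               stringsAsFactors = FALSE)
  }))
  tab <- rbind(c(success$n[1], success$N[1] - success$n[1]),
               c(success$n[2], success$N[2] - success$n[2]))
  success_test <- completion_rate_test(tab)

  errors <- do.call(rbind, lapply(mods, function(m) {
    x <- a[a$modality == m, ]
    data.frame(modality = m,
               group_A = sum(x$human_errors[x$group == "A"]),
               group_B = sum(x$human_errors[x$group == "B"]),
               total = sum(x$human_errors), stringsAsFactors = FALSE)
  }))

  time <- do.call(rbind, lapply(mods, function(m) {
    x <- a[a$modality == m & a$success, ]
    data.frame(modality = m, n = nrow(x),
               median_iqr = median_iqr(x$duration),
               group_A = median_iqr(x$duration[x$group == "A"]),
               group_B = median_iqr(x$duration[x$group == "B"]),
               stringsAsFactors = FALSE)
  }))

  usability <- NULL; usability_tests <- NULL; order_effect <- NULL
  u <- trial$usability
  if (!is.null(u) && nrow(u)) {
    u <- u[order(u$nurse_id), ]
    up <- u[u$modality == "paper", ]
    ud <- u[u$modality == "dst", ]
    stopifnot(identical(up$nurse_id, ud$nurse_id))
    doms <- intersect(LIKERT_DOMAINS, names(u))
    usability <- do.call(rbind, lapply(c(doms, "total"), function(dn) {
      data.frame(domain = dn,
                 paper = median_range(up[[dn]]),
                 dst = median_range(ud[[dn]]),
                 stringsAsFactors = FALSE)
    }))
    usability_tests <- lapply(stats::setNames(c(doms, "total"),
                                              c(doms, "total")),
                              function(dn) paired_wilcoxon(up[[dn]], ud[[dn]]))
    mean_total <- c(paper = mean(up$total), dst = mean(ud$total))
    sd_total <- c(paper = stats::sd(up$total), dst = stats::sd(ud$total))
    order_effect <- order_effect_test(ud$total, ud$group)
  } else {
    mean_total <- sd_total <- NULL
  }

  prevalence <- NULL
  if (!is.null(trial$patients)) {
    assessed <- unique(a$patient_id)
    p <- trial$patients[trial$patients$patient_id %in% assessed, ]
    prevalence <- list(n_pos = sum(p$delirium), n = nrow(p),
                       pct = format_pct(sum(p$delirium), nrow(p), digits = 0))
  }

  structure(list(
    n_assessments = nrow(a), n_pairs = length(unique(a$pair_id)),
    n_nurses = length(unique(a$nurse_id)),
    group_split = table(a$group[!duplicated(a$nurse_id)]),
    success = success, success_test = success_test,
    errors = errors, time = time,
    usability = usability, usability_tests = usability_tests,
    mean_total = mean_total, sd_total = sd_total,
    order_effect = order_effect, prevalence = prevalence
  ), class = "ddst_trial_summary")
}

#' @export
print.ddst_trial_summary <- function(x, ...) {
  cat("== Trial summary ==\n")
  cat(sprintf("%d assessments (%d pairs) by %d nurses",
              x$n_assessments, x$n_pairs, x$n_nurses))
  if (length(x$group_split))
    cat(sprintf(" [group A n=%d, group B n=%d]",
                x$group_split[["A"]], x$group_split[["B"]]))
  cat("\n")
  if (!is.null(x$prevalence))
    cat(sprintf("delirium-positive patients: %d/%d (%s%%)\n",
                x$prevalence$n_pos, x$prevalence$n, x$prevalence$pct))
  cat("\nSuccessful completion rate, n/N (%):\n")
  for (i in seq_len(nrow(x$success)))
    cat(sprintf("  %-6s %d/%d (%s)   A: %s  B: %s\n",
                x$success$modality[i], x$success$n[i], x$success$N[i],
                x$success$pct[i], x$success$group_A[i], x$success$group_B[i]))
  cat(sprintf("  test: %s p = %.3f\n", x$success_test$method,
              x$success_test$p_value))
  cat("\nHuman errors, n (A / B / total):\n")
  for (i in seq_len(nrow(x$errors)))
    cat(sprintf("  %-6s %d / %d / %d\n", x$errors$modality[i],
                x$errors$group_A[i], x$errors$group_B[i], x$errors$total[i]))
  cat("\nCompletion time (min), median (IQR), successful assessments:\n")
  for (i in seq_len(nrow(x$time)))
    cat(sprintf("  %-6s n=%d  %s\n", x$time$modality[i], x$time$n[i],
                x$time$median_iqr[i]))
  if (!is.null(x$usability)) {
    cat("\nUsability domain scores, median (range) [paper | dst], Z, p:\n")
    for (i in seq_len(nrow(x$usability))) {
      dn <- x$usability$domain[i]
      tt <- x$usability_tests[[dn]]
      cat(sprintf("  %-16s %s | %s   Z=%.3f p=%.3g\n", dn,
                  x$usability$paper[i], x$usability$dst[i],
                  tt$statistic, tt$p_value))
    }
    cat(sprintf("  mean total: paper %.2f (SD %.2f), dst %.2f (SD %.2f)\n",
                x$mean_total[["paper"]], x$sd_total[["paper"]],
                x$mean_total[["dst"]], x$sd_total[["dst"]]))
    cat(sprintf("  order effect (ANOVA on dst totals by group): F=%.3f p=%.3f\n",
                x$order_effect$statistic, x$order_effect$p_value))
  }
  invisible(x)
}

#' Sample size with attrition inflation
#'
#' Two-sample normal-approximation formula for a mean difference:
#' `n_per_group = ceiling(2 * ((z_{1-alpha/2} + z_{power}) * sd / delta)^2)`.
#' Enrollment inflates the analysable sample for anticipated
#' non-completion: `n_enrol = ceiling(n_analysable / (1 - attrition))`.
#' Supplying `n_analysable` directly applies the inflation step alone
#' (e.g. 54 analysable with 25% attrition requires enrolling 72).
#'
#' @param delta Smallest meaningful difference (points).
#' @param sd Outcome standard deviation (points).
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @param attrition Anticipated non-completion proportion in `[0, 1)`.
#' @param n_analysable Optional: skip the formula and inflate this count.
#' @return List with `n_analysable` (per group when computed from the
#'   formula; as supplied otherwise) and `n_enrol`.
#' @export
#' @examples
#' required_sample_size(n_analysable = 54, attrition = 0.25)$n_enrol  # 72
#' required_sample_size(delta = 1, sd = 1)$n_analysable               # 22
required_sample_size <- function(delta = NULL, sd = NULL, alpha = 0.05,
                                 power = 0.90, attrition = 0,
                                 n_analysable = NULL) {
  if (attrition < 0 || attrition >= 1)
    stop("attrition must be in [0, 1)", call. = FALSE)
  if (is.null(n_analysable)) {
    stopifnot(delta > 0, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
    z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
    n_analysable <- ceiling(2 * (z * sd / delta)^2)
  }
  list(n_analysable = as.integer(n_analysable),
       n_enrol = as.integer(ceiling(n_analysable / (1 - attrition))))
}
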