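#' Group summary statistics
#'
#' Sample size, mean and standard deviation of one group's change score, as
#' printed in trial reports; the input format for the summary-statistics
#' tests.
#'
#' @param n sample size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (>= 0).
#' @return An object of class `group_summary`.
#' @examples
#' group_summary(24, -39, 166.7)
#' @export
group_summary <- function(n, mean, sd) {
  if (n < 2) .stopf("n must be at least 2")
  if (sd < 0) .stopf("sd must be nonnegative")
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

#' Summarise a raw vector into a group summary
#' @param x numeric vector, length >= 2.
#' @return A [group_summary()].
#' @export
as_group_summary <- function(x) {
  if (length(x) < 2) .stopf("need at least 2 observations")
  group_summary(length(x), mean(x), sd(x))
}

.pooled_sd <- function(a, b) {
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  sqrt(sp2)
}

#' Two-sample pooled-variance (Student) t test from summaries
#'
#' Student's t with pooled variance and `df = n_a + n_b - 2`, the test the
#' trial analysis plan prescribes (the printed degrees of freedom, 44 and
#' 41, identify the pooled rather than the Welch form). Two-sided p value.
#'
#' @param a,b [group_summary()] objects (or raw numeric vectors, which are
#'   summarised first).
#' @return A list with `t`, `df`, `p`.
#' @examples
#' two_sample_t(group_summary(19, -64.7, 119.4), group_summary(24, -46, 143.1))
#' @export
two_sample_t <- function(a, b) {
  if (is.numeric(a)) a <- as_group_summary(a)
  if (is.numeric(b)) b <- as_group_summary(b)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp <- .pooled_sd(a, b)
  if (sp == 0) .stopf("zero pooled variance")
  se <- sp * sqrt(1 / a$n + 1 / b$n)
  t <- (a$mean - b$mean) / se
  df <- a$n + b$n - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Cohen's d with confidence interval from summaries
#'
#' Standardized mean difference `d = (mean_a - mean_b) / s_pooled`. The
#' confidence interval uses the normal approximation with
#' `SE = sqrt((n_a + n_b)/(n_a n_b) + d^2 / (2 (n_a + n_b)))`.
#'
#' @param a,b [group_summary()] objects or raw numeric vectors.
#' @param level confidence level.
#' @return A list with `d`, `lo`, `hi`, `se`.
#' @examples
#' ## full-session effect size of the worked example
#' cohens_d_ci(group_summary(24, -39, 166.7), group_summary(22, -76, 174.5))
#' @export
cohens_d_ci <- function(a, b, level = 0.95) {
  if (is.numeric(a)) a <- as_group_summary(a)
  if (is.numeric(b)) b <- as_group_summary(b)
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  sp <- .pooled_sd(a, b)
  if (sp == 0) .stopf("zero pooled standard deviation")
  d <- (a$mean - b$mean) / sp
  se <- sqrt((a$n + b$n) / (a$n * b$n) + d^2 / (2 * (a$n + b$n)))
  z <- qnorm(1 - (1 - level) / 2)
  list(d = d, lo = d - z * se, hi = d + z * se, se = se)
}

#' Intention-to-treat imputation of a missing second session
#'
#' A subject missing session 2 is imputed by carrying the group's mean
#' change: imputed session-2 value = subject's baseline plus the mean
#' change (session 2 minus session 1) of the other subjects in the same
#' arm; equivalently, the subject's change is set to the group's mean
#' change.
#'
#' @param baseline the subject's session-1 value.
#' @param other_changes changes (session 2 - session 1) of the other
#'   subjects in the arm; nonempty.
#' @return A list with `imputed_session2` and `imputed_change`.
#' @examples
#' impute_missing_change(500, c(-100, -60))  # 420
#' @export
impute_missing_change <- function(baseline, other_changes) {
  if (length(other_changes) == 0) .stopf("other_changes must be nonempty")
  m <- mean(other_changes)
  list(imputed_session2 = baseline + m, imputed_change = m)
}

#' Pearson correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return A list with `r`, `p`.
#' @export
pearson_r <- function(x, y) {
  .check_cor_input(x, y)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spearman rank correlation with two-sided p value
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return A list with `rho`, `p`.
#' @export
spearman_rho <- function(x, y) {
  .check_cor_input(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

.check_cor_input <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(x) < 3) .stopf("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) .stopf("constant vector")
  invisible(TRUE)
}

#' Slopes of subjective responses between assessments
#'
#' Changes in subjective measures are defined as slopes between assessment
#' time points 2 to 3 (ascending phase) and 3 to 4 (plateau phase):
#' `(score3 - score2)/(t3 - t2)` and `(score4 - score3)/(t4 - t3)`.
#'
#' @param scores numeric vector of four assessment scores, or the
#'   `assessments` data frame of an `asa_session` (one slope pair per
#'   scale column).
#' @param times the four assessment times, minutes.
#' @return For a vector: list with `ascending`, `plateau`. For a data
#'   frame: a data frame with one row per scale.
#' @examples
#' subjective_slopes(c(10, 20, 50, 50), c(-25, 15, 75, 150))
#' @export
subjective_slopes <- function(scores, times = c(-25, 15, 75, 150)) {
  if (length(times) != 4 || any(diff(times) <= 0))
    .stopf("times must be four increasing assessment time points")
  if (is.data.frame(scores)) {
    if (nrow(scores) != 4) .stopf("assessment data frame must have 4 rows")
    scales <- setdiff(names(scores), "t")
    tt <- if ("t" %in% names(scores)) scores$t else times
    out <- do.call(rbind, lapply(scales, function(sc) {
      sl <- subjective_slopes(scores[[sc]], tt)
      data.frame(scale = sc, ascending = sl$ascending, plateau = sl$plateau)
    }))
    return(out)
  }
  if (length(scores) != 4 || any(!is.finite(scores)))
    .stopf("scores must be four finite assessment values")
  list(ascending = (scores[3] - scores[2]) / (times[3] - times[2]),
       plateau = (scores[4] - scores[3]) / (times[4] - times[3]))
}

#' Per-subject endpoint table from session logs
#'
#' Builds the endpoint table of a two-session trial: per subject and
#' session, cumulative work for alcohol and saline (full session and per
#' phase), peak and mean BrAC.
#'
#' @param sessions list of `asa_session` objects (both sessions of every
#'   subject).
#' @param groups named character vector mapping subject id to arm
#'   (`"placebo"`/`"naltrexone"`-style labels are conventional but free).
#' @return A data frame with one row per subject.
#' @export
endpoint_table <- function(sessions, groups = NULL) {
  stopifnot(all(vapply(sessions, inherits, TRUE, "asa_session")))
  ids <- vapply(sessions, `[[`, "", "subject")
  idx <- vapply(sessions, `[[`, 0, "session_index")
  one <- function(id) {
    s1 <- sessions[[which(ids == id & idx == 1)[1]]]
    s2 <- sessions[[which(ids == id & idx == 2)[1]]]
    data.frame(
      subject = id,
      group = if (is.null(groups)) NA_character_ else unname(groups[id]),
      drug_level = s2$drug_level,
      cwfa_1 = s1$cwfa, cwfa_2 = s2$cwfa,
      cwfs_1 = s1$cwfs, cwfs_2 = s2$cwfs,
      cwfa_asc_1 = cumulative_work(s1, "alcohol", c(0, 75)),
      cwfa_asc_2 = cumulative_work(s2, "alcohol", c(0, 75)),
      cwfa_plat_1 = cumulative_work(s1, "alcohol", c(75, 150)),
      cwfa_plat_2 = cumulative_work(s2, "alcohol", c(75, 150)),
      peak_brac_1 = s1$peak_brac, peak_brac_2 = s2$peak_brac,
      mean_brac_1 = s1$mean_brac, mean_brac_2 = s2$mean_brac)
  }
  out <- do.call(rbind, lapply(unique(ids), one))
  rownames(out) <- NULL
  out
}

#' Group statistics of a two-session trial
#'
#' Computes the change scores (session 2 minus session 1) of the primary
#' endpoint (cumulative work for alcohol) for the full session and the two
#' phases, compares arms with the pooled t test and Cohen's d (control arm
#' first, so a larger reduction under drug gives positive d), and
#' correlates drug blood level with the change in the treated arm.
#'
#' @param endpoints an [endpoint_table()] with a `group` column containing
#'   exactly two levels.
#' @param control label of the control (reference) arm; defaults to
#'   `"placebo"` when present, else the first level.
#' @return A list of class `asa_trial_stats`.
#' @export
analyze_endpoints <- function(endpoints, control = NULL) {
  g <- unique(endpoints$group)
  if (length(g) != 2) .stopf("endpoints must contain exactly two groups")
  if (is.null(control)) control <- if ("placebo" %in% g) "placebo" else g[1]
  treated <- setdiff(g, control)
  ep <- endpoints
  ep$d_full <- ep$cwfa_2 - ep$cwfa_1
  ep$d_asc <- ep$cwfa_asc_2 - ep$cwfa_asc_1
  ep$d_plat <- ep$cwfa_plat_2 - ep$cwfa_plat_1
  one <- function(var) {
    a <- ep[[var]][ep$group == control]
    b <- ep[[var]][ep$group == treated]
    tt <- two_sample_t(a, b)
    dd <- cohens_d_ci(a, b)
    list(control = as_group_summary(a), treated = as_group_summary(b),
         t = tt$t, df = tt$df, p = tt$p, d = dd$d, lo = dd$lo, hi = dd$hi)
  }
  tr <- ep[ep$group == treated, ]
  corr <- if (nrow(tr) >= 3 && sd(tr$drug_level) > 0 && sd(tr$d_full) > 0)
    pearson_r(tr$drug_level, tr$d_full)
  else list(r = NA_real_, p = NA_real_)
  structure(
    list(control = control, treated = treated,
         full = one("d_full"), ascending = one("d_asc"),
         plateau = one("d_plat"),
         blood_level_correlation = corr),
    class = "asa_trial_stats")
}

#' @export
print.asa_trial_stats <- function(x, ...) {
  row <- function(nm, s)
    cat(sprintf(
      "  %-10s d = %6.3f (%.3f, %.3f), t(%d) = %.3f, p = %.3f\n",
      nm, s$d, s$lo, s$hi, s$df, s$t, s$p))
  cat(sprintf("Change in cWFA, %s vs %s:\n", x$control, x$treated))
  row("full", x$full); row("ascending", x$ascending); row("plateau", x$plateau)
  if (!is.na(x$blood_level_correlation$r))
    cat(sprintf("  blood level vs change in cWFA (%s): r = %.3f, p = %.3f\n",
                x$treated, x$blood_level_correlation$r,
                x$blood_level_correlation$p))
  invisible(x)
}
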