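#' Cohort and trial configuration
#'
#' Study conditions for an in-silico two-session, two-arm trial: cohort
#' size, genotype enrichment, sex composition, drug effect and blood-level
#' distribution, and the between-subject heterogeneity that generates
#' test-retest structure.
#'
#' @param n_per_arm subjects per arm (>= 2).
#' @param g_allele_freq OPRM1 A118G G-allele frequency in the screening
#'   population (Hardy-Weinberg genotype draws); the screening stream is
#'   enriched by [enrich_by_genotype()].
#' @param male_fraction proportion of males in the screening stream.
#' @param delta drug attenuation of positive reinforcement per ng/ml of
#'   blood level.
#' @param blood_mean,blood_sd blood-level distribution (parent drug plus
#'   active metabolite) in the treated arm at session 2, ng/ml (normal,
#'   truncated at 0).
#' @param propensity_sd SD of the persistent between-subject work
#'   propensity random effect (carried across both sessions; a source of
#'   test-retest correlation).
#' @param ceiling_sd SD of the persistent between-subject comfort-ceiling
#'   random effect, mg/dL.
#' @param desire_sdlog lognormal sdlog of the persistent between-subject
#'   desire-responsiveness multiplier (scales the desire gains; with the
#'   strong desire-to-work coupling this is the main stable individual
#'   difference behind plateau-phase work).
#' @param pk_cv lognormal coefficient of variation applied to each
#'   subject's true `vmax` and `vd` (the controller holds the unperturbed
#'   population estimate and relies on recalibration).
#' @param n_noncompliant number of treated-arm subjects whose blood level
#'   is forced to 0 (exercises the per-protocol exclusion path).
#' @param seed RNG seed for the whole trial.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_arm = 23, g_allele_freq = 0.15,
                          male_fraction = 0.87, delta = 0.005,
                          blood_mean = 55.4, blood_sd = 27.6,
                          propensity_sd = 0.45, ceiling_sd = 5,
                          desire_sdlog = 1.2, pk_cv = 0.15,
                          n_noncompliant = 0, seed = NULL) {
  if (n_per_arm < 2) .stopf("need at least 2 subjects per arm")
  if (g_allele_freq < 0 || g_allele_freq > 1)
    .stopf("g_allele_freq must lie in [0, 1]")
  structure(as.list(environment()), class = "cohort_config")
}

#' Genotype-enrichment selection from a screening block
#'
#' Of each block of six consecutively screened subjects only three may
#' enter, chosen by genotype priority GG first, then AG, then AA, ties
#' broken by consent order.
#'
#' @param block_of_6 character vector of six genotypes
#'   (`"AA"`/`"AG"`/`"GG"`), in consent order.
#' @return Integer positions (within the block) of the three selected
#'   subjects, in consent order.
#' @examples
#' enrich_by_genotype(c("AA", "AG", "AA", "GG", "AA", "AG"))  # 4 2 6 -> 2 4 6
#' @export
enrich_by_genotype <- function(block_of_6) {
  if (length(block_of_6) != 6) .stopf("block must contain exactly 6 subjects")
  if (!all(block_of_6 %in% c("AA", "AG", "GG")))
    .stopf("genotypes must be AA, AG or GG")
  priority <- match(block_of_6, c("GG", "AG", "AA"))
  sort(order(priority, seq_along(block_of_6))[1:3])
}

#' Stratified permuted-block randomization
#'
#' Assigns subjects to two arms with permuted blocks of 4 within strata
#' defined by sex and G-allele carrier status (AG or GG vs AA), so that
#' within every stratum the arm counts differ by at most 2.
#'
#' @param subjects data frame with columns `sex` and `genotype`.
#' @param arms labels of the two arms.
#' @param seed optional RNG seed.
#' @return Character vector of arm assignments, one per subject row.
#' @export
stratified_randomize <- function(subjects,
                                 arms = c("placebo", "naltrexone"),
                                 seed = NULL) {
  stopifnot(is.data.frame(subjects),
            all(c("sex", "genotype") %in% names(subjects)),
            length(arms) == 2)
  if (!is.null(seed)) set.seed(seed)
  carrier <- subjects$genotype %in% c("AG", "GG")
  stratum <- paste(subjects$sex, ifelse(carrier, "carrier", "AA"))
  out <- character(nrow(subjects))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    n_blocks <- ceiling(length(idx) / 4)
    seq_arm <- unlist(lapply(seq_len(n_blocks),
                             function(i) sample(rep(arms, 2))))
    out[idx] <- seq_arm[seq_along(idx)]
  }
  out
}

#' Assemble a genotype-enriched synthetic cohort
#'
#' Draws a screening stream (Hardy-Weinberg genotypes at the configured
#' allele frequency, sex by `male_fraction`, age uniform 25-55, height and
#' weight from sex-specific normals truncated at the 130 kg bound), applies
#' the block-of-six genotype enrichment, and equips each enrolled subject
#' with persistent agent and pharmacokinetic random effects.
#'
#' @param config a [cohort_config()].
#' @param n number of subjects to enrol (default `2 * n_per_arm`).
#' @return A data frame with one row per subject (columns `id`, `sex`,
#'   `age`, `height`, `weight`, `genotype`, `work_propensity`, `vmax_mult`,
#'   `vd_mult`).
#' @export
make_cohort <- function(config, n = 2 * config$n_per_arm) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  q <- config$g_allele_freq
  geno_probs <- c(AA = (1 - q)^2, AG = 2 * q * (1 - q), GG = q^2)
  rows <- list()
  while (length(rows) < n) {
    block <- sample(names(geno_probs), 6, replace = TRUE, prob = geno_probs)
    keep <- enrich_by_genotype(block)
    for (k in keep) {
      if (length(rows) >= n) break
      sex <- if (runif(1) < config$male_fraction) "male" else "female"
      height <- if (sex == "male") rnorm(1, 180, 7) else rnorm(1, 167, 7)
      weight <- if (sex == "male") rnorm(1, 85, 12) else rnorm(1, 70, 11)
      weight <- min(max(weight, 50), 130)
      height <- min(max(height, 150), 210)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("s%03d", length(rows) + 1L),
        sex = sex, age = runif(1, 25, 55), height = height, weight = weight,
        genotype = block[k],
        work_propensity = rnorm(1, 0, config$propensity_sd),
        ceiling_shift = rnorm(1, 0, config$ceiling_sd),
        desire_mult = rlnorm(1, 0, config$desire_sdlog),
        vmax_mult = rlnorm(1, 0, config$pk_cv),
        vd_mult = rlnorm(1, 0, config$pk_cv))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete two-session trial
#'
#' Builds the enriched cohort, randomizes it (stratified by sex and carrier
#' status), runs session 1 for every subject, applies the treated arm's
#' drug blood levels, runs session 2, and analyzes the endpoint table. The
#' subject's true pharmacokinetics carry lognormal perturbations; the clamp
#' controller starts from the unperturbed population model and recalibrates
#' from breathalyzer readings. The whole trial is reproducible from
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param schedule,cat,session_cfg paradigm configuration shared by all
#'   sessions.
#' @param agent_base baseline [agent_params()]; each subject's
#'   `work_propensity` random effect and the configured `delta` are applied
#'   on top.
#' @return An object of class `asa_trial`: `cohort`, `endpoints`
#'   ([endpoint_table()] plus blood levels), `stats`
#'   ([analyze_endpoints()]), `sessions` (list of `asa_session`), `config`.
#' @export
simulate_trial <- function(config = cohort_config(),
                           schedule = calibrate_schedule(),
                           cat = cat_config(),
                           session_cfg = session_config(),
                           agent_base = agent_params()) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- make_cohort(config)  # seeds the RNG from config$seed
  cohort$group <- stratified_randomize(cohort)
  treated <- "naltrexone"
  ## blood levels at session 2: truncated normal in the treated arm
  lvl <- ifelse(cohort$group == treated,
                pmax(0, rnorm(nrow(cohort), config$blood_mean,
                              config$blood_sd)),
                0)
  if (config$n_noncompliant > 0) {
    nc <- which(cohort$group == treated)[seq_len(config$n_noncompliant)]
    lvl[nc] <- 0
  }
  cohort$blood_level <- lvl
  ## per-session seeds drawn once, below 2^31
  seeds <- matrix(sample.int(.Machine$integer.max - 1, 2 * nrow(cohort)),
                  ncol = 2)
  sessions <- vector("list", 2 * nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    prof <- subject_profile(cohort$id[i], cohort$sex[i], cohort$age[i],
                            cohort$height[i], cohort$weight[i],
                            cohort$genotype[i])
    pop <- default_pk_params(prof)
    truth <- pk_params(vd = pop$vd * cohort$vd_mult[i],
                       vmax = pop$vmax * cohort$vmax_mult[i],
                       km = pop$km, k_per = pop$k_per, f_per = pop$f_per)
    ag <- agent_base
    ag$work_propensity <- ag$work_propensity + cohort$work_propensity[i]
    ag$brac_ceiling <- max(55, ag$brac_ceiling + cohort$ceiling_shift[i])
    ag$desire_gap <- ag$desire_gap * cohort$desire_mult[i]
    ag$desire_gain <- ag$desire_gain * cohort$desire_mult[i]
    ag$drug_attenuation <- config$delta
    sessions[[2 * i - 1]] <- run_session(
      prof, pk = truth, agent = ag, schedule = schedule, cat = cat,
      config = session_cfg, ctrl_params = pop, drug_level = 0,
      session_index = 1, seed = seeds[i, 1])
    sessions[[2 * i]] <- run_session(
      prof, pk = truth, agent = ag, schedule = schedule, cat = cat,
      config = session_cfg, ctrl_params = pop,
      drug_level = cohort$blood_level[i],
      session_index = 2, seed = seeds[i, 2])
  }
  groups <- setNames(cohort$group, cohort$id)
  ep <- endpoint_table(sessions, groups)
  ep$blood_level <- cohort$blood_level[match(ep$subject, cohort$id)]
  ep$drug_level <- ep$blood_level
  structure(
    list(cohort = cohort, endpoints = ep,
         stats = analyze_endpoints(ep),
         sessions = sessions, config = config),
    class = "asa_trial")
}

#' @export
print.asa_trial <- function(x, ...) {
  n <- table(x$cohort$group)
  cat(sprintf("<asa_trial> %s, delta = %g\n",
              paste(sprintf("%s n=%d", names(n), n), collapse = " vs "),
              x$config$delta))
  print(x$stats)
  invisible(x)
}
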