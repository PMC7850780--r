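# Synthetic survey cohorts with known ground truth. Each respondent carries
# a latent vulnerability trait t in [0, 1]; categorical answers are drawn so
# that higher traits stochastically select higher-scored options, message
# judgments follow an additive belief model in which background evidence
# raises the probability that a false message is marked true, and a planted
# number of records violate the cohort exclusion filters. Subgroup mean-K
# targets are planted exactly in expectation (see calibrate_trait_center).

default_age_distribution <- function() {
  c(under_18 = 25, `19_25` = 395, `26_35` = 160, `36_50` = 291,
    `51_65` = 235, over_65 = 31) / 1137
}

default_occupation_distribution <- function() {
  c(HCW = 291, professionals = 276, managers = 18, service_and_sales = 89,
    elementary = 72, clerical = 7, students = 345, retired_unemployed = 39) / 1137
}

# Planted mean-K gradient across age (lowest for the youngest, rising to the
# oldest) and across occupations (highest in elementary occupations, lowest
# for managers).
default_age_k_targets <- function() {
  c(under_18 = 0.31, `19_25` = 0.31, `26_35` = 0.34, `36_50` = 0.35,
    `51_65` = 0.36, over_65 = 0.38)
}

default_occupation_k_targets <- function() {
  c(HCW = 0.35, professionals = 0.34, managers = 0.33,
    service_and_sales = 0.35, elementary = 0.38, clerical = 0.35,
    students = 0.34, retired_unemployed = 0.36)
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-cohort generator.
#' The defaults are the study conditions: 1191 respondents of whom 54
#' violate an exclusion filter (leaving 1137), the observed age and
#' occupation marginals, a planted mean-K gradient rising with age and
#' peaking in elementary occupations, a latent-trait dispersion matching the
#' vulnerability spread implied by the reported subgroup confidence
#' intervals, and a belief model in which a false message is marked true
#' with probability 0.053 without background evidence and 0.299 with it.
#'
#' @param n_respondents Total generated records, including violators.
#' @param seed Integer seed; every random draw in [generate_cohort()] flows
#'   from it.
#' @param age_distribution Named probabilities over [age_group_levels()].
#' @param occupation_distribution Named probabilities over
#'   [occupation_group_levels()].
#' @param age_k_targets,occupation_k_targets Named target mean K per
#'   subgroup; cell-level targets are additive in the two margins.
#' @param response_noise Standard deviation of the latent trait within a
#'   subgroup cell (trait scale, default 0.09).
#' @param belief_model List with `base_rate` (probability a false message
#'   without evidence is marked true), `evidence_effect` (additive increase
#'   when evidence is attached), and `true_marked_true` (probability a true
#'   message is marked true).
#' @param n_excluded_violators Number of records planted to fail an
#'   exclusion filter.
#' @return Validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_respondents = 1191,
                              seed = 1L,
                              age_distribution = default_age_distribution(),
                              occupation_distribution = default_occupation_distribution(),
                              age_k_targets = default_age_k_targets(),
                              occupation_k_targets = default_occupation_k_targets(),
                              response_noise = 0.09,
                              belief_model = list(base_rate = 0.053,
                                                  evidence_effect = 0.246,
                                                  true_marked_true = 0.8),
                              n_excluded_violators = 54) {
  stopifnot(n_respondents >= 1, n_excluded_violators >= 0,
            n_excluded_violators < n_respondents, response_noise > 0)
  check_dist <- function(d, lv, what) {
    if (!setequal(names(d), lv)) {
      stop(what, " must be named by: ", paste(lv, collapse = ", "))
    }
    if (any(d < 0) || abs(sum(d) - 1) > 1e-8) {
      stop(what, " must be non-negative probabilities summing to 1")
    }
    d[lv]
  }
  age_distribution <- check_dist(age_distribution, age_group_levels(),
                                 "age_distribution")
  occupation_distribution <- check_dist(occupation_distribution,
                                        occupation_group_levels(),
                                        "occupation_distribution")
  if (!setequal(names(age_k_targets), age_group_levels()) ||
      !setequal(names(occupation_k_targets), occupation_group_levels())) {
    stop("k targets must cover every age and occupation subgroup")
  }
  bm <- belief_model
  if (is.null(bm$base_rate) || is.null(bm$evidence_effect) ||
      is.null(bm$true_marked_true)) {
    stop("belief_model needs base_rate, evidence_effect and true_marked_true")
  }
  if (bm$base_rate < 0 || bm$evidence_effect < 0 ||
      bm$base_rate + bm$evidence_effect > 1 ||
      bm$true_marked_true < 0 || bm$true_marked_true > 1) {
    stop("belief model probabilities must lie in [0, 1] with base_rate + evidence_effect <= 1")
  }
  structure(list(
    n_respondents = as.integer(n_respondents), seed = as.integer(seed),
    age_distribution = age_distribution,
    occupation_distribution = occupation_distribution,
    age_k_targets = age_k_targets[age_group_levels()],
    occupation_k_targets = occupation_k_targets[occupation_group_levels()],
    response_noise = response_noise, belief_model = bm,
    n_excluded_violators = as.integer(n_excluded_violators)
  ), class = "simulation_config")
}

# Exact distribution of the incorrect-judgment count under the belief model:
# a Poisson-binomial over the bank's messages (false messages are incorrect
# when marked true; true messages when marked false).
incorrect_count_distribution <- function(bank, belief_model) {
  p_true_mark <- ifelse(
    bank$truth_label == "false",
    pmin(1, belief_model$base_rate +
           belief_model$evidence_effect * (bank$evidence_flag == "has_link_or_source")),
    belief_model$true_marked_true
  )
  p_incorrect <- ifelse(bank$truth_label == "false", p_true_mark,
                        1 - p_true_mark)
  dist <- 1
  for (p in p_incorrect) {
    dist <- c(dist * (1 - p), 0) + c(0, dist * p)
  }
  dist  # dist[k + 1] = P(incorrect count = k)
}

expected_p8_score <- function(rubric, bank, belief_model) {
  if (is.null(rubric$incorrect_bins)) return(0)
  dist <- incorrect_count_distribution(bank, belief_model)
  counts <- seq_along(dist) - 1L
  sum(dist * bin_incorrect(counts, rubric))
}

# Mean of a N(c, sigma) variable clamped (censored) to [0, 1].
clamped_normal_mean <- function(c, sigma) {
  a <- (0 - c) / sigma
  b <- (1 - c) / sigma
  c * (stats::pnorm(b) - stats::pnorm(a)) +
    sigma * (stats::dnorm(a) - stats::dnorm(b)) +
    (1 - stats::pnorm(b))
}

# Find the normal center c such that the [0,1]-clamped trait has mean
# t_target; the clamped mean is strictly increasing in c.
calibrate_trait_center <- function(t_target, sigma) {
  vapply(t_target, function(tt) {
    stats::uniroot(function(c) clamped_normal_mean(c, sigma) - tt,
                   lower = -10 * sigma, upper = 1 + 10 * sigma,
                   extendInt = "yes", tol = 1e-10)$root
  }, numeric(1))
}

# Representative occupation labels compatible with assign_occupation_group().
occupation_label_pool <- function() {
  list(HCW = c("doctor", "nurse"),
       professionals = c("engineer", "teacher", "accountant"),
       managers = c("manager", "director"),
       service_and_sales = c("shopkeeper", "salesperson", "cook"),
       elementary = c("cleaner", "labourer", "driver"),
       clerical = c("clerk", "receptionist"),
       students = "student",
       retired_unemployed = "retired")
}

#' Generate a synthetic survey cohort
#'
#' Draws a full synthetic survey population under a [simulation_config()]:
#' demographics from the configured marginals, answers from the latent-trait
#' response model, message judgments from the belief model, and exactly
#' `n_excluded_violators` records violating an exclusion filter. Fully
#' reproducible given the config seed.
#'
#' @param config A `simulation_config`.
#' @param rubric Scoring rubric (default [default_rubric()]).
#' @param bank Message bank (default [default_message_bank()]).
#' @return Object of class `synthetic_cohort`: list with `records` (survey
#'   data frame in the schema read by [read_survey()]), `truth` (per
#'   respondent: latent trait, subgroups, planted cell target), `bank`,
#'   `rubric`, `config`.
#' @export
generate_cohort <- function(config, rubric = default_rubric(),
                            bank = default_message_bank()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_respondents

  age_group <- sample(age_group_levels(), n, replace = TRUE,
                      prob = config$age_distribution)
  occ_group <- sample(occupation_group_levels(), n, replace = TRUE,
                      prob = config$occupation_distribution)

  age_ranges <- list(under_18 = c(12, 18), `19_25` = c(19, 25),
                     `26_35` = c(26, 35), `36_50` = c(36, 50),
                     `51_65` = c(51, 65), over_65 = c(66, 90))
  age_years <- vapply(age_group, function(g) {
    r <- age_ranges[[g]]
    sample(r[1]:r[2], 1)
  }, numeric(1))

  gender <- sample(c("man", "woman", "gender_fluid"), n, replace = TRUE,
                   prob = c(648, 488, 1) / 1137)

  pool <- occupation_label_pool()
  occ_label <- vapply(occ_group, function(g) {
    labs <- pool[[g]]
    if (length(labs) == 1) labs else sample(labs, 1)
  }, character(1))

  # Planted cell target: additive in the two margins, centered so the age
  # marginal means equal the age targets in expectation.
  occ_centered <- config$occupation_k_targets -
    sum(config$occupation_k_targets * config$occupation_distribution)
  k_target <- config$age_k_targets[age_group] + occ_centered[occ_group]

  trait_items <- rubric$item_table$item_id
  item_min <- vapply(rubric$option_scores, min, numeric(1))
  item_max <- vapply(rubric$option_scores, max, numeric(1))
  min_sum <- sum(item_min)
  score_range <- sum(item_max - item_min)
  e_p8 <- expected_p8_score(rubric, bank, config$belief_model)
  t_req <- (k_target * rubric$s_max - min_sum - e_p8) / score_range
  bad <- which(t_req <= 0 | t_req >= 1)
  if (length(bad)) {
    stop("infeasible subgroup K target: cell target ",
         signif(k_target[bad[1]], 3), " (", age_group[bad[1]], " x ",
         occ_group[bad[1]], ") requires a latent trait outside (0, 1)")
  }
  centers <- calibrate_trait_center(unique(t_req), config$response_noise)
  names(centers) <- as.character(unique(t_req))
  trait <- pmin(pmax(stats::rnorm(n, centers[as.character(t_req)],
                                  config$response_noise), 0), 1)

  answers <- list()
  for (it in trait_items) {
    tab <- rubric$option_scores[[it]]
    ord <- order(tab, names(tab))  # ascending score, labels break ties
    labs <- names(tab)[ord]
    idx <- stats::rbinom(n, size = length(labs) - 1L, prob = trait)
    answers[[paste0("answer_", it)]] <- labs[idx + 1L]
  }

  bm <- config$belief_model
  judgments <- list()
  for (j in seq_len(nrow(bank))) {
    p_true <- if (bank$truth_label[j] == "false") {
      min(1, bm$base_rate +
            bm$evidence_effect * (bank$evidence_flag[j] == "has_link_or_source"))
    } else bm$true_marked_true
    marked_true <- stats::runif(n) < p_true
    sure <- stats::runif(n) < 1 / 3  # "definitely" vs "maybe" intensity
    judgments[[paste0("judgment_", bank$message_id[j])]] <-
      ifelse(marked_true, ifelse(sure, "definitely_true", "maybe_true"),
             ifelse(sure, "definitely_false", "maybe_false"))
  }

  uses_whatsapp <- rep(TRUE, n)
  resides_in_india <- rep(TRUE, n)
  if (config$n_excluded_violators > 0) {
    vio <- sample.int(n, config$n_excluded_violators)
    half <- seq_along(vio) %% 2 == 1
    uses_whatsapp[vio[half]] <- FALSE
    resides_in_india[vio[!half]] <- FALSE
  }

  records <- data.frame(
    respondent_id = sprintf("R%05d", seq_len(n)),
    uses_whatsapp = uses_whatsapp,
    resides_in_india = resides_in_india,
    age_years = as.integer(age_years),
    gender = gender,
    occupation_label = occ_label,
    is_hcw = occ_group == "HCW",
    is_student = occ_group == "students",
    is_retired_or_unemployed = occ_group == "retired_unemployed",
    stringsAsFactors = FALSE
  )
  records <- cbind(records, as.data.frame(answers, stringsAsFactors = FALSE),
                   as.data.frame(judgments, stringsAsFactors = FALSE))

  truth <- data.frame(
    respondent_id = records$respondent_id,
    trait = trait,
    age_group = age_group,
    occupation_group = occ_group,
    k_target = unname(k_target),
    stringsAsFactors = FALSE
  )
  structure(list(records = records, truth = truth, bank = bank,
                 rubric = rubric, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$records), "records (",
      x$config$n_excluded_violators, "planted exclusion violators ), seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the survey CSV in the exact schema consumed by [read_survey()],
#' plus a JSON metadata file recording the seed and configuration.
#'
#' @param cohort A `synthetic_cohort`.
#' @param path Output CSV path; metadata goes to `<path>.meta.json`.
#' @return Invisibly, the CSV path.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$records, path, row.names = FALSE)
  meta <- list(seed = cohort$config$seed,
               n_respondents = cohort$config$n_respondents,
               n_excluded_violators = cohort$config$n_excluded_violators,
               response_noise = cohort$config$response_noise,
               belief_model = cohort$config$belief_model)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Parameter-recovery report for a synthetic cohort
#'
#' Runs the full analysis on a generated cohort and compares what it
#' recovers against what was planted: per-subgroup mean-K error and CI
#' coverage, ANOVA and GT2 detection of the planted ordering, and the bias
#' of the estimated evidence effect.
#'
#' @param cohort A `synthetic_cohort`.
#' @param alpha Significance level for the post hoc comparisons.
#' @param confidence Confidence level for subgroup intervals.
#' @return Object of class `recovery_report`: list with `subgroups` (data
#'   frame: dimension, group, n, estimate, CI, target, abs_error,
#'   ci_covers), `anova` (per dimension), `gt2` (per dimension),
#'   `evidence` (planted effect, estimate, bias), `credibility`, and
#'   `n_retained`.
#' @export
recover_parameters <- function(cohort, alpha = 0.05, confidence = 0.95) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!identical(sort(cohort$records$respondent_id),
                 sort(cohort$truth$respondent_id))) {
    stop("cohort records and truth tables have mismatched respondent ids")
  }
  part <- apply_exclusions(cohort$records)
  scored <- score_survey(part$retained, cohort$rubric, cohort$bank)

  marginal_targets <- list(
    age_group = cohort$config$age_k_targets,
    occupation_group = cohort$config$occupation_k_targets -
      sum(cohort$config$occupation_k_targets * cohort$config$occupation_distribution) +
      sum(cohort$config$age_k_targets * cohort$config$age_distribution)
  )
  subgroups <- NULL
  anova_res <- list()
  gt2_res <- list()
  for (dim in c("age_group", "occupation_group")) {
    sm <- subgroup_summary(scored$k, factor(scored[[dim]],
                                            levels = names(marginal_targets[[dim]])),
                           confidence = confidence)
    sm$target <- unname(marginal_targets[[dim]][sm$group_id])
    sm$abs_error <- abs(sm$k_mean - sm$target)
    sm$ci_covers <- sm$ci_low <= sm$target & sm$target <= sm$ci_high
    sm <- cbind(dimension = sub("_group$", "", dim), sm,
                stringsAsFactors = FALSE)
    subgroups <- rbind(subgroups, sm)
    anova_res[[dim]] <- one_way_anova(scored$k, scored[[dim]])
    gt2_res[[dim]] <- hochberg_gt2(scored$k, scored[[dim]], alpha = alpha)
  }
  cred <- credibility_analysis(part$retained, cohort$bank)
  planted <- cohort$config$belief_model$evidence_effect
  estimated <- cred$ratio_s - cred$ratio_x
  structure(list(
    subgroups = subgroups,
    anova = anova_res,
    gt2 = gt2_res,
    evidence = list(planted = planted, estimated = estimated,
                    bias = estimated - planted),
    credibility = cred,
    n_retained = nrow(part$retained)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Parameter recovery on", x$n_retained, "retained respondents\n")
  cat(sprintf("CI coverage of planted subgroup means: %d/%d\n",
              sum(x$subgroups$ci_covers), nrow(x$subgroups)))
  cat(sprintf("Evidence effect: planted %.3f, estimated %.3f (bias %+.4f)\n",
              x$evidence$planted, x$evidence$estimated, x$evidence$bias))
  invisible(x)
}
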