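# Shared fixtures: all built in code at test time.

minimal_answers <- function() {
  c(duration = "0-30 minutes", communication = "Low", information = "Low",
    covid_source = "Neither social media nor WhatsApp", trust = "0%",
    forwards = "0-2", fact_check = "75-100%",
    allopathic = "Never considered using", herbal = "Never considered using",
    ayurvedic = "Never considered using", homeopathic = "Never considered using",
    home = "Never considered using")
}

maximal_answers <- function() {
  c(duration = ">2 hours", communication = "High", information = "High",
    covid_source = "WhatsApp", trust = "100%", forwards = "More than 8",
    fact_check = "Never",
    allopathic = "Using regularly and recommending",
    herbal = "Using regularly and recommending",
    ayurvedic = "Using regularly and recommending",
    homeopathic = "Using regularly and recommending",
    home = "Using regularly and recommending")
}

# All-correct (or all-incorrect) judgments for a bank.
judgments_for <- function(bank, correct = TRUE) {
  truth_true <- bank$truth_label == "true"
  r <- if (correct) ifelse(truth_true, "maybe_true", "maybe_false")
       else ifelse(truth_true, "maybe_false", "maybe_true")
  stats::setNames(r, bank$message_id)
}

make_record <- function(bank, answers = minimal_answers(),
                        judgments = judgments_for(bank), id = "r1") {
  list(respondent_id = id, answers = answers, judgments = judgments)
}

# A wide survey data frame row (read_survey() schema) from record parts.
make_survey_df <- function(bank, n = 1, answers = minimal_answers(),
                           judgments = judgments_for(bank),
                           age_years = 30, occupation_label = "teacher",
                           is_hcw = FALSE, is_student = FALSE,
                           is_retired = FALSE, uses_whatsapp = TRUE,
                           resides_in_india = TRUE, gender = "woman") {
  base <- data.frame(
    respondent_id = sprintf("r%03d", seq_len(n)),
    uses_whatsapp = rep_len(uses_whatsapp, n),
    resides_in_india = rep_len(resides_in_india, n),
    age_years = rep_len(age_years, n),
    gender = rep_len(gender, n),
    occupation_label = rep_len(occupation_label, n),
    is_hcw = rep_len(is_hcw, n),
    is_student = rep_len(is_student, n),
    is_retired_or_unemployed = rep_len(is_retired, n),
    stringsAsFactors = FALSE
  )
  for (it in names(answers)) base[[paste0("answer_", it)]] <- answers[[it]]
  for (m in names(judgments)) base[[paste0("judgment_", m)]] <- judgments[[m]]
  base
}

# A reduced rubric (3 groups, <=3 options each, no derived group) small
# enough for exhaustive enumeration.
tiny_rubric_config <- function() {
  list(groups = list(
    A = list(items = list("a1"),
             options = list(low = 0L, mid = 1L, high = 2L)),
    B = list(items = list("b1", "b2"),
             options = list(no = 0L, yes = 3L)),
    C = list(items = list("c1"),
             options = list(x = 1L, y = 2L))
  ))
}

# Small fast simulation config for smoke tests: equal occupation mass on
# four groups so every represented subgroup has n >= 2.
small_sim_config <- function(seed = 1L, n = 240, violators = 6) {
  simulation_config(
    n_respondents = n, seed = seed,
    age_distribution = c(under_18 = 0, `19_25` = 0.4, `26_35` = 0.2,
                         `36_50` = 0.4, `51_65` = 0, over_65 = 0),
    occupation_distribution = c(HCW = 0.25, professionals = 0.25, managers = 0,
                                service_and_sales = 0, elementary = 0.25,
                                clerical = 0, students = 0.25,
                                retired_unemployed = 0),
    n_excluded_violators = violators
  )
}
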