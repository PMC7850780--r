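#' Load a scoring rubric
#'
#' A rubric encodes the survey scoring scheme as data: question groups, each
#' holding one or more individually scored items with categorical response
#' options mapped to non-negative integer scores. One group may instead be
#' *derived*: its score is obtained by binning the respondent's count of
#' incorrect message judgments. The maximum achievable total score
#' (`s_max`) is computed from the option scores, never declared.
#'
#' @param config Path to a YAML (or JSON) rubric file, or an already-parsed
#'   list with a top-level `groups` element.
#' @return An object of class `rubric`: a list with elements `groups` (the
#'   parsed group specs), `item_table` (data frame mapping scored answer
#'   items to their group), `option_scores` (named list, item id to named
#'   integer vector), `incorrect_bins` (data frame `label`, `max`, `score`
#'   for the derived group, or `NULL`), and `s_max`.
#' @examples
#' r <- load_rubric(misinfok_file("rubric_default.yaml"))
#' r$s_max  # 46
#' @export
load_rubric <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("rubric config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$groups) || !length(config$groups)) {
    stop("rubric config must contain a non-empty 'groups' mapping")
  }
  groups <- config$groups
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("every rubric group must be named (e.g. P1..P9)")
  }

  item_ids <- character(0)
  item_groups <- character(0)
  option_scores <- list()
  incorrect_bins <- NULL
  derived_group <- NULL

  for (gid in names(groups)) {
    g <- groups[[gid]]
    if (!is.null(g$derived_from)) {
      if (!identical(g$derived_from, "incorrect_count")) {
        stop("group ", gid, ": unsupported derived_from '", g$derived_from, "'")
      }
      if (!is.null(derived_group)) {
        stop("group ", gid, ": only one derived group is allowed (already have ",
             derived_group, ")")
      }
      bins <- g$bins
      if (is.null(bins) || !length(bins)) {
        stop("group ", gid, ": derived group must declare 'bins'")
      }
      bdf <- data.frame(
        label = vapply(bins, function(b) as.character(b$label), character(1)),
        max = vapply(bins, function(b) as.numeric(b$max), numeric(1)),
        score = vapply(bins, function(b) as.numeric(b$score), numeric(1)),
        stringsAsFactors = FALSE
      )
      if (anyDuplicated(bdf$label)) {
        stop("group ", gid, ": duplicate bin label")
      }
      if (any(bdf$score < 0) || any(bdf$score != round(bdf$score))) {
        stop("group ", gid, ": bin scores must be non-negative integers")
      }
      if (is.unsorted(bdf$max, strictly = TRUE)) {
        stop("group ", gid, ": bin upper bounds must be strictly increasing")
      }
      if (!is.infinite(bdf$max[nrow(bdf)])) {
        stop("group ", gid, ": last bin must be unbounded (max: .inf)")
      }
      incorrect_bins <- bdf
      derived_group <- gid
      next
    }
    items <- g$items
    opts <- g$options
    if (is.null(items) || !length(items)) {
      stop("group ", gid, ": missing 'items'")
    }
    if (is.null(opts) || !length(opts)) {
      stop("group ", gid, ": missing 'options'")
    }
    labs <- names(opts)
    if (is.null(labs) || any(!nzchar(labs))) {
      stop("group ", gid, ": every option needs a label")
    }
    if (anyDuplicated(labs)) {
      stop("group ", gid, ": duplicate option label '",
           labs[duplicated(labs)][1], "'")
    }
    sc <- suppressWarnings(as.numeric(unlist(opts)))
    if (anyNA(sc) || any(sc < 0) || any(sc != round(sc))) {
      stop("group ", gid, ": option scores must be non-negative integers")
    }
    items <- as.character(unlist(items))
    if (any(items %in% item_ids)) {
      stop("group ", gid, ": item id already used in another group: ",
           paste(intersect(items, item_ids), collapse = ", "))
    }
    for (it in items) {
      v <- as.integer(sc)
      names(v) <- labs
      option_scores[[it]] <- v
    }
    item_ids <- c(item_ids, items)
    item_groups <- c(item_groups, rep(gid, length(items)))
  }

  if (!length(item_ids)) stop("rubric has no scored answer items")

  s_max <- sum(vapply(option_scores, max, numeric(1))) +
    if (!is.null(incorrect_bins)) max(incorrect_bins$score) else 0

  structure(list(
    groups = groups,
    item_table = data.frame(item_id = item_ids, group_id = item_groups,
                            stringsAsFactors = FALSE),
    option_scores = option_scores,
    incorrect_bins = incorrect_bins,
    derived_group = derived_group,
    s_max = as.integer(s_max)
  ), class = "rubric")
}

#' @export
print.rubric <- function(x, ...) {
  cat("Scoring rubric:", length(x$groups), "question groups,",
      nrow(x$item_table), "scored answer items",
      if (!is.null(x$incorrect_bins)) "+ 1 derived item", "\n")
  cat("Maximum achievable score (s_max):", x$s_max, "\n")
  invisible(x)
}

#' Path to a packaged configuration or fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path to the file.
#' @export
misinfok_file <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "misinfoK")))
  }
  path <- system.file("extdata", file, package = "misinfoK")
  if (!nzchar(path)) stop("no packaged file named '", file, "'")
  path
}

#' Default rubric (s_max = 46)
#'
#' The nine-group scoring scheme with five remedy-action items, whose
#' maximum achievable total score is 46.
#' @return A `rubric` object.
#' @export
default_rubric <- function() {
  load_rubric(misinfok_file("rubric_default.yaml"))
}

#' Load a message bank
#'
#' A message bank declares, for each message judged by respondents, its
#' verified truth label and whether the message carried background evidence
#' (an attached link and/or named source).
#'
#' @param config Path to a YAML (or JSON) bank file, or a parsed list with a
#'   `messages` element; each message needs `message_id`,
#'   `truth_label` (`"true"`/`"false"`) and `evidence_flag`
#'   (`"has_link_or_source"`/`"none"`).
#' @return A data frame of class `message_bank` with columns `message_id`,
#'   `truth_label`, `evidence_flag`.
#' @export
load_message_bank <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("message bank file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  msgs <- config$messages
  if (is.null(msgs) || !length(msgs)) {
    stop("message bank must contain a non-empty 'messages' list")
  }
  bank <- data.frame(
    message_id = vapply(msgs, function(m) as.character(m$message_id), character(1)),
    truth_label = vapply(msgs, function(m) as.character(m$truth_label), character(1)),
    evidence_flag = vapply(msgs, function(m) as.character(m$evidence_flag), character(1)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(bank$message_id)) stop("duplicate message_id in bank")
  if (!all(bank$truth_label %in% c("true", "false"))) {
    stop("truth_label must be 'true' or 'false'")
  }
  if (!all(bank$evidence_flag %in% c("has_link_or_source", "none"))) {
    stop("evidence_flag must be 'has_link_or_source' or 'none'")
  }
  class(bank) <- c("message_bank", "data.frame")
  bank
}

#' Default message bank (10 messages, 8 false, 4/4 evidence split)
#' @return A `message_bank` data frame.
#' @export
default_message_bank <- function() {
  load_message_bank(misinfok_file("message_bank_default.yaml"))
}

#' Judgment rating levels
#'
#' The four-point veracity rating scale offered to respondents.
#' @return Character vector of the four admissible ratings.
#' @export
rating_levels <- function() {
  c("definitely_true", "maybe_true", "maybe_false", "definitely_false")
}

#' Count incorrect message judgments
#'
#' A judgment is incorrect when its polarity (definitely/maybe true counts as
#' "true"; definitely/maybe false counts as "false") disagrees with the
#' message's verified truth label.
#'
#' @param judgments Named character vector: `message_id` to rating, one per
#'   bank message.
#' @param bank A `message_bank`.
#' @return Integer count of incorrect judgments.
#' @examples
#' bank <- default_message_bank()
#' j <- setNames(ifelse(bank$truth_label == "true", "maybe_true", "maybe_false"),
#'               bank$message_id)
#' count_incorrect(j, bank)  # 0
#' @export
count_incorrect <- function(judgments, bank) {
  if (is.null(names(judgments))) stop("judgments must be named by message_id")
  unknown <- setdiff(names(judgments), bank$message_id)
  if (length(unknown)) {
    stop("rating for unknown message_id: ", paste(unknown, collapse = ", "))
  }
  missing <- setdiff(bank$message_id, names(judgments))
  if (length(missing)) {
    stop("missing rating for message: ", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(judgments), rating_levels())
  if (length(bad)) {
    stop("unknown rating level: ", paste(bad, collapse = ", "))
  }
  r <- judgments[bank$message_id]
  polarity <- ifelse(r %in% c("definitely_true", "maybe_true"), "true", "false")
  sum(polarity != bank$truth_label)
}

#' Bin an incorrect-judgment count into its rubric score
#'
#' @param count Integer count(s) of incorrect judgments.
#' @param rubric A `rubric` with a derived group.
#' @return Integer score(s) per the rubric's bins.
#' @export
bin_incorrect <- function(count, rubric) {
  bins <- rubric$incorrect_bins
  if (is.null(bins)) stop("rubric has no derived incorrect-count group")
  if (any(count < 0)) stop("incorrect count cannot be negative")
  idx <- findInterval(count, c(-Inf, bins$max), left.open = TRUE)
  as.integer(bins$score[idx])
}

#' Score one respondent
#'
#' Computes the summed rubric score `s_cal`, the vulnerability index
#' `k = s_cal / s_max`, and the incorrect-judgment count for a single
#' respondent record.
#'
#' @param record A single respondent as a list (or one-row data frame) with
#'   elements `respondent_id`, `answers` (named character vector or list:
#'   item id to option label) and `judgments` (named: message id to rating);
#'   optional `age_group` and `occupation_group` are carried through.
#' @param rubric A `rubric`.
#' @param bank A `message_bank` (required when the rubric has a derived
#'   incorrect-count group).
#' @return A list of class `scored_respondent`: `respondent_id`,
#'   `item_scores` (named integer vector), `s_cal`, `k`, `incorrect_count`,
#'   `age_group`, `occupation_group`.
#' @export
score_respondent <- function(record, rubric, bank = NULL) {
  if (is.data.frame(record)) record <- record_from_row(record, rubric, bank)
  answers <- unlist(record$answers)
  scores <- integer(0)
  for (it in rubric$item_table$item_id) {
    if (!it %in% names(answers) || is.na(answers[[it]]) || !nzchar(answers[[it]])) {
      stop("respondent ", record$respondent_id, ": unanswered scored item '",
           it, "'")
    }
    opt <- answers[[it]]
    tab <- rubric$option_scores[[it]]
    if (!opt %in% names(tab)) {
      stop("respondent ", record$respondent_id, ": option '", opt,
           "' for item '", it, "' is not in the rubric")
    }
    scores[it] <- tab[[opt]]
  }
  incorrect <- NA_integer_
  if (!is.null(rubric$incorrect_bins)) {
    if (is.null(bank)) stop("a message bank is required to score this rubric")
    incorrect <- count_incorrect(unlist(record$judgments), bank)
    scores[["incorrect"]] <- bin_incorrect(incorrect, rubric)
  }
  s_cal <- sum(scores)
  structure(list(
    respondent_id = record$respondent_id,
    item_scores = scores,
    s_cal = as.integer(s_cal),
    k = s_cal / rubric$s_max,
    incorrect_count = incorrect,
    age_group = record$age_group %||% NA_character_,
    occupation_group = record$occupation_group %||% NA_character_
  ), class = "scored_respondent")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert one row of a wide survey data frame (answer_*/judgment_* columns)
# into the record-list shape score_respondent() expects.
record_from_row <- function(row, rubric, bank) {
  stopifnot(nrow(row) == 1L)
  ans_cols <- grep("^answer_", names(row), value = TRUE)
  jdg_cols <- grep("^judgment_", names(row), value = TRUE)
  answers <- as.character(unlist(row[ans_cols]))
  names(answers) <- sub("^answer_", "", ans_cols)
  judgments <- as.character(unlist(row[jdg_cols]))
  names(judgments) <- sub("^judgment_", "", jdg_cols)
  list(
    respondent_id = row$respondent_id,
    answers = answers,
    judgments = judgments,
    age_group = if ("age_group" %in% names(row)) row$age_group
                else if ("age_years" %in% names(row)) as.character(assign_age_group(row$age_years))
                else NULL,
    occupation_group = if ("occupation_group" %in% names(row)) row$occupation_group else NULL
  )
}

#' Score a whole survey
#'
#' Vectorized scoring of validated survey records: one `ScoredRespondent`
#' row per input record, with demographic subgroup assignments attached.
#'
#' @param records Data frame of survey records (see [read_survey()]).
#' @param rubric A `rubric`.
#' @param bank A `message_bank`.
#' @return Data frame with columns `respondent_id`, one `score_<item>`
#'   column per scored item, `s_cal`, `k`, `incorrect_count`, `age_group`,
#'   `occupation_group`.
#' @export
score_survey <- function(records, rubric, bank) {
  n <- nrow(records)
  items <- rubric$item_table$item_id
  score_mat <- matrix(NA_integer_, nrow = n, ncol = length(items),
                      dimnames = list(NULL, items))
  for (it in items) {
    col <- paste0("answer_", it)
    if (!col %in% names(records)) {
      stop("survey is missing answers for scored item '", it, "'")
    }
    opt <- as.character(records[[col]])
    tab <- rubric$option_scores[[it]]
    bad <- which(is.na(opt) | !nzchar(opt))
    if (length(bad)) {
      stop("respondent ", records$respondent_id[bad[1]],
           ": unanswered scored item '", it, "'")
    }
    unknown <- which(!opt %in% names(tab))
    if (length(unknown)) {
      stop("respondent ", records$respondent_id[unknown[1]], ": option '",
           opt[unknown[1]], "' for item '", it, "' is not in the rubric")
    }
    score_mat[, it] <- tab[opt]
  }
  incorrect <- rep(NA_integer_, n)
  if (!is.null(rubric$incorrect_bins)) {
    jcols <- paste0("judgment_", bank$message_id)
    miss <- setdiff(jcols, names(records))
    if (length(miss)) {
      stop("survey is missing judgment columns: ", paste(miss, collapse = ", "))
    }
    wrong <- matrix(FALSE, nrow = n, ncol = nrow(bank))
    for (j in seq_len(nrow(bank))) {
      r <- as.character(records[[jcols[j]]])
      bad <- setdiff(unique(r), rating_levels())
      if (length(bad)) stop("unknown rating level: ", paste(bad, collapse = ", "))
      pol <- ifelse(r %in% c("definitely_true", "maybe_true"), "true", "false")
      wrong[, j] <- pol != bank$truth_label[j]
    }
    incorrect <- as.integer(rowSums(wrong))
    score_mat <- cbind(score_mat, incorrect = bin_incorrect(incorrect, rubric))
  }
  s_cal <- as.integer(rowSums(score_mat))
  age_group <- if ("age_group" %in% names(records)) records$age_group
               else as.character(assign_age_group(records$age_years))
  occ_group <- if ("occupation_group" %in% names(records)) records$occupation_group
               else assign_occupation_group(records$occupation_label,
                                            records$is_hcw, records$is_student,
                                            records$is_retired_or_unemployed)
  out <- data.frame(respondent_id = records$respondent_id,
                    stringsAsFactors = FALSE)
  colnames(score_mat) <- paste0("score_", colnames(score_mat))
  out <- cbind(out, as.data.frame(score_mat))
  out$s_cal <- s_cal
  out$k <- s_cal / rubric$s_max
  out$incorrect_count <- incorrect
  out$age_group <- age_group
  out$occupation_group <- occ_group
  out
}
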