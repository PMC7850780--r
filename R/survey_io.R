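#' Age subgroup labels
#' @return Character vector of the six age bins, youngest first.
#' @export
age_group_levels <- function() {
  c("under_18", "19_25", "26_35", "36_50", "51_65", "over_65")
}

#' Occupation subgroup labels
#' @return Character vector of the eight occupation groups.
#' @export
occupation_group_levels <- function() {
  c("HCW", "professionals", "managers", "service_and_sales",
    "elementary", "clerical", "students", "retired_unemployed")
}

#' Assign age subgroups
#'
#' Bins age in whole years into six contiguous groups: up to 18, 19-25,
#' 26-35, 36-50, 51-65, and 66 or older. The bins partition the
#' non-negative integers; age 18 falls in the youngest bin.
#'
#' @param age_years Integer vector of ages (years), all non-negative.
#' @return Factor with levels [age_group_levels()].
#' @export
assign_age_group <- function(age_years) {
  if (anyNA(age_years) || any(age_years < 0)) {
    stop("age_years must be non-negative and non-missing")
  }
  idx <- findInterval(age_years, c(0, 19, 26, 36, 51, 66))
  factor(age_group_levels()[idx], levels = age_group_levels())
}

# Packaged keyword table mapping free-text occupation labels to the four
# ISCO-derived working groups. Loaded once per session.
isco_lookup <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- utils::read.csv(misinfok_file("isco_keywords.csv"),
                              stringsAsFactors = FALSE)
    }
    tab
  }
})

#' Assign occupation subgroups
#'
#' Maps each respondent to one of eight occupation groups. Health-care
#' workers, students, and retired/unemployed respondents are flagged
#' explicitly and bypass the free-text mapping (HCW takes precedence over
#' everything). Working adults' free-text occupation labels are mapped to
#' ISCO-derived groups through a packaged keyword table; an unmappable label
#' is a hard error so silent misclassification cannot occur.
#'
#' @param occupation_label Character vector of free-text occupation labels.
#' @param is_hcw,is_student,is_retired_or_unemployed Logical flags (at most
#'   one may be `TRUE` per respondent).
#' @return Character vector drawn from [occupation_group_levels()].
#' @export
assign_occupation_group <- function(occupation_label, is_hcw, is_student,
                                    is_retired_or_unemployed) {
  n <- length(occupation_label)
  is_hcw <- rep_len(as.logical(is_hcw), n)
  is_student <- rep_len(as.logical(is_student), n)
  is_ret <- rep_len(as.logical(is_retired_or_unemployed), n)
  if (any(is_hcw + is_student + is_ret > 1L)) {
    stop("at most one of is_hcw/is_student/is_retired_or_unemployed may be set")
  }
  out <- rep(NA_character_, n)
  out[is_ret] <- "retired_unemployed"
  out[is_student] <- "students"
  out[is_hcw] <- "HCW"  # bypasses the free-text lookup
  todo <- which(is.na(out))
  if (length(todo)) {
    tab <- isco_lookup()
    lab <- tolower(trimws(occupation_label[todo]))
    for (i in seq_along(todo)) {
      hit <- match(lab[i], tab$keyword)
      if (is.na(hit)) {
        # fall back to word-boundary containment, first match wins
        m <- which(vapply(tab$keyword, function(k)
          grepl(paste0("\\b", k, "\\b"), lab[i]), logical(1)))
        hit <- if (length(m)) m[1] else NA_integer_
      }
      if (is.na(hit)) {
        stop("unmappable occupation label '", occupation_label[todo[i]],
             "' (no flag set and no keyword match)")
      }
      out[todo[i]] <- tab$occupation_group[hit]
    }
  }
  out
}

# Columns every survey file must provide, beyond answer_*/judgment_*.
mandatory_survey_columns <- function() {
  c("respondent_id", "uses_whatsapp", "resides_in_india", "age_years",
    "gender", "occupation_label", "is_hcw", "is_student",
    "is_retired_or_unemployed")
}

#' Read a survey response file
#'
#' Reads a delimited survey file (one row per respondent) into a validated
#' record data frame. Column order is irrelevant; values are whitespace
#' trimmed; columns outside the schema are dropped with a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param bank Optional `message_bank`; when supplied, the file must carry a
#'   `judgment_<message_id>` column per bank message.
#' @param sep Field separator (default comma).
#' @return Data frame of survey records with logical flag columns, integer
#'   `age_years`, and character answer/judgment columns.
#' @export
read_survey <- function(path, bank = NULL, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  names(raw) <- trimws(names(raw))
  known <- c(mandatory_survey_columns(),
             grep("^(answer|judgment)_", names(raw), value = TRUE))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    warning("ignoring unknown survey columns: ", paste(extra, collapse = ", "))
    raw <- raw[known]
  }
  miss <- setdiff(mandatory_survey_columns(), names(raw))
  if (length(miss)) {
    stop("survey file is missing mandatory columns: ",
         paste(miss, collapse = ", "))
  }
  rec <- raw
  rec[] <- lapply(rec, trimws)
  age <- suppressWarnings(as.integer(rec$age_years))
  bad <- which(is.na(age) & nzchar(rec$age_years) | !nzchar(rec$age_years))
  if (length(bad)) {
    stop("unparseable age_years '", rec$age_years[bad[1]], "' in data row ",
         bad[1])
  }
  rec$age_years <- age
  for (col in c("uses_whatsapp", "resides_in_india", "is_hcw", "is_student",
                "is_retired_or_unemployed")) {
    v <- tolower(rec[[col]])
    parsed <- ifelse(v %in% c("true", "yes", "1", "t"), TRUE,
                     ifelse(v %in% c("false", "no", "0", "f"), FALSE, NA))
    if (anyNA(parsed)) {
      stop("unparseable logical value '", rec[[col]][which(is.na(parsed))[1]],
           "' in column ", col, ", data row ", which(is.na(parsed))[1])
    }
    rec[[col]] <- parsed
  }
  if (anyDuplicated(rec$respondent_id)) stop("duplicate respondent_id")
  if (!is.null(bank)) {
    need <- paste0("judgment_", bank$message_id)
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop("survey file lacks judgment columns for bank messages: ",
           paste(miss, collapse = ", "))
    }
  }
  rec
}

#' Apply the cohort exclusion filters
#'
#' Partitions records into the analyzed cohort (WhatsApp users residing in
#' the study country) and excluded records, each tagged with the first
#' failing reason, checked in the fixed order `non_whatsapp_user`, then
#' `not_in_india`.
#'
#' @param records Data frame of validated survey records.
#' @return Object of class `cohort_partition`: list with `retained` (data
#'   frame) and `excluded` (data frame with an extra `exclusion_reason`
#'   column).
#' @export
apply_exclusions <- function(records) {
  keep <- records$uses_whatsapp & records$resides_in_india
  excluded <- records[!keep, , drop = FALSE]
  reason <- ifelse(!excluded$uses_whatsapp, "non_whatsapp_user", "not_in_india")
  excluded$exclusion_reason <- reason
  structure(list(retained = records[keep, , drop = FALSE],
                 excluded = excluded),
            class = "cohort_partition")
}

#' @export
print.cohort_partition <- function(x, ...) {
  cat("Cohort partition:", nrow(x$retained), "retained,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded)) print(table(x$excluded$exclusion_reason))
  invisible(x)
}

#' Write a cohort partition to disk
#'
#' Writes `retained.csv`, `excluded.csv` and a JSON exclusion log into a
#' directory.
#'
#' @param partition A `cohort_partition`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_partition <- function(partition, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("retained.csv", "excluded.csv", "exclusion_log.json"))
  utils::write.csv(partition$retained, paths[1], row.names = FALSE)
  utils::write.csv(partition$excluded, paths[2], row.names = FALSE)
  log <- list(
    n_input = nrow(partition$retained) + nrow(partition$excluded),
    n_retained = nrow(partition$retained),
    n_excluded = nrow(partition$excluded),
    reasons = as.list(table(partition$excluded$exclusion_reason))
  )
  jsonlite::write_json(log, paths[3], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
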