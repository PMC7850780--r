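# Message-credibility analysis: does background evidence (an attached link
# and/or named source) make a false message more likely to be judged true?
# The unit of analysis is the (respondent, message) instance, pooled across
# respondents, which replicates the original test and its known limitation
# (within-respondent correlation is ignored); a respondent-level cluster
# bootstrap is available as a sensitivity check.

#' Split false messages by background evidence
#'
#' @param bank A `message_bank`.
#' @return List with `with_evidence` and `without_evidence`: the message ids
#'   of the false messages in each stratum. True messages appear in neither.
#' @export
partition_false_messages <- function(bank) {
  false <- bank[bank$truth_label == "false", , drop = FALSE]
  list(
    with_evidence = false$message_id[false$evidence_flag == "has_link_or_source"],
    without_evidence = false$message_id[false$evidence_flag == "none"]
  )
}

#' Credibility analysis of false messages
#'
#' Counts, over all respondents, the (respondent, message) instances in
#' which a false message was marked `definitely_true` or `maybe_true`,
#' separately for false messages with background evidence (a_s of N_s
#' instances) and without (a_x of N_x), and compares the two marked-true
#' rates with a two-tailed two-proportion z-test.
#'
#' @param records Data frame of survey records carrying
#'   `judgment_<message_id>` columns for every bank message.
#' @param bank A `message_bank`.
#' @param pooled Use the pooled-variance z statistic (default TRUE).
#' @param cluster_bootstrap Number of respondent-level bootstrap resamples
#'   for a sensitivity interval on the rate difference (0 = off, the
#'   default).
#' @return Object of class `credibility_result`: list with `n_s`, `n_x`,
#'   `a_s`, `a_x`, `ratio_s`, `ratio_x`, `ratio_of_ratios` (NA, flagged,
#'   when `ratio_x` is 0), `ztest` (a `ztest_result`), `per_message` (data
#'   frame of marked-true rates per false message), and optionally
#'   `bootstrap_ci` for the rate difference.
#' @export
credibility_analysis <- function(records, bank, pooled = TRUE,
                                 cluster_bootstrap = 0) {
  parts <- partition_false_messages(bank)
  false_ids <- c(parts$with_evidence, parts$without_evidence)
  jcols <- paste0("judgment_", false_ids)
  miss <- setdiff(jcols, names(records))
  if (length(miss)) {
    stop("records lack judgment columns: ", paste(miss, collapse = ", "))
  }
  n <- nrow(records)
  marked_true <- vapply(jcols, function(cl) {
    r <- as.character(records[[cl]])
    bad <- setdiff(unique(r), rating_levels())
    if (length(bad)) stop("unknown rating level: ", paste(bad, collapse = ", "))
    r %in% c("definitely_true", "maybe_true")
  }, logical(n))
  if (n == 1L) marked_true <- matrix(marked_true, nrow = 1,
                                     dimnames = list(NULL, jcols))
  colnames(marked_true) <- false_ids
  s_ids <- parts$with_evidence
  x_ids <- parts$without_evidence
  a_s <- sum(marked_true[, s_ids, drop = FALSE])
  a_x <- sum(marked_true[, x_ids, drop = FALSE])
  n_s <- n * length(s_ids)
  n_x <- n * length(x_ids)
  ratio_s <- if (n_s > 0) a_s / n_s else NA_real_
  ratio_x <- if (n_x > 0) a_x / n_x else NA_real_
  rr <- if (isTRUE(ratio_x > 0)) ratio_s / ratio_x else NA_real_
  zt <- if (n_s > 0 && n_x > 0) {
    two_prop_ztest(a_s, n_s, a_x, n_x, pooled = pooled)
  } else NULL
  per_message <- data.frame(
    message_id = false_ids,
    evidence = rep(c("has_link_or_source", "none"),
                   c(length(s_ids), length(x_ids))),
    n_marked_true = colSums(marked_true),
    rate_marked_true = colSums(marked_true) / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  boot_ci <- NULL
  if (cluster_bootstrap > 0) {
    diffs <- vapply(seq_len(cluster_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      mt <- marked_true[idx, , drop = FALSE]
      sum(mt[, s_ids, drop = FALSE]) / n_s - sum(mt[, x_ids, drop = FALSE]) / n_x
    }, numeric(1))
    boot_ci <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
  }
  structure(list(n_s = n_s, n_x = n_x, a_s = a_s, a_x = a_x,
                 ratio_s = ratio_s, ratio_x = ratio_x,
                 ratio_of_ratios = rr, ratio_of_ratios_defined = isTRUE(ratio_x > 0),
                 ztest = zt, per_message = per_message,
                 bootstrap_ci = boot_ci),
            class = "credibility_result")
}

#' @export
print.credibility_result <- function(x, ...) {
  cat(sprintf("False-message credibility: a_s/N_s = %d/%d = %.3f, a_x/N_x = %d/%d = %.3f\n",
              x$a_s, x$n_s, x$ratio_s, x$a_x, x$n_x, x$ratio_x))
  if (x$ratio_of_ratios_defined) {
    cat(sprintf("Evidence raises the marked-true rate %.1f-fold\n",
                x$ratio_of_ratios))
  } else {
    cat("Ratio of ratios undefined (no instances marked true without evidence)\n")
  }
  if (!is.null(x$ztest)) print(x$ztest)
  invisible(x)
}
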