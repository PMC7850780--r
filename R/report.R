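# End-to-end orchestration: score -> stratify -> infer -> credibility, over
# a survey file or a simulation config, emitting publication-shaped CSV
# tables, a machine-readable JSON report, and a run log.

#' Format a count as a percentage
#'
#' `100 * count / total`, rounded half-up to two decimals (publication
#' style; full precision belongs in the JSON report).
#'
#' @param count Numerator count(s), each in `[0, total]`.
#' @param total Positive denominator.
#' @return Numeric percentage(s) with two-decimal resolution.
#' @examples
#' format_percent(648, 1137)  # 56.99
#' @export
format_percent <- function(count, total) {
  if (length(total) != 1 || total <= 0) stop("total must be a single positive count")
  if (any(count < 0) || any(count > total)) stop("count must lie in [0, total]")
  pct <- 100 * count / total
  floor(pct * 100 + 0.5) / 100
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

count_table <- function(values, levels, total) {
  n <- vapply(levels, function(l) sum(values == l), integer(1))
  data.frame(level = levels, n = unname(n),
             pct = format_percent(unname(n), total),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole analysis over either a survey CSV or a simulation
#' configuration: cohort exclusions, rubric scoring, demographic and
#' usage-pattern tables, subgroup mean-K series with confidence intervals,
#' variance-homogeneity screen, one-way ANOVA with Hochberg GT2 post hoc
#' matrices for age and occupation, and the false-message credibility
#' analysis. All artifacts are written into `out_dir`; any stage error
#' propagates with the stage name and no partial bundle is left behind.
#'
#' @param input Path to a survey CSV, or a [simulation_config()].
#' @param out_dir Output directory for the report bundle.
#' @param rubric Scoring rubric (default [default_rubric()]).
#' @param bank Message bank (default [default_message_bank()]).
#' @param alpha Significance level for post hoc comparisons.
#' @param confidence Confidence level for subgroup intervals.
#' @param seed Optional integer; overrides the simulation config seed and is
#'   recorded in the log.
#' @param verbose Print progress messages.
#' @return Invisibly, the full report as a list (the content of
#'   `report.json`).
#' @export
run_pipeline <- function(input, out_dir, rubric = default_rubric(),
                         bank = default_message_bank(), alpha = 0.05,
                         confidence = 0.95, seed = NULL, verbose = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  say <- function(...) if (verbose) message(...)

  records <- with_stage("input", {
    if (inherits(input, "simulation_config")) {
      if (!is.null(seed)) input$seed <- as.integer(seed)
      generate_cohort(input, rubric = rubric, bank = bank)$records
    } else if (is.character(input) && length(input) == 1) {
      read_survey(input, bank = bank)
    } else {
      stop("input must be a survey CSV path or a simulation_config")
    }
  })
  say("read ", nrow(records), " records")

  part <- with_stage("exclusions", apply_exclusions(records))
  retained <- part$retained
  N <- nrow(retained)
  if (N < 2) stop("pipeline stage 'exclusions': fewer than 2 retained records")
  say(N, " retained, ", nrow(part$excluded), " excluded")

  scored <- with_stage("scoring", score_survey(retained, rubric, bank))

  demographics <- with_stage("demographics", {
    rbind(
      cbind(variable = "age_group",
            count_table(scored$age_group, age_group_levels(), N)),
      cbind(variable = "gender",
            count_table(retained$gender, sort(unique(retained$gender)), N)),
      cbind(variable = "occupation_group",
            count_table(scored$occupation_group, occupation_group_levels(), N))
    )
  })

  usage <- with_stage("usage_patterns", {
    out <- NULL
    for (it in rubric$item_table$item_id) {
      opts <- names(rubric$option_scores[[it]])
      tab <- count_table(retained[[paste0("answer_", it)]], opts, N)
      out <- rbind(out, cbind(item_id = it, tab))
    }
    out
  })

  kmean <- list()
  anova_res <- list()
  gt2 <- list()
  fmax <- list()
  for (dim in c("age_group", "occupation_group")) {
    key <- sub("_group$", "", dim)
    lv <- if (dim == "age_group") age_group_levels() else occupation_group_levels()
    gfac <- factor(scored[[dim]], levels = lv)
    kmean[[key]] <- with_stage(paste0("subgroup_summary_", key),
                               subgroup_summary(scored$k, gfac,
                                                confidence = confidence))
    fmax[[key]] <- with_stage(paste0("hartley_fmax_", key),
                              hartley_fmax(scored$k, gfac, seed = 1L))
    anova_res[[key]] <- with_stage(paste0("anova_", key),
                                   one_way_anova(scored$k, gfac))
    gt2[[key]] <- with_stage(paste0("gt2_", key),
                             hochberg_gt2(scored$k, gfac, alpha = alpha))
  }

  cred <- with_stage("credibility", credibility_analysis(retained, bank))

  report <- list(
    n_input = nrow(records),
    n_retained = N,
    n_excluded = nrow(part$excluded),
    exclusion_reasons = as.list(table(part$excluded$exclusion_reason)),
    s_max = rubric$s_max,
    alpha = alpha,
    confidence = confidence,
    demographics = demographics,
    usage_patterns = usage,
    k_mean = kmean,
    hartley_fmax = lapply(fmax, function(h)
      list(f_max = h$f_max, p_value = h$p_value, degenerate = h$degenerate)),
    anova = lapply(anova_res, function(a)
      a[c("f_stat", "df_between", "df_within", "p_value", "mse")]),
    posthoc = lapply(gt2, function(p) p$pairs),
    credibility = list(
      n_s = cred$n_s, n_x = cred$n_x, a_s = cred$a_s, a_x = cred$a_x,
      ratio_s = cred$ratio_s, ratio_x = cred$ratio_x,
      ratio_of_ratios = cred$ratio_of_ratios,
      z = cred$ztest$z, p_value = cred$ztest$p_value
    ),
    per_message_rates = cred$per_message,
    seed = if (inherits(input, "simulation_config")) input$seed else seed
  )

  written <- character(0)
  with_stage("write_bundle", {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    emit <- function(name, writer) {
      path <- file.path(out_dir, name)
      writer(path)
      written <<- c(written, path)
    }
    tryCatch({
      emit("demographic_table.csv", function(p)
        utils::write.csv(demographics, p, row.names = FALSE))
      emit("usage_patterns.csv", function(p)
        utils::write.csv(usage, p, row.names = FALSE))
      emit("kmean_age.csv", function(p)
        utils::write.csv(kmean$age, p, row.names = FALSE))
      emit("kmean_occupation.csv", function(p)
        utils::write.csv(kmean$occupation, p, row.names = FALSE))
      emit("posthoc_age.csv", function(p)
        utils::write.csv(posthoc_matrix(gt2$age, digits = 3), p))
      emit("posthoc_occupation.csv", function(p)
        utils::write.csv(posthoc_matrix(gt2$occupation, digits = 3), p))
      emit("credibility.csv", function(p)
        utils::write.csv(cred$per_message, p, row.names = FALSE))
      emit("report.json", function(p)
        jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows", pretty = TRUE))
      emit("run_log.txt", function(p) {
        cfg <- tempfile()
        on.exit(unlink(cfg))
        jsonlite::write_json(list(alpha = alpha, confidence = confidence,
                                  seed = report$seed, s_max = rubric$s_max),
                             cfg, auto_unbox = TRUE, digits = NA)
        writeLines(c(
          paste("misinfoK", as.character(utils::packageVersion("misinfoK"))),
          paste("R", paste(R.version$major, R.version$minor, sep = ".")),
          paste("timestamp", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
          paste("seed", report$seed %||% "none"),
          paste("config_hash", unname(tools::md5sum(cfg))),
          paste("n_input", report$n_input),
          paste("n_retained", report$n_retained)
        ), p)
      })
    }, error = function(e) {
      file.remove(written[file.exists(written)])
      stop(conditionMessage(e), call. = FALSE)
    })
  })
  say("bundle written to ", out_dir)
  invisible(report)
}
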