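# End-to-end analysis pipeline: configuration, stage seeding, logging, and
# the `run_analysis()` driver that chains every stage into one report
# bundle with a checksummed manifest.

#' Analysis configuration
#'
#' Bundles everything one full pipeline run needs: a corpus source (a file
#' path, an in-memory corpus, or a [generator_config()] to synthesize one),
#' the comparisons to run, and the per-stage parameters.
#'
#' @param corpus a `chat_corpus`, a path to a corpus file, or `NULL` to
#'   generate one from `generator`.
#' @param generator a [generator_config()] used when `corpus` is `NULL`.
#' @param seed master seed; per-stage child seeds are derived by stable
#'   hashing of stage names, so adding a stage never perturbs the others.
#' @param comparisons named list of `c(treated_group, control_group)`
#'   pairs.
#' @param emotions emotions to analyse.
#' @param threshold,window trajectory eligibility rule.
#' @param caliper logit matching caliper.
#' @param grid_points trajectory grid resolution.
#' @param min_freq phrase table minimum frequency.
#' @param min_messages_baseline per-user message filter for baselines.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(corpus = NULL,
                            generator = generator_config(),
                            seed = 1L,
                            comparisons = list(
                              passive_vs_none = c("passive_si", "non_exposed_non_si"),
                              exposed_vs_nonexposed = c("exposed_non_si", "non_exposed_non_si")),
                            emotions = EMOTIONS,
                            threshold = 5, window = 3, caliper = 0.01,
                            grid_points = 101, min_freq = 2,
                            min_messages_baseline = 5) {
  structure(list(corpus = corpus, generator = generator,
                 seed = as.integer(seed), comparisons = comparisons,
                 emotions = emotions, threshold = threshold, window = window,
                 caliper = caliper, grid_points = grid_points,
                 min_freq = min_freq,
                 min_messages_baseline = min_messages_baseline),
            class = "analysis_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       na = "null", pretty = TRUE)
  path
}

curve_frame <- function(curve) {
  data.frame(progression = curve$grid, mean = curve$values,
             sd = curve$sd, n = curve$n)
}

#' Run the full analysis pipeline
#'
#' Executes every stage against one corpus and writes a report bundle to
#' `out_dir`: detection report (confusion counts, metrics, flag latencies,
#' referral timeliness, prevalence), demographic tables, per-group
#' aggregate trajectory CSVs, matched-comparison results (balance,
#' percent changes, Mann-Whitney baselines, ANCOVA interactions), phrase
#' tables, and a manifest recording the seed, config hash and md5 checksum
#' of every output. Identical config + seed produces byte-identical
#' outputs. A failing stage aborts with the stage name; stages already
#' written remain on disk and the manifest is marked partial only if the
#' run is resumed manually.
#'
#' @param config an [analysis_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the in-memory results and the manifest.
#' @export
run_analysis <- function(config, out_dir) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- corpus ---------------------------------------------------------------
  corpus <- run_stage("corpus", {
    if (inherits(config$corpus, "chat_corpus")) {
      config$corpus
    } else if (is.character(config$corpus)) {
      stage_log("corpus", "reading %s", config$corpus)
      read_corpus(config$corpus)
    } else {
      gen <- config$generator
      gen$seed <- stable_seed(config$seed, "generate")
      stage_log("corpus", "generating %d sessions (seed %d)",
                gen$n_sessions, gen$seed)
      generate_corpus(gen)
    }
  })
  stage_log("corpus", "%d sessions, %d visits, %d messages in",
            nrow(corpus$sessions), nrow(corpus$visits), nrow(corpus$messages))

  # --- detection ------------------------------------------------------------
  results$detection <- run_stage("detection", {
    cc <- confusion_counts(corpus)
    dm <- detection_metrics(cc)
    lat_a <- flag_latency_stats(corpus, "active")
    lat_p <- flag_latency_stats(corpus, "passive")
    ref <- referral_latency_stats(corpus)
    prev <- prevalence_summary(corpus)
    stage_log("detection", "confusion %d/%d/%d/%d; %d active latency pairs in",
              cc$tp, cc$fp, cc$fn, cc$tn, lat_a$n)
    list(confusion = cc[c("tp", "fp", "fn", "tn", "n")],
         metrics = list(fraction = as.list(dm$fraction),
                        percent = as.list(dm$percent)),
         latency = list(
           active = lat_a[c("n", "mean", "sd", "p_ai_first")],
           passive = lat_p[c("n", "mean", "sd", "p_ai_first")]),
         referral = ref[c("n", "mean", "sd")],
         prevalence = list(
           n_sessions = prev$n_sessions, n_visits = prev$n_visits,
           counts = as.list(prev$counts),
           visit_rate = as.list(prev$visit_rate),
           session_rate = as.list(prev$session_rate),
           exposure_rate = prev$exposure_rate,
           ratio = prev$ratio, ratio_label = prev$ratio_label))
  })
  write_json_report(results$detection, file.path(out_dir, "detection.json"))
  prev <- prevalence_summary(corpus)
  utils::write.csv(prev$monthly, file.path(out_dir, "prevalence_monthly.csv"),
                   row.names = FALSE)

  # --- demographics ---------------------------------------------------------
  results$demographics <- run_stage("demographics", {
    summarize_demographics(corpus$visits, by_group = TRUE)
  })
  write_json_report(results$demographics, file.path(out_dir, "demographics.json"))

  # --- trajectories ---------------------------------------------------------
  run_stage("trajectories", {
    groups <- setdiff(VISIT_GROUPS, "active_si")
    rows_in <- 0L
    for (emo in config$emotions) {
      for (g in groups) {
        cv <- group_trajectory(corpus, emo, g, config$threshold,
                               config$window, config$grid_points)
        if (is.null(cv)) next
        rows_in <- rows_in + cv$n
        utils::write.csv(curve_frame(cv),
                         file.path(out_dir, sprintf("trajectory_%s_%s.csv", emo, g)),
                         row.names = FALSE)
      }
    }
    stage_log("trajectories", "%d eligible visit-curves aggregated", rows_in)
  })

  # --- comparisons ----------------------------------------------------------
  results$comparisons <- run_stage("comparisons", {
    out <- list()
    for (nm in names(config$comparisons)) {
      pair <- config$comparisons[[nm]]
      for (emo in config$emotions) {
        with_seed(stable_seed(config$seed, paste("match", nm, emo)), {
          tc <- tryCatch(
            trajectory_comparison(corpus, emo, pair[1], pair[2],
                                  threshold = config$threshold,
                                  window = config$window,
                                  grid_points = config$grid_points,
                                  caliper = config$caliper),
            error = function(e) e)
        })
        if (inherits(tc, "error")) {
          stage_log("comparisons", "%s/%s skipped: %s", nm, emo,
                    conditionMessage(tc))
          next
        }
        stage_log("comparisons", "%s/%s: %d pairs, interaction p = %.3g",
                  nm, emo, nrow(tc$match$pairs), tc$ancova$p_value)
        bl <- baseline_comparison(corpus, emo, groups = pair,
                                  min_messages = config$min_messages_baseline)
        out[[paste(nm, emo, sep = ".")]] <- list(
          comparison = nm, emotion = emo,
          n_treated = tc$n_treated, n_control = tc$n_control,
          excluded = length(tc$match$excluded),
          balance = tc$balance,
          percent_change = as.list(tc$percent_change),
          baseline = list(table = bl$table, p = bl$test$p_value),
          ancova = list(interaction = tc$ancova$interaction,
                        t = tc$ancova$t, p = tc$ancova$p_value,
                        slopes = as.list(tc$ancova$slopes)))
      }
    }
    out
  })
  write_json_report(results$comparisons, file.path(out_dir, "comparisons.json"))

  # --- phrases --------------------------------------------------------------
  results$phrases <- run_stage("phrases", {
    out <- list()
    for (cl in c("passive", "active")) {
      tb <- phrase_frequency_table(corpus, cl, min_freq = config$min_freq)
      utils::write.csv(as.data.frame(tb),
                       file.path(out_dir, sprintf("phrases_%s.csv", cl)),
                       row.names = FALSE)
      stage_log("phrases", "%s: %d phrases with frequency >= %d",
                cl, nrow(tb), config$min_freq)
      out[[cl]] <- utils::head(as.data.frame(tb), 20)
    }
    out
  })

  # --- manifest -------------------------------------------------------------
  cfg_file <- tempfile(fileext = ".json")
  cfg_for_hash <- config
  cfg_for_hash$corpus <- if (is.character(config$corpus)) config$corpus else
    if (is.null(config$corpus)) "generated" else "in-memory"
  jsonlite::write_json(
    cfg_for_hash[setdiff(names(cfg_for_hash), "generator")],
    cfg_file, auto_unbox = TRUE, force = TRUE, digits = 10)
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  unlink(cfg_file)
  write_json_report(manifest, file.path(out_dir, "manifest.json"))
  stage_log("manifest", "%d outputs checksummed", length(files))
  invisible(list(corpus = corpus, results = results, manifest = manifest))
}
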