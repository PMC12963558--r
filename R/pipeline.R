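#' Pipeline configuration
#'
#' The pipeline is driven by one YAML file with sections mirroring the
#' stages: `simulate` (generator), `preprocess` (filter/blink/epoch/
#' threshold), `neurometrics` (GFP mode, AW scale), `questionnaire`
#' (screening alpha, composite method), `stats` (ANOVA alpha, Duncan error
#' term), plus top-level `seed` and `output_dir`. Unknown keys are rejected;
#' every parameter has a default (see [default_pipeline_config()]); the seed
#' is mandatory.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @export
default_pipeline_config <- function() {
  list(
    seed = NULL,
    output_dir = "eegmetrics-out",
    simulate = list(n_expert = 11, n_student = 10, fs = 256,
                    task_duration = 300, rest_duration = 60,
                    spike_rate = 0.5, rest_alpha_boost = 2,
                    format = "csv"),
    preprocess = list(low = 2, high = 30, order = 5, epoch_length = 1,
                      threshold_uv = 80, blink_mode = "correct"),
    neurometrics = list(gfp_mode = "subset-mean", aw_scale = "power"),
    questionnaire = list(alpha = 0.001, method = "mean"),
    stats = list(alpha = 0.05, duncan_error = "pooled")
  )
}

validate_pipeline_config <- function(cfg) {
  def <- default_pipeline_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (sec in setdiff(names(def), c("seed", "output_dir"))) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), names(def[[sec]]))
      if (length(bad)) {
        stop("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
      }
      def[[sec]][names(cfg[[sec]])] <- cfg[[sec]]
    }
  }
  def$seed <- cfg$seed
  if (!is.null(cfg$output_dir)) def$output_dir <- cfg$output_dir
  if (is.null(def$seed)) stop("config error: a seed is required")
  def
}

config_checksum <- function(cfg) {
  cfg$output_dir <- NULL          # hash the configuration, not its location
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(dir, cfg, stage, warnings = character()) {
  files <- sort(list.files(dir, full.names = TRUE, recursive = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("eegmetrics")),
    seed = cfg$seed,
    config_checksum = config_checksum(cfg),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))),
    warnings = warnings
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Simulate a study to disk
#'
#' Generates the synthetic study defined by the config's `simulate` section
#' and writes it (recordings, rest segments, questionnaire, ground truth)
#' plus a run manifest with per-file checksums into
#' `<output_dir>/study`. Identical config and seed give identical checksums.
#'
#' @param config a validated pipeline config (see [read_pipeline_config()]).
#' @return the study directory, invisibly.
#' @export
run_simulate <- function(config) {
  config <- validate_pipeline_config(config)
  sim <- config$simulate
  sc <- study_config(n_expert = sim$n_expert, n_student = sim$n_student,
                     fs = sim$fs, task_duration = sim$task_duration,
                     rest_duration = sim$rest_duration,
                     spike_rate = sim$spike_rate,
                     rest_alpha_boost = sim$rest_alpha_boost,
                     seed = config$seed)
  study <- generate_study(sc)
  dir <- file.path(config$output_dir, "study")
  write_study(study, dir, format = sim$format)
  write_manifest(dir, config, "simulate")
  invisible(dir)
}

#' Read a study back from disk
#'
#' @param dir a directory written by [run_simulate()]/[write_study()].
#' @param montage the [channel_montage()] the files follow.
#' @return an `eeg_study`-compatible list.
#' @export
read_study <- function(dir, montage = channel_montage()) {
  prof_path <- file.path(dir, "profiles.csv")
  if (!file.exists(prof_path)) {
    stop("study directory lacks profiles.csv (run the simulate stage first)")
  }
  profiles <- utils::read.csv(prof_path, stringsAsFactors = FALSE)
  class(profiles) <- c("subject_profiles", "data.frame")
  q_path <- file.path(dir, "questionnaire.csv")
  questionnaire <- if (file.exists(q_path)) {
    likert_table(utils::read.csv(q_path, stringsAsFactors = FALSE))
  }
  recordings <- list()
  rest <- list()
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    for (cond in study_conditions) {
      base <- file.path(dir, paste0("task_", p$subject_id, ".", cond))
      path <- if (file.exists(paste0(base, ".csv"))) paste0(base, ".csv")
              else paste0(base, ".edf")
      if (!file.exists(path)) {
        stop("missing task recording for ", p$subject_id, "/", cond,
             " (simulate stage incomplete)")
      }
      recordings[[paste(p$subject_id, cond, sep = ".")]] <-
        read_recording(path, montage = montage, subject_id = p$subject_id,
                       group = p$group, condition = cond)
    }
    base <- file.path(dir, paste0("rest_", p$subject_id))
    path <- if (file.exists(paste0(base, ".csv"))) paste0(base, ".csv")
            else paste0(base, ".edf")
    if (!file.exists(path)) stop("missing rest segment for ", p$subject_id)
    rest[[p$subject_id]] <- read_recording(path, montage = montage,
                                           subject_id = p$subject_id,
                                           group = p$group, kind = "rest")
  }
  gt_path <- file.path(dir, "ground_truth.csv")
  structure(list(profiles = profiles, recordings = recordings, rest = rest,
                 questionnaire = questionnaire,
                 ground_truth = if (file.exists(gt_path))
                   utils::read.csv(gt_path)),
            class = "eeg_study")
}

#' Analyse a study in memory
#'
#' Runs the complete analysis chain on an `eeg_study`: preprocessing and
#' neurometrics per subject x condition, questionnaire screening and
#' composites, and the four 2x2 mixed ANOVAs (work-performance composite,
#' willingness composite, workload, acceptance) with Duncan post-hocs where
#' an effect is significant.
#'
#' @param study an `eeg_study` ([generate_study()] or [read_study()]).
#' @param config a validated pipeline config.
#' @return object of class `eeg_analysis`: `metrics` (neurometric records),
#'   `composites`, `merges` (screening reports), `anovas` (named list of
#'   [mixed_anova()] fits), `duncans`, `warnings`.
#' @export
analyze_study <- function(study, config = NULL) {
  if (is.null(config)) {
    config <- default_pipeline_config()
    config$seed <- 0L
  }
  pp <- config$preprocess; nm <- config$neurometrics
  qn <- config$questionnaire; st <- config$stats
  warn <- character()
  metrics <- withCallingHandlers(
    aggregate_study(study, low = pp$low, high = pp$high, order = pp$order,
                    blink_mode = pp$blink_mode,
                    threshold = pp$threshold_uv,
                    gfp_mode = nm$gfp_mode, aw_scale = nm$aw_scale),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  low_clean <- metrics$n_clean_epochs < 0.5 * max(metrics$n_clean_epochs)
  if (any(low_clean)) {
    warn <- c(warn, paste0("fewer than 50% clean epochs for: ",
                           paste(unique(metrics$subject_id[low_clean]),
                                 collapse = ", ")))
  }
  composites <- list(); merges <- list()
  if (!is.null(study$questionnaire)) {
    specs <- if (!is.null(study$config$composites)) study$config$composites
             else default_composites()
    cm <- correlation_matrix(study$questionnaire)
    for (cs in specs) {
      merges[[cs$name]] <- validate_merge(cm, cs, alpha = qn$alpha)
      if (!merges[[cs$name]]$approved) {
        warn <- c(warn, paste0("composite '", cs$name,
                               "' failed correlation screening; built with ",
                               "forced override"))
      }
      composites[[cs$name]] <- suppressWarnings(
        build_composite(study$questionnaire, cs, method = qn$method,
                        validation = merges[[cs$name]], force = TRUE))
    }
  }
  outcomes <- list()
  for (nm_c in names(composites)) {
    dd <- composites[[nm_c]]
    names(dd)[names(dd) == "composite"] <- "value"
    outcomes[[nm_c]] <- dd
  }
  wl <- metrics[, c("subject_id", "group", "condition", "wl")]
  names(wl)[4] <- "value"
  aw <- metrics[, c("subject_id", "group", "condition", "aw")]
  names(aw)[4] <- "value"
  outcomes$workload <- wl
  outcomes$acceptance <- aw
  anovas <- list(); duncans <- list()
  for (nm_o in names(outcomes)) {
    keep <- stats::ave(seq_len(nrow(outcomes[[nm_o]])),
                       outcomes[[nm_o]]$subject_id,
                       FUN = length) == 2
    fit <- mixed_anova(outcomes[[nm_o]][keep, ], value = "value",
                       subject = "subject_id", group = "group",
                       condition = "condition")
    anovas[[nm_o]] <- fit
    if (any(fit$table$p < st$alpha, na.rm = TRUE)) {
      duncans[[nm_o]] <- duncan(fit, alpha = st$alpha,
                                error = st$duncan_error)
    }
  }
  structure(list(metrics = metrics, composites = composites,
                 merges = merges, anovas = anovas, duncans = duncans,
                 warnings = warn, config = config),
            class = "eeg_analysis")
}

#' @export
print.eeg_analysis <- function(x, ...) {
  cat("Study analysis:", nrow(x$metrics), "neurometric records,",
      length(x$anovas), "outcomes\n\n")
  for (nm in names(x$anovas)) {
    cat("==", nm, "==\n")
    print(x$anovas[[nm]])
    cat("\n")
  }
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Run the analysis stage on an on-disk study
#'
#' Reads the study written by [run_simulate()], analyses it, and writes
#' `neurometrics.csv`, `composites.csv`, one ANOVA table CSV per outcome
#' (columns in the order source, sum of squares, df, mean square, F, p,
#' eta2 classical, eta2 partial), a plain-text `report.txt`, and a manifest.
#'
#' @param config validated pipeline config.
#' @param study_dir study directory; defaults to `<output_dir>/study`.
#' @return the [analyze_study()] result, invisibly.
#' @export
run_analysis <- function(config, study_dir = NULL) {
  config <- validate_pipeline_config(config)
  if (is.null(study_dir)) study_dir <- file.path(config$output_dir, "study")
  study <- read_study(study_dir)
  res <- analyze_study(study, config)
  out <- file.path(config$output_dir, "results")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$metrics, file.path(out, "neurometrics.csv"),
                   row.names = FALSE)
  if (length(res$composites)) {
    utils::write.csv(do.call(rbind, res$composites),
                     file.path(out, "composites.csv"), row.names = FALSE)
  }
  for (nm in names(res$anovas)) {
    tab <- res$anovas[[nm]]$table
    out_tab <- data.frame(
      Source = tab$source, Sum.of.squares = tab$ss, df = tab$df,
      Mean.square = tab$ms, F = tab$F, p = tab$p,
      eta2_classical = tab$eta_classical, eta2_partial = tab$eta_partial)
    utils::write.csv(out_tab, file.path(out, paste0("anova_", nm, ".csv")),
                     row.names = FALSE)
  }
  writeLines(render_report(res), file.path(out, "report.txt"))
  write_manifest(out, config, "analysis", res$warnings)
  invisible(res)
}

render_report <- function(res) {
  lines <- c("eegmetrics analysis report", "==========================", "")
  for (nm in names(res$anovas)) {
    fit <- res$anovas[[nm]]
    tab <- fit$table
    lines <- c(lines, paste0("Outcome: ", nm))
    for (i in which(!grepl("Residuals", tab$source))) {
      lines <- c(lines, sprintf(
        "  %-28s F(%d,%d) = %.3f, p %s, eta2 = %.3f (partial %.3f)%s",
        tab$source[i], tab$df[i],
        tab$df[ifelse(tab$stratum[i] == "within", 3, 5)],
        tab$F[i],
        ifelse(tab$p[i] < 0.001, "< .001",
               sprintf("= %.3f", tab$p[i])),
        tab$eta_classical[i], tab$eta_partial[i],
        ifelse(tab$p[i] < res$config$stats$alpha, "  *", "")))
    }
    lines <- c(lines, "")
  }
  lines <- c(lines, "Clean-epoch counts per record:")
  m <- res$metrics
  lines <- c(lines, sprintf("  %s/%s: %d", m$subject_id, m$condition,
                            m$n_clean_epochs))
  if (length(res$warnings)) {
    lines <- c(lines, "", "Warnings:",
               paste0("  - ", res$warnings))
  }
  lines
}
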