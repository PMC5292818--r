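# Orchestration: configuration, staged execution, report.
#
# A pipeline run is fully described by a flat key = value configuration
# (all seeds explicit). Stages: data -> decompose -> select -> features ->
# cox -> evaluate. Each stage's result is cached on disk under
# <out>/cache keyed by the config hash, so downstream verbs can resume
# without recomputation, and a run is bit-reproducible from config alone.

#' Default pipeline configuration
#'
#' Returns the flat named list of configuration values for a synthetic run.
#' Keys use `section.name` dotted names; [read_config()] produces the same
#' structure from a `key = value` text file.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    mode = "synthetic",
    # synthetic world
    synthetic.seed = 20260910,
    synthetic.grid_dim = 16L,
    synthetic.blob_radius = 2,
    synthetic.n_components_structural = 6L,
    synthetic.n_components_metabolic = 5L,
    synthetic.affected_structural = "1,2",
    synthetic.affected_metabolic = "1",
    synthetic.n_reference_per_group = 40L,
    synthetic.group_shift = 1.5,
    synthetic.noise_sd = 0.01,
    synthetic.n_survival = 200L,
    synthetic.baseline_rate = 0.02,
    synthetic.censor_month = 36,
    synthetic.beta_structural = -0.6,
    synthetic.beta_metabolic = -0.6,
    synthetic.beta_adas = 0.10,
    synthetic.beta_cdr = 0.40,
    synthetic.beta_apoe = 0.60,
    # real-data inputs (unset in synthetic mode)
    real.reference_structural_dir = "",
    real.reference_metabolic_dir = "",
    real.reference_labels_csv = "",
    real.survival_structural_dir = "",
    real.survival_metabolic_dir = "",
    real.subjects_csv = "",
    # ICA
    ica.order_override = 0L,      # 0 = use MDL
    ica.tol = 1e-6,
    ica.max_iter = 2048L,
    ica.seed = 101L,
    # selection
    selection.alpha = 0.05,
    selection.z_threshold = 3.0,
    # Cox
    cox.alpha = 0.05,
    cox.ties = "breslow",
    cox.apoe_binary = FALSE,
    cox.all_clinical = FALSE,
    # evaluation
    evaluation.rule = "youden",
    evaluation.threshold = 0.5,
    # output
    output.dir = "icasurv_out",
    output.write_volumes = FALSE
  )
}

#' Read a flat key = value configuration file
#'
#' Lines are `key = value`; `#` starts a comment; values are parsed as
#' logical / numeric / string. Unknown keys are errors; missing keys take
#' defaults from [default_config()].
#'
#' @param path configuration file.
#' @return named config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: '%s'", path),
                               call. = FALSE)
  base <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("malformed config line (no '='): %s", ln), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub('^"|"$', "", val)
    if (!key %in% names(base)) {
      stop(sprintf("unknown config key: %s", key), call. = FALSE)
    }
    old <- base[[key]]
    base[[key]] <- if (is.logical(old)) {
      toupper(val) %in% c("TRUE", "T", "YES", "1")
    } else if (is.numeric(old)) {
      as.numeric(val)
    } else val
  }
  base
}

#' Write a configuration to a file
#'
#' @param config named config list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- names(default_config())
  lines <- vapply(keys, function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, format(v, scientific = FALSE, trim = TRUE))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Hash of the analysis-relevant configuration (output.* destinations are
# excluded so the same analysis hashes identically wherever it is written).
config_hash <- function(config) {
  keys <- setdiff(names(default_config()), grep("^output\\.",
                                                names(default_config()),
                                                value = TRUE))
  f <- tempfile(fileext = ".cfg")
  on.exit(unlink(f))
  writeLines(vapply(keys, function(k) {
    sprintf("%s = %s", k, format(config[[k]], scientific = FALSE,
                                 trim = TRUE))
  }, character(1)), f)
  unname(tools::md5sum(f))
}

#' Validate a pipeline configuration
#'
#' @param config named config list.
#' @return character vector of problems; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  say <- function(...) problems <<- c(problems, sprintf(...))
  known <- names(default_config())
  extra <- setdiff(names(config), known)
  if (length(extra)) say("unknown keys: %s", paste(extra, collapse = ", "))
  miss <- setdiff(known, names(config))
  if (length(miss)) say("missing keys: %s", paste(miss, collapse = ", "))
  if (length(problems)) return(problems)

  real_keys <- grep("^real\\.", known, value = TRUE)
  real_set <- any(nzchar(unlist(config[real_keys])))
  if (identical(config$mode, "synthetic")) {
    if (real_set) say("mode is 'synthetic' but real.* input paths are set; exactly one input block may be present")
    for (k in c("synthetic.seed", "ica.seed")) {
      if (!is.finite(config[[k]])) say("%s: a seed must be set", k)
    }
    if (config$synthetic.n_reference_per_group < 2) {
      say("synthetic.n_reference_per_group: must be >= 2")
    }
    if (config$synthetic.n_survival < 10) say("synthetic.n_survival: must be >= 10")
    if (config$synthetic.baseline_rate <= 0) say("synthetic.baseline_rate: must be > 0")
    if (config$synthetic.censor_month <= 0) say("synthetic.censor_month: must be > 0")
  } else if (identical(config$mode, "real")) {
    if (!real_set) say("mode is 'real' but no real.* input paths are set")
    for (k in real_keys) {
      if (grepl("_dir$", k) && nzchar(config[[k]]) && !dir.exists(config[[k]])) {
        say("%s: directory '%s' does not exist", k, config[[k]])
      }
      if (grepl("_csv$", k) && nzchar(config[[k]]) && !file.exists(config[[k]])) {
        say("%s: file '%s' does not exist", k, config[[k]])
      }
    }
  } else {
    say("mode: must be 'synthetic' or 'real'")
  }
  if (config$selection.alpha <= 0 || config$selection.alpha >= 1) {
    say("selection.alpha: must be in (0, 1)")
  }
  if (config$selection.z_threshold <= 0) say("selection.z_threshold: must be > 0")
  if (!config$cox.ties %in% c("breslow", "efron")) {
    say("cox.ties: must be 'breslow' or 'efron'")
  }
  if (!config$evaluation.rule %in% c("youden", "fixed")) {
    say("evaluation.rule: must be 'youden' or 'fixed'")
  }
  problems
}

parse_ids <- function(s) {
  if (!nzchar(s)) return(integer(0))
  as.integer(strsplit(s, ",")[[1L]])
}

# stage: synthetic data generation -------------------------------------------

pipeline_data_synthetic <- function(config) {
  g <- config$synthetic.grid_dim
  seed <- config$synthetic.seed
  aff_s <- parse_ids(config$synthetic.affected_structural)
  aff_m <- parse_ids(config$synthetic.affected_metabolic)
  atlas_s <- make_source_atlas(config$synthetic.n_components_structural,
                               rep(g, 3L), config$synthetic.blob_radius,
                               seed = seed + 1L, affected_ids = aff_s)
  atlas_m <- make_source_atlas(config$synthetic.n_components_metabolic,
                               rep(g, 3L), config$synthetic.blob_radius,
                               seed = seed + 2L, affected_ids = aff_m)
  ref_s <- simulate_reference_cohort(atlas_s,
                                     config$synthetic.n_reference_per_group,
                                     config$synthetic.group_shift,
                                     config$synthetic.noise_sd,
                                     seed = seed + 3L)
  ref_m <- simulate_reference_cohort(atlas_m,
                                     config$synthetic.n_reference_per_group,
                                     config$synthetic.group_shift,
                                     config$synthetic.noise_sd,
                                     seed = seed + 4L)
  ref_m$matrix$modality <- "metabolic"
  true_beta <- c(
    stats::setNames(rep(config$synthetic.beta_structural, length(aff_s)),
                    sprintf("structural_IC_%02d", aff_s)),
    stats::setNames(rep(config$synthetic.beta_metabolic, length(aff_m)),
                    sprintf("metabolic_IC_%02d", aff_m)),
    adas_cog = config$synthetic.beta_adas,
    cdr_sb = config$synthetic.beta_cdr,
    apoe_e4 = config$synthetic.beta_apoe)
  surv <- simulate_survival_cohort(
    list(structural = atlas_s, metabolic = atlas_m),
    true_beta = true_beta,
    baseline_rate = config$synthetic.baseline_rate,
    censor_month = config$synthetic.censor_month,
    n = config$synthetic.n_survival, seed = seed + 5L,
    noise_sd = config$synthetic.noise_sd)
  list(reference = list(structural = ref_s, metabolic = ref_m),
       survival_cohort = surv,
       atlases = list(structural = atlas_s, metabolic = atlas_m))
}

read_cohort_dir <- function(dir, ids = NULL) {
  files <- sort(list.files(dir, pattern = "\\.nii$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no .nii volumes in '%s'", dir),
                           call. = FALSE)
  vols <- lapply(files, read_volume)
  list(volumes = vols, ids = sub("\\.nii$", "", basename(files)))
}

pipeline_data_real <- function(config) {
  labs <- utils::read.csv(config$real.reference_labels_csv)
  subj <- utils::read.csv(config$real.subjects_csv)
  ref <- list(); mats <- list()
  for (m in c("structural", "metabolic")) {
    rd <- read_cohort_dir(config[[sprintf("real.reference_%s_dir", m)]])
    lab <- labs$group[match(rd$ids, labs$subject_id)]
    sm <- stack_cohort(rd$volumes, labels = lab, modality = m,
                       subject_ids = rd$ids)
    ref[[m]] <- list(matrix = sm, truth = NULL)
    sd_ <- read_cohort_dir(config[[sprintf("real.survival_%s_dir", m)]])
    mats[[m]] <- stack_cohort(sd_$volumes, modality = m, subject_ids = sd_$ids)
  }
  clin_cols <- setdiff(names(subj), c("time_months", "event"))
  list(reference = ref,
       survival_cohort = list(
         matrices = mats,
         clinical = subj[, clin_cols, drop = FALSE],
         survival = subj[, c("subject_id", "time_months", "event")],
         truth = NULL),
       atlases = NULL)
}

# staged runner ---------------------------------------------------------------

STAGES <- c("data", "decompose", "select", "features", "cox", "evaluate")

#' Run the full network-survival pipeline
#'
#' Executes, in order: cohort generation (or loading), per-modality ICA on
#' the reference cohort, component selection and template construction,
#' template-mean feature extraction on the survival cohort, the five-model
#' Cox suite, and ROC evaluation of each model family's significant
#' factors. Writes CSV/JSON artifacts under `output.dir` and returns the
#' report. Stage results are cached under `<output.dir>/cache` keyed by the
#' config hash; `stop_after` allows partial runs that later verbs resume.
#'
#' @param config named config list (see [default_config()]).
#' @param stop_after last stage to execute, one of
#'   `"data"`, `"decompose"`, `"select"`, `"features"`, `"cox"`,
#'   `"evaluate"`.
#' @param quiet suppress stage logging.
#' @return A `pipeline_report` (list) — see Details. For partial runs, the
#'   stages executed so far.
#' @details The report holds: `config`, `config_hash`, per-modality
#'   `selection` tables, `orders` (MDL/override), the five `cox` tables with
#'   `carried` covariate lists, `metrics` per model family (accuracy,
#'   sensitivity, specificity, AUC), and per-stage wall times.
#' @export
run_pipeline <- function(config = default_config(), stop_after = "evaluate",
                         quiet = FALSE) {
  stopifnot(stop_after %in% STAGES)
  problems <- validate_config(config)
  if (length(problems)) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  hash <- config_hash(config)
  out_dir <- config$output.dir
  cache_dir <- file.path(out_dir, "cache")
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(config, file.path(out_dir, "config.used"))

  log_msg <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  run_stage <- function(stage, fun) {
    cache <- file.path(cache_dir, sprintf("%s_%s.rds", stage, hash))
    if (file.exists(cache)) {
      log_msg("[%s] cached", stage)
      return(readRDS(cache))
    }
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    saveRDS(res, cache)
    log_msg("[%s] done in %.2fs", stage, timings[[stage]])
    res
  }

  # -- data
  data <- run_stage("data", function() {
    d <- if (identical(config$mode, "synthetic")) pipeline_data_synthetic(config)
         else pipeline_data_real(config)
    if (isTRUE(config$output.write_volumes) &&
        identical(config$mode, "synthetic")) {
      write_cohort(d$survival_cohort, file.path(out_dir, "survival_cohort"))
    }
    d
  })
  if (stop_after == "data") return(invisible(list(data = data, config = config,
                                                  config_hash = hash)))

  modalities <- names(data$reference)

  # -- decompose
  decomp <- run_stage("decompose", function() {
    lapply(stats::setNames(modalities, modalities), function(m) {
      sm <- data$reference[[m]]$matrix
      k <- if (config$ica.order_override > 0) config$ica.order_override
           else as.integer(estimate_order_mdl(sm))
      dec <- infomax_ica(sm, order = k, tol = config$ica.tol,
                         max_iter = config$ica.max_iter,
                         seed = config$ica.seed)
      utils::write.csv(
        data.frame(subject_id = sm$subject_ids,
                   `colnames<-`(dec$mixing,
                                sprintf("IC_%02d", seq_len(dec$order)))),
        file.path(out_dir, sprintf("mixing_%s.csv", m)), row.names = FALSE)
      list(order = k, decomposition = dec)
    })
  })
  if (stop_after == "decompose") {
    return(invisible(list(data = data, decompose = decomp, config = config,
                          config_hash = hash)))
  }

  # -- select
  selection <- run_stage("select", function() {
    lapply(stats::setNames(modalities, modalities), function(m) {
      sel <- select_networks(decomp[[m]]$decomposition,
                             data$reference[[m]]$matrix$group_labels,
                             alpha = config$selection.alpha,
                             z_threshold = config$selection.z_threshold,
                             modality = m,
                             mask3d = data$reference[[m]]$matrix$mask)
      utils::write.csv(sel$stats,
                       file.path(out_dir, sprintf("selection_%s.csv", m)),
                       row.names = FALSE)
      ref <- data$reference[[m]]$matrix
      for (tp in sel$templates) {
        write_template(tp, file.path(
          out_dir, sprintf("template_%s_IC_%02d.nii", m, tp$component_id)),
          voxel_size = ref$voxel_size, affine = ref$affine)
      }
      sel
    })
  })
  if (stop_after == "select") {
    return(invisible(list(data = data, decompose = decomp,
                          select = selection, config = config,
                          config_hash = hash)))
  }

  # -- features
  features <- run_stage("features", function() {
    lapply(stats::setNames(modalities, modalities), function(m) {
      tps <- selection[[m]]$templates
      cohort <- data$survival_cohort$matrices[[m]]
      if (!length(tps)) {
        log_msg("[features] no templates for %s; empty feature table", m)
        return(data.frame(subject_id = cohort$subject_ids))
      }
      ft <- extract_network_features(cohort, tps)
      utils::write.csv(ft, file.path(out_dir, sprintf("features_%s.csv", m)),
                       row.names = FALSE)
      ft
    })
  })
  if (stop_after == "features") {
    return(invisible(list(data = data, decompose = decomp, select = selection,
                          features = features, config = config,
                          config_hash = hash)))
  }

  # -- cox suite
  suite <- run_stage("cox", function() {
    clin <- data$survival_cohort$clinical
    if (config$cox.apoe_binary) clin$apoe_e4 <- as.integer(clin$apoe_e4 > 0)
    s <- run_model_suite(features$structural, features$metabolic, clin,
                         data$survival_cohort$survival,
                         alpha = config$cox.alpha, ties = config$cox.ties,
                         all_clinical = config$cox.all_clinical)
    for (nm in names(s$models)) {
      if (!is.null(s$models[[nm]])) {
        write_cox_csv(s$models[[nm]],
                      file.path(out_dir, sprintf("cox_%s.csv", nm)))
      }
    }
    s
  })
  if (stop_after == "cox") {
    return(invisible(list(data = data, decompose = decomp, select = selection,
                          features = features, cox = suite, config = config,
                          config_hash = hash)))
  }

  # -- evaluation
  evaluation <- run_stage("evaluate", function() {
    labels <- as.logical(data$survival_cohort$survival$event)
    feature_tab <- merge(features$structural, features$metabolic,
                         by = "subject_id")
    clin <- data$survival_cohort$clinical
    if (config$cox.apoe_binary) clin$apoe_e4 <- as.integer(clin$apoe_e4 > 0)
    all_tab <- merge(feature_tab, clin, by = "subject_id")
    ids <- data$survival_cohort$survival$subject_id
    eval_family <- function(covs) {
      if (!length(covs)) return(NULL)
      tab <- all_tab[match(ids, all_tab$subject_id),
                     c("subject_id", covs), drop = FALSE]
      evaluate_factors(tab, labels, rule = config$evaluation.rule)
    }
    fams <- lapply(suite$significant, eval_family)
    for (nm in names(fams)) {
      if (!is.null(fams[[nm]])) {
        utils::write.csv(fams[[nm]]$curve,
                         file.path(out_dir, sprintf("roc_%s.csv", nm)),
                         row.names = FALSE)
      }
    }
    rows <- lapply(names(fams), function(nm) {
      f <- fams[[nm]]
      if (is.null(f)) {
        data.frame(model = nm, accuracy = NA_real_, sensitivity = NA_real_,
                   specificity = NA_real_, auc = NA_real_)
      } else {
        data.frame(model = nm, accuracy = f$accuracy,
                   sensitivity = f$sensitivity, specificity = f$specificity,
                   auc = f$auc)
      }
    })
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    list(table = tab, families = fams)
  })

  report <- list(
    config = config,
    config_hash = hash,
    orders = lapply(decomp, `[[`, "order"),
    selection = lapply(selection, `[[`, "stats"),
    templates = lapply(selection, function(s) {
      vapply(s$templates, function(tp)
        sprintf("%s_IC_%02d", tp$modality, tp$component_id), character(1))
    }),
    cox = lapply(suite$models, function(m) if (is.null(m)) NULL
                 else as.data.frame(m)),
    carried = suite$carried,
    significant = suite$significant,
    skipped = suite$skipped,
    metrics = evaluation$table,
    timings = timings
  )
  class(report) <- "pipeline_report"
  jsonlite::write_json(report_to_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}

report_to_json <- function(report) {
  r <- unclass(report)
  r$config <- r$config[order(names(r$config))]
  r
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$config_hash, "\n")
  cat("  ICA orders:", paste(sprintf("%s=%d", names(x$orders),
                                     unlist(x$orders)), collapse = ", "), "\n")
  cat("  templates:", paste(unlist(x$templates), collapse = ", "), "\n")
  cat("  metrics:\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Command-line entry point
#'
#' Verbs: `generate`, `decompose`, `select`, `fit`, `evaluate`, `run`
#' (synonym of `evaluate`: the full pipeline), each accepting
#' `--config <file>` and `--out <dir>` (overrides `output.dir`). Called by
#' the `inst/bin/icasurv` script; usable directly as
#' `icasurv_cli(c("run", "--config", "pipeline.cfg"))`.
#'
#' @param args character vector of command-line arguments.
#' @return The stage result, invisibly.
#' @export
icasurv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  verbs <- c(generate = "data", decompose = "decompose", select = "select",
             fit = "cox", evaluate = "evaluate", run = "evaluate")
  if (!length(args) || !args[1L] %in% names(verbs)) {
    stop(sprintf("usage: icasurv <%s> [--config FILE] [--out DIR]",
                 paste(names(verbs), collapse = "|")), call. = FALSE)
  }
  verb <- args[1L]
  rest <- args[-1L]
  get_opt <- function(flag) {
    i <- which(rest == flag)
    if (length(i)) rest[i[1L] + 1L] else NA_character_
  }
  cfg_path <- get_opt("--config")
  config <- if (!is.na(cfg_path)) read_config(cfg_path) else default_config()
  out <- get_opt("--out")
  if (!is.na(out)) config$output.dir <- out
  run_pipeline(config, stop_after = verbs[[verb]])
}
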