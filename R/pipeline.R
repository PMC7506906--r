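# End-to-end orchestration: simulate a cohort, run every subject's session
# through segmentation and feature extraction, then validate two competing
# predictor models of the CBMS score — model 1: descriptives + iTUG signal
# features; model 2: descriptives + standard clinical tests — against the
# same response with identical Monte-Carlo partitions, and compare their
# prediction errors.

#' Default pipeline configuration
#'
#' @param n_community,n_outpatient cohort sizes.
#' @param seed master seed for the whole run.
#' @param noise_acc,noise_gyro sensor noise SDs passed to the signal
#'   generator.
#' @param n_rep repetitions per subject.
#' @param gap rest between repetitions (s).
#' @param cv a [cv_config()] (its seed is overridden by `seed`).
#' @param segmentation a [seg_config()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_community = 40, n_outpatient = 20, seed = 7,
                       noise_acc = 0.15, noise_gyro = 3, n_rep = 5,
                       gap = 30, cv = cv_config(), segmentation = seg_config()) {
  cv$seed <- seed
  structure(list(n_community = n_community, n_outpatient = n_outpatient,
                 seed = seed, noise_acc = noise_acc,
                 noise_gyro = noise_gyro, n_rep = n_rep, gap = gap,
                 cv = cv, segmentation = segmentation),
            class = "run_config")
}

# read a YAML config file into a run_config, rejecting unknown keys
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop_itug("itug_config_error", "unknown config key(s): %s",
              paste(extra, collapse = ", "))
  if (!is.null(raw$cv)) raw$cv <- do.call(cv_config, raw$cv)
  if (!is.null(raw$segmentation))
    raw$segmentation <- do.call(seg_config, raw$segmentation)
  do.call(run_config, raw)
}

# iTUG feature table for one subject: session -> repetitions -> features,
# averaged across repetitions
subject_features <- function(profile, config, seed) {
  ses <- simulate_session(profile, seed = seed, n_rep = config$n_rep,
                          gap = config$gap, noise_acc = config$noise_acc,
                          noise_gyro = config$noise_gyro)
  reps <- split_repetitions(ses$recording, config$segmentation)
  feats <- lapply(seq_along(reps), function(r) {
    seg <- segment_trial(reps[[r]], config$segmentation)
    extract_features(reps[[r]], seg)
  })
  list(features = average_features(feats), n_rep = length(reps))
}

#' Run the full simulate-segment-extract-validate pipeline
#'
#' Executes the complete chain for a simulated study population and both
#' predictor models, writing all tables to `out_dir`: the per-subject
#' averaged iTUG features, clinical table and CBMS scores; per-model RMSEP
#' curves, selected features (with selection frequency, VIP, per-component
#' weights and univariate r^2), explained-variation tables with confidence
#' intervals; the paired model comparison; and a JSON manifest (seed,
#' configuration, package version) sufficient to reproduce the run.
#' Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()] or path to a YAML file of its fields.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with both `cv_result`s, the comparison and
#'   the output paths.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("itug_run_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("simulating cohort (%d community, %d outpatient)",
      config$n_community, config$n_outpatient)
  cohort <- simulate_cohort(config$n_community, config$n_outpatient,
                            seed = config$seed)
  n <- nrow(cohort$profiles)
  if (n < 12)
    stop_itug("itug_argument_error",
              "pipeline needs at least 12 subjects for a %d-fold validation",
              config$cv$n_folds)
  seeds <- spawn_seeds(config$seed + 1L, n)

  say("simulating and processing %d sessions", n)
  feat_rows <- vector("list", n)
  for (i in seq_len(n)) {
    sf <- tryCatch(
      subject_features(cohort$profiles[i, ], config, seeds[i]),
      error = function(e) stop_itug(
        "itug_pipeline_error", "stage 'features' failed for subject %s: %s",
        cohort$profiles$id[i], conditionMessage(e)))
    feat_rows[[i]] <- sf$features
  }
  itug_X <- do.call(rbind, feat_rows)
  rownames(itug_X) <- cohort$profiles$id

  clin <- cohort$clinical
  descr <- cbind(age = clin$age, education = clin$education,
                 sex = as.numeric(clin$sex == "F"), height = clin$height,
                 weight = clin$weight, bmi = clin$bmi)
  tests <- cbind(tug_s = clin$tug_s, gait_habitual = clin$gait_habitual,
                 gait_fast = clin$gait_fast, sppb = clin$sppb,
                 cst30 = clin$cst30, lbs8 = clin$lbs8,
                 fes_i_short = clin$fes_i_short)
  y <- cohort$cbms$cbms

  drop_const <- function(M) M[, apply(M, 2, stats::sd) > 0, drop = FALSE]
  tab1 <- feature_table(drop_const(cbind(descr, itug_X)), y, ids = clin$id)
  tab2 <- feature_table(drop_const(cbind(descr, tests)), y, ids = clin$id)

  say("validating model 1 (iTUG features) and model 2 (clinical tests)")
  res1 <- monte_carlo_cv(tab1, config$cv)
  res2 <- monte_carlo_cv(tab2, config$cv)
  cmp <- compare_models(res1, res2)

  wcsv <- function(d, f) {
    p <- file.path(out_dir, f)
    utils::write.csv(d, p, row.names = FALSE)
    p
  }
  wcsv(data.frame(id = clin$id, itug_X, check.names = FALSE), "features.csv")
  wcsv(clin, "clinical.csv")
  wcsv(cohort$cbms, "cbms.csv")
  for (k in 1:2) {
    res <- list(res1, res2)[[k]]
    tag <- paste0("model", k)
    wcsv(data.frame(components = seq_along(res$rmsep_mean),
                    rmsep_mean = res$rmsep_mean, rmsep_sd = res$rmsep_sd),
         sprintf("rmsep_curve_%s.csv", tag))
    W <- res$final_model$weights
    tabX <- list(tab1, tab2)[[k]]$X
    sel <- data.frame(name = res$final_features,
                      frequency = res$selection_freq[res$final_features],
                      vip = res$final_vip[res$final_features],
                      r2_univariate = drop(stats::cor(
                        tabX[, res$final_features, drop = FALSE], y))^2,
                      check.names = FALSE, row.names = NULL)
    for (a in seq_len(ncol(W)))
      sel[[sprintf("weight_c%d", a)]] <- W[res$final_features, a]
    wcsv(sel, sprintf("selected_features_%s.csv", tag))
    ev <- res$evar
    ev$component <- ifelse(is.na(ev$component), "total", ev$component)
    wcsv(ev, sprintf("explained_variation_%s.csv", tag))
  }
  wcsv(data.frame(z = cmp$z, p = cmp$p, mean_diff = mean(cmp$d),
                  n_iter = cmp$n_iter), "comparison.csv")
  manifest <- list(package = "itug",
                   version = as.character(utils::packageVersion("itug")),
                   seed = config$seed,
                   n_community = config$n_community,
                   n_outpatient = config$n_outpatient,
                   n_rep = config$n_rep,
                   cv = unclass(config$cv),
                   segmentation = unclass(config$segmentation))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("run written to %s", out_dir)
  invisible(list(model1 = res1, model2 = res2, comparison = cmp,
                 out_dir = out_dir))
}

#' Summarise a completed pipeline run
#'
#' Reads the CSV outputs of [run_pipeline()] and renders a markdown
#' summary: chosen component counts, explained variation with confidence
#' intervals, the paired comparison, and the top features by VIP banded at
#' the conventional 0.83 / 1 / 1.21 cut-offs.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @param file optional path to also write the summary to.
#' @return The summary as a character vector of lines, invisibly printed.
#' @export
run_report <- function(run_dir, file = NULL) {
  need <- c("rmsep_curve_model1.csv", "explained_variation_model1.csv",
            "selected_features_model1.csv", "comparison.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop_itug("itug_report_error", "run directory lacks output(s): %s",
              paste(missing, collapse = ", "))
  lines <- c("# iTUG pipeline run summary", "")
  for (k in 1:2) {
    evp <- file.path(run_dir, sprintf("explained_variation_model%d.csv", k))
    sfp <- file.path(run_dir, sprintf("selected_features_model%d.csv", k))
    if (!file.exists(evp)) next
    ev <- utils::read.csv(evp)
    sel <- utils::read.csv(sfp)
    rc <- utils::read.csv(file.path(run_dir,
                                    sprintf("rmsep_curve_model%d.csv", k)))
    tot <- ev[ev$component == "total", ]
    a_star <- sum(ev$component != "total")
    lines <- c(lines,
      sprintf("## Model %d (%s)", k,
              c("descriptives + iTUG features",
                "descriptives + clinical tests")[k]),
      sprintf("- components: %d; RMSEP %.2f (SD %.2f)", a_star,
              rc$rmsep_mean[a_star], rc$rmsep_sd[a_star]),
      sprintf("- total explained variation: %.3f (95%% CI %.3f-%.3f)",
              tot$mean, tot$ci_lo, tot$ci_hi), "",
      "| feature | selection freq | VIP | band | r2 |",
      "|---|---|---|---|---|")
    sel <- sel[order(-sel$vip), ]
    band <- as.character(classify_vip(sel$vip))
    lines <- c(lines, sprintf("| %s | %.2f | %.3f | %s | %.3f |",
                              sel$name, sel$frequency, sel$vip, band,
                              sel$r2_univariate), "")
  }
  cmp <- utils::read.csv(file.path(run_dir, "comparison.csv"))
  lines <- c(lines, "## Model comparison (paired RMSEP)",
             sprintf("- Z = %.3f, p = %.3g (negative Z favours model 1)",
                     cmp$z, cmp$p))
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
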