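#' Run the full synthetic study: simulate, measure, analyse
#'
#' End-to-end reproduction of the study design on synthetic data. For each
#' group, call specifications are drawn from its species profile and allocated
#' to individuals; every call is synthesized and measured; the measurement
#' table is then pushed through the inference chain: per-parameter group
#' summaries, one-way ANOVA with Tukey post-hoc tests (duration, 50% quartile,
#' entropy, and the fundamental-frequency parameters on voiced calls),
#' Kruskal-Wallis/median test for peak frequency, the two-parent discriminant
#' (resubstitution, split-half cross-validation, randomization chance level,
#' chi-squared comparisons of the attribution rates), and the Mahalanobis
#' placement of individuals with the hybrid intermediacy summary.
#'
#' The whole run is reproducible from `(config, seed)`; the report carries the
#' seed and an MD5 hash of the configuration.
#'
#' @param config a [validate_config()] result, or a raw list of overrides.
#' @param verbose log stage progress via [message()] (default TRUE).
#' @return object of class `vole_study`; see Details. If `config$out_dir` is
#'   set, also writes `measurements.csv`, `ground_truth.csv`, `report.json`,
#'   a `fig_mahalanobis.png` scatter and (optionally) per-call WAV files
#'   there.
#' @examples
#' \donttest{
#' rep <- run_study(list(n_calls = c(tien_shan = 30, hybrid = 20, bank = 20),
#'                       n_individuals = c(tien_shan = 3, hybrid = 2,
#'                                         bank = 2),
#'                       n_reps = 20), verbose = FALSE)
#' print(rep)
#' }
#' @export
run_study <- function(config = list(), verbose = TRUE) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  log_stage <- function(...) if (verbose) message(format(Sys.time(), "%T "),
                                                 ...)
  profiles <- default_profiles()
  groups <- names(config$n_calls)

  log_stage("simulate: drawing ", sum(config$n_calls), " call specs (seed ",
            config$seed, ")")
  specs <- do.call(rbind, lapply(seq_along(groups), function(gi) {
    gname <- groups[gi]
    n <- config$n_calls[[gname]]
    sp <- sample_call_specs(profiles[[gname]], n,
                            seed = config$seed + 1000L * gi)
    counts <- allocate_calls(n, config$n_individuals[[gname]],
                             config$calls_per_animal, gname)
    sp$individual <- paste0(gname, "_", rep(seq_along(counts), counts))
    sp$call_id <- paste0(gname, "_", seq_len(n))
    sp
  }))
  if (config$individual_effect_sd > 0) {
    specs <- with_seed(config$seed + 77L,
                       add_individual_effects(specs,
                                              config$individual_effect_sd))
  }

  log_stage("measure: synthesizing and measuring ", nrow(specs), " calls")
  waves <- lapply(seq_len(nrow(specs)), function(i)
    synthesize(specs[i, ], config$sampling_rate_hz,
               seed = config$seed + 10L * i))
  meas <- do.call(rbind, lapply(waves, measure,
                                fft_size = config$fft_size,
                                overlap = config$overlap))
  meas <- cbind(specs[c("call_id", "individual", "group")], meas)
  rownames(meas) <- NULL

  log_stage("analyze: group statistics and discriminant chain")
  analysis <- analyze_measurements(meas, features = config$features,
                                   n_reps = config$n_reps,
                                   seed = config$seed)

  report <- structure(
    list(config = unclass(config),
         config_hash = config_hash(config),
         seed = config$seed,
         n_calls = table(meas$group),
         group_summary = analysis$group_summary,
         anova = analysis$anova,
         kruskal_peak = analysis$kruskal_peak,
         dfa = analysis$dfa,
         mahalanobis = analysis$mahalanobis,
         intermediacy = analysis$intermediacy,
         measurements = meas,
         ground_truth = specs),
    class = "vole_study")

  if (!is.null(config$out_dir)) {
    log_stage("report: writing outputs to ", config$out_dir)
    write_study_outputs(report, waves, config)
  }
  report
}

# Add a per-animal random intercept to the continuous spec parameters
# (repeated calls from one animal are then correlated).
add_individual_effects <- function(specs, rel_sd) {
  pars <- c("duration_s", "f0max_hz", "q50_hz", "entropy")
  for (ind in unique(specs$individual)) {
    sel <- specs$individual == ind
    for (p in pars) {
      shift <- rnorm(1, 0, rel_sd * mean(specs[[p]][sel]))
      specs[[p]][sel] <- pmax(specs[[p]][sel] + shift, 1e-4)
    }
  }
  specs$entropy <- pmin(specs$entropy, 0.99)
  specs
}

#' Statistical analysis of a measurement table
#'
#' The inference chain of [run_study()], callable on any measurement table
#' (for example one read back from `measurements.csv`).
#'
#' @param meas data.frame with `group`, `individual` and the measurement
#'   columns of [measure()].
#' @param features feature set for the discriminant and Mahalanobis stages.
#' @param parents the two parent group labels.
#' @param n_reps randomization replicates.
#' @param seed integer seed for the random split and permutations.
#' @return list with `group_summary`, `anova`, `kruskal_peak`, `dfa`,
#'   `mahalanobis`, `intermediacy`.
#' @export
analyze_measurements <- function(meas, features = c("duration_s", "q50_hz",
                                                    "entropy"),
                                 parents = c("tien_shan", "bank"),
                                 n_reps = 100, seed = 20190226) {
  grp <- function(col, data = meas) split(data[[col]], data$group)
  group_summary <- do.call(rbind, lapply(
    c("duration_s", "peak_hz", "q25_hz", "q50_hz", "q75_hz", "entropy",
      "f0max_hz", "modulation_range_hz"),
    function(col) {
      s <- grp(col)
      data.frame(parameter = col, group = names(s),
                 n = vapply(s, function(v) sum(!is.na(v)), 1L),
                 mean = vapply(s, function(v) mean(v, na.rm = TRUE),
                               numeric(1)),
                 se = vapply(s, function(v)
                   stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))),
                   numeric(1)),
                 row.names = NULL)
    }))

  anova_pars <- c("duration_s", "q50_hz", "entropy", "f0max_hz",
                  "modulation_range_hz")
  anova <- lapply(anova_pars, function(col) {
    s <- lapply(grp(col), function(v) v[!is.na(v)])
    s <- s[vapply(s, length, 1L) >= 2L]
    tryCatch(one_way_anova(s), error = function(e) NULL)
  })
  names(anova) <- anova_pars

  kruskal_peak <- kruskal_wallis_median(grp("peak_hz"))

  pmeas <- meas[meas$group %in% parents, , drop = FALSE]
  fit <- dfa(pmeas[features], factor(pmeas$group, levels = parents))
  resub <- classify(fit, pmeas)
  cv <- split_half_cv(pmeas, features, seed = seed)
  null <- randomization_null(pmeas, features, n_reps = n_reps, seed = seed)
  n_parent <- nrow(pmeas)
  chi_cv <- compare_proportions_chi2(resub$percent_correct, n_parent,
                                     cv$percent_correct, cv$n_test)
  chi_null <- compare_proportions_chi2(resub$percent_correct, n_parent,
                                       null$mean_percent, n_parent)

  pl <- mahalanobis_placement(meas, features = features, parents = parents)
  list(group_summary = group_summary, anova = anova,
       kruskal_peak = kruskal_peak,
       dfa = list(model = fit, resubstitution = resub,
                  cross_validation = cv, randomization = null,
                  chi2_resub_vs_cv = chi_cv,
                  chi2_resub_vs_null = chi_null),
       mahalanobis = pl,
       intermediacy = intermediacy_summary(pl))
}

config_hash <- function(config) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(path))
}

write_study_outputs <- function(report, waves, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$measurements,
                   file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ground_truth,
                   file.path(config$out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report_as_json(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  grDevices::png(file.path(config$out_dir, "fig_mahalanobis.png"),
                 width = 700, height = 600)
  plot(report$mahalanobis,
       main = "Individuals in parental Mahalanobis coordinates")
  grDevices::dev.off()
  if (isTRUE(config$write_wav)) {
    wav_dir <- file.path(config$out_dir, "wav")
    dir.create(wav_dir, showWarnings = FALSE)
    for (i in seq_along(waves))
      write_wav(waves[[i]],
                file.path(wav_dir,
                          paste0(report$ground_truth$call_id[i], ".wav")))
  }
  invisible(config$out_dir)
}

# Serializable view of a study report (no closures, stable field order, no
# timestamps, so identical runs give byte-identical JSON).
report_as_json <- function(report) {
  dfa <- report$dfa
  list(
    config = report$config[order(names(report$config))],
    config_hash = report$config_hash,
    seed = report$seed,
    n_calls = as.list(report$n_calls),
    group_summary = report$group_summary,
    anova = lapply(report$anova, function(a) if (is.null(a)) NULL else
      list(F = a$F, df = c(a$df_between, a$df_within), p = a$p,
           posthoc = a$posthoc)),
    kruskal_peak = report$kruskal_peak[c("H", "p_kw", "chi2_median",
                                         "p_median")],
    dfa = list(
      features = dfa$model$features,
      coefficients = as.list(dfa$model$coefficients),
      resubstitution_percent = dfa$resubstitution$percent_correct,
      confusion = as.data.frame(dfa$resubstitution$confusion),
      wilks_lambda = dfa$resubstitution$wilks_lambda,
      wilks_partial = as.list(dfa$resubstitution$wilks_partial),
      cross_validation_percent = dfa$cross_validation$percent_correct,
      randomization_mean_percent = dfa$randomization$mean_percent,
      randomization_se_percent = dfa$randomization$se_percent,
      chi2_resub_vs_cv = dfa$chi2_resub_vs_cv[c("chi2", "p")],
      chi2_resub_vs_null = dfa$chi2_resub_vs_null[c("chi2", "p")]),
    mahalanobis = as.data.frame(report$mahalanobis),
    intermediacy = list(
      per_individual = report$intermediacy$per_individual,
      counts = as.list(report$intermediacy$counts),
      majority_nearer = report$intermediacy$majority_nearer,
      n_intermediate = report$intermediacy$n_intermediate))
}

#' @export
print.vole_study <- function(x, ...) {
  cat("Synthetic distress-call study\n")
  cat(sprintf("  %s calls (seed %d, config %s)\n",
              paste(sprintf("%s=%d", names(x$n_calls), x$n_calls),
                    collapse = ", "),
              x$seed, substr(x$config_hash, 1, 8)))
  d <- x$dfa
  cat(sprintf("  parent DFA: %.1f%% resubstitution, %.1f%% split-half CV,\n",
              d$resubstitution$percent_correct,
              d$cross_validation$percent_correct))
  cat(sprintf("  randomization chance %.2f +/- %.2f%% (n = %d)\n",
              d$randomization$mean_percent, d$randomization$se_percent,
              d$randomization$n_reps))
  cat(sprintf("  resub vs CV: chi2 = %.2f, p = %.2g\n",
              d$chi2_resub_vs_cv$chi2, d$chi2_resub_vs_cv$p))
  cat(sprintf("  hybrids nearer to: %s (%d of %d intermediate)\n",
              x$intermediacy$majority_nearer,
              x$intermediacy$n_intermediate,
              nrow(x$intermediacy$per_individual)))
  invisible(x)
}

#' @export
plot.vole_study <- function(x, ...) plot(x$mahalanobis, ...)
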