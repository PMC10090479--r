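#' Study configuration
#'
#' Collects every parameter of the simulated trial in one list: cohort
#' sizes (defaults 20 experimental + 18 sham + 32 healthy controls), the
#' synthetic-EEG and plant parameters, the session schedule and controller
#' targets, and the statistical settings. Defaults are sized so that the
#' full pipeline runs on a laptop in minutes (60-s recordings, 48 sources,
#' 1000 permutations, 3 NFB sessions); they can be raised to the trial's
#' full scale (180 s, 19 sessions, 10000 permutations) without code
#' changes.
#'
#' @param n_exp,n_sham,n_control group sizes.
#' @param n_sources toy source-grid size.
#' @param duration_s resting recording duration (s).
#' @param fs sampling rate (Hz).
#' @param alpha_deficit anterior alpha deficit fraction for PTSD subjects
#'   (0 disables the baseline effect).
#' @param rebound_frac fraction of the deficit recovered post-treatment in
#'   the experimental group (0 disables the rebound effect).
#' @param artifact_rate artifacts per minute in synthetic recordings.
#' @param aperiodic_slope 1/f exponent of the background.
#' @param n_sessions NFB sessions to simulate per PTSD subject (0 skips the
#'   session-level simulation).
#' @param plant named list of [plant_state()] arguments for PTSD subjects.
#' @param clinical named list passed to [gen_clinical_cohort()] (`means`,
#'   `sds`, `rho_prepost`).
#' @param n_perm,q permutation count and FDR level.
#' @param lambda sLORETA regularization.
#' @param target_reward controller reward-rate target.
#' @param seed master seed; all stage seeds derive from it.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_exp = 20, n_sham = 18, n_control = 32,
                         n_sources = 48, duration_s = 60, fs = 250,
                         alpha_deficit = 0.45, rebound_frac = 0.8,
                         artifact_rate = 1, aperiodic_slope = 1,
                         n_sessions = 3,
                         plant = list(alpha_setpoint = 10,
                                      homeostatic_gain = 0.15,
                                      suppression_gain = 4,
                                      relax_rate = 2, noise_sd = 0.6),
                         clinical = list(rho_prepost = 0.2),
                         n_perm = 1000, q = 0.05, lambda = 0.1,
                         target_reward = 0.65, seed = 1) {
  cfg <- list(n_exp = n_exp, n_sham = n_sham, n_control = n_control,
              n_sources = n_sources, duration_s = duration_s, fs = fs,
              alpha_deficit = alpha_deficit, rebound_frac = rebound_frac,
              artifact_rate = artifact_rate,
              aperiodic_slope = aperiodic_slope, n_sessions = n_sessions,
              plant = plant, clinical = clinical, n_perm = n_perm, q = q,
              lambda = lambda, target_reward = target_reward, seed = seed)
  class(cfg) <- "study_config"
  cfg
}

#' Load a study configuration from YAML
#'
#' @param path YAML file whose keys are [study_config()] arguments.
#' @return A `study_config`.
#' @export
load_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals)
}

#' Save a study configuration to YAML
#'
#' @param config a [study_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# preprocess one synthetic recording through the offline chain and return
# its per-source relative alpha map
.subject_alpha_map <- function(profile, leadfield, cfg) {
  rec <- gen_subject_recording(profile, leadfield,
                               duration_s = cfg$duration_s, fs = cfg$fs)
  rec <- common_average_reference(rec)
  rec <- bandpass(rec, 0.5, 40)
  eps <- faster_reject(segment_epochs(rec, 1.0))
  clean <- kept_recording(eps)
  source_relative_power(leadfield, clean, eeg_bands$alpha,
                        eeg_bands$broadband, lambda = cfg$lambda)$values
}

.group_maps <- function(group, n, deficit, cfg, leadfield, stage) {
  t(vapply(seq_len(n), function(i) {
    prof <- subject_profile(group, alpha_deficit = deficit,
                            aperiodic_slope = cfg$aperiodic_slope,
                            artifact_rate = cfg$artifact_rate,
                            seed = child_seed(cfg$seed,
                                              paste0(stage, "_", group,
                                                     "_", i)))
    .subject_alpha_map(prof, leadfield, cfg)
  }, numeric(cfg$n_sources)))
}

# simulate the NFB course for the PTSD groups; experimental subjects run
# closed-loop, sham subjects are yoked to the first experimental subject
.simulate_sessions <- function(cfg) {
  sch <- session_schedule()
  n_per <- length(sch$periods)
  mk_plant <- function() do.call(plant_state, cfg$plant)
  pc <- function(log) percent_change_from_rest(log)

  exp_pc <- array(NA_real_, c(cfg$n_exp, cfg$n_sessions, n_per))
  sham_pc <- array(NA_real_, c(cfg$n_sham, cfg$n_sessions, n_per))
  donor_logs <- vector("list", cfg$n_sessions)
  for (i in seq_len(cfg$n_exp)) {
    plant <- mk_plant()
    for (s in seq_len(cfg$n_sessions)) {
      log <- run_session(plant, sch, "active", session_number = s,
                         seed = child_seed(cfg$seed,
                                           paste0("nfb_exp_", i, "_", s)),
                         target_reward = cfg$target_reward)
      plant <- log$plant
      exp_pc[i, s, ] <- pc(log)
      if (i == 1L) donor_logs[[s]] <- log
    }
  }
  for (i in seq_len(cfg$n_sham)) {
    plant <- mk_plant()
    for (s in seq_len(cfg$n_sessions)) {
      log <- yoked_sham_session(donor_logs[[s]], plant,
                                seed = child_seed(cfg$seed,
                                                  paste0("nfb_sham_", i,
                                                         "_", s)))
      plant <- log$plant
      sham_pc[i, s, ] <- pc(log)
    }
  }
  list(exp = exp_pc, sham = sham_pc,
       exp_session_mean = apply(exp_pc, c(1, 2), mean),
       sham_session_mean = apply(sham_pc, c(1, 2), mean))
}

#' Run the full simulated-trial pipeline
#'
#' End-to-end orchestration of the analysis chain: synthetic cohorts
#' (experimental, sham, healthy control), pre/post resting recordings and
#' their preprocessing, source-space relative alpha maps, the baseline
#' PTSD-vs-control contrast, the experimental pre-vs-post contrast, their
#' FDR-corrected and sign-restricted masks and the conjunction, session-
#' level neurofeedback simulation (active vs yoked sham percent-change
#' matrices), and the clinical outcome table with ANOVA, paired effect
#' sizes, percent reductions and remission rates. All randomness derives
#' deterministically from `config$seed`.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, stat maps and
#'   clinical results are written as JSON/CSV together with a manifest
#'   echoing the full configuration and seed.
#' @return List of class `trial_report` with elements `leadfield`, `maps`
#'   (per group/stage subject x source matrices), `baseline`, `rebound`
#'   (stat maps), `masks` (baseline, rebound, conjunction),
#'   `conjunction_regions`, `sessions` (percent-change arrays or NULL),
#'   `clinical` (table and derived statistics) and `config`.
#' @export
#' @examples
#' \donttest{
#' cfg <- study_config(n_exp = 4, n_sham = 4, n_control = 4,
#'                     n_sources = 12, duration_s = 8, n_perm = 200,
#'                     n_sessions = 0, artifact_rate = 0, seed = 7)
#' rep <- run_trial_pipeline(cfg)
#' }
run_trial_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  lf <- make_toy_leadfield(cfg$n_sources,
                           seed = child_seed(cfg$seed, "leadfield"))

  maps_exp_pre <- .group_maps("ptsd_experimental", cfg$n_exp,
                              cfg$alpha_deficit, cfg, lf, "pre")
  maps_sham_pre <- .group_maps("ptsd_sham", cfg$n_sham, cfg$alpha_deficit,
                               cfg, lf, "pre")
  maps_hc <- .group_maps("healthy_control", cfg$n_control, 0, cfg, lf,
                         "pre")
  post_deficit_exp <- cfg$alpha_deficit * (1 - cfg$rebound_frac)
  maps_exp_post <- .group_maps("ptsd_experimental", cfg$n_exp,
                               post_deficit_exp, cfg, lf, "post")
  maps_sham_post <- .group_maps("ptsd_sham", cfg$n_sham, cfg$alpha_deficit,
                                cfg, lf, "post")

  baseline <- permutation_test(rbind(maps_exp_pre, maps_sham_pre), maps_hc,
                               paired = FALSE, n_perm = cfg$n_perm,
                               seed = child_seed(cfg$seed, "perm_baseline"))
  baseline$contrast_id <- "baseline_ptsd_vs_control"
  baseline$band <- eeg_bands$alpha
  baseline$sig_mask <- fdr_correct(baseline$p_values, cfg$q) &
    baseline$t_values < 0 # PTSD reduced relative alpha

  rebound <- permutation_test(maps_exp_post, maps_exp_pre, paired = TRUE,
                              n_perm = cfg$n_perm,
                              seed = child_seed(cfg$seed, "perm_rebound"))
  rebound$contrast_id <- "experimental_post_vs_pre"
  rebound$band <- eeg_bands$alpha
  rebound$sig_mask <- fdr_correct(rebound$p_values, cfg$q) &
    rebound$t_values > 0 # post-treatment alpha increase

  conj <- conjunction(baseline, rebound)

  sessions <- if (cfg$n_sessions > 0) .simulate_sessions(cfg) else NULL

  clin_args <- cfg$clinical
  clin_args$n_exp <- cfg$n_exp
  clin_args$n_sham <- cfg$n_sham
  clin_args$seed <- child_seed(cfg$seed, "clinical")
  clin_tab <- do.call(gen_clinical_cohort, clin_args)
  anova_fit <- split_plot_rm_anova(clinical_long(clin_tab))
  exp_rows <- clin_tab$group == "ptsd_experimental"
  t_exp_post <- paired_t_and_dz(clin_tab$caps_pre[exp_rows],
                                clin_tab$caps_post[exp_rows])
  t_exp_fu <- paired_t_and_dz(clin_tab$caps_pre[exp_rows],
                              clin_tab$caps_fu[exp_rows])
  t_sham_post <- paired_t_and_dz(clin_tab$caps_pre[!exp_rows],
                                 clin_tab$caps_post[!exp_rows])
  t_sham_fu <- paired_t_and_dz(clin_tab$caps_pre[!exp_rows],
                               clin_tab$caps_fu[!exp_rows])
  pr <- function(rows, col) {
    percent_reduction(mean(clin_tab$caps_pre[rows]),
                      mean(clin_tab[[col]][rows]))
  }
  remit <- function(rows) {
    mean(remission_classify(clin_tab$caps_pre[rows],
                            clin_tab$caps_fu[rows]))
  }
  clinical <- list(
    table = clin_tab, anova = anova_fit,
    t_tests = list(exp_post = t_exp_post, exp_fu = t_exp_fu,
                   sham_post = t_sham_post, sham_fu = t_sham_fu),
    percent_reductions = c(exp_post = pr(exp_rows, "caps_post"),
                           exp_fu = pr(exp_rows, "caps_fu"),
                           sham_post = pr(!exp_rows, "caps_post"),
                           sham_fu = pr(!exp_rows, "caps_fu")),
    remission_rates = c(exp = remit(exp_rows), sham = remit(!exp_rows)))

  report <- list(
    leadfield = lf,
    maps = list(exp_pre = maps_exp_pre, sham_pre = maps_sham_pre,
                hc = maps_hc, exp_post = maps_exp_post,
                sham_post = maps_sham_post),
    baseline = baseline, rebound = rebound,
    masks = list(baseline = baseline$sig_mask, rebound = rebound$sig_mask,
                 conjunction = conj),
    conjunction_regions = lf$region_labels[conj],
    sessions = sessions, clinical = clinical, config = cfg)
  class(report) <- "trial_report"

  if (!is.null(out_dir)) write_trial_report(report, out_dir)
  report
}

#' @export
print.trial_report <- function(x, ...) {
  cat("<trial_report>\n")
  print(x$baseline)
  print(x$rebound)
  cat(sprintf("conjunction: %d source(s) [%s]\n", sum(x$masks$conjunction),
              paste(unique(x$conjunction_regions), collapse = ", ")))
  cat(sprintf("experimental %% CAPS reduction post/fu: %.1f / %.1f (dz %.2f / %.2f)\n",
              x$clinical$percent_reductions["exp_post"],
              x$clinical$percent_reductions["exp_fu"],
              x$clinical$t_tests$exp_post$dz, x$clinical$t_tests$exp_fu$dz))
  cat(sprintf("remission rate exp/sham: %.1f%% / %.1f%%\n",
              100 * x$clinical$remission_rates["exp"],
              100 * x$clinical$remission_rates["sham"]))
  invisible(x)
}

#' Write a trial report bundle to disk
#'
#' Writes the statistical maps and masks (JSON), the clinical table (CSV),
#' session percent-change matrices (CSV) and a manifest echoing the seed
#' and full configuration.
#'
#' @param report a [run_trial_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_trial_report <- function(report, out_dir) {
  stopifnot(inherits(report, "trial_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jw <- function(x, f) {
    jsonlite::write_json(x, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  sm <- function(s) {
    list(contrast = s$contrast_id, band = s$band$name,
         n_perm = s$n_perm, t = s$t_values, p = s$p_values,
         mask = s$sig_mask)
  }
  jw(list(baseline = sm(report$baseline), rebound = sm(report$rebound),
          conjunction = report$masks$conjunction,
          conjunction_regions = report$conjunction_regions),
     "stat_maps.json")
  jw(list(anova = unclass(report$clinical$anova),
          t_tests = report$clinical$t_tests,
          percent_reductions = as.list(report$clinical$percent_reductions),
          remission_rates = as.list(report$clinical$remission_rates)),
     "clinical_results.json")
  write.csv(report$clinical$table, file.path(out_dir, "clinical_table.csv"),
            row.names = FALSE)
  if (!is.null(report$sessions)) {
    write.csv(report$sessions$exp_session_mean,
              file.path(out_dir, "exp_session_percent_change.csv"),
              row.names = FALSE)
    write.csv(report$sessions$sham_session_mean,
              file.path(out_dir, "sham_session_percent_change.csv"),
              row.names = FALSE)
  }
  jw(list(seed = report$config$seed, package = "alphanfb",
          version = as.character(utils::packageVersion("alphanfb")),
          config = unclass(report$config)),
     "manifest.json")
  invisible(out_dir)
}

#' Export a session log as CSV
#'
#' @param log a `session_log`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  df <- log$log
  df$session <- log$session_number
  df$mode <- log$mode
  df$rest_baseline_amp <- log$rest_baseline_amp
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
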