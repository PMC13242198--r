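#' Default pipeline configuration
#'
#' A single serializable document (plain named list, JSON round-trippable)
#' describing a full synthetic experiment: two groups of
#' `n_subjects_per_group` subjects, each measured in a pre and a post
#' session of the cueing task, with reaction-time and (optionally) EEG
#' simulation and the full analysis chain. All stage seeds are derived from
#' the single top-level `seed`, so a config reproduces a run exactly.
#'
#' @param seed top-level RNG seed.
#' @param n_subjects_per_group subjects per group (default 9).
#' @param n_per_cell,n_valid_per_cell schedule stratification (defaults
#'   30/24, i.e. the 120-trial session).
#' @param sampling_rate EEG sampling rate, Hz.
#' @param run_eeg run the EEG branches (ERP, band power, DFA, cluster
#'   tests); reaction-time analysis always runs.
#' @param n_perm Monte Carlo iterations of the cluster permutation test.
#' @param lapse_rate,fast_guess_rate RT model rates.
#' @param rt_effects,eeg_effects optional overrides: `rt_effects` a cell
#'   table for [rt_model_spec()], `eeg_effects` an `effect_spec` list for
#'   [eeg_spec()].
#' @return Named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, n_subjects_per_group = 9L,
                            n_per_cell = 30L, n_valid_per_cell = 24L,
                            sampling_rate = 256, run_eeg = TRUE,
                            n_perm = 2000L, lapse_rate = 0.018,
                            fast_guess_rate = 0.035, rt_effects = NULL,
                            eeg_effects = NULL) {
  validate_config(list(seed = seed,
                       n_subjects_per_group = n_subjects_per_group,
                       n_per_cell = n_per_cell,
                       n_valid_per_cell = n_valid_per_cell,
                       sampling_rate = sampling_rate, run_eeg = run_eeg,
                       n_perm = n_perm, lapse_rate = lapse_rate,
                       fast_guess_rate = fast_guess_rate,
                       rt_effects = rt_effects, eeg_effects = eeg_effects))
}

#' Validate a pipeline configuration document
#'
#' Accepts a named list (e.g. parsed from JSON), checks every key against
#' the known schema and value ranges, injects defaults for absent keys and
#' returns the completed, typed configuration. Unknown keys and
#' out-of-range values raise descriptive errors naming the field.
#'
#' @param document named list (possibly empty) of configuration values.
#' @return Completed `run_config` list.
#' @export
validate_config <- function(document = list()) {
  defaults <- list(seed = 1L, n_subjects_per_group = 9L, n_per_cell = 30L,
                   n_valid_per_cell = 24L, sampling_rate = 256,
                   run_eeg = TRUE, n_perm = 2000L, lapse_rate = 0.018,
                   fast_guess_rate = 0.035, rt_effects = NULL,
                   eeg_effects = NULL)
  unknown <- setdiff(names(document), names(defaults))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, document, keep.null = TRUE)
  chk_num <- function(field, lo, hi = Inf) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi)
      stop("configuration field '", field, "' must be a number in [",
           lo, ", ", hi, "]")
  }
  chk_num("seed", -2^31, 2^31)
  chk_num("n_subjects_per_group", 2)
  chk_num("n_per_cell", 1)
  chk_num("n_valid_per_cell", 0, cfg$n_per_cell)
  chk_num("sampling_rate", 90)
  chk_num("n_perm", 1)
  chk_num("lapse_rate", 0, 1)
  chk_num("fast_guess_rate", 0, 1)
  if (!is.logical(cfg$run_eeg) || length(cfg$run_eeg) != 1)
    stop("configuration field 'run_eeg' must be TRUE or FALSE")
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full simulate-and-analyse pipeline
#'
#' Executes, in order: task-schedule and reaction-time simulation for every
#' subject and session; RT cleaning, categorization and summaries; the
#' 2 x 2 x 4 mixed ANOVA with planned Holm-corrected contrasts and
#' Bonferroni pairwise tests; optionally EEG simulation with ERP component
#' ANOVAs, CTI multitaper band power and DFA exponents with cluster-based
#' permutation tests (pre- vs post-active, paired); the blinding survey
#' McNemar check; and the design sensitivity analysis. Tabular results are
#' persisted as CSV, the run summary as JSON. Deterministic given the
#' configuration.
#'
#' @param config a [pipeline_config()] / [validate_config()] result.
#' @param out_dir output directory (created if missing).
#' @return List of class `run_report`: `outputs` (file paths per stage),
#'   `anova_rt`, `contrasts_rt`, `blinding`, `sensitivity`, and (when
#'   `run_eeg`) `anova_erp`, `cluster_results`; plus the echoed `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  save_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  sch_cfg <- schedule_config(n_per_cell = config$n_per_cell,
                             n_valid_per_cell = config$n_valid_per_cell)
  rt_model <- rt_model_spec(cells = config$rt_effects %||% default_rt_table(),
                            lapse_rate = config$lapse_rate,
                            fast_guess_rate = config$fast_guess_rate)
  groups <- c("sham", "active")
  subjects <- data.frame(
    subject = sprintf("s%02d", seq_len(2 * config$n_subjects_per_group)),
    group = rep(groups, each = config$n_subjects_per_group))

  # --- stage: simulate behaviour -------------------------------------------
  beh <- list()
  for (i in seq_len(nrow(subjects))) {
    for (sess in c("pre", "post")) {
      sd_i <- derive_seed(config$seed, paste("beh", subjects$subject[i], sess))
      sch <- generate_schedule(sch_cfg, seed = sd_i)
      beh[[paste(i, sess)]] <- simulate_rts(
        sch, rt_model, subject = subjects$subject[i],
        group = subjects$group[i], session = sess,
        seed = derive_seed(sd_i, "rt"))
    }
  }
  behavioral <- do.call(rbind, beh)
  rownames(behavioral) <- NULL
  save_csv(behavioral, "behavioral")

  # --- stage: behaviour analysis -------------------------------------------
  filt <- filter_rts(behavioral)
  cat_res <- categorize_trials(filt$table)
  save_csv(cat_res$table, "behavioral_clean")
  save_csv(filt$rejection, "rejection")
  summary_rt <- summarize_rt(cat_res$table)
  save_csv(summary_rt, "rt_summary")
  cond_means <- subject_condition_means(cat_res$table)
  save_csv(cond_means, "rt_condition_means")

  # --- stage: RT statistics ------------------------------------------------
  cond_means$session <- factor(cond_means$session, levels = c("pre", "post"))
  anova_rt <- mixed_anova(cond_means, dv = "mean_ms", subject = "subject",
                          between = "group",
                          within = c("session", "trial_type"))
  save_csv(as.data.frame(anova_rt), "anova_rt")
  contrasts_rt <- planned_contrasts(cond_means)
  save_csv(contrasts_rt, "contrasts_rt")

  # --- stage: EEG ----------------------------------------------------------
  anova_erp <- NULL
  cluster_results <- NULL
  if (config$run_eeg) {
    spec <- eeg_spec(sampling_rate = config$sampling_rate)
    if (!is.null(config$eeg_effects))
      spec$effect_spec <- config$eeg_effects
    erp_rows <- list()
    power_rows <- list()
    dfa_rows <- list()
    for (i in seq_len(nrow(subjects))) {
      for (sess in c("pre", "post")) {
        sd_i <- derive_seed(config$seed,
                            paste("eeg", subjects$subject[i], sess))
        sch <- generate_schedule(sch_cfg, seed = sd_i)
        eps <- simulate_epochs(sch, spec, subject = subjects$subject[i],
                               group = subjects$group[i], session = sess,
                               seed = derive_seed(sd_i, "sig"))
        tgt <- preprocess_epochs(eps$target)
        for (tt in unique(tgt$info$trial_type)) {
          erp <- extract_erp(subset_epochs(tgt, tgt$info$trial_type == tt))
          cm <- component_measures(erp)
          cm$subject <- subjects$subject[i]; cm$group <- subjects$group[i]
          cm$session <- sess; cm$trial_type <- tt
          erp_rows[[length(erp_rows) + 1]] <- cm
        }
        for (ct in unique(eps$cti$info$cue_type)) {
          sel <- subset_epochs(eps$cti, eps$cti$info$cue_type == ct)
          bp <- cti_band_power(sel)
          bp$subject <- subjects$subject[i]; bp$group <- subjects$group[i]
          bp$session <- sess; bp$cue_type <- ct
          power_rows[[length(power_rows) + 1]] <- bp
          da <- cti_dfa(sel)
          da$subject <- subjects$subject[i]; da$group <- subjects$group[i]
          da$session <- sess; da$cue_type <- ct
          dfa_rows[[length(dfa_rows) + 1]] <- da
        }
      }
    }
    erp_measures <- do.call(rbind, erp_rows)
    save_csv(erp_measures, "erp_measures")
    band_powers <- do.call(rbind, power_rows)
    save_csv(band_powers, "band_power")
    dfa_values <- do.call(rbind, dfa_rows)
    save_csv(dfa_values, "dfa")

    anova_erp <- list()
    for (comp in c("N1", "P3")) {
      for (meas in c("mean_amp_uv", "fal_ms")) {
        sub <- erp_measures[erp_measures$component == comp, ]
        sub$session <- factor(sub$session, levels = c("pre", "post"))
        tab <- mixed_anova(sub, dv = meas, subject = "subject",
                           between = "group",
                           within = c("session", "trial_type"))
        tab <- as.data.frame(tab)
        tab$component <- comp
        tab$measure <- meas
        anova_erp[[paste(comp, meas)]] <- tab
      }
    }
    anova_erp <- do.call(rbind, anova_erp)
    rownames(anova_erp) <- NULL
    save_csv(anova_erp, "anova_erp")

    adj <- montage_adjacency()
    to_matrix <- function(df, value) {
      act <- df[df$group == "active", ]
      pre <- act[act$session == "pre", ]
      post <- act[act$session == "post", ]
      chs <- default_montage()$label
      mk <- function(d) {
        w <- tapply(d[[value]], list(d$subject, d$channel), mean)
        w[, chs, drop = FALSE]
      }
      list(pre = mk(pre), post = mk(post))
    }
    cluster_results <- list()
    for (ct in c("endogenous", "exogenous")) {
      for (bd in c("alpha", "gamma")) {
        d <- band_powers[band_powers$band == bd & band_powers$cue_type == ct, ]
        mt <- to_matrix(d, "power_uv2")
        cluster_results[[paste("power", bd, ct)]] <-
          cluster_permutation(mt$pre, mt$post, adj, design = "paired",
                              n_perm = config$n_perm,
                              seed = derive_seed(config$seed,
                                                 paste("clu", bd, ct)))
      }
      d <- dfa_values[dfa_values$cue_type == ct, ]
      mt <- to_matrix(d, "alpha")
      cluster_results[[paste("dfa", ct)]] <-
        cluster_permutation(mt$pre, mt$post, adj, design = "paired",
                            n_perm = config$n_perm,
                            seed = derive_seed(config$seed,
                                               paste("clu dfa", ct)))
    }
    clu_df <- do.call(rbind, lapply(names(cluster_results), function(nm) {
      cl <- cluster_results[[nm]]$clusters
      if (nrow(cl) == 0) return(NULL)
      data.frame(comparison = nm, sign = cl$sign, mass = cl$mass,
                 p_perm = cl$p_perm,
                 electrodes = vapply(cl$electrodes, paste,
                                     character(1), collapse = "|"))
    }))
    save_csv(clu_df %||%
               data.frame(comparison = character(), sign = numeric(),
                          mass = numeric(), p_perm = numeric(),
                          electrodes = character()), "clusters")
  }

  # --- stage: blinding + sensitivity ---------------------------------------
  blind_tab <- generate_blinding_table(
    n_per_group = config$n_subjects_per_group,
    seed = derive_seed(config$seed, "blinding"))
  blinding <- mcnemar_cc(blind_tab)
  sens <- list(primary = min_detectable_d(config$n_subjects_per_group,
                                          alpha = 0.05, power = 0.80),
               follow_up = min_detectable_d(config$n_subjects_per_group,
                                            alpha = 0.0125, power = 0.80))
  report <- list(
    config = unclass(config),
    outputs = paths,
    blinding = list(table = unclass(blind_tab)[, ],
                    chi_sq = blinding$chi_sq, p = blinding$p),
    sensitivity = list(d_min_alpha05 = sens$primary$d_min,
                       d_min_alpha0125 = sens$follow_up$d_min),
    anova_rt_interaction_p =
      anova_rt$p[anova_rt$effect == "group:session"])
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  structure(list(outputs = paths, report_path = report_path,
                 anova_rt = anova_rt, contrasts_rt = contrasts_rt,
                 summary_rt = summary_rt, anova_erp = anova_erp,
                 cluster_results = cluster_results, blinding = blinding,
                 sensitivity = sens, config = config),
            class = "run_report")
}
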