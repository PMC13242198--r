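#' Schedule configuration for one Posner cueing session
#'
#' The default configuration reproduces the session structure of the task:
#' 120 trials, split 50/50 between endogenous (central arrow) and exogenous
#' (peripheral flash) cues, 50/50 between cue-target intervals (CTI) of 0.5
#' and 1.0 s, giving 30 trials per cue-type-by-CTI cell, of which exactly 24
#' are valid (target at the cued side) and 6 invalid. Per-trial durations are
#' fixed per (cue type, CTI) class; the default session therefore always
#' lasts 523.92 s.
#'
#' @param n_per_cell trials in each cue-type-by-CTI cell (default 30).
#' @param n_valid_per_cell valid trials per cell (default 24, i.e. 80%).
#' @param cue_types,ctis factor levels of the stratification.
#' @param durations named numeric vector of per-trial durations in seconds,
#'   names `"<cue_type>_<cti>"`.
#' @return A list of class `schedule_config`.
#' @export
schedule_config <- function(n_per_cell = 30L,
                            n_valid_per_cell = 24L,
                            cue_types = c("endogenous", "exogenous"),
                            ctis = c(0.5, 1.0),
                            durations = c(endogenous_0.5 = 4.55,
                                          endogenous_1 = 5.05,
                                          exogenous_0.5 = 3.682,
                                          exogenous_1 = 4.182)) {
  n_per_cell <- as.integer(n_per_cell)
  n_valid_per_cell <- as.integer(n_valid_per_cell)
  if (is.na(n_per_cell) || n_per_cell < 0)
    stop("n_per_cell must be a non-negative integer")
  if (is.na(n_valid_per_cell) || n_valid_per_cell < 0)
    stop("n_valid_per_cell must be a non-negative integer")
  if (n_valid_per_cell > n_per_cell)
    stop("n_valid_per_cell (", n_valid_per_cell,
         ") exceeds n_per_cell (", n_per_cell, ")")
  need <- as.vector(outer(cue_types, ctis, function(a, b) paste0(a, "_", b)))
  missing_dur <- setdiff(need, names(durations))
  if (length(missing_dur) > 0)
    stop("durations missing for class(es): ", paste(missing_dur, collapse = ", "))
  structure(list(n_per_cell = n_per_cell,
                 n_valid_per_cell = n_valid_per_cell,
                 cue_types = cue_types, ctis = ctis,
                 durations = durations),
            class = "schedule_config")
}

#' Generate a stratified task schedule
#'
#' Cell counts are stratified-exact, not Bernoulli: every cue-type-by-CTI
#' cell receives exactly `n_per_cell` trials of which exactly
#' `n_valid_per_cell` are valid, for any seed. Cue side is drawn 50/50 per
#' trial; the target side equals the cue side on valid trials and the
#' opposite side on invalid trials. Trial order is a uniform shuffle driven
#' by `seed`, so identical (config, seed) pairs give identical schedules.
#'
#' @param config a [schedule_config()].
#' @param seed integer RNG seed.
#' @return A data.frame of class `task_schedule` with columns `index`,
#'   `cue_type`, `cue_side`, `validity`, `target_side`, `cti_s`,
#'   `trial_duration_s`.
#' @export
#' @examples
#' sch <- generate_schedule(seed = 1)
#' table(sch$cue_type, sch$cti_s)         # 30 per cell
#' schedule_duration(sch)                 # 523.92
generate_schedule <- function(config = schedule_config(), seed = 1L) {
  stopifnot(inherits(config, "schedule_config"))
  with_seed(seed, {
    rows <- list()
    for (ct in config$cue_types) {
      for (cti in config$ctis) {
        n <- config$n_per_cell
        if (n == 0) next
        nv <- config$n_valid_per_cell
        validity <- c(rep("valid", nv), rep("invalid", n - nv))
        cue_side <- sample(c("left", "right"), n, replace = TRUE)
        target_side <- ifelse(validity == "valid", cue_side,
                              ifelse(cue_side == "left", "right", "left"))
        rows[[paste0(ct, cti)]] <- data.frame(
          cue_type = ct, cue_side = cue_side, validity = validity,
          target_side = target_side, cti_s = cti,
          trial_duration_s = unname(config$durations[paste0(ct, "_", cti)]),
          stringsAsFactors = FALSE)
      }
    }
    sch <- do.call(rbind, rows)
    if (is.null(sch)) {
      sch <- data.frame(cue_type = character(), cue_side = character(),
                        validity = character(), target_side = character(),
                        cti_s = numeric(), trial_duration_s = numeric())
    } else {
      sch <- sch[sample.int(nrow(sch)), , drop = FALSE]
    }
    sch <- cbind(index = seq_len(nrow(sch)), sch)
    rownames(sch) <- NULL
    attr(sch, "seed") <- as.integer(seed)
    class(sch) <- c("task_schedule", "data.frame")
    sch
  })
}

#' Total duration of a task schedule
#'
#' Exact sum of per-trial durations; a default 120-trial session sums to
#' 523.92 s. An empty schedule has duration 0.
#'
#' @param schedule a `task_schedule`.
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(is.data.frame(schedule), "trial_duration_s" %in% names(schedule))
  if (nrow(schedule) == 0) return(0)
  sum(schedule$trial_duration_s)
}

#' Four trial types of the cueing task
#' @return Character vector: Endo-Valid, Endo-Invalid, Exo-Valid, Exo-Invalid.
#' @export
trial_types <- function() {
  c("Endo-Valid", "Endo-Invalid", "Exo-Valid", "Exo-Invalid")
}

# Map (cue_type, validity) -> trial type label.
trial_type_label <- function(cue_type, validity) {
  ok_ct <- cue_type %in% c("endogenous", "exogenous")
  ok_v <- validity %in% c("valid", "invalid")
  if (!all(ok_ct)) stop("unknown cue_type: ", unique(cue_type[!ok_ct])[1])
  if (!all(ok_v)) stop("unknown validity: ", unique(validity[!ok_v])[1])
  paste0(ifelse(cue_type == "endogenous", "Endo", "Exo"),
         "-", ifelse(validity == "valid", "Valid", "Invalid"))
}

#' Reaction-time cell means and SDs (ms) of the study conditions
#'
#' Per group (sham/active), session (pre/post) and trial type, the mean and
#' standard deviation of reaction time in milliseconds used as generator
#' defaults. The pre/post structure encodes both the practice effect in the
#' sham group and the larger post-stimulation speed-up in the active group,
#' which is absent for Exo-Invalid trials.
#'
#' @return data.frame with columns `group`, `session`, `trial_type`,
#'   `mean_ms`, `sd_ms`.
#' @export
default_rt_table <- function() {
  tt <- trial_types()
  grid <- expand.grid(trial_type = tt, session = c("pre", "post"),
                      group = c("sham", "active"), stringsAsFactors = FALSE)
  grid <- grid[, c("group", "session", "trial_type")]
  grid$mean_ms <- c(334.7, 428.8, 353.3, 373.8,   # sham pre
                    329.5, 419.1, 343.9, 361.6,   # sham post
                    334.1, 422.0, 357.6, 372.2,   # active pre
                    311.2, 388.4, 312.3, 366.0)   # active post
  grid$sd_ms <- c(51.4, 94.1, 67.0, 68.8,
                  67.2, 86.0, 80.7, 63.5,
                  80.3, 125.8, 109.3, 90.5,
                  60.8, 86.6, 75.7, 88.4)
  grid
}

#' Reaction-time generating model
#'
#' Reaction times are drawn from a normal distribution truncated at zero,
#' with the cell mean/SD looked up per (group, session, trial type). With
#' probability `lapse_rate` a trial produces no response (missing RT); with
#' probability `fast_guess_rate` it produces an anticipatory keypress
#' uniform on [0, 100) ms. The default rates jointly reproduce the ~5%
#' per-subject trial loss the cleaning stage is expected to remove.
#'
#' @param cells data.frame like [default_rt_table()].
#' @param lapse_rate probability of a missing response.
#' @param fast_guess_rate probability of an anticipatory (<100 ms) response.
#' @return List of class `rt_model_spec`.
#' @export
rt_model_spec <- function(cells = default_rt_table(),
                          lapse_rate = 0.018, fast_guess_rate = 0.035) {
  stopifnot(is.data.frame(cells),
            all(c("group", "session", "trial_type", "mean_ms", "sd_ms")
                %in% names(cells)))
  if (any(cells$sd_ms < 0)) stop("sd_ms must be >= 0")
  if (lapse_rate < 0 || lapse_rate > 1 ||
      fast_guess_rate < 0 || fast_guess_rate > 1)
    stop("lapse_rate and fast_guess_rate must lie in [0, 1]")
  structure(list(cells = cells, lapse_rate = lapse_rate,
                 fast_guess_rate = fast_guess_rate),
            class = "rt_model_spec")
}

#' Simulate reaction times for a schedule
#'
#' @param schedule a [generate_schedule()] result.
#' @param model an [rt_model_spec()].
#' @param subject,group,session labels attached to every row.
#' @param seed integer RNG seed.
#' @return A behavioural table: data.frame with columns `subject`, `group`,
#'   `session`, `trial_index`, `cue_type`, `cue_side`, `validity`, `cti_s`,
#'   `rt_s` (seconds; `NA` = no response).
#' @export
simulate_rts <- function(schedule, model = rt_model_spec(),
                         subject = "s01", group = "sham", session = "pre",
                         seed = 1L) {
  stopifnot(inherits(model, "rt_model_spec"))
  tt <- trial_type_label(schedule$cue_type, schedule$validity)
  key <- paste(group, session, tt)
  cells <- model$cells
  ckey <- paste(cells$group, cells$session, cells$trial_type)
  idx <- match(key, ckey)
  if (anyNA(idx)) {
    stop("rt model has no parameters for cell(s): ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  }
  m <- cells$mean_ms[idx]
  s <- cells$sd_ms[idx]
  n <- nrow(schedule)
  with_seed(seed, {
    # truncated-at-zero normal via inverse CDF; degenerate sd = point mass
    u <- stats::runif(n)
    p0 <- stats::pnorm(0, m, ifelse(s > 0, s, 1))
    rt_ms <- ifelse(s > 0,
                    stats::qnorm(p0 + u * (1 - p0), m, ifelse(s > 0, s, 1)),
                    m)
    kind <- stats::runif(n)
    rt_ms[kind < model$fast_guess_rate] <-
      stats::runif(sum(kind < model$fast_guess_rate), 0, 100)
    lapse <- kind >= model$fast_guess_rate &
      kind < model$fast_guess_rate + model$lapse_rate
    rt_ms[lapse] <- NA_real_
    data.frame(subject = subject, group = group, session = session,
               trial_index = schedule$index, cue_type = schedule$cue_type,
               cue_side = schedule$cue_side, validity = schedule$validity,
               cti_s = schedule$cti_s, rt_s = rt_ms / 1000,
               stringsAsFactors = FALSE)
  })
}

#' Generate a 2x2 blinding contingency table
#'
#' Rows are the conditioned (true) stimulation group, columns the group the
#' subject reported in the post-session blinding survey. In stochastic mode
#' each row is a binomial draw with the given probability of reporting
#' "active"; `fixed_counts` instead sets the table deterministically (e.g.
#' the study's observed (7, 2; 6, 3)).
#'
#' @param n_per_group subjects per conditioned group.
#' @param report_probabilities length-2 numeric: P(report active | active),
#'   P(report active | sham).
#' @param fixed_counts optional 2x2 matrix of counts overriding simulation.
#' @param seed integer RNG seed.
#' @return 2x2 integer matrix of class `contingency_2x2`, rows
#'   `cond_active`/`cond_sham`, columns `report_active`/`report_sham`, with
#'   attribute `usable` (FALSE when the total count is zero).
#' @export
generate_blinding_table <- function(n_per_group = 9L,
                                    report_probabilities = c(0.75, 0.6),
                                    fixed_counts = NULL, seed = 1L) {
  if (!is.null(fixed_counts)) {
    tab <- matrix(as.integer(fixed_counts), 2, 2)
  } else {
    if (any(report_probabilities < 0) || any(report_probabilities > 1))
      stop("report_probabilities must lie in [0, 1]")
    if (n_per_group < 0) stop("n_per_group must be >= 0")
    tab <- with_seed(seed, {
      ra <- stats::rbinom(1, n_per_group, report_probabilities[1])
      rs <- stats::rbinom(1, n_per_group, report_probabilities[2])
      matrix(as.integer(c(ra, rs, n_per_group - ra, n_per_group - rs)), 2, 2)
    })
  }
  if (any(tab < 0)) stop("counts must be non-negative")
  dimnames(tab) <- list(c("cond_active", "cond_sham"),
                        c("report_active", "report_sham"))
  structure(tab, usable = sum(tab) > 0, class = c("contingency_2x2", "matrix"))
}
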