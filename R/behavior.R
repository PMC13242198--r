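#' Filter reaction times to the genuine-response window
#'
#' Removes anticipatory responses faster than `lo` and extremely slow
#' responses above `hi`, plus trials without a response. The retention
#' interval is closed: RTs exactly at 0.1 s or 1.0 s are kept, because the
#' rejection rules are strictly "< 100 ms" and "> 1 s". Per-subject rejected
#' fractions are reported alongside the filtered table.
#'
#' @param table behavioural table as produced by [simulate_rts()].
#' @param lo,hi retention bounds in seconds (defaults 0.1 and 1.0).
#' @return List with `table` (retained rows) and `rejection` (data.frame
#'   `subject`, `n_total`, `n_rejected`, `fraction`; `fraction` is `NaN` and
#'   flagged `undefined` for subjects with no trials).
#' @export
filter_rts <- function(table, lo = 0.1, hi = 1.0) {
  stopifnot(is.data.frame(table), "rt_s" %in% names(table))
  if (lo >= hi) stop("lo must be < hi")
  keep <- !is.na(table$rt_s) & table$rt_s >= lo & table$rt_s <= hi
  subjects <- unique(table$subject)
  if (length(subjects) == 0) {
    rej <- data.frame(subject = character(), n_total = integer(),
                      n_rejected = integer(), fraction = numeric(),
                      undefined = logical())
  } else {
    n_tot <- vapply(subjects, function(s) sum(table$subject == s), integer(1))
    n_rej <- vapply(subjects, function(s)
      sum(table$subject == s & !keep), integer(1))
    rej <- data.frame(subject = subjects, n_total = n_tot,
                      n_rejected = n_rej, fraction = n_rej / n_tot,
                      undefined = n_tot == 0, row.names = NULL)
  }
  list(table = table[keep, , drop = FALSE], rejection = rej)
}

#' Label trials by cue-type and validity combination
#'
#' Adds a `trial_type` column with the four labels Endo-Valid, Endo-Invalid,
#' Exo-Valid, Exo-Invalid (a bijection on the cue_type x validity grid) and
#' returns the per-label counts.
#'
#' @param table behavioural table with `cue_type` and `validity` columns.
#' @return List with `table` (labelled) and `counts` (named integer vector
#'   over all four labels).
#' @export
categorize_trials <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("cue_type", "validity") %in% names(table)))
  table$trial_type <- if (nrow(table) > 0)
    trial_type_label(table$cue_type, table$validity) else character(0)
  counts <- vapply(trial_types(), function(l) sum(table$trial_type == l),
                   integer(1))
  list(table = table, counts = counts)
}

#' Summarize reaction times
#'
#' Means and SDs in milliseconds with 95% t-based confidence intervals.
#' Inference follows the subject-as-unit convention: when several subjects
#' fall in one summary group, per-subject means are computed first and the
#' CI is taken over subjects, not trials. Groups with fewer than two
#' subjects get an undefined (NA) CI and are flagged.
#'
#' @param table behavioural table including `trial_type` (see
#'   [categorize_trials()]).
#' @param by character vector of grouping columns
#'   (default `c("group", "session", "trial_type")`).
#' @param conf confidence level (default 0.95).
#' @return data.frame with `by` columns plus `n_trials`, `n_subjects`,
#'   `mean_ms`, `sd_ms`, `ci_lo`, `ci_hi`, `ci_undefined`.
#' @export
summarize_rt <- function(table, by = c("group", "session", "trial_type"),
                         conf = 0.95) {
  stopifnot(is.data.frame(table), all(by %in% names(table)),
            "rt_s" %in% names(table))
  key <- interaction(table[by], drop = TRUE, lex.order = TRUE)
  out <- lapply(levels(key), function(k) {
    rows <- table[key == k, , drop = FALSE]
    rt_ms <- rows$rt_s * 1000
    subj_means <- tapply(rt_ms, rows$subject, mean)
    ns <- length(subj_means)
    if (ns >= 2) {
      se <- stats::sd(subj_means) / sqrt(ns)
      hw <- stats::qt(1 - (1 - conf) / 2, ns - 1) * se
      ci <- mean(subj_means) + c(-hw, hw)
      undef <- FALSE
    } else {
      ci <- c(NA_real_, NA_real_)
      undef <- TRUE
    }
    cbind(rows[1, by, drop = FALSE],
          data.frame(n_trials = nrow(rows), n_subjects = ns,
                     mean_ms = mean(rt_ms), sd_ms = stats::sd(rt_ms),
                     ci_lo = ci[1], ci_hi = ci[2], ci_undefined = undef))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-subject condition means for inferential analysis
#'
#' Collapses a cleaned, categorized behavioural table to exactly one mean RT
#' (ms) per subject x session x trial type, the unit of analysis for the
#' mixed ANOVA and planned contrasts.
#'
#' @param table cleaned behavioural table with `trial_type`.
#' @return data.frame `subject`, `group`, `session`, `trial_type`, `mean_ms`.
#' @export
subject_condition_means <- function(table) {
  stopifnot(all(c("subject", "group", "session", "trial_type", "rt_s")
                %in% names(table)))
  agg <- stats::aggregate(rt_s ~ subject + group + session + trial_type,
                          data = table, FUN = mean)
  agg$mean_ms <- agg$rt_s * 1000
  agg$rt_s <- NULL
  agg[order(agg$subject, agg$session, agg$trial_type), ]
}

#' Write / read a behavioural table as CSV
#' @param table behavioural table.
#' @param path file path.
#' @return `write_behavioral` invisibly returns `path`; `read_behavioral`
#'   returns the table.
#' @export
write_behavioral <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavioral
#' @export
read_behavioral <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
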