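#' Mixed repeated-measures ANOVA (one between, one or two within factors)
#'
#' Classical univariate mixed-design analysis for a balanced, complete
#' design with exactly one observation per subject per within-factor cell.
#' Sums of squares are computed by explicit decomposition of cell means:
#' the between-subject effect is tested against subjects-within-groups,
#' and every within effect (and its interaction with the between factor)
#' against the corresponding factor-by-subject-within-groups error stratum.
#' Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error_for_that_effect)`. No sphericity
#' correction is applied, so degrees of freedom are the integer textbook
#' values.
#'
#' @param data data.frame in long format.
#' @param dv name of the numeric response column.
#' @param subject name of the subject identifier column.
#' @param between name of the between-subject factor column.
#' @param within character vector of one or two within-subject factor
#'   column names.
#' @return data.frame of class `anova_table`: `effect`, `df_num`, `df_den`,
#'   `ss`, `ss_error`, `F`, `p`, `partial_eta_sq`.
#' @export
mixed_anova <- function(data, dv, subject, between, within) {
  stopifnot(is.data.frame(data),
            all(c(dv, subject, between, within) %in% names(data)),
            length(within) %in% c(1L, 2L))
  y <- data[[dv]]
  if (!is.numeric(y)) stop("response must be numeric")
  s <- factor(data[[subject]])
  a <- factor(data[[between]])
  # group per subject must be unique
  g_of_s <- tapply(as.character(a), s, function(v) {
    u <- unique(v)
    if (length(u) != 1) stop("subject assigned to more than one group")
    u
  })
  g_of_s <- factor(g_of_s, levels = levels(a))
  n_a <- table(g_of_s)
  if (any(n_a < 2)) stop("each group needs at least 2 subjects")
  ws <- lapply(within, function(w) factor(data[[w]]))
  cells <- interaction(c(list(s), ws), drop = FALSE)
  cnt <- table(cells)
  if (any(cnt != 1))
    stop("design is not balanced/complete: expected exactly one ",
         "observation per subject per within cell")
  N <- length(y)
  m <- mean(y)
  mean_by <- function(...) tapply(y, list(...), mean)
  dev2 <- function(x) sum(x^2)

  m_a <- mean_by(a); m_s <- mean_by(s)
  eff <- list()
  add_eff <- function(name, ss, df1, ss_err, df2) {
    ms_e <- ss_err / df2
    Fv <- if (ss <= 1e-12) 0 else (ss / df1) / ms_e
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    pes <- if (ss + ss_err > 0) ss / (ss + ss_err) else 0
    data.frame(effect = name, df_num = df1, df_den = df2, ss = ss,
               ss_error = ss_err, F = Fv, p = p, partial_eta_sq = pes,
               stringsAsFactors = FALSE)
  }
  la <- nlevels(a)
  n_s <- nlevels(s)
  n_within_cells <- prod(vapply(ws, nlevels, integer(1)))

  # between-subjects stratum
  ss_A <- n_within_cells * sum(n_a * (m_a - m)^2)
  ss_SA <- n_within_cells * dev2(m_s - m_a[g_of_s])
  df_SA <- n_s - la
  eff[[between]] <- add_eff(between, ss_A, la - 1, ss_SA, df_SA)

  if (length(ws) == 1) {
    b <- ws[[1]]; lb <- nlevels(b)
    m_b <- mean_by(b); m_ab <- mean_by(a, b); m_sb <- mean_by(s, b)
    ss_B <- n_s * dev2(m_b - m)
    ab_dev <- sweep(sweep(m_ab, 1, m_a, "-"), 2, m_b, "-") + m
    ss_AB <- sum(rep(n_a, lb) * ab_dev^2)
    # residual stratum B x S(A)
    res <- m_sb - as.vector(m_s) -
      m_ab[cbind(as.integer(g_of_s)[as.vector(row(m_sb))], as.vector(col(m_sb)))] +
      as.vector(m_a[g_of_s])
    ss_BSA <- dev2(res)
    df_BSA <- (lb - 1) * df_SA
    eff[[within[1]]] <- add_eff(within[1], ss_B, lb - 1, ss_BSA, df_BSA)
    eff[[paste(between, within[1], sep = ":")]] <-
      add_eff(paste(between, within[1], sep = ":"), ss_AB,
              (la - 1) * (lb - 1), ss_BSA, df_BSA)
  } else {
    b <- ws[[1]]; cc <- ws[[2]]
    lb <- nlevels(b); lc <- nlevels(cc)
    m_b <- mean_by(b); m_c <- mean_by(cc)
    m_ab <- mean_by(a, b); m_ac <- mean_by(a, cc); m_bc <- mean_by(b, cc)
    m_abc <- mean_by(a, b, cc)
    m_sb <- mean_by(s, b); m_sc <- mean_by(s, cc)
    gi <- as.integer(g_of_s)

    ss_B <- n_s * lc * dev2(m_b - m)
    ss_C <- n_s * lb * dev2(m_c - m)
    ab_dev <- sweep(sweep(m_ab, 1, m_a, "-"), 2, m_b, "-") + m
    ss_AB <- lc * sum(rep(n_a, lb) * ab_dev^2)
    ac_dev <- sweep(sweep(m_ac, 1, m_a, "-"), 2, m_c, "-") + m
    ss_AC <- lb * sum(rep(n_a, lc) * ac_dev^2)
    bc_dev <- sweep(sweep(m_bc, 1, m_b, "-"), 2, m_c, "-") + m
    ss_BC <- n_s * dev2(bc_dev)
    abc_dev <- m_abc
    for (ia in seq_len(la)) for (ib in seq_len(lb)) for (ic in seq_len(lc))
      abc_dev[ia, ib, ic] <- m_abc[ia, ib, ic] - m_ab[ia, ib] -
        m_ac[ia, ic] - m_bc[ib, ic] + m_a[ia] + m_b[ib] + m_c[ic] - m
    ss_ABC <- sum(rep(n_a, lb * lc) * abc_dev^2)

    res_sb <- m_sb - as.vector(m_s) -
      m_ab[cbind(gi[as.vector(row(m_sb))], as.vector(col(m_sb)))] + as.vector(m_a[g_of_s])
    ss_BSA <- lc * dev2(res_sb)
    res_sc <- m_sc - as.vector(m_s) -
      m_ac[cbind(gi[as.vector(row(m_sc))], as.vector(col(m_sc)))] + as.vector(m_a[g_of_s])
    ss_CSA <- lb * dev2(res_sc)

    si <- as.integer(s); bi <- as.integer(b); ci <- as.integer(cc)
    fit <- m_sb[cbind(si, bi)] + m_sc[cbind(si, ci)] +
      m_abc[cbind(gi[si], bi, ci)] - m_ab[cbind(gi[si], bi)] -
      m_ac[cbind(gi[si], ci)] - m_s[si] + m_a[gi[si]]
    ss_BCSA <- dev2(y - fit)

    df_BSA <- (lb - 1) * df_SA
    df_CSA <- (lc - 1) * df_SA
    df_BCSA <- (lb - 1) * (lc - 1) * df_SA
    nm <- function(...) paste(..., sep = ":")
    eff[[within[1]]] <- add_eff(within[1], ss_B, lb - 1, ss_BSA, df_BSA)
    eff[[nm(between, within[1])]] <-
      add_eff(nm(between, within[1]), ss_AB, (la - 1) * (lb - 1),
              ss_BSA, df_BSA)
    eff[[within[2]]] <- add_eff(within[2], ss_C, lc - 1, ss_CSA, df_CSA)
    eff[[nm(between, within[2])]] <-
      add_eff(nm(between, within[2]), ss_AC, (la - 1) * (lc - 1),
              ss_CSA, df_CSA)
    eff[[nm(within[1], within[2])]] <-
      add_eff(nm(within[1], within[2]), ss_BC, (lb - 1) * (lc - 1),
              ss_BCSA, df_BCSA)
    eff[[nm(between, within[1], within[2])]] <-
      add_eff(nm(between, within[1], within[2]), ss_ABC,
              (la - 1) * (lb - 1) * (lc - 1), ss_BCSA, df_BCSA)
  }
  out <- do.call(rbind, eff)
  rownames(out) <- NULL
  attr(out, "ss_subjects") <- ss_SA
  attr(out, "ss_total") <- dev2(y - m)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' t-test with Cohen's d
#'
#' Two-sided paired or independent (pooled-variance) t-test. Cohen's d is
#' the mean difference divided by the SD of differences (paired) or the
#' pooled SD (independent). Identical inputs with zero variance follow the
#' convention t = 0, p = 1.
#'
#' @param a,b numeric vectors (matched order when `mode = "paired"`).
#' @param mode "paired" or "independent".
#' @return List: `t`, `df`, `p`, `cohen_d`, `mode`.
#' @export
ttest <- function(a, b, mode = c("paired", "independent")) {
  mode <- match.arg(mode)
  if (mode == "paired") {
    if (length(a) != length(b)) stop("paired vectors must match in length")
    if (length(a) < 2) stop("need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
      tv <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      return(list(t = tv, df = length(d) - 1,
                  p = if (tv == 0) 1 else 0, cohen_d = tv, mode = mode))
    }
    ht <- stats::t.test(a, b, paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, cohen_d = mean(d) / stats::sd(d), mode = mode)
  } else {
    if (length(a) < 2 || length(b) < 2) stop("need at least 2 per sample")
    sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
      (length(a) + length(b) - 2)
    if (sp2 == 0) {
      tv <- if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b))
      return(list(t = tv, df = length(a) + length(b) - 2,
                  p = if (tv == 0) 1 else 0, cohen_d = tv, mode = mode))
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value, cohen_d = (mean(a) - mean(b)) / sqrt(sp2),
         mode = mode)
  }
}

#' Multiple-comparison adjustment of p-values
#'
#' Single-step Bonferroni, step-down Holm, or step-up Benjamini-Hochberg
#' false-discovery-rate adjustment, clipped at 1 with monotonicity
#' enforced (delegates to [stats::p.adjust()]).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param method "bonferroni", "holm" or "bh_fdr".
#' @param m family size (defaults to `length(p)`).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "holm", "bh_fdr"),
                           m = length(p)) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method, bonferroni = "bonferroni",
                                     holm = "holm", bh_fdr = "BH"), n = m)
}

# Same-sign connected components of supra-threshold electrodes with >= 2
# members; returns list of integer vectors. adj_list: neighbours per node.
find_clusters <- function(tvals, threshold, adj_list) {
  supra <- which(abs(tvals) > threshold)
  if (length(supra) < 2) return(list())
  in_supra <- logical(length(tvals))
  in_supra[supra] <- TRUE
  visited <- logical(length(tvals))
  clusters <- list()
  for (v in supra) {
    if (visited[v]) next
    # BFS over same-sign supra-threshold neighbours
    comp <- integer(0)
    queue <- v
    visited[v] <- TRUE
    sgn <- sign(tvals[v])
    while (length(queue) > 0) {
      node <- queue[1]; queue <- queue[-1]
      comp <- c(comp, node)
      for (nb in adj_list[[node]]) {
        if (!visited[nb] && in_supra[nb] && sign(tvals[nb]) == sgn) {
          visited[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    if (length(comp) >= 2) clusters[[length(clusters) + 1]] <- sort(comp)
  }
  clusters
}

adjacency_to_list <- function(adj) {
  lapply(seq_len(nrow(adj)), function(i) which(adj[i, ]))
}

#' Cluster-based sensor-space permutation test
#'
#' Electrode-wise t-statistics (paired or pooled independent) are
#' thresholded at the two-sided critical value for `threshold_p`; clusters
#' are connected components of two or more adjacent supra-threshold
#' electrodes with identical t-value signs, scored by the summed t
#' (cluster mass). Significance is Monte Carlo: the observed |mass| is
#' referred to the permutation distribution of the maximum |mass| under
#' random within-subject sign flips (paired) or group-label shuffles
#' (independent), with the add-one convention
#' `p = (1 + #{null >= observed}) / (n_perm + 1)` and a conservative
#' `>=` tie rule.
#'
#' @param values_a,values_b subject x electrode matrices (matched rows for
#'   the paired design).
#' @param adjacency symmetric logical electrode adjacency matrix whose
#'   dimnames cover the electrode columns.
#' @param design "paired" or "independent".
#' @param threshold_p electrode-level threshold (default 0.05, two-sided).
#' @param n_perm number of Monte Carlo permutations (default 2000).
#' @param seed integer RNG seed.
#' @return List of class `cluster_result`: `clusters` (data.frame with
#'   `electrodes` list-column, `sign`, `mass`, `p_perm`), `t` (electrode
#'   t-values), `threshold`, `n_permutations`, `null_max_mass`.
#' @export
cluster_permutation <- function(values_a, values_b, adjacency,
                                design = c("paired", "independent"),
                                threshold_p = 0.05, n_perm = 2000,
                                seed = 1L) {
  design <- match.arg(design)
  stopifnot(is.matrix(values_a), is.matrix(values_b),
            ncol(values_a) == ncol(values_b))
  ne <- ncol(values_a)
  labels <- colnames(values_a) %||% rownames(adjacency)[seq_len(ne)]
  if (!all(labels %in% rownames(adjacency)))
    stop("adjacency graph is missing electrode(s): ",
         paste(setdiff(labels, rownames(adjacency)), collapse = ", "))
  adj <- adjacency[labels, labels]
  adj_list <- adjacency_to_list(adj)
  if (n_perm < 100)
    warning("n_perm < 100 gives a very coarse permutation p-value")

  if (design == "paired") {
    if (nrow(values_a) != nrow(values_b))
      stop("paired design requires matched subjects")
    D <- values_a - values_b
    ns <- nrow(D)
    if (ns < 2) stop("need at least 2 subjects")
    df <- ns - 1
    tfun_signs <- function(sgn) {
      M <- colMeans(D * sgn)
      V <- (colSums(D^2) - ns * M^2) / (ns - 1)
      M / sqrt(V / ns)
    }
    t_obs <- tfun_signs(rep(1, ns))
  } else {
    na <- nrow(values_a); nb <- nrow(values_b)
    if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
    X <- rbind(values_a, values_b)
    df <- na + nb - 2
    tfun_labels <- function(idx_a) {
      xa <- X[idx_a, , drop = FALSE]
      xb <- X[-idx_a, , drop = FALSE]
      va <- apply(xa, 2, stats::var); vb <- apply(xb, 2, stats::var)
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / df
      (colMeans(xa) - colMeans(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
    }
    t_obs <- tfun_labels(seq_len(na))
  }
  threshold <- stats::qt(1 - threshold_p / 2, df)
  obs_clusters <- find_clusters(t_obs, threshold, adj_list)
  obs_mass <- vapply(obs_clusters, function(cl) sum(t_obs[cl]), numeric(1))

  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      tp <- if (design == "paired") {
        tfun_signs(sample(c(-1, 1), nrow(values_a), replace = TRUE))
      } else {
        tfun_labels(sample.int(nrow(values_a) + nrow(values_b),
                               nrow(values_a)))
      }
      cl <- find_clusters(tp, threshold, adj_list)
      if (length(cl) == 0) 0
      else max(abs(vapply(cl, function(x) sum(tp[x]), numeric(1))))
    }, numeric(1))
  })
  p_perm <- vapply(obs_mass, function(mm)
    (1 + sum(null_max >= abs(mm))) / (n_perm + 1), numeric(1))
  clusters <- data.frame(
    sign = if (length(obs_mass)) sign(obs_mass) else numeric(0),
    mass = obs_mass, p_perm = p_perm)
  clusters$electrodes <- lapply(obs_clusters, function(cl) labels[cl])
  structure(list(clusters = clusters, t = stats::setNames(t_obs, labels),
                 threshold = threshold, threshold_p = threshold_p,
                 n_permutations = n_perm, null_max_mass = null_max,
                 design = design),
            class = "cluster_result")
}

#' Continuity-corrected McNemar test on a 2x2 blinding table
#'
#' Uses the discordant cells b (conditioned active, reported sham) and c
#' (conditioned sham, reported active):
#' `chi^2 = (max(|b - c| - 1, 0))^2 / (b + c)`, referred to chi-square with
#' one degree of freedom. The correction is floored at zero so b = c gives
#' chi^2 = 0, p = 1.
#'
#' @param table a 2x2 matrix (e.g. [generate_blinding_table()]), or `NULL`
#'   when `b`/`c` are given directly.
#' @param b,c discordant cell counts (overridden by `table`).
#' @return List: `chi_sq`, `p`, `b`, `c`.
#' @export
mcnemar_cc <- function(table = NULL, b = NULL, c = NULL) {
  if (!is.null(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    b <- table[1, 2]
    c <- table[2, 1]
  }
  if (is.null(b) || is.null(c)) stop("supply a 2x2 table or both b and c")
  if (b + c == 0) stop("no discordant pairs; McNemar test undefined")
  chi <- (max(abs(b - c) - 1, 0))^2 / (b + c)
  list(chi_sq = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE),
       b = b, c = c)
}

# Power of the two-sample pooled t-test at standardized difference d.
two_sample_power <- function(d, n_per_group, alpha, sides = 2) {
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (sides == 2) {
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    stats::pt(tc, df, ncp, lower.tail = FALSE)
  }
}

#' Minimum detectable standardized effect of a two-group design
#'
#' Solves the noncentral-t power equation of the two-sample t-test for the
#' standardized difference d at which the design attains the requested
#' power — the design-sensitivity question "what is the smallest effect
#' this n can reliably detect?". Applied to pre/post change scores
#' compared between groups, n = 9 per group at two-sided alpha 0.05 and
#' 80% power gives d of about 1.41 (about 1.75 at the
#' multiplicity-adjusted alpha 0.0125). Solved by bisection to 1e-6.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param alpha type-I error rate.
#' @param power target power, must exceed `alpha`.
#' @param sides 1 or 2 (default two-sided).
#' @return List of class `sensitivity_solution`: `d_min`, `n_per_group`,
#'   `alpha`, `power`, `sides`, `achieved_power`.
#' @export
min_detectable_d <- function(n_per_group, alpha = 0.05, power = 0.80,
                             sides = 2) {
  if (n_per_group < 2) stop("need at least 2 subjects per group")
  if (power <= alpha) stop("requested power must exceed alpha")
  f <- function(d) two_sample_power(d, n_per_group, alpha, sides) - power
  lo <- 0; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  d <- (lo + hi) / 2
  structure(list(d_min = d, n_per_group = n_per_group, alpha = alpha,
                 power = power, sides = sides,
                 achieved_power = two_sample_power(d, n_per_group, alpha,
                                                   sides)),
            class = "sensitivity_solution")
}

#' Planned between-group contrasts of pre/post change per trial type
#'
#' For each trial type, the pre-to-post change score is computed per
#' subject and compared between active and sham groups with an independent
#' t-test; multiplicity across the four trial types is controlled by Holm
#' step-down adjustment.
#'
#' @param cond_means data.frame from [subject_condition_means()].
#' @param value name of the response column (default "mean_ms").
#' @return data.frame `trial_type`, `delta_active`, `delta_sham`, `t`,
#'   `df`, `p`, `p_holm`, `cohen_d`.
#' @export
planned_contrasts <- function(cond_means, value = "mean_ms") {
  tts <- unique(cond_means$trial_type)
  rows <- lapply(tts, function(tt) {
    sub <- cond_means[cond_means$trial_type == tt, ]
    wide <- stats::reshape(sub[, c("subject", "group", "session", value)],
                           idvar = c("subject", "group"),
                           timevar = "session", direction = "wide")
    delta <- wide[[paste0(value, ".post")]] - wide[[paste0(value, ".pre")]]
    act <- delta[wide$group == "active"]
    sham <- delta[wide$group == "sham"]
    tt_res <- ttest(act, sham, mode = "independent")
    data.frame(trial_type = tt, delta_active = mean(act),
               delta_sham = mean(sham), t = tt_res$t, df = tt_res$df,
               p = tt_res$p, cohen_d = tt_res$cohen_d)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- adjust_pvalues(out$p, "holm")
  out
}
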