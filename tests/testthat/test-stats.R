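test_that("mixed ANOVA matches the aov error-strata oracle to 1e-8", {
  d <- make_mixed_data(n_per_group = 9, shift = 2, seed = 42)
  tab <- mixed_anova(d, "y", "subject", "group", c("session", "trial_type"))
  oracle <- summary(aov(y ~ group * session * trial_type +
                          Error(subject / (session * trial_type)),
                        data = d))
  f_oracle <- unlist(lapply(oracle, function(x) {
    fv <- x[[1]][["F value"]]
    fv[!is.na(fv)]
  }), use.names = FALSE)
  # aov stratum order: group | session, group:session | trial_type,
  # group:trial_type | session:trial_type, group:session:trial_type
  f_mine <- tab$F[match(c("group", "session", "group:session",
                          "trial_type", "group:trial_type",
                          "session:trial_type",
                          "group:session:trial_type"), tab$effect)]
  expect_equal(f_mine, f_oracle, tolerance = 1e-8)
  expect_equal(tab$df_num, c(1, 1, 1, 3, 3, 3, 3))
  expect_equal(tab$df_den, c(16, 16, 16, 48, 48, 48, 48))
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
})

test_that("single-within-factor ANOVA matches aov as well", {
  d <- make_mixed_data(n_per_group = 6, n_tt = 1, shift = 1, seed = 7)
  d$trial_type <- NULL
  tab <- mixed_anova(d, "y", "subject", "group", "session")
  oracle <- summary(aov(y ~ group * session + Error(subject / session),
                        data = d))
  f_oracle <- unlist(lapply(oracle, function(x) {
    fv <- x[[1]][["F value"]]; fv[!is.na(fv)]
  }), use.names = FALSE)
  expect_equal(tab$F, f_oracle, tolerance = 1e-8)
})

test_that("sums of squares decompose the total exactly", {
  d <- make_mixed_data(n_per_group = 4, shift = 1.3, seed = 11)
  tab <- mixed_anova(d, "y", "subject", "group", c("session", "trial_type"))
  parts <- sum(tab$ss) + attr(tab, "ss_subjects") +
    sum(unique(tab[, c("df_den", "ss_error")])$ss_error) -
    tab$ss_error[tab$effect == "group"]      # subjects term counted once
  expect_equal(parts, attr(tab, "ss_total"), tolerance = 1e-8)
})

test_that("constant responses give F = 0 throughout", {
  d <- make_mixed_data(n_per_group = 3, seed = 1)
  d$y <- 5
  tab <- mixed_anova(d, "y", "subject", "group", c("session", "trial_type"))
  expect_true(all(tab$F == 0))
  expect_true(all(tab$p == 1))
})

test_that("unbalanced or underpowered designs are rejected", {
  d <- make_mixed_data(n_per_group = 3, seed = 2)
  expect_error(mixed_anova(d[-1, ], "y", "subject", "group",
                           c("session", "trial_type")), "balanced")
  d2 <- make_mixed_data(n_per_group = 1, seed = 2)
  expect_error(mixed_anova(d2, "y", "subject", "group",
                           c("session", "trial_type")), "at least 2")
})

test_that("null type-I rate of the interaction is near nominal", {
  set.seed(19)
  rej <- replicate(500, {
    d <- expand.grid(subject = 1:18, session = c("pre", "post"),
                     tt = paste0("T", 1:4))
    d$group <- ifelse(d$subject <= 9, "sham", "active")
    d$y <- rnorm(nrow(d))
    tab <- mixed_anova(d, "y", "subject", "group", c("session", "tt"))
    tab$p[tab$effect == "group:session"] < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("t-tests match textbook formulas on a hand fixture", {
  a <- c(1, 2, 3, 4); b <- c(2, 2, 5, 7)
  # paired: d = a - b = (-1, 0, -2, -3); mean -1.5, sd sqrt(5/3)
  r <- ttest(a, b, "paired")
  expect_equal(r$t, -1.5 / (sqrt(5 / 3) / 2), tolerance = 1e-12)
  expect_equal(r$df, 3)
  expect_equal(r$cohen_d, -1.5 / sqrt(5 / 3), tolerance = 1e-12)
  # independent pooled
  r2 <- ttest(a, b, "independent")
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  expect_equal(r2$t, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(r2$df, 6)
  # degenerate equal inputs
  r3 <- ttest(c(1, 1, 1), c(1, 1, 1), "paired")
  expect_equal(r3$t, 0)
  expect_equal(r3$p, 1)
  expect_error(ttest(1, 1, "paired"), "at least 2")
})

test_that("a d = 2 shift is detected with high power at n = 9", {
  set.seed(23)
  hits <- replicate(1000, {
    ttest(rnorm(9, 2), rnorm(9, 0), "independent")$p < 0.05
  })
  expect_gte(mean(hits), 0.95)
})

test_that("p-value adjustments match hand-worked fixtures", {
  expect_equal(adjust_pvalues(c(.01, .02, .03, .04), "holm"),
               c(.04, .06, .06, .06))
  expect_equal(adjust_pvalues(.02, "bonferroni", m = 4), .08)
  expect_equal(adjust_pvalues(c(.01, .04), "bh_fdr"), c(.02, .04))
  expect_error(adjust_pvalues(c(0.5, 1.2), "holm"), "\\[0, 1\\]")
  # dominance relations on random families
  set.seed(2)
  for (i in 1:10) {
    p <- runif(6)
    expect_true(all(adjust_pvalues(p, "holm") >= p))
    expect_true(all(adjust_pvalues(p, "bh_fdr") <=
                      adjust_pvalues(p, "bonferroni") + 1e-12))
  }
})

test_that("a single isolated supra-threshold electrode forms no cluster", {
  # line graph a-b-c plus isolated d; only d carries the effect
  labels <- c("a", "b", "c", "d")
  adj <- matrix(FALSE, 4, 4, dimnames = list(labels, labels))
  adj["a", "b"] <- adj["b", "a"] <- TRUE
  adj["b", "c"] <- adj["c", "b"] <- TRUE
  set.seed(6)
  pre <- matrix(rnorm(9 * 4), 9, 4, dimnames = list(NULL, labels))
  post <- pre + cbind(0, 0, 0, 5 + rnorm(9, sd = 0.1))
  res <- cluster_permutation(post, pre, adj, "paired", n_perm = 200,
                             seed = 1)
  expect_gt(abs(res$t["d"]), res$threshold)
  expect_equal(nrow(res$clusters), 0)
})

test_that("clusters require identical t-value signs", {
  labels <- c("a", "b")
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2,
                dimnames = list(labels, labels))
  set.seed(7)
  pre <- matrix(rnorm(10 * 2, sd = 0.2), 10, 2,
                dimnames = list(NULL, labels))
  post <- pre + cbind(3 + rnorm(10, sd = 0.1), -3 + rnorm(10, sd = 0.1))
  res <- cluster_permutation(post, pre, adj, "paired", n_perm = 200,
                             seed = 2)
  expect_true(all(abs(res$t) > res$threshold))
  expect_equal(nrow(res$clusters), 0)      # opposite signs cannot join
})

test_that("permutation p-values respect their analytic bounds", {
  adj <- montage_adjacency()
  set.seed(10)
  pre <- matrix(rnorm(9 * 32), 9, 32, dimnames = list(NULL, rownames(adj)))
  post <- pre + matrix(rnorm(9 * 32, 1.2), 9, 32)
  res <- cluster_permutation(post, pre, adj, "paired", n_perm = 400,
                             seed = 3)
  if (nrow(res$clusters) > 0) {
    expect_true(all(res$clusters$p_perm >= 1 / 401))
    expect_true(all(res$clusters$p_perm <= 1))
    expect_true(all(vapply(res$clusters$electrodes, length, integer(1)) >= 2))
  }
  expect_warning(cluster_permutation(post, pre, adj, "paired",
                                     n_perm = 50, seed = 1), "coarse")
  expect_error(cluster_permutation(post[, 1:5], pre[, 1:5],
                                   adj[1:4, 1:4], "paired", seed = 1),
               "missing electrode")
})

test_that("cluster inference is invariant to graph-preserving relabeling", {
  # left-right mirror of the montage is an adjacency automorphism
  m <- default_montage()
  mirror <- m
  mirror$x <- -mirror$x
  map <- vapply(seq_len(nrow(m)), function(i)
    which(abs(m$x - mirror$x[i]) < 1e-9 & abs(m$y - mirror$y[i]) < 1e-9),
    integer(1))
  adj <- montage_adjacency(m)
  set.seed(15)
  pre <- matrix(rnorm(9 * 32), 9, 32, dimnames = list(NULL, m$label))
  post <- pre
  post[, c("PO3", "P3", "O1")] <- post[, c("PO3", "P3", "O1")] +
    matrix(rnorm(9 * 3, 1.5), 9, 3)
  r1 <- cluster_permutation(post, pre, adj, "paired", n_perm = 300,
                            seed = 4)
  r2 <- cluster_permutation(post[, map], pre[, map], adj, "paired",
                            n_perm = 300, seed = 4)
  expect_equal(sort(r1$clusters$p_perm), sort(r2$clusters$p_perm))
  expect_equal(sort(abs(r1$clusters$mass)), sort(abs(r2$clusters$mass)),
               tolerance = 1e-12)
})

test_that("independent-design permutation runs and detects group shifts", {
  adj <- montage_adjacency()
  set.seed(44)
  ga <- matrix(rnorm(9 * 32), 9, 32, dimnames = list(NULL, rownames(adj)))
  gb <- matrix(rnorm(9 * 32), 9, 32, dimnames = list(NULL, rownames(adj)))
  gb[, c("PO3", "P3", "O1")] <- gb[, c("PO3", "P3", "O1")] + 2.5
  res <- cluster_permutation(gb, ga, adj, "independent", n_perm = 400,
                             seed = 5)
  expect_gt(nrow(res$clusters), 0)
  best <- res$clusters[which.min(res$clusters$p_perm), ]
  expect_lt(best$p_perm, 0.05)
  expect_gte(length(intersect(best$electrodes[[1]],
                              c("PO3", "P3", "O1"))), 2)
})

test_that("McNemar reproduces the blinding-survey statistic", {
  tab <- generate_blinding_table(fixed_counts = matrix(c(7, 6, 2, 3), 2, 2))
  r <- mcnemar_cc(tab)
  expect_equal(r$chi_sq, 9 / 8)                  # = 1.125 exactly
  expect_equal(r$p, 0.2888, tolerance = 1e-3)
  # agrees with the stock continuity-corrected implementation
  sr <- stats::mcnemar.test(unclass(tab)[, ], correct = TRUE)
  expect_equal(r$chi_sq, unname(sr$statistic))
  expect_equal(r$p, sr$p.value)
  # symmetry and the floored correction
  expect_equal(mcnemar_cc(b = 6, c = 2)$chi_sq, 9 / 8)
  r0 <- mcnemar_cc(b = 3, c = 3)
  expect_equal(r0$chi_sq, 0)
  expect_equal(r0$p, 1)
  expect_error(mcnemar_cc(b = 0, c = 0), "discordant")
})

test_that("sensitivity solver round-trips and matches power.t.test", {
  s <- min_detectable_d(9, alpha = 0.05, power = 0.80)
  expect_equal(s$achieved_power, 0.80, tolerance = 1e-4)
  expect_equal(s$d_min, power.t.test(n = 9, power = 0.8,
                                     sig.level = 0.05)$delta,
               tolerance = 1e-3)
  # large-n normal approximation: d ~ (z_{.975} + z_{.80}) * sqrt(2/n)
  big <- min_detectable_d(10000)
  approx <- (qnorm(0.975) + qnorm(0.80)) * sqrt(2 / 10000)
  expect_equal(big$d_min, approx, tolerance = 0.001)
})

test_that("minimum detectable d is monotone in n, power and alpha", {
  expect_gt(min_detectable_d(6)$d_min, min_detectable_d(12)$d_min)
  expect_gt(min_detectable_d(9, power = 0.9)$d_min,
            min_detectable_d(9, power = 0.8)$d_min)
  expect_gt(min_detectable_d(9, alpha = 0.01)$d_min,
            min_detectable_d(9, alpha = 0.05)$d_min)
  expect_error(min_detectable_d(1), "at least 2")
  expect_error(min_detectable_d(9, alpha = 0.5, power = 0.4), "exceed")
})

test_that("planned contrasts detect a planted group x time change", {
  set.seed(33)
  cm <- expand.grid(subject = sprintf("s%02d", 1:18),
                    session = c("pre", "post"),
                    trial_type = trial_types(), stringsAsFactors = FALSE)
  cm$group <- ifelse(as.integer(sub("s", "", cm$subject)) <= 9,
                     "sham", "active")
  cm$mean_ms <- 350 + rnorm(nrow(cm), sd = 8) -
    30 * (cm$group == "active" & cm$session == "post" &
            cm$trial_type == "Endo-Valid")
  pc <- planned_contrasts(cm)
  expect_equal(nrow(pc), 4)
  expect_lt(pc$p_holm[pc$trial_type == "Endo-Valid"], 0.05)
  expect_true(all(pc$p_holm >= pc$p))
})
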