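test_that("signed-rank p-values reproduce the small-sample exact values", {
  x <- c(0.9, 0.8, 0.7, 0.85, 0.75, 0.95)
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(x, x)), 1)
  # n all-positive distinct differences: one-sided exact p = 1 / 2^n
  d6 <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(x + d6, x)), 1 / 64)
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(x[1:5] + d6[1:5], x[1:5])),
               1 / 32)
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(x[1:4] + d6[1:4], x[1:4])),
               1 / 16) # n = 4 can never reach alpha = 0.05
  expect_error(wilcoxon_signed_rank_one_sided(1:3, 1:4),
               class = "segrank_data_error")
})

test_that("exact p-values agree with full sign enumeration and wilcox.test", {
  set.seed(51)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    a <- runif(n)
    b <- runif(n)
    if (i %% 4 == 0) b[1] <- a[1] # occasional zero difference, discarded
    p <- as.numeric(wilcoxon_signed_rank_one_sided(a, b))
    expect_equal(p, oracle_signed_rank_p(a, b), tolerance = 1e-12)
    if (!any(a == b)) {
      ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                                 alternative = "greater",
                                                 exact = TRUE)$p.value)
      expect_equal(p, ref, tolerance = 1e-12)
    }
  }
})

test_that("tied and large samples use the corrected normal approximation", {
  set.seed(52)
  # ties in |differences| force the approximation
  a <- c(1, 2, 3, 4, 5, 6, 7, 8) + 0.5
  b <- c(2, 1, 4, 3, 6, 5, 8, 7)
  p <- wilcoxon_signed_rank_one_sided(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                             alternative = "greater",
                                             exact = FALSE, correct = TRUE)$p.value)
  expect_false(attr(p, "exact"))
  expect_equal(as.numeric(p), ref, tolerance = 1e-12)
  # n beyond the exact switchover
  a2 <- runif(40); b2 <- runif(40)
  p2 <- wilcoxon_signed_rank_one_sided(a2, b2)
  ref2 <- suppressWarnings(stats::wilcox.test(a2, b2, paired = TRUE,
                                              alternative = "greater",
                                              exact = FALSE, correct = TRUE)$p.value)
  expect_false(attr(p2, "exact"))
  expect_equal(as.numeric(p2), ref2, tolerance = 1e-12)
  # all differences zero: no evidence, p = 1
  expect_equal(as.numeric(wilcoxon_signed_rank_one_sided(a, a)), 1)
})

test_that("significance scores count significantly worse competitors", {
  # identical teams: nothing is significant
  m <- matrix(rep(runif(6), 3), 6, 3, dimnames = list(NULL, c("A", "B", "C")))
  tb <- table_from_matrix(m)
  expect_identical(significance_scores(tb, "T1", "organ", "DSC"),
                   c(A = 0L, B = 0L, C = 0L))
  # strict ordering A > B > C on 6 cases: exact p = 1/64 < 0.05 each way down
  m2 <- cbind(A = seq(0.7, 0.95, length.out = 6),
              B = seq(0.4, 0.65, length.out = 6),
              C = seq(0.1, 0.35, length.out = 6))
  tb2 <- table_from_matrix(m2)
  expect_identical(significance_scores(tb2, "T1", "organ", "DSC"),
                   c(A = 2L, B = 1L, C = 0L))
  # 2 teams, 4 cases, untied differences: p = 1/16 >= 0.05 -> no significance
  m3 <- cbind(A = c(0.9, 0.8, 0.85, 0.95), B = c(0.1, 0.2, 0.16, 0.25))
  expect_identical(significance_scores(table_from_matrix(m3), "T1", "organ", "DSC"),
                   c(A = 0L, B = 0L))
  expect_error(significance_scores(tb2, "T9", "organ", "DSC"),
               class = "segrank_data_error")
})

test_that("ranks follow the descending-score mid-rank convention", {
  expect_equal(ranks_from_scores(c(A = 2, B = 1, C = 0)), c(A = 1, B = 2, C = 3))
  expect_equal(ranks_from_scores(c(A = 2, B = 0, C = 0)),
               c(A = 1, B = 2.5, C = 2.5))
  # 19 teams, two tied at positions 15 and 16 -> shared rank 15.5
  scores <- c(seq(30, 17, by = -1), 5, 5, 3, 2, 1)
  names(scores) <- sprintf("t%02d", 1:19)
  r <- ranks_from_scores(scores)
  expect_equal(unname(r[15:16]), c(15.5, 15.5))
  expect_equal(sum(r), 19 * 20 / 2)
})

test_that("rank aggregation averages metrics, ROIs and tasks", {
  expect_equal(aggregate_roi_rank(c(DSC = 1, NSD = 1)), 1)
  expect_equal(aggregate_roi_rank(c(DSC = 1, NSD = 3)), 2)
  expect_equal(aggregate_roi_rank(c(DSC = 2.5, NSD = 2.5)), 2.5)
  expect_error(aggregate_roi_rank(c(DSC = 1)), class = "segrank_data_error")
  expect_equal(aggregate_task_rank(2), 2)
  expect_equal(aggregate_task_rank(c(1, 2, 3)), 2)
  expect_equal(aggregate_task_rank(c(1.5, 2.5)), 2)
})

test_that("phase ranking averages task ranks and shares tied final ranks", {
  tr <- data.frame(task = rep(c("a", "b", "c"), each = 2),
                   team = rep(c("X", "Y"), 3),
                   rank = c(1, 2, 1, 2, 1, 2))
  out <- phase_ranking(tr)
  expect_equal(out$phase_score[out$team == "X"], 1)
  expect_equal(out$final_rank[out$team == "X"], 1)
  # equal phase scores -> shared mid-rank
  tr2 <- data.frame(task = rep(c("a", "b"), each = 2),
                    team = rep(c("X", "Y"), 2), rank = c(1, 2, 2, 1))
  out2 <- phase_ranking(tr2)
  expect_equal(out2$final_rank, c(1.5, 1.5))
  expect_error(phase_ranking(tr[-1, ]), class = "segrank_data_error")
})

test_that("rank sums are conserved in every ranking unit", {
  set.seed(61)
  for (rep in 1:8) {
    nt <- sample(3:6, 1)
    teams <- lapply(seq_len(nt), function(i)
      team_profile(sprintf("tm%02d", i), beta_mean = runif(1, 0.3, 0.9),
                   beta_sd = 0.1))
    cfg <- cohort_config(
      tasks = list(task_spec("T1", "development", c(a = 1, b = 2), 2),
                   task_spec("T2", "mystery", c(c = 1), 3)),
      n_cases = sample(5:10, 1), teams = teams, seed = rep)
    rk <- rank_teams(simulate_metric_table(cfg), task_specs = cfg$tasks)
    S <- nt * (nt + 1) / 2
    sums <- aggregate(rank ~ task + roi + metric, rk$scores, sum)
    expect_true(all(abs(sums$rank - S) < 1e-9))
    expect_true(all(rk$scores$rank >= 1 & rk$scores$rank <= nt))
    expect_true(all(rk$scores$score <= nt - 1))
    expect_true(all(abs(aggregate(rank ~ task + roi, rk$roi_ranks, sum)$rank - S) < 1e-9))
    expect_true(all(abs(aggregate(rank ~ task, rk$task_ranks, sum)$rank - S) < 1e-9))
    expect_true(all(abs(aggregate(final_rank ~ phase, rk$phases, sum)$final_rank - S) < 1e-9))
    # a team scoring N_A - 1 has rank exactly 1
    top <- rk$scores[rk$scores$score == nt - 1, , drop = FALSE]
    if (nrow(top) > 0) expect_true(all(top$rank == 1))
  }
})

test_that("dominance gives descending scores and ranks 1..N", {
  tb <- dominance_table(n_teams = 4, n_cases = 8)
  rk <- rank_teams(tb)
  sc <- rk$scores[rk$scores$metric == "DSC", ]
  sc <- sc[order(sc$team), ]
  expect_equal(sc$score, c(3L, 2L, 1L, 0L))
  expect_equal(sc$rank, c(1, 2, 3, 4))
  ph <- rk$phases[order(rk$phases$team), ]
  expect_equal(ph$final_rank, c(1, 2, 3, 4))
})

test_that("scores are invariant to case order and duplicate teams", {
  tb <- dominance_table(n_teams = 3, n_cases = 8)
  # shuffle case labels: paired values travel with the case, scores unchanged
  set.seed(71)
  perm <- sample(unique(tb$case))
  shuffled <- tb
  shuffled$case <- perm[match(tb$case, unique(tb$case))]
  expect_identical(significance_scores(metric_table(shuffled), "T1", "organ", "DSC"),
                   significance_scores(tb, "T1", "organ", "DSC"))
  # adding an exact copy of team01 never changes original pairwise outcomes:
  # the clone is never significantly worse than its twin (p = 1), so the
  # original teams keep their scores and the clone mirrors team01
  copy <- tb[tb$team == "team01", ]
  copy$team <- "team99"
  s0 <- significance_scores(tb, "T1", "organ", "DSC")
  s1 <- significance_scores(metric_table(rbind(tb, copy)), "T1", "organ", "DSC")
  expect_identical(s1[names(s0)], s0)
  expect_identical(s1[["team99"]], s0[["team01"]])
})

test_that("per_roi and per_task schemes disagree only via multi-ROI weighting", {
  teams <- list(team_profile("u", beta_mean = 0.85, beta_sd = 0.08),
                team_profile("v", beta_mean = 0.75, beta_sd = 0.08),
                team_profile("w", beta_mean = 0.6, beta_sd = 0.08))
  cfg <- cohort_config(
    tasks = list(task_spec("multi", "development", c(a = 1, b = 2, c = 3), 2),
                 task_spec("single", "development", c(d = 1), 3)),
    n_cases = 8, teams = teams, seed = 13)
  tb <- simulate_metric_table(cfg)
  rk_task <- rank_teams(tb, task_specs = cfg$tasks, scheme = "per_task")
  rk_roi <- rank_teams(tb, task_specs = cfg$tasks, scheme = "per_roi")
  expect_identical(rk_task$scheme, "per_task")
  expect_identical(rk_roi$scheme, "per_roi")
  # per-task: mean of 2 task ranks; per-roi: mean of 4 roi ranks
  tX <- rk_task$task_ranks[rk_task$task_ranks$team == "u", "rank"]
  expect_equal(rk_task$phases$phase_score[rk_task$phases$team == "u"], mean(tX))
  rX <- rk_roi$roi_ranks[rk_roi$roi_ranks$team == "u", "rank"]
  expect_equal(rk_roi$phases$phase_score[rk_roi$phases$team == "u"], mean(rX))
})

test_that("identical teams share the middle rank everywhere", {
  vals <- runif(8)
  m <- matrix(rep(vals, 3), 8, 3, dimnames = list(NULL, c("A", "B", "C")))
  rk <- rank_teams(table_from_matrix(m))
  expect_true(all(rk$phases$final_rank == 2))
  expect_true(all(rk$task_ranks$rank == 2))
})
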