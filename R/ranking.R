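#' One-sided Wilcoxon signed-rank test for paired per-case metrics
#'
#' Tests H1 "`values_a` tends to exceed `values_b`" on the paired
#' differences `values_a - values_b`. Zero differences are discarded
#' before ranking (the classic signed-rank convention; Pratt handling of
#' zeros is available via `zero_method = "pratt"`). The exact null
#' distribution is used when the number of non-zero differences is at
#' most `exact_max_n` and their absolute values are untied; otherwise a
#' mid-rank normal approximation with continuity and tie correction is
#' applied. When all differences are zero there is no evidence either way
#' and `p = 1`.
#'
#' @param values_a,values_b equal-length numeric vectors paired by case.
#' @param alternative `"greater"` (default; the directional reading used
#'   for significance scoring) or `"two.sided"`.
#' @param zero_method `"discard"` (default) or `"pratt"`.
#' @param exact_max_n switchover from exact to asymptotic null (default 25).
#' @return The p-value. Attribute `"exact"` records whether the exact
#'   null distribution was used.
#' @examples
#' wilcoxon_signed_rank_one_sided(seq(0.2, 0.7, 0.1) + 0.05, seq(0.2, 0.7, 0.1))
#' @export
wilcoxon_signed_rank_one_sided <- function(values_a, values_b,
                                           alternative = c("greater", "two.sided"),
                                           zero_method = c("discard", "pratt"),
                                           exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  zero_method <- match.arg(zero_method)
  if (length(values_a) != length(values_b))
    stop_segrank("segrank_data_error",
                 "paired samples must have equal length")
  if (length(values_a) < 1L)
    stop_segrank("segrank_data_error", "need at least one pair")
  d <- as.numeric(values_a) - as.numeric(values_b)
  if (any(!is.finite(d)))
    stop_segrank("segrank_data_error", "non-finite paired differences")
  n_all <- length(d)
  nz <- d != 0
  n <- sum(nz)
  if (n == 0L) return(structure(1, exact = TRUE))

  if (zero_method == "discard") {
    dd <- d[nz]
    r <- rank(abs(dd))
    w <- sum(r[dd > 0])
    tied <- anyDuplicated(r) > 0L
    if (!tied && n <= exact_max_n) {
      p <- switch(alternative,
        greater = stats::psignrank(w - 1, n, lower.tail = FALSE),
        two.sided = min(1, 2 * min(stats::psignrank(w, n),
                                   stats::psignrank(w - 1, n, lower.tail = FALSE))))
      return(structure(p, exact = TRUE))
    }
    mu <- n * (n + 1) / 4
    nties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(nties^3 - nties) / 48
  } else {
    # Pratt: rank |d| including zeros, drop the zero contributions
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    n0 <- n_all - n
    mu <- n_all * (n_all + 1) / 4 - n0 * (n0 + 1) / 4
    nties <- table(r[nz])
    sigma2 <- n_all * (n_all + 1) * (2 * n_all + 1) / 24 -
      n0 * (n0 + 1) * (2 * n0 + 1) / 24 - sum(nties^3 - nties) / 48
  }
  if (sigma2 <= 0) return(structure(1, exact = FALSE))
  z <- w - mu
  p <- switch(alternative,
    greater = stats::pnorm((z - 0.5) / sqrt(sigma2), lower.tail = FALSE),
    two.sided = 2 * stats::pnorm((abs(z) - 0.5) / sqrt(sigma2),
                                 lower.tail = FALSE))
  structure(min(1, max(0, p)), exact = FALSE)
}

# case x team value matrix for one (task, roi, metric) slice
slice_matrix <- function(table, task, roi, metric) {
  s <- table[table$task == task & table$roi == roi & table$metric == metric, ,
             drop = FALSE]
  if (nrow(s) == 0L)
    stop_segrank("segrank_data_error",
                 paste0("no records for task '", task, "', roi '", roi,
                        "', metric '", metric, "'"))
  teams <- sort(unique(s$team))
  cases <- sort(unique(s$case))
  m <- matrix(NA_real_, length(cases), length(teams),
              dimnames = list(cases, teams))
  m[cbind(match(s$case, cases), match(s$team, teams))] <- s$value
  if (any(is.na(m))) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop_segrank("segrank_data_error",
                 paste0("incomplete block for task '", task, "', roi '", roi,
                        "', metric '", metric, "': missing ",
                        paste(paste0("(", colnames(m)[bad[, 2]], ", ",
                                     rownames(m)[bad[, 1]], ")"),
                              collapse = ", ")))
  }
  m
}

#' Significance scores for one (task, ROI, metric) slice
#'
#' For each team, counts the number of competitors performing
#' significantly worse: competitor `b` counts towards team `a`'s score
#' when the one-sided Wilcoxon signed-rank test of `a` over `b` on the
#' paired per-case values yields `p < alpha`. Following the benchmark
#' protocol, `alpha` is per comparison and not adjusted for multiplicity.
#'
#' @param table a [metric_table] (complete block).
#' @param task,roi,metric the slice to score.
#' @param alpha per-comparison significance level (default 0.05).
#' @param ... passed to [wilcoxon_signed_rank_one_sided()].
#' @return Named integer vector of scores in `[0, n_teams - 1]`.
#' @export
significance_scores <- function(table, task, roi, metric, alpha = 0.05, ...) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop_segrank("segrank_config_error", "alpha must lie in (0, 1)")
  m <- slice_matrix(table, task, roi, metric)
  score_matrix_slice(m, alpha, ...)
}

score_matrix_slice <- function(m, alpha, ...) {
  teams <- colnames(m)
  nt <- length(teams)
  scores <- integer(nt)
  names(scores) <- teams
  if (nt < 2L) return(scores)
  for (a in seq_len(nt)) {
    for (b in seq_len(nt)) {
      if (a == b) next
      p <- wilcoxon_signed_rank_one_sided(m[, a], m[, b], ...)
      if (p < alpha) scores[a] <- scores[a] + 1L
    }
  }
  scores
}

#' Ranks from significance scores
#'
#' Highest score receives rank 1; tied scores share the mean of the
#' positions they occupy (mid-rank convention), so fractional shared
#' ranks such as 15.5 are possible.
#'
#' @param scores named numeric vector (higher = better).
#' @return Named numeric vector of ranks in `[1, n]` summing to
#'   `n(n+1)/2`.
#' @examples
#' ranks_from_scores(c(A = 2, B = 0, C = 0))
#' @export
ranks_from_scores <- function(scores) {
  if (length(scores) < 1L)
    stop_segrank("segrank_data_error", "need at least one team")
  r <- rank(-as.numeric(scores), ties.method = "average")
  names(r) <- names(scores)
  r
}

#' Aggregate per-metric ranks into a per-ROI rank
#'
#' The benchmark defines significance ranks separately for DSC and NSD;
#' the per-ROI rank is their arithmetic mean (mirroring the documented
#' per-ROI to per-task averaging).
#'
#' @param per_metric_ranks named numeric vector with entries `DSC` and `NSD`.
#' @return The mean rank.
#' @export
aggregate_roi_rank <- function(per_metric_ranks) {
  if (!all(c("DSC", "NSD") %in% names(per_metric_ranks)))
    stop_segrank("segrank_data_error",
                 "per-ROI aggregation needs ranks for both DSC and NSD")
  mean(as.numeric(per_metric_ranks[c("DSC", "NSD")]))
}

#' Aggregate per-ROI ranks into a per-task rank
#'
#' @param roi_ranks numeric vector of per-ROI ranks (>= 1 entry).
#' @return The arithmetic mean of the per-ROI ranks (possibly fractional).
#' @export
aggregate_task_rank <- function(roi_ranks) {
  roi_ranks <- as.numeric(roi_ranks)
  if (length(roi_ranks) < 1L || any(!is.finite(roi_ranks)))
    stop_segrank("segrank_data_error", "need at least one finite ROI rank")
  mean(roi_ranks)
}

#' Phase score and final ranking
#'
#' With the default `per_task` scheme the phase score of a team is the
#' mean of its per-task ranks over the phase's tasks; the alternative
#' `per_roi` scheme averages over all (task, ROI) ranks ignoring task
#' grouping (over-weighting multi-ROI tasks, which is why `per_task` is
#' the default). Final ranks are assigned ascending in phase score (lower
#' mean rank = better) with mid-rank ties.
#'
#' @param task_ranks data frame with columns `task`, `team`, `rank`
#'   (for `scheme = "per_roi"` pass ROI-level rows, one per (task, roi)).
#' @param scheme `"per_task"` or `"per_roi"`.
#' @return A data frame with columns `team`, `phase_score`, `final_rank`.
#' @export
phase_ranking <- function(task_ranks, scheme = c("per_task", "per_roi")) {
  scheme <- match.arg(scheme)
  need <- c("task", "team", "rank")
  if (!all(need %in% names(task_ranks)))
    stop_segrank("segrank_data_error",
                 "task_ranks needs columns task, team, rank")
  teams <- sort(unique(task_ranks$team))
  tab <- table(task_ranks$team, task_ranks$task)
  if (any(tab != 1L))
    stop_segrank("segrank_data_error",
                 "every team needs exactly one rank for every ranking unit in the phase")
  per_team <- split(task_ranks$rank, task_ranks$team)
  score <- vapply(per_team, mean, numeric(1))[teams]
  final <- ranks_from_scores(-score) # lower mean rank = better
  data.frame(team = teams, phase_score = as.numeric(score),
             final_rank = as.numeric(final[teams]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significance ranking of competing teams
#'
#' Runs the full four-step significance-ranking procedure on a per-case
#' metric table: (1) per-case performances are taken from `table`;
#' (2) one-sided pairwise Wilcoxon signed-rank tests are performed
#' between all teams, separately per (task, ROI, metric); (3) each team's
#' significance score is the number of competitors performing
#' significantly worse (per-comparison `alpha`, unadjusted); (4) ranks
#' are assigned descending in score (rank 1 = best, mid-rank ties), then
#' aggregated: per-ROI rank = mean of the DSC and NSD ranks, per-task
#' rank = mean of per-ROI ranks, phase score = mean of per-task ranks
#' (or of all per-ROI ranks under `scheme = "per_roi"`).
#'
#' @param table a [metric_table] (or data frame coercible to one).
#' @param task_specs optional named list of [task_spec] objects supplying
#'   the task-to-phase assignment; tasks not covered (or `NULL`) fall into
#'   a single phase `"all"`.
#' @param alpha per-comparison significance level, default 0.05.
#' @param scheme aggregation scheme, `"per_task"` (default) or `"per_roi"`.
#' @param ... further arguments to [wilcoxon_signed_rank_one_sided()]
#'   (e.g. `alternative`, `zero_method`).
#' @return An object of class `seg_ranking`: a list with data frames
#'   `scores` (per task/ROI/metric/team significance scores and ranks),
#'   `roi_ranks`, `task_ranks`, `phases` (phase score and final rank),
#'   plus `alpha`, `scheme` and `n_teams`.
#' @examples
#' cfg <- cohort_config(
#'   tasks = list(task_spec("T", "development", c(organ = 1), 3)),
#'   n_cases = 12,
#'   teams = list(team_profile("good", beta_mean = 0.9, beta_sd = 0.05),
#'                team_profile("weak", beta_mean = 0.5, beta_sd = 0.05)),
#'   seed = 7)
#' rk <- rank_teams(simulate_metric_table(cfg))
#' rk$phases
#' @export
rank_teams <- function(table, task_specs = NULL, alpha = 0.05,
                       scheme = c("per_task", "per_roi"), ...) {
  scheme <- match.arg(scheme)
  table <- metric_table(table)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha < 1))
    stop_segrank("segrank_config_error", "alpha must lie in (0, 1)")
  phase_of <- task_phase_map(task_specs)
  teams <- sort(unique(table$team))
  tasks <- sort(unique(table$task))

  score_rows <- list()
  roi_rows <- list()
  task_rows <- list()
  for (task in tasks) {
    tt <- table[table$task == task, , drop = FALSE]
    rois <- sort(unique(tt$roi))
    roi_rank_mat <- matrix(NA_real_, length(teams), length(rois),
                           dimnames = list(teams, rois))
    for (roi in rois) {
      metrics <- sort(unique(tt$metric[tt$roi == roi]))
      per_metric <- matrix(NA_real_, length(teams), length(metrics),
                           dimnames = list(teams, metrics))
      for (metric in metrics) {
        sc <- significance_scores(table, task, roi, metric, alpha = alpha, ...)
        rk <- ranks_from_scores(sc)
        per_metric[names(rk), metric] <- rk
        score_rows[[length(score_rows) + 1L]] <-
          data.frame(task = task, roi = roi, metric = metric,
                     team = names(sc), score = as.integer(sc),
                     rank = as.numeric(rk[names(sc)]),
                     stringsAsFactors = FALSE)
      }
      roi_rank <- rowMeans(per_metric)
      roi_rank_mat[, roi] <- roi_rank
      roi_rows[[length(roi_rows) + 1L]] <-
        data.frame(task = task, roi = roi, team = rownames(per_metric),
                   rank = as.numeric(roi_rank), stringsAsFactors = FALSE)
    }
    task_rows[[length(task_rows) + 1L]] <-
      data.frame(task = task, team = teams,
                 rank = as.numeric(rowMeans(roi_rank_mat)),
                 stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, score_rows)
  roi_ranks <- do.call(rbind, roi_rows)
  task_ranks <- do.call(rbind, task_rows)

  phase_for_task <- function(task) {
    if (!is.null(phase_of) && task %in% names(phase_of)) phase_of[[task]]
    else "all"
  }
  task_ranks$phase <- vapply(task_ranks$task, phase_for_task, character(1))
  roi_ranks$phase <- vapply(roi_ranks$task, phase_for_task, character(1))

  phases <- lapply(sort(unique(task_ranks$phase)), function(ph) {
    units <- if (scheme == "per_task") {
      task_ranks[task_ranks$phase == ph, c("task", "team", "rank")]
    } else {
      u <- roi_ranks[roi_ranks$phase == ph, c("task", "roi", "team", "rank")]
      u$task <- paste(u$task, u$roi, sep = "/")
      u[c("task", "team", "rank")]
    }
    out <- phase_ranking(units, scheme = "per_task")
    cbind(phase = ph, out, stringsAsFactors = FALSE)
  })
  phases <- do.call(rbind, phases)
  rownames(phases) <- NULL

  structure(list(scores = scores, roi_ranks = roi_ranks,
                 task_ranks = task_ranks, phases = phases,
                 alpha = alpha, scheme = scheme,
                 n_teams = length(teams)),
            class = "seg_ranking")
}

#' @export
print.seg_ranking <- function(x, ...) {
  cat("<seg_ranking> ", x$n_teams, " teams, ",
      length(unique(x$task_ranks$task)), " tasks; alpha = ", x$alpha,
      ", scheme = ", x$scheme, "\n", sep = "")
  for (ph in unique(x$phases$phase)) {
    p <- x$phases[x$phases$phase == ph, , drop = FALSE]
    p <- p[order(p$final_rank, p$team), , drop = FALSE]
    cat("\nPhase:", ph, "\n")
    print(data.frame(rank = p$final_rank, team = p$team,
                     mean_task_rank = round(p$phase_score, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.seg_ranking <- function(object, ...) {
  cat("Significance ranking (alpha =", object$alpha,
      ", scheme =", object$scheme, ")\n")
  cat("\nPer-task mean significance ranks:\n")
  wide <- stats::reshape(object$task_ranks[c("task", "team", "rank")],
                         direction = "wide", idvar = "team", timevar = "task")
  names(wide) <- sub("^rank\\.", "", names(wide))
  print(wide, row.names = FALSE)
  print(object)
  invisible(object)
}

#' Write a leaderboard to JSON (and optionally a flat CSV)
#'
#' The JSON carries one object per phase with the scheme, alpha and the
#' nested per-task / per-ROI / per-metric ranks for each team; teams are
#' ordered by final rank. The flat CSV has one row per (task, roi,
#' metric, team).
#'
#' @param ranking a `seg_ranking` from [rank_teams()].
#' @param json_path output JSON path.
#' @param csv_path optional flat CSV path.
#' @return `json_path`, invisibly.
#' @export
write_leaderboard <- function(ranking, json_path, csv_path = NULL) {
  stopifnot(inherits(ranking, "seg_ranking"))
  phases <- lapply(unique(ranking$phases$phase), function(ph) {
    p <- ranking$phases[ranking$phases$phase == ph, , drop = FALSE]
    p <- p[order(p$final_rank, p$team), , drop = FALSE]
    teams <- lapply(seq_len(nrow(p)), function(i) {
      team <- p$team[i]
      tr <- ranking$task_ranks[ranking$task_ranks$phase == ph &
                                 ranking$task_ranks$team == team, , drop = FALSE]
      per_task <- lapply(seq_len(nrow(tr)), function(j) {
        task <- tr$task[j]
        rr <- ranking$roi_ranks[ranking$roi_ranks$task == task &
                                  ranking$roi_ranks$team == team, , drop = FALSE]
        per_roi <- lapply(seq_len(nrow(rr)), function(k) {
          roi <- rr$roi[k]
          sm <- ranking$scores[ranking$scores$task == task &
                                 ranking$scores$roi == roi &
                                 ranking$scores$team == team, , drop = FALSE]
          pm <- as.list(structure(sm$rank, names = sm$metric))
          list(rank = rr$rank[k], per_metric = pm)
        })
        names(per_roi) <- rr$roi
        list(rank = tr$rank[j], per_roi = per_roi)
      })
      names(per_task) <- tr$task
      list(team = team, phase_score = p$phase_score[i],
           final_rank = p$final_rank[i], per_task = per_task)
    })
    list(phase = ph, scheme = ranking$scheme, alpha = ranking$alpha,
         teams = teams)
  })
  jsonlite::write_json(phases, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(csv_path)) {
    flat <- ranking$scores[order(ranking$scores$task, ranking$scores$roi,
                                 ranking$scores$metric, ranking$scores$rank,
                                 ranking$scores$team), , drop = FALSE]
    utils::write.csv(flat, csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
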