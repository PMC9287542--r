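#' Bootstrap the significance-ranking pipeline
#'
#' Draws `n_samples` bootstrap replicates of the metric table by
#' resampling test cases with replacement *within each task* (the same
#' resampled case multiset is applied to every team, preserving the
#' paired, complete-block structure; sample size equals the task's
#' original case count) and re-runs the full significance-ranking
#' pipeline on each replicate. The sequence is a pure function of
#' `(table, n_samples, seed)`: the resample indices for sample `s` are
#' drawn from a substream seeded by `seed + s`, so individual samples
#' could be evaluated in parallel with identical results.
#'
#' @param table a [metric_table].
#' @param n_samples number of bootstrap samples (>= 1).
#' @param seed integer seed.
#' @inheritParams rank_teams
#' @return A list of `seg_ranking` objects, one per bootstrap sample.
#' @export
bootstrap_rankings <- function(table, n_samples, seed, task_specs = NULL,
                               alpha = 0.05, scheme = c("per_task", "per_roi"),
                               ...) {
  scheme <- match.arg(scheme)
  table <- metric_table(table)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 1L)
    stop_segrank("segrank_config_error", "n_samples must be >= 1")
  tasks <- sort(unique(table$task))
  cases_by_task <- lapply(tasks, function(tk) sort(unique(table$case[table$task == tk])))
  names(cases_by_task) <- tasks
  split_by_task <- split(seq_len(nrow(table)), table$task)

  lapply(seq_len(n_samples), function(s) {
    boot_rows <- lapply(tasks, function(tk) {
      cases <- cases_by_task[[tk]]
      # per-(sample, task) substream derived by counter: deterministic and
      # order-independent, so samples could be evaluated in parallel
      ti <- match(tk, tasks)
      sub_seed <- (as.integer(seed) + s + (ti - 1L) * n_samples) %%
        .Machine$integer.max
      idx <- local_seed(sub_seed,
                        sample.int(length(cases), length(cases), replace = TRUE))
      tt <- table[split_by_task[[tk]], , drop = FALSE]
      per_case <- split(seq_len(nrow(tt)), tt$case)
      out <- lapply(seq_along(idx), function(k) {
        rows <- tt[per_case[[cases[idx[k]]]], , drop = FALSE]
        rows$case <- sprintf("%s__b%03d", rows$case, k)
        rows
      })
      do.call(rbind, out)
    })
    boot <- do.call(rbind, boot_rows)
    rank_teams(boot, task_specs = task_specs, alpha = alpha, scheme = scheme, ...)
  })
}

#' Kendall's tau-b between two rankings
#'
#' Tie-corrected rank correlation over team pairs: 1 for identical
#' orderings, -1 for exact reversals. Because shared ranks are possible
#' in significance rankings, the tau-b variant is used. When either
#' ranking is fully tied tau is undefined; a flagged `NA` is returned and
#' such values are excluded from stability summaries.
#'
#' @param ranks_a,ranks_b named numeric vectors of ranks over the same
#'   team set (>= 2 teams).
#' @return tau in \[-1, 1\], or `NA` when undefined.
#' @examples
#' kendall_tau(c(A = 1, B = 2, C = 3, D = 4), c(A = 1, B = 2, C = 4, D = 3))
#' @export
kendall_tau <- function(ranks_a, ranks_b) {
  if (is.null(names(ranks_a)) || is.null(names(ranks_b)) ||
      !setequal(names(ranks_a), names(ranks_b)) ||
      anyDuplicated(names(ranks_a)) || anyDuplicated(names(ranks_b)))
    stop_segrank("segrank_data_error",
                 "rankings must cover the same set of uniquely named teams")
  if (length(ranks_a) < 2L)
    stop_segrank("segrank_data_error", "need at least two teams")
  b <- as.numeric(ranks_b[names(ranks_a)])
  a <- as.numeric(ranks_a)
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  unname(stats::cor(a, b, method = "kendall"))
}

#' Summarise bootstrap ranking stability
#'
#' For each task, computes Kendall's tau between the original per-task
#' ranking and each bootstrap per-task ranking, the median and IQR
#' (quartiles by linear interpolation, type 7) of those tau values, and
#' the rank-frequency matrix: the proportion of bootstrap samples in
#' which each team attains each per-task final rank (fractional mid-ranks
#' are multiples of 0.5 and are kept at that resolution).
#'
#' @param original a `seg_ranking` for the full table.
#' @param boots list of `seg_ranking` objects from [bootstrap_rankings()].
#' @param seed,n_samples recorded in the result (optional bookkeeping).
#' @return An object of class `seg_stability`: list with `per_task_tau`
#'   (task -> numeric vector), `summaries` (data frame `task`,
#'   `median_tau`, `iqr_lo`, `iqr_hi`, `n_defined`), `rank_frequency`
#'   (data frame `task`, `team`, `rank`, `frequency`), `n_samples`, `seed`.
#' @export
stability_summary <- function(original, boots, seed = NA_integer_,
                              n_samples = length(boots)) {
  stopifnot(inherits(original, "seg_ranking"))
  if (length(boots) < 1L)
    stop_segrank("segrank_data_error", "need at least one bootstrap ranking")
  tasks <- sort(unique(original$task_ranks$task))
  teams <- sort(unique(original$task_ranks$team))

  task_rank_vec <- function(rk, task) {
    tr <- rk$task_ranks[rk$task_ranks$task == task, , drop = FALSE]
    structure(tr$rank, names = tr$team)
  }
  per_task_tau <- list()
  freq_rows <- list()
  for (task in tasks) {
    orig <- task_rank_vec(original, task)
    taus <- vapply(boots, function(b) {
      v <- task_rank_vec(b, task)
      kendall_tau(orig, v)
    }, numeric(1))
    per_task_tau[[task]] <- taus
    # per-task final ranks (re-ranked mean ROI ranks, ascending, mid-rank)
    final_ranks <- vapply(boots, function(b) {
      v <- task_rank_vec(b, task)
      r <- rank(v, ties.method = "average")
      r[teams]
    }, numeric(length(teams)))
    if (is.null(dim(final_ranks)))
      final_ranks <- matrix(final_ranks, nrow = length(teams),
                            dimnames = list(teams, NULL))
    for (team in teams) {
      tb <- table(final_ranks[team, ]) / length(boots)
      freq_rows[[length(freq_rows) + 1L]] <-
        data.frame(task = task, team = team,
                   rank = as.numeric(names(tb)),
                   frequency = as.numeric(tb), stringsAsFactors = FALSE)
    }
  }
  summaries <- do.call(rbind, lapply(tasks, function(task) {
    taus <- per_task_tau[[task]]
    ok <- taus[!is.na(taus)]
    if (length(ok) == 0L) {
      data.frame(task = task, median_tau = NA_real_, iqr_lo = NA_real_,
                 iqr_hi = NA_real_, n_defined = 0L, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(ok, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      data.frame(task = task, median_tau = q[2], iqr_lo = q[1], iqr_hi = q[3],
                 n_defined = length(ok), stringsAsFactors = FALSE)
    }
  }))
  rank_frequency <- do.call(rbind, freq_rows)
  rownames(rank_frequency) <- rownames(summaries) <- NULL
  structure(list(per_task_tau = per_task_tau, summaries = summaries,
                 rank_frequency = rank_frequency,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "seg_stability")
}

#' Bootstrap ranking-stability analysis
#'
#' Convenience wrapper: ranks the table, draws `n_samples` case-level
#' bootstrap replicates, re-ranks each, and summarises the agreement with
#' the original ranking per task (Kendall's tau median/IQR and rank
#' frequencies). Fully reproducible given `seed`.
#'
#' @inheritParams bootstrap_rankings
#' @param n_samples number of bootstrap samples (default 1000, the
#'   benchmark's protocol value).
#' @return A `seg_stability` object (see [stability_summary()]), with the
#'   original `seg_ranking` attached as `$original`.
#' @export
rank_stability <- function(table, n_samples = 1000, seed, task_specs = NULL,
                           alpha = 0.05, scheme = c("per_task", "per_roi"),
                           ...) {
  scheme <- match.arg(scheme)
  original <- rank_teams(table, task_specs = task_specs, alpha = alpha,
                         scheme = scheme, ...)
  boots <- bootstrap_rankings(table, n_samples = n_samples, seed = seed,
                              task_specs = task_specs, alpha = alpha,
                              scheme = scheme, ...)
  out <- stability_summary(original, boots, seed = seed, n_samples = n_samples)
  out$original <- original
  out
}

#' @export
print.seg_stability <- function(x, ...) {
  cat("<seg_stability> ", x$n_samples, " bootstrap samples (seed ",
      x$seed, ")\n", sep = "")
  s <- x$summaries
  cat("Kendall's tau vs original ranking, per task:\n")
  print(data.frame(task = s$task,
                   median_tau = round(s$median_tau, 3),
                   IQR = sprintf("(%.3f, %.3f)", s$iqr_lo, s$iqr_hi),
                   n_defined = s$n_defined),
        row.names = FALSE)
  invisible(x)
}

#' Write a stability report (JSON) and rank-frequency CSV
#'
#' @param stability a `seg_stability` object.
#' @param json_path output JSON: `{task: {median_tau, iqr, n_samples, seed}}`.
#' @param freq_csv optional CSV `task,team,rank,frequency`.
#' @return `json_path`, invisibly.
#' @export
write_stability_report <- function(stability, json_path, freq_csv = NULL) {
  stopifnot(inherits(stability, "seg_stability"))
  s <- stability$summaries
  rep <- lapply(seq_len(nrow(s)), function(i) {
    list(median_tau = s$median_tau[i],
         iqr = c(s$iqr_lo[i], s$iqr_hi[i]),
         n_samples = stability$n_samples,
         seed = stability$seed)
  })
  names(rep) <- s$task
  jsonlite::write_json(rep, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(freq_csv)) {
    fr <- stability$rank_frequency
    fr <- fr[order(fr$task, fr$team, fr$rank), , drop = FALSE]
    utils::write.csv(fr, freq_csv, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}
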