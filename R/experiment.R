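# The two matching experiments: full-library ranking and the replicated
# trial-set design, with the rank-based accuracy criteria.

#' Extract frame features of one kind from a clip
#'
#' Dispatcher over the three representations: `"rasta_plpcc"`
#' ([compute_rasta_plpcc], 12-dim), `"mfcc"` ([compute_mfcc], 39-dim),
#' `"lsf"` ([compute_lsf_features], 12-dim).
#'
#' @param clip An [audio_clip].
#' @param kind One of `"rasta_plpcc"`, `"mfcc"`, `"lsf"`.
#' @param ... Passed to the underlying extractor.
#' @return A `frame_features` matrix.
#' @export
extract_features <- function(clip, kind = FEATURE_KINDS, ...) {
  kind <- match.arg(kind)
  switch(kind,
    rasta_plpcc = compute_rasta_plpcc(clip, ...),
    mfcc = compute_mfcc(clip, ...),
    lsf = compute_lsf_features(clip, ...)
  )
}

#' Pooled feature vectors for every clip in a library
#'
#' @param library A `call_library`.
#' @param kind Feature kind (see [extract_features]).
#' @param pooling `"mean"` or `"median"` (see [pool_frames]).
#' @return A tibble with columns `id`, `role`, `model_id`, and `feature`
#'   (list-column of pooled numeric vectors).
#' @export
library_features <- function(library, kind = FEATURE_KINDS,
                             pooling = c("mean", "median")) {
  kind <- match.arg(kind)
  pooling <- match.arg(pooling)
  feats <- lapply(library$clips, function(cl) {
    pool_frames(extract_features(cl, kind), pooling)
  })
  dplyr::mutate(
    library$manifest[, c("id", "role", "model_id")],
    feature = unname(feats[.data$id])
  )
}

feature_list <- function(features) {
  if (is.data.frame(features)) {
    stats::setNames(features$feature, features$id)
  } else {
    features
  }
}

#' Build replicated trial sets for the subset matching design
#'
#' For every mimic in the library, `reps` trial sets are drawn. Each set
#' pairs the mimic (the query) with 10 candidates: its putative model plus 3
#' other mimicked calls, 3 conspecific calls and 3 other-species calls drawn
#' at random — 11 call slots per set, matching the design in which 21 mimics
#' x 5 replicates give 105 sets. Draws are without replacement within a set
#' and independent across sets; candidate order is shuffled. Deterministic
#' for a fixed seed.
#'
#' @param library A `call_library` whose mimics all carry a `model_id`
#'   present in the library.
#' @param reps Trial sets per mimic (default 5).
#' @param seed Integer seed.
#' @return A `trial_sets` tibble with columns `set_id`, `query_id`,
#'   `model_id`, and `candidates` (list-column of 10 candidate ids).
#' @export
build_trial_sets <- function(library, reps = 5L, seed = 1L) {
  man <- library$manifest
  mimics <- man[man$role == "mimic", ]
  if (nrow(mimics) == 0L) abort("library contains no mimic calls")
  if (anyNA(mimics$model_id) ||
      !all(mimics$model_id %in% man$id)) {
    abort("every mimic must have its putative model present in the library")
  }
  pools <- list(
    mimic = man$id[man$role == "mimic"],
    conspecific = man$id[man$role == "conspecific"],
    other = man$id[man$role == "other"]
  )
  needed <- c(mimic = 4L, conspecific = 3L, other = 3L)  # mimic pool excludes the query
  for (role in names(needed)) {
    if (length(pools[[role]]) < needed[[role]]) {
      abort(sprintf("insufficient distractors: role '%s' has %d calls, need %d",
                    role, length(pools[[role]]), needed[[role]]))
    }
  }
  with_local_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(mimics))) {
      q <- mimics$id[i]
      mod <- mimics$model_id[i]
      for (r in seq_len(reps)) {
        cand <- c(mod,
                  sample(setdiff(pools$mimic, q), 3L),
                  sample(pools$conspecific, 3L),
                  sample(pools$other, 3L))
        rows[[length(rows) + 1L]] <- tibble(
          query_id = q, model_id = mod,
          candidates = list(sample(cand))
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    out <- out[sample.int(nrow(out)), ]
    out <- dplyr::mutate(out, set_id = sprintf("set%03d", dplyr::row_number()),
                         .before = 1L)
    attr(out, "seed") <- seed
    class(out) <- c("trial_sets", class(out))
    out
  })
}

new_experiment_report <- function(trials, feature = NA_character_,
                                  metric = NA_character_) {
  per_call <- dplyr::summarise(
    dplyr::group_by(trials, .data$query_id),
    n_trials = dplyr::n(),
    n_rank1 = sum(.data$model_rank == 1L),
    n_rank12 = sum(.data$model_rank <= 2L),
    .groups = "drop"
  )
  per_call <- dplyr::mutate(
    per_call,
    all_rank1 = .data$n_rank1 == .data$n_trials,
    ge80_rank1 = .data$n_rank1 >= ceiling(0.8 * .data$n_trials),
    all_rank12 = .data$n_rank12 == .data$n_trials,
    ge80_rank12 = .data$n_rank12 >= ceiling(0.8 * .data$n_trials)
  )
  structure(
    list(trials = trials, per_call = per_call,
         feature = feature, metric = metric),
    class = "experiment_report"
  )
}

#' Score the trial-set matching experiment
#'
#' For every trial set, ranks the 10 candidates against the query under the
#' given features and metric and records the rank of the putative model.
#' Aggregates per call: rank-1 and rank-1+2 trial counts, the all-trials
#' criterion, and the 80 percent threshold criterion (correct in at least 4
#' of 5 trials).
#'
#' @param sets A `trial_sets` tibble from [build_trial_sets].
#' @param features Pooled features: a [library_features] tibble or a named
#'   list of numeric vectors covering every query and candidate id.
#' @param metric Distance/similarity metric (see [rank_library]).
#' @return An `experiment_report`: list with `trials` (per-trial model
#'   ranks) and `per_call` (per-call counts and criteria); see
#'   [tidy.experiment_report] and [glance.experiment_report].
#' @export
run_trial_experiment <- function(sets, features, metric = METRICS) {
  metric <- match.arg(metric)
  fl <- feature_list(features)
  kind <- attr(fl[[1]], "kind")
  missing_ids <- setdiff(unique(c(sets$query_id, unlist(sets$candidates))),
                         names(fl))
  if (length(missing_ids)) {
    abort(paste0("features missing for: ", paste(missing_ids, collapse = ", ")))
  }
  trials <- purrr::map_dfr(seq_len(nrow(sets)), function(i) {
    cand_ids <- sets$candidates[[i]]
    ranked <- rank_library(fl[[sets$query_id[i]]], fl[cand_ids],
                           metric = metric, query_id = sets$query_id[i])
    tibble(
      set_id = sets$set_id[i],
      query_id = sets$query_id[i],
      model_id = sets$model_id[i],
      model_rank = ranked$rank[ranked$candidate_id == sets$model_id[i]]
    )
  })
  new_experiment_report(trials, feature = kind, metric = metric)
}

#' Reconstitute an experiment report from recorded trial outcomes
#'
#' Builds an `experiment_report` from a data frame of per-trial model ranks —
#' e.g. a human-assessment arm read from CSV with columns `set_id` (optional),
#' `query_id`, and `model_rank` (rank given to the putative model; use a
#' value above 2 for "not in the top two").
#'
#' @param trials Data frame with columns `query_id` and `model_rank`.
#' @param feature,metric Optional labels recorded on the report.
#' @return An `experiment_report`.
#' @export
as_experiment_report <- function(trials, feature = "human",
                                 metric = NA_character_) {
  trials <- as_tibble(trials)
  if (!all(c("query_id", "model_rank") %in% names(trials))) {
    abort("trials must have columns query_id and model_rank")
  }
  if (!"set_id" %in% names(trials)) {
    trials$set_id <- sprintf("set%03d", seq_len(nrow(trials)))
  }
  if (!"model_id" %in% names(trials)) trials$model_id <- NA_character_
  new_experiment_report(trials[, c("set_id", "query_id", "model_id",
                                   "model_rank")],
                        feature = feature, metric = metric)
}

#' @export
print.experiment_report <- function(x, ...) {
  g <- glance.experiment_report(x)
  cat(sprintf("<experiment_report> %s / %s: %d calls, %d trials\n",
              x$feature, x$metric, g$n_calls, g$n_trials))
  cat(sprintf("  trial-level rank-1: %.1f%%, rank-1+2: %.1f%%\n",
              100 * g$trial_rank1, 100 * g$trial_rank12))
  cat(sprintf("  per-call all-trials rank-1: %.1f%%, >=80%% rank-1: %.1f%%\n",
              100 * g$call_all_rank1, 100 * g$call_ge80_rank1))
  invisible(x)
}

#' Per-call outcomes of an experiment report
#' @param x An `experiment_report`.
#' @param ... Ignored.
#' @return The per-call tibble: trial counts and the rank-based criteria.
#' @export
tidy.experiment_report <- function(x, ...) x$per_call

#' Aggregate accuracies of an experiment report
#'
#' @param x An `experiment_report`.
#' @param ... Ignored.
#' @return One-row tibble: `n_calls`, `n_trials`, trial-level rank-1 and
#'   rank-1+2 proportions, and the per-call all-trials / 80-percent-threshold
#'   proportions for both rank criteria.
#' @export
glance.experiment_report <- function(x, ...) {
  pc <- x$per_call
  tibble(
    n_calls = nrow(pc),
    n_trials = sum(pc$n_trials),
    trial_rank1 = sum(pc$n_rank1) / sum(pc$n_trials),
    trial_rank12 = sum(pc$n_rank12) / sum(pc$n_trials),
    call_all_rank1 = mean(pc$all_rank1),
    call_ge80_rank1 = mean(pc$ge80_rank1),
    call_all_rank12 = mean(pc$all_rank12),
    call_ge80_rank12 = mean(pc$ge80_rank12)
  )
}

#' Success counts of a report under a named criterion
#'
#' @param report An `experiment_report`.
#' @param criterion `"call_all_rank1"`, `"call_ge80_rank1"`,
#'   `"call_all_rank12"`, `"call_ge80_rank12"` (per-call criteria), or
#'   `"trial_rank1"`, `"trial_rank12"` (per-trial criteria).
#' @return A list with `x` (successes) and `n` (total calls or trials).
#' @export
report_counts <- function(report,
                          criterion = c("call_all_rank1", "call_ge80_rank1",
                                        "call_all_rank12", "call_ge80_rank12",
                                        "trial_rank1", "trial_rank12")) {
  criterion <- match.arg(criterion)
  pc <- report$per_call
  switch(criterion,
    call_all_rank1 = list(x = sum(pc$all_rank1), n = nrow(pc)),
    call_ge80_rank1 = list(x = sum(pc$ge80_rank1), n = nrow(pc)),
    call_all_rank12 = list(x = sum(pc$all_rank12), n = nrow(pc)),
    call_ge80_rank12 = list(x = sum(pc$ge80_rank12), n = nrow(pc)),
    trial_rank1 = list(x = sum(pc$n_rank1), n = sum(pc$n_trials)),
    trial_rank12 = list(x = sum(pc$n_rank12), n = sum(pc$n_trials))
  )
}

#' Full-library matching analysis
#'
#' For every mimic in the library, ranks all remaining files against it
#' (each mimicked file compared with every other file, e.g. the 356 others
#' in a 357-file library) under each requested feature representation and
#' metric, and tabulates how often the putative model lands at ranks 1, 2
#' and 3.
#'
#' @param library A `call_library` with at least 2 files.
#' @param kinds Feature kinds to evaluate (default all three).
#' @param metrics Metrics to evaluate (default all five).
#' @param pooling Frame pooling method.
#' @return A `library_analysis`: list with `details` (per feature x metric x
#'   query: the model's rank) and `rank_counts` (per feature x metric:
#'   correct matches at ranks 1-3, incorrect count, rank variance of the
#'   correct matches).
#' @export
run_library_analysis <- function(library, kinds = FEATURE_KINDS,
                                 metrics = METRICS,
                                 pooling = c("mean", "median")) {
  pooling <- match.arg(pooling)
  man <- library$manifest
  if (nrow(man) < 2L) abort("library must contain at least 2 files")
  mimics <- man[man$role == "mimic", ]
  skip <- is.na(mimics$model_id)
  if (any(skip)) {
    warn(sprintf("%d mimic(s) without model_id excluded from the analysis",
                 sum(skip)))
    mimics <- mimics[!skip, ]
  }
  details <- purrr::map_dfr(kinds, function(kind) {
    fl <- feature_list(library_features(library, kind, pooling))
    purrr::map_dfr(metrics, function(metric) {
      purrr::map_dfr(seq_len(nrow(mimics)), function(i) {
        q <- mimics$id[i]
        ranked <- rank_library(fl[[q]], fl[setdiff(names(fl), q)],
                               metric = metric, query_id = q)
        tibble(feature = kind, metric = metric, query_id = q,
               model_id = mimics$model_id[i],
               model_rank = ranked$rank[ranked$candidate_id == mimics$model_id[i]])
      })
    })
  })
  rank_counts <- dplyr::summarise(
    dplyr::group_by(details, .data$feature, .data$metric),
    rank1 = sum(.data$model_rank == 1L),
    rank2 = sum(.data$model_rank == 2L),
    rank3 = sum(.data$model_rank == 3L),
    incorrect = sum(.data$model_rank > 3L),
    n_queries = dplyr::n(),
    .groups = "drop"
  )
  rank_counts$rank_var <- vapply(seq_len(nrow(rank_counts)), function(i) {
    counts <- unlist(rank_counts[i, c("rank1", "rank2", "rank3")])
    if (sum(counts) < 2L) NA_real_ else rank_variance(counts)
  }, numeric(1))
  structure(list(details = details, rank_counts = rank_counts,
                 pooling = pooling),
            class = "library_analysis")
}

#' @export
print.library_analysis <- function(x, ...) {
  cat("<library_analysis> correct matches in the first three ranks\n")
  print(x$rank_counts)
  invisible(x)
}

#' @export
tidy.library_analysis <- function(x, ...) x$details

#' @export
glance.library_analysis <- function(x, ...) x$rank_counts

#' Variance of assigned ranks for correct matches
#'
#' Expands rank-1/2/3 counts into the list of ranks received by correctly
#' matched calls and returns its sample variance (denominator `n - 1`).
#' With `include_incorrect_as_4 = TRUE`, incorrect matches are appended as
#' rank 4 (the lowest rank) before computing the variance — a sensitivity
#' variant; the default excludes them.
#'
#' @param counts Integer vector of length 3: correct matches at ranks 1, 2
#'   and 3.
#' @param include_incorrect_as_4 Append incorrect matches scored as rank 4.
#' @param n_incorrect Number of incorrect matches (used only when the flag
#'   is set).
#' @return Sample variance of the expanded rank list.
#' @export
rank_variance <- function(counts, include_incorrect_as_4 = FALSE,
                          n_incorrect = 0L) {
  if (length(counts) != 3L || any(counts < 0)) {
    abort("counts must be 3 non-negative values (ranks 1, 2, 3)")
  }
  ranks <- rep(1:3, times = counts)
  if (include_incorrect_as_4) ranks <- c(ranks, rep(4L, n_incorrect))
  if (length(ranks) < 2L) abort("need at least 2 ranks to compute a variance")
  var(ranks)
}

#' Select the best feature representation and two metrics
#'
#' Picks the feature with the most first-ranked correct matches (summed over
#' metrics), then the top two metrics within that feature by rank-1 count.
#' Metric ties are broken by lower rank variance (when available), then by
#' the fixed metric order Jaccard, correlation, cosine, city-block,
#' Euclidean.
#'
#' @param rank_counts A tibble with columns `feature`, `metric`, `rank1`,
#'   and optionally `rank_var` (as produced by [run_library_analysis]).
#' @return A list with `feature` (character) and `metrics` (character
#'   vector of 2, or fewer if fewer are available).
#' @export
select_feature_and_metrics <- function(rank_counts) {
  if (!is.data.frame(rank_counts) || nrow(rank_counts) == 0L) {
    abort("rank_counts must be a non-empty table")
  }
  if (sum(rank_counts$rank1) == 0L) {
    abort("nothing selectable: no first-ranked correct matches")
  }
  totals <- dplyr::summarise(dplyr::group_by(rank_counts, .data$feature),
                             total = sum(.data$rank1), .groups = "drop")
  best_feature <- totals$feature[which.max(totals$total)]
  sub <- rank_counts[rank_counts$feature == best_feature, ]
  rv <- if ("rank_var" %in% names(sub)) sub$rank_var else rep(NA_real_, nrow(sub))
  rv[is.na(rv)] <- Inf
  ord <- order(-sub$rank1, rv, match(sub$metric, METRICS))
  list(feature = best_feature,
       metrics = sub$metric[ord][seq_len(min(2L, nrow(sub)))])
}

#' Compare two matching methods with the Yates-corrected proportion test
#'
#' Applies [yates_prop_test] to the success counts of two experiment reports
#' under a common criterion, and lists the calls on which the two methods
#' disagree (calls matched correctly under the criterion by exactly one of
#' the two).
#'
#' @param report_a,report_b Two `experiment_report`s over the same calls.
#' @param criterion See [report_counts].
#' @return A list with `test` (a `prop_test_result`), `counts`, and
#'   `disagreements` (tibble of call ids and which method matched them).
#' @export
compare_methods <- function(report_a, report_b,
                            criterion = c("call_all_rank1", "call_ge80_rank1",
                                          "call_all_rank12", "call_ge80_rank12",
                                          "trial_rank1", "trial_rank12")) {
  criterion <- match.arg(criterion)
  ids_a <- sort(report_a$per_call$query_id)
  ids_b <- sort(report_b$per_call$query_id)
  if (!identical(ids_a, ids_b)) {
    abort("the two reports cover different call sets")
  }
  ca <- report_counts(report_a, criterion)
  cb <- report_counts(report_b, criterion)
  test <- yates_prop_test(ca$x, ca$n, cb$x, cb$n)

  flag <- switch(criterion,
    call_all_rank1 = "all_rank1", call_ge80_rank1 = "ge80_rank1",
    call_all_rank12 = "all_rank12", call_ge80_rank12 = "ge80_rank12",
    trial_rank1 = "ge80_rank1", trial_rank12 = "ge80_rank12")
  a <- report_a$per_call[order(report_a$per_call$query_id), ]
  b <- report_b$per_call[order(report_b$per_call$query_id), ]
  disagree <- a[[flag]] != b[[flag]]
  disagreements <- tibble(
    query_id = a$query_id[disagree],
    matched_by = ifelse(a[[flag]][disagree], "a", "b")
  )
  list(test = test, criterion = criterion,
       counts = list(a = ca, b = cb), disagreements = disagreements)
}
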