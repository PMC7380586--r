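#' Microbiome novelty score from a top-N match list
#'
#' The novelty of a query against a reference database is one minus the
#' rank-weighted mean similarity of its top `n` matches:
#' `MNS = 1 - sum(S_i * (N - i + 1)) / sum(N - i + 1)` with `S_i` the
#' similarity of the rank-`i` match. Unweighted, the weights are constant and
#' the score is `1 - mean(S_i)`. When fewer than `n` matches are available
#' the available count is used as `N`, so ranks are always within the
#' truncated list.
#'
#' @param matches a match tibble (columns `query_id`, `rank`, `similarity`)
#'   from [search_topn()] or [exhaustive_search()]; may hold several queries.
#' @param n matches used per query (default 10).
#' @param weighted rank-weighted (default) or plain mean.
#' @return a tibble with columns `sample_id` and `mns`, one row per query.
#' @examples
#' m <- tibble::tibble(query_id = "q", rank = 1:3,
#'                     similarity = c(0.9, 0.8, 0.7))
#' compute_mns(m, n = 3)               # 0.1667
#' compute_mns(m, n = 3, weighted = FALSE)  # 0.2
#' @export
compute_mns <- function(matches, n = 10, weighted = TRUE) {
  if (!is.data.frame(matches) || nrow(matches) == 0)
    rlang::abort("`matches` must be a non-empty match tibble")
  matches |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::summarise(mns = mns_from_sims(.data$similarity, n, weighted),
                     .groups = "drop") |>
    dplyr::rename(sample_id = "query_id")
}

mns_from_sims <- function(s, n, weighted) {
  s <- s[seq_len(min(n, length(s)))]
  n_eff <- length(s)
  w <- if (weighted) n_eff - seq_len(n_eff) + 1 else rep(1, n_eff)
  min(max(1 - sum(s * w) / sum(w), 0), 1)
}

#' Threshold a novelty score into a disease-status call
#'
#' A query is called `"diseased"` when its novelty strictly exceeds the
#' threshold, `"healthy"` otherwise (a score exactly at the threshold is
#' healthy). The default threshold of 0.072 is the F1-optimal operating
#' point reported for gut samples against a large healthy baseline;
#' [calibrate_mns_threshold()] re-derives it on labelled calibration data.
#'
#' @param mns numeric novelty score(s) in `[0, 1]`.
#' @param threshold decision threshold in `[0, 1]` (default 0.072).
#' @return a character vector, `"healthy"` or `"diseased"`.
#' @export
detect_status <- function(mns, threshold = 0.072) {
  stopifnot(is.numeric(mns), threshold >= 0, threshold <= 1)
  ifelse(mns > threshold, "diseased", "healthy")
}

#' Pick the F1-maximising novelty threshold on labelled data
#'
#' Sweeps thresholds over the observed scores and returns the one maximising
#' the F1 of detecting the diseased class under the strict `mns > t` rule.
#'
#' @param mns numeric novelty scores.
#' @param diseased logical, `TRUE` for truly diseased samples.
#' @return a list with `threshold` and the `f1` it attains.
#' @export
calibrate_mns_threshold <- function(mns, diseased) {
  stopifnot(length(mns) == length(diseased), any(diseased), any(!diseased))
  cand <- sort(unique(c(0, mns)))
  f1 <- vapply(cand, function(t) {
    pred <- mns > t
    tp <- sum(pred & diseased)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + sum(pred & !diseased) + sum(!pred & diseased))
  }, numeric(1))
  list(threshold = cand[which.max(f1)], f1 = max(f1))
}

#' Rank-weighted multi-cohort classification from a match list
#'
#' Scores each cohort label `g` as the similarity-and-rank-weighted share of
#' matches carrying that label,
#' `Score(g) = sum_{i in g} S_i * (N - i + 1) / sum_j S_j * (N - j + 1)`
#' (unweighted: the rank factor is dropped but similarities are kept). Scores
#' form a probability vector over the labels; the prediction is the argmax,
#' ties resolved by the declared label order.
#'
#' @param matches a match tibble with `query_id`, `rank`, `similarity` and
#'   `status` columns (every match must be labelled).
#' @param n matches used per query (default 10).
#' @param weighted use rank weights (default) or similarities alone.
#' @param labels declared label order, used for tie-breaking and for the
#'   score columns; defaults to the sorted labels observed in `matches`.
#' @return a tibble with `sample_id`, `predicted`, and one `score_<label>`
#'   column per label.
#' @examples
#' m <- tibble::tibble(query_id = "q", rank = 1:3,
#'                     similarity = c(0.9, 0.8, 0.7),
#'                     status = c("IBD", "IBD", "control"))
#' classify_disease(m, n = 3) # Score(IBD) = 0.86
#' @export
classify_disease <- function(matches, n = 10, weighted = TRUE, labels = NULL) {
  if (!is.data.frame(matches) || nrow(matches) == 0)
    rlang::abort("`matches` must be a non-empty match tibble")
  if (anyNA(matches$status))
    rlang::abort("every match must carry a status label")
  if (is.null(labels)) labels <- sort(unique(matches$status))
  res <- matches |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$rank, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      score_row(d$similarity, d$status, n, weighted, labels)
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(sample_id = "query_id")
  res
}

score_row <- function(s, status, n, weighted, labels) {
  keep <- seq_len(min(n, length(s)))
  s <- s[keep]; status <- status[keep]
  n_eff <- length(s)
  w <- if (weighted) n_eff - seq_len(n_eff) + 1 else rep(1, n_eff)
  contrib <- s * w
  tot <- sum(contrib)
  scores <- setNames(numeric(length(labels)), labels)
  if (tot > 0) {
    agg <- tapply(contrib, factor(status, levels = labels), sum, default = 0)
    scores[] <- agg / tot
  } else {
    scores[] <- 1 / length(labels)  # no information: uniform scores
  }
  pred <- labels[which.max(scores)]  # which.max keeps first tie in label order
  out <- tibble::tibble(predicted = pred)
  out[paste0("score_", labels)] <- as.list(unname(scores))
  out
}

#' Two-step search-based diagnosis
#'
#' Step I scores each query's novelty (MNS) against a healthy baseline
#' database and calls disease status by thresholding it. Step II classifies
#' the step-I positives by rank-weighted nearest-neighbour search against a
#' database of samples from diseased subjects; healthy calls stop after step
#' I (set `classify_all = TRUE` to classify every query, e.g. for evaluation
#' sweeps). Both match lists are retained as attributes for provenance.
#'
#' @param queries an OTU table tibble of query samples aligned to the shared
#'   tree.
#' @param baseline_index `search_index` over the healthy baseline database.
#' @param disease_index `search_index` over the labelled disease database
#'   (its metadata must supply `status`).
#' @param n matches per query (default 10).
#' @param threshold MNS decision threshold (default 0.072).
#' @param weighted rank-weighted formulas (default `TRUE`).
#' @param candidates prefilter size (default 200).
#' @param metric similarity metric (default `"phylogenetic"`).
#' @param classify_all classify healthy-called queries too (default `FALSE`).
#' @return a `diagnosis_result` tibble: `sample_id`, `mns`, `status`
#'   (healthy/diseased), `predicted` (NA for healthy unless `classify_all`)
#'   and per-label score columns. Attributes `baseline_matches` and
#'   `disease_matches` hold the underlying match lists.
#' @export
two_step_diagnose <- function(queries, baseline_index, disease_index,
                              n = 10, threshold = 0.072, weighted = TRUE,
                              candidates = 200,
                              metric = c("phylogenetic", "cosine", "euclidean"),
                              classify_all = FALSE) {
  metric <- match.arg(metric)
  base_matches <- search_topn(queries, baseline_index, n = n,
                              candidates = candidates, metric = metric)
  step1 <- compute_mns(base_matches, n = n, weighted = weighted)
  step1$status <- detect_status(step1$mns, threshold)
  to_classify <- if (classify_all) step1$sample_id
                 else step1$sample_id[step1$status == "diseased"]
  labels <- sort(unique(stats::na.omit(disease_index$status)))
  dis_matches <- NULL
  if (length(to_classify) > 0) {
    qsub <- queries[match(to_classify, queries$sample_id), , drop = FALSE]
    dis_matches <- search_topn(qsub, disease_index, n = n,
                               candidates = candidates, metric = metric)
    step2 <- classify_disease(dis_matches, n = n, weighted = weighted,
                              labels = labels)
    out <- dplyr::left_join(step1, step2, by = "sample_id")
  } else {
    out <- step1
    out$predicted <- NA_character_
    out[paste0("score_", labels)] <- NA_real_
  }
  if (!classify_all)
    out$predicted[out$status == "healthy"] <- NA_character_
  structure(out, class = c("diagnosis_result", class(out)),
            baseline_matches = base_matches, disease_matches = dis_matches,
            threshold = threshold, n = n, weighted = weighted)
}
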