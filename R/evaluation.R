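#' Confusion matrix from true and predicted labels
#'
#' @param truth,predicted character vectors of equal length.
#' @param labels label set (default: sorted union of both vectors).
#' @return a square integer matrix, rows = true labels, columns = predicted.
#' @export
confusion_matrix <- function(truth, predicted, labels = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(labels)) labels <- sort(unique(c(truth, predicted)))
  tab <- table(factor(truth, levels = labels),
               factor(predicted, levels = labels))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(true = labels, predicted = labels))
  m
}

#' Cohen's kappa for multi-class agreement
#'
#' Chance-corrected agreement `k = (p_o - p_e) / (1 - p_e)`, with expected
#' agreement `p_e` from the marginal products. The conventional
#' interpretation bands (0.00-0.20 slight, 0.21-0.40 fair, 0.41-0.60
#' moderate, 0.61-0.80 substantial, 0.81-1.00 almost perfect) are attached
#' as the `"interpretation"` attribute; note the standard definition can go
#' negative for worse-than-chance agreement and is reported as computed.
#'
#' @param cm a confusion matrix ([confusion_matrix()]).
#' @return kappa (double), with an `"interpretation"` attribute.
#' @examples
#' cohen_kappa(matrix(c(40, 5, 10, 45), 2, 2)) # 0.7
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  tot <- sum(cm)
  if (tot <= 0) rlang::abort("empty confusion matrix")
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (abs(1 - pe) < 1e-15) {
    if (po == 1) k <- 1
    else rlang::abort("kappa undefined: expected agreement is 1 but observed is not")
  } else {
    k <- (po - pe) / (1 - pe)
  }
  bands <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  idx <- max(1L, min(5L, findInterval(k, c(0.205, 0.405, 0.605, 0.805)) + 1L))
  structure(k, interpretation = if (k < 0) "worse than chance" else bands[idx])
}

#' One-vs-rest recall, precision and F1 per class
#'
#' Recall = TP / (TP + FN), precision = TP / (TP + FP), F1 their harmonic
#' mean. A zero denominator yields 0 and sets the corresponding
#' `undefined_*` flag.
#'
#' @param cm a confusion matrix.
#' @param label a single class, or `NULL` for all classes.
#' @return a tibble with columns `label`, `recall`, `precision`, `f1`,
#'   `undefined_recall`, `undefined_precision`.
#' @export
precision_recall_f1 <- function(cm, label = NULL) {
  cm <- as.matrix(cm)
  labs <- rownames(cm)
  if (!is.null(label)) {
    if (!label %in% labs) rlang::abort(sprintf("label '%s' not in matrix", label))
    labs <- label
  }
  purrr::map_dfr(labs, function(g) {
    tp <- cm[g, g]
    fn <- sum(cm[g, ]) - tp
    fp <- sum(cm[, g]) - tp
    und_r <- (tp + fn) == 0
    und_p <- (tp + fp) == 0
    rec <- if (und_r) 0 else tp / (tp + fn)
    prec <- if (und_p) 0 else tp / (tp + fp)
    f1 <- if (rec + prec == 0) 0 else 2 * rec * prec / (rec + prec)
    tibble::tibble(label = g, recall = rec, precision = prec, f1 = f1,
                   undefined_recall = und_r, undefined_precision = und_p)
  })
}

#' ROC curve and AUC for a binary score
#'
#' The AUC is the probability that a randomly chosen positive outranks a
#' randomly chosen negative, ties counting one half — the rank-statistic
#' (Mann-Whitney) formulation. The ROC curve is traced by sweeping a
#' threshold over the observed scores; trapezoidal integration of the curve
#' equals the rank AUC.
#'
#' @param scores numeric scores, larger = more positive-like.
#' @param labels logical (or 0/1) truth, `TRUE` = positive.
#' @return a `roc_result` list: `roc` (tibble with `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0 || nneg == 0)
    rlang::abort("both classes must be present to compute a ROC")
  r <- rank(scores)  # midranks: ties count 0.5
  auc <- (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & !labels) / nneg,
                   tpr = sum(pred & labels) / npos)
  })
  structure(list(roc = roc, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$roc)))
  invisible(x)
}

#' Keep one sample per host and cohort
#'
#' Longitudinal replicates from the same host inflate apparent sample sizes;
#' before statistics, exactly one sample per (host, status) pair is retained
#' by a seeded uniform draw.
#'
#' @param metadata a metadata tibble with `sample_id`, `host_id`, `status`.
#' @param seed integer seed making the draw reproducible (`NULL` = ambient
#'   RNG).
#' @return the retained sample ids (character vector).
#' @export
dedup_hosts <- function(metadata, seed = NULL) {
  stopifnot(all(c("sample_id", "host_id", "status") %in% names(metadata)))
  local_rng(seed, {
    metadata |>
      dplyr::group_by(.data$host_id, .data$status) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup() |>
      dplyr::pull(.data$sample_id) |>
      sort()
  })
}

#' Repeated stratified cross-validated search classification
#'
#' Per repetition: deduplicate hosts, split samples into stratified folds,
#' and classify each held-out fold by rank-weighted top-N search against the
#' remaining folds; per-repetition Cohen's kappa is summarised as mean, SD
#' and a normal-theory 95% CI (`mean +/- 1.96 * SD / sqrt(reps)`). Per-class
#' recall/precision/F1 are reported both pooled over all repetitions and as
#' the mean of per-repetition values.
#'
#' @param tbl an OTU table tibble (aligned to `tree`).
#' @param metadata metadata tibble with `sample_id`, `host_id`, `status`.
#' @param tree rooted `phylo` (for the phylogenetic metric).
#' @param folds number of folds (default 10).
#' @param reps repetitions (default 30).
#' @param n matches per query (default 10).
#' @param weighted rank weights (default TRUE).
#' @param metric similarity metric.
#' @param seed integer seed; repetition `r` uses a sub-seed derived from it.
#' @param query_tbl optional OTU table with the same sample ids as `tbl`;
#'   when given, held-out samples are scored from this table while the
#'   training folds come from `tbl`. This is how robustness conditions
#'   (e.g. contamination) are evaluated: queries perturbed, reference
#'   database clean.
#' @return an `eval_report` object; see [glance.eval_report()].
#' @export
cross_validate <- function(tbl, metadata, tree = NULL, folds = 10, reps = 30,
                           n = 10, weighted = TRUE,
                           metric = c("phylogenetic", "cosine", "euclidean"),
                           seed = 1, query_tbl = NULL) {
  metric <- match.arg(metric)
  m_all <- otu_matrix(normalize_profiles(tbl))
  m_query <- if (is.null(query_tbl)) m_all else {
    qm <- otu_matrix(normalize_profiles(query_tbl))
    if (!all(rownames(m_all) %in% rownames(qm)))
      rlang::abort("`query_tbl` must cover the same sample ids as `tbl`")
    # queries may carry extra (e.g. contaminant) OTUs; keep the shared tree space
    qm
  }
  enc <- if (metric == "phylogenetic") tree_encoding(tree) else NULL
  labels <- sort(unique(metadata$status))
  kappas <- numeric(reps)
  per_rep_class <- vector("list", reps)
  pooled_truth <- character(0); pooled_pred <- character(0)
  for (r in seq_len(reps)) {
    sr <- derive_seed(seed, r)
    keep <- dedup_hosts(metadata, seed = sr)
    md <- metadata[metadata$sample_id %in% keep, ]
    cnt <- table(md$status)
    short <- names(cnt)[cnt < folds]
    if (length(short) > 0)
      rlang::abort(sprintf("label '%s' has fewer than %d samples after host deduplication",
                           short[1], folds))
    fold_of <- local_rng(derive_seed(sr, 1), stratified_folds(md$status, folds))
    truth <- pred <- character(nrow(md))
    for (f in seq_len(folds)) {
      idx <- which(fold_of == f)
      test_ids <- md$sample_id[idx]
      train_ids <- md$sample_id[-idx]
      sims <- similarity_batch(m_query[test_ids, , drop = FALSE],
                               m_all[train_ids, , drop = FALSE], metric, enc)
      train_status <- md$status[match(train_ids, md$sample_id)]
      ml <- purrr::map_dfr(seq_along(test_ids), function(qi) {
        ord <- order(-sims[qi, ], train_ids)[seq_len(min(n, length(train_ids)))]
        tibble::tibble(query_id = test_ids[qi], rank = seq_along(ord),
                       similarity = unname(sims[qi, ord]),
                       status = train_status[ord])
      })
      cls <- classify_disease(ml, n = n, weighted = weighted, labels = labels)
      pred[idx] <- cls$predicted[match(test_ids, cls$sample_id)]
      truth[idx] <- md$status[idx]
    }
    kappas[r] <- as.numeric(cohen_kappa(confusion_matrix(truth, pred, labels)))
    per_rep_class[[r]] <- precision_recall_f1(confusion_matrix(truth, pred, labels))
    pooled_truth <- c(pooled_truth, truth); pooled_pred <- c(pooled_pred, pred)
  }
  cm_pooled <- confusion_matrix(pooled_truth, pooled_pred, labels)
  per_class_rep_mean <- dplyr::bind_rows(per_rep_class) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(dplyr::across(c("recall", "precision", "f1"), mean),
                     .groups = "drop")
  new_eval_report(kappas, labels, cm_pooled,
                  per_class_pooled = precision_recall_f1(cm_pooled),
                  per_class_rep_mean = per_class_rep_mean,
                  folds = folds, reps = reps, seed = seed, metric = metric)
}

stratified_folds <- function(status, folds) {
  fold_of <- integer(length(status))
  for (g in unique(status)) {
    idx <- sample(which(status == g))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

new_eval_report <- function(kappas, labels, cm, per_class_pooled = NULL,
                            per_class_rep_mean = NULL, ...) {
  reps <- length(kappas)
  mu <- mean(kappas); s <- if (reps > 1) sd(kappas) else 0
  half <- 1.96 * s / sqrt(reps)
  structure(list(kappa = kappas, kappa_mean = mu, kappa_sd = s,
                 kappa_ci = c(lower = mu - half, upper = mu + half),
                 labels = labels, confusion = cm,
                 per_class_pooled = per_class_pooled,
                 per_class_rep_mean = per_class_rep_mean,
                 settings = list(...)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> kappa = %.3f +/- %.3f (95%% CI %.3f-%.3f, %d repetitions)\n",
              x$kappa_mean, x$kappa_sd, x$kappa_ci[1], x$kappa_ci[2],
              length(x$kappa)))
  invisible(x)
}

#' Kappa difference between two evaluation conditions
#'
#' `delta_kappa(condition, reference)` is the difference of mean kappas
#' (condition minus reference), quantifying the impact of a changed
#' condition (e.g. contamination) on classification performance.
#'
#' @param report_a,report_b `eval_report`s over the same label set.
#' @return a double, with both means attached as attributes.
#' @export
delta_kappa <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "eval_report"), inherits(report_b, "eval_report"))
  if (!identical(report_a$labels, report_b$labels))
    rlang::abort("the two reports cover different label sets")
  structure(report_a$kappa_mean - report_b$kappa_mean,
            mean_a = report_a$kappa_mean, mean_b = report_b$kappa_mean)
}

#' Simulate sequencing contamination of a sample
#'
#' Draws one source community uniformly from a contamination pool and mixes
#' `round(m * rate)` contaminant reads (multinomially, from the source's
#' relative abundances) into a target sample holding `m` reads. The rate is
#' therefore a read-mass fraction: at `rate = 0.2` a 100-read sample gains 20
#' contaminant reads.
#'
#' @param counts named non-negative counts of the target sample.
#' @param pool an OTU table tibble of contamination source samples.
#' @param rate contamination rate in `[0, 1]`.
#' @param seed integer seed (`NULL` = ambient RNG).
#' @return named contaminated counts over the union of target and source
#'   OTUs.
#' @export
contaminate_sample <- function(counts, pool, rate, seed = NULL) {
  stopifnot(is.numeric(counts), !is.null(names(counts)),
            rate >= 0, rate <= 1)
  m <- sum(counts)
  if (m <= 0) rlang::abort("target sample has no reads")
  pm <- otu_matrix(pool)
  if (nrow(pm) == 0) rlang::abort("empty contamination pool")
  n_cont <- round(m * rate)
  if (n_cont == 0) return(counts)
  local_rng(seed, {
    src <- pm[sample.int(nrow(pm), 1), ]
    src_p <- src / sum(src)
    add <- rmultinom(1, n_cont, src_p)[, 1]
    ids <- union(names(counts), names(src_p))
    out <- setNames(numeric(length(ids)), ids)
    out[names(counts)] <- counts
    out[names(add)] <- out[names(add)] + add
    out
  })
}

#' @rdname contaminate_sample
#' @param tbl an OTU table tibble of target samples; each row is
#'   contaminated independently with a sub-seed derived from `seed`.
#' @export
contaminate_table <- function(tbl, pool, rate, seed = NULL) {
  m <- otu_matrix(tbl)
  rows <- purrr::map(seq_len(nrow(m)), function(i) {
    contaminate_sample(m[i, ], pool, rate, seed = derive_seed(seed, i))
  })
  ids <- unique(unlist(purrr::map(rows, names)))
  out <- matrix(0, nrow(m), length(ids), dimnames = list(rownames(m), ids))
  for (i in seq_along(rows)) out[i, names(rows[[i]])] <- rows[[i]]
  as_otu_tibble(out)
}

#' Rarefy a reference database to a fixed number of samples
#'
#' Draws `reps` independent uniform subsamples of `n` samples (without
#' replacement) from the database, to study how reference breadth drives
#' detection performance.
#'
#' @param db an OTU table tibble.
#' @param n subsample size (must not exceed the database size).
#' @param reps number of independent subsamples (default 10).
#' @param seed integer seed.
#' @return a list of `reps` OTU table tibbles.
#' @export
rarefy_baseline <- function(db, n, reps = 10, seed = NULL) {
  validate_otu_tbl(db)
  if (n > nrow(db))
    rlang::abort(sprintf("cannot rarefy to %d samples from a database of %d", n, nrow(db)))
  purrr::map(seq_len(reps), function(r) {
    local_rng(derive_seed(seed, r), db[sort(sample.int(nrow(db), n)), , drop = FALSE])
  })
}

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' For groups of at most 8 observations each the null distribution of the
#' rank sum is enumerated exactly over all assignments of the pooled
#' midranks (so ties are handled exactly); larger groups use the normal
#' approximation with tie correction and continuity correction. The
#' two-sided p is twice the smaller tail, capped at 1.
#'
#' @param x,y numeric vectors, both nonempty.
#' @param exact_max largest per-group size for exact enumeration (default 8).
#' @return the two-sided p-value.
#' @examples
#' ranksum_test(1:3, 4:6) # 0.1
#' @export
ranksum_test <- function(x, y, exact_max = 8) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    sums <- combn(r, n1, sum)
    p <- 2 * min(mean(sums <= w + 1e-9), mean(sums >= w - 1e-9))
    return(min(p, 1))
  }
  N <- n1 + n2
  mu <- n1 * (N + 1) / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  min(2 * pnorm(-max(z, 0)), 1)
}
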