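test_that("rank-statistic AUC matches hand-counts and trapezoidal ROC integration", {
  # 3 of 4 positive-negative pairs concordant
  r <- roc_auc(c(0.9, 0.8, 0.85, 0.7), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75, tolerance = 1e-12)
  # perfect separation and all-tied scores
  expect_equal(roc_auc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  trapezoid <- function(roc) {
    o <- order(roc$fpr, roc$tpr)
    x <- roc$fpr[o]; y <- roc$tpr[o]
    sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  }
  set.seed(4)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), sample(1:3, 1))  # coarse grids induce ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, trapezoid(r$roc), tolerance = 1e-9)
  }
  # agreement with an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(9)
  scores <- rnorm(80); labels <- runif(80) < 0.5
  expect_equal(roc_auc(scores, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-9)
})

test_that("Cohen's kappa matches hand arithmetic and behaves at the extremes", {
  cm <- matrix(c(40, 5, 10, 45), 2, 2)  # [[40,10],[5,45]] as true x predicted
  expect_equal(as.numeric(cohen_kappa(cm)), 0.7, tolerance = 1e-12)
  expect_equal(as.numeric(cohen_kappa(diag(c(10, 20, 5)))), 1)
  # shuffled labels concentrate kappa at zero
  set.seed(12)
  ks <- replicate(200, {
    truth <- sample(c("a", "b", "c"), 300, TRUE)
    as.numeric(cohen_kappa(confusion_matrix(truth, sample(truth))))
  })
  expect_lt(abs(mean(ks)), 0.02)
  # degenerate single-cell matrix: perfect agreement reports 1
  one <- matrix(7, 1, 1, dimnames = list("a", "a"))
  expect_equal(as.numeric(cohen_kappa(one)), 1)
  expect_match(attr(cohen_kappa(cm), "interpretation"), "substantial")
})

test_that("per-class recall and precision come from one-vs-rest counts", {
  cm <- confusion_matrix(rep(c("pos", "neg"), c(50, 50)),
                         c(rep("pos", 40), rep("neg", 10),
                           rep("pos", 5), rep("neg", 45)))
  pr <- precision_recall_f1(cm, "pos")
  expect_equal(pr$recall, 0.8)
  expect_equal(pr$precision, 40 / 45, tolerance = 1e-12)
  expect_equal(pr$f1, 2 * 0.8 * (40 / 45) / (0.8 + 40 / 45), tolerance = 1e-12)
  perfect <- precision_recall_f1(diag(c(5, 5)) |>
                                   `dimnames<-`(list(c("a", "b"), c("a", "b"))))
  expect_true(all(perfect$recall == 1 & perfect$precision == 1 & perfect$f1 == 1))
  # a never-predicted class is flagged with zero precision
  cm2 <- matrix(c(3, 2, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  pr2 <- precision_recall_f1(cm2, "b")
  expect_equal(pr2$precision, 0)
  expect_true(pr2$undefined_precision)
})

test_that("host deduplication keeps one sample per host-cohort and is seed-deterministic", {
  md <- tibble::tibble(sample_id = paste0("s", 1:7),
                       host_id = c("h1", "h1", "h1", "h2", "h3", "h3", "h2"),
                       status = c("IBD", "IBD", "IBD", "IBD", "control",
                                  "control", "control"))
  keep <- dedup_hosts(md, seed = 5)
  expect_equal(length(keep), 4)  # h1/IBD, h2/IBD, h3/control, h2/control
  tab <- md[md$sample_id %in% keep, ]
  expect_false(any(duplicated(tab[c("host_id", "status")])))
  expect_identical(dedup_hosts(md, seed = 5), dedup_hosts(md, seed = 5))
  # all-unique hosts are untouched
  uniq <- tibble::tibble(sample_id = c("a", "b"), host_id = c("x", "y"),
                         status = "IBD")
  expect_setequal(dedup_hosts(uniq, seed = 1), c("a", "b"))
})

test_that("contamination adds the specified read mass from a pool sample", {
  pool <- as_otu_tibble(matrix(c(10, 90, 50, 50), 2, 2, byrow = TRUE,
                               dimnames = list(c("p1", "p2"), c("C_1", "C_2"))))
  target <- c(OTU_1 = 60, OTU_2 = 40)
  expect_identical(contaminate_sample(target, pool, 0, seed = 3), target)
  out <- contaminate_sample(target, pool, 0.2, seed = 3)
  expect_equal(sum(out), 120)  # 100 + round(100 * 0.2)
  expect_equal(out[c("OTU_1", "OTU_2")], target)  # original reads untouched
  # the sweep grid used in the robustness experiments
  for (r in c(0.05, 0.10, 0.15, 0.20)) {
    out <- contaminate_sample(target, pool, r, seed = 11)
    expect_equal(sum(out), 100 + round(100 * r))
  }
  expect_identical(contaminate_sample(target, pool, 0.2, seed = 3),
                   contaminate_sample(target, pool, 0.2, seed = 3))
  tblout <- contaminate_table(as_otu_tibble(rbind(t1 = target)), pool, 0.1,
                              seed = 4)
  expect_equal(sum(otu_matrix(tblout)), 110)
})

test_that("baseline rarefaction draws seeded subsamples without replacement", {
  bench <- get_bench()
  db <- bench$baseline$table[1:10, ]
  subs <- rarefy_baseline(db, 3, reps = 4, seed = 6)
  expect_length(subs, 4)
  for (s in subs) {
    expect_equal(nrow(s), 3)
    expect_false(any(duplicated(s$sample_id)))
    expect_true(all(s$sample_id %in% db$sample_id))
  }
  expect_identical(rarefy_baseline(db, 3, reps = 4, seed = 6), subs)
  full <- rarefy_baseline(db, 10, reps = 2, seed = 1)
  expect_setequal(full[[1]]$sample_id, db$sample_id)
  expect_error(rarefy_baseline(db, 11, seed = 1), "cannot rarefy")
})

test_that("rank-sum p-values are exact for small groups and approximate beyond", {
  expect_equal(ranksum_test(1:3, 4:6), 0.1, tolerance = 1e-12)
  expect_equal(ranksum_test(c(2, 2, 2), c(2, 2, 2)), 1)
  # exact route agrees with the reference implementation when tie-free
  set.seed(14)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    expect_equal(ranksum_test(x, y),
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  # normal approximation within 10% of exact at n = 8, in the moderate-p
  # regime where the approximation is meant to be used (deep tails are
  # beyond any normal approximation at this sample size)
  checked <- 0
  for (i in 1:40) {
    x <- rnorm(8); y <- rnorm(8, mean = 0.5)
    pe <- ranksum_test(x, y)
    if (pe < 0.05) next
    pa <- ranksum_test(x, y, exact_max = 0)
    expect_lt(abs(pa - pe) / pe, 0.10)
    checked <- checked + 1
  }
  expect_gte(checked, 10)
  # strongly separated large samples
  set.seed(15)
  expect_lt(ranksum_test(rnorm(50), rnorm(50, mean = 3)), 1e-6)
})

test_that("cross-validation separates synthetic cohorts, nulls out under shuffling, and is reproducible", {
  bench <- get_bench()
  ts <- bench$test
  cv <- cross_validate(ts$table, ts$metadata, bench$tree, folds = 10, reps = 2,
                       seed = 3)
  expect_gte(cv$kappa_mean, 0.8)
  expect_identical(
    glance(cross_validate(ts$table, ts$metadata, bench$tree, folds = 10,
                          reps = 1, seed = 3)),
    glance(cross_validate(ts$table, ts$metadata, bench$tree, folds = 10,
                          reps = 1, seed = 3)))
  # shuffling the labels destroys the signal
  md_shuf <- ts$metadata
  set.seed(99)
  md_shuf$status <- sample(md_shuf$status)
  md_shuf$host_id <- md_shuf$sample_id  # break replicate structure with labels
  cv0 <- cross_validate(ts$table, md_shuf, bench$tree, folds = 10, reps = 2,
                        seed = 3)
  expect_lt(abs(cv0$kappa_mean), 0.1)
  # a label with too few samples is refused by name
  tiny_md <- ts$metadata
  tiny_md$status[tiny_md$sample_id %in% tiny_md$sample_id[tiny_md$status == "CRC"][-(1:3)]] <- "IBD"
  expect_error(cross_validate(ts$table, tiny_md, bench$tree, folds = 10,
                              reps = 1, seed = 1), "CRC")
})

test_that("delta kappa subtracts mean kappas and checks label sets", {
  bench <- get_bench()
  ts <- bench$test
  a <- cross_validate(ts$table, ts$metadata, bench$tree, folds = 5, reps = 1,
                      seed = 2)
  expect_equal(as.numeric(delta_kappa(a, a)), 0)
  b <- a; b$kappa_mean <- a$kappa_mean - 0.07
  expect_equal(as.numeric(delta_kappa(b, a)), -0.07, tolerance = 1e-12)
  c_ <- a; c_$labels <- c("x", "y")
  expect_error(delta_kappa(a, c_), "label sets")
})

test_that("evaluation reports expose tidy, glance and plots", {
  bench <- get_bench()
  ts <- bench$test
  cv <- cross_validate(ts$table, ts$metadata, bench$tree, folds = 5, reps = 2,
                       seed = 2)
  td <- tidy(cv)
  expect_equal(nrow(td), 2)
  expect_named(td, c("repetition", "kappa"))
  pc <- tidy(cv, per_class = TRUE)
  expect_setequal(unique(pc$aggregation), c("pooled", "rep_mean"))
  expect_setequal(unique(pc$label), cv$labels)
  g <- glance(cv)
  expect_equal(g$kappa_mean, cv$kappa_mean)
  expect_true(g$ci_lower <= g$kappa_mean && g$kappa_mean <= g$ci_upper)
  expect_s3_class(autoplot(cv), "ggplot")
  r <- roc_auc(runif(20), rep(c(TRUE, FALSE), 10))
  expect_s3_class(autoplot(r), "ggplot")
})
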