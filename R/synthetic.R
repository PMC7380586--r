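# Dirichlet draw: n vectors over length(alpha) categories.
rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, ] <- 1 / length(alpha)  # degenerate tiny-alpha guard
  x / rowSums(x)
}

#' Random bifurcating tree for synthetic communities
#'
#' Generates a rooted random bifurcating topology with branch lengths drawn
#' uniformly on `(0, max_branch]` and leaves labelled `OTU_1..OTU_n`.
#'
#' @param n_otus number of leaves (>= 2).
#' @param max_branch largest branch length (<= 1, default 1).
#' @param seed integer seed.
#' @return a `phylo` object.
#' @export
make_tree <- function(n_otus, max_branch = 1, seed = NULL) {
  stopifnot(n_otus >= 2, max_branch > 0, max_branch <= 1)
  local_rng(seed, {
    ape::rtree(n_otus, tip.label = paste0("OTU_", seq_len(n_otus)),
               br = function(n) max_branch * (1 - runif(n)))
  })
}

#' Healthy baseline community generator
#'
#' Draws a global base composition from a symmetric Dirichlet (the
#' `base_alpha` default of 0.5 gives realistic unevenness — a few dominant
#' taxa, a long tail), optionally spreads it into `n_clusters`
#' sub-communities (cluster means are log-normal multiplicative jitters of
#' the base, emulating between-study/population heterogeneity), then draws
#' each sample's underlying composition from
#' `Dirichlet(concentration * cluster_mean)` and its counts from a
#' multinomial at the given sequencing depth. With `n_clusters = 1` (the
#' default) the baseline is a single cluster around `base`. Each cluster is
#' pinned to a geographic region drawn from `region_freqs`, so region labels
#' carry compositional signal.
#'
#' @param tree a `phylo` whose tips define the OTUs.
#' @param n_samples number of samples.
#' @param concentration Dirichlet concentration around the cluster mean
#'   (default 100); larger = tighter clusters.
#' @param depth reads per sample (default 5000).
#' @param seed integer seed.
#' @param base optional global base composition (length = tips, sums to 1);
#'   drawn if `NULL`.
#' @param base_alpha symmetric Dirichlet parameter for the base draw.
#' @param n_clusters number of healthy sub-communities (default 1).
#' @param cluster_sd log-scale SD of the cluster-mean jitter (default 0.75).
#' @param label status label for the metadata (default `"control"`).
#' @param prefix sample-id prefix.
#' @param region_freqs,platform_freqs named sampling frequencies for the
#'   metadata columns.
#' @return a list with `table` (counts tibble), `metadata` (tibble), `base`
#'   (the global base composition) and `cluster_means` (matrix, one row per
#'   cluster).
#' @export
make_baseline <- function(tree, n_samples, concentration = 100, depth = 5000,
                          seed = NULL, base = NULL, base_alpha = 0.5,
                          n_clusters = 1, cluster_sd = 0.75,
                          label = "control", prefix = "base",
                          region_freqs = c(US = 0.6, SE = 0.2, UK = 0.15, AU = 0.05),
                          platform_freqs = c(Illumina = 0.7, `454` = 0.3)) {
  n_otus <- length(tree$tip.label)
  stopifnot(n_clusters >= 1, concentration > 0)
  local_rng(seed, {
    if (is.null(base)) base <- rdirichlet(1, rep(base_alpha, n_otus))[1, ]
    cl <- make_clusters(base, n_clusters, cluster_sd)
    cluster_region <- sample(names(region_freqs), n_clusters, TRUE,
                             prob = region_freqs)
    if (n_samples == 0) {
      m <- matrix(numeric(0), 0, n_otus, dimnames = list(NULL, tree$tip.label))
      return(list(table = as_otu_tibble(m),
                  metadata = tibble::tibble(sample_id = character(0),
                                            host_id = character(0),
                                            status = character(0),
                                            region = character(0),
                                            platform = character(0)),
                  base = base, cluster_means = cl))
    }
    which_cl <- sample.int(n_clusters, n_samples, replace = TRUE)
    probs <- matrix(0, n_samples, n_otus)
    for (i in seq_len(n_samples))
      probs[i, ] <- rdirichlet(1, concentration * cl[which_cl[i], ])[1, ]
    counts <- t(apply(probs, 1, function(p) rmultinom(1, depth, p)[, 1]))
    ids <- sprintf("%s_%04d", prefix, seq_len(n_samples))
    dimnames(counts) <- list(ids, tree$tip.label)
    md <- tibble::tibble(sample_id = ids,
                         host_id = sprintf("%s_h%04d", prefix, seq_len(n_samples)),
                         status = label,
                         region = cluster_region[which_cl],
                         platform = sample(names(platform_freqs), n_samples, TRUE,
                                           prob = platform_freqs))
    list(table = as_otu_tibble(counts), metadata = md, base = base,
         cluster_means = cl)
  })
}

# cluster means: lognormal multiplicative jitter of the base, renormalised
make_clusters <- function(base, n_clusters, cluster_sd) {
  cl <- matrix(base, n_clusters, length(base), byrow = TRUE)
  if (n_clusters > 1 && cluster_sd > 0) {
    jit <- matrix(exp(stats::rnorm(n_clusters * length(base), 0, cluster_sd)),
                  n_clusters)
    cl <- cl * jit
    cl <- cl / rowSums(cl)
  }
  cl
}

#' Disease cohort generator with tunable compositional effect size
#'
#' The cohort's composition model is the healthy one (the same cluster
#' means) with a seeded random subset (`affected_fraction` of OTUs)
#' multiplied by `exp(+/- effect_size)` (signs random per OTU) and
#' renormalised — the same disease signature applied to every healthy
#' sub-community. `effect_size = 0` leaves the healthy distribution exactly
#' untouched. Each host draws a cluster and one composition from
#' `Dirichlet(concentration * perturbed_mean)`; longitudinal replicates of a
#' host share that draw and differ only by multinomial counting noise, which
#' is what host deduplication is meant to correct for.
#'
#' @param tree a `phylo` over the OTUs.
#' @param base healthy composition: a single vector, or a matrix of cluster
#'   means (e.g. `cluster_means` from [make_baseline()]).
#' @param label cohort status label.
#' @param n_hosts number of hosts.
#' @param replicates samples per host: a scalar or length-`n_hosts` vector.
#' @param effect_size log-scale perturbation magnitude (>= 0).
#' @param affected_fraction fraction of OTUs perturbed, in (0, 1].
#' @param concentration,depth,region_freqs,platform_freqs as in
#'   [make_baseline()].
#' @param platform_bias_sd per-platform multiplicative bias: when > 0 each
#'   platform gets a lognormal per-OTU bias vector with this log-sd applied
#'   to compositions before the count draw (a synthetic batch effect).
#' @param seed integer seed.
#' @return a list with `table`, `metadata` and `mean` (the perturbed cluster
#'   means, one row per cluster).
#' @export
make_cohort <- function(tree, base, label, n_hosts, replicates = 1,
                        effect_size = 0, affected_fraction = 0.2,
                        concentration = 100, depth = 5000,
                        region_freqs = c(US = 0.6, SE = 0.2, UK = 0.15, AU = 0.05),
                        platform_freqs = c(Illumina = 0.7, `454` = 0.3),
                        platform_bias_sd = 0, seed = NULL) {
  stopifnot(effect_size >= 0, affected_fraction > 0, affected_fraction <= 1,
            concentration > 0, n_hosts >= 1)
  if (!is.matrix(base)) base <- matrix(base, 1, length(base))
  n_otus <- ncol(base)
  n_clusters <- nrow(base)
  if (length(replicates) == 1) replicates <- rep(replicates, n_hosts)
  stopifnot(length(replicates) == n_hosts, all(replicates >= 1))
  local_rng(seed, {
    mu <- base
    if (effect_size > 0) {
      k <- max(1L, round(affected_fraction * n_otus))
      idx <- sample.int(n_otus, k)
      signs <- sample(c(-1, 1), k, replace = TRUE)
      mu[, idx] <- sweep(mu[, idx, drop = FALSE], 2, exp(signs * effect_size), "*")
      mu <- mu / rowSums(mu)
    }
    bias <- list()
    if (platform_bias_sd > 0)
      for (pf in names(platform_freqs))
        bias[[pf]] <- exp(stats::rnorm(n_otus, 0, platform_bias_sd))
    total <- sum(replicates)
    counts <- matrix(0L, total, n_otus)
    ids <- character(total); hosts <- character(total); plats <- character(total)
    regions <- character(total)
    host_platform <- sample(names(platform_freqs), n_hosts, TRUE, prob = platform_freqs)
    host_cluster <- sample.int(n_clusters, n_hosts, replace = TRUE)
    host_region <- sample(names(region_freqs), n_hosts, TRUE, prob = region_freqs)
    row <- 0L
    for (h in seq_len(n_hosts)) {
      p_host <- rdirichlet(1, concentration * mu[host_cluster[h], ])[1, ]
      pf <- host_platform[h]
      p_obs <- p_host
      if (platform_bias_sd > 0) {
        p_obs <- p_host * bias[[pf]]
        p_obs <- p_obs / sum(p_obs)
      }
      for (rep_i in seq_len(replicates[h])) {
        row <- row + 1L
        counts[row, ] <- rmultinom(1, depth, p_obs)[, 1]
        ids[row] <- sprintf("%s_h%03d_r%d", label, h, rep_i)
        hosts[row] <- sprintf("%s_h%03d", label, h)
        plats[row] <- pf
        regions[row] <- host_region[h]
      }
    }
    dimnames(counts) <- list(ids, tree$tip.label)
    md <- tibble::tibble(sample_id = ids, host_id = hosts, status = label,
                         region = regions, platform = plats)
    list(table = as_otu_tibble(counts), metadata = md, mean = mu)
  })
}

#' Full synthetic benchmark bundle
#'
#' One call generating everything the pipeline needs: a random tree, a
#' heterogeneous healthy baseline database (a 10-sub-community mixture,
#' emulating a multi-study reference collection), four disease cohorts plus
#' held-out healthy controls (a five-cohort design with sizes proportioned
#' like a multi-study gut collection), and a contamination pool drawn from a
#' distinct base community. Each disease cohort perturbs its own seeded OTU
#' subset, so cohorts are mutually distinguishable at sufficient effect
#' size; held-out controls use effect 0 and are distributionally identical
#' to the baseline. Roughly 10% of test hosts carry a longitudinal
#' replicate so deduplication has work to do.
#'
#' @param seed integer seed (fully determines the bundle).
#' @param n_otus tree size (default 512).
#' @param baseline_n healthy baseline samples (default 2000).
#' @param effect_size disease effect size (default 2, a separable regime).
#' @param cohort_sizes named target sample counts for the test cohorts.
#' @param n_clusters healthy sub-communities (default 10).
#' @param concentration,depth as in [make_baseline()].
#' @param pool_n contamination pool size (default 100).
#' @param out_dir optional directory; when given, the standard files
#'   (`baseline.tsv`, `test.tsv`, `pool.tsv`, `*.metadata.tsv`, `tree.nwk`)
#'   are written there.
#' @return a list: `tree`, `base`, `cluster_means`, `baseline` (list of
#'   table/metadata), `test` (table/metadata over all five cohorts), `pool`
#'   (table), and the generating `params`.
#' @export
make_benchmark <- function(seed = 1, n_otus = 512, baseline_n = 2000,
                           effect_size = 2,
                           cohort_sizes = c(IBD = 199, HIV = 72, CRC = 24,
                                            EDD = 44, control = 284),
                           n_clusters = 10, concentration = 100, depth = 5000,
                           pool_n = 100, out_dir = NULL) {
  tree <- make_tree(n_otus, seed = derive_seed(seed, 101))
  baseline <- make_baseline(tree, baseline_n, concentration = concentration,
                            depth = depth, n_clusters = n_clusters,
                            seed = derive_seed(seed, 102))
  cohorts <- purrr::imap(cohort_sizes, function(n_target, label) {
    n_dup <- ceiling(0.1 * n_target)               # hosts with one replicate
    n_hosts <- n_target - n_dup
    reps <- rep(1L, n_hosts); reps[seq_len(n_dup)] <- 2L
    make_cohort(tree, baseline$cluster_means, label = label, n_hosts = n_hosts,
                replicates = reps,
                effect_size = if (label == "control") 0 else effect_size,
                concentration = concentration, depth = depth,
                seed = derive_seed(seed, 200 + match(label, names(cohort_sizes))))
  })
  test_table <- dplyr::bind_rows(purrr::map(cohorts, "table"))
  test_md <- dplyr::bind_rows(purrr::map(cohorts, "metadata"))
  pool <- make_baseline(tree, pool_n, concentration = concentration,
                        depth = depth, seed = derive_seed(seed, 300),
                        label = "contaminant", prefix = "pool")
  bundle <- list(tree = tree, base = baseline$base,
                 cluster_means = baseline$cluster_means,
                 baseline = baseline[c("table", "metadata")],
                 test = list(table = test_table, metadata = test_md),
                 pool = pool$table,
                 params = list(seed = seed, n_otus = n_otus,
                               baseline_n = baseline_n,
                               effect_size = effect_size,
                               cohort_sizes = cohort_sizes,
                               n_clusters = n_clusters,
                               concentration = concentration, depth = depth))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    write_otu_table(bundle$baseline$table, file.path(out_dir, "baseline.tsv"))
    write_sample_metadata(bundle$baseline$metadata,
                          file.path(out_dir, "baseline.metadata.tsv"))
    write_otu_table(test_table, file.path(out_dir, "test.tsv"))
    write_sample_metadata(test_md, file.path(out_dir, "test.metadata.tsv"))
    write_otu_table(pool$table, file.path(out_dir, "pool.tsv"))
  }
  bundle
}
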