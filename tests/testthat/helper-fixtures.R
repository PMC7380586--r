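# Shared fixtures, built once per test run.
.fixtures <- new.env()

# Desk-scale benchmark bundle reused across test files.
get_bench <- function() {
  if (is.null(.fixtures$bench)) {
    .fixtures$bench <- make_benchmark(
      seed = 7, n_otus = 128, baseline_n = 300,
      cohort_sizes = c(IBD = 40, HIV = 24, CRC = 16, EDD = 20, control = 60))
  }
  .fixtures$bench
}

three_leaf_tree <- function() {
  ape::read.tree(text = "((L1:0.2,L2:0.2):0.5,L3:0.4);")
}

# Tiny two-sample counts table used across io tests.
tiny_table <- function() {
  as_otu_tibble(matrix(c(5, 10, 5, 0), 2, 2,
                       dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2"))))
}
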