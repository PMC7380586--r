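# Independent recursive implementation of the phylogeny-based similarity,
# written directly from the definition (leaf overlap + attenuated residual
# matching at internal nodes). Deliberately shares no code with the
# package's batch kernel.
ms_oracle <- function(a, b, tree) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  S <- 0
  rec <- function(node) {
    if (node <= ntip) {
      ai <- unname(a[tree$tip.label[node]]); if (is.na(ai)) ai <- 0
      bi <- unname(b[tree$tip.label[node]]); if (is.na(bi)) bi <- 0
      m <- min(ai, bi)
      S <<- S + m
      return(c(ai - m, bi - m))
    }
    ra <- 0; rb <- 0
    for (e in kids[[as.character(node)]]) {
      len <- if (is.null(tree$edge.length)) 0 else
        min(max(tree$edge.length[e], 0), 1)
      r <- rec(tree$edge[e, 2])
      ra <- ra + r[1] * (1 - len)
      rb <- rb + r[2] * (1 - len)
    }
    m <- min(ra, rb)
    S <<- S + m
    c(ra - m, rb - m)
  }
  rec(ntip + 1)
  S
}

# Random sparse relative-abundance profile over the tree's tips.
rprofile <- function(tree, nonzero = NULL) {
  tips <- tree$tip.label
  if (is.null(nonzero)) nonzero <- max(2L, rbinom(1, length(tips), 0.5))
  idx <- sample(seq_along(tips), min(nonzero, length(tips)))
  x <- setNames(numeric(length(tips)), tips)
  x[idx] <- rgamma(length(idx), shape = 1)
  x / sum(x)
}
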