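# Postorder edge-list encoding of a phylo tree, consumed by the C++ kernel.
# Edge lengths are clamped to [0, 1] defensively (read_newick already clamps,
# but trees can also be built programmatically).
tree_encoding <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  phy <- stats::reorder(tree, "postorder")
  elen <- phy$edge.length
  if (is.null(elen)) elen <- rep(0, nrow(phy$edge))
  elen[is.na(elen)] <- 0
  ntip <- length(phy$tip.label)
  list(parent = as.integer(phy$edge[, 1]),
       child = as.integer(phy$edge[, 2]),
       elen = pmin(pmax(elen, 0), 1),
       ntip = ntip,
       nnode = phy$Nnode,
       tip_labels = phy$tip.label,
       # tips in the order they are visited postorder; used for index binning
       tip_postorder = phy$edge[, 2][phy$edge[, 2] <= ntip])
}

# Map a profile matrix (samples x OTUs, named columns) onto tree tips and
# transpose to the kernel layout (one profile per column, row i = tip i).
profiles_to_tips <- function(m, enc, call = rlang::caller_env()) {
  missing <- setdiff(colnames(m), enc$tip_labels)
  if (length(missing) > 0)
    rlang::abort(sprintf("profile is not aligned to the tree: OTU '%s' is not a tree tip (see align_to_tree())",
                         missing[1]), call = call)
  out <- matrix(0, nrow = enc$ntip, ncol = nrow(m),
                dimnames = list(NULL, rownames(m)))
  out[match(colnames(m), enc$tip_labels), ] <- t(m)
  out
}

as_profile <- function(x, arg = "profile") {
  if (is.data.frame(x)) {
    validate_otu_tbl(x)
    if (nrow(x) != 1L)
      rlang::abort(sprintf("`%s` must be a single profile (one row)", arg))
    x <- otu_matrix(x)[1, ]
  }
  if (!is.numeric(x) || is.null(names(x)))
    rlang::abort(sprintf("`%s` must be a named numeric vector or one-row OTU tibble", arg))
  x
}

check_normalized <- function(x, arg, tol = 1e-6) {
  if (abs(sum(x) - 1) > tol)
    rlang::abort(sprintf("`%s` must be a relative-abundance profile summing to 1 (got %.6f)",
                         arg, sum(x)))
  invisible(x)
}

#' Phylogeny-based community similarity between two samples
#'
#' Computes the tree-structured overlap score between two relative-abundance
#' profiles. Abundance shared at a leaf matches in full; each sample's
#' unmatched leftover climbs the tree, attenuated by `(1 - branch length)`
#' per edge, and is matched against the other sample's leftover at every
#' internal node. The score is the total matched mass, in `[0, 1]`, with
#' `S(a, a) = 1`.
#'
#' @param a,b named relative-abundance profiles (named numeric vectors or
#'   one-row OTU tibbles) summing to 1, with all names among `tree`'s tips.
#' @param tree a rooted `phylo` tree with edge lengths in `[0, 1]`.
#' @return a similarity in `[0, 1]`.
#' @examples
#' tree <- ape::read.tree(text = "((L1:0.2,L2:0.2):0.5,L3:0.4);")
#' a <- c(L1 = 0.5, L2 = 0.5, L3 = 0)
#' b <- c(L1 = 0.5, L2 = 0, L3 = 0.5)
#' metastorms_similarity(a, b, tree) # 0.7
#' @export
metastorms_similarity <- function(a, b, tree) {
  a <- as_profile(a, "a"); b <- as_profile(b, "b")
  check_normalized(a, "a"); check_normalized(b, "b")
  enc <- tree_encoding(tree)
  A <- profiles_to_tips(rbind(a = a), enc)
  B <- profiles_to_tips(matrix(b, 1, dimnames = list("b", names(b))), enc)
  ms_similarity_batch(A, B, enc$parent, enc$child, enc$elen, enc$ntip, enc$nnode)[1, 1]
}

#' Cosine and Euclidean profile similarities
#'
#' Tree-free alternatives to [metastorms_similarity()]. `cosine_sim()` is the
#' cosine of the angle between the two abundance vectors (in `[0, 1]` for
#' non-negative profiles). `euclidean_sim()` converts Euclidean distance `d`
#' between probability vectors to a similarity `1 - d / sqrt(2)`, since
#' `sqrt(2)` is the largest distance two probability vectors can attain.
#'
#' @param a,b named numeric profiles (or one-row OTU tibbles); for
#'   `euclidean_sim()` each must sum to 1.
#' @return a similarity in `[0, 1]`.
#' @export
cosine_sim <- function(a, b) {
  a <- as_profile(a, "a"); b <- as_profile(b, "b")
  v <- align_pair(a, b)
  na <- sqrt(sum(v$a^2)); nb <- sqrt(sum(v$b^2))
  if (na == 0 || nb == 0) rlang::abort("cosine similarity is undefined for a zero profile")
  min(max(sum(v$a * v$b) / (na * nb), 0), 1)
}

#' @rdname cosine_sim
#' @export
euclidean_sim <- function(a, b) {
  a <- as_profile(a, "a"); b <- as_profile(b, "b")
  check_normalized(a, "a"); check_normalized(b, "b")
  v <- align_pair(a, b)
  d <- sqrt(sum((v$a - v$b)^2))
  min(max(1 - d / sqrt(2), 0), 1)
}

# Put two named profiles on the union of their OTU ids.
align_pair <- function(a, b) {
  ids <- union(names(a), names(b))
  aa <- setNames(numeric(length(ids)), ids); aa[names(a)] <- a
  bb <- setNames(numeric(length(ids)), ids); bb[names(b)] <- b
  list(a = aa, b = bb)
}

metric_names <- c("phylogenetic", "cosine", "euclidean")

# Batch similarity of queries (rows of Q) against references (rows of R),
# both samples x OTUs matrices sharing the metric's requirements.
similarity_batch <- function(Q, R, metric, enc = NULL) {
  metric <- match.arg(metric, metric_names)
  if (metric == "phylogenetic") {
    if (is.null(enc)) rlang::abort("phylogenetic similarity requires a tree")
    qm <- profiles_to_tips(Q, enc)
    rm_ <- profiles_to_tips(R, enc)
    out <- ms_similarity_batch(qm, rm_, enc$parent, enc$child, enc$elen,
                               enc$ntip, enc$nnode)
  } else if (metric == "cosine") {
    ids <- union(colnames(Q), colnames(R))
    qa <- expand_cols(Q, ids); ra <- expand_cols(R, ids)
    nq <- sqrt(rowSums(qa^2)); nr <- sqrt(rowSums(ra^2))
    if (any(nq == 0) || any(nr == 0))
      rlang::abort("cosine similarity is undefined for a zero profile")
    out <- (qa %*% t(ra)) / outer(nq, nr)
  } else {
    ids <- union(colnames(Q), colnames(R))
    qa <- expand_cols(Q, ids); ra <- expand_cols(R, ids)
    d2 <- outer(rowSums(qa^2), rowSums(ra^2), "+") - 2 * qa %*% t(ra)
    out <- 1 - sqrt(pmax(d2, 0)) / sqrt(2)
  }
  out <- pmin(pmax(out, 0), 1)
  dimnames(out) <- list(rownames(Q), rownames(R))
  out
}

expand_cols <- function(m, ids) {
  out <- matrix(0, nrow(m), length(ids), dimnames = list(rownames(m), ids))
  out[, colnames(m)] <- m
  out
}

#' Pairwise similarity matrix over all samples of an OTU table
#'
#' @param tbl an OTU table tibble; rows are renormalised to relative
#'   abundances first.
#' @param metric `"phylogenetic"` (default), `"cosine"` or `"euclidean"`.
#' @param tree a rooted `phylo`, required for the phylogenetic metric.
#' @return a symmetric numeric matrix with unit diagonal, sample ids as
#'   dimnames.
#' @export
pairwise_matrix <- function(tbl, metric = c("phylogenetic", "cosine", "euclidean"),
                            tree = NULL) {
  metric <- match.arg(metric)
  m <- otu_matrix(normalize_profiles(tbl))
  if (metric == "phylogenetic") {
    if (is.null(tree)) rlang::abort("phylogenetic similarity requires a tree")
    enc <- tree_encoding(tree)
    p <- profiles_to_tips(m, enc)
    out <- ms_similarity_pairwise(p, enc$parent, enc$child, enc$elen,
                                  enc$ntip, enc$nnode)
    dimnames(out) <- list(rownames(m), rownames(m))
  } else {
    out <- similarity_batch(m, m, metric)
    diag(out) <- 1
  }
  out
}

#' Write a pairwise similarity matrix as square TSV
#'
#' @param mat a square matrix as returned by [pairwise_matrix()].
#' @param path output file; sample ids form the header row and first column.
#' @export
write_similarity_matrix <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  names(df)[1] <- "#SampleID"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
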