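#' OTU tables as wide tibbles
#'
#' Throughout the package an OTU table is an ordinary wide tibble: a
#' `sample_id` character column followed by one non-negative numeric column
#' per OTU. Counts and relative abundances share the same shape; functions
#' that need relative abundances renormalise internally via
#' [normalize_profiles()].
#'
#' @param x for `as_otu_tibble()`, a numeric matrix with samples in rows
#'   (row names = sample ids) and OTUs in columns.
#' @param tbl an OTU table tibble (`sample_id` + numeric OTU columns).
#' @return `as_otu_tibble()` returns a tibble; `otu_matrix()` the numeric
#'   matrix with sample ids as row names.
#' @examples
#' m <- matrix(c(5, 10, 5, 0), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU_1", "OTU_2")))
#' tbl <- as_otu_tibble(m)
#' otu_matrix(tbl)
#' @export
as_otu_tibble <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (is.null(rownames(x)) && nrow(x) > 0)
    rownames(x) <- paste0("s", seq_len(nrow(x)))
  ids <- if (nrow(x) == 0) character(0) else rownames(x)
  out <- tibble::as_tibble(x, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(sample_id = ids), out)
}

#' @rdname as_otu_tibble
#' @export
otu_matrix <- function(tbl) {
  validate_otu_tbl(tbl)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$sample_id
  storage.mode(m) <- "double"
  m
}

validate_otu_tbl <- function(tbl, call = rlang::caller_env()) {
  if (!is.data.frame(tbl) || ncol(tbl) < 2L || names(tbl)[1] != "sample_id")
    rlang::abort("expected an OTU table: a `sample_id` column followed by numeric OTU columns",
                 call = call)
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(vals))
    rlang::abort("OTU columns must be numeric", call = call)
  if (anyNA(vals))
    rlang::abort("OTU table contains missing values", call = call)
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    rlang::abort(sprintf("negative abundance for sample '%s', OTU '%s'",
                         tbl$sample_id[neg[1, 1]], colnames(vals)[neg[1, 2]]),
                 call = call)
  dup <- tbl$sample_id[duplicated(tbl$sample_id)]
  if (length(dup) > 0)
    rlang::abort(sprintf("duplicate sample id '%s'", dup[1]), call = call)
  invisible(tbl)
}

#' Copy-number correction and row normalisation of OTU profiles
#'
#' Divides each OTU's counts by its 16S rRNA gene copy number (so profiles
#' reflect organism rather than gene abundance) and renormalises every sample
#' to sum to one. OTUs absent from the copy-number table default to one copy.
#' With `copy_numbers = NULL` this is plain total-sum scaling to relative
#' abundances.
#'
#' @param tbl an OTU table tibble (counts or abundances).
#' @param copy_numbers optional tibble with columns `otu_id` and `copies`
#'   (positive), as returned by [read_copy_numbers()].
#' @return a tibble of the same shape whose rows each sum to 1.
#' @examples
#' tbl <- as_otu_tibble(matrix(c(4, 4), 1, 2,
#'   dimnames = list("s1", c("OTU_1", "OTU_2"))))
#' cn <- tibble::tibble(otu_id = c("OTU_1", "OTU_2"), copies = c(1, 2))
#' normalize_profiles(tbl, cn) # 2/3, 1/3
#' @export
normalize_profiles <- function(tbl, copy_numbers = NULL) {
  m <- otu_matrix(tbl)
  if (!is.null(copy_numbers)) {
    if (!all(c("otu_id", "copies") %in% names(copy_numbers)))
      rlang::abort("`copy_numbers` needs columns `otu_id` and `copies`")
    if (any(copy_numbers$copies <= 0))
      rlang::abort("copy numbers must be positive")
    cn <- copy_numbers$copies[match(colnames(m), copy_numbers$otu_id)]
    cn[is.na(cn)] <- 1
    m <- sweep(m, 2, cn, "/")
  }
  tot <- rowSums(m)
  zero <- tbl$sample_id[tot <= 0]
  if (length(zero) > 0)
    rlang::abort(sprintf("sample '%s' has zero total abundance", zero[1]))
  as_otu_tibble(m / tot)
}

#' Restrict an OTU table to the tips of a phylogenetic tree
#'
#' OTUs without a matching tree leaf are dropped and each sample is
#' renormalised over the remaining OTUs. The fraction of abundance each sample
#' lost is reported (message + `"dropped_fraction"` attribute) so callers can
#' reject low-coverage samples; a sample losing all of its abundance is an
#' error.
#'
#' @param tbl an OTU table tibble.
#' @param tree a rooted `phylo` tree whose tip labels are OTU ids.
#' @return the aligned, renormalised OTU table with attribute
#'   `dropped_fraction` (named numeric, one entry per sample).
#' @export
align_to_tree <- function(tbl, tree) {
  stopifnot(inherits(tree, "phylo"))
  m <- otu_matrix(normalize_profiles(tbl))
  keep <- colnames(m) %in% tree$tip.label
  kept <- m[, keep, drop = FALSE]
  tot <- rowSums(kept)
  dropped <- 1 - tot
  names(dropped) <- rownames(m)
  lost <- rownames(m)[tot <= 0]
  if (length(lost) > 0)
    rlang::abort(sprintf("sample '%s' has no abundance on tree tips", lost[1]))
  if (any(dropped > 1e-12))
    message(sprintf("align_to_tree: dropped off-tree abundance in %d/%d samples (max fraction %.3f)",
                    sum(dropped > 1e-12), nrow(m), max(dropped)))
  out <- as_otu_tibble(kept / tot)
  attr(out, "dropped_fraction") <- pmax(dropped, 0)
  out
}
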