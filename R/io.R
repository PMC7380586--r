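#' Read and write OTU tables
#'
#' The TSV dialect has samples in rows and OTUs in columns: a tab-separated
#' header whose first cell is `#SampleID` followed by OTU ids, then one row
#' per sample. BIOM support targets the JSON (v1.0) flavour via the
#' \pkg{biomformat} package; BIOM stores observations (OTUs) in rows, which is
#' transposed on the way in and out.
#'
#' @param path file to read or write.
#' @param format `"tsv"` or `"biom"`.
#' @param tbl an OTU table tibble to write.
#' @return `read_otu_table()` returns a counts tibble (`sample_id` + numeric
#'   OTU columns); `write_otu_table()` returns `path` invisibly.
#' @export
read_otu_table <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (format == "biom") {
    rlang::check_installed("biomformat")
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))
    tbl <- as_otu_tibble(m)
  } else {
    header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    if (length(header) < 2L || !header[1] %in% c("#SampleID", "sample_id"))
      rlang::abort(sprintf("malformed OTU table header in %s: first cell must be '#SampleID'", path))
    if (anyDuplicated(header[-1]))
      rlang::abort(sprintf("duplicate OTU id '%s' in header", header[-1][duplicated(header[-1])][1]))
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      comment.char = "", stringsAsFactors = FALSE)
    names(raw)[1] <- "sample_id"
    raw$sample_id <- as.character(raw$sample_id)
    tbl <- tibble::as_tibble(raw)
  }
  validate_otu_tbl(tbl)
  tot <- rowSums(tbl[, -1, drop = FALSE])
  if (any(tot <= 0))
    rlang::abort(sprintf("sample '%s' has zero total count", tbl$sample_id[tot <= 0][1]))
  tbl
}

#' @rdname read_otu_table
#' @export
write_otu_table <- function(tbl, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  validate_otu_tbl(tbl)
  if (format == "biom") {
    rlang::check_installed("biomformat")
    b <- biomformat::make_biom(t(otu_matrix(tbl)))
    biomformat::write_biom(b, path)
  } else {
    out <- as.data.frame(tbl)
    names(out)[1] <- "#SampleID"
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a rooted Newick tree with branch lengths sanitised for similarity use
#'
#' The similarity recursion attenuates residual abundance by `(1 - branch
#' length)`, which is only meaningful for lengths in `[0, 1]`. On load,
#' missing branch lengths default to 0 (lossless propagation, message) and
#' lengths outside `[0, 1]` are clamped into it (warning).
#'
#' @param path path to a single-tree Newick file.
#' @param tree a `phylo` object to write.
#' @return a `phylo` object with all edge lengths in `[0, 1]` and unique tip
#'   labels.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) rlang::abort(sprintf("Newick parse error in %s: %s",
                                                            path, conditionMessage(e))))
  if (is.null(tree)) rlang::abort(sprintf("Newick parse error in %s", path))
  if (inherits(tree, "multiPhylo"))
    rlang::abort(sprintf("%s contains more than one tree", path))
  if (anyDuplicated(tree$tip.label))
    rlang::abort(sprintf("duplicate leaf label '%s'",
                         tree$tip.label[duplicated(tree$tip.label)][1]))
  if (is.null(tree$edge.length)) {
    message("read_newick: no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    message(sprintf("read_newick: %d missing branch lengths defaulted to 0",
                    sum(is.na(tree$edge.length))))
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  out_of_range <- tree$edge.length < 0 | tree$edge.length > 1
  if (any(out_of_range)) {
    warning(sprintf("read_newick: %d branch lengths outside [0, 1] clamped",
                    sum(out_of_range)), call. = FALSE)
    tree$edge.length <- pmin(pmax(tree$edge.length, 0), 1)
  }
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write per-sample metadata
#'
#' Metadata is a TSV with columns `sample_id`, `host_id`, `status` (cohort
#' label, e.g. a disease or `control`), `region` and `platform`.
#'
#' @param path file to read or write.
#' @param metadata a metadata tibble to write.
#' @return a tibble with the five metadata columns, `sample_id` unique.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  md <- tibble::as_tibble(read.delim(path, sep = "\t", check.names = FALSE,
                                     stringsAsFactors = FALSE,
                                     colClasses = "character"))
  need <- c("sample_id", "host_id", "status", "region", "platform")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0)
    rlang::abort(sprintf("metadata is missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(md$sample_id))
    rlang::abort(sprintf("duplicate sample id '%s' in metadata",
                         md$sample_id[duplicated(md$sample_id)][1]))
  md[need]
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a 16S copy-number table
#'
#' Two tab-separated columns, `otu_id` and `copies`; copy numbers must be
#' strictly positive. OTUs not listed default to one copy when the table is
#' applied by [normalize_profiles()].
#'
#' @param path file to read.
#' @return a tibble with columns `otu_id` (character) and `copies` (numeric).
#' @export
read_copy_numbers <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  cn <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(cn) < 2)
    rlang::abort("copy-number table needs two columns: otu_id, copies")
  names(cn)[1:2] <- c("otu_id", "copies")
  cn$copies <- as.numeric(cn$copies)
  if (anyNA(cn$copies) || any(cn$copies <= 0))
    rlang::abort("copy numbers must be positive numbers")
  tibble::as_tibble(cn[, 1:2])
}
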