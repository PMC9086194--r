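#' Read an AIRR rearrangement table into a clonotype table
#'
#' Reads a tab-delimited AIRR rearrangement export, normalizes V and J
#' calls to gene level (allele suffixes such as `*01` stripped; for
#' ambiguous comma-separated calls the first listed gene is taken), and
#' collapses duplicate gene-level clonotypes by summing their counts.
#' Files without a count column are treated as one read per row.
#'
#' @param path Path to a TSV file with a header.
#' @param sample_id Sample label; defaults to the file name without
#'   extension.
#' @param dialect Named list mapping the roles `v_call`, `j_call`,
#'   `count` to column names, for legacy exports; `count = NA` forces
#'   one-read-per-row mode.
#' @return A `clonotype_table`: `sample_id`, and `records` (data frame
#'   with `v_call`, `j_call`, `count`), one row per unique gene-level
#'   clonotype.
#' @export
read_airr_rearrangements <- function(path, sample_id = NULL,
                                     dialect = list(v_call = "v_call",
                                                    j_call = "j_call",
                                                    count = "duplicate_count")) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L)
    stop("empty rearrangement file: ", path, call. = FALSE)
  for (role in c("v_call", "j_call")) {
    colname <- dialect[[role]]
    if (is.null(colname) || !colname %in% names(df))
      stop(sprintf("missing mandatory column '%s' (role %s) in %s",
                   colname %||% "<unset>", role, path), call. = FALSE)
  }
  cnt_col <- dialect[["count"]]
  cnt <- if (!is.null(cnt_col) && !is.na(cnt_col) && cnt_col %in% names(df))
    as.integer(df[[cnt_col]]) else rep(1L, nrow(df))
  cnt[is.na(cnt)] <- 1L
  if (any(cnt < 1L))
    stop("counts must be positive integers in ", path, call. = FALSE)
  v <- normalize_gene_call(df[[dialect$v_call]])
  j <- normalize_gene_call(df[[dialect$j_call]])
  clonotype_table(sample_id,
                  data.frame(v_call = v, j_call = j, count = cnt,
                             stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## strip allele suffix ("*01") and resolve ambiguous comma-separated
## calls to the first listed gene
normalize_gene_call <- function(x) {
  x <- trimws(sub(",.*$", "", x))
  sub("\\*.*$", "", x)
}

#' Construct a clonotype table
#'
#' Collapses duplicate (v_call, j_call) records by summing counts so
#' that one row corresponds to one unique gene-level clonotype.
#'
#' @param sample_id Sample label.
#' @param records Data frame with columns `v_call`, `j_call`, `count`.
#' @return A `clonotype_table` object.
#' @export
clonotype_table <- function(sample_id, records) {
  stopifnot(is.data.frame(records),
            all(c("v_call", "j_call", "count") %in% names(records)))
  if (nrow(records) == 0L)
    stop("clonotype table must contain at least one record", call. = FALSE)
  if (any(records$count < 1))
    stop("all clonal counts must be >= 1", call. = FALSE)
  agg <- stats::aggregate(count ~ v_call + j_call, data = records, FUN = sum)
  agg <- agg[order(agg$v_call, agg$j_call), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(sample_id = sample_id, records = agg),
            class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("<clonotype_table> '%s': %d unique clonotype(s), %d read(s)\n",
              x$sample_id, nrow(x$records), sum(x$records$count)))
  invisible(x)
}

vj_labels <- function(tab) paste(tab$records$v_call, tab$records$j_call,
                                 sep = "/")

#' Compute the VJ-gene-usage matrix
#'
#' For each sample, the usage of a VJ combination is the number of
#' unique clonotypes using that V/J gene pair divided by the sample's
#' total number of unique clonotypes.  The feature set is the union of
#' combinations observed across all samples; combinations unobserved in
#' a sample get 0, so each row sums to 1.
#'
#' @param tables List of `clonotype_table` objects.
#' @return A `usage_matrix`: numeric matrix (samples x VJ combinations,
#'   labels like `"TRBV19/TRBJ2-1"`) with attribute `mode = "usage"`.
#' @export
compute_vj_usage <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "clonotype_table")))
  feats <- sort(unique(unlist(lapply(tables, vj_labels))))
  M <- matrix(0, length(tables), length(feats),
              dimnames = list(vapply(tables, `[[`, character(1), "sample_id"),
                              feats))
  for (i in seq_along(tables)) {
    lab <- vj_labels(tables[[i]])
    if (!length(lab))
      stop("sample '", tables[[i]]$sample_id,
           "' has no resolvable VJ pairs", call. = FALSE)
    tt <- table(lab)
    M[i, names(tt)] <- as.numeric(tt) / nrow(tables[[i]]$records)
  }
  usage_matrix(M, mode = "usage")
}

#' Construct a usage matrix
#'
#' Wraps a numeric samples x features matrix with the mode flag used by
#' the VJ-usage pipeline (`"usage"` fractions or signed `"log2_ratio"`
#' values).
#'
#' @param M Numeric matrix with sample row names and VJ-combination
#'   column names.
#' @param mode Value mode.
#' @return A `usage_matrix`.
#' @export
usage_matrix <- function(M, mode = c("usage", "log2_ratio")) {
  mode <- match.arg(mode)
  structure(M, mode = mode, class = c("usage_matrix", class(M)))
}

#' Log2 usage ratio between paired timepoints
#'
#' Entrywise `log2((post + pc) / (baseline + pc))` after aligning the
#' two matrices on the union of their VJ features (missing features are
#' 0).  The default pseudocount for each sample is the reciprocal of a
#' nominal clone number (`1 / pseudocount_clones`); a gene unused at
#' both timepoints yields exactly 0.
#'
#' @param post,baseline `usage_matrix` objects in usage mode with the
#'   same samples in the same order.
#' @param pseudocount Either a single positive number used for all
#'   samples, or a numeric vector with one value per sample (e.g.
#'   `1 / unique-clonotype-count`).
#' @return A `usage_matrix` with attribute `mode = "log2_ratio"`.
#' @export
log2_usage_ratio <- function(post, baseline, pseudocount = 1e-4) {
  stopifnot(inherits(post, "usage_matrix"), inherits(baseline, "usage_matrix"))
  if (nrow(post) != nrow(baseline) ||
      !identical(rownames(post), rownames(baseline)))
    stop("post and baseline matrices must cover the same samples in the ",
         "same order", call. = FALSE)
  feats <- sort(union(colnames(post), colnames(baseline)))
  A <- align_features(post, feats)
  B <- align_features(baseline, feats)
  if (length(pseudocount) == 1L)
    pseudocount <- rep(pseudocount, nrow(A))
  stopifnot(length(pseudocount) == nrow(A), all(pseudocount > 0))
  out <- log2((A + pseudocount) / (B + pseudocount))
  ## 0/0 usage gives log2(pc/pc) = 0 exactly
  dimnames(out) <- list(rownames(post), feats)
  usage_matrix(out, mode = "log2_ratio")
}

align_features <- function(M, feats) {
  out <- matrix(0, nrow(M), length(feats),
                dimnames = list(rownames(M), feats))
  out[, colnames(M)] <- unclass(M)[, , drop = FALSE]
  out
}

#' Summarize repertoires in median [range] layout
#'
#' Per group of samples, reports the median and range of the number of
#' unique clonotypes, the total clonal counts, and the usage values of
#' the supplied usage matrix.
#'
#' @param tables List of `clonotype_table` objects.
#' @param groups Optional factor/character vector assigning each table
#'   to a group (default: one group).
#' @return Data frame with one row per group and statistic, columns
#'   `group`, `statistic`, `median`, `min`, `max`, `formatted`.
#' @export
summarize_repertoire <- function(tables, groups = NULL) {
  stopifnot(length(tables) >= 1L)
  if (is.null(groups)) groups <- rep("all", length(tables))
  stopifnot(length(groups) == length(tables))
  usage <- compute_vj_usage(tables)
  rows <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    uniq <- vapply(tables[idx], function(t) nrow(t$records), numeric(1))
    reads <- vapply(tables[idx], function(t) sum(t$records$count), numeric(1))
    us <- as.numeric(unclass(usage)[idx, , drop = FALSE])
    for (stat in list(list("unique_clonotypes", uniq),
                      list("clonal_counts", reads),
                      list("vj_usage", us))) {
      v <- stat[[2]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, statistic = stat[[1]],
        median = stats::median(v), min = min(v), max = max(v),
        formatted = sprintf("%s [%s, %s]", format(stats::median(v)),
                            format(min(v)), format(max(v))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a usage matrix to CSV
#'
#' Samples as rows, VJ-combination labels as column headers.
#'
#' @param M A `usage_matrix`.
#' @param path Output file path.
#' @export
write_usage_csv <- function(M, path) {
  utils::write.csv(as.data.frame(unclass(M)), path, row.names = TRUE)
  invisible(path)
}
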