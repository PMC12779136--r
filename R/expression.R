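#' Construct an expression matrix object
#'
#' Holds FPKM-like non-negative expression values (genes x samples)
#' together with a binary phenotype label and a provenance flag
#' (real vs. synthetic) per sample.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All values must be >= 0.
#' @param labels Named character vector (or factor) of per-sample labels,
#'   e.g. `"healthy"` / `"cancer"`; names must cover all samples.
#' @param origin Named character vector, `"real"` or `"synthetic"` per
#'   sample; defaults to `"real"` for all.
#' @return An object of class `expr_matrix`: list with `values` (matrix)
#'   and `samples` (tibble: sample_id, label, origin).
#' @export
expr_matrix <- function(values, labels, origin = NULL) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene id: ",
         rownames(values)[duplicated(rownames(values))][1], call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample id: ",
         colnames(values)[duplicated(colnames(values))][1], call. = FALSE)
  }
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop(sprintf("negative expression value at gene '%s', sample '%s'",
                 rownames(values)[neg[1, 1]], colnames(values)[neg[1, 2]]),
         call. = FALSE)
  }
  sids <- colnames(values)
  labels <- as.character(labels)[match(sids, names(labels))] |>
    stats::setNames(sids)
  if (anyNA(labels)) {
    stop("missing label for sample(s): ",
         paste(sids[is.na(labels)], collapse = ", "), call. = FALSE)
  }
  if (is.null(origin)) {
    origin <- stats::setNames(rep("real", length(sids)), sids)
  } else {
    origin <- as.character(origin)[match(sids, names(origin))] |>
      stats::setNames(sids)
    if (anyNA(origin)) {
      stop("missing origin for sample(s): ",
           paste(sids[is.na(origin)], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      values = values,
      samples = tibble::tibble(
        sample_id = sids,
        label = unname(labels),
        origin = unname(origin)
      )
    ),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  print(table(label = x$samples$label, origin = x$samples$origin))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Expression values in long tidy form
#'
#' @param x An `expr_matrix`.
#' @param ... Unused.
#' @return Tibble with columns gene_id, sample_id, value, label, origin.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "gene_id") |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' Read an expression matrix and its sample labels
#'
#' Expects a TSV/CSV with gene ids in the first column and sample ids in
#' the header, plus a two-column labels table (`sample_id`, `label`),
#' optionally with an `origin` column.
#'
#' @param path Expression table path (delimiter inferred: `.csv` = comma,
#'   otherwise tab).
#' @param labels_path Path to the labels table, or a named vector of
#'   labels.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path, labels_path) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  sids <- header[-1]
  if (anyDuplicated(sids)) {
    stop("duplicate sample id in header: ", sids[duplicated(sids)][1],
         call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1]])
  colnames(vals) <- sids
  if (is.character(labels_path) && length(labels_path) == 1L &&
      file.exists(labels_path)) {
    lsep <- if (grepl("\\.csv$", labels_path, ignore.case = TRUE)) {
      ","
    } else {
      "\t"
    }
    ldf <- utils::read.table(labels_path, sep = lsep, header = TRUE,
                             stringsAsFactors = FALSE)
    labels <- stats::setNames(as.character(ldf$label),
                              as.character(ldf$sample_id))
    origin <- if ("origin" %in% names(ldf)) {
      stats::setNames(as.character(ldf$origin), as.character(ldf$sample_id))
    } else {
      NULL
    }
  } else {
    labels <- labels_path
    origin <- NULL
  }
  expr_matrix(vals, labels, origin)
}

#' Write an expression matrix and labels to TSV
#'
#' @param m An `expr_matrix`.
#' @param path Output TSV for the value matrix.
#' @param labels_path Output TSV for sample_id/label/origin; omitted if
#'   `NULL`.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, labels_path = NULL) {
  df <- data.frame(gene_id = rownames(m$values), m$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(labels_path)) {
    utils::write.table(m$samples, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Drop genes with zero counts in every sample
#'
#' Standard preprocessing for FPKM-style matrices: genes whose value is
#' exactly 0 across all samples carry no information and are removed.
#' Gene order of survivors and the sample set are preserved; the
#' operation is idempotent.
#'
#' @param m An `expr_matrix`.
#' @return A filtered `expr_matrix`.
#' @export
filter_zero_genes <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  keep <- rowSums(m$values != 0) > 0
  if (!any(keep)) {
    message("filter_zero_genes: no gene has a nonzero value; ",
            "result is empty")
  }
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out
}

#' Subset an expression matrix by samples
#'
#' @param m An `expr_matrix`.
#' @param sample_ids Character vector of samples to keep.
#' @return An `expr_matrix` with the selected samples, in the given order.
#' @export
subset_samples <- function(m, sample_ids) {
  stopifnot(inherits(m, "expr_matrix"))
  missing <- setdiff(sample_ids, colnames(m$values))
  if (length(missing) > 0) {
    stop("unknown sample id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  labels <- stats::setNames(m$samples$label, m$samples$sample_id)
  origin <- stats::setNames(m$samples$origin, m$samples$sample_id)
  expr_matrix(m$values[, sample_ids, drop = FALSE],
              labels[sample_ids], origin[sample_ids])
}

#' Combine expression matrices column-wise
#'
#' @param ... `expr_matrix` objects sharing the same gene set and order.
#' @return A combined `expr_matrix`.
#' @export
bind_expr <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 1L, all(vapply(ms, inherits, logical(1),
                                         "expr_matrix")))
  g <- rownames(ms[[1]]$values)
  for (m in ms[-1]) {
    if (!identical(rownames(m$values), g)) {
      stop("gene sets/order differ between matrices", call. = FALSE)
    }
  }
  vals <- do.call(cbind, lapply(ms, function(m) m$values))
  samp <- do.call(rbind, lapply(ms, function(m) m$samples))
  expr_matrix(vals,
              stats::setNames(samp$label, samp$sample_id),
              stats::setNames(samp$origin, samp$sample_id))
}
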