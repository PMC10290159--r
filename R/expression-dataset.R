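#' Gene-by-timepoint expression dataset
#'
#' Container for circadian gene-expression time series on the CPM scale:
#' a gene x timepoint value matrix, the sampling times in hours, and a
#' cell-line label. Per-gene maxima (the normalizers of the fitting cost)
#' are cached on construction.
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids,
#'   uppercase HGNC-style), timepoints in columns.
#' @param times numeric vector of sampling times in hours, strictly
#'   increasing, one per column of `values`.
#' @param cell_line character label, e.g. `"HCT116_WT"`.
#' @return object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, times, cell_line = "unknown") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique gene rownames")
  }
  if (length(times) != ncol(values)) {
    stop("length(times) must equal ncol(values)")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (length(times) < 2) stop("need at least 2 timepoints per gene")
  if (anyNA(values)) stop("missing values are not allowed in expression data")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(rownames(values), NULL)
  structure(
    list(
      genes = rownames(values),
      times = as.numeric(times),
      values = values,
      cell_line = cell_line,
      gene_max = apply(values, 1, max)
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d genes x %d timepoints (%.1f-%.1f h), cell line %s\n",
    length(x$genes), length(x$times), min(x$times), max(x$times), x$cell_line
  ))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

#' Collapse paralog families into lumped model variables
#'
#' The dynamical model carries one variable per paralog family (PER for
#' PER1/PER2/PER3, CRY for CRY1/CRY2, NR1D for NR1D1/NR1D2), fitted to the
#' element-wise sum of the family members' expression. Genes not named in
#' the mapping pass through unchanged.
#'
#' @param dataset an [expression_dataset()].
#' @param mapping named list: lumped variable name -> character vector of
#'   paralog gene ids, e.g. `list(PER = c("PER1","PER2","PER3"))`.
#' @param knocked_out character vector of paralogs absent because they are
#'   knocked out; these may be missing from the dataset and contribute zero.
#' @return a new `expression_dataset` with one row per lumped variable.
#' @export
lump_paralogs <- function(dataset, mapping = default_paralog_mapping(),
                          knocked_out = character(0)) {
  stopifnot(inherits(dataset, "expression_dataset"))
  all_members <- unlist(mapping, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- all_members[duplicated(all_members)][1]
    stop(sprintf("paralog '%s' appears in more than one lump", dup))
  }
  nt <- length(dataset$times)
  out <- list()
  for (lump in names(mapping)) {
    members <- mapping[[lump]]
    present <- members %in% dataset$genes
    missing <- members[!present]
    bad <- setdiff(missing, knocked_out)
    if (length(bad) > 0) {
      stop(sprintf(
        "paralog '%s' of lump '%s' absent from dataset and not flagged knocked out",
        bad[1], lump
      ))
    }
    if (any(present)) {
      rows <- dataset$values[members[present], , drop = FALSE]
      out[[lump]] <- colSums(rows)
    } else {
      out[[lump]] <- rep(0, nt)
    }
  }
  passthrough <- setdiff(dataset$genes, all_members)
  for (g in passthrough) out[[g]] <- dataset$values[g, ]
  mat <- do.call(rbind, out)
  rownames(mat) <- names(out)
  expression_dataset(mat, dataset$times, dataset$cell_line)
}

#' Default paralog-family mapping of the core clock
#'
#' PER lumps PER1-3, CRY lumps CRY1-2, NR1D lumps NR1D1-2; ARNTL paralogs
#' are not lumped because they show no compensation (ARNTL2 is co-reduced
#' in ARNTL knock-outs rather than upregulated).
#'
#' @return named list usable as the `mapping` of [lump_paralogs()].
#' @export
default_paralog_mapping <- function() {
  list(
    PER = c("PER1", "PER2", "PER3"),
    CRY = c("CRY1", "CRY2"),
    NR1D = c("NR1D1", "NR1D2")
  )
}
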