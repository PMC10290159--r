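#' Read an expression dataset from TSV/CSV
#'
#' Expects a header row whose first column holds gene identifiers and
#' whose remaining column names parse as sampling times in hours.
#'
#' @param path file path.
#' @param format `"tsv"` or `"csv"` (default guessed from the extension).
#' @param cell_line label for the dataset.
#' @return an [expression_dataset()].
#' @examples
#' path <- system.file("extdata", "synthetic_expression.tsv",
#'                     package = "chronotox")
#' read_expression(path, cell_line = "synthetic_WT")
#' @export
read_expression <- function(path, format = NULL, cell_line = "unknown") {
  format <- format %||%
    (if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv")
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("need a gene column plus >= 2 timepoint columns")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene id '%s'", genes[duplicated(genes)][1]))
  }
  times <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(times)) stop("timepoint column names must be numeric hours")
  if (any(diff(times) <= 0)) stop("timepoint columns must be sorted ascending")
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric expression value encountered")
  if (anyNA(mat)) stop("missing values are not allowed")
  rownames(mat) <- genes
  expression_dataset(mat, times, cell_line)
}

#' Write an expression dataset to TSV/CSV
#'
#' @param dataset an [expression_dataset()].
#' @param path output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(dataset, path, format = "tsv") {
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene = dataset$genes, dataset$values,
                   check.names = FALSE)
  names(df) <- c("gene", as.character(dataset$times))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rescale a dataset to the means of a reference dataset
#'
#' Harmonizes platforms (e.g. microarray vs RNA-seq) by mean-matching. In
#' `per_gene` mode each gene series is scaled so its mean equals the
#' reference gene's mean; `global` mode applies one common factor
#' matching the overall means.
#'
#' @param dataset,reference [expression_dataset()]s sharing gene ids.
#' @param mode `"per_gene"` (default) or `"global"`.
#' @return rescaled `expression_dataset`.
#' @export
rescale_to_reference <- function(dataset, reference,
                                 mode = c("per_gene", "global")) {
  mode <- match.arg(mode)
  shared <- intersect(dataset$genes, reference$genes)
  if (length(shared) == 0) stop("no shared gene ids with the reference")
  vals <- dataset$values
  if (mode == "per_gene") {
    for (g in shared) {
      m <- mean(vals[g, ])
      if (m == 0) stop(sprintf("gene '%s' has zero mean; cannot rescale", g))
      vals[g, ] <- vals[g, ] * (mean(reference$values[g, ]) / m)
    }
  } else {
    m <- mean(vals[shared, ])
    if (m == 0) stop("zero global mean; cannot rescale")
    vals[shared, ] <- vals[shared, ] * (mean(reference$values[shared, ]) / m)
  }
  expression_dataset(vals, dataset$times, dataset$cell_line)
}

#' Read a run configuration (YAML or JSON)
#'
#' Validates the basic schema of a run configuration: a `seed`, and
#' optional `cell_line` (with `ugt_scale` in (0, 1] and
#' `amplitude_exempt` genes), `solver`, `fit`, and `zeitgeber` blocks.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg$cell_line <- cfg$cell_line %||% list()
  cfg$cell_line$ugt_scale <- cfg$cell_line$ugt_scale %||% 1
  if (cfg$cell_line$ugt_scale <= 0 || cfg$cell_line$ugt_scale > 1) {
    stop("cell_line$ugt_scale must be in (0, 1]")
  }
  cfg$cell_line$amplitude_exempt <-
    as.character(cfg$cell_line$amplitude_exempt %||% character(0))
  cfg$solver <- cfg$solver %||% list(rtol = 1e-4, atol = 1e-12)
  cfg
}

#' Write a toxicity profile to CSV plus a JSON summary
#'
#' @param profile a `toxicity_profile`.
#' @param csv_path CSV output (treatment_time_h, normalized_AUC).
#' @param json_path optional JSON summary path (peak time/value,
#'   provenance).
#' @param seed seed recorded in the provenance block.
#' @return `csv_path`, invisibly.
#' @export
write_toxicity_profile <- function(profile, csv_path, json_path = NULL,
                                   seed = NA_integer_) {
  df <- data.frame(
    treatment_time_h = profile$profile$treatment_time,
    normalized_AUC = profile$profile$auc_ratio
  )
  utils::write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(peak_time_h = profile$peak_time,
           peak_value = profile$peak_value,
           provenance = provenance_record(seed = seed)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(csv_path)
}
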