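#' Per-experiment BIR efficiency
#'
#' Efficiency of break-induced replication (BIR) in the chromosome
#' fragmentation assay: the number of transformants obtained with the
#' linearized fragmentation vector divided by the number obtained with the
#' circular control vector in the same experiment.
#'
#' Values above 1 are possible in noisy replicates (the control plate can
#' happen to yield fewer colonies); they are retained with a warning, never
#' clamped.
#'
#' @param linear_count integer vector, transformants with the linearized
#'   vector (>= 0).
#' @param control_count integer vector, transformants with the circular
#'   control vector (> 0).
#' @return numeric vector of efficiency ratios.
#' @examples
#' bir_efficiency(50, 100)
#' bir_efficiency(c(0, 71), c(100, 100))
#' @export
bir_efficiency <- function(linear_count, control_count) {
  if (any(linear_count < 0, na.rm = TRUE) || any(control_count < 0, na.rm = TRUE))
    stop("transformant counts must be non-negative")
  bad <- which(!is.na(control_count) & control_count == 0)
  if (length(bad))
    stop("undefined efficiency ratio: control_count is 0 in experiment(s) ",
         paste(bad, collapse = ", "))
  eff <- linear_count / control_count
  if (any(eff > 1, na.rm = TRUE))
    warning("efficiency exceeds 1 in ", sum(eff > 1, na.rm = TRUE),
            " experiment(s); retained unclamped")
  eff
}

# canonical column set of the interchange table
.eff_cols <- c("locus", "distance_kb", "linear_count", "control_count",
               "efficiency", "condition")

#' Assemble and validate an efficiency dataset
#'
#' An efficiency dataset is a plain data frame with one row per
#' transformation experiment and columns `locus`, `distance_kb`,
#' `linear_count`, `control_count`, `efficiency` and `condition`. Counts may
#' be absent (NA) when only precomputed efficiencies are available; when
#' counts are present the efficiency is (re)computed from them.
#'
#' @param df data frame with at least `locus`, `distance_kb` and either both
#'   count columns or an `efficiency` column.
#' @return validated data frame with the canonical columns, ordered by
#'   increasing distance. Attribute `counts_absent` is TRUE when any row
#'   carries an efficiency without counts.
#' @export
as_efficiency_dataset <- function(df) {
  df <- as.data.frame(df)
  need <- c("locus", "distance_kb")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  if (!("efficiency" %in% names(df)) &&
      !all(c("linear_count", "control_count") %in% names(df)))
    stop("need either count columns (linear_count, control_count) or efficiency")
  for (col in setdiff(.eff_cols, names(df))) df[[col]] <- NA
  if (!is.numeric(df$distance_kb) || anyNA(suppressWarnings(as.numeric(df$distance_kb))))
    stop("non-numeric distance_kb")
  if (any(df$distance_kb < 0)) stop("distance_kb must be >= 0")
  have_counts <- !is.na(df$linear_count) & !is.na(df$control_count)
  if (any(have_counts)) {
    zero <- which(have_counts & df$control_count == 0)
    if (length(zero))
      stop("control_count is 0 in row(s) ", paste(zero, collapse = ", "),
           " (locus ", paste(df$locus[zero], collapse = ", "), ")")
    df$efficiency[have_counts] <-
      bir_efficiency(df$linear_count[have_counts], df$control_count[have_counts])
  }
  if (anyNA(df$efficiency))
    stop("rows without counts must provide efficiency")
  df <- df[order(df$distance_kb), .eff_cols, drop = FALSE]
  rownames(df) <- NULL
  attr(df, "counts_absent") <- any(!have_counts)
  df
}

#' Read an efficiency table from CSV or XLSX
#'
#' Reads one row per transformation experiment. CSV is the canonical
#' interchange format (header
#' `locus,distance_kb,linear_count,control_count,efficiency,condition`,
#' UTF-8, "." decimal separator). XLSX workbooks in the one-sheet-per-figure
#' layout of typical numerical supplements are supported when the readxl
#' package is installed; select the sheet by name.
#'
#' @param path file path ending in `.csv` or `.xlsx`.
#' @param sheet sheet name or index for XLSX input.
#' @return validated efficiency dataset (see [as_efficiency_dataset()]).
#' @export
read_efficiency <- function(path, sheet = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package; export the sheet to CSV")
    df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (any(c(df$linear_count, df$control_count) < 0, na.rm = TRUE))
    stop("negative counts in ", path)
  as_efficiency_dataset(df)
}

#' Write an efficiency dataset to CSV
#'
#' Inverse of [read_efficiency()]: a write followed by a read reproduces all
#' fields.
#'
#' @param data efficiency dataset.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_efficiency <- function(data, path) {
  utils::write.csv(data[, .eff_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-locus summary of replicate efficiencies
#'
#' Mean and sample standard deviation (n - 1 denominator) of the
#' per-experiment efficiency ratios at each locus, as plotted with error
#' bars in replicate assays. The mean is the mean of per-experiment ratios,
#' not the ratio of pooled counts: each transformation experiment is an
#' independent estimate of the efficiency and experiments differ in
#' competence, so pooling counts would weight experiments by plate yield.
#' The pooled-count alternative is [pooled_efficiency()].
#'
#' @param data efficiency dataset.
#' @return data frame with columns `locus`, `distance_kb`, `n`,
#'   `mean_efficiency`, `sd_efficiency` (NA when n = 1), ordered by distance.
#' @export
summarize_by_locus <- function(data) {
  if (nrow(data) == 0L) stop("empty dataset")
  sp <- split(seq_len(nrow(data)), data$locus)
  out <- do.call(rbind, lapply(sp, function(i) {
    e <- data$efficiency[i]
    data.frame(locus = data$locus[i[1L]],
               distance_kb = data$distance_kb[i[1L]],
               n = length(e),
               mean_efficiency = mean(e),
               sd_efficiency = if (length(e) > 1L) stats::sd(e) else NA_real_)
  }))
  out <- out[order(out$distance_kb), ]
  rownames(out) <- NULL
  out
}

#' Pooled-count efficiency per locus
#'
#' Sum of linear counts over sum of control counts per locus. This weights
#' experiments by plate yield and is offered only as an explicitly named
#' alternative to the per-experiment ratio average of [summarize_by_locus()].
#'
#' @param data efficiency dataset with counts present.
#' @return data frame with columns `locus`, `distance_kb`,
#'   `pooled_efficiency`.
#' @export
pooled_efficiency <- function(data) {
  if (anyNA(data$linear_count) || anyNA(data$control_count))
    stop("pooled efficiency needs counts in every row")
  sp <- split(seq_len(nrow(data)), data$locus)
  out <- do.call(rbind, lapply(sp, function(i) {
    data.frame(locus = data$locus[i[1L]],
               distance_kb = data$distance_kb[i[1L]],
               pooled_efficiency =
                 sum(data$linear_count[i]) / sum(data$control_count[i]))
  }))
  out <- out[order(out$distance_kb), ]
  rownames(out) <- NULL
  out
}
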