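#' Construct an LFQ abundance table
#'
#' An abundance table is a [SummarizedExperiment::SummarizedExperiment] with
#' two assays: `log10_lfq` (log10 LFQ intensity; `NA` in a raw table marks a
#' not-quantified cell) and `detected` (logical; `TRUE` = quantified, `FALSE`
#' = missing/imputed), plus per-sample metadata in `colData` and the display
#' floor (the log10 abundance at which undetected proteins are plotted) in
#' `metadata`.
#'
#' @param log10_lfq Numeric matrix, proteins x samples, log10 scale. `NA`
#'   allowed only where `detected` is `FALSE` and imputation has not run.
#' @param detected Logical matrix of the same dimensions.
#' @param sample_meta `data.frame` with one row per sample and columns
#'   `sample_id`, `fraction` (one of [FRACTIONS]), `condition` (one of
#'   [CONDITIONS]) and optionally `gradient_index` (integer 1-24, required
#'   exactly when `fraction == "sucrose_gradient"`).
#' @param display_floor Log10 abundance representing "not detected" in
#'   displays and as the imputation floor. Default 4.
#' @param imputed Logical; has [impute_missing()] been applied?
#' @return A `SummarizedExperiment` of class contract "AbundanceTable".
#' @export
abundance_table <- function(log10_lfq, detected, sample_meta,
                            display_floor = 4, imputed = FALSE) {
  if (!is.matrix(log10_lfq) || !is.matrix(detected))
    om_stop("log10_lfq and detected must be matrices")
  if (!all(dim(log10_lfq) == dim(detected)))
    om_stop("log10_lfq and detected dimensions differ")
  if (is.null(rownames(log10_lfq)))
    om_stop("log10_lfq must carry protein ids as rownames")
  if (anyDuplicated(rownames(log10_lfq)))
    om_stop("duplicate protein ids in abundance table")
  sample_meta <- validate_sample_meta(sample_meta)
  if (nrow(sample_meta) != ncol(log10_lfq))
    om_stop("sample_meta rows (%d) do not match matrix columns (%d)",
            nrow(sample_meta), ncol(log10_lfq))
  colnames(log10_lfq) <- colnames(detected) <- sample_meta$sample_id
  rownames(detected) <- rownames(log10_lfq)
  if (any(is.na(log10_lfq) & detected))
    om_stop("NA log10 value in a cell flagged detected")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log10_lfq = log10_lfq, detected = detected),
    colData = S4Vectors::DataFrame(sample_meta, row.names = sample_meta$sample_id),
    metadata = list(display_floor = display_floor, imputed = imputed))
  validate_abundance_table(se)
  se
}

validate_sample_meta <- function(sample_meta) {
  sample_meta <- as.data.frame(sample_meta)
  req <- c("sample_id", "fraction", "condition")
  miss <- setdiff(req, names(sample_meta))
  if (length(miss))
    om_stop("sample metadata missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(sample_meta$sample_id))
    om_stop("duplicate sample ids in metadata")
  sample_meta$fraction <- match_enum(sample_meta$fraction, FRACTIONS, "fraction")
  sample_meta$condition <- match_enum(sample_meta$condition, CONDITIONS, "condition")
  if (!"gradient_index" %in% names(sample_meta))
    sample_meta$gradient_index <- NA_integer_
  gi <- sample_meta$gradient_index
  is_grad <- sample_meta$fraction == "sucrose_gradient"
  if (any(is_grad & is.na(gi)))
    om_stop("sucrose_gradient samples must carry gradient_index")
  if (any(!is_grad & !is.na(gi)))
    om_stop("gradient_index only allowed on sucrose_gradient samples")
  if (any(!is.na(gi) & (gi < 1 | gi > 24)))
    om_stop("gradient_index must lie in 1..24")
  sample_meta$gradient_index <- as.integer(gi)
  sample_meta
}

validate_abundance_table <- function(x) {
  stopifnot(methods::is(x, "SummarizedExperiment"))
  a <- SummarizedExperiment::assayNames(x)
  if (!all(c("log10_lfq", "detected") %in% a))
    om_stop("abundance table must carry assays 'log10_lfq' and 'detected'")
  if (isTRUE(S4Vectors::metadata(x)$imputed)) {
    v <- SummarizedExperiment::assay(x, "log10_lfq")
    d <- SummarizedExperiment::assay(x, "detected")
    if (anyNA(v)) om_stop("imputed table contains NA values")
    for (j in seq_len(ncol(v))) {
      if (any(d[, j]) && any(!d[, j]) &&
          max(v[!d[, j], j]) >= min(v[d[, j], j]))
        om_stop("imputed values must lie strictly below the sample minimum")
    }
  }
  invisible(x)
}

#' @rdname abundance_table
#' @param x An abundance table.
#' @export
lfq_values <- function(x) SummarizedExperiment::assay(x, "log10_lfq")

#' @rdname abundance_table
#' @export
detected_mask <- function(x) SummarizedExperiment::assay(x, "detected")

#' @rdname abundance_table
#' @export
sample_meta <- function(x) as.data.frame(SummarizedExperiment::colData(x))

#' @rdname abundance_table
#' @export
display_floor <- function(x) S4Vectors::metadata(x)$display_floor

#' @rdname abundance_table
#' @export
is_imputed <- function(x) isTRUE(S4Vectors::metadata(x)$imputed)

# internal: resolve one sample id to a column index or fail loudly
sample_index <- function(x, sample) {
  j <- match(sample, colnames(x))
  if (anyNA(j))
    om_stop("unknown sample id(s): %s",
            paste(sample[is.na(j)], collapse = ", "))
  j
}
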