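#' Percentage helper used by all report summaries
#'
#' `100 * n / total`, rounded to the requested number of decimals; 0 when
#' `total` is 0.
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimals kept (default 1).
#' @return Numeric percentage.
#' @export
percent_of <- function(n, total, digits = 1) {
  if (total == 0) return(0)
  round(100 * n / total, digits)
}

#' Paired OM-vs-intracellular abundance table
#'
#' One row per protein with its log10 abundance in the OM and intracellular
#' samples, its compartment label and whether it exceeds the preliminary
#' LFQ threshold in the OM sample. Undetected proteins are shown at the
#' display floor (4.0), the value representing "not detected" in the
#' comparative proteome plots.
#'
#' @param table Abundance table.
#' @param calls Localization calls (`protein_id`, `label`); proteins
#'   without a call keep label `"unknown"`.
#' @param sample_om,sample_ic Sample ids of the OM and intracellular
#'   fractions.
#' @param lfq_threshold Threshold for the `above_threshold` flag
#'   (default 8.5).
#' @return `data.frame` with columns `protein_id`, `log10_om`, `log10_ic`,
#'   `compartment`, `above_threshold`.
#' @export
figure3_table <- function(table, calls, sample_om, sample_ic,
                          lfq_threshold = 8.5) {
  jo <- sample_index(table, sample_om)
  ji <- sample_index(table, sample_ic)
  v <- lfq_values(table)
  d <- detected_mask(table)
  fl <- display_floor(table)
  om <- ifelse(d[, jo], v[, jo], fl)
  ic <- ifelse(d[, ji], v[, ji], fl)
  lab <- calls$label[match(rownames(v), calls$protein_id)]
  lab[is.na(lab)] <- "unknown"
  data.frame(protein_id = rownames(v), log10_om = unname(om),
             log10_ic = unname(ic), compartment = lab,
             above_threshold = unname(d[, jo] & om > lfq_threshold),
             stringsAsFactors = FALSE)
}

#' Build a count audit trail
#'
#' The analysis narrative is count-based (identified proteins, preliminary
#' candidates, confirmed OM proteins, genome-only additions, responsive
#' proteins); the audit trail records those counts in execution order.
#'
#' @param ... Named non-negative integer counts, in stage order.
#' @param descriptions Optional character vector parallel to the counts.
#' @return `data.frame` of class `audit_trail` with columns `stage`,
#'   `count`, `description`.
#' @export
audit_trail <- function(..., descriptions = NULL) {
  counts <- c(...)
  if (length(counts) && is.null(names(counts)))
    om_stop("audit counts must be named")
  if (any(counts < 0)) om_stop("audit counts must be non-negative")
  if (is.null(descriptions)) descriptions <- rep("", length(counts))
  structure(data.frame(stage = names(counts) %||% character(),
                       count = as.integer(counts),
                       description = descriptions,
                       stringsAsFactors = FALSE),
            class = c("audit_trail", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / restore an audit trail
#' @param trail An [audit_trail()].
#' @param path JSON path.
#' @return `write_audit_trail`: invisibly `path`; `read_audit_trail`: the
#'   restored trail.
#' @export
write_audit_trail <- function(trail, path) {
  jsonlite::write_json(as.data.frame(trail), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_audit_trail
#' @export
read_audit_trail <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  audit_trail(setNames(df$count, df$stage), descriptions = df$description)
}

#' Write the pipeline report
#'
#' Emits a per-protein localization-call TSV, a fold-change/exclusivity
#' TSV, and a JSON summary with the stage counts (`n_om`, `n_preliminary`,
#' `n_genome_only`, `n_fold_responsive`), the OM share of the proteome as a
#' percentage (one decimal) and, when descriptions are supplied, the
#' percentage of genome-only OM calls that are uncharacterized proteins
#' (nearest integer).
#'
#' @param calls Localization calls for detected proteins.
#' @param diff Fold-change table from [fold_changes()] (may be `NULL`).
#' @param out_dir Output directory (created if needed).
#' @param n_proteome Total number of protein-coding sequences.
#' @param genome_calls Genome-screen calls (may be `NULL`).
#' @param descriptions Optional named character vector (protein id ->
#'   description) used to count uncharacterized proteins.
#' @return Invisibly, the summary list.
#' @export
write_report <- function(calls, diff, out_dir, n_proteome,
                         genome_calls = NULL, descriptions = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    om_stop("cannot create output directory %s", out_dir)
  utils::write.table(calls, file.path(out_dir, "localization_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(diff))
    utils::write.table(diff, file.path(out_dir, "fold_changes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  n_om_detected <- sum(calls$label == "om_confirmed")
  n_genome <- if (is.null(genome_calls)) 0L else nrow(genome_calls)
  n_om <- n_om_detected + n_genome
  summary <- list(
    n_proteome = n_proteome,
    n_preliminary = sum(calls$in_preliminary_list, na.rm = TRUE),
    n_om = n_om_detected,
    n_genome_only = n_genome,
    n_fold_responsive = if (is.null(diff)) 0L else sum(diff$responsive),
    om_percent_of_proteome = percent_of(n_om_detected, n_proteome, 1))
  if (!is.null(descriptions) && n_genome > 0) {
    unchar <- grepl("uncharacterized", descriptions[genome_calls$protein_id],
                    ignore.case = TRUE)
    summary$genome_only_uncharacterized_percent <-
      percent_of(sum(unchar), n_genome, 0)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  pipeline_log("report written to %s (OM %% of proteome: %.1f)",
               out_dir, summary$om_percent_of_proteome)
  invisible(summary)
}
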