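#' Read a protein FASTA
#'
#' Parses a protein FASTA via [Biostrings::readAAStringSet()] into a
#' data.frame of protein records. Sequences are uppercased; only the 20
#' canonical residues plus `X` are accepted; duplicate ids and empty
#' sequences are rejected.
#'
#' @param path Path to a FASTA file.
#' @return `data.frame` with columns `protein_id`, `sequence`, `description`
#'   (free text after the first whitespace of the header, `""` if none).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) om_stop("FASTA file not found: %s", path)
  if (file.size(path) == 0)
    return(data.frame(protein_id = character(), sequence = character(),
                      description = character(), stringsAsFactors = FALSE))
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  if (any(ids == ""))
    om_stop("malformed FASTA header (empty id) at record %d",
            which(ids == "")[1])
  if (anyDuplicated(ids))
    om_stop("duplicate protein id(s) in FASTA: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- nchar(seqs) == 0
  if (any(empty))
    om_stop("empty sequence for record %s", ids[which(empty)[1]])
  bad <- vapply(strsplit(seqs, ""),
                function(s) any(!s %in% AA_ALPHABET), logical(1))
  if (any(bad))
    om_stop("non-amino-acid characters in record %s", ids[which(bad)[1]])
  data.frame(protein_id = unname(ids), sequence = unname(seqs),
             description = unname(desc), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- ifelse(nchar(records$description) > 0,
                      paste(records$protein_id, records$description),
                      records$protein_id)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

PREDICTOR_COLUMNS <- c("protein_id", "has_signal_peptide", "lipoprotein_class",
                       "secretomep_score", "tm_helix_count", "bomp_category",
                       "cello_label", "psortb_label")

#' Read a predictor feature table
#'
#' One row per protein of external-predictor outputs: signal-peptide call,
#' lipoprotein class, non-classical secretion score, TM-helix count,
#' beta-barrel category and two independent localization labels. The file is
#' tab-delimited with a header naming all columns of `PREDICTOR_COLUMNS`.
#' Unrecognised compartment strings are mapped to `"unknown"` with a warning.
#'
#' @param path Path to a TSV file.
#' @return Validated `data.frame`, rows in file order.
#' @export
read_predictor_table <- function(path) {
  if (!file.exists(path)) om_stop("predictor table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  miss <- setdiff(PREDICTOR_COLUMNS, names(df))
  if (length(miss))
    om_stop("predictor table missing column(s): %s",
            paste(miss, collapse = ", "))
  validate_predictor_table(df[PREDICTOR_COLUMNS])
}

#' Validate an in-memory predictor table
#'
#' @param df data.frame with the columns of `PREDICTOR_COLUMNS`.
#' @return The validated, type-coerced data.frame.
#' @export
validate_predictor_table <- function(df) {
  df <- as.data.frame(df)
  if (anyDuplicated(df$protein_id))
    om_stop("duplicate protein ids in predictor table")
  df$has_signal_peptide <- parse_logical(df$has_signal_peptide,
                                         "has_signal_peptide")
  df$lipoprotein_class <- match_enum(df$lipoprotein_class,
                                     LIPOPROTEIN_CLASSES, "lipoprotein_class")
  df$secretomep_score <- as.numeric(df$secretomep_score)
  if (any(is.na(df$secretomep_score) | df$secretomep_score < 0 |
          df$secretomep_score > 1))
    om_stop("secretomep_score outside [0,1]")
  df$tm_helix_count <- as.integer(df$tm_helix_count)
  if (any(is.na(df$tm_helix_count) | df$tm_helix_count < 0))
    om_stop("tm_helix_count must be a non-negative integer")
  df$bomp_category <- as.integer(df$bomp_category)
  if (any(is.na(df$bomp_category) | df$bomp_category < 0 |
          df$bomp_category > 5))
    om_stop("bomp_category must lie in 0..5")
  df$cello_label <- match_enum(df$cello_label, COMPARTMENTS,
                               "cello_label", unknown_to = "unknown")
  df$psortb_label <- match_enum(df$psortb_label, COMPARTMENTS,
                                "psortb_label", unknown_to = "unknown")
  df
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  if (anyNA(out)) om_stop("cannot parse %s as logical", what)
  out
}

#' Write a predictor table to TSV
#' @param df Predictor table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_predictor_table <- function(df, path) {
  utils::write.table(df[PREDICTOR_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a raw LFQ intensity table
#'
#' Reads a tab-delimited protein x sample table of *linear-scale* LFQ
#' intensities into a raw (pre-imputation) abundance table. Blank or `0`
#' cells mark not-quantified proteins; they are stored as `NA` log10 values
#' with `detected = FALSE`. Every sample column must have a metadata row.
#'
#' @param path Path to the TSV; first column `protein_id`.
#' @param meta Sample metadata `data.frame` (see [abundance_table()]).
#' @param display_floor Display floor carried by the table (default 4).
#' @return A raw abundance table (`imputed = FALSE`).
#' @export
read_lfq_table <- function(path, meta, display_floor = 4) {
  if (!file.exists(path)) om_stop("LFQ table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  if (names(df)[1] != "protein_id")
    om_stop("first column of an LFQ table must be 'protein_id'")
  meta <- validate_sample_meta(meta)
  samples <- names(df)[-1]
  missing_meta <- setdiff(samples, meta$sample_id)
  if (length(missing_meta))
    om_stop("sample column(s) without metadata: %s",
            paste(missing_meta, collapse = ", "))
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]
  raw <- as.matrix(df[, -1, drop = FALSE])
  raw[raw == ""] <- "0"
  lin <- matrix(as.numeric(raw), nrow = nrow(raw),
                dimnames = list(df$protein_id, samples))
  if (anyNA(lin)) om_stop("non-numeric intensity cell in %s", path)
  if (any(lin < 0)) om_stop("negative intensity in %s", path)
  detected <- lin > 0
  log10_lfq <- ifelse(detected, log10(lin), NA_real_)
  abundance_table(log10_lfq, detected, meta, display_floor = display_floor,
                  imputed = FALSE)
}

#' Write an LFQ table to TSV
#'
#' Linear-scale intensities with full precision; undetected cells are
#' written as empty strings, so the detection mask round-trips and detected
#' values round-trip to well beyond 6 decimals on the log10 scale.
#'
#' @param table An abundance table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_lfq_table <- function(table, path) {
  v <- lfq_values(table)
  d <- detected_mask(table)
  out <- matrix("", nrow = nrow(v), ncol = ncol(v),
                dimnames = dimnames(v))
  out[d] <- sprintf("%.10e", 10^v[d])
  df <- data.frame(protein_id = rownames(v), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default analysis configuration
#'
#' All tunable thresholds of the pipeline in one list: the preliminary-list
#' LFQ threshold (log10 8.5), the display/imputation floor (4.0), the
#' imputation offset, the fold-change threshold (10), the SecretomeP cutoff
#' and the PEP-CTERM scanner parameters.
#'
#' @return Named list of parameter groups.
#' @export
default_config <- function() {
  list(
    impute = list(offset = 0.5, floor = 4.0),
    classifier = unclass(classifier_config()),
    diff = list(fold_threshold = 10),
    pepcterm = unclass(pepcterm_config())
  )
}

#' Read a YAML analysis configuration
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @return Configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  for (grp in intersect(names(user), names(cfg)))
    cfg[[grp]][names(user[[grp]])] <- user[[grp]]
  cfg
}
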