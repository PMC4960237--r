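#' Condition fold changes between two samples
#'
#' Linear-scale fold change `10^(log10_a - log10_b)` per protein, with
#' condition-exclusivity taken from the detection mask (independent of the
#' numeric ratio): a protein detected in exactly one of the two samples is
#' `only_a` / `only_b`. For exclusive proteins the ratio is against the
#' imputed floor of the absent condition, which is why the flag is reported
#' separately.
#'
#' @param table Imputed abundance table.
#' @param sample_a,sample_b Sample ids (e.g. the mucin- and glucose-grown
#'   OM fractions).
#' @param ids Protein ids to compare; default all table proteins.
#' @param threshold Responsiveness threshold on the linear fold change
#'   (strictly greater than `threshold` or less than `1/threshold`);
#'   default 10.
#' @return `data.frame` with columns `protein_id`, `log10_a`, `log10_b`,
#'   `fold_change`, `responsive`, `exclusivity`.
#' @export
fold_changes <- function(table, sample_a, sample_b, ids = NULL,
                         threshold = 10) {
  if (!is_imputed(table))
    om_stop("impute_missing() must run before fold_changes()")
  if (threshold <= 1) om_stop("fold-change threshold must exceed 1")
  ja <- sample_index(table, sample_a)
  jb <- sample_index(table, sample_b)
  v <- lfq_values(table)
  d <- detected_mask(table)
  if (is.null(ids)) ids <- rownames(v)
  miss <- setdiff(ids, rownames(v))
  if (length(miss))
    om_stop("unknown protein id(s): %s", paste(miss, collapse = ", "))
  a <- v[ids, ja]
  b <- v[ids, jb]
  da <- d[ids, ja]
  db <- d[ids, jb]
  fc <- 10^(a - b)
  excl <- ifelse(da & !db, "only_a", ifelse(!da & db, "only_b", "none"))
  data.frame(protein_id = ids, log10_a = unname(a), log10_b = unname(b),
             fold_change = unname(fc),
             responsive = unname(fc > threshold | fc < 1 / threshold),
             exclusivity = unname(excl), stringsAsFactors = FALSE)
}

#' Condition-responsive protein set
#'
#' Proteins whose fold change exceeds the threshold in either direction
#' (strictly `> threshold` or `< 1/threshold`); symmetric in the two
#' samples.
#'
#' @param records Output of [fold_changes()].
#' @param threshold Linear fold-change threshold, must exceed 1 (default 10).
#' @return List with `ids` (character vector) and `count`.
#' @export
responsive_set <- function(records, threshold = 10) {
  if (threshold <= 1) om_stop("fold-change threshold must exceed 1")
  keep <- records$fold_change > threshold |
    records$fold_change < 1 / threshold
  ids <- records$protein_id[keep]
  pipeline_log("responsive proteins (>%g-fold either direction): %d of %d",
               threshold, length(ids), nrow(records))
  list(ids = ids, count = length(ids))
}
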