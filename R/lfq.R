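#' Impute missing LFQ values below the per-sample detection minimum
#'
#' Every not-quantified cell of a sample is substituted with a value lower
#' than the least abundant quantified protein of that sample:
#' `max(min_detected - offset, floor)` on the log10 scale. Detected cells and
#' the detection mask are untouched.
#'
#' @param raw Raw abundance table (each sample must have at least one
#'   detected value).
#' @param offset Positive log10 offset below the sample minimum (default 0.5).
#' @param floor Lower bound for imputed values; defaults to the table's
#'   display floor (4.0). Must stay strictly below every sample minimum.
#' @return The imputed abundance table (`imputed = TRUE`).
#' @export
impute_missing <- function(raw, offset = 0.5, floor = display_floor(raw)) {
  if (offset <= 0) om_stop("offset must be positive")
  v <- lfq_values(raw)
  d <- detected_mask(raw)
  if (!any(!d)) {
    se <- raw
    S4Vectors::metadata(se)$imputed <- TRUE
    return(se)
  }
  n_missing <- 0L
  for (j in seq_len(ncol(v))) {
    if (!any(d[, j]))
      om_stop("sample %s has no detected values; imputation minimum undefined",
              colnames(v)[j])
    m <- min(v[d[, j], j])
    imp <- max(m - offset, floor)
    if (imp >= m)
      om_stop("floor %.3g is not below the minimum detected value %.3g of sample %s",
              floor, m, colnames(v)[j])
    miss <- !d[, j]
    v[miss, j] <- imp
    n_missing <- n_missing + sum(miss)
  }
  pipeline_log("imputed %d missing cells across %d samples (offset %.2f, floor %.2f)",
               n_missing, ncol(v), offset, floor)
  abundance_table(v, d, sample_meta(raw), display_floor = display_floor(raw),
                  imputed = TRUE)
}

#' Per-protein relative abundance within a sample
#'
#' LFQ intensity is used as a proxy for absolute abundance; shares are
#' computed on the linear scale (`10^log10`) and sum to 1. With
#' `detected_only = TRUE` (default) undetected proteins get share 0 and are
#' excluded from the denominator, so imputed floors cannot dominate sparse
#' samples.
#'
#' @param table Abundance table (imputed, unless `detected_only = TRUE`).
#' @param sample A single sample id.
#' @param detected_only Restrict numerator and denominator to detected cells.
#' @return Named numeric vector of shares over all proteins of the table.
#' @export
relative_abundance <- function(table, sample, detected_only = TRUE) {
  j <- sample_index(table, sample)
  if (length(j) != 1) om_stop("exactly one sample id expected")
  v <- lfq_values(table)[, j]
  d <- detected_mask(table)[, j]
  if (!detected_only && (anyNA(v) || !is_imputed(table)))
    om_stop("impute_missing() must run before detected_only = FALSE shares")
  lin <- 10^v
  if (detected_only) lin[!d] <- 0
  tot <- sum(lin)
  if (tot == 0) om_stop("sample %s has no abundance mass", sample)
  lin / tot
}

#' Compartment composition of a sample
#'
#' Sums linear-scale relative abundances by predicted compartment, i.e. the
#' share of the sample's total intensity attributed to proteins of each
#' compartment. Proteins missing from `labels` count as `"unknown"`.
#'
#' @param table Abundance table.
#' @param labels Named character vector, protein id -> compartment.
#' @param sample A single sample id.
#' @param detected_only Passed to [relative_abundance()].
#' @return Object of class `compartment_distribution`: list with `sample_id`
#'   and `shares` (named numeric over the compartments present; sums to 1).
#' @export
compartment_distribution <- function(table, labels, sample,
                                     detected_only = TRUE) {
  shares <- relative_abundance(table, sample, detected_only = detected_only)
  lab <- labels[names(shares)]
  lab[is.na(lab)] <- "unknown"
  lab <- match_enum(lab, COMPARTMENTS, "compartment label",
                    unknown_to = "unknown")
  by_comp <- tapply(shares, factor(lab, levels = unique(lab)), sum)
  structure(list(sample_id = sample,
                 shares = setNames(as.numeric(by_comp), names(by_comp))),
            class = "compartment_distribution")
}

#' @export
print.compartment_distribution <- function(x, ...) {
  cat("Compartment composition of sample", x$sample_id, "\n")
  print(round(x$shares, 4))
  invisible(x)
}

#' Enrichment factor of a compartment between two fractions
#'
#' Ratio of a compartment's abundance *share* in a target sample over a
#' reference sample. Shares (composition) rather than raw sums are compared,
#' so differing total loads between fractions cancel.
#'
#' @param dist_target,dist_reference `compartment_distribution` objects.
#' @param compartment Compartment to compare; must be present in both.
#' @return List with `compartment`, `target_sample`, `reference_sample`,
#'   `factor`.
#' @export
enrichment_factor <- function(dist_target, dist_reference, compartment) {
  st <- dist_target$shares[compartment]
  sr <- dist_reference$shares[compartment]
  if (is.na(st) || is.na(sr))
    om_stop("compartment \"%s\" absent from a distribution", compartment)
  if (sr == 0)
    om_stop("undefined enrichment: reference share of \"%s\" is zero",
            compartment)
  list(compartment = compartment,
       target_sample = dist_target$sample_id,
       reference_sample = dist_reference$sample_id,
       factor = unname(st / sr))
}

#' OM-share profile along a sucrose density gradient
#'
#' Computes the outer-membrane abundance share of each gradient fraction,
#' ordered by `gradient_index` (not file order), plus a Spearman-type
#' monotonicity sign: +1 if shares increase with density rank, -1 if they
#' decrease, 0 for no rank trend.
#'
#' @param table Abundance table containing sucrose-gradient samples.
#' @param labels Named compartment labels as in [compartment_distribution()].
#' @param samples Sample ids to use; default all `sucrose_gradient` samples.
#' @param compartment Compartment profiled (default `"outer membrane"`).
#' @param detected_only Passed to [relative_abundance()].
#' @return List with `gradient_index`, `share` (both ordered by index), and
#'   `monotonicity` in {-1, 0, +1}.
#' @export
sucrose_gradient_profile <- function(table, labels, samples = NULL,
                                     compartment = "outer membrane",
                                     detected_only = TRUE) {
  sm <- sample_meta(table)
  if (is.null(samples))
    samples <- sm$sample_id[sm$fraction == "sucrose_gradient"]
  if (length(samples) == 0) om_stop("no sucrose_gradient samples")
  sm <- sm[match(samples, sm$sample_id), , drop = FALSE]
  if (any(sm$fraction != "sucrose_gradient"))
    om_stop("non-gradient sample(s) passed to sucrose_gradient_profile")
  if (anyDuplicated(sm$gradient_index))
    om_stop("duplicate gradient_index among gradient samples")
  ord <- order(sm$gradient_index)
  share <- vapply(sm$sample_id[ord], function(s) {
    d <- compartment_distribution(table, labels, s,
                                  detected_only = detected_only)
    v <- d$shares[compartment]
    if (is.na(v)) 0 else unname(v)
  }, numeric(1))
  idx <- sm$gradient_index[ord]
  rho <- if (length(idx) > 1 && stats::sd(share) > 0)
    stats::cor(idx, share, method = "spearman") else 0
  list(gradient_index = idx, share = unname(share),
       monotonicity = sign(round(rho, 12)))
}
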