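#' Classifier configuration
#'
#' Thresholds of the localization decision procedure: the log10 LFQ
#' abundance above which a detected protein enters the preliminary OM
#' candidate list (8.5), whether that comparison is strict, the SecretomeP
#' score above which non-classical secretion is called (0.5, the tool's
#' conventional Gram-negative cutoff), and the minimum beta-barrel category
#' counted as a barrel call.
#'
#' @param lfq_threshold Log10 LFQ threshold for the preliminary list.
#' @param secretomep_cutoff SecretomeP score cutoff in `[0, 1]`.
#' @param strict_threshold `TRUE` reads "above 8.5" as strictly greater.
#' @param bomp_min_category Minimum BOMP category (1-5) counted as a barrel.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(lfq_threshold = 8.5, secretomep_cutoff = 0.5,
                              strict_threshold = TRUE, bomp_min_category = 1L) {
  if (secretomep_cutoff < 0 || secretomep_cutoff > 1)
    om_stop("secretomep_cutoff must lie in [0,1]")
  if (bomp_min_category < 1 || bomp_min_category > 5)
    om_stop("bomp_min_category must lie in 1..5")
  structure(list(lfq_threshold = lfq_threshold,
                 secretomep_cutoff = secretomep_cutoff,
                 strict_threshold = isTRUE(strict_threshold),
                 bomp_min_category = as.integer(bomp_min_category)),
            class = "classifier_config")
}

as_classifier_config <- function(cfg) {
  if (inherits(cfg, "classifier_config")) return(cfg)
  do.call(classifier_config, cfg)
}

#' Preliminary OM candidate list
#'
#' The union of (a) proteins detected above the LFQ threshold in at least
#' one OM-fraction sample and (b) detected proteins predicted to be OM by
#' CELLO *or* PSORTb. Imputed cells never satisfy the threshold; "detected"
#' means quantified in at least one of `om_samples`.
#'
#' @param table Abundance table.
#' @param profiles Predictor table covering all table proteins.
#' @param om_samples Ids of the sarkosyl-OM-fraction samples (non-empty).
#' @param cfg A [classifier_config()] (or plain list of its fields).
#' @return Character vector of candidate protein ids, in table order.
#' @export
preliminary_candidates <- function(table, profiles, om_samples,
                                   cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  if (length(om_samples) == 0) om_stop("om_samples must be non-empty")
  if (cfg$lfq_threshold < display_floor(table))
    om_stop("lfq_threshold below the table's display floor")
  j <- sample_index(table, om_samples)
  v <- lfq_values(table)[, j, drop = FALSE]
  d <- detected_mask(table)[, j, drop = FALSE]
  ids <- rownames(v)
  miss <- setdiff(ids, profiles$protein_id)
  if (length(miss))
    om_stop("profiles missing for %d table protein(s), e.g. %s",
            length(miss), miss[1])
  above <- if (cfg$strict_threshold) v > cfg$lfq_threshold else
    v >= cfg$lfq_threshold
  abundant <- rowSums(d & above, na.rm = TRUE) > 0
  detected_any <- rowSums(d) > 0
  p <- profiles[match(ids, profiles$protein_id), ]
  predicted_om <- p$cello_label == "outer membrane" |
    p$psortb_label == "outer membrane"
  keep <- abundant | (detected_any & predicted_om)
  out <- ids[keep]
  pipeline_log("preliminary candidates: %d of %d proteins (%d above LFQ %.1f, %d predicted OM)",
               length(out), length(ids), sum(abundant),
               cfg$lfq_threshold, sum(detected_any & predicted_om))
  out
}

# internal: logical criterion matrix over a predictor table
om_criteria_matrix <- function(profiles, cfg = classifier_config()) {
  cfg <- as_classifier_config(cfg)
  m <- cbind(
    C1_dual_om     = profiles$cello_label == "outer membrane" &
                     profiles$psortb_label == "outer membrane",
    C2_lipoprotein = profiles$lipoprotein_class == "lipoprotein",
    C3_beta_barrel = profiles$bomp_category >= cfg$bomp_min_category,
    C4_nonclassical = !profiles$has_signal_peptide &
                      profiles$secretomep_score > cfg$secretomep_cutoff)
  rownames(m) <- profiles$protein_id
  m
}

#' OM criteria fired by one predictor profile
#'
#' The four independent confirmation criteria: (C1) both CELLO and PSORTb
#' predict OM; (C2) LipoP calls a lipoprotein; (C3) BOMP predicts a
#' beta-barrel; (C4) no signal peptide but SecretomeP predicts non-classical
#' secretion. Any subset may fire.
#'
#' @param profile One-row predictor table.
#' @param cfg A [classifier_config()].
#' @return Character vector, a subset of
#'   `c("C1_dual_om", "C2_lipoprotein", "C3_beta_barrel", "C4_nonclassical")`.
#' @export
om_criteria <- function(profile, cfg = classifier_config()) {
  if (nrow(profile) != 1) om_stop("om_criteria expects a single profile row")
  m <- om_criteria_matrix(profile, cfg)
  OM_CRITERIA[m[1, ]]
}

#' Assign a compartment from criteria and profile
#'
#' `om_confirmed` if any criterion fired; otherwise periplasmic when a
#' signal peptide is present (proteins exported but matching no OM
#' criterion); otherwise the protein keeps its CELLO compartment.
#'
#' @param profile One-row predictor table.
#' @param fired Criteria set as returned by [om_criteria()].
#' @return One-row `data.frame` localization call with columns `protein_id`,
#'   `label`, `criteria` (criteria joined by `;`), `in_preliminary_list`,
#'   `detected_in_proteomics`.
#' @export
assign_compartment <- function(profile, fired = om_criteria(profile)) {
  label <- if (length(fired) > 0) "om_confirmed"
  else if (profile$has_signal_peptide) "periplasmic"
  else profile$cello_label
  data.frame(protein_id = profile$protein_id, label = label,
             criteria = paste(fired, collapse = ";"),
             in_preliminary_list = NA, detected_in_proteomics = NA,
             stringsAsFactors = FALSE)
}

# internal: vectorized call construction
build_calls <- function(profiles, cfg, in_preliminary, detected) {
  if (nrow(profiles) == 0)
    return(data.frame(protein_id = character(), label = character(),
                      criteria = character(), in_preliminary_list = logical(),
                      detected_in_proteomics = logical(),
                      stringsAsFactors = FALSE))
  m <- om_criteria_matrix(profiles, cfg)
  fired_any <- rowSums(m) > 0
  criteria <- apply(m, 1, function(r) paste(OM_CRITERIA[r], collapse = ";"))
  label <- ifelse(fired_any, "om_confirmed",
                  ifelse(profiles$has_signal_peptide, "periplasmic",
                         profiles$cello_label))
  data.frame(protein_id = profiles$protein_id, label = label,
             criteria = unname(criteria),
             in_preliminary_list = in_preliminary,
             detected_in_proteomics = detected,
             stringsAsFactors = FALSE)
}

#' Classify the detected preliminary candidates
#'
#' Applies the four-criterion rule plus the periplasmic fallback to every
#' candidate protein.
#'
#' @param candidates Character vector of candidate ids (from
#'   [preliminary_candidates()]).
#' @param profiles Predictor table.
#' @param cfg A [classifier_config()].
#' @return `data.frame` of localization calls, one row per candidate.
#' @export
classify_detected <- function(candidates, profiles,
                              cfg = classifier_config()) {
  miss <- setdiff(candidates, profiles$protein_id)
  if (length(miss))
    om_stop("candidate(s) without predictor profile: %s",
            paste(miss, collapse = ", "))
  p <- profiles[match(candidates, profiles$protein_id), , drop = FALSE]
  calls <- build_calls(p, cfg, in_preliminary = TRUE, detected = TRUE)
  pipeline_log("classified %d candidates: %d om_confirmed, %d periplasmic, %d other",
               nrow(calls), sum(calls$label == "om_confirmed"),
               sum(calls$label == "periplasmic"),
               sum(!calls$label %in% c("om_confirmed", "periplasmic")))
  calls
}

#' Genome-wide screen for OM proteins missed by proteomics
#'
#' Applies the OM criteria to every protein *not* detected in the analysed
#' fractions and returns the confirmed OM calls, flagged
#' `detected_in_proteomics = FALSE`.
#'
#' @param profiles Predictor table for the whole proteome.
#' @param detected_ids Ids of proteins detected in the proteomics data.
#' @param cfg A [classifier_config()].
#' @return `data.frame` of `om_confirmed` calls among undetected proteins.
#' @export
genome_screen <- function(profiles, detected_ids,
                          cfg = classifier_config()) {
  p <- profiles[!profiles$protein_id %in% detected_ids, , drop = FALSE]
  calls <- build_calls(p, cfg, in_preliminary = FALSE, detected = FALSE)
  calls <- calls[calls$label == "om_confirmed", , drop = FALSE]
  rownames(calls) <- NULL
  pipeline_log("genome screen: %d of %d undetected proteins predicted OM",
               nrow(calls), nrow(p))
  calls
}
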