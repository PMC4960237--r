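# Amino-acid background for simulated sequences: approximate Swiss-Prot
# frequencies with strongly hydrophobic residues (KD > 1.6) down-weighted
# (x 0.3), so that spurious transmembrane stretches are rare and the
# PEP-CTERM scanner can be validated against planted signals alone.
HYDROPHILIC_AA_FREQS <- local({
  f <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
         G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
         P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  hydrophobic <- names(KYTE_DOOLITTLE)[KYTE_DOOLITTLE > 1.6]
  f[intersect(names(f), hydrophobic)] <-
    f[intersect(names(f), hydrophobic)] * 0.3
  f / sum(f)
})

# default (compartment x fraction) log10 LFQ means; rows COMPARTMENTS[1:5].
# Sarkosyl strongly enriches OM proteins (+1.3 over the whole-proteome
# baseline) and depletes cytoplasmic / inner-membrane proteins; the
# intracellular fraction is OM-depleted. Baseline 7.5 everywhere in the
# whole proteome.
default_lfq_means <- function() {
  m <- rbind(
    "cytoplasmic"    = c(whole_proteome = 7.5, intracellular = 7.7, om_sarkosyl = 6.5),
    "inner membrane" = c(whole_proteome = 7.5, intracellular = 7.2, om_sarkosyl = 7.0),
    "periplasmic"    = c(whole_proteome = 7.5, intracellular = 7.5, om_sarkosyl = 7.4),
    "outer membrane" = c(whole_proteome = 7.5, intracellular = 6.8, om_sarkosyl = 8.8),
    "extracellular"  = c(whole_proteome = 7.5, intracellular = 7.0, om_sarkosyl = 7.6))
  m
}

#' Simulation configuration
#'
#' Parameters of the synthetic fractionation-proteomics study: proteome
#' size, compartment proportions, per-field predictor error rate,
#' compartment-by-fraction log10 LFQ means, noise, detection limit,
#' condition effects (responsive and condition-exclusive proteins) and the
#' number of planted PEP-CTERM proteins.
#'
#' @param n_proteins Proteome size.
#' @param compartment_proportions Named probability vector over the five
#'   physical compartments; must sum to 1.
#' @param predictor_error_rate Per-field probability that a predictor value
#'   is replaced by a uniform draw over its domain.
#' @param lfq_means Compartment x fraction matrix of log10 means.
#' @param lfq_sd Log10 standard deviation of intensities.
#' @param detection_limit Log10 value below which intensities are censored
#'   (undetected).
#' @param n_responsive Number of OM proteins given a true condition effect.
#' @param responsive_effect Absolute log10 effect size (default
#'   `log10(20)`, i.e. a true 20-fold change).
#' @param n_exclusive_per_condition OM proteins forced undetected in the
#'   other condition.
#' @param n_undetected_om OM proteins censored in every sample (detectable
#'   only by the genome-wide screen).
#' @param n_pepcterm Proteins with a planted PEP-CTERM tail.
#' @param p_lipoprotein,p_barrel Probabilities that a true OM protein is a
#'   lipoprotein / carries a predicted beta-barrel.
#' @param n_gradient_fractions Number of sucrose-gradient fractions (0 =
#'   none) simulated for the mucin condition, with the OM mean ramping up
#'   along the gradient.
#' @param seq_length_range Range simulated protein lengths are drawn from.
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 2176,
                              compartment_proportions = c(
                                "cytoplasmic" = 0.55, "inner membrane" = 0.20,
                                "periplasmic" = 0.11, "outer membrane" = 0.04,
                                "extracellular" = 0.10),
                              predictor_error_rate = 0.05,
                              lfq_means = default_lfq_means(),
                              lfq_sd = 0.8,
                              detection_limit = 6.0,
                              n_responsive = 20,
                              responsive_effect = log10(20),
                              n_exclusive_per_condition = 4,
                              n_undetected_om = 17,
                              n_pepcterm = 23,
                              p_lipoprotein = 0.3,
                              p_barrel = 0.6,
                              n_gradient_fractions = 0,
                              seq_length_range = c(120, 600),
                              seed = 101) {
  if (abs(sum(compartment_proportions) - 1) > 1e-9)
    om_stop("compartment proportions must sum to 1")
  if (!all(names(compartment_proportions) %in% COMPARTMENTS))
    om_stop("unknown compartment in proportions")
  if (predictor_error_rate < 0 || predictor_error_rate >= 1)
    om_stop("predictor_error_rate must lie in [0,1)")
  if (n_responsive + 2 * n_exclusive_per_condition > n_proteins)
    om_stop("responsive + exclusive proteins exceed the proteome size")
  if (responsive_effect <= 0) om_stop("responsive_effect must be positive")
  if (lfq_sd <= 0) om_stop("lfq_sd must be positive")
  structure(list(n_proteins = as.integer(n_proteins),
                 compartment_proportions = compartment_proportions,
                 predictor_error_rate = predictor_error_rate,
                 lfq_means = lfq_means, lfq_sd = lfq_sd,
                 detection_limit = detection_limit,
                 n_responsive = as.integer(n_responsive),
                 responsive_effect = responsive_effect,
                 n_exclusive_per_condition = as.integer(n_exclusive_per_condition),
                 n_undetected_om = as.integer(n_undetected_om),
                 n_pepcterm = as.integer(n_pepcterm),
                 p_lipoprotein = p_lipoprotein, p_barrel = p_barrel,
                 n_gradient_fractions = as.integer(n_gradient_fractions),
                 seq_length_range = seq_length_range,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Named benchmark scenarios
#'
#' `paper_like`: a 2176-protein proteome with 4% OM proteins, two growth
#' conditions and realistic predictor noise. `noiseless`: error-free
#' predictors and tight intensities, so the classifier must recover ground
#' truth exactly. `sparse`: heavy censoring (every sample still retains at
#' least one detected value).
#'
#' @param name One of `"paper_like"`, `"noiseless"`, `"sparse"`.
#' @return A [simulation_config()] with a fixed seed.
#' @export
benchmark_scenario <- function(name = c("paper_like", "noiseless", "sparse")) {
  name <- match.arg(name)
  switch(name,
    paper_like = simulation_config(seed = 101),
    noiseless = simulation_config(predictor_error_rate = 0, lfq_sd = 0.25,
                                  seed = 202),
    sparse = simulation_config(detection_limit = 7.6, seed = 303))
}

# true (pre-noise) predictor profile implied by a compartment
true_profiles_for <- function(compartment, p_lipo, p_barrel) {
  n <- length(compartment)
  is_om <- compartment == "outer membrane"
  has_signal <- compartment %in% c("outer membrane", "periplasmic",
                                   "extracellular")
  lipo <- ifelse(has_signal, "other-cleaved", "none")
  lipo[is_om & runif(n) < p_lipo] <- "lipoprotein"
  bomp <- integer(n)
  barrel <- is_om & runif(n) < p_barrel
  bomp[barrel] <- sample(1:5, sum(barrel), replace = TRUE)
  tm <- integer(n)
  im <- compartment == "inner membrane"
  tm[im] <- sample(2:12, sum(im), replace = TRUE)
  secp <- ifelse(compartment == "extracellular", 0.7, 0.2)
  data.frame(protein_id = NA_character_, has_signal_peptide = has_signal,
             lipoprotein_class = lipo, secretomep_score = secp,
             tm_helix_count = tm, bomp_category = bomp,
             cello_label = compartment, psortb_label = compartment,
             stringsAsFactors = FALSE)
}

# corrupt each predictor field independently: with probability eps the value
# is replaced by a uniform draw over its domain (which may equal the truth)
corrupt_profiles <- function(truth, eps) {
  if (eps == 0) return(truth)
  n <- nrow(truth)
  redraw <- function() runif(n) < eps
  out <- truth
  r <- redraw(); out$has_signal_peptide[r] <-
    sample(c(TRUE, FALSE), sum(r), replace = TRUE)
  r <- redraw(); out$lipoprotein_class[r] <-
    sample(LIPOPROTEIN_CLASSES, sum(r), replace = TRUE)
  r <- redraw(); out$secretomep_score[r] <- runif(sum(r))
  r <- redraw(); out$tm_helix_count[r] <- sample(0:12, sum(r), replace = TRUE)
  r <- redraw(); out$bomp_category[r] <- sample(0:5, sum(r), replace = TRUE)
  r <- redraw(); out$cello_label[r] <- sample(COMPARTMENTS, sum(r), replace = TRUE)
  r <- redraw(); out$psortb_label[r] <- sample(COMPARTMENTS, sum(r), replace = TRUE)
  out
}

random_sequence <- function(len, freqs = HYDROPHILIC_AA_FREQS) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

# PEP motif + hydrophobic TM (18-22 aa) + basic cluster (3-5 K/R)
pepcterm_tail <- function() {
  tm <- paste(sample(c("L", "I", "V", "F"), sample(18:22, 1),
                     replace = TRUE), collapse = "")
  basic <- paste(sample(c("K", "R"), sample(3:5, 1), replace = TRUE),
                 collapse = "")
  paste0("PEP", tm, basic)
}

#' Generate a fully-labelled synthetic fractionation study
#'
#' Draws compartments from the configured proportions; sets true predictor
#' fields deterministically from the compartment (OM proteins get dual OM
#' localization labels and, with configured probability, a lipoprotein
#' class or beta-barrel) and corrupts each field independently at the
#' configured error rate; samples log10 LFQ intensities per
#' (protein, sample) from a normal with the compartment-by-fraction mean
#' (plus condition effect), censored below the detection limit; plants
#' responsive, condition-exclusive, fully-undetected and PEP-CTERM
#' proteins among the OM stratum; and emits random sequences with
#' PEP-CTERM tails for the flagged proteins. Fully reproducible from the
#' config seed.
#'
#' @param config A [simulation_config()].
#' @return List with `records` (sequences), `profiles` (noisy predictor
#'   table), `table` (raw abundance table over all simulated samples) and
#'   `truth` (list: per-protein `proteins` data.frame and the pre-noise
#'   `profiles`).
#' @export
generate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  ids <- sprintf("SYN_%04d", seq_len(n))
  comp <- sample(names(config$compartment_proportions), n, replace = TRUE,
                 prob = config$compartment_proportions)

  om_ids <- ids[comp == "outer membrane"]
  need <- config$n_responsive + 2 * config$n_exclusive_per_condition +
    config$n_undetected_om
  if (length(om_ids) < need)
    om_stop("OM stratum too small (%d) to host %d planted proteins",
            length(om_ids), need)
  planted <- sample(om_ids, need)
  responsive_ids <- planted[seq_len(config$n_responsive)]
  excl_mucin <- planted[config$n_responsive +
                          seq_len(config$n_exclusive_per_condition)]
  excl_glucose <- planted[config$n_responsive +
                            config$n_exclusive_per_condition +
                            seq_len(config$n_exclusive_per_condition)]
  undetected_ids <- planted[(need - config$n_undetected_om + 1):need]
  pepcterm_ids <- sample(ids, config$n_pepcterm)

  # signed condition effect (mucin minus glucose, log10)
  effect <- setNames(numeric(n), ids)
  effect[responsive_ids] <- config$responsive_effect *
    sample(c(-1, 1), config$n_responsive, replace = TRUE)

  # predictor table
  truth_prof <- true_profiles_for(comp, config$p_lipoprotein, config$p_barrel)
  truth_prof$protein_id <- ids
  profiles <- corrupt_profiles(truth_prof, config$predictor_error_rate)

  # samples: 3 fractions x 2 conditions (+ optional gradient, mucin only)
  meta <- expand.grid(fraction = c("whole_proteome", "intracellular",
                                   "om_sarkosyl"),
                      condition = CONDITIONS, stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$fraction, meta$condition, sep = "_")
  meta$gradient_index <- NA_integer_
  if (config$n_gradient_fractions > 0) {
    g <- data.frame(fraction = "sucrose_gradient", condition = "mucin",
                    sample_id = sprintf("gradient_%02d",
                                        seq_len(config$n_gradient_fractions)),
                    gradient_index = seq_len(config$n_gradient_fractions),
                    stringsAsFactors = FALSE)
    meta <- rbind(meta, g)
  }

  v <- matrix(NA_real_, nrow = n, ncol = nrow(meta),
              dimnames = list(ids, meta$sample_id))
  d <- matrix(FALSE, nrow = n, ncol = nrow(meta),
              dimnames = list(ids, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    if (meta$fraction[j] == "sucrose_gradient") {
      # intracellular-like background, OM share ramping up with density rank
      mu <- config$lfq_means[comp, "intracellular"]
      ramp <- -0.5 + 1.5 * (meta$gradient_index[j] - 1) /
        max(1, config$n_gradient_fractions - 1)
      mu[comp == "outer membrane"] <-
        config$lfq_means["outer membrane", "whole_proteome"] + ramp
    } else {
      mu <- config$lfq_means[comp, meta$fraction[j]]
    }
    if (meta$condition[j] == "mucin") mu <- mu + effect
    x <- rnorm(n, mu, config$lfq_sd)
    det <- x >= config$detection_limit
    # planted exclusives: censored in the other condition
    forced_off <- (ids %in% excl_mucin & meta$condition[j] == "glucose") |
      (ids %in% excl_glucose & meta$condition[j] == "mucin") |
      ids %in% undetected_ids
    det[forced_off] <- FALSE
    if (!any(det)) {
      # sparse-scenario guard: keep at least one quantified protein per
      # sample by redrawing the top non-planted cell above the limit
      top <- which.max(replace(x, forced_off, -Inf))
      x[top] <- config$detection_limit +
        abs(rnorm(1, 0, config$lfq_sd / 4)) + 1e-6
      det[top] <- TRUE
    }
    v[, j] <- ifelse(det, x, NA_real_)
    d[, j] <- det
  }
  table <- abundance_table(v, d, meta[, c("sample_id", "fraction",
                                          "condition", "gradient_index")],
                           display_floor = 4, imputed = FALSE)

  # sequences (hydrophilic background; planted C-terminal tails)
  lens <- sample(config$seq_length_range[1]:config$seq_length_range[2], n,
                 replace = TRUE)
  seqs <- vapply(lens, random_sequence, character(1))
  plant <- ids %in% pepcterm_ids
  seqs[plant] <- vapply(which(plant), function(i) {
    tail <- pepcterm_tail()
    paste0(substr(seqs[i], 1, max(60, lens[i] - nchar(tail))), tail)
  }, character(1))
  records <- data.frame(protein_id = ids, sequence = seqs,
                        description = ifelse(plant,
                                             "synthetic PEP-CTERM protein",
                                             "synthetic protein"),
                        stringsAsFactors = FALSE)

  truth <- list(
    proteins = data.frame(
      protein_id = ids, compartment = comp,
      condition_effect = unname(effect),
      responsive = ids %in% responsive_ids,
      exclusivity = ifelse(ids %in% excl_mucin, "mucin_only",
                           ifelse(ids %in% excl_glucose, "glucose_only",
                                  "none")),
      genome_only = ids %in% undetected_ids,
      pepcterm = plant, stringsAsFactors = FALSE),
    profiles = truth_prof)
  list(records = records, profiles = profiles, table = table, truth = truth,
       config = config)
}
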