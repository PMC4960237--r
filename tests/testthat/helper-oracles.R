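# Independent oracles and fixture builders. Everything here recomputes
# quantities from first principles (plain loops, closed forms), never by
# calling the package code paths it is used to check.

# build an abundance table from a linear-intensity matrix (0 = undetected)
toy_table <- function(lin, fractions = NULL, conditions = NULL, floor = 4) {
  if (is.null(dim(lin))) lin <- matrix(lin, ncol = 1)
  if (is.null(rownames(lin)))
    rownames(lin) <- sprintf("P%02d", seq_len(nrow(lin)))
  if (is.null(colnames(lin)))
    colnames(lin) <- sprintf("s%d", seq_len(ncol(lin)))
  if (is.null(fractions)) fractions <- rep("om_sarkosyl", ncol(lin))
  if (is.null(conditions)) conditions <- rep("mucin", ncol(lin))
  meta <- data.frame(sample_id = colnames(lin), fraction = fractions,
                     condition = conditions, stringsAsFactors = FALSE)
  detected <- lin > 0
  v <- ifelse(detected, log10(lin), NA_real_)
  abundance_table(v, detected, meta, display_floor = floor)
}

# random small raw table for property tests; guarantees >=1 detected/sample
random_toy_table <- function(n_prot = sample(2:6, 1),
                             n_samp = sample(1:3, 1)) {
  repeat {
    lin <- matrix(10^runif(n_prot * n_samp, 4.5, 10), n_prot, n_samp)
    lin[runif(n_prot * n_samp) < 0.25] <- 0
    if (all(colSums(lin > 0) > 0)) break
  }
  toy_table(lin)
}

# --- brute-force recomputations (loops over cells) -------------------------

brute_impute <- function(v, d, offset, floor) {
  out <- v
  for (j in seq_len(ncol(v))) {
    m <- Inf
    for (i in seq_len(nrow(v))) if (d[i, j] && v[i, j] < m) m <- v[i, j]
    for (i in seq_len(nrow(v))) if (!d[i, j]) out[i, j] <- max(m - offset, floor)
  }
  out
}

brute_shares <- function(v, d, j, detected_only = TRUE) {
  num <- numeric(nrow(v))
  for (i in seq_len(nrow(v)))
    num[i] <- if (!detected_only || d[i, j]) 10^v[i, j] else 0
  num / sum(num)
}

brute_compartment_shares <- function(shares, labels) {
  out <- list()
  for (i in seq_along(shares)) {
    l <- labels[i]
    out[[l]] <- (out[[l]] %||% 0) + shares[i]
  }
  unlist(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

brute_fold_change <- function(va, vb) 10^(va - vb)

# --- closed forms ----------------------------------------------------------

# E[10^X ; X > L] for X ~ N(mu, s^2): truncated log-normal partial mean
trunc_linear_mean <- function(mu, s, L) {
  cc <- log(10)
  10^mu * exp(cc^2 * s^2 / 2) * stats::pnorm((mu + cc * s^2 - L) / s)
}

# Monte-Carlo oracle for the OM enrichment factor (detected-only shares)
# between the sarkosyl and whole-proteome fractions of one condition.
# Models the study design directly: multinomial compartments, normal log10
# intensities, censoring below L, and n_om_removed OM proteins that are
# forced undetected in the measured condition.
mc_enrichment <- function(cfg, n_om_removed, reps = 200) {
  comps <- names(cfg$compartment_proportions)
  vapply(seq_len(reps), function(r) {
    counts <- as.vector(stats::rmultinom(1, cfg$n_proteins,
                                         cfg$compartment_proportions))
    names(counts) <- comps
    counts["outer membrane"] <- max(0, counts["outer membrane"] - n_om_removed)
    share_om <- function(fraction) {
      w <- vapply(comps, function(cp) {
        x <- stats::rnorm(counts[cp], cfg$lfq_means[cp, fraction], cfg$lfq_sd)
        sum(10^x[x >= cfg$detection_limit])
      }, numeric(1))
      w["outer membrane"] / sum(w)
    }
    share_om("om_sarkosyl") / share_om("whole_proteome")
  }, numeric(1))
}

# closed-form probability that a corrupted true-OM profile fires >= 1 OM
# criterion, by enumerating the per-field uniform-redraw corruption model
p_om_recovered <- function(true_lipo, true_bomp, eps, cutoff = 0.5,
                           true_signal = TRUE, true_secp = 0.2) {
  q <- (1 - eps) + eps / 6                       # label survives / redrawn right
  p1 <- q^2
  p2 <- if (true_lipo == "lipoprotein") (1 - eps) + eps / 3 else eps / 3
  p3 <- if (true_bomp >= 1) (1 - eps) + eps * 5 / 6 else eps * 5 / 6
  p_nosig <- if (true_signal) eps / 2 else (1 - eps) + eps / 2
  p_secp <- (1 - eps) * (true_secp > cutoff) + eps * (1 - cutoff)
  p4 <- p_nosig * p_secp
  1 - (1 - p1) * (1 - p2) * (1 - p3) * (1 - p4)
}

# closed-form power of the >threshold-fold rule for a planted log10 effect
fold_power <- function(effect, sd, threshold = 10) {
  s <- sd * sqrt(2)
  t <- log10(threshold)
  stats::pnorm((effect - t) / s) + stats::pnorm((-t - effect) / s)
}

# --- brute-force hydropathy / TM / scan oracle -----------------------------

brute_hydropathy <- function(seq, window, scale = KYTE_DOOLITTLE) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res) - window + 1
  vapply(seq_len(n), function(i) mean(scale[res[i:(i + window - 1)]]),
         numeric(1))
}

# independent TM finder: scan every residue interval after merging runs
brute_tm <- function(seq, window = 11, threshold = 1.6, min_len = 15,
                     max_len = 25, slack = 5, merge_gap = 2) {
  v <- brute_hydropathy(seq, window)
  res <- strsplit(seq, "")[[1]]
  h <- unname(KYTE_DOOLITTLE[res])
  above <- which(v >= threshold)
  if (length(above) == 0) return(NULL)
  groups <- split(above, cumsum(c(1, diff(above) > merge_gap + 1)))
  out <- NULL
  hw <- (window - 1) / 2
  for (g in groups) {
    s <- min(g) + hw
    e <- max(g) + hw
    while (s > 1 && h[s - 1] >= threshold) s <- s - 1
    while (e < length(h) && h[e + 1] >= threshold) e <- e + 1
    len <- e - s + 1
    if (len >= min_len && len <= max_len + slack)
      out <- rbind(out, c(start = s - 1, end = e))
  }
  out
}

# deterministic hydrophilic filler (no K/R, no hydrophobics, no P/E runs)
filler <- function(n) paste(rep_len(c("D", "S", "N", "T", "G", "Q"), n),
                            collapse = "")

# planted PEP-CTERM construct: hydrophilic body + PEP + TM + basic cluster
planted_construct <- function(body = 40, tm = 18, basics = "RRKR",
                              tm_res = "L") {
  paste0(filler(body), "PEP", strrep(tm_res, tm), basics)
}

random_protein <- function(len, hydrophilic = TRUE) {
  f <- c(A = 8.3, R = 5.5, N = 4.1, D = 5.5, C = 1.4, Q = 3.9, E = 6.7,
         G = 7.1, H = 2.3, I = 5.9, L = 9.7, K = 5.8, M = 2.4, F = 3.9,
         P = 4.7, S = 6.6, T = 5.4, W = 1.1, Y = 2.9, V = 6.9)
  if (hydrophilic) {
    hyd <- names(KYTE_DOOLITTLE)[KYTE_DOOLITTLE > 1.6]
    f[intersect(names(f), hyd)] <- f[intersect(names(f), hyd)] * 0.3
  }
  paste(sample(names(f), len, replace = TRUE, prob = f / sum(f)),
        collapse = "")
}

# standard predictor profile row, overridable field by field
profile_row <- function(protein_id = "P1", has_signal_peptide = FALSE,
                        lipoprotein_class = "none", secretomep_score = 0.2,
                        tm_helix_count = 0L, bomp_category = 0L,
                        cello_label = "cytoplasmic",
                        psortb_label = "cytoplasmic") {
  data.frame(protein_id = protein_id,
             has_signal_peptide = has_signal_peptide,
             lipoprotein_class = lipoprotein_class,
             secretomep_score = secretomep_score,
             tm_helix_count = tm_helix_count,
             bomp_category = bomp_category,
             cello_label = cello_label, psortb_label = psortb_label,
             stringsAsFactors = FALSE)
}
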