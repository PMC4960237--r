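test_that("the four OM criteria fire independently and as conjunctions", {
  expect_equal(om_criteria(profile_row(cello_label = "outer membrane",
                                       psortb_label = "outer membrane")),
               "C1_dual_om")
  # one OM label alone is not enough for C1
  expect_equal(om_criteria(profile_row(cello_label = "outer membrane")),
               character(0))
  expect_equal(om_criteria(profile_row(lipoprotein_class = "lipoprotein")),
               "C2_lipoprotein")
  # signal-peptidase-I cleaved proteins are not lipoproteins
  expect_equal(om_criteria(profile_row(lipoprotein_class = "other-cleaved")),
               character(0))
  expect_equal(om_criteria(profile_row(bomp_category = 3L)), "C3_beta_barrel")
  expect_equal(om_criteria(profile_row(secretomep_score = 0.8)),
               "C4_nonclassical")
  # C4 requires the signal peptide to be absent
  expect_equal(om_criteria(profile_row(has_signal_peptide = TRUE,
                                       secretomep_score = 0.8)),
               character(0))
  # any subset may fire
  expect_setequal(om_criteria(profile_row(cello_label = "outer membrane",
                                          psortb_label = "outer membrane",
                                          bomp_category = 1L)),
                  c("C1_dual_om", "C3_beta_barrel"))
})

test_that("compartment assignment: OM, periplasmic fallback, CELLO fallback", {
  p <- profile_row(bomp_category = 2L)
  expect_equal(assign_compartment(p)$label, "om_confirmed")

  p <- profile_row(has_signal_peptide = TRUE, cello_label = "periplasmic",
                   psortb_label = "periplasmic")
  expect_equal(assign_compartment(p)$label, "periplasmic")

  p <- profile_row()  # no signal, nothing fired -> keeps CELLO label
  expect_equal(assign_compartment(p)$label, "cytoplasmic")
})

test_that("preliminary list is the union of abundance and predictor arms", {
  lin <- cbind(om1 = c(10^9.0, 10^8.4, 10^8.5, 10^7, 0),
               om2 = c(10^8.9, 10^8.0, 10^8.2, 10^6, 0))
  rownames(lin) <- paste0("P", 1:5)
  tab <- toy_table(lin)
  profs <- do.call(rbind, lapply(paste0("P", 1:5), profile_row))
  profs$cello_label[2] <- "outer membrane"   # P2 enters via predictor arm
  profs$cello_label[5] <- "outer membrane"   # P5 is never detected
  cand <- suppressMessages(
    preliminary_candidates(tab, profs, c("om1", "om2")))
  # P1 above 8.5; P2 via CELLO; P3 exactly 8.5 excluded (strict); P4 out;
  # P5 predicted OM but undetected, so excluded
  expect_equal(cand, c("P1", "P2"))

  loose <- classifier_config(strict_threshold = FALSE)
  cand2 <- suppressMessages(
    preliminary_candidates(tab, profs, c("om1", "om2"), loose))
  expect_equal(cand2, c("P1", "P2", "P3"))

  expect_error(preliminary_candidates(tab, profs, character(0)), "non-empty")
})

test_that("imputed cells never satisfy the preliminary threshold", {
  # undetected cell imputed near a high sample minimum must not qualify
  lin <- cbind(om1 = c(10^9.4, 0))
  rownames(lin) <- c("hi", "gone")
  imp <- suppressMessages(impute_missing(toy_table(lin), offset = 0.5))
  expect_equal(lfq_values(imp)["gone", "om1"], 8.9)  # above 8.5 numerically
  profs <- rbind(profile_row("hi"), profile_row("gone"))
  cand <- suppressMessages(preliminary_candidates(imp, profs, "om1"))
  expect_equal(cand, "hi")
})

test_that("classify_detected counts criteria hits and rejects orphans", {
  profs <- do.call(rbind, lapply(sprintf("Q%02d", 1:10), profile_row))
  profs$bomp_category[1:2] <- 1L
  profs$lipoprotein_class[3] <- "lipoprotein"
  profs$cello_label[4] <- profs$psortb_label[4] <- "outer membrane"
  calls <- suppressMessages(classify_detected(profs$protein_id, profs))
  expect_equal(nrow(calls), 10)
  expect_equal(sum(calls$label == "om_confirmed"), 4)
  expect_true(all(calls$in_preliminary_list))
  expect_error(classify_detected(c("Q01", "ghost"), profs), "ghost")
})

test_that("genome screen flags undetected OM proteins only", {
  profs <- do.call(rbind, lapply(sprintf("G%02d", 1:20), profile_row))
  profs$lipoprotein_class[16:17] <- "lipoprotein"   # 2 undetected hits
  profs$bomp_category[3] <- 2L                      # detected, not screened
  detected <- profs$protein_id[1:15]
  gs <- suppressMessages(genome_screen(profs, detected))
  expect_equal(gs$protein_id, c("G16", "G17"))
  expect_false(any(gs$detected_in_proteomics))
  expect_false(any(gs$in_preliminary_list))

  expect_equal(nrow(suppressMessages(
    genome_screen(profs, profs$protein_id))), 0)
})

test_that("classification is deterministic, total, and criterion-monotone", {
  withr::local_seed(5)
  profs <- data.frame(
    protein_id = sprintf("R%03d", 1:120),
    has_signal_peptide = sample(c(TRUE, FALSE), 120, TRUE),
    lipoprotein_class = sample(c("none", "lipoprotein", "other-cleaved"),
                               120, TRUE),
    secretomep_score = runif(120),
    tm_helix_count = sample(0:10, 120, TRUE),
    bomp_category = sample(0:5, 120, TRUE),
    cello_label = sample(COMPARTMENTS, 120, TRUE),
    psortb_label = sample(COMPARTMENTS, 120, TRUE),
    stringsAsFactors = FALSE)
  c1 <- suppressMessages(classify_detected(profs$protein_id, profs))
  c2 <- suppressMessages(classify_detected(profs$protein_id, profs))
  expect_identical(c1, c2)                          # determinism
  expect_equal(nrow(c1), nrow(profs))               # partition: one call each
  expect_false(anyNA(c1$label))

  # forcing one extra criterion on never demotes an om_confirmed protein
  forced <- profs
  forced$bomp_category <- pmax(forced$bomp_category, 1L)
  c3 <- suppressMessages(classify_detected(forced$protein_id, forced))
  was_om <- c1$label == "om_confirmed"
  expect_true(all(c3$label[was_om] == "om_confirmed"))
})

test_that("noiseless synthetic data is recovered exactly", {
  cfg <- simulation_config(n_proteins = 400, predictor_error_rate = 0,
                           lfq_sd = 0.25, n_responsive = 3,
                           n_exclusive_per_condition = 1,
                           n_undetected_om = 3, n_pepcterm = 3,
                           seq_length_range = c(80, 120), seed = 61)
  sim <- suppressMessages(generate_dataset(cfg))
  truth_om <- sim$truth$proteins$protein_id[
    sim$truth$proteins$compartment == "outer membrane"]
  imp <- suppressMessages(impute_missing(sim$table))
  cand <- suppressMessages(preliminary_candidates(
    imp, sim$profiles, c("om_sarkosyl_mucin", "om_sarkosyl_glucose")))
  calls <- suppressMessages(classify_detected(cand, sim$profiles))
  got_om <- calls$protein_id[calls$label == "om_confirmed"]
  expect_setequal(got_om, intersect(cand, truth_om))

  # genome screen recovers exactly the proteins simulated as never detected
  det <- rownames(lfq_values(imp))[rowSums(detected_mask(imp)) > 0]
  gs <- suppressMessages(genome_screen(sim$profiles, det))
  expect_setequal(gs$protein_id,
                  sim$truth$proteins$protein_id[sim$truth$proteins$genome_only])
})

test_that("recovery under predictor noise matches the enumeration oracle", {
  cfg <- simulation_config(n_proteins = 1000, predictor_error_rate = 0.1,
                           n_responsive = 5, n_exclusive_per_condition = 2,
                           n_undetected_om = 3, n_pepcterm = 3,
                           seq_length_range = c(80, 120), seed = 77)
  sim <- suppressMessages(generate_dataset(cfg))
  tp <- sim$truth$profiles
  is_om <- sim$truth$proteins$compartment == "outer membrane"
  calls <- suppressMessages(
    classify_detected(tp$protein_id[is_om], sim$profiles))
  obs <- sum(calls$label == "om_confirmed")
  p <- mapply(p_om_recovered, tp$lipoprotein_class[is_om],
              tp$bomp_category[is_om],
              MoreArgs = list(eps = 0.1))
  expect_lt(abs(obs - sum(p)), 3 * sqrt(sum(p * (1 - p))) + 1e-9)
})
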