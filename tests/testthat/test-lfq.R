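test_that("imputation substitutes below the per-sample minimum, floored", {
  # minima 6.2 with offset 0.5 -> 5.7; minimum 4.2 with floor 4.0 -> 4.0
  lin <- cbind(s1 = c(10^6.2, 10^8, 0), s2 = c(10^4.2, 0, 10^7))
  rownames(lin) <- c("P1", "P2", "P3")
  tab <- toy_table(lin)
  imp <- suppressMessages(impute_missing(tab, offset = 0.5, floor = 4.0))
  expect_true(is_imputed(imp))
  expect_equal(lfq_values(imp)["P3", "s1"], 5.7)
  expect_equal(lfq_values(imp)["P2", "s2"], 4.0)
  # detected cells and the mask are untouched
  expect_equal(lfq_values(imp)["P2", "s1"], 8)
  expect_identical(detected_mask(imp), detected_mask(tab))
})

test_that("imputation identity, undefined-minimum and floor errors", {
  lin <- cbind(s1 = c(1e6, 1e8))
  tab <- toy_table(lin)
  imp <- impute_missing(tab)
  expect_equal(lfq_values(imp), lfq_values(tab))  # nothing missing

  lin0 <- cbind(s1 = c(0, 0), s2 = c(1e6, 1e7))
  expect_error(suppressMessages(impute_missing(toy_table(lin0))),
               "no detected values")

  # floor at/above the sample minimum would break the substitution rule
  lin2 <- cbind(s1 = c(10^4.2, 0))
  expect_error(suppressMessages(impute_missing(toy_table(lin2), floor = 4.3)),
               "not below")
})

test_that("relative abundance is a linear-scale share", {
  tab <- toy_table(cbind(s1 = c(1e9, 1e8)))
  sh <- relative_abundance(tab, "s1")
  expect_equal(unname(sh), c(10 / 11, 1 / 11))

  expect_equal(unname(relative_abundance(toy_table(cbind(s1 = 1e5)), "s1")), 1)
  expect_error(relative_abundance(tab, "nope"), "unknown sample")

  # named-subset share on a 5-protein table: hand-summed oracle 0.31
  lin <- cbind(s1 = c(10, 15, 6, 40, 29))  # subset P1..P3 sums to 31 of 100
  sh <- relative_abundance(toy_table(lin), "s1")
  expect_equal(round(100 * sum(sh[c("P01", "P02", "P03")])), 31)
})

test_that("compartment distributions sum linear shares by label", {
  lin <- cbind(s1 = c(1e9, 1e9, 1e8, 1e8))
  rownames(lin) <- paste0("P", 1:4)
  labs <- c(P1 = "outer membrane", P2 = "outer membrane",
            P3 = "cytoplasmic", P4 = "cytoplasmic")
  d <- compartment_distribution(toy_table(lin), labs, "s1")
  expect_equal(unname(d$shares["outer membrane"]), 20 / 22)
  expect_equal(unname(d$shares["cytoplasmic"]), 2 / 22)

  # all one label
  d1 <- compartment_distribution(toy_table(lin), setNames(rep("outer membrane", 4),
                                                          paste0("P", 1:4)), "s1")
  expect_equal(unname(d1$shares), 1)

  # permuting protein order leaves the distribution unchanged
  perm <- c(3, 1, 4, 2)
  d2 <- compartment_distribution(toy_table(lin[perm, , drop = FALSE]),
                                 labs, "s1")
  expect_equal(sort(d$shares), sort(d2$shares))

  # unlabeled proteins count as unknown
  d3 <- compartment_distribution(toy_table(lin), labs[1:2], "s1")
  expect_equal(unname(d3$shares["unknown"]), 2 / 22)
})

test_that("enrichment factors are share ratios with reciprocity", {
  lin <- cbind(a = c(4e8, 2e7), b = c(1e7, 49e7))
  labs <- c(P01 = "outer membrane", P02 = "cytoplasmic")
  tab <- toy_table(lin)
  da <- compartment_distribution(tab, labs, "a")
  db <- compartment_distribution(tab, labs, "b")
  expect_equal(enrichment_factor(da, da, "outer membrane")$factor, 1)

  ef <- enrichment_factor(da, db, "outer membrane")
  rf <- enrichment_factor(db, da, "outer membrane")
  expect_equal(ef$factor * rf$factor, 1, tolerance = 1e-9)

  # target share 0.40 over reference 0.02 -> 20-fold
  d40 <- structure(list(sample_id = "t", shares = c("outer membrane" = 0.40)),
                   class = "compartment_distribution")
  d02 <- structure(list(sample_id = "r", shares = c("outer membrane" = 0.02)),
                   class = "compartment_distribution")
  expect_equal(enrichment_factor(d40, d02, "outer membrane")$factor, 20)

  d0 <- structure(list(sample_id = "r", shares = c("outer membrane" = 0)),
                  class = "compartment_distribution")
  expect_error(enrichment_factor(d40, d0, "outer membrane"), "undefined")
})

test_that("sucrose gradient profiles order by index and score monotonicity", {
  n <- 24
  om <- 10^seq(6, 8, length.out = n)        # OM share strictly increasing
  cyto <- rep(1e8, n)
  lin <- rbind(OM1 = om, CY1 = cyto)
  meta <- data.frame(sample_id = sprintf("g%02d", 1:n),
                     fraction = "sucrose_gradient", condition = "mucin",
                     gradient_index = 1:n)
  colnames(lin) <- meta$sample_id
  tab <- abundance_table(ifelse(lin > 0, log10(lin), NA), lin > 0, meta)
  labs <- c(OM1 = "outer membrane", CY1 = "cytoplasmic")
  prof <- sucrose_gradient_profile(tab, labs)
  expect_equal(prof$monotonicity, 1)
  expect_true(all(diff(prof$share) > 0))

  # constant shares -> 0
  lin2 <- rbind(OM1 = rep(1e7, n), CY1 = cyto)
  colnames(lin2) <- meta$sample_id
  tab2 <- abundance_table(log10(lin2), lin2 > 0, meta)
  expect_equal(sucrose_gradient_profile(tab2, labs)$monotonicity, 0)

  # reversing input column order changes nothing: ordering is by index
  rev_meta <- meta[n:1, ]
  tab3 <- abundance_table(ifelse(lin > 0, log10(lin), NA)[, n:1],
                          (lin > 0)[, n:1], rev_meta)
  expect_equal(sucrose_gradient_profile(tab3, labs), prof)

  dup <- meta
  dup$gradient_index[2] <- 1L
  tab4 <- abundance_table(log10(lin), lin > 0, dup)
  expect_error(sucrose_gradient_profile(tab4, labs), "duplicate")
})

test_that("lfq operations match brute-force recomputation on toy tables", {
  withr::local_seed(42)
  for (k in 1:50) {
    tab <- random_toy_table()
    v <- lfq_values(tab)
    d <- detected_mask(tab)
    imp <- suppressMessages(impute_missing(tab, offset = 0.4, floor = 2))
    expect_equal(lfq_values(imp),
                 brute_impute(v, d, 0.4, 2), tolerance = 1e-12)
    for (j in seq_len(ncol(v))) {
      s <- colnames(v)[j]
      expect_equal(unname(relative_abundance(tab, s)),
                   brute_shares(v, d, j), tolerance = 1e-12)
    }
  }
})

test_that("share conservation and imputation monotonicity hold under fuzzing", {
  withr::local_seed(7)
  n_conserved <- 0
  for (k in 1:300) {
    tab <- random_toy_table()
    s <- sample(colnames(lfq_values(tab)), 1)
    expect_lt(abs(sum(relative_abundance(tab, s)) - 1), 1e-9)
    n_conserved <- n_conserved + 1
  }
  expect_equal(n_conserved, 300)

  for (k in 1:200) {
    tab <- random_toy_table()
    o1 <- runif(1, 0.1, 1)
    o2 <- o1 + runif(1, 0.1, 1)   # larger offset
    i1 <- suppressMessages(impute_missing(tab, offset = o1, floor = 0))
    i2 <- suppressMessages(impute_missing(tab, offset = o2, floor = 0))
    m <- !detected_mask(tab)
    expect_true(all(lfq_values(i2)[m] <= lfq_values(i1)[m]))
  }
})
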