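# Synthetic MS and Luminex generators, dropout mechanism, recovery scoring.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_proteins = 200, regions = c("CTX", "CB"), mice_per_group = 2,
         tech_reps = 1, frac_enriched = 0.2, delta_enrich = 3,
         frac_regional = 0.25, delta_region = 2.5, noise_sd = 0.3,
         n_endogenous = 4, seed = 7),
    list(...))
  do.call(synth_ms_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(synth_ms_config(frac_enriched = 1.2), "fractions")
  expect_error(synth_ms_config(n_proteins = 0), "counts")
  expect_error(synth_ms_config(noise_sd = -1), "noise_sd")
  expect_error(synth_ms_config(regions = c("A", "B"),
                               bait_log2_by_region = c(A = 25)),
               "one entry per region")
  expect_error(synth_ms_config(n_proteins = 5, n_endogenous = 9),
               "exceeds")
})

test_that("zero noise reproduces the true group means exactly and recovery
           is perfect at any positive threshold", {
  cfg <- small_cfg(noise_sd = 0)
  ds <- generate_ms_dataset(cfg)
  lm2 <- log2_transform(ds$matrix)
  v <- im_values(lm2)
  for (g in c("labeled", "control")) for (r in cfg$regions) {
    ids <- select_samples(ds$design, genotype = g, region = r)
    cell <- ds$truth$true_means[, paste(g, r, sep = ":")]
    expect_equal(unname(rowMeans(v[names(cell), ids, drop = FALSE])),
                 unname(cell), tolerance = 1e-12)
  }
  no_bait <- setdiff(rownames(v), ds$truth$bait_id)
  tt <- two_group_test(lm2[no_bait, ],
                       select_samples(ds$design, genotype = "labeled"),
                       select_samples(ds$design, genotype = "control"))
  calls <- classify_enrichment(tt, fc_threshold = 1.1, p_threshold = 1)
  rec <- score_recovery(ds$truth, calls)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$fdr, 0)
})

test_that("planted structure respects the declared truth invariants", {
  ds <- generate_ms_dataset(small_cfg())
  tr <- ds$truth
  expect_true(all(names(tr$regional_map) %in% tr$enriched_ids))
  expect_false(tr$bait_id %in% c(tr$enriched_ids, tr$endogenous_ids))
  expect_length(intersect(tr$enriched_ids, tr$endogenous_ids), 0)
  # bait present in every labeled sample, absent in every control
  v <- im_values(ds$matrix)
  lab <- select_samples(ds$design, genotype = "labeled")
  ctl <- select_samples(ds$design, genotype = "control")
  expect_false(anyNA(v[tr$bait_id, lab]))
  expect_true(all(is.na(v[tr$bait_id, ctl])))
  # endogenous proteins present at equal expectation in both genotypes
  tm <- tr$true_means
  expect_equal(tm[tr$endogenous_ids, paste0("labeled:", "CTX")],
               tm[tr$endogenous_ids, paste0("control:", "CTX")])
})

test_that("per-region technical replicate counts reproduce the 18-column
           cohort layout", {
  cfg <- synth_ms_config(n_proteins = 20,
                         regions = c("CTX", "HIP", "ST", "PM", "CB"),
                         mice_per_group = 2,
                         tech_reps = c(CTX = 2, HIP = 1, ST = 2, PM = 2,
                                       CB = 2),
                         seed = 1)
  ds <- generate_ms_dataset(cfg)
  lab <- select_samples(ds$design, genotype = "labeled")
  expect_length(lab, 18)
  expect_length(select_samples(ds$design, genotype = "labeled",
                               region = "HIP"), 2)
  expect_length(select_samples(ds$design, genotype = "labeled",
                               region = "CTX"), 4)
})

test_that("generation is bit-identical for identical config and seed", {
  d1 <- generate_ms_dataset(small_cfg())
  d2 <- generate_ms_dataset(small_cfg())
  expect_identical(im_values(d1$matrix), im_values(d2$matrix))
  expect_identical(d1$truth$enriched_ids, d2$truth$enriched_ids)
  d3 <- generate_ms_dataset(small_cfg(seed = 8))
  expect_false(identical(im_values(d1$matrix), im_values(d3$matrix)))
})

test_that("dropout is logistic in intensity, conserves cell count, and
           never empties a column", {
  n <- 1e5
  v <- matrix(25, n, 1, dimnames = list(sprintf("p%d", 1:n), "s1"))
  mat <- intensity_matrix(v, scale = "log2")
  # at the midpoint the missing probability is 1/2
  out_mid <- apply_dropout(mat, midpoint = 25, slope = 1, seed = 3)
  rate_mid <- mean(is.na(im_values(out_mid)))
  expect_lt(abs(rate_mid - 0.5), 3 * sqrt(0.25 / n))
  expect_equal(dim(out_mid), dim(mat))   # cells conserved
  # two slopes above the midpoint: rate ~ plogis(-2) = 0.119
  out_hi <- apply_dropout(intensity_matrix(v + 2, scale = "log2"),
                          midpoint = 25, slope = 1, seed = 3)
  p_expect <- plogis(-2)
  expect_lt(abs(mean(is.na(im_values(out_hi))) - p_expect),
            3 * sqrt(p_expect * (1 - p_expect) / n))
  # near-zero slope acts as a hard threshold at the midpoint
  vt <- matrix(c(24.9, 24.99, 25.01, 26), 4, 1,
               dimnames = list(sprintf("p%d", 1:4), "s1"))
  out_thr <- apply_dropout(intensity_matrix(vt, scale = "log2"),
                           midpoint = 25, slope = 1e-9, seed = 1)
  expect_equal(unname(is.na(im_values(out_thr))[, 1]),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(apply_dropout(mat, 25, slope = 0), "slope")
  # a column of uniformly low values keeps its strongest cell
  vl <- matrix(c(5, 6, 7), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  out_low <- apply_dropout(intensity_matrix(vl, scale = "log2"),
                           midpoint = 25, slope = 1, seed = 1)
  expect_equal(sum(!is.na(im_values(out_low))), 1)
  expect_false(is.na(im_values(out_low)["c", 1]))
})

test_that("dropout probability is monotone non-increasing in intensity", {
  set.seed(2)
  n <- 4e4
  x <- seq(18, 30, length.out = n)
  v <- matrix(x, n, 1, dimnames = list(sprintf("p%d", 1:n), "s1"))
  out <- apply_dropout(intensity_matrix(v, scale = "log2"),
                       midpoint = 22, slope = 1.5, seed = 9)
  miss <- is.na(im_values(out)[, 1])
  bins <- cut(x, breaks = seq(18, 30, by = 2))
  rates <- tapply(miss, bins, mean)
  expect_true(all(diff(rates) <= 0.03))  # monotone up to binomial noise
})

test_that("raising the enrichment effect never lowers downstream
           sensitivity", {
  sens_at <- function(delta, seed) {
    cfg <- synth_ms_config(n_proteins = 300, regions = "R1",
                           mice_per_group = 3, tech_reps = 1,
                           frac_enriched = 0.1, delta_enrich = delta,
                           frac_regional = 0, noise_sd = 0.5,
                           n_endogenous = 3, seed = seed)
    ds <- generate_ms_dataset(cfg)
    lm2 <- log2_transform(ds$matrix)
    ids <- setdiff(rownames(im_values(lm2)), ds$truth$bait_id)
    tt <- two_group_test(lm2[ids, ],
                         select_samples(ds$design, genotype = "labeled"),
                         select_samples(ds$design, genotype = "control"))
    score_recovery(ds$truth,
                   classify_enrichment(tt))$sensitivity
  }
  deltas <- c(0.5, 1.5, 3)
  mean_sens <- vapply(deltas, function(d)
    mean(vapply(1:20, function(s) sens_at(d, s), numeric(1))), numeric(1))
  expect_true(all(diff(mean_sens) >= 0))
})

test_that("recovery scoring handles perfect, empty, and off-by-one calls", {
  ds <- generate_ms_dataset(small_cfg())
  tr <- ds$truth
  perfect <- score_recovery(tr, tr$enriched_ids)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$fdr, 0)
  expect_equal(perfect$specificity, 1)

  empty <- score_recovery(tr, character())
  expect_equal(empty$sensitivity, 0)
  expect_true(is.na(empty$fdr))
  expect_false(empty$fdr_defined)

  # 8 true calls plus 1 false positive of 9 total: FDR = 1/9
  null_ids <- setdiff(rownames(tr$true_means),
                      c(tr$enriched_ids, tr$endogenous_ids, tr$bait_id))
  calls9 <- c(tr$enriched_ids[1:8], null_ids[1])
  expect_equal(score_recovery(tr, calls9)$fdr, 1 / 9)

  # bait and endogenous proteins never count as positives
  with_excl <- score_recovery(tr, c(tr$enriched_ids[1:8], tr$bait_id,
                                    tr$endogenous_ids[1]))
  expect_equal(with_excl$n_called, 8)
  expect_equal(with_excl$fdr, 0)

  # empty truth: sensitivity undefined, flagged
  tr0 <- tr
  tr0$enriched_ids <- character()
  und <- score_recovery(tr0, character())
  expect_true(is.na(und$sensitivity))
  expect_false(und$sensitivity_defined)
})

test_that("synthetic Luminex: degenerate configs give exact identities and
           the derived fraction is recovered", {
  an <- data.frame(analyte = c("IL6", "TNF"), abundance = c(1000, 400),
                   frac = c(1, 1))
  cfg <- synth_luminex_config(an, regions = "CTX", n_wells = 2,
                              plate_noise_cv = 0, blank_level = 0,
                              seed = 1)
  dl <- generate_luminex_dataset(cfg)
  # fraction 1, CV 0, blank 0, bait 1: adapted equals standard
  expect_equal(dl$adapted_labeled$fluorescence,
               dl$standard$fluorescence)
  # fraction 0: labeled adapted equals control adapted in expectation
  an0 <- transform(an, frac = 0)
  dl0 <- generate_luminex_dataset(
    synth_luminex_config(an0, regions = "CTX", n_wells = 50,
                         plate_noise_cv = 0.05, blank_level = 40,
                         seed = 2))
  expect_lt(abs(mean(dl0$adapted_labeled$fluorescence) -
                  mean(dl0$adapted_control$fluorescence)), 2)

  # fraction 0.6, CV 0.05, 50 wells: recovered within 0.6 +/- 0.05
  an6 <- data.frame(analyte = "IL6", abundance = 1000, frac = 0.6)
  dl6 <- generate_luminex_dataset(
    synth_luminex_config(an6, regions = "CTX", n_wells = 50,
                         plate_noise_cv = 0.05, blank_level = 30,
                         seed = 3))
  std <- suppressMessages(subtract_background(dl6$standard, 30))
  adp <- suppressMessages(subtract_background(dl6$adapted_labeled, 30))
  res <- neuron_derived_fraction(std, adp)
  expect_lt(abs(res$fraction - 0.6), 0.05)
  expect_equal(res$predominant_origin, "cell-type")

  expect_error(synth_luminex_config(transform(an, frac = 2)), "fractions")
  expect_error(synth_luminex_config(an, blank_level = -1), "blank_level")
})
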