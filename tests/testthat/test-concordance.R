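# concordance_eval: matching, Wilson/detection rates, gene rates, refmat, mixing

test_that("match_variants partitions calls exactly (patient 78 fixture case)", {
  t3 <- load_fixture("table3_tissue_plasma")
  p78 <- t3[t3$patient_id == "78", ]
  m <- match_variants(p78[p78$sample_type == "tissue", ],
                      p78[p78$sample_type == "plasma", ], key_mode = "hgvs")
  expect_equal(unname(m$counts["matched"]), 5)
  expect_equal(unname(m$counts["plasma_only"]), 1)
  expect_equal(m$plasma_only$hgvs_c, "c.6747del")
  expect_equal(nrow(m$matched) + nrow(m$tissue_only), 5)

  # identity and disjoint cases
  a <- data.frame(patient_id = "X", gene = "KRAS",
                  hgvs_c = c("c.1A>T", "c.2A>T"), stringsAsFactors = FALSE)
  id <- match_variants(a, a)
  expect_equal(unname(id$counts), c(2, 0, 0))
  b <- a; b$hgvs_c <- c("c.3A>T", "c.4A>T")
  dis <- match_variants(a, b)
  expect_equal(unname(dis$counts["matched"]), 0)
  # duplicates rejected
  expect_error(match_variants(rbind(a, a[1, ]), b), "duplicate")
})

test_that("wilson interval reproduces printed bounds and closed-form properties", {
  ci <- wilson_interval(262, 357, 0.95)
  expect_equal(round(unname(ci), 4), c(0.6857, 0.7771))
  expect_equal(unname(wilson_interval(0, 10)["low"]), 0)
  expect_error(wilson_interval(1, 0), "n >= 1")
  # sweep: contains k/n, ordered, monotone widening in confidence
  for (n in c(1, 5, 16, 357)) {
    for (k in unique(round(seq(0, n, length.out = 5)))) {
      ci95 <- wilson_interval(k, n, 0.95)
      ci99 <- wilson_interval(k, n, 0.99)
      expect_lte(ci95["low"], k / n)
      expect_gte(ci95["high"], k / n)
      expect_lte(ci99["low"], ci95["low"])
      expect_gte(ci99["high"], ci95["high"])
      expect_true(all(c(ci95, ci99) >= 0 & c(ci95, ci99) <= 1))
    }
  }
  # stats::binom.test as the independent oracle for Clopper-Pearson
  bt <- stats::binom.test(262, 357)$conf.int
  cp <- clopper_pearson_interval(262, 357)
  expect_equal(unname(cp), as.numeric(bt), tolerance = 1e-9)
})

test_that("detection_rate reports the printed percentage and flags 0 denominators", {
  dr <- detection_rate(262, 357)
  expect_equal(dr$rate_percent, 73.4)
  expect_equal(round(dr$ci_low, 4), 0.6857)
  expect_equal(round(dr$ci_high, 4), 0.7771)
  expect_equal(detection_rate(11, 11)$rate_percent, 100)
  z <- detection_rate(0, 25)
  expect_equal(z$rate_percent, 0)
  expect_equal(z$ci_low, 0)
  expect_true(detection_rate(0, 0)$undefined)
  expect_error(detection_rate(5, 3), "exceeds")
})

test_that("per-gene patient-level rates reproduce the cohort narrative", {
  t3 <- load_fixture("table3_tissue_plasma")
  n_pat <- attr(t3, "n_patients")
  expect_equal(n_pat, 16)
  apc <- gene_positive_rate(t3, "APC", "plasma_given_tissue")
  kras <- gene_positive_rate(t3, "KRAS", "plasma_given_tissue")
  tp53 <- gene_positive_rate(t3, "TP53", "plasma_given_tissue")
  expect_equal(c(apc$numerator, apc$denominator), c(8, 13))
  expect_equal(apc$rate_percent, 61.5)
  expect_equal(c(kras$numerator, kras$denominator), c(8, 11))
  expect_equal(kras$rate_percent, 72.7)
  expect_equal(c(tp53$numerator, tp53$denominator), c(7, 8))
  expect_equal(tp53$rate_percent, 87.5)
  # tissue/plasma prevalence as printed
  expect_equal(gene_positive_rate(t3, "APC", "tissue_only",
                                  n_patients = n_pat)$rate_percent, 81.3)
  expect_equal(gene_positive_rate(t3, "KRAS", "tissue_only",
                                  n_patients = n_pat)$rate_percent, 68.8)
  expect_equal(gene_positive_rate(t3, "TP53", "tissue_only",
                                  n_patients = n_pat)$rate_percent, 50)
  expect_equal(gene_positive_rate(t3, "APC", "plasma_only",
                                  n_patients = n_pat)$rate_percent, 56.3)
  # unknown gene -> flagged undefined in conditional mode
  expect_true(gene_positive_rate(t3, "MYC", "plasma_given_tissue")$undefined)
})

test_that("combined tissue+plasma actionable-gene rates match Table 5 narrative", {
  t5 <- load_fixture("table5_actionable")
  n <- 16
  braf_t <- gene_positive_rate(t5, "BRAF", "tissue_only", n_patients = n,
                               places = 0)
  braf_c <- gene_positive_rate(t5, "BRAF", "combined", n_patients = n,
                               places = 0)
  pik_t <- gene_positive_rate(t5, "PIK3CA", "tissue_only", n_patients = n,
                              places = 0)
  pik_c <- gene_positive_rate(t5, "PIK3CA", "combined", n_patients = n,
                              places = 0)
  egfr_p <- gene_positive_rate(t5, "EGFR", "plasma_only", n_patients = n,
                               places = 0)
  expect_equal(c(braf_t$numerator, braf_t$rate_percent), c(3, 19))
  expect_equal(c(braf_c$numerator, braf_c$rate_percent), c(5, 31))
  expect_equal(c(pik_t$numerator, pik_t$rate_percent), c(3, 19))
  expect_equal(c(pik_c$numerator, pik_c$rate_percent), c(4, 25))
  expect_equal(c(egfr_p$numerator, egfr_p$rate_percent), c(2, 13))
  expect_equal(gene_positive_rate(t5, "EGFR", "tissue_only",
                                  n_patients = n)$numerator, 0)
  # set inclusion: tissue_only <= combined for every gene present
  for (g in unique(t5$gene)) {
    expect_lte(gene_positive_rate(t5, g, "tissue_only", n_patients = n)$numerator,
               gene_positive_rate(t5, g, "combined", n_patients = n)$numerator)
  }
})

test_that("reference-material panel rates match both extraction arms", {
  t2 <- load_fixture("table2_refmat")
  expect_equal(nrow(t2), 38)
  ll <- refmat_detection_rate(t2, "liquid_liquid")
  sp <- refmat_detection_rate(t2, "solid_phase")
  expect_equal(c(ll$numerator, ll$denominator), c(36, 38))
  expect_equal(ll$rate_percent, 94.7)
  expect_equal(c(sp$numerator, sp$denominator), c(31, 38))
  expect_equal(sp$rate_percent, 81.6)
  none <- t2; none$observed_liquid_liquid <- NA_real_
  expect_equal(refmat_detection_rate(none, "liquid_liquid")$numerator, 0)
  expect_error(refmat_detection_rate(t2[0, ], "liquid_liquid"), "empty")
  expect_error(refmat_detection_rate(t2, "ultracentrifuge"), "arms available")
})

test_that("mixing arithmetic and percentage reporting follow the stated rules", {
  expect_equal(expected_mix_vaf(1.0, 0, 1, 1), 0.5)
  expect_equal(expected_mix_vaf(0.37, 0.37, 3, 11), 0.37)
  expect_equal(expected_mix_vaf(0.8, 0.2, 3, 1), 0.65)
  expect_error(expected_mix_vaf(1, 1, 0, 0), "ratios")
  expect_error(expected_mix_vaf(-1, 0), "non-negative")
  expect_equal(report_percent(13 / 16, 1), "81.3%")
  expect_equal(report_percent(11 / 16, 1), "68.8%")
  expect_equal(report_percent(2 / 16, 0), "13%")
  expect_equal(report_percent(262 / 357, 1), "73.4%")
})

test_that("cohort detection rates: overall equals pooled per-patient counts", {
  co <- simulate_cohort(cohort_sim_spec(seed = 10))
  res <- cohort_detection_rates(co$tissue, co$plasma, key_mode = "coordinate")
  expect_equal(res$overall$numerator, sum(res$per_patient$matched_n))
  expect_equal(res$overall$denominator, sum(res$per_patient$tissue_n))
  expect_equal(res$per_patient$matched_n, co$truth$matched_n)
  # plasma-only calls never enter the denominator
  expect_equal(res$overall$denominator, nrow(co$tissue))
})

test_that("Wilson coverage and cohort parameter recovery (seeded stochastic)", {
  # coverage at p = 0.7, n = 357: >= 93% of 1000 draws contain p
  covered <- withr::with_seed(123, {
    ks <- stats::rbinom(1000, 357, 0.7)
    vapply(ks, function(k) {
      ci <- wilson_interval(k, 357)
      ci["low"] <= 0.7 && ci["high"] >= 0.7
    }, logical(1))
  })
  expect_gte(mean(covered), 0.93)

  # estimated overall rate's CI contains the true p in >= 90% of 100 replicates
  hits <- vapply(1:100, function(i) {
    co <- simulate_cohort(cohort_sim_spec(seed = 1000 + i, n_patients = 16,
                                          mutations_per_patient = c(11, 24),
                                          plasma_detection_prob = 0.734))
    dr <- cohort_detection_rates(co$tissue, co$plasma,
                                 key_mode = "coordinate")$overall
    dr$ci_low <= 0.734 && dr$ci_high >= 0.734
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
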