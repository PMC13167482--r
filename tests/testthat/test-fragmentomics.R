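# fragmentomics: CIGAR projection, allele classification, sizes, rank-sum

test_that("project_locus walks CIGARs with indels as hand-derived", {
  expect_equal(project_locus(100, "50M", 120)$offset, 20)
  expect_true(project_locus(100, "50M", 120)$covered)
  # ref 112 falls inside the deletion of 10M5D40M at pos 100
  pr <- project_locus(100, "10M5D40M", 112)
  expect_false(pr$covered)
  expect_equal(pr$op, "D")
  # insertion shifts query offsets: ref 115 -> offset 20 under 10M5I40M
  expect_equal(project_locus(100, "10M5I40M", 115)$offset, 20)
  # soft clips consume query before alignment starts
  expect_equal(project_locus(100, "5S45M", 100)$offset, 5)
  # outside the span
  expect_false(project_locus(100, "50M", 99)$covered)
  expect_false(project_locus(100, "50M", 150)$covered)
  expect_error(project_locus(100, "5Q", 100), "malformed")
})

test_that("classify_read handles SNVs, exact indel patterns and anchors", {
  ref <- strrep("A", 200)
  snv <- variant_spec("sim_ref", 150, "C", "T")
  # 60M starting at 120: offset of ref 150 is 30
  seqT <- paste0(strrep("G", 30), "T", strrep("G", 29))
  seqC <- paste0(strrep("G", 30), "C", strrep("G", 29))
  seqA <- paste0(strrep("G", 30), "A", strrep("G", 29))
  expect_equal(classify_read(make_record(120, "60M", seqT), snv), "mutant")
  expect_equal(classify_read(make_record(120, "60M", seqC), snv), "non_mutant")
  expect_equal(classify_read(make_record(120, "60M", seqA), snv), "other_allele")
  # read spanning 100-149 does not cover the locus
  expect_equal(classify_read(make_record(100, "50M", strrep("G", 50)), snv),
               "not_covered")
  # locus at the read's last base: no right anchor
  expect_equal(classify_read(make_record(91, "60M", strrep("G", 60)), snv),
               "not_covered")
  # wrong chromosome is not an error
  expect_equal(classify_read(make_record(120, "60M", seqT, rname = "chr9"),
                             snv), "not_covered")

  del <- variant_spec("sim_ref", 149, "CGGG", "C")  # deletes 150-152
  rec_mut <- make_record(120, "30M3D30M", strrep("G", 60))
  rec_wt <- make_record(120, "60M", strrep("G", 60))
  expect_equal(classify_read(rec_mut, del), "mutant")
  expect_equal(classify_read(rec_wt, del), "non_mutant")
  # a deletion of the wrong length is another allele
  expect_equal(classify_read(make_record(120, "30M2D30M", strrep("G", 60)), del),
               "other_allele")
  # mis-positioned deletion (one base early) is another allele
  expect_equal(classify_read(make_record(120, "29M3D31M", strrep("G", 60)), del),
               "other_allele")
  # read ending at the anchor is not informative
  expect_equal(classify_read(make_record(120, "30M", strrep("G", 30)), del),
               "not_covered")

  ins <- variant_spec("sim_ref", 150, "G", "GTTA")
  seq_ins <- paste0(strrep("G", 31), "TTA", strrep("G", 29))
  expect_equal(classify_read(make_record(120, "31M3I29M", seq_ins), ins),
               "mutant")
  expect_equal(classify_read(make_record(120, "60M", strrep("G", 60)), ins),
               "non_mutant")
  # same length, wrong inserted sequence
  seq_bad <- paste0(strrep("G", 31), "CCC", strrep("G", 29))
  expect_equal(classify_read(make_record(120, "31M3I29M", seq_bad), ins),
               "other_allele")
  # wrong insertion length
  seq_short <- paste0(strrep("G", 31), "TT", strrep("G", 29))
  expect_equal(classify_read(make_record(120, "31M2I29M", seq_short), ins),
               "other_allele")
})

test_that("fragment-level aggregation applies mate-conflict and mapq rules", {
  snv <- variant_spec("sim_ref", 150, "C", "T")
  mkpair <- function(b1, b2, mapq2 = 60L, qname = "f1") {
    rbind(make_record(120, "60M", paste0(strrep("G", 30), b1, strrep("G", 29)),
                      qname = qname, tlen = 150L),
          make_record(130, "60M", paste0(strrep("G", 20), b2, strrep("G", 39)),
                      qname = qname, flag = 147L, mapq = mapq2, tlen = -150L))
  }
  both_mut <- classify_fragments(mkpair("T", "T"), snv)
  expect_equal(both_mut$label, "mutant")
  expect_equal(both_mut$n_informative, 2)
  conflict <- classify_fragments(mkpair("T", "C"), snv)
  expect_equal(conflict$label, "ambiguous")
  # low-mapq mate is ignored, leaving a single informative call
  rescued <- classify_fragments(mkpair("T", "C", mapq2 = 5L), snv)
  expect_equal(rescued$label, "mutant")
  # duplicates are dropped before classification
  dup <- mkpair("T", "T")
  dup$flag[1] <- bitwOr(dup$flag[1], 1024L)
  expect_equal(classify_fragments(dup, snv)$n_informative, 1)
  # three primary records for one name is an input error
  three <- rbind(mkpair("T", "T"), mkpair("T", "T")[1, ])
  expect_error(classify_fragments(three, snv), "3 primary")
  # record order never changes labels
  recs <- rbind(mkpair("T", "C", qname = "f1"), mkpair("C", "C", qname = "f2"))
  fwd <- classify_fragments(recs, snv)
  rev <- classify_fragments(recs[rev(seq_len(nrow(recs))), ], snv)
  rev <- rev[match(fwd$fragment, rev$fragment), ]
  expect_equal(fwd$label, rev$label)
})

test_that("fragment label partition is exhaustive on synthetic data", {
  cfg <- sim_config(seed = 31, n_fragments = 400, mutant_fraction = 0.25,
                    background_fraction = 0.1)
  sim <- simulate_read_pairs(cfg)
  fc <- classify_fragments(sim$records, cfg$variant)
  expect_equal(nrow(fc), 400)
  expect_true(all(fc$label %in% c("mutant", "non_mutant", "other_allele",
                                  "ambiguous", "not_covered")))
  # VAF recovery within the 99.9% binomial band among covered fragments
  n_cov <- sum(fc$label %in% c("mutant", "non_mutant"))
  band <- binom_band(n_cov, cfg$mutant_fraction)
  expect_gte(sum(fc$label == "mutant"), band[1])
  expect_lte(sum(fc$label == "mutant"), band[2])
})

test_that("fragment_sizes takes one positive-TLEN size per pair and tallies exclusions", {
  snv <- variant_spec("sim_ref", 150, "C", "T")
  recs <- rbind(
    make_record(100, "60M", paste0(strrep("G", 50), "T", strrep("G", 9)),
                qname = "a", tlen = 180L),
    make_record(220, "60M", strrep("G", 60), qname = "a", flag = 147L,
                tlen = -180L))
  fc <- classify_fragments(recs, snv)
  fs <- fragment_sizes(fc, recs)
  expect_equal(fs$sizes$mutant, 180)
  # tlen 0 excluded and tallied
  recs0 <- recs; recs0$tlen <- 0L
  fs0 <- fragment_sizes(classify_fragments(recs0, snv), recs0)
  expect_equal(length(fs0$sizes$mutant), 0)
  expect_equal(unname(fs0$excluded["zero_tlen"]), 1)
  # inconsistent mate TLENs warn and exclude
  recsi <- recs; recsi$tlen <- c(180L, -179L)
  expect_warning(fsi <- fragment_sizes(classify_fragments(recsi, snv), recsi),
                 "negations")
  expect_equal(unname(fsi$excluded["inconsistent"]), 1)
  # oversize excluded
  recsl <- recs; recsl$tlen <- c(1200L, -1200L)
  fsl <- fragment_sizes(classify_fragments(recsl, snv), recsl)
  expect_equal(unname(fsl$excluded["oversize"]), 1)
  # synthetic run: recovered sizes equal generator truth exactly
  cfg <- sim_config(seed = 17, n_fragments = 150, mutant_fraction = 0.3)
  sim <- simulate_read_pairs(cfg)
  fc2 <- classify_fragments(sim$records, cfg$variant)
  fs2 <- fragment_sizes(fc2, sim$records)
  got <- sort(c(fs2$sizes$mutant, fs2$sizes$non_mutant))
  expect_equal(got, sort(sim$truth$size))
})

test_that("size_summary windows are inclusive and the threshold is strict", {
  s <- size_summary(c(100, 149, 150, 151, 220, 221, 400))
  expect_equal(s$all$n, 7)
  expect_equal(s$all$n_below_threshold, 2)  # 100, 149; 150 is not below
  expect_equal(s$mono$n, 5)                 # 100..220 inclusive
  expect_equal(s$di$n, 2)                   # 221, 400
  expect_equal(sum(s$all$histogram$count), s$all$n)
  empty <- size_summary(numeric(0))
  expect_equal(empty$all$n, 0)
  expect_true(is.na(empty$all$fraction_below_threshold))
  # printed sub-150 fractions from the study counts
  expect_equal(report_percent(1149 / 2839, 1), "40.5%")
  expect_equal(report_percent(7942 / 31681, 1), "25.1%")
})

test_that("rank_sum_less: exact enumeration, ties, and approximation agree with oracle", {
  r <- rank_sum_less(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1 / 20)
  # identical multisets: no shift signal (approx branch, continuity-corrected)
  same <- rank_sum_less(1:11, 1:11)
  expect_gte(same$p_value, 0.05)
  expect_equal(same$p_value, 0.5, tolerance = 0.05)
  # exact branch on a small identical pair also shows no shift
  expect_gte(rank_sum_less(c(5, 6, 7, 8), c(5, 6, 7, 8))$p_value, 0.05)
  expect_error(rank_sum_less(numeric(0), 1), "non-empty")
  # exact branch against stats::wilcox.test on tie-free samples
  withr::with_seed(5, {
    for (i in 1:10) {
      a <- sample(seq(1, 199, 2), 5); b <- sample(seq(2, 200, 2), 7)  # tie-free
      ours <- rank_sum_less(a, b)
      theirs <- stats::wilcox.test(a, b, alternative = "less", exact = TRUE)
      expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-12)
      expect_equal(ours$statistic, unname(theirs$statistic))
    }
  })
  # approximate branch against wilcox.test with continuity correction + ties
  withr::with_seed(6, {
    for (i in 1:10) {
      a <- sample(50, 30, replace = TRUE); b <- sample(50, 30, replace = TRUE)
      ours <- rank_sum_less(a, b)
      expect_equal(ours$method, "normal_approx")
      theirs <- stats::wilcox.test(a, b, alternative = "less", exact = FALSE,
                                   correct = TRUE)
      expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-10)
    }
  })
  # exact and approximate agree within 1e-2 at n = 30/30
  withr::with_seed(7, {
    a <- stats::rnorm(30); b <- stats::rnorm(30, 0.3)
    approx <- rank_sum_less(a, b)$p_value
    exact_oracle <- stats::wilcox.test(a, b, alternative = "less",
                                       exact = TRUE)$p.value
    expect_lt(abs(approx - exact_oracle), 1e-2)
  })
})

test_that("shift detection: mutant-shorter alternative found in seeded replicates", {
  # mirrors the direction of the mono-nucleosome shift (153 vs 162 bp);
  # 20 replicates at n = 200/2000 keep the default run fast — the acceptance
  # suite runs the full-power version
  hits <- vapply(1:20, function(i) {
    withr::with_seed(400 + i, {
      a <- pmin(pmax(round(stats::rnorm(200, 153, 20)), 50), 400)
      b <- pmin(pmax(round(stats::rnorm(2000, 162, 20)), 50), 400)
      rank_sum_less(a, b)$p_value < 0.01
    })
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("classified SAM outputs are label-consistent", {
  cfg <- sim_config(seed = 23, n_fragments = 120, mutant_fraction = 0.4)
  sim <- simulate_read_pairs(cfg)
  fc <- classify_fragments(sim$records, cfg$variant)
  dir <- tempfile()
  paths <- write_classified_sam(sim$records, fc, dir,
                                stats::setNames(cfg$reference_length,
                                                cfg$variant$chrom))
  mut <- read_sam(paths["mutant"])
  expect_true(all(mut$qname %in% fc$fragment[fc$label == "mutant"]))
  nonmut <- read_sam(paths["non_mutant"])
  expect_true(all(nonmut$qname %in% fc$fragment[fc$label == "non_mutant"]))
  expect_equal(nrow(mut) + nrow(nonmut),
               2 * sum(fc$label %in% c("mutant", "non_mutant")))
})
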