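# Inclusion filter, two-group comparison, fold categories and the
# dual-baseline framework.

test_that("minimum-read filter boundary is inclusive at the threshold", {
  counts <- matrix(
    c(rep(99L, 4), 0L, 0L, 0L, 100L, rep(1000L, 4), rep(10L, 4)),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("g99", "g100", "GAPDH", "gLow"),
                    paste0("s", 1:4))
  )
  tse <- tseFromCounts(counts)
  fl <- filterMinReads(tse)
  expect_false(fl$included[fl$gene_id == "g99"])
  expect_identical(fl$reason[fl$gene_id == "g99"], "below_min_reads")
  expect_true(fl$included[fl$gene_id == "g100"])
})

test_that("convergent-overlap genes are excluded whatever their counts", {
  counts <- matrix(rep(c(1000000L, 5000L, 500L), 4), nrow = 3,
                   dimnames = list(c("gOv", "GAPDH", "gOk"),
                                   paste0("s", 1:4)))
  tse <- tseFromCounts(counts,
                       status = c("excluded_overlap", "counted", "counted"))
  fl <- filterMinReads(tse)
  expect_false(fl$included[fl$gene_id == "gOv"])
  expect_identical(fl$reason[fl$gene_id == "gOv"], "overlap")
})

test_that("signed folds follow the +r / -1/r convention", {
  norm <- rbind(
    up4 = c(0.04, 0.04, 0.01, 0.01),
    down7 = c(0.01, 0.01, 0.07, 0.07),
    flat = c(0.02, 0.02, 0.02, 0.02)
  )
  colnames(norm) <- paste0("s", 1:4)
  res <- compareGroups(norm, 1:2, 3:4)
  expect_equal(res$fold[res$gene_id == "up4"], 4)
  expect_equal(res$fold[res$gene_id == "down7"], -7)
  expect_equal(res$fold[res$gene_id == "flat"], 1)
  expect_equal(res$p[res$gene_id == "flat"], 1)  # zero variance, equal means
})

test_that("group comparison is antisymmetric and flags undefined folds", {
  set.seed(21)
  norm <- matrix(rlnorm(240, -4, 0.4), 40,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:6)))
  norm["g40", 4:6] <- 0  # zero B-group mean
  ab <- compareGroups(norm, 1:3, 4:6)
  ba <- compareGroups(norm, 4:6, 1:3)
  ok <- ab$gene_id != "g40"
  expect_equal(ab$fold[ok], -ba$fold[ok], tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_true(is.na(ab$fold[ab$gene_id == "g40"]))
  expect_identical(ab$flag[ab$gene_id == "g40"], "undefined_fold")
  expect_error(compareGroups(norm, 1, 2:3), "2 replicates")
})

test_that("fold categories match the published bin conventions", {
  expect_identical(categorizeFold(12), "10 to <30")
  expect_identical(categorizeFold(-45), "-(30 to <50)")
  expect_identical(categorizeFold(1), "<1.5")
  expect_identical(
    categorizeFold(c(1.5, 3, -3, 9.99, 30, 50, -80)),
    c("1.5 to <2", "2 to <4", "-(2 to <4)", "4 to <10", "30 to <50",
      ">=50", "-(>=50)")
  )
  expect_true(is.na(categorizeFold(NA_real_)))
})

test_that("the framework emits the dual-baseline contrast set", {
  cfg <- simConfig(seed = 6, total_reads_per_sample = 3000)
  gen <- generateGenomeAnnotation(cfg)
  aln <- simulateAlignments(gen$models, gen$truth, cfg)
  tse <- normalizeToHousekeeping(
    quantifyExperiment(gen$models, aln, gen$genome,
                       design = experimentDesign())
  )
  de <- runDEFramework(tse)
  expected <- c(
    "HL_T1_vs_T0", "HL_T1_vs_control_T1", "HL_T2.5_vs_T0",
    "HL_T2.5_vs_control_T2.5", "control_T1_vs_T0", "control_T2.5_vs_T0",
    "control_T2.5_vs_T1", "HLUV_T1_vs_T0", "HLUV_T1_vs_control_T1",
    "HLUV_T2.5_vs_T0", "HLUV_T2.5_vs_control_T2.5",
    "control_T0_cross_experiment"
  )
  expect_setequal(unique(de$contrast), expected)
  # the two control time courses each contribute their own contrasts
  expect_identical(sum(de$contrast == "control_T1_vs_T0" &
                         de$experiment == "HL_experiment") > 0, TRUE)

  # housekeeping genes: fold near 1, never significant
  hk <- de[de$gene_id %in% c("rrl_23S", "GAPDH"), ]
  expect_true(all(abs(hk$fold) < 1.3))
  expect_false(any(hk$significant))

  # no excluded gene is ever significant
  excl <- de[de$status == "excluded_overlap", ]
  expect_false(any(excl$significant))

  # alpha = 0 kills all significance
  de0 <- runDEFramework(tse, alpha = 0)
  expect_false(any(de0$significant))

  # a missing group drops its contrasts with a warning
  cd <- SummarizedExperiment::colData(tse)
  sub <- tse[, !(cd$experiment == "HL_experiment" &
                   cd$condition == "control" & cd$time == 1)]
  expect_warning(runDEFramework(sub), "skipping contrast")
})

test_that("a strong planted repression is recovered with correct sign", {
  cfg <- simConfig(seed = 8, total_reads_per_sample = 5000,
                   dispersion = 0.02)
  gen <- generateGenomeAnnotation(cfg)
  # force one well-expressed chloroplast gene to a 1/32 HL+UV effect
  mult <- gen$truth$multiplier
  cand <- grep("^cp_g", rownames(mult), value = TRUE)
  target <- cand[which.max(gen$truth$base_expression[cand])]
  uv_groups <- grep("HLUV_experiment_HLUV", colnames(mult), value = TRUE)
  gen$truth$multiplier[target, uv_groups] <- 1 / 32
  aln <- simulateAlignments(gen$models, gen$truth, cfg)
  tse <- normalizeToHousekeeping(
    quantifyExperiment(gen$models, aln, gen$genome,
                       design = experimentDesign())
  )
  de <- runDEFramework(tse)
  rec <- de[de$gene_id == target & de$contrast == "HLUV_T1_vs_control_T1", ]
  expect_true(rec$significant)
  expect_lt(rec$fold, -10)
})
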