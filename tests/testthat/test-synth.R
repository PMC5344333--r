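# Synthetic-data generator: determinism, planted features, read placement
# contracts, and the closed-form behaviour of the assay simulators.

test_that("identical config and seed give identical outputs", {
  cfg <- simConfig(seed = 42, total_reads_per_sample = 1000)
  g1 <- generateGenomeAnnotation(cfg)
  g2 <- generateGenomeAnnotation(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(as.data.frame(geneModels(g1$models)),
                   as.data.frame(geneModels(g2$models)))
  expect_identical(g1$truth$multiplier, g2$truth$multiplier)
  a1 <- simulateAlignments(g1$models, g1$truth, cfg)
  a2 <- simulateAlignments(g2$models, g2$truth, cfg)
  expect_identical(a1, a2)
})

test_that("planted features are recoverable and well-formed", {
  gen <- generateGenomeAnnotation(simConfig(seed = 1))
  ids <- geneIds(gen$models)
  # novel ORF absent from the annotation but recorded in the truth
  expect_false(gen$truth$novel_orfs$orf_id %in% ids)
  orf <- gen$truth$novel_orfs
  aa <- translateCDS(gen$genome, orf$contig, orf$start, orf$end, orf$strand)
  expect_identical(substr(aa, 1, 1), "M")
  expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  expect_identical(orf$n_codons,
                   as.integer((orf$end - orf$start + 1L) / 3L) - 1L)
  # truncated gene: extension a multiple of 3, true model ends at a stop
  tr <- gen$truth$truncated
  expect_identical(tr$extension_nt %% 3L, 0L)
  g <- geneModels(gen$models)
  i <- match(tr$gene_id, geneIds(gen$models))
  aa <- translateCDS(gen$genome, "chloroplast",
                     S4Vectors::mcols(g)$cds_start[i], tr$true_cds_end)
  expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  # all annotated CDSs are in-frame and stop-terminated in the true model
  m <- S4Vectors::mcols(g)
  for (j in which(!is.na(m$cds_start) & m$gene_id != tr$gene_id)) {
    expect_identical((m$cds_end[j] - m$cds_start[j] + 1L) %% 3L, 0L,
                     info = m$gene_id[j])
    aa <- translateCDS(gen$genome,
                       as.character(GenomicRanges::seqnames(g)[j]),
                       m$cds_start[j], m$cds_end[j],
                       as.character(GenomicRanges::strand(g)[j]))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)),
                 info = m$gene_id[j])
  }
  # planted structural cases exist
  expect_length(gen$truth$special$convergent_pair, 2L)
  expect_length(gen$truth$special$identical_pair, 2L)
})

test_that("housekeeping genes have true fold 1 in every comparison", {
  gen <- generateGenomeAnnotation(simConfig(seed = 3))
  mult <- gen$truth$multiplier
  for (hk in gen$truth$housekeeping) {
    expect_true(all(mult[hk, ] == 1), info = hk)
  }
  grp <- colnames(mult)
  for (a in grp) for (b in grp) {
    expect_identical(trueFold(gen$truth, "rrl_23S", a, b), 1)
  }
})

test_that("infeasible packing and degenerate configs behave as specified", {
  expect_error(
    generateGenomeAnnotation(simConfig(seed = 1, chloroplast_length = 3000)),
    "infeasible packing"
  )
  gen <- generateGenomeAnnotation(simConfig(seed = 1, n_nuclear_genes = 0))
  m <- S4Vectors::mcols(geneModels(gen$models))
  expect_true(all(m$compartment == "chloroplast"))
  w <- deriveCountWindows(gen$models)
  expect_false(any(S4Vectors::mcols(w)$compartment == "nuclear"))
})

test_that("read placement honours compartment share and 3' bias", {
  design1 <- experimentDesign()[1, ]
  # boundary: everything chloroplast
  cfg <- simConfig(seed = 5, total_reads_per_sample = 2000,
                   chloroplast_read_fraction = 1)
  gen <- generateGenomeAnnotation(cfg)
  aln <- simulateAlignments(gen$models, gen$truth, cfg, design1)
  expect_true(all(aln$reference == "chloroplast"))
  # chloroplast share within 3 binomial SE of 0.5 at 1e5 reads
  cfg <- simConfig(seed = 7, total_reads_per_sample = 100000,
                   dispersion = 0, hk_dispersion = 0)
  gen <- generateGenomeAnnotation(cfg)
  aln <- simulateAlignments(gen$models, gen$truth, cfg, design1)
  frac <- mean(aln$reference == "chloroplast")
  se <- sqrt(0.25 / nrow(aln))
  expect_lt(abs(frac - 0.5), 3 * se)
  # full 3' bias: nuclear read starts within 8 read lengths of the end
  cfg <- simConfig(seed = 9, total_reads_per_sample = 20000,
                   three_prime_bias = 1)
  gen <- generateGenomeAnnotation(cfg)
  aln <- simulateAlignments(gen$models, gen$truth, cfg, design1)
  g <- geneModels(gen$models)
  m <- S4Vectors::mcols(g)
  for (i in which(m$compartment == "nuclear" &
                    lengths(m$exons) == 1L &
                    as.character(GenomicRanges::strand(g)) == "+")) {
    span <- c(GenomicRanges::start(g)[i], GenomicRanges::end(g)[i])
    rr <- aln[aln$reference == "nuclear" & aln$start >= span[1] &
                aln$end <= span[2], ]
    if (nrow(rr) == 0) next
    expect_true(all(rr$start >= span[2] - 400L + 1L), info = m$gene_id[i])
  }
  # zero depth: empty table, not an error
  cfg0 <- simConfig(seed = 1, total_reads_per_sample = 0)
  gen0 <- generateGenomeAnnotation(cfg0)
  expect_identical(
    nrow(simulateAlignments(gen0$models, gen0$truth, cfg0, design1)), 0L
  )
})

test_that("cytometry simulator keeps beads fixed and follows trajectories", {
  cfg <- simConfig(seed = 2)
  ev <- simulateFCM(defaultFCMParams(), cfg)
  beads <- ev[ev$population == "bead", ]
  bead_means <- tapply(beads$fals, beads$sample_id, mean)
  expect_true(all(abs(bead_means - cfg@fcm_bead_mean) <
                    3 * cfg@fcm_bead_mean * cfg@fcm_sdlog /
                      sqrt(cfg@fcm_events_bead)))
  expect_error(simulateFCM(defaultFCMParams(), cfg, sdlog = 0),
               "positive")
  expect_identical(
    nrow(simulateFCM(defaultFCMParams(), cfg, n_cells = 0, n_beads = 0)), 0L
  )
})

test_that("growth simulator is exact in the noiseless closed form", {
  s <- simulateGrowth(c(`100` = log(2)), times = 0:3, noise = 0,
                      replicates = 1, n_transfers = 2)
  one <- s[s$transfer == 1, ]
  expect_equal(one$fluorescence[-1] / one$fluorescence[-4], rep(2, 3))
  expect_error(simulateGrowth(c(`100` = 1), times = c(2, 1), noise = 0),
               "increasing")
})

test_that("qPCR simulator encodes folds and dilutions as 2-fold chemistry", {
  tf <- data.frame(target = "X", condition = "HLUV", time = 1, fold = 32)
  plate <- simulateQPCR(tf, sd_ct = 0)
  w <- plate@wells
  dct <- function(cond, tt) {
    tg <- w$ct[w$target == "X" & w$condition == cond & w$time == tt]
    en <- w$ct[w$target == "Actin" & w$condition == cond & w$time == tt]
    mean(tg - en)
  }
  # 32-fold target sits 5 cycles below the calibrator after correction
  expect_equal(dct("control", 0) - dct("HLUV", 1), 5)
  # 10-fold dilution spacing is log2(10) cycles
  d <- plate@dilution[plate@dilution$target == "X", ]
  expect_equal(diff(d$ct), rep(log2(10), nrow(d) - 1))
  expect_error(simulateQPCR(tf, efficiency = 0), "efficiency")
  expect_error(simulateQPCR(tf, efficiency = 1.2), "efficiency")
})
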