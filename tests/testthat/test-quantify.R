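# Counting windows, exclusion rules, read assignment and housekeeping
# normalization.

test_that("counting windows follow the 403-nt terminal-exon rule", {
  w <- deriveCountWindows(tinyModels())
  m <- S4Vectors::mcols(w)
  win <- function(id) {
    i <- match(id, m$gene_id)
    c(GenomicRanges::start(w)[i], GenomicRanges::end(w)[i])
  }
  expect_identical(win("cpA"), c(100L, 600L))        # full span
  expect_identical(m$basis[match("cpA", m$gene_id)], "full_span")
  expect_identical(win("plusG"), c(1598L, 2000L))    # last 403 nt
  expect_identical(diff(win("plusG")) + 1L, 403L)
  expect_identical(win("minusG"), c(3001L, 3403L))   # mirror case
  expect_identical(win("shortG"), c(5701L, 6000L))   # clipped to 300-nt exon
  expect_identical(m$basis[match("shortG", m$gene_id)], "terminal_403")
})

test_that("gene without exons is an error", {
  gm <- tinyModels()
  g <- geneModels(gm)
  m <- S4Vectors::mcols(g)
  m$exons[[1]] <- IRanges::IRanges()
  S4Vectors::mcols(g) <- m
  bad <- gm
  methods::slot(bad, "genes", check = FALSE) <- g  # bypass validity
  expect_error(deriveCountWindows(bad), "without exons")
})

test_that("only convergent opposite-strand window overlaps are excluded", {
  gm <- tinyModels()
  fl <- flagExclusions(gm)
  st <- setNames(fl$status, fl$gene_id)
  expect_identical(unname(st[c("convP", "convM")]),
                   rep("excluded_overlap", 2))
  expect_true(all(st[c("cpA", "plusG", "minusG", "shortG")] == "counted"))

  # same-strand overlapping windows are NOT excluded
  g <- geneModels(gm)
  GenomicRanges::strand(g)[match("convM", geneIds(gm))] <- "+"
  fl2 <- flagExclusions(GeneModelSet(g))
  expect_true(all(fl2$status[fl2$gene_id %in% c("convP", "convM")] ==
                    "counted"))
})

test_that("identical-window genes are merged into one joint record", {
  cfg <- simConfig(seed = 4, total_reads_per_sample = 2000)
  gen <- generateGenomeAnnotation(cfg)
  fl <- flagExclusions(gen$models, gen$genome)
  pair <- gen$truth$special$identical_pair
  expect_true(all(fl$status[fl$gene_id %in% pair] == "merged_identical"))
  joint <- paste(sort(pair), collapse = "+")
  aln <- simulateAlignments(gen$models, gen$truth, cfg,
                            experimentDesign()[1:3, ])
  tse <- quantifyExperiment(gen$models, aln, gen$genome)
  expect_true(joint %in% rownames(tse))
  expect_false(any(pair %in% rownames(tse)))
  # joint record carries the sum of both members' window counts
  w <- deriveCountWindows(gen$models)
  raw <- countReads(aln, w)
  expect_identical(SummarizedExperiment::assay(tse, "counts")[joint, ],
                   raw[pair[1], ] + raw[pair[2], ])
})

test_that("read assignment matches the brute-force oracle", {
  w <- deriveCountWindows(tinyModels())
  # empty table -> all-zero matrix with no samples
  empty <- countReads(alnRow(1, 0)[0, ], w)
  expect_true(all(empty == 0L))
  # single chloroplast read inside the span
  one <- countReads(alnRow(150, 200, reference = "chloroplast"), w)
  expect_identical(one["cpA", "s1"], 1L)
  # 10-read fixture against exhaustive enumeration
  aln10 <- do.call(rbind, list(
    alnRow(1590, 1639), alnRow(1990, 2039), alnRow(2500, 2549),
    alnRow(3001, 3050), alnRow(3390, 3439), alnRow(5650, 5699),
    alnRow(5690, 5739), alnRow(100, 149, reference = "chloroplast"),
    alnRow(580, 629, reference = "chloroplast"),
    alnRow(650, 699, reference = "chloroplast")
  ))
  expect_identical(countReads(aln10, w), bruteCount(aln10, w))
  # malformed interval names the read
  bad <- alnRow(50, 40, read_id = "bad_read")
  expect_error(countReads(bad, w), "bad_read")
})

test_that("multi-window reads go to the greatest overlap; ties drop", {
  windows <- GenomicRanges::GRanges(
    "ctg", IRanges::IRanges(c(100, 300), c(250, 450)), "+"
  )
  S4Vectors::mcols(windows) <- S4Vectors::DataFrame(
    gene_id = c("gA", "gB"), compartment = "nuclear",
    housekeeping_role = "none", basis = "terminal_403"
  )
  # overlaps gA by 31, gB by 20 -> gA
  aln <- alnRow(220, 319, reference = "ctg")
  expect_identical(countReads(aln, windows)["gA", "s1"], 1L)
  expect_identical(countReads(aln, windows)["gB", "s1"], 0L)
  # symmetric overlap (26 / 26) -> dropped entirely
  tie <- alnRow(225, 325, reference = "ctg")
  expect_true(all(countReads(tie, windows) == 0L))
})

test_that("counting ignores recorded strand entirely", {
  set.seed(77)
  fx <- randomCountingFixture(400)
  flipped <- fx$alignments
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  expect_identical(countReads(fx$alignments, fx$windows),
                   countReads(flipped, fx$windows))
})

test_that("housekeeping normalization is exact and scale invariant", {
  counts <- matrix(
    c(500L, 100000L, 40L,
      250L,  50000L, 20L),
    nrow = 3,
    dimnames = list(c("geneX", "GAPDH", "geneY"), c("s1", "s2"))
  )
  tse <- tseFromCounts(counts)
  norm <- normalizedCounts(tse)
  expect_identical(norm["geneX", "s1"], 0.005)
  expect_identical(unname(norm["GAPDH", ]), c(1, 1))  # self-normalization
  # multiplying one sample's counts by 10 leaves its ratios unchanged
  scaled <- counts
  scaled[, "s2"] <- scaled[, "s2"] * 10L
  norm2 <- normalizedCounts(tseFromCounts(scaled))
  expect_identical(norm2[, "s2"], norm[, "s2"])
  # zero housekeeping count is a hard error naming the sample
  broken <- counts
  broken["GAPDH", "s2"] <- 0L
  expect_error(tseFromCounts(broken), "s2")
})

test_that("duplicated 23S copies are pooled as one denominator", {
  counts <- matrix(c(300L, 4000L, 6000L), nrow = 3,
                   dimnames = list(c("cpX", "rrl_23S_1", "rrl_23S_2"),
                                   "s1"))
  rd <- S4Vectors::DataFrame(
    gene_id = rownames(counts), compartment = "chloroplast",
    housekeeping_role = c("none", "chloro_norm", "chloro_norm"),
    status = "counted", row.names = rownames(counts)
  )
  x <- new("TagSeqExperiment", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd,
    colData = S4Vectors::DataFrame(sample_id = "s1", row.names = "s1")
  ))
  x <- normalizeToHousekeeping(x)
  expect_identical(normalizedCounts(x)["cpX", "s1"], 300 / 10000)
  expect_identical(unname(housekeepingCounts(x)$chloroplast), 10000)
})

test_that("assigned counts never exceed the number of reads", {
  set.seed(31)
  for (rep in 1:5) {
    fx <- randomCountingFixture(300)
    expect_lte(sum(countReads(fx$alignments, fx$windows)), 300L)
  }
})
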