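# Coverage computation, CDS extension and novel-ORF discovery.

test_that("coverage equals the per-base membership count", {
  aln <- alnRow(10, 59, reference = "ctg")
  cov <- computeCoverage(aln, "ctg", 100)
  expect_identical(cov, c(rep(0L, 9), rep(1L, 50), rep(0L, 41)))
  two <- rbind(aln, aln)
  expect_identical(computeCoverage(two, "ctg", 100)[10:59], rep(2L, 50))
  set.seed(19)
  st <- sample.int(450, 100, replace = TRUE)
  many <- data.frame(read_id = sprintf("r%d", 1:100), reference = "ctg",
                     start = st, end = st + 49L, strand = "+",
                     sample_id = "s1")
  expect_identical(computeCoverage(many, "ctg", 500),
                   bruteCoverage(many, "ctg", 500))
  off <- alnRow(490, 540, reference = "ctg")
  expect_error(computeCoverage(off, "ctg", 500), "outside")
})

test_that("CDS extension recovers the planted 90-nt truncation exactly", {
  cfg <- simConfig(seed = 1, total_reads_per_sample = 3000)
  gen <- generateGenomeAnnotation(cfg)
  aln <- simulateAlignments(gen$models, gen$truth, cfg)
  cov <- computeCoverage(aln, "chloroplast", cfg@chloroplast_length)
  tr <- gen$truth$truncated
  r <- extendCDS(gen$models, tr$gene_id, cov, gen$genome)
  expect_true(r$extended)
  expect_identical(r$extension_nt, tr$extension_nt)
  m <- S4Vectors::mcols(geneModels(r$models))
  i <- match(tr$gene_id, m$gene_id)
  expect_identical(m$cds_end[i], tr$true_cds_end)
  # extended model translates cleanly with a single terminal stop
  aa <- translateCDS(gen$genome, "chloroplast", m$cds_start[i],
                     m$cds_end[i])
  expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  # idempotence: a second pass is a fixed point
  r2 <- extendCDS(r$models, tr$gene_id, cov, gen$genome)
  expect_false(r2$extended)
  expect_identical(r2$flag, "already_stop")
})

test_that("extension is gated by coverage and never fires on stop-ended CDS", {
  cfg <- simConfig(seed = 1, total_reads_per_sample = 3000)
  gen <- generateGenomeAnnotation(cfg)
  tr <- gen$truth$truncated
  zero <- integer(cfg@chloroplast_length)
  r <- extendCDS(gen$models, tr$gene_id, zero, gen$genome, min_depth = 1)
  expect_false(r$extended)
  expect_identical(r$flag, "unsupported")
  # a stop-ended gene with zero downstream coverage stays unchanged
  other <- setdiff(geneIds(gen$models)[
    S4Vectors::mcols(geneModels(gen$models))$gene_type == "protein"
  ], tr$gene_id)[1]
  r2 <- extendCDS(gen$models, other, zero, gen$genome)
  expect_identical(r2$flag, "already_stop")
  expect_identical(
    as.data.frame(geneModels(r2$models)),
    as.data.frame(geneModels(gen$models))
  )
})

test_that("minus-strand CDS extension works on a hand-built gene", {
  # gene on (-): revcomp(ATG (20 non-stop codons) TAA); annotate the CDS
  # 9 nt short of the true start-side (reference) end
  set.seed(5)
  inner <- paste(
    setdiff(as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
      paste0), c("A","C","G","T"), paste0)),
      c("TAA","TAG","TGA"))[sample(55, 20)], collapse = "")
  cds_fwd <- paste0("ATG", inner, "TAA")  # 66 nt
  genome_chr <- paste0(strrep("C", 30),
                       as.character(Biostrings::reverseComplement(
                         Biostrings::DNAString(cds_fwd))),
                       strrep("C", 30))
  genome <- Biostrings::DNAStringSet(c(ctg = genome_chr))
  true_start <- 31L
  true_end <- 31L + 66L - 1L
  ann_start <- true_start + 9L   # truncated at the biological 3' side
  gr <- GenomicRanges::GRanges("ctg",
    IRanges::IRanges(ann_start, true_end), "-",
    seqlengths = c(ctg = nchar(genome_chr)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    gene_id = "gM", compartment = "chloroplast", gene_type = "protein",
    housekeeping_role = "chloro_norm",
    cds_start = ann_start, cds_end = true_end,
    exons = IRanges::IRangesList(IRanges::IRanges(ann_start, true_end))
  )
  models <- GeneModelSet(gr)
  cov <- rep(10L, nchar(genome_chr))
  r <- extendCDS(models, "gM", cov, genome)
  expect_true(r$extended)
  expect_identical(r$extension_nt, 9L)
  m <- S4Vectors::mcols(geneModels(r$models))
  expect_identical(m$cds_start[1], true_start)
})

test_that("novel ORF discovery finds the planted ORF at exact coordinates", {
  cfg <- simConfig(seed = 1, total_reads_per_sample = 3000)
  gen <- generateGenomeAnnotation(cfg)
  aln <- simulateAlignments(gen$models, gen$truth, cfg)
  cov <- computeCoverage(aln, "chloroplast", cfg@chloroplast_length)
  orfs <- detectNovelORFs(cov, gen$models, gen$genome, "chloroplast")
  planted <- gen$truth$novel_orfs
  hit <- orfs$start == planted$start & orfs$end == planted$end &
    orfs$strand == planted$strand
  expect_true(any(hit))
  expect_identical(orfs$n_codons[hit][1], planted$n_codons)
  # longest ORF of its interval is reported first
  expect_identical(orfs$start[1], planted$start)
  # no call overlaps an annotated gene
  g <- geneModels(gen$models)
  cp <- g[as.character(GenomicRanges::seqnames(g)) == "chloroplast"]
  for (k in seq_len(nrow(orfs))) {
    expect_false(any(orfs$start[k] <= GenomicRanges::end(cp) &
                       orfs$end[k] >= GenomicRanges::start(cp)))
  }

  # coverage gate: zeroing the ORF's coverage removes the call
  cov0 <- cov
  cov0[planted$start:planted$end] <- 0L
  orfs0 <- detectNovelORFs(cov0, gen$models, gen$genome, "chloroplast")
  expect_false(any(orfs0$start == planted$start &
                     orfs0$end == planted$end))
  # length gate: a threshold above the planted length empties the list
  expect_identical(
    nrow(detectNovelORFs(cov, gen$models, gen$genome, "chloroplast",
                         min_codons = planted$n_codons + 1L)), 0L
  )
  # monotonicity: raising either threshold never adds calls
  loose <- detectNovelORFs(cov, gen$models, gen$genome, "chloroplast",
                           min_codons = 50, min_depth = 2)
  strict_depth <- detectNovelORFs(cov, gen$models, gen$genome,
                                  "chloroplast", min_codons = 50,
                                  min_depth = 20)
  strict_len <- detectNovelORFs(cov, gen$models, gen$genome, "chloroplast",
                                min_codons = 200, min_depth = 2)
  key <- function(d) paste(d$start, d$end, d$strand)
  expect_true(all(key(strict_depth) %in% key(loose)))
  expect_true(all(key(strict_len) %in% key(loose)))
})

test_that("refineAnnotation reports extensions and is idempotent", {
  cfg <- simConfig(seed = 2, total_reads_per_sample = 3000)
  gen <- generateGenomeAnnotation(cfg)
  aln <- simulateAlignments(gen$models, gen$truth, cfg)
  r1 <- refineAnnotation(gen$models, aln, gen$genome)
  expect_identical(sum(r1$report$extended), 1L)
  expect_identical(r1$report$extension_nt[r1$report$extended],
                   gen$truth$truncated$extension_nt)
  r2 <- refineAnnotation(r1$models, aln, gen$genome)
  expect_identical(sum(r2$report$extended), 0L)
  expect_identical(as.data.frame(geneModels(r2$models)),
                   as.data.frame(geneModels(r1$models)))
})

test_that("the improved chloroplast inventory totals 92 genes", {
  inv <- improvedGeneInventory()
  expect_identical(attr(inv, "total"), 92L)
  expect_identical(inv$n[inv$gene_type == "protein"], 60L)
  expect_identical(inv$n[inv$gene_type == "tRNA"], 26L)
  expect_identical(inv$n[inv$gene_type == "rRNA"], 6L)
})
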