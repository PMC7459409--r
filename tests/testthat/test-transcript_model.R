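test_that("degenerate UTRs and model invariants are handled", {
  m <- transcript_models("t1", "g1", "ATGAAACCCTAA", 0, 12)
  expect_equal(utr5_length(m), 0L)
  expect_equal(utr3_length(m), 0L)
  expect_error(transcript_models("t1", "g1", "ATGTAA", 0, 5),
               "CDS length")
  expect_error(transcript_models("t1", "g1", "ATGTAA", 3, 3), "invalid CDS")
  expect_error(transcript_models("t1", "g1", "ATGXAATAA", 0, 9),
               "characters outside")
  expect_error(transcript_models(c("t1", "t1"), "g1",
                                 c("ATGTAA", "ATGTAA"), 0, 6),
               "duplicated")
})

make_gtf_fixture <- function(dir) {
  # transcript assembled by hand: 20 nt 5'UTR, 60 nt CDS (incl stop),
  # 140 nt 3'UTR; placed on the minus strand over two exons
  set.seed(11)
  utr5 <- random_seq(20)
  cds <- paste0("ATG", paste(rep("GCT", 18), collapse = ""), "TAA")
  utr3 <- random_seq(140)
  tx <- paste0(utr5, cds, utr3)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  chr <- paste0(random_seq(100), substr(rc, 1, 120), random_seq(80),
                substr(rc, 121, 220), random_seq(200))
  fa <- file.path(dir, "genome.fa")
  writeLines(c(">chr1", chr), fa)
  attr_of <- function(tx_id) sprintf(
    'gene_id "gm"; transcript_id "%s";', tx_id)
  row <- function(type, s, e, a) sprintf(
    "chr1\ttest\t%s\t%d\t%d\t.\t-\t.\t%s", type, s, e, a)
  gtf <- file.path(dir, "anno.gtf")
  writeLines(c(row("exon", 101, 220, attr_of("tm")),
               row("exon", 301, 400, attr_of("tm")),
               row("CDS", 324, 380, attr_of("tm")),
               row("stop_codon", 321, 323, attr_of("tm"))), gtf)
  list(gtf = gtf, fa = fa, tx = tx)
}

test_that("minus-strand two-exon GTF splicing matches the hand-spliced oracle", {
  dir <- withr::local_tempdir()
  fx <- make_gtf_fixture(dir)
  models <- read_transcriptome_gtf(fx$gtf, fx$fa)
  expect_equal(nrow(models), 1L)
  expect_equal(models$sequence, fx$tx)
  expect_equal(models$cds_start, 20L)
  expect_equal(models$cds_end, 80L)
  expect_equal(models$genomic_stop, 321)
  expect_equal(models$strand, "-")
})

test_that("TSV + transcript FASTA yields models identical to the GTF path", {
  dir <- withr::local_tempdir()
  fx <- make_gtf_fixture(dir)
  from_gtf <- read_transcriptome_gtf(fx$gtf, fx$fa)
  tsv <- file.path(dir, "models.tsv")
  fa <- file.path(dir, "tx.fa")
  write.table(data.frame(transcript_id = "tm", gene_id = "gm",
                         cds_start = 20L, cds_end = 80L),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(">tm", fx$tx), fa)
  from_tsv <- read_transcript_table(tsv, fa)
  shared <- c("transcript_id", "gene_id", "sequence", "length",
              "cds_start", "cds_end")
  expect_equal(from_tsv[, shared], from_gtf[, shared],
               ignore_attr = TRUE)
})

test_that("round-trip through the TSV + FASTA dump reproduces the models", {
  dir <- withr::local_tempdir()
  cc <- shared_sim()
  models <- cc$sim$models[1:20, ]
  class(models) <- class(cc$sim$models)
  tsv <- file.path(dir, "m.tsv"); fa <- file.path(dir, "m.fa")
  write_transcript_models(models, tsv, fa)
  back <- read_transcript_table(tsv, fa)
  rownames(models) <- NULL
  expect_equal(as.data.frame(back)[, names(back) != "genomic_stop"],
               as.data.frame(models)[, names(models) != "genomic_stop"])
})

test_that("representative isoform has the most distal stop, with tie-breaks", {
  m <- transcript_models(
    c("tA", "tB", "tC", "tD", "tE", "tF"),
    c("g1", "g1", "g2", "g2", "g3", "g3"),
    rep(paste0(strrep("A", 10), "ATGGCTGCTTAA", strrep("A", 40)), 6),
    rep(10, 6), rep(22, 6),
    genomic_stop = c(1000, 1300, 5000, 5400, 2000, 2000),
    strand = c("+", "+", "-", "-", "+", "+"))
  rep_iso <- select_representative_isoform(m)
  expect_equal(rep_iso$transcript_id[rep_iso$gene_id == "g1"], "tB")
  # minus strand: distal stop is the genomically smaller coordinate
  expect_equal(rep_iso$transcript_id[rep_iso$gene_id == "g2"], "tC")
  # equal stop: falls back to lexicographically smallest id (equal 3'UTRs)
  expect_equal(rep_iso$transcript_id[rep_iso$gene_id == "g3"], "tE")

  # equal stop, unequal 3'UTR: longer 3'UTR wins
  m2 <- transcript_models(
    c("tX", "tY"), c("g4", "g4"),
    c(paste0("ATGGCTTAA", strrep("A", 200)),
      paste0("ATGGCTTAA", strrep("A", 400))),
    c(0, 0), c(9, 9), genomic_stop = c(7000, 7000))
  expect_equal(select_representative_isoform(m2)$transcript_id, "tY")
  expect_error(select_representative_isoform(m2[0, ]), "no isoforms")
})

test_that("loader skips CDS-less transcripts and errors on ID mismatch", {
  dir <- withr::local_tempdir()
  fx <- make_gtf_fixture(dir)
  # append a transcript with exons but no CDS
  extra <- sprintf(
    "chr1\ttest\texon\t10\t60\t.\t+\t.\tgene_id \"gx\"; transcript_id \"tx\";")
  writeLines(c(readLines(fx$gtf), extra), fx$gtf)
  expect_warning(models <- read_transcriptome_gtf(fx$gtf, fx$fa),
                 "without a usable CDS")
  expect_equal(models$transcript_id, "tm")

  tsv <- file.path(dir, "bad.tsv")
  write.table(data.frame(transcript_id = "missing", gene_id = "g",
                         cds_start = 0L, cds_end = 6L),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "tx.fa")
  writeLines(c(">tm", fx$tx), fa)
  expect_error(read_transcript_table(tsv, fa), "missing from FASTA")
})
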