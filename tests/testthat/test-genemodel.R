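# Gene-model IO and projection of variants onto proteins.

test_that("genePred fixtures round-trip, including multi-exon and empty files", {
  gp <- tempfile(fileext = ".genepred")
  writeLines(paste("TXA", "chr1", "+", 10, 100, 10, 100, 2,
                   "10,60,", "40,100,", 0, "GENEA", sep = "\t"), gp)
  txs <- read_gene_model(gp, "genePred")
  expect_length(txs, 1)
  expect_equal(txs[[1]]$exon_starts, c(10L, 60L))
  expect_equal(txs[[1]]$exon_ends, c(40L, 100L))
  expect_equal(txs[[1]]$cds_start, 10L)
  expect_equal(txs[[1]]$cds_end, 100L)
  expect_equal(txs[[1]]$gene, "GENEA")

  writeLines(character(), gp)
  expect_length(read_gene_model(gp, "genePred"), 0)

  writeLines("TXB\tchr1\t+\tnot-enough-columns", gp)
  expect_error(read_gene_model(gp, "genePred"), "line 1")
})

test_that("a minimal GTF subset yields the same transcript as genePred", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", 11, 40, ".", "+", ".",
          'gene_id "GENEA"; transcript_id "TXA";', sep = "\t"),
    paste("chr1", "src", "exon", 61, 100, ".", "+", ".",
          'gene_id "GENEA"; transcript_id "TXA";', sep = "\t"),
    paste("chr1", "src", "CDS", 11, 40, ".", "+", ".",
          'gene_id "GENEA"; transcript_id "TXA";', sep = "\t"),
    paste("chr1", "src", "CDS", 61, 100, ".", "+", ".",
          'gene_id "GENEA"; transcript_id "TXA";', sep = "\t")), gtf)
  txs <- read_gene_model(gtf, "gtf")
  expect_length(txs, 1)
  expect_equal(txs[[1]]$exon_starts, c(10L, 60L))
  expect_equal(txs[[1]]$exon_ends, c(40L, 100L))
  expect_equal(txs[[1]]$cds_start, 10L)
})

test_that("minus-strand transcripts translate as the reverse complement", {
  # 9-codon toy CDS, translated by an independent route
  cds <- "ATGGATTGGAAACCCGGGTTTCACTAA"
  expected <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  expected <- sub("\\*$", "", expected)
  for (strand in c("+", "-")) {
    g <- toy_gene(cds, strand = strand)
    expect_equal(transcript_protein(g$tx, g$genome)$protein, expected,
                 info = paste("strand", strand))
  }
  # property: random CDS on random strands, with and without introns
  set.seed(42)
  for (i in 1:20) {
    prot <- paste0("M", rand_aa(sample(20:60, 1)))
    cds <- cds_for_protein(prot)
    g <- toy_gene(cds, strand = sample(c("+", "-"), 1),
                  intron = if (i %% 2) "GTAAGTCCCCCCAG" else NULL,
                  intron_after = if (i %% 2) sample(5:(nchar(cds) - 5), 1)
                                 else NULL)
    expect_equal(transcript_protein(g$tx, g$genome)$protein, prot)
  }
})

test_that("VCF reading decomposes multi-allelics and validates REF", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tG\t.\t.\t.",
               "chr1\t200\trs1\tC\tA,T\t.\t.\t.",
               "chr1\t300\t.\tACGT\tA\t.\t.\t."), vcf)
  v <- read_variants(vcf)
  expect_equal(nrow(v), 4)              # one row per ALT allele
  expect_equal(v$alt[2:3], c("A", "T"))
  expect_equal(nchar(v$ref[4]) - nchar(v$alt[4]), 3)  # 3-nt deletion
  expect_equal(v$pos, c(100L, 200L, 200L, 300L))

  genome <- c(chr1 = strrep("T", 400))
  expect_error(read_variants(vcf, genome), "REF mismatch")
})

test_that("SNVs project to missense changes with the right residue", {
  # protein with Asp at residue 387; GAT -> GGT gives Asp387Gly
  prot <- paste0("M", strrep("A", 385), "D", strrep("K", 13))
  g <- toy_gene(cds_for_protein(prot))
  gpos <- g$tx$cds_start + 3L * 386L + 2L  # second base of codon 387, 1-based
  cc <- apply_variant(g$tx, g$genome, snv(gpos, "A", "G"))
  expect_s3_class(cc, "coding_change")
  expect_equal(cc$variant_class, "missense")
  expect_equal(cc$first_changed_aa, 387L)
  expect_equal(substr(cc$wild_protein, 387, 387), "D")
  expect_equal(substr(cc$mutant_protein, 387, 387), "G")
  expect_equal(cc$protein_len_mut, cc$protein_len_wild)
})

test_that("a variant whose ALT equals REF reproduces the wild protein", {
  g <- toy_gene(cds_for_protein(paste0("M", rand_aa(50))))
  p <- g$tx$cds_start + 10L
  b <- substr(g$genome, p, p)
  cc <- apply_variant(g$tx, g$genome, snv(p, b, b))
  expect_equal(cc$variant_class, "synonymous")
  expect_identical(cc$wild_protein, cc$mutant_protein)
})

test_that("a 1-nt insertion causes a frameshift read through to the next stop", {
  lead <- "GGGGGGGGGG"
  cds <- "ATGAAAGATGATGATTGCTGCTGCTAA"
  tail <- "TTTCACTAAGGGCCC"
  genome <- c(chrT = paste0(lead, cds, tail))
  tx <- transcript("TX1", "chrT", "+", 10L, 10L + nchar(cds),
                   10L, 10L + nchar(cds))
  # insert A after the first base of codon 5 (CDS position 13)
  anchor <- 10L + 13L
  b <- substr(genome[["chrT"]], anchor, anchor)
  cc <- apply_variant(tx, genome, snv(anchor, b, paste0(b, "A")))
  expect_equal(cc$variant_class, "frameshift")
  expect_equal(cc$wild_protein, "MKDDDCCC")
  expect_equal(cc$mutant_protein, "MKDDELLLLISLRA")  # hand-translated frame
  expect_equal(cc$first_changed_aa, 5L)
})

test_that("stop gains truncate and stop losses extend the mutant protein", {
  prot <- paste0("M", rand_aa(98))
  g <- toy_gene(cds_for_protein(prot))
  # put a TAA in codon 40: replace codon with TAA via a 3-nt MNV
  cpos <- g$tx$cds_start + 3L * 39L + 1L
  ref3 <- substr(g$genome, cpos, cpos + 2)
  cc <- apply_variant(g$tx, g$genome, snv(cpos, ref3, "TAA"))
  expect_equal(cc$variant_class, "stop_gain")
  expect_equal(cc$protein_len_mut, 39L)
  expect_false(grepl("*", cc$mutant_protein, fixed = TRUE))

  # destroy the stop codon TAA -> CAA
  spos <- g$tx$cds_end - 2L
  cc2 <- apply_variant(g$tx, g$genome, snv(spos, "T", "C"))
  expect_equal(cc2$variant_class, "stop_loss")
  expect_gt(cc2$protein_len_mut, cc2$protein_len_wild)
})

test_that("in-frame indels shift protein length by the codon count", {
  set.seed(7)
  for (k in c(1L, 2L, 4L)) {
    prot <- paste0("M", rand_aa(80))
    g <- toy_gene(cds_for_protein(prot))
    a <- g$tx$cds_start + 30L            # 1-based anchor base within CDS
    block <- substring(g$genome, a + 1L, a + 3L * k)
    ref1 <- substr(g$genome, a, a)
    del <- apply_variant(g$tx, g$genome,
                         snv(a, paste0(ref1, block), ref1))
    expect_equal(del$variant_class, "inframe_deletion")
    expect_equal(del$protein_len_wild - del$protein_len_mut, k)
    ins <- apply_variant(g$tx, g$genome,
                         snv(a, ref1, paste0(ref1, strrep("GCT", k))))
    expect_equal(ins$variant_class, "inframe_insertion")
    expect_equal(ins$protein_len_mut - ins$protein_len_wild, k)
  }
})

test_that("non-coding, oversized and splice-spanning variants are signalled", {
  cds <- cds_for_protein(paste0("M", rand_aa(60)))
  g <- toy_gene(cds, intron = "GTAAGTCCCCCCAG", intron_after = 31L)
  expect_s3_class(apply_variant(g$tx, g$genome, snv(3L, "G", "A")),
                  "not_coding")
  big <- apply_variant(g$tx, g$genome,
                       snv(g$tx$cds_start + 10L, "X",
                           paste(rep("A", 62), collapse = "")))
  expect_s3_class(big, "unsupported_variant")
  # deletion crossing the intron boundary
  jpos <- g$tx$cds_start + 30L  # 1-based, last exon-1 base is cds_start+31
  ref <- substring(g$genome, jpos, jpos + 5L)
  expect_s3_class(apply_variant(g$tx, g$genome,
                                snv(jpos, ref, substr(ref, 1, 1))),
                  "unsupported_variant")
})

test_that("training strata follow the synonymous and FR/SC/SD exclusions", {
  expect_equal(classify_for_training(fake_cc("MAD", "MAV")), "core")
  expect_equal(classify_for_training(fake_cc("MAD", "MAD",
                                             class = "synonymous",
                                             first = 0)), "excluded_syn")
  for (cls in c("frameshift", "stop_gain", "stop_loss"))
    expect_equal(classify_for_training(fake_cc("MAD", "MA", class = cls,
                                               first = 3)),
                 "excluded_fr_sc_sd")
  expect_equal(classify_for_training(fake_cc("MADK", "MAK",
                                             class = "inframe_deletion",
                                             first = 3)), "core")
})
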