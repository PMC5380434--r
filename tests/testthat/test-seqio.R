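test_that("FASTA round trip preserves ids, descriptions and sequence", {
  p <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c("g1 first contig" = "ACGTACGTNN", "g2" = "TTTTCCCCGGGGAAAA")
  write_fasta(seqs, p, width = 5)
  recs <- read_fasta(p)
  expect_named(recs, c("g1", "g2"))
  expect_equal(recs$g1$sequence, "ACGTACGTNN")
  expect_equal(recs$g1$description, "first contig")
  expect_equal(recs$g2$sequence, "TTTTCCCCGGGGAAAA")
})

test_that("read_fasta rejects non-IUPAC characters naming the line", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT", "AXXGT"), p)
  expect_error(read_fasta(p), "non-IUPAC.*line 3")
})

test_that("read_fasta rejects duplicates and empty input", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), p)
  expect_error(read_fasta(p), "duplicate")
  p2 <- withr::local_tempfile(fileext = ".fasta")
  file.create(p2)
  expect_error(read_fasta(p2), "empty input")
  expect_error(read_fasta("/nonexistent/x.fa"), "not found")
})

test_that("revcomp is an involution and complements correctly", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AAACGT"), "ACGTTT")
  set.seed(11)
  for (i in 1:50) {
    s <- random_dna_seq(sample(1:200, 1))
    expect_equal(revcomp(revcomp(s)), s)
  }
})

test_that("genome_record validates sequence", {
  expect_error(genome_record("g", ""), "empty")
  expect_error(genome_record("g", "ACGZ"), "non-IUPAC")
  g <- genome_record("g", "acgt")
  expect_equal(g$sequence, "ACGT")
})

test_that("extract_window clips at contig bounds and checks the anchor", {
  g <- genome_record("c1", strrep("ACGT", 2500))  # 10 kb
  a <- feature("anc", "anchor", "c1", 4000, 4600)
  w <- extract_window(g, a, flank_nt = 1000)
  expect_equal(w$window$start, 3000)
  expect_equal(w$window$end, 5600)
  expect_equal(nchar(w$seq), 2600)
  expect_equal(w$seq, substr(g$sequence, 3001, 5600))
  # clipping
  w2 <- extract_window(g, a, flank_nt = 100000)
  expect_equal(c(w2$window$start, w2$window$end), c(0, 10000))
  expect_error(extract_window(g, feature("a", "anchor", "c2", 1, 5)),
               "does not match")
  expect_error(extract_window(g, list(contig_id = "c1", start = 9000,
                                      end = 10500)), "off contig")
})

test_that("GenBank location parsing handles complement and join", {
  expect_equal(parse_gb_location("12..90"),
               list(start = 11L, end = 90L, strand = "+", joined = FALSE))
  expect_equal(parse_gb_location("complement(12..90)")$strand, "-")
  j <- parse_gb_location("join(10..20,30..45)")
  expect_true(j$joined)
  expect_equal(c(j$start, j$end), c(9L, 45L))
  cj <- parse_gb_location("complement(join(10..20,30..45))")
  expect_true(cj$joined)
  expect_equal(cj$strand, "-")
})

test_that("GenBank write/read round trip preserves CDS table and sequence", {
  feats <- rbind(feature("tox1", "CDS", "c1", 10, 100, "+", "hypothetical"),
                 feature("abc1", "CDS", "c1", 200, 500, "-",
                         "type I secretion ABC transporter"))
  g <- genome_record("c1", random_dna_seq(600), "demo contig", feats)
  p <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, p)
  back <- read_genbank(p)
  expect_named(back, "c1")
  b <- back$c1
  expect_equal(b$sequence, g$sequence)
  expect_equal(b$description, "demo contig")
  expect_equal(b$features$id, feats$id)
  expect_equal(b$features$start, feats$start)
  expect_equal(b$features$end, feats$end)
  expect_equal(b$features$strand, feats$strand)
  expect_equal(b$features$product, feats$product)
})

test_that("read_genbank warns on join() and errors on missing pieces", {
  p <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c(
    "LOCUS       j1 60 bp    DNA     linear   BCT 01-JAN-2026",
    "DEFINITION  joined",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             join(1..9,20..30)",
    "                     /locus_tag=\"jcds\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), p)
  expect_warning(b <- read_genbank(p), "join")
  expect_equal(b$j1$features$start, 0L)
  expect_equal(b$j1$features$end, 30L)
  expect_error(read_genbank("/nonexistent.gbk"), "not found")
})

test_that("multi-record GenBank files read back per contig", {
  g1 <- genome_record("m1", random_dna_seq(90), "one")
  g2 <- genome_record("m2", random_dna_seq(120), "two")
  p <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g1, p)
  write_genbank(g2, p, append = TRUE)
  back <- read_genbank(p)
  expect_named(back, c("m1", "m2"))
  expect_equal(back$m2$sequence, g2$sequence)
})

test_that("GFF3 output round trips and converts coordinates", {
  anchor <- structure(list(
    contig_id = "c1",
    genes = feature("abc", "anchor", "c1", 100, 400, "+", "abc"),
    score = 50, span = c(100, 400)), class = "AnchorLocus")
  toxins <- data.frame(orf_id = "c1:500-680:-", contig_id = "c1",
                       start = 500L, end = 680L, strand = "-",
                       stringsAsFactors = FALSE)
  cl <- structure(list(cluster_id = "c1_cluster1", anchor = anchor,
                       toxins = toxins, toxin_count_class = "1",
                       adjacent = FALSE), class = "ClusterCall")
  p <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(cl), p)
  back <- read_gff3(p)
  expect_equal(nrow(back), 2)
  expect_equal(back$start, c(100L, 500L))
  expect_equal(back$end, c(400L, 680L))
  expect_equal(back$kind, c("anchor_gene", "toxin_candidate"))
  expect_equal(unique(back$cluster_id), "c1_cluster1")
  # independent reader oracle: rtracklayer (1-based inclusive)
  gr <- rtracklayer::import(p)
  expect_equal(GenomicRanges::start(gr), c(101L, 501L))
  expect_equal(GenomicRanges::end(gr), c(400L, 680L))
  # empty cluster list still writes a valid header-only file
  p2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(), p2)
  expect_equal(nrow(read_gff3(p2)), 0)
})

test_that("read_bed keeps 0-based half-open intervals verbatim", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("c1\t100\t400\tanc1\t0\t+", "c2\t0\t90"), p)
  b <- read_bed(p)
  expect_equal(b$start, c(100L, 0L))
  expect_equal(b$end, c(400L, 90L))
  expect_equal(b$id[1], "anc1")
  expect_equal(b$kind, c("anchor", "anchor"))
  expect_error(read_bed("/nonexistent.bed"), "not found")
})
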