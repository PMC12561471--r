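PRIMARY <- "GCAGGUAAGUGCG"
SECONDARY <- "ACGAUGGCUGACC"

test_that("query building converts RNA to DNA and honors orientation", {
  q1 <- suppressMessages(build_query(PRIMARY, "as_printed"))
  expect_equal(q1$dna_query, "GCAGGTAAGTGCG")
  q2 <- suppressMessages(build_query(PRIMARY, "reversed"))
  expect_equal(q2$dna_query, "GCGTGAATGGACG")
  q3 <- suppressMessages(build_query(SECONDARY, "as_printed"))
  expect_equal(q3$dna_query, "ACGATGGCTGACC")
  expect_error(suppressMessages(build_query("ACGT")), "RNA")
  expect_error(suppressMessages(build_query("ACG")), "short")
})

test_that("scanning finds exact matches on both strands", {
  q <- suppressMessages(build_query(PRIMARY))
  h1 <- scan_motif(c(m = "GCAGGTAAGTGCG"), q)
  expect_equal(h1[, c("start", "end", "strand")],
               data.frame(start = 0L, end = 13L, strand = "+"))
  h2 <- scan_motif(c(m = "CGCACTTACCTGC"), q)
  expect_equal(h2[, c("start", "end", "strand")],
               data.frame(start = 0L, end = 13L, strand = "-"))
})

test_that("overlapping occurrences are all reported and N never matches", {
  h <- scan_motif(c(m = "AAAAA"), "AAAA")
  expect_equal(h$start[h$strand == "+"], c(0L, 1L))
  hN <- scan_motif(c(m = "ACGNACGT"), "ACGT")
  expect_equal(hN$start[hN$strand == "+"], 4L)
})

test_that("scanner equals the naive position-by-position oracle", {
  q <- suppressMessages(build_query(PRIMARY))
  set.seed(301)
  for (rep in 1:5) {
    # low-complexity alphabet so matches actually occur
    g <- c(z = paste(sample(c("G", "C", "A", "T"), 3000, replace = TRUE,
                            prob = c(.4, .1, .3, .2)), collapse = ""))
    g[[1]] <- gsub("CATG", "GCAG", g[[1]])  # enrich motif-like context
    got <- scan_motif(g, "GCAG")
    expect_identical(got[, c("contig", "start", "end", "strand")],
                     oracle_scan(g, "GCAG"))
  }
})

test_that("scanning the reverse-complemented genome mirrors hits", {
  set.seed(99)
  g <- c(z = random_dna(4000))
  q <- suppressMessages(build_query(PRIMARY))
  sub <- substr(g[[1]], 1, 13)
  h <- scan_motif(g, "ACG")
  grc <- c(z = oracle_revcomp(g[[1]]))
  hrc <- scan_motif(grc, "ACG")
  expect_equal(nrow(h), nrow(hrc))
  L <- nchar(g[[1]])
  mirrored <- data.frame(start = L - hrc$end, end = L - hrc$start,
                         strand = ifelse(hrc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start, mirrored$strand), ]
  orig <- h[order(h$start, h$strand), c("start", "end", "strand")]
  rownames(orig) <- rownames(mirrored) <- NULL
  expect_equal(orig, mirrored)
})

two_exon_model <- function(strand = "+") {
  gene_model(data.frame(
    contig = "c", strand = strand, gene_id = "g", transcript_id = "t",
    start = c(0, 300), end = c(200, 400)))
}

fake_hits <- function(starts, ends, strand = "+", contig = "c") {
  data.frame(contig = contig, start = starts, end = ends, strand = strand,
             motif = "primary")
}

test_that("hits are classified exon / junction / intron / intergenic", {
  m <- two_exon_model()
  a <- annotate_hits(fake_hits(150, 163), m)
  expect_equal(a$feature_class, "exon")
  a2 <- annotate_hits(fake_hits(195, 208), m)
  expect_equal(a2$feature_class, "junction")
  expect_equal(a2$nearest_splice_site, 200)
  a3 <- annotate_hits(fake_hits(250, 263), m)
  expect_equal(a3$feature_class, "intron")
  a4 <- annotate_hits(fake_hits(900, 913), m)
  expect_equal(a4$feature_class, "intergenic")
  expect_true(is.na(a4$gene_id))
  expect_true(is.na(a4$signed_distance))
  # abutting the boundary without crossing it stays in the flank feature
  a5 <- annotate_hits(fake_hits(187, 200), m)
  expect_equal(a5$feature_class, "exon")
})

test_that("every hit gets exactly one class per overlapping gene", {
  m <- random_model(10, seed = 21)
  genome_len <- max(m$exons$end) + 100
  set.seed(22)
  hits <- do.call(rbind, lapply(unique(m$exons$contig), function(ctg) {
    s <- sort(sample(0:(genome_len - 13), 40))
    fake_hits(s, s + 13, strand = sample(c("+", "-"), 40, TRUE),
              contig = ctg)
  }))
  ann <- annotate_hits(hits, m)
  expect_true(all(ann$feature_class %in%
                    c("exon", "intron", "junction", "intergenic")))
  # each original hit is represented at least once
  key <- function(d) paste(d$contig, d$start, d$strand)
  expect_true(all(key(hits) %in% key(ann)))
  genic <- ann[ann$feature_class != "intergenic", ]
  expect_false(any(is.na(genic$gene_id)))
})

test_that("signed distances follow transcription orientation", {
  # + strand: base at the donor boundary position is at distance 0
  m <- two_exon_model("+")
  a <- annotate_hits(fake_hits(200, 213), m)
  expect_equal(a$signed_distance, 0)
  expect_equal(a$site_role, "donor")
  a_up <- annotate_hits(fake_hits(180, 193), m)
  expect_equal(a_up$signed_distance, -20)
  # - strand: 5'-most base is the hit end; donor is the intron's right edge
  mneg <- two_exon_model("-")
  aneg <- annotate_hits(fake_hits(287, 300), mneg)
  expect_equal(aneg$site_role, "donor")
  expect_equal(aneg$signed_distance, 0)
})

test_that("hit summaries count unique intervals and sense fraction", {
  m <- two_exon_model("+")
  ann <- annotate_hits(rbind(fake_hits(100, 113, "+"),
                             fake_hits(250, 263, "-")), m)
  s <- summarize_hits(ann)
  expect_equal(s$n_exon_hits, 1)
  expect_equal(s$n_intron_hits, 1)
  expect_equal(s$n_junction_hits, 0)
  expect_equal(s$n_genes_hit, 1)
  expect_equal(s$n_transcripts_hit, 1)
  expect_equal(s$sense_fraction, 0.5)

  empty <- summarize_hits(annotate_hits(fake_hits(900, 913), m))
  expect_equal(empty$n_genes_hit, 0)
  expect_true(is.na(empty$sense_fraction))
})

test_that("distance histograms bin by donor and acceptor role", {
  m <- two_exon_model("+")
  ann <- annotate_hits(rbind(fake_hits(200, 213),   # donor, 0
                             fake_hits(180, 193),   # donor, -20
                             fake_hits(300, 313)),  # acceptor, 0
                       m)
  dd <- distance_density(ann, max_distance = 50)
  expect_equal(dd$donor_count[dd$bin_start == 0], 1)
  expect_equal(dd$donor_count[dd$bin_start == -20], 1)
  expect_equal(dd$acceptor_count[dd$bin_start == 0], 1)
  expect_equal(sum(dd$donor_count) + sum(dd$acceptor_count), 3)
  none <- distance_density(annotate_hits(fake_hits(900, 913), m), 50)
  expect_equal(nrow(none), 0)
})
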