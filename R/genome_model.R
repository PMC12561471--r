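#' Read a genome FASTA into a named character vector
#'
#' Sequences are uppercased and restricted to the alphabet {A,C,G,T,N}.
#' RNA-style U characters (motifs are often printed as RNA) are converted to
#' T with a warning. Duplicate contig names, empty records and non-IUPAC
#' characters are hard errors.
#'
#' @param path path to a FASTA file with at least one record.
#' @return named character vector, one element per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA contains no records: ", path)
  # readBStringSet keeps full headers; contig name is the first token
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate contig name in FASTA: ", nm[duplicated(nm)][1])
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record: ", nm[nchar(seqs) == 0L][1])
  if (any(grepl("U", seqs, fixed = TRUE))) {
    warning("U characters found in FASTA; converting U -> T")
    seqs <- gsub("U", "T", seqs, fixed = TRUE)
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop(sprintf("non-IUPAC character '%s' in contig %s at position %d",
                 substr(seqs[i], bad[i], bad[i]), nm[i], bad[i]))
  }
  names(seqs) <- nm
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome named character vector as returned by [read_genome_fasta()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read transcript models from a GTF file
#'
#' Only `exon` feature lines are consumed (CDS/UTR and other features are
#' ignored); genes are assembled from the `gene_id` and `transcript_id`
#' attributes. GTF coordinates (1-based inclusive) are converted to the
#' package's internal 0-based half-open convention. Exons are sorted by
#' genomic start within each transcript.
#'
#' @param path path to a GTF file.
#' @return a `gene_model` object: a list with element `exons`, a data.frame
#'   with columns `contig`, `strand`, `gene_id`, `transcript_id`, `start`,
#'   `end` (0-based half-open), validated so that exons within a transcript
#'   never overlap and all transcripts of a gene share contig and strand.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) {
    warning("GTF contains no exon features; returning empty gene model")
    return(gene_model(data.frame(contig = character(), strand = character(),
                                 gene_id = character(),
                                 transcript_id = character(),
                                 start = integer(), end = integer())))
  }
  if (is.null(ex$gene_id) || is.null(ex$transcript_id) ||
      anyNA(ex$gene_id) || anyNA(ex$transcript_id))
    stop("GTF exon lines must carry gene_id and transcript_id attributes")
  z <- to_zero_based(GenomicRanges::start(ex), GenomicRanges::end(ex))
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = ex$gene_id,
    transcript_id = ex$transcript_id,
    start = z[, "start"], end = z[, "end"],
    stringsAsFactors = FALSE)
  gene_model(df)
}

#' Construct and validate a gene model
#'
#' @param exons data.frame with columns `contig`, `strand`, `gene_id`,
#'   `transcript_id`, `start`, `end` in 0-based half-open coordinates.
#' @return validated `gene_model` object.
#' @export
gene_model <- function(exons) {
  req <- c("contig", "strand", "gene_id", "transcript_id", "start", "end")
  if (!all(req %in% names(exons)))
    stop("exon table must have columns: ", paste(req, collapse = ", "))
  exons <- exons[, req]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons)) {
    if (any(exons$end <= exons$start))
      stop("exon with end <= start (after 0-based conversion): transcript ",
           exons$transcript_id[exons$end <= exons$start][1])
    if (!all(exons$strand %in% c("+", "-")))
      stop("exon strand must be '+' or '-'")
    # sort exons within transcript by genomic start
    exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), ]
    rownames(exons) <- NULL
    # per-transcript: non-overlapping exons, single contig/strand
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      s <- exons$start[idx]; e <- exons$end[idx]
      if (length(idx) > 1L && any(s[-1] < e[-length(e)]))
        stop("overlapping exons within transcript ",
             exons$transcript_id[idx[1]])
      if (length(unique(exons$contig[idx])) != 1L)
        stop("transcript on multiple contigs: ", exons$transcript_id[idx[1]])
    }
    # per-gene: consistent strand and contig
    by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
    for (idx in by_gene) {
      if (length(unique(exons$strand[idx])) != 1L)
        stop("mixed strands within gene ", exons$gene_id[idx[1]])
      if (length(unique(exons$contig[idx])) != 1L)
        stop("gene on multiple contigs: ", exons$gene_id[idx[1]])
    }
  }
  structure(list(exons = exons), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  ex <- x$exons
  n_intron <- nrow(intron_table(x))
  cat("gene_model:",
      length(unique(ex$gene_id)), "genes,",
      length(unique(ex$transcript_id)), "transcripts,",
      nrow(ex), "exon records,",
      n_intron, "introns (per-transcript)\n")
  invisible(x)
}

#' Write a gene model back to GTF
#'
#' Emits exon lines in the same dialect read by [read_gtf()] (1-based
#' inclusive, `gene_id "..."; transcript_id "...";` attributes), so that a
#' read/write round trip preserves exon intervals and strands.
#'
#' @param model a `gene_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(model, path) {
  ex <- model$exons
  one <- to_one_based(ex$start, ex$end)
  gr <- GenomicRanges::GRanges(
    seqnames = ex$contig,
    ranges = IRanges::IRanges(start = one[, "start"], end = one[, "end"]),
    strand = ex$strand)
  gr$source <- "splicescan"
  gr$type <- "exon"
  gr$gene_id <- ex$gene_id
  gr$transcript_id <- ex$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Derive introns for one transcript
#'
#' Introns are the gaps between consecutive exons: a transcript with exons
#' e1..en yields n-1 introns `(end(e_i), start(e_i+1))` in 0-based half-open
#' coordinates; a single-exon transcript yields none. Introns shorter than
#' 30 nt are kept but reported via a message, since very short introns are
#' usually annotation artifacts.
#'
#' @param exons two-column matrix or data.frame of sorted exon (start, end).
#' @return data.frame with columns `start`, `end` (possibly 0 rows).
#' @export
derive_introns <- function(exons) {
  s <- as.integer(exons[[1]]); e <- as.integer(exons[[2]])
  n <- length(s)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  out <- data.frame(start = e[-n], end = s[-1])
  short <- out$end - out$start < 30L
  if (any(short))
    message(sum(short), " intron(s) shorter than 30 nt retained")
  out
}

#' Per-transcript intron table for a gene model
#'
#' @param model a `gene_model`.
#' @return data.frame with columns `contig`, `strand`, `gene_id`,
#'   `transcript_id`, `start`, `end`, one row per intron of each transcript.
#' @export
intron_table <- function(model) {
  ex <- model$exons
  if (!nrow(ex))
    return(data.frame(contig = character(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      start = integer(), end = integer()))
  pieces <- lapply(split(ex, ex$transcript_id), function(t) {
    intr <- suppressMessages(derive_introns(t[, c("start", "end")]))
    if (!nrow(intr)) return(NULL)
    data.frame(contig = t$contig[1], strand = t$strand[1],
               gene_id = t$gene_id[1], transcript_id = t$transcript_id[1],
               start = intr$start, end = intr$end)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    out <- data.frame(contig = character(), strand = character(),
                      gene_id = character(), transcript_id = character(),
                      start = integer(), end = integer())
  rownames(out) <- NULL
  out
}

# span (min start, max end) per gene: data.frame gene_id, contig, strand,
# start, end
gene_spans <- function(model) {
  ex <- model$exons
  if (!nrow(ex))
    return(data.frame(gene_id = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer()))
  sp <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], contig = g$contig[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end))
  }))
  rownames(sp) <- NULL
  sp
}

# internal splice boundaries per transcript of one gene's exon table:
# data.frame(pos, role) with role "donor" (exon -> intron in transcription
# direction) or "acceptor", deduplicated over transcripts per (pos, role)
splice_boundaries <- function(gene_exons) {
  strand <- gene_exons$strand[1]
  pieces <- lapply(split(gene_exons, gene_exons$transcript_id), function(t) {
    n <- nrow(t)
    if (n < 2L) return(NULL)
    ends <- t$end[-n]      # left boundary of each intron
    starts <- t$start[-1]  # right boundary of each intron
    if (strand == "+")
      data.frame(pos = c(ends, starts),
                 role = rep(c("donor", "acceptor"), each = n - 1L))
    else
      data.frame(pos = c(ends, starts),
                 role = rep(c("acceptor", "donor"), each = n - 1L))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(data.frame(pos = integer(), role = character()))
  unique(out[order(out$pos, out$role), , drop = FALSE])
}

#' Summarize a gene model for a validation report
#'
#' @param model a `gene_model`.
#' @return list of counts: genes, transcripts, exon records, unique exon
#'   intervals, per-transcript introns and unique intron intervals.
#' @export
model_stats <- function(model) {
  ex <- model$exons
  intr <- intron_table(model)
  list(
    n_genes = length(unique(ex$gene_id)),
    n_transcripts = length(unique(ex$transcript_id)),
    n_exon_records = nrow(ex),
    n_unique_exons = nrow(unique(ex[, c("contig", "start", "end")])),
    n_intron_records = nrow(intr),
    n_unique_introns = nrow(unique(intr[, c("contig", "start", "end")])))
}
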