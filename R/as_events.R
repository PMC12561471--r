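EVENT_TYPES <- c("SE", "RI", "MXE", "A3SS", "A5SS")

# canonical serialization of one event; uniqueness key for deduplication
event_id_string <- function(type, contig, strand, coords) {
  paste(type, contig, strand, paste(coords, collapse = ","), sep = ":")
}

new_event <- function(type, gene_id, contig, strand, coords, sites) {
  data.frame(
    event_id = event_id_string(type, contig, strand, coords),
    event_type = type, gene_id = gene_id, contig = contig, strand = strand,
    coords = paste(coords, collapse = ","),
    splice_sites = paste(sort(unique(sites)), collapse = ","),
    stringsAsFactors = FALSE)
}

# exon chains of one gene as a named list of (start, end) matrices,
# genomic ascending
exon_chains <- function(gene_exons) {
  lapply(split(gene_exons, gene_exons$transcript_id), function(t) {
    cbind(start = t$start, end = t$end)
  })
}

has_junction <- function(chain, left, right) {
  n <- nrow(chain)
  n >= 2L && any(chain[-n, "end"] == left & chain[-1, "start"] == right)
}

has_exon <- function(chain, s, e) {
  any(chain[, "start"] == s & chain[, "end"] == e)
}

overlaps_exon <- function(chain, s, e) {
  any(chain[, "start"] < e & chain[, "end"] > s)
}

junctions_of <- function(chain) {
  n <- nrow(chain)
  if (n < 2L) return(cbind(left = integer(), right = integer()))
  cbind(left = chain[-n, "end"], right = chain[-1, "start"])
}

# events detected in one ordered transcript pair (X = inclusion-side chain)
pair_events_directional <- function(X, Y, gene_id, contig, strand) {
  out <- list()
  nX <- nrow(X)
  # SE: internal exon of X skipped by a direct junction in Y
  if (nX >= 3L) {
    for (i in 2:(nX - 1L)) {
      e1_end <- X[i - 1L, "end"]; s2 <- X[i, "start"]
      e2 <- X[i, "end"]; s3 <- X[i + 1L, "start"]
      if (has_junction(Y, e1_end, s3) && !overlaps_exon(Y, s2, e2))
        out[[length(out) + 1L]] <- new_event(
          "SE", gene_id, contig, strand, c(e1_end, s2, e2, s3),
          c(e1_end, s2, e2, s3))
    }
  }
  # RI: a junction of Y whose flanking exons are fused into one exon of X
  jY <- junctions_of(Y)
  if (nrow(jY)) {
    nY <- nrow(Y)
    for (j in seq_len(nY - 1L)) {
      s1 <- Y[j, "start"]; e1 <- Y[j, "end"]
      s2 <- Y[j + 1L, "start"]; e2 <- Y[j + 1L, "end"]
      if (has_exon(X, s1, e2))
        out[[length(out) + 1L]] <- new_event(
          "RI", gene_id, contig, strand, c(s1, e1, s2, e2), c(e1, s2))
    }
  }
  # MXE: internal exon of X and internal exon of Y sharing both flanking
  # junction partners, mutually exclusive
  nY <- nrow(Y)
  if (nX >= 3L && nY >= 3L) {
    for (i in 2:(nX - 1L)) for (j in 2:(nY - 1L)) {
      if (X[i - 1L, "end"] != Y[j - 1L, "end"]) next
      if (X[i + 1L, "start"] != Y[j + 1L, "start"]) next
      a <- X[i, , drop = TRUE]; b <- Y[j, , drop = TRUE]
      if (a["start"] == b["start"] && a["end"] == b["end"]) next
      # genomic order and strict non-overlap (abutting exons excluded so
      # the coordinate tuple stays strictly increasing)
      if (a["start"] > b["start"]) { tmp <- a; a <- b; b <- tmp }
      if (a["end"] >= b["start"]) next
      if (has_exon(X, b["start"], b["end"]) ||
          has_exon(Y, a["start"], a["end"])) next
      e1_end <- X[i - 1L, "end"]; s4 <- X[i + 1L, "start"]
      out[[length(out) + 1L]] <- new_event(
        "MXE", gene_id, contig, strand,
        c(e1_end, a["start"], a["end"], b["start"], b["end"], s4),
        c(e1_end, a["start"], a["end"], b["start"], b["end"], s4))
    }
  }
  out
}

# A5SS/A3SS from the two junction catalogs (symmetric in the pair).
# Besides the shared boundary, the two alternative boundaries must come
# from overlapping exons (the two forms of the *same* exon); without this
# requirement the flanking junctions of skipped or mutually exclusive
# exons would spuriously qualify as alternative splice sites.
pair_events_altss <- function(X, Y, gene_id, contig, strand) {
  out <- list()
  jX <- junctions_of(X); jY <- junctions_of(Y)
  if (!nrow(jX) || !nrow(jY)) return(out)
  exon_ending <- function(chain, e) chain[chain[, "end"] == e, , drop = FALSE]
  exon_starting <- function(chain, s)
    chain[chain[, "start"] == s, , drop = FALSE]
  overlap1 <- function(a, b) {
    nrow(a) && nrow(b) && a[1, "start"] < b[1, "end"] &&
      b[1, "start"] < a[1, "end"]
  }
  for (i in seq_len(nrow(jX))) for (j in seq_len(nrow(jY))) {
    lx <- jX[i, "left"]; rx <- jX[i, "right"]
    ly <- jY[j, "left"]; ry <- jY[j, "right"]
    if (rx == ry && lx != ly) {
      # shared right (genomic) boundary, alternative left boundaries:
      # on + the left boundary is the donor -> A5SS; on - it is the
      # acceptor -> A3SS
      if (!overlap1(exon_ending(X, lx), exon_ending(Y, ly))) next
      type <- if (strand == "+") "A5SS" else "A3SS"
      alts <- sort(c(lx, ly))
      out[[length(out) + 1L]] <- new_event(
        type, gene_id, contig, strand, c(rx, alts), c(rx, alts))
    } else if (lx == ly && rx != ry) {
      if (!overlap1(exon_starting(X, rx), exon_starting(Y, ry))) next
      type <- if (strand == "+") "A3SS" else "A5SS"
      alts <- sort(c(rx, ry))
      out[[length(out) + 1L]] <- new_event(
        type, gene_id, contig, strand, c(lx, alts), c(lx, alts))
    }
  }
  out
}

empty_events <- function() {
  structure(
    data.frame(event_id = character(), event_type = character(),
               gene_id = character(), contig = character(),
               strand = character(), coords = character(),
               splice_sites = character(), stringsAsFactors = FALSE),
    class = c("splice_events", "data.frame"))
}

#' Enumerate alternative-splicing events from a gene model
#'
#' Detects the five classic event classes by comparing every unordered pair
#' of transcripts within each gene:
#' \describe{
#'   \item{SE}{skipped exon: one transcript carries an internal exon, the
#'     other joins its flanking exons directly and has no exon overlapping
#'     the skipped one.}
#'   \item{RI}{retained intron: one transcript's single exon spans exactly
#'     the two consecutive exons (and the intervening intron) of the other.}
#'   \item{A5SS/A3SS}{two junctions sharing the acceptor-side (resp.
#'     donor-side) boundary but differing at the donor (resp. acceptor);
#'     donor/acceptor roles follow the gene's strand.}
#'   \item{MXE}{two internal exons sharing both flanking junction partners,
#'     mutually exclusive across the pair, non-overlapping.}
#' }
#' Events discovered through multiple transcript pairs are deduplicated by
#' their canonical coordinate tuple; output is sorted by `event_id` so
#' repeated runs are byte-identical.
#'
#' @param model a `gene_model` (see [read_gtf()]).
#' @return a `splice_events` data.frame with columns `event_id`,
#'   `event_type`, `gene_id`, `contig`, `strand`, `coords` (comma-joined
#'   genomic-ascending tuple; for A5SS/A3SS the tuple is
#'   `shared,alt1,alt2`), `splice_sites` (comma-joined boundary positions).
#' @examples
#' ex <- data.frame(contig = "c", strand = "+", gene_id = "g",
#'                  transcript_id = rep(c("t1", "t2"), c(3, 2)),
#'                  start = c(0, 200, 400, 0, 400),
#'                  end   = c(100, 300, 500, 100, 500))
#' enumerate_events(gene_model(ex))
#' @export
enumerate_events <- function(model) {
  ex <- if (inherits(model, "gene_model")) model$exons else model
  if (!nrow(ex)) return(empty_events())
  found <- list()
  for (g in split(ex, ex$gene_id)) {
    chains <- exon_chains(g)
    if (length(chains) < 2L) next
    gene_id <- g$gene_id[1]; contig <- g$contig[1]; strand <- g$strand[1]
    ids <- names(chains)
    for (i in seq_len(length(chains) - 1L)) for (j in (i + 1L):length(chains)) {
      A <- chains[[i]]; B <- chains[[j]]
      found <- c(found,
                 pair_events_directional(A, B, gene_id, contig, strand),
                 pair_events_directional(B, A, gene_id, contig, strand),
                 pair_events_altss(A, B, gene_id, contig, strand))
    }
  }
  if (!length(found)) return(empty_events())
  ev <- do.call(rbind, found)
  ev <- ev[!duplicated(ev$event_id), , drop = FALSE]
  ev <- ev[order(ev$event_id), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("splice_events", "data.frame")
  ev
}

#' Count events per class
#'
#' @param events a `splice_events` data.frame (duplicated `event_id`s are
#'   counted once).
#' @return named integer vector over SE, RI, MXE, A3SS, A5SS.
#' @export
count_events_by_type <- function(events) {
  events <- events[!duplicated(events$event_id), , drop = FALSE]
  tab <- table(factor(events$event_type, levels = EVENT_TYPES))
  out <- as.integer(tab)
  names(out) <- EVENT_TYPES
  out
}

# splice sites of each event as a list of integer vectors
event_sites <- function(events) {
  lapply(strsplit(events$splice_sites, ",", fixed = TRUE), as.integer)
}

# coordinate tuples as list of integer vectors
event_coords <- function(events) {
  lapply(strsplit(events$coords, ",", fixed = TRUE), as.integer)
}

#' Write events as a tab-separated table
#'
#' @param events a `splice_events` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
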