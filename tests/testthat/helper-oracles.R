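# Independent brute-force oracles, written against the literal event /
# scan definitions with a code path separate from the package internals.

# --- naive O(n*m) motif scanner -------------------------------------------

oracle_revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# every exact occurrence of q (forward) and revcomp(q) (reverse) by direct
# position-by-position substring comparison
oracle_scan <- function(genome, q) {
  m <- nchar(q)
  rc <- oracle_revcomp(q)
  rows <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    n <- nchar(s)
    if (n < m) next
    starts <- seq_len(n - m + 1L)
    subs <- substring(s, starts, starts + m - 1L)
    fwd <- which(subs == q)
    rev <- which(subs == rc)
    if (length(fwd))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, start = fwd - 1L, end = fwd - 1L + m, strand = "+")
    if (length(rev))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ctg, start = rev - 1L, end = rev - 1L + m, strand = "-")
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character()))
  out <- out[order(out$contig, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# --- brute-force AS-event oracle ------------------------------------------

# literal per-pair event definitions; returns sorted unique event id strings
oracle_event_ids <- function(model) {
  ex <- model$exons
  ids <- character()
  add <- function(type, contig, strand, coords) {
    ids <<- c(ids, paste(type, contig, strand,
                         paste(coords, collapse = ","), sep = ":"))
  }
  for (gid in unique(ex$gene_id)) {
    g <- ex[ex$gene_id == gid, ]
    contig <- g$contig[1]; strand <- g$strand[1]
    txs <- lapply(split(g, g$transcript_id),
                  function(t) t[order(t$start), c("start", "end")])
    if (length(txs) < 2) next
    for (ai in seq_along(txs)) for (bi in seq_along(txs)) {
      if (ai == bi) next
      A <- txs[[ai]]; B <- txs[[bi]]
      # SE: internal exon of A absent from B, B joins the flanks directly
      if (nrow(A) >= 3) for (k in 2:(nrow(A) - 1)) {
        left <- A$end[k - 1]; s <- A$start[k]; e <- A$end[k]
        right <- A$start[k + 1]
        direct <- FALSE
        if (nrow(B) >= 2) for (jb in 1:(nrow(B) - 1))
          if (B$end[jb] == left && B$start[jb + 1] == right) direct <- TRUE
        clear <- TRUE
        for (jb in seq_len(nrow(B)))
          if (B$start[jb] < e && B$end[jb] > s) clear <- FALSE
        if (direct && clear) add("SE", contig, strand, c(left, s, e, right))
      }
      # RI: exon of A spans exactly two consecutive exons of B
      if (nrow(B) >= 2) for (jb in 1:(nrow(B) - 1)) {
        s1 <- B$start[jb]; e1 <- B$end[jb]
        s2 <- B$start[jb + 1]; e2 <- B$end[jb + 1]
        for (ka in seq_len(nrow(A)))
          if (A$start[ka] == s1 && A$end[ka] == e2)
            add("RI", contig, strand, c(s1, e1, s2, e2))
      }
      # MXE: internal exons sharing both flanking partners, exclusive
      if (ai < bi && nrow(A) >= 3 && nrow(B) >= 3) {
        for (ka in 2:(nrow(A) - 1)) for (kb in 2:(nrow(B) - 1)) {
          if (A$end[ka - 1] != B$end[kb - 1]) next
          if (A$start[ka + 1] != B$start[kb + 1]) next
          xa <- c(A$start[ka], A$end[ka]); xb <- c(B$start[kb], B$end[kb])
          if (xa[1] == xb[1] && xa[2] == xb[2]) next
          lo <- if (xa[1] <= xb[1]) xa else xb
          hi <- if (xa[1] <= xb[1]) xb else xa
          if (lo[2] >= hi[1]) next
          in_a <- any(A$start == xb[1] & A$end == xb[2])
          in_b <- any(B$start == xa[1] & B$end == xa[2])
          if (in_a || in_b) next
          add("MXE", contig, strand,
              c(A$end[ka - 1], lo[1], lo[2], hi[1], hi[2], A$start[ka + 1]))
        }
      }
      # A5SS/A3SS: junctions sharing one boundary, alternative boundary
      # pair from overlapping exon forms
      if (ai < bi && nrow(A) >= 2 && nrow(B) >= 2) {
        for (ja in 1:(nrow(A) - 1)) for (jb in 1:(nrow(B) - 1)) {
          la <- A$end[ja]; ra <- A$start[ja + 1]
          lb <- B$end[jb]; rb <- B$start[jb + 1]
          if (ra == rb && la != lb) {
            ea <- A[A$end == la, ]; eb <- B[B$end == lb, ]
            if (ea$start[1] < eb$end[1] && eb$start[1] < ea$end[1]) {
              ty <- if (strand == "+") "A5SS" else "A3SS"
              add(ty, contig, strand, c(ra, min(la, lb), max(la, lb)))
            }
          }
          if (la == lb && ra != rb) {
            ea <- A[A$start == ra, ]; eb <- B[B$start == rb, ]
            if (ea$start[1] < eb$end[1] && eb$start[1] < ea$end[1]) {
              ty <- if (strand == "+") "A3SS" else "A5SS"
              add(ty, contig, strand, c(la, min(ra, rb), max(ra, rb)))
            }
          }
        }
      }
    }
  }
  sort(unique(ids))
}

# --- two-sided Fisher p via hypergeometric tail ---------------------------

# conditional two-sided exact p for table rbind(c(a, b), c(c, d)):
# sum of hypergeometric point masses not exceeding the observed one
oracle_fisher_p <- function(a, b, c, d) {
  k1 <- a + b; n1 <- a + c; n2 <- b + d
  xs <- max(0, k1 - n2):min(k1, n1)
  dens <- dhyper(xs, n1, n2, k1)
  obs <- dhyper(a, n1, n2, k1)
  sum(dens[dens <= obs * (1 + 1e-7)])
}

# --- random gene generator for property tests -----------------------------

# gene with 2-6 transcripts derived from a base chain by dropping internal
# exons, fusing adjacent exons (intron retention) and shifting boundaries,
# so all event classes arise; always returns a valid exon table
random_gene <- function(gene_id = "g", contig = "c",
                        strand = sample(c("+", "-"), 1)) {
  n_ex <- sample(1:10, 1)
  widths <- sample(30:100, n_ex, replace = TRUE)
  gaps <- sample(40:120, n_ex, replace = TRUE)
  starts <- cumsum(c(gaps[1], widths[-n_ex] + gaps[-1]))
  base <- cbind(start = starts, end = starts + widths)
  n_tx <- sample(2:6, 1)
  rows <- list()
  for (t in seq_len(n_tx)) {
    ch <- base
    # drop internal exons
    if (nrow(ch) >= 3) {
      keep <- c(TRUE, runif(nrow(ch) - 2) > 0.3, TRUE)
      ch <- ch[keep, , drop = FALSE]
    }
    # fuse adjacent exons across their intron
    k <- 1
    while (k < nrow(ch)) {
      if (runif(1) < 0.2) {
        ch[k, "end"] <- ch[k + 1, "end"]
        ch <- ch[-(k + 1), , drop = FALSE]
      } else k <- k + 1
    }
    # shift junction boundaries, keeping intron length >= 2
    if (nrow(ch) >= 2) for (k in 1:(nrow(ch) - 1)) {
      if (runif(1) < 0.3) {
        sh <- sample(c(-15, -10, 10, 15), 1)
        newe <- ch[k, "end"] + sh
        if (newe > ch[k, "start"] && newe < ch[k + 1, "start"] - 1)
          ch[k, "end"] <- newe
      }
      if (runif(1) < 0.3) {
        sh <- sample(c(-15, -10, 10, 15), 1)
        news <- ch[k + 1, "start"] + sh
        if (news > ch[k, "end"] + 1 && news < ch[k + 1, "end"])
          ch[k + 1, "start"] <- news
      }
    }
    rows[[t]] <- data.frame(contig = contig, strand = strand,
                            gene_id = gene_id,
                            transcript_id = sprintf("%s.t%d", gene_id, t),
                            start = ch[, "start"], end = ch[, "end"])
  }
  do.call(rbind, rows)
}

random_model <- function(n_genes, seed) {
  set.seed(seed)
  gene_model(do.call(rbind, lapply(seq_len(n_genes), function(i)
    random_gene(sprintf("g%03d", i), contig = sprintf("c%02d", i %% 7)))))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
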