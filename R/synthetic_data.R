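#' Configuration for the synthetic splicing simulator
#'
#' Defaults encode the study conditions the simulator is meant to emulate:
#' motif planting probabilities of 0.40 at alternative-splice-site events
#' and 0.20 at SE/RI/MXE events, three replicates per condition, and
#' beta-binomially dispersed junction counts at a mean informative depth
#' of 100 reads per event.
#'
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of the config.
#' @param n_genes number of genes (one AS event per gene, two isoforms).
#' @param event_mix named proportions over SE/RI/MXE/A3SS/A5SS.
#' @param exon_length_range,intron_length_range bp ranges (uniform draws).
#' @param alt_shift_range bp range for the alternative-splice-site offset.
#' @param p_plant named per-class probability that a sense-strand motif
#'   copy is planted straddling one of the event's splice sites.
#' @param background_rate expected motif occurrences per kb away from
#'   junctions (default 0: background occurrences are scrubbed so junction
#'   enrichment is attributable to planting alone).
#' @param motif `motif_query` (or DNA string) planted and later scanned.
#' @param psi_true named list: condition -> true inclusion proportion,
#'   scalar or per-event vector (recycled to `n_genes`).
#' @param depth expected informative reads per event and sample.
#' @param dispersion beta-binomial intra-class correlation rho in [0, 1).
#' @param n_samples replicates per condition.
#' @param spacer_range intergenic gap range in bp.
#' @param contig contig name of the emitted genome.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 100L,
                       event_mix = c(SE = 0.35, RI = 0.25, MXE = 0.10,
                                     A3SS = 0.15, A5SS = 0.15),
                       exon_length_range = c(80L, 200L),
                       intron_length_range = c(120L, 300L),
                       alt_shift_range = c(20L, 60L),
                       p_plant = c(SE = 0.20, RI = 0.20, MXE = 0.20,
                                   A3SS = 0.40, A5SS = 0.40),
                       background_rate = 0,
                       motif = "GCAGGTAAGTGCG",
                       psi_true = list(WT = 0.5, cKO = 0.5),
                       depth = 100,
                       dispersion = 0.01,
                       n_samples = 3L,
                       spacer_range = c(200L, 400L),
                       contig = "chrS1") {
  if (is.character(motif))
    motif <- structure(list(name = "primary", dna_query = toupper(motif)),
                       class = "motif_query")
  m <- nchar(motif$dna_query)
  stopifnot(all(event_mix >= 0), abs(sum(event_mix) - 1) < 1e-8,
            all(p_plant >= 0 & p_plant <= 1),
            all(names(p_plant) %in% EVENT_TYPES),
            depth > 0, dispersion >= 0, dispersion < 1, n_samples >= 1)
  if (exon_length_range[1] < m + 2L || intron_length_range[1] < m + 2L)
    stop("exon/intron lengths must be at least motif length + 2")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 event_mix = event_mix,
                 exon_length_range = exon_length_range,
                 intron_length_range = intron_length_range,
                 alt_shift_range = alt_shift_range,
                 p_plant = p_plant, background_rate = background_rate,
                 motif = motif, psi_true = psi_true, depth = depth,
                 dispersion = dispersion,
                 n_samples = as.integer(n_samples),
                 spacer_range = spacer_range, contig = contig),
            class = "sim_config")
}

runif_int <- function(n, range) {
  if (range[2] <= range[1]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

# local-coordinate gene layout realizing exactly one event of `type`;
# returns exon chains for two transcripts plus the event's canonical
# coordinate tuple and splice sites (all relative to gene start 0)
layout_gene <- function(type, strand, cfg) {
  L <- function() runif_int(1L, cfg$exon_length_range)
  I <- function() runif_int(1L, cfg$intron_length_range)
  D <- function() runif_int(1L, cfg$alt_shift_range)
  if (type == "SE") {
    l1 <- L(); i1 <- I(); l2 <- L(); i2 <- I(); l3 <- L()
    e1 <- c(0L, l1); e2 <- c(l1 + i1, l1 + i1 + l2)
    e3 <- c(e2[2] + i2, e2[2] + i2 + l3)
    t1 <- rbind(e1, e2, e3); t2 <- rbind(e1, e3)
    coords <- c(e1[2], e2[1], e2[2], e3[1]); sites <- coords
  } else if (type == "RI") {
    l1 <- L(); i1 <- I(); l2 <- L()
    e1 <- c(0L, l1); e2 <- c(l1 + i1, l1 + i1 + l2)
    t1 <- rbind(e1, e2); t2 <- rbind(c(0L, e2[2]))
    coords <- c(0L, e1[2], e2[1], e2[2]); sites <- c(e1[2], e2[1])
  } else if (type == "MXE") {
    l1 <- L(); i1 <- I(); la <- L(); i2 <- I(); lb <- L(); i3 <- I()
    l4 <- L()
    e1 <- c(0L, l1); ea <- c(l1 + i1, l1 + i1 + la)
    eb <- c(ea[2] + i2, ea[2] + i2 + lb)
    e4 <- c(eb[2] + i3, eb[2] + i3 + l4)
    t1 <- rbind(e1, ea, e4); t2 <- rbind(e1, eb, e4)
    coords <- c(e1[2], ea[1], ea[2], eb[1], eb[2], e4[1]); sites <- coords
  } else if (type %in% c("A5SS", "A3SS")) {
    # alternative boundary on the donor (A5SS) or acceptor (A3SS) side,
    # which is the exon-end side on + and the exon-start side on -
    l1 <- L(); i1 <- I(); l2 <- L(); d <- D()
    alt_on_left <- (type == "A5SS") == (strand == "+")
    if (alt_on_left) {
      # two exon-end choices for the first exon
      e1a <- c(0L, l1); e1b <- c(0L, l1 + d)
      s2 <- l1 + d + i1
      e2 <- c(s2, s2 + l2)
      t1 <- rbind(e1a, e2); t2 <- rbind(e1b, e2)
      coords <- c(s2, l1, l1 + d); sites <- c(s2, l1, l1 + d)
    } else {
      # two exon-start choices for the second exon
      e1 <- c(0L, l1); s2 <- l1 + i1
      e2a <- c(s2 + d, s2 + d + l2); e2b <- c(s2, s2 + l2 + 0L)
      t1 <- rbind(e1, e2a); t2 <- rbind(e1, e2b)
      coords <- c(l1, s2, s2 + d); sites <- c(l1, s2, s2 + d)
    }
  } else stop("unknown event type: ", type)
  colnames(t1) <- colnames(t2) <- c("start", "end")
  list(t1 = t1, t2 = t2, coords = coords, sites = sites,
       span = max(t1[, "end"], t2[, "end"]))
}

#' Generate a synthetic genome, annotation and planted ground truth
#'
#' Each gene carries two transcripts engineered to realize exactly one
#' alternative-splicing event of a class drawn from `event_mix`. With the
#' per-class probability `p_plant`, one motif copy is planted on the sense
#' strand straddling a randomly chosen splice site of the event (the
#' boundary falls strictly inside the motif interval, so a scanner
#' classifies the hit as junction-spanning). Background sequence is drawn
#' uniformly over {A,C,G,T} and then scrubbed of chance motif occurrences
#' beyond the configured background rate, so junction enrichment in the
#' emitted genome is attributable to planting alone. The returned truth
#' manifest fully determines the simulation given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character), `model` (`gene_model`),
#'   `truth` (list: `events` data.frame with planted-motif columns, `psi`
#'   matrix event x condition, `config`).
#' @export
simulate_splice_genome <- function(config) {
  cfg <- config
  m <- nchar(cfg$motif$dna_query)
  with_seed(cfg$seed, {
    types <- sample(names(cfg$event_mix), cfg$n_genes, replace = TRUE,
                    prob = cfg$event_mix)
    strands <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    exon_rows <- vector("list", cfg$n_genes)
    truth_rows <- vector("list", cfg$n_genes)
    plant_pos <- list()  # planted intervals for scrub protection
    cursor <- runif_int(1L, cfg$spacer_range)
    for (i in seq_len(cfg$n_genes)) {
      ty <- types[i]; st <- strands[i]
      lay <- layout_gene(ty, st, cfg)
      off <- cursor
      gid <- sprintf("g%04d", i)
      mk <- function(chain, tid) data.frame(
        contig = cfg$contig, strand = st, gene_id = gid,
        transcript_id = tid, start = chain[, "start"] + off,
        end = chain[, "end"] + off)
      exon_rows[[i]] <- rbind(mk(lay$t1, paste0(gid, ".t1")),
                              mk(lay$t2, paste0(gid, ".t2")))
      coords <- lay$coords + off
      sites <- lay$sites + off
      planted <- stats::runif(1) < cfg$p_plant[[ty]]
      ps <- NA_integer_; pstart <- NA_integer_
      if (planted) {
        ps <- sites[sample.int(length(sites), 1L)]
        o <- sample.int(m - 1L, 1L)  # boundary strictly inside the motif
        pstart <- ps - o
        plant_pos[[length(plant_pos) + 1L]] <-
          c(start = pstart, strand = if (st == "+") 1L else -1L)
      }
      truth_rows[[i]] <- data.frame(
        gene_id = gid, event_type = ty, contig = cfg$contig, strand = st,
        event_id = event_id_string(ty, cfg$contig, st, coords),
        coords = paste(coords, collapse = ","),
        splice_sites = paste(sort(unique(sites)), collapse = ","),
        planted = planted, plant_site = ps, plant_start = pstart,
        stringsAsFactors = FALSE)
      cursor <- off + lay$span + runif_int(1L, cfg$spacer_range)
    }
    total_len <- cursor + runif_int(1L, cfg$spacer_range)
    seq_chars <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
    # plant motifs (sense strand: the strand reading the query 5'->3')
    q_fwd <- strsplit(cfg$motif$dna_query, "", fixed = TRUE)[[1]]
    q_rev <- strsplit(revcomp(cfg$motif$dna_query), "", fixed = TRUE)[[1]]
    truth <- do.call(rbind, truth_rows)
    planted_iv <- NULL
    for (j in which(truth$planted)) {
      s0 <- truth$plant_start[j]
      seq_chars[(s0 + 1L):(s0 + m)] <-
        if (truth$strand[j] == "+") q_fwd else q_rev
      planted_iv <- rbind(planted_iv,
                          c(s0, s0 + m, if (truth$strand[j] == "+") 1L
                            else 2L))
    }
    # background plantings away from splice boundaries
    n_bg <- if (cfg$background_rate > 0)
      stats::rpois(1, cfg$background_rate * total_len / 1000) else 0L
    bg_rows <- NULL
    if (n_bg > 0) {
      all_sites <- as.integer(unlist(strsplit(truth$splice_sites, ",")))
      tries <- 0L
      while (n_bg > 0 && tries < 50L * n_bg + 100L) {
        tries <- tries + 1L
        s0 <- sample.int(total_len - m, 1L)
        if (any(abs(all_sites - s0) <= m + 50L)) next
        if (!is.null(planted_iv) &&
            any(planted_iv[, 1] < s0 + m & planted_iv[, 2] > s0)) next
        bg_strand <- sample(c("+", "-"), 1L)
        seq_chars[(s0 + 1L):(s0 + m)] <-
          if (bg_strand == "+") q_fwd else q_rev
        planted_iv <- rbind(planted_iv,
                            c(s0, s0 + m, if (bg_strand == "+") 1L else 2L))
        bg_rows <- rbind(bg_rows, data.frame(start = s0, strand = bg_strand))
        n_bg <- n_bg - 1L
      }
    }
    genome <- stats::setNames(paste(seq_chars, collapse = ""), cfg$contig)
    genome <- scrub_chance_hits(genome, cfg$motif, planted_iv)
    model <- gene_model(do.call(rbind, exon_rows))
    conds <- names(cfg$psi_true)
    psi <- vapply(conds, function(cn)
      rep_len(cfg$psi_true[[cn]], cfg$n_genes), numeric(cfg$n_genes))
    psi <- matrix(psi, nrow = cfg$n_genes,
                  dimnames = list(truth$event_id, conds))
    list(genome = genome, model = model,
         truth = list(events = truth, background = bg_rows, psi = psi,
                      config = cfg))
  })
}

# replace chance exact occurrences (either strand) that are not planted by
# mutating one base outside every planted interval; iterate until clean
scrub_chance_hits <- function(genome, motif, planted_iv) {
  bases <- c("A", "C", "G", "T")
  for (iter in 1:25) {
    hits <- scan_motif(genome, motif)
    if (nrow(hits) && !is.null(planted_iv)) {
      keep <- vapply(seq_len(nrow(hits)), function(i) {
        sc <- if (hits$strand[i] == "+") 1L else 2L
        any(planted_iv[, 1] == hits$start[i] & planted_iv[, 3] == sc)
      }, logical(1))
      hits <- hits[!keep, , drop = FALSE]
    }
    if (!nrow(hits)) return(genome)
    seq_chars <- strsplit(genome[[1]], "", fixed = TRUE)[[1]]
    for (i in seq_len(nrow(hits))) {
      cand <- (hits$start[i] + 1L):hits$end[i]
      if (!is.null(planted_iv)) {
        prot <- unlist(lapply(seq_len(nrow(planted_iv)), function(r)
          (planted_iv[r, 1] + 1L):planted_iv[r, 2]))
        cand <- setdiff(cand, prot)
      }
      if (!length(cand)) next
      pos <- cand[ceiling(length(cand) / 2)]
      seq_chars[pos] <- sample(setdiff(bases, seq_chars[pos]), 1L)
    }
    genome[[1]] <- paste(seq_chars, collapse = "")
  }
  genome
}

# probability that an informative read supports inclusion, given the
# inclusion isoform fraction psi: SE/RI inclusion is read out on two
# junction classes versus one for exclusion, so inclusion reads are drawn
# with probability 2*psi/(1+psi); single-junction-per-side classes use psi
inclusion_read_prob <- function(type, psi) {
  if (type %in% c("SE", "RI")) 2 * psi / (1 + psi) else psi
}

#' Simulate junction-count tables from planted truth
#'
#' Per event, sample and condition: total informative reads are Poisson
#' with mean `depth`; the per-sample inclusion proportion is drawn from a
#' beta distribution with mean `psi_true` and intra-class correlation
#' `dispersion` (beta-binomial counts); inclusion reads are then drawn
#' binomially — at the junction-representation-adjusted probability for
#' SE/RI, where the inclusion isoform is read out on two junction classes
#' versus one for exclusion — and split uniformly across the event's
#' inclusion junction classes.
#'
#' @param sim result of [simulate_splice_genome()].
#' @param seed optional seed; defaults to `config seed + 1`.
#' @return junction-count data.frame in the [compute_psi()] layout.
#' @export
simulate_junction_counts <- function(sim, seed = NULL) {
  cfg <- sim$truth$config
  truth <- sim$truth$events
  psi_mat <- sim$truth$psi
  conds <- colnames(psi_mat)
  seed <- seed %||% (cfg$seed + 1L)
  with_seed(seed, {
    rows <- list()
    for (ci in seq_along(conds)) for (s in seq_len(cfg$n_samples)) {
      sample_id <- sprintf("%s_rep%d", conds[ci], s)
      total <- stats::rpois(nrow(truth), cfg$depth)
      mu <- psi_mat[, ci]
      p_s <- draw_sample_psi(mu, cfg$dispersion)
      p_read <- vapply(seq_len(nrow(truth)), function(i)
        inclusion_read_prob(truth$event_type[i], p_s[i]), numeric(1))
      inc <- stats::rbinom(nrow(truth), total, p_read)
      exc <- total - inc
      two_inc <- truth$event_type %in% c("SE", "RI", "MXE")
      inc_1 <- ifelse(two_inc, stats::rbinom(nrow(truth), inc, 0.5), inc)
      inc_2 <- ifelse(two_inc, inc - inc_1, NA_integer_)
      two_exc <- truth$event_type == "MXE"
      exc_1 <- ifelse(two_exc, stats::rbinom(nrow(truth), exc, 0.5), exc)
      exc_2 <- ifelse(two_exc, exc - exc_1, NA_integer_)
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = truth$event_id, sample_id = sample_id,
        condition = conds[ci], event_type = truth$event_type,
        inc_1 = inc_1, inc_2 = inc_2, exc_1 = exc_1, exc_2 = exc_2,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

# per-sample inclusion proportion: Beta with mean mu and intra-class
# correlation rho (degenerate at mu for rho = 0 or boundary mu)
draw_sample_psi <- function(mu, rho) {
  if (rho <= 0) return(mu)
  p <- mu
  inner <- mu > 0 & mu < 1
  if (any(inner)) {
    shape_tot <- (1 - rho) / rho
    p[inner] <- stats::rbeta(sum(inner), mu[inner] * shape_tot,
                             (1 - mu[inner]) * shape_tot)
  }
  p
}

#' Write a simulation to disk
#'
#' Emits `genome.fa`, `annotation.gtf`, `truth.json` (config echo, planted
#' events, per-condition true PSI, md5 checksums of the emitted files) and,
#' when `counts` is supplied, `counts.tsv`.
#'
#' @param sim result of [simulate_splice_genome()].
#' @param dir output directory (created if missing).
#' @param counts optional junction-count table.
#' @return named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gtf <- file.path(dir, "annotation.gtf")
  write_genome_fasta(sim$genome, fa)
  write_gtf(sim$model, gtf)
  paths <- c(fasta = fa, gtf = gtf)
  if (!is.null(counts)) {
    ct <- file.path(dir, "counts.tsv")
    utils::write.table(counts, ct, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, counts = ct)
  }
  cfg <- sim$truth$config
  manifest <- list(
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "motif")],
    motif = list(name = cfg$motif$name %||% "motif",
                 dna_query = cfg$motif$dna_query),
    events = sim$truth$events,
    psi_true = as.data.frame(sim$truth$psi),
    checksums = as.list(stats::setNames(tools::md5sum(paths),
                                        basename(paths))))
  tj <- file.path(dir, "truth.json")
  jsonlite::write_json(manifest, tj, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  paths <- c(paths, truth = tj)
  invisible(paths)
}
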