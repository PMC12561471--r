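#' Read a junction-count table
#'
#' @param path tab-separated file with columns `event_id`, `sample_id`,
#'   `condition`, `event_type`, `inc_1`, `inc_2`, `exc_1`, `exc_2`.
#' @return data.frame in the [compute_psi()] layout.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

default_pipeline_params <- function() {
  list(window_bp = 50L, min_reads = 10L, dpsi_min = 0.1, q_max = 0.05,
       orientation = "as_printed", motif_rna = "GCAGGUAAGUGCG",
       motif_name = "primary", max_distance = 200L, sense_only = TRUE)
}

#' Run the full splicing/motif pipeline
#'
#' Orchestrates the stages parse -> events -> scan -> target -> PSI/diff
#' over either real inputs (FASTA + GTF + counts TSV) or a simulation
#' block, writes every stage output as a plain-text table under `out_dir`,
#' and emits a JSON run manifest echoing every analysis parameter and the
#' md5 checksum of every input and output file, so that no analysis choice
#' is implicit and a rerun with the same config is byte-identical.
#'
#' @param config list with either `simulate` (a [sim_config()]) or paths
#'   `fasta`, `gtf` and optionally `counts`; an optional `conditions`
#'   character pair (a, b) for the differential contrast (defaults to the
#'   first two condition labels found); and any of the parameters
#'   `window_bp`, `min_reads`, `dpsi_min`, `q_max`, `orientation`,
#'   `motif_rna`, `motif_name`, `max_distance`, `sense_only`.
#' @param out_dir output directory.
#' @return invisibly, a list with every stage result (`model`, `events`,
#'   `hits`, `annotations`, `hit_summary`, `targeting`, `psi`,
#'   `expressed`, `diff`, `manifest`).
#' @export
run_splice_pipeline <- function(config, out_dir) {
  params <- default_pipeline_params()
  for (nm in intersect(names(config), names(params)))
    params[[nm]] <- config[[nm]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- character()
  counts <- NULL
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_splice_genome(config$simulate)
    counts <- simulate_junction_counts(sim)
    paths <- write_simulation(sim, file.path(out_dir, "inputs"), counts)
    genome <- sim$genome; model <- sim$model; truth <- sim$truth
    inputs <- paths
  } else {
    if (is.null(config$fasta) || !file.exists(config$fasta %||% ""))
      stop("parse stage: FASTA input missing and no simulation block")
    if (is.null(config$gtf) || !file.exists(config$gtf %||% ""))
      stop("parse stage: GTF input missing and no simulation block")
    genome <- read_genome_fasta(config$fasta)
    model <- read_gtf(config$gtf)
    inputs <- c(fasta = config$fasta, gtf = config$gtf)
    if (!is.null(config$counts)) {
      counts <- read_counts_tsv(config$counts)
      inputs <- c(inputs, counts = config$counts)
    }
  }
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- p
    p
  }

  # events stage
  events <- enumerate_events(model)
  emit(as.data.frame(events), "events.tsv")
  ec <- count_events_by_type(events)
  emit(data.frame(event_type = names(ec), n_events = as.integer(ec)),
       "event_counts.tsv")

  # scan stage
  motif <- suppressMessages(
    build_query(params$motif_rna, params$orientation, params$motif_name))
  hits <- scan_motif(genome, motif)
  p <- file.path(out_dir, "hits.bed")
  write_hits_bed(hits, p)
  outputs[["hits.bed"]] <- p
  ann <- annotate_hits(hits, model)
  emit(ann, "hit_annotations.tsv")
  hs <- summarize_hits(ann)
  emit(data.frame(metric = c("n_intron_hits", "n_exon_hits",
                             "n_junction_hits", "n_intergenic_hits",
                             "n_transcripts_hit", "n_genes_hit",
                             "sense_fraction"),
                  value = c(hs$n_intron_hits, hs$n_exon_hits,
                            hs$n_junction_hits, hs$n_intergenic_hits,
                            hs$n_transcripts_hit, hs$n_genes_hit,
                            hs$sense_fraction)),
       "hit_summary.tsv")
  emit(distance_density(ann, params$max_distance), "distance_density.tsv")

  # targeting stage
  targ <- suppressMessages(
    targeted_events(events, hits, params$window_bp, params$sense_only))
  emit(targ$summary, "targeting.tsv")
  prof <- suppressMessages(
    event_site_distance_profile(events, hits, params$max_distance,
                                sense_only = params$sense_only))
  emit(prof, "site_distance_profile.tsv")

  # quantification stage
  psi <- NULL; expressed <- NULL; diff <- NULL
  if (!is.null(counts)) {
    psi <- compute_psi(counts, params$min_reads)
    emit(psi, "psi.tsv")
    conds <- unique(counts$condition)
    expressed <- do.call(rbind, lapply(conds, function(cn)
      data.frame(condition = cn, event_type = EVENT_TYPES,
                 n_expressed = as.integer(
                   count_expressed_events(psi, cn, params$min_reads)))))
    emit(expressed, "expressed_events.tsv")
    pair <- config$conditions %||% conds[seq_len(min(2L, length(conds)))]
    if (length(pair) == 2L) {
      diff <- suppressMessages(differential_inclusion(
        counts, pair[1], pair[2], params$dpsi_min, params$q_max,
        params$min_reads))
      emit(diff$results, "differential.tsv")
      emit(diff$tally, "differential_tally.tsv")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("splicescan")),
    params = params,
    conditions = if (!is.null(diff))
      unlist(diff$params[c("condition_a", "condition_b")]),
    seed = if (!is.null(config$simulate)) config$simulate$seed,
    inputs = as.list(stats::setNames(tools::md5sum(unlist(inputs)),
                                     basename(unlist(inputs)))),
    outputs = as.list(stats::setNames(tools::md5sum(unlist(outputs)),
                                      basename(unlist(outputs)))),
    stats = model_stats(model))
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  invisible(list(model = model, events = events, hits = hits,
                 annotations = ann, hit_summary = hs, targeting = targ,
                 distance = NULL, psi = psi, expressed = expressed,
                 diff = diff, truth = truth, manifest = manifest,
                 out_dir = out_dir))
}

#' Render a plain-text report from pipeline outputs
#'
#' Summarizes per-class event counts, motif hit classification, targeted
#' proportions with confidence intervals, the donor/acceptor distance
#' histogram peak, and differential up/down tallies. Sections whose stage
#' outputs are absent are listed as missing rather than failing.
#'
#' @param out_dir pipeline output directory.
#' @param path optional path to also write the report to
#'   (`report.txt` under `out_dir` by default); use NA to skip writing.
#' @return character vector of report lines, invisibly; the report is also
#'   printed.
#' @export
render_report <- function(out_dir, path = file.path(out_dir, "report.txt")) {
  lines <- c("splicescan pipeline report", strrep("=", 26))
  have <- function(f) file.exists(file.path(out_dir, f))
  rd <- function(f) utils::read.delim(file.path(out_dir, f),
                                      stringsAsFactors = FALSE)
  missing <- character()
  if (have("event_counts.tsv")) {
    ec <- rd("event_counts.tsv")
    lines <- c(lines, "", "Alternative-splicing events by class:")
    if (sum(ec$n_events) == 0) {
      lines <- c(lines, "  no events")
    } else {
      lines <- c(lines, sprintf("  %-4s %6d", ec$event_type, ec$n_events))
    }
  } else missing <- c(missing, "event_counts.tsv")
  if (have("hit_summary.tsv")) {
    hs <- rd("hit_summary.tsv")
    lines <- c(lines, "", "Motif hits:",
               sprintf("  %-18s %s", hs$metric, format(hs$value)))
  } else missing <- c(missing, "hit_summary.tsv")
  if (have("targeting.tsv")) {
    tg <- rd("targeting.tsv")
    lines <- c(lines, "",
               sprintf("Targeted proportions (window %d bp):",
                       tg$window_bp[1]))
    if (all(tg$n_events == 0)) {
      lines <- c(lines, "  no events")
    } else {
      t2 <- tg[tg$n_events > 0, ]
      lines <- c(lines, sprintf(
        "  %-4s %4d/%4d = %.3f [%.3f, %.3f]", t2$event_type,
        t2$n_targeted, t2$n_events, t2$fraction_targeted, t2$ci_low,
        t2$ci_high))
    }
  } else missing <- c(missing, "targeting.tsv")
  if (have("distance_density.tsv")) {
    dd <- rd("distance_density.tsv")
    if (nrow(dd)) {
      pk_d <- dd$bin_start[which.max(dd$donor_count)]
      pk_a <- dd$bin_start[which.max(dd$acceptor_count)]
      lines <- c(lines, "", sprintf(
        "Hit-to-splice-site distance peaks: donor %d bp (n=%d), acceptor %d bp (n=%d)",
        pk_d, max(dd$donor_count), pk_a, max(dd$acceptor_count)))
    }
  } else missing <- c(missing, "distance_density.tsv")
  if (have("differential_tally.tsv")) {
    tl <- rd("differential_tally.tsv")
    tl <- tl[tl$n_tested > 0, ]
    lines <- c(lines, "", "Differential inclusion (b vs a):",
               sprintf("  %-4s %5d tested, %4d increased, %4d decreased",
                       tl$event_type, tl$n_tested, tl$increased,
                       tl$decreased))
  } else missing <- c(missing, "differential_tally.tsv")
  if (length(missing))
    lines <- c(lines, "", paste("Missing sections:",
                                paste(missing, collapse = ", ")))
  if (!is.na(path)) writeLines(lines, path)
  cat(lines, sep = "\n")
  invisible(lines)
}

#' Barplot of event counts per class
#'
#' @param event_counts named vector from [count_events_by_type()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_event_counts <- function(event_counts, ...) {
  graphics::barplot(event_counts, ylab = "events",
                    xlab = "event class", ...)
}

#' Histogram of hit-to-splice-site distances
#'
#' @param density data.frame from [distance_density()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, NULL.
#' @export
plot_distance_density <- function(density, ...) {
  graphics::plot(density$bin_start, density$donor_count, type = "h",
                 xlab = "distance to splice site (bp)", ylab = "hits",
                 col = "steelblue", ...)
  graphics::points(density$bin_start, density$acceptor_count, type = "h",
                   col = "tomato")
  graphics::legend("topright", legend = c("donor", "acceptor"),
                   col = c("steelblue", "tomato"), lty = 1, bty = "n")
  invisible(NULL)
}
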