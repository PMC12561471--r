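#' Which alternative-splicing events are targeted by a motif
#'
#' An event is targeted when at least one motif hit interval intersects the
#' window `[site - window_bp, site + window_bp + 1)` around any of the
#' event's splice sites, with the hit on the event's (sense) strand by
#' default. A secondary, more permissive definition — any sense hit
#' anywhere in the event's coordinate span — is reported alongside as
#' `targeted_span`.
#'
#' @param events a `splice_events` data.frame.
#' @param hits data.frame from [scan_motif()].
#' @param window_bp half-width of the splice-site window in bp
#'   (default 50).
#' @param sense_only only count hits whose strand matches the event strand
#'   (default TRUE).
#' @return list with `events`: the input plus logical columns `targeted`
#'   and `targeted_span`; and `summary`: per-class data.frame
#'   (`event_type`, `n_events`, `n_targeted`, `fraction_targeted`,
#'   `ci_low`, `ci_high` exact binomial 95% CI, `fraction_span`,
#'   `window_bp`).
#' @export
targeted_events <- function(events, hits, window_bp = 50L,
                            sense_only = TRUE) {
  stopifnot(window_bp >= 0)
  n <- nrow(events)
  targeted <- logical(n)
  targeted_span <- logical(n)
  if (n && nrow(hits)) {
    sites <- event_sites(events)
    coords <- event_coords(events)
    for (i in seq_len(n)) {
      h <- hits[hits$contig == events$contig[i], , drop = FALSE]
      if (sense_only)
        h <- h[h$strand == events$strand[i], , drop = FALSE]
      if (!nrow(h)) next
      for (s in sites[[i]]) {
        lo <- s - window_bp; hi <- s + window_bp + 1L
        if (any(h$start < hi & h$end > lo)) { targeted[i] <- TRUE; break }
      }
      cs <- coords[[i]]
      targeted_span[i] <- any(h$start < max(cs) & h$end > min(cs))
    }
  }
  ev <- as.data.frame(events)
  ev$targeted <- targeted
  ev$targeted_span <- targeted_span
  summ <- do.call(rbind, lapply(EVENT_TYPES, function(ty) {
    sel <- ev$event_type == ty
    ne <- sum(sel); nt <- sum(ev$targeted[sel])
    if (ne > 0) {
      ci <- stats::binom.test(nt, ne)$conf.int
    } else ci <- c(NA_real_, NA_real_)
    data.frame(event_type = ty, n_events = ne, n_targeted = nt,
               fraction_targeted = if (ne) nt / ne else 0,
               ci_low = ci[1], ci_high = ci[2],
               fraction_span = if (ne) mean(ev$targeted_span[sel]) else 0,
               window_bp = window_bp)
  }))
  if (any(summ$n_events == 0))
    message("event classes with zero events: ",
            paste(summ$event_type[summ$n_events == 0], collapse = ", "))
  list(events = ev, summary = summ)
}

#' Distance profile of motif hits around event splice sites
#'
#' For each event class and each site role the signed distance from the
#' nearest (sense) hit to the site is binned within
#' `[-max_distance, max_distance]`. Distances follow the same convention as
#' [annotate_hits()]: measured from the hit's 5'-most base in transcription
#' orientation, positive downstream of the site. Site roles are labeled in
#' transcription orientation per class (e.g. for SE:
#' `upstream_exon_3p`, `alt_exon_5p`, `alt_exon_3p`, `downstream_exon_5p`).
#'
#' @param events a `splice_events` data.frame.
#' @param hits data.frame from [scan_motif()].
#' @param max_distance window half-width in bp (> 0).
#' @param binwidth bin width in bp (default 1).
#' @param sense_only restrict to sense-strand hits (default TRUE).
#' @return data.frame `event_type`, `site_role`, `bin_start`, `count`.
#' @export
event_site_distance_profile <- function(events, hits, max_distance,
                                        binwidth = 1L, sense_only = TRUE) {
  stopifnot(max_distance > 0)
  recs <- list()
  if (nrow(events) && nrow(hits)) {
    sites <- event_sites(events)
    for (i in seq_len(nrow(events))) {
      h <- hits[hits$contig == events$contig[i], , drop = FALSE]
      if (sense_only)
        h <- h[h$strand == events$strand[i], , drop = FALSE]
      if (!nrow(h)) next
      strand <- events$strand[i]
      roles <- event_site_roles(events$event_type[i], sites[[i]], strand,
                                event_coords(events[i, , drop = FALSE])[[1]])
      anchor <- if (strand == "+") h$start else h$end - 1L
      for (k in seq_along(sites[[i]])) {
        s <- sites[[i]][k]
        d <- if (strand == "+") anchor - s else s - 1L - anchor
        d <- d[abs(d) <= max_distance]
        if (!length(d)) next
        dmin <- d[which.min(abs(d))]
        recs[[length(recs) + 1L]] <- data.frame(
          event_type = events$event_type[i], site_role = roles[k],
          distance = dmin)
      }
    }
  }
  present <- unique(events$event_type)
  if (!length(recs)) {
    if (length(setdiff(EVENT_TYPES, present)))
      message("no events for classes: ",
              paste(setdiff(EVENT_TYPES, present), collapse = ", "))
    return(data.frame(event_type = character(), site_role = character(),
                      bin_start = integer(), count = integer()))
  }
  rec <- do.call(rbind, recs)
  breaks <- seq(-max_distance, max_distance + binwidth, by = binwidth)
  rec$bin <- breaks[findInterval(rec$distance, breaks)]
  agg <- stats::aggregate(list(count = rec$distance),
                          by = list(event_type = rec$event_type,
                                    site_role = rec$site_role,
                                    bin_start = rec$bin),
                          FUN = length)
  agg[order(agg$event_type, agg$site_role, agg$bin_start), , drop = FALSE]
}

# transcription-oriented labels for the splice sites of one event;
# `sites` is the sorted genomic-ascending site vector stored on the event,
# `coords` the canonical tuple (for A3SS/A5SS: shared, alt1, alt2)
event_site_roles <- function(type, sites, strand, coords = NULL) {
  if (type %in% c("A3SS", "A5SS")) {
    labs <- character(length(sites))
    labs[sites == coords[1]] <- "shared_site"
    labs[sites == coords[2]] <- "alt_site_1"
    labs[sites == coords[3]] <- "alt_site_2"
    return(labs)
  }
  fwd <- switch(type,
    SE = c("upstream_exon_3p", "alt_exon_5p", "alt_exon_3p",
           "downstream_exon_5p"),
    RI = c("intron_5p", "intron_3p"),
    MXE = c("upstream_exon_3p", "exon_a_5p", "exon_a_3p", "exon_b_5p",
            "exon_b_3p", "downstream_exon_5p"))
  if (strand == "+") fwd else rev(fwd)
}

#' Compare targeted proportions between two runs
#'
#' Per event class, a two-sided exact test (Fisher) on the 2x2 table of
#' targeted vs untargeted counts in the two summaries, with
#' Benjamini-Hochberg correction across classes.
#'
#' @param summary_a,summary_b `summary` data.frames from
#'   [targeted_events()].
#' @return data.frame `event_type`, `fraction_a`, `fraction_b`,
#'   `difference` (a - b), `p_value`, `q_value`.
#' @export
compare_targeting <- function(summary_a, summary_b) {
  common <- intersect(summary_a$event_type, summary_b$event_type)
  skipped <- setdiff(union(summary_a$event_type, summary_b$event_type),
                     common)
  if (length(skipped))
    warning("classes present in only one summary skipped: ",
            paste(skipped, collapse = ", "))
  rows <- lapply(common, function(ty) {
    a <- summary_a[summary_a$event_type == ty, ]
    b <- summary_b[summary_b$event_type == ty, ]
    if (a$n_events == 0 || b$n_events == 0) return(NULL)
    tab <- matrix(c(a$n_targeted, a$n_events - a$n_targeted,
                    b$n_targeted, b$n_events - b$n_targeted), nrow = 2)
    p <- stats::fisher.test(tab)$p.value
    data.frame(event_type = ty, fraction_a = a$fraction_targeted,
               fraction_b = b$fraction_targeted,
               difference = a$fraction_targeted - b$fraction_targeted,
               p_value = p)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep))
    warning("classes with zero events skipped: ",
            paste(common[!keep], collapse = ", "))
  out <- do.call(rbind, rows[keep])
  if (is.null(out))
    return(data.frame(event_type = character(), fraction_a = numeric(),
                      fraction_b = numeric(), difference = numeric(),
                      p_value = numeric(), q_value = numeric()))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}
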