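# effective inclusion/exclusion read counts for one row of a junction-count
# table. Two-junction read classes (SE inclusion, RI boundary reads, both
# MXE sides) are averaged so that PSI is not biased toward events with two
# supporting junction classes.
effective_counts <- function(counts) {
  inc_cols <- cbind(counts$inc_1, counts$inc_2)
  exc_cols <- cbind(counts$exc_1, counts$exc_2)
  if (any(inc_cols < 0, na.rm = TRUE) || any(exc_cols < 0, na.rm = TRUE))
    stop("negative junction count")
  data.frame(inc = rowMeans(inc_cols, na.rm = TRUE),
             exc = rowMeans(exc_cols, na.rm = TRUE))
}

#' Percent-spliced-in from junction counts
#'
#' For each row of a junction-count table, PSI is the ratio of effective
#' inclusion to total informative reads: for skipped exons
#' `PSI = I / (I + S)` with `I` the mean of the upstream and downstream
#' inclusion-junction reads and `S` the skipping-junction reads; for
#' retained introns `PSI = R / (R + J)` with `R` the mean of the two
#' exon-intron boundary-spanning read classes and `J` the spliced-junction
#' reads; for A5SS/A3SS the proximal-junction share; for MXE the exon-A
#' share with each side averaged over its two junctions. PSI is undefined
#' (NA) when the total falls below `min_reads`.
#'
#' @param counts data.frame with columns `event_id`, `sample_id`,
#'   `condition`, `event_type`, `inc_1`, `inc_2`, `exc_1`, `exc_2`
#'   (NA for read classes the event type does not have).
#' @param min_reads minimum effective informative reads for PSI to be
#'   defined (default 10).
#' @return data.frame `event_id`, `sample_id`, `condition`, `event_type`,
#'   `psi`, `total_informative_reads`.
#' @examples
#' compute_psi(data.frame(event_id = "e", sample_id = "s", condition = "WT",
#'                        event_type = "SE", inc_1 = 6, inc_2 = 4,
#'                        exc_1 = 5, exc_2 = NA))
#' @export
compute_psi <- function(counts, min_reads = 10) {
  eff <- effective_counts(counts)
  total <- eff$inc + eff$exc
  psi <- ifelse(total >= min_reads, eff$inc / total, NA_real_)
  data.frame(event_id = counts$event_id, sample_id = counts$sample_id,
             condition = counts$condition, event_type = counts$event_type,
             psi = psi, total_informative_reads = total)
}

#' Count events with quantifiable PSI in a condition
#'
#' An annotated event counts as expressed in a condition when its total
#' informative reads reach `min_reads` in at least half of that
#' condition's samples.
#'
#' @param psi_table data.frame from [compute_psi()].
#' @param condition condition label to count in.
#' @param min_reads read threshold.
#' @return named integer vector over event classes.
#' @export
count_expressed_events <- function(psi_table, condition, min_reads = 10) {
  p <- psi_table[psi_table$condition == condition, , drop = FALSE]
  n_samples <- length(unique(p$sample_id))
  out <- stats::setNames(integer(length(EVENT_TYPES)), EVENT_TYPES)
  if (!nrow(p)) return(out)
  ok <- stats::aggregate(
    list(n_ok = p$total_informative_reads >= min_reads),
    by = list(event_id = p$event_id, event_type = p$event_type), FUN = sum)
  expressed <- ok[ok$n_ok >= n_samples / 2, , drop = FALSE]
  tab <- table(factor(expressed$event_type, levels = EVENT_TYPES))
  out[] <- as.integer(tab)
  out
}

# shared (across events) beta-binomial intra-class correlation, by the
# method of moments on per-replicate inclusion proportions: the summed
# within-condition chi-square against its degrees of freedom gives the
# variance inflation, converted to rho with the mean per-sample depth.
# NA when no condition has >= 2 informative replicates.
estimate_shared_rho <- function(d) {
  chi <- 0; df <- 0; mtot <- 0; k <- 0
  for (grp in split(d, list(d$event_id, d$condition), drop = TRUE)) {
    tot <- grp$inc + grp$exc
    keep <- tot > 0
    if (sum(keep) < 2) next
    tot <- tot[keep]; inc <- grp$inc[keep]
    pbar <- sum(inc) / sum(tot)
    if (pbar <= 0 || pbar >= 1) next
    chi <- chi + sum(tot * (inc / tot - pbar)^2) / (pbar * (1 - pbar))
    df <- df + sum(keep) - 1
    mtot <- mtot + sum(tot); k <- k + sum(keep)
  }
  if (df == 0) return(NA_real_)
  phi <- chi / df
  mbar <- mtot / k
  min(0.99, max(0, (phi - 1) / (mbar - 1)))
}

# beta-binomial log-likelihood (continuous-count quasi version, additive
# constants dropped) at mean mu and shape total s = (1 - rho)/rho
bb_loglik <- function(mu, inc, tot, s) {
  sum(lbeta(inc + mu * s, tot - inc + (1 - mu) * s)) -
    length(inc) * lbeta(mu * s, (1 - mu) * s)
}

# likelihood-ratio test of equal inclusion proportion across conditions,
# with rho fixed at the shared estimate
bb_lrt <- function(inc_a, tot_a, inc_b, tot_b, rho) {
  s <- (1 - rho) / rho
  fit <- function(inc, tot) {
    opt <- stats::optimize(function(mu) -bb_loglik(mu, inc, tot, s),
                           interval = c(1e-6, 1 - 1e-6))
    -opt$objective
  }
  ll_alt <- fit(inc_a, tot_a) + fit(inc_b, tot_b)
  ll_null <- fit(c(inc_a, inc_b), c(tot_a, tot_b))
  stat <- max(0, 2 * (ll_alt - ll_null))
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Differential inclusion between two conditions
#'
#' Per event, the per-replicate effective inclusion/exclusion counts are
#' compared between conditions. The default test is a beta-binomial
#' likelihood-ratio test with an intra-class correlation shared across
#' events (method-of-moments estimate), so that overdispersion across
#' replicates does not inflate the false discovery rate; when no
#' overdispersion is estimable (single replicates, or a zero estimate) it
#' reduces to the two-sided exact test on the pooled 2x2 table, which
#' `test = "pooled"` also selects unconditionally. Benjamini-Hochberg
#' correction is applied across all tested events. An event is called
#' `increased` when `q <= q_max` and `delta_psi >= dpsi_min` (where
#' `delta_psi = PSI(b) - PSI(a)` from pooled counts), `decreased`
#' symmetrically, otherwise `unchanged`. Events with zero informative
#' reads in either condition are excluded.
#'
#' @param counts junction-count table (see [compute_psi()]).
#' @param condition_a,condition_b condition labels; `delta_psi` is b - a.
#' @param dpsi_min minimum |delta PSI| for a call (default 0.1).
#' @param q_max FDR threshold (default 0.05).
#' @param min_reads per-sample threshold used for the reported
#'   replicate-level PSI (default 10); testing uses all informative reads.
#' @param test `"betabin"` (replicate-aware, default) or `"pooled"`
#'   (exact test on pooled counts).
#' @return a `splice_diff` object: list with `results` (per-event
#'   data.frame: `event_id`, `event_type`, `psi_a`, `psi_b`, `delta_psi`,
#'   `p_value`, `q_value`, `direction`), `tally` (per-class increased /
#'   decreased counts), `params` (including the estimated `rho`),
#'   `n_excluded`.
#' @export
differential_inclusion <- function(counts, condition_a, condition_b,
                                   dpsi_min = 0.1, q_max = 0.05,
                                   min_reads = 10,
                                   test = c("betabin", "pooled")) {
  test <- match.arg(test)
  stopifnot(condition_a %in% counts$condition,
            condition_b %in% counts$condition)
  eff <- effective_counts(counts)
  d <- data.frame(event_id = counts$event_id,
                  event_type = counts$event_type,
                  condition = counts$condition,
                  inc = eff$inc, exc = eff$exc)
  d <- d[d$condition %in% c(condition_a, condition_b), , drop = FALSE]
  pool <- stats::aggregate(d[, c("inc", "exc")],
                           by = list(event_id = d$event_id,
                                     event_type = d$event_type,
                                     condition = d$condition), FUN = sum)
  wide <- merge(
    pool[pool$condition == condition_a,
         c("event_id", "event_type", "inc", "exc")],
    pool[pool$condition == condition_b, c("event_id", "inc", "exc")],
    by = "event_id", suffixes = c("_a", "_b"))
  tot_a <- wide$inc_a + wide$exc_a
  tot_b <- wide$inc_b + wide$exc_b
  excl <- tot_a == 0 | tot_b == 0
  if (any(excl))
    message(sum(excl),
            " event(s) with zero informative reads in a condition excluded")
  wide <- wide[!excl, , drop = FALSE]
  if (!nrow(wide)) stop("no testable events")
  psi_a <- wide$inc_a / (wide$inc_a + wide$exc_a)
  psi_b <- wide$inc_b / (wide$inc_b + wide$exc_b)
  rho <- if (test == "betabin") estimate_shared_rho(d) else NA_real_
  use_bb <- test == "betabin" && !is.na(rho) && rho > 0
  if (use_bb) {
    reps <- split(d, d$event_id)
    p <- vapply(wide$event_id, function(eid) {
      r <- reps[[eid]]
      a <- r[r$condition == condition_a, ]
      b <- r[r$condition == condition_b, ]
      bb_lrt(a$inc, a$inc + a$exc, b$inc, b$inc + b$exc, rho)
    }, numeric(1))
  } else {
    p <- vapply(seq_len(nrow(wide)), function(i) {
      tab <- round(matrix(c(wide$inc_a[i], wide$exc_a[i],
                            wide$inc_b[i], wide$exc_b[i]), nrow = 2))
      stats::fisher.test(tab)$p.value
    }, numeric(1))
  }
  q <- stats::p.adjust(p, method = "BH")
  delta <- psi_b - psi_a
  direction <- ifelse(q <= q_max & delta >= dpsi_min, "increased",
               ifelse(q <= q_max & delta <= -dpsi_min, "decreased",
                      "unchanged"))
  res <- data.frame(event_id = wide$event_id, event_type = wide$event_type,
                    psi_a = psi_a, psi_b = psi_b, delta_psi = delta,
                    p_value = p, q_value = q, direction = direction)
  res <- res[order(res$event_id), , drop = FALSE]
  rownames(res) <- NULL
  tally <- do.call(rbind, lapply(EVENT_TYPES, function(ty) {
    r <- res[res$event_type == ty, , drop = FALSE]
    data.frame(event_type = ty, n_tested = nrow(r),
               increased = sum(r$direction == "increased"),
               decreased = sum(r$direction == "decreased"))
  }))
  structure(list(results = res, tally = tally,
                 params = list(condition_a = condition_a,
                               condition_b = condition_b,
                               dpsi_min = dpsi_min, q_max = q_max,
                               min_reads = min_reads, test = test,
                               rho = rho),
                 n_excluded = sum(excl)),
            class = "splice_diff")
}

#' @export
print.splice_diff <- function(x, ...) {
  cat(sprintf("Differential inclusion: %s vs %s (delta = %s - %s)\n",
              x$params$condition_b, x$params$condition_a,
              x$params$condition_b, x$params$condition_a))
  cat(sprintf("  %d events tested (q <= %.3g, |dPSI| >= %.3g); %d excluded\n",
              nrow(x$results), x$params$q_max, x$params$dpsi_min,
              x$n_excluded))
  tl <- x$tally[x$tally$n_tested > 0, , drop = FALSE]
  for (i in seq_len(nrow(tl)))
    cat(sprintf("  %-4s: %d tested, %d increased, %d decreased\n",
                tl$event_type[i], tl$n_tested[i], tl$increased[i],
                tl$decreased[i]))
  invisible(x)
}

#' @export
summary.splice_diff <- function(object, ...) {
  object$tally
}

#' Exon-level RPKM
#'
#' Reads per kilobase of region per million mapped reads:
#' `rpkm = read_count / (region_length/1000) / (library_size/1e6)`.
#' Used for user-supplied sub-exonic regions (e.g. an exon's 5'UTR part)
#' when comparing coverage of specific exons between conditions.
#'
#' @param read_count reads overlapping the region (vectorized).
#' @param region_length region length in bp (> 0).
#' @param library_size total mapped reads in the library (> 0).
#' @param region_id optional region labels.
#' @return data.frame `region_id`, `read_count`, `region_length`,
#'   `library_size`, `rpkm`.
#' @examples
#' exon_rpkm(100, 1000, 1e6)  # rpkm = 100
#' @export
exon_rpkm <- function(read_count, region_length, library_size,
                      region_id = NULL) {
  if (any(region_length <= 0)) stop("region_length must be > 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(read_count < 0)) stop("read_count must be >= 0")
  rpkm <- read_count / (region_length / 1000) / (library_size / 1e6)
  data.frame(region_id = region_id %||% seq_along(rpkm),
             read_count = read_count, region_length = region_length,
             library_size = library_size, rpkm = rpkm)
}
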