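planted_case <- function(seed = 31, n_genes = 80) {
  sim <- simulate_splice_genome(sim_config(seed = seed, n_genes = n_genes))
  list(sim = sim,
       events = enumerate_events(sim$model),
       hits = scan_motif(sim$genome, sim$truth$config$motif))
}

test_that("events with a planted junction hit are targeted; others are not", {
  pc <- planted_case()
  tg <- suppressMessages(targeted_events(pc$events, pc$hits, window_bp = 50))
  truth <- pc$sim$truth$events
  m <- merge(tg$events[, c("event_id", "targeted")],
             truth[, c("event_id", "planted")])
  expect_equal(m$targeted, m$planted)
  s <- tg$summary
  expect_true(all(s$n_targeted <= s$n_events))
  expect_true(all(s$fraction_targeted >= s$ci_low - 1e-9 &
                    s$fraction_targeted <= s$ci_high + 1e-9,
                  na.rm = TRUE))
})

test_that("zero hits give zero targeting; saturation gives one", {
  pc <- planted_case(seed = 32, n_genes = 30)
  no_hits <- pc$hits[0, ]
  tg0 <- suppressMessages(targeted_events(pc$events, no_hits, 50))
  expect_true(all(tg0$summary$fraction_targeted == 0))

  # one sense hit planted at the first splice site of every event
  sites <- lapply(strsplit(pc$events$splice_sites, ","), as.integer)
  all_hits <- data.frame(contig = pc$events$contig,
                         start = sapply(sites, `[`, 1) - 5L,
                         end = sapply(sites, `[`, 1) + 8L,
                         strand = pc$events$strand, motif = "m")
  tg1 <- suppressMessages(targeted_events(pc$events, all_hits, 0))
  expect_true(all(tg1$summary$fraction_targeted[
    tg1$summary$n_events > 0] == 1))
})

test_that("targeted fraction is monotonically non-decreasing in the window", {
  pc <- planted_case(seed = 33, n_genes = 60)
  # shift hits away from sites so the window matters
  hits <- pc$hits
  hits$start <- hits$start - 40L
  hits$end <- hits$end - 40L
  fr <- sapply(c(0, 10, 25, 50, 100, 200), function(w) {
    s <- suppressMessages(targeted_events(pc$events, hits, w))$summary
    sum(s$n_targeted) / max(1, sum(s$n_events))
  })
  expect_true(all(diff(fr) >= 0))
})

test_that("antisense hits only count when sense_only is off", {
  pc <- planted_case(seed = 34, n_genes = 50)
  anti <- pc$hits
  anti$strand <- ifelse(anti$strand == "+", "-", "+")
  tg_sense <- suppressMessages(targeted_events(pc$events, anti, 50))
  expect_equal(sum(tg_sense$summary$n_targeted), 0)
  tg_any <- suppressMessages(
    targeted_events(pc$events, anti, 50, sense_only = FALSE))
  expect_true(sum(tg_any$summary$n_targeted) > 0)
})

test_that("site distance profiles recover the planted offsets per class", {
  pc <- planted_case(seed = 35, n_genes = 120)
  prof <- suppressMessages(
    event_site_distance_profile(pc$events, pc$hits, max_distance = 100))
  planted_types <- unique(
    pc$sim$truth$events$event_type[pc$sim$truth$events$planted])
  expect_setequal(unique(prof$event_type), planted_types)
  # every planted class shows hits straddling a site: counts concentrated
  # just upstream of the boundary (within one motif length)
  for (ty in planted_types) {
    near <- prof$bin_start >= -12 & prof$bin_start <= -1 &
      prof$event_type == ty
    expect_true(any(near), label = ty)
  }

  # RI sites are separated by a full intron (> max_distance), so a planted
  # hit registers only at its own site and all bins sit within the motif
  ri_only <- pc$events[pc$events$event_type == "RI", ]
  prof_ri <- suppressMessages(
    event_site_distance_profile(ri_only, pc$hits, 100))
  expect_true(all(prof_ri$event_type == "RI"))
  expect_true(all(prof_ri$site_role %in% c("intron_5p", "intron_3p")))
  expect_true(all(prof_ri$bin_start >= -12 & prof_ri$bin_start <= -1))
})

test_that("targeting comparison matches the hypergeometric oracle", {
  mk_summary <- function(n_t, n_e) {
    data.frame(event_type = "SE", n_events = n_e, n_targeted = n_t,
               fraction_targeted = n_t / n_e, ci_low = NA, ci_high = NA,
               fraction_span = NA, window_bp = 50)
  }
  same <- compare_targeting(mk_summary(30, 100), mk_summary(30, 100))
  expect_equal(same$difference, 0)
  expect_equal(same$p_value, 1)

  cmp <- compare_targeting(mk_summary(40, 100), mk_summary(20, 100))
  expect_equal(cmp$difference, 0.2)
  expect_equal(cmp$p_value, oracle_fisher_p(40, 60, 20, 80),
               tolerance = 1e-10)
  expect_equal(cmp$p_value,
               stats::fisher.test(matrix(c(40, 60, 20, 80), 2))$p.value,
               tolerance = 1e-12)

  empty <- mk_summary(0, 0)
  expect_warning(out <- compare_targeting(mk_summary(40, 100), empty),
                 "zero events")
  expect_equal(nrow(out), 0)
})

test_that("background-only planting shows no class-specific enrichment", {
  # planting probability equal across classes: per-class fractions should
  # be statistically indistinguishable in most seeded replicates
  n_sig <- 0L
  for (seed in 41:50) {
    cfg <- sim_config(seed = seed, n_genes = 150,
                      p_plant = c(SE = 0.25, RI = 0.25, MXE = 0.25,
                                  A3SS = 0.25, A5SS = 0.25))
    sim <- simulate_splice_genome(cfg)
    ev <- enumerate_events(sim$model)
    hits <- scan_motif(sim$genome, cfg$motif)
    s <- suppressMessages(targeted_events(ev, hits, 50))$summary
    s <- s[s$n_events > 0, ]
    p <- suppressWarnings(stats::fisher.test(
      cbind(s$n_targeted, s$n_events - s$n_targeted),
      simulate.p.value = TRUE, B = 2000)$p.value)
    if (p < 0.05) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig, 2)
})
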