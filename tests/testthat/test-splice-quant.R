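count_row <- function(type, inc_1, exc_1, inc_2 = NA, exc_2 = NA,
                      event_id = "e1", sample_id = "s1", condition = "WT") {
  data.frame(event_id = event_id, sample_id = sample_id,
             condition = condition, event_type = type,
             inc_1 = inc_1, inc_2 = inc_2, exc_1 = exc_1, exc_2 = exc_2)
}

test_that("PSI arithmetic follows the stated junction formulas", {
  expect_equal(compute_psi(count_row("SE", 10, 0, inc_2 = 10))$psi, 1.0)
  expect_equal(compute_psi(count_row("RI", 0, 20, inc_2 = 0))$psi, 0.0)
  expect_equal(compute_psi(count_row("SE", 6, 5, inc_2 = 4))$psi, 0.5)
  # A5SS: proximal / (proximal + distal)
  expect_equal(compute_psi(count_row("A5SS", 30, 10))$psi, 0.75)
  # MXE: exon-A share with both sides averaged over their junctions
  expect_equal(compute_psi(count_row("MXE", 8, 2, inc_2 = 4, exc_2 = 4),
                           min_reads = 0)$psi, 6 / 9)
  expect_error(compute_psi(count_row("SE", -1, 5)), "negative")
})

test_that("PSI is undefined below min_reads and monotone in inclusion", {
  low <- compute_psi(count_row("SE", 3, 2, inc_2 = 3), min_reads = 10)
  expect_true(is.na(low$psi))
  expect_equal(low$total_informative_reads, 5)

  psis <- sapply(1:30, function(i)
    compute_psi(count_row("SE", i, 10, inc_2 = i), min_reads = 0)$psi)
  expect_true(all(diff(psis) > 0))
})

test_that("expressed-event counts respect the half-of-samples rule", {
  counts <- rbind(
    count_row("SE", 50, 50, inc_2 = 50, sample_id = "a"),
    count_row("SE", 50, 50, inc_2 = 50, sample_id = "b"),
    count_row("SE", 1, 1, inc_2 = 1, sample_id = "c"),
    count_row("RI", 1, 1, inc_2 = 1, event_id = "e2", sample_id = "a"),
    count_row("RI", 1, 1, inc_2 = 1, event_id = "e2", sample_id = "b"),
    count_row("RI", 1, 1, inc_2 = 1, event_id = "e2", sample_id = "c"))
  psi <- compute_psi(counts, min_reads = 10)
  n <- count_expressed_events(psi, "WT", min_reads = 10)
  expect_equal(unname(n["SE"]), 1L)  # 2 of 3 samples pass
  expect_equal(unname(n["RI"]), 0L)
  deep <- count_expressed_events(psi, "WT", min_reads = 0)
  expect_equal(sum(deep), 2L)
})

test_that("expressed-event counts decrease monotonically in min_reads", {
  sim <- simulate_splice_genome(sim_config(seed = 71, n_genes = 60))
  counts <- simulate_junction_counts(sim)
  psi <- compute_psi(counts, min_reads = 0)
  ns <- sapply(c(0, 20, 50, 80, 120, 200), function(mr)
    sum(count_expressed_events(psi, "WT", min_reads = mr)))
  expect_true(all(diff(ns) <= 0))
  expect_equal(ns[1], 60)
  expect_equal(ns[length(ns)], 0)
})

test_that("differential inclusion reports delta PSI with exact p-values", {
  counts <- rbind(
    count_row("RI", 90, 10, inc_2 = 90, condition = "WT"),
    count_row("RI", 10, 90, inc_2 = 10, sample_id = "s2",
              condition = "cKO"))
  d <- differential_inclusion(counts, "WT", "cKO", min_reads = 0)
  expect_equal(d$results$delta_psi, -0.8)
  expect_equal(d$results$p_value, oracle_fisher_p(90, 10, 10, 90),
               tolerance = 1e-10)

  same <- rbind(
    count_row("SE", 40, 20, inc_2 = 40, condition = "WT"),
    count_row("SE", 40, 20, inc_2 = 40, sample_id = "s2",
              condition = "cKO"))
  d0 <- differential_inclusion(same, "WT", "cKO")
  expect_equal(d0$results$delta_psi, 0)
  expect_equal(sum(d0$tally$increased) + sum(d0$tally$decreased), 0)
})

test_that("events with no informative reads in a condition are excluded", {
  counts <- rbind(
    count_row("SE", 50, 50, inc_2 = 50, condition = "WT"),
    count_row("SE", 0, 0, inc_2 = 0, sample_id = "s2", condition = "cKO"),
    count_row("SE", 40, 60, inc_2 = 40, event_id = "e2", condition = "WT"),
    count_row("SE", 60, 40, inc_2 = 60, event_id = "e2", sample_id = "s2",
              condition = "cKO"))
  expect_message(d <- differential_inclusion(counts, "WT", "cKO"),
                 "excluded")
  expect_equal(nrow(d$results), 1)
  expect_equal(d$n_excluded, 1)
})

test_that("splice_diff print and summary expose the tally", {
  sim <- simulate_splice_genome(sim_config(seed = 72, n_genes = 30))
  counts <- simulate_junction_counts(sim)
  d <- suppressMessages(differential_inclusion(counts, "WT", "cKO"))
  expect_s3_class(d, "splice_diff")
  expect_output(print(d), "Differential inclusion")
  expect_equal(sum(summary(d)$n_tested), nrow(d$results))
})

test_that("RPKM reproduces hand-computed values on a grid", {
  expect_equal(exon_rpkm(100, 1000, 1e6)$rpkm, 100)
  expect_equal(exon_rpkm(0, 500, 2e6)$rpkm, 0)
  expect_equal(exon_rpkm(250, 500, 1e7)$rpkm, 50)
  grid <- expand.grid(reads = c(10, 250, 999),
                      len = c(120, 1000, 2500),
                      lib = c(5e5, 1e7))
  got <- exon_rpkm(grid$reads, grid$len, grid$lib)$rpkm
  expect_equal(got, grid$reads / (grid$len / 1000) / (grid$lib / 1e6))
  # linear in reads, inverse in length and library size
  expect_equal(exon_rpkm(200, 1000, 1e6)$rpkm,
               2 * exon_rpkm(100, 1000, 1e6)$rpkm)
  expect_equal(exon_rpkm(100, 2000, 1e6)$rpkm,
               exon_rpkm(100, 1000, 1e6)$rpkm / 2)
  expect_equal(exon_rpkm(100, 1000, 2e6)$rpkm,
               exon_rpkm(100, 1000, 1e6)$rpkm / 2)
  expect_error(exon_rpkm(10, 0, 1e6), "region_length")
  expect_error(exon_rpkm(10, 100, 0), "library_size")
})
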