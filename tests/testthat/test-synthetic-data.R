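test_that("config validation rejects impossible settings", {
  expect_error(sim_config(n_events = 0), "n_events")
  expect_error(sim_config(category_mix = c(SE = -1, RI = 1, A5SS = 0,
                                           A3SS = 0, MXE = 0)), "non-negative")
  expect_error(sim_config(category_mix = c(SE = 0, RI = 0, A5SS = 0,
                                           A3SS = 0, MXE = 0)), "positive sum")
  expect_error(sim_config(frac_activated = 0.7, frac_repressed = 0.5), "<= 1")
  expect_error(sim_config(planted_motif = "GAGA"), "hexamer")
  expect_error(sim_config(planted_motif = "GAGANN"), "hexamer")
  expect_error(sim_config(exon_len = 4), "shorter than")
})

test_that("category allocation is exact largest-remainder apportionment", {
  cfg <- sim_config(n_events = 6699,
                    category_mix = c(SE = 5038, RI = 121, A5SS = 354,
                                     A3SS = 345, MXE = 841) / 6699)
  cat_counts <- table(generate_event_catalog(cfg)$category)
  expect_equal(as.integer(cat_counts[c("SE", "RI", "A5SS", "A3SS", "MXE")]),
               c(5038L, 121L, 354L, 345L, 841L))

  # degenerate mix: everything lands in one category
  cfg2 <- sim_config(n_events = 5,
                     category_mix = c(SE = 1, RI = 0, A5SS = 0,
                                      A3SS = 0, MXE = 0))
  expect_equal(unique(generate_event_catalog(cfg2)$category), "SE")
  expect_equal(nrow(generate_event_catalog(cfg2)), 5L)

  # counts always sum to n across a range of n and mixes
  for (n in c(1, 7, 100, 333)) {
    cfg3 <- sim_config(n_events = n)
    expect_equal(nrow(generate_event_catalog(cfg3)), n)
  }
})

test_that("catalog coordinates are ordered, non-overlapping, 0-based", {
  ev <- generate_event_catalog(tiny_config(25))
  expect_true(all(ev$upstream_start >= 0))
  expect_true(all(ev$upstream_end <= ev$cassette_start))
  expect_true(all(ev$cassette_end <= ev$downstream_start))
  expect_true(all(ev$cassette_end - ev$cassette_start == 60))
  expect_true(all(ev$strand %in% c("+", "-")))
})

test_that("same config and seed give byte-identical datasets", {
  a <- simulate_splicing_dataset(tiny_config(20, seed = 5))
  b <- simulate_splicing_dataset(tiny_config(20, seed = 5))
  expect_identical(a$events, b$events)
  expect_identical(a$truth, b$truth)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$counts, b$counts)
})

test_that("regulation labels partition the events exactly", {
  ds <- simulate_splicing_dataset(tiny_config(60, frac_activated = 0.25,
                                              frac_repressed = 0.30),
                                  sequences = FALSE)
  tab <- table(factor(ds$truth$label,
                      c("activated", "repressed", "unchanged")))
  expect_equal(sum(tab), 60)
  expect_equal(as.integer(tab["activated"]), 15L)
  expect_equal(as.integer(tab["repressed"]), 18L)
  expect_true(all(ds$truth$label %in% c("activated", "repressed", "unchanged")))
  expect_equal(anyDuplicated(ds$truth$event_id), 0L)
})

test_that("planted motifs appear only in their designated region", {
  cfg <- tiny_config(45, frac_activated = 0.3, frac_repressed = 0.3, seed = 3)
  ds <- simulate_splicing_dataset(cfg)
  sq <- ds$sequences
  for (i in seq_len(nrow(ds$truth))) {
    lab <- ds$truth$label[i]
    ev <- ds$truth$event_id[i]
    rows <- sq[sq$event_id == ev, ]
    hits_a <- vapply(rows$seq, scan_count_oracle, 0L, kmer = cfg$planted_motif)
    hits_r <- vapply(rows$seq, scan_count_oracle, 0L,
                     kmer = cfg$planted_motif_repressed)
    names(hits_a) <- names(hits_r) <- rows$region
    if (lab == "activated") {
      expect_gte(hits_a[["cassette"]], 1L)
      expect_equal(sum(hits_a) - hits_a[["cassette"]], 0L)
      expect_equal(sum(hits_r), 0L)
    } else if (lab == "repressed") {
      expect_equal(hits_r[["cassette"]], 0L)
      expect_gte(hits_r[["upstream_flank"]] + hits_r[["downstream_flank"]], 1L)
      expect_equal(sum(hits_a), 0L)
    } else {
      expect_equal(sum(hits_a) + sum(hits_r), 0L)
    }
  }
})

test_that("a skewed background makes every planted copy uniquely findable", {
  cfg <- sim_config(n_events = 10, frac_activated = 1, frac_repressed = 0,
                    planted_motif = "GAGAGA", planted_motif_repressed = "GCTGGA",
                    base_comp = c(A = 0, C = 0.5, G = 0, T = 0.5),
                    exon_len = 60, flank_len = 60, seed = 9)
  ds <- simulate_splicing_dataset(cfg)
  cas <- ds$sequences[ds$sequences$region == "cassette", "seq"]
  hits <- vapply(cas, scan_count_oracle, 0L, kmer = "GAGAGA")
  expect_true(all(hits == 1L))
})

test_that("junction count marginals match the read model", {
  cfg <- sim_config(n_events = 1200, coverage = 50, frac_activated = 0,
                    frac_repressed = 0, seed = 21)
  ds <- simulate_splicing_dataset(cfg, sequences = FALSE)
  tot <- ds$counts$inclusion + ds$counts$exclusion
  se <- sqrt(50 / length(tot))  # Poisson variance = mean
  expect_lt(abs(mean(tot) - 50), 3 * se)
  # true PSI = 1 forces all reads to the inclusion junction
  t2 <- data.frame(event_id = "e", psi_control = 1, psi_knockdown = 1)
  c2 <- simulate_counts(t2, sim_config(n_events = 1, coverage = 100, seed = 1))
  expect_true(all(c2$exclusion == 0))
  # high coverage concentrates the empirical PSI near truth
  t3 <- data.frame(event_id = "e", psi_control = 0.5, psi_knockdown = 0.5)
  c3 <- simulate_counts(t3, sim_config(n_events = 1, coverage = 10000, seed = 2))
  expect_lt(abs(c3$inclusion[1] / (c3$inclusion[1] + c3$exclusion[1]) - 0.5),
            0.02)
})

test_that("activated truth applies the knockdown shift with clipping", {
  ds <- simulate_splicing_dataset(
    tiny_config(50, frac_activated = 0.5, frac_repressed = 0.5,
                true_delta_psi = 0.4), sequences = FALSE)
  act <- ds$truth[ds$truth$label == "activated", ]
  rep_ <- ds$truth[ds$truth$label == "repressed", ]
  expect_equal(act$psi_knockdown, pmax(0, act$psi_control - 0.4))
  expect_equal(rep_$psi_knockdown, pmin(1, rep_$psi_control + 0.4))
  unc <- ds$truth[ds$truth$label == "unchanged", ]
  expect_equal(unc$psi_knockdown, unc$psi_control)
})

test_that("survival cohort generator is deterministic and hazard-ordered", {
  a <- simulate_survival_cohort(200, seed = 4)
  b <- simulate_survival_cohort(200, seed = 4)
  expect_identical(a, b)
  expect_error(simulate_survival_cohort(1), ">= 2")
  expect_error(simulate_survival_cohort(10, c(high = -1, low = 1)), "positive")
  expect_error(simulate_survival_cohort(10, censor_rate = 1), "censor_rate")

  # hazard ratio 3: the high-hazard group dies sooner
  co <- simulate_survival_cohort(500, c(high = 0.06, low = 0.02),
                                 censor_rate = 0.2, seed = 8)
  med <- tapply(co$time[co$event == 1], co$latent_group[co$event == 1], median)
  expect_lt(med[["high"]], med[["low"]])
  # PSI/expression profiles encode the latent group (no label noise)
  expect_true(all(co$psi[co$latent_group == "high"] < 0.5))
  expect_true(all(co$expression[co$latent_group == "high"] > 50))
})
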