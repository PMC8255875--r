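test_that("pairwise_r2 matches an independent correlation oracle", {
  ds <- toy_dataset(cbind(x = c(0L, 0L, 1L, 2L), y = c(0L, 1L, 1L, 2L)),
                    pos = c(10000L, 60000L))
  pr <- pairwise_r2(ds, "B1")
  expect_equal(nrow(pr), 1L)
  expect_equal(pr$r2, cor(c(0, 0, 1, 2), c(0, 1, 1, 2))^2)
  expect_equal(pr$dist_bp, 50000)
  expect_true(pr$adjacent)
  # perfectly co-varying columns
  ds2 <- toy_dataset(cbind(c(0L, 1L, 2L, 0L), c(0L, 1L, 2L, 0L)),
                     pos = c(1000L, 2000L))
  expect_equal(pairwise_r2(ds2, "B1")$r2, 1)
  expect_error(pairwise_r2(ds, "absent"), "unknown breed")
})

test_that("independent SNPs give mean r2 near the 1/n finite-sample bias", {
  set.seed(61)
  n <- 30L
  calls <- matrix(rbinom(n * 150L, 2L, 0.4), n, 150L)
  ds <- toy_dataset(calls, pos = seq_len(150L) * 1000L)   # all pairs < 5 Mb
  pr <- pairwise_r2(ds, "B1")
  expect_gt(nrow(pr), 1000L)
  expect_equal(mean(pr$r2), 1 / n, tolerance = 0.2)
})

test_that("binning follows the upper-inclusive scheme and conserves pairs", {
  pairs <- data.frame(chrom = "1", snp_i = "a", snp_j = "b",
                      dist_bp = c(13000, 50000, 40000, 980000, 3.2e6),
                      r2 = c(0.5, 0.4, 0.3, 0.2, 0.1),
                      adjacent = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  prof <- bin_ld(pairs, "T")
  b <- prof$bins
  expect_equal(b$n_pairs[b$lower_mb == 0.01 & b$upper_mb == 0.02], 1L)
  # upper-inclusive edges: exactly 0.05 -> (0.04, 0.05]; exactly 0.04 -> (0.03, 0.04]
  expect_equal(b$n_pairs[b$lower_mb == 0.04 & b$upper_mb == 0.05], 1L)
  expect_equal(b$mean_r2[b$lower_mb == 0.04 & b$upper_mb == 0.05], 0.4)
  expect_equal(b$n_pairs[b$lower_mb == 0.03 & b$upper_mb == 0.04], 1L)
  expect_equal(b$n_pairs[b$lower_mb == 3 & b$upper_mb == 4], 1L)
  expect_equal(sum(b$n_pairs), nrow(pairs))               # conservation
  expect_equal(prof$adjacent_mean_r2, 0.5)
  expect_equal(prof$r2_at_1mb, 0.2)
  expect_true(is.na(b$mean_r2[b$n_pairs == 0][1]))        # empty bins flagged
})

test_that("half-decay distance interpolates from the adjacent-pair anchor", {
  mk_prof <- function(mid, r2, adj) {
    bins <- data.frame(lower_mb = mid - 0.01, upper_mb = mid + 0.01,
                       mid_mb = mid, n_pairs = 100L, mean_r2 = r2)
    structure(list(breed = "T", bins = bins, adjacent_mean_r2 = adj,
                   adjacent_n = 50L, n_samples = 30L,
                   r2_at_1mb = NA, r2_at_5mb = NA), class = "ld_profile")
  }
  flat <- mk_prof(c(0.5, 1, 2), c(0.4, 0.4, 0.4), 0.4)
  expect_true(is.na(half_decay_distance(flat)))
  # line r2(d) = 0.4 - 0.3 d through the midpoints: half of 0.4 at d = 2/3
  mids <- seq(0.1, 1, by = 0.1)
  lin <- mk_prof(mids, 0.4 - 0.3 * mids, 0.4)
  expect_equal(half_decay_distance(lin), 2 / 3, tolerance = 1e-9)
  # step profile: 0.4 then 0.19 from 0.3 Mb -> crossing just before 0.3
  stp <- mk_prof(c(0.1, 0.2, 0.3, 0.4), c(0.4, 0.4, 0.19, 0.19), 0.4)
  d <- half_decay_distance(stp)
  expect_equal(d, 0.2 + 0.1 * (0.4 - 0.2) / (0.4 - 0.19), tolerance = 1e-9)
  expect_lt(abs(d - 0.3), 0.01)
})

test_that("Sved inversion arithmetic and domain errors", {
  expect_equal(ne_from_r2(0.2, 0.0125), 80)
  expect_equal(ne_from_r2(1, 0.01), 0)
  expect_equal(ne_from_r2(0.25, 0.0025), 300)
  expect_error(ne_from_r2(0, 0.01), "infinite")
  expect_error(ne_from_r2(0.2, 0), "positive")
  # strictly decreasing in r2 at fixed c
  r2s <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(ne_from_r2(r2s, 0.01)) < 0))
})

test_that("current_ne uses the 1 Mb bin and scales with recombination rate", {
  bins <- data.frame(lower_mb = c(0.90, 0.95), upper_mb = c(0.95, 1.00),
                     mid_mb = c(0.925, 0.975), n_pairs = c(10L, 40L),
                     mean_r2 = c(0.5, 0.30))
  prof <- structure(list(breed = "T", bins = bins, adjacent_mean_r2 = 0.6,
                         adjacent_n = 5L, r2_at_1mb = 0.30, r2_at_5mb = NA,
                         n_samples = 25L), class = "ld_profile")
  expect_equal(current_ne(prof, 1), (1 / 0.04) * (1 / 0.3 - 1))  # 58.33
  expect_equal(current_ne(prof, 2), current_ne(prof, 1) / 2)
  # alternative reading: pair-weighted mean over all bins <= 1 Mb
  expect_equal(current_ne(prof, 1, all_pairs_below_1mb = TRUE),
               ne_from_r2((0.5 * 10 + 0.3 * 40) / 50, 0.01))
  # 1/n correction
  expect_equal(current_ne(prof, 1, sample_correction = TRUE),
               ne_from_r2(0.30 - 1 / 25, 0.01))
})

test_that("past Ne trajectory maps bins to T = 1/(2c)", {
  bins <- data.frame(lower_mb = c(0.005, 0.4), upper_mb = c(0.015, 0.6),
                     mid_mb = c(0.01, 0.5), n_pairs = c(5L, 5L),
                     mean_r2 = c(0.8, 0.25))
  prof <- structure(list(breed = "T", bins = bins, adjacent_mean_r2 = 0.8,
                         n_samples = 30L), class = "ld_profile")
  tr <- past_ne_trajectory(prof, 1)
  expect_equal(tr$t_generations, c(100, 5000))            # sorted ascending
  expect_equal(tr$c_morgans, c(0.005, 1e-4))
  expect_equal(tr$ne, ne_from_r2(c(0.25, 0.8), c(0.005, 1e-4)))
})

test_that("simulated LD decays with distance and matches Sved + 1/n roughly", {
  set.seed(71)
  cfg <- sim_config(genome = sim_genome(2L, 100, 400L, 1),
                    breeds = data.frame(breed = "B", N = 50L,
                                        generations = 120L),
                    samples_per_breed = 40L, missing_rate = 0, seed = 505)
  sim <- simulate_breeds(cfg)
  ds <- apply_qc(sim$dataset)
  prof <- bin_ld(pairwise_r2(ds, "B"), "B")
  b <- prof$bins[prof$bins$n_pairs >= 200, ]
  # weakly decreasing trend across bins
  expect_lt(coef(lm(mean_r2 ~ mid_mb, data = b))[2], 0)
  # Sved expectation 1/(1 + 4 N c) + 1/n in the well-populated range
  expected <- 1 / (1 + 4 * 50 * b$mid_mb / 100) + 1 / 40
  expect_equal(mean(b$mean_r2 / expected), 1, tolerance = 0.25)
})
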