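test_that("triangular shot trajectory follows the periodic blip formula", {
  cfg <- sampling_config(180, 12, 12, Ry = 3, dmax = 15)
  expect_equal(cfg$w, 7L)
  expect_equal(cfg$period, 12L)            # 2w - 2 acquired lines

  s <- basic_shot_trajectory(cfg, shot_params(0, 0, 0))
  # kz walks up 0..6 then back down; central plane hit once per period
  expect_equal(s$lines[1:10, "kz"], c(0:6, 5, 4, 3))
  nav <- which(s$lines[, "kz"] == cfg$kz_center)
  expect_equal(diff(nav), rep(12L, length(nav) - 1L))
  # ky lines are an arithmetic progression congruent to s_ky mod Ry
  expect_true(all(s$lines[, "ky"] %% 3 == 0))
  expect_equal(nrow(s$lines), 60L)

  # s_p shifts the waveform
  s2 <- basic_shot_trajectory(cfg, shot_params(1, 2, 5))
  t <- (seq_len(nrow(s2$lines)) - 1 + 5) %% 12
  tri <- ifelse(t <= 6, t, 12 - t)
  expect_equal(s2$lines[, "kz"], as.integer(2 + tri))
  expect_true(all(s2$lines[, "kz"] >= 2 & s2$lines[, "kz"] <= 8))

  # minimal slab: w = 2, period 2, kz alternates 0,1,0,1,...
  cfg2 <- sampling_config(8, 2, 2, Ry = 1)
  a <- basic_shot_trajectory(cfg2, shot_params(0, 0, 0))
  expect_equal(a$lines[, "kz"], rep(c(0L, 1L), 4))

  expect_error(basic_shot_trajectory(cfg, shot_params(3, 0, 0)), "s_ky")
  expect_error(basic_shot_trajectory(cfg, shot_params(0, 6, 0)), "s_kz")
  expect_error(basic_shot_trajectory(cfg, shot_params(0, 0, 12)), "s_p")
  expect_error(sampling_config(64, 1, 1), "Nkz")
})

test_that("triangular trajectory visits every kz plane of its band each period", {
  cfg <- sampling_config(96, 12, 12, Ry = 1)
  for (skz in 0:cfg$s_kz_max) for (sp in c(0, 5, 11)) {
    s <- basic_shot_trajectory(cfg, shot_params(0, skz, sp))
    first_period <- s$lines[1:cfg$period, "kz"]
    expect_setequal(unique(first_period), skz + 0:(cfg$w - 1))
  }
})

test_that("kz0 traversal shot stays on the central plane", {
  cfg <- sampling_config(180, 12, 12, Ry = 3, pf = 1)
  tr <- kz0_traversal_shot(cfg, 0)
  expect_equal(nrow(tr$lines), 60L)
  expect_true(all(tr$lines[, "kz"] == 6L))
  expect_true(tr$is_kz0_traversal)
  expect_equal(nav_distance(tr, cfg), 0)   # ky = 90 is acquired
  tr1 <- kz0_traversal_shot(cfg, 1)
  expect_equal(tr1$lines[, "ky"], seq.int(1L, 178L, by = 3L))
})

test_that("overlap and gap metrics agree with brute-force counting", {
  naive_overlap <- function(comb) sum(comb > 1)
  naive_gap <- function(comb, p) {
    occ <- (comb > 0) + 0
    pad <- matrix(0, nrow(occ) + 2 * p, ncol(occ) + 2 * p)
    pad[p + seq_len(nrow(occ)), p + seq_len(ncol(occ))] <- occ
    g <- 0L
    for (i in seq_len(nrow(pad) - 2)) for (j in seq_len(ncol(pad) - 2))
      if (sum(pad[i:(i + 2), j:(j + 2)]) == 0) g <- g + 1L
    g
  }
  set.seed(42)
  for (rep in 1:100) {
    per <- array(as.integer(runif(20 * 12 * 3) < 0.25), c(20, 12, 3))
    masks <- structure(list(per_shot = per,
                            combined = apply(per, c(1, 2), sum),
                            Ny = 20L, Nkz = 12L), class = "sampling_masks")
    comb <- masks$combined
    expect_identical(overlap_metric(masks, 3), naive_overlap(comb))
    expect_identical(gap_metric(masks, 3), naive_gap(comb, 0))
    if (rep <= 10) {
      expect_identical(gap_metric(masks, 3, "full"), naive_gap(comb, 2))
      expect_identical(gap_metric(masks, 3, "same"), naive_gap(comb, 1))
    }
  }
})

test_that("gap metric handles degenerate masks", {
  full <- structure(list(per_shot = array(1L, c(10, 6, 1)),
                         combined = matrix(1L, 10, 6)),
                    class = "sampling_masks")
  expect_equal(gap_metric(full, 1), 0L)
  empty <- structure(list(per_shot = array(0L, c(10, 6, 1)),
                          combined = matrix(0L, 10, 6)),
                     class = "sampling_masks")
  expect_equal(gap_metric(empty, 1), (10L - 2L) * (6L - 2L))
  # one sampled cell in the middle of a 6x6 grid: of the 16 valid windows,
  # the 9 containing the cell are nonempty
  one <- array(0L, c(6, 6, 1)); one[4, 4, 1] <- 1L
  m1 <- structure(list(per_shot = one, combined = one[, , 1]),
                  class = "sampling_masks")
  expect_equal(gap_metric(m1, 1), 16L - 9L)
  expect_error(gap_metric(structure(list(per_shot = array(0L, c(2, 2, 1)),
                                         combined = matrix(0L, 2, 2)),
                                    class = "sampling_masks"), 1),
               "3x3")
})

test_that("nav_distance is the Euclidean distance to the grid center", {
  cfg <- sampling_config(180, 12, 1, Ry = 3)
  sh <- kz0_traversal_shot(cfg, 0)
  sh$lines <- cbind(ky = 105L, kz = 6L)    # single nav point at +15
  expect_equal(nav_distance(sh, cfg), 15)
  sh$lines <- cbind(ky = 10L, kz = 3L)     # off the central plane
  expect_error(nav_distance(sh, cfg), "self-navigation")
})

test_that("greedy optimization is deterministic and respects dmax", {
  cfg <- sampling_config(64, 12, 12, Ry = 3, dmax = 6)
  p1 <- greedy_optimize(cfg)
  p2 <- greedy_optimize(cfg)
  expect_identical(shot_lines(p1), shot_lines(p2))
  m <- attr(p1, "metrics")
  expect_true(all(m$d <= 6))
  expect_equal(nrow(m), 12L)
  # search-space bookkeeping for the published geometry
  cfg12 <- sampling_config(180, 12, 12, Ry = 3, dmax = 15)
  n_cand <- (cfg12$s_ky_max + 1) * (cfg12$s_kz_max + 1) * (cfg12$s_p_max + 1)
  expect_equal(n_cand, 216L)
  expect_equal(n_cand * 11, 2376L)
  expect_equal(log10(as.numeric(n_cand)) * 11, log10(4.78e25),
               tolerance = 1e-3)
  # infeasibility error when dmax excludes every candidate
  cfg_bad <- sampling_config(64, 12, 2, Ry = 3, dmax = -1)
  expect_error(greedy_optimize(cfg_bad), "feasible")
})

test_that("combined-mask structure of the optimized pattern", {
  # cell counts stay in {0, 1, 2} at the published geometry
  cfg <- sampling_config(180, 12, 12, Ry = 3, dmax = 15)
  pats <- greedy_optimize(cfg)
  masks <- sampling_masks(pats, cfg)
  expect_true(all(masks$combined %in% 0:2))
  expect_lt(overlap_metric(masks) / sum(masks$combined), 0.05)
  expect_identical(masks$combined,
                   apply(masks$per_shot, c(1, 2), sum))
})

test_that("central-plane acceleration factors match the trajectory geometry", {
  cfg <- sampling_config(180, 12, 12, Ry = 3, pf = 1)
  # band at the bottom: central plane touched only at the period extremum
  expect_equal(selfnav_acceleration(basic_shot_trajectory(cfg,
    shot_params(0, 0, 0)), cfg), 36)
  # interior crossing: twice per period
  expect_equal(selfnav_acceleration(basic_shot_trajectory(cfg,
    shot_params(0, 3, 0)), cfg), 18)
  expect_equal(selfnav_acceleration(kz0_traversal_shot(cfg, 0), cfg), 3)
})

test_that("per-shot under-sampling factor equals Nkz * Ry", {
  expect_equal(per_shot_undersampling(sampling_config(180, 10, 10, Ry = 3)),
               30)
  expect_equal(per_shot_undersampling(sampling_config(180, 12, 12, Ry = 3)),
               36)
  expect_equal(per_shot_undersampling(sampling_config(64, 2, 2, Ry = 1)), 2)
})

test_that("partial Fourier restricts the acquired ky range", {
  cfg <- sampling_config(180, 12, 12, Ry = 3, pf = 0.75)
  s <- basic_shot_trajectory(cfg, shot_params(0, 0, 0))
  expect_true(all(s$lines[, "ky"] <= round(0.75 * 180) - 1))
  expect_equal(nrow(s$lines), 45L)
  expect_error(sampling_config(180, 12, 12, pf = 0.5), "pf")
})

test_that("shot line tables and masks are consistent", {
  cfg <- sampling_config(48, 6, 4, Ry = 2, dmax = 5)
  pats <- greedy_optimize(cfg)
  tbl <- shot_lines(pats)
  masks <- sampling_masks(pats, cfg)
  expect_s3_class(tbl, "tbl_df")
  expect_equal(nrow(tbl), sum(masks$combined))
  expect_equal(sort(unique(tbl$shot)), 1:4)
  p <- plot_sampling(pats, cfg)
  expect_s3_class(p, "ggplot")
})
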