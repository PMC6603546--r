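test_that("angle_weight matches the 1 - |cos| form", {
  expect_equal(angle_weight(c(0, 0, 1)), 0)              # parallel
  expect_equal(angle_weight(c(0, 0, -2)), 0)             # anti-parallel
  expect_equal(angle_weight(c(1, 0, 0)), 1)              # perpendicular
  expect_equal(angle_weight(c(1, 0, 1)), 1 - cos(pi / 4), tolerance = 1e-12)
  # theta = 60 degrees -> 0.5
  expect_equal(angle_weight(c(sin(pi / 3), 0, cos(pi / 3))), 0.5,
               tolerance = 1e-12)
  # flipping either vector changes nothing
  set.seed(1)
  v <- matrix(rnorm(30), 10)
  expect_equal(angle_weight(v), angle_weight(-v))
  expect_equal(angle_weight(v, c(0, 0, 1)), angle_weight(v, c(0, 0, -1)))
  # degenerate zero-length bone
  expect_equal(angle_weight(c(0, 0, 0)), 0)
  expect_error(angle_weight(c(1, 0, 0), axis = c(0, 0, 0)), "nonzero")
})

test_that("deviation_weight reproduces the capped tent with state factor", {
  cfg <- init_config()
  expect_equal(deviation_weight(1.6, 1.0, "tracked", cfg), 0)   # ratio 0.6
  expect_equal(deviation_weight(1.0, 1.0, "tracked", cfg), 1)   # exact
  # ratio 0.25, halfTracked: 0.8 * (1 - 0.5) = 0.4
  expect_equal(deviation_weight(1.25, 1.0, "halfTracked", cfg), 0.4)
  expect_equal(deviation_weight(1.01, 1.0, "notTracked", cfg), 0)
  # boundary: exactly at the cap -> 0
  expect_equal(deviation_weight(1.5, 1.0, "tracked", cfg), 0)
  set.seed(2)
  w <- deviation_weight(runif(100, 0.1, 3), 1.0,
                        sample(c("tracked", "halfTracked", "notTracked"),
                               100, TRUE), cfg)
  expect_true(all(w >= 0 & w <= 1))
})

test_that("initial pass is the angle-weighted pooled mean", {
  d <- toy_chain()
  # constant length 1 along x (weight 1) -> mean is exactly 1
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  s <- make_seq(d, replicate(5, flat, simplify = FALSE))
  tab <- initial_reference_lengths(s, init_config(n_init_frames = 5))
  expect_equal(tab$l_ref_initial, c(1, 1))

  # an on-axis frame (weight 0) with length 2 must not shift the mean
  axial <- rbind(c(0, 0, 0), c(0, 0, 2), c(0, 0, 4))
  s2 <- make_seq(d, c(replicate(4, flat, simplify = FALSE), list(axial)))
  tab2 <- initial_reference_lengths(s2, init_config(n_init_frames = 5))
  expect_equal(tab2$l_ref_initial, c(1, 1))

  # bone never off-axis -> error naming the class
  s3 <- make_seq(d, replicate(4, axial, simplify = FALSE))
  expect_error(initial_reference_lengths(s3, init_config(4)),
               "A-B")
})

test_that("refined pass zeroes gross outliers and recovers the clean mean", {
  d <- toy_chain()
  flat <- function(L) rbind(c(0, 0, 0), c(L, 0, 0), c(L + 1, 0, 0))
  poses <- c(replicate(5, flat(1), simplify = FALSE), list(flat(1.8)))
  s <- make_seq(d, poses)
  tab <- reference_lengths(s, init_config(n_init_frames = 6))
  # initial is contaminated, final snaps back to the clean value
  expect_gt(tab$l_ref_initial[1], 1.1)
  expect_equal(tab$l_ref_final[1], 1, tolerance = 1e-12)

  # noiseless constant input: final = initial = truth
  s0 <- make_seq(d, replicate(6, flat(1), simplify = FALSE))
  tab0 <- reference_lengths(s0, init_config(6))
  expect_equal(tab0$l_ref_final, tab0$l_ref_initial)
  expect_equal(tab0$l_ref_final, c(1, 1))

  # every observation outside the cap -> fallback to initial with warning
  tab_manual <- build_ref_table(d, c(10, 10))
  expect_warning(
    out <- refined_reference_lengths(s0, tab_manual, init_config(6)),
    "falling back")
  expect_equal(out$l_ref_final, c(10, 10))
})

test_that("weighted means stay inside the observation hull", {
  d <- toy_chain()
  set.seed(3)
  poses <- lapply(1:12, function(i) {
    a <- c(0, 0, 0)
    b <- a + runif(1, 0.8, 1.2) * c(1, runif(1, -0.2, 0.2), 0)
    cpt <- b + runif(1, 0.8, 1.2) * c(1, 0, runif(1, -0.2, 0.2))
    rbind(a, b, cpt)
  })
  s <- make_seq(d, poses)
  tab <- reference_lengths(s, init_config(12))
  lm <- bone_length_matrix(s)
  for (k in 1:2) {
    expect_gte(tab$l_ref_initial[k], min(lm[, k]))
    expect_lte(tab$l_ref_initial[k], max(lm[, k]))
    expect_gte(tab$l_ref_final[k], min(lm[, k]))
    expect_lte(tab$l_ref_final[k], max(lm[, k]))
  }
})

test_that("mirror bones pool into one class with equal references", {
  d <- toy_pair()
  set.seed(4)
  poses <- lapply(1:8, function(i) {
    rbind(c(0, 0, 0),
          c(0.30, 0.02 * rnorm(1), 0),
          c(-0.30, 0.02 * rnorm(1), 0))
  })
  s <- make_seq(d, poses)
  tab <- reference_lengths(s, init_config(8))
  expect_equal(nrow(tab), 1L)   # one shared class for the pair
  lr <- skelrefine:::ref_by_bone(tab, d)
  expect_equal(lr[1], lr[2])    # left/right resolve identically
})

test_that("references recover synthetic truth and beat the plain mean", {
  cfg <- generator_config(frames = 200, n_keyframes = 5,
                          noise_base = 0.005, outlier_rate = 0, seed = 7)
  sim <- simulate_sequence(cfg)
  tab <- reference_lengths(sim$noisy, init_config(100))
  truth <- true_class_lengths(sim)
  expect_lt(max(abs(tab$l_ref_final - truth)), 0.005)

  # 10% outlier frames (one joint displaced 0.5 m): the deviation-weighted
  # estimator must beat an independently computed unweighted pooled mean
  nj <- sim$truth$dialect$n_joints
  cfg2 <- generator_config(frames = 200, n_keyframes = 5,
                           noise_base = 0.005, outlier_rate = 0.10 / nj,
                           outlier_magnitude = 0.5, seed = 7)
  sim2 <- simulate_sequence(cfg2)
  tab2 <- reference_lengths(sim2$noisy, init_config(100))
  d <- sim2$truth$dialect
  lm <- bone_length_matrix(sim2$noisy)[1:100, ]
  plain <- vapply(split(seq_len(d$n_bones), d$bone_class),
                  function(cols) mean(lm[, cols]), numeric(1))
  expect_lt(sum(abs(tab2$l_ref_final - truth)),
            sum(abs(plain - truth)))
})

test_that("reference error shrinks as the window grows", {
  errs <- vapply(c(50L, 200L, 800L), function(N) {
    cfg <- generator_config(frames = N, n_keyframes = max(2L, N %/% 40L),
                            noise_base = 0.005, seed = 11)
    sim <- simulate_sequence(cfg)
    tab <- reference_lengths(sim$noisy, init_config(N))
    sum(abs(tab$l_ref_final - true_class_lengths(sim)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("reference tables round-trip through JSON", {
  d <- toy_chain()
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.5, 0, 0))
  s <- make_seq(d, replicate(5, flat, simplify = FALSE))
  tab <- reference_lengths(s, init_config(5))
  path <- withr::local_tempfile(fileext = ".json")
  write_reference_table(tab, path)
  back <- read_reference_table(path)
  expect_equal(back$l_ref_final, tab$l_ref_final, tolerance = 1e-12)
  expect_equal(attr(back, "dialect"), "toy3")
})
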