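# Generators: determinism, ground-truth consistency, caller RNG isolation.

test_that("every generator is bit-reproducible for a fixed seed", {
  m1 <- make_mock_polymerase(seed = 12, swivel_angle = 3, coordinate_noise = 0.1)
  m2 <- make_mock_polymerase(seed = 12, swivel_angle = 3, coordinate_noise = 0.1)
  expect_identical(m1$query$atoms, m2$query$atoms)

  s1 <- make_collision_scene(seed = 4)
  s2 <- make_collision_scene(seed = 4)
  expect_identical(s1$mobile$atoms, s2$mobile$atoms)

  tmpl <- template_spec(paste(rep("ACGTG", 30), collapse = ""),
                        paste(rep("TTGCA", 30), collapse = ""))
  r1 <- simulate_reads(tmpl, 10, seed = 5, error_rate = 0.05,
                       end_model = list(type = "uniform", min = 40, max = 140))
  r2 <- simulate_reads(tmpl, 10, seed = 5, error_rate = 0.05,
                       end_model = list(type = "uniform", min = 40, max = 140))
  expect_identical(r1, r2)

  d1 <- simulate_decay(0.5, 0.2, 0.5, 0.01, 0:10, noise_sd = 0.05, seed = 6)
  d2 <- simulate_decay(0.5, 0.2, 0.5, 0.01, 0:10, noise_sd = 0.05, seed = 6)
  expect_identical(d1$signal, d2$signal)

  t1 <- simulate_titration(c("50" = 1, "300" = 0.4), noise_sd = 0.02,
                           seed = 7)
  t2 <- simulate_titration(c("50" = 1, "300" = 0.4), noise_sd = 0.02,
                           seed = 7)
  expect_identical(t1, t2)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(make_mock_polymerase(seed = 99))
  invisible(simulate_decay(1, 0.1, 0, 0, 0:10, noise_sd = 0.1, seed = 98))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("zero swivel and zero noise give an identical query", {
  m <- make_mock_polymerase(seed = 20, swivel_angle = 0,
                            coordinate_noise = 0)
  expect_equal(m$query$atoms[, c("x", "y", "z")],
               m$reference$atoms[, c("x", "y", "z")], tolerance = 1e-12)
})

test_that("the constructed swivel rotation is exactly recoverable", {
  m <- make_mock_polymerase(seed = 21, swivel_angle = 3.0)
  expect_equal(compute_swivel(m$query, m$reference)$angle, 3.0,
               tolerance = 1e-6)
})

test_that("noisy mocks recover the true angle on average", {
  errs <- vapply(1:20, function(s) {
    ang <- 0.5 + 9.5 * ((s * 7919) %% 97) / 97
    m <- make_mock_polymerase(seed = s, swivel_angle = ang,
                              coordinate_noise = 0.1)
    abs(compute_swivel(m$query, m$reference)$angle - ang)
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})

test_that("the B-DNA generator respects residue counts and helix algebra", {
  d <- make_bdna(2)
  expect_equal(sum(d$atoms$chain == "T" & d$atoms$elety == "P"), 2L)
  expect_equal(sum(d$atoms$chain == "N" & d$atoms$elety == "P"), 2L)

  d2 <- make_bdna(25)
  # bases i and i+21 (two full turns) are related by pure translation
  a1 <- d2$atoms[d2$atoms$chain == "T" & d2$atoms$resno == 2, c("x", "y", "z")]
  a2 <- d2$atoms[d2$atoms$chain == "T" & d2$atoms$resno == 23, c("x", "y", "z")]
  delta <- as.matrix(a2) - as.matrix(a1)
  expect_equal(unname(colMeans(delta)), c(0, 0, 21 * 3.4), tolerance = 0.1)
  expect_lt(max(abs(sweep(delta, 2, colMeans(delta)))), 0.1)
  expect_error(make_bdna(1), "2 base pairs")
})

test_that("collision scenes expose a usable geometric ground truth", {
  sc <- make_collision_scene(seed = 1, helix = list(n_bp = 50),
                             mobile_radius = 5, fixed_radius = 5,
                             fixed_position = 40, mobile_position = 10)
  # blobs 30 bp apart: zero overlap while the axial gap exceeds contact
  p <- surface_params(grid_spacing = 0.8)
  expect_equal(overlap_volume(sc$mobile, sc$fixed, p), 0)
  # coincident blobs overlap by the blob volume
  sc2 <- make_collision_scene(seed = 1, helix = list(n_bp = 50),
                              fixed_position = 20, mobile_position = 20)
  ov <- overlap_volume(sc2$mobile, sc2$fixed, p)
  expect_equal(ov, molecular_volume(sc2$mobile, p),
               tolerance = 0.05 * molecular_volume(sc2$mobile, p))
  expect_error(make_collision_scene(helix = list(n_bp = 10),
                                    fixed_position = 40), "outside")
})

test_that("simulated reads carry a truth table the classifier reproduces", {
  set.seed(30)
  fw <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
              collapse = "")
  rv <- paste(sample(c("A", "C", "G", "T"), 230, replace = TRUE),
              collapse = "")
  tmpl <- template_spec(fw, rv)
  sim <- simulate_reads(tmpl, 40, seed = 31,
                        end_model = list(type = "uniform", min = 60,
                                         max = 220))
  cls <- classify_reads(sim$five_reads, sim$three_reads, tmpl)
  expect_identical(cls$orientation, sim$truth$orientation)
  expect_identical(cls$five_prime, sim$truth$five_prime)
  expect_identical(cls$three_prime, sim$truth$three_prime)
})

test_that("decay curves map back through the controls exactly", {
  d <- simulate_decay(0.6, 0.2, 0.4, 0.01, c(0, 1, 2, 5, 10), noise_sd = 0,
                      seed = 1)
  f <- fraction_intact(d$signal, d$no_ntp_control, d$pk_control)
  expect_equal(as.numeric(f)[1], 1)  # t = 0: a1 + a2 = 1
  expect_equal(as.numeric(f), d$fraction_true, tolerance = 1e-12)
})

test_that("titration tables recover the injected E_RB profile", {
  truth <- c("50" = 1, "100" = 0.8, "200" = 0.5, "300" = 0.2, "500" = 0.05)
  tab <- simulate_titration(truth, noise_sd = 0, seed = 2)
  out <- rescale_titration(tab)
  expect_equal(out$erb, unname(truth), tolerance = 1e-12)

  # flat truth stays flat
  flat <- simulate_titration(c("50" = 1, "300" = 1), noise_sd = 0, seed = 3)
  expect_equal(rescale_titration(flat)$erb, c(1, 1), tolerance = 1e-12)

  # 2% intensity noise keeps recovered values within 3 sigma (error
  # propagation: the ratio of two noisy ratios has sd ~ 2 * noise)
  noisy <- simulate_titration(truth, noise_sd = 0.02, seed = 4)
  outn <- rescale_titration(noisy)
  expect_true(all(abs(outn$erb - unname(truth)) < 3 * 2 * 0.02 *
                    pmax(outn$erb, 0.3)))
})
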