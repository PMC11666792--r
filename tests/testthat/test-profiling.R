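# Positional profiling: context tables, observed/expected log2 profiles
# (against a brute-force enumeration oracle), smoothing, periodogram
# periodicity estimation, sinusoid fits, phase classification, and TF
# midpoint profiles.

test_that("window context table matches hand enumeration on a toy contig", {
  ref <- c(toy = "ACGTACGTACGTACGTACGTA")  # 21 bp
  anchors <- data.frame(contig = "toy", pos = 10L)
  W <- 3L
  mat <- window_context_table(anchors, ref, W)
  # hand enumeration: offsets -3..3 around 0-based 10
  for (j in -3:3) {
    p0 <- 10 + j
    cx <- substr(ref[["toy"]], p0, p0 + 2)  # 1-based p0 = context start
    col <- as.character(j)
    expect_equal(sum(mat[, col]), 1)
    expect_equal(unname(mat[cx, col]), 1)
  }
  # edge clipping: anchor 2 bp from the start loses leftmost offsets
  anchors2 <- data.frame(contig = "toy", pos = 2L)
  mat2 <- window_context_table(anchors2, ref, 5L)
  expect_equal(unname(colSums(mat2)[as.character(-5:-2)]), c(0, 0, 0, 0))
  expect_equal(unname(colSums(mat2)[as.character(0)]), 1)
})

test_that("event context frequencies satisfy the conservation identity", {
  sim <- cached("small_sim", run_sim(small_config()))
  fr <- event_context_frequency(sim$events, sim$reference)
  expect_equal(sum(fr$f * fr$genome_counts), sum(fr$event_counts))
  expect_equal(sum(fr$event_counts),
               sum(!is.na(sim$events$context)))
  # no events: all frequencies zero
  fr0 <- event_context_frequency(sim$events[0, ], sim$reference)
  expect_true(all(fr0$f == 0))
})

test_that("obs/exp log2 profile matches the brute-force oracle exactly", {
  set.seed(33)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE,
                       prob = c(.2, .3, .3, .2)), collapse = "")
  ref <- c(toyA = base,
           toyB = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                        collapse = ""))
  anchors <- data.frame(contig = c("toyA", "toyA", "toyA", "toyB", "toyB"),
                        pos = c(50L, 120L, 390L, 8L, 200L))
  events <- data.frame(contig = sample(c("toyA", "toyB"), 60, replace = TRUE))
  events$pos <- ifelse(events$contig == "toyA",
                       sample(398, 60, replace = TRUE),
                       sample(298, 60, replace = TRUE))
  W <- 10L
  oracle <- brute_obs_exp(events, anchors, ref, W)
  prof <- obs_exp_log2(events, anchors, ref, W, smooth_window = 11L)
  expect_identical(prof$observed, oracle$O)
  expect_equal(prof$expected, oracle$E, tolerance = 1e-12)
  expect_equal(prof$log2ratio, oracle$L, tolerance = 1e-12)
  # conservation: total observed = all (event, window) incidences
  expect_equal(sum(prof$observed), sum(oracle$O))
  # identities O = 2E -> L = 1 and O = E -> L = 0
  expect_equal(log2(2), 1)
  expect_error(obs_exp_log2(events, anchors[0, ], ref, W), "zero anchors")
})

test_that("Savitzky-Golay smoothing reproduces polynomials and local fits", {
  x <- rep(5, 300)
  expect_equal(savgol_smooth(x, 201, 3), x, tolerance = 1e-9)
  # exact cubic reproduced in the interior
  j <- 1:400
  cubic <- 2 + 0.5 * j - 0.01 * j^2 + 1e-4 * j^3
  sm <- savgol_smooth(cubic, 51, 3)
  expect_equal(sm[26:375], cubic[26:375], tolerance = 1e-6)
  # one interior point equals an independent least-squares cubic fit
  set.seed(4)
  noisy <- cubic + rnorm(400)
  sm2 <- savgol_smooth(noisy, 51, 3)
  i <- 200
  win <- (i - 25):(i + 25)
  fit <- lm(y ~ poly(t, 3, raw = TRUE),
            data = data.frame(y = noisy[win], t = win))
  pred <- predict(fit, newdata = data.frame(t = i))
  expect_equal(sm2[i], unname(pred), tolerance = 1e-6)
  expect_error(savgol_smooth(x, 200, 3), "odd")
  expect_error(savgol_smooth(x[1:100], 201, 3), "length")
})

test_that("periodogram recovers analytic periods and flags flat profiles", {
  j <- -73:73
  y <- cos(2 * pi * j / 10.3)
  est <- estimate_period(y, band = c(8, 15), offsets = j)
  expect_lt(abs(est$period - 10.3), 0.05)
  expect_true(est$significant)
  # translational band on the full window
  j2 <- -500:500
  y2 <- cos(2 * pi * j2 / 192)
  est2 <- estimate_period(y2, band = c(150, 250), offsets = j2)
  expect_lt(abs(est2$period - 192), 1)
  # constant profile: no significant period
  est3 <- estimate_period(rep(1, 147), band = c(8, 15), offsets = j)
  expect_false(est3$significant)
  expect_equal(est3$power, 0)
  # missing offsets are handled by the uneven-sampling formulation
  y4 <- y; y4[sample(seq_along(y4), 30)] <- NA
  est4 <- estimate_period(y4, band = c(8, 15), offsets = j)
  expect_lt(abs(est4$period - 10.3), 0.05)
  expect_error(estimate_period(rep(NA_real_, 147), band = c(8, 15),
                               offsets = j), "all-missing")
})

test_that("sinusoid fits recover parameters and are shift-equivariant", {
  j <- -73:73
  y <- 0.1 + 0.5 * cos(2 * pi * j / 10.3)
  fit <- fit_sinusoid(y, band = c(8, 15), offsets = j)
  expect_equal(fit$offset_term, 0.1, tolerance = 1e-3)
  expect_equal(fit$amplitude, 0.5, tolerance = 1e-3)
  expect_equal(fit$period, 10.3, tolerance = 1e-2)
  expect_lt(min(fit$phase, 2 * pi - fit$phase), 1e-2)
  # flat profile: amplitude ~ 0
  fit2 <- fit_sinusoid(rep(0.2, 147), period = 10.3, offsets = j)
  expect_lt(fit2$amplitude, 1e-6)
  # phase recovered modulo 2 pi for shifted input
  phi <- 1.1
  y3 <- 0.5 * cos(2 * pi * j / 10.3 + phi)
  fit3 <- fit_sinusoid(y3, period = 10.3, offsets = j)
  dphi <- abs(fit3$phase - phi) %% (2 * pi)
  expect_lt(min(dphi, 2 * pi - dphi), 1e-6)
})

test_that("rotational phase labels follow the fitted extrema", {
  j <- -73:73
  y <- 0.5 * cos(2 * pi * j / 10.3)
  fit <- fit_sinusoid(y, period = 10.3, offsets = j)
  lab <- classify_rotational(c(0, round(10.3), round(10.3 / 2)), fit)
  expect_equal(lab[1], "inward")     # at a maximum
  expect_equal(lab[2], "inward")     # one period later
  expect_equal(lab[3], "outward")    # midway: minimum
  # non-significant fit labels everything intermediate
  fit2 <- fit_sinusoid(rep(0, 147), period = 10.3, offsets = j)
  expect_true(all(classify_rotational(j, fit2) == "intermediate"))
})

test_that("planted rotational phase is recovered for nearly all offsets", {
  sim <- cached("rotational_sim", run_sim(
    synthetic_config(seed = 101, rotational_amplitude = 0.5,
                     n_events = 50000L)))
  prof <- obs_exp_log2(sim$events, sim$tracks$dyads, sim$reference)
  fit <- fit_sinusoid(prof, band = c(8, 15), max_offset = 73)
  j <- -73:73
  labels <- classify_rotational(j, fit)
  # planted truth: intensity peaks at cos(2 pi d / 10.3) > 0 (phase 0)
  truth <- ifelse(cos(2 * pi * j / 10.3) > 0, "inward", "outward")
  planted_in <- j[truth == "inward"]
  expect_gte(mean(labels[match(planted_in, j)] == "inward"), 0.95)
})

test_that("TF midpoint profiles count, conserve, and stay flat under uniform events", {
  # zero events: zero profile
  sites <- data.frame(contig = "chrT", pos = c(1000L, 3000L))
  z <- tf_midpoint_profile(data.frame(contig = character(), pos = integer()),
                           sites, halfwidth = 100L, smooth = FALSE)
  expect_true(all(z$counts == 0))
  expect_error(tf_midpoint_profile(data.frame(contig = "chrT", pos = 1L),
                                   sites[0, ]), "zero")
  # conservation under nearest-midpoint assignment, ties to the leftmost
  ev <- data.frame(contig = "chrT", pos = c(990L, 2000L, 2990L, 5000L))
  pr <- tf_midpoint_profile(ev, sites, halfwidth = 1000L, smooth = FALSE)
  expect_equal(sum(pr$counts), 3)  # the 5000 event is beyond the window
  # the tie at 2000 goes to the leftmost site (offset +1000)
  expect_equal(pr$counts[pr$offsets == 1000], 1)
  expect_equal(pr$counts[pr$offsets == -1000], 0)
  # uniform events on a regular >=(2W+1)-spaced site grid give a flat profile
  flat <- cached("tf_flat", {
    cfg <- synthetic_config(seed = 55, contig_lengths = c(chrF = 2000000L),
                            n_events = 50000L)
    ref <- make_reference(cfg)
    tracks <- make_annotation_fixtures(cfg, ref)
    ev <- plant_events(cfg, ref, tracks)
    grid_sites <- data.frame(contig = "chrF",
                             pos = seq(1000L, 1999000L, by = 1100L))
    tf_midpoint_profile(ev, grid_sites, halfwidth = 500L, smooth = FALSE)
  })
  lam <- mean(flat$counts)
  z <- (flat$counts - lam) / sqrt(lam)
  expect_lt(max(abs(z)), 4.5)
})

test_that("null profile is unbiased: |mean L_j| small at planted-null conditions", {
  sim <- cached("flat_sim", run_sim(synthetic_config(seed = 77,
                                                     n_events = 50000L)))
  prof <- cached("flat_prof",
                 obs_exp_log2(sim$events, sim$tracks$dyads, sim$reference))
  expect_lt(abs(mean(prof$log2ratio, na.rm = TRUE)), 0.05)
})
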