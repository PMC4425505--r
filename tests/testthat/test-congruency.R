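# a noiseless scan with Gaussian peaks at known centres
make_scan <- function(centers, amps_ha = NULL, amps_ge = NULL,
                      pixel = 0.165, len = 20, sd = 0.25, base = 3,
                      viaat_amp = 200, id = "s1") {
  x <- seq(0, len, by = pixel)
  bump <- function(amps) {
    y <- rep(base, length(x))
    for (k in seq_along(centers)) {
      y <- y + amps[k] * exp(-(x - centers[k])^2 / (2 * sd^2))
    }
    y
  }
  if (is.null(amps_ha)) amps_ha <- rep(100, length(centers))
  if (is.null(amps_ge)) amps_ge <- amps_ha
  tibble::tibble(scan_id = id, position_um = x,
                 viaat = bump(rep(viaat_amp, length(centers))),
                 ha = bump(amps_ha), gephyrin = bump(amps_ge))
}

test_that("cluster detection finds noiseless peaks exactly and respects thresholds", {
  centers <- c(4, 9.9, 15)
  sc <- make_scan(centers)
  got <- detect_clusters(sc)
  expect_length(got, 3)
  # each detected centre is the sampled pixel nearest a true centre
  expect_true(all(abs(got - centers) <= 0.165 / 2 + 1e-9))

  expect_length(detect_clusters(sc, threshold = max(sc$viaat) + 1), 0)
  flat <- sc; flat$viaat <- 7
  expect_warning(out <- detect_clusters(flat), "flat")
  expect_length(out, 0)
})

test_that("planted clusters are recovered at SNR 5", {
  scans <- simulate_line_scans(n_scans = 20, clusters_per_scan = 5,
                               viaat_amplitude = 200, noise_sd = 40,
                               mode = "congruent", seed = 71)
  truth <- attr(scans, "true_centers")
  found <- 0; total <- 0
  for (sid in names(truth)) {
    sc <- scans[scans$scan_id == sid, ]
    got <- detect_clusters(sc)
    for (ct in truth[[sid]]) {
      total <- total + 1
      if (any(abs(got - ct) <= 0.5)) found <- found + 1
    }
  }
  expect_gte(found / total, 0.95)
})

test_that("window ratios are exact for proportional channels", {
  centers <- c(5, 10, 15)
  sc <- make_scan(centers)
  wr <- window_ratios(sc, centers)
  expect_equal(wr$ratio, rep(1, 3))
  expect_true(all(wr$n_pixels >= 4))

  sc2 <- make_scan(centers, amps_ha = c(100, 120, 80))
  sc2$ha <- 2 * sc2$gephyrin
  wr2 <- window_ratios(sc2, centers)
  expect_equal(wr2$ratio, rep(2, 3))

  # joint rescaling leaves ratios unchanged; scaling HA alone scales them
  sc3 <- sc2
  sc3$ha <- 0.4 * sc2$ha; sc3$gephyrin <- 0.4 * sc2$gephyrin
  expect_equal(window_ratios(sc3, centers)$ratio, wr2$ratio)
  sc4 <- sc2; sc4$ha <- 3 * sc2$ha
  expect_equal(window_ratios(sc4, centers)$ratio, 3 * wr2$ratio)
})

test_that("window ratios agree with a direct pixel-loop recomputation", {
  set.seed(72)
  sc <- make_scan(c(4, 8.5, 13, 17), amps_ha = runif(4, 50, 150),
                  amps_ge = runif(4, 50, 150))
  sc$ha <- sc$ha + rnorm(nrow(sc), 0, 2)
  sc$gephyrin <- sc$gephyrin + rnorm(nrow(sc), 0, 2)
  centers <- c(4, 8.5, 13, 17)
  wr <- window_ratios(sc, centers, full_len = 2.5, peak_len = 0.66)
  for (k in seq_along(centers)) {
    idx <- which(sc$position_um >= centers[k] - 1.25 &
                   sc$position_um <= centers[k] + 1.25)
    pk_pos <- sc$position_um[idx][which.max(sc$ha[idx])]
    pidx <- which(sc$position_um >= pk_pos - 0.33 &
                    sc$position_um <= pk_pos + 0.33)
    oracle <- mean(sc$ha[pidx]) / mean(sc$gephyrin[pidx])
    expect_equal(wr$ratio[k], oracle, tolerance = 1e-12)
  }
})

test_that("edge and low-gephyrin clusters are excluded with reasons", {
  sc <- make_scan(c(0.8, 10))
  wr <- window_ratios(sc, c(0.8, 10))
  expect_equal(wr$flag, c("edge", "ok"))
  expect_true(is.na(wr$ratio[1]))

  sc2 <- make_scan(c(5, 10), amps_ha = c(100, 100), amps_ge = c(100, 100))
  sc2$gephyrin <- 0
  wr2 <- window_ratios(sc2, c(5, 10), gephyrin_floor = 1)
  expect_equal(wr2$flag, rep("no_local_gephyrin", 2))
  expect_true(all(is.na(wr2$ratio)))
})

test_that("cluster correlation behaves on degenerate input", {
  v <- c(10, 20, 30, 40)
  expect_equal(correlate_clusters(v, v), 1)
  expect_equal(correlate_clusters(v, 100 - v), -1)
  expect_warning(r <- correlate_clusters(v, rep(5, 4)), "zero variance")
  expect_true(is.na(r))
  expect_warning(r2 <- correlate_clusters(v[1:2], v[1:2]), "fewer than 3")
  expect_true(is.na(r2))
})

test_that("the ratio histogram bins left-closed from zero and tallies exactly", {
  h <- congruency_histogram(rep(1, 12))
  expect_equal(nrow(h), 1)
  expect_equal(h$bin_lower, 1.0)
  expect_equal(h$bin_upper, 1.2)
  expect_equal(h$count, 12L)

  set.seed(73)
  r <- c(runif(200, 0, 3), 0.2, 0.4, 1.0)  # include exact bin edges
  h2 <- congruency_histogram(r)
  expect_equal(sum(h2$count), length(r))
  for (i in seq_len(nrow(h2))) {
    oracle <- sum(r >= h2$bin_lower[i] & r < h2$bin_upper[i])
    expect_equal(h2$count[i], oracle)
  }
})

test_that("the full pipeline separates congruent from independent coupling", {
  # congruent, zero noise: every ratio exactly 1, R = 1, one occupied bin
  cong <- simulate_line_scans(n_scans = 20, clusters_per_scan = 5,
                              mode = "congruent", noise_sd = 0, seed = 74)
  res <- congruency_analysis(cong)
  expect_equal(res$clusters$ratio, rep(1, res$n))
  expect_equal(res$R, 1)
  expect_equal(nrow(res$histogram), 1)
  expect_equal(res$histogram$bin_lower, 1.0)

  # independent amplitudes: correlation collapses towards zero
  ind <- simulate_line_scans(n_scans = 20, clusters_per_scan = 5,
                             mode = "independent", noise_sd = 4, seed = 75)
  res_i <- congruency_analysis(ind)
  expect_gte(res_i$n, 90)
  expect_lt(abs(res_i$R), 0.2)

  # congruent with moderate noise keeps a strong correlation and a modal bin
  # containing 1
  noisy <- simulate_line_scans(n_scans = 20, clusters_per_scan = 5,
                               mode = "congruent", noise_sd = 4, seed = 76)
  res_n <- congruency_analysis(noisy)
  expect_gt(res_n$R, 0.6)
  expect_equal(glance(res_n)$modal_bin_lower, 1.0)
})

test_that("line-scan CSV round trips through the reader", {
  scans <- simulate_line_scans(n_scans = 2, seed = 77)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(scans, path, row.names = FALSE)
  back <- read_line_scans(path)
  expect_equal(back$ha, scans$ha)
  expect_equal(back$scan_id, scans$scan_id)
  expect_error(read_line_scans({
    p2 <- withr::local_tempfile(fileext = ".csv")
    utils::write.csv(data.frame(a = 1), p2, row.names = FALSE)
    p2
  }), "columns")
})
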