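test_that("contact detection finds a sustained threshold crossing", {
  fc <- force_curve(time = 1:100, force = c(rep(0, 49), rep(5, 51)),
                    loading_rate = 2)
  expect_identical(detect_contact(fc), 50L)
  # below-run-length blips are not contact
  blip <- c(rep(0, 30), 4, rep(0, 18), rep(5, 51))
  expect_identical(detect_contact(force_curve(1:100, blip, 2),
                                  run_length = 3), 50L)
  # pure noise never crosses baseline + 5 sd for a sustained run
  set.seed(1)
  noise <- force_curve(1:200, rnorm(200, 0, 0.01), 2)
  expect_error(detect_contact(noise), class = "relaxlearn_no_contact")
})

test_that("distance transform converts time to crosshead travel", {
  # contact at t = 0 equivalent: rate 2 mm/min, 30 s after contact = 1 mm
  fc <- force_curve(time = 0:90, force = c(0, rep(3, 90)), loading_rate = 2)
  dc <- to_distance_curve(fc, contact = list(baseline_n = 1))
  expect_identical(dc$contact_index, 2L)
  expect_equal(dc$distance[dc$force > 0][31], 2 / 60 * 30)
  # synthetic curve with a known contact index recovers it exactly
  ec <- exact_force_curve(a = 2, b = 0.5, pre = 15, dt = 0.5)
  dc2 <- to_distance_curve(ec)
  expect_identical(dc2$contact_index, which(ec$time == 15))
  expect_equal(dc2$distance[1], 0)
  expect_true(all(diff(dc2$distance) > 0))
  # all-zero trace: no contact
  expect_error(to_distance_curve(force_curve(1:50, rep(0, 50), 2)),
               class = "relaxlearn_no_contact")
})

test_that("log-linear fit recovers exact exponentials", {
  ec <- exact_force_curve(a = 2, b = 0.5, dt = 0.2)
  fit <- window_and_fit(to_distance_curve(ec))
  expect_true(fit$accepted)
  expect_equal(fit$a, 2, tolerance = 1e-9)
  expect_equal(fit$b, 0.5, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # three collinear log-space points: x = 0,1,2 -> y = 1, e, e^2
  dc <- structure(list(distance = c(0, 1, 2, 3.7),
                       force = c(1, exp(1), exp(2), exp(3.7)),
                       contact_index = 1L, sample_id = "s", replicate_id = "1"),
                  class = "distance_curve")
  fit2 <- window_and_fit(dc)
  expect_equal(fit2$a, 1, tolerance = 1e-12)
  expect_equal(fit2$b, 1, tolerance = 1e-12)
  expect_equal(fit2$n_points, 3L)
})

test_that("short curves are rejected, and counts always balance", {
  short <- exact_force_curve(a = 1, b = 0.5, total_distance = 2)
  fit <- window_and_fit(to_distance_curve(short))
  expect_false(fit$accepted)
  expect_match(fit$reason, "insufficient length")
  # mixed set: accepted + rejected == input
  set <- c(lapply(1:5, function(i) exact_force_curve(1 + i / 10, 0.4,
                                                     sid = paste0("s", i))),
           lapply(6:8, function(i) exact_force_curve(1, 0.4,
                                                     total_distance = 2,
                                                     sid = paste0("s", i))),
           list(force_curve(1:50, rep(0, 50), 2, "s9")))
  res <- fit_force_curves(set)
  expect_identical(unname(res$counts["input"]), 9L)
  expect_identical(unname(res$counts["accepted"] + res$counts["rejected"]), 9L)
  expect_identical(nrow(res$fits), 5L)
  expect_setequal(res$rejections$reason,
                  c("insufficient length", "no contact detected"))
})

test_that("parameter recovery from noisy synthetic curves is within 5%", {
  spec <- force_population_spec(
    n_per_group = 10, groups = list(
      A = list(a_mean = 2, a_sd = 0.3, b_mean = 0.6, b_sd = 0.05),
      B = list(a_mean = 1, a_sd = 0.15, b_mean = 0.35, b_sd = 0.05)),
    replicates_per_sample = 5, sampling_rate = 2,
    pre_contact_duration = 10,  # 20 baseline points at 2 Hz
    noise_sd = 0.015, seed = 23)  # ~1% of the typical a
  out <- generate_force_curves(spec)
  res <- fit_force_curves(out$curves)
  merged <- merge(res$fits, out$truth, by = "sample_id",
                  suffixes = c("_hat", "_true"))
  expect_gte(nrow(merged), 100)
  expect_lt(median(abs(merged$a_hat - merged$a_true) / merged$a_true), 0.05)
  expect_lt(median(abs(merged$b_hat - merged$b_true)), 0.05)
})

test_that("Ward k=2 cut matches the exhaustive optimal 2-partition", {
  for (seed in 1:6) {
    set.seed(seed)
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    pts <- rbind(cbind(rnorm(n1, 0, 0.3), rnorm(n1, 0, 0.3)),
                 cbind(rnorm(n2, 4, 0.3), rnorm(n2, 4, 0.3)))
    hc <- hclust(dist(pts), method = "ward.D2")
    got <- cutree(hc, 2)
    want <- best_two_partition(pts)
    expect_true(same_partition(got, want),
                info = paste("seed", seed))
  }
})

test_that("HCA labeling recovers blob membership and orients A = hard", {
  set.seed(11)
  fits <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    a = c(rnorm(5, 2, 0.05), rnorm(5, 1, 0.05)),
    b = c(rnorm(5, 0.6, 0.01), rnorm(5, 0.35, 0.01)))
  lab <- label_by_hca(fits)
  expect_identical(lab$labels$group, rep(c("A", "B"), each = 5))
  # swapping which blob is harder swaps the names, not the partition
  lab2 <- label_by_hca(transform(fits, a = rev(a), b = rev(b)))
  expect_identical(lab2$labels$group, rep(c("B", "A"), each = 5))
  # two samples: forced singleton clusters
  lab3 <- label_by_hca(fits[c(1, 6), ])
  expect_setequal(lab3$labels$group, c("A", "B"))
  expect_error(label_by_hca(data.frame(sample_id = c("x", "y"),
                                       a = c(1, 1), b = c(2, 2))),
               "degenerate")
})

test_that("replicate fits aggregate to one (a,b) per sample before HCA", {
  fits <- data.frame(
    sample_id = rep(c("s1", "s2", "s3", "s4"), each = 3),
    a = rep(c(2, 2.1, 1, 1.1), each = 3) + rep(c(-0.01, 0, 0.01), 4),
    b = rep(c(0.6, 0.62, 0.3, 0.32), each = 3))
  lab <- label_by_hca(fits)
  expect_identical(nrow(lab$labels), 4L)
  expect_identical(lab$labels$group[lab$labels$sample_id %in% c("s1", "s2")],
                   c("A", "A"))
})
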