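mk_montage <- function(n = 4L, patient = "p1", rec = "r1") {
  data.frame(patient_id = patient, recording_id = rec,
             channel_id = sprintf("ch%02d", seq_len(n)),
             stringsAsFactors = FALSE)
}

mk_events <- function(channel, type, times, epoch = 60, patient = "p1", rec = "r1") {
  data.frame(patient_id = patient, recording_id = rec, channel_id = channel,
             event_type = type, time_s = times, epoch_length_s = epoch,
             stringsAsFactors = FALSE)
}

test_that("rates are event counts per minute, zero for silent channels", {
  ev <- mk_events("ch01", "spike", seq(0.5, 58, length.out = 12L))
  r <- compute_rates(ev, mk_montage())
  expect_equal(r$spike_rate[r$channel_id == "ch01"], 12)
  expect_equal(r$spike_rate[r$channel_id == "ch02"], 0)
  expect_equal(r$ripple_rate, rep(0, 4L))
  # a 30 s epoch with 3 ripples: 3 / 0.5 min = 6 per minute
  ev2 <- mk_events("ch02", "ripple", c(1, 10, 20), epoch = 30)
  r2 <- compute_rates(ev2, mk_montage())
  expect_equal(r2$ripple_rate[r2$channel_id == "ch02"], 6)
  expect_equal(r2$epoch_min[r2$channel_id == "ch02"], 0.5)
})

test_that("artifact channels are excluded and carry no rates downstream", {
  ev <- rbind(mk_events("ch01", "spike", c(1, 2, 3)),
              mk_events("ch03", "spike", c(4, 5)))
  art <- data.frame(patient_id = "p1", recording_id = "r1", channel_id = "ch03")
  r <- compute_rates(ev, mk_montage(), artifacts = art)
  expect_false("ch03" %in% r$channel_id)
  expect_equal(nrow(r), 3L)
})

test_that("event validation catches unknown channels, bad times and types", {
  expect_error(compute_rates(mk_events("chXX", "spike", 1), mk_montage()),
               "unknown channel")
  expect_error(compute_rates(mk_events("ch01", "spike", -1), mk_montage()),
               "negative")
  expect_error(compute_rates(mk_events("ch01", "spike", 61), mk_montage()),
               "within the epoch")
  expect_error(compute_rates(mk_events("ch01", "blip", 1), mk_montage()),
               "event_type")
})

test_that("rate x epoch conservation: totals equal event counts", {
  set.seed(51)
  mont <- mk_montage(10L)
  evs <- list()
  for (i in 1:30) {
    ch <- sample(mont$channel_id, 1L)
    ty <- sample(c("spike", "ripple", "fast_ripple"), 1L)
    evs[[i]] <- mk_events(ch, ty, runif(sample.int(5L, 1L), 0, 59.9))
  }
  ev <- do.call(rbind, evs)
  r <- compute_rates(ev, mont)
  for (ty in c("spike", "ripple", "fast_ripple")) {
    col <- c(spike = "spike_rate", ripple = "ripple_rate",
             fast_ripple = "fr_rate")[[ty]]
    expect_equal(sum(r[[col]] * r$epoch_min), sum(ev$event_type == ty))
  }
})

test_that("montage pair counts and ordering match the layout", {
  co <- matrix(rnorm(24L), ncol = 3L)
  strip <- electrode_array("s", 1L, 8L, co)
  expect_equal(nrow(build_montage(strip, "row")), 7L)
  co2 <- matrix(rnorm(60L), ncol = 3L)
  grid45 <- electrode_array("g", 4L, 5L, co2)
  expect_equal(nrow(build_montage(grid45, "row")), 16L)
  co3 <- matrix(rnorm(48L), ncol = 3L)
  grid44 <- electrode_array("h", 4L, 4L, co3)
  mont <- build_montage(grid44, "column")
  expect_equal(nrow(mont), 12L)
  # enumeration oracle: every column-adjacent pair, each exactly once
  pairs <- paste(mont$electrode_a, mont$electrode_b)
  want <- character()
  for (r in 1:3) for (c in 1:4)
    want <- c(want, paste((r - 1) * 4 + c, r * 4 + c))
  expect_setequal(pairs, want)
  # midpoints are the componentwise means
  expect_equal(as.matrix(mont[, c("mid_x", "mid_y", "mid_z")]),
               (co3[mont$electrode_a, ] + co3[mont$electrode_b, ]) / 2,
               ignore_attr = TRUE)
  expect_error(build_montage(strip, "diagonal"))
})

test_that("rate summaries follow the active-channel convention", {
  rec <- data.frame(pathology = c("A", "A", "A", "B", "B"),
                    spike_rate = c(0, 4, 8, 0, 0),
                    ripple_rate = c(1, 0, 2, 3, 5),
                    fr_rate = c(0, 0, 0, 0, 0))
  s <- summarize_rates(rec)
  sa <- s[s$pathology == "A" & s$event_type == "spike", ]
  expect_equal(sa$mean_rate, 6)           # mean over the two active channels
  expect_equal(sa$total_events, 12)
  sb <- s[s$pathology == "B" & s$event_type == "fast_ripple", ]
  expect_equal(sb$total_events, 0)
  expect_true(is.na(sb$mean_rate))        # the table's em-dash cells
  # adding zero-rate channels leaves the active-channel mean unchanged
  rec2 <- rbind(rec, data.frame(pathology = "A", spike_rate = 0,
                                ripple_rate = 0, fr_rate = 0))
  s2 <- summarize_rates(rec2)
  expect_equal(s2$mean_rate[s2$pathology == "A" & s2$event_type == "spike"],
               sa$mean_rate)
  # brute-force filtered mean/SD on random rates
  set.seed(52)
  rec3 <- data.frame(pathology = "X",
                     spike_rate = rpois(40L, 3), ripple_rate = 0, fr_rate = 0)
  s3 <- summarize_rates(rec3)
  pos <- rec3$spike_rate[rec3$spike_rate > 0]
  expect_equal(s3$mean_rate[s3$event_type == "spike"], mean(pos))
  expect_equal(s3$sd_rate[s3$event_type == "spike"], sd(pos))
})

test_that("dmax selects the maximal channel with lowest-id tie-break", {
  rec <- data.frame(patient_id = "p1", recording_id = "r1",
                    channel_id = c("c1", "c2", "c3"),
                    d_edge_mm = c(5, 10, 15),
                    spike_rate = c(3, 7, 7), ripple_rate = 0, fr_rate = 0,
                    stringsAsFactors = FALSE)
  d <- dmax(rec)
  expect_equal(nrow(d), 1L)
  expect_equal(d$channel_id, "c2")  # tie between c2 and c3 -> lowest id
  expect_equal(d$max_rate, 7)
  expect_equal(d$distance_mm, 10)
  # single channel
  d1 <- dmax(rec[1L, ])
  expect_equal(d1$channel_id, "c1")
  # argmax oracle on a random table
  set.seed(53)
  rec2 <- data.frame(patient_id = rep(c("pA", "pB"), each = 20L),
                     recording_id = "r1",
                     channel_id = sprintf("c%02d", rep(1:20, 2L)),
                     d_edge_mm = runif(40L, 0, 40),
                     spike_rate = rpois(40L, 4),
                     ripple_rate = rpois(40L, 2), fr_rate = 0,
                     stringsAsFactors = FALSE)
  d2 <- dmax(rec2)
  for (i in seq_len(nrow(d2))) {
    sel <- rec2[rec2$patient_id == d2$patient_id[i], ]
    col <- c(spike = "spike_rate", ripple = "ripple_rate",
             fast_ripple = "fr_rate")[[d2$event_type[i]]]
    expect_equal(d2$max_rate[i], max(sel[[col]]))
    expect_true(d2$distance_mm[i] %in% sel$d_edge_mm)
  }
})
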