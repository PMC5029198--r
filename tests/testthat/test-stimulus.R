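test_that("element counts, signal fractions and displacement magnitudes hold", {
  for (task in c("rdk", "bar")) {
    elements <- if (task == "rdk") element_spec("dot") else element_spec("bar")
    gen <- if (task == "rdk") generate_rdk_sequence else generate_bar_sequence
    for (coh in c(0, 37, 50, 100)) {
      spec <- coherence_spec(coh, "up")
      seq <- gen(elements = elements, spec = spec, seed = coh + 1)
      expect_length(seq$frames, 8)
      for (f in seq$frames) expect_equal(nrow(f), elements$count)
      k <- signal_count(coh, elements$count)
      expect_true(all(colSums(seq$roles == "signal") == k))
      for (d in displacements(seq)) {
        expect_equal(sqrt(rowSums(d^2)), rep(0.12, elements$count),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("full-coherence motion is uniform translation in the signal direction", {
  seq <- generate_rdk_sequence(spec = coherence_spec(100, "up"), seed = 3)
  for (d in displacements(seq)) {
    expect_equal(d[, 1], rep(0, 200), tolerance = 1e-12)
    expect_equal(d[, 2], rep(0.12, 200), tolerance = 1e-12)
  }
  bars <- generate_bar_sequence(spec = coherence_spec(100, "down"), seed = 4)
  for (d in displacements(bars)) {
    expect_equal(d[, 2], rep(-0.12, 50), tolerance = 1e-12)
  }
})

test_that("zero-coherence noise is directionally symmetric", {
  # dots: mean net vertical displacement over seeds within 3 SE of zero
  net <- vapply(1:600, function(s) {
    seq <- generate_rdk_sequence(spec = coherence_spec(0, "up"), seed = s)
    mean(Reduce(`+`, lapply(displacements(seq), function(d) d[, 2])))
  }, numeric(1))
  expect_lt(abs(mean(net)), 3 * sd(net) / sqrt(length(net)))

  # bars: each noise update is a fair up/down coin (99% binomial interval)
  ups <- unlist(lapply(1:30, function(s) {
    seq <- generate_bar_sequence(spec = coherence_spec(0, "up"), seed = s)
    lapply(displacements(seq), function(d) d[, 2] > 0)
  }))
  n <- length(ups)
  expect_gt(n, 1e4)
  expect_lt(abs(mean(ups) - 0.5), 2.576 * sqrt(0.25 / n))
})

test_that("signal labels are redrawn on every update", {
  seq <- generate_rdk_sequence(spec = coherence_spec(50, "up"), seed = 9)
  expect_true(all(colSums(seq$roles == "signal") == 100))
  sets <- apply(seq$roles, 2, function(r) paste(which(r == "signal"),
                                                collapse = ","))
  expect_gt(length(unique(sets)), 1)
})

test_that("static form superimposes fixed-assignment streaks", {
  img <- collapse_to_static_form(spec = coherence_spec(100, "vertical"),
                                 seed = 5)
  expect_equal(nrow(img$positions), 1600)
  expect_true(all(img$roles == "signal"))
  xs <- sapply(img$frames, function(f) f[, 1])
  ys <- sapply(img$frames, function(f) f[, 2])
  # vertical streaks never move horizontally
  expect_true(all(abs(xs - xs[, 1]) < 1e-12))
  # trails that do not cross the wrap boundary span exactly 7 * 0.12 deg
  extent <- apply(ys, 1, function(y) diff(range(y)))
  wrapped <- extent > 1  # a wrapped trail jumps by ~window size
  expect_lt(mean(wrapped), 0.2)
  expect_equal(extent[!wrapped], rep(7 * 0.12, sum(!wrapped)),
               tolerance = 1e-9)

  # at zero coherence no trail is constrained to the signal axis
  img0 <- collapse_to_static_form(spec = coherence_spec(0, "vertical"),
                                  seed = 6)
  expect_true(all(img0$roles == "noise"))
  xs0 <- sapply(img0$frames, function(f) f[, 1])
  expect_true(all(apply(xs0, 1, function(x) diff(range(x))) > 0))
})

test_that("temporal form alternates jitter between fixed populations", {
  for (coh in c(0, 40, 100)) {
    seq <- generate_temporal_form_sequence(
      spec = coherence_spec(coh, "vertical"), seed = coh + 11)
    ds <- displacements(seq)
    for (u in seq_along(ds)) {
      moved <- rowSums(abs(ds[[u]])) > 0
      expect_equal(sum(moved), 100)
      mover_pop <- if (u %% 2 == 1) 1L else 2L
      expect_true(all(seq$population[moved] == mover_pop))
    }
  }
  # full coherence: populations segregate perfectly about the midline
  seq <- generate_temporal_form_sequence(
    spec = coherence_spec(100, "vertical"), seed = 21)
  x0 <- seq$frames[[1]][, 1]
  expect_true(all(x0[seq$population == 1] < 6))
  expect_true(all(x0[seq$population == 2] >= 6))
})

test_that("empirical coherence matches the generated signal fraction", {
  expect_equal(empirical_coherence(
    generate_rdk_sequence(spec = coherence_spec(100, "up"), seed = 1)), 100)
  # dot noise matches the signal vector with probability zero
  expect_gte(empirical_coherence(
    generate_rdk_sequence(spec = coherence_spec(60, "down"), seed = 2)), 60)
  # bar noise matches with probability 1/2
  vals <- vapply(1:300, function(s) empirical_coherence(
    generate_bar_sequence(spec = coherence_spec(0, "up"), seed = s)),
    numeric(1))
  expect_lt(abs(mean(vals) - 50), 3 * sd(vals) / sqrt(length(vals)))

  expect_error(empirical_coherence(
    collapse_to_static_form(spec = coherence_spec(50, "vertical"),
                            seed = 1)), "motion")
  expect_error(empirical_coherence(
    generate_temporal_form_sequence(spec = coherence_spec(50, "vertical"),
                                    seed = 1)), "motion")
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_rdk_sequence(spec = coherence_spec(35, "up"), seed = 77)
  b <- generate_rdk_sequence(spec = coherence_spec(35, "up"), seed = 77)
  expect_identical(a, b)
  tf1 <- generate_temporal_form_sequence(
    spec = coherence_spec(35, "horizontal"), seed = 78)
  tf2 <- generate_temporal_form_sequence(
    spec = coherence_spec(35, "horizontal"), seed = 78)
  expect_identical(tf1, tf2)
})

test_that("frame sequences round-trip through delimited text", {
  seq <- generate_rdk_sequence(spec = coherence_spec(45, "down"), seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frames(seq, path)
  back <- read_frames(path)
  expect_equal(back$task_kind, seq$task_kind)
  expect_equal(back$signal_direction, seq$signal_direction)
  expect_equal(back$roles, seq$roles, ignore_attr = TRUE)
  for (f in seq_along(seq$frames)) {
    expect_equal(back$frames[[f]], seq$frames[[f]], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("invalid stimulus requests are rejected", {
  expect_error(coherence_spec(101, "up"), "\\[0, 100\\]")
  expect_error(coherence_spec(-1, "up"), "\\[0, 100\\]")
  expect_error(element_spec("dot", count = 0), "positive")
  expect_error(generate_rdk_sequence(elements = element_spec("bar"),
                                     spec = coherence_spec(50, "up")),
               "dot")
  expect_error(generate_bar_sequence(elements = element_spec("dot"),
                                     spec = coherence_spec(50, "up")),
               "bar")
  expect_error(collapse_to_static_form(spec = coherence_spec(50, "up")),
               "vertical")
  expect_error(display_geometry(update_hz = 17), "divide")
})
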