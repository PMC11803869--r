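# profiles: dyad-aligned frequency profiles, smoothing, symmetrization,
# SHL coordinates, off-peak detection, strand asymmetry

test_that("mono_profile handles degenerate compositions", {
  polyA <- make_fragments(rep(strrep("A", 147), 10))
  pW <- mono_profile(polyA, c("A", "T"))
  expect_equal(pW$values, rep(1, 147))
  expect_equal(pW$coverage, rep(10L, 147))

  mix <- make_fragments(c(rep(strrep("A", 147), 5), rep(strrep("G", 147), 5)))
  expect_equal(mono_profile(mix, "A")$values, rep(0.5, 147))
  expect_error(mono_profile(mix[integer(0), ], "A"), "no fragments")
})

test_that("profile counting matches the brute-force tally oracle", {
  set.seed(21)
  fr <- random_fragments(200, lengths = 146:149,
                         bases = c("A", "C", "G", "T", "N"),
                         prob = c(0.3, 0.2, 0.2, 0.28, 0.02))
  for (bs in list("A", c("A", "T"), c("C", "G"))) {
    got <- mono_profile(fr, bs)
    want <- oracle_mono_profile(fr, bs)
    expect_equal(got$counts, want$counts)
    expect_equal(got$coverage, want$coverage)
    expect_equal(got$values, want$values)
  }
  for (ds in list(ww_set(), ss_set(), c("CA", "AC"))) {
    got <- di_profile(fr, ds)
    want <- oracle_di_profile(fr, ds)
    expect_equal(got$counts, want$counts)
    expect_equal(got$coverage, want$coverage)
  }
})

test_that("di_profile degenerate cases", {
  polyG <- make_fragments(rep(strrep("G", 147), 4))
  expect_equal(di_profile(polyG, ss_set())$values, rep(1, 146))
  expect_equal(di_profile(polyG, ww_set())$values, rep(0, 146))
  ag <- make_fragments(rep(strrep("AG", 74), 3))  # 148-mers, all AG/GA dimers
  expect_equal(di_profile(ag, ww_set())$counts, rep(0L, 146))
  expect_equal(di_profile(ag, ss_set())$counts, rep(0L, 146))
  expect_error(di_profile(polyG, character(0)), "empty")
})

test_that("base-frequency closure holds at every covered position", {
  set.seed(22)
  fr <- random_fragments(300, lengths = 146:149,
                         bases = c("A", "C", "G", "T", "N"),
                         prob = c(0.35, 0.15, 0.2, 0.28, 0.02))
  tot <- Reduce(`+`, lapply(c("A", "C", "G", "T"), function(b) {
    mono_profile(fr, b)$values
  }))
  expect_true(all(abs(tot - 1) < 1e-12))
  dtot <- di_profile(fr, ww_set())$values + di_profile(fr, ss_set())$values +
    di_profile(fr, c("AC", "AG", "TC", "TG", "CA", "GA", "CT", "GT"))$values
  expect_true(all(abs(dtot - 1) < 1e-12))
})

test_that("smooth3 uses a shrinking window over covered positions", {
  const <- analytic_profile(rep(0.4, 147), smoothed = FALSE,
                            symmetrized = FALSE)
  expect_equal(smooth3(const)$values, rep(0.4, 147))

  imp <- analytic_profile(c(0, 1, rep(0, 145)), smoothed = FALSE,
                          symmetrized = FALSE)
  sm <- smooth3(imp)$values
  expect_equal(sm[1:4], c(1 / 2, 1 / 3, 1 / 3, 0))

  edge <- analytic_profile(c(rep(0, 146), 1), smoothed = FALSE,
                           symmetrized = FALSE)
  expect_equal(smooth3(edge)$values[147:145], c(1 / 2, 1 / 3, 0))
  expect_error(smooth3(smooth3(imp)), "already smoothed")
})

test_that("symmetrize reflection-averages and is idempotent", {
  set.seed(23)
  v <- runif(147)
  p <- analytic_profile(v, smoothed = FALSE, symmetrized = FALSE)
  s <- symmetrize(p)
  expect_equal(s$values[74 - 50], (v[74 - 50] + v[74 + 50]) / 2)
  expect_equal(s$values[74 + 50], (v[74 - 50] + v[74 + 50]) / 2)
  expect_identical(symmetrize(s)$values, s$values)
  # smooth3 and symmetrize commute on full-coverage profiles
  expect_equal(smooth3(symmetrize(p))$values,
               symmetrize(smooth3(p))$values)
})

test_that("complement-aware symmetrization matches the RC re-tally oracle", {
  set.seed(24)
  fr <- random_fragments(150, lengths = 147L,
                         prob = c(0.4, 0.15, 0.15, 0.3))
  pa <- mono_profile(fr, "A")
  pt <- mono_profile(fr, "T")
  got <- symmetrize(pa, complement_aware = TRUE, complement_profile = pt)
  # reverse-complementing every fragment and re-tallying A must agree
  rc <- fr
  rc$sequence <- reverse_complement(fr$sequence)
  pa_rc <- mono_profile(rc, "A")
  expect_equal(got$values, (pa$values + pa_rc$values) / 2)
  expect_error(symmetrize(pa, complement_aware = TRUE), "complement_profile")
})

test_that("SHL coordinate conversions", {
  expect_equal(shl_of(0), 0)
  expect_equal(position_of(0), 0L)
  expect_equal(position_of(-4), -42L)          # 1-based position 32
  expect_equal(position_of(-4) + 74L, 32L)
  expect_equal(position_of(1.5), 16L)
  expect_equal(position_of(c(-6.5, 6.5)), c(-68L, 68L))
  expect_equal(shl_of(position_of(3.5)), 3.5, tolerance = 0.05)
})

test_that("off-peak detection: absent on a pure cosine, recovers bumps", {
  rel <- -73:73
  period <- 10.4
  # gentle oscillation: a bump only registers as a peak when its curvature
  # exceeds the cosine's at the trough (b/width^2 > a (2 pi / period)^2)
  cosine <- 0.25 + 0.005 * (-cos(2 * pi * rel / period))
  none <- detect_off_peaks(analytic_profile(cosine), period)
  expect_false(any(none$present))
  expect_true(all(none$amplitude <= 0))

  bump_at <- function(shl, b) {
    ctr <- position_of(shl, period)
    b * exp(-(rel - ctr)^2 / (2 * 2^2)) + b * exp(-(rel + ctr)^2 / (2 * 2^2))
  }
  for (b in c(0.01, 0.02, 0.05)) {
    withb <- detect_off_peaks(analytic_profile(cosine + bump_at(4, b)),
                              period)
    expect_true(withb["P1", "present"])
    expect_equal(withb["P1", "amplitude"], b, tolerance = 0.2)
    expect_false(withb["P2", "present"])
  }
  p2only <- detect_off_peaks(analytic_profile(cosine + bump_at(1, 0.03)),
                             period)
  expect_true(p2only["P2", "present"])
  expect_false(p2only["P1", "present"])
  expect_error(
    detect_off_peaks(analytic_profile(cosine, smoothed = FALSE)),
    "smoothed")
})

test_that("strand asymmetry: zeros, planted spike, RC negation", {
  set.seed(25)
  fr <- random_fragments(100, lengths = 147L)
  pa <- mono_profile(fr, "A")
  expect_equal(unclass(strand_asymmetry(pa, pa))[1:147], rep(0, 147),
               ignore_attr = TRUE)

  # plant A enrichment at one position by editing sequences directly
  fr2 <- fr
  substr(fr2$sequence, 30, 30) <- "A"
  d <- strand_asymmetry(mono_profile(fr2, "A"), mono_profile(fr2, "T"))
  expect_equal(which.max(d), 30L)
  expect_gt(d[30], 0.5)
  expect_lt(max(abs(d[-30])), 0.35)

  # reverse-complementing negates the asymmetry up to mirroring
  rc <- fr2
  rc$sequence <- reverse_complement(fr2$sequence)
  d_rc <- strand_asymmetry(mono_profile(rc, "A"), mono_profile(rc, "T"))
  expect_equal(as.numeric(d_rc), -rev(as.numeric(d)))
})

test_that("flatness: position-independent composition gives flat profiles", {
  set.seed(26)
  pop <- sample_population(population_spec(
    n_positions = 500L, occurrence_law = list(type = "fixed", value = 40L),
    composition = composition_model(w_baseline = 0.5)))
  pW <- mono_profile(pop$fragments, c("A", "T"))
  se <- sqrt(0.5 * 0.5 / pW$coverage)
  expect_true(all(abs(pW$values - 0.5) < 5 * se))
})
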