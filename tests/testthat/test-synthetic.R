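# synthetic_data: probability matrices, sampling, shifts, determinism

test_that("probability matrix: flat model, rows sum to 1", {
  P <- build_probability_matrix(composition_model(w_baseline = 0.6,
                                                  at_split = 0.7))
  expect_equal(dim(P), c(147L, 4L))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_true(all(abs(P[, "A"] - 0.42) < 1e-12))
  expect_true(all(abs(P[, "G"] - 0.2) < 1e-12))
  expect_equal(P, P[rep(1, 147), ], ignore_attr = TRUE)  # all rows equal
})

test_that("periodic W term peaks at half-integer SHLs, flips with phase", {
  m <- composition_model(periodic_amplitude = 0.1)
  P <- build_probability_matrix(m)
  w <- P[, "A"] + P[, "T"]
  i <- function(rel) rel + 74L
  expect_gt(w[i(position_of(-1.5))] - w[i(position_of(-2))], 0.1)
  # dyad (integer SHL 0) is a W minimum in the canonical phase
  expect_equal(w[i(0)], 0.4, tolerance = 1e-9)

  Pf <- build_probability_matrix(composition_model(periodic_amplitude = 0.1,
                                                   phase_flip = TRUE))
  wf <- Pf[, "A"] + Pf[, "T"]
  expect_equal(wf[i(0)], 0.6, tolerance = 1e-9)  # maxima move to integer SHL
  expect_equal(wf + w, rep(1, 147), tolerance = 1e-9)
})

test_that("bumps add localized, A-biased W enrichment at both +/- SHL", {
  b <- offpeak_bump(shl = 4, height = 0.02, width = 2, a_over_t = 1)
  P0 <- build_probability_matrix(composition_model())
  P1 <- build_probability_matrix(composition_model(offpeak_bumps = list(b)))
  dw <- (P1[, "A"] + P1[, "T"]) - (P0[, "A"] + P0[, "T"])
  ctr <- c(position_of(-4) + 74L, position_of(4) + 74L)
  expect_equal(unname(dw[ctr]), c(0.02, 0.02), tolerance = 1e-9)
  expect_true(all(dw[abs(seq_len(147) - ctr[1]) > 8 &
                     abs(seq_len(147) - ctr[2]) > 8] < 1e-4))
  # all of the extra W mass is adenine
  da <- P1[, "A"] - P0[, "A"]
  dt <- P1[, "T"] - P0[, "T"]
  expect_equal(unname(da[ctr]), c(0.02, 0.02), tolerance = 1e-9)
  expect_true(all(abs(dt) < 1e-12))
})

test_that("out-of-range probabilities are clipped with a warning", {
  expect_warning(
    P <- build_probability_matrix(
      composition_model(w_baseline = 0.95, periodic_amplitude = 0.2)),
    "clipped")
  expect_true(all(P >= 0 & P <= 1))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
})

test_that("sampling is seed-deterministic and conserves occurrence mass", {
  spec <- population_spec(n_positions = 100L,
                          occurrence_law = list(type = "fixed", value = 10L),
                          seed = 99L)
  a <- sample_population(spec)
  b <- sample_population(spec)
  expect_identical(a$fragments, b$fragments)
  expect_identical(a$dyad_table, b$dyad_table)
  expect_equal(attr(a$dyad_table, "total_occurrence"), 1000L)
  expect_equal(nrow(a$fragments), 1000L)
  spec2 <- spec; spec2$seed <- 100L
  expect_false(identical(sample_population(spec2)$fragments, a$fragments))

  # lognormal occurrences still conserve mass
  spec3 <- population_spec(
    n_positions = 50L,
    occurrence_law = list(type = "lognormal", meanlog = 2, sdlog = 0.5),
    seed = 7L)
  p3 <- sample_population(spec3)
  expect_equal(nrow(p3$fragments), sum(p3$truth$sites$occurrence))
})

test_that("empirical base frequencies converge to the probability matrix", {
  set.seed(61)
  comp <- composition_model(periodic_amplitude = 0.08, at_split = 0.6,
                            offpeak_bumps = list(offpeak_bump(1, 0.03)))
  pop <- sample_population(population_spec(
    n_positions = 500L, occurrence_law = list(type = "fixed", value = 100L),
    composition = comp))
  P <- build_probability_matrix(comp)
  n <- nrow(pop$fragments)
  for (base in c("A", "C", "G", "T")) {
    emp <- mono_profile(pop$fragments, base)$values
    se <- sqrt(P[, base] * (1 - P[, base]) / n)
    expect_true(all(abs(emp - P[, base]) < 5 * se))
  }
})

test_that("planted periodic amplitude is recovered from the raw profile", {
  set.seed(62)
  a <- 0.1
  pop <- sample_population(population_spec(
    n_positions = 1000L, occurrence_law = list(type = "fixed", value = 100L),
    composition = composition_model(periodic_amplitude = a)))
  w <- mono_profile(pop$fragments, c("A", "T"))
  rel <- -73:73
  basis <- -cos(2 * pi * rel / 10.4)
  fit <- stats::lm(w$values ~ basis)
  expect_equal(unname(stats::coef(fit)[2]), a, tolerance = 0.1)
  # 3-bp smoothing attenuates a 10.4-bp cosine by (1 + 2 cos(2*pi/10.4)) / 3
  att <- (1 + 2 * cos(2 * pi / 10.4)) / 3
  sm <- smooth3(w)
  fit_sm <- stats::lm(sm$values ~ basis)
  expect_equal(unname(stats::coef(fit_sm)[2]), a * att, tolerance = 0.1)
})

test_that("fragment length jitter respects the length distribution", {
  set.seed(63)
  ld <- c("146" = 0.1, "147" = 0.6, "148" = 0.2, "149" = 0.1)
  pop <- sample_population(population_spec(
    n_positions = 300L, occurrence_law = list(type = "fixed", value = 20L),
    length_distribution = ld))
  frq <- table(pop$fragments$length) / nrow(pop$fragments)
  expect_equal(as.numeric(frq), as.numeric(ld), tolerance = 0.1)
  expect_true(all(nchar(pop$fragments$sequence) == pop$fragments$length))
})

test_that("shifted populations: unmoved dominates DCC(0), 15-bp forced peak", {
  set.seed(64)
  base <- sample_population(population_spec(
    n_positions = 200L, occurrence_law = list(type = "fixed", value = 10L)))
  still <- make_shifted_population(base, shift_spec(1, 0, 0))
  r0 <- compute_dcc(base$dyad_table, still$dyad_table, max_dist = 100L)
  expect_equal(which.max(r0$dcc), 1L)  # distance 0
  expect_equal(sum(r0$dcc), r0$dcc[1])

  ctr <- make_shifted_population(
    base, shift_spec(0, 0, 1, counterphase_n = 1L))
  r15 <- compute_dcc(base$dyad_table, ctr$dyad_table, max_dist = 100L)
  expect_equal(r15$dcc[16], sum(r15$dcc))
  expect_equal(find_dcc_peaks(r15)$distance, 15L)
  expect_equal(phase_partition(r15)$counterphase_fraction, 1)
  # truth record keeps the per-site shifts
  expect_true(all(abs(ctr$truth$shifts$shift) == 15L))
})

test_that("population files round-trip through FASTA/BED/TSV", {
  set.seed(65)
  pop <- sample_population(population_spec(
    n_positions = 20L, occurrence_law = list(type = "fixed", value = 2L)))
  dir <- withr::local_tempdir()
  paths <- write_population(pop, file.path(dir, "pop"))
  expect_true(all(file.exists(paths)))
  fr <- read_fragments(paths["fasta"], "FASTA")
  expect_equal(sort(fr$sequence), sort(pop$fragments$sequence))
  tab <- read_dyad_table(paths["dyads"])
  expect_equal(tab$occurrence, pop$dyad_table$occurrence)
  truth <- jsonlite::read_json(paths["truth"], simplifyVector = TRUE)
  expect_equal(truth$spec$n_positions, 20L)
})
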