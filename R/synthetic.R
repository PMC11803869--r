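# Synthetic nucleosome fragment populations with planted, analytically known
# sequence structure.
#
# Fragments are sampled base-by-base from a position-specific composition
# model in the dyad frame (not cut from a simulated genome): every planted
# parameter is then exactly recoverable in expectation. Bases are independent
# across positions; WW/SS dinucleotide periodicity is induced through the
# mononucleotide W probability, which is sufficient to drive all downstream
# statistics.

#' Planted composition model for synthetic nucleosomes
#'
#' Describes the per-position base probabilities of a nucleosome population
#' in the dyad frame. The W = A/T probability is
#' `w_baseline + periodic_amplitude * cos-term + bumps`, with the cosine
#' phased so W maxima sit at minor-groove bending sites (half-integer SHLs)
#' -- or at integer SHLs when `phase_flip = TRUE` (the anti-WW/SS pattern).
#' Gaussian off-peak bumps (see [offpeak_bump()]) add localized W enrichment
#' whose extra mass is split between A and T by the bump's `a_over_t` bias,
#' emulating the adenine-specific off-peaks seen near SHL +/-4 and +/-1.
#'
#' @param w_baseline Position-independent W probability (default 0.5).
#' @param periodic_amplitude Amplitude of the 10.4-bp W oscillation
#'   (default 0).
#' @param offpeak_bumps List of [offpeak_bump()]s.
#' @param at_split Probability that a (non-bump) W base is A (default 0.5).
#' @param gc_split Probability that an S base is G (default 0.5).
#' @param phase_flip If TRUE, shift the oscillation by half a period
#'   (anti-WW/SS population).
#' @param end_bias Optional `list(k, delta)`: add `delta` to the W
#'   probability in the terminal `k` bp (crude MNase end-bias emulation).
#' @param period Helical period, bp (default 10.4).
#' @return A `composition_model`.
#' @export
composition_model <- function(w_baseline = 0.5, periodic_amplitude = 0,
                              offpeak_bumps = list(), at_split = 0.5,
                              gc_split = 0.5, phase_flip = FALSE,
                              end_bias = NULL, period = 10.4) {
  stopifnot(w_baseline > 0, w_baseline < 1, periodic_amplitude >= 0,
            at_split >= 0, at_split <= 1, gc_split >= 0, gc_split <= 1)
  structure(
    list(w_baseline = w_baseline, periodic_amplitude = periodic_amplitude,
         offpeak_bumps = offpeak_bumps, at_split = at_split,
         gc_split = gc_split, phase_flip = phase_flip,
         end_bias = end_bias, period = period),
    class = "composition_model"
  )
}

#' Gaussian off-peak bump
#'
#' A localized W enrichment of the given height (probability units) and
#' Gaussian width (sd, bp), centred at SHL `shl`; unless `mirror = FALSE` it
#' is planted symmetrically at -`shl` as well (histone-tail contacts are
#' dyad-symmetric). `a_over_t` sets the fraction of the extra W mass that
#' goes to adenine on the reference-forward strand (1 = adenine-only).
#'
#' @param shl SHL centre (use 4 for a P1-like, 1 for a P2-like bump).
#' @param height Peak height in W-probability units.
#' @param width Gaussian sd, bp.
#' @param a_over_t Fraction of the bump mass assigned to A (default 1).
#' @param mirror Plant at both +shl and -shl (default TRUE).
#' @return A bump description list.
#' @export
offpeak_bump <- function(shl, height, width = 2, a_over_t = 1,
                         mirror = TRUE) {
  stopifnot(height >= 0, width > 0, a_over_t >= 0, a_over_t <= 1)
  list(shl = shl, height = height, width = width, a_over_t = a_over_t,
       mirror = mirror)
}

#' Per-position base-probability matrix of a composition model
#'
#' Evaluates a [composition_model()] on the dyad frame of a fragment of the
#' given length (dyad at 0-based index `floor((L-1)/2)`), clipping W
#' probabilities into \[eps, 1 - eps\] with a warning when clipping occurs.
#'
#' @param model A `composition_model`.
#' @param length Fragment length, bp (default 147).
#' @param eps Clipping margin.
#' @return `length` x 4 matrix of probabilities, columns A, C, G, T; rows
#'   sum to 1.
#' @export
build_probability_matrix <- function(model, length = 147L, eps = 1e-6) {
  stopifnot(inherits(model, "composition_model"))
  L <- as.integer(length)
  dy <- (L - 1L) %/% 2L
  rel <- (0:(L - 1L)) - dy
  sgn <- if (model$phase_flip) 1 else -1   # -cos: maxima at half-integer SHL
  w <- model$w_baseline +
    model$periodic_amplitude * sgn * cos(2 * pi * rel / model$period)
  a_extra <- numeric(L)
  for (b in model$offpeak_bumps) {
    centers <- position_of(b$shl, model$period)
    if (isTRUE(b$mirror) && b$shl != 0) {
      centers <- c(centers, position_of(-b$shl, model$period))
    }
    for (ctr in centers) {
      g <- b$height * exp(-(rel - ctr)^2 / (2 * b$width^2))
      w <- w + g
      a_extra <- a_extra + g * (b$a_over_t - model$at_split)
    }
  }
  if (!is.null(model$end_bias)) {
    k <- model$end_bias$k
    w[c(seq_len(k), (L - k + 1L):L)] <-
      w[c(seq_len(k), (L - k + 1L):L)] + model$end_bias$delta
  }
  n_clip <- sum(w < eps | w > 1 - eps)
  if (n_clip > 0) {
    warning(n_clip, " position(s) clipped into [eps, 1-eps]")
  }
  w <- pmin(pmax(w, eps), 1 - eps)
  pa <- pmin(pmax(w * model$at_split + a_extra, 0), w)
  pt <- w - pa
  pg <- (1 - w) * model$gc_split
  pc <- 1 - w - pg
  out <- cbind(A = pa, C = pc, G = pg, T = pt)
  stopifnot(all(abs(rowSums(out) - 1) < 1e-9))
  out
}

#' Specification of a synthetic nucleosome population
#'
#' @param n_positions Number of distinct dyad sites on the synthetic contig.
#' @param occurrence_law Either `list(type = "fixed", value = k)` or
#'   `list(type = "lognormal", meanlog, sdlog)` (counts rounded, min 1).
#' @param length_distribution Named numeric vector of probabilities over
#'   fragment lengths (names are lengths in bp); default all fragments
#'   147 bp, the nucleosome-core length.
#' @param composition A [composition_model()].
#' @param spacing_range Integer range the inter-dyad spacing is drawn from
#'   uniformly; the default 160--220 bp brackets typical nucleosome repeat
#'   lengths and keeps neighbouring sites outside the default DCC window.
#' @param contig Contig name.
#' @param seed Optional integer; when set, fully determines the sample.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_positions = 200L,
                            occurrence_law = list(type = "fixed", value = 10L),
                            length_distribution = c("147" = 1),
                            composition = composition_model(),
                            spacing_range = c(160L, 220L),
                            contig = "chrS", seed = NULL) {
  stopifnot(n_positions >= 1, abs(sum(length_distribution) - 1) < 1e-9,
            all(as.integer(names(length_distribution)) >= 100))
  structure(
    list(n_positions = as.integer(n_positions),
         occurrence_law = occurrence_law,
         length_distribution = length_distribution,
         composition = composition,
         spacing_range = as.integer(spacing_range),
         contig = contig, seed = seed),
    class = "population_spec"
  )
}

sample_occurrences <- function(law, n) {
  switch(law$type,
    fixed = rep(as.integer(law$value), n),
    lognormal = pmax(1L, as.integer(round(
      stats::rlnorm(n, law$meanlog, law$sdlog)))),
    stop("unknown occurrence law: ", law$type)
  )
}

# sample m fragment sequences of length L from a probability matrix
sample_sequences <- function(prob, m) {
  L <- nrow(prob)
  bases <- c("A", "C", "G", "T")
  cols <- lapply(seq_len(L), function(j) {
    bases[sample.int(4L, m, replace = TRUE, prob = prob[j, ])]
  })
  do.call(paste0, cols)
}

#' Sample a synthetic nucleosome population
#'
#' Draws dyad sites (cumulative spacings from `spacing_range`, first site
#' 200 bp into the contig), per-site occurrence counts, per-fragment lengths,
#' and fragment sequences base-by-base from the composition model in the
#' dyad frame. The same seed reproduces the output exactly.
#'
#' @param spec A [population_spec()].
#' @return List with `fragments` (data.frame), `dyad_table`, `contig_length`
#'   and `truth` (all planted parameters plus the per-site table).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_positions
  spacing <- sample(spec$spacing_range[1]:spec$spacing_range[2], n,
                    replace = TRUE)
  dyads <- 200L + cumsum(spacing)
  occ <- sample_occurrences(spec$occurrence_law, n)
  contig_length <- max(dyads) + 200L
  lens <- as.integer(names(spec$length_distribution))
  frag_dyad <- rep(dyads, occ)
  frag_len <- lens[sample.int(length(lens), length(frag_dyad), replace = TRUE,
                              prob = spec$length_distribution)]
  start <- frag_dyad - (frag_len - 1L) %/% 2L
  seqs <- character(length(frag_dyad))
  for (L in unique(frag_len)) {
    idx <- which(frag_len == L)
    prob <- build_probability_matrix(spec$composition, L)
    seqs[idx] <- sample_sequences(prob, length(idx))
  }
  fragments <- data.frame(
    contig = spec$contig, start = start, end = start + frag_len,
    strand = "+", sequence = seqs, length = frag_len,
    stringsAsFactors = FALSE
  )
  list(
    fragments = fragments,
    dyad_table = dyad_table(dyads, occ, spec$contig),
    contig_length = contig_length,
    truth = list(spec = spec, sites = data.frame(dyad = dyads,
                                                 occurrence = occ))
  )
}

#' Specification of inter-population dyad shifts
#'
#' Fractions of dyad sites left unmoved, shifted by a whole number of
#' helical turns (10n bp, rotational setting preserved) or by 10n + 5 bp
#' (rotational setting inverted), as observed between wild-type and
#' histone-N-tailless nucleosome populations.
#'
#' @param unmoved_fraction,inphase_fraction,counterphase_fraction
#'   Non-negative fractions summing to 1.
#' @param inphase_n,counterphase_n Integer vectors the turn number n is
#'   drawn from uniformly (shift = 10n and 10n + 5 respectively).
#' @param seed Optional integer seed.
#' @return A `shift_spec`.
#' @export
shift_spec <- function(unmoved_fraction = 0, inphase_fraction = 1,
                       counterphase_fraction = 0,
                       inphase_n = 1:3, counterphase_n = 1:2, seed = NULL) {
  fr <- c(unmoved_fraction, inphase_fraction, counterphase_fraction)
  stopifnot(all(fr >= 0), abs(sum(fr) - 1) < 1e-9)
  structure(
    list(unmoved_fraction = unmoved_fraction,
         inphase_fraction = inphase_fraction,
         counterphase_fraction = counterphase_fraction,
         inphase_n = as.integer(inphase_n),
         counterphase_n = as.integer(counterphase_n), seed = seed),
    class = "shift_spec"
  )
}

#' Derive a shifted population from a base population
#'
#' Each dyad site of the base population is independently left unmoved,
#' shifted by 10n bp, or shifted by 10n + 5 bp (random sign) according to
#' the shift spec; fragment sequences are resampled in the new dyad frame
#' under the base composition or an override (e.g. a bump-removed or
#' phase-flipped model for a tailless population). Occurrence counts and the
#' length distribution are inherited from the base spec.
#'
#' @param base Output of [sample_population()].
#' @param shifts A [shift_spec()].
#' @param composition_override Optional [composition_model()] replacing the
#'   base composition for the new population.
#' @return Same shape as [sample_population()]; `truth$shifts` records the
#'   per-site category and signed shift.
#' @export
make_shifted_population <- function(base, shifts,
                                    composition_override = NULL) {
  stopifnot(inherits(shifts, "shift_spec"))
  if (!is.null(shifts$seed)) set.seed(shifts$seed)
  spec <- base$truth$spec
  sites <- base$truth$sites
  n <- nrow(sites)
  cat3 <- sample(c("unmoved", "inphase", "counterphase"), n, replace = TRUE,
                 prob = c(shifts$unmoved_fraction, shifts$inphase_fraction,
                          shifts$counterphase_fraction))
  mag <- integer(n)
  mag[cat3 == "inphase"] <-
    10L * sample(shifts$inphase_n, sum(cat3 == "inphase"), replace = TRUE)
  mag[cat3 == "counterphase"] <-
    10L * sample(shifts$counterphase_n, sum(cat3 == "counterphase"),
                 replace = TRUE) + 5L
  sgn <- sample(c(-1L, 1L), n, replace = TRUE)
  shift <- mag * sgn
  new_dyads <- sites$dyad + shift
  # re-draw the sign for sites pushed too close to a contig edge
  redraw <- which(new_dyads < 100L | new_dyads > base$contig_length - 100L)
  if (length(redraw)) {
    message(length(redraw), " shifted site(s) re-drawn at the contig edge")
    shift[redraw] <- -shift[redraw]
    new_dyads <- sites$dyad + shift
  }
  comp <- if (is.null(composition_override)) spec$composition
          else composition_override
  occ <- sites$occurrence
  lens <- as.integer(names(spec$length_distribution))
  frag_dyad <- rep(new_dyads, occ)
  frag_len <- lens[sample.int(length(lens), length(frag_dyad), replace = TRUE,
                              prob = spec$length_distribution)]
  start <- frag_dyad - (frag_len - 1L) %/% 2L
  seqs <- character(length(frag_dyad))
  for (L in unique(frag_len)) {
    idx <- which(frag_len == L)
    prob <- build_probability_matrix(comp, L)
    seqs[idx] <- sample_sequences(prob, length(idx))
  }
  fragments <- data.frame(
    contig = spec$contig, start = start, end = start + frag_len,
    strand = "+", sequence = seqs, length = frag_len,
    stringsAsFactors = FALSE
  )
  list(
    fragments = fragments,
    dyad_table = dyad_table(new_dyads, occ, spec$contig),
    contig_length = base$contig_length,
    truth = list(spec = spec, composition = comp,
                 sites = data.frame(dyad = new_dyads, occurrence = occ),
                 shifts = data.frame(base_dyad = sites$dyad,
                                     category = cat3, shift = shift))
  )
}

#' Write a synthetic population to disk
#'
#' Emits fragment sequences as FASTA, fragment intervals as BED6, the dyad
#' table as TSV and the truth record as JSON.
#'
#' @param population Output of [sample_population()] /
#'   [make_shifted_population()].
#' @param prefix Output path prefix (directory must exist).
#' @return Named vector of the written paths, invisibly.
#' @export
write_population <- function(population, prefix) {
  fr <- population$fragments
  fa <- paste0(prefix, ".fa")
  ss <- Biostrings::DNAStringSet(fr$sequence)
  names(ss) <- sprintf("frag%06d %s:%d-%d", seq_len(nrow(fr)),
                       fr$contig, fr$start, fr$end)
  Biostrings::writeXStringSet(ss, fa)
  bed <- paste0(prefix, ".bed")
  utils::write.table(
    data.frame(fr$contig, fr$start, fr$end,
               sprintf("frag%06d", seq_len(nrow(fr))), 0L, fr$strand),
    bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  dt <- paste0(prefix, "_dyads.tsv")
  write_dyad_table(population$dyad_table, dt)
  truth <- paste0(prefix, "_truth.json")
  jsonlite::write_json(truth_to_list(population$truth), truth,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(fasta = fa, bed = bed, dyads = dt, truth = truth))
}

truth_to_list <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), truth_to_list))
  x
}
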