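# Dyad-aligned positional frequency profiles.
#
# Internal frame: dyad-relative positions -73..+73 (147 mononucleotide
# columns; dinucleotide starts -73..+72, 146 columns). User-facing reports
# are 1-based nucleosomal positions 1..147 with the dyad at 74.

NUC_SPAN <- 147L
DYAD_1BASED <- 74L

WW_SET <- c("AA", "AT", "TA", "TT")
SS_SET <- c("GG", "GC", "CG", "CC")

# n x 147 integer matrix of base codes (A=1, C=2, G=3, T=4) in the
# dyad-aligned frame; NA where a fragment does not cover the position or
# carries a non-ACGT base there.
frag_code_matrix <- function(fragments) {
  n <- nrow(fragments)
  if (n == 0L) stop("no fragments")
  mat <- matrix(NA_integer_, n, NUC_SPAN)
  lens <- nchar(fragments$sequence)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    dy <- (L - 1L) %/% 2L              # 0-based dyad index within fragment
    for (j in seq_len(NUC_SPAN)) {
      k <- j - DYAD_1BASED + dy + 1L   # 1-based index within sequence
      if (k >= 1L && k <= L) {
        mat[idx, j] <- match(substr(fragments$sequence[idx], k, k),
                             c("A", "C", "G", "T"))
      }
    }
  }
  mat
}

new_positional_profile <- function(motif, kind, counts, coverage,
                                   smoothed = FALSE, symmetrized = FALSE) {
  values <- ifelse(coverage > 0, counts / coverage, NA_real_)
  m <- length(values)
  rel <- seq_len(m) - DYAD_1BASED
  structure(
    list(motif = motif, kind = kind, rel_pos = rel,
         values = values, counts = counts, coverage = coverage,
         smoothed = smoothed, symmetrized = symmetrized),
    class = "positional_profile"
  )
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf(
    "positional_profile: motif %s (%snucleotide), %d positions%s%s\n",
    x$motif, if (x$kind == "mono") "mono" else "di", length(x$values),
    if (x$smoothed) ", smoothed" else "",
    if (x$symmetrized) ", symmetrized" else ""))
  cat(sprintf("  mean frequency %.4f over %d covered positions\n",
              mean(x$values, na.rm = TRUE), sum(x$coverage > 0)))
  invisible(x)
}

#' Mononucleotide positional frequency profile
#'
#' Frequency of a base set at each dyad-relative position -73..+73 across a
#' fragment population. Each fragment is aligned at its dyad; positions not
#' covered by a (short) fragment, or covered by an N, do not enter the
#' denominator at that position.
#'
#' @param fragments Fragment data.frame (typically length-filtered to a
#'   146--149 bp band).
#' @param base_set Subset of `c("A","C","G","T")`, e.g. `c("A","T")` for W.
#' @param motif Label stored on the profile; defaults to the concatenated
#'   base set (`"W"` for A+T, `"S"` for G+C).
#' @return A `positional_profile` with `values`, `counts`, `coverage`.
#' @export
mono_profile <- function(fragments, base_set, motif = NULL) {
  base_set <- unique(toupper(base_set))
  stopifnot(all(base_set %in% c("A", "C", "G", "T")))
  if (nrow(fragments) == 0L) stop("no fragments")
  mat <- frag_code_matrix(fragments)
  mono_profile_from_codes(mat, base_set, motif)
}

mono_profile_from_codes <- function(mat, base_set, motif = NULL) {
  codes <- match(base_set, c("A", "C", "G", "T"))
  hit <- matrix(mat %in% codes, nrow(mat))
  counts <- colSums(hit)
  coverage <- colSums(!is.na(mat))
  if (is.null(motif)) {
    motif <- switch(paste(sort(base_set), collapse = ""),
                    AT = "W", CG = "S", paste(sort(base_set), collapse = ""))
  }
  new_positional_profile(motif, "mono", counts, coverage)
}

#' Dinucleotide positional frequency profile
#'
#' Frequency of a dinucleotide set at each dyad-relative start position
#' -73..+72; the dimer at position i spans bases (i, i+1). Dimers containing
#' N (or falling off a fragment end) are excluded from numerator and
#' denominator.
#'
#' @param fragments Fragment data.frame.
#' @param dimer_set Character vector of 2-mers, e.g. [ww_set()] or [ss_set()].
#' @param motif Label; defaults to `"WW"`/`"SS"` when recognised.
#' @return A `positional_profile` of kind `"di"` (146 positions).
#' @export
di_profile <- function(fragments, dimer_set, motif = NULL) {
  dimer_set <- unique(toupper(dimer_set))
  if (length(dimer_set) == 0L) stop("empty dimer_set")
  stopifnot(all(nchar(dimer_set) == 2L))
  if (nrow(fragments) == 0L) stop("no fragments")
  mat <- frag_code_matrix(fragments)
  di_profile_from_codes(mat, dimer_set, motif)
}

di_profile_from_codes <- function(mat, dimer_set, motif = NULL) {
  bases <- c("A", "C", "G", "T")
  dcodes <- (match(substr(dimer_set, 1, 1), bases) - 1L) * 4L +
    match(substr(dimer_set, 2, 2), bases)
  if (anyNA(dcodes)) stop("dimer_set contains non-ACGT letters")
  m <- ncol(mat) - 1L
  counts <- integer(m)
  coverage <- integer(m)
  for (j in seq_len(m)) {
    d <- (mat[, j] - 1L) * 4L + mat[, j + 1L]
    counts[j] <- sum(d %in% dcodes)
    coverage[j] <- sum(!is.na(d))
  }
  if (is.null(motif)) {
    key <- paste(sort(dimer_set), collapse = ",")
    motif <- if (key == paste(sort(WW_SET), collapse = ",")) "WW"
    else if (key == paste(sort(SS_SET), collapse = ",")) "SS"
    else key
  }
  new_positional_profile(motif, "di", counts, coverage)
}

#' Canonical dinucleotide sets
#'
#' `ww_set()` returns the W|W dimers (AA, AT, TA, TT), `ss_set()` the S|S
#' dimers (GG, GC, CG, CC). Both sets are closed under reverse complement.
#' @return Character vector of 2-mers.
#' @export
ww_set <- function() WW_SET

#' @rdname ww_set
#' @export
ss_set <- function() SS_SET

#' Three-bp running average
#'
#' Replaces each value by the mean over positions \{i-1, i, i+1\} restricted
#' to in-range positions with coverage > 0; the window shrinks at the edges
#' rather than dropping edge positions.
#'
#' @param profile A `positional_profile`, not yet smoothed.
#' @return The smoothed profile (`smoothed = TRUE`); counts and coverage are
#'   carried unchanged.
#' @export
smooth3 <- function(profile) {
  stopifnot(inherits(profile, "positional_profile"))
  if (profile$smoothed) stop("profile already smoothed")
  v <- profile$values
  m <- length(v)
  ok <- profile$coverage > 0 & !is.na(v)
  sm <- vapply(seq_len(m), function(i) {
    w <- (i - 1L):(i + 1L)
    w <- w[w >= 1L & w <= m]
    w <- w[ok[w]]
    if (!length(w)) NA_real_ else mean(v[w])
  }, 0)
  out <- profile
  out$values <- sm
  out$smoothed <- TRUE
  out
}

#' Symmetrize a profile with respect to the dyad
#'
#' Reflection-averages a profile through the dyad. For complement-closed
#' motif sets (W, S, WW, SS) the profile is averaged with its own mirror
#' (mononucleotide mirror(i) = -i; dinucleotide-start mirror(i) = -i-1, which
#' in both cases is a simple reversal of the value vector). For
#' strand-specific motifs the complementary profile over the same fragment
#' set can be supplied: the A profile is then averaged with the mirrored T
#' profile (and vice versa), preserving A-vs-T strand asymmetry.
#'
#' @param profile A `positional_profile` spanning the full dyad frame.
#' @param complement_aware If TRUE, average against `complement_profile`'s
#'   mirror instead of the profile's own mirror.
#' @param complement_profile Profile of the complementary motif (required
#'   when `complement_aware = TRUE`).
#' @return The symmetrized profile (`symmetrized = TRUE`).
#' @export
symmetrize <- function(profile, complement_aware = FALSE,
                       complement_profile = NULL) {
  stopifnot(inherits(profile, "positional_profile"))
  if (complement_aware) {
    if (is.null(complement_profile)) {
      stop("complement_aware = TRUE requires complement_profile")
    }
    stopifnot(length(complement_profile$values) == length(profile$values))
    other <- complement_profile
  } else {
    other <- profile
  }
  out <- profile
  out$values <- (profile$values + rev(other$values)) / 2
  out$counts <- (profile$counts + rev(other$counts)) / 2
  out$coverage <- (profile$coverage + rev(other$coverage)) / 2
  out$symmetrized <- TRUE
  out
}

#' Superhelix location (SHL) coordinates
#'
#' `shl_of()` converts a dyad-relative position in bp to SHL units (helical
#' turns from the dyad); `position_of()` is the inverse, rounding to the
#' nearest bp. Minor-groove bending sites sit at half-integer SHLs,
#' major-groove sites at integer SHLs.
#'
#' @param position Dyad-relative position(s), bp.
#' @param shl SHL value(s), helical turns.
#' @param period Helical period, bp per turn (default 10.4).
#' @return Numeric SHL, or integer dyad-relative position.
#' @export
shl_of <- function(position, period = 10.4) position / period

#' @rdname shl_of
#' @export
position_of <- function(shl, period = 10.4) {
  x <- shl * period
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# 1-based nucleosomal position <-> dyad-relative position
pos1_of_rel <- function(rel) rel + DYAD_1BASED
rel_of_pos1 <- function(pos1) pos1 - DYAD_1BASED

#' Detect off-peak enrichments P1 / P2
#'
#' Searches a smoothed, dyad-symmetrized W or WW profile for the two
#' non-canonical enrichments described for nucleosomal DNA: P1 near SHL
#' +/-4 and P2 near SHL +/-1 (both major-groove sites, i.e. canonical W
#' minima). Within a window of +/-3 bp around the nominal site the highest
#' strict interior local maximum is reported; its amplitude is measured
#' above the straight line joining the profile values at the two adjacent
#' integer-SHL sites (the flanking canonical minima). No interior local
#' maximum, or amplitude <= 0, means the off-peak is absent.
#'
#' @param profile Smoothed, symmetrized `positional_profile` (W or WW).
#' @param period Helical period, bp (default 10.4).
#' @param asymmetry Optional A-minus-T vector (see [strand_asymmetry()]) to
#'   report alongside each peak.
#' @return data.frame with rows P1, P2 and columns `peak`, `position`
#'   (1-based), `rel_pos`, `shl`, `amplitude`, `present`, `a_minus_t`.
#' @export
detect_off_peaks <- function(profile, period = 10.4, asymmetry = NULL) {
  stopifnot(inherits(profile, "positional_profile"))
  if (!profile$smoothed || !profile$symmetrized) {
    stop("off-peak detection expects a smoothed, symmetrized profile")
  }
  v <- profile$values
  one <- function(name, shl_center) {
    ctr <- position_of(shl_center, period)
    anchors <- position_of(c(shl_center - 1, shl_center + 1), period)
    idx <- function(rel) rel + DYAD_1BASED   # works for mono; di offset < 1bp
    win <- (ctr - 3L):(ctr + 3L)
    wi <- idx(win)
    wi <- wi[wi >= 2L & wi <= length(v) - 1L]
    loc <- wi[!is.na(v[wi]) & v[wi] > v[wi - 1L] & v[wi] > v[wi + 1L]]
    ai <- idx(anchors)
    base_at <- function(i) {
      stats::approx(ai, v[ai], xout = i)$y
    }
    if (length(loc) == 0L) {
      peak_i <- idx(ctr)
      amp <- 0
    } else {
      peak_i <- loc[which.max(v[loc])]
      amp <- v[peak_i] - base_at(peak_i)
    }
    rel <- peak_i - DYAD_1BASED
    data.frame(
      peak = name, position = peak_i, rel_pos = rel,
      shl = shl_of(rel, period), amplitude = amp, present = amp > 0,
      a_minus_t = if (is.null(asymmetry)) NA_real_ else asymmetry[peak_i],
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(one("P1", 4), one("P2", 1))
  rownames(out) <- out$peak
  out
}

#' A-minus-T strand asymmetry
#'
#' Element-wise difference between an A profile and a T profile over the same
#' fragment set, in the stored (reference-forward) strand convention. Both
#' profiles must be in the same state: either unsymmetrized or
#' complement-aware symmetrized (plain reflection averaging would erase the
#' asymmetry).
#'
#' @param profile_a,profile_t `positional_profile`s for A and T.
#' @return Numeric vector of A-minus-T per position, with the positions of
#'   the largest values in attribute `"maxima"` (1-based).
#' @export
strand_asymmetry <- function(profile_a, profile_t) {
  if (length(profile_a$values) != length(profile_t$values)) {
    stop("profiles have different lengths")
  }
  if (xor(profile_a$symmetrized, profile_t$symmetrized) ||
      xor(profile_a$smoothed, profile_t$smoothed)) {
    stop("profiles are in different processing states")
  }
  d <- profile_a$values - profile_t$values
  ord <- order(d, decreasing = TRUE)
  attr(d, "maxima") <- utils::head(ord[!is.na(d[ord])], 5L)
  d
}

#' Write a profile as TSV
#'
#' Columns: 1-based position, dyad-relative position, SHL, frequency, counts,
#' coverage, smoothed and symmetrized flags.
#'
#' @param profile A `positional_profile`.
#' @param path Output path.
#' @param period Helical period for the SHL column.
#' @export
write_profile <- function(profile, path, period = 10.4) {
  df <- data.frame(
    position = pos1_of_rel(profile$rel_pos),
    rel_pos = profile$rel_pos,
    shl = round(shl_of(profile$rel_pos, period), 4),
    frequency = profile$values,
    counts = profile$counts,
    coverage = profile$coverage,
    smoothed = profile$smoothed,
    symmetrized = profile$symmetrized
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
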