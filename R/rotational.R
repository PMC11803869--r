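# Rotational-setting classification: canonical WW/SS versus anti-WW/SS.

#' Canonical WW/SS phase template
#'
#' A cosine template over dinucleotide positions in the dyad frame, phased so
#' that its maxima sit at the minor-groove bending sites (half-integer SHLs,
#' where WW dimers are enriched in canonically set nucleosomes) and its
#' minima at the major-groove sites (integer SHLs, the SS-enriched sites).
#' The template is evaluated at dimer centres (start + 0.5 bp), which makes
#' it exactly symmetric under dyad reflection and hence phase scores exactly
#' invariant under reverse complement.
#'
#' @param period Helical period, bp per turn (default 10.4).
#' @param max_shl Support half-width in SHL units (default 6.5).
#' @return A `phase_template`: list with `rel_start` (dinucleotide start
#'   positions, dyad-relative), `values`, `period`, `max_shl`.
#' @export
phase_template <- function(period = 10.4, max_shl = 6.5) {
  rel <- (-(NUC_SPAN %/% 2)):(NUC_SPAN %/% 2 - 1L)   # dimer starts -73..72
  ctr <- rel + 0.5
  keep <- abs(ctr) <= max_shl * period
  structure(
    list(rel_start = rel[keep],
         values = -cos(2 * pi * ctr[keep] / period),
         period = period, max_shl = max_shl),
    class = "phase_template"
  )
}

# n x 146 matrix of per-fragment dimer signals in the dyad frame:
# +1 for WW, -1 for SS, 0 otherwise, NA where the dimer is unavailable.
ww_ss_signal <- function(fragments) {
  mat <- frag_code_matrix(fragments)
  m <- ncol(mat) - 1L
  # base codes: A=1, C=2, G=3, T=4; W = {1,4}, S = {2,3}
  w <- mat == 1L | mat == 4L
  x <- matrix(NA_real_, nrow(mat), m)
  for (j in seq_len(m)) {
    ok <- !is.na(mat[, j]) & !is.na(mat[, j + 1L])
    both_w <- ok & w[, j] & w[, j + 1L]
    both_s <- ok & !w[, j] & !w[, j + 1L]
    x[ok, j] <- 0
    x[both_w, j] <- 1
    x[both_s, j] <- -1
  }
  x
}

#' Phase scores of fragments against the WW/SS template
#'
#' For each fragment, the Pearson correlation between its dimer signal
#' x(i) = \[dimer i in WW\] - \[dimer i in SS\] and the canonical template
#' over the template support, in the dyad-aligned frame. Scores near +1
#' indicate the canonical WW/SS rotational setting, near -1 the anti-WW/SS
#' (counter-phased) setting. N-containing or uncovered dimers are skipped;
#' fragments with zero signal variance get score 0 and label `"weak"`.
#'
#' @param fragments Fragment data.frame (lengths within the supported
#'   146--149 bp band).
#' @param template A [phase_template()].
#' @param threshold Labeling threshold: `canonical` if score > threshold,
#'   `anti` if score < -threshold, else `weak`.
#' @return data.frame with columns `score`, `label` and a `zero_variance`
#'   flag, one row per fragment.
#' @export
phase_score <- function(fragments, template = phase_template(),
                        threshold = 0.1) {
  stopifnot(inherits(template, "phase_template"))
  x <- ww_ss_signal(fragments)
  cols <- match(template$rel_start, (-(NUC_SPAN %/% 2)):(NUC_SPAN %/% 2 - 1L))
  x <- x[, cols, drop = FALSE]
  t0 <- template$values
  n <- nrow(x)
  score <- numeric(n)
  zerovar <- logical(n)
  full <- !apply(x, 1L, anyNA)
  if (any(full)) {
    xs <- x[full, , drop = FALSE]
    sx <- apply(xs, 1L, stats::sd)
    zv <- sx == 0
    sc <- rep(0, nrow(xs))
    if (any(!zv)) {
      sc[!zv] <- as.vector(stats::cor(t(xs[!zv, , drop = FALSE]), t0))
    }
    score[full] <- sc
    zerovar[full] <- zv
  }
  for (i in which(!full)) {
    ok <- !is.na(x[i, ])
    if (sum(ok) < 3L || stats::sd(x[i, ok]) == 0) {
      score[i] <- 0
      zerovar[i] <- TRUE
    } else {
      score[i] <- stats::cor(x[i, ok], t0[ok])
    }
  }
  label <- ifelse(zerovar, "weak",
                  ifelse(score > threshold, "canonical",
                         ifelse(score < -threshold, "anti", "weak")))
  data.frame(score = score, label = label, zero_variance = zerovar,
             stringsAsFactors = FALSE)
}

#' Classify a nucleosome population by rotational setting
#'
#' Scores every fragment with [phase_score()], reports the canonical / anti /
#' weak fractions (over all fragments and over confidently typed fragments),
#' and computes smoothed, symmetrized W(A+T) profiles for the canonical and
#' anti subsets. In mixed populations the two subset profiles are
#' counter-phased: extrema of one align with the opposite extrema of the
#' other.
#'
#' @param fragments Fragment data.frame.
#' @param template A [phase_template()].
#' @param threshold Labeling threshold (default 0.1).
#' @return List with `scores` (per-fragment data.frame), `fractions`,
#'   `fractions_confident` (canonical/anti over non-weak fragments),
#'   `n`, `profile_canonical`, `profile_anti` (NULL when a subset is empty),
#'   and `subset_correlation`: Pearson correlation of the two subset W
#'   profiles over |SHL| <= 5 (NA when either subset is empty).
#' @export
classify_population <- function(fragments, template = phase_template(),
                                threshold = 0.1) {
  if (nrow(fragments) < 1L) stop("no fragments")
  sc <- phase_score(fragments, template, threshold)
  frac <- c(canonical = mean(sc$label == "canonical"),
            anti = mean(sc$label == "anti"),
            weak = mean(sc$label == "weak"))
  conf <- sc$label != "weak"
  frac_conf <- if (any(conf)) {
    c(canonical = mean(sc$label[conf] == "canonical"),
      anti = mean(sc$label[conf] == "anti"))
  } else c(canonical = NA_real_, anti = NA_real_)
  subset_profile <- function(lbl) {
    idx <- which(sc$label == lbl)
    if (!length(idx)) return(NULL)
    symmetrize(smooth3(mono_profile(fragments[idx, , drop = FALSE],
                                    c("A", "T"))))
  }
  p_can <- subset_profile("canonical")
  p_anti <- subset_profile("anti")
  subcor <- NA_real_
  if (!is.null(p_can) && !is.null(p_anti)) {
    rng <- abs(shl_of(p_can$rel_pos, template$period)) <= 5
    ok <- rng & !is.na(p_can$values) & !is.na(p_anti$values)
    if (sum(ok) > 2 && stats::sd(p_can$values[ok]) > 0 &&
        stats::sd(p_anti$values[ok]) > 0) {
      subcor <- stats::cor(p_can$values[ok], p_anti$values[ok])
    }
  }
  list(scores = sc, fractions = frac, fractions_confident = frac_conf,
       n = nrow(sc), profile_canonical = p_can, profile_anti = p_anti,
       subset_correlation = subcor)
}
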