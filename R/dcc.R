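# Inter-population distance cross-correlation (DCC) of dyad maps.

#' Distance cross-correlation between two dyad tables
#'
#' For every cross-population pair of dyad positions (p, q) on a shared
#' contig with unsigned distance |p - q| <= `max_dist`, adds the product of
#' the two occurrence counts to dcc(|p - q|). Multiple occurrences are
#' counted multiply: two positions 20 bp apart occurring 5 and 10 times
#' contribute 5 x 10 = 50 to dcc(20). Positions with occurrence <=
#' `min_occurrence` are excluded from both tables before pairing (the
#' published convention for deep real data is a threshold of 5000; for
#' synthetic data use 0).
#'
#' @param table1,table2 `dyad_table`s (see [build_dyad_table()]).
#' @param max_dist Maximum unsigned distance, bp.
#' @param min_occurrence Strictly-greater-than occurrence threshold.
#' @param signed If TRUE, also return the signed distance spectrum
#'   (table2 position minus table1 position) over -max_dist..max_dist in
#'   element `dcc_signed`.
#' @return A `dcc_result`: list with `distances` (0..max_dist), `dcc`,
#'   `min_occurrence`, and optionally `dcc_signed`.
#' @export
compute_dcc <- function(table1, table2, max_dist = 100L,
                        min_occurrence = 0L, signed = FALSE) {
  stopifnot(max_dist >= 1)
  t1 <- table1[table1$occurrence > min_occurrence, , drop = FALSE]
  t2 <- table2[table2$occurrence > min_occurrence, , drop = FALSE]
  shared <- intersect(unique(table1$contig), unique(table2$contig))
  if (length(shared) == 0L) stop("dyad tables share no contig")
  dcc <- numeric(max_dist + 1L)
  dcc_s <- if (signed) numeric(2L * max_dist + 1L) else NULL
  if (nrow(t1) == 0L || nrow(t2) == 0L) {
    warning("all positions below the occurrence threshold; empty DCC")
  } else {
    for (ctg in shared) {
      p1 <- t1$pos[t1$contig == ctg]; o1 <- t1$occurrence[t1$contig == ctg]
      p2 <- t2$pos[t2$contig == ctg]; o2 <- t2$occurrence[t2$contig == ctg]
      if (!length(p1) || !length(p2)) next
      # block over table1 positions to bound the pair matrix size
      step <- max(1L, floor(4e6 / length(p2)))
      for (lo in seq(1L, length(p1), by = step)) {
        hi <- min(lo + step - 1L, length(p1))
        d <- outer(p2, p1[lo:hi], "-")
        w <- outer(o2, o1[lo:hi], "*")
        keep <- abs(d) <= max_dist
        if (!any(keep)) next
        du <- abs(d[keep]); wk <- w[keep]
        agg <- rowsum(wk, du)
        dcc[as.integer(rownames(agg)) + 1L] <-
          dcc[as.integer(rownames(agg)) + 1L] + agg[, 1L]
        if (signed) {
          aggs <- rowsum(wk, d[keep])
          dcc_s[as.integer(rownames(aggs)) + max_dist + 1L] <-
            dcc_s[as.integer(rownames(aggs)) + max_dist + 1L] + aggs[, 1L]
        }
      }
    }
  }
  out <- list(distances = 0:max_dist, dcc = dcc,
              min_occurrence = min_occurrence)
  if (signed) {
    out$signed_distances <- (-max_dist):max_dist
    out$dcc_signed <- dcc_s
  }
  structure(out, class = "dcc_result")
}

#' @export
print.dcc_result <- function(x, ...) {
  cat(sprintf("dcc_result: distances 0..%d, occurrence threshold > %d\n",
              max(x$distances), x$min_occurrence))
  top <- order(x$dcc, decreasing = TRUE)[1:3]
  cat("  largest values at distances",
      paste(x$distances[top], collapse = ", "), "\n")
  invisible(x)
}

#' Call peaks in a DCC spectrum
#'
#' Internal local maxima of the dcc vector: strictly greater than both
#' neighbouring distinct values, with plateaus reported at their leftmost
#' distance. Peak prominence is the height above the higher of the two
#' valley minima separating the peak from larger values (the full range for
#' the global maximum).
#'
#' @param result A `dcc_result`.
#' @param min_prominence Minimum prominence to report.
#' @return data.frame with columns `distance`, `height`, `prominence`,
#'   sorted by distance.
#' @export
find_dcc_peaks <- function(result, min_prominence = 0) {
  v <- result$dcc
  r <- rle(v)
  k <- length(r$values)
  starts <- cumsum(c(1L, r$lengths[-k]))
  peaks <- integer(0)
  if (k >= 3L) {
    for (j in 2:(k - 1L)) {
      if (r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]) {
        peaks <- c(peaks, starts[j])
      }
    }
  }
  if (!length(peaks)) {
    return(data.frame(distance = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(peaks, function(i) {
    h <- v[i]
    left <- v[seq_len(i - 1L)]
    right <- v[seq((i + 1L), length(v))]
    lmin <- if (any(left >= h)) min(left[seq(max(which(left >= h)),
                                             length(left))]) else min(left)
    rmin <- if (any(right >= h)) min(right[seq_len(min(which(right >= h)))])
            else min(right)
    h - max(lmin, rmin)
  }, 0)
  out <- data.frame(distance = result$distances[peaks],
                    height = v[peaks], prominence = prom)
  out <- out[out$prominence >= min_prominence, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$distance), , drop = FALSE]
}

#' Partition DCC mass into in-phase and counterphase components
#'
#' Shifts by whole helical turns (10n bp) preserve the rotational setting of
#' a nucleosome; shifts by 10n + 5 bp invert it. This partitions the DCC
#' mass into windows of +/-`half_window` bp around the in-phase centres
#' \{0, 10, 20, ...\} and the counterphase centres \{5, 15, 25, ...\};
#' distances are assigned to the nearest centre (with `half_window = 2`
#' every integer distance is assigned to exactly one class).
#'
#' @param result A `dcc_result`.
#' @param period Translational phase period, bp (default 10).
#' @param half_window Window half-width around each centre, bp.
#' @param min_dist Smallest distance included (default 0; distance 0..2
#'   counts as in-phase).
#' @return List with `inphase_mass`, `counterphase_mass`,
#'   `counterphase_fraction` = counter / (in + counter) (NA if both are 0).
#' @export
phase_partition <- function(result, period = 10, half_window = 2L,
                            min_dist = 0L) {
  d <- result$distances
  v <- result$dcc
  keep <- d >= min_dist
  d <- d[keep]; v <- v[keep]
  m <- d %% period
  d_in <- pmin(m, period - m)            # distance to nearest 10n
  d_ct <- abs(m - period / 2)            # distance to nearest 10n+5
  inph <- d_in <= half_window & d_in <= d_ct
  ctr <- d_ct <= half_window & d_ct < d_in
  inphase <- sum(v[inph])
  counter <- sum(v[ctr])
  list(
    inphase_mass = inphase,
    counterphase_mass = counter,
    counterphase_fraction =
      if (inphase + counter > 0) counter / (inphase + counter) else NA_real_
  )
}

#' Write a DCC spectrum as TSV
#'
#' @param result A `dcc_result`.
#' @param path Output path.
#' @export
write_dcc <- function(result, path) {
  utils::write.table(
    data.frame(distance = result$distances, dcc = result$dcc),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
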