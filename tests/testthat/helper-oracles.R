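# Independent brute-force oracles and fixture builders. These deliberately
# use the dumbest possible algorithm so they stay independent of the
# implementation they check.

# fragments data.frame from raw sequences placed on a contig
make_fragments <- function(seqs, starts = NULL, contig = "chrT",
                           strand = "+") {
  lens <- nchar(seqs)
  if (is.null(starts)) starts <- seq(0L, by = 500L, length.out = length(seqs))
  data.frame(contig = contig, start = as.integer(starts),
             end = as.integer(starts + lens), strand = strand,
             sequence = toupper(seqs), length = as.integer(lens),
             stringsAsFactors = FALSE)
}

random_fragments <- function(n, lengths = 147L, bases = c("A", "C", "G", "T"),
                             prob = NULL) {
  lens <- sample(rep(lengths, length.out = max(n, length(lengths))), n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(bases, L, replace = TRUE, prob = prob), collapse = "")
  }, "")
  make_fragments(seqs)
}

# per-position letter tally, one fragment at a time, character by character
oracle_mono_profile <- function(fragments, base_set) {
  counts <- integer(147)
  coverage <- integer(147)
  for (i in seq_len(nrow(fragments))) {
    s <- strsplit(fragments$sequence[i], "")[[1]]
    L <- length(s)
    dy <- (L - 1) %/% 2
    for (k in seq_len(L)) {
      rel <- (k - 1) - dy
      j <- rel + 74
      if (j >= 1 && j <= 147 && s[k] %in% c("A", "C", "G", "T")) {
        coverage[j] <- coverage[j] + 1L
        if (s[k] %in% base_set) counts[j] <- counts[j] + 1L
      }
    }
  }
  list(counts = counts, coverage = coverage,
       values = ifelse(coverage > 0, counts / coverage, NA))
}

oracle_di_profile <- function(fragments, dimer_set) {
  counts <- integer(146)
  coverage <- integer(146)
  for (i in seq_len(nrow(fragments))) {
    s <- strsplit(fragments$sequence[i], "")[[1]]
    L <- length(s)
    dy <- (L - 1) %/% 2
    for (k in seq_len(L - 1)) {
      rel <- (k - 1) - dy
      j <- rel + 74
      dimer <- paste0(s[k], s[k + 1])
      if (j >= 1 && j <= 146 &&
          all(c(s[k], s[k + 1]) %in% c("A", "C", "G", "T"))) {
        coverage[j] <- coverage[j] + 1L
        if (dimer %in% dimer_set) counts[j] <- counts[j] + 1L
      }
    }
  }
  list(counts = counts, coverage = coverage,
       values = ifelse(coverage > 0, counts / coverage, NA))
}

# double-loop pair enumeration
oracle_dcc <- function(table1, table2, max_dist, min_occurrence = 0) {
  t1 <- table1[table1$occurrence > min_occurrence, ]
  t2 <- table2[table2$occurrence > min_occurrence, ]
  dcc <- numeric(max_dist + 1)
  for (i in seq_len(nrow(t1))) {
    for (j in seq_len(nrow(t2))) {
      if (t1$contig[i] != t2$contig[j]) next
      d <- abs(t1$pos[i] - t2$pos[j])
      if (d <= max_dist) {
        dcc[d + 1] <- dcc[d + 1] + t1$occurrence[i] * t2$occurrence[j]
      }
    }
  }
  dcc
}

random_dyad_table <- function(n, span = 500L, max_occ = 20L,
                              contig = "chr") {
  pos <- sample.int(span, n)
  dyad_table(pos, sample.int(max_occ, n, replace = TRUE), contig)
}

reverse_complement <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# analytic positional_profile for detector tests
analytic_profile <- function(values, kind = "mono", smoothed = TRUE,
                             symmetrized = TRUE) {
  p <- nucpatterns:::new_positional_profile(
    "W", kind, counts = values * 1000, coverage = rep(1000, length(values)),
    smoothed = smoothed, symmetrized = symmetrized)
  p$values <- values
  p
}
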