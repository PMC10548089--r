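# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# A fixed 21-nt test miRNA with G/U bases outside the seed (so every
# planted-site class is constructible). Arbitrary sequence, no biological
# meaning.
test_mirna <- function() "UGAGGUAGUAGGUUGUAUAGU"

# Exhaustive-enumeration oracle for the overlap distribution: counts, via a
# lattice DP over the background items, how many n-subsets of a size-B
# background have exactly x elements among the first K. Pure counting; no
# hypergeometric formula involved. Returns the pmf over x = 0..n.
overlap_distribution_dp <- function(B, K, n) {
  if (n == 0) return(1)
  W <- matrix(0, n + 1, n + 1)  # rows: chosen 0..n, cols: overlap 0..n
  W[1, 1] <- 1
  for (b in seq_len(B)) {
    W2 <- W
    if (b <= K) {
      W2[2:(n + 1), 2:(n + 1)] <- W2[2:(n + 1), 2:(n + 1)] + W[1:n, 1:n]
    } else {
      W2[2:(n + 1), ] <- W2[2:(n + 1), ] + W[1:n, ]
    }
    W <- W2
  }
  W[n + 1, ] / choose(B, n)
}

# Literal subset enumeration (combn), for validating the DP oracle itself
# on tiny cases.
overlap_distribution_combn <- function(B, K, n) {
  subsets <- utils::combn(B, n)
  x <- colSums(subsets <= K)
  tabulate(x + 1L, nbins = n + 1L) / ncol(subsets)
}

# Brute-force duplex search over all ungapped and single-gap alignments of
# the miRNA against every window of a (short) transcript, scored through
# score_duplex. Mirrors the scanner's constraints: terminal columns paired,
# seed-mismatch cap, minimum paired span. Returns the minimal feasible
# expectation (Inf when no feasible alignment exists).
brute_force_min_expectation <- function(mirna, transcript,
                                        params = scan_params()) {
  m <- nchar(mirna)
  tx <- strsplit(chartr("T", "U", toupper(transcript)), "")[[1]]
  Lt <- length(tx)
  best <- Inf
  feasible <- function(mrow, trow) {
    sc <- score_duplex(mrow, trow, params)
    span <- sum(strsplit(mrow, "")[[1]] != "-" & strsplit(trow, "")[[1]] != "-")
    if (sc$seed_mismatches <= params$max_seed_mismatches &&
        span >= params$hsp_size) sc$expectation else Inf
  }
  site_rev <- function(s, L) {
    # target row, 3'->5', for the site occupying transcript [s, s+L-1]
    paste(rev(tx[s:(s + L - 1)]), collapse = "")
  }
  for (s in seq_len(Lt)) {
    # ungapped
    if (s + m - 1 <= Lt) {
      best <- min(best, feasible(mirna, site_rev(s, m)))
    }
    # one bulged target base: site length m+1, gap in the miRNA row at
    # aligned column j (terminal columns must pair)
    if (s + m <= Lt) {
      tr <- site_rev(s, m + 1)
      for (j in 2:m) {
        mrow <- paste0(substr(mirna, 1, j - 1), "-", substr(mirna, j, m))
        best <- min(best, feasible(mrow, tr))
      }
    }
    # one bulged miRNA base: site length m-1, gap in the target row at
    # aligned column j; miRNA positions 1 and m must pair
    if (s + m - 2 <= Lt) {
      tr0 <- site_rev(s, m - 1)
      for (j in 2:(m - 1)) {
        trow <- paste0(substr(tr0, 1, j - 1), "-", substr(tr0, j, m - 1))
        best <- min(best, feasible(mirna, trow))
      }
    }
  }
  best
}

# Closed-form two-sample Student t (textbook pooled-variance formula),
# independent of stats::t.test.
student_t_closed_form <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
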