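# Synthetic transcripts with planted miRNA target sites of known
# expectation score.

wobble_partner <- function(b) c(G = "U", U = "G")[b]

# Build one planted site as aligned duplex rows (miRNA 5'->3', target
# 3'->5') plus the site sequence in transcript orientation (5'->3') and
# its nominal expectation under `params`.
build_site <- function(mir_chars, class, params) {
  L <- length(mir_chars)
  seed_pos <- params$seed_start:params$seed_end
  nonseed <- setdiff(seq_len(L), seed_pos)
  mrow <- mir_chars
  trow <- strsplit(comp_rna(paste(mir_chars, collapse = "")), "")[[1]]
  nominal <- 0
  if (class == "perfect") {
    # nothing to do
  } else if (class == "gu_nonseed") {
    cand <- nonseed[mir_chars[nonseed] %in% c("G", "U")]
    # prefer an interior 3' position, away from the duplex ends
    cand <- cand[order(abs(cand - (params$seed_end + 3)))]
    if (length(cand) == 0L) {
      abort("miRNA has no G or U outside the seed; cannot plant a G:U site.")
    }
    p <- cand[1]
    trow[p] <- unname(wobble_partner(mir_chars[p]))
    nominal <- params$gu_penalty
  } else if (class == "seed_mismatch") {
    p <- floor((params$seed_start + params$seed_end) / 2)
    forbidden <- c(comp_rna(mir_chars[p]), wobble_partner(mir_chars[p]))
    bad <- setdiff(c("A", "C", "G", "U"), forbidden[!is.na(forbidden)])
    trow[p] <- bad[1]
    nominal <- params$mismatch_penalty * params$seed_weight
  } else if (class == "bulge") {
    # extra target base between miRNA positions p and p+1; the gap column
    # is weighted at position p+1, which must be outside the seed
    p <- params$seed_end + 1
    if (p + 1 > L - 1) abort("miRNA too short to place a non-seed bulge.")
    forbidden <- unique(c(comp_rna(mir_chars[p]), wobble_partner(mir_chars[p]),
                          comp_rna(mir_chars[p + 1]),
                          wobble_partner(mir_chars[p + 1])))
    bulged <- setdiff(c("A", "C", "G", "U"), forbidden[!is.na(forbidden)])
    if (length(bulged) == 0L) bulged <- "A"
    mrow <- append(mrow, "-", after = p)
    trow <- append(trow, bulged[1], after = p)
    nominal <- params$gap_open
  } else if (class == "decoy") {
    ps <- unique(c(params$seed_start + 1L,
                   floor((params$seed_start + params$seed_end) / 2),
                   params$seed_end - 1L))
    for (p in ps) {
      forbidden <- c(comp_rna(mir_chars[p]), wobble_partner(mir_chars[p]))
      bad <- setdiff(c("A", "C", "G", "U"), forbidden[!is.na(forbidden)])
      trow[p] <- bad[1]
    }
    nominal <- length(ps) * params$mismatch_penalty * params$seed_weight
  } else {
    abort(sprintf("Unknown site class '%s'.", class))
  }
  sc <- score_duplex(paste(mrow, collapse = ""), paste(trow, collapse = ""),
                     params)
  if (abs(sc$expectation - nominal) > 1e-9) {
    abort(sprintf("Internal error: %s site scored %.3f, expected %.3f.",
                  class, sc$expectation, nominal))
  }
  list(class = class,
       site = paste(rev(trow[trow != "-"]), collapse = ""),  # 5'->3'
       expectation = nominal,
       seed_mismatches = sc$seed_mismatches)
}

#' Simulate transcripts with planted miRNA target sites
#'
#' Generates random-sequence transcripts carrying non-overlapping planted
#' miRNA binding sites of known expectation score: `perfect` (score 0),
#' `gu_nonseed` (one non-seed G:U wobble, 0.5 under defaults),
#' `seed_mismatch` (one seed mismatch, 1.5), `bulge` (one bulged target
#' nucleotide outside the seed, exactly 2.0 -- on the acceptance boundary),
#' and `decoy` (three seed mismatches, 4.5 -- must never be reported).
#' Flanking sequence is rejection-sampled so the final transcript contains
#' no accidental site: generation fails after `max_attempts` resamplings
#' rather than returning an unverified transcript.
#'
#' @param mirna miRNA sequence, 19-24 nt (character scalar, named character,
#'   or single-row [read_fasta()] tibble).
#' @param site_classes Named integer vector: number of sites per class.
#'   Sites are distributed round-robin across transcripts.
#' @param n_transcripts Number of transcripts (default: one per site).
#' @param transcript_length Length of each transcript in nt.
#' @param params [scan_params()] the planted scores are defined against.
#' @param seed Optional integer seed.
#' @param max_attempts Flank resampling cap per transcript.
#' @return A list with `transcripts` (tibble: `name`, `seq`, `length`) and
#'   `truth` (tibble: `transcript`, `class`, `start`, `end`,
#'   `expectation`, `emitted` -- whether a scan at these parameters must
#'   report the site).
#' @examples
#' sim <- simulate_transcripts_with_sites("UGAGGUAGUAGGUUGUAUAGU",
#'   site_classes = c(perfect = 1, decoy = 1), transcript_length = 120,
#'   seed = 1)
#' sim$truth
#' @export
simulate_transcripts_with_sites <- function(mirna,
                                            site_classes = c(perfect = 1,
                                                             gu_nonseed = 1,
                                                             seed_mismatch = 1,
                                                             bulge = 1,
                                                             decoy = 1),
                                            n_transcripts = NULL,
                                            transcript_length = 300,
                                            params = scan_params(),
                                            seed = NULL,
                                            max_attempts = 1000) {
  mirna <- as_seq_vector(mirna, "mirna")[1]
  L <- nchar(mirna)
  if (L < 19 || L > 24) {
    abort(sprintf("miRNA must be 19-24 nt, got %d.", L))
  }
  if (is.null(names(site_classes)) || any(site_classes < 0)) {
    abort("`site_classes` must be a named vector of non-negative counts.")
  }
  classes <- rep(names(site_classes), times = site_classes)
  if (length(classes) == 0L) abort("No sites requested.")
  if (is.null(n_transcripts)) n_transcripts <- length(classes)
  mir_chars <- strsplit(mirna, "")[[1]]

  with_seed_opt(seed, {
    assignment <- split(classes,
                        rep_len(seq_len(n_transcripts), length(classes)))
    tx_names <- sprintf("tx_%03d", seq_len(n_transcripts))
    truth_rows <- list()
    seqs <- character(n_transcripts)

    for (ti in seq_len(n_transcripts)) {
      cls <- assignment[[as.character(ti)]] %||% character(0)
      sites <- lapply(cls, function(cl) build_site(mir_chars, cl, params))
      site_lens <- vapply(sites, function(s) nchar(s$site), integer(1))
      min_sep <- 8L  # keep planted duplexes from abutting
      need <- sum(site_lens) + (length(sites) + 1L) * min_sep
      if (transcript_length < need) {
        abort(sprintf(
          "Transcript length %d too short for %d site(s) (need >= %d).",
          transcript_length, length(sites), need))
      }
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        # random composition of the slack across the k+1 flank segments
        slack <- transcript_length - sum(site_lens) -
          (length(sites) + 1L) * min_sep
        seg <- min_sep + as.integer(stats::rmultinom(
          1, slack, rep(1, length(sites) + 1L)))
        pieces <- character(0)
        starts <- integer(length(sites))
        posn <- 0L
        for (k in seq_along(sites)) {
          flank <- paste(sample(c("A", "C", "G", "U"), seg[k], replace = TRUE),
                         collapse = "")
          pieces <- c(pieces, flank, sites[[k]]$site)
          posn <- posn + seg[k]
          starts[k] <- posn + 1L
          posn <- posn + site_lens[k]
        }
        tail_flank <- paste(sample(c("A", "C", "G", "U"),
                                   transcript_length - posn, replace = TRUE),
                            collapse = "")
        tx <- paste(c(pieces, tail_flank), collapse = "")

        expected <- tibble(
          transcript = tx_names[ti],
          class = vapply(sites, `[[`, character(1), "class"),
          start = starts,
          end = starts + site_lens - 1L,
          expectation = vapply(sites, `[[`, numeric(1), "expectation"),
          seed_mismatches = vapply(sites, `[[`, integer(1), "seed_mismatches")
        )
        expected$emitted <-
          expected$expectation <= params$max_expectation + 1e-9 &
          expected$seed_mismatches <= params$max_seed_mismatches
        hits <- scan_targets(setNames(mirna, "mir"), setNames(tx, tx_names[ti]),
                             params = params)
        want <- expected[expected$emitted,
                         c("start", "end", "expectation")]
        got <- hits[, c("start", "end", "expectation")]
        same <- nrow(want) == nrow(got) &&
          (nrow(want) == 0L ||
             isTRUE(all.equal(as.data.frame(want[order(want$start), ]),
                              as.data.frame(got[order(got$start), ]),
                              check.attributes = FALSE, tolerance = 1e-9)))
        if (same) {
          seqs[ti] <- tx
          truth_rows[[ti]] <- expected
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        abort(sprintf(
          "Could not build decoy-free flanks for transcript %d in %d attempts.",
          ti, max_attempts))
      }
    }
    list(
      transcripts = tibble(name = tx_names, seq = seqs,
                           length = nchar(seqs)),
      truth = dplyr::bind_rows(truth_rows)
    )
  })
}
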