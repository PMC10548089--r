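# Expectation-penalty scoring of miRNA-target duplexes and transcript
# scanning. The duplex convention throughout: the miRNA row is written
# 5'->3'; the target row is written 3'->5' so that column i pairs miRNA
# position i; gap characters '-' mark bulges (a gap in the target row is a
# bulged/unpaired miRNA base, a gap in the miRNA row is a bulged target
# base).

rna_codes <- c(A = 0L, C = 1L, G = 2L, U = 3L, N = 4L)

encode_rna <- function(seq, what = "sequence") {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  codes <- rna_codes[chars]
  if (anyNA(codes)) {
    abort(sprintf("Illegal character '%s' in %s (alphabet is ACGT/U/N).",
                  chars[which(is.na(codes))[1]], what))
  }
  unname(codes)
}

pair_kind <- function(m, t) {
  wc <- (m == "A" & t == "U") | (m == "C" & t == "G") |
        (m == "G" & t == "C") | (m == "U" & t == "A")
  gu <- (m == "G" & t == "U") | (m == "U" & t == "G")
  ifelse(wc, "wc", ifelse(gu, "gu", "mismatch"))
}

#' Score an aligned miRNA-target duplex
#'
#' Computes the expectation score of a given duplex alignment: per aligned
#' miRNA position, a Watson-Crick pair scores 0, a G:U wobble scores
#' `gu_penalty`, any other mismatch `mismatch_penalty`; a gap run scores
#' `gap_open` for its first column and `gap_extend` for each subsequent one;
#' every penalty falling at a seed position is multiplied by `seed_weight`.
#' A gap column in the miRNA row (bulged target base) is assigned the
#' position of the next miRNA base for seed weighting; a gap in the target
#' row carries the position of the bulged miRNA base itself. Seed
#' mismatches count every non-Watson-Crick column (mismatch, G:U or gap) at
#' a seed position.
#'
#' @param mirna miRNA alignment row, 5' to 3', possibly containing `-`.
#' @param site Target alignment row written 3' to 5' (in pairing register
#'   with `mirna`), possibly containing `-`.
#' @param params A [scan_params()] list.
#' @return A list with `expectation`, `seed_mismatches`, and `trace` (a
#'   tibble with one row per alignment column: `column`, `mirna_pos`,
#'   `mirna_char`, `target_char`, `kind`, `penalty`).
#' @examples
#' m <- "UGAGGUAGUAGGUUGUAUAGU"
#' score_duplex(m, comp <- chartr("ACGU", "UGCA", m))$expectation  # 0
#' @export
score_duplex <- function(mirna, site, params = scan_params()) {
  mc <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  tc <- strsplit(chartr("T", "U", toupper(site)), "")[[1]]
  if (length(mc) != length(tc)) {
    abort("Aligned rows must have equal length.")
  }
  ok <- c(names(rna_codes), "-")
  if (!all(mc %in% ok) || !all(tc %in% ok)) {
    abort("Illegal character in duplex rows (alphabet is ACGT/U/N plus '-').")
  }
  if (any(mc == "-" & tc == "-")) abort("A column cannot be gap in both rows.")
  if (all(mc == "-" | tc == "-")) abort("All-gap alignment.")

  n <- length(mc)
  pos <- integer(n)      # miRNA position assigned to each column
  kind <- character(n)
  pen <- numeric(n)
  p <- 0L
  prev_gap_row <- ""     # "" / "mirna" / "target": tracks gap runs
  in_seed <- function(q) q >= params$seed_start & q <= params$seed_end
  for (i in seq_len(n)) {
    if (mc[i] == "-") {              # bulged target base
      pos[i] <- p + 1L
      kind[i] <- "target_bulge"
      pen[i] <- if (prev_gap_row == "mirna") params$gap_extend else params$gap_open
      prev_gap_row <- "mirna"
    } else if (tc[i] == "-") {       # bulged miRNA base
      p <- p + 1L
      pos[i] <- p
      kind[i] <- "mirna_bulge"
      pen[i] <- if (prev_gap_row == "target") params$gap_extend else params$gap_open
      prev_gap_row <- "target"
    } else {
      p <- p + 1L
      pos[i] <- p
      kind[i] <- pair_kind(mc[i], tc[i])
      pen[i] <- switch(kind[i], wc = 0,
                       gu = params$gu_penalty,
                       mismatch = params$mismatch_penalty)
      prev_gap_row <- ""
    }
    if (in_seed(pos[i])) pen[i] <- pen[i] * params$seed_weight
  }
  seed_mm <- sum(in_seed(pos) & kind != "wc")
  list(
    expectation = sum(pen),
    seed_mismatches = as.integer(seed_mm),
    trace = tibble(column = seq_len(n), mirna_pos = pos,
                   mirna_char = mc, target_char = tc,
                   kind = kind, penalty = pen)
  )
}

# Coerce FASTA-ish input (read_fasta tibble, named character, or bare
# character) to a named character vector of normalized RNA sequences.
as_seq_vector <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (!all(c("name", "seq") %in% names(x))) {
      abort(sprintf("`%s` must have columns `name` and `seq`.", arg))
    }
    out <- setNames(x$seq, x$name)
  } else {
    out <- setNames(as.character(x), names(x))
  }
  if (length(out) == 0L) abort(sprintf("`%s` contains no sequences.", arg))
  if (is.null(names(out))) {
    names(out) <- paste0(arg, seq_along(out))
  }
  out <- chartr("T", "U", toupper(out))
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    abort(sprintf("Illegal character in %s '%s' (alphabet is ACGT/U/N).",
                  arg, names(out)[bad][1]))
  }
  out
}

pairing_row <- function(mrow, trow) {
  mc <- strsplit(mrow, "")[[1]]
  tc <- strsplit(trow, "")[[1]]
  out <- rep(" ", length(mc))
  base <- mc != "-" & tc != "-"
  k <- pair_kind(mc[base], tc[base])
  out[base] <- ifelse(k == "wc", "|", ifelse(k == "gu", "o", " "))
  paste(out, collapse = "")
}

#' Scan transcripts for high-complementarity miRNA target sites
#'
#' Slides each miRNA over each transcript, computing at every candidate
#' position the optimal gapped complementarity alignment of the whole miRNA
#' against the local window by dynamic programming under the
#' expectation-penalty scheme of [scan_params()] (at most `max_gaps` gap
#' columns; the first and last miRNA positions must be paired). A site is
#' emitted when its expectation is at most `max_expectation` (boundary
#' inclusive), it has at most `max_seed_mismatches` non-Watson-Crick seed
#' columns, and its paired span is at least `hsp_size`. Overlapping
#' candidate placements are resolved by keeping the locally
#' minimal-expectation placement (ties broken to the leftmost site).
#'
#' This is a precise re-specification of plant-style target scanning under
#' the published penalty table, not a claim of bit-compatibility with any
#' web service.
#'
#' @param mirnas miRNA sequences: a [read_fasta()] tibble, a named character
#'   vector, or a bare character vector. `T` and `U` are interchangeable.
#' @param transcripts Transcript sequences, same accepted forms.
#' @param params A [scan_params()] list.
#' @param best_per_transcript If `TRUE`, keep only the minimum-expectation
#'   hit per (miRNA, transcript) pair.
#' @return A tibble of hits: `mirna`, `transcript`, `start`, `end` (1-based
#'   inclusive transcript coordinates), `expectation`, `seed_mismatches`,
#'   `gaps`, `span`, and `alignment` (three newline-separated rows: miRNA
#'   3'->5', pairing row with `|` Watson-Crick and `o` G:U, target 5'->3').
#' @examples
#' mir <- c(mir = "UGAGGUAGUAGGUUGUAUAGU")
#' tx <- c(tx1 = paste0("AGCAG", revcomp_rna(mir[[1]]), "CCAUG"))
#' scan_targets(mir, tx)
#' @export
scan_targets <- function(mirnas, transcripts, params = scan_params(),
                         best_per_transcript = FALSE) {
  mirnas <- as_seq_vector(mirnas, "mirnas")
  transcripts <- as_seq_vector(transcripts, "transcripts")
  for (nm in names(mirnas)) {
    if (nchar(mirnas[[nm]]) < params$hsp_size) {
      abort(sprintf("miRNA '%s' (%d nt) is shorter than hsp_size (%d).",
                    nm, nchar(mirnas[[nm]]), params$hsp_size))
    }
  }

  hits <- purrr::map(names(mirnas), function(mn) {
    mir_codes <- encode_rna(mirnas[[mn]], paste0("miRNA '", mn, "'"))
    purrr::map(names(transcripts), function(tn) {
      tx <- transcripts[[tn]]
      Lt <- nchar(tx)
      rt_codes <- rev(encode_rna(tx, paste0("transcript '", tn, "'")))
      raw <- scan_transcript_cpp(
        mir_codes, rt_codes,
        params$gu_penalty, params$mismatch_penalty, params$seed_weight,
        params$gap_open, params$gap_extend,
        params$seed_start, params$seed_end,
        params$max_expectation, params$max_seed_mismatches,
        params$hsp_size, params$max_gaps)
      cand <- as_tibble(raw)
      if (nrow(cand) == 0L) return(NULL)
      cand <- cand |>
        dplyr::mutate(
          start = Lt - .data$start_rt - .data$site_length + 1L,
          end = Lt - .data$start_rt
        ) |>
        dplyr::arrange(.data$expectation, .data$start)
      # Greedy resolution: best expectation wins its neighbourhood.
      keep <- logical(nrow(cand))
      occ_start <- integer(0)
      occ_end <- integer(0)
      for (k in seq_len(nrow(cand))) {
        s <- cand$start[k]; e <- cand$end[k]
        if (!any(s <= occ_end & e >= occ_start)) {
          keep[k] <- TRUE
          occ_start <- c(occ_start, s)
          occ_end <- c(occ_end, e)
        }
      }
      cand <- cand[keep, , drop = FALSE]
      tibble(
        mirna = mn, transcript = tn,
        start = cand$start, end = cand$end,
        expectation = cand$expectation,
        seed_mismatches = as.integer(cand$seed_mismatches),
        gaps = as.integer(cand$gaps),
        span = as.integer(cand$span),
        alignment = vapply(seq_len(nrow(cand)), function(k) {
          mrow <- cand$mir_row[k]
          trow <- cand$target_row[k]
          paste(paste(rev(strsplit(mrow, "")[[1]]), collapse = ""),
                paste(rev(strsplit(pairing_row(mrow, trow), "")[[1]]), collapse = ""),
                paste(rev(strsplit(trow, "")[[1]]), collapse = ""),
                sep = "\n")
        }, character(1))
      )
    }) |> purrr::compact() |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  if (nrow(hits) == 0L) {
    hits <- tibble(mirna = character(), transcript = character(),
                   start = integer(), end = integer(),
                   expectation = numeric(), seed_mismatches = integer(),
                   gaps = integer(), span = integer(), alignment = character())
  }
  hits <- dplyr::arrange(hits, .data$mirna, .data$transcript, .data$start)
  if (best_per_transcript && nrow(hits) > 0L) {
    hits <- hits |>
      dplyr::group_by(.data$mirna, .data$transcript) |>
      dplyr::slice_min(.data$expectation, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  hits
}
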