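## Position weight matrix handling: JASPAR flat-file reading, consensus
## extraction and min-max relative-score scanning of both strands.

#' Read position weight matrices from a JASPAR-format flat file
#'
#' Parses the four-row `A [ ... ]` count blocks under each `>ID name`
#' header. Counts are returned as-is (scanning normalizes internally).
#'
#' @param path Path to the JASPAR flat file.
#' @return Named list of 4 x width numeric matrices with rownames
#'   A, C, G, T.
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) qtlmed_stop("no PWM headers found")
  out <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    name <- sub("^>\\s*", "", lines[i])
    name <- strsplit(name, "\\s+")[[1]]
    name <- name[length(name)]  # prefer the TF name over the matrix id
    block <- lines[(i + 1):(i + 4)]
    rows <- lapply(block, function(ln) {
      s <- sub("^\\s*[ACGTacgt]", "", ln)
      as.numeric(regmatches(s, gregexpr("[0-9.]+", s))[[1]])
    })
    pwm <- do.call(rbind, rows)
    rownames(pwm) <- toupper(substr(trimws(block), 1, 1))
    pwm <- pwm[c("A", "C", "G", "T"), , drop = FALSE]
    out[[name]] <- pwm
  }
  out
}

#' Consensus sequence of a PWM (per-position maximum-weight base)
#' @param pwm A 4 x width matrix with rownames A, C, G, T.
#' @return Consensus string.
#' @export
pwm_consensus <- function(pwm) {
  paste(rownames(pwm)[apply(pwm, 2, which.max)], collapse = "")
}

revcomp <- function(seq) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

## Score one sequence window against the PWM; ambiguous bases contribute the
## per-position minimum (most pessimistic) score.
pwm_window_scores <- function(seq_chars, pwm) {
  width <- ncol(pwm)
  L <- length(seq_chars)
  n_off <- L - width + 1L
  if (n_off < 1) return(numeric(0))
  idx <- match(seq_chars, rownames(pwm))
  col_min <- apply(pwm, 2, min)
  vapply(seq_len(n_off), function(o) {
    sum(vapply(seq_len(width), function(k) {
      i <- idx[o + k - 1L]
      if (is.na(i)) col_min[k] else pwm[i, k]
    }, numeric(1)))
  }, numeric(1))
}

#' Scan a sequence with a PWM at a minimum relative score
#'
#' The relative score of a window is
#' `(score - min possible) / (max possible - min possible)`, so the
#' consensus scores exactly 1. Both strands are scanned (the reverse strand
#' scores the reverse complement); offsets are 0-based on the forward
#' strand. Ambiguous bases contribute the position minimum and trigger a
#' message.
#'
#' @param sequence A character string over A/C/G/T.
#' @param pwm A 4 x width matrix with rownames A, C, G, T.
#' @param min_relative_score Threshold in `[0, 1]` (default 0.8, i.e. an 80%
#'   match).
#' @return data.frame with `offset`, `strand`, `relative_score` for every
#'   window at or above the threshold.
#' @export
scan_pwm <- function(sequence, pwm, min_relative_score = 0.8) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  if (any(!chars %in% c("A", "C", "G", "T"))) {
    message("scan_pwm: ambiguous bases scored at the position minimum")
  }
  smin <- sum(apply(pwm, 2, min))
  smax <- sum(apply(pwm, 2, max))
  denom <- smax - smin
  if (denom <= 0) qtlmed_stop("degenerate PWM (constant columns)")
  rel <- function(s) (s - smin) / denom
  width <- ncol(pwm)
  fwd <- rel(pwm_window_scores(chars, pwm))
  rev_chars <- strsplit(revcomp(sequence), "")[[1]]
  rev <- rel(pwm_window_scores(rev_chars, pwm))
  hits <- data.frame(offset = integer(0), strand = character(0),
                     relative_score = numeric(0), stringsAsFactors = FALSE)
  keep_f <- which(fwd >= min_relative_score)
  if (length(keep_f)) {
    hits <- rbind(hits, data.frame(offset = keep_f - 1L, strand = "+",
                                   relative_score = fwd[keep_f]))
  }
  keep_r <- which(rev >= min_relative_score)
  if (length(keep_r)) {
    ## report reverse-strand hits at their forward-strand offset
    L <- length(chars)
    hits <- rbind(hits, data.frame(offset = L - width + 1L - keep_r,
                                   strand = "-",
                                   relative_score = rev[keep_r]))
  }
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}
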