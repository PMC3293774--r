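#' Promoter annotation for divergently transcribed genes
#'
#' Holds a promoter-region sequence (top strand, 5' to 3') and the
#' transcription start sites of the genes it drives.  Promoter coordinates
#' follow the biology convention: the TSS is +1, upstream positions are
#' negative, and there is no position 0.
#'
#' @param seq top-strand sequence.
#' @param genes data frame with columns `gene`, `strand` (`+`/`-`), `tss`
#'   (absolute 1-based top-strand position of the +1 nucleotide) and
#'   optionally `m10_start`, `m10_end`, `m35_start`, `m35_end` box
#'   intervals (absolute coordinates).
#' @return An object of class `promoter_annotation`.
#' @export
promoter_annotation <- function(seq, genes) {
  s <- check_dna_seq(seq)
  g <- as_tibble(genes)
  stopifnot(all(c("gene", "strand", "tss") %in% names(g)))
  if (!all(g$strand %in% c("+", "-"))) {
    stop("promoter_annotation: strand must be '+' or '-'", call. = FALSE)
  }
  if (any(g$tss < 1 | g$tss > nchar(s))) {
    stop("promoter_annotation: TSS outside sequence", call. = FALSE)
  }
  structure(list(seq = s, genes = g), class = "promoter_annotation")
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat(sprintf("<promoter_annotation> %d bp, %d gene(s)\n", nchar(x$seq),
              nrow(x$genes)))
  print(x$genes)
  invisible(x)
}

# gene-frame sequence (the strand the gene is transcribed from, 5'->3')
gene_frame_seq <- function(ann, gene) {
  g <- ann$genes[ann$genes$gene == gene, ]
  if (!nrow(g)) stop("unknown gene: ", gene, call. = FALSE)
  if (g$strand == "+") ann$seq else revcomp(ann$seq)
}

# gene-frame index (1-based) of the TSS
gene_tss_index <- function(ann, gene) {
  g <- ann$genes[ann$genes$gene == gene, ]
  if (g$strand == "+") g$tss else nchar(ann$seq) - g$tss + 1
}

#' Promoter coordinate conversion
#'
#' Converts between promoter coordinates (+1 = TSS, negative upstream, no
#' zero) and 1-based indices in the gene-frame sequence.
#'
#' @param ann a [promoter_annotation()].
#' @param gene gene name.
#' @param pos promoter coordinate(s) (non-zero integers) or gene-frame
#'   indices.
#' @return Integer vector of the converted positions.
#' @export
promoter_to_index <- function(ann, gene, pos) {
  if (any(pos == 0)) stop("promoter coordinates have no position 0", call. = FALSE)
  it <- gene_tss_index(ann, gene)
  as.integer(ifelse(pos > 0, it + pos - 1, it + pos))
}

#' @rdname promoter_to_index
#' @param idx gene-frame indices.
#' @export
index_to_promoter <- function(ann, gene, idx) {
  it <- gene_tss_index(ann, gene)
  d <- idx - it
  as.integer(ifelse(d >= 0, d + 1, d))
}

#' Maximal A/T-only runs
#'
#' Finds maximal runs consisting solely of A and T nucleotides of at least
#' `min_len`, such as the long AT-only operator motifs bound by FUR-family
#' regulators.
#'
#' @param seq DNA sequence string.
#' @param min_len minimum run length (>= 1).
#' @return A tibble with `start` (1-based), `length` and `run` (the
#'   sequence of the run), in order of occurrence.
#' @examples
#' find_at_runs("GGATATATTTAAGG", min_len = 8)
#' @export
find_at_runs <- function(seq, min_len) {
  s <- check_dna_seq(seq)
  if (min_len < 1) stop("find_at_runs: min_len must be >= 1", call. = FALSE)
  ch <- strsplit(s, "")[[1]]
  r <- rle(ch %in% c("A", "T"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_len)
  if (!length(keep)) {
    return(tibble(start = integer(0), length = integer(0),
                  run = character(0)))
  }
  tibble(start = as.integer(starts[keep]),
         length = as.integer(r$lengths[keep]),
         run = substring(s, starts[keep], ends[keep]))
}

#' Central (dyad) symmetry score of a window
#'
#' Fraction of positions at which the window equals its own reverse
#' complement -- 1 for a perfect palindrome, the "ideal feature" for
#' binding a symmetric protein dimer.
#'
#' @param window DNA sequence string.
#' @return Fraction in \[0, 1\].  The score is invariant under reverse
#'   complementation of the window.
#' @examples
#' symmetry_score("AATT")  # 1
#' symmetry_score("AAAA")  # 0
#' @export
symmetry_score <- function(window) {
  s <- check_dna_seq(window)
  a <- strsplit(s, "")[[1]]
  b <- strsplit(revcomp(s), "")[[1]]
  mean(a == b)
}

mismatch_profile <- function(word, consensus) {
  a <- strsplit(word, "")[[1]]
  c <- strsplit(consensus, "")[[1]]
  cmp <- c != "N" & a != c
  list(n = sum(cmp), at = which(cmp))
}

#' Scan for a sigma-70 promoter box near a TSS
#'
#' Slides an IUPAC-with-`n` consensus (e.g. `TATAAT`, `TTGACA`,
#' `TGnTATAAT`) over a window of promoter coordinates on a gene's own
#' strand and reports occurrences within a mismatch budget.  `n` positions
#' are wildcards and never count as mismatches.
#'
#' @param ann a [promoter_annotation()].
#' @param gene gene name.
#' @param consensus consensus string over \{A,C,G,T,n\}.
#' @param position_window length-2 vector of promoter coordinates (e.g.
#'   `c(-40, -1)`): hits must start (5'-most base, gene frame) inside it.
#' @param max_mismatch maximum mismatches per hit.
#' @return A tibble of `motif_hit`s: `start`, `end` (promoter
#'   coordinates), `strand`, `match`, `consensus`, `mismatches`,
#'   `mismatch_positions` (list of 1-based positions within the motif).
#' @export
scan_box <- function(ann, gene, consensus, position_window = c(-40, -1),
                     max_mismatch = 0) {
  stopifnot(inherits(ann, "promoter_annotation"))
  cons <- toupper(consensus)
  if (grepl("[^ACGTN]", cons)) {
    stop("scan_box: consensus must be over {A,C,G,T,n}", call. = FALSE)
  }
  g <- ann$genes[ann$genes$gene == gene, ]
  if (!nrow(g)) stop("scan_box: unknown gene: ", gene, call. = FALSE)
  gseq <- gene_frame_seq(ann, gene)
  L <- nchar(gseq)
  k <- nchar(cons)
  idx_lo <- promoter_to_index(ann, gene, position_window[1])
  idx_hi <- promoter_to_index(ann, gene, position_window[2])
  if (idx_lo < 1 || idx_hi + k - 1 > L) {
    stop("scan_box: position window outside sequence", call. = FALSE)
  }
  rows <- list()
  for (i in idx_lo:idx_hi) {
    word <- substr(gseq, i, i + k - 1)
    mm <- mismatch_profile(word, cons)
    if (mm$n <= max_mismatch) {
      rows[[length(rows) + 1]] <- tibble(
        start = index_to_promoter(ann, gene, i),
        end = index_to_promoter(ann, gene, i + k - 1),
        strand = g$strand, match = word, consensus = consensus,
        mismatches = mm$n, mismatch_positions = list(mm$at))
    }
  }
  if (!length(rows)) {
    return(tibble(start = integer(0), end = integer(0),
                  strand = character(0), match = character(0),
                  consensus = character(0), mismatches = integer(0),
                  mismatch_positions = list()))
  }
  bind_rows(rows)
}

#' Tandem repeat arrays and 7-1-7 inverted repeats
#'
#' In `"tandem"` mode, finds maximal arrays of consecutive copies of
#' `unit` (default the invariant FUR-box hexamer `GATAAT`), allowing
#' `max_mismatch_per_unit` mismatches in each copy.  In
#' `"inverted-7-1-7"` mode, finds 15 bp windows whose last 7 bases are
#' the reverse complement of the first 7 (one-spacer inverted repeat, the
#' minimal FUR recognition motif), with the same per-unit mismatch budget.
#'
#' @param seq DNA sequence string.
#' @param unit repeat unit (tandem mode), length >= 2.
#' @param min_repeats minimum copies per array (>= 2).
#' @param max_mismatch_per_unit mismatch budget per unit copy.
#' @param mode `"tandem"` or `"inverted-7-1-7"`.
#' @return A tibble with `start` (1-based), `n_repeats`, `length`,
#'   `mismatches` and `array` (matched sequence).
#' @examples
#' find_repeat_array("GATAATGATAATGATAAT", min_repeats = 3)
#' @export
find_repeat_array <- function(seq, unit = "GATAAT", min_repeats = 2,
                              max_mismatch_per_unit = 0,
                              mode = c("tandem", "inverted-7-1-7")) {
  s <- check_dna_seq(seq)
  mode <- match.arg(mode)
  if (min_repeats < 2) {
    stop("find_repeat_array: min_repeats must be >= 2", call. = FALSE)
  }
  if (mode == "inverted-7-1-7") {
    rows <- list()
    if (nchar(s) >= 15) {
      for (i in 1:(nchar(s) - 14)) {
        left <- substr(s, i, i + 6)
        right <- substr(s, i + 8, i + 14)
        mm <- mismatch_profile(right, revcomp(left))
        if (mm$n <= max_mismatch_per_unit) {
          rows[[length(rows) + 1]] <- tibble(
            start = i, n_repeats = 2L, length = 15L, mismatches = mm$n,
            array = substr(s, i, i + 14))
        }
      }
    }
    return(if (length(rows)) bind_rows(rows) else
      tibble(start = integer(0), n_repeats = integer(0),
             length = integer(0), mismatches = integer(0),
             array = character(0)))
  }
  unit <- toupper(unit)
  if (nchar(unit) < 2) {
    stop("find_repeat_array: unit length must be >= 2", call. = FALSE)
  }
  k <- nchar(unit)
  n <- nchar(s)
  count_at <- function(i) {
    reps <- 0L
    mism <- 0L
    j <- i
    while (j + k - 1 <= n) {
      mm <- mismatch_profile(substr(s, j, j + k - 1), unit)
      if (mm$n > max_mismatch_per_unit) break
      reps <- reps + 1L
      mism <- mism + mm$n
      j <- j + k
    }
    list(reps = reps, mism = mism)
  }
  rows <- list()
  i <- 1L
  while (i + k - 1 <= n) {
    res <- count_at(i)
    if (res$reps >= min_repeats) {
      rows[[length(rows) + 1]] <- tibble(
        start = i, n_repeats = res$reps, length = res$reps * k,
        mismatches = res$mism, array = substr(s, i, i + res$reps * k - 1))
      i <- i + res$reps * k
    } else {
      i <- i + 1L
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(start = integer(0), n_repeats = integer(0), length = integer(0),
           mismatches = integer(0), array = character(0))
}
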