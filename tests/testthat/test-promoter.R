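# brute-force oracle for maximal AT-only runs
at_runs_brute <- function(seq, min_len) {
  ch <- strsplit(toupper(seq), "")[[1]]
  runs <- list()
  i <- 1
  while (i <= length(ch)) {
    if (ch[i] %in% c("A", "T")) {
      j <- i
      while (j < length(ch) && ch[j + 1] %in% c("A", "T")) j <- j + 1
      if (j - i + 1 >= min_len) runs[[length(runs) + 1]] <- c(i, j - i + 1)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

test_that("AT-only runs are maximal and match the brute-force oracle", {
  got <- find_at_runs("GGATATATTTAAGG", min_len = 8)
  expect_equal(nrow(got), 1)
  expect_equal(got$start, 3L)   # 1-based
  expect_equal(got$length, 10L)
  expect_equal(find_at_runs("GGGGG", 1)$start, integer(0))
  one <- find_at_runs("A", 1)
  expect_equal(one$length, 1L)
  expect_error(find_at_runs("ACGT", 0), "min_len")
  # randomised cases against the oracle
  withr::with_seed(11, {
    for (k in 1:20) {
      s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
      ml <- sample(1:6, 1)
      got <- find_at_runs(s, ml)
      want <- at_runs_brute(s, ml)
      expect_equal(nrow(got), length(want))
      if (length(want)) {
        expect_equal(got$start, vapply(want, `[`, numeric(1), 1))
        expect_equal(got$length, vapply(want, `[`, numeric(1), 2))
        expect_false(any(grepl("[GC]", got$run)))
      }
    }
  })
})

test_that("symmetry score measures dyad symmetry and is revcomp-invariant", {
  expect_equal(symmetry_score("AATT"), 1.0)
  expect_equal(symmetry_score("AAAA"), 0.0)
  # position-by-position: AATAT vs revcomp ATATT agrees at 2 of 5
  expect_equal(symmetry_score("AATAT"), 0.4)
  withr::with_seed(4, {
    for (k in 1:10) {
      w <- paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                 collapse = "")
      expect_equal(symmetry_score(w), symmetry_score(revcomp(w)))
    }
  })
})

test_that("box scanning reproduces the sigma-70 element comparisons", {
  genes <- data.frame(gene = c("fwd", "rev"), strand = c("+", "-"),
                      tss = c(151, 60))
  ann <- make_promoter_sequence(
    220, genes,
    plants = data.frame(gene = "fwd", motif = c("TAAGCT", "TGA"),
                        position = c(-12, -15)),
    seed = 5)
  # the planted hexamer against the canonical -10 consensus: 3 mismatches
  hits <- scan_box(ann, "fwd", "TATAAT", c(-20, -5), max_mismatch = 3)
  hit <- hits[hits$start == -12, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$match, "TAAGCT")
  expect_equal(hit$end, -7L)
  expect_equal(hit$mismatches, 3L)
  expect_equal(hit$mismatch_positions[[1]], c(3L, 4L, 5L))
  # extended -10 with a wildcard spacer: same 3 mismatches, none at 'n'
  ext <- scan_box(ann, "fwd", "TGnTATAAT", c(-16, -14), max_mismatch = 3)
  ehit <- ext[ext$start == -15, ]
  expect_equal(nrow(ehit), 1)
  expect_equal(ehit$match, "TGATAAGCT")
  expect_equal(ehit$mismatches, 3L)
  expect_false(3 %in% ehit$mismatch_positions[[1]])
})

test_that("-35 box with a single terminal deviation scores one mismatch", {
  genes <- data.frame(gene = "g", strand = "+", tss = 101)
  ann <- make_promoter_sequence(
    140, genes,
    plants = data.frame(gene = "g", motif = "TTGACT", position = -35),
    seed = 9)
  hits <- scan_box(ann, "g", "TTGACA", c(-40, -30), max_mismatch = 1)
  hit <- hits[hits$start == -35, ]
  expect_equal(hit$mismatches, 1L)
  expect_equal(hit$mismatch_positions[[1]], 6L)
})

test_that("minus-strand genes are scanned in their own promoter frame", {
  genes <- data.frame(gene = c("fwd", "rev"), strand = c("+", "-"),
                      tss = c(180, 41))
  ann <- make_promoter_sequence(
    220, genes,
    plants = data.frame(gene = "rev", motif = "TATTCT", position = -12),
    seed = 2)
  hits <- scan_box(ann, "rev", "TATAAT", c(-20, -5), max_mismatch = 2)
  hit <- hits[hits$start == -12, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$match, "TATTCT")
  expect_equal(hit$mismatches, 2L)
  expect_equal(hit$strand, "-")
  # the planted element sits on the bottom strand: the top strand carries
  # its reverse complement upstream of the absolute TSS position
  top <- substr(ann$seq, 41 + 7, 41 + 12)
  expect_equal(top, revcomp("TATTCT"))
})

test_that("scan_box with no mismatch budget equals naive exact search", {
  genes <- data.frame(gene = "g", strand = "+", tss = 61)
  ann <- make_promoter_sequence(120, genes, seed = 31)
  cons <- "TGCA"
  hits <- scan_box(ann, "g", cons, c(-60, 57), max_mismatch = 0)
  naive <- gregexpr(cons, ann$seq, fixed = TRUE)[[1]]
  naive <- naive[naive > 0]
  got_idx <- furdock::promoter_to_index(ann, "g", hits$start)
  expect_equal(sort(got_idx), sort(as.integer(naive)))
})

test_that("promoter coordinates skip zero in both directions", {
  genes <- data.frame(gene = c("f", "r"), strand = c("+", "-"),
                      tss = c(50, 20))
  ann <- promoter_annotation(strrep("ACGT", 25), genes)
  expect_equal(promoter_to_index(ann, "f", c(-2, -1, 1, 2)),
               c(48L, 49L, 50L, 51L))
  expect_equal(index_to_promoter(ann, "f", c(48, 49, 50, 51)),
               c(-2L, -1L, 1L, 2L))
  expect_error(promoter_to_index(ann, "f", 0), "no position 0")
  # round trip on the minus-strand gene
  idx <- promoter_to_index(ann, "r", c(-5, 3))
  expect_equal(index_to_promoter(ann, "r", idx), c(-5L, 3L))
})

test_that("GATAAT tandem arrays and 7-1-7 inverted repeats are detected", {
  arr <- find_repeat_array("GATAATGATAATGATAAT", min_repeats = 3)
  expect_equal(nrow(arr), 1)
  expect_equal(arr$start, 1L)
  expect_equal(arr$n_repeats, 3L)
  expect_equal(arr$mismatches, 0L)
  # embedded array, with one mismatch allowed per unit
  arr2 <- find_repeat_array("CCGATAATGATCATCC", min_repeats = 2,
                            max_mismatch_per_unit = 1)
  expect_equal(arr2$start, 3L)
  expect_equal(arr2$n_repeats, 2L)
  expect_equal(arr2$mismatches, 1L)
  # no array at zero tolerance
  none <- find_repeat_array("GATAATGATCAT", min_repeats = 2,
                            max_mismatch_per_unit = 0)
  expect_equal(nrow(none), 0)
  # 7-1-7: last seven bases reverse-complement the first seven
  left <- "GATAATG"
  pal <- paste0(left, "C", revcomp(left))
  inv <- find_repeat_array(paste0("GG", pal, "AA"), mode = "inverted-7-1-7")
  expect_true(3 %in% inv$start)
  expect_equal(inv$length[inv$start == 3], 15L)
  expect_error(find_repeat_array("ACGT", min_repeats = 1), "min_repeats")
  expect_error(find_repeat_array("ACGTACGT", unit = "A"), "unit length")
})
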