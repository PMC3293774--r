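#' Wrap an assembled protein-DNA structure as a dock model
#'
#' Builds the carrier object the multimer machinery works on from any
#' structure holding a placed protein (dimer) and a DNA duplex, fitting
#' the helix axis from the DNA unless helical parameters are supplied.
#'
#' @param structure a structure tibble.
#' @param dna_chains the two DNA chain ids, top strand first (default:
#'   detected).
#' @param protein_chains protein chain ids (default: detected).
#' @param params optional [helical_parameters()]; the axis is refitted to
#'   the DNA, rise/twist are kept.
#' @return A `dock_model`.
#' @export
as_dock_model <- function(structure, dna_chains = NULL,
                          protein_chains = NULL,
                          params = helical_parameters()) {
  s <- as_structure(structure)
  if (is.null(dna_chains)) dna_chains <- dna_chains(s)
  if (is.null(protein_chains)) {
    protein_chains <- setdiff(unique(s$chain), dna_chains)
  }
  if (length(dna_chains) != 2) {
    stop("as_dock_model: expected one DNA duplex (2 chains)", call. = FALSE)
  }
  helical <- fit_helix_axis(s, dna_chains, params)
  new_dock_model(s, dna_chains, protein_chains, helical)
}

# base-pair interval covered by the protein of a dock model, from the
# projection of its atoms onto the helix axis
dimer_bp_interval <- function(model) {
  s <- model$structure
  ctr <- bp_centroids(s, model$dna_chains)
  u <- model$helical$axis_dir
  p0 <- c(ctr$x[1], ctr$y[1], ctr$z[1])
  prot <- s[s$chain %in% model$protein_chains, ]
  tproj <- as.matrix(prot[, c("x", "y", "z")]) %*% u - sum(p0 * u)
  bp <- tproj / model$helical$rise + 1
  c(floor(min(bp)), ceiling(max(bp)))
}

n_bp_of <- function(model) nrow(bp_centroids(model$structure, model$dna_chains))

#' Place a dimer copy at a helical offset
#'
#' Applies the screw transform of `offset_bp` base pairs (rotation
#' `offset * twist` about the DNA axis plus translation `offset * rise`
#' along it) to a copy of the dimer, leaving the DNA and the original
#' dimer untouched: the geometry of "fixing the first dimer and moving the
#' second one along the DNA with a one base pair increment".
#'
#' @param model a `dock_model` with a dimer placed on DNA.
#' @param offset_bp non-negative integer offset in base pairs.
#' @param copy_chains chain ids for the copy (default: picked
#'   automatically).
#' @return A structure tibble containing DNA, the original dimer and the
#'   offset copy; the copy's chains are recorded in attribute
#'   `copy_chains`.
#' @export
place_dimer_at_offset <- function(model, offset_bp, copy_chains = NULL) {
  stopifnot(inherits(model, "dock_model"), offset_bp >= 0,
            offset_bp == round(offset_bp))
  iv <- dimer_bp_interval(model)
  if (iv[2] + offset_bp > n_bp_of(model)) {
    stop(sprintf(
      "place_dimer_at_offset: offset %d slides the copy past the DNA end (dimer spans bp %d-%d of %d)",
      offset_bp, iv[1], iv[2], n_bp_of(model)), call. = FALSE)
  }
  s <- model$structure
  prot <- s[s$chain %in% model$protein_chains, ]
  copy <- apply_transform(prot, helical_step(model$helical, offset_bp))
  used <- unique(s$chain)
  if (is.null(copy_chains)) {
    pool <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
    copy_chains <- pool[seq_along(unique(copy$chain))]
  }
  map <- stats::setNames(copy_chains, unique(copy$chain))
  copy$chain <- unname(map[copy$chain])
  out <- bind_rows(s, copy)
  attr(out, "copy_chains") <- unname(copy_chains)
  out
}

#' Scan inter-dimer spacings along the DNA
#'
#' For each offset `s = 1..max_offset` (base pairs), a copy of the
#' reference dimer is slid `s` helical steps along the DNA and the pair is
#' scored: steric clash count and worst van der Waals overlap, inter-dimer
#' contact surface CS_dd, and (optionally) the DNA overlapped surface (the
#' total DNA area buried by both protein copies).  Offsets are classified
#' `clash` (any clashing pair), else `contact` (CS_dd >= `cs_min`), else
#' `separated`.
#'
#' The isolated dimer's SASA is evaluated once and reused for every
#' offset (rigid copies have equal analytic SASA; the deterministic
#' lattice makes the reuse reproducible); the pair and complex SASAs are
#' recomputed per offset.
#'
#' @param model a `dock_model` with a dimer placed on DNA.
#' @param max_offset largest offset scanned, base pairs.
#' @param cs_min contact-surface threshold (Angstrom^2) separating
#'   `contact` from `separated`.
#' @param overlap_tol tolerated van der Waals overlap before a pair counts
#'   as clashing, Angstrom.
#' @param dna_overlap also compute the DNA overlapped surface (slower).
#' @inheritParams sasa
#' @return A tibble of class `spacing_scan`: `offset`, `n_clash`,
#'   `worst_overlap`, `cs_dd`, `dna_overlap`, `class`.
#' @export
scan_spacings <- function(model, max_offset, cs_min = 1.0, overlap_tol = 0.5,
                          dna_overlap = TRUE, probe = 1.4, n_points = 960,
                          radii = NULL) {
  stopifnot(inherits(model, "dock_model"), max_offset >= 1)
  radii <- radii %||% model$radii %||% default_vdw_radii()
  iv <- dimer_bp_interval(model)
  if (iv[2] + max_offset > n_bp_of(model)) {
    stop(sprintf(
      "scan_spacings: max_offset %d exceeds DNA capacity (dimer spans bp %d-%d of %d)",
      max_offset, iv[1], iv[2], n_bp_of(model)), call. = FALSE)
  }
  s <- model$structure
  prot <- s[s$chain %in% model$protein_chains, ]
  dna <- s[s$chain %in% model$dna_chains, ]
  sasa_dimer <- sasa(prot, probe, n_points, radii)$total
  sasa_dna <- if (dna_overlap) sasa(dna, probe, n_points, radii)$atoms$area
  rows <- vector("list", max_offset)
  for (off in seq_len(max_offset)) {
    copy <- apply_transform(prot, helical_step(model$helical, off))
    cl <- clash_score(prot, copy, overlap_tol, radii)
    pair <- bind_rows(prot, copy)
    sasa_pair <- sasa(pair, probe, n_points, radii)$total
    cs_dd <- (2 * sasa_dimer - sasa_pair) / 2
    dov <- NA_real_
    if (dna_overlap) {
      full <- bind_rows(dna, pair)
      in_cplx <- sasa(full, probe, n_points, radii)$atoms$area[seq_len(nrow(dna))]
      dov <- sum(sasa_dna - in_cplx)
    }
    cls <- if (cl$n_clashing_pairs > 0) "clash"
           else if (cs_dd >= cs_min) "contact" else "separated"
    rows[[off]] <- tibble(offset = off, n_clash = cl$n_clashing_pairs,
                          worst_overlap = cl$worst_overlap, cs_dd = cs_dd,
                          dna_overlap = dov, class = cls)
  }
  out <- bind_rows(rows)
  attr(out, "cs_min") <- cs_min
  attr(out, "overlap_tol") <- overlap_tol
  class(out) <- c("spacing_scan", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a multimer from a reference dimer and offsets
#'
#' Places a dimer copy at every offset (base pairs, strictly increasing,
#' first 0) and assembles the multimer on the DNA.  Unless `force` is set,
#' any clashing copy pair aborts with an error naming the offending pair.
#'
#' @param model a `dock_model` with a dimer placed on DNA.
#' @param offsets integer offsets in bp, strictly increasing, starting
#'   at 0.  `c(0, 3, 6)` and `c(0, 6, 12)` build the two hexamer models;
#'   seven copies at 6 bp spacing build the polymerised form.
#' @param force assemble even across clashes.
#' @param surfaces compute adjacent-pair contact surfaces and the total
#'   DNA overlapped surface.
#' @inheritParams scan_spacings
#' @return An object of class `multimer_model`: `structure`, `offsets`,
#'   `copies` (tibble offset/chains), `pair_cs` (adjacent-pair contact
#'   surfaces) and `dna_overlap`.
#' @export
build_multimer <- function(model, offsets, force = FALSE, surfaces = TRUE,
                           overlap_tol = 0.5, probe = 1.4, n_points = 960,
                           radii = NULL) {
  stopifnot(inherits(model, "dock_model"))
  if (!length(offsets)) stop("build_multimer: empty offsets", call. = FALSE)
  if (offsets[1] != 0 || any(diff(offsets) <= 0)) {
    stop("build_multimer: offsets must be strictly increasing and start at 0",
         call. = FALSE)
  }
  radii <- radii %||% model$radii %||% default_vdw_radii()
  iv <- dimer_bp_interval(model)
  if (iv[2] + max(offsets) > n_bp_of(model)) {
    stop("build_multimer: DNA too short for the largest offset", call. = FALSE)
  }
  s <- model$structure
  prot <- s[s$chain %in% model$protein_chains, ]
  dna <- s[s$chain %in% model$dna_chains, ]
  copies <- lapply(offsets, function(off) {
    if (off == 0) prot else
      apply_transform(prot, helical_step(model$helical, off))
  })
  # pairwise clash check
  for (i in seq_along(copies)) {
    for (j in seq_along(copies)) {
      if (j <= i) next
      cl <- clash_score(copies[[i]], copies[[j]], overlap_tol, radii)
      if (cl$n_clashing_pairs > 0 && !force) {
        stop(sprintf(
          "build_multimer: copies at offsets %d and %d clash (%d pairs, worst overlap %.2f A)",
          offsets[i], offsets[j], cl$n_clashing_pairs, cl$worst_overlap),
          call. = FALSE)
      }
    }
  }
  used <- model$dna_chains
  out_copies <- list()
  copy_tbl <- list()
  for (i in seq_along(copies)) {
    cp <- copies[[i]]
    pool <- setdiff(c(LETTERS, letters, as.character(0:9)), used)
    ids <- pool[seq_along(unique(cp$chain))]
    map <- stats::setNames(ids, unique(cp$chain))
    cp$chain <- unname(map[cp$chain])
    used <- c(used, ids)
    out_copies[[i]] <- cp
    copy_tbl[[i]] <- tibble(offset = offsets[i],
                            chains = paste(ids, collapse = ","))
  }
  assembled <- bind_rows(c(list(dna), out_copies))
  pair_cs <- NULL
  dov <- NA_real_
  if (surfaces) {
    sasa_dimer <- sasa(prot, probe, n_points, radii)$total
    pair_cs <- bind_rows(lapply(seq_len(length(copies) - 1), function(i) {
      pair <- bind_rows(out_copies[[i]], out_copies[[i + 1]])
      sp <- sasa(pair, probe, n_points, radii)$total
      tibble(offset_a = offsets[i], offset_b = offsets[i + 1],
             cs_dd = (2 * sasa_dimer - sp) / 2)
    }))
    sasa_dna <- sasa(dna, probe, n_points, radii)$atoms$area
    allp <- bind_rows(out_copies)
    in_cplx <- sasa(bind_rows(dna, allp), probe, n_points,
                    radii)$atoms$area[seq_len(nrow(dna))]
    dov <- sum(sasa_dna - in_cplx)
  }
  structure(list(structure = as_structure(assembled), offsets = offsets,
                 copies = bind_rows(copy_tbl), pair_cs = pair_cs,
                 dna_overlap = dov, dna_chains = model$dna_chains),
            class = "multimer_model")
}

#' @export
print.multimer_model <- function(x, ...) {
  cat(sprintf("<multimer_model> %d dimer copies at offsets [%s] bp\n",
              length(x$offsets), paste(x$offsets, collapse = ", ")))
  if (!is.na(x$dna_overlap)) {
    cat(sprintf("  DNA overlapped surface: %.1f A^2\n", x$dna_overlap))
  }
  invisible(x)
}

#' Protected span of a multimer footprint
#'
#' Analytic footprint arithmetic: copies of a dimer protecting
#' `dimer_footprint_bp` base pairs each, placed at the given offsets,
#' protect a contiguous span of `dimer_footprint_bp + (max(offsets) -
#' min(offsets))` base pairs.  Three dimers at offsets 0/3/6 with a 21 bp
#' single-dimer footprint protect 27 bp; at 0/6/12 they protect 33 bp.
#'
#' @param offsets integer offsets in bp, ascending, starting at 0.
#' @param dimer_footprint_bp footprint of a single dimer, bp (>= 1).
#' @return Integer span in base pairs.
#' @examples
#' multimer_footprint_span(c(0, 3, 6), 21)   # 27
#' multimer_footprint_span(c(0, 6, 12), 21)  # 33
#' @export
multimer_footprint_span <- function(offsets, dimer_footprint_bp) {
  if (!length(offsets)) {
    stop("multimer_footprint_span: empty offsets", call. = FALSE)
  }
  stopifnot(dimer_footprint_bp >= 1,
            all(offsets == round(offsets)))
  if (is.unsorted(offsets, strictly = TRUE) || offsets[1] != 0) {
    stop("multimer_footprint_span: offsets must be ascending and start at 0",
         call. = FALSE)
  }
  as.integer(dimer_footprint_bp + max(offsets) - min(offsets))
}

#' Transcriptional switch report for a divergent promoter
#'
#' Given the DNA interval protected by a bound multimer (absolute
#' top-strand coordinates) and the promoter annotation of two divergently
#' transcribed genes, reports per gene whether the protected region
#' overlaps its -10 or -35 box, i.e. whether sigma-factor binding (and
#' hence transcription) is blocked.  Re-running with the protected
#' interval of a multimer minus one of its end dimers recomputes the
#' switch.
#'
#' @param protected_interval integer length-2 vector, absolute top-strand
#'   positions (start, end) of the protected region.
#' @param annotation a [promoter_annotation()] or a data frame with
#'   columns `gene`, `strand`, `tss`, `m10_start`, `m10_end` and
#'   optionally `m35_start`, `m35_end` (absolute coordinates).
#' @return A tibble of class `switch_report`: `gene`, `strand`,
#'   `overlaps_m10`, `overlaps_m35`, `blocked`, `verdict`.
#' @export
switch_report <- function(protected_interval, annotation) {
  if (inherits(annotation, "promoter_annotation")) {
    genes <- annotation$genes
  } else {
    genes <- as_tibble(annotation)
  }
  stopifnot(length(protected_interval) == 2)
  if (protected_interval[1] > protected_interval[2]) {
    stop("switch_report: protected interval start exceeds end", call. = FALSE)
  }
  need <- c("gene", "strand", "m10_start", "m10_end")
  if (!all(need %in% names(genes))) {
    stop("switch_report: annotation lacks columns: ",
         paste(setdiff(need, names(genes)), collapse = ", "), call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("switch_report: strand must be '+' or '-'", call. = FALSE)
  }
  overlaps <- function(a1, a2, b1, b2) {
    !is.na(b1) & !is.na(b2) & a1 <= b2 & b1 <= a2
  }
  bad <- with(genes, !is.na(m10_start) & m10_start > m10_end)
  if (any(bad)) stop("switch_report: inconsistent -10 box coordinates",
                     call. = FALSE)
  o10 <- overlaps(protected_interval[1], protected_interval[2],
                  genes$m10_start, genes$m10_end)
  if (all(c("m35_start", "m35_end") %in% names(genes))) {
    o35 <- overlaps(protected_interval[1], protected_interval[2],
                    genes$m35_start, genes$m35_end)
  } else {
    o35 <- rep(FALSE, nrow(genes))
  }
  out <- tibble(gene = genes$gene, strand = genes$strand,
                overlaps_m10 = o10, overlaps_m35 = o35,
                blocked = o10 | o35,
                verdict = ifelse(o10 | o35, "blocked", "free"))
  attr(out, "protected_interval") <- as.integer(protected_interval)
  class(out) <- c("switch_report", class(out))
  out
}
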