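# run code under a fixed RNG state without touching the caller's stream
with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Toy dimer specification
#'
#' Describes a pseudo-atom stand-in for a DNA-bound protein dimer.  Two
#' envelope types are available: `"lobes"` (two lobes of backbone-hugging
#' pseudo-atoms whose buried-surface footprint is calibrated to
#' `footprint_bp`) and `"sphere-pair"` (two large spheres on opposite
#' faces of the helix, for which spacing-scan geometry has a closed form).
#' Pseudo-atoms of the lobes envelope use the carbon radius so the surface
#' module needs no special cases; sphere-pair radii are carried in the
#' model's radius table.
#'
#' @param footprint_bp target DNA footprint in base pairs (>= 1).
#' @param envelope `"lobes"` or `"sphere-pair"`.
#' @param atom_radius pseudo-atom radius for the lobes envelope, Angstrom.
#' @param standoff gap between pseudo-atom and DNA van der Waals surfaces,
#'   Angstrom (>= 0).
#' @param sphere_radius sphere radius for the sphere-pair envelope.
#' @param seed reproducibility seed (reserved for jittered variants).
#' @return An object of class `toy_dimer_spec`.
#' @export
toy_dimer_spec <- function(footprint_bp, envelope = c("lobes", "sphere-pair"),
                           atom_radius = 1.7, standoff = 0.5,
                           sphere_radius = 6.0, seed = 0) {
  envelope <- match.arg(envelope)
  stopifnot(footprint_bp >= 1, standoff >= 0, atom_radius > 0,
            sphere_radius > 0)
  structure(list(footprint_bp = as.integer(footprint_bp),
                 envelope = envelope, atom_radius = atom_radius,
                 standoff = standoff, sphere_radius = sphere_radius,
                 seed = seed),
            class = "toy_dimer_spec")
}

# pseudo-atoms hugging the phosphate backbone over the covered bp set
lobe_atoms <- function(dna, covered, chains, spec, radii = default_vdw_radii()) {
  half <- ceiling(length(covered) / 2)
  rows <- list()
  r_p <- radii[["P"]]
  for (k in seq_along(covered)) {
    b <- covered[k]
    mono <- if (k <= half) "C" else "D"
    for (ci in 1:2) {
      ch <- chains[ci]
      resno <- if (ci == 1) b else NULL
      sub <- dna[dna$chain == ch & dna$atom == "P", ]
      # bottom strand: residue pairing with bp b
      n <- max(dna$resno[dna$chain == chains[1]])
      want <- if (ci == 1) b else n - b + 1
      p <- sub[sub$resno == want, ]
      if (!nrow(p)) next   # 5'-terminal nucleotide has no phosphate
      radial <- c(p$x, p$y, 0)
      radial <- radial / sqrt(sum(radial^2))
      push <- r_p + spec$atom_radius + spec$standoff
      pos <- c(p$x, p$y, p$z) + push * radial
      rows[[length(rows) + 1]] <- tibble(
        record = "ATOM", atom = "C", element = "C", chain = mono,
        resid = "DUM", resno = b * 2L + ci, insert = "",
        x = pos[1], y = pos[2], z = pos[3], occ = 1, b = 0, het = FALSE)
    }
  }
  bind_rows(rows)
}

#' Build a toy dimer-DNA complex with a calibrated footprint
#'
#' Builds ideal B-DNA from `dna_seq` and places a two-lobed pseudo-atom
#' dimer over its centre whose [dna_footprint()] span equals
#' `spec$footprint_bp`; the covered base-pair set is adjusted against the
#' footprint measurement at construction time until the span matches.
#' For the `"sphere-pair"` envelope two large spheres are placed on
#' opposite faces of the helix at the central base pair (no footprint
#' calibration; used for spacing-scan geometry).
#'
#' @param spec a [toy_dimer_spec()].
#' @param dna_seq top-strand sequence; must be longer than the footprint.
#' @param params a [helical_parameters()].
#' @param buried_threshold,probe,n_points passed to [dna_footprint()]
#'   during calibration.
#' @return A `dock_model` (DNA chains `X`/`Y`, pseudo-protein chains
#'   `C`/`D`) whose `$footprint` holds the calibration result.
#' @export
make_toy_dimer_complex <- function(spec, dna_seq,
                                   params = helical_parameters(),
                                   buried_threshold = 1.0, probe = 1.4,
                                   n_points = 960) {
  stopifnot(inherits(spec, "toy_dimer_spec"))
  s <- check_dna_seq(dna_seq)
  n <- nchar(s)
  if (n < spec$footprint_bp) {
    stop("make_toy_dimer_complex: DNA shorter than the requested footprint",
         call. = FALSE)
  }
  dna <- build_bdna(s, params, chain_ids = c("X", "Y"))
  if (spec$envelope == "sphere-pair") {
    b0 <- ceiling(n / 2)
    z0 <- (b0 - 1) * params$rise
    phase <- (b0 - 1) * params$twist * pi / 180
    dist <- 10.4 + spec$sphere_radius + spec$standoff
    pos1 <- c(dist * cos(phase), dist * sin(phase), z0)
    pos2 <- -c(dist * cos(phase), dist * sin(phase), -z0)
    prot <- tibble(
      record = "ATOM", atom = "XS", element = "XS", chain = c("C", "D"),
      resid = "DUM", resno = 1L, insert = "",
      x = c(pos1[1], pos2[1]), y = c(pos1[2], pos2[2]),
      z = c(pos1[3], pos2[3]), occ = 1, b = 0, het = FALSE)
    radii <- c(default_vdw_radii(), XS = spec$sphere_radius)
    model <- new_dock_model(bind_rows(dna, prot), c("X", "Y"), c("C", "D"),
                            helical_parameters(params$rise, params$twist),
                            radii = radii)
    model$footprint <- NULL
    model$center_bp <- b0
    return(model)
  }
  target <- spec$footprint_bp
  c0 <- ceiling(n / 2)
  start <- max(1L, c0 - target %/% 2L)
  covered <- seq(start, length.out = target)
  if (max(covered) > n) covered <- covered - (max(covered) - n)
  radii <- default_vdw_radii()
  for (iter in 1:8) {
    prot <- lobe_atoms(dna, covered, c("X", "Y"), spec, radii)
    fp <- dna_footprint(bind_rows(dna, prot), c("X", "Y"), c("C", "D"),
                        buried_threshold, probe, n_points, radii)
    delta <- fp$span_bp - target
    if (delta == 0) {
      model <- new_dock_model(bind_rows(dna, prot), c("X", "Y"), c("C", "D"),
                              helical_parameters(params$rise, params$twist))
      model$footprint <- fp
      return(model)
    }
    # trim or extend the covered set symmetrically and re-measure
    if (delta > 0) {
      trim_head <- delta %/% 2 + delta %% 2
      trim_tail <- delta %/% 2
      covered <- covered[seq(1 + trim_head, length(covered) - trim_tail)]
      if (!length(covered)) break
    } else {
      add <- -delta
      lo <- max(1L, min(covered) - (add %/% 2 + add %% 2))
      hi <- min(n, max(covered) + add %/% 2)
      covered <- seq(lo, hi)
    }
  }
  stop(sprintf(
    "make_toy_dimer_complex: could not calibrate footprint %d bp on %d bp DNA",
    target, n), call. = FALSE)
}

#' Synthetic wHTH homodimer-DNA template complex
#'
#' Builds an ideal B-DNA duplex and a schematic pseudo-protein homodimer
#' whose recognition helix H4 lies against the major-groove face of the
#' DNA, with the trailing antiparallel strands S1/S2 (the wing) and
#' peripheral helices placed outward.  Monomer B is the dyad image of
#' monomer A, so the dimer straddles the duplex like the templates this
#' package emulates.  The result passes [check_template_criteria()] by
#' construction.
#'
#' @param dna_seq top-strand sequence; default a symmetric 25 bp AT-rich
#'   fragment.
#' @param resolution resolution metadata recorded on the template.
#' @param params a [helical_parameters()].
#' @param wing if `FALSE`, the S2 strand is omitted (used to exercise the
#'   motif-topology criterion).
#' @return A [template_complex()] with DNA chains `X`/`Y` and protein
#'   chains `A`/`B`.
#' @export
make_template_complex <- function(dna_seq = NULL, resolution = 2.0,
                                  params = helical_parameters(),
                                  wing = TRUE) {
  if (is.null(dna_seq)) {
    half <- "TATAATTTAAAT"
    dna_seq <- paste0(half, "A", revcomp(half))
  }
  s <- check_dna_seq(dna_seq)
  n <- nchar(s)
  dna <- build_bdna(s, params, chain_ids = c("X", "Y"))
  zc <- (n - 1) * params$rise / 2
  z8 <- zc - 2.5 * params$rise
  segs <- list(
    list(name = "H1", type = "helix", start = 5, end = 14,
         origin = c(19, -6, z8 - 6), dir = c(0, 1, 0.2)),
    list(name = "H2", type = "helix", start = 18, end = 26,
         origin = c(21, 2, z8 - 2), dir = c(0.2, -1, 0.1)),
    list(name = "H3", type = "helix", start = 30, end = 40,
         origin = c(15.5, -6, z8 - 4), dir = c(0.1, 1, 0.1)),
    list(name = "H4", type = "helix", start = 44, end = 57,
         origin = c(11.5, -8, z8), dir = c(0, 1, 0.25)),
    list(name = "S1", type = "strand", start = 61, end = 65,
         origin = c(16, -4, z8 + 3), dir = c(0.1, 1, 0.15)),
    list(name = "S2", type = "strand", start = 68, end = 72,
         origin = c(17.5, 1.5, z8 + 4.5), dir = c(-0.1, -1, -0.15)),
    list(name = "H5", type = "helix", start = 80, end = 90,
         origin = c(23, -4, zc), dir = c(0.1, 1, 0)))
  if (!wing) segs <- segs[vapply(segs, function(x) x$name != "S2", logical(1))]
  monoA <- bind_rows(lapply(segs, function(sg) {
    build_segment(sg, chain = "A")
  }))
  dyad <- axis_rotation(c(1, 0, 0), 180, point = c(0, 0, zc))
  monoB <- apply_transform(monoA, dyad)
  monoB$chain <- "B"
  el <- bind_rows(lapply(segs, function(sg) {
    tibble(element = sg$name, chain = "A", start = sg$start, end = sg$end)
  }))
  motif <- motif_spec(el[el$element %in% c("H3", "H4", "S1", "S2"), ],
                      recognition = "H4",
                      antiparallel = list(c("S1", "S2")))
  template_complex(bind_rows(dna, monoA, monoB), motif,
                   dna = c("X", "Y"), protein = c("A", "B"),
                   resolution = resolution)
}

# schematic alpha-helix / beta-strand backbone segments (N, CA, C, O)
build_segment <- function(sg, chain) {
  res <- sg$start:sg$end
  nres <- length(res)
  u <- sg$dir / sqrt(sum(sg$dir^2))
  # orthonormal frame about the segment axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  v <- ref - sum(ref * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  rows <- list()
  for (i in seq_len(nres)) {
    if (sg$type == "helix") {
      ang <- (i - 1) * 100 * pi / 180
      ca <- sg$origin + (i - 1) * 1.5 * u +
        2.3 * (cos(ang) * v + sin(ang) * w)
      tang <- -sin(ang) * v + cos(ang) * w
    } else {
      ca <- sg$origin + (i - 1) * 3.3 * u +
        0.9 * (if (i %% 2 == 0) v else -v)
      tang <- w
    }
    np <- ca - 1.2 * u + 0.5 * tang
    cp <- ca + 1.2 * u + 0.5 * tang
    op <- cp + 1.23 * (if (sg$type == "helix") tang else v)
    for (a in list(list("N", np), list("CA", ca), list("C", cp),
                   list("O", op))) {
      rows[[length(rows) + 1]] <- tibble(
        record = "ATOM", atom = a[[1]],
        element = substr(a[[1]], 1, 1), chain = chain, resid = "ALA",
        resno = res[i], insert = "",
        x = a[[2]][1], y = a[[2]][2], z = a[[2]][3],
        occ = 1, b = 0, het = FALSE)
    }
  }
  bind_rows(rows)
}

#' Synthetic promoter region with planted elements
#'
#' Generates a seeded random background sequence, plants promoter elements
#' (in each gene's own frame and promoter coordinates) and optionally an
#' AT-only run flanked by G/C so the run is maximal, and returns the
#' annotation with the ground truth attached (attribute `truth`).
#'
#' @param length region length, bp.
#' @param genes data frame with `gene`, `strand`, `tss` (absolute top
#'   strand coordinates), as in [promoter_annotation()].
#' @param plants data frame with `gene`, `motif`, `position` (promoter
#'   coordinate of the motif's 5'-most base in the gene frame); may be
#'   empty.
#' @param at_run optional `c(position, length)`: absolute start and length
#'   of an A/T-only run.
#' @param seed RNG seed (default 0); the same seed always yields the same
#'   sequence.
#' @param gc background GC fraction (default 0.5).
#' @return A [promoter_annotation()].
#' @export
make_promoter_sequence <- function(length, genes, plants = NULL,
                                   at_run = NULL, seed = 0, gc = 0.5) {
  stopifnot(length >= 1)
  base <- with_fixed_seed(seed, {
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  })
  assigned <- rep(NA_character_, length)
  place <- function(pos_abs, chars, what) {
    idx <- pos_abs
    if (any(idx < 1 | idx > length)) {
      stop("make_promoter_sequence: ", what, " outside sequence",
           call. = FALSE)
    }
    conflict <- !is.na(assigned[idx]) & assigned[idx] != chars
    if (any(conflict)) {
      stop("make_promoter_sequence: overlapping planted elements disagree at position ",
           idx[which(conflict)[1]], call. = FALSE)
    }
    assigned[idx] <<- chars
  }
  ann0 <- promoter_annotation(paste(base, collapse = ""), genes)
  if (!is.null(plants) && nrow(plants)) {
    for (i in seq_len(nrow(plants))) {
      p <- plants[i, ]
      g <- ann0$genes[ann0$genes$gene == p$gene, ]
      motif <- toupper(p$motif)
      k <- nchar(motif)
      pos <- p$position + 0:(k - 1)
      pos <- pos + (p$position < 0 & pos >= 0)  # skip the absent 0
      idx_gene <- promoter_to_index(ann0, p$gene, pos)
      chars <- strsplit(motif, "")[[1]]
      if (g$strand == "+") {
        place(idx_gene, chars, paste0("motif ", motif))
      } else {
        abs_idx <- nchar(ann0$seq) - idx_gene + 1
        place(abs_idx, strsplit(chartr("ACGT", "TGCA", motif), "")[[1]],
              paste0("motif ", motif))
      }
    }
  }
  if (!is.null(at_run)) {
    pos <- at_run[1] + 0:(at_run[2] - 1)
    run_chars <- with_fixed_seed(seed + 1, {
      sample(c("A", "T"), at_run[2], replace = TRUE)
    })
    place(pos, run_chars, "AT run")
    for (fl in c(at_run[1] - 1, at_run[1] + at_run[2])) {
      if (fl >= 1 && fl <= length && is.na(assigned[fl])) {
        assigned[fl] <- "G"
      }
    }
  }
  final <- ifelse(is.na(assigned), base, assigned)
  ann <- promoter_annotation(paste(final, collapse = ""), genes)
  attr(ann, "truth") <- list(plants = plants, at_run = at_run, seed = seed)
  ann
}
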