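#' Van der Waals radii
#'
#' Bondi-style heavy-atom radii with a united-atom flavour appropriate for
#' hydrogen-less structures, keyed by element symbol.  Unknown elements
#' fall back to `default` unless `default` is `NA`.
#'
#' @return A named numeric vector of radii (Angstrom).
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
    H = 1.20, FE = 1.20, ZN = 1.39, MN = 1.39, MG = 1.73,
    NA. = 2.27, CL = 1.75, K = 2.75, CA = 2.31, X = 1.70)
}

atom_radii <- function(s, radii = default_vdw_radii(),
                       default = if ("X" %in% names(radii)) radii[["X"]] else NA_real_) {
  el <- toupper(s$element)
  el[el == "NA"] <- "NA."
  r <- unname(radii[el])
  if (anyNA(r)) {
    if (is.na(default)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "), call. = FALSE)
    }
    r[is.na(r)] <- default
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA with a deterministic Fibonacci-lattice point set on each
#' atom sphere; no random numbers are involved, so results are
#' bit-identical across runs and converge to analytic values as `n_points`
#' grows.
#'
#' @param s a structure tibble (or any data frame with `x`,`y`,`z` and
#'   `element` columns).
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points sample points per atom (default 960).
#' @param radii named radius table, see [default_vdw_radii()].
#' @return An object of class `sasa_result`: list with `atoms` (the input
#'   tibble plus an `area` column, Angstrom^2), `total`, `probe`,
#'   `n_points`.
#' @examples
#' dna <- build_bdna("ATGCAT")
#' sasa(dna)$total
#' @export
sasa <- function(s, probe = 1.4, n_points = 960, radii = default_vdw_radii()) {
  if (!nrow(s)) stop("sasa: empty atom set", call. = FALSE)
  stopifnot(probe >= 0, n_points >= 1)
  r <- atom_radii(s, radii)
  area <- .sasa_cpp(coords_matrix(s), r, probe, as.integer(n_points))
  atoms <- as_tibble(s)
  atoms$radius <- r
  atoms$area <- area
  structure(list(atoms = atoms, total = sum(area), probe = probe,
                 n_points = as.integer(n_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> %d atoms, total %.1f A^2 (probe %.2f A, %d pts/atom)\n",
              nrow(x$atoms), x$total, x$probe, x$n_points))
  invisible(x)
}

#' @export
tidy.sasa_result <- function(x, ...) x$atoms

#' @export
glance.sasa_result <- function(x, ...) {
  tibble(total_area = x$total, n_atoms = nrow(x$atoms), probe = x$probe,
         n_points = x$n_points)
}

#' Contact surface between a receptor and a ligand
#'
#' The contact-surface statistic
#' \deqn{CS = (SASA_{rec} + SASA_{lig} - SASA_{cplx}) / 2,}
#' i.e. half the solvent-accessible area lost on complexation.  Symmetric
#' in its arguments; zero (up to sampling noise) for well-separated bodies.
#'
#' @param receptor,ligand structure tibbles with disjoint atoms.
#' @inheritParams sasa
#' @return An object of class `contact_report` with `sasa_rec`, `sasa_lig`,
#'   `sasa_cplx` and `cs` (Angstrom^2).
#' @export
contact_surface <- function(receptor, ligand, probe = 1.4, n_points = 960,
                            radii = default_vdw_radii()) {
  ra <- coords_matrix(receptor); rb <- coords_matrix(ligand)
  if (length(merge_overlap(ra, rb))) {
    stop("contact_surface: receptor and ligand share atom positions",
         call. = FALSE)
  }
  s_rec <- sasa(receptor, probe, n_points, radii)$total
  s_lig <- sasa(ligand, probe, n_points, radii)$total
  cplx <- bind_rows(as_tibble(receptor), as_tibble(ligand))
  s_cplx <- sasa(cplx, probe, n_points, radii)$total
  structure(list(sasa_rec = s_rec, sasa_lig = s_lig, sasa_cplx = s_cplx,
                 cs = (s_rec + s_lig - s_cplx) / 2),
            class = "contact_report")
}

merge_overlap <- function(a, b) {
  key_a <- paste(round(a[, 1], 6), round(a[, 2], 6), round(a[, 3], 6))
  key_b <- paste(round(b[, 1], 6), round(b[, 2], 6), round(b[, 3], 6))
  intersect(key_a, key_b)
}

#' @export
print.contact_report <- function(x, ...) {
  cat(sprintf(
    "<contact_report> CS %.1f A^2 (rec %.1f, lig %.1f, cplx %.1f)\n",
    x$cs, x$sasa_rec, x$sasa_lig, x$sasa_cplx))
  invisible(x)
}

#' @export
tidy.contact_report <- function(x, ...) {
  tibble(sasa_rec = x$sasa_rec, sasa_lig = x$sasa_lig,
         sasa_cplx = x$sasa_cplx, cs = x$cs)
}

#' Steric clash score between two atom sets
#'
#' A pair (i, j) clashes when its distance falls below
#' `r_i + r_j - overlap_tol`.
#'
#' @param a,b structure tibbles (disjoint atom sets).
#' @param overlap_tol tolerated van der Waals overlap, Angstrom.
#' @inheritParams sasa
#' @return A list with `n_clashing_pairs` and `worst_overlap` (Angstrom).
#' @export
clash_score <- function(a, b, overlap_tol = 0.5, radii = default_vdw_radii()) {
  .clash_cpp(coords_matrix(a), atom_radii(a, radii),
             coords_matrix(b), atom_radii(b, radii), overlap_tol)
}

#' Per-nucleotide buried surface and DNA footprint
#'
#' For each nucleotide, the buried area is its SASA in the naked DNA minus
#' its SASA in the full complex.  A base pair is protected when either
#' paired nucleotide buries more than `buried_threshold`; the footprint
#' span is the contiguous first-to-last protected base-pair range, the
#' quantity a DNase protection assay reports.
#'
#' @param complex structure tibble with DNA and (optionally several)
#'   protein components.
#' @param dna_chains the two DNA chain ids, top strand first.
#' @param protein_chains chains treated as the bound protein; may be empty.
#' @param buried_threshold minimum buried area per nucleotide, Angstrom^2.
#' @inheritParams sasa
#' @return An object of class `dna_footprint` with `by_bp` (tibble: `bp`,
#'   `buried_top`, `buried_bottom`, `protected`), `protected_bp` (integer
#'   vector) and `span_bp`.
#' @export
dna_footprint <- function(complex, dna_chains = NULL, protein_chains = NULL,
                          buried_threshold = 1.0, probe = 1.4,
                          n_points = 960, radii = default_vdw_radii()) {
  s <- as_structure(complex)
  if (is.null(dna_chains)) dna_chains <- dna_chains(s)
  if (length(dna_chains) < 1) stop("dna_footprint: no DNA chains", call. = FALSE)
  if (is.null(protein_chains)) {
    protein_chains <- setdiff(unique(s$chain), dna_chains)
  }
  dna <- s[s$chain %in% dna_chains, ]
  prot <- s[s$chain %in% protein_chains, ]
  sa_free <- sasa(dna, probe, n_points, radii)$atoms
  if (nrow(prot)) {
    full <- bind_rows(dna, prot)
    sa_cplx <- sasa(full, probe, n_points, radii)$atoms[seq_len(nrow(dna)), ]
  } else {
    sa_cplx <- sa_free
  }
  per_nt <- tibble(chain = dna$chain, resno = dna$resno,
                   buried = sa_free$area - sa_cplx$area) |>
    group_by(.data$chain, .data$resno) |>
    summarise(buried = sum(.data$buried), .groups = "drop")
  top <- per_nt[per_nt$chain == dna_chains[1], ]
  top <- top[order(top$resno), ]
  n <- nrow(top)
  if (length(dna_chains) >= 2) {
    bot <- per_nt[per_nt$chain == dna_chains[2], ]
    bot <- bot[order(-bot$resno), ]
    nb <- min(n, nrow(bot))
    buried_bottom <- c(bot$buried[seq_len(nb)], rep(0, n - nb))
  } else {
    buried_bottom <- rep(0, n)
  }
  by_bp <- tibble(bp = seq_len(n),
                  buried_top = top$buried,
                  buried_bottom = buried_bottom)
  by_bp$protected <- by_bp$buried_top > buried_threshold |
    by_bp$buried_bottom > buried_threshold
  prot_bp <- by_bp$bp[by_bp$protected]
  span <- if (length(prot_bp)) max(prot_bp) - min(prot_bp) + 1L else 0L
  structure(list(by_bp = by_bp, protected_bp = prot_bp, span_bp = span,
                 buried_threshold = buried_threshold),
            class = "dna_footprint")
}

#' @export
print.dna_footprint <- function(x, ...) {
  cat(sprintf("<dna_footprint> %d protected bp, span %d bp (threshold %.1f A^2)\n",
              length(x$protected_bp), x$span_bp, x$buried_threshold))
  invisible(x)
}

#' @export
tidy.dna_footprint <- function(x, ...) x$by_bp

#' @export
glance.dna_footprint <- function(x, ...) {
  tibble(span_bp = x$span_bp, n_protected = length(x$protected_bp),
         buried_threshold = x$buried_threshold)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
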