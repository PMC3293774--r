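#' Winged helix-turn-helix motif annotation
#'
#' Residue ranges for the secondary-structure elements of a wHTH
#' DNA-binding domain (helices H1..H5, strands S1..S5), with the
#' recognition helix (the one inserted into the major groove) and the
#' antiparallel strand pairs ("wing") designated explicitly.  Motifs are
#' user-supplied annotations, not predictions.
#'
#' @param elements a data frame with columns `element`, `chain`, `start`,
#'   `end` (author residue numbers, inclusive).
#' @param recognition name of the recognition helix element (default "H4").
#' @param antiparallel list of character pairs annotated as antiparallel
#'   strands, default `list(c("S1", "S2"))`.
#' @return An object of class `motif_spec`.
#' @examples
#' motif_spec(data.frame(
#'   element = c("H3", "H4", "S1", "S2"), chain = "A",
#'   start = c(30, 44, 61, 68), end = c(40, 57, 65, 72)))
#' @export
motif_spec <- function(elements, recognition = "H4",
                       antiparallel = list(c("S1", "S2"))) {
  el <- as_tibble(elements)
  stopifnot(all(c("element", "chain", "start", "end") %in% names(el)))
  if (any(el$end < el$start)) {
    stop("motif_spec: element end before start", call. = FALSE)
  }
  if (anyDuplicated(el$element)) {
    stop("motif_spec: duplicated element names", call. = FALSE)
  }
  # non-overlap within a chain
  for (ch in unique(el$chain)) {
    sub <- el[el$chain == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1 && any(sub$start[-1] <= sub$end[-nrow(sub)])) {
      stop("motif_spec: overlapping element ranges on chain ", ch,
           call. = FALSE)
    }
  }
  if (!recognition %in% el$element) {
    stop("motif_spec: recognition helix '", recognition,
         "' not among elements", call. = FALSE)
  }
  structure(list(elements = el, recognition = recognition,
                 antiparallel = antiparallel),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("<motif_spec> recognition helix:", x$recognition, "\n")
  print(x$elements)
  invisible(x)
}

#' A template protein-DNA complex
#'
#' Bundles an experimental (or synthetic) protein-DNA complex with the
#' wHTH motif annotation of its DNA-binding protein, the identity of the
#' DNA duplex chains, and resolution metadata.
#'
#' @param structure a structure tibble.
#' @param motif a [motif_spec()] for one protein monomer.
#' @param dna a length-2 character vector of DNA chain ids (top, bottom);
#'   default: detected.
#' @param protein protein chain ids; default: detected.
#' @param resolution crystallographic resolution, Angstrom.
#' @return An object of class `template_complex`.
#' @export
template_complex <- function(structure, motif, dna = NULL, protein = NULL,
                             resolution = NA_real_) {
  s <- as_structure(structure)
  if (is.null(dna)) dna <- dna_chains(s)
  if (is.null(protein)) protein <- protein_chains(s)
  if (length(dna) != 2) {
    stop("template_complex: expected exactly one DNA duplex (2 chains)",
         call. = FALSE)
  }
  if (length(protein) < 1) {
    stop("template_complex: no protein chains", call. = FALSE)
  }
  stopifnot(inherits(motif, "motif_spec"))
  structure(list(structure = s, motif = motif, dna_chains = dna,
                 protein_chains = protein, resolution = resolution),
            class = "template_complex")
}

#' Template admissibility criteria
#'
#' Evaluates the four qualitative criteria used to retain a protein-DNA
#' complex as a modelling template: (1) the double-stranded DNA target site
#' is at least `min_bp` base pairs; (2) the DNA-bound protein is a
#' homodimer (two protein chains with identical sequences); (3) the
#' recognition helix is followed in sequence by two strand ranges
#' annotated antiparallel (the wing), taken from the motif annotation; (4)
#' the experimental resolution is at most `max_resolution`.
#'
#' @param t a [template_complex()].
#' @param min_bp minimum duplex length (default 20 bp).
#' @param max_resolution maximum resolution, Angstrom.
#' @return A tibble with one row per criterion (`criterion`, `description`,
#'   `pass`) carrying attribute `overall` (all pass); class
#'   `criteria_report`.
#' @export
check_template_criteria <- function(t, min_bp = 20, max_resolution = 3.0) {
  stopifnot(inherits(t, "template_complex"))
  if (is.null(t$motif)) stop("check_template_criteria: missing motif", call. = FALSE)
  s <- t$structure
  n_bp <- nrow(bp_centroids(s, t$dna_chains))
  c1 <- n_bp >= min_bp
  seqs <- vapply(t$protein_chains, function(ch) structure_sequence(s, ch),
                 character(1))
  c2 <- length(seqs) == 2 && seqs[[1]] == seqs[[2]]
  el <- t$motif$elements
  rec <- el[el$element == t$motif$recognition, ]
  strands <- el[grepl("^S", el$element) & el$chain == rec$chain &
                  el$start > rec$end, ]
  anti <- any(vapply(t$motif$antiparallel, function(p) {
    all(p %in% strands$element)
  }, logical(1)))
  c3 <- nrow(strands) >= 2 && anti
  c4 <- !is.na(t$resolution) && t$resolution <= max_resolution
  rep <- tibble(
    criterion = 1:4,
    description = c(
      sprintf("DNA target site >= %d bp (found %d)", min_bp, n_bp),
      "protein is homodimeric (two identical chains)",
      "recognition helix followed by two antiparallel strands",
      sprintf("resolution <= %.2f A", max_resolution)),
    pass = c(c1, c2, c3, c4))
  attr(rep, "overall") <- all(rep$pass)
  class(rep) <- c("criteria_report", class(rep))
  rep
}

# backbone atoms of the motif segments named in a superposition type,
# ordered by segment, residue, then N/CA/C/O
motif_backbone <- function(s, motif, segments) {
  el <- motif$elements
  bborder <- c("N", "CA", "C", "O")
  out <- list()
  for (seg in segments) {
    row <- el[el$element == seg, ]
    if (!nrow(row)) {
      stop("motif element '", seg, "' not annotated", call. = FALSE)
    }
    sub <- s[s$chain == row$chain & s$resno >= row$start &
               s$resno <= row$end & s$atom %in% bborder & !s$het, ]
    if (!nrow(sub)) {
      stop("motif element '", seg, "' (", row$chain, " ", row$start, "-",
           row$end, ") resolves to no backbone atoms", call. = FALSE)
    }
    sub <- sub[order(sub$resno, match(sub$atom, bborder)), ]
    out[[seg]] <- sub
  }
  bind_rows(out)
}

superposition_segments <- function(type) {
  segs <- regmatches(type, gregexpr("[HS][0-9]+", type))[[1]]
  if (!length(segs)) {
    stop("unrecognised superposition type: ", type, call. = FALSE)
  }
  segs
}

new_dock_model <- function(structure, dna_chains, protein_chains, helical,
                           motif = NULL, transforms = list(), rmsd = NA_real_,
                           contact = NULL, restraint_rms = NA_real_,
                           trace = numeric(0), converged = TRUE,
                           radii = NULL) {
  structure(list(structure = as_structure(structure), dna_chains = dna_chains,
                 protein_chains = protein_chains, helical = helical,
                 motif = motif, transforms = transforms, rmsd = rmsd,
                 contact = contact, restraint_rms = restraint_rms,
                 trace = trace, converged = converged, radii = radii),
            class = "dock_model")
}

#' @export
print.dock_model <- function(x, ...) {
  cat(sprintf("<dock_model> %d protein chain(s) [%s] on DNA [%s]\n",
              length(x$protein_chains), paste(x$protein_chains, collapse = ","),
              paste(x$dna_chains, collapse = ",")))
  if (!is.na(x$rmsd)) cat(sprintf("  superposition rmsd: %.4f A\n", x$rmsd))
  if (!is.na(x$restraint_rms)) {
    cat(sprintf("  restraint rms: %.4f A%s\n", x$restraint_rms,
                if (!x$converged) " (NOT converged)" else ""))
  }
  if (!is.null(x$contact)) cat(sprintf("  contact surface: %.1f A^2\n", x$contact$cs))
  invisible(x)
}

#' @export
tidy.dock_model <- function(x, ...) x$structure

#' @export
glance.dock_model <- function(x, ...) {
  tibble(rmsd = x$rmsd, restraint_rms = x$restraint_rms,
         cs = if (is.null(x$contact)) NA_real_ else x$contact$cs,
         converged = x$converged)
}

#' Fit a monomer into a template complex
#'
#' Rigidly places a protein monomer relative to a template's DNA by
#' least-squares superposition of the backbone atoms (N, CA, C, O) of the
#' chosen motif segments onto the template's equivalent atoms, so that the
#' recognition helix adopts the template's major-groove geometry.  The
#' monomer's internal coordinates are untouched (rigid placement).
#'
#' @param monomer structure tibble of the protein monomer.
#' @param monomer_motif [motif_spec()] resolving in `monomer`.
#' @param template a [template_complex()].
#' @param superposition `"H4S1S2"` or `"H3H4S1S2"` (any concatenation of
#'   annotated element names works).
#' @return A `dock_model` containing the placed monomer plus the template
#'   DNA, the applied transform and the superposition rmsd.
#' @export
fit_monomer <- function(monomer, monomer_motif, template,
                        superposition = c("H4S1S2", "H3H4S1S2")) {
  superposition <- superposition[1]
  stopifnot(inherits(template, "template_complex"))
  mono <- as_structure(monomer)
  segs <- superposition_segments(superposition)
  mob <- motif_backbone(mono, monomer_motif, segs)
  ref <- motif_backbone(template$structure, template$motif, segs)
  if (nrow(mob) != nrow(ref)) {
    stop(sprintf(
      "fit_monomer: motif backbone atom counts differ (monomer %d, template %d)",
      nrow(mob), nrow(ref)), call. = FALSE)
  }
  fit <- superpose(mob, ref)
  placed <- apply_transform(mono, fit$transform)
  dna <- template$structure[template$structure$chain %in% template$dna_chains, ]
  # avoid chain-id collisions between monomer and DNA
  placed <- relabel_chains(placed, avoid = template$dna_chains)
  assembled <- bind_rows(dna, placed)
  helical <- fit_helix_axis(assembled, template$dna_chains)
  new_dock_model(assembled, template$dna_chains, unique(placed$chain),
                 helical, motif = monomer_motif,
                 transforms = list(fit = fit$transform), rmsd = fit$rmsd)
}

relabel_chains <- function(s, avoid) {
  pool <- setdiff(c(LETTERS, letters, as.character(0:9)), avoid)
  ch <- unique(s$chain)
  clash <- intersect(ch, avoid)
  if (!length(clash)) return(s)
  free <- setdiff(pool, ch)
  for (i in seq_along(clash)) {
    s$chain[s$chain == clash[i]] <- free[i]
  }
  s
}

#' Distance restraints for dimer closure
#'
#' @param df data frame with columns `chain`, `resno`, `atom` (protein
#'   atom), `dna_chain`, `dna_resno`, `dna_atom`, `target` (Angstrom) and
#'   optionally `weight` (default 1).
#' @return An object of class `restraint_set`.
#' @export
restraint_set <- function(df) {
  r <- as_tibble(df)
  need <- c("chain", "resno", "atom", "dna_chain", "dna_resno", "dna_atom",
            "target")
  stopifnot(all(need %in% names(r)))
  if (is.null(r$weight)) r$weight <- 1
  if (nrow(r) < 3) {
    stop("restraint_set: dimer closure needs at least 3 restraints",
         call. = FALSE)
  }
  if (any(r$target <= 0)) {
    stop("restraint_set: target distances must be positive", call. = FALSE)
  }
  class(r) <- c("restraint_set", class(r))
  r
}

#' Measure default closure restraints from a template
#'
#' For each protein chain of the template, takes the CA atoms of the
#' first, middle and last residues of the recognition helix and records
#' the distance to the nearest DNA phosphorus.  This transfers the
#' template's helix-in-groove geometry as distance restraints when no
#' experimental restraints are supplied.
#'
#' @param template a [template_complex()].
#' @param chains protein chains to derive restraints for (default: all).
#' @return A [restraint_set()].
#' @export
default_restraints <- function(template, chains = NULL) {
  stopifnot(inherits(template, "template_complex"))
  s <- template$structure
  if (is.null(chains)) chains <- template$protein_chains
  rec <- template$motif$elements[
    template$motif$elements$element == template$motif$recognition, ]
  p_atoms <- s[s$chain %in% template$dna_chains & s$atom == "P", ]
  rows <- list()
  for (ch in chains) {
    helix <- s[s$chain == ch & s$atom == "CA" & s$resno >= rec$start &
                 s$resno <= rec$end, ]
    helix <- helix[order(helix$resno), ]
    pick <- unique(c(1L, ceiling(nrow(helix) / 2), nrow(helix)))
    for (k in pick) {
      ca <- helix[k, ]
      d <- sqrt((p_atoms$x - ca$x)^2 + (p_atoms$y - ca$y)^2 +
                  (p_atoms$z - ca$z)^2)
      j <- which.min(d)
      rows[[length(rows) + 1]] <- tibble(
        chain = ca$chain, resno = ca$resno, atom = "CA",
        dna_chain = p_atoms$chain[j], dna_resno = p_atoms$resno[j],
        dna_atom = "P", target = d[j], weight = 1)
    }
  }
  restraint_set(bind_rows(rows))
}

resolve_restraints <- function(restraints, protein, dna) {
  pidx <- integer(nrow(restraints))
  didx <- integer(nrow(restraints))
  for (i in seq_len(nrow(restraints))) {
    p <- which(protein$chain == restraints$chain[i] &
                 protein$resno == restraints$resno[i] &
                 protein$atom == restraints$atom[i])
    d <- which(dna$chain == restraints$dna_chain[i] &
                 dna$resno == restraints$dna_resno[i] &
                 dna$atom == restraints$dna_atom[i])
    if (length(p) != 1 || length(d) != 1) {
      stop(sprintf("restraint %d does not resolve to unique atoms", i),
           call. = FALSE)
    }
    pidx[i] <- p; didx[i] <- d
  }
  list(p = pidx, d = didx)
}

param_to_transform <- function(p, center) {
  ang <- sqrt(sum(p[1:3]^2))
  rot <- if (ang < 1e-12) tf_identity() else
    axis_rotation(p[1:3] / ang, ang, point = center)
  rigid_transform(rot$R, rot$t + p[4:6])
}

#' Close the dimer onto DNA under distance restraints
#'
#' Two-step closure: (1) the intact dimer is superposed onto the partially
#' built complex through the motif backbone of its already-placed monomer,
#' preserving the dimer interface; (2) a single rigid transform of the
#' whole dimer is refined by a deterministic derivative-free minimisation
#' of the weighted sum of squared restraint violations, multi-started from
#' eight fixed axis-angle perturbations (ties broken by the lowest
#' parameter norm).  The dimer is only ever moved rigidly.
#'
#' @param partial a `dock_model` from [fit_monomer()] (placed monomer +
#'   DNA).
#' @param dimer structure tibble of the intact dimer (two protein chains).
#' @param dimer_motif [motif_spec()] resolving the placed monomer's motif
#'   inside `dimer`.
#' @param restraints a [restraint_set()]; at least 3 restraints.
#' @param max_iter maximum optimizer iterations per start.
#' @return A `dock_model` with the closed dimer, the DNA, restraint rms, a
#'   monotone best-objective trace, and the dimer-DNA [contact_surface()]
#'   report.  Non-convergence is flagged (`converged = FALSE`), never
#'   silent.
#' @export
close_dimer <- function(partial, dimer, dimer_motif, restraints,
                        max_iter = 500) {
  stopifnot(inherits(partial, "dock_model"))
  if (!inherits(restraints, "restraint_set")) restraints <- restraint_set(restraints)
  dimer <- as_structure(dimer)
  segs <- superposition_segments("H4S1S2")
  # step 1: carry the dimer onto the placed monomer
  mob <- motif_backbone(dimer, dimer_motif, segs)
  ref <- motif_backbone(partial$structure, partial$motif, segs)
  if (nrow(mob) != nrow(ref)) {
    stop("close_dimer: dimer/placed-monomer motif atom counts differ",
         call. = FALSE)
  }
  step1 <- superpose(mob, ref)
  dimer1 <- apply_transform(dimer, step1$transform)
  dna <- partial$structure[partial$structure$chain %in% partial$dna_chains, ]
  idx <- resolve_restraints(restraints, dimer1, dna)
  pm <- coords_matrix(dimer1)[idx$p, , drop = FALSE]
  dm <- coords_matrix(dna)[idx$d, , drop = FALSE]
  w <- restraints$weight
  tgt <- restraints$target
  center <- colMeans(coords_matrix(dimer1))
  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  obj <- function(p) {
    tf <- param_to_transform(p, center)
    moved <- apply_transform(pm, tf)
    d <- sqrt(rowSums((moved - dm)^2))
    val <- sum(w * (d - tgt)^2)
    if (val < trace_env$best) trace_env$best <- val
    trace_env$trace <- c(trace_env$trace, trace_env$best)
    val
  }
  starts <- rbind(
    rep(0, 6),
    c( 5, 0, 0, 0, 0, 0), c(-5, 0, 0, 0, 0, 0),
    c( 0, 5, 0, 0, 0, 0), c( 0, -5, 0, 0, 0, 0),
    c( 0, 0, 5, 0, 0, 0), c( 0, 0, -5, 0, 0, 0),
    c( 3, 3, 3, 0, 0, 0))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
         sum(fit$par^2) < sum(best$par^2))) {
      best <- fit
    }
  }
  tf2 <- param_to_transform(best$par, center)
  dimer2 <- apply_transform(dimer1, tf2)
  moved <- apply_transform(pm, tf2)
  final_d <- sqrt(rowSums((moved - dm)^2))
  r_rms <- sqrt(mean((final_d - tgt)^2))
  converged <- best$convergence == 0
  if (!converged) {
    warning("close_dimer: restraint optimizer did not converge within ",
            max_iter, " iterations", call. = FALSE)
  }
  dimer2 <- relabel_chains(dimer2, avoid = partial$dna_chains)
  assembled <- bind_rows(dna, dimer2)
  contact <- contact_surface(dimer2, dna)
  new_dock_model(assembled, partial$dna_chains, unique(dimer2$chain),
                 partial$helical, motif = partial$motif,
                 transforms = c(partial$transforms,
                                list(closure_step1 = step1$transform,
                                     closure_step2 = tf2)),
                 rmsd = step1$rmsd, contact = contact,
                 restraint_rms = r_rms, trace = trace_env$trace,
                 converged = converged, radii = partial$radii)
}

#' Rank docked models by contact surface
#'
#' Descending contact surface; ties broken by lower restraint rms, then by
#' input order.
#'
#' @param models a (possibly named) list of `dock_model` objects, each with
#'   a contact report.
#' @return The list reordered; `tidy()` on the result of [glance_models()]
#'   gives the table.
#' @export
rank_models <- function(models) {
  if (!length(models)) stop("rank_models: empty model list", call. = FALSE)
  stopifnot(all(vapply(models, inherits, logical(1), "dock_model")))
  cs <- vapply(models, function(m) {
    if (is.null(m$contact)) {
      stop("rank_models: model without contact report", call. = FALSE)
    }
    m$contact$cs
  }, numeric(1))
  rrms <- vapply(models, function(m) {
    if (is.na(m$restraint_rms)) Inf else m$restraint_rms
  }, numeric(1))
  ord <- order(-cs, rrms, seq_along(models))
  models[ord]
}

#' Summary table for a list of docked models
#'
#' @param models a (possibly named) list of `dock_model` objects.
#' @return A tibble with one row per model (`model`, `cs`,
#'   `restraint_rms`, `rmsd`, `converged`).
#' @export
glance_models <- function(models) {
  nm <- names(models)
  if (is.null(nm)) nm <- as.character(seq_along(models))
  bind_rows(lapply(seq_along(models), function(i) {
    g <- glance(models[[i]])
    g$model <- nm[i]
    g[, c("model", setdiff(names(g), "model"))]
  }))
}
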