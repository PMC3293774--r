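#' Helical parameters of an ideal duplex
#'
#' Canonical B-form defaults: rise 3.38 A per base pair and twist 36
#' degrees per base pair (10.0 bp/turn).  A 10.5 bp/turn helix is obtained
#' with `twist = 360/10.5`.  The axis is given by an anchor point and a
#' unit direction.
#'
#' @param rise rise per base pair, Angstrom (> 0).
#' @param twist twist per base pair, degrees (0 < twist <= 45).
#' @param axis_point a point on the helix axis.
#' @param axis_dir axis direction (normalised internally).
#' @return An object of class `helical_parameters`.
#' @export
helical_parameters <- function(rise = 3.38, twist = 36,
                               axis_point = c(0, 0, 0),
                               axis_dir = c(0, 0, 1)) {
  stopifnot(is.numeric(rise), length(rise) == 1, is.numeric(twist),
            length(twist) == 1)
  if (!(rise > 0)) stop("helical_parameters: rise must be > 0", call. = FALSE)
  if (!(twist > 0 && twist <= 45)) {
    stop("helical_parameters: twist must be in (0, 45] degrees", call. = FALSE)
  }
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  structure(list(rise = rise, twist = twist,
                 axis_point = as.numeric(axis_point),
                 axis_dir = as.numeric(axis_dir)),
            class = "helical_parameters")
}

#' @export
print.helical_parameters <- function(x, ...) {
  cat(sprintf("<helical_parameters> rise %.3f A/bp, twist %.2f deg/bp (%.2f bp/turn)\n",
              x$rise, x$twist, 360 / x$twist))
  invisible(x)
}

check_dna_seq <- function(seq) {
  if (length(seq) != 1 || !is.character(seq)) {
    stop("sequence must be a single string", call. = FALSE)
  }
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty sequence", call. = FALSE)
  if (grepl("[^ACGT]", s)) {
    stop("sequence contains characters outside {A,C,G,T}", call. = FALSE)
  }
  s
}

#' Sequence utilities
#'
#' `at_content()` is the fraction (A + T) / length; `revcomp()` the reverse
#' complement of the top strand.
#'
#' @param seq DNA sequence string over \{A,C,G,T\} (case-insensitive).
#' @return A fraction in \[0, 1\] (`at_content`) or a string (`revcomp`).
#' @examples
#' at_content("ATGC")  # 0.5
#' revcomp("AACG")     # "CGTT"
#' @export
at_content <- function(seq) {
  s <- check_dna_seq(seq)
  ch <- strsplit(s, "")[[1]]
  mean(ch %in% c("A", "T"))
}

#' @rdname at_content
#' @export
revcomp <- function(seq) {
  s <- check_dna_seq(seq)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Build an ideal B-DNA duplex
#'
#' Constructs a two-chain antiparallel duplex from the top-strand sequence.
#' Successive base-pair centroids (C1'-C1' midpoints) are separated by
#' `rise` along the axis and rotated by `twist`; every nucleotide carries
#' the standard sugar-phosphate atom names, with the phosphate group absent
#' from the 5'-terminal nucleotide of each strand.
#'
#' @param seq top strand, 5' to 3'.
#' @param params a [helical_parameters()] object.
#' @param chain_ids two chain identifiers, top then bottom strand.
#' @return A structure tibble.  Residue names are DA/DC/DG/DT; the bottom
#'   strand is numbered in its own 5' to 3' direction.
#' @examples
#' dna <- build_bdna("ATATGCATAT")
#' structure_sequence(dna, "A")
#' @export
build_bdna <- function(seq, params = helical_parameters(),
                       chain_ids = c("A", "B")) {
  s <- check_dna_seq(seq)
  stopifnot(inherits(params, "helical_parameters"), length(chain_ids) == 2)
  bases <- strsplit(s, "")[[1]]
  n <- length(bases)
  frame_tf <- axis_frame_transform(params)
  rows <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    step <- compose_transform(
      frame_tf,
      screw_about_z(params, i - 1))
    top <- nucleotide_local(bases[i], with_phosphate = i > 1)
    bot_base <- COMPLEMENT[[bases[i]]]
    bot <- nucleotide_local(bot_base, with_phosphate = i < n) %*% t(DYAD)
    rownames(bot) <- rownames(nucleotide_local(bot_base, with_phosphate = i < n))
    topg <- apply_transform(top, step)
    botg <- apply_transform(bot, step)
    rows[[2L * i - 1L]] <- tibble(
      record = "ATOM", atom = rownames(top),
      element = nucleotide_elements(rownames(top)),
      chain = chain_ids[1], resid = paste0("D", bases[i]), resno = i,
      insert = "", x = topg[, 1], y = topg[, 2], z = topg[, 3],
      occ = 1, b = 0, het = FALSE)
    rows[[2L * i]] <- tibble(
      record = "ATOM", atom = rownames(bot),
      element = nucleotide_elements(rownames(bot)),
      chain = chain_ids[2], resid = paste0("D", bot_base), resno = n - i + 1,
      insert = "", x = botg[, 1], y = botg[, 2], z = botg[, 3],
      occ = 1, b = 0, het = FALSE)
  }
  out <- bind_rows(rows)
  out <- out[order(match(out$chain, chain_ids),
                   ifelse(out$chain == chain_ids[1], out$resno, out$resno)), ]
  as_structure(out)
}

# screw transform about the canonical z axis (internal)
screw_about_z <- function(params, n_bp) {
  tf <- axis_rotation(c(0, 0, 1), n_bp * params$twist)
  rigid_transform(tf$R, tf$t + c(0, 0, n_bp * params$rise))
}

# transform mapping the canonical frame (axis = z through origin) onto the
# axis described by `params`
axis_frame_transform <- function(params) {
  u <- params$axis_dir
  z <- c(0, 0, 1)
  cr <- c(z[2] * u[3] - z[3] * u[2],
          z[3] * u[1] - z[1] * u[3],
          z[1] * u[2] - z[2] * u[1])
  d <- sum(z * u)
  if (sqrt(sum(cr^2)) < 1e-12) {
    R <- if (d > 0) diag(3) else diag(c(1, -1, -1))
  } else {
    ax <- cr / sqrt(sum(cr^2))
    ang <- acos(max(-1, min(1, d))) * 180 / pi
    R <- axis_rotation(ax, ang)$R
  }
  rigid_transform(R, params$axis_point)
}

#' Screw transform for an n-base-pair helical step
#'
#' The rigid motion relating a dimer placement to the same placement slid
#' `n_bp` base pairs along the helix: rotation by `n_bp * twist` about the
#' axis plus translation `n_bp * rise` along it.  `n_bp` may be fractional.
#' These transforms form a one-parameter group:
#' `helical_step(p, a+b) == compose_transform(helical_step(p, a), helical_step(p, b))`.
#'
#' @param params a [helical_parameters()] object.
#' @param n_bp number of base pairs (real).
#' @return A [rigid_transform()].
#' @export
helical_step <- function(params, n_bp) {
  stopifnot(inherits(params, "helical_parameters"), is.numeric(n_bp),
            length(n_bp) == 1)
  tf <- axis_rotation(params$axis_dir, n_bp * params$twist, params$axis_point)
  rigid_transform(tf$R, tf$t + n_bp * params$rise * params$axis_dir)
}

#' Base-pair centroids of a duplex
#'
#' Midpoints of the paired C1' atoms, pairing the i-th residue of the top
#' chain (resno order) with the (n - i + 1)-th of the bottom chain.
#'
#' @param s a structure tibble containing the duplex.
#' @param chains the two DNA chain ids, top then bottom; default: detected.
#' @return A tibble with `bp`, `x`, `y`, `z`.
#' @export
bp_centroids <- function(s, chains = NULL) {
  if (is.null(chains)) chains <- dna_chains(s)
  stopifnot(length(chains) == 2)
  c1 <- s[s$atom == "C1'" & s$chain == chains[1], ]
  c2 <- s[s$atom == "C1'" & s$chain == chains[2], ]
  c1 <- c1[order(c1$resno), ]
  c2 <- c2[order(-c2$resno), ]
  n <- min(nrow(c1), nrow(c2))
  tibble(bp = seq_len(n),
         x = (c1$x[1:n] + c2$x[1:n]) / 2,
         y = (c1$y[1:n] + c2$y[1:n]) / 2,
         z = (c1$z[1:n] + c2$z[1:n]) / 2)
}

#' Best-fit helix axis of a duplex
#'
#' Principal-axis line through the base-pair centroids, oriented from the
#' first to the last base pair.  For an ideal built duplex this recovers
#' the construction axis exactly.
#'
#' @inheritParams bp_centroids
#' @param params optional helical parameters whose rise/twist are kept.
#' @return A [helical_parameters()] object with the fitted axis.
#' @export
fit_helix_axis <- function(s, chains = NULL, params = helical_parameters()) {
  ctr <- bp_centroids(s, chains)
  m <- as.matrix(ctr[, c("x", "y", "z")])
  mu <- colMeans(m)
  sv <- svd(sweep(m, 2, mu))
  u <- sv$v[, 1]
  if (sum(u * (m[nrow(m), ] - m[1, ])) < 0) u <- -u
  helical_parameters(rise = params$rise, twist = params$twist,
                     axis_point = mu, axis_dir = u)
}

#' Thread a new sequence onto an existing duplex backbone
#'
#' Replaces the bases of a template duplex with a new sequence while
#' keeping every sugar-phosphate atom (P, OP1, OP2, O5', C5', C4', O4',
#' C3', O3', C2', C1') bit-identical to the template.  New base atoms are
#' taken from idealized planar base geometry and placed on the template
#' nucleotide's glycosidic frame (C1' position, glycosidic-bond direction,
#' base plane).  The bottom strand receives the complement.
#'
#' @param complex a structure tibble containing the duplex (protein chains,
#'   if any, are passed through untouched).
#' @param dna_chain_ids the two DNA chain ids, top then bottom strand.
#' @param new_seq replacement top-strand sequence; must match the template
#'   duplex length.
#' @return A structure tibble with threaded bases.
#' @export
thread_sequence <- function(complex, dna_chain_ids, new_seq) {
  s <- as_structure(complex)
  new_seq <- check_dna_seq(new_seq)
  stopifnot(length(dna_chain_ids) == 2)
  top <- s[s$chain == dna_chain_ids[1] & !s$het, ]
  bot <- s[s$chain == dna_chain_ids[2] & !s$het, ]
  n <- length(unique(top$resno))
  if (length(unique(bot$resno)) != n) {
    stop("thread_sequence: strands differ in length", call. = FALSE)
  }
  if (nchar(new_seq) != n) {
    stop(sprintf("thread_sequence: sequence length %d != duplex length %d",
                 nchar(new_seq), n), call. = FALSE)
  }
  bases <- strsplit(new_seq, "")[[1]]
  top_res <- sort(unique(top$resno))
  bot_res <- sort(unique(bot$resno), decreasing = TRUE)
  out <- s
  for (i in seq_len(n)) {
    out <- thread_one(out, dna_chain_ids[1], top_res[i], bases[i])
    out <- thread_one(out, dna_chain_ids[2], bot_res[i], COMPLEMENT[[bases[i]]])
  }
  as_structure(out)
}

thread_one <- function(s, chain, resno, base) {
  idx <- which(s$chain == chain & s$resno == resno & !s$het)
  res <- s[idx, ]
  label <- sprintf("%s/%d", chain, resno)
  if (!"C1'" %in% res$atom) {
    stop("thread_sequence: missing C1' in template nucleotide ", label,
         call. = FALSE)
  }
  gly_tmpl <- intersect(c("N9", "N1"), res$atom)[1]
  if (is.na(gly_tmpl)) {
    stop("thread_sequence: no glycosidic nitrogen in template nucleotide ",
         label, call. = FALSE)
  }
  base_rows <- res[!res$atom %in% BACKBONE_ATOMS, ]
  if (nrow(base_rows) < 3) {
    stop("thread_sequence: template base too incomplete in ", label,
         call. = FALSE)
  }
  f_t <- glyco_frame(
    c1 = unlist(res[res$atom == "C1'", c("x", "y", "z")]),
    ng = unlist(res[res$atom == gly_tmpl, c("x", "y", "z")]),
    centroid = colMeans(as.matrix(base_rows[, c("x", "y", "z")])))
  ideal <- nucleotide_local(base, with_phosphate = TRUE)
  ideal_base <- ideal[!rownames(ideal) %in% BACKBONE_ATOMS, , drop = FALSE]
  f_i <- glyco_frame(
    c1 = ideal["C1'", ], ng = ideal[glyco_atom(base), ],
    centroid = colMeans(ideal_base))
  M <- f_t$B %*% t(f_i$B)
  new_xyz <- sweep(ideal_base, 2, f_i$origin) %*% t(M)
  new_xyz <- sweep(new_xyz, 2, f_t$origin, "+")
  keep <- res[res$atom %in% BACKBONE_ATOMS, ]
  new_rows <- keep[rep(1, nrow(ideal_base)), ]
  new_rows$atom <- rownames(ideal_base)
  new_rows$element <- nucleotide_elements(rownames(ideal_base))
  new_rows$x <- new_xyz[, 1]; new_rows$y <- new_xyz[, 2]; new_rows$z <- new_xyz[, 3]
  repl <- bind_rows(keep, new_rows)
  repl$resid <- paste0("D", base)
  before <- s[seq_len(min(idx) - 1), ]
  after <- if (max(idx) < nrow(s)) s[(max(idx) + 1):nrow(s), ] else s[0, ]
  bind_rows(before, repl, after)
}

# orthonormal frame from C1', glycosidic N and base centroid
glyco_frame <- function(c1, ng, centroid) {
  e1 <- ng - c1
  e1 <- e1 / sqrt(sum(e1^2))
  v <- centroid - c1
  e2 <- v - sum(v * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(origin = c1, B = cbind(e1, e2, e3))
}
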