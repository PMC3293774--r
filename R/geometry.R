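# Idealized nucleotide geometry, constructed in code.
#
# Local base-pair frame: helix axis = z through the origin, base-pair plane
# = z = 0.  The two glycosidic C1' atoms sit at (0, -5.2, 0) (strand 1) and
# (0, +5.2, 0) (strand 2), so the C1'-C1' midpoint lies exactly on the
# axis; C1'-C1' = 10.4 A as in B-form DNA.  Strand 2 geometry is the dyad
# image (x, -y, -z) of strand-1 geometry, which makes the duplex
# antiparallel by construction.  Bases are planar rings with standard bond
# lengths (1.37-1.39 A ring bonds, 1.47 A glycosidic bond, 2.9 A
# Watson-Crick N1..N3 distance), placed by solving the two-anchor problem
# (glycosidic N position and Watson-Crick contact atom position).  The
# sugar-phosphate atoms use canonical B-DNA radial positions (P at ~9.7 A
# from the axis); inter-residue covalent geometry is approximate, which is
# irrelevant for the rigid-body and surface analyses this package performs.

GLYCO_ANGLE <- 55          # degrees, glycosidic bond tilt from the dyad
C1_HALF_SEP <- 5.2         # A, half the C1'-C1' separation
GLYCO_BOND <- 1.47         # A
WC_HBOND <- 2.9            # A, N1(purine)..N3(pyrimidine)

.geom_cache <- new.env(parent = emptyenv())

# regular polygon ring through two given adjacent-vertex anchors is not
# needed; rings are built in their own frame and rigidly mapped.

ring_polygon <- function(n, side, first_angle, center, dir = 1) {
  R <- side / (2 * sin(pi / n))
  k <- seq_len(n) - 1
  ang <- first_angle + dir * k * 2 * pi / n
  cbind(center[1] + R * cos(ang), center[2] + R * sin(ang))
}

# pyrimidine ring in glycosidic frame: N1 at origin, N3 on +x axis.
pyrimidine_ring <- function() {
  side <- 1.38
  Rc <- side                      # hexagon circumradius = side
  d13 <- 2 * side * sin(pi / 3)   # N1..N3 chord (two vertices apart)
  # center below the N1-N3 axis; handedness fixed, mirror applied later
  cx <- d13 / 2
  cy <- -sqrt(Rc^2 - cx^2)
  th0 <- atan2(0 - cy, 0 - cx)
  v <- ring_polygon(6, side, th0, c(cx, cy), dir = 1)
  # check N3 landed on (d13, 0); otherwise wind the other way
  if (sum((v[3, ] - c(d13, 0))^2) > 1e-6) {
    v <- ring_polygon(6, side, th0, c(cx, cy), dir = -1)
  }
  rownames(v) <- c("N1", "C2", "N3", "C4", "C5", "C6")
  v
}

# purine ring system in glycosidic frame: N9 at origin, N1 on +x axis.
purine_ring <- function() {
  side5 <- 1.37
  R5 <- side5 / (2 * sin(pi / 5))
  c5 <- c(R5, 0)
  th0 <- pi
  pent <- ring_polygon(5, side5, th0, c5, dir = 1)
  rownames(pent) <- c("N9", "C8", "N7", "C5", "C4")
  # hexagon fused on the C4-C5 edge, bulging away from the pentagon center
  M <- (pent["C4", ] + pent["C5", ]) / 2
  nvec <- M - c5
  nvec <- nvec / sqrt(sum(nvec^2))
  side6 <- sqrt(sum((pent["C4", ] - pent["C5", ])^2))
  apo <- side6 * sqrt(3) / 2
  c6 <- M + apo * nvec
  thC4 <- atan2(pent["C4", 2] - c6[2], pent["C4", 1] - c6[1])
  hex <- ring_polygon(6, side6, thC4, c6, dir = 1)
  # hexagon order from C4 must run C4, N3, C2, N1, C6, C5
  if (sum((hex[6, ] - pent["C5", ])^2) > 1e-6) {
    hex <- ring_polygon(6, side6, thC4, c6, dir = -1)
  }
  rownames(hex) <- c("C4", "N3", "C2", "N1", "C6", "C5")
  v <- rbind(pent, hex[c("N3", "C2", "N1", "C6"), ])
  # rotate so N1 lies on the +x axis from N9 (origin)
  a <- atan2(v["N1", 2], v["N1", 1])
  rot <- matrix(c(cos(-a), sin(-a), -sin(-a), cos(-a)), 2, 2)
  v %*% t(rot) -> v2
  rownames(v2) <- rownames(v)
  v2
}

add_substituent <- function(ring, host, center, name, bond) {
  u <- ring[host, ] - center
  u <- u / sqrt(sum(u^2))
  pos <- ring[host, ] + bond * u
  out <- rbind(ring, pos)
  rownames(out)[nrow(out)] <- name
  out
}

ring_center <- function(ring, names) colMeans(ring[names, , drop = FALSE])

# full planar base in glycosidic 2D frame (glyco N at origin, WC atom on +x)
base_atoms_2d <- function(base) {
  key <- paste0("base2d_", base)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  if (base %in% c("A", "G")) {
    v <- purine_ring()
    c6c <- ring_center(v, c("C4", "N3", "C2", "N1", "C6", "C5"))
    if (base == "A") {
      v <- add_substituent(v, "C6", c6c, "N6", 1.34)
    } else {
      v <- add_substituent(v, "C6", c6c, "O6", 1.23)
      v <- add_substituent(v, "C2", c6c, "N2", 1.34)
    }
  } else {
    v <- pyrimidine_ring()
    cc <- ring_center(v, rownames(v))
    v <- add_substituent(v, "C2", cc, "O2", 1.23)
    if (base == "C") {
      v <- add_substituent(v, "C4", cc, "N4", 1.34)
    } else {
      v <- add_substituent(v, "C4", cc, "O4", 1.23)
      v <- add_substituent(v, "C5", cc, "C7", 1.50)
    }
  }
  .geom_cache[[key]] <- v
  v
}

glyco_atom <- function(base) if (base %in% c("A", "G")) "N9" else "N1"
wc_atom <- function(base) if (base %in% c("A", "G")) "N1" else "N3"

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

# Watson-Crick anchor solution in the base-pair frame (strand 1).
# Returns glycosidic N and WC-atom targets for a strand-1 base.
wc_anchors <- function(base) {
  gl <- GLYCO_ANGLE * pi / 180
  Ng1 <- c(GLYCO_BOND * sin(gl), -C1_HALF_SEP + GLYCO_BOND * cos(gl))
  L <- 2 * abs(Ng1[2])                       # Ng1 .. Ng2 distance (along y)
  d_pu <- sqrt(sum((base_atoms_2d("A")[wc_atom("A"), ])^2))
  d_py <- sqrt(sum((base_atoms_2d("C")[wc_atom("C"), ])^2))
  cc <- L - WC_HBOND
  a <- (cc + (d_pu^2 - d_py^2) / cc) / 2
  h <- sqrt(d_pu^2 - a^2)
  if (base %in% c("A", "G")) {
    wc <- c(Ng1[1] + h, Ng1[2] + a)
  } else {
    # partner purine sits on strand 2; our N3 faces it across the H-bond
    wc <- c(Ng1[1] + h, -Ng1[2] - a - WC_HBOND)
  }
  list(Ng = Ng1, wc = wc)
}

# place a 2D base into the base-pair plane by its two anchors; `mirror`
# fixes the ring on the chosen side of the glycosidic-WC axis.
place_base <- function(base, mirror = TRUE) {
  v <- base_atoms_2d(base)
  if (mirror) v[, 2] <- -v[, 2]
  an <- wc_anchors(base)
  d <- sqrt(sum((v[wc_atom(base), ])^2))
  u <- (an$wc - an$Ng) / sqrt(sum((an$wc - an$Ng)^2))
  a <- atan2(u[2], u[1])
  rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  out <- v %*% t(rot)
  out <- sweep(out, 2, an$Ng, "+")
  rownames(out) <- rownames(v)
  out
}

SUGAR_PHOSPHATE <- local({
  m <- rbind(
    "C1'" = c( 0.0, -5.2,  0.0),
    "C2'" = c( 1.4, -5.9, -0.3),
    "C3'" = c( 1.2, -7.4, -0.1),
    "O3'" = c( 2.0, -8.2,  0.7),
    "C4'" = c(-0.3, -7.5,  0.2),
    "O4'" = c(-0.8, -6.2,  0.5),
    "C5'" = c(-1.0, -8.5, -0.7),
    "O5'" = c(-0.9, -9.3, -1.9),
    "P"   = c( 0.3, -9.7, -2.6),
    "OP1" = c( 1.5, -10.5, -2.3),
    "OP2" = c(-0.4, -10.8, -3.2))
  m
})

BACKBONE_ATOMS <- rownames(SUGAR_PHOSPHATE)

# full strand-1 nucleotide in the base-pair frame (z = 0 plane for the base)
nucleotide_local <- function(base, with_phosphate = TRUE) {
  key <- paste0("nt_", base, "_", with_phosphate)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  bb <- SUGAR_PHOSPHATE
  if (!with_phosphate) bb <- bb[!rownames(bb) %in% c("P", "OP1", "OP2"), ]
  b2 <- place_base(base)
  base3 <- cbind(b2, 0)
  rownames(base3) <- rownames(b2)
  out <- rbind(bb, base3)
  .geom_cache[[key]] <- out
  out
}

nucleotide_elements <- function(atom_names) {
  substr(gsub("[^A-Za-z]", "", atom_names), 1, 1)
}

DYAD <- diag(c(1, -1, -1))   # 180 degree rotation about the local x axis
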