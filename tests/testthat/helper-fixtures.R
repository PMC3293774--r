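# shared fixtures, built in code (no stored data)

fx <- new.env()

fx_template <- function() {
  if (is.null(fx$template)) fx$template <- make_template_complex()
  fx$template
}

fx_dna10 <- function() {
  if (is.null(fx$dna10)) fx$dna10 <- build_bdna("ATGCATGCAT")
  fx$dna10
}

# a deterministic cloud of points that is not collinear or planar
point_cloud <- function(n, seed = 42) {
  withr::with_seed(seed, matrix(stats::rnorm(3 * n), n, 3))
}

random_rotation <- function(seed = 1) {
  withr::with_seed(seed, {
    ax <- stats::rnorm(3)
    axis_rotation(ax / sqrt(sum(ax^2)), stats::runif(1, 10, 170))
  })
}

pairwise_dists <- function(s) as.numeric(dist(as.matrix(s[, c("x", "y", "z")])))

# analytic SASA of two spheres with expanded radii R1, R2 at centre distance d
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  if (d + min(R1, R2) <= max(R1, R2)) return(4 * pi * max(R1, R2)^2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  4 * pi * (R1^2 + R2^2) - 2 * pi * (R1 * h1 + R2 * h2)
}

one_atom <- function(x = 0, y = 0, z = 0, element = "C", chain = "A",
                     resno = 1) {
  as_structure(data.frame(atom = element, chain = chain, resid = "DUM",
                          resno = resno, x = x, y = y, z = z,
                          element = element))
}

atom_grid <- function(nx, ny, spacing, chain = "A") {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  as_structure(data.frame(atom = "C", chain = chain, resid = "DUM",
                          resno = seq_len(nrow(g)),
                          x = g$x * spacing, y = g$y * spacing, z = 0,
                          element = "C"))
}

reference_data_path <- function(file) {
  system.file("extdata", "reference", file, package = "furdock")
}
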