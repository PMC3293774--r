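test_that("motif_spec validates ranges and recognition helix", {
  el <- data.frame(element = c("H4", "S1", "S2"), chain = "A",
                   start = c(44, 61, 68), end = c(57, 65, 72))
  expect_s3_class(motif_spec(el), "motif_spec")
  bad <- el; bad$start[2] <- 50
  expect_error(motif_spec(bad), "overlapping")
  expect_error(motif_spec(el, recognition = "H9"), "recognition")
})

test_that("template criteria: all pass on the synthetic template", {
  rep <- check_template_criteria(fx_template())
  expect_true(all(rep$pass))
  expect_true(attr(rep, "overall"))
})

test_that("template criteria fail individually as constructed", {
  # short duplex -> criterion 1
  short <- make_template_complex(dna_seq = "TATAATTTAAATATTTAA")  # 18 bp
  r1 <- check_template_criteria(short)
  expect_false(r1$pass[1])
  expect_false(attr(r1, "overall"))
  # heterodimer -> criterion 2
  tm <- fx_template()
  s <- tm$structure
  s$resid[s$chain == "B" & s$resno == 5] <- "GLY"
  het <- template_complex(s, tm$motif, tm$dna_chains, tm$protein_chains,
                          resolution = tm$resolution)
  r2 <- check_template_criteria(het)
  expect_false(r2$pass[2])
  # single strand after the recognition helix -> criterion 3
  nowing <- make_template_complex(wing = FALSE)
  r3 <- check_template_criteria(nowing)
  expect_false(r3$pass[3])
  # poor resolution -> criterion 4
  blurry <- make_template_complex(resolution = 3.4)
  r4 <- check_template_criteria(blurry)
  expect_false(r4$pass[4])
})

test_that("fitting the template's own monomer gives the identity", {
  tm <- fx_template()
  monoA <- tm$structure[tm$structure$chain == "A", ]
  fit <- fit_monomer(monoA, tm$motif, tm, "H4S1S2")
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$transforms$fit$R, diag(3), tolerance = 1e-9)
})

test_that("fit_monomer recovers a known displacement for both motif types", {
  tm <- fx_template()
  monoA <- tm$structure[tm$structure$chain == "A", ]
  tf0 <- rigid_transform(random_rotation(17)$R, c(8, -12, 5))
  displaced <- apply_transform(monoA, tf0)
  for (type in c("H4S1S2", "H3H4S1S2")) {
    fit <- fit_monomer(displaced, tm$motif, tm, type)
    expect_lt(fit$rmsd, 1e-6)
    # the recovered transform must be the inverse of the displacement
    rt <- compose_transform(fit$transforms$fit, tf0)
    expect_equal(rt$R, diag(3), tolerance = 1e-6)
    expect_equal(rt$t, c(0, 0, 0), tolerance = 1e-6)
    # rigidity of the placement
    placed <- fit$structure[fit$structure$chain %in% fit$protein_chains, ]
    expect_equal(pairwise_dists(placed), pairwise_dists(displaced),
                 tolerance = 1e-9)
  }
})

test_that("fit_monomer errors on unresolvable motif ranges", {
  tm <- fx_template()
  monoA <- tm$structure[tm$structure$chain == "A", ]
  off <- motif_spec(data.frame(element = c("H4", "S1", "S2"), chain = "A",
                               start = c(200, 220, 230),
                               end = c(210, 224, 234)))
  expect_error(fit_monomer(monoA, off, tm), "no backbone atoms")
})

test_that("closing an already-satisfying dimer is the identity refinement", {
  tm <- fx_template()
  monoA <- tm$structure[tm$structure$chain == "A", ]
  fit <- fit_monomer(monoA, tm$motif, tm, "H4S1S2")
  dimer <- tm$structure[tm$structure$chain %in% c("A", "B"), ]
  restr <- default_restraints(tm)
  closed <- close_dimer(fit, dimer, tm$motif, restr)
  expect_lt(closed$restraint_rms, 1e-6)
  expect_true(closed$converged)
  expect_false(is.unsorted(rev(closed$trace)))  # monotone descent log
  expect_s3_class(closed$contact, "contact_report")
})

test_that("closure recovers a small displacement to low restraint rms", {
  tm <- fx_template()
  monoA <- tm$structure[tm$structure$chain == "A", ]
  fit <- fit_monomer(monoA, tm$motif, tm, "H4S1S2")
  dimer <- tm$structure[tm$structure$chain %in% c("A", "B"), ]
  restr <- default_restraints(tm)
  nudged <- apply_transform(dimer, axis_rotation(c(0, 1, 0), 4,
                                                 point = c(0, 0, 40)))
  closed <- close_dimer(fit, nudged, tm$motif, restr)
  expect_lt(closed$restraint_rms, 0.1)
  # the dimer interface moved only rigidly
  placed <- closed$structure[closed$structure$chain %in% closed$protein_chains, ]
  expect_equal(pairwise_dists(placed), pairwise_dists(dimer),
               tolerance = 1e-9)
})

test_that("closure demands at least three restraints", {
  tm <- fx_template()
  restr <- default_restraints(tm)
  expect_error(restraint_set(restr[1:2, ]), "3 restraints")
})

test_that("restraint targets must be positive", {
  tm <- fx_template()
  r <- default_restraints(tm)
  r$target[1] <- -2
  expect_error(restraint_set(as.data.frame(r)), "positive")
})

test_that("repeated fits are bit-identical (no randomness anywhere)", {
  tm <- make_template_complex()
  monoA <- tm$structure[tm$structure$chain == "A", ]
  tf0 <- rigid_transform(random_rotation(23)$R, c(-3, 6, 1))
  displaced <- apply_transform(monoA, tf0)
  f1 <- fit_monomer(displaced, tm$motif, tm, "H3H4S1S2")
  f2 <- fit_monomer(displaced, tm$motif, tm, "H3H4S1S2")
  expect_identical(f1$rmsd, f2$rmsd)
  expect_identical(as.data.frame(f1$structure), as.data.frame(f2$structure))
})

test_that("models rank by contact surface with deterministic tie-breaks", {
  mk <- function(cs, rms = NA_real_) {
    m <- furdock:::new_dock_model(one_atom(), "X", "A",
                                  helical_parameters())
    m$contact <- structure(list(sasa_rec = 0, sasa_lig = 0, sasa_cplx = 0,
                                cs = cs), class = "contact_report")
    m$restraint_rms <- rms
    m
  }
  # contact surfaces of the four H4S1S2 template fits: best is 1006
  fits <- list(`1C0W` = mk(900), `1SAX` = mk(890), `1U8R` = mk(949),
               `1Z9C` = mk(1006))
  ranked <- rank_models(fits)
  expect_equal(names(ranked)[1], "1Z9C")
  expect_equal(names(ranked), c("1Z9C", "1U8R", "1C0W", "1SAX"))
  # contact surfaces of the three closed models
  closed <- list(a = mk(1852), b = mk(1083), c = mk(1230))
  expect_equal(names(rank_models(closed)), c("a", "c", "b"))
  # ties break on restraint rms, then input order
  tied <- list(p = mk(500, 2), q = mk(500, 1), r = mk(500, 2))
  expect_equal(names(rank_models(tied)), c("q", "p", "r"))
  expect_equal(names(rank_models(list(z = mk(1)))), "z")
  expect_error(rank_models(list()), "empty")
})
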