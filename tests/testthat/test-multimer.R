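seq70 <- strrep("ATGCATG", 10)

test_that("offset 0 places a coincident copy; full turn is a pure translation", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5), strrep("AT", 20))
  prot <- m$structure[m$structure$chain %in% m$protein_chains, ]
  at0 <- place_dimer_at_offset(m, 0)
  copy0 <- at0[at0$chain %in% attr(at0, "copy_chains"), ]
  expect_equal(rmsd(copy0[, c("x", "y", "z")], prot[, c("x", "y", "z")]), 0,
               tolerance = 1e-9)
  at10 <- place_dimer_at_offset(m, 10)
  copy10 <- at10[at10$chain %in% attr(at10, "copy_chains"), ]
  delta <- as.matrix(copy10[, c("x", "y", "z")]) -
    as.matrix(prot[, c("x", "y", "z")])
  expect_equal(max(abs(sweep(delta, 2, colMeans(delta)))), 0,
               tolerance = 1e-9)
  expect_equal(unname(colMeans(delta)), c(0, 0, 33.8), tolerance = 1e-9)
})

test_that("screw additivity: offset a then b equals offset a+b", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5), strrep("AT", 20))
  prot <- m$structure[m$structure$chain %in% m$protein_chains, ]
  s1 <- apply_transform(prot, helical_step(m$helical, 4))
  s2 <- apply_transform(s1, helical_step(m$helical, 7))
  direct <- apply_transform(prot, helical_step(m$helical, 11))
  expect_equal(as.matrix(s2[, c("x", "y", "z")]),
               as.matrix(direct[, c("x", "y", "z")]), tolerance = 1e-9)
})

test_that("offsets past the DNA end are rejected", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5), strrep("AT", 12))
  expect_error(place_dimer_at_offset(m, 30), "past the DNA end")
  expect_error(scan_spacings(m, 30), "capacity")
})

test_that("spacing scan classification is threshold-consistent at every offset", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5, envelope = "sphere-pair",
                                             sphere_radius = 12),
                              strrep("AT", 35))
  sc <- scan_spacings(m, 25, dna_overlap = FALSE)
  expect_equal(nrow(sc), 25)
  expect_true(all(sc$class %in% c("clash", "contact", "separated")))
  for (i in seq_len(nrow(sc))) {
    if (sc$class[i] == "clash") {
      expect_gt(sc$n_clash[i], 0)
    } else if (sc$class[i] == "contact") {
      expect_equal(sc$n_clash[i], 0)
      expect_gte(sc$cs_dd[i], attr(sc, "cs_min"))
    } else {
      expect_equal(sc$n_clash[i], 0)
      expect_lt(sc$cs_dd[i], attr(sc, "cs_min"))
    }
  }
})

test_that("sphere-pair scan matches the closed-form sphere geometry", {
  rs <- 12; probe <- 1.4
  m <- make_toy_dimer_complex(toy_dimer_spec(5, envelope = "sphere-pair",
                                             sphere_radius = rs),
                              strrep("AT", 35))
  sc <- scan_spacings(m, 25, dna_overlap = FALSE)
  prot <- m$structure[m$structure$chain %in% m$protein_chains, ]
  p <- as.matrix(prot[, c("x", "y", "z")])
  R <- rs + probe
  for (s in 1:25) {
    q <- apply_transform(p, helical_step(m$helical, s))
    dd <- as.matrix(dist(rbind(p, q)))[1:2, 3:4]
    cs_analytic <- sum(vapply(as.numeric(dd), function(d) {
      if (d < 2 * R) 2 * pi * R * (R - d / 2) else 0
    }, numeric(1)))
    class_analytic <- if (min(dd) < 2 * rs - 0.5) "clash"
      else if (cs_analytic >= 1) "contact" else "separated"
    expect_equal(sc$class[s], class_analytic,
                 label = sprintf("class at offset %d", s))
    if (cs_analytic > 0) {
      expect_equal(sc$cs_dd[s], cs_analytic, tolerance = 0.02,
                   label = sprintf("CS at offset %d", s))
    } else {
      expect_lt(abs(sc$cs_dd[s]), 1)
    }
  }
})

test_that("convex toy dimers have a monotone separated tail", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5, envelope = "sphere-pair",
                                             sphere_radius = 9),
                              strrep("AT", 35))
  sc <- scan_spacings(m, 25, dna_overlap = FALSE)
  # beyond the last clash/contact offset everything stays separated
  active <- which(sc$class != "separated")
  if (length(active)) {
    expect_true(all(sc$class[(max(active) + 1):nrow(sc)] == "separated"))
  }
})

test_that("assembling [0, s] reproduces the scan metrics at s", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5, envelope = "sphere-pair",
                                             sphere_radius = 9),
                              strrep("AT", 30))
  sc <- scan_spacings(m, 8, dna_overlap = FALSE)
  mm <- build_multimer(m, c(0, 8), surfaces = TRUE)
  expect_equal(mm$pair_cs$cs_dd, sc$cs_dd[8], tolerance = 1e-9)
})

test_that("multimers assemble when clash-free and refuse clashing offsets", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5, envelope = "sphere-pair",
                                             sphere_radius = 9),
                              strrep("AT", 40))
  mm <- build_multimer(m, c(0, 3, 6), surfaces = FALSE)
  expect_equal(length(unique(mm$copies$chains)), 3)
  expect_equal(mm$offsets, c(0, 3, 6))
  # offsets colliding head-on are refused with the pair named
  expect_error(build_multimer(m, c(0, 1), surfaces = FALSE), "0 and 1")
  expect_error(build_multimer(m, c(0, 0)), "strictly increasing")
  expect_error(build_multimer(m, c(1, 2)), "start at 0")
})

test_that("seven dimers at 6 bp spacing fit on a long duplex", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5, envelope = "sphere-pair",
                                             sphere_radius = 9),
                              strrep("ATGCAT", 14))
  mm <- build_multimer(m, seq(0, 36, by = 6), surfaces = FALSE)
  expect_equal(nrow(mm$copies), 7)
  expect_equal(length(unique(unlist(strsplit(mm$copies$chains, ",")))), 14)
})

test_that("footprint span arithmetic is exact", {
  expect_identical(multimer_footprint_span(c(0, 3, 6), 21), 27L)
  expect_identical(multimer_footprint_span(c(0, 6, 12), 21), 33L)
  expect_identical(multimer_footprint_span(0, 21), 21L)
  # property: span = footprint + range for assorted offset sets
  for (off in list(c(0, 5), c(0, 2, 4, 8), c(0, 6, 12, 18, 24, 30, 36))) {
    for (w in c(1, 7, 21)) {
      expect_identical(multimer_footprint_span(off, w),
                       as.integer(w + max(off)))
    }
  }
  expect_error(multimer_footprint_span(integer(0), 21), "empty")
  expect_error(multimer_footprint_span(c(0, 3, 3), 21), "ascending")
  expect_error(multimer_footprint_span(c(3, 6), 21), "start at 0")
})

test_that("switch report flags genes whose boxes the footprint covers", {
  ann <- data.frame(
    gene = c("left", "right"), strand = c("-", "+"), tss = c(90, 133),
    m10_start = c(96, 120), m10_end = c(101, 125),
    m35_start = c(70, 140), m35_end = c(75, 145))
  # hexamer at offsets 0/3/6, 21 bp dimer footprint, first protected bp 100:
  # protected interval spans multimer_footprint_span(c(0,3,6), 21) = 27 bp
  span <- multimer_footprint_span(c(0, 3, 6), 21)
  both <- switch_report(c(100, 100 + span - 1), ann)
  expect_equal(both$verdict, c("blocked", "blocked"))
  none <- switch_report(c(30, 50), ann)
  expect_equal(none$verdict, c("free", "free"))
  # removing the left-end dimer (offset 0) shifts the protected start to
  # bp 103 and frees the left gene only: the transcriptional switch
  minus_left <- switch_report(c(103, 100 + span - 1), ann)
  expect_equal(minus_left$verdict, c("free", "blocked"))
  expect_error(switch_report(c(10, 5), ann), "start exceeds end")
  bad <- ann; bad$strand[1] <- "x"
  expect_error(switch_report(c(1, 10), bad), "strand")
})

test_that("DNA overlapped surface plateaus near twice the single-dimer burial", {
  m <- make_toy_dimer_complex(toy_dimer_spec(5), strrep("AT", 25),
                              n_points = 240)
  single <- sum(m$footprint$by_bp$buried_top + m$footprint$by_bp$buried_bottom)
  sc <- scan_spacings(m, 14, dna_overlap = TRUE, n_points = 240)
  tail_vals <- sc$dna_overlap[sc$offset >= 8]   # well past the contact regime
  expect_true(all(abs(tail_vals / (2 * single) - 1) < 0.05))
  # and never increases by more than sampling noise as the offset grows there
  expect_true(all(diff(tail_vals) < 0.05 * 2 * single))
})
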