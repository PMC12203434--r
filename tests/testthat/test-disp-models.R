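test_that("coordination numbers match direct evaluation of the counting function", {
  # isolated atom: empty sum
  expect_equal(coordination_number(molecule("C", c(0, 0, 0))), 0)

  # far pair: essentially zero
  far <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 100)))
  expect_lt(max(coordination_number(far)), 1e-6)

  # H2 at the bond distance: independent evaluation of the logistic count
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  rcov_h <- 0.32
  cn_expected <- 1 / (1 + exp(-16 * ((4 / 3) * (2 * rcov_h) / 0.74 - 1)))
  expect_equal(coordination_number(h2), rep(cn_expected, 2),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("london_c6 reproduces the combination formula", {
  # identical atoms: (3/4) alpha^2 I in internal units
  a <- 1.674; i <- 11.2603
  bohr3 <- 1.8897261254578281^3
  expect_equal(london_c6(a, a, i, i),
               0.75 * (a * bohr3)^2 * (i / 27.211386245988),
               tolerance = 1e-12)

  # zero polarizability kills the coefficient
  expect_equal(london_c6(0, a, i, i), 0)

  # H-H from packaged constants vs direct evaluation
  aH <- polarizability("H"); iH <- ionization_energy("H")
  expected <- 1.5 * (aH * bohr3) * (aH * bohr3) *
    ((iH / 27.211386245988)^2 / (2 * iH / 27.211386245988))
  expect_equal(london_c6(aH, aH, iH, iH), expected, tolerance = 1e-12)
})

test_that("c6 interpolation respects its reference points and symmetry", {
  # single-reference element: any CN returns that C6
  ref <- adld_params()$c6_reference
  ne_c6 <- ref$c6_ref_au[ref$element == "Ne"]
  for (cn in c(0, 1.3, 7)) {
    expect_equal(c6_interpolated("Ne", "Ne", cn, cn), ne_c6)
  }

  # at a reference point with well-separated neighbours, the weight mass
  # concentrates there (brute-force weight evaluation)
  c6_at_ref <- c6_interpolated("C", "C", 3.984, 3.984)
  expect_lt(abs(c6_at_ref - 18.21) / 18.21, 0.01)

  # swap symmetry to near machine precision
  for (case in list(c(0.4, 2.7), c(1.1, 3.3), c(0, 0.9))) {
    expect_equal(c6_interpolated("C", "N", case[1], case[2]),
                 c6_interpolated("N", "C", case[2], case[1]),
                 tolerance = 1e-14)
  }

  expect_error(c6_interpolated("Xx", "C", 0, 0), "reference")
})

test_that("BJ-damped pair energy has the documented closed form and limits", {
  damp <- damping_preset("pbe0")

  # zero numerators
  expect_equal(pair_energy_bj(0, 0, 3.0, damp), 0)

  # long-range: damping is negligible, leaving the bare C6 asymptote
  c6 <- 30; c8 <- 3 * c6 * sqrt((0.5 * sqrt(6) * 7.8715)^2)
  r <- 40
  rb <- r * 1.8897261254578281
  undamped_c6 <- -damp$s6 * c6 / rb^6 * 627.5094740631
  expect_lt(abs((pair_energy_bj(c6, 0, r, damp) - undamped_c6) /
                  undamped_c6), 1e-3)
  # with C8 included the full undamped two-term form is the asymptote
  undamped_both <- undamped_c6 - damp$s8 * c8 / rb^8 * 627.5094740631
  e <- pair_energy_bj(c6, c8, r, damp)
  expect_lt(abs((e - undamped_both) / undamped_both), 1e-3)

  # one printed parameter set at r = 3 A vs independent hand evaluation
  rb3 <- 3.0 * 1.8897261254578281
  f0 <- damp$a1 * sqrt(c8 / c6) + damp$a2
  expected <- (-damp$s6 * c6 / (rb3^6 + f0^6) -
                 damp$s8 * c8 / (rb3^8 + f0^8)) * 627.5094740631
  expect_equal(pair_energy_bj(c6, c8, 3.0, damp), expected, tolerance = 1e-13)

  # finite at r -> 0
  expect_true(is.finite(pair_energy_bj(c6, c8, 1e-9, damp)))

  expect_error(damping_preset("nosuch"), "unknown damping preset")
})

test_that("total dispersion equals the brute-force pair sum for both engines", {
  # no pairs
  single <- molecule("Ne", c(0, 0, 0))
  res <- total_dispersion(single)
  expect_equal(res$total, 0)
  expect_equal(dim(res$pairs), c(1L, 1L))

  # diatomic: total is the one pair energy
  ne2 <- molecule(c("Ne", "Ne"), rbind(c(0, 0, 0), c(0, 0, 3.1)))
  for (engine in c("london", "cnd")) {
    res <- total_dispersion(ne2, engine = engine)
    expect_identical(res$total, res$pairs[1, 2])
    expect_lt(res$total, 0)  # stabilizing
  }

  # random clusters: O(N^2) double-loop oracle at 1e-12 relative
  for (engine in c("london", "cnd")) {
    m <- make_cluster(50, "C", seed = 5)
    res <- total_dispersion(m, engine = engine)
    expect_rel_equal(res$total, total_oracle(res$pairs), 1e-12)
    expect_equal(res$pairs, t(res$pairs))
    expect_true(all(diag(res$pairs) == 0))
  }

  expect_error(total_dispersion(ne2, charges = c(0, 0, 0)),
               "charges vector length")
})

test_that("total dispersion is invariant under rigid motions", {
  m <- make_cluster(10, "C", seed = 3)
  for (engine in c("london", "cnd")) {
    e0 <- total_dispersion(m, engine = engine)$total
    set.seed(99)
    for (k in 1:5) {
      m2 <- transform_molecule(m, random_rotation(), rnorm(3, sd = 20))
      expect_lt(abs(total_dispersion(m2, engine = engine)$total - e0), 1e-10)
    }
  }
})

test_that("pair energies decay as R^-6 at long range (London engine)", {
  for (R in c(20, 30)) {
    e1 <- total_dispersion(molecule(c("Ne", "Ne"),
                                    rbind(c(0, 0, 0), c(0, 0, R))),
                           engine = "london")$total
    e2 <- total_dispersion(molecule(c("Ne", "Ne"),
                                    rbind(c(0, 0, 0), c(0, 0, 2 * R))),
                           engine = "london")$total
    expect_lt(abs(e2 / e1 - 2^-6) / 2^-6, 1e-3)
  }
})

test_that("the charge scaler obeys its contract", {
  s <- exponential_charge_scaler()
  v <- 42.5
  # exact identity at q = 0
  expect_identical(s$scale(v, 0), v)
  # strictly decreasing for positive q, strictly positive output
  qs <- c(0.1, 0.5, 1, 2)
  vals <- vapply(qs, function(q) s$scale(v, q), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0))
  # calibration: q = +1 reproduces the packaged Li+ polarizability
  expect_equal(s$scale(polarizability("Li"), 1), polarizability("Li+"),
               tolerance = 1e-12)
})

test_that("charge sweep: identity at q=0 and monotone loss of dispersion with charge", {
  ring <- make_ring(6, "C", 1.39)
  m <- molecule(c(ring$element, "Li"), rbind(ring$xyz, c(0, 0, 2.0)))

  for (engine in c("london", "cnd")) {
    res0 <- total_dispersion(m, engine = engine)
    # scaler at q = 0 is bitwise identical to the uncharged run
    resq0 <- total_dispersion(m, engine = engine,
                              charges = rep(0, n_atoms(m)))
    expect_identical(res0$total, resq0$total)
    expect_identical(res0$pairs, resq0$pairs)

    sw <- charge_sweep(m, 7, c(0, 0.25, 0.5, 1.0), engine = engine)
    expect_equal(sw$eps_kcalmol[1],
                 atomic_contributions(res0)$eps[7])
    # |eps_Li| strictly decreasing with q; verified pointwise against
    # direct recomputation
    expect_true(all(diff(abs(sw$eps_kcalmol)) < 0))
    for (i in seq_len(nrow(sw))) {
      q <- rep(0, n_atoms(m)); q[7] <- sw$q[i]
      direct <- atomic_contributions(
        total_dispersion(m, engine = engine, charges = q))$eps[7]
      expect_identical(sw$eps_kcalmol[i], direct)
    }
  }

  # degenerate single-point grid
  sw1 <- charge_sweep(m, 7, 0.5)
  expect_equal(nrow(sw1), 1)
  expect_error(charge_sweep(m, 99, 0), "out of range")
})

test_that("engines without charges are charge-blind by construction", {
  # the geometry-only path never consults atomic charge fields
  ring <- make_ring(6, "C", 1.39)
  m1 <- molecule(c(ring$element, "Li"), rbind(ring$xyz, c(0, 0, 2.0)))
  m2 <- molecule(c(ring$element, "Li"), rbind(ring$xyz, c(0, 0, 2.0)),
                 charge = c(rep(0, 6), 1))
  expect_identical(total_dispersion(m1)$total, total_dispersion(m2)$total)
})
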