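test_that("atomic contributions are the half-sum of pair energies", {
  # homonuclear diatomic: each atom gets half of the one pair energy
  ne2 <- molecule(c("Ne", "Ne"), rbind(c(0, 0, 0), c(0, 0, 3.1)))
  res <- total_dispersion(ne2)
  acs <- atomic_contributions(res)
  expect_equal(acs$eps, rep(res$total / 2, 2))
  expect_identical(acs$total, sum(acs$eps))

  # single atom: empty sum
  acs1 <- atomic_contributions(total_dispersion(molecule("C", c(0, 0, 0))))
  expect_equal(acs1$eps, 0)
  expect_equal(acs1$total, 0)

  # invalid matrices are rejected
  expect_error(atomic_contributions(matrix(1, 2, 3)), "square")
  expect_error(atomic_contributions(rbind(c(0, 1), c(2, 0))), "symmetric")
  expect_error(atomic_contributions(diag(2)), "zero diagonal")
})

test_that("half-sum oracle equivalence holds property-style over random clusters", {
  # >= 100 random cases across engines and sizes, against the explicit
  # double-loop oracle
  worst <- 0
  for (seed in 1:50) {
    for (engine in c("london", "cnd")) {
      m <- make_cluster(5 + (seed %% 6), "C", seed = seed)
      res <- total_dispersion(m, engine = engine)
      acs <- atomic_contributions(res)
      oracle <- half_sum_oracle(res$pairs)
      worst <- max(worst, max(abs(acs$eps - oracle)))
      # conservation to 1e-10 relative
      expect_rel_equal(sum(acs$eps), res$total, 1e-10)
    }
  }
  expect_lt(worst, 1e-13)
})

test_that("oracle equivalence holds at 50 atoms to near machine precision", {
  for (engine in c("london", "cnd")) {
    m <- make_cluster(50, "C", seed = 17)
    res <- total_dispersion(m, engine = engine)
    acs <- atomic_contributions(res)
    oracle <- half_sum_oracle(res$pairs)
    scale <- max(abs(oracle))
    expect_lt(max(abs(acs$eps - oracle)) / scale, 1e-14)
  }
})

test_that("fragment contributions conserve the total under any partition", {
  m <- make_cluster(9, "C", seed = 2)

  # single fragment: the fragment sum is the total
  acs <- atomic_contributions(total_dispersion(m))
  fc <- fragment_contributions(acs, m)
  expect_equal(nrow(fc$table), 1)
  expect_equal(fc$table$eps_kcalmol, acs$total)

  # one-atom fragments: fragment sums are the atomic values
  m2 <- molecule(m$element, m$xyz, fragment = as.character(seq_len(9)))
  acs2 <- atomic_contributions(total_dispersion(m2))
  fc2 <- fragment_contributions(acs2, m2)
  expect_equal(fc2$table$eps_kcalmol, acs2$eps)

  # two-fragment dimer vs manual grouping
  d <- make_dimer(make_ring(4, "C", 1.4), R = 5)
  acs3 <- atomic_contributions(total_dispersion(d))
  fc3 <- fragment_contributions(acs3, d)
  expect_equal(fc3$table$eps_kcalmol[fc3$table$fragment == "A"],
               sum(acs3$eps[1:4]))
  expect_equal(fc3$table$eps_kcalmol[fc3$table$fragment == "B"],
               sum(acs3$eps[5:8]))
  expect_equal(fc3$residual, 0)
})

test_that("pair-classified split identity is exact and vanishes at long range", {
  ring <- make_ring(6, "C", 1.39)

  for (engine in c("london", "cnd")) {
    d <- make_dimer(ring, R = 4.5)
    sp <- supramolecular_split(d, engine = engine)
    # identity exact as summed
    expect_identical(sp$E1 + sp$E2 + sp$E_int, sp$E_tot)
    # and consistent with the engine's own total at fp reproducibility
    expect_rel_equal(sp$E_tot, total_dispersion(d, engine = engine)$total,
                     1e-10)

    # far-separated monomers: interaction is numerically zero
    far <- make_dimer(ring, R = 500)
    for (conv in c("pair-classified", "isolated-monomer")) {
      spf <- supramolecular_split(far, engine = engine, convention = conv)
      expect_lt(abs(spf$E_int), 1e-9)
    }
  }
})

test_that("split conventions agree for the environment-free London engine", {
  d <- make_dimer(make_ring(6, "C", 1.39), R = 4.0)
  sp_pc <- supramolecular_split(d, engine = "london")
  sp_im <- supramolecular_split(d, engine = "london",
                                convention = "isolated-monomer")
  expect_equal(sp_pc$E1, sp_im$E1, tolerance = 1e-12)
  expect_equal(sp_pc$E2, sp_im$E2, tolerance = 1e-12)
  expect_equal(sp_pc$E_int, sp_im$E_int, tolerance = 1e-12)
})

test_that("CN-engine convention difference equals the recomputed monomer shift", {
  # at contact distance the in-dimer coordination numbers differ from the
  # isolated-monomer ones; the convention difference must equal that shift
  d <- make_dimer(make_ring(6, "C", 1.39), R = 3.2)
  sp_pc <- supramolecular_split(d, engine = "cnd")
  sp_im <- supramolecular_split(d, engine = "cnd",
                                convention = "isolated-monomer")
  expect_identical(sp_pc$E1 + sp_pc$E2 + sp_pc$E_int, sp_pc$E_tot)

  # direct recomputation of the isolated monomers
  e_mono <- total_dispersion(subset_fragment(d, "A"), engine = "cnd")$total
  expect_equal(sp_im$E1, e_mono, tolerance = 1e-12)
  expect_equal(sp_im$E_int - sp_pc$E_int,
               (sp_pc$E1 - sp_im$E1) + (sp_pc$E2 - sp_im$E2),
               tolerance = 1e-10)

  # more than two fragments is an instructive error
  m3 <- molecule(rep("C", 3), diag(3) * 3, fragment = c("A", "B", "C"))
  expect_error(supramolecular_split(m3), "pairwise")
})

test_that("delta contributions subtract mapped atoms and conserve the total difference", {
  chainA <- make_chain(5, "C", 1.5)
  chainB <- make_chain(5, "C", 1.8)
  acsA <- atomic_contributions(total_dispersion(chainA))
  acsB <- atomic_contributions(total_dispersion(chainB))

  # identical structures, identity mapping: all zeros
  d0 <- delta_contributions(acsA, acsA)
  expect_equal(d0$delta_eps, rep(0, 5))

  # antisymmetry under order swap
  dAB <- delta_contributions(acsA, acsB)
  dBA <- delta_contributions(acsB, acsA)
  expect_equal(dAB$delta_eps, -dBA$delta_eps, tolerance = 1e-14)

  # elementwise oracle and conservation of the total difference
  expect_equal(dAB$delta_eps, acsA$eps - acsB$eps, tolerance = 1e-14)
  expect_rel_equal(sum(dAB$delta_eps), acsA$total - acsB$total, 1e-10)

  # a nontrivial permutation mapping
  perm <- c(2L, 1L, 3L, 5L, 4L)
  mp <- atom_mapping(chainA, chainB, perm)
  dp <- delta_contributions(acsA, acsB, mapping = mp)
  expect_equal(dp$delta_eps, acsA$eps - acsB$eps[perm], tolerance = 1e-14)
})

test_that("contribution interchange tables round-trip and validate their schema", {
  m <- make_cluster(6, "C", seed = 4)
  acs <- atomic_contributions(total_dispersion(m))
  path <- withr::local_tempfile(fileext = ".csv")
  write_contributions(acs, path)

  back <- read_contributions(path)
  expect_equal(back$eps, acs$eps, tolerance = 1e-10)
  expect_equal(back$provenance, "external")
  expect_rel_equal(back$total, acs$total, 1e-10)

  # geometry cross-check against a reference molecule
  back2 <- read_contributions(path, molecule = m)
  expect_identical(back2$molecule, m)
  shifted <- transform_molecule(m, translation = c(1e-3, 0, 0))
  expect_error(read_contributions(path, molecule = shifted), "deviate")
  wrong_elem <- molecule(c("N", m$element[-1]), m$xyz)
  expect_error(read_contributions(path, molecule = wrong_elem),
               "element mismatch")

  # missing column is a schema error naming the column
  df <- read.csv(path, comment.char = "#")
  df$eps_kcalmol <- NULL
  write.csv(df, path, row.names = FALSE)
  expect_error(read_contributions(path), "eps_kcalmol")

  # hand-written 3-row table: total is the column sum
  hand <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# hand-written", "index,element,x,y,z,eps_kcalmol",
               "1,C,0,0,0,-1.25", "2,H,1,0,0,-0.5", "3,O,0,1,0,-2.0"), hand)
  acs_h <- read_contributions(hand)
  expect_equal(acs_h$total, -3.75)
  expect_equal(acs_h$molecule$element, c("C", "H", "O"))
})
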