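test_that("Monte-Carlo overlap matches closed-form sphere intersections", {
  a <- make_sphere_set(c(0, 0, 0), 1)
  b <- make_sphere_set(c(1, 0, 0), 1)
  # coincident unit spheres: full sphere volume
  v <- mc_overlap_volume(a, a, n_samples = 2e5, seed = 7)
  expect_lt(abs(v$volume - 4 * pi / 3), 3 * v$se)
  # lens at distance 1: 5*pi/12
  v2 <- mc_overlap_volume(a, b, n_samples = 2e5, seed = 7)
  expect_equal(sphere_lens_volume(1, 1, 1), 5 * pi / 12)
  expect_lt(abs(v2$volume - 5 * pi / 12), 3 * v2$se)
  # disjoint spheres: exactly zero (empty sampling region)
  far <- make_sphere_set(c(3, 0, 0), 1)
  expect_equal(mc_overlap_volume(a, far, n_samples = 1e4, seed = 1)$volume, 0)
  expect_error(mc_overlap_volume(a, b, n_samples = 0, seed = 1), "n_samples")
  expect_error(mc_overlap_volume(a, b, n_samples = 100), "seed")
})

test_that("the overlap estimator is symmetric and bounded by either body", {
  withr::with_seed(5, {
    for (k in 1:4) {
      centers_a <- matrix(rnorm(9, sd = 1), 3)
      centers_b <- matrix(rnorm(6, sd = 1), 2)
      A <- make_sphere_set(centers_a, runif(3, 0.8, 1.5))
      B <- make_sphere_set(centers_b, runif(2, 0.8, 1.5))
      vab <- mc_overlap_volume(A, B, n_samples = 5e4, seed = k)
      vba <- mc_overlap_volume(B, A, n_samples = 5e4, seed = k)
      expect_identical(vab$volume, vba$volume)
      vol_bound <- min(sum(4 * pi * A$radius^3 / 3), sum(4 * pi * B$radius^3 / 3))
      expect_lt(vab$volume, vol_bound + 3 * vab$se)
    }
  })
})

test_that("sidechain truncation removes atoms and can only reduce overlap", {
  h <- make_helix_coords(6)
  # fake leucine: backbone of residue 3 plus a bulky sidechain sphere
  ca3 <- h[h$resno == 3 & h$elety == "CA", ]
  side <- tibble::tibble(chain = "A", resno = 3L, resname = "LEU",
                         elety = "CD1", x = ca3$x + 4, y = ca3$y, z = ca3$z,
                         element = "C")
  leu <- atom_set(dplyr::bind_rows(as.data.frame(h), as.data.frame(side)))
  leu$resname[leu$resno == 3] <- "LEU"
  ala <- mutate_sidechain(leu, "A", 3L, "ALA")
  gly <- mutate_sidechain(leu, "A", 3L, "GLY")
  expect_equal(sum(gly$resno == 3), 4L)          # N, CA, C, O
  expect_equal(gly$resname[gly$resno == 3][1], "GLY")
  expect_equal(sum(ala$resno == 3), 4L)          # no CB in the fixture
  # truncating an Ala to Ala is the identity
  expect_equal(nrow(mutate_sidechain(gly, "A", 3L, "GLY")), nrow(gly))
  expect_error(mutate_sidechain(leu[leu$elety != "CA", ], "A", 3L, "GLY"),
               "backbone")
  # an RF-like probe sphere sits where the sidechain points
  rf <- make_sphere_set(c(ca3$x + 4.5, ca3$y, ca3$z), 2)
  v_leu <- mc_overlap_volume(leu, rf, n_samples = 1e5, seed = 2)
  v_gly <- mc_overlap_volume(gly, rf, n_samples = 1e5, seed = 2)
  expect_gt(v_leu$volume, v_gly$volume)
})

test_that("Kabsch superposition recovers rigid transforms exactly", {
  withr::with_seed(8, {
    P <- matrix(rnorm(30), 10)
    A <- make_sphere_set(P, 1)
    s0 <- superpose(A, A)
    expect_equal(s0$rmsd, 0, tolerance = 1e-10)
    expect_equal(s0$R, diag(3), tolerance = 1e-10)
    # 90-degree rotation plus translation
    R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
    B <- make_sphere_set(sweep(P %*% t(R90), 2, c(4, -2, 1), "+"), 1)
    s <- superpose(A, B)
    expect_equal(s$rmsd, 0, tolerance = 1e-9)
    # RMSD after fitting noisy copies sits at the noise level
    N <- make_sphere_set(P + matrix(rnorm(30, sd = 0.1), 10), 1)
    sn <- superpose(A, N)
    expect_gt(sn$rmsd, 0.05)
    expect_lt(sn$rmsd, 0.1 * sqrt(3) * 1.6)
    expect_error(superpose(A, B, pairs = list(mobile = 1:2, reference = 1:2)),
                 "3 paired")
  })
})

test_that("superposed RMSD is invariant to pre-transforming the mobile set and matches bio3d", {
  withr::with_seed(12, {
    P <- matrix(rnorm(24), 8)
    Q <- P + matrix(rnorm(24, sd = 0.3), 8)
    A <- make_sphere_set(P, 1); B <- make_sphere_set(Q, 1)
    r0 <- superpose(A, B)$rmsd
    th <- 1.1
    Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                 byrow = TRUE)
    A2 <- make_sphere_set(sweep(P %*% t(Rz), 2, c(10, 5, -3), "+"), 1)
    expect_equal(superpose(A2, B)$rmsd, r0, tolerance = 1e-9)
    # independent reference implementation
    fit <- bio3d::fit.xyz(fixed = as.vector(t(Q)), mobile = as.vector(t(P)),
                          fixed.inds = 1:24, mobile.inds = 1:24)
    rmsd_bio3d <- sqrt(mean(colSums(matrix((fit - as.vector(t(Q)))^2, 3))))
    expect_equal(r0, rmsd_bio3d, tolerance = 1e-6)
  })
})

test_that("helical backbones carry the full i+4 hydrogen-bond ladder, strands none", {
  helix <- make_helix_coords(10)
  hb <- count_i4_hbonds(helix)
  expect_equal(hb$count, 6L)   # pairs (1,5) ... (6,10)
  expect_true(all(hb$pairs$distance > 2.6 & hb$pairs$distance < 3.3))
  strand <- make_helix_coords(10, phi = -139, psi = 135)  # extended chain
  expect_equal(count_i4_hbonds(strand)$count, 0L)
  expect_equal(count_i4_hbonds(helix[helix$resno <= 4, ])$count, 0L)
  # an 18-residue ideal helix carries exactly 14 (i, i+4) pairs
  expect_equal(count_i4_hbonds(make_helix_coords(18), residues = 1:18)$count,
               14L)
})

test_that("extended-chain length is linear at 3.5 angstroms per residue", {
  expect_equal(extended_length(27), 94.5)
  expect_equal(extended_length(0), 0)
  expect_equal(extended_length(10, rise = 3.5), 35)
  expect_equal(extended_length(5) + extended_length(22), extended_length(27))
})

test_that("atom sets validate coordinates and assign Bondi radii by element", {
  df <- data.frame(chain = "A", resno = 1L, resname = "GLY",
                   elety = c("N", "CA", "C", "O"),
                   x = 0, y = 0, z = c(0, 1, 2, 3),
                   element = c("N", "C", "C", "O"))
  a <- atom_set(df)
  expect_equal(a$radius, c(1.55, 1.70, 1.70, 1.52))
  expect_error(atom_set(transform(df, x = Inf)), "finite")
  expect_error(atom_set(transform(df, element = "Q")), "radius")
  b <- atom_set(df, radii = c(C = 2.0))
  expect_equal(b$radius[2], 2.0)
})
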