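test_that("plane fitting recovers exact and rotated planes", {
  hexa <- hexagon_xy()
  p <- fit_plane(hexa)
  expect_equal(p$unit_normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(p$rms_out_of_plane, 0, tolerance = 1e-12)
  expect_equal(p$centroid, c(0, 0, 0), tolerance = 1e-12)

  # closed-form oracle: rotating the z = 0 plane by 30 degrees about x
  # carries the normal to (0, -sin 30, cos 30)
  rot <- rotation_matrix(c(1, 0, 0), 30)
  p30 <- fit_plane(hexa %*% t(rot))
  oracle_normal <- as.numeric(rot %*% c(0, 0, 1))
  if (oracle_normal[which.max(abs(oracle_normal))] < 0) {
    oracle_normal <- -oracle_normal
  }
  expect_lt(max(abs(p30$unit_normal - oracle_normal)), 1e-9)

  # rms against an independent brute-force point-to-plane evaluation
  pts <- rbind(hexa, c(0.3, 0.2, 0.1))
  pf <- fit_plane(pts)
  dists <- apply(pts, 1L, function(q) {
    abs(sum((q - pf$centroid) * pf$unit_normal))
  })
  expect_equal(pf$rms_out_of_plane, sqrt(mean(dists^2)), tolerance = 1e-12)

  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "degenerate")
  expect_error(fit_plane(hexa[1:2, ]), "at least 3")
})

test_that("interplanar angles fold to [0, 90] and ignore normal sign", {
  a <- fit_plane(hexagon_xy())
  expect_equal(interplanar_angle(a, a), 0)
  expect_equal(interplanar_angle(c(0, 0, 1), c(0, 1, 0)), 90)
  # normals 150 degrees apart fold to 30
  n150 <- c(0, sin(150 * pi / 180), cos(150 * pi / 180))
  expect_equal(interplanar_angle(c(0, 0, 1), n150), 30, tolerance = 1e-9)
  # symmetric and sign-invariant
  set.seed(11)
  for (i in 1:10) {
    u <- rnorm(3); v <- rnorm(3)
    expect_equal(interplanar_angle(u, v), interplanar_angle(v, u))
    expect_equal(interplanar_angle(u, v), interplanar_angle(-u, v))
    expect_lte(interplanar_angle(u, v), 90)
  }
})

test_that("minimum contact distance matches a brute-force double loop", {
  a <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  expect_equal(min_contact_distance(a, a[1, , drop = FALSE]), 0)
  set.seed(21)
  pa <- matrix(rnorm(60, sd = 5), 20, 3)
  pb <- matrix(rnorm(60, mean = 3, sd = 5), 20, 3)
  brute <- Inf
  for (i in 1:20) for (j in 1:20) {
    brute <- min(brute, sqrt(sum((pa[i, ] - pb[j, ])^2)))
  }
  expect_equal(min_contact_distance(pa, pb), brute, tolerance = 1e-12)
  expect_error(min_contact_distance(pa[0, , drop = FALSE], pb), "empty")
})

test_that("radius of gyration closed forms and scaling law hold", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1)
  # weighted centroid: weights shift the centre
  expect_equal(radius_of_gyration(two, c(3, 1)),
               sqrt((3 * 0.5^2 + 1 * 1.5^2) / 4))
  set.seed(31)
  pts <- matrix(rnorm(90), 30, 3)
  expect_equal(radius_of_gyration(pts * 2.5),
               2.5 * radius_of_gyration(pts), tolerance = 1e-12)
})

test_that("superposition is a proper least-squares fit", {
  set.seed(41)
  ref <- matrix(rnorm(90, sd = 10), 30, 3)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  # pure translation
  fit_t <- superpose(sweep(ref, 2, c(5, -3, 2), "+"), ref)
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-9)
  # rotated copy with noise: cross-checked against the independent bio3d
  # least-squares superposition
  rot <- rotation_matrix(c(1, 2, 3), 53)
  mob <- ref %*% t(rot) + matrix(rnorm(90, sd = 0.1), 30, 3)
  mob <- sweep(mob, 2, c(4, 4, -1), "+")
  fit <- superpose(mob, ref)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob))))
  oracle <- sqrt(mean(colSums(matrix((fitted - as.vector(t(ref)))^2, 3))))
  expect_equal(fit$rmsd, oracle, tolerance = 1e-9)
  # symmetry of the minimised rmsd
  expect_equal(superpose(ref, mob)$rmsd, fit$rmsd, tolerance = 1e-9)
  expect_error(superpose(ref[1:5, ], ref), "differ in length")
})

test_that("the axial frame follows its closed form and P700 symmetry", {
  mg <- matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  fe <- matrix(rep(c(0, 0, 10), 4), 4, 3, byrow = TRUE) +
    rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) * 0.5
  fr <- axial_frame(mg, fe)
  expect_equal(fr$origin, c(0, 0, 5), tolerance = 1e-12)
  expect_equal(fr$axis, c(0, 0, 1), tolerance = 1e-12)
  # swapping the two Mg gives the identical frame
  fr2 <- axial_frame(mg[2:1, ], fe)
  expect_identical(fr2$origin, fr$origin)
  expect_identical(fr2$axis, fr$axis)
  expect_error(axial_frame(matrix(0, 2, 3), matrix(0, 4, 3)), "degenerate")
})

test_that("cylindrical decomposition matches the projection formula", {
  fr <- axial_frame(matrix(c(-1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE),
                    matrix(rep(c(0, 0, 10), 4), 4, 3, byrow = TRUE))
  on_axis <- cylindrical_decompose(fr, c(0, 0, 7))
  expect_equal(on_axis$radial, 0, tolerance = 1e-12)
  expect_equal(on_axis$axial, 2)
  perp <- cylindrical_decompose(fr, c(5, 0, 5))
  expect_equal(perp$radial, 5)
  expect_equal(perp$axial, 0)
  # independent projection formula on random points and a random frame
  set.seed(51)
  p7 <- matrix(rnorm(6), 2, 3)
  fx <- matrix(rnorm(12, mean = 8), 4, 3)
  fr2 <- axial_frame(p7, fx)
  for (i in 1:5) {
    q <- rnorm(3, sd = 10)
    got <- cylindrical_decompose(fr2, q)
    rel <- q - fr2$origin
    ax <- sum(rel * fr2$axis)
    rad <- sqrt(sum((rel - ax * fr2$axis)^2))
    expect_equal(got$axial, ax, tolerance = 1e-12)
    expect_equal(got$radial, rad, tolerance = 1e-12)
  }
})

test_that("geometry is invariant under a common rigid motion", {
  set.seed(61)
  hexa <- hexagon_xy()
  other <- sweep(hexagon_xy() %*% t(rotation_matrix(c(0, 1, 0), 40)),
                 2, c(1, 2, 3.4), "+")
  for (k in 1:5) {
    mo <- random_rigid_motion(100 + k)
    ha <- apply_rigid(hexa, mo)
    hb <- apply_rigid(other, mo)
    expect_equal(interplanar_angle(fit_plane(ha), fit_plane(hb)),
                 interplanar_angle(fit_plane(hexa), fit_plane(other)),
                 tolerance = 1e-9)
    expect_equal(min_contact_distance(ha, hb),
                 min_contact_distance(hexa, other), tolerance = 1e-9)
    expect_equal(radius_of_gyration(ha), radius_of_gyration(hexa),
                 tolerance = 1e-9)
    expect_equal(fit_plane(ha)$rms_out_of_plane,
                 fit_plane(hexa)$rms_out_of_plane, tolerance = 1e-9)
  }
})
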