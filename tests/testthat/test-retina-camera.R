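test_that("maximal object angle reproduces the schematic-eye constants", {
  cam <- camera_model()
  expect_equal(round(max_object_angle(cam, pi / 8), 2), 0.63)
  expect_equal(max_object_angle(cam, 0), 0)
  # a = 0 reduces the relation to ybar = psi
  cam0 <- camera_model(a = 0)
  for (psi in c(0.1, 0.3, pi / 8))
    expect_equal(max_object_angle(cam0, psi), psi, tolerance = 1e-12)
})

test_that("projection and unprojection are mutually inverse", {
  cam <- camera_model()
  expect_equal(unname(retina_project(cam, 0, 0)), matrix(c(0, 0), 1),
               ignore_attr = TRUE)
  XY <- retina_project(cam, 0, 0.63)
  expect_equal(XY[1, "X"], c(X = 0))
  expect_equal(unname(XY[1, "Y"]), 0.5858307, tolerance = 1e-6)
  set.seed(5)
  x <- runif(1000, -0.63, 0.63); y <- runif(1000, -0.63, 0.63)
  XY <- retina_project(cam, x, y)
  back <- retina_unproject(cam, XY[, 1], XY[, 2])
  expect_lt(max(abs(back[, 1] - x)), 1e-10)
  expect_lt(max(abs(back[, 2] - y)), 1e-10)
  # the other composition, on the image of the valid domain
  fwd <- retina_project(cam, back[, 1], back[, 2])
  expect_lt(max(abs(fwd - XY)), 1e-10)
  # specific round trip
  expect_equal(unname(retina_unproject(cam, retina_project(cam, 0.3, -0.4)[1],
                                       retina_project(cam, 0.3, -0.4)[2])[1, ]),
               c(0.3, -0.4), tolerance = 1e-10)
  # eta handling: scale inputs
  cam2 <- camera_model(eta = 2)
  XY2 <- retina_project(cam2, 0.2, 0.3)
  expect_equal(unname(retina_unproject(cam2, XY2[1], XY2[2])[1, ]), c(0.2, 0.3),
               tolerance = 1e-10)
})

test_that("Jacobian matches the schematic-eye constants and numerical differentiation", {
  cam <- camera_model()
  expect_equal(round(camera_jacobian(cam, 0, 0), 2), 0.77)
  expect_equal(round(camera_jacobian(cam, 0.63, 0.63), 1), 1.1)
  set.seed(6)
  h <- 1e-6
  for (k in 1:15) {
    x <- runif(1, -0.6, 0.6); y <- runif(1, -0.6, 0.6)
    Jfd <- det(rbind(
      (retina_project(cam, x + h, y) - retina_project(cam, x - h, y)) / (2 * h),
      (retina_project(cam, x, y + h) - retina_project(cam, x, y - h)) / (2 * h)))
    expect_equal(camera_jacobian(cam, x, y), Jfd, tolerance = 1e-5)
  }
  # bounds over the field of view
  gr <- expand.grid(x = seq(-0.63, 0.63, length.out = 200),
                    y = seq(-0.63, 0.63, length.out = 200))
  J <- camera_jacobian(cam, gr$x, gr$y)
  expect_gt(min(J), 0.76); expect_lt(min(J), 0.78)
  expect_gt(max(J), 1.09); expect_lt(max(J), 1.12)
})

test_that("global distortion peaks near 7% at the edge of the field of view", {
  cam <- camera_model()
  expect_equal(round(global_distortion(cam, 0.63), 2), 0.07)
  expect_equal(global_distortion(cam, 0), abs(1 - (13 / 21 + 4 / 5) / (13 / 21 + 1)),
               tolerance = 1e-12)
  expect_equal(global_distortion(cam, 1e-9), global_distortion(cam, 0),
               tolerance = 1e-6)
  yv <- seq(0.05, 0.63, length.out = 20)
  expect_equal(global_distortion(cam, yv), global_distortion(cam, -yv))
})

test_that("image resampling between flat and spherical charts is consistent", {
  cam <- camera_model()
  # smooth pattern; resampling should preserve values approximately
  np <- 64
  Xs <- seq(-0.6, 0.6, length.out = np)
  img <- outer(Xs, Xs, function(Y, X) sin(3 * X) * cos(2 * Y))
  sph <- resample_retina_image(img, cam, "flat2sphere", XYlim = 0.6)
  expect_equal(dim(sph), c(np, np))
  expect_true(mean(is.finite(sph)) > 0.8)
})
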