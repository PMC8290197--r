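# Rigid/deformable registration, transform chains, stack reconstruction,
# landmark error.

reg_base <- function(size = 48L) {
  phantom_anatomy(phantom_spec(width = size, height = size, seed = 5L))
}

test_that("pre-rotation: identity, quarter turn, round trip", {
  img <- reg_base()
  expect_equal(pre_rotate(img, 0)$image, img)

  sq <- img[1:41, 1:41]  # odd-sized square so the centre is a pixel
  rot <- pre_rotate(sq, 90)$image
  # 90 degrees about the centre (y pointing down) equals transpose +
  # row reversal, up to interpolation at the borders
  ref <- t(sq)[rev(seq_len(41)), ]
  interior <- 5:37
  expect_lt(max(abs(rot[interior, interior] - ref[interior, interior])),
            1e-8)

  smooth <- msilazy:::.gauss_blur(img, 2.5)
  fwd <- pre_rotate(smooth, 12)$image
  back <- pre_rotate(fwd, -12)$image
  interior <- 10:39
  expect_lt(max(abs(back[interior, interior] -
                      smooth[interior, interior])),
            0.02 * diff(range(smooth)))
  expect_error(pre_rotate(img, 200), "180")
})

test_that("landmark error: ground truth, uniform offset, hand arithmetic", {
  sp <- c(1, 1)
  ctr <- c(10, 10)
  A <- rigid_transform(0.2, 3, -2, ctr)
  fixed <- cbind(c(2, 8, 15), c(3, 12, 7))
  moving <- msilazy:::.map_points(A, fixed)
  e <- landmark_error(fixed, moving, transform_chain(A))
  expect_lt(e$mean, 1e-6)

  e2 <- landmark_error(fixed, fixed + 10 / sqrt(2), NULL)
  expect_equal(e2$mean, 10)
  expect_equal(e2$sd, 0)

  e3 <- landmark_error(cbind(c(0, 0), c(0, 0)), cbind(c(3, 0), c(0, 5)))
  expect_equal(e3$mean, 4)
  expect_equal(e3$sd, 1)
  expect_equal(e3$per_point, c(3, 5))

  expect_error(landmark_error(fixed, fixed[1:2, ]), "pairing")
})

test_that("registering an image to itself returns the identity", {
  img <- reg_base()
  r <- register_rigid(img, img, registration_params(), c(20, 20))
  expect_lt(abs(r$theta) * 180 / pi, 0.25)
  expect_lt(max(abs(c(r$tx, r$ty))) / 20, 0.25)
})

test_that("known shifts and rotations are recovered", {
  img <- reg_base()
  sp <- c(20, 20)
  ctr <- c((ncol(img) - 1) / 2 * sp[1], (nrow(img) - 1) / 2 * sp[2])

  A <- rigid_transform(0, 3 * sp[1], -2 * sp[2], ctr)
  mov <- apply_chain(img, rigid_inverse(A), "linear", sp)
  r <- register_rigid(img, mov, registration_params(), sp)
  expect_lt(max(abs(c(r$tx - A$tx, r$ty - A$ty))) / sp[1], 0.5)

  B <- rigid_transform(10 * pi / 180, 0, 0, ctr)
  movB <- apply_chain(img, rigid_inverse(B), "linear", sp)
  rB <- register_rigid(img, movB, registration_params(), sp)
  expect_lt(abs(rB$theta - B$theta) * 180 / pi, 0.5)

  # metric improves for every accepted registration
  for (case in list(list(mov, r), list(movB, rB))) {
    aligned <- apply_chain(case[[1]], case[[2]], "linear", sp)
    expect_gte(mattes_mi(img, aligned), mattes_mi(img, case[[1]]))
  }
  expect_error(register_rigid(matrix(1, 10, 10), img), "constant")
})

test_that("chains compose into one interpolation pass", {
  img <- reg_base()
  expect_equal(apply_chain(img, transform_chain()), img)

  fwd <- rigid_transform(0, 3, 0)
  bwd <- rigid_transform(0, -3, 0)
  round <- apply_chain(img, transform_chain(fwd, bwd), "linear")
  expect_equal(round, img)   # exact: the composed map is the identity

  mask <- matrix(0L, 20, 20); mask[6:12, 4:9] <- 1L
  shifted <- apply_chain(mask, rigid_transform(0.1, 1.3, -0.7, c(9, 9)),
                         "nearest")
  expect_true(all(shifted %in% c(0, 1)))
})

test_that("stacks with known cumulative shifts are reconstructed", {
  img <- reg_base(40L)
  sp <- c(20, 20)
  n <- 5L
  shifts <- c(0, 1, 2, 3, 4)   # cumulative, pixels
  slices <- lapply(shifts, function(s) {
    A <- rigid_transform(0, s * sp[1], 0)
    apply_chain(img, rigid_inverse(A), "linear", sp)
  })
  # mono-modal serial sections: mean squares is the sharper metric when
  # the reference itself is an interpolated (already aligned) image
  fast <- registration_params(metric = "mean_squares",
                              search_theta_deg = 6)
  for (ref in c(1L, 3L)) {
    chains <- reconstruct_stack(slices, ref, fast, sp)
    expect_equal(length(chains[[ref]]), 0L)
    for (i in seq_len(n)) {
      if (i == ref) next
      tr <- chains[[i]][[1]]
      expect_lt(abs(tr$tx - (shifts[i] - shifts[ref]) * sp[1]) / sp[1],
                0.5)
      expect_lt(abs(tr$ty) / sp[2], 0.5)
    }
  }
  expect_error(reconstruct_stack(list(), 1L), "empty")
  expect_error(reconstruct_stack(slices, 9L), "reference_index")
})

test_that("deformable stage: stability, warp correction, metric gain", {
  img <- reg_base(40L)
  sp <- c(20, 20)
  p <- registration_params(grid_spacing_mm = 0.32,
                           deformable_iterations = 400L)

  ch0 <- register_deformable(img, img, rigid_transform(0, 0, 0), p, sp)
  expect_lt(max(abs(c(ch0[[2]]$Dx, ch0[[2]]$Dy))) / sp[1], 0.1)

  h <- nrow(img); w <- ncol(img)
  pts <- msilazy:::.grid_points(h, w, sp)
  amp <- 2 * sp[1]
  warped_pts <- cbind(pts[, 1] + amp * sin(pts[, 2] / ((h - 1) * sp[2]) *
                                             2 * pi), pts[, 2])
  mv <- matrix(msilazy:::.sample_image(img, warped_pts, sp), h, w)
  mv[is.na(mv)] <- 0
  ch <- register_deformable(img, mv, rigid_transform(0, 0, 0), p, sp)

  aligned <- apply_chain(mv, ch, "linear", sp)
  expect_gt(mattes_mi(img, aligned), mattes_mi(img, mv))

  # landmark error after the chain is no worse than before
  sub <- pts[seq(1, nrow(pts), by = 173), , drop = FALSE]
  sub <- sub[sub[, 1] > 4 * sp[1] & sub[, 1] < (w - 5) * sp[1], ,
             drop = FALSE]
  fixed_pts <- cbind(sub[, 1] + amp * sin(sub[, 2] / ((h - 1) * sp[2]) *
                                            2 * pi), sub[, 2])
  before <- landmark_error(fixed_pts, sub, NULL)$mean
  after <- landmark_error(fixed_pts, sub, ch)$mean
  expect_lte(after, before)

  expect_error(register_deformable(img, mv, rigid_transform(0, 0, 0), p,
                                   sp, backend = FALSE), "configuration")
  # external backend pass-through
  fake <- function(fixed, moving, initial, params, spacing) {
    transform_chain(initial)
  }
  expect_identical(register_deformable(img, mv, rigid_transform(0, 0, 0),
                                       p, sp, backend = fake),
                   transform_chain(rigid_transform(0, 0, 0)))
})

test_that("chain serialization writes a documented JSON schema", {
  d <- tempfile(fileext = ".json")
  chains <- list(transform_chain(rigid_transform(0.1, 5, -3, c(10, 10))),
                 transform_chain())
  write_chains_json(chains, d)
  j <- jsonlite::fromJSON(d, simplifyVector = FALSE)
  expect_equal(j$units, "um")
  expect_equal(j$chains[[1]]$steps[[1]]$type, "rigid")
  expect_equal(j$chains[[1]]$steps[[1]]$theta, 0.1)
  expect_equal(length(j$chains[[2]]$steps), 0L)
})
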