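test_that("mask centroid equals the brute-force voxel mean", {
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  expect_equal(mask_centroid(m, diag(4)), c(3, 3, 3))
  # symmetric cube centered by construction
  m2 <- array(FALSE, c(10, 10, 10)); m2[3:6, 3:6, 3:6] <- TRUE
  expect_equal(mask_centroid(m2, diag(4)), c(3.5, 3.5, 3.5))
  # random blob vs exhaustive sum under a non-trivial affine
  set.seed(31)
  m3 <- array(FALSE, c(20, 20, 20))
  m3[sample(length(m3), 500)] <- TRUE
  A <- diag(c(1.3, 0.7, 2.1, 1)); A[1:3, 4] <- c(-5, 8, 3)
  idx <- which(m3, arr.ind = TRUE) - 1
  oracle <- colMeans(t(A %*% t(cbind(idx, 1))))[1:3]
  expect_lt(max(abs(mask_centroid(m3, A) - oracle)), 1e-9)
  expect_error(mask_centroid(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("sectioning frames follow the pole axis and tumor centroid", {
  lm <- landmark_set(list(upper_pole = c(0, 0, 50), lower_pole = c(0, 0, -50),
                          hilum = c(-10, 0, 0), tumor_contact = c(25, 0, 5)))
  ctr <- c(30, 0, 0)
  fl <- sectioning_frame(lm, ctr, "longitudinal")
  expect_equal(abs(fl$normal), c(0, 1, 0), tolerance = 1e-12)
  ft <- sectioning_frame(lm, ctr, "transverse")
  expect_equal(ft$normal, c(0, 0, 1), tolerance = 1e-12)
  # degenerate longitudinal geometry is rejected with advice
  expect_error(sectioning_frame(lm, c(0, 0, 10), "longitudinal"),
               "transverse")
})

test_that("random frames satisfy the vector-algebra oracle", {
  set.seed(41)
  for (i in 1:100) {
    up_p <- rnorm(3, sd = 30)
    lo_p <- rnorm(3, sd = 30)
    if (sqrt(sum((up_p - lo_p)^2)) < 1) next
    ctr <- rnorm(3, sd = 30)
    a <- (up_p - lo_p) / sqrt(sum((up_p - lo_p)^2))
    rej <- ctr - lo_p - sum((ctr - lo_p) * a) * a
    if (sqrt(sum(rej^2)) < 1) next
    lm <- landmark_set(list(upper_pole = up_p, lower_pole = lo_p,
                            hilum = rnorm(3), tumor_contact = rnorm(3)))
    for (mode in c("transverse", "longitudinal")) {
      fr <- sectioning_frame(lm, ctr, mode)
      B <- rbind(fr$normal, fr$lateral, fr$up)
      # orthonormal right-handed triad
      expect_lt(max(abs(B %*% t(B) - diag(3))), 1e-9)
      expect_equal(det(B), 1, tolerance = 1e-9)
      expect_lt(max(abs(cross3(fr$normal, fr$lateral) - fr$up)), 1e-9)
      if (mode == "longitudinal") {
        # normal perpendicular to the pole axis; explicit cross-product oracle
        expect_lt(abs(sum(fr$normal * a)), 1e-9)
        oracle <- cross3(a, ctr - lo_p)
        oracle <- oracle / sqrt(sum(oracle^2))
        expect_lt(max(abs(fr$normal - oracle)), 1e-9)
      } else {
        expect_lt(max(abs(fr$normal - a)), 1e-9)
      }
    }
  }
})

test_that("base roll matches exhaustive grid search and never loses to the
           unrolled frame", {
  sf <- sphere_field(12, 1)
  aff <- diag(4)
  ctr <- sf$center
  set.seed(51)
  for (i in 1:5) {
    # random anchor placement on the sphere
    th1 <- runif(1, 0, 2 * pi); th2 <- th1 + runif(1, 0.3, 1.5)
    hil <- ctr + 12 * c(0, cos(th1), sin(th1))
    tc <- ctr + 12 * c(0, cos(th2), sin(th2))
    lm <- landmark_set(list(upper_pole = ctr + c(12, 0, 0),
                            lower_pole = ctr - c(12, 0, 0),
                            hilum = hil, tumor_contact = tc))
    fr <- sectioning_frame(lm, ctr, "transverse")
    rolled <- base_roll(fr, hil, tc, sf$mask, aff)

    # the same sub-voxel outline support the optimizer sees, but with the
    # objective evaluated exhaustively over the full angle grid
    surf_pts <- extract_surface(gaussian_smooth(sf$mask, 1, c(1, 1, 1)),
                                c(1, 1, 1), 0.5)$vertices
    height_sum <- function(up) {
      low <- min(surf_pts %*% up)
      sum(rbind(hil, tc) %*% up) - 2 * low
    }
    objs <- vapply(0:359, function(adeg) {
      t <- adeg * pi / 180
      height_sum(cos(t) * fr$up + sin(t) * fr$lateral)
    }, 0)
    expect_equal(height_sum(rolled$up), min(objs), tolerance = 1e-6)
    expect_lte(height_sum(rolled$up), height_sum(fr$up) + 1e-9)
  }
})

test_that("an already-optimal anchor placement rolls by zero and
           antipodal anchors roll half a turn", {
  sf <- sphere_field(12, 1)
  ctr <- sf$center
  lm <- landmark_set(list(upper_pole = ctr + c(12, 0, 0),
                          lower_pole = ctr - c(12, 0, 0),
                          hilum = ctr + c(0, -3, -11),
                          tumor_contact = ctr + c(0, 3, -11)))
  fr <- sectioning_frame(lm, ctr, "transverse")
  # force a frame with up = +z so the anchors already sit at the bottom
  fr$up <- c(0, 0, 1); fr$lateral <- cross3(fr$up, fr$normal)
  r0 <- base_roll(fr, lm$points["hilum", ], lm$points["tumor_contact", ],
                  sf$mask, diag(4))
  # the voxelized support function resolves the optimum to a few degrees
  wrap0 <- ifelse(r0$roll_deg > 180, r0$roll_deg - 360, r0$roll_deg)
  expect_lte(abs(wrap0), 5)
  # both anchors at the top: expect half a turn
  fr2 <- fr; fr2$up <- c(0, 0, -1); fr2$lateral <- cross3(fr2$up, fr$normal)
  r180 <- base_roll(fr2, lm$points["hilum", ], lm$points["tumor_contact", ],
                    sf$mask, diag(4))
  expect_lte(abs(r180$roll_deg - 180), 5)
})

test_that("resampling preserves masks, volumes and landmark positions", {
  an <- small_anatomy()
  study <- an$study
  ctr <- mask_centroid(study$seg$masks$tumor, study$seg$affine)

  # identity frame at matching spacing reproduces the masks voxel for voxel
  fr_id <- structure(list(normal = c(1, 0, 0), lateral = c(0, 1, 0),
                          up = c(0, 0, 1), origin = ctr,
                          mode = "transverse", roll_deg = 0),
                     class = "sectioning_frame")
  rs <- resample_to_frame(study, fr_id, spacing_mm = 1)
  expect_true(all(abs(rs$volume_ratio - 1) < 0.05))
  in_src <- sum(study$seg$masks$tumor)
  expect_equal(sum(rs$seg$masks$tumor), in_src)

  # landmarks transform exactly
  lw <- rs$landmarks$points
  lf <- rs$landmarks_frame
  B <- rbind(fr_id$normal, fr_id$lateral, fr_id$up)
  oracle <- sweep(lw, 2, fr_id$origin) %*% t(B)
  expect_lt(max(abs(lf - oracle)), 1e-9)

  # pole axis expressed in frame coordinates is parallel to the normal
  axis_f <- frame_coords(fr_id, lw["upper_pole", ]) -
    frame_coords(fr_id, lw["lower_pole", ])
  ang <- acos(abs(axis_f[1]) / sqrt(sum(axis_f^2))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("a 90-degree rotation permutes an axis-aligned box exactly and an
           oblique rotation preserves a sphere's analytic volume", {
  box <- array(FALSE, c(30, 30, 30))
  box[10:21, 13:18, 14:17] <- TRUE # 12 x 6 x 4
  seg <- segmentation_set(list(tumor = box), diag(4))
  lm <- landmark_set(list(upper_pole = c(25, 15, 15), lower_pole = c(5, 15, 15),
                          hilum = c(15, 12, 15), tumor_contact = c(15, 15, 12)))
  study <- mri_study(seg, lm)
  ctr <- mask_centroid(box, diag(4))
  # frame whose normal is +y: 90-degree relabelling of axes
  lm90 <- landmark_set(list(upper_pole = ctr + c(0, 10, 0),
                            lower_pole = ctr - c(0, 10, 0),
                            hilum = ctr + c(3, 0, 0),
                            tumor_contact = ctr + c(0, 0, 3)))
  fr <- sectioning_frame(lm90, ctr, "transverse")
  rs <- resample_to_frame(study, fr, spacing_mm = 1)
  expect_equal(sum(rs$seg$masks$tumor), sum(box))
  ext <- apply(which(rs$seg$masks$tumor, arr.ind = TRUE), 2, function(v) {
    diff(range(v)) + 1
  })
  expect_setequal(ext, c(12, 6, 4))

  # 37-degree oblique rotation of a 20-mm sphere at 1 mm spacing
  sf <- sphere_field(10, 1)
  segs <- segmentation_set(list(tumor = sf$mask), diag(4))
  th <- 37 * pi / 180
  axis_dir <- c(cos(th), sin(th), 0)
  lmo <- landmark_set(list(upper_pole = sf$center + 10 * axis_dir,
                           lower_pole = sf$center - 10 * axis_dir,
                           hilum = sf$center + c(0, 0, -10),
                           tumor_contact = sf$center + c(0, -7, -7)))
  fro <- sectioning_frame(lmo, sf$center, "transverse")
  rso <- resample_to_frame(mri_study(segs, lmo), fro, spacing_mm = 1)
  vol <- sum(rso$seg$masks$tumor)
  expect_lt(abs(vol / (4 / 3 * pi * 10^3) - 1), 0.05)

  # too-coarse resampling that wipes a mask out raises an error: a small
  # ball whose bounding-box corners (where the coarse lattice nodes fall)
  # lie outside it
  idx <- which(array(TRUE, c(11, 11, 11)), arr.ind = TRUE)
  tiny <- array(sqrt(rowSums(sweep(idx, 2, c(6, 6, 6))^2)) <= 2,
                c(11, 11, 11))
  segt <- segmentation_set(list(tumor = tiny), diag(4))
  lmt <- landmark_set(list(upper_pole = c(10, 5, 5), lower_pole = c(0, 5, 5),
                           hilum = c(5, 3, 5), tumor_contact = c(5, 5, 3)))
  frt <- structure(list(normal = c(1, 0, 0), lateral = c(0, 1, 0),
                        up = c(0, 0, 1), origin = c(5, 5, 5),
                        mode = "transverse", roll_deg = 0),
                   class = "sectioning_frame")
  expect_error(resample_to_frame(mri_study(segt, lmt), frt, spacing_mm = 9),
               "vanished")
})

test_that("resampling an already-resampled study with the same frame is
           idempotent on the mask content", {
  rs <- sphere_study(10, 1)
  study2 <- mri_study(rs$seg, rs$landmarks)
  rs2 <- resample_to_frame(study2, rs$frame, spacing_mm = 1)
  crop <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    rng <- apply(idx, 2, range)
    m[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2], rng[1, 3]:rng[2, 3]]
  }
  expect_identical(crop(rs2$seg$masks$tumor), crop(rs$seg$masks$tumor))
})

test_that("longitudinal central cut plane contains both poles", {
  an <- small_anatomy()
  study <- an$study
  ctr <- mask_centroid(study$seg$masks$tumor, study$seg$affine)
  fr <- sectioning_frame(study$landmarks, ctr, "longitudinal")
  for (p in c("upper_pole", "lower_pole")) {
    s <- frame_coords(fr, study$landmarks$points[p, ])["s"]
    expect_lt(abs(s), 1) # within one voxel of the s = 0 centroid plane
  }
})
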