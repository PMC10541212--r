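dwi_grid <- function(shape = c(12, 10, 6)) image_grid(shape, c(2.5, 2.5, 5.0))

test_that("expand_roi matches the brute-force physical-distance oracle", {
  grid <- dwi_grid()
  # single voxel, anisotropic spacing, 10 mm: offset enumeration oracle
  m <- array(FALSE, grid$shape); m[6, 5, 3] <- TRUE
  roi <- roi_mask(m, grid, "cancer")
  out <- expand_roi(roi, 10)
  count <- 0
  for (di in -4:4) for (dj in -4:4) for (dk in -2:2)
    if ((2.5 * di)^2 + (2.5 * dj)^2 + (5 * dk)^2 <= 100) count <- count + 1
  expect_equal(sum(out$mask), count)
  expect_equal(out$label, "tumor_containing")

  # random masks on an anisotropic grid vs per-voxel min-distance oracle
  set.seed(8)
  for (rep in 1:3) {
    m <- array(runif(prod(grid$shape)) < 0.05, grid$shape)
    if (!any(m)) m[1, 1, 1] <- TRUE
    roi <- roi_mask(m, grid, "cancer")
    for (d in c(4, 10)) {
      out <- expand_roi(roi, d)
      expect_identical(out$mask, oracle_expand_roi(m, grid$spacing, d))
    }
  }

  # superset, monotone in distance, identity at zero
  m <- array(runif(prod(grid$shape)) < 0.1, grid$shape)
  roi <- roi_mask(m, grid, "cancer")
  expect_identical(expand_roi(roi, 0)$mask, m)
  small <- expand_roi(roi, 5)$mask
  big <- expand_roi(roi, 11)$mask
  expect_true(all(small >= m))
  expect_true(all(big >= small))
  expect_error(expand_roi(roi_mask(array(FALSE, grid$shape), grid, "cancer")),
               "empty")
})

test_that("components are labelled like the flood-fill oracle at all connectivities", {
  set.seed(19)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:3) {
      m <- array(runif(9 * 8 * 5) < 0.35, c(9, 8, 5))
      lab <- label_components(m, conn)
      oracle <- oracle_label_components(m, conn)
      # same partition (labels may differ): check via cross-tabulation
      expect_equal(max(lab), max(oracle))
      if (any(m)) {
        tab <- table(lab[m], oracle[m])
        expect_true(all(rowSums(tab > 0) == 1))
        expect_true(all(colSums(tab > 0) == 1))
      }
      expect_true(all((lab > 0) == m))
    }
  }
})

test_that("largest_component takes max cardinality with a deterministic tie-break", {
  grid <- dwi_grid(c(12, 6, 3))
  m <- array(FALSE, grid$shape)
  m[1:5, 1, 1] <- TRUE                   # 5 voxels
  m[1:3, 4:6, 2] <- TRUE                 # 9 voxels
  region <- roi_mask(array(TRUE, grid$shape), grid, "tumor_containing")
  comp <- largest_component(m, region, 26)
  expect_equal(sum(comp), 9)
  expect_true(all(comp[1:3, 4:6, 2]))

  # empty intersection
  empty_region <- roi_mask(array(FALSE, grid$shape), grid, "tumor_containing")
  expect_equal(sum(largest_component(m, empty_region, 26)), 0)

  # tie: two 4-voxel components; the one with the smaller linear index wins
  m2 <- array(FALSE, grid$shape)
  m2[1:4, 1, 1] <- TRUE
  m2[1:4, 1, 3] <- TRUE
  comp2 <- largest_component(m2, region, 26)
  expect_true(all(comp2[1:4, 1, 1]) && !any(comp2[, , 3]))

  # random mask: component returned is a component of the oracle labelling
  # with maximal size
  set.seed(4)
  m3 <- array(runif(prod(grid$shape)) < 0.3, grid$shape)
  comp3 <- largest_component(m3, region, 6)
  oracle <- oracle_label_components(m3, 6)
  expect_equal(sum(comp3), max(tabulate(oracle[oracle > 0])))
  expect_equal(length(unique(oracle[comp3])), 1)
})

test_that("attach_connected_growth absorbs exactly the touching components", {
  grid <- dwi_grid(c(14, 8, 4))
  region_mask <- array(FALSE, grid$shape); region_mask[3:6, 3:6, 2] <- TRUE
  region <- roi_mask(region_mask, grid, "tumor_containing")

  expect_identical(attach_connected_growth(region,
                                           array(FALSE, grid$shape))$mask,
                   region_mask)

  # component straddling the region boundary is absorbed in full
  classified <- array(FALSE, grid$shape)
  classified[5:10, 4, 2] <- TRUE     # starts inside, extends out
  classified[13:14, 8, 4] <- TRUE    # detached, must be ignored
  grown <- attach_connected_growth(region, classified, 26)
  expect_true(all(grown$mask[5:10, 4, 2]))
  expect_false(any(grown$mask[13:14, 8, 4]))
  expect_true(all(grown$mask[region_mask]))

  # random masks vs labelling oracle
  set.seed(27)
  cl <- array(runif(prod(grid$shape)) < 0.25, grid$shape)
  grown <- attach_connected_growth(region, cl, 26)
  oracle <- oracle_label_components(cl, 26)
  touching <- setdiff(unique(oracle[region_mask]), 0)
  expected <- region_mask | array(oracle %in% touching & oracle > 0,
                                  grid$shape)
  expect_identical(grown$mask, expected)
})

test_that("longest_diameter equals the all-pairs oracle and handles degenerate sets", {
  grid <- image_grid(c(20, 20, 8), c(0.625, 0.625, 2.4))
  expect_equal(longest_diameter(array(FALSE, grid$shape), grid), 0)
  single <- array(FALSE, grid$shape); single[4, 4, 2] <- TRUE
  expect_equal(longest_diameter(single, grid), 0)

  # two voxels 4 in-plane steps apart at 0.625 mm spacing -> 0.25 cm
  two <- array(FALSE, grid$shape); two[3, 5, 2] <- TRUE; two[7, 5, 2] <- TRUE
  expect_equal(longest_diameter(two, grid), 0.25)

  set.seed(55)
  for (rep in 1:5) {
    m <- array(FALSE, grid$shape)
    m[sample(prod(grid$shape), 40)] <- TRUE
    expect_equal(longest_diameter(m, grid),
                 oracle_longest_diameter(m, grid$spacing), tolerance = 1e-12)
  }

  # boundary-reduction path (n > 600) agrees with the direct computation
  grid2 <- dwi_grid(c(16, 16, 8))
  big <- array(runif(prod(grid2$shape)) < 0.5, grid2$shape)
  expect_gt(sum(big), 600)
  ijk <- arrayInd(which(big), grid2$shape)
  direct <- max(stats::dist(sweep(ijk - 1, 2, grid2$spacing, `*`))) / 10
  expect_equal(longest_diameter(big, grid2), direct, tolerance = 1e-12)
})

test_that("axial mode restricts diameter pairs to a shared slice", {
  grid <- dwi_grid(c(10, 10, 4))
  m <- array(FALSE, grid$shape)
  m[2, 2, 1] <- TRUE; m[8, 2, 1] <- TRUE   # 15 mm apart in-plane
  m[2, 2, 4] <- TRUE                        # adds a long oblique 3D chord
  expect_equal(longest_diameter(m, grid, plane = "axial"), 1.5)
  expect_gt(longest_diameter(m, grid), 1.5)
  # oracle: per-slice all-pairs maximum
  set.seed(77)
  m2 <- array(runif(prod(grid$shape)) < 0.1, grid$shape)
  per_slice <- 0
  for (k in 1:4) {
    sl <- m2[, , k, drop = FALSE]
    if (sum(sl) < 2) next
    sl3 <- array(FALSE, grid$shape); sl3[, , k] <- sl
    per_slice <- max(per_slice, oracle_longest_diameter(sl3, grid$spacing))
  }
  expect_equal(longest_diameter(m2, grid, plane = "axial"), per_slice)
})

test_that("adjacent attachment also absorbs face-touching components", {
  grid <- dwi_grid(c(12, 6, 3))
  region_mask <- array(FALSE, grid$shape); region_mask[3:5, 3:5, 2] <- TRUE
  region <- roi_mask(region_mask, grid, "tumor_containing")
  classified <- array(FALSE, grid$shape)
  classified[6:9, 3, 2] <- TRUE   # face-adjacent to the region, no overlap
  inter <- attach_connected_growth(region, classified, 26, "intersect")
  expect_false(any(inter$mask[6:9, 3, 2]))
  adj <- attach_connected_growth(region, classified, 26, "adjacent")
  expect_true(all(adj$mask[6:9, 3, 2]))
})

test_that("diameter grows monotonically and respects axis permutation", {
  grid <- dwi_grid(c(10, 10, 5))
  set.seed(66)
  m <- array(FALSE, grid$shape)
  m[sample(prod(grid$shape), 25)] <- TRUE
  d0 <- longest_diameter(m, grid)
  m2 <- m; m2[which(!m)[1:10]] <- TRUE
  expect_gte(longest_diameter(m2, grid), d0)

  # permute axes together with spacing: diameter invariant
  perm <- aperm(m, c(3, 1, 2))
  gridp <- image_grid(grid$shape[c(3, 1, 2)], grid$spacing[c(3, 1, 2)])
  expect_equal(longest_diameter(perm, gridp), d0, tolerance = 1e-12)
})

test_that("measure_timepoint composes the geometric steps faithfully", {
  grid <- dwi_grid(c(24, 24, 10))
  # ellipsoidal high-probability tumor with semi-axes (10, 6, 6) mm
  prob_arr <- array(0, grid$shape)
  center <- c(30, 30, 25)
  for (lin in seq_len(prod(grid$shape))) {
    v <- (arrayInd(lin, grid$shape) - 1) * grid$spacing
    if (sum(((v - center) / c(10, 6, 6))^2) <= 1) prob_arr[lin] <- 0.95
  }
  prob <- structure(list(prob = prob_arr, grid = grid),
                    class = "probability_map")
  pre <- roi_mask(prob_arr > 0.5, grid, "cancer")
  meas <- measure_timepoint(prob, pre)
  expect_equal(meas$diameter_cm, 2.0,
               tolerance = sqrt(sum(grid$spacing^2)) / 10 / 2.0)
  expect_true(all(meas$component_mask[pre$mask]))
  expect_true(all(!meas$component_mask | meas$region_mask))

  # zero probability map -> 0 cm, 0 voxels
  zero <- structure(list(prob = array(0, grid$shape), grid = grid),
                    class = "probability_map")
  m0 <- measure_timepoint(zero, pre)
  expect_equal(m0$diameter_cm, 0)
  expect_equal(m0$n_voxels, 0)

  # equals the step-by-step manual composition
  region <- expand_roi(pre, 10)
  classified <- classify_map(prob, 0.5)
  region <- attach_connected_growth(region, classified, 26)
  comp <- largest_component(classified, region, 26)
  expect_identical(meas$component_mask, comp)
  expect_equal(meas$diameter_cm, longest_diameter(comp, grid))
})
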