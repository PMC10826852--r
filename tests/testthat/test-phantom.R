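test_that("2D phantom meets its construction contract", {
  m <- build_phantom(head_phantom_spec(
    radii = c(0.09, 0.085, 0.078, 0.076), n_electrodes = 16L), "coarse")
  expect_setequal(unique(m$tissue), c("scalp", "skull", "csf", "brain"))
  expect_equal(sort(unique(m$electrode[m$electrode > 0])), 1:16)
  # hemorrhage shells nested and labelled with the spec diameters
  expect_true(all(stats::na.omit(unique(m$hemorrhage_d)) %in%
                    seq(0.010, 0.030, 0.005)))
  # shells only inside the brain layer
  expect_true(all(m$tissue[!is.na(m$hemorrhage_d)] == "brain"))
})

test_that("3D phantom places 32 disjoint electrode patches", {
  m3 <- build_phantom(head_phantom_spec(dimension = 3, n_electrodes = 32L),
                      "coarse")
  tab <- table(m3$electrode[m3$electrode > 0])
  expect_length(tab, 32L)            # every electrode owns >= 1 facet
  expect_true(all(tab >= 1))
  # facet sets are disjoint by construction (one label per facet); volumes
  expect_lt(abs(mesh_volume(m3) - 4 / 3 * pi * 0.09^3) /
              (4 / 3 * pi * 0.09^3), 0.01)
})

test_that("infeasible hemorrhage geometry is rejected", {
  expect_error(head_phantom_spec(hemorrhage_center = c(0, 0.080)),
               "inside the brain layer")
  expect_error(head_phantom_spec(hemorrhage_center = c(0, 0.070)),
               "fully inside")
  expect_error(head_phantom_spec(radii = c(0.09, 0.085, 0.085, 0.076)),
               "decreasing")
})

test_that("hemorrhage-labelled volume converges to the sphere volume", {
  # 2D: disc area within 2% at moderate density
  m <- build_phantom(head_phantom_spec(), "medium")
  g <- mesh_geometry(m)
  area <- sum(g$vol[!is.na(m$hemorrhage_d) & m$hemorrhage_d <= 0.030])
  expect_lt(abs(area - pi * 0.03^2 / 4) / (pi * 0.03^2 / 4), 0.02)
  # 3D: within 2% with a hemorrhage-refined grid
  m3 <- build_phantom(head_phantom_spec(dimension = 3), 0.018)
  g3 <- mesh_geometry(m3)
  vol <- sum(g3$vol[!is.na(m3$hemorrhage_d) & m3$hemorrhage_d <= 0.030])
  expect_lt(abs(vol - pi * 0.03^3 / 6) / (pi * 0.03^3 / 6), 0.02)
})

test_that("conductivity assignment maps tissues and hemorrhage states", {
  m <- small_mesh()
  healthy <- assign_conductivity(m, state = "healthy")
  # no node at blood value; brain background is white matter (cortical)
  expect_true(all(healthy$element_values != 0.70))
  expect_true(any(abs(healthy$element_values - 0.06) < 1e-12))
  # deep location displaces gray matter
  md <- build_phantom(head_phantom_spec(location = "deep"), "coarse")
  hd <- assign_conductivity(md, state = "healthy")
  expect_true(any(abs(hd$element_values - 0.10) < 1e-12))
  # 30 mm state: all shells become blood
  s30 <- assign_conductivity(m, state = 0.030)
  sel <- !is.na(m$hemorrhage_d)
  expect_true(all(s30$element_values[sel] == 0.70))
  # determinism
  expect_identical(assign_conductivity(m, state = 0.020)$values,
                   assign_conductivity(m, state = 0.020)$values)
  # unknown state rejected
  expect_error(assign_conductivity(m, state = 0.033), "diameters")
})

test_that("conductivity assignment is monotone in hemorrhage diameter", {
  m <- small_mesh()
  v1 <- assign_conductivity(m, state = 0.020)$values
  v2 <- assign_conductivity(m, state = 0.030)$values
  changed <- which(abs(v2 - v1) > 0)
  # nodes that changed belong to elements inside the 30 mm sphere
  dist <- sqrt((m$nodes[changed, 1] - 0)^2 + (m$nodes[changed, 2] - 0.055)^2)
  h <- 2 * pi * 0.09 / 40
  expect_true(all(dist <= 0.015 + h))
  expect_true(all(v2 >= v1 - 1e-15))
})

test_that("reference image thresholds layer interfaces and defines the ROI", {
  m <- small_mesh()
  ref <- make_reference(m, threshold_frac = 0.5, gamma1 = 0.01)
  g <- mesh_geometry(m)
  # brute-force per-element gradient of kappa
  grad <- cbind(as.vector(g$D[[1]] %*% ref$kappa),
                as.vector(g$D[[2]] %*% ref$kappa))
  gn <- sqrt(rowSums(grad^2))
  expect_equal(ref$gamma == 0.01, gn >= 0.5 * max(gn))
  # unit directions where the gradient exists, zero where it vanishes
  expect_equal(rowSums(ref$nu^2)[gn > 1e-12], rep(1, sum(gn > 1e-12)))
  expect_true(all(ref$nu[gn <= 1e-12, ] == 0))
  # ROI is the brain compartment
  expect_true(all(m$tissue[ref$roi_elements] == "brain"))
  expect_gt(length(ref$roi_nodes), 0)
})

test_that("weighting tensor has eigenvalue gamma1 along the edge normal", {
  m <- small_mesh()
  ref <- make_reference(m, gamma1 = 0.01)
  e <- which(ref$gamma == 0.01)[1]
  B <- diag(2) - (1 - 0.01) * tcrossprod(ref$nu[e, ])
  ev <- eigen(B, symmetric = TRUE)$values
  expect_equal(sort(ev), c(0.01, 1))
})

test_that("constant reference image degrades gracefully", {
  m <- small_mesh()
  m2 <- m
  m2$tissue <- rep("brain", length(m$tissue))
  m2$geom <- m$geom
  expect_warning(ref <- make_reference(m2), "constant")
  expect_true(all(ref$gamma == 1))
  expect_true(all(ref$nu == 0))
})
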