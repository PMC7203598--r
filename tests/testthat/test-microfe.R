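test_that("model construction maps voxels to elements and nodes", {
  bar <- makeFixture("bar", c(1, 1, 10), spacing = 40)
  mod <- buildFEModel(bar, nu = 0)
  expect_equal(nrow(mod@elems), 10)
  expect_equal(nrow(mod@nodeIJK), 2 * 2 * 11) # 44 nodes
  tube <- phantomMask(cleanSpec)
  modT <- buildFEModel(tube)
  expect_equal(nrow(modT@elems), sum(imgData(tube)))
  # detached voxel refused with a pointer to largestComponent
  m <- array(FALSE, c(6, 6, 6))
  m[2:3, 2:3, 2:4] <- TRUE
  m[6, 6, 6] <- TRUE
  expect_error(buildFEModel(BoneMask(m, 40)), "largestComponent")
  expect_error(buildFEModel(BoneMask(array(FALSE, c(2, 2, 2)), 40)), "empty")
})

test_that("axial bar matches the closed-form FL/EA tip displacement", {
  E <- 14.8e9
  for (N in c(10, 50)) {
    bar <- makeFixture("bar", c(1, 1, N), spacing = 40)
    mod <- buildFEModel(bar, E = E, nu = 0)
    f <- solveUnitLoads(mod, "si")$si
    h <- 40e-6
    uExpect <- 1 * (N * h) / (E * h^2)
    distal <- mod@nodeType == 2L
    expect_lt(abs(mean(f@values[distal, 3]) - uExpect) / uExpect, 1e-6)
    # proximal nodes are fixed
    expect_true(all(f@values[mod@nodeType == 1L, ] == 0))
  }
})

test_that("solver respects linearity: zero load and load negation", {
  bar <- makeFixture("bar", c(2, 2, 8), spacing = 40)
  mod <- buildFEModel(bar)
  z <- solveLoad(mod, c(ml = 0, ap = 0, si = 0))
  expect_true(all(z@values == 0))
  up <- solveLoad(mod, c(ml = 0, ap = 0, si = 1))
  dn <- solveLoad(mod, c(ml = 0, ap = 0, si = -1))
  expect_equal(dn@values, -up@values, tolerance = 1e-6)
})

test_that("distal coupling enforces one shared translation without rotation", {
  # eccentric section: an L-shaped column, so axial load induces bending
  m <- array(FALSE, c(4, 4, 12))
  m[1:3, 1, 1:12] <- TRUE
  m[1, 1:3, 1:12] <- TRUE
  mod <- buildFEModel(BoneMask(m, 40))
  f <- solveUnitLoads(mod, "si")$si
  distal <- f@values[mod@nodeType == 2L, , drop = FALSE]
  for (c in 1:3)
    expect_lt(diff(range(distal[, c])), 1e-12 * max(1e-12, max(abs(distal))))
})

test_that("superposed combined load equals a direct combined solve", {
  mod <- buildFEModel(tinyMask)
  units <- solveUnitLoads(mod, c("ap", "si"), tol = 1e-10)
  load <- physiologicalLoad(20)
  sup <- superpose(units, load)
  direct <- solveLoad(mod, load, tol = 1e-10)
  scale <- max(abs(direct@values))
  expect_lt(max(abs(sup@values - direct@values)) / scale, 1e-5)
  # identity and homogeneity of superposition
  expect_equal(superpose(units, c(ml = 0, ap = 0, si = 1))@values,
               units$si@values)
  expect_equal(superpose(units, c(ml = 0, ap = 0, si = 2))@values,
               2 * units$si@values)
  expect_error(superpose(units, c(ml = 1, ap = 0, si = 0)), "missing")
})

test_that("physiological load follows the per-gram coefficients", {
  l20 <- physiologicalLoad(20)
  expect_equal(unname(l20), c(0, 0.0578, 0.271), tolerance = 1e-12)
  # linear in body mass over the study's 16-22 g range
  expect_equal(unname(physiologicalLoad(22) / physiologicalLoad(16))[2:3],
               rep(22 / 16, 2))
  expect_error(physiologicalLoad(0), "positive")
  expect_error(physiologicalLoad(-5), "positive")
})

test_that("surface nodes are exactly those on unshared element faces", {
  single <- buildFEModel(makeFixture("bar", c(1, 1, 2), spacing = 40), nu = 0)
  # a 1x1x2 column: every node lies on an exposed face
  expect_equal(length(surfaceNodes(single)), nrow(single@nodeIJK))
  cube <- buildFEModel(makeFixture("cube", c(3, 3, 3), spacing = 40))
  sn <- surfaceNodes(cube)
  # brute force: mark the 4 nodes of every element face whose neighbouring
  # voxel is absent
  m <- array(TRUE, c(3, 3, 3))
  ref <- array(FALSE, c(4, 4, 4))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
      inside <- ii >= 1 && ii <= 3 && jj >= 1 && jj <= 3 && kk >= 1 && kk <= 3
      if (inside && m[ii, jj, kk]) next
      # exposed face: its 4 corner nodes
      fix <- which(d != 0)
      perp <- which(d == 0)
      for (u in 0:1) for (v in 0:1) {
        nn <- c(i, j, k)
        nn[fix] <- nn[fix] + if (d[fix] > 0) 1 else 0
        nn[perp[1]] <- nn[perp[1]] + u
        nn[perp[2]] <- nn[perp[2]] + v
        ref[nn[1], nn[2], nn[3]] <- TRUE
      }
    }
  }
  gotIJK <- cube@nodeIJK[sn, , drop = FALSE] + 1L
  got <- array(FALSE, c(4, 4, 4))
  got[gotIJK] <- TRUE
  expect_identical(got, ref)
  expect_equal(length(sn), 64 - 8) # all nodes except the 2x2x2 interior core
})

test_that("hollow tube surface nodes split into outer and inner shells", {
  ann <- makeFixture("annulus", c(20, 20, 6), outer = 7, inner = 4,
                     spacing = 40)
  mod <- buildFEModel(ann)
  sn <- surfaceNodes(mod)
  ijk <- mod@nodeIJK[sn, , drop = FALSE]
  # annulus centre sits at node coordinate 10.5 (voxel centres at i - 0.5)
  r <- sqrt((ijk[, 1] - 10.5)^2 + (ijk[, 2] - 10.5)^2)
  # shells: surface nodes cluster near the inner (r ~ 4) and outer (r ~ 7)
  # walls; none sit strictly mid-wall on interior slices
  expect_gt(sum(r < 5), 0)
  expect_gt(sum(r > 6), 0)
  mid <- ijk[, 3] %in% 2:4 & r > 5.2 & r < 5.8
  expect_equal(sum(mid), 0)
})

test_that("uniform axial strain reproduces the closed-form SED and principal strain", {
  E <- 14.8e9
  eps <- 1e-4
  cube <- buildFEModel(makeFixture("cube", c(3, 3, 3), spacing = 40),
                       E = E, nu = 0)
  u <- matrix(0, nrow(cube@nodeIJK), 3)
  u[, 3] <- cube@nodeIJK[, 3] * 40e-6 * eps
  uf <- new("DisplacementField", values = u, load = c(ml = 0, ap = 0, si = 0),
            iters = 0L, relres = 0)
  sed <- computeStimulusField(cube, uf, "sed")
  expect_equal(unname(sed@values), rep(E * eps^2 / 2, length(sed@values)),
               tolerance = 1e-10)
  # with nu = 0.3 the laterally constrained modulus applies instead of E
  nu <- 0.3
  cube3 <- buildFEModel(makeFixture("cube", c(3, 3, 3), spacing = 40),
                        E = E, nu = nu)
  sed3 <- computeStimulusField(cube3, uf, "sed")
  M <- E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))
  expect_equal(unname(sed3@values), rep(M * eps^2 / 2, length(sed3@values)),
               tolerance = 1e-10)
  # compressive uniform strain with zero lateral strain: max principal = 0
  ufc <- new("DisplacementField", values = -u, load = c(ml = 0, ap = 0, si = 0),
             iters = 0L, relres = 0)
  mp <- computeStimulusField(cube3, ufc, "maxprinc")
  # zero up to eigen-solver roundoff (values are in microstrain)
  expect_equal(unname(mp@values), rep(0, length(mp@values)),
               tolerance = 1e-5)
  # tensile case: max principal equals eps (in microstrain)
  mpT <- computeStimulusField(cube3, uf, "maxprinc")
  expect_equal(unname(mpT@values), rep(eps * 1e6, length(mpT@values)),
               tolerance = 1e-8)
  # zero displacement -> zero stimulus
  z <- new("DisplacementField", values = 0 * u, load = c(ml = 0, ap = 0, si = 0),
           iters = 0L, relres = 0)
  expect_true(all(computeStimulusField(cube3, z, "sed")@values == 0))
})

test_that("stiffness action is symmetric and vanishes for rigid translations", {
  mod <- buildFEModel(makeFixture("cube", c(3, 3, 4), spacing = 40))
  nn <- nrow(mod@nodeIJK)
  set.seed(21)
  for (rep in 1:3) {
    u <- matrix(rnorm(3 * nn), nn, 3)
    v <- matrix(rnorm(3 * nn), nn, 3)
    Ku <- BoneAdapt:::.k_apply(mod@elems, nn, mod@ke, u)
    Kv <- BoneAdapt:::.k_apply(mod@elems, nn, mod@ke, v)
    expect_equal(sum(v * Ku), sum(u * Kv), tolerance = 1e-9)
  }
  tr <- matrix(rep(c(1e-3, -2e-3, 5e-4), each = nn), nn, 3)
  Kt <- BoneAdapt:::.k_apply(mod@elems, nn, mod@ke, tr)
  expect_lt(max(abs(Kt)), 1e-9 * max(abs(mod@ke)) * 1e-3)
})

test_that("SED is non-negative and total strain energy positive under load", {
  mod <- buildFEModel(tinyMask)
  units <- solveUnitLoads(mod, c("ap", "si"))
  load <- physiologicalLoad(19)
  u <- superpose(units, load)
  st <- computeStimulusField(mod, u, "sed")
  expect_true(all(st@values >= 0))
  expect_gt(strainEnergy(mod, u), 0)
})
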