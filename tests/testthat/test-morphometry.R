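# Profiles, AUC density proxies, spline geometry and their invariances.

constImage <- function(value, n = 128, mmPerPx = NA) {
  Radiograph(matrix(value, n, n), mmPerPx = mmPerPx)
}

test_that("profile of a constant field is constant", {
  img <- constImage(7)
  prof <- profileCurve(img, c(10, 40), c(60, 90), widthPx = 5)
  expect_true(all(abs(prof$values - 7) < 1e-12))
  expect_equal(prof$unit, "px")
})

test_that("a linear ramp is its own profile", {
  m <- matrix(rep(0:127, each = 128), 128, 128)  # I(x, y) = x
  img <- Radiograph(m)
  prof <- profileCurve(img, c(10, 50), c(20, 50), widthPx = 3)
  expect_equal(prof$values, 10 + prof$positions, tolerance = 1e-6)
})

test_that("wide-line profile matches a naive dense-sampling oracle", {
  set.seed(9)
  img <- Radiograph(matrix(runif(128 * 128), 128, 128))
  start <- c(20.3, 30.7)
  end <- c(80.1, 95.2)
  width <- 9
  prof <- profileCurve(img, start, end, widthPx = width)
  # independent loop implementation with 0.1 px perpendicular spacing
  u <- (end - start) / sqrt(sum((end - start)^2))
  v <- c(-u[2], u[1])
  offs <- seq(-width / 2, width / 2, length.out = round(width / 0.1) + 1)
  px <- pixels(img)
  oracle <- sapply(prof$positions, function(p) {
    acc <- 0
    for (w in offs) {
      pt <- start + p * u + w * v
      x0 <- floor(pt[1]); y0 <- floor(pt[2])
      fx <- pt[1] - x0; fy <- pt[2] - y0
      acc <- acc + (1 - fy) * ((1 - fx) * px[y0 + 1, x0 + 1] +
                               fx * px[y0 + 1, x0 + 2]) +
                   fy * ((1 - fx) * px[y0 + 2, x0 + 1] +
                         fx * px[y0 + 2, x0 + 2])
    }
    acc / length(offs)
  })
  expect_lt(max(abs(prof$values - oracle)), 1e-3)
})

test_that("profile regions exiting the image name the overflow side", {
  img <- constImage(1)
  expect_error(profileCurve(img, c(120, 50), c(130, 50)), "right")
  expect_error(profileCurve(img, c(50, 126), c(60, 126), widthPx = 9),
               "bottom")
})

test_that("profile AUC does trapezoid arithmetic and is linear", {
  p <- structure(list(positions = 0:2, values = c(1, 2, 3), step = 1,
                      unit = "px"), class = "IntensityProfile")
  expect_equal(profileAuc(p), 4.0)
  # constant c over span L -> c * L
  img <- constImage(3)
  prof <- profileCurve(img, c(10, 50), c(30, 50), widthPx = 5)
  expect_equal(profileAuc(prof), 3 * 20, tolerance = 1e-9)
  p2 <- p
  p2$values <- 2 * p2$values
  expect_equal(profileAuc(p2), 2 * profileAuc(p))
})

test_that("spline length: straight segments and collinear points", {
  sp <- keelSplineLength(rbind(c(0, 0), c(3, 4)))
  expect_equal(sp$length, 5)
  expect_equal(sp$midpoint, c(1.5, 2.0))
  pts <- cbind(seq(0, 10, length.out = 5), 0)
  expect_equal(keelSplineLength(pts)$length, 10, tolerance = 1e-6)
})

test_that("spline length of a quarter circle is within 1% of analytic", {
  theta <- seq(0, pi / 2, length.out = 9)
  pts <- cbind(100 * cos(theta), 100 * sin(theta))
  sp <- keelSplineLength(pts)
  expect_lt(abs(sp$length - 100 * pi / 2) / (100 * pi / 2), 0.01)
})

test_that("keel geometry forms the ratio and guards degenerate input", {
  img <- constImage(1)
  ann <- KeelAnnotation("g",
    tibiotarsalLine = rbind(c(1, 1), c(10, 1)),
    keelPolyline = rbind(c(10, 10), c(60, 10), c(110, 10)),
    middepthLine = rbind(c(60, 0), c(60, 20)),
    cranialdepthLine = rbind(c(10, 0), c(10, 20)),
    densityAnchor = list(point = c(10, 10), direction = c(1, 0)))
  geo <- keelGeometry(img, ann)
  expect_equal(geo$length, 100, tolerance = 1e-6)
  expect_equal(geo$midDepth, 20)
  expect_equal(geo$xlm, 5, tolerance = 1e-6)
  # length = mid-depth -> ratio 1
  ann2 <- ann
  ann2@middepthLine <- rbind(c(60, 10), c(60, 110))
  expect_equal(keelGeometry(img, ann2)$xlm, 1, tolerance = 1e-6)
  # a mid-depth line missing the spline midpoint draws a warning
  annW <- ann
  annW@middepthLine <- rbind(c(90, 30), c(90, 50))
  expect_warning(keelGeometry(img, annW), "midpoint")
  ann3 <- ann
  ann3@middepthLine <- rbind(c(60, 10), c(60, 10))
  expect_error(keelGeometry(img, ann3), "zero length")
})

test_that("tibiotarsal density recovers the band closed form and scales
          with bone width", {
  # two uniform vertical bands, the second twice as wide (edges on
  # half-pixel boundaries: x in [59.5, 99.5] and [59.5, 139.5])
  line <- function(x0, x1, y) rbind(c(x0, y), c(x1, y))
  mk <- function(tl) KeelAnnotation("t", tibiotarsalLine = tl,
    keelPolyline = rbind(c(10, 10), c(20, 10)),
    middepthLine = rbind(c(10, 5), c(10, 15)),
    cranialdepthLine = rbind(c(10, 5), c(10, 15)),
    densityAnchor = list(point = c(10, 10), direction = c(1, 0)))
  mA <- matrix(0, 200, 200)
  mA[, 61:100] <- 30
  mB <- matrix(0, 200, 200)
  mB[, 61:140] <- 30
  bandA <- Radiograph(mA)
  bandB <- Radiograph(mB)
  # user line fully inside the wide band -> AUC = level * length
  inside <- tibiotarsalDensity(bandB, mk(line(65, 95, 100)))
  expect_equal(as.numeric(inside), 30 * 30, tolerance = 0.005 * 30 * 30)
  # drawn across the bone (small margin past both edges): a bone twice as
  # wide doubles the AUC
  a1 <- tibiotarsalDensity(bandA, mk(line(57, 102, 100)))
  a2 <- tibiotarsalDensity(bandB, mk(line(57, 142, 100)))
  expect_equal(as.numeric(a1), 30 * 40, tolerance = 0.005 * 30 * 40)
  expect_equal(as.numeric(a2) / as.numeric(a1), 2, tolerance = 0.01)
  # width-normalized variant removes the width dependence
  n1 <- tibiotarsalDensity(bandA, mk(line(59.5, 99.5, 100)),
                           widthNormalized = TRUE)
  n2 <- tibiotarsalDensity(bandB, mk(line(59.5, 139.5, 100)),
                           widthNormalized = TRUE)
  expect_equal(as.numeric(n1), as.numeric(n2), tolerance = 0.01)
})

test_that("keel density realizes 10 mm via spacing and errors without it", {
  ph <- testPhantom(noiseSd = 0)
  kd <- keelDensity(ph$image, ph$annotation)
  expect_equal(as.numeric(kd), ph$truth$keelDensity,
               tolerance = 0.005 * ph$truth$keelDensity)
  # zero image -> 0
  z <- Radiograph(matrix(0, 128, 128), mmPerPx = 0.2)
  annZ <- KeelAnnotation("z",
    tibiotarsalLine = rbind(c(1, 1), c(10, 1)),
    keelPolyline = rbind(c(10, 10), c(20, 10)),
    middepthLine = rbind(c(10, 5), c(10, 15)),
    cranialdepthLine = rbind(c(10, 5), c(10, 15)),
    densityAnchor = list(point = c(20, 64), direction = c(1, 0)))
  expect_equal(as.numeric(keelDensity(z, annZ)), 0)
  zNo <- Radiograph(matrix(0, 128, 128))
  expect_error(keelDensity(zNo, annZ), "cannot realize")
})

test_that("background correction subtracts the pedestal and clamps", {
  img <- constImage(2)
  ann <- KeelAnnotation("b",
    tibiotarsalLine = rbind(c(1, 1), c(10, 1)),
    keelPolyline = rbind(c(10, 10), c(20, 10)),
    middepthLine = rbind(c(10, 5), c(10, 15)),
    cranialdepthLine = rbind(c(10, 5), c(10, 15)),
    densityAnchor = list(point = c(20, 64), direction = c(1, 0)),
    backgroundRegion = c(40, 40, 60, 60))
  out <- backgroundCorrect(100, img, ann, regionLength = 10)
  expect_equal(as.numeric(out), 80)
  expect_equal(attr(out, "backgroundLevel"), 2)
  # clamp at zero
  expect_equal(as.numeric(backgroundCorrect(10, img, ann, 10)), 0)
  # absent region: unchanged with a warning
  ann0 <- ann
  ann0@backgroundRegion <- numeric(0)
  expect_warning(out0 <- backgroundCorrect(100, img, ann0, 10),
                 "no background region")
  expect_equal(as.numeric(out0), 100)
})

test_that("measurements are 90-degree rotation equivariant", {
  ph <- testPhantom(noiseSd = 0)
  m0 <- measureRadiograph(ph$image, ph$annotation)
  imgR <- keelmetry:::rotateRadiograph90(ph$image)
  annR <- keelmetry:::rotateAnnotation90(ph$annotation,
                                         ncol(pixels(ph$image)))
  mR <- measureRadiograph(imgR, annR)
  for (v in c("tibiotarsal_density", "keel_density", "keel_length_px",
              "keel_mid_depth_px", "keel_cranial_depth_px", "xlm")) {
    expect_equal(mR[[v]], m0[[v]], tolerance = 0.005, label = v)
  }
})

test_that("density measures are linear in pixel intensity", {
  ph <- testPhantom(noiseSd = 0)
  img2 <- Radiograph(3 * pixels(ph$image), mmPerPx = mmPerPx(ph$image))
  m1 <- measureRadiograph(ph$image, ph$annotation)
  m2 <- measureRadiograph(img2, ph$annotation)
  expect_equal(m2$tibiotarsal_density, 3 * m1$tibiotarsal_density,
               tolerance = 1e-9)
  expect_equal(m2$keel_density, 3 * m1$keel_density, tolerance = 1e-9)
  # geometry untouched
  expect_equal(m2$xlm, m1$xlm)
})

test_that("annotation jitter keeps test-retest correlation high", {
  # 50 phantoms, two measurement rounds with N(0, 1 px) keypoint jitter;
  # mirrors the human repeat-measurement design as a property
  set.seed(77)
  jitterAnn <- function(ann) {
    jit <- function(m) m + matrix(rnorm(length(m)), nrow(m), ncol(m))
    KeelAnnotation(ann@imageId,
                   tibiotarsalLine = jit(ann@tibiotarsalLine),
                   keelPolyline = jit(ann@keelPolyline),
                   middepthLine = jit(ann@middepthLine),
                   cranialdepthLine = jit(ann@cranialdepthLine),
                   densityAnchor = list(
                     point = ann@densityAnchor$point + rnorm(2),
                     direction = ann@densityAnchor$direction),
                   backgroundRegion = ann@backgroundRegion)
  }
  keep <- c("tibiotarsal_density", "keel_density", "keel_length_px",
            "keel_mid_depth_px", "xlm")
  r1 <- list()
  r2 <- list()
  for (i in 1:50) {
    ph <- makePhantom(randomPhantomSpec(3000 + i))
    r1[[i]] <- measureRadiograph(ph$image, jitterAnn(ph$annotation))
    r2[[i]] <- measureRadiograph(ph$image, jitterAnn(ph$annotation))
  }
  r1 <- do.call(rbind, r1)
  r2 <- do.call(rbind, r2)
  for (v in keep) {
    expect_gte(cor(r1[[v]], r2[[v]]), 0.9)
  }
})
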