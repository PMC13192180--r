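# Soma markers, watershed territories, skeletonization, Sholl counting.

morphoFixture <- function(nCells, phenotype = "ramified", seed = 1,
                          fieldUm = c(160, 160))
  generateImagePair(imageGenSpec(fieldUm = fieldUm, nCells = nCells,
                                 phenotype = phenotype, seed = seed))

test_that("soma markers land on the true centers", {
  im <- morphoFixture(6, fieldUm = c(220, 220), seed = 14)
  mk <- findSomaMarkers(im$dapi, im$iba1)
  expect_equal(nrow(mk$centersPx), 6)
  tc <- im$truth$centersUm
  for (k in seq_len(6)) {
    d <- min(sqrt(rowSums(sweep(tc, 2, mk$centersUm[k, ])^2)))
    expect_lt(d, 4.5)   # within one soma radius
  }
})

test_that("a DAPI-only field yields no markers", {
  im <- morphoFixture(3, seed = 2)
  blank <- ChannelImage(matrix(0.02, nrow(im$iba1@pixels),
                               ncol(im$iba1@pixels)),
                        im$iba1@pixelUm, "Iba1")
  mk <- findSomaMarkers(im$dapi, blank)
  expect_equal(nrow(mk$centersPx), 0)
})

test_that("somata below the area cutoff are excluded", {
  im <- morphoFixture(4, seed = 3)
  mk <- findSomaMarkers(im$dapi, im$iba1, minSomaPx = 1e5)
  expect_equal(nrow(mk$centersPx), 0)
})

test_that("territories partition the dilated domain, one per marker", {
  im <- morphoFixture(4, seed = 4)
  mk <- findSomaMarkers(im$dapi, im$iba1)
  terr <- assignTerritories(im$iba1, mk, dilationPx = 60)
  lab <- territoryLabels(terr)
  expect_equal(nCells(terr), nrow(mk$centersPx))
  expect_setequal(unique(as.integer(lab)), 0:nCells(terr))
  # territories stay within the dilated-soma domain
  dist <- gliaSlice:::ebMat(EBImage::distmap(EBImage::Image(1 - mk$somaMask)))
  expect_true(all(dist[lab > 0] <= 60 + 1.5))
  # each marker's center lies in its own territory
  for (k in seq_len(nCells(terr))) {
    p <- round(mk$centersPx[k, ])
    expect_equal(lab[p[1], p[2]], k)
  }
})

test_that("two mirrored cells get territories of equal area", {
  # build a synthetic, exactly mirror-symmetric two-cell image
  n <- 301
  iba <- matrix(0.02, n, n)
  dap <- matrix(0.02, n, n)
  for (cy in c(101, 201)) {
    iba <- gliaSlice:::drawDisk(iba, 151, cy, 14, 0.85)
    dap <- gliaSlice:::drawDisk(dap, 151, cy, 12, 0.75)
    for (a in seq(0, 2 * pi, length.out = 5)[-5])
      iba <- gliaSlice:::drawSegment(iba, 151 + 14 * cos(a), cy + 14 * sin(a),
                                     151 + 60 * cos(a), cy + 60 * sin(a),
                                     3, 0.55)
  }
  di <- ChannelImage(dap, 0.31, "DAPI"); bi <- ChannelImage(iba, 0.31, "Iba1")
  mk <- findSomaMarkers(di, bi)
  expect_equal(nrow(mk$centersPx), 2)
  terr <- assignTerritories(bi, mk, dilationPx = 50)
  areas <- table(territoryLabels(terr)[territoryLabels(terr) > 0])
  expect_lt(abs(areas[1] - areas[2]) / mean(areas), 0.01)
})

test_that("skeletons are deterministic and capture branch length", {
  im <- morphoFixture(1, fieldUm = c(120, 120), seed = 6)
  mk <- findSomaMarkers(im$dapi, im$iba1)
  terr <- assignTerritories(im$iba1, mk)
  s1 <- skeletonizeCell(im$iba1, terr, 1)
  s2 <- skeletonizeCell(im$iba1, terr, 1)
  expect_identical(s1$skeleton, s2$skeleton)
  # analytic case: four axis-aligned 40 um branches, so pixel count times
  # pixel size measures length without diagonal-step bias; light blur and
  # noise make the intensity histogram realistic for the auto-threshold
  px <- 0.31
  n <- 451
  somaRpx <- round(4.5 / px); armPx <- round(40 / px)
  iba <- gliaSlice:::drawDisk(matrix(0.02, n, n), 226, 226, somaRpx, 0.85)
  dap <- gliaSlice:::drawDisk(matrix(0.02, n, n), 226, 226,
                              0.9 * somaRpx, 0.75)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    iba <- gliaSlice:::drawSegment(iba,
      226 + d[1] * somaRpx, 226 + d[2] * somaRpx,
      226 + d[1] * (somaRpx + armPx), 226 + d[2] * (somaRpx + armPx),
      5, 0.55)
  iba <- gliaSlice:::ebMat(EBImage::gblur(EBImage::Image(iba), sigma = 1.3))
  dap <- gliaSlice:::ebMat(EBImage::gblur(EBImage::Image(dap), sigma = 1.3))
  set.seed(7)
  iba <- pmin(pmax(iba + rnorm(length(iba), 0, 0.01), 0), 1)
  dap <- pmin(pmax(dap + rnorm(length(dap), 0, 0.01), 0), 1)
  bi <- ChannelImage(iba, px, "Iba1"); di <- ChannelImage(dap, px, "DAPI")
  mkA <- findSomaMarkers(di, bi)
  # dilate wide enough that the territory does not clip the 44.5 um reach
  terrA <- assignTerritories(bi, mkA, dilationPx = 160)
  skA <- skeletonizeCell(bi, terrA, 1)
  skLenUm <- sum(skA$skeleton) * px
  # thinning runs the centerline through the soma: 4 x (arm + soma radius)
  expected <- 4 * (40 + 4.5)
  expect_gt(skLenUm, 0.85 * expected)
  expect_lt(skLenUm, 1.15 * expected)
})

test_that("a disk-only cell thins to a tiny near-center skeleton", {
  n <- 201
  iba <- gliaSlice:::drawDisk(matrix(0.02, n, n), 101, 101, 15, 0.85)
  dap <- gliaSlice:::drawDisk(matrix(0.02, n, n), 101, 101, 13, 0.75)
  bi <- ChannelImage(iba, 0.31, "Iba1"); di <- ChannelImage(dap, 0.31, "DAPI")
  mk <- findSomaMarkers(di, bi)
  terr <- assignTerritories(bi, mk, dilationPx = 40)
  sk <- skeletonizeCell(bi, terr, 1)
  expect_lt(sum(sk$skeleton), 20)
  w <- which(sk$skeleton, arr.ind = TRUE)
  if (nrow(w))
    expect_lt(max(sqrt((w[, 1] - 101)^2 + (w[, 2] - 101)^2)), 16)
})

test_that("Sholl counting matches the analytic plus-sign geometry", {
  sk <- plusSkeleton(armUm = 40, pixelUm = 1)
  prof <- sholl(sk, pixelUm = 1, stepUm = 5, rStartUm = 5)
  r <- shollRadii(prof); n <- shollCounts(prof)
  expect_true(all(n[r > 5 & r < 40] == 4))
  expect_true(all(n[r > 41] == 0))
  # straight line through the center: 2 crossings up to the half-length
  line <- list(skeleton = matrix(FALSE, 101, 101), centerPx = c(51, 51),
               cellId = 1L)
  line$skeleton[51, ] <- TRUE
  lp <- sholl(line, pixelUm = 1, stepUm = 5, rStartUm = 5, rMaxUm = 45)
  expect_true(all(shollCounts(lp) == 2))
  empty <- list(skeleton = matrix(FALSE, 51, 51), centerPx = c(26, 26),
                cellId = 1L)
  expect_true(all(shollCounts(sholl(empty, pixelUm = 1)) == 0))
})

test_that("pipeline is translation-equivariant", {
  im <- morphoFixture(2, fieldUm = c(140, 140), seed = 8)
  dx <- 13L; dy <- 7L
  shift <- function(m) {
    out <- matrix(0.02, nrow(m), ncol(m))
    out[(1 + dx):nrow(m), (1 + dy):ncol(m)] <-
      m[1:(nrow(m) - dx), 1:(ncol(m) - dy)]
    out
  }
  px <- im$iba1@pixelUm
  d2 <- ChannelImage(shift(im$dapi@pixels), px, "DAPI")
  b2 <- ChannelImage(shift(im$iba1@pixels), px, "Iba1")
  out1 <- morphometryPipeline(im$dapi, im$iba1)
  out2 <- morphometryPipeline(d2, b2)
  c1 <- somaCenters(out1$territories)
  c2 <- somaCenters(out2$territories)
  ord1 <- order(c1[, 1], c1[, 2]); ord2 <- order(c2[, 1], c2[, 2])
  expect_equal(unname(c2[ord2, ] - c1[ord1, ]),
               matrix(rep(c(dx, dy) * px, each = 2), 2), tolerance = 0.5)
  auc1 <- sort(vapply(out1$profiles, shollAuc, numeric(1)))
  auc2 <- sort(vapply(out2$profiles, shollAuc, numeric(1)))
  expect_equal(auc1, auc2, tolerance = 0.1 * max(auc1))
})

test_that("ramified fields have larger Sholl AUC than deramified", {
  r <- morphoFixture(2, "ramified", seed = 9)
  d <- morphoFixture(2, "deramified", seed = 9)
  aucR <- mean(vapply(morphometryPipeline(r$dapi, r$iba1)$profiles,
                      shollAuc, numeric(1)))
  aucD <- mean(vapply(morphometryPipeline(d$dapi, d$iba1)$profiles,
                      shollAuc, numeric(1)))
  expect_gt(aucR, aucD)
})

test_that("an empty field gives empty pipeline output", {
  im <- generateImagePair(imageGenSpec(fieldUm = c(100, 100), nCells = 0,
                                       nucleiDensity = 0, seed = 2))
  out <- morphometryPipeline(im$dapi, im$iba1)
  expect_null(out$territories)
  expect_length(out$profiles, 0)
})
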