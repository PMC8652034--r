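anchorsOf <- function(m) {
  a <- as.matrix(m)
  rownames(a) <- paste0("L", seq_len(nrow(a)))
  a
}

# independent oracle: exhaustive enumeration of all placements of the
# elements on a discrete grid, returning the minimum stress
gridOracle <- function(anchors, gridSide = 5L, spacing = NULL) {
  D <- as.matrix(dist(anchors))
  if (is.null(spacing)) spacing <- max(D) / (gridSide - 1L)
  pts <- expand.grid(x = (0:(gridSide - 1L)) * spacing,
                     y = (0:(gridSide - 1L)) * spacing)
  n <- nrow(anchors)
  stopifnot(n == 3L)  # enumeration is meant for tiny cases
  best <- Inf
  m <- nrow(pts)
  for (i in seq_len(m)) for (j in seq_len(m)) for (k in seq_len(m)) {
    p <- rbind(pts[i, ], pts[j, ], pts[k, ])
    d12 <- sqrt(sum((p[1, ] - p[2, ])^2))
    d13 <- sqrt(sum((p[1, ] - p[3, ])^2))
    d23 <- sqrt(sum((p[2, ] - p[3, ])^2))
    s <- (d12 - D[1, 2])^2 + (d13 - D[1, 3])^2 + (d23 - D[2, 3])^2
    if (s < best) best <- s
  }
  best
}

test_that("element anchors are axis midpoints and sheet centroids", {
  tab <- sse2d:::.emptySSETable()
  tab[1, ] <- list("H1", "helix", "A", 1L, 10L, 1L, 10L, 10L,
                   0, 0, 0, 0, 0, 10)
  tab[2, ] <- list("E1", "strand", "A", 15L, 19L, 15L, 19L, 5L,
                   -2, 0, 0, 2, 0, 0)
  tab[3, ] <- list("E2", "strand", "A", 23L, 27L, 23L, 27L, 5L,
                   2, 0, 0, 6, 0, 0)
  sheets <- list(S1 = new("SheetModel", sheetId = "S1",
                          strandLabels = c("E1", "E2"),
                          orientations = "parallel",
                          template = data.frame(label = c("E1", "E2"),
                                                ox = c(-2.4, 2.4), oy = 0,
                                                sign = c(1L, 1L),
                                                length = 16.5)))
  a <- elementAnchors3d(tab, sheets)
  expect_equal(a["H1", ], c(0, 0, 5))            # axis midpoint
  expect_equal(a["S1", ], c(2, 0, 0))            # centroid of (0,..) (4,..)
  a1 <- elementAnchors3d(tab[1:2, ],
                         list(S1 = new("SheetModel", sheetId = "S1",
                                       strandLabels = "E1",
                                       orientations = character(),
                                       template = data.frame(
                                         label = "E1", ox = 0, oy = 0,
                                         sign = 1L, length = 16.5))))
  expect_equal(a1["S1", ], c(0, 0, 0))           # singleton = its midpoint
})

test_that("stress matches hand-computed values and rejects label mismatch", {
  a <- anchorsOf(rbind(c(0, 0, 0), c(10, 0, 0)))
  p <- rbind(L1 = c(0, 0), L2 = c(7, 0))
  expect_equal(layoutStress(p, a), 9.0)

  # coplanar anchors at their own in-plane coordinates: zero stress
  a3 <- anchorsOf(rbind(c(0, 0, 0), c(10, 0, 0), c(3, 8, 0)))
  p3 <- a3[, 1:2]
  expect_equal(layoutStress(p3, a3), 0)

  bad <- p3; rownames(bad) <- c("L1", "L2", "XX")
  expect_error(layoutStress(bad, a3), class = "usageError")
})

test_that("stress with lambda 0 is invariant under rigid 2D transforms", {
  set.seed(11)
  a <- anchorsOf(matrix(rnorm(15, sd = 8), 5))
  p <- a[, 1:2] + matrix(rnorm(10), 5)
  s0 <- layoutStress(p, a)
  th <- 1.2
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  moved <- sweep(p %*% t(R), 2, c(40, -7), "+")
  rownames(moved) <- rownames(p)
  expect_equal(layoutStress(moved, a), s0, tolerance = 1e-9)
})

test_that("starting-layout selection maximizes overlap with a floor", {
  expect_null(selectStartingLayout(c("H1", "H2"), list(), 0.5))
  d <- jitteredDiagrams()[[1]]
  labs <- diagramElements(d)$label
  sel <- selectStartingLayout(labs, setNames(list(d), domainId(d)), 0.5)
  expect_identical(domainId(sel$diagram), domainId(d))
  expect_setequal(sel$shared, labs)
  expect_null(selectStartingLayout(c("Z1", "Z2", "Z3", "Z4", labs[1]),
                                   setNames(list(d), domainId(d)), 0.5))
})

test_that("initialization honours the start exactly and embeds planes", {
  a3 <- anchorsOf(rbind(c(0, 0, 0), c(10, 0, 0), c(3, 8, 0)))
  p <- initialPositions(a3)
  expect_equal(as.matrix(dist(p)), as.matrix(dist(a3)), tolerance = 1e-9)

  start <- rbind(L1 = c(5, 5), L2 = c(15, 5), L3 = c(8, 13))
  pAll <- initialPositions(a3, start)
  expect_equal(pAll[rownames(start), ], start[rownames(start), ])

  part <- start[1:2, , drop = FALSE]
  pPart <- initialPositions(a3, part)
  expect_equal(pPart[c("L1", "L2"), ], part)
})

test_that("placement achieves exact planar embeddings and beats the grid oracle", {
  set.seed(21)
  a <- anchorsOf(cbind(matrix(rnorm(10, sd = 6), 5), 0))
  cls <- setNames(rep("primary", 5), rownames(a))
  pos <- placeElements(a, cls)
  meanD <- mean(dist(a))
  expect_lt(attr(pos, "objective"), 1e-6 * meanD^2)

  one <- anchorsOf(matrix(c(3, 4, 5), 1))
  p1 <- placeElements(one, setNames("primary", "L1"))
  expect_equal(as.vector(p1), c(0, 0))

  a3 <- anchorsOf(rbind(c(0, 0, 0), c(9, 0, 2), c(4, 7, 5)))
  cls3 <- setNames(rep("primary", 3), rownames(a3))
  p3 <- placeElements(a3, cls3)
  expect_lte(attr(p3, "objective"), gridOracle(a3) + 1e-6)
})

test_that("the optimizer descends monotonically", {
  set.seed(31)
  a <- anchorsOf(matrix(rnorm(21, sd = 7), 7))
  cls <- setNames(rep("primary", 7), rownames(a))
  # start from a deliberately bad layout via a start covering everything
  start <- matrix(rnorm(14, sd = 20), 7)
  rownames(start) <- rownames(a)
  pos <- placeElements(a, cls, start = start,
                       config = layoutConfig(lambda = 0))
  tr <- attr(pos, "trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("secondary placement leaves primaries frozen", {
  set.seed(41)
  a <- anchorsOf(matrix(rnorm(18, sd = 6), 6))
  cls <- setNames(c(rep("primary", 4), rep("secondary", 2)), rownames(a))
  pos <- placeElements(a, cls)
  # moving a secondary anchor must not move any primary element
  a2 <- a
  a2[5, ] <- a2[5, ] + c(4, -3, 2)
  pos2 <- placeElements(a2, cls)
  expect_equal(pos2[1:4, ], pos[1:4, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(pos2[5, ], pos[5, ])))
})

test_that("angles follow projected axes and parallel axes stay parallel", {
  tab <- sse2d:::.emptySSETable()
  tab[1, ] <- list("H1", "helix", "A", 1L, 10L, 1L, 10L, 10L,
                   0, 0, 0, 10, 0, 0)
  tab[2, ] <- list("H2", "helix", "A", 15L, 24L, 15L, 24L, 10L,
                   0, 20, 0, 10, 20, 0)
  tab[3, ] <- list("H3", "helix", "A", 30L, 39L, 30L, 39L, 10L,
                   20, 10, 0, 20, 20, 0)
  anchors <- elementAnchors3d(tab, list())
  pos <- initialPositions(anchors)
  ei <- sse2d:::.elementInfo(tab, list(),
                             computeFamilyStats(AnnotatedFamily(
                               "9.9.9.9",
                               list(aaaA01 = domainFromCoords(
                                 cbind(seq_len(50) * 3.3, 0, 0), "aaaA01")),
                               list(aaaA01 = tab))))
  ang <- adjustAngles(ei$info, ei$dirs, pos)
  # H1 and H2 have equal 3D directions: equal projected angles (before any
  # overlap refinement both sit far apart, so none occurs)
  d12 <- abs(sse2d:::.wrapAngle(ang["H1"] - ang["H2"])) * 180 / pi
  expect_lt(min(d12, 180 - d12), 10)
  # H3 is perpendicular to H1 in the plane
  d13 <- abs(sse2d:::.wrapAngle(ang["H1"] - ang["H3"])) * 180 / pi
  expect_equal(min(d13, 180 - d13), 90, tolerance = 5)
})

test_that("domain layout is deterministic and records its objective", {
  jf <- jitteredFamily()
  af <- jf$annotated
  id <- memberIds(af)[1]
  tab <- sseTable(af, id)
  sheets <- buildSheetsForMember(memberStructure(af, id), tab)
  d1 <- layoutDomain(memberStructure(af, id), tab, sheets, jf$stats)
  d2 <- layoutDomain(memberStructure(af, id), tab, sheets, jf$stats)
  expect_identical(diagramElements(d1), diagramElements(d2))
  expect_gte(diagramStress(d1), 0)
})

test_that("a single-helix domain sits at the origin", {
  dom <- domainFromCoords(makeIdealHelix(12))
  af <- annotateStructures("9.9.9.9", list(synA01 = dom))
  st <- computeFamilyStats(af)
  d <- layoutFamily(af, st)[[1]]
  el <- diagramElements(d)
  expect_equal(nrow(el), 1L)
  expect_equal(c(el$x, el$y), c(0, 0))
  expect_equal(diagramStress(d), 0)
})

test_that("the deviation penalty shrinks displacement from the start", {
  fam <- makeFamily(familySpec(mixedRecipe(), nMembers = 2,
                               jitterSigma = 0.3, seed = 9))
  af <- annotateStructures(fam$familyId,
                           lapply(fam$members, `[[`, "structure"))
  st <- computeFamilyStats(af)
  disp <- function(lambda) {
    cfg <- layoutConfig(lambda = lambda)
    ids <- memberIds(af)
    t1 <- sseTable(af, ids[1])
    s1 <- buildSheetsForMember(memberStructure(af, ids[1]), t1)
    d1 <- layoutDomain(memberStructure(af, ids[1]), t1, s1, st, list(), cfg)
    t2 <- sseTable(af, ids[2])
    s2 <- buildSheetsForMember(memberStructure(af, ids[2]), t2)
    d2 <- layoutDomain(memberStructure(af, ids[2]), t2, s2, st,
                       setNames(list(d1), ids[1]), cfg)
    e1 <- diagramElements(d1); e2 <- diagramElements(d2)
    shared <- intersect(e1$label, e2$label)
    i1 <- match(shared, e1$label); i2 <- match(shared, e2$label)
    sum(sqrt((e1$x[i1] - e2$x[i2])^2 + (e1$y[i1] - e2$y[i2])^2))
  }
  expect_lt(disp(0.05), disp(0))
})

test_that("family layout keeps shared elements coherent across members", {
  diags <- jitteredDiagrams()
  els <- lapply(diags, diagramElements)
  meanD <- mean(vapply(els, function(e)
    if (nrow(e) >= 2) mean(dist(cbind(e$x, e$y))) else NA_real_,
    numeric(1)), na.rm = TRUE)
  labs <- unique(unlist(lapply(els, `[[`, "label")))
  for (l in labs) {
    cs <- do.call(rbind, lapply(els, function(e)
      if (l %in% e$label) c(e$x[e$label == l], e$y[e$label == l])))
    if (is.null(cs) || nrow(cs) < 2) next
    sdev <- sqrt(mean(rowSums(sweep(cs, 2, colMeans(cs))^2)))
    expect_lte(sdev, 0.2 * meanD)
  }
})

test_that("a family of one member equals the direct domain layout", {
  dom <- makeDomain(mixedRecipe())$structure
  af <- annotateStructures("9.9.9.9", list(synA01 = dom))
  st <- computeFamilyStats(af)
  viaFamily <- layoutFamily(af, st)[[1]]
  tab <- sseTable(af, "synA01")
  sheets <- buildSheetsForMember(dom, tab)
  direct <- layoutDomain(dom, tab, sheets, st)
  expect_identical(diagramElements(viaFamily), diagramElements(direct))
})

test_that("3D and 2D inter-element distances stay rank-concordant", {
  worst <- 1
  for (s in 1:6) {
    rec <- randomDomainRecipe(5 + (s %% 4), 3000 + s)
    dom <- makeDomain(rec, "synA01")
    af <- annotateStructures("9.9.9.9", list(synA01 = dom$structure))
    st <- computeFamilyStats(af)
    d <- layoutFamily(af, st)[[1]]
    e <- diagramElements(d)
    if (nrow(e) < 4) next
    anch <- elementAnchors3d(sseTable(af, "synA01"),
                             d@sheets)[e$label, , drop = FALSE]
    rho <- cor(as.vector(dist(anch)), as.vector(dist(cbind(e$x, e$y))),
               method = "spearman")
    worst <- min(worst, rho)
  }
  expect_gte(worst, 0.9)
})
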