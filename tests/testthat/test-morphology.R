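test_that("discretization yields ceil(L/dl) equal compartments per segment", {
  g <- discretize(cylinder_morphology(80, 1), 1)
  expect_identical(g$n, 80L)
  expect_true(all(abs(g$length - 1) < 1e-12))
  g2 <- discretize(cylinder_morphology(7.5, 1), 2)
  expect_identical(g2$n, 4L)
  g3 <- discretize(cylinder_morphology(5, 1), 10)  # dl >= L -> 1 compartment
  expect_identical(g3$n, 1L)
  expect_error(discretize(cylinder_morphology(5, 1), 0), "dl")
})

test_that("compartment volumes sum to the frustum volumes", {
  segs <- data.frame(id = 1:3, parent = c(NA, 1L, 1L),
                     prox_radius = c(2, 1.5, 1.5),
                     dist_radius = c(1.5, 0.5, 1.0),
                     length = c(10, 7.3, 4.1),
                     tag = c("soma", "apical", "basal"))
  m <- morphology(segs)
  g <- discretize(m, 0.9)
  frustum <- function(r0, r1, h) pi * h / 3 * (r0^2 + r0 * r1 + r1^2)
  vtot <- sum(frustum(segs$prox_radius, segs$dist_radius, segs$length))
  expect_lt(abs(sum(g$volume) - vtot) / vtot, 1e-10)
})

test_that("the reduced pyramidal-cell specs discretize to 48 and 31 compartments", {
  expect_identical(morpho_cell_spec("small", "long")$grid$n, 48L)
  expect_identical(morpho_cell_spec("small", "short")$grid$n, 31L)
  # the synthesis compartment sits between the two soma halves
  sp <- morpho_cell_spec("small", "long")
  expect_identical(sp$grid$tag[sp$soma_center], "prp")
})

test_that("morphology validation rejects malformed trees", {
  base <- data.frame(id = 1:2, parent = c(NA, 1L), prox_radius = 1,
                     dist_radius = 1, length = 5, tag = "dendrite")
  expect_s3_class(morphology(base), "morphology")
  bad <- base; bad$parent[2] <- 99
  expect_error(morphology(bad), "unknown parent")
  bad <- base; bad$length[1] <- 0
  expect_error(morphology(bad), "length")
  bad <- base; bad$prox_radius[2] <- -1
  expect_error(morphology(bad), "radii")
  bad <- base; bad$parent <- c(2L, 1L)
  expect_error(morphology(bad), "root")
  expect_error(morphology(base[0, ]), "at least one")
})

test_that("SWC round trip preserves the branched tree", {
  set.seed(1)  # geometry of the fixture only; the package itself is R-RNG free
  segs <- data.frame(id = 1:10,
                     parent = c(NA, 1, 1, 2, 2, 3, 3, 4, 5, 6),
                     prox_radius = runif(10, 0.5, 2),
                     dist_radius = runif(10, 0.5, 2),
                     length = runif(10, 5, 50),
                     tag = sample(c("dendrite", "apical", "basal"), 10, TRUE))
  m <- morphology(segs)
  path <- tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- load_swc(path)
  a <- m$segments
  b <- m2$segments
  expect_identical(nrow(b), nrow(a))
  # isomorphism: sort both by (depth, length) and compare structure
  depth_of <- function(s) {
    d <- integer(nrow(s))
    for (i in seq_len(nrow(s)))
      d[i] <- if (is.na(s$parent[i])) 0L else d[match(s$parent[i], s$id)] + 1L
    d
  }
  ka <- order(depth_of(a), round(a$length, 6))
  kb <- order(depth_of(b), round(b$length, 6))
  expect_equal(a$length[ka], b$length[kb], tolerance = 1e-6)
  expect_equal(a$dist_radius[ka], b$dist_radius[kb], tolerance = 1e-6)
  expect_equal(depth_of(a)[ka], depth_of(b)[kb])
})

test_that("SWC parse errors name the offending line", {
  p <- tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 7"), p)   # parent 7 undefined on line 3
  expect_error(load_swc(p), "line 3.*undefined parent")
  writeLines(c("1 1 0 0 0 5 -1",
               "2 3 10 0 0 -2 1"), p)  # non-positive radius on line 2
  expect_error(load_swc(p), "line 2.*radius")
  writeLines(c("1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 1",
               "3 3 20 0 0 1"), p)     # malformed field count
  expect_error(load_swc(p), "line 3")
  expect_error(load_swc(tempfile()), "not found")
})

test_that("a minimal two-sample SWC gives a one-segment morphology", {
  p <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 3 12 0 0 1 1"), p)
  m <- load_swc(p)
  expect_identical(nrow(m$segments), 1L)
  expect_equal(m$segments$length, 12)
  expect_equal(m$segments$prox_radius, 5)
  expect_equal(m$segments$dist_radius, 1)
})

test_that("total species amount equals the direct weighted sum", {
  g <- discretize(cylinder_morphology(30, 1.3), 1)
  f <- species_field(g, conc = 2.5)
  expect_equal(total_amount(f, g), 2.5 * sum(g$volume) * 1e-15)
  f$conc[] <- 0
  expect_identical(total_amount(f, g), 0)
  cs <- sin(seq_len(g$n))^2
  f$conc <- cs
  expect_equal(total_amount(f, g), sum(cs * g$volume) * 1e-15,
               tolerance = 1e-15)
  f2 <- species_field(g, conc = 1)
  g2 <- discretize(cylinder_morphology(30, 1.3), 2)
  expect_error(total_amount(f2, g2), "compartments")
})
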