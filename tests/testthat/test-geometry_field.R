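test_that("flat-disc cone distances equal planar distances", {
  geom <- cone_geometry(1)
  ## diametrically opposite points on a flat disc
  expect_equal(cone_distance(surface_point(2, 0), surface_point(2, pi), geom),
               4)
  expect_equal(cone_distance(surface_point(1.3, 0.7), surface_point(1.3, 0.7),
                             geom), 0)
  ## property: 1000 random pairs match the planar law of cosines
  set.seed(41)
  ra <- runif(1000, 0, 5); ta <- runif(1000, 0, 2 * pi)
  rb <- runif(1000, 0, 5); tb <- runif(1000, 0, 2 * pi)
  d <- cone_distance(surface_point(ra, ta), surface_point(rb, tb), geom)
  expect_equal(d, bf_cone_distance(ra, ta, rb, tb, 1), tolerance = 1e-12)
})

test_that("unrolled-cone geodesics are correct and metric axioms hold", {
  ## unroll 0.5: opposite points at slant radius 1 unroll to a right angle,
  ## so the geodesic is sqrt(2)
  g05 <- cone_geometry(0.5)
  expect_equal(cone_distance(surface_point(1, 0), surface_point(1, pi), g05),
               sqrt(2), tolerance = 1e-12)
  ## symmetry and triangle inequality on random triples, several cone angles
  set.seed(42)
  for (c in c(0.3, 0.6, 0.95, 1)) {
    geom <- cone_geometry(c)
    r <- matrix(runif(300, 0, 4), ncol = 3)
    th <- matrix(runif(300, 0, 2 * pi), ncol = 3)
    pA <- surface_point(r[, 1], th[, 1])
    pB <- surface_point(r[, 2], th[, 2])
    pC <- surface_point(r[, 3], th[, 3])
    ab <- cone_distance(pA, pB, geom)
    ba <- cone_distance(pB, pA, geom)
    ac <- cone_distance(pA, pC, geom)
    cb <- cone_distance(pC, pB, geom)
    expect_equal(ab, ba, tolerance = 1e-12)
    expect_true(all(ab <= ac + cb + 1e-9))
  }
  expect_error(cone_distance(surface_point(1, 0), surface_point(1, 1),
                             cone_geometry(0)), "unroll_factor")
})

test_that("cone geodesics agree with a shortest path on a 3-d cone mesh", {
  skip_if_not_installed("igraph")
  ## discretize the unroll-0.5 cone embedded in 3-d, connect each mesh node
  ## to its 8 neighbours with Euclidean edge lengths, and run Dijkstra
  c <- 0.5
  nr <- 61; nth <- 180
  rho <- seq(0.02, 1.3, length.out = nr)
  th <- seq(0, 2 * pi, length.out = nth + 1)[-(nth + 1)]
  id <- function(i, j) (i - 1) * nth + ((j - 1) %% nth) + 1
  xyz <- cbind(
    x = rep(rho, each = nth) * c * cos(rep(th, nr)),
    y = rep(rho, each = nth) * c * sin(rep(th, nr)),
    z = -rep(rho, each = nth) * sqrt(1 - c^2))
  edges <- NULL
  for (i in seq_len(nr)) for (dj in c(1)) {
    a <- id(i, seq_len(nth)); b <- id(i, seq_len(nth) + dj)
    edges <- rbind(edges, cbind(a, b))
  }
  for (i in seq_len(nr - 1)) for (dj in c(-1, 0, 1)) {
    a <- id(i, seq_len(nth)); b <- id(i + 1, seq_len(nth) + dj)
    edges <- rbind(edges, cbind(a, b))
  }
  w <- sqrt(rowSums((xyz[edges[, 1], ] - xyz[edges[, 2], ])^2))
  gr <- igraph::make_graph(t(edges), n = nr * nth, directed = FALSE)
  ia <- id(nr, 1)                          # (rho = 1.3, theta = 0)
  ib <- id(nr, which.min(abs(th - pi)))    # (rho = 1.3, theta = pi)
  dd <- igraph::distances(gr, v = ia, to = ib, weights = w)[1, 1]
  exact <- cone_distance(surface_point(1.3, 0), surface_point(1.3, pi),
                         cone_geometry(c))
  ## the mesh path zigzags, so Dijkstra slightly overestimates
  expect_gt(dd, exact * 0.999)
  expect_lt(dd, exact * 1.04)
})

test_that("kernels are normalized at d0, strictly decreasing, singular at 0", {
  fp_pow <- field_params(3, 2, "power")
  expect_equal(inhibition_kernel(3, fp_pow), 1)
  expect_equal(inhibition_kernel(6, fp_pow), 0.25)
  expect_equal(inhibition_kernel(1.5, fp_pow), 4)
  expect_equal(inhibition_kernel(3 / 2, field_params(3, 3, "power")), 8)
  fp_exp <- field_params(3, 2, "exponential")
  expect_equal(inhibition_kernel(3, fp_exp), 1)
  d <- seq(0.2, 12, by = 0.2)
  for (fp in list(fp_pow, fp_exp)) {
    k <- inhibition_kernel(d, fp)
    expect_true(all(diff(k) < 0))
    expect_true(all(k > 0))
    expect_error(inhibition_kernel(0, fp), "singular")
  }
})

test_that("total inhibition is the brute-force sum over sources", {
  geom <- cone_geometry(0.95)
  expect_identical(total_inhibition(1.2, 0, primordia(numeric(0), numeric(0),
                                                      numeric(0))), 0)
  ## a single source directly behind the probe at distance d0 contributes 1
  p1 <- primordia(0.4, 0, 2 + 3)
  for (form in c("power", "exponential")) {
    fp <- field_params(3, 2, form)
    expect_equal(total_inhibition(0.4, 0, p1, fp, geom, R_circle = 2), 1,
                 tolerance = 1e-12)
  }
  ## 20 random sources vs element-by-element brute force
  set.seed(7)
  p <- primordia(runif(20, 0, 2 * pi), -runif(20, 0, 30), runif(20, 1.8, 2.2))
  th <- runif(25, 0, 2 * pi)
  for (form in c("power", "exponential")) {
    fp <- field_params(3.2, 2, form)
    got <- total_inhibition(th, 0, p, fp, geom, R_circle = 2, prune_eps = 0)
    want <- bf_total_inhibition(th, 0, p, 3.2, 2, form, 0.95, 2, 1)
    expect_equal(got, want, tolerance = 1e-12)
  }
  ## non-integer steepness exercises the pow path
  fp <- field_params(3, 2.7, "power")
  got <- total_inhibition(th, 0, p, fp, geom, R_circle = 2, prune_eps = 0)
  want <- bf_total_inhibition(th, 0, p, 3, 2.7, "power", 0.95, 2, 1)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("total inhibition decays in time and pruning error is bounded", {
  geom <- cone_geometry(0.95)
  fp <- field_params(3, 2)
  set.seed(8)
  p <- primordia(runif(30, 0, 2 * pi), -runif(30, 0.5, 20), runif(30, 1.9, 2.1))
  th <- runif(10, 0, 2 * pi)
  ## receding sources: the field at a fixed probe never increases with time
  ts <- seq(0, 10, by = 0.5)
  E <- sapply(ts, function(t) total_inhibition(th, t, p, fp, geom, 2))
  expect_true(all(diff(t(E)) <= 1e-12))
  ## pruning: error bounded by (number pruned) * eps
  eps <- 1e-4
  exact <- total_inhibition(th, 25, p, fp, geom, 2, prune_eps = 0)
  pruned <- total_inhibition(th, 25, p, fp, geom, 2, prune_eps = eps)
  expect_true(all(abs(exact - pruned) <= length(p$azimuth) * eps))
})
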