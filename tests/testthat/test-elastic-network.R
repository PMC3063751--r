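test_that("network energy sums harmonic terms and is rigid-invariant", {
  # one bond, k = 2, stretched 1 A beyond rest: 1/2 * 2 * 1^2 = 1 kcal/mol
  net1 <- elastic_network(
    tibble::tibble(i = 1L, j = 2L, b = 3, k = 2),
    coords = rbind(c(0, 0, 0), c(3, 0, 0))
  )
  expect_equal(network_energy(net1, net1$coords), 0)
  expect_equal(network_energy(net1, rbind(c(0, 0, 0), c(4, 0, 0))), 1)

  net <- make_toy_network(n_sites = 10, n_extra_contacts = 12, seed = 4)
  conf <- withr::with_seed(5, net$coords + matrix(rnorm(30, sd = 0.3), 10))
  # term-by-term oracle
  d <- sqrt(rowSums((conf[net$bonds$j, ] - conf[net$bonds$i, ])^2))
  expect_equal(network_energy(net, conf), sum(0.5 * net$bonds$k * (d - net$bonds$b)^2))

  qrd <- withr::with_seed(6, qr(matrix(rnorm(9), 3)))
  R <- qr.Q(qrd); if (det(R) < 0) R[, 1] <- -R[, 1]
  moved <- sweep(conf %*% t(R), 2, c(5, -3, 2), `+`)
  expect_equal(network_energy(net, moved), network_energy(net, conf))

  expect_error(network_energy(net, conf[-1, ]), "cover all sites")
})

test_that("an isolated harmonic bond has variance kB*T/k", {
  net <- elastic_network(
    tibble::tibble(i = 1L, j = 2L, b = 4, k = 2.5),
    coords = rbind(c(0, 0, 0), c(4, 0, 0)), temperature = 300
  )
  expect_equal(predict_bond_variances(net)$variance, kBT(300) / 2.5, tolerance = 1e-12)
})

test_that("predicted variances scale as 1/k and are mass-independent", {
  net <- make_toy_network(n_sites = 12, n_extra_contacts = 30, seed = 8)
  v1 <- predict_bond_variances(net)$variance
  stiff <- net; stiff$bonds$k <- 2 * net$bonds$k
  expect_equal(predict_bond_variances(stiff)$variance, v1 / 2, tolerance = 1e-10)

  heavy <- net; heavy$masses <- 2 * net$masses
  expect_equal(predict_bond_variances(heavy)$variance, v1, tolerance = 1e-12)
})

test_that("predicted variances match the Gaussian sampler on the bond coordinate", {
  net <- make_toy_network(n_sites = 12, n_extra_contacts = 30, seed = 9)
  pred <- predict_bond_variances(net)
  n_draw <- 20000
  traj <- sample_from_network(net, n_draw, seed = 10)
  obs <- measure_projected_variances(traj, net$bonds[, c("i", "j")], net$coords)
  z <- (obs$variance - pred$variance) / (pred$variance * sqrt(2 / n_draw))
  expect_lt(max(abs(z)), 4)
})

test_that("disconnected networks and degenerate geometries are rejected", {
  two_dimers <- elastic_network(
    tibble::tibble(i = c(1L, 3L), j = c(2L, 4L), b = c(3, 3), k = c(1, 1)),
    coords = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 5, 0), c(3, 5, 0))
  )
  expect_error(predict_bond_variances(two_dimers), "disconnected")

  # bonds whose k was driven to zero can cut the graph
  net <- make_toy_network(n_sites = 8, n_extra_contacts = 0, seed = 11)
  net$bonds$k[4] <- 0
  expect_error(predict_bond_variances(net), "disconnected")
})

test_that("the bond pool is the min-distance contact map and grows with the cutoff", {
  # two sites at fixed 5 A
  fixed <- array(NA_real_, c(2, 2, 3))
  for (f in 1:2) fixed[f, , ] <- rbind(c(0, 0, 0), c(5, 0, 0))
  expect_equal(init_bond_pool(cg_trajectory(fixed), 10), tibble::tibble(i = 1L, j = 2L))

  # oscillating 9 -> 11 A: the minimum (9) is inside the cutoff
  osc <- array(NA_real_, c(2, 2, 3))
  osc[1, , ] <- rbind(c(0, 0, 0), c(9, 0, 0))
  osc[2, , ] <- rbind(c(0, 0, 0), c(11, 0, 0))
  expect_equal(init_bond_pool(cg_trajectory(osc), 10), tibble::tibble(i = 1L, j = 2L))

  # brute-force oracle on a random 30-site trajectory
  coords <- withr::with_seed(12, array(rnorm(5 * 30 * 3, sd = 6), c(5, 30, 3)))
  traj <- cg_trajectory(coords)
  pool <- init_bond_pool(traj, 10)
  expected <- list()
  for (i in 1:29) for (j in (i + 1):30) {
    dmin <- min(sapply(1:5, function(f) sqrt(sum((coords[f, i, ] - coords[f, j, ])^2))))
    if (dmin <= 10) expected[[length(expected) + 1]] <- c(i, j)
  }
  em <- do.call(rbind, expected)
  expect_equal(as.matrix(pool), em, ignore_attr = TRUE)

  # monotonicity: enlarging the cutoff never removes a pair
  for (cut in c(6, 8, 12)) {
    small <- init_bond_pool(traj, cut)
    large <- init_bond_pool(traj, cut + 2)
    expect_true(all(paste(small$i, small$j) %in% paste(large$i, large$j)))
  }
})

test_that("network TSV round-trips exactly", {
  net <- make_toy_network(n_sites = 7, n_extra_contacts = 10, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network_tsv(net, path)
  back <- read_network_tsv(path)
  expect_equal(back$bonds, net$bonds)
  expect_equal(back$coords, net$coords, ignore_attr = TRUE)
  expect_equal(back$temperature, net$temperature)
  expect_equal(back$residues, net$residues)
})
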