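test_that("residue coupling aggregates site bonds and excludes intra-residue terms", {
  # two residues, two sites each; three inter-residue bonds k = 1, 2, 3 plus
  # one intra-residue bond that must not reach k_I
  net <- elastic_network(
    tibble::tibble(
      i = c(1L, 1L, 2L, 1L),
      j = c(3L, 4L, 4L, 2L),
      b = rep(4, 4),
      k = c(1, 2, 3, 7)
    ),
    coords = withr::with_seed(1, matrix(rnorm(12, sd = 5), 4)),
    residues = c(1L, 1L, 2L, 2L)
  )
  rc <- residue_coupling(net)
  expect_equal(rc$pairs$k[rc$pairs$I == 1 & rc$pairs$J == 2], 6)
  expect_equal(rc$pairs$k[rc$pairs$I == 1 & rc$pairs$J == 1], 7)
  expect_equal(rc$residues$k_I, c(6, 6))

  # residues with no connecting bonds couple at zero
  rc0 <- residue_coupling(
    elastic_network(
      tibble::tibble(i = 1L, j = 2L, b = 4, k = 5),
      coords = withr::with_seed(2, matrix(rnorm(9, sd = 5), 3)),
      residues = 1:3
    )
  )
  expect_equal(rc0$residues$k_I[rc0$residues$residue == 3], 0)

  # brute-force oracle on a random network with paired sites
  net_r <- make_toy_network(n_sites = 16, n_extra_contacts = 40, seed = 30)
  net_r$residues <- as.integer(rep(1:8, each = 2))
  expect_equal(
    dplyr::arrange(residue_coupling(net_r)$pairs, I, J),
    residue_pair_oracle(net_r)
  )
})

test_that("identical fluctuograms give zero differences and all-weak classes", {
  pool <- tibble::tibble(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L))
  K <- matrix(c(2, 3, 4), 3, 4) # constant over 4 windows
  fl <- fake_fluctuogram(pool, K)
  d <- delta_k_two_states(fl, fl)
  expect_true(all(d$series$delta_k == 0))
  expect_true(all(d$summary$class == "medium_weak"))

  expect_true(all(delta_k_consecutive(fl)$delta_k == 0))
  expect_true(all(conformational_change(fl)$delta_b == 0))
  expect_true(all(psi(fl)$psi == 0))
})

test_that("a planted constant shift is classified large and the comparison is antisymmetric", {
  withr::with_seed(31, {
    pool <- tibble::tibble(
      i = rep(1:9, times = 9:1),
      j = unlist(lapply(1:9, function(i) (i + 1):10))
    )
    K <- matrix(runif(nrow(pool) * 5, 0, 4), nrow(pool), 5)
  })
  fl_a <- fake_fluctuogram(pool, K)
  K_b <- K
  touched <- pool$i == 5 | pool$j == 5
  # shift residue 5's total coupling by +25 in every window, spread over its bonds
  K_b[touched, ] <- K_b[touched, ] + 25 / sum(touched)
  fl_b <- fake_fluctuogram(pool, K_b)
  d <- delta_k_two_states(fl_b, fl_a)
  expect_equal(d$summary$class[d$summary$residue == 5], factor("large", levels = levels(d$summary$class)))

  d_rev <- delta_k_two_states(fl_a, fl_b)
  expect_equal(d_rev$series$delta_k, -d$series$delta_k)

  # classes equal brute-force thresholding of the time-averaged |dk|
  brute <- tapply(abs(d$series$delta_k), d$series$residue, mean)
  expect_equal(
    as.character(d$summary$class[order(d$summary$residue)]),
    ifelse(brute >= 20, "large", ifelse(brute >= 10, "significant", "medium_weak")),
    ignore_attr = TRUE
  )
})

test_that("conformational change sums |db| over mechanically active bonds only", {
  pool <- tibble::tibble(i = c(1L, 1L), j = c(2L, 3L))
  K <- cbind(c(1, 0), c(1, 0)) # bond 2 never active
  B <- cbind(c(4, 5), c(4.3, 5.7))
  fl <- fake_fluctuogram(pool, K, B)
  cc <- conformational_change(fl)
  expect_equal(cc$delta_b[cc$residue == 1], 0.3, tolerance = 1e-12)
  expect_equal(cc$delta_b[cc$residue == 2], 0.3, tolerance = 1e-12)
  expect_equal(cc$delta_b[cc$residue == 3], 0) # its only bond never has k > 0
})

test_that("psi reproduces the worked three-bond case and attains its bounds", {
  pool <- tibble::tibble(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L))
  K <- cbind(c(2, 0, 4), c(4, 1, 2))
  fl <- fake_fluctuogram(pool, K)
  p <- psi(fl)
  # terms (1/2, 1, -1/2) average to 1/3
  expect_equal(p$psi[p$residue == 1], 1 / 3, tolerance = 1e-12)
  expect_equal(p$n_bonds[p$residue == 1], 3L)

  # all bonds newly appear: +1; all vanish: -1
  appear <- fake_fluctuogram(pool, cbind(c(0, 0, 0), c(1, 2, 3)))
  expect_equal(psi(appear)$psi[1], 1)
  vanish <- fake_fluctuogram(pool, cbind(c(1, 2, 3), c(0, 0, 0)))
  expect_equal(psi(vanish)$psi[1], -1)

  # a residue with no active bonds is undefined, not zero
  dead <- fake_fluctuogram(pool, cbind(c(0, 0, 0), c(0, 0, 0)))
  expect_true(all(is.na(psi(dead)$psi)))
  expect_true(all(psi(dead)$n_bonds == 0))
})

test_that("psi stays within [-1, 1] on randomized fluctuograms", {
  n_checked <- 0
  for (case in 1:45) {
    fl <- withr::with_seed(100 + case, {
      n <- sample(5:10, 1)
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      take <- sample(nrow(pairs), min(nrow(pairs), 2 * n))
      pool <- tibble::tibble(i = pairs[take, 1], j = pairs[take, 2])
      nw <- sample(3:6, 1)
      K <- matrix(runif(nrow(pool) * nw, 0, 10), nrow(pool))
      K[runif(length(K)) < 0.3] <- 0 # sparse activity incl. appearing/vanishing bonds
      fake_fluctuogram(pool, K)
    })
    p <- psi(fl)
    vals <- p$psi[!is.na(p$psi)]
    expect_true(all(vals >= -1 - 1e-12 & vals <= 1 + 1e-12))
    n_checked <- n_checked + length(vals)
  }
  expect_gt(n_checked, 1000)
})

test_that("metric tables serialise to the long TSV layout", {
  pool <- tibble::tibble(i = c(1L, 1L), j = c(2L, 3L))
  fl <- fake_fluctuogram(pool, cbind(c(1, 2), c(2, 1), c(0, 3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_tsv(list(psi = psi(fl), delta_k = delta_k_consecutive(fl)), path)
  lines <- readLines(path)
  expect_equal(lines[1], "# residue\twindow\tmetric\tvalue")
  body <- do.call(rbind, strsplit(lines[-1], "\t"))
  expect_setequal(unique(body[, 3]), c("psi", "delta_k"))
})
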