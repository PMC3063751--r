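test_that("pair statistics use the population convention", {
  series <- tibble::tibble(
    window = rep(1:2, each = 2),
    I = rep(c(1L, 3L), 2), J = rep(c(10L, 8L), 2),
    k = c(5, 0, 5, 4)
  )
  st <- pair_statistics(series)
  expect_equal(st$mean[st$I == 1], 5)
  expect_equal(st$sd[st$I == 1], 0)
  expect_equal(st$max[st$I == 1], 5)
  expect_equal(st$mean[st$I == 3], 2)
  expect_equal(st$sd[st$I == 3], 2) # population sd of (0, 4)
  expect_equal(st$max[st$I == 3], 4)
  expect_equal(st$separation, c(9L, 5L))
})

test_that("criterion A counts well-separated strong partners against the hub cutoff", {
  # star: residue 1 coupled at 3 to 12 partners, all with separation > 3
  star <- tibble::tibble(
    I = 1L, J = seq(5L, by = 2L, length.out = 12),
    mean = 3, sd = 0.5, max = 4
  )
  star$separation <- abs(star$J - star$I)
  expect_equal(criterion_a(star, criteria_params(k_cut = 2.5, n_cut = 10)), 1L)
  expect_equal(criterion_a(star, criteria_params(k_cut = 3.5, n_cut = 10)), integer(0))
  expect_equal(criterion_a(star, criteria_params(k_cut = 2.5, n_cut = 13)), integer(0))
})

test_that("criterion B selects both ends of strongly coupled pairs", {
  st <- tibble::tibble(
    I = c(5L, 2L), J = c(40L, 4L), mean = c(12, 30), sd = 0, max = c(12, 30),
    separation = c(35L, 2L)
  )
  # the second pair is closer than the separation cutoff
  expect_equal(criterion_b(st, criteria_params(k_b = 11)), c(5L, 40L))
  expect_equal(criterion_b(st[0, ], criteria_params()), integer(0))
})

test_that("criterion C combines a maximum-coupling and a variation cutoff", {
  p <- criteria_params(k_c = 8, s_c = 0.8)
  yes <- tibble::tibble(I = 2L, J = 30L, mean = 4, sd = 4, max = 9, separation = 28L)
  expect_equal(criterion_c(yes, p), c(2L, 30L)) # cv = 1 >= 0.8 and max 9 >= 8
  no_var <- dplyr::mutate(yes, sd = 0)
  expect_equal(criterion_c(no_var, p), integer(0))
  no_max <- dplyr::mutate(yes, max = 7)
  expect_equal(criterion_c(no_max, p), integer(0))
  zero_mean <- dplyr::mutate(yes, mean = 0)
  expect_equal(criterion_c(zero_mean, p), integer(0))
})

test_that("criteria match brute-force enumeration on random tables in every variation mode", {
  for (case in 1:20) {
    st <- random_stats_table(seed = 400 + case)
    p <- criteria_params()
    ok <- st$separation >= p$min_separation

    a_brute <- sort(as.integer(names(which(
      table(c(st$I[ok & st$mean >= p$k_cut], st$J[ok & st$mean >= p$k_cut])) >= p$n_cut
    ))))
    expect_equal(criterion_a(st, p), a_brute)

    b_brute <- sort(unique(c(st$I[ok & st$mean >= p$k_b], st$J[ok & st$mean >= p$k_b])))
    expect_equal(criterion_b(st, p), b_brute)

    for (mode in c("cv_mean", "cv_max", "absolute")) {
      pm <- criteria_params(variation_mode = mode)
      v <- switch(mode, cv_mean = st$sd / st$mean, cv_max = st$sd / st$max,
                  absolute = st$sd)
      sel <- ok & st$mean > 0 & st$max >= pm$k_c & v >= pm$s_c
      expect_equal(criterion_c(st, pm), sort(unique(c(st$I[sel], st$J[sel]))))
    }

    comb <- combine_criteria(st, p)
    expect_equal(comb$residue, sort(unique(c(
      criterion_a(st, p), criterion_b(st, p), criterion_c(st, p)
    ))))
    expect_equal(comb$residue[comb$A], criterion_a(st, p))
  }
})

test_that("raising any cutoff never enlarges a selection", {
  st <- random_stats_table(n_res = 60, n_pairs = 300, seed = 77)
  sizes_a <- sapply(seq(0.5, 6, by = 0.5), function(kc) {
    length(criterion_a(st, criteria_params(k_cut = kc)))
  })
  expect_true(all(diff(sizes_a) <= 0))
  sizes_n <- sapply(2:14, function(nc) {
    length(criterion_a(st, criteria_params(n_cut = nc)))
  })
  expect_true(all(diff(sizes_n) <= 0))
  sizes_b <- sapply(seq(1, 14, by = 1), function(kb) {
    length(criterion_b(st, criteria_params(k_b = kb)))
  })
  expect_true(all(diff(sizes_b) <= 0))
  sizes_c <- sapply(seq(0.1, 2, by = 0.1), function(sc) {
    length(criterion_c(st, criteria_params(s_c = sc)))
  })
  expect_true(all(diff(sizes_c) <= 0))
})

test_that("hit rate and coverage follow the +/-1 rule", {
  ev <- evaluate_selection(c(3, 10, 50), c(3, 10, 50), n_residues = 60)
  expect_equal(ev$hit_rate, 1)
  expect_equal(ev$coverage, 1)

  ev2 <- evaluate_selection(10, 11, n_residues = 60)
  expect_equal(ev2$hit_rate, 1)
  expect_equal(ev2$coverage, 1)

  ev3 <- evaluate_selection(integer(0), c(5, 9), n_residues = 60)
  expect_true(is.na(ev3$hit_rate))
  expect_equal(ev3$coverage, 0)

  # selecting the whole universe always covers everything
  ev4 <- evaluate_selection(1:60, c(1, 30, 60), n_residues = 60)
  expect_equal(ev4$coverage, 1)

  # exhaustive oracle on random selections
  for (case in 1:20) {
    withr::with_seed(500 + case, {
      n <- 50
      sel <- sample.int(n, sample(0:12, 1))
      ref <- sample.int(n, sample(1:10, 1))
    })
    ev <- evaluate_selection(sel, ref, n_residues = n)
    hits <- sum(vapply(sel, function(s) any(abs(s - ref) <= 1), logical(1)))
    cov <- sum(vapply(ref, function(r) any(abs(r - sel) <= 1), logical(1)))
    expect_equal(ev$n_hits, hits)
    expect_equal(ev$n_covered, cov)
  }
})

test_that("the random baseline is seeded and respects degenerate limits", {
  # reference = whole universe: every pick is a hit with zero spread
  b <- random_baseline(5, 30, 1:30, n_rounds = 200, seed = 3)
  expect_equal(b$mean_hit_rate, 1)
  expect_equal(b$sd_hit_rate, 0)

  b1 <- random_baseline(10, 100, c(10, 40, 70), n_rounds = 500, seed = 11)
  b2 <- random_baseline(10, 100, c(10, 40, 70), n_rounds = 500, seed = 11)
  expect_identical(b1, b2)
  b3 <- random_baseline(10, 100, c(10, 40, 70), n_rounds = 500, seed = 12)
  expect_false(identical(b1$mean_hits, b3$mean_hits))
})

test_that("residue lists round-trip with comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# reference sites", "10", "25 # loop", "", "3"), path)
  expect_equal(read_residue_list(path), c(3L, 10L, 25L))
  write_residue_list(c(7, 2, 7), path)
  expect_equal(read_residue_list(path), c(2L, 7L))
})
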