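toy_msa <- function(strings, refpos = NULL) {
  msa(do.call(rbind, strsplit(strings, "")), refpos = refpos)
}

test_that("gap filters keep alignable sequences and enforce the loop rule", {
  aln <- toy_msa(c(
    "ACDEFGHIKL", # gapless
    "AC-EFGHIK-", # 2 gaps, none in loop
    "ACDEF--IKL", # 2 gaps in loop columns
    "A---F--IKL"  # many gaps
  ))
  out <- filter_alignment(aln, max_gaps = 2, loop_positions = 6:7, max_loop_gaps = 1)
  expect_equal(out$ids, c("seq1", "seq2"))

  # brute-force count oracle over random gap patterns
  withr::with_seed(600, {
    mat <- matrix(sample(c("A", "C", "-"), 30 * 20, TRUE, prob = c(.4, .4, .2)), 30)
  })
  aln_r <- msa(mat)
  out_r <- filter_alignment(aln_r, max_gaps = 4, loop_positions = 8:10,
                            max_loop_gaps = 1)
  keep <- rowSums(mat == "-") <= 4 & rowSums(mat[, 8:10] == "-") <= 1
  expect_equal(out_r$ids, paste0("seq", which(keep)))

  all_gapped <- toy_msa(c("A-CDEFGHIK", "AC-DEFGHIK"))
  expect_error(filter_alignment(all_gapped, max_gaps = 0), "no sequences")
})

test_that("redundancy removal clusters by single linkage and keeps first-seen", {
  aln <- toy_msa(c(
    "ACDEFGHIKLMNPQRSTVWY",
    "ACDEFGHIKLMNPQRSTVWF", # 95% identical to seq1
    "YWVTSRQPNMLKIHGFEDCA", # unrelated
    "ACDEFGHIKLMNPQRSTVCF"  # 90% to seq1 but 95% to seq2 -> chained into cluster 1
  ))
  out <- remove_redundant(aln, identity = 0.95)
  expect_equal(out$ids, c("seq1", "seq3"))

  distinct <- toy_msa(c("ACDEFGHIKL", "ACDEFGHIVW", "MNPQRSTVWY"))
  expect_equal(remove_redundant(distinct, identity = 0.95)$ids, distinct$ids)
})

test_that("binarisation uses the consensus letter, ties, gaps and pseudocounts correctly", {
  aln <- toy_msa(c("AAC", "AC-", "GCA", "ACA"))
  bz <- binarize(aln)
  expect_equal(bz$profile$consensus, c("A", "C", "A"))
  expect_equal(bz$x[, 1], c(1L, 1L, 0L, 1L))
  expect_equal(bz$x[, 3], c(0L, 0L, 1L, 1L)) # the gap scores 0

  # column 3 ties A (2) against C (1)... recompute: entries C, -, A, A -> A wins
  tie <- toy_msa(c("AC", "CA", "GA", "GC"))
  bz_tie <- binarize(tie)
  # column 1: A=1, C=1, G=2 -> G; column 2: A=2, C=2 tie -> A (alphabetical)
  expect_equal(bz_tie$profile$consensus, c("G", "A"))

  # conservation is a relative entropy: non-negative, zero iff f_reg = q
  q <- aa_background_frequencies()
  rand <- binarize(synth_alignment(150, 25, sectors = list(), seed = 605))
  expect_true(all(rand$profile$D >= 0))
  f_at_q <- q[["V"]]
  D_at_q <- f_at_q * log(f_at_q / q[["V"]]) +
    (1 - f_at_q) * log((1 - f_at_q) / (1 - q[["V"]]))
  expect_equal(unname(D_at_q), 0)

  # fully conserved column matches the direct regularised formula
  expect_warning(
    cons <- binarize(toy_msa(rep("W", 50)), pseudocount = 0.01),
    "constant columns"
  )
  lam <- 0.01; qW <- q[["W"]]
  f_reg <- (1 - lam) * 1 + lam * qW
  D_direct <- f_reg * log(f_reg / qW) + (1 - f_reg) * log((1 - f_reg) / (1 - qW))
  expect_equal(cons$profile$D, unname(D_direct), tolerance = 1e-12)
})

test_that("the coupling matrix is symmetric, non-negative, and finds a planted pair", {
  # two perfectly co-varying columns among independent ones
  withr::with_seed(601, {
    n <- 400
    z <- rbinom(n, 1, 0.5)
    col_letters <- function(active) ifelse(active == 1, "A", "C")
    mat <- cbind(
      col_letters(z), col_letters(z),
      replicate(8, col_letters(rbinom(n, 1, 0.6)))
    )
  })
  bz <- binarize(msa(mat))
  scam <- sca_matrix(bz$x, bz$profile)
  expect_true(isSymmetric(scam$C))
  expect_true(all(scam$C >= 0))
  expect_true(all(Re(scam$values) == scam$values))
  # the dominant coupling mode loads on exactly the planted pair (in this
  # small homogeneous alignment the pair block outweighs the conservation
  # mode, so it surfaces as the leading eigenvector)
  lead <- abs(scam$vectors[, 1])
  expect_setequal(order(lead, decreasing = TRUE)[1:2], 1:2)

  # independent columns: off-diagonal mass is small against the diagonal
  off <- scam$C[-(1:2), -(1:2)]
  expect_lt(mean(off[upper.tri(off)]), 0.1 * mean(diag(off)))
})

test_that("eigenvector significance is seeded and calibrated", {
  aln <- synth_alignment(200, 60, sectors = list(10:17), seed = 602)
  bz <- binarize(aln)
  scam <- sca_matrix(bz$x, bz$profile)
  s1 <- eigen_significance(scam, bz$x, n_randomizations = 25, seed = 7)
  s2 <- eigen_significance(scam, bz$x, n_randomizations = 25, seed = 7)
  expect_identical(s1, s2)
  expect_true(2 %in% s1$significant)
  expect_error(eigen_significance(scam, bz$x, n_randomizations = 5), "at least 10")
})

test_that("sector selection respects the cutoff and clusters planted sectors", {
  sectors <- list(seq(4, 26, by = 2), seq(30, 52, by = 2), seq(56, 78, by = 2))
  aln <- synth_alignment(300, 80, sectors, seed = 603)
  bz <- binarize(aln)
  scam <- sca_matrix(bz$x, bz$profile)

  all_sel <- select_sectors(scam, cutoff = 0, n_sectors = 3, seed = 1)
  expect_true(all(!is.na(all_sel$sector)))

  sa <- select_sectors(scam, cutoff = 0.07, n_sectors = 3, seed = 1)
  sel <- sa$refpos[!is.na(sa$sector)]
  planted <- sort(unlist(sectors))
  expect_gte(mean(sel %in% planted), 0.9)
  expect_gte(mean(planted %in% sel), 0.9)
  # partition matches the planting up to label permutation
  lab <- sa$sector[match(intersect(sel, planted), sa$refpos)]
  truth <- sapply(intersect(sel, planted), function(p) {
    which(sapply(sectors, function(ss) p %in% ss))
  })
  conf <- table(lab, truth)
  expect_gte(sum(apply(conf, 1, max)) / sum(conf), 0.9)

  # nothing reaches an absurd cutoff: empty selection, no labels, no error
  none <- select_sectors(scam, cutoff = 0.9, n_sectors = 3)
  expect_true(all(is.na(none$sector)))

  # a non-empty selection smaller than the sector count is an error
  tiny <- structure(
    list(
      values = c(3, 2, 1),
      vectors = rbind(c(1, 0.5, 0), c(0, 0, 0.5), c(1, 0.001, 0.001)) ,
      profile = tibble::tibble(column = 1:3, refpos = 1:3),
      C = diag(3)
    ),
    class = "sca_matrix"
  )
  expect_error(select_sectors(tiny, cutoff = 0.07, n_sectors = 3), "cannot form")
})

test_that("matrix cleaning reconstructs low-rank structure with sector-block contrast", {
  sectors <- list(seq(4, 26, by = 2), seq(30, 52, by = 2), seq(56, 78, by = 2))
  aln <- synth_alignment(300, 80, sectors, seed = 603)
  bz <- binarize(aln)
  scam <- sca_matrix(bz$x, bz$profile)
  sa <- select_sectors(scam, cutoff = 0.07, n_sectors = 3, seed = 1)

  rank1 <- clean_matrix(scam, sa, indices = 2)
  expect_equal(qr(rank1)$rank, 1)

  # summing all eigenvectors reconstructs the full matrix on the selection
  full <- clean_matrix(scam, sa, indices = seq_along(scam$values))
  ord <- attr(full, "order")
  expect_equal(unclass(full), scam$C[ord$column, ord$column],
               ignore_attr = TRUE, tolerance = 1e-8)

  cleaned <- clean_matrix(scam, sa, indices = 2:4)
  ord <- attr(cleaned, "order")
  same <- outer(ord$sector, ord$sector, "==")
  diag(same) <- NA
  expect_gt(mean(abs(cleaned[same & !is.na(same)])),
            mean(abs(cleaned[!same & !is.na(same)])))
})

test_that("aligned FASTA round-trips", {
  aln <- synth_alignment(12, 30, sectors = list(), seed = 604)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_alignment_fasta(aln, path)
  back <- read_alignment_fasta(path)
  expect_equal(back$mat, aln$mat)
  expect_error(
    read_alignment_fasta({
      p <- withr::local_tempfile(fileext = ".fasta")
      writeLines(c(">a", "ACDE", ">b", "ACD"), p); p
    }),
    "unequal"
  )
})
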