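# Shared fixtures, memoised so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

default_network <- function() memo("net1", make_toy_network(seed = 1))

default_traj_4000 <- function() {
  memo("traj4000", sample_from_network(default_network(), 4000, seed = 101))
}

default_pool <- function() memo("pool1", init_bond_pool(default_traj_4000(), 10))

# independent SVD-based Kabsch superposition used as the oracle for the
# bio3d-backed fitting inside the package
kabsch_oracle <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- svd(t(Pc) %*% Qc)
  d <- sign(det(S$v %*% t(S$u)))
  R <- S$v %*% diag(c(1, 1, d)) %*% t(S$u)
  sweep(Pc %*% t(R), 2, cq, `+`)
}

rmsd_oracle <- function(P, Q) {
  fit <- kabsch_oracle(P, Q)
  sqrt(mean(rowSums((fit - Q)^2)))
}

# minimal synthetic atomic structure: per residue N, CA, C, O plus two
# sidechain atoms (CB, CG) unless glycine; optional single-atom ion
make_fake_protein <- function(n_res, glycine_at = integer(), ion = FALSE,
                              seed = 42) {
  withr::with_seed(seed, {
    rows <- list()
    for (r in seq_len(n_res)) {
      base <- c(3.8 * r, 0, 0)
      gly <- r %in% glycine_at
      names_r <- if (gly) c("N", "CA", "C", "O") else c("N", "CA", "C", "O", "CB", "CG")
      mass_r <- if (gly) c(14.007, 12.011, 12.011, 15.999) else
        c(14.007, 12.011, 12.011, 15.999, 12.011, 12.011)
      for (a in seq_along(names_r)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          atom = names_r[a],
          residue = r,
          resname = if (gly) "GLY" else "ALA",
          mass = mass_r[a],
          x = base[1] + stats::rnorm(1, sd = 0.8),
          y = base[2] + stats::rnorm(1, sd = 0.8),
          z = base[3] + stats::rnorm(1, sd = 0.8)
        )
      }
    }
    if (ion) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        atom = "CA", residue = n_res + 1L, resname = "CAL", mass = 40.078,
        x = 3.8 * (n_res + 1), y = 0, z = 0
      )
    }
    dplyr::bind_rows(rows)
  })
}

# build a fluctuogram object directly from per-window force-constant and
# rest-length matrices (bonds x windows), bypassing the matcher, for metric
# unit tests with exactly controlled values
fake_fluctuogram <- function(pool, K, B = NULL, residues = NULL, coords = NULL) {
  n_sites <- max(pool$j)
  if (is.null(residues)) residues <- seq_len(n_sites)
  if (is.null(coords)) {
    coords <- withr::with_seed(1, matrix(stats::rnorm(3 * n_sites, sd = 5), n_sites))
  }
  if (is.null(B)) B <- matrix(4, nrow(pool), ncol(K))
  networks <- lapply(seq_len(ncol(K)), function(w) {
    elastic_network(
      tibble::tibble(i = pool$i, j = pool$j, b = B[, w], k = K[, w]),
      coords = coords, residues = residues
    )
  })
  structure(
    list(
      networks = networks,
      windows = tibble::tibble(
        window = seq_len(ncol(K)),
        start = seq_len(ncol(K)), end = seq_len(ncol(K)) + 1L,
        midpoint_time = as.double(seq_len(ncol(K)))
      ),
      pool = pool[, c("i", "j")],
      residues = as.integer(residues),
      convergence = NULL, config = NULL
    ),
    class = "fluctuogram"
  )
}

# brute-force residue-pair aggregation oracle
residue_pair_oracle <- function(network) {
  res <- network$residues
  out <- list()
  for (r in seq_len(nrow(network$bonds))) {
    I <- min(res[network$bonds$i[r]], res[network$bonds$j[r]])
    J <- max(res[network$bonds$i[r]], res[network$bonds$j[r]])
    key <- paste(I, J)
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + network$bonds$k[r]
  }
  tb <- tibble::tibble(
    I = as.integer(sub(" .*", "", names(out))),
    J = as.integer(sub(".* ", "", names(out))),
    k = unlist(out, use.names = FALSE)
  )
  dplyr::arrange(tb, I, J)
}

# random pair-statistics table for criteria tests
random_stats_table <- function(n_res = 40, n_pairs = 120, seed = 1) {
  withr::with_seed(seed, {
    pr <- unique(t(replicate(n_pairs, sort(sample.int(n_res, 2)))))
    mean_k <- stats::runif(nrow(pr), 0, 15)
    sdk <- stats::runif(nrow(pr), 0, 10)
    tibble::tibble(
      I = as.integer(pr[, 1]), J = as.integer(pr[, 2]),
      mean = mean_k, sd = sdk,
      max = mean_k + stats::runif(nrow(pr), 0, 2) * sdk,
      separation = as.integer(abs(pr[, 2] - pr[, 1]))
    )
  })
}
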