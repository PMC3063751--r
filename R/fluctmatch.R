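#' Bond pool from a trajectory
#'
#' A site pair enters the pool iff its distance dips to the cutoff or below
#' in at least one frame of the trajectory, so the pool is a superset of any
#' single-frame contact map at the same cutoff and enlarging the cutoff can
#' only add pairs.
#'
#' @param traj A [cg_trajectory()].
#' @param cutoff Distance cutoff in Angstrom (default 10).
#' @return Tibble with columns `i`, `j` (`i < j`), ordered by `i` then `j`.
#' @export
init_bond_pool <- function(traj, cutoff = 10) {
  stop_if_not_scalar_number(cutoff, "cutoff", positive = TRUE)
  n <- n_sites(traj)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- as.integer(unname(pairs[, 1])); j <- as.integer(unname(pairs[, 2]))
  dmin <- rep(Inf, length(i))
  for (f in seq_len(n_frames(traj))) {
    dmin <- pmin(dmin, pair_distances(traj$coords[f, , ], i, j))
  }
  keep <- dmin <= cutoff
  arrange(tibble(i = i[keep], j = j[keep]), .data$i, .data$j)
}

#' Per-bond target statistics of a trajectory window
#'
#' For every pool pair, the mean inter-site distance over the window (the
#' rest length handed to the elastic network) and the population variance of
#' the distance (the fluctuation the matcher inverts), plus the window-mean
#' structure used as the rest geometry.
#'
#' @param traj A [cg_trajectory()].
#' @param bonds Pool tibble with columns `i`, `j` (see [init_bond_pool()]).
#' @param frames Optional integer vector restricting the window (default:
#'   all frames).
#' @return A `target_statistics` object: list with `bonds` (tibble `i`, `j`,
#'   `b`, `variance`), `coords` (mean structure), `residues`, `masses`,
#'   `n_frames`.
#' @export
measure_targets <- function(traj, bonds, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  if (length(frames) < 2) abort("a window needs at least 2 frames")
  sub <- traj$coords[frames, , , drop = FALSE]
  nf <- length(frames)
  d <- vapply(
    seq_len(nf),
    function(f) pair_distances(sub[f, , ], bonds$i, bonds$j),
    double(nrow(bonds))
  )
  if (nrow(bonds) == 1) d <- matrix(d, nrow = 1)
  b <- rowMeans(d)
  variance <- rowMeans((d - b)^2)
  if (any(variance == 0)) {
    bad <- which(variance == 0)[1]
    abort(sprintf(
      "bond (%d,%d) has zero distance variance; inversion undefined",
      bonds$i[bad], bonds$j[bad]
    ))
  }
  structure(
    list(
      bonds = tibble(i = bonds$i, j = bonds$j, b = b, variance = variance),
      coords = colMeans(sub, dims = 1),
      residues = site_residues(traj$mapping, n_sites(traj)),
      masses = if (!is.null(traj$mapping)) traj$mapping$mass else rep(1, n_sites(traj)),
      n_frames = nf
    ),
    class = "target_statistics"
  )
}

#' Sample variances of the linearised bond coordinate
#'
#' Projects each frame's inter-site displacement onto the unit bond vector
#' of the reference geometry and returns the population variance of that
#' projection.  This is the quantity normal-mode analysis predicts exactly
#' for a Gaussian ensemble, whereas the Euclidean distance variance of
#' [measure_targets()] additionally carries second-order (transverse)
#' contributions of relative size ~ (transverse variance / bond length)^2.
#' Used to cross-validate [predict_bond_variances()] against the Gaussian
#' sampler without the distance nonlinearity.
#'
#' @param traj A [cg_trajectory()].
#' @param bonds Tibble with columns `i`, `j`.
#' @param reference Sites x 3 reference geometry defining the bond
#'   directions (e.g. the network's rest geometry).
#' @return Tibble `i`, `j`, `variance` (Angstrom^2).
#' @export
measure_projected_variances <- function(traj, bonds, reference) {
  variance <- vapply(seq_len(nrow(bonds)), function(r) {
    i <- bonds$i[r]; j <- bonds$j[r]
    e <- reference[j, ] - reference[i, ]
    e <- e / sqrt(sum(e * e))
    d <- (traj$coords[, j, ] - traj$coords[, i, ]) %*% e
    mean((d - mean(d))^2)
  }, double(1))
  tibble(i = bonds$i, j = bonds$j, variance = variance)
}

#' @export
print.target_statistics <- function(x, ...) {
  cat(sprintf(
    "<target_statistics> %d bonds over %d frames\n", nrow(x$bonds), x$n_frames
  ))
  invisible(x)
}

#' Fluctuation-matching settings
#'
#' @param alpha Dimensionless step constant of the iterative update
#'   (default 0.2).  The isolated-bond iteration contracts for any
#'   `alpha < 2`; dense pools of overlapping bonds amplify the collective
#'   update, and 0.2 keeps the iteration stable on realistic contact
#'   densities while converging within a few dozen steps.
#' @param rule Update rule.  `"inverse_variance"` (default):
#'   `k <- k + alpha * kB * T * (1/var_target - 1/var_predicted)`, whose fixed
#'   point for an isolated bond is exactly `kB*T/var`.
#'   `"variance_difference"`: `k <- k - alpha * kB * T *
#'   (var_predicted - var_target) / var_target^2`, a first-order equivalent
#'   scale-matched form.
#' @param tolerance Convergence threshold on the RMS force-constant change
#'   between successive iterations, kcal/mol/A^2 (default 0.005).
#' @param max_iterations Iteration cap (default 1000).
#' @param temperature Temperature in Kelvin (default 300).
#' @return A `fluctmatch_config` list.
#' @export
fluctmatch_config <- function(alpha = 0.2,
                              rule = c("inverse_variance", "variance_difference"),
                              tolerance = 0.005, max_iterations = 1000,
                              temperature = 300) {
  rule <- match.arg(rule)
  stop_if_not_scalar_number(alpha, "alpha", positive = TRUE)
  stop_if_not_scalar_number(tolerance, "tolerance", positive = TRUE)
  structure(
    list(
      alpha = alpha, rule = rule, tolerance = tolerance,
      max_iterations = as.integer(max_iterations), temperature = temperature
    ),
    class = "fluctmatch_config"
  )
}

#' Initial force constants from target variances
#'
#' The starting distribution is inversely proportional to the observed
#' variances with proportionality constant `kB*T`, so an isolated harmonic
#' bond starts at its exact answer `kB*T / var`.
#'
#' @param targets A `target_statistics` from [measure_targets()], or a
#'   numeric vector of variances.
#' @param temperature Temperature in Kelvin.
#' @return Numeric vector of initial force constants (kcal/mol/A^2).
#' @export
initialize_force_constants <- function(targets, temperature = 300) {
  v <- if (inherits(targets, "target_statistics")) targets$bonds$variance else targets
  if (any(v <= 0)) abort("target variances must be > 0")
  kBT(temperature) / v
}

#' Invert bond-length fluctuations into force constants
#'
#' Iterative fluctuation matching: starting from [initialize_force_constants()],
#' each step predicts every bond's length variance by normal-mode analysis of
#' the current network ([predict_bond_variances()]), moves each force
#' constant by the configured update rule toward agreement with the target
#' variance, clamps at zero (only non-negative force constants are
#' physical), and stops once the RMS force-constant change drops below the
#' tolerance.  Bonds driven to zero stay in the pool and may re-enter.  The
#' procedure is deterministic given the targets.
#'
#' @param targets A `target_statistics` from [measure_targets()].
#' @param config A [fluctmatch_config()].
#' @param k_init Optional warm-start force constants (one per target bond);
#'   default [initialize_force_constants()].  Starting at an exact fixed
#'   point (predicted variances equal to the targets) terminates at
#'   iteration 1 with zero change.
#' @return A `fluct_match` object: list with `network` (the matched
#'   [elastic_network()], rest lengths = target means), `trace` (tibble
#'   `iteration`, `rms_dk`, `rms_dvar`), `converged`, `iterations`.
#' @export
fluctuation_match <- function(targets, config = fluctmatch_config(),
                              k_init = NULL) {
  stopifnot(inherits(targets, "target_statistics"))
  k <- if (is.null(k_init)) {
    initialize_force_constants(targets, config$temperature)
  } else {
    stopifnot(length(k_init) == nrow(targets$bonds), all(k_init >= 0))
    as.double(k_init)
  }
  net <- elastic_network(
    mutate(targets$bonds[, c("i", "j", "b")], k = k),
    coords = targets$coords, masses = targets$masses,
    temperature = config$temperature, residues = targets$residues
  )
  v_target <- targets$bonds$variance
  kbt <- kBT(config$temperature)

  trace <- vector("list", config$max_iterations)
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_iterations) {
    iter <- iter + 1L
    v_pred <- predict_bond_variances(net)$variance
    dk <- switch(config$rule,
      inverse_variance = config$alpha * kbt * (1 / v_target - 1 / v_pred),
      variance_difference = -config$alpha * kbt * (v_pred - v_target) / v_target^2
    )
    k_new <- pmax(net$bonds$k + dk, 0)
    rms_dk <- sqrt(mean((k_new - net$bonds$k)^2))
    trace[[iter]] <- tibble(
      iteration = iter, rms_dk = rms_dk,
      rms_dvar = sqrt(mean((v_pred - v_target)^2))
    )
    net$bonds$k <- k_new
    if (rms_dk < config$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf(
      "fluctuation matching did not converge in %d iterations (last RMS dk = %.3g)",
      config$max_iterations, trace[[iter]]$rms_dk
    ))
  }
  structure(
    list(
      network = net, trace = bind_rows(trace[seq_len(iter)]),
      converged = converged, iterations = iter, config = config
    ),
    class = "fluct_match"
  )
}

#' @export
print.fluct_match <- function(x, ...) {
  cat(sprintf(
    "<fluct_match> %d bonds, %s after %d iterations (RMS dk = %.3g)\n",
    nrow(x$network$bonds),
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$trace$rms_dk[x$iterations]
  ))
  invisible(x)
}

#' @export
tidy.fluct_match <- function(x, ...) tidy(x$network)

#' @export
glance.fluct_match <- function(x, ...) {
  tibble(
    converged = x$converged, iterations = x$iterations,
    rms_dk = x$trace$rms_dk[x$iterations],
    rms_dvar = x$trace$rms_dvar[x$iterations],
    n_bonds = nrow(x$network$bonds),
    n_zero = sum(x$network$bonds$k == 0)
  )
}

#' Write a convergence trace as TSV
#'
#' @param x A `fluct_match` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# iter\trms_dk\trms_dvar", con)
  writeLines(sprintf(
    "%d\t%.17g\t%.17g", x$trace$iteration, x$trace$rms_dk, x$trace$rms_dvar
  ), con)
  invisible(path)
}
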