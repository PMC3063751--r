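#' Coarse-grained trajectory container
#'
#' Holds site coordinates over time: an array `frames x sites x 3` (Angstrom),
#' strictly increasing frame times (ns), and optionally the [build_cg_mapping()]
#' the sites came from.  Toy trajectories from the synthetic generators carry
#' no mapping; metrics then treat each site as its own residue.
#'
#' @param coords Array `frames x sites x 3`.
#' @param times Numeric vector of frame times in ns, strictly increasing.
#' @param mapping Optional `cg_mapping`.
#' @return A `cg_trajectory` object.
#' @export
cg_trajectory <- function(coords, times = NULL, mapping = NULL) {
  if (!(is.array(coords) && length(dim(coords)) == 3 && dim(coords)[3] == 3)) {
    abort("`coords` must be a frames x sites x 3 array")
  }
  if (is.null(times)) times <- (seq_len(dim(coords)[1]) - 1) * 0.001
  if (length(times) != dim(coords)[1]) {
    abort("`times` must have one entry per frame")
  }
  if (any(diff(times) <= 0)) abort("frame times must be strictly increasing")
  structure(
    list(coords = coords, times = as.double(times), mapping = mapping),
    class = "cg_trajectory"
  )
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat(sprintf(
    "<cg_trajectory> %d frames x %d sites, t = %.4g..%.4g ns\n",
    n_frames(x), n_sites(x), x$times[1], x$times[n_frames(x)]
  ))
  invisible(x)
}

#' @rdname cg_trajectory
#' @param traj A `cg_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname cg_trajectory
#' @export
n_sites <- function(traj) dim(traj$coords)[2]

#' Residue index of each site
#'
#' Sites of a mapped trajectory belong to the residues recorded in its
#' mapping; sites of an unmapped (toy) trajectory or network are their own
#' residues.
#'
#' @param x A `cg_trajectory`, `cg_mapping`, or `NULL`.
#' @param n Number of sites, required when `x` is `NULL`.
#' @return Integer vector: residue index per site.
#' @export
site_residues <- function(x, n = NULL) {
  if (inherits(x, "cg_trajectory")) x <- x$mapping
  if (inherits(x, "cg_mapping")) return(x$residue)
  if (is.null(x)) {
    if (is.null(n)) abort("`n` is required when no mapping is available")
    return(seq_len(n))
  }
  abort("cannot derive site residues from this object")
}

# frames x 3n matrix view used by the bio3d fitting routines
traj_xyz <- function(coords) {
  nf <- dim(coords)[1]
  t(vapply(seq_len(nf), function(f) as.vector(t(coords[f, , ])), double(dim(coords)[2] * 3)))
}

xyz_to_coords <- function(xyz) {
  nf <- nrow(xyz)
  ns <- ncol(xyz) / 3
  out <- array(NA_real_, c(nf, ns, 3))
  for (f in seq_len(nf)) out[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  out
}

#' Per-site root-mean-square fluctuation
#'
#' Frames are rigid-body superposed on the mean structure (least-squares
#' Kabsch fit, iterated until the mean converges) before accumulating squared
#' deviations, so rigid translations and rotations contribute nothing.
#'
#' @param traj A [cg_trajectory()].
#' @param sites Optional integer vector of sites to fit and report
#'   (default: all).
#' @return Tibble with columns `site`, `residue`, `rmsf` (Angstrom).
#' @export
compute_rmsf <- function(traj, sites = NULL) {
  if (n_frames(traj) < 2) abort("RMSF needs at least 2 frames")
  if (is.null(sites)) sites <- seq_len(n_sites(traj))
  coords <- traj$coords[, sites, , drop = FALSE]
  check_fit_geometry(colMeans(coords[, , , drop = FALSE], dims = 1))
  xyz <- traj_xyz(coords)
  inds <- seq_len(ncol(xyz))
  ref <- xyz[1, ]
  for (it in 1:3) {
    fitted <- bio3d::fit.xyz(ref, xyz, fixed.inds = inds, mobile.inds = inds)
    ref <- colMeans(fitted)
  }
  dev2 <- sweep(fitted, 2, ref)^2
  per_site <- matrix(colMeans(dev2), ncol = 3, byrow = TRUE)
  tibble(
    site = sites,
    residue = site_residues(traj$mapping, n_sites(traj))[sites],
    rmsf = sqrt(rowSums(per_site))
  )
}

check_fit_geometry <- function(mean_coords) {
  centered <- sweep(mean_coords, 2, colMeans(mean_coords))
  if (qr(centered)$rank < 2) {
    warn("mean structure is (nearly) collinear; superposition is ill-determined")
  }
  invisible(NULL)
}

#' Per-frame root-mean-square deviation from a reference
#'
#' Each frame is least-squares superposed on the reference before the RMSD
#' is taken, so a frame differing only by a rigid-body transform scores 0.
#'
#' @param traj A [cg_trajectory()].
#' @param reference A sites x 3 coordinate matrix.
#' @return Tibble with columns `frame`, `time`, `rmsd` (Angstrom).
#' @export
compute_rmsd <- function(traj, reference) {
  if (!is.matrix(reference) || nrow(reference) != n_sites(traj)) {
    abort("`reference` must be a sites x 3 matrix matching the trajectory")
  }
  xyz <- traj_xyz(traj$coords)
  ref <- as.vector(t(reference))
  inds <- seq_along(ref)
  fitted <- bio3d::fit.xyz(ref, xyz, fixed.inds = inds, mobile.inds = inds)
  dev2 <- sweep(fitted, 2, ref)^2
  vals <- sqrt(rowSums(dev2) / n_sites(traj))
  tibble(frame = seq_len(n_frames(traj)), time = traj$times, rmsd = as.double(vals))
}

#' Read and write the plain-text XYZT trajectory format
#'
#' A minimal whitespace-separated dialect: a header line `nsites nframes`,
#' then for each frame one line with the time in ns followed by `nsites`
#' lines `x y z` in Angstrom, written at full double precision.
#'
#' @param path File path.
#' @param traj A [cg_trajectory()] (writer).
#' @return `read_xyzt()` returns a [cg_trajectory()] (without mapping);
#'   `write_xyzt()` returns `path` invisibly.
#' @export
read_xyzt <- function(path) {
  tok <- scan(path, what = double(), quiet = TRUE, comment.char = "#")
  ns <- as.integer(tok[1]); nf <- as.integer(tok[2])
  expect <- 2 + nf * (1 + 3 * ns)
  if (length(tok) != expect) {
    abort(sprintf("malformed XYZT file: expected %d numbers, found %d", expect, length(tok)))
  }
  body <- tok[-(1:2)]
  per <- 1 + 3 * ns
  times <- body[seq(1, by = per, length.out = nf)]
  coords <- array(NA_real_, c(nf, ns, 3))
  for (f in seq_len(nf)) {
    block <- body[((f - 1) * per + 2):(f * per)]
    coords[f, , ] <- matrix(block, ncol = 3, byrow = TRUE)
  }
  cg_trajectory(coords, times = times)
}

#' @rdname read_xyzt
#' @export
write_xyzt <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(sprintf("%d %d", n_sites(traj), n_frames(traj)), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(fmt(traj$times[f]), con)
    m <- traj$coords[f, , , drop = FALSE]
    writeLines(paste(fmt(m[1, , 1]), fmt(m[1, , 2]), fmt(m[1, , 3])), con)
  }
  invisible(path)
}
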