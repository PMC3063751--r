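#' Elastic network model of one trajectory window
#'
#' A set of coarse-grained sites with a rest geometry and harmonic bonds.
#' The potential is the sum over bonds of `k_ij/2 * (d_ij - b_ij)^2` with
#' `d_ij` the inter-site distance, `b_ij` the rest length (Angstrom) and
#' `k_ij >= 0` the force constant (kcal/mol/A^2).  Rest lengths are taken as
#' the window-mean distances, so the Hessian at the rest geometry reduces to
#' the standard ENM block form `-k * e %o% e` per bond.
#'
#' @param bonds Tibble with columns `i`, `j` (1-based site ids, `i < j`),
#'   `b` (rest length, Angstrom) and `k` (force constant, kcal/mol/A^2).
#' @param coords Sites x 3 rest-geometry matrix used for bond directions.
#' @param masses Site masses (amu); default 1 for every site.  Equal-time
#'   positional covariances are mass-independent; masses are carried for
#'   completeness.
#' @param temperature Temperature in Kelvin (default 300).
#' @param residues Optional integer vector: residue of each site (default:
#'   each site its own residue).
#' @return An `elastic_network` object.
#' @export
elastic_network <- function(bonds, coords, masses = NULL, temperature = 300,
                            residues = NULL) {
  bonds <- as_tibble(bonds)
  stopifnot(all(c("i", "j", "b", "k") %in% names(bonds)))
  if (!is.matrix(coords) || ncol(coords) != 3) {
    abort("`coords` must be a sites x 3 matrix")
  }
  n <- nrow(coords)
  if (any(bonds$i >= bonds$j)) abort("bonds must have i < j")
  if (any(bonds$i < 1 | bonds$j > n)) abort("bond site ids out of range")
  if (anyDuplicated(bonds[, c("i", "j")]) > 0) abort("duplicate bonds")
  if (any(bonds$k < 0)) abort("force constants must be >= 0")
  if (any(bonds$b <= 0)) abort("rest lengths must be > 0")
  if (is.null(masses)) masses <- rep(1, n)
  if (is.null(residues)) residues <- seq_len(n)
  structure(
    list(
      bonds = bonds, coords = coords, masses = as.double(masses),
      temperature = temperature, residues = as.integer(residues)
    ),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf(
    "<elastic_network> %d sites, %d bonds (%d with k > 0), T = %g K\n",
    nrow(x$coords), nrow(x$bonds), sum(x$bonds$k > 0), x$temperature
  ))
  invisible(x)
}

#' @export
tidy.elastic_network <- function(x, ...) {
  mutate(x$bonds,
    residue_i = x$residues[.data$i],
    residue_j = x$residues[.data$j]
  )
}

#' Harmonic potential energy of a configuration
#'
#' Sums `k/2 (d - b)^2` over the network's bonds.  Zero when every bond sits
#' at its rest length, and invariant under rigid-body transforms of the
#' coordinates.
#'
#' @param network An [elastic_network()].
#' @param coords Sites x 3 configuration matrix.
#' @return Energy in kcal/mol.
#' @export
network_energy <- function(network, coords) {
  if (!is.matrix(coords) || nrow(coords) != nrow(network$coords) ||
      ncol(coords) != 3 || !all(is.finite(coords))) {
    abort("`coords` must cover all sites with finite values")
  }
  d <- pair_distances(coords, network$bonds$i, network$bonds$j)
  sum(0.5 * network$bonds$k * (d - network$bonds$b)^2)
}

# 3n x 3n second-derivative matrix at the rest geometry: off-diagonal block
# for bond (i,j) is -k e e^T with e the unit bond vector; diagonal blocks
# are minus the sum of the incident off-diagonal blocks.
enm_hessian <- function(network) {
  n <- nrow(network$coords)
  H <- matrix(0, 3 * n, 3 * n)
  for (r in seq_len(nrow(network$bonds))) {
    i <- network$bonds$i[r]; j <- network$bonds$j[r]
    k <- network$bonds$k[r]
    if (k == 0) next
    e <- network$coords[j, ] - network$coords[i, ]
    e <- e / sqrt(sum(e * e))
    blk <- k * (e %o% e)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- H[ii, jj] - blk
    H[jj, ii] <- H[jj, ii] - blk
    H[ii, ii] <- H[ii, ii] + blk
    H[jj, jj] <- H[jj, jj] + blk
  }
  H
}

# number of rigid-body zero modes expected from the rest geometry:
# 3 for a single point, 5 for a collinear arrangement, 6 otherwise
expected_rigid_modes <- function(coords) {
  if (nrow(coords) == 1) return(3L)
  centered <- sweep(coords, 2, colMeans(coords))
  r <- qr(centered, tol = 1e-10)$rank
  if (r <= 1) 5L else 6L
}

# eigendecomposition of the Hessian with rigid-mode accounting.  Zero modes
# beyond the rigid-body count are tolerated when the bond graph is connected:
# an under-constrained ("floppy") network changes no bond length along such
# modes to first order, so bond-length statistics remain well defined.  A
# disconnected bond graph, or fewer zero modes than rigid-body motions
# (degenerate geometry), is an error.
enm_modes <- function(network, zero_tol = 1e-8) {
  H <- enm_hessian(network)
  eig <- eigen(H, symmetric = TRUE)
  lmax <- max(abs(eig$values))
  if (lmax == 0) abort("network has no bonds with positive force constants")
  zero <- abs(eig$values) < zero_tol * lmax
  expected <- expected_rigid_modes(network$coords)
  if (sum(zero) > expected) {
    active <- network$bonds[network$bonds$k > 0, c("i", "j")]
    g <- igraph::graph_from_edgelist(as.matrix(active), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nrow(network$coords) - igraph::vcount(g)))
    comp <- igraph::components(g)
    if (comp$no > 1) {
      abort(sprintf(
        "disconnected network: %d zero modes (expected %d); components: %s",
        sum(zero), expected,
        paste(vapply(
          seq_len(comp$no),
          function(cc) paste0("{", paste(which(comp$membership == cc), collapse = ","), "}"),
          character(1)
        ), collapse = " ")
      ))
    }
  }
  if (sum(zero) < expected) {
    abort(sprintf(
      "geometry error: %d zero modes found but %d rigid-body modes expected",
      sum(zero), expected
    ))
  }
  list(values = eig$values, vectors = eig$vectors, zero = zero)
}

#' Predict bond-length variances by normal-mode analysis
#'
#' Diagonalises the Hessian at the rest geometry, discards the rigid-body
#' zero modes, and returns for each bond the thermal variance of its length
#' under the Gaussian (harmonic) ensemble at the network temperature:
#' `kB T * e' (C_ii + C_jj - 2 C_ij) e` with `C` the positional covariance
#' `kB T H^+` and `e` the unit bond vector.
#'
#' @param network An [elastic_network()]; must be connected (only
#'   rigid-body zero modes).
#' @param zero_tol Relative eigenvalue threshold below which a mode is
#'   treated as zero (default 1e-8 of the largest eigenvalue).
#' @return Tibble `i`, `j`, `b`, `k`, `variance` (Angstrom^2).
#' @export
predict_bond_variances <- function(network, zero_tol = 1e-8) {
  modes <- enm_modes(network, zero_tol)
  keep <- which(!modes$zero)
  V <- modes$vectors[, keep, drop = FALSE]
  inv_l <- 1 / modes$values[keep]
  kbt <- kBT(network$temperature)

  bonds <- network$bonds
  variance <- vapply(seq_len(nrow(bonds)), function(r) {
    i <- bonds$i[r]; j <- bonds$j[r]
    e <- network$coords[j, ] - network$coords[i, ]
    e <- e / sqrt(sum(e * e))
    # projection of each kept mode onto the bond-length coordinate
    proj <- as.vector(
      e %*% (V[(3 * j - 2):(3 * j), , drop = FALSE] -
               V[(3 * i - 2):(3 * i), , drop = FALSE])
    )
    kbt * sum(proj^2 * inv_l)
  }, double(1))
  mutate(bonds, variance = variance)
}

#' Read and write the elastic-network TSV format
#'
#' Tab-separated columns `i`, `j`, `b`, `k` with `#`-prefixed header
#' comments recording the temperature and, when available, site residues,
#' masses and rest coordinates, so a round trip reproduces the network.
#'
#' @param network An [elastic_network()] (writer).
#' @param path File path.
#' @return `read_network_tsv()` an [elastic_network()]; `write_network_tsv()`
#'   `path`, invisibly.
#' @export
write_network_tsv <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sprintf("%.17g", x)
  writeLines(sprintf("# T=%s", fmt(network$temperature)), con)
  writeLines(sprintf("# residues=%s", paste(network$residues, collapse = ",")), con)
  writeLines(sprintf("# masses=%s", paste(fmt(network$masses), collapse = ",")), con)
  for (ax in 1:3) {
    writeLines(sprintf(
      "# coords%d=%s", ax, paste(fmt(network$coords[, ax]), collapse = ",")
    ), con)
  }
  writeLines("# i\tj\tb\tk", con)
  writeLines(sprintf(
    "%d\t%d\t%s\t%s",
    network$bonds$i, network$bonds$j, fmt(network$bonds$b), fmt(network$bonds$k)
  ), con)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  get_field <- function(name) {
    ln <- hdr[startsWith(hdr, paste0("# ", name, "="))]
    if (length(ln) == 0) return(NULL)
    as.numeric(strsplit(sub(paste0("^# ", name, "="), "", ln[1]), ",")[[1]])
  }
  parts <- do.call(rbind, strsplit(body, "\t"))
  bonds <- tibble(
    i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
    b = as.numeric(parts[, 3]), k = as.numeric(parts[, 4])
  )
  coords <- cbind(get_field("coords1"), get_field("coords2"), get_field("coords3"))
  elastic_network(
    bonds, coords,
    masses = get_field("masses"),
    temperature = get_field("T"),
    residues = as.integer(get_field("residues"))
  )
}
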