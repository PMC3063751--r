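#' Generate a toy elastic network with a realisable 3-D geometry
#'
#' Builds a connected network shaped like a globular coarse-grained
#' protein: a compact self-avoiding chain embedding (growth biased toward
#' the centroid, excluded volume respected) with chain bonds between
#' consecutive sites plus random longer-range contacts drawn from pairs
#' whose embedded distance lies within the contact window, so every bond
#' is also a spatial contact.  The default contact density mirrors a
#' protein interior at a ~9.5 Angstrom contact cutoff and makes the
#' network mechanically over-braced: its softest internal mode is stiff
#' enough that bond-length fluctuations stay small against the bond
#' lengths, the regime in which the harmonic (Gaussian) treatment of bond
#' statistics is accurate.  Force constants are drawn uniformly from
#' `k_range`.  Deterministic for a fixed seed.
#'
#' @param n_sites Number of sites (>= 2; default 20).
#' @param n_extra_contacts Number of non-chain bonds (default 100).
#' @param k_range Force-constant range in kcal/mol/A^2 (default `c(1, 20)`).
#' @param b_range Chain-bond length range in Angstrom (default
#'   `c(3.5, 4.1)`, the scale of consecutive coarse-grained sites).
#' @param temperature Temperature in Kelvin (default 300).
#' @param contact_window Distance window (Angstrom) from which extra
#'   contacts are drawn (default `c(3.5, 9.5)`).
#' @param seed RNG seed (required).
#' @return An [elastic_network()] with rest lengths equal to the embedded
#'   distances (each site its own residue).
#' @export
make_toy_network <- function(n_sites = 20, n_extra_contacts = 100,
                             k_range = c(1, 20), b_range = c(3.5, 4.1),
                             temperature = 300, contact_window = c(3.5, 9.5),
                             seed = 1) {
  if (n_sites < 2) abort("need at least 2 sites")
  with_seed(seed, {
    for (attempt in 1:50) {
      coords <- self_avoiding_chain(n_sites, b_range)
      if (is.null(coords)) next
      bonds <- tibble(
        i = seq_len(n_sites - 1L), j = seq_len(n_sites - 1L) + 1L
      )
      if (n_extra_contacts > 0 && n_sites > 2) {
        cand <- which(upper.tri(matrix(0, n_sites, n_sites)), arr.ind = TRUE)
        cand <- cand[cand[, 2] - cand[, 1] >= 2, , drop = FALSE]
        d <- pair_distances(coords, cand[, 1], cand[, 2])
        ok <- which(d >= contact_window[1] & d <= contact_window[2])
        if (length(ok) < n_extra_contacts) next
        pick <- sort(sample(ok, n_extra_contacts))
        bonds <- bind_rows(bonds, tibble(i = cand[pick, 1], j = cand[pick, 2]))
      }
      bonds <- arrange(bonds, .data$i, .data$j)
      bonds$b <- pair_distances(coords, bonds$i, bonds$j)
      bonds$k <- stats::runif(nrow(bonds), k_range[1], k_range[2])
      return(elastic_network(bonds, coords, temperature = temperature))
    }
    abort("could not embed a self-avoiding chain with enough contacts; relax the settings")
  })
}

# compact self-avoiding chain: candidate steps respect excluded volume and
# the closest-to-centroid candidate among a batch is kept, giving a
# globular embedding; NULL on failure
self_avoiding_chain <- function(n_sites, b_range, min_sep = 3.2,
                                max_tries = 500, batch = 20) {
  coords <- matrix(NA_real_, n_sites, 3)
  coords[1, ] <- 0
  for (s in 2:n_sites) {
    centroid <- colMeans(coords[seq_len(s - 1), , drop = FALSE])
    best <- NULL
    best_score <- Inf
    tried <- 0L
    for (try in seq_len(max_tries)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- coords[s - 1, ] + stats::runif(1, b_range[1], b_range[2]) * u
      prev <- coords[seq_len(s - 1), , drop = FALSE]
      d2 <- rowSums(sweep(prev, 2, cand)^2)
      if (s > 2 && any(d2[seq_len(s - 2)] < min_sep^2)) next
      tried <- tried + 1L
      score <- sum((cand - centroid)^2)
      if (score < best_score) {
        best <- cand
        best_score <- score
      }
      if (tried >= batch) break
    }
    if (is.null(best)) return(NULL)
    coords[s, ] <- best
  }
  coords
}

#' Sample a Gaussian trajectory from an elastic network
#'
#' Draws frames from the multivariate normal the harmonic model defines:
#' mean = rest geometry, covariance = `kB T` times the pseudoinverse of the
#' Hessian over its non-rigid modes.  Rigid-body modes are given zero
#' amplitude by default, so internal statistics are exact without any
#' superposition; `rigid_motion = TRUE` additionally applies a random rigid
#' rotation and translation per frame to exercise fitting code paths.
#' Sample bond-length variances converge to [predict_bond_variances()] as
#' the frame count grows — the defining property used to cross-validate
#' the normal-mode prediction.
#'
#' @param network An [elastic_network()].
#' @param n_frames Number of frames.
#' @param seed RNG seed (required).
#' @param dt Frame spacing in ns (default 0.001).
#' @param rigid_motion Add random rigid placement per frame (default FALSE).
#' @return A [cg_trajectory()] (sites are their own residues).
#' @export
sample_from_network <- function(network, n_frames, seed = 1, dt = 0.001,
                                rigid_motion = FALSE) {
  modes <- enm_modes(network)
  keep <- which(!modes$zero)
  V <- modes$vectors[, keep, drop = FALSE]
  amp <- sqrt(kBT(network$temperature) / modes$values[keep])
  n <- nrow(network$coords)
  rest <- as.vector(t(network$coords))
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_frames * length(keep)), n_frames)
    disp <- Z %*% t(sweep(V, 2, amp, `*`))
    xyz <- sweep(disp, 2, rest, `+`)
    coords <- xyz_to_coords(xyz)
    if (rigid_motion) {
      for (f in seq_len(n_frames)) {
        R <- random_rotation()
        shift <- stats::runif(3, -20, 20)
        coords[f, , ] <- sweep(coords[f, , ] %*% t(R), 2, shift, `+`)
      }
    }
    cg_trajectory(coords, times = (seq_len(n_frames) - 1) * dt)
  })
}

random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Concatenate alternating Gaussian segments from two networks
#'
#' Emulates a two-state system whose mechanical coupling switches at known
#' change points: segments of `frames_per_segment` frames are drawn
#' alternately from networks A and B (A first) and concatenated.  The frame
#' index starting each segment after the first is recorded for oracle
#' checks.
#'
#' @param network_a,network_b [elastic_network()]s on identical site
#'   rosters.
#' @param frames_per_segment Frames per segment.
#' @param n_segments Number of segments (default 2: A then B).
#' @param seed RNG seed.
#' @param dt Frame spacing in ns.
#' @return A [cg_trajectory()] with attribute `"change_points"` (integer
#'   frame indices) and `"states"` (state label per frame).
#' @export
two_state_trajectory <- function(network_a, network_b, frames_per_segment,
                                 n_segments = 2, seed = 1, dt = 0.001) {
  if (nrow(network_a$coords) != nrow(network_b$coords)) {
    abort("networks have different site rosters")
  }
  segs <- vector("list", n_segments)
  for (s in seq_len(n_segments)) {
    net <- if (s %% 2 == 1) network_a else network_b
    segs[[s]] <- sample_from_network(
      net, frames_per_segment, seed = seed + s, dt = dt
    )$coords
  }
  coords <- do.call(abind3, segs)
  nf <- dim(coords)[1]
  traj <- cg_trajectory(coords, times = (seq_len(nf) - 1) * dt)
  attr(traj, "change_points") <- (seq_len(n_segments - 1)) * frames_per_segment + 1L
  attr(traj, "states") <- rep(
    rep(c("A", "B"), length.out = n_segments), each = frames_per_segment
  )
  traj
}

abind3 <- function(...) {
  parts <- list(...)
  nf <- sum(vapply(parts, function(p) dim(p)[1], integer(1)))
  out <- array(NA_real_, c(nf, dim(parts[[1]])[2], 3))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Shift one bond's force constant
#'
#' Returns a copy of the network with `dk` added to the force constant of
#' bond (i, j) (clamped at zero); the bond is added at the embedded
#' distance if absent.  Used to plant localised coupling changes.
#'
#' @param network An [elastic_network()].
#' @param i,j Site ids (`i < j`).
#' @param dk Force-constant shift (kcal/mol/A^2).
#' @return An [elastic_network()].
#' @export
perturb_bond <- function(network, i, j, dk) {
  hit <- which(network$bonds$i == i & network$bonds$j == j)
  if (length(hit) == 1) {
    network$bonds$k[hit] <- max(network$bonds$k[hit] + dk, 0)
  } else {
    b <- sqrt(sum((network$coords[j, ] - network$coords[i, ])^2))
    network$bonds <- arrange(
      bind_rows(network$bonds, tibble(i = i, j = j, b = b, k = max(dk, 0))),
      .data$i, .data$j
    )
  }
  network
}

#' Generate an alignment with planted co-evolving sectors
#'
#' Emulates the signal a statistical coupling analysis assumes: for each
#' sequence and each sector an independent latent state `z ~ Bernoulli(p)`
#' decides whether the sector's columns emit their consensus letter with
#' probability `f_active` (z = 1) or `f_inactive` (z = 0); non-sector
#' columns emit their consensus independently with a per-column
#' conservation level drawn once from `conservation_range`.  Non-consensus
#' letters are drawn from the background distribution restricted to the
#' other 19 amino acids.  Deterministic for a fixed seed.
#'
#' @param n_sequences,n_positions Alignment dimensions.
#' @param sectors List of disjoint integer vectors of planted sector
#'   positions.
#' @param p_sector Probability of the active latent state (default 0.5).
#' @param f_active,f_inactive Consensus emission probabilities in the two
#'   latent states (defaults 0.95 and 0.4).
#' @param conservation_range Range of per-column consensus frequencies for
#'   non-sector columns (default `c(0.3, 0.95)`, spanning the weakly to
#'   strongly conserved columns seen in real alignments).
#' @param background Amino-acid background frequencies.
#' @param seed RNG seed (required).
#' @return An [msa()] with attribute `"sectors"` (the planted positions).
#' @export
synth_alignment <- function(n_sequences, n_positions, sectors,
                            p_sector = 0.5, f_active = 0.95, f_inactive = 0.4,
                            conservation_range = c(0.3, 0.95),
                            background = aa_background_frequencies(),
                            seed = 1) {
  all_sector <- unlist(sectors)
  if (anyDuplicated(all_sector) > 0) abort("sector position sets must be disjoint")
  if (any(all_sector < 1 | all_sector > n_positions)) {
    abort("sector positions out of range")
  }
  with_seed(seed, {
    consensus <- sample(names(background), n_positions, replace = TRUE,
                        prob = background)
    f_col <- stats::runif(n_positions, conservation_range[1], conservation_range[2])
    mat <- matrix(NA_character_, n_sequences, n_positions)
    z <- matrix(
      stats::rbinom(n_sequences * length(sectors), 1, p_sector),
      n_sequences, length(sectors)
    )
    sector_of <- integer(n_positions)
    for (g in seq_along(sectors)) sector_of[sectors[[g]]] <- g
    for (i in seq_len(n_positions)) {
      p_cons <- if (sector_of[i] > 0) {
        ifelse(z[, sector_of[i]] == 1, f_active, f_inactive)
      } else {
        rep(f_col[i], n_sequences)
      }
      is_cons <- stats::runif(n_sequences) < p_cons
      others <- setdiff(names(background), consensus[i])
      qo <- background[others] / sum(background[others])
      mat[, i] <- ifelse(
        is_cons, consensus[i],
        sample(others, n_sequences, replace = TRUE, prob = qo)
      )
    }
    aln <- msa(mat)
    attr(aln, "sectors") <- sectors
    aln
  })
}
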