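#' Multiple sequence alignment container
#'
#' A rectangular alignment of single-letter amino-acid codes with gaps
#' (`-`), plus a strictly increasing map from alignment columns to 1-based
#' residue numbers of the reference sequence.
#'
#' @param mat Character matrix, sequences x columns, entries in the 20
#'   amino-acid letters, `-` or `X`.
#' @param ids Sequence identifiers (default `seq1`, `seq2`, ...).
#' @param refpos Integer vector mapping columns to reference residue
#'   numbers (default `1:ncol`).
#' @return An `msa` object.
#' @export
msa <- function(mat, ids = NULL, refpos = NULL) {
  if (!is.matrix(mat) || !is.character(mat)) {
    abort("`mat` must be a character matrix")
  }
  ok <- c(.aa1, "-", "X")
  if (!all(mat %in% ok)) abort("alignment contains letters outside the amino-acid alphabet")
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  if (is.null(refpos)) refpos <- seq_len(ncol(mat))
  if (any(diff(refpos) <= 0)) abort("`refpos` must be strictly increasing")
  structure(
    list(mat = mat, ids = as.character(ids), refpos = as.integer(refpos)),
    class = "msa"
  )
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path Path to an aligned (equal-length) FASTA file.
#' @param refpos Optional column-to-residue map (default `1:ncol`).
#' @return An [msa()] object.  Unknown letters are mapped to `X`.
#' @export
read_alignment_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(unique(Biostrings::width(set))) != 1) {
    abort("sequences have unequal lengths; not an alignment")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(set)), ""))
  dimnames(mat) <- NULL
  mat[mat == "."] <- "-"
  mat[!(mat %in% c(.aa1, "-"))] <- "X"
  msa(mat, ids = names(set))
}

#' Write an alignment as FASTA
#'
#' @param aln An [msa()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  writeLines(as.vector(rbind(paste0(">", aln$ids), seqs)), path)
  invisible(path)
}

#' Filter alignment sequences by gap content
#'
#' Keeps sequences with at most `max_gaps` gaps overall and at most
#' `max_loop_gaps` gaps within the designated loop columns (used to require
#' the presence of a structurally essential loop, e.g. a ligand-binding
#' loop).  The column set is unchanged.
#'
#' @param aln An [msa()].
#' @param max_gaps Maximum total gaps per sequence (default 100).
#' @param loop_positions Reference residue numbers of the loop columns
#'   (matched against `refpos`); `NULL` disables the loop rule.
#' @param max_loop_gaps Maximum gaps within the loop columns (default 1).
#' @return A filtered [msa()].
#' @export
filter_alignment <- function(aln, max_gaps = 100, loop_positions = NULL,
                             max_loop_gaps = 1) {
  gaps <- rowSums(aln$mat == "-")
  keep <- gaps <= max_gaps
  if (!is.null(loop_positions)) {
    cols <- which(aln$refpos %in% loop_positions)
    if (length(cols) == 0) abort("loop positions not found in the column map")
    loop_gaps <- rowSums(aln$mat[, cols, drop = FALSE] == "-")
    keep <- keep & loop_gaps <= max_loop_gaps
  }
  if (!any(keep)) abort("no sequences pass the gap filters")
  msa(aln$mat[keep, , drop = FALSE], aln$ids[keep], aln$refpos)
}

# fractional identity over mutually non-gap columns; NA when the mutual
# coverage is below `min_coverage` of the columns
pairwise_identity <- function(a, b, min_coverage = 0.5) {
  both <- a != "-" & b != "-"
  if (mean(both) < min_coverage) return(NA_real_)
  mean(a[both] == b[both])
}

#' Remove redundant sequences
#'
#' Single-linkage clustering at the identity threshold: sequences whose
#' identity over mutually non-gap columns reaches the threshold (directly
#' or through a chain) form one cluster, and the first-seen sequence of
#' each cluster is kept, preserving input order.  Pairs whose mutual
#' non-gap coverage is below `min_coverage` are treated as non-redundant.
#'
#' @param aln An [msa()].
#' @param identity Identity threshold (default 0.95).
#' @param min_coverage Minimum fraction of mutually non-gap columns for an
#'   identity to be meaningful (default 0.5).
#' @return A reduced [msa()].
#' @export
remove_redundant <- function(aln, identity = 0.95, min_coverage = 0.5) {
  n <- nrow(aln$mat)
  if (n == 0) abort("empty alignment")
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      idp <- pairwise_identity(aln$mat[a, ], aln$mat[b, ], min_coverage)
      if (!is.na(idp) && idp >= identity) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- which(!duplicated(roots))
  msa(aln$mat[keep, , drop = FALSE], aln$ids[keep], aln$refpos)
}

#' Binary approximation and positional conservation
#'
#' Each alignment cell becomes 1 if it holds the column's most prevalent
#' amino acid (ties broken toward the alphabetically first letter; gaps are
#' never the consensus and always map to 0).  Conservation of column i is
#' the relative entropy (nats) between the regularised consensus frequency
#' `f' = (1 - lambda) f + lambda q` and the background frequency `q` of the
#' consensus letter: `D = f' ln(f'/q) + (1-f') ln((1-f')/(1-q))`.  The
#' pseudocount keeps the entropy gradient finite at `f` of 0 or 1.
#'
#' @param aln An [msa()].
#' @param background Named amino-acid frequency vector
#'   (default [aa_background_frequencies()]).
#' @param pseudocount Mixing weight `lambda` toward the background
#'   (default 0.01).
#' @return List with `x` (binary sequences x columns matrix) and `profile`
#'   (tibble `column`, `refpos`, `consensus`, `f`, `f_reg`, `q`, `D`,
#'   `phi`), where `phi = |d D / d f|` is the conservation weight used by
#'   [sca_matrix()].
#' @export
binarize <- function(aln, background = aa_background_frequencies(),
                     pseudocount = 0.01) {
  n_pos <- ncol(aln$mat)
  consensus <- character(n_pos)
  for (i in seq_len(n_pos)) {
    col <- aln$mat[, i]
    col <- col[col %in% .aa1]
    if (length(col) == 0) {
      consensus[i] <- NA_character_
      next
    }
    tab <- table(col)
    consensus[i] <- sort(names(tab)[tab == max(tab)])[1]
  }
  x <- matrix(0L, nrow(aln$mat), n_pos)
  for (i in seq_len(n_pos)) {
    if (!is.na(consensus[i])) x[, i] <- as.integer(aln$mat[, i] == consensus[i])
  }
  f <- colMeans(x)
  q <- ifelse(is.na(consensus), mean(background), background[consensus])
  f_reg <- (1 - pseudocount) * f + pseudocount * q
  D <- f_reg * log(f_reg / q) + (1 - f_reg) * log((1 - f_reg) / (1 - q))
  phi <- abs(log(f_reg * (1 - q) / (q * (1 - f_reg))))
  if (any(f %in% c(0, 1))) {
    warn("constant columns present; pseudocount regularisation applied")
  }
  list(
    x = x,
    profile = tibble(
      column = seq_len(n_pos), refpos = aln$refpos,
      consensus = consensus, f = f, f_reg = f_reg,
      q = unname(q), D = unname(D), phi = unname(phi)
    )
  )
}

#' Conservation-weighted coupling matrix of an alignment
#'
#' Positional coupling matrix in the binary approximation:
#' `C_ij = phi_i phi_j |cov(x_i, x_j)|` with `phi` the conservation weights
#' from [binarize()] and the covariance taken over sequences (population
#' convention).  The absolute value makes the matrix entrywise
#' non-negative; its leading eigenvector is conservation-dominated and the
#' following eigenvectors carry the co-evolution signal.
#'
#' @param x Binary matrix from [binarize()].
#' @param profile Conservation profile from [binarize()].
#' @return An `sca_matrix` object: list with `C` (positions x positions),
#'   `values` (eigenvalues, descending), `vectors`, `profile`.
#' @export
sca_matrix <- function(x, profile) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  covm <- crossprod(xc) / nrow(x)
  C <- abs(covm) * (profile$phi %o% profile$phi)
  eig <- eigen(C, symmetric = TRUE)
  structure(
    list(C = C, values = eig$values, vectors = eig$vectors, profile = profile),
    class = "sca_matrix"
  )
}

#' @export
print.sca_matrix <- function(x, ...) {
  cat(sprintf(
    "<sca_matrix> %d positions; top eigenvalues: %s\n",
    nrow(x$C), paste(sprintf("%.3g", utils::head(x$values, 4)), collapse = ", ")
  ))
  invisible(x)
}

#' @export
tidy.sca_matrix <- function(x, n_vectors = 4, ...) {
  out <- tibble(
    column = x$profile$column, refpos = x$profile$refpos
  )
  for (v in seq_len(min(n_vectors, ncol(x$vectors)))) {
    out[[paste0("v", v)]] <- x$vectors[, v]
  }
  out
}

#' Significant eigenvectors by column-permutation randomisation
#'
#' Destroys inter-column correlations by independently permuting each
#' column of the binary matrix across sequences (conservation is exactly
#' preserved), rebuilds the coupling matrix, and records for each
#' randomised matrix its largest eigenvalue beyond the leading one.  The
#' leading eigenvalue of this entrywise non-negative matrix is a
#' conservation-dominated Perron mode that survives randomisation, so it is
#' set aside on both sides of the comparison; eigenvectors of the observed
#' matrix (beyond the first) whose eigenvalue exceeds the chosen quantile
#' of the randomised records are significant.
#'
#' @param scam An [sca_matrix()].
#' @param x The binary matrix it was built from.
#' @param n_randomizations Number of randomisations (>= 10, default 100).
#' @param seed RNG seed.
#' @param level Quantile of the null maxima (default 0.95).
#' @return List with `significant` (indices > 1 whose eigenvalue beats the
#'   threshold), `threshold`, `null_maxima`, `first_eigenvalue`.
#' @export
eigen_significance <- function(scam, x, n_randomizations = 100, seed = 1,
                               level = 0.95) {
  if (n_randomizations < 10) abort("need at least 10 randomizations")
  n_seq <- nrow(x)
  maxima <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(r) {
      xp <- apply(x, 2, function(col) col[sample.int(n_seq)])
      xc <- scale(xp, center = TRUE, scale = FALSE)
      covm <- crossprod(xc) / n_seq
      Cp <- abs(covm) * (scam$profile$phi %o% scam$profile$phi)
      eigen(Cp, symmetric = TRUE, only.values = TRUE)$values[2]
    }, double(1))
  })
  threshold <- stats::quantile(maxima, level, names = FALSE)
  sig <- which(scam$values > threshold)
  list(
    significant = setdiff(sig, 1L),
    threshold = threshold,
    null_maxima = maxima,
    first_eigenvalue = scam$values[1]
  )
}

#' Select co-evolving positions and partition them into sectors
#'
#' Positions whose distance from the origin in the plane of eigenvectors 2
#' and 3 reaches the cutoff are selected as co-evolving; the selected
#' positions are partitioned into `n_sectors` clusters by k-means on their
#' angular direction in that plane (each point mapped to the unit circle),
#' and sector labels are ordered by decreasing cluster size.
#'
#' @param scam An [sca_matrix()].
#' @param cutoff Distance-to-origin cutoff (default 0.07).
#' @param n_sectors Number of sectors (default 3).
#' @param seed Seed for the k-means initialisation.
#' @return A `sector_assignment` tibble: `column`, `refpos`, `v2`, `v3`,
#'   `dist`, `sector` (integer, `NA` below the cutoff), with the cutoff as
#'   attribute `"cutoff"`.  An empty selection (no position reaches the
#'   cutoff) is returned with every sector `NA`; a non-empty selection
#'   smaller than `n_sectors` is an error.
#' @export
select_sectors <- function(scam, cutoff = 0.07, n_sectors = 3, seed = 1) {
  if (ncol(scam$vectors) < 3) abort("need at least 3 eigenvectors")
  v2 <- scam$vectors[, 2]; v3 <- scam$vectors[, 3]
  dist <- sqrt(v2^2 + v3^2)
  sel <- which(dist >= cutoff)
  sector <- rep(NA_integer_, length(dist))
  if (length(sel) > 0 && n_sectors > 0 && length(sel) < n_sectors) {
    abort(sprintf(
      "only %d positions above the cutoff; cannot form %d sectors",
      length(sel), n_sectors
    ))
  }
  if (length(sel) > 0 && n_sectors > 0) {
    pts <- cbind(v2[sel], v3[sel]) / dist[sel]
    km <- with_seed(seed, stats::kmeans(pts, centers = n_sectors, nstart = 20))
    size_rank <- rank(-km$size, ties.method = "first")
    sector[sel] <- as.integer(size_rank[km$cluster])
  }
  out <- tibble(
    column = scam$profile$column, refpos = scam$profile$refpos,
    v2 = v2, v3 = v3, dist = dist, sector = sector
  )
  attr(out, "cutoff") <- cutoff
  class(out) <- c("sector_assignment", class(out))
  out
}

#' Cleaned coupling matrix from selected eigenvectors
#'
#' Low-rank reconstruction `sum_k lambda_k v_k v_k'` over the chosen
#' eigenvector indices, restricted to the selected positions and ordered by
#' sector (then by decreasing distance-to-origin within each sector), the
#' standard way of visualising sector structure.
#'
#' @param scam An [sca_matrix()].
#' @param sectors A `sector_assignment` from [select_sectors()].
#' @param indices Eigenvector indices used for the reconstruction
#'   (default `2:4`).
#' @return Square matrix over the selected positions, dimnames = reference
#'   residue numbers, with attribute `"order"` (tibble of the row order).
#' @export
clean_matrix <- function(scam, sectors, indices = 2:4) {
  if (any(indices < 1 | indices > length(scam$values))) {
    abort("eigenvector indices out of range")
  }
  recon <- matrix(0, nrow(scam$C), ncol(scam$C))
  for (k in indices) {
    recon <- recon + scam$values[k] * (scam$vectors[, k] %o% scam$vectors[, k])
  }
  ord <- sectors |>
    filter(!is.na(.data$sector)) |>
    arrange(.data$sector, dplyr::desc(.data$dist))
  sub <- recon[ord$column, ord$column, drop = FALSE]
  dimnames(sub) <- list(ord$refpos, ord$refpos)
  attr(sub, "order") <- ord
  sub
}

#' Write the conservation profile as TSV
#'
#' Columns `column`, `refpos`, `consensus`, `f`, `D`.
#'
#' @param profile Profile tibble from [binarize()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# column\trefpos\tconsensus\tf\tD", con)
  writeLines(sprintf(
    "%d\t%d\t%s\t%.17g\t%.17g",
    profile$column, profile$refpos, profile$consensus, profile$f, profile$D
  ), con)
  invisible(path)
}
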