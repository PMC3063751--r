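#' Per-pair coupling statistics over windows
#'
#' For each residue pair, the mean, population standard deviation and
#' maximum of its coupling over the windows of a fluctuogram, plus the
#' sequence separation; the inputs the selection criteria screen.
#'
#' @param series Tibble `window`, `I`, `J`, `k` from [coupling_series()],
#'   or a fluctuogram (converted automatically).
#' @return Tibble `I`, `J`, `mean`, `sd`, `max`, `separation`.
#' @export
pair_statistics <- function(series) {
  if (inherits(series, "fluctuogram")) series <- coupling_series(series)
  series |>
    group_by(.data$I, .data$J) |>
    summarise(
      mean = mean(.data$k),
      sd = sqrt(mean((.data$k - mean(.data$k))^2)),
      max = max(.data$k),
      .groups = "drop"
    ) |>
    mutate(separation = abs(.data$J - .data$I))
}

#' Selection-criteria parameters
#'
#' Cutoffs of the three residue-selection criteria.  Defaults are the
#' subtilisin working point; `k_b = 17` and `n_cut = 8` are the published
#' alternatives for less globular proteins.
#'
#' @param k_cut Coupling cutoff (kcal/mol/A^2) above which a partner counts
#'   in criterion A (default 2.5).
#' @param n_cut Minimum number of strongly coupled partners for criterion A
#'   (default 10).
#' @param k_b Mean-coupling cutoff of criterion B (default 11).
#' @param k_c Maximum-coupling cutoff of criterion C (default 8).
#' @param s_c Variation cutoff of criterion C (default 0.8).
#' @param min_separation Minimum sequence separation `|I - J|` for a pair to
#'   be screened (default 4, i.e. `|I - J| > 3`).
#' @param variation_mode How criterion C measures variation:
#'   `"cv_mean"` (default) sd/mean, `"cv_max"` sd/max, `"absolute"` sd in
#'   kcal/mol/A^2.
#' @return A `criteria_params` list.
#' @export
criteria_params <- function(k_cut = 2.5, n_cut = 10, k_b = 11, k_c = 8,
                            s_c = 0.8, min_separation = 4,
                            variation_mode = c("cv_mean", "cv_max", "absolute")) {
  variation_mode <- match.arg(variation_mode)
  stopifnot(k_cut >= 0, n_cut >= 0, k_b >= 0, k_c >= 0, s_c >= 0)
  structure(
    list(
      k_cut = k_cut, n_cut = n_cut, k_b = k_b, k_c = k_c, s_c = s_c,
      min_separation = min_separation, variation_mode = variation_mode
    ),
    class = "criteria_params"
  )
}

sep_filter <- function(stats, params) {
  filter(stats, .data$separation >= params$min_separation)
}

#' Residue-selection criteria
#'
#' Criterion A selects hub residues: I is selected when its number of
#' partners J with `|I-J|` at least the separation cutoff and mean coupling
#' `>= k_cut` reaches `n_cut`.  Criterion B selects both ends of every pair
#' with mean coupling `>= k_b`.  Criterion C selects both ends of pairs
#' whose maximum coupling reaches `k_c` and whose normalised variation
#' (sd/mean by default) reaches `s_c`; pairs with zero mean are skipped.
#' `combine_criteria()` returns the union with per-criterion provenance
#' flags.
#'
#' @param stats Pair statistics from [pair_statistics()].
#' @param params A [criteria_params()].
#' @return `criterion_a/b/c()`: sorted integer vector of selected residues.
#'   `combine_criteria()`: tibble `residue`, `A`, `B`, `C` (logical), one
#'   row per selected residue.
#' @export
criterion_a <- function(stats, params = criteria_params()) {
  qualifying <- filter(sep_filter(stats, params), .data$mean >= params$k_cut)
  counts <- bind_rows(
    select(qualifying, residue = "I"),
    select(qualifying, residue = "J")
  ) |> count(.data$residue)
  sort(counts$residue[counts$n >= params$n_cut])
}

#' @rdname criterion_a
#' @export
criterion_b <- function(stats, params = criteria_params()) {
  hit <- filter(sep_filter(stats, params), .data$mean >= params$k_b)
  sort(unique(c(hit$I, hit$J)))
}

#' @rdname criterion_a
#' @export
criterion_c <- function(stats, params = criteria_params()) {
  st <- filter(sep_filter(stats, params), .data$mean > 0)
  variation <- switch(params$variation_mode,
    cv_mean = st$sd / st$mean,
    cv_max = st$sd / st$max,
    absolute = st$sd
  )
  hit <- st[st$max >= params$k_c & variation >= params$s_c, ]
  sort(unique(c(hit$I, hit$J)))
}

#' @rdname criterion_a
#' @export
combine_criteria <- function(stats, params = criteria_params()) {
  a <- criterion_a(stats, params)
  b <- criterion_b(stats, params)
  cc <- criterion_c(stats, params)
  residues <- sort(unique(c(a, b, cc)))
  tibble(
    residue = residues,
    A = residues %in% a, B = residues %in% b, C = residues %in% cc
  )
}

# residues of the universe lying within +/- tolerance of any residue in
# `set`, truncated at the chain termini (no wraparound)
neighbourhood <- function(set, n_residues, tolerance) {
  hits <- logical(n_residues)
  for (r in set) {
    lo <- max(1, r - tolerance); hi <- min(n_residues, r + tolerance)
    hits[lo:hi] <- TRUE
  }
  hits
}

#' Score a selection against a reference residue set
#'
#' A selected residue is a hit when it lies within `tolerance` residues of
#' at least one reference residue; a reference residue is covered when a
#' selected residue lies within `tolerance` of it.  The hit rate is
#' hits/selected, the coverage covered/reference.  Selecting every residue
#' gives coverage 1; an empty selection gives hit rate `NA` and coverage 0.
#'
#' @param selected Integer vector of selected residues.
#' @param reference Integer vector of reference residues.
#' @param n_residues Size of the residue universe (default: max index seen).
#' @param tolerance Matching tolerance in residue numbering (default 1).
#' @return One-row tibble: `n_selected`, `n_hits`, `hit_rate`, `n_reference`,
#'   `n_covered`, `coverage`, `tolerance`.
#' @export
evaluate_selection <- function(selected, reference,
                               n_residues = max(c(selected, reference)),
                               tolerance = 1) {
  selected <- unique(as.integer(selected))
  reference <- unique(as.integer(reference))
  ref_nb <- neighbourhood(reference, n_residues, tolerance)
  sel_nb <- neighbourhood(selected, n_residues, tolerance)
  n_hits <- sum(ref_nb[selected])
  n_cov <- sum(sel_nb[reference])
  tibble(
    n_selected = length(selected),
    n_hits = n_hits,
    hit_rate = if (length(selected) == 0) NA_real_ else n_hits / length(selected),
    n_reference = length(reference),
    n_covered = n_cov,
    coverage = if (length(reference) == 0) 0 else n_cov / length(reference),
    tolerance = tolerance
  )
}

#' Random-pick baseline for hit rate and coverage
#'
#' Monte-Carlo reference: repeatedly picks `n_pick` residues uniformly
#' without replacement from `1:n_residues` and scores them against the
#' reference set.  Reports the mean and population standard deviation of
#' the hit count, the covered-to-picked ratio (covered reference residues
#' divided by `n_pick`) and the hit rate.  Deterministic for a fixed seed.
#'
#' @param n_pick Number of residues picked per round.
#' @param n_residues Residue universe size.
#' @param reference Reference residue set.
#' @param tolerance Matching tolerance (default 1).
#' @param n_rounds Monte-Carlo rounds (default 10000).
#' @param seed RNG seed (required for reproducibility).
#' @return One-row tibble: `mean_hits`, `sd_hits`, `mean_covered`,
#'   `sd_covered`, `mean_ratio`, `sd_ratio`, `mean_hit_rate`, `sd_hit_rate`,
#'   `n_rounds`, `seed`.
#' @export
random_baseline <- function(n_pick, n_residues, reference, tolerance = 1,
                            n_rounds = 10000, seed = 1) {
  stopifnot(n_pick <= n_residues)
  reference <- unique(as.integer(reference))
  ref_nb <- neighbourhood(reference, n_residues, tolerance)
  windows <- lapply(reference, function(r) {
    max(1, r - tolerance):min(n_residues, r + tolerance)
  })
  hits <- covered <- integer(n_rounds)
  with_seed(seed, {
    for (rnd in seq_len(n_rounds)) {
      picks <- sample.int(n_residues, n_pick)
      hits[rnd] <- sum(ref_nb[picks])
      inpick <- logical(n_residues)
      inpick[picks] <- TRUE
      covered[rnd] <- sum(vapply(windows, function(w) any(inpick[w]), logical(1)))
    }
  })
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  tibble(
    mean_hits = mean(hits), sd_hits = pop_sd(hits),
    mean_covered = mean(covered), sd_covered = pop_sd(covered),
    mean_ratio = mean(covered / n_pick), sd_ratio = pop_sd(covered / n_pick),
    mean_hit_rate = mean(hits / n_pick), sd_hit_rate = pop_sd(hits / n_pick),
    n_rounds = n_rounds, seed = as.integer(seed)
  )
}

#' Read and write plain-text residue lists
#'
#' One 1-based residue number per line; `#` comments allowed.
#'
#' @param path File path.
#' @param residues Integer vector (writer).
#' @return `read_residue_list()`: sorted integer vector.
#' @export
read_residue_list <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  sort(as.integer(lines[nzchar(lines)]))
}

#' @rdname read_residue_list
#' @export
write_residue_list <- function(residues, path) {
  writeLines(as.character(sort(unique(as.integer(residues)))), path)
  invisible(path)
}
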