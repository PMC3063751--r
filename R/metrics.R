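# bonds x windows matrices of force constants / rest lengths, aligned on the
# shared pool (every window's bonds are stored in pool order)
fluct_k_matrix <- function(fluct) {
  vapply(fluct$networks, function(nw) nw$bonds$k, double(nrow(fluct$pool)))
}

fluct_b_matrix <- function(fluct) {
  vapply(fluct$networks, function(nw) nw$bonds$b, double(nrow(fluct$pool)))
}

# residue at each end of every pool bond
pool_residues <- function(fluct) {
  tibble(
    bond = seq_len(nrow(fluct$pool)),
    ri = fluct$residues[fluct$pool$i],
    rj = fluct$residues[fluct$pool$j]
  )
}

# long incidence: one row per (bond, residue) with the bond touching the
# residue; intra-residue bonds touch their single residue once
bond_incidence <- function(fluct, drop_intra = FALSE) {
  pr <- pool_residues(fluct)
  if (drop_intra) pr <- filter(pr, .data$ri != .data$rj)
  bind_rows(
    tibble(bond = pr$bond, residue = pr$ri),
    tibble(bond = pr$bond[pr$ri != pr$rj], residue = pr$rj[pr$ri != pr$rj])
  )
}

#' Residue-level mechanical coupling of one network
#'
#' Aggregates site-site force constants to residues: the coupling between
#' residues I and J is the sum of the force constants of all bonds linking a
#' site of I to a site of J, and the coupling of residue I is the sum over
#' all partners J != I.  Intra-residue (backbone-sidechain) bonds are
#' reported as `I == J` rows of the pair table and never enter the
#' per-residue totals.
#'
#' @param network An [elastic_network()] whose `residues` field maps sites
#'   to residues.
#' @param min_separation Minimum `|I - J|` for a pair to count toward the
#'   per-residue total (default 0: sequence neighbours included).
#' @return List with `pairs` (tibble `I`, `J`, `k`, with `I <= J`) and
#'   `residues` (tibble `residue`, `k_I`).
#' @export
residue_coupling <- function(network, min_separation = 0) {
  ri <- network$residues[network$bonds$i]
  rj <- network$residues[network$bonds$j]
  pairs <- tibble(
    I = pmin(ri, rj), J = pmax(ri, rj), k = network$bonds$k
  ) |>
    group_by(.data$I, .data$J) |>
    summarise(k = sum(.data$k), .groups = "drop")
  inter <- filter(pairs, .data$J - .data$I >= max(1, min_separation))
  per_res <- bind_rows(
    select(inter, residue = "I", k = "k"),
    select(inter, residue = "J", k = "k")
  ) |>
    group_by(.data$residue) |>
    summarise(k_I = sum(.data$k), .groups = "drop")
  residues <- tibble(residue = sort(unique(network$residues))) |>
    left_join(per_res, by = "residue") |>
    mutate(k_I = ifelse(is.na(.data$k_I), 0, .data$k_I))
  list(pairs = pairs, residues = residues)
}

#' Residue-pair coupling series over the windows of a fluctuogram
#'
#' One row per (window, residue pair) for every pair linked by at least one
#' pool bond, including windows where the matched force constant is zero.
#' Intra-residue pairs (`I == J`) are excluded.
#'
#' @param fluct A fluctuogram from [compute_fluctuogram()].
#' @return Tibble `window`, `I`, `J`, `k` with `I < J`.
#' @export
coupling_series <- function(fluct) {
  K <- fluct_k_matrix(fluct)
  pr <- pool_residues(fluct)
  keep <- pr$ri != pr$rj
  id <- paste(pmin(pr$ri, pr$rj)[keep], pmax(pr$ri, pr$rj)[keep])
  agg <- rowsum(K[keep, , drop = FALSE], id)
  ij <- do.call(rbind, strsplit(rownames(agg), " "))
  out <- tibble(
    I = rep(as.integer(ij[, 1]), ncol(agg)),
    J = rep(as.integer(ij[, 2]), ncol(agg)),
    window = rep(seq_len(ncol(agg)), each = nrow(agg)),
    k = as.vector(agg)
  )
  arrange(select(out, "window", "I", "J", "k"), .data$window, .data$I, .data$J)
}

#' Per-residue coupling series
#'
#' `k_I(t)`: total inter-residue coupling of each residue in each window
#' (see [residue_coupling()]).
#'
#' @inheritParams coupling_series
#' @param min_separation Minimum `|I - J|` for a pair to count (default 0).
#' @return Tibble `window`, `residue`, `k_I`.
#' @export
residue_series <- function(fluct, min_separation = 0) {
  cs <- filter(coupling_series(fluct), .data$J - .data$I >= max(1, min_separation))
  all_res <- sort(unique(fluct$residues))
  long <- bind_rows(
    select(cs, "window", residue = "I", "k"),
    select(cs, "window", residue = "J", "k")
  ) |>
    group_by(.data$window, .data$residue) |>
    summarise(k_I = sum(.data$k), .groups = "drop")
  tidyr::complete(
    long,
    window = seq_len(n_windows(fluct)), residue = all_res,
    fill = list(k_I = 0)
  ) |>
    arrange(.data$window, .data$residue)
}

#' Two-state coupling difference and residue classification
#'
#' Window-by-window difference of the per-residue coupling between two
#' fluctuograms computed under different conditions (e.g. ligand-bound vs
#' apo): `dk_I(t) = k_I^A(t) - k_I^B(t)`.  Residues are classified by the
#' time average of `|dk_I|`: large (> 20 kcal/mol/A^2), significant (10-20),
#' medium/weak (< 10), and the top fraction by that average is flagged.
#'
#' @param fluct_a,fluct_b Fluctuograms with identical window counts and
#'   residue rosters.
#' @param thresholds Two ascending class boundaries in kcal/mol/A^2
#'   (default `c(10, 20)`).
#' @param top_fraction Fraction of residues flagged as most affected
#'   (default 0.1).
#' @param min_separation Passed to [residue_series()].
#' @return List with `series` (tibble `window`, `residue`, `delta_k`) and
#'   `summary` (tibble `residue`, `mean_abs_dk`, `class`, `top`), ordered by
#'   decreasing `mean_abs_dk`.
#' @export
delta_k_two_states <- function(fluct_a, fluct_b, thresholds = c(10, 20),
                               top_fraction = 0.1, min_separation = 0) {
  if (n_windows(fluct_a) != n_windows(fluct_b)) {
    abort("fluctuograms have different window counts")
  }
  ra <- residue_series(fluct_a, min_separation)
  rb <- residue_series(fluct_b, min_separation)
  if (!identical(sort(unique(ra$residue)), sort(unique(rb$residue)))) {
    abort("fluctuograms have different residue rosters")
  }
  series <- left_join(ra, rb, by = c("window", "residue"),
                      suffix = c("_a", "_b")) |>
    mutate(delta_k = .data$k_I_a - .data$k_I_b) |>
    select("window", "residue", "delta_k")
  summary <- series |>
    group_by(.data$residue) |>
    summarise(mean_abs_dk = mean(abs(.data$delta_k)), .groups = "drop") |>
    mutate(
      class = cut(
        .data$mean_abs_dk, c(-Inf, thresholds, Inf),
        labels = c("medium_weak", "significant", "large"), right = FALSE
      )
    ) |>
    arrange(dplyr::desc(.data$mean_abs_dk)) |>
    mutate(top = dplyr::row_number() <= ceiling(top_fraction * dplyr::n()))
  list(series = series, summary = summary)
}

#' Coupling change between consecutive windows
#'
#' `dk_I(t) = k_I(t) - k_I(t-1)` on consecutive (by default half-overlapping)
#' windows; the first window carries no value.
#'
#' @inheritParams residue_series
#' @return Tibble `window` (2..W), `residue`, `delta_k`.
#' @export
delta_k_consecutive <- function(fluct, min_separation = 0) {
  rs <- residue_series(fluct, min_separation)
  rs |>
    group_by(.data$residue) |>
    arrange(.data$window, .by_group = TRUE) |>
    mutate(delta_k = .data$k_I - dplyr::lag(.data$k_I)) |>
    ungroup() |>
    filter(!is.na(.data$delta_k)) |>
    select("window", "residue", "delta_k") |>
    arrange(.data$window, .data$residue)
}

#' Local conformational change between consecutive windows
#'
#' `db_I(t)`: sum of `|b_ij(t) - b_ij(t-1)|` over the bonds touching residue
#' I that carry a non-zero force constant in either window, measuring how
#' much of the local rest geometry moved where mechanical coupling exists.
#'
#' @inheritParams residue_series
#' @return Tibble `window` (2..W), `residue`, `delta_b` (Angstrom).
#' @export
conformational_change <- function(fluct) {
  K <- fluct_k_matrix(fluct)
  B <- fluct_b_matrix(fluct)
  inc <- bond_incidence(fluct, drop_intra = FALSE)
  all_res <- sort(unique(fluct$residues))
  out <- lapply(2:n_windows(fluct), function(t) {
    active <- K[, t] > 0 | K[, t - 1] > 0
    db <- abs(B[, t] - B[, t - 1]) * active
    val <- rowsum(db[inc$bond], inc$residue)
    tibble(
      window = t, residue = as.integer(rownames(val)), delta_b = as.vector(val)
    )
  })
  bind_rows(out) |>
    tidyr::complete(window = 2:n_windows(fluct), residue = all_res,
                    fill = list(delta_b = 0)) |>
    arrange(.data$window, .data$residue)
}

#' Relative coupling variation between consecutive windows
#'
#' For each residue, the average over its inter-residue bonds (with a
#' positive force constant in at least one of the two windows) of
#' `(k_ij(t) - k_ij(t-1)) / max(k_ij(t), k_ij(t-1))`.  Normalising by the
#' larger of the two values bounds the metric in `[-1, 1]`: +1 when every
#' bond newly appears, -1 when every bond vanishes, 0 when nothing changes.
#' Residues with no active bond in a window pair get `NA` (undefined), not 0.
#'
#' @inheritParams residue_series
#' @return Tibble `window` (2..W), `residue`, `psi`, `n_bonds`.
#' @export
psi <- function(fluct) {
  K <- fluct_k_matrix(fluct)
  inc <- bond_incidence(fluct, drop_intra = TRUE)
  all_res <- sort(unique(fluct$residues))
  out <- lapply(2:n_windows(fluct), function(t) {
    mx <- pmax(K[, t], K[, t - 1])
    active <- mx > 0
    ratio <- ifelse(active, (K[, t] - K[, t - 1]) / ifelse(active, mx, 1), NA_real_)
    sub <- filter(inc, active[.data$bond])
    if (nrow(sub) == 0) {
      return(tibble(window = t, residue = integer(), psi = double(), n_bonds = integer()))
    }
    sub |>
      group_by(.data$residue) |>
      summarise(
        psi = mean(ratio[.data$bond]), n_bonds = dplyr::n(), .groups = "drop"
      ) |>
      mutate(window = t, .before = 1)
  })
  bind_rows(out) |>
    tidyr::complete(window = 2:n_windows(fluct), residue = all_res,
                    fill = list(psi = NA_real_, n_bonds = 0L)) |>
    arrange(.data$window, .data$residue)
}

#' Write residue-level metrics as long-format TSV
#'
#' Columns `residue`, `window`, `metric`, `value`.
#'
#' @param metrics Named list of metric tibbles (each with `window`,
#'   `residue` and one value column), e.g.
#'   `list(psi = psi(f), delta_b = conformational_change(f))`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(metrics, path) {
  long <- bind_rows(lapply(names(metrics), function(nm) {
    tb <- metrics[[nm]]
    value_col <- setdiff(names(tb), c("window", "residue", "n_bonds"))[1]
    tibble(
      residue = tb$residue, window = tb$window,
      metric = nm, value = tb[[value_col]]
    )
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# residue\twindow\tmetric\tvalue", con)
  writeLines(sprintf(
    "%d\t%d\t%s\t%.17g", long$residue, long$window, long$metric, long$value
  ), con)
  invisible(path)
}
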