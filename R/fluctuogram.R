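#' Half-overlapping analysis windows
#'
#' Splits `nframes` frames into windows of `window_frames` frames advancing
#' by `stride` frames (default half the window, so consecutive windows share
#' exactly half their frames).  The window count is
#' `floor((nframes - window_frames)/stride) + 1`.
#'
#' @param nframes Total number of frames.
#' @param window_frames Window length in frames; must be even and >= 4.
#' @param stride Advance between window starts (default `window_frames/2`).
#' @return Tibble with columns `window`, `start`, `end` (inclusive frame
#'   indices).
#' @export
make_windows <- function(nframes, window_frames, stride = window_frames / 2) {
  if (window_frames %% 2 != 0 || window_frames < 4) {
    abort("`window_frames` must be even and >= 4")
  }
  if (nframes < window_frames) abort("`nframes` must be >= `window_frames`")
  starts <- seq(1L, nframes - window_frames + 1L, by = as.integer(stride))
  tibble(
    window = seq_along(starts),
    start = starts,
    end = starts + as.integer(window_frames) - 1L
  )
}

#' Compute a fluctuogram
#'
#' Runs [measure_targets()] + [fluctuation_match()] independently on each
#' window of the trajectory over a shared bond pool, yielding the
#' time-ordered sequence of elastic networks ("fluctuogram") that records
#' the temporal evolution of the mechanical coupling network.  Windows are
#' independent, so results do not depend on evaluation order.
#'
#' @param traj A [cg_trajectory()].
#' @param window_frames Window length in frames (even, >= 4).
#' @param pool Bond pool tibble (`i`, `j`); default
#'   [init_bond_pool()] over the whole trajectory at 10 Angstrom.
#' @param config A [fluctmatch_config()].
#' @param stride Window advance in frames (default half-overlap).
#' @param cutoff Pool cutoff in Angstrom when `pool` is not supplied.
#' @return A `fluctuogram` object: list with `networks` (list of
#'   [elastic_network()]s on the shared pool), `windows` (tibble `window`,
#'   `start`, `end`, `midpoint_time` in ns), `pool`, `residues`,
#'   `convergence` (per-window [glance()] rows), `config`.
#' @export
compute_fluctuogram <- function(traj, window_frames, pool = NULL,
                                config = fluctmatch_config(),
                                stride = window_frames / 2, cutoff = 10) {
  if (is.null(pool)) pool <- init_bond_pool(traj, cutoff = cutoff)
  windows <- make_windows(n_frames(traj), window_frames, stride)
  fits <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    frames <- windows$start[w]:windows$end[w]
    fits[[w]] <- tryCatch(
      fluctuation_match(measure_targets(traj, pool, frames = frames), config),
      error = function(e) {
        abort(sprintf("window %d: %s", w, conditionMessage(e)))
      }
    )
  }
  windows$midpoint_time <- vapply(
    seq_len(nrow(windows)),
    function(w) mean(traj$times[c(windows$start[w], windows$end[w])]),
    double(1)
  )
  structure(
    list(
      networks = lapply(fits, function(f) f$network),
      windows = windows,
      pool = pool,
      residues = site_residues(traj$mapping, n_sites(traj)),
      convergence = bind_rows(lapply(fits, glance)) |>
        mutate(window = windows$window, .before = 1),
      config = config
    ),
    class = "fluctuogram"
  )
}

#' @export
print.fluctuogram <- function(x, ...) {
  cat(sprintf(
    "<fluctuogram> %d windows x %d bonds, %d/%d converged\n",
    length(x$networks), nrow(x$pool),
    sum(x$convergence$converged), length(x$networks)
  ))
  invisible(x)
}

n_windows <- function(fluct) length(fluct$networks)

#' @export
tidy.fluctuogram <- function(x, ...) {
  bind_rows(lapply(seq_along(x$networks), function(w) {
    mutate(tidy(x$networks[[w]]), window = w, .before = 1)
  }))
}

#' @export
glance.fluctuogram <- function(x, ...) x$convergence

#' Write and read a fluctuogram directory
#'
#' One directory per run: `windows.tsv` (index, frame range, midpoint time)
#' and `window_<n>.network.tsv` per window in the format of
#' [write_network_tsv()].
#'
#' @param fluct A `fluctuogram`.
#' @param dir Directory path (created if missing).
#' @return `write_fluctuogram()` returns `dir` invisibly;
#'   `read_fluctuogram()` a `fluctuogram` (convergence traces are not
#'   persisted).
#' @export
write_fluctuogram <- function(fluct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "windows.tsv"), "w")
  writeLines("# window\tstart\tend\tmidpoint_ns", con)
  writeLines(sprintf(
    "%d\t%d\t%d\t%.17g",
    fluct$windows$window, fluct$windows$start, fluct$windows$end,
    fluct$windows$midpoint_time
  ), con)
  close(con)
  for (w in seq_along(fluct$networks)) {
    write_network_tsv(
      fluct$networks[[w]],
      file.path(dir, sprintf("window_%d.network.tsv", w))
    )
  }
  invisible(dir)
}

#' @rdname write_fluctuogram
#' @export
read_fluctuogram <- function(dir) {
  lines <- readLines(file.path(dir, "windows.tsv"))
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  parts <- do.call(rbind, strsplit(body, "\t"))
  windows <- tibble(
    window = as.integer(parts[, 1]), start = as.integer(parts[, 2]),
    end = as.integer(parts[, 3]), midpoint_time = as.numeric(parts[, 4])
  )
  networks <- lapply(windows$window, function(w) {
    read_network_tsv(file.path(dir, sprintf("window_%d.network.tsv", w)))
  })
  structure(
    list(
      networks = networks, windows = windows,
      pool = networks[[1]]$bonds[, c("i", "j")],
      residues = networks[[1]]$residues,
      convergence = NULL, config = NULL
    ),
    class = "fluctuogram"
  )
}
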