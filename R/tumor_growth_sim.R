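# R interface to the 3D lattice growth simulator and virtual tumor cutting.
#
# The model: cells occupy integer lattice sites (one per site). At rate b a
# cell divides, placing a daughter with the same heritable barcode in a
# uniformly chosen empty neighbor site (suppressed if all neighbors are
# full); at rate d it dies; at rate M it migrates to an empty neighbor.
# Started from a compact cluster of n_init cells with distinct barcodes,
# this produces the patchy clonal geography seen in cut barcoded tumors.

#' Growth-simulation parameters
#'
#' Default rates are a design choice of this package (the published model
#' this emulates does not print its values): `birth_rate = 1` sets the time
#' unit, `death_rate = 0.1` gives net growth, and `migration_rate = 1e-3`
#' adds mild local mixing. The default target of 1e5 cells is a desk-scale
#' stand-in for real tumors of 1e7-1e8 cells.
#'
#' @param birth_rate per-cell division rate (> 0).
#' @param death_rate per-cell death rate (>= 0).
#' @param migration_rate per-cell migration rate (>= 0).
#' @param n_init number of barcoded initiating cells (default 200).
#' @param target_cells stop once this many cells are alive.
#' @param neighborhood `"von_neumann"` (6 neighbors) or `"moore"` (26).
#' @param seed integer seed.
#' @param max_events event-count safety cap.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(birth_rate = 1, death_rate = 0.1,
                       migration_rate = 1e-3, n_init = 200L,
                       target_cells = 1e5, neighborhood = c("von_neumann",
                                                            "moore"),
                       seed = 1L, max_events = 5e8) {
  neighborhood <- match.arg(neighborhood)
  if (birth_rate <= 0) stop_ct("birth_rate must be > 0")
  if (death_rate < 0 || migration_rate < 0)
    stop_ct("death_rate and migration_rate must be >= 0")
  n_init <- as.integer(n_init)
  if (n_init < 1L) stop_ct("n_init must be >= 1")
  if (target_cells < n_init) stop_ct("target_cells must be >= n_init")
  structure(list(birth_rate = birth_rate, death_rate = death_rate,
                 migration_rate = migration_rate, n_init = n_init,
                 target_cells = as.integer(target_cells),
                 neighborhood = neighborhood, seed = as.integer(seed),
                 max_events = max_events),
            class = "sim_params")
}

#' Simulate 3D growth of barcoded tumor cells
#'
#' Stochastic (Gillespie-style) birth/death/migration on a cubic lattice,
#' starting from a compact cluster of `n_init` cells carrying distinct
#' barcode labels. Runs until `target_cells` cells are alive or the
#' population goes extinct. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()].
#' @return Object of class `sim_state`: `coords` (cells x 3 integer lattice
#'   positions), `labels` (barcode label per cell, subset of 1..n_init),
#'   `time`, event counts, `extinct` and `reached_target` flags, `params`.
#' @export
simulate_growth <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  raw <- with_local_seed(params$seed, .sim_growth_cpp(
    params$n_init, params$birth_rate, params$death_rate,
    params$migration_rate, params$target_cells,
    params$neighborhood == "moore", params$max_events))
  colnames(raw$coords) <- c("x", "y", "z")
  structure(list(coords = raw$coords, labels = raw$labels, time = raw$time,
                 births = raw$births, deaths = raw$deaths,
                 migrations = raw$migrations, extinct = raw$extinct,
                 reached_target = raw$reached_target, events = raw$events,
                 params = params),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf(
    "<sim_state> %d cells, %d surviving barcodes, t = %.2f%s\n",
    nrow(x$coords), length(unique(x$labels)), x$time,
    if (x$extinct) " (extinct)" else ""))
  invisible(x)
}

#' Clone sizes of a simulated tumor
#' @param state a [sim_state()] from [simulate_growth()].
#' @return Named integer vector of cells per barcode label.
#' @export
clone_sizes <- function(state) {
  tab <- table(state$labels)
  stats::setNames(as.integer(tab), paste0("sim_bc", names(tab)))
}

#' Virtually cut a simulated tumor into pieces
#'
#' Partitions the cells into spatial regions and tallies barcode counts per
#' piece, mirroring the physical cutting of a resected tumor.
#' `"octants"` (default, requires 8 pieces) splits at the median x, then
#' median y within halves, then median z within quarters, giving pieces
#' balanced to within one cell; `"slabs"` cuts `n_pieces` equal-count slabs
#' along x; `"kmeans_regions"` clusters cell coordinates (seeded).
#'
#' @param state a [sim_state()].
#' @param n_pieces number of pieces (>= 2, <= number of cells).
#' @param scheme cutting scheme.
#' @param seed seed for `"kmeans_regions"`.
#' @return Object of class `virtual_cut`: `counts` (pieces x barcodes),
#'   `assignment` (piece per cell), `adjacency` (pieces x pieces logical,
#'   TRUE where pieces touch on the lattice).
#' @export
virtual_cut <- function(state, n_pieces = 8L,
                        scheme = c("octants", "slabs", "kmeans_regions"),
                        seed = 1L) {
  scheme <- match.arg(scheme)
  n <- nrow(state$coords)
  if (n == 0L) stop_ct("state has no cells")
  if (n_pieces < 2L) stop_ct("n_pieces must be >= 2")
  if (n_pieces > n) stop_ct("n_pieces exceeds total cells")
  xyz <- state$coords

  split_median <- function(idx, col) {
    # balanced split by rank (median split with deterministic tie handling)
    ord <- idx[order(xyz[idx, col], idx)]
    half <- length(ord) %/% 2L
    list(ord[seq_len(half)], ord[seq(half + 1L, length(ord))])
  }
  if (scheme == "octants") {
    if (n_pieces != 8L) stop_ct("octants scheme requires n_pieces = 8")
    assignment <- integer(n)
    halves <- split_median(seq_len(n), 1L)
    piece <- 0L
    for (h in halves) for (q in split_median(h, 2L))
      for (o in split_median(q, 3L)) {
        piece <- piece + 1L
        assignment[o] <- piece
      }
  } else if (scheme == "slabs") {
    ord <- order(xyz[, 1L], seq_len(n))
    assignment <- integer(n)
    assignment[ord] <- as.integer(cut(seq_len(n), n_pieces, labels = FALSE))
  } else {
    km <- with_local_seed(seed,
                          stats::kmeans(xyz, centers = n_pieces, nstart = 5L))
    assignment <- km$cluster
  }

  labels <- paste0("sim_bc", state$labels)
  counts <- table(factor(assignment, levels = seq_len(n_pieces)),
                  factor(labels, levels = sort(unique(labels))))
  counts <- matrix(as.integer(counts), n_pieces,
                   dimnames = list(paste0("piece_", seq_len(n_pieces)),
                                   colnames(counts)))

  # pieces are adjacent when some cell has a lattice neighbor across the cut
  key <- function(x, y, z) (x + 2048) + (y + 2048) * 4096 + (z + 2048) * 4096^2
  keys <- key(xyz[, 1L], xyz[, 2L], xyz[, 3L])
  adj <- matrix(FALSE, n_pieces, n_pieces,
                dimnames = list(rownames(counts), rownames(counts)))
  offsets <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  for (k in seq_len(nrow(offsets))) {
    nk <- key(xyz[, 1L] + offsets[k, 1L], xyz[, 2L] + offsets[k, 2L],
              xyz[, 3L] + offsets[k, 3L])
    hit <- match(nk, keys)
    ok <- !is.na(hit)
    a <- assignment[ok]
    b <- assignment[hit[ok]]
    cross <- a != b
    if (any(cross)) {
      adj[cbind(a[cross], b[cross])] <- TRUE
      adj[cbind(b[cross], a[cross])] <- TRUE
    }
  }
  structure(list(counts = counts, assignment = assignment, adjacency = adj,
                 scheme = scheme),
            class = "virtual_cut")
}

#' Convert a virtual cut into per-piece clonal profiles
#'
#' @param cut a [virtual_cut()].
#' @return Named list of [clonal_profile()] objects, one per piece, ready
#'   for [dispersion()], [hellinger_matrix()] etc.
#' @export
pieces_to_profiles <- function(cut) {
  stopifnot(inherits(cut, "virtual_cut"))
  out <- lapply(rownames(cut$counts), function(pid) {
    row <- cut$counts[pid, ]
    clonal_profile(pid, row / sum(row))
  })
  stats::setNames(out, rownames(cut$counts))
}
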