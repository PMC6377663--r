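# Hellinger distances between tumor-piece profiles, stress-majorization
# 2D layout (a deterministic, seedable take on force-directed placement),
# and hierarchical clustering of pieces and barcodes.

profiles_to_matrix <- function(piece_profiles, tol = 1e-6) {
  freq_list <- lapply(piece_profiles, profile_freq)
  sums <- vapply(freq_list, sum, numeric(1))
  if (any(abs(sums - 1) > tol))
    stop_ct("profiles must be normalized (sum 1 within ", tol, ")")
  ids <- names(piece_profiles) %||%
    vapply(piece_profiles, function(p) p$sample_id, character(1))
  all_bc <- unique(unlist(lapply(freq_list, names)))
  mat <- matrix(0, length(freq_list), length(all_bc),
                dimnames = list(ids, all_bc))
  for (i in seq_along(freq_list))
    mat[i, names(freq_list[[i]])] <- freq_list[[i]]
  mat
}

#' Hellinger distance between two clonal profiles
#'
#' \eqn{H(p,q) = \frac{1}{\sqrt 2}\sqrt{\sum_i(\sqrt{p_i}-\sqrt{q_i})^2}}
#' over the union barcode set (absent barcodes contribute frequency 0).
#' Bounded in \[0, 1\]: 0 for identical profiles, 1 for disjoint supports.
#'
#' @param p,q [clonal_profile()] objects.
#' @return Hellinger distance.
#' @export
hellinger_distance <- function(p, q) {
  m <- profiles_to_matrix(list(a = p, b = q))
  sqrt(0.5 * sum((sqrt(m[1L, ]) - sqrt(m[2L, ]))^2))
}

#' Pairwise Hellinger distance matrix between tumor pieces
#'
#' @param piece_profiles list of >= 2 normalized [clonal_profile()] objects.
#' @return Symmetric matrix of class `piece_distance_matrix` with zero
#'   diagonal, dimnames = piece ids.
#' @export
hellinger_matrix <- function(piece_profiles) {
  if (length(piece_profiles) < 2L) stop_ct("need >= 2 pieces")
  m <- profiles_to_matrix(piece_profiles)
  d <- as.matrix(stats::dist(sqrt(m))) / sqrt(2)
  structure(d, class = c("piece_distance_matrix", "matrix"))
}

#' 2D spatial reconstruction of tumor pieces by stress majorization
#'
#' Embeds the pieces in the plane so that Euclidean distances approximate
#' the Hellinger distances, by SMACOF stress majorization with
#' Kamada-Kawai weights \eqn{w_{ij} = 1/d_{ij}^2} from a seeded random
#' start. Majorization guarantees a non-increasing stress sequence, so the
#' layout is deterministic given the seed.
#'
#' @param distances a [hellinger_matrix()] (or any symmetric distance
#'   matrix with zero diagonal).
#' @param seed integer seed for the random initial configuration.
#' @param max_iter,tol iteration cap and relative stress-change tolerance.
#' @return Object of class `piece_layout`: `coords` (pieces x 2), final
#'   normalized `stress`, the per-iteration `stress_trace`, and `seed`.
#' @export
force_layout <- function(distances, seed = 1L, max_iter = 500L, tol = 1e-10) {
  d <- unclass(as.matrix(distances))
  n <- nrow(d)
  if (n < 2L) stop_ct("need >= 2 pieces to lay out")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop_ct("distances must be symmetric with zero diagonal")
  w <- 1 / pmax(d, 1e-8)^2
  diag(w) <- 0
  # Moore-Penrose inverse of the weighted Laplacian V (nullspace = ones)
  v <- -w
  diag(v) <- rowSums(w)
  vinv <- solve(v + 1 / n) - 1 / n
  scale_w <- sum(w * d^2) / 2

  stress_of <- function(x) {
    e <- as.matrix(stats::dist(x))
    sum(w * (e - d)^2) / 2 / scale_w
  }
  x <- with_local_seed(seed, matrix(stats::runif(2 * n, -0.5, 0.5), n, 2L))
  trace <- stress_of(x)
  for (it in seq_len(max_iter)) {
    e <- as.matrix(stats::dist(x))
    ratio <- ifelse(e > 0, d / e, 0)
    bmat <- -w * ratio
    diag(bmat) <- -rowSums(bmat)
    x_new <- vinv %*% (bmat %*% x)
    s_new <- stress_of(x_new)
    x <- x_new
    trace <- c(trace, s_new)
    if (abs(trace[it] - s_new) < tol * max(s_new, 1e-12)) break
  }
  x <- sweep(x, 2L, colMeans(x))  # center; orientation is arbitrary
  rownames(x) <- rownames(d)
  structure(list(coords = x, stress = trace[length(trace)],
                 stress_trace = trace, seed = as.integer(seed)),
            class = "piece_layout")
}

#' @export
print.piece_layout <- function(x, ...) {
  cat(sprintf("<piece_layout> %d pieces, stress %.4g (seed %d)\n",
              nrow(x$coords), x$stress, x$seed))
  invisible(x)
}

#' Hierarchical clustering of tumor pieces and barcodes
#'
#' Pieces are clustered by average linkage on the Hellinger matrix; barcodes
#' by average linkage on Euclidean distances between square-root frequency
#' vectors. Leaf orders are returned for heatmap rendering.
#'
#' @param piece_profiles list of >= 2 normalized [clonal_profile()] objects.
#' @return List with `pieces` and `barcodes` (`hclust` objects; `barcodes`
#'   is NULL when fewer than 2 barcodes are present) plus `piece_order` and
#'   `barcode_order` leaf orderings.
#' @export
cluster_pieces <- function(piece_profiles) {
  if (length(piece_profiles) < 2L) stop_ct("need >= 2 pieces")
  h <- hellinger_matrix(piece_profiles)
  hc_pieces <- stats::hclust(stats::as.dist(h), method = "average")
  m <- profiles_to_matrix(piece_profiles)
  hc_bc <- NULL
  bc_order <- colnames(m)
  if (ncol(m) >= 2L) {
    hc_bc <- stats::hclust(stats::dist(t(sqrt(m))), method = "average")
    bc_order <- colnames(m)[hc_bc$order]
  }
  list(pieces = hc_pieces, barcodes = hc_bc,
       piece_order = rownames(m)[hc_pieces$order],
       barcode_order = bc_order)
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` object (e.g. from [cluster_pieces()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_dendrogram <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
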