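# The proportional-shedding null model: if every clone shed cells into
# blood/lung in proportion to its size in the primary tumor, a distal sample
# of n FACS-sorted cells is a multinomial draw from the tumor profile.
# Observed distal statistics are compared against replicates of that draw.

#' Virtually sample cells from a tumor profile
#'
#' Draws `n_cells` cells with replacement, each barcode sampled with
#' probability equal to its measured tumor frequency (one multinomial draw),
#' and returns the normalized profile of the draw.
#'
#' @param tumor a normalized [clonal_profile()].
#' @param n_cells number of cells sorted from the virtual tissue (>= 0).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return A [clonal_profile()] of the virtual sample (empty if `n_cells`
#'   is 0).
#' @export
subsample_profile <- function(tumor, n_cells, seed = 1L) {
  if (n_cells < 0) stop_ct("n_cells must be >= 0")
  p <- profile_freq(tumor)
  sid <- paste0(tumor$sample_id, "_subsample")
  if (n_cells == 0 || length(p) == 0L)
    return(clonal_profile(sid, numeric(0)))
  draw <- with_local_seed(seed, stats::rmultinom(1L, n_cells, p)[, 1L])
  clonal_profile(sid, draw / sum(draw))
}

#' Expected number of detected clones under multinomial subsampling
#'
#' Closed form \eqn{E[K] = \sum_i (1 - (1 - p_i)^n)} for the number of
#' distinct barcodes in a draw of n cells; the analytic oracle for
#' [subsample_profile()].
#'
#' @param tumor a [clonal_profile()].
#' @param n_cells sample size (>= 0).
#' @return Expected clone count.
#' @export
expected_detection_analytic <- function(tumor, n_cells) {
  if (n_cells < 0) stop_ct("n_cells must be >= 0")
  p <- profile_freq(tumor)
  sum(1 - (1 - p)^n_cells)
}

null_stats <- function(p_tumor, detected_mask) {
  # detected_mask: logical over names(p_tumor) support
  shared <- which(detected_mask)
  list(n_clones = length(shared),
       biomass_representation = sum(p_tumor[shared]))
}

#' Compare an observed distal profile against the proportional-shedding null
#'
#' Draws `n_replicates` virtual distal samples of `n_cells` cells from the
#' tumor profile and computes, for the observed profile and every replicate:
#' the clone count, the tumor biomass representation, and the Pearson
#' correlation of log10 frequencies with the tumor over shared barcodes.
#' Empirical two-sided p-values use the (r+1)/(n+1) estimator.
#'
#' @param tumor a normalized [clonal_profile()].
#' @param observed_distal the observed distal [clonal_profile()].
#' @param n_cells number of cells FACS-sorted for the distal tissue (from
#'   the sample sheet's `sorted_cell_count`).
#' @param n_replicates null replicates (>= 100 recommended; fewer warns).
#' @param seed integer seed.
#' @return Named list of `null_result` objects (one per statistic), each
#'   with `observed`, `null_values`, `null_mean`, `null_sd`, `p_value`.
#' @export
null_comparison <- function(tumor, observed_distal, n_cells,
                            n_replicates = 1000L, seed = 1L) {
  if (is.null(n_cells) || is.na(n_cells))
    stop_ct("n_cells missing for sample ", observed_distal$sample_id,
            " (no sorted_cell_count in the sample sheet)")
  if (n_replicates < 1L) stop_ct("n_replicates must be >= 1")
  if (n_replicates < 100L)
    warning("n_replicates < 100 gives a degenerate empirical p",
            call. = FALSE)
  pt <- profile_freq(tumor)
  fo <- profile_freq(observed_distal)
  draws <- with_local_seed(seed,
                           stats::rmultinom(n_replicates, n_cells, pt))
  det <- draws > 0L

  obs_shared <- names(pt) %in% names(fo)
  observed <- c(n_clones = length(fo),
                biomass_representation = sum(pt[obs_shared]))
  null_vals <- list(
    n_clones = colSums(det),
    biomass_representation = colSums(pt * det))

  # log10 frequency correlation with the tumor over shared barcodes
  log_cor <- function(freq_named) {
    shared <- intersect(names(pt), names(freq_named))
    if (length(shared) < 3L) return(NA_real_)
    stats::cor(log10(pt[shared]), log10(freq_named[shared]))
  }
  observed["log_correlation"] <- log_cor(fo)
  freqs <- sweep(draws, 2L, pmax(colSums(draws), 1L), "/")
  null_vals$log_correlation <- vapply(seq_len(n_replicates), function(j) {
    f <- freqs[, j]
    names(f) <- names(pt)
    log_cor(f[f > 0])
  }, numeric(1))

  out <- lapply(names(null_vals), function(stat) {
    nv <- null_vals[[stat]]
    obs <- unname(observed[stat])
    ok <- !is.na(nv)
    p <- if (is.na(obs) || !any(ok)) NA_real_ else {
      n <- sum(ok)
      p_lo <- (sum(nv[ok] <= obs) + 1) / (n + 1)
      p_hi <- (sum(nv[ok] >= obs) + 1) / (n + 1)
      min(1, 2 * min(p_lo, p_hi))
    }
    structure(list(statistic = stat, observed = obs, null_values = nv,
                   null_mean = mean(nv, na.rm = TRUE),
                   null_sd = stats::sd(nv, na.rm = TRUE),
                   p_value = p, n_replicates = n_replicates,
                   n_cells = n_cells, seed = as.integer(seed)),
              class = "null_result")
  })
  stats::setNames(out, names(null_vals))
}

#' @export
print.null_result <- function(x, ...) {
  cat(sprintf("<null_result> %s: observed %.4g, null %.4g +/- %.4g (p = %.3g, %d replicates)\n",
              x$statistic, x$observed, x$null_mean, x$null_sd, x$p_value,
              x$n_replicates))
  invisible(x)
}
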