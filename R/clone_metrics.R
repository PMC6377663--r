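# Clonal statistics: engraftment, clone-size distributions, dispersion,
# biomass representation, fold-change classes, diversity, cross-tissue
# regression, organ overlap, group tests, and small closed-form helpers.

profile_freq <- function(p) {
  stopifnot(inherits(p, "clonal_profile"))
  p$frequencies
}

#' Engraftment summary
#'
#' Number of detected clones and the fraction of injected barcoded cells
#' that engrafted (clone count / cells injected).
#'
#' @param profile a [clonal_profile()] of the grown tumor.
#' @param n_injected number of barcoded cells injected (default 2500).
#' @return List with `n_clones` and `efficiency`.
#' @export
engraftment_summary <- function(profile, n_injected = 2500L) {
  if (n_injected < 1L) stop_ct("n_injected must be >= 1")
  n <- profile$n_barcodes_detected
  list(n_clones = n, efficiency = n / n_injected)
}

#' Cumulative clone-size distribution
#'
#' Pools clone frequencies over the given profiles (each (sample, barcode)
#' pair is one clone observation), sorts ascending and returns the cumulative
#' fraction of clones at or below each frequency.
#'
#' @param profiles list of [clonal_profile()] objects.
#' @return data.frame with columns `frequency` and `cum_fraction`
#'   (nondecreasing, ending at 1).
#' @export
cumulative_clone_distribution <- function(profiles) {
  if (inherits(profiles, "clonal_profile")) profiles <- list(profiles)
  freqs <- unlist(lapply(profiles, profile_freq), use.names = FALSE)
  if (length(freqs) == 0L) stop_ct("all profiles are empty")
  freqs <- sort(freqs)
  data.frame(frequency = freqs,
             cum_fraction = seq_along(freqs) / length(freqs))
}

#' Clone dispersion across tumor pieces
#'
#' For each barcode detected anywhere in the tumor, the number of pieces in
#' which it is detected divided by the total number of pieces.
#'
#' @param piece_profiles list of [clonal_profile()] objects, one per piece
#'   of a single tumor (>= 2 pieces).
#' @return Named numeric vector in (0, 1].
#' @export
dispersion <- function(piece_profiles) {
  if (length(piece_profiles) < 2L)
    stop_ct("dispersion is undefined for a single piece")
  freq_list <- lapply(piece_profiles, profile_freq)
  all_bc <- unique(unlist(lapply(freq_list, names)))
  if (length(all_bc) == 0L) return(stats::setNames(numeric(0), character(0)))
  hits <- vapply(freq_list, function(f) all_bc %in% names(f),
                 logical(length(all_bc)))
  stats::setNames(rowSums(hits) / length(piece_profiles), all_bc)
}

#' Tumor biomass represented in a distal tissue
#'
#' The sum of primary-tumor frequencies of the barcodes shared between the
#' primary tumor and the distal tissue. A value of 0.8 means clones seen in
#' the distal tissue account for 80% of the tumor's biomass.
#'
#' @param tumor,distal [clonal_profile()] objects.
#' @return Fraction in \[0, 1\].
#' @export
biomass_representation <- function(tumor, distal) {
  ft <- profile_freq(tumor)
  fd <- profile_freq(distal)
  sum(ft[names(ft) %in% names(fd)])
}

#' Classify shared clones by tissue fold change
#'
#' Over barcodes shared between the two profiles, the ratio of distal to
#' tumor frequency is thresholded into over-represented (> threshold),
#' under-represented (< 1/threshold) and proportional classes.
#'
#' @param tumor,distal [clonal_profile()] objects.
#' @param threshold fold-change threshold (> 1, default 10).
#' @return List with `classes` (data.frame barcode_id/ratio/class) and
#'   `proportions` over the shared set; empty with a flag when the profiles
#'   share no barcodes.
#' @export
fold_change_classify <- function(tumor, distal, threshold = 10) {
  if (threshold <= 1) stop_ct("threshold must be > 1")
  ft <- profile_freq(tumor)
  fd <- profile_freq(distal)
  shared <- intersect(names(ft), names(fd))
  if (length(shared) == 0L) {
    return(list(classes = data.frame(barcode_id = character(0),
                                     ratio = numeric(0), class = character(0),
                                     stringsAsFactors = FALSE),
                proportions = c(over = NA_real_, under = NA_real_,
                                proportional = NA_real_),
                no_shared_barcodes = TRUE))
  }
  ratio <- unname(fd[shared] / ft[shared])
  cls <- ifelse(ratio > threshold, "over",
                ifelse(ratio < 1 / threshold, "under", "proportional"))
  tab <- data.frame(barcode_id = shared, ratio = ratio, class = cls,
                    stringsAsFactors = FALSE)
  props <- vapply(c("over", "under", "proportional"),
                  function(k) mean(cls == k), numeric(1))
  list(classes = tab, proportions = props, no_shared_barcodes = FALSE)
}

#' Shannon diversity and Simpson index
#'
#' Shannon diversity is \eqn{-\sum p_i \ln p_i} (in nats); the Simpson index
#' is \eqn{\sum p_i^2}, the probability that two random draws are the same
#' clone. Set `complement = TRUE` for the Gini-Simpson orientation
#' \eqn{1 - \sum p_i^2}.
#'
#' @param profile a nonempty [clonal_profile()].
#' @param complement report `1 - sum(p^2)` instead of `sum(p^2)`.
#' @return List with `shannon` and `simpson`.
#' @export
diversity_indices <- function(profile, complement = FALSE) {
  p <- profile_freq(profile)
  if (length(p) == 0L) stop_ct("diversity undefined for an empty profile")
  simpson <- sum(p^2)
  list(shannon = -sum(p * log(p)),
       simpson = if (complement) 1 - simpson else simpson)
}

#' Regression of shared-clone frequencies between two tissues
#'
#' Ordinary least squares of log10 frequency in tissue B on log10 frequency
#' in tissue A, restricted to barcodes detected in both tissues. Barcodes
#' found in only one tissue are reported separately and never enter the fit
#' (no pseudocounts).
#'
#' @param a,b [clonal_profile()] objects.
#' @return Object of class `tissue_comparison`: shared/a-only/b-only barcode
#'   sets, the paired log10 frequencies, and (when >= 3 barcodes are shared)
#'   `regression` with slope, intercept, adjusted R squared and F-test p.
#' @export
shared_barcode_regression <- function(a, b) {
  fa <- profile_freq(a)
  fb <- profile_freq(b)
  shared <- intersect(names(fa), names(fb))
  out <- list(sample_a = a$sample_id, sample_b = b$sample_id,
              shared_barcodes = shared,
              a_only = setdiff(names(fa), shared),
              b_only = setdiff(names(fb), shared),
              log10_a = log10(unname(fa[shared])),
              log10_b = log10(unname(fb[shared])),
              regression = NULL)
  if (length(shared) >= 3L) {
    fit <- stats::lm(out$log10_b ~ out$log10_a)
    sm <- summary(fit)
    fstat <- sm$fstatistic
    out$regression <- list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      slope_se = sm$coefficients[2L, 2L],
      adj_r_squared = sm$adj.r.squared,
      f_p_value = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                                   lower.tail = FALSE)))
  } else {
    out$too_few_shared <- TRUE
  }
  structure(out, class = "tissue_comparison")
}

#' @export
print.tissue_comparison <- function(x, ...) {
  cat(sprintf("<tissue_comparison> %s vs %s: %d shared, %d a-only, %d b-only\n",
              x$sample_a, x$sample_b, length(x$shared_barcodes),
              length(x$a_only), length(x$b_only)))
  if (!is.null(x$regression))
    cat(sprintf("  log10 OLS: slope %.3f, adj R^2 %.3f, F-test p %.3g\n",
                x$regression$slope, x$regression$adj_r_squared,
                x$regression$f_p_value))
  invisible(x)
}

#' Count metastatic sites per tumor clone
#'
#' For every barcode detected in the tumor, counts the non-tumor tissues in
#' which it is also detected (0 = tumor only). Barcodes seen only outside
#' the tumor are listed separately.
#'
#' @param profiles named list of [clonal_profile()] objects for one mouse;
#'   names are tissue labels.
#' @param tumor_tissue name of the tumor entry in `profiles`.
#' @return List with `sites_per_barcode` (named integer), `histogram`
#'   (table over site counts) and `non_tumor_resident` (character).
#' @export
organ_overlap_counts <- function(profiles, tumor_tissue = "tumor") {
  if (!tumor_tissue %in% names(profiles))
    stop_ct("no tumor profile named ", tumor_tissue)
  tumor_bc <- names(profile_freq(profiles[[tumor_tissue]]))
  other <- profiles[setdiff(names(profiles), tumor_tissue)]
  other_sets <- lapply(other, function(p) names(profile_freq(p)))
  sites <- vapply(tumor_bc, function(bc)
    sum(vapply(other_sets, function(s) bc %in% s, logical(1))), integer(1))
  non_res <- setdiff(unique(unlist(other_sets)), tumor_bc)
  list(sites_per_barcode = sites,
       histogram = table(factor(sites, levels = 0:length(other))),
       non_tumor_resident = non_res)
}

#' Two-group comparison tests used for clonal statistics
#'
#' * `welch_log`: Welch two-sample t-test on log-transformed values
#'   (requires strictly positive inputs).
#' * `wilcoxon`: Wilcoxon rank-sum test with continuity correction.
#' * `ks_pairwise_mean`: for groups given as lists of per-animal vectors,
#'   the mean and SD of two-sample Kolmogorov-Smirnov p-values over all
#'   within-group animal pairs (a reproducibility summary, reported per
#'   group).
#'
#' All tests are two-sided.
#'
#' @param a,b the two groups: numeric vectors for `welch_log`/`wilcoxon`,
#'   lists of numeric vectors (one per animal) for `ks_pairwise_mean`
#'   (`b` may be NULL to summarize a single group).
#' @param mode one of `"welch_log"`, `"ks_pairwise_mean"`, `"wilcoxon"`.
#' @return List with `statistic` and `p` (welch/wilcoxon), or per-group
#'   `mean_p`/`sd_p`/`n_pairs` (ks mode).
#' @export
group_comparison_tests <- function(a, b = NULL,
                                   mode = c("welch_log", "ks_pairwise_mean",
                                            "wilcoxon")) {
  mode <- match.arg(mode)
  if (mode == "welch_log") {
    if (any(c(a, b) <= 0))
      stop_ct("welch_log requires strictly positive values")
    tt <- stats::t.test(log(a), log(b), var.equal = FALSE)
    return(list(statistic = unname(tt$statistic), p = tt$p.value,
                df = unname(tt$parameter)))
  }
  if (mode == "wilcoxon") {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    return(list(statistic = unname(wt$statistic), p = wt$p.value))
  }
  ks_group <- function(g) {
    if (length(g) < 2L) stop_ct("ks_pairwise_mean needs >= 2 animals per group")
    pairs <- utils::combn(length(g), 2L)
    ps <- apply(pairs, 2L, function(ij)
      suppressWarnings(stats::ks.test(g[[ij[1L]]], g[[ij[2L]]])$p.value))
    list(mean_p = mean(ps), sd_p = stats::sd(ps), n_pairs = ncol(pairs))
  }
  out <- list(group_a = ks_group(a))
  if (!is.null(b)) out$group_b <- ks_group(b)
  out
}

#' Tumor volume and cell-number estimate from caliper measurements
#'
#' Volume is (minimum diameter)^2 x (maximum diameter) / 2; when a tumor
#' mass is supplied, the cell estimate assumes 1e6 cells per mg.
#'
#' @param min_diameter,max_diameter caliper diameters in mm.
#' @param mass_mg optional tumor mass in mg.
#' @return List with `volume_mm3` and `cell_estimate` (NULL without mass).
#' @export
estimate_tumor_cells <- function(min_diameter, max_diameter, mass_mg = NULL) {
  if (min_diameter <= 0 || max_diameter <= 0) stop_ct("diameters must be > 0")
  if (max_diameter < min_diameter)
    stop_ct("max_diameter must be >= min_diameter")
  list(volume_mm3 = min_diameter^2 * max_diameter / 2,
       cell_estimate = if (!is.null(mass_mg)) mass_mg * 1e6 else NULL)
}

#' Poisson single-integration fraction for lentiviral barcoding
#'
#' Under Poisson statistics for independent integrations, a transduction
#' fraction f (fraction of cells with at least one integration) corresponds
#' to a multiplicity of infection m = -ln(1 - f), and the fraction of
#' transduced cells carrying exactly one barcode is
#' m e^{-m} / (1 - e^{-m}). At 10-20% transduction this is the classical
#' 90-95% single-copy guarantee of barcoding protocols.
#'
#' @param transduction fraction of cells transduced, in (0, 1).
#' @return List with `moi` and `single_fraction`.
#' @export
poisson_single_integration <- function(transduction) {
  if (any(transduction <= 0 | transduction >= 1))
    stop_ct("transduction must be in (0, 1)")
  moi <- -log(1 - transduction)
  list(moi = moi,
       single_fraction = moi * exp(-moi) / (1 - exp(-moi)))
}
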