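# Replicate-based quality filters and normalization to clonal profiles.
#
# Order is fixed and deliberate: (1) drop replicates below the read-depth
# threshold and samples left with too few surviving replicates, (2) within
# each sample zero out barcodes seen in fewer than two replicates (non-
# reproducible PCR products), (3) pool replicates and normalize to frequency.

#' QC configuration
#'
#' @param min_reads_per_replicate replicate rows with fewer assigned reads
#'   are removed (default 8000).
#' @param min_supporting_replicates a barcode must be detected (count >= 1)
#'   in at least this many replicates of a sample to be kept (default 2).
#' @param min_replicates_per_sample samples retaining fewer replicate rows
#'   after the depth filter are removed entirely (default 2).
#' @return Object of class `qc_config`.
#' @export
qc_config <- function(min_reads_per_replicate = 8000L,
                      min_supporting_replicates = 2L,
                      min_replicates_per_sample = 2L) {
  cfg <- list(min_reads_per_replicate = as.integer(min_reads_per_replicate),
              min_supporting_replicates = as.integer(min_supporting_replicates),
              min_replicates_per_sample = as.integer(min_replicates_per_sample))
  if (any(unlist(cfg) < 1L)) stop_ct("all QC thresholds must be >= 1")
  structure(cfg, class = "qc_config")
}

#' Depth filter on technical replicates
#'
#' Removes replicate rows whose total assigned reads fall below
#' `min_reads_per_replicate`, then removes whole samples that retain fewer
#' than `min_replicates_per_sample` rows. Every removal is recorded in the
#' attached report.
#'
#' @param matrix a [barcode_count_matrix()].
#' @param cfg a [qc_config()].
#' @return The filtered matrix; removals in `attr(, "qc_report")`, a
#'   data.frame with columns sample_id, replicate_id, total_reads, reason.
#' @export
filter_replicates_by_depth <- function(matrix, cfg = qc_config()) {
  stopifnot(inherits(matrix, "barcode_count_matrix"))
  totals <- rowSums(matrix$counts)
  meta <- matrix$metadata
  report <- data.frame(sample_id = character(0), replicate_id = character(0),
                       total_reads = numeric(0), reason = character(0),
                       stringsAsFactors = FALSE)
  low <- totals < cfg$min_reads_per_replicate
  if (any(low)) {
    report <- rbind(report, data.frame(
      sample_id = meta$sample_id[low], replicate_id = meta$replicate_id[low],
      total_reads = totals[low],
      reason = sprintf("below %d reads", cfg$min_reads_per_replicate),
      stringsAsFactors = FALSE))
  }
  keep <- !low
  surviving <- table(meta$sample_id[keep])
  dead_samples <- union(
    setdiff(meta$sample_id, names(surviving)),
    names(surviving)[surviving < cfg$min_replicates_per_sample])
  drop_sample <- keep & meta$sample_id %in% dead_samples
  if (any(drop_sample)) {
    report <- rbind(report, data.frame(
      sample_id = meta$sample_id[drop_sample],
      replicate_id = meta$replicate_id[drop_sample],
      total_reads = totals[drop_sample],
      reason = sprintf("sample has fewer than %d replicates above threshold",
                       cfg$min_replicates_per_sample),
      stringsAsFactors = FALSE))
  }
  keep <- keep & !(meta$sample_id %in% dead_samples)
  out <- barcode_count_matrix(matrix$counts[keep, , drop = FALSE],
                              meta[keep, , drop = FALSE],
                              unassigned = matrix$unassigned,
                              unassigned_reasons = matrix$unassigned_reasons)
  attr(out, "qc_report") <- report
  out
}

#' Replicate-support filter on barcodes
#'
#' Within each sample, a barcode detected (count >= 1) in fewer than
#' `min_supporting_replicates` technical replicates has all its counts in
#' that sample set to zero. Targets non-reproducible amplification such as
#' single-replicate contaminants.
#'
#' @param matrix a depth-filtered [barcode_count_matrix()].
#' @param cfg a [qc_config()].
#' @return The filtered matrix.
#' @export
filter_barcodes_by_replicate_support <- function(matrix, cfg = qc_config()) {
  stopifnot(inherits(matrix, "barcode_count_matrix"))
  meta <- matrix$metadata
  counts <- matrix$counts
  for (sid in unique(meta$sample_id)) {
    rows <- which(meta$sample_id == sid)
    if (length(rows) < 2L)
      stop_ct("sample ", sid, " has a single surviving replicate; the ",
              "replicate-support filter is undefined - apply ",
              "filter_replicates_by_depth with min_replicates_per_sample >= 2 first")
    support <- colSums(counts[rows, , drop = FALSE] > 0L)
    kill <- support < cfg$min_supporting_replicates & support > 0L
    if (any(kill)) counts[rows, kill] <- 0L
  }
  barcode_count_matrix(counts, meta, unassigned = matrix$unassigned,
                       unassigned_reasons = matrix$unassigned_reasons)
}

#' Clonal frequency profile of one sample
#'
#' @param sample_id sample identifier.
#' @param frequencies named numeric vector of barcode frequencies; zeros are
#'   dropped; must sum to 1 within 1e-9 unless empty.
#' @param provenance data.frame of the replicate rows pooled into the profile.
#' @return Object of class `clonal_profile`.
#' @export
clonal_profile <- function(sample_id, frequencies,
                           provenance = NULL) {
  frequencies <- frequencies[frequencies > 0]
  if (length(frequencies) && abs(sum(frequencies) - 1) > 1e-9)
    stop_ct("profile frequencies must sum to 1 (got ", sum(frequencies), ")")
  if (length(frequencies) && is.null(names(frequencies)))
    stop_ct("frequencies must be named by barcode id")
  structure(list(sample_id = sample_id,
                 frequencies = frequencies,
                 n_barcodes_detected = length(frequencies),
                 provenance = provenance),
            class = "clonal_profile")
}

#' @export
print.clonal_profile <- function(x, ...) {
  cat(sprintf("<clonal_profile> %s: %d barcodes%s\n", x$sample_id,
              x$n_barcodes_detected,
              if (x$n_barcodes_detected == 0L) " (empty)" else ""))
  invisible(x)
}

#' Pool technical replicates and normalize to clonal frequencies
#'
#' Replicates from the same sequencing run are pooled by adding reads per
#' barcode and normalizing the sum to one. Replicates spanning runs are each
#' normalized to one first, then summed and renormalized, to mitigate
#' differing library sizes between runs.
#'
#' @param matrix a filtered [barcode_count_matrix()].
#' @return Named list of [clonal_profile()] objects, one per sample. Samples
#'   with zero total reads yield an empty profile (with a warning) that
#'   downstream statistics skip.
#' @export
pool_and_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "barcode_count_matrix"))
  meta <- matrix$metadata
  out <- list()
  for (sid in unique(meta$sample_id)) {
    rows <- which(meta$sample_id == sid)
    sub <- matrix$counts[rows, , drop = FALSE]
    runs <- unique(meta$run_id[rows])
    if (length(runs) == 1L) {
      pooled <- colSums(sub)
    } else {
      rt <- rowSums(sub)
      norm_rows <- sub[rt > 0, , drop = FALSE] / rt[rt > 0]
      pooled <- if (nrow(norm_rows)) colSums(norm_rows) else colSums(sub) * 0
    }
    tot <- sum(pooled)
    if (tot == 0) {
      warning("sample ", sid, " has zero reads after filtering; ",
              "emitting empty profile", call. = FALSE)
      prof <- clonal_profile(sid, numeric(0), meta[rows, , drop = FALSE])
    } else {
      prof <- clonal_profile(sid, pooled / tot, meta[rows, , drop = FALSE])
    }
    out[[sid]] <- prof
  }
  out
}

#' Run the full QC + normalization chain
#'
#' Depth filter, replicate-support filter, pooling and normalization, in the
#' fixed order the filters are defined for.
#'
#' @inheritParams filter_replicates_by_depth
#' @return List with elements `profiles` (list of [clonal_profile()]),
#'   `matrix` (the filtered count matrix) and `report` (depth-filter removals).
#' @export
qc_pipeline <- function(matrix, cfg = qc_config()) {
  depth_ok <- filter_replicates_by_depth(matrix, cfg)
  report <- attr(depth_ok, "qc_report")
  if (nrow(depth_ok$counts) == 0L)
    return(list(profiles = list(), matrix = depth_ok, report = report))
  supported <- filter_barcodes_by_replicate_support(depth_ok, cfg)
  profiles <- pool_and_normalize(supported)
  list(profiles = profiles, matrix = supported, report = report)
}

# ---- profile persistence ----------------------------------------------------

#' Write clonal profiles to a long-format TSV
#'
#' One row per (sample, barcode) with the sample's tissue metadata repeated;
#' the companion reader is [read_profiles()].
#'
#' @param profiles list of [clonal_profile()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    meta <- p$provenance
    first <- if (!is.null(meta) && nrow(meta)) meta[1L, ] else
      data.frame(mouse_id = NA, tissue = NA, timepoint = NA,
                 sorted_cell_count = NA)
    if (p$n_barcodes_detected == 0L) return(NULL)
    data.frame(sample_id = p$sample_id,
               mouse_id = first$mouse_id, tissue = first$tissue,
               timepoint = first$timepoint,
               sorted_cell_count = first$sorted_cell_count,
               barcode_id = names(p$frequencies),
               frequency = unname(p$frequencies),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read clonal profiles written by [write_profiles()]
#' @param path TSV path.
#' @return Named list of [clonal_profile()] objects.
#' @export
read_profiles <- function(path) {
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out <- list()
  for (sid in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == sid, , drop = FALSE]
    freq <- stats::setNames(sub$frequency, sub$barcode_id)
    freq <- freq / sum(freq)  # guard against rounding in the text file
    meta <- unique(sub[, c("sample_id", "mouse_id", "tissue", "timepoint",
                           "sorted_cell_count")])
    out[[sid]] <- clonal_profile(sid, freq, meta)
  }
  out
}
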