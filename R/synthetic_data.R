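# Synthetic barcoding experiments with known ground truth.
#
# The generator states the world the real assay lives in: ~2500 injected
# barcoded cells of which ~10% engraft, a heavy-tailed clone-size law
# spanning orders of magnitude, patchy allocation of clones to tumor pieces
# (adjacent pieces share clones), blood shedding proportional to tumor
# frequency times lognormal noise, a small seeder subset that repopulates
# the lung after resection at frequencies unrelated to the tumor, paired
# technical replicates with multinomial read noise, occasional replicates
# below the 8000-read QC threshold, and single-replicate spurious barcodes.

#' Configuration of a synthetic barcoding experiment
#'
#' Defaults mirror the experimental design being emulated: a 2500-member
#' library, 2500 injected cells, 10% engraftment, a log-normal clone-size
#' law with sdlog 2.5 (spanning ~6 orders of magnitude), 8 tumor pieces,
#' and 2 technical replicates per sample.
#'
#' @param library_size barcodes in the reference library.
#' @param n_injected barcoded cells injected per mouse.
#' @param engraft_prob per-cell engraftment probability.
#' @param clone_law `"log_normal"` or `"pareto"` clone-size law.
#' @param clone_meanlog,clone_sdlog log-normal parameters.
#' @param pareto_alpha Pareto tail index (used when `clone_law = "pareto"`).
#' @param n_tumor_pieces pieces the tumor is cut into (chain-adjacent).
#' @param sigma_shed sdlog of the multiplicative shedding noise.
#' @param shedder_fraction fraction of engrafted clones that shed
#'   (size-weighted sample); shedders include all seeders.
#' @param seeder_fraction fraction of shedders that persist as lung
#'   metastases after resection.
#' @param n_replicates_per_sample technical replicates per sample.
#' @param mean_reads_per_replicate mean sequencing depth of a good replicate.
#' @param frac_low_depth fraction of replicates forced below the 8000-read
#'   threshold (drawn uniformly in 2000-7500 reads).
#' @param spurious_barcode_rate expected spurious barcodes per sample, each
#'   injected into exactly one replicate at 1-20 reads.
#' @param sorted_cells named vector of FACS-sorted cell counts recorded in
#'   the sample sheet for distal tissues.
#' @param treatment_survival_prob per-clone probability of surviving
#'   chemotherapy (used only by treated-arm generation).
#' @param seed integer master seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(library_size = 2500L, n_injected = 2500L,
                             engraft_prob = 0.10,
                             clone_law = c("log_normal", "pareto"),
                             clone_meanlog = 0, clone_sdlog = 2.5,
                             pareto_alpha = 1,
                             n_tumor_pieces = 8L, sigma_shed = 0.5,
                             shedder_fraction = 1, seeder_fraction = 0.05,
                             n_replicates_per_sample = 2L,
                             mean_reads_per_replicate = 1e5,
                             frac_low_depth = 0,
                             spurious_barcode_rate = 0,
                             sorted_cells = c(blood = 1000L, lung = 2000L),
                             treatment_survival_prob = 0.8,
                             seed = 1L) {
  clone_law <- match.arg(clone_law)
  probs <- c(engraft_prob, shedder_fraction, seeder_fraction,
             frac_low_depth, treatment_survival_prob)
  if (any(probs < 0 | probs > 1)) stop_ct("probabilities must be in [0, 1]")
  if (library_size < n_injected)
    stop_ct("library_size must be >= n_injected")
  if (sigma_shed < 0 || spurious_barcode_rate < 0)
    stop_ct("rates must be >= 0")
  structure(list(library_size = as.integer(library_size),
                 n_injected = as.integer(n_injected),
                 engraft_prob = engraft_prob, clone_law = clone_law,
                 clone_meanlog = clone_meanlog, clone_sdlog = clone_sdlog,
                 pareto_alpha = pareto_alpha,
                 n_tumor_pieces = as.integer(n_tumor_pieces),
                 sigma_shed = sigma_shed,
                 shedder_fraction = shedder_fraction,
                 seeder_fraction = seeder_fraction,
                 n_replicates_per_sample = as.integer(n_replicates_per_sample),
                 mean_reads_per_replicate = mean_reads_per_replicate,
                 frac_low_depth = frac_low_depth,
                 spurious_barcode_rate = spurious_barcode_rate,
                 sorted_cells = sorted_cells,
                 treatment_survival_prob = treatment_survival_prob,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate the ground truth of a synthetic experiment
#'
#' Draws the engrafted clone set (Binomial(n_injected, engraft_prob)), the
#' heavy-tailed tumor clone sizes, a patchy allocation of clones to
#' chain-adjacent tumor pieces (larger clones span more pieces), blood
#' frequencies proportional to tumor frequency times lognormal shedding
#' noise, lung frequencies under the same shedding model, and a post-
#' resection lung supported only on the seeder subset at frequencies
#' independent of the tumor.
#'
#' @param cfg a [synthetic_config()].
#' @return Object of class `synthetic_truth`: `barcode_ids`, `sequences`
#'   (98-bp per library barcode), `engrafted`, `shedders`, `seeders`,
#'   `tissue_truth` (named list of frequency vectors: `tumor`,
#'   `piece_1..K`, `blood`, `lung`, `lung_T3`), `piece_adjacency`, `cfg`.
#' @export
generate_ground_truth <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    ids <- sprintf("bc%04d", seq_len(cfg$library_size))
    seqs <- vapply(seq_len(cfg$library_size), function(i)
      paste(sample(c("A", "C", "G", "T"), 98L, replace = TRUE),
            collapse = ""), character(1))
    while (anyDuplicated(seqs)) {  # vanishingly unlikely at 98 bp
      dup <- which(duplicated(seqs))
      seqs[dup] <- vapply(dup, function(i)
        paste(sample(c("A", "C", "G", "T"), 98L, replace = TRUE),
              collapse = ""), character(1))
    }
    names(seqs) <- ids

    engrafted_mask <- stats::rbinom(cfg$n_injected, 1L, cfg$engraft_prob) == 1L
    engrafted <- ids[seq_len(cfg$n_injected)][engrafted_mask]
    n_eng <- length(engrafted)
    if (n_eng == 0L)
      stop_ct("no clones engrafted under this seed/config; raise engraft_prob")

    sizes <- switch(cfg$clone_law,
      log_normal = stats::rlnorm(n_eng, cfg$clone_meanlog, cfg$clone_sdlog),
      pareto = (1 / stats::runif(n_eng))^(1 / cfg$pareto_alpha))
    tumor <- stats::setNames(sizes / sum(sizes), engrafted)

    # patchy piece allocation on a chain: clone i occupies a contiguous
    # window of pieces, wider for larger clones, with lognormal piece noise
    k <- cfg$n_tumor_pieces
    piece_mat <- matrix(0, n_eng, k,
                        dimnames = list(engrafted, paste0("piece_", 1:k)))
    size_rank <- rank(tumor, ties.method = "first") / n_eng
    for (i in seq_len(n_eng)) {
      width <- 1L + stats::rbinom(1L, k - 1L, 0.8 * size_rank[i])
      start <- sample.int(k - width + 1L, 1L)
      pieces <- start:(start + width - 1L)
      piece_mat[i, pieces] <- tumor[i] * stats::rlnorm(width, 0, 0.5)
    }
    piece_truth <- lapply(seq_len(k), function(j) {
      col <- piece_mat[, j]
      col <- col[col > 0]
      col / sum(col)
    })
    names(piece_truth) <- colnames(piece_mat)

    n_shed <- max(1L, round(cfg$shedder_fraction * n_eng))
    shedders <- if (n_shed >= n_eng) engrafted else
      engrafted[sample.int(n_eng, n_shed, prob = tumor)]
    shed_profile <- function() {
      w <- tumor[shedders] * stats::rlnorm(length(shedders), 0, cfg$sigma_shed)
      w / sum(w)
    }
    blood <- shed_profile()
    lung <- shed_profile()

    n_seed <- round(cfg$seeder_fraction * length(shedders))
    seeders <- if (n_seed == 0L) character(0) else
      shedders[sample.int(length(shedders), n_seed)]
    lung_t3 <- if (n_seed == 0L) stats::setNames(numeric(0), character(0))
      else {
        w <- stats::rlnorm(n_seed, 0, 1)  # independent of tumor frequency
        stats::setNames(w / sum(w), seeders)
      }

    structure(list(barcode_ids = ids, sequences = seqs,
                   engrafted = engrafted, shedders = shedders,
                   seeders = seeders,
                   tissue_truth = c(list(tumor = tumor), piece_truth,
                                    list(blood = blood, lung = lung,
                                         lung_T3 = lung_t3)),
                   piece_adjacency = cbind(1:(k - 1), 2:k),
                   cfg = cfg),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d/%d engrafted, %d shedders, %d seeders, %d pieces\n",
    length(x$engrafted), x$cfg$n_injected, length(x$shedders),
    length(x$seeders), x$cfg$n_tumor_pieces))
  invisible(x)
}

index_for_row <- function(i) {
  # deterministic unique 8-mers: base-4 encoding of the row number
  digits <- integer(8L)
  v <- i - 1L
  for (pos in 8:1) {
    digits[pos] <- v %% 4L
    v <- v %/% 4L
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

#' Synthesize a barcode-count matrix from ground truth
#'
#' Emits one sample per tissue in the truth (whole tumor, each piece, blood,
#' lung at T2, lung at T3) with `n_replicates_per_sample` technical
#' replicates. Each replicate's reads are a multinomial draw of its depth
#' over the tissue truth; a configured fraction of replicates is forced
#' below the 8000-read threshold; spurious barcodes from the unengrafted
#' remainder of the library are injected into exactly one replicate each.
#'
#' @param truth a [generate_ground_truth()] result.
#' @param cfg configuration; defaults to `truth$cfg`.
#' @param mouse_id,run_id metadata recorded in the sample sheet.
#' @return A [barcode_count_matrix()] over the full library. The injected
#'   spurious barcodes are recorded in `attr(, "spurious")` as a data.frame
#'   (sample_id, replicate row, barcode_id, count).
#' @export
synthesize_counts <- function(truth, cfg = truth$cfg, mouse_id = "m1",
                              run_id = "R1") {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!identical(cfg$library_size, truth$cfg$library_size))
    stop_ct("config does not match the truth's library")
  tissues <- names(truth$tissue_truth)
  timepoint <- ifelse(tissues == "lung_T3", "T3", "T2")
  with_local_seed(cfg$seed + 1L, {
    rows <- list()
    counts <- list()
    spurious_log <- list()
    unengrafted <- setdiff(truth$barcode_ids, truth$engrafted)
    row_i <- 0L
    for (ti in seq_along(tissues)) {
      tissue <- tissues[ti]
      p <- truth$tissue_truth[[tissue]]
      sid <- paste0(mouse_id, "_", tissue)
      sc_key <- sub("_T3$", "", tissue)
      sorted_n <- if (sc_key %in% names(cfg$sorted_cells))
        as.integer(cfg$sorted_cells[[sc_key]]) else NA_integer_
      n_spur <- stats::rpois(1L, cfg$spurious_barcode_rate)
      spur_rep <- if (n_spur > 0L)
        sample.int(cfg$n_replicates_per_sample, n_spur, replace = TRUE)
        else integer(0)
      for (r in seq_len(cfg$n_replicates_per_sample)) {
        row_i <- row_i + 1L
        depth <- if (stats::runif(1) < cfg$frac_low_depth)
          sample(2000:7500, 1L)
          else max(1L, round(stats::rlnorm(1L,
                                           log(cfg$mean_reads_per_replicate),
                                           0.3)))
        vec <- stats::setNames(integer(length(truth$barcode_ids)),
                               truth$barcode_ids)
        if (length(p) > 0L)
          vec[names(p)] <- stats::rmultinom(1L, depth, p)[, 1L]
        which_spur <- which(spur_rep == r)
        if (length(which_spur)) {
          spur_bc <- sample(unengrafted, length(which_spur))
          spur_counts <- sample(1:20, length(which_spur), replace = TRUE)
          vec[spur_bc] <- vec[spur_bc] + spur_counts
          spurious_log[[length(spurious_log) + 1L]] <- data.frame(
            sample_id = sid, replicate_id = paste0("rep", r),
            barcode_id = spur_bc, count = spur_counts,
            stringsAsFactors = FALSE)
        }
        rows[[row_i]] <- data.frame(
          sample_id = sid, index_sequence = index_for_row(row_i),
          mouse_id = mouse_id, tissue = tissue, timepoint = timepoint[ti],
          replicate_id = paste0("rep", r), run_id = run_id,
          sorted_cell_count = sorted_n, stringsAsFactors = FALSE)
        counts[[row_i]] <- vec
      }
    }
    bcm <- barcode_count_matrix(do.call(rbind, counts),
                                do.call(rbind, rows))
    attr(bcm, "spurious") <- if (length(spurious_log))
      do.call(rbind, spurious_log) else NULL
    bcm
  })
}

#' Render demultiplexable FASTQ reads for a count matrix
#'
#' Wraps every counted barcode in the amplicon structure (replicate index +
#' 5' flank + barcode sequence + 3' flank, padded to the product length)
#' and writes `count` copies of the read. Intended for small end-to-end
#' tests of [demultiplex_and_count()].
#'
#' @param matrix a [barcode_count_matrix()].
#' @param truth the [generate_ground_truth()] providing barcode sequences.
#' @param path output FASTQ path.
#' @param design the [amplicon_design()] to render with.
#' @return `path`, invisibly.
#' @export
render_reads <- function(matrix, truth, path, design = amplicon_design()) {
  con <- file(path, "w")
  on.exit(close(con))
  read_no <- 0L
  for (i in seq_len(nrow(matrix$counts))) {
    idx <- matrix$metadata$index_sequence[i]
    nz <- which(matrix$counts[i, ] > 0L)
    for (j in nz) {
      bc_id <- colnames(matrix$counts)[j]
      body <- paste0(idx, design$flank_5p, truth$sequences[[bc_id]],
                     design$flank_3p)
      pad <- design$product_length - nchar(body)
      if (pad > 0) body <- paste0(body, strrep("A", pad))
      n <- matrix$counts[i, j]
      for (r in seq_len(n)) {
        read_no <- read_no + 1L
        writeLines(c(paste0("@synthetic_read_", read_no), body, "+",
                     strrep("I", nchar(body))), con)
      }
    }
  }
  invisible(path)
}

#' Write a complete synthetic experiment to disk
#'
#' Produces `library.fasta`, `sample_sheet.tsv`, `counts.tsv` and
#' `truth.json` under `dir` (and `reads.fastq` when `reads = TRUE`).
#'
#' @param truth a [generate_ground_truth()] result.
#' @param dir output directory (created if needed).
#' @param reads also render FASTQ reads (keep depths small).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_experiment <- function(truth, dir, reads = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(library = file.path(dir, "library.fasta"),
             sheet = file.path(dir, "sample_sheet.tsv"),
             counts = file.path(dir, "counts.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(truth$sequences), paths[["library"]])
  bcm <- synthesize_counts(truth)
  write.table(bcm$metadata, paths[["sheet"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  persist_count_matrix(bcm, paths[["counts"]])
  truth_json <- list(engrafted = truth$engrafted, shedders = truth$shedders,
                     seeders = truth$seeders,
                     tissue_truth = lapply(truth$tissue_truth, as.list),
                     config = unclass(truth$cfg))
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  if (reads) {
    paths[["reads"]] <- file.path(dir, "reads.fastq")
    render_reads(bcm, truth, paths[["reads"]])
  }
  invisible(paths)
}
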