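# Amplicon structure, sample sheets, demultiplexing, count-matrix I/O.
#
# The assay is a fixed-structure PCR product:
#   [8-bp sample index][constant 5' flank][98-bp barcode][constant 3' flank]
# Reads are assigned to (replicate, barcode) cells of a count matrix; reads
# failing any stage are tallied as unassigned, never dropped silently.

META_COLS <- c("sample_id", "index_sequence", "mouse_id", "tissue",
               "timepoint", "replicate_id", "run_id", "sorted_cell_count")
TIMEPOINTS <- c("T1", "T2", "T3", "T4")

#' Amplicon design of the barcode PCR product
#'
#' Describes the fixed read structure used for demultiplexing: a sample index,
#' a constant 5' flank (the library PCR primer), the semi-random barcode, and
#' a constant 3' flank. Defaults correspond to a 150-bp product carrying an
#' 8-bp index and a 98-bp barcode.
#'
#' @param index_length integer, bases of sample index at the read start.
#' @param flank_5p constant sequence between index and barcode.
#' @param flank_3p constant sequence following the barcode.
#' @param barcode_length integer, barcode length in bases.
#' @param product_length integer, full amplicon length.
#' @return An object of class `amplicon_design`.
#' @export
amplicon_design <- function(index_length = 8L,
                            flank_5p = "TGCTGCCGTCAACTAGAACA",
                            flank_3p = "TAAGCGCCTGATTCGAGATC",
                            barcode_length = 98L,
                            product_length = 150L) {
  index_length <- as.integer(index_length)
  barcode_length <- as.integer(barcode_length)
  if (index_length < 1L) stop_ct("index_length must be >= 1")
  if (barcode_length < 1L) stop_ct("barcode_length must be >= 1")
  for (fl in c(flank_5p, flank_3p)) {
    if (!nzchar(fl) || grepl("[^ACGT]", fl))
      stop_ct("flanks must be nonempty uppercase DNA over {A,C,G,T}")
  }
  structure(list(index_length = index_length, flank_5p = flank_5p,
                 flank_3p = flank_3p, barcode_length = barcode_length,
                 product_length = as.integer(product_length)),
            class = "amplicon_design")
}

#' Read a barcode reference library
#'
#' Accepts FASTA (parsed with Biostrings) or a two-column TSV
#' (`barcode_id`, `sequence`). Ids and sequences must be unique and all
#' sequences the same length.
#'
#' @param path file path.
#' @return Named character vector of sequences (names are barcode ids),
#'   class `barcode_library`.
#' @export
read_barcode_library <- function(path) {
  if (!file.exists(path)) stop_ct("library file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    ss <- Biostrings::readDNAStringSet(path)
    entries <- stats::setNames(as.character(ss), names(ss))
  } else {
    tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (!all(c("barcode_id", "sequence") %in% names(tab)))
      stop_ct("library TSV needs columns barcode_id, sequence")
    entries <- stats::setNames(toupper(tab$sequence), tab$barcode_id)
  }
  barcode_library(entries)
}

#' Construct and validate a barcode library
#'
#' @param entries named character vector, barcode_id -> sequence.
#' @return Validated `barcode_library`.
#' @export
barcode_library <- function(entries) {
  if (length(entries) == 0L) stop_ct("empty barcode library")
  if (is.null(names(entries)) || anyDuplicated(names(entries)))
    stop_ct("barcode ids must be present and unique")
  if (anyDuplicated(entries)) stop_ct("barcode sequences must be unique")
  if (length(unique(nchar(entries))) != 1L)
    stop_ct("all barcode sequences must have the same length")
  structure(entries, class = "barcode_library")
}

#' Parse a sample sheet
#'
#' The sheet is a TSV with one row per technical replicate and columns
#' `sample_id, index_sequence, mouse_id, tissue, timepoint, replicate_id,
#' run_id, sorted_cell_count` (the last may be empty). `(index_sequence,
#' run_id)` pairs must be unique and timepoints one of T1-T4.
#'
#' @param path TSV file path.
#' @return data.frame of class `sample_sheet`.
#' @export
parse_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_ct("sample sheet not found: ", path)
  tab <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    colClasses = "character")
  sample_sheet(tab)
}

#' Validate a sample-sheet data.frame
#' @param tab data.frame with the sample-sheet columns.
#' @return data.frame of class `sample_sheet`.
#' @export
sample_sheet <- function(tab) {
  if (nrow(tab) == 0L) stop_ct("no samples in sheet")
  missing <- setdiff(setdiff(META_COLS, "sorted_cell_count"), names(tab))
  if (length(missing))
    stop_ct("sample sheet missing columns: ", paste(missing, collapse = ", "))
  if (is.null(tab$sorted_cell_count)) tab$sorted_cell_count <- NA_integer_
  tab$sorted_cell_count <- suppressWarnings(as.integer(tab$sorted_cell_count))
  tab <- tab[, META_COLS]
  bad_tp <- setdiff(unique(tab$timepoint), TIMEPOINTS)
  if (length(bad_tp))
    stop_ct("unknown timepoint token(s): ", paste(bad_tp, collapse = ", "),
            " (expected ", paste(TIMEPOINTS, collapse = "/"), ")")
  key <- paste(tab$index_sequence, tab$run_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(key %in% key[duplicated(key)])
    stop_ct("duplicate (index_sequence, run_id) in sheet rows ",
            paste(dup, collapse = ", "), ": ",
            paste(unique(tab$index_sequence[dup]), collapse = ", "))
  }
  rownames(tab) <- NULL
  class(tab) <- c("sample_sheet", "data.frame")
  tab
}

#' Construct a barcode-count matrix
#'
#' @param counts integer matrix, replicate rows x barcode columns.
#' @param metadata sample-sheet data.frame aligned with rows of `counts`.
#' @param unassigned integer, reads not assigned to any cell.
#' @param unassigned_reasons optional named integer breakdown.
#' @return Object of class `barcode_count_matrix`.
#' @export
barcode_count_matrix <- function(counts, metadata, unassigned = 0L,
                                 unassigned_reasons = integer(0)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("bc%03d", seq_len(ncol(counts)))
  if (nrow(counts) != nrow(metadata))
    stop_ct("counts rows and metadata rows differ")
  if (any(counts < 0L, na.rm = TRUE)) stop_ct("counts must be >= 0")
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (nrow(metadata) == 0L) {
    # an empty matrix is a valid (fully filtered) result
    metadata <- metadata[, intersect(META_COLS, names(metadata)),
                         drop = FALSE]
    class(metadata) <- c("sample_sheet", "data.frame")
  } else {
    metadata <- sample_sheet(metadata)
  }
  rownames(counts) <- paste(metadata$sample_id, metadata$replicate_id,
                            sep = ".")
  structure(list(counts = counts, metadata = metadata,
                 unassigned = as.integer(unassigned),
                 unassigned_reasons = unassigned_reasons),
            class = "barcode_count_matrix")
}

#' @export
print.barcode_count_matrix <- function(x, ...) {
  cat(sprintf(
    "<barcode_count_matrix> %d replicate rows (%d samples) x %d barcodes; %s assigned reads, %d unassigned\n",
    nrow(x$counts), length(unique(x$metadata$sample_id)), ncol(x$counts),
    format(sum(as.numeric(x$counts)), big.mark = ","), x$unassigned))
  invisible(x)
}

# ---- FASTQ demultiplexing ---------------------------------------------------

read_fastq_sequences <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) return(character(0))
  if (length(lines) %% 4L != 0L)
    stop_ct("malformed FASTQ: truncated record ", length(lines) %/% 4L + 1L)
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop_ct("malformed FASTQ record ", bad[1L],
            ": expected '@' header and '+' separator")
  toupper(lines[seq(2L, length(lines), by = 4L)])
}

hamming_to_set <- function(query, set_mat) {
  # set_mat: n x L character matrix of candidate sequences
  q <- strsplit(query, "", fixed = TRUE)[[1L]]
  rowSums(set_mat != matrix(q, nrow(set_mat), length(q), byrow = TRUE))
}

#' Demultiplex amplicon reads into a barcode-count matrix
#'
#' Each read is matched in three stages: exact sample-index lookup (optional
#' single-mismatch rescue), exact 5'-flank anchoring, then barcode lookup in
#' the reference library (exact first, else unique Hamming neighbor within
#' `max_mismatch`; distance ties are rejected as ambiguous). Reads failing
#' any stage are counted as unassigned, so assigned + unassigned always
#' equals the input read count.
#'
#' @param reads path to a FASTQ file (4-line records).
#' @param design an [amplicon_design()].
#' @param sheet a [sample_sheet()]; restricted to `run_id` if given.
#' @param library a [barcode_library()].
#' @param max_mismatch maximum Hamming distance for the library match.
#' @param run_id run to demultiplex; defaults to the sheet's single run.
#' @param index_rescue allow a unique 1-mismatch index match.
#' @param search_revcomp also try the reverse complement of failing reads.
#' @return A [barcode_count_matrix()] with one row per sheet replicate.
#' @export
demultiplex_and_count <- function(reads, design, sheet, library,
                                  max_mismatch = 2L, run_id = NULL,
                                  index_rescue = FALSE,
                                  search_revcomp = FALSE) {
  stopifnot(inherits(design, "amplicon_design"))
  if (length(library) == 0L) stop_ct("empty barcode library")
  if (max_mismatch < 0L) stop_ct("max_mismatch must be >= 0")
  if (is.null(run_id)) {
    runs <- unique(sheet$run_id)
    if (length(runs) != 1L)
      stop_ct("sheet covers runs ", paste(runs, collapse = ", "),
              "; supply run_id")
    run_id <- runs
  }
  sheet <- sheet[sheet$run_id == run_id, , drop = FALSE]
  if (nrow(sheet) == 0L) stop_ct("no sheet rows for run ", run_id)

  seqs <- if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    read_fastq_sequences(reads) else as.character(reads)

  il <- design$index_length
  fl <- nchar(design$flank_5p)
  bl <- design$barcode_length
  need <- il + fl + bl

  counts <- matrix(0L, nrow(sheet), length(library),
                   dimnames = list(NULL, names(library)))
  reasons <- c(too_short = 0L, no_index = 0L, flank_mismatch = 0L,
               no_barcode_match = 0L, ambiguous_barcode = 0L)
  if (length(seqs)) {
    lib_mat <- NULL
    idx_mat <- NULL
    assign_one <- function(s) {
      # returns c(row, col) or a reason name
      if (nchar(s) < need) return("too_short")
      row <- match(substr(s, 1L, il), sheet$index_sequence)
      if (is.na(row) && index_rescue) {
        if (is.null(idx_mat))
          idx_mat <<- do.call(rbind, strsplit(sheet$index_sequence, ""))
        dd <- hamming_to_set(substr(s, 1L, il), idx_mat)
        hit <- which(dd <= 1L)
        if (length(hit) == 1L) row <- hit
      }
      if (is.na(row)) return("no_index")
      if (substr(s, il + 1L, il + fl) != design$flank_5p)
        return("flank_mismatch")
      bc <- substr(s, il + fl + 1L, il + fl + bl)
      col <- match(bc, library)
      if (is.na(col) && max_mismatch > 0L) {
        if (is.null(lib_mat))
          lib_mat <<- do.call(rbind, strsplit(unname(library), ""))
        dd <- hamming_to_set(bc, lib_mat)
        dmin <- min(dd)
        if (dmin <= max_mismatch) {
          hit <- which(dd == dmin)
          if (length(hit) > 1L) return("ambiguous_barcode")
          col <- hit
        }
      }
      if (is.na(col)) return("no_barcode_match")
      c(row, col)
    }
    for (s in seqs) {
      res <- assign_one(s)
      if (is.character(res) && search_revcomp) {
        res2 <- assign_one(revcomp(s))
        if (!is.character(res2)) res <- res2
      }
      if (is.character(res)) {
        reasons[res] <- reasons[res] + 1L
      } else {
        counts[res[1L], res[2L]] <- counts[res[1L], res[2L]] + 1L
      }
    }
  }
  bcm <- barcode_count_matrix(counts, sheet, unassigned = sum(reasons),
                              unassigned_reasons = reasons)
  stopifnot(sum(as.numeric(bcm$counts)) + bcm$unassigned == length(seqs))
  bcm
}

# ---- persistence ------------------------------------------------------------

#' Write a barcode-count matrix to TSV
#'
#' Metadata columns come first, then one column per barcode with explicit
#' zeros, so that [read_count_matrix()] round-trips the object bit-exactly.
#' The unassigned tally is kept in a `#` header line.
#'
#' @param matrix a [barcode_count_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
persist_count_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "barcode_count_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# clonetrace count matrix v1",
               paste0("# unassigned: ", matrix$unassigned)), con)
  df <- cbind(matrix$metadata,
              as.data.frame(matrix$counts, check.names = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode-count matrix written by [persist_count_matrix()]
#' @param path TSV path.
#' @return A [barcode_count_matrix()].
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop_ct("count matrix not found: ", path)
  head_lines <- readLines(path, n = 5L)
  unassigned <- 0L
  ua <- grep("^# unassigned:", head_lines, value = TRUE)
  if (length(ua)) unassigned <- as.integer(sub("^# unassigned:\\s*", "", ua[1L]))
  tab <- read.delim(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(setdiff(META_COLS, "sorted_cell_count"), names(tab))
  if (length(missing))
    stop_ct("count matrix file missing metadata columns: ",
            paste(missing, collapse = ", "))
  meta_cols <- intersect(META_COLS, names(tab))
  meta <- tab[, meta_cols, drop = FALSE]
  for (col in setdiff(meta_cols, "sorted_cell_count"))
    meta[[col]] <- as.character(meta[[col]])
  bc_cols <- setdiff(names(tab), meta_cols)
  counts <- as.matrix(tab[, bc_cols, drop = FALSE])
  if (is.null(dim(counts))) counts <- matrix(counts, nrow(tab))
  colnames(counts) <- bc_cols
  barcode_count_matrix(counts, meta, unassigned = unassigned)
}
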