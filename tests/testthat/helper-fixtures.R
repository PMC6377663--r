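# Shared fixture builders. Everything is generated in code; no stored data.

meta_row <- function(sample_id, replicate_id, index, run_id = "R1",
                     tissue = "tumor", timepoint = "T2", mouse_id = "m1",
                     sorted_cell_count = NA_integer_) {
  data.frame(sample_id = sample_id, index_sequence = index,
             mouse_id = mouse_id, tissue = tissue, timepoint = timepoint,
             replicate_id = replicate_id, run_id = run_id,
             sorted_cell_count = sorted_cell_count,
             stringsAsFactors = FALSE)
}

# count matrix from a numeric matrix and parallel replicate descriptors
make_bcm <- function(counts, sample_ids, replicate_ids = NULL,
                     run_ids = "R1", tissues = "tumor") {
  n <- nrow(counts)
  if (is.null(replicate_ids))
    replicate_ids <- paste0("rep", stats::ave(seq_len(n), sample_ids,
                                              FUN = seq_along))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("bc%03d", seq_len(ncol(counts)))
  meta <- do.call(rbind, lapply(seq_len(n), function(i)
    meta_row(sample_ids[i], replicate_ids[i],
             index = paste0(strrep("A", 6), c("A","C","G","T")[(i - 1) %% 4 + 1],
                            c("A","C","G","T")[((i - 1) %/% 4) %% 4 + 1]),
             run_id = rep_len(run_ids, n)[i],
             tissue = rep_len(tissues, n)[i])))
  barcode_count_matrix(counts, meta)
}

make_profile <- function(freqs, sample_id = "s1") {
  if (is.null(names(freqs))) names(freqs) <- sprintf("bc%03d", seq_along(freqs))
  clonal_profile(sample_id, freqs / sum(freqs))
}

random_profile <- function(n_clones, sample_id = "s1", sdlog = 1.5) {
  w <- stats::rlnorm(n_clones, 0, sdlog)
  make_profile(stats::setNames(w, sprintf("bc%03d", seq_len(n_clones))),
               sample_id)
}

# tiny demultiplexing world: 4-barcode library, 2 samples x 2 replicates
demux_world <- function() {
  lib <- barcode_library(stats::setNames(
    vapply(1:4, function(i) {
      set.seed(100 + i)
      paste(sample(c("A", "C", "G", "T"), 98, replace = TRUE), collapse = "")
    }, character(1)),
    paste0("B", 1:4)))
  sheet <- sample_sheet(rbind(
    meta_row("S1", "rep1", "ACGTACGT"), meta_row("S1", "rep2", "TTTTCCCC"),
    meta_row("S2", "rep1", "GGGGAAAA"), meta_row("S2", "rep2", "CACACACA")))
  design <- amplicon_design()
  list(lib = lib, sheet = sheet, design = design)
}

make_read <- function(index, barcode_seq, design = amplicon_design()) {
  body <- paste0(index, design$flank_5p, barcode_seq, design$flank_3p)
  pad <- design$product_length - nchar(body)
  if (pad > 0) body <- paste0(body, strrep("A", pad))
  body
}

write_fastq <- function(seqs, path = tempfile(fileext = ".fastq")) {
  if (length(seqs) == 0) {
    file.create(path)
    return(path)
  }
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

# substitute n bases of a sequence at fixed positions
mutate_seq <- function(s, positions) {
  ch <- strsplit(s, "")[[1]]
  for (p in positions) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}
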