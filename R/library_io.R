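#' Read an sgRNA library index
#'
#' Loads the guide library from a tab-separated file with columns
#' `guide_id`, `gene`, `spacer` and optionally `is_control`
#' (logical/0-1). Control guides that carry no `gene` entry are assigned the
#' reserved pseudo-gene label `"CTRL"` so they can be excluded as a block
#' from gene-level aggregation.
#'
#' @param path path to a TSV file (header required).
#' @param control_label pseudo-gene label shared by all control guides.
#' @return A data.frame of class `library_index` with columns `guide_id`,
#'   `gene`, `spacer`, `is_control`.
#' @details Validation enforces the library invariants: unique guide ids,
#'   unique spacer sequences (a duplicated spacer would make read assignment
#'   ambiguous, so it is rejected at load time), a single spacer length over
#'   the alphabet A/C/G/T, and a non-empty gene for every targeting guide.
#' @export
load_library <- function(path, control_label = "CTRL") {
  if (!file.exists(path)) stop("library index not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("guide_id", "gene", "spacer")
  if (!all(need %in% names(df)))
    stop("library index must have columns guide_id, gene, spacer; got: ",
         paste(names(df), collapse = ", "))
  is_control <- if ("is_control" %in% names(df)) {
    v <- tolower(trimws(df$is_control))
    v %in% c("1", "true", "t", "yes")
  } else rep(FALSE, nrow(df))
  validate_library(data.frame(
    guide_id = trimws(df$guide_id),
    gene = trimws(df$gene),
    spacer = toupper(trimws(df$spacer)),
    is_control = is_control,
    stringsAsFactors = FALSE
  ), control_label = control_label, path = path)
}

# Shared validator used by load_library() and simulate_screen().
validate_library <- function(df, control_label = "CTRL", path = "<library>") {
  bad <- which(df$guide_id == "" | is.na(df$guide_id))
  if (length(bad))
    stop("malformed row in ", path, ": empty guide_id at line ", bad[1] + 1L)
  dup <- df$guide_id[duplicated(df$guide_id)]
  if (length(dup))
    stop("duplicate guide_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  if (any(!grepl("^[ACGT]+$", df$spacer))) {
    i <- which(!grepl("^[ACGT]+$", df$spacer))[1]
    stop("spacer with characters outside {A,C,G,T} at line ", i + 1L,
         " (guide ", df$guide_id[i], ")")
  }
  if (length(unique(nchar(df$spacer))) != 1L)
    stop("mixed spacer lengths in ", path, ": ",
         paste(sort(unique(nchar(df$spacer))), collapse = ", "))
  dsp <- df$spacer[duplicated(df$spacer)]
  if (length(dsp))
    stop("duplicate spacer sequences (ambiguous at count time): ",
         paste(unique(dsp), collapse = ", "))
  df$gene[df$is_control] <- control_label
  if (any(!df$is_control & (df$gene == "" | is.na(df$gene)))) {
    i <- which(!df$is_control & (df$gene == "" | is.na(df$gene)))[1]
    stop("non-control guide without gene at line ", i + 1L)
  }
  attr(df, "control_label") <- control_label
  class(df) <- c("library_index", "data.frame")
  df
}

#' @export
print.library_index <- function(x, ...) {
  cat("sgRNA library index: ", nrow(x), " guides (",
      sum(x$is_control), " controls), ",
      length(unique(x$gene[!x$is_control])), " genes, spacer length ",
      nchar(x$spacer[1]), "\n", sep = "")
  invisible(x)
}

#' Count sgRNA spacers in sequencing reads
#'
#' Extracts guide spacer sequences from reads and tallies them against the
#' library index. In `"substring"` mode (default) every read is scanned for
#' any library spacer and the left-most match wins; in `"exact"` mode the
#' fixed-length window starting at `offset` must equal a spacer. Matching is
#' exact string equality, on the given strand only, and each read increments
#' at most one guide.
#'
#' @param reads FASTQ path (plain or gzipped), or a character vector of read
#'   sequences.
#' @param index a `library_index`.
#' @param mode `"substring"` or `"exact"`.
#' @param offset 1-based spacer start for `"exact"` mode.
#' @param revcomp also search the reverse complement of each read
#'   (default `FALSE`; amplicon orientation is normally fixed by the PCR
#'   design).
#' @return list with `counts` (named integer vector over all guide ids) and
#'   `report` (list: `total_reads`, `matched_reads`, `unmatched_reads`).
#' @export
count_reads <- function(reads, index, mode = c("substring", "exact"),
                        offset = 1L, revcomp = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(index, "library_index"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    seqs <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  } else {
    seqs <- toupper(as.character(reads))
  }
  L <- nchar(index$spacer[1])
  counts <- setNames(integer(nrow(index)), index$guide_id)
  n <- length(seqs)
  if (n == 0L) {
    warning("no reads supplied; returning all-zero counts")
    return(list(counts = counts,
                report = list(total_reads = 0L, matched_reads = 0L,
                              unmatched_reads = 0L)))
  }
  spacer_to_guide <- setNames(index$guide_id, index$spacer)
  assign_one <- function(ss) {
    # ss: character vector of candidate L-mers in left-to-right order
    hit <- match(ss, names(spacer_to_guide))
    j <- which(!is.na(hit))
    if (length(j)) spacer_to_guide[[hit[j[1]]]] else NA_character_
  }
  assigned <- character(n)
  if (mode == "exact") {
    window <- substr(seqs, offset, offset + L - 1L)
    g <- spacer_to_guide[window]
    assigned <- ifelse(nchar(window) == L, unname(g), NA_character_)
    if (revcomp) {
      miss <- which(is.na(assigned))
      if (length(miss)) {
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[miss])))
        w2 <- substr(rc, offset, offset + L - 1L)
        assigned[miss] <- ifelse(nchar(w2) == L,
                                 unname(spacer_to_guide[w2]), NA_character_)
      }
    }
  } else {
    scan_seqs <- seqs
    for (i in seq_len(n)) {
      s <- scan_seqs[i]
      nk <- nchar(s) - L + 1L
      a <- NA_character_
      if (nk >= 1L) {
        kmers <- substring(s, seq_len(nk), seq_len(nk) + L - 1L)
        a <- assign_one(kmers)
      }
      if (is.na(a) && revcomp) {
        rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
        nk <- nchar(rc) - L + 1L
        if (nk >= 1L) {
          kmers <- substring(rc, seq_len(nk), seq_len(nk) + L - 1L)
          a <- assign_one(kmers)
        }
      }
      assigned[i] <- a
    }
  }
  tab <- table(factor(assigned[!is.na(assigned)], levels = index$guide_id))
  counts[] <- as.integer(tab)
  matched <- sum(counts)
  list(counts = counts,
       report = list(total_reads = n, matched_reads = matched,
                     unmatched_reads = n - matched))
}

#' Merge per-sample count columns into a screen count matrix
#'
#' @param columns named list of integer count vectors (names = sample ids);
#'   each vector is named by guide id. Guides absent from a column get 0.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `replicate`; column order of the result follows this metadata.
#' @param index a `library_index`; its guide ids define the row universe.
#' @return A list of class `screen_counts` with elements `counts`
#'   (guides x samples integer matrix), `samples`, `index`.
#' @export
merge_counts <- function(columns, samples, index) {
  stopifnot(inherits(index, "library_index"))
  if (anyDuplicated(samples$sample_id))
    stop("sample_id collision: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (!all(samples$sample_id %in% names(columns)))
    stop("missing count column for sample(s): ",
         paste(setdiff(samples$sample_id, names(columns)), collapse = ", "))
  m <- matrix(0L, nrow(index), nrow(samples),
              dimnames = list(index$guide_id, samples$sample_id))
  for (sid in samples$sample_id) {
    col <- columns[[sid]]
    extra <- setdiff(names(col), index$guide_id)
    if (length(extra))
      stop("column ", sid, " has guides not in the library: ",
           paste(head(extra, 3), collapse = ", "))
    if (any(col < 0) || any(col != round(col)))
      stop("column ", sid, " has negative or non-integer counts")
    m[names(col), sid] <- as.integer(col)
  }
  screen_counts(m, samples, index)
}

#' Construct a screen count container
#'
#' @param counts guides x samples non-negative integer matrix with dimnames.
#' @param samples sample metadata (`sample_id`, `condition`, `replicate`).
#' @param index a `library_index` covering all row ids.
#' @return object of class `screen_counts`.
#' @export
screen_counts <- function(counts, samples, index) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!all(rownames(counts) %in% index$guide_id))
    stop("count rows not in library index")
  if (!identical(colnames(counts), as.character(samples$sample_id)))
    stop("count columns must match samples$sample_id in order")
  structure(list(counts = counts, samples = as.data.frame(samples),
                 index = index),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat("screen_counts: ", nrow(x$counts), " guides x ", ncol(x$counts),
      " samples\n", sep = "")
  tab <- table(x$samples$condition)
  cat("conditions:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' The TSV carries `guide_id`, `gene`, then one column per sample; sample
#' metadata (condition, replicate) travels in `#`-prefixed header lines so a
#' round trip is lossless.
#' @param x a `screen_counts`.
#' @param path output TSV path.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "screen_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# condition: ",
                    paste(x$samples$sample_id, x$samples$condition, sep = "=",
                          collapse = ",")), con)
  writeLines(paste0("# replicate: ",
                    paste(x$samples$sample_id, x$samples$replicate, sep = "=",
                          collapse = ",")), con)
  df <- data.frame(guide_id = rownames(x$counts),
                   gene = x$index$gene[match(rownames(x$counts), x$index$guide_id)],
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_counts
#' @param index a `library_index` matching the stored guides.
#' @export
read_counts <- function(path, index) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  parse_map <- function(tag) {
    ln <- sub(paste0("^# ", tag, ": "), "", grep(paste0("^# ", tag), hdr, value = TRUE))
    kv <- strsplit(strsplit(ln, ",")[[1]], "=")
    setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  }
  cond <- parse_map("condition")
  repl <- parse_map("replicate")
  df <- utils::read.delim(text = lines[!grepl("^#", lines)], check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("guide_id", "gene")), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$guide_id
  samples <- data.frame(sample_id = colnames(m),
                        condition = unname(cond[colnames(m)]),
                        replicate = as.integer(repl[colnames(m)]),
                        stringsAsFactors = FALSE)
  screen_counts(m, samples, index)
}
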