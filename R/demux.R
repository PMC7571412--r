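#' Barcode library
#'
#' A barcode library maps strain barcode IDs to their DNA tag sequences.
#' Tags are equal-length (20 bp by design) and are constructed to differ
#' from one another by at least six substitutions, so that a single
#' sequencing error can never convert one library barcode into another
#' under the exact-match demultiplexing rule.
#'
#' @param barcode_id character vector of unique IDs
#' @param sequence character vector of uppercase DNA sequences, one per ID
#' @return data.frame of class `bse_library` with columns barcode_id,
#'   sequence
#' @export
barcode_library <- function(barcode_id, sequence) {
  barcode_id <- as.character(barcode_id)
  sequence <- toupper(as.character(sequence))
  if (length(barcode_id) != length(sequence))
    stop("barcode_id and sequence lengths differ")
  if (anyDuplicated(barcode_id))
    stop("duplicate barcode IDs: ",
         paste(unique(barcode_id[duplicated(barcode_id)]), collapse = ", "))
  lens <- nchar(sequence)
  if (length(unique(lens)) > 1L)
    stop("barcode sequences must all have the same length")
  if (any(grepl("[^ACGTN]", sequence)))
    stop("barcode sequences must use alphabet A/C/G/T/N")
  structure(data.frame(barcode_id = barcode_id, sequence = sequence,
                       stringsAsFactors = FALSE),
            class = c("bse_library", "data.frame"))
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character scalars of equal length
#' @return integer substitution count
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("strings must have equal length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Validate a barcode library's pairwise separation
#'
#' Computes all pairwise Hamming distances and reports any pair closer
#' than the separation threshold. A library passes when its minimum
#' pairwise distance is at least `min_distance` (default 6 substitutions).
#'
#' @param library a [barcode_library()]
#' @param min_distance required minimum pairwise Hamming distance
#' @return list with `min_distance` observed, `violations` (data.frame of
#'   offending pairs with their distance), and `pass`
#' @export
validate_library <- function(library, min_distance = 6) {
  if (!nrow(library)) stop("library is empty")
  n <- nrow(library)
  if (n == 1L)
    return(list(min_distance = NA_integer_,
                violations = data.frame(barcode_1 = character(),
                                        barcode_2 = character(),
                                        distance = integer()),
                pass = TRUE))
  # n is at most a few hundred; compare split sequences pairwise
  chars <- strsplit(library$sequence, "")
  pairs <- utils::combn(n, 2)
  d <- apply(pairs, 2, function(ij) sum(chars[[ij[1]]] != chars[[ij[2]]]))
  bad <- which(d < min_distance)
  violations <- data.frame(
    barcode_1 = library$barcode_id[pairs[1, bad]],
    barcode_2 = library$barcode_id[pairs[2, bad]],
    distance = d[bad],
    stringsAsFactors = FALSE)
  list(min_distance = min(d), violations = violations,
       pass = length(bad) == 0L)
}

#' Amplicon read layout
#'
#' Describes how a single-end barcode-sequencing read is laid out:
#' a forward sample index (variable length), a constant forward spacer,
#' the 20-bp strain barcode, a constant reverse spacer, and a reverse
#' sample index (variable length). The default spacers are a synthetic
#' template (the amplicon's true primer-derived constant regions are a
#' property of the primer design, not of the analysis); the simulator's
#' FASTQ emitter and the demultiplexer share whatever layout is supplied,
#' so end-to-end tests are exact.
#'
#' @param forward_spacer constant sequence between forward index and barcode
#' @param reverse_spacer constant sequence between barcode and reverse index
#' @param index_length_range integer pair, allowed index lengths (default 9-12)
#' @param barcode_length barcode length in bp (default 20)
#' @param reverse_index_orientation how the reverse index appears in the
#'   read: "as-is" or "reverse-complement" of the sheet's reverse index
#' @return list of class `bse_layout`
#' @export
read_layout <- function(forward_spacer = "TTGACA",
                        reverse_spacer = "GTCAAT",
                        index_length_range = c(9L, 12L),
                        barcode_length = 20L,
                        reverse_index_orientation = c("as-is",
                                                      "reverse-complement")) {
  reverse_index_orientation <- match.arg(reverse_index_orientation)
  stopifnot(barcode_length > 0,
            length(index_length_range) == 2L,
            index_length_range[1] <= index_length_range[2])
  structure(list(forward_spacer = toupper(forward_spacer),
                 reverse_spacer = toupper(reverse_spacer),
                 index_length_range = as.integer(index_length_range),
                 barcode_length = as.integer(barcode_length),
                 reverse_index_orientation = reverse_index_orientation),
            class = "bse_layout")
}

#' Reverse-complement a DNA string vector
#' @param x character vector of DNA sequences
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Validate a sample sheet against a library and layout
#'
#' Checks that (fwd_index, rev_index) pairs are unique, that every
#' expected barcode ID exists in the library, that index lengths fall in
#' the layout's allowed range, and that no index within the sheet is a
#' strict prefix of another (which would make longest-prefix matching
#' ambiguous for the forward index and position-anchored matching
#' ambiguous for the reverse index).
#'
#' @param sheet sample sheet data.frame (see [read_sample_sheet()])
#' @param library a [barcode_library()]
#' @param layout a [read_layout()]
#' @return the sheet, invisibly, on success; otherwise an error
#' @export
validate_sample_sheet <- function(sheet, library, layout = read_layout()) {
  key <- paste(sheet$fwd_index, sheet$rev_index)
  if (anyDuplicated(key))
    stop("duplicate index pairs in sample sheet: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  unknown <- setdiff(unlist(sheet$expected_barcodes), library$barcode_id)
  if (length(unknown))
    stop("expected barcodes absent from library: ",
         paste(unknown, collapse = ", "))
  rng <- layout$index_length_range
  for (col in c("fwd_index", "rev_index")) {
    idx <- unique(sheet[[col]])
    ln <- nchar(idx)
    if (any(ln < rng[1] | ln > rng[2]))
      stop(col, " lengths outside allowed range ",
           rng[1], "-", rng[2])
    if (.has_prefix_ambiguity(idx))
      stop("ambiguous ", col,
           " set: one index is a strict prefix of another")
  }
  invisible(sheet)
}

.has_prefix_ambiguity <- function(indices) {
  indices <- unique(indices)
  if (length(indices) < 2L) return(FALSE)
  for (i in seq_along(indices)) {
    others <- indices[-i]
    if (any(startsWith(others, indices[i]) &
            nchar(others) > nchar(indices[i])))
      return(TRUE)
  }
  FALSE
}

#' Assign one read to a (sample index pair, barcode) cell
#'
#' Exact-match assignment: the forward index must match a known index as
#' the read's prefix (longest known index wins), the barcode must match a
#' library sequence exactly at the position implied by the forward index
#' plus forward spacer, and the reverse index must match a known index
#' exactly after the reverse spacer (orientation per the layout). The
#' first failing element determines the discard reason, checked in the
#' order forward index, barcode, reverse index.
#'
#' @param sequence read sequence (character scalar, uppercase DNA)
#' @param layout a [read_layout()]
#' @param fwd_indices,rev_indices character vectors of known indices
#'   (as written in the sample sheet)
#' @param library a [barcode_library()]
#' @param max_barcode_mismatch optional Hamming tolerance for the barcode
#'   (default 0 = perfect match; at most 2 is meaningful given the
#'   library's 6-substitution separation)
#' @return list with `fwd_index`, `rev_index`, `barcode_id` on success, or
#'   list with `reason` in {"no-forward-index","no-barcode",
#'   "no-reverse-index"}
#' @export
match_read <- function(sequence, layout, fwd_indices, rev_indices, library,
                       max_barcode_mismatch = 0L) {
  res <- .match_reads_vec(sequence, layout, fwd_indices, rev_indices,
                          library, max_barcode_mismatch)
  if (is.na(res$reason[1]))
    list(fwd_index = res$fwd[1], rev_index = res$rev[1],
         barcode_id = res$barcode_id[1])
  else
    list(reason = res$reason[1])
}

# Vectorized matcher shared by match_read and demultiplex.
# Returns list(fwd, rev, barcode_id, reason) with NA reason on success.
.match_reads_vec <- function(seqs, layout, fwd_indices, rev_indices,
                             library, max_barcode_mismatch = 0L) {
  n <- length(seqs)
  fwd <- rep(NA_character_, n)
  rev_ix <- rep(NA_character_, n)
  bc <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  fwd_indices <- unique(fwd_indices)
  rev_target <- unique(rev_indices)
  if (layout$reverse_index_orientation == "reverse-complement")
    rev_target <- stats::setNames(reverse_complement(rev_target), rev_target)
  else
    rev_target <- stats::setNames(rev_target, rev_target)

  # forward index: longest known prefix wins
  for (L in sort(unique(nchar(fwd_indices)), decreasing = TRUE)) {
    cand <- fwd_indices[nchar(fwd_indices) == L]
    todo <- is.na(fwd)
    if (!any(todo)) break
    hit <- todo & substr(seqs, 1L, L) %in% cand
    fwd[hit] <- substr(seqs[hit], 1L, L)
  }
  reason[is.na(fwd)] <- "no-forward-index"

  # barcode at the position implied by the forward index + spacer
  ok <- is.na(reason)
  if (any(ok)) {
    start <- nchar(fwd[ok]) + nchar(layout$forward_spacer) + 1L
    stop_ <- start + layout$barcode_length - 1L
    observed <- substr(seqs[ok], start, stop_)
    spacer_ok <- substr(seqs[ok], nchar(fwd[ok]) + 1L, start - 1L) ==
      layout$forward_spacer
    hit <- match(observed, library$sequence)
    if (max_barcode_mismatch > 0L) {
      miss <- which(is.na(hit))
      for (k in miss) {
        d <- vapply(library$sequence, function(s)
          sum(strsplit(observed[k], "")[[1]] != strsplit(s, "")[[1]]),
          integer(1))
        if (min(d) <= max_barcode_mismatch) hit[k] <- which.min(d)
      }
    }
    good <- spacer_ok & !is.na(hit)
    bc[ok][good] <- library$barcode_id[hit[good]]
    reason[ok][!good] <- "no-barcode"
  }

  # reverse index after the reverse spacer
  ok <- is.na(reason)
  if (any(ok)) {
    bstart <- nchar(fwd[ok]) + nchar(layout$forward_spacer) + 1L
    rstart <- bstart + layout$barcode_length + nchar(layout$reverse_spacer)
    spacer_ok <- substr(seqs[ok], bstart + layout$barcode_length,
                        rstart - 1L) == layout$reverse_spacer
    found <- rep(NA_character_, sum(ok))
    for (L in sort(unique(nchar(rev_target)), decreasing = TRUE)) {
      cand <- rev_target[nchar(rev_target) == L]
      todo <- is.na(found)
      if (!any(todo)) break
      obs <- substr(seqs[ok][todo], rstart[todo], rstart[todo] + L - 1L)
      m <- match(obs, cand)
      found[todo][!is.na(m)] <- names(cand)[m[!is.na(m)]]
    }
    good <- spacer_ok & !is.na(found)
    rev_ix[ok][good] <- found[good]
    reason[ok][!good] <- "no-reverse-index"
  }

  list(fwd = fwd, rev = rev_ix, barcode_id = bc, reason = reason)
}

#' Demultiplex a FASTQ file into a count matrix
#'
#' Streams 4-line FASTQ records (plain or gzip) in chunks, assigns each
#' read by exact matching of forward index, barcode, and reverse index
#' (see [match_read()]), and accumulates a sample x barcode count matrix.
#' Reads whose index pair is valid but absent from the sample sheet are
#' tallied under "index-pair-unlisted" and excluded from the matrix, so
#' retained reads plus the discard tally always equal the raw read count.
#'
#' @param fastq path to a FASTQ file (".gz" handled transparently)
#' @param sheet validated sample sheet
#' @param layout a [read_layout()]
#' @param library a [barcode_library()]
#' @param max_barcode_mismatch barcode Hamming tolerance (default 0)
#' @param chunk_size reads per streaming chunk
#' @return list with `counts` (integer matrix, all sheet samples x all
#'   library barcodes) and `summary` (raw_reads, retained_reads,
#'   retained_fraction, discard_tally)
#' @export
demultiplex <- function(fastq, sheet, layout = read_layout(),
                        library, max_barcode_mismatch = 0L,
                        chunk_size = 100000L) {
  validate_sample_sheet(sheet, library, layout)
  counts <- matrix(0L, nrow = nrow(sheet), ncol = nrow(library),
                   dimnames = list(sheet$sample_id, library$barcode_id))
  tally <- c("no-forward-index" = 0L, "no-barcode" = 0L,
             "no-reverse-index" = 0L, "index-pair-unlisted" = 0L)
  raw <- 0L
  pair_key <- paste(sheet$fwd_index, sheet$rev_index)

  con <- if (grepl("\\.gz$", fastq)) gzfile(fastq, "r") else file(fastq, "r")
  on.exit(close(con))
  repeat {
    lines <- readLines(con, n = 4L * chunk_size)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L)
      stop("truncated FASTQ record at read ",
           raw + length(lines) %/% 4L + 1L)
    heads <- lines[seq(1L, length(lines), by = 4L)]
    seps <- lines[seq(3L, length(lines), by = 4L)]
    badh <- which(!startsWith(heads, "@"))
    if (length(badh))
      stop("malformed FASTQ header at read ", raw + badh[1L])
    bads <- which(!startsWith(seps, "+"))
    if (length(bads))
      stop("malformed FASTQ separator at read ", raw + bads[1L])
    seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
    raw <- raw + length(seqs)

    res <- .match_reads_vec(seqs, layout, sheet$fwd_index, sheet$rev_index,
                            library, max_barcode_mismatch)
    failed <- !is.na(res$reason)
    if (any(failed)) {
      t0 <- table(res$reason[failed])
      tally[names(t0)] <- tally[names(t0)] + as.integer(t0)
    }
    okk <- !failed
    if (any(okk)) {
      srow <- match(paste(res$fwd[okk], res$rev[okk]), pair_key)
      unlisted <- is.na(srow)
      tally["index-pair-unlisted"] <-
        tally["index-pair-unlisted"] + sum(unlisted)
      if (any(!unlisted)) {
        bcol <- match(res$barcode_id[okk][!unlisted], library$barcode_id)
        inc <- table(factor(srow[!unlisted], levels = seq_len(nrow(sheet))),
                     factor(bcol, levels = seq_len(nrow(library))))
        counts <- counts + as.vector(inc)
        storage.mode(counts) <- "integer"
      }
    }
  }
  retained <- sum(counts)
  list(counts = counts,
       summary = retention_summary(raw, retained, tally))
}

#' Read-retention summary
#'
#' @param raw_reads raw read count entering demultiplexing
#' @param retained_reads reads that matched all three elements and a
#'   listed sample
#' @param discard_tally named integer vector of discard reasons
#' @return list with raw_reads, retained_reads, retained_fraction,
#'   retained_percent (1 decimal place, as conventionally reported),
#'   discard_tally
#' @export
retention_summary <- function(raw_reads, retained_reads,
                              discard_tally = integer(0)) {
  if (raw_reads < 0 || retained_reads < 0)
    stop("read counts must be non-negative")
  if (length(discard_tally) &&
      retained_reads + sum(discard_tally) != raw_reads)
    stop("retained reads + discards must equal raw reads")
  frac <- if (raw_reads > 0) retained_reads / raw_reads else NA_real_
  list(raw_reads = raw_reads,
       retained_reads = retained_reads,
       retained_fraction = frac,
       retained_percent = if (is.na(frac)) NA_real_ else
         round(100 * frac, 1),
       discard_tally = discard_tally)
}
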