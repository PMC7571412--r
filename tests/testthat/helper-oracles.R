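# Independent brute-force oracles the tests compare the implementation
# against. Deliberately naive: plain loops over the definitions.

oracle_hamming_scan <- function(sequences) {
  n <- length(sequences)
  dmin <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(sequences[i], "")[[1]]
    b <- strsplit(sequences[j], "")[[1]]
    dmin <- min(dmin, sum(a != b))
  }
  dmin
}

oracle_contamination <- function(counts, expected, library) {
  contaminants <- setdiff(library, expected)
  acc <- 0
  for (id in contaminants) acc <- acc + counts[[id]]
  tot <- 0
  for (id in library) tot <- tot + counts[[id]]
  (acc / length(contaminants)) / tot
}

# Straight-loop evaluation of the seven trajectory metrics + fixation.
oracle_trajectory <- function(g, p) {
  keep <- !is.na(p); g <- g[keep]; p <- p[keep]
  n <- length(p)
  best_dev <- -1; t_max <- NA
  for (i in 1:n) {
    d <- abs(p[i] - p[1])
    if (d > best_dev) { best_dev <- d; t_max <- g[i] }
  }
  best_rate <- -1; t_rate <- NA
  for (i in 2:n) {
    r <- abs(p[i] - p[i - 1]) / (g[i] - g[i - 1])
    if (r > best_rate) { best_rate <- r; t_rate <- g[i] }
  }
  best_diff <- -1; t_diff <- NA
  for (i in 1:n) {
    d <- abs(p[i] - (1 - p[i]))
    if (d > best_diff) { best_diff <- d; t_diff <- g[i] }
  }
  total <- 0
  for (i in 2:n) total <- total + abs(p[i] - p[i - 1])
  fixed <- FALSE; fix_gen <- NA
  for (i in 1:n) {
    if (all(pmax(p[i:n], 1 - p[i:n]) >= 0.95)) {
      fixed <- TRUE; fix_gen <- g[i]; break
    }
  }
  list(t_max = t_max, m_max = best_dev, t_max_rate = t_rate,
       m_max_rate = best_rate, t_max_diff = t_diff, m_max_diff = best_diff,
       total_change = total, fixed = fixed, fixation_generation = fix_gen)
}

# Position-by-position string matcher for single reads.
oracle_match <- function(seq, layout, fwd_set, rev_set, library) {
  fwd_hit <- NULL
  for (f in fwd_set[order(-nchar(fwd_set))]) {
    if (substr(seq, 1, nchar(f)) == f) { fwd_hit <- f; break }
  }
  if (is.null(fwd_hit)) return(list(reason = "no-forward-index"))
  pos <- nchar(fwd_hit) + 1
  if (substr(seq, pos, pos + nchar(layout$forward_spacer) - 1) !=
      layout$forward_spacer) return(list(reason = "no-barcode"))
  pos <- pos + nchar(layout$forward_spacer)
  bc <- substr(seq, pos, pos + layout$barcode_length - 1)
  hit <- which(library$sequence == bc)
  if (!length(hit)) return(list(reason = "no-barcode"))
  pos <- pos + layout$barcode_length
  if (substr(seq, pos, pos + nchar(layout$reverse_spacer) - 1) !=
      layout$reverse_spacer) return(list(reason = "no-reverse-index"))
  pos <- pos + nchar(layout$reverse_spacer)
  rev_hit <- NULL
  targets <- if (layout$reverse_index_orientation == "reverse-complement")
    stats::setNames(reverse_complement(rev_set), rev_set) else
      stats::setNames(rev_set, rev_set)
  for (k in order(-nchar(targets))) {
    r <- targets[k]
    if (substr(seq, pos, pos + nchar(r) - 1) == r) {
      rev_hit <- names(targets)[k]; break
    }
  }
  if (is.null(rev_hit)) return(list(reason = "no-reverse-index"))
  list(fwd_index = fwd_hit, rev_index = rev_hit,
       barcode_id = library$barcode_id[hit])
}
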