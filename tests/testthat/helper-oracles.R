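# Independent brute-force oracles. These deliberately re-derive results from
# definitions (exhaustive enumeration, explicit loops) rather than reusing any
# package internals.

# All tryptic peptides of `seq` by exhaustive substring enumeration.
oracle_digest <- function(seq, max_mc, min_len, specificity = "full") {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  # cut after position i?
  is_cut <- vapply(seq_len(n - 1), function(i) {
    ch[i] %in% c("K", "R") && ch[i + 1] != "P"
  }, logical(1))
  if (n == 1) is_cut <- logical(0)
  rows <- list()
  for (s in 1:n) {
    for (e in s:n) {
      if (e - s + 1 < min_len) next
      nt <- s == 1 || is_cut[s - 1]
      ct <- e == n || is_cut[e]
      mc <- if (e > s) sum(is_cut[s:(e - 1)]) else 0L
      if (mc > max_mc) next
      keep <- if (specificity == "full") nt && ct else nt || ct
      if (keep) {
        rows[[length(rows) + 1]] <- data.frame(
          start = s, end = e, sequence = substr(seq, s, e),
          missed_cleavages = mc, n_term_tryptic = nt, c_term_tryptic = ct
        )
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), sequence = character(),
               missed_cleavages = integer(), n_term_tryptic = logical(),
               c_term_tryptic = logical())
}

random_protein <- function(len, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                             "I", "K", "L", "M", "N", "P", "Q",
                                             "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Exhaustive threshold scan for target-decoy filtering at level alpha.
oracle_filter <- function(scores, is_decoy, alpha) {
  ts <- sort(unique(scores))
  fdr <- sapply(ts, function(t) {
    nt <- sum(scores >= t & !is_decoy)
    nd <- sum(scores >= t & is_decoy)
    if (nt == 0) 0 else nd / nt
  })
  # q(t) = min fdr over thresholds <= t (more permissive ones included)
  q <- sapply(seq_along(ts), function(i) min(fdr[1:i]))
  ok <- which(q <= alpha)
  if (!length(ok)) {
    return(list(threshold = Inf, accepted_idx = integer()))
  }
  t_star <- ts[min(ok)]
  list(threshold = t_star,
       accepted_idx = which(scores >= t_star & !is_decoy))
}

# Group-by-max peptide collapse by explicit split.
oracle_collapse <- function(df, key) {
  parts <- split(seq_len(nrow(df)), df$peptide_id)
  keep <- vapply(parts, function(idx) {
    v <- df[[key]][idx]
    best <- idx[v == max(v)]
    if (length(best) > 1) best <- best[order(df$spectrum_id[best])][1]
    best
  }, integer(1))
  df[sort(unname(keep)), , drop = FALSE]
}

# Brute-force single-strand ORF translation via a literal codon walk.
oracle_orfs_one_strand <- function(s, min_aa) {
  table <- Biostrings::GENETIC_CODE
  out <- character()
  for (frame in 1:3) {
    i <- frame
    aa <- character()
    while (i + 2 <= nchar(s)) {
      cod <- substr(s, i, i + 2)
      aa <- c(aa, if (grepl("N", cod)) "X" else unname(table[cod]))
      i <- i + 3
    }
    # walk regions between stops
    start <- 1
    pos <- 1
    while (pos <= length(aa) + 1) {
      if (pos > length(aa) || aa[pos] == "*") {
        region <- if (start <= pos - 1) start:(pos - 1) else integer()
        codons_start <- region[vapply(region, function(cidx) {
          substr(s, frame + 3 * (cidx - 1), frame + 3 * (cidx - 1) + 2) == "ATG"
        }, logical(1))]
        if (length(codons_start)) {
          orf <- aa[codons_start[1]:(pos - 1)]
          if (length(orf) >= min_aa) out <- c(out, paste(orf, collapse = ""))
        }
        start <- pos + 1
      }
      pos <- pos + 1
    }
  }
  out
}

oracle_sixframe <- function(s, min_aa) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  c(oracle_orfs_one_strand(s, min_aa), oracle_orfs_one_strand(rc, min_aa))
}

sorted_chars <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(sort(ch), collapse = ""),
         character(1))
}
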