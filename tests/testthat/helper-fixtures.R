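# Shared helpers: tiny file writers and independent oracles used across the
# suite. The oracles are deliberately naive (per-read loops, direct
# enumeration) so they share no code path with the implementation.

write_vcf_file <- function(body_rows, path = tempfile(fileext = ".vcf"),
                           sample = "s") {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
                   sample))
  writeLines(c(hdr, body_rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, gt = "0/1") {
  sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s", chrom, pos, ref, alt, gt)
}

# minimal SAM writer: `reads` is a data frame with qname, flag, pos, mapq,
# cigar, seq (and optionally rnext/pnext)
write_sam_file <- function(reads, seq_len = 1000, seq_name = "ref",
                           path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", seq_name, seq_len))
  rnext <- reads$rnext %||% rep("*", nrow(reads))
  pnext <- reads$pnext %||% rep(0L, nrow(reads))
  reads <- reads[order(reads$pos), ]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s",
                  reads$qname, reads$flag, seq_name, reads$pos, reads$mapq,
                  reads$cigar, rnext, pnext, reads$seq,
                  strrep("I", nchar(reads$seq)))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive per-read pileup: parses M/D/I/N/S CIGAR by hand, counts every read
# independently (read-level, not fragment-level)
naive_pileup <- function(sam_path, mapq_min = 20) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (as.integer(f[5]) <= mapq_min) next
    pos <- as.integer(f[4])
    cig <- f[6]
    seq <- strsplit(f[10], "")[[1]]
    ops <- regmatches(cig, gregexpr("[0-9]+[MIDNSHP=X]", cig))[[1]]
    qi <- 1L; ri <- pos
    for (op in ops) {
      n <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        for (k in seq_len(n)) {
          b <- seq[qi]
          if (b %in% c("A", "C", "G", "T")) {
            key <- as.character(ri)
            if (is.null(counts[[key]])) counts[[key]] <- c(A = 0, C = 0,
                                                           G = 0, T = 0)
            counts[[key]][b] <- counts[[key]][b] + 1
          }
          qi <- qi + 1L; ri <- ri + 1L
        }
      } else if (type %in% c("I", "S")) {
        qi <- qi + n
      } else if (type %in% c("D", "N")) {
        ri <- ri + n
      }
    }
  }
  counts
}

# independent single-pass election for one (position, subgenome) cell
oracle_elect <- function(bases, scores, mode) {
  if (length(bases) == 0L) return(NA_character_)
  if (mode == "max") {
    mx <- max(scores)
    w <- unique(bases[abs(scores - mx) < 1e-9])
  } else {
    agg <- tapply(scores, bases, sum)
    mx <- max(agg)
    w <- names(agg)[abs(agg - mx) < 1e-9]
  }
  if (length(w) == 1L) w else NA_character_
}

# hand-build a pattern tibble from a list of list(pos=, base=, support=)
mk_patterns <- function(defs, gene_id = "g1", seq_name = "ref") {
  tibble::tibble(
    pattern_id = seq_along(defs),
    gene_id = gene_id, seq_name = seq_name,
    positions = lapply(defs, function(d) as.integer(d$pos)),
    bases = lapply(defs, function(d) d$base),
    size = vapply(defs, function(d) length(d$pos), integer(1)),
    support = vapply(defs, function(d) as.integer(d$support %||% 1L),
                     integer(1)),
    state = "active"
  )
}

# random pattern tibble over a handful of HSP positions, for property tests
random_patterns <- function(n, positions, gene_id = "g1",
                            seq_name = "ref") {
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(seq_along(positions), 1L)
    start <- sample(seq_len(length(positions) - k + 1L), 1L)
    idx <- start:(start + k - 1L)
    list(positions = positions[idx],
         bases = sample(c("A", "C", "G", "T"), k, replace = TRUE),
         support = sample(1:20, 1L))
  })
  tibble::tibble(
    pattern_id = seq_len(n),
    gene_id = gene_id,
    seq_name = seq_name,
    positions = lapply(rows, `[[`, "positions"),
    bases = lapply(rows, `[[`, "bases"),
    size = vapply(rows, function(r) length(r$positions), integer(1)),
    support = vapply(rows, `[[`, integer(1), "support"),
    state = "active"
  )
}

pattern_key_set <- function(patterns) {
  sort(mapply(function(p, b) paste(p, b, sep = ":", collapse = ";"),
              patterns$positions, patterns$bases))
}
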