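# Deterministic allopolyploid transcriptome simulator with truth tables.
# Reads are emitted as pre-aligned SAM records at their true coordinates on
# the concatenated reference, so no external aligner is involved; the HSP
# and SBS input lists are derived from the simulated pileups with the same
# naive threshold rules the validation step uses, so a full run exercises
# ingestion and validation, not just the core algorithm.

#' Simulation configuration
#'
#' Parameters of the allopolyploid read simulator. The defaults describe
#' the standard evaluation condition: an allotetraploid transcriptome of
#' 200 one-kilobase genes, each subgenome diverged from the common ancestor
#' at 1% of sites, each diploid progenitor diverged 0.3% from its
#' subgenome, 2 x 100 bp read pairs at 30x coverage per subgenome with 0.2%
#' base error.
#'
#' @param n_genes Number of genes.
#' @param gene_length Gene length in bp.
#' @param n_subgenomes Number of subgenomes (2-10).
#' @param hsp_rate Per-base probability that a subgenome differs from the
#'   ancestral base.
#' @param diploid_divergence Per-base probability that a diploid progenitor
#'   differs from its subgenome.
#' @param read_length Read length in bp.
#' @param insert_mean,insert_sd Fragment insert size distribution (bp).
#' @param coverage Polyploid read coverage per subgenome (x).
#' @param diploid_coverage Read coverage of each diploid progenitor (x).
#' @param base_error_rate Per-base sequencing error probability.
#' @param paired Paired-end reads (default `TRUE`).
#' @param gap_length N-spacer length between genes in the concatenated
#'   reference.
#' @param min_call_coverage Minimum pileup depth for calling an input HSP or
#'   SBS from the simulated coverage (default 3, matching the validation
#'   default).
#' @param seed Random seed (mandatory; all outputs are reproducible from
#'   it).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, gene_length = 1000, n_subgenomes = 2,
                       hsp_rate = 0.01, diploid_divergence = 0.003,
                       read_length = 100, insert_mean = 250, insert_sd = 25,
                       coverage = 30, diploid_coverage = 30,
                       base_error_rate = 0.002, paired = TRUE,
                       gap_length = 200, min_call_coverage = 3, seed) {
  if (missing(seed) || !is.numeric(seed)) abort("`seed` is mandatory")
  stopifnot(n_genes >= 1, gene_length >= 1,
            n_subgenomes >= 2, n_subgenomes <= 10,
            hsp_rate >= 0, hsp_rate < 1,
            diploid_divergence >= 0, diploid_divergence < 1,
            base_error_rate >= 0, base_error_rate < 1,
            coverage > 0, diploid_coverage > 0,
            read_length >= 1, insert_mean >= read_length,
            gene_length >= read_length)
  structure(
    list(n_genes = as.integer(n_genes),
         gene_length = as.integer(gene_length),
         n_subgenomes = as.integer(n_subgenomes), hsp_rate = hsp_rate,
         diploid_divergence = diploid_divergence,
         read_length = as.integer(read_length), insert_mean = insert_mean,
         insert_sd = insert_sd, coverage = coverage,
         diploid_coverage = diploid_coverage,
         base_error_rate = base_error_rate, paired = isTRUE(paired),
         gap_length = as.integer(gap_length),
         min_call_coverage = as.integer(min_call_coverage),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# mutate integer bases (1..4) in place with probability `rate`, always to a
# different base chosen uniformly
mutate_bases <- function(x, rate) {
  if (rate <= 0) return(x)
  idx <- which(stats::runif(length(x)) < rate)
  if (length(idx)) {
    x[idx] <- ((x[idx] - 1L + sample.int(3L, length(idx), replace = TRUE)) %%
                 4L) + 1L
  }
  x
}

# sample reads for one genome copy; returns a list of per-read vectors and
# the flat base vector (with sequencing errors applied)
sim_reads_for_copy <- function(copy_vec, cfg, frag_offset) {
  L <- cfg$gene_length
  n <- cfg$n_genes
  rl <- cfg$read_length
  if (cfg$paired) {
    nfrag_per_gene <- max(1L, as.integer(round(cfg$coverage_this * L /
                                                 (2 * rl))))
  } else {
    nfrag_per_gene <- max(1L, as.integer(round(cfg$coverage_this * L / rl)))
  }
  nfrag <- nfrag_per_gene * n
  gidx <- rep(seq_len(n), each = nfrag_per_gene)
  if (cfg$paired) {
    ins <- pmin(pmax(as.integer(round(stats::rnorm(nfrag, cfg$insert_mean,
                                                   cfg$insert_sd))),
                     rl), L)
    start <- 1L + as.integer(floor(stats::runif(nfrag) * (L - ins + 1)))
    r1_start <- start
    r2_start <- start + ins - rl
    read_gidx <- rep(gidx, each = 2L)
    read_start <- as.vector(rbind(r1_start, r2_start))
    read_frag <- rep(frag_offset + seq_len(nfrag), each = 2L)
    mate <- rep(c(1L, 2L), nfrag)
    tlen <- as.vector(rbind(ins, -ins))
  } else {
    start <- 1L + as.integer(floor(stats::runif(nfrag) * (L - rl + 1)))
    read_gidx <- gidx
    read_start <- start
    read_frag <- frag_offset + seq_len(nfrag)
    mate <- rep(0L, nfrag)
    tlen <- rep(0L, nfrag)
  }
  n_reads <- length(read_start)
  idx <- rep((read_gidx - 1L) * L + read_start, each = rl) +
    rep(0L:(rl - 1L), times = n_reads)
  bases <- mutate_bases(copy_vec[idx], cfg$base_error_rate)
  list(frag = read_frag, gidx = read_gidx, start = read_start,
       mate = mate, tlen = tlen, bases = bases, n_reads = n_reads,
       nfrag = nfrag)
}

reads_to_seq_strings <- function(bases, rl, n_reads) {
  s_all <- paste0(DNA_BASES[bases], collapse = "")
  substring(s_all, seq(1L, by = rl, length.out = n_reads),
            seq(rl, by = rl, length.out = n_reads))
}

# long fragment-base tibble (mate-fused) from simulated reads
reads_to_fragments <- function(rd, cfg, genes) {
  rl <- cfg$read_length
  ref_start <- genes$start[rd$gidx] + rd$start - 1L
  dt <- data.table::data.table(
    frag = rep(rd$frag, each = rl),
    gi = rep(rd$gidx, each = rl),
    pos = rep(ref_start, each = rl) + rep(0L:(rl - 1L), times = rd$n_reads),
    base = rd$bases
  )
  dt <- fuse_mate_bases(dt)
  tibble(
    fragment_id = dt$frag,
    gene_id = genes$gene_id[dt$gi],
    seq_name = genes$seq_name[dt$gi],
    pos = dt$pos,
    base = DNA_BASES[dt$base]
  )
}

write_simple_vcf <- function(df, path, sample_name) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    sprintf("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t%s",
            sample_name)
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s",
                  df$seq_name, df$pos, df$ref, df$alt, df$gt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# call candidate HSPs from a polyploid coverage table: depth >=
# min_call_coverage, a base observed at >= hsp_min_frac with at least two
# supporting reads (the two-read floor emulates the upstream caller's
# low-quality-variant filter, which discards singleton error alleles)
call_hsps_from_coverage <- function(cov, ref_base_at, min_frac, min_depth) {
  total <- cov_totals(cov)
  cov <- cov[total >= min_depth, ]
  if (nrow(cov) == 0L) {
    return(tibble(seq_name = character(), pos = integer(), ref = character(),
                  alt = character(), gt = character()))
  }
  counts <- cbind(cov$A, cov$C, cov$G, cov$T)
  ok2 <- counts >= 2L
  qual <- qualifying_bases(cov, min_frac)
  qual <- lapply(seq_along(qual), function(i)
    intersect(qual[[i]], DNA_BASES[ok2[i, ]]))
  keep <- lengths(qual) >= 2L
  cov <- cov[keep, ]
  qual <- qual[keep]
  if (nrow(cov) == 0L) {
    return(tibble(seq_name = character(), pos = integer(), ref = character(),
                  alt = character(), gt = character()))
  }
  ref <- ref_base_at(cov$seq_name, cov$pos)
  alts <- map2(qual, ref, setdiff)
  has_ref <- map2_lgl(qual, ref, function(q, r) r %in% q)
  ok <- which(lengths(alts) >= 1L)
  n_alt <- lengths(alts)[ok]
  gt <- vapply(seq_along(ok), function(i) {
    if (has_ref[ok[i]]) paste(0:n_alt[i], collapse = "/")
    else paste(seq_len(n_alt[i]), collapse = "/")
  }, character(1))
  tibble(
    seq_name = cov$seq_name[ok], pos = cov$pos[ok], ref = ref[ok],
    alt = map_chr(alts[ok], paste0, collapse = ","), gt = gt
  )
}

# call SBSs from a diploid coverage table: one base at >= sbs_min_frac,
# different from the reference, no second base above the ambiguity floor
call_sbss_from_coverage <- function(cov, ref_base_at, sbs_min_frac,
                                    ambiguous_min_frac, min_depth) {
  total <- cov_totals(cov)
  cov <- cov[total >= min_depth, ]
  if (nrow(cov) == 0L) {
    return(tibble(seq_name = character(), pos = integer(), ref = character(),
                  alt = character(), gt = character()))
  }
  strong <- qualifying_bases(cov, sbs_min_frac)
  ambig <- lengths(qualifying_bases(cov, ambiguous_min_frac)) >= 2L
  keep <- lengths(strong) == 1L & !ambig
  cov <- cov[keep, ]
  if (nrow(cov) == 0L) {
    return(tibble(seq_name = character(), pos = integer(), ref = character(),
                  alt = character(), gt = character()))
  }
  base <- unlist(strong[keep])
  ref <- ref_base_at(cov$seq_name, cov$pos)
  ok <- base != ref
  tibble(seq_name = cov$seq_name[ok], pos = cov$pos[ok], ref = ref[ok],
         alt = base[ok], gt = "1/1")
}

#' Simulate an allopolyploid RNA-seq dataset with known truth
#'
#' Draws ancestral gene sequences uniformly over ACGT, mutates each site
#' independently in every subgenome with probability `hsp_rate` (to a
#' distinct base chosen uniformly), derives one diploid progenitor per
#' subgenome with additional per-base divergence `diploid_divergence`,
#' samples read pairs per subgenome and per diploid at the configured
#' coverages with uniform positional placement and per-base sequencing
#' error, and emits the full input file set of the pipeline: the
#' concatenated reference (FASTA + GFF3), position-sorted polyploid SAM,
#' per-base coverage tables, a candidate HSP VCF and per-diploid SBS VCFs
#' called from the simulated pileups, plus truth tables.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, all files are written
#'   there and their paths returned in the `files` element.
#'
#' @return A list of class `homeallele_sim` with elements `config`,
#'   `reference` (a `reference_build`), `fragments` (polyploid fragment
#'   tibble), `hsp` (candidate HSP tibble as read back from the VCF rules),
#'   `sbs` (named list of SBS tibbles), `poly_coverage`, `dip_coverage`,
#'   `truth` (list: `bases` per position/subgenome, `hsp_positions`,
#'   `sbs` per diploid) and, with `out_dir`, `files`.
#' @export
simulate_allopolyploid <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$gene_length
  n <- cfg$n_genes
  S <- cfg$n_subgenomes
  subgenomes <- paste0("s", seq_len(S))
  gene_names <- sprintf("g%04d", seq_len(n))

  anc <- sample.int(4L, n * L, replace = TRUE)
  sub_vecs <- lapply(seq_len(S), function(s) mutate_bases(anc, cfg$hsp_rate))
  dip_vecs <- lapply(sub_vecs, mutate_bases, rate = cfg$diploid_divergence)
  names(sub_vecs) <- names(dip_vecs) <- subgenomes

  anc_strings <- reads_to_seq_strings(anc, L, n)
  build <- build_reference(setNames(anc_strings, gene_names),
                           gap_length = cfg$gap_length)
  genes <- build$genes

  # global reference coordinates of all gene bases, in gene-vector order
  gene_pos <- rep(genes$start, each = L) + rep(0L:(L - 1L), times = n)
  ref_base_at <- function(seq_name, pos) {
    DNA_BASES[anc[match(pos, gene_pos)]]
  }

  # truth
  sub_mat <- do.call(cbind, sub_vecs)
  is_hsp <- sites_divergent(sub_mat)
  truth_bases <- tibble(
    seq_name = build$seq_name,
    pos = rep(gene_pos, times = S),
    subgenome = rep(subgenomes, each = length(gene_pos)),
    base = DNA_BASES[as.vector(sub_mat)]
  )
  truth_hsp <- tibble(seq_name = build$seq_name, pos = gene_pos[is_hsp])
  truth_sbs <- purrr::map(subgenomes, function(s) {
    d <- dip_vecs[[s]] != anc
    tibble(seq_name = build$seq_name, pos = gene_pos[d],
           ref_base = DNA_BASES[anc[d]],
           diploid_base = DNA_BASES[dip_vecs[[s]][d]])
  })
  names(truth_sbs) <- subgenomes

  # polyploid reads: one batch per subgenome
  cfg_poly <- cfg
  cfg_poly$coverage_this <- cfg$coverage
  poly_reads <- list()
  frag_offset <- 0L
  for (s in seq_len(S)) {
    rd <- sim_reads_for_copy(sub_vecs[[s]], cfg_poly, frag_offset)
    rd$origin <- subgenomes[s]
    frag_offset <- frag_offset + rd$nfrag
    poly_reads[[s]] <- rd
  }
  fragments <- bind_rows(lapply(poly_reads, reads_to_fragments,
                                cfg = cfg, genes = genes))
  poly_cov <- compute_base_coverage(fragments)

  # diploid reads -> coverage tables only
  dip_cov <- purrr::map(subgenomes, function(s) {
    cfg_dip <- cfg
    cfg_dip$coverage_this <- cfg$diploid_coverage
    rd <- sim_reads_for_copy(dip_vecs[[s]], cfg_dip, 0L)
    compute_base_coverage(reads_to_fragments(rd, cfg, genes))
  })
  names(dip_cov) <- subgenomes

  # candidate input lists from the simulated pileups
  pre <- preprocess_config(min_diploid_coverage = cfg$min_call_coverage)
  hsp_calls <- call_hsps_from_coverage(poly_cov, ref_base_at,
                                       pre$hsp_min_frac,
                                       cfg$min_call_coverage)
  sbs_calls <- purrr::map(dip_cov, call_sbss_from_coverage,
                          ref_base_at = ref_base_at,
                          sbs_min_frac = pre$sbs_min_frac,
                          ambiguous_min_frac = pre$ambiguous_min_frac,
                          min_depth = cfg$min_call_coverage)

  hsp_tbl <- tibble(
    seq_name = hsp_calls$seq_name, pos = hsp_calls$pos,
    ref_base = hsp_calls$ref,
    observed_bases = map2(strsplit(hsp_calls$alt, ",", fixed = TRUE),
                          ifelse(startsWith(hsp_calls$gt, "0"),
                                 hsp_calls$ref, NA_character_),
                          function(a, r) sort(unique(c(a, r[!is.na(r)]))))
  )
  sbs_tbls <- purrr::map(sbs_calls, function(x)
    tibble(seq_name = x$seq_name, pos = x$pos, ref_base = x$ref,
           diploid_base = x$alt))

  out <- structure(
    list(config = cfg, reference = build, genes = genes,
         fragments = fragments, hsp = hsp_tbl, sbs = sbs_tbls,
         poly_coverage = poly_cov, dip_coverage = dip_cov,
         truth = list(bases = truth_bases, hsp_positions = truth_hsp,
                      sbs = truth_sbs),
         subgenomes = subgenomes),
    class = "homeallele_sim"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    prefix <- file.path(out_dir, "ref")
    write_reference(build, prefix)
    sam <- file.path(out_dir, "poly.sam")
    write_sim_sam(poly_reads, cfg, build, sam)
    write_coverage_table(poly_cov, file.path(out_dir, "poly_cov.tsv"))
    write_simple_vcf(hsp_calls, file.path(out_dir, "hsp.vcf"), "polyploid")
    for (s in subgenomes) {
      write_simple_vcf(sbs_calls[[s]],
                       file.path(out_dir, sprintf("sbs_%s.vcf", s)), s)
      write_coverage_table(dip_cov[[s]],
                           file.path(out_dir, sprintf("cov_%s.tsv", s)))
    }
    utils::write.table(truth_bases, file.path(out_dir, "truth_bases.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth_hsp, file.path(out_dir, "truth_hsp.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$files <- c(
      fasta = paste0(prefix, ".fa"), gff3 = paste0(prefix, ".gff3"),
      sam = sam, poly_cov = file.path(out_dir, "poly_cov.tsv"),
      hsp = file.path(out_dir, "hsp.vcf"),
      setNames(file.path(out_dir, sprintf("sbs_%s.vcf", subgenomes)),
               paste0("sbs_", subgenomes)),
      setNames(file.path(out_dir, sprintf("cov_%s.tsv", subgenomes)),
               paste0("cov_", subgenomes))
    )
  }
  out
}

# TRUE where the subgenome bases at a site are not all equal
sites_divergent <- function(m) {
  mx <- do.call(pmax, as.data.frame(m))
  mn <- do.call(pmin, as.data.frame(m))
  mx != mn
}

# position-sorted SAM with minimal fields; reads are placed at their true
# coordinates, so the file stands in for an aligner's output
write_sim_sam <- function(read_batches, cfg, build, path) {
  rl <- cfg$read_length
  genes <- build$genes
  rows <- purrr::map(read_batches, function(rd) {
    ref_start <- genes$start[rd$gidx] + rd$start - 1L
    seqs <- reads_to_seq_strings(rd$bases, rl, rd$n_reads)
    if (cfg$paired) {
      flag <- ifelse(rd$mate == 1L, 67L, 131L)
      # coordinate of the other read of the same fragment
      mate_pos <- ifelse(rd$mate == 1L, ref_start + rd$tlen - rl,
                         ref_start + rd$tlen + rl)
      rnext <- "="
    } else {
      flag <- 0L
      mate_pos <- 0L
      rnext <- "*"
    }
    tibble(
      qname = sprintf("frag%08d", rd$frag),
      flag = flag, pos = ref_start, mpos = mate_pos, tlen = rd$tlen,
      seq = seqs, rnext = rnext
    )
  })
  df <- bind_rows(rows)
  df <- df[order(df$pos, df$qname, df$flag), ]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", build$seq_name,
                   nchar(build$sequence)))
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t%d\t%s\t%s",
                  df$qname, df$flag, build$seq_name, df$pos, rl,
                  df$rnext, df$mpos, df$tlen, df$seq, strrep("I", rl))
  writeLines(c(hdr, body), path)
  invisible(path)
}
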