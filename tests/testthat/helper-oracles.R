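# Independent oracles and tiny fixture builders shared across tests.

# Brute-force rank-sum p-value by enumerating all choose(n, n1) group
# labelings (mid-ranks, conditional on observed ties).
bf_ranksum_p <- function(a, b, alternative = "two_sided") {
  n1 <- length(a)
  r <- rank(c(a, b))
  n <- length(r)
  W <- sum(r[seq_len(n1)])
  mu <- n1 * mean(r)
  sums <- apply(utils::combn(n, n1), 2, function(id) sum(r[id]))
  eps <- 1e-9
  switch(alternative,
         two_sided = mean(abs(sums - mu) >= abs(W - mu) - eps),
         greater = mean(sums >= W - eps),
         less = mean(sums <= W + eps))
}

# Brute-force distribution of the group-1 rank sum (support in 2*rank units)
bf_ranksum_dist <- function(ranks, n1) {
  sums <- apply(utils::combn(length(ranks), n1), 2, function(id) sum(ranks[id]))
  table(as.integer(round(2 * sums)))
}

# all compositions of n (ordered tie-group sizes) via cut-point bitmasks
compositions_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (mask in 0:(2^(n - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2L))) > 0L)
    out[[length(out) + 1L]] <- diff(c(0L, cuts, n))
  }
  out
}

# translation-based frame oracle: the fusion is in frame iff the protein
# translated from ATG1 (to its first stop) ends with the wild-type 3'
# protein suffix from the first retained residue.
oracle_in_frame <- function(cdna, atg1_offset, wt3_protein, first_retained_residue) {
  aa <- orfrescue:::translate_nt(substr(cdna, atg1_offset + 1L, nchar(cdna)))
  prot <- sub("\\*.*$", "", aa)
  suffix <- substr(wt3_protein, first_retained_residue, nchar(wt3_protein))
  endsWith(prot, suffix)
}

# wild-type protein of the toy reference's 3' gene (stop stripped)
toy_wt3_protein <- function(ref) {
  cds <- substr(ref$meta$tx3, ref$meta$v3 + 1L, ref$meta$v3 + ref$meta$cds_len3)
  sub("\\*$", "", orfrescue:::translate_nt(cds))
}

# a small, fast synthetic configuration (reduced gene sizes)
small_config <- function(seed, frame_shift = 1L, rescue = c(130L, 154L),
                         premature_stop_offset = 2L, strand5 = "+", strand3 = "+",
                         r_first = 100L, n_res3 = 300L, b3 = 5L, n_ex3 = 9L,
                         b5 = 2L, n_ex5 = 6L, domain = c(200L, 280L),
                         caller_frame_label = NULL, fold_change = 10) {
  cfg <- simulation_config(
    seed = seed,
    gene_5p = list(name = "GA", contig = "c5", strand = strand5, n_exons = n_ex5,
                   breakpoint_exon = b5, n_residues = 60L + 50L * b5),
    gene_3p = list(name = "GB", contig = "c3", strand = strand3, n_exons = n_ex3,
                   breakpoint_exon = b3, n_residues = n_res3,
                   first_retained_residue = r_first, rescue_residues = rescue,
                   domain_start = domain[1], domain_end = domain[2],
                   domain_name = "Protein kinase"),
    frame_shift = frame_shift, premature_stop_offset = premature_stop_offset,
    caller_frame_label = caller_frame_label)
  cfg$counts$fold_change <- fold_change
  cfg
}

# harmonized fusion reconstructed from an engineered toy reference
toy_harmonized <- function(ref) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  engineer_fusion(ref, dir)
  calls <- c(read_fusion_calls(file.path(dir, "calls_dialect_A.tsv"), "dialect_A"),
             read_fusion_calls(file.path(dir, "calls_dialect_F.tsv"), "dialect_F"),
             read_fusion_calls(file.path(dir, "calls_dialect_S.tsv"), "dialect_S"))
  harmonize_calls(calls)[[1]]
}

# same, but constructed in memory (no file I/O) for large loops
toy_harmonized_mem <- function(ref) {
  bp <- orfrescue:::fusion_breakpoints_genomic(ref)
  call <- orfrescue:::new_fusion_call(
    orfrescue:::new_breakpoint(bp$m5$contig, bp$pos5, bp$m5$gene_name, "five_prime",
                               strand = bp$m5$strand),
    orfrescue:::new_breakpoint(bp$m3$contig, bp$pos3, bp$m3$gene_name, "three_prime",
                               strand = bp$m3$strand),
    "arriba", 8L, 6L, "unknown")
  harmonize_calls(list(call), 10)[[1]]
}

# hand-written two-gene GTF + FASTA fixture (plus- and minus-strand toys)
write_tiny_reference <- function(dir) {
  genome <- c(chrT = paste(rep("ACGT", 30), collapse = ""))  # 120 nt
  writeLines(c(">chrT", genome), file.path(dir, "genome.fa"))
  gtf <- c(
    # plus-strand: exon1 g[0,8) exon2 g[12,20); CDS g[5,8)+g[12,15)
    'chrT\ttoy\texon\t1\t8\t.\t+\t.\tgene_id "gp"; gene_name "GP"; transcript_id "tp"; exon_number "1";',
    'chrT\ttoy\texon\t13\t20\t.\t+\t.\tgene_id "gp"; gene_name "GP"; transcript_id "tp"; exon_number "2";',
    'chrT\ttoy\tCDS\t6\t8\t.\t+\t0\tgene_id "gp"; gene_name "GP"; transcript_id "tp";',
    'chrT\ttoy\tCDS\t13\t15\t.\t+\t0\tgene_id "gp"; gene_name "GP"; transcript_id "tp";',
    # minus-strand: exons g[30,38) and g[44,52); rank 1 must be the rightmost
    'chrT\ttoy\texon\t31\t38\t.\t-\t.\tgene_id "gm"; gene_name "GM"; transcript_id "tm"; exon_number "2";',
    'chrT\ttoy\texon\t45\t52\t.\t-\t.\tgene_id "gm"; gene_name "GM"; transcript_id "tm"; exon_number "1";')
  writeLines(gtf, file.path(dir, "annotation.gtf"))
  invisible(dir)
}
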