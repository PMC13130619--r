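#' @name synthetic
#' @title Seeded synthetic references, engineered fusions and exon counts
#' @description
#' Fully self-contained toy data with the structure the analysis assumes:
#' two multi-exon protein-coding genes, an engineered chimeric cDNA with a
#' controlled junction frame shift, a premature stop planted a chosen
#' number of codons past the junction in the ATG1 frame, frame-restoring
#' ATGs planted at chosen wild-type residues of the 3' partner, and
#' negative-binomial per-exon read counts with a step fold-change at the
#' breakpoint exon. All randomness flows from a single seed.
NULL

SENSE_CODONS_NO_ATG <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA", "ATG"))
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# random coding sequence: ATG + (n_residues - 1) sense non-ATG codons + TAA.
# Codon-aligned ATGs appear only where planted, so planted rescue starts are
# provably the only frame-restoring starts.
rand_cds <- function(n_residues) {
  paste(c("ATG", sample(SENSE_CODONS_NO_ATG, n_residues - 1L, replace = TRUE), "TAA"),
        collapse = "")
}

partition_lengths <- function(total, k, min_len = 20L) {
  base <- total %/% k
  if (base < min_len)
    abort_input(sprintf("cannot partition %d nt into %d exons of >= %d nt", total, k, min_len))
  rem <- total %% k
  as.integer(base + (seq_len(k) <= rem))
}

#' Simulation configuration
#'
#' Defaults echo the index-case geometry: a 7-exon 5' partner fused at
#' exon 2 to a 29-exon kinase gene at exon 18, a +1 junction frame shift
#' with a stop 2 codons past the junction, frame-restoring ATGs planted at
#' wild-type residues 973 and 997 (24 residues apart) of a 1620-residue
#' kinase whose catalytic domain spans residues 1116-1392, and a 10-fold
#' negative-binomial count step (dispersion 0.1, baseline mean 50) on the
#' retained exons. The kinase gene is a synthetic stand-in: its sequence
#' is random, only its exon/residue geometry mirrors the real gene.
#'
#' @param seed integer seed (fixed seed implies byte-identical outputs)
#' @param gene_5p,gene_3p gene geometry lists; see defaults for the fields
#' @param frame_shift junction frame shift in \{0, 1, 2\} (0 = in-frame)
#' @param premature_stop_offset complete codons past the junction at which
#'   the ATG1-frame stop is planted (ignored when `frame_shift = 0`)
#' @param caller_frame_label override for the frame label written in the
#'   caller dialect tables (default: the engineered truth)
#' @param split_reads,spanning_pairs evidence counts written to the tables
#' @param counts list: `baseline_mean`, `dispersion`, `fold_change`
#' @return a `simulation_config` list
#' @export
simulation_config <- function(seed = 1L,
    gene_5p = list(name = "PART5", contig = "chr5p", strand = "+", n_exons = 7L,
                   breakpoint_exon = 2L, n_residues = 183L),
    gene_3p = list(name = "ALK", contig = "chr3p", strand = "+", n_exons = 29L,
                   breakpoint_exon = 18L, n_residues = 1620L,
                   first_retained_residue = 940L,
                   rescue_residues = c(973L, 997L),
                   domain_start = 1116L, domain_end = 1392L,
                   domain_name = "Protein kinase"),
    frame_shift = 1L, premature_stop_offset = 2L,
    caller_frame_label = NULL, split_reads = 8L, spanning_pairs = 6L,
    counts = list(baseline_mean = 50, dispersion = 0.1, fold_change = 10)) {
  stopifnot(frame_shift %in% 0:2)
  g3 <- gene_3p
  if (any(g3$rescue_residues < g3$first_retained_residue) ||
      any(g3$rescue_residues > g3$n_residues))
    abort_input("rescue residues must lie in the retained 3' region")
  structure(list(seed = seed, gene_5p = gene_5p, gene_3p = g3,
                 frame_shift = as.integer(frame_shift),
                 premature_stop_offset = as.integer(premature_stop_offset),
                 caller_frame_label = caller_frame_label,
                 split_reads = split_reads, spanning_pairs = spanning_pairs,
                 counts = counts),
            class = "simulation_config")
}

# place a transcript on a contig with fixed-length introns and padding
place_gene <- function(tx_seq, exon_lens, strand, intron_len = 60L, pad = 100L) {
  stops <- cumsum(exon_lens); starts <- c(0L, utils::head(stops, -1L))
  exon_seqs <- substring(tx_seq, starts + 1L, stops)
  n <- length(exon_lens)
  introns <- vapply(seq_len(max(n - 1L, 0L)), function(i) rand_seq(intron_len), character(1))
  body_parts <- character(0)
  blocks <- matrix(0L, nrow = n, ncol = 2L)  # [start, end) within body, transcript order
  cursor <- 0L
  for (i in seq_len(n)) {
    body_parts <- c(body_parts, exon_seqs[i])
    blocks[i, ] <- c(cursor, cursor + exon_lens[i])
    cursor <- cursor + exon_lens[i]
    if (i < n) { body_parts <- c(body_parts, introns[i]); cursor <- cursor + intron_len }
  }
  body <- paste(body_parts, collapse = "")
  B <- nchar(body)
  if (strand == "+") {
    contig_seq <- paste0(rand_seq(pad), body, rand_seq(pad))
    ex <- data.frame(start = pad + blocks[, 1], end = pad + blocks[, 2], rank = seq_len(n))
  } else {
    contig_seq <- paste0(rand_seq(pad), revcomp(body), rand_seq(pad))
    ex <- data.frame(start = pad + B - blocks[, 2], end = pad + B - blocks[, 1], rank = seq_len(n))
  }
  list(contig_seq = contig_seq, exons = ex)
}

#' Generate a toy two-gene reference
#'
#' Builds the two genes of `config` with exon partitions chosen so that an
#' exon-boundary fusion of the configured breakpoint exons has exactly the
#' configured junction frame shift, plants the frame-restoring rescue
#' ATGs and (for shifted configurations) the premature ATG1-frame stop,
#' and guarantees the coding sequences contain no spurious stop codon in
#' either the native or the shifted reading between junction and planted
#' stop. Optionally writes `genome.fa`, `annotation.gtf`, `domains.tsv`
#' to `dir`.
#'
#' @param config a [simulation_config()]
#' @param dir optional output directory
#' @return list: `genome` (DNAStringSet), `models`, `domains`, `meta`
#'   (layout bookkeeping used by [engineer_fusion()])
#' @export
make_toy_reference <- function(config, dir = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  g5 <- config$gene_5p; g3 <- config$gene_3p
  s <- config$frame_shift
  # ---- 3' gene layout ---------------------------------------------------
  v3 <- 90L; cds_len3 <- 3L * (g3$n_residues + 1L); utr3_3 <- 150L
  total3 <- v3 + cds_len3 + utr3_3
  b3 <- g3$breakpoint_exon
  if (b3 < 2L || b3 > g3$n_exons) abort_input("3' breakpoint exon must be in 2..n_exons")
  P3 <- v3 + 3L * (g3$first_retained_residue - 1L)  # tx offset of first retained base
  if (P3 >= v3 + cds_len3 - 3L) abort_input("first retained residue beyond the 3' CDS")
  lens3 <- c(partition_lengths(P3, b3 - 1L), partition_lengths(total3 - P3, g3$n_exons - b3 + 1L))
  tx3 <- paste0(rand_seq(v3), rand_cds(g3$n_residues), rand_seq(utr3_3))
  protected <- c(v3, v3 + 3L * (g3$rescue_residues - 1L), v3 + cds_len3 - 3L)
  for (r in g3$rescue_residues) {
    pos <- v3 + 3L * (r - 1L)
    substr(tx3, pos + 1L, pos + 3L) <- "ATG"
  }
  # ---- 5' gene layout ---------------------------------------------------
  b5 <- g5$breakpoint_exon
  if (b5 < 1L || b5 >= g5$n_exons) abort_input("5' breakpoint exon must be in 1..n_exons-1")
  total5 <- 150L * g5$n_exons
  lens5 <- partition_lengths(total5, g5$n_exons)
  L5 <- sum(lens5[seq_len(b5)])
  # native 3' phase at the junction is 0 by construction, so the 5' UTR
  # length u sets the junction phase: (L5 - u) mod 3 == frame_shift
  u <- 9L + ((L5 - s - 9L) %% 3L)
  cds_len5 <- 3L * (g5$n_residues + 1L)
  if (u + 3L >= L5) abort_input("5' breakpoint exon too short: start codon not upstream of junction")
  if (u + cds_len5 <= L5) abort_input("5' CDS ends before the junction; enlarge n_residues")
  if (u + cds_len5 + 1L > total5) abort_input("5' CDS does not fit in the transcript")
  tx5 <- paste0(rand_seq(u), rand_cds(g5$n_residues), rand_seq(total5 - u - cds_len5))
  # ---- premature stop in the shifted frame ------------------------------
  stop_tx3 <- NA_integer_
  if (s != 0L && !is.na(config$premature_stop_offset)) {
    k <- config$premature_stop_offset
    stopifnot(k >= 1L)
    t_stop <- P3 - s + 3L * k
    if (t_stop + 3L > v3 + cds_len3 - 3L)
      abort_input("premature stop position falls beyond the 3' CDS")
    if (any(abs(t_stop - protected) < 3L))
      abort_input("premature stop would overwrite a planted start/stop codon")
    substr(tx3, t_stop + 1L, t_stop + 3L) <- "TAA"
    stop_tx3 <- t_stop
    # the off-grid TAA rewrites parts of two native codons; neither can
    # become a stop, but the downstream one can become a codon-aligned ATG
    # (e.g. planted ...A + "TG"), which would be a spurious rescue start
    for (cstart in (t_stop - 2L):(t_stop + 2L)) {
      if ((cstart - v3) %% 3L != 0L || cstart < v3) next
      if (substr(tx3, cstart + 1L, cstart + 3L) == "ATG" &&
          !any(cstart >= protected & cstart < protected + 3L)) {
        free <- setdiff(cstart:(cstart + 2L), t_stop:(t_stop + 2L))
        substr(tx3, free[length(free)] + 1L, free[length(free)] + 1L) <- "C"
      }
    }
    # clear any earlier stop on the shifted (ATG1) grid
    jc <- paste0(substr(tx5, L5 - s + 1L, L5), substr(tx3, P3 + 1L, P3 + 3L - s))
    if (jc %in% STOP_CODONS) {
      fixed <- FALSE
      for (q in P3:(P3 + 2L - s)) {
        if (!any(q >= protected & q < protected + 3L)) {
          substr(tx3, q + 1L, q + 1L) <- "C"; fixed <- TRUE; break
        }
      }
      if (!fixed) abort_input("cannot clear a stop codon spanning the junction")
    }
    t <- P3 - s + 3L
    while (t + 3L <= t_stop) {
      if (substr(tx3, t + 1L, t + 3L) %in% STOP_CODONS) {
        fixed <- FALSE
        for (q in t:(t + 2L)) {
          if (!any(q >= protected & q < protected + 3L)) {
            substr(tx3, q + 1L, q + 1L) <- "C"; fixed <- TRUE; break
          }
        }
        if (!fixed) abort_input("cannot clear a shifted-frame stop without damaging a planted codon")
      }
      t <- t + 3L
    }
  }
  # ---- genomic placement ------------------------------------------------
  placed5 <- place_gene(tx5, lens5, g5$strand)
  placed3 <- place_gene(tx3, lens3, g3$strand)
  genome <- Biostrings::DNAStringSet(c(placed5$contig_seq, placed3$contig_seq))
  names(genome) <- c(paste0(g5$contig, " seed=", config$seed %||% "NA"),
                     paste0(g3$contig, " seed=", config$seed %||% "NA"))
  names(genome) <- vapply(strsplit(names(genome), " "), `[[`, "", 1L)
  tx5_id <- paste0("TX_", g5$name); tx3_id <- paste0("TX_", g3$name)
  m5 <- new_transcript_model(paste0("G_", g5$name), g5$name, tx5_id, g5$contig, g5$strand,
                             placed5$exons, u, u + cds_len5)
  m3 <- new_transcript_model(paste0("G_", g3$name), g3$name, tx3_id, g3$contig, g3$strand,
                             placed3$exons, v3, v3 + cds_len3)
  models <- stats::setNames(list(m5, m3), c(tx5_id, tx3_id))
  domains <- data.frame(gene = toupper(g3$name), domain = g3$domain_name,
                        start_res = g3$domain_start, end_res = g3$domain_end,
                        stringsAsFactors = FALSE)
  meta <- list(config = config, tx5 = tx5, tx3 = tx3, u = u, v3 = v3,
               L5 = L5, P3 = P3, cds_len5 = cds_len5, cds_len3 = cds_len3,
               stop_tx3 = stop_tx3, lens5 = lens5, lens3 = lens3,
               tx5_id = tx5_id, tx3_id = tx3_id)
  ref <- list(genome = genome, models = models, domains = domains, meta = meta)
  if (!is.null(dir)) write_reference(ref, dir)
  ref
}

write_tsv_seeded <- function(df, path, seed) {
  con <- file(path, "w")
  writeLines(sprintf("## seed: %s", seed %||% "NA"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(path)
}

#' Write a toy reference to disk
#' @param ref from [make_toy_reference()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(ref$genome, file.path(dir, "genome.fa"))
  write_annotation(ref$models, file.path(dir, "annotation.gtf"))
  write_tsv_seeded(ref$domains, file.path(dir, "domains.tsv"), ref$meta$config$seed)
  invisible(dir)
}

# genomic (0-based) positions of the junction bases
fusion_breakpoints_genomic <- function(ref) {
  m5 <- ref$models[[ref$meta$tx5_id]]; m3 <- ref$models[[ref$meta$tx3_id]]
  b5 <- ref$meta$config$gene_5p$breakpoint_exon
  b3 <- ref$meta$config$gene_3p$breakpoint_exon
  e5 <- m5$exons[m5$exons$rank == b5, ]
  e3 <- m3$exons[m3$exons$rank == b3, ]
  pos5 <- if (m5$strand == "+") e5$end - 1L else e5$start       # last retained 5' base
  pos3 <- if (m3$strand == "+") e3$start else e3$end - 1L       # first retained 3' base
  list(pos5 = pos5, pos3 = pos3, m5 = m5, m3 = m3, b5 = b5, b3 = b3)
}

#' Engineer a fusion event from a toy reference
#'
#' Produces the chimeric cDNA by exon-boundary concatenation, the ground
#' truth the frame/rescue analysis must recover, and the corresponding
#' caller rows in all three dialects (the FusionCatcher-style row gets a
#' 2 nt intronic jitter to exercise breakpoint snapping and harmonization).
#'
#' @param ref from [make_toy_reference()]
#' @param dir optional directory: writes `calls_dialect_A/F/S.tsv`,
#'   `fusion_cdna.fa`, `ground_truth.json`
#' @return list: `fusion_id`, `cdna`, `truth`, `calls` (per-dialect
#'   one-row data.frames)
#' @export
engineer_fusion <- function(ref, dir = NULL) {
  cfg <- ref$meta$config
  bp <- fusion_breakpoints_genomic(ref)
  m5 <- bp$m5; m3 <- bp$m3
  L5 <- ref$meta$L5; P3 <- ref$meta$P3
  cdna <- paste0(substr(ref$meta$tx5, 1L, L5), substr(ref$meta$tx3, P3 + 1L, nchar(ref$meta$tx3)))
  s <- cfg$frame_shift
  g3 <- cfg$gene_3p
  rescue <- data.frame(residue = as.integer(g3$rescue_residues),
                       covered = g3$rescue_residues <= g3$domain_start,
                       stringsAsFactors = FALSE)
  truth <- list(fusion_id = paste0(cfg$gene_5p$name, "::", g3$name),
                status = if (s == 0L) "in_frame" else "out_of_frame",
                frame_shift = s,
                stop_distance_codons = if (s == 0L) NA_integer_ else cfg$premature_stop_offset,
                first_retained_residue = g3$first_retained_residue,
                junction_offset = L5,
                breakpoint_exon_5p = bp$b5, breakpoint_exon_3p = bp$b3,
                rescue = rescue)
  frame_label <- cfg$caller_frame_label %||%
    (if (s == 0L) "in-frame" else "out-of-frame")
  fmt1 <- function(contig, pos0) sprintf("%s:%d", contig, pos0 + 1L)
  fmt1s <- function(contig, pos0, strand) sprintf("%s:%d:%s", contig, pos0 + 1L, strand)
  jit5 <- if (m5$strand == "+") 2L else -2L
  jit3 <- if (m3$strand == "+") -2L else 2L
  calls <- list(
    dialect_A = data.frame(
      gene1 = cfg$gene_5p$name, gene2 = g3$name,
      strand1 = m5$strand, strand2 = m3$strand,
      breakpoint1 = fmt1(m5$contig, bp$pos5), breakpoint2 = fmt1(m3$contig, bp$pos3),
      split_reads1 = cfg$split_reads, split_reads2 = 0L,
      discordant_mates = cfg$spanning_pairs, reading_frame = frame_label,
      stringsAsFactors = FALSE),
    dialect_F = data.frame(
      gene_5p = cfg$gene_5p$name, gene_3p = g3$name,
      exon_5p = paste0("exon_", bp$b5), exon_3p = paste0("exon_", bp$b3),
      breakpoint_5p = fmt1s(m5$contig, bp$pos5 + jit5, m5$strand),
      breakpoint_3p = fmt1s(m3$contig, bp$pos3 + jit3, m3$strand),
      spanning_pairs = cfg$spanning_pairs, spanning_unique_reads = cfg$split_reads,
      predicted_effect = frame_label, stringsAsFactors = FALSE),
    dialect_S = data.frame(
      FusionName = paste0(cfg$gene_5p$name, "--", g3$name),
      JunctionReadCount = cfg$split_reads, SpanningFragCount = cfg$spanning_pairs,
      LeftBreakpoint = fmt1s(m5$contig, bp$pos5, m5$strand),
      RightBreakpoint = fmt1s(m3$contig, bp$pos3, m3$strand),
      stringsAsFactors = FALSE))
  out <- list(fusion_id = truth$fusion_id, cdna = cdna, truth = truth, calls = calls)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (d in names(calls))
      write_tsv_seeded(calls[[d]], file.path(dir, sprintf("calls_%s.tsv", d)), cfg$seed)
    writeLines(c(sprintf(">%s|engineered_fusion|seed=%s", truth$fusion_id, cfg$seed %||% "NA"), cdna),
               file.path(dir, "fusion_cdna.fa"))
    jsonlite::write_json(c(list(seed = cfg$seed), truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' Simulate one per-exon count profile
#'
#' Negative-binomial counts with mean `baseline_mean` on lost exons and
#' `baseline_mean * fold_change` on retained-side exons (5' partner: exon
#' ranks up to and including the breakpoint exon; 3' partner: the
#' breakpoint exon onward). `dispersion = 0` gives the Poisson limit.
#'
#' @param n_exons number of exons
#' @param breakpoint_exon_rank breakpoint-containing exon
#' @param retained_side `"five_prime"` or `"three_prime"`
#' @param baseline_mean,fold_change,dispersion count model parameters
#' @return integer vector of counts, rank order
#' @export
simulate_exon_profile <- function(n_exons, breakpoint_exon_rank, retained_side,
                                  baseline_mean = 50, fold_change = 10, dispersion = 0.1) {
  stopifnot(fold_change > 0, dispersion >= 0)
  retained <- if (retained_side == "five_prime") seq_len(n_exons) <= breakpoint_exon_rank
              else seq_len(n_exons) >= breakpoint_exon_rank
  mu <- ifelse(retained, baseline_mean * fold_change, baseline_mean)
  if (dispersion == 0) stats::rpois(n_exons, mu)
  else stats::rnbinom(n_exons, size = 1 / dispersion, mu = mu)
}

#' Simulate exon-level count tables for a fusion
#'
#' @param ref from [make_toy_reference()]
#' @param path optional output TSV
#' @param fold_change override of the configured fold change (e.g. 1 for a
#'   null profile)
#' @return data.frame with columns gene, transcript, contig, start, end,
#'   strand, count (rows in genomic order)
#' @export
simulate_exon_counts <- function(ref, path = NULL, fold_change = NULL) {
  cfg <- ref$meta$config
  fc <- fold_change %||% cfg$counts$fold_change
  rows <- list()
  spec <- list(list(m = ref$models[[ref$meta$tx5_id]], b = cfg$gene_5p$breakpoint_exon, side = "five_prime"),
               list(m = ref$models[[ref$meta$tx3_id]], b = cfg$gene_3p$breakpoint_exon, side = "three_prime"))
  for (sp in spec) {
    m <- sp$m
    counts <- simulate_exon_profile(nrow(m$exons), sp$b, sp$side,
                                    cfg$counts$baseline_mean, fc, cfg$counts$dispersion)
    df <- data.frame(gene = m$gene_name, transcript = m$transcript_id, contig = m$contig,
                     start = m$exons$start + 1L, end = m$exons$end, strand = m$strand,
                     count = counts, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- df[order(df$start), , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(path)) write_tsv_seeded(out, path, cfg$seed)
  out
}
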