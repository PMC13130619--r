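#' Load a reference genome from FASTA
#'
#' Reads a (possibly soft-masked) multi-record FASTA into memory and
#' uppercases all bases, since downstream junction arithmetic and codon
#' matching are case-sensitive. Contig names are taken as the first
#' whitespace-delimited token of each header.
#'
#' @param path path to a FASTA file
#' @return a [Biostrings::DNAStringSet] keyed by contig name
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("genome FASTA not found: %s", path))
  gen <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) abort_input(sprintf("malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(gen) == 0L) abort_input(sprintf("FASTA '%s' contains no records", path))
  names(gen) <- vapply(strsplit(names(gen), "\\s+"), `[[`, "", 1L)
  if (anyDuplicated(names(gen)))
    abort_input(sprintf("duplicate contig name in '%s': %s", path,
                        names(gen)[duplicated(names(gen))][1]))
  Biostrings::DNAStringSet(toupper(gen))
}

#' Extract an interval from a loaded genome
#'
#' Coordinates are 0-based half-open (internal convention); the returned
#' string has exactly `end - start` bases.
#'
#' @param genome a DNAStringSet from [read_genome()]
#' @param contig contig name
#' @param start,end 0-based half-open interval
#' @return nucleotide string
#' @export
genome_seq <- function(genome, contig, start, end) {
  if (!contig %in% names(genome)) abort_input(sprintf("contig '%s' not in genome", contig))
  len <- length(genome[[contig]])
  if (!(is.numeric(start) && is.numeric(end)) || start < 0 || end > len || start > end)
    abort_input(sprintf("interval [%s,%s) out of bounds for contig '%s' (length %d)",
                        format(start), format(end), contig, len))
  if (start == end) return("")
  as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
}

new_transcript_model <- function(gene_id, gene_name, transcript_id, contig, strand,
                                 exons, cds_start = NA_integer_, cds_end = NA_integer_) {
  structure(list(gene_id = gene_id, gene_name = gene_name,
                 transcript_id = transcript_id, contig = contig, strand = strand,
                 exons = exons, cds_start = cds_start, cds_end = cds_end),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding" else sprintf("CDS [%d,%d)", x$cds_start, x$cds_end)
  cat(sprintf("<transcript_model> %s (%s) %s:%s strand %s, %d exons, %s\n",
              x$transcript_id, x$gene_name, x$contig,
              paste0(min(x$exons$start), "-", max(x$exons$end)),
              x$strand, nrow(x$exons), cds))
  invisible(x)
}

# cumulative transcript offsets of exon starts (0-based), rank order
exon_cumlen <- function(model) {
  w <- model$exons$end - model$exons$start
  c(0L, cumsum(w))[seq_along(w)]
}

transcript_length <- function(model) sum(model$exons$end - model$exons$start)

# transcript offset (0-based) of a genomic base (0-based); NA if not exonic
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  cum <- exon_cumlen(model)
  hit <- which(gpos >= ex$start & gpos < ex$end)
  if (length(hit) == 0L) return(NA_integer_)
  i <- hit[1]
  if (model$strand == "+") cum[i] + (gpos - ex$start[i]) else cum[i] + (ex$end[i] - 1L - gpos)
}

#' Read transcript models from a GTF annotation
#'
#' Parses exon (and optional CDS) features grouped by `transcript_id`.
#' Exons are ordered 5'->3' in transcript orientation (rank 1 is the
#' leftmost exon for `+` strand genes, the rightmost for `-`). The CDS
#' span is converted to 0-based half-open transcript coordinates; for
#' models written by this package the CDS includes the stop codon.
#' Coding spans whose length is not a multiple of 3 are kept but flagged
#' with a warning (annotation may be 5'/3' truncated).
#'
#' @param path path to a GTF file (Ensembl-style attributes)
#' @return named list of `transcript_model` objects keyed by transcript_id
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("annotation GTF not found: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) abort_input(sprintf("malformed GTF '%s': %s", path, conditionMessage(e))))
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  tx_ids <- unique(stats::na.omit(md$transcript_id))
  models <- list()
  for (tx in tx_ids) {
    sel <- which(md$transcript_id == tx)
    sub <- gr[sel]
    smd <- S4Vectors::mcols(sub)
    ex <- sub[smd$type == "exon"]
    if (length(ex) == 0L) { warning(sprintf("transcript '%s' has no exon features; skipped", tx)); next }
    strands <- unique(as.character(BiocGenerics::strand(sub)))
    if (length(strands) != 1L)
      abort_input(sprintf("transcript '%s' has conflicting strands: %s", tx, paste(strands, collapse = ",")))
    strand <- strands
    contig <- as.character(GenomicRanges::seqnames(ex))[1]
    # 0-based half-open genomic intervals, rank-ordered in transcript orientation
    df <- data.frame(start = BiocGenerics::start(ex) - 1L, end = BiocGenerics::end(ex))
    df <- df[order(df$start, decreasing = (strand == "-")), , drop = FALSE]
    gs <- df[order(df$start), , drop = FALSE]
    if (nrow(gs) > 1L && any(gs$end[-nrow(gs)] > gs$start[-1]))
      abort_input(sprintf("transcript '%s' has overlapping exons", tx))
    df$rank <- seq_len(nrow(df))
    rownames(df) <- NULL
    emd <- S4Vectors::mcols(ex)
    gene_id <- as.character(emd$gene_id[1] %||% NA_character_)
    gene_name <- as.character(emd$gene_name[1] %||% gene_id)
    model <- new_transcript_model(gene_id, gene_name, tx, contig, strand, df)
    cds <- sub[smd$type == "CDS"]
    if (length(cds) > 0L) {
      gpos <- c(BiocGenerics::start(cds) - 1L, BiocGenerics::end(cds) - 1L)
      toff <- vapply(gpos, function(g) genomic_to_transcript(model, g), integer(1))
      if (anyNA(toff)) abort_input(sprintf("CDS of transcript '%s' falls outside its exons", tx))
      model$cds_start <- min(toff)
      model$cds_end <- max(toff) + 1L
      if ((model$cds_end - model$cds_start) %% 3L != 0L)
        warning(sprintf("CDS length of transcript '%s' is not a multiple of 3 (possibly truncated)", tx))
    }
    models[[tx]] <- model
  }
  models
}

# transcript range [t0, t1) -> list of genomic 0-based half-open blocks
transcript_to_genomic_blocks <- function(model, t0, t1) {
  ex <- model$exons
  cum <- exon_cumlen(model)
  w <- ex$end - ex$start
  blocks <- list()
  for (i in seq_len(nrow(ex))) {
    a <- max(t0, cum[i]); b <- min(t1, cum[i] + w[i])
    if (a >= b) next
    if (model$strand == "+") {
      blocks[[length(blocks) + 1L]] <- c(ex$start[i] + (a - cum[i]), ex$start[i] + (b - cum[i]))
    } else {
      blocks[[length(blocks) + 1L]] <- c(ex$end[i] - (b - cum[i]), ex$end[i] - (a - cum[i]))
    }
  }
  blocks
}

#' Write transcript models to GTF
#'
#' Inverse of [read_annotation()]: emits gene/transcript/exon/CDS rows with
#' Ensembl-style attributes, converting internal 0-based half-open
#' coordinates back to 1-based inclusive GTF.
#'
#' @param models named list of `transcript_model`
#' @param path output path
#' @return invisibly, the path
#' @export
write_annotation <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attr_base <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                         m$gene_id, m$gene_name, m$transcript_id)
    g0 <- min(m$exons$start); g1 <- max(m$exons$end)
    lines <- c(lines,
               sprintf('%s\torfrescue\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
                       m$contig, g0 + 1L, g1, m$strand, m$gene_id, m$gene_name),
               sprintf("%s\torfrescue\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       m$contig, g0 + 1L, g1, m$strand, attr_base))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, sprintf('%s\torfrescue\texon\t%d\t%d\t.\t%s\t.\t%s exon_number "%d";',
                                m$contig, m$exons$start[i] + 1L, m$exons$end[i],
                                m$strand, attr_base, m$exons$rank[i]))
    }
    if (!is.na(m$cds_start)) {
      for (b in transcript_to_genomic_blocks(m, m$cds_start, m$cds_end)) {
        lines <- c(lines, sprintf("%s\torfrescue\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                  m$contig, b[1] + 1L, b[2], m$strand, attr_base))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Spliced transcript sequence
#'
#' Concatenates exon sequences in rank (5'->3') order; minus-strand exons
#' are reverse-complemented so the result reads in transcript orientation.
#'
#' @param model a `transcript_model`
#' @param genome a DNAStringSet from [read_genome()]
#' @return nucleotide string of length `sum(exon lengths)`
#' @export
spliced_sequence <- function(model, genome) {
  if (!model$contig %in% names(genome))
    abort_input(sprintf("contig '%s' (transcript %s) not in genome", model$contig, model$transcript_id))
  parts <- vapply(seq_len(nrow(model$exons)), function(i) {
    s <- genome_seq(genome, model$contig, model$exons$start[i], model$exons$end[i])
    if (model$strand == "-") revcomp(s) else s
  }, character(1))
  paste(parts, collapse = "")
}

#' Read a protein-domain coordinate table
#'
#' Tab-separated with header columns `gene`, `domain`, `start_res`,
#' `end_res` (1-based inclusive residues on the wild-type protein).
#' Unknown columns are ignored; rows with `start_res > end_res` are
#' rejected with a message.
#'
#' @param path TSV path
#' @return data.frame with columns gene, domain, start_res, end_res
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("domain table not found: %s", path))
  df <- read_tsv_table(path)
  need <- c("gene", "domain", "start_res", "end_res")
  if (!all(need %in% names(df)))
    abort_input(sprintf("domain table '%s' must have columns %s", path, paste(need, collapse = ", ")))
  df <- df[need]
  df$start_res <- as.integer(df$start_res); df$end_res <- as.integer(df$end_res)
  bad <- is.na(df$start_res) | is.na(df$end_res) | df$start_res < 1L | df$start_res > df$end_res
  if (any(bad)) {
    warning(sprintf("rejected %d domain row(s) with invalid residue range (e.g. gene %s)",
                    sum(bad), df$gene[which(bad)[1]]))
    df <- df[!bad, , drop = FALSE]
  }
  df$gene <- toupper(df$gene)
  rownames(df) <- NULL
  df
}

#' Read a druggable-kinase gene list
#'
#' Accepts either a one-gene-per-line text file or a TSV whose first column
#' (optionally headed `gene`) is the gene symbol; a second column, if
#' present, is kept as a note. Names are uppercased and deduplicated.
#'
#' @param path file path
#' @return character vector of gene symbols (a `note` attribute carries any
#'   second column)
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("gene list not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw)) & !startsWith(trimws(raw), "#")]
  if (length(raw) == 0L) abort_input(sprintf("gene list '%s' is empty", path))
  fields <- strsplit(raw, "\t", fixed = TRUE)
  genes <- toupper(trimws(vapply(fields, `[[`, "", 1L)))
  notes <- vapply(fields, function(f) if (length(f) > 1L) f[[2]] else NA_character_, character(1))
  if (identical(genes[1], "GENE")) { genes <- genes[-1]; notes <- notes[-1] }
  if (length(genes) == 0L) abort_input(sprintf("gene list '%s' is empty", path))
  keep <- !duplicated(genes)
  structure(genes[keep], note = notes[keep])
}

#' Built-in default druggable-kinase gene list
#'
#' A conservative set of kinases with approved or late-stage inhibitors,
#' intended as an editable starting point (the triage criterion only asks
#' whether the 3' fusion partner is on this list). Users with their own
#' actionability list should supply it via [read_gene_list()].
#'
#' @return character vector of gene symbols
#' @export
default_kinase_genes <- function() {
  c("ALK", "RET", "ROS1", "NTRK1", "NTRK2", "NTRK3", "LTK", "EGFR", "BRAF",
    "RAF1", "MET", "KIT", "PDGFRA", "PDGFRB", "FGFR1", "FGFR2", "FGFR3",
    "FGFR4", "ERBB2", "ABL1", "JAK2", "FLT3", "MAP2K1", "DDR2", "SYK")
}

# pick the transcript for a gene: caller-named transcript if resolvable,
# else the longest CDS, else the longest transcript
resolve_transcript <- function(models, gene_name, transcript_id = NULL) {
  if (!is.null(transcript_id) && !is.na(transcript_id) && transcript_id %in% names(models))
    return(models[[transcript_id]])
  cand <- Filter(function(m) identical(m$gene_name, gene_name), models)
  if (length(cand) == 0L) return(NULL)
  cds_len <- vapply(cand, function(m) if (is.na(m$cds_start)) -1L else m$cds_end - m$cds_start, integer(1))
  if (all(cds_len < 0L)) {
    tx_len <- vapply(cand, transcript_length, integer(1))
    return(cand[[which.max(tx_len)]])
  }
  cand[[which.max(cds_len)]]
}
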