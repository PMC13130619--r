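#' @name frame_rescue
#' @title Chimeric transcript reconstruction, frame classification and ORF rescue
#' @description
#' An out-of-frame fusion junction usually puts a stop codon a few codons
#' downstream of the breakpoint, and such transcripts are routinely
#' filtered as nonfunctional. Translation can nevertheless re-initiate at
#' a downstream ATG; when that ATG sits on the 3' partner's native codon
#' grid the ribosome reproduces the wild-type downstream protein, kinase
#' domain included. This module reconstructs the chimeric cDNA, classifies
#' the junction frame, locates the premature stop, and enumerates
#' downstream ATG start candidates with their frame and kinase-domain
#' coverage.
NULL

# map a 0-based genomic breakpoint to a transcript offset, snapping to the
# nearest exon boundary within snap_tol when the position is intronic.
# side = "last_retained" (5' partner: returned offset is one past the base,
# i.e. the fragment length) or "first_retained" (3' partner).
breakpoint_to_offset <- function(model, gpos, side, snap_tol = 10L) {
  toff <- genomic_to_transcript(model, gpos)
  if (is.na(toff)) {
    ex <- model$exons
    bounds <- c(ex$start, ex$end - 1L)  # genomic first/last base of each exon
    d <- abs(bounds - gpos)
    i <- which.min(d)
    if (d[i] > snap_tol)
      abort_input(sprintf("breakpoint %s:%d of %s is intronic and > %d nt from any exon boundary",
                          model$contig, gpos, model$transcript_id, snap_tol))
    toff <- genomic_to_transcript(model, bounds[i])
  }
  if (side == "last_retained") toff + 1L else toff
}

#' Reconstruct a chimeric fusion transcript
#'
#' Concatenates the 5' partner's spliced sequence through the breakpoint
#' with the 3' partner's spliced sequence from the breakpoint onward.
#' Breakpoints at (or within `snap_tol` of) annotated exon boundaries
#' retain the full exon on the retained side. The result records the
#' junction offset, the 5' partner's annotated start codon (ATG1) when it
#' is retained, the native codon phase of the first retained 3'-partner
#' base (0 = codon start), and the wild-type residue number of the first
#' fully retained 3' codon.
#'
#' @param fusion a `harmonized_fusion` (or `fusion_call`) with 5'/3'
#'   breakpoints
#' @param models annotation list from [read_annotation()]
#' @param genome genome from [read_genome()]
#' @param snap_tol intronic-breakpoint snap tolerance in nt (default 10)
#' @return a `fusion_transcript` object
#' @export
build_fusion_transcript <- function(fusion, models, genome, snap_tol = 10L) {
  m5 <- resolve_transcript(models, fusion$gene_5p %||% fusion$five_prime$gene_name,
                           (fusion$breakpoint_5p %||% fusion$five_prime)$transcript_id)
  m3 <- resolve_transcript(models, fusion$gene_3p %||% fusion$three_prime$gene_name,
                           (fusion$breakpoint_3p %||% fusion$three_prime)$transcript_id)
  bp5 <- fusion$breakpoint_5p %||% fusion$five_prime
  bp3 <- fusion$breakpoint_3p %||% fusion$three_prime
  if (is.null(m5)) abort_input(sprintf("5' partner '%s' not found in annotation", bp5$gene_name))
  if (is.null(m3)) abort_input(sprintf("3' partner '%s' not found in annotation", bp3$gene_name))
  if (is.na(m3$cds_start))
    abort_input(sprintf("3' partner transcript '%s' is non-coding; frame analysis undefined", m3$transcript_id))
  seq5 <- spliced_sequence(m5, genome)
  seq3 <- spliced_sequence(m3, genome)
  t5_end <- breakpoint_to_offset(m5, bp5$position, "last_retained", snap_tol)
  t3_start <- breakpoint_to_offset(m3, bp3$position, "first_retained", snap_tol)
  if (t5_end <= 0L || t5_end > nchar(seq5))
    abort_input(sprintf("5' breakpoint maps outside transcript %s", m5$transcript_id))
  if (t3_start < 0L || t3_start >= nchar(seq3))
    abort_input(sprintf("3' breakpoint maps outside transcript %s", m3$transcript_id))
  sequence <- paste0(substr(seq5, 1L, t5_end), substr(seq3, t3_start + 1L, nchar(seq3)))
  junction_offset <- t5_end
  cds_start_5p <- if (!is.na(m5$cds_start) && m5$cds_start < junction_offset) m5$cds_start else NA_integer_
  native_phase_3p <- ((t3_start - m3$cds_start) %% 3L + 3L) %% 3L
  three_prime_protein_offset <- if (t3_start <= m3$cds_start) 1L
    else (t3_start - m3$cds_start) %/% 3L + (if (native_phase_3p == 0L) 1L else 2L)
  structure(list(
    sequence = sequence,
    junction_offset = junction_offset,
    gene_5p = m5$gene_name, gene_3p = m3$gene_name,
    transcript_5p = m5$transcript_id, transcript_3p = m3$transcript_id,
    cds_start_5p = cds_start_5p,
    t3_start = t3_start,
    cds_start_3p = m3$cds_start, cds_end_3p = m3$cds_end,
    native_phase_3p = native_phase_3p,
    three_prime_protein_offset = three_prime_protein_offset,
    breakpoint_exon_5p = exon_rank_of_offset(m5, t5_end - 1L),
    breakpoint_exon_3p = exon_rank_of_offset(m3, t3_start)),
    class = "fusion_transcript")
}

# exon rank containing a transcript offset
exon_rank_of_offset <- function(model, toff) {
  cum <- exon_cumlen(model)
  w <- model$exons$end - model$exons$start
  hit <- which(toff >= cum & toff < cum + w)
  if (length(hit) == 0L) NA_integer_ else model$exons$rank[hit[1]]
}

#' @export
print.fusion_transcript <- function(x, ...) {
  cat(sprintf("<fusion_transcript> %s::%s length %d, junction @%d (exon %s | exon %s), native 3' phase %d, first retained residue %d\n",
              x$gene_5p, x$gene_3p, nchar(x$sequence), x$junction_offset,
              x$breakpoint_exon_5p, x$breakpoint_exon_3p,
              x$native_phase_3p, x$three_prime_protein_offset))
  invisible(x)
}

# fusion-transcript offset of the 3' CDS end (one past the stop codon)
fusion_cds_end_3p <- function(ft) ft$junction_offset + (ft$cds_end_3p - ft$t3_start)

#' Classify the reading frame of a fusion junction
#'
#' Translating from the 5' partner's annotated start codon (ATG1), the
#' junction is in frame when the translated codon grid lands on the 3'
#' partner's native codon grid (`(junction_offset - cds_start_5p) mod 3`
#' equals the native phase of the first retained 3' base) and no stop is
#' encountered before the 3' CDS end; otherwise it is out of frame.
#' `stop_distance_codons` counts the complete codons at or past the
#' junction up to and including the first stop (0 when the first stop
#' spans the junction itself). When the breakpoint lies upstream of the
#' 5' start codon the verdict is indeterminate.
#'
#' @param ft a `fusion_transcript`
#' @return a `frame_verdict` list: `status`
#'   (`in_frame | out_of_frame | indeterminate`), `stop_distance_codons`,
#'   `stop_offset`, `phase_match`
#' @export
classify_frame <- function(ft) {
  if (is.na(ft$cds_start_5p))
    return(structure(list(status = "indeterminate", stop_distance_codons = NA_integer_,
                          stop_offset = NA_integer_, phase_match = NA), class = "frame_verdict"))
  phase5 <- (ft$junction_offset - ft$cds_start_5p) %% 3L
  phase_match <- phase5 == ft$native_phase_3p
  stop1 <- first_stop_at(ft$sequence, ft$cds_start_5p + 1L)  # 1-based
  stop_off <- if (is.na(stop1)) NA_integer_ else stop1 - 1L  # 0-based
  cds_end_fus <- fusion_cds_end_3p(ft)
  in_frame <- phase_match && !is.na(stop_off) && (stop_off + 3L) == cds_end_fus
  if (isTRUE(phase_match) && is.na(stop_off)) in_frame <- TRUE  # no stop anywhere: annotation-truncated CDS
  sdc <- NA_integer_
  if (!in_frame && !is.na(stop_off)) {
    # first codon start at or past the junction, on the ATG1 grid
    c0 <- ft$cds_start_5p + 3L * ((ft$junction_offset - ft$cds_start_5p + 2L) %/% 3L)
    sdc <- if (stop_off < c0) 0L else (stop_off - c0) %/% 3L + 1L
  }
  structure(list(status = if (in_frame) "in_frame" else "out_of_frame",
                 stop_distance_codons = sdc, stop_offset = stop_off,
                 phase_match = phase_match), class = "frame_verdict")
}

#' @export
print.frame_verdict <- function(x, ...) {
  cat(sprintf("<frame_verdict> %s%s\n", x$status,
              if (!is.na(x$stop_distance_codons))
                sprintf(" (stop %d codon(s) past the junction)", x$stop_distance_codons) else ""))
  invisible(x)
}

#' Map a fusion-transcript offset to a wild-type 3' protein residue
#'
#' For an offset at or past the junction that lies on the 3' partner's
#' native codon grid, returns the 1-based residue index of the wild-type
#' 3' protein whose codon begins at that offset.
#'
#' @param ft a `fusion_transcript`
#' @param offset 0-based offset in the fusion transcript
#' @return integer residue number
#' @export
map_offset_to_residue <- function(ft, offset) {
  if (offset < ft$junction_offset) abort_input("offset is upstream of the junction")
  t3 <- ft$t3_start + (offset - ft$junction_offset)
  if ((t3 - ft$cds_start_3p) %% 3L != 0L)
    abort_input(sprintf("offset %d is off the native 3' codon grid; residue undefined", offset))
  if (t3 < ft$cds_start_3p) abort_input("offset lies upstream of the 3' CDS")
  as.integer((t3 - ft$cds_start_3p) %/% 3L + 1L)
}

#' Scan for downstream alternative translation starts
#'
#' Enumerates every ATG at or past the junction, in transcript order, plus
#' the 5' partner's annotated start codon (ATG1) when retained. Each
#' candidate is annotated with whether it is frame-restoring (on the 3'
#' partner's native codon grid, so translation from it reproduces the
#' wild-type downstream protein), its ORF end and protein length, the
#' wild-type residue it corresponds to (frame-restoring starts only), and
#' whether the ORF covers a complete kinase domain of the 3' partner.
#' Successive frame-restoring downstream starts are labeled ATG2, ATG3,
#' ...; non-restoring starts are reported unlabeled. The list is truncated
#' after `max_starts` frame-restoring entries (non-restoring entries up to
#' the same offset are kept).
#'
#' @param ft a `fusion_transcript`
#' @param domains domain table from [read_domain_table()] (may be empty)
#' @param max_starts maximum number of frame-restoring starts to report
#' @return data.frame with one row per candidate start: `start_offset`,
#'   `start_label`, `frame_restoring`, `stop_offset`, `protein_length_aa`,
#'   `wildtype_start_residue`, `kinase_domain_covered`
#' @export
scan_downstream_starts <- function(ft, domains = NULL, max_starts = 10L) {
  stopifnot(max_starts >= 1L)
  dom <- if (is.null(domains) || nrow(domains) == 0L) NULL
         else domains[domains$gene == toupper(ft$gene_3p), , drop = FALSE]
  cds_end_fus <- fusion_cds_end_3p(ft)
  seqlen <- nchar(ft$sequence)

  orf_row <- function(off, label) {
    stop1 <- first_stop_at(ft$sequence, off + 1L)
    stop_off <- if (is.na(stop1)) NA_integer_ else stop1 - 1L
    prot_len <- if (is.na(stop_off)) (seqlen - off) %/% 3L else (stop_off - off) %/% 3L
    t3 <- ft$t3_start + (off - ft$junction_offset)
    # a rescue start must sit on the native codon grid, within the coding
    # region proper (a grid-aligned ATG in the 3' UTR restores nothing)
    restoring <- off >= ft$junction_offset &&
      t3 >= ft$cds_start_3p && t3 <= ft$cds_end_3p - 6L &&
      (t3 - ft$cds_start_3p) %% 3L == 0L
    wt_res <- if (restoring) as.integer((t3 - ft$cds_start_3p) %/% 3L + 1L) else NA_integer_
    covered <- FALSE
    if (restoring && !is.null(dom) && nrow(dom) > 0L) {
      last_res <- wt_res + prot_len - 1L
      covered <- any(wt_res <= dom$start_res & last_res >= dom$end_res)
    }
    data.frame(start_offset = off, start_label = label, frame_restoring = restoring,
               stop_offset = stop_off, protein_length_aa = prot_len,
               wildtype_start_residue = wt_res, kinase_domain_covered = covered,
               stringsAsFactors = FALSE)
  }

  rows <- list()
  if (!is.na(ft$cds_start_5p)) {
    r <- orf_row(ft$cds_start_5p, "ATG1")
    # ATG1 restores the 3' frame only if the whole junction is in frame
    r$frame_restoring <- identical(classify_frame(ft)$status, "in_frame")
    r$wildtype_start_residue <- NA_integer_
    # in-frame ATG1 runs to the annotated 3' stop, so coverage reduces to
    # the junction lying upstream of the complete domain
    r$kinase_domain_covered <- r$frame_restoring && !is.null(dom) && nrow(dom) > 0L &&
      any(ft$three_prime_protein_offset <= dom$start_res)
    rows[[1]] <- r
  }
  hits <- Biostrings::matchPattern("ATG", Biostrings::DNAString(ft$sequence))
  offs <- BiocGenerics::start(hits) - 1L
  offs <- offs[offs >= ft$junction_offset]
  n_restoring <- 0L
  for (off in offs) {
    r <- orf_row(off, NA_character_)
    if (r$frame_restoring) {
      n_restoring <- n_restoring + 1L
      if (n_restoring > max_starts) break
      r$start_label <- paste0("ATG", n_restoring + 1L)
    }
    rows[[length(rows) + 1L]] <- r
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- orf_row(integer(0), character(0))[0, ]
  rownames(out) <- NULL
  out
}

#' Predicted protein sequence from a candidate start
#'
#' @param ft a `fusion_transcript`
#' @param start_offset 0-based start offset (e.g. from
#'   [scan_downstream_starts()])
#' @return amino-acid string, translation stopping before the first stop
#'   codon
#' @export
orf_protein <- function(ft, start_offset) {
  aa <- translate_nt(substr(ft$sequence, start_offset + 1L, nchar(ft$sequence)))
  sub("\\*.*$", "", aa)
}

#' Export fusion transcript and predicted ORFs as FASTA
#'
#' Writes the chimeric cDNA and, for each predicted start, the peptide,
#' with headers encoding start label, wild-type start residue and domain
#' coverage.
#'
#' @param ft a `fusion_transcript`
#' @param starts data.frame from [scan_downstream_starts()]
#' @param path output FASTA path
#' @return invisibly, the path
#' @export
write_orf_fasta <- function(ft, starts, path) {
  lines <- c(sprintf(">%s::%s|fusion_cdna|junction=%d", ft$gene_5p, ft$gene_3p, ft$junction_offset),
             ft$sequence)
  for (i in seq_len(nrow(starts))) {
    s <- starts[i, ]
    lines <- c(lines,
               sprintf(">%s::%s|%s|offset=%d|frame_restoring=%s|wt_start_residue=%s|kinase_domain_covered=%s",
                       ft$gene_5p, ft$gene_3p, s$start_label %||% "unlabeled", s$start_offset,
                       s$frame_restoring, s$wildtype_start_residue %||% "NA", s$kinase_domain_covered),
               orf_protein(ft, s$start_offset))
  }
  writeLines(lines, path)
  invisible(path)
}
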