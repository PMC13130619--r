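#' @name fusion_calls
#' @title Fusion caller table parsing and harmonization
#' @description
#' Three widely used RNA-seq fusion callers report the same event with
#' different column schemas and slightly different breakpoint coordinates.
#' `read_fusion_calls()` normalizes any of the three dialects into a common
#' breakpoint model; `harmonize_calls()` merges calls of the same ordered
#' gene pair whose breakpoints agree within a window, yielding per-event
#' cross-caller concordance counts; `check_in_strand()` tests whether the
#' reported orientation is compatible with one sense chimeric transcript.
NULL

normalize_frame_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("in-frame", "in_frame", "inframe")] <- "in_frame"
  out[x %in% c("out-of-frame", "out_of_frame", "frameshift", "stop-codon",
               "stop_codon", "premature_stop", "out-of-frame.")] <- "out_of_frame"
  out
}

parse_locus <- function(x, what) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L) abort_input(sprintf("cannot parse %s locus '%s'", what, x))
  pos <- suppressWarnings(as.integer(parts[2]))
  if (is.na(pos)) abort_input(sprintf("cannot parse %s position in '%s'", what, x))
  strand <- if (length(parts) >= 3L && parts[3] %in% c("+", "-")) parts[3] else NA_character_
  # caller coordinates are 1-based; internal are 0-based
  list(contig = parts[1], position = pos - 1L, strand = strand)
}

new_breakpoint <- function(contig, position, gene_name, retained_side,
                           strand = NA_character_, transcript_id = NA_character_,
                           exon_rank = NA_integer_) {
  structure(list(contig = contig, position = as.integer(position),
                 gene_name = gene_name, transcript_id = transcript_id,
                 exon_rank = exon_rank, retained_side = retained_side,
                 strand = strand),
            class = "breakpoint")
}

new_fusion_call <- function(five_prime, three_prime, caller_name,
                            split_reads, spanning_pairs, caller_frame_prediction) {
  stopifnot(identical(five_prime$retained_side, "five_prime"),
            identical(three_prime$retained_side, "three_prime"))
  structure(list(five_prime = five_prime, three_prime = three_prime,
                 caller_name = caller_name,
                 split_reads = as.integer(split_reads),
                 spanning_pairs = as.integer(spanning_pairs),
                 caller_frame_prediction = caller_frame_prediction),
            class = "fusion_call")
}

#' @export
print.fusion_call <- function(x, ...) {
  cat(sprintf("<fusion_call> %s::%s [%s] %s:%d | %s:%d split=%d span=%d frame=%s\n",
              x$five_prime$gene_name, x$three_prime$gene_name, x$caller_name,
              x$five_prime$contig, x$five_prime$position,
              x$three_prime$contig, x$three_prime$position,
              x$split_reads, x$spanning_pairs, x$caller_frame_prediction))
  invisible(x)
}

# TSV reader skipping "##" comment lines (used for embedded seed headers);
# a single leading "#" on the header row (Arriba convention) is stripped.
read_tsv_table <- function(path) {
  if (!file.exists(path)) abort_input(sprintf("table not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^##", lines)]
  if (length(lines) <= 1L && (length(lines) == 0L || !grepl("\t", lines[1])))
    return(data.frame())
  df <- utils::read.delim(text = paste(lines, collapse = "\n"), sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- sub("^#", "", names(df))
  df
}

int_or_zero <- function(x, what, warn_missing = TRUE) {
  if (is.null(x)) {
    if (warn_missing) warning(sprintf("missing evidence column %s; defaulting to 0", what))
    return(0L)
  }
  v <- suppressWarnings(as.integer(x))
  v[is.na(v)] <- 0L
  v
}

#' Read a fusion caller output table
#'
#' Supported dialects:
#' \describe{
#'   \item{dialect_A}{Arriba-style: `gene1, gene2, strand1, strand2,
#'     breakpoint1, breakpoint2` (`contig:position`), `split_reads1,
#'     split_reads2, discordant_mates, reading_frame`.}
#'   \item{dialect_F}{FusionCatcher-style: `gene_5p, gene_3p, exon_5p,
#'     exon_3p, breakpoint_5p, breakpoint_3p` (`contig:position:strand`),
#'     `spanning_pairs, spanning_unique_reads, predicted_effect`.}
#'   \item{dialect_S}{STAR-Fusion-style: `FusionName` (`A--B`),
#'     `JunctionReadCount, SpanningFragCount, LeftBreakpoint,
#'     RightBreakpoint` (`contig:position:strand`).}
#' }
#' Caller positions are 1-based and converted to the internal 0-based
#' convention; the 5' breakpoint is the last retained base of the 5'
#' partner and the 3' breakpoint the first retained base of the 3' partner.
#' Caller reading-frame vocabulary is normalized to
#' `in_frame | out_of_frame | unknown` (stop-codon flavored labels count as
#' out_of_frame); missing evidence columns default to 0 with a warning.
#'
#' @param path TSV path
#' @param dialect one of `"dialect_A"`, `"dialect_F"`, `"dialect_S"`
#' @param caller_name optional caller label; defaults to the dialect's tool
#' @return list of `fusion_call` objects
#' @export
read_fusion_calls <- function(path, dialect, caller_name = NULL) {
  if (!dialect %in% c("dialect_A", "dialect_F", "dialect_S"))
    abort_input(sprintf("unknown dialect '%s'", dialect))
  df <- read_tsv_table(path)
  if (nrow(df) == 0L) return(list())
  caller <- caller_name %||% switch(dialect, dialect_A = "arriba",
                                    dialect_F = "fusioncatcher", dialect_S = "starfusion")
  calls <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, , drop = FALSE]
    call <- tryCatch(switch(dialect,
      dialect_A = {
        b1 <- parse_locus(row$breakpoint1, "breakpoint1")
        b2 <- parse_locus(row$breakpoint2, "breakpoint2")
        new_fusion_call(
          new_breakpoint(b1$contig, b1$position, row$gene1, "five_prime",
                         strand = as.character(row$strand1 %||% NA)),
          new_breakpoint(b2$contig, b2$position, row$gene2, "three_prime",
                         strand = as.character(row$strand2 %||% NA)),
          caller,
          split_reads = int_or_zero(row$split_reads1, "split_reads1") +
            int_or_zero(row$split_reads2, "split_reads2"),
          spanning_pairs = int_or_zero(row$discordant_mates, "discordant_mates"),
          caller_frame_prediction = normalize_frame_label(row$reading_frame %||% NA))
      },
      dialect_F = {
        b1 <- parse_locus(row$breakpoint_5p, "breakpoint_5p")
        b2 <- parse_locus(row$breakpoint_3p, "breakpoint_3p")
        rank_of <- function(x) {
          r <- suppressWarnings(as.integer(sub(".*exon[_ ]?", "", as.character(x))))
          if (length(r) == 0L) NA_integer_ else r
        }
        new_fusion_call(
          new_breakpoint(b1$contig, b1$position, row$gene_5p, "five_prime",
                         strand = b1$strand, exon_rank = rank_of(row$exon_5p %||% NA)),
          new_breakpoint(b2$contig, b2$position, row$gene_3p, "three_prime",
                         strand = b2$strand, exon_rank = rank_of(row$exon_3p %||% NA)),
          caller,
          split_reads = int_or_zero(row$spanning_unique_reads, "spanning_unique_reads"),
          spanning_pairs = int_or_zero(row$spanning_pairs, "spanning_pairs"),
          caller_frame_prediction = normalize_frame_label(row$predicted_effect %||% NA))
      },
      dialect_S = {
        genes <- strsplit(as.character(row$FusionName), "--", fixed = TRUE)[[1]]
        if (length(genes) != 2L) abort_input(sprintf("cannot parse FusionName '%s'", row$FusionName))
        b1 <- parse_locus(row$LeftBreakpoint, "LeftBreakpoint")
        b2 <- parse_locus(row$RightBreakpoint, "RightBreakpoint")
        new_fusion_call(
          new_breakpoint(b1$contig, b1$position, genes[1], "five_prime", strand = b1$strand),
          new_breakpoint(b2$contig, b2$position, genes[2], "three_prime", strand = b2$strand),
          caller,
          split_reads = int_or_zero(row$JunctionReadCount, "JunctionReadCount"),
          spanning_pairs = int_or_zero(row$SpanningFragCount, "SpanningFragCount"),
          caller_frame_prediction = "unknown")
      }),
      orfrescue_input_error = function(e) {
        warning(sprintf("row %d of '%s' rejected: %s", i, path, conditionMessage(e)))
        NULL
      })
    if (!is.null(call)) calls[[length(calls) + 1L]] <- call
  }
  calls
}

#' Merge fusion calls across callers
#'
#' Calls with the same ordered (5', 3') gene pair whose 5' and 3'
#' breakpoints both lie within `window_nt` are merged into one harmonized
#' event (single-linkage clustering, so merging is independent of input
#' order). The concordance count is the number of distinct callers in the
#' merged group. Reciprocal gene pairs are never merged, and the default
#' 10 nt window absorbs the small coordinate jitter between tools without
#' collapsing distinct junctions.
#'
#' @param calls list of `fusion_call`
#' @param window_nt non-negative merge window in nucleotides (default 10)
#' @return list of `harmonized_fusion` objects, ordered by gene pair then
#'   5' breakpoint
#' @export
harmonize_calls <- function(calls, window_nt = 10) {
  stopifnot(window_nt >= 0)
  if (length(calls) == 0L) return(list())
  key <- vapply(calls, function(cl) paste(cl$five_prime$gene_name, cl$three_prime$gene_name,
                                          cl$five_prime$contig, cl$three_prime$contig, sep = "\r"),
                character(1))
  out <- list()
  for (k in sort(unique(key))) {
    grp <- calls[key == k]
    n <- length(grp)
    p5 <- vapply(grp, function(cl) cl$five_prime$position, integer(1))
    p3 <- vapply(grp, function(cl) cl$three_prime$position, integer(1))
    # single-linkage connected components on joint breakpoint proximity
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (comp[i] != comp[j] && abs(p5[i] - p5[j]) <= window_nt && abs(p3[i] - p3[j]) <= window_nt) {
          comp[comp == comp[j]] <- comp[i]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cid in sort(unique(comp))) {
      members <- grp[comp == cid]
      callers <- vapply(members, `[[`, "", "caller_name")
      frames <- vapply(members, `[[`, "", "caller_frame_prediction")
      known <- setdiff(unique(frames), "unknown")
      caller_frame <- if (length(known) == 1L) known else if (length(known) > 1L) "discordant" else "unknown"
      ord <- order(vapply(members, function(m) m$five_prime$position, integer(1)),
                   vapply(members, function(m) m$three_prime$position, integer(1)),
                   callers)
      hf <- structure(list(
        gene_5p = members[[1]]$five_prime$gene_name,
        gene_3p = members[[1]]$three_prime$gene_name,
        fusion_id = paste0(members[[1]]$five_prime$gene_name, "::", members[[1]]$three_prime$gene_name),
        breakpoint_5p = members[[ord[1]]]$five_prime,
        breakpoint_3p = members[[ord[1]]]$three_prime,
        calls = members,
        callers = sort(unique(callers)),
        concordance_count = length(unique(callers)),
        split_reads = max(vapply(members, `[[`, 0L, "split_reads")),
        spanning_pairs = max(vapply(members, `[[`, 0L, "spanning_pairs")),
        caller_frame = caller_frame,
        in_strand = NA), class = "harmonized_fusion")
      out[[length(out) + 1L]] <- hf
    }
  }
  ord <- order(vapply(out, function(h) paste(h$fusion_id, sprintf("%012d", h$breakpoint_5p$position)), character(1)))
  out[ord]
}

#' @export
print.harmonized_fusion <- function(x, ...) {
  cat(sprintf("<harmonized_fusion> %s  %d caller(s): %s  5'=%s:%d 3'=%s:%d frame(caller)=%s\n",
              x$fusion_id, x$concordance_count, paste(x$callers, collapse = ","),
              x$breakpoint_5p$contig, x$breakpoint_5p$position,
              x$breakpoint_3p$contig, x$breakpoint_3p$position, x$caller_frame))
  invisible(x)
}

#' Is a harmonized fusion in-strand?
#'
#' A chimeric transcript can only be read through as one sense mRNA if the
#' retained fragment of each partner is transcribed in the same direction
#' the fusion junction implies: the caller-reported fragment orientation
#' must equal the annotated gene strand for both the 5' and the 3' partner.
#'
#' @param fusion a `harmonized_fusion`
#' @param models annotation from [read_annotation()]
#' @return `TRUE`, `FALSE`, or `NA` when either gene is absent from the
#'   annotation or a caller strand is unavailable (indeterminate)
#' @export
check_in_strand <- function(fusion, models) {
  m5 <- resolve_transcript(models, fusion$gene_5p, fusion$breakpoint_5p$transcript_id)
  m3 <- resolve_transcript(models, fusion$gene_3p, fusion$breakpoint_3p$transcript_id)
  if (is.null(m5) || is.null(m3)) return(NA)
  s5 <- fusion$breakpoint_5p$strand
  s3 <- fusion$breakpoint_3p$strand
  if (is.na(s5) || is.na(s3)) return(NA)
  identical(s5, m5$strand) && identical(s3, m3$strand)
}
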