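#' @name triage
#' @title Five-criterion fusion triage
#' @description
#' An ideal candidate for a functional (and potentially actionable)
#' fusion fulfills five predefined criteria: (C1) the 3' partner is a
#' druggable kinase gene; (C2) the orientation is in-strand; (C3) the
#' junction is predicted out of frame; (C4) the kinase domain of the 3'
#' partner is preserved; (C5) both partners show a 5'/3' expression
#' imbalance. The frame is always recomputed from the reconstructed
#' transcript; caller labels are advisory only and are kept for the
#' reclassification audit (callers frequently mislabel in-frame events as
#' out of frame). A fusion passing everything and carrying at least one
#' frame-restoring, domain-covering downstream ATG is classified
#' `candidate_functional_out_of_frame`; a fusion recomputed as in frame
#' that passes C1/C2/C4/C5 is `in_frame_imbalanced_candidate`; fusions
#' with any indeterminate criterion are routed to `needs_input` for
#' manual review; everything else is `filtered`.
NULL

#' Triage configuration
#'
#' @param alpha imbalance significance level
#' @param window_nt breakpoint merge window for harmonization
#' @param min_nonzero minimum nonzero exons per imbalance group
#' @param direction_required require the biologically expected direction
#'   of imbalance
#' @param partial_domain if `TRUE`, criterion C4 accepts junctions inside
#'   the kinase domain (partial retention); default requires the complete
#'   domain downstream of the junction
#' @param max_starts maximum frame-restoring starts reported per fusion
#' @param snap_tol intronic breakpoint snap tolerance (nt)
#' @return a named list of settings
#' @export
triage_config <- function(alpha = 0.05, window_nt = 10, min_nonzero = 2L,
                          direction_required = FALSE, partial_domain = FALSE,
                          max_starts = 10L, snap_tol = 10L) {
  stopifnot(alpha > 0, alpha < 1, window_nt >= 0, min_nonzero >= 1L)
  list(alpha = alpha, window_nt = window_nt, min_nonzero = min_nonzero,
       direction_required = direction_required, partial_domain = partial_domain,
       max_starts = max_starts, snap_tol = snap_tol)
}

criterion <- function(id, name, status, evidence) {
  list(id = id, name = name, status = status, evidence = evidence)
}

#' Evaluate the five triage criteria for one harmonized fusion
#'
#' @param fusion a `harmonized_fusion`
#' @param models annotation from [read_annotation()]
#' @param genome genome from [read_genome()]
#' @param domains domain table from [read_domain_table()]
#' @param gene_list druggable-kinase gene symbols (e.g.
#'   [default_kinase_genes()])
#' @param counts named list of `exon_count_vector` from
#'   [read_exon_counts()], or `NULL` (C5 becomes indeterminate)
#' @param config from [triage_config()]
#' @return a `triage_verdict`
#' @export
evaluate_criteria <- function(fusion, models, genome, domains, gene_list,
                              counts = NULL, config = triage_config()) {
  crit <- list()
  # C1: druggable kinase 3' partner
  in_list <- toupper(fusion$gene_3p) %in% toupper(gene_list)
  crit$C1 <- criterion("C1", "druggable kinase 3' partner",
                       if (in_list) "pass" else "fail",
                       sprintf("3' partner %s %s in gene list", fusion$gene_3p,
                               if (in_list) "is" else "is not"))
  # C2: in-strand orientation
  instr <- check_in_strand(fusion, models)
  crit$C2 <- criterion("C2", "in-strand orientation",
                       if (is.na(instr)) "indeterminate" else if (instr) "pass" else "fail",
                       if (is.na(instr)) "gene or caller strand unavailable"
                       else sprintf("caller strands %s/%s vs annotated %s",
                                    fusion$breakpoint_5p$strand, fusion$breakpoint_3p$strand,
                                    if (instr) "match" else "mismatch"))
  # transcript reconstruction feeds C3, C4 and the rescue scan
  ft <- tryCatch(build_fusion_transcript(fusion, models, genome, snap_tol = config$snap_tol),
                 error = function(e) e)
  if (inherits(ft, "error")) {
    msg <- conditionMessage(ft)
    crit$C3 <- criterion("C3", "predicted out-of-frame", "indeterminate", msg)
    crit$C4 <- criterion("C4", "kinase domain preserved", "indeterminate", msg)
    verdict_frame <- "indeterminate"
    starts <- NULL
    ft <- NULL
  } else {
    fv <- classify_frame(ft)
    verdict_frame <- fv$status
    crit$C3 <- criterion("C3", "predicted out-of-frame",
                         switch(fv$status, out_of_frame = "pass", in_frame = "fail",
                                indeterminate = "indeterminate"),
                         sprintf("recomputed %s (caller: %s)%s", fv$status, fusion$caller_frame,
                                 if (!is.na(fv$stop_distance_codons))
                                   sprintf("; stop %d codon(s) past junction", fv$stop_distance_codons)
                                 else ""))
    dom <- domains[domains$gene == toupper(fusion$gene_3p), , drop = FALSE]
    if (nrow(dom) == 0L) {
      crit$C4 <- criterion("C4", "kinase domain preserved", "indeterminate",
                           sprintf("no domain annotation for %s", fusion$gene_3p))
    } else {
      thresh <- if (config$partial_domain) dom$end_res else dom$start_res
      preserved <- any(ft$three_prime_protein_offset <= thresh)
      crit$C4 <- criterion("C4", "kinase domain preserved",
                           if (preserved) "pass" else "fail",
                           sprintf("junction at wild-type residue %d vs domain %d-%d (%s retention)",
                                   ft$three_prime_protein_offset, dom$start_res[1], dom$end_res[1],
                                   if (config$partial_domain) "partial" else "full"))
    }
    starts <- scan_downstream_starts(ft, domains, max_starts = config$max_starts)
  }
  # C5: dual-gene expression imbalance
  imb <- NULL
  if (!is.null(counts) && !is.null(ft)) {
    tx5 <- ft$transcript_5p; tx3 <- ft$transcript_3p
    v5 <- counts[[tx5]]; v3 <- counts[[tx3]]
    if (is.null(v5)) v5 <- Filter(function(v) identical(v$gene_name, fusion$gene_5p), counts)[1][[1]]
    if (is.null(v3)) v3 <- Filter(function(v) identical(v$gene_name, fusion$gene_3p), counts)[1][[1]]
    if (!is.null(v5) && !is.null(v3)) {
      v5 <- with_breakpoint(v5, ft$breakpoint_exon_5p, "five_prime")
      v3 <- with_breakpoint(v3, ft$breakpoint_exon_3p, "three_prime")
      imb <- assess_fusion(v5, v3, alpha = config$alpha, min_nonzero = config$min_nonzero,
                           direction_required = config$direction_required)
    }
  }
  if (is.null(imb)) {
    crit$C5 <- criterion("C5", "5'/3' expression imbalance", "indeterminate",
                         "exon counts unavailable for one or both partners")
  } else if (imb$status == "indeterminate") {
    crit$C5 <- criterion("C5", "5'/3' expression imbalance", "indeterminate", imb$reason)
  } else {
    crit$C5 <- criterion("C5", "5'/3' expression imbalance",
                         if (imb$overall_verdict) "pass" else "fail",
                         sprintf("5' p=%.4g, 3' p=%.4g (both must be < %g)",
                                 imb$five_prime$p_value, imb$three_prime$p_value, config$alpha))
  }

  statuses <- vapply(crit, `[[`, "", "status")
  rescue <- !is.null(starts) &&
    any(starts$frame_restoring & starts$kinase_domain_covered &
          starts$start_offset >= (ft$junction_offset %||% Inf), na.rm = TRUE)
  reclassified <- identical(fusion$caller_frame, "out_of_frame") &&
    identical(verdict_frame, "in_frame")
  final_class <-
    if (all(statuses == "pass") && identical(verdict_frame, "out_of_frame") && rescue)
      "candidate_functional_out_of_frame"
    else if (identical(verdict_frame, "in_frame") &&
             all(statuses[c("C1", "C2", "C4", "C5")] == "pass"))
      "in_frame_imbalanced_candidate"
    else if (any(statuses == "indeterminate")) "needs_input"
    else "filtered"
  structure(list(fusion_id = fusion$fusion_id,
                 gene_5p = fusion$gene_5p, gene_3p = fusion$gene_3p,
                 concordance_count = fusion$concordance_count,
                 criteria = crit,
                 recomputed_frame = verdict_frame,
                 caller_frame = fusion$caller_frame,
                 reclassified = reclassified,
                 has_domain_covering_rescue = rescue,
                 rescue_predictions = starts,
                 imbalance = imb,
                 final_class = final_class),
            class = "triage_verdict")
}

#' @export
print.triage_verdict <- function(x, ...) {
  st <- vapply(x$criteria, `[[`, "", "status")
  cat(sprintf("<triage_verdict> %s [%s]  %s  frame=%s%s\n", x$fusion_id,
              paste(sprintf("%s:%s", names(st), st), collapse = " "),
              x$final_class, x$recomputed_frame,
              if (x$reclassified) " (reclassified from caller out_of_frame)" else ""))
  invisible(x)
}

#' Run the full triage pipeline over harmonized fusions
#'
#' @param fusions list of `harmonized_fusion`
#' @inheritParams evaluate_criteria
#' @return list of `triage_verdict`
#' @export
triage_fusions <- function(fusions, models, genome, domains, gene_list,
                           counts = NULL, config = triage_config()) {
  lapply(fusions, evaluate_criteria, models = models, genome = genome,
         domains = domains, gene_list = gene_list, counts = counts, config = config)
}

verdict_row <- function(v) {
  st <- vapply(v$criteria, `[[`, "", "status")
  ev <- vapply(v$criteria, `[[`, "", "evidence")
  rp <- v$rescue_predictions
  rescue_str <- if (is.null(rp) || nrow(rp) == 0L) "" else {
    fr <- rp[which(rp$frame_restoring & !is.na(rp$start_label)), , drop = FALSE]
    paste(sprintf("%s:res%s:%s", fr$start_label,
                  ifelse(is.na(fr$wildtype_start_residue), "NA", fr$wildtype_start_residue),
                  ifelse(fr$kinase_domain_covered, "domain_covered", "domain_not_covered")),
          collapse = ";")
  }
  data.frame(fusion_id = v$fusion_id, gene_5p = v$gene_5p, gene_3p = v$gene_3p,
             concordance_count = v$concordance_count,
             C1 = st[["C1"]], C2 = st[["C2"]], C3 = st[["C3"]], C4 = st[["C4"]], C5 = st[["C5"]],
             recomputed_frame = v$recomputed_frame, caller_frame = v$caller_frame,
             reclassified = v$reclassified,
             rescue_starts = rescue_str,
             p_value_5p = if (is.null(v$imbalance)) NA_real_ else v$imbalance$five_prime$p_value,
             p_value_3p = if (is.null(v$imbalance)) NA_real_ else v$imbalance$three_prime$p_value,
             final_class = v$final_class,
             evidence_C1 = ev[["C1"]], evidence_C2 = ev[["C2"]], evidence_C3 = ev[["C3"]],
             evidence_C4 = ev[["C4"]], evidence_C5 = ev[["C5"]],
             stringsAsFactors = FALSE)
}

#' Write a triage report
#'
#' TSV: one row per fusion with criterion statuses, frame comparison,
#' compact rescue summary and evidence strings, in a fixed column order
#' (byte-identical across runs on identical input). JSON: the full
#' verdicts including per-start rescue predictions.
#'
#' @param verdicts list of `triage_verdict`
#' @param path output path
#' @param format `"tsv"` or `"json"`
#' @return invisibly, the path
#' @export
write_report <- function(verdicts, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- do.call(rbind, lapply(verdicts, verdict_row))
    if (is.null(df)) {
      cols <- c("fusion_id", "gene_5p", "gene_3p", "concordance_count", "C1", "C2",
                "C3", "C4", "C5", "recomputed_frame", "caller_frame", "reclassified",
                "rescue_starts", "p_value_5p", "p_value_3p", "final_class",
                "evidence_C1", "evidence_C2", "evidence_C3", "evidence_C4", "evidence_C5")
      df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    payload <- lapply(verdicts, function(v) {
      out <- v
      class(out) <- NULL
      out$rescue_predictions <- if (is.null(v$rescue_predictions)) NULL else v$rescue_predictions
      out$imbalance <- if (is.null(v$imbalance)) NULL else lapply(unclass(v$imbalance), unclass)
      out
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  }
  invisible(path)
}

#' Read back a triage report
#'
#' @param path report path
#' @param format `"tsv"` or `"json"`
#' @return data.frame (tsv) or list (json)
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  else jsonlite::read_json(path, simplifyVector = FALSE)
}
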