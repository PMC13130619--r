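#' @name panel
#' @title The nine-fusion synthetic triage panel
#' @description
#' One engineered fusion per triage failure mode, one full pass, and one
#' reclassification case, so the end-to-end pipeline has a fixture with a
#' known verdict table: F1 passes all five criteria out of frame with
#' planted rescue starts (the only `candidate_functional_out_of_frame`);
#' F2-F6 each fail exactly one criterion (C1 non-kinase partner, C2
#' antisense orientation, C3 in-frame junction, C4 domain lost, C5 flat
#' counts); F7 is in frame but caller-labeled out of frame with a real
#' imbalance (the one reclassified `in_frame_imbalanced_candidate`); F8
#' lacks exon counts (`needs_input`); F9 is out of frame with no planted
#' rescue ATG (passes all criteria yet yields no rescued protein, so it
#' is filtered).
NULL

panel_gene3 <- function(name, contig, strand = "+",
                        rescue = c(530L, 554L), domain = c(600L, 750L)) {
  list(name = name, contig = contig, strand = strand, n_exons = 21L,
       breakpoint_exon = 12L, n_residues = 800L, first_retained_residue = 500L,
       rescue_residues = rescue, domain_start = domain[1], domain_end = domain[2],
       domain_name = "Protein kinase")
}

# 5 exons retained / 7 lost: small enough to be realistic, large enough
# that an exact two-sided rank-sum test can fall below 0.05 (a 2-exon
# group, as in the index case, has a p-value floor of 2/21).
panel_gene5 <- function(name, contig, strand = "+") {
  list(name = name, contig = contig, strand = strand, n_exons = 12L,
       breakpoint_exon = 5L, n_residues = 400L)
}

flip_strand3 <- function(calls) {
  flip <- function(s) ifelse(s == "+", "-", "+")
  calls$dialect_A$strand2 <- flip(calls$dialect_A$strand2)
  calls$dialect_F$breakpoint_3p <- sub(":\\+$", ":FLIP", calls$dialect_F$breakpoint_3p)
  calls$dialect_F$breakpoint_3p <- sub(":-$", ":+", calls$dialect_F$breakpoint_3p)
  calls$dialect_F$breakpoint_3p <- sub(":FLIP$", ":-", calls$dialect_F$breakpoint_3p)
  calls$dialect_S$RightBreakpoint <- sub(":\\+$", ":FLIP", calls$dialect_S$RightBreakpoint)
  calls$dialect_S$RightBreakpoint <- sub(":-$", ":+", calls$dialect_S$RightBreakpoint)
  calls$dialect_S$RightBreakpoint <- sub(":FLIP$", ":-", calls$dialect_S$RightBreakpoint)
  calls
}

#' Generate the nine-fusion synthetic triage panel
#'
#' @param dir optional output directory; when given, writes `genome.fa`,
#'   `annotation.gtf`, `domains.tsv`, `gene_list.txt`,
#'   `calls_dialect_A/F/S.tsv`, `exon_counts.tsv` and
#'   `ground_truth.json`
#' @param seed integer master seed
#' @return list with `genome`, `models`, `domains`, `gene_list`, `calls`
#'   (per-dialect data.frames), `counts` (data.frame), `truth`
#'   (data.frame of expected classifications)
#' @export
make_fixture_panel <- function(dir = NULL, seed = 1L) {
  specs <- list(
    list(id = "F1", g5 = panel_gene5("PANTA", "chr5p_1"),
         g3 = NULL,  # default index-case-like kinase geometry
         shift = 1L, fold = 10, label = NULL, counts = TRUE, flip = FALSE,
         expect = "candidate_functional_out_of_frame"),
    list(id = "F2", g5 = panel_gene5("PANTB", "chr5p_2"),
         g3 = panel_gene3("STK99X", "chr3p_2"),
         shift = 1L, fold = 10, label = NULL, counts = TRUE, flip = FALSE,
         expect = "filtered"),
    list(id = "F3", g5 = panel_gene5("PANTC", "chr5p_3"),
         g3 = panel_gene3("RET", "chr3p_3"),
         shift = 1L, fold = 10, label = NULL, counts = TRUE, flip = TRUE,
         expect = "filtered"),
    list(id = "F4", g5 = panel_gene5("PANTD", "chr5p_4"),
         g3 = panel_gene3("ROS1", "chr3p_4"),
         shift = 0L, fold = 1, label = NULL, counts = TRUE, flip = FALSE,
         expect = "filtered"),
    list(id = "F5", g5 = panel_gene5("PANTE", "chr5p_5"),
         g3 = panel_gene3("NTRK1", "chr3p_5", domain = c(300L, 450L)),
         shift = 1L, fold = 10, label = NULL, counts = TRUE, flip = FALSE,
         expect = "filtered"),
    list(id = "F6", g5 = panel_gene5("PANTF", "chr5p_6", strand = "-"),
         g3 = panel_gene3("LTK", "chr3p_6"),
         shift = 1L, fold = 1, label = NULL, counts = TRUE, flip = FALSE,
         expect = "filtered"),
    list(id = "F7", g5 = panel_gene5("PANTG", "chr5p_7"),
         g3 = panel_gene3("EGFR", "chr3p_7"),
         shift = 0L, fold = 10, label = "out-of-frame", counts = TRUE, flip = FALSE,
         expect = "in_frame_imbalanced_candidate"),
    list(id = "F8", g5 = panel_gene5("PANTH", "chr5p_8"),
         g3 = panel_gene3("MET", "chr3p_8"),
         shift = 1L, fold = 10, label = NULL, counts = FALSE, flip = FALSE,
         expect = "needs_input"),
    list(id = "F9", g5 = panel_gene5("PANTI", "chr5p_9"),
         g3 = panel_gene3("KIT", "chr3p_9", strand = "-", rescue = integer(0)),
         shift = 1L, fold = 10, label = NULL, counts = TRUE, flip = FALSE,
         expect = "filtered"))
  genomes <- list(); models <- list(); domains <- list()
  calls <- list(dialect_A = list(), dialect_F = list(), dialect_S = list())
  counts <- list(); truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    cfg <- simulation_config(seed = seed * 100L + i,
                             gene_5p = sp$g5,
                             frame_shift = sp$shift,
                             caller_frame_label = sp$label)
    if (!is.null(sp$g3)) cfg$gene_3p <- sp$g3
    cfg$counts$fold_change <- sp$fold
    ref <- make_toy_reference(cfg)
    fus <- engineer_fusion(ref)
    if (sp$flip) fus$calls <- flip_strand3(fus$calls)
    genomes[[i]] <- ref$genome
    models <- c(models, ref$models)
    domains[[i]] <- ref$domains
    for (d in names(calls)) calls[[d]][[i]] <- fus$calls[[d]]
    if (sp$counts) counts[[length(counts) + 1L]] <- simulate_exon_counts(ref)
    truth[[i]] <- data.frame(panel_id = sp$id, fusion_id = fus$fusion_id,
                             expected_class = sp$expect,
                             frame_status = fus$truth$status,
                             stringsAsFactors = FALSE)
  }
  genome <- do.call(c, genomes)
  out <- list(genome = genome, models = models,
              domains = do.call(rbind, domains),
              gene_list = default_kinase_genes(),
              calls = lapply(calls, function(x) do.call(rbind, x)),
              counts = do.call(rbind, counts),
              truth = do.call(rbind, truth),
              seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
    write_annotation(models, file.path(dir, "annotation.gtf"))
    write_tsv_seeded(out$domains, file.path(dir, "domains.tsv"), seed)
    writeLines(c(sprintf("# seed: %d", seed), out$gene_list), file.path(dir, "gene_list.txt"))
    for (d in names(out$calls))
      write_tsv_seeded(out$calls[[d]], file.path(dir, sprintf("calls_%s.tsv", d)), seed)
    write_tsv_seeded(out$counts, file.path(dir, "exon_counts.tsv"), seed)
    jsonlite::write_json(list(seed = seed, fusions = out$truth),
                         file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}
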