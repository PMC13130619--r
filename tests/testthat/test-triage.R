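# shared panel fixture for this file (built once; generation is seeded)
panel_dir <- NULL
panel_obj <- NULL
setup_panel <- function() {
  if (is.null(panel_dir)) {
    panel_dir <<- file.path(tempdir(), "orfrescue-panel-tests")
    unlink(panel_dir, recursive = TRUE)
    panel_obj <<- make_fixture_panel(panel_dir, seed = 1L)
  }
  list(dir = panel_dir, panel = panel_obj)
}

panel_paths <- function(dir) {
  list(genome = file.path(dir, "genome.fa"),
       gtf = file.path(dir, "annotation.gtf"),
       calls = c(dialect_A = file.path(dir, "calls_dialect_A.tsv"),
                 dialect_F = file.path(dir, "calls_dialect_F.tsv"),
                 dialect_S = file.path(dir, "calls_dialect_S.tsv")),
       domains = file.path(dir, "domains.tsv"),
       gene_list = file.path(dir, "gene_list.txt"),
       counts = file.path(dir, "exon_counts.tsv"))
}

run_panel_triage <- function(dir, out, config = triage_config()) {
  p <- panel_paths(dir)
  cmd_triage(p$genome, p$gtf, p$calls, p$domains, gene_list_path = p$gene_list,
             counts_path = p$counts, out_path = out, config = config, quiet = TRUE)
}

test_that("nine-fusion panel reproduces its designed verdict table", {
  px <- setup_panel()
  out <- file.path(px$dir, "report.tsv")
  run_panel_triage(px$dir, out)
  rep <- read_report(out)
  m <- merge(px$panel$truth, rep[, c("fusion_id", "final_class", "reclassified")], by = "fusion_id")
  expect_identical(nrow(m), 9L)
  expect_identical(m$final_class, m$expected_class)
  expect_identical(sum(rep$final_class == "candidate_functional_out_of_frame"), 1L)
  expect_identical(sum(rep$reclassified & rep$final_class == "in_frame_imbalanced_candidate"), 1L)
  # per-criterion failure counts fixed by panel construction
  expect_identical(sum(rep$C1 == "fail"), 1L)
  expect_identical(sum(rep$C2 == "fail"), 1L)
  expect_identical(sum(rep$C3 == "fail"), 2L)  # F4 and reclassified F7
  expect_identical(sum(rep$C4 == "fail"), 1L)
  expect_identical(sum(rep$C5 == "fail"), 2L)  # F4 (fold 1) and F6
  expect_identical(sum(rep$C5 == "indeterminate"), 1L)  # F8: no counts
  # F9: every criterion passes yet no rescue start exists -> filtered
  f9 <- rep[rep$gene_3p == "KIT", ]
  expect_true(all(unlist(f9[, c("C1", "C2", "C3", "C4", "C5")]) == "pass"))
  expect_identical(f9$final_class, "filtered")
  expect_identical(f9$rescue_starts, "")
})

test_that("reports are byte-identical across repeated runs and round-trip", {
  px <- setup_panel()
  out1 <- file.path(px$dir, "r1.tsv"); out2 <- file.path(px$dir, "r2.tsv")
  run_panel_triage(px$dir, out1)
  run_panel_triage(px$dir, out2)
  expect_identical(readLines(out1), readLines(out2))
  outj <- file.path(px$dir, "r.json")
  v <- run_panel_triage(px$dir, outj)  # (tsv written, verdicts returned)
  write_report(v, outj, format = "json")
  back <- read_report(outj, format = "json")
  expect_length(back, 9)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$fusion_id, v[[i]]$fusion_id)
    expect_identical(back[[i]]$final_class, v[[i]]$final_class)
    expect_identical(back[[i]]$recomputed_frame, v[[i]]$recomputed_frame)
    expect_identical(unlist(back[[i]]$criteria$C5$status), v[[i]]$criteria$C5$status)
  }
})

test_that("monotonicity: breaking any single criterion never promotes a fusion", {
  px <- setup_panel()
  p <- panel_paths(px$dir)
  genome <- read_genome(p$genome)
  models <- read_annotation(p$gtf)
  domains <- read_domain_table(p$domains)
  gene_list <- read_gene_list(p$gene_list)
  counts <- read_exon_counts(p$counts, models)
  calls <- orfrescue:::load_all_calls(p$calls)
  fusions <- harmonize_calls(calls)
  f1 <- Filter(function(f) f$gene_3p == "ALK", fusions)[[1]]
  base <- evaluate_criteria(f1, models, genome, domains, gene_list, counts)
  expect_identical(base$final_class, "candidate_functional_out_of_frame")
  # C1 broken: drop ALK from the list
  v <- evaluate_criteria(f1, models, genome, domains, setdiff(gene_list, "ALK"), counts)
  expect_identical(v$final_class, "filtered")
  # C4 broken: pretend the domain starts upstream of the junction
  dom2 <- domains; dom2$start_res[dom2$gene == "ALK"] <- 10L
  v <- evaluate_criteria(f1, models, genome, dom2, gene_list, counts)
  expect_identical(v$final_class, "filtered")
  # C5 broken: withhold counts -> indeterminate -> needs_input, never candidate
  v <- evaluate_criteria(f1, models, genome, domains, gene_list, NULL)
  expect_identical(v$final_class, "needs_input")
  # C2 broken: flip the caller strand of the 3' breakpoint
  f1b <- f1; f1b$breakpoint_3p$strand <- "-"
  v <- evaluate_criteria(f1b, models, genome, domains, gene_list, counts)
  expect_identical(v$final_class, "filtered")
})

test_that("partial-domain mode relaxes C4 as documented", {
  px <- setup_panel()
  p <- panel_paths(px$dir)
  genome <- read_genome(p$genome)
  models <- read_annotation(p$gtf)
  domains <- read_domain_table(p$domains)
  gene_list <- read_gene_list(p$gene_list)
  counts <- read_exon_counts(p$counts, models)
  fusions <- harmonize_calls(orfrescue:::load_all_calls(p$calls))
  f5 <- Filter(function(f) f$gene_3p == "NTRK1", fusions)[[1]]  # domain 300-450, junction at 500
  full <- evaluate_criteria(f5, models, genome, domains, gene_list, counts)
  expect_identical(full$criteria$C4$status, "fail")
  part <- evaluate_criteria(f5, models, genome, domains, gene_list, counts,
                            config = triage_config(partial_domain = TRUE))
  # junction (residue 500) is past domain end 450 even for partial retention
  expect_identical(part$criteria$C4$status, "fail")
  # a junction inside the domain passes only in partial mode
  dom2 <- domains
  dom2$start_res[dom2$gene == "NTRK1"] <- 450L; dom2$end_res[dom2$gene == "NTRK1"] <- 600L
  inside_full <- evaluate_criteria(f5, models, genome, dom2, gene_list, counts)
  inside_part <- evaluate_criteria(f5, models, genome, dom2, gene_list, counts,
                                   config = triage_config(partial_domain = TRUE))
  expect_identical(inside_full$criteria$C4$status, "fail")
  expect_identical(inside_part$criteria$C4$status, "pass")
})
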