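#' @name imbalance
#' @title 5'/3' exon-level expression imbalance test
#' @description
#' A functional fusion transcribes the retained exons of each partner from
#' the (often highly active) fusion promoter, while the lost exons are
#' expressed only from the wild-type allele. Exon-level read counts then
#' show a step at the breakpoint. The procedure: extract per-exon counts
#' for the reported transcript of each partner, identify the
#' breakpoint-containing exon, split exons into the group preceding and
#' the group succeeding the breakpoint (the breakpoint exon joins the
#' retained side: group 1 for the 5' partner, group 2 for the 3' partner),
#' drop zero-count exons, compare the groups with a Wilcoxon rank-sum
#' test, call a gene significant at p < alpha, and call the fusion
#' imbalanced only when both partners are significant.
NULL

#' Build an exon count vector
#'
#' @param gene_name,transcript_id identifiers
#' @param counts per-exon counts ordered by transcript-orientation rank
#'   (rank 1 = 5'-most exon); `NA` marks exons absent from the count table
#'   (unmeasured, distinct from zero)
#' @param breakpoint_exon_rank rank of the breakpoint-containing exon
#' @param retained_side `"five_prime"` or `"three_prime"`
#' @return an `exon_count_vector`
#' @export
exon_count_vector <- function(gene_name, transcript_id, counts,
                              breakpoint_exon_rank = NA_integer_,
                              retained_side = NA_character_) {
  stopifnot(is.numeric(counts), all(counts[!is.na(counts)] >= 0))
  if (!is.na(breakpoint_exon_rank))
    stopifnot(breakpoint_exon_rank >= 1L, breakpoint_exon_rank <= length(counts))
  structure(list(gene_name = gene_name, transcript_id = transcript_id,
                 counts = as.numeric(counts), exon_ranks = seq_along(counts),
                 breakpoint_exon_rank = as.integer(breakpoint_exon_rank),
                 retained_side = retained_side),
            class = "exon_count_vector")
}

#' Attach a breakpoint to an exon count vector
#' @param vec an `exon_count_vector`
#' @param breakpoint_exon_rank breakpoint-containing exon rank
#' @param retained_side `"five_prime"` or `"three_prime"`
#' @return the updated vector
#' @export
with_breakpoint <- function(vec, breakpoint_exon_rank, retained_side) {
  stopifnot(retained_side %in% c("five_prime", "three_prime"))
  exon_count_vector(vec$gene_name, vec$transcript_id, vec$counts,
                    breakpoint_exon_rank, retained_side)
}

#' Read exon-level counts
#'
#' TSV with header `gene, transcript, contig, start, end, strand, count`
#' (featureCounts-style exon rows; `start`/`end` 1-based inclusive). Rows
#' are matched to annotated exons by exact interval; unmatched rows are
#' dropped with a warning, duplicate ranks are an error, and annotated
#' exons missing from the table are padded with `NA` (unmeasured), not 0.
#' Counts are ordered by transcript-orientation exon rank, so a
#' minus-strand table in genomic order comes back reversed.
#'
#' @param path TSV path
#' @param models annotation from [read_annotation()]
#' @return named list of `exon_count_vector` keyed by transcript_id
#' @export
read_exon_counts <- function(path, models) {
  if (!file.exists(path)) abort_input(sprintf("exon count table not found: %s", path))
  df <- read_tsv_table(path)
  if (nrow(df) == 0L) return(list())
  need <- c("gene", "transcript", "start", "end", "count")
  if (!all(need %in% names(df)))
    abort_input(sprintf("exon count table '%s' must have columns %s", path, paste(need, collapse = ", ")))
  out <- list()
  for (tx in unique(df$transcript)) {
    sub <- df[df$transcript == tx, , drop = FALSE]
    m <- models[[tx]]
    if (is.null(m)) {
      m <- resolve_transcript(models, sub$gene[1])
      if (is.null(m) || !identical(m$transcript_id, tx)) {
        warning(sprintf("transcript '%s' absent from annotation; %d count row(s) dropped", tx, nrow(sub)))
        next
      }
    }
    counts <- rep(NA_real_, nrow(m$exons))
    seen <- logical(nrow(m$exons))
    for (i in seq_len(nrow(sub))) {
      s0 <- sub$start[i] - 1L; e0 <- sub$end[i]
      hit <- which(m$exons$start == s0 & m$exons$end == e0)
      if (length(hit) == 0L) {
        warning(sprintf("exon %s:%d-%d not annotated for transcript '%s'; dropped",
                        sub$gene[i], sub$start[i], sub$end[i], tx))
        next
      }
      rank <- m$exons$rank[hit[1]]
      if (seen[rank]) abort_input(sprintf("duplicate count row for exon rank %d of '%s'", rank, tx))
      seen[rank] <- TRUE
      counts[rank] <- as.numeric(sub$count[i])
    }
    out[[tx]] <- exon_count_vector(m$gene_name, tx, counts)
  }
  out
}

#' Split exons around the breakpoint
#'
#' Group 1 holds ranks preceding the breakpoint, group 2 ranks succeeding
#' it; the breakpoint-containing exon joins the retained side (group 1
#' when the gene is the 5' partner, group 2 when it is the 3' partner).
#' Zero-count exons are recorded as excluded; unmeasured (`NA`) exons are
#' excluded too but reported separately.
#'
#' @param vec an `exon_count_vector` with breakpoint attached
#' @return list with `group1`, `group2` (ranks), `zero_excluded`,
#'   `missing_excluded`
#' @export
split_exons <- function(vec) {
  b <- vec$breakpoint_exon_rank
  if (is.na(b) || is.na(vec$retained_side))
    abort_input("exon count vector has no breakpoint; use with_breakpoint()")
  ranks <- vec$exon_ranks
  cutoff <- if (vec$retained_side == "five_prime") b else b - 1L
  g1 <- ranks[ranks <= cutoff]
  g2 <- ranks[ranks > cutoff]
  zero <- ranks[!is.na(vec$counts) & vec$counts == 0]
  missing <- ranks[is.na(vec$counts)]
  list(group1 = setdiff(g1, c(zero, missing)), group2 = setdiff(g2, c(zero, missing)),
       zero_excluded = zero, missing_excluded = missing)
}

# exact distribution of the group-1 rank sum (mid-ranks, conditional on the
# observed tie pattern) by dynamic programming over subset sums.
# Returns list(support, count) where support is in units of 2*rank.
ranksum_exact_dist <- function(ranks2, n1) {
  n <- length(ranks2)
  smax <- sum(ranks2)
  # counts[k+1, s+1] = number of n1-subsets ... use list of vectors indexed by k
  counts <- vector("list", n1 + 1L)
  counts[[1]] <- c(1, rep(0, smax))
  for (k in seq_len(n1)) counts[[k + 1L]] <- rep(0, smax + 1L)
  for (r in ranks2) {
    for (k in min(n1, length(ranks2)):1) {
      shifted <- c(rep(0, r), counts[[k]][seq_len(smax + 1L - r)])
      counts[[k + 1L]] <- counts[[k + 1L]] + shifted
    }
  }
  list(support = 0:smax, count = counts[[n1 + 1L]])
}

#' Wilcoxon rank-sum test with exact tie-aware enumeration
#'
#' Exon counts are small integers, so ties are the rule; the large-sample
#' normal approximation can misbehave at the 4-20 exons typical of a
#' partner gene. Exact mode computes the permutation distribution of the
#' mid-rank sum conditional on the observed tie pattern by dynamic
#' programming over subset sums (equivalent to enumerating all
#' `choose(n1+n2, n1)` group labelings). The two-sided p-value is the
#' probability of a rank sum at least as far from its permutation mean as
#' observed. Normal mode applies the tie-corrected approximation with
#' continuity correction; auto (default) selects exact when
#' `n1 + n2 <= 20`.
#'
#' @param a,b numeric vectors (non-empty)
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`
#' @param alternative `"two_sided"`, `"greater"` (a tends larger) or
#'   `"less"`
#' @return list with `U` (Mann-Whitney statistic for `a`), `p_value`,
#'   `method`
#' @export
rank_sum_test <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                          alternative = c("two_sided", "greater", "less")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) abort_input("rank_sum_test: both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  if (mode == "auto") mode <- if (n <= 20L) "exact" else "normal_approx"
  if (mode == "exact") {
    r2 <- as.integer(round(2 * r))
    dist <- ranksum_exact_dist(r2, n1)
    total <- sum(dist$count)
    w2 <- as.integer(round(2 * W))
    mu2 <- n1 * mean(r2)
    eps <- 1e-9
    p <- switch(alternative,
      two_sided = sum(dist$count[abs(dist$support - mu2) >= abs(w2 - mu2) - eps]) / total,
      greater = sum(dist$count[dist$support >= w2 - eps]) / total,
      less = sum(dist$count[dist$support <= w2 + eps]) / total)
    return(list(U = U, p_value = min(1, p), method = "exact"))
  }
  # tie-corrected normal approximation with continuity correction
  ties <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(U = U, p_value = 1, method = "normal_approx"))
  z <- U - n1 * n2 / 2
  sigma <- sqrt(sigma2)
  p <- switch(alternative,
    two_sided = {
      cc <- sign(z) * 0.5
      2 * min(stats::pnorm((z - cc) / sigma, lower.tail = FALSE),
              stats::pnorm((z - cc) / sigma))
    },
    greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
    less = stats::pnorm((z + 0.5) / sigma))
  list(U = U, p_value = min(1, p), method = "normal_approx")
}

#' Test one partner gene for expression imbalance
#'
#' Splits the exon counts around the breakpoint, drops zero-count and
#' unmeasured exons, and compares the two groups with [rank_sum_test()].
#' A group left with fewer than `min_nonzero` exons makes the result
#' indeterminate (a 1-exon group cannot reach p < 0.05, and reporting it
#' as "balanced" would conflate absence of evidence with balance).
#'
#' @param vec an `exon_count_vector` with breakpoint attached
#' @param alpha significance level (default 0.05)
#' @param min_nonzero minimum nonzero exons per group (default 2)
#' @param mode,alternative passed to [rank_sum_test()]
#' @param direction_required if `TRUE`, significance additionally requires
#'   the retained-side group to be the higher one
#' @return an `imbalance_test_result` list
#' @export
assess_gene <- function(vec, alpha = 0.05, min_nonzero = 2L,
                        mode = "auto", alternative = "two_sided",
                        direction_required = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  sp <- split_exons(vec)
  g1 <- vec$counts[sp$group1]; g2 <- vec$counts[sp$group2]
  base <- list(gene_name = vec$gene_name, transcript_id = vec$transcript_id,
               n1 = length(g1), n2 = length(g2),
               median1 = if (length(g1)) stats::median(g1) else NA_real_,
               median2 = if (length(g2)) stats::median(g2) else NA_real_,
               zero_excluded = length(sp$zero_excluded),
               missing_excluded = length(sp$missing_excluded))
  if (length(g1) < min_nonzero || length(g2) < min_nonzero) {
    return(structure(c(base, list(U = NA_real_, p_value = NA_real_, direction = "none",
                                  significant = FALSE, status = "indeterminate",
                                  reason = sprintf("fewer than %d nonzero exons in a group", min_nonzero))),
                     class = "imbalance_test_result"))
  }
  tst <- rank_sum_test(g1, g2, mode = mode, alternative = alternative)
  direction <- if (base$median2 > base$median1) "group2_higher"
               else if (base$median1 > base$median2) "group1_higher" else "none"
  significant <- tst$p_value < alpha
  if (direction_required && significant) {
    expected <- if (identical(vec$retained_side, "five_prime")) "group1_higher" else "group2_higher"
    significant <- identical(direction, expected)
  }
  structure(c(base, list(U = tst$U, p_value = tst$p_value, direction = direction,
                         significant = significant, status = "ok", reason = NA_character_)),
            class = "imbalance_test_result")
}

#' @export
print.imbalance_test_result <- function(x, ...) {
  cat(sprintf("<imbalance_test_result> %s n1=%d n2=%d U=%s p=%s %s%s\n",
              x$gene_name, x$n1, x$n2, format(x$U), format(x$p_value),
              if (isTRUE(x$significant)) "significant" else "not significant",
              if (x$status == "indeterminate") sprintf(" [indeterminate: %s]", x$reason) else ""))
  invisible(x)
}

#' Dual-gene fusion imbalance verdict
#'
#' A fusion exhibits a 5'/3' imbalance only when both partner genes show a
#' significant step at the breakpoint.
#'
#' @param vec5,vec3 `exon_count_vector`s for the 5' and 3' partner (with
#'   breakpoints attached)
#' @param alpha significance level
#' @param ... passed to [assess_gene()]
#' @return list with `five_prime`, `three_prime` results,
#'   `overall_verdict` (logical), `status` (`ok`/`indeterminate`),
#'   `reason`
#' @export
assess_fusion <- function(vec5, vec3, alpha = 0.05, ...) {
  r5 <- assess_gene(vec5, alpha = alpha, ...)
  r3 <- assess_gene(vec3, alpha = alpha, ...)
  indet <- r5$status == "indeterminate" || r3$status == "indeterminate"
  verdict <- isTRUE(r5$significant) && isTRUE(r3$significant)
  structure(list(five_prime = r5, three_prime = r3,
                 overall_verdict = verdict && !indet,
                 status = if (indet) "indeterminate" else "ok",
                 reason = if (indet) paste(stats::na.omit(c(r5$reason, r3$reason)), collapse = "; ")
                          else NA_character_),
            class = "fusion_imbalance_result")
}

#' @export
print.fusion_imbalance_result <- function(x, ...) {
  cat(sprintf("<fusion_imbalance_result> 5'=%s (p=%s) 3'=%s (p=%s) -> %s%s\n",
              x$five_prime$gene_name, format(x$five_prime$p_value),
              x$three_prime$gene_name, format(x$three_prime$p_value),
              if (x$overall_verdict) "imbalanced" else "no dual-gene imbalance",
              if (x$status == "indeterminate") " [indeterminate]" else ""))
  invisible(x)
}
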