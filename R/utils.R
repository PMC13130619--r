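`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement a nucleotide string
#' @param x character scalar of A/C/G/T/N
#' @return reverse complement, character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string in frame 0
#'
#' Trailing bases that do not fill a codon are dropped. Translation does not
#' stop at stop codons; stops appear as `*` so callers can locate them.
#' @param x nucleotide string
#' @return amino-acid string
#' @keywords internal
translate_nt <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                     if.fuzzy.codon = "X"))
}

codons_of <- function(x, from = 1L) {
  n <- nchar(x)
  starts <- seq.int(from, n - 2L, by = 3L)
  if (length(starts) == 0L || starts[1] > n - 2L) return(character(0))
  substring(x, starts, starts + 2L)
}

# first stop codon start (1-based) reading x from position `from` in steps of 3;
# NA if none before the string ends
first_stop_at <- function(x, from) {
  n <- nchar(x)
  if (from > n - 2L) return(NA_integer_)
  starts <- seq.int(from, n - 2L, by = 3L)
  cods <- substring(x, starts, starts + 2L)
  hit <- which(cods %in% STOP_CODONS)
  if (length(hit) == 0L) NA_integer_ else starts[hit[1]]
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)

abort_input <- function(msg) stop(structure(class = c("orfrescue_input_error", "error", "condition"),
                                            list(message = msg, call = NULL)))
abort_usage <- function(msg) stop(structure(class = c("orfrescue_usage_error", "error", "condition"),
                                            list(message = msg, call = NULL)))
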