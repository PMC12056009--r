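#' The 61 sense codons
#'
#' All DNA trinucleotides except the three stop codons (TAA, TAG, TGA),
#' in lexicographic order. All per-codon statistics in this package are
#' defined over this universe; stop codons are excluded throughout.
#'
#' @return Character vector of length 61.
#' @export
sense_codons <- function() .SENSE_CODONS

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.ALL_CODONS <- {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(n3 = b, n2 = b, n1 = b, stringsAsFactors = FALSE)
  sort(paste0(g$n1, g$n2, g$n3))
}

.SENSE_CODONS <- setdiff(.ALL_CODONS, .STOP_CODONS)

#' Default codon sets
#'
#' The codon sets used throughout the wobble-uridine analyses: the three
#' VAA codons AAA (Lys), CAA (Gln) and GAA (Glu) -- decoded by tRNAs whose
#' wobble uridine (U34) carries the mcm5s2 modification -- individually,
#' their union `VAA`, and the complementary control set `nonVAA` (all other
#' sense codons).
#'
#' @return Named list mapping set name to a character vector of codons.
#' @export
#' @examples
#' default_codon_sets()$VAA
default_codon_sets <- function() {
  vaa <- c("AAA", "CAA", "GAA")
  list(
    AAA = "AAA",
    CAA = "CAA",
    GAA = "GAA",
    VAA = vaa,
    nonVAA = setdiff(.SENSE_CODONS, vaa)
  )
}

#' Define a custom codon set
#'
#' @param name Set label.
#' @param codons Character vector of sense codons.
#' @return Named list of length one, suitable for concatenation with
#'   [default_codon_sets()].
#' @export
codon_set <- function(name, codons) {
  codons <- toupper(codons)
  bad <- setdiff(codons, .SENSE_CODONS)
  if (length(bad) > 0L) {
    stop("codon set '", name, "' contains non-sense codons: ",
         paste(bad, collapse = ", "))
  }
  stats::setNames(list(unique(codons)), name)
}

# split a nucleotide string into consecutive triplets
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}
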