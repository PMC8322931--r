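# Synthetic stand-in for the MTHFR coding sequence. The real RefSeq mRNA is
# not bundled; this generator produces a deterministic 656-residue CDS with
# the well-known MTHFR landmark residues pinned so that named variants
# (p.Ala222Val, p.Glu429Ala, p.Trp165Ter, ...) exist and the common
# polymorphisms are reachable by a single nucleotide change.

# Landmark residues of human MTHFR, with codons chosen so that the
# frequently discussed substitutions are single-nucleotide accessible
# (GCC -> GTC gives Ala222Val; GAA -> GCA gives Glu429Ala; ...).
MTHFR_LANDMARKS <- c(
  `165` = "TGG",  # Trp165, disordered-loop FAD tether
  `175` = "GCT",  # Ala175
  `222` = "GCC",  # Ala222 (c.665C>T -> Val is one substitution)
  `263` = "CAT",  # His263
  `325` = "CGC",  # Arg325
  `368` = "GCT",  # Ala368 (-> Gly by one substitution)
  `429` = "GAA",  # Glu429 (c.1286A>C -> Ala is one substitution)
  `461` = "GCT",  # Ala461
  `463` = "GAA",  # Glu463
  `575` = "GTT"   # Val575
)

#' Synthetic MTHFR-like coding sequence
#'
#' Deterministically generates a synthetic 656-residue coding sequence that
#' mimics the domain organisation of human MTHFR: a serine-rich N-terminal
#' stretch, a catalytic domain, a short linker and a C-terminal regulatory
#' domain. Landmark residues (Trp165, Ala222, Arg325, Ala368, Glu429,
#' Glu463, Val575, His263, Ala175, Ala461) are pinned with codons that make
#' the canonical substitutions single-nucleotide accessible. This is a
#' synthetic stand-in, not the RefSeq sequence; supply a real FASTA via
#' [read_coding_sequence()] for work on actual MTHFR data.
#'
#' @param length Protein length (default 656).
#' @param seed Seed for the deterministic codon draw.
#' @return A [coding_sequence()] with id `"MTHFR_synthetic"`.
#' @export
synthetic_mthfr_cds <- function(length = 656L, seed = 101L) {
  ct <- codon_table()
  sense <- names(ct)[ct != "*"]
  with_seed(seed, {
    codons <- sample(sense, length, replace = TRUE)
    # serine-enriched disordered N terminus
    n_ser <- min(37L, length)
    ser_codons <- names(ct)[ct == "S"]
    ser_idx <- sample(seq_len(n_ser), size = ceiling(n_ser * 0.4))
    codons[ser_idx] <- sample(ser_codons, length(ser_idx), replace = TRUE)
    # avoid methionine-start ambiguity issues: fix position 1 to ATG
    codons[1L] <- "ATG"
    for (pos in names(MTHFR_LANDMARKS)) {
      p <- as.integer(pos)
      if (p <= length) codons[p] <- MTHFR_LANDMARKS[[pos]]
    }
    coding_sequence(paste0(paste(codons, collapse = ""), "TAA"),
                    id = "MTHFR_synthetic")
  })
}
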