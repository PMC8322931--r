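# Coding-sequence container, enumeration of amino-acid-level outcomes,
# HGVS-p parsing/formatting and single-nucleotide accessibility.

#' Construct a coding sequence
#'
#' Holds a protein-coding nucleotide sequence together with its translation.
#' Codon `i` occupies nucleotides `3i-2 .. 3i` (1-based, closed intervals).
#' A trailing stop codon, if present, is retained in `nucleotides` but not in
#' `protein`.
#'
#' @param nucleotides A single DNA string (A/C/G/T), length divisible by 3.
#' @param id Sequence identifier.
#' @return An object of class `coding_sequence`: a list with elements `id`,
#'   `nucleotides`, `protein` (one-letter amino acids, no stop) and
#'   `has_stop`.
#' @export
coding_sequence <- function(nucleotides, id = "cds") {
  abort_if(length(nucleotides) != 1L || !is.character(nucleotides),
           "`nucleotides` must be a single string.")
  nucleotides <- toupper(nucleotides)
  abort_if(nchar(nucleotides) %% 3L != 0L,
           "Coding sequence length must be divisible by 3.")
  abort_if(grepl("[^ACGT]", nucleotides),
           "Coding sequence may only contain A, C, G, T.")
  prot <- translate_cds(nucleotides)
  has_stop <- endsWith(prot, "*")
  if (has_stop) prot <- substr(prot, 1L, nchar(prot) - 1L)
  abort_if(grepl("\\*", prot),
           "Coding sequence contains an internal stop codon.")
  structure(
    list(id = id, nucleotides = nucleotides, protein = prot,
         has_stop = has_stop),
    class = "coding_sequence"
  )
}

translate_cds <- function(nucleotides) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(nucleotides),
    no.init.codon = TRUE
  ))
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence> ", x$id, ": ", nchar(x$nucleotides), " nt, ",
      nchar(x$protein), " aa",
      if (x$has_stop) " (+stop)" else "", "\n", sep = "")
  invisible(x)
}

#' Read a coding sequence from a FASTA file
#'
#' @param path Path to a FASTA file; the first record is used.
#' @inheritParams coding_sequence
#' @return A [coding_sequence()] object.
#' @export
read_coding_sequence <- function(path, id = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  abort_if(length(seqs) == 0L, "No sequences found in FASTA file.")
  coding_sequence(as.character(seqs[[1L]]), id = id %||% names(seqs)[1L])
}

#' Codon at a protein position
#' @param cds A [coding_sequence()].
#' @param position Integer vector of codon (protein) positions.
#' @return Character vector of codons.
#' @export
codon_at <- function(cds, position) {
  abort_if(any(position < 1L | position > nchar(cds$protein)),
           "Position outside the protein.")
  substring(cds$nucleotides, 3L * position - 2L, 3L * position)
}

#' Enumerate all amino-acid-level mutational outcomes
#'
#' For each protein position there are 21 outcomes: the 19 missense
#' substitutions, one nonsense (`*`) and one synonymous (`=`) outcome.
#' A 656-residue protein therefore has 13,776 outcomes.
#'
#' @param protein A one-letter amino-acid string, or a [coding_sequence()].
#' @return A tibble with columns `variant` (compact key such as `"A222V"`,
#'   `"W165*"`, `"A222="`), `position`, `ref_aa`, `alt` and `type`
#'   (`missense`/`nonsense`/`synonymous`).
#' @export
enumerate_outcomes <- function(protein) {
  if (inherits(protein, "coding_sequence")) protein <- protein$protein
  abort_if(!is.character(protein) || length(protein) != 1L ||
             nchar(protein) == 0L, "`protein` must be a non-empty string.")
  aa <- strsplit(protein, "")[[1L]]
  bad <- which(!aa %in% AA_STANDARD)
  abort_if(length(bad) > 0L,
           paste0("Non-standard residue at position ",
                  paste(head(bad, 5L), collapse = ", "), "."))
  n <- length(aa)
  alt <- unlist(lapply(aa, function(a) c(setdiff(AA_STANDARD, a), "*", "=")),
                use.names = FALSE)
  pos <- rep(seq_len(n), each = 21L)
  ref <- rep(aa, each = 21L)
  tibble::tibble(
    variant = paste0(ref, pos, alt),
    position = pos,
    ref_aa = ref,
    alt = alt,
    type = dplyr::case_when(
      alt == "*" ~ "nonsense",
      alt == "=" ~ "synonymous",
      TRUE ~ "missense"
    )
  )
}

#' Parse HGVS-p variant notation
#'
#' Accepts three-letter HGVS protein notation such as `"p.Ala222Val"`,
#' `"p.Trp165Ter"` and the synonymous form `"p.Ala222="`. Round-trips
#' exactly through [format_protein_variant()].
#'
#' @param x Character vector of HGVS-p strings.
#' @param cds Optional [coding_sequence()]; if supplied, reference residues
#'   are validated against it.
#' @return A tibble with columns `hgvs_p`, `variant`, `position`, `ref_aa`,
#'   `alt`, `type`.
#' @export
parse_protein_variant <- function(x, cds = NULL) {
  m <- stringr::str_match(x, "^p\\.([A-Z][a-z]{2})(\\d+)(=|[A-Z][a-z]{2})$")
  bad <- which(is.na(m[, 1L]))
  abort_if(length(bad) > 0L,
           paste0("Malformed HGVS-p string: ",
                  paste(unique(x[head(bad, 5L)]), collapse = ", ")))
  ref3 <- m[, 2L]
  pos <- as.integer(m[, 3L])
  alt3 <- m[, 4L]
  abort_if(!all(ref3 %in% names(AA_ONE)) ||
             !all(alt3 %in% c(names(AA_ONE), "=")),
           "Unknown amino-acid code in HGVS-p string.")
  ref <- unname(AA_ONE[ref3])
  alt <- ifelse(alt3 == "=", "=", unname(AA_ONE[alt3]))
  abort_if(any(ref == "*"), "Reference residue cannot be a stop.")
  abort_if(any(alt == ref), "Use `=` for synonymous outcomes, not Ref==Alt.")
  if (!is.null(cds)) {
    aa <- strsplit(cds$protein, "")[[1L]]
    abort_if(any(pos < 1L | pos > length(aa)),
             "Variant position outside the protein.")
    mism <- which(aa[pos] != ref)
    abort_if(length(mism) > 0L,
             paste0("Reference mismatch at position ",
                    paste(unique(pos[head(mism, 5L)]), collapse = ", "), "."))
  }
  tibble::tibble(
    hgvs_p = x,
    variant = paste0(ref, pos, alt),
    position = pos,
    ref_aa = ref,
    alt = alt,
    type = dplyr::case_when(
      alt == "*" ~ "nonsense",
      alt == "=" ~ "synonymous",
      TRUE ~ "missense"
    )
  )
}

#' Format variants as HGVS-p strings
#'
#' @param position,ref_aa,alt Vectors describing variants (one-letter codes,
#'   `"*"` for stop, `"="` for synonymous), or a data frame with those
#'   columns as the first argument.
#' @return Character vector of HGVS-p strings.
#' @export
format_protein_variant <- function(position, ref_aa = NULL, alt = NULL) {
  if (is.data.frame(position)) {
    df <- position
    position <- df$position
    ref_aa <- df$ref_aa
    alt <- df$alt
  }
  paste0("p.", AA_THREE[ref_aa], position,
         ifelse(alt == "=", "=", AA_THREE[alt]))
}

# All 9 single-nucleotide substitutions of a codon.
codon_snvs <- function(codon) {
  bases <- c("A", "C", "G", "T")
  nts <- strsplit(codon, "")[[1L]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(bases, nts[i])) {
      mut <- nts
      mut[i] <- b
      out <- c(out, paste(mut, collapse = ""))
    }
  }
  out
}

#' Single-nucleotide accessibility of protein variants
#'
#' A variant is SNV-accessible when some single-nucleotide substitution of
#' the reference codon produces the outcome: any codon of the alternate
#' residue for missense, any stop codon (TAA/TAG/TGA) for nonsense, or a
#' different codon of the same residue for synonymous outcomes.
#'
#' @param variants A data frame with columns `position` and `alt` (as from
#'   [enumerate_outcomes()] or [parse_protein_variant()]).
#' @param cds A [coding_sequence()].
#' @return Logical vector, one element per row of `variants`.
#' @export
is_snv_accessible <- function(variants, cds) {
  ct <- codon_table()
  codons <- codon_at(cds, variants$position)
  ref_aa <- unname(ct[codons])
  target <- ifelse(variants$alt == "=", ref_aa, variants$alt)
  purrr::map2_lgl(codons, target, function(cod, tgt) {
    any(unname(ct[codon_snvs(cod)]) == tgt)
  })
}

# Number of distinct single-nucleotide paths from the reference codon to the
# outcome; used by the sequencing-error model.
snv_path_count <- function(variants, cds) {
  ct <- codon_table()
  codons <- codon_at(cds, variants$position)
  ref_aa <- unname(ct[codons])
  target <- ifelse(variants$alt == "=", ref_aa, variants$alt)
  purrr::map2_int(codons, target, function(cod, tgt) {
    sum(unname(ct[codon_snvs(cod)]) == tgt)
  })
}
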