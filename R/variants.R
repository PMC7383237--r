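#' @importFrom stats cor rnorm rlnorm runif rmultinom setNames sd
#' @importFrom utils combn head read.delim write.table
NULL

# Residue positions randomised in the library, in amplicon order.
SPEC_POSITIONS <- c(173L, 179L, 184L, 201L)

# The two wild-type specificity words: ParB (binds parS) and Noc (binds NBS).
WT_PARS <- "RTAG"
WT_NBS <- "QKKR"

# Canonical 20-letter amino-acid alphabet (alphabetical).
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Fixed linkers of the 87-bp amplicon between the four NNS codon slots.
AMPLICON_LINKERS <- c(
  "TCTCACGTAGCGAAT",
  "ATGCGTCTTCTT",
  "TTGCCGGACGAGGTACAGTCCTATCTTGTGAGTGGAGAGCTGACAGCG"
)

# 1-based start of each codon within the 87-mer: 1-3, 19-21, 34-36, 85-87.
CODON_STARTS <- c(1L, 19L, 34L, 85L)

.pkg_cache <- new.env(parent = emptyenv())

#' All 160,000 four-residue variants
#'
#' Enumerates every amino-acid word over the four specificity positions
#' (173, 179, 184, 201), i.e. \eqn{20^4 = 160{,}000} variants. The order is
#' deterministic: position 173 varies slowest, 201 fastest.
#'
#' @return Character vector of length 160,000 of 4-letter variants.
#' @export
#' @examples
#' length(all_variants())
#' head(all_variants())
all_variants <- function() {
  if (is.null(.pkg_cache$all_variants)) {
    g <- expand.grid(p201 = AA20, p184 = AA20, p179 = AA20, p173 = AA20,
                     stringsAsFactors = FALSE)
    .pkg_cache$all_variants <- paste0(g$p173, g$p179, g$p184, g$p201)
  }
  .pkg_cache$all_variants
}

#' Residue matrix of variant words
#'
#' @param variants character vector of 4-letter variants.
#' @return n x 4 character matrix, columns named by position.
#' @export
variant_residues <- function(variants) {
  m <- matrix("", nrow = length(variants), ncol = 4,
              dimnames = list(variants, as.character(SPEC_POSITIONS)))
  for (j in 1:4) m[, j] <- substr(variants, j, j)
  m
}

#' Hamming distance between 4-letter variants
#'
#' Number of positions at which two variant words differ. Vectorised;
#' `a` and `b` are recycled to a common length.
#'
#' @param a,b character vectors of 4-letter variants.
#' @return Integer vector of distances in 0..4.
#' @export
#' @examples
#' hamming4("RTAG", "QKKR")  # 4
hamming4 <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  d <- integer(n)
  for (j in 1:4) d <- d + (substr(a, j, j) != substr(b, j, j))
  d
}

.validate_variants <- function(variants, arg = "variants") {
  if (!is.character(variants) || any(nchar(variants) != 4L) ||
      any(!strsplit(paste(variants, collapse = ""), "")[[1]] %in% AA20)) {
    stop(sprintf("'%s' must be 4-letter words over the 20 amino-acid alphabet",
                 arg), call. = FALSE)
  }
  invisible(variants)
}

#' Codon tables for the NNS library and the full standard code
#'
#' NNS degenerate codons have any base at the first two positions and G or C
#' at the third; they encode all 20 amino acids plus the single amber stop
#' TAG. `codons_by_aa` returns, per residue, its codon set under either model.
#'
#' @param codon_model `"NNS"` (library encoding; 31 sense codons) or
#'   `"full_standard"` (all 61 sense codons).
#' @return Named list mapping each amino-acid letter to a character vector of
#'   codons.
#' @export
#' @examples
#' codons_by_aa("NNS")$K   # "AAG" only: AAA is not NNS
codons_by_aa <- function(codon_model = c("NNS", "full_standard")) {
  codon_model <- match.arg(codon_model)
  key <- paste0("codons_", codon_model)
  if (is.null(.pkg_cache[[key]])) {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    if (codon_model == "NNS") {
      keep <- substr(codons, 3, 3) %in% c("G", "C")
      gc <- gc[keep]
      codons <- codons[keep]
    }
    sense <- gc != "*"
    tab <- split(codons[sense], gc[sense])
    if (!all(AA20 %in% names(tab))) {
      stop("internal error: codon model does not cover all 20 residues")
    }
    .pkg_cache[[key]] <- tab[AA20]
  }
  .pkg_cache[[key]]
}

#' Minimum nucleotide distance between two residues
#'
#' Minimum Hamming distance over all codon pairs (one codon for each residue)
#' under the chosen codon model; 0 iff the residues are identical. Used to
#' decide single-nucleotide-substitution adjacency in the nt-mode
#' sequence-space graph.
#'
#' @param a,b single amino-acid letters.
#' @param codon_model `"NNS"` or `"full_standard"`.
#' @return Integer in 0..3.
#' @export
#' @examples
#' min_nt_distance("R", "Q")  # 1 (CGG vs CAG)
#' min_nt_distance("A", "K")  # 2 under NNS
min_nt_distance <- function(a, b, codon_model = c("NNS", "full_standard")) {
  codon_model <- match.arg(codon_model)
  m <- nt_distance_matrix(codon_model)
  if (!a %in% AA20 || !b %in% AA20) {
    stop("residues must be single letters of the 20 amino-acid alphabet")
  }
  m[a, b]
}

#' Pairwise residue nucleotide-distance matrix
#'
#' @inheritParams min_nt_distance
#' @return 20 x 20 integer matrix of minimum codon Hamming distances.
#' @export
nt_distance_matrix <- function(codon_model = c("NNS", "full_standard")) {
  codon_model <- match.arg(codon_model)
  key <- paste0("ntdist_", codon_model)
  if (is.null(.pkg_cache[[key]])) {
    tab <- codons_by_aa(codon_model)
    all_codons <- unlist(tab, use.names = FALSE)
    aa_of <- rep(names(tab), lengths(tab))
    b1 <- substr(all_codons, 1, 1)
    b2 <- substr(all_codons, 2, 2)
    b3 <- substr(all_codons, 3, 3)
    cd <- outer(b1, b1, "!=") + outer(b2, b2, "!=") + outer(b3, b3, "!=")
    m <- matrix(3L, 20, 20, dimnames = list(AA20, AA20))
    for (i in seq_along(AA20)) {
      ci <- aa_of == AA20[i]
      for (j in seq_along(AA20)) {
        m[i, j] <- as.integer(min(cd[ci, aa_of == AA20[j]]))
      }
    }
    .pkg_cache[[key]] <- m
  }
  .pkg_cache[[key]]
}

#' The 87-bp degenerate amplicon template as a regular expression
#'
#' Four NNS codon slots (`[ACGT][ACGT][GC]`) separated by the fixed linkers
#' of the B1H amplicon; matching a read against this pattern and pulling out
#' the four codon slots is the variant-decoding step.
#'
#' @return A single regular-expression string with four capture groups.
#' @export
amplicon_template_regex <- function() {
  slot <- "([ACGT][ACGT][GC])"
  paste0(slot, AMPLICON_LINKERS[1], slot, AMPLICON_LINKERS[2], slot,
         AMPLICON_LINKERS[3], slot)
}

#' Build the 87-bp amplicon for four codons
#'
#' @param codons character vector (or 4-column matrix) of four codon triplets.
#' @return Character vector of 87-bp sequences.
#' @export
amplicon_from_codons <- function(codons) {
  if (is.matrix(codons)) {
    paste0(codons[, 1], AMPLICON_LINKERS[1], codons[, 2], AMPLICON_LINKERS[2],
           codons[, 3], AMPLICON_LINKERS[3], codons[, 4])
  } else {
    stopifnot(length(codons) == 4)
    paste0(codons[1], AMPLICON_LINKERS[1], codons[2], AMPLICON_LINKERS[2],
           codons[3], AMPLICON_LINKERS[3], codons[4])
  }
}
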