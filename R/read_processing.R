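# Read processing: FASTQ -> trimmed, quality-filtered, template-matched,
# translated variant counts, with a per-stage conservation tally.

#' Read a FASTQ file into plain vectors
#'
#' @param path FASTQ or gzipped FASTQ path.
#' @return List with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # muffle the reader's benign note about dropped metadata columns
  fq <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  suppressWarnings(list(
    id = names(fq),
    seq = as.character(fq),
    qual = as.character(Biostrings::quality(fq))))
}

.phred_scores <- function(qual) {
  methods::as(Biostrings::PhredQuality(qual), "IntegerList")
}

#' Trim a read to a 1-based inclusive window
#'
#' Mirrors `fastx_trimmer -f first -l last` semantics. A read shorter than
#' `last` cannot supply the window and is skipped (`NULL`, with a warning).
#'
#' @param read list with elements `seq` and `qual` (and optionally `id`).
#' @param first,last 1-based inclusive window bounds, `1 <= first <= last`.
#' @return The trimmed read, or `NULL` if the read is too short.
#' @export
#' @examples
#' r <- list(seq = strrep("A", 150), qual = strrep("I", 150))
#' nchar(trim_read(r, 20, 114)$seq)  # 95
trim_read <- function(read, first = 20L, last = 114L) {
  stopifnot(first >= 1, first <= last)
  if (nchar(read$seq) < last) {
    warning(sprintf("read shorter than trim window [%d, %d]; skipped",
                    first, last))
    return(NULL)
  }
  read$seq <- substr(read$seq, first, last)
  read$qual <- substr(read$qual, first, last)
  read
}

#' Quality-filter a read
#'
#' `mode = "mean"` keeps reads whose mean Phred score is at least `q` (the
#' described criterion); `mode = "all_bases"` keeps reads with every base at
#' least `q` (the behaviour of `fastq_quality_filter -q 28 -p 100`, the
#' default here). Empty reads are discarded.
#'
#' @param read list with element `qual` (Phred+33 string).
#' @param q minimum Phred score (default 28).
#' @param mode `"all_bases"` or `"mean"`.
#' @return `TRUE` to keep the read.
#' @export
quality_filter <- function(read, q = 28L, mode = c("all_bases", "mean")) {
  mode <- match.arg(mode)
  stopifnot(q >= 0)
  if (nchar(read$qual) == 0L) return(FALSE)
  s <- utf8ToInt(read$qual) - 33L
  if (mode == "mean") mean(s) >= q else all(s >= q)
}

.match_template <- function(seqs) {
  # Returns a list: codon matrix (NA rows when unmatched) and per-read match
  # counts, scanning for the 87-bp degenerate template at any offset.
  rx <- amplicon_template_regex()
  up <- toupper(seqs)
  hits <- gregexpr(rx, up, perl = TRUE)
  n_match <- vapply(hits, function(h) {
    if (h[1] == -1L) 0L else length(h)
  }, integer(1))
  codons <- matrix(NA_character_, nrow = length(seqs), ncol = 4)
  one <- which(n_match == 1L)
  if (length(one)) {
    starts <- vapply(hits[one], `[`, integer(1), 1L)
    for (j in 1:4) {
      cs <- starts + CODON_STARTS[j] - 1L
      codons[one, j] <- substr(up[one], cs, cs + 2L)
    }
  }
  list(codons = codons, n_match = n_match)
}

#' Match a read against the 87-bp amplicon template and extract codons
#'
#' Searches the read for the degenerate template (four NNS codon slots
#' separated by the exact fixed linkers) at any offset, case-insensitively.
#' Returns `NULL` if there is no exact match; a read containing more than one
#' distinct template occurrence is rejected.
#'
#' @param read list with element `seq`, or a single sequence string.
#' @return List with `matched` (the 87-mer) and `codons` (4 triplets), or
#'   `NULL`.
#' @export
match_and_extract <- function(read) {
  seq <- if (is.list(read)) read$seq else read
  m <- .match_template(seq)
  if (m$n_match != 1L) return(NULL)
  codons <- m$codons[1, ]
  list(matched = amplicon_from_codons(codons), codons = codons)
}

#' Translate four extracted codons to a variant word
#'
#' Standard genetic code; returns `NA` if any codon is the amber stop (TAG)
#' or contains an ambiguous base.
#'
#' @param codons character vector of four codon triplets (a `TemplateMatch`
#'   list from [match_and_extract()] is also accepted).
#' @return A 4-letter variant string, or `NA_character_`.
#' @export
#' @examples
#' translate_variant(c("CGC", "ACG", "GCC", "GGC"))  # "RTAG"
#' translate_variant(c("CAG", "AAG", "AAG", "AGG"))  # "QKKR"
translate_variant <- function(codons) {
  if (is.list(codons)) codons <- codons$codons
  stopifnot(length(codons) == 4)
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- unname(gc_tab[toupper(codons)])
  if (any(is.na(aa)) || any(aa == "*")) return(NA_character_)
  paste(aa, collapse = "")
}

#' Decode one FASTQ file into variant calls
#'
#' Runs the full per-read pipeline (trim, quality filter, template match,
#' codon translation, stop/ambiguity removal) and keeps a per-stage tally so
#' that every input read is accounted for.
#'
#' @param path FASTQ path.
#' @param trim_first,trim_last trim window (defaults 20 and 114).
#' @param min_qual minimum Phred score (default 28).
#' @param qual_mode `"all_bases"` (default) or `"mean"`; see
#'   [quality_filter()].
#' @param search_revcomp also search the reverse complement of unmatched
#'   reads (default `FALSE`: the amplicon design fixes the orientation).
#' @return List with `variants` (one decoded 4-letter word per kept read) and
#'   `tally` (named integer vector: input, trim_skipped, quality_fail,
#'   no_template, multi_template, stop_or_ambiguous, kept).
#' @export
fastq_to_variants <- function(path, trim_first = 20L, trim_last = 114L,
                              min_qual = 28L,
                              qual_mode = c("all_bases", "mean"),
                              search_revcomp = FALSE) {
  qual_mode <- match.arg(qual_mode)
  stopifnot(trim_first >= 1, trim_first <= trim_last)
  fq <- read_fastq(path)
  n_in <- length(fq$seq)
  tally <- c(input = n_in, trim_skipped = 0L, quality_fail = 0L,
             no_template = 0L, multi_template = 0L,
             stop_or_ambiguous = 0L, kept = 0L)
  if (n_in == 0L) {
    return(list(variants = character(), tally = tally))
  }
  ok_len <- nchar(fq$seq) >= trim_last
  tally["trim_skipped"] <- sum(!ok_len)
  seqs <- substr(fq$seq[ok_len], trim_first, trim_last)
  quals <- substr(fq$qual[ok_len], trim_first, trim_last)

  scores <- .phred_scores(quals)
  keep_q <- if (qual_mode == "mean") {
    lens <- lengths(scores)
    ifelse(lens > 0, sum(scores) / pmax(lens, 1L), -Inf) >= min_qual
  } else {
    lengths(scores) > 0 & suppressWarnings(min(scores)) >= min_qual
  }
  tally["quality_fail"] <- sum(!keep_q)
  seqs <- seqs[keep_q]

  m <- .match_template(seqs)
  if (search_revcomp) {
    miss <- which(m$n_match == 0L)
    if (length(miss)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[miss])))
      m2 <- .match_template(rc)
      m$codons[miss, ] <- m2$codons
      m$n_match[miss] <- m2$n_match
    }
  }
  tally["no_template"] <- sum(m$n_match == 0L)
  tally["multi_template"] <- sum(m$n_match > 1L)
  codons <- m$codons[m$n_match == 1L, , drop = FALSE]

  gc_tab <- Biostrings::GENETIC_CODE
  aa <- matrix(gc_tab[codons], ncol = 4)
  bad <- is.na(aa[, 1]) | is.na(aa[, 2]) | is.na(aa[, 3]) | is.na(aa[, 4]) |
    aa[, 1] == "*" | aa[, 2] == "*" | aa[, 3] == "*" | aa[, 4] == "*"
  tally["stop_or_ambiguous"] <- sum(bad)
  variants <- paste0(aa[!bad, 1], aa[!bad, 2], aa[!bad, 3], aa[!bad, 4])
  if (nrow(aa) == 0L) variants <- character()
  tally["kept"] <- length(variants)
  list(variants = variants, tally = tally)
}

#' Process a set of FASTQ files into a filtered count table
#'
#' @param manifest data.frame with columns `library`, `replicate`, `path`
#'   (as returned by [emit_reads()]).
#' @param min_count pooled minimum read count per library (default 10).
#' @param ... passed to [fastq_to_variants()].
#' @return List with `counts` (a [count_table]), `pooled`, `present`
#'   (see [count_and_pool()]) and `diagnostics` (per-file stage tallies).
#' @export
process_reads <- function(manifest, min_count = 10, ...) {
  stopifnot(all(c("library", "replicate", "path") %in% names(manifest)))
  decoded <- list()
  diag <- list()
  for (i in seq_len(nrow(manifest))) {
    lib <- manifest$library[i]
    rep_i <- as.character(manifest$replicate[i])
    res <- fastq_to_variants(manifest$path[i], ...)
    decoded[[lib]][[rep_i]] <- res$variants
    diag[[paste0(lib, ".", rep_i)]] <- res$tally
  }
  counts <- count_table_from_variants(decoded)
  pooled <- count_and_pool(counts, min_count = min_count)
  list(counts = counts, pooled = pooled$pooled, present = pooled$present,
       min_count = min_count, diagnostics = diag)
}

#' Replicate reproducibility as R-squared of log10 counts
#'
#' For each pair of replicates within a library, the squared Pearson
#' correlation of log10 counts over variants exceeding `min_reads` in both
#' replicates (default more than 4 reads). Pairs sharing fewer than two such
#' variants are reported as `NA`.
#'
#' @param counts a [count_table].
#' @param min_reads strict lower bound on per-replicate counts (default 4).
#' @return Named list (per library) of replicate-by-replicate R-squared
#'   matrices.
#' @export
replicate_correlation <- function(counts, min_reads = 4) {
  stopifnot(inherits(counts, "count_table"))
  libs <- attr(counts, "library")
  reps <- attr(counts, "replicate")
  out <- list()
  for (lib in unique(libs)) {
    cols <- which(libs == lib)
    r <- reps[cols]
    m <- matrix(NA_real_, length(cols), length(cols),
                dimnames = list(paste0("rep", r), paste0("rep", r)))
    diag(m) <- 1
    if (length(cols) >= 2) {
      for (a in seq_along(cols)) {
        for (b in seq_along(cols)) {
          if (b <= a) next
          ca <- counts[, cols[a]]
          cb <- counts[, cols[b]]
          use <- ca > min_reads & cb > min_reads
          if (sum(use) < 2) next
          m[a, b] <- m[b, a] <- cor(log10(ca[use]), log10(cb[use]))^2
        }
      }
    }
    out[[lib]] <- m
  }
  out
}
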