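# Fitness scores: raw log10 enrichment relative to wild type, anchor-based
# normalisation, specificity classes, frequency logos and permissive-residue
# fractions.

CLASS_LEVELS <- c("dark_green", "light_green", "magenta", "pink", "black",
                  "gray")

#' Raw enrichment fitness relative to wild type
#'
#' For each variant,
#' `f_raw = log10(N_variant,post / N_wt,post) - log10(N_variant,pre / N_wt,pre)`
#' where the wild type is RTAG for the parS assay and QKKR for the NBS assay.
#' Variants absent (below the pooled minimum count) or with zero counts in
#' the pre- or post-library of the assay are `NA` (undefined for that assay).
#'
#' @param pooled integer matrix of pooled counts, variants x libraries (must
#'   contain columns `pre` and the assay's post library).
#' @param assay `"parS"` or `"NBS"`.
#' @param wt wild-type variant (defaults: RTAG for parS, QKKR for NBS).
#' @param present optional logical matrix like `pooled` flagging variants
#'   that pass the minimum-count filter per library.
#' @param exempt variants (e.g. the two anchors) excused from the `present`
#'   filter; they only need nonzero counts.
#' @return Named numeric vector of raw fitness scores (`NA` = undefined).
#' @export
raw_fitness <- function(pooled, assay = c("parS", "NBS"), wt = NULL,
                        present = NULL, exempt = character()) {
  assay <- match.arg(assay)
  post_lib <- paste0(assay, "_post")
  stopifnot(all(c("pre", post_lib) %in% colnames(pooled)))
  if (is.null(wt)) wt <- if (assay == "parS") WT_PARS else WT_NBS
  if (!wt %in% rownames(pooled)) {
    stop(sprintf("wild type %s absent from the count table", wt))
  }
  for (lib in c("pre", post_lib)) {
    if (pooled[wt, lib] == 0) {
      stop(sprintf("wild type %s has zero counts in the %s library",
                   wt, lib))
    }
  }
  pre <- pooled[, "pre"]
  post <- pooled[, post_lib]
  ok <- pre > 0 & post > 0
  if (!is.null(present)) {
    pass <- present[, "pre"] & present[, post_lib]
    pass[rownames(pooled) %in% c(wt, exempt)] <- TRUE
    ok <- ok & pass
  }
  f <- rep(NA_real_, nrow(pooled))
  names(f) <- rownames(pooled)
  f[ok] <- log10(post[ok] / post[wt]) - log10(pre[ok] / pre[wt])
  f
}

#' Anchor-normalise raw fitness scores
#'
#' Affine map sending the winning wild type's raw score to 1 and the losing
#' wild type's to 0 (for parS: winner RTAG, loser QKKR; for NBS the
#' reverse). Since the winner's raw score is identically 0, this is
#' `1 - f_raw / raw(loser)`.
#'
#' @param raw named numeric vector from [raw_fitness()].
#' @param winner_wt,loser_wt anchor variants.
#' @return Named numeric vector of normalised scores.
#' @export
#' @examples
#' normalize_fitness(c(RTAG = 0, QKKR = -2, XAAA = -1), "RTAG", "QKKR")
normalize_fitness <- function(raw, winner_wt, loser_wt) {
  for (a in c(winner_wt, loser_wt)) {
    if (!a %in% names(raw) || is.na(raw[a])) {
      stop(sprintf("anchor %s has no defined raw fitness", a))
    }
  }
  denom <- raw[winner_wt] - raw[loser_wt]
  if (denom == 0) {
    stop("degenerate selection: the two anchors have equal raw fitness")
  }
  (raw - raw[loser_wt]) / denom
}

#' Assign specificity classes from the two fitness scores
#'
#' Five functional classes plus gray (non-functional / undefined), with
#' strong and weak thresholds 0.6 and 0.2: black = dual specificity (both
#' scores at least `strong`); dark green = strong parS, no NBS; light green
#' = strong parS, weak-to-medium NBS; magenta = strong NBS, no parS; pink =
#' strong NBS, weak-to-medium parS. At an exact boundary the stricter class
#' wins (dark green over light green, magenta over pink), and black takes
#' precedence over light green and pink.
#'
#' @param f_parS,f_NBS normalised fitness scores (vectors; `NA` = undefined).
#' @param strong,weak class thresholds (defaults 0.6 and 0.2).
#' @return Factor with levels dark_green, light_green, magenta, pink, black,
#'   gray.
#' @export
#' @examples
#' classify_variants(c(0.8, 0.65, 0.5), c(0.1, 0.65, 0.1))
classify_variants <- function(f_parS, f_NBS, strong = 0.6, weak = 0.2) {
  stopifnot(length(f_parS) == length(f_NBS), weak <= strong)
  cls <- rep("gray", length(f_parS))
  def <- !is.na(f_parS) & !is.na(f_NBS)
  p <- f_parS[def]
  n <- f_NBS[def]
  cl <- rep("gray", sum(def))
  cl[n >= strong & p > weak & p <= strong] <- "pink"
  cl[n >= strong & p <= weak] <- "magenta"
  cl[p >= strong & n > weak & n <= strong] <- "light_green"
  cl[p >= strong & n <= weak] <- "dark_green"
  cl[p >= strong & n >= strong] <- "black"
  cls[def] <- cl
  factor(cls, levels = CLASS_LEVELS)
}

#' Full fitness table from a count table
#'
#' Pools replicates, applies the minimum-count filter, computes raw and
#' anchor-normalised fitness for both assays and assigns specificity classes.
#'
#' @param counts a [count_table].
#' @param min_count pooled minimum read count (default 10).
#' @param wt_parS,wt_NBS anchor variants (defaults RTAG, QKKR).
#' @param strong,weak class thresholds (defaults 0.6, 0.2).
#' @return data.frame with columns `variant`, `f_parS_raw`, `f_NBS_raw`,
#'   `f_parS`, `f_NBS`, `defined_parS`, `defined_NBS`, `class`.
#' @export
fitness_scores <- function(counts, min_count = 10, wt_parS = WT_PARS,
                           wt_NBS = WT_NBS, strong = 0.6, weak = 0.2) {
  cp <- count_and_pool(counts, min_count = min_count)
  anchors <- c(wt_parS, wt_NBS)
  raw_p <- raw_fitness(cp$pooled, "parS", wt = wt_parS, present = cp$present,
                       exempt = anchors)
  raw_n <- raw_fitness(cp$pooled, "NBS", wt = wt_NBS, present = cp$present,
                       exempt = anchors)
  f_p <- normalize_fitness(raw_p, winner_wt = wt_parS, loser_wt = wt_NBS)
  f_n <- normalize_fitness(raw_n, winner_wt = wt_NBS, loser_wt = wt_parS)
  data.frame(
    variant = rownames(cp$pooled),
    f_parS_raw = unname(raw_p), f_NBS_raw = unname(raw_n),
    f_parS = unname(f_p), f_NBS = unname(f_n),
    defined_parS = unname(!is.na(raw_p)), defined_NBS = unname(!is.na(raw_n)),
    class = classify_variants(f_p, f_n, strong = strong, weak = weak),
    stringsAsFactors = FALSE
  )
}

#' Position frequency matrix of a set of variants
#'
#' Unweighted per-position residue frequencies over the member variants of a
#' class, the matrix behind a frequency logo. Each position's frequencies sum
#' to 1.
#'
#' @param variants character vector of 4-letter variants.
#' @return 4 x 20 numeric matrix (rows = positions 173/179/184/201,
#'   columns = residues); all-zero with a warning if `variants` is empty.
#' @export
#' @examples
#' class_logo(c("RTAG", "RKAG"))["179", c("T", "K")]
class_logo <- function(variants) {
  m <- matrix(0, nrow = 4, ncol = 20,
              dimnames = list(as.character(SPEC_POSITIONS), AA20))
  if (length(variants) == 0L) {
    warning("empty class: returning all-zero frequency matrix")
    return(m)
  }
  .validate_variants(variants)
  res <- variant_residues(variants)
  for (j in 1:4) {
    tab <- table(factor(res[, j], levels = AA20))
    m[j, ] <- as.numeric(tab) / length(variants)
  }
  m
}

#' Permissive-residue (K/R at 179/184) fractions of a class
#'
#' Observed fractions of class members carrying lysine or arginine at
#' position 179, at 184, at either, and at both, together with the
#' expectations if residues were drawn uniformly from the 20 amino acids:
#' 10% per position, 19% for either, 1% for both.
#'
#' @param variants character vector of 4-letter variants.
#' @return data.frame with columns `feature`, `observed`, `expected_random`.
#' @export
permissive_fraction <- function(variants) {
  .validate_variants(variants)
  if (length(variants) == 0L) stop("empty class")
  res <- variant_residues(variants)
  at179 <- res[, 2] %in% c("K", "R")
  at184 <- res[, 3] %in% c("K", "R")
  data.frame(
    feature = c("at179", "at184", "either", "both"),
    observed = c(mean(at179), mean(at184), mean(at179 | at184),
                 mean(at179 & at184)),
    expected_random = c(2 / 20, 2 / 20, 1 - (18 / 20)^2, (2 / 20)^2),
    stringsAsFactors = FALSE
  )
}
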