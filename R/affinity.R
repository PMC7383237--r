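# Trajectory-scanning affinity analysis: PtoN intermediate enumeration,
# transitional DNA sites, and hierarchical clustering of K_D matrices.

#' Enumerate ParB-to-Noc (PtoN) intermediates
#'
#' All variants obtained by replacing each non-empty subset of the positions
#' where `start` and `end` differ with the `end` residue; for RTAG to QKKR
#' (k = 4 differing positions) this yields the 15 PtoN intermediates,
#' including the full QKKR.
#'
#' @param start,end 4-letter variant words.
#' @return Character vector of `2^k - 1` variants (no duplicates); empty if
#'   `start == end`.
#' @export
#' @examples
#' length(enumerate_pton())  # 15
enumerate_pton <- function(start = WT_PARS, end = WT_NBS) {
  .validate_variants(c(start, end))
  diff_pos <- which(strsplit(start, "")[[1]] != strsplit(end, "")[[1]])
  if (length(diff_pos) == 0L) return(character())
  out <- character()
  for (k in seq_along(diff_pos)) {
    subsets <- combn(diff_pos, k, simplify = FALSE)
    for (s in subsets) {
      v <- start
      for (p in s) substr(v, p, p) <- substr(end, p, p)
      out <- c(out, v)
    }
  }
  out
}

#' Enumerate transitional DNA sites
#'
#' Cartesian product of the four DNA bases at the variable positions of a
#' site (parS and NBS differ at half-site positions 1 and 6), giving the
#' 4^k transitional sites; the original site is among them.
#'
#' @param site DNA word (default a two-letter abstraction of the parS
#'   identity bases at positions 1 and 6).
#' @param positions 1-based positions within `site` to vary.
#' @param alphabet base alphabet.
#' @return Character vector of sites.
#' @export
#' @examples
#' length(enumerate_sites("GC", 1:2))  # 16
enumerate_sites <- function(site = "GC", positions = seq_len(nchar(site)),
                            alphabet = c("A", "C", "G", "T")) {
  stopifnot(all(positions >= 1), all(positions <= nchar(site)))
  combos <- expand.grid(rep(list(alphabet), length(positions)),
                        stringsAsFactors = FALSE)
  out <- rep(site, nrow(combos))
  for (j in seq_along(positions)) {
    substr(out, positions[j], positions[j]) <- combos[[j]]
  }
  unique(out)
}

#' Hierarchically cluster a K_D matrix
#'
#' Replaces the no-binding sentinel (`NA`: no interaction detected in the
#' screening at 1 uM, so K_D undetermined) by a cap value, then clusters rows
#' and columns independently by complete-linkage agglomeration on Euclidean
#' distances — the heatmap ordering.
#'
#' @param kd numeric matrix of dissociation constants in nM (positive;
#'   `NA` = no binding detected).
#' @param sentinel_cap value substituted for `NA` before distance
#'   computation (default 10000 nM).
#' @param log10_transform log10-transform K_D before distances (default
#'   `FALSE`).
#' @return List with `row_order`, `col_order` (leaf orders), `row_tree`,
#'   `col_tree` (`hclust` objects) and `matrix` (the imputed, possibly
#'   transformed matrix).
#' @export
cluster_heatmap <- function(kd, sentinel_cap = 10000, log10_transform = FALSE) {
  stopifnot(is.matrix(kd), nrow(kd) >= 2, ncol(kd) >= 2)
  if (any(kd <= 0, na.rm = TRUE)) {
    stop("input error: K_D values must be positive")
  }
  m <- kd
  m[is.na(m)] <- sentinel_cap
  if (log10_transform) m <- log10(m)
  row_tree <- stats::hclust(stats::dist(m), method = "complete")
  col_tree <- stats::hclust(stats::dist(t(m)), method = "complete")
  list(row_order = rownames(m)[row_tree$order],
       col_order = colnames(m)[col_tree$order],
       row_tree = row_tree, col_tree = col_tree, matrix = m)
}

#' Newick string of a merge tree
#'
#' @param tree an `hclust` object from [cluster_heatmap()].
#' @return Single Newick string.
#' @export
merge_tree_newick <- function(tree) {
  ape::write.tree(ape::as.phylo(tree))
}

#' Restrict a K_D matrix to variants with a residue at a position
#'
#' Keeps rows whose variant word carries `residue` at the specificity
#' `position` (e.g. only PtoN intermediates with glutamine at 173); columns
#' are unchanged.
#'
#' @param kd K_D matrix with variant rownames.
#' @param position one of 173, 179, 184, 201.
#' @param residue single amino-acid letter.
#' @return The row-subset matrix (with a warning if empty).
#' @export
conditioned_subset <- function(kd, position, residue) {
  j <- match(as.integer(position), SPEC_POSITIONS)
  if (is.na(j)) stop("position must be one of 173, 179, 184, 201")
  keep <- substr(rownames(kd), j, j) == residue
  if (!any(keep)) warning("no variants match the condition; empty matrix")
  kd[keep, , drop = FALSE]
}

#' Synthetic K_D matrix for ParB + PtoN intermediates
#'
#' A synthetic stand-in for a measured dissociation-constant matrix (the
#' published values exist only as a figure heatmap): ParB plus the 15 PtoN
#' intermediates against the 16 transitional sites between the parS and NBS
#' identity bases. Affinity follows the ground-truth landscape: binding
#' strength is the variant's parS-mode truth times the site's similarity to
#' parS plus its NBS-mode truth times the similarity to NBS; K_D = 50 nM /
#' strength with 10% log-normal noise, and pairs weaker than the screening
#' limit are `NA` (no binding detected).
#'
#' @param seed integer seed.
#' @param detection_limit K_D above which binding is undetectable at the
#'   screening concentration (default 4000 nM).
#' @return Numeric matrix (16 proteins x 16 sites, nM) with `NA` sentinels.
#' @export
synthetic_kd_matrix <- function(seed = 1L, detection_limit = 4000) {
  set.seed(seed)
  proteins <- c(WT_PARS, enumerate_pton(WT_PARS, WT_NBS))
  sites <- enumerate_sites("GC", 1:2)
  truth <- build_truth_landscape()
  tt <- truth[match(proteins, truth$variant), ]
  site_b <- cbind(substr(sites, 1, 1), substr(sites, 2, 2))
  # per-position compatibility of the site with each binding mode
  parS_ref <- c("G", "C")
  nbs_ref <- c("A", "G")
  m_site <- function(ref) {
    apply(site_b, 1, function(b) prod(ifelse(b == ref, 1, 0.1)))
  }
  m_parS <- m_site(parS_ref)
  m_NBS <- m_site(nbs_ref)
  strength <- outer(tt$t_parS, m_parS) + outer(tt$t_NBS, m_NBS)
  kd <- 50 / pmax(strength, 1e-6)
  kd <- kd * exp(rnorm(length(kd), 0, 0.1))
  kd[kd > detection_limit] <- NA
  dimnames(kd) <- list(proteins, sites)
  kd
}

#' Write and read K_D matrices as CSV
#'
#' The no-binding sentinel is written as the string `ND`.
#'
#' @param kd K_D matrix with `NA` sentinels.
#' @param file path.
#' @return `read_kd_matrix` returns the matrix with `NA` sentinels.
#' @export
write_kd_matrix <- function(kd, file) {
  out <- kd
  out[] <- ifelse(is.na(kd), "ND", format(kd, trim = TRUE, digits = 6))
  df <- data.frame(variant = rownames(kd), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_kd_matrix
#' @export
read_kd_matrix <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "ND"] <- NA
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
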