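#' Per-variant, per-library, per-replicate count table
#'
#' A `count_table` is an integer matrix with one row per observed variant and
#' one column per (library, replicate) pair, with the library and replicate of
#' each column stored as attributes. Libraries are `pre` (pre-selection),
#' `parS_post` and `NBS_post` (post-selection for binding parS / NBS).
#'
#' @param counts integer matrix, rownames = variants.
#' @param library character vector, one library label per column.
#' @param replicate integer vector, one replicate index per column.
#' @return A `count_table` object.
#' @export
count_table <- function(counts, library, replicate) {
  stopifnot(is.matrix(counts), ncol(counts) == length(library),
            length(library) == length(replicate))
  if (is.null(rownames(counts))) stop("'counts' must have variant rownames")
  if (any(counts < 0)) stop("counts must be non-negative")
  .validate_variants(rownames(counts))
  storage.mode(counts) <- "integer"
  colnames(counts) <- paste0(library, ".", replicate)
  structure(counts,
            library = as.character(library),
            replicate = as.integer(replicate),
            class = c("count_table", "matrix", "array"))
}

LIBRARIES <- c("pre", "parS_post", "NBS_post")

#' Pool replicate counts per library
#'
#' Sums counts over replicates within each library, as done before fitness
#' scoring (replicates are pooled once their reproducibility is confirmed).
#'
#' @param x a [count_table].
#' @return Integer matrix, variants x libraries.
#' @export
pool_counts <- function(x) {
  stopifnot(inherits(x, "count_table"))
  libs <- attr(x, "library")
  out <- sapply(unique(libs), function(l) {
    cols <- which(libs == l)
    if (length(cols) == 1L) x[, cols] else rowSums(x[, cols, drop = FALSE])
  })
  out <- as.matrix(out)
  rownames(out) <- rownames(x)
  storage.mode(out) <- "integer"
  out
}

#' Pool counts and apply the minimum-read filter
#'
#' Pools replicates per library and flags, per library, which variants meet
#' the pooled minimum read count (default 10 reads); variants below it are
#' treated as absent from that library downstream.
#'
#' @param x a [count_table].
#' @param min_count pooled-count threshold below which a variant is flagged
#'   absent for a library (default 10).
#' @return List with `pooled` (integer matrix), `present` (logical matrix,
#'   same shape) and `min_count`.
#' @export
#' @examples
#' ct <- count_table(matrix(c(4L, 3L, 3L), 1, 3,
#'                          dimnames = list("RTAG", NULL)),
#'                   library = rep("pre", 3), replicate = 1:3)
#' count_and_pool(ct)$present  # pooled 10 meets the threshold
count_and_pool <- function(x, min_count = 10) {
  if (nrow(x) == 0L) warning("empty count table")
  pooled <- pool_counts(x)
  list(pooled = pooled, present = pooled >= min_count, min_count = min_count)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d variants x %d (library, replicate) columns\n",
              nrow(x), ncol(x)))
  cat("libraries:", paste(unique(attr(x, "library")), collapse = ", "), "\n")
  cat("total reads:", sum(x), "\n")
  invisible(x)
}

#' Build a count table from decoded read variants
#'
#' @param decoded nested named list: `decoded[[library]][[replicate]]` is the
#'   character vector of decoded variants (one entry per kept read).
#' @return A [count_table] over the union of observed variants.
#' @export
count_table_from_variants <- function(decoded) {
  libs <- names(decoded)
  if (is.null(libs)) stop("'decoded' must be a named list of libraries")
  cols <- list()
  library <- character()
  replicate <- integer()
  for (l in libs) {
    for (r in seq_along(decoded[[l]])) {
      cols[[length(cols) + 1L]] <- decoded[[l]][[r]]
      library <- c(library, l)
      replicate <- c(replicate, r)
    }
  }
  variants <- sort(unique(unlist(cols)))
  if (length(variants) == 0L) {
    warning("no decoded variants; returning empty count table")
    m <- matrix(integer(), 0, length(cols),
                dimnames = list(character(), NULL))
    return(count_table(m, library, replicate))
  }
  m <- vapply(cols, function(v) {
    tab <- table(factor(v, levels = variants))
    as.integer(tab)
  }, integer(length(variants)))
  m <- matrix(m, nrow = length(variants), dimnames = list(variants, NULL))
  count_table(m, library, replicate)
}

#' Write a count table as long-format TSV
#'
#' Columns: variant, library, replicate, count. Zero counts are kept so the
#' file round-trips exactly.
#'
#' @param x a [count_table].
#' @param file output path.
#' @export
write_count_table <- function(x, file) {
  libs <- attr(x, "library")
  reps <- attr(x, "replicate")
  long <- data.frame(
    variant = rep(rownames(x), times = ncol(x)),
    library = rep(libs, each = nrow(x)),
    replicate = rep(reps, each = nrow(x)),
    count = as.vector(x)
  )
  write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a long-format count table TSV
#'
#' @param file path written by [write_count_table()].
#' @return A [count_table].
#' @export
read_count_table <- function(file) {
  long <- read.delim(file, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "library", "replicate", "count") %in% names(long)))
  key <- paste0(long$library, ".", long$replicate)
  cols <- unique(key)
  variants <- sort(unique(long$variant))
  m <- matrix(0L, length(variants), length(cols),
              dimnames = list(variants, cols))
  m[cbind(match(long$variant, variants), match(key, cols))] <-
    as.integer(long$count)
  info <- long[!duplicated(key), c("library", "replicate")]
  count_table(m, info$library, info$replicate)
}
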