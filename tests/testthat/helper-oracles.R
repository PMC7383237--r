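# Independent oracles used to cross-check the implementation. These are
# deliberately naive (sliding windows, DFS enumeration, stepwise
# agglomeration) and share no code with the package internals.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# The 87-bp degenerate template as a per-position character specification:
# a list of allowed-character sets, built from its literal layout.
template_spec <- local({
  slot <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"), c("G", "C"))
  fixed <- function(s) lapply(strsplit(s, "")[[1]], identity)
  c(slot, fixed("TCTCACGTAGCGAAT"), slot, fixed("ATGCGTCTTCTT"), slot,
    fixed("TTGCCGGACGAGGTACAGTCCTATCTTGTGAGTGGAGAGCTGACAGCG"), slot)
})

# Slide the template across every offset of a read; return list of codon
# quadruples for each matching offset.
brute_template_scan <- function(seq) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  L <- length(template_spec)
  out <- list()
  if (length(chars) < L) return(out)
  for (start in 1:(length(chars) - L + 1)) {
    window <- chars[start:(start + L - 1)]
    ok <- TRUE
    for (i in seq_len(L)) {
      if (!window[i] %in% template_spec[[i]]) { ok <- FALSE; break }
    }
    if (ok) {
      cs <- c(1, 19, 34, 85)
      out[[length(out) + 1L]] <- vapply(cs, function(p) {
        paste(window[p:(p + 2)], collapse = "")
      }, character(1))
    }
  }
  out
}

# Decode a FASTQ file by brute force: same trim/quality rules, then the
# sliding-window template scan and a plain genetic-code lookup.
brute_decode_fastq <- function(path, trim_first = 20, trim_last = 114,
                               min_qual = 28, qual_mode = "all_bases") {
  lines <- readLines(path)
  if (length(lines) == 0) return(character())
  seqs <- lines[seq(2, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  gc_tab <- Biostrings::GENETIC_CODE
  out <- character()
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < trim_last) next
    s <- substr(seqs[i], trim_first, trim_last)
    q <- utf8ToInt(substr(quals[i], trim_first, trim_last)) - 33
    keep <- if (qual_mode == "mean") mean(q) >= min_qual else all(q >= min_qual)
    if (!keep) next
    hits <- brute_template_scan(s)
    if (length(hits) != 1) next
    aa <- unname(gc_tab[hits[[1]]])
    if (any(is.na(aa)) || any(aa == "*")) next
    out <- c(out, paste(aa, collapse = ""))
  }
  out
}

# Exhaustive enumeration of all shortest paths between two nodes of a small
# graph given as an adjacency list (named list of character vectors).
dfs_all_shortest_paths <- function(adj, from, to) {
  best <- Inf
  found <- list()
  recurse <- function(path) {
    node <- path[length(path)]
    if (node == to) {
      len <- length(path) - 1
      if (len < best) { best <<- len; found <<- list(path) }
      else if (len == best) found[[length(found) + 1L]] <<- path
      return()
    }
    if (length(path) - 1 >= best) return()
    for (nb in adj[[node]]) {
      if (!nb %in% path) recurse(c(path, nb))
    }
  }
  recurse(from)
  list(dist = if (is.finite(best)) best else Inf, paths = found)
}

# Adjacency list of an igraph object.
igraph_adj_list <- function(g) {
  vn <- igraph::V(g)$name
  al <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), function(v) vn[v])
  names(al) <- vn
  al
}

# Naive complete-linkage agglomeration on the rows of a matrix; returns the
# sorted merge heights.
brute_complete_linkage_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  d <- as.matrix(stats::dist(m))
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (b <= a) next
        h <- max(d[clusters[[a]], clusters[[b]]])
        if (h < best[1]) best <- c(h, a, b)
      }
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1L]] <- merged
  }
  heights
}

# Minimum codon Hamming distance between two residues by nested-loop
# enumeration over codon sets taken straight from the genetic code table.
brute_min_nt <- function(a, b, nns_only = TRUE) {
  gc_tab <- Biostrings::GENETIC_CODE
  codons_of <- function(r) {
    cods <- names(gc_tab)[gc_tab == r]
    if (nns_only) cods <- cods[substr(cods, 3, 3) %in% c("G", "C")]
    cods
  }
  ca <- codons_of(a)
  cb <- codons_of(b)
  best <- 3L
  for (x in ca) {
    for (y in cb) {
      d <- sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
      if (d < best) best <- d
    }
  }
  best
}

# Small random count table over a handful of variants (anchors included),
# for anchor-exactness property tests.
random_count_table <- function(seed, n_extra = 30) {
  set.seed(seed)
  extra <- unique(replicate(n_extra, paste(sample(AA_LETTERS, 4, TRUE),
                                           collapse = "")))
  variants <- unique(c("RTAG", "QKKR", extra))
  cols <- list()
  for (lib in c("pre", "parS_post", "NBS_post")) {
    for (r in 1:3) {
      cols[[length(cols) + 1L]] <- rpois(length(variants), lambda = 60) + 5L
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- variants
  count_table(m, rep(c("pre", "parS_post", "NBS_post"), each = 3),
              rep(1:3, times = 3))
}
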