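# Sequence-space networks of functional variants: graph construction,
# shortest mutational paths to the NBS-specific wild type, step-wise residue
# features, class traversal, and an edge-shuffled random-graph null.

#' Build the functional-variant sequence-space graph
#'
#' Nodes are functional (non-gray) classified variants; undirected edges join
#' variants differing by a single amino acid (`mode = "aa"`), or by a single
#' amino acid reachable through one nucleotide substitution under the chosen
#' codon model (`mode = "nt"`). Node degree is stored as a vertex attribute
#' (the node-size proxy in force-directed renderings).
#'
#' @param fitness data.frame with columns `variant` and `class` (as from
#'   [fitness_scores()]), or a character vector of variants with `classes`
#'   given separately.
#' @param classes optional class labels parallel to `fitness` when the
#'   latter is a character vector.
#' @param mode `"aa"` or `"nt"` adjacency.
#' @param codon_model codon set for nt adjacency: `"NNS"` (the library
#'   encoding, default) or `"full_standard"`.
#' @return An [igraph::igraph] with vertex attributes `name` (variant),
#'   `class` and `degree`, plus graph attributes `mode` and `codon_model`.
#' @export
build_graph <- function(fitness, classes = NULL, mode = c("aa", "nt"),
                        codon_model = c("NNS", "full_standard")) {
  mode <- match.arg(mode)
  codon_model <- match.arg(codon_model)
  if (is.data.frame(fitness)) {
    variants <- fitness$variant
    classes <- as.character(fitness$class)
  } else {
    variants <- fitness
    classes <- as.character(classes)
  }
  stopifnot(length(variants) == length(classes))
  keep <- classes != "gray" & !is.na(classes)
  variants <- variants[keep]
  classes <- classes[keep]
  if (anyDuplicated(variants)) stop("duplicate variants in graph input")
  if (length(variants) == 0L) {
    warning("no functional variants: returning empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    .validate_variants(variants)
    ntd <- if (mode == "nt") nt_distance_matrix(codon_model) else NULL
    edges <- .hamming1_edges(variants, ntd)
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = data.frame(name = variants, class = classes,
                            stringsAsFactors = FALSE))
  }
  igraph::V(g)$degree <- igraph::degree(g)
  g$mode <- mode
  g$codon_model <- codon_model
  g
}

# Enumerate pairs of variants at amino-acid Hamming distance 1; when a
# nucleotide-distance matrix is supplied, keep only pairs whose differing
# residues are one nucleotide substitution apart.
.hamming1_edges <- function(variants, ntd = NULL) {
  from <- character()
  to <- character()
  for (j in 1:4) {
    key <- paste0(substr(variants, 1, j - 1), substr(variants, j + 1, 4))
    buckets <- split(seq_along(variants), key)
    buckets <- buckets[lengths(buckets) > 1]
    for (b in buckets) {
      pr <- combn(b, 2)
      from <- c(from, variants[pr[1, ]])
      to <- c(to, variants[pr[2, ]])
    }
  }
  if (!is.null(ntd) && length(from)) {
    diff_pos <- integer(length(from))
    ra <- rb <- character(length(from))
    for (j in 1:4) {
      d <- substr(from, j, j) != substr(to, j, j)
      diff_pos[d] <- j
      ra[d] <- substr(from, j, j)[d]
      rb[d] <- substr(to, j, j)[d]
    }
    keep <- ntd[cbind(ra, rb)] == 1L
    from <- from[keep]
    to <- to[keep]
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' All shortest mutational paths from a source set to a target
#'
#' For each source, the geodesic distance to the target and the exhaustive
#' set of shortest paths (as node sequences). Unreachable sources get
#' infinite distance and contribute no paths.
#'
#' @param graph a graph from [build_graph()].
#' @param sources character vector of source variants (must be graph nodes).
#' @param target target variant (default QKKR); must be a graph node.
#' @return A `path_ensemble`: list with `sources`, `target`, `dist` (named,
#'   `Inf` if unreachable), `paths` (list of character node sequences) and
#'   `n_paths`.
#' @export
shortest_path_ensemble <- function(graph, sources, target = WT_NBS) {
  vn <- igraph::V(graph)$name
  if (!target %in% vn) stop(sprintf("target %s is not in the graph", target))
  missing_src <- setdiff(sources, vn)
  if (length(missing_src)) {
    stop("sources not in graph: ", paste(head(missing_src, 5), collapse = ", "))
  }
  if (length(sources) == 0L) {
    return(structure(list(sources = character(), target = target,
                          dist = numeric(), paths = list(), n_paths = 0L),
                     class = "path_ensemble"))
  }
  d <- igraph::distances(graph, v = sources, to = target)[, 1]
  names(d) <- sources
  paths <- list()
  for (s in sources) {
    if (!is.finite(d[s])) next
    sp <- igraph::all_shortest_paths(graph, from = s, to = target)$res
    paths <- c(paths, lapply(sp, function(p) igraph::V(graph)$name[p]))
  }
  structure(list(sources = sources, target = target, dist = d,
                 paths = paths, n_paths = length(paths)),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat(sprintf("path_ensemble: %d sources -> %s; %d shortest paths\n",
              length(x$sources), x$target, x$n_paths))
  if (length(x$dist)) {
    reach <- sum(is.finite(x$dist))
    cat(sprintf("reachable sources: %d; geodesic range %s-%s steps\n", reach,
                if (reach) min(x$dist[is.finite(x$dist)]) else NA,
                if (reach) max(x$dist[is.finite(x$dist)]) else NA))
  }
  invisible(x)
}

#' Sources for path analysis: parS-specific RXXG variants
#'
#' Dark-green (highly parS-specific) variants with the absolutely conserved
#' arginine at 173 and glycine at 201, excluding the target itself.
#'
#' @param graph a graph from [build_graph()].
#' @return Character vector of source variants.
#' @export
rxxg_sources <- function(graph) {
  vn <- igraph::V(graph)$name
  vn[igraph::V(graph)$class == "dark_green" & grepl("^R..G$", vn)]
}

#' Cumulative fraction of sources reaching the target within k steps
#'
#' @param ensemble a `path_ensemble`.
#' @param max_steps largest step count reported (default 8).
#' @return Named numeric vector, entry `k` = fraction of sources with
#'   geodesic distance at most k; unreachable sources never count.
#' @export
cumulative_reach <- function(ensemble, max_steps = 8L) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  k <- 0:max_steps
  out <- vapply(k, function(kk) mean(ensemble$dist <= kk), numeric(1))
  names(out) <- k
  out
}

#' Default step-feature predicates
#'
#' Residue features tracked along shortest paths: permissive K/R at 179 or
#' 184 (and at both), the NBS-switching arginine at 201, the NBS-switching
#' glutamine at 173, and C/T/S at 201 (the hallmark of dual-specificity
#' variants).
#'
#' @return Named list of predicate functions over variant vectors.
#' @export
default_step_predicates <- function() {
  list(
    KR_179_or_184 = function(v) {
      substr(v, 2, 2) %in% c("K", "R") | substr(v, 3, 3) %in% c("K", "R")
    },
    KR_179_and_184 = function(v) {
      substr(v, 2, 2) %in% c("K", "R") & substr(v, 3, 3) %in% c("K", "R")
    },
    R_201 = function(v) substr(v, 4, 4) == "R",
    Q_173 = function(v) substr(v, 1, 1) == "Q",
    CTS_201 = function(v) substr(v, 4, 4) %in% c("C", "T", "S")
  )
}

#' Residue-feature fractions of path intermediates per step
#'
#' For each step k, over all shortest paths of length at least k (each
#' geodesic counted once), the fraction whose node after k steps satisfies
#' each predicate; the node at k = path length is the target.
#'
#' @param ensemble a `path_ensemble`.
#' @param predicates named list of predicate functions (default
#'   [default_step_predicates()]).
#' @return Numeric matrix, rows = steps 0..max path length, columns =
#'   predicates; `NA` where no path is long enough.
#' @export
step_feature_fractions <- function(ensemble,
                                   predicates = default_step_predicates()) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  if (ensemble$n_paths == 0L) stop("empty path ensemble")
  lens <- lengths(ensemble$paths) - 1L
  kmax <- max(lens)
  out <- matrix(NA_real_, nrow = kmax + 1L, ncol = length(predicates),
                dimnames = list(0:kmax, names(predicates)))
  for (k in 0:kmax) {
    use <- lens >= k
    if (!any(use)) next
    nodes <- vapply(ensemble$paths[use], `[`, character(1), k + 1L)
    for (p in names(predicates)) {
      out[as.character(k), p] <- mean(predicates[[p]](nodes))
    }
  }
  out
}

#' Percentage of shortest paths traversing a class
#'
#' Percentage of paths in the ensemble with at least one intermediate node
#' (endpoints excluded) of the given class(es).
#'
#' @param ensemble a `path_ensemble`.
#' @param graph the graph the ensemble was computed on (for node classes),
#'   or a named character vector of classes.
#' @param classes class labels to report (default black, light_green, pink).
#' @return Named numeric vector of percentages (0-100).
#' @export
class_traversal <- function(ensemble, graph,
                            classes = c("black", "light_green", "pink")) {
  stopifnot(inherits(ensemble, "path_ensemble"))
  if (inherits(graph, "igraph")) {
    node_class <- setNames(igraph::V(graph)$class, igraph::V(graph)$name)
  } else {
    node_class <- graph
  }
  out <- setNames(numeric(length(classes)), classes)
  if (ensemble$n_paths == 0L) return(out)
  inter <- lapply(ensemble$paths, function(p) {
    if (length(p) <= 2L) character() else p[-c(1L, length(p))]
  })
  for (cl in classes) {
    hit <- vapply(inter, function(v) any(node_class[v] == cl, na.rm = TRUE),
                  logical(1))
    out[cl] <- 100 * mean(hit)
  }
  out
}

#' Edge-shuffled random-graph null for class traversal
#'
#' Repeatedly replaces the observed edge set by a uniform random simple graph
#' on the same node set with the same number of edges (hence identical
#' density), recomputes all shortest paths from the sources to the target,
#' and records the class-traversal percentages. Sources unreachable in a
#' shuffle are dropped from that shuffle's path set. The observed value's
#' empirical percentile is `100 * mean(null <= observed)`.
#'
#' @param graph graph from [build_graph()].
#' @param sources,target as in [shortest_path_ensemble()].
#' @param classes classes whose traversal is measured.
#' @param n_shuffles number of shuffles (default 1000).
#' @param seed integer seed.
#' @return A `null_distribution`: list with `observed`, `null` (matrix
#'   n_shuffles x classes), `percentile`, `n_shuffles`, and
#'   `unreachable_sources` per shuffle.
#' @export
shuffle_null <- function(graph, sources, target = WT_NBS,
                         classes = c("black", "light_green", "pink"),
                         n_shuffles = 1000L, seed = 1L) {
  stopifnot(n_shuffles >= 1)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  if (m > n * (n - 1) / 2) stop("edge count exceeds the simple-graph maximum")
  obs_ens <- shortest_path_ensemble(graph, sources, target)
  observed <- class_traversal(obs_ens, graph, classes)
  node_class <- setNames(igraph::V(graph)$class, igraph::V(graph)$name)
  vn <- igraph::V(graph)$name
  set.seed(seed)
  null <- matrix(NA_real_, n_shuffles, length(classes),
                 dimnames = list(NULL, classes))
  unreachable <- integer(n_shuffles)
  edge_counts <- node_counts <- integer(n_shuffles)
  for (i in seq_len(n_shuffles)) {
    gs <- igraph::sample_gnm(n, m, directed = FALSE)
    igraph::V(gs)$name <- vn
    igraph::V(gs)$class <- unname(node_class)
    edge_counts[i] <- igraph::ecount(gs)
    node_counts[i] <- igraph::vcount(gs)
    ens <- shortest_path_ensemble(gs, sources, target)
    unreachable[i] <- sum(!is.finite(ens$dist))
    null[i, ] <- class_traversal(ens, node_class, classes)
  }
  percentile <- setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    percentile[cl] <- 100 * mean(null[, cl] <= observed[cl])
  }
  structure(list(observed = observed, null = null, percentile = percentile,
                 n_shuffles = as.integer(n_shuffles),
                 unreachable_sources = unreachable,
                 node_counts = node_counts, edge_counts = edge_counts),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("edge-shuffle null (%d shuffles)\n", x$n_shuffles))
  for (cl in names(x$observed)) {
    cat(sprintf("  %-12s observed %5.1f%%  null mean %5.1f%%  percentile %5.1f\n",
                cl, x$observed[cl], mean(x$null[, cl]), x$percentile[cl]))
  }
  invisible(x)
}

#' Export a sequence-space graph to GraphML
#'
#' Writes nodes (variant, class, degree) and edges in GraphML, readable by
#' igraph and by network-visualisation tools for force-directed layout.
#'
#' @param graph graph from [build_graph()].
#' @param file output path.
#' @export
export_graph <- function(graph, file) {
  if (igraph::vcount(graph) > 0) {
    if (is.null(igraph::V(graph)$degree)) {
      igraph::V(graph)$degree <- igraph::degree(graph)
    }
    igraph::V(graph)$variant <- igraph::V(graph)$name
  }
  igraph::write_graph(graph, file, format = "graphml")
  invisible(file)
}
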