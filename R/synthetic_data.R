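# Synthetic-data generator: ground-truth landscapes, selection-distorted
# count tables, and raw staggered-amplicon reads with Phred qualities.

#' Default ground-truth landscape rules
#'
#' Per-assay, per-position residue weight tables plus permissive-gate residue
#' sets. The truth fitness of a variant in an assay is the product of its
#' four position weights, multiplied by a permissive gate: the gate is open
#' (1) if position 179 or 184 carries a gate residue for that assay, and
#' `gate_floor` otherwise. For the NBS assay the gate residues are the
#' positively charged K/R (non-specific phosphate-backbone affinity); for the
#' parS assay the native ParB residues (T179, A184) open the gate as well.
#'
#' The weight tables are graded (log-spaced from the preferred residue down
#' to a per-position floor) so that true fitness is broadly distributed —
#' the regime in which enrichment-based estimates can be benchmarked against
#' truth — while hard zeros carry the specificity logic: glutamine at 173
#' abolishes the parS mode, arginine/lysine at 201 abolish parS, and glycine
#' at 201 abolishes NBS. Together with the gate this reproduces the
#' qualitative epistasis of the selections: R173Q and G201R alone kill
#' binding, while a lysine/arginine at 179 or 184 licenses the NBS-binding
#' mode.
#'
#' @param gate_floor multiplier in \[0, 1\] applied when no gate residue is
#'   present at either 179 or 184 (default 0.4: residual, sub-threshold
#'   binding; 0 recovers a hard gate).
#' @return List with elements `parS`, `NBS` (each `weights` 20 x 4 matrix and
#'   `gate` list for positions 179/184) and `gate_floor`.
#' @export
default_truth_rules <- function(gate_floor = 0.4) {
  stopifnot(gate_floor >= 0, gate_floor <= 1)
  w_parS <- cbind(
    `173` = c(A = 0.747, C = 0.705, D = 0.526, E = 0.839, F = 0.469,
              G = 0.417, H = 0.890, I = 0.792, K = 0.943, L = 0.350,
              M = 0.371, N = 0.442, P = 0.592, Q = 0.000, R = 1.000,
              S = 0.665, T = 0.558, V = 0.497, W = 0.627, Y = 0.393),
    `179` = c(A = 0.970, C = 0.873, D = 0.834, E = 0.821, F = 0.773,
              G = 0.927, H = 0.913, I = 0.797, K = 0.956, L = 0.886,
              M = 0.847, N = 0.809, P = 0.859, Q = 0.785, R = 0.941,
              S = 0.985, T = 1.000, V = 0.761, W = 0.899, Y = 0.750),
    `184` = c(A = 1.000, C = 0.773, D = 0.797, E = 0.834, F = 0.873,
              G = 0.927, H = 0.750, I = 0.886, K = 0.956, L = 0.847,
              M = 0.785, N = 0.913, P = 0.809, Q = 0.899, R = 0.941,
              S = 0.970, T = 0.985, V = 0.821, W = 0.859, Y = 0.761),
    `201` = c(A = 0.722, C = 0.783, D = 0.294, E = 0.408, F = 0.565,
              G = 1.000, H = 0.319, I = 0.442, K = 0.000, L = 0.480,
              M = 0.665, N = 0.250, P = 0.376, Q = 0.613, R = 0.000,
              S = 0.922, T = 0.850, V = 0.521, W = 0.346, Y = 0.271)
  )
  w_NBS <- cbind(
    `173` = c(A = 0.370, C = 0.718, D = 0.461, E = 0.802, F = 0.391,
              G = 0.515, H = 0.847, I = 0.488, K = 0.946, L = 0.437,
              M = 0.350, N = 0.895, P = 0.643, Q = 1.000, R = 0.759,
              S = 0.545, T = 0.679, V = 0.575, W = 0.608, Y = 0.413),
    `179` = c(A = 0.773, C = 0.847, D = 0.873, E = 0.886, F = 0.941,
              G = 0.761, H = 0.809, I = 0.899, K = 1.000, L = 0.859,
              M = 0.927, N = 0.797, P = 0.750, Q = 0.913, R = 0.985,
              S = 0.956, T = 0.970, V = 0.821, W = 0.834, Y = 0.785),
    `184` = c(A = 0.970, C = 0.750, D = 0.886, E = 0.927, F = 0.761,
              G = 0.773, H = 0.859, I = 0.899, K = 1.000, L = 0.847,
              M = 0.834, N = 0.941, P = 0.809, Q = 0.913, R = 0.985,
              S = 0.956, T = 0.797, V = 0.785, W = 0.821, Y = 0.873),
    `201` = c(A = 0.367, C = 0.735, D = 0.583, E = 0.315, F = 0.680,
              G = 0.000, H = 0.397, I = 0.630, K = 0.926, L = 0.270,
              M = 0.250, N = 0.463, P = 0.429, Q = 0.540, R = 1.000,
              S = 0.794, T = 0.857, V = 0.340, W = 0.500, Y = 0.292)
  )
  list(
    parS = list(weights = w_parS,
                gate = list(`179` = c("T", "K", "R"),
                            `184` = c("A", "K", "R"))),
    NBS = list(weights = w_NBS,
               gate = list(`179` = c("K", "R"), `184` = c("K", "R"))),
    gate_floor = gate_floor
  )
}

.check_rules <- function(rules) {
  for (assay in c("parS", "NBS")) {
    w <- rules[[assay]]$weights
    if (!is.matrix(w) || !identical(sort(rownames(w)), AA20) ||
        ncol(w) != 4L) {
      stop(sprintf(
        "configuration error: %s weight table must cover all 20 residues at all 4 positions",
        assay), call. = FALSE)
    }
    if (any(is.na(w)) || any(w < 0) || any(w > 1)) {
      stop("configuration error: weights must lie in [0, 1]", call. = FALSE)
    }
    if (!all(c("179", "184") %in% names(rules[[assay]]$gate))) {
      stop("configuration error: gate sets needed for positions 179 and 184",
           call. = FALSE)
    }
  }
  if (is.null(rules$gate_floor) || rules$gate_floor < 0 ||
      rules$gate_floor > 1) {
    stop("configuration error: gate_floor must lie in [0, 1]", call. = FALSE)
  }
  invisible(rules)
}

.assay_truth <- function(res, rules, assay, noise_scale) {
  w <- rules[[assay]]$weights
  base <- w[res[, 1], "173"] * w[res[, 2], "179"] *
    w[res[, 3], "184"] * w[res[, 4], "201"]
  if (noise_scale > 0) {
    base <- base * exp(rnorm(nrow(res), 0, noise_scale))
  }
  gate_set <- rules[[assay]]$gate
  open <- res[, 2] %in% gate_set[["179"]] | res[, 3] %in% gate_set[["184"]]
  pmin(base, 1) * ifelse(open, 1, rules$gate_floor)
}

#' Build a ground-truth fitness landscape
#'
#' Assigns every one of the 160,000 four-residue variants a true fitness pair
#' (`t_parS`, `t_NBS`) in \[0, 1\] under the rule set of
#' [default_truth_rules()]. Noise is multiplicative log-normal
#' (`base * exp(N(0, noise_scale))`, clamped), so dead variants stay exactly
#' dead and the permissive-gate bound survives perturbation. The two
#' wild-type anchors are pinned by construction: `t_parS(RTAG) = 1` and
#' `t_NBS(QKKR) = 1`.
#'
#' @param rules rule set as returned by [default_truth_rules()].
#' @param noise_scale standard deviation of the log-scale perturbation
#'   (default 0: examples are exact).
#' @param seed integer seed; the landscape is deterministic given it.
#' @return A `truth_landscape`: data.frame with columns `variant`, `t_parS`,
#'   `t_NBS`, with the rules attached as attributes.
#' @export
#' @examples
#' tl <- build_truth_landscape()
#' subset(tl, variant %in% c("RTAG", "QKKR", "QTAG"))
build_truth_landscape <- function(rules = default_truth_rules(),
                                  noise_scale = 0, seed = 1L) {
  .check_rules(rules)
  stopifnot(noise_scale >= 0)
  set.seed(seed)
  v <- all_variants()
  res <- variant_residues(v)
  t_parS <- .assay_truth(res, rules, "parS", noise_scale)
  t_NBS <- .assay_truth(res, rules, "NBS", noise_scale)
  t_parS[v == WT_PARS] <- 1
  t_NBS[v == WT_NBS] <- 1
  structure(
    data.frame(variant = v, t_parS = unname(t_parS), t_NBS = unname(t_NBS),
               stringsAsFactors = FALSE),
    rules = rules, noise_scale = noise_scale, seed = seed,
    class = c("truth_landscape", "data.frame"))
}

#' Simulation configuration
#'
#' Parameters of the synthetic B1H-seq experiment. `depth` is the number of
#' reads drawn per library per replicate; `alpha` scales selection strength
#' (post-selection sampling probability is proportional to pre-selection
#' abundance times `10^(alpha * t)`, the inverse of the log10 enrichment
#' fitness definition); `error_rate` is the per-base substitution rate;
#' `offsets` are the staggered forward-primer offsets that shift the amplicon
#' within the read; the quality profile is a two-component mixture of
#' uniformly high (`qual_high`) and uniformly low (`qual_low`) reads with
#' low-read weight `low_qual_frac`.
#'
#' @param depth reads per library per replicate (> 0).
#' @param alpha selection strength exponent.
#' @param error_rate per-base substitution probability in \[0, 1).
#' @param offsets non-negative integer stagger offsets.
#' @param replicates number of independent replicates (default 3).
#' @param abundance_sigma log-normal sd of pre-selection variant abundances
#'   (default 0.5; real libraries are uneven).
#' @param qual_high,qual_low Phred scores of the two quality components.
#' @param low_qual_frac mixture weight of the low-quality component.
#' @param read_length simulated read length (default 150).
#' @param seed integer random seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(depth = 1e6, alpha = 1, error_rate = 0.001,
                       offsets = 0:4, replicates = 3,
                       abundance_sigma = 0.5, qual_high = 38L,
                       qual_low = 20L, low_qual_frac = 0.05,
                       read_length = 150L, seed = 1L) {
  stopifnot(depth > 0, error_rate >= 0, error_rate < 1,
            all(offsets >= 0), replicates >= 1,
            abundance_sigma >= 0, low_qual_frac >= 0, low_qual_frac <= 1)
  if (any(20L + offsets + 87L > read_length)) {
    stop("offsets too large: the 87-bp template must fit in the read after ",
         "the 20-nt leading flank")
  }
  structure(list(depth = depth, alpha = alpha, error_rate = error_rate,
                 offsets = as.integer(offsets),
                 replicates = as.integer(replicates),
                 abundance_sigma = abundance_sigma,
                 qual_high = as.integer(qual_high),
                 qual_low = as.integer(qual_low),
                 low_qual_frac = low_qual_frac,
                 read_length = as.integer(read_length),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate selection-distorted count tables
#'
#' Draws pre-selection counts from a multinomial over (log-normally uneven)
#' variant abundances, and post-selection counts from probabilities
#' proportional to abundance times `10^(alpha * t)` for the assay's truth
#' fitness, independently per replicate.
#'
#' @param truth a `truth_landscape` from [build_truth_landscape()].
#' @param cfg a [sim_config()].
#' @param abundances optional non-negative relative pre-selection abundances
#'   (one per truth row); drawn log-normally when `NULL`.
#' @return A [count_table] over all truth variants.
#' @export
simulate_selection_counts <- function(truth, cfg = sim_config(),
                                      abundances = NULL) {
  stopifnot(inherits(truth, "truth_landscape"), inherits(cfg, "sim_config"))
  set.seed(.stage_seed(cfg$seed, 1L))
  n <- nrow(truth)
  if (is.null(abundances)) {
    abundances <- rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sigma)
  }
  stopifnot(length(abundances) == n, all(abundances >= 0))
  if (sum(abundances) == 0) {
    stop("degenerate input: all-zero abundance vector")
  }
  probs <- list(
    pre = abundances,
    parS_post = abundances * 10^(cfg$alpha * truth$t_parS),
    NBS_post = abundances * 10^(cfg$alpha * truth$t_NBS)
  )
  cols <- list()
  library <- character()
  replicate <- integer()
  for (lib in LIBRARIES) {
    p <- probs[[lib]] / sum(probs[[lib]])
    for (r in seq_len(cfg$replicates)) {
      cols[[length(cols) + 1L]] <- rmultinom(1, size = cfg$depth, prob = p)[, 1]
      library <- c(library, lib)
      replicate <- c(replicate, r)
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- truth$variant
  count_table(m, library, replicate)
}

# Fixed non-template flanks surrounding the amplicon in simulated reads;
# chosen free of the amplicon linkers so no spurious template match arises.
FLANK_LEFT <- "GATCTTAAGGCTAGAGTACTTAATACGACTCACTATAGGGAGACCACAACGGTTTCCCTCTAG"
FLANK_RIGHT <- "CAAGGAGATATACATATGGCAGATCTCGATCCCGCGAAATTAATACGATCACTATAGGGGAAT"

.random_codons_for <- function(res, codon_tab) {
  out <- character(length(res))
  for (r in unique(res)) {
    idx <- which(res == r)
    out[idx] <- sample(codon_tab[[r]], length(idx), replace = TRUE)
  }
  out
}

.apply_base_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  len <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), len, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(len[i], n_err[i])
    for (p in pos) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  seqs
}

#' Emit raw FASTQ reads for a simulated count table
#'
#' For every counted molecule, picks NNS codons uniformly among those encoding
#' each residue, embeds the resulting 87-bp amplicon into a read at a
#' staggered offset between fixed flanks, applies per-base substitution
#' errors, attaches Phred+33 quality strings from the two-component quality
#' profile, and writes one FASTQ file per (library, replicate). With
#' `error_rate = 0` and `low_qual_frac = 0` the decoded counts equal the
#' input counts exactly.
#'
#' @param counts a [count_table].
#' @param cfg a [sim_config()]; its `error_rate`, `offsets`, quality profile,
#'   `read_length` and `seed` are used.
#' @param dir output directory (created if missing).
#' @param gzip write `.fastq.gz` instead of `.fastq`.
#' @return Manifest data.frame with columns `library`, `replicate`, `path`,
#'   `n_reads`.
#' @export
emit_reads <- function(counts, cfg = sim_config(), dir, gzip = FALSE) {
  stopifnot(inherits(counts, "count_table"), inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.stage_seed(cfg$seed, 2L))
  codon_tab <- codons_by_aa("NNS")
  libs <- attr(counts, "library")
  reps <- attr(counts, "replicate")
  manifest <- data.frame(library = libs, replicate = reps,
                         path = character(length(libs)),
                         n_reads = integer(length(libs)),
                         stringsAsFactors = FALSE)
  q_high <- strrep(rawToChar(as.raw(33L + cfg$qual_high)), cfg$read_length)
  q_low <- strrep(rawToChar(as.raw(33L + cfg$qual_low)), cfg$read_length)
  right_need <- cfg$read_length - 107L  # after 20-nt flank + max-offset fit
  if (nchar(FLANK_LEFT) < 20L + max(cfg$offsets) ||
      nchar(FLANK_RIGHT) < right_need) {
    stop("internal error: flank constants shorter than required")
  }
  for (k in seq_along(libs)) {
    cnt <- counts[, k]
    v <- rep(rownames(counts), times = cnt)
    n <- length(v)
    if (n > 0) {
      v <- v[sample.int(n)]
      res <- variant_residues(v)
      codons <- cbind(.random_codons_for(res[, 1], codon_tab),
                      .random_codons_for(res[, 2], codon_tab),
                      .random_codons_for(res[, 3], codon_tab),
                      .random_codons_for(res[, 4], codon_tab))
      amplicon <- amplicon_from_codons(codons)
      off <- sample(cfg$offsets, n, replace = TRUE)
      left <- substr(FLANK_LEFT, nchar(FLANK_LEFT) - (20L + off) + 1L,
                     nchar(FLANK_LEFT))
      right_len <- cfg$read_length - 20L - off - 87L
      right <- substr(FLANK_RIGHT, 1L, right_len)
      seqs <- .apply_base_errors(paste0(left, amplicon, right),
                                 cfg$error_rate)
      low <- runif(n) < cfg$low_qual_frac
      quals <- ifelse(low, q_low, q_high)
      ids <- sprintf("@sim:%s:%d:%d", libs[k], reps[k], seq_len(n))
    } else {
      seqs <- quals <- ids <- character()
    }
    fname <- sprintf("%s_rep%d.fastq%s", libs[k], reps[k],
                     if (gzip) ".gz" else "")
    path <- file.path(dir, fname)
    con <- if (gzip) gzfile(path, "wb") else file(path, "wb")
    lines <- if (n > 0) as.vector(rbind(ids, seqs, "+", quals)) else character()
    writeLines(lines, con, sep = "\n")
    close(con)
    manifest$path[k] <- path
    manifest$n_reads[k] <- n
  }
  manifest
}

# Derive a bounded per-stage seed from the run seed.
.stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435761 + 97 * k) %% 2147483629)
}
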