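pooled_matrix <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- c("pre", "parS_post", "NBS_post")
  m
}

test_that("raw fitness is the log10 enrichment relative to wild type", {
  pooled <- pooled_matrix(
    RTAG = c(100L, 1000L, 50L),
    QKKR = c(100L, 1000L, 50L),
    AAAA = c(10L, 100L, 5L))
  f <- raw_fitness(pooled, "parS")
  expect_equal(unname(f["RTAG"]), 0)          # wt self-score
  expect_equal(unname(f["AAAA"]), 0)          # log10(0.1) - log10(0.1)
  pooled_b <- pooled_matrix(
    RTAG = c(100L, 100L, 50L),
    QKKR = c(100L, 100L, 50L),
    CCCC = c(10L, 1000L, 5L))
  fb <- raw_fitness(pooled_b, "parS")
  expect_equal(unname(fb["CCCC"]), 2)         # 1 - (-1)
  # zero wild-type counts are a hard error naming the library
  bad <- pooled
  bad["RTAG", "parS_post"] <- 0L
  expect_error(raw_fitness(bad, "parS"), "parS_post")
  # zero variant counts flag the variant undefined, not an error
  pooled2 <- pooled
  pooled2["AAAA", "parS_post"] <- 0L
  expect_true(is.na(raw_fitness(pooled2, "parS")["AAAA"]))
})

test_that("normalisation sends the anchors to exactly 1 and 0", {
  raw <- c(RTAG = 0, QKKR = -2, AAAA = -1)
  f <- normalize_fitness(raw, "RTAG", "QKKR")
  expect_equal(unname(f["RTAG"]), 1)
  expect_equal(unname(f["QKKR"]), 0)
  expect_equal(unname(f["AAAA"]), 0.5)        # (-1 + 2) / (0 + 2)
  expect_error(normalize_fitness(c(RTAG = 0, QKKR = 0), "RTAG", "QKKR"),
               "degenerate")
  expect_error(normalize_fitness(c(RTAG = 0), "RTAG", "QKKR"), "anchor")
})

test_that("anchors are exact on arbitrary random count tables", {
  for (seed in c(1, 7, 23)) {
    ct <- random_count_table(seed)
    fit <- fitness_scores(ct, min_count = 10)
    expect_equal(fit$f_parS[fit$variant == "RTAG"], 1)
    expect_equal(fit$f_parS[fit$variant == "QKKR"], 0)
    expect_equal(fit$f_NBS[fit$variant == "QKKR"], 1)
    expect_equal(fit$f_NBS[fit$variant == "RTAG"], 0)
  }
})

test_that("raw fitness is invariant to per-library count rescaling", {
  ct <- random_count_table(11)
  f1 <- raw_fitness(count_and_pool(ct)$pooled, "parS")
  scaled <- unclass(ct)
  pre_cols <- which(attr(ct, "library") == "pre")
  scaled[, pre_cols] <- scaled[, pre_cols] * 7L
  ct2 <- count_table(scaled, attr(ct, "library"), attr(ct, "replicate"))
  f2 <- raw_fitness(count_and_pool(ct2)$pooled, "parS")
  expect_equal(f1, f2)
})

test_that("specificity classes follow the two-threshold scheme", {
  expect_equal(as.character(classify_variants(0.8, 0.1)), "dark_green")
  expect_equal(as.character(classify_variants(0.65, 0.65)), "black")
  expect_equal(as.character(classify_variants(0.5, 0.1)), "gray")
  expect_equal(as.character(classify_variants(0.7, 0.4)), "light_green")
  expect_equal(as.character(classify_variants(0.1, 0.9)), "magenta")
  expect_equal(as.character(classify_variants(0.4, 0.9)), "pink")
  expect_equal(as.character(classify_variants(NA_real_, 0.9)), "gray")
  # boundary ties resolve to the stricter class; black beats the weak bands
  expect_equal(as.character(classify_variants(0.7, 0.2)), "dark_green")
  expect_equal(as.character(classify_variants(0.2, 0.7)), "magenta")
  expect_equal(as.character(classify_variants(0.6, 0.6)), "black")
  # every score pair gets exactly one label
  grid <- expand.grid(p = seq(0, 1, by = 0.1), n = seq(0, 1, by = 0.1))
  cls <- classify_variants(grid$p, grid$n)
  expect_equal(length(cls), nrow(grid))
  expect_false(any(is.na(cls)))
})

test_that("class logos are per-position frequency matrices", {
  m <- class_logo("RTAG")
  expect_equal(dim(m), c(4L, 20L))
  expect_equal(unname(m["173", "R"]), 1)
  expect_equal(unname(rowSums(m)), rep(1, 4))
  m2 <- class_logo(c("RTAG", "RKAG"))
  expect_equal(unname(m2["179", c("T", "K")]), c(0.5, 0.5))
  expect_equal(unname(rowSums(m2)), rep(1, 4))
  expect_warning(m0 <- class_logo(character()), "empty")
  expect_true(all(m0 == 0))
})

test_that("permissive K/R fractions and random expectations are correct", {
  pf <- permissive_fraction(c("QKKR", "QKAR"))
  obs <- setNames(pf$observed, pf$feature)
  expect_equal(unname(obs["at179"]), 1)
  expect_equal(unname(obs["at184"]), 0.5)
  expect_equal(unname(obs["either"]), 1)
  expect_equal(unname(obs["both"]), 0.5)
  exp_ <- setNames(pf$expected_random, pf$feature)
  expect_equal(unname(exp_["at179"]), 0.10)
  expect_equal(unname(exp_["at184"]), 0.10)
  expect_equal(unname(exp_["either"]), 0.19)
  expect_equal(unname(exp_["both"]), 0.01)
})

test_that("variants absent post-selection come out gray, not scored", {
  ct <- random_count_table(31)
  m <- unclass(ct)
  # make one variant absent from the parS post-selection library
  v <- setdiff(rownames(m), c("RTAG", "QKKR"))[1]
  m[v, which(attr(ct, "library") == "parS_post")] <- 0L
  ct2 <- count_table(m, attr(ct, "library"), attr(ct, "replicate"))
  fit <- fitness_scores(ct2)
  expect_false(fit$defined_parS[fit$variant == v])
  expect_equal(as.character(fit$class[fit$variant == v]), "gray")
})

test_that("estimates recover the true landscape when depth per variant suffices", {
  # a 2000-variant sub-library sequenced at full depth: ~1500 reads/variant
  tl <- build_truth_landscape(noise_scale = 0.05, seed = 11)
  set.seed(123)
  ab <- rep(0, nrow(tl))
  ab[sample(nrow(tl), 2000)] <- rlnorm(2000, 0, 0.5)
  ab[tl$variant %in% c("RTAG", "QKKR")] <- 1
  ct <- simulate_selection_counts(tl, sim_config(depth = 1e6, seed = 7),
                                  abundances = ab)
  fit <- fitness_scores(ct)
  okp <- fit$defined_parS
  okn <- fit$defined_NBS
  expect_gte(cor(fit$f_parS[okp], tl$t_parS[okp], method = "spearman"), 0.9)
  expect_gte(cor(fit$f_NBS[okn], tl$t_NBS[okn], method = "spearman"), 0.9)
  # normalized fitness estimates truth on its own scale, not just in rank
  expect_lte(mean(abs(fit$f_parS[okp] - tl$t_parS[okp])), 0.05)
})
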