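test_that("filter scanning visits S - F + 1 sites with leftmost-tie argmax", {
  withr::local_seed(43)
  enc <- matrix(stats::runif(373 * 16), 373, 16)
  filt <- matrix(stats::rnorm(26 * 16), 26, 16)
  sc <- scanActivations(filt, enc)
  expect_length(sc$activations, 373 - 26 + 1)  # 348

  z <- scanActivations(matrix(0, 5, 16), enc)
  expect_true(all(z$activations == 0))
  expect_equal(z$site, 1L)

  # brute-force double-loop oracle
  oracle <- numeric(348)
  for (p in 1:348) {
    tot <- 0
    for (r in 1:26) for (cc in 1:16) tot <- tot + filt[r, cc] * enc[p + r - 1, cc]
    oracle[p] <- tot
  }
  expect_equal(sc$activations, oracle, tolerance = 1e-6)
  expect_error(scanActivations(matrix(0, 10, 16), enc[1:5, ]), "exceeds")
})

test_that("harvested substrings decode to width F + k1 - 1 nucleotides", {
  cfg <- kdeepConfig(inputCols = 16, inputRows = 28, nFilters = 3,
                     filterWidth = 5, poolSize = 2, lstmUnits = 4,
                     denseUnits = 8, seed = 47L)
  mod <- buildModel(cfg)
  withr::local_seed(47)
  seqs <- stats::setNames(vapply(1:6, function(i) randomStrand(30),
                                 character(1)), paste0("s", 1:6))
  subs <- harvestSubstrings(mod, seqs, activationFraction = 0)
  expect_length(subs, 3L)
  # keep-all: exactly one substring per (filter, strand)
  expect_true(all(lengths(subs) == 6L))
  expect_true(all(nchar(unlist(subs)) == 5 + 3 - 1))

  # a filter that is never positive harvests nothing at fraction > 0 ...
  mod@params$convW[, 2] <- -abs(mod@params$convW[, 2]) - 1
  subs2 <- harvestSubstrings(mod, seqs, activationFraction = 0.5)
  expect_length(subs2[[2]], 0L)
  # ... yet the motif pipeline still emits a (uniform) PWM for it
  pwms <- extractMotifs(mod, seqs, activationFraction = 0.5)
  expect_length(pwms, 3L)
  expect_equal(nSites(pwms[[2]]), 0L)
  expect_true(all(pwmMatrix(pwms[[2]]) == 0.25))
})

test_that("position frequency matrices tally aligned substrings", {
  pfm <- pfmFromSubstrings(c("ACG", "ACG"))
  expect_equal(unname(pfmCounts(pfm)[, 1]), c(2, 0, 0, 0))

  pfm2 <- pfmFromSubstrings(c("ACG", "TCG"))
  expect_equal(unname(pfmCounts(pfm2)[, 1]), c(1, 0, 0, 1))
  expect_equal(unname(pfmCounts(pfm2)[, 2]), c(0, 2, 0, 0))
  expect_equal(unname(pfmCounts(pfm2)[, 3]), c(0, 0, 2, 0))

  expect_error(pfmFromSubstrings(c("ACG", "ACGT")), "width")

  # N contributes to no base
  pfmN <- pfmFromSubstrings(c("AN", "AA"))
  expect_equal(unname(colSums(pfmCounts(pfmN))), c(2, 1))

  # random substrings against a per-position counting oracle
  withr::local_seed(53)
  subs <- vapply(1:100, function(i) randomStrand(7), character(1))
  got <- pfmCounts(pfmFromSubstrings(subs))
  for (j in 1:7) {
    tab <- table(factor(substr(subs, j, j), levels = c("A", "C", "G", "T")))
    expect_equal(unname(got[, j]), as.numeric(tab))
  }
})

test_that("PWM normalization applies the pseudocount formula per column", {
  pfm <- pfmFromSubstrings(c("A", "A"))
  pwm <- pwmFromPfm(pfm, 0.25)
  expect_equal(unname(pwmMatrix(pwm)[, 1]), c(0.75, 1/12, 1/12, 1/12))

  empty <- pwmFromPfm(pfmFromSubstrings(character(0), W = 3), 0.25)
  expect_true(all(pwmMatrix(empty) == 0.25))

  withr::local_seed(59)
  subs <- vapply(1:20, function(i) randomStrand(5), character(1))
  pwm2 <- pwmFromPfm(pfmFromSubstrings(subs), 0.1)
  expect_equal(unname(colSums(pwmMatrix(pwm2))), rep(1, 5))
  expect_error(pwmFromPfm(pfm, 0), "pseudocount > 0")
})

test_that("motif extraction emits one PWM per filter with provenance", {
  cfg <- tinyConfig(nFilters = 16, seed = 61L)
  mod <- buildModel(cfg)
  ds <- tinyDataset(30, seed = 61)
  pwms <- extractMotifs(mod, strands(ds))
  expect_length(pwms, 16L)
  expect_true(all(vapply(pwms, function(p) ncol(pwmMatrix(p)), integer(1))
                  == 16 + 3 - 1))
  expect_equal(vapply(pwms, function(p) p@filterIndex, integer(1)), 1:16)
  expect_true(all(vapply(pwms, function(p)
    all(abs(colSums(pwmMatrix(p)) - 1) < 1e-9), logical(1))))
})

test_that("MEME minimal format round-trips and supports the RNA alphabet", {
  uni <- pwmFromPfm(pfmFromSubstrings(character(0), W = 3), 0.25)
  withr::local_seed(67)
  subs <- vapply(1:30, function(i) randomStrand(4), character(1))
  rich <- pwmFromPfm(pfmFromSubstrings(subs), 0.25, filterIndex = 7L)
  f <- withr::local_tempfile(fileext = ".meme")
  writeMeme(list(uni, rich), f)
  txt <- readLines(f)
  expect_equal(sum(grepl("^MOTIF", txt)), 2L)
  expect_true(any(grepl("ALPHABET= ACGT", txt)))
  back <- readMeme(f)
  expect_equal(pwmMatrix(back[[1]]), pwmMatrix(uni), tolerance = 1e-5)
  expect_equal(pwmMatrix(back[[2]]), pwmMatrix(rich), tolerance = 1e-5)
  expect_equal(back[[2]]@filterIndex, 7L)

  writeMeme(rich, f, alphabet = "RNA")
  expect_true(any(grepl("ALPHABET= ACGU", readLines(f))))
})

test_that("PWM similarity finds an embedded motif at the right offset", {
  ref <- defaultMotifPwm()
  expect_equal(pwmSimilarity(ref, ref)$score, 1)
  wide <- matrix(0.25, 4, 14)
  wide[, 4:11] <- ref
  m <- pwmSimilarity(wide, ref)
  expect_equal(m$offset, 3L)
  expect_equal(m$score, 1)
  # uniform columns score zero, not NA
  expect_equal(pwmSimilarity(matrix(0.25, 4, 8), ref)$score, 0)
})

test_that("attention heatmaps export row-stochastic scores", {
  mod <- buildModel(tinyConfig(useAttention = TRUE, seed = 71L))
  withr::local_seed(71)
  s <- randomStrand(61)
  seqs <- c(a = s, b = randomStrand(61), c = s)
  prefix <- file.path(withr::local_tempdir(), "attn")
  scores <- attentionHeatmap(mod, seqs, prefix)
  expect_equal(unname(rowSums(scores)), rep(1, 3), tolerance = 1e-6)
  expect_equal(scores["a", ], scores["c", ])  # identical strands, identical rows
  expect_true(file.exists(paste0(prefix, ".tsv")))
  expect_true(file.exists(paste0(prefix, ".png")))

  plain <- buildModel(tinyConfig(seed = 71L))
  expect_error(attentionHeatmap(plain, seqs, prefix), "attention")
})
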