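test_that("sliding-window k-merization follows the stride-1 contract", {
  expect_identical(kmerize("ATGCGA", 3), c("ATG", "TGC", "GCG", "CGA"))
  expect_identical(kmerize("AAAA", 3), c("AAA", "AAA"))
  expect_error(kmerize("AT", 3, id = "s9"), "s9")
  expect_length(kmerize(randomStrand(20), 3, stride = 2), 9L)
})

test_that("the lookup table enumerates every word over {A,C,G,T,N}", {
  lt <- buildLookup(3, 2)
  expect_equal(nrow(lt@entries), 125L)
  expect_equal(ncol(lt@entries), 16L)
  # each entry equals the FCGR vector recomputed on demand
  withr::local_seed(21)
  for (w in sample(rownames(lt@entries), 20))
    expect_equal(unname(lt@entries[w, ]), fcgrVector(w, 2))

  lt33 <- buildLookup(3, 3)
  expect_equal(dim(lt33@entries), c(125L, 64L))
  nfree <- rownames(lt33@entries)[!grepl("N", rownames(lt33@entries))]
  expect_true(all(rowSums(lt33@entries[nfree, ] == 1) == 1))  # one-hot rows

  expect_equal(nrow(buildLookup(2, 2)@entries), 25L)
  expect_error(buildLookup(2, 3), "exceed")
})

test_that("2Lk encoding obeys the (L - k1 + 1) x 4^k2 shape law", {
  m <- encode2Lk("ATGCGA", 3, 2)
  expect_equal(dim(m), c(4L, 16L))
  expect_equal(which(m[1, ] != 0) - 1L, c(3L, 14L))
  expect_true(all(rowSums(m) == 2))

  expect_equal(dim(encode2Lk(randomStrand(375), 3, 2)), c(373L, 16L))
  expect_equal(dim(encode2Lk(randomStrand(101), 3, 3)), c(99L, 64L))
})

test_that("lookup-table encoding equals direct FCGR computation bitwise", {
  withr::local_seed(31)
  lt <- buildLookup(3, 2)
  for (i in 1:10) {
    s <- randomStrand(sample(10:60, 1))
    expect_identical(encode2Lk(s, 3, 2, lookup = lt),
                     unname(t(vapply(kmerize(s, 3), fcgrVector,
                                     numeric(16), k2 = 2))))
  }
})

test_that("2Lk rows sum to k1 - k2 + 1 even with N characters", {
  withr::local_seed(41)
  for (i in 1:10) {
    k1 <- sample(2:4, 1); k2 <- sample(seq_len(k1), 1)
    s <- randomStrand(sample(20:50, 1), c("A", "C", "G", "T", "N"))
    m <- encode2Lk(s, k1, k2, lookup = buildLookup(k1, k2))
    expect_equal(rowSums(m), rep(k1 - k2 + 1, nrow(m)), tolerance = 1e-9)
  }
})

test_that("one-hot encoding uses A,C,G,T columns and zero rows for N", {
  expect_equal(encodeOneHot("ACGT"), diag(4))
  expect_equal(encodeOneHot("AN"), rbind(c(1, 0, 0, 0), c(0, 0, 0, 0)))
  expect_equal(dim(encodeOneHot(randomStrand(375))), c(375L, 4L))
})

test_that("batch encoding zero-pads on the right and tracks validity", {
  b <- encodeBatch(c(x = "ATGCGA", y = "ATGCGATG"), "2lk", 3, 2)
  expect_equal(dim(encodedTensor(b)), c(2L, 6L, 16L))
  expect_true(all(encodedTensor(b)[1, 5:6, ] == 0))
  expect_equal(unname(rowSums(validMask(b))), c(4, 6))

  # fixed-length batch: no padding, all-true mask
  bf <- encodeBatch(c(a = "ACGTACGT", b = "TTTTAAAA"), "2lk", 3, 2)
  expect_true(all(validMask(bf)))

  expect_error(encodeBatch(character(0)), "empty")
})

test_that("row sums are conserved under batch padding (masked rows zero)", {
  withr::local_seed(51)
  seqs <- vapply(1:40, function(i) randomStrand(sample(10:30, 1)), character(1))
  names(seqs) <- paste0("s", 1:40)
  b <- encodeBatch(seqs, "2lk", 3, 2)
  rs <- apply(encodedTensor(b), c(1, 2), sum)
  expect_true(all(rs[validMask(b)] == 2))
  expect_true(all(rs[!validMask(b)] == 0))
  # subsetting preserves content
  expect_equal(encodedTensor(b["s7"])[1, , ], encodedTensor(b)[7, , ])
})

test_that("footprint arithmetic reproduces the published shape comparison", {
  fp <- footprintReport(375, 1, "2lk", 3, 2)
  expect_equal(fp$rows, 373L)
  expect_equal(fp$cols, 16L)
  oh <- footprintReport(375, 1, "onehot")
  expect_equal(oh$rows, 375L)
  expect_equal(oh$cols, 4L)
  expect_equal(footprintReport(375, 1, "2lk", 3, 3)$cols, 64L)
  expect_equal(footprintReport(101, 30000, "2lk", 3, 2)$totalValues,
               30000 * 99 * 16)
})
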