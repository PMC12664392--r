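# positional-scanning profiling: averaging, normalization, tolerance calls

mkMatrix <- function(wt, fill = NA_real_, nrep = 1) {
  L <- nchar(wt)
  v <- array(fill, c(L, 20, nrep),
             dimnames = list(as.character(seq_len(L)), AA_ALPHABET20,
                             paste0("r", seq_len(nrep))))
  v
}

test_that("replicate averaging is the cell-wise arithmetic mean", {
  v <- mkMatrix("SL", nrep = 2)
  wt <- c("S", "L")
  for (i in 1:2) v[i, wt[i], ] <- c(80, 100)
  v[1, "A", ] <- c(40, 60)
  m <- averageReplicates(ActivationMatrix("SL", v))
  expect_equal(nReplicates(m), 1)
  expect_equal(activationValues(m)[1, "A", 1], 50)
  expect_false(isNormalized(m))

  # single replicate: identity
  v1 <- mkMatrix("SL")
  for (i in 1:2) v1[i, wt[i], 1] <- 80
  v1[2, "C", 1] <- 33
  m1 <- ActivationMatrix("SL", v1)
  expect_equal(activationValues(averageReplicates(m1))[, , 1],
               activationValues(m1)[, , 1])
})

test_that("averaging a full random matrix equals the element-wise loop", {
  set.seed(41)
  m <- randomFullMatrix(nrep = 3)
  avg <- activationValues(averageReplicates(m))[, , 1]
  v <- activationValues(m)
  expected <- matrix(0, nrow(avg), ncol(avg), dimnames = dimnames(avg))
  for (i in seq_len(nrow(avg))) for (j in seq_len(ncol(avg)))
    expected[i, j] <- mean(v[i, j, ])
  expect_equal(avg, expected)
})

test_that("averaging rejects mismatched wild types and partially missing cells", {
  a <- randomFullMatrix("SLLMWITQV")
  b <- randomFullMatrix("SLLMWITQL")
  expect_error(averageReplicates(list(a, b)), "wild-type")

  v <- mkMatrix("SL", nrep = 2)
  for (i in 1:2) v[i, c("S", "L")[i], ] <- 80
  v[1, "C", 1] <- 40            # measured in replicate 1 only
  expect_error(averageReplicates(ActivationMatrix("SL", v)),
               "position 1, residue C")
})

test_that("normalization scales to the per-position wild-type cell", {
  v <- mkMatrix("SL")
  v[1, "S", 1] <- 80; v[1, "A", 1] <- 40
  v[2, "L", 1] <- 50; v[2, "A", 1] <- 75
  n <- normalizeToWildType(ActivationMatrix("SL", v))
  expect_true(isNormalized(n))
  expect_equal(activationValues(n)[1, "A", 1], 50)
  expect_equal(activationValues(n)[2, "A", 1], 150)   # above-WT values legal
  expect_identical(activationValues(n)[1, "S", 1], 100)
  expect_identical(activationValues(n)[2, "L", 1], 100)
})

test_that("normalizing twice is rejected and zero wild-type cells are errors", {
  m <- normalizeToWildType(averageReplicates(randomFullMatrix()))
  expect_error(normalizeToWildType(m), "already normalized")

  v <- mkMatrix("SL")
  v[1, "S", 1] <- 0; v[2, "L", 1] <- 50
  expect_error(normalizeToWildType(ActivationMatrix("SL", v)),
               "position\\(s\\) 1")
})

test_that("normalization of a random matrix matches an independent per-position loop", {
  set.seed(42)
  m <- averageReplicates(randomFullMatrix())
  n <- activationValues(normalizeToWildType(m))[, , 1]
  raw <- activationValues(m)[, , 1]
  wt <- strsplit(wildType(m), "")[[1]]
  for (i in seq_along(wt)) {
    expect_equal(unname(n[i, ]), unname(raw[i, ] * 100 / raw[i, wt[i]]))
    expect_identical(n[i, wt[i]], 100)
  }
})

test_that("tolerated sets use a strict threshold and always contain the wild type", {
  # degenerate: all non-WT cells zero -> singleton sets
  v <- mkMatrix("SLW", fill = 0)
  wt <- c("S", "L", "W")
  for (i in 1:3) v[i, wt[i], 1] <- 90
  prof <- toleranceProfile(normalizeToWildType(ActivationMatrix("SLW", v)))
  expect_identical(allowedResidues(prof), list("S", "L", "W"))

  # boundary: exactly 30 is NOT tolerated, just above is
  v <- mkMatrix("S", fill = 0)
  v[1, "S", 1] <- 100
  v[1, "A", 1] <- 30
  v[1, "C", 1] <- 30.0001
  prof <- toleranceProfile(normalizeToWildType(ActivationMatrix("S", v)))
  expect_identical(allowedResidues(prof)[[1]], c("C", "S"))
})

test_that("tolerated sets of a random matrix equal brute-force cell comparison", {
  set.seed(43)
  m <- normalizeToWildType(averageReplicates(randomFullMatrix()))
  prof <- toleranceProfile(m, threshold = 30)
  vals <- activationValues(m)[, , 1]
  for (i in seq_len(nrow(vals))) {
    expected <- sort(AA_ALPHABET20[vals[i, ] > 30])
    expect_identical(allowedResidues(prof)[[i]], expected)
  }
})

test_that("tolerance calls reject un-normalized, multi-replicate or gappy input", {
  raw <- randomFullMatrix()
  expect_error(toleranceProfile(raw), "normalized")
  norm2 <- normalizeToWildType(raw)   # per-replicate normalization, 2 layers
  expect_error(toleranceProfile(norm2), "average")
  v <- mkMatrix("SL")
  v[1, "S", 1] <- 80; v[2, "L", 1] <- 80   # only WT measured
  expect_error(toleranceProfile(normalizeToWildType(ActivationMatrix("SL", v))),
               "unmeasured")
})

test_that("thresholds are monotone: higher cutoff gives nested subsets", {
  set.seed(44)
  for (rep in 1:5) {
    m <- normalizeToWildType(averageReplicates(randomFullMatrix()))
    t1 <- sort(runif(1, 5, 40)); t2 <- t1 + runif(1, 1, 40)
    p1 <- allowedResidues(toleranceProfile(m, threshold = t1))
    p2 <- allowedResidues(toleranceProfile(m, threshold = t2))
    for (i in seq_along(p1)) expect_true(all(p2[[i]] %in% p1[[i]]))
  }
})

test_that("alanine sensitivity flags are a pure threshold function", {
  r <- alanineSensitivity(c("1" = 100, "3" = 0, "4" = 30, "5" = 30.5, "2+9" = 4))
  expect_identical(r@sensitive, c(FALSE, TRUE, TRUE, FALSE, TRUE))

  set.seed(45)
  vals <- setNames(runif(8, 0, 110), as.character(1:8))
  r <- alanineSensitivity(vals, threshold = 30)
  expect_identical(r@sensitive, unname(vals <= 30))
})

test_that("matrix-based alanine calls read the Ala column and need the joint anchor variant", {
  m <- normalizeToWildType(averageReplicates(randomFullMatrix("SLLMWITQV")))
  expect_error(alanineSensitivity(m), "jointValue")
  r <- alanineSensitivity(m, jointValue = 3)
  expect_identical(r@position, c("1", "3", "4", "5", "6", "7", "8", "2+9"))
  vals <- activationValues(m)[, "A", 1]
  expect_equal(r@value, unname(c(vals[c(1, 3:8)], 3)))
  expect_true(r@sensitive[r@position == "2+9"])

  # missing alanine cell is an error, not an imputed zero
  v <- mkMatrix("SLL")
  for (i in 1:3) v[i, c("S", "L", "L")[i], 1] <- 80
  v[1, "A", 1] <- 50              # positions 2-3 lack the Ala variant
  n <- normalizeToWildType(ActivationMatrix("SLL", v))
  expect_error(alanineSensitivity(n, jointAnchors = integer()), "position")
})

test_that("long-format TSV round-trips matrices including the wild-type header", {
  set.seed(46)
  m <- randomFullMatrix("SLLMW")
  tf <- tempfile(fileext = ".tsv")
  writeActivationMatrix(m, tf)
  back <- readActivationMatrix(tf)
  expect_identical(wildType(back), "SLLMW")
  expect_equal(activationValues(back), activationValues(m))
  expect_false(isNormalized(back))

  n <- normalizeToWildType(averageReplicates(m))
  writeActivationMatrix(n, tf)
  expect_true(isNormalized(readActivationMatrix(tf)))
})
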