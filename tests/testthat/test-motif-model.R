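test_that("frequency and probability matrices follow the pseudocount
           formula", {
  fm <- frequency_matrix(c("ACG", "ACG"))
  expect_equal(unname(fm$f["A", 1]), 2)
  expect_equal(unname(fm$f["C", 1]), 0)
  # p(A,1) = (2 + 1 * 0.25) / (2 + 1) = 0.75 with delta = 1, uniform q
  expect_equal(unname(fm$p["A", 1]), 0.75)
  expect_equal(colSums(fm$p), rep(1, 3), ignore_attr = TRUE)

  # single site: argmax of p per column is that site's base
  fm1 <- frequency_matrix("GATTACA")
  expect_equal(rownames(fm1$p)[apply(fm1$p, 2, which.max)],
               strsplit("GATTACA", "")[[1]])

  # all-A column converges to p = 1 as n grows
  pbig <- frequency_matrix(rep("A", 5000))$p["A", 1]
  expect_gt(pbig, 0.999)

  expect_error(frequency_matrix(c("ACG", "AC")), "length")
  expect_error(frequency_matrix(character()), "no sites")
})

test_that("the profile matrix is log2 odds against the background", {
  q <- uniform_background()
  p <- matrix(0.25, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(profile_matrix(p, q), matrix(0, 4, 3), ignore_attr = TRUE)
  p2 <- p
  p2["A", 1] <- 0.5
  expect_equal(unname(profile_matrix(p2, q)["A", 1]), 1.0)
  # near-certain base approaches 2 bits
  p3 <- matrix(c(1 - 3e-9, 1e-9, 1e-9, 1e-9), 4, 1)
  expect_equal(profile_matrix(p3, q)[1, 1], 2, tolerance = 1e-6)
})

test_that("information content is zero for background-like motifs, ~2
           bits per hard column, and additive", {
  expect_lt(abs(information_content(
    motif_from_seqs(c("AC", "CA", "GT", "TG")))), 0.35)
  expect_equal(information_content(motif_from_seqs("A"), delta = 1e-6),
               2, tolerance = 1e-4)
  # additivity over independent columns
  m1 <- motif_from_seqs(c("AA", "AC", "AG"))
  m2 <- motif_from_seqs(c("GT", "CT", "TT"))
  m12 <- motif_from_seqs(c("AAGT", "ACCT", "AGTT"))
  expect_equal(information_content(m12),
               information_content(m1) + information_content(m2),
               tolerance = 1e-9)
})

test_that("alignment scoring counts and normalises columns as
           specified", {
  q <- uniform_background()
  hardA <- frequency_matrix(rep(strrep("A", 4), 50))
  P <- profile_matrix(hardA$p, q)
  fhatA <- hardA$f / 50
  a0 <- alignment_score(P, fhatA, 0)
  expect_equal(a0$n_cols, 4L)
  expect_equal(a0$score, 1.0)  # self-match ceiling after normalisation
  hardC <- frequency_matrix(rep(strrep("C", 4), 50))
  aC <- alignment_score(P, hardC$f / 50, 0)
  expect_equal(aC$n_cols, 0L)
  expect_equal(aC$score, 0)
  a2 <- alignment_score(P, fhatA, 2)  # two-column overlap
  expect_equal(a2$n_cols, 2L)
  expect_equal(a2$score, 0.5)
  expect_error(alignment_score(P, fhatA, 4), "no overlapping")
})

test_that("motif similarity is 1 for zero-entropy self-matches, 0 for
           opposite hard motifs", {
  mA <- motif_from_seqs(rep(strrep("A", 16), 8), "A")
  mC <- motif_from_seqs(rep(strrep("C", 16), 8), "C")
  expect_equal(motif_similarity(mA, mA), 1.0)
  expect_equal(motif_similarity(mA, mC), 0)
  m <- motif_from_seqs(rep("ACGTACGTACGTACGT", 6))
  expect_equal(motif_similarity(m, m), 1.0)
})

test_that("motif similarity is symmetric and reverse-complement
           invariant", {
  set.seed(23)
  for (i in 1:40) {
    mx <- rand_motif()
    my <- rand_motif()
    s <- motif_similarity(mx, my)
    expect_equal(s, motif_similarity(my, mx), tolerance = 1e-12)
    my_rc <- motif_from_seqs(reverse_complement(my$sites$seq))
    expect_equal(s, motif_similarity(mx, my_rc), tolerance = 1e-12)
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("the best ungapped alignment matches exhaustive offset
           enumeration on small motifs", {
  # independent oracle: triple loop over offsets and columns
  naive_best <- function(P, fhat, tau = 0.5) {
    Lx <- ncol(P)
    Ly <- ncol(fhat)
    cmax <- apply(P, 2, max)
    denom <- sum(cmax)
    best <- c(n = 0, s = 0)
    for (o in (1 - Lx):(Ly - 1)) {
      ncols <- 0
      ssum <- 0
      for (i in 1:Lx) {
        j <- i + o
        if (j < 1 || j > Ly) next
        cc <- sum(P[, i] * fhat[, j])
        if (cc > tau * cmax[[i]]) {
          ncols <- ncols + 1
          ssum <- ssum + cc
        }
      }
      sc <- if (ncols == 0 || denom <= 0) 0 else ssum / denom
      if (ncols > best[["n"]] ||
          (ncols == best[["n"]] && sc > best[["s"]]))
        best <- c(n = ncols, s = sc)
    }
    best[["s"]]
  }
  set.seed(37)
  q <- uniform_background()
  for (i in 1:30) {
    wx <- sample(4:8, 1)
    wy <- sample(4:8, 1)
    mx <- rand_motif(n = 4, w = wx)
    my <- rand_motif(n = 4, w = wy)
    px <- frequency_matrix(mx)
    py <- frequency_matrix(my)
    Px <- profile_matrix(px$p, q)
    Py <- profile_matrix(py$p, q)
    fx <- px$f / px$n
    fy <- py$f / py$n
    s_oracle <- (naive_best(Px, fy) + naive_best(Py, fx)) / 2
    fyr <- fy[4:1, rev(seq_len(ncol(fy))), drop = FALSE]
    Pyr <- Py[4:1, rev(seq_len(ncol(Py))), drop = FALSE]
    s_oracle_rc <- (naive_best(Px, fyr) + naive_best(Pyr, fx)) / 2
    expect_equal(motif_similarity(mx, my),
                 min(1, max(0, s_oracle, s_oracle_rc)),
                 tolerance = 1e-12)
  }
})

test_that("padding both motifs with shared flanks preserves a strong
           core alignment", {
  set.seed(41)
  core <- rand_string(12)
  mx <- family_motif(core, n = 6, mut = 0.05)
  my <- family_motif(core, n = 6, mut = 0.05)
  s0 <- motif_similarity(mx, my)
  flank_l <- rand_string(3)
  flank_r <- rand_string(3)
  pad <- function(m) motif_from_seqs(paste0(flank_l, m$sites$seq, flank_r))
  s1 <- motif_similarity(pad(mx), pad(my))
  expect_gt(s0, 0.5)
  expect_gt(s1, 0.5)
})

test_that("random motif pairs score low while sub-motifs of one family
           score high", {
  set.seed(53)
  rand_pool <- replicate(30, rand_motif(), simplify = FALSE)
  rand_scores <- c()
  for (i in 1:29)
    rand_scores <- c(rand_scores,
                     motif_similarity(rand_pool[[i]], rand_pool[[i + 1]]))
  fam_pool <- replicate(10, family_motif(rand_string(16), n = 5,
                                         mut = 0.1),
                        simplify = FALSE)
  # sub-motif pairs: split one family's sites into halves
  fam_scores <- c()
  for (f in fam_pool) {
    a <- motif_from_seqs(f$sites$seq[1:2])
    b <- motif_from_seqs(f$sites$seq[3:5])
    fam_scores <- c(fam_scores, motif_similarity(a, b))
  }
  expect_lt(median(rand_scores), 0.2)
  expect_gt(median(fam_scores), 0.5)
  expect_lt(quantile(rand_scores, 0.9), min(0.5, median(fam_scores)))
})

test_that("the compiled all-pairs kernel agrees with the scalar
           implementation", {
  set.seed(61)
  pool <- c(replicate(8, rand_motif(), simplify = FALSE),
            replicate(4, family_motif(rand_string(16)), simplify = FALSE),
            list(rand_motif(w = 10), rand_motif(w = 22)))
  for (i in seq_along(pool)) pool[[i]]$id <- paste0("m", i)
  S <- similarity_matrix(pool)
  expect_true(isSymmetric(S))
  for (i in seq_along(pool))
    for (j in seq_along(pool))
      if (i < j)
        expect_equal(S[i, j],
                     motif_similarity(pool[[i]], pool[[j]]),
                     tolerance = 1e-12)
})

test_that("MEME minimal format round-trips letter probabilities", {
  set.seed(71)
  ms <- list(rand_motif(n = 6, w = 8, id = "alpha"),
             family_motif(rand_string(12), n = 9, id = "beta"))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(ms, f)
  back <- read_meme(f)
  expect_equal(length(back), 2L)
  expect_equal(vapply(back, `[[`, character(1), "id"), c("alpha", "beta"))
  for (k in 1:2) {
    # the file stores the pseudocounted probabilities; the read-back
    # counts matrix reproduces them after normalisation
    p0 <- frequency_matrix(ms[[k]])$p
    p1 <- back[[k]]$counts / sum(back[[k]]$counts[, 1])
    expect_equal(p0, p1, tolerance = 1e-4, ignore_attr = TRUE)
  }
})
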