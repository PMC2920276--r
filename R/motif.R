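## Motif representation and the motif-motif similarity metric.
##
## A motif is a set of equal-length, gap-free binding sites summarised by a
## count matrix F (4 x L, rows A,C,G,T), a pseudocounted column probability
## matrix p, and a log-odds profile matrix P = log2(p/q) against a
## background base composition q.  Similarity between two motifs is the
## symmetrised, orientation-maximised score of the best ungapped alignment
## of one motif's profile against the other's observed column frequencies.

DNA_BASES <- c("A", "C", "G", "T")

#' Background base composition
#'
#' @param p named (A,C,G,T) probability vector; defaults to uniform.
#' @return validated background vector.
#' @export
uniform_background <- function(p = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  p <- p[DNA_BASES]
  if (anyNA(p) || any(p <= 0) || abs(sum(p) - 1) > 1e-9)
    stop("background must be positive A,C,G,T probabilities summing to 1")
  p
}

#' Construct a motif from sites
#'
#' All sites must have the same width; sites whose sequence contains `N`
#' are discarded.  At least one usable site must remain.
#'
#' @param sites site data frame (see [new_site()]); the `seq` column holds
#'   the aligned site sequences.
#' @param id motif identifier.
#' @param origin optional provenance list, e.g.
#'   `list(coor_id =, finder =, rank =)` or a pipeline stage tag.
#' @return an object of class `pf_motif` with elements `id`, `sites`,
#'   `width`, `counts` (4 x L count matrix) and `origin`.
#' @export
new_motif <- function(sites, id = "motif", origin = list()) {
  keep <- !grepl("N", sites$seq, fixed = TRUE)
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) stop("motif ", id, " has no N-free sites")
  w <- unique(nchar(sites$seq))
  if (length(w) != 1L) stop("motif ", id, " sites differ in length")
  structure(list(id = id, sites = sites, width = w,
                 counts = site_count_matrix(sites$seq), origin = origin),
            class = "pf_motif")
}

#' @export
print.pf_motif <- function(x, ...) {
  cat(sprintf("<pf_motif %s: %d sites x %d bp, consensus %s>\n",
              x$id, nrow(x$sites), x$width, motif_consensus(x)))
  invisible(x)
}

#' Helper: motif directly from aligned strings (no genomic coordinates)
#'
#' Intended for tests, examples and imported (MEME-format) motifs; the
#' sites get placeholder coordinates.
#'
#' @param seqs character vector of equal-length site sequences.
#' @inheritParams new_motif
#' @export
motif_from_seqs <- function(seqs, id = "motif", origin = list()) {
  w <- nchar(seqs)
  sites <- data.frame(genome_id = NA_character_, start = 0L, end = w,
                      strand = "+", seq = toupper(seqs), source = "ad hoc",
                      stringsAsFactors = FALSE)
  new_motif(sites, id = id, origin = origin)
}

site_count_matrix <- function(seqs) {
  w <- nchar(seqs[[1L]])
  codes <- match(unlist(strsplit(seqs, "", fixed = TRUE)), DNA_BASES)
  pos <- rep(seq_len(w), length(seqs))
  matrix(tabulate((pos - 1L) * 4L + codes, nbins = 4L * w),
         nrow = 4L, ncol = w, dimnames = list(DNA_BASES, NULL))
}

motif_consensus <- function(motif) {
  paste0(DNA_BASES[apply(motif$counts, 2L, which.max)], collapse = "")
}

#' Column frequency and probability matrices of a motif
#'
#' `f` holds the raw per-column base counts; `p` adds a pseudocount mass
#' `delta` distributed by the background composition:
#' `p(b,i) = (f(b,i) + delta * q(b)) / (n + delta)`.
#'
#' @param x a `pf_motif`, or a character vector of equal-length site
#'   sequences.
#' @param background background base probabilities (see
#'   [uniform_background()]).
#' @param delta pseudocount mass (default 1).
#' @return list with `f` (counts), `p` (probabilities) and `n` (site
#'   count).
#' @export
frequency_matrix <- function(x, background = uniform_background(),
                             delta = 1.0) {
  if (inherits(x, "pf_motif")) {
    f <- x$counts
  } else {
    if (length(x) == 0L) stop("no sites")
    if (length(unique(nchar(x))) != 1L) stop("sites differ in length")
    f <- site_count_matrix(toupper(x))
  }
  n <- sum(f[, 1L])
  p <- (f + delta * background) / (n + delta)
  list(f = f, p = p, n = n)
}

#' Log-odds profile matrix
#'
#' `P(b,i) = log2(p(b,i) / q(b))`.
#'
#' @param p 4 x L column probability matrix (rows A,C,G,T).
#' @inheritParams frequency_matrix
#' @return 4 x L profile matrix.
#' @export
profile_matrix <- function(p, background = uniform_background()) {
  log2(p / background)
}

#' Information content of a motif (bits)
#'
#' `sum_i sum_b p(b,i) * log2(p(b,i)/q(b))` -- the Kullback-Leibler
#' divergence of the motif columns from the background, in bits.
#'
#' @inheritParams frequency_matrix
#' @export
information_content <- function(x, background = uniform_background(),
                                delta = 1.0) {
  fm <- frequency_matrix(x, background, delta)
  sum(fm$p * profile_matrix(fm$p, background))
}

## Reverse complement of a motif's matrices: reverse columns, swap
## complementary rows (A<->T, C<->G).
rc_matrix <- function(m) {
  m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
}

#' Score one ungapped alignment offset between two motifs
#'
#' Columns `i` of the profile `P_x` are placed against columns `i +
#' offset` of motif y's observed column proportions `fhat_y`.  The raw
#' per-column score is `c(i) = sum_b P_x(b,i) * fhat_y(b, i+offset)`; a
#' column counts as aligned when `c(i)` exceeds `tau` times the column's
#' maximum attainable score `m(i) = max_b P_x(b,i)`.  The aggregate score
#' is the aligned-column score sum normalised by `sum_i m(i)`, so a
#' full-length perfect match scores 1.
#'
#' @param P_x 4 x Lx profile matrix of motif x.
#' @param fhat_y 4 x Ly column proportion matrix of motif y (counts / n).
#' @param offset integer shift of y relative to x.
#' @param tau per-column alignment threshold in (0, 1).
#' @return list with `n_cols` (aligned column count) and `score`.
#' @export
alignment_score <- function(P_x, fhat_y, offset, tau = 0.5) {
  Lx <- ncol(P_x)
  Ly <- ncol(fhat_y)
  i0 <- max(1L, 1L - offset)
  i1 <- min(Lx, Ly - offset)
  if (i0 > i1) stop("offset ", offset, " yields no overlapping columns")
  cmax <- apply(P_x, 2L, max)
  denom <- sum(cmax)
  if (denom <= 0) return(list(n_cols = 0L, score = 0))
  idx <- i0:i1
  cc <- colSums(P_x[, idx, drop = FALSE] *
                  fhat_y[, idx + offset, drop = FALSE])
  aligned <- cc > tau * cmax[idx]
  n_cols <- sum(aligned)
  score <- if (n_cols == 0L) 0 else sum(cc[aligned]) / denom
  list(n_cols = as.integer(n_cols), score = score)
}

## One direction of the similarity metric: best ungapped alignment of
## P_x against fhat_y.  Among the offsets attaining the maximum number of
## aligned columns, the largest aggregate score is taken.
profile_frequency_score <- function(P_x, fhat_y, tau = 0.5) {
  Lx <- ncol(P_x)
  Ly <- ncol(fhat_y)
  best_n <- 0L
  best_s <- 0
  for (o in (1L - Lx):(Ly - 1L)) {
    a <- alignment_score(P_x, fhat_y, o, tau)
    if (a$n_cols > best_n || (a$n_cols == best_n && a$score > best_s)) {
      if (a$n_cols > 0L) {
        best_n <- a$n_cols
        best_s <- a$score
      }
    }
  }
  if (best_n == 0L) 0 else best_s
}

motif_pf <- function(motif, background, delta) {
  fm <- frequency_matrix(motif, background, delta)
  list(P = profile_matrix(fm$p, background), fhat = fm$f / fm$n)
}

#' Motif-motif similarity score
#'
#' Symmetrised best-ungapped-alignment score:
#' `S(Mx, My) = (s(Px, Fy) + s(Py, Fx)) / 2`, where `s` scores the
#' alignments with the maximum number of aligned columns (see
#' [alignment_score()]).  Both the forward and the reverse-complement
#' orientation of `My` are tried and the larger value kept; the result is
#' clipped to `[0, 1]`.
#'
#' @param mx,my `pf_motif` objects.
#' @param tau per-column alignment threshold; the default is calibrated so
#'   that unrelated random 16-mer motifs rarely exceed 0.2.
#' @inheritParams frequency_matrix
#' @return similarity score in `[0, 1]`.
#' @export
motif_similarity <- function(mx, my, tau = 0.5,
                             background = uniform_background(),
                             delta = 1.0) {
  x <- motif_pf(mx, background, delta)
  y <- motif_pf(my, background, delta)
  s_fwd <- (profile_frequency_score(x$P, y$fhat, tau) +
              profile_frequency_score(y$P, x$fhat, tau)) / 2
  s_rc <- (profile_frequency_score(x$P, rc_matrix(y$fhat), tau) +
             profile_frequency_score(rc_matrix(y$P), x$fhat, tau)) / 2
  min(max(max(s_fwd, s_rc), 0), 1)
}

#' All-pairs motif similarity matrix
#'
#' Computes [motif_similarity()] for every motif pair with a compiled
#' kernel; used to build motif similarity graphs.
#'
#' @param motifs list of `pf_motif` objects.
#' @inheritParams motif_similarity
#' @return symmetric numeric matrix with unit diagonal omitted (diagonal
#'   set to 1), dimnames = motif ids.
#' @export
similarity_matrix <- function(motifs, tau = 0.5,
                              background = uniform_background(),
                              delta = 1.0) {
  n <- length(motifs)
  ids <- vapply(motifs, `[[`, character(1), "id")
  if (n == 0L)
    return(matrix(numeric(), 0L, 0L))
  widths <- vapply(motifs, `[[`, integer(1), "width")
  P <- matrix(0, 4L, sum(widths))
  Fh <- matrix(0, 4L, sum(widths))
  off <- c(0L, cumsum(widths))
  for (i in seq_len(n)) {
    pf <- motif_pf(motifs[[i]], background, delta)
    cols <- (off[[i]] + 1L):off[[i + 1L]]
    P[, cols] <- pf$P
    Fh[, cols] <- pf$fhat
  }
  S <- sim_matrix_cpp(P, Fh, widths, off[seq_len(n)], tau)
  dimnames(S) <- list(ids, ids)
  S
}

## --- MEME minimal motif format --------------------------------------------

#' Write motifs in MEME minimal format
#'
#' @param motifs list of `pf_motif` objects.
#' @param path output path.
#' @inheritParams frequency_matrix
#' @export
write_meme <- function(motifs, path, background = uniform_background(),
                       delta = 1.0) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, background),
                     collapse = " "), ""), con)
  for (m in motifs) {
    fm <- frequency_matrix(m, background, delta)
    writeLines(sprintf("MOTIF %s", m$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      m$width, fm$n), con)
    for (i in seq_len(m$width))
      writeLines(paste(sprintf("%.6f", fm$p[, i]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' Letter-probability matrices are returned as `pf_motif` objects whose
#' `counts` matrix is the probability matrix scaled by `nsites` (site
#' lists are not part of the format).
#'
#' @param path path to a MEME minimal format file.
#' @return list of `pf_motif` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[[i]], "MOTIF")) {
      id <- strsplit(trimws(lines[[i]]), "\\s+")[[1L]][[2L]]
      j <- i + 1L
      while (j <= length(lines) &&
             !startsWith(lines[[j]], "letter-probability matrix"))
        j <- j + 1L
      hdr <- lines[[j]]
      w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
      nsites <- as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
      pm <- t(vapply(lines[(j + 1L):(j + w)], function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1L]]), numeric(4)))
      counts <- t(pm) * nsites
      rownames(counts) <- DNA_BASES
      m <- structure(list(id = id, sites = data.frame(), width = w,
                          counts = counts, origin = list(source = path)),
                     class = "pf_motif")
      out[[length(out) + 1L]] <- m
      i <- j + w + 1L
    } else i <- i + 1L
  }
  out
}
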