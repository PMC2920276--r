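## Built-in motif finder: a Gibbs site sampler with masked re-runs.  It is
## the default adapter for every ensemble slot and for all motif-refinement
## stages of the clustering cascade; external finders can be plugged in via
## the adapter contract in ensemble.R.

encode_dna <- function(seqs) {
  lapply(strsplit(toupper(seqs), "", fixed = TRUE), function(ch) {
    v <- match(ch, DNA_BASES) - 1L
    v[is.na(v)] <- -1L
    v
  })
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Find motifs with the built-in Gibbs site sampler
#'
#' One site per sequence per restart, both strands searched; the best
#' configuration of each run (by joint log-odds, then polished by argmax
#' passes) becomes a motif, its sites are masked, and the search repeats
#' for the next motif.  Results are ordered by information content,
#' descending, and are reproducible given `seed`.
#'
#' @param seqs character vector of input sequences (>= 3, each at least
#'   `width` long).
#' @param width motif width in bases.
#' @param n_results maximum number of motifs to return.
#' @param seed integer seed controlling all randomness of this call.
#' @param n_restarts,n_iter random restarts and Gibbs sweeps per restart.
#' @param background,delta background composition and pseudocount mass.
#' @return list of raw motifs; each has `sites` (data frame with
#'   `seq_index`, `offset` 0-based within the input sequence, `revcomp`,
#'   `seq`) and `score` (information content, bits).
#' @export
builtin_sampler_find <- function(seqs, width, n_results, seed,
                                 n_restarts = 2L, n_iter = 30L,
                                 background = uniform_background(),
                                 delta = 1.0) {
  if (length(seqs) < 3L) stop("need at least 3 sequences")
  if (any(nchar(seqs) < width))
    stop("all sequences must be at least width (", width, ") long")
  enc <- encode_dna(seqs)
  res <- with_local_seed(seed, gibbs_sampler_cpp(
    enc, as.integer(width), as.integer(n_results),
    as.integer(n_restarts), as.integer(n_iter),
    as.numeric(background), delta))
  out <- lapply(res, function(r) {
    site_seq <- vapply(seq_along(r$seq_index), function(a) {
      s <- substr(seqs[[r$seq_index[[a]]]], r$offset[[a]] + 1L,
                  r$offset[[a]] + width)
      if (r$revcomp[[a]]) reverse_complement(s) else s
    }, character(1))
    list(sites = data.frame(seq_index = r$seq_index, offset = r$offset,
                            revcomp = r$revcomp, seq = site_seq,
                            stringsAsFactors = FALSE),
         score = r$score, width = width)
  })
  out[order(-vapply(out, `[[`, numeric(1), "score"))]
}

## Best single motif over a set of candidate widths, for the stages that
## auto-detect motif length.  Widths are compared by total information
## content net of the expected random-alignment contribution per column
## (chi-square expectation 3 / (2 n ln 2) bits for 3 free parameters),
## scaled by the site count.
best_motif_auto_width <- function(seqs, widths, seed, ...) {
  widths <- widths[widths <= min(nchar(seqs))]
  if (length(widths) == 0L) return(NULL)
  best <- NULL
  best_score <- -Inf
  for (w in widths) {
    res <- builtin_sampler_find(seqs, w, 1L, seed = seed + w, ...)
    if (length(res) == 0L) next
    m <- res[[1L]]
    n <- nrow(m$sites)
    net <- n * (m$score - w * 3 / (2 * n * log(2)))
    if (net > best_score) {
      best_score <- net
      best <- m
    }
  }
  best
}
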