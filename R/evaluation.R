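## Evaluation statistics: recovery of known sites and motifs, unique-site
## counts, lower-bound specificity, cumulative per-rank curves, saturation
## and a hypergeometric enrichment utility.

#' Is a predicted site a recovery of a known site?
#'
#' True iff the sites are on the same genome and their intervals overlap
#' by at least `min_overlap` bases (strand-agnostic).
#'
#' @param predicted,known one-row site data frames (or anything with
#'   `genome_id`, `start`, `end`).
#' @param min_overlap minimum overlap in bases (default 9).
#' @export
site_recovered <- function(predicted, known, min_overlap = 9L) {
  predicted$genome_id == known$genome_id &&
    min(predicted$end, known$end) - max(predicted$start, known$start) >=
      min_overlap
}

## Vectorised: for each known site, is it recovered by any predicted site?
sites_recovered <- function(predicted, known, min_overlap = 9L) {
  if (nrow(known) == 0L) return(logical())
  out <- rep(FALSE, nrow(known))
  if (nrow(predicted) == 0L) return(out)
  pred_by_g <- split(predicted[c("start", "end")], predicted$genome_id)
  for (gid in unique(known$genome_id)) {
    p <- pred_by_g[[gid]]
    if (is.null(p)) next
    for (i in which(known$genome_id == gid))
      out[[i]] <- any(pmin(p$end, known$end[[i]]) -
                        pmax(p$start, known$start[[i]]) >= min_overlap)
  }
  out
}

#' Integer recovery percentage
#'
#' `round(100 * n_recovered / n_total)` with half-up rounding (so 79.5
#' prints as 80).
#'
#' @param n_recovered,n_total non-negative counts, `n_total > 0`.
#' @export
recovery_percent <- function(n_recovered, n_total) {
  stopifnot(n_total > 0, n_recovered >= 0, n_recovered <= n_total)
  as.integer(floor(100 * n_recovered / n_total + 0.5))
}

#' Is a known motif recovered by a cluster?
#'
#' True iff at least `frac` of the known motif's sites are recovered
#' ([site_recovered()]) by the cluster's sites.
#'
#' @param cluster_sites predicted site data frame of one cluster.
#' @param known_motif_sites site data frame of one known motif (>= 1
#'   rows).
#' @param frac minimum recovered fraction (default 0.2, inclusive).
#' @param min_overlap site-recovery overlap (default 9).
#' @export
motif_recovered <- function(cluster_sites, known_motif_sites, frac = 0.2,
                            min_overlap = 9L) {
  if (nrow(known_motif_sites) == 0L) stop("known motif has no sites")
  mean(sites_recovered(cluster_sites, known_motif_sites, min_overlap)) >=
    frac
}

#' Unique sites and their count
#'
#' Sites on the same genome overlapping by strictly more than
#' `overlap_threshold` bases are grouped transitively (strand-agnostic);
#' `unique_sites()` collapses each group to its union interval,
#' `unique_site_count()` returns the number of groups.
#'
#' @param sites site data frame.
#' @param overlap_threshold overlap in bases beyond which two sites are
#'   "the same" (default 8).
#' @export
unique_sites <- function(sites, overlap_threshold = 8L) {
  if (nrow(sites) == 0L)
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer()))
  out <- lapply(split(sites, sites$genome_id), function(p) {
    p <- p[order(p$start, p$end), , drop = FALSE]
    grp <- integer(nrow(p))
    grp[[1L]] <- 1L
    run_end <- p$end[[1L]]
    for (i in seq_len(nrow(p))[-1L]) {
      if (min(run_end, p$end[[i]]) - p$start[[i]] > overlap_threshold) {
        grp[[i]] <- grp[[i - 1L]]
        run_end <- max(run_end, p$end[[i]])
      } else {
        grp[[i]] <- grp[[i - 1L]] + 1L
        run_end <- p$end[[i]]
      }
    }
    data.frame(genome_id = p$genome_id[[1L]],
               start = as.integer(tapply(p$start, grp, min)),
               end = as.integer(tapply(p$end, grp, max)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @rdname unique_sites
#' @export
unique_site_count <- function(sites, overlap_threshold = 8L) {
  nrow(unique_sites(sites, overlap_threshold))
}

#' Lower bound of prediction specificity
#'
#' Predicted known sites divided by unique predicted sites, as an integer
#' percentage; a lower bound because unknown true sites count against it.
#'
#' @param n_known_recovered known sites recovered.
#' @param n_unique_predicted unique predicted sites.
#' @export
lower_bound_specificity <- function(n_known_recovered,
                                    n_unique_predicted) {
  recovery_percent(n_known_recovered, n_unique_predicted)
}

#' Cumulative per-rank recovery curves
#'
#' For every rank `r`, the known sites and known motifs recovered by the
#' union of the top-`r` clusters of a genome, and the number of unique
#' predicted sites in that union.
#'
#' @param ranked_clusters one genome's ranked cluster list (see
#'   [run_clustering_pipeline()]).
#' @param known_table known-site data frame with a `motif_name` column.
#' @param min_overlap site-recovery overlap (default 9).
#' @param motif_frac known-motif recovery fraction (default 0.2).
#' @param overlap_threshold uniqueness overlap (default 8).
#' @return data frame with columns `rank`, `n_known_sites`,
#'   `n_known_motifs`, `n_unique_sites`, all monotone non-decreasing.
#' @export
cumulative_curves <- function(ranked_clusters, known_table,
                              min_overlap = 9L, motif_frac = 0.2,
                              overlap_threshold = 8L) {
  R <- length(ranked_clusters)
  out <- data.frame(rank = seq_len(R), n_known_sites = 0L,
                    n_known_motifs = 0L, n_unique_sites = 0L)
  known_by_motif <- split(known_table, known_table$motif_name)
  site_rec <- rep(FALSE, nrow(known_table))
  motif_rec <- setNames(rep(FALSE, length(known_by_motif)),
                        names(known_by_motif))
  acc <- NULL
  for (r in seq_len(R)) {
    cs <- ranked_clusters[[r]]$sites
    acc <- if (is.null(acc)) cs else rbind(acc, cs)
    site_rec <- site_rec | sites_recovered(cs, known_table, min_overlap)
    for (mn in names(known_by_motif)) {
      if (!motif_rec[[mn]] &&
          motif_recovered(cs, known_by_motif[[mn]], motif_frac,
                          min_overlap))
        motif_rec[[mn]] <- TRUE
    }
    out$n_known_sites[[r]] <- sum(site_rec)
    out$n_known_motifs[[r]] <- sum(motif_rec)
    out$n_unique_sites[[r]] <- unique_site_count(acc, overlap_threshold)
  }
  out
}

#' Saturation rank of a cumulative curve
#'
#' The smallest rank at which the mean per-rank gain over the next
#' `window` ranks drops below `epsilon` times the current cumulative
#' value; the last rank if that never happens.
#'
#' @param curve numeric vector of cumulative values by rank.
#' @param window look-ahead window in ranks (default 20).
#' @param epsilon relative gain threshold (default 0.01).
#' @export
saturation_rank <- function(curve, window = 20L, epsilon = 0.01) {
  R <- length(curve)
  if (R == 0L) stop("empty curve")
  for (r in seq_len(R - 1L)) {
    upto <- min(R, r + window)
    gain <- (curve[[upto]] - curve[[r]]) / (upto - r)
    if (curve[[r]] > 0 && gain < epsilon * curve[[r]]) return(r)
  }
  R
}

#' Hypergeometric enrichment p-value
#'
#' Probability of drawing at least `q` known sites when `k` unique
#' predictions are sampled from a universe of `n_universe` candidate
#' sites of which `m` are known: `P[X >= q]`, upper-tail hypergeometric.
#'
#' @param q known sites among the predictions.
#' @param m known sites in the universe.
#' @param n_universe size of the candidate universe.
#' @param k number of predictions drawn.
#' @export
enrichment_pvalue <- function(q, m, n_universe, k) {
  stopifnot(q >= 0, m >= q, n_universe >= m, k >= q)
  stats::phyper(q - 1, m, n_universe - m, k, lower.tail = FALSE)
}

#' Funnel report: recovery of known sites/motifs at each pipeline step
#'
#' Counts the known sites (and motifs) that survive into each stage of
#' the pipeline: present in the extracted upstream sequence sets,
#' recovered by the input (footprinting) motifs, and recovered by the
#' final clusters.
#'
#' @param known_table known-site data frame with `motif_name`.
#' @param seq_sets sequence sets from [build_sequence_sets()].
#' @param input_motifs list of input `pf_motif`s.
#' @param result output of [run_clustering_pipeline()].
#' @param min_overlap site-recovery overlap (default 9).
#' @param motif_frac known-motif recovery fraction (default 0.2).
#' @return one-row data frame with the funnel counts and percentages.
#' @export
recovery_report <- function(known_table, seq_sets, input_motifs, result,
                            min_overlap = 9L, motif_frac = 0.2) {
  regions <- do.call(rbind, lapply(seq_sets, function(s)
    s$entries[c("genome_id", "start", "end")]))
  if (is.null(regions))
    regions <- data.frame(genome_id = character(), start = integer(),
                          end = integer())
  input_sites <- do.call(rbind, lapply(input_motifs, `[[`, "sites"))
  if (is.null(input_sites))
    input_sites <- data.frame(genome_id = character(), start = integer(),
                              end = integer())
  final_sites <- result$stages$final$sites
  if (is.null(final_sites))
    final_sites <- data.frame(genome_id = character(), start = integer(),
                              end = integer())
  known_by_motif <- split(known_table, known_table$motif_name)
  motif_level <- function(pred) {
    sum(vapply(known_by_motif, function(km)
      motif_recovered(pred, km, motif_frac, min_overlap), logical(1)))
  }
  extracted <- sites_recovered(regions, known_table, min_overlap)
  footprint <- sites_recovered(input_sites, known_table, min_overlap)
  final <- sites_recovered(final_sites, known_table, min_overlap)
  data.frame(
    known_sites = nrow(known_table),
    extracted_sites = sum(extracted),
    footprint_sites = sum(footprint & extracted),
    cluster_sites = sum(final & footprint & extracted),
    known_motifs = length(known_by_motif),
    extracted_motifs = motif_level(regions),
    footprint_motifs = motif_level(input_sites),
    cluster_motifs = motif_level(final_sites))
}
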