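## Result serialisation: ranked-report TSV, MEME motif file and a
## BED-like site table (0-based half-open) per run.

#' Write pipeline results to a directory
#'
#' Emits `report.tsv` (one row per ranked cluster), `motifs.meme` (the
#' best motif of every cluster, MEME minimal format) and `sites.tsv`
#' (all final predicted sites, 0-based half-open, BED-like with rank and
#' cluster annotations).
#'
#' @param result output of [run_clustering_pipeline()].
#' @param dir output directory (created if missing).
#' @param background background passed to [write_meme()].
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir,
                          background = uniform_background()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hash_tsv(ranked_report(result), file.path(dir, "report.tsv"))
  motifs <- list()
  rows <- list()
  for (gid in names(result$ranked)) {
    for (cl in result$ranked[[gid]]) {
      m <- cl$best_motif
      m$id <- cl$id
      motifs[[length(motifs) + 1L]] <- m
      s <- cl$sites
      if (nrow(s) > 0L)
        rows[[length(rows) + 1L]] <-
          data.frame(genome_id = s$genome_id, start = s$start,
                     end = s$end, strand = s$strand,
                     cluster_id = cl$id, rank = cl$rank,
                     stringsAsFactors = FALSE)
    }
  }
  write_meme(motifs, file.path(dir, "motifs.meme"), background)
  sites <- do.call(rbind, rows)
  if (is.null(sites))
    sites <- data.frame(genome_id = character(), start = integer(),
                        end = integer(), strand = character(),
                        cluster_id = character(), rank = integer())
  write_hash_tsv(sites, file.path(dir, "sites.tsv"))
  invisible(dir)
}
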