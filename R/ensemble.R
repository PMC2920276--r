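## Ensemble phylogenetic footprinting: every COOR sequence set is mined by
## a configurable list of motif-finder adapters, each contributing its
## top-k predictions ("input motifs").  External tools can be wrapped as
## adapters; the default configuration fills all five slots with the
## built-in Gibbs sampler under distinct seeds.

#' Build a motif-finder adapter
#'
#' The adapter contract: `find(seqs, width, n_results, seed)` returns an
#' ordered list of raw motifs (see [builtin_sampler_find()] for the
#' shape), each with at least 2 sites drawn from the input sequences,
#' deterministically given `seed`.
#'
#' @param name adapter name (used in motif provenance).
#' @param find the finder function.
#' @param capability `"fixed"` (honours the requested width) or
#'   `"auto-range"`.
#' @return adapter object.
#' @export
finder_adapter <- function(name, find, capability = c("fixed", "auto-range")) {
  capability <- match.arg(capability)
  stopifnot(is.function(find))
  structure(list(name = name, find = find, capability = capability),
            class = "pf_finder_adapter")
}

#' The built-in Gibbs sampler as a finder adapter
#'
#' @param name adapter name.
#' @param ... passed through to [builtin_sampler_find()]
#'   (`n_restarts`, `n_iter`, `background`, `delta`).
#' @export
builtin_adapter <- function(name = "gibbs", ...) {
  finder_adapter(name, function(seqs, width, n_results, seed)
    builtin_sampler_find(seqs, width, n_results, seed, ...),
    capability = "fixed")
}

#' Ensemble configuration
#'
#' The default mirrors the published slot sizes (15 + 10 + 5 + 5 + 5 = 40
#' motifs per sequence set, width 16), with the built-in sampler standing
#' in for each slot.
#'
#' @param slots list of `list(adapter =, k =)` entries; `sum(k)` is the
#'   number `T` of input motifs per sequence set.
#' @param width motif width forced on fixed-width adapters (default 16).
#' @param seed global seed; each (COOR, adapter) run derives a stable
#'   offset from it.
#' @return ensemble configuration object.
#' @export
ensemble_config <- function(slots = NULL, width = 16L, seed = 1L) {
  if (is.null(slots)) {
    ks <- c(15L, 10L, 5L, 5L, 5L)
    slots <- lapply(seq_along(ks), function(i)
      list(adapter = builtin_adapter(paste0("gibbs", i)), k = ks[[i]]))
  }
  for (s in slots)
    stopifnot(inherits(s$adapter, "pf_finder_adapter"), s$k >= 1L)
  structure(list(slots = slots, width = as.integer(width),
                 seed = as.integer(seed)),
            class = "pf_ensemble_config")
}

## Stable small-integer seed for a (COOR, adapter) pair.
stable_seed <- function(seed, ...) {
  key <- paste(..., sep = "\r")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147480009
  as.integer((seed + h) %% 2147480009)
}

#' Run the motif-finder ensemble on one COOR sequence set
#'
#' Each adapter contributes its ordered top-k motifs; every motif is
#' tagged with its provenance `(coor_id, finder, rank)` and its sites are
#' mapped back to genomic coordinates.  An adapter failure is logged as a
#' warning and its slots are skipped.
#'
#' @param seq_set a sequence set from [build_sequence_sets()]: a list with
#'   `coor_id` and `entries` (one upstream site per operon).
#' @param config an [ensemble_config()].
#' @return list of `pf_motif` objects (length at most `sum(k)`).
#' @export
run_ensemble <- function(seq_set, config = ensemble_config()) {
  entries <- seq_set$entries
  out <- list()
  for (slot in config$slots) {
    ad <- slot$adapter
    raw <- tryCatch(
      ad$find(entries$seq, config$width, slot$k,
              stable_seed(config$seed, seq_set$coor_id, ad$name)),
      error = function(e) {
        warning("adapter ", ad$name, " failed on ", seq_set$coor_id, ": ",
                conditionMessage(e))
        NULL
      })
    if (is.null(raw)) next
    for (r in seq_along(raw)) {
      rm_ <- raw[[r]]
      sites <- sites_from_windows(entries[rm_$sites$seq_index, ],
                                  rm_$sites$offset, rm_$width,
                                  rm_$sites$revcomp,
                                  source = paste(seq_set$coor_id, ad$name,
                                                 r, sep = "|"))
      id <- sprintf("%s|%s|%02d", seq_set$coor_id, ad$name, r)
      out[[length(out) + 1L]] <-
        new_motif(sites, id = id,
                  origin = list(coor_id = seq_set$coor_id,
                                finder = ad$name, rank = r))
    }
  }
  out
}

#' Collect input motifs across all sequence sets
#'
#' @param sets list of sequence sets (see [build_sequence_sets()]).
#' @param config an [ensemble_config()].
#' @return flat list of `pf_motif` objects with stable globally unique
#'   ids; with `n` sets and `T = sum(k)` motifs per set this is at most
#'   `n * T` motifs.
#' @export
collect_input_motifs <- function(sets, config = ensemble_config()) {
  out <- unlist(lapply(sets, run_ensemble, config = config),
                recursive = FALSE)
  if (is.null(out)) out <- list()
  ids <- vapply(out, `[[`, character(1), "id")
  stopifnot(!anyDuplicated(ids))
  out
}
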