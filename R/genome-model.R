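## Core genomic value types.  Coordinates are 0-based half-open throughout;
## sites on the minus strand store the reverse complement of the genome
## slice, so `seq` always reads 5'->3' on the site's own strand.

#' Construct a genome object
#'
#' @param id genome identifier.
#' @param seq DNA string over `A,C,G,T,N`.
#' @param topology `"linear"` or `"circular"`; circular topology permits
#'   upstream extraction to wrap the origin.
#' @return an object of class `pf_genome`.
#' @export
new_genome <- function(id, seq, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("genome ", id, " has empty sequence")
  if (grepl("[^ACGTN]", seq))
    stop("genome ", id, " contains characters outside A,C,G,T,N")
  structure(list(id = id, seq = seq, length = nchar(seq),
                 topology = topology),
            class = "pf_genome")
}

#' @export
print.pf_genome <- function(x, ...) {
  cat(sprintf("<pf_genome %s: %d bp, %s>\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Extract the sequence of a genomic interval
#'
#' Minus-strand slices are reverse-complemented so the result reads
#' 5'->3' on the requested strand.
#'
#' @param genome a `pf_genome`.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return DNA string.
#' @export
genome_slice <- function(genome, start, end, strand = "+") {
  stopifnot(start >= 0L, end <= genome$length, start < end)
  s <- substr(genome$seq, start + 1L, end)
  if (strand == "-") s <- reverse_complement(s)
  s
}

#' Build a site record
#'
#' @param genome_id genome identifier.
#' @param start,end 0-based half-open genomic interval.
#' @param strand `"+"` or `"-"`.
#' @param seq the site sequence (5'->3' on `strand`).
#' @param source free-text provenance tag.
#' @return one-row data frame.
#' @export
new_site <- function(genome_id, start, end, strand, seq, source = "") {
  data.frame(genome_id = genome_id, start = as.integer(start),
             end = as.integer(end), strand = strand, seq = seq,
             source = source, stringsAsFactors = FALSE)
}

#' Validate a site against its genome
#'
#' Checks coordinate bounds, `end - start == nchar(seq)`, and that `seq`
#' equals the (strand-aware) genome slice.
#'
#' @param site one-row site data frame.
#' @param genomes named list of `pf_genome` objects.
#' @return the site, invisibly; errors on mismatch.
#' @export
validate_site <- function(site, genomes) {
  g <- genomes[[site$genome_id]]
  if (is.null(g)) stop("unknown genome: ", site$genome_id)
  if (site$start < 0L || site$end > g$length || site$start >= site$end)
    stop("site coordinates out of range for genome ", site$genome_id)
  if (site$end - site$start != nchar(site$seq))
    stop("site length does not match its coordinates")
  sl <- genome_slice(g, site$start, site$end, site$strand)
  if (sl != toupper(site$seq))
    stop("site sequence does not match genome ", site$genome_id,
         " at [", site$start, ",", site$end, ")")
  invisible(site)
}

## Map windows found inside extracted (possibly minus-strand) parent
## sites back to genomic coordinates.  `offset` is 0-based within the
## parent's stored sequence; `revcomp` marks windows matched on the
## reverse strand of that stored sequence.  Vectorised: `parents` has one
## row per window.
sites_from_windows <- function(parents, offset, width, revcomp,
                               source = "") {
  gstart <- ifelse(parents$strand == "+", parents$start + offset,
                   parents$end - offset - width)
  strand <- ifelse(xor(parents$strand == "-", revcomp), "-", "+")
  s <- substr(parents$seq, offset + 1L, offset + width)
  if (any(revcomp)) s[revcomp] <- reverse_complement(s[revcomp])
  data.frame(genome_id = parents$genome_id, start = as.integer(gstart),
             end = as.integer(gstart + width), strand = strand, seq = s,
             source = source, stringsAsFactors = FALSE)
}

site_from_window <- function(parent, offset, width, revcomp = FALSE,
                             source = "") {
  sites_from_windows(parent, offset, width, revcomp, source)
}

## Re-extract site sequences after interval surgery (merging, extension).
refresh_site_seqs <- function(sites, genomes) {
  if (nrow(sites) == 0L) return(sites)
  seqs <- character(nrow(sites))
  for (gid in unique(sites$genome_id)) {
    idx <- sites$genome_id == gid
    seqs[idx] <- substring(genomes[[gid]]$seq,
                           sites$start[idx] + 1L, sites$end[idx])
  }
  neg <- sites$strand == "-"
  if (any(neg)) seqs[neg] <- reverse_complement(seqs[neg])
  sites$seq <- seqs
  sites
}
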