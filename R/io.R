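## File formats.
##
## All tabular inputs and outputs are TSV with a single header line that
## begins with "#".  File coordinates are 1-based inclusive (GFF/DOOR
## convention); everything internal is 0-based half-open.  The two helpers
## below are the only place the conversion happens.

#' Convert between file (1-based inclusive) and internal (0-based half-open)
#' coordinates
#'
#' @param start,end interval bounds in the source convention.
#' @return a list with `start` and `end` in the target convention.
#' @examples
#' from_file_coords(1, 4)  # -> [0, 4)
#' to_file_coords(0, 4)    # -> 1..4
#' @export
from_file_coords <- function(start, end) {
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

#' @rdname from_file_coords
#' @export
to_file_coords <- function(start, end) {
  list(start = as.integer(start) + 1L, end = as.integer(end))
}

## --- hash-header TSV -------------------------------------------------------

read_hash_tsv <- function(path, col_classes = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty table file: ", path)
  if (!startsWith(lines[[1L]], "#"))
    stop("expected a '#'-prefixed header line in ", path)
  header <- strsplit(sub("^#\\s*", "", lines[[1L]]), "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) {
    df <- as.data.frame(setNames(rep(list(character()), length(header)), header))
  } else {
    df <- read.table(text = lines[-1L], sep = "\t", header = FALSE,
                     quote = "", comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) != length(header))
      stop("column count does not match header in ", path)
    names(df) <- header
  }
  if (!is.null(col_classes)) {
    for (nm in names(col_classes)) {
      if (nm %in% names(df)) {
        df[[nm]] <- switch(col_classes[[nm]],
                           integer = as.integer(df[[nm]]),
                           numeric = as.numeric(df[[nm]]),
                           character = as.character(df[[nm]]))
      }
    }
  }
  df
}

write_hash_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## --- sequences -------------------------------------------------------------

#' Reverse complement of IUPAC DNA strings
#'
#' An involution over IUPAC DNA; `N` maps to `N`.  Vectorised.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character())
  revcomp_cpp(seq)
}

#' Read a genome from a FASTA file
#'
#' By default the file must contain exactly one record (one genome per
#' file); multi-record files are accepted only with `multi = TRUE`, in
#' which case a list of genomes is returned.  Sequences are uppercased and
#' any IUPAC ambiguity letter other than A/C/G/T is mapped to `N`.
#'
#' @param path path to a FASTA file.
#' @param multi allow multiple records and return a list of genomes.
#' @param topology `"linear"` (default) or `"circular"`.
#' @return a `pf_genome` (or a named list of them when `multi = TRUE`).
#' @export
read_genome_fasta <- function(path, multi = FALSE, topology = "linear") {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  if (length(ss) > 1L && !multi)
    stop("multiple FASTA records in ", path,
         "; one genome per file expected (use multi = TRUE to override)")
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  gs <- lapply(seq_along(ss), function(i) {
    s <- toupper(as.character(ss[[i]]))
    if (grepl("[^ACGTRYSWKMBDHVN]", s))
      stop("illegal sequence characters in record ", ids[[i]])
    s <- gsub("[RYSWKMBDHV]", "N", s)
    new_genome(ids[[i]], s, topology = topology)
  })
  names(gs) <- ids
  if (multi) gs else gs[[1L]]
}

#' Write genomes to FASTA
#'
#' @param genomes a `pf_genome` or list of them.
#' @param path output path.
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "pf_genome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, `[[`, character(1), "seq"))
  names(ss) <- vapply(genomes, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

## --- annotations -----------------------------------------------------------

#' Read a gene annotation table
#'
#' PTT-like TSV with columns `gene_id`, `genome_id`, `start`, `end`,
#' `strand`, `protein_id`; coordinates 1-based inclusive in the file.
#'
#' @param path path to the TSV.
#' @return data frame with internal 0-based half-open `start`/`end`.
#' @export
read_annotation_table <- function(path) {
  df <- read_hash_tsv(path, c(start = "integer", end = "integer"))
  need <- c("gene_id", "genome_id", "start", "end", "strand", "protein_id")
  if (!all(need %in% names(df))) stop("missing annotation columns in ", path)
  cc <- from_file_coords(df$start, df$end)
  df$start <- cc$start
  df$end <- cc$end
  validate_annotation(df)
  df
}

#' @rdname read_annotation_table
#' @param annotation internal annotation data frame.
#' @export
write_annotation_table <- function(annotation, path) {
  out <- annotation
  cc <- to_file_coords(out$start, out$end)
  out$start <- cc$start
  out$end <- cc$end
  write_hash_tsv(out, path)
}

#' Read gene annotations from a GFF3 file
#'
#' Extracts `gene`/`CDS` features into the internal annotation layout.
#' The protein id is taken from the `protein_id` attribute, falling back
#' to `ID`.
#'
#' @param path path to a GFF3 file.
#' @param genome_id genome the annotation belongs to (defaults to the
#'   seqnames in the file).
#' @param feature_types feature types to keep (default `"gene"` and
#'   `"CDS"`, deduplicated by gene id).
#' @return internal annotation data frame (0-based half-open
#'   coordinates).
#' @export
read_annotation_gff3 <- function(path, genome_id = NULL,
                                 feature_types = c("gene", "CDS")) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- as.data.frame(rtracklayer::import(path, format = "gff3"))
  gr <- gr[gr$type %in% feature_types, , drop = FALSE]
  if (nrow(gr) == 0L) stop("no ", paste(feature_types, collapse = "/"),
                           " features in ", path)
  id <- as.character(gr$ID)
  prot <- if (!is.null(gr$protein_id)) as.character(gr$protein_id)
          else rep(NA_character_, nrow(gr))
  prot[is.na(prot)] <- id[is.na(prot)]
  df <- data.frame(
    gene_id = id,
    genome_id = if (is.null(genome_id)) as.character(gr$seqnames)
                else genome_id,
    start = gr$start - 1L,   # GFF3 is 1-based inclusive
    end = gr$end,
    strand = as.character(gr$strand),
    protein_id = prot, stringsAsFactors = FALSE)
  df <- df[!duplicated(paste(df$genome_id, df$gene_id)), , drop = FALSE]
  rownames(df) <- NULL
  validate_annotation(df)
  df
}

validate_annotation <- function(df) {
  if (anyDuplicated(paste(df$genome_id, df$gene_id)))
    stop("duplicate gene ids within a genome")
  if (any(df$start < 0L) || any(df$end <= df$start))
    stop("invalid gene coordinates")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  invisible(df)
}

## --- operons ---------------------------------------------------------------

#' Read an operon table
#'
#' DOOR-like TSV with columns `operon_id`, `genome_id`, `gene_ids`
#' (comma-joined, in transcription order) and `strand`.  Coordinates are
#' resolved against the annotation: the operon span is the interval hull of
#' its member genes.
#'
#' @param path path to the TSV.
#' @param annotation internal annotation data frame (see
#'   [read_annotation_table()]).
#' @return data frame of operons with internal coordinates and a
#'   `gene_ids` list column.
#' @export
read_operon_table <- function(path, annotation) {
  df <- read_hash_tsv(path)
  need <- c("operon_id", "genome_id", "gene_ids", "strand")
  if (!all(need %in% names(df))) stop("missing operon columns in ", path)
  genes <- strsplit(df$gene_ids, ",", fixed = TRUE)
  make_operons(df$operon_id, df$genome_id, genes, df$strand, annotation)
}

#' Construct validated operons from gene-id lists
#'
#' @param operon_id,genome_id,strand character vectors (one per operon).
#' @param gene_ids list of character vectors of member gene ids.
#' @param annotation internal annotation data frame.
#' @return operon data frame (`operon_id`, `genome_id`, `gene_ids` list
#'   column, `strand`, `start`, `end`).
#' @export
make_operons <- function(operon_id, genome_id, gene_ids, strand, annotation) {
  key <- paste(annotation$genome_id, annotation$gene_id)
  n <- length(operon_id)
  start <- integer(n)
  end <- integer(n)
  for (i in seq_len(n)) {
    g <- gene_ids[[i]]
    if (length(g) < 1L) stop("operon ", operon_id[[i]], " has no genes")
    idx <- match(paste(genome_id[[i]], g), key)
    if (anyNA(idx))
      stop("operon ", operon_id[[i]], " refers to unknown gene(s): ",
           paste(g[is.na(idx)], collapse = ","))
    ann <- annotation[idx, ]
    if (length(unique(ann$strand)) != 1L || ann$strand[[1L]] != strand[[i]])
      stop("operon ", operon_id[[i]], " mixes strands")
    ord <- if (strand[[i]] == "+") order(ann$start) else order(-ann$start)
    if (!identical(ord, seq_along(g)))
      stop("operon ", operon_id[[i]],
           " gene order inconsistent with coordinates")
    start[[i]] <- min(ann$start)
    end[[i]] <- max(ann$end)
  }
  data.frame(operon_id = operon_id, genome_id = genome_id,
             gene_ids = I(gene_ids), strand = strand,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' @rdname read_operon_table
#' @param operons operon data frame.
#' @export
write_operon_table <- function(operons, path) {
  out <- data.frame(operon_id = operons$operon_id,
                    genome_id = operons$genome_id,
                    gene_ids = vapply(operons$gene_ids, paste,
                                      character(1), collapse = ","),
                    strand = operons$strand, stringsAsFactors = FALSE)
  write_hash_tsv(out, path)
}

## --- known sites -----------------------------------------------------------

#' Read a known-site table
#'
#' TSV with columns `motif_name`, `genome_id`, `start`, `end`, `strand`,
#' `seq` (1-based inclusive coordinates in the file).  Every site is
#' validated against its genome: `seq` must equal the genome slice
#' (reverse-complemented for minus-strand sites).
#'
#' @param path path to the TSV.
#' @param genomes named list of `pf_genome` objects.
#' @return data frame of validated sites (internal coordinates).
#' @export
read_known_sites <- function(path, genomes) {
  df <- read_hash_tsv(path, c(start = "integer", end = "integer"))
  need <- c("motif_name", "genome_id", "start", "end", "strand", "seq")
  if (!all(need %in% names(df))) stop("missing known-site columns in ", path)
  cc <- from_file_coords(df$start, df$end)
  df$start <- cc$start
  df$end <- cc$end
  if (any(!nzchar(df$motif_name))) stop("empty motif_name in ", path)
  for (i in seq_len(nrow(df)))
    validate_site(df[i, ], genomes)
  df
}

#' @rdname read_known_sites
#' @param sites internal site data frame.
#' @export
write_known_sites <- function(sites, path) {
  out <- sites[c("motif_name", "genome_id", "start", "end", "strand", "seq")]
  cc <- to_file_coords(out$start, out$end)
  out$start <- cc$start
  out$end <- cc$end
  write_hash_tsv(out, path)
}

## --- BLAST-like hit tables -------------------------------------------------

#' Read a protein-similarity hit table
#'
#' BLAST tabular (outfmt 6)-like TSV; only columns 1 (query), 2 (subject),
#' 11 (E-value) and 12 (bit score) are consumed.  A `#` header line is
#' permitted but not required.
#'
#' @param path path to the TSV.
#' @return data frame with `query`, `subject`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), bitscore = numeric()))
  df <- read.table(text = lines, sep = "\t", header = FALSE,
                   quote = "", comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected >= 12 tab-separated columns in ", path)
  out <- data.frame(query = as.character(df[[1L]]),
                    subject = as.character(df[[2L]]),
                    evalue = as.numeric(df[[11L]]),
                    bitscore = as.numeric(df[[12L]]),
                    stringsAsFactors = FALSE)
  if (any(out$evalue < 0)) stop("negative E-value in ", path)
  out
}

#' Read a TF-presence table
#'
#' TSV of `(genome_id, tf_family_id)` pairs.
#'
#' @param path path to the TSV.
#' @return data frame with `genome_id` and `tf_family_id`.
#' @export
read_tf_table <- function(path) {
  df <- read_hash_tsv(path)
  if (!all(c("genome_id", "tf_family_id") %in% names(df)))
    stop("missing TF-table columns in ", path)
  df
}
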