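## Synthetic genome-group simulator.
##
## Generates a complete toy input bundle -- genome sequences, annotations,
## operons, pairwise protein hit tables, a TF-presence table -- together
## with a planted-site truth table in the known-site format, so the whole
## pipeline and its evaluation run without any external data.  Each operon
## "template" is instantiated once per genome with the same gene families,
## making every template one COOR of the group by construction; a subset
## of templates carries a planted motif whose per-genome sites decay from
## the consensus at a configurable mutation rate, emulating the
## phylogenetic footprinting signal.

#' Configuration for the synthetic genome group
#'
#' @param n_genomes number of genomes in the group.
#' @param n_operons operon templates per genome (= COORs by
#'   construction).
#' @param genes_per_operon integer vector sampled from for the gene count
#'   of each template.
#' @param gene_length_range min/max gene length (bp).
#' @param intergenic_range min/max intergenic (upstream) length (bp);
#'   bounded by the 800 bp upstream-extraction window.
#' @param n_planted_motifs number of distinct planted motifs.
#' @param motif_width planted motif width (bp).
#' @param motif_fraction fraction of templates carrying each motif.
#' @param mutation_rate per-base probability that a planted site deviates
#'   from its consensus in a given genome.
#' @param minus_strand_frac fraction of templates on the minus strand.
#' @param gc background GC content.
#' @param n_tf_families TF families in the presence table.
#' @param seed mandatory integer seed.
#' @return fixture configuration object.
#' @export
fixture_config <- function(n_genomes = 5L, n_operons = 60L,
                           genes_per_operon = 1:3,
                           gene_length_range = c(200L, 400L),
                           intergenic_range = c(200L, 500L),
                           n_planted_motifs = 4L, motif_width = 16L,
                           motif_fraction = 0.2,
                           mutation_rate = 0.05,
                           minus_strand_frac = 0.2, gc = 0.5,
                           n_tf_families = 30L, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_genomes >= 2L, n_operons >= 1L,
            mutation_rate >= 0, mutation_rate < 1,
            max(intergenic_range) <= 800L,
            min(intergenic_range) >= motif_width + 20L)
  structure(list(n_genomes = as.integer(n_genomes),
                 n_operons = as.integer(n_operons),
                 genes_per_operon = as.integer(genes_per_operon),
                 gene_length_range = as.integer(gene_length_range),
                 intergenic_range = as.integer(intergenic_range),
                 n_planted_motifs = as.integer(n_planted_motifs),
                 motif_width = as.integer(motif_width),
                 motif_fraction = motif_fraction,
                 mutation_rate = mutation_rate,
                 minus_strand_frac = minus_strand_frac, gc = gc,
                 n_tf_families = as.integer(n_tf_families),
                 seed = as.integer(seed)),
            class = "pf_fixture_config")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

#' Sample a site from a position weight matrix
#'
#' Independent per-column draw; a hard (single-base-per-column) PWM always
#' yields its consensus.
#'
#' @param pwm 4 x w probability matrix (rows A,C,G,T).
#' @return DNA string of width `ncol(pwm)`.
#' @export
sample_pwm_site <- function(pwm) {
  paste0(vapply(seq_len(ncol(pwm)), function(i)
    sample(DNA_BASES, 1L, prob = pwm[, i]), character(1)), collapse = "")
}

mutate_site <- function(site, rate) {
  ch <- strsplit(site, "", fixed = TRUE)[[1L]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- vapply(ch[hit], function(b)
    sample(setdiff(DNA_BASES, b), 1L), character(1))
  paste0(ch, collapse = "")
}

#' Plant a site into a sequence by substitution
#'
#' @param seq host sequence.
#' @param site site string to plant.
#' @param position 0-based start of the substitution.
#' @param occupied optional list of previously planted `c(start, end)`
#'   intervals (0-based half-open); overlap is an error.
#' @return the modified sequence.
#' @export
plant_site <- function(seq, site, position, occupied = NULL) {
  w <- nchar(site)
  if (position < 0L || position + w > nchar(seq))
    stop("planted site does not fit the sequence")
  for (iv in occupied)
    if (min(iv[[2L]], position + w) - max(iv[[1L]], position) > 0L)
      stop("planted sites overlap")
  paste0(substr(seq, 1L, position), site,
         substr(seq, position + w + 1L, nchar(seq)))
}

#' Generate a synthetic genome group with planted motifs
#'
#' @param cfg a [fixture_config()].
#' @return a bundle: named `genomes` (`pf_genome`s), `annotation`,
#'   `operons`, `hit_tables` (named `"<a>|<b>"`), `tf_table`,
#'   `truth_sites` (known-site format with `motif_name =
#'   "planted_m<k>"`), `consensus` (planted consensus strings) and
#'   `config`.
#' @export
generate_group <- function(cfg) {
  with_local_seed(cfg$seed, generate_group_impl(cfg))
}

generate_group_impl <- function(cfg) {
  gw <- cfg$motif_width
  genome_ids <- sprintf("g%02d", seq_len(cfg$n_genomes))

  ## planted motifs: hard PWMs (2-bit columns) from random consensus
  consensus <- vapply(seq_len(cfg$n_planted_motifs), function(k)
    random_dna(gw, cfg$gc), character(1))

  ## assign motifs to disjoint template subsets
  per_motif <- round(cfg$motif_fraction * cfg$n_operons)
  if (cfg$n_planted_motifs * per_motif > cfg$n_operons)
    stop("not enough operon templates to place the planted motifs")
  shuffled <- sample(cfg$n_operons)
  carrier <- integer(cfg$n_operons)  # 0 = no motif
  for (k in seq_len(cfg$n_planted_motifs))
    carrier[shuffled[((k - 1L) * per_motif + 1L):(k * per_motif)]] <- k

  ## operon templates, shared across genomes
  templates <- lapply(seq_len(cfg$n_operons), function(t) {
    ng <- sample(cfg$genes_per_operon, 1L)
    list(n_genes = ng,
         strand = if (runif(1) < cfg$minus_strand_frac) "-" else "+",
         gene_len = sample(cfg$gene_length_range[[1L]]:
                             cfg$gene_length_range[[2L]], ng,
                           replace = TRUE))
  })

  ann <- list()
  ops <- list()
  genomes <- list()
  truth <- list()
  for (gi in seq_along(genome_ids)) {
    gid <- genome_ids[[gi]]
    pieces <- character()
    pos <- 0L
    for (t in seq_len(cfg$n_operons)) {
      tpl <- templates[[t]]
      igl <- sample(cfg$intergenic_range[[1L]]:cfg$intergenic_range[[2L]],
                    1L)
      ig <- random_dna(igl, cfg$gc)
      if (carrier[[t]] > 0L) {
        site <- mutate_site(consensus[[carrier[[t]]]], cfg$mutation_rate)
        sp <- sample(5L:(igl - gw - 5L), 1L)
        ig <- plant_site(ig, site, sp)
        ig_offset <- if (tpl$strand == "+") pos else
          pos + sum(tpl$gene_len)
        truth[[length(truth) + 1L]] <- data.frame(
          motif_name = sprintf("planted_m%d", carrier[[t]]),
          genome_id = gid, start = ig_offset + sp,
          end = ig_offset + sp + gw, strand = "+", seq = site,
          stringsAsFactors = FALSE)
      }
      gene_seqs <- vapply(tpl$gene_len, random_dna, character(1),
                          gc = cfg$gc)
      ## '+' layout: [IG][genes...]; '-' layout: [genes...][IG]
      block <- if (tpl$strand == "+") c(ig, gene_seqs)
               else c(gene_seqs, ig)
      gene_start <- pos + if (tpl$strand == "+") igl else 0L
      gene_ids <- sprintf("%s_t%02d_%d", gid, t, seq_len(tpl$n_genes))
      starts <- gene_start + cumsum(c(0L, head(tpl$gene_len, -1L)))
      ann[[length(ann) + 1L]] <- data.frame(
        gene_id = gene_ids, genome_id = gid, start = starts,
        end = starts + tpl$gene_len, strand = tpl$strand,
        protein_id = paste0("p_", gene_ids), stringsAsFactors = FALSE)
      ## transcription order: ascending coords for '+', descending for '-'
      tx_order <- if (tpl$strand == "+") gene_ids else rev(gene_ids)
      ops[[length(ops) + 1L]] <- data.frame(
        operon_id = sprintf("op_%s_t%02d", gid, t), genome_id = gid,
        gene_ids_str = paste(tx_order, collapse = ","),
        strand = tpl$strand, stringsAsFactors = FALSE)
      pieces <- c(pieces, block)
      pos <- pos + igl + sum(tpl$gene_len)
    }
    genomes[[gid]] <- new_genome(gid, paste0(pieces, collapse = ""))
  }
  annotation <- do.call(rbind, ann)
  op_df <- do.call(rbind, ops)
  operons <- make_operons(op_df$operon_id, op_df$genome_id,
                          strsplit(op_df$gene_ids_str, ",", fixed = TRUE),
                          op_df$strand, annotation)
  truth_sites <- do.call(rbind, truth)
  if (is.null(truth_sites))
    truth_sites <- data.frame(motif_name = character(),
                              genome_id = character(), start = integer(),
                              end = integer(), strand = character(),
                              seq = character())

  ## pairwise hit tables: family members are mutual best hits far below
  ## the BDBH cutoff; a couple of weak decoy hits exercise the cutoff
  hit_tables <- list()
  for (a in genome_ids)
    for (b in setdiff(genome_ids, a)) {
      rows <- list()
      for (t in seq_len(cfg$n_operons)) {
        for (k in seq_len(templates[[t]]$n_genes)) {
          rows[[length(rows) + 1L]] <- data.frame(
            query = sprintf("p_%s_t%02d_%d", a, t, k),
            subject = sprintf("p_%s_t%02d_%d", b, t, k),
            evalue = 1e-50, bitscore = 500, stringsAsFactors = FALSE)
        }
      }
      df <- do.call(rbind, rows)
      decoy <- data.frame(
        query = df$query[[1L]],
        subject = df$subject[[min(2L, nrow(df))]],
        evalue = 1e-3, bitscore = 30, stringsAsFactors = FALSE)
      hit_tables[[paste(a, b, sep = "|")]] <- rbind(df, decoy)
    }

  ## TF-presence table: a shared core plus variable accessory families
  fams <- sprintf("tf%02d", seq_len(cfg$n_tf_families))
  core <- fams[seq_len(min(20L, cfg$n_tf_families))]
  acc <- setdiff(fams, core)
  tf_rows <- list()
  for (gid in genome_ids) {
    present <- c(core, acc[runif(length(acc)) < 0.5])
    tf_rows[[gid]] <- data.frame(genome_id = gid, tf_family_id = present,
                                 stringsAsFactors = FALSE)
  }
  tf_table <- do.call(rbind, tf_rows)
  rownames(tf_table) <- NULL

  list(genomes = genomes, annotation = annotation, operons = operons,
       hit_tables = hit_tables, tf_table = tf_table,
       truth_sites = truth_sites, consensus = consensus, config = cfg)
}

#' Write a fixture bundle to files in the pipeline's input formats
#'
#' Emits per-genome FASTA, `annotation.tsv`, `operons.tsv`,
#' `tf_table.tsv`, per-pair `hits_<a>__<b>.tsv` (BLAST outfmt-6-like) and
#' `truth_sites.tsv` (known-site format, 1-based coordinates).
#'
#' @param bundle output of [generate_group()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_group_files <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in bundle$genomes)
    write_genome_fasta(g, file.path(dir, paste0("genome_", g$id, ".fa")))
  write_annotation_table(bundle$annotation,
                         file.path(dir, "annotation.tsv"))
  write_operon_table(bundle$operons, file.path(dir, "operons.tsv"))
  write_hash_tsv(bundle$tf_table, file.path(dir, "tf_table.tsv"))
  write_known_sites(bundle$truth_sites, file.path(dir, "truth_sites.tsv"))
  for (nm in names(bundle$hit_tables)) {
    h <- bundle$hit_tables[[nm]]
    out <- data.frame(h$query, h$subject, 100, 100, 0, 0, 1, 100, 1, 100,
                      h$evalue, h$bitscore)
    f <- file.path(dir, paste0("hits_", gsub("|", "__", nm, fixed = TRUE),
                               ".tsv"))
    write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(dir)
}

#' Read a fixture bundle back from a directory
#'
#' @param dir directory written by [write_group_files()].
#' @return a bundle in the same shape as [generate_group()] (without
#'   `consensus`/`config`).
#' @export
read_group_files <- function(dir) {
  fa <- list.files(dir, pattern = "^genome_.*\\.fa$", full.names = TRUE)
  genomes <- lapply(fa, read_genome_fasta)
  names(genomes) <- vapply(genomes, `[[`, character(1), "id")
  annotation <- read_annotation_table(file.path(dir, "annotation.tsv"))
  operons <- read_operon_table(file.path(dir, "operons.tsv"), annotation)
  tf_table <- read_tf_table(file.path(dir, "tf_table.tsv"))
  truth_path <- file.path(dir, "truth_sites.tsv")
  truth_sites <- if (file.exists(truth_path))
    read_known_sites(truth_path, genomes) else NULL
  hf <- list.files(dir, pattern = "^hits_.*\\.tsv$", full.names = TRUE)
  hit_tables <- lapply(hf, read_hit_table)
  names(hit_tables) <- gsub("__", "|",
                            sub("^hits_(.*)\\.tsv$", "\\1", basename(hf)),
                            fixed = TRUE)
  list(genomes = genomes, annotation = annotation, operons = operons,
       hit_tables = hit_tables, tf_table = tf_table,
       truth_sites = truth_sites)
}
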