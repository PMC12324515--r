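# Serialization of simulated datasets: FASTA (80-column wrap), GFF3
# (gene + CDS features, 1-based inclusive coordinates), a combined truth TSV
# of events, a Newick copy of the tree, and a JSON manifest. The GFF3
# writer/reader pair round-trips every gene-model field exactly.

#' Write a genome to FASTA
#' @param genome an [AnnotatedGenome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(contigSeqs(genome), filepath = path, width = 80L)
  invisible(path)
}

#' Write gene models to GFF3
#'
#' Emits one `gene` and one `CDS` feature per gene model. Internal 0-based
#' half-open coordinates are converted to the 1-based inclusive convention of
#' GFF3. Family, intactness and parent-gene lineage are carried in the
#' attribute column.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenomeGff3 <- function(genome, path) {
  g <- geneModels(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  sq <- contigSeqs(genome)
  for (i in seq_along(sq))
    writeLines(sprintf("##sequence-region %s 1 %d", names(sq)[i],
                       Biostrings::width(sq)[i]), con)
  if (nrow(g)) {
    g <- g[order(g$contig, g$start), , drop = FALSE]
    attrs <- sprintf("ID=%s;family=%s;intact=%s%s", g$gene_id, g$family,
                     ifelse(g$intact, "true", "false"),
                     ifelse(is.na(g$parent_id), "",
                            paste0(";parent_gene=", g$parent_id)))
    geneRows <- sprintf("%s\thyperlocus\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$contig, g$start + 1L, g$end, g$strand, attrs)
    cdsRows <- sprintf("%s\thyperlocus\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                       g$contig, g$start + 1L, g$end, g$strand,
                       g$gene_id, g$gene_id)
    writeLines(as.vector(rbind(geneRows, cdsRows)), con)
  }
  invisible(path)
}

.gffAttr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
}

#' Read a genome from FASTA + GFF3
#'
#' Counterpart of [writeGenomeFasta()]/[writeGenomeGff3()]: reconstructs the
#' [AnnotatedGenome-class] exactly, converting GFF3 coordinates back to the
#' package's 0-based half-open convention.
#'
#' @param fasta,gff3 file paths.
#' @param genomeId identifier to assign; defaults to the FASTA basename.
#' @return An [AnnotatedGenome-class].
#' @export
readAnnotatedGenome <- function(fasta, gff3,
                                genomeId = sub("\\.[^.]*$", "",
                                               basename(fasta))) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  lines <- readLines(gff3)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  genes <- if (length(lines)) {
    f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    sel <- f[, 3] == "gene"
    f <- f[sel, , drop = FALSE]
    pid <- .gffAttr(f[, 9], "parent_gene")
    data.frame(gene_id = .gffAttr(f[, 9], "ID"),
               family = .gffAttr(f[, 9], "family"),
               contig = f[, 1],
               start = as.numeric(f[, 4]) - 1,
               end = as.numeric(f[, 5]),
               strand = f[, 7],
               intact = .gffAttr(f[, 9], "intact") == "true",
               parent_id = pid,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(), family = character(),
               contig = character(), start = numeric(), end = numeric(),
               strand = character(), intact = logical(),
               parent_id = character(), stringsAsFactors = FALSE)
  }
  AnnotatedGenome(genomeId, seqs, genes)
}

#' Write a complete simulated dataset to disk
#'
#' Per tip: `<tip>.fasta` and `<tip>.gff3`. Additionally `root.fasta`,
#' `root.gff3`, a combined `truth.tsv` of all events (one row per event, with
#' a `tip` column), `tree.nwk`, and `manifest.json` echoing the seed and all
#' simulation parameters.
#'
#' @param sim a `hotspotSim` object from [evolveAlongTree()].
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
writeFixtures <- function(sim, dir) {
  stopifnot(inherits(sim, "hotspotSim"), length(sim$tips) > 0L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (nm in names(sim$tips)) {
    paths[[paste0(nm, ".fasta")]] <-
      writeGenomeFasta(sim$tips[[nm]], file.path(dir, paste0(nm, ".fasta")))
    paths[[paste0(nm, ".gff3")]] <-
      writeGenomeGff3(sim$tips[[nm]], file.path(dir, paste0(nm, ".gff3")))
  }
  writeGenomeFasta(sim$root, file.path(dir, "root.fasta"))
  writeGenomeGff3(sim$root, file.path(dir, "root.gff3"))
  truth <- do.call(rbind, lapply(names(sim$logs), function(nm) {
    lg <- sim$logs[[nm]]
    if (nrow(lg)) cbind(tip = nm, lg) else NULL
  }))
  if (is.null(truth)) truth <- cbind(tip = character(), .emptyLog())
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  paths$truth <- tp
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  paths$tree <- file.path(dir, "tree.nwk")
  p <- sim$params
  manifest <- list(seed = p@seed,
                   resamples = sim$resamples,
                   params = stats::setNames(
                     lapply(methods::slotNames(p), function(s)
                       methods::slot(p, s)),
                     methods::slotNames(p)))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  paths$manifest <- mp
  invisible(paths)
}

#' Read back a simulated dataset written by [writeFixtures()]
#'
#' @param dir the fixture directory.
#' @return A list with `tips` (named list of [AnnotatedGenome-class]), `root`,
#'   `logs` (named list of event logs), `tree`, and `manifest`.
#' @export
readFixtures <- function(dir) {
  fa <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  ids <- sub("\\.fasta$", "", basename(fa))
  genomes <- stats::setNames(lapply(seq_along(fa), function(i)
    readAnnotatedGenome(fa[i], file.path(dir, paste0(ids[i], ".gff3")),
                        genomeId = ids[i])), ids)
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             quote = "", comment.char = "",
                             colClasses = c(tip = "character",
                                            branch = "character",
                                            kind = "character",
                                            src_contig = "character",
                                            dst_contig = "character",
                                            gene_ids = "character",
                                            detail = "character"))
  logs <- split(truth[, setdiff(names(truth), "tip")], truth$tip)
  list(tips = genomes[setdiff(ids, "root")],
       root = genomes[["root"]],
       logs = logs,
       tree = ape::read.tree(file.path(dir, "tree.nwk")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}
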