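#' Order accession identifiers "lowest first"
#'
#' Accessions are compared by the numeric part after a fixed prefix split
#' (e.g. `NM_000200` before `NM_001008663` before `XM_000510` within the
#' same prefix); distinct prefixes, or accessions without a numeric part,
#' fall back to lexicographic order.
#'
#' @param acc Character vector of accession identifiers.
#' @return An ordering permutation (as from [order()]).
#' @export
accession_order <- function(acc) {
  prefix <- sub("([0-9]+)(\\.[0-9]+)?$", "", acc)
  digits <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)(\\.[0-9]+)?$",
                                            "\\1", acc)))
  digits[!grepl("[0-9]", acc)] <- Inf
  order(prefix, digits, acc)
}

gene_spans <- function(genes) {
  # one row per gene: span over its exons
  sp <- do.call(rbind, lapply(split(genes, genes$gene_name), function(g) {
    data.frame(gene_name = g$gene_name[1], accession = g$accession[1],
               species = g$species[1], chrom = g$chrom[1],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Overlap a probe alignment with gene models
#'
#' Finds all genes (on the probe's chromosome) whose span intersects the
#' probe interval, classifying each as an exon overlap when any exon
#' intersects and an intron overlap otherwise. Coordinates are 0-based
#' half-open; strand is ignored.
#'
#' @param probe One-row data.frame (`probe_id`, `chrom`, `start`, `end`).
#' @param genes Gene-model table, one row per exon (`gene_name`,
#'   `accession`, `species`, `chrom`, `start`, `end`).
#' @return Data frame of overlapping genes with an `overlap_kind` column
#'   (`"exon"` or `"intron"`); zero rows when nothing overlaps.
#' @export
probe_overlap <- function(probe, genes) {
  stopifnot(nrow(probe) == 1L, probe$start < probe$end,
            all(genes$start < genes$end))
  g <- genes[genes$chrom == probe$chrom, , drop = FALSE]
  if (nrow(g) == 0L) return(empty_overlap())
  pr <- IRanges::IRanges(start = probe$start + 1L, end = probe$end)
  spans <- gene_spans(g)
  gr <- IRanges::IRanges(start = spans$start + 1L, end = spans$end)
  hit <- IRanges::overlapsAny(gr, pr)
  if (!any(hit)) return(empty_overlap())
  spans <- spans[hit, , drop = FALSE]
  spans$overlap_kind <- vapply(spans$gene_name, function(nm) {
    ex <- g[g$gene_name == nm, , drop = FALSE]
    er <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    if (any(IRanges::overlapsAny(er, pr))) "exon" else "intron"
  }, "")
  rownames(spans) <- NULL
  spans
}

empty_overlap <- function() {
  data.frame(gene_name = character(0), accession = character(0),
             species = character(0), chrom = character(0),
             start = integer(0), end = integer(0),
             overlap_kind = character(0), stringsAsFactors = FALSE)
}

#' Nearest gene to a probe alignment
#'
#' Returns the gene on the probe's chromosome minimising the interval
#' distance to the probe (zero when overlapping); ties are broken by the
#' lowest accession number.
#'
#' @inheritParams probe_overlap
#' @return One-row data.frame of the nearest gene with its `distance`, or
#'   zero rows when the chromosome carries no gene.
#' @export
nearest_gene <- function(probe, genes) {
  g <- genes[genes$chrom == probe$chrom, , drop = FALSE]
  if (nrow(g) == 0L)
    return(cbind(empty_overlap()[0, 1:6], distance = integer(0)))
  spans <- gene_spans(g)
  pr <- IRanges::IRanges(start = probe$start + 1L, end = probe$end)
  gr <- IRanges::IRanges(start = spans$start + 1L, end = spans$end)
  d <- IRanges::distance(gr, pr)
  spans$distance <- as.integer(d)
  best <- spans[spans$distance == min(spans$distance), , drop = FALSE]
  best <- best[accession_order(best$accession)[1L], , drop = FALSE]
  rownames(best) <- NULL
  best[, c("gene_name", "accession", "species", "chrom", "start", "end",
           "distance")]
}

is_provisional <- function(name) grepl("^(LOC|MGC)", name)

#' Assign a gene name to one probe by the four-step rule
#'
#' Implements the deterministic assignment cascade:
#' \enumerate{
#'   \item a bovine exon overlap whose gene name is not provisional
#'     (LOC/MGC prefix) supplies the name; several candidates are resolved
#'     by the lowest accession number;
#'   \item when the bovine overlap is provisional, or there is no usable
#'     bovine overlap, an overlapping human gene name is used (lowest
#'     accession on ties);
#'   \item with no overlap at all, the nearest gene on the chromosome
#'     supplies the name;
#'   \item when a BLAST best hit exists and its name differs from the
#'     step 1/2 choice, the entry is flagged for manual curation -- the
#'     name is retained, never overridden.
#' }
#' Intron-only bovine overlaps do not satisfy step 1 (which requires an
#' exon) and fall through to the step 2/3 logic.
#'
#' @param probe One-row probe alignment.
#' @param bovine,human Gene-model tables for the two species (each may be
#'   empty).
#' @param blast Optional BLAST best-hit table (`probe_id`, `gene_name`,
#'   `bitscore`); at most one row per probe is used (highest bitscore).
#' @return One-row data.frame: `probe_id`, `gene_name` (NA when
#'   unassigned), `decision_step` (`"1"`, `"2"`, `"3"`, `"unassigned"`),
#'   `flagged`, `overlap_kind` (`"exon"`, `"intron"`, `"none"`).
#' @export
assign_gene <- function(probe, bovine, human, blast = NULL) {
  bov <- probe_overlap(probe, bovine)
  hum <- probe_overlap(probe, human)
  pick_lowest <- function(df) df[accession_order(df$accession)[1L], ]

  name <- NA_character_
  step <- "unassigned"
  kind <- "none"
  if (nrow(bov)) kind <- if (any(bov$overlap_kind == "exon")) "exon" else "intron"
  else if (nrow(hum)) kind <- if (any(hum$overlap_kind == "exon")) "exon" else "intron"

  bov_exon <- bov[bov$overlap_kind == "exon" & !is_provisional(bov$gene_name), ,
                  drop = FALSE]
  if (nrow(bov_exon)) {
    name <- pick_lowest(bov_exon)$gene_name
    step <- "1"
  } else if (nrow(hum)) {
    name <- pick_lowest(hum)$gene_name
    step <- "2"
  } else {
    all_genes <- rbind(bovine, human)
    near <- nearest_gene(probe, all_genes)
    if (nrow(near)) {
      name <- near$gene_name
      step <- "3"
    }
  }

  flagged <- FALSE
  if (!is.null(blast) && nrow(blast)) {
    bh <- blast[blast$probe_id == probe$probe_id, , drop = FALSE]
    if (nrow(bh)) {
      bh <- bh[order(-bh$bitscore), ][1L, ]
      if (step %in% c("1", "2") && !is.na(name) && bh$gene_name != name)
        flagged <- TRUE
    }
  }
  data.frame(probe_id = probe$probe_id, gene_name = name,
             decision_step = step, flagged = flagged, overlap_kind = kind,
             stringsAsFactors = FALSE)
}

#' Annotate a set of probes
#'
#' Applies [assign_gene()] to every probe alignment. Output order follows
#' the input; the result is independent of the row order of the gene and
#' BLAST tables.
#'
#' @param probes Probe-alignment table (`probe_id`, `chrom`, `start`,
#'   `end`).
#' @param genes Combined gene-model table with a `species` column
#'   (`"bovine"` / `"human"`), or a list with elements `bovine` and
#'   `human`.
#' @param blast Optional BLAST best-hit table.
#' @return Data frame of [assign_gene()] rows, one per probe.
#' @export
annotate_probes <- function(probes, genes, blast = NULL) {
  if (is.data.frame(genes)) {
    bovine <- genes[genes$species == "bovine", , drop = FALSE]
    human <- genes[genes$species == "human", , drop = FALSE]
  } else {
    bovine <- genes$bovine
    human <- genes$human
  }
  if (nrow(probes) == 0L)
    return(data.frame(probe_id = character(0), gene_name = character(0),
                      decision_step = character(0), flagged = logical(0),
                      overlap_kind = character(0), stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(probes)), function(i)
    assign_gene(probes[i, , drop = FALSE], bovine, human, blast))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally annotation results by name category
#'
#' @param results Output of [annotate_probes()].
#' @return Named integer vector with counts of `LOC`, `MGC`, `named` and
#'   `none` assignments; sums to the number of probes.
#' @export
summarise_annotation <- function(results) {
  nm <- results$gene_name
  c(LOC = sum(!is.na(nm) & grepl("^LOC", nm)),
    MGC = sum(!is.na(nm) & grepl("^MGC", nm)),
    named = sum(!is.na(nm) & !grepl("^(LOC|MGC)", nm)),
    none = sum(is.na(nm)))
}

#' Read and write the annotation module's table formats
#'
#' Plain-text interchange for the rule engine's inputs: probe alignments as
#' BED-like tab-separated text (`chrom`, `start`, `end`, `probe_id`,
#' optional `score`, `strand`; 0-based half-open), gene models as a
#' BED-like exon table (`chrom`, `start`, `end`, `gene_name`, `accession`,
#' `species`), and BLAST best hits in tabular form (`probe_id`,
#' `gene_name`, `bitscore`). Files written by [write_annotation_tables()]
#' round-trip through these readers.
#'
#' @param path File to read.
#' @return A data.frame in the layout [annotate_probes()] expects.
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
read_probe_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  names(d)[1:4] <- c("chrom", "start", "end", "probe_id")
  if (ncol(d) >= 6) names(d)[6] <- "strand" else d$strand <- "+"
  if (any(d$start >= d$end)) stop("malformed interval: start must be < end")
  d[, c("probe_id", "chrom", "start", "end", "strand")]
}

#' @rdname annotation_io
#' @export
read_gene_models <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "start", "end", "gene_name",
                                       "accession", "species"))
  if (any(d$start >= d$end)) stop("malformed interval: start must be < end")
  d[, c("gene_name", "accession", "species", "chrom", "start", "end")]
}

#' @rdname annotation_io
#' @export
read_blast_hits <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("probe_id", "gene_name", "bitscore"))
}

#' @rdname annotation_io
#' @param fixtures A list with `probes`, `genes`, `blast` as produced by
#'   [generate_annotation_fixtures()].
#' @param dir Directory the three files are written into.
#' @return (write) Invisibly, the paths written.
#' @export
write_annotation_tables <- function(fixtures, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(probes = file.path(dir, "probes.bed"),
             genes = file.path(dir, "gene_models.bed"),
             blast = file.path(dir, "blast_hits.tsv"))
  p <- fixtures$probes
  utils::write.table(data.frame(p$chrom, p$start, p$end, p$probe_id,
                                0L, p$strand),
                     paths["probes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  g <- fixtures$genes
  utils::write.table(data.frame(g$chrom, g$start, g$end, g$gene_name,
                                g$accession, g$species),
                     paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fixtures$blast, paths["blast"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
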