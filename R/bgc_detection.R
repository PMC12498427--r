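# BGC detection: gene-class annotation and fixed-width windowing.
#
# Proteins are annotated against per-gene-class profile HMMs (HMMER's
# hmmsearch, one profile per class, NAME = class id), or read from a
# precomputed annotation TSV so the pipeline runs without profile
# databases. Each annotated gene seeds a window extending 10 kb up- and
# downstream; overlapping windows on a contig are merged into one BGC
# region, and a region's binary gene-class presence vector feeds the
# monomer-selection models. Coordinates are 1-based inclusive; strand is
# recorded but ignored downstream.

# protein headers of the form ">id contig=c1;start=100;end=400;strand=+"
# carry genomic coordinates through a protein FASTA
parse_coord_header <- function(desc) {
  get1 <- function(k) {
    m <- regmatches(desc, regexpr(paste0(k, "=[^;[:space:]]+"), desc))
    if (length(m)) sub(paste0(k, "="), "", m) else NA_character_
  }
  list(contig = get1("contig"),
       start = suppressWarnings(as.integer(get1("start"))),
       end = suppressWarnings(as.integer(get1("end"))),
       strand = get1("strand"))
}

empty_hits <- function() {
  data.frame(protein_id = character(), gene_class_id = character(),
             evalue = numeric(), contig_id = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Read a precomputed annotation table
#'
#' The TSV bypass for live HMM search: columns `protein_id`,
#' `gene_class_id`, `evalue`, `contig_id`, `start`, `end`, `strand`.
#'
#' @param path TSV file.
#' @return a GeneHit data.frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          na.strings = character())
  need <- c("protein_id", "gene_class_id", "evalue", "contig_id",
            "start", "end", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation TSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$evalue <- as.numeric(df$evalue)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) stop("hit with start > end")
  if (any(df$evalue < 0)) stop("negative e-value")
  df[need]
}

# HMMER3 --tblout parser: whitespace-delimited, first 18 fixed fields
parse_hmmer_tbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(target = character(), query = character(),
                      evalue = numeric(), score = numeric()))
  tok <- strsplit(lines, "[[:space:]]+")
  data.frame(
    target = vapply(tok, `[`, "", 1),
    query = vapply(tok, `[`, "", 3),
    evalue = as.numeric(vapply(tok, `[`, "", 5)),
    score = as.numeric(vapply(tok, `[`, "", 6)),
    stringsAsFactors = FALSE
  )
}

#' Annotate proteins against gene-class profile HMMs
#'
#' Runs hmmsearch (HMMER 3) of every profile in `hmm_file` against the
#' protein set and returns hits passing the e-value cutoff. Under the
#' one-class-per-gene policy only the best-scoring class is kept per
#' protein. Genomic coordinates are taken from FASTA description fields of
#' the form `contig=...;start=...;end=...;strand=...` when present.
#'
#' @param proteins path to a protein FASTA file.
#' @param hmm_file path to a (possibly concatenated) HMMER3 profile file;
#'   profile NAME fields must be gene-class ids.
#' @param evalue_cutoff per-sequence e-value threshold (default 1e-5).
#' @param hmmsearch executable name/path (default "hmmsearch").
#' @return a GeneHit data.frame (protein_id, gene_class_id, evalue,
#'   contig_id, start, end, strand).
#' @export
annotate_proteins <- function(proteins, hmm_file, evalue_cutoff = 1e-5,
                              hmmsearch = "hmmsearch") {
  if (!file.exists(proteins)) stop("protein FASTA not found: ", proteins)
  if (!file.exists(hmm_file)) stop("profile file not found: ", hmm_file)
  seqs <- Biostrings::readAAStringSet(proteins)
  if (!length(seqs)) return(empty_hits())
  tbl <- tempfile(fileext = ".tbl")
  on.exit(unlink(tbl), add = TRUE)
  status <- system2(hmmsearch,
                    c("--tblout", shQuote(tbl), "-E", format(evalue_cutoff),
                      "--noali", shQuote(hmm_file), shQuote(proteins)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("hmmsearch failed with status ", status)
  hits <- parse_hmmer_tbl(tbl)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (!nrow(hits)) return(empty_hits())
  # one class per gene: best score wins
  hits <- hits[order(hits$target, -hits$score), , drop = FALSE]
  hits <- hits[!duplicated(hits$target), , drop = FALSE]
  desc <- names(seqs)
  ids <- vapply(strsplit(desc, "[[:space:]]+"), `[`, "", 1)
  coords <- lapply(desc, parse_coord_header)
  i <- match(hits$target, ids)
  data.frame(
    protein_id = hits$target,
    gene_class_id = hits$query,
    evalue = hits$evalue,
    contig_id = vapply(coords[i], function(x) x$contig, ""),
    start = vapply(coords[i], function(x) x$start, 1L),
    end = vapply(coords[i], function(x) x$end, 1L),
    strand = vapply(coords[i], function(x) x$strand, ""),
    stringsAsFactors = FALSE
  )
}

#' Delimit BGC regions by fixed-width windowing
#'
#' Extends every hit by `window` bp on both sides, clips to the contig,
#' and merges overlapping extensions per contig into disjoint regions.
#'
#' @param hits GeneHit data.frame.
#' @param contig_lengths named integer vector of contig lengths.
#' @param window extension in bp (default 10000).
#' @return list with `regions` (region_id, contig_id, start, end, n_hits)
#'   and `hits` (the input plus a region_id column).
#' @export
window_regions <- function(hits, contig_lengths, window = 10000) {
  if (!nrow(hits))
    return(list(regions = data.frame(region_id = character(),
                                     contig_id = character(),
                                     start = integer(), end = integer(),
                                     n_hits = integer()),
                hits = cbind(hits, region_id = character(0))))
  if (any(!hits$contig_id %in% names(contig_lengths)))
    stop("hit on unknown contig")
  len <- contig_lengths[hits$contig_id]
  if (any(hits$start < 1 | hits$end > len))
    stop("hit outside contig bounds")
  regions <- NULL
  hits$region_id <- NA_character_
  for (ctg in sort(unique(hits$contig_id))) {
    sel <- which(hits$contig_id == ctg)
    ext <- IRanges::IRanges(
      start = pmax(1L, hits$start[sel] - as.integer(window)),
      end = pmin(as.integer(contig_lengths[[ctg]]),
                 hits$end[sel] + as.integer(window)))
    merged <- IRanges::reduce(ext)
    ov <- IRanges::findOverlaps(ext, merged)
    ids <- sprintf("%s:%d-%d", ctg, IRanges::start(merged),
                   IRanges::end(merged))
    hits$region_id[sel] <- ids[S4Vectors::subjectHits(ov)]
    regions <- rbind(regions, data.frame(
      region_id = ids, contig_id = ctg,
      start = IRanges::start(merged), end = IRanges::end(merged),
      n_hits = as.integer(table(factor(S4Vectors::subjectHits(ov),
                                       levels = seq_along(merged)))),
      stringsAsFactors = FALSE))
  }
  rownames(regions) <- NULL
  list(regions = regions, hits = hits)
}

#' Binary gene-class presence vector of a BGC region
#'
#' @param region_hits GeneHit data.frame restricted to one region.
#' @param kb a `glyco_kb`.
#' @return named binary integer vector of length G (one entry per gene
#'   class), 1 where the class has at least one hit.
#' @export
presence_vector <- function(region_hits, kb) {
  classes <- kb$gene_classes$id
  unknown <- setdiff(region_hits$gene_class_id, classes)
  if (length(unknown)) stop("unknown gene-class id(s): ",
                            paste(unique(unknown), collapse = ", "))
  setNames(as.integer(classes %in% region_hits$gene_class_id), classes)
}
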