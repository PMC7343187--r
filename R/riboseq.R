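#' Read aligned ribosome footprints from a SAM/BAM file
#'
#' Imports primary alignments as a `GRanges` whose ranges are the reference
#' span of each alignment (CIGAR-aware, so soft-clipped bases are excluded).
#' Plain-text SAM files are converted on the fly; a malformed file is a
#' parse error.
#'
#' @param path path to a SAM or BAM file.
#' @return a `GRanges` with strand set from the alignment flag.
#' @export
read_footprints <- function(path) {
  stopifnot(file.exists(path))
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  gal <- GenomicAlignments::readGAlignments(bam)
  GenomicRanges::granges(gal)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene features (GFF3 1-based inclusive coordinates, kept as such in
#' the returned `GRanges`) with a `gene_id` column taken from the `ID`
#' attribute.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature types to keep (default `"gene"`).
#' @return a `GRanges` with metadata column `gene_id`.
#' @export
read_gene_models <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) %in% feature_type]
  if (is.null(gr$ID) || anyNA(gr$ID)) {
    stop("gene features must carry an ID attribute", call. = FALSE)
  }
  gr$gene_id <- gr$ID
  gr
}

#' Filter footprints by alignment length
#'
#' Keeps alignments whose reference span lies between `min_len` and `max_len`
#' nucleotides, bounds inclusive (defaults 23 and 41, the footprint window
#' used for centre-weighted counting).
#'
#' @param reads a `GRanges` of alignments.
#' @param min_len,max_len inclusive span bounds in nt.
#' @return the kept `GRanges`, with attribute `n_rejected`.
#' @export
filter_reads <- function(reads, min_len = 23, max_len = 41) {
  w <- GenomicRanges::width(reads)
  keep <- w >= min_len & w <= max_len
  out <- reads[keep]
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Strand-specific centre-weighted coverage
#'
#' Counts, at each nucleotide position, the footprints whose trimmed central
#' window covers it: a read spanning `l` nt contributes +1 to the `l - 22`
#' positions remaining after trimming `trim = 11` positions from either end
#' of the alignment. Coverage is accumulated separately for the forward and
#' reverse strands. Trimmed windows extending past the reference end are
#' clipped with a warning.
#'
#' @param reads a length-filtered `GRanges` (all spans > `2 * trim`).
#' @param reference_lengths named integer vector of reference lengths (nt);
#'   defaults to the `seqlengths` of `reads`.
#' @param trim positions trimmed from each alignment end (default 11).
#' @return an object of class `coverage_track`: list with `plus` and `minus`
#'   (`RleList` per reference) and `total_counted` (sum over both strands).
#' @export
center_weighted_coverage <- function(reads, reference_lengths = NULL,
                                     trim = 11) {
  if (is.null(reference_lengths)) {
    reference_lengths <- GenomeInfoDb::seqlengths(reads)
  }
  if (anyNA(reference_lengths)) {
    stop("reference lengths are required (set seqlengths or pass them)",
         call. = FALSE)
  }
  if (any(GenomicRanges::width(reads) <= 2 * trim)) {
    stop("reads shorter than 2*trim+1 present; run filter_reads() first",
         call. = FALSE)
  }
  # out-of-bound windows are detected and clipped explicitly below, so the
  # container's own out-of-bound notices are silenced here
  trimmed <- suppressWarnings(
    GenomicRanges::narrow(reads, start = trim + 1, end = -(trim + 1)))
  suppressWarnings(
    GenomeInfoDb::seqlengths(trimmed) <-
      reference_lengths[GenomeInfoDb::seqlevels(trimmed)])
  oob <- sum(GenomicRanges::end(trimmed) >
               reference_lengths[as.character(GenomicRanges::seqnames(trimmed))])
  if (oob > 0) {
    warning(oob, " trimmed window(s) extended past the reference end; clipped")
    trimmed <- GenomicRanges::trim(trimmed)
  }
  strands <- as.character(GenomicRanges::strand(trimmed))
  plus <- GenomicRanges::coverage(trimmed[strands != "-"])
  minus <- GenomicRanges::coverage(trimmed[strands == "-"])
  structure(list(plus = plus, minus = minus,
                 total_counted = sum(as.numeric(sum(plus))) +
                   sum(as.numeric(sum(minus)))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track>", length(x$plus), "reference(s),",
      format(x$total_counted, big.mark = ","), "counted positions\n")
  invisible(x)
}

#' Per-gene RPKM from centre-weighted coverage
#'
#' Sums the coverage on each gene's own strand within its interval and scales
#' by gene length (kb) and by the genome-wide total of counted positions over
#' both strands (millions): `RPKM = count / (length_kb * total_millions)`.
#'
#' @param track a [center_weighted_coverage()] track.
#' @param genes a `GRanges` of gene models with `gene_id` (see
#'   [read_gene_models()]).
#' @return a tibble: `gene_id`, `reference`, `strand`, `length_nt`, `count`,
#'   `rpkm`.
#' @export
rpkm_table <- function(track, genes) {
  stopifnot(inherits(track, "coverage_track"))
  refs <- as.character(GenomicRanges::seqnames(genes))
  unknown <- setdiff(refs, names(track$plus))
  if (length(unknown) > 0) {
    bad <- genes$gene_id[refs %in% unknown]
    stop("gene(s) on reference(s) absent from the coverage track: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  total_millions <- track$total_counted / 1e6
  n <- length(genes)
  counts <- numeric(n)
  for (i in seq_len(n)) {
    rle_set <- if (as.character(GenomicRanges::strand(genes)[i]) == "-")
      track$minus else track$plus
    r <- rle_set[[refs[i]]]
    from <- GenomicRanges::start(genes)[i]
    to <- min(GenomicRanges::end(genes)[i], length(r))
    counts[i] <- if (from <= to)
      sum(as.numeric(S4Vectors::runValue(IRanges::Views(r, from, to)[[1]]) *
                       S4Vectors::runLength(IRanges::Views(r, from, to)[[1]])))
    else 0
  }
  len_nt <- GenomicRanges::width(genes)
  rpkm <- if (total_millions > 0) {
    counts / ((len_nt / 1000) * total_millions)
  } else {
    rep(0, n)
  }
  tibble::tibble(gene_id = genes$gene_id, reference = refs,
                 strand = as.character(GenomicRanges::strand(genes)),
                 length_nt = len_nt, count = counts, rpkm = rpkm)
}

#' Log2 expression ratio with pseudocount
#'
#' `log2((a + pseudocount) / (b + pseudocount))`; the pseudocount (default
#' 0.5 RPKM on both sides) keeps ratios finite for silent genes.
#'
#' @param a,b RPKM vectors.
#' @param pseudocount added to both sides before the ratio.
#' @return numeric log2 ratios.
#' @export
log2_ratio <- function(a, b, pseudocount = 0.5) {
  log2((a + pseudocount) / (b + pseudocount))
}

#' Classify genes into translatome regulon classes
#'
#' Given two per-gene log2 contrasts - A (mutant vs wild type, e.g. rimBK
#' deletion) and B (glutamation allele vs the mutant) - and the significance
#' threshold `tau` (default 1.0 log2), with `sig(x) = |x| > tau`:
#'
#' * `class1`: sig(A) and not sig(B) - affected by the deletion only;
#' * `class2`: sig(A) and sig(B), same sign - concordant;
#' * `class3`: sig(A) and sig(B), opposite sign - inversely affected, the
#'   direct glutamation-regulon candidates;
#' * `glutamation_only`: sig(B) and not sig(A);
#' * `unaffected`: otherwise.
#'
#' Genes with a missing contrast are labelled `unclassifiable`.
#'
#' @param table data frame with columns `gene_id`, `log2_a`, `log2_b`.
#' @param tau significance threshold in log2 units; must be > 0.
#' @return the input tibble with a `class` column added.
#' @export
classify_regulon <- function(table, tau = 1.0) {
  stopifnot(all(c("gene_id", "log2_a", "log2_b") %in% names(table)),
            tau > 0)
  a <- table$log2_a
  b <- table$log2_b
  sig_a <- abs(a) > tau
  sig_b <- abs(b) > tau
  cls <- dplyr::case_when(
    is.na(a) | is.na(b) ~ "unclassifiable",
    sig_a & !sig_b ~ "class1",
    sig_a & sig_b & sign(a) == sign(b) ~ "class2",
    sig_a & sig_b ~ "class3",
    !sig_a & sig_b ~ "glutamation_only",
    TRUE ~ "unaffected"
  )
  out <- tibble::as_tibble(table)
  out$class <- cls
  out
}

#' Filter differential protein-abundance records
#'
#' Applies the quantitative-proteomics significance filter: a protein is
#' flagged iff it was quantified with at least `min_peptides` unique peptides,
#' the condition ratio differs by at least `min_delta_log2` (default 1, i.e.
#' 2-fold) between wild type and mutant, and at least one of the two adjusted
#' p-values is at most `max_p`. Direction is the sign of
#' `log2_mut - log2_wt`. Records missing a p-value are excluded with a
#' warning.
#'
#' @param records data frame with columns `protein_id`, `peptides`,
#'   `log2_wt`, `log2_mut`, `p_wt`, `p_mut` (p-values arrive pre-adjusted and
#'   are consumed as-is).
#' @param min_peptides,min_delta_log2,max_p filter thresholds.
#' @return the flagged subset as a tibble with a `direction` column
#'   (`"up"`/`"down"` in the mutant).
#' @export
differential_protein_filter <- function(records, min_peptides = 2,
                                        min_delta_log2 = 1, max_p = 0.05) {
  need <- c("protein_id", "peptides", "log2_wt", "log2_mut", "p_wt", "p_mut")
  stopifnot(all(need %in% names(records)))
  records <- tibble::as_tibble(records)
  bad_p <- is.na(records$p_wt) & is.na(records$p_mut)
  if (any(bad_p)) {
    warning(sum(bad_p), " record(s) without any p-value excluded")
    records <- records[!bad_p, ]
  }
  delta <- records$log2_mut - records$log2_wt
  min_p <- pmin(records$p_wt, records$p_mut, na.rm = TRUE)
  flagged <- records$peptides >= min_peptides &
    abs(delta) >= min_delta_log2 & min_p <= max_p
  out <- records[flagged, ]
  out$direction <- ifelse(delta[flagged] > 0, "up", "down")
  out
}

#' Export a coverage track as strand-specific bedGraph files
#'
#' @param track a [center_weighted_coverage()] track.
#' @param prefix output path prefix; writes `<prefix>_plus.bedGraph` and
#'   `<prefix>_minus.bedGraph`.
#' @return invisibly, the two file paths.
#' @export
export_bedgraph <- function(track, prefix) {
  stopifnot(inherits(track, "coverage_track"))
  paths <- c(plus = paste0(prefix, "_plus.bedGraph"),
             minus = paste0(prefix, "_minus.bedGraph"))
  rtracklayer::export(methods::as(track$plus, "GRanges"), paths["plus"],
                      format = "bedGraph")
  rtracklayer::export(methods::as(track$minus, "GRanges"), paths["minus"],
                      format = "bedGraph")
  invisible(paths)
}
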