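#' Configuration for the synthetic ATPase assay generator
#'
#' Forward model of the coupled pyruvate-kinase / lactate-dehydrogenase
#' ATPase assay: steady-state RimK state occupancies under each condition
#' feed a composite Michaelis-Menten rate, observed with multiplicative
#' Gaussian noise. Assay constants follow the NADH-coupled readout:
#' extinction coefficient 6220 M^-1 cm^-1 at 340 nm, 0.4 mM initial NADH,
#' one NADH oxidised per ATP hydrolysed.
#'
#' @param variant true model variant label.
#' @param params named list of true-parameter overrides for [make_model()].
#' @param conditions named list of condition concentration vectors
#'   (default [default_conditions()]).
#' @param atp_grid ATP concentrations in uM.
#' @param noise Gaussian sd as a fraction of signal (default 0.02).
#' @param nadh_extinction_M_cm extinction coefficient (default 6220).
#' @param nadh_initial_uM initial NADH (default 400 uM).
#' @param path_cm effective optical path length (default 0.5 cm).
#' @param enzyme_mg_ml enzyme loading (default 0.01 mg/ml).
#' @param seed integer seed.
#' @return a list of class `assay_generator_config`.
#' @export
assay_generator_config <- function(variant = "four_state", params = list(),
                                   conditions = default_conditions(),
                                   atp_grid = c(50, 100, 250, 500, 1000,
                                                2500, 5000),
                                   noise = 0.02,
                                   nadh_extinction_M_cm = 6220,
                                   nadh_initial_uM = 400,
                                   path_cm = 0.5,
                                   enzyme_mg_ml = 0.01,
                                   seed = 1) {
  if (noise < 0) stop("noise must be >= 0", call. = FALSE)
  if (length(atp_grid) == 0) stop("ATP grid must be nonempty", call. = FALSE)
  structure(list(variant = variant, params = params, conditions = conditions,
                 atp_grid = atp_grid, noise = noise,
                 nadh_extinction_M_cm = nadh_extinction_M_cm,
                 nadh_initial_uM = nadh_initial_uM, path_cm = path_cm,
                 enzyme_mg_ml = enzyme_mg_ml, seed = seed),
            class = "assay_generator_config")
}

#' Generate synthetic multi-condition rate data
#'
#' Noiseless activities are `composite_rate` evaluated on the normalized
#' steady-state occupancies of the true model under each condition; observed
#' activities multiply in Gaussian noise (`1 + noise * N(0,1)`, floored at
#' zero). Seed-deterministic; the generating truth is attached for
#' parameter-recovery studies.
#'
#' @param cfg an [assay_generator_config()].
#' @return tibble with `condition`, `atp_uM`, `activity` and attribute
#'   `truth` (list: model, noiseless activities).
#' @export
gen_rate_data <- function(cfg) {
  stopifnot(inherits(cfg, "assay_generator_config"))
  model <- make_model(cfg$variant, overrides = cfg$params)
  rows <- lapply(names(cfg$conditions), function(lbl) {
    w <- state_weights(model, condition = cfg$conditions[[lbl]],
                       normalize = TRUE, method = "equilibrium")
    tibble::tibble(condition = lbl, atp_uM = cfg$atp_grid,
                   noiseless = composite_rate(w, cfg$atp_grid))
  })
  out <- dplyr::bind_rows(rows)
  out$activity <- withr::with_seed(cfg$seed, {
    pmax(0, out$noiseless * (1 + cfg$noise * stats::rnorm(nrow(out))))
  })
  truth <- list(model = model, noiseless = out$noiseless)
  out <- out[c("condition", "atp_uM", "activity")]
  attr(out, "truth") <- truth
  out
}

#' Generate synthetic NADH-coupled progress curves
#'
#' A340 time series for each condition at a fixed ATP concentration: the
#' PK/LDH couple oxidises one NADH per ATP hydrolysed, so absorbance at
#' 340 nm declines linearly from the NADH-determined start at a slope
#' proportional to the ATPase rate, floored at zero when NADH is exhausted.
#'
#' @param cfg an [assay_generator_config()].
#' @param atp_uM ATP concentration for the curves (default 500 uM).
#' @param times_min sampling times in minutes (default 0..60).
#' @return tibble with `condition`, `time_min`, `a340`.
#' @export
gen_progress_curves <- function(cfg, atp_uM = 500, times_min = 0:60) {
  stopifnot(inherits(cfg, "assay_generator_config"))
  model <- make_model(cfg$variant, overrides = cfg$params)
  eps_uM <- cfg$nadh_extinction_M_cm * 1e-6   # absorbance per uM per cm
  rows <- lapply(names(cfg$conditions), function(lbl) {
    w <- state_weights(model, condition = cfg$conditions[[lbl]],
                       normalize = TRUE, method = "equilibrium")
    # nmol/min/mg * mg/ml = nmol/min/ml = uM/min
    rate_uM_min <- composite_rate(w, atp_uM) * cfg$enzyme_mg_ml
    nadh <- pmax(0, cfg$nadh_initial_uM - rate_uM_min * times_min)
    tibble::tibble(condition = lbl, time_min = times_min,
                   a340 = eps_uM * cfg$path_cm * nadh)
  })
  out <- dplyr::bind_rows(rows)
  if (cfg$noise > 0) {
    out$a340 <- withr::with_seed(cfg$seed, {
      pmax(0, out$a340 * (1 + cfg$noise * stats::rnorm(nrow(out))))
    })
  }
  out
}

#' Configuration for the synthetic ribosome-footprint generator
#'
#' Emulates the statistical structure of length-filtered ribosome footprints
#' over a toy genome: reads are multinomial across genes proportionally to
#' `rate * length`, uniform within genes on the gene's strand, with footprint
#' lengths drawn from a discrete triangular distribution peaked at 30 nt over
#' 23..41 nt, plus an optional out-of-window contaminant fraction.
#'
#' @param genome_length toy genome length in nt (default 20000).
#' @param n_genes number of genes (default 10, alternating strands).
#' @param rates per-gene translation rates (default log-normal, seeded).
#' @param depth number of footprints (default 1e5).
#' @param contaminant_frac fraction of reads with out-of-window lengths
#'   (default 0.02).
#' @param seed integer seed.
#' @return a list of class `read_generator_config` with a `genes` tibble.
#' @export
read_generator_config <- function(genome_length = 20000, n_genes = 10,
                                  rates = NULL, depth = 1e5,
                                  contaminant_frac = 0.02, seed = 1) {
  stopifnot(n_genes >= 1, genome_length >= n_genes * 500)
  if (is.null(rates)) {
    rates <- withr::with_seed(seed, stats::rlnorm(n_genes, 0, 1))
  }
  if (length(rates) != n_genes || any(rates < 0)) {
    stop("rates must be a non-negative vector of length n_genes",
         call. = FALSE)
  }
  # evenly spaced genes with 100 nt intergenic gaps, lengths 400..(slot-100)
  slot <- genome_length %/% n_genes
  gene_len <- withr::with_seed(seed + 1,
    sample(seq(400, slot - 100, by = 50), n_genes, replace = TRUE))
  start <- (seq_len(n_genes) - 1) * slot + 50
  genes <- tibble::tibble(
    gene_id = sprintf("gene%02d", seq_len(n_genes)),
    start = start, end = start + gene_len - 1,
    strand = rep(c("+", "-"), length.out = n_genes),
    rate = rates
  )
  structure(list(genome_length = as.integer(genome_length), genes = genes,
                 depth = as.integer(depth),
                 contaminant_frac = contaminant_frac, seed = seed),
            class = "read_generator_config")
}

# triangular footprint length pmf over 23..41 peaked at 30
.footprint_length_probs <- function() {
  lens <- 23:41
  w <- pmin(lens - 22, 42 - lens)
  stats::setNames(w / sum(w), lens)
}

#' Generate a synthetic SAM alignment file and matching GFF3 gene models
#'
#' Writes a valid single-reference SAM file (header + primary alignments,
#' CIGAR `<len>M`) and a GFF3 file of the gene models. Read placement follows
#' the configuration's rate vector; contaminant reads have lengths outside
#' the 23-41 nt window and uniform genomic positions.
#'
#' @param cfg a [read_generator_config()].
#' @param sam_path,gff_path output paths.
#' @return invisibly, a list with the two paths and the `genes` tibble.
#' @export
gen_alignments <- function(cfg, sam_path, gff_path) {
  stopifnot(inherits(cfg, "read_generator_config"))
  genes <- cfg$genes
  ref <- "toygenome"
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", ref, cfg$genome_length))

  records <- if (cfg$depth == 0) character() else withr::with_seed(cfg$seed + 2, {
    n <- cfg$depth
    n_cont <- stats::rbinom(1, n, cfg$contaminant_frac)
    n_sig <- n - n_cont
    lp <- .footprint_length_probs()
    gene_len <- genes$end - genes$start + 1
    probs <- genes$rate * gene_len
    rec <- character(0)
    if (n_sig > 0 && sum(probs) > 0) {
      gi <- sample.int(nrow(genes), n_sig, replace = TRUE,
                       prob = probs / sum(probs))
      len <- as.integer(sample(names(lp), n_sig, replace = TRUE, prob = lp))
      # uniform start with the whole alignment inside the gene
      pos <- genes$start[gi] +
        floor(stats::runif(n_sig) * (gene_len[gi] - len + 1))
      flag <- ifelse(genes$strand[gi] == "-", 16L, 0L)
      rec <- sprintf("sig%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                     seq_len(n_sig), flag, ref, as.integer(pos), len,
                     strrep("A", len))
    }
    if (n_cont > 0) {
      clen <- sample(c(18:22, 42:50), n_cont, replace = TRUE)
      cpos <- floor(stats::runif(n_cont) * (cfg$genome_length - 50)) + 1
      cflag <- sample(c(0L, 16L), n_cont, replace = TRUE)
      rec <- c(rec,
               sprintf("cont%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       seq_len(n_cont), cflag, ref, as.integer(cpos),
                       as.integer(clen), strrep("A", clen)))
    }
    rec
  })
  writeLines(c(header, records), sam_path)

  gr <- GenomicRanges::GRanges(
    seqnames = ref,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id,
    seqlengths = stats::setNames(cfg$genome_length, ref)
  )
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(list(sam = sam_path, gff = gff_path, genes = genes))
}

#' Generate a synthetic contrast table with known regulon classes
#'
#' Draws per-gene log2 contrasts whose true class is known by construction:
#' significant effects have magnitude uniform in `tau + margin` to `max_lfc`,
#' non-significant effects uniform within `(-(tau - margin), tau - margin)`.
#' With `margin > 0` every gene lies strictly beyond (or below) the
#' threshold, so [classify_regulon()] must recover the labels exactly.
#'
#' @param n_genes number of genes.
#' @param proportions named proportions over
#'   `class1, class2, class3, glutamation_only, unaffected`; must sum to 1.
#' @param tau significance threshold used for generation (default 1.0).
#' @param margin gap kept clear of the threshold (default 0.2 log2).
#' @param max_lfc maximal effect magnitude (default 4).
#' @param seed integer seed.
#' @return tibble with `gene_id`, `log2_a`, `log2_b`, `true_class`.
#' @export
gen_contrast_tables <- function(n_genes = 1000,
                                proportions = c(class1 = 0.15, class2 = 0.05,
                                                class3 = 0.05,
                                                glutamation_only = 0.05,
                                                unaffected = 0.70),
                                tau = 1.0, margin = 0.2, max_lfc = 4,
                                seed = 1) {
  labels <- c("class1", "class2", "class3", "glutamation_only", "unaffected")
  stopifnot(setequal(names(proportions), labels),
            abs(sum(proportions) - 1) < 1e-8, margin > 0, margin < tau)
  withr::with_seed(seed, {
    cls <- sample(labels, n_genes, replace = TRUE,
                  prob = proportions[labels])
    sig <- function(n) (tau + margin + stats::runif(n) *
                          (max_lfc - tau - margin)) *
      sample(c(-1, 1), n, replace = TRUE)
    nonsig <- function(n) stats::runif(n, -(tau - margin), tau - margin)
    a <- numeric(n_genes)
    b <- numeric(n_genes)
    for (lab in labels) {
      i <- which(cls == lab)
      n <- length(i)
      if (n == 0) next
      switch(lab,
        class1 = { a[i] <- sig(n); b[i] <- nonsig(n) },
        class2 = { a[i] <- sig(n); b[i] <- abs(sig(n)) * sign(a[i]) },
        class3 = { a[i] <- sig(n); b[i] <- -abs(sig(n)) * sign(a[i]) },
        glutamation_only = { a[i] <- nonsig(n); b[i] <- sig(n) },
        unaffected = { a[i] <- nonsig(n); b[i] <- nonsig(n) }
      )
    }
    tibble::tibble(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                   log2_a = a, log2_b = b, true_class = cls)
  })
}

#' Generate a synthetic protein-abundance ratio table with known flags
#'
#' Records generated as truly-differential carry >= `min_peptides` unique
#' peptides, a WT-vs-mutant log2 difference strictly beyond
#' `min_delta_log2 + margin` and one p-value below `max_p`; null records
#' violate at least one criterion by the same margin, so
#' [differential_protein_filter()] recovers the truth exactly.
#'
#' @param n_proteins number of records.
#' @param flagged_frac fraction of truly differential records.
#' @param min_peptides,min_delta_log2,max_p the filter thresholds emulated.
#' @param margin clearance kept around each threshold.
#' @param seed integer seed.
#' @return tibble with the [differential_protein_filter()] columns plus
#'   `true_flag`.
#' @export
gen_protein_table <- function(n_proteins = 500, flagged_frac = 0.1,
                              min_peptides = 2, min_delta_log2 = 1,
                              max_p = 0.05, margin = 0.2, seed = 1) {
  withr::with_seed(seed, {
    flag <- stats::runif(n_proteins) < flagged_frac
    n <- n_proteins
    log2_wt <- stats::rnorm(n, 0, 0.5)
    delta <- numeric(n)
    delta[flag] <- (min_delta_log2 + margin + stats::runif(sum(flag), 0, 2)) *
      sample(c(-1, 1), sum(flag), replace = TRUE)
    delta[!flag] <- stats::runif(sum(!flag),
                                 -(min_delta_log2 - margin),
                                 min_delta_log2 - margin)
    peptides <- ifelse(flag, min_peptides + stats::rpois(n, 3),
                       pmax(1, stats::rpois(n, 4)))
    p_wt <- ifelse(flag, stats::runif(n, 0, max_p * 0.8),
                   stats::runif(n, max_p * 1.2, 1))
    p_mut <- stats::runif(n, max_p * 1.2, 1)
    tibble::tibble(
      protein_id = sprintf("prot%04d", seq_len(n)),
      peptides = as.integer(peptides),
      log2_wt = log2_wt, log2_mut = log2_wt + delta,
      p_wt = p_wt, p_mut = p_mut,
      true_flag = flag
    )
  })
}
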