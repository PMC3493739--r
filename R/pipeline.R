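# End-to-end orchestration: synthesize (or load) inputs, preprocess both
# libraries, map and annotate, call novel hairpins, run differential
# expression on known miRNAs, predict targets of novel matures, and run GO
# enrichment.  Also houses the packaged transcriptions of the reference
# result tables and their arithmetic self-checks.

#' Default pipeline configuration
#'
#' All thresholds of the pipeline in one list: insert length bounds 18-30 nt
#' (inclusive), fold-change gate 1 (log2), raw p gate 0.001, FDR gate 0.01,
#' MFE-ratio gate 0.75, and the hairpin-caller thresholds; plus the
#' synthetic-design knobs used when no input files are supplied.
#'
#' @param outdir output directory for the report bundle.
#' @param seed master seed; every stage derives its own seed from it.
#' @param total_reads reads per simulated library.
#' @return named list of class `run_config`.
#' @export
default_config <- function(outdir = tempfile("srnarun"), seed = 1L,
                           total_reads = 50000L) {
  structure(list(
    outdir = outdir,
    seed = as.integer(seed),
    total_reads = as.integer(total_reads),
    adapter3 = "TCGTATGCCGTCTTCTGCTTG",
    adapter5 = NULL,
    error_rate = 0.001,
    min_len = 18L, max_len = 30L,
    min_quality = 20,
    fc_cut = 1, p_cut = 0.001, fdr_cut = 0.01, use_fdr = FALSE,
    mfe_ratio_min = 0.75,
    hairpin = hairpin_params(),
    design_seed = 101L
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The configuration round-trips losslessly (the nested hairpin block
#' included).
#'
#' @param config a `run_config` list.
#' @param path YAML file path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config())
  for (nm in names(cfg)) base[nm] <- list(cfg[[nm]])  # keeps NULL members
  int_fields <- c("seed", "total_reads", "min_len", "max_len", "design_seed")
  for (nm in int_fields) base[[nm]] <- as.integer(base[[nm]])
  structure(base, class = "run_config")
}

#' Run the full two-condition pipeline
#'
#' Generates the synthetic reference bundle and two condition libraries from
#' the design, then runs every stage and writes the report bundle to
#' `config$outdir`: `tableI.tsv` (novel hairpin candidates shared between
#' conditions), `tableII.tsv` (known-miRNA differential expression, columns
#' named as in the reference report), `categories.tsv` (per-condition
#' annotation summary), `targets.tsv`, `go.tsv`, `summary.tsv` (per-stage
#' read conservation) and `checksums.tsv`.  Deterministic: the same seed
#' yields a byte-identical bundle.
#'
#' @param config a [default_config()] list.
#' @param design optional [spike_in_design()]; defaults to
#'   [default_design()] drawn with `config$design_seed`.
#' @return list with every stage result (invisible file paths in
#'   `$files`).
#' @export
run_pipeline <- function(config = default_config(), design = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(design)) design <- default_design(config$design_seed)

  ref <- build_reference(design, seed = child_seed(config$seed, 1L))
  annotation <- with(ref$annotation, GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start, end),
    strand = strand, category = category
  ))
  index <- kmer_index(ref$genome)

  sims <- list()
  libs <- list()
  for (cond in c("A", "B")) {
    cfg <- read_sim_config(
      total_reads = config$total_reads, adapter3 = config$adapter3,
      adapter5 = config$adapter5, error_rate = config$error_rate,
      seed = child_seed(config$seed, 2L)
    )
    sim <- simulate_library(design, cfg, condition = cond)
    pp <- preprocess_reads(sim$reads$sequence, adapter3 = config$adapter3,
                           adapter5 = config$adapter5,
                           qualities = sim$reads$quality,
                           min_len = config$min_len, max_len = config$max_len,
                           min_quality = config$min_quality)
    hits <- map_exact(pp$tags, ref$genome, index = index)
    assign <- assign_category(pp$tags, hits, annotation, ref$known_mirnas)
    unann <- assign[!is.na(assign$category) & assign$category == "unannotated", ]
    cands <- call_candidates(unann, ref$genome,
                             hits = hits[hits$tag %in% unann$sequence, ],
                             params = config$hairpin)
    sims[[cond]] <- sim
    libs[[cond]] <- list(pp = pp, hits = hits, assign = assign,
                         candidates = cands)
  }

  shared <- intersect_candidates(libs$A$candidates, libs$B$candidates)

  # known-miRNA counts per condition (by exact mature sequence)
  known <- ref$known_mirnas
  counts <- sapply(c("A", "B"), function(cond) {
    a <- libs[[cond]]$assign
    idx <- match(known, a$sequence)
    ifelse(is.na(idx), 0L, a$count[idx])
  })
  de <- diff_expression(counts[, "A"], counts[, "B"],
                        total_case = config$total_reads,
                        total_control = config$total_reads,
                        names = names(known), fc_cut = config$fc_cut,
                        p_cut = config$p_cut, use_fdr = config$use_fdr,
                        fdr_cut = config$fdr_cut)

  novel_matures <- stats::setNames(shared$sequence, shared$name)
  tx <- generate_transcripts(novel_matures, seed = child_seed(config$seed, 3L))
  targets <- predict_targets(novel_matures, tx$transcripts,
                             tx2gene = tx$tx2gene,
                             mfe_ratio_min = config$mfe_ratio_min)
  target_genes <- unique(targets$gene)
  go_map <- generate_go_map(
    n_genes = nrow(tx$tx2gene) + 60L, n_terms = 8L,
    target_genes = target_genes, seed = child_seed(config$seed, 4L)
  )
  # synthetic gene ids beyond the transcriptome pad the background
  go_map <- rbind(go_map, data.frame(gene = target_genes,
                                     term = "GO:0000001",
                                     stringsAsFactors = FALSE))
  go_map <- unique(go_map)
  go <- enrich_go(target_genes, go_map, p_cut = config$p_cut)

  files <- write_bundle(config, design, sims, libs, shared, de, targets, go)
  invisible(list(
    config = config, design = design, reference = ref, sims = sims,
    libraries = libs, shared_candidates = shared, de = de,
    targets = targets, go = go, files = files
  ))
}

#' @noRd
write_bundle <- function(config, design, sims, libs, shared, de, targets, go) {
  out <- config$outdir
  fmt_num <- function(x, digits = 6) {
    ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
  }

  tableI <- data.frame(
    Name = shared$name,
    Sequence = shared$sequence,
    Arm = ifelse(shared$arm == "5p", "5'", "3'"),
    Length = shared$length,
    Location = sprintf("%s:%d:%d:%s", shared$chrom, shared$start,
                       shared$end, shared$strand),
    `Precursor length (nt)` = shared$precursor_length,
    MFE = fmt_num(shared$mfe, 4),
    Count = shared$count,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  tableII <- data.frame(
    Name = de$name,
    `Klinefelter syndrome-std` = fmt_num(de$case_std),
    `Healthy control-std` = fmt_num(de$control_std),
    `Fold change (log2 ratio)` = fmt_num(de$log2fc, 9),
    `P-value` = fmt_num(de$pvalue, 9),
    fdr = fmt_num(de$fdr, 9),
    class = de$class,
    check.names = FALSE, stringsAsFactors = FALSE
  )
  categories <- do.call(rbind, lapply(c("A", "B"), function(cond) {
    s <- summarize_categories(libs[[cond]]$assign)
    cbind(condition = cond, s, stringsAsFactors = FALSE)
  }))
  summary <- do.call(rbind, lapply(c("A", "B"), function(cond) {
    s <- libs[[cond]]$pp$summary
    cbind(condition = cond, s, stringsAsFactors = FALSE)
  }))

  paths <- c(
    tableI = file.path(out, "tableI.tsv"),
    tableII = file.path(out, "tableII.tsv"),
    categories = file.path(out, "categories.tsv"),
    targets = file.path(out, "targets.tsv"),
    go = file.path(out, "go.tsv"),
    summary = file.path(out, "summary.tsv")
  )
  write_tsv(tableI, paths["tableI"])
  write_tsv(tableII, paths["tableII"])
  write_tsv(categories, paths["categories"])
  targets_out <- targets
  for (cn in c("score", "mfe", "mfe_ratio")) {
    targets_out[[cn]] <- fmt_num(targets_out[[cn]], 6)
  }
  write_tsv(targets_out, paths["targets"])
  go_out <- go
  go_out$pvalue <- fmt_num(go_out$pvalue, 9)
  go_out$fdr <- fmt_num(go_out$fdr, 9)
  write_tsv(go_out, paths["go"])
  write_tsv(summary, paths["summary"])

  sums <- tools::md5sum(unname(paths))
  checks <- data.frame(file = basename(names(sums)), md5 = unname(sums),
                       stringsAsFactors = FALSE)
  check_path <- file.path(out, "checksums.tsv")
  write_tsv(checks, check_path)
  c(paths, checksums = check_path)
}

# -- packaged reference tables ----------------------------------------------

#' @noRd
normalize_minus <- function(x) {
  trimws(gsub("−", "-", x))
}

#' Load the packaged reference result tables
#'
#' Transcriptions of the two printed result tables of the reference
#' profiling experiment: the 25 novel miRNA candidates found in both
#' libraries (name, sequence, arm, length, location, precursor length, MFE,
#' count) and the 89 differentially expressed known miRNAs (normalized
#' expression in each library, log2 fold change, p-value).  Unicode minus
#' signs from typesetting are normalized to ASCII on load.
#'
#' @return list with data frames `novel` and `de`.
#' @export
load_reference_tables <- function() {
  f1 <- system.file("extdata", "novel_mirna_reference.tsv",
                    package = "srnaprofiler", mustWork = TRUE)
  f2 <- system.file("extdata", "known_mirna_de_reference.tsv",
                    package = "srnaprofiler", mustWork = TRUE)
  novel <- read.delim(f1, check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character", fileEncoding = "UTF-8")
  de <- read.delim(f2, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", fileEncoding = "UTF-8")
  novel$MFE <- as.numeric(normalize_minus(novel$MFE))
  novel$Length <- as.integer(novel$Length)
  novel$`Precursor length (nt)` <- as.integer(novel$`Precursor length (nt)`)
  novel$Count <- as.integer(novel$Count)
  novel$Location <- normalize_minus(novel$Location)
  for (cn in c("Klinefelter syndrome-std", "Healthy control-std",
               "Fold change (log2 ratio)", "P-value")) {
    de[[cn]] <- as.numeric(normalize_minus(de[[cn]]))
  }
  list(novel = novel, de = de)
}

#' Verify the packaged reference tables' internal arithmetic
#'
#' Re-derives what the printed tables encode: for the novel-candidate table,
#' that each location satisfies precursor length = end - start + 1 and each
#' sequence has the printed length; for the differential-expression table,
#' that the printed fold-change column equals log2(control-std / case-std)
#' within `tol` and that the positive/negative sign partition matches.
#' Fails naming the offending row.
#'
#' @param tables optional result of [load_reference_tables()] (or a
#'   compatible list), e.g. a deliberately corrupted copy.
#' @param tol fold-change reproduction tolerance, default 1e-4.
#' @return list report: `novel_rows`, `de_rows`, `max_fc_delta`,
#'   `n_positive`, `n_negative`, `pass`.
#' @export
verify_reference_tables <- function(tables = load_reference_tables(),
                                    tol = 1e-4) {
  novel <- tables$novel
  for (i in seq_len(nrow(novel))) {
    loc <- parse_location(novel$Location[i])
    plen <- precursor_length(loc)
    if (plen != novel$`Precursor length (nt)`[i]) {
      stop("novel table row ", i, " (", novel$Name[i], "): location spans ",
           plen, " nt but printed precursor length is ",
           novel$`Precursor length (nt)`[i])
    }
    if (nchar(novel$Sequence[i]) != novel$Length[i]) {
      stop("novel table row ", i, " (", novel$Name[i],
           "): sequence length ", nchar(novel$Sequence[i]),
           " != printed length ", novel$Length[i])
    }
  }
  de <- tables$de
  recomputed <- log2_ratio(floor_zero(de$`Healthy control-std`),
                           floor_zero(de$`Klinefelter syndrome-std`))
  delta <- abs(recomputed - de$`Fold change (log2 ratio)`)
  if (any(delta > tol)) {
    bad <- which.max(delta)
    stop("DE table row ", bad, " (", de$Name[bad],
         "): recomputed fold change ", format(recomputed[bad]),
         " differs from printed ", de$`Fold change (log2 ratio)`[bad])
  }
  list(
    novel_rows = nrow(novel),
    de_rows = nrow(de),
    max_fc_delta = max(delta),
    n_positive = sum(de$`Fold change (log2 ratio)` > 0),
    n_negative = sum(de$`Fold change (log2 ratio)` < 0),
    pass = TRUE
  )
}
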