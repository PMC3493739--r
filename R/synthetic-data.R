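# Synthetic-data generators: toy genome, planted hairpins and spike-ins,
# two-condition read simulation with ground truth, and a gene->GO map.
# Every downstream stage of the pipeline can be exercised against the truth
# tables these functions emit.

#' Generate a toy genome
#'
#' Builds a small random genome with an exact base composition (so the GC
#' fraction is by construction inside \[0.3, 0.7\] for the default) and an
#' empty feature registry that planting functions append to.
#'
#' @param n_chrom number of chromosomes (>= 1).
#' @param length length of each chromosome in bases (>= 200).
#' @param seed integer seed; the genome is byte-identical for a fixed seed.
#' @param gc target GC fraction, default 0.5.
#' @return an object of class `ToyGenome`: a list with `chromosomes` (named
#'   uppercase DNA strings) and `features` (a data frame registry of planted
#'   features).
#' @export
generate_genome <- function(n_chrom = 1L, length = 10000L, seed = 1L, gc = 0.5) {
  if (n_chrom < 1L) stop("n_chrom must be >= 1")
  if (length < 200L) stop("chromosome length must be >= 200 (too short to host a hairpin)")
  if (gc < 0.3 || gc > 0.7) stop("gc must be in [0.3, 0.7]")
  set.seed(as.integer(seed))
  chroms <- vapply(seq_len(n_chrom), function(i) rand_dna(length, gc), character(1))
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  structure(
    list(
      chromosomes = chroms,
      features = empty_features()
    ),
    class = "ToyGenome"
  )
}

#' @noRd
empty_features <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), type = character(), name = character(),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ToyGenome <- function(x, ...) {
  cat("ToyGenome:", length(x$chromosomes), "chromosome(s),",
      sum(nchar(x$chromosomes)), "bases,",
      nrow(x$features), "planted feature(s)\n")
  invisible(x)
}

#' @noRd
check_no_overlap <- function(genome, chrom, start, end) {
  f <- genome$features
  f <- f[f$chrom == chrom, , drop = FALSE]
  if (nrow(f) && any(f$start <= end & f$end >= start)) {
    stop("planted feature at ", chrom, ":", start, "-", end,
         " overlaps an existing feature")
  }
}

#' @noRd
replace_substring <- function(s, start, value) {
  paste0(
    substr(s, 1L, start - 1L),
    value,
    substr(s, start + nchar(value), nchar(s))
  )
}

#' Plant a pre-miRNA hairpin into a toy genome
#'
#' Writes a precursor at the given position whose one arm carries the mature
#' sequence exactly and whose other arm is the reverse complement of the
#' mature arm except at up to three designed mismatch positions, so the
#' precursor folds into a stem-loop detectable by [fold_hairpin()].
#'
#' @param genome a `ToyGenome`.
#' @param mature mature miRNA sequence (DNA alphabet, 18-30 nt).
#' @param arm which precursor arm carries the mature sequence, `"5p"` or `"3p"`.
#' @param chrom chromosome name (default first chromosome).
#' @param position 1-based start of the precursor on the chromosome.
#' @param precursor_len precursor length, 60-100 nt.
#' @param loop_len terminal loop length, 3-20 nt (adjusted by one base if
#'   needed so the two arms have equal length).
#' @param n_mismatches number of designed mismatches (0-3) placed on the
#'   non-mature arm.
#' @param name feature name recorded in the registry.
#' @param seed integer seed for the random arm padding and mismatch placement.
#' @return list with elements `genome` (updated) and `locus` (list with
#'   `chrom`, `start`, `end`, `strand` of the planted precursor).
#' @export
plant_hairpin <- function(genome, mature, arm = c("5p", "3p"), chrom = NULL,
                          position, precursor_len = 80L, loop_len = 8L,
                          n_mismatches = 2L, name = "novel", seed = 1L) {
  arm <- match.arg(arm)
  stopifnot(inherits(genome, "ToyGenome"))
  if (!is_dna(mature)) stop("mature sequence must be non-empty A/C/G/T")
  if (precursor_len < 60L || precursor_len > 100L) {
    stop("precursor_len must be in [60, 100]")
  }
  if (n_mismatches < 0L || n_mismatches > 3L) stop("n_mismatches must be 0-3")
  if (is.null(chrom)) chrom <- names(genome$chromosomes)[1L]
  if (!chrom %in% names(genome$chromosomes)) stop("unknown chromosome: ", chrom)

  set.seed(as.integer(seed))
  arm_len <- (precursor_len - loop_len) %/% 2L
  loop_len <- precursor_len - 2L * arm_len
  if (loop_len < 3L || loop_len > 20L) stop("loop_len out of range after arm sizing")
  m_len <- nchar(mature)
  if (m_len > arm_len) stop("mature does not fit in a ", arm_len, "-nt arm")
  pad <- if (arm_len > m_len) rand_dna(arm_len - m_len) else ""

  if (arm == "5p") {
    arm5 <- paste0(mature, pad)
    arm3 <- mutate_bases(revcomp(arm5), n_mismatches, partner = arm5, reversed = TRUE)
    mature_offset <- 0L
  } else {
    arm3 <- paste0(pad, mature)
    arm5 <- mutate_bases(revcomp(arm3), n_mismatches, partner = arm3, reversed = TRUE)
    mature_offset <- arm_len + loop_len + nchar(pad)
  }
  loop <- rand_dna(loop_len)
  precursor <- paste0(arm5, loop, arm3)
  stopifnot(nchar(precursor) == precursor_len)

  end <- position + precursor_len - 1L
  chrom_len <- nchar(genome$chromosomes[[chrom]])
  if (position < 1L || end > chrom_len) {
    stop("precursor ", position, "-", end, " does not fit on ", chrom,
         " (length ", chrom_len, ")")
  }
  check_no_overlap(genome, chrom, position, end)
  genome$chromosomes[[chrom]] <- replace_substring(
    genome$chromosomes[[chrom]], position, precursor
  )
  genome$features <- rbind(genome$features, data.frame(
    chrom = chrom, start = position, end = end, strand = "+",
    type = "precursor", name = name, stringsAsFactors = FALSE
  ))
  # record the mature span too (used by truth-driven tests)
  genome$features <- rbind(genome$features, data.frame(
    chrom = chrom,
    start = position + mature_offset,
    end = position + mature_offset + m_len - 1L,
    strand = "+", type = "mature", name = paste0(name, "_mature"),
    stringsAsFactors = FALSE
  ))
  list(
    genome = genome,
    locus = list(chrom = chrom, start = position, end = end, strand = "+")
  )
}

# Substitute n bases of `x` so each substituted position cannot pair with its
# partner base on the opposite arm (the substituted base is set equal to the
# partner base; no DNA/RNA base pairs with itself).
#' @noRd
mutate_bases <- function(x, n, partner, reversed = FALSE) {
  if (n == 0L) return(x)
  chars <- strsplit(x, "")[[1]]
  pchars <- strsplit(partner, "")[[1]]
  L <- length(chars)
  # avoid the two terminal positions to keep the closing stack intact
  pos <- sort(sample(2:(L - 1L), n))
  for (p in pos) {
    q <- if (reversed) L - p + 1L else p
    chars[p] <- pchars[q]
  }
  paste(chars, collapse = "")
}

#' Plant a plain sequence into a toy genome
#'
#' Used for known-miRNA spike-ins and for annotated-class fragments (rRNA,
#' tRNA, ...) whose surrounding interval then goes into the annotation BED.
#'
#' @inheritParams plant_hairpin
#' @param sequence DNA sequence to write at `position`.
#' @param type feature type recorded in the registry.
#' @return list with `genome` (updated) and `locus`.
#' @export
plant_sequence <- function(genome, sequence, chrom = NULL, position,
                           type = "spikein", name = type) {
  stopifnot(inherits(genome, "ToyGenome"))
  if (!is_dna(sequence)) stop("sequence must be non-empty A/C/G/T")
  if (is.null(chrom)) chrom <- names(genome$chromosomes)[1L]
  end <- position + nchar(sequence) - 1L
  chrom_len <- nchar(genome$chromosomes[[chrom]])
  if (position < 1L || end > chrom_len) stop("sequence does not fit on ", chrom)
  check_no_overlap(genome, chrom, position, end)
  genome$chromosomes[[chrom]] <- replace_substring(
    genome$chromosomes[[chrom]], position, sequence
  )
  genome$features <- rbind(genome$features, data.frame(
    chrom = chrom, start = position, end = end, strand = "+",
    type = type, name = name, stringsAsFactors = FALSE
  ))
  list(genome = genome,
       locus = list(chrom = chrom, start = position, end = end, strand = "+"))
}

# -- spike-in design ---------------------------------------------------------

#' Construct a spike-in design table
#'
#' A design row names one small-RNA species, its mature sequence, its type
#' (`known_mirna`, `novel`, or an annotated class such as `rRNA`), and its
#' expected abundance (reads per million) in each condition.  The true-DE
#' flag is derived with the same RPM floor and 2-fold rule the differential
#' expression module applies.
#'
#' @param name character vector of species names.
#' @param mature character vector of mature/fragment sequences (18-30 nt).
#' @param type one of `"known_mirna"`, `"novel"`, `"rRNA"`, `"scRNA"`,
#'   `"snoRNA"`, `"snRNA"`, `"piRNA"`, `"tRNA"`, `"repeat"`, `"exon"`,
#'   `"intron"` per row.
#' @param rpm_a,rpm_b expected reads per million in condition A and B (>= 0).
#' @return data frame of class `spike_in_design` with a derived `true_de`
#'   logical column.
#' @export
spike_in_design <- function(name, mature, type, rpm_a, rpm_b) {
  stopifnot(length(name) == length(mature),
            length(name) == length(type),
            length(name) == length(rpm_a),
            length(name) == length(rpm_b))
  if (anyDuplicated(name)) stop("design names must be unique")
  if (any(rpm_a < 0 | rpm_b < 0)) stop("expected RPM must be >= 0")
  if (!all(is_dna(mature))) stop("mature sequences must be A/C/G/T")
  ok_types <- c("known_mirna", "novel", "rRNA", "scRNA", "snoRNA", "snRNA",
                "piRNA", "tRNA", "repeat", "exon", "intron")
  if (!all(type %in% ok_types)) {
    stop("unknown design type: ", paste(setdiff(type, ok_types), collapse = ", "))
  }
  d <- data.frame(
    name = name, mature = mature, type = type,
    rpm_a = rpm_a, rpm_b = rpm_b, stringsAsFactors = FALSE
  )
  d$true_de <- abs(log2(floor_zero(rpm_b) / floor_zero(rpm_a))) >= 1
  class(d) <- c("spike_in_design", "data.frame")
  d
}

#' Default two-condition spike-in design
#'
#' The stock study conditions used by the end-to-end tests: known miRNAs
#' spanning four orders of magnitude of abundance (a let-7f-like species
#' dominating both libraries), a block of 4-fold differentially expressed
#' miRNAs at baseline RPM >= 100, five novel hairpin-borne matures present in
#' both conditions at RPM >= 500, and one fragment from each annotated class
#' to exercise the category cascade.
#'
#' @param seed integer seed used to draw the mature sequences.
#' @return a `spike_in_design` data frame.
#' @export
default_design <- function(seed = 101L) {
  set.seed(as.integer(seed))
  draw <- function(n, len = 22L) vapply(seq_len(n), function(i) rand_dna(len), character(1))

  known_flat <- paste0("kmir-", sprintf("%02d", 1:12))
  flat_rpm <- c(200000, 50000, 20000, 8000, 3000, 1500, 800, 500, 300, 200, 150, 100)
  known_up <- paste0("kmir-up-", 1:6)     # 4-fold higher in condition B
  up_a <- c(100, 200, 400, 800, 1600, 3200)
  known_dn <- paste0("kmir-dn-", 1:6)     # 4-fold lower in condition B
  dn_a <- c(120, 240, 480, 960, 1920, 3840)
  novel <- paste0("novel-", 1:5)
  novel_rpm <- c(500, 800, 1500, 3000, 600)
  classes <- c("rRNA", "tRNA", "snoRNA", "repeat", "exon")
  class_rpm <- c(150000, 40000, 10000, 5000, 5000)

  spike_in_design(
    name  = c(known_flat, known_up, known_dn, novel, paste0(classes, "-frag")),
    mature = draw(12 + 6 + 6 + 5 + 5),
    type  = c(rep("known_mirna", 24), rep("novel", 5), classes),
    rpm_a = c(flat_rpm, up_a, dn_a, novel_rpm, class_rpm),
    rpm_b = c(flat_rpm, up_a * 4, dn_a / 4, novel_rpm, class_rpm)
  )
}

#' Read-simulation configuration
#'
#' @param total_reads reads per simulated library (> 0).
#' @param adapter3 3' adapter sequence appended to every insert (as
#'   sequenced); the standard small-RNA adapter by default.
#' @param adapter5 optional 5' adapter; when set, `contaminant_rate` of reads
#'   carry it as a prefix (ligation contaminants the preprocessor must drop).
#' @param error_rate per-base substitution error rate; errors are never
#'   injected into the first 18 bases of an insert so tag counting stays
#'   deterministic at small scale.
#' @param read_length sequenced read length.
#' @param contaminant_rate fraction of reads turned into 5' adapter
#'   contaminants when `adapter5` is set.
#' @param seed integer seed; fixed seed gives byte-identical FASTQ output.
#' @return list of class `read_sim_config`.
#' @export
read_sim_config <- function(total_reads = 50000L,
                            adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                            adapter5 = NULL,
                            error_rate = 0.001,
                            read_length = 36L,
                            contaminant_rate = 0.01,
                            seed = 1L) {
  if (total_reads <= 0L) stop("total_reads must be > 0")
  if (error_rate < 0 || error_rate > 0.1) stop("error_rate must be in [0, 0.1]")
  if (!is_dna(adapter3)) stop("adapter3 must be A/C/G/T")
  structure(
    list(total_reads = as.integer(total_reads), adapter3 = adapter3,
         adapter5 = adapter5, error_rate = error_rate,
         read_length = as.integer(read_length),
         contaminant_rate = contaminant_rate, seed = as.integer(seed)),
    class = "read_sim_config"
  )
}

#' Simulate one small-RNA library
#'
#' Draws per-species read counts from a multinomial with probabilities
#' proportional to the design's expected RPM for the chosen condition, then
#' builds reads as insert + 3' adapter suffix (truncated at the read length),
#' with optional substitution errors outside the first 18 insert bases and
#' optional 5' adapter contaminants.
#'
#' @param design a [spike_in_design()] table.
#' @param cfg a [read_sim_config()].
#' @param condition `"A"` or `"B"`.
#' @return list with `reads` (data frame: `id`, `sequence`, `quality`) and
#'   `truth` (data frame: `name`, `mature`, `type`, `count`, `condition`);
#'   truth counts sum to `cfg$total_reads`.
#' @export
simulate_library <- function(design, cfg, condition = c("A", "B")) {
  condition <- match.arg(condition)
  stopifnot(inherits(design, "spike_in_design"), inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed + ifelse(condition == "A", 0L, 1L))

  rpm <- if (condition == "A") design$rpm_a else design$rpm_b
  active <- rpm > 0
  counts <- integer(nrow(design))
  if (any(active)) {
    counts[active] <- as.integer(
      rmultinom(1, cfg$total_reads, prob = rpm[active] / sum(rpm[active]))
    )
  }
  truth <- data.frame(
    name = design$name, mature = design$mature, type = design$type,
    count = counts, condition = condition, stringsAsFactors = FALSE
  )

  inserts <- rep(design$mature, counts)
  n <- length(inserts)
  reads <- make_read(inserts, cfg)
  if (!is.null(cfg$adapter5) && cfg$contaminant_rate > 0) {
    contam <- runif(n) < cfg$contaminant_rate
    if (any(contam)) {
      reads[contam] <- substr(paste0(cfg$adapter5, reads[contam]),
                              1L, cfg$read_length)
    }
  }
  ord <- sample.int(n)
  data.frame(
    id = sprintf("read_%06d", seq_len(n)),
    sequence = reads[ord],
    quality = strrep("I", cfg$read_length),
    stringsAsFactors = FALSE
  ) -> reads_df
  list(reads = reads_df, truth = truth)
}

#' @noRd
make_read <- function(inserts, cfg) {
  L <- cfg$read_length
  reads <- substr(paste0(inserts, strrep(cfg$adapter3, ceiling(L / nchar(cfg$adapter3)) + 1L)),
                  1L, L)
  if (cfg$error_rate > 0) {
    # substitution errors, never within the first 18 bases
    n <- length(reads)
    k <- rbinom(n, L - 18L, cfg$error_rate)
    hit <- which(k > 0L)
    for (i in hit) {
      pos <- sample(19:L, k[i])
      ch <- strsplit(reads[i], "")[[1]]
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      reads[i] <- paste(ch, collapse = "")
    }
  }
  reads
}

#' Write simulated reads as FASTQ (Phred+33)
#'
#' @param sim result of [simulate_library()].
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  r <- sim$reads
  con <- file(path, "wb")  # binary mode: identical bytes on every platform
  on.exit(close(con))
  writeLines(paste0("@", r$id, "\n", r$sequence, "\n+\n", r$quality),
             con, sep = "\n")
  invisible(path)
}

#' Write a simulation truth table as TSV
#'
#' @param sim result of [simulate_library()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(sim, path) {
  write_tsv(sim$truth, path)
  invisible(path)
}

#' @noRd
write_tsv <- function(d, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# -- reference bundle --------------------------------------------------------

#' Plant a full design into a toy genome
#'
#' Lays out every design species on the genome: novel species become planted
#' hairpins, known miRNAs and annotated-class fragments become plain planted
#' sequences; annotated-class features additionally get an interval (with a
#' small margin) destined for the annotation BED.
#'
#' @param design a [spike_in_design()] table.
#' @param chrom_len chromosome length; enlarged automatically if the design
#'   does not fit.
#' @param seed integer seed.
#' @param spacing bases reserved per feature slot.
#' @return list with `genome` (`ToyGenome`), `annotation` (data frame:
#'   `chrom`, `start`, `end`, `strand`, `category`, `name`; 1-based
#'   inclusive), and `known_mirnas` (named character vector of mature
#'   sequences of type `known_mirna`).
#' @export
build_reference <- function(design, chrom_len = 20000L, seed = 1L,
                            spacing = 200L) {
  stopifnot(inherits(design, "spike_in_design"))
  needed <- (nrow(design) + 2L) * spacing
  chrom_len <- max(chrom_len, needed)
  genome <- generate_genome(1L, chrom_len, seed = seed)
  ann <- data.frame(
    chrom = character(), start = integer(), end = integer(),
    strand = character(), category = character(), name = character(),
    stringsAsFactors = FALSE
  )
  classes <- c("rRNA", "scRNA", "snoRNA", "snRNA", "piRNA", "tRNA",
               "repeat", "exon", "intron")
  for (i in seq_len(nrow(design))) {
    pos <- i * spacing
    type <- design$type[i]
    if (type == "novel") {
      res <- plant_hairpin(genome, design$mature[i],
                           arm = if (i %% 2L == 0L) "3p" else "5p",
                           position = pos, name = design$name[i],
                           seed = child_seed(seed, i))
      genome <- res$genome
    } else {
      res <- plant_sequence(genome, design$mature[i], position = pos,
                            type = type, name = design$name[i])
      genome <- res$genome
      if (type %in% classes) {
        ann <- rbind(ann, data.frame(
          chrom = res$locus$chrom,
          start = max(1L, res$locus$start - 10L),
          end = res$locus$end + 10L,
          strand = "+",
          category = if (type %in% c("exon", "intron")) "exon_intron" else type,
          name = design$name[i],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  known <- design$mature[design$type == "known_mirna"]
  names(known) <- design$name[design$type == "known_mirna"]
  list(genome = genome, annotation = ann, known_mirnas = known)
}

#' Write a toy genome as FASTA
#' @param genome a `ToyGenome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "ToyGenome"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$chromosomes), path
  )
  invisible(path)
}

#' Write annotation intervals as BED6 (0-based half-open)
#'
#' The internal representation is 1-based inclusive; on disk the intervals
#' follow the BED convention (start - 1, end), with the category in the name
#' column.
#'
#' @param annotation annotation data frame from [build_reference()].
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- data.frame(
    chrom = annotation$chrom,
    start = annotation$start - 1L,
    end = annotation$end,
    name = annotation$category,
    score = 0L,
    strand = annotation$strand,
    stringsAsFactors = FALSE
  )
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write mature miRNA sequences as FASTA
#' @param mirnas named character vector of mature sequences.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_mirna_fasta <- function(mirnas, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(mirnas), path)
  invisible(path)
}

# -- transcripts and GO map --------------------------------------------------

#' Generate a toy transcriptome with planted antisense target sites
#'
#' Each miRNA gets one transcript carrying a perfect antisense binding site
#' at a recorded offset; additional background transcripts carry no planted
#' site.  A transcript-to-gene map accompanies the sequences.
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param n_background number of site-free background transcripts.
#' @param tx_length transcript length in nt.
#' @param seed integer seed.
#' @return list with `transcripts` (named character), `sites` (data frame:
#'   `mirna`, `transcript`, `offset` 1-based), and `tx2gene` (data frame).
#' @export
generate_transcripts <- function(mirnas, n_background = 5L, tx_length = 400L,
                                 seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(mirnas) + n_background
  tx <- vapply(seq_len(n), function(i) rand_dna(tx_length), character(1))
  names(tx) <- sprintf("tx_%03d", seq_len(n))
  sites <- data.frame(mirna = character(), transcript = character(),
                      offset = integer(), stringsAsFactors = FALSE)
  for (i in seq_along(mirnas)) {
    site <- revcomp(mirnas[[i]])
    offset <- sample.int(tx_length - nchar(site) - 20L, 1L) + 10L
    tx[i] <- replace_substring(tx[i], offset, site)
    sites <- rbind(sites, data.frame(
      mirna = names(mirnas)[i], transcript = names(tx)[i],
      offset = offset, stringsAsFactors = FALSE
    ))
  }
  tx2gene <- data.frame(
    transcript = names(tx),
    gene = sprintf("gene_%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
  list(transcripts = tx, sites = sites, tx2gene = tx2gene)
}

#' Generate a synthetic gene-to-GO map
#'
#' Annotates background genes to each term at a base rate and the target
#' genes to one chosen term at an elevated rate, so the enrichment module
#' has a planted positive with a known closed-form hypergeometric tail.
#'
#' @param n_genes number of genes (`gene_001` ...).
#' @param n_terms number of GO terms (`GO:0000001` ...).
#' @param enriched_term the term enriched among `target_genes`.
#' @param target_genes character vector of target gene ids.
#' @param seed integer seed.
#' @param base_rate probability a background gene is annotated to any term.
#' @param elevated_rate probability a target gene is annotated to
#'   `enriched_term`.
#' @return data frame with columns `gene` and `term` (one row per
#'   annotation), deterministic for a fixed seed.
#' @export
generate_go_map <- function(n_genes = 100L, n_terms = 10L,
                            enriched_term = "GO:0000001",
                            target_genes = character(), seed = 1L,
                            base_rate = 0.05, elevated_rate = 0.9) {
  set.seed(as.integer(seed))
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  if (!enriched_term %in% terms) terms <- c(terms, enriched_term)
  out <- list()
  for (tm in terms) {
    ann <- runif(n_genes) < base_rate
    if (tm == enriched_term && length(target_genes)) {
      idx <- genes %in% target_genes
      ann[idx] <- runif(sum(idx)) < elevated_rate
    }
    if (any(ann)) out[[tm]] <- data.frame(gene = genes[ann], term = tm,
                                          stringsAsFactors = FALSE)
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d[order(d$gene, d$term), , drop = FALSE]
}
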