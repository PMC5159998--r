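# Readers and writers: FASTA (via Biostrings), GFF3 gene models, peak-list
# and report TSVs. All tables are TSV to avoid quoting ambiguity in peptide
# strings.

#' Read a FASTA file
#'
#' Sequences are upper-cased on load; record ids are left untouched. DNA
#' reads are validated against the A/C/G/T/N alphabet.
#'
#' @param path FASTA file.
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of sequences (empty for an empty file).
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) return(stats::setNames(character(0), character(0)))
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA '", path, "': sequence before header at line ",
         first)
  }
  set <- if (type == "DNA") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  out <- stats::setNames(toupper(as.character(set)), names(set))
  if (type == "DNA") {
    bad <- grepl("[^ACGTN]", out)
    if (any(bad)) {
      stop("non-ACGTN characters in DNA record(s): ",
           paste(utils::head(names(out)[bad], 3L), collapse = ", "))
    }
  }
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 80).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  stopifnot(is.character(x))
  if (length(x) > 0L && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stop("all sequences must be named")
  }
  is_dna <- length(x) > 0L && all(!grepl("[^ACGTN]", x))
  set <- if (is_dna) {
    Biostrings::DNAStringSet(x)
  } else {
    Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Write a TSV table
#'
#' Tab-separated, no quoting, no row names; the column order of the input is
#' preserved.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits the version pragma and gene/mRNA/exon/CDS rows with 1-based
#' inclusive coordinates. The CDS phase column is computed for the two-exon
#' structure (first CDS in transcript order has phase 0). Gene attributes
#' carry the core sequence, leader class, processability and score.
#' Coordinate inconsistencies (feature adjacency, start > end) are an error,
#' never silently clamped.
#'
#' @param models Gene-model data frame ([mine_genome()] or truth from
#'   [generate_scaffolds()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  if (nrow(models) > 0L) {
    starts <- c("exon1_start", "intron_start", "exon2_start")
    ends <- c("exon1_end", "intron_end", "exon2_end")
    for (i in seq_len(nrow(models))) {
      m <- models[i, ]
      if (any(unlist(m[starts]) > unlist(m[ends]))) {
        stop("model ", i, ": feature start exceeds end")
      }
      adjacent <- if (m$strand == "+") {
        m$exon1_end + 1L == m$intron_start &&
          m$intron_end + 1L == m$exon2_start
      } else {
        m$exon2_end + 1L == m$intron_start &&
          m$intron_end + 1L == m$exon1_start
      }
      if (!adjacent) stop("model ", i, ": exons not adjacent to intron")
      id <- sprintf("msdin%03d", i)
      score <- if (is.na(m$score)) "." else sprintf("%.2f", m$score)
      feat <- function(type, start, end, phase, attrs) {
        paste(m$scaffold, "msdinminer", type, start, end, score, m$strand,
              phase, attrs, sep = "\t")
      }
      gene_attrs <- sprintf(
        "ID=%s;core=%s;leader_class=%s;processable=%s;donor=%s",
        id, m$core, m$leader_class, m$processable, m$donor)
      # genomic (left-to-right) order of the two exons
      left_first <- m$exon1_start < m$exon2_start
      ex <- if (left_first) {
        rbind(c(m$exon1_start, m$exon1_end), c(m$exon2_start, m$exon2_end))
      } else {
        rbind(c(m$exon2_start, m$exon2_end), c(m$exon1_start, m$exon1_end))
      }
      exon1_nt <- m$exon1_end - m$exon1_start + 1L
      phase2 <- (3L - exon1_nt %% 3L) %% 3L
      # CDS phase by transcript order: exon1 first (phase 0)
      cds_phase <- if (left_first) c(0L, phase2) else c(phase2, 0L)
      lines <- c(
        lines,
        feat("gene", m$start, m$end, ".", gene_attrs),
        feat("mRNA", m$start, m$end, ".",
             sprintf("ID=%s.t1;Parent=%s", id, id)),
        feat("exon", ex[1, 1], ex[1, 2], ".",
             sprintf("Parent=%s.t1", id)),
        feat("exon", ex[2, 1], ex[2, 2], ".",
             sprintf("Parent=%s.t1", id)),
        feat("CDS", ex[1, 1], ex[1, 2], cds_phase[1],
             sprintf("ID=%s.cds;Parent=%s.t1", id, id)),
        feat("CDS", ex[2, 1], ex[2, 2], cds_phase[2],
             sprintf("ID=%s.cds;Parent=%s.t1", id, id))
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a peak list TSV
#'
#' Two columns (m/z, intensity), tab-separated, optional header. Peaks are
#' validated (m/z > 0) and sorted ascending on load.
#'
#' @param path Input TSV.
#' @return Data frame with columns `mz`, `intensity`.
#' @export
read_peaklist <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "\t", fixed = TRUE)[[1]][1])))
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("peak list must have two columns (m/z, intensity)")
  df <- df[, 1:2]
  names(df) <- c("mz", "intensity")
  .as_peaklist(df)
}

#' @rdname read_peaklist
#' @param pl Peak list data frame.
#' @param path Output path.
#' @export
write_peaklist <- function(pl, path) {
  write_tsv(pl[, c("mz", "intensity")], path)
}

#' Write the mining report TSV
#'
#' One row per gene model with the stable column order of [mine_genome()]
#' output (locus coordinates, strand, donor, intron length, leader class,
#' core, validation flags, score).
#'
#' @param models Gene-model data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mining_report <- function(models, path) {
  write_tsv(models[, .MODEL_COLUMNS], path)
}
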